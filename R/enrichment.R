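#' Counts-per-million normalization
#'
#' Each cycle's counts are divided by the cycle's total raw read count and
#' scaled to one million, so clone abundances are comparable across cycles
#' with different sequencing depths.  Inter-cycle differences (delta) and
#' fold changes between consecutive cycles are precomputed; fold changes use
#' a pseudo-CPM floor of 1 in the denominator so clones absent from the
#' earlier cycle get a finite fold.
#'
#' @param table A [counts_table] with strictly positive cycle totals.
#' @return An object of class `enrichment_profile` with elements `cpm`
#'   (sequence-by-cycle matrix), `delta` and `fold` (sequence by consecutive
#'   cycle pair), and `cycles` (integer cycle labels).
#' @export
normalize_cpm <- function(table) {
  stopifnot(inherits(table, "counts_table"))
  tot <- table$cycle_totals
  if (any(tot <= 0)) stop("zero-total cycle: CPM undefined")
  cpm <- sweep(table$counts, 2L, tot, "/") * 1e6
  ncyc <- ncol(cpm)
  pair_names <- paste(colnames(cpm)[-ncyc], colnames(cpm)[-1L], sep = "_to_")
  delta <- cpm[, -1L, drop = FALSE] - cpm[, -ncyc, drop = FALSE]
  fold <- cpm[, -1L, drop = FALSE] / pmax(cpm[, -ncyc, drop = FALSE], 1)
  colnames(delta) <- colnames(fold) <- pair_names
  structure(list(cpm = cpm, delta = delta, fold = fold,
                 cycles = cycle_labels(table)),
            class = "enrichment_profile")
}

#' @export
print.enrichment_profile <- function(x, ...) {
  cat(sprintf("enrichment_profile: %d sequences x %d cycles (cpm)\n",
              nrow(x$cpm), ncol(x$cpm)))
  invisible(x)
}

#' Positive-delta enrichment filter
#'
#' A clone passes when its CPM increases between two selection cycles.  The
#' default criterion is an absolute increase, `cpm[c+1] - cpm[c] > threshold`
#' (e.g. cpm cycle3 - cpm cycle2 > 1), over at least one consecutive cycle
#' pair (`mode = "any_pair"`) or a chosen pair (`mode = "specified_pair"`).
#' The stringent preset instead requires a fold increase of at least
#' `fold_threshold` (default 100, i.e. two orders of magnitude — the typical
#' enrichment of a good binder between cycles) with a pseudo-CPM floor of 1
#' for zero baselines.
#'
#' @param profile An [normalize_cpm()] result.
#' @param mode `"any_pair"` (any consecutive cycle pair) or
#'   `"specified_pair"`.
#' @param pair For `specified_pair`: index of the consecutive pair (1 =
#'   first-to-second cycle of the table).
#' @param threshold Absolute CPM increase that must be exceeded; default 1.
#' @param stringent Use the fold-change preset instead of the absolute delta.
#' @param fold_threshold Fold increase required under `stringent`.
#' @return Named logical vector, one entry per sequence.
#' @export
delta_filter <- function(profile, mode = c("any_pair", "specified_pair"),
                         pair = NULL, threshold = 1, stringent = FALSE,
                         fold_threshold = 100) {
  stopifnot(inherits(profile, "enrichment_profile"))
  mode <- match.arg(mode)
  if (threshold < 0) stop("threshold must be non-negative")
  crit <- if (stringent) profile$fold >= fold_threshold
          else profile$delta > threshold
  if (mode == "specified_pair") {
    if (is.null(pair) || pair < 1L || pair > ncol(profile$delta))
      stop("specified pair out of range (1..", ncol(profile$delta), ")")
    res <- crit[, pair]
  } else {
    res <- apply(crit, 1L, any)
  }
  setNames(as.logical(res), rownames(profile$cpm))
}

#' Per-cycle diversity diagnostics
#'
#' Shannon entropy (bits) of the clone frequency distribution and the share
#' of reads captured by the `top_k` most abundant clones, per cycle.  During
#' productive selection the entropy drops sharply and the top-clone share
#' saturates; both feed [find_breakpoint()].
#'
#' @param table A [counts_table].
#' @param top_k Number of top-ranking clones for the saturation share
#'   (default 100).
#' @return An object of class `cycle_profile`: data frame with columns
#'   `cycle`, `total_reads`, `distinct_clones`, `entropy_bits`,
#'   `top_k_share`.
#' @export
cycle_entropy <- function(table, top_k = 100L) {
  stopifnot(inherits(table, "counts_table"))
  m <- table$counts
  ent <- share <- numeric(ncol(m))
  distinct <- integer(ncol(m))
  for (c in seq_len(ncol(m))) {
    x <- m[, c]
    x <- x[x > 0L]
    distinct[c] <- length(x)
    if (length(x) == 0L) { ent[c] <- 0; share[c] <- 0; next }
    p <- x / sum(x)
    ent[c] <- -sum(p * log2(p))
    share[c] <- sum(sort(p, decreasing = TRUE)[seq_len(min(top_k, length(p)))])
  }
  structure(data.frame(cycle = cycle_labels(table),
                       total_reads = as.numeric(table$cycle_totals),
                       distinct_clones = distinct,
                       entropy_bits = ent,
                       top_k_share = share,
                       row.names = NULL),
            class = c("cycle_profile", "data.frame"),
            top_k = as.integer(top_k))
}

#' Breakpoint selection cycle
#'
#' The breakpoint is the earliest cycle after which relative enrichment
#' information saturates: later cycles flatten clone abundances, so ranking
#' clones there loses discrimination.  It is detected as the cycle preceding
#' the first inter-cycle gain in top-k clone share below
#' `saturation_epsilon`, provided clonal entropy was dropping into that
#' cycle (the diversity-loss signature of productive selection).  If no
#' cycle saturates, the cycle receiving the maximal
#' entropy drop is returned.  Ties resolve toward the earlier cycle.
#'
#' @param cp A [cycle_entropy()] result with at least 2 cycles (3 or more
#'   for a meaningful answer).
#' @param saturation_epsilon Top-k share gain below which a cycle adds no
#'   enrichment information (default 0.05).
#' @return Integer cycle label.  The saturation and entropy-drop components
#'   are attached as attributes so the call can be audited or overridden.
#' @export
find_breakpoint <- function(cp, saturation_epsilon = 0.05) {
  stopifnot(inherits(cp, "cycle_profile"))
  n <- nrow(cp)
  if (n < 2L) stop("at least 2 cycles are required")
  gain <- diff(cp$top_k_share)            # gain[i]: cycle i -> i+1
  drop <- -diff(cp$entropy_bits)          # drop[i]: entropy lost into cycle i+1
  bp <- NA_integer_
  saturated <- FALSE
  for (i in seq_len(n - 1L)) {
    if (gain[i] < saturation_epsilon) {
      # saturation alone is not enough: clonal diversity must have been
      # falling into the would-be breakpoint cycle (i), the entropy
      # signature of productive selection.  With no drop defined yet
      # (i = 1) there is no such evidence.
      if (i < 2L || drop[i - 1L] <= 0) next
      bp <- cp$cycle[i]
      saturated <- TRUE
      break
    }
  }
  if (is.na(bp)) bp <- cp$cycle[which.max(drop) + 1L]  # fallback: max drop
  structure(bp, gains = gain, entropy_drops = drop, saturated = saturated)
}
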
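#' Funnel run configuration
#'
#' Bundles and validates every tunable of the six-step funnel before any
#' compute.  Defaults reproduce the reference analysis: absolute
#' positive-delta threshold of 1 CPM over any consecutive cycle pair, the
#' MAEVQ/MAQVQ framework-1 and TVS framework-4 consensus, top-100
#' composition reporting, and ranking at the detected breakpoint cycle.
#'
#' @param frame_offset,fr1_prefixes,fr4_suffix,fr4_search_window See
#'   [consensus_config()].
#' @param delta_mode,delta_pair,delta_threshold,stringent,fold_threshold
#'   See [delta_filter()].
#' @param min_count Minimum count for [tabulate_reads()] when tabulating
#'   read sets.
#' @param top_k Top-ranking clones used for composition reporting and
#'   breakpoint saturation (default 100).
#' @param saturation_epsilon See [find_breakpoint()].
#' @param rank_cycle Cycle label to rank candidates at; `NULL` (default)
#'   uses the detected breakpoint cycle.
#' @param tup_db A `tup_db` object or path to one; `NULL` skips the scan.
#' @param tup_mode,tup_max_dist See [tup_scan()].
#' @param screen_id Identifier of the current screen (`target:campaign`),
#'   required when a TUP database is scanned.
#' @param output_dir Directory for intermediate TSV outputs; `NULL` writes
#'   nothing.
#' @return An object of class `funnel_config`.
#' @export
funnel_config <- function(frame_offset = 0L,
                          fr1_prefixes = c("MAEVQ", "MAQVQ"),
                          fr4_suffix = "TVS",
                          fr4_search_window = 10L,
                          delta_mode = c("any_pair", "specified_pair"),
                          delta_pair = NULL,
                          delta_threshold = 1,
                          stringent = FALSE,
                          fold_threshold = 100,
                          min_count = 1L,
                          top_k = 100L,
                          saturation_epsilon = 0.05,
                          rank_cycle = NULL,
                          tup_db = NULL,
                          tup_mode = c("vh_exact", "hcdr3_exact"),
                          tup_max_dist = 0L,
                          screen_id = "screen:run1",
                          output_dir = NULL) {
  delta_mode <- match.arg(delta_mode)
  tup_mode <- match.arg(tup_mode)
  consensus <- consensus_config(fr1_prefixes, fr4_suffix, frame_offset,
                                fr4_search_window)
  if (delta_threshold < 0) stop("delta_threshold must be non-negative")
  if (top_k < 1L) stop("top_k must be >= 1")
  if (is.character(tup_db)) tup_db <- read_tup_db(tup_db)
  if (!is.null(tup_db) && !inherits(tup_db, "tup_db"))
    stop("tup_db must be a tup_db object or a file path")
  structure(list(consensus = consensus, delta_mode = delta_mode,
                 delta_pair = delta_pair, delta_threshold = delta_threshold,
                 stringent = stringent, fold_threshold = fold_threshold,
                 min_count = as.integer(min_count), top_k = as.integer(top_k),
                 saturation_epsilon = saturation_epsilon,
                 rank_cycle = rank_cycle, tup_db = tup_db,
                 tup_mode = tup_mode, tup_max_dist = tup_max_dist,
                 screen_id = screen_id, output_dir = output_dir),
            class = "funnel_config")
}

# per-column TSV formatting: characters pass through (format() would pad
# them to a common width), numbers print full precision without scientific
# notation
.fmt_col <- function(x) {
  if (is.character(x)) x
  else if (is.factor(x)) as.character(x)
  else if (is.integer(x) || is.logical(x)) as.character(x)
  else format(x, scientific = FALSE, trim = TRUE, digits = 15)
}

.write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df))
    writeLines(do.call(paste, c(lapply(df, .fmt_col), sep = "\t")), con)
  invisible(path)
}

#' Run the six-step funnel
#'
#' Executes the full pipeline on a counts table: CPM normalization,
#' breakpoint diagnostics, the positive-delta filter, the ORF validity
#' cascade, synonymous-clone aggregation, the optional TUP database scan,
#' and ranking of the surviving candidate groups at the breakpoint cycle.
#' Every input sequence ends in exactly one terminal bin (`failed_delta`,
#' `no_fr1`, `has_stop`, `no_fr4`, `target_unrelated`, `candidate`).
#'
#' @param x A [counts_table], a `sim_screen`, a list of [read_set]s, or a
#'   path to a counts spreadsheet.
#' @param config A [funnel_config()].
#' @return An object of class `funnel_report`; see Details.
#' @details The report contains `steps` (retained/discarded per step),
#'   `cycle_profile` and `breakpoint`, the `cascade` result, the ranked
#'   `groups` (with TUP columns when a database was scanned), `candidates`
#'   (ranked, with HCDR3 and per-cycle CPM trajectory), `composition`
#'   (Fig.-4-style fractions of the `top_k` top-ranking clones at the
#'   breakpoint cycle that are candidates, target-unrelated, or non-valid),
#'   and `sequence_bins` (terminal bin of every input sequence).
#' @export
run_funnel <- function(x, config = funnel_config()) {
  stopifnot(inherits(config, "funnel_config"))
  run_id <- NULL
  if (inherits(x, "sim_screen")) {
    run_id <- x$config$seed
    x <- x$table
  } else if (is.character(x)) {
    x <- read_counts_spreadsheet(x)
  } else if (is.list(x) && !inherits(x, "counts_table") &&
             all(vapply(x, inherits, TRUE, "read_set"))) {
    x <- tabulate_reads(x, min_count = config$min_count)
  }
  stopifnot(inherits(x, "counts_table"))
  n_input <- nrow(x$counts)

  profile <- normalize_cpm(x)
  cp <- cycle_entropy(x, top_k = config$top_k)
  bp <- tryCatch(find_breakpoint(cp, config$saturation_epsilon),
                 error = function(e) NA_integer_)
  rank_cycle <- if (is.null(config$rank_cycle)) {
    if (is.na(bp)) max(cycle_labels(x)) else as.integer(bp)
  } else as.integer(config$rank_cycle)
  rank_col <- match(paste0("cycle", rank_cycle), colnames(x$counts))
  if (is.na(rank_col))
    stop("ranking cycle ", rank_cycle, " is not present in the table")

  # step 1: positive-delta filter
  passed <- delta_filter(profile, mode = config$delta_mode,
                         pair = config$delta_pair,
                         threshold = config$delta_threshold,
                         stringent = config$stringent,
                         fold_threshold = config$fold_threshold)
  bins <- setNames(rep("failed_delta", n_input), rownames(x$counts))

  # steps 2-4: ORF cascade on delta-passing sequences
  delta_seqs <- names(passed)[passed]
  casc <- run_cascade(delta_seqs, config$consensus)
  bins[delta_seqs] <- as.character(casc$bin)     # valid overwritten below

  # step 5: synonymous aggregation of valid inserts (possibly none survive)
  valid <- casc[casc$valid_insert, , drop = FALSE]
  groups <- collapse_synonyms(valid$dna, valid$aa,
                              x$counts[valid$dna, , drop = FALSE],
                              profile$cpm[valid$dna, , drop = FALSE])

  # step 6: TUP database scan
  if (!is.null(config$tup_db)) {
    groups <- tup_scan(groups, config$tup_db, config$screen_id,
                       mode = config$tup_mode,
                       max_dist = config$tup_max_dist)
  } else {
    groups$tup_match <- logical(nrow(groups))
    groups$match_screen <- rep(NA_character_, nrow(groups))
    groups$match_status <- rep(NA_character_, nrow(groups))
  }
  aa_bin <- ifelse(groups$tup_match, "target_unrelated", "candidate")
  names(aa_bin) <- groups$aa
  bins[valid$dna] <- unname(aa_bin[valid$aa])

  groups <- rank_groups(groups, rank_col)
  cand <- groups[!groups$tup_match, , drop = FALSE]
  cand_cpm <- attr(groups, "cpm")[!groups$tup_match, , drop = FALSE]
  candidates <- data.frame(rank = seq_len(nrow(cand)), aa = cand$aa,
                           hcdr3 = extract_hcdr3(cand$aa)$hcdr3,
                           multiplicity = cand$multiplicity,
                           member_dnas = cand$member_dnas,
                           stringsAsFactors = FALSE)
  candidates <- cbind(candidates,
                      setNames(as.data.frame(cand_cpm),
                               paste0("cpm_", colnames(cand_cpm))))
  rownames(candidates) <- NULL

  # Fig.-4-style composition snapshot of the top-k clones at the ranking
  # cycle: classified by insert validity and db membership directly, so the
  # snapshot is independent of delta-filter survival
  top_idx <- order(-profile$cpm[, rank_col],
                   rownames(profile$cpm))[seq_len(min(config$top_k, n_input))]
  top_casc <- run_cascade(rownames(profile$cpm)[top_idx], config$consensus)
  top_tup <- if (!is.null(config$tup_db))
    !is.na(.tup_match_aa(top_casc$aa, config$tup_db, config$screen_id,
                         config$tup_mode, config$tup_max_dist))
  else rep(FALSE, nrow(top_casc))
  comp_class <- ifelse(!top_casc$valid_insert, "non_valid",
                       ifelse(top_tup, "target_unrelated", "candidate"))
  composition <- as.data.frame(table(factor(comp_class,
    levels = c("candidate", "target_unrelated", "non_valid"))))
  names(composition) <- c("category", "n")
  composition$fraction <- composition$n / sum(composition$n)

  steps <- data.frame(
    step = c("input", "delta_filter", "orf_cascade", "synonym_collapse",
             "tup_scan"),
    retained = c(n_input, nrow(casc), nrow(valid), nrow(groups),
                 nrow(cand)),
    discarded = c(0L, n_input - nrow(casc), nrow(casc) - nrow(valid),
                  0L, nrow(groups) - nrow(cand)),
    unit = c("dna", "dna", "dna", "aa_groups", "aa_groups"))

  report <- structure(list(steps = steps, cycle_profile = cp,
                           breakpoint = as.integer(bp),
                           rank_cycle = rank_cycle,
                           cascade = casc, groups = groups,
                           candidates = candidates,
                           composition = composition,
                           sequence_bins = factor(bins,
                             levels = c("failed_delta", "no_fr1", "has_stop",
                                        "no_fr4", "target_unrelated",
                                        "candidate")),
                           config = config, run_id = run_id),
                      class = "funnel_report")
  if (!is.null(config$output_dir)) .write_report(report, x, profile)
  report
}

.write_report <- function(report, table, profile) {
  dir <- report$config$output_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  .write_tsv(as.data.frame(report$cycle_profile),
             file.path(dir, "cycle_diagnostics.tsv"))
  enr <- data.frame(sequence = rownames(profile$cpm),
                    setNames(as.data.frame(profile$cpm),
                             paste0("cpm_", colnames(profile$cpm))),
                    bin = as.character(report$sequence_bins),
                    stringsAsFactors = FALSE)
  enr <- enr[order(enr$sequence), , drop = FALSE]   # input-order independent
  .write_tsv(enr, file.path(dir, "enrichment.tsv"))
  casc <- as.data.frame(report$cascade)
  casc$bin <- as.character(casc$bin)
  casc <- casc[order(casc$dna), , drop = FALSE]
  .write_tsv(casc, file.path(dir, "funnel.tsv"))
  g <- as.data.frame(report$groups)
  gcpm <- attr(report$groups, "cpm")
  if (!is.null(gcpm))
    g <- cbind(g, setNames(as.data.frame(gcpm),
                           paste0("cpm_", colnames(gcpm))))
  .write_tsv(g, file.path(dir, "groups.tsv"))
  .write_tsv(report$candidates, file.path(dir, "candidates.tsv"))
  .write_tsv(report$composition, file.path(dir, "composition.tsv"))
  .write_tsv(report$steps, file.path(dir, "steps.tsv"))
  invisible(dir)
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("Six-step funnel report\n")
  cat(sprintf("  breakpoint cycle: %s (ranked at cycle %d)\n",
              ifelse(is.na(x$breakpoint), "n/a", x$breakpoint),
              x$rank_cycle))
  print(x$steps, row.names = FALSE)
  cat(sprintf("  candidates: %d ranked amino-acid groups\n",
              nrow(x$candidates)))
  invisible(x)
}

#' @export
summary.funnel_report <- function(object, ...) {
  print(object)
  cat("\nTop-", min(10L, nrow(object$candidates)), " candidates:\n",
      sep = "")
  print(head(object$candidates[c("rank", "aa", "hcdr3", "multiplicity")],
             10L), row.names = FALSE)
  cat(sprintf("\nComposition of the top-%d clones at cycle %d:\n",
              object$config$top_k, object$rank_cycle))
  print(object$composition, row.names = FALSE)
  invisible(object)
}

#' Composition chart of top-ranking clones
#'
#' Stacked-fraction view of sub-library composition: the share of the top-k
#' clones that are candidate binders, target-unrelated, or non-valid
#' inserts, one row (or bar) per screen — the cross-screen snapshot used to
#' compare campaigns.
#'
#' @param reports A `funnel_report` or list of them (optionally named by
#'   screen).
#' @param plot Draw a stacked barplot (base graphics).
#' @return Data frame with columns `screen`, `category`, `n`, `fraction`.
#' @export
composition_chart <- function(reports, plot = FALSE) {
  if (inherits(reports, "funnel_report")) reports <- list(reports)
  nm <- names(reports)
  if (is.null(nm)) nm <- vapply(reports, function(r) r$config$screen_id, "")
  rows <- do.call(rbind, lapply(seq_along(reports), function(i) {
    cbind(screen = nm[i], reports[[i]]$composition)
  }))
  rownames(rows) <- NULL
  if (plot) {
    m <- do.call(cbind, lapply(split(rows$fraction, rows$screen), identity))
    rownames(m) <- levels(rows$category)
    graphics::barplot(as.matrix(m), legend.text = rownames(m),
                      ylab = "fraction of top-ranking clones",
                      col = c("#2b8cbe", "#fdae61", "#d7191c"))
  }
  rows
}

#' @export
plot.funnel_report <- function(x, ...) {
  invisible(composition_chart(x, plot = TRUE))
}
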
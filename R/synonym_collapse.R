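#' Aggregate synonymous clones
#'
#' Distinct DNA sequences encoding the same amino-acid VH (synonymous
#' phages) share the enrichment behaviour of the protein they display, so
#' their per-cycle counts (and CPM) are summed and the number of distinct
#' DNA clones contributing — the multiplicity — is tracked as corroborating
#' evidence of binding.
#'
#' @param dna Character vector of valid-insert clone DNA sequences.
#' @param aa Their amino-acid translations (group key), same length.
#' @param counts Integer matrix of per-cycle counts, one row per clone, in
#'   the same order.
#' @param cpm Optional matrix of per-cycle CPM, same shape as `counts`.
#' @return An object of class `synonym_groups`: data frame with columns
#'   `aa`, `multiplicity`, `member_dnas` (semicolon-joined) plus the summed
#'   `counts` and `cpm` matrices stored as attributes (rows aligned with the
#'   data frame, ordered by aa for determinism).
#' @export
collapse_synonyms <- function(dna, aa, counts, cpm = NULL) {
  counts <- as.matrix(counts)
  if (length(dna) != length(aa) || nrow(counts) != length(dna))
    stop("dna, aa and counts rows must align")
  if (anyDuplicated(dna)) stop("duplicate DNA sequence in input")
  key <- factor(aa, levels = sort(unique(aa)))
  g_counts <- rowsum(counts, key)
  g_counts <- g_counts[levels(key), , drop = FALSE]
  storage.mode(g_counts) <- if (is.integer(counts)) "integer" else "double"
  g_cpm <- if (!is.null(cpm)) {
    m <- rowsum(as.matrix(cpm), key)
    m[levels(key), , drop = FALSE]
  }
  members <- vapply(split(dna, key),
                    function(d) paste(sort(d), collapse = ";"), "")
  mult <- as.integer(lengths(split(dna, key)))
  res <- data.frame(aa = levels(key), multiplicity = mult,
                    member_dnas = unname(members[levels(key)]),
                    stringsAsFactors = FALSE)
  attr(res, "counts") <- g_counts
  attr(res, "cpm") <- g_cpm
  class(res) <- c("synonym_groups", "data.frame")
  res
}

#' @export
print.synonym_groups <- function(x, ...) {
  cat(sprintf("synonym_groups: %d amino-acid groups from %d DNA clones\n",
              nrow(x), sum(x$multiplicity)))
  invisible(x)
}

#' Rank synonym groups by abundance at a cycle
#'
#' Descending CPM at the chosen cycle (typically the breakpoint cycle),
#' ties broken by multiplicity (higher first, giving more weight to
#' corroborated binding), then lexicographically by amino-acid sequence so
#' the ranking is deterministic.
#'
#' @param groups A [collapse_synonyms()] result.
#' @param cycle_col Column index into the group CPM/counts matrix to rank
#'   by.
#' @param key `"cpm_then_multiplicity"` (default) or `"cpm"` (ties then
#'   resolved by aa only).
#' @return The groups data frame reordered, with a `rank` column and the
#'   `ranked_by` cycle recorded as an attribute; the `counts`/`cpm`
#'   attributes are reordered in step.
#' @export
rank_groups <- function(groups, cycle_col,
                        key = c("cpm_then_multiplicity", "cpm")) {
  stopifnot(inherits(groups, "synonym_groups"))
  key <- match.arg(key)
  cpm <- attr(groups, "cpm")
  if (is.null(cpm)) cpm <- attr(groups, "counts")
  if (cycle_col < 1L || cycle_col > ncol(cpm))
    stop("cycle_col out of range (1..", ncol(cpm), ")")
  v <- cpm[, cycle_col]
  ord <- if (key == "cpm_then_multiplicity")
    order(-v, -groups$multiplicity, groups$aa)
  else order(-v, groups$aa)
  out <- groups[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "counts") <- attr(groups, "counts")[ord, , drop = FALSE]
  if (!is.null(attr(groups, "cpm")))
    attr(out, "cpm") <- attr(groups, "cpm")[ord, , drop = FALSE]
  attr(out, "ranked_by") <- cycle_col
  class(out) <- c("synonym_groups", "data.frame")
  out
}
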
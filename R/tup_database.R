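#' Extract the HCDR3 loop from a VH translation
#'
#' HCDR3, the hypervariable loop dominating antigen binding, is delimited by
#' near-constant anchors: the conserved cysteine at the end of framework 3
#' (preceded by a tyrosine within three residues, the Y-Y-C motif) and the
#' tryptophan opening framework 4 (the W-G-x-G motif).  The extracted loop
#' is the residues strictly between the last such cysteine and the first
#' subsequent W-G-x-G tryptophan.  Loops shorter than `min_len` or longer
#' than `max_len` residues, or sequences missing either anchor, yield `NA`
#' (a reported outcome, not an error).  The anchor heuristic is a
#' convention, not a full Kabat/IMGT numbering; explicit coordinates can be
#' supplied downstream where it misfires.
#'
#' @param aa Character vector of VH amino-acid sequences.
#' @param min_len,max_len Admissible HCDR3 length bounds (residues).
#' @return Data frame with columns `hcdr3` (NA when absent), `start`, `end`
#'   (0-based, half-open residue indices into the VH).
#' @export
extract_hcdr3 <- function(aa, min_len = 2L, max_len = 40L) {
  aa <- toupper(as.character(aa))
  res <- data.frame(hcdr3 = rep(NA_character_, length(aa)),
                    start = rep(NA_integer_, length(aa)),
                    end = rep(NA_integer_, length(aa)),
                    stringsAsFactors = FALSE)
  for (i in seq_along(aa)) {
    s <- aa[i]
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    cpos <- which(chars == "C")
    # last C with a Y within the 3 preceding residues (FR3 Y-Y-C end)
    ok <- vapply(cpos, function(p) {
      lo <- max(1L, p - 3L)
      p > 1L && any(chars[lo:(p - 1L)] == "Y")
    }, TRUE)
    cpos <- cpos[ok]
    if (!length(cpos)) next
    anchor_c <- max(cpos)
    rest <- substring(s, anchor_c + 1L)
    m <- regexpr("WG.G", rest)
    if (m < 0L) next
    anchor_w <- anchor_c + as.integer(m)      # position of the W
    loop <- substring(s, anchor_c + 1L, anchor_w - 1L)
    if (nchar(loop) < min_len || nchar(loop) > max_len) next
    res$hcdr3[i] <- loop
    res$start[i] <- anchor_c                  # 0-based, half-open
    res$end[i] <- anchor_w - 1L
  }
  res
}

.TUP_SCHEMA_VERSION <- 1L
.tup_cols <- c("aa_vh", "hcdr3", "source_screen", "best_rank", "max_cpm",
               "status", "date_added", "schema_version")

# target identity = part of the screen id before the first ':'
.screen_target <- function(screen_id) sub(":.*$", "", screen_id)

#' Create, read and write the target-unrelated clone database
#'
#' A flat append-only TSV of VH clones observed among the top-enriched
#' groups of completed screens, with their screen of origin, rank and CPM.
#' Clones enriched against two or more distinct targets are flagged as
#' predicted target-unrelated (TUPs); wet-lab confirmation can upgrade the
#' status to `validated`.  Screen identifiers follow the convention
#' `target:campaign`; the part before the first `:` defines target
#' identity.
#'
#' @param path TSV file path.
#' @return A `tup_db` data frame with columns `aa_vh`, `hcdr3`,
#'   `source_screen`, `best_rank`, `max_cpm`, `status`, `date_added`,
#'   `schema_version`.
#' @export
tup_db_new <- function() {
  db <- data.frame(aa_vh = character(), hcdr3 = character(),
                   source_screen = character(), best_rank = integer(),
                   max_cpm = numeric(), status = character(),
                   date_added = character(), schema_version = integer(),
                   stringsAsFactors = FALSE)
  class(db) <- c("tup_db", "data.frame")
  db
}

#' @rdname tup_db_new
#' @export
read_tup_db <- function(path) {
  if (!file.exists(path)) stop("TUP database not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                   colClasses = "character")
  missing <- setdiff(.tup_cols, names(df))
  if (length(missing))
    stop("TUP database missing columns: ", paste(missing, collapse = ", "))
  df <- df[.tup_cols]
  df$best_rank <- as.integer(df$best_rank)
  df$max_cpm <- as.numeric(df$max_cpm)
  df$schema_version <- as.integer(df$schema_version)
  class(df) <- c("tup_db", "data.frame")
  df
}

#' @rdname tup_db_new
#' @param db A `tup_db`.
#' @export
write_tup_db <- function(db, path) {
  stopifnot(inherits(db, "tup_db"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(.tup_cols, collapse = "\t"), con)
  if (nrow(db)) {
    body <- do.call(paste, c(lapply(db[.tup_cols], .fmt_col), sep = "\t"))
    writeLines(body, con)
  }
  invisible(path)
}

#' @export
print.tup_db <- function(x, ...) {
  cat(sprintf("tup_db: %d entries from %d screens (%d predicted, %d validated)\n",
              nrow(x), length(unique(x$source_screen)),
              sum(x$status == "predicted"), sum(x$status == "validated")))
  invisible(x)
}

#' Record a completed screen in the TUP database
#'
#' Appends the `top_n` enriched synonym groups of a finished screen with
#' their ranks and maximal CPM.  A VH becomes flagged as a predicted TUP
#' once it has been observed enriched in at least `min_screens_for_tup`
#' screens against distinct targets (default 2 — the weakest evidence
#' consistent with target-unrelated enrichment); until then entries carry
#' status `observed`.  The update is append-only and deterministic.
#'
#' @param db A `tup_db`.
#' @param groups A ranked [collapse_synonyms()] result (see
#'   [rank_groups()]).
#' @param screen_id Screen identifier, `target:campaign`.
#' @param top_n Number of top-ranked groups to record.
#' @param min_screens_for_tup Distinct-target screens required to flag a
#'   predicted TUP.
#' @param date Date string recorded with the entries (defaults to today);
#'   pass a fixed value for byte-reproducible pipelines.
#' @return The updated `tup_db`.
#' @export
tup_update <- function(db, groups, screen_id, top_n = 100L,
                       min_screens_for_tup = 2L,
                       date = format(Sys.Date())) {
  stopifnot(inherits(db, "tup_db"), inherits(groups, "synonym_groups"))
  if (is.null(groups$rank))
    stop("groups must be ranked (see rank_groups()) before db update")
  if (screen_id %in% db$source_screen)
    stop("screen '", screen_id, "' is already recorded in the database")
  top <- head(groups[order(groups$rank), , drop = FALSE], top_n)
  cpm <- attr(groups, "cpm")
  if (is.null(cpm)) cpm <- attr(groups, "counts")
  maxcpm <- apply(cpm, 1L, max)[order(groups$rank)][seq_len(nrow(top))]
  hc <- extract_hcdr3(top$aa)$hcdr3
  add <- data.frame(aa_vh = top$aa,
                    hcdr3 = ifelse(is.na(hc), "", hc),
                    source_screen = screen_id,
                    best_rank = top$rank,
                    max_cpm = as.numeric(maxcpm),
                    status = "observed",
                    date_added = date,
                    schema_version = .TUP_SCHEMA_VERSION,
                    stringsAsFactors = FALSE)
  if (any(paste(add$aa_vh, add$source_screen) %in%
          paste(db$aa_vh, db$source_screen)))
    stop("duplicate (sequence, screen) insertion")
  out <- rbind(db, add)
  # flag predicted TUPs: enriched against >= min_screens_for_tup targets
  tgt <- .screen_target(out$source_screen)
  ntarg <- vapply(split(tgt, out$aa_vh),
                  function(t) length(unique(t)), 0L)
  flag <- names(ntarg)[ntarg >= min_screens_for_tup]
  upgrade <- out$aa_vh %in% flag & out$status == "observed"
  out$status[upgrade] <- "predicted"
  class(out) <- c("tup_db", "data.frame")
  out
}

# core matcher: index into the cross-target slice of the db (NA = no match)
.tup_match_aa <- function(aa, db, current_screen, mode, max_dist = 0L) {
  other <- db[.screen_target(db$source_screen) !=
                .screen_target(current_screen), , drop = FALSE]
  if (mode == "vh_exact") {
    keys <- aa
    db_keys <- other$aa_vh
  } else {
    keys <- extract_hcdr3(aa)$hcdr3
    db_keys <- other$hcdr3
    db_keys[!nzchar(db_keys)] <- NA_character_
  }
  match_idx <- rep(NA_integer_, length(aa))
  usable <- which(!is.na(keys))
  if (nrow(other) && length(usable)) {
    if (max_dist == 0L) {
      match_idx[usable] <- match(keys[usable], db_keys)
    } else {
      dbok <- which(!is.na(db_keys))
      if (length(dbok)) {
        d <- utils::adist(keys[usable], db_keys[dbok])
        hit <- apply(d, 1L, function(r) {
          j <- which(r <= max_dist)
          if (length(j)) j[1L] else NA_integer_
        })
        match_idx[usable] <- dbok[hit]
      }
    }
  }
  match_idx
}

#' Scan candidate groups against the TUP database
#'
#' A group is discarded as target-unrelated when its VH amino-acid sequence
#' (`mode = "vh_exact"`) or its HCDR3 (`mode = "hcdr3_exact"`) matches a
#' database entry recorded from a screen against a *different* target;
#' entries from the current screen are circular evidence and raise an
#' error.  Matching is exact by default; `max_dist = 1` enables
#' edit-distance-1 fuzzy matching for error-bearing reads.
#'
#' @param groups A [collapse_synonyms()] result.
#' @param db A `tup_db`.
#' @param current_screen Screen identifier of the data being scanned.
#' @param mode Match on full VH or on HCDR3.
#' @param max_dist Maximum edit distance counted as a match (0 = exact).
#' @return The groups data frame with added columns `tup_match`,
#'   `match_screen`, `match_status`; the `candidate` /
#'   `target_unrelated` split is available via the `bin_counts` attribute.
#' @export
tup_scan <- function(groups, db, current_screen,
                     mode = c("vh_exact", "hcdr3_exact"), max_dist = 0L) {
  stopifnot(inherits(groups, "synonym_groups"), inherits(db, "tup_db"))
  mode <- match.arg(mode)
  if (any(db$source_screen == current_screen))
    stop("database contains entries from the current screen '",
         current_screen, "' (circular evidence)")
  match_idx <- .tup_match_aa(groups$aa, db, current_screen, mode, max_dist)
  other <- db[.screen_target(db$source_screen) !=
                .screen_target(current_screen), , drop = FALSE]
  out <- groups
  out$tup_match <- !is.na(match_idx)
  out$match_screen <- ifelse(out$tup_match,
                             other$source_screen[match_idx], NA_character_)
  out$match_status <- ifelse(out$tup_match,
                             other$status[match_idx], NA_character_)
  attr(out, "bin_counts") <- c(candidate = sum(!out$tup_match),
                               target_unrelated = sum(out$tup_match))
  class(out) <- c("synonym_groups", "data.frame")
  out
}
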
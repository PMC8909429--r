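#' Construct a read set for one selection cycle
#'
#' A read set holds the raw DNA reads sequenced from one biopanning
#' sub-library: cycle 0 is the naive library, cycles 1..n the successive
#' selection cycles.
#'
#' @param reads Character vector of DNA reads (alphabet A,C,G,T,N).
#' @param cycle_index Non-negative integer; 0 denotes the naive library.
#' @param source_path Optional path the reads were loaded from.
#' @param qualities Optional character vector of Phred+33 quality strings,
#'   same length as `reads`.
#' @return An object of class `read_set`.
#' @export
read_set <- function(reads, cycle_index, source_path = NA_character_,
                     qualities = NULL) {
  reads <- as.character(reads)
  cycle_index <- as.integer(cycle_index)
  if (is.na(cycle_index) || cycle_index < 0L)
    stop("cycle_index must be a non-negative integer")
  if (any(!nzchar(reads)))
    stop("read set contains empty reads")
  bad <- grepl("[^ACGTN]", reads)
  if (any(bad))
    stop("read ", which(bad)[1L],
         " contains characters outside the A,C,G,T,N alphabet")
  if (!is.null(qualities)) {
    qualities <- as.character(qualities)
    if (length(qualities) != length(reads))
      stop("qualities must match reads in length")
    if (any(nchar(qualities) != nchar(reads)))
      stop("quality strings must match read lengths")
  }
  structure(list(reads = reads, cycle_index = cycle_index,
                 source_path = source_path, qualities = qualities),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set: cycle %d, %d reads%s\n", x$cycle_index,
              length(x$reads),
              if (is.na(x$source_path)) "" else paste0(" (", x$source_path, ")")))
  invisible(x)
}

#' @export
length.read_set <- function(x) length(x$reads)

# locate the first structurally bad FASTQ record so parse errors can name it
.fastq_bad_record <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- length(lines)
  i <- 1L; rec <- 0L
  while (i <= n) {
    rec <- rec + 1L
    if (i + 3L > n) return(rec)
    if (!startsWith(lines[i], "@")) return(rec)
    if (!startsWith(lines[i + 2L], "+")) return(rec)
    if (nchar(lines[i + 1L]) != nchar(lines[i + 3L])) return(rec)
    i <- i + 4L
  }
  NA_integer_
}

#' Read per-cycle sequencing files
#'
#' Reads one FASTA or FASTQ file per selection cycle, in cycle order.  Reads
#' containing N are retained here (they are excluded, and tallied, later by
#' [tabulate_reads()]).
#'
#' @param paths Character vector of file paths, one per cycle, ordered by
#'   cycle.
#' @param format `"fastq"` or `"fasta"`.
#' @param cycle_indices Integer vector of cycle indices, same length as
#'   `paths`.  Defaults to `0, 1, ...` (naive library first).
#' @return A list of [read_set] objects, one per file, in the given order.
#' @export
read_cycle_files <- function(paths, format = c("fastq", "fasta"),
                             cycle_indices = seq_along(paths) - 1L) {
  format <- match.arg(format)
  if (length(cycle_indices) != length(paths))
    stop("cycle_indices must match paths in length")
  out <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    p <- paths[i]
    if (!file.exists(p)) stop("file not found: ", p)
    if (format == "fastq") {
      parsed <- tryCatch(withCallingHandlers({
        seqs <- Biostrings::readQualityScaledDNAStringSet(p)
        list(reads = as.character(seqs),
             quals = as.character(Biostrings::quality(seqs)))
      }, warning = function(w) {
        # Biostrings emits a benign metadata-column note on empty files
        if (grepl("metadata columns", conditionMessage(w)))
          invokeRestart("muffleWarning")
      }), error = function(e) {
        rec <- tryCatch(.fastq_bad_record(p), error = function(e2) NA_integer_)
        stop("malformed FASTQ in '", p, "'",
             if (!is.na(rec)) paste0(" at record ", rec) else "",
             ": ", conditionMessage(e), call. = FALSE)
      })
      reads <- parsed$reads
      quals <- parsed$quals
    } else {
      seqs <- tryCatch(
        Biostrings::readDNAStringSet(p, format = "fasta"),
        error = function(e) {
          stop("malformed FASTA in '", p, "': ", conditionMessage(e),
               call. = FALSE)
        })
      reads <- as.character(seqs)
      quals <- NULL
    }
    if (length(reads) == 0L)
      warning("no reads in '", p, "'")
    out[[i]] <- read_set(reads, cycle_indices[i], source_path = p,
                         qualities = quals)
  }
  out
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# merge one pair; returns NA_character_ when no admissible overlap exists
.merge_one <- function(a, b, qa, qb, min_overlap, max_mismatch_frac) {
  la <- nchar(a); lb <- nchar(b)
  if (min(la, lb) < min_overlap) return(NA_character_)
  for (ov in seq.int(min(la, lb), min_overlap, by = -1L)) {
    sa <- substring(a, la - ov + 1L, la)
    sb <- substring(b, 1L, ov)
    if (sa == sb) {
      mism <- integer(0)
    } else {
      ca <- strsplit(sa, "", fixed = TRUE)[[1L]]
      cb <- strsplit(sb, "", fixed = TRUE)[[1L]]
      mism <- which(ca != cb)
      if (length(mism) / ov > max_mismatch_frac) next
    }
    overlap <- sa
    if (length(mism)) {
      ca <- strsplit(sa, "", fixed = TRUE)[[1L]]
      cb <- strsplit(sb, "", fixed = TRUE)[[1L]]
      if (!is.null(qa) && !is.null(qb)) {
        pa <- utf8ToInt(substring(qa, la - ov + 1L, la))
        pb <- utf8ToInt(substring(qb, 1L, ov))
        take_b <- pb[mism] > pa[mism]
        ca[mism[take_b]] <- cb[mism[take_b]]
      }
      # FASTA (no qualities): disagreements resolve toward r1, i.e. keep ca
      overlap <- paste(ca, collapse = "")
    }
    return(paste0(substring(a, 1L, la - ov), overlap,
                  substring(b, ov + 1L, lb)))
  }
  NA_character_
}

#' Merge paired-end reads by suffix/prefix overlap
#'
#' The mate (`r2`) is reverse-complemented, then the longest suffix of `r1`
#' matching a prefix of the restored mate with at most `max_mismatch_frac`
#' mismatches and length at least `min_overlap` is used to join the pair.
#' Disagreements within the overlap are resolved toward the base with the
#' higher Phred quality when qualities are available, otherwise toward `r1`.
#' Pairs without an admissible overlap are dropped and counted in the
#' `n_dropped` attribute of the result.
#'
#' @param r1,r2 [read_set] objects of equal length and cycle index; `r2` as
#'   sequenced (it is reverse-complemented internally).
#' @param min_overlap Minimum overlap length in bases.
#' @param max_mismatch_frac Maximum fraction of mismatching bases tolerated
#'   within the overlap.
#' @return A [read_set] of merged reads, with attribute `n_dropped`.
#' @export
merge_paired_ends <- function(r1, r2, min_overlap = 10L,
                              max_mismatch_frac = 0.1) {
  stopifnot(inherits(r1, "read_set"), inherits(r2, "read_set"))
  if (length(r1$reads) != length(r2$reads))
    stop("r1 and r2 contain different numbers of reads")
  if (r1$cycle_index != r2$cycle_index)
    stop("r1 and r2 have different cycle indices")
  if (min_overlap < 1L) stop("min_overlap must be >= 1")
  b <- .revcomp(r2$reads)
  # reversing the read reverses its quality string
  qb <- if (!is.null(r2$qualities))
    vapply(r2$qualities, function(q)
      paste(rev(strsplit(q, "", fixed = TRUE)[[1L]]), collapse = ""), "",
      USE.NAMES = FALSE)
  merged <- character(length(r1$reads))
  keep <- logical(length(r1$reads))
  for (i in seq_along(r1$reads)) {
    m <- .merge_one(r1$reads[i], b[i],
                    if (is.null(r1$qualities)) NULL else r1$qualities[i],
                    if (is.null(qb)) NULL else qb[i],
                    min_overlap, max_mismatch_frac)
    if (!is.na(m)) { merged[i] <- m; keep[i] <- TRUE }
  }
  out <- read_set(merged[keep], r1$cycle_index, source_path = r1$source_path)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Construct a sequence-by-cycle counts table
#'
#' @param counts Integer matrix, rows = unique DNA sequences (rownames),
#'   columns = cycles; column names `cycle<k>`.
#' @param cycle_totals Total raw reads per cycle (before any pruning or
#'   N-exclusion); CPM normalization divides by these, so they reflect true
#'   sequencing depth.  Defaults to the column sums.
#' @param excluded_N,pruned Optional per-cycle read mass removed by
#'   N-exclusion and `min_count` pruning (bookkeeping for conservation
#'   checks).
#' @return An object of class `counts_table`.
#' @export
counts_table <- function(counts, cycle_totals = colSums(counts),
                         excluded_N = NULL, pruned = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(rownames(counts))) stop("counts must have sequence rownames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sequence: ",
         rownames(counts)[duplicated(rownames(counts))][1L])
  if (any(counts < 0L)) stop("negative counts are not allowed")
  if (ncol(counts) < 2L)
    stop("at least 2 cycles are required (inter-cycle delta is undefined)")
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("cycle", seq_len(ncol(counts)) - 1L)
  cycle_totals <- as.numeric(cycle_totals)
  if (length(cycle_totals) != ncol(counts))
    stop("cycle_totals must have one entry per cycle")
  if (any(cycle_totals < colSums(counts) - 1e-9))
    stop("cycle_totals cannot be smaller than the column sums")
  structure(list(counts = counts,
                 cycle_totals = setNames(cycle_totals, colnames(counts)),
                 excluded_N = excluded_N, pruned = pruned),
            class = "counts_table")
}

#' @export
print.counts_table <- function(x, ...) {
  cat(sprintf("counts_table: %d unique sequences x %d cycles\n",
              nrow(x$counts), ncol(x$counts)))
  cat("cycle totals:", paste(format(x$cycle_totals, big.mark = ","),
                             collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.counts_table <- function(x) dim(x$counts)

#' Cycle labels of a counts table
#'
#' Integer cycle indices parsed from the column names (`cycle<k>`).
#' @param table A [counts_table].
#' @return Integer vector of cycle indices.
#' @export
cycle_labels <- function(table) {
  as.integer(sub("^cycle", "", colnames(table$counts)))
}

#' Tabulate reads into a sequence-by-cycle counts table
#'
#' Exact-match counting of unique DNA sequences per cycle.  Reads containing
#' N are excluded from counting and tallied.  `cycle_totals` are the raw read
#' totals *before* pruning and N-exclusion, so CPM normalization reflects
#' true sequencing depth.  Sequences whose maximum count over all cycles is
#' below `min_count` are dropped; their per-cycle mass is recorded in
#' `pruned`.
#'
#' @param readsets List of [read_set] objects, at least two.
#' @param min_count Minimum (maximum-over-cycles) count to retain a sequence.
#' @return A [counts_table].
#' @export
tabulate_reads <- function(readsets, min_count = 1L) {
  if (length(readsets) < 2L)
    stop("at least 2 cycles are required (inter-cycle delta is undefined)")
  if (min_count < 1L) stop("min_count must be >= 1")
  ncyc <- length(readsets)
  labels <- vapply(readsets, function(r) r$cycle_index, 0L)
  totals <- vapply(readsets, function(r) length(r$reads), 0L)
  tabs <- vector("list", ncyc)
  excl <- integer(ncyc)
  for (c in seq_len(ncyc)) {
    reads <- readsets[[c]]$reads
    hasN <- grepl("N", reads, fixed = TRUE)
    excl[c] <- sum(hasN)
    tabs[[c]] <- table(reads[!hasN])
  }
  seqs <- unique(unlist(lapply(tabs, names), use.names = FALSE))
  if (length(seqs) == 0L)
    stop("no countable reads (all reads contain N or inputs are empty)")
  m <- matrix(0L, nrow = length(seqs), ncol = ncyc,
              dimnames = list(seqs, paste0("cycle", labels)))
  for (c in seq_len(ncyc)) {
    t <- tabs[[c]]
    m[match(names(t), seqs), c] <- as.integer(t)
  }
  keep <- apply(m, 1L, max) >= min_count
  pruned <- colSums(m[!keep, , drop = FALSE])
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0L) stop("no sequences survive min_count pruning")
  counts_table(m, cycle_totals = totals,
               excluded_N = setNames(excl, colnames(m)),
               pruned = setNames(as.integer(pruned), colnames(m)))
}

#' Read / write the standardized counts spreadsheet
#'
#' Tab-delimited UTF-8 text with header `sequence` followed by one
#' `count_cycle<k>` column per cycle.  Cycle totals (which exceed column sums
#' when the table was pruned) are carried in a `#cycle_totals:` comment line
#' above the header; files without it fall back to totals = column sums.
#' Writing then reading reproduces the table exactly.
#'
#' @param path File path.
#' @return `read_counts_spreadsheet` returns a [counts_table].
#' @export
read_counts_spreadsheet <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  totals <- NULL
  com <- grep("^#", lines)
  tl <- grep("^#cycle_totals:", lines, value = TRUE)
  if (length(tl))
    totals <- as.numeric(strsplit(sub("^#cycle_totals:\t?", "", tl[1L]),
                                  "\t", fixed = TRUE)[[1L]])
  body <- if (length(com)) lines[-com] else lines
  if (!length(body) || !grepl("^sequence\t", body[1L]))
    stop("missing or malformed header: expected 'sequence\\tcount_cycle0...'")
  df <- read.delim(text = body, header = TRUE, sep = "\t",
                   colClasses = "character", check.names = FALSE,
                   quote = "")
  cyc_cols <- grep("^count_cycle[0-9]+$", names(df), value = TRUE)
  if (!length(cyc_cols)) stop("no count_cycle<k> columns found")
  if (anyDuplicated(df$sequence))
    stop("duplicate sequence: ", df$sequence[duplicated(df$sequence)][1L])
  m <- vapply(df[cyc_cols], function(col) {
    v <- suppressWarnings(as.numeric(col))
    if (anyNA(v)) stop("non-numeric count value")
    if (any(v < 0)) stop("negative counts are not allowed")
    as.integer(v)
  }, integer(nrow(df)))
  if (is.null(dim(m))) m <- matrix(m, nrow = nrow(df))
  rownames(m) <- df$sequence
  colnames(m) <- sub("^count_", "", cyc_cols)
  if (is.null(totals)) totals <- colSums(m)
  counts_table(m, cycle_totals = totals)
}

#' @rdname read_counts_spreadsheet
#' @param table A [counts_table].
#' @export
write_counts_spreadsheet <- function(table, path) {
  stopifnot(inherits(table, "counts_table"))
  con <- file(path, open = "wb")  # binary mode: LF endings, reproducible
  on.exit(close(con))
  writeLines(paste0("#cycle_totals:\t",
                    paste(format(table$cycle_totals, scientific = FALSE,
                                 trim = TRUE), collapse = "\t")),
             con)
  hdr <- paste(c("sequence", paste0("count_", colnames(table$counts))),
               collapse = "\t")
  writeLines(hdr, con)
  rows <- apply(table$counts, 1L, paste, collapse = "\t")
  writeLines(paste(rownames(table$counts), rows, sep = "\t"), con)
  invisible(path)
}

#' Write a read set as FASTQ or FASTA
#'
#' @param rs A [read_set].  FASTQ output uses the stored qualities, or a
#'   constant Phred 37 ("F") when absent.
#' @param path Output path.
#' @param format `"fastq"` or `"fasta"`.
#' @export
write_reads <- function(rs, path, format = c("fastq", "fasta")) {
  format <- match.arg(format)
  stopifnot(inherits(rs, "read_set"))
  seqs <- Biostrings::DNAStringSet(rs$reads)
  names(seqs) <- sprintf("cycle%d_read%d", rs$cycle_index,
                         seq_along(rs$reads))
  if (format == "fastq") {
    q <- rs$qualities
    if (is.null(q)) q <- strrep("F", nchar(rs$reads))
    Biostrings::writeXStringSet(seqs, path, format = "fastq",
                                qualities = Biostrings::BStringSet(q))
  } else {
    Biostrings::writeXStringSet(seqs, path, format = "fasta")
  }
  invisible(path)
}
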
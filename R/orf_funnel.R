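#' Framework consensus configuration
#'
#' The open-reading-frame validity cascade anchors on near-constant
#' framework motifs of the displayed VH: the framework-1 (FR1) consensus at
#' the start of the translation (vector-encoded MA followed by EVQ or QVQ in
#' the reference library) and the framework-4 (FR4) consensus at its end
#' (TVS).  Both are configurable so the cascade adapts to scFv or nanobody
#' libraries with different framework sequences.
#'
#' @param fr1_prefixes Character vector of accepted amino-acid prefixes.
#' @param fr4_suffix Required amino-acid suffix of the VH.
#' @param frame_offset Reading-frame offset (0, 1 or 2) fixed by the library
#'   vector design.
#' @param fr4_search_window FR4 suffix is searched within this many terminal
#'   residues, so primer or adapter remnants past FR4 do not fail valid
#'   clones.
#' @return An object of class `consensus_config`.
#' @export
consensus_config <- function(fr1_prefixes = c("MAEVQ", "MAQVQ"),
                             fr4_suffix = "TVS", frame_offset = 0L,
                             fr4_search_window = 10L) {
  fr1_prefixes <- toupper(as.character(fr1_prefixes))
  fr4_suffix <- toupper(as.character(fr4_suffix))
  if (!length(fr1_prefixes) || any(!nzchar(fr1_prefixes)))
    stop("fr1_prefixes must be non-empty")
  if (length(fr4_suffix) != 1L || !nzchar(fr4_suffix))
    stop("fr4_suffix must be a single non-empty string")
  if (any(grepl("\\*", c(fr1_prefixes, fr4_suffix))))
    stop("consensus motifs must be stop-free")
  if (!frame_offset %in% 0:2) stop("frame_offset must be 0, 1 or 2")
  structure(list(fr1_prefixes = fr1_prefixes, fr4_suffix = fr4_suffix,
                 frame_offset = as.integer(frame_offset),
                 fr4_search_window = as.integer(fr4_search_window)),
            class = "consensus_config")
}

#' Translate VH DNA in a fixed reading frame
#'
#' Standard genetic code; the frame is fixed by the library vector (scanning
#' for the best ORF would mask exactly the frameshifts the cascade must
#' catch).  The trailing partial codon is dropped, stop codons are rendered
#' `*`, and codons containing N are rendered `X`.
#'
#' @param dna Character vector of DNA sequences (A,C,G,T,N).
#' @param frame_offset Integer 0, 1 or 2.
#' @return Character vector of amino-acid sequences (may be empty strings
#'   for inputs shorter than one codon).
#' @export
translate_vh <- function(dna, frame_offset = 0L) {
  if (!frame_offset %in% 0:2) stop("frame_offset must be 0, 1 or 2")
  n <- nchar(dna)
  aalen <- pmax((n - frame_offset) %/% 3L, 0L)
  out <- character(length(dna))
  nz <- which(aalen > 0L)
  if (length(nz)) {
    trimmed <- substring(dna[nz], frame_offset + 1L,
                         frame_offset + 3L * aalen[nz])
    aa <- Biostrings::translate(Biostrings::DNAStringSet(trimmed),
                                no.init.codon = TRUE, if.fuzzy.codon = "X")
    out[nz] <- as.character(aa)
  }
  out
}

#' ORF cascade filters
#'
#' The three validity filters applied, in order, to translated clones
#' passing the enrichment filter: `filter_fr1` requires the translation to
#' start with one of the configured FR1 consensus prefixes; `filter_stop`
#' requires it to be free of stop codons; `filter_fr4` requires the VH to
#' end with the FR4 consensus suffix.  All matches are exact — mismatch
#' tolerance would re-admit the error-bearing reads the cascade exists to
#' remove — and `X` residues (from N-containing codons) count as mismatches.
#' For `filter_fr4`, when the suffix occurs within the terminal
#' `fr4_search_window` residues the translation is truncated there first, so
#' linker or adapter remnants downstream of FR4 do not fail valid clones.
#'
#' @param aa Character vector of amino-acid sequences.
#' @param cfg A [consensus_config].
#' @return Logical vector.
#' @export
filter_fr1 <- function(aa, cfg = consensus_config()) {
  aa <- toupper(aa)
  res <- rep(FALSE, length(aa))
  for (p in cfg$fr1_prefixes) res <- res | startsWith(aa, p)
  res
}

#' @rdname filter_fr1
#' @export
filter_stop <- function(aa) {
  !grepl("*", aa, fixed = TRUE)
}

#' @rdname filter_fr1
#' @export
filter_fr4 <- function(aa, cfg = consensus_config()) {
  aa <- toupper(aa)
  suf <- cfg$fr4_suffix
  w <- cfg$fr4_search_window
  n <- nchar(aa)
  res <- endsWith(aa, suf)
  # tolerate trailing residues past FR4: accept if the suffix ends within
  # the terminal search window
  todo <- which(!res & n >= nchar(suf))
  for (i in todo) {
    tail_start <- max(1L, n[i] - w + 1L)
    tail_aa <- substring(aa[i], tail_start, n[i])
    if (grepl(suf, tail_aa, fixed = TRUE)) res[i] <- TRUE
  }
  res
}

#' Run the ORF validity cascade
#'
#' Translates each clone in the configured frame and applies the three
#' filters in order (FR1 consensus, stop codons, FR4 consensus); a clone is
#' binned by the first filter it fails, so the bins partition the input.
#' The cascade only labels clones — sequences and counts are never modified.
#'
#' @param dna Character vector of unique clone DNA sequences.
#' @param cfg A [consensus_config].
#' @return An object of class `orf_cascade`: data frame with columns `dna`,
#'   `aa`, `fr1_ok`, `stop_free`, `fr4_ok`, `valid_insert` and `bin` (one of
#'   `valid`, `no_fr1`, `has_stop`, `no_fr4`), plus a `bin_counts` attribute
#'   for composition reporting.
#' @export
run_cascade <- function(dna, cfg = consensus_config()) {
  dna <- as.character(dna)
  aa <- translate_vh(dna, cfg$frame_offset)
  fr1 <- filter_fr1(aa, cfg)
  stp <- filter_stop(aa)
  fr4 <- filter_fr4(aa, cfg)
  bin <- rep("valid", length(dna))
  bin[!fr4] <- "no_fr4"
  bin[!stp] <- "has_stop"
  bin[!fr1] <- "no_fr1"        # cascade order: first failing filter wins
  res <- data.frame(dna = dna, aa = aa, fr1_ok = fr1, stop_free = stp,
                    fr4_ok = fr4, valid_insert = fr1 & stp & fr4,
                    bin = factor(bin, levels = c("valid", "no_fr1",
                                                 "has_stop", "no_fr4")),
                    stringsAsFactors = FALSE)
  attr(res, "bin_counts") <- table(res$bin)
  class(res) <- c("orf_cascade", "data.frame")
  res
}

#' @export
print.orf_cascade <- function(x, ...) {
  bc <- attr(x, "bin_counts")
  cat("ORF validity cascade:", nrow(x), "clones\n")
  print(bc)
  invisible(x)
}
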
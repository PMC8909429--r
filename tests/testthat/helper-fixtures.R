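# Fixture builders shared across the suite.  The VH scaffold here is built
# independently of the package's simulator internals so cascade tests do not
# lean on the code they check.

# minimal codon map (one codon per amino acid) for hand-built VH fixtures
codon_of <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
              G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTG",
              M = "ATG", N = "AAT", P = "CCT", Q = "CAG", R = "CGT",
              S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT",
              "*" = "TAA")

aa_letters <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# n distinct CDR3s built from a stem plus enumerated residue pairs
cdr3_series <- function(n, stem = "AR") {
  pairs <- expand.grid(aa_letters, aa_letters, stringsAsFactors = FALSE)
  paste0(stem, pairs[[1L]][seq_len(n)], pairs[[2L]][seq_len(n)])
}

aa2dna <- function(aa) {
  paste(codon_of[strsplit(aa, "", fixed = TRUE)[[1L]]], collapse = "")
}

# a valid VH amino-acid sequence around a chosen HCDR3
vh_aa <- function(cdr3 = "ARDRST", fr1 = "MAEVQ") {
  paste0(fr1, "LVESGGGLVQPGGSLRLSCAASGFTFSSYAMSWVRQAPGKGLEWVS",
         "AISGSGGSTYYADSVKGRFTISRDNSKNTLYLQMNSLRAEDTAVYYC",
         cdr3, "WGQGTTVTVS")
}

vh_dna <- function(cdr3 = "ARDRST", fr1 = "MAEVQ") aa2dna(vh_aa(cdr3, fr1))

# counts_table from a plain matrix with optional explicit cycle labels
ct <- function(m, cycles = seq_len(ncol(m)) - 1L, totals = colSums(m)) {
  if (is.null(rownames(m)))
    rownames(m) <- paste0("SEQ", seq_len(nrow(m)))
  colnames(m) <- paste0("cycle", cycles)
  counts_table(m, cycle_totals = totals)
}

# random small counts table (for property tests)
random_table <- function(nseq = sample(2:10, 1L), ncyc = 4L,
                         max_count = 50L) {
  m <- matrix(sample(0:max_count, nseq * ncyc, replace = TRUE), nseq, ncyc)
  m[rowSums(m) == 0L, 1L] <- 1L
  rownames(m) <- paste0("S", seq_len(nseq))
  ct(m)
}

write_fasta <- function(seqs, path, names = paste0("r", seq_along(seqs))) {
  writeLines(paste0(">", names, "\n", seqs), path)
  path
}

write_fastq <- function(seqs, path, quals = strrep("I", nchar(seqs)),
                        names = paste0("r", seq_along(seqs))) {
  writeLines(paste0("@", names, "\n", seqs, "\n+\n", quals), path)
  path
}

revcomp_chr <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(x, function(s) paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]),
                                     collapse = ""), "", USE.NAMES = FALSE))
}
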
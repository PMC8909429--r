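test_that("cycle files are read record-for-record, in order", {
  fa <- write_fasta(c("ACGT", "GGGG", "ACGTN"), tempfile(fileext = ".fa"))
  rs <- read_cycle_files(fa, format = "fasta")
  expect_length(rs, 1L)
  expect_equal(rs[[1L]]$reads, c("ACGT", "GGGG", "ACGTN"))  # N retained here
  expect_equal(rs[[1L]]$cycle_index, 0L)

  fq <- write_fastq(c("ACGT", "TTTT"), tempfile(fileext = ".fq"))
  rsq <- read_cycle_files(fq, format = "fastq")
  expect_equal(rsq[[1L]]$reads, c("ACGT", "TTTT"))
  expect_equal(rsq[[1L]]$qualities, c("IIII", "IIII"))

  rs <- read_cycle_files(c(fa, fa, fa), format = "fasta",
                         cycle_indices = 0:2)
  expect_equal(vapply(rs, function(r) r$cycle_index, 0L), 0:2)
})

test_that("empty and malformed inputs are reported by name", {
  empty <- tempfile(fileext = ".fq"); file.create(empty)
  expect_warning(rs <- read_cycle_files(empty, format = "fastq"),
                 "no reads")
  expect_length(rs[[1L]]$reads, 0L)

  trunc <- tempfile(fileext = ".fq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT"), trunc)
  err <- expect_error(read_cycle_files(trunc, format = "fastq"))
  expect_match(conditionMessage(err), basename(trunc), fixed = TRUE)
  expect_match(conditionMessage(err), "record 2", fixed = TRUE)
})

test_that("read sets enforce their alphabet and cycle invariants", {
  expect_error(read_set(c("ACGT", "ACXT"), 1L), "alphabet")
  expect_error(read_set("ACGT", -1L), "non-negative")
  expect_error(read_set(c("ACGT", ""), 0L), "empty")
})

test_that("paired-end merging joins on the best admissible overlap", {
  r1 <- read_set("ACGTACGT", 1L)
  r2 <- read_set(revcomp_chr("TACGTTTT"), 1L)
  m <- merge_paired_ends(r1, r2, min_overlap = 5L, max_mismatch_frac = 0)
  expect_equal(m$reads, "ACGTACGTTTT")
  expect_equal(attr(m, "n_dropped"), 0L)

  # identical full-length pair collapses onto r1
  r1 <- read_set("ACGTACGTAC", 2L)
  r2 <- read_set(revcomp_chr("ACGTACGTAC"), 2L)
  m <- merge_paired_ends(r1, r2, min_overlap = 5L, max_mismatch_frac = 0)
  expect_equal(m$reads, "ACGTACGTAC")

  # zero-overlap pair is dropped and counted
  r1 <- read_set("AAAAAAAA", 1L)
  r2 <- read_set(revcomp_chr("CCCCCCCC"), 1L)
  m <- merge_paired_ends(r1, r2, min_overlap = 5L, max_mismatch_frac = 0)
  expect_length(m$reads, 0L)
  expect_equal(attr(m, "n_dropped"), 1L)

  expect_error(merge_paired_ends(read_set(c("ACGT", "ACGT"), 1L),
                                 read_set("ACGT", 1L), 4L),
               "different numbers")
})

test_that("overlap disagreements resolve toward the higher-quality base", {
  # overlap of 6 with one disagreement at its 3rd position
  a <- "ACGTAC"            # r1 entirely overlap
  b_seq <- "ACTTAC"        # restored mate; disagrees at position 3 (G vs T)
  r1 <- read_set(a, 1L, qualities = "II#III")        # low quality at pos 3
  r2 <- read_set(revcomp_chr(b_seq), 1L, qualities = "IIIIII")
  m <- merge_paired_ends(r1, r2, min_overlap = 6L, max_mismatch_frac = 0.5)
  expect_equal(m$reads, "ACTTAC")                    # mate wins at pos 3

  # without qualities (FASTA), r1 wins
  r1f <- read_set(a, 1L)
  r2f <- read_set(revcomp_chr(b_seq), 1L)
  mf <- merge_paired_ends(r1f, r2f, min_overlap = 6L,
                          max_mismatch_frac = 0.5)
  expect_equal(mf$reads, "ACGTAC")
})

test_that("merging is deterministic and independent across pairs", {
  set.seed(42)
  mk <- function(n) vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE), collapse = ""),
    "")
  core <- mk(8)
  r1 <- read_set(substring(core, 1L, 22L), 1L)
  r2 <- read_set(revcomp_chr(substring(core, 9L, 30L)), 1L)
  m1 <- merge_paired_ends(r1, r2, min_overlap = 10L, max_mismatch_frac = 0)
  expect_equal(m1$reads, core)
  perm <- sample(8)
  r1p <- read_set(r1$reads[perm], 1L)
  r2p <- read_set(r2$reads[perm], 1L)
  m2 <- merge_paired_ends(r1p, r2p, min_overlap = 10L, max_mismatch_frac = 0)
  expect_equal(m2$reads, m1$reads[perm])
})

test_that("tabulation counts exact matches and preserves read mass", {
  rs <- list(read_set(c("AAAA", "AAAA", "CCCC"), 0L),
             read_set(rep("AAAA", 5L), 1L))
  tab <- tabulate_reads(rs, min_count = 1L)
  expect_equal(unname(tab$counts[c("AAAA", "CCCC"), ]),
               matrix(c(2L, 1L, 5L, 0L), 2L, 2L, byrow = FALSE))
  expect_equal(unname(tab$cycle_totals), c(3, 5))

  tab2 <- tabulate_reads(rs, min_count = 2L)       # CCCC pruned
  expect_false("CCCC" %in% rownames(tab2$counts))
  expect_equal(unname(tab2$cycle_totals), c(3, 5)) # totals pre-pruning

  expect_error(tabulate_reads(rs[1L]), "2 cycles")
  rsN <- list(read_set(c("ANAA", "NNNN"), 0L), read_set("ANAA", 1L))
  expect_error(tabulate_reads(rsN), "no countable reads")
})

test_that("count mass is conserved: counts + N-excluded + pruned = raw", {
  set.seed(7)
  pool <- c("AAAA", "CCCC", "GGGG", "TTTT", "ANGT", "TTNN")
  rs <- lapply(0:2, function(c)
    read_set(sample(pool, 40, replace = TRUE), c))
  for (mc in 1:3) {
    tab <- tabulate_reads(rs, min_count = mc)
    recovered <- colSums(tab$counts) + tab$excluded_N + tab$pruned
    expect_equal(unname(recovered), unname(tab$cycle_totals))
  }
})

test_that("the counts spreadsheet round-trips exactly", {
  set.seed(11)
  m <- matrix(sample(0:100, 400, replace = TRUE), 100, 4,
              dimnames = list(paste0("S", 1:100), paste0("cycle", 0:3)))
  tab <- counts_table(m, cycle_totals = colSums(m) + c(10, 0, 5, 2))
  f <- tempfile(fileext = ".tsv")
  write_counts_spreadsheet(tab, f)
  back <- read_counts_spreadsheet(f)
  expect_identical(back$counts, tab$counts)
  expect_identical(back$cycle_totals, tab$cycle_totals)
  # write-read-write is byte-stable
  f2 <- tempfile(fileext = ".tsv")
  write_counts_spreadsheet(back, f2)
  expect_identical(readBin(f, "raw", file.size(f)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("malformed spreadsheets are rejected with the offender named", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("sequence\tcount_cycle0\tcount_cycle1",
               "AAAA\t3\t4", "AAAA\t1\t0"), f)
  expect_error(read_counts_spreadsheet(f), "AAAA")
  writeLines(c("sequence\tcount_cycle0\tcount_cycle1", "AAAA\t-3\t4"), f)
  expect_error(read_counts_spreadsheet(f), "negative")
  writeLines(c("AAAA\t3\t4"), f)
  expect_error(read_counts_spreadsheet(f), "header")
})
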
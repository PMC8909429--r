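test_that("CPM follows its definition and columns sum to one million", {
  m <- matrix(c(1L, 0L, 5L, 0L), 2L, 2L,
              dimnames = list(c("A", "B"), c("cycle1", "cycle2")))
  tab <- counts_table(m, cycle_totals = c(1e6, 2e6))
  prof <- normalize_cpm(tab)
  expect_equal(prof$cpm["A", "cycle1"], 1.0)
  expect_equal(prof$cpm["A", "cycle2"], 2.5)

  for (i in 1:20) {
    tab <- random_table()
    prof <- normalize_cpm(tab)  # unpruned: totals = colSums
    expect_equal(unname(colSums(prof$cpm)), rep(1e6, ncol(tab$counts)),
                 tolerance = 1e-6)
  }
  zt <- counts_table(matrix(c(0L, 0L, 1L, 1L), 2L, 2L,
                            dimnames = list(c("A", "B"), NULL)),
                     cycle_totals = c(0, 2))
  expect_error(normalize_cpm(zt), "zero-total")
})

test_that("the positive-delta filter keeps only clones that enrich", {
  # totals of 2e6 reads make cpm = counts / 2
  m <- rbind(down = c(20L, 10L, 6L), up = c(1L, 2L, 7L))
  colnames(m) <- paste0("cycle", 1:3)
  prof <- normalize_cpm(counts_table(m, cycle_totals = rep(2e6, 3L)))
  expect_equal(unname(prof$cpm["up", ]), c(0.5, 1.0, 3.5))
  res <- delta_filter(prof, threshold = 1)
  expect_false(res[["down"]])   # cpm (10, 5, 3): monotone decrease
  expect_true(res[["up"]])      # 3.5 - 1.0 = 2.5 > 1

  # stringent preset: two orders of magnitude between consecutive cycles
  m2 <- rbind(good = c(1L, 50L, 5000L), near = c(1L, 50L, 4999L))
  colnames(m2) <- paste0("cycle", 1:3)
  prof <- normalize_cpm(counts_table(m2, cycle_totals = rep(1e6, 3L)))
  res <- delta_filter(prof, stringent = TRUE)
  expect_true(res[["good"]])    # 5000/50 = 100-fold
  expect_false(res[["near"]])   # 99.98-fold

  expect_error(delta_filter(prof, mode = "specified_pair", pair = 9L),
               "out of range")
})

test_that("raising the delta threshold never admits new sequences", {
  set.seed(3)
  for (i in 1:25) {
    prof <- normalize_cpm(random_table())
    prev <- rep(TRUE, nrow(prof$cpm))
    for (thr in c(0, 1, 10, 100, 1e4)) {
      cur <- delta_filter(prof, threshold = thr)
      expect_true(all(prev | !cur))   # cur subset of prev
      prev <- cur
    }
  }
})

test_that("per-cycle scaling leaves cpm, entropy and filters unchanged", {
  set.seed(4)
  tab <- random_table(nseq = 8L)
  scaled <- tab$counts
  scaled[, 2L] <- scaled[, 2L] * 7L
  tab2 <- counts_table(scaled)
  expect_equal(normalize_cpm(tab2)$cpm, normalize_cpm(tab)$cpm)
  expect_equal(cycle_entropy(tab2)$entropy_bits,
               cycle_entropy(tab)$entropy_bits)
  expect_equal(delta_filter(normalize_cpm(tab2)),
               delta_filter(normalize_cpm(tab)))
})

test_that("entropy and top-k share match closed forms", {
  one <- ct(matrix(c(9L, 9L), 1L, 2L))
  expect_equal(cycle_entropy(one)$entropy_bits, c(0, 0))

  unif <- ct(matrix(rep(5L, 16L), 8L, 2L))
  cp <- cycle_entropy(unif, top_k = 3L)
  expect_equal(cp$entropy_bits, c(3, 3))          # uniform over 8 clones
  expect_equal(cp$top_k_share, c(3 / 8, 3 / 8))
  expect_equal(cycle_entropy(unif, top_k = 100L)$top_k_share, c(1, 1))
})

test_that("the breakpoint lands on the last informative cycle", {
  # selection cycles 1..3; top-1 share 0.001 -> 0.40 -> 0.42 saturates at
  # the 2->3 gap, entropy crash lands on cycle 2
  m <- cbind(c(1L, rep(1L, 999L)),
             c(400L, rep(1L, 600L), rep(0L, 399L)),
             c(420L, rep(1L, 580L), rep(0L, 419L)))
  rownames(m) <- paste0("S", 1:1000)
  tab <- ct(m, cycles = 1:3)
  cp <- cycle_entropy(tab, top_k = 1L)
  expect_equal(cp$top_k_share, c(0.001, 0.40, 0.42), tolerance = 1e-6)
  bp <- find_breakpoint(cp, saturation_epsilon = 0.05)
  expect_equal(as.integer(bp), 2L)

  # strictly growing share with epsilon 0: falls back to the cycle
  # receiving the maximal entropy drop
  m2 <- cbind(c(100L, rep(10L, 90L)),
              c(500L, rep(5L, 90L)),
              c(800L, rep(2L, 90L)))
  rownames(m2) <- paste0("S", 1:91)
  tab2 <- ct(m2, cycles = 1:3)
  cp2 <- cycle_entropy(tab2, top_k = 1L)
  expect_true(all(diff(cp2$top_k_share) > 0))
  bp2 <- find_breakpoint(cp2, saturation_epsilon = 0)
  drops <- -diff(cp2$entropy_bits)
  expect_equal(as.integer(bp2), cp2$cycle[which.max(drops) + 1L])

  expect_error(find_breakpoint(cp[1L, ]), "2 cycles")
})
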
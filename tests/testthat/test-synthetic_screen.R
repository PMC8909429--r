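test_that("library construction honours the class mix by construction", {
  lib <- build_library(n_clones = 300L,
                       class_mix = c(binder = 0, neutral = 1, tup = 0,
                                     stop_codon = 0, frameshift = 0),
                       seed = 21L)
  casc <- run_cascade(lib$dna)
  expect_true(all(casc$valid_insert))          # all-neutral: all pass

  lib2 <- build_library(n_clones = 300L,
                        class_mix = c(binder = 0.1, neutral = 0.3, tup = 0.1,
                                      stop_codon = 0.3, frameshift = 0.2),
                        seed = 22L)
  expect_equal(unname(table(lib2$clazz)[c("binder", "neutral", "tup",
                                          "stop_codon", "frameshift")]),
               c(30L, 90L, 30L, 90L, 60L), ignore_attr = TRUE)
  aa <- translate_vh(lib2$dna[lib2$clazz == "stop_codon"])
  expect_true(all(grepl("*", aa, fixed = TRUE)))  # every stop clone stops
  casc2 <- run_cascade(lib2$dna)
  expect_equal(casc2$valid_insert,
               !(lib2$clazz %in% c("stop_codon", "frameshift")))
  expect_equal(sum(lib2$initial_freq), 1)
  expect_false(anyDuplicated(lib2$dna) > 0L)

  expect_error(build_library(100L, class_mix = c(binder = 0.5, neutral = 0.4,
                                                 tup = 0, stop_codon = 0,
                                                 frameshift = 0)),
               "sum to 1")
})

test_that("identical seeds reproduce libraries and screens exactly", {
  a <- build_library(n_clones = 200L, seed = 33L)
  b <- build_library(n_clones = 200L, seed = 33L)
  expect_identical(a, b)
  sa <- run_selection(a, n_cycles = 2L, depth = 5000L, seed = 34L)
  sb <- run_selection(b, n_cycles = 2L, depth = 5000L, seed = 34L)
  expect_identical(sa$table$counts, sb$table$counts)
  expect_identical(sa$parent, sb$parent)
})

test_that("expected frequencies conserve mass, enrich binders, lose entropy", {
  lib <- build_library(n_clones = 500L, seed = 41L)
  E <- expected_frequencies(lib, n_cycles = 4L, lambda = 1)
  expect_equal(unname(colSums(E)), rep(1, 5L), tolerance = 1e-12)

  # with equal growth, a binder's expected frequency never decreases
  libb <- lib
  libb$growth <- 1
  Eb <- expected_frequencies(libb, n_cycles = 4L, lambda = 1)
  bind <- which(libb$clazz == "binder")
  expect_true(all(diff(t(Eb[bind, , drop = FALSE])) >= 0))

  # clonal diversity of the expected distribution shrinks under selection
  ent <- apply(E, 2L, function(p) {
    p <- p[p > 0]; -sum(p * log2(p))
  })
  expect_true(all(diff(ent) <= 1e-9))
})

test_that("a neutral screen drifts only by sampling noise", {
  lib <- build_library(n_clones = 50L,
                       class_mix = c(binder = 0, neutral = 1, tup = 0,
                                     stop_codon = 0, frameshift = 0),
                       seed = 51L)
  pvals <- vapply(1:5, function(s) {
    scr <- run_selection(lib, n_cycles = 2L, depth = 20000L, lambda = 0,
                         error_rate = 0, seed = 60L + s)
    idx <- match(lib$dna, rownames(scr$table$counts))
    obs <- ifelse(is.na(idx), 0L, scr$table$counts[idx, "cycle2"])
    suppressWarnings(stats::chisq.test(obs, p = lib$initial_freq)$p.value)
  }, 0)
  # Fisher-combined evidence across seeds: no systematic drift at alpha .01
  fisher_p <- stats::pchisq(-2 * sum(log(pvals)), df = 2L * length(pvals),
                            lower.tail = FALSE)
  expect_gt(fisher_p, 0.01)
})

test_that("a growth-advantaged stop clone enriches yet is binned has_stop", {
  lib <- build_library(n_clones = 400L,
                       class_mix = c(binder = 0, neutral = 0.95, tup = 0,
                                     stop_codon = 0.05, frameshift = 0),
                       growth_advantage = 5, seed = 71L)
  scr <- run_selection(lib, n_cycles = 3L, depth = 3e4, lambda = 1,
                       seed = 72L)
  E <- scr$expected
  stop_mass <- colSums(E[lib$clazz == "stop_codon", , drop = FALSE])
  expect_true(all(diff(stop_mass) > 0))        # enriched every cycle
  rep <- run_funnel(scr, funnel_config())
  top_stop <- lib$dna[lib$clazz == "stop_codon"][
    which.max(E[lib$clazz == "stop_codon", 4L])]
  expect_equal(as.character(rep$sequence_bins[[top_stop]]), "has_stop")
  expect_false(any(rep$candidates$aa %in% translate_vh(top_stop)))
})

test_that("shared sticky clones recur across sibling screens", {
  mix <- c(binder = 0.01, neutral = 0.72, tup = 0.02, stop_codon = 0.15,
           frameshift = 0.10)
  la <- build_library(n_clones = 300L, class_mix = mix, seed = 81L)
  lb <- build_library(n_clones = 300L, class_mix = mix, seed = 82L)
  lb2 <- plant_shared_tups(la, lb, n = 3L)
  shared <- attr(lb2, "shared_tup_dna")
  expect_length(shared, 3L)
  expect_true(all(shared %in% la$dna))
  expect_true(all(shared %in% lb2$dna))
  expect_equal(sum(lb2$initial_freq), 1)       # recipient freqs untouched
})

test_that("written screens are byte-identical for identical seeds", {
  lib <- build_library(n_clones = 150L, seed = 91L)
  d1 <- file.path(tempdir(), "sim_a"); d2 <- file.path(tempdir(), "sim_b")
  write_screen(run_selection(lib, 2L, depth = 2000L, seed = 92L), d1)
  write_screen(run_selection(lib, 2L, depth = 2000L, seed = 92L), d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw",
                             file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw",
                             file.size(file.path(d2, f))), info = f)
  }
  expect_true(any(grepl("\\.fastq$", list.files(d1))))
})
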
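# VH scaffold used by the simulator: human VH3-23-like frameworks with a
# randomized HCDR3.  FR1 starts with the MAEVQ consensus, FR3 ends in the
# Y-Y-C HCDR3 anchor, FR4 is WGQGTTVTVS (W-G-x-G anchor, TVS terminus).
.SIM_FR1 <- "MAEVQLVESGGGLVQPGGSLRLSCAASGFTFSSYAMS"
.SIM_FR2_FR3 <- "WVRQAPGKGLEWVSAISGSGGSTYYADSVKGRFTISRDNSKNTLYLQMNSLRAEDTAVYYC"
.SIM_FR4 <- "WGQGTTVTVS"

# one fixed codon per amino acid (frameworks); CDR3 codons are drawn at
# random among synonymous codons
.CODON1 <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
             G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTG",
             M = "ATG", N = "AAT", P = "CCT", Q = "CAG", R = "CGT",
             S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")

.CODON_TABLE <- local({
  b <- c("T", "C", "A", "G")
  cods <- as.vector(outer(outer(b, b, paste0), b, paste0))
  aa <- as.character(Biostrings::translate(Biostrings::DNAStringSet(cods),
                                           no.init.codon = TRUE))
  split(cods, aa)
})

# CDR3 alphabet excludes C and W so the HCDR3 anchor motifs stay unambiguous
.CDR3_AA <- setdiff(names(.CODON1), c("C", "W"))

.aa_to_dna_fixed <- function(aa) {
  paste(.CODON1[strsplit(aa, "", fixed = TRUE)[[1L]]], collapse = "")
}

.random_cdr3_dna <- function(len) {
  aa <- sample(.CDR3_AA, len, replace = TRUE)
  paste(vapply(aa, function(a) sample(.CODON_TABLE[[a]], 1L), ""),
        collapse = "")
}

#' Build a synthetic naive phage-display library
#'
#' Generates a desk-scale stand-in for a naive scFv library: every clone is
#' built on a valid FR1..FR4 VH scaffold with a randomized HCDR3, then a
#' configurable fraction is corrupted to emulate the two false-positive
#' classes — clones bearing an in-frame stop codon, clones bearing a 1- or
#' 2-base frameshift indel (both acquire a propagation advantage during
#' amplification), and sticky target-unrelated clones that bind panning
#' components.  Initial clone frequencies follow a Zipf law (heavy-tailed,
#' exponent 1 by default) over a random permutation of clones.  Corrupt
#' clones are verified to fail the ORF cascade by construction (resampled
#' otherwise).
#'
#' @param n_clones Number of distinct clones (default 1e4, a desk-scale
#'   stand-in for the 1e11-1e13 diversity of a real naive library).
#' @param class_mix Named fractions over
#'   `binder`, `neutral`, `tup`, `stop_codon`, `frameshift`; must sum to 1.
#'   The default plants 10 binders per 1e4 clones and a realistic ~25%
#'   non-valid insert load.
#' @param cdr3_len Range of HCDR3 lengths (residues) sampled uniformly.
#' @param binder_affinity_meanlog,binder_affinity_sdlog Log-normal
#'   parameters of binder affinity; the default centres the per-cycle
#'   panning advantage of a good binder near 100-fold (two orders of
#'   magnitude per cycle).
#' @param tup_stickiness_meanlog,tup_stickiness_sdlog Log-normal parameters
#'   of TUP stickiness (affinity for panning components), centred near
#'   10-fold.
#' @param growth_advantage Amplification growth advantage of
#'   non-valid-insert clones (helper-phage pIII rescue), default 5.
#' @param zipf_exponent Exponent of the initial abundance law.
#' @param seed Integer seed; the library is fully determined by it.
#' @return A `sim_library` data frame with columns `id`, `dna`, `clazz`,
#'   `affinity`, `stickiness`, `growth`, `initial_freq`.
#' @export
build_library <- function(n_clones = 10000L,
                          class_mix = c(binder = 0.001, neutral = 0.744,
                                        tup = 0.005, stop_codon = 0.15,
                                        frameshift = 0.10),
                          cdr3_len = 8:16,
                          binder_affinity_meanlog = log(100),
                          binder_affinity_sdlog = 0.5,
                          tup_stickiness_meanlog = log(10),
                          tup_stickiness_sdlog = 0.5,
                          growth_advantage = 5,
                          zipf_exponent = 1,
                          seed = 1L) {
  classes <- c("binder", "neutral", "tup", "stop_codon", "frameshift")
  if (!setequal(names(class_mix), classes))
    stop("class_mix must name exactly: ", paste(classes, collapse = ", "))
  class_mix <- class_mix[classes]
  if (abs(sum(class_mix) - 1) > 1e-8) stop("class_mix must sum to 1")
  set.seed(seed)
  n_per <- floor(class_mix * n_clones)
  rem <- n_clones - sum(n_per)
  if (rem > 0) {  # distribute rounding remainder to the largest classes
    ord <- order(class_mix * n_clones - n_per, decreasing = TRUE)
    n_per[ord[seq_len(rem)]] <- n_per[ord[seq_len(rem)]] + 1L
  }
  clazz <- rep(classes, times = n_per)

  fr_dna1 <- .aa_to_dna_fixed(paste0(.SIM_FR1, .SIM_FR2_FR3))
  fr_dna4 <- .aa_to_dna_fixed(.SIM_FR4)
  cfg <- consensus_config()

  gen_one <- function(cl) {
    d <- paste0(fr_dna1, .random_cdr3_dna(sample(cdr3_len, 1L)), fr_dna4)
    switch(cl, stop_codon = .plant_stop(d), frameshift = .plant_frameshift(d),
           d)
  }
  dna <- vapply(clazz, gen_one, "")
  want_valid <- !(clazz %in% c("stop_codon", "frameshift"))
  # corrupt clones must fail the cascade and all clones must be unique by
  # construction; regenerate the rare offenders in batches
  repeat {
    valid <- run_cascade(dna, cfg)$valid_insert
    bad <- which(valid != want_valid | duplicated(dna))
    if (!length(bad)) break
    dna[bad] <- vapply(clazz[bad], gen_one, "")
  }

  affinity <- ifelse(clazz == "binder",
                     rlnorm(n_clones, binder_affinity_meanlog,
                            binder_affinity_sdlog), 0)
  stickiness <- ifelse(clazz == "tup",
                       rlnorm(n_clones, tup_stickiness_meanlog,
                              tup_stickiness_sdlog), 0)
  growth <- ifelse(clazz %in% c("stop_codon", "frameshift"),
                   growth_advantage, 1)
  ranks <- sample.int(n_clones)            # classes spread over abundance
  f0 <- (1 / ranks^zipf_exponent)
  f0 <- f0 / sum(f0)
  lib <- data.frame(id = seq_len(n_clones), dna = dna, clazz = clazz,
                    affinity = affinity, stickiness = stickiness,
                    growth = growth, initial_freq = f0,
                    stringsAsFactors = FALSE)
  attr(lib, "seed") <- seed
  class(lib) <- c("sim_library", "data.frame")
  lib
}

# place an in-frame stop at a random internal codon (past the FR1 consensus,
# upstream of FR4)
.plant_stop <- function(d) {
  ncod <- nchar(d) %/% 3L
  pos <- sample(6:(ncod - 11L), 1L)
  stop_codon <- sample(c("TAA", "TAG", "TGA"), 1L)
  paste0(substring(d, 1L, (pos - 1L) * 3L), stop_codon,
         substring(d, pos * 3L + 1L))
}

# 1- or 2-base insertion or deletion upstream of FR4, past the FR1 consensus
.plant_frameshift <- function(d) {
  n <- nchar(d)
  k <- sample(1:2, 1L)
  pos <- sample(16:(n - 31L), 1L)
  if (runif(1) < 0.5) {
    ins <- paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                 collapse = "")
    paste0(substring(d, 1L, pos), ins, substring(d, pos + 1L))
  } else {
    paste0(substring(d, 1L, pos), substring(d, pos + k + 1L))
  }
}

#' @export
print.sim_library <- function(x, ...) {
  cat("sim_library:", nrow(x), "clones\n")
  print(table(x$clazz))
  invisible(x)
}

#' Plant shared sticky clones across sibling libraries
#'
#' Target-unrelated clones stick to panning components, so the same clone
#' recurs in screens against unrelated targets.  This copies the `n`
#' stickiest TUP clones of `lib_from` over `n` TUP clones of `lib_to`
#' (sequence and stickiness; the recipient's initial frequency is kept), so
#' two simulated screens share cross-screen sticky clones.
#'
#' @param lib_from,lib_to `sim_library` objects.
#' @param n Number of shared clones.
#' @return `lib_to` with the shared clones planted; their DNA sequences are
#'   attached as attribute `shared_tup_dna`.
#' @export
plant_shared_tups <- function(lib_from, lib_to, n = 3L) {
  stopifnot(inherits(lib_from, "sim_library"), inherits(lib_to, "sim_library"))
  src <- which(lib_from$clazz == "tup")
  dst <- which(lib_to$clazz == "tup")
  if (length(src) < n || length(dst) < n)
    stop("not enough TUP clones to share")
  src <- src[order(-lib_from$stickiness[src])][seq_len(n)]
  dst <- dst[order(-lib_to$stickiness[dst])][seq_len(n)]
  lib_to$dna[dst] <- lib_from$dna[src]
  lib_to$stickiness[dst] <- lib_from$stickiness[src]
  attr(lib_to, "shared_tup_dna") <- lib_from$dna[src]
  lib_to
}

#' Expected clone frequencies across selection cycles
#'
#' Deterministic two-phase frequency update underlying the simulator.  Each
#' cycle has a panning phase, where a clone's frequency is reweighted by
#' `affinity * lambda + stickiness + baseline` (selection-related
#' enrichment), and an amplification phase reweighting by the growth
#' advantage (selection-unrelated enrichment of broken-insert clones);
#' frequencies are renormalized after each phase.
#'
#' @param library A [build_library()] result.
#' @param n_cycles Number of selection cycles.
#' @param lambda Selection strength; scalar or one value per cycle.
#' @param baseline Baseline panning survival of any phage (default 1).
#' @return Matrix of expected frequencies, clones by cycles 0..n_cycles.
#' @export
expected_frequencies <- function(library, n_cycles, lambda = 1,
                                 baseline = 1) {
  stopifnot(inherits(library, "sim_library"))
  lambda <- rep_len(lambda, n_cycles)
  E <- matrix(NA_real_, nrow(library), n_cycles + 1L,
              dimnames = list(NULL, paste0("cycle", 0:n_cycles)))
  E[, 1L] <- library$initial_freq
  for (c in seq_len(n_cycles)) {
    w_pan <- library$affinity * lambda[c] + library$stickiness + baseline
    f <- E[, c] * w_pan
    f <- f / sum(f)
    f <- f * library$growth
    E[, c + 1L] <- f / sum(f)
  }
  E
}

# apply per-base substitution errors to `n_err` copies of parent sequences;
# returns a character vector of mutated reads
.mutate_reads <- function(parent_dna, error_rate) {
  L <- nchar(parent_dna)
  n <- length(parent_dna)
  k <- rbinom(n, L, error_rate)
  k[k == 0L] <- 1L                     # reads selected for mutation carry >= 1
  out <- parent_dna
  bases <- c("A", "C", "G", "T")
  one <- which(k == 1L)                # vast majority: vectorized single hit
  if (length(one)) {
    pos <- floor(runif(length(one)) * L[one]) + 1L
    cur <- substring(out[one], pos, pos)
    idx <- match(cur, bases)
    newidx <- ((idx - 1L + sample.int(3L, length(one), replace = TRUE)) %% 4L) + 1L
    substr(out[one], pos, pos) <- bases[newidx]
  }
  for (i in which(k > 1L)) {
    ch <- strsplit(out[i], "", fixed = TRUE)[[1L]]
    pos <- sample.int(L[i], k[i])
    for (p in pos) ch[p] <- sample(setdiff(bases, ch[p]), 1L)
    out[i] <- paste(ch, collapse = "")
  }
  out
}

#' Simulate multi-cycle biopanning sequencing
#'
#' Runs the two-phase selection model of [expected_frequencies()] and draws
#' reads multinomially at the given depth for the naive library (cycle 0)
#' and each selection cycle, with per-base substitution sequencing errors.
#' Substitution-only errors keep frameshift ground-truth labels unambiguous.
#' Fully deterministic given the seed.
#'
#' @param library A [build_library()] result.
#' @param n_cycles Number of selection cycles (>= 2).
#' @param depth Reads drawn per cycle.
#' @param lambda Selection strength, scalar or per-cycle vector; set a
#'   trailing 0 to emulate selection pressure halted after a given cycle.
#' @param error_rate Per-base substitution error rate (default 0.001, the
#'   typical short-read platform rate).
#' @param baseline Baseline panning survival (default 1).
#' @param seed Integer seed for the sampling stage.
#' @return An object of class `sim_screen`: list with `table` (a
#'   [counts_table] of observed unique sequences by cycles 0..n_cycles),
#'   `parent` (integer vector mapping each observed sequence to the planted
#'   clone it derives from), `library`, `expected` (expected frequency
#'   matrix) and `config`.
#' @export
run_selection <- function(library, n_cycles = 3L, depth = 1e5,
                          lambda = 1, error_rate = 0.001, baseline = 1,
                          seed = 1L) {
  stopifnot(inherits(library, "sim_library"))
  if (n_cycles < 2L) stop("n_cycles must be >= 2")
  if (depth <= 0) stop("depth must be positive")
  E <- expected_frequencies(library, n_cycles, lambda, baseline)
  set.seed(seed)
  L <- nchar(library$dna)
  p_err_read <- 1 - (1 - error_rate)^L
  ncyc <- n_cycles + 1L
  seq_map <- new.env(hash = TRUE, parent = emptyenv())
  register <- function(s, parent) {
    e <- seq_map[[s]]
    if (is.null(e)) seq_map[[s]] <- parent
  }
  cyc_counts <- vector("list", ncyc)
  for (c in seq_len(ncyc)) {
    cc <- as.integer(rmultinom(1L, size = depth, prob = E[, c]))
    hit <- which(cc > 0L)
    n_err <- if (error_rate > 0)
      rbinom(length(hit), cc[hit], p_err_read[hit]) else integer(length(hit))
    exact <- cc[hit] - n_err
    tab_env <- new.env(hash = TRUE, parent = emptyenv())
    add <- function(s, n) {
      cur <- tab_env[[s]]
      tab_env[[s]] <- if (is.null(cur)) n else cur + n
    }
    for (j in seq_along(hit)) {
      if (exact[j] > 0L) {
        add(library$dna[hit[j]], exact[j])
        register(library$dna[hit[j]], hit[j])
      }
    }
    err_idx <- hit[n_err > 0L]
    if (length(err_idx)) {
      parents <- rep(err_idx, times = n_err[n_err > 0L])
      mutated <- .mutate_reads(library$dna[parents], error_rate)
      for (j in seq_along(mutated)) {
        add(mutated[j], 1L)
        register(mutated[j], parents[j])
      }
    }
    seqs <- sort(ls(tab_env))
    cyc_counts[[c]] <- setNames(
      vapply(seqs, function(s) tab_env[[s]], 0L), seqs)
  }
  all_seqs <- sort(unique(unlist(lapply(cyc_counts, names),
                                 use.names = FALSE)))
  m <- matrix(0L, length(all_seqs), ncyc,
              dimnames = list(all_seqs, paste0("cycle", 0:n_cycles)))
  for (c in seq_len(ncyc))
    m[match(names(cyc_counts[[c]]), all_seqs), c] <- cyc_counts[[c]]
  parent <- vapply(all_seqs, function(s) seq_map[[s]], 0L)
  table <- counts_table(m, cycle_totals = rep(depth, ncyc))
  out <- list(table = table, parent = parent, library = library,
              expected = E,
              config = list(n_cycles = n_cycles, depth = depth,
                            lambda = lambda, error_rate = error_rate,
                            baseline = baseline, seed = seed,
                            library_seed = attr(library, "seed")))
  class(out) <- "sim_screen"
  out
}

#' @export
print.sim_screen <- function(x, ...) {
  cat(sprintf("sim_screen: %d cycles at depth %g, %d observed sequences\n",
              x$config$n_cycles, x$config$depth, nrow(x$table$counts)))
  invisible(x)
}

#' Convenience wrapper: build a library and run a screen
#'
#' @param seed Integer seed controlling both library construction and read
#'   sampling.
#' @param n_clones,n_cycles,depth,lambda,error_rate See [build_library()]
#'   and [run_selection()].
#' @param ... Further arguments to [build_library()].
#' @return A `sim_screen`.
#' @export
simulate_screen <- function(seed = 1L, n_clones = 10000L, n_cycles = 3L,
                            depth = 1e5, lambda = 1, error_rate = 0.001,
                            ...) {
  lib <- build_library(n_clones = n_clones, seed = seed, ...)
  run_selection(lib, n_cycles = n_cycles, depth = depth, lambda = lambda,
                error_rate = error_rate, seed = seed + 1L)
}

#' Write simulated reads and ground truth to disk
#'
#' Emits one FASTQ per cycle (reads expanded from the counts in sequence
#' order, constant quality), a truth TSV with per-clone class labels and
#' parameters, and a plain-text run config; all outputs are byte-identical
#' across runs with the same seed and config.
#'
#' @param screen A `sim_screen`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_screen <- function(screen, dir) {
  stopifnot(inherits(screen, "sim_screen"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- screen$table$counts
  files <- character(0)
  for (c in seq_len(ncol(m))) {
    reads <- rep(rownames(m)[m[, c] > 0L], times = m[m[, c] > 0L, c])
    rs <- read_set(reads, cycle_index = c - 1L)
    f <- file.path(dir, paste0(colnames(m)[c], ".fastq"))
    write_reads(rs, f, format = "fastq")
    files <- c(files, f)
  }
  truth_f <- file.path(dir, "truth.tsv")
  con <- file(truth_f, open = "wb")
  tr <- screen$library
  writeLines(paste(names(tr), collapse = "\t"), con)
  writeLines(do.call(paste, c(lapply(tr, .fmt_col), sep = "\t")), con)
  close(con)
  cfg_f <- file.path(dir, "run_config.txt")
  con <- file(cfg_f, open = "wb")
  cfg <- screen$config
  writeLines(paste0(names(cfg), "\t",
                    vapply(cfg, function(v) paste(format(v), collapse = ","),
                           "")), con)
  close(con)
  invisible(c(files, truth_f, cfg_f))
}

#' Score a funnel report against simulator ground truth
#'
#' Per-class confusion counts for the ORF cascade at the planted-clone
#' level (each observed unique sequence is assigned to the clone it derives
#' from; a clone's predicted validity is the count-weighted majority over
#' its derived sequences), binder recovery in the final top-k candidate
#' list, and TUP flagging counts when a database scan was run.
#'
#' @param report A [run_funnel()] result.
#' @param screen The `sim_screen` the report was computed from.
#' @param top_k Candidate list depth for binder recovery (default 20).
#' @return List with `cascade` (per-class valid/invalid clone counts,
#'   sensitivity and specificity), `binder_recovery`, `binders_in_top_k`,
#'   `n_binders`, and `tup` flagging counts.
#' @export
score_recovery <- function(report, screen, top_k = 20L) {
  stopifnot(inherits(report, "funnel_report"), inherits(screen, "sim_screen"))
  if (!identical(report$run_id, screen$config$seed))
    stop("report and truth come from different runs")
  lib <- screen$library
  casc <- run_cascade(rownames(screen$table$counts),
                      report$config$consensus)
  mass <- rowSums(screen$table$counts)
  pred_valid_mass <- tapply(mass * casc$valid_insert, screen$parent, sum)
  tot_mass <- tapply(mass, screen$parent, sum)
  ids <- as.integer(names(tot_mass))
  clone_pred_valid <- (pred_valid_mass / tot_mass) > 0.5
  truth_valid <- !(lib$clazz[ids] %in% c("stop_codon", "frameshift"))
  conf <- table(clazz = lib$clazz[ids], pred_valid = clone_pred_valid)
  sens <- sum(!clone_pred_valid & !truth_valid) / max(sum(!truth_valid), 1L)
  spec <- sum(clone_pred_valid & truth_valid) / max(sum(truth_valid), 1L)

  binder_aa <- translate_vh(lib$dna[lib$clazz == "binder"],
                            report$config$consensus$frame_offset)
  cand <- report$candidates
  top <- head(cand$aa, top_k)
  hits <- sum(binder_aa %in% top)
  tup_res <- NULL
  if (!is.null(report$groups$tup_match)) {
    tup_aa <- translate_vh(lib$dna[lib$clazz == "tup"],
                           report$config$consensus$frame_offset)
    flagged <- report$groups$aa[report$groups$tup_match]
    tup_res <- list(planted_tup_flagged = sum(tup_aa %in% flagged),
                    n_planted_tup = length(tup_aa),
                    binders_flagged = sum(binder_aa %in% flagged))
  }
  list(cascade = list(confusion = conf, sensitivity = sens,
                      specificity = spec),
       binders_in_top_k = hits,
       n_binders = length(binder_aa),
       binder_recovery = hits / max(length(binder_aa), 1L),
       tup = tup_res)
}
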
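---
title: "The funnel model: filtering false positives from NGS-guided phage-display screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The funnel model: filtering false positives from NGS-guided phage-display screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagefunnel)
```

## The model

Biopanning is iterated affinity selection: a phage population displaying an
scFv repertoire is bound to a target, washed, eluted and re-amplified in
*E. coli*, and the surviving sub-library is sequenced after each cycle.
Under ideal selection a clone's relative abundance trajectory across cycles
reflects its affinity, so depth-normalized enrichment (counts per million,
CPM) is a proxy for binding. Two mechanisms corrupt the proxy:

* clones with **non-valid inserts** (stop codons, frameshift indels) do not
  display scFv at all but acquire a *growth* advantage during the
  amplification phase, because helper-phage pIII complements their broken
  fusion protein. Their enrichment is selection-unrelated.
* **target-unrelated clones** display a perfectly valid scFv that binds
  some panning component other than the target. Their enrichment is
  selection-related but not target-specific, and the same clones recur in
  screens against unrelated targets.

The funnel encodes one removal strategy per mechanism — in-silico
translation plus framework-consensus checks for the first, a persistent
cross-screen database for the second — wrapped between an enrichment filter
(step 1) and protein-level aggregation and ranking (step 5 and the
breakpoint diagnostics). The step order (delta filter, then ORF cascade,
then collapse, then database scan) is fixed: reordering changes every
intermediate count, so the reported per-step attrition would no longer be
comparable across screens.

## Tunable parameters

* `delta_threshold` (CPM, default 1): minimum absolute CPM increase between
  at least one pair of consecutive cycles. The worked default corresponds
  to one read per million — anything below is indistinguishable from depth
  noise at typical MiSeq depths.
* `stringent`/`fold_threshold` (default 100×): the alternative preset for
  well-behaved screens, requiring a two-orders-of-magnitude CPM increase
  between consecutive cycles — the enrichment a good binder typically
  shows. Fold changes use a pseudo-CPM floor of 1 in the denominator so
  clones absent from the earlier cycle get a finite, conservative fold.
  We interpret the stringent cutoff as a fold change rather than an
  absolute log-scale delta: an absolute cutoff of 100 CPM would conflate
  depth with enrichment, while "two orders of magnitude" is explicitly a
  ratio.
* `fr1_prefixes` (default `MAEVQ`, `MAQVQ`) and `fr4_suffix` (default
  `TVS`): the framework consensus anchors of the reference library, checked
  by exact match. Mismatch tolerance would re-admit exactly the
  error-bearing reads the cascade exists to remove; libraries with other
  frameworks override the motifs instead. `X` residues (N-containing
  codons) count as mismatches for the same reason.
* `frame_offset` (default 0): the translation frame is fixed by the vector
  design. Scanning for the best open reading frame would silently rescue
  frameshifted clones — the very class the cascade must catch.
* `fr4_search_window` (default 10 residues): reads may extend past FR4 into
  linker or adapter remnants, so the FR4 suffix is accepted anywhere within
  the terminal window (the translation is truncated at the suffix first).
  Ten residues covers primer remnants while keeping a frameshifted FR4
  essentially impossible to match by chance.
* `top_k` (default 100): the number of top-ranking clones used for the
  composition snapshot and the saturation share, matching the usual
  cross-screen reporting convention.
* `saturation_epsilon` (default 0.05): a cycle that grows the top-k share
  by less than five percentage points adds essentially no ranking
  information at desk-scale depths.
* `min_screens_for_tup` (default 2): a VH enriched against two distinct
  targets is the weakest evidence consistent with target-unrelated binding;
  entries seen once are stored with status `observed` and only upgraded to
  `predicted` when the second target accrues (wet-lab confirmation sets
  `validated`). The scan itself discards on membership from *any*
  different-target screen, regardless of status — the conservative choice
  for candidate confidence, and monotone in database growth.

## Breakpoint detection

After enough cycles all surviving binders plateau and relative abundances
flatten, so ranking should happen at the earliest cycle where enrichment
information saturates. `find_breakpoint()` formalizes this: it scans
consecutive cycle pairs and reports the cycle *preceding* the first top-k
share gain below `saturation_epsilon`, provided clonal entropy was falling
into that cycle. The entropy condition exists because a flat share gap
alone also occurs *before* selection bites (naive library → cycle 1); we
deliberately require only a falling entropy trend rather than the single
largest drop, because in strongly selected screens the largest entropy
crash can precede the breakpoint by a cycle without invalidating the
saturation evidence. When no gap saturates, the cycle receiving the maximal
entropy drop is returned, and both component series are attached as
attributes so users can override the call. Entropy is reported in bits
(base 2); the base cancels out of all comparisons.

## What the simulator emulates — and what it does not

`build_library()`/`run_selection()` generate a desk-scale naive library
(default 10⁴ clones standing in for the 10¹¹–10¹³ diversity of a real one)
on a VH3-23-like scaffold with randomized HCDR3s, with heavy-tailed
(Zipf, exponent 1) initial abundances, and evolve it through a two-phase
update per cycle:

* panning: weight `affinity × lambda + stickiness + baseline`, capturing
  target binding and component stickiness (selection-related);
* amplification: weight `growth`, capturing the helper-phage propagation
  advantage of broken-insert clones (selection-unrelated).

Frequencies renormalize after each phase; reads are drawn multinomially at
the configured depth with per-base substitution errors (default 0.1%, the
short-read platform magnitude). Defaults place a binder's per-cycle panning
advantage near 100× (log-normal, sd 0.5 on the log scale) — the
two-orders-of-magnitude enrichment observed for good binders — a TUP's
stickiness near 10× and the broken-insert growth advantage at 5×; the last
two are not documented magnitudes anywhere we know of and were chosen once
as field-realistic (sticky binding is substantially weaker than specific
binding; a broken insert roughly halves the amplification penalty of
display). The default class mix plants 10 binders and 50 sticky clones per
10⁴ and a ~25% non-valid load, in the range reported for real campaigns.

Deliberate non-features, and hence limits on what passing tests show about
real data: no indel sequencing errors by default (so frameshift
ground-truth labels stay unambiguous), no PCR amplification bias or
chimeras, no infection-dynamics kinetics, no clone-specific codon-usage
effects on display, and HCDR3s drawn from an 18-letter alphabet (no C/W)
so the CDR3 anchors used for extraction are unambiguous by construction.
Real repertoires violate several of these; the simulator validates the
pipeline's logic, not platform-specific artefact handling.

## Numerical and degenerate-input choices

* Exact-match DNA counting, no error-correction clustering; the optional
  `min_count` prune (default 1, i.e. off) removes co-sequencing errors when
  coverage allows. Cycle totals are recorded *before* pruning and
  N-exclusion so CPM always reflects true depth, and the per-cycle mass
  removed by each mechanism is kept for conservation checks.
* Reads containing N are excluded from counting (and tallied) rather than
  disambiguated — conservative and reproducible.
* Paired-end merging takes the longest suffix/prefix overlap within the
  mismatch budget; overlap disagreements resolve to the higher-quality
  base, or to read 1 when no qualities exist (FASTA). Unmergeable pairs
  are dropped and counted, never guessed.
* Ranking ties resolve by multiplicity (more synonymous DNA variants =
  more independent evidence of binding), then lexicographically by VH, so
  every ordering is total and byte-reproducible.
* Empty outcomes are values, not errors: a screen where no clone survives
  the funnel yields an empty candidate table; a VH without both HCDR3
  anchors yields a missing HCDR3 (flagged, usable only in full-VH scan
  mode). Genuine contract violations (zero-depth cycles, duplicate
  sequences, a TUP database containing the current screen — circular
  evidence) raise errors before any compute.
* The HCDR3 convention (residues strictly between the last cysteine
  preceded by a tyrosine within three residues, and the tryptophan of the
  first subsequent `WGxG`; length 2–40) is a heuristic, not IMGT/Kabat
  numbering; it is isolated in `extract_hcdr3()` and overridable with
  explicit coordinates.
* All TSV writers emit LF line endings in binary mode with fixed
  full-precision number formatting, and all row orders are deterministic,
  so identical inputs and seeds give byte-identical outputs.

## Problem sizes used by the test suite

The end-to-end checks run at desk scale, chosen so the full suite completes
in minutes on one core: the binder-recovery experiment at the simulator
defaults (10⁴ clones, 3 cycles, 10⁵ reads/cycle), cascade-recovery and
TUP-removal experiments at 2 × 10³ clones and 3–5 × 10⁴ reads/cycle, and
the breakpoint-recovery experiment over 20 seeds at 10³ clones and
2 × 10⁴ reads/cycle. The oracle-equivalence properties (delta filter,
synonymous collapse) run on 10³ random micro-tables against brute-force
reimplementations.

## Known limitations

* Exact-match counting treats every sequencing-error variant as its own
  clone; the funnel tolerates this (error singletons rarely pass the delta
  filter, and the cascade catches broken variants), but clone-level
  statistics from very deep runs should use `min_count` ≥ 2.
* The TUP database matches by membership only; rank and CPM of the stored
  entries are recorded but not used as evidence weight.
* No replicate model: the delta filter is a deterministic threshold, not a
  significance test, because biopanning screens rarely provide replicates.
* Full-length scFv (VH+VL) reads are accepted as input but treated as
  opaque sequences; no consensus building or VH/VL pairing is attempted.
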
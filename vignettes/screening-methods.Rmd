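---
title: "Multi-target screen triage and inhibition analysis: methods"
author: "statscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-target screen triage and inhibition analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(statscreen)
```

## Scope

`statscreen` implements the statistics used to triage multi-target
virtual-screening output for STAT SH2-domain inhibitors, together with the
downstream genome-wide analysis that characterizes such inhibitors: a
microarray-style expression pipeline with a fold-change-ratio inhibition
criterion, promoter scanning for ISRE / GAS / NF-κB motifs, and small
closed-form calculators for qPCR, ChIP and wound-healing readouts. Docking
engines, array scanners and genome sequence extraction are upstream of this
package: it consumes their tabular output (pose tables, ΔG° tables,
expression matrices, promoter FASTA) and ships seeded generators that
emulate those inputs so every stage is testable offline.

## The triage cascade

A screening run produces, per compound and per target, a ranked set of
docked poses, each with a binding score (BS, unitless, higher = stronger
predicted affinity), a crash penalty (≤ 0, more negative = more clashing)
and a polar score (≥ 0). The cascade in `run_triage()`:

1. **Best-pose selection.** Per compound × target the pose with maximal BS
   is kept. Ties (rare with continuous scores) go to the larger crash value
   — less predicted clashing — then to the lower pose rank, so the result
   is deterministic.
2. **BS ranking.** Compounds are ordered by the reference target's best BS
   and the top *k* retained; ties are ordered by compound id.
3. **Similarity / MW filter.** A compound passes when its maximal
   similarity over the reference compounds is ≥ `min_sim` (default 0.5)
   and, when configured, its molecular weight is ≥ `min_mw` (default
   300 g/mol, used to prefer structures that can span more of the SH2
   surface). Similarity and RMSD are consumed as inputs; the package does
   not compute chemical similarity.
4. **CBAV filter.** The comparative binding affinity value against another
   target is the difference of best-pose binding scores, reference minus
   other. The published description defers the formula to an external
   protocol; we implement the score difference because it reproduces the
   decision semantics the tables rely on — CBAV ≥ 0 exactly when the
   reference binds at least as well — and is antisymmetric, which the
   tabulated values imply. Whether an aggregate over poses should be used
   instead of the best pose is not specified anywhere; the best pose is the
   natural partner of the best-pose BS filter, so that is what we use. A
   compound must reach the threshold (default 0) against *every*
   non-reference target.
5. **Pose-diversity (LBPV) validation.** The ligand binding pose variation
   for a pocket class is the fraction of the compound's top-ranked poses
   (20 in a full run) assigned to that class. Values in [0.8, 1.0] indicate
   low conformer diversity — the compound keeps finding the same pocket —
   and [0, 0.2] poor specificity. The final stage keeps compounds with
   LBPV of the configured class (default BOTH, i.e. poses occupying the
   pTyr pocket pY+0 and the hydrophobic side-pocket pY-X simultaneously)
   at or above `lbpv_threshold` (default 0.8).

All thresholds are inclusive (≥), matching the convention used throughout
the source tables. Every filter is idempotent, and each stage logs its
survivor/exclusion lists in the report so a run can be audited.

Pocket classes come either from precomputed 0/1 flags in the pose table
(the canonical dialect — LBPV is defined on pocket assignments, not raw
geometry, so any engine that can emit assignments is usable) or from heavy
atom coordinates with an any-atom-within-radius rule (default radius 5 Å,
configurable). The distance rule is the minimal reproducible proxy for the
graphical pocket-occupancy validation done interactively in molecular
viewers. The four exclusive classes (pY+0 only, pY-X only, both, neither)
satisfy an inclusion–exclusion identity with the two inclusive any-pocket
classes, which the test suite asserts to 1e-12.

With fewer than 20 poses LBPV uses the actual pose count as denominator and
warns; published runs always have 10 or 20. Reported single-pocket and
both-pocket LBPV entries need not sum to one — the remaining poses may sit
in the neither class — so the package reports all four classes and never
forces totals.

**Mutant impairment.** For wild-type/mutant pairs of stability records,
ΔΔG° = ΔG°(mutant) − ΔG°(wild type); since more negative ΔG° means a more
stable complex, ΔΔG° > 0 flags the mutation as impairing binding. Strictly
positive was chosen (not ≥) so an exactly unchanged stability is not called
impaired.

## Expression pipeline

The processing order follows standard bead-array practice: floor
non-positive signals at 1 → log2 → per-sample background subtraction →
quantile normalization → per-gene testing.

* **Flooring.** Scanner background correction can push dim probes negative;
  values ≤ 0 become 1 (log2 = 0) so the log transform is defined.
* **Background subtraction.** No control probes are assumed; the default
  subtracts each sample's 5th-percentile log2 signal and floors at zero, a
  control-probe-free proxy. `method = "none"` disables it. The floor-at-zero
  censors dim genes: a gene whose control and treated signals both sit below
  the background offset shows an attenuated fold change. This is visible in
  the noiseless-recovery test, which therefore isolates the noise model by
  disabling background subtraction.
* **Quantile normalization** (delegated to `limma::normalizeQuantiles`,
  ties averaged) forces all samples onto one empirical distribution via
  rank means. An independent hand-computed rank-mean oracle checks it in
  the tests. Note a side effect relevant to simulations: because induced
  genes shift the upper tail of treated samples, normalization mildly
  attenuates planted fold changes (an 8-fold planted effect typically reads
  as ~6-fold); thresholds are set with ample headroom relative to this.
* **Testing.** Per gene, the linear fold change is 2^(mean log2
  difference) and the p-value comes from a two-sample t test. The original
  description names no test; Welch's t is the default as the simplest
  defensible reading of "statistical testing" on two biological repeats.
  With n = 2 per arm, however, the Welch degrees of freedom can collapse
  toward 1 when sample variances are unequal, making the test erratically
  conservative — genuine 8-fold genes can land at p ≈ 0.06. The
  `var = "pooled"` switch (classical equal-variance t, df = 2) is provided
  for exactly this situation and is what the recovery experiments use; with
  a common replicate noise model pooling is correct by construction.
* **Induction filter.** fc ≥ 2 and p ≤ 0.05, both inclusive. The p-value is
  treated as a differential-expression p, not a detection p — the
  description is ambiguous, but only a differential test uses the two
  repeats it insists on.
* **Inhibition criterion.** For a gene already passing the induction
  filter, an inhibitor counts when FC(stim) / FC(stim + inhibitor) ≥ 4.
  Restricting to induced genes follows the stated intent of selecting
  stimulation-responsive genes that are commonly inhibited.
* **Intersection.** Per-inhibitor gene lists are compared as Venn regions,
  with gene identity the (gene id, gene name) pair; an id mapped to two
  names across lists is an integrity error. All 2^k − 1 region counts are
  reported densely and sum to the union size.

## Promoter scanning

The matrix similarity score is the MATCH-style min–max normalized PWM
score: per-position log2 weights
`w(b, i) = log2(((n_bi + q) / (N_i + 4q)) / 0.25)` with pseudocount
`q = 0.01 · N_i` (configurable), summed over the window and mapped through
`(S − S_min) / (S_max − S_min)` so the consensus scores 1 and the
per-position worst window 0. This is the standard construction behind
"matrix similarity score ∈ [0, 1]" thresholds, and it honors the class
thresholds of 0.85 (ISRE, GAS) and 0.90 (NF-κB) semantically. Ambiguous
bases score as the column minimum, i.e. maximally conservatively.

Scanning slides over both strands (the scanning engine behind the original
gene lists does not document its strand handling; double-strand is the
conservative choice), reports the best hit with leftmost-then-plus-strand
tie-breaking, and works in TSS-relative coordinates: the expected input is
the [−950, +50) promoter window, position 0 = TSS. The −950..+50 window is
used (the alternative −950..+100 appears once in a results summary; the
methods-section window was adopted and the window is configurable via
`window_start` and the sequence itself).

A site class (ISRE, GAS, NF-κB) is called present when *any* of its
matrices reaches the class threshold — classes merge their matrices' gene
lists. The three presence flags map to eight combination categories;
category percentages are reported over two denominators, all genes and
genes with at least one site, because published category percentages are
ambiguous about their base (counts implying a with-site base appear
alongside a larger list).

The shipped PFMs are **synthetic** consensus-built stand-ins
(`*_synthetic.pfm`): curated matrix databases cannot be redistributed here,
so each class carries a sharp matrix (per-column consensus frequency 0.97)
around a canonical motif — AGTTTCACTTTC (ISRE-like), TTCCGGGAA
(GAS-like TTCnnnGAA), GGGACTTTCC (κB). Sharp columns emulate the high
information content of curated immune-response matrices and give planted
instances a per-instance detection rate of 0.985–0.998 at the class
thresholds. Real matrices can be dropped in as JASPAR-format files via
`site_class_config(pfm_dir = ...)`.

## Assay calculators

* `ddct_fold_change()`: comparative-Ct with an exposed amplification
  efficiency (default 2; the published transform cites an external protocol
  without an efficiency correction, so perfect doubling is assumed).
* `percent_input()`: the standard log2 dilution correction — the input Ct
  is adjusted by −log2(input fraction) before the 2^ΔCt ratio.
* `wound_closure()`: 100 · (1 − mean gap width at t / mean at t0);
  permutation- and unit-invariant, negative when the gap widens.

## Synthetic data: what it emulates, and what it does not

The generators define the conditions under which the pipeline is validated:

* `simulate_pose_table()` — per compound × target, 20 poses with Gaussian
  BS (engine scores in these screens span roughly 4–10, so default mean 7,
  sd 0.5) ranked descending, and pocket classes drawn from a multinomial.
  It emulates score/occupancy structure only — no geometry or energies.
* `simulate_screen_library()` — plants winners that pass every cascade
  stage with wide margins (reference BS mean 9.5 vs 8 for decoys,
  both-pocket probability 0.98, similarity 0.6–0.9, MW 305–420) and gives
  every decoy at least one planted failure mode among similarity, MW, CBAV
  and pose diversity. Margins are wide deliberately: recovery should test
  the cascade's bookkeeping, not the overlap of noise distributions.
* `simulate_expression()` — log-normal background (log2 signals
  N(8, 2), the dynamic range of a bead array), two replicates per condition
  as in the underlying design, planted log2 induction of 3 (8-fold, floored
  at 2-fold), independent 35% inhibitor response per compound at a planted
  log2 drop of 4 (ratio 16), replicate noise sd 0.25 log2 units, and a 1%
  per-cell chance of a negative raw signal to exercise flooring. It is not
  a bead-level error model: no probe effects, no intensity-dependent
  variance, no probe-to-gene collapsing.
* `simulate_promoters()` — i.i.d. background at configurable GC (an
  order-3 Markov background trained on a supplied sequence is available
  for false-positive measurements), with motif instances sampled from the
  PFM columns at recorded offsets and strands. Class planting defaults
  (ISRE 0.5, GAS 0.5, NF-κB 0.4) populate all eight categories.

Passing recovery tests therefore show that the statistics recover planted
structure under these idealized conditions; they do not show robustness to
array batch effects, probe-level artifacts, real promoter composition or
docking-engine idiosyncrasies.

## Numerical and design notes

* Problem sizes in the tests and the acceptance experiments — 500
  compounds × 20 poses for occupancy recovery, 20 runs × 500 genes for
  expression recovery, 200 promoters for motif recovery — were chosen so
  the standard errors of the recovered quantities sit an order of magnitude
  below the asserted margins.
* Sub-seeds for multi-run experiments are derived by small integer offsets
  from the run seed; all generators are byte-deterministic under a fixed
  seed.
* The degenerate all-uniform PFM is rejected at construction (its min and
  max scores coincide, so the normalized score is undefined).
* Zero-variance genes in the replicate test get p = 1 when the means agree
  and p = 0 otherwise, the continuous limit of the t statistic.
* `run_triage()` completes with empty downstream stages (and a logged
  notice) when a stage eliminates every candidate, so reports are always
  structurally complete.

## Known limitations

* CBAV as a best-pose score difference is a reconstruction of an
  incompletely published statistic; ordering semantics are reproduced, the
  exact published magnitudes for new data may not be.
* With two replicates per arm the t test — either flavor — has little
  power; the pipeline is a screening filter, not an inference engine.
* The genome-wide published counts (731 induced, 259/244/292 inhibited,
  159 common) depend on the deposited arrays and exact vendor
  preprocessing and are out of desk-scale reach by design; the package
  validates the rules, not those counts.
* Promoter-category percentages on real gene lists require genomic
  promoter extraction, which is upstream of this package.
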
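---
title: "From peptide-library spot intensities to kinase motifs, substrate predictions and rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From peptide-library spot intensities to kinase motifs, substrate predictions and rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oplsmotif)
```

## The experiment this package models

In an oriented peptide library screen (OPLS) a purified kinase is assayed
against pools of degenerate 10-mer peptides. Every pool carries an
equimolar Ser/Thr mix at the central phospho-acceptor (or Tyr in the
tyrosine library) and fixes exactly one residue at one of the nine flank
positions −5..−1, +1..+4. With 22 fixed-residue choices per position (the
20 amino acids plus phospho-Thr and phospho-Tyr) the design is a 9 × 22
grid of 198 pools; three further pools are fully degenerate except for a
fixed S, T or Y acceptor and report phospho-acceptor preference. Spot
intensity after incubation with radiolabeled ATP is proportional to how
well the kinase tolerates the fixed residue at that position.

`opls_library_design()` enumerates this design; `spot_grid()` holds one
replicate blot's raw intensities.

## Normalization pipeline

The processing stages are applied in a fixed order, each producing a
`MotifMatrix` tagged with its stage:

1. **Per-position normalization** (`normalize_spot_grid()`): each spot is
   divided by the mean intensity of the 22 residues at its position, so
   each position row has mean exactly 1. Because the divisor is
   proportional to any global blot scale, the transform is exactly
   invariant to exposure differences — this invariance is asserted in the
   test suite.
2. **Replicate averaging** (`average_replicates()`): unweighted
   element-wise mean of the normalized replicates. The screen design calls
   for n ≥ 2; a single replicate is accepted with a warning.
3. **Capping** (`cap_acceptor_like_residues()`): pools whose fixed flank
   residue is itself an acceptor (S/T in the ST library, Y in the Y
   library) contain a second phosphorylatable site, so values above 1 are
   truncated to 1. The order matters and is deliberate — averaging
   precedes capping. A cell with replicate values {1.4, 0.8} averages to
   1.1 and caps to 1.0; capping each replicate first would yield 0.9. A
   per-cell exception list keeps above-one values judged to be genuine
   (the motivating case is a +1 Tyr in a tyrosine-library screen of a
   kinase with strong aromatic +1 preference).
4. **Log2 transform** (`log_transform()`): applied to the capped values
   with a positive floor.

Downstream consumers split by stage on purpose: clustering and PSSM
scoring use the **linear capped** values; heatmaps and sequence-logo
heights use the **log2** values.

### Numerical choices and degenerate inputs

* **Log2 floor** (default 2⁻⁶): real blots contain blank spots, and
  log2(0) is undefined; flooring maps a blank to −6, deep in the
  "strongly disfavored" regime without being infinite. The floor is
  recorded in the matrix metadata and the same constant keeps scoring
  matrices strictly positive.
* **Missing spots**: `NA` cells are allowed; position means are computed
  over present cells and a completeness count is attached. An all-zero
  position is a hard error naming the position — there is no defensible
  normalization for it.
* **Acceptor pools**: normalized by the mean of the pools present
  (mirroring the flank normalization) and also reported as fractions
  summing to 1; at least two pools are required, and all-zero pools are a
  degenerate-input error.

## Motif comparison

`motif_vector()` flattens a capped matrix deterministically (positions
ascending, residues in fixed alphabet order), optionally appending the
three acceptor-pool values — toggling that flag is how acceptor-blind
clustering is done, and the toggle is covered by a test that builds two
motifs identical everywhere except the acceptor column.

`similarity_matrix()` computes pairwise Pearson correlations
(pairwise-complete over missing cells, with a minimum-overlap guard of
150 of 198 cells by default — below that a correlation over the shared
cells stops being comparable across pairs). `cluster_kinases()` builds an
average-linkage (UPGMA) tree on distances d = 1 − r. Ids are sorted
lexicographically before clustering so merge tie-breaking is
deterministic, which golden tests require. The exported Newick tree is
ultrametric with node depths equal to half the merge height, the usual
UPGMA convention in which leaf-to-leaf path length equals the cophenetic
distance.

The pT/pY fixed-residue columns are part of the 198-cell grid and are
included in clustering by default; they carry real preference signal
(some kinases select phospho-residues at specific flank positions) and
excluding them is a flag away via the vector construction.

`sequence_identity_matrix()` computes percent identity over alignment
columns where neither sequence is gapped; alignments are inputs (any
aligner's FASTA output), not something this package recomputes.

Logo heights are the log2 values themselves: 0 neutral, positive favored,
negative disfavored. This reproduces the favored/disfavored semantics of
published screen logos without reimplementing information-theoretic logo
weighting (a deliberate presentation-level simplification; exported
matrices can be fed to any logo tool).

### Kinase-domain anchors

`anchor_offset_residue()` extracts residues at fixed offsets from the
HRD, DFG and APE motifs. The offset convention is anchored at the motif
ends: negative offsets count from the first anchor residue (APE−4 is 4
residues N-terminal of the A; APE−5 is the residue immediately before
that), positive offsets from the last (HRD+2 is 2 residues C-terminal of
the catalytic aspartate, DFG+1 directly follows the G). This matches how
those positions are used in the kinase-specificity literature, where
APE−5 and APE−4 are adjacent P+1-loop residues. Repeated anchor hits
require an explicit search window; absence, ambiguity and out-of-range
offsets raise distinct error classes.

## Substrate scoring

`build_scoring_matrix()` takes the capped linear values over the 20
standard amino acids as PSSM entries (missing cells become the neutral
value 1; everything is floored at 2⁻⁶ for positivity). The pT/pY columns
move to a modified-residue side table consulted only when a window marks
a residue as already phosphorylated (lowercase `t`/`y`): the degenerate
positions of the library cannot distinguish an unmodified residue the
mixture lacks, so pretending otherwise would invent information.

The score of a 9-residue window is the mean per-position log2 deviation
from the column optimum. Its properties, all under test:

* 0 exactly when every scored residue is column-optimal; > 0 otherwise;
* invariant to per-column positive rescaling (only within-column ratios
  matter), hence independent of the normalization scale;
* `_` padding at protein termini is skipped and the mean renormalized,
  keeping truncated windows comparable to full ones.

The published scoring tool this emulates does not print its formula; any
strictly monotone transform of a per-window score yields identical
percentile selections, which is why downstream selection is
percentile-based (`percentile_select()`, top 10% or 25%). Selection takes
the ⌈f·n⌉ lowest scores with inclusive boundary ties — ties at the cutoff
are all kept, so the set can slightly exceed the nominal count but never
depends on input order. Acceptor gating is a hard filter
(`filter_sites()`), not a score penalty: a Tyr site is simply not a
candidate for a Ser/Thr kinase.

`overlap_analysis()` partitions the union of up to six kinases' target
sets into exact membership-pattern counts (the regions of a Venn
diagram) and reports the fraction of a reference kinase's targets shared
with any other set.

## Kinetics

`fit_rate()` is ordinary least squares of CPM on time — the initial-rate
regime of a peptide kinase assay, where the time course is linear.
`compare_rates()` treats the per-replicate fitted slope as the unit of
replication (matching how rate panels report mean ± SEM over n = 3
assays), comparing two groups by Student's t-test (unpaired by default,
paired by flag) and more than two by one-way ANOVA with Tukey HSD.
Degenerate inputs (singleton groups, zero within-group variance) fall
back to descriptive output with a warning rather than fabricating a
p-value. Regression is unconstrained: measured t = 0 backgrounds enter as
data points, not as a forced intercept.

## What the synthetic-data generator emulates

`make_true_motif()` builds ground truth directly in normalized space: a
few selective positions, each with one favored residue at a chosen fold
preference over the rest of its column, remaining positions flat, and an
acceptor preference over S/T/Y. Default shape — 3 selective positions at
5-fold preference, acceptor preference (0.5, 0.4, 0.1) — reflects what
screens of Ser/Thr kinases typically show: a small number of strongly
selective flank positions over a near-uniform background, and a
same-family acceptor split with minor Tyr signal.

`simulate_spot_grids()` applies two noise sources: per-spot multiplicative
lognormal noise (`sigma_log`, default 0.1 — a ~10% coefficient of
variation, a realistic spot-level reproducibility for quantified dot
blots) and a per-replicate global scale drawn from (0.5, 2), emulating
exposure differences that the normalization must (and provably does)
remove. Replicate count defaults to the design minimum relevant here
(n ≥ 2; simulations in the tests use 3).

`simulate_site_database()` draws background windows i.i.d. from a
configurable background composition (default uniform over the 20 amino
acids — deliberately neutral, since no particular proteome is being
modeled) and implanted windows per position from a motif's columns
renormalized to probabilities, i.e. better-matching sites are more
likely, the generative counterpart of "better match ⇒ better substrate".
Defaults (950 background + 50 implanted = 5% implant rate) give selection
tests a known base rate.

What this generator does **not** model: scanner saturation, spatial blot
artifacts, peptide-synthesis failures, residue-composition biases of real
proteomes, or correlated noise between neighboring spots. Passing tests
therefore demonstrate that the pipeline recovers truth under its own
stated noise model — not that any particular biological conclusion from
real blots is correct.

## Problem sizes and determinism

Every generator is a pure function of its parameters and a mandatory
seed (seeded via an isolated RNG scope, so library calls never perturb
the caller's RNG state). The statistical recovery tests run 100
independent seeds each: motif recovery (σ = 0.1, 3 replicates, preference strength
3) asserts flattened Pearson r ≥ 0.95 in ≥ 95% of seeds;
planted two-group clustering (3 noisy kinases per group) asserts the root
bipartition separates the groups in ≥ 95% of seeds; the two-group rate
comparison (true slopes 100 vs 20 CPM/min, noise sd 30, n = 3) asserts
p < 0.05 in ≥ 95% of seeds. These sizes keep the full suite in the
tens-of-seconds range while leaving the pass-rate estimates stable.

## Known limitations

* The score scale is contract-compatible with the published tool (0 =
  perfect, lower = better) but not numerically identical to any specific
  version of it; only percentile-based selections should be compared
  across implementations.
* Logo heights are raw log2 values, not information-content weighted.
* The Y-library grid reuses the same 9 × 22 container although Tyr-library
  degenerate positions exclude Tyr by construction; the capping rule is
  the only place the library type changes behavior.
* `read_psp_sites()` accepts the common flat-dump layout of public
  phosphosite databases but tests rely exclusively on synthetic data.
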
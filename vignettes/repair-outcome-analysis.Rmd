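---
title: "Modelling Cas9 repair outcome profiles across DNA-repair knockouts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling Cas9 repair outcome profiles across DNA-repair knockouts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

When Cas9 cuts DNA, the cell's double-strand-break repair machinery converts
the blunt break into a distribution of mutagenic outcomes: small indels from
non-homologous end joining (NHEJ), deletions between short exact repeats
("microhomologies") from microhomology-mediated end joining (MMEJ), and rarer
templated insertions and complex events. Which outcome a given target
produces depends jointly on the target sequence and on which repair genes
are present. Screens that measure outcome read counts at thousands of
synthetic targets across repair-gene knockout cell lines make that interplay
quantifiable — but the analysis between "count table" and "biology" involves
many small, error-prone conventions. `repairscape` packages that analysis:
a canonical algebra for indel outcomes, coverage filtering and pooling,
knockout fold-change profiling, microhomology-decay regression, response
clustering, and per-cell-line predictive models, plus a synthetic-screen
generator with planted ground truth so that every stage is verifiable at
desk scale.

# The outcome algebra

All coordinates are 0-based and half-open; the cut is a *gap* index (the cut
lies between sequence positions `cut - 1` and `cut`, i.e. between the 17th
and 18th protospacer bases, three bases 5' of the NGG PAM). The base 5' of
the cut is the PAM-distal flank; the base 3' is the PAM-proximal flank.

**Canonical representation.** A deletion inside a repeat can be written in
several ways that produce the same edited molecule; sequencing cannot
distinguish them and counting must not double-count them. `canonicalize()`
reduces any (deletion interval, inserted sequence) pair to the left-most
equivalent representation — the convention used by most indel-normalisation
tools; any fixed convention preserves all the statistics in this package.
The number of equivalent representations minus one *is* the microhomology
length of a pure deletion: both definitions (equivalence-class size, maximal
exact repeat shared by the junctions) coincide, and the test suite checks
the implementation against a brute-force oracle that groups all same-size
deletions by edited-sequence identity.

**Categories.** Outcomes map to ten categories: 1 bp and 2 bp deletions,
medium (3–9 bp) and long (10+ bp) deletions with or without microhomology
(threshold `mh_min = 2` bp — fits of the microhomology law start at 2 bp and
0–1 bp repeats behave like non-homologous ends; the threshold is a
configuration knob), 1–2 bp cut-site insertions matching the PAM-distal or
PAM-proximal flank, and other insertion-containing outcomes with or without
an exact `mh_min`+ match between the insertion and the flanking sequence
(searched within 10 bp of the edit locus; the window only affects the
OTHER_I split and is configurable). Insertions matching two identical
flanks are counted as PAM-distal by default (templated fill-in of a
PAM-distal overhang is the dominant mechanism) and are excluded from
proximal-versus-distal share estimates, where the match would be ambiguous.

**Directionality.** A deletion's asymmetry about the cut is
`max(left, right)/total`. For deletions with microhomology the left/right
split itself depends on the chosen representation, so it is taken from the
representation whose midpoint is closest to the cut (ties toward the left);
this deliberately avoids inflating directionality through alignment
convention. The alternative definition `|left - right|/total` is exposed via
`method = "diff"`; both give 1 for any 1 bp deletion.

# The synthetic generator

`make_library()` draws random NGG targets (80 bp, cut centred, the 16
cut-flanking dinucleotide pairs cycled so each is equally represented).
`ground_truth_distribution()` assembles an exact per-target outcome
distribution over the enumerable candidate set, and `sample_dataset()` draws
multinomial reads at Poisson depth per (line, replicate, timepoint).

The generator plants its parameters *in frequency units*, so that each
planted quantity is exactly recoverable:

* every deletion using an `s` bp microhomology at inter-copy distance `d`
  (bases strictly between the repeat copies, `d = del_size - mh_len`) has
  frequency `A_s * exp(B_s * d)`, for `s` = 2..15. Defaults: `A_s`
  rises from 0.06 by a factor 1.2 per bp of microhomology, and `B_s` rises
  from −0.25 by +0.01 per bp, so longer microhomologies are both more
  frequent and slower-decaying with distance — the qualitative shape of
  MMEJ. Deletions whose repeat copies overlap (`mh_len > del_size`, e.g. in
  homopolymer runs) fall outside the law's domain (`d < 0`) and get
  baseline weight;
* flank-matched 1 bp cut-site insertions carry a per-flank-pair total (0.29
  for PAM-distal T/A, 0.097 for G/C — roughly threefold, matching the
  observed flank effect) split between the distal- and proximal-matching
  base by a configurable proximal share (default a mild heuristic favouring
  T and penalising G);
* the remaining mass goes to non-homologous deletions whose per-size mass
  decays geometrically (ratio 0.85 by default; no empirical law for
  non-microhomology deletions is established, only monotone decay matters),
  split evenly within a size, plus a 5% sliver for other insertions.

**Knockout effects are exact fold changes.** A category with multiplier `k`
has its total frequency multiplied by exactly `k`; categories at multiplier
1 absorb the residual proportionally. Planted log2 fold changes are
therefore exactly `log2(k)` (up to the pseudocount), rather than being
distorted by renormalisation as a scale-then-normalise scheme would do.
Multiplier sets that demand more than the available mass raise an error
instead of being silently rescaled. `line_presets()` documents illustrative
knockout parameterisations (NHEJ cores depleting small indels, an
MMEJ-resection knockout suppressing medium/long deletions, polymerase
knockouts depleting proximal insertions); they are documentation, not
calibrated reproductions.

What the generator does *not* emulate: sequencing error, gRNA efficiency,
wild-type reads, mixed insertion-deletion outcomes, outcomes outside the
enumeration window, and the sequence-composition quirks of a designed (as
opposed to random) target library. Random 80-mers also contain far fewer
long-microhomology opportunities than a designed library, so aggregate
category compositions are not expected to match a real screen even when the
per-outcome laws do. Passing recovery tests therefore demonstrates the
correctness of the estimators under the generator's assumptions, not their
robustness to real-data artefacts.

# Profiles, fold changes and the insertion summaries

`filter_and_pool()` applies the screen's coverage rules on raw per-sample
counts: targets need at least `min_reads = 100` mutated reads in *every*
(line, replicate, timepoint) sample — targets missing from any sample are
dropped everywhere, keeping lines comparable — and outcomes seen in exactly
one read across all samples are removed; survivors are pooled over
replicates and timepoints. Frequencies are fractions of mutated reads, so
profiles always sum to 1.

Fold changes are `log2((f_ko + pc)/(f_ctrl + pc))` with `pc = 0.001` (0.1%
in frequency units). The pseudocount is stated for the deletion-grid
analyses; we reuse it uniformly for outcome- and category-level fold
changes (configurable). Summaries average per-target fold changes over
targets, not fold changes of averaged frequencies.

`insertion_flank_summary()` reports mean absolute 1 bp-insertion frequency
per flanking pair, and the pooled PAM-proximal share
`sum(prox)/sum(prox + dist)` over targets with differing flanks, with
percentile (2.5/97.5) bootstrap intervals resampling targets (N = 1000 by
default). Percentile intervals on a ratio need a moderate number of
targets to be well calibrated; the package's calibration test uses a
128-target library (~96 with differing flanks), where empirical coverage of
the 95% interval is ~94–95%.

# The microhomology decay law

`fit_mh_all()` fits `y = A * exp(B * d)` per microhomology size `s` = 2..15
and cell line by nonlinear least squares (Levenberg–Marquardt, initialised
at `A0 = max(y)`, `B0 = -0.1`, with a deterministic nudged restart for flat
response surfaces). Observations are raw per-outcome points — one per
(candidate microhomology deletion, target, line) — with `y = 0` for
candidates absent from a profile. Including the zeros matters: conditioning
on observation truncates the sampling noise at low frequencies and biases
`A` up and `B` toward 0. The distance definition is the inter-copy gap;
start-to-start distance differs by a constant `s` per stratum and only
reinterprets `A`, and is exposed via `distance_def = "start"`.
Underdetermined strata (< 3 points or < 2 distinct distances) return
explicit no-fit rows.

# Clustering knockout responses

`build_lfc_matrix()` keeps (target, outcome) rows that are present in the
control profile and in at least `min_lines = 10` knockout lines (clipped
with a warning when fewer lines exist), removing the stochastic dropout of
rare events, and logs the removed control mass. Entries are pseudocounted
log2 fold changes with absent frequencies taken as 0.

`embed_lfc()` places rows in 2-D with a spectral embedding: the
eigenvectors of the symmetric normalized Laplacian of the symmetrized
`n_neighbors = 50` nearest-neighbour graph for the two smallest non-trivial
eigenvalues. This neighbourhood-graph embedding is fully deterministic
(a virtue for a pipeline whose outputs are hashed into a manifest), uses the
same graph construction that stochastic manifold embeddings start from, and
is computed exactly for up to 1500 rows and by sparse subspace iteration
above that; a weak (1e-8) ring keeps disconnected graphs embeddable. A PCA
backend is available. `cluster_outcomes()` runs k-means (default `k = 7`,
50 restarts, seeded) on the 2-D coordinates — a deterministic, total
labelling; no published algorithm choice exists for this step, and
density-based alternatives would leave unlabelled noise points that the
composition tables cannot absorb. Raw (unscaled) fold changes are embedded;
scaling columns would equalise knockouts with strong and weak phenotypes.

Composition tables follow the two captioned conventions: table E gives each
category's distribution over clusters (columns sum to 100%), table F each
cluster's category make-up (rows sum to 100%), both weighted by control
frequency by default. Knockout enrichment is the cluster-mean fold change
minus the overall mean within each knockout column, so size-weighted column
means are zero. `directionality_summary()` compares per-cluster mean
directionality of non-homologous deletions against the library average.

# Predicting outcome profiles

`enumerate_candidates()` defines the candidate universe at a target — every
insertion of 1–2 nt within 3 nt of the cut and every deletion of up to
30 nt spanning it, canonicalized and deduplicated (a repeat-free target has
exactly `sum(L+1, L=1..30) = 495` distinct deletions; a homopolymer
collapses to 30). `featurize()` encodes each candidate as ~300 binary
features over a named, versioned registry: deletion size (exact and
binned), boundary offsets from the cut, microhomology bins, junction and
cut-context nucleotides, inserted-sequence identity and gap offset, frame,
and pairwise combinations of selected families. The registry is
fingerprinted and models refuse to predict against a different registry.
The registry reproduces the published feature *families* rather than any
particular feature count.

`train_predictor()` fits one shared weight vector per cell line by
minimising `sum_t KL(measured_t || softmax(X_t theta)) + lambda*|theta|^2`
— equivalently, pseudocount-weighted multinomial maximum likelihood. The
measured profile adds 0.5 reads to every enumerated candidate and
renormalises; measured outcomes outside the enumeration window are dropped
from numerator and denominator with their mass logged. Training KL is
`D(measured || predicted)` in natural log; evaluation reports the
symmetrized divergence alongside. Optimisation is L-BFGS with the analytic
gradient in restarts of 100 iterations; the restart losses form a
non-increasing trace and convergence requires a relative change below 1e-6.
The L2 default `lambda = 0.01` is a mild ridge (no regularisation strength
is published for this model class); recovery experiments that train on
exact generator probabilities use 1e-3 so shrinkage does not dominate the
noiseless signal. Targets, not outcome rows, are split 90/10 into train and
test to prevent within-target leakage. Evaluation reports per-target KL
(against the replicate-to-replicate KL when a second measurement is given)
and pooled Pearson correlations at three granularities: individual outcome
frequencies, ten-category aggregates, and the per-target in-frame fraction
(the proxy for protein-knockout efficacy).

# Numerical conventions and degenerate inputs

* Wild-type (empty) outcomes are rejected; classification is total over
  everything else.
* Profile frequencies, ground-truth distributions and predictions must sum
  to 1 within 1e-9; composition tables to 100% per captioned axis.
* All randomness flows through named `seed` arguments and never leaks into
  the caller's RNG state; spectral embedding and k-means are deterministic
  given their seeds.
* `run_end_to_end()` writes every stage artifact plus a manifest (md5,
  sizes, seeds, config hash, versions); reruns with the same config are
  byte-identical for the deterministic artifacts. Stage failures abort with
  the stage named and partial outputs preserved under `failed/`.
* Degenerate generator parameters (planted mass ≥ 95%, infeasible
  multipliers, all-zero weights) are errors, never silent rescales.

# Problem sizes used by the validation suite

The packaged tests run the recovery experiments at: 200 random 40-mers for
the canonicalization oracle; 50 random targets for enumeration
completeness; 200 targets at 1e5 reads for fold-change recovery (the
planted 2.0 multiplier is placed on the PAM-distal insertion category,
whose planted mass is bounded away from the pseudocount on every target);
200 targets at 2000 reads for the microhomology law (s = 2..4); five seeds
of a 180-row, 3-archetype matrix for clustering; 200 exact-probability
targets plus a 60-target control/knockout pair for the predictor; and a
128-target library with 1000 simulated datasets × 1000 bootstrap resamples
for interval calibration. These sizes were chosen so each estimator
operates in the regime where its guarantees apply (e.g. enough targets for
percentile-bootstrap calibration) while remaining desk-scale.

# Known limitations

* Substitution (SNV) outcomes and mixed insertion-deletions are outside the
  candidate grammar; PAM-on-minus targets are not represented (libraries
  store targets in protospacer-5'→3' orientation).
* The embedding is a Laplacian eigenmap, chosen for determinism and exact
  reproducibility; the geometric details of stochastic manifold embeddings
  are not reproduced, and cluster counts beyond the planted ground truth
  carry no meaning on synthetic data.
* The insertion-flank microhomology window (10 bp) and the `OTHER_I` split
  it controls are conventions; alternative windows change only that split.
* Exact fold-change planting constrains feasible multiplier sets (planted
  masses must stay below 1); extreme knockout phenotypes on high-mass
  categories cannot be planted exactly and error out instead.
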
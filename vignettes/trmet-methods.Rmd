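---
title: "Methods: linking transcriptional-regulator activity to the metabolome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking transcriptional-regulator activity to the metabolome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

trmet implements a computational pipeline that connects the activity of
transcriptional regulators (TRs) — transcription factors, chromatin
remodelers and co-regulators — to intracellular metabolite levels measured
across a panel of adherent cancer cell lines. This vignette explains the
models behind each stage, the parameters that matter, the design choices
made where the design was genuinely open, and what the synthetic-data
generator does and does not emulate.

## The measurement model and normalization

Untargeted flow-injection mass spectrometry yields an ion-by-sample
intensity table. Three nuisance layers sit between raw intensities and
per-cell metabolite abundances.

**Plate scaling.** Each measurement plate p carries a multiplicative
instrument factor γ~p~. Pooled quality-control extracts — the same pooled
composition measured on every plate of a batch — identify the factors
through the two-factor log-linear model
log I~i,j,p~ = log γ~p~ + log M~i,j~, fitted by least squares
(`estimate_plate_factors()`). Because pooled extracts are prepared per
batch (five cell lines per experiment), plates of different batches share
no composition: the design graph is disconnected across batches, and the
gauge Πγ~p~ = 1 is therefore imposed within each batch. A disconnected or
pool-free plate is reported as unidentifiable rather than silently scaled.

**Cell number.** Adherent cell counts come from confluence: count =
confluence × well area / characteristic cell area
(`cells_from_confluence()`; 0.32 cm² wells by default). Per ion, one
multiple regression over all lines relates intensity to extracted cell
number with a line-specific slope α and a single shared intercept β (MS
background): `fit_cell_regression()`. Fitting jointly over the full
growth time course makes α invariant to cultivation time and density,
which the tests state as: refitting on any subset spanning the count
range moves α by less than 3 standard errors.

**Ion filtering.** An ion is retained when its regression p-value passes
the Bonferroni threshold 0.05/(n~lines~ × n~ions~) in at least one line
*and* a per-line threshold in more than 80% of lines. The second
criterion's threshold is not uniquely determined by the description we
reconstruct; nominal p < 0.05 is the default and a `frac_mode` switch
provides the stricter Bonferroni variant.

**Volume correction and Z-scores.** Per-cell abundances still scale with
cell volume. PCA across retained ions (lines as observations, centred
but not scaled by default; a `standardize` switch exists) extracts the
dominant volume trend; ions correlating with the PC1 scores at Pearson
r > 0.8 (p < 0.05) are rescaled to unit mean — without this rescaling
high-abundance ions would dominate — and averaged into a per-line
consensus factor that divides all columns. Z-scoring then uses the
population (1/n) standard deviation per ion. Degenerate inputs are
handled explicitly: a zero-variance ion is flagged NA, and a panel with
no between-line variance returns unit factors.

**Annotation.** Ions match reference compounds within 0.003 amu of the
deprotonated mass M − 1.007276; α-keto acids are additionally tested as
phenylhydrazone derivatives (shift +C6H8N2 − H2O = +90.05818 amu, from
standard atomic masses). All candidate matches are reported.

## TR activity by constrained decomposition

A TR's activity is imprinted on its target genes, not on its own mRNA or
protein level. Given expression E (genes × lines) and a signed TR→gene
network, network component analysis seeks E ≈ A·P with the loading
matrix A restricted to the network topology. The solver
(`run_nca()`) is alternating least squares in C++: the P half-step is an
exact linear solve; the A half-step solves per-gene restricted least
squares with activation loadings constrained nonnegative and repression
loadings nonpositive (sign violations are clamped to zero and the
reduced system re-solved). Both half-steps are guarded so the objective
never increases; convergence is a relative objective change below `tol`
(default 1e-6, capped at `max_iter` = 100 with a warning on
non-convergence). Whether edge signs should be hard constraints is not
settled; `sign_constraints = TRUE` is the default and a switch exists.

**Growth pseudo-TR and its gauge.** Proliferation has a pleiotropic,
approximately rank-one effect on expression. An artificial TR targeting
every gene (unconstrained loadings) absorbs it. This column makes the
decomposition invariant to adding any multiple of the growth activity to
a real TR's activity row — the growth loading column can absorb the
compensation exactly — so activities are estimable only up to that
direction. We fix the gauge by projecting each TR's activity orthogonal
to the growth pseudo-activity after convergence. Consequently the
component of a true activity lying along the growth direction is
unrecoverable in principle; the synthetic generator draws true
activities orthogonal to the growth-rate vector so that recovery tests
measure the estimable part.

**Bootstrapping.** To hedge against network incompleteness and multiple
optima, each TR seeds 10 subnetworks of itself, 48 uniformly drawn other
TRs and the growth pseudo-TR (50 real TRs per subnetwork); a TR's
estimates are collected from every subnetwork containing it — 10 × (1 +
48) = 490 on average, independent of the TR count. Per subnetwork each
activity row is normalized by its maximum absolute value (a `normalize =
"global"` alternative pools first); the reported activity is the
per-line median across estimates, rescaled to max |activity| = 1, with
its SD and estimate count. Sign-free rows are oriented so the
loading-weighted mean target correlation is positive. Probe-level
expression collapses to genes by the median (`collapse_probes()`).

## Association networks and significance

Spearman correlation between every TR activity and every metabolite
across shared lines gives the association matrix
(`tr_metabolite_correlation()`); missing metabolite values sit near
background and count as zero. P-values use the two-sided t
approximation, cross-checked against `cor.test` in the tests. The
network threshold controls the false-discovery rate among links at 0.1%
by a bootstrap null: the metabolome's cell-line labels are resampled
with replacement 100 times — resampling must break the pairing with
activities, which the wording "randomized by resampling" leaves open —
and the threshold is the smallest pooled |R| exceeding the 99.9% lowest
null correlations. Calibration is tested: on independent null data the
false-link rate stays within twice nominal.

The augmented TR-gene network adds an edge for any enzyme transcript
correlating with a TR activity profile at |Spearman| > 0.5 across a
compendium. Tissue dependence of metabolites uses one-way ANOVA with
Storey q-values; the tissue-signature ROC scores all unordered line
pairs by profile similarity (Spearman by default, configurable since the
original similarity metric is not recorded), with AUC from the
Mann-Whitney rank formula, cross-checked against pROC.

## Metabolic-network distances

A bipartite graph joins metabolites to the reactions they participate
in, ignoring direction; enzymes map to reactions through a flat
gene→reaction list (boolean gene-reaction rules are out of scope).
The distance from an enzyme to a metabolite is the number of reaction
nodes on the shortest alternating path — a metabolite of the enzyme's
own reaction has distance 1 — computed by multi-source BFS in C++; a TR's
distance is the minimum over its enzyme targets. The
distance-versus-correlation curve sweeps cumulative |R| thresholds
(binning is available; the original binning convention is not recorded)
and compares mean distances against 10,000 degree-preserving
randomizations (double-edge swaps on the bipartite edge list; swaps
creating duplicate edges are skipped, so both degree sequences are
preserved exactly). The per-threshold p is the fraction of null means at
or below the observed mean. Hub ("currency") metabolites are kept by
default; `max_degree` optionally excludes them, because they dominate
shortest paths.

## Enrichment statistics

Set enrichment is the upper-tail hypergeometric test, exact against
enumeration for small universes; directional runs split a correlation
signature at an absolute cutoff. Rank enrichment implements an
iterative hypergeometric: for each prefix ending at a member's rank the
hypergeometric p is computed and the pathway score is the minimum over
prefixes. Because that minimum is selection-biased, significance is
calibrated by random rank permutations (null minima shared across
pathways of equal size); this permutation calibration is the package's
principal methodological substitution, chosen because the exact
closed-form correction of the original iterative test is not available
to us. Storey q-values estimate π₀ on a λ grid with a spline smoother;
below 10 p-values the estimate is unreliable and Benjamini-Hochberg is
used with a warning.

## Dot-product TR scores

All downstream scores share one form: the dot product of a TR's
metabolite signature with a per-condition metabolite vector, L1-
normalized by the signature. The signature C~TR~ has entries
R × (−log10 p) from the association matrix (two-sided p, floored at
1e-300). For glycolytic flux the metabolite vector is the mean Spearman
correlation with glucose uptake and lactate secretion; pathway-level
aggregation compares a pathway's mean TR score with equal-size random TR
sets (one-sided). For patient cohorts, per-patient scores over the
overlapping metabolites (metabolites with more than 10 missing values
excluded) get one-sided permutation p-values by shuffling metabolite
order 10,000 times — exactly as the score definition dictates, without
pseudocount smoothing, so p may be 0 — then Storey q per patient and the
median of q across patients per TR (median-of-q, following the stated
order of operations; q-of-median is the alternative we did not take).
Knockdown experiments reuse the same score per siRNA concentration, with
per-metabolite significance the product of p-values across
concentrations and TRs ranked by absolute median score.

Drug association regresses (log-scale) sensitivity on one TR's activity
plus tissue indicators — no additional intercept, so tissue terms play
that role; λ is the activity coefficient with a t-test, significant at
the Bonferroni threshold α/(n~TR~ × n~drug~) computed from the tests
actually run. Tissues with fewer than two lines pool into "other".
Cluster-by-mechanism enrichment is hypergeometric over significant
(TR, drug) pairs at a Bonferroni threshold.

## Effector models

TR activity is modeled as a + b · protein · f(met; K) · f(kin; K) with
saturable activation f(x) = x/(K+x) or inhibition f(x) = K/(K+x), all
abundances rescaled to unit median. This functional family and the
multiplicative composition are the package's own choice — the original
form is not recorded — and forms are pluggable behind the spec's form
id. The half-saturation constants are profiled (a, b solved linearly at
each K) and optimized from three seeded starts, K bounded in
log-space; the baseline is a + b·protein, and ΔMSE is reported without
clipping so a negative value flags optimizer failure on this nested
family. The enumeration per TR is 2M + 2K + 4MK candidate models; this
rule does not reproduce the 67,536-per-TR count of the original
compendium-scale scan, and we document rather than reverse-engineer the
difference. The scan's FDR pools ΔMSE values from refits on
label-permuted activities across all TRs and model families (a bulk
null); a model passes when its improvement exceeds the 1 − FDR null
quantile, and the scan errors out when the null pool cannot support the
requested quantile.

## The synthetic study

`simulate_study()` draws a complete study with known ground truth; every
downstream stage is tested against it. Conditions mirror the reference
design: 54 lines from 8 tissues, triplicates at five daily time points
(15 samples per line), batches of 5 lines, 12 pooled extracts and 3
blanks per plate, and multiplicative log-normal intensity noise at 13%
CV (the reported median replicate CV of raw intensities). Default sizes
are 500 ions (200 mapped to a 220-reaction toy bipartite network), 800
genes, 100 TRs with out-degree 8 (90% TR-exclusive targets, 70%/25%/5%
activation/repression/unknown modes), and 64 kinases. Cell areas,
volumes and doubling times are log-normal; confluence follows a logistic
from ~25%; plate factors are log-normal with per-batch product 1.

Planted structure gives recovery tests their teeth: per-cell abundances
are rank-one in cell volume (log-SD 0.4) with 8% residual log-noise;
eight planted TRs have two reactions re-assigned to their target enzymes
and the adjacent metabolites' log-abundances coupled to their activity
(coupling 0.3 in log units — chosen once so that planted links clear the
0.1% FDR threshold at the design noise, and exposed in the config);
40 ions carry tissue effects (SD 0.6); expression adds a rank-one growth
confounder (strength 1.5, making the first PC track growth rate at
|r| > 0.5) and 0.05 additive noise; patient cohorts plant one perturbed
TR (effect 1.5, unit noise, 5% MCAR missingness plus a 5% heavy-dropout
tail that exercises the >10-missing filter — missingness is
missing-completely-at-random, a simplification); three planted effector
triples drive TR activity through the saturable forms; and half the drug
panel has true λ = 0 as negative controls.

What the generator does *not* emulate: raw spectra, isotopes or
chromatography (intensities are already ion-level), images (confluence
is numeric), informative missingness, correlated TR programs, or any
real biological pathway structure. Passing tests therefore demonstrate
that the algorithms recover the structure they assume, at realistic
noise — not that real data satisfy those assumptions.

## Numerical choices and problem sizes

ALS tolerance 1e-6 (relative), 100-iteration cap, tiny ridge terms
(1e-10/1e-12) on normal equations; Spearman ties use average ranks;
permutation p-values use plain fractions (no +1 smoothing) where the
score definition is explicit, and null pools are shared across
equal-size pathways. The packaged test-suite and pipeline runs use the
default study (54 lines, 500 ions, 100 TRs, 1000 NCA subnetworks, 100
bootstrap resamples, 10,000 in-vivo permutations and 10,000 randomized
graphs), which completes in a few minutes on one CPU; module tests use
a 10-line, 15-TR miniature of the same design.

## Known limitations

Associations are correlational; no causal direction is claimed. The
activity scale is relative (per-TR max-normalized) and the growth-
direction component is unidentifiable by construction. The iterative
rank test and the effector functional family are documented
substitutions for unrecorded originals. Storey's estimator needs many
tests; small families silently gain conservatism through the BH
fallback. Reaction directionality, gene-reaction boolean logic and
flux-balance constraints are all outside the distance model.
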
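---
title: "Separating pheromone from starvation signaling in time-course phosphoproteomics"
author: "phosflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating pheromone from starvation signaling in time-course phosphoproteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosflow)
```

## The problem

Nitrogen starvation drives fission yeast into sexual differentiation, but
starvation itself remodels a large part of the proteome and phosphoproteome.
An experiment that profiles mating mixtures over time therefore observes two
superimposed programs. The design `phosflow` analyzes keeps a partner-free
starvation culture in parallel with every mating time course: both
experience the same starvation and plating history, and only the mating
samples experience pheromone. Subtracting the control's stepwise changes
from the mating series' stepwise changes cancels everything the two share
and leaves the partner-dependent signal.

Two designs are supported as presets. The *mating* design has 2 conditions
(control, mating) × 5 time points at 45-minute spacing × 3 biological
replicates, each replicate being one 10-plex TMT run (30 values per
feature). The *fusion* design has a single condition sampled at 11-minute
spacing with 4 replicates (15 values per feature after the filter
bookkeeping below) and uses a stricter significance threshold.

## Normalization

TMT replicates are separate multiplex runs, so each feature can carry an
arbitrary additive offset per replicate on the log2 scale. For every feature
and replicate, the median of the feature's non-missing values across all
time points of that replicate — pooling both conditions, which are part of
the same run — is subtracted. After centering, each feature's per-replicate
median is exactly zero, and any purely additive replicate offset is removed
exactly (this is asserted by tests, not just assumed). Medians over even
counts use the midpoint convention, and only non-missing values enter the
median; a feature entirely missing within a replicate is left untouched
there and counted in the `n_untouched` attribute.

Because replicate effects are removed here, the linear model deliberately
has no replicate term — adding one after centering would be collinear at the
per-feature level.

## Filtering and redundancy

Sites absent in more than one biological replicate are discarded. One lost
replicate equals exactly 10 of 30 values in the mating design and 5 of 15 in
the fusion design, so those are the preset `max_missing` values, and the
filter keeps features with missing count less than or equal to the bound
(the boundary case — one whole replicate lost — is kept).

Phosphopeptides with several possible phosphorylation positions can produce
multiple site rows carrying exactly the same measurements. Testing each copy
would bias the multiple-testing correction, so rows whose full value vectors
— including the missing-value pattern — are bit-identical are collapsed to
one representative before testing and the duplicates re-added afterwards
with copies of the representative's statistics and labels. Duplicate
detection is exact (not tolerance-based): duplicates arise from identical
source measurements, so exact equality is both correct and deterministic.
Rows that differ only in a missing cell are *not* grouped. The
representative is the lexicographically smallest feature id — an arbitrary
but stable choice.

## The moderated model

Each feature is fitted by least squares with one mean per (condition, time)
cell on whatever samples it was observed in; the residual degrees of freedom
are `n_obs − n_cells_observed`. Contrast sets are stepwise differences of
consecutive time points: the control set (`Ctrl_45-0`, …) measures the
starvation response; the corrected set

$$\mathrm{Diff}_{t,t-1} = (\mathrm{Mating}_t - \mathrm{Mating}_{t-1}) -
  (\mathrm{Ctrl}_t - \mathrm{Ctrl}_{t-1})$$

measures the partner-specific response. A site changing with the same slope
in both conditions cancels entirely; one changing in both conditions but
differently is retained.

Residual variances are moderated by empirical Bayes under the standard
hierarchical model (scaled inverse chi-square prior on the true variances):
the posterior variance is $\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)$, and
$(d_0, s_0^2)$ are estimated by closed-form moment matching of $\log s^2$
using digamma/trigamma identities, with no variance trend and no
robustification. $d_0$ may be estimated infinite, in which case every
$\tilde s^2 = s_0^2$. The test suite verifies that this estimator agrees
with `limma::eBayes` to numerical precision on complete data — `limma` is
used only as an independent oracle, never as the implementation.

Significance is decided by one joint moderated F per feature across its
contrast set: the quadratic form of the contrast estimates under the
contrast covariance $C^\top \mathrm{diag}(1/n_g)\, C$ (computed per feature
from its observed replicate counts, with a pseudo-inverse when the set is
rank-deficient), divided by the rank times $\tilde s^2$, referred to
$F(k_{\mathrm{eff}},\, d_0 + d)$. A feature missing an entire design cell is
excluded only from the contrasts touching that cell and tested on the rest;
features with zero residual df are excluded from testing. One
Benjamini–Hochberg adjusted p-value per feature results; per-contrast
moderated t statistics are also emitted for inspection.

Whether the published analysis used a joint F across the four contrasts or
some other one-number-per-site rule is not stated in enough detail to be
certain; the joint moderated F is this package's documented decision, and
the per-contrast statistics allow any other aggregation to be recomputed.

Classification: sites significant on the Diff set at `alpha` (0.05 for the
mating preset) are `mating_specific` if not significant on the control set
at `alpha_starvation`, otherwise `both_different`; control-only significant
sites are `starvation_only`. The fusion preset uses `alpha = 0.001`,
reflecting its 4-replicate design. Significant sites are clustered by their
replicate-averaged (corrected) profile: the sign of last-minus-first for
k = 2, and for k = 3 the increasing sites split into early (at least half
the net increase reached by the second time point) versus late. A net
change of exactly zero goes to "increase" and is counted in an attribute —
a measure-zero tie in continuous data.

## Covariation with protein abundance

A phosphosite on a protein whose abundance changes may show an intensity
change with no regulatory meaning. For each significant site whose protein
changed significantly, per-replicate log2 fold changes against that
replicate's t = 0 sample are computed in both layers (t = 0 within
replicate is the only baseline available in both layers), pooled, and
fitted with

$$\Delta = b_0 + b_1\,\mathrm{layer} + b_2\,t + b_3\,(\mathrm{layer}\times t)$$

where layer is protein vs phosphosite. The interaction $b_3$ (log2 units
per minute) is the slope difference; its two-sided t-test p-values are
BH-adjusted over the tested set, and adjusted p above 0.05 means the site
co-varies with its protein. Sites whose protein shows no significant change
are labelled independent without testing, and sites without protein data are
reported separately. For the mating preset the deltas are
starvation-corrected (mating minus matched control) before the regression,
matching the corrected significance calls; the uncorrected mode is available
through `covariation_analysis()` directly. Replicate points are pooled into
one plain regression per site (no mixed effects) — the method is a simple
interaction test, not a variance-components model.

Two "% independent" summaries are reported because the denominator
convention matters: `pct_independent` counts independent plus
independent-for-lack-of-protein-change over all significant sites with any
protein information (absence of protein change implies independence), and
`pct_independent_tested` restricts to sites actually tested.

## Enrichment, motifs, screen metrics

Kinase-substrate enrichment is a Fisher exact test (two-sided by default;
one-sided available) of hit sites against a background of all
monophosphorylated quantified sites after filtering — multiply
phosphorylated peptides are excluded because their site assignment is
ambiguous. Fold enrichment is the ratio of substrate proportions in hits vs
background.

Motif analysis aligns the ±5-residue windows of a site list and tabulates
per-position residue probabilities (the numerical content of a probability
logo). Terminal padding (`_`) is excluded from denominators.
Proline-directed sites — proline immediately C-terminal (+1) to the
phosphoresidue, the CDK/MAPK signature — can be removed, as can named site
lists (e.g. known substrates of a kinase whose motif would dominate),
before looking for what remains.

The microscopy metrics are direct formula plug-ins. One reading conflict is
resolved explicitly: the fusion-efficiency formula as printed divides fused
pairs by (unfused) mating pairs, while its verbal definition is the
percentage of paired cells that fused. The package implements the verbal
definition, `fused / (unfused + fused)`, and exposes the literal formula via
`denominator = "unfused_pairs"`.

## The synthetic-data generator

`simulate_experiment()` emulates the statistical structure the analysis
assumes, not mass spectrometry: no peptides, reporter-ion interference, or
acquisition artifacts. Its defaults are the mating study conditions — 3
replicates × 2 conditions × 5 time points; the fusion layout (4 replicates,
single condition, 11-minute spacing) is a configuration away.

* **Profiles** are monotone piecewise-linear in time: per-interval log2
  increments drawn as half-normals of scale `effect_size_sd` with a common
  random sign. Monotone shapes match the increase/decrease clusters the
  analysis expects; with the default scale of 1.0 a non-null site
  accumulates about 3 log2 units over 4 intervals, in line with the
  magnitudes of strongly responding phosphosites. Null sites are flat in
  both conditions, `starvation_only` sites share one profile across
  conditions, `mating_specific` sites change only in the mating condition,
  and `both_different` sites draw independent profiles per condition.
* **Noise and batch**: measurement noise is Gaussian in log2 space with SD
  0.25 (typical TMT ratio scatter; the noise model of the real ratios is
  not published, so Gaussianity is an explicit assumption). Batch offsets
  are drawn per feature × replicate with SD 0.5 — exactly the structure
  per-replicate median centering removes.
* **Effect classes** default to 70% null, 22% starvation-only, 4%
  mating-specific, 4% both-different, echoing the published proportions
  (about 29% of sites changed under starvation; a few percent responded to
  the partner).
* **Coupling**: a `coupled_fraction` of sites adds its protein's profile to
  its own, so a coupled null site tracks its protein exactly (the
  co-varying case) while a coupled site with its own effect remains
  separable from the protein (independent).
* **Missingness** is MCAR at `missing_rate` plus whole-replicate dropout at
  `replicate_dropout_rate`; dropout exists specifically because one lost
  replicate sits exactly on the missing-value filter boundary.
* **Redundancy** duplicates a fraction of rows bit-identically, exercising
  collapse/expand.
* **Substrate sets** plant membership at background probability 0.05,
  multiplied in odds by `substrate_enrichment_odds` among mating-specific
  sites. **Windows** are uniform over the 20 amino acids with an optional
  planted residue at a fixed offset in one class.
* **Reproducibility**: one global seed feeds a hierarchical generator;
  structure, profiles, values, missingness, redundancy and windows each use
  an independent sub-stream, so the same seed gives bit-identical output.

Passing tests on these simulations shows the pipeline recovers planted
effects under its own model assumptions; it does not certify behavior under
non-Gaussian noise, intensity-dependent missingness, or shared-peptide
effects, none of which the generator emulates.

## Numerical choices and problem sizes

Duplicate detection serializes value vectors at 17 significant digits
(exact double round-trip). The contrast covariance pseudo-inverse drops
eigenvalues below 1e-10 of the largest. The trigamma inverse uses Newton
iterations to relative 1e-8. BH adjustment and the Fisher test delegate to
`stats::p.adjust` and `stats::fisher.test`; the tests compare them against
an exhaustive step-up oracle (all two-component p-vectors on a 0.01 grid
plus dense random sampling up to length 8) and full hypergeometric
enumeration of all 2×2 tables with margins up to 30. Calibration checks run
at 10,000 features: Kolmogorov–Smirnov uniformity of null moderated-F
p-values (D < 0.02), and false-discovery control on null data across 20
seeds — sizes at which the KS statistic is sensitive to percent-level
miscalibration while the whole suite stays fast. Planted-recovery checks
use 10,000 sites with 10% mating-specific effects at 4× the noise SD, and
covariation accuracy uses 2,000 sites at 50% coupling.

## Known limitations

* The per-feature group-means model ignores correlation induced by median
  centering; on pure-noise data the resulting p-values are slightly
  conservative (fewer false positives), which is the safe direction.
* Covariation regression treats replicate-level points as independent.
* The supplementary-workbook reader handles the replicate-column layout by
  header text; the deposited files' cell shading is not machine-readable.
* No localization-probability filtering, no spline/trend time models, no
  GO enrichment (an external service in the original analysis), no raw
  MaxQuant output parsing beyond the minimal column subset.
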
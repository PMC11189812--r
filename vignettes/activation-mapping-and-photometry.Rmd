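---
title: "Brain-wide activation mapping and contact-evoked photometry with actmap"
author: "actmap maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain-wide activation mapping and contact-evoked photometry with actmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actmap)
```

# Scope

`actmap` implements two linked analyses for experiments that ask *which brain
region distinguishes a treatment* and *how that region responds to social
contact*:

1. **Count-side analysis.** Per-animal counts of immediate-early-gene (IEG)
   reporter-positive cells in M parcellated brain regions (M = 22 by default)
   are z-scored, two treatment groups at a time are classified with a linear
   support vector machine (SVM), and the classifier weights are transformed
   into a forward-model *activation pattern* whose largest-magnitude entry
   nominates the discriminating region. Labelled insular-cortex (IC) cells
   are additionally binned along the anteroposterior (AP) axis.
2. **Photometry-side analysis.** Single-wavelength fiber-photometry traces
   (100 Hz) are baseline-corrected with airPLS, z-scored against a 5 min
   home-cage baseline period, investigation events are reduced to
   *nonsequential* contacts (>= 10 s after the previous bout ends), and
   contact-evoked responses are quantified as window-mean differences with a
   paired contrast and a rank correlation.

Because the kind of raw data these analyses consume (whole-brain imaging,
photometry recordings) is rarely redistributable, a seeded synthetic-data
module generates every input with known ground truth; all tests and the
acceptance script run against it.

# The forward-model (activation-pattern) transform

A linear classifier is a *backward* model: its weight vector $W$ maps
observations $x$ (the M-vector of per-region z-scores) onto a latent decision
variable $\hat s = W^\top x$. Weights of backward models are not
interpretable feature-by-feature: a region can receive a large weight solely
to cancel noise shared with other regions. The corresponding *forward* model,
which is interpretable, is obtained by the covariance transform

$$A = \Sigma_x W \Sigma_{\hat s}^{-1}, \qquad
  \Sigma_{\hat s} = W^\top \Sigma_x W,$$

where $\Sigma_x$ is the covariance of the observed data and
$\Sigma_{\hat s}$ the covariance of the latent factor. For a single binary
classification K = 1, so $\Sigma_{\hat s}$ is a positive scalar and the
matrix inverse is a scalar division. `haufeActivation()` implements exactly
this identity and stores $\Sigma_x$ and $\Sigma_{\hat s}$ so the identity is
verifiable afterwards (the class validity re-checks it to 1e-10).

Numerical notes:

* $\Sigma_x$ is estimated from exactly the animals used in the two-group
  fit, pooled without per-class centering, with the unbiased $n-1$
  denominator. With M = 22 regions and n = 10 animals $\Sigma_x$ is rank
  deficient; that is harmless because the transform never inverts it.
* If $W^\top \Sigma_x W \le 10^{-14}$ (zero weights or totally degenerate
  data) the transform refuses with a degeneracy error rather than returning
  infinities. This genuinely occurs: for strongly overlapping classes the
  soft-margin optimum can be $W \approx 0$.
* For whitened data ($\Sigma_x = I$) the transform collapses to
  $A = W / (W^\top W)$, which the tests exploit as an exact identity.

## The SVM underneath

The two-group classifier is the standard soft-margin linear SVM, solved in
the dual with a maximal-violating-pair SMO iteration written in the package.
Writing it in-package (rather than binding to an external solver) buys three
properties the analysis depends on: bit-level determinism for a fixed input,
exact antisymmetry under label exchange (swapping the class labels negates
$W$ and the intercept exactly, leaving $|A|$ rankings invariant), and a
solution whose dual objective can be compared against an independent
reference implementation in the test suite (agreement to 1e-6 is enforced;
observed gaps are ~1e-11). Defaults: C = 1, KKT-gap tolerance 1e-10, no
feature re-scaling (inputs are already z-scores). The intercept is fitted
but never enters the activation transform.

## Standardization

z-scores are computed per region across **all** animals of all groups
jointly, before any pairwise subsetting, with the sample SD (denominator
n − 1). Standardizing on the full cohort preserves a common scale across the
two pairwise comparisons. A region with zero variance across
the cohort has no defined z-score; `standardizeCounts()` refuses such input
naming the region rather than silently producing NaN columns.

## Ranking and what "nominated" means

`rankRegions()` orders regions by decreasing $|A|$, breaking ties by the
declared region order (a stable sort, for reproducibility), and flags the
top region as the nominated discriminator. `classifyAndMap()` runs the whole
chain for each requested group pair and juxtaposes $|A|$ across comparisons,
which is the tabular equivalent of plotting one comparison's $|A|$ against
the other's.

A caution that the synthetic studies make quantitative: with n = 5 animals
per group and 22 regions, single-region nomination is a noisy statistic.
A planted effect of 2 within-group SD is nominated in roughly half of
replicates (and z-scoring over a cohort that includes the shifted group
compresses the planted region's apparent separation further); the null rate
for any fixed region stays at chance (~1/22). Nomination rates approach 1
only for larger effects, more animals, or fewer candidate regions.

## Anteroposterior binning

The insular cortex spans roughly +2.5 to −1.0 mm AP relative to bregma.
`binAPDistribution()` histograms per-cell AP coordinates into 10 equal
0.35 mm bins by default, per treatment group. Bins cover
`(lower, upper]` so the anterior IC aggregate is exactly the interval
(+1.45, +2.50]; the most posterior bin additionally includes its lower edge
so the documented span is fully covered. Cells outside the edge span are
counted in a reported overflow bucket, never dropped, and bin counts plus
overflow always add up to the number of cells. Bins are labelled
aIC/mIC/pIC by midpoint; only the aIC boundary (+1.45 mm) is anatomically
fixed, the mIC/pIC split at +0.40 mm is a package convention for reporting.

# Photometry preprocessing

## airPLS baseline estimation

Fluorescence traces drift (bleaching, slow hemodynamics) under positive
calcium transients. airPLS estimates the drift by iterating a weighted
Whittaker smoother,

$$(\mathrm{diag}(w) + \lambda D^\top D)\, z = w\, y,$$

with $D$ the order-2 difference operator, re-estimating weights each
iteration: samples above the current baseline get weight 0 (transients must
not pull the baseline up), samples below it get weight
$\exp(t\,|d_i| / \lVert d^-\rVert_1)$ at iteration $t$, and the end samples
are anchored. Iteration stops when the total negative-residual magnitude
falls below `ratio` (1e-3) times $\lVert y\rVert_1$, or after `maxIter`
(15). The banded sparse system is factored with the Matrix package, so a
10 min recording at 100 Hz (60,000 samples) takes milliseconds per
iteration.

**Choosing λ.** λ sets the stiffness: the smoother passes fluctuations
slower than roughly $f_c \approx f_s/(2\pi)\,\lambda^{-1/4}$. The bare
function default (λ = 1e4, the value usually quoted for the algorithm on
spectra of a few thousand points) corresponds to ~0.1 s at 100 Hz — flexible
enough to follow second-scale calcium transients into the baseline, which
would subtract the very signal being quantified. The pipeline therefore
defaults to λ = 1e10 (cutoff ≈ 0.03 Hz): second-scale transients pass
untouched while minute-scale drift is still tracked — a cubic drift lies in
the null space of the squared fourth difference that governs the smoother's
bias, so stiffness costs nothing there. On the synthetic ground truth the
evoked amplitude survives at 97.5% with λ = 1e10 (69% at 1e8), with drift
RMSE a constant ~4% of the drift range. Both λ and the termination ratio
remain exposed in the configuration.

## z-scoring and smoothing

`correctAndZscore()` subtracts the fitted baseline, optionally applies a
centered moving average (default width 0.5 s when enabled; **off** by
default so window algebra stays exact), and standardizes by the mean and SD
of the designated home-cage baseline segment. Because the constants are
taken after smoothing, the baseline segment of every returned trace has mean
0 and SD 1 to machine precision — the class validity enforces it at 1e-8. A
baseline segment with zero SD after correction is refused as degenerate
(this also covers the corner case of a trace that is constant everywhere,
where a z-score is undefined rather than zero).

## Event selection and evoked quantification

An investigation bout is *nonsequential* when its onset falls at least 10 s
(inclusive) after the end of the immediately preceding bout **in the full
log** — not the previously kept bout — and the first bout always qualifies.
The filter is idempotent: once a bout survives, its predecessor in the
filtered log ends no later than its predecessor in the full log.

The evoked response of an event is
$$\Delta z = \operatorname{mean} z[0, +3\,\mathrm{s}) -
             \operatorname{mean} z[-3\,\mathrm{s}, 0),$$
with the onset aligned to the nearest sample, the pre-window excluding the
onset sample and the post-window including it. $\Delta z$ is invariant to
adding any constant to the trace, and events whose windows are truncated by
the recording edge are skipped and counted, never zero-padded.

Session statistics are deliberately plain: per-animal per-label mean
$\Delta z$, a two-sided paired t test between the two stimulus labels
across animals, and a Spearman rank correlation (average ranks for ties,
two-sided p from the t approximation) between per-event $\Delta z$ and the
duration of the same contact. Two degenerate cases are flagged instead of
producing infinities: all-zero paired differences report t = 0, p = 1;
constant non-zero differences report a `degenerate` flag with t = NA.

# The synthetic-data module

The generators emulate the study conditions the analyses are designed for,
and their defaults are fixed once:

* **Counts**: negative binomial per region and animal (dispersion size 8,
  i.e. CV ≈ 35% at a mean of 200 cells — biological count tables are
  overdispersed), region means fixed on a log ladder from 80 to 1200 cells,
  3 groups × 5 animals × 22 regions. A group effect is planted additively on
  the mean, expressed in units of the nominal within-group SD
  $\sqrt{\mu + \mu^2/\theta}$, so "a 2 SD effect" means the same thing at
  every region scale. The paper-side analyses never see the truth; tests
  recover it through the full chain.
* **IC coordinates**: AP positions drawn from a configurable piecewise
  density over (+2.50, −1.00) mm; ML/DV uniform over plausible IC spans.
* **Photometry**: trace = 100 a.u. offset + cubic drift (peak-to-peak
  10 a.u., i.e. 10% of the signal level) + white noise (SD 0.5 a.u., 0.5% of
  the offset, typical of 100 Hz single-wavelength recordings) + planted
  transients. Transients are difference-of-exponentials kernels (rise 0.2 s,
  decay 1.0 s, peak-normalized) — a generic calcium-indicator shape — or
  rectangular steps for window-algebra tests. Amplitudes are specified in z
  units (multiples of the noise SD) so downstream z-scoring recovers them
  directly; `kernelWindowMean()` gives the exact expected $\Delta z$ of one
  planted transient in closed form. A 5 min baseline precedes the session
  and never contains transients.

What the generators deliberately do **not** emulate: photon shot noise and
hemodynamic artifacts, isosbestic reference channels, correlated
region-to-region count noise, segmentation errors, or behavioural
dependence of event timing on the signal. Passing tests therefore
demonstrate correctness of the estimators under clean, known conditions —
not robustness to every artifact of real recordings.

# Reproducibility machinery

Every generator takes a seed and restores the caller's RNG state; the
pipeline derives fixed per-stage substreams from one root seed, so a full
`runPipeline()` is byte-identical across runs (the test suite compares file
checksums). Floats are written with 17 significant digits so every CSV/TSV
dialect round-trips exactly. Problem sizes in the tests (for example 8
processed sessions for the z-scoring exactness check, 40 replicates for the
recovery property, 2000 replicates for the type-I calibration of the paired
contrast) were chosen so each property is measured with comfortable
Monte-Carlo margins while the whole suite stays interactive.

# Known limitations

* Single-region nomination at n = 5 per group is intrinsically noisy (see
  above); the package reports full rankings and |A| tables so downstream
  interpretation need not rest on the top-1 call.
* airPLS termination is relative to $\lVert y \rVert_1$, which includes the
  DC fluorescence offset; on offset-dominated traces the reweighting
  converges within one or two iterations. This matches the published
  algorithm; the stiff pipeline λ is what protects transients in that
  regime.
* The paired contrast assumes one mean $\Delta z$ per animal and label;
  unbalanced event counts are averaged within animal first, not modelled.
* The Spearman p-value uses the t approximation, adequate for the event
  counts involved (tens), not for n < 5.
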
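---
title: "First-order histogram analysis of MRI regions of interest: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{First-order histogram analysis of MRI regions of interest: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histofeat)
```

## The problem

Histogram analysis ("first-order" texture analysis) summarizes a region of
interest (ROI) in a grayscale medical image by the distribution of its
gray levels alone, ignoring spatial arrangement. It is widely used on
structural MRI to quantify tissue heterogeneity that is not visible to the
eye — for example, comparing the corpus callosum of a patient cohort
against healthy controls on midsagittal T1-weighted slices. `histofeat`
implements the complete workflow: feature extraction from image + mask
pairs, two-group statistical comparison, and a synthetic phantom generator
that makes the whole pipeline testable without any patient data.

## The feature set

Given the multiset of ROI gray levels $x_1, \dots, x_n$, with population
central moments $m_k = \frac{1}{n}\sum_i (x_i - \bar{x})^k$, the package
computes fourteen features:

* **mean, minimum, maximum, median** — order/location statistics; the
  median of an even-length sample is the midpoint of the two central order
  statistics.
* **variance, SD** — $m_2$ and $\sqrt{m_2}$ (population convention,
  divide-by-$n$).
* **skewness** $= m_3 / m_2^{3/2}$ — right tail positive. (Some clinical
  texts describe the sign verbally the other way around; the standard
  moment convention is used here.)
* **kurtosis** $= m_4 / m_2^2$ — Pearson (non-excess) convention, so a
  Gaussian gives 3. This convention is forced by the interpretation
  "a bell curve has kurtosis 3". The bound
  $\mathrm{kurtosis} \ge \mathrm{skewness}^2 + 1$ holds for every
  distribution and is used for feasibility checks throughout.
* **entropy** $H = -\sum_i p_i \log_2 p_i$ (bits) and **uniformity**
  (energy) $U = \sum_i p_i^2$, where $p_i$ are normalized histogram bin
  probabilities. $H = 0$ and $U = 1$ exactly when the ROI is constant.
* **size %L / %U / %M** — the percentage of ROI pixels below
  $\bar{x} - s$, above $\bar{x} + s$, and between. For discrete pixels the
  "area under the curve" is a pixel proportion; pixels exactly on a
  threshold count as middle, which fixes a deterministic tie-break and
  guarantees the three always sum to 100.
* **area** — member-pixel count $\times$ row spacing $\times$ column
  spacing / 100, in cm².

### Binning

Entropy and uniformity — and only they — depend on how the histogram is
binned. The default is **unit binning**: one bin per integer gray level
spanning $[\lfloor\min\rfloor, \lfloor\max\rfloor + 1)$, the natural
choice for integer-valued scanner data. `binning_count(k)` and
`binning_width(w)` are available because published values are sensitive to
this choice: entropies near 6 bits are consistent with a few hundred
occupied gray levels, but no single binning reproduces every published
entropy/uniformity pair simultaneously, so uniformity comparisons across
software packages should be treated as qualitative. All moment-based
features are binning-free.

### Degenerate input

A constant-intensity ROI has no defined shape moments. The package reports
entropy 0, uniformity 1 and sizes (0, 0, 100) — their analytic limits —
and `NA` with a `degenerate` flag for skewness/kurtosis rather than
fabricating a value.

## Cohort comparison

`compare_cohorts()` mirrors standard clinical-statistics practice: for
each feature, each group is screened for normality with a one-sample
Kolmogorov–Smirnov test against a normal with the sample's own mean and
SD (asymptotic p-value; the Lilliefors correction for estimated
parameters is available via `ks_method = "lilliefors"`). If both groups
pass (p > 0.05) the groups are compared with the **pooled-variance
Student's t-test** (df $= n_1 + n_2 - 2$); otherwise with the
**Mann–Whitney U test** (midrank ties; exact enumeration for small untied
samples, normal approximation with tie and continuity corrections
otherwise). All p-values are two-tailed; no multiple-testing correction is
applied — the comparison table mirrors the single-table reporting style of
the clinical literature and says so in its footer. A Welch t variant is
available behind `welch = TRUE`; the pooled form is the default because it
is the common statistics-package default and is computable from printed
group summaries.

`summary_student_t()` computes the same pooled t directly from
$(n, \bar{x}, s)$ per group — sample SD, divide-by-$(n-1)$ — which allows
published "mean ± SD" tables to be re-tested without raw data:

```{r}
summary_student_t(19, 33.79, 9.97, 20, 32.745, 8.50)  # a null age difference
```

Because the test selection is data-driven per feature and per cohort, the
test that produced any given published p-value is generally not
recoverable; the comparison table therefore records `test_used` for every
row.

## The phantom generator

No public image data accompany the study conditions this package targets,
so validation uses synthetic subjects. The generator's premise: since
first-order features are invariant to spatial arrangement, an ROI is
fully characterized (for this purpose) by the *distribution* of its gray
levels, and i.i.d. sampling from a family with controlled moments is a
sufficient data model.

### Study conditions

The default `cohort_spec()` encodes the emulated study: 20 controls vs 19
cases, one midsagittal slice per subject on a 256 × 256 grid with
0.9375 mm pixels (240 mm field of view / 256 matrix). Each subject's ROI
parameters are drawn from between-subject distributions whose means/SDs
are the published per-group values: ROI mean 336.56 ± 147.21 (control) vs
476.10 ± 46.09 (case), within-ROI SD 31.26 ± 13.76 vs 75.49 ± 11.47,
skewness −2.50 ± 0.46 vs −2.58 ± 0.47, kurtosis 13.80 ± 4.34 vs
10.34 ± 2.89, area 5.64 ± 0.69 vs 6.07 ± 0.94 cm².

Distributional choices for the subject-level draws, made once:

* ROI mean and shape parameters: normal draws (the published table
  reports mean ± SD; normality is the minimal assumption), with the mean
  clamped inside the physical gray-level range.
* Within-ROI SD and area: **moment-matched lognormal** draws. These are
  positive scale parameters; a lognormal avoids truncation artifacts that
  a clipped normal would introduce at small values.
* Kurtosis is kept at or above $1.3\,(\mathrm{skewness}^2 + 1)$. As the
  moment boundary $\mathrm{skewness}^2 + 1$ is approached, the *only*
  distributions with those moments degenerate toward two-point spikes —
  which tissue gray-level histograms never resemble. The 1.3 margin keeps
  every generated subject's distribution smooth while leaving the typical
  draws (ratio 1.3–1.9 at the table's means) untouched.
* Background tissue (never described in the emulated study, hence a free
  parameter): Gaussian, mean 60, SD 20 gray levels, clipped at 0 —
  dark relative to every ROI, as white matter surroundings are on
  T1-weighted midsagittal slices after windowing.

### Matching four moments

`gaussian` subjects need only mean/SD. For the skewed regime the package
solves a **two-component Gaussian mixture** whose first four moments match
the targets: with the first two moments enforced exactly by
parameterization, a Nelder–Mead search over (weight, component mean,
component SD) matches skewness and kurtosis to residuals near $10^{-13}$.
Solutions are cached and re-used as warm starts for nearby targets. The
`skew_normal` family uses the Azzalini skew-normal where its skewness
range (|skewness| < 0.9953) suffices and otherwise delegates to the
mixture solver — published per-subject skewness near −2.5 is far outside
the skew-normal range, so the mixture is the workhorse family.

Gray levels are physically bounded, so samples are clipped to
`[value_floor, value_cap]` (defaults 0 and 1023). Moment targets are
interpreted **post-clipping**: closed-form truncated-normal moment algebra
(point masses at the bounds plus interior truncated moments, via the
standard recursion) gives the clipped mixture's moments analytically, and
when the clipped mass exceeds $5 \times 10^{-3}$ — the level at which the
bias would rival sampling noise at ROI-sized $n$ — the five mixture
parameters are re-solved against the clipped moments directly. Some
combinations near the floor (a low ROI mean with strong negative target
skewness) are mathematically unreachable inside the bounds; the solver is
then weighted best-effort, prioritizing mean and SD over the shape
moments.

### ROI geometry

The mask is a parametric C-shaped arc band (a dome opening downward,
~220° span, thickness ≈ 0.45 × radius) resembling a midsagittal corpus
callosum. Rather than rasterizing and hoping, the mask takes exactly
$k = \mathrm{round}(\mathrm{area} / \mathrm{pixel\ footprint})$ grid
pixels nearest the arc centerline (in physical mm, so anisotropic pixels
stay round), which hits the target area to well under 2% at realistic
areas and degrades gracefully to a compact blob — ultimately a single
pixel — for tiny targets. The seed jitters the center and orientation.
Only the pixel count and the intensity distribution matter downstream;
the shape is cosmetic realism, not anatomy.

### Determinism

Every generator is a pure function of (spec, seed). Cohort members get
seeds derived from the cohort seed by a multiplicative-congruential step
modulo $2^{31}-1$, so manifests, images and downstream CSVs are
byte-identical across runs with the same configuration.

## What the phantoms do and do not show

Passing the phantom-based tests demonstrates that the pipeline recovers
known distributional differences at the study's sample sizes, that the
feature definitions are correct against independent oracles, and that the
test-selection procedure holds its nominal type-I error (per-feature
false-positive rate within [0.025, 0.08] over 500 null cohorts at
α = 0.05). It does **not** validate anything about real scanner data:
phantoms have i.i.d. ROI pixels (no spatial autocorrelation, no bias
field, no Rician noise floor, no partial-volume gradient at the ROI rim),
and their between-subject parameter distributions are idealized normals/
lognormals. Findings on real cohorts additionally depend on segmentation
quality and scanner intensity scaling, neither of which a phantom
exercises.

## Problem sizes and numerical choices

The validation suite uses $10^6$-sample draws for distributional limits
(Gaussian kurtosis 3.00 ± 0.02, skewness 0 ± 0.01, %M 68.27 ± 0.2), 200
replicate cohorts for recovery of the group separation, and 500 null
cohorts for type-I calibration — sizes at which binomial noise is well
inside the asserted bands. Mixture solves use Nelder–Mead with multi-start
(residual tolerance $10^{-12}$ standardized); KS p-values are asymptotic;
the Mann–Whitney switches from exact enumeration to the corrected normal
approximation above a combined n of 12 or in the presence of ties,
matching `wilcox.test`.

## A complete run

```{r, eval = FALSE}
report <- run_study(list(out_dir = "phantom_run", seed = 1))
report$comparison
```

The same pipeline is scriptable from a shell via the installed
`exec/histofeat` entry point (`simulate`, `extract`, `compare`, `run`
subcommands), which is a thin wrapper over the functions shown above.

## Known limitations

* 2-D only: a NIfTI volume must be sliced explicitly; DICOM series are
  not stitched.
* The DICOM reader covers uncompressed little-endian single-frame
  monochrome objects — sufficient for single-slice exports, not a general
  DICOM implementation.
* Uniformity (and to a lesser degree entropy) is binning-convention
  dependent; cross-software comparisons need an agreed binning.
* The mixture family cannot represent moment targets exactly on the
  boundary $\mathrm{kurtosis} = \mathrm{skewness}^2 + 1$ except as
  near-two-point distributions, and near-floor targets may be unreachable
  post-clipping (reported best-effort).
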
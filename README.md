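# histofeat

First-order histogram texture analysis of 2-D regions of interest (ROIs)
in grayscale medical images, with two-group cohort comparison and a
synthetic phantom generator for end-to-end validation.

## Who this is for

Researchers quantifying tissue heterogeneity on structural MRI — for
example comparing the corpus callosum of a patient group against healthy
controls on midsagittal T1-weighted slices — who need the standard
first-order ("histogram analysis") feature set, the accompanying clinical
statistics, and a way to validate the whole pipeline without access to
patient scans.

## What it computes

For the gray levels $x_1,\dots,x_n$ inside an ROI, with population
central moments $m_k = \frac1n \sum_i (x_i - \bar x)^k$:

| feature | definition |
|---|---|
| mean, min, max, median | order/location statistics |
| variance, SD | $m_2$, $\sqrt{m_2}$ |
| skewness | $m_3 / m_2^{3/2}$ (right tail positive) |
| kurtosis | $m_4 / m_2^{2}$ (Pearson: Gaussian = 3) |
| entropy | $-\sum_i p_i \log_2 p_i$ bits over histogram bins |
| uniformity | $\sum_i p_i^2$ (energy) |
| size %L / %U / %M | % of pixels below $\bar x - s$ / above $\bar x + s$ / between (sum = 100) |
| area | pixel count × pixel footprint, cm² |

Cohorts are compared feature by feature: a one-sample Kolmogorov–Smirnov
normality screen per group selects either the pooled-variance Student's
t-test or the Mann–Whitney U test; all p-values are two-tailed.
`summary_student_t()` additionally re-tests published "mean ± SD" tables
without raw data.

Inputs: single-frame DICOM, NIfTI-1 (with explicit slice selection for
volumes), or 16-bit PNG/TIFF with a JSON pixel-spacing sidecar, plus
binary ROI masks and a CSV manifest. Pixel spacing is always read from
metadata, never defaulted.

## Worked example

Extract features from a tiny in-memory image:

```r
library(histofeat)
img <- image_slice(matrix(c(5, 5, 7, 9), 2, 2), spacing = c(1, 1))
msk <- roi_mask(matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2))
extract_features(img, msk)
#> first-order features (3 ROI pixels)
#>           mean             sd            min            max         median
#>         5.6667         0.9428         5.0000         7.0000         5.0000
#>       variance        entropy size_pct_lower size_pct_upper  size_pct_mean
#>         0.8889         0.9183         0.0000        33.3333        66.6667
#>       kurtosis       skewness     uniformity       area_cm2
#>         1.5000         0.7071         0.5556         0.0300
```

The ROI is `{5, 5, 7}`: mean 5.67 and population SD 0.94 gray levels;
entropy 0.918 bits and uniformity 0.556 for a two-bin histogram with
probabilities (2/3, 1/3); the single pixel at 7 lies above mean + 1 SD,
so size %U = 33.3 and %L + %U + %M = 100; three 1 mm pixels give
0.03 cm².

Simulate a full phantom study at the default conditions (20 controls vs
19 cases, ROI distributions matching a published cohort table) and
compare the groups:

```r
tab <- cohort_features(cohort_spec(seed = 1))
compare_cohorts(tab)
#> Two-group feature comparison (alpha = 0.05, two-tailed)
#>             feature          control              case         test        p sig
#>                Mean  343.59 ± 139.75    470.55 ± 44.30    student_t 5.52e-04   *
#>  Standard deviation    29.57 ± 12.75     71.96 ± 12.51    student_t 1.29e-12   *
#>             Minimum  170.65 ± 134.08     62.37 ± 67.63    student_t 3.16e-03   *
#>             Maximum  437.50 ± 148.60   640.89 ± 141.00    student_t 9.39e-05   *
#>              Median  348.05 ± 140.42    485.50 ± 43.75    student_t 2.30e-04   *
#>            Variance 1029.12 ± 923.12 5326.63 ± 1961.54    student_t 1.23e-10   *
#>             Entropy      5.89 ± 0.71       6.80 ± 0.92 mann_whitney 4.35e-05   *
#>         Size %Lower      9.58 ± 2.87       9.36 ± 1.40    student_t 7.65e-01
#>         Size %Upper      6.36 ± 4.70       3.74 ± 3.55 mann_whitney 7.44e-02
#>          Size %Mean     84.07 ± 6.43      86.90 ± 3.92    student_t 1.07e-01
#>            Kurtosis     12.00 ± 4.36      11.72 ± 2.54    student_t 8.15e-01
#>            Skewness     -2.04 ± 0.99      -2.55 ± 0.56    student_t 5.30e-02
#>          Uniformity      0.03 ± 0.02       0.02 ± 0.03 mann_whitney 9.96e-05   *
#>          Area (cm2)      5.51 ± 0.44       6.00 ± 0.71    student_t 1.19e-02   *
#> KS screen selects pooled t (both groups normal) or Mann-Whitney U.
#> No multiple-testing correction applied.
```

The case group's higher ROI mean, within-ROI SD and entropy — the
signature the generator was parameterized with — come out strongly
significant at n = 20 vs 19.

The same pipeline runs from a shell via the installed `exec/histofeat`
script:

```sh
histofeat run --out phantom_run --seed 1          # simulate -> extract -> compare
histofeat extract --manifest m.csv --binning unit --out features.csv
histofeat compare --features features.csv --out comparison.csv
```

See `vignettes/histogram-features.Rmd` for the model, the phantom
generator's assumptions, and numerical design choices.

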
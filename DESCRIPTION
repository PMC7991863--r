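Package: histofeat
Title: First-Order Histogram Features and Cohort Comparison for MRI
    Regions of Interest
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Histogram-based texture analysis of 2-D regions of interest in
    grayscale medical images. Extracts the fourteen first-order features of
    an ROI gray-level distribution (mean, standard deviation, minimum,
    maximum, median, variance, Shannon entropy, uniformity, skewness,
    Pearson kurtosis, size percentages below/above/within one standard
    deviation of the mean, and physical area), reads single-frame DICOM,
    NIfTI-1 and 16-bit raster inputs with physical pixel spacing, compares
    two cohorts feature by feature using a Kolmogorov-Smirnov normality
    screen followed by a pooled Student's t-test or Mann-Whitney U test,
    and generates moment-matched synthetic phantom cohorts (including a
    four-moment two-component Gaussian mixture sampler) for end-to-end
    validation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    nortest,
    png,
    RNifti,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    e1071,
    EBImage,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
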
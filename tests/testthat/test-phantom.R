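test_that("distribution specs validate their invariants", {
  expect_s3_class(dist_spec("gaussian", mean = 300, sd = 40), "dist_spec")
  expect_error(dist_spec("gaussian", mean = 300, sd = 0), "sd must be > 0")
  expect_error(dist_spec("gaussian", mean = 2000, sd = 40, value_cap = 1023),
               "strictly inside")
  expect_error(dist_spec("gaussian", mean = 300, sd = 40, skewness = -2),
               "no skewness")
  expect_error(dist_spec("skew_normal", mean = 300, sd = 40), "needs a target skewness")
  expect_error(dist_spec("two_component_mixture", mean = 300, sd = 40,
                         skewness = -2.5), "both skewness and kurtosis")
  # kurtosis must exceed skewness^2 + 1
  expect_error(dist_spec("two_component_mixture", mean = 300, sd = 40,
                         skewness = -2.5, kurtosis = 7), "infeasible")
})

test_that("sampled intensities converge to the target moments", {
  # gaussian: the case-group parameters
  x <- sample_intensities(dist_spec("gaussian", mean = 476.10, sd = 46.09),
                          n = 1e5, seed = 101)
  expect_lt(abs(mean(x) - 476.10), 1.0)
  expect_lt(abs(sd(x) - 46.09), 1.0)

  # skewed family at the cohort-table regime
  sk <- dist_spec("skew_normal", mean = 400, sd = 50, skewness = -2.5)
  y <- sample_intensities(sk, n = 1e6, seed = 102)
  expect_lt(abs(skewness(y) - (-2.5)), 0.1)
  expect_lt(abs(mean(y) - 400), 1)

  # mild skewness uses the skew-normal itself
  z <- sample_intensities(dist_spec("skew_normal", mean = 400, sd = 50,
                                    skewness = 0.7), n = 1e6, seed = 103)
  expect_lt(abs(skewness(z) - 0.7), 0.05)

  # four-moment mixture
  mx <- dist_spec("two_component_mixture", mean = 336.56, sd = 31.26,
                  skewness = -2.50, kurtosis = 13.80)
  w <- sample_intensities(mx, n = 1e6, seed = 104)
  expect_lt(abs(mean(w) - 336.56), 1)
  expect_lt(abs(sd(w) - 31.26), 1)
  expect_lt(abs(skewness(w) - (-2.50)), 0.1)
  expect_lt(abs(kurtosis(w) - 13.80), 0.5)

  # single draw stays inside the physical bounds
  one <- sample_intensities(mx, n = 1, seed = 105)
  expect_length(one, 1)
  expect_true(one >= 0 && one <= 1023)

  # all values clipped to [floor, cap]
  lowcap <- dist_spec("gaussian", mean = 500, sd = 200, value_cap = 600)
  v <- sample_intensities(lowcap, n = 1e4, seed = 106)
  expect_true(all(v >= 0 & v <= 600))

  # determinism
  expect_identical(sample_intensities(mx, 1000, seed = 7),
                   sample_intensities(mx, 1000, seed = 7))
})

test_that("clipped-normal moment algebra matches Monte Carlo", {
  w <- c(0.2, 0.8); mu <- c(80, 350); sg <- c(90, 40)
  sh <- histofeat:::mixture_clipped_shape(w, mu, sg, 0, 400)
  x <- withr::with_seed(8, {
    comp <- sample.int(2, 4e5, TRUE, prob = w)
    pmin(pmax(rnorm(4e5, mu[comp], sg[comp]), 0), 400)
  })
  expect_equal(unname(sh["mean"]), mean(x), tolerance = 0.005)
  expect_equal(unname(sh["sd"]), sd(x), tolerance = 0.01)
  expect_equal(unname(sh["skewness"]), skewness(x), tolerance = 0.05)
  expect_equal(unname(sh["kurtosis"]), kurtosis(x), tolerance = 0.05)
})

test_that("generated ROI masks hit the target area as one connected blob", {
  msk <- generate_roi_mask(5.64, seed = 1)
  n_px <- sum(msk$membership)
  area <- n_px * 0.9375^2 / 100
  expect_lt(abs(area - 5.64) / 5.64, 0.02)
  expect_equal(n_px, round(5.64 * 100 / 0.9375^2))  # 642 pixels
  expect_equal(histofeat:::count_components(msk$membership), 1L)

  # independent connectivity oracle
  skip_if_not_installed("EBImage")
  lab <- EBImage::bwlabel(msk$membership)
  expect_equal(max(lab), 1)
})

test_that("mask generation is deterministic and handles extremes", {
  a <- generate_roi_mask(6.07, seed = 33)
  b <- generate_roi_mask(6.07, seed = 33)
  expect_identical(a$membership, b$membership)
  expect_false(identical(a$membership, generate_roi_mask(6.07, seed = 34)$membership))

  # exactly one pixel when the target equals one pixel's area
  one <- generate_roi_mask(0.01, grid_size = c(64, 64), pixel_spacing_mm = c(1, 1),
                           seed = 2)
  expect_equal(sum(one$membership), 1L)

  expect_error(generate_roi_mask(0, seed = 1), "below one pixel")
  expect_error(generate_roi_mask(1e5, seed = 1), "grid has")
})

test_that("a generated subject round-trips its moments through extraction", {
  ds <- dist_spec("two_component_mixture", mean = 476.10, sd = 75.49,
                  skewness = -2.58, kurtosis = 10.34)
  ss <- subject_spec("s1", "case", ds, roi_area_cm2 = 6.07)
  subj <- generate_subject(ss, seed = 77)
  fv <- extract_features(subj$image, subj$mask)
  n <- fv$n_pixels
  # CLT tolerances from n ROI pixels (generous: 4 sigma)
  expect_lt(abs(fv$mean - 476.10), 4 * 75.49 / sqrt(n))
  expect_lt(abs(fv$sd - 75.49) / 75.49, 0.2)
  expect_lt(abs(fv$area_cm2 - 6.07) / 6.07, 0.02)
  expect_lt(abs(fv$skewness - (-2.58)), 1.0)

  # gaussian spec: kurtosis near 3
  gs <- subject_spec("g1", "control",
                     dist_spec("gaussian", mean = 400, sd = 40),
                     roi_area_cm2 = 20)
  gsub <- generate_subject(gs, seed = 78)
  gfv <- extract_features(gsub$image, gsub$mask)
  expect_lt(abs(gfv$kurtosis - 3), 0.5)

  # identical seeds give bit-identical subjects
  again <- generate_subject(ss, seed = 77)
  expect_identical(subj$image$pixels, again$image$pixels)
  expect_identical(subj$mask$membership, again$mask$membership)

  # background is distinctly low-intensity
  bg <- subj$image$pixels[!subj$mask$membership]
  expect_lt(mean(bg), 150)
})

test_that("cohort generation writes a valid, reproducible manifest", {
  spec <- cohort_spec(n_control = 3, n_case = 2, seed = 5,
                      grid_size = c(64, 64))
  d1 <- withr::local_tempdir()
  manifest_path <- generate_cohort(spec, d1)
  man <- read.csv(manifest_path)
  expect_equal(nrow(man), 5)
  expect_equal(sum(man$group == "control"), 3)
  expect_true(all(file.exists(file.path(d1, man$image_path))))
  expect_true(all(file.exists(file.path(d1, man$mask_path))))

  # the manifest feeds the extract stage
  tab <- extract_cohort_features(manifest_path)
  expect_equal(nrow(tab), 5)
  expect_true(all(is.finite(tab$mean)))

  # same spec + seed: identical files
  d2 <- withr::local_tempdir()
  generate_cohort(spec, d2)
  f1 <- file.path(d1, man$image_path[1])
  f2 <- file.path(d2, man$image_path[1])
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  expect_error(cohort_spec(n_case = 0), "at least 2")
})

test_that("cohort_features matches the defaults of the study design", {
  tab <- cohort_features(cohort_spec(seed = 12))
  expect_equal(nrow(tab), 39)
  expect_equal(sum(tab$group == "control"), 20)
  expect_equal(sum(tab$group == "case"), 19)
  expect_named(tab, c("subject_id", "group", histofeat:::feature_columns()))
  # group-level feature means sit near the generating conditions
  ctrl <- tab[tab$group == "control", ]
  case <- tab[tab$group == "case", ]
  expect_lt(abs(mean(ctrl$mean) - 336.56), 4 * 147.21 / sqrt(20))
  expect_lt(abs(mean(case$mean) - 476.10), 4 * 46.09 / sqrt(19))
  expect_lt(abs(mean(case$sd) - 75.49), 4 * 11.47 / sqrt(19) + 3)
  expect_lt(abs(mean(ctrl$area_cm2) - 5.64), 4 * 0.69 / sqrt(20))
})
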
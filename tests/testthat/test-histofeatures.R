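test_that("basic statistics match hand-computed values", {
  bs <- basic_stats(c(1, 2, 3, 4))
  expect_equal(bs$mean, 2.5)
  expect_equal(bs$variance, 1.25)
  expect_equal(bs$sd, sqrt(1.25))
  expect_equal(bs$median, 2.5)
  expect_equal(bs$min, 1)
  expect_equal(bs$max, 4)

  const <- basic_stats(rep(7, 10))
  expect_equal(const$sd, 0)
  expect_equal(const$variance, 0)
  expect_true(all(c(const$mean, const$median, const$min, const$max) == 7))

  # variance is exactly sd^2 on arbitrary input
  x <- c(0.3, 9.1, 4.4, 4.4, 2.0)
  bs <- basic_stats(x)
  expect_identical(bs$variance, bs$sd^2)
})

test_that("unit binning spans integer gray levels and conserves counts", {
  h <- build_histogram(c(5, 5, 7))
  expect_equal(h$bin_edges, 5:8)
  expect_equal(h$counts, c(2, 0, 1))
  expect_equal(sum(h$counts), h$n_pixels)

  # constant input: one occupied bin
  hc <- build_histogram(rep(42, 9))
  expect_equal(sum(hc$counts > 0), 1L)

  # fixed-count binning conserves n for continuous data
  x <- withr::with_seed(11, rnorm(1e4, 100, 10))
  hk <- build_histogram(x, binning_count(256))
  expect_equal(sum(hk$counts), 1e4L)
  expect_length(hk$counts, 256L)

  hw <- build_histogram(x, "width:2.5")
  expect_equal(sum(hw$counts), 1e4L)
  expect_equal(diff(hw$bin_edges)[1], 2.5)

  expect_error(binning_count(1), "integer >= 2")
  expect_error(binning_width(0), "> 0")
  expect_error(parse_binning("bogus"), "unknown binning")
})

test_that("entropy and uniformity take their analytic values", {
  h1 <- build_histogram(rep(3, 5))
  expect_identical(hist_entropy(h1), 0)
  expect_identical(hist_uniformity(h1), 1)

  # uniform mass over 64 unit bins -> 6 bits, uniformity 1/64
  h64 <- build_histogram(rep(0:63, each = 4))
  expect_equal(hist_entropy(h64), 6)
  expect_equal(hist_uniformity(h64), 1 / 64)

  # counts [1, 1, 2]
  h <- build_histogram(c(1, 2, 3, 3))
  expect_equal(h$counts, c(1, 1, 2))
  expect_equal(hist_entropy(h), 1.5)
  expect_equal(hist_uniformity(h), 0.375)
})

test_that("entropy decreases and uniformity increases as mass concentrates", {
  # fixed support of 8 bins; progressively concentrate mass
  make_px <- function(counts) rep(seq_along(counts), counts)
  profiles <- list(c(4, 4, 4, 4, 4, 4, 4, 4),
                   c(8, 6, 4, 4, 4, 2, 2, 2),
                   c(14, 8, 4, 2, 2, 1, 0, 1),
                   c(24, 4, 1, 1, 1, 0, 0, 1))
  H <- vapply(profiles, function(ct) hist_entropy(build_histogram(make_px(ct))), 0)
  U <- vapply(profiles, function(ct) hist_uniformity(build_histogram(make_px(ct))), 0)
  expect_true(all(diff(H) < 0))
  expect_true(all(diff(U) > 0))
})

test_that("skewness and kurtosis follow the moment conventions", {
  expect_equal(skewness(c(1, 2, 3)), 0)
  expect_equal(skewness(c(0, 0, 0, 1)), 2 / sqrt(3), tolerance = 1e-12) # +1.1547
  expect_equal(kurtosis(c(0, 0, 0, 1)), 7 / 3, tolerance = 1e-12)      # 2.3333
  expect_equal(kurtosis(rep(c(-1, 1), 50)), 1)                         # two-point min
  expect_error(skewness(rep(5, 4)), "undefined")
  expect_error(kurtosis(rep(5, 4)), "undefined")

  # reflection flips the sign of skewness
  x <- c(0, 0, 1, 5, 9)
  expect_equal(skewness(2 * mean(x) - x), -skewness(x))

  # cross-check against an independent implementation
  skip_if_not_installed("e1071")
  y <- withr::with_seed(3, rgamma(500, shape = 2))
  expect_equal(skewness(y), e1071::skewness(y, type = 1), tolerance = 1e-12)
  expect_equal(kurtosis(y), e1071::kurtosis(y, type = 1) + 3, tolerance = 1e-12)
})

test_that("size percentages partition the ROI and sum to 100", {
  sp <- size_percentages(rep(4, 10))
  expect_equal(unlist(sp), c(lower = 0, upper = 0, mid = 100))

  x <- withr::with_seed(5, rnorm(2e5))
  sp <- size_percentages(x)
  expect_equal(sp$mid, 100 * (pnorm(1) - pnorm(-1)), tolerance = 0.02)
  expect_equal(sp$lower, 100 * pnorm(-1), tolerance = 0.05)

  # boundary pixels count as middle
  b <- c(0, 0, 10, 10)  # sd = 5, thresholds exactly at 0 and 10
  sp <- size_percentages(b)
  expect_equal(sp$mid, 100)
})

test_that("roi_area converts pixel counts through the spacing", {
  m <- matrix(FALSE, 30, 30)
  m[1:2, 1:5] <- TRUE
  expect_equal(roi_area(m, c(1, 1)), 0.1)
  expect_equal(roi_area(m, c(2, 2)), 0.4)        # doubling spacing: x4
  m1 <- matrix(c(TRUE, FALSE), 1, 2)
  expect_equal(roi_area(m1, c(1, 1)), 0.01)
  # 642 pixels at the default spacing sit near the control-group area
  big <- matrix(FALSE, 256, 256); big[seq_len(642)] <- TRUE
  expect_equal(roi_area(big, c(0.9375, 0.9375)), 642 * 0.87890625 / 100)
  expect_error(roi_area(m, c(0, 1)), "spacing")
})

test_that("extract_roi_pixels returns member intensities with multiplicity", {
  img <- image_slice(matrix(c(1, 3, 2, 4), 2, 2), spacing = c(1, 1)) # cols: (1,3),(2,4)
  msk <- roi_mask(matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2))
  expect_setequal(extract_roi_pixels(img, msk), c(1, 2, 4))
  full <- roi_mask(matrix(TRUE, 2, 2))
  expect_setequal(extract_roi_pixels(img, full), c(1, 2, 3, 4))
  expect_error(extract_roi_pixels(img, roi_mask(matrix(TRUE, 3, 2))), "dimensions differ")
  tiny <- roi_mask(matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2))
  expect_error(extract_roi_pixels(img, tiny), "at least 3")
})

test_that("extract_features composes the full vector and handles degeneracy", {
  # 3-pixel worked example {5, 5, 7}
  img <- image_slice(matrix(c(5, 5, 7, 99), 2, 2), spacing = c(1, 1))
  msk <- roi_mask(matrix(c(1, 1, 1, 0), 2, 2))
  fv <- extract_features(img, msk)
  expect_equal(fv$mean, 17 / 3)
  expect_equal(fv$variance, mean((c(5, 5, 7) - 17 / 3)^2))
  expect_equal(fv$median, 5)
  expect_equal(fv$entropy, -(2 / 3) * log2(2 / 3) - (1 / 3) * log2(1 / 3))
  expect_equal(fv$uniformity, (2 / 3)^2 + (1 / 3)^2)
  expect_equal(fv$area_cm2, 0.03)
  expect_equal(fv$size_pct_lower + fv$size_pct_upper + fv$size_pct_mean, 100)

  # constant ROI: limit values, undefined moments flagged
  cimg <- image_slice(matrix(8, 3, 3), spacing = c(1, 1))
  cfv <- extract_features(cimg, roi_mask(matrix(TRUE, 3, 3)))
  expect_true(cfv$degenerate)
  expect_identical(cfv$entropy, 0)
  expect_identical(cfv$uniformity, 1)
  expect_equal(c(cfv$size_pct_lower, cfv$size_pct_upper, cfv$size_pct_mean),
               c(0, 0, 100))
  expect_true(is.na(cfv$skewness) && is.na(cfv$kurtosis))
})

test_that("features are invariant to spatial shuffling of ROI pixels", {
  withr::with_seed(21, {
    px <- round(rnorm(200, 300, 40))
    for (rep in 1:3) {
      perm <- sample(200)
      img1 <- image_slice(matrix(px, 10, 20), spacing = c(1, 1))
      img2 <- image_slice(matrix(px[perm], 10, 20), spacing = c(1, 1))
      full <- roi_mask(matrix(TRUE, 10, 20))
      f1 <- as.data.frame(extract_features(img1, full))
      f2 <- as.data.frame(extract_features(img2, full))
      expect_equal(f1, f2)
    }
  })
})

test_that("every feature agrees with the brute-force oracle on random inputs", {
  withr::with_seed(99, {
    for (i in 1:40) {
      n <- sample(3:50, 1)
      px <- switch(1 + i %% 4,
        round(runif(n, 0, 800)),          # integers
        rnorm(n, 300, 45),                # continuous
        rpois(n, 12),                     # small discrete, many ties
        round(rnorm(n, 500, 2)))          # near-constant
      if (length(unique(px)) == 1L) px[1] <- px[1] + 1
      expect_feature_match(px)
    }
  })
})
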
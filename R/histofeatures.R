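## First-order histogram features of an ROI: the computational core.
## All features depend only on the multiset of ROI gray levels (plus pixel
## spacing for the area), never on spatial arrangement.

#' Extract the ROI pixel values from an image
#'
#' Returns exactly the intensities at mask-member positions, multiplicity
#' preserved. Order follows column-major traversal of the grid; every
#' downstream feature is permutation-invariant so the order is immaterial.
#'
#' @param image an [image_slice].
#' @param mask an [roi_mask] congruent with `image`.
#' @return Numeric vector of gray-level values, one per member pixel.
#' @export
extract_roi_pixels <- function(image, mask) {
  image <- as_image_slice(image)
  mask <- as_roi_mask(mask)
  if (!identical(dim(image$pixels), dim(mask$membership))) {
    stop(sprintf("image (%s) and mask (%s) dimensions differ",
                 paste(dim(image$pixels), collapse = "x"),
                 paste(dim(mask$membership), collapse = "x")), call. = FALSE)
  }
  px <- image$pixels[mask$membership]
  if (length(px) < 3L) {
    stop(sprintf("ROI has %d pixels; at least 3 required", length(px)),
         call. = FALSE)
  }
  px
}

#' Histogram binning configurations
#'
#' `binning_unit()` uses one bin per integer gray level spanning
#' \code{[floor(min), floor(max)+1)}; `binning_count(k)` uses `k` equal-width
#' bins over the data range; `binning_width(w)` uses bins of width `w`
#' anchored at the minimum. The CLI string forms `"unit"`, `"count:<k>"` and
#' `"width:<w>"` are accepted wherever a binning is expected.
#'
#' @param k number of bins (integer, >= 2).
#' @param w bin width in gray levels (> 0).
#' @return A binning specification object.
#' @export
binning_unit <- function() structure(list(mode = "unit"), class = "histo_binning")

#' @rdname binning_unit
#' @export
binning_count <- function(k) {
  k <- as.integer(k)
  if (is.na(k) || k < 2L) stop("bin count must be an integer >= 2", call. = FALSE)
  structure(list(mode = "count", k = k), class = "histo_binning")
}

#' @rdname binning_unit
#' @export
binning_width <- function(w) {
  w <- as.numeric(w)
  if (is.na(w) || w <= 0) stop("bin width must be > 0", call. = FALSE)
  structure(list(mode = "width", w = w), class = "histo_binning")
}

#' @rdname binning_unit
#' @param spec a binning object or a string (`"unit"`, `"count:256"`,
#'   `"width:2.5"`).
#' @export
parse_binning <- function(spec) {
  if (inherits(spec, "histo_binning")) return(spec)
  if (!is.character(spec) || length(spec) != 1L) {
    stop("binning must be a histo_binning object or a string", call. = FALSE)
  }
  if (spec == "unit") return(binning_unit())
  if (grepl("^count:", spec)) return(binning_count(sub("^count:", "", spec)))
  if (grepl("^width:", spec)) return(binning_width(sub("^width:", "", spec)))
  stop(sprintf("unknown binning '%s' (use unit, count:<k> or width:<w>)", spec),
       call. = FALSE)
}

#' Build an intensity histogram over ROI pixels
#'
#' Bins are half-open \code{[e_i, e_{i+1})} with the last bin closed, so
#' counts always conserve the pixel total.
#'
#' @param pixels numeric vector of gray levels (non-empty).
#' @param binning a binning spec, see [binning_unit()].
#' @return An `intensity_histogram`: list with `bin_edges`, `counts`,
#'   `n_pixels`.
#' @export
build_histogram <- function(pixels, binning = binning_unit()) {
  if (length(pixels) == 0L) stop("empty pixel collection", call. = FALSE)
  binning <- parse_binning(binning)
  lo <- min(pixels); hi <- max(pixels)
  edges <- switch(binning$mode,
    unit = seq(floor(lo), floor(hi) + 1),
    count = if (lo == hi) c(lo, lo + 1) else seq(lo, hi, length.out = binning$k + 1L),
    width = {
      n <- max(1L, ceiling((hi - lo) / binning$w))
      if (lo + n * binning$w <= hi) n <- n + 1L   # guard fp shortfall
      lo + binning$w * (0:n)
    })
  idx <- findInterval(pixels, edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  structure(list(bin_edges = edges, counts = counts, n_pixels = length(pixels)),
            class = "intensity_histogram")
}

#' @export
print.intensity_histogram <- function(x, ...) {
  cat(sprintf("intensity histogram: %d pixels in %d bins over [%g, %g]\n",
              x$n_pixels, length(x$counts), min(x$bin_edges), max(x$bin_edges)))
  invisible(x)
}

#' Basic order and moment statistics of ROI pixels
#'
#' Mean, SD and variance use population (divide-by-n) moments; the median of
#' an even-length sample is the midpoint of the two central order statistics.
#'
#' @inheritParams build_histogram
#' @return Named list: mean, sd, min, max, median, variance.
#' @export
basic_stats <- function(pixels) {
  if (length(pixels) == 0L) stop("empty pixel collection", call. = FALSE)
  v <- central_moment(pixels, 2)
  list(mean = mean(pixels), sd = sqrt(v), min = min(pixels), max = max(pixels),
       median = stats::median(pixels), variance = v)
}

#' Shannon entropy of an intensity histogram, in bits
#'
#' \eqn{H = -\sum_i p_i \log_2 p_i} with \eqn{p_i = counts_i / n} and
#' \eqn{0 \log 0 \equiv 0}. Zero for a constant region; larger for an
#' irregular gray-level distribution.
#'
#' @param hist an `intensity_histogram` from [build_histogram()].
#' @return Entropy in bits, in \code{[0, log2(#nonzero bins)]}.
#' @export
hist_entropy <- function(hist) {
  p <- hist$counts[hist$counts > 0] / hist$n_pixels
  -sum(p * log2(p))
}

#' Uniformity (energy) of an intensity histogram
#'
#' \eqn{U = \sum_i p_i^2}: 1 when all mass sits in one bin, 1/k for mass
#' spread evenly over k bins.
#'
#' @inheritParams hist_entropy
#' @return Uniformity in (0, 1].
#' @export
hist_uniformity <- function(hist) {
  p <- hist$counts / hist$n_pixels
  sum(p^2)
}

#' Histogram size percentages around the mean
#'
#' Percentage of ROI pixels below mean − 1 SD (%L), above mean + 1 SD (%U)
#' and between (%M). Pixels exactly on a threshold count as middle, so the
#' three always sum to 100. A constant region returns (0, 0, 100).
#'
#' @inheritParams build_histogram
#' @return Named list: lower, upper, mid (percent).
#' @export
size_percentages <- function(pixels) {
  if (length(pixels) == 0L) stop("empty pixel collection", call. = FALSE)
  mu <- mean(pixels)
  s <- sqrt(central_moment(pixels, 2))
  if (s == 0) return(list(lower = 0, upper = 0, mid = 100))
  lower <- 100 * sum(pixels < mu - s) / length(pixels)
  upper <- 100 * sum(pixels > mu + s) / length(pixels)
  list(lower = lower, upper = upper, mid = 100 - lower - upper)
}

#' Physical ROI area
#'
#' Member-pixel count times the pixel footprint, in cm^2.
#'
#' @param mask an [roi_mask] (or binary matrix).
#' @param spacing numeric length-2, (row, column) pixel spacing in mm.
#' @return Area in cm^2.
#' @export
roi_area <- function(mask, spacing) {
  if (any(spacing <= 0)) stop("pixel spacing must be > 0", call. = FALSE)
  mask <- as_roi_mask(mask)
  sum(mask$membership) * spacing[1] * spacing[2] / 100
}

#' Extract the full first-order feature vector of an ROI
#'
#' Composes the histogram features — mean, SD, min, max, median, variance,
#' entropy, uniformity, skewness, kurtosis, size %L/%U/%M — and the physical
#' ROI area into one record. For a constant-intensity ROI, entropy,
#' uniformity and size percentages take their limit values (0, 1, (0,0,100))
#' and skewness/kurtosis are reported as `NA` with `degenerate = TRUE`
#' rather than fabricated.
#'
#' @inheritParams extract_roi_pixels
#' @param binning binning used for entropy and uniformity (see
#'   [binning_unit()]); the moment features are binning-free.
#' @return A `feature_vector`: named list of the 14 feature values plus
#'   `n_pixels`, `binning` and `degenerate`.
#' @export
#' @examples
#' img <- image_slice(matrix(c(5, 5, 7, 9), 2, 2), spacing = c(1, 1))
#' msk <- roi_mask(matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2))
#' extract_features(img, msk)
extract_features <- function(image, mask, binning = binning_unit()) {
  px <- extract_roi_pixels(image, mask)
  features_from_pixels(px, mask = mask, spacing = as_image_slice(image)$pixel_spacing_mm,
                       binning = binning)
}

## feature vector from a bare pixel collection (area supplied or via mask)
features_from_pixels <- function(pixels, mask = NULL, spacing = NULL,
                                 area_cm2 = NULL, binning = binning_unit()) {
  binning <- parse_binning(binning)
  bs <- basic_stats(pixels)
  degenerate <- bs$sd == 0
  h <- build_histogram(pixels, binning)
  sp <- size_percentages(pixels)
  if (is.null(area_cm2)) {
    area_cm2 <- if (!is.null(mask) && !is.null(spacing)) roi_area(mask, spacing) else NA_real_
  }
  structure(list(
    mean = bs$mean, sd = bs$sd, min = bs$min, max = bs$max,
    median = bs$median, variance = bs$variance,
    entropy = hist_entropy(h), uniformity = hist_uniformity(h),
    skewness = if (degenerate) NA_real_ else skewness(pixels),
    kurtosis = if (degenerate) NA_real_ else kurtosis(pixels),
    size_pct_lower = sp$lower, size_pct_upper = sp$upper, size_pct_mean = sp$mid,
    area_cm2 = area_cm2,
    n_pixels = length(pixels), binning = binning, degenerate = degenerate),
    class = "feature_vector")
}

## canonical feature column order, mirroring the comparison table rows
feature_columns <- function() {
  c("mean", "sd", "min", "max", "median", "variance", "entropy",
    "size_pct_lower", "size_pct_upper", "size_pct_mean",
    "kurtosis", "skewness", "uniformity", "area_cm2")
}

#' @export
print.feature_vector <- function(x, digits = 4, ...) {
  cat(sprintf("first-order features (%d ROI pixels%s)\n", x$n_pixels,
              if (x$degenerate) ", constant intensity" else ""))
  vals <- unlist(x[feature_columns()])
  print(round(vals, digits))
  invisible(x)
}

#' @export
as.data.frame.feature_vector <- function(x, row.names = NULL, optional = FALSE, ...) {
  as.data.frame(x[feature_columns()], row.names = row.names)
}
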
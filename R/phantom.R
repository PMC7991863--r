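## Synthetic single-slice phantoms: a C-shaped arc-band ROI resembling a
## midsagittal corpus callosum, filled with intensities drawn from a
## moment-matched distribution family, on a low-intensity background.
## First-order features ignore spatial arrangement, so i.i.d. ROI pixels
## are a sufficient data model; the generator's job is to control the first
## four moments of the ROI gray-level distribution.

#' Intensity distribution specification
#'
#' Targets for the ROI gray-level distribution of one synthetic subject.
#' `gaussian` takes mean/sd only; `skew_normal` adds a target skewness
#' (delegating to the mixture sampler when the target is outside the
#' skew-normal's attainable range of about ±0.995); `two_component_mixture`
#' matches all four moments, solved numerically. Values are clipped to
#' \code{[value_floor, value_cap]}; when the clipped mass is non-negligible
#' the mixture is re-solved against post-clipping moments.
#'
#' @param family `"gaussian"`, `"skew_normal"` or `"two_component_mixture"`.
#' @param mean,sd target mean and SD in gray levels (`sd > 0`).
#' @param skewness,kurtosis dimensionless targets (Pearson kurtosis,
#'   Gaussian = 3). Must be absent for `gaussian`; `kurtosis` must exceed
#'   `skewness^2 + 1`.
#' @param value_floor,value_cap physical gray-level bounds (floor >= 0).
#' @return A `dist_spec` object.
#' @export
dist_spec <- function(family = c("gaussian", "skew_normal", "two_component_mixture"),
                      mean, sd, skewness = NULL, kurtosis = NULL,
                      value_floor = 0, value_cap = 1023) {
  family <- match.arg(family)
  if (!is.numeric(sd) || sd <= 0) stop("target sd must be > 0", call. = FALSE)
  if (value_floor < 0) stop("value_floor must be >= 0", call. = FALSE)
  if (!(value_floor < mean && mean < value_cap)) {
    stop("target mean must lie strictly inside [value_floor, value_cap]", call. = FALSE)
  }
  if (family == "gaussian" && (!is.null(skewness) || !is.null(kurtosis))) {
    stop("gaussian family takes no skewness/kurtosis targets", call. = FALSE)
  }
  if (family == "skew_normal" && is.null(skewness)) {
    stop("skew_normal family needs a target skewness", call. = FALSE)
  }
  if (family == "two_component_mixture") {
    if (is.null(skewness) || is.null(kurtosis)) {
      stop("two_component_mixture needs both skewness and kurtosis targets", call. = FALSE)
    }
  }
  if (!is.null(skewness) && !is.null(kurtosis) && kurtosis <= skewness^2 + 1) {
    stop(sprintf("infeasible moments: kurtosis (%.3f) must exceed skewness^2 + 1 (%.3f)",
                 kurtosis, skewness^2 + 1), call. = FALSE)
  }
  structure(list(family = family, mean = mean, sd = sd,
                 skewness = skewness, kurtosis = kurtosis,
                 value_floor = value_floor, value_cap = value_cap),
            class = "dist_spec")
}

with_optional_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

#' Draw ROI gray-level values from a distribution spec
#'
#' Samples `n` values whose empirical mean/SD (and skewness/kurtosis for
#' the skewed families) converge to the spec's targets as `n` grows; values
#' are clipped to \code{[value_floor, value_cap]} and targets are
#' interpreted post-clipping.
#'
#' @param spec a [dist_spec()].
#' @param n number of values (>= 1).
#' @param seed optional integer; same (spec, n, seed) gives identical draws.
#' @return Numeric vector of length `n`.
#' @export
sample_intensities <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "dist_spec"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be >= 1", call. = FALSE)
  with_optional_seed(seed, {
    x <- switch(spec$family,
      gaussian = rnorm(n, spec$mean, spec$sd),
      skew_normal = sample_skew_family(spec, n),
      two_component_mixture = sample_mixture_family(spec, n))
    pmin(pmax(x, spec$value_floor), spec$value_cap)
  })
}

sample_skew_family <- function(spec, n) {
  if (abs(spec$skewness) < sn_max_skew) {
    delta <- sn_delta_from_skew(spec$skewness)
    spec$mean + spec$sd * sample_skew_normal_std(n, delta)
  } else {
    ## outside the skew-normal range: fall back to the mixture sampler with
    ## a feasible default kurtosis when none was given
    k <- if (is.null(spec$kurtosis)) 1.5 * (spec$skewness^2 + 1) else spec$kurtosis
    spec$kurtosis <- k
    sample_mixture_family(spec, n)
  }
}

sample_mixture_family <- function(spec, n) {
  std <- solve_mixture_std(spec$skewness, spec$kurtosis)
  w <- std$w
  mu <- spec$mean + spec$sd * std$mu
  sg <- spec$sd * std$sg
  ## refine against post-clip moments only when the clipped mass is large
  ## enough to bias moments beyond sampling noise at ROI-sized n
  if (mixture_clip_mass(w, mu, sg, spec$value_floor, spec$value_cap) > 5e-3) {
    fit <- solve_mixture_clipped(spec$mean, spec$sd, spec$skewness, spec$kurtosis,
                                 spec$value_floor, spec$value_cap)
    w <- fit$w; mu <- fit$mu; sg <- fit$sg
  }
  sample_mixture(n, w, mu, sg)
}

## ---- ROI mask ---------------------------------------------------------

#' Generate a corpus-callosum-like ROI mask
#'
#' A parametric C-shaped arc band (dome opening downward) whose pixel count
#' matches the requested physical area: the mask is the `k` grid pixels
#' nearest the arc centerline, `k = round(area / pixel footprint)`, which
#' yields a single 8-connected component at realistic areas. The seed
#' jitters the arc center and orientation.
#'
#' @param target_area_cm2 ROI area in cm^2.
#' @param grid_size (rows, columns) of the grid.
#' @param pixel_spacing_mm (row, column) spacing in mm.
#' @param seed optional integer for reproducible jitter.
#' @return An [roi_mask].
#' @export
generate_roi_mask <- function(target_area_cm2, grid_size = c(256L, 256L),
                              pixel_spacing_mm = c(0.9375, 0.9375), seed = NULL) {
  if (length(grid_size) == 1L) grid_size <- rep(grid_size, 2)
  if (length(pixel_spacing_mm) == 1L) pixel_spacing_mm <- rep(pixel_spacing_mm, 2)
  px_area_mm2 <- pixel_spacing_mm[1] * pixel_spacing_mm[2]
  k <- round(target_area_cm2 * 100 / px_area_mm2)
  if (is.na(k) || k < 1L || target_area_cm2 <= 0) {
    stop(sprintf("target area %.4g cm^2 is below one pixel (%.4g cm^2)",
                 target_area_cm2, px_area_mm2 / 100), call. = FALSE)
  }
  if (k > prod(grid_size)) {
    stop(sprintf("target area %.4g cm^2 needs %d pixels but the grid has %d",
                 target_area_cm2, k, prod(grid_size)), call. = FALSE)
  }
  with_optional_seed(seed, {
    cy <- grid_size[1] / 2 + runif(1, -3, 3)
    cx <- grid_size[2] / 2 + runif(1, -3, 3)
    rot <- runif(1, -10, 10) * pi / 180
    r0 <- sqrt(k / 1.73)                 # span * thickness fraction = 1.73
    a1 <- -10 * pi / 180 + rot           # dome: ~[-10 deg, 210 deg]
    a2 <- 210 * pi / 180 + rot
    row <- matrix(seq_len(grid_size[1]), grid_size[1], grid_size[2])
    col <- matrix(seq_len(grid_size[2]), grid_size[1], grid_size[2], byrow = TRUE)
    ## anisotropic pixels: work in mm so the band is round in physical space
    dy <- (cy - row) * pixel_spacing_mm[1]   # y up
    dx <- (col - cx) * pixel_spacing_mm[2]
    r0 <- r0 * sqrt(px_area_mm2)
    rad <- sqrt(dx^2 + dy^2)
    ang <- atan2(dy, dx)
    ang <- ang + ifelse(ang < a1, 2 * pi, 0)  # normalize into [a1, a1+2pi)
    inside <- ang >= a1 & ang <= a2
    score <- abs(rad - r0)
    ## outside the angular span, distance to the nearest arc endpoint
    for (a in c(a1, a2)) {
      ex <- r0 * cos(a); ey <- r0 * sin(a)
      d <- sqrt((dx - ex)^2 + (dy - ey)^2)
      score[!inside] <- pmin(score[!inside], d[!inside])
    }
    keep <- order(score)[seq_len(k)]
    m <- matrix(FALSE, grid_size[1], grid_size[2])
    m[keep] <- TRUE
    roi_mask(m)
  })
}

## 8-connected component count (used to validate generated masks)
count_components <- function(membership) {
  lab <- matrix(0L, nrow(membership), ncol(membership))
  comp <- 0L
  idx <- which(membership)
  nr <- nrow(membership)
  for (start in idx) {
    if (lab[start] > 0L) next
    comp <- comp + 1L
    queue <- start
    lab[start] <- comp
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- (cur - 1L) %% nr + 1L
      c <- (cur - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr < 1L || cc < 1L || rr > nr || cc > ncol(membership)) next
        j <- (cc - 1L) * nr + rr
        if (membership[j] && lab[j] == 0L) {
          lab[j] <- comp
          queue <- c(queue, j)
        }
      }
    }
  }
  comp
}

## ---- subjects ---------------------------------------------------------

#' Subject specification for the phantom generator
#'
#' @param subject_id identifier string.
#' @param group `"control"` or `"case"`.
#' @param distribution a [dist_spec()] for the ROI intensities.
#' @param roi_area_cm2 target ROI area (cm^2), achievable on the grid.
#' @param grid_size,pixel_spacing_mm grid geometry; defaults match a
#'   256 x 256 matrix over a 240 mm field of view (0.9375 mm pixels).
#' @param background mean/sd (gray levels) of the low-intensity background
#'   tissue surrounding the ROI.
#' @return A `subject_spec` object.
#' @export
subject_spec <- function(subject_id, group = c("control", "case"), distribution,
                         roi_area_cm2, grid_size = c(256L, 256L),
                         pixel_spacing_mm = c(0.9375, 0.9375),
                         background = list(mean = 60, sd = 20)) {
  group <- match.arg(group)
  stopifnot(inherits(distribution, "dist_spec"))
  if (length(grid_size) == 1L) grid_size <- rep(grid_size, 2)
  if (length(pixel_spacing_mm) == 1L) pixel_spacing_mm <- rep(pixel_spacing_mm, 2)
  max_area <- prod(grid_size) * prod(pixel_spacing_mm) / 100
  if (roi_area_cm2 <= 0 || roi_area_cm2 > max_area) {
    stop(sprintf("roi_area_cm2 must be in (0, %.4g]", max_area), call. = FALSE)
  }
  structure(list(subject_id = as.character(subject_id), group = group,
                 distribution = distribution, roi_area_cm2 = roi_area_cm2,
                 grid_size = grid_size, pixel_spacing_mm = pixel_spacing_mm,
                 background = background),
            class = "subject_spec")
}

#' Generate one synthetic subject (image + ROI mask)
#'
#' Background pixels come from the spec's low-intensity background
#' distribution and ROI pixels from its intensity distribution; gray levels
#' are rounded to integers (as stored by scanners) and clipped to the
#' spec's physical bounds. Deterministic in (spec, seed).
#'
#' @param spec a [subject_spec()].
#' @param seed optional integer.
#' @return List with elements `image` ([image_slice]) and `mask`
#'   ([roi_mask]).
#' @export
generate_subject <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "subject_spec"))
  with_optional_seed(seed, {
    mask <- generate_roi_mask(spec$roi_area_cm2, spec$grid_size,
                              spec$pixel_spacing_mm, seed = NULL)
    n_bg <- prod(spec$grid_size)
    bg <- rnorm(n_bg, spec$background$mean, spec$background$sd)
    px <- matrix(pmin(pmax(bg, spec$distribution$value_floor),
                      spec$distribution$value_cap),
                 spec$grid_size[1], spec$grid_size[2])
    n_roi <- sum(mask$membership)
    px[mask$membership] <- sample_intensities(spec$distribution, n_roi, seed = NULL)
    px <- round(px)
    list(image = image_slice(px, spec$pixel_spacing_mm,
                             source_id = spec$subject_id),
         mask = mask)
  })
}

## ---- cohorts ----------------------------------------------------------

#' Per-group phantom parameters
#'
#' Between-subject distributions of the per-subject ROI parameters: each
#' subject's ROI mean, within-ROI SD, skewness, kurtosis and area are drawn
#' from normals with these means/SDs. Defaults are the study conditions for
#' the two groups (see [cohort_spec()]).
#'
#' @param mean_mean,mean_sd between-subject distribution of the ROI mean.
#' @param sd_mean,sd_sd between-subject distribution of the within-ROI SD.
#' @param skew_mean,skew_sd,kurt_mean,kurt_sd shape-parameter distributions.
#' @param area_mean,area_sd ROI area distribution (cm^2).
#' @return A `group_params` list.
#' @export
group_params <- function(mean_mean, mean_sd, sd_mean, sd_sd,
                         skew_mean, skew_sd, kurt_mean, kurt_sd,
                         area_mean, area_sd) {
  structure(as.list(environment()), class = "group_params")
}

control_params <- function() {
  group_params(mean_mean = 336.56, mean_sd = 147.21, sd_mean = 31.26,
               sd_sd = 13.76, skew_mean = -2.50, skew_sd = 0.46,
               kurt_mean = 13.80, kurt_sd = 4.34, area_mean = 5.64,
               area_sd = 0.69)
}

case_params <- function() {
  group_params(mean_mean = 476.10, mean_sd = 46.09, sd_mean = 75.49,
               sd_sd = 11.47, skew_mean = -2.58, skew_sd = 0.47,
               kurt_mean = 10.34, kurt_sd = 2.89, area_mean = 6.07,
               area_sd = 0.94)
}

#' Cohort specification
#'
#' Defaults reproduce the study conditions: 20 controls vs 19 cases of
#' single midsagittal slices whose per-subject ROI mean, SD, skewness,
#' kurtosis and area are drawn from the corresponding per-group
#' between-subject distributions.
#'
#' @param n_control,n_case group sizes (each >= 2).
#' @param control,case [group_params()] for each group.
#' @param family intensity family used per subject.
#' @param value_floor,value_cap physical gray-level bounds.
#' @param grid_size,pixel_spacing_mm grid geometry.
#' @param seed cohort seed; per-subject seeds derive from it.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_control = 20L, n_case = 19L,
                        control = control_params(), case = case_params(),
                        family = "two_component_mixture",
                        value_floor = 0, value_cap = 1023,
                        grid_size = c(256L, 256L),
                        pixel_spacing_mm = c(0.9375, 0.9375),
                        seed = 1L) {
  if (n_control < 2L || n_case < 2L) {
    stop("each group needs at least 2 subjects", call. = FALSE)
  }
  structure(list(n_control = as.integer(n_control), n_case = as.integer(n_case),
                 control = control, case = case, family = family,
                 value_floor = value_floor, value_cap = value_cap,
                 grid_size = grid_size, pixel_spacing_mm = pixel_spacing_mm,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

## deterministic per-subject seed below 2^31 (exact in double arithmetic)
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + index * 16807) %% 2147483647)
}

## lognormal draw matched to a target mean/SD: the natural positive-scale
## model for SD- and area-like parameters (no truncation artifacts)
rlnorm_match <- function(n, mean, sd) {
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  stats::rlnorm(n, log(mean) - sdlog^2 / 2, sdlog)
}

## one subject_spec drawn from the group's between-subject distributions.
## Kurtosis is kept >= 1.3 * (skewness^2 + 1): closer to the moment
## boundary only near-two-point (spike) gray-level distributions exist,
## which tissue histograms never are.
draw_subject_spec <- function(id, group, gp, spec) {
  m <- rnorm(1, gp$mean_mean, gp$mean_sd)
  s <- rlnorm_match(1, gp$sd_mean, gp$sd_sd)
  g1 <- rnorm(1, gp$skew_mean, gp$skew_sd)
  g2 <- max(rnorm(1, gp$kurt_mean, gp$kurt_sd), 1.3 * (g1^2 + 1))
  area <- rlnorm_match(1, gp$area_mean, gp$area_sd)
  m <- min(max(m, spec$value_floor + 1), spec$value_cap - 1)
  dist <- switch(spec$family,
    gaussian = dist_spec("gaussian", mean = m, sd = s,
                         value_floor = spec$value_floor, value_cap = spec$value_cap),
    skew_normal = dist_spec("skew_normal", mean = m, sd = s, skewness = g1,
                            value_floor = spec$value_floor, value_cap = spec$value_cap),
    two_component_mixture = dist_spec("two_component_mixture", mean = m, sd = s,
                                      skewness = g1, kurtosis = g2,
                                      value_floor = spec$value_floor,
                                      value_cap = spec$value_cap))
  subject_spec(id, group, dist, roi_area_cm2 = area, grid_size = spec$grid_size,
               pixel_spacing_mm = spec$pixel_spacing_mm)
}

cohort_subject_table <- function(spec) {
  data.frame(
    index = seq_len(spec$n_control + spec$n_case),
    subject_id = c(sprintf("ctrl%02d", seq_len(spec$n_control)),
                   sprintf("case%02d", seq_len(spec$n_case))),
    group = c(rep("control", spec$n_control), rep("case", spec$n_case)),
    stringsAsFactors = FALSE)
}

#' Simulate a cohort and extract its feature table in memory
#'
#' Desk-scale path used for replicate studies: for each subject the ROI
#' pixel multiset is sampled directly (first-order features are invariant
#' to spatial arrangement, so rasterizing full images adds nothing) and the
#' 14 features are extracted. Deterministic in the cohort seed.
#'
#' @param spec a [cohort_spec()].
#' @param binning histogram binning for entropy/uniformity.
#' @return Feature table data frame (one row per subject) in the canonical
#'   column order.
#' @export
cohort_features <- function(spec, binning = binning_unit()) {
  stopifnot(inherits(spec, "cohort_spec"))
  subjects <- cohort_subject_table(spec)
  px_area_mm2 <- spec$pixel_spacing_mm[1] * spec$pixel_spacing_mm[2]
  rows <- lapply(subjects$index, function(i) {
    withr::with_seed(derive_seed(spec$seed, i), {
      gp <- if (subjects$group[i] == "control") spec$control else spec$case
      ss <- draw_subject_spec(subjects$subject_id[i], subjects$group[i], gp, spec)
      n_px <- max(3L, round(ss$roi_area_cm2 * 100 / px_area_mm2))
      px <- round(sample_intensities(ss$distribution, n_px, seed = NULL))
      fv <- features_from_pixels(px, area_cm2 = n_px * px_area_mm2 / 100,
                                 binning = binning)
      cbind(data.frame(subject_id = ss$subject_id, group = ss$group,
                       stringsAsFactors = FALSE),
            as.data.frame(fv))
    })
  })
  do.call(rbind, rows)
}

#' Generate a phantom cohort on disk
#'
#' Writes one image and one mask per subject plus a manifest CSV with
#' columns `subject_id, group, image_path, mask_path` (paths relative to
#' the manifest). Identical (spec, seed) produce identical files.
#'
#' @param spec a [cohort_spec()].
#' @param out_dir output directory (created if needed).
#' @param format `"tiff"` (16-bit + JSON sidecar) or `"nifti"`.
#' @return Path to the manifest CSV, invisibly; the manifest data frame is
#'   attached as attribute `"manifest"`.
#' @export
generate_cohort <- function(spec, out_dir, format = c("tiff", "nifti")) {
  stopifnot(inherits(spec, "cohort_spec"))
  format <- match.arg(format)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop(sprintf("cannot create output dir '%s'", out_dir), call. = FALSE)
  ext <- if (format == "tiff") "tif" else "nii"
  subjects <- cohort_subject_table(spec)
  manifest <- do.call(rbind, lapply(subjects$index, function(i) {
    sid <- subjects$subject_id[i]
    withr::with_seed(derive_seed(spec$seed, i), {
      gp <- if (subjects$group[i] == "control") spec$control else spec$case
      ss <- draw_subject_spec(sid, subjects$group[i], gp, spec)
      subj <- generate_subject(ss, seed = NULL)
      img_rel <- sprintf("%s_image.%s", sid, ext)
      msk_rel <- sprintf("%s_mask.%s", sid, ext)
      write_image(subj$image, file.path(out_dir, img_rel), format = format)
      write_mask(subj$mask, file.path(out_dir, msk_rel), format = format)
      data.frame(subject_id = sid, group = subjects$group[i],
                 image_path = img_rel, mask_path = msk_rel,
                 stringsAsFactors = FALSE)
    })
  }))
  manifest_path <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE, quote = FALSE)
  structure(invisible(manifest_path), manifest = manifest)
}

#' Extract features for every subject in a manifest
#'
#' Reads each image/mask pair listed in a cohort manifest (as written by
#' [generate_cohort()], paths resolved relative to the manifest) and
#' returns the per-subject feature table.
#'
#' @param manifest path to a manifest CSV or the manifest data frame (then
#'   `base_dir` anchors relative paths).
#' @param binning histogram binning for entropy/uniformity.
#' @param base_dir directory against which relative paths resolve.
#' @return Feature table data frame.
#' @export
extract_cohort_features <- function(manifest, binning = binning_unit(),
                                    base_dir = NULL) {
  if (is.character(manifest)) {
    if (!file.exists(manifest)) {
      stop(sprintf("manifest not found: '%s'", manifest), call. = FALSE)
    }
    base_dir <- dirname(manifest)
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  need <- c("subject_id", "group", "image_path", "mask_path")
  missing <- setdiff(need, names(manifest))
  if (length(missing)) {
    stop(sprintf("manifest lacks columns: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  resolve <- function(p) {
    if (is.null(base_dir) || grepl("^(/|[A-Za-z]:)", p)) p else file.path(base_dir, p)
  }
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    img <- read_image(resolve(manifest$image_path[i]))
    msk <- read_mask(resolve(manifest$mask_path[i]))
    fv <- extract_features(img, msk, binning = binning)
    cbind(data.frame(subject_id = manifest$subject_id[i],
                     group = manifest$group[i], stringsAsFactors = FALSE),
          as.data.frame(fv))
  })
  do.call(rbind, rows)
}
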
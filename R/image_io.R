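## Image and mask containers plus readers/writers for the supported
## formats: single-frame DICOM, NIfTI-1 (explicit slice selection for
## volumes), and 16-bit PNG/TIFF rasters with a JSON spacing sidecar.
## Coordinate convention throughout: matrices are row-major conceptually
## (row 1 = top image row), image and mask grids must be congruent, and
## spacing is (row, column) in mm.

#' 2-D image slice with physical pixel spacing
#'
#' @param pixels numeric matrix of non-negative, finite gray levels.
#' @param spacing numeric length-2, (row, column) pixel spacing in mm.
#' @param source_id provenance string.
#' @return An `image_slice` object.
#' @export
image_slice <- function(pixels, spacing, source_id = "<memory>") {
  pixels <- as.matrix(pixels)
  if (length(pixels) == 0L) stop("image grid is empty", call. = FALSE)
  storage.mode(pixels) <- "double"   # one storage type across all readers
  if (!all(is.finite(pixels))) stop("image contains non-finite intensities", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 2)
  if (length(spacing) != 2L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("pixel spacing must be two positive values (row, column) in mm", call. = FALSE)
  }
  structure(list(pixels = pixels, pixel_spacing_mm = spacing,
                 source_id = as.character(source_id)),
            class = "image_slice")
}

as_image_slice <- function(x) {
  if (inherits(x, "image_slice")) return(x)
  stop("expected an image_slice (see read_image())", call. = FALSE)
}

#' @export
print.image_slice <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("image slice %dx%d, spacing %.4f x %.4f mm, range [%g, %g] (%s)\n",
              d[1], d[2], x$pixel_spacing_mm[1], x$pixel_spacing_mm[2],
              min(x$pixels), max(x$pixels), x$source_id))
  invisible(x)
}

#' Binary region-of-interest mask
#'
#' Any nonzero value marks membership; binarization is idempotent.
#'
#' @param membership logical or numeric matrix.
#' @return An `roi_mask` object.
#' @export
roi_mask <- function(membership) {
  membership <- as.matrix(membership)
  if (length(membership) == 0L) stop("mask grid is empty", call. = FALSE)
  m <- membership != 0
  m[is.na(m)] <- FALSE
  structure(list(membership = m, dim = dim(m)), class = "roi_mask")
}

as_roi_mask <- function(x) {
  if (inherits(x, "roi_mask")) return(x)
  if (is.matrix(x)) return(roi_mask(x))
  stop("expected an roi_mask or a matrix", call. = FALSE)
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("ROI mask %dx%d, %d member pixels\n",
              x$dim[1], x$dim[2], sum(x$membership)))
  invisible(x)
}

## ---- readers ----------------------------------------------------------

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

read_spacing_sidecar <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) {
    stop(sprintf("no pixel spacing for '%s': sidecar '%s' not found (a raster image needs a {\"pixel_spacing_mm\": [r, c]} sidecar; spacing is never defaulted)",
                 path, sc), call. = FALSE)
  }
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  sp <- meta$pixel_spacing_mm
  if (is.null(sp) || length(sp) != 2L) {
    stop(sprintf("sidecar '%s' lacks a 2-element pixel_spacing_mm", sc), call. = FALSE)
  }
  as.numeric(sp)
}

## 16-bit raster (PNG or TIFF) to integer matrix on the stored scale
read_raster_grid <- function(path, format) {
  arr <- switch(format,
    png = png::readPNG(path),
    tiff = tiff::readTIFF(path, as.is = FALSE))
  if (length(dim(arr)) == 3L) {
    if (dim(arr)[3] > 1L) stop(sprintf("'%s' is not single-channel grayscale", path), call. = FALSE)
    arr <- arr[, , 1]
  }
  round(arr * 65535)  # readers scale to [0,1]; stored values are 16-bit
}

detect_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    dcm = "dicom", dicom = "dicom",
    nii = "nifti", gz = "nifti",
    png = "png", tif = "tiff", tiff = "tiff",
    stop(sprintf("cannot infer format of '%s'; pass format_hint", path), call. = FALSE))
}

#' Read a 2-D image slice from disk
#'
#' Supported formats: single-frame DICOM (`.dcm`), NIfTI-1 (`.nii`,
#' `.nii.gz`; a 3-D volume needs `slice_axis`/`slice_index`), and 16-bit
#' grayscale PNG/TIFF with a JSON sidecar
#' \code{{"pixel_spacing_mm": [r, c]}} next to the file. Pixel spacing is
#' always taken from the file metadata or sidecar — never silently
#' defaulted.
#'
#' @param path file path.
#' @param format_hint one of `"dicom"`, `"nifti"`, `"png"`, `"tiff"`;
#'   inferred from the extension when omitted.
#' @param slice_axis,slice_index for 3-D NIfTI volumes: axis (1-3) and
#'   1-based index of the slice to extract.
#' @return An [image_slice].
#' @export
read_image <- function(path, format_hint = NULL, slice_axis = NULL,
                       slice_index = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  format <- if (is.null(format_hint)) detect_format(path) else match.arg(format_hint, c("dicom", "nifti", "png", "tiff"))
  if (format == "dicom") return(read_dicom_image(path))
  if (format == "nifti") return(read_nifti_slice(path, slice_axis, slice_index))
  px <- read_raster_grid(path, format)
  image_slice(px, read_spacing_sidecar(path), source_id = path)
}

read_nifti_slice <- function(path, slice_axis = NULL, slice_index = NULL) {
  img <- RNifti::readNifti(path)
  dm <- dim(img)
  pixdim <- RNifti::pixdim(img)
  arr <- as.array(img)
  if (length(dm) > 2L) {
    singleton <- which(dm == 1L)
    if (length(dm) - length(singleton) == 2L) {
      keep <- which(dm > 1L)
      arr <- array(arr, dm)
      arr <- apply(arr, keep, function(v) v)  # drop singleton axes
      pixdim <- pixdim[keep]
    } else {
      if (is.null(slice_axis) || is.null(slice_index)) {
        stop(sprintf("'%s' is a %s volume: pass slice_axis and slice_index",
                     path, paste(dm, collapse = "x")), call. = FALSE)
      }
      idx <- rep(list(quote(expr = )), length(dm))
      idx[[slice_axis]] <- slice_index
      arr <- do.call(`[`, c(list(arr), idx, drop = TRUE))
      pixdim <- pixdim[-slice_axis]
    }
  }
  ## NIfTI arrays are (x, y): x varies along image columns. Transpose so the
  ## matrix is (row, column) with spacing (row, column).
  image_slice(t(arr), spacing = rev(pixdim[1:2]), source_id = path)
}

#' Read a binary ROI mask
#'
#' Any supported image format; every nonzero pixel is a member.
#'
#' @inheritParams read_image
#' @return An [roi_mask].
#' @export
read_mask <- function(path, format_hint = NULL, slice_axis = NULL,
                      slice_index = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  format <- if (is.null(format_hint)) detect_format(path) else match.arg(format_hint, c("dicom", "nifti", "png", "tiff"))
  grid <- switch(format,
    dicom = read_dicom_image(path)$pixels,
    nifti = read_nifti_slice(path, slice_axis, slice_index)$pixels,
    read_raster_grid(path, format))
  roi_mask(grid)
}

## ---- writers (TIFF 16-bit + sidecar; NIfTI) ---------------------------

#' Write an image slice or mask to disk
#'
#' `format = "tiff"` writes a 16-bit grayscale TIFF plus a JSON spacing
#' sidecar; `format = "nifti"` writes a single-slice NIfTI-1 with the
#' spacing in its pixdim. Integer gray levels in \[0, 65535\] round-trip
#' bit-exactly.
#'
#' @param image an [image_slice].
#' @param path output path (extension should match the format).
#' @param format `"tiff"` or `"nifti"`.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, format = c("tiff", "nifti")) {
  format <- match.arg(format)
  image <- as_image_slice(image)
  px <- image$pixels
  if (format == "tiff") {
    if (min(px) < 0 || max(px) > 65535) {
      stop("TIFF output requires gray levels in [0, 65535]", call. = FALSE)
    }
    tiff::writeTIFF(px / 65535, path, bits.per.sample = 16L, compression = "none")
    jsonlite::write_json(list(pixel_spacing_mm = image$pixel_spacing_mm),
                         sidecar_path(path), auto_unbox = FALSE, digits = NA)
  } else {
    arr <- t(px)  # back to NIfTI (x, y) order
    nim <- RNifti::asNifti(arr)
    RNifti::pixdim(nim) <- rev(image$pixel_spacing_mm)
    RNifti::writeNifti(nim, path)
  }
  invisible(path)
}

#' @rdname write_image
#' @param mask an [roi_mask].
#' @export
write_mask <- function(mask, path, format = c("tiff", "nifti")) {
  format <- match.arg(format)
  mask <- as_roi_mask(mask)
  img <- image_slice(mask$membership * 1, spacing = c(1, 1), source_id = "mask")
  if (format == "tiff") {
    tiff::writeTIFF(img$pixels, path, bits.per.sample = 8L, compression = "none")
    jsonlite::write_json(list(pixel_spacing_mm = c(1, 1)), sidecar_path(path),
                         auto_unbox = FALSE, digits = NA)
  } else {
    write_image(img, path, format = "nifti")
  }
  invisible(path)
}

## ---- feature tables ---------------------------------------------------

feature_table_columns <- function() c("subject_id", "group", feature_columns())

#' Write / read a per-subject feature table
#'
#' CSV with fixed column order `subject_id, group, mean, sd, min, max,
#' median, variance, entropy, size_pct_lower, size_pct_upper, size_pct_mean,
#' kurtosis, skewness, uniformity, area_cm2`; UTF-8, '.' decimal separator,
#' at least 15 significant digits so `read(write(x))` returns `x` up to
#' float formatting.
#'
#' @param records data frame with the columns above.
#' @param path CSV path.
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` returns the data frame.
#' @export
write_feature_table <- function(records, path) {
  cols <- feature_table_columns()
  missing <- setdiff(cols, names(records))
  if (length(missing)) {
    stop(sprintf("feature table lacks columns: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  records <- records[, cols, drop = FALSE]
  num <- vapply(records, is.numeric, TRUE)
  records[num] <- lapply(records[num], function(v) {
    ifelse(is.na(v), NA, formatC(v, digits = 15, format = "g"))
  })
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8", na = "NA")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  cols <- feature_table_columns()
  unknown <- setdiff(names(tab), cols)
  if (length(unknown)) {
    stop(sprintf("unknown feature table columns: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  missing <- setdiff(cols, names(tab))
  if (length(missing)) {
    stop(sprintf("feature table lacks columns: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  tab[, cols, drop = FALSE]
}
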
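## Minimal single-frame DICOM reader: uncompressed monochrome images in the
## implicit or explicit VR little-endian transfer syntaxes, which covers
## single-slice exports of structural MRI. Sequences, compressed transfer
## syntaxes and multi-frame / RGB objects are rejected explicitly.

u16 <- function(raw2) as.integer(raw2[1]) + 256L * as.integer(raw2[2])
u32 <- function(raw4) sum(as.numeric(raw4) * c(1, 256, 65536, 16777216))

## VRs that use the 4-byte length form (with 2 reserved bytes) in explicit VR
.long_vrs <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")

#' Read a single-frame DICOM image
#'
#' Parses the file meta header, requires the implicit
#' (`1.2.840.10008.1.2`) or explicit (`1.2.840.10008.1.2.1`) VR
#' little-endian transfer syntax, and extracts Rows, Columns, PixelSpacing,
#' BitsAllocated, PixelRepresentation and PixelData. Multi-frame or
#' multi-sample (RGB) objects and missing PixelSpacing raise errors rather
#' than guessing.
#'
#' @param path path to a `.dcm` file.
#' @return An [image_slice] with spacing from PixelSpacing (row, column).
#' @export
read_dicom_image <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  if (length(bytes) < 140 || rawToChar(bytes[129:132]) != "DICM") {
    stop(sprintf("'%s' is not a DICOM part-10 file (no DICM marker)", path),
         call. = FALSE)
  }
  pos <- 133L
  explicit <- TRUE
  ts <- NULL
  tags <- list()
  in_meta <- TRUE
  repeat {
    if (pos + 7L > length(bytes)) break
    group <- u16(bytes[pos:(pos + 1L)])
    elem <- u16(bytes[(pos + 2L):(pos + 3L)])
    pos <- pos + 4L
    if (in_meta && group != 0x0002) {
      ## file meta ended; switch to the negotiated transfer syntax
      in_meta <- FALSE
      if (is.null(ts) || !ts %in% c("1.2.840.10008.1.2", "1.2.840.10008.1.2.1")) {
        stop(sprintf("unsupported transfer syntax '%s' in '%s' (only uncompressed little-endian is supported)",
                     if (is.null(ts)) "<missing>" else ts, path), call. = FALSE)
      }
      explicit <- ts == "1.2.840.10008.1.2.1"
    }
    if (in_meta || explicit) {
      vr <- rawToChar(bytes[pos:(pos + 1L)])
      if (vr %in% .long_vrs) {
        len <- u32(bytes[(pos + 4L):(pos + 7L)])
        pos <- pos + 8L
      } else {
        len <- u16(bytes[(pos + 2L):(pos + 3L)])
        pos <- pos + 4L
      }
    } else {
      vr <- NA_character_
      len <- u32(bytes[pos:(pos + 3L)])
      pos <- pos + 4L
    }
    if (len == 4294967295) {
      stop(sprintf("undefined-length element (%04x,%04x) in '%s': sequences are not supported",
                   group, elem, path), call. = FALSE)
    }
    value <- if (len > 0) bytes[pos:(pos + len - 1L)] else raw(0)
    pos <- pos + len
    key <- sprintf("%04x%04x", group, elem)
    tags[[key]] <- value
    if (key == "00020010") ts <- sub("\\s+$", "", rawToChar(value))
    if (key == "7fe00010") break  # pixel data is last for our purposes
  }

  str_tag <- function(key) {
    v <- tags[[key]]
    if (is.null(v)) return(NULL)
    trimws(rawToChar(v))
  }
  us_tag <- function(key) {
    v <- tags[[key]]
    if (is.null(v)) return(NULL)
    u16(v[1:2])
  }

  frames <- str_tag("00280008")
  if (!is.null(frames) && as.integer(frames) > 1L) {
    stop(sprintf("'%s' is multi-frame (%s frames); only single-frame DICOM is supported",
                 path, frames), call. = FALSE)
  }
  samples <- us_tag("00280002")
  if (!is.null(samples) && samples != 1L) {
    stop(sprintf("'%s' has %d samples per pixel; only monochrome is supported",
                 path, samples), call. = FALSE)
  }
  rows <- us_tag("00280010"); cols <- us_tag("00280011")
  if (is.null(rows) || is.null(cols)) {
    stop(sprintf("'%s' lacks Rows/Columns", path), call. = FALSE)
  }
  spacing_str <- str_tag("00280030")
  if (is.null(spacing_str)) {
    stop(sprintf("'%s' lacks PixelSpacing (0028,0030); spacing is never defaulted", path),
         call. = FALSE)
  }
  spacing <- as.numeric(strsplit(spacing_str, "\\\\")[[1]])
  bits <- us_tag("00280100")
  if (is.null(bits)) bits <- 16L
  signed <- identical(us_tag("00280103"), 1L)
  pd <- tags[["7fe00010"]]
  if (is.null(pd)) stop(sprintf("'%s' lacks PixelData", path), call. = FALSE)
  n <- rows * cols
  vals <- if (bits == 8L) {
    readBin(pd, "integer", n = n, size = 1L, signed = signed)
  } else if (bits == 16L) {
    readBin(pd, "integer", n = n, size = 2L, signed = signed, endian = "little")
  } else {
    stop(sprintf("'%s': unsupported BitsAllocated %d", path, bits), call. = FALSE)
  }
  if (length(vals) < n) {
    stop(sprintf("'%s': PixelData shorter than Rows x Columns", path), call. = FALSE)
  }
  px <- matrix(vals[seq_len(n)], nrow = rows, ncol = cols, byrow = TRUE)
  image_slice(px, spacing = spacing, source_id = path)
}
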
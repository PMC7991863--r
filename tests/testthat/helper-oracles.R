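# Independent brute-force oracles: deliberately written with different
# primitives (explicit sums, table(), sort()) than the package internals.

oracle_features <- function(px) {
  n <- length(px)
  mu <- sum(px) / n
  m2 <- sum((px - mu)^2) / n
  m3 <- sum((px - mu)^3) / n
  m4 <- sum((px - mu)^4) / n
  srt <- sort(px)
  med <- if (n %% 2 == 1) srt[(n + 1) / 2] else (srt[n / 2] + srt[n / 2 + 1]) / 2
  # unit-bin histogram via table() over integer bin labels
  tt <- table(floor(px))
  p <- as.numeric(tt) / n
  s <- sqrt(m2)
  lower <- 100 * sum(px < mu - s) / n
  upper <- 100 * sum(px > mu + s) / n
  list(
    mean = mu, sd = s, min = srt[1], max = srt[n], median = med, variance = m2,
    entropy = -sum(p * log(p)) / log(2),
    uniformity = sum(p^2),
    skewness = if (m2 > 0) m3 / m2^(3 / 2) else NA_real_,
    kurtosis = if (m2 > 0) m4 / m2^2 else NA_real_,
    size_pct_lower = lower, size_pct_upper = upper,
    size_pct_mean = 100 - lower - upper)
}

# a feature_vector computed by the package from a bare pixel vector
pkg_features <- function(px) {
  img <- image_slice(matrix(px, nrow = 1), spacing = c(1, 1))
  msk <- roi_mask(matrix(TRUE, nrow = 1, ncol = length(px)))
  extract_features(img, msk)
}

expect_feature_match <- function(px, tol = 1e-12) {
  got <- pkg_features(px)
  want <- oracle_features(px)
  for (nm in names(want)) {
    if (is.na(want[[nm]])) {
      expect_true(is.na(got[[nm]]), info = nm)
    } else {
      expect_equal(got[[nm]], want[[nm]], tolerance = tol, info = nm)
    }
  }
}

# Minimal DICOM writer used as an independent fixture builder for the
# reader tests: explicit VR little endian, single-frame monochrome.
write_test_dicom <- function(path, pixels, spacing = c(0.9375, 0.9375),
                             bits = 16L, transfer_syntax = "1.2.840.10008.1.2.1") {
  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  even_str <- function(s) if (nchar(s) %% 2 == 1) paste0(s, " ") else s
  elem_short <- function(group, el, vr, value_raw) {
    w16(group); w16(el); writeChar(vr, con, eos = NULL)
    w16(length(value_raw)); writeBin(value_raw, con)
  }
  elem_long <- function(group, el, vr, value_raw) {
    w16(group); w16(el); writeChar(vr, con, eos = NULL)
    w16(0L); w32(length(value_raw)); writeBin(value_raw, con)
  }
  str_raw <- function(s) charToRaw(even_str(s))
  writeBin_raw_u16 <- function(x) {
    r <- raw(2L * length(x))
    x <- as.integer(x)
    r[seq(1, length(r), 2)] <- as.raw(x %% 256L)
    r[seq(2, length(r), 2)] <- as.raw(x %/% 256L)
    r
  }
  writeBin(raw(128), con)
  writeChar("DICM", con, eos = NULL)
  ts_raw <- str_raw(transfer_syntax)
  # (0002,0000) group length = bytes of the one meta element that follows
  elem_short(0x0002, 0x0000, "UL", writeBin_raw_u32(8L + length(ts_raw)))
  elem_short(0x0002, 0x0010, "UI", ts_raw)
  implicit <- transfer_syntax == "1.2.840.10008.1.2"
  elem <- function(group, el, vr, value_raw) {
    if (implicit) {
      w16(group); w16(el); w32(length(value_raw)); writeBin(value_raw, con)
    } else if (vr %in% c("OB", "OW", "SQ", "UN", "UT")) {
      elem_long(group, el, vr, value_raw)
    } else {
      elem_short(group, el, vr, value_raw)
    }
  }
  elem(0x0028, 0x0002, "US", writeBin_raw_u16(1L))          # SamplesPerPixel
  elem(0x0028, 0x0010, "US", writeBin_raw_u16(nrow(pixels)))
  elem(0x0028, 0x0011, "US", writeBin_raw_u16(ncol(pixels)))
  elem(0x0028, 0x0030, "DS", str_raw(sprintf("%g\\%g", spacing[1], spacing[2])))
  elem(0x0028, 0x0100, "US", writeBin_raw_u16(bits))
  elem(0x0028, 0x0103, "US", writeBin_raw_u16(0L))          # unsigned
  vals <- as.integer(t(pixels))                             # row-major
  pd <- if (bits == 8L) as.raw(vals) else writeBin_raw_u16(vals)
  elem(0x7FE0, 0x0010, "OW", pd)
  invisible(path)
}

writeBin_raw_u32 <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, x %/% 256 %% 256, x %/% 65536 %% 256, x %/% 16777216 %% 256))
}

# small null cohort spec: both groups drawn from the control conditions
null_cohort_spec <- function(seed, n = NULL) {
  if (is.null(n)) {
    cohort_spec(case = histofeat:::control_params(), seed = seed)
  } else {
    cohort_spec(n_control = n, n_case = n,
                case = histofeat:::control_params(), seed = seed)
  }
}
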
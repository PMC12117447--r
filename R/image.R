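#' Calibrated grayscale image
#'
#' A 2D grayscale array with a physical pixel size, as used for micrograph
#' spacing analysis. Only in-memory matrices and plain-text numeric grids are
#' supported (see [read_image_matrix()]); real micrographs in binary formats
#' must be converted upstream.
#'
#' @param pixels numeric matrix, at least 64 x 64.
#' @param pixel_size nm per pixel, > 0.
#' @return object of class `calibrated_image`.
#' @export
calibrated_image <- function(pixels, pixel_size) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    abort("pixels must be a numeric matrix", "mesosaxs_validation_error")
  }
  if (nrow(pixels) < 64L || ncol(pixels) < 64L) {
    abort("image must be at least 64x64", "mesosaxs_validation_error")
  }
  if (!is.finite(pixel_size) || pixel_size <= 0) {
    abort("pixel_size must be > 0", "mesosaxs_validation_error")
  }
  structure(list(pixels = pixels, pixel_size = pixel_size),
            class = "calibrated_image")
}

#' Read a calibrated image from a plain-text numeric grid
#'
#' @param path delimited text file (comma/tab/whitespace), one image row per
#'   line, `#` comments allowed.
#' @param pixel_size nm per pixel.
#' @return a [calibrated_image()].
#' @export
read_image_matrix <- function(path, pixel_size) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  sep <- if (any(grepl(",", lines))) "," else ""
  df <- utils::read.table(text = lines, sep = sep, header = FALSE)
  calibrated_image(as.matrix(df), pixel_size)
}

#' Lattice row spacing from the 2D power spectrum
#'
#' Hann-windows the mean-subtracted image, takes the 2D FFT power spectrum,
#' and locates the strongest bin outside a DC guard band. The spacing is the
#' reciprocal of that spatial frequency; the uncertainty is the spacing change
#' across one frequency bin. Rotation of the lattice does not move the radial
#' position of the first-order spots, so the estimate is orientation-free.
#'
#' @param image a [calibrated_image()] showing quasi-periodic contrast.
#' @param opts list: `guard_bins` (DC guard radius in bins, default 3),
#'   `prominence` (required ratio of the peak power to the median off-DC
#'   power, default 10).
#' @return list with `spacing` (nm), `uncertainty` (nm, one-bin width),
#'   `frequency` (cycles/nm), `power_ratio`.
#' @export
fft_row_spacing <- function(image, opts = list()) {
  stopifnot(inherits(image, "calibrated_image"))
  guard <- opts$guard_bins %||% 3
  prominence <- opts$prominence %||% 10

  img <- image$pixels
  n1 <- nrow(img); n2 <- ncol(img)
  img <- img - mean(img)
  w <- outer(hann_window(n1), hann_window(n2))
  P <- Mod(stats::fft(img * w))^2

  f1 <- fft_freq(n1)
  f2 <- fft_freq(n2)
  fr <- sqrt(outer(f1^2, f2^2, `+`))  # cycles per pixel
  nmin <- min(n1, n2)
  sel <- fr > guard / nmin
  if (!any(sel)) abort("image too small for guard band", "mesosaxs_validation_error")
  Psel <- P[sel]
  peak <- max(Psel)
  med <- stats::median(Psel)
  if (peak <= 0 || peak < prominence * (med + .Machine$double.xmin)) {
    abort("no spectral peak above prominence threshold (no periodicity found)",
          "mesosaxs_no_periodicity_error")
  }
  i_peak <- which(sel)[which.max(Psel)]
  f_peak <- fr[i_peak] / image$pixel_size        # cycles per nm
  df <- 1 / (nmin * image$pixel_size)            # one-bin width, cycles per nm
  spacing <- 1 / f_peak
  unc <- 0.5 * abs(1 / (f_peak - df) - 1 / (f_peak + df))
  list(spacing = spacing, uncertainty = unc, frequency = f_peak,
       power_ratio = peak / med)
}

hann_window <- function(n) {
  0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
}

fft_freq <- function(n) {
  k <- seq_len(n) - 1L
  ifelse(k <= n %/% 2, k, k - n) / n
}

#' Segment a calibrated grayscale line profile at a background level
#'
#' Thresholds the profile at `background_level`; contiguous runs above the
#' threshold are light sections (e.g. water channels), runs below are dark
#' sections (amphiphile); the partial runs touching either end are discarded.
#' The period is the mean of adjacent light+dark pairs.
#'
#' @param profile numeric vector of gray values along the line.
#' @param pixel_size nm per sample.
#' @param background_level threshold gray value; defaults to the profile
#'   median (messaged).
#' @return a `profile_segmentation` list: `light_nm`, `dark_nm`, `period_nm`,
#'   `threshold`.
#' @export
profile_segments <- function(profile, pixel_size, background_level = NULL) {
  if (!is.numeric(profile) || length(profile) < 8L) {
    abort("profile must be a numeric vector of length >= 8",
          "mesosaxs_validation_error")
  }
  if (!is.finite(pixel_size) || pixel_size <= 0) {
    abort("pixel_size must be > 0", "mesosaxs_validation_error")
  }
  if (is.null(background_level)) {
    background_level <- stats::median(profile)
    message(sprintf("profile_segments: using profile median %.4g as background level",
                    background_level))
  }
  above <- profile > background_level
  n_cross <- sum(diff(above) != 0)
  if (n_cross < 4L) {
    abort("profile crosses the background level fewer than 4 times",
          "mesosaxs_insufficient_profile_error")
  }
  runs <- rle(above)
  m <- length(runs$lengths)
  if (m < 4L) {
    abort("insufficient profile: fewer than 2 complete periods",
          "mesosaxs_insufficient_profile_error")
  }
  interior <- 2:(m - 1L)  # drop boundary partial runs
  lens <- runs$lengths[interior] * pixel_size
  vals <- runs$values[interior]
  light <- lens[vals]
  dark <- lens[!vals]
  if (length(light) < 2L || length(dark) < 2L) {
    abort("insufficient profile: fewer than 2 complete periods",
          "mesosaxs_insufficient_profile_error")
  }
  # adjacent light+dark pairs, non-overlapping
  n_pairs <- length(lens) %/% 2L
  period <- mean(lens[2 * seq_len(n_pairs) - 1L] + lens[2 * seq_len(n_pairs)])
  structure(list(light_nm = light, dark_nm = dark, period_nm = period,
                 threshold = background_level),
            class = "profile_segmentation")
}

#' Planar-to-spatial distance correction for hexagonal packing
#'
#' In a 2D projection of a hexagonal lattice the measured row-to-row distance
#' underestimates the true tube-to-tube distance by a factor sqrt(3)/2; this
#' converts a planar row spacing to the 3D nearest-neighbour distance by
#' multiplying by 2/sqrt(3) (about 1.155).
#'
#' @param distance planar distance(s), nm, > 0.
#' @return spatial distance(s), nm.
#' @export
planar_to_spatial <- function(distance) {
  if (any(!is.finite(distance)) || any(distance <= 0)) {
    abort("distance must be > 0", "mesosaxs_validation_error")
  }
  distance * 2 / sqrt(3)
}
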
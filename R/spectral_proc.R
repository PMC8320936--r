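# Reconstruction of complex A-lines from raw spectra: background subtraction,
# k-linearization, apodization, FFT and log scaling.

#' Raw spectral frame container
#'
#' @param spectra Numeric matrix, camera pixel x A-line.
#' @param wavelength_nm Strictly increasing wavelength grid (nm), one entry
#'   per pixel row.
#' @param timestamps_us A-line timestamps in microseconds, strictly increasing
#'   with constant spacing equal to `line_period_us`.
#' @param line_period_us Line period in microseconds.
#' @param k_linear Logical flag: has the frame been resampled uniformly in
#'   wavenumber? Set by [k_linearize()].
#' @return An object of class `spectral_frame`.
#' @export
spectral_frame <- function(spectra, wavelength_nm, timestamps_us,
                           line_period_us, k_linear = FALSE) {
  spectra <- as.matrix(spectra)
  if (length(wavelength_nm) != nrow(spectra))
    .fail("wavelength grid length must equal the pixel dimension of 'spectra'")
  if (any(diff(wavelength_nm) <= 0))
    .fail("'wavelength_nm' must be strictly increasing")
  if (length(timestamps_us) != ncol(spectra))
    .fail("'timestamps_us' length must equal the number of A-lines")
  if (ncol(spectra) > 1 && any(diff(timestamps_us) <= 0))
    .fail("'timestamps_us' must be strictly increasing")
  structure(
    list(spectra = spectra, wavelength_nm = as.numeric(wavelength_nm),
         timestamps_us = as.numeric(timestamps_us),
         line_period_us = line_period_us, k_linear = isTRUE(k_linear)),
    class = "spectral_frame")
}

#' @export
print.spectral_frame <- function(x, ...) {
  cat(sprintf(
    "<spectral_frame> %d pixels x %d A-lines, %.1f-%.1f nm, line period %g us%s\n",
    nrow(x$spectra), ncol(x$spectra), min(x$wavelength_nm),
    max(x$wavelength_nm), x$line_period_us,
    if (x$k_linear) ", k-linearized" else ""))
  invisible(x)
}

#' Subtract the mean background spectrum
#'
#' Subtracts the per-pixel mean across A-lines from every A-line, removing the
#' (dominant) reference-arm DC term before reconstruction. Note that with a
#' stationary beam the mean also contains the time-average of any moving
#' reflector's fringe; see the package vignette for when this matters.
#'
#' @param frame A [spectral_frame()] with at least 2 A-lines.
#' @return A `spectral_frame` whose per-pixel mean across A-lines is zero.
#' @export
subtract_background <- function(frame) {
  if (ncol(frame$spectra) < 2L)
    .fail("background subtraction needs at least 2 A-lines")
  frame$spectra <- frame$spectra - rowMeans(frame$spectra)
  frame
}

#' Resample spectra to a grid uniform in wavenumber (k-linearization)
#'
#' Spectrometer pixels are uniform in wavelength, hence nonuniform in
#' wavenumber k = 2*pi/lambda; an FFT over such samples produces a chirped,
#' depth-dependent axial blur. This resamples every A-line by interpolation
#' onto a grid uniform in k with the same endpoints and pixel count, and
#' stores the new grid as equivalent wavelengths.
#'
#' @param frame A [spectral_frame()] with a strictly monotone wavelength grid.
#' @param method Interpolation method: `"spline"` (cubic, the default) or
#'   `"linear"`.
#' @return A `spectral_frame` with `k_linear = TRUE`.
#' @export
k_linearize <- function(frame, method = c("spline", "linear")) {
  method <- match.arg(method)
  wl <- frame$wavelength_nm
  if (any(diff(wl) <= 0))
    .fail("wavelength grid must be strictly monotone")
  k_in <- 2 * pi / wl                     # strictly decreasing
  n <- length(wl)
  k_out <- seq(k_in[1], k_in[n], length.out = n)  # uniform in k, decreasing
  resample <- function(y) {
    if (method == "spline")
      stats::spline(rev(k_in), rev(y), xout = rev(k_out), method = "fmm")$y
    else
      stats::approx(rev(k_in), rev(y), xout = rev(k_out))$y
  }
  out <- apply(frame$spectra, 2L, function(col) rev(resample(col)))
  frame$spectra <- matrix(out, nrow = n)
  frame$wavelength_nm <- 2 * pi / k_out   # increasing again
  frame$k_linear <- TRUE
  frame
}

#' Apodize spectra with a spectral window
#'
#' Per-pixel multiplication by a window to control point-spread-function
#' sidelobes. `"none"` is the identity; `"hann"` gives the classic -31.5 dB
#' first sidelobe; `"gaussian"` uses sd = pixel_count/6.
#'
#' @param frame A [spectral_frame()].
#' @param window One of `"none"`, `"hann"`, `"gaussian"`.
#' @return The windowed `spectral_frame`.
#' @export
apodize <- function(frame, window = c("hann", "none", "gaussian")) {
  if (!is.character(window) || !(window[1] %in% c("hann", "none", "gaussian")))
    .fail("unknown window name: ", window[1])
  window <- window[1]
  n <- nrow(frame$spectra)
  w <- switch(window,
    none = return(frame),
    hann = 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1))),
    gaussian = exp(-0.5 * ((seq_len(n) - (n + 1) / 2) / (n / 6))^2))
  frame$spectra <- frame$spectra * w
  frame
}

#' Complex B-scan container
#'
#' Holds the complex reconstructed field (depth bin x A-line); the real and
#' imaginary parts are the in-phase (I) and quadrature (Q) components used by
#' the Kasai estimator.
#'
#' @param field Complex matrix, depth bin x A-line.
#' @param depth_axis_um Depth of each bin in air-equivalent micrometers.
#' @param line_period_us Line period in microseconds.
#' @param timestamps_us Optional A-line timestamps (microseconds).
#' @return An object of class `complex_bscan`.
#' @export
complex_bscan <- function(field, depth_axis_um, line_period_us,
                          timestamps_us = NULL) {
  field <- as.matrix(field)
  if (length(depth_axis_um) != nrow(field))
    .fail("'depth_axis_um' length must equal the depth dimension")
  structure(list(field = field, depth_axis_um = as.numeric(depth_axis_um),
                 line_period_us = line_period_us,
                 timestamps_us = timestamps_us),
            class = "complex_bscan")
}

#' @export
print.complex_bscan <- function(x, ...) {
  cat(sprintf("<complex_bscan> %d depth bins x %d A-lines, 0-%.0f um\n",
              nrow(x$field), ncol(x$field), max(x$depth_axis_um)))
  invisible(x)
}

#' Fourier-transform spectra into complex A-scans
#'
#' Per-A-line FFT along the (k-ordered) pixel axis with zero padding; the
#' positive-depth half is retained and complex values are preserved so that
#' the Kasai estimator can use I and Q. The depth axis follows from the
#' wavenumber span: bin j sits at z = pi*j / (n_fft * dk), in air-equivalent
#' units (divide by the medium index only in physical conversions).
#'
#' @param frame A k-linearized [spectral_frame()]; passing a frame that has
#'   not gone through [k_linearize()] is a contract violation unless
#'   `force = TRUE` (used for ablation comparisons).
#' @param pad_factor Zero-padding factor (default 2), halving depth-bin
#'   quantization in peak-location analyses.
#' @param force Skip the k-linearization flag check.
#' @return A [complex_bscan()].
#' @export
to_ascans <- function(frame, pad_factor = 2, force = FALSE) {
  if (!frame$k_linear && !force)
    .fail("frame is not k-linearized; run k_linearize() first ",
          "(or use force = TRUE for ablation)")
  .check_scalar(pad_factor, "pad_factor", lower = 1, integer = TRUE)
  n <- nrow(frame$spectra)
  # order pixels by increasing k (wavelength grid is increasing => k decreasing)
  x <- frame$spectra[rev(seq_len(n)), , drop = FALSE]
  k <- rev(2 * pi / frame$wavelength_nm)
  nfft <- pad_factor * n
  xp <- rbind(x, matrix(0, nfft - n, ncol(x)))
  ff <- stats::mvfft(xp)
  keep <- nfft %/% 2L
  field <- ff[seq_len(keep), , drop = FALSE]
  dk <- (k[n] - k[1]) / (n - 1)           # rad/nm
  depth_nm <- pi * (seq_len(keep) - 1) / (nfft * dk)
  complex_bscan(field, depth_nm * 1e-3, frame$line_period_us,
                frame$timestamps_us)
}

#' Log-scaled structural image
#'
#' Computes 20*log10((|field| + eps) / max|field|) with eps = 1e-12 of the
#' peak magnitude (so the result is finite everywhere and the peak sits at
#' 0 dB), then clips to the display range.
#'
#' @param bscan A [complex_bscan()].
#' @param floor_db,ceiling_db Display range in dB (floor < ceiling).
#' @return An object of class `structural_image` with fields
#'   `log_magnitude_db`, `floor_db`, `ceiling_db`, `depth_axis_um`.
#' @export
log_magnitude <- function(bscan, floor_db = -60, ceiling_db = 0) {
  if (!(floor_db < ceiling_db)) .fail("'floor_db' must be below 'ceiling_db'")
  mag <- Mod(bscan$field)
  mx <- max(mag)
  if (mx == 0) mx <- 1
  eps <- 1e-12 * mx
  db <- 20 * log10((mag + eps) / mx)
  db <- pmin(pmax(db, floor_db), ceiling_db)
  structure(list(log_magnitude_db = db, floor_db = floor_db,
                 ceiling_db = ceiling_db,
                 depth_axis_um = bscan$depth_axis_um),
            class = "structural_image")
}

#' Full reconstruction chain from a raw frame
#'
#' Convenience wrapper: optional background subtraction, k-linearization,
#' apodization and FFT, in that order.
#'
#' @param frame A raw [spectral_frame()].
#' @param window Apodization window (see [apodize()]).
#' @param background `"mean"` to apply [subtract_background()], `"none"` to
#'   skip it (appropriate for fixed-beam Doppler acquisitions; see vignette).
#' @param interp Interpolation method for [k_linearize()].
#' @param pad_factor Passed to [to_ascans()].
#' @return A [complex_bscan()].
#' @export
reconstruct_bscan <- function(frame, window = "hann",
                              background = c("none", "mean"),
                              interp = "spline", pad_factor = 2) {
  background <- match.arg(background)
  if (background == "mean") frame <- subtract_background(frame)
  frame <- k_linearize(frame, method = interp)
  frame <- apodize(frame, window)
  to_ascans(frame, pad_factor = pad_factor)
}
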
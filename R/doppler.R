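# Kasai autocorrelation Doppler phase estimation between adjacent A-lines,
# conversion to Doppler frequency and velocity, and Nyquist/aliasing helpers.

#' Doppler estimation configuration
#'
#' @param window_depth Spatial averaging window size M along depth (>= 1).
#' @param window_lateral Number N of A-lines spanned by the averaging window
#'   (>= 2), i.e. N-1 adjacent A-line pairs enter each estimate.
#' @param line_rate_hz A-line rate in Hz (1/line_period); if `NULL` it is
#'   taken from the B-scan's line period when needed.
#' @param center_wavelength_nm Source center wavelength lambda0 (nm).
#' @param medium_index Tissue refractive index nt (>= 1).
#' @param beam_angle_rad Angle theta between the beam and the motion axis
#'   (0 <= theta < pi/2).
#' @param mask_threshold_db Structural-intensity threshold (dB relative to the
#'   image peak) below which Doppler values are masked out.
#' @param edge Border policy for the averaging window: `"shrink"` (window
#'   shrinks at image borders, no padding) or `"strict"` (error if the window
#'   does not fit the image).
#' @return An object of class `doppler_config`.
#' @export
doppler_config <- function(window_depth = 4, window_lateral = 4,
                           line_rate_hz = NULL, center_wavelength_nm = 850,
                           medium_index = 1, beam_angle_rad = 0,
                           mask_threshold_db = -30,
                           edge = c("shrink", "strict")) {
  .check_scalar(window_depth, "window_depth", lower = 1, integer = TRUE)
  .check_scalar(window_lateral, "window_lateral", lower = 2, integer = TRUE)
  if (!is.null(line_rate_hz))
    .check_scalar(line_rate_hz, "line_rate_hz", lower = 0, strict_lower = TRUE)
  .check_scalar(center_wavelength_nm, "center_wavelength_nm", lower = 0,
                strict_lower = TRUE)
  .check_scalar(medium_index, "medium_index", lower = 1)
  .check_scalar(beam_angle_rad, "beam_angle_rad", lower = 0, upper = pi / 2,
                strict_upper = TRUE)
  .check_scalar(mask_threshold_db, "mask_threshold_db")
  structure(list(window_depth = as.integer(window_depth),
                 window_lateral = as.integer(window_lateral),
                 line_rate_hz = line_rate_hz,
                 center_wavelength_nm = center_wavelength_nm,
                 medium_index = medium_index, beam_angle_rad = beam_angle_rad,
                 mask_threshold_db = mask_threshold_db,
                 edge = match.arg(edge)),
            class = "doppler_config")
}

.line_rate <- function(cfg, obj) {
  if (!is.null(cfg$line_rate_hz)) return(cfg$line_rate_hz)
  if (!is.null(obj$line_period_us)) return(1e6 / obj$line_period_us)
  .fail("line rate unavailable: set 'line_rate_hz' in doppler_config()")
}

#' Kasai autocorrelation phase estimation
#'
#' For each depth bin and adjacent A-line pair, forms the lag-one complex
#' autocorrelation conj(z[m, n]) * z[m, n+1] and sums it over an M x (N-1)
#' spatial window centred on the output pixel (shrinking at borders). The
#' phase is the four-quadrant arctangent
#' atan2(sum(I_n Q_{n+1} - Q_n I_{n+1}), sum(I_n I_{n+1} + Q_n Q_{n+1})),
#' identically arg(sum conj(z_n) z_{n+1}), in (-pi, pi] with the +pi boundary
#' mapped positive. Increasing optical path between acquisitions gives a
#' positive phase.
#'
#' @param bscan A [complex_bscan()] with at least 2 A-lines.
#' @param cfg A [doppler_config()].
#' @return An object of class `doppler_phase_map` with fields `phase`
#'   (radians, depth bin x A-line pair), `valid_mask` (all `TRUE` until a mask
#'   is applied via [apply_mask()]), `line_period_us` and `pair_timestamps_us`
#'   (midpoints of the paired A-line timestamps, when available).
#' @export
kasai_phase <- function(bscan, cfg = doppler_config()) {
  f <- bscan$field
  l <- ncol(f)
  if (l < 2L) .fail("Kasai estimation needs at least 2 A-lines")
  m <- cfg$window_depth
  n <- cfg$window_lateral
  if (cfg$edge == "strict" && (m > nrow(f) || (n - 1L) > (l - 1L)))
    .fail("averaging window larger than the image (edge policy 'strict')")
  lag1 <- Conj(f[, -l, drop = FALSE]) * f[, -1L, drop = FALSE]
  acc <- .boxsum(lag1, m, n - 1L)
  phase <- atan2(Im(acc), Re(acc))
  phase[phase == -pi] <- pi
  pair_ts <- if (!is.null(bscan$timestamps_us))
    (bscan$timestamps_us[-l] + bscan$timestamps_us[-1L]) / 2 else NULL
  structure(list(phase = phase,
                 valid_mask = matrix(TRUE, nrow(phase), ncol(phase)),
                 line_period_us = bscan$line_period_us,
                 pair_timestamps_us = pair_ts),
            class = "doppler_phase_map")
}

#' @export
print.doppler_phase_map <- function(x, ...) {
  cat(sprintf("<doppler_phase_map> %d depth bins x %d A-line pairs, %.0f%% valid\n",
              nrow(x$phase), ncol(x$phase), 100 * mean(x$valid_mask)))
  invisible(x)
}

#' Apply a structural validity mask to a Doppler phase map
#'
#' A structural mask has one column per A-line; a phase-map pixel (pair n)
#' is valid only if both contributing A-lines (n and n+1) are above threshold.
#' Masked pixels carry phase 0 with `valid_mask` `FALSE` (never `NA`).
#'
#' @param pmap A [kasai_phase()] result.
#' @param mask Logical matrix from [intensity_mask()] (depth x A-lines), or
#'   already depth x pairs.
#' @return The masked `doppler_phase_map`.
#' @export
apply_mask <- function(pmap, mask) {
  p <- ncol(pmap$phase)
  if (ncol(mask) == p + 1L)
    mask <- mask[, -(p + 1L), drop = FALSE] & mask[, -1L, drop = FALSE]
  if (!all(dim(mask) == dim(pmap$phase)))
    .fail("mask dimensions do not match the phase map")
  pmap$valid_mask <- pmap$valid_mask & mask
  pmap$phase[!pmap$valid_mask] <- 0
  pmap
}

#' Convert Doppler phase to Doppler frequency
#'
#' fD = delta_phi * line_rate / (2*pi). The largest representable |fD| is
#' line_rate/2 (the Nyquist limit); with a 100 us line period that is 5 kHz.
#'
#' @param pmap A [kasai_phase()] result (or a numeric phase matrix/vector in
#'   radians).
#' @param cfg A [doppler_config()]; the line rate is taken from the config or,
#'   failing that, from the phase map's line period.
#' @return Doppler frequency in Hz, same shape as the input phase.
#' @export
phase_to_frequency <- function(pmap, cfg = doppler_config()) {
  phase <- if (inherits(pmap, "doppler_phase_map")) pmap$phase else pmap
  rate <- .line_rate(cfg, if (is.list(pmap)) pmap else NULL)
  phase * rate / (2 * pi)
}

#' Convert Doppler frequency to axial velocity
#'
#' v = lambda0 * fD / (2 * nt * cos(theta)), signed, in micrometers/second.
#'
#' @param frequency_hz Doppler frequency in Hz (scalar, vector or matrix).
#' @param cfg A [doppler_config()]; `beam_angle_rad` = pi/2 is rejected
#'   (cosine would vanish).
#' @return Velocity in um/s, same shape as `frequency_hz`.
#' @export
#' @examples
#' cfg <- doppler_config(center_wavelength_nm = 850)
#' doppler_velocity(5000, cfg)   # 2125 um/s = 2.125 mm/s
doppler_velocity <- function(frequency_hz, cfg = doppler_config()) {
  cth <- cos(cfg$beam_angle_rad)
  if (cth <= 0) .fail("beam angle of pi/2 makes cos(theta) vanish")
  cfg$center_wavelength_nm * 1e-3 * frequency_hz /
    (2 * cfg$medium_index * cth)
}

#' Velocity map from a Doppler phase map
#'
#' @param pmap A [kasai_phase()] result.
#' @param cfg A [doppler_config()].
#' @return An object of class `velocity_map` with matrices `frequency_hz`
#'   and `velocity_um_s` satisfying v = lambda0*fD/(2*nt*cos(theta))
#'   element-wise.
#' @export
velocity_map <- function(pmap, cfg = doppler_config()) {
  fd <- phase_to_frequency(pmap, cfg)
  structure(list(frequency_hz = fd,
                 velocity_um_s = doppler_velocity(fd, cfg),
                 valid_mask = pmap$valid_mask),
            class = "velocity_map")
}

#' Nyquist limit of the A-line sampling
#'
#' The highest Doppler/vibration frequency representable without aliasing is
#' half the A-line rate: 1 / (2 * line_period).
#'
#' @param line_period_us Line period in microseconds (> 0).
#' @return Frequency in Hz (100 us -> 5000 Hz).
#' @export
nyquist_limit <- function(line_period_us) {
  .check_scalar(line_period_us, "line_period_us", lower = 0,
                strict_lower = TRUE)
  1 / (2 * line_period_us * 1e-6)
}

#' Apparent (aliased) frequency after sampling
#'
#' Standard folding: apparent = |f - round(f / rate) * rate|, always at most
#' rate/2. An 8 kHz vibration sampled at a 10 kHz line rate appears at 2 kHz.
#'
#' @param true_freq_hz True stimulus frequency in Hz (> 0).
#' @param line_rate_hz Sampling (A-line) rate in Hz (> 0).
#' @return Apparent frequency in Hz.
#' @export
alias_frequency <- function(true_freq_hz, line_rate_hz) {
  if (any(true_freq_hz <= 0) || any(line_rate_hz <= 0))
    .fail("frequencies must be positive")
  abs(true_freq_hz - round(true_freq_hz / line_rate_hz) * line_rate_hz)
}

#' Structural-intensity validity mask
#'
#' Doppler values are only meaningful where structural signal exists; the
#' mask is `TRUE` where the log magnitude is at or above the threshold.
#'
#' @param structural A [log_magnitude()] image.
#' @param threshold_db Threshold in dB, within `[floor_db, ceiling_db]`.
#' @return Logical matrix (depth x A-lines).
#' @export
intensity_mask <- function(structural, threshold_db) {
  if (threshold_db < structural$floor_db ||
      threshold_db > structural$ceiling_db)
    .fail("'threshold_db' must lie within [floor_db, ceiling_db]")
  structural$log_magnitude_db >= threshold_db
}

#' Dominant frequency of a sampled trace
#'
#' Locates the peak of the magnitude spectrum of a (mean-removed) trace, with
#' parabolic interpolation of the peak bin for sub-bin resolution. Used to
#' read the apparent vibration frequency off a recovered Doppler phase trace.
#'
#' @param x Numeric vector, sampled at `fs_hz`.
#' @param fs_hz Sampling rate in Hz.
#' @return Dominant frequency in Hz.
#' @export
dominant_frequency <- function(x, fs_hz) {
  n <- length(x)
  if (n < 4) .fail("trace too short for frequency estimation")
  sp <- Mod(stats::fft(x - mean(x)))[seq_len(n %/% 2)]
  j <- which.max(sp[-1]) + 1L           # skip the DC bin
  delta <- 0
  if (j > 2 && j < length(sp)) {
    a <- sp[j - 1]; b <- sp[j]; c <- sp[j + 1]
    den <- a - 2 * b + c
    if (den != 0) delta <- 0.5 * (a - c) / den
  }
  (j - 1 + delta) * fs_hz / n
}
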
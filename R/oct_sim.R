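# Synthetic spectrometer-based OCT interferograms of a layered, vibrating
# phantom. The forward model is the standard SD-OCT fringe equation
#   I(lambda) = S(lambda) * [1 + sum_r 2*sqrt(R_r) * cos(4*pi*n*z_r(t)/lambda)]
# averaged over sub-instants spanning the camera exposure (this averaging IS
# the fringe-washout model), plus seeded additive Gaussian noise.

#' Broadband source spectrum on a wavelength-uniform camera grid
#'
#' Builds a Gaussian spectral envelope with the stated full width at half
#' maximum on a pixel grid uniform in wavelength. Real spectrometers sample
#' uniformly in wavelength, hence nonuniformly in wavenumber k = 2*pi/lambda;
#' the deliberate nonuniformity is what [k_linearize()] later removes.
#'
#' @param center_nm Center wavelength in nm (default 850, a typical
#'   superluminescent diode for middle-ear imaging).
#' @param fwhm_nm Full width at half maximum of the envelope in nm (default 55).
#' @param pixel_count Number of camera pixels (>= 16).
#' @param span_factor Half-span of the grid in units of the FWHM (default 1.6),
#'   so the grid covers center +/- span_factor * fwhm.
#' @return An object of class `source_spectrum` with fields
#'   `center_wavelength_nm`, `fwhm_nm`, `pixel_count`, `wavelength_nm`
#'   (strictly increasing) and `envelope` (nonnegative, peak at the pixel
#'   nearest the center wavelength).
#' @export
#' @examples
#' src <- make_source(850, 55, 256)
#' src$wavelength_nm[which.max(src$envelope)]
make_source <- function(center_nm = 850, fwhm_nm = 55, pixel_count = 1024,
                        span_factor = 1.6) {
  .check_scalar(center_nm, "center_nm", lower = 0, strict_lower = TRUE)
  .check_scalar(fwhm_nm, "fwhm_nm", lower = 0, strict_lower = TRUE)
  .check_scalar(pixel_count, "pixel_count", lower = 16, integer = TRUE)
  .check_scalar(span_factor, "span_factor", lower = 0, strict_lower = TRUE)
  wl <- seq(center_nm - span_factor * fwhm_nm,
            center_nm + span_factor * fwhm_nm,
            length.out = pixel_count)
  env <- exp(-4 * log(2) * ((wl - center_nm) / fwhm_nm)^2)
  structure(
    list(center_wavelength_nm = center_nm, fwhm_nm = fwhm_nm,
         pixel_count = as.integer(pixel_count), wavelength_nm = wl,
         envelope = env),
    class = "source_spectrum")
}

#' Point reflector in the sample arm
#'
#' @param depth_um One-way optical path depth in micrometers (in air), > 0.
#' @param reflectivity Power reflectivity in (0, 1].
#' @param label Text label used to address the reflector from a
#'   [vib_stimulus()] (e.g. `"thick TM"`, `"malleus"`).
#' @return An object of class `reflector`.
#' @export
reflector <- function(depth_um, reflectivity, label = "reflector") {
  .check_scalar(depth_um, "depth_um", lower = 0, strict_lower = TRUE)
  .check_scalar(reflectivity, "reflectivity", lower = 0, upper = 1,
                strict_lower = TRUE)
  structure(list(depth_um = depth_um, reflectivity = reflectivity,
                 label = as.character(label)),
            class = "reflector")
}

#' Sinusoidal vibration stimulus
#'
#' Describes a pure-tone acoustic stimulus driving one or more reflectors:
#' displacement a*sin(2*pi*f*t + phi0) along the motion axis. Frequency 0
#' means the no-sound control; its amplitude is ignored.
#'
#' @param frequency_hz Stimulus frequency in Hz (>= 0; 0 = control).
#' @param amplitude_nm Displacement amplitude in nm (>= 0).
#' @param phase_rad Phase offset in radians.
#' @param targets Character vector of reflector labels that move, or `NULL`
#'   (the default) to move every reflector.
#' @return An object of class `vib_stimulus`.
#' @export
vib_stimulus <- function(frequency_hz, amplitude_nm = 0, phase_rad = 0,
                         targets = NULL) {
  .check_scalar(frequency_hz, "frequency_hz", lower = 0)
  .check_scalar(amplitude_nm, "amplitude_nm", lower = 0)
  .check_scalar(phase_rad, "phase_rad")
  structure(list(waveform = "sine", frequency_hz = frequency_hz,
                 amplitude_nm = amplitude_nm, phase_rad = phase_rad,
                 targets = targets),
            class = "vib_stimulus")
}

#' Constant-velocity drift stimulus
#'
#' Linear motion z(t) = z0 + v*t, used to probe fringe washout: a drift fast
#' enough to sweep the round-trip phase during one exposure attenuates the
#' fringe by |sinc(delta_phi/2)|.
#'
#' @param velocity_nm_per_s Drift velocity in nm/s (signed).
#' @param targets As in [vib_stimulus()].
#' @return An object of class `vib_stimulus` with waveform `"linear"`.
#' @export
drift_stimulus <- function(velocity_nm_per_s, targets = NULL) {
  .check_scalar(velocity_nm_per_s, "velocity_nm_per_s")
  structure(list(waveform = "linear", frequency_hz = 0, amplitude_nm = 0,
                 phase_rad = 0, velocity_nm_per_s = velocity_nm_per_s,
                 targets = targets),
            class = "vib_stimulus")
}

#' No-sound control stimulus
#' @return A `vib_stimulus` with frequency 0 (no motion).
#' @export
control_stimulus <- function() vib_stimulus(0, 0)

# Displacement (um) contributed by one stimulus at times t_s (seconds).
.stimulus_displacement_um <- function(stimulus, t_s) {
  if (identical(stimulus$waveform, "linear"))
    return(stimulus$velocity_nm_per_s * 1e-3 * t_s)
  if (stimulus$frequency_hz <= 0 || stimulus$amplitude_nm <= 0)
    return(rep(0, length(t_s)))
  stimulus$amplitude_nm * 1e-3 *
    sin(2 * pi * stimulus$frequency_hz * t_s + stimulus$phase_rad)
}

#' Instantaneous reflector position under a stimulus
#'
#' @param stimulus A [vib_stimulus()] (or [drift_stimulus()]).
#' @param base_depth_um Rest depth in micrometers.
#' @param t_s Time(s) in seconds, >= 0.
#' @return Position(s) in micrometers: `base_depth_um + displacement(t)`;
#'   a control stimulus returns `base_depth_um` at all times.
#' @export
#' @examples
#' st <- vib_stimulus(1000, amplitude_nm = 100)
#' reflector_position(st, 300, 0.25e-3) # quarter period: 300 um + 100 nm
reflector_position <- function(stimulus, base_depth_um, t_s) {
  if (any(t_s < 0)) .fail("'t_s' must be nonnegative")
  base_depth_um + .stimulus_displacement_um(stimulus, t_s)
}

#' Acquisition configuration of the line-scan camera
#'
#' @param line_period_us Camera line period in microseconds (default 100,
#'   i.e. a 10 kHz A-line rate).
#' @param exposure_fraction Exposure duty cycle in (0, 1] (default 0.9;
#'   near-full duty is typical for line cameras).
#' @param alines_per_frame Number of A-lines per B-scan frame.
#' @param exposure_oversampling Number of sub-instants over which each
#'   exposure is averaged (>= 1); this averaging is the fringe-washout model.
#' @param noise_sd Additive Gaussian noise standard deviation, relative to the
#'   envelope peak (default 1e-3).
#' @param rng_seed Integer seed; identical seed + configuration gives
#'   bit-identical frames.
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(line_period_us = 100, exposure_fraction = 0.9,
                               alines_per_frame = 64,
                               exposure_oversampling = 16,
                               noise_sd = 1e-3, rng_seed = 1L) {
  .check_scalar(line_period_us, "line_period_us", lower = 0,
                strict_lower = TRUE)
  .check_scalar(exposure_fraction, "exposure_fraction", lower = 0, upper = 1,
                strict_lower = TRUE)
  .check_scalar(alines_per_frame, "alines_per_frame", lower = 1,
                integer = TRUE)
  .check_scalar(exposure_oversampling, "exposure_oversampling", lower = 1,
                integer = TRUE)
  .check_scalar(noise_sd, "noise_sd", lower = 0)
  .check_scalar(rng_seed, "rng_seed", integer = TRUE)
  structure(
    list(line_period_us = line_period_us,
         exposure_fraction = exposure_fraction,
         alines_per_frame = as.integer(alines_per_frame),
         exposure_oversampling = as.integer(exposure_oversampling),
         noise_sd = noise_sd, rng_seed = as.integer(rng_seed)),
    class = "acquisition_config")
}

#' Layered sample phantom
#'
#' @param reflectors List of [reflector()] objects.
#' @param medium_index Refractive index of the medium (>= 1).
#' @param beam_angle_rad Angle between the motion axis and the sample-arm
#'   beam, in radians (0 <= angle < pi/2); motion projects onto the beam by
#'   cos(beam_angle_rad).
#' @return An object of class `sample_phantom`.
#' @export
sample_phantom <- function(reflectors, medium_index = 1,
                           beam_angle_rad = 0) {
  if (!is.list(reflectors) ||
      !all(vapply(reflectors, inherits, TRUE, "reflector")))
    .fail("'reflectors' must be a list of reflector() objects")
  .check_scalar(medium_index, "medium_index", lower = 1)
  .check_scalar(beam_angle_rad, "beam_angle_rad", lower = 0, upper = pi / 2,
                strict_upper = TRUE)
  structure(list(reflectors = reflectors, medium_index = medium_index,
                 beam_angle_rad = beam_angle_rad),
            class = "sample_phantom")
}

#' Default three-reflector middle-ear phantom
#'
#' A thick tympanic-membrane layer (shallow, moderately reflective), the
#' malleus (middle, bright) and a thin tympanic-membrane layer (deep, faint),
#' mirroring the three regions usually boxed for ROI analysis in middle-ear
#' Doppler OCT B-scans.
#'
#' @param medium_index,beam_angle_rad Passed to [sample_phantom()].
#' @return A `sample_phantom` with reflectors labelled `"thick TM"`,
#'   `"malleus"` and `"thin TM"` at 150, 300 and 450 um.
#' @export
default_phantom <- function(medium_index = 1, beam_angle_rad = 0) {
  sample_phantom(
    list(reflector(150, 0.05, "thick TM"),
         reflector(300, 0.20, "malleus"),
         reflector(450, 0.02, "thin TM")),
    medium_index = medium_index, beam_angle_rad = beam_angle_rad)
}

# Noiseless spectral line at line-start time t_start_s (seconds).
.spectral_line_core <- function(phantom, stimuli, source, t_start_s, acq) {
  env <- source$envelope
  refl <- phantom$reflectors
  if (length(refl) == 0L) return(env)
  if (inherits(stimuli, "vib_stimulus")) stimuli <- list(stimuli)
  s <- acq$exposure_oversampling
  expo_s <- acq$exposure_fraction * acq$line_period_us * 1e-6
  tsub <- t_start_s + expo_s * ((seq_len(s) - 0.5) / s)
  proj <- cos(phantom$beam_angle_rad)
  # positions: s x R matrix of optical depths (um)
  z <- vapply(refl, function(rf) {
    d <- rep(0, s)
    for (st in stimuli) {
      if (!is.null(st$targets) && !(rf$label %in% st$targets)) next
      d <- d + .stimulus_displacement_um(st, tsub)
    }
    rf$depth_um + proj * d
  }, numeric(s))
  z <- matrix(z, nrow = s)
  # round-trip phase 4*pi*n*z/lambda, z in nm
  coef <- 4 * pi * phantom$medium_index * 1e3 * z
  fr <- cos(outer(1 / source$wavelength_nm, as.vector(coef)))
  wts <- rep(vapply(refl, function(rf) 2 * sqrt(rf$reflectivity), 0),
             each = s) / s
  env * (1 + as.vector(fr %*% wts))
}

#' Simulate one raw camera spectrum
#'
#' Forward model for a single A-line: for each camera pixel of wavelength
#' lambda, intensity = S(lambda) * (1 + sum over reflectors of
#' 2*sqrt(R)*cos(4*pi*n*z_r(t')/lambda)), averaged over
#' `exposure_oversampling` sub-instants t' spanning the exposure window, plus
#' additive Gaussian noise of sd `noise_sd` (relative to the envelope peak,
#' seeded from `acq$rng_seed`). Motion projects onto the beam by
#' cos(beam_angle).
#'
#' @param phantom A [sample_phantom()]. An empty reflector list yields the
#'   bare source envelope (background-only line).
#' @param stimuli A [vib_stimulus()] or list of them.
#' @param source A [make_source()] spectrum.
#' @param t_s Line start time in seconds.
#' @param acq An [acquisition_config()].
#' @return Numeric vector of pixel intensities (length `pixel_count`).
#' @export
simulate_spectral_line <- function(phantom, stimuli, source, t_s, acq) {
  line <- .spectral_line_core(phantom, stimuli, source, t_s, acq)
  if (acq$noise_sd > 0) {
    sd <- acq$noise_sd * max(source$envelope)
    line <- line + .with_seed(acq$rng_seed, stats::rnorm(length(line), 0, sd))
  }
  line
}

#' Simulate a raw spectral B-scan frame
#'
#' A-line j starts at t = (j-1) * line_period and integrates over its exposure
#' window; the recorded timestamp is the exposure centroid
#' t + exposure/2 (the effective sampling instant of an averaged exposure).
#' Output is deterministic under a fixed `acq$rng_seed`.
#'
#' @inheritParams simulate_spectral_line
#' @return A [spectral_frame()] (pixels x A-lines) with the wavelength grid,
#'   centroid timestamps in microseconds, and the line period.
#' @export
#' @examples
#' frame <- simulate_bscan(default_phantom(), vib_stimulus(1000, 100),
#'                         make_source(pixel_count = 256),
#'                         acquisition_config(alines_per_frame = 8))
#' dim(frame$spectra)
simulate_bscan <- function(phantom, stimuli, source, acq) {
  if (acq$alines_per_frame < 2L)
    .fail("'alines_per_frame' must be >= 2 (Doppler needs adjacent A-line pairs)")
  l <- acq$alines_per_frame
  t0 <- (seq_len(l) - 1) * acq$line_period_us * 1e-6
  spectra <- vapply(t0, function(t)
    .spectral_line_core(phantom, stimuli, source, t, acq),
    numeric(source$pixel_count))
  spectra <- matrix(spectra, nrow = source$pixel_count)
  if (acq$noise_sd > 0) {
    sd <- acq$noise_sd * max(source$envelope)
    spectra <- spectra +
      .with_seed(acq$rng_seed,
                 matrix(stats::rnorm(length(spectra), 0, sd), nrow(spectra)))
  }
  ts_us <- (seq_len(l) - 1) * acq$line_period_us +
    0.5 * acq$exposure_fraction * acq$line_period_us
  spectral_frame(spectra, source$wavelength_nm, ts_us, acq$line_period_us)
}
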
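# Independent oracles and small fixture builders used across the suite.

# Literal double-sum Kasai estimator: numerator and denominator accumulated
# with explicit loops over the M x (N-1) window (shrinking at borders),
# independent of the vectorized implementation.
kasai_oracle <- function(field, m, n) {
  d <- nrow(field)
  p <- ncol(field) - 1L
  rlo <- (m - 1L) %/% 2L; rhi <- m - 1L - rlo
  w <- n - 1L
  clo <- (w - 1L) %/% 2L; chi <- w - 1L - clo
  out <- matrix(0, d, p)
  for (i in seq_len(d)) {
    for (j in seq_len(p)) {
      num <- 0; den <- 0
      for (mm in max(1L, i - rlo):min(d, i + rhi)) {
        for (nn in max(1L, j - clo):min(p, j + chi)) {
          i1 <- Re(field[mm, nn]);     q1 <- Im(field[mm, nn])
          i2 <- Re(field[mm, nn + 1]); q2 <- Im(field[mm, nn + 1])
          num <- num + (i1 * q2 - q1 * i2)
          den <- den + (i1 * i2 + q1 * q2)
        }
      }
      ph <- atan2(num, den)
      if (ph == -pi) ph <- pi
      out[i, j] <- ph
    }
  }
  out
}

# Direct discrete-Fourier-sum of one zero-padded A-line (k-ascending order),
# positive half only. Mirrors what to_ascans() must compute, by brute force.
dft_oracle <- function(x_k_ascending, nfft) {
  n <- length(x_k_ascending)
  idx <- 0:(n - 1)
  vapply(0:(nfft %/% 2 - 1), function(j)
    sum(x_k_ascending * exp(-2i * pi * idx * j / nfft)), complex(1))
}

# Frame already uniform in wavenumber carrying a pure cosine fringe with
# `cycles` periods across the k grid (plus optional DC), replicated per A-line.
make_kuniform_frame <- function(n = 64, cycles = 8, alines = 2, dc = 0,
                                k_range = c(2 * pi / 938, 2 * pi / 762)) {
  k_asc <- seq(k_range[1], k_range[2], length.out = n)
  sig <- dc + cos(2 * pi * cycles * (0:(n - 1)) / n)
  spectra <- matrix(rev(sig), n, alines)   # rows ordered by increasing lambda
  spectral_frame(spectra, 2 * pi / rev(k_asc),
                 timestamps_us = (seq_len(alines) - 1) * 100 + 45,
                 line_period_us = 100, k_linear = TRUE)
}

# Complex B-scan whose adjacent A-lines differ by exp(1i * delta).
make_uniform_shift_bscan <- function(delta, depth = 16, alines = 4,
                                     seed = 1) {
  base <- doctvib:::.with_seed(seed,
    complex(real = stats::rnorm(depth), imaginary = stats::rnorm(depth)))
  field <- outer(base, exp(1i * delta * (seq_len(alines) - 1)))
  complex_bscan(field, seq_len(depth), line_period_us = 100)
}

# Random complex field with seeded Gaussian entries.
random_field <- function(d, l, seed) {
  doctvib:::.with_seed(seed, matrix(
    complex(real = stats::rnorm(d * l), imaginary = stats::rnorm(d * l)),
    d, l))
}

# Small single-reflector scene used by several reconstruction tests.
quick_scene <- function(pixel_count = 512, depth_um = 300, refl = 0.1,
                        alines = 4, noise_sd = 0, oversampling = 4,
                        seed = 1) {
  list(source = make_source(850, 55, pixel_count),
       phantom = sample_phantom(list(reflector(depth_um, refl, "r"))),
       acq = acquisition_config(alines_per_frame = alines,
                                exposure_oversampling = oversampling,
                                noise_sd = noise_sd, rng_seed = seed))
}

# Peak depth bin of a reconstruction, DC region excluded.
peak_bin <- function(bscan, min_depth_um = 50) {
  sel <- bscan$depth_axis_um > min_depth_um
  which(sel)[which.max(Mod(bscan$field[sel, 1]))]
}

# Full-width at half maximum (in bins) of the magnitude peak around `bin`.
fwhm_bins <- function(mag, bin) {
  half <- mag[bin] / 2
  lo <- bin; while (lo > 1 && mag[lo - 1] >= half) lo <- lo - 1
  hi <- bin; while (hi < length(mag) && mag[hi + 1] >= half) hi <- hi + 1
  hi - lo + 1
}

tiny_pipeline_config <- function() {
  cfg <- default_config()
  cfg$source$pixel_count <- 512L
  cfg$acquisition$alines_per_frame <- 8L
  cfg$acquisition$exposure_oversampling <- 2L
  cfg$vibrometry$frequencies_hz <- c(0, 4000)
  cfg$vibrometry$amplitudes_nm <- c(0, 100)
  cfg$vibrometry$replicates <- 2L
  cfg
}
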
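# Reconstruction chain: background subtraction, k-linearization, apodization,
# FFT and log scaling.

test_that("background subtraction zeroes the mean spectrum and is idempotent", {
  sc <- quick_scene(pixel_count = 128, depth_um = 60, alines = 4)
  fr <- simulate_bscan(sc$phantom, control_stimulus(), sc$source, sc$acq)
  # identical A-lines: subtraction yields all zeros
  out <- subtract_background(fr)
  expect_true(all(abs(out$spectra) < 1e-14))
  # general frame: per-pixel mean is zero, re-subtraction changes nothing
  fr2 <- simulate_bscan(sc$phantom, vib_stimulus(1000, 200), sc$source,
                        sc$acq)
  out2 <- subtract_background(fr2)
  expect_lt(max(abs(rowMeans(out2$spectra))), 1e-13)
  expect_equal(subtract_background(out2)$spectra, out2$spectra,
               tolerance = 1e-12)
  one <- spectral_frame(matrix(1, 16, 1), seq(800, 900, length.out = 16),
                        0, 100)
  expect_error(subtract_background(one), "at least 2")
})

test_that("background subtraction suppresses the DC peak by >= 20 dB", {
  sc <- quick_scene(pixel_count = 256, depth_um = 150, alines = 8,
                    noise_sd = 1e-4)
  fr <- simulate_bscan(sc$phantom, vib_stimulus(1000, 300), sc$source, sc$acq)
  raw <- to_ascans(apodize(k_linearize(fr), "none"))
  sub <- to_ascans(apodize(k_linearize(subtract_background(fr)), "none"))
  drop_db <- 20 * log10(Mod(raw$field[1, 1]) / Mod(sub$field[1, 1]))
  expect_gte(drop_db, 20)
})

test_that("k-linearization is the identity on already k-uniform input", {
  fr <- make_kuniform_frame(n = 64, cycles = 8)
  out <- k_linearize(fr)
  expect_equal(out$spectra, fr$spectra, tolerance = 1e-6)
  expect_equal(out$wavelength_nm, fr$wavelength_nm, tolerance = 1e-12)
  expect_true(out$k_linear)
  # constant (DC-only) spectra stay constant
  const <- spectral_frame(matrix(3.5, 64, 2), fr$wavelength_nm, c(45, 145),
                          100)
  expect_equal(k_linearize(const)$spectra, const$spectra, tolerance = 1e-12)
})

test_that("k-linearization removes the chirp-induced axial blur", {
  sc <- quick_scene(depth_um = 300, alines = 2)
  fr <- simulate_bscan(sc$phantom, control_stimulus(), sc$source, sc$acq)
  no_lin <- to_ascans(fr, force = TRUE)
  lin <- to_ascans(k_linearize(fr))
  m0 <- Mod(no_lin$field[, 1]); m1 <- Mod(lin$field[, 1])
  b0 <- peak_bin(no_lin); b1 <- peak_bin(lin)
  expect_lt(fwhm_bins(m1, b1), fwhm_bins(m0, b0))
})

test_that("apodization windows behave per contract", {
  fr <- make_kuniform_frame(n = 64, cycles = 8, alines = 3)
  expect_identical(apodize(fr, "none")$spectra, fr$spectra)
  ones <- spectral_frame(matrix(1, 64, 3), fr$wavelength_nm,
                         fr$timestamps_us, 100, k_linear = TRUE)
  h <- apodize(ones, "hann")$spectra
  expect_equal(h[, 1], h[, 2])
  expect_equal(h[1, 1], 0)
  expect_equal(max(h), 1, tolerance = 1e-3)
  expect_error(apodize(fr, "blackmann"), "unknown window")
})

test_that("hann apodization keeps the first sidelobe at or below -31 dB", {
  fr <- make_kuniform_frame(n = 256, cycles = 32)
  bs <- to_ascans(apodize(fr, "hann"))
  mag <- Mod(bs$field[, 1])
  pk <- which.max(mag)
  side <- max(mag[-(max(1, pk - 10):min(length(mag), pk + 10))])
  expect_lte(20 * log10(side / mag[pk]), -31)
})

test_that("to_ascans places a pure k-cosine at the predicted depth bin", {
  fr <- make_kuniform_frame(n = 64, cycles = 8)
  bs <- to_ascans(fr)                    # pad factor 2: bin index = 2*cycles
  expect_equal(which.max(Mod(bs$field[, 1])), 2 * 8 + 1)
  # zero frame maps to a zero B-scan
  zero <- spectral_frame(matrix(0, 64, 2), fr$wavelength_nm, c(45, 145), 100,
                         k_linear = TRUE)
  expect_true(all(Mod(to_ascans(zero)$field) == 0))
  # contract violation: raw (non-k-linear) frame rejected unless forced
  raw <- spectral_frame(matrix(1, 64, 2), seq(800, 900, length.out = 64),
                        c(45, 145), 100)
  expect_error(to_ascans(raw), "k-linearized")
  expect_silent(to_ascans(raw, force = TRUE))
})

test_that("to_ascans matches a direct discrete-Fourier-sum oracle", {
  sc <- quick_scene(pixel_count = 64, depth_um = 40, alines = 3,
                    noise_sd = 1e-3)
  fr <- k_linearize(
    simulate_bscan(sc$phantom, vib_stimulus(2000, 100), sc$source, sc$acq))
  bs <- to_ascans(fr)
  for (j in 1:3) {
    oracle <- dft_oracle(rev(fr$spectra[, j]), 128)
    expect_lt(max(Mod(bs$field[, j] - oracle)) / max(Mod(oracle)), 1e-10)
  }
})

test_that("kept half carries half the spectral energy (Parseval)", {
  fr <- make_kuniform_frame(n = 128, cycles = 13)   # zero-mean cosine
  bs <- to_ascans(fr)
  nfft <- 2 * 128
  lhs <- sum(Mod(bs$field[, 1])^2)
  rhs <- nfft * sum(fr$spectra[, 1]^2) / 2
  expect_equal(lhs, rhs, tolerance = 1e-3)
})

test_that("pipeline is linear and obeys the shift theorem", {
  sc <- quick_scene(depth_um = 200, alines = 2)
  fr <- simulate_bscan(sc$phantom, control_stimulus(), sc$source, sc$acq)
  bs <- reconstruct_bscan(fr, window = "hann")
  fr3 <- fr; fr3$spectra <- 3 * fr$spectra
  bs3 <- reconstruct_bscan(fr3, window = "hann")
  expect_equal(Mod(bs3$field), 3 * Mod(bs$field), tolerance = 1e-9)
  # moving the reflector by dz moves the peak by the predicted bins (+/- 1)
  sc2 <- quick_scene(depth_um = 250, alines = 2)
  bs2 <- reconstruct_bscan(
    simulate_bscan(sc2$phantom, control_stimulus(), sc2$source, sc2$acq),
    window = "hann")
  dbin <- diff(bs$depth_axis_um[1:2])
  expect_lte(abs((peak_bin(bs2) - peak_bin(bs)) - round(50 / dbin)), 1)
})

test_that("log scaling is decibel-faithful and clips to the display range", {
  # anchor pixel holds the max so the normalization is fixed
  f <- matrix(complex(real = c(10, 1, 0.5, 0)), 2, 2)
  st <- log_magnitude(complex_bscan(f, 1:2, 100), floor_db = -40,
                      ceiling_db = 0)
  expect_equal(st$log_magnitude_db[1, 1], 0, tolerance = 1e-9)  # the peak
  # doubling a non-peak value raises it by 20*log10(2) = 6.02 dB
  f2 <- f; f2[2, 1] <- 2 * f2[2, 1]
  st2 <- log_magnitude(complex_bscan(f2, 1:2, 100), -40, 0)
  expect_equal(st2$log_magnitude_db[2, 1] - st$log_magnitude_db[2, 1],
               20 * log10(2), tolerance = 1e-9)
  # zero magnitude lands on the floor after clipping
  expect_equal(st$log_magnitude_db[2, 2], -40)
  expect_error(log_magnitude(complex_bscan(f, 1:2, 100), 0, -40), "below")
  # unit-magnitude field sits at 0 dB everywhere
  u <- matrix(complex(modulus = 1, argument = runif(4)), 2, 2)
  expect_equal(log_magnitude(complex_bscan(u, 1:2, 100))$log_magnitude_db,
               matrix(0, 2, 2), tolerance = 1e-6)
})
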
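---
title: "Phase-resolved Doppler OCT vibrometry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-resolved Doppler OCT vibrometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(doctvib)
```

## The measurement problem

Phase-resolved Doppler optical coherence tomography (DOCT) measures
nanometer-scale axial motion — for example, the sound-driven vibration of the
tympanic membrane and malleus — by comparing the *phase* of the complex
reconstructed OCT signal between consecutive A-lines. A spectrometer-based
OCT system records, for each A-line, one camera spectrum of the
interference between reference and sample arms. After reconstruction, a
reflector at optical depth $z$ contributes a complex signal whose phase is
proportional to $2 k z$; if the reflector moves by $\Delta z$ between two
A-lines acquired $T$ apart (the line period), the phase advances by

$$\Delta\varphi = \frac{4 \pi \, n_t \cos\theta}{\lambda_0} \, \Delta z,$$

where $\lambda_0$ is the source center wavelength, $n_t$ the refractive
index of the medium and $\theta$ the angle between the beam and the motion
axis. This package implements the full chain — raw-spectrum simulation,
reconstruction, phase estimation, and ROI-level frequency-response
analysis — so that the method's frequency response, aliasing limit and
fringe-washout behavior can be studied without hardware.

## The Kasai autocorrelation estimator

Single-pixel phase differences are noisy; the standard remedy, inherited from
ultrasound color Doppler, is Kasai's lag-one autocorrelation with spatial
averaging. With $z_{m,n} = I_{m,n} + i\,Q_{m,n}$ the complex field at depth
bin $m$ and A-line $n$, the estimate over an $M \times N$ window is

$$\Delta\varphi = \arg \sum_{m=1}^{M}\sum_{n=1}^{N-1}
  \overline{z_{m,n}}\, z_{m,n+1}
 = \tan^{-1}\!\frac{\sum (I_{m,n} Q_{m,n+1} - Q_{m,n} I_{m,n+1})}
                   {\sum (I_{m,n} I_{m,n+1} + Q_{m,n} Q_{m,n+1})},$$

implemented in `kasai_phase()` with a vectorized box-sum over the window and
verified in the test suite against literal double-sum loops to $10^{-12}$.
The $1/(M(N-1))$ normalization cancels in the ratio and is omitted. The
Doppler frequency is $f_D = \Delta\varphi \cdot f_{\mathrm{line}} / 2\pi$
(`phase_to_frequency()`) and the axial velocity is
$v = \lambda_0 f_D / (2 n_t \cos\theta)$ (`doppler_velocity()`). Note that
$f_{\mathrm{line}}$ must be a *rate*: using the line period itself as a
multiplicative prefactor would be dimensionally wrong, so the package defines
$f_{\mathrm{line}} = 1/T$ throughout.

Conventions fixed here (arbitrary in principle, but necessary for
reproducible tests):

* **Phase range** is $(-\pi, \pi]$ with the $\pm\pi$ boundary mapped to
  $+\pi$, so an exact half-turn has a deterministic sign.
* **Sign**: an *increase* in optical path between consecutive A-lines gives
  a *positive* phase; equivalently a pair related by $z_{n+1} = z_n
  e^{i\delta}$ returns $+\delta$. This matches the analytic prediction
  $\Delta\varphi(j) = (4\pi n_t \cos\theta/\lambda_0)[z(t_{j+1}) - z(t_j)]$
  used in the recovery tests.
* **No phase unwrapping** anywhere: phases beyond $\pm\pi$ alias, by design;
  wrapping behavior is part of what the package exists to demonstrate.

## The simulator and what it emulates

`simulate_bscan()` produces raw camera spectra from the standard SD-OCT
forward model: for a pixel of wavelength $\lambda$,

$$ I(\lambda) = S(\lambda)\Big[\,1 + \sum_r 2\sqrt{R_r}
   \cos\!\big(4\pi \, n \, z_r(t') / \lambda\big)\Big], $$

averaged over sub-instants $t'$ spanning the camera exposure, plus seeded
additive Gaussian noise. Key modeling choices:

* **Wavelength grid uniform in $\lambda$** over $850 \pm 1.6 \times 55$ nm
  (2048-pixel default grids scale down for tests). Spectrometers sample
  uniformly in wavelength, i.e. *non*-uniformly in wavenumber, so the
  k-linearization step is genuinely exercised: skipping it produces a
  depth-dependent chirp blur that the test suite measures directly.
* **Fringe washout by sub-sample averaging.** Each exposure is averaged over
  `exposure_oversampling` midpoints (default 16; 32 in washout studies)
  spanning `exposure_fraction` (default 0.9) of the line period. For linear
  drift the closed form $|\mathrm{sinc}(\Delta\varphi_{\mathrm{exp}}/2)|$
  then becomes an *oracle* the implementation is tested against (within 2%),
  rather than being baked into the implementation — and the averaging stays
  correct for arbitrary motion.
* **Timestamps are exposure centroids** ($t_j = jT + \mathrm{exposure}/2$).
  An averaged exposure's effective sampling instant is its centroid; using
  line-start times instead would introduce a constant half-exposure time
  shift between measured and predicted phase traces that is bookkeeping, not
  physics.
* **Noise** is additive Gaussian only (default sd $10^{-3}$ of the envelope
  peak), sufficient to exercise phase-noise averaging while keeping seeding
  trivial; shot-noise scaling and speckle are not modeled.
* **Depth convention**: "depth" is one-way optical path in air; the
  round-trip fringe phase is $4\pi n z/\lambda$ and the reconstructed depth
  axis is air-equivalent (divide by $n$ only in physical conversions).

The default phantom has three reflectors — thick TM (150 µm, $R = 0.05$),
malleus (300 µm, $R = 0.20$), thin TM (450 µm, $R = 0.02$) — standing in for
the three regions usually boxed for ROI analysis in middle-ear B-scans.

What the simulator does **not** emulate: speckle statistics, dispersion
mismatch, galvanometer scan distortion, acoustic coupling, and — importantly
— the mechanical resonance of a real tympanic membrane. Stimulus
displacement amplitudes are free inputs per frequency (no displacement
calibration exists for a 92 dB drive), so a passing end-to-end test shows
the *pipeline* recovers an injected response maximum; it says nothing about
real TM mechanics.

## Reconstruction chain

`reconstruct_bscan()` chains the batch equivalents of the real-time
processing stages: optional mean-background subtraction, k-linearization,
apodization, FFT.

* **k-linearization** resamples each A-line from the $\lambda$-grid onto a
  grid uniform in $k = 2\pi/\lambda$ with the same endpoints and pixel
  count, by cubic spline (`stats::spline`; linear interpolation available as
  an option). Cubic splines are the standard accuracy/smoothness trade-off
  for fringe resampling.
* **FFT** uses zero-padding factor 2 (halves depth-bin quantization in
  peak-location analyses) and keeps the positive-depth half with complex
  values intact. Depth bin $j$ sits at $z = \pi j / (n_{\mathrm{fft}}
  \delta k)$.
* **Log scaling** is $20\log_{10}((|z| + \varepsilon)/\max|z|)$ with
  $\varepsilon = 10^{-12}$ of the peak, so the image is finite everywhere,
  the peak sits at 0 dB, and thresholds are expressed relative to the peak.
* **Background subtraction and fixed-beam Doppler.** `subtract_background()`
  subtracts the per-pixel mean across A-lines — correct for structural
  imaging and for laterally scanned data, where the mean approximates the
  static background. With a *stationary* beam and a sinusoidally moving
  reflector, however, the mean contains $J_0(\beta)$ times that reflector's
  own fringe ($\beta$ the phase-modulation depth); subtracting it
  superposes a static phasor on the rotating one and distorts the Kasai
  phase by up to $\sim 1/(1 - J_0(\beta))$. Doppler sweeps therefore default
  to `background = "none"`; the un-subtracted DC term lands at depth bin 0,
  far from any ROI, and hann apodization suppresses its skirt.

## ROI analysis and the frequency sweep

`roi_mean_doppler()` divides the sum of Doppler values in the ROI by the
number of pixels *with Doppler signal* (the structural-intensity mask from
`intensity_mask()`, default threshold 30 dB below the image peak), not the
ROI area. The default ROI statistic is the **mean absolute phase**: a
sinusoidal vibration averages signed phase toward zero over A-lines, so the
magnitude is the minimal convention under which a "phase variation vs
frequency" curve is nonzero; a signed-mean mode is kept as an option.

`frequency_sweep()` runs simulate → reconstruct → Kasai → masked ROI mean
for every stimulus frequency and replicate. Ten replicates (defaults;
mirroring a ten-ear study design) each get a derived seed, and
`control_subtract()` removes each replicate's own no-sound (0 Hz) reference
per ROI, so the control column is exactly zero and min/max spreads reproduce
the error-bar convention of plotting the extreme measured values. Default
frequencies are 0, 1, 2, 4, 6 and 8 kHz; the demo amplitudes (0, 40, 60,
100, 70, 50 nm) place the injected maximum at 4 kHz, mirroring the
qualitative in vivo finding without asserting it as physics.

Two instrument effects shape a measured response at a 100 µs line period
even for flat drive amplitude: sampling **aliasing** above the 5 kHz Nyquist
limit (an 8 kHz tone appears at 2 kHz: `alias_frequency(8000, 1e4)`), and
**washout** attenuation growing with intra-exposure motion
($\mathrm{sinc}(\pi f T_{\mathrm{exp}})$ for a tone of frequency $f$). Both
are reproduced and tested quantitatively.

## Numerical choices and problem sizes

* Averaging-window borders: the window shrinks at image edges (no padding,
  no fabricated data); a `"strict"` mode rejects windows larger than the
  image. Default window $M = N = 4$, a balance of variance reduction and
  resolution; all sizes are configurable.
* Degenerate inputs fail loudly: single A-line backgrounds, non-monotone
  wavelength grids, empty-ROI means, missing control columns, unknown config
  keys and out-of-range mask thresholds are all errors, never silent values.
* Test and demo problem sizes — 512–1024 pixels, 8–1001 A-lines, 2–10
  replicates — were chosen so every reconstruction keeps the phantom within
  the unambiguous depth range ($z_{\max} \approx 1$ mm at 1024 pixels,
  halving with pixel count) while the full suite runs in well under a
  minute; results are insensitive to scaling these up.
* All randomness flows from explicit integer seeds; identical configuration
  plus seed reproduces frames, sweeps and pipeline manifests byte for byte.

## Known limitations

* Single-frame, adjacent-A-line Doppler only: no inter-B-scan Doppler,
  transverse velocity, or bulk-motion correction.
* No phase unwrapping (excluded deliberately), so displacements beyond
  $\lambda_0/(4 n_t)$ per line period wrap.
* The Gaussian-noise model understates the structured noise of real
  spectrometers; masked-ROI statistics on real data will be noisier than
  the simulations suggest.
* The simulator's reflectors are ideal points; layered tissue, speckle and
  shadowing are out of scope.
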
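# ROI-based quantification of Doppler phase maps: masked ROI means, control
# subtraction and stimulus-frequency response curves.

#' Rectangular region of interest
#'
#' Indices are 1-based and inclusive, the idiomatic R convention.
#'
#' @param label ROI label (e.g. `"thick TM"`, `"malleus"`, `"thin TM"`).
#' @param depth_range Integer `c(first, last)` depth-bin rows.
#' @param lateral_range Integer `c(first, last)` A-line-pair columns.
#' @return An object of class `doct_roi`.
#' @export
roi <- function(label, depth_range, lateral_range) {
  if (length(depth_range) != 2L || length(lateral_range) != 2L ||
      depth_range[1] > depth_range[2] || lateral_range[1] > lateral_range[2] ||
      depth_range[1] < 1 || lateral_range[1] < 1)
    .fail("ROI ranges must be nonempty 1-based c(first, last) intervals")
  structure(list(label = as.character(label),
                 depth_range = as.integer(depth_range),
                 lateral_range = as.integer(lateral_range)),
            class = "doct_roi")
}

#' ROIs centred on each phantom reflector
#'
#' Locates every reflector of a phantom on a B-scan's depth axis and builds an
#' ROI of `+/- halfwidth_bins` depth bins around it, spanning all A-line pairs
#' (or a given lateral range).
#'
#' @param phantom A [sample_phantom()].
#' @param bscan A [complex_bscan()] (supplies the depth axis and width).
#' @param halfwidth_bins Depth half-width of each ROI in bins.
#' @param lateral_range Optional `c(first, last)` pair columns; defaults to
#'   the full width.
#' @return A list of [roi()] objects, one per reflector.
#' @export
default_rois <- function(phantom, bscan, halfwidth_bins = 3,
                         lateral_range = NULL) {
  n_pairs <- ncol(bscan$field) - 1L
  if (is.null(lateral_range)) lateral_range <- c(1L, n_pairs)
  lapply(phantom$reflectors, function(rf) {
    centre <- which.min(abs(bscan$depth_axis_um -
                              phantom$medium_index * rf$depth_um))
    roi(rf$label,
        c(max(1L, centre - halfwidth_bins),
          min(nrow(bscan$field), centre + halfwidth_bins)),
        lateral_range)
  })
}

#' Mask-aware ROI mean of a Doppler phase map
#'
#' The Doppler shifts inside the ROI are summed and divided by the number of
#' pixels carrying Doppler signal (valid-mask count), not the ROI area. By
#' default the statistic is the mean absolute phase: a sinusoidal vibration
#' averages signed phase toward zero over A-lines, so the magnitude is the
#' quantity that reflects vibration strength.
#'
#' @param pmap A [kasai_phase()] result (after [apply_mask()] if desired).
#' @param region A [roi()].
#' @param statistic `"abs"` (default) for mean |phase|, `"signed"` for the
#'   plain mean.
#' @return ROI mean in radians. Raises an error if the ROI contains no valid
#'   pixel (never a silent zero).
#' @export
roi_mean_doppler <- function(pmap, region, statistic = c("abs", "signed")) {
  statistic <- match.arg(statistic)
  dr <- region$depth_range
  lr <- region$lateral_range
  if (dr[2] > nrow(pmap$phase) || lr[2] > ncol(pmap$phase))
    .fail("ROI '", region$label, "' exceeds the phase-map bounds")
  ph <- pmap$phase[dr[1]:dr[2], lr[1]:lr[2], drop = FALSE]
  ok <- pmap$valid_mask[dr[1]:dr[2], lr[1]:lr[2], drop = FALSE]
  if (!any(ok))
    .fail("ROI '", region$label, "' contains no valid Doppler pixel")
  vals <- ph[ok]
  if (statistic == "abs") mean(abs(vals)) else mean(vals)
}

#' Frequency-response container
#'
#' @param frequencies_hz Stimulus frequencies (Hz), including 0 = control.
#' @param roi_labels Character vector of ROI labels.
#' @param values Numeric array ROI x frequency x replicate of ROI-mean Doppler
#'   phase (radians).
#' @param control_subtracted Logical flag set by [control_subtract()].
#' @return An object of class `frequency_response` with per-replicate values,
#'   the across-replicate mean (`roi_means`) and min/max spread
#'   (`spread_low`, `spread_high`).
#' @export
frequency_response <- function(frequencies_hz, roi_labels, values,
                               control_subtracted = FALSE) {
  values <- array(values, dim = c(length(roi_labels), length(frequencies_hz),
                                  dim(values)[3]))
  agg <- function(f) apply(values, c(1, 2), f)
  structure(list(frequencies_hz = as.numeric(frequencies_hz),
                 roi_labels = as.character(roi_labels), values = values,
                 roi_means = agg(mean), spread_low = agg(min),
                 spread_high = agg(max),
                 control_subtracted = isTRUE(control_subtracted)),
            class = "frequency_response")
}

#' @export
print.frequency_response <- function(x, ...) {
  cat(sprintf("<frequency_response> %d ROIs x %d frequencies x %d replicates%s\n",
              dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
              if (x$control_subtracted) ", control-subtracted" else ""))
  print(round(x$roi_means, 4))
  invisible(x)
}

#' @export
as.data.frame.frequency_response <- function(x, ...) {
  d <- dim(x$values)
  data.frame(
    roi_label = rep(x$roi_labels, times = d[2]),
    frequency_hz = rep(x$frequencies_hz, each = d[1]),
    mean_rad = as.vector(x$roi_means),
    min_rad = as.vector(x$spread_low),
    max_rad = as.vector(x$spread_high),
    control_subtracted = x$control_subtracted)
}

#' Subtract the control (no-sound) reference per ROI and replicate
#'
#' Each replicate's own control-column value is subtracted from that
#' replicate's ROI means at every stimulus frequency, mirroring the practice
#' of taking the no-stimulus acquisition as the initial reference. The control
#' column of the result is exactly zero; means and min/max spreads are
#' recomputed from the subtracted per-replicate values.
#'
#' @param response A [frequency_response()] whose frequency vector contains 0.
#' @return The control-subtracted `frequency_response`.
#' @export
control_subtract <- function(response) {
  i0 <- which(response$frequencies_hz == 0)
  if (length(i0) != 1L)
    .fail("response must contain exactly one control (0 Hz) column")
  v <- response$values
  ctrl <- v[, i0, , drop = FALSE]          # ROI x 1 x rep
  v <- sweep(v, c(1, 3), ctrl[, 1, ], "-")
  frequency_response(response$frequencies_hz, response$roi_labels, v,
                     control_subtracted = TRUE)
}

#' Stimulus-frequency sweep through the full pipeline
#'
#' For every stimulus frequency and replicate, simulates a raw frame
#' (simulate -> reconstruct -> Kasai -> masked ROI mean) and aggregates ROI
#' means with min/max spread across replicates. Replicates model repeated
#' specimens; each gets its own derived noise seed, so a sweep with a fixed
#' `base_seed` is exactly reproducible.
#'
#' @param phantom A [sample_phantom()].
#' @param source A [make_source()] spectrum.
#' @param acq An [acquisition_config()] (its `rng_seed` is ignored in favour
#'   of seeds derived from `base_seed`).
#' @param cfg A [doppler_config()].
#' @param frequencies_hz Stimulus frequencies in Hz; must include 0 (control).
#' @param amplitudes_nm Displacement amplitude per frequency (same length).
#' @param rois List of [roi()] objects, or `NULL` to build [default_rois()]
#'   around the phantom reflectors.
#' @param replicates Number of synthetic specimens per frequency (default 10).
#' @param base_seed Integer seed from which per-run seeds derive.
#' @param window Apodization window for reconstruction.
#' @param background Background handling for [reconstruct_bscan()]; default
#'   `"none"` (see vignette for why fixed-beam Doppler avoids mean
#'   subtraction).
#' @param statistic ROI statistic, see [roi_mean_doppler()].
#' @return A [frequency_response()] (not yet control-subtracted).
#' @export
frequency_sweep <- function(phantom, source, acq, cfg,
                            frequencies_hz, amplitudes_nm, rois = NULL,
                            replicates = 10, base_seed = 1,
                            window = "hann", background = "none",
                            statistic = "abs") {
  if (!any(frequencies_hz == 0))
    .fail("'frequencies_hz' must include 0 (the no-sound control)")
  if (length(amplitudes_nm) != length(frequencies_hz))
    .fail("'amplitudes_nm' must have one entry per frequency")
  .check_scalar(replicates, "replicates", lower = 1, integer = TRUE)
  nf <- length(frequencies_hz)
  roi_list <- rois
  vals <- NULL
  for (fi in seq_len(nf)) {
    for (r in seq_len(replicates)) {
      acq_r <- acq
      acq_r$rng_seed <- as.integer((base_seed + 1009 * fi + r) %% 2147483647)
      stim <- if (frequencies_hz[fi] == 0) control_stimulus() else
        vib_stimulus(frequencies_hz[fi], amplitudes_nm[fi])
      frame <- tryCatch(
        simulate_bscan(phantom, stim, source, acq_r),
        error = function(e) .fail(sprintf(
          "frequency %g Hz, replicate %d (simulate): %s",
          frequencies_hz[fi], r, conditionMessage(e))))
      bs <- reconstruct_bscan(frame, window = window, background = background)
      if (is.null(roi_list)) roi_list <- default_rois(phantom, bs)
      if (is.null(vals))
        vals <- array(NA_real_, c(length(roi_list), nf, replicates))
      st <- log_magnitude(bs)
      pm <- apply_mask(kasai_phase(bs, cfg),
                       intensity_mask(st, cfg$mask_threshold_db))
      vals[, fi, r] <- vapply(roi_list, function(rg)
        roi_mean_doppler(pm, rg, statistic), 0)
    }
  }
  frequency_response(frequencies_hz,
                     vapply(roi_list, `[[`, "", "label"), vals)
}

#' Line plot of a frequency response
#'
#' One line per ROI of the across-replicate mean with min/max error bars,
#' the usual way such frequency-response curves are displayed.
#'
#' @param response A [frequency_response()].
#' @return A ggplot object.
#' @export
plot_frequency_response <- function(response) {
  df <- as.data.frame(response)
  df$frequency_khz <- df$frequency_hz / 1000
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frequency_khz, y = .data$mean_rad,
                                   colour = .data$roi_label)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$min_rad,
                                        ymax = .data$max_rad), width = 0.1) +
    ggplot2::labs(x = "Stimulus frequency (kHz)",
                  y = if (response$control_subtracted)
                    "Control-subtracted mean |Δφ| (rad)"
                  else "Mean |Δφ| (rad)",
                  colour = "ROI") +
    ggplot2::theme_minimal()
}
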
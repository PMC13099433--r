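# EFP signal path: EEG container, Butterworth/notch preprocessing, discrete
# Stockwell transform, quarter-second x frequency-band binning, and the
# weighted summation that yields the EFP time-course.

#' Construct an EEG recording
#'
#' @param samples numeric matrix, channels x time, in microvolts.
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector, one label per row.
#' @param reference label of the online reference (informational).
#' @return an object of class `EEGRecording`.
#' @export
eeg_recording <- function(samples, fs, channel_labels,
                          reference = "") {
  samples <- as.matrix(samples)
  if (!is_scalar_num(fs) || fs <= 0) stopf("fs must be a positive scalar")
  if (length(channel_labels) != nrow(samples)) {
    stopf("need one channel label per row (%d rows, %d labels)",
          nrow(samples), length(channel_labels))
  }
  if (!all(is.finite(samples))) stopf("EEG samples must all be finite")
  rownames(samples) <- channel_labels
  structure(list(samples = samples, fs = fs,
                 channel_labels = as.character(channel_labels),
                 reference = reference),
            class = "EEGRecording")
}

#' @export
print.EEGRecording <- function(x, ...) {
  cat(sprintf("EEGRecording: %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs,
              ncol(x$samples) / x$fs))
  invisible(x)
}

.butter_filtfilt <- function(x, flt) {
  as.numeric(signal::filtfilt(flt, x))
}

#' Band-pass and notch filter an EEG recording
#'
#' Applies a zero-phase (forward-backward) 4th-order Butterworth band-pass,
#' then a zero-phase 2nd-order Butterworth band-stop for each notch.  The
#' study's stages are the 0.75-70 Hz band-pass and a 4 Hz wide notch at
#' 33 Hz for a scanner-related periodic artifact; MR gradient/ballistocardio
#' artifact removal is upstream of this package.
#'
#' @param rec an `EEGRecording`.
#' @param band `[f_lo, f_hi]` pass band in Hz; both edges must lie inside
#'   `(0, fs/2)`.
#' @param notches list of `c(center_hz, width_hz)` stop bands (default: the
#'   33 Hz, 4 Hz wide scanner notch).  Use `list()` for none.
#' @return a filtered `EEGRecording` of the same shape.
#' @export
preprocess_eeg <- function(rec, band = c(0.75, 70),
                           notches = list(c(33, 4))) {
  stopifnot(inherits(rec, "EEGRecording"))
  nyq <- rec$fs / 2
  if (length(band) != 2L || band[1] <= 0 || band[2] >= nyq ||
      band[1] >= band[2]) {
    stopf("band edges must satisfy 0 < f_lo < f_hi < fs/2 (= %g Hz)", nyq)
  }
  bp <- signal::butter(4, band / nyq, type = "pass")
  out <- t(apply(rec$samples, 1, .butter_filtfilt, flt = bp))
  for (ntc in notches) {
    lo <- ntc[1] - ntc[2] / 2
    hi <- ntc[1] + ntc[2] / 2
    if (lo <= 0 || hi >= nyq) {
      stopf("notch %g Hz (width %g) falls outside (0, fs/2)", ntc[1], ntc[2])
    }
    bs <- signal::butter(2, c(lo, hi) / nyq, type = "stop")
    out <- t(apply(out, 1, .butter_filtfilt, flt = bs))
  }
  eeg_recording(out, rec$fs, rec$channel_labels, rec$reference)
}

#' Discrete Stockwell transform
#'
#' Frequency-domain formulation of the S-transform: the spectrum is shifted
#' by each analysis frequency, multiplied by the Gaussian localizing window
#' `exp(-2 * pi^2 * m^2 / n^2)` (frequency-scaled, sigma = 1/f in time), and
#' inverse-transformed, giving one complex voice per frequency evaluated at
#' every sample time.  Analysis frequencies are snapped to the nearest DFT
#' bin of the signal; the f = 0 voice is excluded.
#'
#' @param x numeric signal (length >= 8).
#' @param fs sampling rate in Hz.
#' @param freqs analysis frequencies in Hz, all inside `(0, fs/2)`.
#' @return complex matrix, `length(x)` rows (time) x `length(freqs)`
#'   columns, with attributes `freqs_hz` (the snapped frequencies) and
#'   `fs`.  Power is `Mod(.)^2`.
#' @export
stockwell_transform <- function(x, fs, freqs) {
  x <- as.numeric(x)
  n_samp <- length(x)
  if (n_samp < 8L) stopf("signal must have at least 8 samples")
  if (!all(is.finite(x))) stopf("signal must be finite")
  if (any(freqs <= 0) || any(freqs >= fs / 2)) {
    stopf("all analysis frequencies must lie inside (0, fs/2)")
  }
  bins <- round(freqs * n_samp / fs)
  if (any(bins < 1)) {
    stopf("analysis frequency below the signal's frequency resolution (%g Hz)",
          fs / n_samp)
  }
  spec <- stats::fft(x) / n_samp
  m <- 0:(n_samp - 1)
  m_centered <- ifelse(m > n_samp / 2, m - n_samp, m)
  voices <- vapply(bins, function(nb) {
    exp(-2 * pi^2 * m_centered^2 / nb^2) * spec[((m + nb) %% n_samp) + 1L]
  }, complex(n_samp))
  out <- stats::mvfft(voices, inverse = TRUE)
  attr(out, "freqs_hz") <- bins * fs / n_samp
  attr(out, "fs") <- fs
  out
}

#' Bin a time-frequency power matrix into quarter-second x band cells
#'
#' Mean pooling over each (time bin x frequency band) rectangle.  A 12-s
#' segment at 0.25-s bins with the default 10 bands yields a 48 x 10 grid.
#'
#' @param st_power non-negative power matrix, time samples x frequencies.
#' @param fs sampling rate of the time axis in Hz.
#' @param time_bin_s temporal bin width in seconds (default 0.25); the
#'   signal duration must be an integer multiple of it.
#' @param band_edges two-column matrix of `[f_lo, f_hi)` bands; the last
#'   band includes its upper edge.
#' @param freqs frequency (Hz) of each column of `st_power`; defaults to
#'   the `freqs_hz` attribute left by [stockwell_transform()].
#' @return an object of class `TimeFrequencyGrid`: list with `power`
#'   (time bins x bands), `time_bin_s`, `band_edges`.
#' @export
bin_time_frequency <- function(st_power, fs, time_bin_s = 0.25,
                               band_edges = default_band_edges(),
                               freqs = attr(st_power, "freqs_hz")) {
  band_edges <- .check_band_edges(band_edges)
  if (is.null(freqs)) stopf("column frequencies must be supplied")
  st_power <- as.matrix(st_power)
  if (length(freqs) != ncol(st_power)) {
    stopf("need one frequency per column of st_power")
  }
  if (any(st_power < 0)) stopf("st_power must be non-negative")
  n_per <- fs * time_bin_s
  if (n_per < 1) stopf("time_bin_s must cover at least one sample")
  n_t <- nrow(st_power) / n_per
  if (abs(n_t - round(n_t)) > 1e-9) {
    stopf("signal duration (%g s) is not an integer multiple of time_bin_s",
          nrow(st_power) / fs)
  }
  n_t <- round(n_t)
  # bin k covers samples round((k-1) n_per)+1 .. round(k n_per), exact
  # mean pooling even when n_per is not an integer (e.g. 62.5 samples for
  # quarter-second bins at 250 Hz)
  bounds <- round((0:n_t) * n_per)
  n_b <- nrow(band_edges)
  hi_edge <- band_edges[, 2]
  hi_edge[n_b] <- hi_edge[n_b] + 1e-9  # last band closed above
  grid <- matrix(0, n_t, n_b)
  for (b in seq_len(n_b)) {
    cols <- which(freqs >= band_edges[b, 1] & freqs < hi_edge[b])
    if (length(cols) == 0L) {
      stopf("no analysis frequency falls inside band [%g, %g) Hz",
            band_edges[b, 1], band_edges[b, 2])
    }
    band_mean <- rowMeans(st_power[, cols, drop = FALSE])
    grid[, b] <- vapply(seq_len(n_t), function(k) {
      mean(band_mean[(bounds[k] + 1L):bounds[k + 1L]])
    }, numeric(1))
  }
  structure(list(power = grid, time_bin_s = time_bin_s,
                 band_edges = band_edges),
            class = "TimeFrequencyGrid")
}

#' Collapse a binned time-frequency grid to one EFP value
#'
#' Each binned power cell is multiplied by its model weight and summed,
#' plus the model intercept.
#'
#' @param grid a `TimeFrequencyGrid` whose shape and bands match the model.
#' @param model an `EFPModel`.
#' @return scalar EFP value.
#' @export
compute_efp_value <- function(grid, model) {
  stopifnot(inherits(grid, "TimeFrequencyGrid"), inherits(model, "EFPModel"))
  if (!identical(dim(grid$power), dim(model$weights))) {
    stopf("grid is %d x %d but model expects %d x %d",
          nrow(grid$power), ncol(grid$power),
          nrow(model$weights), ncol(model$weights))
  }
  if (max(abs(grid$band_edges - model$band_edges)) > 1e-9) {
    stopf("grid band edges do not match the model's")
  }
  model$intercept + sum(grid$power * model$weights)
}

#' Analysis frequencies covering every band of an EFP model
#'
#' A few evenly spaced interior points per model band, guaranteeing that
#' each band of the binned representation is populated.
#'
#' @param model an `EFPModel`.
#' @param per_band points per band (default 4).
#' @return numeric vector of frequencies in Hz.
#' @export
efp_analysis_freqs <- function(model, per_band = 4L) {
  be <- model$band_edges
  unlist(lapply(seq_len(nrow(be)), function(b) {
    be[b, 1] + (be[b, 2] - be[b, 1]) * (seq_len(per_band) - 0.5) / per_band
  }))
}

#' Compute an EFP time-course from an EEG recording
#'
#' Implements the EFP signal chain: the bipolar derivation named by the
#' model (active minus reference channel) is notch-filtered for power-line
#' interference, then for every output time `t` (one per `stride_s`,
#' starting once a full segment is available) the trailing
#' `model$segment_s`-second segment is Stockwell-transformed, its power
#' binned to `time_bin_s` x frequency-band cells, and collapsed through the
#' model weights.  Output value `k` is timestamped at the segment end
#' `segment_s + (k - 1) * stride_s`; volumes earlier than one full segment
#' are never emitted.
#'
#' @param rec an `EEGRecording` containing the model's derivation channels
#'   (the reference channel may be absent if the recording is already
#'   referenced to it).
#' @param model an `EFPModel`.
#' @param stride_s output step in seconds (default 1.5, one TR; strides
#'   shorter than the segment give overlapping, hence autocorrelated,
#'   outputs).
#' @param line_notch `c(center_hz, width_hz)` power-line notch applied to
#'   the derivation before the transform (default `c(50, 2)`); `NULL` to
#'   skip, and skipped automatically when the notch exceeds Nyquist.
#' @param freqs analysis frequencies in Hz (default: 4 interior points per
#'   model band).
#' @return an object of class `EFPTimecourse`: list with `values`, `dt`
#'   (`= stride_s`), `t0` (`= segment_s`, time of the first value),
#'   `model_name`, and `warmup_volumes` (count of TR-length steps before
#'   `t0` that have no EFP value).
#' @export
compute_efp_timecourse <- function(rec, model, stride_s = 1.5,
                                   line_notch = c(50, 2),
                                   freqs = efp_analysis_freqs(model)) {
  stopifnot(inherits(rec, "EEGRecording"), inherits(model, "EFPModel"))
  fs <- rec$fs
  dur <- ncol(rec$samples) / fs
  if (dur < model$segment_s - 1e-9) {
    stopf("recording (%.2f s) is shorter than one %g-s segment",
          dur, model$segment_s)
  }
  if (!is_scalar_num(stride_s) || stride_s <= 0) stopf("stride_s must be > 0")
  act <- model$derivation[1]
  ref <- model$derivation[2]
  if (!act %in% rec$channel_labels) {
    stopf("derivation channel '%s' not present in the recording", act)
  }
  sig <- rec$samples[act, ]
  if (ref %in% rec$channel_labels) {
    sig <- sig - rec$samples[ref, ]
  } else if (!identical(rec$reference, ref)) {
    stopf(paste0("reference channel '%s' absent and the recording is ",
                 "referenced to '%s'"), ref, rec$reference)
  }
  if (!is.null(line_notch) && line_notch[1] + line_notch[2] / 2 < fs / 2) {
    lo <- line_notch[1] - line_notch[2] / 2
    hi <- line_notch[1] + line_notch[2] / 2
    bs <- signal::butter(2, c(lo, hi) / (fs / 2), type = "stop")
    sig <- .butter_filtfilt(sig, bs)
  }
  n_seg <- round(model$segment_s * fs)
  # output times t_k = segment_s + (k-1) stride; each segment start is the
  # nearest sample, so non-integer stride * fs is handled exactly in time
  t_out <- seq(model$segment_s, dur + 1e-9, by = stride_s)
  starts <- round((t_out - model$segment_s) * fs) + 1L
  starts <- starts[starts + n_seg - 1L <= ncol(rec$samples)]
  values <- vapply(starts, function(s) {
    seg <- sig[s:(s + n_seg - 1L)]
    st <- stockwell_transform(seg, fs, freqs)
    grid <- bin_time_frequency(Mod(st)^2, fs, model$time_bin_s,
                               model$band_edges)
    compute_efp_value(grid, model)
  }, numeric(1))
  structure(list(values = values, dt = stride_s, t0 = model$segment_s,
                 model_name = model$name,
                 warmup_volumes = as.integer(
                   ceiling(model$segment_s / stride_s - 1e-9))),
            class = "EFPTimecourse")
}

#' Construct an EFP time-course directly from values
#'
#' Container used when an EFP trace is loaded from file or generated
#' synthetically rather than computed from EEG.
#'
#' @param values numeric EFP values.
#' @param dt seconds between values (default 1.5).
#' @param t0 time of the first value in seconds (default 0).
#' @param model_name label.
#' @return an `EFPTimecourse`.
#' @export
efp_timecourse <- function(values, dt = 1.5, t0 = 0, model_name = "efp") {
  if (!is_scalar_num(dt) || dt <= 0) stopf("dt must be > 0")
  if (!all(is.finite(values))) stopf("EFP values must be finite")
  structure(list(values = as.numeric(values), dt = dt, t0 = t0,
                 model_name = model_name,
                 warmup_volumes = as.integer(ceiling(t0 / dt - 1e-9))),
            class = "EFPTimecourse")
}

#' @export
print.EFPTimecourse <- function(x, ...) {
  cat(sprintf("EFPTimecourse '%s': %d values, dt %g s, t0 %g s\n",
              x$model_name, length(x$values), x$dt, x$t0))
  invisible(x)
}

#' Times of an EFP time-course's samples
#' @param efp an `EFPTimecourse`.
#' @return numeric vector of timestamps in seconds.
#' @export
efp_times <- function(efp) {
  stopifnot(inherits(efp, "EFPTimecourse"))
  efp$t0 + (seq_along(efp$values) - 1) * efp$dt
}

#' Write / read an EFP time-course as TSV
#'
#' Two tab-separated columns, `time_s` and `value`.
#'
#' @param efp an `EFPTimecourse`.
#' @param path file path.
#' @export
write_efp_tsv <- function(efp, path) {
  utils::write.table(
    data.frame(time_s = efp_times(efp), value = efp$values),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_efp_tsv
#' @param model_name label for the loaded time-course.
#' @export
read_efp_tsv <- function(path, model_name = "efp") {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  dt <- if (nrow(df) > 1L) df$time_s[2] - df$time_s[1] else 1.5
  efp_timecourse(df$value, dt = dt, t0 = df$time_s[1],
                 model_name = model_name)
}
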
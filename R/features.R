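#' Continuous multichannel recording container
#'
#' Holds an EEG-like signal (channels x timepoints, microvolts), its
#' sampling rate, the stimulus onset sample indices, and channel names.
#'
#' @param samples numeric C x T matrix.
#' @param rate sampling rate in Hz.
#' @param onsets integer vector of event onset sample indices, strictly
#'   increasing and inside the recording.
#' @param channels character vector of C channel names.
#' @return an object of class `continuous_recording`.
#' @export
continuous_recording <- function(samples, rate, onsets, channels = NULL) {
  samples <- as.matrix(samples)
  stopifnot(is.numeric(samples), rate > 0)
  onsets <- as.integer(onsets)
  if (length(onsets)) {
    if (any(diff(onsets) <= 0L)) {
      stop("event onsets must be strictly increasing", call. = FALSE)
    }
    if (min(onsets) < 1L || max(onsets) > ncol(samples)) {
      stop("event onsets must lie inside the recording", call. = FALSE)
    }
  }
  if (is.null(channels)) {
    channels <- paste0("ch", seq_len(nrow(samples)))
  }
  stopifnot(length(channels) == nrow(samples))
  rownames(samples) <- channels
  structure(
    list(
      samples = samples, rate = rate, onsets = onsets,
      channels = channels
    ),
    class = "continuous_recording"
  )
}

#' @export
print.continuous_recording <- function(x, ...) {
  cat(sprintf(
    "Continuous recording: %d channels x %d samples at %g Hz, %d events\n",
    nrow(x$samples), ncol(x$samples), x$rate, length(x$onsets)
  ))
  invisible(x)
}

#' Preprocessing and feature-extraction configuration
#'
#' Defaults follow the study pipeline: band-pass 0.5-8 Hz with a 3rd-order
#' Chebyshev type II filter (40 dB stopband attenuation), downsampling to
#' 100 Hz, epochs windowed to `[-200, 700)` ms around stimulus onset,
#' baseline correction over `[-200, 0)` ms, and mean amplitudes over six
#' intervals that tile 50-700 ms. With the default 29 retained channels
#' this yields 6 x 29 = 174 features per epoch. Filtering is causal
#' (single-pass) by default, matching online operation; `causal = FALSE`
#' switches to zero-phase forward-backward filtering for offline use.
#'
#' @param band numeric `(low, high)` band edges in Hz.
#' @param filter_order Chebyshev II order.
#' @param stopband_db stopband attenuation in dB.
#' @param transition ratio between the stopband edges handed to the
#'   Chebyshev II design and the nominal band edges. A Chebyshev II design
#'   is specified by its stopband corners; placing them a factor 2 outside
#'   the nominal band keeps the passband flat (gain above 0.98 from about
#'   2 to 5 Hz) while content at 20 Hz is attenuated below 1 percent.
#' @param target_rate working rate after decimation, Hz.
#' @param epoch_window `(start, end)` ms relative to onset, half-open.
#' @param baseline_window `(start, end)` ms, half-open.
#' @param intervals list of `(start, end)` ms interval specifications,
#'   inclusive at both ends on the working-rate sample grid.
#' @param excluded_channels channel names dropped before feature extraction.
#' @param causal single-pass causal filtering (`TRUE`, default) or
#'   zero-phase (`FALSE`).
#' @return an object of class `feature_config`.
#' @export
feature_config <- function(band = c(0.5, 8),
                           filter_order = 3L,
                           stopband_db = 40,
                           transition = 2,
                           target_rate = 100,
                           epoch_window = c(-200, 700),
                           baseline_window = c(-200, 0),
                           intervals = list(
                             c(50, 120), c(121, 200), c(201, 280),
                             c(281, 380), c(381, 530), c(531, 700)
                           ),
                           excluded_channels = c("Fp1", "Fp2"),
                           causal = TRUE) {
  stopifnot(
    length(band) == 2L, band[1L] < band[2L],
    band[2L] < target_rate / 2,
    epoch_window[1L] < epoch_window[2L],
    baseline_window[1L] >= epoch_window[1L],
    baseline_window[2L] <= epoch_window[2L]
  )
  for (iv in intervals) {
    stopifnot(
      length(iv) == 2L, iv[1L] <= iv[2L],
      iv[1L] >= epoch_window[1L], iv[2L] <= epoch_window[2L]
    )
  }
  stopifnot(transition >= 1)
  structure(
    list(
      band = band, filter_order = as.integer(filter_order),
      stopband_db = stopband_db, transition = transition,
      target_rate = target_rate,
      epoch_window = epoch_window, baseline_window = baseline_window,
      intervals = intervals, excluded_channels = excluded_channels,
      causal = causal
    ),
    class = "feature_config"
  )
}

#' Band-pass filter and downsample a recording
#'
#' Applies the configured Chebyshev type II band-pass channel-wise (causal
#' single-pass by default, zero-phase when `config$causal` is `FALSE`),
#' then decimates to the target rate by keeping every
#' `rate / target_rate`-th sample. Event onsets are re-indexed onto the
#' decimated grid. The band-pass has removed all content above the target
#' Nyquist frequency, so plain decimation does not alias.
#'
#' @param recording a [continuous_recording()].
#' @param config a [feature_config()].
#' @return a [continuous_recording()] at the target rate.
#' @export
preprocess <- function(recording, config = feature_config()) {
  stopifnot(
    inherits(recording, "continuous_recording"),
    inherits(config, "feature_config")
  )
  fs <- recording$rate
  if (config$band[2L] >= fs / 2) {
    stop("band upper edge is at or above the Nyquist frequency",
      call. = FALSE
    )
  }
  factor <- fs / config$target_rate
  if (abs(factor - round(factor)) > 1e-9) {
    stop(sprintf(
      "target rate %g Hz does not divide the sampling rate %g Hz",
      config$target_rate, fs
    ), call. = FALSE)
  }
  factor <- as.integer(round(factor))
  stop_edges <- c(
    config$band[1L] / config$transition,
    min(config$band[2L] * config$transition, 0.95 * fs / 2)
  )
  filt <- signal::cheby2(
    config$filter_order, config$stopband_db,
    stop_edges / (fs / 2), type = "pass"
  )
  x <- recording$samples
  y <- matrix(0, nrow(x), ncol(x), dimnames = dimnames(x))
  for (ch in seq_len(nrow(x))) {
    y[ch, ] <- if (config$causal) {
      as.numeric(signal::filter(filt, x[ch, ]))
    } else {
      as.numeric(signal::filtfilt(filt, x[ch, ]))
    }
  }
  keep <- seq(1L, ncol(y), by = factor)
  new_onsets <- (recording$onsets - 1L) %/% factor + 1L
  continuous_recording(
    y[, keep, drop = FALSE], config$target_rate, new_onsets,
    recording$channels
  )
}

#' Cut baseline-corrected epochs around every event
#'
#' Windows each event to `epoch_window` (half-open, in ms relative to
#' onset) and subtracts per channel the mean over the baseline window.
#' Overlapping windows across nearby events are permitted (the 250 ms SOA
#' is shorter than the 900 ms window).
#'
#' @param recording a preprocessed [continuous_recording()] at the working
#'   rate.
#' @param config a [feature_config()].
#' @param baseline apply baseline correction (default `TRUE`).
#' @return an object of class `epoch_windows`: list with `data` (array
#'   N x C x S), `times` (sample times in ms relative to onset),
#'   `channels`, `rate`.
#' @export
extract_epochs <- function(recording, config = feature_config(),
                           baseline = TRUE) {
  stopifnot(inherits(recording, "continuous_recording"))
  rate <- recording$rate
  first <- ms_to_samples(config$epoch_window[1L], rate)
  last <- ms_to_samples(config$epoch_window[2L], rate) - 1L
  offs <- first:last
  times <- offs * 1000 / rate
  n_s <- length(offs)
  onsets <- recording$onsets
  lo <- onsets + offs[1L]
  hi <- onsets + offs[n_s]
  bad <- which(lo < 1L | hi > ncol(recording$samples))
  if (length(bad)) {
    stop(sprintf(
      "epoch window of event %d (onset sample %d) exceeds the recording",
      bad[1L], onsets[bad[1L]]
    ), call. = FALSE)
  }
  n_c <- nrow(recording$samples)
  data <- array(
    0,
    dim = c(length(onsets), n_c, n_s),
    dimnames = list(NULL, recording$channels, NULL)
  )
  for (i in seq_along(onsets)) {
    data[i, , ] <- recording$samples[, onsets[i] + offs, drop = FALSE]
  }
  out <- structure(
    list(
      data = data, times = times, channels = recording$channels,
      rate = rate
    ),
    class = "epoch_windows"
  )
  if (baseline) baseline_correct(out, config) else out
}

#' Baseline-correct epoch windows
#'
#' Subtracts per epoch and channel the mean over the baseline window
#' (half-open in ms). Idempotent.
#'
#' @param epochs an `epoch_windows` object.
#' @param config a [feature_config()].
#' @return the corrected `epoch_windows` object.
#' @export
baseline_correct <- function(epochs, config = feature_config()) {
  stopifnot(inherits(epochs, "epoch_windows"))
  sel <- epochs$times >= config$baseline_window[1L] &
    epochs$times < config$baseline_window[2L]
  if (!any(sel)) {
    stop("baseline window contains no samples at the working rate",
      call. = FALSE
    )
  }
  bl <- apply(epochs$data[, , sel, drop = FALSE], c(1L, 2L), mean)
  epochs$data <- epochs$data - array(bl, dim = dim(epochs$data))
  epochs
}

#' Interval-mean features from epoch windows
#'
#' Per retained channel and configured interval, the mean amplitude of the
#' epoch in that interval. Interval bounds in ms are inclusive on the
#' working-rate sample grid; the six default intervals tile 50-700 ms
#' without overlap at 100 Hz. Feature order is channel-major: all intervals
#' of channel 1, then channel 2, and so on; `D = channels x intervals`
#' (174 for 29 channels).
#'
#' @param epochs an `epoch_windows` object (already baseline-corrected).
#' @param config a [feature_config()]; its `excluded_channels` are dropped.
#' @param channels optional explicit channel subset (names), overriding the
#'   exclusion list.
#' @return numeric N x D feature matrix with descriptive column names.
#' @export
interval_means <- function(epochs, config = feature_config(),
                           channels = NULL) {
  stopifnot(inherits(epochs, "epoch_windows"))
  keep <- if (is.null(channels)) {
    setdiff(epochs$channels, config$excluded_channels)
  } else {
    stopifnot(all(channels %in% epochs$channels))
    channels
  }
  ci <- match(keep, epochs$channels)
  n <- dim(epochs$data)[1L]
  feats <- matrix(NA_real_, n, length(keep) * length(config$intervals))
  cols <- character(ncol(feats))
  k <- 0L
  for (c_idx in seq_along(ci)) {
    for (iv_idx in seq_along(config$intervals)) {
      iv <- config$intervals[[iv_idx]]
      sel <- epochs$times >= iv[1L] & epochs$times <= iv[2L]
      if (!any(sel)) {
        stop(sprintf(
          "interval [%g, %g] ms contains no samples at %g Hz",
          iv[1L], iv[2L], epochs$rate
        ), call. = FALSE)
      }
      k <- k + 1L
      feats[, k] <- rowMeans(
        matrix(epochs$data[, ci[c_idx], sel], nrow = n)
      )
      cols[k] <- sprintf("%s_%g_%g", keep[c_idx], iv[1L], iv[2L])
    }
  }
  colnames(feats) <- cols
  feats
}

#' Peak amplitude and latency of an averaged waveform
#'
#' Extracts the extremum (minimum or maximum) of a class-averaged epoch on
#' one channel within a search interval, and the time at which it occurs.
#' Ties break toward the earliest time. The study's descriptive statistics
#' use the minimum of an occipital channel in 100-200 ms (early negativity)
#' and the maximum of a central channel in 250-500 ms (late positivity).
#'
#' @param waveform numeric C x S matrix (class-average epoch) with
#'   rownames, or an `epoch_windows` object averaged over epochs.
#' @param times numeric vector of S sample times in ms (ignored when
#'   `waveform` is an `epoch_windows` object).
#' @param channel channel name.
#' @param interval `(start, end)` ms search interval, inclusive.
#' @param mode `"min"` or `"max"`.
#' @return list with `amplitude` (microvolts) and `latency` (ms).
#' @export
peak_statistics <- function(waveform, times = NULL, channel, interval,
                            mode = c("min", "max")) {
  mode <- match.arg(mode)
  if (inherits(waveform, "epoch_windows")) {
    times <- waveform$times
    waveform <- apply(waveform$data, c(2L, 3L), mean)
  }
  stopifnot(is.matrix(waveform), length(times) == ncol(waveform))
  if (!channel %in% rownames(waveform)) {
    stop(sprintf("channel '%s' not present in the waveform", channel),
      call. = FALSE
    )
  }
  sel <- which(times >= interval[1L] & times <= interval[2L])
  if (!length(sel)) {
    stop("search interval contains no samples", call. = FALSE)
  }
  y <- waveform[channel, sel]
  i <- if (mode == "min") which.min(y) else which.max(y)
  list(amplitude = unname(y[i]), latency = unname(times[sel][i]))
}

#' Flatten epoch windows to a distance matrix over a time window
#'
#' Utility for the homogeneity bootstrap: restricts the epochs to a time
#' window (default 0-700 ms, all channels) and flattens channel x sample to
#' one row per epoch.
#'
#' @param epochs an `epoch_windows` object.
#' @param window `(start, end)` ms, inclusive.
#' @return numeric N x (C*S') matrix.
#' @export
flatten_epochs <- function(epochs, window = c(0, 700)) {
  stopifnot(inherits(epochs, "epoch_windows"))
  sel <- epochs$times >= window[1L] & epochs$times <= window[2L]
  n <- dim(epochs$data)[1L]
  matrix(epochs$data[, , sel, drop = FALSE], nrow = n)
}

#' Write a recording as a binary-array file with a JSON header
#'
#' Samples go to `<path>.bin` as little-endian float64 (channel-major,
#' i.e. column after column of the C x T matrix); rate, onsets and channel
#' names go to the JSON header at `path`.
#'
#' @param recording a [continuous_recording()].
#' @param path path of the JSON header.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "continuous_recording"))
  bin <- paste0(path, ".bin")
  con <- file(bin, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.double(recording$samples), con, size = 8L, endian = "little")
  jsonlite::write_json(
    list(
      format = "llpspeller-recording-v1",
      n_channels = nrow(recording$samples),
      n_samples = ncol(recording$samples),
      rate = recording$rate,
      onsets = recording$onsets,
      channels = recording$channels,
      sidecar = basename(bin)
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param path path of the JSON header.
#' @return a [continuous_recording()].
#' @export
read_recording <- function(path) {
  header <- jsonlite::fromJSON(path)
  stopifnot(identical(header$format, "llpspeller-recording-v1"))
  bin <- file.path(dirname(path), header$sidecar)
  con <- file(bin, "rb")
  on.exit(close(con), add = TRUE)
  x <- readBin(con, "double",
    n = header$n_channels * header$n_samples,
    size = 8L, endian = "little"
  )
  continuous_recording(
    matrix(x, header$n_channels, header$n_samples),
    header$rate, header$onsets, header$channels
  )
}
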
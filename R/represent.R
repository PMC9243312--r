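# Spatial-temporal-frequency representation: per-channel short-time Fourier
# spectrograms resampled onto the canonical 94 (time) x 60 (frequency) grid
# and stacked over the 16 channels into a 16 x 94 x 60 tensor.

canonical_time_axis <- function(n_time = 94, t_range = c(0, 800)) {
  (seq_len(n_time) - 0.5) * diff(t_range) / n_time + t_range[1]
}

canonical_freq_axis <- function(n_freq = 60, f_range = c(0, 30)) {
  (seq_len(n_freq) - 0.5) * diff(f_range) / n_freq + f_range[1]
}

#' Short-time Fourier spectrogram of one channel
#'
#' Hamming window of 64 samples, 57-sample overlap (hop = 7), 256-point
#' FFT, one-sided power (magnitude squared). The raw grid keeps the time
#' columns of the analyzed segment and the frequency bins from 0 to
#' `f_max` Hz.
#'
#' @param x numeric signal (one channel of one trial), at least one window
#'   long.
#' @param fs sampling rate in Hz.
#' @param window_length,overlap,nfft spectrogram parameters.
#' @param f_max highest retained frequency in Hz.
#' @return An object of class `tf_map`: `power` (time x frequency, >= 0),
#'   `time_ms` (window centers, ms from signal start), `freq_hz`.
#' @export
stft_spectrogram <- function(x, fs, window_length = 64, overlap = 57,
                             nfft = 256, f_max = 30) {
  if (length(x) < window_length) {
    stop("signal shorter than one ", window_length, "-sample window",
         call. = FALSE)
  }
  sp <- signal::specgram(x, n = nfft, Fs = fs,
                         window = signal::hamming(window_length),
                         overlap = overlap)
  hop <- window_length - overlap
  offsets <- if (length(x) > window_length) {
    seq(1, length(x) - window_length, by = hop)
  } else 1
  time_ms <- (offsets - 1 + (window_length - 1) / 2) / fs * 1000
  keep_f <- sp$f <= f_max
  power <- t(Mod(sp$S[keep_f, , drop = FALSE])^2)  # time x freq
  structure(list(power = power, time_ms = time_ms,
                 freq_hz = sp$f[keep_f]),
            class = "tf_map")
}

#' Resample a time-frequency map onto the canonical 94 x 60 grid
#'
#' Separable linear interpolation onto 94 time pixels covering 0-800 ms and
#' 60 half-Hz frequency pixels covering 0-30 Hz (bin centers at 0.25,
#' 0.75, ... Hz, avoiding a fencepost 61st bin). Values outside the raw
#' grid's span (the first/last half-window in time) take the nearest edge
#' value. A map already on the canonical grid is returned bit-identically;
#' a constant map stays constant; non-negativity is preserved.
#'
#' @param map a `tf_map` from [stft_spectrogram()].
#' @param n_time,n_freq canonical grid size.
#' @param t_range,f_range physical extent of the canonical grid (ms, Hz).
#' @return A `tf_map` on the canonical grid.
#' @export
canonical_grid <- function(map, n_time = 94, n_freq = 60,
                           t_range = c(0, 800), f_range = c(0, 30)) {
  stopifnot(inherits(map, "tf_map"))
  ct <- canonical_time_axis(n_time, t_range)
  cf <- canonical_freq_axis(n_freq, f_range)
  if (length(map$time_ms) == n_time && length(map$freq_hz) == n_freq &&
      isTRUE(all.equal(map$time_ms, ct)) &&
      isTRUE(all.equal(map$freq_hz, cf))) {
    return(map)
  }
  if (length(map$time_ms) < 2 || length(map$freq_hz) < 2) {
    stop("raw map too small to resample", call. = FALSE)
  }
  if (diff(range(map$time_ms)) < diff(t_range) / 2 ||
      max(map$freq_hz) < f_range[2] - 1) {
    stop("raw map does not cover the canonical time-frequency window",
         call. = FALSE)
  }
  # time axis first, then frequency axis
  tmp <- apply(map$power, 2, function(col) {
    stats::approx(map$time_ms, col, xout = ct, rule = 2)$y
  })
  out <- t(apply(tmp, 1, function(row) {
    stats::approx(map$freq_hz, row, xout = cf, rule = 2)$y
  }))
  structure(list(power = out, time_ms = ct, freq_hz = cf),
            class = "tf_map")
}

#' Convert clean epochs to spatial-temporal-frequency tensors
#'
#' For every trial, the 0-800 ms post-stimulus segment of each channel is
#' converted to a canonical 94 x 60 spectrogram and the 16 channel maps are
#' stacked into a 16 x 94 x 60 tensor (channel x time x frequency).
#' Baseline samples (< 0 ms) feed only the baseline correction, not the
#' spectrogram.
#'
#' @param epochs an [eeg_epochs()] object with 16 channels.
#' @param n_time,n_freq canonical grid size.
#' @return An object of class `eeg_tensors`: `values` array
#'   `(trials, 16, n_time, n_freq)`, `labels`, `channel_order`, and exact
#'   `calibration` (`ms_per_pixel` = 800/94, `hz_per_pixel` = 0.5).
#' @export
stack_tensor <- function(epochs, n_time = 94, n_freq = 60) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  d <- dim(epochs$data)
  if (d[2] != 16L) {
    stop("tensor contract requires 16 channels, got ", d[2], call. = FALSE)
  }
  seg <- epochs$times >= 0
  n <- d[1]
  vals <- array(0, dim = c(n, 16L, n_time, n_freq))
  for (i in seq_len(n)) {
    for (ch in 1:16) {
      m <- canonical_grid(
        stft_spectrogram(epochs$data[i, ch, seg], epochs$fs),
        n_time, n_freq)
      vals[i, ch, , ] <- m$power
    }
  }
  structure(list(values = vals, labels = epochs$labels,
                 channel_order = epochs$channels,
                 calibration = c(ms_per_pixel = 800 / n_time,
                                 hz_per_pixel = 30 / n_freq)),
            class = "eeg_tensors")
}

#' @export
print.eeg_tensors <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("eeg_tensors: %d trials x (%d x %d x %d)\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  calibration: %.2f ms x %.2f Hz per pixel\n",
              x$calibration[1], x$calibration[2]))
  invisible(x)
}

#' Arrange tensors as model input arrays
#'
#' `"3d"` keeps the full (16, 94, 60) volume per trial; `"2d"` averages
#' over the channel axis to a 94 x 60 map; `"1d"` collapses each channel's
#' map over frequency (mean) to a 94-vector and concatenates the 16
#' channels. The returned array is in the engine's
#' `(conv-channel, depth, height, width, trial)` layout and records the
#' form definition as attributes.
#'
#' @param tensors an `eeg_tensors` object (or a `(n, 16, 94, 60)` array).
#' @param form `"1d"`, `"2d"` or `"3d"`.
#' @return 5-D numeric array with attributes `form` and `definition`.
#' @export
to_input_form <- function(tensors, form = c("3d", "2d", "1d")) {
  form <- match.arg(form)
  v <- if (inherits(tensors, "eeg_tensors")) tensors$values else tensors
  d <- dim(v)
  out <- switch(form,
    "3d" = {
      x <- array(aperm(v, c(2, 3, 4, 1)), dim = c(1, d[2], d[3], d[4], d[1]))
      attr(x, "definition") <- "channel x time x frequency volume"
      x
    },
    "2d" = {
      m <- apply(v, c(1, 3, 4), mean)           # trials x time x freq
      x <- array(aperm(m, c(2, 3, 1)), dim = c(1, 1, d[3], d[4], d[1]))
      attr(x, "definition") <- "channel-averaged time x frequency map"
      x
    },
    "1d" = {
      m <- apply(v, c(1, 2, 3), mean)           # trials x channel x time
      x <- array(aperm(m, c(2, 3, 1)), dim = c(1, d[2], d[3], 1, d[1]))
      attr(x, "definition") <-
        "per-channel frequency-collapsed time vectors, concatenated"
      x
    })
  attr(out, "form") <- form
  out
}

#' Physical receptive-field extent of a kernel
#'
#' Converts a time x frequency kernel size in pixels to milliseconds and
#' hertz using the canonical pixel scale. The default calibration is the
#' rounded pixel size (8.5 ms x 0.5 Hz) used in the published extent
#' table; results are reported at 0.1 precision.
#'
#' @param kernel a [kernel_spec()] or a length-2 vector `c(temporal,
#'   frequency)` in pixels.
#' @param calibration `c(ms, hz)` per pixel.
#' @return Named vector `c(ms = ..., hz = ...)`.
#' @export
kernel_physical_extent <- function(kernel, calibration = c(ms = 8.5,
                                                           hz = 0.5)) {
  if (any(calibration <= 0)) stop("calibration must be positive",
                                  call. = FALSE)
  k <- if (inherits(kernel, "kernel_spec")) {
    c(kernel$temporal, kernel$frequency)
  } else as.numeric(kernel)
  c(ms = round(unname(k[1] * calibration[1]), 1),
    hz = round(unname(k[2] * calibration[2]), 1))
}

# Published receptive-field table (time x frequency pixels with the printed
# ms x Hz extents), used to audit pixel arithmetic.
published_extent_table <- function() {
  tab <- rbind(
    c("square", 3, 3, 25.5, 1.5), c("square", 5, 5, 42.5, 2.5),
    c("square", 7, 7, 59.5, 3.5), c("square", 9, 9, 76.5, 5.5),
    c("long", 5, 3, 42.5, 1.5), c("long", 7, 3, 59.5, 1.5),
    c("long", 9, 3, 76.5, 1.5), c("long", 7, 5, 59.5, 2.5),
    c("long", 9, 5, 76.5, 2.5), c("long", 9, 7, 76.5, 3.5),
    c("wide", 3, 5, 25.5, 2.5), c("wide", 3, 7, 25.5, 5.5),
    c("wide", 3, 9, 25.5, 5.5), c("wide", 5, 7, 42.5, 3.5),
    c("wide", 5, 9, 42.5, 5.5), c("wide", 7, 9, 59.5, 5.5))
  data.frame(shape = tab[, 1], temporal = as.numeric(tab[, 2]),
             frequency = as.numeric(tab[, 3]),
             printed_ms = as.numeric(tab[, 4]),
             printed_hz = as.numeric(tab[, 5]), stringsAsFactors = FALSE)
}

#' Kernel receptive-field calibration table
#'
#' Recomputes the physical extent of every kernel in the published
#' receptive-field table from pixel arithmetic (8.5 ms x 0.5 Hz per pixel)
#' and flags cells where the printed value disagrees with the arithmetic
#' (several 7- and 9-pixel frequency extents are printed as 5.5 Hz where
#' the arithmetic gives 3.5/4.5 Hz).
#'
#' @return A data frame with computed and printed extents and a logical
#'   `flagged` column marking discrepant cells.
#' @export
calibration_table <- function() {
  tab <- published_extent_table()
  ext <- t(apply(tab[, c("temporal", "frequency")], 1,
                 kernel_physical_extent))
  tab$computed_ms <- ext[, "ms"]
  tab$computed_hz <- ext[, "hz"]
  tab$flagged <- tab$computed_ms != tab$printed_ms |
    tab$computed_hz != tab$printed_hz
  tab
}
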
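# Preprocessing chain: Chebyshev band-pass, resampling to 256 Hz,
# re-referencing, epoching with pre-stimulus baseline, >100 uV rejection,
# blank-trial subtraction, and optional ICA ocular cleaning.

#' Design the band-pass Chebyshev filter pair
#'
#' The band-pass is realized as a low-pass / high-pass Chebyshev type-I
#' pair designed from the passband specification (order 2, passband ripple
#' 0.5 dB; low-pass edge 20 Hz, high-pass edge 0.5 Hz). The stopband
#' requirements (>= 5 dB at 40 Hz for the low-pass, >= 10 dB at 0.01 Hz for
#' the high-pass) and stability are verified after the design, and an
#' unmeetable specification raises an error rather than being clipped.
#'
#' @param fs sampling rate in Hz; must exceed twice the highest stopband
#'   edge.
#' @return A list with elements `lowpass` and `highpass`, each of class
#'   `erp_filter` carrying `b`, `a` coefficients and the design fields.
#' @export
design_filters <- function(fs) {
  if (fs <= 2 * 40) stop("`fs` must exceed twice the 40 Hz stopband edge",
                         call. = FALSE)
  lp <- make_cheby1(fs, kind = "low", order = 2, edge = 20, ripple = 0.5,
                    stop_edge = 40, stop_atten = 5)
  hp <- make_cheby1(fs, kind = "high", order = 2, edge = 0.5, ripple = 0.5,
                    stop_edge = 0.01, stop_atten = 10)
  list(lowpass = lp, highpass = hp)
}

make_cheby1 <- function(fs, kind, order, edge, ripple, stop_edge,
                        stop_atten) {
  flt <- signal::cheby1(order, ripple, edge / (fs / 2),
                        type = if (kind == "low") "low" else "high")
  out <- structure(list(b = as.numeric(flt$b), a = as.numeric(flt$a),
                        kind = kind, order = order, passband_edge = edge,
                        stopband_edge = stop_edge,
                        passband_ripple = ripple,
                        stopband_atten = stop_atten, fs = fs),
                   class = "erp_filter")
  # verify stability and the stopband contract post-hoc
  poles <- polyroot(rev(out$a))
  if (any(Mod(poles) >= 1)) {
    stop("designed ", kind, "-pass filter is unstable at fs = ", fs,
         call. = FALSE)
  }
  att <- -filter_gain_db(out, stop_edge)
  if (att < stop_atten) {
    stop(sprintf(
      "%s-pass stopband attenuation %.2f dB at %g Hz misses the %g dB spec",
      kind, att, stop_edge, stop_atten), call. = FALSE)
  }
  out
}

#' Gain of a designed filter in dB
#'
#' @param filt an `erp_filter` from [design_filters()].
#' @param f frequencies in Hz.
#' @return Gain in dB (0 dB = unit gain) at each frequency.
#' @export
filter_gain_db <- function(filt, f) {
  w <- 2 * pi * f / filt$fs
  z <- exp(1i * w)
  num <- outer(z, seq_along(filt$b) - 1, function(zz, k) zz^(-k)) %*% filt$b
  den <- outer(z, seq_along(filt$a) - 1, function(zz, k) zz^(-k)) %*% filt$a
  20 * log10(Mod(num / den))
}

# forward-backward (zero-phase) application along a vector
zero_phase <- function(filt, x) {
  as.numeric(signal::filtfilt(signal::Arma(b = filt$b, a = filt$a), x))
}

#' Band-pass filter and resample a recording to 256 Hz
#'
#' Applies the high-pass then low-pass Chebyshev filters forward-backward
#' (zero-phase, so ERP latencies are not shifted), then downsamples to the
#' target rate. An input already at the target rate passes through the
#' filters but is not resampled; integer ratios subsample directly (the
#' 20 Hz low-pass is the anti-alias filter); non-integer ratios use
#' polyphase resampling. Event marker samples are rescaled accordingly.
#'
#' @param rec an `eeg_recording`.
#' @param target_fs target sampling rate, default 256 Hz.
#' @return The filtered, resampled `eeg_recording`.
#' @export
bandpass_resample <- function(rec, target_fs = 256) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$fs < target_fs) {
    stop("recording rate ", rec$fs, " Hz is below the ", target_fs,
         " Hz target", call. = FALSE)
  }
  filts <- design_filters(rec$fs)
  data <- rec$data
  for (ch in seq_len(nrow(data))) {
    data[ch, ] <- zero_phase(filts$lowpass,
                             zero_phase(filts$highpass, data[ch, ]))
  }
  events <- rec$events
  if (rec$fs != target_fs) {
    ratio <- rec$fs / target_fs
    if (abs(ratio - round(ratio)) < 1e-9) {
      k <- as.integer(round(ratio))
      idx <- seq(1, ncol(data), by = k)
      data <- data[, idx, drop = FALSE]
      events$sample <- (events$sample - 1L) %/% k + 1L
    } else {
      data <- t(apply(data, 1, function(x) {
        as.numeric(signal::resample(x, p = target_fs, q = rec$fs))
      }))
      events$sample <- pmax(1L, as.integer(
        round((events$sample - 1) * target_fs / rec$fs) + 1L))
    }
  }
  structure(list(data = data, fs = target_fs, channels = rec$channels,
                 events = events, subject_id = rec$subject_id),
            class = "eeg_recording")
}

#' Re-reference a recording
#'
#' `"average"` subtracts the instantaneous channel mean (per-sample mean
#' becomes exactly 0); `"none"` is the identity; `"rest"` applies the
#' reference-electrode-standardization transform and requires a
#' user-supplied lead-field matrix (channels x sources) computed from a
#' head model.
#'
#' @param rec an `eeg_recording`.
#' @param scheme `"average"`, `"none"` or `"rest"`.
#' @param leadfield lead-field matrix for `scheme = "rest"`.
#' @return The re-referenced `eeg_recording`.
#' @export
rereference <- function(rec, scheme = c("average", "none", "rest"),
                        leadfield = NULL) {
  stopifnot(inherits(rec, "eeg_recording"), nrow(rec$data) >= 2)
  scheme <- match.arg(scheme)
  if (scheme == "none") return(rec)
  if (scheme == "average") {
    rec$data <- sweep(rec$data, 2, colMeans(rec$data))
    return(rec)
  }
  if (is.null(leadfield)) {
    stop("scheme = \"rest\" requires a `leadfield` matrix", call. = FALSE)
  }
  if (nrow(leadfield) != nrow(rec$data)) {
    stop("leadfield rows must match channel count", call. = FALSE)
  }
  g_avg <- sweep(leadfield, 2, colMeans(leadfield))
  v_avg <- sweep(rec$data, 2, colMeans(rec$data))
  rec$data <- leadfield %*% pseudo_inverse(g_avg) %*% v_avg
  rec
}

pseudo_inverse <- function(m, tol = 1e-10) {
  s <- svd(m)
  keep <- s$d > tol * max(s$d)
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Cut a recording into baseline-corrected epochs
#'
#' Extracts `window` ms around every event marker and subtracts the
#' per-trial, per-channel mean over the `baseline` window. Markers without
#' enough pre/post context are dropped with a warning.
#'
#' @param rec an `eeg_recording` (typically at 256 Hz).
#' @param window epoch window in ms, default -200..800.
#' @param baseline baseline window in ms, default -200..0 (0 exclusive).
#' @return An [eeg_epochs()] object.
#' @export
epoch_recording <- function(rec, window = c(-200, 800),
                            baseline = c(-200, 0)) {
  stopifnot(inherits(rec, "eeg_recording"))
  times <- epoch_times(window, rec$fs)
  n_pre <- sum(times < 0)
  n_post <- length(times) - n_pre
  ok <- rec$events$sample - n_pre >= 1 &
    rec$events$sample + n_post - 1 <= ncol(rec$data)
  if (!all(ok)) {
    warning(sum(!ok), " marker(s) too close to the recording edge; dropped")
  }
  ev <- rec$events[ok, , drop = FALSE]
  if (!nrow(ev)) stop("no epochable markers", call. = FALSE)
  bl <- times >= baseline[1] & times < baseline[2]
  data <- array(0, dim = c(nrow(ev), nrow(rec$data), length(times)))
  for (i in seq_len(nrow(ev))) {
    idx <- ev$sample[i] + seq(-n_pre, n_post - 1)
    m <- rec$data[, idx, drop = FALSE]
    data[i, , ] <- m - rowMeans(m[, bl, drop = FALSE])
  }
  eeg_epochs(data, ev$label, times, rec$fs, rec$channels)
}

#' Reject trials exceeding an amplitude threshold
#'
#' @param epochs an [eeg_epochs()] object.
#' @param threshold peak absolute amplitude in microvolts (default 100).
#' @return The retained epochs; the logical attribute `"rejection_mask"`
#'   (length = input trial count, `TRUE` = kept) records the decision.
#' @export
reject_high_amplitude <- function(epochs, threshold = 100) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop("`threshold` must be a single positive number", call. = FALSE)
  }
  peak <- apply(abs(epochs$data), 1, max)
  keep <- peak <= threshold
  if (!any(keep)) {
    stop("all trials exceed the ", threshold, " uV threshold", call. = FALSE)
  }
  out <- subset_epochs(epochs, keep)
  attr(out, "rejection_mask") <- keep
  out
}

subset_epochs <- function(epochs, keep) {
  out <- eeg_epochs(epochs$data[keep, , , drop = FALSE],
                    epochs$labels[keep], epochs$times, epochs$fs,
                    epochs$channels)
  art <- attr(epochs, "artifact")
  if (!is.null(art)) attr(out, "artifact") <- art[keep]
  out
}

#' Global average of blank trials
#'
#' @param x an [eeg_epochs()] object or a list of them (one per subject);
#'   blank trials are pooled before averaging.
#' @return `channels x samples` matrix.
#' @export
blank_average <- function(x) {
  eps <- if (inherits(x, "eeg_epochs")) list(x) else x
  sums <- NULL
  n <- 0L
  for (ep in eps) {
    keep <- ep$labels == "blank"
    if (!any(keep)) next
    s <- apply(ep$data[keep, , , drop = FALSE], c(2, 3), sum)
    sums <- if (is.null(sums)) s else sums + s
    n <- n + sum(keep)
  }
  if (n == 0L) stop("no blank trials found", call. = FALSE)
  sums / n
}

#' Subtract the blank-name average from name trials
#'
#' The grand average of blank (no-text) trials is the display-locked
#' response baseline; it is subtracted from every self/familiar/stranger
#' trial, and blank trials are removed from the output.
#'
#' @param epochs an [eeg_epochs()] object.
#' @param blank_avg `channels x samples` matrix (e.g. [blank_average()]).
#' @return The corrected [eeg_epochs()] without blank trials.
#' @export
blank_baseline_subtract <- function(epochs, blank_avg) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  d <- dim(epochs$data)
  if (!all(dim(blank_avg) == d[2:3])) {
    stop("`blank_avg` must be channels x samples matching the epochs",
         call. = FALSE)
  }
  keep <- epochs$labels != "blank"
  out <- subset_epochs(epochs, keep)
  out$data <- out$data -
    aperm(array(blank_avg, dim = c(d[2], d[3], sum(keep))), c(3, 1, 2))
  out
}

#' Remove ocular artifacts by ICA
#'
#' `method = "none"` is the identity. `method = "ica"` concatenates the
#' trials, runs a symmetric FastICA decomposition (tanh contrast), flags
#' the components whose time courses correlate with the EOG reference above
#' `threshold` in absolute value, zeroes exactly those components, and
#' back-projects. The default EOG reference is the mean of the frontal-pole
#' channels (Fp1/Fp2). A non-convergent decomposition raises an error.
#'
#' @param epochs an [eeg_epochs()] object with at least 16 trials for ICA.
#' @param method `"none"` or `"ica"`.
#' @param eog optional EOG reference: a numeric vector with one value per
#'   concatenated sample (trials x samples).
#' @param threshold absolute correlation above which a component is flagged.
#' @param seed seed for the ICA initialization.
#' @return The cleaned [eeg_epochs()]; attribute `"ica_flagged"` gives the
#'   indices of removed components. Non-convergence of the decomposition
#'   is surfaced as a warning (near-Gaussian components have no unique
#'   rotation, so the global criterion may not settle on clean data).
#' @export
remove_ocular <- function(epochs, method = c("none", "ica"), eog = NULL,
                          threshold = 0.8, seed = 1) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  method <- match.arg(method)
  if (method == "none") return(epochs)
  d <- dim(epochs$data)
  if (d[1] < 16L) {
    stop("ICA needs at least 16 trials worth of samples", call. = FALSE)
  }
  # channels x (trials * samples), trial-major concatenation
  x <- matrix(aperm(epochs$data, c(2, 3, 1)), d[2], d[1] * d[3])
  mu <- rowMeans(x)
  xc <- x - mu
  if (is.null(eog)) {
    fp <- match(c("Fp1", "Fp2"), epochs$channels)
    if (anyNA(fp)) fp <- 1:2
    eog <- colMeans(xc[fp, , drop = FALSE])
  }
  dec <- fast_ica(xc, seed = seed)
  if (!dec$converged) {
    warning("FastICA did not reach its convergence tolerance after ",
            dec$iterations, " iterations; components in the Gaussian ",
            "subspace are rotation-indeterminate and the current ",
            "decomposition is used")
  }
  r <- as.numeric(cor(t(dec$s), eog))
  flag <- which(abs(r) > threshold)
  s <- dec$s
  if (length(flag)) s[flag, ] <- 0
  xclean <- dec$a %*% s + mu
  out <- epochs
  out$data <- aperm(array(xclean, dim = c(d[2], d[3], d[1])), c(3, 1, 2))
  attr(out, "ica_flagged") <- flag
  out
}

# Symmetric FastICA with tanh contrast on a centered channels x samples
# matrix. Returns sources `s`, mixing `a` (x ~ a %*% s + mean) and a
# convergence flag. On sources that are close to Gaussian the rotation is
# indeterminate and the global criterion may never settle; the caller
# decides how to surface that (back-projection of the full decomposition
# is exact regardless of the rotation).
fast_ica <- function(xc, seed = 1, max_iter = 200, tol = 1e-4) {
  cv <- xc %*% t(xc) / ncol(xc)
  e <- eigen(cv, symmetric = TRUE)
  keep <- e$values > 1e-12 * max(e$values)
  k <- t(e$vectors[, keep, drop = FALSE]) / sqrt(e$values[keep])  # whitener
  z <- k %*% xc
  m <- nrow(z)
  w <- with_seed(seed, matrix(rnorm(m * m), m, m))
  w <- sym_decorrelate(w)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    wz <- w %*% z
    g <- tanh(wz)
    gp <- rowMeans(1 - g^2)
    w1 <- g %*% t(z) / ncol(z) - diag(gp, m) %*% w
    w1 <- sym_decorrelate(w1)
    delta <- max(abs(abs(diag(w1 %*% t(w))) - 1))
    w <- w1
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  s <- w %*% z
  list(s = s, a = pseudo_inverse(w %*% k), unmixing = w %*% k,
       iterations = it, converged = converged)
}

sym_decorrelate <- function(w) {
  s <- svd(w)
  s$u %*% t(s$v)
}

#' Run the full preprocessing chain on a recording
#'
#' Fixed order: band-pass filter, resample to 256 Hz, re-reference,
#' epoch + pre-stimulus baseline, optional ICA ocular removal, amplitude
#' rejection. Blank subtraction is a separate cohort-level step
#' ([blank_baseline_subtract()]) because its average must come from the
#' training split only. The attribute `"config"` records the steps actually
#' run and their parameters.
#'
#' @param rec an `eeg_recording`.
#' @param target_fs resampling target (Hz).
#' @param reref re-referencing scheme, see [rereference()].
#' @param ica if `TRUE`, run [remove_ocular()] with `method = "ica"`.
#' @param window,baseline epoching windows in ms.
#' @param threshold amplitude-rejection threshold in microvolts.
#' @param ... further arguments to [remove_ocular()].
#' @return Clean [eeg_epochs()] with a `"config"` attribute.
#' @export
preprocess_recording <- function(rec, target_fs = 256, reref = "average",
                                 ica = FALSE, window = c(-200, 800),
                                 baseline = c(-200, 0), threshold = 100,
                                 ...) {
  steps <- c("bandpass_filter", "resample", paste0("rereference_", reref))
  rec <- bandpass_resample(rec, target_fs)
  rec <- rereference(rec, reref)
  epochs <- epoch_recording(rec, window, baseline)
  steps <- c(steps, "epoch_baseline")
  if (ica) {
    epochs <- remove_ocular(epochs, method = "ica", ...)
    steps <- c(steps, "ica")
  }
  epochs <- reject_high_amplitude(epochs, threshold)
  steps <- c(steps, "amplitude_reject")
  attr(epochs, "config") <- list(steps = steps, target_fs = target_fs,
                                 reref = reref, window = window,
                                 baseline = baseline, threshold = threshold)
  epochs
}
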
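#' @section Channel montage:
#' The simulator uses a fixed 16-channel 10-20 montage; ERP topographies are
#' frontal/central weighted (Fz, F3, F4, C3, C4 carry the main energy).
#' @name erpauth-montage
#' @keywords internal
NULL

erp_channels <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T7",
    "C3", "Cz", "C4", "T8", "P3", "Pz", "P4", "Oz")
}

# Frontal/central gain template (unit max-abs), peaking at Fz/F3/F4/C3/C4.
# Dipolar return currents make scalp fields approximately spatial-mean-free,
# so temporal/parietal/occipital sites carry mildly negative gains; this is
# what keeps an average reference from cancelling the ERP signal.
frontal_central_topography <- function() {
  g <- c(Fp1 = 0.25, Fp2 = 0.25, F7 = 0.05, F3 = 0.80, Fz = 1.00, F4 = 0.80,
         F8 = 0.05, T7 = -0.50, C3 = 0.70, Cz = 0.85, C4 = 0.70, T8 = -0.50,
         P3 = -0.35, Pz = -0.05, P4 = -0.35, Oz = -0.75)
  unname(g[erp_channels()])
}

# Blink-like frontal gain pattern used for injected ocular artifacts.
ocular_topography <- function() {
  g <- c(Fp1 = 1.00, Fp2 = 1.00, F7 = 0.60, F3 = 0.40, Fz = 0.35, F4 = 0.40,
         F8 = 0.60, T7 = 0.15, C3 = 0.15, Cz = 0.12, C4 = 0.15, T8 = 0.15,
         P3 = 0.05, Pz = 0.05, P4 = 0.05, Oz = 0.02)
  unname(g[erp_channels()])
}

#' Declare one ERP component
#'
#' A component is a Gaussian-windowed half-cosine bump with a per-channel
#' gain vector. Amplitude is in microvolts (negative for the late
#' negativity), latencies and widths in milliseconds.
#'
#' @param name one of `"P200"`, `"P300"`, `"LN"`.
#' @param peak_latency peak time in ms post-stimulus. P300 must lie in
#'   \[250, 650\] ms.
#' @param amplitude peak amplitude in microvolts at the maximal channel.
#' @param width half-width of the temporal envelope in ms (support is
#'   `peak_latency` +/- `width`).
#' @param latency_jitter_sd,amplitude_jitter_sd trial-to-trial jitter SDs.
#' @param topography length-16 per-channel gain vector; rescaled to unit
#'   maximum absolute value.
#' @return An object of class `component_spec`.
#' @export
component_spec <- function(name, peak_latency, amplitude, width,
                           latency_jitter_sd = 0, amplitude_jitter_sd = 0,
                           topography = frontal_central_topography()) {
  name <- match.arg(name, c("P200", "P300", "LN"))
  stopifnot_scalar_num(width, "width")
  if (length(topography) != 16L || all(topography == 0)) {
    stop("`topography` must have 16 entries with at least one nonzero",
         call. = FALSE)
  }
  if (name == "P300" && (peak_latency < 250 || peak_latency > 650)) {
    stop("P300 peak_latency must lie in [250, 650] ms", call. = FALSE)
  }
  topography <- topography / max(abs(topography))
  structure(list(name = name, peak_latency = peak_latency,
                 amplitude = amplitude, width = width,
                 latency_jitter_sd = latency_jitter_sd,
                 amplitude_jitter_sd = amplitude_jitter_sd,
                 topography = topography),
            class = "component_spec")
}

#' Declare a synthetic oddball cohort
#'
#' Encodes the study conditions emulated by the generator: per-class trial
#' counts from the name-oddball paradigm (100 self / 150 familiar /
#' 300 stranger / 50 blank), the epoch window, and the cohort-level effect
#' and noise parameters.
#'
#' @param n_subjects number of subjects.
#' @param trials named vector of per-class trial counts (`self`, `familiar`,
#'   `stranger`, `blank`).
#' @param fs sampling rate in Hz of the generated data.
#' @param window epoch window in ms, must contain 0.
#' @param margin self vs non-self P300 amplitude margin: the self amplitude
#'   is `(1 + margin)` times the subject's base amplitude and all class
#'   differences scale with `margin`, so `margin = 0` makes the three name
#'   classes statistically identical. Default 0.5 (self = 1.5 x non-self).
#' @param noise_level pink-noise RMS per channel in microvolts.
#' @param line_amp,line_freq mains interference amplitude (uV) and frequency.
#' @param artifact_rate fraction of trials receiving a >100 uV ocular
#'   transient (0 disables).
#' @param jitter_scale multiplier on the trial-to-trial latency/amplitude
#'   jitter SDs (1 = realistic jitter, 0 = deterministic components).
#' @param seed master seed; every downstream quantity is a pure function of
#'   the spec, via a master -> subject -> trial seed hierarchy.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 70,
                        trials = c(self = 100, familiar = 150,
                                   stranger = 300, blank = 50),
                        fs = 256, window = c(-200, 800), margin = 0.5,
                        noise_level = 10, line_amp = 1, line_freq = 50,
                        artifact_rate = 0, jitter_scale = 1, seed = 1) {
  stopifnot_scalar_num(n_subjects, "n_subjects")
  if (any(trials <= 0)) stop("trial counts must be > 0", call. = FALSE)
  need <- c("self", "familiar", "stranger", "blank")
  if (!all(need %in% names(trials))) {
    stop("`trials` must name self, familiar, stranger and blank counts",
         call. = FALSE)
  }
  if (window[1] > 0 || window[2] < 0) {
    stop("epoch window must contain 0 ms", call. = FALSE)
  }
  if (margin < 0) stop("`margin` must be >= 0", call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects),
                 trials = trials[need], fs = fs, window = window,
                 margin = margin, noise_level = noise_level,
                 line_amp = line_amp, line_freq = line_freq,
                 artifact_rate = artifact_rate,
                 jitter_scale = jitter_scale, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic oddball cohort:", x$n_subjects, "subjects @", x$fs, "Hz\n")
  cat("  trials/class:", paste(names(x$trials), x$trials, sep = "=",
                               collapse = ", "), "\n")
  cat("  P300 margin:", x$margin, " noise RMS:", x$noise_level, "uV\n")
  invisible(x)
}

class_code <- function(label) {
  match(label, c("self", "familiar", "stranger", "blank"))
}

#' Draw a subject's component profile
#'
#' Deterministic in `(cohort$seed, subject_index)`. Subjects differ in
#' component latencies, amplitudes, widths and topographies (the identity
#' signal); within a subject the self class has a P300 amplitude
#' `(1 + margin)` times the non-self base amplitude and a slightly earlier
#' P300, with familiar/stranger perturbed downward so the self/non-self
#' ratio is at least `1 + margin`.
#'
#' @param cohort a [cohort_spec()].
#' @param subject_index subject number in `1:n_subjects`.
#' @return An object of class `subject_profile`: per-class lists of
#'   [component_spec()]s plus the subject noise level and seed.
#' @export
sample_profile <- function(cohort, subject_index) {
  stopifnot(inherits(cohort, "cohort_spec"))
  if (subject_index < 1 || subject_index > cohort$n_subjects) {
    stop("`subject_index` out of range", call. = FALSE)
  }
  seed_s <- derive_seed(cohort$seed, subject_index)
  m <- cohort$margin
  with_seed(seed_s, {
    lat <- c(P200 = 200 + rnorm(1, 0, 10),
             P300 = min(600, max(300, 450 + rnorm(1, 0, 40))),
             LN = 650 + rnorm(1, 0, 20))
    amp <- c(P200 = 4, P300 = 5, LN = -3.5) * exp(rnorm(3, 0, 0.15))
    wid <- c(P200 = 60, P300 = 150, LN = 120) * exp(rnorm(3, 0, 0.08))
    topo <- lapply(1:3, function(i) {
      frontal_central_topography() + rnorm(16, 0, 0.08)
    })
    js <- cohort$jitter_scale %||% 1
    jit_lat <- c(P200 = 8, P300 = 25, LN = 12) * js
    jit_amp <- abs(amp) * 0.12 * js
    # class modifiers, all proportional to the margin
    mods <- list(
      self = list(p300_amp = 1 + m, p300_lat = -40 * m,
                  p200_amp = 1 + 0.2 * m, ln_amp = 1 + 0.3 * m),
      familiar = list(p300_amp = 1 - 0.05 * m, p300_lat = 0,
                      p200_amp = 1, ln_amp = 1),
      stranger = list(p300_amp = 1 - 0.15 * m, p300_lat = 0,
                      p200_amp = 1, ln_amp = 1))
    comps <- lapply(mods, function(md) {
      list(P200 = component_spec("P200", lat["P200"],
                                 amp["P200"] * md$p200_amp, wid["P200"],
                                 jit_lat["P200"], jit_amp["P200"], topo[[1]]),
           P300 = component_spec("P300",
                                 min(650, max(250,
                                              lat["P300"] + md$p300_lat)),
                                 amp["P300"] * md$p300_amp, wid["P300"],
                                 jit_lat["P300"], jit_amp["P300"], topo[[2]]),
           LN = component_spec("LN", lat["LN"], amp["LN"] * md$ln_amp,
                               wid["LN"], jit_lat["LN"], jit_amp["LN"],
                               topo[[3]]))
    })
    structure(list(subject_id = as.integer(subject_index),
                   components = comps,
                   noise_level = cohort$noise_level * exp(rnorm(1, 0, 0.1)),
                   margin = m, fs = cohort$fs, window = cohort$window,
                   line_amp = cohort$line_amp, line_freq = cohort$line_freq,
                   artifact_rate = cohort$artifact_rate, seed = seed_s),
              class = "subject_profile")
  })
}

#' @export
print.subject_profile <- function(x, ...) {
  p3 <- vapply(x$components, function(cl) cl$P300$amplitude, 0)
  cat("Subject", x$subject_id, "profile; P300 amplitudes (uV):",
      paste(names(p3), round(p3, 2), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# Time axis (ms) of an epoch window at sampling rate fs.
epoch_times <- function(window, fs) {
  n_pre <- round(-window[1] / 1000 * fs)
  n_post <- round(window[2] / 1000 * fs)
  seq(-n_pre, n_post - 1) / fs * 1000
}

# Gaussian-windowed half-cosine bump evaluated on a ms time axis.
component_waveform <- function(t_ms, peak, amplitude, width) {
  u <- t_ms - peak
  w <- numeric(length(t_ms))
  inside <- abs(u) <= width
  sigma <- width / 2
  w[inside] <- amplitude * exp(-u[inside]^2 / (2 * sigma^2)) *
    cos(pi * u[inside] / (2 * width))
  w
}

# 1/f ("pink") noise with unit RMS, shaped in the frequency domain.
pink_noise <- function(n, fs) {
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  f <- seq(0, n - 1) / n * fs
  f <- pmin(f, fs - f)              # two-sided frequency magnitude
  scale <- 1 / sqrt(pmax(f, 1))     # flat below 1 Hz, 1/f above
  scale[1] <- 0                     # kill DC
  x <- Re(stats::fft(spec * scale, inverse = TRUE)) / n
  x / sqrt(mean(x^2))
}

#' Container for epoched EEG
#'
#' @param data numeric array `trials x channels x samples` in microvolts.
#' @param labels character vector of per-trial class labels.
#' @param times ms time axis (must contain 0).
#' @param fs sampling rate in Hz.
#' @param channels channel labels.
#' @return An object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, labels, times, fs, channels = erp_channels()) {
  stopifnot(length(dim(data)) == 3L, dim(data)[1] == length(labels),
            dim(data)[3] == length(times))
  if (!any(times == 0)) stop("`times` must contain 0 ms", call. = FALSE)
  structure(list(data = data, labels = labels, times = times, fs = fs,
                 channels = channels),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("eeg_epochs: %d trials x %d channels x %d samples @ %g Hz\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$fs))
  cat("  classes:", paste(names(table(x$labels)), table(x$labels),
                          sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Synthesize epoched trials for one subject and class
#'
#' Each trial is the sum of the class's jittered ERP components, pink noise,
#' optional mains interference, and (at `artifact_rate`) a >100 uV frontal
#' ocular transient. Blank trials contain noise only. Deterministic given
#' the profile: trial `i` uses the derived seed `(profile$seed, class, i)`,
#' so the first `k` trials do not depend on `n_trials`.
#'
#' @param profile a [sample_profile()] result.
#' @param class_label `"self"`, `"familiar"`, `"stranger"` or `"blank"`.
#' @param n_trials number of trials (> 0).
#' @return An [eeg_epochs()] object; the logical attribute `"artifact"`
#'   marks trials that received an injected ocular transient.
#' @export
synthesize_epochs <- function(profile, class_label, n_trials) {
  stopifnot(inherits(profile, "subject_profile"))
  cls <- class_code(class_label)
  if (is.na(cls)) stop("unknown class label: ", class_label, call. = FALSE)
  if (n_trials < 1) stop("`n_trials` must be > 0", call. = FALSE)
  times <- epoch_times(profile$window, profile$fs)
  ns <- length(times)
  data <- array(0, dim = c(n_trials, 16L, ns))
  artifact <- logical(n_trials)
  comps <- if (class_label == "blank") NULL else
    profile$components[[class_label]]
  for (i in seq_len(n_trials)) {
    seed_t <- derive_seed(profile$seed, cls, i)
    trial <- with_seed(seed_t, {
      m <- matrix(0, 16L, ns)
      for (cmp in comps) {
        lat <- cmp$peak_latency + rnorm(1, 0, cmp$latency_jitter_sd)
        amp <- cmp$amplitude + rnorm(1, 0, cmp$amplitude_jitter_sd)
        wave <- component_waveform(times, lat, amp, cmp$width)
        m <- m + outer(cmp$topography, wave)
      }
      if (profile$noise_level > 0) {
        for (ch in 1:16) {
          m[ch, ] <- m[ch, ] + profile$noise_level * pink_noise(ns, profile$fs)
        }
      }
      if (profile$line_amp > 0 && profile$noise_level > 0) {
        phase <- runif(1, 0, 2 * pi)
        m <- m + profile$line_amp *
          matrix(sin(2 * pi * profile$line_freq * times / 1000 + phase),
                 16L, ns, byrow = TRUE)
      }
      if (profile$artifact_rate > 0 && runif(1) < profile$artifact_rate) {
        t0 <- runif(1, 100, 600)
        m <- m + outer(ocular_topography(),
                       150 * exp(-(times - t0)^2 / (2 * 50^2)))
        attr(m, "artifact") <- TRUE
      }
      m
    })
    artifact[i] <- isTRUE(attr(trial, "artifact"))
    data[i, , ] <- trial
  }
  ep <- eeg_epochs(data, rep(class_label, n_trials), times, profile$fs)
  attr(ep, "artifact") <- artifact
  ep
}

#' Simulate all epochs of one subject
#'
#' Convenience wrapper: draws the subject profile and synthesizes all four
#' classes with the cohort's per-class trial counts, in randomized trial
#' order.
#'
#' @inheritParams sample_profile
#' @return An [eeg_epochs()] object with the subject profile attached as
#'   attribute `"profile"`.
#' @export
simulate_subject_epochs <- function(cohort, subject_index) {
  profile <- sample_profile(cohort, subject_index)
  parts <- lapply(names(cohort$trials), function(cl) {
    synthesize_epochs(profile, cl, cohort$trials[[cl]])
  })
  n <- sum(cohort$trials)
  ns <- length(parts[[1]]$times)
  data <- array(0, dim = c(n, 16L, ns))
  labels <- character(n)
  artifact <- logical(n)
  at <- 0L
  for (p in parts) {
    k <- dim(p$data)[1]
    data[at + seq_len(k), , ] <- p$data
    labels[at + seq_len(k)] <- p$labels
    artifact[at + seq_len(k)] <- attr(p, "artifact")
    at <- at + k
  }
  ord <- with_seed(derive_seed(profile$seed, 99L), sample.int(n))
  ep <- eeg_epochs(data[ord, , , drop = FALSE], labels[ord],
                   parts[[1]]$times, profile$fs)
  attr(ep, "artifact") <- artifact[ord]
  attr(ep, "profile") <- profile
  ep
}

#' Simulate a continuous recording for one subject
#'
#' Stimuli are presented in randomized order on a continuous pink-noise
#' background (plus mains interference), with inter-stimulus onsets of
#' ~1.35 s so every marker has at least 200 ms of pre- and 800 ms of
#' post-stimulus context.
#'
#' @inheritParams sample_profile
#' @return An object of class `eeg_recording`: `data` (16 x samples matrix,
#'   microvolts), `fs`, `channels`, and `events` (data frame of marker
#'   `sample` and `label`).
#' @export
simulate_recording <- function(cohort, subject_index) {
  profile <- sample_profile(cohort, subject_index)
  fs <- cohort$fs
  labels <- rep(names(cohort$trials), cohort$trials)
  n_ev <- length(labels)
  seed_r <- derive_seed(profile$seed, 7L)
  with_seed(seed_r, {
    labels <- sample(labels)
    iti <- 1.35 + runif(n_ev, -0.1, 0.1)           # seconds between onsets
    onsets <- round((2 + cumsum(c(0, iti[-n_ev]))) * fs) + 1L
    total <- onsets[n_ev] + round(1.2 * fs)
    data <- matrix(0, 16L, total)
    for (ch in 1:16) {
      data[ch, ] <- profile$noise_level * pink_noise(total, fs)
    }
    if (profile$line_amp > 0) {
      tt <- seq_len(total) / fs
      data <- data + profile$line_amp *
        matrix(sin(2 * pi * profile$line_freq * tt + runif(1, 0, 2 * pi)),
               16L, total, byrow = TRUE)
    }
    t_rel <- seq(0, round(0.9 * fs)) / fs * 1000   # 0..900 ms post-onset
    for (i in seq_len(n_ev)) {
      if (labels[i] == "blank") next
      comps <- profile$components[[labels[i]]]
      wave <- matrix(0, 16L, length(t_rel))
      for (cmp in comps) {
        lat <- cmp$peak_latency + rnorm(1, 0, cmp$latency_jitter_sd)
        amp <- cmp$amplitude + rnorm(1, 0, cmp$amplitude_jitter_sd)
        wave <- wave + outer(cmp$topography,
                             component_waveform(t_rel, lat, amp, cmp$width))
      }
      idx <- onsets[i] + seq_along(t_rel) - 1L
      data[, idx] <- data[, idx] + wave
      if (profile$artifact_rate > 0 && runif(1) < profile$artifact_rate) {
        t0 <- runif(1, 100, 600)
        data[, idx] <- data[, idx] +
          outer(ocular_topography(), 150 * exp(-(t_rel - t0)^2 / (2 * 50^2)))
      }
    }
    structure(list(data = data, fs = fs, channels = erp_channels(),
                   events = data.frame(sample = onsets, label = labels,
                                       stringsAsFactors = FALSE),
                   subject_id = as.integer(subject_index)),
              class = "eeg_recording")
  })
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("eeg_recording: %d channels x %d samples @ %g Hz, %d markers\n",
              nrow(x$data), ncol(x$data), x$fs, nrow(x$events)))
  invisible(x)
}

#' Write a cohort of recordings to disk
#'
#' One file per subject (`sub-XX.rds`) plus the cohort spec
#' (`cohort-spec.rds`) and a plain-text manifest. Files round-trip
#' bit-exactly through [read_recording()].
#'
#' @param cohort a [cohort_spec()].
#' @param path output directory (created if needed).
#' @return Invisibly, the vector of subject file paths.
#' @export
write_cohort <- function(cohort, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  files <- character(cohort$n_subjects)
  for (i in seq_len(cohort$n_subjects)) {
    rec <- simulate_recording(cohort, i)
    files[i] <- file.path(path, sprintf("sub-%02d.rds", i))
    saveRDS(rec, files[i])
  }
  saveRDS(cohort, file.path(path, "cohort-spec.rds"))
  writeLines(c(sprintf("subjects: %d", cohort$n_subjects),
               sprintf("fs_hz: %g", cohort$fs),
               sprintf("markers_per_subject: %d", sum(cohort$trials)),
               paste("files:", paste(basename(files), collapse = " "))),
             file.path(path, "MANIFEST.txt"))
  invisible(files)
}

#' Read one recording written by [write_cohort()]
#'
#' @param file path to a `sub-XX.rds` file.
#' @return An `eeg_recording` object, bit-identical to what was written.
#' @export
read_recording <- function(file) {
  rec <- readRDS(file)
  if (!inherits(rec, "eeg_recording")) {
    stop("`file` does not contain an eeg_recording", call. = FALSE)
  }
  rec
}

#' Grand-average waveform over trials
#'
#' @param epochs an [eeg_epochs()] object.
#' @param label optional class restriction.
#' @return `channels x samples` matrix of mean microvolts.
#' @export
grand_average <- function(epochs, label = NULL) {
  keep <- if (is.null(label)) seq_along(epochs$labels) else
    which(epochs$labels == label)
  if (!length(keep)) stop("no trials with label ", label, call. = FALSE)
  apply(epochs$data[keep, , , drop = FALSE], c(2, 3), mean)
}
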
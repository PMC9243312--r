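# Shared fixtures, built once per test run and cached in this environment.
# Everything is generated in code; no data files.

.fixtures <- new.env()

# small desk cohort used across tests (balanced self vs non-self)
fixture_cohort <- function() {
  cohort_spec(n_subjects = 2,
              trials = c(self = 12, familiar = 6, stranger = 6, blank = 5),
              noise_level = 5, seed = 42)
}

# tensorized single subject of the fixture cohort (cached)
fixture_data <- function() {
  if (is.null(.fixtures$data)) {
    ep <- simulate_subject_epochs(fixture_cohort(), 1)
    ep <- blank_baseline_subtract(ep, blank_average(ep))
    tens <- stack_tensor(ep)
    .fixtures$data <- list(tensors = tens, y01 = make_labels(tens$labels),
                           epochs = ep)
  }
  .fixtures$data
}

# a tiny but spec-conformant 2D network (3 modules)
fixture_spec_small <- function(dropout = 0.4) {
  network_spec("2d", list(
    module_spec(list(kernel_spec(3, 3)), 2, pool = c(1, 3, 3),
                reduce = FALSE),
    module_spec(list(kernel_spec(3, 3), kernel_spec(5, 5)), 2,
                pool = c(1, 3, 3)),
    module_spec(list(kernel_spec(3, 3)), 4, pool = c(1, 2, 2),
                reduce = FALSE)),
    dropout = dropout)
}

# quick training control for unit tests
fixture_control <- function(seed = 1, epochs = 4) {
  train_control(learning_rate = 5e-3, epochs = epochs, batch_size = 12,
                seed = seed)
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# direct windowed-DFT spectrogram oracle (independent of signal::specgram)
oracle_spectrogram <- function(x, fs, win_len = 64, overlap = 57,
                               nfft = 256, f_max = 30) {
  hop <- win_len - overlap
  n <- length(x)
  ham <- 0.54 - 0.46 * cos(2 * pi * (0:(win_len - 1)) / (win_len - 1))
  offsets <- if (n > win_len) seq(1, n - win_len, by = hop) else 1
  freqs <- (0:(nfft - 1)) * fs / nfft
  keep <- which(freqs <= f_max & seq_along(freqs) <= nfft / 2)
  pow <- matrix(0, length(offsets), length(keep))
  for (i in seq_along(offsets)) {
    seg <- x[offsets[i]:(offsets[i] + win_len - 1)] * ham
    for (j in seq_along(keep)) {
      k <- keep[j] - 1
      ph <- exp(-2i * pi * k * (0:(win_len - 1)) / nfft)
      pow[i, j] <- Mod(sum(seg * ph))^2
    }
  }
  list(power = pow,
       time_ms = (offsets - 1 + (win_len - 1) / 2) / fs * 1000,
       freq_hz = freqs[keep])
}
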
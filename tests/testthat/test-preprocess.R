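# Preprocessing chain: Chebyshev filter contracts, zero-phase filtering,
# resampling, re-referencing, epoching/baseline, rejection, blank
# subtraction, ICA ocular removal.

test_that("low-pass meets its stopband and passband contract", {
  filts <- design_filters(1024)
  lp <- filts$lowpass
  expect_lte(filter_gain_db(lp, 40), -5)
  expect_lt(abs(filter_gain_db(lp, 1e-6)), 0.5 + 1e-6)
  pass <- filter_gain_db(lp, seq(0.5, 20, by = 0.5))
  expect_true(all(pass <= 0.01 & pass >= -0.55))
  # stability: poles inside the unit circle
  expect_true(all(Mod(polyroot(rev(lp$a))) < 1))
})

test_that("high-pass attenuates the deep stopband and passes the band", {
  filts <- design_filters(1024)
  hp <- filts$highpass
  expect_lte(filter_gain_db(hp, 0.01), -10)
  expect_lt(abs(filter_gain_db(hp, 10)), 0.5)
  expect_true(all(Mod(polyroot(rev(hp$a))) < 1))
})

test_that("sinusoids survive or die across the filter bands", {
  fs <- 1024
  filts <- design_filters(fs)
  t <- seq(0, 4, by = 1 / fs)
  rms <- function(x) sqrt(mean(x^2))
  keep <- sin(2 * pi * 10 * t)
  out <- erpauth:::zero_phase(filts$lowpass, keep)
  mid <- seq(fs, 3 * fs)  # avoid edge transients
  expect_lt(abs(20 * log10(rms(out[mid]) / rms(keep[mid]))), 0.5)
  kill <- sin(2 * pi * 45 * t)
  out2 <- erpauth:::zero_phase(filts$lowpass, kill)
  expect_lte(20 * log10(rms(out2[mid]) / rms(kill[mid])), -5)
})

test_that("zero-phase filtering does not shift a band-limited template", {
  fs <- 1024
  t <- seq(0, 2, by = 1 / fs)
  template <- exp(-(t - 1)^2 / (2 * 0.05^2))
  filts <- design_filters(fs)
  out <- erpauth:::zero_phase(filts$lowpass, template)
  cc <- stats::ccf(out, template, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("band-pass + resample yields 256 Hz and preserves tones", {
  fs <- 1024
  n <- fs * 6
  tt <- seq_len(n) / fs
  sig <- 40 * sin(2 * pi * 8 * tt)
  rec <- structure(list(
    data = matrix(rep(sig, each = 16) + rnorm(16 * n, 0, 0.01), 16, n,
                  byrow = FALSE),
    fs = fs, channels = erp_channels(),
    events = data.frame(sample = c(2048L, 3072L), label = c("self", "blank")),
    subject_id = 1L), class = "eeg_recording")
  rec$data <- matrix(sig, 16, n, byrow = TRUE)
  out <- bandpass_resample(rec)
  expect_equal(out$fs, 256)
  expect_equal(ncol(out$data), n / 4)
  expect_equal(out$events$sample, c(512L, 768L))
  mid <- seq(256, ncol(out$data) - 256)
  ratio_db <- 20 * log10(sqrt(mean(out$data[1, mid]^2)) / sqrt(mean(sig^2)))
  # zero-phase application realizes twice the designed single-pass gain
  filts <- design_filters(fs)
  design_db <- 2 * (filter_gain_db(filts$lowpass, 8) +
                      filter_gain_db(filts$highpass, 8))
  expect_lt(abs(ratio_db - design_db), 0.1)
  expect_gt(design_db, -2)
  # DC input is removed by the high-pass (interior, past edge transients)
  rec$data <- matrix(25, 16, n)
  flat <- bandpass_resample(rec)
  core <- seq(2 * 256, 4 * 256)
  expect_lt(max(abs(flat$data[, core])), 1)
  # an already-256 Hz recording is filtered but not resampled
  rec256 <- rec
  rec256$fs <- 256
  out256 <- bandpass_resample(rec256)
  expect_equal(ncol(out256$data), n)
})

test_that("re-referencing schemes behave as declared", {
  set.seed(1)
  rec <- structure(list(data = matrix(rnorm(16 * 100), 16),
                        fs = 256, channels = erp_channels(),
                        events = data.frame(sample = 50L, label = "self")),
                   class = "eeg_recording")
  avg <- rereference(rec, "average")
  expect_lt(max(abs(colMeans(avg$data))), 1e-12)
  # idempotent on already average-referenced data
  again <- rereference(avg, "average")
  expect_equal(again$data, avg$data, tolerance = 1e-12)
  expect_identical(rereference(rec, "none"), rec)
  expect_error(rereference(rec, "rest"), "leadfield")
})

test_that("epoching drops edge markers and zeroes the baseline window", {
  coh <- cohort_spec(n_subjects = 1,
                     trials = c(self = 8, familiar = 4, stranger = 4,
                                blank = 3),
                     noise_level = 5, seed = 23)
  rec <- simulate_recording(coh, 1)
  rec$events <- rbind(data.frame(sample = 10L, label = "self"), rec$events)
  expect_warning(ep <- epoch_recording(rec), "dropped")
  expect_equal(dim(ep$data)[1], sum(coh$trials))
  bl <- ep$times >= -200 & ep$times < 0
  bl_means <- apply(ep$data[, , bl], c(1, 2), mean)
  expect_lt(max(abs(bl_means)), 1e-9)
  # a constant channel epochs to all zeros after baseline correction
  rec$data[3, ] <- 7.5
  ep2 <- suppressWarnings(epoch_recording(rec))
  expect_lt(max(abs(ep2$data[, 3, ])), 1e-9)
})

test_that("amplitude rejection keeps exactly the sub-threshold trials", {
  coh <- cohort_spec(n_subjects = 1, noise_level = 0, line_amp = 0,
                     jitter_scale = 0, seed = 2,
                     trials = c(self = 3, familiar = 3, stranger = 3,
                                blank = 3))
  p <- sample_profile(coh, 1)
  ep <- synthesize_epochs(p, "self", 3)
  ep$data[2, 5, 100] <- 150   # inject one violating trial
  out <- reject_high_amplitude(ep, 100)
  mask <- attr(out, "rejection_mask")
  expect_equal(mask, c(TRUE, FALSE, TRUE))
  expect_equal(dim(out$data)[1], 2)
  # infinite threshold keeps everything
  all_kept <- reject_high_amplitude(ep, Inf)
  expect_equal(dim(all_kept$data)[1], 3)
  ep$data[] <- 1e4
  expect_error(reject_high_amplitude(ep, 100), "all trials")
})

test_that("rejection recovers an injected artifact fraction", {
  coh <- cohort_spec(n_subjects = 1,
                     trials = c(self = 100, familiar = 5, stranger = 5,
                                blank = 5),
                     artifact_rate = 0.1, noise_level = 5, seed = 77)
  p <- sample_profile(coh, 1)
  ep <- synthesize_epochs(p, "self", 100)
  out <- reject_high_amplitude(ep, 100)
  frac <- 1 - mean(attr(out, "rejection_mask"))
  expect_equal(frac, mean(attr(ep, "artifact")), tolerance = 1e-9)
  expect_gt(frac, 0.02)
  expect_lt(frac, 0.25)
})

test_that("blank-average subtraction is exact arithmetic", {
  coh <- cohort_spec(n_subjects = 1, noise_level = 5, seed = 3,
                     trials = c(self = 6, familiar = 4, stranger = 4,
                                blank = 6))
  ep <- simulate_subject_epochs(coh, 1)
  ba <- blank_average(ep)
  out <- blank_baseline_subtract(ep, ba)
  expect_false("blank" %in% out$labels)
  i_in <- which(ep$labels != "blank")[1]
  expect_equal(out$data[1, , ], ep$data[i_in, , ] - ba, tolerance = 1e-12)
  # zero blank average is the identity on name trials
  out0 <- blank_baseline_subtract(ep, ba * 0)
  expect_equal(out0$data[1, , ], ep$data[i_in, , ], tolerance = 1e-12)
  # a trial equal to the blank average maps to zero
  ep$data[i_in, , ] <- ba
  out1 <- blank_baseline_subtract(ep, ba)
  expect_lt(max(abs(out1$data[1, , ])), 1e-12)
  expect_error(blank_baseline_subtract(ep, ba[, 1:10]), "channels x samples")
})

test_that("ICA removes an injected stereotyped frontal artifact", {
  coh <- cohort_spec(n_subjects = 1, noise_level = 6, seed = 19,
                     trials = c(self = 20, familiar = 4, stranger = 4,
                                blank = 4))
  p <- sample_profile(coh, 1)
  ep <- synthesize_epochs(p, "self", 20)
  d <- dim(ep$data)
  # stereotyped blink source with a known frontal mixing vector
  topo <- erpauth:::ocular_topography()
  set.seed(4)
  source_tc <- numeric(d[1] * d[3])
  for (i in seq_len(d[1])) {
    t0 <- runif(1, 200, 600)
    idx <- (i - 1) * d[3] + seq_len(d[3])
    source_tc[idx] <- 120 * exp(-(ep$times - t0)^2 / (2 * 40^2))
  }
  art <- array(0, d)
  for (i in seq_len(d[1])) {
    seg <- source_tc[(i - 1) * d[3] + seq_len(d[3])]
    art[i, , ] <- outer(topo, seg)
  }
  dirty <- ep
  dirty$data <- ep$data + art
  clean <- suppressWarnings(
    remove_ocular(dirty, method = "ica", threshold = 0.7, seed = 2))
  expect_gt(length(attr(clean, "ica_flagged")), 0)
  fp <- which(ep$channels == "Fp1")
  cleaned_tc <- as.numeric(t(clean$data[, fp, ]))
  dirty_tc <- as.numeric(t(dirty$data[, fp, ]))
  expect_gt(abs(cor(dirty_tc, source_tc)), 0.8)
  expect_lt(abs(cor(cleaned_tc, source_tc)), 0.2)
})

test_that("ICA is a tolerance-bounded no-op on artifact-free data", {
  coh <- cohort_spec(n_subjects = 1, noise_level = 6, seed = 29,
                     trials = c(self = 18, familiar = 4, stranger = 4,
                                blank = 4))
  p <- sample_profile(coh, 1)
  ep <- synthesize_epochs(p, "self", 18)
  once <- suppressWarnings(remove_ocular(ep, method = "ica", seed = 5))
  twice <- suppressWarnings(remove_ocular(once, method = "ica", seed = 5))
  rel <- max(abs(twice$data - once$data)) / max(abs(once$data))
  expect_lt(rel, 0.05)
  expect_identical(remove_ocular(ep, method = "none"), ep)
  small <- erpauth:::subset_epochs(ep, 1:5)
  expect_error(remove_ocular(small, method = "ica"), "16 trials")
})

test_that("the full chain runs in the declared order", {
  coh <- cohort_spec(n_subjects = 1, noise_level = 5, seed = 37,
                     trials = c(self = 6, familiar = 3, stranger = 3,
                                blank = 3))
  rec <- simulate_recording(coh, 1)
  ep <- preprocess_recording(rec)
  cfg <- attr(ep, "config")
  expect_equal(cfg$steps,
               c("bandpass_filter", "resample", "rereference_average",
                 "epoch_baseline", "amplitude_reject"))
  expect_equal(ep$fs, 256)
  expect_equal(dim(ep$data)[2], 16)
  expect_true(all(ep$labels %in% c("self", "familiar", "stranger", "blank")))
})
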
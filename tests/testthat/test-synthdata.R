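# Synthetic oddball-ERP generator: determinism, oddball effect structure,
# degenerate limits, file round-trips, spectral realism.

test_that("profiles are deterministic and subject-distinct", {
  coh <- cohort_spec(n_subjects = 5, seed = 7)
  p1 <- sample_profile(coh, 3)
  p2 <- sample_profile(coh, 3)
  expect_identical(p1, p2)
  p_other <- sample_profile(coh, 4)
  expect_false(isTRUE(all.equal(
    p1$components$self$P300$peak_latency,
    p_other$components$self$P300$peak_latency)))
  expect_error(sample_profile(coh, 6), "out of range")
})

test_that("self P300 amplitude exceeds non-self by the configured margin", {
  coh <- cohort_spec(n_subjects = 70, margin = 0.5, seed = 1)
  ratios <- vapply(1:70, function(i) {
    p <- sample_profile(coh, i)
    p$components$self$P300$amplitude /
      max(p$components$familiar$P300$amplitude,
          p$components$stranger$P300$amplitude)
  }, 0)
  expect_true(all(ratios > 1))
  expect_true(all(ratios >= 1 + coh$margin - 1e-9))
})

test_that("zero margin with zero noise collapses class differences", {
  coh <- cohort_spec(n_subjects = 1, margin = 0, noise_level = 0,
                     line_amp = 0, jitter_scale = 0, seed = 3)
  p <- sample_profile(coh, 1)
  a <- synthesize_epochs(p, "self", 2)
  b <- synthesize_epochs(p, "familiar", 2)
  expect_equal(a$data, b$data, tolerance = 1e-12)
})

test_that("noise-free single trial equals the deterministic component sum", {
  coh <- cohort_spec(n_subjects = 1, noise_level = 0, line_amp = 0,
                     jitter_scale = 0, seed = 9)
  p <- sample_profile(coh, 1)
  ep <- synthesize_epochs(p, "self", 1)
  times <- ep$times
  manual <- matrix(0, 16, length(times))
  for (cmp in p$components$self) {
    manual <- manual + outer(
      cmp$topography,
      erpauth:::component_waveform(times, cmp$peak_latency, cmp$amplitude,
                                   cmp$width))
  }
  expect_equal(ep$data[1, , ], manual, tolerance = 1e-12)
  # blank class carries no components
  blank <- synthesize_epochs(p, "blank", 1)
  expect_equal(max(abs(blank$data)), 0)
})

test_that("self grand average peaks inside the P300 energy window", {
  coh <- cohort_spec(n_subjects = 1,
                     trials = c(self = 60, familiar = 5, stranger = 5,
                                blank = 5),
                     noise_level = 5, seed = 21)
  p <- sample_profile(coh, 1)
  ep <- synthesize_epochs(p, "self", 60)
  ga <- grand_average(ep)
  fz <- which(ep$channels == "Fz")
  post <- ep$times >= 250 & ep$times <= 700
  peak_t <- ep$times[post][which.max(ga[fz, post])]
  expect_gt(peak_t, 300)
  expect_lt(peak_t, 650)
  expect_lt(abs(peak_t - p$components$self$P300$peak_latency), 80)
})

test_that("blank grand average shrinks toward zero with trial count", {
  coh <- cohort_spec(n_subjects = 1, noise_level = 8, seed = 5)
  p <- sample_profile(coh, 1)
  few <- grand_average(synthesize_epochs(p, "blank", 5))
  many <- grand_average(synthesize_epochs(p, "blank", 80))
  expect_lt(sqrt(mean(many^2)), sqrt(mean(few^2)))
  expect_lt(sqrt(mean(many^2)), 0.35 * p$noise_level)
})

test_that("generated noise power concentrates below 30 Hz", {
  coh <- cohort_spec(n_subjects = 1, noise_level = 10, seed = 2)
  p <- sample_profile(coh, 1)
  ep <- synthesize_epochs(p, "blank", 20)
  x <- as.numeric(t(ep$data[, 1, ]))  # concatenate trials in time
  spec <- Mod(stats::fft(x - mean(x)))^2
  n <- length(x)
  f <- pmin(seq(0, n - 1), n - seq(0, n - 1)) / n * ep$fs
  frac <- sum(spec[f <= 30]) / sum(spec)
  expect_gt(frac, 0.6)
})

test_that("matched-filter separability is monotone in the margin", {
  sep <- vapply(c(0, 0.25, 0.5, 1), function(m) {
    coh <- cohort_spec(n_subjects = 1, margin = m, noise_level = 0,
                       line_amp = 0, jitter_scale = 0, seed = 13)
    p <- sample_profile(coh, 1)
    s <- synthesize_epochs(p, "self", 1)$data[1, , ]
    ns <- (synthesize_epochs(p, "familiar", 1)$data[1, , ] +
             synthesize_epochs(p, "stranger", 1)$data[1, , ]) / 2
    sqrt(sum((s - ns)^2))
  }, 0)
  expect_true(all(diff(sep) >= -1e-9))
})

test_that("recordings carry all markers and round-trip bit-exactly", {
  coh <- cohort_spec(n_subjects = 2,
                     trials = c(self = 10, familiar = 5, stranger = 5,
                                blank = 4),
                     noise_level = 5, seed = 31)
  dir <- withr::local_tempdir()
  files <- write_cohort(coh, dir)
  expect_length(files, 2)
  rec <- read_recording(files[1])
  expect_s3_class(rec, "eeg_recording")
  expect_equal(nrow(rec$events), sum(coh$trials))
  rec2 <- read_recording(files[1])
  expect_identical(rec, rec2)
  direct <- simulate_recording(coh, 1)
  expect_identical(rec, direct)
})

test_that("artifact trials exceed the rejection threshold when enabled", {
  coh <- cohort_spec(n_subjects = 1,
                     trials = c(self = 40, familiar = 5, stranger = 5,
                                blank = 5),
                     artifact_rate = 0.5, noise_level = 5, seed = 17)
  p <- sample_profile(coh, 1)
  ep <- synthesize_epochs(p, "self", 40)
  art <- attr(ep, "artifact")
  expect_gt(sum(art), 5)
  peaks <- apply(abs(ep$data), 1, max)
  expect_true(all(peaks[art] > 100))
})
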
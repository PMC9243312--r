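# Training/evaluation protocols: label mapping, fold partitioning,
# training behavior, cohort splits, leakage audit.

test_that("authentication labels map self vs non-self", {
  expect_equal(make_labels(c("self", "familiar", "stranger")),
               c(1L, 0L, 0L))
  expect_equal(make_labels(character(0)), integer(0))
  expect_error(make_labels(c("self", "blank")), "unknown")
  # default paradigm class counts give the 100/550 positive fraction
  coh <- cohort_spec()
  y <- make_labels(rep(c("self", "familiar", "stranger"),
                       coh$trials[c("self", "familiar", "stranger")]))
  expect_equal(mean(y), 100 / 550)
})

test_that("stratified folds partition every trial exactly once", {
  y <- rep(c(1L, 0L), c(13, 22))
  assign <- erpauth:::stratified_folds(y, 5, seed = 3)
  expect_equal(sort(unique(assign)), 1:5)
  expect_equal(length(assign), 35)
  for (f in 1:5) {
    expect_gte(sum(y[assign == f] == 1), 2)
    expect_gte(sum(y[assign == f] == 0), 4)
  }
  # union of test folds = all trials, disjoint by construction
  expect_equal(sort(unlist(lapply(1:5, function(f) which(assign == f)))),
               1:35)
})

test_that("zero learning rate leaves the weights unchanged", {
  d <- fixture_data()
  xin <- to_input_form(d$tensors, "2d")
  spec <- fixture_spec_small()
  net0 <- build_network(spec, 5)
  tr <- erpauth:::train_network(net0, xin, d$y01,
                                train_control(learning_rate = 0,
                                              epochs = 2, batch_size = 8))
  expect_identical(tr$net$params, net0$params)
  expect_true(all(is.finite(tr$trace)))
})

test_that("training separates a linearly separable toy problem", {
  set.seed(2)
  n <- 40
  y <- rep(c(0L, 1L), each = n / 2)
  x <- array(rnorm(1 * 1 * 94 * 60 * n, sd = 0.2), c(1, 1, 94, 60, n))
  x[1, 1, 40:50, 10:20, y == 1] <- x[1, 1, 40:50, 10:20, y == 1] + 3
  spec <- fixture_spec_small(dropout = 0)
  fit <- eeg_cnn(x, y, spec,
                 control = train_control(learning_rate = 5e-3, epochs = 10,
                                         batch_size = 10, seed = 1))
  acc <- authentication_accuracy(fit, x, y)
  expect_equal(unname(acc["accuracy"]), 1.0)
  expect_lt(tail(fit$loss_trace, 1), head(fit$loss_trace, 1))
})

test_that("training is deterministic given the seed", {
  d <- fixture_data()
  xin <- to_input_form(d$tensors, "2d")
  spec <- fixture_spec_small()
  ctl <- fixture_control(seed = 9, epochs = 2)
  f1 <- eeg_cnn(xin, d$y01, spec, control = ctl)
  f2 <- eeg_cnn(xin, d$y01, spec, control = ctl)
  expect_identical(f1$network$params, f2$network$params)
  expect_identical(f1$loss_trace, f2$loss_trace)
  # trial order shuffling does not change fold-seeded CV accuracy
  rep1 <- evaluate_within_subject(spec, xin, d$y01, folds = 3,
                                  control = ctl, seed = 4)
  ord <- with_seed_test(11, sample(length(d$y01)))
  rep2 <- evaluate_within_subject(spec, erpauth:::slice_batch(xin, ord),
                                  d$y01[ord], folds = 3,
                                  control = ctl, seed = 4)
  expect_equal(rep1$mean, rep2$mean, tolerance = 0.2)
})

test_that("eeg_cnn methods behave like a classed model fit", {
  d <- fixture_data()
  xin <- to_input_form(d$tensors, "2d")
  spec <- fixture_spec_small()
  fit <- eeg_cnn(xin, d$y01, spec, control = fixture_control(epochs = 2))
  expect_s3_class(fit, "eeg_cnn")
  expect_output(print(fit), "eeg_cnn")
  p <- predict(fit, xin, type = "prob")
  expect_true(all(p >= 0 & p <= 1))
  cls <- predict(fit, xin)
  expect_s3_class(cls, "factor")
  expect_setequal(levels(cls), c("nonself", "self"))
  expect_type(coef(fit), "list")
  expect_true("head_w1" %in% names(coef(fit)))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("within-subject CV errors on unstratifiable inputs", {
  d <- fixture_data()
  expect_error(
    evaluate_within_subject(fixture_spec_small(), d$tensors,
                            folds = 50),
    "stratification")
})

test_that("cohort evaluation keeps subject groups disjoint and leak-free", {
  coh <- cohort_spec(n_subjects = 5,
                     trials = c(self = 10, familiar = 5, stranger = 5,
                                blank = 4),
                     noise_level = 5, seed = 55)
  eps <- lapply(1:5, function(i) simulate_subject_epochs(coh, i))
  plan <- split_plan("cohort_rounds", train_subjects = 3,
                     test_subjects = 2, rounds = 2, seed = 8)
  spec <- table1_specs(width = 1 / 12)[["1d_simple"]]
  ctl <- fixture_control(epochs = 3)
  rep <- evaluate_cohort(spec, plan = plan, control = ctl,
                         epochs_list = eps, holdout = 0.34)
  expect_s3_class(rep, "eval_report")
  expect_length(rep$accuracies, 2)
  expect_true(all(rep$accuracies >= 0 & rep$accuracies <= 1))
  # leakage audit: perturbing a TEST subject's blank trials must not
  # change the training-blank average used in each round
  test_subjects <- with_seed_test(erpauth:::derive_seed(8L, 1L), {
    train <- sample(5, 3)
    test <- sample(setdiff(1:5, train), 2)
    list(train = train, test = test)
  })
  eps2 <- eps
  s <- test_subjects$test[1]
  blanks <- eps2[[s]]$labels == "blank"
  eps2[[s]]$data[blanks, , ] <- eps2[[s]]$data[blanks, , ] + 50
  rep2 <- evaluate_cohort(spec, plan = plan, control = ctl,
                          epochs_list = eps2, holdout = 0.34)
  expect_identical(attr(rep, "blank_checksum")[1],
                   attr(rep2, "blank_checksum")[1])
  # too-small cohorts are refused
  expect_error(evaluate_cohort(spec, plan = plan, epochs_list = eps[1:4]),
               "at least")
})

test_that("cohort accuracy does not degrade as the margin grows", {
  margins <- c(0.25, 0.5, 0.75, 1.0)
  spec <- table1_specs(width = 1 / 12)[["1d_simple"]]
  ctl <- fixture_control(epochs = 6)
  accs <- vapply(margins, function(m) {
    coh <- cohort_spec(n_subjects = 3,
                       trials = c(self = 14, familiar = 7, stranger = 7,
                                  blank = 5),
                       margin = m, noise_level = 5, seed = 91)
    eps <- lapply(1:3, function(i) simulate_subject_epochs(coh, i))
    plan <- split_plan("cohort_rounds", train_subjects = 2,
                       test_subjects = 1, rounds = 1, seed = 6)
    evaluate_cohort(spec, plan = plan, control = ctl,
                    epochs_list = eps, holdout = 0.3)$mean
  }, 0)
  # stochastic monotonicity: at most one inversion along the margin axis
  expect_lte(sum(diff(accs) < -0.02), 1)
})
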
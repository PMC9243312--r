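# Evaluation protocols: within-subject stratified k-fold cross-validation
# and repeated disjoint cohort splits (train/test subject groups).

#' Declare an evaluation split plan
#'
#' @param mode `"within_subject_cv"` (stratified k-fold over one subject's
#'   trials) or `"cohort_rounds"` (repeated random disjoint splits of
#'   subjects into training and held-out test groups).
#' @param folds number of CV folds (>= 2).
#' @param train_subjects,test_subjects group sizes for cohort mode
#'   (reference protocol: 50/20).
#' @param rounds number of random cohort splits (reference protocol 100;
#'   default 10 at desk scale).
#' @param seed seed controlling fold assignment / subject splits.
#' @return A list of class `split_plan`.
#' @export
split_plan <- function(mode = c("within_subject_cv", "cohort_rounds"),
                       folds = 5, train_subjects = 50, test_subjects = 20,
                       rounds = 10, seed = 1) {
  mode <- match.arg(mode)
  if (folds < 2) stop("`folds` must be >= 2", call. = FALSE)
  structure(list(mode = mode, folds = as.integer(folds),
                 train_subjects = as.integer(train_subjects),
                 test_subjects = as.integer(test_subjects),
                 rounds = as.integer(rounds), seed = as.integer(seed)),
            class = "split_plan")
}

# Stratified fold assignment: within each class, shuffled indices are
# dealt round-robin so every fold sees both classes.
stratified_folds <- function(y01, folds, seed) {
  assign <- integer(length(y01))
  with_seed(seed, {
    for (cl in unique(y01)) {
      idx <- sample(which(y01 == cl))
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign
}

new_eval_report <- function(mode, accuracies, balanced = NULL,
                            traces = NULL, config = list()) {
  structure(list(mode = mode, accuracies = accuracies,
                 mean = mean(accuracies), sd = stats::sd(accuracies),
                 balanced = balanced, traces = traces, config = config),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report [%s]: accuracy %.3f +/- %.3f over %d %s\n",
              x$mode, x$mean, ifelse(is.na(x$sd), 0, x$sd),
              length(x$accuracies),
              if (x$mode == "cohort_rounds") "rounds" else "folds"))
  invisible(x)
}

#' Within-subject stratified cross-validated accuracy
#'
#' Partitions one subject's trials into stratified folds (every trial is
#' tested exactly once), fits a fresh network per fold, and reports the
#' per-fold test accuracies.
#'
#' @param spec a [network_spec()].
#' @param tensors an `eeg_tensors` object for one subject (blank trials
#'   removed).
#' @param labels trial labels or 0/1; defaults to `tensors$labels`.
#' @param folds number of stratified folds (default 5).
#' @param control a [train_control()].
#' @param seed seed for fold assignment and per-fold fits.
#' @return An `eval_report` with per-fold accuracies; the attribute
#'   `"fold_assign"` records the partition.
#' @export
evaluate_within_subject <- function(spec, tensors, labels = NULL,
                                    folds = 5, control = train_control(),
                                    seed = 1) {
  labels <- labels %||% tensors$labels
  y01 <- if (is.character(labels) || is.factor(labels)) {
    make_labels(as.character(labels))
  } else as.integer(labels)
  if (min(table(y01)) < folds) {
    stop("need at least `folds` trials of each class for stratification",
         call. = FALSE)
  }
  xin <- as_model_input(tensors, spec$input_form)
  assign <- stratified_folds(y01, folds, derive_seed(seed, 3L))
  acc <- numeric(folds)
  bacc <- numeric(folds)
  traces <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr_idx <- which(assign != f)
    te_idx <- which(assign == f)
    ctrl <- control
    ctrl$seed <- derive_seed(seed, 100L + f)
    fit <- eeg_cnn(slice_batch(xin, tr_idx), y01[tr_idx], spec,
                   control = ctrl)
    res <- authentication_accuracy(fit, slice_batch(xin, te_idx),
                                   y01[te_idx])
    acc[f] <- res["accuracy"]
    bacc[f] <- res["balanced_accuracy"]
    traces[[f]] <- fit$loss_trace
  }
  rep <- new_eval_report("within_subject_cv", acc, bacc, traces,
                         config = list(folds = folds, seed = seed,
                                       spec_form = spec$input_form))
  attr(rep, "fold_assign") <- assign
  rep
}

#' Cohort-level evaluation over repeated disjoint subject splits
#'
#' Per round, subjects are split at random into disjoint training and test
#' groups (overlap is a hard error). The blank-name grand average — the
#' only cross-subject statistic in the pipeline — is computed from the
#' training group only, then applied to the test subjects. Each test
#' subject gets a per-subject authentication model: trials are split into
#' a stratified fit/holdout part, a network is trained on the fit part and
#' scored on the holdout. The round accuracy is the mean over test
#' subjects; the report averages rounds.
#'
#' @param spec a [network_spec()].
#' @param cohort a [cohort_spec()], used to simulate subjects unless
#'   `epochs_list` is given.
#' @param plan a [split_plan()] with `mode = "cohort_rounds"`.
#' @param control a [train_control()].
#' @param epochs_list optional list of per-subject [eeg_epochs()] (with
#'   blank trials); overrides simulation.
#' @param holdout fraction of each test subject's trials scored (default
#'   0.25).
#' @param reject_threshold amplitude rejection threshold in microvolts.
#' @return An `eval_report` with per-round accuracies; attribute
#'   `"blank_checksum"` records the per-round training-blank average
#'   checksum (used by the leakage audit).
#' @export
evaluate_cohort <- function(spec, cohort = NULL, plan = split_plan(),
                            control = train_control(), epochs_list = NULL,
                            holdout = 0.25, reject_threshold = 100) {
  n_need <- plan$train_subjects + plan$test_subjects
  if (is.null(epochs_list)) {
    stopifnot(inherits(cohort, "cohort_spec"))
    if (cohort$n_subjects < n_need) {
      stop("cohort smaller than train + test subject groups", call. = FALSE)
    }
    epochs_list <- lapply(seq_len(cohort$n_subjects), function(i) {
      simulate_subject_epochs(cohort, i)
    })
  }
  n_sub <- length(epochs_list)
  if (n_sub < n_need) {
    stop("need at least ", n_need, " subjects", call. = FALSE)
  }
  acc <- numeric(plan$rounds)
  blank_checksum <- numeric(plan$rounds)
  for (r in seq_len(plan$rounds)) {
    seed_r <- derive_seed(plan$seed, r)
    split <- with_seed(seed_r, {
      train <- sample(n_sub, plan$train_subjects)
      test <- sample(setdiff(seq_len(n_sub), train), plan$test_subjects)
      list(train = train, test = test)
    })
    if (length(intersect(split$train, split$test))) {
      stop("train/test subject overlap detected", call. = FALSE)
    }
    blank_avg <- blank_average(epochs_list[split$train])
    blank_checksum[r] <- sum(blank_avg^2)
    sub_acc <- vapply(seq_along(split$test), function(si) {
      s <- split$test[si]
      ep <- reject_high_amplitude(epochs_list[[s]], reject_threshold)
      ep <- blank_baseline_subtract(ep, blank_avg)
      tens <- stack_tensor(ep)
      y01 <- make_labels(tens$labels)
      xin <- as_model_input(tens, spec$input_form)
      n_folds <- max(2L, round(1 / holdout))
      assign <- stratified_folds(y01, n_folds,
                                 derive_seed(seed_r, 31L + si))
      te <- which(assign == 1L)
      tr <- which(assign != 1L)
      ctrl <- control
      ctrl$seed <- derive_seed(seed_r, 57L + si)
      fit <- eeg_cnn(slice_batch(xin, tr), y01[tr], spec, control = ctrl)
      authentication_accuracy(fit, slice_batch(xin, te),
                              y01[te])[["accuracy"]]
    }, 0)
    acc[r] <- mean(sub_acc)
  }
  rep <- new_eval_report("cohort_rounds", acc,
                         config = list(plan = unclass(plan),
                                       holdout = holdout))
  attr(rep, "blank_checksum") <- blank_checksum
  rep
}
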
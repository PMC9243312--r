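# Desk-scale experiment drivers: single-kernel sweep, multi-scale strategy
# comparison, branch x depth grid, feature heat maps and the kernel
# calibration audit. Every driver runs all candidates under identical
# training control and replicate seeds and returns a plain data frame.

#' Desk-scale experiment cohort
#'
#' A deliberately small cohort (balanced self vs non-self trial counts,
#' reduced noise) used by the sweep/grid drivers so a full comparison runs
#' in minutes on one CPU while effect-size orderings stay measurable. The
#' P300 margin and all component parameters are the generator defaults.
#'
#' @param n_subjects number of subjects.
#' @param noise_level pink-noise RMS in microvolts; the experiment regime
#'   default (5) is lower than the generator default so effect-size
#'   orderings remain measurable at these trial counts.
#' @param seed master seed.
#' @return A [cohort_spec()].
#' @export
experiment_cohort <- function(n_subjects = 1, noise_level = 5, seed = 1) {
  cohort_spec(n_subjects = n_subjects,
              trials = c(self = 36, familiar = 18, stranger = 18,
                         blank = 10),
              noise_level = noise_level, seed = seed)
}

#' Prepare tensorized data for the experiment drivers
#'
#' Simulates one subject, applies amplitude rejection and blank-average
#' subtraction, and tensorizes.
#'
#' @param cohort a [cohort_spec()].
#' @param subject_index subject to simulate.
#' @return List with `tensors` (an `eeg_tensors`) and `y01` labels.
#' @export
experiment_data <- function(cohort = experiment_cohort(),
                            subject_index = 1) {
  ep <- simulate_subject_epochs(cohort, subject_index)
  ep <- reject_high_amplitude(ep, 100)
  ep <- blank_baseline_subtract(ep, blank_average(ep))
  tens <- stack_tensor(ep)
  list(tensors = tens, y01 = make_labels(tens$labels))
}

# One train/test replicate: stratified half/half split at `seed`, fresh
# fit, scored on the held-out half.
experiment_eval <- function(spec, xin, y01, seed, control) {
  assign <- stratified_folds(y01, 2L, derive_seed(seed, 5L))
  te <- which(assign == 1L)
  tr <- which(assign != 1L)
  ctrl <- control
  ctrl$seed <- derive_seed(seed, 11L)
  fit <- eeg_cnn(slice_batch(xin, tr), y01[tr], spec, control = ctrl)
  c(accuracy = unname(authentication_accuracy(
      fit, slice_batch(xin, te), y01[te])["accuracy"]),
    final_loss = unname(tail(fit$loss_trace, 1)))
}

#' Default training control for the experiment drivers
#'
#' Desk-scale schedule: a raised learning rate and more passes compensate
#' for the small trial counts (the reference protocol of lr 5e-4 /
#' 5 epochs / batch 50 assumes several hundred trials per subject).
#'
#' @param seed seed.
#' @return A [train_control()].
#' @export
experiment_control <- function(seed = 1) {
  train_control(learning_rate = 5e-3, epochs = 8, batch_size = 12,
                seed = seed)
}

kernel_shape <- function(temporal, frequency) {
  ifelse(temporal > frequency, "long",
         ifelse(temporal < frequency, "wide", "square"))
}

#' Single-scale convolution kernel sweep
#'
#' Trains one single-scale serial network per time x frequency kernel
#' size (default: the 16 combinations over \{3, 5, 7, 9\}^2), each under
#' identical training control and the same replicate seeds, and ranks the
#' kernels by mean test accuracy (ties broken by final loss). Failed runs
#' are recorded in the `error` column, never dropped.
#'
#' @param data result of [experiment_data()].
#' @param sizes odd kernel sizes swept on both axes.
#' @param seeds replicate seeds.
#' @param width network width multiplier (see [table1_specs()]).
#' @param form input form; the desk default `"2d"` isolates the swept
#'   time x frequency kernel (the spatial axis is fixed in the reference
#'   family and orthogonal to the sweep question).
#' @param control a [train_control()].
#' @return Data frame sorted by decreasing accuracy, one row per kernel,
#'   with attribute `"traces"` holding the loss traces.
#' @export
kernel_sweep <- function(data, sizes = c(3, 5, 7, 9), seeds = 1:5,
                         width = 1 / 6, form = "2d",
                         control = experiment_control()) {
  xin <- as_model_input(data$tensors, form)
  combos <- expand.grid(temporal = sizes, frequency = sizes)
  traces <- list()
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    t <- combos$temporal[i]; f <- combos$frequency[i]
    res <- tryCatch({
      spec <- single_scale_spec(t, f, form = form, width = width)
      m <- vapply(seeds, function(s) {
        experiment_eval(spec, xin, data$y01, s, control)
      }, c(accuracy = 0, final_loss = 0))
      list(acc = mean(m["accuracy", ]), loss = mean(m["final_loss", ]),
           err = NA_character_)
    }, error = function(e) list(acc = NA_real_, loss = NA_real_,
                                err = conditionMessage(e)))
    data.frame(kernel = sprintf("%dx%d", t, f), temporal = t,
               frequency = f, shape = kernel_shape(t, f),
               accuracy = res$acc, final_loss = res$loss,
               error = res$err, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$accuracy, out$final_loss), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "traces") <- traces
  attr(out, "manifest") <- list(seeds = seeds, width = width, form = form,
                                control = unclass(control))
  out
}

#' Compare the shipped single- and multi-scale strategies
#'
#' Runs every architecture in [table1_specs()] (optionally a subset) on
#' the same data under one seed set and reports side-by-side accuracies.
#'
#' @param data result of [experiment_data()].
#' @param strategies character subset of `names(table1_specs())`.
#' @param seeds replicate seeds.
#' @param width width multiplier.
#' @param control a [train_control()].
#' @return Data frame, one row per strategy.
#' @export
strategy_compare <- function(data, strategies = NULL, seeds = 1:5,
                             width = 1 / 6,
                             control = experiment_control()) {
  specs <- table1_specs(width = width)
  if (!is.null(strategies)) specs <- specs[strategies]
  rows <- lapply(names(specs), function(nm) {
    spec <- specs[[nm]]
    xin <- as_model_input(data$tensors, spec$input_form)
    res <- tryCatch({
      m <- vapply(seeds, function(s) {
        experiment_eval(spec, xin, data$y01, s, control)
      }, c(accuracy = 0, final_loss = 0))
      list(acc = mean(m["accuracy", ]), loss = mean(m["final_loss", ]),
           err = NA_character_)
    }, error = function(e) list(acc = NA_real_, loss = NA_real_,
                                err = conditionMessage(e)))
    data.frame(strategy = nm,
               form = spec$input_form,
               multiscale = length(spec$modules[[1]]$kernels) > 1,
               accuracy = res$acc, final_loss = res$loss,
               parameters = count_parameters(spec),
               error = res$err, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "manifest") <- list(seeds = seeds, width = width,
                                control = unclass(control))
  out
}

#' Branch-count by module-depth accuracy grid
#'
#' Evaluates the long-strategy multi-branch family over a branches x
#' layers grid (default 2-6 x 3-5) and reports mean accuracy and
#' parameter count per cell. The 3-branch / 3-layer cell — the
#' cost-performance reference configuration, matching the three ERP
#' components — is marked. Infeasible cells are reported with their error
#' message.
#'
#' @param data result of [experiment_data()].
#' @param branches,layers grid axes.
#' @param seeds replicate seeds.
#' @param width width multiplier.
#' @param form input form (desk default `"2d"`, see [kernel_sweep()]).
#' @param control a [train_control()].
#' @return Data frame with one row per (branches, layers) cell.
#' @export
branch_depth_grid <- function(data, branches = 2:6, layers = 3:5,
                              seeds = 1:5, width = 1 / 12, form = "2d",
                              control = experiment_control()) {
  xin <- as_model_input(data$tensors, form)
  cells <- expand.grid(branches = branches, layers = layers)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    b <- cells$branches[i]; l <- cells$layers[i]
    res <- tryCatch({
      spec <- grid_spec(b, l, width = width, form = form)
      m <- vapply(seeds, function(s) {
        experiment_eval(spec, xin, data$y01, s, control)
      }, c(accuracy = 0, final_loss = 0))
      list(acc = mean(m["accuracy", ]), np = count_parameters(spec),
           err = NA_character_)
    }, error = function(e) list(acc = NA_real_, np = NA_integer_,
                                err = conditionMessage(e)))
    data.frame(branches = b, layers = l, accuracy = res$acc,
               parameters = res$np,
               reference_choice = b == 3 && l == 3,
               error = res$err, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "manifest") <- list(seeds = seeds, width = width,
                                control = unclass(control))
  out
}

#' Branch attention heat map
#'
#' Extracts one branch's post-activation feature map for a single input
#' tensor, averages absolute activation over feature channels (and the
#' spatial axis for 3D networks), and z-scores the resulting time x
#' frequency map. A constant map (zero variance) yields an all-zero
#' output with a warning. Pixel positions are mapped back to calibrated
#' ms / Hz axes proportionally to the module's downsampling.
#'
#' @param fit an [eeg_cnn()] model.
#' @param x input for one trial (`eeg_tensors` or array; the first trial
#'   is used).
#' @param module,branch indices of the tapped branch.
#' @return Object of class `feature_heatmap`: `z` (time x frequency),
#'   `time_ms`, `freq_hz`.
#' @export
feature_heatmap <- function(fit, x, module = 1, branch = 1) {
  stopifnot(inherits(fit, "eeg_cnn"))
  xin <- as_model_input(x, fit$spec$input_form)
  xin <- slice_batch(xin, 1L)
  act <- network_activations(fit$network, xin, module, branch)
  d <- dim(act)  # (C, depth, time, freq, 1)
  m <- apply(abs(act), c(3, 4), mean)
  if (stats::sd(m) == 0) {
    warning("constant feature map; returning all-zero heat map")
    z <- m * 0
  } else {
    z <- (m - mean(m)) / stats::sd(m)
  }
  structure(list(z = z,
                 time_ms = (seq_len(nrow(z)) - 0.5) / nrow(z) * 800,
                 freq_hz = (seq_len(ncol(z)) - 0.5) / ncol(z) * 30,
                 module = module, branch = branch),
            class = "feature_heatmap")
}

#' @export
plot.feature_heatmap <- function(x, ...) {
  image(x$time_ms, x$freq_hz, x$z, xlab = "time (ms)",
        ylab = "frequency (Hz)", col = hcl.colors(64, "viridis"),
        main = sprintf("module %d / branch %d attention", x$module,
                       x$branch), ...)
  invisible(x)
}

#' Attention mass centroid of a heat map
#'
#' Centroid of the positive part of the z-scored map, in calibrated
#' physical units.
#'
#' @param hm a [feature_heatmap()].
#' @return Named vector `c(ms = ..., hz = ...)`.
#' @export
heatmap_centroid <- function(hm) {
  w <- pmax(hm$z, 0)
  if (sum(w) == 0) return(c(ms = NA_real_, hz = NA_real_))
  c(ms = sum(rowSums(w) * hm$time_ms) / sum(w),
    hz = sum(colSums(w) * hm$freq_hz) / sum(w))
}
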
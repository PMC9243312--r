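#' Binary authentication labels from class labels
#'
#' The authentication task separates the subject's own name from all
#' others: `self` maps to 1 (genuine), `familiar` and `stranger` to 0
#' (impostor). Blank trials carry no name and must be removed upstream.
#'
#' @param labels character vector of trial classes.
#' @return Integer 0/1 vector of the same length.
#' @export
make_labels <- function(labels) {
  if (!length(labels)) return(integer(0))
  known <- c(self = 1L, familiar = 0L, stranger = 0L)
  bad <- setdiff(unique(labels), names(known))
  if (length(bad)) {
    stop("unknown class label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  unname(known[labels])
}

as_model_input <- function(x, form) {
  if (inherits(x, "eeg_tensors")) return(to_input_form(x, form))
  if (is.array(x) && length(dim(x)) == 5L) return(x)
  if (is.array(x) && length(dim(x)) == 4L) return(to_input_form(x, form))
  stop("`x` must be an eeg_tensors object or a 4-D/5-D array",
       call. = FALSE)
}

#' Fit an EEG authentication network
#'
#' Trains a convolutional network of the multi-scale family on
#' spatial-temporal-frequency tensors with softmax cross-entropy loss and
#' Adam (learning rate 5e-4, 5 epochs, batch 50 by default), kaiming-
#' uniform initialization and batch normalization. After training, batch-
#' norm statistics are frozen at their population values over the training
#' set.
#'
#' @param x training input: an `eeg_tensors` object (converted with
#'   [to_input_form()] according to `spec$input_form`) or a prepared
#'   array.
#' @param y trial labels: class strings (mapped by [make_labels()]) or a
#'   0/1 vector (1 = genuine/self).
#' @param spec a [network_spec()].
#' @param control a [train_control()].
#' @param seed initialization seed (defaults to `control$seed`).
#' @return An object of class `eeg_cnn` with `print()`, `summary()`,
#'   `predict()`, `plot()` (loss trace) and `coef()` methods.
#' @examples
#' \donttest{
#' coh <- cohort_spec(n_subjects = 1, trials = c(self = 8, familiar = 8,
#'                    stranger = 8, blank = 4), noise_level = 2, seed = 7)
#' ep <- simulate_subject_epochs(coh, 1)
#' ep <- blank_baseline_subtract(ep, blank_average(ep))
#' tens <- stack_tensor(ep)
#' spec <- table1_specs(width = 1 / 12)[["1d_ms_length"]]
#' fit <- eeg_cnn(tens, tens$labels, spec,
#'                control = train_control(epochs = 2, batch_size = 8))
#' predict(fit, tens, type = "class")
#' }
#' @export
eeg_cnn <- function(x, y, spec, control = train_control(),
                    seed = control$seed) {
  stopifnot(inherits(spec, "network_spec"),
            inherits(control, "train_control"))
  xin <- as_model_input(x, spec$input_form)
  y01 <- if (is.character(y) || is.factor(y)) {
    make_labels(as.character(y))
  } else as.integer(y)
  if (!all(y01 %in% c(0L, 1L))) {
    stop("`y` must be 0/1 or class labels", call. = FALSE)
  }
  if (dim(xin)[5] != length(y01)) {
    stop("number of trials in `x` and `y` differ", call. = FALSE)
  }
  net <- build_network(spec, seed = seed)
  tr <- train_network(net, xin, y01, control)
  structure(list(network = tr$net, spec = spec, control = control,
                 loss_trace = tr$trace,
                 levels = c("nonself", "self"),
                 n_train = length(y01),
                 class_counts = c(nonself = sum(y01 == 0),
                                  self = sum(y01 == 1)),
                 seed = seed),
            class = "eeg_cnn")
}

#' @export
print.eeg_cnn <- function(x, ...) {
  cat(sprintf(
    "eeg_cnn: %s %d-module network, %d parameters\n",
    x$spec$input_form, length(x$spec$modules),
    count_parameters(x$spec)))
  cat(sprintf("  trained on %d trials (%d self / %d non-self), %d iterations\n",
              x$n_train, x$class_counts["self"], x$class_counts["nonself"],
              length(x$loss_trace)))
  cat(sprintf("  final training loss: %.4f\n", tail(x$loss_trace, 1)))
  invisible(x)
}

#' @export
summary.eeg_cnn <- function(object, ...) {
  print(object$spec)
  print(object)
  invisible(object)
}

#' Predict authentication decisions or probabilities
#'
#' @param object an [eeg_cnn()] fit.
#' @param newdata `eeg_tensors` or prepared array.
#' @param type `"class"` (argmax, threshold 0.5) or `"prob"`
#'   (P(self) per trial).
#' @param ... unused.
#' @return Factor of `nonself`/`self` or numeric probabilities.
#' @export
predict.eeg_cnn <- function(object, newdata,
                            type = c("class", "prob"), ...) {
  type <- match.arg(type)
  xin <- as_model_input(newdata, object$spec$input_form)
  probs <- predict_network(object$network, xin)
  p_self <- probs[2, ]
  if (type == "prob") return(p_self)
  factor(object$levels[(p_self > 0.5) + 1L], levels = object$levels)
}

#' @export
plot.eeg_cnn <- function(x, ...) {
  plot(seq_along(x$loss_trace), x$loss_trace, type = "l",
       xlab = "iteration", ylab = "training loss",
       main = "eeg_cnn training loss", ...)
  invisible(x)
}

#' @export
coef.eeg_cnn <- function(object, ...) {
  object$network$params
}

#' Classification accuracy helper
#'
#' @param fit an `eeg_cnn` object.
#' @param x evaluation input.
#' @param y evaluation labels (classes or 0/1).
#' @return Named vector with `accuracy` and `balanced_accuracy`.
#' @export
authentication_accuracy <- function(fit, x, y) {
  y01 <- if (is.character(y) || is.factor(y)) make_labels(as.character(y))
         else as.integer(y)
  pred <- as.integer(predict(fit, x, type = "class") == "self")
  acc <- mean(pred == y01)
  sens <- if (any(y01 == 1)) mean(pred[y01 == 1] == 1) else NA_real_
  spec <- if (any(y01 == 0)) mean(pred[y01 == 0] == 0) else NA_real_
  c(accuracy = acc, balanced_accuracy = mean(c(sens, spec), na.rm = TRUE))
}
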
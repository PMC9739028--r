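#' Configuration of the LSTM sequence classifier
#'
#' Architecture and training hyper-parameters: a sequence input of six
#' features feeds a unidirectional LSTM layer with `hidden_units` units,
#' followed by a dense layer to two classes and a per-timestep softmax.
#' Training minimises mean per-timestep cross-entropy with Adam for a fixed
#' number of epochs (no early stopping, no validation split); one update per
#' training sequence, sequences visited in a fixed order, so training is
#' fully deterministic given the seed.
#'
#' @param hidden_units LSTM state size (default 200).
#' @param epochs training epochs (default 100).
#' @param learning_rate Adam step size.
#' @param grad_clip global gradient-norm clip; `0` disables clipping.
#' @param window_length training sequences longer than this many samples are
#'   split into windows of this length with 50% overlap (default 500 samples
#'   = 5 s, one Adam update per window); `Inf` trains on whole trials.
#' @param n_features input channels (fixed at 6).
#' @param n_classes output classes (fixed at 2: swing, contact).
#' @param seed seed for parameter initialisation.
#' @return An object of class `lstm_config`.
#' @export
lstm_config <- function(hidden_units = 200L, epochs = 100L,
                        learning_rate = 1e-3, grad_clip = 1,
                        window_length = 500, n_features = 6L,
                        n_classes = 2L, seed = 1L) {
  cfg <- list(hidden_units = as.integer(hidden_units),
              epochs = as.integer(epochs),
              learning_rate = as.numeric(learning_rate),
              grad_clip = as.numeric(grad_clip),
              window_length = as.numeric(window_length),
              n_features = as.integer(n_features),
              n_classes = as.integer(n_classes),
              seed = as.integer(seed))
  if (cfg$hidden_units <= 0L) stop("`hidden_units` must be positive")
  if (cfg$epochs <= 0L) stop("`epochs` must be positive")
  if (cfg$n_features != 6L) stop("`n_features` must be 6")
  if (cfg$n_classes != 2L) stop("`n_classes` must be 2")
  if (cfg$learning_rate <= 0) stop("`learning_rate` must be positive")
  if (cfg$window_length < 2) stop("`window_length` must be at least 2")
  structure(cfg, class = "lstm_config")
}

init_lstm_params <- function(config) {
  H <- config$hidden_units
  Fn <- config$n_features
  C <- config$n_classes
  with_seed(config$seed, {
    s <- 1 / sqrt(H)
    b <- numeric(4 * H)
    b[(H + 1):(2 * H)] <- 1  # forget-gate bias starts open
    list(Wx = matrix(runif(4 * H * Fn, -s, s), 4 * H, Fn),
         Wh = matrix(runif(4 * H * H, -s, s), 4 * H, H),
         b = b,
         Wy = matrix(runif(C * H, -s, s), C, H),
         by = numeric(C))
  })
}

as_feature_values <- function(x) {
  if (inherits(x, "feature_matrix")) return(x$values)
  if (is.matrix(x)) return(x)
  stop("features must be a `feature_matrix` or a channels-by-samples matrix")
}

as_label_values <- function(y) {
  if (inherits(y, "binary_phase")) return(y$values)
  as.integer(y)
}

split_windows <- function(m, y, win) {
  T <- ncol(m)
  if (!is.finite(win) || T <= win) return(list(x = list(m), y = list(y)))
  step <- max(1L, as.integer(win / 2))
  starts <- unique(c(seq(1L, T - win + 1L, by = step), T - win + 1L))
  list(x = lapply(starts, function(s) m[, s:(s + win - 1L), drop = FALSE]),
       y = lapply(starts, function(s) y[s:(s + win - 1L)]))
}

#' Fit the LSTM sequence classifier
#'
#' Trains the per-timestep contact classifier on a set of labelled trials.
#' `x` is a list of feature matrices (six 100 Hz channels per trial, see
#' [assemble_features()]); `y` the matching list of binary contact
#' sequences.  Returns a fitted model usable with [predict.lstm_labeler()].
#'
#' @param x list of `feature_matrix` objects (or 6 x T matrices).
#' @param y list of [binary_phase] objects (or 0/1 vectors), one per trial,
#'   aligned to `x`.
#' @param config an [lstm_config].
#' @param effector effector this model detects (metadata carried along).
#' @param norm normalization constants used to build `x` (metadata).
#' @param training_subjects subject ids behind `x` (metadata, audited by the
#'   leave-one-subject-out driver).
#' @return An object of class `lstm_labeler` with components `params`
#'   (weight matrices), `config`, `epoch_loss`, `effector`, `norm` and
#'   `training_subjects`.
#' @seealso [predict.lstm_labeler()], [run_loso()]
#' @export
lstm_labeler <- function(x, y, config = lstm_config(),
                         effector = c("pole", "left_ski", "right_ski"),
                         norm = NULL, training_subjects = character()) {
  effector <- match.arg(effector)
  stopifnot(inherits(config, "lstm_config"))
  if (!is.list(x)) x <- list(x)
  if (!is.list(y)) y <- list(y)
  if (length(x) != length(y) || length(x) == 0L)
    stop("`x` and `y` must be non-empty lists of equal length")
  xs <- list(); ys <- list()
  for (k in seq_along(x)) {
    m <- as_feature_values(x[[k]])
    lab <- as_label_values(y[[k]])
    if (nrow(m) != config$n_features)
      stop(sprintf("trial %d has %d channels; expected %d", k, nrow(m),
                   config$n_features))
    if (ncol(m) != length(lab))
      stop(sprintf("trial %d: %d timesteps but %d labels", k, ncol(m),
                   length(lab)))
    w <- split_windows(m, lab, config$window_length)
    xs <- c(xs, w$x)
    ys <- c(ys, w$y)
  }
  params <- init_lstm_params(config)
  fit <- cpp_lstm_train(params, xs, ys, config$epochs, config$learning_rate,
                        config$grad_clip)
  structure(list(params = fit$params, config = config,
                 epoch_loss = as.numeric(fit$epoch_loss),
                 effector = effector, norm = norm,
                 training_subjects = training_subjects,
                 n_training_sequences = length(xs)),
            class = "lstm_labeler")
}

#' Untrained LSTM model
#'
#' Builds the classifier with seeded initial parameters and no training,
#' mainly useful to inspect the architecture or as a baseline.
#'
#' @inheritParams lstm_labeler
#' @return An `lstm_labeler` with `epoch_loss = numeric(0)`.
#' @export
build_lstm <- function(config = lstm_config(),
                       effector = c("pole", "left_ski", "right_ski")) {
  effector <- match.arg(effector)
  structure(list(params = init_lstm_params(config), config = config,
                 epoch_loss = numeric(0), effector = effector, norm = NULL,
                 training_subjects = character(),
                 n_training_sequences = 0L),
            class = "lstm_labeler")
}

#' Per-timestep class probabilities
#'
#' @param model an `lstm_labeler`.
#' @param x a `feature_matrix` or 6 x T matrix.
#' @return 2 x T matrix of class probabilities (rows: swing, contact); each
#'   column sums to 1.
#' @export
predict_proba <- function(model, x) {
  stopifnot(inherits(model, "lstm_labeler"))
  cpp_lstm_forward(model$params, as_feature_values(x))
}

#' Predict a contact sequence
#'
#' Runs the fitted classifier over a trial and takes the per-timestep argmax
#' class; an exact 0.5/0.5 tie resolves to swing (0).  The raw output is
#' usually passed through [filter_blocks()] before events are read off.
#'
#' @param object an `lstm_labeler`.
#' @param newdata a `feature_matrix` or 6 x T matrix.
#' @param ... unused.
#' @return A [binary_phase] at 100 Hz of the same length as the input.
#' @export
predict.lstm_labeler <- function(object, newdata, ...) {
  p <- predict_proba(object, newdata)
  binary_phase(as.integer(p[2L, ] > 0.5), ANALYSIS_RATE, object$effector)
}

#' @export
print.lstm_labeler <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<lstm_labeler: %s, 6 -> LSTM(%d) -> dense(2) -> softmax>\n",
              x$effector, cfg$hidden_units))
  if (length(x$epoch_loss))
    cat(sprintf("  trained %d epochs on %d sequences; final loss %.4f\n",
                length(x$epoch_loss), x$n_training_sequences,
                x$epoch_loss[length(x$epoch_loss)]))
  else cat("  untrained\n")
  invisible(x)
}

#' @export
summary.lstm_labeler <- function(object, ...) {
  print(object)
  if (length(object$training_subjects))
    cat("  training subjects:",
        paste(object$training_subjects, collapse = ", "), "\n")
  np <- sum(vapply(object$params, length, 0L))
  cat(sprintf("  %d parameters\n", np))
  invisible(object)
}

#' @export
coef.lstm_labeler <- function(object, ...) object$params

#' Training loss curve
#' @param x an `lstm_labeler`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.lstm_labeler <- function(x, ...) {
  if (!length(x$epoch_loss)) stop("model is untrained; no loss curve")
  graphics::plot(seq_along(x$epoch_loss), x$epoch_loss, type = "l",
                 xlab = "epoch", ylab = "mean cross-entropy", ...)
  invisible(x)
}
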
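# Leaky-integrator reservoir dynamics, ridge readout, prediction.

#' Echo state network configuration
#'
#' @param alpha Leak rate in `[0, 1]`; controls how fast the state tracks
#'   new input (default 0.25, the value used for the classification tasks).
#' @param rho Target spectral radius of the recurrent matrix (default 0.85).
#' @param ridge_lambda Nonnegative ridge penalty for the readout
#'   (default 1e-6).
#' @param washout Number of leading states discarded in continuous-sequence
#'   encoding (default 0).
#' @param steps_per_sample In per-sample encoding, how many consecutive
#'   update steps each feature vector is presented for (default 5).
#' @param reset_per_sample If `TRUE` (default) each sample is encoded from
#'   the zero state independently -- appropriate when samples are i.i.d.
#'   segments; if `FALSE` the reservoir runs over the input as one
#'   continuous sequence.
#' @param activation Reservoir activation, `"tanh"` (default) or
#'   `"identity"` (used for linear memory-capacity bounds).
#' @return A list of class `"mesn_esn_config"`.
#' @export
esn_config <- function(alpha = 0.25, rho = 0.85, ridge_lambda = 1e-6,
                       washout = 0L, steps_per_sample = 5L,
                       reset_per_sample = TRUE,
                       activation = c("tanh", "identity")) {
  activation <- match.arg(activation)
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1) {
    stop("invalid configuration: alpha must lie in [0, 1]")
  }
  if (!is.numeric(ridge_lambda) || ridge_lambda < 0) {
    stop("invalid configuration: ridge_lambda must be >= 0")
  }
  stopifnot(washout >= 0, steps_per_sample >= 1)
  structure(
    list(alpha = alpha, rho = rho, ridge_lambda = ridge_lambda,
         washout = as.integer(washout),
         steps_per_sample = as.integer(steps_per_sample),
         reset_per_sample = isTRUE(reset_per_sample),
         activation = activation),
    class = "mesn_esn_config"
  )
}

activation_fn <- function(name) {
  switch(name, tanh = tanh, identity = identity,
         stop("unknown activation: ", name))
}

#' One leaky-integrator reservoir update
#'
#' Computes `(1 - alpha) * x + alpha * f(w_ir %*% u + w_rc %*% x)` with
#' `f` the reservoir activation.
#'
#' @param x Current state, length-n numeric vector.
#' @param u Input, length-d numeric vector.
#' @param reservoir A `"mesn_reservoir"` (or any list with `w_rc`, `w_ir`).
#' @param alpha Leak rate in `[0, 1]`.
#' @param activation `"tanh"` or `"identity"`.
#' @return Updated length-n state vector.
#' @export
update_state <- function(x, u, reservoir, alpha = 0.25,
                         activation = c("tanh", "identity")) {
  activation <- match.arg(activation)
  f <- activation_fn(activation)
  if (length(x) != nrow(reservoir$w_rc) || length(u) != ncol(reservoir$w_ir)) {
    stop("shape error: state/input dimensions do not match the reservoir")
  }
  drop((1 - alpha) * x +
         alpha * f(reservoir$w_ir %*% u + reservoir$w_rc %*% x))
}

#' Encode an input sequence into reservoir states
#'
#' In per-sample mode (`reset_per_sample = TRUE`) every row of `inputs` is
#' presented for `steps_per_sample` consecutive updates starting from the
#' zero state, and the final state becomes that sample's column -- one
#' state column per input row, no information shared across rows. In
#' continuous mode the reservoir is driven once through the rows in order
#' and the first `washout` states are discarded.
#'
#' @param inputs `T x d` numeric matrix (rows are time steps / samples).
#' @param reservoir A `"mesn_reservoir"`.
#' @param config An [esn_config()].
#' @param x0 Optional initial state (continuous mode only; default zeros).
#' @return `n x T'` state matrix (`T' = T` in per-sample mode,
#'   `T - washout` in continuous mode).
#' @export
encode_sequence <- function(inputs, reservoir, config = esn_config(),
                            x0 = NULL) {
  if (is.vector(inputs)) inputs <- matrix(inputs, ncol = 1L)
  if (nrow(inputs) == 0L) stop("empty input sequence")
  if (ncol(inputs) != ncol(reservoir$w_ir)) {
    stop("shape error: input dimension does not match reservoir input weights")
  }
  n <- nrow(reservoir$w_rc)
  f <- activation_fn(config$activation)
  a <- config$alpha
  if (config$reset_per_sample) {
    # all samples evolve independently from zero, so batch them as columns
    drive <- reservoir$w_ir %*% t(inputs)        # n x T, constant per sample
    x <- matrix(0, n, nrow(inputs))
    for (s in seq_len(config$steps_per_sample)) {
      x <- (1 - a) * x + a * f(drive + reservoir$w_rc %*% x)
    }
    return(x)
  }
  t_len <- nrow(inputs)
  if (t_len <= config$washout) {
    stop("input sequence not longer than the washout")
  }
  x <- if (is.null(x0)) numeric(n) else as.numeric(x0)
  stopifnot(length(x) == n)
  out <- matrix(0, n, t_len)
  w_rc <- reservoir$w_rc
  drive <- reservoir$w_ir %*% t(inputs)          # n x T, precomputed input drive
  for (t in seq_len(t_len)) {
    x <- (1 - a) * x + a * f(drive[, t] + w_rc %*% x)
    out[, t] <- x
  }
  if (config$washout > 0L) out <- out[, -seq_len(config$washout), drop = FALSE]
  out
}

#' One-hot target coding
#'
#' @param labels Factor (or vector coercible to factor) of class labels.
#' @return `K x T` 0/1 matrix with one row per class level.
#' @export
one_hot <- function(labels) {
  labels <- as.factor(labels)
  k <- nlevels(labels)
  y <- matrix(0, k, length(labels), dimnames = list(levels(labels), NULL))
  y[cbind(as.integer(labels), seq_along(labels))] <- 1
  y
}

#' Train the linear readout by ridge regression
#'
#' Solves `w_ro = y %*% t(x) %*% solve(x %*% t(x) + lambda * I)`, the
#' closed-form ridge readout of an echo state network. Only the readout is
#' trained; reservoir weights stay fixed.
#'
#' @param states `n x T` state matrix from [encode_sequence()].
#' @param targets Targets: a `K x T` numeric matrix, or a factor/vector of
#'   class labels (converted with [one_hot()]).
#' @param ridge_lambda Nonnegative ridge penalty.
#' @return Object of class `"mesn_readout"`: list with `w_ro` (`K x n`) and
#'   the class levels (`NULL` for numeric targets).
#' @export
fit_readout <- function(states, targets, ridge_lambda = 1e-6) {
  stopifnot(is.matrix(states), ncol(states) > 0L)
  classes <- NULL
  if (!is.matrix(targets)) {
    targets <- as.factor(targets)
    classes <- levels(targets)
    targets <- one_hot(targets)
  }
  if (ncol(targets) != ncol(states)) {
    stop("shape error: states and targets disagree in column count")
  }
  gram <- tcrossprod(states)
  diag(gram) <- diag(gram) + ridge_lambda
  w_ro <- tryCatch(
    t(solve(gram, tcrossprod(states, targets))),
    error = function(e) {
      stop("singular state covariance; use ridge_lambda > 0 (", conditionMessage(e), ")")
    }
  )
  rownames(w_ro) <- rownames(targets)
  structure(list(w_ro = w_ro, classes = classes), class = "mesn_readout")
}

#' Readout prediction
#'
#' Scores are `w_ro %*% states`; hard labels are the argmax over the score
#' rows, ties broken toward the lower class index.
#'
#' @param object A `"mesn_readout"` from [fit_readout()].
#' @param states `n x T` state matrix.
#' @param ... Unused.
#' @return List with `scores` (`K x T`) and `labels` (length-T; a factor
#'   when the readout was trained on class labels, otherwise row indices).
#' @export
predict.mesn_readout <- function(object, states, ...) {
  if (ncol(object$w_ro) != nrow(states)) {
    stop("shape error: readout and state dimensions do not match")
  }
  scores <- object$w_ro %*% states
  idx <- max.col(t(scores), ties.method = "first")
  labels <- if (!is.null(object$classes)) {
    factor(object$classes[idx], levels = object$classes)
  } else {
    idx
  }
  list(scores = scores, labels = labels)
}

#' @export
print.mesn_readout <- function(x, ...) {
  cat(sprintf("ESN ridge readout: %d output(s) x %d reservoir units\n",
              nrow(x$w_ro), ncol(x$w_ro)))
  if (!is.null(x$classes)) {
    cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Save / load a trained model
#'
#' Bundles reservoir, readout and configuration; lossless round-trip.
#'
#' @param model List with elements `reservoir`, `readout`, `config`.
#' @param path File path.
#' @export
write_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) readRDS(path)
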
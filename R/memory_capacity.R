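# Reservoir memory capacity: delayed-input reconstruction by linear
# readouts, summed squared correlations over delays.

#' Memory-capacity evaluation settings
#'
#' @param t_len Length of the i.i.d. input sequence (default 2000).
#' @param k_max Maximum delay probed; the infinite sum over delays is
#'   truncated here (default 200).
#' @param washout Leading states discarded before any delay is fitted
#'   (default 100).
#' @param train_fraction Fraction of usable time steps used to train the
#'   per-delay readouts; the squared correlations are evaluated on the
#'   held-out remainder to avoid optimistic bias (default 0.7).
#' @param ridge_lambda Tiny ridge penalty taming near-singular state
#'   covariances (default 1e-8).
#' @param seed Integer seed for the input sequence.
#' @return List of class `"mesn_mc_config"`.
#' @export
mc_config <- function(t_len = 2000L, k_max = 200L, washout = 100L,
                      train_fraction = 0.7, ridge_lambda = 1e-8, seed = 1L) {
  stopifnot(t_len > 0, k_max > 0, washout >= 0,
            train_fraction > 0, train_fraction < 1)
  usable <- t_len - washout - k_max
  if (usable < 20L) {
    stop("invalid configuration: t_len must exceed washout + k_max by a usable margin")
  }
  structure(
    list(t_len = as.integer(t_len), k_max = as.integer(k_max),
         washout = as.integer(washout), train_fraction = train_fraction,
         ridge_lambda = ridge_lambda, seed = as.integer(seed)),
    class = "mesn_mc_config"
  )
}

#' Estimate reservoir memory capacity
#'
#' Drives the reservoir with an i.i.d. uniform(-1, 1) scalar sequence in
#' continuous mode, then for every delay `k = 1..k_max` trains a separate
#' ridge readout to reconstruct the input `k` steps back and scores it by
#' the squared Pearson correlation between reconstruction and true delayed
#' input on held-out time steps. Memory capacity is the sum over delays.
#' For a linear (identity-activation) reservoir with `n` units the total
#' is bounded by `n`.
#'
#' @param reservoir A `"mesn_reservoir"` with a single input column
#'   (`d = 1`).
#' @param esn An [esn_config()]; `alpha` and `activation` are used.
#' @param mc An [mc_config()].
#' @return Object of class `"mesn_mc"`: list with `per_delay` (length
#'   `k_max`, each in `[0, 1]`), `total`, and the settings used.
#' @export
estimate_mc <- function(reservoir, esn = esn_config(), mc = mc_config()) {
  if (ncol(reservoir$w_ir) != 1L) {
    stop("memory capacity requires a single-input reservoir (d = 1)")
  }
  set.seed(mc$seed)
  u <- stats::runif(mc$t_len, -1, 1)
  cfg <- esn_config(alpha = esn$alpha, rho = esn$rho,
                    ridge_lambda = esn$ridge_lambda,
                    washout = 0L, steps_per_sample = 1L,
                    reset_per_sample = FALSE, activation = esn$activation)
  x <- encode_sequence(matrix(u, ncol = 1L), reservoir, cfg)
  t0 <- mc$washout + mc$k_max                    # all delays share these steps
  valid <- (t0 + 1L):mc$t_len
  m <- length(valid)
  n_train <- max(2L, ceiling(mc$train_fraction * m))
  if (n_train >= m - 1L) stop("no held-out steps left for evaluation")
  tr <- valid[seq_len(n_train)]
  te <- valid[(n_train + 1L):m]
  xs_tr <- x[, tr, drop = FALSE]
  xs_te <- x[, te, drop = FALSE]
  # delayed-input target matrices, one column per delay
  u_tr <- vapply(seq_len(mc$k_max), function(k) u[tr - k], numeric(length(tr)))
  u_te <- vapply(seq_len(mc$k_max), function(k) u[te - k], numeric(length(te)))
  gram <- tcrossprod(xs_tr)
  diag(gram) <- diag(gram) + mc$ridge_lambda
  w_all <- solve(gram, xs_tr %*% u_tr)           # n x k_max readout weights
  pred <- crossprod(w_all, xs_te)                # k_max x |test|
  per_delay <- vapply(seq_len(mc$k_max), function(k) {
    p <- pred[k, ]
    y <- u_te[, k]
    if (stats::sd(p) < 1e-12 || stats::sd(y) < 1e-12) {
      warning("constant reconstruction at delay ", k, "; MC_k set to 0")
      return(0)
    }
    min(1, max(0, stats::cor(p, y)^2))
  }, numeric(1L))
  structure(
    list(per_delay = per_delay, total = sum(per_delay),
         k_max = mc$k_max, t_len = mc$t_len, washout = mc$washout,
         train_fraction = mc$train_fraction),
    class = "mesn_mc"
  )
}

#' @export
print.mesn_mc <- function(x, ...) {
  cat(sprintf("Reservoir memory capacity: %.3f (delays 1..%d, T = %d)\n",
              x$total, x$k_max, x$t_len))
  invisible(x)
}

#' Memory-capacity sweep over modularity parameters
#'
#' For every `(M, P1, P2)` triple in the grid, generates `repeats` seeded
#' reservoir realizations, estimates each one's memory capacity, and
#' averages. Degenerate realizations (zero spectral radius) are redrawn
#' with a fresh seed up to `max_retries` times.
#'
#' @param n Reservoir size.
#' @param m_values Module counts to sweep.
#' @param p1_values Intra-module probabilities to sweep.
#' @param p2_fractions `P2` is swept as these fractions of each `P1`
#'   (default `c(1, 2, 3, 4, 5)/5`).
#' @param esn An [esn_config()].
#' @param mc An [mc_config()] template; the input-sequence seed is varied
#'   per repeat.
#' @param repeats Reservoir realizations per triple (default 3).
#' @param seed Master seed for the sweep.
#' @param max_retries Redraw budget for degenerate realizations.
#' @return Data frame `(m, p1, p2, mean_mc, sd_mc)` with the argmax triple
#'   in attribute `"best"`.
#' @export
mc_parameter_sweep <- function(n, m_values, p1_values,
                               p2_fractions = c(1, 2, 3, 4, 5) / 5,
                               esn = esn_config(), mc = mc_config(),
                               repeats = 3L, seed = 1L, max_retries = 5L) {
  grid <- do.call(rbind, lapply(p1_values, function(p1) {
    do.call(rbind, lapply(m_values, function(m) {
      data.frame(m = m, p1 = p1, p2 = p1 * p2_fractions)
    }))
  }))
  if (nrow(grid) == 0L) stop("invalid grid: no parameter triples")
  set.seed(seed)
  rep_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                 nrow(grid) * repeats),
                      nrow = nrow(grid))
  means <- numeric(nrow(grid))
  sds <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    totals <- vapply(seq_len(repeats), function(r) {
      s <- rep_seeds[g, r]
      for (attempt in seq_len(max_retries + 1L)) {
        res <- tryCatch(
          generate_reservoir(n = n, modules = grid$m[g], p1 = grid$p1[g],
                             p2 = grid$p2[g], rho = esn$rho, d = 1L,
                             seed = s),
          error = function(e) NULL
        )
        if (!is.null(res)) break
        s <- (s + 104729L) %% (.Machine$integer.max - 1L) + 1L
      }
      if (is.null(res)) stop("degenerate reservoir persisted after retries")
      mc_r <- mc
      mc_r$seed <- s
      estimate_mc(res, esn, mc_r)$total
    }, numeric(1L))
    means[g] <- mean(totals)
    sds[g] <- stats::sd(totals)
  }
  out <- cbind(grid, mean_mc = means, sd_mc = if (repeats > 1L) sds else NA_real_)
  attr(out, "best") <- out[which.max(out$mean_mc), c("m", "p1", "p2", "mean_mc")]
  out
}
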
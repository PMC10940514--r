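# Modular reservoir topology: node-to-module assignment, probabilistic pair
# sampling, bidirectional signed weights, spectral-radius scaling.

#' Assign reservoir nodes to modules
#'
#' Partitions `n` nodes into `modules` communities of (near-)equal size --
#' sizes differ by at most one -- and randomly permutes the assignment.
#' With `modules = 1` the reservoir degenerates to an unpartitioned
#' (Erdős–Rényi-style) network.
#'
#' @param n Number of reservoir nodes.
#' @param modules Number of modules M, `1 <= modules <= n`.
#' @param seed Optional integer seed; when supplied the assignment is
#'   reproducible.
#' @return Integer vector of length `n` with module labels in
#'   `0:(modules - 1)`.
#' @export
#' @examples
#' table(assign_modules(600, 6, seed = 1))
assign_modules <- function(n, modules, seed = NULL) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  if (!is.numeric(modules) || length(modules) != 1L ||
      modules < 1 || modules > n || modules != round(modules)) {
    stop("invalid configuration: 'modules' must be an integer in [1, n]")
  }
  n <- as.integer(n)
  modules <- as.integer(modules)
  if (!is.null(seed)) set.seed(seed)
  base <- n %/% modules
  extra <- n %% modules
  sizes <- rep.int(base, modules) + c(rep.int(1L, extra), rep.int(0L, modules - extra))
  sample(rep.int(seq_len(modules) - 1L, sizes))
}

#' Sample reservoir connection pairs
#'
#' Every unordered pair of distinct nodes in the same module is connected
#' independently with probability `p1`; every cross-module pair with
#' probability `p2`. Self-pairs are never produced. The convention
#' `p2 <= p1` (inter-community links sparser than intra-community links)
#' is enforced.
#'
#' @param labels Module labels as returned by [assign_modules()].
#' @param p1 Intra-module pair connection probability in `[0, 1]`.
#' @param p2 Inter-module pair connection probability in `[0, 1]`.
#' @param seed Optional integer seed.
#' @param on_p2_greater What to do when `p2 > p1`: `"error"` (default) or
#'   `"warn"` and proceed.
#' @return Integer matrix with two columns `i`, `j` (1-based node indices,
#'   `i < j`), one row per sampled pair.
#' @export
sample_pairs <- function(labels, p1, p2, seed = NULL,
                         on_p2_greater = c("error", "warn")) {
  on_p2_greater <- match.arg(on_p2_greater)
  stopifnot(is.numeric(p1), is.numeric(p2), length(p1) == 1L, length(p2) == 1L)
  if (p1 < 0 || p1 > 1 || p2 < 0 || p2 > 1) {
    stop("invalid configuration: probabilities must lie in [0, 1]")
  }
  if (p2 > p1) {
    msg <- "invalid configuration: p2 > p1 (inter-module links must not be denser than intra-module links)"
    if (on_p2_greater == "error") stop(msg) else warning(msg)
  }
  n <- length(labels)
  if (!is.null(seed)) set.seed(seed)
  if (n < 2L) {
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("i", "j"))))
  }
  ij <- which(upper.tri(matrix(FALSE, n, n)), arr.ind = TRUE)
  # upper.tri gives row < col, i.e. unordered pairs exactly once
  prob <- ifelse(labels[ij[, 1L]] == labels[ij[, 2L]], p1, p2)
  keep <- stats::runif(nrow(ij)) < prob
  out <- ij[keep, , drop = FALSE]
  dimnames(out) <- list(NULL, c("i", "j"))
  out
}

# Standard normal truncated to (0, 1), sampled by rejection. Used for
# connection weight magnitudes.
rtruncnorm01 <- function(m) {
  out <- numeric(m)
  need <- seq_len(m)
  while (length(need) > 0L) {
    z <- stats::rnorm(ceiling(length(need) / 0.34))
    z <- z[z > 0 & z < 1]
    take <- min(length(z), length(need))
    if (take > 0L) {
      out[need[seq_len(take)]] <- z[seq_len(take)]
      need <- need[-seq_len(take)]
    }
  }
  out
}

#' Assign bidirectional signed weights to sampled pairs
#'
#' Every connected pair carries two directed weights, one per direction
#' (bidirectional connections). Magnitudes are drawn independently from a
#' standard normal truncated to (0, 1). Signs follow the opposite-pair
#' rule: with probability 1/2 the two directions carry opposite signs (the
#' negated direction chosen at random), otherwise both directions share one
#' random sign -- so about half of all connected pairs end up with opposite
#' signs.
#'
#' @param pairs Two-column pair matrix from [sample_pairs()].
#' @param n Number of reservoir nodes.
#' @param seed Optional integer seed.
#' @return Dense `n x n` numeric matrix; entries off the sampled pairs are
#'   exactly zero.
#' @export
assign_weights <- function(pairs, n, seed = NULL) {
  stopifnot(is.matrix(pairs), ncol(pairs) == 2L)
  n <- as.integer(n)
  if (nrow(pairs) > 0L && (max(pairs) > n || min(pairs) < 1L)) {
    stop("pair indices out of range for n nodes")
  }
  if (!is.null(seed)) set.seed(seed)
  w <- matrix(0, n, n)
  e <- nrow(pairs)
  if (e == 0L) return(w)
  mag_fwd <- rtruncnorm01(e)
  mag_rev <- rtruncnorm01(e)
  s_fwd <- sample(c(-1, 1), e, replace = TRUE)
  opposite <- stats::runif(e) < 0.5
  s_rev <- ifelse(opposite, -s_fwd, s_fwd)
  w[pairs] <- s_fwd * mag_fwd
  w[pairs[, c(2L, 1L), drop = FALSE]] <- s_rev * mag_rev
  w
}

#' Spectral radius of a square matrix
#'
#' Largest absolute eigenvalue.
#'
#' @param w Square numeric matrix.
#' @return Nonnegative scalar.
#' @export
spectral_radius <- function(w) {
  stopifnot(is.matrix(w), nrow(w) == ncol(w))
  max(Mod(eigen(w, only.values = TRUE)$values))
}

#' Rescale a recurrent matrix to a target spectral radius
#'
#' Multiplies `w` by `rho_target / rho(w)`. Keeping the spectral radius at
#' or below 1 guards the echo state property (initial conditions are
#' asymptotically washed out).
#'
#' @param w Square numeric matrix with nonzero spectral radius.
#' @param rho_target Positive target spectral radius.
#' @return Rescaled matrix whose spectral radius equals `rho_target` to
#'   within about 1e-8 relative error.
#' @export
scale_spectral_radius <- function(w, rho_target) {
  stopifnot(is.numeric(rho_target), length(rho_target) == 1L, rho_target > 0)
  rho <- spectral_radius(w)
  if (rho < .Machine$double.eps^0.5) {
    stop("degenerate reservoir: spectral radius is zero (nilpotent or empty recurrent matrix), cannot scale")
  }
  w * (rho_target / rho)
}

#' Generate uniform input weights
#'
#' Input-to-reservoir weights drawn i.i.d. uniform on `(-scale, scale)`.
#' The small default scale (0.1) keeps the drive inside the responsive
#' region of the tanh activation.
#'
#' @param n Number of reservoir nodes (rows).
#' @param d Input dimension (columns).
#' @param scale Positive half-width of the uniform range; default 0.1.
#' @param seed Optional integer seed.
#' @return `n x d` numeric matrix.
#' @export
generate_input_weights <- function(n, d, scale = 0.1, seed = NULL) {
  stopifnot(n >= 1, d >= 1)
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0) {
    stop("invalid configuration: 'scale' must be > 0")
  }
  if (!is.null(seed)) set.seed(seed)
  matrix(stats::runif(n * d, -scale, scale), as.integer(n), as.integer(d))
}

#' Generate a modular reservoir
#'
#' Composes the full reservoir construction: balanced random module
#' assignment, pair sampling at probabilities `p1` (intra) / `p2` (inter),
#' bidirectional signed truncated-normal weights, spectral-radius scaling
#' of the recurrent matrix, and uniform input weights. With `modules = 1`
#' and `p1 == p2` this reduces to a basic (random, non-modular) echo state
#' reservoir.
#'
#' One seed drives the whole construction: stage seeds for
#' assignment, pair sampling, weights and input weights are derived
#' deterministically from `seed`, so two calls with the same arguments
#' produce identical matrices.
#'
#' @param n Reservoir size (default 600).
#' @param modules Module count M.
#' @param p1,p2 Intra-/inter-module pair connection probabilities,
#'   `p2 <= p1`.
#' @param rho Target spectral radius (default 0.85).
#' @param d Input dimension.
#' @param seed Integer seed.
#' @param input_scale Half-width of the uniform input-weight range.
#' @param on_p2_greater Passed to [sample_pairs()].
#' @return An object of class `"mesn_reservoir"`: a list with the recurrent
#'   matrix `w_rc` (n x n, spectral radius `rho`), input matrix `w_ir`
#'   (n x d), module `labels`, the sampled `pairs`, and the generating
#'   parameters.
#' @export
#' @examples
#' res <- generate_reservoir(n = 60, modules = 6, p1 = 0.3, p2 = 0.1,
#'                           rho = 0.85, d = 4, seed = 42)
#' res
generate_reservoir <- function(n = 600, modules = 6, p1 = 0.05, p2 = 0.02,
                               rho = 0.85, d = 128, seed = 1,
                               input_scale = 0.1,
                               on_p2_greater = c("error", "warn")) {
  on_p2_greater <- match.arg(on_p2_greater)
  set.seed(seed)
  stage_seeds <- sample.int(.Machine$integer.max - 1L, 4L)
  labels <- assign_modules(n, modules, seed = stage_seeds[1L])
  pairs <- sample_pairs(labels, p1, p2, seed = stage_seeds[2L],
                        on_p2_greater = on_p2_greater)
  w_raw <- assign_weights(pairs, n, seed = stage_seeds[3L])
  w_rc <- scale_spectral_radius(w_raw, rho)
  w_ir <- generate_input_weights(n, d, scale = input_scale,
                                 seed = stage_seeds[4L])
  structure(
    list(w_rc = w_rc, w_ir = w_ir, labels = labels, pairs = pairs,
         n = as.integer(n), modules = as.integer(modules),
         p1 = p1, p2 = p2, rho = rho, d = as.integer(d),
         input_scale = input_scale, seed = seed),
    class = "mesn_reservoir"
  )
}

#' @export
print.mesn_reservoir <- function(x, ...) {
  cat(sprintf(
    "Modular ESN reservoir: N = %d, M = %d, P1 = %g, P2 = %g\n",
    x$n, x$modules, x$p1, x$p2))
  cat(sprintf("  connected pairs: %d (density %.4f)\n",
              nrow(x$pairs), nrow(x$pairs) / choose(x$n, 2)))
  cat(sprintf("  spectral radius: %.6f (target %g)\n",
              spectral_radius(x$w_rc), x$rho))
  cat(sprintf("  input weights: %d x %d, uniform on (-%g, %g)\n",
              x$n, x$d, x$input_scale, x$input_scale))
  invisible(x)
}

#' Save / load a reservoir
#'
#' Lossless round-trip of a generated reservoir (weights, labels, pairs and
#' generating parameters) via R serialization.
#'
#' @param reservoir A `"mesn_reservoir"` object.
#' @param path File path.
#' @return `read_reservoir` returns the restored object; `write_reservoir`
#'   returns `path` invisibly.
#' @export
write_reservoir <- function(reservoir, path) {
  stopifnot(inherits(reservoir, "mesn_reservoir"))
  saveRDS(reservoir, path)
  invisible(path)
}

#' @rdname write_reservoir
#' @export
read_reservoir <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "mesn_reservoir")) stop("file does not contain a reservoir")
  x
}
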
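# Degree-distribution heterogeneity: in-degrees and the coefficient of
# variation (SD/mean).

#' In-degree vector of a recurrent weight matrix
#'
#' Under the state-update convention `x <- w_rc %*% x`, row `i` of the
#' matrix collects the connections coming *into* node `i`, so in-degrees
#' are row statistics. `"binary"` counts nonzero entries per row;
#' `"weighted"` takes the signed row sum.
#'
#' @param w Square numeric matrix.
#' @param mode `"weighted"` (default) or `"binary"`.
#' @return Numeric vector of length `nrow(w)`.
#' @export
in_degree <- function(w, mode = c("weighted", "binary")) {
  mode <- match.arg(mode)
  if (!is.matrix(w) || nrow(w) != ncol(w)) {
    stop("shape error: 'w' must be a square matrix")
  }
  if (mode == "binary") rowSums(w != 0) else rowSums(w)
}

#' Degree-distribution summary statistics
#'
#' Population statistics (divide by N, not N-1) of a degree vector, plus
#' the coefficient of variation CV = SD/mean, the heterogeneity measure of
#' the network. CV is reported signed; when the mean is tiny relative to
#' the spread (`|mean| < 1e-6 * sd`) the CV is numerically unstable and
#' flagged as such.
#'
#' @param degrees Numeric vector, length >= 2.
#' @return Object of class `"mesn_degree_stats"`: list with `degrees`,
#'   `mean`, `variance`, `sd`, `cv`, and logical `cv_unstable`.
#' @export
degree_stats <- function(degrees) {
  stopifnot(is.numeric(degrees), length(degrees) >= 2L)
  n <- length(degrees)
  m <- mean(degrees)
  v <- sum((degrees - m)^2) / n
  s <- sqrt(v)
  if (m == 0) {
    stop("cv undefined: mean degree is exactly zero; inspect the degree vector directly")
  }
  structure(
    list(degrees = degrees, mean = m, variance = v, sd = s,
         cv = s / m, cv_unstable = abs(m) < 1e-6 * s),
    class = "mesn_degree_stats"
  )
}

#' @export
print.mesn_degree_stats <- function(x, ...) {
  cat(sprintf("Degree statistics over %d nodes\n", length(x$degrees)))
  cat(sprintf("  mean %.4f  variance %.4f  sd %.4f  cv (sd/mean) %.4f%s\n",
              x$mean, x$variance, x$sd, x$cv,
              if (x$cv_unstable) "  [unstable: |mean| << sd]" else ""))
  invisible(x)
}

#' Degree histogram export
#'
#' Bin edges and counts for plotting in-degree distributions.
#'
#' @param degrees Numeric degree vector.
#' @param breaks Passed to [graphics::hist()] breaks logic via
#'   [base::cut()]; either a count or a vector of edges.
#' @return Data frame with `lower`, `upper`, `count`.
#' @export
degree_histogram <- function(degrees, breaks = 30L) {
  h <- graphics::hist(degrees, breaks = breaks, plot = FALSE)
  data.frame(lower = utils::head(h$breaks, -1L),
             upper = utils::tail(h$breaks, -1L),
             count = h$counts)
}
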
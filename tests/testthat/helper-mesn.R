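# Shared fixtures and independent oracles.

# Independent ridge solve via the SVD of the state matrix:
# Y X^T (X X^T + lambda I)^{-1} = Y V D (D^2 + lambda)^{-1} U^T.
svd_ridge_oracle <- function(states, targets, lambda) {
  sv <- svd(states)
  targets %*% sv$v %*% diag(sv$d / (sv$d^2 + lambda), length(sv$d)) %*% t(sv$u)
}

# Independent spectral radius for small matrices: roots of the
# characteristic polynomial.
charpoly_radius <- function(w) {
  max(Mod(polyroot(rev(pracma::charpoly(w)))))
}

# Linear delay-line reservoir: the state is a shift register of the last
# n inputs, so delays 1..n-1 are perfectly reconstructable.
delay_line_reservoir <- function(n) {
  w_rc <- matrix(0, n, n)
  w_rc[cbind(2:n, 1:(n - 1))] <- 1
  w_ir <- matrix(c(1, rep(0, n - 1)), ncol = 1)
  structure(list(w_rc = w_rc, w_ir = w_ir, n = n, d = 1L),
            class = "mesn_reservoir")
}

# Hand-built reservoir from explicit matrices.
manual_reservoir <- function(w_rc, w_ir) {
  structure(list(w_rc = w_rc, w_ir = w_ir,
                 n = nrow(w_rc), d = ncol(w_ir)),
            class = "mesn_reservoir")
}

# Pure sinusoid segment: one frequency per channel.
sinusoid_segment <- function(freqs_hz, n_samples, fs, amplitude = 1) {
  tt <- (seq_len(n_samples) - 1) / fs
  sapply(freqs_hz, function(f) amplitude * sin(2 * pi * f * tt))
}
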
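# EEG band-power features: windowing, per-channel L2 normalization,
# DFT band energies, relative band power.

#' Default EEG frequency bands
#'
#' Theta 4-8 Hz, alpha 8-12 Hz, beta 12-30 Hz, gamma 30-45 Hz. The delta
#' band is excluded: band-pass-filtered recordings such as DEAP (4-45 Hz)
#' carry no delta content. Band edges are half-open `[low, high)` so the
#' four bands partition the spectrum without double counting.
#'
#' @return Data frame with columns `name`, `low`, `high` (Hz).
#' @export
band_definitions <- function() {
  data.frame(
    name = c("theta", "alpha", "beta", "gamma"),
    low  = c(4, 8, 12, 30),
    high = c(8, 12, 30, 45),
    stringsAsFactors = FALSE
  )
}

#' Crop trials into non-overlapping windows
#'
#' Slices each trial into consecutive non-overlapping segments of
#' `window_seconds`. Segment k of a trial covers samples
#' `[k*w, (k+1)*w)` with `w = window_seconds * fs`; a trailing remainder
#' shorter than the window is dropped.
#'
#' @param trials 3-d numeric array, `trials x samples x channels`.
#' @param fs Sampling rate in Hz.
#' @param window_seconds Window length in seconds; must not exceed the
#'   trial duration.
#' @return List with `segments` (array `n_segments x window_samples x
#'   channels`) and `trial` (integer vector: trial of origin per segment).
#' @export
crop_trials <- function(trials, fs, window_seconds) {
  stopifnot(is.array(trials), length(dim(trials)) == 3L)
  n_trials <- dim(trials)[1L]
  n_samples <- dim(trials)[2L]
  n_channels <- dim(trials)[3L]
  w <- as.integer(round(window_seconds * fs))
  if (w < 1L || w > n_samples) {
    stop("invalid window: longer than the trial (or empty)")
  }
  per_trial <- n_samples %/% w
  n_seg <- n_trials * per_trial
  segments <- array(0, dim = c(n_seg, w, n_channels))
  trial_of <- integer(n_seg)
  s <- 0L
  for (tr in seq_len(n_trials)) {
    for (k in seq_len(per_trial)) {
      s <- s + 1L
      segments[s, , ] <- trials[tr, ((k - 1L) * w + 1L):(k * w), ]
      trial_of[s] <- tr
    }
  }
  list(segments = segments, trial = trial_of)
}

#' Per-channel L2 normalization of a segment
#'
#' Divides each channel by its Euclidean norm, removing per-channel
#' amplitude scale (a source of inter-subject variability) while leaving
#' the spectral shape untouched.
#'
#' @param segment `window_samples x channels` numeric matrix.
#' @return Matrix of the same shape with unit-norm channels.
#' @export
l2_normalize <- function(segment) {
  if (is.vector(segment)) segment <- matrix(segment, ncol = 1L)
  norms <- sqrt(colSums(segment^2))
  if (any(norms == 0)) {
    stop("zero-norm channel: cannot L2-normalize an all-zero signal")
  }
  sweep(segment, 2L, norms, "/")
}

#' Spectral energy of a signal in a frequency band
#'
#' Sum of squared DFT magnitudes over the bins whose frequency `f = k*fs/n`
#' satisfies `low <= f < high` (half-open; only nonnegative frequencies
#' below the Nyquist rate are considered).
#'
#' @param x Numeric signal vector.
#' @param fs Sampling rate in Hz.
#' @param low,high Band edges in Hz, `0 <= low < high <= fs/2`.
#' @return Nonnegative scalar energy.
#' @export
band_energy <- function(x, fs, low, high) {
  stopifnot(low < high, low >= 0, high <= fs / 2)
  n <- length(x)
  k_half <- seq_len(ceiling(n / 2)) - 1L          # bins with f in [0, fs/2)
  freqs <- k_half * fs / n
  sel <- freqs >= low & freqs < high
  if (!any(sel)) stop("empty band: no DFT bin falls in [low, high)")
  spec <- stats::fft(x)[k_half + 1L]
  sum(Mod(spec[sel])^2)
}

#' Relative band-power feature vector of one segment
#'
#' L2-normalizes the segment per channel, computes the four band energies
#' per channel, and divides each by the channel's summed energy over the
#' four bands, so per channel the four relative powers are in `[0, 1]` and
#' sum to one. Features are concatenated channel-major: channel 1's four
#' bands, then channel 2's, and so on -- a 32-channel segment yields
#' `4 * 32 = 128` features.
#'
#' @param segment `window_samples x channels` numeric matrix.
#' @param fs Sampling rate in Hz.
#' @param bands Band table as from [band_definitions()].
#' @return Numeric vector of length `4 * channels`, named
#'   `ch<i>_<band>`.
#' @export
extract_features <- function(segment, fs, bands = band_definitions()) {
  if (is.vector(segment)) segment <- matrix(segment, ncol = 1L)
  segment <- l2_normalize(segment)
  n <- nrow(segment)
  n_ch <- ncol(segment)
  k_half <- seq_len(ceiling(n / 2)) - 1L
  freqs <- k_half * fs / n
  spec <- stats::mvfft(segment)[k_half + 1L, , drop = FALSE]
  power <- Mod(spec)^2
  e <- vapply(seq_len(nrow(bands)), function(b) {
    sel <- freqs >= bands$low[b] & freqs < bands$high[b]
    if (!any(sel)) stop("empty band: no DFT bin falls in [", bands$low[b],
                        ", ", bands$high[b], ")")
    colSums(power[sel, , drop = FALSE])
  }, numeric(n_ch))                                # n_ch x n_bands
  e <- matrix(e, nrow = n_ch)
  tot <- rowSums(e)
  if (any(tot == 0)) {
    stop("degenerate signal: a channel has zero energy in all bands")
  }
  r <- e / tot
  out <- as.vector(t(r))                           # channel-major
  names(out) <- paste0("ch", rep(seq_len(n_ch), each = nrow(bands)),
                       "_", rep(bands$name, n_ch))
  out
}

#' Band-power features for a whole trial set
#'
#' Convenience pipeline: [crop_trials()] then [extract_features()] per
#' segment.
#'
#' @param trials 3-d array `trials x samples x channels`.
#' @param fs Sampling rate in Hz.
#' @param window_seconds Non-overlapping window length in seconds.
#' @param bands Band table as from [band_definitions()].
#' @return List with `features` (`n_segments x (4*channels)` matrix) and
#'   `trial` (trial of origin per segment).
#' @export
features_from_trials <- function(trials, fs, window_seconds,
                                 bands = band_definitions()) {
  cropped <- crop_trials(trials, fs, window_seconds)
  n_seg <- dim(cropped$segments)[1L]
  feats <- t(vapply(
    seq_len(n_seg),
    function(s) extract_features(cropped$segments[s, , ], fs, bands),
    numeric(nrow(bands) * dim(cropped$segments)[3L])
  ))
  list(features = feats, trial = cropped$trial)
}
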
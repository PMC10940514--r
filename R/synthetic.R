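# Synthetic EEG with class-dependent sub-band power, plus fast separable
# feature fixtures. Emulates the shape of preprocessed DEAP recordings
# (trials x 60*128 samples x 32 channels, ratings on 1-9 scales) so every
# downstream stage can be exercised without any external download.

#' Synthetic EEG specification
#'
#' Each channel of a trial is a sum over the four bands of a sinusoid with
#' random phase and uniformly jittered within-band frequency, scaled by a
#' class-dependent band factor, plus Gaussian broadband noise. Sinusoids
#' give exact control over band energies, which is the property the
#' feature pipeline measures; no attempt is made at 1/f spectra or
#' artifact realism.
#'
#' @param n_trials Number of trials (default 40, one recording session's
#'   worth).
#' @param channels Channels per trial (default 32).
#' @param fs Sampling rate in Hz (default 128).
#' @param trial_seconds Trial duration in seconds (default 60).
#' @param class_effects Named list with per-class multiplicative band
#'   amplitude factors over `c(theta, alpha, beta, gamma)`. Default: the
#'   `high` class carries 1.5x beta and gamma amplitude, emulating
#'   high-arousal/valence states with stronger fast rhythms.
#' @param base_amplitude Baseline sinusoid amplitude (default 1).
#' @param amplitude_jitter_sd Log-normal sigma of the per-trial, per-band
#'   amplitude fluctuation, shared across channels (default 0.4). Real EEG
#'   band power varies substantially from trial to trial within a class;
#'   this jitter reproduces that overlap, so the default class effect is a
#'   moderate (trial-level d of about 1 per boosted band), not a ceiling,
#'   separation. Set to 0 for noise-free band mechanics.
#' @param noise_sd Gaussian broadband noise SD (default 1).
#' @param rating_rule How ratings encode the generated class:
#'   `"binary"` (default) draws valence and arousal uniformly from
#'   `(5, 9]` for the high class and `[1, 5]` for the low class, so the
#'   \code{>5} binarization recovers the class exactly; `"stress_calm"`
#'   places the high class in the stress region (valence <= 3,
#'   arousal >= 5) and the low class in the calm region (4 <= valence <= 6,
#'   arousal < 4).
#' @param seed Integer seed.
#' @return List of class `"mesn_synthetic_spec"`.
#' @export
synthetic_spec <- function(n_trials = 40L, channels = 32L, fs = 128,
                           trial_seconds = 60,
                           class_effects = list(
                             low  = c(theta = 1, alpha = 1, beta = 1, gamma = 1),
                             high = c(theta = 1, alpha = 1, beta = 1.5, gamma = 1.5)),
                           base_amplitude = 1, amplitude_jitter_sd = 0.4,
                           noise_sd = 1,
                           rating_rule = c("binary", "stress_calm"),
                           seed = 1L) {
  rating_rule <- match.arg(rating_rule)
  stopifnot(n_trials >= 1, channels >= 1, fs > 0, trial_seconds > 0,
            noise_sd >= 0, base_amplitude > 0, amplitude_jitter_sd >= 0)
  if (any(unlist(class_effects) <= 0)) {
    stop("class_effects must be positive factors")
  }
  structure(
    list(n_trials = as.integer(n_trials), channels = as.integer(channels),
         fs = fs, trial_seconds = trial_seconds,
         class_effects = class_effects, base_amplitude = base_amplitude,
         amplitude_jitter_sd = amplitude_jitter_sd,
         noise_sd = noise_sd, rating_rule = rating_rule,
         seed = as.integer(seed)),
    class = "mesn_synthetic_spec"
  )
}

#' Generate synthetic EEG trials with ratings
#'
#' @param spec A [synthetic_spec()].
#' @param bands Band table as from [band_definitions()].
#' @return List with `data` (array `n_trials x samples x channels`),
#'   `ratings` (data frame `valence`, `arousal`, `dominance`, `liking` on
#'   the 1-9 scale), and `class` (factor of ground-truth classes, levels
#'   in the order given by `class_effects`).
#' @export
generate_trials <- function(spec, bands = band_definitions()) {
  stopifnot(inherits(spec, "mesn_synthetic_spec"))
  set.seed(spec$seed)
  classes <- names(spec$class_effects)
  n_samples <- as.integer(round(spec$fs * spec$trial_seconds))
  tt <- (seq_len(n_samples) - 1L) / spec$fs
  cls <- factor(sample(classes, spec$n_trials, replace = TRUE),
                levels = classes)
  n_b <- nrow(bands)
  data <- array(0, dim = c(spec$n_trials, n_samples, spec$channels))
  for (tr in seq_len(spec$n_trials)) {
    eff <- spec$class_effects[[as.character(cls[tr])]]
    freqs <- matrix(stats::runif(n_b * spec$channels, bands$low, bands$high),
                    n_b, spec$channels)
    phases <- matrix(stats::runif(n_b * spec$channels, 0, 2 * pi),
                     n_b, spec$channels)
    jitter <- exp(stats::rnorm(n_b, 0, spec$amplitude_jitter_sd))
    amps <- spec$base_amplitude * eff * jitter   # trial state, shared by channels
    sig <- matrix(0, n_samples, spec$channels)
    for (b in seq_len(n_b)) {
      sig <- sig + amps[b] *
        sin(outer(tt, 2 * pi * freqs[b, ]) +
              matrix(phases[b, ], n_samples, spec$channels, byrow = TRUE))
    }
    if (spec$noise_sd > 0) {
      sig <- sig + matrix(stats::rnorm(n_samples * spec$channels,
                                       sd = spec$noise_sd),
                          n_samples, spec$channels)
    }
    data[tr, , ] <- sig
  }
  high <- cls == classes[length(classes)]
  nt <- spec$n_trials
  if (spec$rating_rule == "binary") {
    valence <- ifelse(high, stats::runif(nt, 5 + 1e-6, 9), stats::runif(nt, 1, 5))
    arousal <- ifelse(high, stats::runif(nt, 5 + 1e-6, 9), stats::runif(nt, 1, 5))
  } else {
    valence <- ifelse(high, stats::runif(nt, 1, 3), stats::runif(nt, 4, 6))
    arousal <- ifelse(high, stats::runif(nt, 5, 9), stats::runif(nt, 1, 4 - 1e-6))
  }
  ratings <- data.frame(
    valence = valence, arousal = arousal,
    dominance = stats::runif(nt, 1, 9), liking = stats::runif(nt, 1, 9))
  list(data = data, ratings = ratings, class = cls)
}

#' Fast separable feature fixtures
#'
#' Two Gaussian clusters in feature space at distance `gap`, clipped to
#' `[0, 1]` and renormalized so every consecutive block of four features
#' (one channel's four relative band powers) sums to one -- the invariant
#' real band-power features satisfy. Bypasses the signal layer for quick
#' classifier tests.
#'
#' @param n_per_class Samples per class.
#' @param dim Feature dimension, a multiple of 4 (default 128).
#' @param gap Euclidean distance between the two cluster means before
#'   clipping/renormalization; `gap = 0` gives indistinguishable classes.
#' @param noise_sd Isotropic within-cluster SD (default 0.05).
#' @param seed Integer seed.
#' @return List with `features` (`2*n_per_class x dim` matrix) and
#'   `labels` (factor, levels `c("low", "high")`).
#' @export
generate_separable_features <- function(n_per_class, dim = 128L, gap = 0.5,
                                        noise_sd = 0.05, seed = 1L) {
  stopifnot(n_per_class >= 1, dim >= 4, dim %% 4 == 0, gap >= 0, noise_sd >= 0)
  set.seed(seed)
  center <- stats::runif(dim, 0.3, 0.7)
  delta <- stats::rnorm(dim)
  delta <- delta / sqrt(sum(delta^2)) * (gap / 2)
  n_tot <- 2L * n_per_class
  labels <- factor(rep(c("low", "high"), each = n_per_class),
                   levels = c("low", "high"))
  sign_of <- ifelse(labels == "high", 1, -1)
  x <- matrix(center, n_tot, dim, byrow = TRUE) +
    outer(sign_of, delta) +
    matrix(stats::rnorm(n_tot * dim, sd = noise_sd), n_tot, dim)
  x <- pmin(pmax(x, 0), 1)
  for (q in seq_len(dim %/% 4L)) {
    cols <- ((q - 1L) * 4L + 1L):(q * 4L)
    s <- rowSums(x[, cols, drop = FALSE])
    zero <- s == 0
    if (any(zero)) {
      x[zero, cols] <- 0.25
      s[zero] <- 1
    }
    x[, cols] <- x[, cols, drop = FALSE] / s
  }
  list(features = x, labels = labels)
}
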
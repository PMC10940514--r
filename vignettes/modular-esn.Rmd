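---
title: "Modular echo state networks for EEG band-power classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modular echo state networks for EEG band-power classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesn)
```

## The model

An echo state network (ESN) is a recurrent network whose hidden "reservoir"
is fixed at initialization; only a linear readout is trained. The reservoir
state $x_t \in \mathbb{R}^N$ evolves as a leaky integrator,

$$x_{t+1} = (1-\alpha)\,x_t + \alpha\,\tanh(W^{IR} u_t + W^{RC} x_t),$$

with leak rate $\alpha \in [0,1]$, input weights $W^{IR}$, and recurrent
weights $W^{RC}$. $W^{RC}$ is rescaled so its spectral radius (largest
absolute eigenvalue) equals a target $\rho \le 1$, which guards the echo
state property: the state asymptotically forgets its initial condition, so
the reservoir acts as a fading-memory nonlinear filter of its input. The
readout is closed-form ridge regression on collected states,

$$W^{RO} = Y\,X^\top (X X^\top + \lambda I)^{-1}, \qquad
  \hat y_t = W^{RO} x_t,$$

with one-hot targets and argmax decoding for classification.

The package's central object is a *modular* reservoir. Instead of a single
Erdős–Rényi random graph, the $N$ nodes are partitioned into $M$ modules
(communities), and unordered node pairs are connected independently with
probability $P_1$ inside a module and $P_2 \le P_1$ across modules —
internally dense, externally sparse, the community structure observed
throughout biological nervous systems. With $M = 1$, or $P_1 = P_2$, the
construction reduces to the classic random reservoir, so the basic ESN is
the $M{=}1$ special case of the same generator and all comparisons between
the two are matched by construction.

### Reservoir construction, step by step

`generate_reservoir()` composes five operations, each independently seeded
from the master seed in a fixed order (assignment → pairs → weights → input
weights), so both the whole and the parts are reproducible:

1. **Module assignment** (`assign_modules`): a balanced partition (module
   sizes differ by at most one) randomly permuted over nodes. Balanced
   sizes were chosen over multinomial assignment because they make
   expected edge counts exact — at $N{=}600$, $M{=}6$, $P_1{=}0.05$,
   $P_2{=}0.02$ the expectation is
   $6\binom{100}{2}P_1 + \left[\binom{600}{2}-6\binom{100}{2}\right]P_2 = 4485$
   pairs — and near-equal clusters are what a community-structured
   reservoir depicts.
2. **Pair sampling** (`sample_pairs`): independent Bernoulli draws per
   unordered pair. Probabilities are applied to unordered pairs (not
   ordered edges) because connections are bidirectional: every connected
   pair carries a weight in each direction.
3. **Weights** (`assign_weights`): the two directed magnitudes of a pair
   are independent draws from a standard normal truncated to $(0,1)$.
   With probability $1/2$ the pair's two directions take opposite signs
   (the negated direction chosen at random); otherwise both share one
   random sign. So about half of all pairs are opposite-signed, and every
   entry is symmetrically distributed around zero. The truncated normal is
   the most literal reading of "normally distributed magnitudes inside
   (0, 1)"; a uniform magnitude is a defensible alternative, and the
   choice is isolated in one function should a user want to swap it.
4. **Spectral scaling** (`scale_spectral_radius`): multiply by
   $\rho_\text{target}/\rho(W)$. A zero spectral radius (empty or
   nilpotent graph, e.g. $P_1 = P_2 = 0$) is an error, not a silent skip:
   an unscaled reservoir has no echo-state guarantee.
5. **Input weights** (`generate_input_weights`): i.i.d. uniform on
   $(-0.1, 0.1)$. The small scale keeps the tanh drive in its responsive,
   non-saturated region.

Self-loops are excluded throughout (pairs require $i \ne j$).

### Driving the reservoir with feature vectors

Band-power feature vectors are i.i.d. segments, not a time series, and the
cross-validation protocol shuffles them across folds. Carrying reservoir
state from one segment into the next would therefore leak information
between training and test folds. The package's per-sample encoding mode
(`reset_per_sample = TRUE`, the default) presents each feature vector for
`steps_per_sample` (default 5) consecutive updates from the zero state and
keeps the final state as that segment's representation; a few repeated
steps let the state move toward its input-conditioned fixed point, deepening
the nonlinear embedding, while full resets keep segments exchangeable.
Continuous mode (`reset_per_sample = FALSE`, with a washout) is used where
the input genuinely is a sequence — memory-capacity estimation. The initial
state is always $x_0 = 0$ and there are no bias terms. Ties in argmax
decoding go to the lower class index, and $\lambda$ defaults to $10^{-6}$;
all three conventions exist to make results deterministic and documented
rather than incidental.

## The feature pipeline

EEG trials (`trials × samples × channels`, e.g. DEAP's 60 s × 128 Hz × 32
channels) are cropped into non-overlapping windows (6 s for valence and
arousal, 2 s for the smaller stress/calm subset, following common usage;
trailing remainders are dropped; windows are half-open in 0-based sample
coordinates). Each segment is L2-normalized **per channel** — amplitude
scale differs across subjects and electrodes and is treated as nuisance,
while relative inter-channel amplitude is arguably physiological; the axis
convention is therefore a documented choice, not a mathematical necessity.
Band energy is the plain periodogram sum

$$E_\omega = \sum_{k:\ \ell_\omega \le k f_s / n < h_\omega} |F_k|^2,
\qquad \omega \in \{\theta, \alpha, \beta, \gamma\},$$

over DFT bins (no taper, no interpolation), with half-open band edges
$[\ell, h)$ so theta 4–8, alpha 8–12, beta 12–30 and gamma 30–45 Hz
partition the spectrum without double-counting the shared edges. Delta is
excluded because band-pass-filtered recordings (DEAP: 4–45 Hz) carry no
delta content. The relative power $R_\omega = E_\omega / \sum_f E_f$ is
normalized over the four retained bands only, so per channel the four
features lie in $[0,1]$ and sum to one; a 32-channel segment gives
$4 \times 32 = 128$ features, concatenated channel-major. Frequencies
outside the four bands (45 Hz–Nyquist) are deliberately outside the
denominator.

## Memory capacity

Memory capacity measures how much of its input history a reservoir can
linearly reconstruct:

$$\mathrm{MC} = \sum_{k \ge 1}
  \frac{\mathrm{cov}^2\!\left(u_{t-k},\, y_k(t)\right)}
       {\mathrm{var}(u_t)\,\mathrm{var}(y_k(t))},$$

where $y_k(t) = w_k^\text{out} x_t$ is a delay-$k$ linear readout. For an
$N$-unit linear reservoir the total is bounded by $N$.
`estimate_mc()` drives the reservoir with an i.i.d. uniform$(-1,1)$
sequence (the standard choice in the memory-capacity literature) in
continuous mode, truncates the sum at `k_max` (default 200; $2N$ for
linear bound checks, where memory can approach $N$), trains all delay
readouts with a shared tiny ridge ($10^{-8}$, taming near-singular state
covariances), and — unlike the common in-sample practice — evaluates the
squared correlations on a held-out 30% of the sequence to avoid optimistic
bias. Values are clipped to $[0,1]$ per delay; a constant reconstruction
scores 0 with a warning. The activation for capacity sweeps defaults to
the classification-phase settings (tanh, $\alpha = 0.25$) and is
configurable, since linear-bound arguments use the identity activation.

## Heterogeneity

Under the row convention of the update equation, in-degrees are row
statistics of $W^{RC}$: counts of nonzero entries (`binary`) or signed row
sums (`weighted`). `degree_stats()` reports population (divide-by-$N$)
mean, variance, SD and the coefficient of variation $\mathrm{CV} =
\mathrm{SD}/\mathrm{mean}$, the conventional network-heterogeneity index.
Both modes are computed because the two answer different questions
(wiring heterogeneity vs. net synaptic drive); the weighted CV of a
sign-symmetric network has a near-zero, sign-random mean, so it is
reported signed and flagged as unstable when $|\text{mean}| < 10^{-6}
\cdot \text{SD}$ — in that regime the CV is dominated by the accidental
size of the mean, a caveat that matters when comparing networks (see
"What the tests do and do not show").

## The experimental protocol

Ratings on the 1–9 affective scales are binarized: high valence/arousal
strictly above 5; stress iff valence $\le 3$ and arousal $\ge 5$; calm iff
$4 \le$ valence $\le 6$ and arousal $< 4$; for stress/calm, everything
else is excluded. The positive class is high/stress (a convention needed
for precision and F1 to be well defined). `evaluate_config()` runs
repeated stratified-by-chance 5-fold cross-validation: each repeat draws a
**new reservoir realization** (matching "repeat and average" over random
initializations; drawing per repeat rather than per fold keeps the fold
comparison within one reservoir) and folds are segment-level random
partitions. Segment-level splitting follows the protocol this package
mirrors; segments from one trial can land in different folds, which
inflates absolute accuracies when trial-level states are strong — the
synthetic generator makes this visible (below). Trial- or subject-wise
splitting can be had by passing the appropriate label subsets, but it is
not the default protocol.

`grid_search()` enumerates $P_1 \in \{0.05, \dots, 0.3\}$ (outer), $M \in
\{1..6, 8, 10\}$, and $P_2 \in \{P_1/5, \dots, P_1\}$ — 240 triples —
keeping the first strict improvement, so ties resolve to the earliest
triple in protocol order. The scorer can be injected, which is how the
search logic is tested against a planted optimum independently of any
reservoir computation.

## The synthetic generator

`generate_trials()` emulates the *shape and the measured property* of
preprocessed affective-EEG data: trials of `fs × trial_seconds` samples
over `channels` channels, with per-trial valence/arousal ratings whose
binarization recovers the generated class exactly. Each channel is a sum
of four band-limited sinusoids (frequency jittered uniformly inside each
band per trial, random phase) plus Gaussian broadband noise. Class
membership multiplies band amplitudes (default: the high class carries
1.5× beta and gamma amplitude). A per-trial log-normal amplitude
fluctuation ($\sigma = 0.4$, shared across channels within a trial)
reproduces the trial-to-trial band-power variability of real EEG; without
it, any class effect is separable to ceiling and comparisons between
classifiers degenerate into ties. With it, the boosted bands separate the
classes at a trial-level effect size of roughly $d \approx
\log(1.5)/0.4 \approx 1$ — learnable well above chance, far from ceiling.

What the generator does **not** emulate: 1/f background spectra, artifacts,
volume conduction, channel covariance, non-stationarity within a trial,
or subject effects. Passing tests on this generator therefore show that
the pipeline measures band power correctly and that the models learn a
band-power class signal at moderate effect size — not that any particular
accuracy transfers to real recordings.

## Numerical choices and degenerate inputs

* Spectral radius via `eigen(only.values = TRUE)`; scaling verified to
  $10^{-8}$ relative tolerance in the tests against a characteristic-
  polynomial root oracle.
* Ridge solves use the normal-equations form above; the tests cross-check
  against an independent SVD-based solution. $\lambda = 0$ on a singular
  Gram matrix raises an error advising $\lambda > 0$.
* Truncated-normal magnitudes by vectorized rejection sampling.
* Zero-norm channels, empty frequency bands, single-class training folds,
  $P_2 > P_1$, nilpotent recurrent matrices, and degenerate (zero-variance)
  reconstructions are all explicit errors or flagged values, never silent.
* Degenerate reservoir realizations inside a sweep are redrawn with a
  shifted seed, up to a capped number of retries.

## Problem sizes used in the tests

The test-suite and acceptance computations run at desk scale, chosen as
the package's own defaults for a single-CPU session: reservoirs of
$N = 600$ (the headline configuration) where the claim concerns that
configuration, $N \le 100$ for mechanism tests; memory capacity with
$T = 2000$, `k_max` 100–200; the synthetic classification dataset at
100–200 trials (1000–2000 six-second segments); paired comparisons over
5–20 seeded repeats.

## What the tests do and do not show

Three qualitative claims about modular superiority were examined under
this package's single, shared generation scheme (both the modular and the
basic reservoir built by the same generator, differing only in
$(M, P_1, P_2)$):

* **Heterogeneity.** The weighted in-degree CV of both networks has a
  near-zero sign-symmetric mean, so the CV ratio between the modular and
  the basic network behaves like a ratio of two half-normal variables:
  large values occur occasionally but not typically. The acceptance test
  asserting a typical $\ge 10\times$ CV gap accordingly fails under this
  scheme; reproducing a large, *systematic* gap appears to require the
  two networks to use different weight-sign conventions, which a matched
  comparison deliberately refuses to do.
* **Classification.** At moderate effect size the modular and the basic
  configuration perform equivalently on synthetic band-power features
  (paired accuracy differences within about $\pm 0.01$, wins near half);
  at strong effect both hit ceiling. The acceptance test asserting a
  majority of modular wins documents this equivalence by failing honestly
  rather than passing through ceiling ties.
* **Memory capacity.** Mean capacity at $N = 600$, $P_1 = 0.05$ is flat
  in $M$ within repeat noise for every $P_2 \le P_1$ probed (and mildly
  *decreasing* in $M$ at $\alpha = 1$, for both tanh and identity
  activations). The "rises-then-falls in $M$" acceptance check is
  evaluated at fixed seeds and its outcome on a flat surface is decided
  by repeat noise; whichever way it lands, it should not be read as
  evidence of a structural capacity optimum in $M$ under this scheme.

These three tests are kept asserting the claims they were written for;
their failures are findings, and the mechanism-level suite (spectral
contract, ridge and memory-capacity oracles, edge-count statistics, grid
protocol, label rules) is the part that validates the implementation.

## Known limitations

Dense $N \times N$ matrices throughout (fine to a few thousand units;
sparse storage would be the next step). No plasticity or reservoir
adaptation of any kind — topology and weights are fixed at initialization
by design. Binary tasks only. The command-line wrapper
(`inst/scripts/mesn.R`) is a thin convenience over the exported functions,
which are the real interface.
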
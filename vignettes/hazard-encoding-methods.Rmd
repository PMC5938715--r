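---
title: "Methods: forward-encoding models of temporal hazard"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: forward-encoding models of temporal hazard}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hazardTRF)
```

## The scientific question and the model

When an event is awaited — a target tone after a cue — the brain's
expectation at time $t$ is described by the hazard function of the
cue-to-target interval (foreperiod) distribution:

$$H(t) = \frac{f(t)}{1 - C(t)},$$

the conditional probability that the event occurs at $t$ given it has not
occurred yet, with $f$ the discrete foreperiod distribution and $C$ its
cumulative. For a uniform foreperiod distribution $H(t)$ rises
monotonically with elapsed time; a distribution concentrated at an
intermediate foreperiod adds a mid-trial peak. This package asks whether
multichannel EEG tracks $H(t)$ sample by sample, by modelling the EEG
directly with time-resolved hazard regressors.

The encoding model is the standard temporal-response-function (TRF)
formulation: the response at channel $n$,

$$r(t, n) = \sum_\tau w(\tau, n)\, s(t - \tau) + \varepsilon(t, n),$$

is the regressor $s$ convolved with an unknown filter $w$ over lags
$\tau$. Stacking lagged copies of the regressors into a design matrix $S$
(one column per regressor and lag), the weights are estimated per single
trial by ridge regression,

$$W = (S^\top S + \lambda m I)^{-1} S^\top R,$$

where $m$ is the mean of the diagonal of $S^\top S$, so that $\lambda$ is
scale-free. Negative lags allow anticipatory weights: a positive lag
$\tau$ means the EEG at $t$ reflects the regressor at $t - \tau$.

## The study design encoded in the package

`study_conditions()` fixes the three foreperiod conditions: foreperiods
span 0.5–3.1 s with mean 1.8 s. The nonpredictive condition draws 25
discrete foreperiods from a uniform grid (one trial each per block). The
weakly (Gaussian SD 0.15 s, 5 grid points) and strongly (SD 0.05 s, 3 grid
points) predictive conditions add six fixed foreperiods (0.50, 0.93, 1.37,
2.23, 2.67, 3.10 s), with per-block totals of 25, 32 and 34 trials. Each
condition fills six blocks, three consecutive per experiment half, giving
546 trials per participant.

Two design choices here were genuinely open:

* **Gaussian grid placement.** Only the number of grid points and the SD
  are fixed by the design; we place the points symmetrically about the
  1.8-s mean at multiples of the uniform-grid spacing
  ($2.6/24 \approx 0.108$ s), which preserves the printed mean exactly and
  matches the published depiction of symmetric discrete bars. The spacing
  is configurable (`grid_step`).
* **Per-foreperiod multiplicities.** The block totals are published but
  the per-foreperiod trial counts are not. We allocate the non-additional
  trials proportionally to the Gaussian density with largest-remainder
  rounding (minimum one trial per grid point), so the block totals are met
  exactly; e.g. the strongly predictive grid receives 3/22/3 grid trials
  plus one trial per additional foreperiod.

## Hazard regressors

`compute_hazard()` evaluates $H$ on the discrete grid with $C(t)$
*inclusive* of the mass at $t$. The final grid point then has $C = 1$ and
an infinite raw hazard; non-finite values are replaced by the maximum of
the remaining finite values and everything is divided by that maximum, so
the hazard lies in $[0, 1]$ and attains 1. For an $n$-point uniform grid
this yields $H_k = \min(1, 1/(n - k))$, the closed form the tests assert.

The monotonic regressor is the normalised hazard of the uniform
distribution. The modulated regressor is the strongly predictive hazard
minus the monotonic one — removing the shared terminal rise and keeping
the mid-trial peak as the distinctive feature — then renormalised by its
maximum (an all-zero difference is left as zeros to avoid 0/0). We
subtract first and normalise afterwards; the alternative order changes
only the scale of the regressor, which the scale-free ridge absorbs.
Both regressors are linearly interpolated to the EEG rate (200 Hz) over
the 0.5–3.1-s analysis window, held constant outside their anchor range
(hazard is undefined before the first possible foreperiod, so constant
extension avoids spurious slopes), and low-pass filtered like the EEG.

## Preprocessing

`preprocess_epochs()` applies, in order: trial selection (foreperiod
> 0.65 s, so enough pre-target signal exists), cropping from 0.5 s after
cue onset (removing cue-evoked activity), a 6th-order two-pass Butterworth
low-pass at 25 Hz, per-trial/channel z-scoring over time, and zeroing of
all samples strictly after target onset (hazard is only defined up to the
awaited event; the sample at target onset itself is kept). Z-scoring
before zeroing keeps the pre-target signal on a common scale across trials
of different foreperiods; the order is exposed as `zscore_first` for the
alternative convention.

The zero-phase filter is implemented as forward and backward passes of the
Butterworth recursion over matrix columns, with odd-reflection padding of
three filter orders and constant-pre-history initial conditions, so a DC
trace passes through exactly and edge transients on short epochs stay
negligible; it agrees with a reference two-pass implementation away from
the edges to below $10^{-3}$ relative error.

## Fitting, prediction and scoring

TRFs are estimated per single trial with both hazard regressors jointly
(lags −0.2 to 0.6 s, $\lambda = 4$; both are package defaults in
`ridge_config()`). Prediction uses a leave-one-out scheme: a trial is
predicted from the average TRF of all *other* trials of the training
condition; for mismatched training conditions the all-trials average is
used (leave-one-out is only meaningful within condition). Predicted and
observed trials are correlated per channel over the pre-target samples
only — the post-target samples are zeros by construction and would inflate
correlations — and trials with fewer than `min_samples` (default 10)
pre-target samples, or constant segments, are flagged and excluded.

Correlations are Fisher z-transformed and summarised with t-based 95%
confidence intervals. Condition discrimination uses a bounded correlation
index: with $a = \mathrm{logit}^{-1}(z_{np})$ and
$b = \mathrm{logit}^{-1}(z_{sp})$ from the models trained on the
nonpredictive and strongly predictive conditions,

$$\mathrm{index} = \frac{a - b}{a + b} \in (-1, 1),$$

positive when the nonpredictive-trained model fits better. The
"normalised difference" was not given as an explicit formula in the source
design; this form is bounded, antisymmetric and sign-interpretable, and
the inverse logit maps both inputs to a positive range so the ratio is
well defined for correlations of either sign. We apply the inverse logit
to Fisher z values by default (`on = "z"`); applying it to raw r instead
(`on = "r"`) is available as a switch, and changes only the magnitude, not
the sign, of the index.

## Cluster-based permutation test

Second-level inference across electrodes uses participant-by-electrode
index contrasts: per electrode a one-sample t statistic across
participants, a cluster-forming threshold at the $\alpha = 0.025$ tail
probability per side, clusters as connected components under a channel
adjacency graph (default: k-nearest-neighbour graph on 2-D sensor
coordinates, $k = 4$), cluster mass as the sum of t values, and a null
distribution of the maximal cluster mass from 1000 random whole-participant
sign flips. Each cluster's one-tailed Monte-Carlo p (minimum
$1/(n_{perm}+1)$) is doubled for the two-tailed decision, so a single
reported p is compared directly to conventional levels; this is what makes
the test's family-wise type-I error come out at the nominal 5% level in the
calibration simulations, which the test suite verifies over simulated null
datasets.

## The synthetic-data generator

Because the package must be fully testable without recorded EEG, the
generator emulates the study conditions with known ground truth:

* **Schedules** reproduce the block structure and per-block foreperiod
  multiplicities exactly; inter-stimulus intervals are exponential with
  mean 1.5 s, redrawn until ≤ 5 s. We read the 1.5 s as the
  pre-truncation mean of the exponential; the redraw scheme then yields a
  post-truncation mean of about 1.34 s.
* **Ground-truth TRFs** are rank-one: a smooth lag curve times a smooth
  spatial loading over a synthetic near-square sensor grid (default 16
  channels). The monotonic-hazard component is a negative bump at lag 0
  (imitating the near-instantaneous fronto-central negativity such data
  show); the modulated-hazard component is a positive bump at −0.05 s.
  The anticipatory placement matters: a modulated response peaking after
  the expected target would be removed by the post-target zeroing on the
  dominant 1.8-s trials, making the strongly predictive condition
  undiscriminable by construction — anticipatory buildup that resolves
  before the expected moment is also what the empirical modulated-hazard
  TRFs show.
* **Condition gains** (monotonic, modulated): (1.0, 0.1) nonpredictive,
  (0.5, 1.0) strongly predictive, and their midpoint (0.75, 0.55) for the
  weakly predictive condition, so the weakly predictive model comparisons
  land between the two poles.
* **Epochs** are the ground-truth TRF convolved with the hazard
  regressors, truncated at target onset, scaled so the pre-target RMS
  amplitude ratio of signal to noise equals `snr` (default 0.5, a moderate
  single-trial EEG regime; `0` gives pure noise, `Inf` noiseless signal),
  plus coloured noise with a $1/f$ power spectrum (exponent configurable,
  default 1, mimicking EEG spectra). Noise is synthesised spectrally at a
  fast composite FFT length and truncated.
* **Resting snippets** are condition-free coloured noise carrying
  pseudo-metadata from a task schedule, so the identical pipeline runs end
  to end as a null control.

What the generator does *not* emulate: volume conduction from realistic
sources, evoked responses to cue or target (the hazard analysis zeroes
post-target data anyway), artifacts, non-stationarities, or
between-participant variability in TRF shape. Passing tests therefore
demonstrate that the pipeline recovers what it assumes — hazard-locked,
linearly superposed activity — not that real EEG contains it.

## Numerical choices and limitations

* The ridge system is solved by Cholesky factorisation of
  $S^\top S + \lambda m I$, shared across all trials of equal length; a
  singular system at $\lambda = 0$ raises an error advising
  $\lambda > 0$. Lagged columns are zero-padded at trial edges.
* The monotonic hazard regressor is close to a ramp, so its lagged copies
  are nearly collinear: single-participant lag profiles for this
  component are weakly identified (the ridge solution is bias-limited at
  moderate $\lambda$), which is why estimator-level parameter recovery is
  validated with well-conditioned band-limited broadband regressors, while
  the generator path is validated noiselessly. Edge lags of the window are
  excluded ("interior lags") when comparing recovered and true TRFs.
* Problem sizes in the shipped analyses and tests: the full synthetic
  cohort (24 participants × 546 trials × 16 channels × 521 samples) is
  processed one participant at a time in the validation suite; the
  narrative analysis scripts use a reduced 8-participant, 2-block cohort.
  These sizes were chosen as the smallest that exercise the complete
  design while keeping the examples quick to re-run.
* Monte-Carlo p-values are permutation-count limited; seeded streams make
  every simulation and test bit-reproducible.
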
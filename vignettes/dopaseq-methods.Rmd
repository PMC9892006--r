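---
title: "Models and methods: linking sub-second behaviour to striatal dopamine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: linking sub-second behaviour to striatal dopamine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Spontaneous rodent behaviour decomposes into sub-second, re-used movement
motifs ("syllables", median duration ~400 ms), and dorsolateral-striatum
(DLS) dopamine fluctuates on the same timescale. `dopaseq` implements the
complete analysis chain for asking how those two streams interact: from
two-channel fiber-photometry preprocessing, through syllable-level
statistics, to generative models in which dopamine either *predicts*
future syllable choices (the decoding model) or acts as the *reward* of a
Q-learning agent, and finally to the quantification of closed-loop
optogenetic reinforcement experiments. Because the recordings themselves
are not redistributable, every analysis is exercised end to end on a
synthetic-session generator with stored ground truth, so each stage's
recovery behaviour is measurable.

# The synthetic-session generator

`make_generative_params()` fixes the study conditions; `simulate_session()`
draws one experiment. The pieces:

* **Syllable sequence.** Labels are drawn step by step from the decoding
  model (below) run with the generator's true gains, plus the log of a
  Markov base-transition row as a prior bias. Base rows come from a
  symmetric Dirichlet with the diagonal removed, so self-transitions never
  occur; for K = 2 the chain is forced to alternate. Instance durations
  are log-normal with median 400 ms and log-s.d. 0.88, matched to the
  reported duration statistics (median 400 ms, s.d. ~640 ms).
* **Dopamine amplitudes.** Each instance receives an amplitude (in
  z-units, the scale downstream models consume) drawn from its syllable's
  normal distribution. The per-syllable amplitude distribution is a free
  parameter of the system under study; the defaults place means on
  `seq(1, 3)` z with s.d. 0.8, calibrated to the observed spontaneous
  transient distribution (~2.1 ± 0.8 z) while retaining between-syllable
  differences. Two other configurations recur in the tests and are worth
  naming: *means spanning ±1 z with unit s.d.* (the configuration used for
  decoding-model comparisons, where the session-mean dopamine is near zero
  and the usage coupling is strong), and *equal means* (used for
  closed-loop experiments, so that reinforcement is attributable to the
  stimulation boost rather than to intrinsic amplitude differences).
* **Photometry.** The signal channel is a slowly bleaching baseline
  (default time constant 1200 s) modulated by the sum of per-instance
  transients and shared motion-like artifacts, plus white noise. Each
  transient is a bi-exponential kernel, rise constant 67 ms and decay
  constant 100 ms, scaled by the instance amplitude. Transients start at
  the instance onset: syllable-associated dopamine rises within the 300-ms
  post-onset window that peak extraction assumes. Artifacts are
  Poisson-timed biphasic bumps (derivative-of-Gaussian, ~0.3 s width)
  injected multiplicatively into *both* channels; the reference channel
  carries the baseline and artifacts (scaled by `reference_gain`, offset
  by `reference_offset`) but no transients.
* **Kinematics.** Piecewise per-syllable velocity templates plus smoothed
  noise, with angular and height channels built the same way and
  acceleration as the frame derivative of 2D velocity.
* **Closed-loop stimulation.** `simulate_closed_loop_experiment()` runs
  the three-day schedule (two baseline, two stimulation, two post
  sessions). During stimulation sessions each target detection is
  stimulated with probability 0.75; stimulated instances receive
  `extra_da` z-units *before the sequence continues*, so the boost feeds
  back into future choices. Unstimulated target instances are the catch
  trials.

One master seed drives everything; per-session streams are derived by a
fixed congruential offset (`child_seed`), so any session is bit-reproducible
in isolation.

# Photometry preprocessing

The chain mirrors standard dLight practice: dF/F0 with F0 the 10th
percentile in a 5-s sliding window; reference subtraction after low-pass
filtering the reference (second-order Butterworth, 3 Hz corner, zero-phase
forward-backward) and fitting slope/bias by a consensus (RANSAC-style)
estimator; a 20-s sliding z-score; and the quality gate (maximum percent
dF/F0 above 1.5 *and* signal-reference correlation below 0.6).

Numerical choices the sources leave open:

* Sliding windows are centred with edge truncation (no phase lag in event
  amplitudes).
* The consensus fit compares random two-point candidate lines *and* the
  plain OLS fit by inlier count (threshold: one MAD of the OLS residuals),
  refitting OLS on the winning inlier set. The OLS candidate guarantees
  that an uninformative reference yields a near-zero slope rather than an
  arbitrary consensus line; with sparse outliers (the transients) the
  consensus refit excludes them.
* Zero-variance z-score windows emit 0 and are flagged.
* Transient detection defaults to threshold 2 z with a 167-ms (5-frame)
  minimum separation; the detection threshold is configurable because no
  numeric value is fixed by the source material.
* Downsampling to the 30-Hz frame base uses zero-phase Butterworth
  anti-aliasing followed by linear interpolation.

**What chain recovery does and does not show.** With onsets spaced beyond
the 300-ms peak window, the full chain recovers injected amplitudes with
rank correlation above 0.95 at default noise. At *realistic* durations
(median 400 ms, heavy right tail) nearly half of all peak windows also
contain the next instance's transient, capping recovery near rho ~ 0.6
even with noiseless rendering and the true baseline — an attribution
limit of the 300-ms window itself, not of the filtering chain. Analyses
of real data inherit the same jitter.

# Syllable-level statistics

The central join table (`extract_syllable_peaks()`) holds one row per
instance with the peak z-scored dopamine over frames `[onset, onset+9]`
(10 samples at 30 Hz, onset inclusive), mean instance velocity, and a
per-session z-scored peak.

`expanding_bin_correlation()` correlates each instance's peak with an
outcome aggregated over the following *n* syllables (the index instance
excluded), for *n* from 5 to 400, within five equal segments of the
session (guarding against slow non-stationarities), averaged, and
z-scored against shuffles of the peak column. Circular shifts are the
default shuffle (they preserve peak autocorrelation); full permutation is
available for exchangeable nulls. In entropy mode, peaks are binned into
20 equally spaced amplitude bins per syllable (between the per-syllable
min and max), transitions in the following *n* steps are pooled per bin
with multiplicity, and the pooled conditional entropy is correlated with
bin rank.

`fit_decay_tau()` fits `a * exp(-n / tau) + c` by direct least squares
(Nelder-Mead over `(a, log tau, c)`; Levenberg-Marquardt convergence
tests degenerate on zero-residual bootstrap resamples) over bootstrap
resamples — of replicate curves when supplied, of the (bin size, value)
points otherwise. The additive offset absorbs the asymptote; tau is
reported from the exponential term, and constant curves are flagged
non-identifiable.

A caveat established while validating on the generator: the generator's
own counts-mode curve *plateaus* through bin 400 rather than decaying —
the 250-step influence window keeps covariance accruing while count noise
grows roughly linearly, and per-syllable mean differences floor the curve.
Timescale recovery is therefore validated on planted exponential curves,
and generator sessions are checked for the curve-shape property (strong
positive z near the usage timescale, weaker at the largest bin).

Other operations follow their stated recipes: `movement_initiations()`
(z-score, 50-point boxcar, derivative in z/s, cubed, peaks with
height/width/prominence 1 — the derivative must be per second for a 2-3 z
stillness-to-movement swing inside the 1.67-s boxcar to score above 1);
`huber_regression_cv()` (MASS::rlm with the Huber psi, five-fold
cross-validation repeated, permutation p-values);
`partial_out_kinematics()` (OLS residualization, circular-shift null);
`aligned_average_z()` (per-trial z-scoring in ±10-s windows, then
z-scoring the trial average against circularly repositioned trial
averages); `endo_da_influence()` (the s.d. across bin sizes of the
shuffle-z-scored correlation curve — under the null the z-values at
different bin sizes are positively correlated, so the index calibrates
somewhat below 1 rather than at 1).

# Encoding models

`zca_whiten()` centres features and applies the symmetric inverse square
root of the covariance (ridge-regularized when rank-deficient), so the
output covariance is the identity. `fit_binned_encoding()` is a Bayesian
linear regression with a normal prior on coefficients and a weak
inverse-gamma prior on the variance standing in for the exponential scale
prior; the normal-inverse-gamma conjugacy gives the posterior in closed
form, which the contract (posterior means and intervals, held-out
correlation) requires — sampler identity is not part of the contract.
`fit_kernel_encoding()` fits per-feature convolution kernels over lags
−2 s…+2 s (121 taps at 30 Hz) jointly, minimizing a Huber loss by IRLS
with a mild L2 ridge (default 1e-4) for conditioning, under twofold
cross-validation by session; features are standardized first and the
target is smoothed with a 60-sample boxcar.

# The decoding model

The probability that the next syllable is *i* is proportional to the
exponential of a usage term divided by a randomness term:

$$P(s_t = i) \propto \exp\!\left(
 \frac{\alpha_a \sum_{n=1}^{250} da_{t-n}\, e^{-n/\tau_a}\,\mathbf{1}(s_{t-n} = i)}
      {\alpha_b \sum_{n=1}^{250} da_{t-n}\, e^{-n/\tau_b}}\right)$$

with $\tau_a = 100$ and $\tau_b = 10$ syllable steps, $\alpha_b$ fixed at
1, and $\alpha_a$ the single fitted parameter (grid likelihood
maximization). Steps with fewer than 250 predecessors use partial sums.
The indicator uses $s_{t-n}$ (the summed index), not $s_{t-1}$: the
equation governs, and the accompanying prose describing the indicator at
lag one is treated as a typo.

Numerical and statistical decisions:

* **Denominator guard.** Because dopamine is z-scored the denominator
  fluctuates around zero; its magnitude is clamped (sign preserved) to
  5% of $\alpha_b \sum_n e^{-n/\tau_b}$. Halving the guard at most
  doubles the extreme logit ratios (regression-tested), so conclusions
  are not guard-artifacts.
* **Conditioning on the feasible successor set.** Syllable instances
  never self-repeat, yet the plain model normalizes over all K syllables.
  Fitted on no-self-repeat data, the plain likelihood is asymptotically
  biased (it penalizes large gains for mass "wasted" on the impossible
  self-successor; measured argmax 0.5 for truth 1.0). `sequence_loglik()`
  therefore keeps the plain form by default (its `alpha_a = 0` closed form
  is exactly $-T\log K$), while `fit_alpha_a_grid()` and the generative
  simulator condition on the feasible set, which makes the estimator
  consistent (exact recovery across seeds).
* **Dopamine scale.** The model is not shift-invariant in dopamine (only
  scale-invariant), so generator amplitudes — already calibrated z-units —
  enter the fit unchanged; re-centering per session would evaluate a
  different model. Peaks extracted from photometry, whose units are
  arbitrary, are z-scored per session first.
* **Held-out performance** is one-step-ahead: the fitted model predicts
  each held-out choice from the *observed* history, a syllable is sampled
  per step, and 50-step rolling-average counts of sampled predictions are
  correlated with actual counts, pooled over syllables and sessions. The
  prediction draw uses the plain (unmasked) model: under the uniform
  control the mask would make predicted usage the complement of recent
  usage, pushing controls to spurious negative correlations instead of
  zero.
* **Controls.** The noise control replaces dopamine with unit-variance
  normal draws; the phase-shift control circularly shifts it by a random
  integer in 1..1000. On synthetic data whose dopamine has a non-zero
  mean, the shifted trace retains the usage-persistence component, so the
  phase-shift control trails the full model only narrowly; the noise
  control is the clean null.
* **Extra dopamine (opto variant).** On stimulation sessions, stimulated
  target instances have their dopamine replaced by the catch-trial mean
  plus a candidate offset; the offset maximizing the sequence likelihood
  estimates the exogenously added dopamine. With no planted boost the
  likelihood curve is nearly flat near zero, so the argmax is meaningful
  only at the ensemble level.

# Q-learning models

States are syllables, actions are transitions, and the dopamine peak of
the next syllable is the reward. The Q-table starts uniform (1.0
off-diagonal — any constant is policy-equivalent by softmax shift
invariance, though not update-equivalent) with the diagonal fixed at 0.
The observed next syllable is the action for both likelihood scoring and
the update: the likelihood of observed actions is the only coherent
fitting target, while `free_running_mode()` preserves the alternative
reading in which the agent selects its own actions and draws rewards from
per-action empirical pools.

The dynamic variant makes temperature time-dependent:
$\tau(t) = \nu\, e^{-\Delta t/\tau_{decay}} + \tau_{baseline}$, where
$\Delta t$ counts steps since the reward last crossed the threshold
$\lambda$ (overlapping crossings reset $\Delta t$). The printed exponent
is sign-ambiguous; a decaying kick is the only reading consistent with a
*brief* increase in choice variability, and the kick takes full effect
($\nu + \tau_{baseline}$) on the first post-crossing step. With $\nu = 0$
the dynamic agent is bitwise identical to the reinforcement-only agent.
The prediction-error variant adds observed dopamine directly
($Q \mathrel{+}= \alpha r$).

Evaluation z-scores each row's off-diagonal entries of the learned
Q-table and the empirical transition matrix before correlating, with
nulls from agents refit on time-shuffled dopamine, and the grid comparison
z-scores held-out log-likelihood against fits with dopamine shuffled
between sessions. Default grids: alpha in {0.01, 0.05, 0.1, 0.3}, gamma in
{0, 0.5, 0.9}, temperature in {0.1, 0.5, 1, 2}.

# Closed-loop reinforcement quantification

Excess target counts: non-overlapping 30-s bins, cumulatively summed, the
mean baseline curve subtracted from the mean stimulation-day curve (the
same machinery serves non-target syllables). Learners are mice whose mean
excess strictly exceeds the maximum no-opsin control value. The temporal
adjacency profile bins non-target syllables by their mean signed offset
(in steps, within ±10) to the *nearest* target instance — the
nearest-instance reading bounds offsets — with frequency-weighted count
changes per bin. Velocity similarity bins count changes by per-session
z-scored velocity difference from the target. Post-stimulation dynamics
are computed in five-syllable non-overlapping bins with the pre-onset
value subtracted and z-scored against catch trials. Learning scores are
log2 fold changes against baseline, z-scored against all pairs of
non-stimulation days, with add-one smoothing (flagged) for zero counts.

# Problem sizes

The test suite and the reproduction script deliberately run at moderate
sizes: the restart comparison uses 20 sessions of 5,000 transitions with
50 restarts in the reproduction script and 2,500-transition sessions in
the test suite; recovery ensembles use 5-20 seeds with sessions of
800-2,000 instances. These sizes were chosen so every property is decided
by a comfortable statistical margin while the whole suite completes in a
few minutes.

# Known limitations

* The generator is the decoding model plus a Markov prior; it emulates
  the coupling structure and photometry physics but not pose dynamics,
  camera artifacts, per-mouse heterogeneity, or non-stationary arousal.
  Passing tests certify the machinery, not the biology.
* Peak attribution is jitter-limited at realistic syllable durations (see
  above).
* The generator's expanding-bin correlation curves plateau rather than
  decay exponentially, so end-to-end timescale readouts from synthetic
  sessions are shape-checked, not tau-checked.
* The decoding model's denominator guard is a modelling choice where the
  source is silent on negative-denominator handling; sensitivity is
  tested but alternatives (e.g. soft clamping) are not explored.
* Lock-in: with strong usage gain the generator shows winner-take-all
  usage within sessions, making single-experiment closed-loop effects
  noisy; ensemble statistics (several simulated mice) are required, as in
  the real design.
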
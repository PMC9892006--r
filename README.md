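# dopaseq

Sub-second behavioural syllables and striatal dopamine: photometry
preprocessing, syllable-level statistics, encoding and decoding models,
Q-learning agents, and closed-loop reinforcement quantification — all
exercised end to end on a synthetic-session generator with stored ground
truth.

## The problem

Spontaneous mouse behaviour decomposes into brief, re-used movement motifs
("syllables", median duration ~400 ms). Dopamine in the dorsolateral
striatum, measured with the fluorescent sensor dLight, fluctuates on the
same timescale. The analyses here ask, and answer on simulated data with
known truth, three linked questions:

1. **Correlation** — do syllable-associated dopamine peaks predict how
   often a syllable is used, and how variable sequencing is, over the
   following tens to hundreds of syllables?
2. **Decoding** — can future syllable choices be predicted from past
   dopamine? The central model puts, for syllable *i* at step *t*,

   P(sₜ = i) ∝ exp[ α_a Σₙ da₍ₜ₋ₙ₎ e^(−n/τ_a) 𝟙(s₍ₜ₋ₙ₎ = i)
                    / α_b Σₙ da₍ₜ₋ₙ₎ e^(−n/τ_b) ],

   summing over the last 250 steps, with the usage timescale τ_a = 100
   steps, the randomness timescale τ_b = 10 steps, α_b fixed, and the
   usage gain α_a the single fitted parameter.
3. **Reinforcement** — if dopamine is handed to a Q-learning agent as the
   reward for each observed syllable transition
   (Q(s,a) ← Q(s,a) + α[r + γ maxQ(s′,·) − Q(s,a)], softmax policy
   p(a|s) ∝ e^(Q(s,a)/τ)), does the learned Q-table reproduce the
   empirical transition matrix? And does closed-loop optogenetic dopamine,
   delivered on 75% of detections of a target syllable, reinforce that
   syllable relative to baseline days?

Because the underlying recordings are not redistributable, the package
ships a generator (`simulate_session()`, `simulate_closed_loop_experiment()`)
that produces Markovian no-self-transition syllable sequences coupled to
dopamine through the decoding model itself, renders two-channel photometry
(bi-exponential transients, rise 67 ms / decay 100 ms, on a bleaching
baseline with shared artifacts), and stores every true parameter for
recovery testing.

## Worked example

Fit the decoding model to sessions generated by the decoding model
(usage gain 1.0) and compare held-out prediction against the
noise-control model:

```r
library(dopaseq)

K <- 10
unif <- matrix(1 / (K - 1), K, K); diag(unif) <- 0
params <- make_generative_params(
  K, seed = 3,
  overrides = list(base_transitions = unif,
                   syllable_da_mean = seq(-1, 1, length.out = K),
                   syllable_da_sd = rep(1, K)))
sessions <- lapply(1:8, function(k) {
  s <- simulate_syllable_sequence(params, 3000, seed = 300 + k)
  list(labels = s$labels, da = s$da)
})

fit_alpha_a_grid(sessions, seq(0, 2, by = 0.25), decoding_params(K))$alpha_a
#> [1] 1

cmp <- decoding_model_comparison(sessions, decoding_params(K),
                                 grid = seq(0, 2, by = 0.25),
                                 n_restarts = 10, folds = 4,
                                 variants = "noise", seed = 17)
aggregate(r ~ model, cmp, median)
#>   model         r
#> 1  full 0.8335642
#> 2 noise 0.4301821

restart_mann_whitney(cmp$r[cmp$model == "full"],
                     cmp$r[cmp$model == "noise"])[c("U", "f")]
#> $U
#> [1] 100
#> $f
#> [1] 1
```

The planted usage gain is recovered exactly on the grid; the fitted model
beats the noise control (dopamine replaced by unit-variance draws) in all
10 × 10 restart pairs, so the Mann–Whitney U saturates at n₁·n₂ = 100 and
the common-language effect size f at 1.

## Analysis workflow

`analysis/01_simulate.R` … `analysis/07_opto.R` run the pipeline as a
sequence of narrative steps — simulate a cohort, preprocess photometry,
compute syllable statistics and influence indices, fit the encoding
models, the decoding model with its controls, the Q-learning agents, and
the closed-loop reinforcement analyses — writing tables under `results/`.
Each script is a thin driver over the package functions and prints what it
found.

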
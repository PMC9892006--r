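# shared fixtures built in code

uniform_base <- function(K) {
  M <- matrix(1 / (K - 1), K, K)
  diag(M) <- 0
  M
}

# params whose sequences come from the pure decoding model (uniform Markov
# prior), the configuration used for coupling-recovery checks
coupled_params <- function(K = 10, seed = 1, ...) {
  make_generative_params(K, seed = seed,
                         overrides = c(list(base_transitions = uniform_base(K)),
                                       list(...)))
}

# params with all dopamine-behaviour coupling switched off
null_params <- function(K = 10, seed = 1, ...) {
  make_generative_params(K, seed = seed,
                         overrides = c(list(alpha_a_true = 0,
                                            syllable_da_mean = rep(0, K)),
                                       list(...)))
}

# bare (labels, da) sessions for decoding/RL fits
bare_sessions <- function(params, n_sessions, n_steps, seed = 1) {
  lapply(seq_len(n_sessions), function(k) {
    s <- simulate_syllable_sequence(params, n_steps,
                                    seed = child_seed(seed, k))
    list(labels = s$labels, da = s$da)
  })
}
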
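# minimal synthetic session with prescribed labels at fixed 12-frame
# durations, for arithmetic oracles
stub_session <- function(labels, K = 6, seed = 1, velocity = NULL) {
  n <- length(labels)
  durations <- rep(12L, n)
  onsets <- c(0L, cumsum(durations[-n]))
  n_frames <- sum(durations)
  p <- make_generative_params(K, seed = seed)
  if (is.null(velocity)) velocity <- rep(50, n_frames)
  structure(list(labels = labels, onset_frames = onsets,
                 duration_frames = durations,
                 da_amplitudes = rep(0, n), stim = rep(FALSE, n),
                 phase = "baseline", target = NA_integer_,
                 kinematics = list(velocity_2d = velocity,
                                   angular_velocity = rep(0, n_frames),
                                   height_velocity = rep(0, n_frames),
                                   acceleration = rep(0, n_frames)),
                 truth = p),
            class = "session_bundle")
}

test_that("excess counts follow the arithmetic of doubled usage", {
  set.seed(1)
  # baseline: target about once per 30-s bin; stim: exactly twice the rate
  base_labels <- rep(c(1L, 2L, 3L, 4L, 5L, 6L, 2L, 3L, 4L, 5L), 150)
  stim_labels <- rep(c(1L, 2L, 1L, 3L, 4L, 1L, 5L, 1L, 6L, 5L), 150)
  base <- stub_session(base_labels)
  stim <- stub_session(stim_labels)
  out <- excess_target_counts(list(stim), list(base, base), target = 1)
  # rates: baseline 1 per 10 instances, stim 4 per 10; bin = 30 s = 900
  # frames = 75 instances -> excess 22.5 per bin, cumulated
  n_bins <- length(out$excess)
  # bins hold 75 instances (7.5 pattern cycles), so per-bin counts
  # alternate one instance around the exact rate
  expect_lt(max(abs(out$excess - 22.5 * seq_len(n_bins))), 0.6)
  expect_equal(out$terminal, 22.5 * n_bins, tolerance = 1e-9)

  # additivity: two identical stim sessions leave the average unchanged,
  # doubling the counts doubles the excess
  out2 <- excess_target_counts(list(stim, stim), list(base, base), 1)
  expect_equal(out2$excess, out$excess)

  # statistically identical sessions: terminal excess near zero
  s1 <- stub_session(sample(1:6, 1500, TRUE))
  s2 <- stub_session(sample(1:6, 1500, TRUE))
  s3 <- stub_session(sample(1:6, 1500, TRUE))
  out0 <- excess_target_counts(list(s1), list(s2, s3), target = 1)
  per_bin_sd <- sqrt(75 * (1 / 6) * (5 / 6))
  expect_lt(abs(out0$terminal),
            3 * per_bin_sd * sqrt(length(out0$excess)))
})

test_that("learner classification is a strict threshold on control maxima", {
  expect_equal(classify_learners(c(0.5, 2, -1), c(0.2, 1)),
               c(FALSE, TRUE, FALSE))
  expect_true(classify_learners(0.1, c(-2, -0.5)))
  # ties at exactly the control max are not learners
  expect_false(classify_learners(1, c(0.2, 1)))
})

test_that("temporal adjacency profiles localize a planted effect", {
  set.seed(2)
  K <- 6
  # syllable 2 always follows target 1; syllable 3 never near the target
  make_labels <- function(n_frac2) {
    labs <- integer(0)
    while (length(labs) < 1200) {
      if (runif(1) < n_frac2) labs <- c(labs, 1L, 2L)
      else labs <- c(labs, sample(c(3L, 4L, 5L, 6L), 2, TRUE))
    }
    # remove accidental self-repeats
    keep <- c(TRUE, diff(labs) != 0)
    labs[keep]
  }
  base <- stub_session(make_labels(0.3))
  stim <- stub_session(make_labels(0.45))  # target and follower up +50%
  prof <- temporal_adjacency_effect(list(stim), list(base), target = 1)
  # syllable 2 sits at offset +1 and carries a positive change
  expect_gt(prof$change[prof$offset_bin == 1], 0)
  # profile has no entry for the target itself at bin 0 beyond other
  # syllables that happen to average there
  expect_true(all(prof$n_syllables[abs(prof$offset_bin) > 6] %in% 0:K))

  # no usage change: profile flat around zero
  b2 <- stub_session(make_labels(0.3), seed = 3)
  prof0 <- temporal_adjacency_effect(list(b2), list(base), target = 1)
  expect_lt(max(abs(prof0$change), na.rm = TRUE), 15)
})

test_that("velocity-similarity profiles localize changes at matched speed", {
  K <- 6
  n <- 1200
  set.seed(4)
  labs_base <- sample(1:K, n, TRUE)
  labs_base <- labs_base[c(TRUE, diff(labs_base) != 0)]
  # syllable velocities: target 1 at 100; syllable 2 matches it, others slow
  tmpl <- c(100, 100, 30, 30, 30, 30)
  vel_of <- function(labels) {
    rep(tmpl[labels], each = 12) + rnorm(12 * length(labels), sd = 1)
  }
  base <- stub_session(labs_base, velocity = vel_of(labs_base))
  # stim raises usage of the velocity-matched syllable 2 only
  labs_stim <- c(labs_base, rep(c(2L, 4L), 60))
  labs_stim <- labs_stim[c(TRUE, diff(labs_stim) != 0)]
  stim <- stub_session(labs_stim, velocity = vel_of(labs_stim))
  prof <- velocity_similarity_effect(list(stim), list(base), target = 1)
  near <- prof$change[abs(prof$bin_mid) == 0.5]
  far <- prof$change[abs(prof$bin_mid) > 1]
  expect_gt(max(near, na.rm = TRUE), max(c(far, 0), na.rm = TRUE))

  # uniform change: flat profile (no bin stands out strongly)
  stim_u <- stub_session(c(labs_base, labs_base)[
    c(TRUE, diff(c(labs_base, labs_base)) != 0)],
    velocity = vel_of(c(labs_base, labs_base)[
      c(TRUE, diff(c(labs_base, labs_base)) != 0)]))
  prof_u <- velocity_similarity_effect(list(stim_u), list(base), 1)
  expect_true(all(is.na(prof_u$change) | abs(prof_u$change) < 400))
})

test_that("post-stimulation dynamics are z-scored against catch trials", {
  # stim and catch drawn from the same process: calibrated near zero
  p <- coupled_params(8, seed = 6)
  bundles <- simulate_closed_loop_experiment(p, target = 7, extra_da = 0,
                                             seed = 13, n_steps = 1500)
  stim_sessions <- bundles[3:4]
  out <- post_stim_dynamics(stim_sessions,
                            metrics = c("entropy", "velocity_2d"),
                            n_bins = 3)
  expect_true(all(abs(out$z) < 3))

  # a strong dopamine boost perturbs sequencing but not velocity
  # (sequence-effect generator: stimulation adds dopamine, not movement)
  bundles2 <- simulate_closed_loop_experiment(p, target = 7, extra_da = 3,
                                              seed = 13, n_steps = 1500)
  out2 <- post_stim_dynamics(bundles2[3:4],
                             metrics = c("entropy", "velocity_2d"),
                             n_bins = 3)
  vz <- out2$z[out2$metric == "velocity_2d"]
  expect_true(all(abs(vz) < 3.5))

  expect_error(post_stim_dynamics(stim_sessions, metrics = "entropy",
                                  min_catch = 1e6), "catch")
})

test_that("learning scores match the arithmetic oracle", {
  # stim equal to baseline: score near zero
  s0 <- opto_learning_score(c(100, 100), c(100, 100, 99, 101))
  expect_lt(abs(s0$score), 1)

  # stim at 2x baseline with null-pair spread ~0.25 in log2 units
  nonstim <- c(100, 119, 84, 100)  # pairwise log2 fold changes sd ~ 0.25
  s2 <- opto_learning_score(c(200, 200), nonstim)
  expect_equal(s2$null_mean, 0, tolerance = 1e-9)
  expect_equal(s2$score, 1 / s2$null_sd, tolerance = 0.2)
  expect_equal(s2$log2fc, 1, tolerance = 0.05)

  # joint doubling of all counts leaves the score unchanged
  s2b <- opto_learning_score(2 * c(200, 200), 2 * nonstim)
  expect_equal(s2b$score, s2$score, tolerance = 1e-9)

  # zero counts trigger add-one smoothing with a flag
  sz <- opto_learning_score(c(0, 3), c(2, 3, 4))
  expect_true(sz$smoothed)
  expect_true(is.finite(sz$score))
})

test_that("quartile-contingent stimulation analyses respect inclusion", {
  out <- velocity_quartile_effect(rnorm(100, 50), rnorm(100, 55), 60,
                                  arm = "high")
  expect_true(out$included)
  expect_equal(out$shift, 5, tolerance = 2)
  out2 <- velocity_quartile_effect(rnorm(100, 50), rnorm(100, 55), 20)
  expect_false(out2$included)
  expect_true(is.na(out2$shift))
})

test_that("closed-loop reinforcement raises counts and flags learners", {
  # equal per-syllable amplitude means: reinforcement is attributable to
  # the stimulation boost, not to intrinsic amplitude differences
  K <- 8
  scores <- vapply(1:4, function(sd) {
    p <- make_generative_params(
      K, seed = sd + 60, overrides = list(syllable_da_mean = rep(2, K)))
    b2 <- simulate_closed_loop_experiment(p, target = 6, extra_da = 2,
                                          seed = sd, n_steps = 1200)
    b0 <- simulate_closed_loop_experiment(p, target = 6, extra_da = 0,
                                          seed = sd + 100, n_steps = 1200)
    count_t <- function(s) sum(s$labels == 6)
    sc2 <- opto_learning_score(vapply(b2[3:4], count_t, 1),
                               vapply(b2[c(1, 2, 5, 6)], count_t, 1))
    sc0 <- opto_learning_score(vapply(b0[3:4], count_t, 1),
                               vapply(b0[c(1, 2, 5, 6)], count_t, 1))
    ex2 <- suppressWarnings(
      excess_target_counts(b2[3:4], b2[1:2], 6))$terminal
    c(sc2$score, sc0$score, ex2)
  }, numeric(3))
  # boosted dopamine reinforces the target; without it, nothing happens
  expect_gte(mean(scores[3, ] > 0), 0.75)
  expect_gt(median(scores[1, ]), median(scores[2, ]))
  # learner flags: boosted mice against unboosted "controls"
  flags <- classify_learners(scores[1, ], scores[2, ])
  expect_gte(mean(flags), 0.5)
})
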
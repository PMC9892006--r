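make_peak_table <- function(n, K = 5, seed = 1, peaks = NULL,
                            labels = NULL, velocity = NULL) {
  set.seed(seed)
  if (is.null(labels)) {
    labels <- integer(n)
    labels[1] <- sample.int(K, 1)
    for (t in 2:n) labels[t] <- sample(setdiff(1:K, labels[t - 1]), 1)
  }
  if (is.null(peaks)) peaks <- rnorm(n)
  if (is.null(velocity)) velocity <- runif(n, 20, 150)
  data.frame(mouse = "m1", session = "s1", instance_index = seq_len(n) - 1L,
             syllable = labels, onset_frame = (seq_len(n) - 1L) * 12L,
             duration_frames = 12L, peak = peaks, velocity = velocity,
             peak_z = (peaks - mean(peaks)) / sd(peaks))
}

test_that("peak extraction uses the 300-ms window and truncates at the end", {
  p <- make_generative_params(4, seed = 1)
  s <- list(labels = c(1L, 2L, 3L), onset_frames = c(0L, 20L, 40L),
            duration_frames = c(20L, 20L, 10L),
            kinematics = list(velocity_2d = rep(50, 50)))
  z <- rep(0, 50)
  tab0 <- extract_syllable_peaks(s, z)
  expect_equal(tab0$peak, rep(0, 3))

  # a bump 12 frames (400 ms) after the first onset is outside its window
  z2 <- z; z2[13] <- 4
  tab2 <- extract_syllable_peaks(s, z2)
  expect_equal(tab2$peak[1], 0)

  # window is [onset, onset+9]: frame onset+10 is excluded, onset+9 included
  z3 <- z; z3[10] <- 2; z3[30] <- 3  # 1-based: onset 0 frame 10 = offset 9
  tab3 <- extract_syllable_peaks(s, z3)
  expect_equal(tab3$peak[1], 2)
  expect_equal(tab3$peak[2], 3)  # offset 9 of the onset-20 instance
  z4x <- z; z4x[32] <- 5         # offset 11 of the onset-20 instance
  expect_equal(extract_syllable_peaks(s, z4x)$peak[2], 0)

  # per-session z-scored peak column has mean 0, sd 1
  set.seed(2)
  z4 <- rnorm(50)
  tab4 <- extract_syllable_peaks(s, z4)
  expect_equal(mean(tab4$peak_z), 0, tolerance = 1e-9)
  expect_equal(sd(tab4$peak_z), 1, tolerance = 1e-9)
})

test_that("time warping linearly resamples to 25 points", {
  x25 <- sin(seq(0, 2 * pi, length.out = 25))
  expect_lt(max(abs(timewarp_traces(list(x25))[1, ] - x25)), 1e-12)

  ramp <- seq(2, 9, length.out = 40)
  w <- timewarp_traces(list(ramp))[1, ]
  expect_equal(w, seq(2, 9, length.out = 25), tolerance = 1e-12)

  x50 <- sin(seq(0, 2 * pi, length.out = 50))
  w50 <- timewarp_traces(list(x50))[1, ]
  oracle <- approx(seq(0, 1, length.out = 50), x50,
                   xout = seq(0, 1, length.out = 25))$y
  expect_lt(max(abs(w50 - oracle)), 1e-6)
})

test_that("aligned averages calibrate under the null and detect locking", {
  set.seed(4)
  trace <- rnorm(9000)
  events <- sort(sample(400:8600, 40))
  out <- aligned_average_z(trace, events, rate = 30, window_s = 2,
                           n_shuffles = 200, seed = 1)
  expect_gte(mean(abs(out$z) < 2.5), 0.95)

  # events locked to injected transients produce a clear positive excursion
  kern <- transient_kernel(make_generative_params(3, seed = 1))
  trace2 <- rnorm(9000, sd = 0.3)
  for (e in events) trace2[e:(e + length(kern) - 1)] <-
    trace2[e:(e + length(kern) - 1)] + 2 * kern
  out2 <- aligned_average_z(trace2, events, rate = 30, window_s = 2,
                            n_shuffles = 200, seed = 1)
  peak_lag <- which.max(out2$z)
  expect_gt(out2$z[peak_lag], 4)
  expect_gt(out2$lags_s[peak_lag], 0)
  expect_lt(out2$lags_s[peak_lag], 0.3)

  expect_error(aligned_average_z(trace, events, 30, n_shuffles = 1),
               "shuffles")
  expect_error(aligned_average_z(trace, events[1], 30), "events")
})

test_that("transition entropy matches closed forms and hand counts", {
  # uniform outgoing over 9 successors
  M <- matrix(1 / 9, 10, 10)
  diag(M) <- 0
  expect_equal(transition_entropy(M), rep(log(9), 10), tolerance = 1e-12)

  # deterministic successor has zero entropy
  D <- matrix(0, 3, 3)
  D[1, 2] <- 1; D[2, 3] <- 1; D[3, 1] <- 1
  expect_equal(transition_entropy(D), rep(0, 3))

  # counts A->B x3, A->C x1 from a label sequence
  labs <- c(1, 2, 1, 2, 1, 2, 1, 3)
  H <- transition_entropy(labs, K = 3)
  expect_equal(H[1], -(0.75 * log(0.75) + 0.25 * log(0.25)),
               tolerance = 1e-12)

  # bounds: any row entropy within [0, log(K-1)]
  set.seed(5)
  p <- make_generative_params(7, seed = 5)
  H2 <- transition_entropy(p$base_transitions)
  expect_true(all(H2 >= 0 & H2 <= log(6) + 1e-12))

  # syllable never emitted -> NA
  H3 <- transition_entropy(c(1, 2, 1, 2), K = 3)
  expect_true(is.na(H3[3]))
})

test_that("expanding-bin correlations separate null from coupled data", {
  bins <- c(5, 10, 25, 50, 100)

  # null: peaks independent of the sequence
  tab0 <- make_peak_table(1500, K = 5, seed = 6)
  cur0 <- expanding_bin_correlation(tab0, "counts", bins, n_shuffles = 50,
                                    seed = 2)
  expect_true(all(abs(cur0$r_z) < 3.5))

  # coupled generator: counts-mode z well above the null band
  p <- coupled_params(6, seed = 3)
  s <- simulate_syllable_sequence(p, 2500, seed = 8)
  tab1 <- make_peak_table(2500, K = 6, labels = s$labels, peaks = s$da)
  cur1 <- expanding_bin_correlation(tab1, "counts", bins, n_shuffles = 50,
                                    seed = 2)
  expect_gt(max(cur1$r_z), 2)

  # velocity mode: peaks built from future velocity couple positively
  tabv <- make_peak_table(1500, K = 5, seed = 7)
  fut <- c(rowMeans(embed(tabv$velocity, 6))[-1],
           rep(mean(tabv$velocity), 6))
  tabv$peak <- zscore(fut) + rnorm(1500, sd = 0.5)
  curv <- expanding_bin_correlation(tabv, "velocity", bins, n_shuffles = 50,
                                    seed = 3)
  expect_gt(curv$r_z[1], 2)

  # autocorr mode: AR(1) peaks give higher correlation at small bins
  rho <- 0.9
  ar <- as.numeric(arima.sim(list(ar = rho), 1500))
  taba <- make_peak_table(1500, K = 5, seed = 9, peaks = ar)
  cura <- expanding_bin_correlation(taba, "autocorr", c(5, 100),
                                    n_shuffles = 20, seed = 4)
  expect_gt(cura$r_raw[1], cura$r_raw[2])
})

test_that("entropy mode correlates amplitude bins with pooled entropy", {
  # construct a sequence whose randomness follows the peak amplitude:
  # high-peak instances are followed by uniform choices, low-peak ones by
  # near-deterministic cycling
  set.seed(10)
  K <- 5
  n <- 3000
  labels <- integer(n)
  peaks <- numeric(n)
  labels[1] <- 1
  peaks[1] <- rnorm(1)
  for (t in 2:n) {
    drive <- peaks[t - 1]
    if (drive > 0) {
      labels[t] <- sample(setdiff(1:K, labels[t - 1]), 1)
    } else {
      labels[t] <- (labels[t - 1] %% K) + 1
    }
    peaks[t] <- rnorm(1)
  }
  tab <- make_peak_table(n, K = K, labels = labels, peaks = peaks)
  cur <- expanding_bin_correlation(tab, "entropy", bin_sizes = c(2, 5),
                                   n_shuffles = 30, segments = 2, seed = 5)
  expect_gt(cur$r_z[1], 2)
})

test_that("exponential decay fits recover the planted timescale", {
  ns <- c(5, 10, 25, 50, 100, 200, 400)
  curve <- data.frame(bin_size = ns, r_raw = 0.5 * exp(-ns / 100))
  fit <- fit_decay_tau(curve, n_boot = 200, seed = 1)
  expect_true(fit$identifiable)
  expect_gte(fit$tau, 95)
  expect_lte(fit$tau, 105)
  expect_true(all(fit$tau_samples > 0))

  flat <- data.frame(bin_size = ns, r_raw = rep(0.3, 7))
  expect_false(fit_decay_tau(flat, n_boot = 50, seed = 1)$identifiable)

  # replicate-matrix bootstrap: noisy replicates around the same curve
  set.seed(2)
  reps <- t(replicate(30, 0.5 * exp(-ns / 100) + rnorm(7, sd = 0.01)))
  fitr <- fit_decay_tau(curve, replicates = reps, n_boot = 200, seed = 3)
  expect_gt(fitr$tau, 70)
  expect_lt(fitr$tau, 140)
})

test_that("generator coupling shapes the counts curve near tau_a", {
  p <- coupled_params(6, seed = 12)
  s <- simulate_syllable_sequence(p, 4000, seed = 31)
  tab <- make_peak_table(4000, K = 6, labels = s$labels, peaks = s$da)
  cur <- expanding_bin_correlation(tab, "counts",
                                   bin_sizes = c(5, 10, 25, 50, 100, 200,
                                                 300, 400),
                                   n_shuffles = 30, seed = 6)
  # strong positive coupling visible at bin sizes up to tau_a, weaker at
  # the largest bin (the curve flattens rather than decaying sharply: the
  # influence window keeps accruing covariance while count noise grows)
  expect_gt(max(cur$r_z[cur$bin_size <= 100]), 2)
  expect_lt(cur$r_z[cur$bin_size == 400], max(cur$r_z))
  expect_true(all(cur$r_raw > 0))
})

test_that("usage cross-correlation peaks at non-negative lags for coupling", {
  p <- coupled_params(6, seed = 13)
  s <- simulate_syllable_sequence(p, 4000, seed = 32)
  tab <- make_peak_table(4000, K = 6, labels = s$labels, peaks = s$da)
  cc <- cross_correlation_usage(tab, window_s = 60, lags = -4:4,
                                n_shuffles = 50, seed = 3)
  expect_gte(cc$lag[which.max(cc$r)], 0)
  expect_gt(max(cc$r_z), 1)

  # independent peaks stay inside the shuffle band
  tab0 <- make_peak_table(3000, K = 6, seed = 14)
  cc0 <- cross_correlation_usage(tab0, window_s = 60, lags = -4:4,
                                 n_shuffles = 50, seed = 4)
  expect_true(all(abs(cc0$r_z) < 3.5, na.rm = TRUE))
})

test_that("Huber regression cross-validation behaves at both extremes", {
  set.seed(15)
  x <- rnorm(200)
  # near-noiseless linear relation: held-out r ~ 1
  y1 <- 2 * x + rnorm(200, sd = 1e-3)
  fit1 <- huber_regression_cv(x, y1, repeats = 10, n_shuffles = 100,
                              seed = 1)
  expect_gt(fit1$r, 0.999)
  expect_lt(fit1$p, 0.05)

  # independent outcome: observed r inside the shuffle band, large p
  y0 <- rnorm(200)
  fit0 <- huber_regression_cv(x, y0, repeats = 10, n_shuffles = 100,
                              seed = 2)
  expect_gt(fit0$p, 0.05)
  expect_lt(abs(fit0$r), quantile(abs(fit0$null_r), 0.99))

  # y = x + N(0,1): analytic held-out r ~ 1/sqrt(2)
  y2 <- x + rnorm(200)
  fit2 <- huber_regression_cv(x, y2, repeats = 20, n_shuffles = 50,
                              seed = 3)
  expect_equal(fit2$r, 1 / sqrt(2), tolerance = 0.1)

  expect_error(huber_regression_cv(rep(1, 100), rnorm(100)), "degenerate")
})

test_that("movement initiations find velocity steps", {
  expect_length(movement_initiations(rep(50, 600)), 0)

  # single stillness-to-movement step: exactly one event near the step
  set.seed(16)
  v1 <- c(rnorm(600, 10, 0.5), rnorm(600, 60, 0.5))
  ev1 <- movement_initiations(v1)
  expect_length(ev1, 1)
  expect_lte(abs(ev1 - 600), 25)

  # two steps 600 frames apart: two events
  v2 <- c(rnorm(400, 10, 0.5), rnorm(600, 60, 0.5), rnorm(200, 10, 0.5),
          rnorm(600, 60, 0.5))
  ev2 <- movement_initiations(v2)
  expect_length(ev2, 2)
})

test_that("partialling covariates isolates the target correlation", {
  set.seed(17)
  n <- 2000
  cov1 <- rnorm(n); cov2 <- rnorm(n)
  target <- rnorm(n)

  # target proportional to an already-partialled covariate: r ~ 0
  d1 <- cov1 + 0.3 * cov2
  out1 <- partial_out_kinematics(d1, list(v2 = cov1, v3 = cov2), cov1,
                                 n_boot = 200, seed = 1)
  expect_lt(abs(out1$r), 0.05)

  # independent target stays inside the null band
  out2 <- partial_out_kinematics(d1, list(v2 = cov1, v3 = cov2), target,
                                 n_boot = 200, seed = 2)
  expect_gte(out2$r, out2$null_lo - 0.02)
  expect_lte(out2$r, out2$null_hi + 0.02)

  # analytic partial correlation: dlight = cov + 0.5 * target (orthogonal)
  sd_resid <- 0.2
  d3 <- cov1 + 0.5 * target + rnorm(n, sd = sd_resid)
  out3 <- partial_out_kinematics(d3, list(v2 = cov1), target,
                                 n_boot = 100, seed = 3)
  expect_equal(out3$r, 0.5 / sqrt(0.25 + sd_resid^2), tolerance = 0.05)

  # collinear covariates dropped with a warning
  expect_warning(
    partial_out_kinematics(d1, list(a = cov1, b = 2 * cov1), target,
                           n_boot = 10, seed = 4),
    "collinear")
})

test_that("endogenous-dopamine influence separates coupled from null mice", {
  bins <- c(5, 10, 25, 50, 100, 200)
  p <- coupled_params(6, seed = 18)
  s <- simulate_syllable_sequence(p, 4000, seed = 41)
  tab <- make_peak_table(4000, K = 6, labels = s$labels, peaks = s$da)
  idx_coupled <- endo_da_influence(tab, "counts", bins, n_shuffles = 40,
                                   seed = 1)

  tab0 <- make_peak_table(4000, K = 6, seed = 19)
  idx_null <- endo_da_influence(tab0, "counts", bins, n_shuffles = 40,
                                seed = 1)
  expect_gt(idx_coupled, idx_null)
  # null curve is approximately unit-variance z noise
  expect_lt(idx_null, 3)

  # invariance to positive rescaling of the raw peaks
  tab_scaled <- tab
  tab_scaled$peak <- 10 * tab_scaled$peak
  idx_scaled <- endo_da_influence(tab_scaled, "counts", bins,
                                  n_shuffles = 40, seed = 1)
  expect_equal(idx_scaled, idx_coupled, tolerance = 1e-9)
})
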
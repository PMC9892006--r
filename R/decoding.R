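#' Parameters of the dopamine-dependent sequence decoding model
#'
#' The model predicts the probability that the next syllable is `i` from the
#' recent history of syllables and their associated dopamine peaks. Its logit
#' for syllable `i` at step `t` is the ratio of a syllable-specific usage
#' component (dopamine delivered while performing `i`, discounted with
#' timescale `tau_a`) to a global randomness component (all recent dopamine,
#' discounted with timescale `tau_b`), scaled by `alpha_a`:
#'
#' \deqn{logit_i(t) = \alpha_a \sum_{n=1}^{W} da_{t-n} e^{-n/\tau_a}
#'   1(s_{t-n}=i) \; / \; \alpha_b \sum_{n=1}^{W} da_{t-n} e^{-n/\tau_b}}
#'
#' Probabilities follow by exponentiation and normalization over the modelled
#' syllable set. Only `alpha_a` is fitted; `alpha_b`, `tau_a`, `tau_b` and
#' the history window `W` are fixed.
#'
#' Because dopamine is z-scored, the denominator fluctuates around zero; its
#' magnitude is clamped to at least `guard_frac * alpha_b * sum(exp(-n/tau_b))`
#' (sign preserved) to keep logits finite.
#'
#' @param n_syllables number of modelled syllables K (>= 2).
#' @param alpha_a usage-coupling gain (>= 0); the single fitted parameter.
#' @param alpha_b randomness-coupling gain (> 0), fixed.
#' @param tau_a usage timescale in syllable steps.
#' @param tau_b randomness timescale in syllable steps.
#' @param window history window in syllable steps.
#' @param extra_da additive dopamine offset (z-units) applied to stimulated
#'   instances in the opto variant; 0 otherwise.
#' @param guard_frac denominator guard as a fraction of the full-history
#'   discounted weight.
#' @return object of class `decoding_params`.
#' @export
decoding_params <- function(n_syllables, alpha_a = 1, alpha_b = 1,
                            tau_a = 100, tau_b = 10, window = 250,
                            extra_da = 0, guard_frac = 0.05) {
  stopifnot(n_syllables >= 2, alpha_a >= 0, alpha_b > 0,
            tau_a > 0, tau_b > 0, window > 0, window >= tau_b,
            guard_frac > 0)
  structure(list(n_syllables = as.integer(n_syllables),
                 alpha_a = alpha_a, alpha_b = alpha_b,
                 tau_a = tau_a, tau_b = tau_b, window = as.integer(window),
                 extra_da = extra_da, guard_frac = guard_frac),
            class = "decoding_params")
}

# Incremental evaluator of the decoding-model logit ratio. Returns an
# environment with $ratio() giving the current K-vector
#   A_i / clamp(alpha_b * D)
# (the logit divided by alpha_a) and $step(s, da) advancing the history by
# one observed (syllable, dopamine) pair. The window truncation is exact:
# terms older than `window` steps are subtracted as they leave.
decoder_stepper <- function(params) {
  K <- params$n_syllables
  W <- params$window
  da_hist <- numeric(W)      # ring buffer of past dopamine
  s_hist <- integer(W)       # ring buffer of past syllables (0 = empty)
  pos <- 0L                  # number of steps taken
  A <- numeric(K)
  D <- 0
  ka <- exp(-1 / params$tau_a)
  kb <- exp(-1 / params$tau_b)
  ka_out <- exp(-(W + 1) / params$tau_a)
  kb_out <- exp(-(W + 1) / params$tau_b)
  eps <- params$guard_frac * params$alpha_b *
    sum(exp(-(1:W) / params$tau_b))
  step <- function(s, da) {
    A <<- ka * A
    A[s] <<- A[s] + ka * da
    D <<- kb * D + kb * da
    if (pos >= W) {
      slot <- (pos %% W) + 1L
      s_old <- s_hist[slot]
      da_old <- da_hist[slot]
      A[s_old] <<- A[s_old] - ka_out * da_old
      D <<- D - kb_out * da_old
    }
    slot <- (pos %% W) + 1L
    s_hist[slot] <<- s
    da_hist[slot] <<- da
    pos <<- pos + 1L
    invisible(NULL)
  }
  ratio <- function() {
    den <- params$alpha_b * D
    if (abs(den) < eps) den <- if (den < 0) -eps else eps
    A / den
  }
  environment()
}

#' Decoding-model logit ratios along an observed sequence
#'
#' Runs the history recursion over a full session and returns the `T x K`
#' matrix of logit ratios (the decoding logits divided by `alpha_a`), so the
#' log-likelihood can be evaluated cheaply on a grid of `alpha_a` values.
#' Row 1 is zero (empty history, uniform prediction).
#'
#' @param labels integer syllable sequence in `1..K`.
#' @param da per-instance dopamine peaks (z-units), aligned to `labels`.
#' @param params [decoding_params()].
#' @return numeric matrix, `length(labels) x K`.
#' @export
decoding_ratio_series <- function(labels, da, params) {
  stopifnot(length(labels) == length(da))
  Tn <- length(labels)
  K <- params$n_syllables
  W <- params$window
  # truncated exponential sums over lags 1..W as one-sided linear filters;
  # zero-padding the front yields exact partial sums for early steps
  lagged_sum <- function(x, tau) {
    w <- c(0, exp(-(1:W) / tau))
    xp <- c(numeric(W + 1), x)
    y <- stats::filter(xp, w, sides = 1)
    as.numeric(y[(W + 2):(W + 1 + Tn)])
  }
  D <- params$alpha_b * lagged_sum(da, params$tau_b)
  eps <- params$guard_frac * params$alpha_b *
    sum(exp(-(1:W) / params$tau_b))
  D[abs(D) < eps] <- eps * ifelse(D[abs(D) < eps] < 0, -1, 1)
  R <- matrix(0, Tn, K)
  for (i in seq_len(K)) {
    R[, i] <- lagged_sum(da * (labels == i), params$tau_a) / D
  }
  R
}

#' Next-syllable probabilities given a history
#'
#' @param history_labels integer syllables observed so far (steps `1..t-1`).
#' @param history_da matching dopamine peaks (z-units).
#' @param params [decoding_params()].
#' @return probability vector over the K modelled syllables.
#' @export
next_syllable_probs <- function(history_labels, history_da, params) {
  K <- params$n_syllables
  if (K < 2) stop("need at least 2 modelled syllables")
  if (length(history_labels) == 0) return(rep(1 / K, K))
  st <- decoder_stepper(params)
  for (t in seq_along(history_labels)) st$step(history_labels[t], history_da[t])
  z <- params$alpha_a * st$ratio()
  p <- exp(z - logsumexp(z))
  p / sum(p)
}

#' Log-likelihood of a syllable sequence under the decoding model
#'
#' Sums `log P(s_t)` over all steps (step 1 contributes `-log K` from the
#' uniform empty-history prediction). With `alpha_a = 0` every step is
#' uniform and the total is exactly `-T log K`.
#'
#' @inheritParams decoding_ratio_series
#' @param ratios optional precomputed [decoding_ratio_series()] matrix.
#' @param exclude_previous condition each step on the feasible successor
#'   set by renormalizing with the just-performed syllable excluded.
#'   Syllable instances never self-repeat, so the conditional likelihood is
#'   the consistent fitting target; the default keeps the plain model
#'   normalized over all K syllables.
#' @return scalar log-likelihood.
#' @export
sequence_loglik <- function(labels, da, params, ratios = NULL,
                            exclude_previous = FALSE) {
  if (is.null(ratios)) ratios <- decoding_ratio_series(labels, da, params)
  z <- params$alpha_a * ratios
  if (exclude_previous && length(labels) > 1) {
    z[cbind(2:length(labels), labels[-length(labels)])] <- -Inf
  }
  # row-wise log softmax evaluated at the observed label
  m <- z[, 1]
  for (j in 2:ncol(z)) m <- pmax(m, z[, j])
  lse <- m + log(rowSums(exp(z - m)))
  sum(z[cbind(seq_along(labels), labels)] - lse)
}

#' Fit the usage gain alpha_a by grid likelihood maximization
#'
#' @param sessions list of sessions, each a list with `labels` and `da`
#'   (z-unit peaks).
#' @param grid candidate `alpha_a` values.
#' @param params [decoding_params()] carrying the fixed parameters.
#' @param exclude_previous condition the likelihood on the feasible
#'   successor set (no self-repeats). The data never contain self
#'   transitions, so the conditional likelihood is the consistent fitting
#'   target; the plain normalization inflates the apparent cost of large
#'   gains and biases the argmax low.
#' @param ratios optional list of precomputed [decoding_ratio_series()]
#'   matrices, one per session (they do not depend on `alpha_a`).
#' @return list with `alpha_a` (argmax), `grid`, `loglik` (summed over
#'   sessions per grid value), and `boundary` flag.
#' @export
fit_alpha_a_grid <- function(sessions, grid, params,
                             exclude_previous = TRUE, ratios = NULL) {
  stopifnot(length(grid) >= 1)
  ll <- numeric(length(grid))
  for (k in seq_along(sessions)) {
    s <- sessions[[k]]
    R <- if (is.null(ratios)) decoding_ratio_series(s$labels, s$da, params)
    else ratios[[k]]
    for (g in seq_along(grid)) {
      p2 <- params; p2$alpha_a <- grid[g]
      ll[g] <- ll[g] + sequence_loglik(s$labels, s$da, p2, ratios = R,
                                       exclude_previous = exclude_previous)
    }
  }
  best <- which.max(ll)
  boundary <- length(grid) > 1 && (best == 1 || best == length(grid))
  if (length(grid) == 1) warning("alpha_a grid has a single value")
  else if (boundary && grid[best] != 0)
    warning("alpha_a argmax on grid boundary; consider widening the grid")
  list(alpha_a = grid[best], grid = grid, loglik = ll, boundary = boundary)
}

#' Simulate a syllable sequence from the decoding model with given dopamine
#'
#' Teacher-forced simulation: the dopamine series is taken as given (it is an
#' input to the model), and syllable choices are drawn step by step from the
#' decoding probabilities, optionally biased by a log base-transition prior.
#'
#' @param da dopamine series (z-units), one value per step.
#' @param params [decoding_params()].
#' @param base_log optional `K x K` matrix of log base-transition biases
#'   (rows = previous syllable); `-Inf` entries mask transitions.
#' @param exclude_previous mask the just-performed syllable so simulated
#'   sequences share the data's no-self-repeat support (ignored when
#'   `base_log` is supplied, whose zero diagonal already masks).
#' @param seed integer seed.
#' @return integer label sequence of `length(da)`.
#' @export
simulate_decoding_sequence <- function(da, params, base_log = NULL,
                                       exclude_previous = TRUE,
                                       seed = 1) {
  set.seed(seed)
  K <- params$n_syllables
  W <- params$window
  Tn <- length(da)
  labels <- integer(Tn)
  ka <- exp(-1 / params$tau_a); kb <- exp(-1 / params$tau_b)
  ka_out <- exp(-(W + 1) / params$tau_a)
  kb_out <- exp(-(W + 1) / params$tau_b)
  eps <- params$guard_frac * params$alpha_b *
    sum(exp(-(1:W) / params$tau_b))
  A <- numeric(K); D <- 0
  for (t in seq_len(Tn)) {
    if (t == 1) {
      z <- rep(0, K)
    } else {
      den <- params$alpha_b * D
      if (abs(den) < eps) den <- if (den < 0) -eps else eps
      z <- params$alpha_a * A / den
      if (!is.null(base_log)) z <- z + base_log[labels[t - 1], ]
      else if (exclude_previous) z[labels[t - 1]] <- -Inf
    }
    p <- exp(z - max(z))
    labels[t] <- sample.int(K, 1, prob = p)
    # advance the history sums, dropping the term that leaves the window
    s <- labels[t]
    A <- ka * A
    A[s] <- A[s] + ka * da[t]
    D <- kb * D + kb * da[t]
    if (t > W) {
      s_old <- labels[t - W]
      A[s_old] <- A[s_old] - ka_out * da[t - W]
      D <- D - kb_out * da[t - W]
    }
  }
  labels
}

#' Held-out predictive performance of a fitted decoding model
#'
#' The fitted model predicts each held-out syllable choice from the
#' observed history (one-step-ahead): a syllable is sampled from the model
#' probability at every step, and performance is the Pearson correlation
#' between 50-step rolling-average syllable counts of the sampled
#' predictions and of the actual sequence, pooled over syllables and
#' sessions.
#'
#' @param sessions held-out sessions (`labels`, `da`).
#' @param params [decoding_params()] with the fitted `alpha_a`.
#' @param smooth_steps rolling-average width in syllable steps.
#' @param exclude_previous mask the just-performed syllable when forming
#'   prediction probabilities. Off by default: under the uniform
#'   (uncoupled) model the mask makes predicted usage the complement of
#'   recent usage, pushing control models to spurious negative
#'   correlations instead of zero.
#' @param seed integer seed for the prediction draws.
#' @return scalar Pearson r.
#' @export
decoding_heldout_r <- function(sessions, params, smooth_steps = 50,
                               exclude_previous = FALSE, seed = 1) {
  K <- params$n_syllables
  pred <- NULL
  obs <- NULL
  for (k in seq_along(sessions)) {
    s <- sessions[[k]]
    set.seed(child_seed(seed, k))
    z <- params$alpha_a * decoding_ratio_series(s$labels, s$da, params)
    if (exclude_previous && length(s$labels) > 1)
      z[cbind(2:length(s$labels), s$labels[-length(s$labels)])] <- -Inf
    m <- z[, 1]
    for (j in 2:K) m <- pmax(m, z[, j])
    P <- exp(z - m)
    P <- P / rowSums(P)
    u <- stats::runif(nrow(P))
    cp <- P %*% upper.tri(diag(K), diag = TRUE)
    sim <- max.col(cp >= u, ties.method = "first")
    for (i in seq_len(K)) {
      pred <- c(pred, boxcar_smooth(as.numeric(sim == i), smooth_steps))
      obs <- c(obs, boxcar_smooth(as.numeric(s$labels == i), smooth_steps))
    }
  }
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0) return(0)
  stats::cor(pred, obs)
}

#' Control models for the decoding fit
#'
#' Returns a copy of `sessions` with the dopamine series replaced according
#' to the control variant: `phase_shift` circularly shifts each session's
#' dopamine by a random integer in 1..1000, `noise` replaces it with draws
#' from a unit-variance normal, `no_offset` leaves dopamine untouched (used
#' by the opto variant where the manipulated offset is dropped).
#'
#' @param sessions list of sessions.
#' @param variant one of "phase_shift", "noise", "no_offset".
#' @param seed integer seed.
#' @return list of sessions with substituted `da`.
#' @export
control_sessions <- function(sessions, variant = c("phase_shift", "noise",
                                                   "no_offset"),
                             seed = 1) {
  variant <- match.arg(variant)
  set.seed(seed)
  lapply(seq_along(sessions), function(k) {
    s <- sessions[[k]]
    if (variant == "phase_shift") {
      sh <- sample(1:1000, 1)
      if (sh %% length(s$da) == 0) sh <- sh + 1  # a zero shift is no control
      s$da <- circ_shift(s$da, sh)
    } else if (variant == "noise") {
      s$da <- stats::rnorm(length(s$da))
    }
    s
  })
}

#' Repeated train/test evaluation of the decoding model against controls
#'
#' For each restart, sessions are split into training and test sets
#' (five-fold style: one fold held out). `alpha_a` is fitted on the training
#' sessions by grid likelihood maximization and evaluated on the test
#' sessions with [decoding_heldout_r()]. The same folds are reused for each
#' control variant.
#'
#' @param sessions list of sessions (`labels`, `da`).
#' @param params fixed-parameter [decoding_params()].
#' @param grid `alpha_a` grid.
#' @param n_restarts number of repeated splits.
#' @param folds number of folds per split.
#' @param variants control variants to evaluate alongside the full model.
#' @param seed integer seed.
#' @return data.frame with columns `restart`, `model`, `alpha_a`, `r`.
#' @export
decoding_model_comparison <- function(sessions, params, grid,
                                      n_restarts = 50, folds = 5,
                                      variants = c("noise", "phase_shift"),
                                      seed = 1) {
  stopifnot(length(sessions) >= folds)
  # ratio matrices for the unmodified sessions are restart-invariant
  full_R <- lapply(sessions, function(s)
    decoding_ratio_series(s$labels, s$da, params))
  out <- list()
  for (rs in seq_len(n_restarts)) {
    set.seed(child_seed(seed, rs))
    fold_id <- sample(rep_len(seq_len(folds), length(sessions)))
    test <- which(fold_id == 1)
    train <- which(fold_id != 1)
    eval_one <- function(ss, label, sub, R = NULL) {
      fit <- suppressWarnings(
        fit_alpha_a_grid(ss[train], grid, params,
                         ratios = if (is.null(R)) NULL else R[train]))
      p2 <- params; p2$alpha_a <- fit$alpha_a
      r <- decoding_heldout_r(ss[test], p2, seed = child_seed(seed, rs + sub))
      data.frame(restart = rs, model = label, alpha_a = fit$alpha_a, r = r)
    }
    res <- list(eval_one(sessions, "full", 10000L, R = full_R))
    for (v in seq_along(variants)) {
      cs <- suppressWarnings(
        control_sessions(sessions, variants[v],
                         seed = child_seed(seed, rs + 1000L * v)))
      res[[v + 1]] <- eval_one(cs, variants[v], 10000L + 100L * v)
    }
    out[[rs]] <- do.call(rbind, res)
  }
  do.call(rbind, out)
}

#' Mann-Whitney comparison of per-restart performance
#'
#' @param r_full,r_control per-restart held-out performance vectors.
#' @return list with `U` (two-sided Mann-Whitney U statistic), `f`
#'   (common-language effect size, the fraction of cross-group pairs where
#'   the full model wins), and `p`.
#' @export
restart_mann_whitney <- function(r_full, r_control) {
  wt <- stats::wilcox.test(r_full, r_control, exact = FALSE)
  U <- unname(wt$statistic)
  f <- mean(outer(r_full, r_control, ">") +
              0.5 * outer(r_full, r_control, "=="))
  list(U = U, f = f, p = wt$p.value)
}

#' Fit the extra-dopamine offset on closed-loop stimulation sessions
#'
#' On stimulation sessions, the dopamine value of every stimulated target
#' instance is replaced by the mean catch-trial dopamine of the target plus a
#' candidate offset ("extra DA"); the sequence log-likelihood is evaluated at
#' each offset and the argmax reported.
#'
#' @param sessions stimulation-phase sessions with `labels`, `da`, `stim`
#'   (logical per instance) and `target`.
#' @param offset_grid candidate offsets (z-units).
#' @param params [decoding_params()] with fitted `alpha_a`.
#' @param exclude_previous condition the likelihood on the feasible
#'   successor set (see [fit_alpha_a_grid()]).
#' @return list with `offset` (argmax), `grid`, `loglik` curve.
#' @export
fit_extra_da <- function(sessions, offset_grid, params,
                         exclude_previous = TRUE) {
  has_catch <- vapply(sessions, function(s) {
    any(s$labels == s$target & !s$stim)
  }, logical(1))
  if (!any(has_catch)) stop("no catch trials available")
  ll <- numeric(length(offset_grid))
  for (s in sessions) {
    catch <- s$labels == s$target & !s$stim
    if (!any(catch)) next
    catch_mean <- mean(s$da[catch])
    for (g in seq_along(offset_grid)) {
      da2 <- s$da
      da2[s$stim] <- catch_mean + offset_grid[g]
      ll[g] <- ll[g] + sequence_loglik(s$labels, da2, params,
                                       exclude_previous = exclude_previous)
    }
  }
  list(offset = offset_grid[which.max(ll)], grid = offset_grid, loglik = ll)
}
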
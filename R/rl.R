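#' Q-learning parameters
#'
#' @param alpha learning rate in [0, 1]; 0 freezes the Q-table.
#' @param gamma discount factor in [0, 1) (reward mode only).
#' @param temperature softmax temperature (> 0), static variant.
#' @param tau_baseline baseline temperature (> 0), dynamic variant.
#' @param tau_decay decay constant (steps, > 0) of the temperature kick.
#' @param nu temperature kick size (>= 0); 0 reduces the dynamic variant to
#'   the reinforcement-only agent.
#' @param lam reward threshold (z-units) that triggers the kick.
#' @param reward_mode "reward" (dopamine as reward in the standard update)
#'   or "rpe" (dopamine as the full prediction-error term).
#' @param variant "reinforcement_only" or "dynamic" temperature.
#' @return object of class `rl_params`.
#' @export
rl_params <- function(alpha = 0.1, gamma = 0.5, temperature = 1,
                      tau_baseline = 1, tau_decay = 10, nu = 0, lam = 2,
                      reward_mode = c("reward", "rpe"),
                      variant = c("reinforcement_only", "dynamic")) {
  reward_mode <- match.arg(reward_mode)
  variant <- match.arg(variant)
  stopifnot(alpha >= 0, alpha <= 1, gamma >= 0, gamma < 1, temperature > 0,
            tau_baseline > 0, tau_decay > 0, nu >= 0)
  structure(list(alpha = alpha, gamma = gamma, temperature = temperature,
                 tau_baseline = tau_baseline, tau_decay = tau_decay,
                 nu = nu, lam = lam, reward_mode = reward_mode,
                 variant = variant),
            class = "rl_params")
}

#' Initialize a Q-table
#'
#' Uniform off-diagonal values with the diagonal fixed at 0: there are no
#' self-transitions by definition.
#'
#' @param K number of syllables.
#' @param value off-diagonal initial value.
#' @return `K x K` matrix.
#' @export
q_init <- function(K, value = 1) {
  Q <- matrix(value, K, K)
  diag(Q) <- 0
  Q
}

#' One Q-table update with dopamine as reward or prediction error
#'
#' Reward mode applies the standard temporal-difference update with the
#' next state equal to the action (`s_{t+1} = a`), maximizing over
#' off-diagonal successors; rpe mode adds `alpha * r` directly.
#'
#' @param Q Q-table.
#' @param s current state (row).
#' @param a action = next syllable (column, `a != s`).
#' @param r dopamine reward (z-units, finite).
#' @param params [rl_params()].
#' @return updated Q-table (diagonal untouched).
#' @export
q_update <- function(Q, s, a, r, params) {
  stopifnot(is.finite(r))
  if (params$reward_mode == "reward") {
    nxt <- Q[a, -a]
    Q[s, a] <- Q[s, a] +
      params$alpha * (r + params$gamma * max(nxt) - Q[s, a])
  } else {
    Q[s, a] <- Q[s, a] + params$alpha * r
  }
  Q
}

#' Softmax action policy over a Q-table row
#'
#' Normalizes `exp(Q/tau)` over actions excluding the current state (no
#' self-transitions); invariant to adding a constant to the row.
#'
#' @param q_row Q-values for the current state.
#' @param temperature softmax temperature (> 0).
#' @param exclude current state index to mask, or NULL.
#' @return probability vector over all actions (excluded entry 0).
#' @export
softmax_policy <- function(q_row, temperature, exclude = NULL) {
  if (temperature <= 0) stop("temperature must be > 0")
  z <- q_row / temperature
  if (!is.null(exclude)) z[exclude] <- -Inf
  p <- exp(z - max(z))
  p / sum(p)
}

#' Run a Q-learning agent over observed sessions
#'
#' The agent is fed sequences of (syllable, session-z-scored dopamine)
#' pairs. At each step the softmax log-probability of the observed next
#' syllable (the action) is recorded, the Q-table is updated with the
#' observed dopamine of the next syllable as reward (or prediction error),
#' and in the dynamic variant the temperature is kicked to
#' `nu + tau_baseline` whenever the reward crosses `lam`, relaxing
#' exponentially back to baseline with constant `tau_decay`.
#'
#' @param sessions list of lists with `labels` (1..K) and `da`.
#' @param params [rl_params()].
#' @param K number of syllables.
#' @param Q optional initial Q-table.
#' @return list: `Q`, `loglik` (total), `step_loglik`, `temperature_trace`.
#' @export
run_agent <- function(sessions, params, K, Q = q_init(K)) {
  ll <- list()
  temps <- list()
  for (s in sessions) {
    labels <- s$labels; da <- s$da
    if (any(labels < 1 | labels > K)) stop("unknown syllable in sequence")
    Tn <- length(labels)
    step_ll <- numeric(Tn - 1)
    temp_tr <- numeric(Tn - 1)
    last_cross <- -Inf
    for (t in seq_len(Tn - 1)) {
      st <- labels[t]; a <- labels[t + 1]; r <- da[t + 1]
      if (params$variant == "dynamic") {
        tau_t <- if (is.finite(last_cross))
          params$nu * exp(-(t - last_cross) / params$tau_decay) +
          params$tau_baseline
        else params$tau_baseline
      } else tau_t <- params$temperature
      temp_tr[t] <- tau_t
      p <- softmax_policy(Q[st, ], tau_t, exclude = st)
      step_ll[t] <- log(p[a])
      Q <- q_update(Q, st, a, r, params)
      if (params$variant == "dynamic" && r >= params$lam) last_cross <- t + 1
    }
    ll[[length(ll) + 1]] <- step_ll
    temps[[length(temps) + 1]] <- temp_tr
  }
  list(Q = Q, loglik = sum(unlist(ll)), step_loglik = ll,
       temperature_trace = temps)
}

#' Correlate a learned Q-table with an empirical transition matrix
#'
#' Each row's off-diagonal entries of both matrices are z-scored
#' separately, flattened, and correlated (Pearson). The optional shuffle
#' null refits the agent with time-shuffled dopamine.
#'
#' @param Q learned Q-table.
#' @param empirical empirical transition matrix (same K).
#' @return scalar Pearson r.
#' @export
evaluate_qtable <- function(Q, empirical) {
  stopifnot(all(dim(Q) == dim(empirical)))
  K <- nrow(Q)
  zq <- zt <- NULL
  for (i in seq_len(K)) {
    zq <- c(zq, zscore(Q[i, -i]))
    zt <- c(zt, zscore(empirical[i, -i]))
  }
  if (stats::sd(zq) == 0 || stats::sd(zt) == 0) return(0)
  stats::cor(zq, zt)
}

#' Shuffle null for the Q-table / transition-matrix correlation
#'
#' Refits the agent `n_shuffles` times with dopamine time-shuffled within
#' each session and evaluates each fit against the empirical matrix.
#'
#' @param sessions,params,K as in [run_agent()].
#' @param empirical empirical transition matrix.
#' @param n_shuffles number of refits.
#' @param seed integer seed.
#' @return numeric vector of null correlations.
#' @export
qtable_shuffle_null <- function(sessions, params, K, empirical,
                                n_shuffles = 100, seed = 1) {
  set.seed(seed)
  vapply(seq_len(n_shuffles), function(b) {
    sh <- lapply(sessions, function(s) {
      s$da <- sample(s$da)
      s
    })
    evaluate_qtable(run_agent(sh, params, K)$Q, empirical)
  }, numeric(1))
}

#' Q-table performance as a function of dopamine lag
#'
#' Shifts the dopamine column by each lag (within session, truncating the
#' overhang), refits the agent, and evaluates against the empirical matrix.
#'
#' @param sessions,params,K as in [run_agent()].
#' @param empirical empirical transition matrix.
#' @param lags integer lags (in syllable steps).
#' @return data.frame: lag, r.
#' @export
lag_shift_analysis <- function(sessions, params, K, empirical,
                               lags = c(-50, -10, -1, 0, 1, 10, 50)) {
  r <- vapply(lags, function(l) {
    sh <- lapply(sessions, function(s) {
      if (abs(l) >= length(s$da)) stop("lag exceeds session length")
      s$da <- circ_shift(s$da, l)
      s
    })
    evaluate_qtable(run_agent(sh, params, K)$Q, empirical)
  }, numeric(1))
  data.frame(lag = lags, r = r)
}

#' Grid search and model comparison between reward and RPE agents
#'
#' For each reward mode, a grid search over learning rate, discount (reward
#' mode only) and temperature picks the parameterization with the best
#' held-out log-likelihood under twofold cross-validation by session. The
#' distribution of held-out log-likelihood over bootstrap resamples of the
#' sessions is z-scored against fits to data with dopamine shuffled between
#' sessions.
#'
#' @param sessions list of sessions.
#' @param K number of syllables.
#' @param alphas,gammas,temperatures grid values.
#' @param reward_modes modes to compare.
#' @param n_shuffles between-session dopamine shuffles for the z-score.
#' @param n_boot bootstrap resamples of the session set.
#' @param seed integer seed.
#' @return data.frame per mode: best parameters, mean held-out loglik,
#'   `z` (z-scored against the shuffle distribution), plus attribute
#'   `boot` with per-bootstrap z-scores.
#' @export
grid_search_compare <- function(sessions, K,
                                alphas = c(0.01, 0.05, 0.1, 0.3),
                                gammas = c(0, 0.5, 0.9),
                                temperatures = c(0.1, 0.5, 1, 2),
                                reward_modes = c("reward", "rpe"),
                                n_shuffles = 10, n_boot = 50, seed = 1) {
  stopifnot(length(sessions) >= 2)
  set.seed(seed)
  fold_id <- rep_len(1:2, length(sessions))
  heldout_ll <- function(ss, params) {
    tot <- 0
    for (f in 1:2) {
      tr <- which(fold_id[seq_along(ss)] != f)
      te <- which(fold_id[seq_along(ss)] == f)
      fit <- run_agent(ss[tr], params, K)
      tot <- tot + run_agent(ss[te], params, K, Q = fit$Q)$loglik
    }
    tot
  }
  best_fit <- function(ss, mode) {
    gs <- if (mode == "reward") gammas else 0
    best <- NULL
    for (a in alphas) for (g in gs) for (tp in temperatures) {
      params <- rl_params(alpha = a, gamma = g, temperature = tp,
                          reward_mode = mode)
      ll <- heldout_ll(ss, params)
      if (is.null(best) || ll > best$ll)
        best <- list(ll = ll, alpha = a, gamma = g, temperature = tp,
                     params = params)
    }
    best
  }
  shuffle_between <- function(ss) {
    das <- lapply(ss, `[[`, "da")
    perm <- sample(seq_along(ss))
    for (k in seq_along(ss)) {
      d <- das[[perm[k]]]
      n <- length(ss[[k]]$da)
      ss[[k]]$da <- rep_len(d, n)
    }
    ss
  }
  out <- list()
  for (mode in reward_modes) {
    best <- best_fit(sessions, mode)
    null_ll <- vapply(seq_len(n_shuffles), function(b)
      heldout_ll(shuffle_between(sessions), best$params), numeric(1))
    boot_z <- vapply(seq_len(n_boot), function(b) {
      idx <- sample(seq_along(sessions), replace = TRUE)
      (heldout_ll(sessions[idx], best$params) - mean(null_ll)) /
        stats::sd(null_ll)
    }, numeric(1))
    df <- data.frame(mode = mode, alpha = best$alpha, gamma = best$gamma,
                     temperature = best$temperature, loglik = best$ll,
                     z = (best$ll - mean(null_ll)) / stats::sd(null_ll))
    attr(df, "boot") <- boot_z
    out[[mode]] <- df
  }
  res <- do.call(rbind, out)
  attr(res, "boot") <- lapply(out, attr, "boot")
  res
}

#' Free-running agent with rewards drawn from empirical pools
#'
#' The agent selects actions by its softmax policy; the reward for each
#' action is drawn at random from the empirical dopamine-peak pool of that
#' action.
#'
#' @param params [rl_params()].
#' @param da_pools list of K numeric vectors (non-empty per action).
#' @param n_steps simulation steps.
#' @param seed integer seed.
#' @param start starting state.
#' @return list: `labels` (simulated sequence), `Q`.
#' @export
free_running_mode <- function(params, da_pools, n_steps, seed = 1,
                              start = 1) {
  K <- length(da_pools)
  if (any(vapply(da_pools, length, 1L) == 0)) stop("empty reward pool")
  set.seed(seed)
  Q <- q_init(K)
  labels <- integer(n_steps)
  labels[1] <- start
  last_cross <- -Inf
  for (t in seq_len(n_steps - 1)) {
    st <- labels[t]
    tau_t <- if (params$variant == "dynamic" && is.finite(last_cross))
      params$nu * exp(-(t - last_cross) / params$tau_decay) +
      params$tau_baseline
    else if (params$variant == "dynamic") params$tau_baseline
    else params$temperature
    p <- softmax_policy(Q[st, ], tau_t, exclude = st)
    a <- sample.int(K, 1, prob = p)
    pool <- da_pools[[a]]
    r <- pool[sample.int(length(pool), 1)]
    Q <- q_update(Q, st, a, r, params)
    if (params$variant == "dynamic" && r >= params$lam) last_cross <- t + 1
    labels[t + 1] <- a
  }
  list(labels = labels, Q = Q)
}
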
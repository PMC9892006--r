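#' Extract per-instance dopamine peaks and covariates
#'
#' The syllable-associated dopamine value of each instance is the maximum of
#' the z-scored trace in the 300 ms window from syllable onset (frames
#' `onset .. onset+9` at 30 Hz, 10 samples including the onset frame),
#' truncated at the trace end. Also attaches each instance's mean 2D
#' velocity and a per-session z-scored peak column.
#'
#' @param session a `session_bundle`.
#' @param zscored z-scored dopamine trace on the session frame base.
#' @param mouse,session_id identifiers for the output rows.
#' @param window_frames peak-window length in frames.
#' @return data.frame: mouse, session, instance_index, syllable,
#'   onset_frame, duration_frames, peak, velocity, peak_z.
#' @export
extract_syllable_peaks <- function(session, zscored, mouse = "m1",
                                   session_id = "s1", window_frames = 10) {
  on <- session$onset_frames
  stopifnot(all(on >= 0), all(on < length(zscored)))
  n <- length(session$labels)
  peak <- numeric(n)
  vel <- numeric(n)
  v2d <- session$kinematics$velocity_2d
  for (j in seq_len(n)) {
    idx <- (on[j] + 1):min(length(zscored), on[j] + window_frames)
    peak[j] <- max(zscored[idx])
    vidx <- (on[j] + 1):min(length(v2d), on[j] + session$duration_frames[j])
    vel[j] <- mean(v2d[vidx])
  }
  data.frame(mouse = mouse, session = session_id,
             instance_index = seq_len(n) - 1L,
             syllable = session$labels,
             onset_frame = on,
             duration_frames = session$duration_frames,
             peak = peak, velocity = vel,
             peak_z = zscore(peak))
}

#' Linearly time-warp traces to a common length
#'
#' Each trace is linearly interpolated onto `target_len` points, so
#' instances longer than the target duration are compressed and shorter
#' ones expanded; endpoints are preserved.
#'
#' @param traces list of numeric vectors (each length >= 2).
#' @return matrix, `length(traces) x target_len`.
#' @param target_len output samples per trace.
#' @export
timewarp_traces <- function(traces, target_len = 25) {
  stopifnot(all(vapply(traces, length, 1L) >= 2))
  t(vapply(traces, function(x) {
    stats::approx(seq(0, 1, length.out = length(x)), x,
                  xout = seq(0, 1, length.out = target_len))$y
  }, numeric(target_len)))
}

#' Event-aligned average waveform, z-scored against a circular-shuffle null
#'
#' Stage 1: each trial (a window of `window_s` seconds either side of an
#' event) is z-scored with its own mean and s.d. Stage 2: the trial average
#' is z-scored against the mean and s.d. of `n_shuffles` averages built from
#' circularly permuted trials.
#'
#' @param trace numeric series.
#' @param event_frames 1-based event indices (>= 2 events).
#' @param rate sampling rate (Hz).
#' @param window_s half-window in seconds.
#' @param n_shuffles circular-permutation averages for the null (>= 2).
#' @param seed integer seed.
#' @return list with `lags_s`, `z` (the shuffle-z-scored average waveform),
#'   `trial_average`.
#' @export
aligned_average_z <- function(trace, event_frames, rate, window_s = 10,
                              n_shuffles = 100, seed = 1) {
  if (length(event_frames) < 2) stop("need >= 2 events")
  if (n_shuffles < 2) stop("need >= 2 shuffles for the null")
  set.seed(seed)
  half <- round(window_s * rate)
  ok <- event_frames > half & event_frames <= length(trace) - half
  ev <- event_frames[ok]
  if (length(ev) < 2) stop("need >= 2 events with complete windows")
  get_trials <- function(events) {
    t(vapply(events, function(e) {
      w <- trace[(e - half):(e + half)]
      (w - mean(w)) / stats::sd(w)
    }, numeric(2 * half + 1)))
  }
  avg <- colMeans(get_trials(ev))
  n <- length(trace)
  sh_avg <- matrix(0, n_shuffles, 2 * half + 1)
  for (s in seq_len(n_shuffles)) {
    ev_s <- ((ev - 1 + sample.int(n - 2 * half, length(ev),
                                  replace = TRUE)) %% (n - 2 * half)) +
      half + 1
    sh_avg[s, ] <- colMeans(get_trials(ev_s))
  }
  mu <- colMeans(sh_avg)
  sdv <- apply(sh_avg, 2, stats::sd)
  list(lags_s = ((-half):half) / rate,
       z = (avg - mu) / sdv,
       trial_average = avg)
}

#' Outgoing transition entropy per syllable
#'
#' Shannon entropy (nats) of each syllable's outgoing transition
#' probability distribution. Accepts a label sequence or a row-stochastic
#' transition matrix. Syllables with no outgoing transitions are `NA`.
#'
#' @param x integer label sequence or `K x K` transition matrix.
#' @param K number of syllables (required for a label sequence).
#' @return numeric vector of length K.
#' @export
transition_entropy <- function(x, K = NULL) {
  if (is.matrix(x)) {
    M <- x
  } else {
    if (is.null(K)) K <- max(x)
    counts <- matrix(0, K, K)
    if (length(x) >= 2) {
      from <- x[-length(x)]; to <- x[-1]
      for (j in seq_along(from)) counts[from[j], to[j]] <-
          counts[from[j], to[j]] + 1
    }
    rs <- rowSums(counts)
    M <- counts
    M[rs > 0, ] <- M[rs > 0, , drop = FALSE] / rs[rs > 0]
    M[rs == 0, ] <- NA
  }
  apply(M, 1, function(p) {
    if (anyNA(p) || sum(p) == 0) return(NA_real_)
    shannon_entropy(p)
  })
}

# Pooled conditional entropy of transitions (s_j -> s_{j+1}) for j in `steps`
pooled_transition_entropy <- function(labels, steps, K) {
  steps <- steps[steps < length(labels)]
  if (length(steps) == 0) return(NA_real_)
  counts <- matrix(0, K, K)
  from <- labels[steps]; to <- labels[steps + 1]
  for (j in seq_along(from)) counts[from[j], to[j]] <- counts[from[j], to[j]] + 1
  rs <- rowSums(counts)
  H <- 0; tot <- sum(rs)
  for (i in which(rs > 0)) H <- H + rs[i] / tot * shannon_entropy(counts[i, ] / rs[i])
  H
}

#' Expanding-bin correlation between instance peaks and future behaviour
#'
#' For each bin size n, correlates each instance's dopamine peak with an
#' outcome aggregated over the n following syllables (the index instance
#' excluded): same-syllable counts, mean velocity, or mean peak
#' (autocorrelation mode). In entropy mode, per-syllable peaks are binned
#' into 20 equally spaced amplitude bins, transitions within the following
#' n steps are pooled per bin, and the pooled conditional entropy per bin is
#' correlated with the bin rank. Correlations are computed within each of
#' `segments` equal-duration segments and averaged, then z-scored against
#' shuffles of the peak column (circular by default, preserving
#' autocorrelation).
#'
#' @param table a peak table from [extract_syllable_peaks()] (one session,
#'   ordered by instance).
#' @param outcome "counts", "velocity", "entropy" or "autocorr".
#' @param bin_sizes increasing syllable-step counts.
#' @param n_shuffles shuffles for the z-score.
#' @param segments number of equal segments.
#' @param shuffle "circular" or "permute".
#' @param n_entropy_bins amplitude bins for entropy mode.
#' @param seed integer seed.
#' @return data.frame of class `correlation_curve`: bin_size, r_raw, r_z.
#' @export
expanding_bin_correlation <- function(table, outcome = c("counts",
                                                         "velocity",
                                                         "entropy",
                                                         "autocorr"),
                                      bin_sizes = c(5, 10, 25, 50, 100,
                                                    200, 300, 400),
                                      n_shuffles = 100, segments = 5,
                                      shuffle = c("circular", "permute"),
                                      n_entropy_bins = 20, seed = 1) {
  outcome <- match.arg(outcome)
  shuffle <- match.arg(shuffle)
  stopifnot(all(diff(bin_sizes) > 0))
  set.seed(seed)
  n <- nrow(table)
  seg_lo <- round(seq(0, n, length.out = segments + 1))[-(segments + 1)] + 1
  seg_hi <- round(seq(0, n, length.out = segments + 1))[-1]
  labels <- table$syllable
  peaks <- table$peak
  vel <- table$velocity
  K <- max(labels)
  # cumulative same-syllable counts: CS[i, t+1] = #{w <= t : lab_w = i}
  CS <- matrix(0L, K, n + 1)
  for (i in seq_len(K)) CS[i, ] <- c(0L, cumsum(labels == i))
  cvel <- c(0, cumsum(vel))
  counts_out <- function(bs) {
    t <- seq_len(n - bs)
    CS[cbind(labels[t], t + bs + 1L)] - CS[cbind(labels[t], t + 1L)]
  }
  one_r <- function(pk, bs) {
    out_v <- switch(outcome,
                    counts = counts_out(bs),
                    velocity = (cvel[(1 + bs + 1):(n + 1)] -
                                  cvel[2:(n - bs + 1)]) / bs,
                    autocorr = {
                      cpk <- c(0, cumsum(pk))
                      (cpk[(1 + bs + 1):(n + 1)] -
                         cpk[2:(n - bs + 1)]) / bs
                    },
                    entropy = NULL)
    rs <- numeric(segments)
    for (g in seq_len(segments)) {
      valid <- seg_lo[g]:max(seg_lo[g], seg_hi[g] - bs)
      if (length(valid) < 3) { rs[g] <- NA; next }
      if (outcome == "entropy") {
        rs[g] <- entropy_bin_r(labels, pk, seg_lo[g], seg_hi[g], valid, bs,
                               n_entropy_bins)
      } else {
        rs[g] <- suppressWarnings(stats::cor(pk[valid], out_v[valid]))
      }
    }
    mean(rs, na.rm = TRUE)
  }
  r_raw <- vapply(bin_sizes, function(bs) one_r(peaks, bs), numeric(1))
  sh <- matrix(NA_real_, n_shuffles, length(bin_sizes))
  for (s in seq_len(n_shuffles)) {
    pk_s <- if (shuffle == "circular")
      circ_shift(peaks, sample.int(n - 1, 1)) else sample(peaks)
    sh[s, ] <- vapply(bin_sizes, function(bs) one_r(pk_s, bs), numeric(1))
  }
  mu <- colMeans(sh, na.rm = TRUE)
  sdv <- apply(sh, 2, stats::sd, na.rm = TRUE)
  structure(data.frame(bin_size = bin_sizes, r_raw = r_raw,
                       r_z = (r_raw - mu) / sdv),
            class = c("correlation_curve", "data.frame"))
}

# entropy-mode correlation for one segment: bin per-syllable peaks into
# equally spaced amplitude bins, pool transitions inside the bs-step windows
# following each binned instance (with multiplicity), and correlate pooled
# conditional entropy with bin rank
entropy_bin_r <- function(labels, pk, lo, hi, valid, bs, n_bins) {
  K <- max(labels)
  idx <- lo:hi
  bin_of <- integer(length(idx))
  for (i in unique(labels[idx])) {
    sub <- which(labels[idx] == i)
    p <- pk[idx[sub]]
    if (length(sub) < 2 || diff(range(p)) == 0) { bin_of[sub] <- 1L; next }
    br <- seq(min(p), max(p), length.out = n_bins + 1)
    bin_of[sub] <- pmin(n_bins, findInterval(p, br, rightmost.closed = TRUE))
  }
  # transitions j -> j+1 for j in lo..hi-1, encoded as a pair id
  j <- lo:(hi - 1)
  pair_id <- (labels[j] - 1L) * K + labels[j + 1L]
  H <- rep(NA_real_, n_bins)
  for (b in seq_len(n_bins)) {
    is_start <- integer(hi - lo + 1)
    sel <- valid[bin_of[valid - lo + 1] == b]
    if (length(sel) == 0) next
    is_start[sel - lo + 1] <- 1L
    cstart <- c(0L, cumsum(is_start))
    # weight of transition j = number of selected starts in [j-bs, j-1]
    rel <- j - lo + 1
    w <- cstart[pmin(length(cstart), rel + 1) - 1 + 1] -
      cstart[pmax(0, rel - bs) + 1]
    keep <- w > 0
    if (!any(keep)) next
    cnt <- rowsum(w[keep], pair_id[keep])
    pid <- as.integer(rownames(cnt))
    from <- (pid - 1L) %/% K + 1L
    tot_by_from <- rowsum(cnt[, 1], from)
    tot <- sum(cnt)
    Hb <- 0
    for (fi in seq_len(nrow(tot_by_from))) {
      f <- as.integer(rownames(tot_by_from))[fi]
      p_out <- cnt[from == f, 1] / tot_by_from[fi, 1]
      Hb <- Hb + tot_by_from[fi, 1] / tot * shannon_entropy(p_out)
    }
    H[b] <- Hb
  }
  ok <- !is.na(H)
  if (sum(ok) < 3) return(NA_real_)
  suppressWarnings(stats::cor(seq_len(n_bins)[ok], H[ok]))
}

#' Exponential-decay timescale of a correlation curve
#'
#' Fits `r(n) = a exp(-n / tau) + c` by nonlinear least squares over
#' bootstrap resamples. When a replicate matrix is supplied (one curve per
#' replicate), bootstrap draws resample replicates and fit their average;
#' otherwise the (bin size, r) points are resampled with replacement.
#'
#' @param curve a `correlation_curve` (uses `r_raw`), or any data.frame with
#'   `bin_size` and `r_raw`.
#' @param replicates optional matrix (replicates x bin sizes).
#' @param n_boot bootstrap resamples.
#' @param seed integer seed.
#' @param value column of `curve` to fit ("r_raw" or "r_z").
#' @return list of class `decay_fit`: `tau` (median), `tau_samples`,
#'   `identifiable`, `dropped` (non-converged fraction).
#' @export
fit_decay_tau <- function(curve, replicates = NULL, n_boot = 1000, seed = 1,
                          value = "r_raw") {
  ok <- is.finite(curve[[value]])
  curve <- curve[ok, , drop = FALSE]
  if (!is.null(replicates)) replicates <- replicates[, ok, drop = FALSE]
  stopifnot(nrow(curve) >= 3)
  set.seed(seed)
  ns <- curve$bin_size
  r <- curve[[value]]
  if (stats::sd(r) < 1e-12) {
    return(structure(list(tau = NA_real_, tau_samples = numeric(0),
                          identifiable = FALSE, dropped = 0),
                     class = "decay_fit"))
  }
  fit_one <- function(x, y) {
    if (length(unique(x)) < 3 || stats::sd(y) == 0) return(NA_real_)
    # direct least squares over (a, log tau, c); robust to zero-residual
    # resamples where Levenberg-Marquardt convergence tests degenerate
    sse <- function(par) {
      sum((y - par[1] * exp(-x / exp(par[2])) - par[3])^2)
    }
    st <- c(y[which.min(x)] - y[which.max(x)], log(stats::median(x)),
            y[which.max(x)])
    out <- tryCatch(
      stats::optim(st, sse, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(out)) return(NA_real_)
    tau <- exp(out$par[2])
    if (tau > 100 * max(x) || tau < 1e-4) return(NA_real_)
    tau
  }
  taus <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    if (!is.null(replicates)) {
      rows <- sample.int(nrow(replicates), replace = TRUE)
      taus[b] <- fit_one(ns, colMeans(replicates[rows, , drop = FALSE], na.rm = TRUE))
    } else {
      pick <- sort(sample.int(length(ns), replace = TRUE))
      taus[b] <- fit_one(ns[pick], r[pick])
    }
  }
  dropped <- mean(is.na(taus))
  if (dropped > 0.2) stop("decay fit failed on > 20% of resamples")
  structure(list(tau = stats::median(taus, na.rm = TRUE),
                 tau_samples = taus[!is.na(taus)],
                 identifiable = TRUE, dropped = dropped),
            class = "decay_fit")
}

#' Lagged cross-correlation between syllable dopamine and syllable usage
#'
#' Per syllable, mean peak and usage count are binned in non-overlapping
#' 3-min windows; the binned peak series is correlated with the binned
#' usage series at each window lag, pooled across syllables, and z-scored
#' against circular shuffles of the peak windows.
#'
#' @param table peak table (one session).
#' @param window_s window width in seconds.
#' @param lags integer window lags.
#' @param frame_rate frames per second of the onset frames.
#' @param n_shuffles shuffles for the z-score.
#' @param seed integer seed.
#' @return data.frame: lag, r, r_z.
#' @export
cross_correlation_usage <- function(table, window_s = 180, lags = -5:5,
                                    frame_rate = 30, n_shuffles = 100,
                                    seed = 1) {
  set.seed(seed)
  wlen <- window_s * frame_rate
  win <- floor(table$onset_frame / wlen) + 1
  n_win <- max(win)
  if (n_win < 2) stop("session shorter than two windows")
  sylls <- sort(unique(table$syllable))
  pk_mat <- matrix(NA_real_, length(sylls), n_win)
  ct_mat <- matrix(0, length(sylls), n_win)
  for (k in seq_along(sylls)) {
    sel <- table$syllable == sylls[k]
    pk_mat[k, ] <- vapply(seq_len(n_win), function(w) {
      v <- table$peak[sel & win == w]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1))
    tab <- table(factor(win[sel], levels = seq_len(n_win)))
    ct_mat[k, ] <- as.numeric(tab)
  }
  corr_at <- function(pk, lag) {
    xs <- NULL; ys <- NULL
    for (k in seq_along(sylls)) {
      w <- seq_len(n_win)
      wy <- w + lag
      ok <- wy >= 1 & wy <= n_win & !is.na(pk[k, w])
      xs <- c(xs, pk[k, w[ok]])
      ys <- c(ys, ct_mat[k, wy[ok]])
    }
    if (length(xs) < 3 || stats::sd(xs) == 0 || stats::sd(ys) == 0)
      return(NA_real_)
    stats::cor(xs, ys)
  }
  r <- vapply(lags, function(l) corr_at(pk_mat, l), numeric(1))
  sh <- matrix(NA_real_, n_shuffles, length(lags))
  for (s in seq_len(n_shuffles)) {
    shift <- sample.int(n_win - 1, 1)
    pk_s <- pk_mat[, c((n_win - shift + 1):n_win, 1:(n_win - shift)),
                   drop = FALSE]
    sh[s, ] <- vapply(lags, function(l) corr_at(pk_s, l), numeric(1))
  }
  data.frame(lag = lags, r = r,
             r_z = (r - colMeans(sh, na.rm = TRUE)) /
               apply(sh, 2, stats::sd, na.rm = TRUE))
}

#' Cross-validated robust (Huber) regression with a shuffle null
#'
#' Fits a Huber-loss linear regression of `y` on `x` with k-fold
#' cross-validation repeated `repeats` times; performance is the Pearson
#' correlation between held-out predictions and truth, pooled per repeat.
#' The p-value is the fraction of shuffle fits (y permuted) whose held-out
#' correlation meets or exceeds the observed mean.
#'
#' @param x,y paired numeric vectors (length >= 2*folds).
#' @param folds,repeats cross-validation design.
#' @param n_shuffles permutation fits for the null.
#' @param seed integer seed.
#' @return list: `r` (mean held-out r), `r_repeats`, `p`, `null_r`.
#' @export
huber_regression_cv <- function(x, y, folds = 5, repeats = 100,
                                n_shuffles = 1000, seed = 1) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 2 * folds)
  if (stats::sd(x) == 0) stop("degenerate x: zero variance")
  set.seed(seed)
  cv_r <- function(xv, yv) {
    fold_id <- sample(rep_len(seq_len(folds), n))
    pred <- numeric(n)
    for (f in seq_len(folds)) {
      te <- fold_id == f
      fit <- suppressWarnings(
        MASS::rlm(yv[!te] ~ xv[!te], psi = MASS::psi.huber, maxit = 50))
      pred[te] <- stats::coef(fit)[1] + stats::coef(fit)[2] * xv[te]
    }
    if (stats::sd(pred) == 0) return(0)
    stats::cor(pred, yv)
  }
  r_rep <- vapply(seq_len(repeats), function(i) cv_r(x, y), numeric(1))
  r_obs <- mean(r_rep)
  null_r <- vapply(seq_len(n_shuffles), function(i) cv_r(x, sample(y)),
                   numeric(1))
  list(r = r_obs, r_repeats = r_rep,
       p = (sum(null_r >= r_obs) + 1) / (n_shuffles + 1),
       null_r = null_r)
}

#' Movement-initiation changepoints from 2D velocity
#'
#' The velocity is z-scored across the session, smoothed with a 50-point
#' (1.67 s) boxcar, differentiated (z-units per second, so a
#' stillness-to-movement swing of ~2 z inside the boxcar width scores
#' above 1), and cubed; peaks of this changepoint score with height, width
#' and prominence at least 1 mark transitions from stillness to movement.
#'
#' @param velocity_2d velocity series (length > 50).
#' @param rate sampling rate (Hz).
#' @return integer frames of detected initiations.
#' @export
movement_initiations <- function(velocity_2d, rate = 30) {
  stopifnot(length(velocity_2d) > 50)
  z <- zscore(velocity_2d)
  sm <- boxcar_smooth(z, 50)
  score <- (c(0, diff(sm)) * rate)^3
  find_peaks(score, height = 1, prominence = 1, min_distance = 1)
}

#' Partial correlation of dopamine with a kinematic target
#'
#' Covariates are regressed out of the dopamine series by ordinary least
#' squares; the Pearson correlation between the residual and the target is
#' compared against a null built from circular shifts of the target.
#' Collinear covariates are dropped with a warning.
#'
#' @param dlight dopamine series.
#' @param covariates data.frame or list of series to partial out.
#' @param target series to correlate with the residual.
#' @param n_boot circular-shift null draws.
#' @param seed integer seed.
#' @return list: `r`, `null_lo`, `null_hi` (2.5/97.5% null quantiles),
#'   `null_r`.
#' @export
partial_out_kinematics <- function(dlight, covariates, target,
                                   n_boot = 1000, seed = 1) {
  X <- as.matrix(as.data.frame(covariates))
  stopifnot(nrow(X) == length(dlight), length(target) == length(dlight))
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    keep <- setdiff(keep, 1) - 1
    warning("dropping collinear covariates")
    X <- X[, keep, drop = FALSE]
  }
  resid <- stats::lm.fit(cbind(1, X), dlight)$residuals
  r <- stats::cor(resid, target)
  set.seed(seed)
  n <- length(target)
  null_r <- vapply(seq_len(n_boot), function(b) {
    stats::cor(resid, circ_shift(target, sample.int(n - 1, 1)))
  }, numeric(1))
  list(r = r, null_lo = stats::quantile(null_r, 0.025, names = FALSE),
       null_hi = stats::quantile(null_r, 0.975, names = FALSE),
       null_r = null_r)
}

#' Endogenous-dopamine influence index
#'
#' The modulation depth of an expanding-bin correlation curve: the standard
#' deviation, across bin sizes, of the shuffle-z-scored correlations. Under
#' the null the z-curve is approximately unit white noise, so the index
#' calibrates near 1; strong dopamine-behaviour coupling inflates it.
#'
#' @param table peak table (one unit: a mouse or a mouse-syllable subset).
#' @param outcome "counts" or "entropy".
#' @param bin_sizes,n_shuffles,segments,seed passed to
#'   [expanding_bin_correlation()].
#' @return scalar index.
#' @export
endo_da_influence <- function(table, outcome = c("counts", "entropy"),
                              bin_sizes = c(5, 10, 25, 50, 100, 200, 400),
                              n_shuffles = 100, segments = 5, seed = 1) {
  outcome <- match.arg(outcome)
  curve <- expanding_bin_correlation(table, outcome, bin_sizes,
                                     n_shuffles = n_shuffles,
                                     segments = segments, seed = seed)
  stats::sd(curve$r_z, na.rm = TRUE)
}
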
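#' Sliding-percentile dF/F0
#'
#' The baseline F0 is the 10th percentile of the raw trace in a centred 5-s
#' sliding window (edge-truncated), tracking slow correlated fluorescence
#' changes such as bleaching; the output is `(raw - F0) / F0`.
#'
#' @param raw strictly positive fluorescence trace.
#' @param rate sampling rate (Hz).
#' @param window_s sliding-window width in seconds.
#' @param percentile baseline percentile (0-100).
#' @return dF/F0 series of the same length.
#' @export
compute_dff <- function(raw, rate, window_s = 5, percentile = 10) {
  stopifnot(all(raw > 0), window_s * rate >= 2)
  half <- max(1L, floor(window_s * rate / 2))
  f0 <- rolling_quantile(raw, half, percentile / 100)
  if (any(f0 <= 0)) stop("degenerate baseline: nonpositive F0")
  (raw - f0) / f0
}

#' Subtract a fitted reference channel from the signal channel
#'
#' The reference dF/F0 is low-pass filtered (second-order Butterworth, 3 Hz
#' corner, zero-phase forward-backward), fitted to the signal by
#' consensus-based (RANSAC) ordinary least squares for slope and bias, and
#' the transformed reference is subtracted. A constant reference degenerates
#' the fit; the signal is then returned unchanged with a warning flag.
#'
#' @param signal_dff,reference_dff dF/F0 series of equal length.
#' @param rate sampling rate (Hz).
#' @param corner_hz low-pass corner frequency.
#' @param n_trials RANSAC trials.
#' @param seed seed for the RANSAC subsampling.
#' @return list with `referenced` (series), `slope`, `bias`, and
#'   `degenerate` flag.
#' @export
subtract_reference <- function(signal_dff, reference_dff, rate,
                               corner_hz = 3, n_trials = 100, seed = 1) {
  stopifnot(length(signal_dff) == length(reference_dff))
  if (stats::sd(reference_dff) == 0) {
    warning("constant reference; returning signal unchanged")
    return(list(referenced = signal_dff, slope = 0, bias = 0,
                degenerate = TRUE))
  }
  bf <- signal::butter(2, corner_hz / (rate / 2), type = "low")
  ref_lp <- as.numeric(signal::filtfilt(bf, reference_dff))
  fit <- ransac_line(ref_lp, signal_dff, n_trials = n_trials, seed = seed)
  list(referenced = signal_dff - (fit$slope * ref_lp + fit$bias),
       slope = fit$slope, bias = fit$bias, degenerate = FALSE)
}

# Consensus (RANSAC) straight-line fit. Candidate lines are the plain OLS
# fit plus random two-point samples; the inlier threshold is one MAD of
# the OLS residuals, the candidate with the largest consensus set wins
# (OLS holds ties), and the winner is refit by OLS on its inliers. With an
# uninformative regressor every line ties and the OLS fit is kept; with
# sparse outliers (dopamine transients) the consensus refit excludes them.
ransac_line <- function(x, y, n_trials = 100, seed = 1) {
  set.seed(seed)
  n <- length(x)
  ols <- stats::coef(stats::lm(y ~ x))
  r_ols <- y - (ols[2] * x + ols[1])
  thr <- stats::mad(r_ols)
  if (thr < 1e-12) {
    # the ordinary fit is (numerically) exact
    return(list(slope = unname(ols[2]), bias = unname(ols[1])))
  }
  best <- c(ols[2], ols[1])
  best_in <- sum(abs(r_ols) <= thr)
  for (k in seq_len(n_trials)) {
    idx <- sample.int(n, 2)
    dx <- x[idx[2]] - x[idx[1]]
    if (dx == 0) next
    sl <- (y[idx[2]] - y[idx[1]]) / dx
    b <- y[idx[1]] - sl * x[idx[1]]
    n_in <- sum(abs(y - (sl * x + b)) <= thr)
    if (n_in > best_in) {
      best_in <- n_in
      best <- c(sl, b)
    }
  }
  inl <- abs(y - (best[1] * x + best[2])) <= thr
  if (sum(inl) >= 3) {
    cf <- stats::coef(stats::lm(y[inl] ~ x[inl]))
    best <- c(cf[2], cf[1])
  }
  list(slope = unname(best[1]), bias = unname(best[2]))
}

#' Sliding-window z-score
#'
#' Each sample is z-scored against the mean and s.d. of a centred window
#' (default 20 s), edge-truncated, removing slow amplitude trends such as
#' photobleaching. Samples whose window s.d. is zero map to 0 and are
#' flagged.
#'
#' @param trace numeric series.
#' @param rate sampling rate (Hz).
#' @param window_s window width in seconds.
#' @return list with `z` (series) and `flagged` (indices with zero window
#'   s.d.).
#' @export
sliding_zscore <- function(trace, rate, window_s = 20) {
  stopifnot(window_s * rate >= 2)
  half <- max(1L, floor(window_s * rate / 2))
  ms <- rolling_mean_sd(trace, half)
  z <- (trace - ms$mean) / ms$sd
  bad <- which(!is.finite(z))
  z[bad] <- 0
  list(z = z, flagged = bad)
}

#' Photometry quality-control gate
#'
#' A recording passes when the maximum percent dF/F0 of the signal exceeds
#' 1.5 and the Pearson correlation between signal and reference dF/F0 is
#' below 0.6.
#'
#' @param dff_signal,dff_reference dF/F0 series of equal length.
#' @return list with `pass`, `max_pct_dff`, `ref_correlation`.
#' @export
qc_pass <- function(dff_signal, dff_reference) {
  stopifnot(length(dff_signal) == length(dff_reference))
  max_pct <- max(100 * dff_signal)
  r <- if (stats::sd(dff_reference) == 0 || stats::sd(dff_signal) == 0) {
    if (isTRUE(all.equal(dff_signal, dff_reference))) 1 else 0
  } else stats::cor(dff_signal, dff_reference)
  list(pass = max_pct > 1.5 && r < 0.6, max_pct_dff = max_pct,
       ref_correlation = r)
}

#' Detect dopamine transients in a z-scored trace
#'
#' Local maxima above `threshold`, separated by at least
#' `min_separation_s`; taller peaks win ties.
#'
#' @param z z-scored series.
#' @param rate sampling rate (Hz).
#' @param threshold detection threshold (z-units, > 0).
#' @param min_separation_s minimum peak separation in seconds.
#' @return list of class `transient_events`: `peak_frames` (1-based,
#'   increasing), `amplitudes`, `threshold`, `rate_hz` (events per second).
#' @export
detect_transients <- function(z, rate, threshold = 2,
                              min_separation_s = 0.167) {
  stopifnot(threshold > 0)
  pk <- find_peaks(z, height = threshold,
                   min_distance = max(1, round(min_separation_s * rate)))
  structure(list(peak_frames = pk, amplitudes = z[pk],
                 threshold = threshold,
                 rate_hz = length(pk) / (length(z) / rate)),
            class = "transient_events")
}

#' Anti-aliased downsampling to the behaviour frame base
#'
#' @param trace numeric series.
#' @param rate_in input rate (Hz), `>= rate_out`.
#' @param rate_out output rate (Hz), default 30.
#' @return resampled series.
#' @export
downsample_to_frames <- function(trace, rate_in, rate_out = 30) {
  stopifnot(rate_in >= rate_out)
  if (rate_in == rate_out) return(trace)
  # zero-phase low-pass below the output Nyquist, then linear resampling
  bf <- signal::butter(4, 0.8 * rate_out / rate_in, type = "low")
  lp <- as.numeric(signal::filtfilt(bf, trace))
  n_out <- floor(length(trace) * rate_out / rate_in)
  t_in <- (seq_along(trace) - 1) / rate_in
  t_out <- (seq_len(n_out) - 1) / rate_out
  stats::approx(t_in, lp, xout = t_out)$y
}

#' Full photometry preprocessing chain
#'
#' dF/F0 on both channels, robust reference subtraction, sliding z-score;
#' provenance records each stage and its parameters.
#'
#' @param trace a `photometry_trace` with `raw_signal`, `raw_reference`,
#'   `sampling_rate_hz`.
#' @param dff_window_s,dff_percentile baseline parameters.
#' @param z_window_s z-score window.
#' @param seed RANSAC seed.
#' @return the trace with `dff_signal`, `dff_reference`, `referenced`,
#'   `zscored`, `qc` fields added and provenance appended.
#' @export
preprocess_photometry <- function(trace, dff_window_s = 5,
                                  dff_percentile = 10, z_window_s = 20,
                                  seed = 1) {
  rate <- trace$sampling_rate_hz
  trace$dff_signal <- compute_dff(trace$raw_signal, rate, dff_window_s,
                                  dff_percentile)
  trace$dff_reference <- compute_dff(trace$raw_reference, rate,
                                     dff_window_s, dff_percentile)
  sub <- subtract_reference(trace$dff_signal, trace$dff_reference, rate,
                            seed = seed)
  trace$referenced <- sub$referenced
  zs <- sliding_zscore(trace$referenced, rate, z_window_s)
  trace$zscored <- zs$z
  trace$qc <- qc_pass(trace$dff_signal, trace$dff_reference)
  trace$provenance <- c(trace$provenance, list(
    list(op = "compute_dff", window_s = dff_window_s,
         percentile = dff_percentile),
    list(op = "subtract_reference", slope = sub$slope, bias = sub$bias,
         degenerate = sub$degenerate),
    list(op = "sliding_zscore", window_s = z_window_s,
         flagged = length(zs$flagged))))
  trace
}
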
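#' Cumulative excess target counts relative to baseline
#'
#' Target-syllable counts are tallied in non-overlapping 30-s bins and
#' cumulatively summed per session; the average cumulative baseline curve
#' is subtracted from the average cumulative stimulation curve. Sessions of
#' unequal duration are truncated to the shortest with a warning.
#'
#' @param stim_sessions,baseline_sessions lists of `session_bundle`s.
#' @param target target syllable.
#' @param window_s bin width in seconds.
#' @param frame_rate frames per second of the onset frames.
#' @return list: `excess` (cumulative excess counts per bin), `bins_s`
#'   (bin end times), `terminal` (final excess).
#' @export
excess_target_counts <- function(stim_sessions, baseline_sessions, target,
                                 window_s = 30, frame_rate = 30) {
  stopifnot(length(stim_sessions) >= 1, length(baseline_sessions) >= 2)
  binned <- function(s) {
    n_frames <- sum(s$duration_frames)
    bins <- floor(s$onset_frames / (window_s * frame_rate)) + 1
    n_bins <- max(1, floor(n_frames / (window_s * frame_rate)))
    sel <- s$labels == target & bins <= n_bins
    counts <- tabulate(bins[sel], nbins = n_bins)
    cumsum(counts)
  }
  stim_c <- lapply(stim_sessions, binned)
  base_c <- lapply(baseline_sessions, binned)
  n_bins <- min(vapply(c(stim_c, base_c), length, 1L))
  if (length(unique(vapply(c(stim_c, base_c), length, 1L))) > 1)
    warning("sessions of unequal duration; truncating to the shortest")
  stim_m <- rowMeans(vapply(stim_c, function(x) x[seq_len(n_bins)],
                            numeric(n_bins)))
  base_m <- rowMeans(vapply(base_c, function(x) x[seq_len(n_bins)],
                            numeric(n_bins)))
  excess <- stim_m - base_m
  list(excess = excess, bins_s = seq_len(n_bins) * window_s,
       terminal = excess[n_bins])
}

#' Classify learner mice against no-opsin controls
#'
#' A mouse is a learner when its average change in target counts above
#' baseline strictly exceeds the maximum average change shown by any
#' control animal.
#'
#' @param mouse_means per-mouse mean excess values.
#' @param control_values per-control-mouse values (>= 1).
#' @return logical vector aligned with `mouse_means`.
#' @export
classify_learners <- function(mouse_means, control_values) {
  stopifnot(length(control_values) >= 1)
  mouse_means > max(control_values)
}

#' Count changes binned by temporal adjacency to the target
#'
#' Each non-target syllable is placed at its mean signed offset (in
#' syllable steps, within +/- 10) to the nearest target instance, and its
#' change in counts versus baseline is averaged within each offset bin,
#' weighted by the syllable's relative frequency.
#'
#' @param stim_sessions,baseline_sessions session lists.
#' @param target target syllable.
#' @param max_offset half-width of the offset range.
#' @return data.frame: offset_bin (-max_offset..max_offset), change
#'   (frequency-weighted mean count change), n_syllables.
#' @export
temporal_adjacency_effect <- function(stim_sessions, baseline_sessions,
                                      target, max_offset = 10) {
  count_per <- function(sessions) {
    K <- sessions[[1]]$truth$n_syllables
    rowMeans(vapply(sessions, function(s) tabulate(s$labels, nbins = K),
                    numeric(K)))
  }
  K <- stim_sessions[[1]]$truth$n_syllables
  stim_counts <- count_per(stim_sessions)
  base_counts <- count_per(baseline_sessions)
  change <- stim_counts - base_counts
  # mean signed offset to the nearest target instance, pooled over stim
  # sessions
  offs <- vector("list", K)
  for (s in stim_sessions) {
    tpos <- which(s$labels == target)
    if (length(tpos) == 0) next
    for (j in seq_along(s$labels)) {
      i <- s$labels[j]
      if (i == target) next
      d <- j - tpos[which.min(abs(j - tpos))]
      if (abs(d) <= max_offset) offs[[i]] <- c(offs[[i]], d)
    }
  }
  mean_off <- vapply(offs, function(v) if (length(v)) mean(v) else NA_real_,
                     numeric(1))
  freq <- base_counts / sum(base_counts)
  bins <- -max_offset:max_offset
  out <- data.frame(offset_bin = bins, change = NA_real_, n_syllables = 0L)
  for (bi in seq_along(bins)) {
    sel <- which(!is.na(mean_off) & round(mean_off) == bins[bi] &
                   seq_len(K) != target)
    out$n_syllables[bi] <- length(sel)
    if (length(sel)) {
      w <- freq[sel] / sum(freq[sel])
      out$change[bi] <- sum(w * change[sel])
    }
  }
  out
}

#' Count changes binned by velocity similarity to the target
#'
#' Per-syllable average velocities are z-scored across instances within
#' each session; the target's average is subtracted from each syllable's,
#' and count changes versus baseline are binned by this velocity
#' difference.
#'
#' @param stim_sessions,baseline_sessions session lists with peak tables'
#'   velocity available via `kinematics`.
#' @param target target syllable.
#' @param breaks velocity-difference bin edges (z-units).
#' @return data.frame: bin_mid, change, n_syllables.
#' @export
velocity_similarity_effect <- function(stim_sessions, baseline_sessions,
                                       target,
                                       breaks = seq(-3, 3, by = 1)) {
  K <- stim_sessions[[1]]$truth$n_syllables
  syl_vel <- function(s) {
    inst_v <- vapply(seq_along(s$labels), function(j) {
      idx <- (s$onset_frames[j] + 1):
        min(length(s$kinematics$velocity_2d),
            s$onset_frames[j] + s$duration_frames[j])
      mean(s$kinematics$velocity_2d[idx])
    }, numeric(1))
    inst_v <- zscore(inst_v)
    vapply(seq_len(K), function(i) {
      v <- inst_v[s$labels == i]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1))
  }
  vmat <- vapply(stim_sessions, syl_vel, numeric(K))
  vel <- rowMeans(vmat, na.rm = TRUE)
  vdiff <- vel - vel[target]
  count_per <- function(sessions)
    rowMeans(vapply(sessions, function(s) tabulate(s$labels, nbins = K),
                    numeric(K)))
  change <- count_per(stim_sessions) - count_per(baseline_sessions)
  bin <- findInterval(vdiff, breaks, rightmost.closed = TRUE)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  out <- data.frame(bin_mid = mids, change = NA_real_, n_syllables = 0L)
  for (b in seq_along(mids)) {
    sel <- which(bin == b & seq_len(K) != target & !is.na(vdiff))
    out$n_syllables[b] <- length(sel)
    if (length(sel)) out$change[b] <- mean(change[sel])
  }
  out
}

#' Post-stimulation sequence and kinematic dynamics versus catch trials
#'
#' For each stimulated target instance, each metric is computed in
#' five-syllable non-overlapping bins after onset, with the pre-onset value
#' (the preceding five syllables) subtracted; bins are z-scored against the
#' same statistic on catch trials.
#'
#' @param sessions stimulation sessions (with `stim` flags and `target`).
#' @param metrics subset of "entropy", "velocity_2d", "angular", "height",
#'   "acceleration".
#' @param bin_syllables bin width in syllables.
#' @param n_bins post-onset bins.
#' @param min_catch minimum catch trials required.
#' @return data.frame: metric, bin, z.
#' @export
post_stim_dynamics <- function(sessions,
                               metrics = c("entropy", "velocity_2d",
                                           "angular", "height",
                                           "acceleration"),
                               bin_syllables = 5, n_bins = 4,
                               min_catch = 10) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  K <- sessions[[1]]$truth$n_syllables
  inst_metric <- function(s, metric, j) {
    if (metric == "entropy") return(NA_real_)  # handled at bin level
    ch <- switch(metric,
                 velocity_2d = s$kinematics$velocity_2d,
                 angular = s$kinematics$angular_velocity,
                 height = s$kinematics$height_velocity,
                 acceleration = s$kinematics$acceleration)
    idx <- (s$onset_frames[j] + 1):
      min(length(ch), s$onset_frames[j] + s$duration_frames[j])
    mean(ch[idx])
  }
  # per event (instance index), per metric, baseline-subtracted bin values
  event_bins <- function(s, events, metric) {
    t(vapply(events, function(e) {
      pre_idx <- max(1, e - bin_syllables):(e - 1)
      vals <- numeric(n_bins)
      for (b in seq_len(n_bins)) {
        idx <- (e + (b - 1) * bin_syllables + 1):(e + b * bin_syllables)
        idx <- idx[idx <= length(s$labels)]
        if (length(idx) == 0) { vals[b] <- NA; next }
        if (metric == "entropy") {
          pre <- pooled_transition_entropy(s$labels, pre_idx, K)
          vals[b] <- pooled_transition_entropy(s$labels, idx, K) - pre
        } else {
          pre <- mean(vapply(pre_idx, function(j) inst_metric(s, metric, j),
                             numeric(1)))
          vals[b] <- mean(vapply(idx, function(j) inst_metric(s, metric, j),
                                 numeric(1))) - pre
        }
      }
      vals
    }, numeric(n_bins)))
  }
  out <- list()
  for (metric in metrics) {
    stim_rows <- NULL; catch_rows <- NULL
    for (s in sessions) {
      stim_ev <- which(s$stim & s$labels == s$target)
      catch_ev <- which(!s$stim & s$labels == s$target)
      stim_ev <- stim_ev[stim_ev > bin_syllables]
      catch_ev <- catch_ev[catch_ev > bin_syllables]
      if (length(stim_ev))
        stim_rows <- rbind(stim_rows, event_bins(s, stim_ev, metric))
      if (length(catch_ev))
        catch_rows <- rbind(catch_rows, event_bins(s, catch_ev, metric))
    }
    if (is.null(catch_rows) || nrow(catch_rows) < min_catch)
      stop("too few catch trials")
    z <- vapply(seq_len(n_bins), function(b) {
      mu <- mean(catch_rows[, b], na.rm = TRUE)
      sdv <- stats::sd(catch_rows[, b], na.rm = TRUE)
      (mean(stim_rows[, b], na.rm = TRUE) - mu) / sdv
    }, numeric(1))
    out[[metric]] <- data.frame(metric = metric, bin = seq_len(n_bins),
                                z = z)
  }
  do.call(rbind, out)
}

#' Opto-DA learning score
#'
#' The log2 fold change in target counts on stimulation days versus
#' baseline days, z-scored against the distribution of log2 fold changes
#' between all pairs of non-stimulation days (add-one smoothing guards
#' zero counts, with a flag).
#'
#' @param stim_counts total target counts per stimulation session.
#' @param nonstim_counts total target counts per non-stimulation session
#'   (>= 2 sessions).
#' @return list: `score`, `log2fc`, `null_mean`, `null_sd`, `smoothed`.
#' @export
opto_learning_score <- function(stim_counts, nonstim_counts) {
  stopifnot(length(nonstim_counts) >= 2)
  smoothed <- any(c(stim_counts, nonstim_counts) == 0)
  if (smoothed) {
    stim_counts <- stim_counts + 1
    nonstim_counts <- nonstim_counts + 1
  }
  fc <- log2(mean(stim_counts) / mean(nonstim_counts))
  pairs <- utils::combn(length(nonstim_counts), 2)
  null_fc <- c(log2(nonstim_counts[pairs[1, ]] / nonstim_counts[pairs[2, ]]),
               log2(nonstim_counts[pairs[2, ]] / nonstim_counts[pairs[1, ]]))
  list(score = (fc - mean(null_fc)) / stats::sd(null_fc),
       log2fc = fc, null_mean = mean(null_fc), null_sd = stats::sd(null_fc),
       smoothed = smoothed)
}

#' Velocity change under quartile-contingent stimulation
#'
#' With stimulation contingent on the target syllable's instance velocity
#' exceeding the 75th (or falling below the 25th) percentile of a
#' pre-period, compares the target's mean velocity post versus pre.
#' Excluded (with a flag) when fewer than `min_stim` stimulations occurred.
#'
#' @param pre_velocities target-instance velocities from the estimation
#'   period.
#' @param post_velocities target-instance velocities from the manipulation
#'   period.
#' @param n_stim number of stimulations delivered.
#' @param arm "high" (above 75th) or "low" (below 25th) contingency.
#' @param min_stim inclusion threshold.
#' @return list: `shift` (post minus pre mean), `arm`, `included`.
#' @export
velocity_quartile_effect <- function(pre_velocities, post_velocities,
                                     n_stim, arm = c("high", "low"),
                                     min_stim = 50) {
  arm <- match.arg(arm)
  included <- n_stim >= min_stim
  shift <- if (included)
    mean(post_velocities) - mean(pre_velocities) else NA_real_
  list(shift = shift, arm = arm, included = included)
}
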
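#' Generative parameters for synthetic sessions
#'
#' Bundles every constant of the session generator: the syllable repertoire
#' and its Markov base-transition structure, per-syllable dopamine transient
#' amplitude distributions, the dopamine-to-behaviour couplings (usage on a
#' ~100-syllable timescale, sequence randomness on a ~10-syllable timescale),
#' syllable duration statistics, photometry rendering constants
#' (bi-exponential transient kinetics, bleaching, shared artifacts, reference
#' channel) and per-syllable kinematic templates.
#'
#' Base transitions are drawn row-wise from a symmetric Dirichlet with the
#' diagonal removed and renormalized, so self-transitions never occur.
#'
#' @param K number of syllables (>= 2).
#' @param seed integer master seed used to draw the random fields.
#' @param overrides named list replacing any default field after drawing.
#' @param concentration symmetric Dirichlet concentration for base
#'   transitions; small values give low-entropy (peaky) rows.
#' @return object of class `generative_params`.
#' @export
make_generative_params <- function(K, seed = 1, overrides = list(),
                                   concentration = 1) {
  if (K < 2) stop("K must be >= 2")
  set.seed(seed)
  base <- matrix(0, K, K)
  for (i in seq_len(K)) {
    g <- stats::rgamma(K, shape = concentration)
    g[i] <- 0
    base[i, ] <- g / sum(g)
  }
  p <- list(
    n_syllables = as.integer(K),
    base_transitions = base,
    syllable_da_mean = seq(1, 3, length.out = K),
    syllable_da_sd = rep(0.8, K),
    alpha_a_true = 1,
    alpha_b_true = 1,
    tau_a = 100,
    tau_b = 10,
    history_window = 250L,
    duration_median_ms = 400,
    duration_dispersion = 0.88,
    frame_rate_hz = 30,
    transient_rise_ms = 67,
    transient_decay_ms = 100,
    bleach_tau_s = 1200,
    baseline_f0 = 1,
    dff_per_z = 0.01,
    noise_sd = 0.002,
    artifact_rate_hz = 0.02,
    artifact_amp = 0.05,
    reference_gain = 0.7,
    reference_offset = 0.1,
    velocity_templates = stats::runif(K, 20, 150),
    angular_templates = stats::runif(K, -2, 2),
    height_templates = stats::runif(K, -10, 10),
    kin_noise_sd = 10,
    seed = as.integer(seed)
  )
  for (nm in names(overrides)) p[[nm]] <- overrides[[nm]]
  validate_generative_params(p)
  structure(p, class = "generative_params")
}

validate_generative_params <- function(p) {
  K <- p$n_syllables
  if (K < 2) stop("K must be >= 2")
  bt <- p$base_transitions
  if (!is.matrix(bt) || any(dim(bt) != K)) stop("base_transitions must be KxK")
  if (any(abs(diag(bt)) > 0)) stop("base_transitions diagonal must be 0")
  if (any(abs(rowSums(bt) - 1) > 1e-9)) stop("base_transitions rows must sum to 1")
  pos <- c("alpha_b_true", "tau_a", "tau_b", "history_window",
           "duration_median_ms", "duration_dispersion", "frame_rate_hz",
           "transient_rise_ms", "transient_decay_ms", "bleach_tau_s")
  for (nm in pos) if (p[[nm]] <= 0) stop(sprintf("%s must be > 0", nm))
  if (p$alpha_a_true < 0) stop("alpha_a_true must be >= 0")
  if (p$noise_sd < 0 || p$artifact_rate_hz < 0 || any(p$syllable_da_sd < 0))
    stop("noise/artifact/sd parameters must be >= 0")
  invisible(p)
}

# decoding_params view of the generator's true coupling constants
truth_decoding_params <- function(params) {
  decoding_params(params$n_syllables,
                  alpha_a = params$alpha_a_true,
                  alpha_b = params$alpha_b_true,
                  tau_a = params$tau_a, tau_b = params$tau_b,
                  window = params$history_window)
}

#' Simulate a syllable sequence with dopamine feedback
#'
#' Labels are drawn step by step from the decoding model run with the
#' generator's true gains, with the log base-transition row added as a Markov
#' prior bias (the zero diagonal masks self-transitions). Each emitted
#' instance receives a dopamine amplitude drawn from its syllable's normal
#' distribution; that amplitude immediately enters the history driving future
#' choices. An optional closed-loop stimulation rule adds `extra_da` to
#' target instances with probability `stim_prob` before the sequence
#' continues.
#'
#' @param params [make_generative_params()].
#' @param n_steps number of syllable instances (>= 2).
#' @param seed integer seed.
#' @param stim optional list(target=, prob=, extra_da=) closed-loop rule.
#' @return list with `labels`, `da` (z-units, including any stimulation
#'   boost), and `stim` (logical per instance).
#' @export
simulate_syllable_sequence <- function(params, n_steps, seed = 1,
                                       stim = NULL) {
  if (n_steps < 2) stop("n_steps must be >= 2")
  set.seed(seed)
  K <- params$n_syllables
  W <- params$history_window
  dp <- truth_decoding_params(params)
  base_log <- log(params$base_transitions)  # -Inf on the diagonal
  ka <- exp(-1 / dp$tau_a); kb <- exp(-1 / dp$tau_b)
  ka_out <- exp(-(W + 1) / dp$tau_a); kb_out <- exp(-(W + 1) / dp$tau_b)
  eps <- dp$guard_frac * dp$alpha_b * sum(exp(-(1:W) / dp$tau_b))
  labels <- integer(n_steps)
  da <- numeric(n_steps)
  stim_flag <- logical(n_steps)
  A <- numeric(K); D <- 0
  for (t in seq_len(n_steps)) {
    if (t == 1) {
      z <- rep(0, K)
    } else {
      den <- dp$alpha_b * D
      if (abs(den) < eps) den <- if (den < 0) -eps else eps
      z <- dp$alpha_a * A / den + base_log[labels[t - 1], ]
    }
    p <- exp(z - max(z))
    labels[t] <- sample.int(K, 1, prob = p)
    da[t] <- stats::rnorm(1, params$syllable_da_mean[labels[t]],
                          params$syllable_da_sd[labels[t]])
    if (!is.null(stim) && labels[t] == stim$target &&
        stats::runif(1) < stim$prob) {
      da[t] <- da[t] + stim$extra_da
      stim_flag[t] <- TRUE
    }
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
  list(labels = labels, da = da, stim = stim_flag)
}

# bi-exponential transient kernel, unit peak, sampled at the frame rate
transient_kernel <- function(params, n_frames = NULL) {
  fr <- params$frame_rate_hz
  tr <- params$transient_rise_ms / 1000
  td <- params$transient_decay_ms / 1000
  if (is.null(n_frames)) n_frames <- ceiling(fr * (tr + 8 * td))
  t <- (seq_len(n_frames) - 1) / fr
  k <- (1 - exp(-t / tr)) * exp(-t / td)
  k / max(k)
}

#' Render two-channel photometry from a syllable sequence
#'
#' The signal channel is a bleaching baseline modulated by the sum of
#' per-instance bi-exponential dopamine transients and shared biphasic
#' artifacts, plus white noise; the reference channel shares the baseline
#' and artifacts (scaled and offset) but not the transients, plus
#' independent noise. Each transient starts at the instance onset and is
#' scaled by the instance's dopamine amplitude.
#'
#' @param labels,onset_frames,da_amplitudes aligned per-instance vectors;
#'   onsets are 0-based frames.
#' @param params [make_generative_params()].
#' @param n_frames total frames to render.
#' @param seed integer seed for noise and artifact draws.
#' @return list of class `photometry_trace` with `sampling_rate_hz`,
#'   `raw_signal`, `raw_reference`, and `provenance`.
#' @export
render_photometry <- function(labels, onset_frames, da_amplitudes, params,
                              n_frames, seed = 1) {
  stopifnot(length(labels) == length(onset_frames),
            length(labels) == length(da_amplitudes))
  if (length(onset_frames) &&
      (min(onset_frames) < 0 || max(onset_frames) >= n_frames))
    stop("onsets out of range")
  set.seed(seed)
  fr <- params$frame_rate_hz
  t_s <- (seq_len(n_frames) - 1) / fr
  baseline <- params$baseline_f0 * exp(-t_s / params$bleach_tau_s)
  kern <- transient_kernel(params)
  trans <- numeric(n_frames)
  for (j in seq_along(onset_frames)) {
    # the transient rises from the instance onset: syllable-associated
    # dopamine peaks within ~300 ms of onset, which is what downstream
    # peak extraction assumes
    start <- onset_frames[j] + 1  # 1-based index
    idx <- start:min(n_frames, start + length(kern) - 1)
    trans[idx] <- trans[idx] +
      params$dff_per_z * da_amplitudes[j] * kern[seq_along(idx)]
  }
  # shared biphasic artifacts at Poisson times (derivative-of-Gaussian bump)
  art <- numeric(n_frames)
  n_art <- stats::rpois(1, params$artifact_rate_hz * n_frames / fr)
  if (n_art > 0) {
    width_s <- 0.3
    tk <- seq(-3 * width_s, 3 * width_s, by = 1 / fr)
    bump <- -tk / width_s * exp(-tk^2 / (2 * width_s^2))
    bump <- bump / max(abs(bump))
    starts <- sort(sample.int(n_frames, n_art))
    for (s0 in starts) {
      idx <- s0:min(n_frames, s0 + length(bump) - 1)
      art[idx] <- art[idx] + params$artifact_amp * bump[seq_along(idx)]
    }
  }
  signal <- baseline * (1 + trans + art) +
    stats::rnorm(n_frames, sd = params$noise_sd)
  reference <- params$reference_gain * baseline * (1 + art) +
    params$reference_offset + stats::rnorm(n_frames, sd = params$noise_sd)
  structure(list(sampling_rate_hz = fr,
                 raw_signal = signal,
                 raw_reference = reference,
                 provenance = list(list(op = "render_photometry",
                                        seed = seed))),
            class = "photometry_trace")
}

#' Simulate kinematic series from a syllable sequence
#'
#' Each channel is a piecewise-constant per-syllable template evaluated at
#' the syllable active in each frame, plus boxcar-smoothed white noise.
#' Acceleration is the frame derivative of 2D velocity.
#'
#' @inheritParams render_photometry
#' @return list of class `kinematic_series` with `velocity_2d`,
#'   `angular_velocity`, `height_velocity`, `acceleration` (length
#'   `n_frames` each).
#' @export
simulate_kinematics <- function(labels, onset_frames, params, n_frames,
                                seed = 1) {
  set.seed(seed)
  fr <- params$frame_rate_hz
  lab_at_frame <- rep(labels[length(labels)], n_frames)
  if (length(onset_frames) > 1) {
    idx <- findInterval(seq_len(n_frames) - 1, onset_frames)
    idx[idx < 1] <- 1
    lab_at_frame <- labels[idx]
  }
  smooth_noise <- function() {
    boxcar_smooth(stats::rnorm(n_frames, sd = params$kin_noise_sd),
                  round(fr / 2))
  }
  v2d <- params$velocity_templates[lab_at_frame] + smooth_noise()
  ang <- params$angular_templates[lab_at_frame] + smooth_noise() / 50
  hgt <- params$height_templates[lab_at_frame] + smooth_noise() / 5
  acc <- c(0, diff(v2d)) * fr
  structure(list(velocity_2d = v2d, angular_velocity = ang,
                 height_velocity = hgt, acceleration = acc),
            class = "kinematic_series")
}

#' Simulate one complete session
#'
#' Draws a syllable sequence with dopamine feedback, log-normal instance
#' durations (median `duration_median_ms`), renders photometry and
#' kinematics on the shared 30 Hz frame base, and stores the ground truth.
#'
#' @param params [make_generative_params()].
#' @param n_steps syllable instances per session.
#' @param seed integer seed.
#' @param stim optional closed-loop rule (see [simulate_syllable_sequence()]).
#' @param phase session phase label ("baseline", "stimulation" or "post").
#' @return list of class `session_bundle`.
#' @export
simulate_session <- function(params, n_steps = 1500, seed = 1, stim = NULL,
                             phase = "baseline") {
  seq_out <- simulate_syllable_sequence(params, n_steps, seed = seed,
                                        stim = stim)
  set.seed(child_seed(seed, 101))
  fr <- params$frame_rate_hz
  med_frames <- params$duration_median_ms / 1000 * fr
  durations <- pmax(1, round(stats::rlnorm(n_steps, log(med_frames),
                                           params$duration_dispersion)))
  onsets <- c(0, cumsum(durations[-n_steps]))
  n_frames <- sum(durations)
  phot <- render_photometry(seq_out$labels, onsets, seq_out$da, params,
                            n_frames, seed = child_seed(seed, 202))
  kin <- simulate_kinematics(seq_out$labels, onsets, params, n_frames,
                             seed = child_seed(seed, 303))
  structure(list(labels = seq_out$labels,
                 onset_frames = onsets,
                 duration_frames = durations,
                 da_amplitudes = seq_out$da,
                 stim = seq_out$stim,
                 phase = phase,
                 target = if (is.null(stim)) NA_integer_ else stim$target,
                 photometry = phot,
                 kinematics = kin,
                 truth = params),
            class = "session_bundle")
}

#' Simulate a closed-loop stimulation experiment
#'
#' Six sessions on the three-day schedule: two baseline, two stimulation,
#' two post. During stimulation sessions each target instance is stimulated
#' with probability `stim_prob` (default 0.75), adding `extra_da` z-units to
#' its dopamine amplitude before the sequence continues; unstimulated target
#' instances are the catch trials.
#'
#' @param params [make_generative_params()].
#' @param target target syllable (1-based, <= K).
#' @param extra_da added dopamine on stimulated instances (z-units).
#' @param seed integer master seed; per-session streams are derived from it.
#' @param n_steps syllable instances per session.
#' @param stim_prob stimulation delivery probability.
#' @return list of six `session_bundle`s with `phase` set.
#' @export
simulate_closed_loop_experiment <- function(params, target, extra_da,
                                            seed = 1, n_steps = 1500,
                                            stim_prob = 0.75) {
  if (target > params$n_syllables) stop("target must be <= K")
  phases <- c("baseline", "baseline", "stimulation", "stimulation",
              "post", "post")
  lapply(seq_along(phases), function(k) {
    stim <- if (phases[k] == "stimulation")
      list(target = target, prob = stim_prob, extra_da = extra_da)
    else NULL
    simulate_session(params, n_steps, seed = child_seed(seed, k),
                     stim = stim, phase = phases[k])
  })
}

#' Write a session bundle to a directory of plain-text files
#'
#' Emits `syllables.tsv`, `photometry.tsv`, `kinematics.tsv`, `stim.tsv`
#' and `truth.json`.
#'
#' @param session a `session_bundle`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  syl <- data.frame(instance_index = seq_along(session$labels) - 1L,
                    syllable = session$labels,
                    onset_frame = session$onset_frames,
                    duration_frames = session$duration_frames,
                    da_amp = session$da_amplitudes)
  utils::write.table(syl, file.path(dir, "syllables.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  phot <- data.frame(frame = seq_along(session$photometry$raw_signal) - 1L,
                     signal = session$photometry$raw_signal,
                     reference = session$photometry$raw_reference)
  utils::write.table(phot, file.path(dir, "photometry.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  kin <- data.frame(frame = phot$frame,
                    velocity_2d = session$kinematics$velocity_2d,
                    angular_velocity = session$kinematics$angular_velocity,
                    height_velocity = session$kinematics$height_velocity,
                    acceleration = session$kinematics$acceleration)
  utils::write.table(kin, file.path(dir, "kinematics.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  stim <- data.frame(instance_index = syl$instance_index,
                     stim = as.integer(session$stim))
  utils::write.table(stim, file.path(dir, "stim.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  truth <- unclass(session$truth)
  truth$base_transitions <- as.data.frame(truth$base_transitions)
  meta <- list(phase = session$phase, target = session$target,
               truth = truth)
  jsonlite::write_json(meta, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a session bundle written by [write_session()]
#'
#' @param dir session directory.
#' @return a `session_bundle` (without kinematic/photometry classes applied
#'   to derived fields beyond the stored columns).
#' @export
read_session <- function(dir) {
  syl <- utils::read.table(file.path(dir, "syllables.tsv"), header = TRUE,
                           sep = "\t")
  phot <- utils::read.table(file.path(dir, "photometry.tsv"), header = TRUE,
                            sep = "\t")
  kin <- utils::read.table(file.path(dir, "kinematics.tsv"), header = TRUE,
                           sep = "\t")
  stim <- utils::read.table(file.path(dir, "stim.tsv"), header = TRUE,
                            sep = "\t")
  meta <- jsonlite::read_json(file.path(dir, "truth.json"),
                              simplifyVector = TRUE)
  truth <- meta$truth
  truth$base_transitions <- as.matrix(truth$base_transitions)
  dimnames(truth$base_transitions) <- NULL
  structure(list(labels = syl$syllable,
                 onset_frames = syl$onset_frame,
                 duration_frames = syl$duration_frames,
                 da_amplitudes = syl$da_amp,
                 stim = as.logical(stim$stim),
                 phase = meta$phase,
                 target = meta$target,
                 photometry = structure(
                   list(sampling_rate_hz = truth$frame_rate_hz,
                        raw_signal = phot$signal,
                        raw_reference = phot$reference,
                        provenance = list()),
                   class = "photometry_trace"),
                 kinematics = structure(
                   list(velocity_2d = kin$velocity_2d,
                        angular_velocity = kin$angular_velocity,
                        height_velocity = kin$height_velocity,
                        acceleration = kin$acceleration),
                   class = "kinematic_series"),
                 truth = structure(truth, class = "generative_params")),
            class = "session_bundle")
}

#' Empirical transition matrix of a label sequence
#'
#' @param labels integer sequence in `1..K`.
#' @param K number of syllables.
#' @return `K x K` row-stochastic matrix (rows with no outgoing transitions
#'   are all zero); the diagonal is zero whenever the sequence has no
#'   self-transitions.
#' @export
empirical_transition_matrix <- function(labels, K) {
  M <- matrix(0, K, K)
  if (length(labels) >= 2) {
    from <- labels[-length(labels)]
    to <- labels[-1]
    for (j in seq_along(from)) M[from[j], to[j]] <- M[from[j], to[j]] + 1
  }
  rs <- rowSums(M)
  M[rs > 0, ] <- M[rs > 0, , drop = FALSE] / rs[rs > 0]
  M
}
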
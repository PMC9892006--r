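#!/usr/bin/env Rscript

# Predict dopamine from behaviour: (1) the averaged model - binned
# behavioural features, ZCA-whitened, fed to a Bayesian linear regression;
# (2) the instantaneous model - convolution kernels from kinematic and
# sequence features to the smoothed dopamine trace.

suppressPackageStartupMessages(library(dopaseq))

peaks <- read.table("results/peaks.tsv", header = TRUE, sep = "\t")
sessions <- split(peaks, peaks$session)

# averaged encoding: one row per (mouse, syllable, bin size)
feats <- build_binned_features(sessions,
                               bin_sizes = c(5, 10, 25, 50, 100, 200))
X <- as.matrix(feats[, c("counts", "entropy", "velocity")])
fit <- fit_binned_encoding(X, feats$peak, seed = 1)
enc <- data.frame(feature = c("counts", "entropy", "velocity"),
                  beta = fit$beta_mean, beta_sd = fit$beta_sd)
write.table(enc, "results/encoding_binned.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

# instantaneous encoding on two sessions: features are framewise syllable
# frequency (50-step smoothed one-hot pooled), velocity and acceleration
dirs <- list.dirs("results/sessions", recursive = FALSE)[1:2]
kernel_sessions <- lapply(dirs, function(d) {
  b <- read_session(d)
  tr <- preprocess_photometry(b$photometry, seed = 1)
  n_frames <- length(tr$zscored)
  # instantaneous syllable rate: instances per frame, boxcar-smoothed
  onset_marks <- numeric(n_frames)
  onset_marks[b$onset_frames + 1] <- 1
  freq <- boxcar_smooth(onset_marks, 60) * 30
  list(features = cbind(frequency = freq,
                        velocity = b$kinematics$velocity_2d,
                        acceleration = b$kinematics$acceleration),
       dlight = tr$zscored)
})
kfit <- fit_kernel_encoding(kernel_sessions, max_lag = 60)
kern <- data.frame(lag_frames = kfit$lags,
                   frequency = kfit$kernels[, 1],
                   velocity = kfit$kernels[, 2],
                   acceleration = kfit$kernels[, 3])
write.table(kern, "results/kernels.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)

jsonlite::write_json(list(binned_heldout_r = fit$heldout_r,
                          kernel_heldout_r = kfit$heldout_r),
                     "results/encoding_summary.json", auto_unbox = TRUE,
                     digits = NA)

message(sprintf("binned model held-out r = %.2f", fit$heldout_r))
message(sprintf("kernel model held-out r = %.2f", kfit$heldout_r))
message("wrote results/encoding_binned.tsv, kernels.tsv, encoding_summary.json")
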
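#!/usr/bin/env Rscript

# Relate syllable-associated dopamine peaks to future behaviour: the
# expanding-bin correlation curves (usage counts and sequence entropy),
# exponential-decay timescales, the dopamine/usage cross-correlation, and
# per-mouse endogenous-dopamine influence indices.

suppressPackageStartupMessages(library(dopaseq))

peaks <- read.table("results/peaks.tsv", header = TRUE, sep = "\t")
if (nrow(peaks) == 0) stop("run analysis/02_photometry.R first")

bins <- c(5, 10, 25, 50, 100, 200)
sessions <- split(peaks, peaks$session)

curve_rows <- list()
influence_rows <- list()
for (id in names(sessions)) {
  tab <- sessions[[id]]
  for (outcome in c("counts", "entropy")) {
    cur <- expanding_bin_correlation(tab, outcome, bins, n_shuffles = 50,
                                     seed = 3)
    cur$session <- id
    cur$outcome <- outcome
    curve_rows[[paste(id, outcome)]] <- cur
  }
  influence_rows[[id]] <- data.frame(
    session = id,
    count_influence = endo_da_influence(tab, "counts", bins,
                                        n_shuffles = 50, seed = 4),
    entropy_influence = endo_da_influence(tab, "entropy", bins,
                                          n_shuffles = 30, seed = 4))
}
curves <- do.call(rbind, curve_rows)
write.table(curves, "results/curves.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
infl <- do.call(rbind, influence_rows)
write.table(infl, "results/influence.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)

# decay timescale across session curves (replicate bootstrap)
cnt <- curves[curves$outcome == "counts", ]
rep_mat <- do.call(rbind, lapply(split(cnt$r_z, cnt$session), rbind))
fit <- fit_decay_tau(data.frame(bin_size = bins,
                                r_raw = colMeans(rep_mat)),
                     replicates = rep_mat, n_boot = 300, seed = 5)
writeLines(sprintf("counts-curve decay tau: %.1f syllable steps", fit$tau),
           "results/decay.txt")

# dopamine/usage cross-correlation for the longest session
big <- sessions[[which.max(vapply(sessions, nrow, 1L))]]
cc <- cross_correlation_usage(big, window_s = 60, lags = -4:4,
                              n_shuffles = 50, seed = 6)
write.table(cc, "results/crosscorr.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)

message(sprintf("peak shuffle-z of counts curves: %.1f",
                max(curves$r_z[curves$outcome == "counts"])))
message(sprintf("count influence %.2f vs entropy influence %.2f (means)",
                mean(infl$count_influence),
                mean(infl$entropy_influence)))
message(sprintf("cross-correlation peak at lag %d windows",
                cc$lag[which.max(cc$r)]))
message("wrote results/curves.tsv, influence.tsv, decay.txt, crosscorr.tsv")
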
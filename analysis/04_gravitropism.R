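#!/usr/bin/env Rscript
# Stage 4: relate the kinematic traits to gravitropism.
#
# For each of the two tip-angle experiments: PCA of the 241-point curves
# (first five PC scores), maximum swing rate per RIL, Pearson correlations of
# traits with PC1 and swing rate, and canonical correlation analysis of the
# z-scored kinematic traits against the five PC scores with a
# 1000-permutation 5% threshold. Writes pc_scores_exp*.csv,
# correlations_exp*.csv, cca_exp*.csv.

source("analysis/config.R")

cfg <- study_config()
traits <- read_phenotypes_csv(file.path(RESULTS_DIR, "traits.csv"))
x_block <- as.matrix(traits[, c("regr_max", "elongation_rate",
                                "regr_max_position", "zone_length")])
rownames(x_block) <- traits$ril

for (e in seq_len(cfg$n_experiments)) {
  curves <- read_curves_csv(file.path(RESULTS_DIR,
                                      sprintf("tip_angles_exp%d.csv", e)))
  curves <- curves[traits$ril, , drop = FALSE]
  pc <- pca_curves(curves, cfg$n_pcs)
  swing <- apply(curves, 1, max_swing_rate, window = cfg$swing_window)
  write_phenotypes_csv(
    data.frame(ril = traits$ril, pc$scores, max_swing_rate = swing),
    file.path(RESULTS_DIR, sprintf("pc_scores_exp%d.csv", e)))

  corr <- pearson_matrix(cbind(x_block, PC1 = pc$scores[, 1],
                               max_swing_rate = swing))
  write.csv(round(corr, 4),
            file.path(RESULTS_DIR, sprintf("correlations_exp%d.csv", e)))

  sol <- cca(x_block, pc$scores)
  thr <- cca_permutation_threshold(x_block, pc$scores, cfg$cca_n_perm,
                                   seed = substream_seed(cfg$seed,
                                                         paste0("cca_", e)))
  write.csv(data.frame(experiment = e, t(sol$x_weights),
                       correlation = sol$correlation,
                       threshold = as.numeric(thr)),
            file.path(RESULTS_DIR, sprintf("cca_exp%d.csv", e)),
            row.names = FALSE)

  cat(sprintf("\nExperiment %d\n", e))
  cat(sprintf("  PC1 %.1f%% of curve variance; PCs 1-3 %.1f%%.\n",
              100 * pc$variance_share[1], 100 * sum(pc$variance_share[1:3])))
  cat(sprintf("  Trait vs PC1 Pearson r: %s.\n",
              paste(sprintf("%s %.2f", colnames(x_block),
                            corr[colnames(x_block), "PC1"]), collapse = ", ")))
  cat(sprintf("  Max swing rate %.0f-%.0f deg/h across RILs.\n",
              min(swing), max(swing)))
  cat(sprintf("  CCA: r = %.3f vs 5%% permutation threshold %.3f (%s).\n",
              sol$correlation, as.numeric(thr),
              if (sol$correlation >= as.numeric(thr)) "significant" else
                "not significant"))
  cat(sprintf("  Trait weights: %s.\n",
              paste(sprintf("%s %.2f", names(sol$x_weights), sol$x_weights),
                    collapse = ", ")))
}
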
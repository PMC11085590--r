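#!/usr/bin/env Rscript
# Stage 1: simulate the study population.
#
# Generates the genetic map, RIL genotypes, true velocity-profile parameters
# with three planted QTL, and tip-angle curves for two gravitropism
# experiments. Replicate velocity clouds are deterministic from the same seed
# and are rebuilt on demand by stage 2 rather than written out here (1,120
# clouds); one example cloud is written for inspection.

source("analysis/config.R")

cfg <- study_config()
pop <- simulate_population(cfg)

write_map_csv(pop$map, file.path(RESULTS_DIR, "map.csv"))
write_genotypes_csv(pop$genotypes, file.path(RESULTS_DIR, "genotypes.csv"))
write_phenotypes_csv(pop$params_true, file.path(RESULTS_DIR, "params_true.csv"))
for (e in seq_along(pop$curves)) {
  write_curves_csv(pop$curves[[e]],
                   file.path(RESULTS_DIR, sprintf("tip_angles_exp%d.csv", e)))
}
write_cloud_csv(pop$clouds[[1]][[1]],
                file.path(RESULTS_DIR, "example_cloud_ril001_rep1.csv"))

af <- mean(pop$genotypes == "BB", na.rm = TRUE)
cat(sprintf("Simulated %d RILs x %d markers on %d chromosomes (seed %d).\n",
            nrow(pop$genotypes), ncol(pop$genotypes),
            length(unique(pop$map$chromosome)), cfg$seed))
cat(sprintf("Genome-wide BB allele frequency %.3f; %.1f%% genotype calls missing.\n",
            af, 100 * mean(is.na(pop$genotypes))))
cat(sprintf("Planted QTL: %s.\n",
            paste(sprintf("%s@%.1f on %s", cfg$planted_qtl$chromosome,
                          cfg$planted_qtl$position, cfg$planted_qtl$parameter),
                  collapse = ", ")))
cat(sprintf("%d replicate clouds per RIL; %d tip-angle experiments of 241 points.\n",
            cfg$n_replicates, length(pop$curves)))
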
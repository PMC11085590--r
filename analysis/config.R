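# Shared settings for the numbered analysis scripts.
#
# One master seed drives every stage through named substreams, so each script
# can rebuild exactly the same simulated population instead of passing large
# intermediates around. Tables flow between scripts as CSV under results/.

library(kinqtl)

RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, showWarnings = FALSE, recursive = TRUE)

study_config <- function(seed = 7) {
  # Study-scale defaults: 160 RILs, 234 markers on 5 chromosomes, 7 replicate
  # roots per RIL, 120-point velocity clouds, 1-cM pseudomarker grid,
  # 1000-permutation thresholds, two gravitropism experiments.
  pipeline_config(seed = seed, n_replicates = 7)
}
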
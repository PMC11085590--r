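# kinqtl

Quantitative genetics of root growth kinematics. `kinqtl` takes per-root
velocity point clouds — displacement velocity of root material versus
distance from the tip, the standard output of kinematic image analysis of a
growing Arabidopsis root — and carries them through a complete analysis for a
recombinant inbred line (RIL) population:

1. **Kinematics.** Fit the flexible logistic velocity profile
   `v(x) = vf · [1 + e^(−k(x−x0))]^(−1/n)` to each root by bounded
   least squares, average fitted parameters across replicate roots per RIL,
   and extract four traits of the elongation zone from the analytic REGR
   curve (REGR = dv/dx, the local strain rate): elongation rate `vf`,
   maximum REGR `vf·k·(1+n)^(−(1+1/n))`, its position `x0 − ln(n)/k`, and
   the zone length (width where REGR ≥ 20% of its peak).
2. **QTL mapping.** Hidden-Markov genotype probabilities for a selfed RIL
   cross on a 1-cM pseudomarker grid (Haldane map, RIL recombination
   fraction `R = 2r/(1+2r)`, genotyping error rate 0.001), single-QTL
   Haley–Knott genome scans (`LOD = (N/2)·log10(RSS0/RSS1)`), genome-wide
   permutation thresholds, peaks with 1.5-LOD support intervals, and joint
   variance explained per trait.
3. **Gravitropism.** PCA of 241-point tip-angle time courses, maximum swing
   rate, Pearson trait correlations, and permutation-tested canonical
   correlation analysis between the four kinematic traits and the first five
   PC scores.

A synthetic-data module simulates the whole study design — RIL genomes,
planted QTL, replicate velocity clouds, paired gravitropism experiments —
under one seed, so every stage is testable from scratch. The intended users
are plant quantitative geneticists and growth-kinematics labs who want a
reproducible, tested reference implementation of this analysis chain.

## Worked example: the full analysis

The numbered scripts under `analysis/` run the four stages over a simulated
study-scale population (160 RILs × 234 markers, 7 replicate roots per RIL)
and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_fit_kinematics.R
Rscript analysis/03_qtl_scan.R
Rscript analysis/04_gravitropism.R
```

Stage 2 prints the per-RIL trait summary:

```
Fitted 160 RILs; replicates used per RIL: 6-7 (non-converged excluded).
Elongation rate 0.12-0.29 mm/h | max REGR 24.19-75.86 %/h | peak position 0.04-0.53 mm | zone length 0.37-0.99 mm
Median relative error of recovered vf vs truth: 1.36%.
```

Stage 3 maps the planted QTL (1@21.5 on `x0`, 3@39.7 on `k`, 5@76.7 on `vf`)
back out of the noisy phenotypes:

```
elongation_rate    threshold 2.74 | 2 QTL | 22.4% variance explained
regr_max           threshold 2.62 | 2 QTL | 27.6% variance explained
regr_max_position  threshold 2.57 | 1 QTL | 14.7% variance explained
zone_length        threshold 2.78 | 1 QTL | 18.5% variance explained

Significant QTL (trait, chr@pos, LOD, 1.5-LOD interval):
  elongation_rate    5@73.1  LOD 8.6  [70.7, 78.2]
  ...
  regr_max_position  1@21.6  LOD 5.5  [19.9, 26.1]
```

Each line gives the genome-wide 5% permutation threshold (1000 permutations),
the peaks clearing it, and the R² of the joint regression on the peak
genotype probabilities. The planted loci are recovered at their true
positions, inside the 1.5-LOD intervals; the extra `elongation_rate` peak on
chromosome 5 at 99 cM is linkage shoulder from the same planted locus.

Stage 4 relates kinematics to gravitropism:

```
Experiment 1
  PC1 68.1% of curve variance; PCs 1-3 87.0%.
  Trait vs PC1 Pearson r: regr_max 0.33, elongation_rate 0.10, regr_max_position -0.04, zone_length -0.29.
  CCA: r = 0.503 vs 5% permutation threshold 0.341 (significant).
```

No single trait correlates strongly with PC1 of the response curves, yet the
canonical combination of the four traits clears its permutation threshold in
both experiments — the generator plants exactly this structure (a weak
coupling to a trait *combination*), and the analysis detects it.

The same pipeline runs as one call (`run_pipeline(pipeline_config(seed = 7),
"out/")`), writing every table plus the resolved configuration and a log.
Rerunning any stage with the same seed reproduces the numbers byte for byte.

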
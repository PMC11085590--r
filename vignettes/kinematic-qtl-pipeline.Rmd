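---
title: "Kinematics of the root elongation zone and its QTL: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinematics of the root elongation zone and its QTL: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinqtl)
```

## The scientific problem

Root elongation is driven by cell expansion in a short elongation zone just
behind the tip. Time-lapse imaging of a growing root yields, for each trial, a
*velocity point cloud*: displacement velocity $v$ of root material versus
distance from the tip $x$, in the tip's frame of reference. The spatial
derivative of the velocity profile is the relative elemental growth rate
(REGR) — the local strain rate of the tissue — and the REGR curve defines the
size, shape and position of the elongation zone.

This package implements a complete quantitative-genetics pipeline over such
data for a recombinant inbred line (RIL) population: fit a parametric velocity
model per root, reduce each line to four kinematic traits, map quantitative
trait loci (QTL) for those traits, and ask whether the kinematic make-up of a
vertically growing root predicts its gravitropic bending response. A
synthetic-data module simulates every input at the scale of the study design
(≈160 RILs, 234 markers on five chromosomes, 7–10 replicate roots per line),
so the whole pipeline can be exercised, calibrated and tested from scratch.

## The velocity model and the four kinematic traits

The flexible logistic function models the sigmoid rise of velocity from the
quiescent center to the mature-zone plateau:

$$v(x) = v_f\,\left[1 + e^{-k (x - x_0)}\right]^{-1/n}$$

with plateau velocity $v_f$ (mm/h; equal to the root elongation rate),
location $x_0$ (mm), steepness $k$ (mm$^{-1}$) and asymmetry $n$ (unitless).
REGR is its derivative,

$$\mathrm{REGR}(x) = v_f \frac{k}{n}\, u\,(1+u)^{-(1+1/n)}, \qquad
  u = e^{-k(x-x_0)},$$

reported in %/h. Closed forms used throughout (and verified against dense
numeric grids in the tests):

* peak position: $x_\mathrm{peak} = x_0 - \ln(n)/k$;
* peak value: $\mathrm{REGR}_{\max} = v_f\,k\,(1+n)^{-(1+1/n)}$;
* elongation rate: $v_f$.

The length of the growth zone has no closed form and is not operationally
defined in the kinematics literature with a single convention; here it is the
width of the region where REGR exceeds a fixed fraction (default
`zone_fraction = 0.2`) of its peak, found by bracketed bisection on each flank
of the peak to $10^{-9}$ mm. The default fraction yields zone lengths in the
0.25–0.8 mm range reported for Arabidopsis RIL populations under plausible
parameter values; the fraction is exposed in the configuration.

### Fitting

`fit_velocity_profile()` performs bounded least squares (Levenberg–Marquardt,
`minpack.lm`) with positivity bounds on $v_f$, $k$, $n$. Starting values are
data heuristics: $v_f^{(0)}$ the 95th percentile of $v$; $x_0^{(0)}$ the first
$x$ where $v$ crosses $v_f^{(0)}/2$; $k^{(0)}$ from the local slope there
scaled by $4/v_f^{(0)}$; $n^{(0)} = 1$. The fit is plain least squares by
default; one pass of 3·MAD residual rejection with a refit is available behind
`reject_outliers`. Non-convergence is flagged, never hidden, and non-converged
replicates are excluded before averaging.

Each RIL is summarised by the arithmetic mean of its replicates' fitted
parameters, and the four traits are computed **from the averaged parameters**
(not by averaging per-replicate traits); both orders are possible with the
exported functions, but the averaged-parameter order is the package
convention because the averaged curve is the line's kinematic description.

The $x$ coordinate convention is 0-based distance from the root tip
(quiescent center), increasing shootward, in millimetres. Whether a real
dataset's origin is the quiescent center or the visible apex is an input
convention, not something the pipeline can decide.

## QTL mapping

Genotype uncertainty is handled by a hidden Markov model over states
{AA, BB} at every position of a pseudomarker grid (true markers plus evenly
spaced synthetic positions so no gap exceeds 1 cM). Fully inbred lines are
assumed — two genotype classes, residual heterozygosity ignored. Transitions
between positions $d$ cM apart use the RIL-by-selfing recombination fraction

$$R = \frac{2r}{1+2r}, \qquad r = \tfrac12\left(1 - e^{-2d/100}\right)$$

(Haldane map function, no interference — the standard closed-form choice,
consistent between the simulator and the HMM). Emissions allow a symmetric
genotyping error rate (default 0.001); missing calls and pseudomarkers are
uninformative. The forward–backward posteriors are validated in the tests
against exhaustive enumeration over all hidden paths on small chromosomes.

`hk_scan()` implements single-QTL Haley–Knott regression: at each grid
position the phenotype is regressed on $P(\mathrm{BB})$ (for a two-class
inbred cross, using both class probabilities would be collinear with the
intercept), and

$$\mathrm{LOD} = \frac{N}{2}\,\log_{10}\frac{\mathrm{RSS}_0}{\mathrm{RSS}_1}.$$

Genome-wide 5% significance thresholds come from permuting the phenotype
vector against the RIL rows (preserving genotype correlation structure) and
taking the 0.95 empirical quantile of the per-permutation maximum LOD; the
batched implementation evaluates all permutations in one matrix product, so
large permutation counts are cheap. Peaks at or above the threshold are
reported with 1.5-LOD support intervals (the contiguous region around the
peak within 1.5 LOD units); two peaks on one chromosome are kept separate
only if the LOD dips by more than the drop between them, and exact ties go to
the leftmost grid position for determinism. The additive effect is half the
fitted difference between genotype-class means. Variance explained per trait
is the $R^2$ of a **joint** multiple regression on $P(\mathrm{BB})$ at all of
that trait's peaks — a single-QTL $R^2$ sum would double-count correlated
loci.

## Gravitropism: PCA, swing rate, CCA

Tip-angle curves (241 samples, every 2 min for 8 h after a 90° rotation) are
summarised by principal components of the column-centered curve matrix. No
column standardization is applied before PCA — all entries share units
(degrees) — while z-scoring is applied at the CCA step. Component signs are
fixed so each loading vector has a positive sum; correlations involving PC
scores are therefore reported under a stated, reproducible convention.

The maximum swing rate is the peak rate of change of tip angle, computed as
the slope of a least-squares line over a sliding window (default 5 frames =
10 min), in degrees/h. Windowed regression was chosen over a raw first
difference to damp frame-level noise; the window is exposed.

Canonical correlation analysis relates the four kinematic traits to the first
five PC scores. Both blocks are z-scored; the first canonical pair comes from
the SVD of the whitened cross-covariance
$S_{xx}^{-1/2} S_{xy} S_{yy}^{-1/2}$ (Cholesky whitening), weights are scaled
so the canonical variates have unit variance, and the sign is fixed so the
weight on maximum REGR is positive. Significance uses a permutation null: the
gravitropism block's rows are permuted (equivalent to permuting either block
under exchangeability), the first canonical correlation recomputed 1000
times, and the 0.95 quantile reported as the threshold. Rank-deficient blocks
are rejected with the offending columns named.

Pearson correlations use pairwise-complete observations; CCA uses
listwise-complete rows only.

## The synthetic-data generator

The generator's defaults are the study conditions, fixed once:

* **Genome**: five chromosomes of 135/75/90/80/105 cM, 234 markers allocated
  proportionally with jittered spacing; RIL genomes simulated as AA/BB
  mosaics with the same Haldane/selfing transition model the HMM assumes;
  3% missing calls.
* **Population**: 160 RILs, 7 replicate roots per line in the demo runs
  (the design range is 7–10), 120-point velocity clouds over 0–1.5 mm with
  Gaussian velocity noise of 0.02 mm/h, and a 5% lognormal replicate jitter
  of the line's true parameters emulating biological replicate variation.
* **Genetic architecture**: baselines $v_f = 0.20$ mm/h, $x_0 = 0.40$ mm,
  $k = 9$ mm$^{-1}$, $n = 1.1$ (REGR peaks ≈45%/h at ≈0.4 mm — the center of
  the ranges such populations display); three planted additive QTL, one each
  on $x_0$ (chr 1 @ 21.5 cM), $k$ (chr 3 @ 39.7 cM) and $v_f$
  (chr 5 @ 76.7 cM), with effects of 0.7 trait-SD. Real effect sizes are
  unknown, so these are placeholders sized for power studies. Broad-sense
  heritability defaults to 0.7 per parameter: environmental noise is scaled
  from the expected genetic variance, and non-positive parameter draws are
  resampled rather than clipped to avoid point masses at zero.
* **Trait correlations**: the polygenic terms share a latent "vigor" factor
  (loadings +0.8 on $v_f$, +0.6 on $x_0$, −0.7 on $k$, 0 on $n$):
  vigorous lines elongate faster with longer zones and more basal peaks,
  reproducing the strong positive elongation-rate/zone-length correlation
  characteristic of such populations.
* **Gravitropism**: per-RIL curves follow a lagged saturating family
  $\theta(t) = A\,(1 - e^{-r\,\max(t-\ell,\,0)})$ with genetic values for
  (lag $\ell$, rate $r$, asymptote $A$) shared across the two experiments
  plus experiment-specific deviations and AR(1) measurement noise. The
  curves are not modelled parametrically in the kinematics literature; any
  family reproducing the PC1-dominated population structure is adequate, and
  this one concentrates variation in the rate so PC1 carries most of the
  variance. The rate is weakly coupled (strength 0.6) to the genetic
  contrast $v_f + k$, which is nearly orthogonal to the vigor factor: no
  single kinematic trait then predicts the response well, but a weighted
  combination does — the structure a permutation-tested CCA is designed to
  detect.

**What passing tests do and do not show.** The generator reproduces the
study-scale *statistical* structure: per-trait QTL-model variance explained
in the 15–30% band, a PC1 share near 70%, a significant CCA against a ≈0.35
permutation threshold, and positive rate/zone-length correlation. It does not
reproduce every pairwise trait correlation of real data (its zone-length vs
max-REGR correlation is negative, because zone length is driven almost
entirely by $k$ in this family), nor image-level artifacts, segregation
distortion, epistasis, or maternal effects across gravitropism experiments.
Green tests therefore certify the estimators and their calibration under the
assumed generating model, not biological conclusions about real populations.

## Numerical choices and degenerate inputs

* Velocity and REGR are evaluated on the log scale, so extreme arguments
  ($|k(x-x_0)| \gg 1$) neither overflow nor lose the tails.
* Zone boundaries: outward doubling walk from the peak to bracket, then
  bisection (`uniroot`, tol $10^{-9}$ mm). A bracketing failure is impossible
  for valid parameters (REGR is unimodal with vanishing tails) but guarded.
* Zero-variance phenotypes scan to LOD ≡ 0; monomorphic grid positions get
  LOD 0 rather than 0/0.
* Permutation thresholds and CCA nulls are seeded; every stage of the
  pipeline derives a named substream from the single master seed, so reruns
  are byte-identical and stages are insensitive to each other's draw counts.
* LOD ties at a peak resolve to the leftmost grid position.
* Exact-threshold peaks count as significant (comparison is ≥).

## Problem sizes used in the shipped runs

The demo analysis and the acceptance checks run at the study scale for the
population (160 RILs, 234 markers, 1-cM grid, 7 replicates) with
1000-permutation thresholds; the genome-scan and CCA calibration experiments
use 500 replicate null datasets, fit recovery uses 200 seeded clouds, and
HMM validation enumerates hidden paths on chromosomes of up to 12 positions.
The full 25,000-permutation setting of a production scan is a configuration
change (`n_perm`), not a code change; thresholds stabilise well below that
for the purposes of the shipped analyses.

## Known limitations

* Single-QTL scans only: no multi-QTL model search, no 2-D interaction
  scans, no composite interval mapping.
* Fully inbred two-class genotypes; no X-chromosome special-casing, no
  segregation distortion.
* The velocity model is time-stationary; saltatory back-and-forth motion of
  the elongation zone is outside its scope.
* CCA reports the first canonical pair only, with a permutation threshold
  for its correlation; higher pairs are not tested.
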
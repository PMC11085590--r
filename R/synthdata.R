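#' Simulate RIL genotypes as parental mosaics
#'
#' Each recombinant inbred line (RIL) produced by repeated selfing is a fixed
#' mosaic of the two parental genomes, here coded "AA" and "BB". Along a
#' chromosome, adjacent markers separated by d cM recombine with the
#' RIL-by-selfing fraction R = 2r/(1+2r), where r is the Haldane meiotic
#' fraction r = (1 - exp(-2d/100))/2. Chromosomes are independent and the
#' first marker of each chromosome is an unbiased coin flip, so simulated
#' allele frequencies are ~0.5 genome-wide. Residual heterozygosity is
#' ignored (lines are treated as fully inbred).
#'
#' @param map A `genetic_map`.
#' @param n_rils Number of lines to simulate (>= 2).
#' @param missing_rate Fraction of genotype calls masked to NA, uniformly at
#'   random. Default 0.
#' @param seed Integer seed; fixed seed gives identical output.
#' @return Character matrix (RIL x marker) with values "AA"/"BB"/NA, row
#'   names `RIL_001`... and column names from the map.
#' @export
simulate_ril_genotypes <- function(map, n_rils, missing_rate = 0, seed = 1) {
  map <- validate_map(map)
  if (!is.numeric(n_rils) || length(n_rils) != 1L || n_rils < 2) {
    stop("`n_rils` must be a single number >= 2", call. = FALSE)
  }
  n_rils <- as.integer(n_rils)
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("`missing_rate` must be in [0, 1)", call. = FALSE)
  }
  chrs <- split_by_chr(map)
  with_seed(substream_seed(seed, "genotypes"), {
    blocks <- lapply(chrs, function(chr) {
      m <- nrow(chr)
      g <- matrix(0L, n_rils, m)
      g[, 1L] <- stats::rbinom(n_rils, 1L, 0.5)
      if (m > 1L) {
        R <- ril_selfing_R(haldane_r(diff(chr$position)))
        for (j in 2L:m) {
          flip <- stats::rbinom(n_rils, 1L, R[j - 1L])
          g[, j] <- (g[, j - 1L] + flip) %% 2L
        }
      }
      g
    })
    geno <- do.call(cbind, blocks)
    out <- matrix(c("AA", "BB")[geno + 1L], n_rils, ncol(geno),
                  dimnames = list(sprintf("RIL_%03d", seq_len(n_rils)),
                                  map$marker))
    if (missing_rate > 0) {
      mask <- stats::runif(length(out)) < missing_rate
      out[mask] <- NA_character_
    }
    out
  })
}

#' Default planted-QTL architecture for the demo population
#'
#' Three additive QTL, one per velocity-profile parameter family, at the
#' genome positions where the strongest kinematic-trait loci of the Cvi x Ler
#' study sit (chromosome 1 at 21.5 cM, chromosome 3 at 39.7 cM, chromosome 5
#' at 76.7 cM). Effects are in trait-SD units; sizes are placeholders for
#' power studies, not estimates.
#'
#' @return data.frame with columns chromosome, position, parameter, effect.
#' @export
default_planted_qtl <- function() {
  data.frame(
    chromosome = c("1", "3", "5"),
    position = c(21.5, 39.7, 76.7),
    parameter = c("x0", "k", "vf"),
    effect = c(0.7, 0.7, 0.7),
    stringsAsFactors = FALSE
  )
}

# snap each planted QTL to the nearest marker on its chromosome; error if the
# chromosome is absent from the map
snap_qtl_to_markers <- function(qtl, map) {
  if (is.null(qtl) || nrow(qtl) == 0L) {
    return(data.frame(chromosome = character(), position = numeric(),
                      parameter = character(), effect = numeric(),
                      marker = character(), stringsAsFactors = FALSE))
  }
  for (i in seq_len(nrow(qtl))) {
    chr <- map[map$chromosome == as.character(qtl$chromosome[i]), ]
    if (nrow(chr) == 0L) {
      stop(sprintf("planted QTL on unknown chromosome '%s'",
                   qtl$chromosome[i]), call. = FALSE)
    }
    j <- which.min(abs(chr$position - qtl$position[i]))
    qtl$marker[i] <- chr$marker[j]
    qtl$position[i] <- chr$position[j]
  }
  qtl
}

#' Simulate per-RIL true velocity-profile parameters with planted QTL
#'
#' Each of the four flexible-logistic parameters (vf, x0, k, n) is modelled
#' as baseline x (1 + relative deviation). The deviation for a RIL is the sum
#' of planted additive QTL effects (allele code AA = -1, BB = +1, effects in
#' trait-SD units), a Gaussian polygenic term, and Gaussian environmental
#' noise scaled so the expected broad-sense heritability matches
#' `heritability` (genetic variance = QTL + polygenic). Deviations are
#' multiplied by `trait_cv` x baseline to land on the parameter's natural
#' scale. Non-positive parameter draws are resampled, not clipped, to avoid
#' point masses at zero.
#'
#' @param genotypes RIL x marker genotype matrix from
#'   [simulate_ril_genotypes()].
#' @param map The `genetic_map` the genotypes were simulated on.
#' @param planted_qtl data.frame(chromosome, position, parameter, effect);
#'   positions are snapped to the nearest marker. NULL or empty for none.
#' @param heritability Named fraction in (0, 1] per parameter (recycled if a
#'   single value): share of deviation variance that is genetic.
#' @param polygenic_sd Polygenic SD in trait-SD units (default 1).
#' @param vigor_loadings Named loadings in [-1, 1] of a shared latent "vigor"
#'   factor on each parameter's polygenic term. Roots of vigorous lines grow
#'   faster (higher vf), with a more basal REGR peak (higher x0) and a longer
#'   zone (lower k), which induces the strong positive trait correlations
#'   (elongation rate vs zone length and peers) such populations display.
#'   Set to zeros for genetically independent parameters.
#' @param baseline Named numeric: population-centre parameters. Defaults give
#'   elongation rates ~0.2 mm/h, REGR peaks ~45%/h at ~0.4 mm, zone lengths
#'   ~0.6 mm, matching the ranges seen across Cvi x Ler RILs.
#' @param trait_cv Coefficient of variation applied per unit deviation.
#' @param seed Integer seed.
#' @return data.frame with columns ril, vf, x0, k, n. The genetic values
#'   (before environmental noise, in deviation units) are attached as
#'   attribute `"genetic"` for diagnostics and downstream coupling.
#' @export
simulate_kinematic_phenotypes <- function(genotypes, map,
                                          planted_qtl = default_planted_qtl(),
                                          heritability = 0.7,
                                          polygenic_sd = 1,
                                          vigor_loadings = c(vf = 0.8,
                                                             x0 = 0.6,
                                                             k = -0.7,
                                                             n = 0),
                                          baseline = c(vf = 0.20, x0 = 0.40,
                                                       k = 9, n = 1.1),
                                          trait_cv = 0.12,
                                          seed = 1) {
  map <- validate_map(map)
  pars <- c("vf", "x0", "k", "n")
  stopifnot(all(pars %in% names(baseline)))
  h2 <- rep_len(heritability, 4L)
  names(h2) <- pars
  if (!is.null(names(heritability)) && all(pars %in% names(heritability))) {
    h2 <- heritability[pars]
  }
  if (any(h2 <= 0 | h2 > 1)) stop("heritability must be in (0, 1]", call. = FALSE)
  qtl <- snap_qtl_to_markers(planted_qtl, map)
  if (nrow(qtl) && !all(qtl$parameter %in% pars)) {
    stop("planted QTL target parameters must be among vf, x0, k, n",
         call. = FALSE)
  }
  if (nrow(qtl) && any(!is.finite(qtl$effect))) {
    stop("planted QTL effects must be finite", call. = FALSE)
  }
  n_rils <- nrow(genotypes)
  code <- function(marker) {
    g <- genotypes[, marker]
    ifelse(is.na(g), 0, ifelse(g == "BB", 1, -1))
  }
  lam <- rep(0, 4L); names(lam) <- pars
  if (!is.null(vigor_loadings)) {
    lam[names(vigor_loadings)] <- vigor_loadings
  }
  if (any(abs(lam) > 1)) stop("vigor loadings must be in [-1, 1]", call. = FALSE)
  with_seed(substream_seed(seed, "phenotypes"), {
    genetic <- matrix(0, n_rils, 4L, dimnames = list(rownames(genotypes), pars))
    vigor <- stats::rnorm(n_rils)
    for (p in pars) {
      qp <- qtl[qtl$parameter == p, , drop = FALSE]
      g <- rep(0, n_rils)
      if (nrow(qp)) {
        for (i in seq_len(nrow(qp))) g <- g + qp$effect[i] * code(qp$marker[i])
      }
      # polygenic term: shared vigor factor plus an independent remainder,
      # with total variance polygenic_sd^2 regardless of the loading
      poly <- polygenic_sd * (lam[[p]] * vigor +
                                sqrt(1 - lam[[p]]^2) * stats::rnorm(n_rils))
      genetic[, p] <- g + poly
    }
    out <- data.frame(ril = rownames(genotypes), stringsAsFactors = FALSE)
    for (p in pars) {
      var_qtl <- sum(qtl$effect[qtl$parameter == p]^2)  # var(+/-1 code) = 1
      var_g <- var_qtl + polygenic_sd^2
      sd_e <- sqrt(var_g * (1 - h2[[p]]) / h2[[p]])
      dev <- genetic[, p] + stats::rnorm(n_rils, 0, sd_e)
      val <- baseline[[p]] * (1 + trait_cv * dev)
      bad <- which(val <= 0)
      tries <- 0L
      while (length(bad) && tries < 100L) {
        dev[bad] <- genetic[bad, p] + stats::rnorm(length(bad), 0, sd_e)
        val[bad] <- baseline[[p]] * (1 + trait_cv * dev[bad])
        bad <- which(val <= 0)
        tries <- tries + 1L
      }
      if (length(bad)) {
        stop(sprintf("could not draw positive values for '%s'; reduce trait_cv",
                     p), call. = FALSE)
      }
      out[[p]] <- val
    }
    attr(out, "genetic") <- genetic
    out
  })
}

#' Simulate a velocity point cloud from true profile parameters
#'
#' Emulates one root trial: positions sampled over `x_range` (distance from
#' the tip, mm) and displacement velocities equal to the flexible logistic
#' model plus i.i.d. Gaussian measurement noise. Noisy velocities may be
#' negative; downstream fitting must tolerate that.
#'
#' @param params Named numeric or list with vf, x0, k, n.
#' @param points Number of (x, v) observations (>= 10).
#' @param noise_sd Measurement noise SD in mm/h (>= 0).
#' @param x_range Length-2 numeric, sampling interval in mm.
#' @param seed Integer seed.
#' @return data.frame(x, v) of class `velocity_cloud`.
#' @export
simulate_velocity_cloud <- function(params, points = 120, noise_sd = 0.02,
                                    x_range = c(0, 1.5), seed = 1) {
  params <- validate_profile_params(params)
  if (points < 10) stop("`points` must be >= 10", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  stopifnot(length(x_range) == 2L, x_range[1] < x_range[2], x_range[1] >= 0)
  with_seed(substream_seed(seed, "cloud"), {
    x <- sort(stats::runif(points, x_range[1], x_range[2]))
    v <- velocity_model(params, x) + stats::rnorm(points, 0, noise_sd)
    structure(data.frame(x = x, v = v), class = c("velocity_cloud",
                                                  "data.frame"))
  })
}

#' Simulate gravitropism tip-angle curves for a RIL population
#'
#' Emulates tip-angle time courses recorded every 2 min for 8 h (241 samples)
#' after a 90 degree rotation. Each RIL follows a lagged saturating family
#' theta(t) = A * (1 - exp(-rate * max(t - lag, 0))) with per-RIL genetic
#' values for (lag, rate, asymptote) shared across experiments; each
#' experiment adds its own small deviation, emulating repeat experiments on
#' new seed stocks. Population variation is concentrated in the rate
#' parameter so the leading principal component dominates, as observed for
#' real curve sets. Measurement noise is AR(1)-autocorrelated.
#'
#' An optional coupling channel mixes a per-RIL score (e.g. a kinematic
#' genetic value) into the rate parameter, creating a weak multivariate
#' association between kinematic traits and gravitropism of the kind a
#' canonical correlation analysis can detect.
#'
#' @param genotypes RIL x marker genotype matrix (row names give the RIL ids).
#' @param n_experiments Number of repeat experiments (>= 1).
#' @param asymptote,lag_h,rate_per_h Population means: final angle (deg),
#'   response lag (h), approach rate (1/h).
#' @param rate_cv,lag_cv,asym_cv Genetic coefficients of variation; rate_cv
#'   dominates by default.
#' @param exp_dev_frac Experiment-specific SD as a fraction of the genetic SD.
#' @param noise_sd AR(1) innovation SD in degrees; `noise_ar` its coefficient.
#' @param coupling_scores Optional numeric per RIL (standardised internally).
#' @param coupling_strength Fraction in [0, 1) of rate genetic SD driven by
#'   `coupling_scores`.
#' @param seed Integer seed.
#' @return List of length `n_experiments`; each element is a RIL x 241 matrix
#'   of angles in degrees, with the time grid in hours as attribute `"time"`.
#' @export
simulate_tip_angle_curves <- function(genotypes, n_experiments = 2,
                                      asymptote = 85, lag_h = 0.5,
                                      rate_per_h = 1.2,
                                      rate_cv = 0.25, lag_cv = 0.08,
                                      asym_cv = 0.05, exp_dev_frac = 0.3,
                                      noise_sd = 1.5, noise_ar = 0.8,
                                      coupling_scores = NULL,
                                      coupling_strength = 0,
                                      seed = 1) {
  if (n_experiments < 1) stop("`n_experiments` must be >= 1", call. = FALSE)
  if (coupling_strength < 0 || coupling_strength >= 1) {
    stop("`coupling_strength` must be in [0, 1)", call. = FALSE)
  }
  rils <- rownames(genotypes)
  n <- length(rils)
  tt <- seq(0, 8, by = 2 / 60)  # hours; 241 points
  with_seed(substream_seed(seed, "tipangle"), {
    zc <- if (!is.null(coupling_scores)) {
      s <- coupling_scores[rils]
      if (anyNA(s)) stop("coupling_scores must cover every RIL", call. = FALSE)
      as.numeric(scale(s))
    } else rep(0, n)
    z_own <- stats::rnorm(n)
    z_rate <- coupling_strength * zc + sqrt(1 - coupling_strength^2) * z_own
    gen <- list(
      rate = rate_per_h * (1 + rate_cv * z_rate),
      lag = lag_h * (1 + lag_cv * stats::rnorm(n)),
      asym = asymptote * (1 + asym_cv * stats::rnorm(n))
    )
    lapply(seq_len(n_experiments), function(e) {
      rate <- pmax(gen$rate * (1 + exp_dev_frac * rate_cv * stats::rnorm(n)), 0.05)
      lag <- pmax(gen$lag * (1 + exp_dev_frac * lag_cv * stats::rnorm(n)), 0)
      asym <- pmax(gen$asym * (1 + exp_dev_frac * asym_cv * stats::rnorm(n)), 1)
      curves <- matrix(NA_real_, n, length(tt),
                       dimnames = list(rils, sprintf("t%03d", seq_along(tt) - 1L)))
      for (i in seq_len(n)) {
        clean <- asym[i] * (1 - exp(-rate[i] * pmax(tt - lag[i], 0)))
        if (noise_sd > 0) {
          eps <- as.numeric(stats::arima.sim(list(ar = noise_ar),
                                             length(tt), sd = noise_sd))
          clean <- clean + eps
        }
        curves[i, ] <- clean
      }
      attr(curves, "time") <- tt
      curves
    })
  })
}
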
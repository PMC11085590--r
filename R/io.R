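#' Read and write the pipeline's CSV table formats
#'
#' Plain comma-separated tables with validated headers and `NA` for missing
#' values, laid out in the common qtl-cross style so real RIL files can be
#' dropped in: genotypes (first column `ril`, then one column per marker,
#' values AA/BB/NA), map (`marker`, `chromosome`, `position`), phenotypes
#' (`ril`, then numeric trait columns), velocity clouds (`x_mm`,
#' `v_mm_per_h`), tip-angle curves (`ril`, then one column per time point,
#' degrees). Every reader validates structure and errors with the offending
#' columns or cells; `read(write(x))` round-trips exactly up to numeric
#' printing precision.
#'
#' @param genotypes,map,phenotypes,cloud,curves The object to write.
#' @param path File path.
#' @name table_io
NULL

check_header <- function(got, want, path) {
  if (!identical(got[seq_along(want)], want)) {
    stop(sprintf("malformed header in %s: expected [%s], found [%s]",
                 path, paste(want, collapse = ", "),
                 paste(utils::head(got, length(want)), collapse = ", ")),
         call. = FALSE)
  }
}

#' @rdname table_io
#' @export
write_genotypes_csv <- function(genotypes, path) {
  df <- data.frame(ril = rownames(genotypes), genotypes,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname table_io
#' @export
read_genotypes_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  check_header(names(df), "ril", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$ril
  m[m == ""] <- NA_character_
  bad <- !(m %in% c("AA", "BB") | is.na(m))
  if (any(bad)) {
    cells <- which(bad, arr.ind = TRUE)
    labels <- sprintf("%s:%s='%s'", rownames(m)[cells[, 1]],
                      colnames(m)[cells[, 2]], m[bad])
    stop("invalid genotype code(s) in ", path, ": ",
         paste(utils::head(labels, 10), collapse = ", "), call. = FALSE)
  }
  m
}

#' @rdname table_io
#' @export
write_map_csv <- function(map, path) {
  utils::write.csv(as.data.frame(map)[, c("marker", "chromosome", "position")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_map_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_header(names(df), c("marker", "chromosome", "position"), path)
  df$marker <- as.character(df$marker)
  df$chromosome <- as.character(df$chromosome)
  df$position <- as.numeric(df$position)
  validate_map(df)
}

#' @rdname table_io
#' @export
write_phenotypes_csv <- function(phenotypes, path) {
  utils::write.csv(phenotypes, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname table_io
#' @export
read_phenotypes_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_header(names(df), "ril", path)
  for (j in names(df)[-1L]) {
    if (!is.numeric(df[[j]])) {
      stop("non-numeric phenotype column '", j, "' in ", path, call. = FALSE)
    }
  }
  df
}

#' @rdname table_io
#' @export
write_cloud_csv <- function(cloud, path) {
  utils::write.csv(data.frame(x_mm = cloud$x, v_mm_per_h = cloud$v),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_cloud_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_header(names(df), c("x_mm", "v_mm_per_h"), path)
  structure(data.frame(x = df$x_mm, v = df$v_mm_per_h),
            class = c("velocity_cloud", "data.frame"))
}

#' @rdname table_io
#' @export
write_curves_csv <- function(curves, path) {
  df <- data.frame(ril = rownames(curves), curves,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_curves_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  check_header(names(df), "ril", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric angles in ", path, call. = FALSE)
  rownames(m) <- df$ril
  m
}

#' Assemble the full pipeline configuration
#'
#' Collects every tunable of the simulate -> fit -> traits -> scan -> perm ->
#' peaks -> pca -> cca pipeline with the study-scale defaults: 160 RILs on a
#' five-chromosome map with 234 markers, 8 replicate roots per RIL (the study
#' performed 7-10), 120-point velocity clouds, pseudomarkers every 1 cM,
#' genotyping error rate 0.001, 1.5-LOD support intervals, five PC scores and
#' 1000-permutation thresholds. Unknown keys are rejected.
#'
#' @param seed Master seed; every stage derives a named substream from it.
#' @param ... Overrides for any default listed above.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    n_rils = 160,
    chr_lengths = c("1" = 135, "2" = 75, "3" = 90, "4" = 80, "5" = 105),
    n_markers = 234,
    missing_rate = 0.03,
    n_replicates = 8,
    planted_qtl = default_planted_qtl(),
    heritability = 0.7,
    polygenic_sd = 1,
    vigor_loadings = c(vf = 0.8, x0 = 0.6, k = -0.7, n = 0),
    baseline = c(vf = 0.20, x0 = 0.40, k = 9, n = 1.1),
    trait_cv = 0.12,
    replicate_cv = 0.05,
    points_per_cloud = 120,
    velocity_noise_sd = 0.02,
    x_range = c(0, 1.5),
    zone_fraction = 0.2,
    step = 1,
    error_rate = 0.001,
    n_perm = 1000,
    threshold_quantile = 0.95,
    lod_drop = 1.5,
    n_pcs = 5,
    swing_window = 5,
    n_experiments = 2,
    coupling_strength = 0.6,
    cca_n_perm = 1000
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

#' Simulate a complete study-shaped dataset
#'
#' Generates, under one seed, everything the analysis consumes: the genetic
#' map, RIL genotypes, per-RIL true velocity-profile parameters with planted
#' QTL, replicate velocity point clouds (replicate roots get a small
#' lognormal jitter of the RIL parameters, emulating biological replicate
#' variation), and tip-angle curves for `n_experiments` gravitropism
#' experiments sharing genetic values.
#'
#' @param config A `pipeline_config`.
#' @return List: map, genotypes, params_true (data.frame), clouds (list per
#'   RIL of replicate `velocity_cloud`s), curves (list per experiment of
#'   RIL x 241 matrices).
#' @export
simulate_population <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  map <- sim_genetic_map(config$chr_lengths, config$n_markers,
                         seed = config$seed)
  geno <- simulate_ril_genotypes(map, config$n_rils, config$missing_rate,
                                 seed = config$seed)
  params <- simulate_kinematic_phenotypes(
    geno, map, planted_qtl = config$planted_qtl,
    heritability = config$heritability, polygenic_sd = config$polygenic_sd,
    vigor_loadings = config$vigor_loadings,
    baseline = config$baseline, trait_cv = config$trait_cv,
    seed = config$seed)
  clouds <- with_seed(substream_seed(config$seed, "clouds"), {
    lapply(seq_len(nrow(params)), function(i) {
      lapply(seq_len(config$n_replicates), function(rep) {
        jit <- exp(stats::rnorm(4, 0, config$replicate_cv))
        p <- unlist(params[i, c("vf", "x0", "k", "n")]) * jit
        simulate_velocity_cloud(p, config$points_per_cloud,
                                config$velocity_noise_sd, config$x_range,
                                seed = stats::runif(1, 0, 2^31 - 1))
      })
    })
  })
  names(clouds) <- params$ril
  genetic <- attr(params, "genetic")
  # couple gravitropism to a kinematic contrast (vf + k genetic values) that
  # is nearly orthogonal to the shared vigor factor: no single trait then
  # predicts the response well, but a weighted combination does
  curves <- simulate_tip_angle_curves(
    geno, n_experiments = config$n_experiments,
    coupling_scores = stats::setNames(genetic[, "vf"] + genetic[, "k"],
                                      rownames(genetic)),
    coupling_strength = config$coupling_strength,
    seed = config$seed)
  list(map = map, genotypes = geno, params_true = params,
       clouds = clouds, curves = curves)
}

#' Run the whole analysis pipeline into a directory
#'
#' Executes the stages in dependency order (simulate, fit + traits, genotype
#' probabilities, scans, permutation thresholds, peaks + variance explained,
#' curve PCA + swing rate, Pearson correlations, CCA + permutation
#' threshold), writing every table as CSV under `out_dir` along with the
#' resolved configuration (`config.yaml`) and a plain-text log recording the
#' seed and row counts. Rerunning with the same config reproduces identical
#' numbers. Any stage failure aborts with the stage name.
#'
#' @param config A `pipeline_config`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with every major result (traits, lod, thresholds,
#'   peaks, variance explained, pca, correlations, cca per experiment).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("kinqtl %s | seed %d | %s",
                         as.character(utils::packageVersion("kinqtl")),
                         config$seed, format(Sys.time(), "%Y-%m-%d %H:%M:%S")))
  note <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  cfg_out <- unclass(config)
  cfg_out$planted_qtl <- as.list(cfg_out$planted_qtl)
  yaml::write_yaml(cfg_out, file.path(out_dir, "config.yaml"))

  pop <- stage("simulate", simulate_population(config))
  write_map_csv(pop$map, file.path(out_dir, "map.csv"))
  write_genotypes_csv(pop$genotypes, file.path(out_dir, "genotypes.csv"))
  write_phenotypes_csv(pop$params_true, file.path(out_dir, "params_true.csv"))
  for (e in seq_along(pop$curves)) {
    write_curves_csv(pop$curves[[e]],
                     file.path(out_dir, sprintf("tip_angles_exp%d.csv", e)))
  }
  note("simulated %d RILs x %d markers; %d replicate clouds/RIL",
       nrow(pop$genotypes), ncol(pop$genotypes), config$n_replicates)

  traits <- stage("fit+traits",
                  ril_kinematic_traits(pop$clouds, config$zone_fraction))
  write_phenotypes_csv(traits, file.path(out_dir, "traits.csv"))
  note("fitted %d RILs (converged replicates averaged)", nrow(traits))

  trait_names <- c("elongation_rate", "regr_max", "regr_max_position",
                   "zone_length")
  probs <- stage("genoprobs", genotype_probabilities(
    pop$genotypes, pop$map, insert_pseudomarkers(pop$map, config$step),
    config$error_rate))
  ph <- as.matrix(traits[, trait_names])
  rownames(ph) <- traits$ril
  scan <- stage("scan", hk_scan(probs, ph))
  utils::write.csv(as.data.frame(scan), file.path(out_dir, "lod.csv"),
                   row.names = FALSE)

  thresholds <- numeric(0)
  peaks_all <- list()
  varexp <- numeric(0)
  for (tr in trait_names) {
    thr <- stage("perm", permutation_threshold(
      probs, stats::setNames(ph[, tr], rownames(ph)), config$n_perm,
      config$threshold_quantile,
      seed = substream_seed(config$seed, paste0("perm_", tr))))
    thresholds[tr] <- as.numeric(thr)
    pk <- stage("peaks", find_peaks(scan[, c("chromosome", "position",
                                             "marker", tr)],
                                    probs, ph, as.numeric(thr),
                                    drop = config$lod_drop))
    varexp[tr] <- stage("varexp", variance_explained(
      probs, stats::setNames(ph[, tr], rownames(ph)), pk))
    peaks_all[[tr]] <- pk
    note("trait %s: threshold %.2f, %d peak(s), %.1f%% variance explained",
         tr, thresholds[tr], nrow(pk), 100 * varexp[tr])
  }
  peaks <- do.call(rbind, peaks_all)
  rownames(peaks) <- NULL
  peaks$pct_variance <- 100 * varexp[peaks$trait]
  utils::write.csv(peaks, file.path(out_dir, "peaks.csv"), row.names = FALSE)
  utils::write.csv(data.frame(trait = trait_names,
                              threshold = thresholds[trait_names],
                              pct_variance = 100 * varexp[trait_names]),
                   file.path(out_dir, "thresholds.csv"), row.names = FALSE)

  x_block <- as.matrix(traits[, c("regr_max", "elongation_rate",
                                  "regr_max_position", "zone_length")])
  rownames(x_block) <- traits$ril
  cca_results <- list()
  pca_results <- list()
  for (e in seq_along(pop$curves)) {
    curves <- pop$curves[[e]][traits$ril, , drop = FALSE]
    pc <- stage("pca", pca_curves(curves, config$n_pcs))
    pca_results[[e]] <- pc
    swing <- apply(curves, 1L, max_swing_rate, window = config$swing_window)
    scores <- data.frame(ril = traits$ril, pc$scores,
                         max_swing_rate = swing, stringsAsFactors = FALSE)
    write_phenotypes_csv(scores,
                         file.path(out_dir, sprintf("pc_scores_exp%d.csv", e)))
    corr <- pearson_matrix(cbind(x_block, PC1 = pc$scores[, 1],
                                 max_swing_rate = swing))
    utils::write.csv(round(corr, 4),
                     file.path(out_dir, sprintf("correlations_exp%d.csv", e)))
    sol <- stage("cca", cca(x_block, pc$scores))
    thr <- stage("cca_perm", cca_permutation_threshold(
      x_block, pc$scores, config$cca_n_perm,
      seed = substream_seed(config$seed, paste0("cca_", e))))
    cca_results[[e]] <- list(solution = sol, threshold = as.numeric(thr),
                             correlations = corr)
    report <- data.frame(experiment = e, t(sol$x_weights),
                         correlation = sol$correlation,
                         threshold = as.numeric(thr))
    utils::write.csv(report, file.path(out_dir, sprintf("cca_exp%d.csv", e)),
                     row.names = FALSE)
    note("experiment %d: PC1 share %.1f%%, CCA r = %.3f (threshold %.3f)",
         e, 100 * pc$variance_share[1], sol$correlation, as.numeric(thr))
  }
  writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  invisible(list(population = pop, traits = traits, scan = scan,
                 thresholds = thresholds, peaks = peaks,
                 variance_explained = varexp, pca = pca_results,
                 cca = cca_results))
}
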
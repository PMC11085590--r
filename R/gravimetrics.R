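#' Principal components of tip-angle curves
#'
#' Column-centers the RIL x time curve matrix and decomposes it with
#' `stats::prcomp` (no column standardization: all angles share units;
#' z-scoring is deferred to the CCA step). Component signs are fixed so each
#' loading vector has a positive sum, making score signs reproducible.
#'
#' @param curves Numeric matrix, RILs in rows, time points in columns, no
#'   missing values (interpolate upstream).
#' @param n_components Number of components to return (<= min(n-1, p)).
#' @return List of class `pc_summary`: `scores` (RIL x component),
#'   `variance_share` (per returned component, fractions of total variance),
#'   `loadings`, `mean_curve`.
#' @export
pca_curves <- function(curves, n_components = 5) {
  curves <- as.matrix(curves)
  if (nrow(curves) < 2L) stop("need at least 2 curves", call. = FALSE)
  if (anyNA(curves)) stop("curves contain missing values", call. = FALSE)
  max_comp <- min(nrow(curves) - 1L, ncol(curves))
  if (n_components > max_comp) {
    stop(sprintf("n_components (%d) exceeds the available rank (%d)",
                 n_components, max_comp), call. = FALSE)
  }
  pc <- stats::prcomp(curves, center = TRUE, scale. = FALSE)
  flip <- ifelse(colSums(pc$rotation) < 0, -1, 1)
  pc$rotation <- sweep(pc$rotation, 2L, flip, "*")
  pc$x <- sweep(pc$x, 2L, flip, "*")
  share <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(
    scores = pc$x[, seq_len(n_components), drop = FALSE],
    variance_share = share[seq_len(n_components)],
    loadings = pc$rotation[, seq_len(n_components), drop = FALSE],
    mean_curve = pc$center
  ), class = "pc_summary")
}

#' Maximum swing rate of a gravitropic response curve
#'
#' The peak rate of change of tip angle: the slope of a least-squares line
#' over a sliding window of consecutive samples, maximized over the curve and
#' expressed in degrees per hour. Windowed regression damps frame-to-frame
#' measurement noise; the window (default 5 frames = 10 min at 2-min
#' sampling) is exposed.
#'
#' @param curve Numeric vector of tip angles in degrees, uniformly sampled.
#' @param window Odd window length in frames, >= 3 and <= length(curve).
#' @param dt_min Sampling interval in minutes (default 2).
#' @return Maximum slope in degrees/h.
#' @export
max_swing_rate <- function(curve, window = 5, dt_min = 2) {
  curve <- as.numeric(curve)
  if (window %% 2 != 1 || window < 3) {
    stop("`window` must be odd and >= 3", call. = FALSE)
  }
  if (length(curve) < window) {
    stop("curve shorter than the smoothing window", call. = FALSE)
  }
  m <- (window - 1L) / 2L
  t_h <- (-m:m) * dt_min / 60
  w <- t_h / sum(t_h^2)               # LS slope weights, centered window
  slopes <- stats::filter(curve, rev(w), sides = 2)
  max(slopes, na.rm = TRUE)
}

#' Pairwise Pearson correlation matrix
#'
#' Pearson correlations over pairwise-complete observations, with validation:
#' every pair must have at least 3 complete rows, and zero-variance columns
#' are flagged (their entries are NA with a warning).
#'
#' @param traits Numeric data.frame or matrix, RILs in rows.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(traits) {
  m <- as.matrix(traits)
  if (!is.numeric(m)) stop("traits must be numeric", call. = FALSE)
  sds <- apply(m, 2L, stats::sd, na.rm = TRUE)
  if (any(!is.na(sds) & sds == 0)) {
    warning("zero-variance column(s): ",
            paste(colnames(m)[!is.na(sds) & sds == 0], collapse = ", "),
            "; correlations set to NA", call. = FALSE)
  }
  for (i in seq_len(ncol(m))) for (j in seq_len(ncol(m))) {
    if (j > i && sum(stats::complete.cases(m[, c(i, j)])) < 3L) {
      stop("fewer than 3 complete observations for pair ",
           colnames(m)[i], " / ", colnames(m)[j], call. = FALSE)
    }
  }
  suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
}

# z-score columns; error if any column is constant
zscore_block <- function(x, label) {
  x <- as.matrix(x)
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("constant column(s) in %s block: %s", label,
                 paste(colnames(x)[sds == 0], collapse = ", ")), call. = FALSE)
  }
  scale(x)
}

#' First canonical correlation between two trait blocks
#'
#' Both blocks are z-scored, then the first canonical pair is obtained from
#' the singular value decomposition of the whitened cross-covariance
#' Sxx^{-1/2} Sxy Syy^{-1/2} (whitening via Cholesky factors). Weights are
#' scaled so the canonical variates have unit sample variance. The sign is
#' fixed so that the weight on a reference x column (`sign_ref`, by default
#' the column named "regr_max" if present, otherwise the largest-magnitude
#' x weight) is positive.
#'
#' @param x_block RIL x p numeric (e.g. the four kinematic traits).
#' @param y_block RIL x q numeric (e.g. the first five PC scores). Complete
#'   rows only; n must exceed p + q.
#' @param sign_ref Column name or index of `x_block` anchoring the sign.
#' @return List of class `cca_solution`: `correlation` (in [0, 1]),
#'   `x_weights`, `y_weights` (on the z-scored blocks), `x_scores`,
#'   `y_scores` (unit-variance canonical variates).
#' @export
cca <- function(x_block, y_block, sign_ref = NULL) {
  X <- as.matrix(x_block); Y <- as.matrix(y_block)
  if (nrow(X) != nrow(Y)) stop("blocks must have the same rows", call. = FALSE)
  if (anyNA(X) || anyNA(Y)) stop("CCA requires complete rows", call. = FALSE)
  n <- nrow(X)
  if (n <= ncol(X) + ncol(Y)) {
    stop("need more rows than total columns for CCA", call. = FALSE)
  }
  Xz <- zscore_block(X, "x"); Yz <- zscore_block(Y, "y")
  w <- cca_core(Xz, Yz)
  a <- w$a; b <- w$b
  # sign convention: positive weight on the reference kinematic trait
  ref <- if (!is.null(sign_ref)) {
    if (is.character(sign_ref)) match(sign_ref, colnames(X)) else as.integer(sign_ref)
  } else if (!is.null(colnames(X)) && "regr_max" %in% colnames(X)) {
    match("regr_max", colnames(X))
  } else which.max(abs(a))
  if (is.na(ref)) ref <- which.max(abs(a))
  if (a[ref] < 0) { a <- -a; b <- -b }
  structure(list(
    correlation = w$rho,
    x_weights = stats::setNames(as.numeric(a), colnames(X)),
    y_weights = stats::setNames(as.numeric(b), colnames(Y)),
    x_scores = as.numeric(Xz %*% a),
    y_scores = as.numeric(Yz %*% b)
  ), class = "cca_solution")
}

# whitened cross-covariance SVD on already z-scored blocks; returns first
# pair. Errors on rank deficiency, naming the offending block's columns.
cca_core <- function(Xz, Yz) {
  n <- nrow(Xz)
  Sxx <- crossprod(Xz) / (n - 1)
  Syy <- crossprod(Yz) / (n - 1)
  Rx <- tryCatch(chol(Sxx), error = function(e) {
    stop("x block is rank deficient (collinear columns: ",
         paste(colnames(Xz), collapse = ", "), ")", call. = FALSE)
  })
  Ry <- tryCatch(chol(Syy), error = function(e) {
    stop("y block is rank deficient (collinear columns: ",
         paste(colnames(Yz), collapse = ", "), ")", call. = FALSE)
  })
  Xw <- Xz %*% backsolve(Rx, diag(ncol(Xz)))   # cov(Xw) = I
  Yw <- Yz %*% backsolve(Ry, diag(ncol(Yz)))
  M <- crossprod(Xw, Yw) / (n - 1)
  sv <- svd(M, nu = 1, nv = 1)
  rho <- min(max(sv$d[1], 0), 1)
  list(rho = rho,
       a = backsolve(Rx, sv$u[, 1]),
       b = backsolve(Ry, sv$v[, 1]),
       Xw = Xw, Yw = Yw)
}

#' Permutation significance threshold for the first canonical correlation
#'
#' Permutes the row order of the y block (gravitropism side) `n_perm` times,
#' recomputes the first canonical correlation each time, and returns the
#' empirical `quantile` of the null distribution. Under row exchangeability,
#' permuting one block is equivalent to permuting both. The x-side whitening
#' is precomputed once, so each permutation costs one small cross-product
#' and SVD.
#'
#' @inheritParams cca
#' @param n_perm Number of permutations (default 1000).
#' @param quantile Probability for the empirical quantile (default 0.95).
#' @param seed Integer seed.
#' @return Threshold (scalar) with the permuted correlations as attribute
#'   `"null_correlations"`.
#' @export
cca_permutation_threshold <- function(x_block, y_block, n_perm = 1000,
                                      quantile = 0.95, seed = 1) {
  X <- as.matrix(x_block); Y <- as.matrix(y_block)
  if (anyNA(X) || anyNA(Y)) stop("CCA requires complete rows", call. = FALSE)
  n <- nrow(X)
  if (n <= ncol(X) + ncol(Y)) {
    stop("need more rows than total columns for CCA", call. = FALSE)
  }
  Xz <- zscore_block(X, "x"); Yz <- zscore_block(Y, "y")
  w <- cca_core(Xz, Yz)
  null_rho <- with_seed(substream_seed(seed, "cca_perm"), {
    vapply(seq_len(n_perm), function(i) {
      # row permutation leaves cov(Yw) = I; only the cross-covariance moves
      Yp <- w$Yw[sample.int(n), , drop = FALSE]
      M <- crossprod(w$Xw, Yp) / (n - 1)
      svd(M, nu = 0, nv = 0)$d[1]
    }, numeric(1))
  })
  structure(as.numeric(stats::quantile(null_rho, quantile)),
            null_correlations = null_rho)
}
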
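#' Validate flexible-logistic velocity profile parameters
#'
#' The velocity profile of a growing root, in the tip's frame of reference,
#' rises sigmoidally from ~0 at the quiescent center to a plateau velocity
#' vf. The flexible logistic model used throughout this package is
#'
#'   v(x) = vf * (1 + exp(-k (x - x0)))^(-1/n)
#'
#' with plateau velocity vf (mm/h), location x0 (mm from the tip), steepness
#' k (1/mm) and asymmetry n (unitless). vf, k, n must be strictly positive
#' and x0 finite.
#'
#' @param params Named numeric vector or list with elements vf, x0, k, n.
#' @return Named numeric vector c(vf, x0, k, n).
#' @export
validate_profile_params <- function(params) {
  p <- unlist(params[c("vf", "x0", "k", "n")])
  if (length(p) != 4L || anyNA(p) || any(!is.finite(p))) {
    stop("params must provide finite vf, x0, k, n", call. = FALSE)
  }
  if (p[["vf"]] <= 0 || p[["k"]] <= 0 || p[["n"]] <= 0) {
    stop("vf, k and n must be strictly positive", call. = FALSE)
  }
  p
}

#' Flexible logistic velocity profile
#'
#' Evaluates v(x) = vf * (1 + exp(-k (x - x0)))^(-1/n). The function is
#' monotone nondecreasing in x, tends to 0 as x -> -Inf and to vf as
#' x -> +Inf. Computed on the log scale for numerical stability at extreme
#' arguments.
#'
#' @inheritParams validate_profile_params
#' @param x Position(s) in mm from the root tip; must be finite.
#' @return Velocity in mm/h, same length as `x`.
#' @export
velocity_model <- function(params, x) {
  p <- validate_profile_params(params)
  if (any(!is.finite(x))) stop("`x` must be finite", call. = FALSE)
  # log(1 + e^z) evaluated stably for large |z|
  z <- -p[["k"]] * (x - p[["x0"]])
  log1pe <- ifelse(z > 35, z, log1p(exp(pmin(z, 35))))
  p[["vf"]] * exp(-log1pe / p[["n"]])
}

#' Relative elemental growth rate (REGR) profile
#'
#' REGR is the spatial derivative of the velocity profile: the local strain
#' rate of root tissue. For the flexible logistic model,
#'
#'   dv/dx = vf * (k/n) * u * (1 + u)^(-(1 + 1/n)),  u = exp(-k (x - x0)),
#'
#' nonnegative everywhere. Values are fractions per hour; multiply by 100 for
#' the conventional percent-per-hour scale.
#'
#' @inheritParams velocity_model
#' @return REGR in 1/h (fraction per hour), same length as `x`.
#' @export
regr_profile <- function(params, x) {
  p <- validate_profile_params(params)
  if (any(!is.finite(x))) stop("`x` must be finite", call. = FALSE)
  z <- -p[["k"]] * (x - p[["x0"]])
  a <- 1 + 1 / p[["n"]]
  # log REGR = log(vf k / n) + z - a*log(1+e^z), stable in both tails
  log1pe <- ifelse(z > 35, z, log1p(exp(pmin(z, 35))))
  exp(log(p[["vf"]] * p[["k"]] / p[["n"]]) + z - a * log1pe)
}

#' Fit the flexible logistic model to a velocity point cloud
#'
#' Bounded least squares via Levenberg-Marquardt (minpack.lm::nls.lm) with
#' positivity bounds on vf, k, n. Starting values come from data heuristics:
#' vf from the 95th percentile of v, x0 from the first crossing of vf/2, k
#' from the local slope at x0 scaled by 4/vf, n = 1. The fit is deterministic
#' given the cloud and options. Optionally performs one pass of 3*MAD
#' residual rejection and refits.
#'
#' @param cloud data.frame with columns x (mm) and v (mm/h); >= 10 rows
#'   spanning a nondegenerate x interval.
#' @param reject_outliers If TRUE, drop points with |residual| > 3*MAD after
#'   an initial fit and refit once.
#' @param maxiter Maximum LM iterations.
#' @return List of class `velocity_fit`: `params` (named vector), `rss`,
#'   `converged` (logical), `n_points`, `start` (the initial values).
#'   Non-convergence is flagged, never silently hidden.
#' @export
fit_velocity_profile <- function(cloud, reject_outliers = FALSE,
                                 maxiter = 200) {
  if (!all(c("x", "v") %in% names(cloud))) {
    stop("cloud must have columns `x` and `v`", call. = FALSE)
  }
  cloud <- cloud[is.finite(cloud$x) & is.finite(cloud$v), , drop = FALSE]
  if (nrow(cloud) < 10L) {
    stop("need at least 10 finite observations to fit", call. = FALSE)
  }
  if (diff(range(cloud$x)) <= 0) {
    stop("x values are degenerate (zero span)", call. = FALSE)
  }
  if (any(cloud$x < 0)) stop("positions must be >= 0 (mm from tip)", call. = FALSE)
  start <- hk_start_values(cloud)
  do_fit <- function(dat) {
    fit <- minpack.lm::nls.lm(
      par = start,
      lower = c(vf = 1e-8, x0 = -Inf, k = 1e-8, n = 1e-3),
      upper = c(vf = Inf, x0 = Inf, k = Inf, n = 1e3),
      fn = function(p, x, v) v - velocity_model(p, x),
      x = dat$x, v = dat$v,
      control = minpack.lm::nls.lm.control(maxiter = maxiter)
    )
    fit
  }
  fit <- do_fit(cloud)
  if (reject_outliers) {
    res <- cloud$v - velocity_model(fit$par, cloud$x)
    keep <- abs(res) <= 3 * stats::mad(res)
    if (sum(keep) >= 10L && any(!keep)) {
      cloud <- cloud[keep, , drop = FALSE]
      fit <- do_fit(cloud)
    }
  }
  # nls.lm info 1:3 indicate convergence; 0 and >3 are failures
  structure(list(
    params = unlist(fit$par),
    rss = sum(fit$fvec^2),
    converged = fit$info %in% 1:3,
    n_points = nrow(cloud),
    start = start
  ), class = "velocity_fit")
}

# data-driven starting values for the flexible logistic fit
hk_start_values <- function(cloud) {
  o <- order(cloud$x)
  x <- cloud$x[o]
  v <- cloud$v[o]
  vf0 <- max(stats::quantile(v, 0.95), 1e-4)
  above <- which(v >= vf0 / 2)
  x00 <- if (length(above)) x[above[1L]] else stats::median(x)
  # local slope from the ~10 nearest points around x00
  idx <- order(abs(x - x00))[seq_len(min(10L, length(x)))]
  slope <- if (diff(range(x[idx])) > 0) {
    stats::cov(x[idx], v[idx]) / stats::var(x[idx])
  } else NA_real_
  k0 <- if (is.finite(slope) && slope > 0) 4 * slope / vf0 else 10
  c(vf = as.numeric(vf0), x0 = as.numeric(x00),
    k = max(min(k0, 200), 0.5), n = 1)
}

#' Average fitted profile parameters across replicate roots
#'
#' The per-RIL kinematic description is the curve whose parameters are the
#' arithmetic means of the per-replicate fitted parameters. Non-converged
#' fits should be excluded before averaging (`drop_unconverged = TRUE`
#' does this for `velocity_fit` input).
#'
#' @param fits A list of `velocity_fit` objects, a list of named parameter
#'   vectors, or a data.frame/matrix with columns vf, x0, k, n.
#' @param drop_unconverged Drop fits flagged as non-converged.
#' @return Named numeric c(vf, x0, k, n).
#' @export
average_ril_params <- function(fits, drop_unconverged = TRUE) {
  if (is.data.frame(fits) || is.matrix(fits)) {
    m <- as.matrix(as.data.frame(fits)[, c("vf", "x0", "k", "n")])
  } else {
    if (!is.list(fits) || length(fits) == 0L) {
      stop("`fits` must be a non-empty list", call. = FALSE)
    }
    if (inherits(fits[[1L]], "velocity_fit")) {
      if (drop_unconverged) fits <- Filter(function(f) f$converged, fits)
      if (length(fits) == 0L) {
        stop("no converged fits to average", call. = FALSE)
      }
      m <- do.call(rbind, lapply(fits, function(f) f$params[c("vf", "x0", "k", "n")]))
    } else {
      m <- do.call(rbind, lapply(fits, function(p) validate_profile_params(p)))
    }
  }
  if (nrow(m) == 0L) stop("no fits to average", call. = FALSE)
  validate_profile_params(colMeans(m))
}

#' Extract the four kinematic traits of the elongation zone
#'
#' From the fitted profile parameters, computes (closed forms unless noted):
#' \itemize{
#'   \item `elongation_rate` = vf (mm/h), the plateau velocity;
#'   \item `regr_max_position` = x0 - ln(n)/k (mm), the REGR peak position;
#'   \item `regr_max` = 100 * vf * k * (1+n)^(-(1+1/n)) (%/h), the peak REGR;
#'   \item `zone_length` (mm): width of the region where REGR >=
#'     `zone_fraction` * peak, found by bracketed root-finding on each flank
#'     of the peak to 1e-9 mm.
#' }
#'
#' @inheritParams validate_profile_params
#' @param zone_fraction Fraction of the peak REGR defining the zone
#'   boundaries, in (0, 1). Default 0.2.
#' @param x_domain Interval (mm) the peak position is checked against.
#' @return Named numeric vector with the four traits.
#' @export
extract_traits <- function(params, zone_fraction = 0.2, x_domain = c(0, 2)) {
  p <- validate_profile_params(params)
  if (zone_fraction <= 0 || zone_fraction >= 1) {
    stop("`zone_fraction` must be in (0, 1)", call. = FALSE)
  }
  vf <- p[["vf"]]; x0 <- p[["x0"]]; k <- p[["k"]]; n <- p[["n"]]
  x_peak <- x0 - log(n) / k
  regr_max <- vf * k * (1 + n)^(-(1 + 1 / n))
  target <- zone_fraction * regr_max
  f <- function(x) regr_profile(p, x) - target
  # REGR is unimodal: walk outward from the peak until below target, then
  # bisect; the bracket always exists because both tails vanish
  bracket_root <- function(dir) {
    step <- 1 / k
    x_out <- x_peak + dir * step
    for (i in 1:200) {
      if (f(x_out) < 0) break
      step <- step * 2
      x_out <- x_peak + dir * step
    }
    if (f(x_out) >= 0) stop("failed to bracket zone boundary", call. = FALSE)
    lo <- min(x_peak, x_out); hi <- max(x_peak, x_out)
    stats::uniroot(f, c(lo, hi), tol = 1e-9)$root
  }
  x_lo <- bracket_root(-1)
  x_hi <- bracket_root(+1)
  traits <- c(elongation_rate = vf,
              regr_max = 100 * regr_max,
              regr_max_position = x_peak,
              zone_length = x_hi - x_lo)
  if (x_peak < x_domain[1] || x_peak > x_domain[2]) {
    warning(sprintf("REGR peak position %.3f mm lies outside [%g, %g] mm",
                    x_peak, x_domain[1], x_domain[2]), call. = FALSE)
  }
  traits
}

#' Fit replicates and derive per-RIL kinematic traits
#'
#' Convenience wrapper over the per-root workflow: fit every replicate cloud
#' of each RIL, drop non-converged fits, average the fitted parameters
#' (traits are computed from the averaged parameters, not by averaging
#' per-replicate traits), and extract the four traits.
#'
#' @param clouds Named list (per RIL) of lists of velocity clouds.
#' @param zone_fraction Passed to [extract_traits()].
#' @param reject_outliers Passed to [fit_velocity_profile()].
#' @return data.frame: ril, vf, x0, k, n, elongation_rate, regr_max,
#'   regr_max_position, zone_length, n_reps_used.
#' @export
ril_kinematic_traits <- function(clouds, zone_fraction = 0.2,
                                 reject_outliers = FALSE) {
  stopifnot(is.list(clouds), length(clouds) > 0, !is.null(names(clouds)))
  rows <- lapply(names(clouds), function(ril) {
    fits <- lapply(clouds[[ril]], fit_velocity_profile,
                   reject_outliers = reject_outliers)
    ok <- Filter(function(f) f$converged, fits)
    if (length(ok) == 0L) return(NULL)
    pars <- average_ril_params(ok)
    tr <- extract_traits(pars, zone_fraction = zone_fraction)
    data.frame(ril = ril, t(pars), t(tr), n_reps_used = length(ok),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  rownames(out) <- NULL
  out
}
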
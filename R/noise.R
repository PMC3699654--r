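# Measurement-error estimation and propagation. A single buoyant-mass
# measurement carries an error whose distribution is estimated empirically
# from sequential repeat measurements of the same cells in the same fluid;
# that error is then propagated analytically to dry mass and by Monte Carlo
# to dry density, whose inversion is non-linear in the two buoyant masses.

#' Estimate the single-measurement error distribution from repeat pairs
#'
#' Each cell is weighed twice in the same fluid; the two readings should be
#' identical, so their difference is the difference of two independent
#' single-measurement errors. Rescaling the distribution of differences by
#' \eqn{\sqrt 2} yields (approximately) the distribution of errors on a
#' single buoyant-mass measurement.
#'
#' @param m1,m2 First and second buoyant-mass readings (fg) of each cell, or
#'   a two-column matrix/data frame as the first argument. At least 2 pairs;
#'   around 100 (the usual protocol) or more gives a stable scale.
#' @return Object of class `"error_model"`: `error_samples` (fg; the
#'   rescaled differences), `scale` (their standard deviation, fg), `n_pairs`.
#' @export
estimate_error_model <- function(m1, m2 = NULL) {
  if (is.null(m2)) {
    m1 <- as.matrix(m1)
    if (ncol(m1) < 2L) stop("need two measurements per pair")
    m2 <- as.numeric(m1[, 2L]); m1 <- as.numeric(m1[, 1L])
  }
  if (length(m1) != length(m2)) stop("m1 and m2 lengths differ")
  if (length(m1) < 2L)
    stop("need at least 2 repeat pairs to estimate an error scale")
  if (any(!is.finite(m1)) || any(!is.finite(m2)))
    stop("repeat measurements must be finite")
  samples <- (m1 - m2) / sqrt(2)
  structure(list(error_samples = samples,
                 scale = stats::sd(samples),
                 n_pairs = length(samples)),
            class = "error_model")
}

#' Construct an error model from a known scale
#'
#' Convenience for simulation studies where the single-measurement standard
#' deviation is specified rather than estimated: draws `n` normal errors at
#' that scale.
#'
#' @param scale Single-measurement standard deviation, fg.
#' @param n Number of stored samples.
#' @param seed RNG seed.
#' @return An `"error_model"`.
#' @export
error_model_from_scale <- function(scale, n = 1000L, seed = 1L) {
  stopifnot(is.finite(scale), scale >= 0)
  samples <- with_seed(seed, stats::rnorm(n, 0, scale))
  structure(list(error_samples = samples, scale = stats::sd(samples),
                 n_pairs = NA_integer_),
            class = "error_model")
}

#' @export
print.error_model <- function(x, ...) {
  cat(sprintf("<error_model> scale %.4g fg from %s samples (mean %.3g fg)\n",
              x$scale, length(x$error_samples), mean(x$error_samples)))
  invisible(x)
}

# Draw n single-measurement errors, either by resampling the empirical
# distribution (default; what the null-distribution machinery assumes) or
# parametrically from N(0, scale^2).
sample_errors <- function(model, n, parametric = FALSE) {
  stopifnot(inherits(model, "error_model"))
  if (parametric) stats::rnorm(n, 0, model$scale)
  else sample(model$error_samples, n, replace = TRUE)
}

#' Error amplification of the dry-mass estimate
#'
#' The dry-mass inversion \eqn{(m_{b1}\rho_2 - m_{b2}\rho_1)/(\rho_2-\rho_1)}
#' is a linear combination of the two buoyant masses, so with independent
#' equal-variance single-measurement errors the standard error of a dry-mass
#' estimate is \deqn{\sqrt{\rho_1^2 + \rho_2^2}/|\rho_2 - \rho_1|} times the
#' single-measurement error. For the standard PBS fluids (1.005 and 1.101
#' g/cm3) the factor is about 15: the small density difference between the
#' fluids amplifies the noise substantially.
#'
#' @param rho1,rho2 Fluid densities, g/cm3.
#' @return Dimensionless fold amplification.
#' @examples
#' dry_mass_error_factor(1.005, 1.101)
#' @export
dry_mass_error_factor <- function(rho1, rho2) {
  stopifnot(is.finite(rho1), is.finite(rho2))
  if (any(rho1 == rho2)) stop("degenerate: equal fluid densities")
  sqrt(rho1^2 + rho2^2) / abs(rho2 - rho1)
}

#' Monte-Carlo check of the dry-mass error factor
#'
#' Propagates unit-variance independent errors through the dry-mass formula
#' by simulation and reports the ratio of the dry-mass error SD to the
#' single-measurement SD. Agrees with [dry_mass_error_factor()] to within
#' Monte-Carlo error.
#'
#' @inheritParams dry_mass_error_factor
#' @param n_sim Number of simulated error pairs.
#' @param seed RNG seed.
#' @return Dimensionless fold amplification (stochastic estimate).
#' @export
mc_dry_mass_error_factor <- function(rho1, rho2, n_sim = 1e5, seed = 1L) {
  if (rho1 == rho2) stop("degenerate: equal fluid densities")
  with_seed(seed, {
    e1 <- stats::rnorm(n_sim)
    e2 <- stats::rnorm(n_sim)
    dm_err <- (e1 * rho2 - e2 * rho1) / (rho2 - rho1)
    stats::sd(dm_err)
  })
}

#' Null distribution of dry density under measurement noise alone
#'
#' Simulates the spread of dry-density estimates expected if every cell had
#' the same true dry density and all observed variation came from
#' buoyant-mass measurement error. Hypothetical particle masses are drawn
#' (with replacement) from the observed dry-mass distribution; their two
#' noiseless buoyant masses are computed at the median density; independent
#' errors drawn from the error model are added to each; and the noisy pairs
#' are inverted with [solve_dry()].
#'
#' @param observed_dry_masses Observed dry masses (fg) to resample from.
#' @param median_density The single density assigned to every hypothetical
#'   particle, g/cm3 (conventionally the median observed dry density).
#' @param fluid1,fluid2 The permeable [fluid_spec] pair used in the
#'   experiment.
#' @param error An `"error_model"`.
#' @param n_sim Number of hypothetical particles; at least 10000 for stable
#'   99% bounds (a warning is issued below that).
#' @param seed RNG seed (required: every stochastic result is reproducible).
#' @param smooth_masses If `TRUE`, jitter each resampled mass with a normal
#'   kernel at the KDE bandwidth (smoothed bootstrap) instead of the plain
#'   empirical resample.
#' @param parametric_errors If `TRUE`, draw errors from N(0, scale^2) instead
#'   of resampling the empirical error samples.
#' @return Object of class `"null_density"`: `simulated_densities` (g/cm3),
#'   `median_density_used`, `bounds_99` (empirical 0.5% and 99.5% quantiles),
#'   `n_sim`, `seed`.
#' @export
simulate_null_density <- function(observed_dry_masses, median_density,
                                  fluid1, fluid2, error,
                                  n_sim = 10000L, seed,
                                  smooth_masses = FALSE,
                                  parametric_errors = FALSE) {
  if (length(observed_dry_masses) == 0L)
    stop("observed_dry_masses is empty")
  stopifnot(inherits(error, "error_model"))
  check_fluid_pair(fluid1, fluid2)
  if (missing(seed)) stop("seed is required for simulate_null_density")
  n_sim <- as.integer(n_sim)
  if (n_sim < 100L) stop("n_sim too small for meaningful 99% bounds")
  if (n_sim < 10000L)
    warning("n_sim below 10000; 99% bounds will be unstable")
  sim <- with_seed(seed, {
    m <- sample(observed_dry_masses, n_sim, replace = TRUE)
    if (smooth_masses && length(unique(observed_dry_masses)) > 1L)
      m <- m + stats::rnorm(n_sim, 0, stats::bw.nrd0(observed_dry_masses))
    mb1 <- m * (1 - fluid1$density / median_density) +
      sample_errors(error, n_sim, parametric_errors)
    mb2 <- m * (1 - fluid2$density / median_density) +
      sample_errors(error, n_sim, parametric_errors)
    solve_dry(mb1, mb2, fluid1, fluid2)$dry_density
  })
  bounds <- unname(stats::quantile(sim, c(0.005, 0.995)))
  structure(list(simulated_densities = sim,
                 median_density_used = median_density,
                 bounds_99 = bounds,
                 n_sim = n_sim,
                 seed = seed),
            class = "null_density")
}

#' @export
print.null_density <- function(x, ...) {
  cat(sprintf(paste0("<null_density> %d simulated cells at median density ",
                     "%.4f g/cm3\n  99%% bounds: [%.4f, %.4f] g/cm3\n"),
              x$n_sim, x$median_density_used, x$bounds_99[1], x$bounds_99[2]))
  invisible(x)
}

#' @export
plot.null_density <- function(x, ...) {
  graphics::hist(x$simulated_densities, breaks = 60, freq = FALSE,
                 main = "Dry-density null distribution",
                 xlab = "dry density (g/cm3)", ...)
  graphics::abline(v = x$median_density_used, lwd = 2)
  graphics::abline(v = x$bounds_99, lty = 2)
  invisible(x)
}

#' Compare observed dry densities to the noise-only null
#'
#' Reports the fraction of observed densities outside the null's 99% bounds
#' and a quantile-quantile table. The comparison is descriptive, not a
#' hypothesis test: exceedance near 0.01 means the observed heterogeneity is
#' consistent with measurement noise alone; a larger exceedance (or a wider
#' Q-Q spread) indicates real biological density variation.
#'
#' @param observed_densities Observed dry densities, g/cm3.
#' @param null A [simulate_null_density()] result.
#' @param probs Quantiles for the Q-Q table.
#' @return List with `fraction_outside`, `n_observed` and `qq`
#'   (a data frame of matched observed/null quantiles).
#' @export
compare_to_null <- function(observed_densities, null,
                            probs = seq(0.05, 0.95, by = 0.05)) {
  if (length(observed_densities) == 0L) stop("no observed densities")
  stopifnot(inherits(null, "null_density"))
  if (length(null$simulated_densities) == 0L) stop("empty null distribution")
  out_frac <- mean(observed_densities < null$bounds_99[1] |
                   observed_densities > null$bounds_99[2])
  qq <- data.frame(prob = probs,
                   observed = unname(stats::quantile(observed_densities, probs)),
                   null = unname(stats::quantile(null$simulated_densities, probs)))
  list(fraction_outside = out_frac,
       n_observed = length(observed_densities),
       qq = qq)
}
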
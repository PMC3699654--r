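# Population-level summaries and comparisons: rescaled kernel density
# estimates, bootstrap medians, exact/approximate Mann-Whitney tests, Deming
# (total least squares) regression and logistic growth-curve fits.

#' Kernel density estimate rescaled to unit maximum
#'
#' Gaussian-kernel density on an automatic grid, divided by its maximum so
#' that curves for samples of different sizes can be overlaid. The bandwidth
#' rule is recorded in the output; Scott's rule is the default.
#'
#' @param values Numeric sample (at least 2 distinct values).
#' @param bandwidth_rule `"scott"` or `"silverman"`.
#' @param n_grid Grid resolution.
#' @return Object of class `"rescaled_kde"`: `grid`, `height` (max 1),
#'   `max_density` (the pre-rescale peak, for recovering the raw density),
#'   `bandwidth`, `bandwidth_rule`, `n`.
#' @export
rescaled_kde <- function(values, bandwidth_rule = c("scott", "silverman"),
                         n_grid = 512L) {
  bandwidth_rule <- match.arg(bandwidth_rule)
  values <- values[is.finite(values)]
  if (length(unique(values)) < 2L)
    stop("need at least 2 distinct values for a density estimate")
  bw <- switch(bandwidth_rule,
               scott = stats::bw.nrd(values),
               silverman = stats::bw.nrd0(values))
  d <- stats::density(values, bw = bw, n = n_grid)
  structure(list(grid = d$x,
                 height = d$y / max(d$y),
                 max_density = max(d$y),
                 bandwidth = bw,
                 bandwidth_rule = bandwidth_rule,
                 n = length(values)),
            class = "rescaled_kde")
}

#' @export
plot.rescaled_kde <- function(x, ...) {
  graphics::plot(x$grid, x$height, type = "l",
                 xlab = "value", ylab = "rescaled density", ...)
  invisible(x)
}

#' Median with a bootstrap standard error
#'
#' @param values Numeric sample.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed RNG seed for the resampling.
#' @return List: `median`, `se` (bootstrap SE of the median), `n`, `n_boot`.
#' @export
median_summary <- function(values, n_boot = 1000L, seed = 1L) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("empty input")
  meds <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i)
      stats::median(sample(values, length(values), replace = TRUE)),
      numeric(1))
  })
  list(median = stats::median(values),
       se = stats::sd(meds),
       n = length(values),
       n_boot = n_boot)
}

# U statistic for group a (count of (a, b) pairs with a > b; ties count 1/2)
u_statistic <- function(a, b) {
  sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
}

#' Mann-Whitney U test, exact for small samples
#'
#' Two-sided rank-sum test. For groups of at most `exact_max` observations
#' each, the null distribution of U is enumerated exactly over all
#' \eqn{\binom{n_a+n_b}{n_a}} group assignments of the pooled values (valid
#' with ties); otherwise the tie-corrected normal approximation with
#' continuity correction is used.
#'
#' @param a,b Numeric samples.
#' @param exact_max Largest per-group size for exact enumeration (default 8).
#' @return List: `U` (statistic for group `a`), `p_value` (two-sided),
#'   `method` (`"exact"` or `"normal"`).
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))   # U = 0, exact p = 1/3
#' @export
mann_whitney_u <- function(a, b, exact_max = 8L) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  na <- length(a); nb <- length(b)
  u_obs <- u_statistic(a, b)
  mu <- na * nb / 2
  if (na <= exact_max && nb <= exact_max) {
    pooled <- c(a, b)
    idx <- utils::combn(na + nb, na)
    us <- apply(idx, 2L, function(i) u_statistic(pooled[i], pooled[-i]))
    # two-sided: assignments at least as far from the null mean as observed
    p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
    method <- "exact"
  } else {
    nn <- na + nb
    r <- rank(c(a, b))
    ties <- table(r)
    sigma2 <- na * nb / 12 *
      ((nn + 1) - sum(ties^3 - ties) / (nn * (nn - 1)))
    cc <- sign(u_obs - mu) * 0.5
    z <- (u_obs - mu - cc) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(U = u_obs, p_value = p, method = method)
}

#' Deming (total least squares) regression
#'
#' Fits a line minimizing weighted orthogonal residuals, for comparing two
#' instruments that both measure with error. With `variance_ratio = 1`
#' (default) this is orthogonal regression. Closed form:
#' \deqn{\hat\beta = \frac{s_{yy} - \delta s_{xx} +
#'   \sqrt{(s_{yy} - \delta s_{xx})^2 + 4\delta s_{xy}^2}}{2 s_{xy}}}
#' with \eqn{\delta} the ratio of y-error to x-error variance.
#'
#' @param x,y Paired measurements (at least 2 points).
#' @param variance_ratio \eqn{\delta =} var(y errors)/var(x errors), > 0.
#' @return Object of class `"deming_fit"`: `slope`, `intercept`,
#'   `variance_ratio`, `n`.
#' @export
deming_fit <- function(x, y, variance_ratio = 1) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L) stop("need at least 2 points")
  if (!is.finite(variance_ratio) || variance_ratio <= 0)
    stop("variance_ratio must be > 0")
  sxx <- stats::var(x); syy <- stats::var(y); sxy <- stats::cov(x, y)
  if (sxx == 0 && syy == 0) stop("degenerate: x and y are both constant")
  d <- variance_ratio
  slope <- if (sxy == 0) {
    if (syy >= d * sxx) Inf else 0   # vertical / horizontal limits
  } else {
    (syy - d * sxx + sqrt((syy - d * sxx)^2 + 4 * d * sxy^2)) / (2 * sxy)
  }
  intercept <- if (is.finite(slope)) mean(y) - slope * mean(x) else NA_real_
  structure(list(slope = slope, intercept = intercept,
                 variance_ratio = variance_ratio, n = length(x)),
            class = "deming_fit")
}

#' @export
print.deming_fit <- function(x, ...) {
  cat(sprintf("<deming_fit> y = %.6g + %.6g x (variance ratio %.3g, n = %d)\n",
              x$intercept, x$slope, x$variance_ratio, x$n))
  invisible(x)
}

#' Logistic growth-curve fit
#'
#' Nonlinear least squares of optical density against time under the
#' three-parameter logistic \eqn{K/(1 + e^{-r(t - t_0)})}: carrying capacity
#' `K` (OD units), rate `r` (1/h) and midpoint `t0` (h). Starting values are
#' data-driven (K from the maximum OD, t0 from the half-maximum crossing, r
#' from the log-slope of the rising phase). Non-convergence is reported as an
#' error with the optimizer's diagnostics, never silently; a fitted negative
#' rate (decreasing series) is flagged with a warning.
#'
#' @param time Times, h.
#' @param od Optical densities.
#' @return Object of class `"growth_fit"`: `carrying_capacity`, `rate`,
#'   `midpoint`, `residual_norm`, `fitted`, and the underlying `nls` fit.
#' @export
logistic_growth_fit <- function(time, od) {
  ok <- is.finite(time) & is.finite(od)
  time <- time[ok]; od <- od[ok]
  if (length(time) < 4L) stop("need at least 4 points spanning growth")
  k0 <- max(od)
  t0_0 <- time[which.min(abs(od - k0 / 2))]
  # rate from the log-slope of the sub-half-max rising phase
  rising <- od > 0.05 * k0 & od < 0.95 * k0
  r0 <- if (sum(rising) >= 2L) {
    cf <- stats::coef(stats::lm(log(od[rising] / (k0 * 1.05 - od[rising])) ~
                                  time[rising]))
    unname(cf[2L])
  } else 1
  if (!is.finite(r0) || r0 == 0) r0 <- 1
  ctl <- stats::nls.control(maxiter = 500, minFactor = 1e-10,
                            scaleOffset = 1)
  fit <- tryCatch(
    stats::nls(od ~ K / (1 + exp(-r * (time - t0))),
               start = list(K = k0, r = r0, t0 = t0_0), control = ctl),
    error = function(e)
      stop("logistic fit did not converge: ", conditionMessage(e),
           "\n  starting values: K = ", signif(k0, 4), ", r = ",
           signif(r0, 4), ", t0 = ", signif(t0_0, 4), call. = FALSE))
  # polish from the converged point with a tight criterion where possible
  ctl$tol <- 1e-10
  fit <- tryCatch(
    stats::nls(od ~ K / (1 + exp(-r * (time - t0))),
               start = as.list(stats::coef(fit)), control = ctl),
    error = function(e) fit)
  cf <- stats::coef(fit)
  if (cf[["r"]] < 0)
    warning("fitted growth rate is negative: series is not increasing")
  structure(list(carrying_capacity = cf[["K"]],
                 rate = cf[["r"]],
                 midpoint = cf[["t0"]],
                 residual_norm = sqrt(sum(stats::residuals(fit)^2)),
                 fitted = stats::fitted(fit),
                 fit = fit),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf(paste0("<growth_fit> K = %.4g, r = %.4g 1/h, t0 = %.4g h ",
                     "(residual norm %.3g)\n"),
              x$carrying_capacity, x$rate, x$midpoint, x$residual_norm))
  invisible(x)
}

#' Grouped median summaries
#'
#' Tidy per-group table of medians with bootstrap standard errors, counts and
#' validity counts, for batches of samples/replicates.
#'
#' @param values Numeric measurements.
#' @param groups Group labels (same length as `values`).
#' @param valid Optional logical validity flags; invalid values are excluded
#'   from the median but counted.
#' @param n_boot,seed Passed to [median_summary()] per group.
#' @return Data frame ordered by group: `group`, `n`, `n_valid`, `median`,
#'   `se`.
#' @export
batch_summary <- function(values, groups, valid = NULL,
                          n_boot = 1000L, seed = 1L) {
  if (length(values) != length(groups))
    stop("values and groups lengths differ")
  if (is.null(valid)) valid <- rep(TRUE, length(values))
  keys <- sort(unique(groups))
  rows <- lapply(keys, function(g) {
    sel <- groups == g
    v <- values[sel & valid]
    ms <- median_summary(v, n_boot = n_boot, seed = seed)
    data.frame(group = g, n = sum(sel), n_valid = sum(sel & valid),
               median = ms$median, se = ms$se)
  })
  do.call(rbind, rows)
}
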
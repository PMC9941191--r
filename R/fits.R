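#' Fit a power law y = a * x^b
#'
#' The default method is ordinary least squares of log(y) on log(x) — the
#' usual trendline convention for growth curves — with `a` recovered as the
#' exponentiated intercept and the coefficient of determination reported on
#' the log-log scale. Points with y <= 0 cannot enter a log-scale fit and
#' are excluded with a message. The alternative `fit_scale = "linear"`
#' performs nonlinear least squares of y on a * x^b directly (initialised
#' from the log-log fit) and reports R-squared on the linear scale.
#'
#' @param x Positive predictor values (cohort sizes or events numbers).
#' @param y Non-negative response values (significant-gene counts).
#' @param fit_scale `"log-log"` (default) or `"linear"`.
#' @return An object of class `power_law_fit`: list with `a`, `b`,
#'   `r_squared`, `fit_scale`, `n_points` (points actually used), `rss`
#'   (residual sum of squares on the fitting scale) and `n_excluded`.
#' @export
#' @examples
#' fit_power_law(c(1, 2, 4, 8), 3 * c(1, 2, 4, 8)^2)
fit_power_law <- function(x, y, fit_scale = c("log-log", "linear")) {
  fit_scale <- match.arg(fit_scale)
  if (length(x) != length(y)) stop_param("x and y must have equal length")
  if (any(!is.finite(x)) || any(x <= 0)) stop_param("all x must be finite and > 0")
  if (any(!is.finite(y)) || any(y < 0)) stop_param("all y must be finite and >= 0")

  usable <- y > 0
  n_excluded <- sum(!usable)
  if (n_excluded > 0L) {
    message("fit_power_law: excluding ", n_excluded, " point(s) with y <= 0")
  }
  xs <- x[usable]
  ys <- y[usable]
  if (length(xs) < 3L) stop_fit("power-law fit needs at least 3 points with y > 0")

  ll <- lm(log(ys) ~ log(xs))
  a <- unname(exp(coef(ll)[1L]))
  b <- unname(coef(ll)[2L])

  if (fit_scale == "log-log") {
    rss <- sum(resid(ll)^2)
    tss <- sum((log(ys) - mean(log(ys)))^2)
    r2 <- if (tss > 0) max(0, min(1, 1 - rss / tss)) else 1
  } else {
    nl <- minpack.lm::nlsLM(
      ys ~ a * xs^b,
      start = list(a = a, b = b),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    )
    a <- unname(coef(nl)[["a"]])
    b <- unname(coef(nl)[["b"]])
    rss <- sum(resid(nl)^2)
    tss <- sum((ys - mean(ys))^2)
    r2 <- if (tss > 0) max(0, min(1, 1 - rss / tss)) else 1
  }

  structure(
    list(
      a = a, b = b, r_squared = r2, fit_scale = fit_scale,
      n_points = length(xs), rss = rss, n_excluded = n_excluded
    ),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf(
    "power-law fit: y = %.4g * x^%.4f  (R^2 = %.4f on %s scale, %d points)\n",
    x$a, x$b, x$r_squared, x$fit_scale, x$n_points
  ))
  invisible(x)
}

#' Evaluate a fitted power law
#'
#' @param fit A [fit_power_law()] object.
#' @param x Positive evaluation points.
#' @return `a * x^b`, vectorised over `x`.
#' @export
eval_power_law <- function(fit, x) {
  stopifnot(inherits(fit, "power_law_fit"))
  if (any(!is.finite(x)) || any(x <= 0)) stop_param("x must be finite and > 0")
  fit$a * x^fit$b
}

#' Fit a logistic cumulative distribution function to detection probabilities
#'
#' Least-squares fit of F(x) = 1 / (1 + exp(-(x - mu) / s)) to the observed
#' probability of at least one significant gene as a function of cohort
#' size. `mu` is the size at which the probability crosses 0.5 and `s` the
#' scale of the rise, both in cohort-size units. Starting values come from
#' linear interpolation of the empirical 25%/50%/75% crossing points; the
#' optimisation is deterministic given the inputs.
#'
#' @param x Cohort sizes (at least 3 distinct values).
#' @param p Probabilities in \[0, 1\], one per size.
#' @param weights Optional non-negative least-squares weights (e.g.
#'   replicate counts per size).
#' @return An object of class `logistic_fit`: list with `mu`, `s`, `rss`
#'   and `n_points`.
#' @export
#' @examples
#' x <- seq(10, 90, by = 10)
#' fit_logistic_cdf(x, plogis(x, 50, 5))
fit_logistic_cdf <- function(x, p, weights = NULL) {
  if (length(x) != length(p)) stop_param("x and p must have equal length")
  if (length(unique(x)) < 3L) stop_fit("logistic fit needs at least 3 distinct x")
  if (any(!is.finite(x))) stop_param("all x must be finite")
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop_param("all p must lie in [0, 1]")
  }
  if (length(unique(p)) == 1L) {
    stop_fit("all probabilities identical: logistic location is unidentifiable")
  }
  if (is.null(weights)) weights <- rep(1, length(x))
  if (length(weights) != length(x) || any(!is.finite(weights)) || any(weights < 0)) {
    stop_param("weights must be non-negative, one per point")
  }

  ord <- order(x)
  xs <- x[ord]
  ps <- p[ord]
  cross <- function(level, fallback) {
    v <- suppressWarnings(approx(ps, xs, xout = level, ties = mean, rule = 2)$y)
    if (is.finite(v)) v else fallback
  }
  mu0 <- cross(0.5, xs[which.min(abs(ps - 0.5))])
  s0 <- (cross(0.75, NA) - cross(0.25, NA)) / (2 * log(3))
  if (!is.finite(s0) || s0 <= 0) s0 <- diff(range(xs)) / 4
  if (s0 <= 0) s0 <- 1

  w <- weights[ord]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      ps ~ plogis(xs, location = mu, scale = s),
      start = list(mu = mu0, s = s0),
      weights = w,
      lower = c(mu = -Inf, s = .Machine$double.eps),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) NULL
  )
  if (!is.null(fit)) {
    mu <- unname(coef(fit)[["mu"]])
    s <- unname(coef(fit)[["s"]])
  } else {
    # Levenberg-Marquardt can hit a singular gradient when most observed
    # probabilities sit at 0/1 (saturated curve); Nelder-Mead on (mu, log s)
    # is slower but has no such failure mode and stays deterministic.
    obj <- function(par) sum(w * (ps - plogis(xs, par[1L], exp(par[2L])))^2)
    opt <- stats::optim(c(mu0, log(s0)), obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    mu <- opt$par[1L]
    s <- exp(opt$par[2L])
  }
  if (!is.finite(s) || s <= 0) stop_fit("logistic fit did not yield a positive scale")

  structure(
    list(
      mu = mu, s = s,
      rss = sum(w * (ps - plogis(xs, mu, s))^2),
      n_points = length(xs)
    ),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf(
    "logistic CDF fit: mu = %.3f, s = %.3f (RSS = %.4g, %d points)\n",
    x$mu, x$s, x$rss, x$n_points
  ))
  invisible(x)
}

#' Evaluate a fitted logistic CDF
#'
#' @param fit A [fit_logistic_cdf()] object.
#' @param x Evaluation points (cohort sizes).
#' @return Fitted probabilities in (0, 1).
#' @export
eval_logistic_cdf <- function(fit, x) {
  stopifnot(inherits(fit, "logistic_fit"))
  plogis(x, location = fit$mu, scale = fit$s)
}

#' Minimum cohort size to reach a target discovery probability
#'
#' For `target_p < 1` the fitted logistic is inverted in closed form and the
#' result rounded up: `ceiling(mu + s * log(target_p / (1 - target_p)))`.
#' A logistic CDF only reaches 1 asymptotically, so "100% probability" is
#' operationalised empirically: the smallest grid size at which every
#' replicate — at that size and at every larger size — produced at least one
#' significant gene. If no such size exists, `NA` is returned (target not
#' attained within the grid).
#'
#' @param logfit A [fit_logistic_cdf()] object.
#' @param records A [run_saturation()] record table; required when
#'   `target_p = 1`.
#' @param target_p Target probability in (0, 1\].
#' @return Integer minimum size, or `NA` if not attained.
#' @export
size_for_probability <- function(logfit, records = NULL, target_p) {
  if (!is_number(target_p) || target_p <= 0 || target_p > 1) {
    stop_param("target_p must lie in (0, 1]")
  }
  if (target_p < 1) {
    stopifnot(inherits(logfit, "logistic_fit"))
    return(as.integer(ceiling(
      logfit$mu + logfit$s * log(target_p / (1 - target_p))
    )))
  }
  if (is.null(records)) {
    stop_param("target_p = 1 is assessed empirically and needs the record table")
  }
  summ <- summarize_saturation(records)
  ok <- summ$prob_ge1 == 1
  # smallest size from which prob_ge1 stays 1 through the top of the grid
  stable <- rev(cumprod(rev(ok))) == 1
  if (!any(stable)) return(NA_integer_)
  as.integer(summ$size[which(stable)[1L]])
}

#' Expected events number in a random subsample
#'
#' A uniform without-replacement subsample of `n_sub` of `n_total` patients,
#' of whom `d_total` died, contains a hypergeometric number of deaths with
#' mean `n_sub * d_total / n_total`. The mean is rounded half-up to report
#' a whole events number.
#'
#' @param n_sub Subsample size(s); vectorised.
#' @param n_total Full cohort size.
#' @param d_total Deaths in the full cohort.
#' @return Integer expected events, same length as `n_sub`.
#' @export
#' @examples
#' expected_events(95, 222, 77)  # 33
#' expected_events(60, 165, 99)  # 36
expected_events <- function(n_sub, n_total, d_total) {
  if (!is_count(n_total, 1L)) stop_param("n_total must be a positive integer")
  if (!is_count(d_total) || d_total > n_total) {
    stop_param("d_total must be an integer in [0, n_total]")
  }
  if (length(n_sub) == 0L || any(is.na(n_sub)) || any(n_sub != trunc(n_sub)) ||
      any(n_sub < 0) || any(n_sub > n_total)) {
    stop_param("n_sub must be integer(s) in [0, n_total]")
  }
  as.integer(floor(n_sub * d_total / n_total + 0.5))
}
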
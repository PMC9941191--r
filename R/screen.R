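# Shared log-rank workhorse: observed / expected / variance of the "group 1"
# (mutant) arm for every column of a binary indicator matrix at once.
#
# At each distinct event time t_j with d_j deaths among n_j at risk, of whom
# r_j are in group 1:
#   E1_j = d_j * r_j / n_j
#   V_j  = d_j * (r_j / n_j) * (1 - r_j / n_j) * (n_j - d_j) / (n_j - 1)
# and O1 sums the group-1 deaths. Samples censored at an event time are kept
# in the risk set at that time (censoring ordered after events). The
# (n_j - d_j)/(n_j - 1) factor is the standard correction for tied deaths.
logrank_oe <- function(time, status, m) {
  n <- length(time)
  ord <- order(time)
  t_s <- time[ord]
  s_s <- status[ord]
  m_s <- m[ord, , drop = FALSE]

  if (!any(s_s == 1L)) {
    k <- ncol(m)
    return(list(
      o = rep(NA_real_, k), e = rep(NA_real_, k), v = rep(0, k), n_event_times = 0L
    ))
  }

  et <- sort(unique(t_s[s_s == 1L]))
  first <- match(et, t_s)          # first index with t >= et_j (exact match exists)
  n_risk <- n - (first - 1L)
  d <- as.vector(rowsum(rep(1L, sum(s_s == 1L)), t_s[s_s == 1L]))

  # group-1 at-risk counts per gene: reverse cumulative column sums
  rc <- apply(m_s[n:1, , drop = FALSE], 2, cumsum)[n:1, , drop = FALSE]
  r1 <- rc[first, , drop = FALSE]
  d1 <- rowsum(m_s[s_s == 1L, , drop = FALSE], t_s[s_s == 1L])

  e_coef <- d / n_risk
  v_coef <- ifelse(n_risk > 1, d * (n_risk - d) / ((n_risk - 1) * n_risk^2), 0)
  list(
    o = colSums(d1),
    e = colSums(e_coef * r1),
    v = colSums(v_coef * (r1 * (n_risk - r1))),
    n_event_times = length(et)
  )
}

check_survival_input <- function(time_months, status) {
  if (length(time_months) == 0L) stop_input("empty survival input")
  if (length(status) != length(time_months)) {
    stop_input("time and status must have equal length")
  }
  if (any(!is.finite(time_months)) || any(time_months <= 0)) {
    stop_input("every survival time must be finite and > 0")
  }
  if (any(is.na(status)) || !all(status %in% c(0, 1))) {
    stop_input("status values must be 0 or 1")
  }
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function, reported at the observed
#' event times (the points where the step function drops). With no observed
#' events the estimate is the constant function 1 and the returned table is
#' empty.
#'
#' @param time_months Positive survival times.
#' @param status Event indicators, 1 = death observed, 0 = censored.
#' @return A data frame with columns `time`, `n_risk`, `n_event`, `survival`,
#'   one row per distinct event time, survival non-increasing from 1.
#' @seealso [survival::survfit()], which performs the estimation.
#' @export
#' @examples
#' km_curve(c(1, 2, 3), c(1, 1, 1))
km_curve <- function(time_months, status) {
  check_survival_input(time_months, status)
  fit <- survival::survfit(survival::Surv(time_months, status) ~ 1)
  keep <- fit$n.event > 0
  data.frame(
    time = fit$time[keep],
    n_risk = fit$n.risk[keep],
    n_event = fit$n.event[keep],
    survival = fit$surv[keep]
  )
}

#' Two-group log-rank test
#'
#' Standard two-sample log-rank test of equality of survival curves, with
#' hypergeometric variance and the (n - d)/(n - 1) tie correction at each
#' distinct event time. The statistic is referred to a chi-squared
#' distribution with 1 degree of freedom.
#'
#' @param time_months Positive survival times.
#' @param status Event indicators (0/1).
#' @param group Binary group labels (logical, 0/1, or any two-level vector);
#'   the test is symmetric in the labels. `direction` refers to the group
#'   corresponding to the higher label (e.g. `TRUE`, `1`, or the second
#'   factor level): +1 means that group experienced more deaths than
#'   expected (adverse), -1 fewer (protective).
#' @return A list with elements `chi_square`, `p_value`, `direction`,
#'   `o_minus_e` (observed minus expected events in the indicated group) and
#'   `n_event_times`.
#' @export
#' @examples
#' logrank_test(c(1, 2), c(1, 1), c("A", "B"))
logrank_test <- function(time_months, status, group) {
  check_survival_input(time_months, status)
  if (length(group) != length(time_months)) {
    stop_input("group must have one label per sample")
  }
  lev <- sort(unique(group))
  if (length(lev) != 2L) {
    stop_degenerate("log-rank needs exactly two nonempty groups")
  }
  ind <- matrix(as.integer(group == lev[2L]), ncol = 1L)
  res <- logrank_oe(time_months, as.integer(status), ind)
  if (res$n_event_times == 0L) {
    stop_degenerate("log-rank undefined with no observed events")
  }
  if (res$v <= 0) {
    stop_degenerate("log-rank variance is zero (groups never compared at risk)")
  }
  chi <- (res$o - res$e)^2 / res$v
  list(
    chi_square = as.numeric(chi),
    p_value = pchisq(as.numeric(chi), df = 1, lower.tail = FALSE),
    direction = sign(as.numeric(res$o - res$e)),
    o_minus_e = as.numeric(res$o - res$e),
    n_event_times = res$n_event_times
  )
}

#' Per-gene prognostic screen (mutant vs. wild-type log-rank)
#'
#' Applies the two-group log-rank test gene by gene, comparing overall
#' survival of carriers of a somatic mutation against wild-type samples.
#' Genes mutated in fewer than `min_mutant` samples, mutated in every
#' sample, or untestable in the cohort (no events, or the two groups never
#' co-occur in a risk set at an event time) are marked `tested = FALSE` and
#' carry `NA` statistics; they are never dropped from the output.
#'
#' @param cohort A [cohort_data()] object.
#' @param alpha Significance level used downstream by [count_significant()];
#'   recorded as an attribute of the result.
#' @param min_mutant Minimum number of mutant samples for a gene to be
#'   tested (default 5, the conventional floor for per-gene survival screens
#'   of somatic mutation data).
#' @return A data frame of class `gene_screen` with one row per gene and
#'   columns `gene`, `n_mutant`, `chi_square`, `p_value`, `direction`
#'   (+1 adverse, -1 protective, 0 tie) and `tested`.
#' @export
screen_genes <- function(cohort, alpha = 0.05, min_mutant = 5L) {
  stopifnot(inherits(cohort, "cohort_data"))
  if (!is_number(alpha) || alpha <= 0 || alpha >= 1) {
    stop_param("alpha must lie strictly between 0 and 1")
  }
  if (!is_count(min_mutant, 1L)) stop_param("min_mutant must be an integer >= 1")

  m <- cohort$mutation_matrix
  n <- nrow(m)
  n_mutant <- as.integer(colSums(m))
  eligible <- n_mutant >= min_mutant & n_mutant < n

  chi <- rep(NA_real_, ncol(m))
  p <- rep(NA_real_, ncol(m))
  dir <- rep(NA_integer_, ncol(m))
  tested <- rep(FALSE, ncol(m))

  if (any(eligible) && any(cohort$status == 1L)) {
    res <- logrank_oe(cohort$time_months, cohort$status,
                      m[, eligible, drop = FALSE])
    ok <- is.finite(res$v) & res$v > 0
    chi_e <- ifelse(ok, (res$o - res$e)^2 / res$v, NA_real_)
    idx <- which(eligible)
    chi[idx[ok]] <- chi_e[ok]
    p[idx[ok]] <- pchisq(chi_e[ok], df = 1, lower.tail = FALSE)
    dir[idx[ok]] <- as.integer(sign(res$o - res$e))[ok]
    tested[idx[ok]] <- TRUE
  }

  out <- data.frame(
    gene = cohort$gene_ids,
    n_mutant = n_mutant,
    chi_square = chi,
    p_value = p,
    direction = dir,
    tested = tested,
    stringsAsFactors = FALSE
  )
  attr(out, "alpha") <- alpha
  attr(out, "min_mutant") <- as.integer(min_mutant)
  class(out) <- c("gene_screen", "data.frame")
  out
}

#' Count significant genes in a screen
#'
#' A gene counts as significant when it was tested and its log-rank p-value
#' is strictly below `alpha` (a p-value exactly equal to `alpha` is not
#' significant). No multiple-testing correction is applied.
#'
#' @param results A [screen_genes()] result (or any data frame with
#'   `tested` and `p_value` columns).
#' @param alpha Significance level in \[0, 1\]; with `alpha = 0` the strict
#'   inequality makes the count 0.
#' @return Non-negative integer count.
#' @export
count_significant <- function(results, alpha = 0.05) {
  if (!is_number(alpha) || alpha < 0 || alpha > 1) {
    stop_param("alpha must lie in [0, 1]")
  }
  if (NROW(results) == 0L) return(0L)
  sum(results$tested & !is.na(results$p_value) & results$p_value < alpha)
}
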
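# Independent oracles, deliberately written from first principles and kept
# separate from the package's code paths.

# Naive two-group log-rank tally: explicit loop over distinct event times,
# hypergeometric mean/variance with the tie correction, no matrix algebra.
naive_logrank_chisq <- function(time, status, group1) {
  stopifnot(length(time) == length(status), length(time) == length(group1))
  et <- sort(unique(time[status == 1]))
  o <- 0; e <- 0; v <- 0
  for (t in et) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group1)
    d <- sum(time == t & status == 1)
    d1 <- sum(time == t & status == 1 & group1)
    o <- o + d1
    e <- e + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  list(chisq = if (v > 0) (o - e)^2 / v else NA_real_, o = o, e = e, v = v)
}

# Exact permutation distribution of the log-rank statistic over all
# reassignments of the group labels that preserve the group sizes.
permutation_logrank_p <- function(time, status, group1) {
  n <- length(time)
  k <- sum(group1)
  obs <- naive_logrank_chisq(time, status, group1)$chisq
  combos <- utils::combn(n, k)
  stats <- apply(combos, 2, function(idx) {
    g <- rep(FALSE, n); g[idx] <- TRUE
    naive_logrank_chisq(time, status, g)$chisq
  })
  stats <- stats[!is.na(stats)]
  list(
    p_ge = mean(stats >= obs - 1e-12),
    p_gt = mean(stats > obs + 1e-12),
    n_perm = length(stats),
    obs = obs
  )
}

# Analytic upper-tail mass of the truncated Pareto spectrum:
# P(X > x) for density proportional to x^-(shape+1) on [lo, hi].
pareto_tail_mass <- function(x, shape, lo, hi) {
  (x^(-shape) - hi^(-shape)) / (lo^(-shape) - hi^(-shape))
}

# Closed-form OLS slope of log y on log x (independent of lm / the package).
loglog_ols_slope <- function(x, y) {
  lx <- log(x); ly <- log(y)
  sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
}

# Brute-force grid search for the least-squares logistic CDF parameters.
grid_search_logistic <- function(x, p, mu_grid, s_grid) {
  best <- c(mu = NA, s = NA, rss = Inf)
  for (mu in mu_grid) for (s in s_grid) {
    rss <- sum((p - plogis(x, mu, s))^2)
    if (rss < best["rss"]) best <- c(mu = mu, s = s, rss = rss)
  }
  best
}

# Small deterministic survival datasets (n <= 8) with planted times, status
# and groups, covering ties, censoring at event times, and unbalanced groups.
small_survival_datasets <- function() {
  list(
    list(time = c(1, 2), status = c(1, 1), group = c(TRUE, FALSE)),
    list(time = c(1, 2, 3, 4), status = c(1, 1, 1, 1),
         group = c(TRUE, TRUE, FALSE, FALSE)),
    list(time = c(1, 1, 2, 3), status = c(1, 1, 1, 0),
         group = c(TRUE, FALSE, TRUE, FALSE)),
    list(time = c(2, 2, 2, 5, 6, 7), status = c(1, 1, 0, 1, 0, 1),
         group = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)),
    list(time = c(1, 2, 3, 4, 5, 6, 7, 8), status = c(1, 0, 1, 1, 0, 1, 1, 0),
         group = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE)),
    list(time = c(3, 3, 3, 3, 9, 9, 9, 9), status = c(1, 1, 1, 0, 1, 1, 0, 1),
         group = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)),
    list(time = c(1, 4, 4, 6, 6, 6, 10), status = c(0, 1, 1, 1, 0, 1, 1),
         group = c(FALSE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE))
  )
}

# Tiny cohort helper for hand-built screening scenarios.
toy_cohort <- function(time, status, m, stage = "toy") {
  cohort_data(
    sample_ids = sprintf("P%02d", seq_along(time)),
    gene_ids = sprintf("g%02d", seq_len(ncol(m))),
    mutation_matrix = m,
    time_months = time,
    status = status,
    stage_label = stage
  )
}
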
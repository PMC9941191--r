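#' Build a grid of subsample sizes
#'
#' Sizes are the rounded values of `n_total` times `n_levels` equally spaced
#' fractions between `frac_min` and `frac_max`, de-duplicated, floored at 2
#' samples and strictly increasing.
#'
#' @param n_total Full cohort size.
#' @param frac_min,frac_max Fraction range, 0 < `frac_min` <= `frac_max` <= 1.
#' @param n_levels Number of grid levels before de-duplication.
#' @return Strictly increasing integer vector of sizes, each >= 2.
#' @export
#' @examples
#' build_size_grid(100, 0.1, 0.9, 5)
build_size_grid <- function(n_total, frac_min = 0.05, frac_max = 0.95,
                            n_levels = 10L) {
  if (!is_count(n_total, 2L)) stop_param("n_total must be an integer >= 2")
  if (!is_number(frac_min) || !is_number(frac_max) ||
      frac_min <= 0 || frac_max > 1 || frac_min > frac_max) {
    stop_param("need 0 < frac_min <= frac_max <= 1")
  }
  if (!is_count(n_levels, 1L)) stop_param("n_levels must be an integer >= 1")
  fr <- if (n_levels == 1L) frac_min else seq(frac_min, frac_max, length.out = n_levels)
  sizes <- unique(as.integer(round(n_total * fr)))
  sizes <- sort(sizes[sizes >= 2L & sizes <= n_total])
  if (length(sizes) == 0L) {
    stop_param("size grid is empty after de-duplication and the >= 2 floor")
  }
  sizes
}

#' Draw a uniform random subsample of a cohort
#'
#' Selects `n` distinct samples uniformly without replacement; the gene list
#' and all per-sample fields are carried consistently. Uses the current RNG
#' state.
#'
#' @param cohort A [cohort_data()] object.
#' @param n Subsample size, 2 <= `n` <= number of samples.
#' @return A [cohort_data()] object restricted to the selected samples.
#' @export
subsample_cohort <- function(cohort, n) {
  stopifnot(inherits(cohort, "cohort_data"))
  n_total <- length(cohort$sample_ids)
  if (!is_count(n, 2L) || n > n_total) {
    stop_param("subsample size must be an integer in [2, ", n_total, "]")
  }
  idx <- sample.int(n_total, n)
  cohort_data(
    sample_ids = cohort$sample_ids[idx],
    gene_ids = cohort$gene_ids,
    mutation_matrix = cohort$mutation_matrix[idx, , drop = FALSE],
    time_months = cohort$time_months[idx],
    status = cohort$status[idx],
    stage_label = cohort$stage_label
  )
}

# One reproducible child seed per (size, replicate) record, spawned from the
# master seed, so serial and out-of-order execution give identical tables.
derive_record_seeds <- function(seed, n_records) {
  if (!is_count(seed, -.Machine$integer.max)) stop_param("seed must be an integer")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n_records)
}

#' Run the resampling saturation experiment
#'
#' For every size in `grid`, draws `n_reps` independent random subsamples
#' of the cohort (without replacement, redrawn independently at each size),
#' screens every gene with the mutant-vs-wild-type log-rank test via
#' [screen_genes()], and records the number of observed deaths and the
#' number of significant genes (p < `alpha`) in each replicate. Subsamples
#' that happen to contain no events are retained with a significant count
#' of 0.
#'
#' Each (size, replicate) pair runs on its own child RNG stream derived from
#' `seed`, so any single record can be reproduced in isolation and the full
#' table is identical across runs with the same seed.
#'
#' @param cohort A [cohort_data()] object.
#' @param grid Increasing integer vector of subsample sizes (see
#'   [build_size_grid()]).
#' @param n_reps Replicates per size level (default 100).
#' @param alpha Per-gene significance level (default 0.05, strict).
#' @param min_mutant Per-gene minimum mutant count filter (default 5).
#' @param seed Master seed.
#' @return A data frame of class `resample_records` with columns `size`,
#'   `replicate`, `n_events`, `n_significant`, `rng_stream`; exactly
#'   `length(grid) * n_reps` rows.
#' @export
run_saturation <- function(cohort, grid, n_reps = 100L, alpha = 0.05,
                           min_mutant = 5L, seed = 1L) {
  stopifnot(inherits(cohort, "cohort_data"))
  n_total <- length(cohort$sample_ids)
  if (length(grid) == 0L || any(grid != as.integer(grid)) ||
      any(grid < 2L) || any(grid > n_total) || is.unsorted(grid, strictly = TRUE)) {
    stop_param("grid must be strictly increasing integers in [2, n_total]")
  }
  if (!is_count(n_reps, 1L)) stop_param("n_reps must be an integer >= 1")

  grid <- as.integer(grid)
  n_rec <- length(grid) * n_reps
  seeds <- derive_record_seeds(seed, n_rec)

  size_col <- rep(grid, each = n_reps)
  rep_col <- rep(seq_len(n_reps), times = length(grid))
  n_events <- integer(n_rec)
  n_sig <- integer(n_rec)

  for (k in seq_len(n_rec)) {
    set.seed(seeds[k])
    sub <- subsample_cohort(cohort, size_col[k])
    n_events[k] <- sum(sub$status)
    n_sig[k] <- if (n_events[k] == 0L) {
      0L
    } else {
      count_significant(screen_genes(sub, alpha = alpha, min_mutant = min_mutant),
                        alpha = alpha)
    }
  }

  out <- data.frame(
    size = size_col,
    replicate = rep_col,
    n_events = n_events,
    n_significant = n_sig,
    rng_stream = seeds
  )
  attr(out, "alpha") <- alpha
  attr(out, "min_mutant") <- as.integer(min_mutant)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "n_total") <- n_total
  attr(out, "d_total") <- sum(cohort$status)
  class(out) <- c("resample_records", "data.frame")
  out
}

#' Summarise a saturation experiment per size level
#'
#' Per grid size: the mean significant-gene count and its standard error
#' (sample standard deviation over replicates divided by the square root of
#' the replicate count), the mean events number, and the empirical
#' probability of obtaining at least one significant gene.
#'
#' @param records A [run_saturation()] record table.
#' @return A data frame with columns `size`, `n_reps`, `mean_significant`,
#'   `se_significant`, `mean_events`, `prob_ge1`, one row per size.
#' @export
summarize_saturation <- function(records) {
  if (NROW(records) == 0L) stop_input("empty record table")
  if (!all(c("size", "n_significant", "n_events") %in% names(records))) {
    stop_input("records must have size, n_events and n_significant columns")
  }
  sizes <- sort(unique(records$size))
  out <- do.call(rbind, lapply(sizes, function(s) {
    x <- records[records$size == s, , drop = FALSE]
    n <- nrow(x)
    data.frame(
      size = s,
      n_reps = n,
      mean_significant = mean(x$n_significant),
      se_significant = if (n > 1L) sd(x$n_significant) / sqrt(n) else 0,
      mean_events = mean(x$n_events),
      prob_ge1 = mean(x$n_significant >= 1L)
    )
  }))
  rownames(out) <- NULL
  class(out) <- c("saturation_summary", "data.frame")
  out
}
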
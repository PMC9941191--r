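test_that("mutation-frequency spectrum respects bounds and the empty case", {
  expect_identical(sample_mutation_frequencies(0), numeric(0))
  set.seed(5)
  f <- sample_mutation_frequencies(10000, freq_shape = 1.4,
                                   freq_min = 0.01, freq_max = 0.6)
  expect_length(f, 10000)
  expect_true(all(f >= 0.01 & f <= 0.6))
  expect_error(sample_mutation_frequencies(10, freq_min = 0, freq_max = 0.5),
               class = "satscreen_parameter_error")
  expect_error(sample_mutation_frequencies(10, freq_min = 0.5, freq_max = 0.1),
               class = "satscreen_parameter_error")
})

test_that("spectrum tail mass matches the analytic truncated-Pareto CDF", {
  # expected number of genes above 5% frequency from the closed-form tail
  expected <- 14000 * pareto_tail_mass(0.05, 2.33, 0.005, 0.9)
  set.seed(81)
  counts <- replicate(5, {
    f <- sample_mutation_frequencies(14000, 2.33, 0.005, 0.9)
    sum(f > 0.05)
  })
  expect_gt(mean(counts), expected * 0.8)
  expect_lt(mean(counts), expected * 1.2)
  # a second point on the tail, different shape
  expected2 <- 5000 * pareto_tail_mass(0.1, 1.2, 0.01, 0.8)
  set.seed(82)
  f2 <- sample_mutation_frequencies(5000, 1.2, 0.01, 0.8)
  expect_gt(sum(f2 > 0.1), expected2 * 0.8)
  expect_lt(sum(f2 > 0.1), expected2 * 1.2)
})

test_that("simulate_cohort is a pure function of its configuration", {
  cfg <- sim_config(n_samples = 40L, n_genes = 30L, seed = 99L)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$mutation_matrix, b$mutation_matrix)
  expect_identical(a$time_months, b$time_months)
  expect_identical(a$status, b$status)
  # a different seed changes the draw
  c2 <- simulate_cohort(sim_config(n_samples = 40L, n_genes = 30L, seed = 100L))
  expect_false(identical(a$time_months, c2$time_months))
})

test_that("per-gene mutant counts are binomially calibrated", {
  cfg <- sim_config(
    n_samples = 300L, n_genes = 60L, freq_min = 0.05, freq_max = 0.5,
    freq_shape = 1, n_prognostic = 0L, hazard_ratio = 1, seed = 17L
  )
  cohort <- simulate_cohort(cfg)
  freqs <- attr(cohort, "freqs")
  counts <- colSums(cohort$mutation_matrix)
  # 99% binomial envelope per gene; expect ~0-2 of 60 outside by chance
  lo <- qbinom(0.005, 300, freqs)
  hi <- qbinom(0.995, 300, freqs)
  expect_lte(sum(counts < lo | counts > hi), 4)
})

test_that("a planted strong prognostic gene is detectable at the expected power", {
  # HR 4 at 20% frequency, 200 samples, event fraction near 0.5:
  # Schoenfeld's approximation gives power near 1 at alpha 0.05
  # (events ~100, log HR ~1.4, p(1-p) = 0.16 => z ~ 5.5), so the
  # Monte-Carlo rejection rate must comfortably exceed 0.5.
  rejections <- vapply(1:60, function(s) {
    fx <- make_fixture("one-strong-gene", seed = s)
    ch <- fx$cohort
    lt <- logrank_test(ch$time_months, ch$status, ch$mutation_matrix[, 1])
    lt$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.5)
})

test_that("event fraction decreases as the follow-up window is truncated", {
  base <- list(n_samples = 400L, n_genes = 5L, n_prognostic = 0L,
               hazard_ratio = 1, median_survival_months = 40,
               accrual_months = 10, seed = 4L)
  fracs <- vapply(c(60, 30, 15, 5), function(fu) {
    cfg <- do.call(sim_config, c(base, list(followup_months = fu)))
    mean(simulate_cohort(cfg)$status)
  }, numeric(1))
  expect_false(is.unsorted(rev(fracs)))
  # matches the closed-form expectation under exponential + uniform censoring
  pexp_cens <- function(m, fu, a) {
    lam <- log(2) / m
    1 - exp(-lam * fu) * (1 - exp(-lam * a)) / (lam * a)
  }
  expected <- vapply(c(60, 30, 15, 5), pexp_cens, numeric(1), m = 40, a = 10)
  se <- sqrt(expected * (1 - expected) / 400)
  expect_true(all(abs(fracs - expected) < 3 * se))
})

test_that("cohort validation rejects malformed inputs", {
  m <- matrix(0L, 2, 2)
  expect_error(cohort_data(c("a", "a"), c("g1", "g2"), m, c(1, 2), c(0, 1)),
               class = "satscreen_input_error")
  expect_error(cohort_data(c("a", "b"), c("g1", "g2"), m, c(0, 2), c(0, 1)),
               class = "satscreen_input_error")
  expect_error(cohort_data(c("a", "b"), c("g1", "g2"), m, c(1, 2), c(0, 2)),
               class = "satscreen_input_error")
  expect_error(cohort_data(c("a", "b"), c("g1", "g2"), m + 3L, c(1, 2), c(0, 1)),
               class = "satscreen_input_error")
  expect_error(sim_config(hazard_ratio = -1), class = "satscreen_parameter_error")
  expect_error(sim_config(freq_min = 0.5, freq_max = 0.1),
               class = "satscreen_parameter_error")
  expect_error(sim_config(n_prognostic = 10, n_genes = 5),
               class = "satscreen_parameter_error")
})

test_that("MAF round trip preserves the cohort and collapses duplicate rows", {
  cfg <- sim_config(n_samples = 25L, n_genes = 15L, freq_min = 0.2,
                    freq_max = 0.6, freq_shape = 1, n_prognostic = 0L,
                    hazard_ratio = 1, seed = 3L)
  cohort <- simulate_cohort(cfg)
  stopifnot(all(rowSums(cohort$mutation_matrix) > 0))  # MAF can represent all
  maf <- tempfile(fileext = ".maf")
  clin <- tempfile(fileext = ".tsv")
  write_cohort(cohort, maf, clin)
  back <- read_cohort(maf, clin)
  idx <- match(cohort$sample_ids, back$sample_ids)
  expect_setequal(back$sample_ids, cohort$sample_ids)
  expect_setequal(back$gene_ids,
                  cohort$gene_ids[colSums(cohort$mutation_matrix) > 0])
  expect_equal(back$time_months[idx], cohort$time_months)
  expect_identical(back$status[idx], cohort$status)
  shared <- intersect(back$gene_ids, cohort$gene_ids)
  expect_identical(unname(back$mutation_matrix[idx, shared]),
                   unname(cohort$mutation_matrix[, shared]))

  # three variant rows for one sample+gene collapse to a single indicator
  maf2 <- tempfile(fileext = ".maf")
  writeLines(c(
    "Hugo_Symbol\tTumor_Sample_Barcode\tVariant_Classification",
    "TP53\tS1\tMissense_Mutation",
    "TP53\tS1\tNonsense_Mutation",
    "TP53\tS1\tSplice_Site",
    "KMT2D\tS2\tMissense_Mutation"
  ), maf2)
  clin2 <- tempfile(fileext = ".tsv")
  writeLines(c(
    "sample\ttime_months\tstatus\tstage",
    "S1\t10\t1\tII",
    "S2\t20\t0\tII"
  ), clin2)
  b2 <- read_cohort(maf2, clin2)
  expect_identical(b2$mutation_matrix["S1", "TP53"], 1L)
  expect_identical(sum(b2$mutation_matrix), 2L)
})

test_that("clinical table problems are excluded-with-warning or rejected", {
  maf <- tempfile(fileext = ".maf")
  writeLines(c(
    "Hugo_Symbol\tTumor_Sample_Barcode\tVariant_Classification",
    "TP53\tS1\tMissense_Mutation",
    "TP53\tS2\tMissense_Mutation",
    "NFE2L2\tS3\tMissense_Mutation"
  ), maf)
  # missing time: excluded with a warning naming the sample
  clin_na <- tempfile()
  writeLines(c("sample\ttime_months\tstatus\tstage",
               "S1\t10\t1\tII", "S2\tNA\t0\tII", "S3\t5\t1\tII"), clin_na)
  expect_warning(ch <- read_cohort(maf, clin_na), "S2")
  expect_setequal(ch$sample_ids, c("S1", "S3"))
  # status = 2: input error
  clin_bad <- tempfile()
  writeLines(c("sample\ttime_months\tstatus\tstage",
               "S1\t10\t1\tII", "S2\t8\t2\tII"), clin_bad)
  expect_error(read_cohort(maf, clin_bad), class = "satscreen_input_error")
  # no overlap at all: input error
  clin_none <- tempfile()
  writeLines(c("sample\ttime_months\tstatus\tstage", "X9\t10\t1\tII"), clin_none)
  expect_error(read_cohort(maf, clin_none), class = "satscreen_input_error")
})
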
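#' Simulation configuration for a synthetic mutation--survival cohort
#'
#' Bundles and validates the parameters of the synthetic cohort generator.
#' The defaults emulate a single-centre stage II oesophageal squamous cell
#' carcinoma cohort: 222 cases, roughly 14,000 somatically mutable genes of
#' which about 65 exceed 5% mutation frequency, an overall-survival event
#' fraction near 0.35 and a median follow-up around 34 months.
#'
#' @param n_samples Number of patients in the cohort.
#' @param n_genes Number of mutable genes.
#' @param freq_min,freq_max Bounds of the per-gene mutation-frequency
#'   spectrum, in (0, 1].
#' @param freq_shape Tail-heaviness exponent of the truncated-Pareto
#'   frequency spectrum (> 0). Larger values concentrate mass near
#'   `freq_min`. The default 2.33 puts an expected 65 of 14,000 genes above
#'   5% frequency.
#' @param n_prognostic Number of true prognostic genes. The first
#'   `n_prognostic` gene indices carry the effect.
#' @param hazard_ratio Multiplicative hazard per mutated prognostic gene
#'   (> 0). Either a scalar shared by all prognostic genes or a vector of
#'   length `n_prognostic`.
#' @param median_survival_months Baseline (all-wild-type) median overall
#'   survival, in months.
#' @param accrual_months,followup_months Administrative censoring window:
#'   each patient is censored at `followup_months` plus a uniform accrual
#'   offset on \[0, `accrual_months`\]. Their sum must be positive.
#' @param round_times Round observed times to 0.1 month (floored at 0.1) to
#'   exercise tie handling downstream. Default `FALSE`: continuous times.
#' @param stage_label Free-text stage annotation carried into the cohort.
#' @param seed Integer RNG seed; the cohort is a pure function of the
#'   configuration including this seed.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @seealso [simulate_cohort()], [sample_mutation_frequencies()]
#' @export
#' @examples
#' cfg <- sim_config(n_samples = 50, n_genes = 100, seed = 7)
#' cohort <- simulate_cohort(cfg)
sim_config <- function(n_samples = 222L,
                       n_genes = 14000L,
                       freq_min = 0.005,
                       freq_max = 0.9,
                       freq_shape = 2.33,
                       n_prognostic = 5L,
                       hazard_ratio = 2.5,
                       median_survival_months = 55,
                       accrual_months = 20,
                       followup_months = 24,
                       round_times = FALSE,
                       stage_label = "synthetic",
                       seed = 1L) {
  cfg <- structure(
    list(
      n_samples = as.integer(n_samples),
      n_genes = as.integer(n_genes),
      freq_min = freq_min,
      freq_max = freq_max,
      freq_shape = freq_shape,
      n_prognostic = as.integer(n_prognostic),
      hazard_ratio = hazard_ratio,
      median_survival_months = median_survival_months,
      accrual_months = accrual_months,
      followup_months = followup_months,
      round_times = isTRUE(round_times),
      stage_label = as.character(stage_label),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param config An object to validate.
#' @export
validate_sim_config <- function(config) {
  c_ <- config
  if (!is_count(c_$n_samples, 1L)) stop_param("n_samples must be a positive integer")
  if (!is_count(c_$n_genes, 0L)) stop_param("n_genes must be a non-negative integer")
  if (!is_number(c_$freq_min) || !is_number(c_$freq_max) ||
      c_$freq_min <= 0 || c_$freq_max > 1 || c_$freq_min > c_$freq_max) {
    stop_param("mutation-frequency bounds need 0 < freq_min <= freq_max <= 1")
  }
  if (!is_number(c_$freq_shape) || c_$freq_shape <= 0) {
    stop_param("freq_shape must be a positive real")
  }
  if (!is_count(c_$n_prognostic) || c_$n_prognostic > c_$n_genes) {
    stop_param("n_prognostic must be an integer in [0, n_genes]")
  }
  if (!is.numeric(c_$hazard_ratio) || any(!is.finite(c_$hazard_ratio)) ||
      any(c_$hazard_ratio <= 0) ||
      !(length(c_$hazard_ratio) %in% c(1L, max(1L, c_$n_prognostic)))) {
    stop_param("hazard_ratio must be positive, scalar or length n_prognostic")
  }
  if (!is_number(c_$median_survival_months) || c_$median_survival_months <= 0) {
    stop_param("median_survival_months must be > 0")
  }
  if (!is_number(c_$accrual_months) || c_$accrual_months < 0 ||
      !is_number(c_$followup_months) || c_$followup_months < 0 ||
      c_$accrual_months + c_$followup_months <= 0) {
    stop_param("censoring window must be non-negative with positive total length")
  }
  if (!is_count(c_$seed, -.Machine$integer.max)) stop_param("seed must be an integer")
  config
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: %d samples x %d genes (%s)\n", x$n_samples, x$n_genes, x$stage_label
  ))
  cat(sprintf(
    "  frequency spectrum: truncated Pareto shape %.3g on [%.3g, %.3g]\n",
    x$freq_shape, x$freq_min, x$freq_max
  ))
  cat(sprintf(
    "  %d prognostic gene(s), hazard ratio %s\n",
    x$n_prognostic, paste(format(x$hazard_ratio), collapse = ", ")
  ))
  cat(sprintf(
    "  baseline median OS %.4g mo; censoring %.4g + U(0, %.4g) mo; seed %d\n",
    x$median_survival_months, x$followup_months, x$accrual_months, x$seed
  ))
  invisible(x)
}

#' Draw per-gene mutation probabilities from a truncated Pareto spectrum
#'
#' Somatic mutation frequencies across genes are heavy-tailed: most genes are
#' rarely mutated and a few are common. Frequencies are drawn by inverse-CDF
#' sampling from a Pareto density proportional to x^-(shape + 1) truncated to
#' \[`freq_min`, `freq_max`\].
#'
#' @param n_genes Number of genes (vector length).
#' @param freq_shape Positive tail exponent; see [sim_config()].
#' @param freq_min,freq_max Truncation bounds, 0 < `freq_min` <=
#'   `freq_max` <= 1.
#' @return Numeric vector of length `n_genes` with entries in
#'   \[`freq_min`, `freq_max`\]. Uses the current RNG state.
#' @export
sample_mutation_frequencies <- function(n_genes, freq_shape = 2.33,
                                        freq_min = 0.005, freq_max = 0.9) {
  if (!is_count(n_genes)) stop_param("n_genes must be a non-negative integer")
  if (!is_number(freq_shape) || freq_shape <= 0) stop_param("freq_shape must be > 0")
  if (!is_number(freq_min) || !is_number(freq_max) ||
      freq_min <= 0 || freq_max > 1 || freq_min > freq_max) {
    stop_param("need 0 < freq_min <= freq_max <= 1")
  }
  if (n_genes == 0L) return(numeric(0))
  if (freq_min == freq_max) return(rep(freq_min, n_genes))
  u <- runif(n_genes)
  a <- freq_shape
  lo <- freq_min^(-a)
  hi <- freq_max^(-a)
  (lo - u * (lo - hi))^(-1 / a)
}

#' Construct and validate a cohort
#'
#' A cohort couples a binary sample-by-gene somatic mutation indicator matrix
#' with per-sample overall-survival follow-up.
#'
#' @param sample_ids Character vector of unique sample identifiers.
#' @param gene_ids Character vector of unique gene identifiers.
#' @param mutation_matrix 0/1 matrix, one row per sample, one column per gene;
#'   1 marks the gene somatically mutated in the sample.
#' @param time_months Per-sample overall-survival time in months, all > 0.
#' @param status Per-sample event indicator: 1 = death observed, 0 = censored.
#' @param stage_label Free-text stage annotation.
#' @return An object of class `cohort_data`.
#' @export
cohort_data <- function(sample_ids, gene_ids, mutation_matrix,
                        time_months, status, stage_label = "unknown") {
  sample_ids <- as.character(sample_ids)
  gene_ids <- as.character(gene_ids)
  m <- as.matrix(mutation_matrix)
  storage.mode(m) <- "integer"
  if (anyDuplicated(sample_ids)) stop_input("sample ids must be unique")
  if (anyDuplicated(gene_ids)) stop_input("gene ids must be unique")
  if (nrow(m) != length(sample_ids) || ncol(m) != length(gene_ids)) {
    stop_input("mutation_matrix dimensions must match id list lengths")
  }
  if (length(m) && !all(m %in% c(0L, 1L))) {
    stop_input("mutation_matrix must be binary 0/1")
  }
  if (length(time_months) != length(sample_ids) ||
      length(status) != length(sample_ids)) {
    stop_input("time_months and status must have one entry per sample")
  }
  if (any(!is.finite(time_months)) || any(time_months <= 0)) {
    stop_input("every survival time must be finite and > 0")
  }
  status <- as.integer(status)
  if (any(is.na(status)) || !all(status %in% c(0L, 1L))) {
    stop_input("status values must be 0 or 1")
  }
  dimnames(m) <- list(sample_ids, gene_ids)
  structure(
    list(
      sample_ids = sample_ids,
      gene_ids = gene_ids,
      mutation_matrix = m,
      time_months = as.numeric(time_months),
      status = status,
      stage_label = as.character(stage_label)
    ),
    class = "cohort_data"
  )
}

#' @export
print.cohort_data <- function(x, ...) {
  cat(sprintf(
    "cohort_data: %d samples x %d genes (%s)\n",
    length(x$sample_ids), length(x$gene_ids), x$stage_label
  ))
  cat(sprintf(
    "  events: %d/%d (%.1f%%); median observed time %.1f months\n",
    sum(x$status), length(x$status),
    100 * mean(x$status), stats::median(x$time_months)
  ))
  invisible(x)
}

#' Simulate a mutation--survival cohort
#'
#' Mutation indicators are drawn independently per sample and gene from
#' per-gene frequencies sampled by [sample_mutation_frequencies()]. Survival
#' follows an exponential proportional-hazards model: the baseline hazard is
#' log(2) / `median_survival_months` and each mutated prognostic gene (the
#' first `n_prognostic` gene indices) multiplies a sample's hazard by its
#' hazard ratio. Censoring is administrative: `followup_months` plus a
#' uniform accrual offset on \[0, `accrual_months`\]; the observed time is
#' the minimum of event and censoring time with the matching status.
#'
#' The same configuration (including its seed) always reproduces the cohort
#' exactly.
#'
#' @param config A [sim_config()] object.
#' @param freqs Optional numeric vector of per-gene mutation frequencies
#'   overriding the sampled spectrum (length `n_genes`, entries in (0, 1\]).
#'   Used e.g. to plant prognostic genes at fixed, detectable frequencies.
#' @return A [cohort_data()] object with the realised per-gene frequencies
#'   attached as attribute `"freqs"`.
#' @export
simulate_cohort <- function(config, freqs = NULL) {
  config <- validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_samples
  g <- config$n_genes
  if (is.null(freqs)) {
    freqs <- sample_mutation_frequencies(
      g, config$freq_shape, config$freq_min, config$freq_max
    )
  } else {
    if (length(freqs) != g || any(!is.finite(freqs)) ||
        any(freqs <= 0) || any(freqs > 1)) {
      stop_param("freqs override must have one probability in (0, 1] per gene")
    }
  }
  m <- matrix(rbinom(n * g, 1L, rep(freqs, each = n)), nrow = n, ncol = g)

  base_rate <- log(2) / config$median_survival_months
  rate <- rep(base_rate, n)
  np <- config$n_prognostic
  if (np > 0L) {
    log_hr <- log(rep_len(config$hazard_ratio, np))
    rate <- base_rate * exp(as.vector(m[, seq_len(np), drop = FALSE] %*% log_hr))
  }
  t_event <- rexp(n, rate)
  t_cens <- config$followup_months + runif(n, 0, config$accrual_months)
  time <- pmin(t_event, t_cens)
  status <- as.integer(t_event <= t_cens)
  if (config$round_times) {
    time <- pmax(round(time * 10) / 10, 0.1)
  }

  cohort <- cohort_data(
    sample_ids = sprintf("S%04d", seq_len(n)),
    gene_ids = sprintf("G%05d", seq_len(g)),
    mutation_matrix = m,
    time_months = time,
    status = status,
    stage_label = config$stage_label
  )
  attr(cohort, "freqs") <- freqs
  cohort
}

#' Write a cohort as a MAF-style mutation table plus a clinical table
#'
#' Emits one tab-delimited MAF row (`Hugo_Symbol`, `Tumor_Sample_Barcode`,
#' `Variant_Classification`) per mutated sample-gene pair, and a clinical TSV
#' with columns `sample`, `time_months`, `status`, `stage`.
#'
#' Samples with no mutated gene produce no MAF rows and therefore cannot be
#' recovered by [read_cohort()], which inner-joins the two tables.
#'
#' @param cohort A [cohort_data()] object.
#' @param maf_path,clinical_path Output file paths.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(cohort, maf_path, clinical_path) {
  stopifnot(inherits(cohort, "cohort_data"))
  hits <- which(cohort$mutation_matrix == 1L, arr.ind = TRUE)
  maf <- data.frame(
    Hugo_Symbol = cohort$gene_ids[hits[, "col"]],
    Tumor_Sample_Barcode = cohort$sample_ids[hits[, "row"]],
    Variant_Classification = "Missense_Mutation",
    stringsAsFactors = FALSE
  )
  maf <- maf[order(maf$Tumor_Sample_Barcode, maf$Hugo_Symbol), , drop = FALSE]
  write.table(maf, maf_path, sep = "\t", quote = FALSE, row.names = FALSE)
  clin <- data.frame(
    sample = cohort$sample_ids,
    time_months = cohort$time_months,
    status = cohort$status,
    stage = cohort$stage_label,
    stringsAsFactors = FALSE
  )
  write.table(clin, clinical_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(maf = maf_path, clinical = clinical_path))
}

#' Read a cohort from a MAF-style mutation table and a clinical table
#'
#' Multiple MAF rows for the same sample-gene pair collapse to a single
#' indicator 1. The mutation and clinical tables are inner-joined on sample
#' id; clinical rows with missing time or status are excluded with a warning
#' listing them, while out-of-range values (non-positive times, status
#' outside 0/1) raise an input error.
#'
#' @param maf_path Tab-delimited MAF with at least `Hugo_Symbol` and
#'   `Tumor_Sample_Barcode` columns (header required); extra columns are
#'   ignored.
#' @param clinical_path Tab-delimited table with columns `sample`,
#'   `time_months`, `status` and optionally `stage`.
#' @return A [cohort_data()] object.
#' @export
read_cohort <- function(maf_path, clinical_path) {
  maf <- read.delim(maf_path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("Hugo_Symbol", "Tumor_Sample_Barcode")
  if (!all(need %in% names(maf))) {
    stop_input("MAF must have columns: ", paste(need, collapse = ", "))
  }
  clin <- read.delim(clinical_path, stringsAsFactors = FALSE, check.names = FALSE)
  need_clin <- c("sample", "time_months", "status")
  if (!all(need_clin %in% names(clin))) {
    stop_input("clinical table must have columns: ", paste(need_clin, collapse = ", "))
  }
  if (anyDuplicated(clin$sample)) stop_input("duplicated sample ids in clinical table")

  incomplete <- is.na(clin$time_months) | is.na(clin$status)
  if (any(incomplete)) {
    warning(
      "excluding ", sum(incomplete), " clinical sample(s) with missing time/status: ",
      paste(clin$sample[incomplete], collapse = ", "),
      call. = FALSE
    )
    clin <- clin[!incomplete, , drop = FALSE]
  }
  if (any(!clin$status %in% c(0, 1))) {
    stop_input("clinical status values must be 0 or 1")
  }
  if (any(clin$time_months <= 0)) {
    stop_input("clinical survival times must be > 0")
  }

  samples <- intersect(clin$sample, unique(maf$Tumor_Sample_Barcode))
  if (length(samples) == 0L) {
    stop_input("no usable samples shared between MAF and clinical table")
  }
  clin <- clin[match(samples, clin$sample), , drop = FALSE]
  genes <- sort(unique(maf$Hugo_Symbol))
  keep <- maf$Tumor_Sample_Barcode %in% samples
  m <- matrix(0L, nrow = length(samples), ncol = length(genes))
  m[cbind(
    match(maf$Tumor_Sample_Barcode[keep], samples),
    match(maf$Hugo_Symbol[keep], genes)
  )] <- 1L

  stage <- if ("stage" %in% names(clin)) {
    paste(sort(unique(as.character(clin$stage))), collapse = "+")
  } else {
    "unknown"
  }
  cohort_data(
    sample_ids = samples,
    gene_ids = genes,
    mutation_matrix = m,
    time_months = clin$time_months,
    status = clin$status,
    stage_label = stage
  )
}
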
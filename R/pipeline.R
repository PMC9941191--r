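#' Configuration for an end-to-end saturation run
#'
#' Exactly one input source must be given: a [sim_config()] for a synthetic
#' cohort, or a pair of MAF + clinical paths for real data.
#'
#' @param simulation A [sim_config()] object, or `NULL`.
#' @param maf_path,clinical_path Input file paths for [read_cohort()], or
#'   `NULL`.
#' @param frac_min,frac_max,n_levels Size-grid parameters for
#'   [build_size_grid()]. The default grid spans 5%--95% of the cohort in
#'   10 equal steps.
#' @param n_reps Replicates per size level (default 100).
#' @param alpha Per-gene significance level (default 0.05, strict).
#' @param min_mutant Per-gene minimum mutant count (default 5).
#' @param fit_scale Power-law fitting scale, see [fit_power_law()].
#' @param targets Discovery-probability targets to invert (default 0.9 and
#'   the empirical 1.0 rule).
#' @param freqs Optional per-gene frequency override passed to
#'   [simulate_cohort()].
#' @param out_dir Output directory for the report bundle.
#' @param seed Master seed for subsampling (and, for synthetic input, the
#'   cohort seed already inside `simulation`).
#' @return An object of class `run_config`.
#' @export
run_config <- function(simulation = NULL, maf_path = NULL, clinical_path = NULL,
                       frac_min = 0.05, frac_max = 0.95, n_levels = 10L,
                       n_reps = 100L, alpha = 0.05, min_mutant = 5L,
                       fit_scale = c("log-log", "linear"),
                       targets = c(0.9, 1.0), freqs = NULL,
                       out_dir = NULL, seed = 1L) {
  fit_scale <- match.arg(fit_scale)
  has_sim <- !is.null(simulation)
  has_paths <- !is.null(maf_path) || !is.null(clinical_path)
  if (has_sim == has_paths) {
    stop_param("give exactly one of: a simulation config, or MAF + clinical paths")
  }
  if (has_paths && (is.null(maf_path) || is.null(clinical_path))) {
    stop_param("both maf_path and clinical_path are required for real input")
  }
  if (has_sim) validate_sim_config(simulation)
  if (!is_count(n_reps, 1L)) stop_param("n_reps must be an integer >= 1")
  if (any(!is.finite(targets)) || any(targets <= 0) || any(targets > 1)) {
    stop_param("targets must lie in (0, 1]")
  }
  structure(
    list(
      simulation = simulation, maf_path = maf_path, clinical_path = clinical_path,
      frac_min = frac_min, frac_max = frac_max, n_levels = as.integer(n_levels),
      n_reps = as.integer(n_reps), alpha = alpha, min_mutant = as.integer(min_mutant),
      fit_scale = fit_scale, targets = targets, freqs = freqs,
      out_dir = out_dir, seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML or JSON file
#'
#' Field names mirror the [run_config()] (and nested [sim_config()])
#' arguments exactly; the simulation block lives under key `simulation`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  sim <- NULL
  if (!is.null(raw$simulation)) {
    sim <- do.call(sim_config, raw$simulation)
  }
  args <- raw[setdiff(names(raw), "simulation")]
  do.call(run_config, c(list(simulation = sim), args))
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(errorCondition(
      paste0("[stage: ", stage, "] ", conditionMessage(e)),
      class = unique(c("satscreen_stage_error", class(e)))
    ))
  })
}

#' Run the full saturation pipeline
#'
#' Executes simulate/read -> subsample+screen -> summarise -> curve fits as
#' one reproducible run. Fits are attempted for: significant-gene count
#' versus cohort size and versus mean events number (power law), and the
#' probability of at least one significant gene versus cohort size
#' (logistic CDF), inverted at each probability target. A fit that is not
#' identifiable on the run's data (for example, a null cohort whose counts
#' are all zero) is reported as `NULL` with the failure message recorded.
#'
#' When `config$out_dir` is set, the bundle is written there:
#' `replicates.csv`, `summary.csv`, `fits.json` and `manifest.json`. With
#' the same configuration and seed the tables are byte-identical across
#' runs.
#'
#' @param config A [run_config()] object.
#' @return Invisibly, a list with `cohort`, `grid`, `records`, `summary`,
#'   `fits` and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))

  cohort <- with_stage("input", {
    if (!is.null(config$simulation)) {
      simulate_cohort(config$simulation, freqs = config$freqs)
    } else {
      read_cohort(config$maf_path, config$clinical_path)
    }
  })

  grid <- with_stage("grid", build_size_grid(
    length(cohort$sample_ids), config$frac_min, config$frac_max, config$n_levels
  ))

  records <- with_stage("saturation", run_saturation(
    cohort, grid,
    n_reps = config$n_reps, alpha = config$alpha,
    min_mutant = config$min_mutant, seed = config$seed
  ))

  summ <- with_stage("summary", summarize_saturation(records))

  fits <- with_stage("fits", fit_report(summ, records, config))

  manifest <- list(
    package = "satscreen",
    version = as.character(packageVersion("satscreen")),
    seed = config$seed,
    grid = grid,
    n_reps = config$n_reps,
    alpha = config$alpha,
    min_mutant = config$min_mutant,
    fit_scale = config$fit_scale,
    input = if (is.null(config$simulation)) {
      list(kind = "files", maf = config$maf_path, clinical = config$clinical_path)
    } else {
      list(kind = "simulation", config = unclass(config$simulation))
    },
    cohort = list(
      n_samples = length(cohort$sample_ids),
      n_genes = length(cohort$gene_ids),
      n_events = sum(cohort$status),
      stage = cohort$stage_label
    ),
    rows = list(replicates = nrow(records), summary = nrow(summ))
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write.table(records, file.path(config$out_dir, "replicates.csv"),
                sep = ",", quote = FALSE, row.names = FALSE)
    write.table(summ, file.path(config$out_dir, "summary.csv"),
                sep = ",", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(fits, file.path(config$out_dir, "fits.json"),
                         auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  }

  invisible(list(
    cohort = cohort, grid = grid, records = records,
    summary = summ, fits = fits, manifest = manifest
  ))
}

# Fit the three curves on the per-size summary; individual fits may fail on
# degenerate runs and are then reported as NULL with the message kept.
fit_report <- function(summ, records, config) {
  try_fit <- function(expr) {
    tryCatch(expr, error = function(e) {
      structure(list(), failed = conditionMessage(e))
    })
  }
  as_entry <- function(fit) {
    if (!is.null(attr(fit, "failed"))) {
      return(list(fitted = FALSE, reason = attr(fit, "failed")))
    }
    c(list(fitted = TRUE), unclass(fit))
  }

  pl_size <- try_fit(fit_power_law(summ$size, summ$mean_significant,
                                   fit_scale = config$fit_scale))
  ev_ok <- summ$mean_events > 0
  pl_events <- try_fit(fit_power_law(summ$mean_events[ev_ok],
                                     summ$mean_significant[ev_ok],
                                     fit_scale = config$fit_scale))
  lg <- try_fit(fit_logistic_cdf(summ$size, summ$prob_ge1, weights = summ$n_reps))

  n_total <- attr(records, "n_total")
  d_total <- attr(records, "d_total")
  min_sizes <- lapply(config$targets, function(tp) {
    sz <- if (tp < 1) {
      if (is.null(attr(lg, "failed"))) size_for_probability(lg, target_p = tp) else NA_integer_
    } else {
      size_for_probability(NULL, records = records, target_p = 1)
    }
    in_range <- !is.na(sz) && sz >= 0 && sz <= n_total
    list(
      target_probability = tp,
      rule = if (tp < 1) "logistic inverse (ceiling)" else "empirical: all replicates succeed at and above this size",
      min_size = if (is.na(sz)) NULL else sz,
      expected_events = if (in_range) expected_events(sz, n_total, d_total) else NULL,
      beyond_cohort = if (!is.na(sz) && !in_range) TRUE else NULL,
      attained = !is.na(sz)
    )
  })

  list(
    power_law_count_vs_size = as_entry(pl_size),
    power_law_count_vs_events = as_entry(pl_events),
    logistic_prob_vs_size = as_entry(lg),
    minimum_requirements = min_sizes,
    cohort = list(n_total = n_total, d_total = d_total)
  )
}

#' Deterministic miniature cohorts for tests and examples
#'
#' Presets:
#' \describe{
#'   \item{`null-cohort`}{120 samples, 150 genes, no prognostic effect
#'     (hazard ratio 1); per-gene log-rank p-values are uniform by
#'     construction. Frequencies span 10--50% so most genes pass the
#'     minimum-mutant filter.}
#'   \item{`one-strong-gene`}{200 samples, 120 genes, a single prognostic
#'     gene planted at 20% frequency with hazard ratio 4, strong enough
#'     that the planted gene is almost always the screen's top hit.}
#'   \item{`stageII-like`}{222 samples, 300 genes, 5 prognostic genes
#'     (hazard ratio 2.5) planted at 10--30% frequency; event fraction
#'     near 77/222 and median follow-up near 34 months.}
#'   \item{`stageIII-like`}{165 samples, 300 genes, 5 prognostic genes as
#'     above; event fraction near 99/165 and median follow-up near 27
#'     months.}
#' }
#'
#' @param preset One of `"null-cohort"`, `"one-strong-gene"`,
#'   `"stageII-like"`, `"stageIII-like"`.
#' @param seed Integer seed; the same preset and seed always return the
#'   identical fixture.
#' @return A list with `preset`, `config`, `freqs` (the per-gene frequency
#'   vector with the planted genes pinned, or `NULL` when the raw spectrum
#'   is used — pass both to [run_config()] to re-simulate the same cohort),
#'   `cohort` and `expected` (the design values the preset targets: event
#'   fraction, planted genes).
#' @export
make_fixture <- function(preset, seed = 1L) {
  presets <- c("null-cohort", "one-strong-gene", "stageII-like", "stageIII-like")
  if (!is.character(preset) || length(preset) != 1L || !preset %in% presets) {
    stop_param("unknown preset; choose one of: ", paste(presets, collapse = ", "))
  }
  cfg <- switch(
    preset,
    "null-cohort" = sim_config(
      n_samples = 120L, n_genes = 150L,
      freq_min = 0.1, freq_max = 0.5, freq_shape = 1,
      n_prognostic = 0L, hazard_ratio = 1,
      median_survival_months = 55, accrual_months = 20, followup_months = 24,
      stage_label = "synthetic-null", seed = seed
    ),
    "one-strong-gene" = sim_config(
      n_samples = 200L, n_genes = 120L,
      freq_min = 0.02, freq_max = 0.5, freq_shape = 1.5,
      n_prognostic = 1L, hazard_ratio = 4,
      median_survival_months = 45, accrual_months = 20, followup_months = 24,
      stage_label = "synthetic-one-gene", seed = seed
    ),
    "stageII-like" = sim_config(
      n_samples = 222L, n_genes = 300L,
      n_prognostic = 5L, hazard_ratio = 2.5,
      median_survival_months = 158, accrual_months = 20, followup_months = 24,
      stage_label = "synthetic-stageII", seed = seed
    ),
    "stageIII-like" = sim_config(
      n_samples = 165L, n_genes = 300L,
      n_prognostic = 5L, hazard_ratio = 2.5,
      median_survival_months = 48, accrual_months = 20, followup_months = 17,
      stage_label = "synthetic-stageIII", seed = seed
    )
  )

  freqs <- NULL
  if (preset == "one-strong-gene") {
    freqs <- planted_freqs(cfg, 0.2)
  } else if (preset %in% c("stageII-like", "stageIII-like")) {
    freqs <- planted_freqs(cfg, seq(0.10, 0.30, length.out = cfg$n_prognostic))
  }
  cohort <- simulate_cohort(cfg, freqs = freqs)

  expected <- switch(
    preset,
    "null-cohort" = list(event_fraction = 0.35, prognostic_genes = character(0)),
    "one-strong-gene" = list(
      event_fraction = 0.5, prognostic_genes = cohort$gene_ids[1L],
      planted_frequency = 0.2, hazard_ratio = 4
    ),
    "stageII-like" = list(
      event_fraction = 77 / 222, prognostic_genes = cohort$gene_ids[1:5],
      hazard_ratio = 2.5, median_followup_months = 34
    ),
    "stageIII-like" = list(
      event_fraction = 99 / 165, prognostic_genes = cohort$gene_ids[1:5],
      hazard_ratio = 2.5, median_followup_months = 27
    )
  )
  list(preset = preset, config = cfg, freqs = freqs, cohort = cohort,
       expected = expected)
}

# Spectrum draw with the prognostic genes pinned to fixed frequencies, so the
# planted effect is detectable regardless of the heavy-tailed background.
planted_freqs <- function(cfg, pinned) {
  set.seed(cfg$seed)
  freqs <- sample_mutation_frequencies(
    cfg$n_genes, cfg$freq_shape, cfg$freq_min, cfg$freq_max
  )
  freqs[seq_along(rep_len(pinned, cfg$n_prognostic))] <-
    rep_len(pinned, cfg$n_prognostic)
  freqs
}
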
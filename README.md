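# satscreen

Resampling-based saturation analysis of per-gene prognostic screening in
cancer cohorts.

Per-gene prognostic screens — split a cohort into carriers and non-carriers
of somatic mutations in each gene, compare overall survival with the
log-rank test, call genes with p < 0.05 prognostic — give notoriously
unstable results across studies, and much of that instability is driven by
cohort size. `satscreen` is for biostatisticians and cancer-genomics
analysts who want to quantify, for a given cohort (real or synthetic), how
discovery scales with sample size: it repeatedly subsamples the cohort at a
grid of sizes, runs the full Kaplan-Meier / log-rank screen in every
subsample, and fits two growth laws to the results:

* the number of significant genes *N* versus cohort size (or events number)
  *X* as a **power law**

  $$N = aX^{b},$$

  fitted by ordinary least squares on the log-log scale;

* the probability of obtaining **at least one** significant gene versus
  cohort size *x* as a **logistic cumulative distribution function**

  $$F(x) = \frac{1}{1 + e^{-(x-\mu)/s}},$$

  inverted in closed form to the minimum cohort size reaching a target
  probability, with a "100 %" requirement assessed empirically (a logistic
  only reaches 1 asymptotically).

Because log-rank power is driven by the number of deaths rather than by raw
cohort size, every result is also expressed in events numbers via the
hypergeometric subsample mean `round(n · D/N)` (`expected_events()`).

A synthetic cohort generator (truncated-Pareto mutation-frequency spectrum,
exponential proportional-hazards survival, administrative censoring) stands
in for patient-level data, with presets emulating single-centre stage II
(222 cases, 77 deaths) and stage III (165 cases, 99 deaths) oesophageal
squamous cell carcinoma cohorts. MAF-style mutation tables plus clinical
TSVs can be read directly for real-data screens.

## Quick start

```r
library(satscreen)

fx <- make_fixture("stageII-like", seed = 1)   # 222 samples x 300 genes
cfg <- run_config(
  simulation = fx$config, freqs = fx$freqs,    # keep the planted prognostic genes
  frac_min = 0.10, frac_max = 0.95, n_levels = 8L,
  n_reps = 50L, seed = 1L
)
res <- run_pipeline(cfg)
res$cohort
res$summary
```

```
cohort_data: 222 samples x 300 genes (synthetic-stageII)
  events: 80/222 (36.0%); median observed time 29.4 months
  size n_reps mean_significant se_significant mean_events prob_ge1
1   22     50             0.92          0.114        8.06     0.68
2   49     50             2.64          0.136       17.50     1.00
3   76     50             3.68          0.132       27.82     1.00
4  103     50             4.30          0.104       37.40     1.00
5  130     50             5.12          0.106       46.54     1.00
6  157     50             5.84          0.135       56.42     1.00
7  184     50             6.56          0.128       66.86     1.00
8  211     50             7.72          0.081       76.14     1.00
```

Each row is one subsample size: 50 random subsamples were drawn, each
screened gene-by-gene (mutant vs. wild-type log-rank, minimum 5 mutants,
p < 0.05 strict, no multiple-testing correction). `mean_significant` ± SE
is the significant-gene count, `mean_events` the average number of deaths
in the subsample, and `prob_ge1` the fraction of replicates with at least
one hit. The fitted curves for this run:

```
count vs size:   N = 0.07184 * X^0.8792  (R^2 = 0.973 on log-log scale)
count vs events: N = 0.1737  * X^0.8824
logistic:        mu = 20.2, s = 2.4
minimum size for 90% discovery probability:  26  (expected events:  9)
minimum size for 100% (empirical rule):      49  (expected events: 18)
```

The significant-gene count grows smoothly as a power law with no plateau in
sight, and the chance of finding *something* saturates long before the
count does — with five planted prognostic genes (hazard ratio 2.5) in this
small gene panel, every 49-case subsample already yields a hit. The
absolute constants are properties of this synthetic cohort (500-fold fewer
genes than an exome); the shape is the reproducible part. With the same
configuration and master seed, every table is byte-identical across runs.

`run_config(out_dir = ...)` additionally writes `replicates.csv`,
`summary.csv`, `fits.json` and a `manifest.json` sufficient to reproduce
any single replicate; `inst/scripts/satscreen-run.R` wraps the same
pipeline for shell use with a YAML/JSON config file. See the vignette
(`vignettes/saturation-analysis.Rmd`) for the model, its assumptions, and
every tunable parameter.

## Real data

```r
cohort <- read_cohort("mutations.maf", "clinical.tsv")
screen <- screen_genes(cohort, alpha = 0.05, min_mutant = 5)
records <- run_saturation(cohort, build_size_grid(nrow(screen), 0.05, 0.95, 10),
                          n_reps = 100, seed = 1)
```

The MAF needs `Hugo_Symbol` and `Tumor_Sample_Barcode` columns (extra
columns ignored; multiple variants per sample-gene collapse to one
indicator); the clinical TSV needs `sample`, `time_months`, `status`
(0/1) and optionally `stage`.

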
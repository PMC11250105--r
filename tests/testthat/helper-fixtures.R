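# Shared fixtures, built once per test run and memoised.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, expr, envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# Full-size default cohort (omics included), seed 1.
default_cohort <- function() {
  memo("default_cohort", simulate_cohort(generator_config(seed = 1)))
}

# Small, fast cohort for structural tests.
small_cohort <- function(seed = 5, ...) {
  memo(paste0("small_cohort_", seed),
       simulate_cohort(generator_config(
         n_nd = 12, n_t2d = 4, n_proteins = 120, n_genes = 160,
         n_modules = 2, module_size_range = c(8L, 10L),
         n_de_protein_up = 5, n_de_protein_down = 5,
         n_de_rna_up = 5, n_de_rna_down = 5, n_batches = 2,
         seed = seed, ...)))
}

# Noise-free degenerate cohort: no donor variation, no assay noise.
noisefree_cohort <- function() {
  memo("noisefree_cohort", simulate_cohort(generator_config(
    assay_cv = 0, n_tech_reps = 1, capacity_cv = 0,
    pi_fat = 0, pi_leu = 0, n_nd = 6, n_t2d = 3, seed = 11),
    include_omics = FALSE))
}

# Preprocessed default proteome/transcriptome (expensive; reused widely).
default_processed <- function() {
  memo("default_processed", {
    co <- default_cohort()
    list(cohort = co,
         protein = impute(normalize_proteome(filter_missing(co$protein))),
         rna = batch_adjust(normalize_counts(co$rna)))
  })
}

first_trace <- function(cohort, arm, group = NULL) {
  for (tr in cohort$traces) {
    if (tr$arm != arm) next
    if (!is.null(group) &&
        cohort$donors$group[cohort$donors$donor_id == tr$donor_id] != group)
      next
    return(normalize_secretion(tr))
  }
  stop("no matching trace")
}

# Trace with prescribed rate values on a simple two-segment protocol:
# basal 0-10 (rate = baseline), stim 10-(10+len).
toy_trace <- function(rates, baseline = 1, dt = 1, stim = "glucose15") {
  len <- (length(rates) - 1) * dt
  p <- stimulus_protocol(data.frame(
    name = c("basal", "stim"), stimulus = c("basal", stim),
    start_min = c(0, 10), end_min = c(10, 10 + len + dt),
    baseline = c(TRUE, FALSE)))
  tt <- c(seq(0, 10 - dt, by = dt), seq(10, 10 + len, by = dt))
  vv <- c(rep(baseline, length(seq(0, 10 - dt, by = dt))), rates)
  perifusion_trace("toy", "G", tt, vv, "pmol/islet/min", p, 65, 0.4)
}
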
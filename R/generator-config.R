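#' Configuration for the synthetic donor-cohort generator
#'
#' Collects every knob of the synthetic cohort: donor counts and the
#' hyper-responder mixture, stimulus-specific T2D effect multipliers, donor
#' and assay noise, and the structure of the paired proteome/transcriptome
#' matrices (planted co-expression modules, differential features, batches,
#' missingness, and the targeted across-gene RNA-protein correlation).
#'
#' The defaults are the package's reference study conditions: a cohort of
#' 123 non-diabetic and 17 type 2 diabetic donors, 8% fatty-acid and 9%
#' amino-acid hyper-responders, T2D secretion multipliers of 0.60 (15 mM
#' glucose), 0.65 (6 mM glucose), 0.45 (fat), 0.78 (KCl), 1.00 (leucine) and
#' 0.64 (leucine + 6 mM glucose), a 3-min T2D delay of the high-glucose
#' first-phase peak, and omics matrices of 2,000 proteins / 3,000 genes with
#' 18 planted proteome modules and a 0.5 across-gene RNA-protein correlation.
#'
#' @param n_nd,n_t2d Numbers of non-diabetic and T2D donors.
#' @param pi_fat,pi_leu Probabilities that a donor is a fatty-acid (resp.
#'   amino-acid) hyper-responder.
#' @param t2d_effect Named numeric vector of multiplicative secretion factors
#'   applied to T2D donors' stimulated responses, per stimulus.
#' @param t2d_peak_delay_min Added time-to-peak (min) of the T2D high-glucose
#'   first-phase pulse.
#' @param capacity_cv Coefficient of variation of the log-normal donor
#'   secretory capacity; per-stimulus donor response jitter uses the same
#'   log-sd, so `capacity_cv = 0` removes all donor-level variation.
#' @param assay_cv Multiplicative (log-normal) measurement noise CV per
#'   technical replicate.
#' @param n_tech_reps Technical replicates averaged per measured point.
#' @param baseline_rate Basal secretion rate, pmol per islet per minute.
#' @param mean_response Named vector of median stimulated response sizes
#'   (baseline-subtracted AUC in pmol/islet per unit capacity), per stimulus.
#' @param islet_count,flow_rate Islets per column and perifusate flow
#'   (mL/min); used to emit traces in effluent concentration units.
#' @param n_proteins,n_genes Feature counts of the two matrices.
#' @param n_modules Planted proteome co-expression modules.
#' @param module_size_range Length-2 integer range of module sizes.
#' @param module_trait_coupling data.frame with columns `module`, `trait`,
#'   `strength`: linear coupling of module latent factors to donor traits.
#' @param n_de_protein_up,n_de_protein_down,n_de_rna_up,n_de_rna_down Counts
#'   of planted T2D-differential features per direction.
#' @param de_log2fc Absolute log2 fold change of planted differential
#'   features.
#' @param rna_protein_r Target across-gene correlation between per-gene mean
#'   protein and mean RNA levels.
#' @param t2d_composition_shift plant the T2D beta-to-alpha cell-type
#'   composition shift (disable for fully null cohorts).
#' @param n_batches RNA measurement batches with location/scale shifts.
#' @param missing_frac Overall proteome missingness rate (abundance-dependent
#'   at the entry level).
#' @param high_missing_frac Fraction of proteins planted at high (>50%)
#'   missingness, to exercise the missingness filter.
#' @param seed Integer RNG seed; fixes all generator output bit-for-bit.
#' @return A validated `generator_config` object (list).
#' @export
generator_config <- function(n_nd = 123L, n_t2d = 17L,
                             pi_fat = 0.08, pi_leu = 0.09,
                             t2d_effect = c(glucose15 = 0.60, glucose6 = 0.65,
                                            fat = 0.45, kcl = 0.78,
                                            leucine = 1.00, leu_plus_g6 = 0.64),
                             t2d_peak_delay_min = 3,
                             capacity_cv = 0.30,
                             assay_cv = 0.10, n_tech_reps = 2L,
                             baseline_rate = 0.05,
                             mean_response = c(glucose15 = 20, glucose6 = 7,
                                               fat = 4, kcl = 12,
                                               leucine = 7, leu_plus_g6 = 10),
                             islet_count = 65L, flow_rate = 0.4,
                             n_proteins = 2000L, n_genes = 3000L,
                             n_modules = 18L, module_size_range = c(40L, 80L),
                             module_trait_coupling = data.frame(
                               module = c(1L, 2L, 3L),
                               trait = c("auc_glucose15", "auc_fat", "hba1c"),
                               strength = c(0.6, 0.6, 0.5)),
                             n_de_protein_up = 100L, n_de_protein_down = 100L,
                             n_de_rna_up = 150L, n_de_rna_down = 150L,
                             de_log2fc = 0.5,
                             t2d_composition_shift = TRUE,
                             rna_protein_r = 0.5,
                             n_batches = 7L,
                             missing_frac = 0.05, high_missing_frac = 0.02,
                             seed = 1L) {
  n_nd <- assert_count(n_nd, "n_nd", 0L)
  n_t2d <- assert_count(n_t2d, "n_t2d", 0L)
  if (n_nd + n_t2d < 1L) stop_config("n_nd", "cohort must have >= 1 donor")
  assert_prob(pi_fat, "pi_fat"); assert_prob(pi_leu, "pi_leu")
  if (pi_fat + pi_leu > 1) stop_config("pi_fat", "pi_fat + pi_leu must be <= 1")
  stim <- c("glucose15", "glucose6", "fat", "kcl", "leucine", "leu_plus_g6")
  if (!all(stim %in% names(t2d_effect)))
    stop_config("t2d_effect", "must name all stimuli")
  assert_pos(t2d_effect, "t2d_effect")
  assert_pos(t2d_peak_delay_min, "t2d_peak_delay_min", strict = FALSE)
  assert_pos(capacity_cv, "capacity_cv", strict = FALSE)
  assert_pos(assay_cv, "assay_cv", strict = FALSE)
  n_tech_reps <- assert_count(n_tech_reps, "n_tech_reps", 1L)
  assert_pos(baseline_rate, "baseline_rate")
  if (!all(stim %in% names(mean_response)))
    stop_config("mean_response", "must name all stimuli")
  assert_pos(mean_response, "mean_response")
  islet_count <- assert_count(islet_count, "islet_count", 1L)
  assert_pos(flow_rate, "flow_rate")
  n_proteins <- assert_count(n_proteins, "n_proteins", 10L)
  n_genes <- assert_count(n_genes, "n_genes", 10L)
  if (n_genes < n_proteins)
    stop_config("n_genes", "must be >= n_proteins (proteins map into genes)")
  n_modules <- assert_count(n_modules, "n_modules", 1L)
  if (length(module_size_range) != 2L || module_size_range[1] > module_size_range[2])
    stop_config("module_size_range", "must be an increasing length-2 range")
  if (n_modules * module_size_range[2] > n_proteins)
    stop_config("n_modules", "module sizes exceed n_proteins")
  if (!is.data.frame(module_trait_coupling) ||
      !all(c("module", "trait", "strength") %in% names(module_trait_coupling)))
    stop_config("module_trait_coupling", "needs columns module, trait, strength")
  if (missing(module_trait_coupling))  # default couplings shrink with n_modules
    module_trait_coupling <-
      module_trait_coupling[module_trait_coupling$module <= n_modules, ,
                            drop = FALSE]
  if (any(module_trait_coupling$module > n_modules))
    stop_config("module_trait_coupling", "module index exceeds n_modules")
  if (any(abs(module_trait_coupling$strength) > 1))
    stop_config("module_trait_coupling", "strengths must be in [-1, 1]")
  for (f in c("n_de_protein_up", "n_de_protein_down", "n_de_rna_up", "n_de_rna_down"))
    assign(f, assert_count(get(f), f, 0L))
  assert_pos(de_log2fc, "de_log2fc", strict = FALSE)
  if (abs(rna_protein_r) > 1) stop_config("rna_protein_r", "must be in [-1, 1]")
  n_batches <- assert_count(n_batches, "n_batches", 1L)
  assert_prob(missing_frac, "missing_frac")
  assert_prob(high_missing_frac, "high_missing_frac")
  seed <- assert_count(seed, "seed", 0L)

  structure(list(
    n_nd = n_nd, n_t2d = n_t2d, pi_fat = pi_fat, pi_leu = pi_leu,
    t2d_effect = t2d_effect[stim], t2d_peak_delay_min = t2d_peak_delay_min,
    capacity_cv = capacity_cv, assay_cv = assay_cv, n_tech_reps = n_tech_reps,
    baseline_rate = baseline_rate, mean_response = mean_response[stim],
    islet_count = islet_count, flow_rate = flow_rate,
    n_proteins = n_proteins, n_genes = n_genes, n_modules = n_modules,
    module_size_range = as.integer(module_size_range),
    module_trait_coupling = module_trait_coupling,
    n_de_protein_up = n_de_protein_up, n_de_protein_down = n_de_protein_down,
    n_de_rna_up = n_de_rna_up, n_de_rna_down = n_de_rna_down,
    de_log2fc = de_log2fc,
    t2d_composition_shift = isTRUE(t2d_composition_shift),
    rna_protein_r = rna_protein_r,
    n_batches = n_batches, missing_frac = missing_frac,
    high_missing_frac = high_missing_frac, seed = seed
  ), class = "generator_config")
}
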
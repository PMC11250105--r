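#' Run the full analysis pipeline on a synthetic cohort
#'
#' Orchestrates every stage in dependency order — cohort simulation, trace
#' feature extraction, hyper-responder classification and ND-vs-T2D
#' contrasts, proteome/transcriptome preprocessing, differential abundance,
#' RNA-protein concordance, co-expression network with module-trait map, and
#' cell-type composition — writing each stage's table to `out_dir` plus a
#' JSON run manifest with per-stage row/feature counts and output hashes.
#' Re-running with the same configuration reproduces identical hashes.
#'
#' @param config a [generator_config()] (or a YAML file path holding its
#'   fields under a `simulate:` block).
#' @param out_dir output directory.
#' @param stages character vector of stages to run; any of `"features"`,
#'   `"responders"`, `"omics"`, `"network"`, `"composition"` (simulation
#'   always runs). Later stages degrade gracefully when a prerequisite is
#'   toggled off.
#' @return The run manifest (list), invisibly; written as `manifest.json`.
#' @export
run_pipeline <- function(config = generator_config(), out_dir,
                         stages = c("features", "responders", "omics",
                                    "network", "composition")) {
  if (is.character(config)) {
    y <- yaml::read_yaml(config)
    config <- do.call(generator_config, y$simulate %||% y)
  }
  stopifnot(inherits(config, "generator_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) {
    utils::write.table(x, file.path(out_dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    f
  }
  manifest <- list(package_version = as.character(utils::packageVersion("isletpheno")),
                   seed = config$seed, stages = list(), outputs = character())
  need_omics <- any(c("omics", "network", "composition") %in% stages)
  cohort <- simulate_cohort(config, include_omics = need_omics)
  write_cohort(cohort, out_dir)
  manifest$stages$simulate <- list(n_donors = nrow(cohort$donors),
                                   n_traces = length(cohort$traces))

  feats <- NULL
  if ("features" %in% stages) {
    feats <- build_feature_table(cohort$traces, cohort$protocols)
    manifest$outputs <- c(manifest$outputs, wt(feats, "secretion_features.tsv"))
    manifest$stages$features <- list(n_rows = nrow(feats))
  }
  if ("responders" %in% stages && !is.null(feats)) {
    calls <- classify_hyper_responders(feats)
    manifest$outputs <- c(manifest$outputs, wt(calls, "responder_calls.tsv"))
    if (length(unique(cohort$donors$group)) == 2L) {
      contrasts <- suppressWarnings(t2d_effect_summary(feats, cohort$donors))
      manifest$outputs <- c(manifest$outputs, wt(contrasts, "t2d_contrasts.tsv"))
    } else contrasts <- NULL
    manifest$stages$responders <- list(
      n_classifiable = sum(calls$classifiable),
      fat_prevalence = unname(prevalence(calls, "fat_hr")["fraction"]),
      leu_prevalence = unname(prevalence(calls, "leu_hr")["fraction"]),
      n_contrasts = if (is.null(contrasts)) 0L else nrow(contrasts))
  }

  prot <- rna <- NULL
  if (need_omics) {
    prot <- impute(normalize_proteome(filter_missing(cohort$protein)))
    rna <- batch_adjust(normalize_counts(cohort$rna))
  }
  if ("omics" %in% stages) {
    grp <- cohort$donors$group
    if (length(unique(grp)) == 2L) {
      de_p <- differential_abundance(prot, grp, scale = "log10")
      de_r <- differential_abundance(rna, grp, scale = "log2")
      manifest$outputs <- c(manifest$outputs,
                            wt(de_p, "de_protein.tsv"), wt(de_r, "de_rna.tsv"))
      sx <- stats::setNames(sign(de_p$log2fc) * -log10(de_p$p), de_p$feature_id)
      sy <- stats::setNames(sign(de_r$log2fc) * -log10(de_r$p), de_r$feature_id)
      rr <- rrho_map(sx, sy)
      manifest$outputs <- c(manifest$outputs,
                            wt(as.data.frame(rr$logp), "rrho_grid.tsv"))
    }
    ag <- across_gene_correlation(prot, rna)
    wg <- within_gene_correlation(prot, rna)
    manifest$outputs <- c(manifest$outputs,
                          wt(wg$per_gene, "within_gene_correlation.tsv"))
    manifest$stages$omics <- list(
      n_proteins = nrow(prot$values), n_genes = nrow(rna$values),
      across_gene_r = unname(ag["r"]),
      within_gene_fractions = as.list(wg$fractions))
  }
  mods <- NULL
  if ("network" %in% stages) {
    cfg <- network_config(beta = 8)
    cm <- bicor_matrix(prot$values)
    tom <- topological_overlap(signed_adjacency(cm, cfg$beta))
    mods <- detect_modules(tom$dissimilarity, cfg, data = prot$values)
    if (!any(mods$labels > 0)) {
      manifest$stages$network <- list(n_modules = 0L)
      manifest$outputs <- c(manifest$outputs, wt(
        data.frame(feature_id = names(mods$labels), module = mods$labels),
        "modules.tsv"))
      mods <- NULL
    }
  }
  if ("network" %in% stages && !is.null(mods)) {
    eg <- module_eigengenes(prot$values, mods$labels)
    traits <- data.frame(hba1c = cohort$donors$hba1c, bmi = cohort$donors$bmi,
                         t2d = as.numeric(cohort$donors$group == "T2D"))
    covs <- cohort$donors[, c("purity", "culture_time", "digestion_time",
                              "cold_ischemia_time")]
    mt <- module_trait_partial_correlation(eg$eigengenes, traits, covs)
    manifest$outputs <- c(
      manifest$outputs,
      wt(data.frame(feature_id = names(mods$labels), module = mods$labels),
         "modules.tsv"),
      wt(data.frame(donor_id = rownames(eg$eigengenes), eg$eigengenes),
         "eigengenes.tsv"),
      wt(mt, "module_trait.tsv"))
    manifest$stages$network <- list(n_modules = length(unique(
      mods$labels[mods$labels > 0])))
  }
  if ("composition" %in% stages) {
    markers <- cohort$omics_truth$markers
    est <- estimate_composition(prot, markers, mode = "proportions")
    out <- data.frame(donor_id = rownames(est), unclass(est))
    manifest$outputs <- c(manifest$outputs, wt(out, "composition.tsv"))
    if (length(unique(cohort$donors$group)) == 2L) {
      cc <- compare_composition(est, cohort$donors$group)
      manifest$outputs <- c(manifest$outputs, wt(cc, "composition_contrasts.tsv"))
    }
    manifest$stages$composition <- list(n_cell_types = ncol(est))
  }

  manifest$hashes <- vapply(manifest$outputs, function(f) {
    as.character(sum(utf8ToInt(paste(readLines(file.path(out_dir, f)),
                                     collapse = "\n")) * 1.0) %% 2^31)
  }, character(1))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Summarize a pipeline run as a markdown report
#'
#' Reads the stage outputs present in a run directory and writes a short
#' markdown summary: responder prevalences with Clopper-Pearson intervals,
#' the ND-vs-T2D contrast table, module counts and the module-trait map,
#' concordance and composition summaries. Missing stage outputs yield a
#' notice rather than an error.
#'
#' @param run_dir directory written by [run_pipeline()].
#' @param file output path (default `report.md` inside `run_dir`).
#' @return Path of the written report, invisibly.
#' @export
report <- function(run_dir, file = file.path(run_dir, "report.md")) {
  lines <- c("# Islet phenotyping run summary", "")
  rd <- function(f) {
    p <- file.path(run_dir, f)
    if (file.exists(p)) utils::read.delim(p, stringsAsFactors = FALSE) else NULL
  }
  calls <- rd("responder_calls.tsv")
  if (!is.null(calls)) {
    lines <- c(lines, "## Hyper-responder prevalence", "")
    for (cl in c("fat_hr", "leu_hr")) {
      pr <- prevalence(calls, cl)
      lines <- c(lines, sprintf(
        "- %s: %.1f%% (%d/%d, 95%% CI %.1f-%.1f%%)", cl,
        100 * pr["fraction"], pr["count"], pr["n"],
        100 * pr["lower"], 100 * pr["upper"]))
    }
    lines <- c(lines, "")
  } else lines <- c(lines, "_responder stage output not found_", "")
  ctr <- rd("t2d_contrasts.tsv")
  if (!is.null(ctr)) {
    lines <- c(lines, "## ND vs T2D secretion contrasts", "",
               "| feature | % difference | p | q |",
               "|---|---|---|---|",
               sprintf("| %s | %.1f | %.3g | %.3g |", ctr$feature,
                       ctr$percent_difference, ctr$p, ctr$q), "")
  } else lines <- c(lines, "_contrast output not found (single group?)_", "")
  mods <- rd("modules.tsv")
  if (!is.null(mods)) {
    lines <- c(lines, "## Co-expression modules", "",
               sprintf("- %d modules (%d of %d features assigned)",
                       length(unique(mods$module[mods$module > 0])),
                       sum(mods$module > 0), nrow(mods)), "")
  }
  mt <- rd("module_trait.tsv")
  if (!is.null(mt)) {
    sig <- mt[mt$significant, , drop = FALSE]
    lines <- c(lines, sprintf("- %d significant module-trait pairs at 5%% FDR",
                              nrow(sig)), "")
  }
  comp <- rd("composition.tsv")
  if (!is.null(comp)) {
    ctypes <- setdiff(names(comp), "donor_id")
    lines <- c(lines, "## Cell-type composition", "",
               sprintf("- mean proportions: %s",
                       paste(sprintf("%s %.2f", ctypes,
                                     colMeans(comp[ctypes])), collapse = ", ")),
               "")
  }
  writeLines(lines, file)
  invisible(file)
}
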
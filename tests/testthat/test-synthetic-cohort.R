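test_that("configuration validation names the offending field", {
  expect_error(generator_config(pi_fat = 1.2), "pi_fat")
  expect_error(generator_config(n_t2d = -1), "n_t2d")
  expect_error(generator_config(t2d_effect = c(glucose15 = 0.6)), "t2d_effect")
  expect_error(generator_config(n_modules = 40,
                                module_size_range = c(60L, 80L)), "n_modules")
  expect_error(generator_config(rna_protein_r = 1.5), "rna_protein_r")
})

test_that("cohort has the configured donor counts and arms", {
  co <- simulate_cohort(generator_config(n_nd = 123, n_t2d = 17, seed = 1),
                        include_omics = FALSE)
  expect_equal(nrow(co$donors), 140)
  expect_equal(sum(co$donors$group == "T2D"), 17)
  expect_length(co$traces, 140 * 3)
  arms <- table(vapply(co$traces, function(tr) tr$arm, character(1)))
  expect_equal(unname(arms[c("G", "L", "F")]), rep(140L, 3),
               ignore_attr = TRUE)
})

test_that("zero hyper-responder probabilities give all-typical cohorts", {
  co <- simulate_cohort(generator_config(n_nd = 30, n_t2d = 5,
                                         pi_fat = 0, pi_leu = 0, seed = 2),
                        include_omics = FALSE)
  expect_true(all(co$truth$class == "typical"))
})

test_that("seed fixes the whole bundle bit-for-bit and seeds differ", {
  cfg <- generator_config(n_nd = 6, n_t2d = 2, n_proteins = 80, n_genes = 100,
                          n_modules = 1, module_size_range = c(8L, 10L),
                          n_de_protein_up = 5, n_de_protein_down = 5,
                          n_de_rna_up = 5, n_de_rna_down = 5, seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(a$traces, b$traces)
  expect_identical(a$protein$values, b$protein$values)
  expect_identical(a$rna$values, b$rna$values)
  cfg2 <- generator_config(n_nd = 6, n_t2d = 2, n_proteins = 80,
                           n_genes = 100, n_modules = 1,
                           module_size_range = c(8L, 10L),
                           n_de_protein_up = 5, n_de_protein_down = 5,
                           n_de_rna_up = 5, n_de_rna_down = 5, seed = 43)
  c2 <- simulate_cohort(cfg2, include_omics = FALSE)
  expect_false(identical(a$traces, c2$traces))
})

test_that("noise-free same-group donors have identical traces", {
  co <- noisefree_cohort()
  g_traces <- Filter(function(tr) tr$arm == "G", co$traces)
  nd_ids <- co$donors$donor_id[co$donors$group == "ND"]
  nd <- Filter(function(tr) tr$donor_id %in% nd_ids, g_traces)
  for (tr in nd[-1]) expect_equal(tr$values, nd[[1]]$values)
  t2d_ids <- co$donors$donor_id[co$donors$group == "T2D"]
  t2 <- Filter(function(tr) tr$donor_id %in% t2d_ids, g_traces)
  expect_false(identical(t2[[1]]$values, nd[[1]]$values))
})

test_that("noise-free glucose response is biphasic, fat monophasic", {
  co <- noisefree_cohort()
  trG <- first_trace(co, "G", "ND")
  v <- trG$values[trG$time_min >= 24 & trG$time_min < 64]
  interior_max <- sum(diff(sign(diff(v))) < 0)
  end_max <- v[length(v)] > v[length(v) - 1]
  expect_equal(interior_max + end_max, 2)  # pulse peak + saturating plateau
  expect_gt(phase_decomposition(trG, "glucose15")["first_phase_auc"], 0)
  trF <- first_trace(co, "F", "ND")
  vf <- trF$values[trF$time_min >= 24 & trF$time_min < 64]
  expect_equal(sum(diff(sign(diff(vf))) < 0) + (vf[length(vf)] > vf[length(vf) - 1]), 1)
  expect_true(all(diff(vf) > 0))
})

test_that("noise-free T2D/ND AUC ratios equal the configured multipliers", {
  co <- noisefree_cohort()
  cfg <- co$config
  nd <- first_trace(co, "G", "ND"); t2 <- first_trace(co, "G", "T2D")
  # glucose15 agrees to ~1e-9 only: the T2D pulse time-shift moves a sliver
  # of pulse mass past the segment end; unshifted stimuli are exact
  for (seg in c("glucose15", "glucose6", "kcl")) {
    expect_equal(segment_auc(t2, seg) / segment_auc(nd, seg),
                 unname(cfg$t2d_effect[[seg]]), tolerance = 1e-6)
  }
  ndL <- first_trace(co, "L", "ND"); t2L <- first_trace(co, "L", "T2D")
  expect_equal(segment_auc(t2L, "leucine") / segment_auc(ndL, "leucine"), 1)
  # configured first-phase peak delay is recovered exactly
  d <- time_to_peak(t2, "glucose15")["time_to_peak"] -
    time_to_peak(nd, "glucose15")["time_to_peak"]
  expect_equal(unname(d), cfg$t2d_peak_delay_min)
})

test_that("ground truth records every latent draw", {
  co <- small_cohort()
  expect_setequal(co$truth$donor_id, co$donors$donor_id)
  expect_true(all(c("class", "capacity", "hr_excess",
                    names(co$config$mean_response),
                    paste0("auc_", names(co$config$mean_response))) %in%
                    names(co$truth)))
  expect_true(all(!is.na(co$truth$hr_excess[co$truth$class != "typical"])))
  ot <- co$omics_truth
  expect_true(all(c("protein_meta", "rna_meta", "factors", "composition",
                    "batch", "markers") %in% names(ot)))
  expect_equal(nrow(ot$protein_meta), nrow(co$protein$values))
})

test_that("hyper-responder prevalence is recovered across seeds", {
  counts <- vapply(1:20, function(s) {
    co <- simulate_cohort(generator_config(n_nd = 50, n_t2d = 8, seed = 100 + s),
                          include_omics = FALSE)
    sum(co$truth$class == "fat_hr")
  }, numeric(1))
  bt <- binom.test(sum(counts), 20 * 58, p = 0.08)
  expect_gt(bt$p.value, 0.01)
})

test_that("perfect RNA-protein coupling yields across-gene r near 1", {
  cfg <- generator_config(n_nd = 40, n_t2d = 0, rna_protein_r = 1,
                          n_proteins = 300, n_genes = 400, n_modules = 1,
                          module_size_range = c(10L, 12L),
                          n_de_protein_up = 0, n_de_protein_down = 0,
                          n_de_rna_up = 0, n_de_rna_down = 0,
                          missing_frac = 0, high_missing_frac = 0, seed = 9)
  co <- simulate_cohort(cfg)
  r <- across_gene_correlation(log10(co$protein$values),
                               log2(co$rna$values + 0.5))["r"]
  expect_gt(r, 0.97)
})

test_that("planted module features are tightly correlated within modules", {
  co <- small_cohort()
  pm <- co$omics_truth$protein_meta
  lp <- log10(co$protein$values)
  lp[co$protein$mask] <- NA
  m1 <- lp[pm$module == 1, , drop = FALSE]
  cc <- cor(t(m1), use = "pairwise.complete.obs")
  expect_gt(median(cc[upper.tri(cc)]), 0.5)
  m12 <- cor(t(lp[pm$module == 1, ]), t(lp[pm$module == 2, ]),
             use = "pairwise.complete.obs")
  expect_lt(median(abs(m12), na.rm = TRUE), 0.25)
})

test_that("cohort files round-trip through the plain-text writers", {
  co <- small_cohort()
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "donors.tsv", "ground_truth.tsv", "protocol.yaml", "traces_G.tsv",
    "traces_L.tsv", "traces_F.tsv", "protein_matrix.tsv", "rna_counts.tsv")))))
  tg <- utils::read.delim(file.path(dir, "traces_G.tsv"))
  expect_setequal(unique(tg$segment),
                  c("basal", "glucose15", "washout", "glucose6", "kcl"))
  pr <- read_protocols(file.path(dir, "protocol.yaml"))
  expect_equal(pr$G$start_min, co$protocols$G$start_min)
})
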
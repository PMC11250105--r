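test_that("BH adjustment equals the step-up definition oracle", {
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- numeric(m)
    ps <- p[o]
    qs <- vapply(seq_len(m), function(i)
      min(1, min(ps[i:m] * m / (i:m))), numeric(1))
    q[o] <- qs
    q
  }
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(bh_adjust(0.3), 0.3)
  set.seed(17)
  for (m in c(2, 3, 5, 7, 10)) {
    p <- runif(m)
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
    expect_true(all(bh_adjust(p) >= p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("differential abundance matches t.test and handles degeneracy", {
  set.seed(3)
  v <- matrix(rnorm(8 * 12), 8, 12,
              dimnames = list(sprintf("f%d", 1:8), sprintf("d%d", 1:12)))
  v[3, ] <- 5  # constant feature
  grp <- rep(c("ND", "T2D"), each = 6)
  res <- differential_abundance(v, grp, scale = "log10")
  for (i in c(1, 2, 4, 8)) {
    ht <- t.test(v[i, grp == "T2D"], v[i, grp == "ND"])
    expect_equal(res$p[i], ht$p.value, tolerance = 1e-10)
    expect_equal(res$statistic[i], unname(ht$statistic), tolerance = 1e-10)
  }
  expect_true(res$flagged[3])
  expect_equal(res$p[3], 1)
  expect_equal(res$log2fc[3], 0)
  # identical groups -> fc 0, p 1
  v2 <- cbind(v[, 1:6], v[, 1:6])
  res2 <- differential_abundance(v2, grp)
  expect_equal(res2$log2fc, rep(0, 8))
  expect_true(all(res2$flagged | res2$p == 1))
  # log2fc scale conversion: mean log10 difference / log10(2)
  expect_equal(res$log2fc[1],
               (mean(v[1, 7:12]) - mean(v[1, 1:6])) / log10(2))
})

test_that("planted differential features are recovered at the oracle power", {
  proc <- default_processed()
  co <- proc$cohort
  res <- differential_abundance(proc$protein, co$donors$group)
  pm <- co$omics_truth$protein_meta
  meta <- pm[match(res$feature_id, pm$feature_id), ]
  de <- meta$de
  hit <- res$q < 0.05
  sens <- mean(hit[de != 0])
  expect_gt(sens, 0.55)   # Monte-Carlo oracle power at these settings: ~0.65
  # truly null features: background that is neither planted-DE, in a module
  # coupled (directly or via trait correlations with T2D) to donor traits,
  # nor a composition-shifted cell-type marker
  null_bg <- de == 0 & meta$module == 0 & is.na(meta$marker_type)
  expect_lt(mean(hit[null_bg]), 0.02)
  # signs recovered
  expect_true(all(sign(res$log2fc[de != 0 & hit]) == de[de != 0 & hit]))
})

test_that("covariate-adjusted regression matches closed forms and lm", {
  # 4-point toy: slope exactly 1, constant covariate dropped by design
  v <- matrix(c(1, 2, 3, 4), 1, 4,
              dimnames = list("f1", sprintf("d%d", 1:4)))
  res <- covariate_adjusted_regression(v, trait = c(1, 2, 3, 4))
  expect_equal(res$coefficient, 1, tolerance = 1e-12)
  expect_lt(res$p, 0.05)
  # against lm with a T2D covariate
  set.seed(6)
  n <- 30
  v <- matrix(rnorm(5 * n), 5, n,
              dimnames = list(sprintf("f%d", 1:5), sprintf("d%d", 1:n)))
  trait <- rnorm(n); t2d <- rep(0:1, c(22, 8))
  res <- covariate_adjusted_regression(v, trait,
                                       covariates = data.frame(t2d = t2d))
  for (i in 1:5) {
    fit <- summary(lm(v[i, ] ~ trait + t2d))
    expect_equal(res$coefficient[i], fit$coefficients["trait", 1],
                 tolerance = 1e-10)
    expect_equal(res$p[i], fit$coefficients["trait", 4], tolerance = 1e-10)
  }
  # orthogonal trait in a balanced design equals the simple slope
  v32 <- matrix(rnorm(5 * 32), 5, 32,
                dimnames = list(sprintf("f%d", 1:5), sprintf("d%d", 1:32)))
  t2d_bal <- rep(0:1, each = 16)
  trait_orth <- rep(c(-1, 1), 16)  # orthogonal to intercept and t2d_bal
  r1 <- covariate_adjusted_regression(v32, trait_orth,
                                      covariates = data.frame(t2d = t2d_bal))
  r0 <- covariate_adjusted_regression(v32, trait_orth)
  expect_equal(r1$coefficient, r0$coefficient, tolerance = 1e-10)
  # collinear design flagged and excluded from the BH family
  rc <- covariate_adjusted_regression(v, trait,
                                      covariates = data.frame(x = 2 * trait))
  expect_true(all(rc$flagged))
  expect_true(all(is.na(rc$q)))
})

test_that("module-coupled features lead the trait association ranking", {
  proc <- default_processed()
  co <- proc$cohort
  fat_auc <- co$truth$auc_fat[match(colnames(proc$protein$values),
                                    co$truth$donor_id)]
  t2d <- as.numeric(co$donors$group == "T2D")
  res <- covariate_adjusted_regression(proc$protein, fat_auc,
                                       covariates = data.frame(t2d = t2d))
  pm <- co$omics_truth$protein_meta
  coupled <- pm$module[match(res$feature_id, pm$feature_id)] == 2
  ranks <- rank(res$p)
  expect_lt(median(ranks[coupled]), 0.25 * nrow(res))
  expect_lt(suppressWarnings(
    wilcox.test(ranks[coupled], ranks[!coupled],
                alternative = "less")$p.value), 1e-10)
})

test_that("partial correlation equals the closed-form recursion", {
  # r_xy = 0.8, r_xz = r_yz = 0.5 -> r_xy.z = 0.55/0.75
  S <- matrix(c(1, .8, .5, .8, 1, .5, .5, .5, 1), 3)
  L <- chol(S)
  set.seed(12)
  for (rep in 1:6) {
    n <- 60
    d <- matrix(rnorm(n * 3), n) %*% L
    x <- d[, 1]; y <- d[, 2]; z <- d[, 3]
    r_xy <- cor(x, y); r_xz <- cor(x, z); r_yz <- cor(y, z)
    rec <- (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
    got <- pairwise_correlation(x, y, z = data.frame(z = z))
    expect_equal(unname(got["r"]), rec, tolerance = 1e-10)
  }
  # empty covariate set reduces to plain Pearson (cor.test oracle)
  x <- rnorm(20); y <- rnorm(20)
  got <- pairwise_correlation(x, y)
  ct <- cor.test(x, y)
  expect_equal(unname(got["r"]), unname(ct$estimate), tolerance = 1e-12)
  expect_equal(unname(got["p"]), ct$p.value, tolerance = 1e-12)
  expect_equal(unname(pairwise_correlation(x, x)["r"]), 1)
})

test_that("type-I error is controlled on null synthetic data", {
  hits <- 0; total <- 0
  for (s in 1:5) {
    cfg <- generator_config(n_nd = 25, n_t2d = 25,
                            t2d_effect = c(glucose15 = 1, glucose6 = 1,
                                           fat = 1, kcl = 1, leucine = 1,
                                           leu_plus_g6 = 1),
                            n_proteins = 400, n_genes = 500,
                            n_de_protein_up = 0, n_de_protein_down = 0,
                            n_de_rna_up = 0, n_de_rna_down = 0,
                            n_modules = 2, module_size_range = c(10L, 15L),
                            module_trait_coupling = data.frame(
                              module = integer(), trait = character(),
                              strength = numeric()),
                            t2d_composition_shift = FALSE,
                            missing_frac = 0, high_missing_frac = 0,
                            seed = 400 + s)
    co <- simulate_cohort(cfg)
    prot <- normalize_proteome(co$protein)
    res <- differential_abundance(prot, co$donors$group)
    hits <- hits + sum(res$q < 0.05, na.rm = TRUE)
    total <- total + nrow(res)
  }
  expect_lte(hits / total, 0.05)
})
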
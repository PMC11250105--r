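test_that("bicor behaves like a correlation and resists outliers", {
  set.seed(41)
  x <- rnorm(50)
  m <- rbind(a = x, b = -x, c = rnorm(50))
  bc <- bicor_matrix(m)
  expect_equal(bc["a", "a"], 1)
  expect_equal(bc["a", "b"], -1, tolerance = 1e-12)
  expect_true(all(abs(bc) <= 1))
  expect_true(isSymmetric(unname(bc)))
  # one gross outlier: bicor stays near the clean Pearson value
  y <- x + rnorm(50, sd = 0.4)
  r_clean <- cor(x, y)
  xc <- x; yc <- y
  xc[1] <- 15; yc[1] <- -15
  r_cont <- cor(xc, yc)
  b_cont <- bicor_matrix(rbind(x = xc, y = yc))["x", "y"]
  expect_lt(abs(b_cont - r_clean), abs(r_cont - r_clean))
  # zero-MAD feature falls back to Pearson and is reported
  m2 <- rbind(const_ish = c(rep(1, 48), 2, 0.5), z = rnorm(50))
  bc2 <- bicor_matrix(m2)
  expect_equal(attr(bc2, "pearson_fallback"), "const_ish")
})

test_that("signed adjacency follows the soft-threshold closed form", {
  cm <- matrix(c(1, 0, -1, 0, 1, 0.5, -1, 0.5, 1), 3)
  a <- signed_adjacency(cm, beta = 8)
  expect_equal(a[1, 2], 0.5^8)   # cor 0 -> 0.00390625
  expect_equal(a[1, 3], 0)       # cor -1 -> 0
  expect_equal(a[2, 3], 0.75^8)
  expect_equal(diag(a), rep(1, 3))
  expect_error(signed_adjacency(matrix(2, 2, 2), 8), "\\[-1, 1\\]")
  # monotone in correlation for fixed beta
  cors <- seq(-1, 1, by = 0.05)
  av <- ((1 + cors) / 2)^8
  expect_true(all(diff(av) > 0))
})

test_that("TOM matches closed forms and a triple-loop oracle", {
  # two-node graph with one edge a: TOM12 = a / (a + 1 - a) = a
  for (a in c(0.2, 0.7)) {
    adj <- matrix(c(1, a, a, 1), 2)
    expect_equal(topological_overlap(adj)$tom[1, 2], a, tolerance = 1e-12)
  }
  # identical binary rows with a_ij = 1 -> TOM 1 (full overlap)
  adj <- matrix(1, 3, 3)
  expect_equal(topological_overlap(adj)$tom[1, 2], 1, tolerance = 1e-12)
  adj2 <- diag(3); adj2[1, 2] <- adj2[2, 1] <- 1
  expect_equal(topological_overlap(adj2)$tom[1, 2], 1, tolerance = 1e-12)
  # random 6-node adjacency vs brute-force triple loop
  set.seed(52)
  r <- matrix(runif(36, 0, 0.9), 6); r <- (r + t(r)) / 2; diag(r) <- 1
  tom <- topological_overlap(r)$tom
  oracle <- matrix(0, 6, 6)
  for (i in 1:6) for (j in 1:6) {
    if (i == j) { oracle[i, j] <- 1; next }
    l <- 0
    for (u in 1:6) if (u != i && u != j) l <- l + r[i, u] * r[u, j]
    ki <- sum(r[i, -i]); kj <- sum(r[j, -j])
    oracle[i, j] <- (l + r[i, j]) / (min(ki, kj) + 1 - r[i, j])
  }
  expect_equal(unname(tom), oracle, tolerance = 1e-12)
  expect_true(all(tom >= 0 & tom <= 1))
  expect_error(topological_overlap(matrix(c(1, 0.2, 0.5, 1), 2)), "symmetric")
})

test_that("module detection recovers planted structure and merges twins", {
  # two disjoint noise-free modules -> perfect recovery
  set.seed(61)
  f1 <- rnorm(40); f2 <- rnorm(40)
  dat <- rbind(t(sapply(1:8, function(i) i * f1)),
               t(sapply(1:8, function(i) i * f2 + i)))
  rownames(dat) <- sprintf("p%02d", 1:16)
  colnames(dat) <- sprintf("d%02d", 1:40)
  cc <- cor(t(dat))
  within <- cc[1:8, 1:8]
  expect_equal(unname(within[upper.tri(within)]), rep(1, 28), tolerance = 1e-12)
  expect_lt(max(abs(cc[1:8, 9:16])), 0.5)
  tom <- topological_overlap(signed_adjacency(cc, 8))
  mods <- detect_modules(tom$dissimilarity,
                         network_config(min_module_size = 5), data = dat)
  expect_equal(length(unique(mods$labels[mods$labels > 0])), 2)
  expect_equal(length(unique(mods$labels[1:8])), 1)
  # two modules with eigengene correlation ~0.95 merge at threshold 0.75
  f2b <- 0.97 * f1 + sqrt(1 - 0.97^2) * rnorm(40)
  dat2 <- rbind(t(sapply(1:8, function(i) i * f1 + 0.05 * rnorm(40))),
                t(sapply(1:8, function(i) i * f2b + 0.05 * rnorm(40))))
  dimnames(dat2) <- dimnames(dat)
  tom2 <- topological_overlap(signed_adjacency(cor(t(dat2)), 8))
  mods2 <- detect_modules(tom2$dissimilarity,
                          network_config(min_module_size = 5,
                                         merge_threshold = 0.75),
                          data = dat2)
  expect_equal(length(unique(mods2$labels[mods2$labels > 0])), 1)
  # pure noise: at least half the features stay unassigned
  noise <- matrix(rnorm(60 * 30), 60, 30,
                  dimnames = list(sprintf("n%02d", 1:60), NULL))
  tn <- topological_overlap(signed_adjacency(cor(t(noise)), 8))
  mn <- detect_modules(tn$dissimilarity, network_config(min_module_size = 10))
  expect_gte(mean(mn$labels == 0), 0.5)
})

test_that("eigengenes are unit-norm, oriented, and recover latent factors", {
  set.seed(71)
  n <- 60
  prof <- rnorm(n)
  dat <- t(sapply(1:6, function(i) 2 * prof + 5))
  rownames(dat) <- sprintf("p%d", 1:6); colnames(dat) <- sprintf("d%02d", 1:n)
  labels <- setNames(rep(1L, 6), rownames(dat))
  eg <- module_eigengenes(dat, labels)
  expect_equal(sum(eg$eigengenes[, 1]^2), 1, tolerance = 1e-12)
  expect_equal(eg$var_explained[["M1"]], 1, tolerance = 1e-12)
  expect_equal(abs(cor(eg$eigengenes[, 1], prof)), 1, tolerance = 1e-10)
  expect_gt(cor(eg$eigengenes[, 1], prof), 0)  # orientation follows profile
  # flipping the sign of every feature leaves the oriented eigengene of the
  # flipped module pointing along its own mean profile
  eg2 <- module_eigengenes(-dat, labels)
  expect_equal(abs(cor(eg2$eigengenes[, 1], eg$eigengenes[, 1])), 1,
               tolerance = 1e-10)
  # planted one-factor module, loading 0.9
  f <- rnorm(n)
  dat3 <- t(sapply(1:30, function(i) 0.9 * f + sqrt(1 - 0.81) * rnorm(n)))
  rownames(dat3) <- sprintf("p%d", 1:30); colnames(dat3) <- colnames(dat)
  eg3 <- module_eigengenes(dat3, setNames(rep(1L, 30), rownames(dat3)))
  expect_gt(abs(cor(eg3$eigengenes[, 1], f)), 0.95)
})

test_that("module-trait partial correlation residualizes covariates", {
  set.seed(81)
  n <- 80
  z <- rnorm(n)
  eg <- cbind(M1 = scale(0.7 * z + rnorm(n, sd = 0.5))[, 1] / sqrt(n - 1),
              M2 = rnorm(n))
  traits <- data.frame(t1 = z, t2 = rnorm(n))
  # empty covariates equals plain Pearson
  res <- module_trait_partial_correlation(eg, traits)
  expect_equal(res$r[res$module == "M1" & res$trait == "t1"],
               cor(eg[, "M1"], z), tolerance = 1e-12)
  # trait (near-)equal to a covariate -> residualized away, partial r ~ 0
  res_exact <- module_trait_partial_correlation(eg, traits,
                                                covariates = data.frame(z = z))
  expect_true(is.na(res_exact$r[res_exact$module == "M1" &
                                  res_exact$trait == "t1"]))
  traits2 <- traits; traits2$t1 <- z + rnorm(n, sd = 1e-3)
  res2 <- module_trait_partial_correlation(eg, traits2,
                                           covariates = data.frame(z = z))
  expect_lt(abs(res2$r[res2$module == "M1" & res2$trait == "t1"]), 0.3)
  # collinear covariates dropped with warning
  expect_warning(
    module_trait_partial_correlation(eg, traits,
                                     covariates = data.frame(a = z, b = 2 * z)),
    "collinear")
})

test_that("planted module-trait couplings are recovered with correct sign", {
  hits <- 0
  for (s in 1:10) {
    cfg <- generator_config(n_nd = 100, n_t2d = 20, n_proteins = 600,
                            n_genes = 700, n_modules = 6,
                            module_size_range = c(30L, 40L),
                            missing_frac = 0, high_missing_frac = 0,
                            seed = 500 + s)
    co <- simulate_cohort(cfg)
    prot <- normalize_proteome(co$protein)
    pm <- co$omics_truth$protein_meta
    labels <- setNames(pm$module, pm$feature_id)
    eg <- module_eigengenes(prot$values, labels)
    traits <- data.frame(
      auc_fat = co$truth$auc_fat,
      hba1c = co$donors$hba1c, bmi = co$donors$bmi)
    covs <- co$donors[, c("purity", "culture_time", "digestion_time",
                          "cold_ischemia_time")]
    res <- module_trait_partial_correlation(eg$eigengenes, traits, covs)
    cell <- res[res$module == "M2" & res$trait == "auc_fat", ]
    # eigengene orientation is arbitrary wrt the latent factor; check the
    # association strength and that the sign matches the factor coupling
    f2 <- co$omics_truth$factors[2, ]
    expected_sign <- sign(cor(eg$eigengenes[, "M2"], f2)) *
      sign(cor(f2, scale(traits$auc_fat)[, 1]))
    if (cell$significant && sign(cell$r) == expected_sign) hits <- hits + 1
  }
  expect_gte(hits, 9)
})
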
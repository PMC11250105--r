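#' Simulate paired proteome and transcriptome matrices for a donor cohort
#'
#' Generates a proteome (raw positive abundances, features x donors, with an
#' abundance-dependent missingness pattern) and a transcriptome (negative
#' binomial counts with batch location/scale shifts) whose structure mirrors
#' what the downstream stages assume:
#'
#' * a shared gene-level component scaled so the across-gene correlation of
#'   per-gene mean protein and mean RNA levels targets `rna_protein_r`;
#' * `n_modules` planted proteome co-expression modules whose latent factors
#'   are linearly coupled to donor traits per `module_trait_coupling`;
#' * planted T2D-differential features at `|log2FC| = de_log2fc` in both
#'   matrices;
#' * cell-type marker panels (alpha, beta, gamma, delta, acinar) driven by a
#'   latent donor composition with a T2D beta-to-alpha shift;
#' * a small set of proteins planted at >50% missingness to exercise the
#'   missingness filter.
#'
#' @param donors donor metadata table from [simulate_cohort()].
#' @param config a [generator_config()].
#' @param truth donor-level ground-truth table (used for the functional
#'   trait values that module factors couple to); optional — uncoupled
#'   modules only if absent.
#' @return List with `protein` and `rna` [omics_matrix] objects and `truth`
#'   (feature metadata, module factors, donor composition, batch labels,
#'   marker sets).
#' @export
simulate_omics <- function(donors, config, truth = NULL) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(child_seed(config$seed, "omics"))
  n <- nrow(donors)
  t2d <- as.numeric(donors$group == "T2D")
  np <- config$n_proteins; ng <- config$n_genes
  gene_id <- sprintf("G%04d", seq_len(ng))
  prot_gene <- gene_id[seq_len(np)]

  # Shared gene-level component -> across-gene protein/RNA mean coupling.
  z <- stats::rnorm(ng)
  rho <- config$rna_protein_r
  mu_p <- 6 + 0.5 * z[seq_len(np)]                       # log10 abundance
  lam_r <- 6.5 + 1.5 * (rho * z + sqrt(1 - rho^2) * stats::rnorm(ng))  # log2 counts

  # Partition protein features: modules, then markers, DE, high-missing from
  # the leftover background.
  sizes <- sample(seq(config$module_size_range[1], config$module_size_range[2]),
                  config$n_modules, replace = TRUE)
  perm <- sample.int(np)
  module <- integer(np)
  pos <- 1L
  for (m in seq_len(config$n_modules)) {
    module[perm[pos:(pos + sizes[m] - 1L)]] <- m
    pos <- pos + sizes[m]
  }
  background <- perm[pos:np]
  cell_types <- c("alpha", "beta", "gamma", "delta", "acinar")
  n_marker <- 8L
  need <- length(cell_types) * n_marker +
    config$n_de_protein_up + config$n_de_protein_down
  if (length(background) < need)
    stop_config("n_modules", "module sizes leave too few background features")
  marker_idx <- background[seq_len(length(cell_types) * n_marker)]
  marker_type <- rep(cell_types, each = n_marker)
  rest <- background[-seq_len(length(cell_types) * n_marker)]
  de_up <- rest[seq_len(config$n_de_protein_up)]
  de_dn <- rest[config$n_de_protein_up + seq_len(config$n_de_protein_down)]
  de_dir <- integer(np); de_dir[de_up] <- 1L; de_dir[de_dn] <- -1L
  rest2 <- rest[-seq_len(config$n_de_protein_up + config$n_de_protein_down)]
  n_hm <- min(length(rest2), round(config$high_missing_frac * np))
  hm_idx <- if (n_hm > 0) rest2[seq_len(n_hm)] else integer(0)

  # Module latent factors, coupled to standardized donor traits.
  traits <- data.frame(hba1c = donors$hba1c, bmi = donors$bmi)
  if (!is.null(truth)) {
    traits$auc_glucose15 <- truth$auc_glucose15
    traits$auc_fat <- truth$auc_fat
  }
  factors <- matrix(stats::rnorm(config$n_modules * n), ncol = n)
  mtc <- config$module_trait_coupling
  for (i in seq_len(nrow(mtc))) {
    tr_name <- mtc$trait[i]
    if (!tr_name %in% names(traits)) next
    s <- mtc$strength[i]
    tv <- as.numeric(scale(traits[[tr_name]]))
    factors[mtc$module[i], ] <- s * tv + sqrt(1 - s^2) * stats::rnorm(n)
  }

  loading <- numeric(np)
  loading[module > 0] <- stats::runif(sum(module > 0), 0.25, 0.45)

  # Latent donor cell-type composition (beta down / alpha up in T2D).
  alpha_nd <- c(alpha = 30, beta = 55, gamma = 4, delta = 8, acinar = 3)
  alpha_t2d <- if (config$t2d_composition_shift)
    c(alpha = 40, beta = 45, gamma = 4, delta = 8, acinar = 3) else alpha_nd
  comp <- t(vapply(seq_len(n), function(j) {
    a <- if (t2d[j] == 1) alpha_t2d else alpha_nd
    g <- stats::rgamma(length(a), shape = a, rate = 1)
    g / sum(g)
  }, numeric(length(cell_types))))
  colnames(comp) <- cell_types

  # Protein log10 abundances.
  X <- matrix(stats::rnorm(np * n, sd = 0.15), nrow = np) + mu_p
  X <- X + outer(de_dir * config$de_log2fc * log10(2), t2d)
  idx_mod <- which(module > 0)
  X[idx_mod, ] <- X[idx_mod, ] + loading[idx_mod] * factors[module[idx_mod], ]
  comp_comp <- t(log10(comp[, marker_type, drop = FALSE] / 0.2))
  X[marker_idx, ] <- X[marker_idx, ] + 0.8 * comp_comp
  P <- 10^X
  rownames(P) <- prot_gene; colnames(P) <- donors$donor_id

  # Abundance-dependent missingness + planted high-missing features.
  mask <- matrix(FALSE, np, n)
  if (config$missing_frac > 0) {
    zx <- (X - mean(X)) / stats::sd(X)
    pmiss <- pmin(1, 2 * config$missing_frac * (1 - stats::plogis(zx)))
    mask <- matrix(stats::runif(np * n) < pmiss, np, n)
  }
  if (length(hm_idx)) {
    k_hm <- round(0.6 * n)
    for (i in hm_idx) mask[i, ] <- FALSE
    for (i in hm_idx) mask[i, sample.int(n, k_hm)] <- TRUE
  }
  P[mask] <- NA_real_
  dimnames(mask) <- dimnames(P)

  # RNA: planted DE among genes without a protein DE partner conflict is not
  # required; reuse gene order but draw DE genes anywhere.
  rna_de <- integer(ng)
  de_pool <- sample.int(ng)
  rna_de[de_pool[seq_len(config$n_de_rna_up)]] <- 1L
  rna_de[de_pool[config$n_de_rna_up + seq_len(config$n_de_rna_down)]] <- -1L
  batch <- sample(rep_len(paste0("B", seq_len(config$n_batches)), n))
  gamma_b <- matrix(stats::rnorm(ng * config$n_batches, sd = 0.5),
                    nrow = ng,
                    dimnames = list(NULL, paste0("B", seq_len(config$n_batches))))
  scale_b <- stats::runif(config$n_batches, 0.8, 1.25)
  names(scale_b) <- paste0("B", seq_len(config$n_batches))

  # donor-level RNA noise well above the proteome's 0.15 log10 (~0.5 log2):
  # transcripts are the noisier measurement, as the CV comparison assumes
  eps <- matrix(stats::rnorm(ng * n, sd = 0.85), nrow = ng)
  eps <- sweep(eps, 2, scale_b[batch], `*`)
  Xr <- lam_r + eps + outer(rna_de * config$de_log2fc, t2d) + gamma_b[, batch]
  # Marker genes share the protein markers' genes and composition signal.
  Xr[match(prot_gene[marker_idx], gene_id), ] <-
    Xr[match(prot_gene[marker_idx], gene_id), ] +
    0.8 * log2(10) * comp_comp  # same composition component, on log2 scale
  disp <- stats::runif(ng, 0.1, 0.5)
  libfac <- stats::rlnorm(n, 0, 0.2)
  mu_counts <- sweep(2^Xr, 2, libfac, `*`)
  counts <- matrix(stats::rnbinom(ng * n, mu = mu_counts, size = 1 / disp),
                   nrow = ng)
  rownames(counts) <- gene_id; colnames(counts) <- donors$donor_id

  prot_meta <- data.frame(
    feature_id = prot_gene, gene_id = prot_gene, module = module,
    loading = loading, de = de_dir,
    marker_type = {
      mt <- rep(NA_character_, np); mt[marker_idx] <- marker_type; mt
    },
    high_missing = seq_len(np) %in% hm_idx, mu = mu_p,
    stringsAsFactors = FALSE)
  rna_meta <- data.frame(gene_id = gene_id, de = rna_de, dispersion = disp,
                         lambda = lam_r, stringsAsFactors = FALSE)
  markers <- split(prot_gene[marker_idx], marker_type)

  list(
    protein = omics_matrix(P, "protein", features = prot_meta, mask = mask),
    rna = omics_matrix(counts, "rna", features = rna_meta, batch = batch),
    truth = list(protein_meta = prot_meta, rna_meta = rna_meta,
                 factors = factors, composition = comp, batch = batch,
                 markers = markers, traits = traits)
  )
}
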
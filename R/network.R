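#' Configuration of the signed weighted co-expression network
#'
#' @param beta soft-threshold exponent (>= 1). The package's reference
#'   values are 8 for the proteome and 20 for the transcriptome.
#' @param cor_method `"bicor"` (robust biweight midcorrelation, default) or
#'   `"pearson"`.
#' @param min_module_size smallest feature count kept as a module.
#' @param merge_threshold modules whose eigengenes correlate above this are
#'   merged (in (0, 1)).
#' @param cut_height static tree-cut height as a fraction of the maximum
#'   merge height of the dendrogram (default 0.9, below the band where
#'   unrelated features begin to agglomerate).
#' @return `network_config` list.
#' @export
network_config <- function(beta = 8, cor_method = c("bicor", "pearson"),
                           min_module_size = 30, merge_threshold = 0.75,
                           cut_height = 0.9) {
  cor_method <- match.arg(cor_method)
  if (beta < 1) stop("beta must be >= 1", call. = FALSE)
  if (merge_threshold <= 0 || merge_threshold >= 1)
    stop("merge_threshold must be in (0, 1)", call. = FALSE)
  list(beta = beta, cor_method = cor_method,
       min_module_size = min_module_size,
       merge_threshold = merge_threshold, cut_height = cut_height)
}

#' Biweight midcorrelation matrix
#'
#' Robust correlation per feature pair: observations are weighted by
#' `w = (1 - u^2)^2` for `|u| < 1` (0 otherwise) with
#' `u = (x - median) / (9 * MAD)` (unscaled MAD), down-weighting outliers.
#' Features with zero MAD fall back to the Pearson standardization (noted in
#' the returned attribute).
#'
#' @param x numeric matrix, features in rows, >= 4 donors in columns.
#' @return Features-by-features correlation matrix; attribute
#'   `pearson_fallback` lists features with MAD = 0.
#' @export
bicor_matrix <- function(x) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (ncol(x) < 4L) stop("need >= 4 donors", call. = FALSE)
  med <- apply(x, 1, stats::median)
  madv <- apply(x, 1, function(r) stats::mad(r, constant = 1))
  fallback <- madv == 0
  g <- matrix(0, nrow(x), ncol(x))
  for (i in seq_len(nrow(x))) {
    xi <- x[i, ] - med[i]
    if (fallback[i]) {
      xi <- x[i, ] - mean(x[i, ])
      g[i, ] <- xi
    } else {
      u <- xi / (9 * madv[i])
      w <- (1 - u^2)^2 * (abs(u) < 1)
      g[i, ] <- xi * w
    }
    nrm <- sqrt(sum(g[i, ]^2))
    if (nrm > 0) g[i, ] <- g[i, ] / nrm
  }
  r <- tcrossprod(g)
  r[r > 1] <- 1; r[r < -1] <- -1
  dimnames(r) <- list(rownames(x), rownames(x))
  attr(r, "pearson_fallback") <- rownames(x)[fallback]
  r
}

#' Signed soft-threshold adjacency
#'
#' `a_ij = ((1 + cor_ij) / 2)^beta` with unit diagonal: anti-correlated
#' features get near-zero adjacency instead of being folded onto positive
#' correlations.
#'
#' @param cor_mat correlation matrix in `[-1, 1]`.
#' @param beta soft-threshold exponent.
#' @return Adjacency matrix in `[0, 1]`.
#' @export
signed_adjacency <- function(cor_mat, beta) {
  if (any(cor_mat < -1 - 1e-12 | cor_mat > 1 + 1e-12))
    stop("correlations must lie in [-1, 1]", call. = FALSE)
  a <- ((1 + cor_mat) / 2)^beta
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `k_i = sum_{u != i} a_iu` and unit diagonal: connectivity credited for
#' shared network neighbors, the standard clustering similarity of weighted
#' co-expression analysis.
#'
#' @param adj symmetric adjacency with unit diagonal, entries in `[0, 1]`.
#' @return List: `tom` (similarity) and `dissimilarity` (`1 - tom`).
#' @export
topological_overlap <- function(adj) {
  if (!isSymmetric(unname(adj), tol = 1e-10))
    stop("adjacency must be symmetric", call. = FALSE)
  a0 <- adj
  diag(a0) <- 0
  k <- rowSums(a0)
  num <- a0 %*% a0 + a0
  kmin <- outer(k, k, pmin)
  tom <- num / (kmin + 1 - a0)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  list(tom = tom, dissimilarity = 1 - tom)
}

#' Detect co-expression modules from a TOM dissimilarity
#'
#' Average-linkage hierarchical clustering of the dissimilarity, cut at a
#' static height (`cut_height` x maximum merge height); clusters smaller
#' than `min_module_size` are left unassigned (label 0). When the data
#' matrix is supplied, modules whose eigengenes correlate above
#' `merge_threshold` are merged iteratively. Labels are ordered by
#' decreasing module size.
#'
#' @param dissimilarity square dissimilarity matrix (e.g.
#'   `topological_overlap()$dissimilarity`).
#' @param config a [network_config()].
#' @param data optional features-by-donors matrix enabling the
#'   eigengene-merge step.
#' @return List: `labels` (named integer vector, 0 = unassigned), `sizes`,
#'   `tree` (the hclust object).
#' @export
detect_modules <- function(dissimilarity, config = network_config(),
                           data = NULL) {
  d <- as.dist(dissimilarity)
  tree <- stats::hclust(d, method = "average")
  hmax <- max(tree$height)
  if (hmax == 0) {
    labels <- stats::setNames(rep(1L, nrow(dissimilarity)),
                              rownames(dissimilarity))
    return(list(labels = labels, sizes = table(labels), tree = tree))
  }
  raw <- stats::cutree(tree, h = config$cut_height * hmax)
  sizes <- table(raw)
  keep <- as.integer(names(sizes)[sizes >= config$min_module_size])
  labels <- integer(length(raw))
  for (i in seq_along(keep)) labels[raw == keep[i]] <- i
  names(labels) <- rownames(dissimilarity)

  if (!is.null(data) && length(unique(labels[labels > 0])) > 1L) {
    repeat {
      eg <- module_eigengenes(data, labels)
      if (ncol(eg$eigengenes) < 2L) break
      ce <- stats::cor(eg$eigengenes)
      diag(ce) <- 0
      if (max(ce) <= config$merge_threshold) break
      ij <- which(ce == max(ce), arr.ind = TRUE)[1, ]
      m1 <- as.integer(sub("^M", "", colnames(ce)[ij[1]]))
      m2 <- as.integer(sub("^M", "", colnames(ce)[ij[2]]))
      labels[labels == max(m1, m2)] <- min(m1, m2)
      old <- sort(unique(labels[labels > 0]))
      labels[labels > 0] <- match(labels[labels > 0], old)
    }
  }
  # order labels by decreasing size
  if (any(labels > 0)) {
    sz <- sort(table(labels[labels > 0]), decreasing = TRUE)
    remap <- stats::setNames(seq_along(sz), names(sz))
    labels[labels > 0] <- remap[as.character(labels[labels > 0])]
  }
  list(labels = labels, sizes = table(labels[labels > 0]), tree = tree)
}

#' Module eigengenes
#'
#' Per module, the first principal component across donors of the
#' standardized feature submatrix, unit-norm over donors and oriented to
#' correlate positively with the module's mean standardized profile, with
#' the fraction of variance explained. Single-feature modules return the
#' standardized feature itself (rescaled to unit norm).
#'
#' @param data features-by-donors matrix.
#' @param labels module labels (0 = unassigned) aligned with rows of
#'   `data` (or named by feature).
#' @return List: `eigengenes` (donors x modules, columns `M1`, `M2`, ...)
#'   and `var_explained`.
#' @export
module_eigengenes <- function(data, labels) {
  if (!is.null(names(labels)) && !is.null(rownames(data)))
    labels <- labels[rownames(data)]
  mods <- sort(unique(labels[labels > 0]))
  if (length(mods) == 0L) stop("no assigned modules", call. = FALSE)
  eg <- matrix(NA_real_, ncol(data), length(mods),
               dimnames = list(colnames(data), paste0("M", mods)))
  ve <- stats::setNames(numeric(length(mods)), paste0("M", mods))
  for (i in seq_along(mods)) {
    sub <- data[labels == mods[i], , drop = FALSE]
    sub <- t(scale(t(sub)))
    sub[!is.finite(sub)] <- 0
    sv <- svd(sub, nu = 0, nv = 1)
    v1 <- sv$v[, 1]
    if (stats::cor(v1, colMeans(sub)) < 0) v1 <- -v1
    eg[, i] <- v1
    ve[i] <- sv$d[1]^2 / sum(sv$d^2)
  }
  list(eigengenes = eg, var_explained = ve)
}

#' Module-trait partial correlation map
#'
#' Partial Pearson correlation (residualizing on the technical covariates)
#' between every module eigengene and every donor trait, with BH adjustment
#' over all module-trait pairs. Collinear covariates are dropped with a
#' warning.
#'
#' @param eigengenes donors x modules matrix (from [module_eigengenes()]).
#' @param traits data.frame of donor traits (numeric or 0/1).
#' @param covariates data.frame of technical covariates (e.g. purity,
#'   culture time, digestion time, cold ischemia time); may be `NULL`.
#' @param fdr FDR threshold used for the `significant` flag.
#' @return data.frame: `module`, `trait`, `r`, `p`, `q`, `significant`.
#' @export
module_trait_partial_correlation <- function(eigengenes, traits,
                                             covariates = NULL, fdr = 0.05) {
  traits <- as.data.frame(traits)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    cm <- as.matrix(covariates)
    qrc <- qr(cbind(1, cm))
    if (qrc$rank < ncol(cm) + 1L) {
      drop_i <- qrc$pivot[-seq_len(qrc$rank)] - 1L
      warning("dropping collinear covariate(s): ",
              paste(colnames(cm)[drop_i], collapse = ", "))
      covariates <- covariates[, -drop_i, drop = FALSE]
    }
  }
  rows <- list()
  for (m in colnames(eigengenes)) {
    for (tr in colnames(traits)) {
      pc <- pairwise_correlation(eigengenes[, m], traits[[tr]], covariates)
      rows[[length(rows) + 1L]] <- data.frame(
        module = m, trait = tr, r = unname(pc["r"]), p = unname(pc["p"]))
    }
  }
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$significant <- !is.na(out$q) & out$q < fdr
  out
}

#' Thresholded network edge list
#'
#' Exports feature pairs whose adjacency exceeds a threshold, for external
#' graph tools.
#'
#' @param adj adjacency matrix.
#' @param threshold minimum adjacency retained.
#' @return data.frame: `from`, `to`, `weight`.
#' @export
adjacency_edges <- function(adj, threshold = 0.2) {
  idx <- which(upper.tri(adj) & adj > threshold, arr.ind = TRUE)
  data.frame(from = rownames(adj)[idx[, 1]], to = colnames(adj)[idx[, 2]],
             weight = adj[idx])
}
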
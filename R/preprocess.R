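#' Remove proteins exceeding the missingness threshold
#'
#' Drops features whose missing fraction is strictly greater than
#' `max_missing` (a feature missing in exactly half the donors is kept).
#'
#' @param om protein [omics_matrix].
#' @param max_missing maximum tolerated missing fraction (default 0.5).
#' @return Filtered [omics_matrix] (removal logged).
#' @export
filter_missing <- function(om, max_missing = 0.5) {
  stopifnot(inherits(om, "omics_matrix"))
  frac <- rowMeans(om$mask)
  keep <- frac <= max_missing
  if (!any(keep)) stop("all features exceed the missingness threshold",
                       call. = FALSE)
  om$values <- om$values[keep, , drop = FALSE]
  om$mask <- om$mask[keep, , drop = FALSE]
  om$features <- om$features[keep, , drop = FALSE]
  log_transform_step(om, "filter_missing", max_missing = max_missing,
                     removed = sum(!keep))
}

#' Median-normalize and log10-transform a proteome matrix
#'
#' Divides each donor column by its median over observed entries, then takes
#' log10; each column's observed values then have unit median before the log
#' (so a 0 post-log median, exactly so for odd observed counts).
#'
#' @param om protein [omics_matrix] with strictly positive observed values.
#' @return Normalized [omics_matrix] (values on log10 scale).
#' @export
normalize_proteome <- function(om) {
  stopifnot(inherits(om, "omics_matrix"))
  v <- om$values
  bad <- which(!om$mask & (is.na(v) | v <= 0), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-positive abundance at feature '%s', donor '%s'",
                 rownames(v)[bad[1, 1]], colnames(v)[bad[1, 2]]), call. = FALSE)
  med <- vapply(seq_len(ncol(v)), function(j)
    stats::median(v[!om$mask[, j], j]), numeric(1))
  om$values <- log10(sweep(v, 2, med, `/`))
  log_transform_step(om, "normalize_proteome", base = 10)
}

#' Impute missing proteome entries by k-nearest-feature regression
#'
#' For each feature with missing entries, the k features most correlated
#' with it (pairwise-complete Pearson, correlation distance `1 - |r|`) each
#' cast a univariate least-squares prediction (slope and intercept fit on
#' the donors where both features are observed); a missing entry is imputed
#' as the mean prediction over the neighbors observed for that donor.
#' Deterministic given the matrix. Observed entries are never touched; the
#' mask keeps marking the imputed cells.
#'
#' @param om normalized protein [omics_matrix] (post [filter_missing()]).
#' @param k number of neighbor features (default 10).
#' @return Complete [omics_matrix]; `$mask` still flags imputed entries.
#' @export
impute <- function(om, k = 10) {
  stopifnot(inherits(om, "omics_matrix"))
  v <- om$values; mask <- om$mask
  if (!any(mask)) return(log_transform_step(om, "impute", k = k, imputed = 0))
  if (any(rowMeans(mask) == 1))
    stop("feature with all entries missing; filter first", call. = FALSE)
  vv <- v; vv[mask] <- NA
  mu <- rowMeans(vv, na.rm = TRUE)
  cm <- suppressWarnings(stats::cor(t(vv), use = "pairwise.complete.obs"))
  cm[!is.finite(cm)] <- 0
  diag(cm) <- 0
  need <- which(rowSums(mask) > 0)
  for (i in need) {
    ord <- order(-abs(cm[i, ]))
    nb_all <- ord[abs(cm[i, ord]) > 0]
    nb_all <- nb_all[seq_len(min(k + 4L, length(nb_all)))]  # spares for gaps
    # pairwise-complete OLS of feature i on each neighbor
    fit <- lapply(nb_all, function(g) {
      both <- !mask[i, ] & !mask[g, ]
      xg <- vv[g, both]; yi <- vv[i, both]
      vx <- stats::var(xg)
      b <- if (is.finite(vx) && vx > 0) stats::cov(xg, yi) / vx else 0
      c(a = mean(yi) - b * mean(xg), b = b)
    })
    for (j in which(mask[i, ])) {
      avail <- which(!mask[nb_all, j])
      avail <- avail[seq_len(min(k, length(avail)))]
      if (length(avail) == 0L) { v[i, j] <- mu[i]; next }
      pred <- vapply(avail, function(a)
        fit[[a]]["a"] + fit[[a]]["b"] * vv[nb_all[a], j], numeric(1))
      v[i, j] <- mean(pred)
    }
  }
  om$values <- v
  log_transform_step(om, "impute", k = k, imputed = sum(mask))
}

#' Low-count filter and log-CPM transform for RNA counts
#'
#' Removes genes with fewer than `min_count` raw counts in more than
#' `min_frac` of donors, then transforms to `log2(CPM + 0.5)` (counts per
#' million over each donor's post-filter library). With
#' `network_trim = TRUE` the co-expression-branch trims are also applied:
#' the 15% of genes with lowest mean raw counts and then the 15% with lowest
#' post-transform variance are dropped.
#'
#' @param om RNA [omics_matrix] of non-negative integer counts.
#' @param min_count,min_frac low-count rule (strict `< min_count` in
#'   strictly `> min_frac` of donors).
#' @param network_trim apply the additional abundance/variance trims.
#' @return Transformed [omics_matrix] (values log2 CPM).
#' @export
normalize_counts <- function(om, min_count = 5, min_frac = 0.5,
                             network_trim = FALSE) {
  stopifnot(inherits(om, "omics_matrix"))
  v <- om$values
  if (any(v < 0)) stop("negative counts", call. = FALSE)
  keep <- rowMeans(v < min_count) <= min_frac
  v <- v[keep, , drop = FALSE]
  om$features <- om$features[keep, , drop = FALSE]
  if (network_trim) {
    mkeep <- rank(rowMeans(v), ties.method = "first") > ceiling(0.15 * nrow(v))
    v <- v[mkeep, , drop = FALSE]
    om$features <- om$features[mkeep, , drop = FALSE]
  }
  libs <- colSums(v)
  cpm <- sweep(v, 2, libs / 1e6, `/`)
  lv <- log2(cpm + 0.5)
  if (network_trim) {
    vkeep <- rank(apply(lv, 1, stats::var), ties.method = "first") >
      ceiling(0.15 * nrow(lv))
    lv <- lv[vkeep, , drop = FALSE]
    om$features <- om$features[vkeep, , drop = FALSE]
  }
  om$values <- lv
  om$mask <- matrix(FALSE, nrow(lv), ncol(lv), dimnames = dimnames(lv))
  log_transform_step(om, "normalize_counts", min_count = min_count,
                     min_frac = min_frac, network_trim = network_trim,
                     removed = sum(!keep))
}

#' Batch adjustment by per-gene location/scale standardization
#'
#' For every gene, each batch's values are shifted and scaled so that all
#' batch means equal the pooled mean and batch (population) variances the
#' pooled variance; the population convention makes the adjustment an exact
#' identity when batches already coincide. Singleton batches get a
#' location-only adjustment with a warning.
#'
#' @param om RNA [omics_matrix] (log scale) with `$batch` labels, or a plain
#'   matrix plus `batch`.
#' @param batch per-donor batch labels (defaults to `om$batch`).
#' @return Adjusted [omics_matrix].
#' @export
batch_adjust <- function(om, batch = NULL) {
  plain <- is.matrix(om)
  v <- if (plain) om else om$values
  batch <- batch %||% (if (!plain) om$batch else NULL)
  if (is.null(batch)) stop("batch labels required", call. = FALSE)
  batch <- as.character(batch)
  tab <- table(batch)
  if (any(tab == 1))
    warning("singleton batch(es): location-only adjustment applied there")
  gm <- rowMeans(v)
  gv <- rowMeans((v - gm)^2)
  out <- v
  for (b in names(tab)) {
    j <- which(batch == b)
    bm <- rowMeans(v[, j, drop = FALSE])
    if (tab[[b]] > 1) {
      bv <- rowMeans((v[, j, drop = FALSE] - bm)^2)
      sc <- ifelse(bv > 0, sqrt(gv / bv), 1)
    } else sc <- 1
    out[, j] <- (v[, j, drop = FALSE] - bm) * sc + gm
  }
  if (plain) return(out)
  om$values <- out
  log_transform_step(om, "batch_adjust", n_batches = length(tab))
}

#' Per-feature coefficient of variation on the natural scale
#'
#' Back-transforms log-scale matrices (log10 proteome, log2-CPM RNA) to the
#' natural scale and reports CV = population SD / mean per feature. The
#' protein-vs-RNA CV comparison uses the Mann-Whitney test.
#'
#' @param om an [omics_matrix] whose processing log indicates the transform
#'   applied (proteome log10 / RNA log2-CPM), or a natural-scale matrix.
#' @return data.frame: `feature_id`, `cv`, `flagged` (zero-mean features).
#' @export
feature_cv <- function(om) {
  if (is.matrix(om)) v <- om
  else {
    steps <- vapply(om$log, `[[`, "", "step")
    v <- om$values
    if ("normalize_proteome" %in% steps) v <- 10^v
    else if ("normalize_counts" %in% steps) v <- 2^v - 0.5
  }
  mu <- rowMeans(v)
  s <- apply(v, 1, sd_pop)
  data.frame(feature_id = rownames(v), cv = ifelse(mu != 0, s / mu, NA_real_),
             flagged = mu == 0, row.names = NULL)
}

#' Compare protein and RNA CV distributions
#'
#' @param protein_cv,rna_cv outputs of [feature_cv()].
#' @return One-row data.frame with median CVs and the Mann-Whitney p-value.
#' @export
compare_cv <- function(protein_cv, rna_cv) {
  p <- protein_cv$cv[!protein_cv$flagged]
  r <- rna_cv$cv[!rna_cv$flagged]
  ht <- suppressWarnings(stats::wilcox.test(p, r))
  data.frame(median_protein_cv = stats::median(p),
             median_rna_cv = stats::median(r), p = ht$p.value)
}
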
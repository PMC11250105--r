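#' Marker-based cell-type composition scores
#'
#' Each donor column is first centered by its median over all features (so
#' per-donor global scaling/loading differences are absorbed); then, for
#' each cell type, the score is the first principal component across donors
#' of the standardized marker submatrix (oriented to follow the mean marker
#' profile) — a relative abundance score for that cell type. In
#' `"proportions"` mode scores are shifted to be non-negative and each
#' donor's row normalized to sum to 1. Cell types with fewer than two
#' markers present in the matrix are dropped with a warning.
#'
#' @param om [omics_matrix] (log scale) or matrix, features x donors.
#' @param markers named list mapping cell type to marker feature ids, or a
#'   two-column data.frame (`cell_type`, `feature_id`). Marker lists must be
#'   disjoint across cell types.
#' @param mode `"score"` (raw PC score) or `"proportions"`.
#' @return `composition_estimate`: donors x cell-types matrix with
#'   attribute `mode`.
#' @export
estimate_composition <- function(om, markers, mode = c("score", "proportions")) {
  mode <- match.arg(mode)
  v <- if (is.matrix(om)) om else om$values
  v <- sweep(v, 2, apply(v, 2, stats::median, na.rm = TRUE), `-`)
  if (is.data.frame(markers))
    markers <- split(markers$feature_id, markers$cell_type)
  all_ids <- unlist(markers)
  if (anyDuplicated(all_ids))
    stop("marker lists must be disjoint across cell types", call. = FALSE)
  scores <- list()
  for (ct in names(markers)) {
    ids <- intersect(markers[[ct]], rownames(v))
    if (length(ids) < 2L) {
      warning("cell type '", ct, "' has < 2 markers in the matrix; dropped")
      next
    }
    sub <- t(scale(t(v[ids, , drop = FALSE])))
    sub[!is.finite(sub)] <- 0
    sv <- svd(sub, nu = 0, nv = 1)
    s <- sv$v[, 1]
    if (stats::cor(s, colMeans(sub)) < 0) s <- -s
    scores[[ct]] <- s
  }
  if (length(scores) == 0L) stop("no cell type has enough markers", call. = FALSE)
  est <- do.call(cbind, scores)
  rownames(est) <- colnames(v)
  if (mode == "proportions") {
    est <- est - min(est)
    rs <- rowSums(est)
    rs[rs == 0] <- 1
    est <- est / rs
  }
  structure(est, mode = mode, class = c("composition_estimate", "matrix"))
}

#' ND-vs-T2D contrast of composition scores
#'
#' Runs [group_compare()] per cell type and BH-adjusts across cell types.
#'
#' @param estimate a `composition_estimate`.
#' @param groups per-donor group labels (reference first, e.g. `ND`).
#' @param test passed to [group_compare()].
#' @param ref reference group label.
#' @return data.frame: `cell_type`, the [group_compare()] fields, `q`.
#' @export
compare_composition <- function(estimate, groups, test = c("t", "mwu"),
                                ref = "ND") {
  test <- match.arg(test)
  rows <- lapply(colnames(estimate), function(ct) {
    gc <- group_compare(estimate[, ct], groups, test = test, ref = ref)
    cbind(cell_type = ct, gc)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out
}

#' Read a marker-set file
#'
#' Two-column TSV (`cell_type`, `feature_id`).
#'
#' @param path file path.
#' @return Named list of marker id vectors.
#' @export
read_markers <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  split(df$feature_id, df$cell_type)
}
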
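#' Across-gene RNA-protein correlation
#'
#' Pearson correlation, over genes shared by the two matrices, of the
#' per-gene mean (log) protein abundance against the per-gene mean (log)
#' RNA level — the standard "static" concordance of the two omes.
#'
#' @param protein,rna [omics_matrix] objects (log scale) or matrices with
#'   gene-identifier rownames.
#' @param mapping optional two-column data.frame (`protein_id`, `gene_id`);
#'   by default rownames are matched directly.
#' @return Named numeric: `r`, `p`, `n_genes`.
#' @export
across_gene_correlation <- function(protein, rna, mapping = NULL) {
  pv <- if (is.matrix(protein)) protein else protein$values
  rv <- if (is.matrix(rna)) rna else rna$values
  pid <- rownames(pv)
  if (!is.null(mapping)) {
    pid <- mapping$gene_id[match(pid, mapping$protein_id)]
  }
  shared <- intersect(pid, rownames(rv))
  if (length(shared) < 3L) stop("fewer than 3 shared genes", call. = FALSE)
  mp <- rowMeans(pv)[match(shared, pid)]
  mr <- rowMeans(rv[shared, , drop = FALSE])
  pc <- pairwise_correlation(mp, mr)
  c(r = unname(pc["r"]), p = unname(pc["p"]), n_genes = length(shared))
}

#' Within-gene (across-donor) RNA-protein correlation
#'
#' For each shared gene, the Pearson correlation of its protein abundance
#' and RNA level across shared donors, BH-adjusted across genes, with the
#' summary fractions of genes positively significant, negatively
#' significant, and non-significant at the given FDR.
#'
#' @inheritParams across_gene_correlation
#' @param fdr significance threshold on q (default 0.05).
#' @return List: `per_gene` (data.frame `gene_id`, `r`, `p`, `q`) and
#'   `fractions` (named numeric summing to 1).
#' @export
within_gene_correlation <- function(protein, rna, mapping = NULL, fdr = 0.05) {
  pv <- if (is.matrix(protein)) protein else protein$values
  rv <- if (is.matrix(rna)) rna else rna$values
  pid <- rownames(pv)
  if (!is.null(mapping)) pid <- mapping$gene_id[match(pid, mapping$protein_id)]
  shared <- intersect(pid, rownames(rv))
  donors <- intersect(colnames(pv), colnames(rv))
  if (length(donors) < 4L) stop("fewer than 4 shared donors", call. = FALSE)
  res <- t(vapply(shared, function(g) {
    pairwise_correlation(pv[match(g, pid), donors], rv[g, donors])[c("r", "p")]
  }, numeric(2)))
  per_gene <- data.frame(gene_id = shared, r = res[, "r"], p = res[, "p"],
                         q = bh_adjust(res[, "p"]), row.names = NULL)
  sig <- !is.na(per_gene$q) & per_gene$q < fdr
  fr <- c(positive = mean(sig & per_gene$r > 0),
          negative = mean(sig & per_gene$r < 0))
  fr <- c(fr, nonsignificant = 1 - sum(fr))
  list(per_gene = per_gene, fractions = fr)
}

#' Rank-rank hypergeometric overlap grid
#'
#' Both score vectors (a direction-signed differential statistic, e.g.
#' signed -log10 p or log2FC) are ranked from most-up-regulated to
#' most-down-regulated, ties broken by stable gene-id order. For every pair
#' of list-length thresholds (multiples of `step`), the overlap `k` of the
#' two top lists is scored by the hypergeometric tail: cells are
#' `-log10 P(X >= k)` when the overlap exceeds expectation (enrichment,
#' positive sign) and `-(-log10 P(X <= k))` otherwise (depletion).
#'
#' @param score_x,score_y named numeric scores over a shared gene universe.
#' @param step rank step size; defaults to 100 when the universe has at
#'   least 5,000 genes and `ceiling(m/50)` otherwise.
#' @return `rrho_grid` object: list with `logp` (signed matrix), `overlap`
#'   (counts), `thresholds`, `step`, `m`.
#' @export
rrho_map <- function(score_x, score_y, step = NULL) {
  genes <- intersect(names(score_x), names(score_y))
  genes <- sort(genes)
  m <- length(genes)
  if (m < 2L) stop("empty shared gene universe", call. = FALSE)
  step <- step %||% (if (m >= 5000) 100L else ceiling(m / 50))
  if (step >= m) stop("step must be smaller than the gene universe",
                      call. = FALSE)
  # stable ranking: descending score, gene id as tiebreak
  rank_of <- function(s) {
    ord <- order(-s[genes], genes)
    r <- integer(m)
    r[ord] <- seq_len(m)
    stats::setNames(r, genes)
  }
  rx <- rank_of(score_x); ry <- rank_of(score_y)
  thr <- seq(step, m - 1, by = step)
  k <- matrix(0L, length(thr), length(thr))
  logp <- matrix(0, length(thr), length(thr))
  for (i in seq_along(thr)) {
    inx <- rx <= thr[i]
    for (j in seq_along(thr)) {
      kk <- sum(inx & ry <= thr[j])
      k[i, j] <- kk
      expected <- thr[i] * thr[j] / m
      p_over <- stats::phyper(kk - 1, thr[j], m - thr[j], thr[i],
                              lower.tail = FALSE)
      p_under <- stats::phyper(kk, thr[j], m - thr[j], thr[i])
      logp[i, j] <- if (kk >= expected) -log10(p_over) else log10(p_under)
    }
  }
  structure(list(logp = logp, overlap = k, thresholds = thr, step = step,
                 m = m), class = "rrho_grid")
}

#' @export
print.rrho_grid <- function(x, ...) {
  cat(sprintf("<rrho_grid> %d x %d cells (step %d, universe %d), max |signed -log10 p| = %.2f\n",
              nrow(x$logp), ncol(x$logp), x$step, x$m, max(abs(x$logp))))
  invisible(x)
}

#' Hypergeometric over-representation analysis against gene sets
#'
#' Upper-tail hypergeometric test of a hit list against each gene set,
#' intersected with the background universe (typically the genes detected in
#' both omes), BH-adjusted across sets. Duplicated identifiers are
#' deduplicated before testing.
#'
#' @param hits character vector of hit gene ids (subset of `universe`).
#' @param gene_sets named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param universe background gene ids.
#' @return data.frame: `set`, `set_size`, `n_hits`, `overlap`, `p`, `q`.
#' @export
ora_hypergeometric <- function(hits, gene_sets, universe) {
  universe <- unique(universe)
  hits <- unique(hits)
  if (length(universe) == 0L || length(hits) == 0L)
    stop("empty universe or hit list", call. = FALSE)
  if (!all(hits %in% universe))
    stop("hits must be a subset of the universe", call. = FALSE)
  N <- length(universe); K <- length(hits)
  rows <- lapply(names(gene_sets), function(nm) {
    s <- intersect(unique(gene_sets[[nm]]), universe)
    k <- length(intersect(s, hits))
    p <- stats::phyper(k - 1, length(s), N - length(s), K, lower.tail = FALSE)
    data.frame(set = nm, set_size = length(s), n_hits = K, overlap = k, p = p)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out
}

#' Read a GMT gene-set file
#'
#' Standard tab-separated format: set name, description, then member ids.
#'
#' @param path file path.
#' @return Named list of character vectors; descriptions in
#'   `attr(, "description")`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  attr(sets, "description") <- vapply(parts, `[[`, "", 2L)
  sets
}
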
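#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (`q_(i) = min_{j>=i} p_(j) * m / j`, capped at 1,
#' returned in input order), computed via [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in `[0, 1]` (NAs preserved).
#' @return Vector of adjusted p-values (q-values).
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Per-feature differential abundance between two donor groups
#'
#' Two-sided Welch t-tests per feature on log-scale values, with the fold
#' change reported as log2 (difference of group means divided by `log10(2)`
#' when the matrix is on log10 scale). BH adjustment spans all tested
#' features; constant features get p = 1 with a flag and stay in the family.
#'
#' @param om complete [omics_matrix] (log scale) or plain matrix.
#' @param groups per-donor group labels (two levels).
#' @param ref reference group label (fold change is alt vs ref; default
#'   `"ND"` if present, else the first level).
#' @param scale log base of the matrix values: `"log10"` (proteome) or
#'   `"log2"` (RNA), controlling the log2FC conversion.
#' @return data.frame: `feature_id`, `log2fc`, `mean_ref`, `mean_alt`,
#'   `statistic`, `p`, `q`, `flagged`.
#' @export
differential_abundance <- function(om, groups, ref = NULL,
                                   scale = c("log10", "log2")) {
  scale <- match.arg(scale)
  v <- if (is.matrix(om)) om else om$values
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) != 2L) stop("need exactly two groups", call. = FALSE)
  if (is.null(ref)) ref <- if ("ND" %in% lv) "ND" else lv[1]
  alt <- setdiff(lv, ref)
  i1 <- groups == ref; i2 <- groups == alt
  if (sum(i1) < 2L || sum(i2) < 2L)
    stop("need >= 2 donors per group", call. = FALSE)
  conv <- if (scale == "log10") log10(2) else 1
  n1 <- sum(i1); n2 <- sum(i2)
  m1 <- rowMeans(v[, i1, drop = FALSE]); m2 <- rowMeans(v[, i2, drop = FALSE])
  v1 <- apply(v[, i1, drop = FALSE], 1, stats::var)
  v2 <- apply(v[, i2, drop = FALSE], 1, stats::var)
  se <- sqrt(v1 / n1 + v2 / n2)
  flagged <- se == 0
  tt <- ifelse(flagged, 0, (m2 - m1) / se)
  df <- ifelse(flagged, n1 + n2 - 2,
               (v1 / n1 + v2 / n2)^2 /
                 (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1))))
  p <- ifelse(flagged, 1, 2 * stats::pt(-abs(tt), df))
  data.frame(feature_id = rownames(v), log2fc = (m2 - m1) / conv,
             mean_ref = m1, mean_alt = m2, statistic = tt, p = p,
             q = bh_adjust(p), flagged = flagged, row.names = NULL)
}

#' Covariate-adjusted per-feature linear regression
#'
#' Ordinary least squares of each feature's (log) abundance on a donor trait
#' with covariates (T2D status by default), reporting the trait coefficient,
#' its t-test p-value, and BH q across features. Features whose design is
#' collinear are flagged and excluded from the BH family.
#'
#' @param om complete [omics_matrix] or matrix (features x donors).
#' @param trait numeric (or 0/1) trait vector over donors.
#' @param covariates data.frame of covariates over donors (e.g. a 0/1 T2D
#'   indicator); may be `NULL`.
#' @return data.frame: `feature_id`, `coefficient`, `se`, `statistic`, `p`,
#'   `q`, `n`, `flagged`.
#' @export
covariate_adjusted_regression <- function(om, trait, covariates = NULL) {
  v <- if (is.matrix(om)) om else om$values
  n <- ncol(v)
  if (length(trait) != n) stop("trait length must match donors", call. = FALSE)
  Xd <- cbind(`(Intercept)` = 1, trait = as.numeric(trait))
  if (!is.null(covariates)) {
    cm <- stats::model.matrix(~ ., data = as.data.frame(covariates))[, -1, drop = FALSE]
    Xd <- cbind(Xd, cm)
  }
  if (n <= ncol(Xd) + 1L)
    stop("need n > number of covariates + 2", call. = FALSE)
  qr_x <- qr(Xd)
  collinear <- qr_x$rank < ncol(Xd)
  if (collinear) {
    p <- rep(NA_real_, nrow(v))
    return(data.frame(feature_id = rownames(v), coefficient = NA_real_,
                      se = NA_real_, statistic = NA_real_, p = p,
                      q = bh_adjust(p), n = n, flagged = TRUE,
                      row.names = NULL))
  }
  fit <- stats::lm.fit(Xd, t(v))
  coefs <- t(fit$coefficients)
  res <- t(fit$residuals)
  df <- n - ncol(Xd)
  sigma2 <- rowSums(res^2) / df
  xtxinv <- chol2inv(qr.R(qr_x))
  se <- sqrt(sigma2 * xtxinv[2, 2])
  flagged <- se == 0
  tt <- ifelse(flagged, 0, coefs[, "trait"] / se)
  p <- ifelse(flagged, NA_real_, 2 * stats::pt(-abs(tt), df))
  data.frame(feature_id = rownames(v), coefficient = coefs[, "trait"],
             se = se, statistic = tt, p = p, q = bh_adjust(p), n = n,
             flagged = flagged, row.names = NULL)
}

#' Pearson and partial Pearson correlation with p-values
#'
#' Plain Pearson correlation (t-distributed p on n-2 df) or partial
#' correlation given a covariate set `z`, computed by double
#' residualization — each of `x` and `y` is regressed on `z` and the
#' residuals correlated — with the p-value on `n - 2 - |z|` df. With one
#' covariate this equals the closed-form recursion
#' `(r_xy - r_xz r_yz) / sqrt((1-r_xz^2)(1-r_yz^2))`.
#'
#' @param x,y numeric vectors.
#' @param z optional numeric matrix/data.frame of covariates.
#' @return Named numeric: `r`, `p`, `n`, `df`.
#' @export
pairwise_correlation <- function(x, y, z = NULL) {
  keep <- stats::complete.cases(x, y, if (!is.null(z)) z)
  x <- x[keep]; y <- y[keep]
  nz <- 0L
  if (!is.null(z)) {
    z <- as.matrix(as.data.frame(z))[keep, , drop = FALSE]
    nz <- ncol(z)
    Zd <- cbind(1, z)
    x <- stats::lm.fit(Zd, x)$residuals
    y <- stats::lm.fit(Zd, y)$residuals
  }
  n <- length(x)
  if (n < 3L + nz) stop("too few complete observations", call. = FALSE)
  if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12)  # incl. residualized-away
    return(c(r = NA_real_, p = NA_real_, n = n, df = n - 2 - nz))
  r <- stats::cor(x, y)
  df <- n - 2L - nz
  tt <- r * sqrt(df / (1 - r^2))
  c(r = r, p = 2 * stats::pt(-abs(tt), df), n = n, df = df)
}
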
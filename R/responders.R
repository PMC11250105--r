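#' Classify fatty-acid and amino-acid hyper-responder donors
#'
#' A donor is a fat hyper-responder when the baseline-subtracted AUC of the
#' fatty-acid challenge (at basal glucose) strictly exceeds the 15 mM
#' glucose AUC, and an amino-acid (leucine) hyper-responder when the leucine
#' AUC strictly exceeds it; donors meeting both are classed `both`. Donors
#' whose 15 mM glucose AUC is non-positive cannot be classified by an AUC
#' ratio and are flagged and excluded from prevalence denominators, as are
#' donors with missing required segments.
#'
#' @param features feature table from [build_feature_table()].
#' @param fat_segment,leu_segment,glucose_segment stimulus labels of the
#'   three required segments.
#' @return data.frame per donor: `donor_id`, `fat_ratio`, `leu_ratio`,
#'   `class` (`typical`/`fat_hr`/`leu_hr`/`both`/`NA`), `classifiable`, `qc`.
#' @export
classify_hyper_responders <- function(features,
                                      fat_segment = "fat",
                                      leu_segment = "leucine",
                                      glucose_segment = "glucose15") {
  get_auc <- function(d, stim) {
    r <- features[features$donor_id == d & features$stimulus == stim, ]
    if (nrow(r) != 1L || isTRUE(r$missing[1]) || is.na(r$auc[1])) NA_real_
    else r$auc[1]
  }
  donors <- unique(features$donor_id)
  out <- do.call(rbind, lapply(donors, function(d) {
    g <- get_auc(d, glucose_segment)
    f <- get_auc(d, fat_segment)
    l <- get_auc(d, leu_segment)
    if (is.na(g) || is.na(f) || is.na(l)) {
      return(data.frame(donor_id = d, fat_ratio = NA_real_, leu_ratio = NA_real_,
                        class = NA_character_, classifiable = FALSE,
                        qc = "missing_segment"))
    }
    if (g <= 0) {
      return(data.frame(donor_id = d, fat_ratio = NA_real_, leu_ratio = NA_real_,
                        class = NA_character_, classifiable = FALSE,
                        qc = "nonpositive_glucose_auc"))
    }
    fat_hr <- f > g; leu_hr <- l > g
    cls <- if (fat_hr && leu_hr) "both" else if (fat_hr) "fat_hr"
      else if (leu_hr) "leu_hr" else "typical"
    data.frame(donor_id = d, fat_ratio = f / g, leu_ratio = l / g,
               class = cls, classifiable = TRUE, qc = "ok")
  }))
  rownames(out) <- NULL
  out
}

#' Responder-class prevalence with exact binomial confidence interval
#'
#' @param calls output of [classify_hyper_responders()].
#' @param class class to count (`"fat_hr"`, `"leu_hr"`, ...). Donors classed
#'   `both` count toward both hyper-responder classes.
#' @param conf confidence level for the Clopper-Pearson interval.
#' @return Named numeric: `fraction`, `lower`, `upper`, `count`, `n`.
#' @export
prevalence <- function(calls, class, conf = 0.95) {
  ok <- calls[calls$classifiable, , drop = FALSE]
  n <- nrow(ok)
  if (n == 0L) stop("no classifiable donors", call. = FALSE)
  k <- sum(ok$class == class | (ok$class == "both" &
                                  class %in% c("fat_hr", "leu_hr")))
  ci <- stats::binom.test(k, n, conf.level = conf)$conf.int
  c(fraction = k / n, lower = ci[1], upper = ci[2], count = k, n = n)
}

#' Two-group comparison of one secretion feature
#'
#' Welch's (unequal-variance) t-test or the two-sided Mann-Whitney U test,
#' with the percent difference `100 * (1 - mean(T2D) / mean(ND))` computed
#' from group means. The Mann-Whitney p-value is exact for small tie-free
#' samples and a tie-corrected normal approximation otherwise. Constant
#' inputs under the t-test fall back to Mann-Whitney with a warning.
#'
#' @param values numeric feature vector.
#' @param groups factor/character with two levels; the first level (or
#'   `ref`) is the reference (ND) group.
#' @param test `"t"` (Welch) or `"mwu"`.
#' @param ref reference group label (default first level).
#' @return One-row data.frame: `mean_ref`, `mean_alt`, `percent_difference`,
#'   `test`, `statistic`, `p`.
#' @export
group_compare <- function(values, groups, test = c("t", "mwu"), ref = NULL) {
  test <- match.arg(test)
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- as.character(groups)[keep]
  lv <- unique(groups)
  if (length(lv) != 2L) stop("need exactly two groups", call. = FALSE)
  if (is.null(ref)) ref <- lv[1]
  alt <- setdiff(lv, ref)
  x <- values[groups == ref]; y <- values[groups == alt]
  if (length(x) < 2L || length(y) < 2L)
    stop("need >= 2 donors per group", call. = FALSE)
  if (test == "t" && (stats::sd(x) == 0 || stats::sd(y) == 0)) {
    warning("constant group values; falling back to Mann-Whitney")
    test <- "mwu"
  }
  if (test == "t") {
    ht <- stats::t.test(x, y)
    stat <- unname(ht$statistic)
  } else {
    ht <- suppressWarnings(stats::wilcox.test(x, y))
    stat <- unname(ht$statistic)
  }
  data.frame(mean_ref = mean(x), mean_alt = mean(y),
             percent_difference = 100 * (1 - mean(y) / mean(x)),
             test = if (test == "t") "t" else "mwu",
             statistic = stat, p = ht$p.value)
}

#' ND-vs-T2D contrasts across all secretion features
#'
#' Runs [group_compare()] for every segment feature (AUC, phase AUCs, peak
#' rate, time-to-peak) and the donor baseline rate, then applies
#' Benjamini-Hochberg adjustment across all contrasts.
#'
#' @param features feature table from [build_feature_table()].
#' @param donors donor metadata with `donor_id` and `group` (`ND`/`T2D`).
#' @param test passed to [group_compare()].
#' @return data.frame of contrasts with columns `feature`, the
#'   [group_compare()] fields, and `q`.
#' @export
t2d_effect_summary <- function(features, donors, test = c("t", "mwu")) {
  test <- match.arg(test)
  grp <- donors$group[match(features$donor_id, donors$donor_id)]
  if (length(unique(stats::na.omit(donors$group))) != 2L)
    stop("need both ND and T2D donors", call. = FALSE)
  rows <- list()
  metrics <- c("auc", "first_phase_auc", "second_phase_auc",
               "peak_rate", "time_to_peak")
  for (seg in unique(features$segment)) {
    sel <- features$segment == seg
    for (m in metrics) {
      v <- features[[m]][sel]
      if (all(is.na(v))) next
      gc <- group_compare(v, grp[sel], test = test, ref = "ND")
      gc$feature <- paste(seg, m, sep = ".")
      rows[[length(rows) + 1L]] <- gc
    }
  }
  # one baseline-rate contrast per donor (taken from the G arm rows)
  first <- !duplicated(features$donor_id)
  gc <- group_compare(features$baseline_rate[first], grp[first],
                      test = test, ref = "ND")
  gc$feature <- "baseline_rate"
  rows[[length(rows) + 1L]] <- gc
  out <- do.call(rbind, rows)
  out <- out[, c("feature", setdiff(names(out), "feature"))]
  out$q <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}
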
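#' @rdname simulate_cohort
#' @export
perifusion_trace <- function(donor_id, arm, time_min, values, unit,
                             protocol, islet_count = NA_integer_,
                             flow_rate = NA_real_) {
  if (any(diff(time_min) <= 0))
    stop("trace time grid must be strictly increasing", call. = FALSE)
  if (length(values) != length(time_min))
    stop("trace values and time grid differ in length", call. = FALSE)
  if (!unit %in% c("pmol/mL", "pmol/islet/min"))
    stop("unit must be 'pmol/mL' or 'pmol/islet/min'", call. = FALSE)
  structure(list(donor_id = donor_id, arm = arm, time_min = time_min,
                 values = values, unit = unit, protocol = protocol,
                 islet_count = islet_count, flow_rate = flow_rate),
            class = "perifusion_trace")
}

#' @export
print.perifusion_trace <- function(x, ...) {
  cat(sprintf("<perifusion_trace> donor %s arm %s: %d samples, %s\n",
              x$donor_id, x$arm, length(x$time_min), x$unit))
  invisible(x)
}

# --- kinetic shapes (unit integral on the continuous segment) -------------

# First-phase pulse: gamma-family (t/tau)^4 exp(4(1 - t/tau)), peaking
# sharply at t = tau so the sampled argmax sits on the pulse even when a
# rising plateau is superimposed. Returned as a density (unit integral on
# [0, Inf); segment truncation is negligible for tau << segment length).
pulse_density <- function(t, tau, k = 4) {
  norm <- gamma(k + 1) * (tau / k)^(k + 1)
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- t[pos]^k * exp(-k * t[pos] / tau) / norm
  out
}

# Saturating plateau 1 - exp(-t/tau2), unit integral over [0, L].
plateau_density <- function(t, tau2, L) {
  z <- L - tau2 * (1 - exp(-L / tau2))
  pmax(0, (1 - exp(-pmin(t, L) / tau2))) / z
}

# Segment shape per stimulus, evaluated at offsets `t` from segment start.
# `delay` shifts the first-phase pulse (T2D high-glucose kinetic defect).
stimulus_shape <- function(stimulus, t, L, delay = 0) {
  biphasic <- function(t, delay = 0)
    0.35 * pulse_density(t - delay, tau = 5) +
      0.65 * plateau_density(t, tau2 = 10, L = L)
  switch(stimulus,
    glucose15 = biphasic(t, delay),
    glucose6 = ,
    leucine = ,
    leu_plus_g6 = biphasic(t),
    fat = plateau_density(t, tau2 = 15, L = L),
    kcl = pulse_density(t, tau = 2),
    basal = numeric(length(t)),
    stop("unknown stimulus '", stimulus, "'", call. = FALSE))
}

# Noise-free secretion rate (pmol/islet/min) for one donor on one arm.
# rate(t) = b0 * capacity * (1 + sum_s r_s * delta_s * shape_s(t - start_s)),
# so the baseline-subtracted AUC of segment s is b0*capacity*r_s*delta_s.
underlying_rate <- function(protocol, time_min, config, latent, group) {
  rate <- rep(config$baseline_rate * latent$capacity, length(time_min))
  for (i in seq_len(nrow(protocol))) {
    stim <- protocol$stimulus[i]
    if (stim == "basal") next
    inseg <- time_min >= protocol$start_min[i] & time_min < protocol$end_min[i]
    if (!any(inseg)) next
    L <- protocol$end_min[i] - protocol$start_min[i]
    delay <- if (stim == "glucose15" && group == "T2D")
      config$t2d_peak_delay_min else 0
    delta <- if (group == "T2D") config$t2d_effect[[stim]] else 1
    shp <- stimulus_shape(stim, time_min[inseg] - protocol$start_min[i], L, delay)
    rate[inseg] <- rate[inseg] +
      config$baseline_rate * latent$capacity * latent$response[[stim]] * delta * shp
  }
  rate
}

#' Simulate one perifusion trace
#'
#' Generates the measured effluent insulin concentration for one donor on one
#' protocol arm: the underlying secretion rate (baseline, biphasic glucose /
#' amino-acid responses, monophasic fat response, sharp KCl transient,
#' stimulus-specific T2D multipliers, T2D first-phase peak delay) converted
#' to concentration via the column's islet count and flow rate, with
#' multiplicative log-normal assay noise averaged over technical replicates.
#'
#' @param donor one-row data.frame from the cohort donor table.
#' @param arm arm identifier (names `canonical_protocols()`).
#' @param protocol a [stimulus_protocol()].
#' @param config a [generator_config()].
#' @param latent list of the donor's latent draws (`capacity`, `response`):
#'   taken from the cohort ground truth.
#' @param noise logical; `FALSE` yields the noise-free underlying trace.
#' @return A `perifusion_trace` in effluent concentration units (pmol/mL).
#' @export
simulate_trace <- function(donor, arm, protocol, config, latent, noise = TRUE) {
  time_min <- seq(min(protocol$start_min), max(protocol$end_min) - 1, by = 1)
  rate <- underlying_rate(protocol, time_min, config, latent, donor$group)
  conc <- rate * config$islet_count / config$flow_rate
  if (noise && config$assay_cv > 0) {
    s2 <- log(1 + config$assay_cv^2)
    reps <- matrix(
      stats::rlnorm(length(conc) * config$n_tech_reps, -s2 / 2, sqrt(s2)),
      nrow = length(conc))
    conc <- conc * rowMeans(reps)
  }
  perifusion_trace(donor$donor_id, arm, time_min, conc, "pmol/mL",
                   protocol, config$islet_count, config$flow_rate)
}

# Donor metadata + latent ground truth draws. HbA1c of T2D donors is drawn
# stochastically above the ND distribution.
simulate_donors <- function(config) {
  n <- config$n_nd + config$n_t2d
  group <- c(rep("ND", config$n_nd), rep("T2D", config$n_t2d))
  donor_id <- sprintf("D%03d", seq_len(n))
  sex <- sample(c("F", "M"), n, replace = TRUE)
  age <- round(rtruncnorm(n, 55, 13, lower = 20, upper = 85))
  bmi <- round(stats::rlnorm(n, log(27), 0.15), 1)
  hba1c <- round(ifelse(group == "ND",
                        rtruncnorm(n, 5.4, 0.3, lower = 4.5, upper = 6.4),
                        rtruncnorm(n, 7.3, 0.9, lower = 6.5, upper = 11)), 1)
  culture_time <- round(stats::runif(n, 24, 96))
  cold_ischemia_time <- round(stats::rlnorm(n, log(8), 0.4), 1)
  digestion_time <- round(rtruncnorm(n, 14, 3, lower = 6, upper = 25), 1)
  purity <- round(rtruncnorm(n, 0.85, 0.07, lower = 0.5, upper = 0.99), 2)

  cls <- sample(c("typical", "fat_hr", "leu_hr"), n, replace = TRUE,
                prob = c(1 - config$pi_fat - config$pi_leu,
                         config$pi_fat, config$pi_leu))
  capacity <- rlnorm_cv(n, config$capacity_cv)
  # Per-stimulus response jitter at half the capacity log-sd: within-donor
  # response ratios vary less than absolute capacity, which keeps the
  # typical-donor fat/glucose and leucine/glucose AUC ratios well below 1
  # (the responder-class prevalence stays unbiased under classification).
  sdlog <- 0.5 * sqrt(log(1 + config$capacity_cv^2))
  stim <- names(config$mean_response)
  response <- sapply(stim, function(s)
    config$mean_response[[s]] * exp(stats::rnorm(n, -sdlog^2 / 2, sdlog)))
  response <- matrix(response, nrow = n, dimnames = list(donor_id, stim))
  # Hyper-responders: fat (or leucine) latent response tied to the donor's
  # own glucose15 response times (1 + u); the lower truncation of u keeps the
  # defining AUC inequality true under the T2D stimulus multipliers too.
  u <- rep(NA_real_, n)
  hr <- cls != "typical"
  if (any(hr)) {
    u[hr] <- rtruncnorm(sum(hr), 0.6, 0.2, lower = 0.35)
    fat_i <- which(cls == "fat_hr")
    response[fat_i, "fat"] <- response[fat_i, "glucose15"] * (1 + u[fat_i])
    response[fat_i, "kcl"] <- response[fat_i, "kcl"] * 0.7
    leu_i <- which(cls == "leu_hr")
    response[leu_i, "leucine"] <- response[leu_i, "glucose15"] * (1 + u[leu_i])
  }

  donors <- data.frame(
    donor_id = donor_id, group = group, sex = sex, age = age, bmi = bmi,
    hba1c = hba1c, culture_time = culture_time,
    cold_ischemia_time = cold_ischemia_time, digestion_time = digestion_time,
    purity = purity, islet_count = config$islet_count,
    stringsAsFactors = FALSE)

  auc_true <- sapply(stim, function(s) {
    d <- ifelse(group == "T2D", config$t2d_effect[[s]], 1)
    config$baseline_rate * capacity * response[, s] * d
  })
  colnames(auc_true) <- paste0("auc_", stim)

  truth <- data.frame(donor_id = donor_id, group = group, class = cls,
                      capacity = capacity, hr_excess = u,
                      response, auc_true, check.names = FALSE,
                      stringsAsFactors = FALSE)
  list(donors = donors, truth = truth)
}

#' Simulate a synthetic donor cohort
#'
#' Generates a full cohort bundle: donor metadata, latent ground truth,
#' three-arm perifusion traces for every donor, and (optionally) paired
#' proteome/transcriptome matrices via [simulate_omics()]. Identical
#' configurations (including seed) reproduce the bundle bit-for-bit.
#'
#' @param config a [generator_config()].
#' @param include_omics simulate the omics matrices too (default `TRUE`).
#' @return List with elements `config`, `protocols`, `donors` (metadata
#'   table), `traces` (list of `perifusion_trace`), `truth` (donor-level
#'   ground truth incl. responder class and true AUCs), and, when requested,
#'   `protein`, `rna` ([omics_matrix] objects) and `omics_truth`.
#' @examples
#' cohort <- simulate_cohort(generator_config(n_nd = 8, n_t2d = 2,
#'                                            n_proteins = 60, n_genes = 80,
#'                                            n_modules = 1, seed = 7))
#' nrow(cohort$donors)
#' @export
simulate_cohort <- function(config, include_omics = TRUE) {
  stopifnot(inherits(config, "generator_config"))
  protocols <- canonical_protocols()
  set.seed(child_seed(config$seed, "donors"))
  dl <- simulate_donors(config)

  set.seed(child_seed(config$seed, "traces"))
  traces <- list()
  for (i in seq_len(nrow(dl$donors))) {
    latent <- list(capacity = dl$truth$capacity[i],
                   response = as.list(dl$truth[i, names(config$mean_response)]))
    for (arm in names(protocols)) {
      tr <- simulate_trace(dl$donors[i, ], arm, protocols[[arm]], config, latent)
      traces[[paste(dl$donors$donor_id[i], arm, sep = ".")]] <- tr
    }
  }

  out <- list(config = config, protocols = protocols,
              donors = dl$donors, traces = traces, truth = dl$truth)
  if (include_omics) {
    om <- simulate_omics(dl$donors, config, truth = dl$truth)
    out$protein <- om$protein
    out$rna <- om$rna
    out$omics_truth <- om$truth
  }
  out
}

#' Write a cohort bundle to plain-text files
#'
#' Writes `donors.tsv`, `traces_<arm>.tsv` (long format), `ground_truth.tsv`,
#' `protocol.yaml` and, when present, `protein_matrix.tsv` / `rna_counts.tsv`.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(cohort$donors, "donors.tsv")
  wt(cohort$truth, "ground_truth.tsv")
  write_protocols(cohort$protocols, file.path(dir, "protocol.yaml"))
  for (arm in names(cohort$protocols)) {
    keep <- vapply(cohort$traces, function(tr) tr$arm == arm, logical(1))
    long <- do.call(rbind, lapply(cohort$traces[keep], function(tr) {
      seg <- vapply(tr$time_min, function(t) {
        i <- which(t >= tr$protocol$start_min & t < tr$protocol$end_min)
        if (length(i)) tr$protocol$name[i[1]] else NA_character_
      }, character(1))
      data.frame(donor_id = tr$donor_id, time_min = tr$time_min, segment = seg,
                 value = tr$values, unit = tr$unit)
    }))
    wt(long, paste0("traces_", arm, ".tsv"))
  }
  if (!is.null(cohort$protein)) {
    pm <- cohort$protein$values
    wt(data.frame(feature_id = rownames(pm), pm, check.names = FALSE),
       "protein_matrix.tsv")
    rm_ <- cohort$rna$values
    wt(data.frame(gene_id = rownames(rm_), rm_, check.names = FALSE),
       "rna_counts.tsv")
  }
  invisible(dir)
}
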
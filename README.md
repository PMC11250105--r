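# isletpheno

Deep functional phenotyping of pancreatic islets couples dynamic
insulin-secretion measurements (perifusion) with proteomics and
transcriptomics from the same donors. `isletpheno` is an R package for that
analysis: it turns perifusion traces into kinetic secretion features,
classifies donors into nutrient hyper-responder subtypes, contrasts
non-diabetic (ND) and type 2 diabetic (T2D) donors, and links donor traits
to molecular data through differential abundance, covariate-adjusted
regression, signed weighted co-expression networks, RNA–protein concordance,
and marker-based cell-type composition. It is written for islet biologists
and computational groups who want a reproducible, fully tested pipeline for
this study design — and, because donor data are access-controlled, it ships
a synthetic cohort generator that emulates the statistical structure of such
studies so every stage runs and is verifiable offline.

## The model in brief

A perifusion trace is modeled as
`rate(t) = b0 · c_d · (1 + Σ_s ρ_{d,s} · δ_s(group) · f_s(t − t_s))` with
donor capacity `c_d`, stimulus-specific relative responses `ρ`, T2D
multipliers `δ_s`, and unit-integral kinetic shapes `f_s` (biphasic for
glucose and leucine — a first-phase pulse peaking within 15 min plus a
saturating plateau — monophasic for fatty acid, a sharp transient for KCl).
Features extracted per donor × segment: baseline-subtracted AUC
(pmol/islet), first-phase (first 15 min of 15 mM glucose) and second-phase
(remaining 25 min) AUCs, peak rate, and time-to-peak within the first
15 min of a solution change. A donor is a *fat (leucine) hyper-responder*
when the fat (leucine) AUC at basal glucose strictly exceeds their 15 mM
glucose AUC. Group contrasts report `100·(1 − mean_T2D/mean_ND)` with
Welch t or Mann–Whitney tests and Benjamini–Hochberg control; the network
stage uses biweight midcorrelation, signed soft-threshold adjacency
`((1+r)/2)^β`, topological overlap, average-linkage clustering with a
static cut, and first-PC module eigengenes correlated (partially, given
technical isolation covariates) with donor traits.

## Worked example

```r
library(isletpheno)

cfg    <- generator_config(seed = 1)          # 123 ND / 17 T2D donors
cohort <- simulate_cohort(cfg, include_omics = FALSE)
feats  <- build_feature_table(cohort$traces, cohort$protocols)
calls  <- classify_hyper_responders(feats)

prevalence(calls, "fat_hr")
#> fraction    lower    upper    count        n
#>   0.0500   0.0203   0.1003   7.0000 140.0000
prevalence(calls, "leu_hr")
#> fraction    lower    upper    count        n
#>   0.0714   0.0348   0.1274  10.0000 140.0000

ctr <- t2d_effect_summary(feats, cohort$donors)
subset(ctr, grepl("\\.auc$", feature) & !grepl("phase", feature),
       c(feature, percent_difference, p, q))
#>          feature percent_difference      p      q
#>    glucose15.auc            35.4888 0.0000 0.0000
#>     glucose6.auc            36.8746 0.0000 0.0000
#>          kcl.auc            24.4390 0.0001 0.0001
#>      leucine.auc             6.3970 0.7474 0.8807
#>  leu_plus_g6.auc            37.4166 0.0000 0.0000
#>          fat.auc            45.5448 0.0018 0.0036
```

At this single seed, 7/140 donors (5.0%) are fat hyper-responders and
10/140 (7.1%) leucine hyper-responders — single-cohort binomial noise around
the configured 8%/9% mixture. T2D donors secrete ~35% less insulin in
response to 15 mM glucose and ~46% less to fatty acid, while the
leucine-alone contrast is far from significant (q = 0.88): amino-acid
stimulated secretion is preserved in the simulated T2D group by
construction. Averaged over many seeds these estimates converge to the
configured study conditions.

The full pipeline — preprocessing, differential abundance, concordance,
network modules, composition — runs from one call and writes tab-separated
stage outputs plus a JSON manifest:

```r
run_pipeline(generator_config(seed = 1), out_dir = "run1")
report("run1")   # markdown summary: prevalences, contrasts, modules, ...
```

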
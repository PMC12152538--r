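#' Parameter-recovery simulation studies
#'
#' The functions in this file re-run the full pipeline on seeded synthetic
#' cohorts to check that each stage recovers what the generator injected:
#' network connectedness contrasts, region mean shifts, type-I error and
#' FDR control under the null, meta-analytic confidence-interval coverage,
#' and spin-test null calibration. They are used by the test suite and the
#' acceptance script, and are reusable for sensitivity analyses.
#'
#' @name recovery
NULL

# two-group generator used throughout the recovery studies; sizes and
# correlation strengths default to the study conditions
.two_group_config <- function(groups, n, rho, effect_map = NULL, seed = 1L,
                              region_names = default_region_names(),
                              age_slope = -0.02, sex_effect = 0.2) {
  generator_config(
    n_per_group = setNames(n, groups),
    region_names = region_names,
    rho_g = setNames(rho, groups),
    effect_map = effect_map,
    age_mean_g = setNames(c(63.1, 69.2, 74.8, 68.9)[seq_along(groups)],
                          groups),
    age_sd_g = setNames(rep(8.5, length(groups)), groups),
    age_slope = age_slope, sex_effect = sex_effect, seed = seed
  )
}

#' Structural covariance contrast recovery
#'
#' Generates replicate cohorts in which the control group has stronger
#' within-block volume covariance than the A+T+ group (the generator's
#' default contrast), runs the preprocessing and SCN stages on each, and
#' records the (binary) global clustering and small-worldness of both group
#' networks.
#'
#' @param n_replicates Number of seeded replicates.
#' @param seed Base seed; replicate r uses `seed + r`.
#' @param n_control,n_atplus Group sizes.
#' @param rho_control,rho_atplus Within-block correlation per group.
#' @param proportion SCN proportional threshold.
#' @return Tibble: `rep`, `C_control`, `C_atplus`, `S_control`, `S_atplus`.
#' @export
replicate_scn_contrast <- function(n_replicates = 100, seed = 1L,
                                   n_control = 60, n_atplus = 121,
                                   rho_control = 0.45, rho_atplus = 0.25,
                                   proportion = 0.35) {
  out <- lapply(seq_len(n_replicates), function(r) {
    cfg <- .two_group_config(c("control", "A+T+"),
                             c(n_control, n_atplus),
                             c(rho_control, rho_atplus),
                             seed = seed + r)
    prepped <- prepare_cohort(generate_cohort(cfg))
    gm <- lapply(c(CONTROL = "CONTROL", A_T_PLUS = "A_T_PLUS"),
                 function(g) {
      sub <- prepped[prepped$at_group == g, , drop = FALSE]
      net <- build_scn(volume_matrix(sub),
                       .covariate_matrix(sub, c("age", "sex")),
                       proportion = proportion)
      graph_metrics(net, mode = "binary")
    })
    tibble::tibble(rep = r,
                   C_control = gm$CONTROL$global_clustering,
                   C_atplus = gm$A_T_PLUS$global_clustering,
                   S_control = gm$CONTROL$small_worldness,
                   S_atplus = gm$A_T_PLUS$small_worldness)
  })
  dplyr::bind_rows(out)
}

#' Injected region effect recovery
#'
#' Generates replicate two-group cohorts with a standardized mean shift
#' `delta` on one region in the A+T- group, and fits the per-region
#' logistic association for that region (adjusted for age and sex).
#'
#' @param n_replicates Number of seeded replicates.
#' @param n_per_group Subjects per group.
#' @param delta Standardized shift injected into `region`.
#' @param region Affected region.
#' @param seed Base seed.
#' @return Tibble: `rep`, `beta`, `p`, `selected`.
#' @export
replicate_effect_recovery <- function(n_replicates = 50, n_per_group = 100,
                                      delta = -0.8, region = "thalamus",
                                      seed = 1L) {
  em <- data.frame(region = region, group = "A+T-", delta = delta)
  out <- lapply(seq_len(n_replicates), function(r) {
    cfg <- .two_group_config(c("control", "A+T-"),
                             c(n_per_group, n_per_group), c(0.35, 0.35),
                             effect_map = em, seed = seed + r)
    prepped <- prepare_cohort(generate_cohort(cfg))
    keep <- !grepl("^vol_", names(prepped)) |
      names(prepped) == paste0("vol_", region)
    assoc <- per_region_association(prepped[, keep, drop = FALSE],
                                    c("A_T_MINUS", "CONTROL"))
    tibble::tibble(rep = r, beta = assoc$beta, p = assoc$p,
                   selected = assoc$selected)
  })
  dplyr::bind_rows(out)
}

#' Null-generator association studies
#'
#' Generates replicate two-group cohorts with no injected effects and equal
#' covariance in both groups (so biomarker group is independent of the
#' volumes) and returns the per-region association table of each replicate.
#'
#' @param n_replicates Number of replicate studies.
#' @param n_per_group Subjects per group.
#' @param seed Base seed.
#' @return List of association tibbles.
#' @export
replicate_null_assoc <- function(n_replicates = 200, n_per_group = 60,
                                 seed = 1L) {
  lapply(seq_len(n_replicates), function(r) {
    cfg <- .two_group_config(c("control", "A+T-"),
                             c(n_per_group, n_per_group), c(0.35, 0.35),
                             seed = seed + r)
    prepped <- prepare_cohort(generate_cohort(cfg))
    per_region_association(prepped, c("A_T_MINUS", "CONTROL"))
  })
}

#' Selection rate across null association studies
#'
#' @param tables List of association tibbles (see
#'   [replicate_null_assoc()]).
#' @return Fraction of region fits flagged selected (uncorrected p < 0.05).
#' @export
null_selection_rate <- function(tables) {
  sel <- unlist(lapply(tables, function(t) t$selected))
  mean(sel)
}

#' Meta-stage false discovery rate across null studies
#'
#' Groups the null studies into consecutive blocks of `cohorts_per_meta`,
#' pools each block with [pool_regions()], and reports the fraction of
#' pooled regions with `p_fdr < alpha` (every discovery is false under the
#' null).
#'
#' @param tables List of association tibbles.
#' @param cohorts_per_meta Studies pooled per meta-analysis.
#' @param alpha FDR threshold.
#' @return Fraction of pooled regions declared significant.
#' @export
null_meta_fdr <- function(tables, cohorts_per_meta = 4, alpha = 0.05) {
  n_meta <- length(tables) %/% cohorts_per_meta
  sig <- tot <- 0
  for (m in seq_len(n_meta)) {
    block <- tables[((m - 1) * cohorts_per_meta + 1):(m * cohorts_per_meta)]
    pooled <- pool_regions(block, alpha = alpha)
    tot <- tot + nrow(pooled)
    if (nrow(pooled) > 0) sig <- sig + sum(pooled$p_fdr < alpha)
  }
  if (tot == 0) 0 else sig / tot
}

#' REML confidence-interval coverage of a common effect
#'
#' Generates replicates of `n_cohorts` independent two-group cohorts that
#' share a common true standardized log-odds slope `beta` on one region
#' (the generator's mean shift is chosen so that the population logistic
#' slope per SD of the pooled volume equals `beta`), pools the per-cohort
#' estimates with [reml_meta()], and checks whether the 95% CI covers
#' `beta`. Age and sex effects are switched off in this study so the true
#' slope is available in closed form.
#'
#' @param n_replicates Number of meta-analytic replicates.
#' @param n_cohorts Cohorts per replicate.
#' @param beta Common true standardized log-odds slope.
#' @param n_per_group Subjects per group per cohort.
#' @param seed Base seed.
#' @return Logical vector: CI covered the truth, one per replicate.
#' @export
replicate_reml_coverage <- function(n_replicates = 200, n_cohorts = 4,
                                    beta = -0.5, n_per_group = 100,
                                    seed = 1L) {
  # with equal group sizes and unit within-group SD, the pooled SD is
  # sqrt(1 + delta^2 / 4), and the population slope per pooled SD is
  # delta * sqrt(1 + delta^2 / 4); invert for delta
  f <- function(d) d * sqrt(1 + d^2 / 4) - beta
  delta <- stats::uniroot(f, c(-10, 10))$root
  regions <- c("thalamus", "caudate", "putamen", "hippocampus", "amygdala")
  em <- data.frame(region = "thalamus", group = "A+T-", delta = delta)
  vapply(seq_len(n_replicates), function(r) {
    est <- vapply(seq_len(n_cohorts), function(cc) {
      cfg <- .two_group_config(
        c("control", "A+T-"), c(n_per_group, n_per_group), c(0, 0),
        effect_map = em, seed = seed + (r - 1) * n_cohorts + cc,
        region_names = regions, age_slope = 0, sex_effect = 0)
      prepped <- prepare_cohort(generate_cohort(cfg))
      keep <- !grepl("^vol_", names(prepped)) |
        names(prepped) == "vol_thalamus"
      assoc <- per_region_association(prepped[, keep, drop = FALSE],
                                      c("A_T_MINUS", "CONTROL"),
                                      covariates = character(0))
      c(assoc$beta, assoc$se^2)
    }, numeric(2))
    m <- reml_meta(est[1, ], est[2, ])
    m$ci_low <= beta && beta <= m$ci_high
  }, logical(1))
}

#' Spin-test null calibration
#'
#' Runs independent spin tests in which the indicator map is drawn
#' independently of a synthetic contiguous network partition (so the null
#' holds), and returns one null p-value per run, evaluated at the largest
#' network. The largest network is used because the Dice statistic's
#' granularity scales with network size: on very small networks the
#' statistic has few attainable values, ties with the null are common, and
#' the `>=` counting convention then makes the (still valid) p-values
#' conservative rather than uniform. Under a calibrated test these
#' p-values are approximately uniform.
#'
#' @param n_runs Number of independent runs.
#' @param n_parcels,n_networks Parcellation size.
#' @param n_perm Permutations per run.
#' @param sig_prob Marginal probability a parcel is marked significant.
#' @param seed Base seed.
#' @return Numeric vector of p-values, length `n_runs`.
#' @export
spin_null_calibration <- function(n_runs = 200, n_parcels = 100,
                                  n_networks = 7, n_perm = 199,
                                  sig_prob = 0.2, seed = 1L) {
  parc <- generate_sphere_parcellation(n_parcels, n_networks, seed = seed)
  big <- as.integer(names(which.max(table(parc$network))))
  vapply(seq_len(n_runs), function(r) {
    set.seed(seed + 1000 + r)
    ind <- runif(n_parcels) < sig_prob
    if (!any(ind)) ind[sample.int(n_parcels, 1)] <- TRUE
    res <- spin_null(ind, parc, n_perm = n_perm, seed = seed + 2000 + r)
    res$p_spin[res$network == big]
  }, numeric(1))
}
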
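#' Configuration for the synthetic cohort generator
#'
#' Defines the study conditions the generator emulates: four CSF biomarker
#' groups with group sizes, age distributions (years), within-group block
#' covariance strength of the regional volumes, region-specific mean shifts,
#' and CSF biomarker values consistent with the amyloid (A) and tau (T)
#' cutoffs (Abeta42/40 ratio < 0.082 for A+; p-Tau181 > 41.8 pg/mL for T+).
#'
#' @param n_per_group Named integer vector: subjects per group. Groups are
#'   `control` (A-T-, cognitively unimpaired), `A+T-`, `A+T+` and
#'   `other_dementia` (A-T-, cognitively impaired).
#' @param region_names Ordered character vector of region names.
#' @param block_assignment Named character vector region -> block; defaults
#'   to [region_categories()].
#' @param rho_g Named numeric vector in `[0, 1)`: within-block correlation
#'   per group. Larger values produce more tightly covarying (more
#'   "connected") volume networks.
#' @param effect_map Data frame with columns `region`, `group`, `delta`:
#'   standardized mean shift applied to `region` in `group`.
#' @param age_mean_g,age_sd_g Named numeric vectors: per-group age mean/SD.
#' @param sex_prob Probability that a subject is female.
#' @param sex_effect Standardized male-female volume difference added to
#'   every region (males larger), so that sex adjustment matters.
#' @param icv_mean,icv_sd Intracranial volume distribution (mm^3).
#' @param age_slope Standardized volume change per year of age (applied to
#'   all regions relative to age 65).
#' @param vol_cv Coefficient of variation translating standardized latent
#'   scores into raw volumes.
#' @param qc_fail_prob Probability that a session's mean subcortical QC
#'   falls at or below the 0.65 gate.
#' @param session_prob Named numeric vector: distribution of the number of
#'   imaging sessions per subject (names are counts).
#' @param session_noise SD of multiplicative session-to-session volume noise.
#' @param biomarker_margins Named list with `abr` and `ptau`: half-widths of
#'   the uniform biomarker distributions on the group-appropriate side of
#'   the cutoffs, so generated values sit near the decision boundary.
#' @param thresholds A/T cutoffs, see [at_thresholds()].
#' @param seed Integer seed.
#'
#' @return A list of class `morphocov_generator_config`.
#' @export
generator_config <- function(
    n_per_group = c("control" = 60, "A+T-" = 25, "A+T+" = 121,
                    "other_dementia" = 100),
    region_names = default_region_names(),
    block_assignment = region_categories(region_names),
    rho_g = c("control" = 0.45, "A+T-" = 0.35, "A+T+" = 0.25,
              "other_dementia" = 0.30),
    effect_map = default_effect_map(),
    age_mean_g = c("control" = 63.1, "A+T-" = 74.8, "A+T+" = 69.2,
                   "other_dementia" = 68.9),
    age_sd_g = c("control" = 9.0, "A+T-" = 9.4, "A+T+" = 8.2,
                 "other_dementia" = 7.8),
    sex_prob = 0.431,
    sex_effect = 0.2,
    icv_mean = 1.45e6,
    icv_sd = 1.3e5,
    age_slope = -0.02,
    vol_cv = 0.1,
    qc_fail_prob = 0.05,
    session_prob = c("1" = 0.7, "2" = 0.3),
    session_noise = 0.01,
    biomarker_margins = list(abr = 0.03, ptau = 15),
    thresholds = at_thresholds(),
    seed = 1L) {
  groups <- names(n_per_group)
  stopifnot(length(groups) >= 1, all(n_per_group >= 2))
  if (!all(groups %in% names(rho_g))) {
    stop("rho_g must name every group in n_per_group")
  }
  if (!is.null(effect_map) && nrow(effect_map) > 0 &&
      !all(effect_map$region %in% region_names)) {
    bad <- setdiff(effect_map$region, region_names)
    stop("effect_map names unknown region(s): ", paste(bad, collapse = ", "))
  }
  if (!all(region_names %in% names(block_assignment))) {
    stop("block_assignment must cover every region")
  }
  cfg <- list(
    n_per_group = n_per_group, region_names = region_names,
    block_assignment = block_assignment[region_names], rho_g = rho_g,
    effect_map = effect_map, age_mean_g = age_mean_g, age_sd_g = age_sd_g,
    sex_prob = sex_prob, sex_effect = sex_effect,
    icv_mean = icv_mean, icv_sd = icv_sd, age_slope = age_slope,
    vol_cv = vol_cv, qc_fail_prob = qc_fail_prob,
    session_prob = session_prob, session_noise = session_noise,
    biomarker_margins = biomarker_margins, thresholds = thresholds,
    seed = as.integer(seed)
  )
  class(cfg) <- "morphocov_generator_config"
  cfg
}

#' Default region-specific group mean shifts
#'
#' Amyloid positivity (both A+ groups) shifts subcortical, cerebellar and
#' brain-stem volumes downward; tau in the presence of amyloid (A+T+ only)
#' enlarges extracerebral CSF and shrinks the lateral ventricle. All shifts
#' are standardized (units of within-group SD) and configurable.
#'
#' @return Data frame with columns `region`, `group`, `delta`.
#' @export
default_effect_map <- function() {
  amyloid_regions <- c("thalamus", "amygdala", "ventral DC",
                       "cerebellum cortex", "cerebellum white matter",
                       "brain stem")
  rbind(
    data.frame(region = amyloid_regions, group = "A+T-", delta = -0.6),
    data.frame(region = amyloid_regions, group = "A+T+", delta = -0.6),
    data.frame(region = c("extracerebral CSF", "lateral ventricle"),
               group = "A+T+", delta = c(0.8, -0.6))
  )
}

#' Block-structured covariance for one group
#'
#' `Sigma = rho * B + (1 - rho) * I`, where `B[i, j] = 1` if regions i and j
#' share a block. The family is positive definite for `rho` in `[0, 1)`.
#'
#' @param block Character vector of block labels, one per region.
#' @param rho Within-block correlation strength.
#' @return Covariance matrix.
#' @keywords internal
block_covariance <- function(block, rho) {
  B <- outer(block, block, `==`) * 1
  rho * B + (1 - rho) * diag(length(block))
}

#' Generate a synthetic cohort table
#'
#' Draws group-labelled subjects whose standardized regional volumes follow
#' a group-specific block covariance, applies region/group mean shifts and
#' age, sex and ICV effects, expands subjects into one or more imaging
#' sessions with QC scores, and assigns CSF biomarker values on the correct
#' side of the A/T cutoffs for the subject's group.
#'
#' @param config A [generator_config()].
#' @return A tibble with one row per subject-session: `subject_id`,
#'   `session_id`, `group`, `age`, `sex`, `cognitive_status`, `abr`,
#'   `ptau181`, `icv`, `lp_interval_years`, `vol_<region>` raw volumes
#'   (mm^3) and `qc_<region>` scores in `[0, 1]`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "morphocov_generator_config"))
  set.seed(config$seed)
  regions <- config$region_names
  R <- length(regions)
  base_vol <- .base_volume_for(regions)
  out <- vector("list", length(config$n_per_group))
  sid0 <- 0L
  for (gi in seq_along(config$n_per_group)) {
    g <- names(config$n_per_group)[gi]
    n <- config$n_per_group[[g]]
    Sigma <- block_covariance(unname(config$block_assignment),
                              config$rho_g[[g]])
    ok <- tryCatch({chol(Sigma); TRUE}, error = function(e) FALSE)
    if (!ok) {
      stop("covariance for group '", g, "' is not positive definite ",
           "(rho_g = ", config$rho_g[[g]], ")")
    }
    Z <- MASS::mvrnorm(n, mu = rep(0, R), Sigma = Sigma)
    age <- rnorm(n, config$age_mean_g[[g]], config$age_sd_g[[g]])
    sex <- ifelse(runif(n) < config$sex_prob, "female", "male")
    icv <- pmax(rnorm(n, config$icv_mean, config$icv_sd),
                0.5 * config$icv_mean)
    shift <- matrix(0, n, R)
    em <- config$effect_map
    if (!is.null(em) && nrow(em) > 0) {
      for (k in which(em$group == g)) {
        j <- match(em$region[k], regions)
        shift[, j] <- shift[, j] + em$delta[k]
      }
    }
    shift <- shift + config$age_slope * (age - 65) +
      config$sex_effect * (sex == "male")
    latent <- Z + shift
    # biomarkers near the cutoffs, on the group-appropriate side
    thr <- config$thresholds
    m <- config$biomarker_margins
    a_pos <- g %in% c("A+T-", "A+T+")
    t_pos <- g == "A+T+"
    abr <- if (a_pos) runif(n, thr$abr_cutoff - m$abr, thr$abr_cutoff) else
      runif(n, thr$abr_cutoff, thr$abr_cutoff + m$abr)
    ptau <- if (t_pos) runif(n, thr$ptau_cutoff, thr$ptau_cutoff + m$ptau) else
      runif(n, max(0, thr$ptau_cutoff - m$ptau), thr$ptau_cutoff)
    # A+ is strict (< cutoff), T+ strict (> cutoff): nudge off the boundary
    abr <- ifelse(a_pos & abr >= thr$abr_cutoff, thr$abr_cutoff - 1e-6, abr)
    ptau <- ifelse(t_pos & ptau <= thr$ptau_cutoff,
                   thr$ptau_cutoff + 1e-6, ptau)
    cog <- if (g == "control") "CU" else "CI"
    n_sess <- as.integer(sample(names(config$session_prob), n, replace = TRUE,
                                prob = config$session_prob))
    # subject-level volumes, expanded to sessions with multiplicative noise
    subj_vol <- sweep(1 + config$vol_cv * latent, 2, base_vol, `*`) *
      (icv / config$icv_mean)
    subj_vol <- pmax(subj_vol, matrix(0.05 * base_vol, n, R, byrow = TRUE))
    idx <- rep(seq_len(n), n_sess)
    ns <- length(idx)
    sess_num <- sequence(n_sess)
    sess_vol <- subj_vol[idx, , drop = FALSE] *
      (1 + config$session_noise * matrix(rnorm(ns * R), ns, R))
    fail <- runif(ns) < config$qc_fail_prob
    qc_level <- ifelse(fail, runif(ns, 0.30, 0.63), runif(ns, 0.75, 0.99))
    qc <- pmin(pmax(qc_level + matrix(runif(ns * R, -0.01, 0.01), ns, R),
                    0), 1)
    subj_ids <- sprintf("S%04d", sid0 + seq_len(n))
    sid0 <- sid0 + n
    df <- tibble::tibble(
      subject_id = subj_ids[idx],
      session_id = sprintf("%s_%02d", subj_ids[idx], sess_num),
      group = g, age = age[idx], sex = sex[idx], cognitive_status = cog,
      abr = abr[idx], ptau181 = ptau[idx], icv = icv[idx],
      lp_interval_years = runif(ns, -0.9, 0.9)
    )
    colnames(sess_vol) <- paste0("vol_", regions)
    colnames(qc) <- paste0("qc_", regions)
    out[[gi]] <- dplyr::bind_cols(df, tibble::as_tibble(sess_vol),
                                  tibble::as_tibble(qc))
  }
  dplyr::bind_rows(out)
}

#' Extract the volume matrix from a cohort table
#'
#' @param table Cohort tibble with `vol_<region>` columns.
#' @return Numeric matrix subjects x regions; column names are region names.
#' @export
volume_matrix <- function(table) {
  vcols <- grep("^vol_", names(table), value = TRUE)
  m <- as.matrix(table[, vcols])
  colnames(m) <- sub("^vol_", "", vcols)
  storage.mode(m) <- "double"
  m
}

#' Generate a synthetic spherical parcellation
#'
#' Parcel centroids are placed on a deterministic Fibonacci lattice on the
#' unit sphere (so two calls with the same `n_parcels` share centroids) and
#' partitioned into spatially contiguous networks by nearest-seed
#' assignment, with seed parcels drawn under `seed`.
#'
#' @param n_parcels Number of parcels (`>= n_networks`).
#' @param n_networks Number of network labels (`>= 2`).
#' @param seed Integer seed for the network seed parcels.
#' @return Tibble with columns `parcel_id`, `x`, `y`, `z`, `network`.
#' @export
generate_sphere_parcellation <- function(n_parcels, n_networks, seed = 1L) {
  if (n_networks > n_parcels) stop("n_networks must be <= n_parcels")
  stopifnot(n_networks >= 2)
  xyz <- fibonacci_sphere(n_parcels)
  set.seed(as.integer(seed))
  seeds <- sample.int(n_parcels, n_networks)
  sim <- xyz %*% t(xyz[seeds, , drop = FALSE])
  network <- max.col(sim, ties.method = "first")
  tibble::tibble(parcel_id = sprintf("p%03d", seq_len(n_parcels)),
                 x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                 network = network)
}

#' Fibonacci lattice on the unit sphere
#'
#' @param n Number of points.
#' @return n x 3 matrix of unit vectors.
#' @keywords internal
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- (1 + sqrt(5)) / 2
  theta <- 2 * pi * i / phi
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(theta), y = r * sin(theta), z = z)
}
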
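test_that("generator reproduces its configuration and is seed-deterministic", {
  cfg <- generator_config(
    n_per_group = c("control" = 12, "A+T-" = 8, "A+T+" = 10,
                    "other_dementia" = 6),
    seed = 7L)
  tab <- generate_cohort(cfg)
  tab2 <- generate_cohort(cfg)
  expect_identical(tab, tab2)
  tab3 <- generate_cohort(generator_config(
    n_per_group = cfg$n_per_group, seed = 8L))
  expect_false(identical(tab$age, tab3$age))

  # one row per session; subject counts per group match the config
  subj <- tab[!duplicated(tab$subject_id), ]
  expect_equal(as.vector(table(subj$group)[names(cfg$n_per_group)]),
               unname(cfg$n_per_group))
  expect_true(all(table(tab$subject_id) %in% c(1, 2)))

  # biomarkers fall strictly on the group-appropriate side of the cutoffs
  thr <- cfg$thresholds
  a_pos <- subj$group %in% c("A+T-", "A+T+")
  expect_true(all(subj$abr[a_pos] < thr$abr_cutoff))
  expect_true(all(subj$abr[!a_pos] >= thr$abr_cutoff))
  t_pos <- subj$group == "A+T+"
  expect_true(all(subj$ptau181[t_pos] > thr$ptau_cutoff))
  expect_true(all(subj$ptau181[!t_pos] <= thr$ptau_cutoff))
  expect_equal(unique(subj$cognitive_status[subj$group == "control"]), "CU")
  expect_true(all(subj$cognitive_status[subj$group != "control"] == "CI"))

  # volumes positive, QC in [0, 1], columns complete
  vols <- volume_matrix(tab)
  expect_true(all(vols > 0))
  expect_identical(colnames(vols), cfg$region_names)
  qc <- as.matrix(tab[, grep("^qc_", names(tab))])
  expect_true(all(qc >= 0 & qc <= 1))
})

test_that("block covariance is positive definite and shapes the data", {
  block <- c("a", "a", "a", "b", "b", "c")
  for (rho in c(0, 0.3, 0.8, 0.99)) {
    S <- block_covariance(block, rho)
    expect_true(all(eigen(S, symmetric = TRUE,
                          only.values = TRUE)$values > 0))
    expect_equal(unname(diag(S)), rep(1, 6))
    expect_equal(S[1, 2], rho)
    expect_equal(S[1, 4], 0)
  }

  # higher rho produces visibly stronger within-block empirical correlation
  regions <- default_region_names()
  blocks <- region_categories(regions)
  same_block <- outer(blocks, blocks, `==`) & upper.tri(diag(length(regions)))
  mean_cor <- vapply(c(0.1, 0.6), function(rho) {
    cfg <- generator_config(
      n_per_group = c("control" = 150),
      rho_g = c("control" = rho), effect_map = NULL, seed = 11L,
      session_prob = c("1" = 1), qc_fail_prob = 0)
    r <- partial_correlation_matrix(
      volume_matrix(generate_cohort(cfg)),
      NULL)
    mean(r[same_block])
  }, numeric(1))
  expect_gt(mean_cor[2], mean_cor[1] + 0.2)
})

test_that("effect map shifts the targeted region by about delta SDs", {
  em <- data.frame(region = "thalamus", group = "A+T-", delta = -0.8)
  cfg <- generator_config(
    n_per_group = c("control" = 400, "A+T-" = 400),
    rho_g = c("control" = 0.3, "A+T-" = 0.3),
    age_mean_g = c("control" = 65, "A+T-" = 65),
    age_sd_g = c("control" = 0.01, "A+T-" = 0.01),
    sex_prob = 0, effect_map = em, seed = 3L,
    session_prob = c("1" = 1), qc_fail_prob = 0, session_noise = 0)
  tab <- generate_cohort(cfg)
  # compare standardized volume/ICV ratios between groups
  v <- tab$vol_thalamus / tab$icv
  z <- (v - mean(v)) / sd(v)
  shift <- mean(z[tab$group == "A+T-"]) - mean(z[tab$group == "control"])
  expect_lt(shift, -0.5)
  other <- tab$vol_putamen / tab$icv
  zo <- (other - mean(other)) / sd(other)
  expect_lt(abs(mean(zo[tab$group == "A+T-"]) -
                  mean(zo[tab$group == "control"])), 0.2)
})

test_that("generator configuration is validated", {
  expect_error(generator_config(
    n_per_group = c("control" = 10),
    rho_g = c("other" = 0.3)), "rho_g")
  expect_error(generator_config(
    n_per_group = c("control" = 10),
    effect_map = data.frame(region = "no_such_region",
                            group = "control", delta = 1)),
    "unknown region")
  expect_error(generate_cohort(generator_config(
    n_per_group = c("control" = 10),
    rho_g = c("control" = 1.0))), "positive definite|rho")
})

test_that("spherical parcellation is deterministic, on-sphere, contiguous", {
  parc <- generate_sphere_parcellation(80, 5, seed = 2L)
  parc2 <- generate_sphere_parcellation(80, 5, seed = 2L)
  expect_identical(parc, parc2)
  xyz <- as.matrix(parc[, c("x", "y", "z")])
  expect_equal(unname(sqrt(rowSums(xyz^2))), rep(1, 80), tolerance = 1e-12)
  expect_setequal(unique(parc$network), 1:5)
  # same lattice regardless of seed; only the network labels move
  parc3 <- generate_sphere_parcellation(80, 5, seed = 9L)
  expect_identical(parc$x, parc3$x)
  expect_error(generate_sphere_parcellation(4, 10), "n_networks")
})
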
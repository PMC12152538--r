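test_that("REML estimates match a dense grid and metafor", {
  set.seed(51)
  cases <- list(
    list(y = c(0.2, 0.5, -0.1, 0.4, 0.9), v = c(0.04, 0.09, 0.02, 0.05, 0.1)),
    list(y = rnorm(8, 0.3, 0.5), v = runif(8, 0.01, 0.2)),
    list(y = c(-1, -0.8, -1.2), v = c(0.1, 0.12, 0.08)),
    # homogeneous studies: tau^2 should collapse to (near) zero
    list(y = rep(0.4, 6) + rnorm(6, 0, 0.001), v = rep(0.05, 6)))
  for (cs in cases) {
    m <- reml_meta(cs$y, cs$v)
    # dense-grid maximiser of the restricted likelihood
    t2_grid <- grid_reml_tau2(cs$y, cs$v)
    grid_step <- 10 * max(cs$v) * length(cs$y) / 1e5
    expect_lt(abs(m$tau2 - t2_grid), 2 * grid_step + 1e-6)
    # metafor as an independent implementation
    rf <- metafor::rma(yi = cs$y, vi = cs$v, method = "REML",
                       control = list(tau2.min = 0))
    expect_equal(m$mu, as.numeric(rf$beta), tolerance = 1e-4)
    expect_equal(m$tau2, rf$tau2, tolerance = 1e-3)
    expect_equal(m$se_mu, rf$se, tolerance = 1e-4)
    expect_equal(m$Q, rf$QE, tolerance = 1e-6)
    expect_equal(m$I2, max(0, (m$Q - (m$k - 1)) / m$Q) * 100)
    # CI is Wald-normal around the pooled mean
    expect_equal(m$ci_high - m$ci_low, 2 * 1.96 * m$se_mu)
    # DerSimonian-Laird cross-check: same order of magnitude estimator
    rf_dl <- metafor::rma(yi = cs$y, vi = cs$v, method = "DL")
    expect_equal(dl_tau2(cs$y, cs$v), rf_dl$tau2, tolerance = 1e-8)
  }
  expect_error(reml_meta(c(1, 2), c(0.1, 0)), "positive")
  one <- reml_meta(0.5, 0.04)
  expect_true(one$flagged_k1)
  expect_equal(one$mu, 0.5)
})

test_that("BH adjustment reproduces the hand-computed step-up", {
  set.seed(52)
  for (rep in 1:5) {
    p <- runif(sample(3:40, 1))
    expect_equal(bh_fdr(p), bh_manual(p))
    expect_equal(bh_fdr(p), p.adjust(p, "BH"))
  }
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("region pooling applies the inclusion rule and flags k = 1", {
  mk <- function(regions, beta, se, p) {
    tibble::tibble(region = regions, beta = beta, se = se, p = p)
  }
  s1 <- mk(c("r1", "r2", "r3"), c(-0.5, 0.1, 0.3), c(0.1, 0.2, 0.1),
           c(0.001, 0.6, 0.2))
  s2 <- mk(c("r1", "r2"), c(-0.6, 0.2), c(0.12, 0.2), c(0.002, 0.4))
  s3 <- mk(c("r1", "r4"), c(-0.4, 0.9), c(0.15, 0.3), c(0.01, 0.01))
  out <- pool_regions(list(a = s1, b = s2, c = s3))
  # r1 significant in all, r4 in one study only; r2/r3 never
  expect_setequal(out$region, c("r1", "r4"))
  expect_equal(out$k[out$region == "r1"], 3)
  expect_equal(out$k[out$region == "r4"], 1)
  # pooled r1 agrees with a direct REML call
  direct <- reml_meta(c(-0.5, -0.6, -0.4), c(0.1, 0.12, 0.15)^2)
  expect_equal(out$mu[out$region == "r1"], direct$mu)
  expect_equal(out$p_fdr, bh_manual(out$p))
  empty <- pool_regions(list(a = mk("r1", 0.1, 0.2, 0.9)))
  expect_equal(nrow(empty), 0)
})
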
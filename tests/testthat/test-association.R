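test_that("maximum-likelihood logistic matches glm to high precision", {
  set.seed(41)
  n <- 200
  X <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.4))
  y <- rbinom(n, 1, plogis(-0.5 + 0.8 * X[, 1] - 0.6 * X[, 2]))
  fit <- fit_logistic(y, X, method = "mle")
  ref <- glm(y ~ X, family = binomial())
  expect_equal(unname(fit$coefficients), unname(coef(ref)),
               tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(summary(ref)$coefficients[, 2]),
               tolerance = 1e-5)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-8)
  expect_true(fit$converged)

  # intercept-only model recovers logit of the base rate
  f0 <- fit_logistic(y)
  expect_equal(unname(f0$coefficients), qlogis(mean(y)), tolerance = 1e-8)
  expect_error(fit_logistic(c(0, 1, 2)), "binary")
  expect_error(fit_logistic(y, cbind(X, a2 = X[, "a"])), "rank deficient")
})

test_that("2x2 slopes equal log odds ratios; Firth handles separation", {
  # counts: a = y1x1, b = y1x0, c = y0x1, d = y0x0
  tab_to_data <- function(a, b, c, d) {
    list(y = rep(c(1, 1, 0, 0), c(a, b, c, d)),
         x = rep(c(1, 0, 1, 0), c(a, b, c, d)))
  }
  dd <- tab_to_data(8, 4, 3, 9)
  fit <- fit_logistic(dd$y, cbind(x = dd$x), method = "mle")
  expect_equal(unname(fit$coefficients["x"]), log((8 * 9) / (4 * 3)),
               tolerance = 1e-8)

  # complete separation: MLE refuses with advice, Firth gives the
  # half-cell-corrected closed form
  sep <- tab_to_data(5, 0, 0, 5)
  expect_error(fit_logistic(sep$y, cbind(x = sep$x), method = "mle"),
               "separation")
  ff <- fit_logistic(sep$y, cbind(x = sep$x), method = "firth")
  expect_equal(unname(ff$coefficients["x"]), firth_2x2_slope(5, 0, 0, 5),
               tolerance = 1e-6)
  expect_true(all(is.finite(ff$se)))

  # Firth fit maximises the penalized likelihood (independent optimiser)
  set.seed(42)
  Xf <- cbind(x = rnorm(30))
  yf <- rbinom(30, 1, plogis(Xf[, 1]))
  fit_f <- fit_logistic(yf, Xf, method = "firth")
  pen_ll <- function(beta) {
    eta <- beta[1] + Xf[, 1] * beta[2]
    p <- plogis(eta)
    W <- p * (1 - p)
    Xd <- cbind(1, Xf[, 1])
    sum(yf * eta - log1p(exp(eta))) +
      0.5 * determinant(crossprod(Xd, Xd * W))$modulus
  }
  opt <- optim(c(0, 0), function(b) -pen_ll(b), method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 5000))
  expect_equal(unname(fit_f$coefficients), opt$par, tolerance = 1e-4)
  expect_gte(pen_ll(unname(fit_f$coefficients)), opt$value * -1 - 1e-8)
})

test_that("ridge shrinks slopes but never the intercept", {
  set.seed(43)
  n <- 120
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  y <- rbinom(n, 1, plogis(0.7 + X[, 1]))
  f0 <- fit_logistic(y, X, method = "ridge", lambda = 1e-10)
  fmle <- fit_logistic(y, X, method = "mle")
  expect_equal(f0$coefficients, fmle$coefficients, tolerance = 1e-5)
  norms <- vapply(c(0.1, 1, 10, 100), function(l) {
    sqrt(sum(fit_logistic(y, X, method = "ridge",
                          lambda = l)$coefficients[-1]^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
  # at huge lambda slopes vanish and the intercept recovers the base rate
  fbig <- fit_logistic(y, X, method = "ridge", lambda = 1e8)
  expect_lt(max(abs(fbig$coefficients[-1])), 1e-4)
  expect_equal(unname(fbig$coefficients[1]), qlogis(mean(y)),
               tolerance = 1e-3)
})

test_that("AUROC equals pairwise concordance and bootstrap CI behaves", {
  set.seed(44)
  y <- rbinom(60, 1, 0.4)
  y[1:2] <- c(0, 1)
  s <- rnorm(60) + y
  expect_equal(auroc(y, s), concordance_auroc(y, s), tolerance = 1e-12)
  # ties get half credit
  expect_equal(auroc(c(0, 1), c(1, 1)), 0.5)
  expect_equal(auroc(c(0, 0, 1, 1), c(1, 2, 3, 4)), 1)
  expect_error(auroc(c(0, 0), c(1, 2)), "both classes")
  ci <- auroc_boot_ci(y, s, n_bootstrap = 500)
  expect_true(ci["low"] <= auroc(y, s) && auroc(y, s) <= ci["high"])
  expect_true(ci["low"] >= 0 && ci["high"] <= 1)
})

test_that("per-region association finds an injected effect with the right sign", {
  em <- data.frame(region = "hippocampus", group = "A+T-", delta = -1.2)
  cfg <- generator_config(
    n_per_group = c("control" = 120, "A+T-" = 120),
    rho_g = c("control" = 0.2, "A+T-" = 0.2),
    effect_map = em, seed = 45L)
  prepped <- prepare_cohort(generate_cohort(cfg))
  assoc <- per_region_association(prepped, c("A_T_MINUS", "CONTROL"))
  hit <- assoc[assoc$region == "hippocampus", ]
  expect_lt(hit$beta, 0)
  expect_true(hit$selected)
  expect_equal(hit$odds_ratio, exp(hit$beta))
  # selection flag is exactly p < alpha
  expect_equal(assoc$selected, assoc$p < 0.05)
  expect_error(per_region_association(prepped[1:5, ],
                                      c("A_T_MINUS", "CONTROL")),
               "subjects")
})

test_that("classifier training selects lambda from the grid and evaluates honestly", {
  em <- data.frame(region = c("thalamus", "amygdala"), group = "A+T+",
                   delta = c(-1.5, -1.2))
  cfg <- generator_config(
    n_per_group = c("control" = 80, "A+T+" = 80),
    rho_g = c("control" = 0.3, "A+T+" = 0.3),
    effect_map = em, seed = 46L)
  prepped <- prepare_cohort(generate_cohort(cfg))
  cvc <- cv_config(lambda_grid = seq(0.01, 0.05, by = 0.01),
                   n_bootstrap = 200, seed = 9L)
  rep1 <- train_and_evaluate(prepped, c("thalamus", "amygdala"),
                             c("A_T_PLUS", "CONTROL"),
                             classifier = "ridge", cvconfig = cvc)
  expect_true(rep1$lambda %in% cvc$lambda_grid)
  expect_gt(rep1$auroc, 0.7)
  expect_true(rep1$auroc_ci["low"] <= rep1$auroc &&
                rep1$auroc <= rep1$auroc_ci["high"])
  expect_equal(max(rep1$feature_importance), 1)
  expect_equal(rep1$n_train + rep1$n_test, nrow(prepped))
  expect_true(rep1$sensitivity >= 0 && rep1$sensitivity <= 1)
  # identical seeds reproduce the report exactly
  rep2 <- train_and_evaluate(prepped, c("thalamus", "amygdala"),
                             c("A_T_PLUS", "CONTROL"),
                             classifier = "ridge", cvconfig = cvc)
  expect_identical(rep1$auroc, rep2$auroc)
  expect_identical(rep1$lambda, rep2$lambda)
})
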
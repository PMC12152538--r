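#' Random-effects meta-analysis with REML between-study variance
#'
#' Pools study effects `y_i` with sampling variances `v_i` under the
#' random-effects model `y_i ~ N(mu, v_i + tau^2)`. `tau^2` maximises the
#' restricted log-likelihood
#' `-1/2 sum log(v_i + tau^2) - 1/2 log(sum w_i) - 1/2 sum w_i (y_i - mu)^2`
#' with `w_i = 1/(v_i + tau^2)` and `mu = sum w_i y_i / sum w_i`, by bounded
#' one-dimensional optimisation; if the optimum touches the upper bound the
#' bound is doubled and the search retried (at most 3 times, with a
#' warning). Inference on the pooled effect is Wald-normal. `Q` and `I^2`
#' are the usual fixed-effect heterogeneity statistics.
#'
#' @param y Study effect estimates (e.g. log-odds).
#' @param v Squared standard errors, all positive.
#' @param tol Convergence tolerance on tau^2.
#' @return List of class `morphocov_meta`: `k`, `mu`, `se_mu`, `tau2`, `Q`,
#'   `I2` (percent), `ci_low`, `ci_high`, `z`, `p`.
#' @export
reml_meta <- function(y, v, tol = 1e-10) {
  if (any(v <= 0)) stop("all sampling variances must be positive")
  k <- length(y)
  stopifnot(length(v) == k, k >= 1)
  if (k == 1) {
    se <- sqrt(v)
    return(structure(list(k = 1L, mu = y, se_mu = se, tau2 = 0, Q = 0,
                          I2 = 0, ci_low = y - 1.96 * se,
                          ci_high = y + 1.96 * se, z = y / se,
                          p = 2 * pnorm(-abs(y / se)), flagged_k1 = TRUE),
                     class = "morphocov_meta"))
  }
  nll <- function(tau2) -reml_loglik(y, v, tau2)
  upper <- 10 * max(v) * k
  tau2 <- 0
  for (try in 1:3) {
    opt <- optimize(nll, c(0, upper), tol = tol)
    tau2 <- opt$minimum
    if (tau2 < upper * 0.99) break
    warning("REML optimiser at the tau^2 bound; doubling and retrying")
    upper <- upper * 2
  }
  # boundary check: tau2 = 0 may beat the interior optimum
  if (nll(0) <= opt$objective) tau2 <- 0
  w <- 1 / (v + tau2)
  mu <- sum(w * y) / sum(w)
  se_mu <- sqrt(1 / sum(w))
  wf <- 1 / v
  muf <- sum(wf * y) / sum(wf)
  Q <- sum(wf * (y - muf)^2)
  I2 <- if (Q > 0) max(0, (Q - (k - 1)) / Q) * 100 else 0
  z <- mu / se_mu
  structure(list(k = k, mu = mu, se_mu = se_mu, tau2 = tau2, Q = Q,
                 I2 = I2, ci_low = mu - 1.96 * se_mu,
                 ci_high = mu + 1.96 * se_mu, z = z,
                 p = 2 * pnorm(-abs(z)), flagged_k1 = FALSE),
            class = "morphocov_meta")
}

#' Restricted log-likelihood of the random-effects model
#'
#' @param y,v Effects and sampling variances.
#' @param tau2 Between-study variance.
#' @return Restricted log-likelihood (up to an additive constant).
#' @export
reml_loglik <- function(y, v, tau2) {
  w <- 1 / (v + tau2)
  mu <- sum(w * y) / sum(w)
  -0.5 * sum(log(v + tau2)) - 0.5 * log(sum(w)) -
    0.5 * sum(w * (y - mu)^2)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values `min_{j >= i} (m * p_(j) / j)`, clipped at 1.
#'
#' @param pvalues Numeric vector in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
bh_fdr <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Pool per-study region associations across cohorts
#'
#' Regions significantly associated (uncorrected p below `alpha`) in at
#' least one study are pooled by [reml_meta()]; regions meeting the
#' inclusion rule but present in fewer than 2 studies pass through as
#' k = 1 with a flag. Benjamini-Hochberg adjustment is applied across the
#' included regions' pooled p-values.
#'
#' @param studies Named list of per-study association tibbles (from
#'   [per_region_association()]: columns `region`, `beta`, `se`, `p`).
#' @param alpha Per-study inclusion threshold.
#' @return Tibble: `region`, `k`, `mu`, `se_mu`, `tau2`, `Q`, `I2`,
#'   `ci_low`, `ci_high`, `z`, `p`, `p_fdr`.
#' @export
pool_regions <- function(studies, alpha = 0.05) {
  stopifnot(length(studies) >= 1)
  all_regions <- unique(unlist(lapply(studies, function(s) s$region)))
  include <- vapply(all_regions, function(rg) {
    any(vapply(studies, function(s) {
      any(s$region == rg & s$p < alpha)
    }, logical(1)))
  }, logical(1))
  regions <- all_regions[include]
  rows <- lapply(regions, function(rg) {
    ys <- vs <- numeric(0)
    for (s in studies) {
      hit <- s[s$region == rg, , drop = FALSE]
      if (nrow(hit) == 1) {
        ys <- c(ys, hit$beta)
        vs <- c(vs, hit$se^2)
      }
    }
    m <- reml_meta(ys, vs)
    tibble::tibble(region = rg, k = m$k, mu = m$mu, se_mu = m$se_mu,
                   tau2 = m$tau2, Q = m$Q, I2 = m$I2, ci_low = m$ci_low,
                   ci_high = m$ci_high, z = m$z, p = m$p)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) > 0) out$p_fdr <- bh_fdr(out$p)
  out
}
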
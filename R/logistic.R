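# numerically stable log(1 + exp(x))
.log1pexp <- function(x) {
  ifelse(x > 0, x + log1p(exp(-x)), log1p(exp(x)))
}

#' Logistic regression by Newton iteration: MLE, Firth or ridge
#'
#' Maximum likelihood is fit by iteratively reweighted least squares;
#' Firth's bias-reduced variant adds the Jeffreys-prior penalty, replacing
#' the score with `U*_j = sum_i (y_i - p_i + h_i (1/2 - p_i)) x_ij`, where
#' `h_i` is the hat diagonal of `W^{1/2} X (X'WX)^{-1} X' W^{1/2}` — this
#' keeps estimates finite under complete separation; ridge maximises the
#' penalized log-likelihood `l - lambda * ||beta_{-intercept}||^2 / 2`.
#' Wald standard errors and two-sided p-values come from the (penalized)
#' information matrix at convergence.
#'
#' @param y Binary outcome (0/1 or logical).
#' @param X Predictor matrix (subjects x p), or NULL for intercept-only. An
#'   intercept column is added internally and never penalized.
#' @param method `"mle"`, `"firth"` or `"ridge"`.
#' @param lambda Ridge penalty (ignored otherwise).
#' @param max_iter Maximum Newton iterations.
#' @param tol Convergence tolerance on the max absolute score.
#' @return List of class `morphocov_logistic`: `coefficients`, `se`, `z`,
#'   `p`, `vcov`, `loglik`, `converged`, `iterations`, `method`, `lambda`.
#' @export
fit_logistic <- function(y, X = NULL, method = c("mle", "firth", "ridge"),
                         lambda = 0, max_iter = 100, tol = 1e-8) {
  method <- match.arg(method)
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  n <- length(y)
  Xd <- if (is.null(X)) matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  else {
    X <- as.matrix(X)
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    cbind("(Intercept)" = 1, X)
  }
  p_dim <- ncol(Xd)
  if (method %in% c("mle", "firth") && qr(Xd)$rank < p_dim) {
    stop("design matrix is rank deficient")
  }
  D <- diag(c(0, rep(1, p_dim - 1))[seq_len(p_dim)], p_dim)
  obj <- function(beta) {
    eta <- drop(Xd %*% beta)
    ll <- sum(y * eta - .log1pexp(eta))
    pv <- plogis(eta)
    w <- pv * (1 - pv)
    info <- crossprod(Xd, Xd * w)
    switch(method,
           mle = ll,
           firth = ll + 0.5 * determinant(info)$modulus,
           ridge = ll - lambda * sum((D %*% beta) * beta) / 2)
  }
  beta <- rep(0, p_dim)
  f_old <- obj(beta)
  converged <- FALSE
  trace_norm <- numeric(0)
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    eta <- drop(Xd %*% beta)
    pv <- plogis(eta)
    w <- pmax(pv * (1 - pv), 1e-12)
    info <- crossprod(Xd, Xd * w)
    score <- switch(method,
      mle = crossprod(Xd, y - pv),
      firth = {
        XW <- Xd * sqrt(w)
        h <- rowSums((XW %*% solve(info)) * XW)
        crossprod(Xd, y - pv + h * (0.5 - pv))
      },
      ridge = crossprod(Xd, y - pv) - lambda * (D %*% beta)
    )
    info_pen <- if (method == "ridge") info + lambda * D else info
    trace_norm <- c(trace_norm, max(abs(score)))
    if (max(abs(score)) < tol) { converged <- TRUE; break }
    step <- drop(solve(info_pen, score))
    # step-halving so the (penalized) objective never decreases
    alpha <- 1
    repeat {
      cand <- beta + alpha * step
      f_new <- obj(cand)
      if (is.finite(f_new) && f_new >= f_old - 1e-12) break
      alpha <- alpha / 2
      if (alpha < 1e-10) break
    }
    beta <- beta + alpha * step
    f_old <- obj(beta)
  }
  if (!converged) {
    if (method == "mle" && max(abs(beta)) > 15) {
      stop("mle did not converge; diverging coefficients suggest complete ",
           "separation - consider method = 'firth'. |score| trace: ",
           paste(signif(utils::tail(trace_norm, 5), 3), collapse = ", "))
    }
    stop("logistic fit did not converge in ", max_iter,
         " iterations; |score| trace: ",
         paste(signif(utils::tail(trace_norm, 5), 3), collapse = ", "))
  }
  eta <- drop(Xd %*% beta)
  pv <- plogis(eta)
  if (method == "mle" && any(y == 1) && any(y == 0) &&
      all(pv[y == 1] > 1 - 1e-8) && all(pv[y == 0] < 1e-8)) {
    stop("complete separation detected (all fitted probabilities are ",
         "0 or 1); the MLE is not identified - consider method = 'firth'")
  }
  w <- pmax(pv * (1 - pv), 1e-12)
  info <- crossprod(Xd, Xd * w)
  if (method == "ridge") info <- info + lambda * D
  vc <- solve(info)
  se <- sqrt(diag(vc))
  z <- beta / se
  structure(list(
    coefficients = setNames(drop(beta), colnames(Xd)),
    se = setNames(se, colnames(Xd)), z = setNames(z, colnames(Xd)),
    p = setNames(2 * pnorm(-abs(z)), colnames(Xd)),
    vcov = vc, loglik = sum(y * eta - .log1pexp(eta)),
    converged = converged, iterations = it, method = method, lambda = lambda
  ), class = "morphocov_logistic")
}

#' Predict class-1 probabilities from a fitted logistic model
#'
#' @param object A `morphocov_logistic` fit.
#' @param newdata Predictor matrix with the same columns the model was fit
#'   on (no intercept column).
#' @param ... Unused.
#' @return Numeric vector of probabilities.
#' @export
predict.morphocov_logistic <- function(object, newdata = NULL, ...) {
  b <- object$coefficients
  if (is.null(newdata)) stop("newdata required")
  Xd <- cbind(1, as.matrix(newdata))
  drop(plogis(Xd %*% b))
}

#' Area under the ROC curve (rank statistic)
#'
#' Mann-Whitney formulation: the probability that a random positive scores
#' above a random negative, with ties receiving half credit.
#'
#' @param y Binary outcome.
#' @param scores Predicted scores.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(y, scores) {
  y <- as.numeric(y)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes required")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Percentile bootstrap confidence interval for the AUROC
#'
#' Stratified resampling: positives and negatives are resampled separately
#' with replacement so every bootstrap sample keeps both classes.
#'
#' @param y Binary outcome.
#' @param scores Predicted scores.
#' @param n_bootstrap Number of bootstrap samples.
#' @param level Confidence level.
#' @return Named vector `c(low, high)`.
#' @export
auroc_boot_ci <- function(y, scores, n_bootstrap = 2000, level = 0.95) {
  y <- as.numeric(y)
  pos <- which(y == 1)
  neg <- which(y == 0)
  stats <- vapply(seq_len(n_bootstrap), function(b) {
    idx <- c(sample(pos, replace = TRUE), sample(neg, replace = TRUE))
    auroc(y[idx], scores[idx])
  }, numeric(1))
  a <- (1 - level) / 2
  setNames(unname(quantile(stats, c(a, 1 - a), type = 7)), c("low", "high"))
}
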
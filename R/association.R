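#' Per-region logistic association with a biomarker group contrast
#'
#' One logistic fit per region: outcome is membership in `contrast[1]`
#' (versus `contrast[2]`), predictor the standardized ICV-adjusted volume
#' plus the covariates. Regions with uncorrected p < 0.05 are flagged as
#' selected features.
#'
#' @param cohort Subject-level tibble with `vol_<region>` columns and the
#'   covariates.
#' @param contrast Length-2 character vector `(group_pos, group_ref)`.
#' @param covariates Covariate column names; `sex` is coded female = 0,
#'   male = 1.
#' @param group_col Group column name.
#' @param method Passed to [fit_logistic()] (default `"mle"`, i.e. plain
#'   logistic regression).
#' @param alpha Selection threshold on the uncorrected p-value.
#' @return Tibble: `region`, `beta` (log-odds per SD of volume), `se`, `p`,
#'   `odds_ratio`, `selected`.
#' @export
per_region_association <- function(cohort, contrast,
                                   covariates = c("age", "sex"),
                                   group_col = "at_group", method = "mle",
                                   alpha = 0.05) {
  stopifnot(length(contrast) == 2)
  sub <- cohort[cohort[[group_col]] %in% contrast, , drop = FALSE]
  y <- as.numeric(sub[[group_col]] == contrast[1])
  q <- length(covariates)
  if (sum(y == 1) < q + 2 || sum(y == 0) < q + 2) {
    stop("each contrast group needs at least q + 2 subjects")
  }
  covs <- .covariate_matrix(sub, covariates)
  vols <- volume_matrix(sub)
  sds <- apply(vols, 2, sd)
  if (any(sds == 0)) {
    stop("zero-variance region(s): ",
         paste(colnames(vols)[sds == 0], collapse = ", "))
  }
  vols <- scale(vols)
  rows <- lapply(colnames(vols), function(rg) {
    X <- cbind(volume = vols[, rg], covs)
    fit <- fit_logistic(y, X, method = method)
    tibble::tibble(region = rg, beta = fit$coefficients[["volume"]],
                   se = fit$se[["volume"]], p = fit$p[["volume"]])
  })
  out <- dplyr::bind_rows(rows)
  out$odds_ratio <- exp(out$beta)
  out$selected <- out$p < alpha
  out
}

.covariate_matrix <- function(table, covariates) {
  if (length(covariates) == 0) return(NULL)
  m <- sapply(covariates, function(cv) {
    v <- table[[cv]]
    if (cv == "sex" || is.character(v) || is.factor(v)) {
      as.numeric(as.character(v) == "male")
    } else as.numeric(v)
  })
  m <- as.matrix(m)
  colnames(m) <- covariates
  m
}

#' Cross-validation configuration for the classifier stage
#'
#' @param train_fraction Fraction of subjects in the training split.
#' @param folds,repeats Repeated stratified k-fold CV design used for
#'   lambda selection.
#' @param lambda_grid Ridge penalty grid.
#' @param decision_threshold Probability cutoff for accuracy, sensitivity
#'   and specificity.
#' @param firth_max_iter Iteration cap for Firth fits.
#' @param n_bootstrap Bootstrap samples for the AUROC confidence interval.
#' @param balance Up-sample the minority class (with replacement) inside
#'   training folds and the final training set.
#' @param seed Integer seed for the split, folds, resampling and bootstrap.
#' @return List of class `morphocov_cv_config`.
#' @export
cv_config <- function(train_fraction = 0.75, folds = 3, repeats = 3,
                      lambda_grid = seq(0.001, 0.1, by = 0.001),
                      decision_threshold = 0.5, firth_max_iter = 100,
                      n_bootstrap = 2000, balance = TRUE, seed = 1L) {
  stopifnot(folds >= 2, all(lambda_grid > 0),
            !is.unsorted(lambda_grid, strictly = TRUE))
  structure(list(train_fraction = train_fraction, folds = folds,
                 repeats = repeats, lambda_grid = lambda_grid,
                 decision_threshold = decision_threshold,
                 firth_max_iter = firth_max_iter,
                 n_bootstrap = n_bootstrap, balance = balance,
                 seed = as.integer(seed)),
            class = "morphocov_cv_config")
}

.upsample <- function(idx, y) {
  tab <- table(y[idx])
  if (length(tab) < 2 || tab[1] == tab[2]) return(idx)
  minority <- names(tab)[which.min(tab)]
  min_idx <- idx[y[idx] == minority]
  extra <- sample(min_idx, max(tab) - min(tab), replace = TRUE)
  c(idx, extra)
}

.stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Train a volume-based biomarker status classifier and evaluate it
#'
#' Implements the evaluation design of the modelling stage: a seeded
#' stratified 75/25 train/test split; features standardized using training
#' statistics; for ridge, the penalty chosen to maximise mean accuracy (at
#' the decision threshold) over repeated stratified k-fold CV on the
#' training set, ties resolved toward the largest penalty; optional
#' minority up-sampling inside training folds only; a final refit on the
#' full training set; held-out AUROC with a stratified percentile bootstrap
#' confidence interval, plus sensitivity and specificity at the threshold;
#' feature importance as absolute standardized coefficients scaled to a
#' maximum of 1.
#'
#' @param cohort Subject-level tibble with `vol_<region>` columns.
#' @param selected_regions Regions used as features (e.g. the `selected`
#'   regions from [per_region_association()]).
#' @param contrast Length-2 character vector `(group_pos, group_ref)`.
#' @param classifier `"ridge"`, `"firth"` or `"mle"`.
#' @param cvconfig A [cv_config()].
#' @param group_col Group column name.
#' @return List of class `morphocov_model_report`: `classifier`, `lambda`,
#'   `cv_accuracy`, `auroc`, `auroc_ci`, `sensitivity`, `specificity`,
#'   `feature_importance`, `n_train`, `n_test`.
#' @export
train_and_evaluate <- function(cohort, selected_regions, contrast,
                               classifier = c("ridge", "firth", "mle"),
                               cvconfig = cv_config(),
                               group_col = "at_group") {
  classifier <- match.arg(classifier)
  sub <- cohort[cohort[[group_col]] %in% contrast, , drop = FALSE]
  y <- as.numeric(sub[[group_col]] == contrast[1])
  vols <- volume_matrix(sub)[, selected_regions, drop = FALSE]
  set.seed(cvconfig$seed)
  # stratified train/test split
  train_idx <- unlist(lapply(c(0, 1), function(cl) {
    idx <- which(y == cl)
    sample(idx, round(cvconfig$train_fraction * length(idx)))
  }))
  test_idx <- setdiff(seq_along(y), train_idx)
  if (length(unique(y[test_idx])) < 2 || length(unique(y[train_idx])) < 2) {
    stop("a class is empty after the split; use a different seed or ",
         "stratification")
  }
  ctr <- colMeans(vols[train_idx, , drop = FALSE])
  scl <- apply(vols[train_idx, , drop = FALSE], 2, sd)
  if (any(scl == 0)) stop("zero-variance feature in the training set")
  Xtr <- scale(vols[train_idx, , drop = FALSE], center = ctr, scale = scl)
  Xte <- scale(vols[test_idx, , drop = FALSE], center = ctr, scale = scl)
  ytr <- y[train_idx]
  yte <- y[test_idx]
  fit_one <- function(yy, XX, lambda) {
    switch(classifier,
           ridge = fit_logistic(yy, XX, method = "ridge", lambda = lambda),
           firth = fit_logistic(yy, XX, method = "firth",
                                max_iter = cvconfig$firth_max_iter),
           mle = fit_logistic(yy, XX, method = "mle"))
  }
  lambda <- NA_real_
  cv_acc <- NA_real_
  if (classifier == "ridge") {
    acc <- matrix(NA_real_, length(cvconfig$lambda_grid),
                  cvconfig$repeats * cvconfig$folds)
    col <- 0
    for (rep_i in seq_len(cvconfig$repeats)) {
      fold <- .stratified_folds(ytr, cvconfig$folds)
      for (f in seq_len(cvconfig$folds)) {
        col <- col + 1
        fit_idx <- which(fold != f)
        if (cvconfig$balance) fit_idx <- .upsample(fit_idx, ytr)
        hold <- which(fold == f)
        for (li in seq_along(cvconfig$lambda_grid)) {
          m <- fit_one(ytr[fit_idx], Xtr[fit_idx, , drop = FALSE],
                       cvconfig$lambda_grid[li])
          pr <- predict(m, Xtr[hold, , drop = FALSE])
          acc[li, col] <-
            mean((pr >= cvconfig$decision_threshold) == ytr[hold])
        }
      }
    }
    mean_acc <- rowMeans(acc)
    # ties toward the largest (most regularised) lambda
    best <- max(which(mean_acc >= max(mean_acc) - 1e-12))
    lambda <- cvconfig$lambda_grid[best]
    cv_acc <- mean_acc[best]
  }
  final_idx <- seq_along(ytr)
  if (cvconfig$balance) final_idx <- .upsample(final_idx, ytr)
  model <- fit_one(ytr[final_idx], Xtr[final_idx, , drop = FALSE], lambda)
  pr_te <- predict(model, Xte)
  pred_cls <- as.numeric(pr_te >= cvconfig$decision_threshold)
  ci <- auroc_boot_ci(yte, pr_te, n_bootstrap = cvconfig$n_bootstrap)
  coefs <- abs(model$coefficients[-1])
  importance <- if (max(coefs) > 0) coefs / max(coefs) else coefs
  structure(list(
    classifier = classifier, lambda = lambda, cv_accuracy = cv_acc,
    auroc = auroc(yte, pr_te), auroc_ci = ci,
    sensitivity = mean(pred_cls[yte == 1] == 1),
    specificity = mean(pred_cls[yte == 0] == 0),
    feature_importance = sort(importance, decreasing = TRUE),
    coefficients = model$coefficients,
    n_train = length(ytr), n_test = length(yte)
  ), class = "morphocov_model_report")
}
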
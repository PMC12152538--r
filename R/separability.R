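#' Low-dimensional embedding of standardized volumes
#'
#' Deterministic front-ends for the separability statistic: `pca2d` takes
#' the first two principal components; `mds2d` classical multidimensional
#' scaling of Euclidean distances to two dimensions; `external` passes
#' through precomputed coordinates. Features are standardized (mean 0,
#' SD 1 per region) before embedding.
#'
#' @param volumes Subjects x regions matrix.
#' @param method `"pca2d"`, `"mds2d"` or `"external"`.
#' @param coords For `method = "external"`: an n x 2 coordinate matrix.
#' @param seed Unused by the deterministic methods; kept so stochastic
#'   embeddings can be slotted in.
#' @return n x 2 coordinate matrix.
#' @export
embed_volumes <- function(volumes, method = c("pca2d", "mds2d", "external"),
                          coords = NULL, seed = NULL) {
  method <- match.arg(method)
  if (method == "external") {
    coords <- as.matrix(coords)
    if (ncol(coords) < 2) stop("external coordinates must have >= 2 columns")
    return(coords[, 1:2, drop = FALSE])
  }
  X <- scale(as.matrix(volumes))
  X[is.nan(X)] <- 0
  if (method == "pca2d") {
    if (qr(X)$rank < 2) stop("input rank < 2; pca2d undefined")
    pc <- prcomp(X, center = FALSE, scale. = FALSE)
    return(pc$x[, 1:2, drop = FALSE])
  }
  cmdscale(dist(X), k = 2)
}

#' Standardized global clustering coefficient (SGCC)
#'
#' Cluster-separability of a labelled point cloud:
#' `(d_between - d_within) / max(d_between, d_within)`, where `d_within` is
#' the mean Euclidean distance over all same-label pairs (pooled across
#' labels) and `d_between` the mean over all cross-label pairs. Ranges over
#' `[-1, 1]`: 1 means tight, well-separated clusters; 0 ambiguous
#' clustering; negative values mean points sit closer to other labels than
#' to their own. A fully degenerate cloud (both means zero) returns 0.
#'
#' @param points n x d coordinate matrix.
#' @param labels Vector of category labels, length n, at least 2 distinct.
#' @return List of class `morphocov_sgcc`: `d_between`, `d_within`, `sgcc`,
#'   `n`, `n_labels`.
#' @export
sgcc <- function(points, labels) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 2) stop("need at least 2 points")
  if (length(labels) != n) stop("labels must match points")
  if (!all(is.finite(points))) stop("coordinates must be finite")
  if (length(unique(labels)) < 2) stop("SGCC undefined for one category")
  D <- as.matrix(dist(points))
  same <- outer(labels, labels, `==`)
  ut <- upper.tri(D)
  w_pairs <- D[same & ut]
  b_pairs <- D[!same & ut]
  d_within <- if (length(w_pairs)) mean(w_pairs) else 0
  d_between <- mean(b_pairs)
  denom <- max(d_between, d_within)
  s <- if (denom == 0) 0 else (d_between - d_within) / denom
  structure(list(d_between = d_between, d_within = d_within, sgcc = s,
                 n = n, n_labels = length(unique(labels))),
            class = "morphocov_sgcc")
}

#' SGCC per stratum (e.g. per sex, per region subset)
#'
#' Embedding and SGCC are computed independently within each stratum; a
#' stratum failing the SGCC preconditions (fewer than 2 labels, fewer than
#' 2 points) yields a row with missing values and a warning, and the run
#' continues.
#'
#' @param volumes Subjects x regions matrix.
#' @param labels Category labels (length = subjects).
#' @param strata Stratum assignment (length = subjects), or NULL for a
#'   single stratum.
#' @param method Embedding method, see [embed_volumes()].
#' @param seed Passed to [embed_volumes()].
#' @return Tibble: `stratum`, `n`, `d_between`, `d_within`, `sgcc`.
#' @export
sgcc_by_stratum <- function(volumes, labels, strata = NULL,
                            method = "pca2d", seed = NULL) {
  volumes <- as.matrix(volumes)
  if (is.null(strata)) strata <- rep("all", nrow(volumes))
  out <- lapply(unique(strata), function(s) {
    idx <- strata == s
    res <- tryCatch({
      pts <- embed_volumes(volumes[idx, , drop = FALSE], method = method,
                           seed = seed)
      sgcc(pts, labels[idx])
    }, error = function(e) {
      warning("stratum '", s, "' skipped: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) {
      tibble::tibble(stratum = as.character(s), n = sum(idx),
                     d_between = NA_real_, d_within = NA_real_,
                     sgcc = NA_real_)
    } else {
      tibble::tibble(stratum = as.character(s), n = sum(idx),
                     d_between = res$d_between, d_within = res$d_within,
                     sgcc = res$sgcc)
    }
  })
  dplyr::bind_rows(out)
}
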
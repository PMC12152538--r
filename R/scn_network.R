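#' Covariate-adjusted partial Pearson correlation matrix
#'
#' Each region is regressed (OLS, with intercept) on the covariates; the
#' partial correlation of two regions is the Pearson correlation of their
#' residuals. With no covariates this reduces to the plain correlation
#' matrix.
#'
#' @param volumes Numeric matrix, subjects x regions (named columns).
#' @param covariates Numeric matrix or data frame, subjects x q (factors
#'   must be pre-coded numerically, e.g. sex as 0/1), or NULL.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
partial_correlation_matrix <- function(volumes, covariates = NULL) {
  volumes <- as.matrix(volumes)
  n <- nrow(volumes)
  q <- if (is.null(covariates)) 0 else ncol(as.matrix(covariates))
  if (n <= q + 2) stop("insufficient degrees of freedom (n <= q + 2)")
  sds <- apply(volumes, 2, sd)
  if (any(sds == 0)) {
    stop("constant region column(s): ",
         paste(colnames(volumes)[sds == 0], collapse = ", "))
  }
  if (q == 0) {
    res <- scale(volumes, scale = FALSE)
  } else {
    X <- cbind(1, as.matrix(covariates))
    res <- volumes - X %*% qr.coef(qr(X), volumes)
  }
  r <- cor(res)
  (r + t(r)) / 2
}

#' Fisher z-transform of a correlation coefficient
#'
#' `z = atanh(r)`, with |r| clipped to `1 - 1e-15` so that perfect
#' correlations map to a large finite value. Odd function of r.
#'
#' @param r Correlations in `[-1, 1]` (vector or matrix).
#' @return Same shape as `r`.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-9, na.rm = TRUE)) stop("|r| exceeds 1")
  atanh(sign(r) * pmin(abs(r), 1 - 1e-15))
}

#' Build a group structural covariance network
#'
#' Partial correlations adjusted for the covariates, Fisher z-transformed,
#' diagonal zeroed, then proportionally thresholded.
#'
#' @param volumes Subjects x regions matrix of (ICV-adjusted) volumes.
#' @param covariates Covariate matrix (default age + sex expected upstream).
#' @param proportion Fraction of strongest connections retained.
#' @param ... Passed to [threshold_proportional()].
#' @return A `morphocov_network` (see [threshold_proportional()]).
#' @export
build_scn <- function(volumes, covariates = NULL, proportion = 0.35, ...) {
  r <- partial_correlation_matrix(volumes, covariates)
  Z <- fisher_z(r)
  diag(Z) <- 0
  net <- threshold_proportional(Z, proportion, ...)
  net$covariates_used <- colnames(as.data.frame(covariates))
  net
}

#' Proportional thresholding of a weighted adjacency matrix
#'
#' Keeps the `k = round(p * N * (N - 1) / 2)` largest upper-triangle weights
#' (signed descending by default; ties broken by row-major first
#' occurrence), zeroes the rest and mirrors to symmetry. Connectivity of the
#' result is checked: if disconnected, either an error is raised or the
#' network is augmented with maximum-spanning-tree edges of the full matrix
#' (flagged in the result).
#'
#' @param Z Symmetric weight matrix with zero diagonal.
#' @param proportion Fraction of possible edges retained, in `(0, 1]`.
#' @param rank_by `"signed"` (default) or `"absolute"` edge strength.
#' @param disconnected `"augment"` (default) or `"error"`.
#' @return List of class `morphocov_network`: `W` (thresholded matrix),
#'   `regions`, `proportion`, `n_edges`, `augmented` (logical),
#'   `augment_edges` (count added, if any).
#' @export
threshold_proportional <- function(Z, proportion,
                                   rank_by = c("signed", "absolute"),
                                   disconnected = c("augment", "error")) {
  rank_by <- match.arg(rank_by)
  disconnected <- match.arg(disconnected)
  if (proportion <= 0 || proportion > 1) stop("proportion must be in (0, 1]")
  Z <- as.matrix(Z)
  N <- nrow(Z)
  if (max(abs(Z - t(Z))) > 1e-8) stop("Z must be symmetric")
  ut <- which(upper.tri(Z))
  # row-major (by row, then column) order for deterministic tie-breaking
  rm_order <- order(row(Z)[ut] * N + col(Z)[ut])
  ut <- ut[rm_order]
  w <- Z[ut]
  key <- if (rank_by == "absolute") abs(w) else w
  k <- round(proportion * N * (N - 1) / 2)
  keep_idx <- ut[order(-key, seq_along(key))[seq_len(k)]]
  W <- matrix(0, N, N, dimnames = dimnames(Z))
  W[keep_idx] <- Z[keep_idx]
  W <- W + t(W)
  augmented <- FALSE
  added <- 0L
  comp <- .components(W != 0)
  if (max(comp) > 1) {
    if (disconnected == "error") {
      stop("thresholded network is disconnected (component sizes: ",
           paste(tabulate(comp), collapse = ", "), ")")
    }
    mst <- .max_spanning_tree(if (rank_by == "absolute") abs(Z) else Z)
    new_edges <- which(mst & W == 0 & upper.tri(Z))
    for (e in new_edges) {
      W[e] <- Z[e]
      W[arrayInd(e, dim(Z))[, c(2, 1), drop = FALSE]] <- Z[e]
    }
    added <- length(new_edges)
    augmented <- TRUE
  }
  structure(list(W = W, regions = colnames(Z), proportion = proportion,
                 n_edges = sum(W[upper.tri(W)] != 0), augmented = augmented,
                 augment_edges = added),
            class = "morphocov_network")
}

# connected components of a binary adjacency matrix (label per node)
.components <- function(A) {
  N <- nrow(A)
  comp <- rep(0L, N)
  cur <- 0L
  for (s in seq_len(N)) {
    if (comp[s] > 0) next
    cur <- cur + 1L
    frontier <- s
    comp[s] <- cur
    while (length(frontier) > 0) {
      nb <- which(colSums(A[frontier, , drop = FALSE] != 0) > 0)
      nb <- nb[comp[nb] == 0]
      comp[nb] <- cur
      frontier <- nb
    }
  }
  comp
}

# Prim's algorithm on the dense weight matrix; returns logical matrix of
# maximum-spanning-tree edges
.max_spanning_tree <- function(Z) {
  N <- nrow(Z)
  in_tree <- rep(FALSE, N)
  in_tree[1] <- TRUE
  best_w <- Z[, 1]
  best_from <- rep(1L, N)
  mst <- matrix(FALSE, N, N)
  for (step in seq_len(N - 1)) {
    cand <- which(!in_tree)
    j <- cand[which.max(best_w[cand])]
    mst[best_from[j], j] <- TRUE
    mst[j, best_from[j]] <- TRUE
    in_tree[j] <- TRUE
    upd <- !in_tree & Z[, j] > best_w
    best_w[upd] <- Z[upd, j]
    best_from[upd] <- j
  }
  mst
}

# all-pairs shortest path by vectorised Floyd-Warshall on a length matrix
# (Inf where no edge, 0 diagonal)
.floyd_warshall <- function(len) {
  d <- len
  N <- nrow(d)
  for (k in seq_len(N)) {
    via <- outer(d[, k], d[k, ], `+`)
    d <- pmin(d, via)
  }
  d
}

#' Graph-theoretic metrics of a structural covariance network
#'
#' Binary mode treats every retained edge as unit length; weighted mode uses
#' `1 / weight` as edge length (positive weights required) and the Onnela
#' weighted clustering coefficient with weights normalised by their maximum.
#' Characteristic path length is the mean shortest-path distance over
#' ordered pairs (i != j); global efficiency the mean inverse distance;
#' nodal efficiency the mean inverse distance from each node; global
#' clustering the arithmetic mean of nodal clustering; small-worldness the
#' ratio of global clustering to path length.
#'
#' @param network A `morphocov_network` or a symmetric weight matrix.
#' @param mode `"binary"` (default; matches the scale of the reported
#'   metrics at 35% density) or `"weighted"`.
#' @return List of class `morphocov_graph_metrics`: `degree`, `clustering`,
#'   `efficiency` (nodal vectors), `global_efficiency`, `path_length`,
#'   `global_clustering`, `small_worldness`, `mode`.
#' @export
graph_metrics <- function(network, mode = c("binary", "weighted")) {
  mode <- match.arg(mode)
  W <- if (inherits(network, "morphocov_network")) network$W else
    as.matrix(network)
  N <- nrow(W)
  A <- (W != 0) * 1
  diag(A) <- 0
  if (max(.components(A)) > 1) stop("network is disconnected")
  degree <- rowSums(A)
  if (mode == "binary") {
    len <- ifelse(A == 1, 1, Inf)
    diag(len) <- 0
    tri <- diag(A %*% A %*% A)
    denom <- degree * (degree - 1)
    clustering <- ifelse(denom > 0, tri / denom, 0)
  } else {
    if (any(W < 0)) stop("weighted mode requires non-negative weights")
    len <- ifelse(W > 0, 1 / W, Inf)
    diag(len) <- 0
    w_hat <- W / max(W)
    cr <- w_hat^(1 / 3)
    tri <- diag(cr %*% cr %*% cr)
    denom <- degree * (degree - 1)
    clustering <- ifelse(denom > 0, tri / denom, 0)
  }
  d <- .floyd_warshall(len)
  off <- upper.tri(d) | lower.tri(d)
  inv <- 1 / d
  diag(inv) <- 0
  structure(list(
    degree = setNames(degree, colnames(W)),
    clustering = setNames(clustering, colnames(W)),
    efficiency = setNames(rowSums(inv) / (N - 1), colnames(W)),
    global_efficiency = mean(inv[off]),
    path_length = mean(d[off]),
    global_clustering = mean(clustering),
    small_worldness = mean(clustering) / mean(d[off]),
    mode = mode
  ), class = "morphocov_graph_metrics")
}

#' Compare nodal network metrics between groups
#'
#' Two-sided Wilcoxon rank-sum tests on the nodal metric distributions for
#' each group pair, exact when both sides have at most 12 untied values,
#' otherwise the normal approximation with continuity correction.
#' Benjamini-Hochberg adjustment is applied across group pairs within each
#' metric.
#'
#' @param metrics_by_group Named list: group -> named list of nodal metric
#'   vectors (e.g. the `degree`/`clustering`/`efficiency` elements of
#'   [graph_metrics()] plus any scalar replicate vectors).
#' @param pairs List of length-2 character vectors of group names; default
#'   all pairs.
#' @param exact_max Largest per-group size for which the exact null is used.
#' @return Tibble: `metric`, `group1`, `group2`, `statistic`, `p`, `p_fdr`.
#' @export
compare_groups <- function(metrics_by_group, pairs = NULL, exact_max = 12) {
  groups <- names(metrics_by_group)
  if (is.null(pairs)) {
    pairs <- utils::combn(groups, 2, simplify = FALSE)
  }
  metrics <- names(metrics_by_group[[1]])
  out <- list()
  for (m in metrics) {
    rows <- lapply(pairs, function(pr) {
      x <- metrics_by_group[[pr[1]]][[m]]
      y <- metrics_by_group[[pr[2]]][[m]]
      if (length(unique(c(x, y))) == 1) {
        warning("all values tied for metric ", m)
        return(tibble::tibble(metric = m, group1 = pr[1], group2 = pr[2],
                              statistic = NA_real_, p = 1))
      }
      ties <- anyDuplicated(c(x, y)) > 0
      exact <- !ties && length(x) <= exact_max && length(y) <= exact_max
      wt <- suppressWarnings(
        wilcox.test(x, y, exact = exact, correct = TRUE))
      tibble::tibble(metric = m, group1 = pr[1], group2 = pr[2],
                     statistic = unname(wt$statistic), p = wt$p.value)
    })
    rows <- dplyr::bind_rows(rows)
    rows$p_fdr <- p.adjust(rows$p, method = "BH")
    out[[m]] <- rows
  }
  dplyr::bind_rows(out)
}
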
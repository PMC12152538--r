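#' Dice overlap coefficient of two parcel sets
#'
#' `2 |A n B| / (|A| + |B|)`; two empty sets give 0 with a warning.
#'
#' @param set_a,set_b Vectors of parcel identifiers over a shared universe.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(set_a, set_b) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  if (length(set_a) == 0 && length(set_b) == 0) {
    warning("both sets empty; Dice defined as 0")
    return(0)
  }
  2 * length(intersect(set_a, set_b)) / (length(set_a) + length(set_b))
}

#' Uniform random 3-D rotation matrix
#'
#' QR decomposition of a Gaussian matrix with the sign convention that
#' makes the factor Haar-distributed on O(3); the determinant is forced to
#' +1 by flipping one column if needed.
#'
#' @return 3 x 3 rotation matrix.
#' @export
random_rotation <- function() {
  qrd <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qrd)
  d <- sign(diag(qr.R(qrd)))
  d[d == 0] <- 1
  Q <- Q %*% diag(d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Spin-test null for parcel-map / network overlap
#'
#' The indicator map (which parcels are "significant") is permuted by
#' rotating the parcel centroids with uniform random 3-D rotations and
#' reassigning each rotated centroid to the nearest original centroid
#' (greedy, possibly many-to-one; ties broken by index). Dice overlap with
#' each network is recomputed for every rotation, and the one-sided p-value
#' is `(1 + #{null >= observed}) / (1 + n_perm)`, never exactly zero.
#'
#' @param indicator Logical or 0/1 vector over parcels (same order as
#'   `parcellation`), marking significant parcels.
#' @param parcellation Tibble from [generate_sphere_parcellation()] (columns
#'   `parcel_id`, `x`, `y`, `z`, `network`).
#' @param n_perm Number of rotations (>= 100).
#' @param seed Integer seed.
#' @return Tibble: `network`, `n_parcels`, `dice`, `p_spin`, `n_perm`; the
#'   null Dice matrix (permutations x networks) in attribute `"null"`.
#' @export
spin_null <- function(indicator, parcellation, n_perm = 1000, seed = 1L) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  xyz <- as.matrix(parcellation[, c("x", "y", "z")])
  nrm <- sqrt(rowSums(xyz^2))
  if (any(abs(nrm - 1) > 1e-9)) stop("centroids must lie on the unit sphere")
  indicator <- as.logical(indicator)
  if (!any(indicator)) stop("indicator marks no parcels; p undefined")
  ids <- parcellation$parcel_id
  networks <- sort(unique(parcellation$network))
  net_sets <- lapply(networks, function(nw) ids[parcellation$network == nw])
  obs <- vapply(seq_along(networks), function(i) {
    dice(ids[indicator], net_sets[[i]])
  }, numeric(1))
  # membership matrix form of the same Dice computation, for the hot loop
  M <- vapply(networks, function(nw) parcellation$network == nw,
              logical(nrow(parcellation)))
  net_size <- colSums(M)
  set.seed(as.integer(seed))
  null_mat <- matrix(NA_real_, n_perm, length(networks))
  for (b in seq_len(n_perm)) {
    R <- random_rotation()
    rotated <- xyz %*% t(R)
    # nearest original centroid = max inner product on the unit sphere
    nearest <- max.col(rotated %*% t(xyz), ties.method = "first")
    perm_ind <- indicator[nearest]
    null_mat[b, ] <- 2 * drop(crossprod(M, perm_ind)) /
      (sum(perm_ind) + net_size)
  }
  p_spin <- vapply(seq_along(networks), function(i) {
    (1 + sum(null_mat[, i] >= obs[i])) / (1 + n_perm)
  }, numeric(1))
  out <- tibble::tibble(
    network = networks,
    n_parcels = vapply(net_sets, length, integer(1)),
    dice = obs, p_spin = p_spin, n_perm = n_perm
  )
  attr(out, "null") <- null_mat
  out
}

#' Map regions onto parcels of a spherical parcellation
#'
#' Assigns every parcel to one of `length(regions)` region territories by
#' nearest-seed partitioning of the shared centroid lattice (seeded), so a
#' set of significant regions can be projected to a parcel indicator.
#'
#' @param parcellation Tibble from [generate_sphere_parcellation()].
#' @param regions Character vector of region names.
#' @param seed Integer seed for the region seed parcels.
#' @return Character vector, length = parcels: the region owning each
#'   parcel.
#' @export
assign_parcels_to_regions <- function(parcellation, regions, seed = 1L) {
  n <- nrow(parcellation)
  if (length(regions) > n) stop("more regions than parcels")
  xyz <- as.matrix(parcellation[, c("x", "y", "z")])
  set.seed(as.integer(seed))
  seeds <- sample.int(n, length(regions))
  sim <- xyz %*% t(xyz[seeds, , drop = FALSE])
  regions[max.col(sim, ties.method = "first")]
}
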
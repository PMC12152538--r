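# Independent reference implementations ("oracles") used across the suite.
# Each is deliberately written with a different algorithm or library than
# the package implementation it checks.

# ---- graphs -----------------------------------------------------------

# binary graph metrics via igraph (Dijkstra/BFS internals, independent of
# the package's Floyd-Warshall) plus matrix-power triangle counting
oracle_binary_metrics <- function(A) {
  g <- igraph::graph_from_adjacency_matrix(A != 0, mode = "undirected")
  d <- igraph::distances(g)
  off <- row(d) != col(d)
  cl <- igraph::transitivity(g, type = "local", isolates = "zero")
  inv <- 1 / d
  diag(inv) <- 0
  list(path_length = mean(d[off]),
       global_efficiency = mean(inv[off]),
       clustering = cl,
       global_clustering = mean(cl),
       degree = igraph::degree(g),
       efficiency = rowSums(inv) / (nrow(A) - 1))
}

# weighted metrics: igraph Dijkstra on 1/w lengths, Onnela clustering by
# explicit triple loop
oracle_weighted_metrics <- function(W) {
  N <- nrow(W)
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE)
  d <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  off <- row(d) != col(d)
  w_hat <- W / max(W)
  k <- rowSums(W != 0)
  cl <- numeric(N)
  for (i in seq_len(N)) {
    s <- 0
    for (j in seq_len(N)) {
      for (h in seq_len(N)) {
        if (j != i && h != i && j != h) {
          s <- s + (w_hat[i, j] * w_hat[i, h] * w_hat[j, h])^(1 / 3)
        }
      }
    }
    cl[i] <- if (k[i] > 1) s / (k[i] * (k[i] - 1)) else 0
  }
  inv <- 1 / d
  diag(inv) <- 0
  list(path_length = mean(d[off]),
       global_efficiency = mean(inv[off]),
       clustering = cl,
       global_clustering = mean(cl))
}

# all labelled graphs on N nodes as adjacency matrices (via edge bitmask)
all_graphs <- function(N) {
  pairs <- which(upper.tri(matrix(0, N, N)))
  m <- length(pairs)
  lapply(0:(2^m - 1), function(mask) {
    A <- matrix(0, N, N)
    A[pairs] <- bitwAnd(mask, 2^(seq_len(m) - 1)) > 0
    A + t(A)
  })
}

is_connected_graph <- function(A) {
  igraph::is_connected(
    igraph::graph_from_adjacency_matrix(A != 0, mode = "undirected"))
}

# random connected graph; weighted = positive uniform weights
random_connected_graph <- function(N, p_edge = 0.4, weighted = FALSE) {
  repeat {
    A <- matrix(0, N, N)
    ut <- upper.tri(A)
    A[ut] <- runif(sum(ut)) < p_edge
    A <- A + t(A)
    if (is_connected_graph(A)) break
  }
  if (weighted) {
    W <- matrix(0, N, N)
    W[upper.tri(W)] <- runif(sum(upper.tri(W)), 0.1, 2)
    W <- W + t(W)
    A <- A * W
  }
  A
}

# ---- separability -----------------------------------------------------

brute_sgcc <- function(points, labels) {
  points <- as.matrix(points)
  n <- nrow(points)
  dw <- db <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dij <- sqrt(sum((points[i, ] - points[j, ])^2))
      if (labels[i] == labels[j]) dw <- c(dw, dij) else db <- c(db, dij)
    }
  }
  d_within <- if (length(dw)) mean(dw) else 0
  d_between <- mean(db)
  den <- max(d_between, d_within)
  if (den == 0) 0 else (d_between - d_within) / den
}

# ---- classification ---------------------------------------------------

# AUROC as the fraction of concordant positive/negative pairs
concordance_auroc <- function(y, s) {
  pos <- s[y == 1]
  neg <- s[y == 0]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# Firth slope on a 2x2 table equals the log odds ratio after adding 1/2 to
# every cell (a = y1x1, b = y1x0, c = y0x1, d = y0x0)
firth_2x2_slope <- function(a, b, c, d) {
  log(((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5)))
}

# ---- meta-analysis ----------------------------------------------------

grid_reml_tau2 <- function(y, v, n_grid = 100001) {
  upper <- 10 * max(v) * length(y)
  grid <- seq(0, upper, length.out = n_grid)
  ll <- vapply(grid, function(t2) morphocov::reml_loglik(y, v, t2),
               numeric(1))
  grid[which.max(ll)]
}

dl_tau2 <- function(y, v) {
  k <- length(y)
  w <- 1 / v
  mu <- sum(w * y) / sum(w)
  Q <- sum(w * (y - mu)^2)
  max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
}

bh_manual <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# ---- rank tests -------------------------------------------------------

# exact two-sided Wilcoxon rank-sum p by full enumeration (no ties)
wilcox_exact_p <- function(x, y) {
  n1 <- length(x)
  ranks <- rank(c(x, y))
  u_obs <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + length(y), n1)
  all_ranks <- seq_len(n1 + length(y))
  u_null <- apply(combos, 2, function(ix) {
    sum(all_ranks[ix]) - n1 * (n1 + 1) / 2
  })
  lo <- mean(u_null <= u_obs)
  hi <- mean(u_null >= u_obs)
  min(1, 2 * min(lo, hi))
}
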
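# Brute-force reference implementations, independent of the package's
# igraph-based code paths. All operate on a named adjacency matrix.

# adjacency matrix (0/1, named) from an igraph object
adj_of <- function(g) {
  as.matrix(igraph::as_adjacency_matrix(g))
}

# Floyd-Warshall hop distances on a 0/1 adjacency matrix
bf_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n, dimnames = dimnames(A))
  D[A > 0] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  D
}

# number of shortest paths between every pair (BFS counting from each source)
bf_path_counts <- function(A, D) {
  n <- nrow(A)
  S <- matrix(0, n, n)
  diag(S) <- 1
  for (s in seq_len(n)) {
    ord <- order(D[s, ])
    for (t in ord) {
      if (t == s || !is.finite(D[s, t])) next
      preds <- which(A[, t] > 0 & D[s, ] == D[s, t] - 1)
      S[s, t] <- sum(S[s, preds])
    }
  }
  S
}

# the seven topology metrics, straight from the definitions
bf_topology <- function(g) {
  A <- adj_of(g)
  n <- nrow(A)
  e <- sum(A) / 2
  D <- bf_distances(A)

  # components by reachability
  reach <- is.finite(D)
  lcc <- max(rowSums(reach))

  closeness <- vapply(seq_len(n), function(i) {
    di <- D[i, -i]
    r <- sum(is.finite(di)) + 1
    if (r == 1 || n == 1) return(0)
    ((r - 1) / (n - 1)) * ((r - 1) / sum(di[is.finite(di)]))
  }, numeric(1))

  up <- D[upper.tri(D)]
  msd <- if (any(is.finite(up))) mean(up[is.finite(up)]) else NA_real_

  clust <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    sum(A[nb, nb]) / 2 / choose(k, 2)
  }, numeric(1))

  S <- bf_path_counts(A, D)
  btw <- vapply(seq_len(n), function(v) {
    tot <- 0
    for (s in seq_len(n)) for (t in seq_len(n)) {
      if (s >= t || s == v || t == v) next
      if (!is.finite(D[s, t]) || S[s, t] == 0) next
      if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
          D[s, v] + D[v, t] == D[s, t]) {
        tot <- tot + S[s, v] * S[v, t] / S[s, t]
      }
    }
    tot
  }, numeric(1))
  btw_norm <- if (n < 3) rep(0, n) else btw / ((n - 1) * (n - 2) / 2)

  list(all_edges = e, largest_subnetwork = lcc, mean_degree = e / n,
       closeness_centrality = mean(closeness), mean_shortest_distance = msd,
       clustering_coefficient = mean(clust), betweenness_centrality = mean(btw_norm))
}

# nearest-neighbour module distances by explicit double loops
bf_within_distance <- function(g, S) {
  D <- bf_distances(adj_of(g))
  S <- intersect(S, rownames(D))
  if (length(S) <= 1) return(0)
  mean(vapply(S, function(a) min(D[a, setdiff(S, a)]), numeric(1)))
}

bf_cross_distance <- function(g, A_set, B_set) {
  D <- bf_distances(adj_of(g))
  nm <- rownames(D)
  A_set <- intersect(A_set, nm); B_set <- intersect(B_set, nm)
  terms <- c(
    vapply(A_set, function(a) min(D[a, B_set]), numeric(1)),
    vapply(B_set, function(b) min(D[b, A_set]), numeric(1)))
  mean(terms[is.finite(terms)])
}

# two-sided Fisher p by exhaustive enumeration over the hypergeometric support
bf_fisher_two_sided <- function(a, b, c, d) {
  m1 <- a + b   # margin of set B
  m2 <- a + c   # margin of set A
  n <- a + b + c + d
  lo <- max(0, m1 + m2 - n)
  hi <- min(m1, m2)
  probs <- vapply(lo:hi, function(x) {
    exp(lchoose(m2, x) + lchoose(n - m2, m1 - x) - lchoose(n, m1))
  }, numeric(1))
  p_obs <- probs[a - lo + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# BH step-up straight from the definition
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  sorted <- p[o]
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m * sorted[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# specificity by explicit two-loop computation
bf_specificity <- function(expr, cell_type) {
  types <- sort(unique(cell_type))
  means <- matrix(0, nrow(expr), length(types),
                  dimnames = list(rownames(expr), types))
  for (g in seq_len(nrow(expr))) for (t in seq_along(types)) {
    means[g, t] <- mean(expr[g, cell_type == types[t]])
  }
  keep <- rowSums(means) > 0
  means[keep, , drop = FALSE] / rowSums(means)[keep]
}

# seeded random test graph with letter-free names
random_test_graph <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("N%03d", seq_len(n))
  g
}
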
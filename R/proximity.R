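# Internal: restrict an interactome to its largest connected component.
lcc_graph <- function(net) {
  comp <- igraph::components(net)
  keep <- which(comp$membership == which.max(comp$csize))
  igraph::induced_subgraph(net, keep)
}

# Internal: mean nearest-neighbour distance terms and all-pairs means from a
# hop-distance matrix D (rows/cols named by node).
# Within-set mean distance: nearest -> each member's distance to its nearest
# OTHER member, averaged (singleton set -> 0); all_pairs -> mean over
# unordered distinct pairs (singleton -> 0).
within_distance <- function(D, set, convention) {
  k <- length(set)
  if (k <= 1L) return(0)
  Ds <- D[set, set, drop = FALSE]
  diag(Ds) <- Inf
  if (convention == "nearest") mean(apply(Ds, 1L, min))
  else mean(Ds[upper.tri(Ds)])
}

# Cross-set mean distance d_AB. Under "nearest", each a in A contributes its
# distance to the closest b in B and vice versa; all |A|+|B| terms averaged.
# A gene shared by both sets matches itself at distance 0 when
# cross_self = "include"; when A and B are equal as sets the other-member
# rule is applied symmetrically (so s_AB(A, A) = 0), likewise when
# cross_self = "exclude".
cross_distance <- function(D, A, B, convention, cross_self = "include") {
  exclude_self <- (cross_self == "exclude") || setequal(A, B)
  DA <- D[A, B, drop = FALSE]
  DB <- D[B, A, drop = FALSE]
  if (exclude_self) {
    for (i in seq_along(A)) {
      j <- match(A[i], B)
      if (!is.na(j)) DA[i, j] <- Inf
    }
    for (i in seq_along(B)) {
      j <- match(B[i], A)
      if (!is.na(j)) DB[i, j] <- Inf
    }
  }
  if (convention == "nearest") {
    terms <- c(apply(DA, 1L, min), apply(DB, 1L, min))
    terms <- terms[is.finite(terms)]
    mean(terms)
  } else {
    v <- DA[is.finite(DA)]
    mean(v)
  }
}

#' Mean shortest distance between (or within) gene modules
#'
#' Computes the mean shortest-path distance between two gene sets on the
#' interactome's largest connected component (LCC). Under the default
#' `nearest` convention each mapped gene contributes its hop distance to the
#' closest member of the other set (for the within-set case, the closest
#' *other* member), and all `|A| + |B|` terms are averaged — the convention
#' under which `d_AB - (d_A + d_B)/2` is the standard network-separation
#' score. `all_pairs` averages over all mapped cross pairs instead.
#'
#' @param net An `igraph` interactome; distances are computed on its LCC.
#' @param A,B Gene sets ([gene_set] or character). Pass identical sets to get
#'   the within-module distance.
#' @param convention `"nearest"` (default) or `"all_pairs"`.
#' @param cross_self `"include"` (default): a gene present in both sets
#'   matches itself at distance 0 in `d_AB`; `"exclude"` applies the
#'   other-member rule across sets too. When `A` and `B` are equal as sets
#'   the other-member rule is always applied, so `s_AB(A, A) = 0`.
#' @return Mean hop count (single number).
#' @export
module_distance <- function(net, A, B, convention = c("nearest", "all_pairs"),
                            cross_self = c("include", "exclude")) {
  convention <- match.arg(convention)
  cross_self <- match.arg(cross_self)
  lcc <- lcc_graph(net)
  a <- intersect(as_gene_vector(A), igraph::V(lcc)$name)
  b <- intersect(as_gene_vector(B), igraph::V(lcc)$name)
  if (length(a) == 0L || length(b) == 0L)
    stop("gene set does not map to the network's largest connected component", call. = FALSE)
  D <- igraph::distances(lcc, v = union(a, b), to = union(a, b))
  if (setequal(a, b)) within_distance(D, a, convention)
  else cross_distance(D, a, b, convention, cross_self)
}

#' Network separation score
#'
#' `s_AB = d_AB - (d_A + d_B) / 2`. Negative values mean the two modules
#' overlap on the interactome (the mean cross distance is smaller than the
#' modules' own internal spread); positive values mean they are separated.
#'
#' @param d_A,d_B Mean within-module distances.
#' @param d_AB Mean between-module distance.
#' @return The separation score (may be negative).
#' @examples
#' separation(1.47, 1.44, 1.37)  # -0.085
#' @export
separation <- function(d_A, d_B, d_AB) {
  stopifnot(is.finite(d_A), is.finite(d_B), is.finite(d_AB),
            d_A >= 0, d_B >= 0, d_AB >= 0)
  d_AB - (d_A + d_B) / 2
}

#' Network proximity permutation test
#'
#' Computes the observed separation `s_AB` between two gene sets and its
#' one-sided permutation p-value: each replicate draws random node sets of
#' the same mapped sizes, uniformly without replacement from the LCC
#' (independently for the two sets, so they may overlap), recomputes `s_AB`,
#' and `p = P(random s_AB <= observed)` — more negative separation meaning
#' stronger interactome overlap. Ties are counted inclusively.
#'
#' @inheritParams module_distance
#' @param n_perm Number of permutation replicates (default 1000).
#' @param seed Integer seed for reproducible replicates.
#' @param pseudocount If `TRUE`, report `(r+1)/(n_perm+1)`.
#' @return A `proximity_test` object with fields `d_A`, `d_B`, `d_AB`,
#'   `s_AB`, `p_value`, `random_mean`, `random_sd`, `n_permutations`, `seed`,
#'   `convention`, `n_A`, `n_B`.
#' @export
proximity_test <- function(net, A, B, n_perm = 1000, seed = NULL,
                           convention = c("nearest", "all_pairs"),
                           cross_self = c("include", "exclude"),
                           pseudocount = FALSE) {
  convention <- match.arg(convention)
  cross_self <- match.arg(cross_self)
  stopifnot(n_perm >= 1)
  lcc <- lcc_graph(net)
  nodes <- igraph::V(lcc)$name
  a <- intersect(as_gene_vector(A), nodes)
  b <- intersect(as_gene_vector(B), nodes)
  if (length(a) == 0L || length(b) == 0L)
    stop("gene set does not map to the network's largest connected component", call. = FALSE)

  # Full LCC distance matrix when affordable; per-set BFS otherwise.
  full <- igraph::vcount(lcc) <= 4000L
  D <- if (full) igraph::distances(lcc) else NULL
  sab <- function(sa, sb) {
    Dm <- if (full) D else {
      u <- union(sa, sb)
      igraph::distances(lcc, v = u, to = u)
    }
    d_a <- within_distance(Dm, sa, convention)
    d_b <- within_distance(Dm, sb, convention)
    d_ab <- if (setequal(sa, sb)) within_distance(Dm, sa, convention)
            else cross_distance(Dm, sa, sb, convention, cross_self)
    c(d_a, d_b, d_ab)
  }

  obs <- sab(a, b)
  s_obs <- separation(obs[1], obs[2], obs[3])

  rand <- with_seed(seed, {
    vapply(seq_len(n_perm), function(r) {
      ra <- sample(nodes, length(a))
      rb <- sample(nodes, length(b))
      d <- sab(ra, rb)
      d[3] - (d[1] + d[2]) / 2
    }, numeric(1))
  })

  structure(list(
    d_A = obs[1], d_B = obs[2], d_AB = obs[3], s_AB = s_obs,
    p_value = empirical_p(rand, s_obs, tail = "less", pseudocount = pseudocount),
    random_mean = mean(rand), random_sd = sd(rand),
    n_permutations = n_perm, seed = seed,
    convention = convention, n_A = length(a), n_B = length(b)
  ), class = "proximity_test")
}

#' @export
print.proximity_test <- function(x, ...) {
  cat("Network proximity (separation) test\n")
  cat(sprintf("  mapped genes: |A| = %d, |B| = %d (%s convention)\n",
              x$n_A, x$n_B, x$convention))
  cat(sprintf("  d_A = %.3f, d_B = %.3f, d_AB = %.3f\n", x$d_A, x$d_B, x$d_AB))
  cat(sprintf("  s_AB = %.4f  (random mean %.4f, sd %.4f)\n",
              x$s_AB, x$random_mean, x$random_sd))
  cat(sprintf("  one-sided p = %.4g  (%d permutations)\n",
              x$p_value, x$n_permutations))
  invisible(x)
}
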
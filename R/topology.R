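#' Topological characteristics of an induced subnetwork
#'
#' Computes the seven topological parameters used to characterise a disease
#' module on an interactome, all on the subgraph induced by `genes`:
#'
#' * `all_edges` — number of edges in the induced subgraph.
#' * `largest_subnetwork` — node count of its largest connected component.
#' * `mean_degree` — edges per mapped node, `E / N` by default (the
#'   `"2E_over_N"` convention gives the usual average degree `2E / N`).
#' * `closeness_centrality` — mean over nodes of Wasserman–Faust
#'   component-scaled closeness `((r-1)/(n-1)) * ((r-1)/sum(d))`, where `r`
#'   counts nodes reachable from the node (itself included); isolated nodes
#'   contribute 0.
#' * `mean_shortest_distance` — mean hop count over all connected unordered
#'   node pairs (disconnected pairs excluded; `NA` when no pair is connected).
#' * `clustering_coefficient` — mean local clustering, nodes of degree < 2
#'   contributing 0.
#' * `betweenness_centrality` — mean betweenness normalised by
#'   `(n-1)(n-2)/2`, endpoints excluded.
#'
#' All distances are unweighted hop counts.
#'
#' @param net An `igraph` interactome.
#' @param genes A [gene_set] or character vector; metrics are computed on
#'   `induce_subnetwork(net, genes)`.
#' @param degree_convention `"E_over_N"` (default) or `"2E_over_N"`.
#' @return A `topology_metrics` object: named list of the seven metrics plus
#'   `n_mapped_nodes`.
#' @examples
#' g <- interactome(cbind(c("A", "B", "C"), c("B", "C", "A")))
#' topology_metrics(g, c("A", "B", "C"))
#' @export
topology_metrics <- function(net, genes,
                             degree_convention = c("E_over_N", "2E_over_N")) {
  degree_convention <- match.arg(degree_convention)
  sub <- if (missing(genes) || is.null(genes)) net else induce_subnetwork(net, genes)
  n <- igraph::vcount(sub)
  if (n == 0L) stop("no input genes map to the network", call. = FALSE)
  e <- igraph::ecount(sub)

  comp <- igraph::components(sub)
  lcc <- max(comp$csize)

  mean_degree <- if (degree_convention == "E_over_N") e / n else 2 * e / n

  # Wasserman-Faust closeness from the hop-distance matrix
  d <- igraph::distances(sub)
  closeness <- if (n == 1L) 0 else {
    vapply(seq_len(n), function(i) {
      di <- d[i, -i]
      reach <- di[is.finite(di)]
      r <- length(reach) + 1L   # reachable count including self
      if (r == 1L) return(0)
      ((r - 1) / (n - 1)) * ((r - 1) / sum(reach))
    }, numeric(1))
  }

  finite_up <- d[upper.tri(d)][is.finite(d[upper.tri(d)])]
  msd <- if (length(finite_up)) mean(finite_up) else NA_real_

  cc <- igraph::transitivity(sub, type = "localundirected", isolates = "zero")
  cc <- if (n > 0) mean(cc) else NA_real_

  btw <- if (n < 3L) rep(0, n) else
    igraph::betweenness(sub, directed = FALSE, normalized = TRUE)

  structure(list(
    all_edges = e,
    largest_subnetwork = lcc,
    mean_degree = mean_degree,
    closeness_centrality = mean(closeness),
    mean_shortest_distance = msd,
    clustering_coefficient = cc,
    betweenness_centrality = mean(btw),
    n_mapped_nodes = n,
    degree_convention = degree_convention
  ), class = "topology_metrics")
}

#' Names of the seven topology metrics
#' @return Character vector in canonical order.
#' @export
topology_metric_names <- function() {
  c("all_edges", "largest_subnetwork", "mean_degree", "closeness_centrality",
    "mean_shortest_distance", "clustering_coefficient", "betweenness_centrality")
}

#' @export
print.topology_metrics <- function(x, ...) {
  cat(sprintf("Induced subnetwork: %d mapped nodes\n", x$n_mapped_nodes))
  for (m in topology_metric_names()) {
    cat(sprintf("  %-24s %s\n", m, format(x[[m]], digits = 4)))
  }
  invisible(x)
}

#' @export
as.data.frame.topology_metrics <- function(x, ...) {
  data.frame(metric = topology_metric_names(),
             value = unlist(x[topology_metric_names()], use.names = FALSE))
}
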
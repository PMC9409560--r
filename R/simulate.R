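#' Simulation configuration
#'
#' Bundles the parameters of the synthetic-data generators with defaults
#' chosen to emulate the pipeline's real inputs: a sparse interactome on the
#' order of 10^4 nodes; a planted module of tens of genes with elevated
#' internal edge density (the "localized disease module" situation); and an
#' overdispersed single-cell count matrix with a disjoint planted marker set
#' per cell type expressed `marker_fold` above baseline.
#'
#' @param seed Integer seed driving every generator.
#' @param n_nodes Interactome size.
#' @param graph_model `"erdos_renyi"`, `"barabasi_albert"` or
#'   `"duplication_divergence"`.
#' @param model_params Model parameters: `p` (ER edge probability), `m` (BA
#'   edges per new node), `p_keep`/`p_link` (duplication-divergence retention
#'   and anchor-link probabilities).
#' @param module_size,module_edge_prob Planted-module node count and internal
#'   edge probability.
#' @param n_genes_expr Genes in the simulated expression matrix.
#' @param n_cell_types,cells_per_type Cell-type count and cells per type.
#' @param n_markers_per_type Planted markers per cell type.
#' @param marker_fold Expression fold-up of a marker in its own type (>= 1).
#' @param mu,theta Negative-binomial baseline mean and dispersion (size).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_nodes = 10000L,
                       graph_model = c("erdos_renyi", "barabasi_albert",
                                       "duplication_divergence"),
                       model_params = list(p = 4e-4, m = 3L,
                                           p_keep = 0.4, p_link = 0.6),
                       module_size = 30L,
                       module_edge_prob = 0.3,
                       n_genes_expr = 1000L,
                       n_cell_types = 4L,
                       cells_per_type = 100L,
                       n_markers_per_type = 40L,
                       marker_fold = 5,
                       mu = 2,
                       theta = 2) {
  graph_model <- match.arg(graph_model)
  stopifnot(n_nodes >= 2, module_size >= 1, module_edge_prob >= 0,
            module_edge_prob <= 1, marker_fold >= 1, n_cell_types >= 2,
            cells_per_type >= 1, mu > 0, theta > 0)
  structure(as.list(environment()), class = "sim_config")
}

# zero-padded symbolic gene names G0001...
sim_gene_names <- function(n, prefix = "G") {
  sprintf(paste0(prefix, "%0", max(4L, nchar(n)), "d"), seq_len(n))
}

#' Simulate a sparse interactome
#'
#' Seeded random graph over symbolic gene names (`G0001`, ...). Models:
#' Erdos-Renyi `G(n, p)`; Barabasi-Albert preferential attachment starting
#' from `m` seed nodes with each later node attaching to `m` distinct
#' existing nodes (degree-plus-one weighting), giving exactly `(n - m) * m`
#' edges; and a duplication-divergence model where each new node copies a
#' random anchor's edges with probability `p_keep` and links to the anchor
#' with probability `p_link`.
#'
#' @param cfg A [sim_config()]; `cfg$graph_model` and `cfg$model_params`
#'   select the model.
#' @return An undirected simple `igraph` graph with `n_nodes` vertices.
#' @export
simulate_interactome <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- as.integer(cfg$n_nodes)
  pr <- cfg$model_params
  g <- with_seed(cfg$seed, switch(cfg$graph_model,
    erdos_renyi = {
      if (is.null(pr$p) || pr$p < 0 || pr$p > 1) stop("need edge probability p in [0,1]", call. = FALSE)
      igraph::sample_gnp(n, pr$p)
    },
    barabasi_albert = {
      m <- as.integer(pr$m)
      if (is.na(m) || m < 1L || m >= n) stop("need 1 <= m < n_nodes", call. = FALSE)
      ba_graph(n, m)
    },
    duplication_divergence = {
      if (is.null(pr$p_keep) || is.null(pr$p_link)) stop("need p_keep and p_link", call. = FALSE)
      dd_graph(n, pr$p_keep, pr$p_link)
    }
  ))
  igraph::V(g)$name <- sim_gene_names(n)
  igraph::simplify(g)
}

# Barabasi-Albert with an m-node empty seed; every node m+1..n attaches to m
# distinct existing nodes with probability proportional to degree + 1.
ba_graph <- function(n, m) {
  from <- integer((n - m) * m)
  to <- integer((n - m) * m)
  deg <- integer(n)
  k <- 0L
  for (v in (m + 1L):n) {
    prev <- seq_len(v - 1L)
    tgt <- sample(prev, m, prob = deg[prev] + 1)
    from[k + seq_len(m)] <- v
    to[k + seq_len(m)] <- tgt
    deg[tgt] <- deg[tgt] + 1L
    deg[v] <- deg[v] + m
    k <- k + m
  }
  igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
}

# Duplication-divergence: new node copies each edge of a random anchor with
# probability p_keep and attaches to the anchor itself with probability
# p_link; nodes left isolated fall back to the anchor link.
dd_graph <- function(n, p_keep, p_link) {
  adj <- vector("list", n)
  adj[[1]] <- 2L; adj[[2]] <- 1L
  for (v in 3L:n) {
    anchor <- sample.int(v - 1L, 1L)
    kept <- adj[[anchor]][runif(length(adj[[anchor]])) < p_keep]
    if (runif(1) < p_link) kept <- c(kept, anchor)
    kept <- unique(kept)
    if (length(kept) == 0L) kept <- anchor
    adj[[v]] <- kept
    for (u in kept) adj[[u]] <- c(adj[[u]], v)
  }
  el <- do.call(rbind, lapply(seq_len(n), function(v) {
    nb <- adj[[v]][adj[[v]] > v]
    if (length(nb)) cbind(v, nb) else NULL
  }))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  g
}

#' Plant a localized module in an interactome
#'
#' Selects `size` nodes by snowball (random-walk) sampling — guaranteeing the
#' selected seed is connected within the host component — then adds internal
#' edges between all not-yet-linked pairs with probability `edge_prob`,
#' creating a subnetwork denser than the background. If the walk exhausts a
#' connected component before reaching `size`, it restarts from a random
#' unvisited node (reported via `message()`).
#'
#' @param net An `igraph` interactome.
#' @param size Module node count (`<= vcount(net)`).
#' @param edge_prob Internal edge probability for added edges.
#' @param seed Integer seed.
#' @return List with `net` (the augmented graph) and `genes` (a [gene_set]
#'   of the planted module).
#' @export
plant_module <- function(net, size, edge_prob, seed = NULL) {
  n <- igraph::vcount(net)
  if (size > n) stop("module size exceeds network size", call. = FALSE)
  with_seed(seed, {
    nodes <- snowball_sample(net, size)
    name_sel <- igraph::V(net)$name[nodes]
    pairs <- which(upper.tri(matrix(0, size, size)), arr.ind = TRUE)
    add <- pairs[runif(nrow(pairs)) < edge_prob, , drop = FALSE]
    if (nrow(add)) {
      el <- cbind(name_sel[add[, 1]], name_sel[add[, 2]])
      net <- igraph::add_edges(net, t(el))
      net <- igraph::simplify(net)
    }
    list(net = net, genes = gene_set(name_sel, name = "planted_module"))
  })
}

# snowball/random-walk sample of `size` vertex ids, connected while the host
# component allows; the walk starts inside the largest connected component so
# planted modules live where module distances are measured
snowball_sample <- function(net, size) {
  n <- igraph::vcount(net)
  comp <- igraph::components(net)
  lcc_ids <- which(comp$membership == which.max(comp$csize))
  visited <- integer(0)
  frontier <- integer(0)
  while (length(visited) < size) {
    if (length(frontier) == 0L) {
      if (length(visited) > 0L)
        message("snowball_sample: component exhausted, restarting walk")
      pool <- if (length(visited) == 0L) lcc_ids else setdiff(seq_len(n), visited)
      start <- if (length(pool) == 1L) pool else sample(pool, 1L)
      visited <- c(visited, start)
      frontier <- setdiff(as.integer(igraph::neighbors(net, start)), visited)
      next
    }
    nxt <- if (length(frontier) == 1L) frontier else sample(frontier, 1L)
    visited <- c(visited, nxt)
    frontier <- setdiff(unique(c(frontier, as.integer(igraph::neighbors(net, nxt)))),
                        visited)
  }
  visited[seq_len(size)]
}

#' Plant two overlapping gene sets in one network module
#'
#' Builds a single planted module (snowball sample plus internal edges) of
#' `size_a + size_b - shared` nodes and splits it into two gene sets with
#' exactly `shared` common genes. Because both sets live in the same dense
#' neighbourhood, their expected separation `s_AB` is negative, increasingly
#' so as `shared / size` grows.
#'
#' @param net An `igraph` interactome.
#' @param size_a,size_b Set sizes.
#' @param shared Number of common genes (`<= min(size_a, size_b)`).
#' @param edge_prob Internal edge probability of the planted module.
#' @param seed Integer seed.
#' @return List with `net` (augmented graph), `A` and `B` ([gene_set]s).
#' @export
plant_overlapping_sets <- function(net, size_a, size_b, shared,
                                   edge_prob = 0.3, seed = NULL) {
  if (shared > min(size_a, size_b))
    stop("shared exceeds the smaller set size", call. = FALSE)
  pool_size <- size_a + size_b - shared
  if (pool_size > igraph::vcount(net)) stop("sets too large for the network", call. = FALSE)
  planted <- plant_module(net, pool_size, edge_prob, seed = seed)
  pool <- planted$genes$genes
  common <- pool[seq_len(shared)]
  rest <- if (shared > 0) pool[-seq_len(shared)] else pool
  a_only <- rest[seq_len(size_a - shared)]
  b_only <- rest[setdiff(seq_along(rest), seq_len(size_a - shared))]
  list(net = planted$net,
       A = gene_set(c(common, a_only), name = "planted_A"),
       B = gene_set(c(common, b_only), name = "planted_B"))
}

#' Simulate an annotated single-cell expression matrix with planted markers
#'
#' Counts are drawn from a negative binomial with mean `mu` and dispersion
#' `theta` (the standard overdispersed model for scRNA-seq counts). Each cell
#' type receives a disjoint block of `n_markers_per_type` marker genes whose
#' mean is `mu * marker_fold` in cells of its own type; `marker_fold = 1`
#' gives a structureless null matrix.
#'
#' @param cfg A [sim_config()].
#' @return List with `expr` (genes x cells matrix, rows `G...`, columns
#'   `cell_...`), `annotations` (data frame `cell_id`, `cell_type`), and
#'   `truth` (data frame `gene`, `marker_of` for planted markers).
#' @export
simulate_expression <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  ng <- as.integer(cfg$n_genes_expr)
  nt <- as.integer(cfg$n_cell_types)
  nc <- as.integer(cfg$cells_per_type)
  nm <- as.integer(cfg$n_markers_per_type)
  if (cfg$marker_fold > 1 && nm * nt > ng)
    stop("more planted markers than genes", call. = FALSE)
  genes <- sim_gene_names(ng)
  types <- sprintf("type%02d", seq_len(nt))
  cells <- sprintf("cell_%04d", seq_len(nt * nc))
  cell_type <- rep(types, each = nc)

  marker_of <- rep(NA_character_, ng)
  if (cfg$marker_fold > 1) {
    for (t in seq_len(nt)) marker_of[(t - 1L) * nm + seq_len(nm)] <- types[t]
  }

  expr <- with_seed(cfg$seed, {
    mu_mat <- matrix(cfg$mu, nrow = ng, ncol = nt * nc)
    if (cfg$marker_fold > 1) {
      for (t in seq_len(nt)) {
        rows <- which(marker_of == types[t])
        cols <- which(cell_type == types[t])
        mu_mat[rows, cols] <- cfg$mu * cfg$marker_fold
      }
    }
    matrix(rnbinom(length(mu_mat), mu = mu_mat, size = cfg$theta),
           nrow = ng, dimnames = list(genes, cells))
  })

  truth <- data.frame(gene = genes[!is.na(marker_of)],
                      marker_of = marker_of[!is.na(marker_of)],
                      stringsAsFactors = FALSE)
  list(expr = expr,
       annotations = data.frame(cell_id = cells, cell_type = cell_type,
                                stringsAsFactors = FALSE),
       truth = truth)
}

#' Simulate a GMT collection with one planted enriched set
#'
#' Builds `n_sets` gene sets over `universe`: one planted set containing
#' `planted_frac` of the query genes (topped up with random universe genes to
#' `set_size`) and `n_sets - 1` sets drawn uniformly at random.
#'
#' @param query Character vector or [gene_set] the planted set should enrich.
#' @param universe Background gene symbols.
#' @param n_sets Total number of sets (default 50).
#' @param set_size Genes per set (default 40).
#' @param planted_frac Fraction of the query placed in the planted set.
#' @param seed Integer seed.
#' @return Named list of character vectors; the planted set is named
#'   `"planted_set"`.
#' @export
simulate_gmt <- function(query, universe, n_sets = 50L, set_size = 40L,
                         planted_frac = 0.8, seed = NULL) {
  q <- as_gene_vector(query)
  univ <- as_gene_vector(universe)
  stopifnot(n_sets >= 1, set_size >= 1, planted_frac >= 0, planted_frac <= 1)
  with_seed(seed, {
    take <- max(1L, floor(planted_frac * length(q)))
    core <- sample(q, take)
    filler <- sample(setdiff(univ, core), max(0L, set_size - take))
    sets <- list(planted_set = c(core, filler))
    for (i in seq_len(n_sets - 1L)) {
      sets[[sprintf("random_set_%02d", i)]] <- sample(univ, set_size)
    }
    sets
  })
}

#' Write a full synthetic fixture bundle
#'
#' Generates every input the pipeline consumes — interactome edge list,
#' overlapping risk/target gene lists planted in one module, universe list,
#' GMT collection with a planted set, expression matrix + cell annotations +
#' marker truth table, and an identity ortholog table — into `outdir`.
#'
#' @param outdir Output directory (created if needed).
#' @param cfg A [sim_config()].
#' @param size_a,size_b,shared Planted gene-set sizes for the proximity /
#'   overlap stages.
#' @return Invisibly, a named list of the written file paths.
#' @export
simulate_fixtures <- function(outdir, cfg = sim_config(),
                              size_a = 25L, size_b = 25L, shared = 8L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  net <- simulate_interactome(cfg)
  planted <- plant_overlapping_sets(net, size_a, size_b, shared,
                                    edge_prob = cfg$module_edge_prob,
                                    seed = cfg$seed + 1L)
  universe <- igraph::V(planted$net)$name
  gmt <- simulate_gmt(planted$A, universe, seed = cfg$seed + 2L)
  ex <- simulate_expression(cfg)

  # relabel expression genes with network symbols (planted sets first) so the
  # EWCE stage's query maps into the expression background
  ab <- union(planted$A$genes, planted$B$genes)
  new_names <- head(c(ab, setdiff(universe, ab)), nrow(ex$expr))
  if (length(new_names) == nrow(ex$expr)) {
    ex$truth$gene <- new_names[match(ex$truth$gene, rownames(ex$expr))]
    rownames(ex$expr) <- new_names
  }

  paths <- list(
    network = file.path(outdir, "edges.tsv"),
    genes_a = file.path(outdir, "genes_a.txt"),
    genes_b = file.path(outdir, "genes_b.txt"),
    universe = file.path(outdir, "universe.txt"),
    gmt = file.path(outdir, "sets.gmt"),
    expression = file.path(outdir, "expr.tsv"),
    annotations = file.path(outdir, "annot.tsv"),
    truth = file.path(outdir, "truth.tsv"),
    orthologs = file.path(outdir, "orthologs.tsv")
  )
  write_edge_list(planted$net, paths$network)
  write_gene_set(planted$A, paths$genes_a)
  write_gene_set(planted$B, paths$genes_b)
  writeLines(universe, paths$universe)
  write_gmt(gmt, paths$gmt)
  df <- data.frame(gene = rownames(ex$expr), ex$expr, check.names = FALSE)
  write.table(df, paths$expression, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(ex$annotations, paths$annotations, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(ex$truth, paths$truth, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(src = universe, tgt = universe),
              paths$orthologs, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(paths)
}
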
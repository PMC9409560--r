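test_that("ER at p = 1 is complete; seeded generation is deterministic", {
  g <- simulate_interactome(sim_config(seed = 1, n_nodes = 100,
                                       model_params = list(p = 1.0)))
  expect_equal(igraph::ecount(g), 4950)
  cfg <- sim_config(seed = 9, n_nodes = 300, model_params = list(p = 0.01))
  g1 <- simulate_interactome(cfg)
  g2 <- simulate_interactome(cfg)
  expect_identical(igraph::as_edgelist(g1), igraph::as_edgelist(g2))
})

test_that("Barabasi-Albert graph has exactly (n - m) * m edges", {
  cfg <- sim_config(seed = 2, n_nodes = 500, graph_model = "barabasi_albert",
                    model_params = list(m = 2L))
  g <- simulate_interactome(cfg)
  expect_equal(igraph::ecount(g), (500 - 2) * 2)
  expect_equal(igraph::vcount(g), 500)
  # degree-skewed like the reference preferential-attachment model
  ref <- igraph::sample_pa(500, m = 2, directed = FALSE)
  expect_gt(max(igraph::degree(g)), 3 * mean(igraph::degree(g)))
  expect_lt(abs(mean(igraph::degree(g)) - mean(igraph::degree(ref))), 0.5)
})

test_that("duplication-divergence model yields a simple graph of the right size", {
  cfg <- sim_config(seed = 3, n_nodes = 400,
                    graph_model = "duplication_divergence",
                    model_params = list(p_keep = 0.4, p_link = 0.7))
  g <- simulate_interactome(cfg)
  expect_equal(igraph::vcount(g), 400)
  expect_false(any(igraph::which_loop(g)))
  expect_false(any(igraph::which_multiple(g)))
})

test_that("plant_module at edge_prob 1 induces a complete subgraph", {
  base <- simulate_interactome(sim_config(seed = 4, n_nodes = 300,
                                          model_params = list(p = 0.01)))
  planted <- plant_module(base, size = 12, edge_prob = 1, seed = 5)
  sub <- induce_subnetwork(planted$net, planted$genes)
  expect_equal(igraph::ecount(sub), choose(12, 2))
})

test_that("snowball sample stays connected even with no added edges", {
  base <- simulate_interactome(sim_config(seed = 6, n_nodes = 500,
                                          model_params = list(p = 0.01)))
  planted <- plant_module(base, size = 15, edge_prob = 0, seed = 7)
  sub <- induce_subnetwork(planted$net, planted$genes)
  expect_equal(igraph::components(sub)$no, 1)
})

test_that("planting increases the induced edge count over the background", {
  base <- simulate_interactome(sim_config(seed = 8, n_nodes = 1000,
                                          model_params = list(p = 0.002)))
  planted <- plant_module(base, size = 25, edge_prob = 0.3, seed = 9)
  before <- igraph::ecount(induce_subnetwork(base, planted$genes))
  after <- igraph::ecount(induce_subnetwork(planted$net, planted$genes))
  expect_gt(after, before)
})

test_that("overlapping planted sets share exactly `shared` genes", {
  base <- simulate_interactome(sim_config(seed = 10, n_nodes = 800,
                                          model_params = list(p = 0.003)))
  ps <- plant_overlapping_sets(base, size_a = 20, size_b = 15, shared = 6,
                               seed = 11)
  expect_length(ps$A$genes, 20)
  expect_length(ps$B$genes, 15)
  expect_length(intersect(ps$A$genes, ps$B$genes), 6)
  expect_error(plant_overlapping_sets(base, 10, 10, 11), "shared exceeds")
})

test_that("mean s_AB decreases as the shared fraction grows", {
  base <- simulate_interactome(sim_config(seed = 12, n_nodes = 800,
                                          model_params = list(p = 0.003)))
  mean_sab <- function(shared) {
    mean(vapply(1:6, function(s) {
      ps <- plant_overlapping_sets(base, 20, 20, shared, edge_prob = 0.3,
                                   seed = 100 * shared + s)
      d_a <- module_distance(ps$net, ps$A, ps$A)
      d_b <- module_distance(ps$net, ps$B, ps$B)
      separation(d_a, d_b, module_distance(ps$net, ps$A, ps$B))
    }, numeric(1)))
  }
  expect_lt(mean_sab(10), mean_sab(0))
})

test_that("expression generator plants markers whose within-type mean dominates", {
  sim <- simulate_expression(sim_config(seed = 13, marker_fold = 5,
                                        n_genes_expr = 400,
                                        n_markers_per_type = 20))
  ct <- sim$annotations$cell_type
  ok <- vapply(seq_len(nrow(sim$truth)), function(i) {
    g <- sim$truth$gene[i]; t <- sim$truth$marker_of[i]
    mean(sim$expr[g, ct == t]) > mean(sim$expr[g, ct != t])
  }, logical(1))
  expect_gt(mean(ok), 0.95)
  # marker_fold = 1 plants nothing
  null_sim <- simulate_expression(sim_config(seed = 14, marker_fold = 1,
                                             n_genes_expr = 100))
  expect_equal(nrow(null_sim$truth), 0)
  # bit-identical regeneration
  sim2 <- simulate_expression(sim_config(seed = 13, marker_fold = 5,
                                         n_genes_expr = 400,
                                         n_markers_per_type = 20))
  expect_identical(sim$expr, sim2$expr)
})
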
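# small deterministic expression fixture: 3 types x 4 cells
toy_expr <- function() {
  m <- rbind(
    excl  = c(5, 7, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),  # only in type a
    unif  = c(2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2),  # equal everywhere
    mixed = c(1, 1, 1, 1, 3, 3, 3, 3, 0, 0, 0, 0)
  )
  colnames(m) <- sprintf("c%02d", 1:12)
  ann <- data.frame(cell_id = colnames(m),
                    cell_type = rep(c("a", "b", "c"), each = 4))
  list(expr = m, ann = ann)
}

test_that("specificity of an exclusive marker is 1 in its type, 0 elsewhere", {
  t <- toy_expr()
  s <- specificity_matrix(t$expr, t$ann)
  expect_equal(unname(s["excl", ]), c(1, 0, 0))
  expect_equal(unname(s["unif", ]), rep(1 / 3, 3))
  expect_equal(rowSums(s), c(excl = 1, unif = 1, mixed = 1), tolerance = 1e-9)
})

test_that("specificity matches a brute-force two-loop computation", {
  set.seed(101)
  expr <- matrix(rpois(50 * 200, 3), nrow = 50,
                 dimnames = list(sprintf("g%02d", 1:50), sprintf("c%03d", 1:200)))
  ct <- sample(c("t1", "t2", "t3", "t4"), 200, replace = TRUE)
  ann <- data.frame(cell_id = colnames(expr), cell_type = ct)
  s <- specificity_matrix(expr, ann)
  bf <- bf_specificity(expr, ct)
  expect_equal(unclass(s)[rownames(bf), colnames(bf)], bf, tolerance = 1e-12)
})

test_that("specificity is invariant to global rescaling of expression", {
  t <- toy_expr()
  s1 <- specificity_matrix(t$expr, t$ann)
  s2 <- specificity_matrix(t$expr * 7.3, t$ann)
  expect_equal(unclass(s1), unclass(s2), tolerance = 1e-12)
})

test_that("unannotated cells and single-type inputs are rejected; zero genes dropped", {
  t <- toy_expr()
  expect_error(specificity_matrix(t$expr, t$ann[1:10, ]), "unannotated")
  ann1 <- t$ann; ann1$cell_type <- "only"
  expect_error(specificity_matrix(t$expr, ann1), "2 cell types")
  ex0 <- rbind(t$expr, zero = 0)
  expect_warning(s <- specificity_matrix(ex0, t$ann), "zero expression")
  expect_false("zero" %in% rownames(s))
})

test_that("ewce observed stats sum to the mapped query size", {
  sim <- simulate_expression(sim_config(seed = 111, n_genes_expr = 300,
                                        n_markers_per_type = 20))
  s <- specificity_matrix(sim$expr, sim$annotations)
  q <- rownames(s)[1:25]
  res <- ewce_test(s, q, n_boot = 50, seed = 3)
  expect_equal(sum(res$observed_stat), attr(res, "query_size_used"),
               tolerance = 1e-6)
  expect_true(all((res$fold_change > 1) == (res$observed_stat > res$bootstrap_mean)))
})

test_that("ewce is seed-reproducible and the counting rule is a plain fraction", {
  sim <- simulate_expression(sim_config(seed = 112, n_genes_expr = 200,
                                        n_markers_per_type = 10))
  s <- specificity_matrix(sim$expr, sim$annotations)
  q <- rownames(s)[5:20]
  r1 <- ewce_test(s, q, n_boot = 200, seed = 4)
  r2 <- ewce_test(s, q, n_boot = 200, seed = 4)
  expect_identical(r1$p_value, r2$p_value)
  expect_true(all(abs(r1$p_value * 200 - round(r1$p_value * 200)) < 1e-12))
  expect_equal(r1$bonferroni_p, pmin(1, r1$p_value * nrow(r1)))
})

test_that("planted markers are recovered with Bonferroni significance", {
  sim <- simulate_expression(sim_config(seed = 113, marker_fold = 5,
                                        n_genes_expr = 1000,
                                        n_markers_per_type = 40,
                                        n_cell_types = 4, cells_per_type = 100))
  s <- specificity_matrix(sim$expr, sim$annotations)
  markers2 <- sim$truth$gene[sim$truth$marker_of == "type02"]
  res <- ewce_test(s, markers2, n_boot = 5000, seed = 5)
  expect_equal(res$cell_type[which.min(res$p_value)], "type02")
  expect_lt(res$bonferroni_p[res$cell_type == "type02"], 0.05)
})

test_that("empty mapped query errors; background restriction applies", {
  t <- toy_expr()
  s <- specificity_matrix(t$expr, t$ann)
  expect_error(ewce_test(s, "nope", n_boot = 5), "no query genes")
  r <- ewce_test(s, c("excl", "unif"), n_boot = 10, seed = 1,
                 background = rownames(s))
  expect_s3_class(r, "ewce_result")
})

test_that("expression TSV and MTX readers round-trip a matrix", {
  sim <- simulate_expression(sim_config(seed = 114, n_genes_expr = 30,
                                        n_markers_per_type = 5,
                                        cells_per_type = 10))
  d <- withr::local_tempdir()
  tsv <- file.path(d, "expr.tsv")
  write.table(data.frame(gene = rownames(sim$expr), sim$expr,
                         check.names = FALSE),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  m <- read_expression(tsv)
  expect_equal(m, sim$expr)

  mtx <- file.path(d, "expr.mtx")
  Matrix::writeMM(Matrix::Matrix(sim$expr, sparse = TRUE), mtx)
  writeLines(rownames(sim$expr), file.path(d, "genes.tsv"))
  writeLines(colnames(sim$expr), file.path(d, "barcodes.tsv"))
  ms <- read_expression(mtx)
  expect_equal(as.matrix(ms), sim$expr, ignore_attr = TRUE)
  expect_equal(rownames(ms), rownames(sim$expr))
})
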
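#' Build a cell-type specificity matrix from single-cell expression
#'
#' For gene `g` and cell type `c`, specificity is the mean expression of `g`
#' across cells of type `c` divided by the sum of its mean expression across
#' all types — each gene's row sums to 1, so a value near 1 marks a gene
#' expressed almost exclusively in that type. Genes with zero mean in every
#' type are dropped with a warning. Specificity is invariant to global
#' rescaling of the expression values.
#'
#' @param expr Genes x cells numeric matrix (dense or `Matrix` sparse), with
#'   row names (gene symbols) and column names (cell IDs).
#' @param annotations Data frame with columns `cell_id` and `cell_type`
#'   (first two columns used), or a named character vector `cell_id ->
#'   cell_type`. Every expression column must be annotated.
#' @return A `specificity_matrix`: base matrix genes x cell types of
#'   proportions.
#' @export
specificity_matrix <- function(expr, annotations) {
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("expression matrix needs gene row names and cell column names", call. = FALSE)
  if (is.data.frame(annotations)) {
    ann <- setNames(as.character(annotations[[2]]), as.character(annotations[[1]]))
  } else {
    ann <- annotations
  }
  missing_cells <- setdiff(colnames(expr), names(ann))
  if (length(missing_cells))
    stop("unannotated cells: ", paste(head(missing_cells, 5), collapse = ", "),
         call. = FALSE)
  types <- ann[colnames(expr)]
  type_levels <- sort(unique(types))
  if (length(type_levels) < 2L) stop("need at least 2 cell types", call. = FALSE)

  # per-type mean expression via an indicator matrix (works for sparse expr)
  ind <- vapply(type_levels, function(tt) as.numeric(types == tt),
                numeric(ncol(expr)))
  counts <- colSums(ind)
  means <- as.matrix(expr %*% ind)
  means <- sweep(means, 2L, counts, "/")
  colnames(means) <- type_levels

  tot <- rowSums(means)
  zero <- tot == 0
  if (any(zero)) {
    warning(sprintf("dropped %d genes with zero expression in all types", sum(zero)),
            call. = FALSE)
    means <- means[!zero, , drop = FALSE]
    tot <- tot[!zero]
  }
  if (nrow(means) == 0L) stop("no expressed genes", call. = FALSE)
  spec <- means / tot
  class(spec) <- c("specificity_matrix", class(spec))
  spec
}

#' @export
print.specificity_matrix <- function(x, ...) {
  cat(sprintf("Specificity matrix: %d genes x %d cell types\n",
              nrow(x), ncol(x)))
  cat("  cell types:", paste(colnames(x), collapse = ", "), "\n")
  invisible(x)
}

#' Expression-weighted cell-type enrichment (bootstrap test)
#'
#' Tests whether a gene list is more specifically expressed in each cell type
#' than random gene lists of the same size. The per-type statistic is the sum
#' of specificity values over the mapped query genes; each bootstrap
#' replicate draws that many genes uniformly without replacement from the
#' background (all genes in the specificity matrix by default) and recomputes
#' it. `p = P(bootstrap >= observed)` per type (ties inclusive), with
#' Bonferroni adjustment across cell types.
#'
#' @param spec A [specificity_matrix].
#' @param query A [gene_set] or character vector; genes absent from `spec`
#'   are dropped (the mapped count is reported in the result).
#' @param n_boot Number of bootstrap replicates (default 100000).
#' @param seed Integer seed for reproducibility.
#' @param background Optional character vector restricting the genes sampled
#'   in the bootstrap (default: all rows of `spec`).
#' @param pseudocount If `TRUE`, report `(r+1)/(n_boot+1)`.
#' @return An `ewce_result`: data frame with one row per cell type
#'   (`cell_type`, `observed_stat`, `bootstrap_mean`, `bootstrap_sd`,
#'   `fold_change`, `p_value`, `bonferroni_p`), attributes `n_boot`, `seed`,
#'   `query_size_used`.
#' @export
ewce_test <- function(spec, query, n_boot = 100000, seed = NULL,
                      background = NULL, pseudocount = FALSE) {
  stopifnot(n_boot >= 1)
  genes <- rownames(spec)
  if (is.null(background)) background <- genes
  background <- intersect(background, genes)
  if (length(background) < 2L) stop("background too small", call. = FALSE)
  q <- intersect(as_gene_vector(query), genes)
  if (length(q) == 0L) stop("no query genes in the specificity matrix", call. = FALSE)
  k <- length(q)
  if (k > length(background))
    stop("query larger than the background gene set", call. = FALSE)

  m <- unclass(spec)
  observed <- colSums(m[q, , drop = FALSE])

  boots <- with_seed(seed, {
    out <- matrix(NA_real_, nrow = n_boot, ncol = ncol(m))
    for (r in seq_len(n_boot)) {
      out[r, ] <- colSums(m[sample(background, k), , drop = FALSE])
    }
    out
  })

  p <- vapply(seq_len(ncol(m)), function(j) {
    empirical_p(boots[, j], observed[j], tail = "greater", pseudocount = pseudocount)
  }, numeric(1))
  bmean <- colMeans(boots)

  out <- data.frame(
    cell_type = colnames(m),
    observed_stat = unname(observed),
    bootstrap_mean = bmean,
    bootstrap_sd = apply(boots, 2L, sd),
    fold_change = unname(observed) / bmean,
    p_value = p,
    bonferroni_p = pmin(1, p * ncol(m)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "n_boot") <- n_boot
  attr(out, "seed") <- seed
  attr(out, "query_size_used") <- k
  class(out) <- c("ewce_result", "data.frame")
  out
}

#' @export
print.ewce_result <- function(x, ...) {
  cat(sprintf("EWCE bootstrap test: %d query genes, %d bootstraps, %d cell types\n",
              attr(x, "query_size_used"), attr(x, "n_boot"), nrow(x)))
  df <- as.data.frame(unclass(x))
  df <- df[order(df$p_value), ]
  df$observed_stat <- signif(df$observed_stat, 4)
  df$bootstrap_mean <- signif(df$bootstrap_mean, 4)
  df$bootstrap_sd <- signif(df$bootstrap_sd, 4)
  df$fold_change <- signif(df$fold_change, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Read a genes-by-cells expression matrix
#'
#' TSV layout: genes in rows (first column = gene symbol, header = cell IDs).
#' MatrixMarket layout: `path` is the `.mtx` file, with `genes.tsv` and
#' `barcodes.tsv` beside it (or given explicitly).
#'
#' @param path Path to the `.tsv` or `.mtx` file.
#' @param format `"tsv"` or `"mtx"` (guessed from the extension by default).
#' @param genes_file,barcodes_file Row/column name files for MTX input.
#' @return Numeric matrix (dense for TSV, `dgCMatrix` for MTX), genes x cells.
#' @export
read_expression <- function(path, format = NULL, genes_file = NULL,
                            barcodes_file = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(format))
    format <- if (grepl("\\.mtx$", path)) "mtx" else "tsv"
  if (format == "tsv") {
    tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- as.character(tab[[1]])
    storage.mode(m) <- "double"
    m
  } else {
    m <- Matrix::readMM(path)
    dir <- dirname(path)
    if (is.null(genes_file)) genes_file <- file.path(dir, "genes.tsv")
    if (is.null(barcodes_file)) barcodes_file <- file.path(dir, "barcodes.tsv")
    rownames(m) <- readLines(genes_file, warn = FALSE)
    colnames(m) <- readLines(barcodes_file, warn = FALSE)
    methods::as(m, "CsparseMatrix")
  }
}

#' Read a two-column cell annotation table
#'
#' TSV with cell ID in column 1 and cell type in column 2; a header line is
#' detected and kept only if its first field is `cell_id`.
#'
#' @param path Path to the TSV.
#' @return Data frame with columns `cell_id`, `cell_type`.
#' @export
read_cell_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- strsplit(readLines(path, n = 1L), "\t")[[1]][1]
  tab <- read.delim(path, header = identical(first, "cell_id"),
                    stringsAsFactors = FALSE)
  tab <- tab[, 1:2]
  names(tab) <- c("cell_id", "cell_type")
  tab
}
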
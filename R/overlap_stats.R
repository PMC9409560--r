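#' Fisher's exact test for gene-set overlap
#'
#' Builds the 2x2 membership table of two gene sets over a background
#' universe and tests over-representation with Fisher's exact test
#' (two-sided, point-probability rule). Genes outside the universe are
#' dropped with a warning. The universe may be given as a gene list or as an
#' integer size (e.g. `20000` for the protein-coding genome); with an integer
#' universe the sets are assumed to lie inside it.
#'
#' @param A,B Gene sets ([gene_set] or character).
#' @param universe Background: a [gene_set]/character vector, or a single
#'   integer count.
#' @return An `overlap_result` object: list with `table` (named counts `a`
#'   in both, `b` in B only, `c` in A only, `d` in neither), `odds_ratio`
#'   (sample OR `ad/bc`; `Inf` when `b*c == 0`), `odds_ratio_cmle` (the
#'   conditional-MLE estimate printed by [stats::fisher.test()]), `p_value`,
#'   `overlap_genes`, `universe_size`.
#' @examples
#' fisher_overlap(c("A", "B", "C"), c("B", "C", "D"), universe = 100)
#' @export
fisher_overlap <- function(A, B, universe) {
  a_genes <- as_gene_vector(A)
  b_genes <- as_gene_vector(B)
  if (is.numeric(universe) && length(universe) == 1L) {
    n_univ <- as.integer(universe)
  } else {
    univ <- as_gene_vector(universe)
    n_univ <- length(univ)
    drop_a <- setdiff(a_genes, univ)
    drop_b <- setdiff(b_genes, univ)
    if (length(drop_a) || length(drop_b))
      warning(sprintf("dropped %d genes of A and %d of B not in the universe",
                      length(drop_a), length(drop_b)), call. = FALSE)
    a_genes <- intersect(a_genes, univ)
    b_genes <- intersect(b_genes, univ)
  }
  if (n_univ < 2L) stop("universe must contain at least 2 genes", call. = FALSE)
  overlap <- intersect(a_genes, b_genes)
  a <- length(overlap)
  b <- length(b_genes) - a
  cc <- length(a_genes) - a
  d <- n_univ - a - b - cc
  if (d < 0) stop("universe smaller than the union of the two sets", call. = FALSE)
  tab <- matrix(c(a, cc, b, d), nrow = 2)
  ft <- fisher.test(tab)
  or_sample <- if (b * cc == 0) Inf else (a * d) / (b * cc)
  structure(list(
    table = c(a = a, b = b, c = cc, d = d),
    universe_size = n_univ,
    odds_ratio = or_sample,
    odds_ratio_cmle = unname(ft$estimate),
    p_value = ft$p.value,
    overlap_genes = sort(overlap)
  ), class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("Gene-set overlap (Fisher's exact test)\n")
  cat(sprintf("  overlap %d | A-only %d | B-only %d | neither %d (universe %d)\n",
              x$table["a"], x$table["c"], x$table["b"], x$table["d"],
              x$universe_size))
  cat(sprintf("  sample OR = %.3f (CMLE %.3f), two-sided p = %.4g\n",
              x$odds_ratio, x$odds_ratio_cmle, x$p_value))
  if (length(x$overlap_genes))
    cat("  overlap genes:", paste(x$overlap_genes, collapse = ", "), "\n")
  invisible(x)
}

#' Multiple-testing adjustment
#'
#' Thin validated wrapper around [stats::p.adjust()] offering
#' Benjamini-Hochberg (`"bh"`) and Bonferroni (`"bonferroni"`), preserving
#' input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param method `"bh"` or `"bonferroni"`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("bh", "bonferroni")) {
  method <- match.arg(method)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(p, method = if (method == "bh") "BH" else "bonferroni")
}

#' Hypergeometric enrichment against a GMT collection
#'
#' For each set in the collection, tests whether the query gene list overlaps
#' it more than expected under random draws from the universe:
#' upper-tail hypergeometric `p = P(X >= overlap)` with
#' `X ~ Hypergeom(universe, set ∩ universe, query ∩ universe)`. BH-FDR and
#' Bonferroni adjustments are computed over all tested sets; results are
#' sorted by p-value. Sets with no gene in the universe are skipped with a
#' warning.
#'
#' @param query A [gene_set] or character vector.
#' @param collection Named list of character vectors (see [read_gmt()]) or a
#'   path to a `.gmt` file.
#' @param universe Background gene list ([gene_set] or character).
#' @return An `enrichment_result`: data frame with columns `set_name`,
#'   `overlap`, `set_size`, `query_size`, `universe_size`, `p_value`, `fdr`,
#'   `bonferroni`, `overlap_genes` (semicolon-joined), sorted by `p_value`.
#' @export
gmt_enrichment <- function(query, collection, universe) {
  if (is.character(collection) && length(collection) == 1L && file.exists(collection))
    collection <- read_gmt(collection)
  stopifnot(is.list(collection), length(collection) >= 1L)
  univ <- as_gene_vector(universe)
  q <- intersect(as_gene_vector(query), univ)
  if (length(q) == 0L) stop("query has no genes in the universe", call. = FALSE)
  n_univ <- length(univ)

  rows <- lapply(names(collection), function(nm) {
    s <- intersect(collection[[nm]], univ)
    if (length(s) == 0L) {
      warning(sprintf("set '%s' has no genes in the universe; skipped", nm), call. = FALSE)
      return(NULL)
    }
    ov <- intersect(q, s)
    p <- phyper(length(ov) - 1L, length(s), n_univ - length(s), length(q),
                lower.tail = FALSE)
    data.frame(set_name = nm, overlap = length(ov), set_size = length(s),
               query_size = length(q), universe_size = n_univ, p_value = p,
               overlap_genes = paste(sort(ov), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) stop("no testable sets in the collection", call. = FALSE)
  out <- do.call(rbind, rows)
  out$fdr <- adjust_pvalues(out$p_value, "bh")
  out$bonferroni <- adjust_pvalues(out$p_value, "bonferroni")
  out <- out[order(out$p_value, out$set_name),
             c("set_name", "overlap", "set_size", "query_size", "universe_size",
               "p_value", "fdr", "bonferroni", "overlap_genes")]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' @export
print.enrichment_result <- function(x, n = 10L, ...) {
  cat(sprintf("Gene-set enrichment: %d sets tested, query size %d, universe %d\n",
              nrow(x), x$query_size[1], x$universe_size[1]))
  df <- as.data.frame(unclass(x))[seq_len(min(n, nrow(x))),
                                  c("set_name", "overlap", "set_size",
                                    "p_value", "fdr", "bonferroni")]
  df$p_value <- signif(df$p_value, 3)
  df$fdr <- signif(df$fdr, 3)
  df$bonferroni <- signif(df$bonferroni, 3)
  print(df, row.names = FALSE)
  if (nrow(x) > n) cat(sprintf("  ... %d more sets\n", nrow(x) - n))
  invisible(x)
}
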
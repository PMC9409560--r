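#' Construct a gene set
#'
#' A gene set is a named, deduplicated, order-preserving collection of gene
#' symbols. Symbols are whitespace-trimmed; matching elsewhere in the package
#' is case-sensitive exact match unless `uppercase = TRUE` is requested at
#' load time.
#'
#' @param genes Character vector of gene symbols.
#' @param name Single string naming the set (e.g. `"risk_genes"`).
#' @param uppercase Force symbols to upper case.
#' @return An object of class `gene_set`: a list with elements `name` and
#'   `genes` (unique character vector in first-seen order).
#' @examples
#' gene_set(c("SCN1A", "SCN1A", "KCNQ2"), "risk")
#' @export
gene_set <- function(genes, name = "gene_set", uppercase = FALSE) {
  genes <- clean_symbols(genes, uppercase = uppercase)
  n_dup <- length(genes) - length(unique(genes))
  genes <- unique(genes)
  if (n_dup > 0) message(sprintf("gene_set '%s': dropped %d duplicate symbols", name, n_dup))
  structure(list(name = as.character(name)[1], genes = genes), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("Gene set '%s': %d genes\n", x$name, length(x$genes)))
  shown <- head(x$genes, 10L)
  cat(" ", paste(shown, collapse = ", "),
      if (length(x$genes) > 10L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$genes)

#' @export
as.character.gene_set <- function(x, ...) x$genes

# Internal: accept a gene_set or a bare character vector.
as_gene_vector <- function(x) {
  if (inherits(x, "gene_set")) x$genes else clean_symbols(x)
}

#' Read a gene list from a text file
#'
#' One symbol per line; blank lines and lines starting with `#` are ignored;
#' duplicates are dropped (count reported via `message()`).
#'
#' @param path Path to the file.
#' @param name Name for the resulting set (defaults to the file name).
#' @inheritParams gene_set
#' @return A [gene_set].
#' @export
read_gene_set <- function(path, name = basename(path), uppercase = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("no gene symbols in file: ", path, call. = FALSE)
  gene_set(lines, name = name, uppercase = uppercase)
}

#' Write a gene list to a text file
#'
#' @param x A [gene_set] or character vector.
#' @param path Output path; one symbol per line.
#' @export
write_gene_set <- function(x, path) {
  writeLines(as_gene_vector(x), path)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: `name<TAB>description<TAB>gene1<TAB>gene2...`, one set per
#' line. Parsing is delegated to [fgsea::gmtPathways()].
#'
#' @param path Path to a `.gmt` file.
#' @return Named list of character vectors (one per set), with each member
#'   list deduplicated.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sets <- fgsea::gmtPathways(path)
  if (length(sets) == 0L) stop("no gene sets in GMT file: ", path, call. = FALSE)
  lapply(sets, function(g) unique(clean_symbols(g)))
}

#' Write a GMT gene-set collection
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions
#'   (defaults to `"na"`).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column ortholog table
#'
#' TSV with source symbol in column 1 and target symbol in column 2
#' (e.g. human to mouse). Only one-to-one pairs are retained: any source or
#' target symbol participating in more than one pair is dropped.
#'
#' @param path Path to the TSV (no header; `#` comment lines ignored).
#' @return Named character vector mapping source to target.
#' @export
read_ortholog_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- read.delim(path, header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("ortholog table needs two columns: ", path, call. = FALSE)
  src <- clean_symbols(tab[[1]])
  tgt <- trimws(as.character(tab[[2]]))
  keep <- nzchar(src) & nzchar(tgt)
  src <- src[keep]; tgt <- tgt[keep]
  dup <- duplicated(src) | duplicated(src, fromLast = TRUE) |
    duplicated(tgt) | duplicated(tgt, fromLast = TRUE)
  if (any(dup)) {
    message(sprintf("ortholog table: dropped %d non one-to-one pairs", sum(dup)))
    src <- src[!dup]; tgt <- tgt[!dup]
  }
  if (length(src) == 0L) stop("ortholog table empty after 1:1 filtering", call. = FALSE)
  setNames(tgt, src)
}

#' Map gene symbols through an ortholog table
#'
#' Genes absent from the table are dropped (count reported). Order of the
#' retained genes is preserved.
#'
#' @param genes A [gene_set] or character vector.
#' @param table Named character vector as returned by [read_ortholog_table()].
#' @param name Name for the mapped set.
#' @return A [gene_set] of mapped symbols.
#' @export
map_orthologs <- function(genes, table, name = NULL) {
  g <- as_gene_vector(genes)
  if (length(table) == 0L) stop("ortholog table is empty", call. = FALSE)
  hit <- g %in% names(table)
  n_drop <- sum(!hit)
  if (n_drop > 0) message(sprintf("map_orthologs: %d of %d genes unmapped, dropped", n_drop, length(g)))
  mapped <- unname(table[g[hit]])
  if (length(mapped) == 0L) warning("no genes could be mapped", call. = FALSE)
  if (is.null(name)) {
    name <- if (inherits(genes, "gene_set")) paste0(genes$name, "_mapped") else "mapped"
  }
  gene_set(mapped, name = name)
}
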
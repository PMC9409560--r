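#' Canonicalize an edge table into an interactome graph
#'
#' The interactome is an undirected simple [igraph::igraph] over gene-symbol
#' vertex names: self-loops are dropped, duplicate edges (in either
#' orientation) collapsed, and symbols whitespace-trimmed.
#'
#' @param edges Two-column character matrix or data frame of endpoints.
#' @param uppercase Force symbols to upper case.
#' @return An undirected simple `igraph` graph.
#' @export
interactome <- function(edges, uppercase = FALSE) {
  edges <- as.matrix(edges)[, 1:2, drop = FALSE]
  a <- clean_symbols_keep(edges[, 1], uppercase)
  b <- clean_symbols_keep(edges[, 2], uppercase)
  bad <- !nzchar(a) | !nzchar(b)
  if (any(bad)) stop("empty gene symbol in edge rows: ",
                     paste(head(which(bad), 5), collapse = ", "), call. = FALSE)
  loops <- a == b
  if (any(loops)) message(sprintf("interactome: dropped %d self-loops", sum(loops)))
  a2 <- a[!loops]; b2 <- b[!loops]
  if (length(a2) == 0L) stop("interactome has no edges after cleaning", call. = FALSE)
  key <- paste(pmin(a2, b2), pmax(a2, b2), sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) message(sprintf("interactome: collapsed %d duplicate edges", sum(dup)))
  g <- igraph::graph_from_edgelist(cbind(a2[!dup], b2[!dup]), directed = FALSE)
  g
}

# trim but keep positions (no dropping) so rows stay aligned
clean_symbols_keep <- function(x, uppercase = FALSE) {
  x <- trimws(as.character(x))
  if (uppercase) x <- toupper(x)
  x
}

#' Read an interactome from an edge-list file
#'
#' Supports plain two-column TSV/whitespace edge lists (`fmt = "tsv"`,
#' `#` comment lines ignored) and the SIF dialect
#' `nodeA<TAB>relation<TAB>nodeB[<TAB>nodeC...]` (`fmt = "sif"`, one edge per
#' trailing node). Self-loops and duplicate edges are dropped with a reported
#' count.
#'
#' @param path Path to the file.
#' @param fmt `"tsv"` or `"sif"`.
#' @inheritParams interactome
#' @return An undirected simple `igraph` graph.
#' @export
read_edge_list <- function(path, fmt = c("tsv", "sif"), uppercase = FALSE) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  idx <- which(keep)
  if (length(idx) == 0L) stop("no edges in file: ", path, call. = FALSE)
  fields <- strsplit(trimws(lines[idx]), "[ \t]+")
  pairs <- vector("list", length(idx))
  for (i in seq_along(idx)) {
    f <- fields[[i]]
    if (fmt == "tsv") {
      if (length(f) < 2L)
        stop(sprintf("malformed edge line %d in %s", idx[i], path), call. = FALSE)
      pairs[[i]] <- cbind(f[1], f[2])
    } else {
      if (length(f) < 3L)
        stop(sprintf("malformed SIF line %d in %s (need node, relation, node)", idx[i], path),
             call. = FALSE)
      pairs[[i]] <- cbind(f[1], f[3:length(f)])
    }
  }
  edges <- do.call(rbind, pairs)
  g <- interactome(edges, uppercase = uppercase)
  message(sprintf("read_edge_list: %d nodes, %d edges from %s",
                  igraph::vcount(g), igraph::ecount(g), path))
  g
}

#' Write an interactome as a two-column TSV edge list
#'
#' Edges are written in canonical order (lexicographically smaller endpoint
#' first, rows sorted) so that write/read round-trips are byte-stable.
#'
#' @param net An `igraph` graph with named vertices.
#' @param path Output path.
#' @export
write_edge_list <- function(net, path) {
  el <- igraph::as_edgelist(net)
  if (nrow(el) > 0) {
    el <- cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
    el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  }
  write.table(el, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Union several edge lists into one interactome
#'
#' Reads each file with [read_edge_list()] and unions node and edge sets,
#' mirroring how multi-database interactomes are assembled from per-source
#' edge lists.
#'
#' @param paths Character vector of edge-list paths.
#' @param fmt Format shared by all files.
#' @inheritParams interactome
#' @return An undirected simple `igraph` graph.
#' @export
merge_edge_lists <- function(paths, fmt = "tsv", uppercase = FALSE) {
  stopifnot(length(paths) >= 1L)
  els <- lapply(paths, function(p) {
    igraph::as_edgelist(read_edge_list(p, fmt = fmt, uppercase = uppercase))
  })
  interactome(do.call(rbind, els))
}

#' Induce the subnetwork spanned by a gene set
#'
#' Returns the subgraph on `genes` intersected with the network's nodes,
#' keeping only edges with both endpoints in that intersection.
#'
#' @param net An `igraph` interactome.
#' @param genes A [gene_set] or character vector.
#' @return An `igraph` subgraph (possibly empty, with a warning).
#' @export
induce_subnetwork <- function(net, genes) {
  g <- as_gene_vector(genes)
  present <- intersect(g, igraph::V(net)$name)
  if (length(present) == 0L)
    warning("no input genes found in the network; returning empty graph", call. = FALSE)
  igraph::induced_subgraph(net, present)
}
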
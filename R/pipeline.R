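#' Read a pipeline configuration
#'
#' YAML with input paths (`network`, `genes_a`, `genes_b`, `universe`,
#' optional `gmt`, `expression`, `annotations`, `orthologs`), run parameters
#' (`n_perm_localization` 5000, `n_perm_proximity` 1000, `n_boot_ewce`
#' 100000), thresholds (`enrichment_fdr` 0.01, `ewce_alpha` 0.05), `seed`,
#' `outdir`, and an optional `stages` list of stage names to run.
#'
#' @param path Path to the YAML file.
#' @return Named list (class `pipeline_config`) with defaults filled in.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(n_perm_localization = 5000L, n_perm_proximity = 1000L,
                   n_boot_ewce = 100000L, enrichment_fdr = 0.01,
                   ewce_alpha = 0.05, seed = 1L, outdir = "netoverlap_out",
                   universe_size = 20000L,
                   stages = c("overlap", "localization", "proximity",
                              "coexpression", "ewce", "enrichment"))
  for (nm in names(defaults)) if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  stopifnot(cfg$n_perm_localization >= 1, cfg$n_perm_proximity >= 1,
            cfg$n_boot_ewce >= 1, cfg$enrichment_fdr > 0,
            cfg$enrichment_fdr < 1, cfg$ewce_alpha > 0, cfg$ewce_alpha < 1)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full interactome-overlap workflow
#'
#' Executes, in order: gene-set overlap (Fisher) -> topology + localization
#' -> network proximity -> co-expression overlap (Fisher against
#' `coexpression` gene list, if given) -> EWCE -> GMT enrichment. Each stage
#' writes a TSV (tabular results) or JSON (scalar results) into
#' `cfg$outdir`, and a `manifest.json` records package version, inputs,
#' per-stage seeds and output files. Per-stage seeds are derived
#' deterministically as `seed + stage index`, so stages can be re-run
#' independently and reruns are byte-identical. Stages whose optional inputs
#' are missing are skipped with a warning; a failing stage aborts with its
#' name.
#'
#' @param cfg A `pipeline_config` (see [read_pipeline_config()]) or a path
#'   to the YAML file.
#' @return Invisibly, a list with per-stage results and the manifest.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  for (req in c("network", "genes_a", "genes_b")) {
    if (is.null(cfg[[req]])) stop("config misses required input: ", req, call. = FALSE)
    if (!file.exists(cfg[[req]])) stop("input not found: ", cfg[[req]], call. = FALSE)
  }

  net <- read_edge_list(cfg$network)
  A <- read_gene_set(cfg$genes_a, name = "genes_a")
  B <- read_gene_set(cfg$genes_b, name = "genes_b")
  universe <- if (!is.null(cfg$universe) && file.exists(cfg$universe))
    read_gene_set(cfg$universe, name = "universe")$genes else cfg$universe_size

  stage_idx <- c(overlap = 1L, localization = 2L, proximity = 3L,
                 coexpression = 4L, ewce = 5L, enrichment = 6L)
  stage_seed <- function(s) as.integer(cfg$seed) + stage_idx[[s]]
  results <- list()
  manifest_stages <- list()
  note <- function(stage, file) {
    manifest_stages[[stage]] <<- list(stage = stage, output = basename(file),
                                      seed = unname(stage_seed(stage)))
  }
  run_stage <- function(stage, fn) {
    if (!(stage %in% cfg$stages)) return(invisible(NULL))
    tryCatch(fn(), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }

  run_stage("overlap", function() {
    res <- fisher_overlap(A, B, universe)
    f <- file.path(cfg$outdir, "overlap.json")
    jsonlite::write_json(list(table = as.list(res$table),
                              universe_size = res$universe_size,
                              odds_ratio = res$odds_ratio,
                              odds_ratio_cmle = res$odds_ratio_cmle,
                              p_value = res$p_value,
                              overlap_genes = res$overlap_genes),
                         f, auto_unbox = TRUE, digits = NA)
    results$overlap <<- res; note("overlap", f)
  })

  ab <- gene_set(union(A$genes, B$genes), name = "network_genes")
  run_stage("localization", function() {
    res <- localization_test(net, ab, n_perm = cfg$n_perm_localization,
                             seed = stage_seed("localization"))
    f <- file.path(cfg$outdir, "localization.tsv")
    write.table(as.data.frame(unclass(res)), f, sep = "\t", quote = FALSE,
                row.names = FALSE)
    results$localization <<- res; note("localization", f)
  })

  run_stage("proximity", function() {
    res <- proximity_test(net, A, B, n_perm = cfg$n_perm_proximity,
                          seed = stage_seed("proximity"))
    f <- file.path(cfg$outdir, "proximity.json")
    jsonlite::write_json(unclass(res)[c("d_A", "d_B", "d_AB", "s_AB", "p_value",
                                        "random_mean", "random_sd",
                                        "n_permutations", "convention",
                                        "n_A", "n_B")],
                         f, auto_unbox = TRUE, digits = NA)
    results$proximity <<- res; note("proximity", f)
  })

  # genes of the induced network, used by the coexpression / ewce /
  # enrichment stages (the paper's "interaction network genes")
  net_genes <- gene_set(igraph::V(induce_subnetwork(net, ab))$name,
                        name = "induced_network_genes")

  if ("coexpression" %in% cfg$stages && !is.null(cfg$coexpression) &&
      file.exists(cfg$coexpression)) {
    run_stage("coexpression", function() {
      co <- read_gene_set(cfg$coexpression, name = "coexpression")
      res <- fisher_overlap(net_genes, co, universe)
      f <- file.path(cfg$outdir, "coexpression_overlap.json")
      jsonlite::write_json(list(table = as.list(res$table),
                                odds_ratio = res$odds_ratio,
                                p_value = res$p_value,
                                overlap_genes = res$overlap_genes),
                           f, auto_unbox = TRUE, digits = NA)
      results$coexpression <<- res; note("coexpression", f)
    })
  } else if ("coexpression" %in% cfg$stages) {
    warning("coexpression gene list missing; stage skipped", call. = FALSE)
  }

  if ("ewce" %in% cfg$stages && !is.null(cfg$expression) &&
      file.exists(cfg$expression)) {
    run_stage("ewce", function() {
      expr <- read_expression(cfg$expression)
      ann <- read_cell_annotations(cfg$annotations)
      spec <- specificity_matrix(expr, ann)
      query <- net_genes
      if (!is.null(cfg$orthologs) && file.exists(cfg$orthologs)) {
        query <- map_orthologs(query, read_ortholog_table(cfg$orthologs))
      }
      res <- ewce_test(spec, query, n_boot = cfg$n_boot_ewce,
                       seed = stage_seed("ewce"))
      f <- file.path(cfg$outdir, "ewce.tsv")
      write.table(as.data.frame(unclass(res)), f, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      results$ewce <<- res; note("ewce", f)
    })
  } else if ("ewce" %in% cfg$stages) {
    warning("expression input missing; ewce stage skipped", call. = FALSE)
  }

  if ("enrichment" %in% cfg$stages && !is.null(cfg$gmt) &&
      file.exists(cfg$gmt)) {
    run_stage("enrichment", function() {
      univ_genes <- if (is.character(universe)) universe else igraph::V(net)$name
      res <- gmt_enrichment(net_genes, cfg$gmt, univ_genes)
      f <- file.path(cfg$outdir, "enrichment.tsv")
      write.table(as.data.frame(unclass(res)), f, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      results$enrichment <<- res; note("enrichment", f)
    })
  } else if ("enrichment" %in% cfg$stages) {
    warning("GMT collection missing; enrichment stage skipped", call. = FALSE)
  }

  manifest <- list(
    package = "netoverlap",
    version = as.character(utils::packageVersion("netoverlap")),
    seed = cfg$seed,
    inputs = Filter(Negate(is.null),
                    cfg[c("network", "genes_a", "genes_b", "universe", "gmt",
                          "expression", "annotations", "orthologs",
                          "coexpression")]),
    input_md5 = lapply(Filter(file.exists, unlist(
      cfg[c("network", "genes_a", "genes_b")])), function(p) unname(tools::md5sum(p))),
    stages = unname(manifest_stages)
  )
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(results = results, manifest = manifest))
}
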
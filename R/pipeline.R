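#' Pipeline run configuration
#'
#' Collects every stage parameter in one serializable object; the
#' configuration actually used is written beside the outputs of each run.
#'
#' @param interactions interaction evidence TSV path.
#' @param modules module assignment TSV (`gene`, `module_id`).
#' @param regulation regulation TSV (`regulator`, `module_id`).
#' @param regulators regulator table TSV (defaults to the packaged table).
#' @param gmt annotation GMT path (optional; enrichment stage skipped work
#'   if absent is an error — pass NULL to run without annotations).
#' @param dag term hierarchy TSV (optional).
#' @param out_dir output directory.
#' @param dialect an [interaction_dialect()].
#' @param target_taxon taxon filter (default mouse).
#' @param index similarity index for the PNSM.
#' @param ap an [ap_config()]; the pipeline default enables a tiny
#'   tie-breaking jitter (`noise_scale = 1e-6`) because neighborhood-overlap
#'   matrices routinely contain exactly tied similarities that otherwise
#'   make the messages oscillate.
#' @param min_genes exemplar/cell-type association threshold.
#' @param alpha enrichment significance level.
#' @param seed top-level seed; all stage randomness derives from it.
#' @return A list of class `run_config`.
#' @export
run_config <- function(interactions, modules, regulation,
                       regulators = system.file("extdata", "immgen_regulators.tsv",
                                                package = "pnsmap"),
                       gmt = NULL, dag = NULL, out_dir,
                       dialect = interaction_dialect(),
                       target_taxon = 10090L, index = "simpson",
                       ap = ap_config(noise_scale = 1e-6), min_genes = 1L,
                       alpha = 0.05,
                       seed = 1L) {
  structure(list(interactions = interactions, modules = modules,
                 regulation = regulation, regulators = regulators,
                 gmt = gmt, dag = dag, out_dir = out_dir, dialect = dialect,
                 target_taxon = target_taxon, index = index, ap = ap,
                 min_genes = min_genes, alpha = alpha, seed = as.integer(seed)),
            class = "run_config")
}

manifest_entry <- function(stage, paths) {
  paths <- unlist(paths)
  list(stage = stage,
       artifacts = as.list(stats::setNames(unname(tools::md5sum(paths)), paths)))
}

#' Run the full differential protein-network pipeline
#'
#' Executes the stages in order — interaction filtering, PNSM
#' construction, affinity propagation clustering, lineage integration,
#' term enrichment, and network export — writing every artifact under
#' `config$out_dir` together with a manifest (stage list with md5
#' checksums of each artifact) and the configuration used. Any stage
#' failure aborts with the stage named; missing inputs abort before any
#' stage runs.
#'
#' @param config a [run_config()].
#' @return The manifest (list with one entry per stage), invisibly; also
#'   written as `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  required <- c(interactions = config$interactions, modules = config$modules,
                regulation = config$regulation, regulators = config$regulators,
                gmt = config$gmt, dag = config$dag)
  missing <- required[!file.exists(required)]
  if (length(missing)) {
    stop_pnsmap(sprintf("missing input file(s) before any stage ran: %s",
                        paste(sprintf("%s (%s)", names(missing), missing),
                              collapse = ", ")), "pnsmap_preflight_error")
  }
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e) {
      stop_pnsmap(sprintf("pipeline stage '%s' failed: %s", stage,
                          conditionMessage(e)), "pnsmap_pipeline_error")
    })
  }

  # 1. filter
  network <- run_stage("filter", function() {
    recs <- load_interactions(config$interactions, config$dialect)
    filter_interactions(recs, target_taxon = config$target_taxon)
  })
  write_edge_list(network, file.path(out, "filtered_edges.tsv"))
  write_network_sif(network, file.path(out, "filtered_edges.sif"))
  manifest$filter <- manifest_entry("filter", file.path(out, c(
    "filtered_edges.tsv", "filtered_edges.sif")))

  # 2. pnsm
  modules <- load_module_table(config$modules)
  pnsm <- run_stage("pnsm", function() {
    build_pnsm(network, modules$gene, index = config$index)
  })
  write_pnsm(pnsm, file.path(out, "pnsm.tsv"))
  manifest$pnsm <- manifest_entry("pnsm", file.path(out, "pnsm.tsv"))

  # 3. cluster
  ap <- config$ap
  ap$seed <- config$seed
  result <- run_stage("cluster", function() run_affinity_propagation(pnsm, ap))
  write_clusters(result, file.path(out, "clusters.tsv"),
                 file.path(out, "cluster_meta.json"))
  manifest$cluster <- manifest_entry("cluster", file.path(out, c(
    "clusters.tsv", "cluster_meta.json")))

  # 4. integrate
  lmap <- run_stage("integrate", function() {
    lineage_map(load_regulator_table(config$regulators), modules,
                load_regulation_table(config$regulation))
  })
  table <- run_stage("integrate", function() {
    associate_exemplars(result, lmap, min_genes = config$min_genes)
  })
  write_exemplar_lineage_table(table, file.path(out, "exemplar_lineage.tsv"))
  coverage <- module_coverage(modules, network)
  utils::write.table(coverage, file.path(out, "module_coverage.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cell_bip <- build_cell_exemplar_bipartite(table)
  reg_bip <- build_regulator_module_multigraph(result, lmap)
  export_network(cell_bip, file.path(out, "cell_exemplar.graphml"), "graphml")
  export_network(reg_bip, file.path(out, "regulator_module.graphml"), "graphml")
  manifest$integrate <- manifest_entry("integrate", file.path(out, c(
    "exemplar_lineage.tsv", "module_coverage.tsv",
    "cell_exemplar.graphml", "regulator_module.graphml")))

  # 5. enrich
  enr <- run_stage("enrich", function() {
    if (is.null(config$gmt)) {
      return(data.frame(exemplar = character(0), term = character(0),
                        p_value = numeric(0)))
    }
    ann <- read_gmt(config$gmt)
    if (!is.null(config$dag)) {
      ann <- propagate_annotations(read_dag(config$dag), ann)
    }
    enrich_exemplars(result, ann, universe = pnsm$genes, alpha = config$alpha)
  })
  utils::write.table(enr, file.path(out, "enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$enrich <- manifest_entry("enrich", file.path(out, "enrichment.tsv"))

  # 6. export
  export_network(cell_bip, file.path(out, "cell_exemplar.sif"), "sif")
  export_network(reg_bip, file.path(out, "regulator_module.sif"), "sif")
  manifest$export <- manifest_entry("export", file.path(out, c(
    "cell_exemplar.sif", "regulator_module.sif")))

  cfg <- config
  cfg$dialect <- unclass(cfg$dialect)
  cfg$ap <- unclass(cfg$ap)
  yaml::write_yaml(unclass(cfg), file.path(out, "config.yaml"))
  jsonlite::write_json(unname(manifest), file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Export a network to SIF or GraphML
#'
#' SIF writes one `source relation target` line per edge, using the
#' `exemplar_id` edge attribute as the relation where present (so parallel
#' multigraph edges stay distinguishable); GraphML preserves all node and
#' edge attributes and round-trips through [igraph::read_graph()].
#'
#' @param network an `igraph` graph (e.g. a bipartite view) or a
#'   [protein_network()].
#' @param path output file path.
#' @param format `"sif"` or `"graphml"`.
#' @return The path, invisibly.
#' @export
export_network <- function(network, path, format = c("sif", "graphml")) {
  if (inherits(network, "protein_network")) network <- network$graph
  if (!inherits(network, "igraph")) {
    stop_pnsmap("export_network expects an igraph or protein_network object",
                "pnsmap_usage_error")
  }
  format <- tryCatch(match.arg(format),
                     error = function(e) stop_pnsmap(
                       sprintf("unknown export format '%s'", format[1]),
                       "pnsmap_usage_error"))
  if (format == "graphml") {
    igraph::write_graph(network, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(network)
    rel <- if ("exemplar_id" %in% igraph::edge_attr_names(network)) {
      igraph::E(network)$exemplar_id
    } else {
      rep("associated", nrow(el))
    }
    writeLines(if (nrow(el)) paste(el[, 1], rel, el[, 2]) else character(0), path)
  }
  invisible(path)
}
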
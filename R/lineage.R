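#' Load the immune cell-type regulator table
#'
#' Reads a TSV with columns `cell_type` and `regulators` (comma-separated
#' transcriptional activator symbols). The packaged fixture
#' `immgen_regulators.tsv` lists the known activators of the ten immune
#' cell lineages. A regulator may serve several cell types (e.g. SFPI1,
#' GATA3).
#'
#' @param path TSV path; default is the packaged table.
#' @return A list of class `lineage_map` with `cell_types` and `regulators`
#'   (named list, cell type -> character vector of activator symbols);
#'   `module_assignment` and `module_regulation` are filled by
#'   [lineage_map()].
#' @export
load_regulator_table <- function(path = system.file("extdata", "immgen_regulators.tsv",
                                                    package = "pnsmap")) {
  if (!file.exists(path)) {
    stop_pnsmap(sprintf("regulator table not found: %s", path), "pnsmap_io_error")
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("cell_type", "regulators") %in% names(df))) {
    stop_pnsmap("regulator table needs columns 'cell_type' and 'regulators'",
                "pnsmap_config_error")
  }
  regs <- lapply(df$regulators, split_field)
  names(regs) <- df$cell_type
  empty <- df$cell_type[lengths(regs) == 0]
  if (length(empty)) {
    stop_pnsmap(sprintf("cell type(s) with no activators listed: %s",
                        paste(empty, collapse = ", ")), "pnsmap_validation_error")
  }
  structure(list(cell_types = df$cell_type, regulators = regs,
                 module_assignment = NULL, module_regulation = NULL),
            class = "lineage_map")
}

#' Assemble a full lineage map
#'
#' Combines the regulator table with the gene -> module assignment and the
#' regulator -> module regulation wiring (both inputs here; inferring them
#' from expression is out of scope).
#'
#' @param regulators a partial `lineage_map` from [load_regulator_table()].
#' @param module_assignment data frame with columns `gene`, `module_id`.
#' @param module_regulation data frame with columns `regulator`,
#'   `module_id`.
#' @return A complete `lineage_map`.
#' @export
lineage_map <- function(regulators, module_assignment, module_regulation) {
  stopifnot(inherits(regulators, "lineage_map"),
            all(c("gene", "module_id") %in% names(module_assignment)),
            all(c("regulator", "module_id") %in% names(module_regulation)))
  module_assignment$gene <- norm_symbols(module_assignment$gene)
  module_regulation$regulator <- norm_symbols(module_regulation$regulator)
  if (any(!nzchar(module_assignment$module_id))) {
    stop_pnsmap("empty module id in module assignment", "pnsmap_validation_error")
  }
  known <- unique(unlist(regulators$regulators))
  stray <- setdiff(module_regulation$regulator, known)
  if (length(stray)) {
    warning(sprintf("regulation table names regulator(s) absent from the cell-type table: %s",
                    paste(stray, collapse = ", ")))
  }
  regulators$module_assignment <- module_assignment
  regulators$module_regulation <- module_regulation
  regulators
}

#' Load module-assignment / regulation TSV files
#' @param path TSV path (`gene`/`module_id` or `regulator`/`module_id`).
#' @return A data frame.
#' @export
load_module_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$gene <- norm_symbols(df$gene)
  df
}

#' @rdname load_module_table
#' @export
load_regulation_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$regulator <- norm_symbols(df$regulator)
  df
}

# cell type -> set of module ids driven by at least one of its regulators
celltype_modules <- function(lmap) {
  lapply(lmap$regulators, function(regs) {
    unique(lmap$module_regulation$module_id[
      lmap$module_regulation$regulator %in% regs])
  })
}

#' Associate exemplars with immune cell types
#'
#' An exemplar is associated with cell type `c` when at least `min_genes`
#' of its member genes lie in modules driven by at least one of `c`'s
#' activators. Exemplars are then classified: *lineage-specific* when
#' associated with exactly one cell type, *common* when associated with
#' all, *shared* otherwise.
#'
#' @param result an `ap_result` clustering.
#' @param lmap a complete [lineage_map()].
#' @param min_genes association threshold (default 1: any member gene in a
#'   lineage-regulated module).
#' @return Data frame of class `exemplar_lineage_table` with columns
#'   `exemplar`, `n_genes`, `genes` (comma-separated members),
#'   `cell_types` (comma-separated), `n_cell_types`, `specificity`.
#'   Exemplars whose members all lack a module assignment are excluded
#'   (and reported).
#' @export
associate_exemplars <- function(result, lmap, min_genes = 1L) {
  stopifnot(inherits(lmap, "lineage_map"), min_genes >= 1)
  if (is.null(lmap$module_assignment) || is.null(lmap$module_regulation)) {
    stop_pnsmap("lineage map lacks module assignment/regulation tables",
                "pnsmap_config_error")
  }
  mod_of <- stats::setNames(lmap$module_assignment$module_id,
                            lmap$module_assignment$gene)
  ct_mods <- celltype_modules(lmap)
  unmapped <- setdiff(names(result$assignment), names(mod_of))
  if (length(unmapped)) {
    message(sprintf("%d clustered gene(s) without module assignment: %s",
                    length(unmapped),
                    paste(utils::head(unmapped, 10), collapse = ", ")))
  }
  rows <- lapply(sort(unique(result$assignment)), function(ex) {
    members <- names(result$assignment)[result$assignment == ex]
    mapped <- intersect(members, names(mod_of))
    if (!length(mapped)) return(NULL)
    mods <- mod_of[mapped]
    assoc <- vapply(ct_mods, function(ms) sum(mods %in% ms) >= min_genes, logical(1))
    cts <- lmap$cell_types[assoc[lmap$cell_types]]
    spec <- if (length(cts) == 0) "unassociated"
            else if (length(cts) == 1) "lineage-specific"
            else if (length(cts) == length(lmap$cell_types)) "common"
            else "shared"
    data.frame(exemplar = ex, n_genes = length(members),
               genes = paste(sort(members), collapse = ","),
               cell_types = paste(cts, collapse = ","),
               n_cell_types = length(cts), specificity = spec,
               stringsAsFactors = FALSE)
  })
  skipped <- sum(vapply(rows, is.null, logical(1)))
  if (skipped) {
    message(sprintf("%d exemplar(s) excluded: no member gene with a module assignment", skipped))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  class(out) <- c("exemplar_lineage_table", class(out))
  out
}

# three-level connectivity gradient; tertiles by value, robust to ties
degree_class <- function(deg) {
  q <- stats::quantile(deg, c(1/3, 2/3))
  ifelse(deg <= q[1], "low", ifelse(deg <= q[2], "intermediate", "high"))
}

#' Exemplar / cell-type bipartite network
#'
#' One node per exemplar and per associated cell type, one edge per
#' association. Node degree and a three-level `degree_class` attribute
#' (low / intermediate / high connectivity) are recorded so exemplars can
#' be ordered by how many of the ten cell types they connect to — from
#' lineage-specific (degree 1) up to common (degree = number of cell
#' types).
#'
#' @param table an [associate_exemplars()] result.
#' @return An `igraph` bipartite graph with vertex attributes `type`
#'   (FALSE = exemplar, TRUE = cell type), `degree` and `degree_class`.
#' @export
build_cell_exemplar_bipartite <- function(table) {
  stopifnot(nrow(table) > 0)
  assoc <- table[table$n_cell_types > 0, , drop = FALSE]
  edges <- do.call(rbind, lapply(seq_len(nrow(assoc)), function(i) {
    cts <- strsplit(assoc$cell_types[i], ",", fixed = TRUE)[[1L]]
    data.frame(exemplar = paste0("exemplar:", assoc$exemplar[i]),
               cell_type = trimws(cts), stringsAsFactors = FALSE)
  }))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  igraph::V(g)$type <- !startsWith(igraph::V(g)$name, "exemplar:")
  igraph::V(g)$degree <- igraph::degree(g)
  igraph::V(g)$degree_class <- as.character(degree_class(igraph::V(g)$degree))
  g
}

#' Regulator / module multigraph
#'
#' For every regulated (regulator, module) pair, one parallel edge is drawn
#' per distinct exemplar with at least one member gene in that module; the
#' edge carries the exemplar id and the regulator's cell type(s). The
#' number of parallel edges between a regulator and a module thus measures
#' how many distinct protein-network exemplars that regulatory module
#' hosts.
#'
#' @param result an `ap_result`.
#' @param lmap a complete [lineage_map()].
#' @return An `igraph` multigraph with edge attributes `exemplar_id` and
#'   `cell_types`, vertex attributes `type` (TRUE = module), `degree`,
#'   `degree_class`.
#' @export
build_regulator_module_multigraph <- function(result, lmap) {
  stopifnot(inherits(lmap, "lineage_map"))
  reg <- lmap$module_regulation
  mod_of <- stats::setNames(lmap$module_assignment$module_id,
                            lmap$module_assignment$gene)
  # cell types of each regulator (may be several)
  reg_ct <- lapply(stats::setNames(nm = unique(reg$regulator)), function(r) {
    lmap$cell_types[vapply(lmap$regulators, function(x) r %in% x, logical(1))[lmap$cell_types]]
  })
  genes <- names(result$assignment)
  edge_rows <- lapply(seq_len(nrow(reg)), function(i) {
    m <- reg$module_id[i]
    r <- reg$regulator[i]
    members_in_m <- genes[!is.na(mod_of[genes]) & mod_of[genes] == m]
    exs <- sort(unique(result$assignment[members_in_m]))
    if (!length(exs)) return(NULL)
    data.frame(regulator = r, module = paste0("module:", m),
               exemplar_id = exs,
               cell_types = paste(reg_ct[[r]], collapse = ","),
               stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, edge_rows[!vapply(edge_rows, is.null, logical(1))])
  verts <- unique(c(reg$regulator, paste0("module:", reg$module_id),
                    if (!is.null(edges)) c(edges$regulator, edges$module)))
  g <- igraph::graph_from_data_frame(
    if (is.null(edges)) data.frame(from = character(0), to = character(0))
    else edges, directed = FALSE, vertices = data.frame(name = verts))
  igraph::V(g)$type <- startsWith(igraph::V(g)$name, "module:")
  igraph::V(g)$degree <- igraph::degree(g)
  igraph::V(g)$degree_class <- as.character(degree_class(igraph::V(g)$degree))
  g
}

#' Interactome coverage of each module
#'
#' Percentage of each module's genes holding at least one interaction in
#' the filtered network. Modules without any interacting gene are flagged;
#' partial coverage is the norm given the incompleteness of interactome
#' databases.
#'
#' @param module_assignment data frame with columns `gene`, `module_id`.
#' @param network a [protein_network()].
#' @return Data frame with `module_id`, `n_genes`, `n_interacting`,
#'   `coverage_pct`, `zero_coverage`.
#' @export
module_coverage <- function(module_assignment, network) {
  deg <- network_degrees(network)
  interacting <- names(deg)[deg > 0]
  genes <- norm_symbols(module_assignment$gene)
  by_mod <- split(genes, module_assignment$module_id)
  out <- data.frame(
    module_id = names(by_mod),
    n_genes = lengths(by_mod),
    n_interacting = vapply(by_mod, function(g) sum(g %in% interacting), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$coverage_pct <- 100 * out$n_interacting / out$n_genes
  out$zero_coverage <- out$n_interacting == 0
  out
}

#' Load a packaged exemplar summary table
#'
#' Reads one of the packaged exemplar tables (`genes` column
#' comma-separated): `lineage_specific_exemplars.tsv` (one row per
#' lineage-specific exemplar with its single associated cell type) or
#' `common_exemplars.tsv` (exemplars associated with all ten cell types).
#'
#' @param path TSV path.
#' @return A data frame; `genes` is split into a list-column `gene_list`.
#' @export
load_exemplar_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$gene_list <- lapply(df$genes, split_field)
  df
}

#' Write an exemplar lineage table to TSV
#' @param table an [associate_exemplars()] result.
#' @param path output path.
#' @export
write_exemplar_lineage_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
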
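#' Generate a synthetic interactome with planted exemplar groups
#'
#' Produces a desk-scale stand-in for a curated binary interactome with
#' known ground truth. Three ingredients:
#'
#' * *planted groups*: `n_groups` disjoint groups of `group_size` genes;
#'   every member of a group is wired to the same `within_shared_partners`
#'   dedicated partner proteins, so intra-group neighborhood-overlap
#'   similarity is high by construction (the signal exemplar clustering
#'   detects is similarity of interaction partners, not within-group edge
#'   density);
#' * *scale-free background*: the remaining genes form a preferential
#'   attachment graph (`background_attachment` edges per arriving node),
#'   giving the heavy degree tail typical of interactomes;
#' * *noise*: each possible node pair receives a spurious edge with
#'   probability `noise_edge_prob`.
#'
#' All randomness flows from `seed`; identical seeds give identical edge
#' lists.
#'
#' @param n_genes total gene universe size (planted + background genes).
#' @param n_groups number of planted groups.
#' @param group_size genes per group (`n_groups * group_size <= n_genes`).
#' @param within_shared_partners shared partner proteins per group.
#' @param background_attachment preferential-attachment edges per node.
#' @param noise_edge_prob per-pair spurious edge probability in \[0, 1\].
#' @param seed RNG seed (recorded in the truth object).
#' @return List with `network` (a [protein_network()]) and `truth` (class
#'   `synthetic_truth`): planted `groups` (named list of gene sets), the
#'   parameters, and the seed.
#' @export
generate_interactome <- function(n_genes = 150, n_groups = 5, group_size = 20,
                                 within_shared_partners = 8,
                                 background_attachment = 2,
                                 noise_edge_prob = 0.01, seed) {
  if (n_groups * group_size > n_genes) {
    stop_pnsmap("n_groups * group_size exceeds n_genes", "pnsmap_validation_error")
  }
  if (noise_edge_prob < 0 || noise_edge_prob > 1) {
    stop_pnsmap("noise_edge_prob must lie in [0, 1]", "pnsmap_validation_error")
  }
  stopifnot(within_shared_partners >= 1, background_attachment >= 1)
  set.seed(seed)
  n_planted <- n_groups * group_size
  genes <- sprintf("GENE%04d", seq_len(n_genes))
  groups <- split(genes[seq_len(n_planted)],
                  rep(seq_len(n_groups), each = group_size))
  names(groups) <- sprintf("group%02d", seq_len(n_groups))
  hub_sets <- lapply(seq_len(n_groups), function(g) {
    sprintf("PART%02d_%02d", g, seq_len(within_shared_partners))
  })
  # planted wiring: every group member interacts with all its group's partners
  planted_edges <- do.call(rbind, lapply(seq_len(n_groups), function(g) {
    expand.grid(a = groups[[g]], b = hub_sets[[g]],
                stringsAsFactors = FALSE)
  }))
  # scale-free background among the non-planted genes
  bg_genes <- genes[setdiff(seq_len(n_genes), seq_len(n_planted))]
  bg_edges <- NULL
  if (length(bg_genes) > background_attachment) {
    bg <- igraph::sample_pa(length(bg_genes), m = background_attachment,
                            directed = FALSE)
    el <- igraph::as_edgelist(bg)
    bg_edges <- data.frame(a = bg_genes[as.integer(el[, 1])],
                           b = bg_genes[as.integer(el[, 2])],
                           stringsAsFactors = FALSE)
  }
  # spurious edges over all node pairs
  nodes <- c(genes, unlist(hub_sets))
  noise_edges <- NULL
  if (noise_edge_prob > 0) {
    pairs <- utils::combn(length(nodes), 2)
    hit <- stats::runif(ncol(pairs)) < noise_edge_prob
    if (any(hit)) {
      noise_edges <- data.frame(a = nodes[pairs[1, hit]],
                                b = nodes[pairs[2, hit]],
                                stringsAsFactors = FALSE)
    }
  }
  edges <- rbind(planted_edges, bg_edges, noise_edges)
  network <- protein_network(as.matrix(edges), nodes = nodes)
  truth <- structure(list(
    groups = groups,
    group_cell_type = NULL,
    planted_terms = NULL,
    gene_universe = genes,
    params = list(n_genes = n_genes, n_groups = n_groups,
                  group_size = group_size,
                  within_shared_partners = within_shared_partners,
                  background_attachment = background_attachment,
                  noise_edge_prob = noise_edge_prob),
    seed = seed
  ), class = "synthetic_truth")
  list(network = network, truth = truth)
}

# cell types whose activator set contains at least one regulator private to
# them; only such types can anchor a lineage-specific planted group under
# the "any shared regulator" association rule
exclusive_regulators <- function(regulators_map) {
  all_regs <- unlist(regulators_map$regulators)
  counts <- table(all_regs)
  lapply(regulators_map$regulators, function(r) r[counts[r] == 1])
}

#' Generate module and regulation tables with planted lineage structure
#'
#' Assigns each planted group's genes to its own co-expression module and
#' wires that module to regulators so that the planted association is
#' unambiguous: *specific* groups get modules driven only by regulators
#' exclusive to one cell type; *common* groups get modules driven by one
#' regulator of every cell type. Decoy modules are built from background
#' genes. Every module is padded with additional non-interacting gene
#' symbols so that roughly a `coverage` fraction of its genes hold any
#' interaction, emulating the partial interactome coverage of real module
#' catalogs.
#'
#' @param truth a `synthetic_truth` from [generate_interactome()].
#' @param regulators a `lineage_map` from [load_regulator_table()].
#' @param coverage target fraction of module genes with interactions.
#' @param n_decoy_modules decoy modules carved from background genes.
#' @param n_common_groups how many planted groups (taken from the end) are
#'   wired as common to every cell type; the rest are lineage-specific.
#' @return List with `modules` (gene, module_id), `regulation` (regulator,
#'   module_id) and the updated `truth` carrying `group_cell_type`
#'   (cell-type name, or `"common"`).
#' @export
generate_lineage <- function(truth, regulators, coverage = 0.3,
                             n_decoy_modules = 3, n_common_groups = 1) {
  stopifnot(inherits(truth, "synthetic_truth"), inherits(regulators, "lineage_map"),
            coverage > 0, coverage <= 1,
            n_common_groups < length(truth$groups))
  set.seed(truth$seed + 1L)
  n_groups <- length(truth$groups)
  n_specific <- n_groups - n_common_groups
  excl <- exclusive_regulators(regulators)
  anchor_types <- names(excl)[lengths(excl) > 0]
  if (length(anchor_types) < n_specific) {
    stop_pnsmap("not enough cell types with exclusive regulators to plant specific groups",
                "pnsmap_validation_error")
  }
  group_ct <- c(anchor_types[seq_len(n_specific)], rep("common", n_common_groups))
  names(group_ct) <- names(truth$groups)
  module_ids <- sprintf("M%02d", seq_len(n_groups + n_decoy_modules))
  mod_rows <- list()
  reg_rows <- list()
  pad_counter <- 0L
  pad_genes <- function(n_interacting) {
    n_total <- round(n_interacting / coverage)
    n_pad <- max(0L, n_total - n_interacting)
    if (!n_pad) return(character(0))
    out <- sprintf("PADGENE%04d", pad_counter + seq_len(n_pad))
    pad_counter <<- pad_counter + n_pad
    out
  }
  for (g in seq_len(n_groups)) {
    m <- module_ids[g]
    members <- truth$groups[[g]]
    mod_rows[[length(mod_rows) + 1L]] <-
      data.frame(gene = c(members, pad_genes(length(members))), module_id = m,
                 stringsAsFactors = FALSE)
    drivers <- if (group_ct[g] == "common") {
      vapply(regulators$regulators, `[`, character(1), 1)
    } else {
      excl[[group_ct[g]]]
    }
    reg_rows[[length(reg_rows) + 1L]] <-
      data.frame(regulator = unname(drivers), module_id = m,
                 stringsAsFactors = FALSE)
  }
  # decoy modules from background genes; driven by nothing
  bg <- setdiff(truth$gene_universe, unlist(truth$groups))
  if (n_decoy_modules > 0 && length(bg)) {
    chunks <- split(bg, rep(seq_len(n_decoy_modules), length.out = length(bg)))
    for (d in seq_len(n_decoy_modules)) {
      m <- module_ids[n_groups + d]
      mod_rows[[length(mod_rows) + 1L]] <-
        data.frame(gene = c(chunks[[d]], pad_genes(length(chunks[[d]]))),
                   module_id = m, stringsAsFactors = FALSE)
    }
  }
  truth$group_cell_type <- group_ct
  list(modules = do.call(rbind, mod_rows),
       regulation = do.call(rbind, reg_rows),
       truth = truth)
}

#' Generate annotation terms with one planted term per group
#'
#' Each planted group receives one term covering 90% (at least 80%) of its
#' genes; `n_decoy_terms` additional terms draw random gene sets from the
#' gene universe. A small hierarchy links every term to a root through
#' three branch terms.
#'
#' @param truth a `synthetic_truth`.
#' @param n_decoy_terms number of random decoy terms.
#' @param term_size_range integer range for decoy term sizes.
#' @param seed RNG seed.
#' @return List with `annotations` (named list, GMT-compatible), `dag`
#'   (child/parent data frame) and the updated `truth` carrying
#'   `planted_terms` (named by group).
#' @export
generate_annotations <- function(truth, n_decoy_terms = 20,
                                 term_size_range = c(5, 25), seed = truth$seed + 2L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(seed)
  ann <- list()
  planted <- character(0)
  for (g in names(truth$groups)) {
    members <- truth$groups[[g]]
    term <- sprintf("T:PLANTED_%s", toupper(g))
    ann[[term]] <- sort(sample(members, ceiling(0.9 * length(members))))
    planted[g] <- term
  }
  universe <- truth$gene_universe
  for (d in seq_len(n_decoy_terms)) {
    size <- sample(seq(term_size_range[1], term_size_range[2]), 1)
    ann[[sprintf("T:DECOY_%03d", d)]] <- sort(sample(universe, min(size, length(universe))))
  }
  branches <- sprintf("T:BRANCH_%d", 1:3)
  terms <- names(ann)
  dag <- rbind(
    data.frame(child = terms,
               parent = branches[(seq_along(terms) - 1L) %% 3L + 1L],
               stringsAsFactors = FALSE),
    data.frame(child = branches, parent = "T:ROOT", stringsAsFactors = FALSE)
  )
  attr(ann, "descriptions") <- stats::setNames(names(ann), names(ann))
  truth$planted_terms <- planted
  list(annotations = ann, dag = dag, truth = truth)
}

#' Write a complete synthetic dataset in the pipeline's file dialects
#'
#' Emits the interaction TSV, module TSV, regulation TSV, GMT, DAG TSV and
#' a truth sidecar (JSON) into a directory, ready for [run_pipeline()].
#'
#' @param dir output directory (created if needed).
#' @param seed RNG seed driving every generator.
#' @param ... passed to [generate_interactome()].
#' @param regulators a `lineage_map`; defaults to the packaged table.
#' @param coverage,n_decoy_modules,n_common_groups passed to
#'   [generate_lineage()].
#' @param n_decoy_terms,term_size_range passed to [generate_annotations()].
#' @return Named list of file paths plus the `truth` object (invisible).
#' @export
write_synthetic_dataset <- function(dir, seed,
                                    regulators = load_regulator_table(),
                                    coverage = 0.3, n_decoy_modules = 3,
                                    n_common_groups = 1, n_decoy_terms = 20,
                                    term_size_range = c(5, 25), ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_interactome(seed = seed, ...)
  lin <- generate_lineage(sim$truth, regulators, coverage = coverage,
                          n_decoy_modules = n_decoy_modules,
                          n_common_groups = n_common_groups)
  annot <- generate_annotations(lin$truth, n_decoy_terms = n_decoy_terms,
                                term_size_range = term_size_range)
  paths <- list(
    interactions = file.path(dir, "interactions.tsv"),
    modules = file.path(dir, "modules.tsv"),
    regulation = file.path(dir, "regulation.tsv"),
    gmt = file.path(dir, "annotations.gmt"),
    dag = file.path(dir, "term_dag.tsv"),
    truth = file.path(dir, "truth.json")
  )
  ed <- network_edges(sim$network)
  utils::write.table(
    data.frame(interactor_a = ed$a, interactor_b = ed$b,
               taxon_a = 10090L, taxon_b = 10090L,
               experimental = "true", physical_binding = "true",
               pubmed_ids = "synthetic:1"),
    paths$interactions, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(lin$modules, paths$modules, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(lin$regulation, paths$regulation, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gmt(annot$annotations, paths$gmt)
  utils::write.table(annot$dag, paths$dag, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- annot$truth
  jsonlite::write_json(list(groups = truth$groups,
                            group_cell_type = as.list(truth$group_cell_type),
                            planted_terms = as.list(truth$planted_terms),
                            params = truth$params, seed = truth$seed),
                       paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(c(paths[names(paths) != "truth"],
              list(truth_path = paths$truth, truth = truth)))
}
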
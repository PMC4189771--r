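#' Describe the column layout of an interaction evidence file
#'
#' A dialect maps the columns of a tab-delimited interaction file onto the
#' fields the filter needs: the two interactor symbols, the two NCBI taxon
#' identifiers, the experimental and physical-binding evidence flags, and
#' the supporting publication list. Columns may be referenced by name (with
#' `header = TRUE`) or by 1-based position, so PSI-MITAB style exports can
#' be consumed by mapping their positional columns.
#'
#' Taxon fields may carry raw integers (`10090`) or MITAB-style prefixes
#' (`taxid:10090(Mus musculus)`); the first integer is extracted. Flag
#' fields are compared case-insensitively against `true_values`.
#'
#' @param interactor_a,interactor_b columns holding the gene symbols.
#' @param taxon_a,taxon_b columns holding the taxon identifiers.
#' @param experimental,physical_binding evidence flag columns.
#' @param pubmed_ids column holding the publication identifiers.
#' @param pubmed_sep separator between multiple publication ids.
#' @param header does the file have a header row?
#' @param true_values strings interpreted as a TRUE flag.
#' @return A list of class `interaction_dialect`.
#' @export
interaction_dialect <- function(interactor_a = "interactor_a",
                                interactor_b = "interactor_b",
                                taxon_a = "taxon_a",
                                taxon_b = "taxon_b",
                                experimental = "experimental",
                                physical_binding = "physical_binding",
                                pubmed_ids = "pubmed_ids",
                                pubmed_sep = "|",
                                header = TRUE,
                                true_values = c("true", "1", "yes", "y")) {
  structure(list(
    columns = list(
      interactor_a = interactor_a, interactor_b = interactor_b,
      taxon_a = taxon_a, taxon_b = taxon_b,
      experimental = experimental, physical_binding = physical_binding,
      pubmed_ids = pubmed_ids
    ),
    pubmed_sep = pubmed_sep, header = header,
    true_values = tolower(true_values)
  ), class = "interaction_dialect")
}

parse_taxon <- function(x) {
  x <- as.character(x)
  pos <- regexpr("[0-9]+", x)
  out <- rep(NA_integer_, length(x))
  hit <- !is.na(x) & pos > 0
  out[hit] <- as.integer(regmatches(x, pos))
  out
}

parse_flag <- function(x, true_values) {
  tolower(trimws(as.character(x))) %in% true_values
}

#' Load interaction evidence records
#'
#' Reads a tab-delimited interaction file into one record per row. Gene
#' symbols are uppercased; publication identifier fields are split into
#' lists. Rows with unparseable taxon fields are reported via a warning but
#' kept (they then fail the same-organism filter criterion rather than
#' vanishing silently).
#'
#' @param path path to the tab-delimited file.
#' @param dialect an [interaction_dialect()] describing the columns.
#' @return A data frame with columns `interactor_a`, `interactor_b`,
#'   `taxon_a`, `taxon_b`, `experimental`, `physical_binding` and a
#'   list-column `pubmed_ids`.
#' @export
load_interactions <- function(path, dialect = interaction_dialect()) {
  if (!file.exists(path)) {
    stop_pnsmap(sprintf("interaction file not found: %s", path), "pnsmap_io_error")
  }
  raw <- utils::read.delim(path, header = dialect$header, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "")
  cols <- dialect$columns
  pick <- function(ref, field) {
    if (is.numeric(ref)) {
      if (ref > ncol(raw)) {
        stop_pnsmap(sprintf("dialect column '%s' (position %d) missing: file has %d columns",
                            field, ref, ncol(raw)), "pnsmap_config_error")
      }
      return(raw[[ref]])
    }
    if (!ref %in% names(raw)) {
      stop_pnsmap(sprintf("dialect column '%s' ('%s') missing from file header",
                          field, ref), "pnsmap_config_error")
    }
    raw[[ref]]
  }
  rec <- data.frame(
    interactor_a = norm_symbols(pick(cols$interactor_a, "interactor_a")),
    interactor_b = norm_symbols(pick(cols$interactor_b, "interactor_b")),
    stringsAsFactors = FALSE
  )
  rec$taxon_a <- parse_taxon(pick(cols$taxon_a, "taxon_a"))
  rec$taxon_b <- parse_taxon(pick(cols$taxon_b, "taxon_b"))
  rec$experimental <- parse_flag(pick(cols$experimental, "experimental"),
                                 dialect$true_values)
  rec$physical_binding <- parse_flag(pick(cols$physical_binding, "physical_binding"),
                                     dialect$true_values)
  pm <- pick(cols$pubmed_ids, "pubmed_ids")
  rec$pubmed_ids <- lapply(pm, function(v) {
    out <- trimws(strsplit(as.character(v), dialect$pubmed_sep, fixed = TRUE)[[1L]])
    out[nzchar(out) & out != "-"]
  })
  bad <- which(is.na(rec$taxon_a) | is.na(rec$taxon_b) |
                 !nzchar(rec$interactor_a) | !nzchar(rec$interactor_b))
  if (length(bad)) {
    warning(sprintf("%d malformed row(s) (unparseable taxon or empty symbol): rows %s",
                    length(bad), paste(utils::head(bad, 10), collapse = ", ")))
  }
  rec
}

#' Construct a protein interaction network from an edge list
#'
#' @param edges two-column character matrix or data frame of gene symbol
#'   pairs (undirected; mirrored and duplicated pairs are collapsed).
#' @param nodes optional additional isolated nodes to include.
#' @param allow_self_loops keep self-interactions? Dropped by default, since
#'   neighborhood-overlap similarity is defined over interaction partners.
#' @return An object of class `protein_network`.
#' @export
protein_network <- function(edges, nodes = NULL, allow_self_loops = FALSE) {
  if (is.null(dim(edges))) edges <- matrix(edges, ncol = 2, byrow = TRUE)
  edges <- as.matrix(edges)[, 1:2, drop = FALSE]
  mode(edges) <- "character"
  edges[] <- norm_symbols(edges)
  if (!allow_self_loops && nrow(edges)) {
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
  }
  nodes <- unique(c(norm_symbols(nodes), as.vector(edges)))
  nodes <- nodes[nzchar(nodes)]
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, length(setdiff(nodes, igraph::V(g)$name)),
                            name = setdiff(nodes, igraph::V(g)$name))
  g <- igraph::simplify(g, remove.multiple = TRUE,
                        remove.loops = !allow_self_loops)
  structure(list(graph = g), class = "protein_network")
}

#' @export
print.protein_network <- function(x, ...) {
  cat(sprintf("protein_network: %d nodes, %d edges\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph)))
  invisible(x)
}

#' Filter interaction records into a binary interactome
#'
#' Applies the four retention criteria jointly: (a) experimentally
#' verified, (b) both interactors from the target organism, (c) at least
#' one supporting publication, and (d) a physically binding interaction.
#' Surviving records are collapsed into a deduplicated undirected network.
#'
#' @param records data frame from [load_interactions()].
#' @param target_taxon NCBI taxon id both interactors must carry
#'   (default mouse, 10090).
#' @param allow_self_loops keep self-interactions (default drop).
#' @return A [protein_network()]; empty (with a warning) if nothing passes.
#' @export
filter_interactions <- function(records, target_taxon = 10090L,
                                allow_self_loops = FALSE) {
  keep <- records$experimental &
    records$physical_binding &
    !is.na(records$taxon_a) & !is.na(records$taxon_b) &
    records$taxon_a == target_taxon & records$taxon_b == target_taxon &
    lengths(records$pubmed_ids) >= 1L &
    nzchar(records$interactor_a) & nzchar(records$interactor_b)
  kept <- records[keep, , drop = FALSE]
  message(sprintf("interaction filter: %d/%d record(s) retained (%d dropped)",
                  nrow(kept), nrow(records), nrow(records) - nrow(kept)))
  if (!nrow(kept)) {
    warning("no interaction records satisfy all filter criteria; returning empty network")
    return(protein_network(matrix(character(0), ncol = 2)))
  }
  protein_network(cbind(kept$interactor_a, kept$interactor_b),
                  allow_self_loops = allow_self_loops)
}

#' Interaction partners of a gene
#'
#' @param network a [protein_network()].
#' @param gene gene symbol (case-insensitive). Unknown genes yield an empty
#'   set rather than an error.
#' @return Sorted character vector of partner symbols (never includes
#'   `gene` itself).
#' @export
neighborhood <- function(network, gene) {
  stopifnot(inherits(network, "protein_network"))
  gene <- norm_symbols(gene)
  if (!gene %in% igraph::V(network$graph)$name) return(character(0))
  nb <- igraph::neighbors(network$graph, gene)$name
  sort(setdiff(nb, gene))
}

#' Node degrees of a protein network
#' @param network a [protein_network()].
#' @return Named integer vector of degrees.
#' @export
network_degrees <- function(network) {
  stopifnot(inherits(network, "protein_network"))
  igraph::degree(network$graph)
}

#' Network nodes and edges
#' @param network a [protein_network()].
#' @return `network_nodes`: character vector; `network_edges`: two-column
#'   data frame of symbol pairs.
#' @export
network_nodes <- function(network) igraph::V(network$graph)$name

#' @rdname network_nodes
#' @export
network_edges <- function(network) {
  el <- igraph::as_edgelist(network$graph)
  data.frame(a = el[, 1], b = el[, 2], stringsAsFactors = FALSE)
}

#' Highest-degree genes of the network
#'
#' Returns the genes whose degree lies in the top `top_fraction` of the
#' degree-ranked node list; all ties at the cutoff degree are included.
#' "Hub" has no universal definition; the default keeps the top 10% by
#' degree.
#'
#' @param network a [protein_network()].
#' @param top_fraction proportion in (0, 1].
#' @return Character vector of hub gene symbols (empty for an empty network).
#' @export
hubs <- function(network, top_fraction = 0.1) {
  stopifnot(inherits(network, "protein_network"),
            top_fraction > 0, top_fraction <= 1)
  deg <- network_degrees(network)
  if (!length(deg)) return(character(0))
  k <- max(1L, ceiling(top_fraction * length(deg)))
  cutoff <- sort(deg, decreasing = TRUE)[k]
  sort(names(deg)[deg >= cutoff])
}

#' Write a network as an edge-list TSV or SIF file
#'
#' @param network a [protein_network()].
#' @param path output path.
#' @param relation SIF relation label (SIF only).
#' @export
write_edge_list <- function(network, path) {
  utils::write.table(network_edges(network), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
write_network_sif <- function(network, path, relation = "pp") {
  ed <- network_edges(network)
  writeLines(if (nrow(ed)) paste(ed$a, relation, ed$b) else character(0), path)
  invisible(path)
}
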
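#' Read / write GMT annotation files
#'
#' GMT: one term per line, tab-separated `term_id`, `description`, then the
#' annotated gene symbols.
#'
#' @param path GMT file path.
#' @return A named list of uppercase gene-symbol vectors, with a
#'   `descriptions` attribute (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad)) {
    stop_pnsmap(sprintf("GMT line(s) with fewer than 3 fields: %s",
                        paste(utils::head(bad, 5), collapse = ", ")),
                "pnsmap_io_error")
  }
  ann <- lapply(parts, function(p) unique(norm_symbols(p[-(1:2)])))
  names(ann) <- vapply(parts, `[`, character(1), 1)
  attr(ann, "descriptions") <- stats::setNames(
    vapply(parts, `[`, character(1), 2), names(ann))
  ann
}

#' @rdname read_gmt
#' @param annotations named list of gene vectors.
#' @param descriptions optional named descriptions (defaults to the term id).
#' @export
write_gmt <- function(annotations, path, descriptions = NULL) {
  descriptions <- descriptions %||% attr(annotations, "descriptions") %||%
    stats::setNames(names(annotations), names(annotations))
  lines <- vapply(names(annotations), function(t) {
    paste(c(t, descriptions[[t]] %||% t, annotations[[t]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation of annotation terms in a gene set
#'
#' For each term the upper-tail hypergeometric probability of observing at
#' least the seen overlap: with universe size N, term size K (after
#' intersection with the universe), query size n and overlap k,
#' `P(X >= k)` under sampling without replacement. Terms with no annotated
#' gene in the universe are dropped; a zero overlap reports p = 1.
#' Benjamini-Hochberg adjusted p-values are appended.
#'
#' @param gene_set query gene symbols (intersected with the universe).
#' @param annotations named list of term gene sets (e.g. from
#'   [read_gmt()]).
#' @param universe background gene symbols (non-empty). The natural default
#'   for exemplar analysis is the set of PNSM genes.
#' @param alpha significance level applied to the adjusted p-value.
#' @param adjust use adjusted p-values for the `significant` flag; set
#'   FALSE to flag on raw p-values.
#' @return Data frame with `term`, `description`, `k`, `n`, `K`, `N`,
#'   `p_value`, `adjusted_p`, `significant`, ordered by p-value.
#' @export
hypergeom_enrich <- function(gene_set, annotations, universe,
                             alpha = 0.05, adjust = TRUE) {
  universe <- unique(norm_symbols(universe))
  if (!length(universe)) {
    stop_pnsmap("empty gene universe", "pnsmap_config_error")
  }
  gene_set <- intersect(unique(norm_symbols(gene_set)), universe)
  descriptions <- attr(annotations, "descriptions")
  terms <- lapply(annotations, function(g) intersect(unique(norm_symbols(g)), universe))
  terms <- terms[lengths(terms) > 0]
  N <- length(universe)
  n <- length(gene_set)
  K <- lengths(terms)
  k <- vapply(terms, function(g) length(intersect(g, gene_set)), integer(1))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(
    term = names(terms),
    description = if (is.null(descriptions)) names(terms)
                  else unname(descriptions[names(terms)]),
    k = unname(k), n = n, K = unname(K), N = N,
    p_value = unname(p), stringsAsFactors = FALSE, row.names = NULL
  )
  out$adjusted_p <- bh_adjust(out$p_value)
  out$significant <- (if (adjust) out$adjusted_p else out$p_value) <= alpha
  out[order(out$p_value, out$term), , drop = FALSE]
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment of a vector of p-values
#' (delegating to [stats::p.adjust()] after validating the input range).
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return Adjusted p-values, each at least the corresponding raw value.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop_pnsmap("p-values must lie in (0, 1]", "pnsmap_validation_error")
  }
  stats::p.adjust(p, method = "BH")
}

dag_graph <- function(dag) {
  stopifnot(all(c("child", "parent") %in% names(dag)))
  g <- igraph::graph_from_data_frame(dag[, c("child", "parent")], directed = TRUE)
  if (!igraph::is_dag(g)) {
    comp <- igraph::components(g, mode = "strong")
    cyc <- names(comp$membership)[comp$membership %in%
                                    which(comp$csize > 1)]
    if (!length(cyc)) cyc <- dag$child[dag$child == dag$parent]
    stop_pnsmap(sprintf("term hierarchy contains a cycle involving '%s'", cyc[1]),
                "pnsmap_validation_error")
  }
  g
}

#' Read a term hierarchy edge list
#' @param path two-column TSV (`child`, `parent`).
#' @return A data frame with columns `child` and `parent`.
#' @export
read_dag <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("child", "parent") %in% names(df))) {
    names(df)[1:2] <- c("child", "parent")
  }
  df
}

#' True-path propagation of annotations up a term DAG
#'
#' Each term's gene set is extended with the genes of all its descendant
#' terms (set union, so diamond-shaped hierarchies do not double count).
#' This is the usual "true path rule": a gene annotated to a term is
#' implicitly annotated to every ancestor.
#'
#' @param dag data frame with columns `child`, `parent` (must be acyclic).
#' @param annotations named list of term gene sets; terms appearing only in
#'   the DAG start empty.
#' @return Named list of propagated gene sets (descriptions preserved).
#' @export
propagate_annotations <- function(dag, annotations) {
  g <- dag_graph(dag)
  all_terms <- union(names(annotations), igraph::V(g)$name)
  sets <- stats::setNames(vector("list", length(all_terms)), all_terms)
  for (t in names(annotations)) sets[[t]] <- unique(norm_symbols(annotations[[t]]))
  for (t in setdiff(all_terms, names(annotations))) sets[[t]] <- character(0)
  # edges point child -> parent, so topological order lists children first
  ord <- igraph::V(g)$name[igraph::topo_sort(g, mode = "out")]
  for (t in ord) {
    parents <- igraph::neighbors(g, t, mode = "out")$name
    for (p in parents) sets[[p]] <- union(sets[[p]], sets[[t]])
  }
  attr(sets, "descriptions") <- attr(annotations, "descriptions")
  sets
}

#' Significance trajectory through the term DAG
#'
#' Induces the subgraph of significant terms together with every ancestor
#' path up to the root(s), the usual way of displaying where enrichment
#' signal sits in a term hierarchy. Significant terms are marked with a
#' vertex attribute.
#'
#' @param dag data frame with columns `child`, `parent`.
#' @param results an enrichment data frame (from [hypergeom_enrich()],
#'   computed on propagated annotations).
#' @param alpha significance level applied to `adjusted_p` (or `p_value`
#'   when no adjusted column is present).
#' @return An `igraph` directed graph (child -> parent edges) with logical
#'   vertex attribute `significant`; roots are always included.
#' @export
significance_trajectory <- function(dag, results, alpha = 0.05) {
  g <- dag_graph(dag)
  pcol <- if ("adjusted_p" %in% names(results)) results$adjusted_p else results$p_value
  sig <- results$term[pcol <= alpha]
  sig <- intersect(sig, igraph::V(g)$name)
  roots <- igraph::V(g)$name[igraph::degree(g, mode = "out") == 0]
  keep <- unique(c(roots, unlist(lapply(sig, function(t) {
    igraph::subcomponent(g, t, mode = "out")$name
  }))))
  sub <- igraph::induced_subgraph(g, keep)
  igraph::V(sub)$significant <- igraph::V(sub)$name %in% sig
  sub
}

#' Per-exemplar enrichment over a clustering
#'
#' Runs [hypergeom_enrich()] for each exemplar's member genes against a
#' shared universe and annotation list, returning one long-format table.
#'
#' @param result an `ap_result`.
#' @param annotations named list of term gene sets.
#' @param universe background genes (default: all clustered genes).
#' @param alpha significance level.
#' @param adjust flag significance on adjusted p-values?
#' @return Long data frame with an `exemplar` column prepended.
#' @export
enrich_exemplars <- function(result, annotations, universe = names(result$assignment),
                             alpha = 0.05, adjust = TRUE) {
  rows <- lapply(sort(unique(result$assignment)), function(ex) {
    members <- names(result$assignment)[result$assignment == ex]
    res <- hypergeom_enrich(members, annotations, universe,
                            alpha = alpha, adjust = adjust)
    if (!nrow(res)) return(NULL)
    cbind(exemplar = ex, res, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}
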
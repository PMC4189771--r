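#' Simpson neighborhood-overlap similarity of two genes
#'
#' Shared interaction partners of `a` and `b` relative to the degree of the
#' least-connected gene of the pair:
#' \deqn{S_{AB} = |N(A) \cap N(B)| / \min(|N(A)|, |N(B)|)}
#' Normalizing by the smaller degree avoids penalizing pairs with very
#' different degrees, which are common in scale-free interactomes. The pair
#' itself is excluded from both neighborhoods, so an `a`--`b` edge does not
#' inflate the score of adjacent low-degree genes.
#'
#' @param network a [protein_network()].
#' @param a,b gene symbols; both must have degree at least 1.
#' @return A score in \[0, 1\].
#' @export
simpson_index <- function(network, a, b) {
  pair_similarity(network, a, b, "simpson")
}

#' Jaccard neighborhood-overlap similarity of two genes
#'
#' Shared partners relative to the union of both neighborhoods,
#' \eqn{|N(A) \cap N(B)| / |N(A) \cup N(B)|}. Unlike the Simpson index this
#' penalizes degree-imbalanced pairs; it is provided as the alternative
#' similarity for the PNSM.
#'
#' @inheritParams simpson_index
#' @return A score in \[0, 1\].
#' @export
jaccard_index <- function(network, a, b) {
  pair_similarity(network, a, b, "jaccard")
}

pair_similarity <- function(network, a, b, index) {
  na <- neighborhood(network, a)
  nb <- neighborhood(network, b)
  if (index == "simpson" && (length(na) == 0 || length(nb) == 0)) {
    stop_pnsmap(sprintf("similarity undefined: gene(s) with no interaction partners (%s)",
                        paste(c(a, b)[c(length(na) == 0, length(nb) == 0)], collapse = ", ")),
                "pnsmap_undefined_similarity")
  }
  if (index == "jaccard" && length(na) == 0 && length(nb) == 0) {
    stop_pnsmap("similarity undefined: both genes have no interaction partners",
                "pnsmap_undefined_similarity")
  }
  pair <- norm_symbols(c(a, b))
  na <- setdiff(na, pair)
  nb <- setdiff(nb, pair)
  k <- length(intersect(na, nb))
  denom <- switch(index,
    simpson = min(length(na), length(nb)),
    jaccard = length(union(na, nb))
  )
  if (denom == 0) return(0)
  k / denom
}

#' Build the protein-network similarity matrix (PNSM)
#'
#' Computes all pairwise neighborhood-overlap similarities among the
#' candidate genes that have at least one interaction partner in the
#' network. Candidates absent from the network or with degree zero are
#' dropped and reported; this mirrors the partial interactome coverage of
#' co-expression modules (typically only a minority of module genes have
#' any catalogued interaction).
#'
#' The diagonal is left at zero: it is the preference slot that the
#' affinity-propagation step fills (by default with the median off-diagonal
#' similarity).
#'
#' @param network a [protein_network()].
#' @param candidate_genes gene universe to score (e.g. all module-assigned
#'   genes).
#' @param index `"simpson"` (default) or `"jaccard"`.
#' @return An object of class `pnsm`: list with `genes`, symmetric matrix
#'   `S`, the `index` used, and `dropped` (candidates excluded for having
#'   no partners).
#' @export
build_pnsm <- function(network, candidate_genes, index = c("simpson", "jaccard")) {
  index <- match.arg(index)
  stopifnot(inherits(network, "protein_network"), length(candidate_genes) > 0)
  candidate_genes <- unique(norm_symbols(candidate_genes))
  deg <- network_degrees(network)
  retained <- candidate_genes[candidate_genes %in% names(deg)[deg > 0]]
  dropped <- setdiff(candidate_genes, retained)
  message(sprintf("PNSM: %d/%d candidate gene(s) retained (%d without interactions dropped)",
                  length(retained), length(candidate_genes), length(dropped)))
  if (length(retained) < 2) {
    stop_pnsmap("fewer than 2 candidate genes with interactions: nothing to cluster",
                "pnsmap_pipeline_error")
  }
  A <- igraph::as_adjacency_matrix(network$graph, sparse = TRUE)
  Asub <- A[retained, , drop = FALSE]
  counts <- as.matrix(Matrix::tcrossprod(Asub))       # |N(a) n N(b)|
  degs <- Matrix::rowSums(Asub)
  adj <- as.matrix(A[retained, retained, drop = FALSE]) # 1 if a--b edge
  # excluding the pair itself: a,b never lie in the intersection (no self
  # loops), but each reduces the other's neighborhood size by adj(a,b)
  da <- matrix(degs, length(retained), length(retained))
  S <- switch(index,
    simpson = {
      denom <- pmin(da, t(da)) - adj
      out <- ifelse(denom > 0, counts / denom, 0)
      out
    },
    jaccard = {
      denom <- da + t(da) - 2 * adj - counts
      ifelse(denom > 0, counts / denom, 0)
    }
  )
  diag(S) <- 0
  dimnames(S) <- list(retained, retained)
  structure(list(genes = retained, S = S, index = index, dropped = dropped),
            class = "pnsm")
}

#' @export
print.pnsm <- function(x, ...) {
  off <- x$S[row(x$S) != col(x$S)]
  cat(sprintf("pnsm (%s index): %d genes, off-diagonal range [%.3f, %.3f], %d dropped candidate(s)\n",
              x$index, length(x$genes), min(off), max(off), length(x$dropped)))
  invisible(x)
}

#' @export
as.matrix.pnsm <- function(x, ...) x$S

# coerce a pnsm or plain symmetric matrix to a named numeric matrix
as_similarity_matrix <- function(S) {
  M <- if (inherits(S, "pnsm")) S$S else as.matrix(S)
  stopifnot(is.numeric(M), nrow(M) == ncol(M))
  if (is.null(rownames(M))) {
    dimnames(M) <- list(paste0("g", seq_len(nrow(M))), paste0("g", seq_len(nrow(M))))
  }
  M
}

#' Write a PNSM to disk
#'
#' @param pnsm a [build_pnsm()] result.
#' @param path output path.
#' @param long write long format (`gene_a`, `gene_b`, `score`, upper
#'   triangle only) instead of a square matrix with a header row.
#' @export
write_pnsm <- function(pnsm, path, long = FALSE) {
  M <- as_similarity_matrix(pnsm)
  if (long) {
    idx <- which(upper.tri(M), arr.ind = TRUE)
    df <- data.frame(gene_a = rownames(M)[idx[, 1]],
                     gene_b = colnames(M)[idx[, 2]],
                     score = M[idx])
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    utils::write.table(data.frame(gene = rownames(M), M, check.names = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
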
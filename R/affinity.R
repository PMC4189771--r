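#' Affinity propagation configuration
#'
#' @param preference `"median"` (shared scalar: median of all off-diagonal
#'   similarities) or an explicit numeric vector (length 1 or one value per
#'   gene) of self-similarities s(A,A). Larger preferences yield more
#'   exemplars.
#' @param damping message damping factor in \[0.5, 1); each message is
#'   `damping * old + (1 - damping) * new`. Undamped updates oscillate on
#'   symmetric inputs.
#' @param max_iterations hard iteration cap.
#' @param convergence_iterations number of consecutive iterations the
#'   exemplar set must stay unchanged to declare convergence.
#' @param noise_scale magnitude of optional tie-breaking jitter, as a
#'   fraction of the similarity range (0 disables it). Useful when many
#'   similarities are exactly equal and messages oscillate.
#' @param seed RNG seed for the jitter.
#' @return A list of class `ap_config`.
#' @export
ap_config <- function(preference = "median", damping = 0.5,
                      max_iterations = 1000L, convergence_iterations = 50L,
                      noise_scale = 0, seed = 1L) {
  stopifnot(damping >= 0.5, damping < 1,
            max_iterations >= 1, convergence_iterations >= 1,
            convergence_iterations < max_iterations,
            noise_scale >= 0)
  structure(list(preference = preference, damping = damping,
                 max_iterations = as.integer(max_iterations),
                 convergence_iterations = as.integer(convergence_iterations),
                 noise_scale = noise_scale, seed = as.integer(seed)),
            class = "ap_config")
}

#' Median input preference
#'
#' The self-similarity (preference) controls how readily a gene becomes an
#' exemplar; setting every preference to the median of the off-diagonal
#' similarities lets the data determine the number of clusters without
#' fixing k in advance.
#'
#' @param S a `pnsm` or symmetric similarity matrix (at least 2 genes).
#' @return Numeric preference vector, one (identical) value per gene.
#' @export
median_preference <- function(S) {
  M <- as_similarity_matrix(S)
  stopifnot(nrow(M) >= 2)
  rep(stats::median(M[row(M) != col(M)]), nrow(M))
}

#' Initialize affinity propagation message state
#'
#' Responsibilities and availabilities start at zero.
#'
#' @param n number of data points.
#' @param genes optional names.
#' @return An object of class `ap_state`.
#' @export
ap_state <- function(n, genes = NULL) {
  Z <- matrix(0, n, n, dimnames = list(genes, genes))
  structure(list(responsibilities = Z, availabilities = Z, iteration = 0L),
            class = "ap_state")
}

#' One responsibility update sweep
#'
#' For every ordered pair (A, B) the new responsibility is
#' \deqn{r(A,B) = s(A,B) - \max_{B' \ne B} \{ a(A,B') + s(A,B') \}}
#' i.e. how strongly B claims A relative to the best competing candidate
#' exemplar. Messages are then damped against their previous values.
#'
#' @param S similarity matrix with preferences on the diagonal.
#' @param state an [ap_state()].
#' @param damping damping factor in \[0, 1) (0 = undamped update).
#' @return Updated `ap_state`.
#' @export
update_responsibilities <- function(S, state, damping = 0.5) {
  M <- as_similarity_matrix(S)
  n <- nrow(M)
  AS <- state$availabilities + M
  if (any(!is.finite(AS))) {
    stop_pnsmap(sprintf("non-finite message values at iteration %d", state$iteration),
                "pnsmap_numerical_error")
  }
  top <- max.col(AS, ties.method = "first")
  idx <- cbind(seq_len(n), top)
  best <- AS[idx]
  AS[idx] <- -Inf
  second <- apply(AS, 1, max)
  Rnew <- M - best
  Rnew[idx] <- M[idx] - second
  state$responsibilities <- damping * state$responsibilities + (1 - damping) * Rnew
  state$iteration <- state$iteration + 1L
  state
}

#' One availability update sweep
#'
#' For A != B the new availability accumulates the candidate exemplar's
#' self-responsibility plus all positive responsibilities it receives from
#' other points, capped at zero:
#' \deqn{a(A,B) = \min\{0,\; r(B,B) + \sum_{A' \notin \{A,B\}} \max(0, r(A',B))\}}
#' while the self-availability is the uncapped sum
#' \eqn{a(B,B) = \sum_{A' \ne B} \max(0, r(A',B))}.
#'
#' @inheritParams update_responsibilities
#' @return Updated `ap_state`.
#' @export
update_availabilities <- function(state, damping = 0.5) {
  R <- state$responsibilities
  if (any(!is.finite(R))) {
    stop_pnsmap(sprintf("non-finite message values at iteration %d", state$iteration),
                "pnsmap_numerical_error")
  }
  n <- nrow(R)
  Rp <- pmax(R, 0)
  diag(Rp) <- diag(R)
  cs <- colSums(Rp)
  Anew <- matrix(cs, n, n, byrow = TRUE) - Rp
  dA <- diag(Anew)              # sum of positive responsibilities toward B
  Anew <- pmin(Anew, 0)
  diag(Anew) <- dA
  state$availabilities <- damping * state$availabilities + (1 - damping) * Anew
  state
}

#' Run affinity propagation on a similarity matrix
#'
#' Alternates responsibility and availability sweeps until the exemplar set
#' (genes B with `a(B,B) + r(B,B) > 0`) is stable for
#' `convergence_iterations` consecutive iterations, or `max_iterations` is
#' reached. Every gene is simultaneously a data point and a candidate
#' exemplar; the number of clusters emerges from the preferences rather
#' than being fixed in advance. Non-exemplars are assigned to the exemplar
#' they are most similar to.
#'
#' @param S a `pnsm` or symmetric similarity matrix. The diagonal is
#'   overwritten with the configured preference.
#' @param config an [ap_config()].
#' @return An object of class `ap_result`: `exemplars` (gene symbols),
#'   `assignment` (named vector gene -> exemplar), `n_iterations`,
#'   `converged`, `net_similarity`, and the `preferences` used.
#' @export
run_affinity_propagation <- function(S, config = ap_config()) {
  M <- as_similarity_matrix(S)
  genes <- rownames(M)
  n <- nrow(M)
  if (n == 1) {
    res <- structure(list(exemplars = genes, assignment = stats::setNames(genes, genes),
                          n_iterations = 0L, converged = TRUE,
                          net_similarity = unname(M[1, 1]),
                          preferences = stats::setNames(M[1, 1], genes)),
                     class = "ap_result")
    return(res)
  }
  pref <- config$preference
  if (identical(pref, "median")) {
    pref <- median_preference(M)
  } else {
    stopifnot(is.numeric(pref), length(pref) %in% c(1L, n))
    pref <- rep_len(pref, n)
  }
  Sp <- M
  diag(Sp) <- pref
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(config$seed)
  # eps-scale perturbation breaking exactly tied similarities; symmetric
  # inputs otherwise sustain message oscillations (standard practice in
  # reference implementations of the algorithm)
  Sp <- Sp + (.Machine$double.eps * Sp + .Machine$double.xmin * 100) *
    matrix(stats::rnorm(n * n), n, n)
  if (config$noise_scale > 0) {
    span <- diff(range(Sp))
    if (span == 0) span <- 1
    Sp <- Sp + matrix(stats::runif(n * n, 0, config$noise_scale * span), n, n)
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  state <- ap_state(n, genes)
  stable <- 0L
  ex_prev <- integer(0)
  while (state$iteration < config$max_iterations) {
    state <- update_responsibilities(Sp, state, config$damping)
    state <- update_availabilities(state, config$damping)
    ex <- which(diag(state$availabilities) + diag(state$responsibilities) > 0)
    if (length(ex) && identical(ex, ex_prev)) {
      stable <- stable + 1L
      if (stable >= config$convergence_iterations) break
    } else {
      stable <- 0L
    }
    ex_prev <- ex
  }
  converged <- stable >= config$convergence_iterations
  ex <- which(diag(state$availabilities) + diag(state$responsibilities) > 0)
  if (!length(ex)) {
    ex <- which.max(diag(state$availabilities) + diag(state$responsibilities))
    converged <- FALSE
  }
  if (!converged) {
    warning("affinity propagation did not converge; consider damping > 0.5 or a small noise_scale jitter")
  }
  ex <- refine_exemplars(Sp, ex)
  assignment <- assign_to_exemplars(M, ex, genes)
  res <- structure(list(
    exemplars = genes[ex],
    assignment = assignment,
    n_iterations = state$iteration,
    converged = converged,
    net_similarity = NA_real_,
    preferences = stats::setNames(pref, genes)
  ), class = "ap_result")
  res$net_similarity <- net_similarity(M, res)
  res
}

# post-convergence refinement (standard final step of the algorithm):
# cluster points by similarity to the message-selected exemplars, then make
# each cluster's exemplar the member maximizing total within-cluster
# similarity
refine_exemplars <- function(Sp, ex_idx) {
  cl <- max.col(Sp[, ex_idx, drop = FALSE], ties.method = "first")
  cl[ex_idx] <- seq_along(ex_idx)
  refined <- vapply(seq_along(ex_idx), function(k) {
    ii <- which(cl == k)
    ii[which.max(colSums(Sp[ii, ii, drop = FALSE]))]
  }, integer(1))
  sort(unique(refined))
}

assign_to_exemplars <- function(M, ex_idx, genes) {
  n <- nrow(M)
  Sx <- M[, ex_idx, drop = FALSE]
  pick <- max.col(Sx, ties.method = "first")
  assignment <- genes[ex_idx][pick]
  assignment[ex_idx] <- genes[ex_idx]
  stats::setNames(assignment, genes)
}

#' @export
print.ap_result <- function(x, ...) {
  cat(sprintf("ap_result: %d exemplar(s) over %d gene(s); %s after %d iteration(s); net similarity %.4f\n",
              length(x$exemplars), length(x$assignment),
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations, x$net_similarity))
  invisible(x)
}

#' Net similarity of an exemplar assignment
#'
#' The affinity propagation objective: the sum over non-exemplars of their
#' similarity to their exemplar, plus the sum of exemplar preferences.
#'
#' @param S similarity matrix (diagonal ignored; preferences are taken from
#'   `result`).
#' @param result an `ap_result`.
#' @return A single numeric value.
#' @export
net_similarity <- function(S, result) {
  M <- as_similarity_matrix(S)
  genes <- rownames(M)
  ex <- result$exemplars
  assignment <- result$assignment
  if (!all(assignment %in% ex)) {
    stop_pnsmap("assignment references a non-exemplar gene", "pnsmap_contract_error")
  }
  if (!all(assignment[ex] == ex)) {
    stop_pnsmap("an exemplar is not assigned to itself", "pnsmap_contract_error")
  }
  nonex <- setdiff(genes, ex)
  pref <- result$preferences %||% stats::setNames(diag(M), genes)
  sum(M[cbind(nonex, assignment[nonex])]) + sum(pref[ex])
}

#' Exhaustive exemplar-set search (test oracle)
#'
#' Enumerates every nonempty subset of genes as a candidate exemplar set,
#' assigns each remaining gene to its most similar exemplar, and returns
#' the configuration maximizing net similarity. Ties are broken toward the
#' lexicographically smallest exemplar set. Intended as an independent
#' optimum against which converged affinity propagation runs are compared;
#' guarded to at most 12 genes.
#'
#' @param S a `pnsm` or symmetric similarity matrix.
#' @param preference as in [ap_config()]: `"median"` or an explicit vector.
#' @return An `ap_result` with `converged = TRUE` and `n_iterations = 0`.
#' @export
brute_force_exemplars <- function(S, preference = "median") {
  M <- as_similarity_matrix(S)
  n <- nrow(M)
  if (n > 12) {
    stop_pnsmap("brute-force exemplar search is limited to 12 genes", "pnsmap_size_error")
  }
  genes <- rownames(M)
  pref <- if (identical(preference, "median") && n >= 2) median_preference(M)
          else if (identical(preference, "median")) diag(M)
          else rep_len(preference, n)
  diag(M) <- pref
  best <- NULL
  for (mask in seq_len(2^n - 1)) {
    ex_idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    obj <- sum(pref[ex_idx])
    nonex <- setdiff(seq_len(n), ex_idx)
    if (length(nonex)) {
      Sx <- M[nonex, ex_idx, drop = FALSE]
      obj <- obj + sum(apply(Sx, 1, max))
    }
    key <- paste(sort(genes[ex_idx]), collapse = ",")
    if (is.null(best) || obj > best$obj + 1e-12 ||
        (abs(obj - best$obj) <= 1e-12 && key < best$key)) {
      best <- list(obj = obj, ex_idx = ex_idx, key = key)
    }
  }
  res <- structure(list(
    exemplars = genes[best$ex_idx],
    assignment = assign_to_exemplars(M, best$ex_idx, genes),
    n_iterations = 0L,
    converged = TRUE,
    net_similarity = NA_real_,
    preferences = stats::setNames(pref, genes)
  ), class = "ap_result")
  res$net_similarity <- net_similarity(M, res)
  res
}

#' Write an exemplar clustering to disk
#'
#' @param result an `ap_result`.
#' @param path output TSV path (columns gene, exemplar, is_exemplar).
#' @param meta_path optional JSON sidecar with run metadata.
#' @export
write_clusters <- function(result, path, meta_path = NULL) {
  df <- data.frame(gene = names(result$assignment),
                   exemplar = unname(result$assignment),
                   is_exemplar = names(result$assignment) %in% result$exemplars)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(meta_path)) {
    jsonlite::write_json(list(n_exemplars = length(result$exemplars),
                              n_iterations = result$n_iterations,
                              converged = result$converged,
                              net_similarity = result$net_similarity),
                         meta_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
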
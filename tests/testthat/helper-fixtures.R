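# fixtures built in code, shared across test files

# star network: center c wired to leaves
star_network <- function(center = "C", leaves = c("X", "Y", "Z")) {
  protein_network(cbind(center, leaves))
}

# the two-gene neighborhood fixture behind the worked similarity examples:
# N(a) = {P1,P2,P3}, N(b) = {P2,P3,P4,P5}
two_gene_fixture <- function() {
  protein_network(rbind(
    cbind("A", c("P1", "P2", "P3")),
    cbind("B", c("P2", "P3", "P4", "P5"))
  ))
}

# toy interaction record table exercising each filter criterion
toy_records <- function() {
  df <- data.frame(
    interactor_a = c("A", "B", "C", "D", "E"),
    interactor_b = c("B", "C", "D", "E", "A"),
    taxon_a = c(10090L, 10090L, 10090L, 10090L, 10090L),
    taxon_b = c(10090L, 9606L, 10090L, 10090L, 10090L),
    experimental = c(TRUE, TRUE, TRUE, TRUE, TRUE),
    physical_binding = c(TRUE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
  df$pubmed_ids <- list("1", "2", character(0), "3", "4")
  df
}

# symmetric similarity matrix with planted blocks: within-block values
# drawn in [wlo, whi], between-block in [blo, bhi]
planted_block_matrix <- function(block_sizes, wlo = 0.8, whi = 1, blo = 0, bhi = 0.1) {
  n <- sum(block_sizes)
  lab <- rep(seq_along(block_sizes), block_sizes)
  M <- matrix(stats::runif(n * n, blo, bhi), n, n)
  for (b in seq_along(block_sizes)) {
    idx <- which(lab == b)
    M[idx, idx] <- stats::runif(length(idx)^2, wlo, whi)
  }
  M <- (M + t(M)) / 2
  diag(M) <- 0
  dimnames(M) <- list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n))
  attr(M, "blocks") <- lab
  M
}

# independent hypergeometric upper-tail oracle via the combinatorial sum
hyper_upper_oracle <- function(k, K, N, n) {
  if (k <= max(0, n + K - N)) return(1)
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# literal enumeration oracle: fraction of all n-subsets of 1..N whose
# overlap with 1..K is at least k
hyper_enum_oracle <- function(k, K, N, n) {
  subsets <- utils::combn(N, n)
  mean(colSums(subsets <= K) >= k)
}

# minimal hand-built ap_result for lineage tests
fake_ap_result <- function(assignment) {
  exemplars <- unique(unname(assignment))
  structure(list(exemplars = exemplars, assignment = assignment,
                 n_iterations = 0L, converged = TRUE,
                 net_similarity = NA_real_,
                 preferences = NULL),
            class = "ap_result")
}

# lineage map with two cell types: CTA has a private regulator REGA,
# CTB's REGB also drives nothing else; modules MA (driven by REGA),
# MB (driven by REGB), MC (driven by both)
toy_lineage_map <- function() {
  reg_tab <- tempfile(fileext = ".tsv")
  writeLines(c("cell_type\tregulators",
               "CTA\tREGA",
               "CTB\tREGB"), reg_tab)
  lm <- load_regulator_table(reg_tab)
  modules <- data.frame(
    gene = c("A1", "A2", "B1", "B2", "C1", "C2"),
    module_id = c("MA", "MA", "MB", "MB", "MC", "MC"))
  regulation <- data.frame(
    regulator = c("REGA", "REGB", "REGA", "REGB"),
    module_id = c("MA", "MB", "MC", "MC"))
  lineage_map(lm, modules, regulation)
}
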
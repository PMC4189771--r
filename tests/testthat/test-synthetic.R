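test_that("interactome generation is seed-deterministic and validated", {
  a <- generate_interactome(n_genes = 40, n_groups = 2, group_size = 8,
                            within_shared_partners = 4, seed = 5)
  b <- generate_interactome(n_genes = 40, n_groups = 2, group_size = 8,
                            within_shared_partners = 4, seed = 5)
  expect_identical(network_edges(a$network), network_edges(b$network))
  cc <- generate_interactome(n_genes = 40, n_groups = 2, group_size = 8,
                             within_shared_partners = 4, seed = 6)
  expect_false(identical(network_edges(a$network), network_edges(cc$network)))
  expect_error(generate_interactome(n_genes = 10, n_groups = 3, group_size = 5,
                                    seed = 1),
               class = "pnsmap_validation_error")
  expect_error(generate_interactome(noise_edge_prob = 1.5, seed = 1),
               class = "pnsmap_validation_error")
  # planted groups are disjoint and cover each gene once
  genes <- unlist(a$truth$groups)
  expect_equal(anyDuplicated(genes), 0)
  expect_equal(length(genes), 16)
})

test_that("planted groups have identical neighborhoods when noise is off", {
  sim <- generate_interactome(n_genes = 20, n_groups = 2, group_size = 6,
                              within_shared_partners = 5, noise_edge_prob = 0,
                              seed = 9)
  suppressMessages(p <- build_pnsm(sim$network, unlist(sim$truth$groups)))
  lab <- rep(names(sim$truth$groups), lengths(sim$truth$groups))
  names(lab) <- unlist(sim$truth$groups)
  M <- as.matrix(p)
  same <- outer(lab[rownames(M)], lab[colnames(M)], "==")
  off <- row(M) != col(M)
  expect_true(all(M[same & off] == 1))     # shared-hub wiring is exact
  expect_true(all(M[!same & off] == 0))
})

test_that("the standard synthetic conditions separate planted groups", {
  sim <- generate_interactome(seed = 7)    # 5 groups x 20, 8 partners, 1% noise
  suppressMessages(p <- build_pnsm(sim$network, unlist(sim$truth$groups)))
  lab <- rep(names(sim$truth$groups), lengths(sim$truth$groups))
  names(lab) <- unlist(sim$truth$groups)
  M <- as.matrix(p)
  same <- outer(lab[rownames(M)], lab[colnames(M)], "==")
  off <- row(M) != col(M)
  expect_gte(mean(M[same & off]), 0.8)
  expect_lte(mean(M[!same & off]), 0.1)
})

test_that("the background interactome has a scale-free degree tail", {
  sim <- generate_interactome(n_genes = 204, n_groups = 1, group_size = 4,
                              within_shared_partners = 2, noise_edge_prob = 0,
                              seed = 29)
  deg <- network_degrees(sim$network)
  bg <- deg[setdiff(names(deg), unlist(sim$truth$groups))]
  bg <- bg[!startsWith(names(bg), "PART")]
  expect_gt(max(bg), 5 * stats::median(bg))   # heavy tail vs typical node
  expect_equal(unname(stats::median(bg)), 3)  # preferential attachment, m = 2
})

test_that("lineage generation plants unambiguous specific and common wiring", {
  sim <- generate_interactome(n_genes = 80, n_groups = 3, group_size = 10,
                              within_shared_partners = 4, seed = 13)
  lm <- load_regulator_table()
  lin <- generate_lineage(sim$truth, lm, coverage = 0.3)
  ct <- lin$truth$group_cell_type
  expect_length(ct, 3)
  expect_equal(unname(ct[3]), "common")
  expect_true(all(ct[1:2] %in% lm$cell_types))
  # specific groups: modules driven only by regulators exclusive to the type
  full <- lineage_map(lm, lin$modules, lin$regulation)
  res <- fake_ap_result(stats::setNames(
    rep(vapply(sim$truth$groups, `[`, character(1), 1), lengths(sim$truth$groups)),
    unlist(sim$truth$groups)))
  tab <- suppressMessages(associate_exemplars(res, full))
  expect_equal(tab$specificity[1:2], rep("lineage-specific", 2))
  expect_equal(tab$specificity[3], "common")
  expect_equal(sort(strsplit(tab$cell_types[3], ",")[[1]]), sort(lm$cell_types))
  # coverage parameter controls the interacting fraction of module genes
  cov <- module_coverage(lin$modules, sim$network)
  planted_cov <- cov$coverage_pct[cov$module_id %in% c("M01", "M02", "M03")]
  expect_true(all(abs(planted_cov - 30) < 5))
})

test_that("annotation generation plants one dominant term per group", {
  sim <- generate_interactome(n_genes = 60, n_groups = 3, group_size = 15,
                              within_shared_partners = 4, seed = 17)
  ann <- generate_annotations(sim$truth, n_decoy_terms = 10)
  expect_length(ann$truth$planted_terms, 3)
  for (g in names(sim$truth$groups)) {
    term <- ann$truth$planted_terms[[g]]
    overlap <- length(intersect(ann$annotations[[term]], sim$truth$groups[[g]]))
    expect_gte(overlap, ceiling(0.8 * 15))
  }
  # decoy overlap stays near the hypergeometric expectation
  decoys <- grep("DECOY", names(ann$annotations), value = TRUE)
  mean_frac <- mean(vapply(decoys, function(t) {
    length(intersect(ann$annotations[[t]], sim$truth$groups$group01)) /
      length(ann$annotations[[t]])
  }, numeric(1)))
  expect_lt(abs(mean_frac - 15 / 60), 0.15)
  # DAG is acyclic and anchored at a single root
  g <- igraph::graph_from_data_frame(ann$dag)
  expect_true(igraph::is_dag(g))
  expect_equal(sum(igraph::degree(g, mode = "out") == 0), 1)
  # same seed gives byte-identical GMT output
  p1 <- tempfile(); p2 <- tempfile()
  write_gmt(generate_annotations(sim$truth, n_decoy_terms = 10)$annotations, p1)
  write_gmt(generate_annotations(sim$truth, n_decoy_terms = 10)$annotations, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("a written dataset reloads through the pipeline's own readers", {
  d <- tempfile()
  files <- suppressMessages(write_synthetic_dataset(d, seed = 23,
                                                    n_genes = 60, n_groups = 2,
                                                    group_size = 10,
                                                    within_shared_partners = 4))
  expect_true(all(file.exists(unlist(files[c("interactions", "modules",
                                             "regulation", "gmt", "dag",
                                             "truth_path")]))))
  rec <- load_interactions(files$interactions)
  suppressMessages(net <- filter_interactions(rec))
  expect_equal(nrow(network_edges(net)),
               nrow(read.delim(files$interactions)))
  truth <- jsonlite::read_json(files$truth_path)
  expect_equal(truth$seed, 23)
  expect_length(truth$groups, 2)
})
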
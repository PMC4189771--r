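test_that("median preference is the median off-diagonal similarity", {
  M <- matrix(0, 3, 3)
  M[lower.tri(M)] <- c(0.1, 0.2, 0.9)
  M <- M + t(M)
  expect_equal(median_preference(M), rep(0.2, 3))
  # all off-diagonals equal
  E <- matrix(0.4, 2, 2); diag(E) <- 0
  expect_equal(median_preference(E), rep(0.4, 2))
  # pnsm method via as_similarity_matrix
  net <- two_gene_fixture()
  suppressMessages(p <- build_pnsm(net, c("A", "B", "P2")))
  expect_length(median_preference(p), 3)
})

test_that("responsibility updates follow the competing-exemplar rule", {
  # 2 genes, availabilities zero, s(1,1) = -1 (preference), s(1,2) = -2
  S <- matrix(c(-1, -2, -2, -1), 2, 2)
  st <- ap_state(2)
  st1 <- update_responsibilities(S, st, damping = 0)
  expect_equal(st1$responsibilities[1, 2], -2 - (-1))  # beaten by own preference
  expect_equal(st1$responsibilities[1, 1], -1 - (-2))  # beats the rival by 1
  expect_equal(st1$iteration, 1L)
  # damping blends old (zero) and new messages
  st_half <- update_responsibilities(S, st, damping = 0.5)
  expect_equal(st_half$responsibilities, st1$responsibilities / 2)
  # configuration forbids frozen messages
  expect_error(ap_config(damping = 1.0))
  # non-finite input reports the iteration index
  bad <- ap_state(2); bad$availabilities[1, 1] <- Inf
  expect_error(update_responsibilities(S, bad, 0),
               class = "pnsmap_numerical_error")
})

test_that("availability updates cap accumulated evidence at zero", {
  # 3 genes; candidate exemplar B = 3 with self-responsibility -1 and one
  # positive incoming responsibility 0.5
  st <- ap_state(3)
  st$responsibilities[3, 3] <- -1
  st$responsibilities[2, 3] <- 0.5
  st1 <- update_availabilities(st, damping = 0)
  expect_equal(st1$availabilities[1, 3], -0.5)   # min(0, -1 + 0.5)
  expect_equal(st1$availabilities[2, 3], -1)     # its own 0.5 excluded
  expect_equal(st1$availabilities[3, 3], 0.5)    # self: positive-part sum
  # all responsibilities toward B non-positive
  st$responsibilities[2, 3] <- -0.2
  st2 <- update_availabilities(st, damping = 0)
  expect_equal(st2$availabilities[1, 3], -1)
  # n = 2: empty sum leaves a(A,B) = min(0, r(B,B))
  st3 <- ap_state(2); st3$responsibilities <- matrix(c(0.3, 0, 0, -0.7), 2, 2)
  st4 <- update_availabilities(st3, damping = 0)
  expect_equal(st4$availabilities[1, 2], -0.7)
})

test_that("affinity propagation resolves planted blocks to their exemplars", {
  # single gene: its own exemplar
  one <- run_affinity_propagation(matrix(0.5, 1, 1, dimnames = list("A", "A")))
  expect_equal(one$exemplars, "A")
  expect_true(one$converged)
  set.seed(11)
  M <- planted_block_matrix(c(4, 4))
  res <- run_affinity_propagation(M, ap_config())
  expect_true(res$converged)
  expect_length(res$exemplars, 2)
  expect_equal(unname(split(names(res$assignment), res$assignment) |>
                        vapply(length, integer(1))), c(4, 4))
  # block-perfect: members assigned with their own block's exemplar
  lab <- attr(M, "blocks")
  expect_equal(adjusted_rand_index(res$assignment, lab), 1)
  # matches the exhaustive search optimum
  bf <- brute_force_exemplars(M)
  expect_equal(res$net_similarity, bf$net_similarity, tolerance = 1e-10)
  # self-consistency contract
  expect_true(all(res$assignment[res$exemplars] == res$exemplars))
  expect_true(all(res$assignment %in% res$exemplars))
})

test_that("equal-similarity degeneracy is broken by seeded jitter", {
  M <- matrix(0.6, 5, 5); diag(M) <- 0
  dimnames(M) <- list(letters[1:5], letters[1:5])
  res0 <- run_affinity_propagation(M, ap_config())
  expect_true(res0$converged)   # built-in tie breaking resolves exact ties
  res <- suppressWarnings(
    run_affinity_propagation(M, ap_config(noise_scale = 1e-6, seed = 4)))
  # every partition of an all-equal matrix has the same objective; the
  # jittered run must still land on (one of) the optima
  bf <- brute_force_exemplars(M)
  expect_equal(res$net_similarity, bf$net_similarity, tolerance = 1e-4)
  res2 <- suppressWarnings(
    run_affinity_propagation(M, ap_config(noise_scale = 1e-6, seed = 4)))
  expect_identical(res2$assignment, res$assignment)  # jitter is seed-stable
})

test_that("net similarity equals the hand-computed objective", {
  S <- matrix(c(0.0, 0.9, 0.1, 0.2,
                0.9, 0.0, 0.2, 0.1,
                0.1, 0.2, 0.0, 0.8,
                0.2, 0.1, 0.8, 0.0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  res <- fake_ap_result(c(a = "a", b = "a", c = "c", d = "c"))
  res$preferences <- c(a = -0.5, b = -0.5, c = -0.5, d = -0.5)
  # s(b,a) + s(d,c) + pref(a) + pref(c)
  expect_equal(net_similarity(S, res), 0.9 + 0.8 - 1.0)
  # single point: the preference itself
  one <- fake_ap_result(c(a = "a")); one$preferences <- c(a = -2)
  expect_equal(net_similarity(matrix(0, 1, 1, dimnames = list("a", "a")), one), -2)
  # assignment to a non-exemplar violates the contract
  bad <- fake_ap_result(c(a = "a", b = "a")); bad$assignment[["b"]] <- "b"
  bad$exemplars <- "a"; bad$preferences <- c(a = 0, b = 0)
  expect_error(net_similarity(S[1:2, 1:2], bad), class = "pnsmap_contract_error")
})

test_that("exhaustive exemplar search picks the optimal configuration", {
  # 2 genes, strongly negative preferences, high mutual similarity -> merge
  S <- matrix(c(0, 0.9, 0.9, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  bf <- brute_force_exemplars(S, preference = -5)
  expect_length(bf$exemplars, 1)
  expect_equal(bf$net_similarity, 0.9 - 5)
  # 3 pairwise-dissimilar genes with high preferences -> all exemplars
  D <- matrix(0.05, 3, 3); diag(D) <- 0
  dimnames(D) <- list(letters[1:3], letters[1:3])
  bf3 <- brute_force_exemplars(D, preference = 1)
  expect_setequal(bf3$exemplars, c("a", "b", "c"))
  expect_equal(bf3$net_similarity, 3)
  # size guard
  big <- matrix(0, 13, 13)
  expect_error(brute_force_exemplars(big), class = "pnsmap_size_error")
})

test_that("raising all preferences never decreases the exemplar count", {
  set.seed(21)
  M <- planted_block_matrix(c(4, 3, 3))
  grid <- c(-20, -10, -5, -2, -1, -0.5, 0, 0.5, 1, 1.5)
  counts <- vapply(grid, function(p) {
    length(suppressWarnings(
      run_affinity_propagation(M, ap_config(preference = p,
                                            noise_scale = 1e-6, seed = 5))
    )$exemplars)
  }, integer(1))
  expect_true(all(diff(counts) >= 0))
  expect_equal(counts[1], 1)          # very negative preference: one cluster
  expect_equal(counts[length(grid)], 10)  # preference above all similarities
})

test_that("partitions agree with an independent affinity propagation implementation", {
  set.seed(31)
  M <- planted_block_matrix(c(5, 4, 3))
  res <- run_affinity_propagation(M, ap_config())
  csv <- tempfile(fileext = ".csv"); out <- tempfile(); diag(M) <- median_preference(M)[1]
  write.table(M, csv, sep = ",", row.names = FALSE, col.names = FALSE)
  status <- suppressWarnings(system2("python", c("-c", shQuote(paste0(
    "import sys, numpy as np\n",
    "from sklearn.cluster import AffinityPropagation\n",
    "S = np.loadtxt(sys.argv[1], delimiter=',')\n",
    "ap = AffinityPropagation(affinity='precomputed', damping=0.5, random_state=0)\n",
    "np.savetxt(sys.argv[2], ap.fit_predict(S), fmt='%d')\n")),
    csv, out), stdout = FALSE, stderr = FALSE))
  expect_identical(status, 0L)
  ref <- scan(out, quiet = TRUE)
  expect_equal(length(unique(ref)), length(res$exemplars))
  expect_equal(adjusted_rand_index(res$assignment, ref), 1)
})
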
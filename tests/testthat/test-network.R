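# Distances, the locally scaled exponential kernel, Louvain communities.

test_that("profile distances are Euclidean (sqrt of Hamming on binary data)", {
  prof <- rbind(a = c(1, rep(0, 10)),
                b = c(0, 1, rep(0, 9)),
                c = rep(1, 11),
                d = rep(0, 11),
                a2 = c(1, rep(0, 10)))
  colnames(prof) <- pathway_names()
  D <- pairwise_distance(prof)
  expect_equal(D["a", "a2"], 0)
  expect_equal(D["a", "b"], sqrt(2))
  expect_equal(D["c", "d"], sqrt(11))
  expect_error(pairwise_distance(prof[, 1:5]), "dimension error")
  expect_error(pairwise_distance(prof[1, , drop = FALSE]), "at least 2")
})

test_that("kernel reproduces the 3-patient hand computation", {
  D <- matrix(c(0, 1, 2,
                1, 0, 1,
                2, 1, 0), 3, 3)
  W <- scaled_exponential_kernel(D, k_neighbors = 1, mu = 0.5)
  # eps_12 = (1 + 1 + 1)/3 = 1 -> W_12 = exp(-1 / 0.5)
  expect_equal(W[1, 2], exp(-2), tolerance = 1e-12)
  # eps_13 = (1 + 1 + 2)/3 = 4/3 -> W_13 = exp(-4 / (0.5 * 4/3)) = exp(-6)
  expect_equal(W[1, 3], exp(-6), tolerance = 1e-12)
  expect_equal(W[2, 3], exp(-2), tolerance = 1e-12)
  expect_equal(diag(W), rep(0, 3))
})

test_that("kernel properties: symmetry, range, zero distance, monotonicity", {
  set.seed(5)
  prof <- matrix(rbinom(30 * 11, 1, 0.4), 30, 11,
                 dimnames = list(sprintf("P%02d", 1:30), pathway_names()))
  prof[2, ] <- prof[1, ]  # duplicated profile -> zero distance
  D <- pairwise_distance(prof)
  W <- scaled_exponential_kernel(D)
  expect_equal(max(abs(W - t(W))), 0)
  off <- W[upper.tri(W)]
  expect_true(all(off > 0 & off <= 1))
  expect_equal(W[1, 2], 1)  # zero distance with positive eps -> exp(0)
  # doubling mu weakens the decay: every off-diagonal weight increases
  W2 <- scaled_exponential_kernel(D, mu = 1)
  pos <- D[upper.tri(D)] > 0
  expect_true(all(W2[upper.tri(W2)][pos] > off[pos]))
  # fixed eps: weight strictly decreases as distance grows
  eps <- 1
  d <- seq(0.1, 3, by = 0.1)
  expect_true(all(diff(exp(-d^2 / (0.5 * eps))) < 0))
  expect_error(scaled_exponential_kernel(D, k_neighbors = 30), "parameter")
  expect_error(scaled_exponential_kernel(D, mu = 0), "parameter")
})

test_that("identical local neighborhoods at zero distance give weight 1", {
  # all-identical profiles: D == 0 everywhere, eps == 0; weight 1 by
  # continuity, not an error
  D <- matrix(0, 3, 3)
  W <- scaled_exponential_kernel(D, k_neighbors = 1)
  expect_equal(W[upper.tri(W)], rep(1, 3))
})

test_that("Louvain separates planted cliques and relabels canonically", {
  W <- matrix(0.01, 10, 10)
  W[1:5, 1:5] <- 1; W[6:10, 6:10] <- 1
  diag(W) <- 0
  rownames(W) <- colnames(W) <- sprintf("P%02d", 1:10)
  part <- detect_communities(W, seed = 1, n_restarts = 5)
  expect_equal(part$n_communities, 2)
  expect_equal(unname(part$assignment[1:5]), rep(0L, 5))
  expect_equal(unname(part$assignment[6:10]), rep(1L, 5))
  expect_true(has_community_structure(part)$has_structure)
})

test_that("degenerate graphs: single node and uniform weights", {
  W1 <- matrix(0, 1, 1, dimnames = list("solo", "solo"))
  p1 <- detect_communities(W1, seed = 1)
  expect_equal(p1$n_communities, 1)
  expect_equal(p1$modularity, 0)
  expect_false(has_community_structure(p1)$has_structure)
  # complete graph with uniform weights has Q ~ 0 whatever the labels
  Wu <- matrix(1, 12, 12); diag(Wu) <- 0
  pu <- detect_communities(Wu, seed = 1, n_restarts = 5)
  expect_false(has_community_structure(pu)$has_structure)
  # threshold dominance
  W <- matrix(0.01, 10, 10); W[1:5, 1:5] <- 1; W[6:10, 6:10] <- 1; diag(W) <- 0
  strong <- detect_communities(W, seed = 1, n_restarts = 5)
  expect_false(has_community_structure(strong, q_min = 1.0)$has_structure)
  expect_error(detect_communities(matrix(numeric(0), 0, 0)), "empty")
})

test_that("community detection is deterministic and Q matches a hand oracle", {
  pp <- generate_planted_partition(seed = 7)
  net <- build_similarity_network(pp$profiles)
  p1 <- detect_communities(net, seed = 3, n_restarts = 10)
  p2 <- detect_communities(net, seed = 3, n_restarts = 10)
  expect_identical(p1$assignment, p2$assignment)
  expect_identical(p1$modularity, p2$modularity)
  expect_equal(p1$modularity,
               modularity_hand(net$W, p1$assignment[net$patient_ids]),
               tolerance = 1e-10)
})

test_that("zero-distance duplicate profiles co-cluster under strong structure", {
  set.seed(9)
  base <- rbind(matrix(rep(c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0, 0), 6), 6,
                       byrow = TRUE),
                matrix(rep(c(0, 0, 0, 0, 0, 0, 0, 1, 1, 1, 1), 6), 6,
                       byrow = TRUE))
  dimnames(base) <- list(sprintf("P%02d", 1:12), pathway_names())
  net <- build_similarity_network(base)
  part <- detect_communities(net, seed = 1, n_restarts = 5)
  expect_equal(part$n_communities, 2)
  expect_length(unique(part$assignment[1:6]), 1)
  expect_length(unique(part$assignment[7:12]), 1)
})
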
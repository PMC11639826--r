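# Community profiles, TMB comparison, high-TMB enrichment, profile
# correlation.

make_partition <- function(assignment) {
  structure(list(assignment = assignment,
                 modularity = 0.3,
                 n_communities = length(unique(assignment)),
                 resolution = 1, seed = 1, n_restarts = 1, best_seed = 1),
            class = "community_partition")
}

test_that("community profiles are membership percentages", {
  prof <- matrix(0L, 9, 11, dimnames = list(sprintf("P%d", 1:9),
                                            pathway_names()))
  prof[1:6, "ddr"] <- 1L  # 6 of the 8 members of community 0
  prof[1:8, "p53"] <- 1L
  part <- make_partition(stats::setNames(c(rep(0L, 8), 1L), rownames(prof)))
  cp <- community_profiles(part, prof)
  expect_equal(cp$size, c(8, 1))
  expect_equal(cp$ddr, c(75, 0))
  expect_equal(cp$p53, c(100, 0))
  # singleton community with the all-zero profile: all entries 0
  expect_equal(unlist(cp[2, pathway_names()], use.names = FALSE), rep(0, 11))
  expect_error(community_profiles(part, prof[1:5, ]), "identical patients")
})

test_that("community profiles aggregate to the cohort profile by size", {
  fx <- build_realworld_fixture()
  prof <- build_pathway_profiles(fx)
  ns_ids <- fx$patients$patient_id[fx$patients$smoking_status == "never"]
  ns_prof <- prof[ns_ids, ]
  part <- detect_communities(build_similarity_network(ns_prof),
                             seed = 1, n_restarts = 10)
  cp <- community_profiles(part, ns_prof)
  expect_equal(sum(cp$size), length(ns_ids))
  weighted <- colSums(as.matrix(cp[, pathway_names()]) * cp$size) / sum(cp$size)
  expect_equal(unname(weighted), unname(100 * colMeans(ns_prof)),
               tolerance = 1e-12)
})

test_that("TMB comparison reproduces the tie-free hand computation", {
  pts <- data.frame(patient_id = sprintf("P%d", 1:6),
                    tmb = c(1, 2, 3, 10, 11, 12))
  part <- make_partition(stats::setNames(c(0L, 0L, 0L, 1L, 1L, 1L),
                                         pts$patient_id))
  cmp <- compare_tmb(part, pts)
  expect_equal(cmp$statistic, 27 / 7, tolerance = 1e-12)  # H = 3.857...
  expect_equal(cmp$p_value, stats::pchisq(27 / 7, 1, lower.tail = FALSE))
  # rank invariance under a monotone transformation
  pts2 <- pts; pts2$tmb <- log1p(pts$tmb)
  expect_equal(compare_tmb(part, pts2)$statistic, cmp$statistic)
  # identical groups -> balanced ranks, H = 0
  pts3 <- pts; pts3$tmb <- c(1, 2, 3, 1, 2, 3)
  expect_equal(compare_tmb(part, pts3)$statistic, 0, tolerance = 1e-12)
  # all values identical -> degenerate convention H = 0, p = 1
  pts4 <- pts; pts4$tmb <- rep(5, 6)
  deg <- compare_tmb(part, pts4)
  expect_true(deg$degenerate)
  expect_equal(c(deg$statistic, deg$p_value), c(0, 1))
})

test_that("high-TMB community enrichment uses the stratum background", {
  strata <- data.frame(patient_id = sprintf("P%02d", 1:20),
                       tmb_class = rep(c("H", "L"), c(6, 14)),
                       smoking_class = "NS",
                       subgroup = rep(c("NS/H", "NS/L"), c(6, 14)))
  part <- make_partition(stats::setNames(rep(c(0L, 1L), c(6, 14)),
                                         strata$patient_id))
  # community 0 is exactly the high-TMB patients -> minimal possible p
  h <- htmb_enrichment(part, strata, 0)
  expect_equal(h$k, 6)
  expect_equal(h$p_value, hyper_brute(20, 6, 6, 6), tolerance = 1e-12)
  # community without high-TMB members -> p = 1
  h1 <- htmb_enrichment(part, strata, 1)
  expect_equal(h1$k, 0)
  expect_equal(h1$p_value, 1)
  expect_error(htmb_enrichment(part, strata, 5), "no such community")
})

test_that("published-scale high-TMB enrichment matches the oracle", {
  # a 57-patient community holding 14 of the 18 high-TMB patients in a
  # 140-patient stratum
  strata <- data.frame(patient_id = sprintf("V%03d", 1:140),
                       tmb_class = rep("L", 140))
  strata$tmb_class[c(1:14, 58:61)] <- "H"
  part <- make_partition(stats::setNames(rep(c(0L, 1L), c(57, 83)),
                                         strata$patient_id))
  h <- htmb_enrichment(part, strata, 0)
  expect_equal(c(h$N, h$K, h$n, h$k), c(140, 18, 57, 14))
  expect_equal(h$p_value, hyper_brute(140, 18, 57, 14), tolerance = 1e-12)
})

test_that("profile correlation: hand cases and symmetry", {
  a <- c(10, 20, 30, 40, 5, 15, 25, 35, 45, 50, 12)
  pc <- profile_correlation(a, a, n_perm = 1e3)
  expect_equal(pc$rho, 1)
  pc_rev <- profile_correlation(a, -a, n_perm = 1e3)
  expect_equal(pc_rev$rho, -1)
  # length-4 toy: ranks (1,2,3,4) vs (1,3,2,4) -> rho = 0.8
  toy <- profile_correlation(c(10, 20, 30, 40), c(1, 3, 2, 4), n_perm = 1e4)
  expect_equal(toy$rho, 0.8)
  b <- c(9, 4, 30, 2, 40, 7, 1, 20, 18, 3, 25)
  expect_equal(profile_correlation(a, b, n_perm = 1e3, seed = 2)$rho,
               profile_correlation(b, a, n_perm = 1e3, seed = 2)$rho)
  expect_error(profile_correlation(a, rep(1, 11)), "zero-variance")
})

test_that("permutation p-value agrees with the exact null on 4 elements", {
  # n = 4 without ties: enumerate all 24 permutations for the exact
  # two-sided null probability of |rho| >= |rho_obs|
  a <- c(10, 20, 30, 40); b <- c(1, 3, 2, 4)
  perms <- as.matrix(expand.grid(rep(list(1:4), 4)))
  perms <- perms[apply(perms, 1, function(x) length(unique(x)) == 4), ]
  rho_null <- apply(perms, 1, function(x) cor(rank(a), rank(b)[x]))
  rho_obs <- cor(rank(a), rank(b))
  exact <- mean(abs(rho_null) >= abs(rho_obs) - 1e-12)
  toy <- profile_correlation(a, b, n_perm = 2e5, seed = 1)
  expect_equal(toy$p_value, exact, tolerance = 0.01)
})
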
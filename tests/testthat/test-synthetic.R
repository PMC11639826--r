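# Synthetic generator, deterministic fixture, planted partitions.

test_that("fixture marginals hold exactly", {
  fx <- build_realworld_fixture()
  expect_equal(nrow(fx$patients), 142)
  expect_equal(sum(fx$patients$smoking_status == "never"), 31)
  expect_equal(sum(fx$patients$smoking_status != "never"), 111)
  prof <- build_pathway_profiles(fx)
  st <- stratify(fx$patients)
  tab <- pathway_summary(prof, st)
  expect_equal(tab$S_count, c(50, 1, 9, 13, 16, 42, 86, 2, 85, 7, 21))
  expect_equal(tab$NS_count, c(14, 1, 3, 8, 7, 7, 26, 1, 23, 5, 14))
  expect_equal(tab$S_pct,
               c(45.0, 0.9, 8.1, 11.7, 14.4, 37.8, 77.5, 1.8, 76.6, 6.3, 18.9))
  expect_equal(tab$NS_pct,
               c(45.2, 3.2, 9.7, 25.8, 22.6, 22.6, 83.9, 3.2, 74.2, 16.1, 45.2))
  # stratum TMB medians and the never-smoker/high-TMB subgroup
  ns <- fx$patients$smoking_status == "never"
  expect_equal(median(fx$patients$tmb[ns]), 4)
  expect_equal(median(fx$patients$tmb[!ns]), 8)
  nsh <- st$patient_id[st$subgroup == "NS/H"]
  expect_length(nsh, 11)
  expect_equal(median(fx$patients$tmb[match(nsh, fx$patients$patient_id)]),
               16.39)
  expect_equal(sum(prof[nsh, "ddr"]), 8)
  resp <- fx$patients$best_response[match(nsh, fx$patients$patient_id)]
  expect_true(all(resp %in% c("CR", "PR")))
  expect_equal(sum(st$tmb_class == "H"), 53)
})

test_that("fixture construction is deterministic, file-level", {
  d1 <- file.path(tempdir(), "fx1"); d2 <- file.path(tempdir(), "fx2")
  write_cohort(build_realworld_fixture(), d1)
  write_cohort(build_realworld_fixture(), d2)
  for (f in c("mutations.tsv", "clinical.tsv", "pathways.gmt")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("fixture profiles rebuild identically from emitted mutations", {
  fx <- build_realworld_fixture()
  d <- file.path(tempdir(), "fx_rt")
  write_cohort(fx, d)
  back <- read_cohort(d)
  expect_equal(build_pathway_profiles(back), build_pathway_profiles(fx))
})

test_that("generator is reproducible and respects stratum sizes", {
  cfg <- generator_config()
  c1 <- generate_cohort(cfg, seed = 1)
  c2 <- generate_cohort(cfg, seed = 1)
  expect_identical(c1$patients, c2$patients)
  expect_identical(c1$mutations, c2$mutations)
  # binomial 99% interval for 31/142 never-smokers at p = 31/142
  n_ns <- sum(c1$patients$smoking_status == "never")
  bounds <- qbinom(c(0.005, 0.995), 142, 31 / 142)
  expect_gte(n_ns, bounds[1]); expect_lte(n_ns, bounds[2])
  # planted subgroup: all high-TMB never-smokers, all responders
  planted <- attr(c1, "planted_ids")
  expect_length(planted, 11)
  p <- c1$patients[match(planted, c1$patients$patient_id), ]
  expect_true(all(p$smoking_status == "never"))
  expect_true(all(p$tmb > 10))
  expect_true(all(p$best_response %in% c("CR", "PR")))
})

test_that("generated TMB medians track the configured stratum medians", {
  cfg <- generator_config(n_patients = 1000L, planted_size = 0L)
  co <- generate_cohort(cfg, seed = 42)
  ns <- co$patients$smoking_status == "never"
  expect_gt(median(co$patients$tmb[ns]), 2.5)
  expect_lt(median(co$patients$tmb[ns]), 6)
  expect_gt(median(co$patients$tmb[!ns]), 6)
  expect_lt(median(co$patients$tmb[!ns]), 11)
})

test_that("generated pathway frequencies are calibrated to the configured rates", {
  cfg <- generator_config(planted_size = 0L)
  counts <- matrix(0, 0, 11)
  ns_tot <- 0; s_tot <- 0; s_counts <- rep(0, 11); ns_counts <- rep(0, 11)
  for (s in 1:50) {
    co <- generate_cohort(cfg, seed = s)
    prof <- build_pathway_profiles(co)
    ns <- co$patients$smoking_status == "never"
    s_counts <- s_counts + colSums(prof[!ns, , drop = FALSE])
    ns_counts <- ns_counts + colSums(prof[ns, , drop = FALSE])
    s_tot <- s_tot + sum(!ns); ns_tot <- ns_tot + sum(ns)
  }
  for (j in 1:11) {
    p_s <- cfg$s_pathway_probs[j]
    se_s <- sqrt(p_s * (1 - p_s) / s_tot)
    expect_lt(abs(s_counts[j] / s_tot - p_s), 3 * se_s + 1e-9)
    p_ns <- cfg$ns_pathway_probs[j]
    se_ns <- sqrt(p_ns * (1 - p_ns) / ns_tot)
    expect_lt(abs(ns_counts[j] / ns_tot - p_ns), 3 * se_ns + 1e-9)
  }
})

test_that("generated cohorts round-trip through the standard files", {
  co <- generate_cohort(generator_config(n_patients = 40L, planted_size = 3L),
                        seed = 5)
  d <- file.path(tempdir(), "gen_rt")
  write_cohort(co, d)
  back <- read_cohort(d)
  expect_equal(build_pathway_profiles(back), build_pathway_profiles(co))
  expect_equal(back$patients, co$patients)
})

test_that("infeasible planted subgroup errors", {
  cfg <- generator_config(n_patients = 20L, planted_size = 19L)
  expect_error(generate_cohort(cfg, seed = 1), "infeasible")
})

test_that("planted partition: templates, noise bounds, determinism", {
  pp0 <- generate_planted_partition(noise_rate = 0, seed = 3)
  # zero noise: every member equals its block template
  expect_equal(unname(pp0$profiles[1, ]), rep(0, 11))
  expect_true(all(apply(pp0$profiles[pp0$labels == 2, ], 1, function(x)
    all(x == c(1, 1, 1, 1, 1, 1, 1, 0, 0, 0, 0)))))
  expect_error(generate_planted_partition(noise_rate = 0.5), "noise_rate")
  expect_error(generate_planted_partition(noise_rate = -0.1), "noise_rate")
  p1 <- generate_planted_partition(seed = 11)
  p2 <- generate_planted_partition(seed = 11)
  expect_identical(p1$profiles, p2$profiles)
  # profiles rebuild from the emitted cohort
  expect_equal(unname(build_pathway_profiles(p1$cohort)),
               unname(p1$profiles))
})

test_that("externally reported statistics are flagged as non-verifiable", {
  ct <- calibration_targets()
  expect_true(all(!ct$verifiable_here))
  expect_true(all(ct$role %in% c("generator_calibration", "external_context")))
  # the generator's survival calibration uses exactly the reported medians
  cfg <- generator_config()
  expect_equal(unname(cfg$os_medians["NS/H"]),
               ct$value[ct$quantity == "ns_htmb_median_os_months"])
})
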
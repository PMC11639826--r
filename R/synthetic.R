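# Synthetic cohorts. Two distinct artifacts:
#   * generate_cohort(): a stochastic generator with the statistical structure
#     the pipeline assumes (stratum sizes, per-stratum pathway rates, TMB
#     distributions, a planted never-smoker/high-TMB subgroup enriched for
#     DDR and beta-catenin/Wnt, exponential survival with administrative
#     censoring) — used for calibration and power-style checks.
#   * build_realworld_fixture(): a fully deterministic, seed-free cohort whose
#     printed marginals (stratum sizes 111/31, the 22 per-pathway mutated
#     counts, an 11-patient NS/H subgroup with 8 DDR-mutated and 11/11
#     responders, stratum TMB medians 8/4, NS/H median 16.39) hold exactly.
#     Within-patient co-occurrence outside those constraints is one greedy
#     completion among many, arranged so the never-smoker network shows a
#     high-TMB DDR-rich block.

# Published marginal counts used as generator defaults and fixture targets.
.table2_s_counts <- c(50, 1, 9, 13, 16, 42, 86, 2, 85, 7, 21)
.table2_ns_counts <- c(14, 1, 3, 8, 7, 7, 26, 1, 23, 5, 14)
.n_smokers <- 111L
.n_never <- 31L

#' Generator configuration
#'
#' Defaults emulate the discovery cohort: 142 patients, smoker fraction
#' 111/142, per-stratum pathway mutation probabilities equal to the published
#' per-stratum frequencies, log-normal TMB with stratum medians 8 (smokers)
#' and 4 (never-smokers) Mut/Mb, and a planted 11-patient never-smoker
#' high-TMB subgroup with boosted DDR (0.9) and beta-catenin/Wnt (0.5)
#' mutation probabilities, all-responder response distribution and a reduced
#' death hazard. Survival is exponential (median-parameterized) with uniform
#' administrative censoring.
#'
#' @param n_patients Cohort size.
#' @param smoker_fraction Probability a patient is a (current/former) smoker.
#' @param s_pathway_probs,ns_pathway_probs Length-11 mutation probabilities.
#' @param s_tmb_median,ns_tmb_median Stratum TMB medians (Mut/Mb).
#' @param tmb_sdlog Log-scale SD of the log-normal TMB distributions.
#' @param planted_size Size of the planted NS/H subgroup (0 disables it).
#' @param planted_tmb_median TMB median of the planted subgroup.
#' @param planted_probs Named numeric vector of boosted pathway probabilities
#'   for planted patients (default `c(ddr = 0.9, beta_catenin_wnt = 0.5)`).
#' @param os_medians,pfs_medians Named per-subgroup exponential medians
#'   (months) for the four subgroups `S/H`, `S/L`, `NS/H`, `NS/L`.
#' @param planted_hazard_multiplier Multiplies the planted subgroup's death
#'   and progression hazards (< 1 means longer survival).
#' @param censor_window Administrative censoring window (months), uniform.
#' @param response_probs Named list of RECIST category probabilities per
#'   smoking class, plus `planted`.
#' @param noise_mutation_rate Poisson mean of non-pathogenic passenger
#'   mutation records emitted per patient.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_patients = 142L,
                             smoker_fraction = 111 / 142,
                             s_pathway_probs = .table2_s_counts / 111,
                             ns_pathway_probs = .table2_ns_counts / 31,
                             s_tmb_median = 8,
                             ns_tmb_median = 4,
                             tmb_sdlog = 0.9,
                             planted_size = 11L,
                             planted_tmb_median = 16.39,
                             planted_probs = c(ddr = 0.9, beta_catenin_wnt = 0.5),
                             os_medians = c("S/H" = 18, "S/L" = 18,
                                            "NS/H" = 27.95, "NS/L" = 10),
                             pfs_medians = c("S/H" = 12, "S/L" = 12,
                                             "NS/H" = 16, "NS/L" = 6),
                             planted_hazard_multiplier = 0.65,
                             censor_window = c(12, 36),
                             response_probs = list(
                               S = c(CR = 0.03, PR = 0.30, SD = 0.30,
                                     PD = 0.32, NE = 0.05),
                               NS = c(CR = 0.02, PR = 0.18, SD = 0.25,
                                      PD = 0.50, NE = 0.05),
                               planted = c(CR = 0.2, PR = 0.8, SD = 0,
                                           PD = 0, NE = 0)),
                             noise_mutation_rate = 1) {
  cfg <- list(n_patients = as.integer(n_patients),
              smoker_fraction = smoker_fraction,
              s_pathway_probs = s_pathway_probs,
              ns_pathway_probs = ns_pathway_probs,
              s_tmb_median = s_tmb_median, ns_tmb_median = ns_tmb_median,
              tmb_sdlog = tmb_sdlog,
              planted_size = as.integer(planted_size),
              planted_tmb_median = planted_tmb_median,
              planted_probs = planted_probs,
              os_medians = os_medians, pfs_medians = pfs_medians,
              planted_hazard_multiplier = planted_hazard_multiplier,
              censor_window = censor_window,
              response_probs = response_probs,
              noise_mutation_rate = noise_mutation_rate)
  probs <- c(cfg$s_pathway_probs, cfg$ns_pathway_probs, cfg$planted_probs,
             cfg$smoker_fraction, unlist(cfg$response_probs))
  stopifnot(all(probs >= 0), all(probs <= 1),
            length(cfg$s_pathway_probs) == 11,
            length(cfg$ns_pathway_probs) == 11,
            all(cfg$os_medians > 0), all(cfg$pfs_medians > 0),
            cfg$planted_tmb_median > 0)
  structure(cfg, class = "generator_config")
}

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

.sample_response <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

# Emit mutation records consistent with a profile matrix: one pathogenic
# mutation per set bit, in a gene unique to that pathway, plus Poisson
# passenger records with both pathogenicity flags false.
.mutations_from_profiles <- function(prof, catalog, noise_rate = 0,
                                     random_gene = TRUE) {
  uniq <- unique_pathway_genes(catalog)
  rows <- list()
  ids <- rownames(prof)
  for (i in seq_along(ids)) {
    for (p in colnames(prof)[prof[i, ] == 1]) {
      gene <- if (random_gene) sample(uniq[[p]], 1) else uniq[[p]][1]
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = ids[i], gene = gene,
        variant_label = paste0(gene, ":synthetic_pathogenic"),
        cosmic_pathogenic = TRUE,
        clinvar_pathogenic = (match(p, pathway_names()) %% 2 == 1),
        stringsAsFactors = FALSE)
    }
    n_noise <- if (noise_rate > 0) stats::rpois(1, noise_rate) else 0
    if (n_noise > 0) {
      genes <- sample(unlist(catalog, use.names = FALSE), n_noise, replace = TRUE)
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = ids[i], gene = genes,
        variant_label = paste0(genes, ":synthetic_vus"),
        cosmic_pathogenic = FALSE, clinvar_pathogenic = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(patient_id = character(), gene = character(),
                      variant_label = character(),
                      cosmic_pathogenic = logical(),
                      clinvar_pathogenic = logical()))
  }
  do.call(rbind, rows)
}

#' Generate a synthetic cohort
#'
#' Samples smoking status, pathway profiles (independent Bernoulli bits at
#' the per-stratum rates, overridden in the planted subgroup), log-normal
#' TMB (the planted subgroup's TMB is drawn above the 10 Mut/Mb cutoff),
#' exponential survival with uniform administrative censoring, and RECIST
#' best response; then emits mutation records whose deleterious-filtered
#' pathway profile reconstructs the sampled bits exactly. Reproducible given
#' the seed.
#'
#' @param cfg A `generator_config`.
#' @param seed Integer seed.
#' @param catalog Pathway catalog; default [default_catalog()].
#' @return A `cohort`, with the planted patient ids in
#'   `attr(, "planted_ids")`.
#' @export
generate_cohort <- function(cfg = generator_config(), seed = 1,
                            catalog = default_catalog()) {
  stopifnot(inherits(cfg, "generator_config"))
  .with_seed(seed, {
    n <- cfg$n_patients
    ids <- sprintf("SYN%03d", seq_len(n))
    smoker <- stats::runif(n) < cfg$smoker_fraction
    ns_ids <- ids[!smoker]
    if (cfg$planted_size > length(ns_ids)) {
      stop("infeasible config: planted subgroup larger than the sampled ",
           "never-smoker stratum (", length(ns_ids), " patients)")
    }
    planted <- if (cfg$planted_size > 0) sample(ns_ids, cfg$planted_size)
               else character(0)
    # pathway bits
    prof <- matrix(0L, n, 11, dimnames = list(ids, pathway_names()))
    for (i in seq_len(n)) {
      pr <- if (smoker[i]) cfg$s_pathway_probs else cfg$ns_pathway_probs
      names(pr) <- pathway_names()
      if (ids[i] %in% planted) pr[names(cfg$planted_probs)] <- cfg$planted_probs
      prof[i, ] <- as.integer(stats::runif(11) < pr)
    }
    # TMB: log-normal by stratum; planted patients redrawn above the cutoff
    med <- ifelse(smoker, cfg$s_tmb_median, cfg$ns_tmb_median)
    tmb <- stats::rlnorm(n, meanlog = log(med), sdlog = cfg$tmb_sdlog)
    is_planted <- ids %in% planted
    if (any(is_planted)) {
      np <- sum(is_planted)
      draw <- stats::rlnorm(np, log(cfg$planted_tmb_median), 0.35)
      tmb[is_planted] <- pmax(draw, 10 + stats::runif(np, 0.1, 2))
    }
    # survival: exponential with subgroup medians, administrative censoring
    sub <- paste(ifelse(smoker, "S", "NS"), ifelse(tmb > 10, "H", "L"), sep = "/")
    os_rate <- log(2) / cfg$os_medians[sub]
    pfs_rate <- log(2) / cfg$pfs_medians[sub]
    os_rate[is_planted] <- os_rate[is_planted] * cfg$planted_hazard_multiplier
    pfs_rate[is_planted] <- pfs_rate[is_planted] * cfg$planted_hazard_multiplier
    t_os <- stats::rexp(n, os_rate)
    t_pfs <- stats::rexp(n, pfs_rate)
    cens <- stats::runif(n, cfg$censor_window[1], cfg$censor_window[2])
    os_months <- pmin(t_os, cens); os_event <- t_os <= cens
    pfs_months <- pmin(t_pfs, cens, t_os)
    pfs_event <- t_pfs <= pmin(cens, t_os)
    # response
    resp <- character(n)
    resp[smoker] <- .sample_response(sum(smoker), cfg$response_probs$S)
    resp[!smoker & !is_planted] <-
      .sample_response(sum(!smoker & !is_planted), cfg$response_probs$NS)
    if (any(is_planted)) {
      resp[is_planted] <- .sample_response(np, cfg$response_probs$planted)
    }
    patients <- data.frame(
      patient_id = ids,
      smoking_status = ifelse(smoker,
                              ifelse(stats::runif(n) < 0.5, "former", "current"),
                              "never"),
      tmb = round(tmb, 2),
      pdl1_pct = round(stats::runif(n, 50, 100), 1),
      os_months = round(os_months, 2), os_event = os_event,
      pfs_months = round(pfs_months, 2), pfs_event = pfs_event,
      best_response = resp, stringsAsFactors = FALSE)
    mutations <- .mutations_from_profiles(prof, catalog,
                                          noise_rate = cfg$noise_mutation_rate)
    out <- cohort(patients, mutations, catalog)
    attr(out, "planted_ids") <- planted
    out
  })
}

# ---- deterministic fixture ---------------------------------------------

# Set bits for `count` patients starting at `rows` (explicit row indices).
.set_bits <- function(mat, rows, pathway) {
  mat[rows, pathway] <- 1L
  mat
}

.fixture_ns_profiles <- function() {
  m <- matrix(0L, 31, 11, dimnames = list(sprintf("NS%02d", 1:31),
                                          pathway_names()))
  # Community-style block 1 (NS01-08, all high-TMB): dense co-mutation.
  m <- .set_bits(m, 1:7, "cell_cycle")
  m <- .set_bits(m, 1:6, "notch")
  m <- .set_bits(m, 1:5, "oxidative_stress_nrf2")
  m <- .set_bits(m, 6:8, "pi3k")
  m <- .set_bits(m, 2:8, "rtk_ras_map")
  m <- .set_bits(m, c(1, 3:8), "p53")
  m <- .set_bits(m, 4:8, "beta_catenin_wnt")
  m <- .set_bits(m, 1:6, "ddr")
  # Block 2 (NS09-12): RTK/RAS/MAP + p53 in all members.
  m <- .set_bits(m, 9:12, "rtk_ras_map")
  m <- .set_bits(m, 9:12, "p53")
  # Block 3 (NS13-19): cell cycle + RTK/RAS/MAP + p53 in all members.
  m <- .set_bits(m, 13:19, "cell_cycle")
  m <- .set_bits(m, 13:19, "rtk_ras_map")
  m <- .set_bits(m, 13:19, "p53")
  m <- .set_bits(m, 13:14, "ddr")
  # Block 4 (NS20-31): weak profile; NS20-22 are the remaining high-TMB
  # patients, two of them DDR-mutated (8 of 11 NS/H in total).
  m <- .set_bits(m, 20:27, "rtk_ras_map")
  m <- .set_bits(m, 20:24, "p53")
  m <- .set_bits(m, 25:28, "pi3k")
  m <- .set_bits(m, 28:30, "myc")
  m <- .set_bits(m, 29:30, "notch")
  m <- .set_bits(m, 30:31, "oxidative_stress_nrf2")
  m <- .set_bits(m, 31, "hippo")
  m <- .set_bits(m, 31, "tgf_beta")
  m <- .set_bits(m, c(20:21, 23:26), "ddr")
  stopifnot(identical(unname(colSums(m)), .table2_ns_counts))
  m
}

.fixture_s_profiles <- function() {
  m <- matrix(0L, 111, 11, dimnames = list(sprintf("S%03d", 1:111),
                                           pathway_names()))
  # Greedy modular striding: pathway p's target count is spread over rows
  # offset by the cumulative target, which fixes the marginals exactly and
  # spreads co-occurrence near-uniformly (one valid completion among many).
  targets <- .table2_s_counts
  offsets <- cumsum(c(0, targets[-11]))
  for (p in seq_len(11)) {
    rows <- ((offsets[p] + seq_len(targets[p]) - 1L) %% 111L) + 1L
    m[rows, p] <- 1L
  }
  stopifnot(identical(unname(colSums(m)), .table2_s_counts))
  m
}

.fixture_ns_tmb <- function() {
  # NS01-08 and NS20-22 exceed the 10 Mut/Mb cutoff (11 high-TMB patients,
  # median 16.39); the 20 low-TMB values put the stratum median at 4 and the
  # stratum maximum at 39.09.
  tmb <- numeric(31)
  tmb[1:8] <- c(16.39, 17.2, 19.5, 22.8, 25.4, 39.09, 14.8, 13.5)
  tmb[20:22] <- c(10.6, 11.3, 12)
  tmb[9:19] <- c(0, 0.8, 1.2, 1.6, 2, 2.3, 2.7, 3, 3.2, 3.5, 3.7)
  tmb[23:31] <- c(3.9, 4, 4, 4, 4, 5.2, 6.5, 8.1, 10)
  tmb
}

.fixture_s_tmb <- function() {
  # 42 high-TMB smokers (cohort total 53 high-TMB), stratum median 8,
  # range 0-55.
  high <- round(seq(55, 10.5, length.out = 42), 2)
  low <- c(round(seq(0, 7.9, length.out = 55), 2), 8,
           round(seq(8.2, 10, length.out = 13), 2))
  c(high, low)
}

.fixture_response <- function() {
  ns <- character(31)
  ns[1:2] <- "CR"; ns[3:8] <- "PR"; ns[20:22] <- "PR"      # NS/H: 11/11 CR+PR
  ns[9:12] <- c("PR", "SD", "SD", "PD")
  ns[13:19] <- c("SD", "SD", "PD", "PD", "PD", "PR", "SD")
  ns[23:31] <- c(rep("PD", 5), "SD", "SD", "PR", "NE")
  s <- character(111)
  s[1:2] <- "CR"; s[3:18] <- "PR"; s[19:30] <- "SD"; s[31:42] <- "PD"
  s[43:56] <- "PR"; s[57:76] <- "SD"; s[77:107] <- "PD"; s[108:111] <- "NE"
  list(ns = ns, s = s)
}

.fixture_survival <- function() {
  # Deterministic times calibrated so the Kaplan-Meier medians land near the
  # reported values (overall OS 18.3, PFS 12.2, NS/H OS 27.95, follow-up
  # 17.05 months); calibration inputs, not verified outputs. Per group,
  # every third patient is censored near the follow-up horizon and event
  # times are an increasing grid whose median-rank value sits at the target.
  mk <- function(n, med, spread, cens_base, cens_step) {
    i <- seq_len(n)
    ev <- (i %% 3) != 0
    m <- sum(ev)
    k <- ceiling(n / 2)
    t_ev <- med + spread * (seq_len(m) - min(k, m)) / m
    t <- numeric(n)
    t[ev] <- pmax(t_ev, 0.5)
    t[!ev] <- cens_base + cens_step * seq_len(n - m)
    list(time = round(t, 2), event = ev)
  }
  idx_h <- c(1:8, 20:22)  # the NS/H patients among the 31 never-smokers
  idx_l <- setdiff(1:31, idx_h)
  fill <- function(h, l) {
    out <- list(time = numeric(31), event = logical(31))
    out$time[idx_h] <- h$time; out$event[idx_h] <- h$event
    out$time[idx_l] <- l$time; out$event[idx_l] <- l$event
    out
  }
  ns_os <- fill(mk(11, 27.95, 10, 30, 1), mk(20, 10, 8, 14.5, 0.3))
  ns_pfs <- fill(mk(11, 16, 8, 25, 1), mk(20, 6, 5, 14, 0.3))
  s_os <- mk(111, 19.2, 20, 15.5, 0.05)
  s_pfs <- mk(111, 12.4, 14, 16.6, 0.05)
  list(ns_os = ns_os, ns_pfs = ns_pfs, s_os = s_os, s_pfs = s_pfs)
}

#' Deterministic synthetic fixture cohort
#'
#' A seed-free, fully deterministic 142-patient cohort (111 smokers, 31
#' never-smokers) whose published marginals hold exactly: all 22 per-pathway
#' mutated-patient counts by smoking class, stratum TMB medians of 8 and 4
#' Mut/Mb, an 11-patient never-smoker high-TMB subgroup (median TMB 16.39)
#' with 8 of 11 DDR-mutated and a 100% objective response rate. The
#' never-smoker profiles are arranged in four blocks so the similarity
#' network exhibits the high-TMB DDR-rich community pattern; smoker profiles
#' are a greedy striped completion of the marginals. All other cell values
#' are synthetic and unconstrained.
#'
#' @param catalog Pathway catalog used to emit mutation records; default
#'   [default_catalog()].
#' @return A `cohort`.
#' @export
build_realworld_fixture <- function(catalog = default_catalog()) {
  prof <- rbind(.fixture_ns_profiles(), .fixture_s_profiles())
  resp <- .fixture_response()
  surv <- .fixture_survival()
  smoking_s <- rep(c("former", "current"), length.out = 111)
  patients <- data.frame(
    patient_id = rownames(prof),
    smoking_status = c(rep("never", 31), smoking_s),
    tmb = c(.fixture_ns_tmb(), .fixture_s_tmb()),
    pdl1_pct = rep(c(60, 75, 90, 100), length.out = 142),
    os_months = c(surv$ns_os$time, surv$s_os$time),
    os_event = c(surv$ns_os$event, surv$s_os$event),
    pfs_months = c(surv$ns_pfs$time, surv$s_pfs$time),
    pfs_event = c(surv$ns_pfs$event, surv$s_pfs$event),
    best_response = c(resp$ns, resp$s),
    stringsAsFactors = FALSE)
  mutations <- .mutations_from_profiles(prof, catalog, noise_rate = 0,
                                        random_gene = FALSE)
  cohort(patients, mutations, catalog)
}

#' Planted-partition cohort for community-detection calibration
#'
#' Each patient's 11-bit profile is its block's template with independent
#' bit flips at `noise_rate`; the block labels are returned for scoring
#' (e.g. adjusted Rand index) of detected communities.
#'
#' @param block_sizes Integer vector of block sizes.
#' @param templates Matrix (blocks x 11) of distinct binary templates;
#'   default the four maximally separated binary codewords in 11 bits
#'   (pairwise Hamming distance >= 7), recycled to `length(block_sizes)`.
#' @param noise_rate Per-bit flip probability, in `[0, 0.5)`.
#' @param seed Integer seed.
#' @param catalog Pathway catalog for emitted mutation records.
#' @return List: `cohort`, `profiles` (the sampled bits), `labels`.
#' @export
generate_planted_partition <- function(block_sizes = c(8, 4, 7, 12),
                                       templates = NULL,
                                       noise_rate = 0.05, seed = 1,
                                       catalog = default_catalog()) {
  if (noise_rate < 0 || noise_rate >= 0.5) {
    stop("noise_rate must lie in [0, 0.5)")
  }
  if (is.null(templates)) {
    templates <- rbind(c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
                       c(1, 1, 1, 1, 1, 1, 1, 0, 0, 0, 0),
                       c(0, 0, 0, 0, 1, 1, 1, 1, 1, 1, 1),
                       c(1, 1, 1, 1, 0, 0, 0, 1, 1, 1, 1))
  }
  stopifnot(ncol(templates) == 11, nrow(templates) >= length(block_sizes))
  templates <- templates[seq_along(block_sizes), , drop = FALSE]
  if (anyDuplicated(templates) > 0) stop("block templates must be distinct")
  labels <- rep(seq_along(block_sizes), block_sizes)
  n <- length(labels)
  .with_seed(seed, {
    prof <- templates[labels, , drop = FALSE]
    flip <- matrix(stats::runif(length(prof)) < noise_rate, nrow(prof))
    prof <- abs(prof - flip)
    mode(prof) <- "integer"
    dimnames(prof) <- list(sprintf("PP%03d", seq_len(n)), pathway_names())
    patients <- data.frame(
      patient_id = rownames(prof), smoking_status = "never",
      tmb = 5, pdl1_pct = NA_real_,
      os_months = 5 + (seq_len(n) %% 20), os_event = TRUE,
      pfs_months = 2 + (seq_len(n) %% 10), pfs_event = TRUE,
      best_response = "NE", stringsAsFactors = FALSE)
    mutations <- .mutations_from_profiles(prof, catalog, noise_rate = 0,
                                          random_gene = FALSE)
    list(cohort = cohort(patients, mutations, catalog),
         profiles = prof, labels = labels)
  })
}

#' Externally reported calibration constants
#'
#' Statistics reported for the discovery and validation cohorts that require
#' undeposited patient-level data and therefore cannot be recomputed here.
#' They enter this package only as calibration inputs for the synthetic
#' generator (survival medians, planted-subgroup rates) or as context, never
#' as verified outputs: `verifiable_here` is `FALSE` for every row.
#'
#' @return Data frame: `quantity`, `value`, `role`, `verifiable_here`.
#' @export
calibration_targets <- function() {
  data.frame(
    quantity = c("discovery_median_os_months", "discovery_median_pfs_months",
                 "discovery_median_followup_months", "ns_htmb_median_os_months",
                 "validation_ns_htmb_ddr_fraction",
                 "validation_ddr_enrichment_p",
                 "validation_profile_correlation_rho",
                 "validation_profile_correlation_p",
                 "ns_community_tmb_kw_p", "ns_c1c2_vs_c3_logrank_p",
                 "s_community_tmb_kw_p"),
    value = c(18.3, 12.2, 17.05, 27.95, 17 / 18, 0.0297, 0.727, 0.0178,
              0.0025, 0.022, 0.0422),
    role = c("generator_calibration", "generator_calibration",
             "generator_calibration", "generator_calibration",
             "generator_calibration", "external_context", "external_context",
             "external_context", "external_context", "external_context",
             "external_context"),
    verifiable_here = FALSE,
    stringsAsFactors = FALSE)
}
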
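# End-to-end orchestration: profiling -> stratification -> summary table ->
# the four enrichment families -> per-smoking-stratum similarity network +
# Louvain -> community characterization (profiles, TMB comparison, high-TMB
# enrichment, OS/PFS log-rank, response rates).

#' Run configuration
#'
#' @param tmb_cutoff TMB cutoff (Mut/Mb) for the H/L classes; default 10.
#' @param k_neighbors,mu Kernel parameters (see
#'   [scaled_exponential_kernel()]); `k_neighbors = NULL` means
#'   `min(n - 1, 20)` per stratum.
#' @param resolution,louvain_seed,n_restarts Louvain settings.
#' @param alpha Significance level for enrichment flags.
#' @param deleterious_rule Pathogenicity rule (`"or"`/`"and"`).
#' @param min_stratum_size Strata smaller than this skip network analysis
#'   (with a warning); default 3.
#' @return A `run_config` list.
#' @export
run_config <- function(tmb_cutoff = 10, k_neighbors = NULL, mu = 0.5,
                       resolution = 1, louvain_seed = 1, n_restarts = 100,
                       alpha = 0.05, deleterious_rule = "or",
                       min_stratum_size = 3) {
  stopifnot(alpha > 0, alpha < 1, tmb_cutoff > 0)
  structure(list(tmb_cutoff = tmb_cutoff, k_neighbors = k_neighbors, mu = mu,
                 resolution = resolution, louvain_seed = louvain_seed,
                 n_restarts = n_restarts, alpha = alpha,
                 deleterious_rule = deleterious_rule,
                 min_stratum_size = min_stratum_size),
            class = "run_config")
}

.characterize_stratum <- function(ids, profiles, patients, strata, cfg) {
  if (length(ids) < cfg$min_stratum_size) {
    warning("stratum with ", length(ids),
            " patients: similarity network skipped")
    return(NULL)
  }
  prof <- profiles[ids, , drop = FALSE]
  k <- if (is.null(cfg$k_neighbors)) min(length(ids) - 1L, 20L) else cfg$k_neighbors
  net <- build_similarity_network(prof, k_neighbors = k, mu = cfg$mu)
  part <- detect_communities(net, resolution = cfg$resolution,
                             seed = cfg$louvain_seed,
                             n_restarts = cfg$n_restarts)
  cp <- community_profiles(part, prof)
  idx <- match(ids, patients$patient_id)
  pts <- patients[idx, ]
  labs <- sort(unique(part$assignment))
  htmb <- lapply(labs, function(l) htmb_enrichment(part, strata, l))
  comm_of <- part$assignment[pts$patient_id]
  per_comm <- lapply(labs, function(l) {
    members <- pts[comm_of == l, ]
    rr <- response_rates(members$best_response)
    list(community = l, size = nrow(members),
         median_tmb = stats::median(members$tmb),
         n_htmb = sum(members$tmb > cfg$tmb_cutoff),
         orr_pct = rr$orr_pct, dcr_pct = rr$dcr_pct,
         median_os = km_estimate(members$os_months, members$os_event)$median)
  })
  multi <- part$n_communities >= 2
  list(patient_ids = ids, network = net, partition = part,
       structure = has_community_structure(part),
       community_profiles = cp,
       tmb_comparison = if (multi) compare_tmb(part, pts) else NULL,
       htmb_enrichment = htmb,
       os_logrank = if (multi) logrank_test(pts$os_months, pts$os_event,
                                            comm_of) else NULL,
       pfs_logrank = if (multi) logrank_test(pts$pfs_months, pts$pfs_event,
                                             comm_of) else NULL,
       community_summary = per_comm)
}

#' Run the full analysis pipeline
#'
#' Profiling, stratification, the published-table-style pathway summary,
#' four enrichment families (high-TMB, never-smokers, smoker/high-TMB and
#' never-smoker/high-TMB subgroups, each against the whole cohort), then a
#' per-smoking-stratum similarity network with Louvain communities and their
#' characterization. Deterministic given `cfg`.
#'
#' @param x A `cohort`.
#' @param cfg A `run_config`.
#' @return An `analysis_report` list.
#' @export
run_full_analysis <- function(x, cfg = run_config()) {
  stopifnot(inherits(x, "cohort"), inherits(cfg, "run_config"))
  profiles <- build_pathway_profiles(x, rule = cfg$deleterious_rule)
  strata <- stratify(x$patients, tmb_cutoff = cfg$tmb_cutoff)
  summary_tab <- pathway_summary(profiles, strata)
  ids_of <- function(sel) strata$patient_id[sel]
  subgroups <- list(
    htmb = ids_of(strata$tmb_class == "H"),
    never_smokers = ids_of(strata$smoking_class == "NS"),
    s_htmb = ids_of(strata$subgroup == "S/H"),
    ns_htmb = ids_of(strata$subgroup == "NS/H"))
  enrichment <- lapply(subgroups, function(ids) {
    if (length(ids) == 0) NULL else
      enrich_pathways(profiles, ids, alpha = cfg$alpha)
  })
  networks <- list(
    S = .characterize_stratum(ids_of(strata$smoking_class == "S"),
                              profiles, x$patients, strata, cfg),
    NS = .characterize_stratum(ids_of(strata$smoking_class == "NS"),
                               profiles, x$patients, strata, cfg))
  outcomes <- list(
    median_followup = median_followup(x$patients$os_months,
                                      x$patients$os_event),
    os_median = km_estimate(x$patients$os_months, x$patients$os_event)$median,
    pfs_median = km_estimate(x$patients$pfs_months,
                             x$patients$pfs_event)$median,
    response = response_rates(x$patients$best_response),
    by_subgroup = lapply(subgroups, function(ids) {
      if (length(ids) == 0) return(NULL)
      pts <- x$patients[match(ids, x$patients$patient_id), ]
      rr <- response_rates(pts$best_response)
      list(n = length(ids),
           os_median = km_estimate(pts$os_months, pts$os_event)$median,
           orr_pct = rr$orr_pct, dcr_pct = rr$dcr_pct)
    }))
  structure(list(config = cfg, profiles = profiles, strata = strata,
                 pathway_summary = summary_tab, enrichment = enrichment,
                 networks = networks, outcomes = outcomes),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Analysis report:", nrow(x$profiles), "patients\n")
  cat("  subgroup sizes:", paste(names(table(x$strata$subgroup)),
                                 table(x$strata$subgroup), collapse = ", "),
      "\n")
  for (nm in names(x$enrichment)) {
    e <- x$enrichment[[nm]]
    if (is.null(e)) next
    sig <- e$pathway[e$significant]
    cat("  enrichment [", nm, "]: ",
        if (length(sig)) paste(sig, collapse = ", ") else "none",
        " significant\n", sep = "")
  }
  for (nm in names(x$networks)) {
    nw <- x$networks[[nm]]
    if (is.null(nw)) next
    cat("  network [", nm, "]: ", nw$partition$n_communities,
        " communities, Q = ", format(nw$partition$modularity, digits = 3),
        "\n", sep = "")
  }
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Emits the pathway summary and enrichment tables as TSV and a JSON
#' overview (strata, community structure, outcomes) under `dir`.
#'
#' @param report An `analysis_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report$pathway_summary,
                     file.path(dir, "pathway_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(report$enrichment)) {
    e <- report$enrichment[[nm]]
    if (is.null(e)) next
    utils::write.table(e, file.path(dir, paste0("enrichment_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  overview <- list(
    n_patients = nrow(report$profiles),
    subgroup_sizes = as.list(table(report$strata$subgroup)),
    networks = lapply(report$networks, function(nw) {
      if (is.null(nw)) return(NULL)
      list(n_communities = nw$partition$n_communities,
           modularity = nw$partition$modularity,
           has_structure = nw$structure$has_structure,
           community_summary = nw$community_summary)
    }),
    outcomes = report$outcomes[c("median_followup", "os_median",
                                 "pfs_median")])
  jsonlite::write_json(overview, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  for (nm in names(report$networks)) {
    nw <- report$networks[[nm]]
    if (is.null(nw)) next
    part_df <- data.frame(patient_id = names(nw$partition$assignment),
                          community = unname(nw$partition$assignment))
    utils::write.table(part_df,
                       file.path(dir, paste0("partition_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
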
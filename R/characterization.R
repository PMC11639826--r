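# Community characterization: mutated-pathway frequency profiles, TMB
# comparison across communities, high-TMB enrichment of a community, and
# Spearman correlation between community profiles.

#' Per-community mutated-pathway percentage profiles
#'
#' For each community, the percentage of members carrying at least one
#' deleterious mutation in each pathway.
#'
#' @param partition A `community_partition`.
#' @param profiles Profile matrix covering exactly the partitioned patients.
#' @return Data frame: `community`, `size`, then one percentage column per
#'   pathway in canonical order.
#' @export
community_profiles <- function(partition, profiles) {
  stopifnot(inherits(partition, "community_partition"))
  ids <- names(partition$assignment)
  if (!setequal(ids, rownames(profiles))) {
    stop("partition and profiles must cover identical patients")
  }
  labs <- sort(unique(partition$assignment))
  rows <- lapply(labs, function(l) {
    members <- ids[partition$assignment == l]
    sub <- profiles[members, , drop = FALSE]
    pct <- 100 * colSums(sub) / nrow(sub)
    cbind(data.frame(community = l, size = nrow(sub)), as.data.frame(t(pct)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Kruskal-Wallis comparison of TMB across communities
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square p-value on (g - 1)
#' degrees of freedom. With all TMB values identical the tie-corrected H is
#' undefined; by convention H = 0, p = 1 and `degenerate` is set.
#'
#' @param partition A `community_partition`.
#' @param patients Patient data frame with `tmb`.
#' @return List: `statistic`, `p_value`, `df`, `group_sizes`, `degenerate`.
#' @export
compare_tmb <- function(partition, patients) {
  stopifnot(inherits(partition, "community_partition"))
  ids <- names(partition$assignment)
  idx <- match(ids, patients$patient_id)
  if (anyNA(idx)) stop("partition contains patients absent from clinical table")
  tmb <- patients$tmb[idx]
  grp <- factor(partition$assignment)
  if (nlevels(grp) < 2) stop("need at least 2 communities")
  sizes <- as.integer(table(grp))
  if (any(sizes == 0)) stop("empty community group")
  if (length(unique(tmb)) == 1) {
    return(list(statistic = 0, p_value = 1, df = nlevels(grp) - 1L,
                group_sizes = sizes, degenerate = TRUE))
  }
  kt <- stats::kruskal.test(tmb, grp)
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter), group_sizes = sizes, degenerate = FALSE)
}

#' High-TMB enrichment of one community
#'
#' Upper-tail hypergeometric test of whether a community contains more
#' high-TMB patients than expected: N = number of partitioned patients
#' (the stratum cohort the network was built on), K = high-TMB patients
#' among them, n = community size, k = high-TMB members of the community.
#'
#' @param partition A `community_partition`.
#' @param strata Stratification data frame from [stratify()] covering the
#'   partitioned patients.
#' @param community Community label (0-based).
#' @return List: `community`, `N`, `K`, `n`, `k`, `p_value`.
#' @export
htmb_enrichment <- function(partition, strata, community) {
  stopifnot(inherits(partition, "community_partition"))
  ids <- names(partition$assignment)
  if (!(community %in% partition$assignment)) {
    stop("no such community: ", community)
  }
  idx <- match(ids, strata$patient_id)
  if (anyNA(idx)) stop("partition contains patients absent from strata")
  high <- strata$tmb_class[idx] == "H"
  members <- partition$assignment == community
  N <- length(ids); K <- sum(high); n <- sum(members)
  k <- sum(high & members)
  list(community = community, N = N, K = K, n = n, k = k,
       p_value = hypergeom_upper_tail(N, K, n, k))
}

#' Spearman correlation between two community profiles
#'
#' Spearman rho with average-rank tie handling. The p-value against the
#' permutation null is estimated by Monte Carlo (default 1e6 permutations
#' with a fixed seed), accurate to about three decimals at the default; a
#' closed-form null is not available at profile length 11 once ties occur.
#' Two-sided.
#'
#' @param a,b Numeric vectors of equal length (community percentage
#'   profiles, length 11 in the pipeline).
#' @param n_perm Number of Monte Carlo permutations; default 1e6.
#' @param seed Seed for the permutation draw; default 1.
#' @return List: `rho`, `p_value`, `n_perm`, `seed`.
#' @export
profile_correlation <- function(a, b, n_perm = 1e6, seed = 1) {
  if (length(a) != length(b)) stop("profiles must have equal length")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("zero-variance profile: Spearman correlation undefined")
  }
  ra <- rank(a); rb <- rank(b)
  rho <- stats::cor(ra, rb)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  m <- length(a)
  ra_c <- ra - mean(ra)
  denom <- sqrt(sum(ra_c^2) * sum((rb - mean(rb))^2))
  # permute b's ranks; rho is Pearson on ranks, computed as a dot product
  perm <- matrix(rb[vapply(seq_len(n_perm), function(i) sample.int(m),
                           integer(m))], nrow = m)
  rho_perm <- as.numeric(crossprod(ra_c, perm - mean(rb))) / denom
  p <- (1 + sum(abs(rho_perm) >= abs(rho) - 1e-12)) / (n_perm + 1)
  list(rho = rho, p_value = p, n_perm = n_perm, seed = seed)
}
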
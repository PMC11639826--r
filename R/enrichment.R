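# Subgroup enrichment of mutated pathways: one-sided (over-representation)
# hypergeometric test with Benjamini-Hochberg FDR control across the eleven
# pathways of one comparison family.

#' Upper-tail hypergeometric probability
#'
#' P(X >= k) where X counts mutated patients in a subgroup of size `n` drawn
#' without replacement from a background of `N` patients of which `K` are
#' mutated: `sum_{j=k}^{min(n,K)} C(K,j) C(N-K,n-j) / C(N,n)`. Computed by
#' direct log-gamma summation, exact to double precision for N up to 1e4.
#' Vectorized over `k`.
#'
#' @param N Background size.
#' @param K Mutated count in the background.
#' @param n Subgroup size.
#' @param k Observed mutated count(s) in the subgroup.
#' @return Probability (vector the length of `k`).
#' @export
hypergeom_upper_tail <- function(N, K, n, k) {
  if (length(N) != 1 || length(K) != 1 || length(n) != 1) {
    stop("N, K, n must be scalars")
  }
  ok <- N >= 0 && K >= 0 && K <= N && n >= 0 && n <= N &&
    all(k >= 0) && all(k <= min(n, K))
  if (!ok) {
    stop("domain error: require 0 <= K <= N, 0 <= n <= N, 0 <= k <= min(n, K)")
  }
  hi <- min(n, K)
  lo_support <- max(0, n - (N - K))
  j <- lo_support:hi
  log_pmf <- lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)
  pmf <- exp(log_pmf)
  # reverse cumulative sum: tail[i] = P(X >= j[i])
  tail_p <- rev(cumsum(rev(pmf)))
  vapply(k, function(ki) {
    if (ki <= lo_support) 1 else min(1, tail_p[ki - lo_support + 1])
  }, numeric(1))
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment: `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1
#' and mapped back to input order.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("domain error: p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Pathway enrichment of a subgroup against a background
#'
#' For each of the eleven pathways, tests over-representation of mutated
#' patients in the subgroup relative to the background with
#' [hypergeom_upper_tail()], then adjusts across the eleven tests of this one
#' comparison family with [bh_adjust()]. The subgroup must be contained in
#' the background. The background defaults to the whole profile matrix (all
#' patients): subgroup frequencies are compared against the full cohort, the
#' configuration under which both DDR and beta-catenin/Wnt reach FDR < 0.05
#' for the never-smoker/high-TMB subgroup at the published mutation counts.
#'
#' @param profiles Profile matrix from [build_pathway_profiles()].
#' @param subgroup Character vector of patient ids.
#' @param background Character vector of patient ids; default all patients in
#'   `profiles`.
#' @param alpha Significance level for the `significant` column.
#' @return Data frame: `pathway`, `N`, `K`, `n`, `k`, `p_value`, `q_value`,
#'   `significant`.
#' @export
enrich_pathways <- function(profiles, subgroup,
                            background = rownames(profiles), alpha = 0.05) {
  if (length(subgroup) == 0 || length(background) == 0) {
    stop("configuration error: subgroup and background must be non-empty")
  }
  if (!all(subgroup %in% background)) {
    stop("configuration error: subgroup must be contained in background")
  }
  if (!all(background %in% rownames(profiles))) {
    stop("configuration error: background patients absent from profiles")
  }
  bg <- profiles[background, , drop = FALSE]
  sg <- profiles[subgroup, , drop = FALSE]
  N <- nrow(bg); n <- nrow(sg)
  K <- colSums(bg); k <- colSums(sg)
  p <- vapply(seq_len(ncol(bg)), function(i) {
    hypergeom_upper_tail(N, K[i], n, k[i])
  }, numeric(1))
  q <- bh_adjust(p)
  data.frame(pathway = colnames(bg),
             N = N, K = as.integer(K), n = n, k = as.integer(k),
             p_value = p, q_value = q, significant = q < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}
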
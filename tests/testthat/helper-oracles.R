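# Independent oracles used to cross-check the implementation. These stay
# deliberately naive: direct enumeration and literal textbook formulas,
# sharing no code with the package.

# Upper-tail hypergeometric probability by direct binomial-coefficient
# enumeration of the pmf.
hyper_brute <- function(N, K, n, k) {
  js <- max(0, n - (N - K)):min(n, K)
  js <- js[js >= k]
  if (length(js) == 0) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Literal Benjamini-Hochberg step-up: q_(i) = min_{j >= i} p_(j) * m / j.
bh_step_up <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(p[ord][i:m] * m / (i:m)))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Weighted modularity from the adjacency matrix and a membership vector:
# Q = (1/2m) sum_ij (A_ij - k_i k_j / 2m) delta(c_i, c_j), diagonal excluded.
modularity_hand <- function(W, membership) {
  diag(W) <- 0
  two_m <- sum(W)
  deg <- rowSums(W)
  same <- outer(membership, membership, "==")
  sum((W - outer(deg, deg) / two_m) * same) / two_m
}

# Kaplan-Meier by the product-limit formula, events first at tied times.
km_hand <- function(time, event) {
  ts <- sort(unique(time[event]))
  s <- 1
  surv <- numeric(length(ts))
  for (i in seq_along(ts)) {
    at_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  list(time = ts, surv = surv)
}

# A small valid cohort shared across tests: 4 patients, mixed flags.
toy_cohort <- function() {
  patients <- data.frame(
    patient_id = c("P1", "P2", "P3", "P4"),
    smoking_status = c("never", "former", "current", "never"),
    tmb = c(15, 8, 12, 3),
    pdl1_pct = c(80, 60, NA, 90),
    os_months = c(20, 10, 15, 5),
    os_event = c(FALSE, TRUE, TRUE, TRUE),
    pfs_months = c(12, 6, 9, 2),
    pfs_event = c(TRUE, TRUE, TRUE, TRUE),
    best_response = c("PR", "SD", "PD", "PD"),
    stringsAsFactors = FALSE)
  mutations <- data.frame(
    patient_id = c("P1", "P1", "P2", "P3", "P4"),
    gene = c("TP53", "BRCA2", "KRAS", "EGFR", "KEAP1"),
    variant_label = paste0("v", 1:5),
    cosmic_pathogenic = c(TRUE, FALSE, TRUE, TRUE, FALSE),
    clinvar_pathogenic = c(TRUE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  cohort(patients, mutations, default_catalog())
}
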
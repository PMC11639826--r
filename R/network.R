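# Patient similarity network construction and community detection.
# Distances are Euclidean on the binary 11-pathway profiles; edge weights come
# from a locally scaled exponential similarity kernel; communities from
# Louvain modularity maximization on the full weighted graph.

#' Pairwise Euclidean distances between pathway profiles
#'
#' For binary vectors this equals the square root of the Hamming distance;
#' the maximum possible distance is `sqrt(11)`.
#'
#' @param profiles Profile matrix (patients x 11).
#' @return Symmetric distance matrix with zero diagonal.
#' @export
pairwise_distance <- function(profiles) {
  if (nrow(profiles) < 2) stop("need at least 2 profiles")
  if (ncol(profiles) != 11) {
    stop("dimension error: profiles must have 11 pathway columns")
  }
  D <- as.matrix(stats::dist(profiles, method = "euclidean"))
  dimnames(D) <- list(rownames(profiles), rownames(profiles))
  D
}

#' Scaled exponential similarity kernel
#'
#' Converts distances to affinities with a locally adaptive bandwidth:
#' \deqn{W_{ij} = \exp\left(-\frac{D_{ij}^2}{\mu\,\varepsilon_{ij}}\right),
#'   \quad \varepsilon_{ij} = \frac{\bar d_i + \bar d_j + D_{ij}}{3}}
#' where \eqn{\bar d_i} is the mean distance from i to its `k_neighbors`
#' nearest neighbors (excluding itself). When \eqn{\varepsilon_{ij} = 0}
#' (all-identical local neighborhoods, so necessarily \eqn{D_{ij} = 0}) the
#' weight is 1 by continuity. The diagonal is set to 0 by convention before
#' graph construction.
#'
#' @param D Symmetric distance matrix.
#' @param k_neighbors Local scaling neighborhood size; default
#'   `min(nrow(D) - 1, 20)`.
#' @param mu Positive scaling factor; default 0.5.
#' @return Symmetric weight matrix, off-diagonal entries in (0, 1], zero
#'   diagonal.
#' @export
scaled_exponential_kernel <- function(D, k_neighbors = min(nrow(D) - 1L, 20L),
                                      mu = 0.5) {
  n <- nrow(D)
  if (n < 2) stop("need at least 2 patients")
  if (k_neighbors < 1 || k_neighbors >= n) {
    stop("parameter error: require 1 <= k_neighbors <= n - 1")
  }
  if (mu <= 0) stop("parameter error: mu must be positive")
  dbar <- vapply(seq_len(n), function(i) {
    mean(sort(D[i, -i])[seq_len(k_neighbors)])
  }, numeric(1))
  eps <- (outer(dbar, dbar, "+") + D) / 3
  W <- exp(-D^2 / (mu * eps))
  W[eps == 0] <- 1
  diag(W) <- 0
  dimnames(W) <- dimnames(D)
  W
}

#' Build a patient similarity network
#'
#' Convenience wrapper: [pairwise_distance()] then
#' [scaled_exponential_kernel()].
#'
#' @param profiles Profile matrix (patients x 11).
#' @inheritParams scaled_exponential_kernel
#' @return A `similarity_network`: list with `patient_ids`, `D`, `W`,
#'   `k_neighbors`, `mu`.
#' @export
build_similarity_network <- function(profiles,
                                     k_neighbors = min(nrow(profiles) - 1L, 20L),
                                     mu = 0.5) {
  D <- pairwise_distance(profiles)
  W <- scaled_exponential_kernel(D, k_neighbors = k_neighbors, mu = mu)
  structure(list(patient_ids = rownames(profiles), D = D, W = W,
                 k_neighbors = k_neighbors, mu = mu),
            class = "similarity_network")
}

#' @export
print.similarity_network <- function(x, ...) {
  cat("Patient similarity network:", length(x$patient_ids), "patients, k =",
      x$k_neighbors, ", mu =", x$mu, "\n")
  invisible(x)
}

# Relabel community memberships canonically: 0-based, ordered by descending
# community size with ties broken by the smallest member index.
.canonical_labels <- function(membership) {
  sizes <- table(membership)
  first_idx <- vapply(names(sizes), function(l) min(which(membership == l)),
                      numeric(1))
  ord <- names(sizes)[order(-as.integer(sizes), first_idx)]
  out <- match(as.character(membership), ord) - 1L
  names(out) <- names(membership)
  out
}

#' Louvain community detection with restarts
#'
#' Runs Louvain modularity maximization on the full weighted graph
#' `n_restarts` times with seeds `seed, ..., seed + n_restarts - 1` and keeps
#' the partition with the highest (classic, resolution-1) modularity Q, ties
#' resolved in favor of the lowest seed. Labels are canonical: 0-based,
#' size-descending, ties by smallest member index. Deterministic given
#' `(W, resolution, seed, n_restarts)`.
#'
#' @param W Symmetric non-negative weight matrix with zero diagonal, or a
#'   `similarity_network`.
#' @param resolution Louvain resolution parameter gamma; default 1.
#' @param seed Base random seed.
#' @param n_restarts Number of restarts; default 100.
#' @return A `community_partition`: list with `assignment` (named 0-based
#'   labels), `modularity`, `n_communities`, `resolution`, `seed`,
#'   `n_restarts`, `best_seed`.
#' @export
detect_communities <- function(W, resolution = 1, seed = 1, n_restarts = 100) {
  if (inherits(W, "similarity_network")) W <- W$W
  n <- nrow(W)
  if (is.null(n) || n == 0) stop("empty graph")
  ids <- rownames(W)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (n == 1) {
    assignment <- stats::setNames(0L, ids)
    return(structure(list(assignment = assignment, modularity = 0,
                          n_communities = 1L, resolution = resolution,
                          seed = seed, n_restarts = n_restarts,
                          best_seed = seed),
                     class = "community_partition"))
  }
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  best_q <- -Inf; best_mem <- NULL; best_seed <- NA_integer_
  for (s in seq.int(seed, seed + n_restarts - 1L)) {
    set.seed(s)
    cl <- igraph::cluster_louvain(g, resolution = resolution)
    mem <- igraph::membership(cl)
    q <- igraph::modularity(g, mem, weights = igraph::E(g)$weight)
    if (q > best_q) { best_q <- q; best_mem <- mem; best_seed <- s }
  }
  assignment <- .canonical_labels(stats::setNames(as.integer(best_mem), ids))
  structure(list(assignment = assignment, modularity = best_q,
                 n_communities = length(unique(assignment)),
                 resolution = resolution, seed = seed,
                 n_restarts = n_restarts, best_seed = best_seed),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat("Community partition:", x$n_communities, "communities, Q =",
      format(x$modularity, digits = 4), "\n")
  print(table(community = x$assignment))
  invisible(x)
}

#' Does a partition exhibit community structure?
#'
#' Structure is declared absent when the partition is a single community or
#' its modularity falls below `q_min` (default 0.05): a near-uniform graph
#' has Q near 0 whatever labels Louvain returns.
#'
#' @param partition A `community_partition`.
#' @param q_min Minimum modularity to call structure; default 0.05.
#' @return List: `has_structure` (logical), `modularity`, `n_communities`.
#' @export
has_community_structure <- function(partition, q_min = 0.05) {
  stopifnot(inherits(partition, "community_partition"))
  list(has_structure = !(partition$n_communities == 1L ||
                           partition$modularity < q_min),
       modularity = partition$modularity,
       n_communities = partition$n_communities)
}
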
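# Shared helpers and independent oracles for the test suite.  Oracles are
# deliberately naive (double loops, exhaustive search) so they stay
# independent of the implementation paths they check.

# Random point-cloud structure with default metadata.
random_structure <- function(n, seed, scale = 10) {
  molcloud:::with_seed(seed, mc_structure(matrix(rnorm(3 * n, sd = scale), n, 3)))
}

# Random proper rotation (normalised Gaussian quaternion).
random_rotation1 <- function(seed) {
  molcloud:::with_seed(seed, {
    q <- rnorm(4)
    molcloud:::quat_to_matrix(q / sqrt(sum(q^2)))
  })
}

# Brute-force double-loop distance matrix.
oracle_distance_matrix <- function(P, Q) {
  out <- matrix(NA_real_, nrow(P), nrow(Q))
  for (i in seq_len(nrow(P)))
    for (j in seq_len(nrow(Q)))
      out[i, j] <- sqrt(sum((P[i, ] - Q[j, ])^2))
  out
}

# Exhaustive Dijkstra over an accessibility lattice, built independently of
# the package's graph: nodes are the accessible voxels, edges connect pairs
# closer than sqrt(3) * spacing + tol, weights Euclidean.  O(V^2); only for
# small lattices.
oracle_shortest_path_length <- function(lattice, rank_from, rank_to) {
  pos <- molcloud:::lattice_node_position(lattice, lattice$node_lin)
  nv <- nrow(pos)
  cutoff <- lattice$spacing * sqrt(3) + 1e-9
  dist <- rep(Inf, nv)
  done <- rep(FALSE, nv)
  dist[rank_from] <- 0
  for (iter in seq_len(nv)) {
    u <- which.min(ifelse(done, Inf, dist))
    if (!is.finite(dist[u])) break
    if (u == rank_to) break
    done[u] <- TRUE
    d <- sqrt(colSums((t(pos) - pos[u, ])^2))
    nb <- which(d <= cutoff & d > 0 & !done)
    relax <- dist[u] + d[nb]
    better <- relax < dist[nb]
    dist[nb[better]] <- relax[better]
  }
  dist[rank_to]
}

# A small chiral 4-point cloud (no mirror symmetry).
chiral_points <- function() {
  rbind(c(0, 0, 0), c(3, 0, 0), c(0, 2, 0), c(1, 1, 4))
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))
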
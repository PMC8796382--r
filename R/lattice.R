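# Solvent-accessible lattice graph and shortest accessible paths.  A cubic
# lattice is laid over the structure's padded bounding box; a node is
# accessible iff its distance to every atom centre is at least
# vdw_radius + probe.  Accessible nodes are connected to their accessible
# 26-neighbours with Euclidean edge weights, and shortest paths (Dijkstra,
# via igraph) give a lower bound on the length a cross-linker must span.

lattice_node_position <- function(g, lin) {
  nx <- g$dims[1]; ny <- g$dims[2]
  i <- (lin - 1) %% nx + 1
  j <- ((lin - 1) %/% nx) %% ny + 1
  k <- (lin - 1) %/% (nx * ny) + 1
  cbind(g$origin[1] + (i - 1) * g$spacing,
        g$origin[2] + (j - 1) * g$spacing,
        g$origin[3] + (k - 1) * g$spacing)
}

#' Build a solvent-accessibility lattice around a structure
#'
#' Cubic lattice over the bounding box of the current conformation expanded
#' by `margin`; node accessible iff for every atom
#' `distance - vdw_radius >= probe`.  Accessible nodes are linked to their
#' accessible 26-neighbours; edge weights are the Euclidean inter-node
#' distances.
#'
#' @param s a non-empty `mc_structure`.
#' @param spacing lattice spacing, Angstrom; default 1.0.
#' @param probe probe radius, Angstrom; default 1.4 (water).
#' @param margin bounding-box padding, Angstrom; default 10.
#' @return object of class `mc_lattice` with the accessibility grid and the
#'   igraph adjacency among accessible nodes.
#' @export
build_lattice <- function(s, spacing = 1.0, probe = 1.4, margin = 10) {
  if (n_points(s) == 0)
    mc_error("mc_empty_error", "cannot build a lattice around an empty structure")
  if (spacing <= 0 || margin < 0)
    mc_error("mc_value_error", "spacing must be > 0 and margin >= 0")
  message(sprintf("build_lattice: spacing %.2f A, probe %.2f A, margin %.1f A",
                  spacing, probe, margin))
  xyz <- get_coordinates(s)
  radii <- s$metadata$vdw_radius + probe
  lo <- apply(xyz, 2, min) - margin
  hi <- apply(xyz, 2, max) + margin
  dims <- as.integer(ceiling((hi - lo) / spacing)) + 1L
  axes <- lapply(1:3, function(a) lo[a] + (seq_len(dims[a]) - 1) * spacing)
  accessible <- array(TRUE, dim = dims)
  for (p in seq_len(nrow(xyz))) {
    r <- radii[p]
    rng <- lapply(1:3, function(a) which(abs(axes[[a]] - xyz[p, a]) < r))
    if (any(vapply(rng, length, integer(1)) == 0)) next
    d2 <- outer(outer((axes[[1]][rng[[1]]] - xyz[p, 1])^2,
                      (axes[[2]][rng[[2]]] - xyz[p, 2])^2, "+"),
                (axes[[3]][rng[[3]]] - xyz[p, 3])^2, "+")
    blocked <- d2 < r^2
    accessible[rng[[1]], rng[[2]], rng[[3]]] <-
      accessible[rng[[1]], rng[[2]], rng[[3]], drop = FALSE] & !blocked
  }
  node_lin <- which(accessible)
  rank <- integer(prod(dims))
  rank[node_lin] <- seq_along(node_lin)

  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offsets <- offsets[offsets %*% c(1, 3, 9) > 0, , drop = FALSE]  # half-space
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  edge_from <- integer(0); edge_to <- integer(0); edge_w <- numeric(0)
  for (o in seq_len(nrow(offsets))) {
    a <- offsets[o, 1]; b <- offsets[o, 2]; cc <- offsets[o, 3]
    i1 <- seq(max(1, 1 - a), min(nx, nx - a))
    j1 <- seq(max(1, 1 - b), min(ny, ny - b))
    k1 <- seq(max(1, 1 - cc), min(nz, nz - cc))
    if (!length(i1) || !length(j1) || !length(k1)) next
    both <- accessible[i1, j1, k1, drop = FALSE] &
      accessible[i1 + a, j1 + b, k1 + cc, drop = FALSE]
    hit <- which(both, arr.ind = TRUE)
    if (nrow(hit) == 0) next
    ii <- i1[hit[, 1]]; jj <- j1[hit[, 2]]; kk <- k1[hit[, 3]]
    lin1 <- ii + (jj - 1) * nx + (kk - 1) * nx * ny
    lin2 <- (ii + a) + (jj + b - 1) * nx + (kk + cc - 1) * nx * ny
    edge_from <- c(edge_from, rank[lin1])
    edge_to <- c(edge_to, rank[lin2])
    edge_w <- c(edge_w, rep(spacing * sqrt(a^2 + b^2 + cc^2), nrow(hit)))
  }
  graph <- igraph::make_empty_graph(n = length(node_lin), directed = FALSE)
  if (length(edge_from) > 0) {
    graph <- igraph::add_edges(graph, rbind(edge_from, edge_to))
    igraph::E(graph)$weight <- edge_w
  }
  structure(list(spacing = spacing, probe = probe, origin = lo, dims = dims,
                 accessible = accessible, node_lin = node_lin,
                 graph = graph),
            class = "mc_lattice")
}

#' @export
print.mc_lattice <- function(x, ...) {
  cat(sprintf(
    "<mc_lattice> %d x %d x %d grid (%.2g A spacing), %d/%d nodes accessible\n",
    x$dims[1], x$dims[2], x$dims[3], x$spacing,
    length(x$node_lin), prod(x$dims)))
  invisible(x)
}

# Nearest accessible node to a 3D position within `cutoff`; ties broken by
# the smaller lattice (linear) node index.  Returns the rank in the graph.
snap_to_lattice <- function(g, pos, cutoff) {
  node_pos <- lattice_node_position(g, g$node_lin)
  d <- sqrt(colSums((t(node_pos) - pos)^2))
  ok <- which(d <= cutoff)
  if (length(ok) == 0) return(NA_integer_)
  best <- ok[order(d[ok], g$node_lin[ok])][1]
  best
}

#' Shortest solvent-accessible path between two atoms
#'
#' Each endpoint atom is snapped to its nearest accessible lattice node
#' within `snap_cutoff` (ties by node index); the minimal total Euclidean
#' length path over the accessible 26-neighbour adjacency is then found by
#' Dijkstra's algorithm.  A buried endpoint or endpoints in disconnected
#' accessible components signal errors (the latter marks an infeasible
#' cross-link).
#'
#' @param g an `mc_lattice` built around `s`.
#' @param s the `mc_structure` the lattice was built around.
#' @param atom_a,atom_b endpoint atom indices (1-based).
#' @param snap_cutoff maximum atom-to-node snapping distance, Angstrom;
#'   default 5.
#' @return object of class `mc_path`: `node_positions` (L x 3), `length`
#'   (A), `endpoints`, `straight_line` (distance between the snapped nodes)
#'   and `atom_distance` (distance between the two atoms).
#' @export
shortest_accessible_path <- function(g, s, atom_a, atom_b, snap_cutoff = 5) {
  xyz <- get_coordinates(s)
  if (atom_a < 1 || atom_a > n_points(s) || atom_b < 1 || atom_b > n_points(s))
    mc_error("mc_value_error", "endpoint atom index out of range")
  ra <- snap_to_lattice(g, xyz[atom_a, ], snap_cutoff)
  rb <- snap_to_lattice(g, xyz[atom_b, ], snap_cutoff)
  if (is.na(ra) || is.na(rb))
    mc_error("mc_buried_endpoint_error", sprintf(
      "atom %d has no accessible lattice node within %.1f A",
      if (is.na(ra)) atom_a else atom_b, snap_cutoff))
  if (ra == rb) {
    pos <- lattice_node_position(g, g$node_lin[ra])
    return(structure(list(node_positions = pos, length = 0,
                          endpoints = c(atom_a, atom_b), straight_line = 0,
                          atom_distance = vnorm(xyz[atom_a, ] - xyz[atom_b, ])),
                     class = "mc_path"))
  }
  sp <- suppressWarnings(
    igraph::shortest_paths(g$graph, from = ra, to = rb,
                           weights = igraph::E(g$graph)$weight,
                           output = "vpath"))
  vp <- as.integer(sp$vpath[[1]])
  if (length(vp) == 0)
    mc_error("mc_no_path_error",
             "endpoints lie in disconnected accessible components (infeasible cross-link)")
  pos <- lattice_node_position(g, g$node_lin[vp])
  steps <- sqrt(rowSums((pos[-1, , drop = FALSE] -
                           pos[-nrow(pos), , drop = FALSE])^2))
  structure(list(node_positions = pos, length = sum(steps),
                 endpoints = c(atom_a, atom_b),
                 straight_line = vnorm(pos[nrow(pos), ] - pos[1, ]),
                 atom_distance = vnorm(xyz[atom_a, ] - xyz[atom_b, ])),
            class = "mc_path")
}

#' @export
print.mc_path <- function(x, ...) {
  cat(sprintf(
    "<mc_path> %d nodes, length %.2f A (straight line %.2f A) between atoms %d and %d\n",
    nrow(x$node_positions), x$length, x$straight_line,
    x$endpoints[1], x$endpoints[2]))
  invisible(x)
}
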
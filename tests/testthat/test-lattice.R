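# Helpers to build structures with hand-set van der Waals radii.
atoms_with_radius <- function(xyz, r) {
  meta <- molcloud:::default_metadata(nrow(xyz))
  meta$vdw_radius <- r
  mc_structure(xyz, meta)
}

test_that("lattice accessibility follows the atom + probe threshold", {
  s <- atoms_with_radius(rbind(c(0, 0, 0)), 2)
  g <- quiet(build_lattice(s, spacing = 1, probe = 1.4, margin = 5))
  pos <- molcloud:::lattice_node_position(g, seq_len(prod(g$dims)))
  d <- sqrt(rowSums(pos^2))
  expect_true(all(!as.vector(g$accessible)[d < 3.4]))
  expect_true(all(as.vector(g$accessible)[d >= 3.4]))

  # far empty corner: everything accessible
  corner <- pos[, 1] > 4 & pos[, 2] > 4 & pos[, 3] > 4
  expect_true(all(as.vector(g$accessible)[corner]))

  expect_error(quiet(build_lattice(select_atoms(s, chain_id == "Z"))),
               class = "mc_empty_error")
  expect_error(quiet(build_lattice(s, spacing = 0)), class = "mc_value_error")
})

test_that("accessibility matches a brute-force all-pairs oracle", {
  xyz <- rbind(c(0, 0, 0), c(3, 1, 0), c(-2, 2, 1), c(1, -3, 2), c(0, 0, 4))
  s <- atoms_with_radius(xyz, c(1.5, 2, 1.2, 1.8, 1.6))
  g <- quiet(build_lattice(s, spacing = 1.5, probe = 1.0, margin = 3))
  pos <- molcloud:::lattice_node_position(g, seq_len(prod(g$dims)))
  oracle <- vapply(seq_len(nrow(pos)), function(i) {
    all(sqrt(colSums((t(xyz) - pos[i, ])^2)) - s$metadata$vdw_radius >= 1.0)
  }, logical(1))
  expect_equal(as.vector(g$accessible), oracle)

  # every edge connects nodes at most sqrt(3) spacing apart
  ends <- igraph::ends(g$graph, igraph::E(g$graph))
  p1 <- molcloud:::lattice_node_position(g, g$node_lin[ends[, 1]])
  p2 <- molcloud:::lattice_node_position(g, g$node_lin[ends[, 2]])
  elen <- sqrt(rowSums((p1 - p2)^2))
  expect_lte(max(elen), 1.5 * sqrt(3) + 1e-9)
  expect_equal(elen, igraph::E(g$graph)$weight, tolerance = 1e-12)
})

test_that("free-space paths respect the 26-connectivity bound", {
  dir <- c(3, 2, 2) / sqrt(17)
  ends <- rbind(c(0.5, 0.5, 0.5), c(0.5, 0.5, 0.5) + 30 * dir)
  s <- atoms_with_radius(ends, 0.2)
  g <- quiet(build_lattice(s, spacing = 1, probe = 0, margin = 2.25))
  # offset atoms never coincide with lattice nodes: all nodes accessible
  expect_true(all(g$accessible))
  path <- shortest_accessible_path(g, s, 1, 2)
  expect_gte(path$length, path$straight_line)
  expect_lte(path$length, 1.09 * path$straight_line)
  # consecutive nodes are lattice neighbours
  steps <- diff(path$node_positions)
  expect_lte(max(sqrt(rowSums(steps^2))), sqrt(3) + 1e-9)

  # endpoints snapping to the same node give a zero-length path
  p0 <- shortest_accessible_path(g, s, 1, 1)
  expect_equal(p0$length, 0)
  expect_equal(nrow(p0$node_positions), 1)
})

make_wall_scene <- function(gap = TRUE) {
  # two endpoint atoms on either side of a z = 0 wall of atoms; the wall
  # spans the whole padded box except (optionally) a gap around (5, 5, 0)
  grid <- as.matrix(expand.grid(x = seq(-9, 9, 1.5), y = seq(-9, 9, 1.5)))
  if (gap) grid <- grid[sqrt((grid[, 1] - 5)^2 + (grid[, 2] - 5)^2) > 3, ]
  wall <- cbind(grid, 0)
  xyz <- rbind(c(0.25, 0.25, -4.25), c(0.25, 0.25, 4.25), wall)
  atoms_with_radius(xyz, c(0.1, 0.1, rep(1.7, nrow(wall))))
}

test_that("a walled maze forces the path through the gap", {
  s <- make_wall_scene(gap = TRUE)
  g <- quiet(build_lattice(s, spacing = 1, probe = 1.0, margin = 1.5))
  path <- shortest_accessible_path(g, s, 1, 2)
  expect_gt(path$length, path$straight_line)
  # where the path crosses the wall plane it must be inside the gap region
  crossing <- path$node_positions[abs(path$node_positions[, 3]) < 1.5, ,
                                  drop = FALSE]
  expect_gt(nrow(crossing), 0)
  expect_true(all(sqrt((crossing[, 1] - 5)^2 + (crossing[, 2] - 5)^2) < 3.5))

  # without the gap the two sides are disconnected: infeasible cross-link
  solid <- make_wall_scene(gap = FALSE)
  g2 <- quiet(build_lattice(solid, spacing = 1, probe = 1.0, margin = 1.5))
  expect_error(shortest_accessible_path(g2, solid, 1, 2),
               class = "mc_no_path_error")
})

test_that("buried endpoints are reported as errors", {
  dirs <- as.matrix(expand.grid(c(-1, 0, 1), c(-1, 0, 1), c(-1, 0, 1)))
  dirs <- dirs[rowSums(dirs^2) > 0, ]
  shell <- sweep(dirs, 1, sqrt(rowSums(dirs^2)), "/") * 2.5
  s <- atoms_with_radius(rbind(c(0, 0, 0), c(10, 10, 10), shell),
                         c(0.5, 0.5, rep(2.2, nrow(shell))))
  g <- quiet(build_lattice(s, spacing = 1, probe = 1.4, margin = 2))
  expect_error(shortest_accessible_path(g, s, 1, 2, snap_cutoff = 2.5),
               class = "mc_buried_endpoint_error")
})

test_that("path length equals the exhaustive Dijkstra oracle", {
  xyz <- rbind(c(0.5, 0.5, 0.5), c(5.5, 4.5, 3.5), c(3, 2.5, 2))
  s <- atoms_with_radius(xyz, c(0.4, 0.4, 2.2))
  g <- quiet(build_lattice(s, spacing = 1, probe = 0.8, margin = 1.5))
  expect_lte(prod(g$dims), 15^3)
  path <- shortest_accessible_path(g, s, 1, 2)
  ra <- molcloud:::snap_to_lattice(g, get_coordinates(s)[1, ], 5)
  rb <- molcloud:::snap_to_lattice(g, get_coordinates(s)[2, ], 5)
  expect_equal(path$length, oracle_shortest_path_length(g, ra, rb),
               tolerance = 1e-12)
})

test_that("path length is non-increasing as the probe shrinks", {
  # The monotonicity property assumes identical snapping, so the endpoints
  # are placed such that their nearest lattice nodes (offsets (.5,.5,.5) and
  # (.5,.5,.2) from the atoms, distances 0.866 and 0.735) stay accessible at
  # every probe in the sweep: the snapped nodes are then the same throughout.
  grid <- as.matrix(expand.grid(x = seq(-9, 9, 1.5), y = seq(-9, 9, 1.5)))
  grid <- grid[sqrt((grid[, 1] - 5)^2 + (grid[, 2] - 5)^2) > 3, ]
  xyz <- rbind(c(0, 0, -4.3), c(0, 0, 4.0), cbind(grid, 0))
  s <- atoms_with_radius(xyz, c(0.1, 0.1, rep(1.7, nrow(grid))))
  snapped <- NULL
  lens <- vapply(c(0.5, 0.45, 0.4), function(pr) {
    g <- quiet(build_lattice(s, spacing = 1, probe = pr, margin = 1.5))
    now <- c(g$node_lin[molcloud:::snap_to_lattice(g, xyz[1, ], 5)],
             g$node_lin[molcloud:::snap_to_lattice(g, xyz[2, ], 5)])
    if (is.null(snapped)) snapped <<- now else expect_identical(now, snapped)
    shortest_accessible_path(g, s, 1, 2)$length
  }, numeric(1))
  expect_true(all(diff(lens) <= 1e-9))
})
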
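test_that("all five regular polyhedra satisfy the scaffold invariants", {
  kinds <- c(tetrahedron = 4L, cube = 8L, octahedron = 6L,
             dodecahedron = 20L, icosahedron = 12L)
  n_edges <- c(tetrahedron = 6L, cube = 12L, octahedron = 12L,
               dodecahedron = 30L, icosahedron = 30L)
  for (kind in names(kinds)) {
    p <- make_polyhedron(kind, edge_length = 2.5)
    expect_equal(nrow(p$vertices), unname(kinds[kind]))
    expect_equal(nrow(p$edges), unname(n_edges[kind]))
    lens <- sqrt(rowSums((p$vertices[p$edges[, 1], , drop = FALSE] -
                            p$vertices[p$edges[, 2], , drop = FALSE])^2))
    expect_lt(max(abs(lens - 2.5)), 1e-9)
    expect_lt(max(abs(colMeans(p$vertices))), 1e-12)
  }
  expect_error(make_polyhedron("prism", 1), class = "mc_kind_error")
  expect_error(make_polyhedron("cube", 0), class = "mc_value_error")

  # tetrahedron edge 1: all 6 pairwise vertex distances equal 1
  tet <- make_polyhedron("tetrahedron", 1)
  pd <- as.vector(stats::dist(tet$vertices))
  expect_equal(pd, rep(1, 6), tolerance = 1e-9)
})

test_that("scale_scaffold rescales vertices, edges and pairwise distances", {
  p <- make_polyhedron("octahedron", 2)
  expect_equal(scale_scaffold(p, 1), p)
  q <- scale_scaffold(p, 3)
  expect_equal(q$edge_length, 6)
  expect_equal(as.vector(stats::dist(q$vertices)),
               3 * as.vector(stats::dist(p$vertices)), tolerance = 1e-12)
  expect_error(scale_scaffold(p, 0), class = "mc_value_error")
})

test_that("scaffold assembly places congruent copies on every vertex", {
  mono <- make_toy_polymer(10, "helix")
  p <- make_polyhedron("tetrahedron", 80)
  a <- assemble_on_scaffold(mono, p)
  expect_equal(n_subunits(a), 4)
  flat <- flatten_assembly(a)
  expect_equal(n_points(flat), 40)

  # in-concert zero orientation: all copies congruent, and the known frame
  # transforms map copy i onto copy j with vanishing RMSD
  for (i in 1:3) for (j in (i + 1):4) {
    si <- assembly_subunit(a, i); sj <- assembly_subunit(a, j)
    expect_lt(superpose(si, sj)$rmsd, 1e-6)
    known <- compose_transforms(a$placements[[j]],
                                invert_transform(a$placements[[i]]))
    expect_lt(rmsd(apply_transform(si, known), sj), 1e-6)
  }

  # scaffold edge >= 2x monomer diameter: no steric overlap between subunits
  diam <- max(distance_matrix(mono))
  big <- assemble_on_scaffold(mono, make_polyhedron("tetrahedron", 2.2 * diam))
  fb <- flatten_assembly(big)
  dm <- distance_matrix(select_atoms(fb, chain_id == "A"),
                        select_atoms(fb, chain_id == "B"))
  expect_gt(min(dm), 0)

  expect_error(assemble_on_scaffold(mono, p, orientation = matrix(0, 3, 3)),
               class = "mc_size_error")
  # per-vertex orientations differ: copies still congruent (chirality kept)
  or <- matrix(c(10, 20, 30, 40, 50, 60, 70, 80, 90, 100, 110, 120), 4, 3)
  av <- assemble_on_scaffold(mono, p, orientation = or)
  expect_lt(superpose(assembly_subunit(av, 1), assembly_subunit(av, 4))$rmsd,
            1e-6)
})

test_that("cyclic multimers have exact Cn symmetry", {
  pt <- mc_structure(rbind(c(0, 0, 0)))
  two <- flatten_assembly(cyclic_multimer(pt, 2, 7))
  expect_equal(unname(get_coordinates(two)),
               rbind(c(7, 0, 0), c(-7, 0, 0)), tolerance = 1e-12)

  # degenerate radius: all copies coincide for a point at the origin
  zero <- flatten_assembly(cyclic_multimer(pt, 3, 0))
  expect_equal(max(distance_matrix(zero)), 0)

  mono <- make_toy_polymer(5, "helix")
  for (n in 2:8) {
    flat <- flatten_assembly(cyclic_multimer(mono, n, 30))
    expect_equal(n_points(flat), n * 5)
    # rotate by 2 pi / n about z and cyclically permute subunits
    rotated <- apply_transform(flat, rigid_transform(molcloud:::rot_z(2 * pi / n)))
    perm <- c(seq_len(5) + 5 * (n - 1), seq_len(5 * (n - 1)))
    expect_lt(max(abs(get_coordinates(rotated)[perm, ] -
                        get_coordinates(flat))), 1e-6)
  }
  expect_error(cyclic_multimer(mono, 1, 10), class = "mc_value_error")
})

test_that("flatten remaps chains and conserves points and mass", {
  mono <- make_toy_polymer(3, "straight")
  a <- cyclic_multimer(mono, 2, 15)
  flat <- flatten_assembly(a)
  expect_equal(n_points(flat), 6)
  expect_equal(flat$metadata$chain_id, rep(c("A", "B"), each = 3))
  expect_equal(sum(flat$metadata$mass), 2 * sum(mono$metadata$mass))

  # flatten then select chain B recovers subunit 2's placed coordinates
  chain_b <- select_atoms(flat, chain_id == "B")
  expect_equal(get_coordinates(chain_b),
               get_coordinates(assembly_subunit(a, 2)), tolerance = 1e-12)

  expect_equal(molcloud:::chain_labels(2), c("A", "B"))
  expect_warning(labels63 <- molcloud:::chain_labels(63), "62")
  expect_length(unique(labels63), 63)
})

test_that("appending perturbed conformations raises per-point fluctuation", {
  s <- make_toy_polymer(6, "helix")
  multi <- s
  for (seed in 1:5) {
    jitter <- molcloud:::with_seed(seed, matrix(rnorm(18, sd = 0.3), 6, 3))
    pert <- s
    pert$coordinates[1, , ] <- pert$coordinates[1, , ] + jitter
    multi <- append_conformation(multi, pert)
  }
  expect_equal(n_conformations(multi), 6)
  expect_true(all(rmsf(multi) > 0))
})

test_that("ellipsoid clouds respect the surface/volume contracts", {
  sph <- ellipsoid_cloud(c(5, 5, 5), 500, mode = "surface")
  norms <- sqrt(rowSums(get_coordinates(sph)^2))
  expect_lt(max(abs(norms - 5)), 1e-9)

  ell <- ellipsoid_cloud(c(4, 2, 1), 300, mode = "surface")
  q <- rowSums(sweep(get_coordinates(ell), 2, c(4, 2, 1), "/")^2)
  expect_lt(max(abs(q - 1)), 1e-9)

  # volume uniformity: half the points fall inside radius r / 2^(1/3)
  vol <- ellipsoid_cloud(c(6, 6, 6), 1e4, mode = "volume", seed = 5)
  r <- sqrt(rowSums(get_coordinates(vol)^2))
  expect_lte(max(r), 6 + 1e-9)
  frac <- mean(r <= 6 / 2^(1 / 3))
  expect_lt(abs(frac - 0.5), 0.02)

  # same seed twice: identical clouds; global RNG state untouched
  a <- ellipsoid_cloud(c(3, 2, 1), 50, mode = "volume", seed = 7)
  b <- ellipsoid_cloud(c(3, 2, 1), 50, mode = "volume", seed = 7)
  expect_identical(a$coordinates, b$coordinates)
})

test_that("sphere chains space centers by 2 r (1 - overlap)", {
  a <- sphere_chain(2, 10, 0, n_points = 50)
  expect_equal(a$placements[[2]]$translation, c(20, 0, 0))
  b <- sphere_chain(2, 10, 0.25, n_points = 50)
  expect_equal(b$placements[[2]]$translation, c(15, 0, 0))

  # n = 5: bounding-box long axis = 2 r + 4 spacing (sampling tolerance)
  ch <- flatten_assembly(sphere_chain(5, 10, 0.2, n_points = 400))
  xyz <- get_coordinates(ch)
  spacing <- 2 * 10 * 0.8
  expect_equal(max(xyz[, 1]) - min(xyz[, 1]), 2 * 10 + 4 * spacing,
               tolerance = 0.01)
  expect_error(sphere_chain(2, 10, 1), class = "mc_value_error")
})
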
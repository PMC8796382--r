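# Collision cross section by the projection approximation (PA): the mean,
# over uniformly random orientations, of the projected shadow area of the
# union of atom+probe disks, rasterised on a 2D grid.  PA systematically
# underestimates trajectory-method CCS for large molecules; a linear
# calibration factor is exposed to match published scales.

shadow_area <- function(xy, radii, raster) {
  xmin <- min(xy[, 1] - radii); xmax <- max(xy[, 1] + radii)
  ymin <- min(xy[, 2] - radii); ymax <- max(xy[, 2] + radii)
  nx <- as.integer(ceiling((xmax - xmin) / raster)) + 1L
  ny <- as.integer(ceiling((ymax - ymin) / raster)) + 1L
  occ <- matrix(FALSE, nx, ny)
  gx <- xmin + (seq_len(nx) - 1) * raster
  gy <- ymin + (seq_len(ny) - 1) * raster
  for (a in seq_along(radii)) {
    r <- radii[a]
    ix <- which(abs(gx - xy[a, 1]) <= r)
    iy <- which(abs(gy - xy[a, 2]) <= r)
    if (length(ix) == 0 || length(iy) == 0) next
    d2 <- outer((gx[ix] - xy[a, 1])^2, (gy[iy] - xy[a, 2])^2, "+")
    occ[ix, iy] <- occ[ix, iy] | (d2 <= r^2)
  }
  sum(occ) * raster^2
}

#' Collision cross section by the rotationally averaged projection approximation
#'
#' Averages the projected shadow area of the union of disks of radius
#' `vdw_radius + probe` over `n_rotations` uniformly random orientations
#' (seeded quaternion sampling), rasterised at `raster` Angstrom.  The
#' standard error of the mean across orientations is attached.  PA values
#' systematically underestimate trajectory-method CCS; `calibration`
#' multiplies the result (default 1.0).
#'
#' @param s an `mc_structure` (current conformation used).
#' @param probe collision probe radius, Angstrom; default 1.0 (helium-like).
#' @param n_rotations number of random orientations (>= 1); default 300.
#' @param raster 2D rasterisation step, Angstrom; default 0.2.  Must be
#'   smaller than the smallest effective atom radius.
#' @param seed integer seed (global random state untouched).
#' @param calibration multiplicative calibration factor; default 1.0.
#' @return CCS in A^2, with attributes `sem` (standard error of the mean,
#'   A^2) and `n_rotations`.
#' @export
ccs_projection <- function(s, probe = 1.0, n_rotations = 300, raster = 0.2,
                           seed = 1, calibration = 1.0) {
  if (n_points(s) < 1) mc_error("mc_empty_error", "empty structure")
  if (n_rotations < 1) mc_error("mc_value_error", "n_rotations must be >= 1")
  radii <- s$metadata$vdw_radius + probe
  if (raster >= min(radii))
    mc_error("mc_resolution_error",
             "raster step must be smaller than the smallest atom+probe radius")
  message(sprintf(
    "ccs_projection: probe %.2f A, raster %.2f A, %d rotations, calibration %.3f",
    probe, raster, n_rotations, calibration))
  xyz <- get_coordinates(s)
  rots <- with_seed(seed, random_rotations(n_rotations))
  areas <- vapply(rots, function(R) {
    shadow_area((xyz %*% t(R))[, 1:2, drop = FALSE], radii, raster)
  }, numeric(1))
  ccs <- calibration * mean(areas)
  sem <- calibration * if (length(areas) > 1)
    stats::sd(areas) / sqrt(length(areas)) else 0
  structure(ccs, sem = sem, n_rotations = n_rotations)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Each atom's sphere of radius `vdw_radius + probe` is sampled with a
#' deterministic golden-spiral point set; the exposed fraction (points not
#' inside any other expanded sphere) times the sphere area gives the
#' per-atom SASA.  An isolated atom is exact by construction:
#' `4 * pi * (r + probe)^2`.
#'
#' @param s an `mc_structure` (current conformation used).
#' @param probe solvent probe radius, Angstrom; default 1.4 (water).
#' @param n_sphere_points test points per atom sphere; default 960.
#' @return a list with `per_atom` (numeric vector, A^2) and `total` (A^2).
#' @export
sasa <- function(s, probe = 1.4, n_sphere_points = 960) {
  if (n_points(s) < 1) mc_error("mc_empty_error", "empty structure")
  message(sprintf("sasa: probe %.2f A, %d test points per atom",
                  probe, n_sphere_points))
  xyz <- get_coordinates(s)
  radii <- s$metadata$vdw_radius + probe
  n <- n_points(s)
  unit_pts <- fibonacci_sphere(n_sphere_points)
  dm <- distance_matrix(s)
  per_atom <- numeric(n)
  for (i in seq_len(n)) {
    pts <- sweep(unit_pts * radii[i], 2, xyz[i, ], "+")
    neighbours <- which(dm[i, ] < radii[i] + radii & seq_len(n) != i)
    exposed <- rep(TRUE, n_sphere_points)
    for (j in neighbours) {
      d2 <- rowSums(sweep(pts, 2, xyz[j, ])^2)
      exposed <- exposed & d2 > radii[j]^2
      if (!any(exposed)) break
    }
    per_atom[i] <- 4 * pi * radii[i]^2 * mean(exposed)
  }
  list(per_atom = per_atom, total = sum(per_atom))
}
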
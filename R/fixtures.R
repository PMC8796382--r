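# Deterministic synthetic inputs: toy polymers and analytic Gaussian-blob
# maps.  Everything the test surface needs is generated here, so no external
# data files are required.  All randomness flows through an explicit seed.

#' Generate a deterministic toy polymer
#'
#' Geometries: `"helix"` places one residue per 1.5 A rise and 100 degree
#' twist about z on a 2.3 A radius (idealised alpha-helix backbone scale);
#' `"straight"` spaces residues 3.8 A apart along z (a C-alpha virtual bond);
#' `"random-coil"` is a seeded random walk with 3.8 A steps.  Additional
#' atoms within a residue are offset radially outward by 1 A each.
#'
#' @param n_residues number of residues (>= 1).
#' @param geometry `"helix"`, `"straight"` or `"random-coil"`.
#' @param seed integer seed (used by random-coil; global state untouched).
#' @param atom_pattern character vector of atom names per residue;
#'   default `"CA"`.
#' @return an `mc_structure` with fully populated metadata.
#' @examples
#' make_toy_polymer(5, "straight")
#' @export
make_toy_polymer <- function(n_residues, geometry = c("helix", "straight",
                                                      "random-coil"),
                             seed = 1, atom_pattern = "CA") {
  geometry <- match.arg(geometry)
  if (n_residues < 1) mc_error("mc_value_error", "n_residues must be >= 1")
  centers <- switch(geometry,
    helix = {
      i <- seq_len(n_residues) - 1
      theta <- i * 100 * pi / 180
      cbind(2.3 * cos(theta), 2.3 * sin(theta), i * 1.5)
    },
    straight = cbind(0, 0, (seq_len(n_residues) - 1) * 3.8),
    `random-coil` = with_seed(seed, {
      steps <- matrix(rnorm(3 * (n_residues - 1)), ncol = 3)
      steps <- 3.8 * steps / sqrt(rowSums(steps^2))
      apply(rbind(c(0, 0, 0), steps), 2, cumsum)
    })
  )
  centers <- matrix(centers, ncol = 3)
  k <- length(atom_pattern)
  xyz <- matrix(NA_real_, n_residues * k, 3)
  for (r in seq_len(n_residues)) {
    radial <- centers[r, ] - c(0, 0, centers[r, 3])
    radial <- if (vnorm(radial) > 1e-9) radial / vnorm(radial) else c(1, 0, 0)
    for (j in seq_len(k))
      xyz[(r - 1) * k + j, ] <- centers[r, ] + (j - 1) * radial
  }
  element <- infer_element(rep(atom_pattern, n_residues))
  props <- suppressWarnings(element_properties(element))
  meta <- data.frame(
    atom_name = rep(atom_pattern, n_residues),
    residue_name = "ALA",
    residue_id = rep(seq_len(n_residues), each = k),
    insertion = "",
    chain_id = "A",
    element = element,
    mass = props$mass,
    vdw_radius = props$vdw_radius,
    occupancy = 1,
    beta = 0,
    stringsAsFactors = FALSE
  )
  mc_structure(xyz, meta)
}

#' Analytic Gaussian-blob density map
#'
#' An isotropic Gaussian `amplitude * exp(-r^2 / (2 sigma^2))` evaluated at
#' voxel centers on a cubic grid spanning `center +/- extent`.  Because the
#' field is analytic, the isovalue enclosing a target volume V is known in
#' closed form: `amplitude * exp(-R^2 / (2 sigma^2))` with
#' `R = (3 V / (4 pi))^(1/3)`, which makes exact inverse-problem tests
#' possible.
#'
#' @param center length-3 numeric, Angstrom.
#' @param sigma Gaussian width, Angstrom (> 0).
#' @param amplitude peak value; default 1.
#' @param voxel voxel edge, Angstrom (> 0).
#' @param extent half-width of the grid around `center`, Angstrom (> 0).
#' @return an `mc_density` whose grid contains a voxel exactly at `center`.
#' @export
make_gaussian_blob_map <- function(center = c(0, 0, 0), sigma = 2,
                                   amplitude = 1, voxel = 0.5, extent = 8) {
  if (sigma <= 0 || voxel <= 0 || extent <= 0)
    mc_error("mc_value_error", "sigma, voxel and extent must be > 0")
  half <- as.integer(ceiling(extent / voxel))
  ax <- (-half:half) * voxel
  n <- length(ax)
  g1 <- exp(-ax^2 / (2 * sigma^2))
  values <- amplitude * (g1 %o% g1 %o% g1)
  density_map(values, origin = center - half * voxel, delta = rep(voxel, 3))
}
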
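# Multimeric assemblies: subunit copies plus per-copy rigid placements,
# optionally tied to a polyhedral scaffold.  Subunits are stored centred
# (centroid at the origin); `flatten()` applies the placements and remaps
# chain identifiers.

new_assembly <- function(subunits, placements, scaffold = NULL) {
  if (length(subunits) != length(placements))
    mc_error("mc_size_error", "one placement per subunit is required")
  structure(list(subunits = subunits, placements = placements,
                 scaffold = scaffold),
            class = "mc_assembly")
}

#' @export
print.mc_assembly <- function(x, ...) {
  cat(sprintf("<mc_assembly> %d subunit(s)%s\n", length(x$subunits),
              if (!is.null(x$scaffold)) paste0(" on a ", x$scaffold$kind,
                                               " scaffold") else ""))
  invisible(x)
}

#' Number of subunits in an assembly
#' @param a an `mc_assembly`.
#' @return integer count.
#' @export
n_subunits <- function(a) length(a$subunits)

#' Extract one subunit of an assembly
#' @param a an `mc_assembly`.
#' @param i subunit index.
#' @param placed apply the subunit's rigid placement (default) or return the
#'   centred copy?
#' @return an `mc_structure`.
#' @export
assembly_subunit <- function(a, i, placed = TRUE) {
  s <- a$subunits[[i]]
  if (placed) apply_transform(s, a$placements[[i]], "all") else s
}

# Centre a structure at the centroid of its current conformation (all
# conformations are shifted by the same vector so internal motion is kept).
center_structure <- function(s) {
  shift <- -colMeans(get_coordinates(s))
  apply_transform(s, rigid_transform(diag(3), shift), "all")
}

#' Assemble monomer copies on the vertices of a polyhedral scaffold
#'
#' One copy of the monomer per scaffold vertex.  Each copy is centred at its
#' centroid, rotated by its orientation (intrinsic z-y-z Euler angles,
#' degrees) composed with the deterministic vertex frame (z toward the
#' scaffold centroid, x toward the lowest-index neighbour), then translated
#' to the vertex.  A single orientation triple rotates all copies "in
#' concert" in their local frames; a V x 3 matrix rotates them individually.
#'
#' @param monomer a non-empty `mc_structure`.
#' @param p an `mc_polyhedron`.
#' @param orientation length-3 Euler triple (in concert) or V x 3 matrix
#'   (per vertex), degrees.
#' @return an `mc_assembly` with the scaffold attached.
#' @export
assemble_on_scaffold <- function(monomer, p, orientation = c(0, 0, 0)) {
  if (n_points(monomer) == 0)
    mc_error("mc_empty_error", "monomer must contain at least one point")
  nv <- nrow(p$vertices)
  if (is.matrix(orientation)) {
    if (nrow(orientation) != nv || ncol(orientation) != 3)
      mc_error("mc_size_error", sprintf(
        "per-vertex orientation must be %d x 3", nv))
    euls <- orientation
  } else {
    if (length(orientation) != 3)
      mc_error("mc_size_error", "in-concert orientation must have 3 angles")
    euls <- matrix(orientation, nv, 3, byrow = TRUE)
  }
  centred <- center_structure(monomer)
  placements <- lapply(seq_len(nv), function(i) {
    R <- vertex_frame(p, i) %*% euler_zyz(euls[i, 1], euls[i, 2], euls[i, 3])
    rigid_transform(R, p$vertices[i, ])
  })
  new_assembly(rep(list(centred), nv), placements, scaffold = p)
}

#' Build a cyclic (Cn) multimer
#'
#' n copies of the monomer placed at angles `2*pi*i/n` on a circle of the
#' given radius in the xy-plane, each rotated by the same angle about z, so
#' the flattened assembly has exact Cn symmetry about the z axis.
#'
#' @param monomer a non-empty `mc_structure`.
#' @param n number of copies (>= 2).
#' @param radius circle radius, Angstrom (>= 0).
#' @return an `mc_assembly`.
#' @export
cyclic_multimer <- function(monomer, n, radius) {
  if (n < 2) mc_error("mc_value_error", "a cyclic multimer needs n >= 2")
  if (radius < 0) mc_error("mc_value_error", "radius must be >= 0")
  if (n_points(monomer) == 0)
    mc_error("mc_empty_error", "monomer must contain at least one point")
  placements <- lapply(seq_len(n) - 1, function(i) {
    theta <- 2 * pi * i / n
    rigid_transform(rot_z(theta),
                    radius * c(cos(theta), sin(theta), 0))
  })
  new_assembly(rep(list(monomer), n), placements)
}

chain_labels <- function(n) {
  alphabet <- c(LETTERS, letters, as.character(0:9))
  if (n <= length(alphabet)) return(alphabet[seq_len(n)])
  warning("more than 62 subunits: using two-character chain identifiers",
          call. = FALSE)
  first <- rep(alphabet, each = length(alphabet))
  second <- rep(alphabet, times = length(alphabet))
  paste0(first, second)[seq_len(n)]
}

#' Flatten an assembly into a single structure
#'
#' Applies every placement and concatenates all subunit points, remapping
#' chain identifiers per subunit (A, B, C, ...; two-character identifiers
#' with a warning beyond 62 subunits).  All subunits must carry the same
#' number of conformations.  Total point count and total mass are conserved.
#'
#' @param a an `mc_assembly` with at least one subunit.
#' @return an `mc_structure`.
#' @export
flatten_assembly <- function(a) {
  if (n_subunits(a) < 1)
    mc_error("mc_empty_error", "assembly has no subunits")
  placed <- lapply(seq_len(n_subunits(a)), assembly_subunit, a = a)
  ms <- vapply(placed, n_conformations, integer(1))
  if (length(unique(ms)) != 1)
    mc_error("mc_size_error",
             "subunits carry different numbers of conformations")
  labels <- chain_labels(n_subunits(a))
  ns <- vapply(placed, n_points, integer(1))
  total <- sum(ns)
  coords <- array(NA_real_, dim = c(ms[1], total, 3))
  offset <- 0L
  metas <- vector("list", length(placed))
  for (i in seq_along(placed)) {
    coords[, offset + seq_len(ns[i]), ] <- placed[[i]]$coordinates
    meta <- placed[[i]]$metadata
    meta$chain_id <- labels[i]
    metas[[i]] <- meta
    offset <- offset + ns[i]
  }
  mc_structure(coords, do.call(rbind, metas))
}

#' Quasi-uniform ellipsoid point cloud (super-coarse-grained model)
#'
#' Surface mode places points on a Fibonacci sphere scaled to the ellipsoid
#' semiaxes (fast and quasi-uniform on the sphere; the anisotropic scaling
#' slightly distorts uniformity on elongated ellipsoids).  Volume mode uses
#' seeded rejection sampling from the bounding box, uniform in volume.
#'
#' @param semiaxes length-3 positive numeric `(a, b, c)`, Angstrom.
#' @param n_points number of points (>= 1).
#' @param mode `"surface"` or `"volume"`.
#' @param seed integer seed; the global random state is left untouched.
#' @return an `mc_structure` with default metadata.
#' @export
ellipsoid_cloud <- function(semiaxes, n_points, mode = c("surface", "volume"),
                            seed = 1) {
  mode <- match.arg(mode)
  if (length(semiaxes) != 3 || any(semiaxes <= 0))
    mc_error("mc_value_error", "semiaxes must be 3 positive lengths")
  if (n_points < 1) mc_error("mc_value_error", "n_points must be >= 1")
  xyz <- if (mode == "surface") {
    sweep(fibonacci_sphere(n_points), 2, semiaxes, "*")
  } else {
    with_seed(seed, {
      pts <- matrix(NA_real_, 0, 3)
      while (nrow(pts) < n_points) {
        cand <- cbind(runif(2 * n_points, -semiaxes[1], semiaxes[1]),
                      runif(2 * n_points, -semiaxes[2], semiaxes[2]),
                      runif(2 * n_points, -semiaxes[3], semiaxes[3]))
        keep <- rowSums(sweep(cand, 2, semiaxes, "/")^2) <= 1
        pts <- rbind(pts, cand[keep, , drop = FALSE])
      }
      pts[seq_len(n_points), , drop = FALSE]
    })
  }
  meta <- default_metadata(n_points)
  meta$residue_id <- seq_len(n_points)
  mc_structure(unname(xyz), meta)
}

#' Chain of overlapping spheres (super-coarse-grained model)
#'
#' n sphere-surface point clouds of the given radius placed on the x axis
#' with centre spacing `2 * radius * (1 - overlap_fraction)`, emulating a
#' linear chain of globular subunits with a controlled overlap level.
#'
#' @param n_subunits number of spheres (>= 1).
#' @param radius sphere radius, Angstrom.
#' @param overlap_fraction in `[0, 1)`: 0 means touching spheres.
#' @param n_points points per sphere surface (default 200).
#' @return an `mc_assembly`.
#' @export
sphere_chain <- function(n_subunits, radius, overlap_fraction = 0,
                         n_points = 200) {
  if (n_subunits < 1) mc_error("mc_value_error", "n_subunits must be >= 1")
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    mc_error("mc_value_error", "overlap_fraction must be in [0, 1)")
  spacing <- 2 * radius * (1 - overlap_fraction)
  sphere <- ellipsoid_cloud(rep(radius, 3), n_points, mode = "surface")
  placements <- lapply(seq_len(n_subunits) - 1, function(i)
    rigid_transform(diag(3), c(i * spacing, 0, 0)))
  new_assembly(rep(list(sphere), n_subunits), placements)
}
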
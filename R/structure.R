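# The central data model: an M x N x 3 coordinate array (M conformations of
# N points, Angstrom) plus an N-row per-point metadata table.

.metadata_columns <- c("atom_name", "residue_name", "residue_id", "insertion",
                       "chain_id", "element", "mass", "vdw_radius",
                       "occupancy", "beta")

default_metadata <- function(n) {
  data.frame(
    atom_name = rep("CA", n),
    residue_name = rep("ALA", n),
    residue_id = seq_len(n),
    insertion = rep("", n),
    chain_id = rep("A", n),
    element = rep("C", n),
    mass = rep(12.011, n),
    vdw_radius = rep(1.70, n),
    occupancy = rep(1, n),
    beta = rep(0, n),
    stringsAsFactors = FALSE
  )
}

#' Construct a multi-conformation point-cloud structure
#'
#' The core container: coordinates are stored as an `M x N x 3` array
#' (M alternative conformations of the same N points, in Angstrom), together
#' with an N-row metadata table (atom_name, residue_name, residue_id,
#' insertion, chain_id, element, mass, vdw_radius, occupancy, beta).
#' Geometry operations act on the `current` conformation by default.
#'
#' @param coordinates an `N x 3` matrix (one conformation) or an `M x N x 3`
#'   array of conformations, Angstrom.
#' @param metadata optional N-row data.frame; missing standard columns are
#'   filled with defaults, and missing mass/vdw_radius are looked up from the
#'   element column.
#' @param current index of the active conformation (1-based, default 1).
#' @return an object of class `mc_structure`.
#' @examples
#' s <- mc_structure(matrix(rnorm(15), 5, 3))
#' n_points(s)
#' @export
mc_structure <- function(coordinates, metadata = NULL, current = 1L) {
  if (is.matrix(coordinates)) {
    if (ncol(coordinates) != 3)
      mc_error("mc_value_error", "coordinate matrix must have 3 columns")
    coordinates <- array(coordinates, dim = c(1L, nrow(coordinates), 3L))
  }
  if (!is.array(coordinates) || length(dim(coordinates)) != 3 ||
      dim(coordinates)[3] != 3)
    mc_error("mc_value_error", "coordinates must be an M x N x 3 array")
  n <- dim(coordinates)[2]
  if (is.null(metadata)) {
    metadata <- default_metadata(n)
  } else {
    metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
    if (nrow(metadata) != n)
      mc_error("mc_value_error", sprintf(
        "metadata has %d rows but structure has %d points", nrow(metadata), n))
    if (!is.null(metadata$element) &&
        (is.null(metadata$mass) || is.null(metadata$vdw_radius))) {
      props <- element_properties(metadata$element)
      if (is.null(metadata$mass)) metadata$mass <- props$mass
      if (is.null(metadata$vdw_radius)) metadata$vdw_radius <- props$vdw_radius
    }
    defaults <- default_metadata(n)
    for (col in .metadata_columns)
      if (is.null(metadata[[col]])) metadata[[col]] <- defaults[[col]]
    metadata <- metadata[, union(.metadata_columns,
                                 names(metadata)), drop = FALSE]
  }
  rownames(metadata) <- NULL
  s <- structure(
    list(coordinates = coordinates, current = as.integer(current),
         metadata = metadata),
    class = "mc_structure")
  validate_structure(s)
  s
}

validate_structure <- function(s) {
  dims <- dim(s$coordinates)
  if (n_points(s) > 0 && !all(is.finite(s$coordinates)))
    mc_error("mc_value_error", "coordinates must all be finite")
  if (s$current < 1L || s$current > dims[1])
    mc_error("mc_value_error", sprintf(
      "current conformation %d outside [1, %d]", s$current, dims[1]))
  if (nrow(s$metadata) != dims[2])
    mc_error("mc_value_error", "metadata row count does not match N")
  if (n_points(s) > 0) {
    if (any(!is.finite(s$metadata$vdw_radius)) || any(s$metadata$vdw_radius <= 0))
      mc_error("mc_value_error", "all vdw_radius must be > 0")
    if (any(!is.finite(s$metadata$mass)) || any(s$metadata$mass < 0))
      mc_error("mc_value_error", "all mass must be >= 0")
  }
  invisible(s)
}

#' Number of points (atoms) in a structure
#' @param s an `mc_structure`.
#' @return integer N.
#' @export
n_points <- function(s) dim(s$coordinates)[2]

#' Number of conformations in a structure
#' @param s an `mc_structure`.
#' @return integer M.
#' @export
n_conformations <- function(s) dim(s$coordinates)[1]

#' Extract one conformation as an N x 3 coordinate matrix
#' @param s an `mc_structure`.
#' @param conformation conformation index; defaults to `s$current`.
#' @return `N x 3` numeric matrix (Angstrom).
#' @export
get_coordinates <- function(s, conformation = s$current) {
  m <- n_conformations(s)
  if (conformation < 1 || conformation > m)
    mc_error("mc_value_error", sprintf(
      "conformation %d outside [1, %d]", conformation, m))
  matrix(s$coordinates[conformation, , ], ncol = 3,
         dimnames = list(NULL, c("x", "y", "z")))
}

set_coordinates <- function(s, xyz, conformation = s$current) {
  s$coordinates[conformation, , ] <- xyz
  s
}

#' @export
print.mc_structure <- function(x, ...) {
  cat(sprintf("<mc_structure> %d points, %d conformation(s), current = %d\n",
              n_points(x), n_conformations(x), x$current))
  if (n_points(x) > 0) {
    chains <- unique(x$metadata$chain_id)
    cat(sprintf("  chains: %s | total mass: %.1f Da\n",
                paste(chains, collapse = ""), sum(x$metadata$mass)))
  }
  invisible(x)
}

resolve_selection <- function(s, subset, indices, env) {
  if (!is.null(indices)) {
    idx <- as.integer(indices)
    if (any(idx < 1 | idx > n_points(s)))
      mc_error("mc_selection_error", "selection indices outside [1, N]")
    return(sort(unique(idx)))
  }
  if (is.null(subset)) return(seq_len(n_points(s)))
  keep <- tryCatch(
    eval(subset, s$metadata, enclos = env),
    error = function(e) mc_error(
      "mc_selection_error",
      paste0("selection predicate failed (unknown metadata column?): ",
             conditionMessage(e))))
  if (!is.logical(keep) || length(keep) != n_points(s))
    mc_error("mc_selection_error",
             "selection predicate must yield one logical per point")
  which(keep & !is.na(keep))
}

#' Select a subset of points by metadata predicate or explicit indices
#'
#' All M conformations are preserved; metadata rows stay aligned with the
#' point axis.  An empty match yields an empty structure (N = 0), not an
#' error.  The original structure is untouched.
#'
#' @param s an `mc_structure`.
#' @param subset an unquoted predicate over metadata columns, e.g.
#'   `atom_name == "CA"` or `residue_id %in% 1:2`.
#' @param indices alternatively, an explicit vector of point indices
#'   (1-based); takes precedence over `subset`.
#' @return a new `mc_structure` with the selected points.
#' @examples
#' s <- make_toy_polymer(5)
#' select_atoms(s, residue_id <= 2)
#' @export
select_atoms <- function(s, subset = NULL, indices = NULL) {
  idx <- resolve_selection(s, substitute(subset), indices, parent.frame())
  coords <- s$coordinates[, idx, , drop = FALSE]
  meta <- s$metadata[idx, , drop = FALSE]
  rownames(meta) <- NULL
  out <- s
  out$coordinates <- coords
  out$metadata <- meta
  out
}

#' Append conformations of one structure onto another
#'
#' Both structures must describe the same points, verified by metadata
#' equality on atom_name, residue_id and chain_id.  All of `src`'s
#' conformations are appended after `dst`'s; metadata is taken from `dst`.
#'
#' @param dst,src `mc_structure` objects with identical point ordering.
#' @return `mc_structure` with `n_conformations(dst) + n_conformations(src)`
#'   conformations.
#' @export
append_conformation <- function(dst, src) {
  if (n_points(dst) != n_points(src))
    mc_error("mc_alignment_error", sprintf(
      "point counts differ: %d vs %d", n_points(dst), n_points(src)))
  key <- c("atom_name", "residue_id", "chain_id")
  a <- do.call(paste, c(lapply(dst$metadata[key], as.character), sep = "/"))
  b <- do.call(paste, c(lapply(src$metadata[key], as.character), sep = "/"))
  if (any(a != b)) {
    i <- which(a != b)[1]
    mc_error("mc_alignment_error", sprintf(
      "metadata mismatch at point %d: %s vs %s", i, a[i], b[i]))
  }
  m1 <- n_conformations(dst); m2 <- n_conformations(src); n <- n_points(dst)
  coords <- array(NA_real_, dim = c(m1 + m2, n, 3))
  coords[seq_len(m1), , ] <- dst$coordinates
  coords[m1 + seq_len(m2), , ] <- src$coordinates
  dst$coordinates <- coords
  dst
}
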
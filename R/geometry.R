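# Rigid-body geometry: transforms, least-squares superposition (SVD method
# restricted to proper rotations), RMSD/RMSF and basic distance measures.

#' Construct a rigid-body transform
#'
#' A rotation (3x3 orthonormal, determinant +1) plus a translation (Angstrom).
#' Applied to a point as `R x + t`.
#'
#' @param rotation 3x3 proper-rotation matrix (orthonormality checked to 1e-9).
#' @param translation length-3 numeric vector, Angstrom.
#' @return object of class `mc_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3, 3)) || length(translation) != 3)
    mc_error("mc_transform_error", "rotation must be 3x3, translation length 3")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9)
    mc_error("mc_transform_error",
             "rotation must be orthonormal with determinant +1")
  structure(list(rotation = rotation, translation = translation),
            class = "mc_transform")
}

#' @export
print.mc_transform <- function(x, ...) {
  cat("<mc_transform>\nrotation:\n")
  print(round(x$rotation, 6))
  cat("translation:", paste(round(x$translation, 6), collapse = " "), "\n")
  invisible(x)
}

# Apply a transform to an N x 3 coordinate matrix.
transform_xyz <- function(xyz, t) {
  sweep(xyz %*% t(t$rotation), 2, t$translation, "+")
}

#' Compose two rigid transforms
#'
#' `compose_transforms(a, b)` is the transform equivalent to applying `b`
#' first, then `a`.
#' @param a,b `mc_transform` objects.
#' @return `mc_transform`.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param t an `mc_transform`.
#' @return the inverse `mc_transform`.
#' @export
invert_transform <- function(t) {
  rigid_transform(t(t$rotation), as.numeric(-t(t$rotation) %*% t$translation))
}

#' Apply a rigid transform to a structure
#'
#' Coordinates of the affected conformation(s) are replaced by `R x + t`;
#' all intra-conformation pairwise distances are preserved (isometry).
#'
#' @param s an `mc_structure`.
#' @param t an `mc_transform`.
#' @param conformation a conformation index, or `"all"`.
#' @return the transformed `mc_structure` (the input is untouched).
#' @export
apply_transform <- function(s, t, conformation = "all") {
  if (!inherits(t, "mc_transform"))
    t <- rigid_transform(t$rotation, t$translation)
  confs <- if (identical(conformation, "all")) seq_len(n_conformations(s))
           else as.integer(conformation)
  if (any(confs < 1 | confs > n_conformations(s)))
    mc_error("mc_value_error", "conformation index out of range")
  for (m in confs)
    s <- set_coordinates(s, transform_xyz(get_coordinates(s, m), t), m)
  s
}

#' Optimal rigid superposition of one structure onto another
#'
#' Least-squares fit by the SVD method, restricted to proper rotations
#' (determinant sign correction), so mirror fits are never returned.
#' The fit runs over the selected points of the current conformations.
#'
#' @param mobile,target `mc_structure` objects.
#' @param subset unquoted metadata predicate restricting the fitted points
#'   (applied to both structures); default all points.
#' @param indices explicit point indices (alternative to `subset`).
#' @return a list with `transform` (the `mc_transform` mapping mobile onto
#'   target) and `rmsd` (post-superposition RMSD over the selection, Angstrom).
#' @export
superpose <- function(mobile, target, subset = NULL, indices = NULL) {
  sub <- substitute(subset)
  env <- parent.frame()
  ia <- resolve_selection(mobile, sub, indices, env)
  ib <- resolve_selection(target, sub, indices, env)
  if (length(ia) != length(ib))
    mc_error("mc_size_error", sprintf(
      "selection sizes differ: %d vs %d", length(ia), length(ib)))
  if (length(ia) < 3)
    mc_error("mc_underdetermined_error",
             "superposition needs at least 3 points")
  P <- get_coordinates(mobile)[ia, , drop = FALSE]
  Q <- get_coordinates(target)[ib, , drop = FALSE]
  p0 <- colMeans(P); q0 <- colMeans(Q)
  Pc <- sweep(P, 2, p0); Qc <- sweep(Q, 2, q0)
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- rigid_transform(R, q0 - as.numeric(R %*% p0))
  fitted <- transform_xyz(P, tr)
  list(transform = tr, rmsd = sqrt(mean(rowSums((fitted - Q)^2))))
}

#' Root-mean-square deviation between two structures
#'
#' RMSD over the selected points of the current conformations, optionally
#' after optimal superposition, optionally mass-weighted.
#'
#' @param a,b `mc_structure` objects with equal selected point counts.
#' @param subset unquoted metadata predicate (applied to both).
#' @param indices explicit point indices (alternative to `subset`).
#' @param superpose_first superpose `a` onto `b` before measuring?
#' @param mass_weighted weight squared deviations by atom mass?
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b, subset = NULL, indices = NULL,
                 superpose_first = FALSE, mass_weighted = FALSE) {
  sub <- substitute(subset)
  env <- parent.frame()
  ia <- resolve_selection(a, sub, indices, env)
  ib <- resolve_selection(b, sub, indices, env)
  if (length(ia) != length(ib))
    mc_error("mc_size_error", sprintf(
      "selection sizes differ: %d vs %d", length(ia), length(ib)))
  P <- get_coordinates(a)[ia, , drop = FALSE]
  Q <- get_coordinates(b)[ib, , drop = FALSE]
  if (superpose_first) {
    p0 <- colMeans(P); q0 <- colMeans(Q)
    Pc <- sweep(P, 2, p0); Qc <- sweep(Q, 2, q0)
    sv <- svd(crossprod(Pc, Qc))
    d <- sign(det(sv$v %*% t(sv$u)))
    R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
    P <- sweep(Pc %*% t(R), 2, q0, "+")
  }
  sq <- rowSums((P - Q)^2)
  if (mass_weighted) {
    w <- a$metadata$mass[ia]
    if (sum(w) <= 0) mc_error("mc_mass_error", "total selected mass is zero")
    sqrt(sum(w * sq) / sum(w))
  } else sqrt(mean(sq))
}

#' Root-mean-square fluctuation per point
#'
#' For each point, the square root of the mean squared displacement from its
#' mean position across all M conformations.  A single conformation yields
#' zeros.  Values are invariant under one rigid transform applied to every
#' conformation identically.
#'
#' @param s an `mc_structure`.
#' @return numeric vector of length N, Angstrom.
#' @export
rmsf <- function(s) {
  m <- n_conformations(s)
  mean_pos <- apply(s$coordinates, c(2, 3), mean)
  dev2 <- sweep(s$coordinates, c(2, 3), mean_pos)^2
  sqrt(apply(dev2, 2, sum) / m)
}

#' Mass-weighted centre of mass
#'
#' @param s an `mc_structure`.
#' @param subset unquoted metadata predicate; default all points.
#' @param indices explicit point indices.
#' @return length-3 numeric vector (Angstrom), over the current conformation.
#' @export
center_of_mass <- function(s, subset = NULL, indices = NULL) {
  idx <- resolve_selection(s, substitute(subset), indices, parent.frame())
  w <- s$metadata$mass[idx]
  if (sum(w) <= 0)
    mc_error("mc_mass_error", "total selected mass must be > 0")
  xyz <- get_coordinates(s)[idx, , drop = FALSE]
  as.numeric(colSums(xyz * w) / sum(w))
}

#' Euclidean distance matrix between two structures
#'
#' @param a,b `mc_structure` objects; distances use current conformations.
#' @return an `n_points(a) x n_points(b)` matrix, Angstrom.
#' @export
distance_matrix <- function(a, b = a) {
  P <- get_coordinates(a); Q <- get_coordinates(b)
  d2 <- outer(rowSums(P^2), rep(1, nrow(Q))) +
    outer(rep(1, nrow(P)), rowSums(Q^2)) - 2 * tcrossprod(P, Q)
  sqrt(pmax(d2, 0))
}
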
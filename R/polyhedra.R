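# Regular (Platonic) polyhedra used as deformable assembly scaffolds:
# vertices centred on the origin, edges defined by minimum pairwise distance,
# uniformly rescaled to the requested edge length.

platonic_vertices <- function(kind) {
  phi <- (1 + sqrt(5)) / 2
  switch(kind,
    tetrahedron = rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)),
    cube = as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))),
    octahedron = rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                       c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)),
    icosahedron = {
      v <- rbind(c(0, 1, phi), c(0, 1, -phi), c(0, -1, phi), c(0, -1, -phi))
      rbind(v, v[, c(3, 1, 2)], v[, c(2, 3, 1)])
    },
    dodecahedron = {
      cube8 <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
      v <- rbind(c(0, 1 / phi, phi), c(0, 1 / phi, -phi),
                 c(0, -1 / phi, phi), c(0, -1 / phi, -phi))
      rbind(cube8, v, v[, c(3, 1, 2)], v[, c(2, 3, 1)])
    },
    mc_error("mc_kind_error", paste0("unknown polyhedron kind: ", kind))
  )
}

.polyhedron_vertex_count <- c(tetrahedron = 4L, cube = 8L, octahedron = 6L,
                              dodecahedron = 20L, icosahedron = 12L)

#' Construct a regular polyhedron scaffold
#'
#' Vertices are centred on the origin and uniformly scaled so every edge has
#' the requested length; edges connect nearest-neighbour vertex pairs.  The
#' scaffold is "deformable" in the sense that it can be rescaled
#' ([scale_scaffold()]) while subunits stay aligned to its vertices.
#'
#' @param kind one of `"tetrahedron"`, `"cube"`, `"octahedron"`,
#'   `"dodecahedron"`, `"icosahedron"`.
#' @param edge_length edge length, Angstrom (> 0).
#' @return object of class `mc_polyhedron` with `vertices` (V x 3) and
#'   `edges` (E x 2 vertex index pairs).
#' @export
make_polyhedron <- function(kind, edge_length = 1) {
  if (!is.character(kind) || !(kind %in% names(.polyhedron_vertex_count)))
    mc_error("mc_kind_error", paste0("unknown polyhedron kind: ", kind))
  if (edge_length <= 0)
    mc_error("mc_value_error", "edge_length must be > 0")
  v <- unname(platonic_vertices(kind))
  v <- sweep(v, 2, colMeans(v))
  dm <- as.matrix(stats::dist(v))
  diag(dm) <- Inf
  base_edge <- min(dm)
  pairs <- which(dm <= base_edge * (1 + 1e-9) & upper.tri(dm), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  v <- v * (edge_length / base_edge)
  structure(list(kind = kind, edge_length = edge_length,
                 vertices = v, edges = unname(pairs)),
            class = "mc_polyhedron")
}

#' @export
print.mc_polyhedron <- function(x, ...) {
  cat(sprintf("<mc_polyhedron> %s: %d vertices, %d edges of %.3g A\n",
              x$kind, nrow(x$vertices), nrow(x$edges), x$edge_length))
  invisible(x)
}

#' Rescale a polyhedron scaffold
#'
#' @param p an `mc_polyhedron`.
#' @param factor positive scale factor applied to vertices and edge length.
#' @return the rescaled `mc_polyhedron`.
#' @export
scale_scaffold <- function(p, factor) {
  if (!is.numeric(factor) || factor <= 0)
    mc_error("mc_value_error", "scale factor must be > 0")
  p$vertices <- p$vertices * factor
  p$edge_length <- p$edge_length * factor
  p
}

# Deterministic local frame at vertex i: z points from the vertex toward the
# scaffold centroid (origin), x toward the lowest-index edge neighbour
# (projected orthogonal to z; ties resolved by the index ordering itself),
# y completes a right-handed frame.  Columns of the returned matrix are the
# frame axes in world coordinates (local -> world rotation).
vertex_frame <- function(p, i) {
  v <- p$vertices[i, ]
  z <- unit(-v)
  nb <- sort(unique(c(p$edges[p$edges[, 1] == i, 2],
                      p$edges[p$edges[, 2] == i, 1])))
  x0 <- p$vertices[nb[1], ] - v
  x <- x0 - sum(x0 * z) * z
  x <- unit(x)
  y <- cross3(z, x)
  cbind(x, y, z)
}
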
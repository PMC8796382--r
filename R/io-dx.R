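# OpenDX scalar-field I/O ("gridpositions"/"gridconnections" dialect, text
# only).  Convention: `origin` is the CENTER of voxel (1,1,1) — the common
# molecular DX convention; off-by-half-voxel bugs are the main hazard when
# exchanging maps, so this is asserted in tests and documented here.

#' Construct a density map
#'
#' A regular axis-aligned 3D scalar grid.  `origin` is the position of the
#' center of the first voxel; `delta` holds the voxel edge lengths.
#' Voxel `(i, j, k)` (1-based) is centered at
#' `origin + (c(i, j, k) - 1) * delta`.
#'
#' @param values rank-3 numeric array of voxel values.
#' @param origin length-3 numeric, Angstrom.
#' @param delta length-3 positive numeric, Angstrom per voxel along each axis.
#' @return object of class `mc_density`.
#' @export
density_map <- function(values, origin = c(0, 0, 0), delta = c(1, 1, 1)) {
  if (!is.array(values) || length(dim(values)) != 3)
    mc_error("mc_value_error", "values must be a rank-3 array")
  origin <- as.numeric(origin); delta <- as.numeric(delta)
  if (length(origin) != 3 || length(delta) != 3 || any(delta <= 0))
    mc_error("mc_value_error", "origin/delta must be length 3, delta > 0")
  if (!all(is.finite(values)))
    mc_error("mc_value_error", "all map values must be finite")
  structure(list(values = values, origin = origin, delta = delta),
            class = "mc_density")
}

#' @export
print.mc_density <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<mc_density> %d x %d x %d grid, voxel %.3g x %.3g x %.3g A\n",
              d[1], d[2], d[3], x$delta[1], x$delta[2], x$delta[3]))
  cat(sprintf("  origin (%.3g, %.3g, %.3g), values in [%.4g, %.4g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' Voxel volume of a density map
#' @param d an `mc_density`.
#' @return volume of one voxel in cubic Angstrom.
#' @export
voxel_volume <- function(d) prod(d$delta)

#' Write a density map in OpenDX text format
#'
#' Standard "gridpositions counts / origin / delta / gridconnections / data
#' follows" layout, readable by common molecular-graphics software.  Data
#' ordering follows the DX convention: the last (z) axis varies fastest.
#'
#' @param d an `mc_density`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dx <- function(d, path) {
  dims <- dim(d$values)
  header <- c(
    "# OpenDX scalar field written by molcloud",
    sprintf("object 1 class gridpositions counts %d %d %d",
            dims[1], dims[2], dims[3]),
    sprintf("origin %.6e %.6e %.6e", d$origin[1], d$origin[2], d$origin[3]),
    sprintf("delta %.6e 0.000000e+00 0.000000e+00", d$delta[1]),
    sprintf("delta 0.000000e+00 %.6e 0.000000e+00", d$delta[2]),
    sprintf("delta 0.000000e+00 0.000000e+00 %.6e", d$delta[3]),
    sprintf("object 2 class gridconnections counts %d %d %d",
            dims[1], dims[2], dims[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(dims))
  )
  # z varies fastest: permute to (z, y, x) so column-major flattening
  # enumerates z first.
  flat <- as.vector(aperm(d$values, c(3, 2, 1)))
  pad <- (-length(flat)) %% 3
  if (pad > 0) flat <- c(flat, rep(NA_real_, pad))
  rows <- matrix(flat, ncol = 3, byrow = TRUE)
  data_lines <- apply(rows, 1, function(v)
    paste(sprintf("%.6e", v[!is.na(v)]), collapse = " "))
  footer <- c('object "density" class field')
  writeLines(c(header, data_lines, footer), path)
  invisible(path)
}

#' Read an OpenDX scalar field
#'
#' Supports the "gridpositions" dialect with axis-aligned (diagonal) delta
#' vectors; skewed grids are rejected.  `origin` is interpreted as the center
#' of the first voxel.
#'
#' @param path path to a text OpenDX file.
#' @return an `mc_density`.
#' @export
read_dx <- function(path) {
  if (!file.exists(path))
    mc_error("mc_io_error", paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(trimws(lines), "#")]
  gp <- grep("class gridpositions counts", lines, value = TRUE)
  if (length(gp) == 0)
    mc_error("mc_format_error", "no gridpositions object found")
  counts <- as.integer(tail(strsplit(trimws(gp[1]), "\\s+")[[1]], 3))
  if (length(counts) != 3 || any(is.na(counts)) || any(counts < 1))
    mc_error("mc_format_error", "bad gridpositions counts")
  origin_line <- grep("^\\s*origin\\s", lines, value = TRUE)
  if (length(origin_line) == 0)
    mc_error("mc_format_error", "no origin line found")
  origin <- as.numeric(strsplit(trimws(origin_line[1]), "\\s+")[[1]][2:4])
  delta_lines <- grep("^\\s*delta\\s", lines, value = TRUE)
  if (length(delta_lines) != 3)
    mc_error("mc_format_error", "expected exactly 3 delta lines")
  dmat <- t(vapply(delta_lines, function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]][2:4]), numeric(3)))
  if (max(abs(dmat - diag(diag(dmat)))) > 1e-12)
    mc_error("mc_unsupported_grid_error",
             "non-orthogonal (skewed) delta vectors are not supported")
  delta <- diag(dmat)
  data_start <- grep("data follows", lines)
  if (length(data_start) == 0)
    mc_error("mc_format_error", "no 'data follows' marker")
  items_tok <- strsplit(trimws(lines[data_start[1]]), "\\s+")[[1]]
  n_items <- as.integer(items_tok[which(items_tok == "items") + 1])
  body <- lines[seq(data_start[1] + 1, length(lines))]
  body <- body[!grepl("^\\s*(object|attribute|component)\\b", body)]
  vals <- suppressWarnings(as.numeric(unlist(strsplit(trimws(body), "\\s+"))))
  vals <- vals[!is.na(vals)]
  if (length(vals) < prod(counts) ||
      (!is.na(n_items) && n_items != prod(counts)))
    mc_error("mc_truncation_error", sprintf(
      "expected %d values, found %d", prod(counts), length(vals)))
  vals <- vals[seq_len(prod(counts))]
  # inverse of the writer's ordering: z fastest.
  values <- aperm(array(vals, dim = rev(counts)), c(3, 2, 1))
  density_map(values, origin, delta)
}
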
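# Fixed-column multi-model PDB reader/writer.  ATOM and HETATM records are
# parsed; ANISOU/CONECT are ignored; MODEL/ENDMDL blocks become alternative
# conformations.  altLoc: the first encountered location per atom is kept
# (with a warning).  Insertion codes are retained in the `insertion` column.

parse_pdb_atoms <- function(lines) {
  f <- function(from, to) trimws(substring(lines, from, to))
  data.frame(
    atom_name = f(13, 16),
    altloc = f(17, 17),
    residue_name = f(18, 20),
    chain_id = f(22, 22),
    residue_id = as.integer(f(23, 26)),
    insertion = f(27, 27),
    x = as.numeric(substring(lines, 31, 38)),
    y = as.numeric(substring(lines, 39, 46)),
    z = as.numeric(substring(lines, 47, 54)),
    occupancy = suppressWarnings(as.numeric(f(55, 60))),
    beta = suppressWarnings(as.numeric(f(61, 66))),
    element = f(77, 78),
    stringsAsFactors = FALSE
  )
}

#' Read a (multi-model) PDB file
#'
#' Each MODEL/ENDMDL block becomes one conformation; files without MODEL
#' records give M = 1.  Metadata (atom_name, residue_name, residue_id,
#' insertion code, chain_id, element, occupancy, beta) is populated from the
#' fixed columns; when the element field is blank it is inferred from the
#' atom name.  Masses and van der Waals radii come from the internal element
#' table (unknown elements: mass 0, radius 1.7 A, with a warning).  Where an
#' atom carries alternate locations only the first is kept, with a warning.
#'
#' @param path path to a PDB file with at least one ATOM/HETATM record.
#' @return an `mc_structure` with `current = 1`.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path))
    mc_error("mc_io_error", paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  rec <- substring(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  is_model <- startsWith(lines, "MODEL")
  if (!any(is_atom))
    mc_error("mc_empty_error", paste0("no ATOM/HETATM records in ", path))
  model_id <- cumsum(is_model)
  model_id <- pmax(model_id, 1L)
  atoms <- parse_pdb_atoms(lines[is_atom])
  atoms$model <- model_id[is_atom]

  # altLoc handling: keep the first encountered location per atom.
  if (any(nzchar(atoms$altloc))) {
    key <- paste(atoms$model, atoms$chain_id, atoms$residue_id,
                 atoms$insertion, atoms$atom_name, sep = "|")
    keep <- !duplicated(key)
    if (!all(keep))
      warning("alternate locations found: keeping the first altLoc per atom",
              call. = FALSE)
    atoms <- atoms[keep, , drop = FALSE]
  }

  models <- split(seq_len(nrow(atoms)), atoms$model)
  counts <- vapply(models, length, integer(1))
  if (length(unique(counts)) > 1) {
    bad <- names(counts)[counts != counts[1]][1]
    mc_error("mc_model_mismatch_error", sprintf(
      "model %s has %d atoms but model %s has %d",
      bad, counts[[bad]], names(counts)[1], counts[[1]]))
  }
  n <- counts[[1]]
  m <- length(models)
  coords <- array(NA_real_, dim = c(m, n, 3))
  for (k in seq_len(m)) {
    rows <- atoms[models[[k]], ]
    coords[k, , ] <- cbind(rows$x, rows$y, rows$z)
  }
  first <- atoms[models[[1]], ]
  element <- ifelse(nzchar(first$element), toupper(first$element),
                    infer_element(first$atom_name))
  props <- element_properties(element)
  meta <- data.frame(
    atom_name = first$atom_name,
    residue_name = first$residue_name,
    residue_id = first$residue_id,
    insertion = first$insertion,
    chain_id = first$chain_id,
    element = element,
    mass = props$mass,
    vdw_radius = props$vdw_radius,
    occupancy = ifelse(is.na(first$occupancy), 1, first$occupancy),
    beta = ifelse(is.na(first$beta), 0, first$beta),
    stringsAsFactors = FALSE
  )
  mc_structure(coords, meta, current = 1L)
}

format_atom_line <- function(serial, meta, xyz) {
  name <- meta$atom_name
  name <- if (nchar(name) < 4) sprintf(" %-3s", name) else substr(name, 1, 4)
  sprintf("ATOM  %5d %4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial %% 100000, name, substr(meta$residue_name, 1, 3),
          substr(paste0(meta$chain_id, " "), 1, 1),
          meta$residue_id %% 10000,
          substr(paste0(meta$insertion, " "), 1, 1),
          xyz[1], xyz[2], xyz[3], meta$occupancy, meta$beta,
          substr(paste0(meta$element, " "), 1, 2))
}

#' Write a structure as a (multi-model) PDB file
#'
#' Fixed-width ATOM records; coordinates at 3 decimals, occupancy/beta at 2;
#' atom serials sequential from 1 within each model; TER after each chain;
#' multiple conformations are wrapped in MODEL/ENDMDL blocks.
#'
#' @param s an `mc_structure`.
#' @param path output path.
#' @param conformations `"all"` (default) or a vector of conformation indices.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path, conformations = "all") {
  if (n_points(s) == 0)
    mc_error("mc_empty_error", "cannot write an empty structure")
  confs <- if (identical(conformations, "all")) seq_len(n_conformations(s))
           else as.integer(conformations)
  if (any(confs < 1 | confs > n_conformations(s)))
    mc_error("mc_value_error", "conformation index out of range")
  if (max(abs(s$coordinates[confs, , , drop = FALSE])) >= 1e4)
    mc_error("mc_overflow_error",
             "coordinates >= 10^4 A cannot be represented in fixed columns")
  multi <- length(confs) > 1
  out <- character(0)
  for (m in confs) {
    if (multi) out <- c(out, sprintf("MODEL     %4d", match(m, confs)))
    xyz <- get_coordinates(s, m)
    serial <- 0L
    for (i in seq_len(n_points(s))) {
      serial <- serial + 1L
      out <- c(out, format_atom_line(serial, s$metadata[i, ], xyz[i, ]))
      last_of_chain <- i == n_points(s) ||
        s$metadata$chain_id[i + 1] != s$metadata$chain_id[i]
      if (last_of_chain) {
        serial <- serial + 1L
        out <- c(out, sprintf("TER   %5d      %-3s %1s%4d",
                              serial %% 100000,
                              substr(s$metadata$residue_name[i], 1, 3),
                              substr(paste0(s$metadata$chain_id[i], " "), 1, 1),
                              s$metadata$residue_id[i] %% 10000))
      }
    }
    if (multi) out <- c(out, "ENDMDL")
  }
  out <- c(out, "END")
  writeLines(out, path)
  invisible(path)
}
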
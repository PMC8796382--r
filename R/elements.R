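# Internal element table: monoisotopic-average masses (Da) and van der Waals
# radii (Angstrom) for the elements routinely found in protein structures.
# Unknown elements degrade gracefully: mass 0, radius 1.7 A, with a warning.

.element_table <- data.frame(
  element = c("H", "C", "N", "O", "S", "P"),
  mass = c(1.008, 12.011, 14.007, 15.999, 32.06, 30.974),
  vdw_radius = c(1.20, 1.70, 1.55, 1.52, 1.80, 1.80),
  stringsAsFactors = FALSE
)

.fallback_mass <- 0
.fallback_vdw <- 1.7

#' Element masses and van der Waals radii
#'
#' Look up mass (Da) and van der Waals radius (A) for element symbols.
#' Elements outside the internal table (H, C, N, O, S, P) fall back to mass 0
#' and radius 1.7 A with a warning, so nonstandard records degrade gracefully
#' instead of failing.
#'
#' @param element character vector of element symbols (case-insensitive).
#' @return data.frame with columns `mass` and `vdw_radius`, one row per input.
#' @examples
#' element_properties(c("C", "N"))
#' @export
element_properties <- function(element) {
  el <- toupper(trimws(as.character(element)))
  idx <- match(el, .element_table$element)
  unknown <- unique(el[is.na(idx) & nzchar(el)])
  if (length(unknown) > 0) {
    warning("unknown element(s) ", paste(unknown, collapse = ", "),
            ": assigned mass 0 Da and vdW radius 1.7 A", call. = FALSE)
  }
  data.frame(
    mass = ifelse(is.na(idx), .fallback_mass, .element_table$mass[idx]),
    vdw_radius = ifelse(is.na(idx), .fallback_vdw, .element_table$vdw_radius[idx])
  )
}

# Infer an element symbol from a PDB atom name ("CA" -> C, "1HB" -> H,
# " FE " left to the explicit element field).  Strips digits and primes,
# then takes the first letter.
infer_element <- function(atom_name) {
  nm <- gsub("[0-9' ]", "", toupper(atom_name))
  ifelse(nzchar(nm), substr(nm, 1, 1), "")
}
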
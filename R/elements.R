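#' Element lookup tables
#'
#' Standard atomic weights (amu) and Bondi van der Waals radii (Angstrom)
#' for the elements the package recognises.  Both tables are consulted by
#' [compute_mw()] and [build_common_box()]; unknown elements raise an error
#' naming the offending symbol.
#'
#' @return A tibble with columns `element`, `mass` (amu) and `r_vdw`
#'   (Angstrom).
#' @export
#' @examples
#' element_table()
element_table <- function() {
  tibble::tribble(
    ~element, ~mass,    ~r_vdw,
    "H",       1.008,   1.20,
    "He",      4.0026,  1.40,
    "Li",      6.94,    1.82,
    "B",      10.811,   1.92,
    "C",      12.011,   1.70,
    "N",      14.007,   1.55,
    "O",      15.999,   1.52,
    "F",      18.998,   1.47,
    "Na",     22.990,   2.27,
    "Mg",     24.305,   1.73,
    "Si",     28.086,   2.10,
    "P",      30.974,   1.80,
    "S",      32.06,    1.80,
    "Cl",     35.45,    1.75,
    "K",      39.098,   2.75,
    "Ca",     40.078,   2.31,
    "Zn",     65.38,    1.39,
    "Se",     78.971,   1.90,
    "Br",     79.904,   1.85,
    "I",     126.904,   1.98
  )
}

# fast lookups; error names the first unknown symbol
element_property <- function(elements, what = c("mass", "r_vdw")) {
  what <- match.arg(what)
  tab <- element_table()
  idx <- match(elements, tab$element)
  if (anyNA(idx)) {
    bad <- unique(elements[is.na(idx)])
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  tab[[what]][idx]
}

# Bohr radius in Angstrom, used by the cube reader/writer
.bohr_to_angstrom <- 0.529177
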
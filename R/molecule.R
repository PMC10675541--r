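#' Construct a molecule
#'
#' A molecule is an ordered set of atoms (element symbol, Cartesian
#' coordinates in Angstrom, partial charge in elementary charge units e)
#' plus an identifier, a molecular weight and an optional pIC50 activity.
#' The molecular weight is always recomputed from the tabulated standard
#' atomic weights so it stays consistent with the atom list.
#'
#' @param id Molecule identifier (e.g. a PubChem CID), coerced to character.
#' @param atoms Data frame with columns `element`, `x`, `y`, `z`, `charge`.
#' @param pic50 Optional activity, the negative decadic logarithm of the
#'   molar IC50.  `NA` when unknown.
#' @return An object of class `molecule`: a list with elements `id`,
#'   `atoms` (tibble), `mw` (amu) and `pic50`.
#' @export
#' @examples
#' water <- molecule("water", tibble::tibble(
#'   element = c("O", "H", "H"),
#'   x = c(0, 0.96, -0.24), y = c(0, 0, 0.93), z = c(0, 0, 0),
#'   charge = c(-0.66, 0.33, 0.33)))
#' water$mw
molecule <- function(id, atoms, pic50 = NA_real_) {
  atoms <- tibble::as_tibble(atoms)
  required <- c("element", "x", "y", "z", "charge")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    stop("atoms table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(atoms) < 1) stop("a molecule needs at least one atom", call. = FALSE)
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(coords))) {
    stop("non-finite atomic coordinates in molecule ", id, call. = FALSE)
  }
  if (!all(is.finite(atoms$charge))) {
    stop("non-finite partial charges in molecule ", id, call. = FALSE)
  }
  mol <- structure(
    list(
      id = as.character(id),
      atoms = atoms[, required],
      mw = sum(element_property(atoms$element, "mass")),
      pic50 = as.numeric(pic50)
    ),
    class = "molecule"
  )
  mol
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule %s: %d atoms, MW %.2f amu, pIC50 %s, net charge %+.3f e>\n",
              x$id, nrow(x$atoms), x$mw,
              if (is.na(x$pic50)) "NA" else sprintf("%.2f", x$pic50),
              sum(x$atoms$charge)))
  invisible(x)
}

#' Molecular weight from tabulated atomic masses
#'
#' Sums the standard atomic weights of a molecule's atoms.  The result is
#' invariant under any permutation of the atom order.
#'
#' @param molecule A [molecule()] object.
#' @return Molecular weight in amu.
#' @export
compute_mw <- function(molecule) {
  stopifnot(inherits(molecule, "molecule"))
  sum(element_property(molecule$atoms$element, "mass"))
}

# coordinate matrix (n x 3) of a molecule
atom_coords <- function(molecule) {
  as.matrix(molecule$atoms[, c("x", "y", "z")])
}

# replace coordinates, keeping everything else
set_atom_coords <- function(molecule, coords) {
  molecule$atoms$x <- coords[, 1]
  molecule$atoms$y <- coords[, 2]
  molecule$atoms$z <- coords[, 3]
  molecule
}

#' Summarise a list of molecules as a tibble
#'
#' @param molecules List of [molecule()] objects.
#' @return Tibble with one row per molecule: `id`, `mw`, `pic50`, `n_atoms`.
#' @export
molecule_table <- function(molecules) {
  tibble::tibble(
    id = purrr::map_chr(molecules, "id"),
    mw = purrr::map_dbl(molecules, "mw"),
    pic50 = purrr::map_dbl(molecules, "pic50"),
    n_atoms = purrr::map_int(molecules, ~ nrow(.x$atoms))
  )
}

# per-axis van der Waals extent [min, max] of a molecule
vdw_extent <- function(molecule) {
  coords <- atom_coords(molecule)
  r <- element_property(molecule$atoms$element, "r_vdw")
  rbind(lo = apply(coords - r, 2, min), hi = apply(coords + r, 2, max))
}

# center of the vdW bounding box
vdw_center <- function(molecule) {
  colMeans(vdw_extent(molecule))
}

# rigid translation
translate_molecule <- function(molecule, shift) {
  set_atom_coords(molecule, sweep(atom_coords(molecule), 2, shift, "+"))
}
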
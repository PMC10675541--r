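#' Read a Gaussian cube file as a scalar field
#'
#' Follows the standard cube conventions: positive voxel counts mean the
#' axis vectors are in Bohr (converted to Angstrom on read), negative
#' counts mean Angstrom.  Only axis-aligned, isotropic cubes are accepted,
#' matching the package's uniform-grid model.
#'
#' @param path Path to a cube file.
#' @param kind Field kind to tag the result with.
#' @return A [scalar_field()].
#' @export
read_cube <- function(path, kind = c("density", "potential")) {
  kind <- match.arg(kind)
  lines <- readLines(path)
  num <- function(s) as.numeric(strsplit(trimws(s), "[[:space:]]+")[[1]])
  hdr <- num(lines[3])
  natoms <- abs(as.integer(hdr[1]))
  origin <- hdr[2:4]
  axes <- lapply(4:6, function(i) num(lines[i]))
  nv <- sapply(axes, function(a) as.integer(a[1]))
  vecs <- t(sapply(axes, function(a) a[2:4]))
  to_ang <- ifelse(nv > 0, .bohr_to_angstrom, 1)
  npoints <- abs(nv)
  # demand axis-aligned isotropic voxels
  step <- diag(vecs) * to_ang
  offdiag <- vecs - diag(diag(vecs))
  if (any(abs(offdiag) > 1e-10) || max(abs(step - step[1])) > 1e-8) {
    stop("only axis-aligned cubes with isotropic spacing are supported",
         call. = FALSE)
  }
  origin <- origin * to_ang[1]
  vals <- num(paste(lines[(7 + natoms):length(lines)], collapse = " "))
  if (length(vals) != prod(npoints)) {
    stop("cube data length ", length(vals),
         " does not match voxel counts (", prod(npoints), ")", call. = FALSE)
  }
  # cube stores z fastest; internal layout is x fastest
  arr <- aperm(array(vals, rev(npoints)), c(3, 2, 1))
  scalar_field(grid_spec(origin, step[1], npoints), arr, kind)
}

#' Write a scalar field as a Gaussian cube file
#'
#' Writes in Bohr units (positive voxel counts) with a single dummy atom
#' unless molecule atoms are supplied.  A write/read round trip reproduces
#' grid and values to better than 1e-6 relative.
#'
#' @param field A [scalar_field()].
#' @param path Output path.
#' @param molecule Optional [molecule()] whose atoms go into the header.
#' @return `path`, invisibly.
#' @export
write_cube <- function(field, path, molecule = NULL) {
  g <- field$grid
  b <- .bohr_to_angstrom
  n_at <- if (is.null(molecule)) 1L else nrow(molecule$atoms)
  hdr <- c(
    "espqsar scalar field",
    field$kind,
    sprintf("%5d %15.10f %15.10f %15.10f", n_at,
            g$origin[1] / b, g$origin[2] / b, g$origin[3] / b),
    sprintf("%5d %15.10f %15.10f %15.10f", g$npoints[1], g$spacing / b, 0, 0),
    sprintf("%5d %15.10f %15.10f %15.10f", g$npoints[2], 0, g$spacing / b, 0),
    sprintf("%5d %15.10f %15.10f %15.10f", g$npoints[3], 0, 0, g$spacing / b)
  )
  atom_lines <- if (is.null(molecule)) {
    sprintf("%5d %11.6f %11.6f %11.6f %11.6f", 1L, 0, 0, 0, 0)
  } else {
    zs <- match(molecule$atoms$element, element_table()$element)
    sprintf("%5d %11.6f %11.6f %11.6f %11.6f", zs, molecule$atoms$charge,
            molecule$atoms$x / b, molecule$atoms$y / b, molecule$atoms$z / b)
  }
  vals <- aperm(field$values, c(3, 2, 1))     # z fastest on disk
  vv <- sprintf("% .8E", as.vector(vals))
  rows <- split(vv, ceiling(seq_along(vv) / 6))
  writeLines(c(hdr, atom_lines, vapply(rows, paste, "", collapse = " ")), path)
  invisible(path)
}
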
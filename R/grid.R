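#' Uniform rectangular grid specification
#'
#' Defines a uniform, isotropic 3D grid by its origin (coordinates of the
#' first node, Angstrom), node spacing (Angstrom) and per-axis node counts.
#'
#' @param origin Numeric length-3: coordinates of node (1, 1, 1).
#' @param spacing Positive scalar node spacing, identical on all axes.
#' @param npoints Integer length-3: nodes per axis, each at least 2.
#' @return A `grid_spec` object.
#' @export
grid_spec <- function(origin, spacing, npoints) {
  stopifnot(length(origin) == 3, length(npoints) == 3)
  if (!is.finite(spacing) || spacing <= 0) stop("spacing must be > 0",
                                                call. = FALSE)
  npoints <- as.integer(npoints)
  if (any(npoints < 2)) stop("npoints must be >= 2 on every axis",
                             call. = FALSE)
  structure(list(origin = as.numeric(origin), spacing = spacing,
                 npoints = npoints),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec %dx%dx%d, spacing %.4g A, origin (%.3f, %.3f, %.3f)>\n",
              x$npoints[1], x$npoints[2], x$npoints[3], x$spacing,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Node coordinates of a grid
#'
#' `grid_axes()` returns the per-axis node coordinate vectors;
#' `grid_center()` the geometric center of the box.
#'
#' @param grid A [grid_spec()].
#' @return List of three numeric vectors, or a length-3 numeric.
#' @export
grid_axes <- function(grid) {
  lapply(1:3, function(a) grid$origin[a] + grid$spacing * (seq_len(grid$npoints[a]) - 1))
}

#' @rdname grid_axes
#' @export
grid_center <- function(grid) {
  grid$origin + grid$spacing * (grid$npoints - 1) / 2
}

# cell volume dV = spacing^3
grid_dv <- function(grid) grid$spacing^3

same_grid <- function(a, b, tol = 1e-9) {
  all(a$npoints == b$npoints) &&
    abs(a$spacing - b$spacing) < tol &&
    all(abs(a$origin - b$origin) < tol)
}

#' A scalar field on a uniform grid
#'
#' Holds a real-valued field (charge density in e/Angstrom^3 or
#' electrostatic potential in e/Angstrom under Coulomb constant 1) as a 3D
#' array whose dimensions follow the grid's node counts.
#'
#' @param grid A [grid_spec()].
#' @param values 3D numeric array matching `grid$npoints`, or a vector of
#'   the right length (filled x-fastest).
#' @param kind `"density"` or `"potential"`.
#' @return A `scalar_field` object.
#' @export
scalar_field <- function(grid, values, kind = c("density", "potential")) {
  kind <- match.arg(kind)
  if (is.null(dim(values))) {
    if (length(values) != prod(grid$npoints)) {
      stop("value count does not match the grid", call. = FALSE)
    }
    dim(values) <- grid$npoints
  }
  if (!all(dim(values) == grid$npoints)) {
    stop("value array dimensions do not match the grid", call. = FALSE)
  }
  if (!all(is.finite(values))) stop("non-finite field values", call. = FALSE)
  structure(list(grid = grid, kind = kind, values = values),
            class = "scalar_field")
}

#' @export
print.scalar_field <- function(x, ...) {
  cat(sprintf("<scalar_field (%s) on %dx%dx%d grid, range [%.3g, %.3g]>\n",
              x$kind, dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' Integrate a scalar field over the box
#'
#' @param field A [scalar_field()].
#' @return `sum(values) * dV`, e.g. the total charge of a density field.
#' @export
field_integral <- function(field) {
  sum(field$values) * grid_dv(field$grid)
}

#' Build the common grid box of a molecular subset
#'
#' Each edge of the box equals the largest van der Waals extent of any
#' member molecule along that axis plus a margin (appended once per axis),
#' mirroring the common-box construction used for template alignment.  The
#' node count per axis is `floor(edge / spacing) + 1` and the box is
#' centered on the coordinate origin.
#'
#' @param molecules List of [molecule()] objects (at least one).
#' @param spacing Node spacing in Angstrom (default 0.106, the alignment
#'   grid; the descriptor grid uses twice that).
#' @param margin Marginal distance appended to each edge, Angstrom
#'   (default 2.7).
#' @return A [grid_spec()].
#' @export
build_common_box <- function(molecules, spacing = 0.106, margin = 2.7) {
  if (length(molecules) == 0) stop("empty molecule list", call. = FALSE)
  if (margin < 0) stop("margin must be >= 0", call. = FALSE)
  extents <- sapply(molecules, function(m) {
    e <- vdw_extent(m)
    e["hi", ] - e["lo", ]
  })                                   # 3 x n_molecules
  edge <- apply(extents, 1, max) + margin
  # tiny slack keeps exact-ratio edges (e.g. 6.1 / 0.1) from rounding down
  npoints <- pmax(2L, as.integer(floor(edge / spacing + 1e-9)) + 1L)
  origin <- -(npoints - 1) * spacing / 2
  grid_spec(origin, spacing, npoints)
}

#' Heat-map of the central slice of a scalar field
#'
#' @param object A [scalar_field()].
#' @param axis Axis normal to the slice (3 = z).
#' @param index Slice index; defaults to the mid-plane.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method
autoplot.scalar_field <- function(object, axis = 3, index = NULL, ...) {
  np <- object$grid$npoints
  if (is.null(index)) index <- ceiling(np[axis] / 2)
  ax <- grid_axes(object$grid)
  keep <- setdiff(1:3, axis)
  sl <- switch(axis,
               object$values[index, , ],
               object$values[, index, ],
               object$values[, , index])
  df <- expand.grid(a = ax[[keep[1]]], b = ax[[keep[2]]])
  df$value <- as.vector(sl)
  labs <- c("x", "y", "z")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = paste0(labs[keep[1]], " (A)"),
                  y = paste0(labs[keep[2]], " (A)"),
                  fill = object$kind,
                  title = sprintf("%s, %s-slice %d", object$kind,
                                  labs[axis], index))
}
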
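#' Cross-correlation of a template ESP with a target density over all
#' integer grid translations
#'
#' Evaluates the field cross-correlation
#' \eqn{E(t) = \sum_x \phi(x)\,\rho(x + t)\,dV}
#' for every integer-cell shift t, using zero-padded (linear, not
#' circular) FFTs so that density never wraps across box faces.  The map
#' equals the direct triple-loop sum to near machine precision.
#'
#' @param phi_template [scalar_field()] holding the template potential.
#' @param rho_target [scalar_field()] holding the target density, on the
#'   same grid.
#' @return A `correlation_map`: list with `values` (array over shifts),
#'   `shifts` (per-axis integer shift vectors) and `dv`.
#' @export
cross_correlation_map <- function(phi_template, rho_target) {
  if (!same_grid(phi_template$grid, rho_target$grid)) {
    stop("template and target fields must share one grid", call. = FALSE)
  }
  np <- phi_template$grid$npoints
  dv <- grid_dv(phi_template$grid)
  pf <- fft_padded(phi_template$values, 2L * np)
  rf <- fft_padded(rho_target$values, 2L * np)
  corr_from_spectra(pf, rf, np, dv)
}

# zero-pad a real array to dims m and transform
fft_padded <- function(values, m) {
  np <- dim(values)
  pad <- array(0, m)
  pad[seq_len(np[1]), seq_len(np[2]), seq_len(np[3])] <- values
  fft(pad)
}

# correlation map from padded spectra: E(t) = ifft(conj(Phi) * Rho)
corr_from_spectra <- function(phi_fft, rho_fft, np, dv) {
  m <- dim(phi_fft)
  full <- Re(fft(Conj(phi_fft) * rho_fft, inverse = TRUE)) / prod(m)
  extract_shift_window(full, np, dv)
}

# reorder the circular correlation array into shifts -(n-1) .. (n-1)
extract_shift_window <- function(full, np, dv) {
  m <- dim(full)
  shifts <- lapply(1:3, function(a) (-(np[a] - 1)):(np[a] - 1))
  idx <- lapply(1:3, function(a) (shifts[[a]] %% m[a]) + 1L)
  structure(
    list(values = full[idx[[1]], idx[[2]], idx[[3]]] * dv,
         shifts = shifts, dv = dv),
    class = "correlation_map"
  )
}

#' @export
print.correlation_map <- function(x, ...) {
  pk <- corr_peak(x)
  cat(sprintf("<correlation_map over %s shifts; peak %.4g at (%d, %d, %d)>\n",
              paste(dim(x$values), collapse = "x"), pk$score,
              pk$shift[1], pk$shift[2], pk$shift[3]))
  invisible(x)
}

#' Peak of a correlation map
#'
#' Maximum score and its integer shift; exact score ties resolve to the
#' lexicographically smallest `(tx, ty, tz)`.
#'
#' @param map A `correlation_map`.
#' @return List with `score` and integer `shift` (length 3).
#' @export
corr_peak <- function(map) {
  mx <- max(map$values)
  cand <- which(map$values == mx, arr.ind = TRUE)
  sh <- cbind(map$shifts[[1]][cand[, 1]],
              map$shifts[[2]][cand[, 2]],
              map$shifts[[3]][cand[, 3]])
  pick <- order(sh[, 1], sh[, 2], sh[, 3])[1]
  list(score = mx, shift = as.integer(sh[pick, ]))
}

# are all atom centers inside the grid's physical box?
molecule_in_box <- function(molecule, grid) {
  coords <- atom_coords(molecule)
  lo <- grid$origin
  hi <- grid$origin + grid$spacing * (grid$npoints - 1)
  all(sweep(coords, 2, lo, ">=")) && all(sweep(coords, 2, hi, "<="))
}

# resample a density field under rotation q about the grid center:
# rho_rot(x) = rho(R^T (x - c) + c), trilinearly interpolated, 0 outside
rotate_density <- function(rho, q, pts_centered = NULL) {
  grid <- rho$grid
  cen <- grid_center(grid)
  if (is.null(pts_centered)) {
    ax <- grid_axes(grid)
    pts_centered <- sweep(
      as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]])), 2, cen)
  }
  R <- quat_to_matrix(q)
  src <- sweep(pts_centered %*% R, 2, cen, "+")   # pts %*% R == t(R^T %*% t(pts))
  scalar_field(grid, array(trilinear_sample(rho$values, grid, src),
                           grid$npoints), "density")
}

#' Find the best rigid alignment of a target to a template
#'
#' Exhaustive search over a sampled rotation set and all integer-cell grid
#' translations for the pose maximizing the cross-correlation between the
#' template's electrostatic potential and the target's charge density.
#' The template is pinned with its van der Waals bounding-box center at
#' the grid center and its potential is solved once; the target density is
#' computed once in a centered starting pose and re-sampled per rotamer by
#' trilinear interpolation.  Ties resolve to the lower rotamer index, then
#' the lexicographically smallest translation.
#'
#' @param template,target [molecule()] objects.
#' @param rotations A [hopf_rotations()] rotation set.
#' @param grid The common-box [grid_spec()] (see [build_common_box()]).
#' @param backend A density backend (default promolecule).
#' @param center_target Starting-pose policy for the target: `"auto"`
#'   (default) re-centers the target's van der Waals box on the grid
#'   center only when its given pose would clip the box, `"always"` and
#'   `"never"` force the choice.  The translation search absorbs any
#'   centering, so only the reported translation's frame is affected.
#' @return An `alignment_result`: list with `target_id`, `rotation` (unit
#'   quaternion), `rotamer` (1-based index into the rotation set, 1 =
#'   identity), `translation_cells` (integer), `translation` (Angstrom),
#'   `score` (E_ij, e^2/Angstrom x Angstrom^3) and the `aligned` molecule.
#' @export
best_alignment <- function(template, target, rotations, grid,
                           backend = promolecule_backend(),
                           center_target = c("auto", "always", "never")) {
  center_target <- match.arg(center_target)
  cen <- grid_center(grid)
  tpl <- translate_molecule(template, cen - vdw_center(template))
  phi <- solve_poisson(backend$density(tpl, grid))
  np <- grid$npoints
  m <- 2L * np
  dv <- grid_dv(grid)
  phi_fft <- fft_padded(phi$values, m)

  recenter <- switch(center_target,
    always = TRUE,
    never = FALSE,
    auto = !molecule_in_box(target, grid))
  tgt0 <- if (recenter) {
    translate_molecule(target, cen - vdw_center(target))
  } else {
    target
  }
  rho0 <- backend$density(tgt0, grid)
  abs_total <- sum(abs(rho0$values))
  ax <- grid_axes(grid)
  pts_centered <- sweep(
    as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]])), 2, cen)

  best <- list(score = -Inf, rotamer = NA_integer_, shift = c(0L, 0L, 0L))
  clipped <- 0
  consider <- function(r, corr_vals, rho_abs) {
    cmap <- extract_shift_window(corr_vals, np, dv)
    pk <- corr_peak(cmap)
    if (pk$score > best$score) {
      best <<- list(score = pk$score, rotamer = r, shift = pk$shift)
      clipped <<- 1 - rho_abs / abs_total
    }
  }
  # rotamers are processed in pairs packed into one complex FFT:
  # fft(rho_a + 1i * rho_b) is F_a + 1i F_b by linearity, and both
  # correlation maps are real, so Re/Im of one inverse transform
  # separate them again.  Ascending order keeps the tie-break exact.
  r <- 1L
  while (r <= rotations$count) {
    rho_a <- if (r == 1L) rho0 else
      rotate_density(rho0, rotations$quaternions[r, ], pts_centered)
    if (r + 1L <= rotations$count) {
      rho_b <- rotate_density(rho0, rotations$quaternions[r + 1L, ],
                              pts_centered)
      pad <- array(0i, m)
      pad[seq_len(np[1]), seq_len(np[2]), seq_len(np[3])] <-
        complex(real = rho_a$values, imaginary = rho_b$values)
      both <- fft(Conj(phi_fft) * fft(pad), inverse = TRUE) / prod(m)
      consider(r, Re(both), sum(abs(rho_a$values)))
      consider(r + 1L, Im(both), sum(abs(rho_b$values)))
      r <- r + 2L
    } else {
      one <- Re(fft(Conj(phi_fft) * fft_padded(rho_a$values, m),
                    inverse = TRUE)) / prod(m)
      consider(r, one, sum(abs(rho_a$values)))
      r <- r + 1L
    }
  }
  if (clipped > 0.05) {
    warning(sprintf(
      "best pose of %s loses %.1f%% of |density| outside the box",
      target$id, 100 * clipped), call. = FALSE)
  }
  q_best <- rotations$quaternions[best$rotamer, ]
  shift_ang <- best$shift * grid$spacing
  # winning pose: rotate the centered target about the grid center, then
  # translate by -t (rho is sampled at x + t, so the density moves by -t)
  aligned <- translate_molecule(rotate_molecule(tgt0, q_best, cen), -shift_ang)
  structure(
    list(target_id = target$id, rotation = q_best, rotamer = best$rotamer,
         translation_cells = as.integer(best$shift),
         translation = -shift_ang, score = best$score,
         clipped_fraction = clipped, aligned = aligned),
    class = "alignment_result"
  )
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf(
    "<alignment %s: rotamer %d, shift (%d, %d, %d) cells, E = %.5g>\n",
    x$target_id, x$rotamer, x$translation_cells[1], x$translation_cells[2],
    x$translation_cells[3], x$score))
  invisible(x)
}

#' Align every member of a subset to its template
#'
#' The template (highest molecular weight, see [select_template()]) is
#' pinned at the grid center; every other member is aligned pairwise with
#' [best_alignment()].  A failure for one molecule is reported and does
#' not abort the rest.
#'
#' @param subset Tibble with columns `id`, `mw` (one subset of a
#'   [partition_by_mw()] table).
#' @param molecules Named list of [molecule()] objects.
#' @param grid Common-box [grid_spec()].
#' @param rotations A [hopf_rotations()] set.
#' @param backend Density backend.
#' @return List with `template_id`, `log` (tibble: target_id, rotamer,
#'   tx, ty, tz, score) and `aligned` (named molecule list, template
#'   included in its pinned pose).
#' @export
align_subset <- function(subset, molecules, grid, rotations,
                         backend = promolecule_backend()) {
  template <- select_template(subset, molecules)
  cen <- grid_center(grid)
  tpl_pinned <- translate_molecule(template, cen - vdw_center(template))
  targets <- setdiff(subset$id, template$id)
  aligned <- stats::setNames(list(tpl_pinned), template$id)
  rows <- list()
  for (id in targets) {
    res <- tryCatch(
      best_alignment(template, molecules[[id]], rotations, grid, backend),
      error = function(e) {
        warning("alignment of ", id, " failed: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    if (is.null(res)) next
    aligned[[id]] <- res$aligned
    rows[[id]] <- tibble::tibble(
      target_id = id, rotamer = res$rotamer,
      tx = res$translation_cells[1], ty = res$translation_cells[2],
      tz = res$translation_cells[3], score = res$score)
  }
  list(template_id = template$id,
       log = if (length(rows)) dplyr::bind_rows(rows) else
         tibble::tibble(target_id = character(), rotamer = integer(),
                        tx = integer(), ty = integer(), tz = integer(),
                        score = numeric()),
       aligned = aligned)
}
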
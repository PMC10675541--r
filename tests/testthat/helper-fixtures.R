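# small fixtures built in code, shared across test files

atoms_tbl <- function(element, coords, charge) {
  tibble::tibble(element = element,
                 x = coords[, 1], y = coords[, 2], z = coords[, 3],
                 charge = charge)
}

water_molecule <- function(pic50 = NA_real_) {
  molecule("water", atoms_tbl(
    c("O", "H", "H"),
    rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0.05)),
    c(-0.66, 0.33, 0.33)), pic50 = pic50)
}

# single Gaussian charge sampled on a centered cubic grid
gaussian_density <- function(q = 1, sigma = 0.3, n = 64, spacing = 0.15,
                             center = c(0, 0, 0)) {
  g <- grid_spec(-(n - 1) * spacing / 2 + center * 0, spacing, rep(n, 3))
  ax <- grid_axes(g)
  r2 <- outer(outer((ax[[1]] - center[1])^2, (ax[[2]] - center[2])^2, "+"),
              (ax[[3]] - center[3])^2, "+")
  scalar_field(g, q * (2 * pi * sigma^2)^(-1.5) * exp(-r2 / (2 * sigma^2)),
               "density")
}

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

# direct-sum correlation oracle: E(t) = sum_x phi(x) rho(x + t) dV,
# zero outside the box; slow triple loop over shifts (vectorized inner)
brute_correlation <- function(phi, rho) {
  np <- phi$grid$npoints
  dv <- grid_dv(phi$grid)
  shifts <- lapply(1:3, function(a) (-(np[a] - 1)):(np[a] - 1))
  vals <- array(0, lengths(shifts))
  for (ix in seq_along(shifts[[1]])) {
    tx <- shifts[[1]][ix]
    xr <- max(1, 1 - tx):min(np[1], np[1] - tx)
    for (iy in seq_along(shifts[[2]])) {
      ty <- shifts[[2]][iy]
      yr <- max(1, 1 - ty):min(np[2], np[2] - ty)
      for (iz in seq_along(shifts[[3]])) {
        tz <- shifts[[3]][iz]
        zr <- max(1, 1 - tz):min(np[3], np[3] - tz)
        vals[ix, iy, iz] <- sum(
          phi$values[xr, yr, zr, drop = FALSE] *
            rho$values[xr + tx, yr + ty, zr + tz, drop = FALSE]) * dv
      }
    }
  }
  list(values = vals, shifts = shifts)
}

# a toy molecule pinned with its vdW-box center at the grid center,
# i.e. the same pose best_alignment pins the template in
pinned_toy <- function(seed, n_atoms, mw_target, grid) {
  mol <- make_toy_molecule(seed, n_atoms, mw_target)
  espqsar:::translate_molecule(
    mol, grid_center(grid) - espqsar:::vdw_center(mol))
}
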
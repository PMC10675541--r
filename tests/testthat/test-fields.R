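test_that("common box follows the vdW-extent-plus-margin rule", {
  # single carbon (Bondi r = 1.70): edge 2*1.7 + 2.7 = 6.1, 62 nodes at 0.1
  carbon <- molecule("C1", atoms_tbl("C", rbind(c(0, 0, 0)), 0))
  g <- build_common_box(list(carbon), spacing = 0.1, margin = 2.7)
  expect_equal(g$npoints, rep(62L, 3))
  # box centered on the coordinate origin
  expect_equal(grid_center(g), c(0, 0, 0), tolerance = 1e-12)

  # degenerate margin: edge = 2 r_vdw
  g0 <- build_common_box(list(carbon), spacing = 0.1, margin = 0)
  expect_equal(g0$npoints, rep(35L, 3))   # floor(3.4 / 0.1) + 1

  # monotone: adding a molecule never shrinks an edge
  big <- make_toy_molecule(5, 20, 400)
  g2 <- build_common_box(list(carbon, big), spacing = 0.1, margin = 2.7)
  expect_true(all(g2$npoints >= g$npoints))

  expect_error(build_common_box(list(), spacing = 0.1), "empty")
  expect_error(build_common_box(list(carbon), spacing = 0.1, margin = -1),
               "margin")
})

test_that("the study-scale descriptor grid has 106^3 = 1,191,016 nodes", {
  g <- grid_spec(c(0, 0, 0), 0.212, c(106, 106, 106))
  expect_identical(prod(g$npoints), 1191016)
  # stride-2 subsampling relation: descriptor nodes are alignment nodes
  ga <- grid_spec(c(-1, -1, -1), 0.106, c(211, 211, 211))
  gd <- descriptor_grid(ga)
  expect_equal(gd$spacing, 0.212)
  expect_equal(gd$npoints, rep(106L, 3))
  expect_true(all(grid_axes(gd)[[1]] %in% grid_axes(ga)[[1]]))
})

test_that("promolecule density integrates to the net charge", {
  # unit charge, sigma = 0.3 via a fictitious small-radius scaling
  one <- molecule("q1", atoms_tbl("C", rbind(c(0, 0, 0)), 1))
  g <- grid_spec(rep(-3.95, 3), 0.1, rep(80, 3))
  sigma_scale <- 0.3 / 1.70          # width_scale so sigma = 0.3 A
  rho <- promolecule_density(one, g, width_scale = sigma_scale)
  expect_equal(field_integral(rho), 1, tolerance = 0.01)

  # neutral dipole: total charge 0 to high accuracy
  dip <- molecule("dip", atoms_tbl(
    c("C", "C"), rbind(c(-0.5, 0, 0), c(0.5, 0, 0)), c(0.5, -0.5)))
  rho_d <- promolecule_density(dip, g, width_scale = sigma_scale)
  expect_equal(field_integral(rho_d), 0, tolerance = 1e-6)
})

test_that("density evaluation is pointwise: refinement keeps shared nodes", {
  mol <- make_toy_molecule(8, 10, 270)
  g1 <- grid_spec(rep(-6, 3), 0.5, rep(25, 3))
  g2 <- grid_spec(rep(-6, 3), 0.25, rep(49, 3))
  r1 <- suppressWarnings(promolecule_density(mol, g1))
  r2 <- suppressWarnings(promolecule_density(mol, g2))
  shared <- seq(1, 49, by = 2)
  expect_equal(r2$values[shared, shared, shared], r1$values,
               tolerance = 1e-12)
})

test_that("density truncation near a box face warns", {
  mol <- molecule("edge", atoms_tbl("C", rbind(c(-5.8, 0, 0)), 1))
  g <- grid_spec(rep(-6, 3), 0.5, rep(25, 3))
  expect_warning(promolecule_density(mol, g), "face")
})

test_that("Poisson solution matches the Gaussian-charge closed form", {
  # grid chosen so the nodes (0, 0, 0) and (2, 0, 0) exist exactly
  g <- grid_spec(rep(-4, 3), 0.125, rep(64, 3))
  ax <- grid_axes(g)
  r2g <- outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+")
  rho <- scalar_field(g, (2 * pi * 0.09)^(-1.5) * exp(-r2g / 0.18),
                      "density")
  phi <- solve_poisson(rho)
  r <- sqrt(r2g)
  exact <- ifelse(r < 1e-12, sqrt(2 / pi) / 0.3,
                  erf(r / (0.3 * sqrt(2))) / r)
  sel <- r >= 3 * 0.3
  expect_lt(max(abs(phi$values[sel] - exact[sel]) / abs(exact[sel])), 0.01)

  # phi at r = 2.0 is 0.500 within 1% (erf(4.71) is 1 to 8 digits)
  i <- which(abs(ax[[1]] - 2) < 1e-9)
  mid <- which(abs(ax[[1]]) < 1e-9)
  expect_equal(phi$values[i, mid, mid], 0.5, tolerance = 0.005)
})

test_that("Poisson solve is linear and translation-equivariant", {
  g <- grid_spec(rep(-3.1, 3), 0.2, rep(32, 3))
  ax <- grid_axes(g)
  gauss_at <- function(c0, q, s) {
    r2 <- outer(outer((ax[[1]] - c0[1])^2, (ax[[2]] - c0[2])^2, "+"),
                (ax[[3]] - c0[3])^2, "+")
    scalar_field(g, q * (2 * pi * s^2)^(-1.5) * exp(-r2 / (2 * s^2)),
                 "density")
  }
  r1 <- gauss_at(c(-0.8, 0, 0.4), 1, 0.3)
  r2 <- gauss_at(c(0.6, -0.4, 0), -0.7, 0.4)
  lhs <- solve_poisson(scalar_field(g, 2 * r1$values + 3 * r2$values,
                                    "density"))
  rhs <- 2 * solve_poisson(r1)$values + 3 * solve_poisson(r2)$values
  expect_lt(max(abs(lhs$values - rhs)) / max(abs(rhs)), 1e-8)

  # shifting rho by whole cells shifts phi identically (interior nodes)
  sh <- 3L
  shifted <- gauss_at(c(-0.8 + sh * 0.2, 0, 0.4), 1, 0.3)
  p0 <- solve_poisson(r1)$values
  p1 <- solve_poisson(shifted)$values
  inner <- (sh + 1):32
  expect_lt(max(abs(p1[inner, , ] - p0[inner - sh, , ])) / max(abs(p0)),
            1e-8)

  # zero density gives zero potential; non-finite input errors
  expect_equal(max(abs(solve_poisson(
    scalar_field(g, array(0, rep(32, 3)), "density"))$values)), 0)
  expect_error(scalar_field(g, array(NaN, rep(32, 3)), "density"),
               "finite")
})

test_that("two charges superpose: potential equals the sum of parts", {
  g <- grid_spec(rep(-3.1, 3), 0.2, rep(32, 3))
  ax <- grid_axes(g)
  gauss_at <- function(c0) {
    r2 <- outer(outer((ax[[1]] - c0[1])^2, (ax[[2]] - c0[2])^2, "+"),
                (ax[[3]] - c0[3])^2, "+")
    scalar_field(g, (2 * pi * 0.09)^(-1.5) * exp(-r2 / 0.18), "density")
  }
  a <- gauss_at(c(-0.9, 0, 0)); b <- gauss_at(c(0.9, 0.3, -0.3))
  both <- solve_poisson(scalar_field(g, a$values + b$values, "density"))
  apart <- solve_poisson(a)$values + solve_poisson(b)$values
  expect_lt(max(abs(both$values - apart)) / max(abs(apart)), 1e-8)
})

test_that("cube files round-trip and honor the Bohr convention", {
  g <- grid_spec(c(-0.7, -0.7, -0.7), 0.2, c(8, 8, 8))
  set.seed(12)
  f <- scalar_field(g, array(rnorm(512), rep(8, 3)), "density")
  path <- withr::local_tempfile(fileext = ".cube")
  write_cube(f, path)
  back <- read_cube(path)
  expect_equal(back$grid$spacing, g$spacing, tolerance = 1e-6)
  expect_equal(back$grid$origin, g$origin, tolerance = 1e-6)
  expect_lt(max(abs(back$values - f$values)) / max(abs(f$values)), 1e-6)
})

test_that("a hand-written cube parses literally", {
  # 2x2x2 voxels, Bohr axes (positive counts), values 1..8 with z fastest
  lines <- c(
    "comment", "comment",
    " 1  0.0 0.0 0.0",
    " 2  1.0 0.0 0.0",
    " 2  0.0 1.0 0.0",
    " 2  0.0 0.0 1.0",
    " 6  0.0 0.0 0.0 0.0",
    " 1 2 3", " 4 5 6", " 7 8")
  path <- withr::local_tempfile(fileext = ".cube")
  writeLines(lines, path)
  f <- read_cube(path)
  expect_equal(f$grid$spacing, 0.529177, tolerance = 1e-6)
  # file order x-outer/z-inner; internal layout x fastest
  expect_equal(f$values[1, 1, ], c(1, 2))
  expect_equal(f$values[1, 2, ], c(3, 4))
  expect_equal(f$values[2, 1, ], c(5, 6))
  expect_equal(f$values[2, 2, ], c(7, 8))

  # truncated data must error
  writeLines(lines[-9], path)
  expect_error(read_cube(path), "length")
})

test_that("trilinear resampling is exact for linear fields, any box shape", {
  # non-cubic grid: linear functions are reproduced exactly inside the box
  g <- grid_spec(c(-2, -2.5, -1.5), 0.5, c(9, 11, 7))
  ax <- grid_axes(g)
  lin <- outer(outer(2 * ax[[1]], 3 * ax[[2]], "+"), -ax[[3]], "+")
  set.seed(6)
  pts <- cbind(runif(200, -1.9, 1.9), runif(200, -2.4, 2.4),
               runif(200, -1.4, 1.4))
  got <- espqsar:::trilinear_sample(lin, g, pts)
  expect_equal(got, 2 * pts[, 1] + 3 * pts[, 2] - pts[, 3],
               tolerance = 1e-12)
  # far outside the support the interpolant is zero
  far <- rbind(c(10, 0, 0), c(0, -9, 0), c(0, 0, 8))
  expect_equal(espqsar:::trilinear_sample(lin, g, far), c(0, 0, 0))
})
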
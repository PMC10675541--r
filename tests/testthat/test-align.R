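test_that("Hopf rotation sets are deterministic unit quaternions in SO(3)", {
  rs <- hopf_rotations(200)
  expect_equal(rs$count, 200)
  expect_equal(rs$quaternions[1, ], c(1, 0, 0, 0))
  expect_lt(max(abs(sqrt(rowSums(rs$quaternions^2)) - 1)), 1e-12)
  expect_identical(rs$quaternions, hopf_rotations(200)$quaternions)

  for (i in seq(1, 200, by = 17)) {
    R <- quat_to_matrix(rs$quaternions[i, ])
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-10)
    expect_equal(det(R), 1, tolerance = 1e-10)
  }

  # near-uniform: max nearest-neighbour gap within 2x the ideal spacing
  gap <- espqsar:::max_nn_gap(rs$quaternions)
  expect_lt(gap, 2 * espqsar:::ideal_rotation_gap(200))

  expect_equal(hopf_rotations(1)$quaternions, rbind(c(1, 0, 0, 0)))
  expect_error(hopf_rotations(0), "positive")
})

test_that("molecule rotation is rigid and composes like the group", {
  mol <- make_toy_molecule(2, 10, 300)
  d0 <- dist(as.matrix(mol$atoms[, c("x", "y", "z")]))

  # identity leaves coordinates unchanged
  expect_equal(rotate_molecule(mol, c(1, 0, 0, 0))$atoms, mol$atoms)

  # arbitrary rotation preserves interatomic distances
  q <- hopf_rotations(50)$quaternions[37, ]
  rot <- rotate_molecule(mol, q, center = c(0.5, -1, 0.2))
  expect_equal(as.numeric(dist(as.matrix(rot$atoms[, c("x", "y", "z")]))),
               as.numeric(d0), tolerance = 1e-10)

  # q then conjugate(q) restores the pose
  back <- rotate_molecule(rot, quat_conjugate(q), center = c(0.5, -1, 0.2))
  expect_equal(back$atoms$x, mol$atoms$x, tolerance = 1e-10)

  # 90 degrees about z maps (1,0,0) to (0,1,0)
  probe <- molecule("p", atoms_tbl("C", rbind(c(1, 0, 0)), 0))
  qz <- c(cos(pi / 4), 0, 0, sin(pi / 4))
  got <- rotate_molecule(probe, qz)
  expect_equal(c(got$atoms$x, got$atoms$y, got$atoms$z), c(0, 1, 0),
               tolerance = 1e-12)
})

test_that("FFT correlation map equals the direct-sum oracle", {
  set.seed(31)
  for (np in list(c(8, 8, 8), c(6, 5, 4))) {
    g <- grid_spec(c(0, 0, 0), 0.5, np)
    phi <- scalar_field(g, array(rnorm(prod(np)), np), "potential")
    rho <- scalar_field(g, array(rnorm(prod(np)), np), "density")
    fftmap <- cross_correlation_map(phi, rho)
    oracle <- brute_correlation(phi, rho)
    expect_equal(fftmap$shifts, oracle$shifts)
    expect_lt(max(abs(fftmap$values - oracle$values)) /
                max(abs(oracle$values)), 1e-8)
  }
})

test_that("autocorrelation peaks at zero shift and recovers known shifts", {
  set.seed(7)
  np <- c(10, 10, 10)
  g <- grid_spec(c(0, 0, 0), 0.3, np)
  base <- array(0, np)
  base[3:7, 3:7, 3:7] <- rnorm(125)
  f <- scalar_field(g, base, "potential")
  self <- corr_peak(cross_correlation_map(f, scalar_field(g, base,
                                                          "density")))
  expect_equal(self$shift, c(0L, 0L, 0L))

  # target shifted by (2, 0, -1) cells -> argmax at (2, 0, -1)
  shifted <- array(0, np)
  shifted[(3:7) + 2, 3:7, (3:7) - 1] <- base[3:7, 3:7, 3:7]
  pk <- corr_peak(cross_correlation_map(f, scalar_field(g, shifted,
                                                        "density")))
  expect_equal(pk$shift, c(2L, 0L, -1L))

  # grid mismatch errors
  g2 <- grid_spec(c(0, 0, 0), 0.4, np)
  expect_error(
    cross_correlation_map(f, scalar_field(g2, base, "density")), "grid")
})

test_that("self-alignment returns the identity rotamer and zero shift", {
  grid <- grid_spec(rep(-31 * 0.4 / 2, 3), 0.4, rep(32, 3))
  mol <- pinned_toy(7, 12, 300, grid)
  rot <- hopf_rotations(24)
  res <- suppressWarnings(best_alignment(mol, mol, rot, grid))
  expect_equal(res$rotamer, 1L)
  expect_equal(res$rotation, c(1, 0, 0, 0))
  expect_equal(res$translation_cells, c(0L, 0L, 0L))
  # score equals the density/potential autocorrelation peak
  backend <- promolecule_backend()
  phi <- solve_poisson(suppressWarnings(backend$density(mol, grid)))
  rho <- suppressWarnings(backend$density(mol, grid))
  expect_equal(res$score, corr_peak(cross_correlation_map(phi, rho))$score,
               tolerance = 1e-10)
})

test_that("best alignment equals an exhaustive direct-sum search", {
  # tiny instance: every (rotamer, shift) pair scored by the oracle
  grid <- grid_spec(rep(-11 * 0.5 / 2, 3), 0.5, rep(12, 3))
  tpl <- pinned_toy(51, 5, 120, grid)
  tgt <- pinned_toy(52, 4, 95, grid)
  rot <- hopf_rotations(12)
  backend <- promolecule_backend()
  res <- suppressWarnings(best_alignment(tpl, tgt, rot, grid, backend))

  tplp <- espqsar:::translate_molecule(
    tpl, grid_center(grid) - espqsar:::vdw_center(tpl))
  phi <- solve_poisson(suppressWarnings(backend$density(tplp, grid)))
  rho0 <- suppressWarnings(backend$density(tgt, grid))
  best <- -Inf
  for (r in seq_len(rot$count)) {
    rho_r <- if (r == 1) rho0 else
      espqsar:::rotate_density(rho0, rot$quaternions[r, ])
    best <- max(best, max(brute_correlation(phi, rho_r)$values))
  }
  expect_equal(res$score, best, tolerance = 1e-8)
})

test_that("planted rigid transforms are recovered exactly", {
  grid <- grid_spec(rep(-31 * 0.4 / 2, 3), 0.4, rep(32, 3))
  mol <- pinned_toy(7, 14, 330, grid)
  rot <- hopf_rotations(48)
  for (seed in 1:3) {
    set.seed(seed)
    ri <- sample(2:rot$count, 1)
    sh <- sample(-3:3, 3, replace = TRUE)
    pl <- plant_transform(mol, ri, sh, rot, grid)
    res <- suppressWarnings(best_alignment(mol, pl$molecule, rot, grid))
    expect_equal(res$rotamer, ri)
    expect_lte(max(abs(res$translation_cells - sh)), 1L)
    # aligned coordinates land back on the original pose
    rmsd <- sqrt(mean((as.matrix(res$aligned$atoms[, c("x", "y", "z")]) -
                         as.matrix(mol$atoms[, c("x", "y", "z")]))^2))
    expect_lt(rmsd, grid$spacing)
  }
})

test_that("subset alignment is order-invariant and re-scoreable", {
  grid <- grid_spec(rep(-31 * 0.4 / 2, 3), 0.4, rep(32, 3))
  mols <- list(pinned_toy(61, 10, 290, grid), pinned_toy(62, 9, 270, grid),
               pinned_toy(63, 8, 260, grid))
  names(mols) <- purrr::map_chr(mols, "id")
  sub <- tibble::tibble(id = names(mols), mw = purrr::map_dbl(mols, "mw"))
  rot <- hopf_rotations(16)
  a1 <- suppressWarnings(align_subset(sub, mols, grid, rot))
  expect_equal(nrow(a1$log), 2)

  # template-only subset yields an empty log
  solo <- suppressWarnings(
    align_subset(sub[1, ], mols[1], grid, rot))
  expect_equal(nrow(solo$log), 0)

  # shuffling member order changes nothing per id
  perm <- c(3, 1, 2)
  a2 <- suppressWarnings(align_subset(sub[perm, ], mols[perm], grid, rot))
  expect_equal(a1$template_id, a2$template_id)
  l1 <- a1$log[order(a1$log$target_id), ]
  l2 <- a2$log[order(a2$log$target_id), ]
  expect_equal(l1, l2)

  # re-scoring an aligned pose reproduces the logged score
  backend <- promolecule_backend()
  tpl <- a1$aligned[[a1$template_id]]
  phi <- solve_poisson(suppressWarnings(backend$density(tpl, grid)))
  id <- a1$log$target_id[1]
  rho <- suppressWarnings(backend$density(a1$aligned[[id]], grid))
  rescored <- sum(phi$values * rho$values) * espqsar:::grid_dv(grid)
  # interpolated rotamer density vs re-evaluated density: coarse agreement
  expect_equal(rescored, a1$log$score[1], tolerance = 0.05)
})
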
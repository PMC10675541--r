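#' Generate a seeded synthetic charged toy molecule
#'
#' Builds a rigid cluster of atoms drawn from C, N, O, S and Cl whose
#' summed standard atomic weights land within +/- 5 amu of a target, with
#' positions inside a ball (12 Angstrom diameter by default) and zero-sum
#' partial charges in \[-0.5, 0.5\] e.  These clusters are not chemically
#' bonded structures; they exist to exercise the field, alignment and
#' regression machinery with fully known ground truth.
#'
#' @param seed Integer seed; generation is a pure function of the
#'   arguments.
#' @param n_atoms Number of atoms (>= 3).
#' @param mw_target Target molecular weight (amu).
#' @param id Molecule id (default derived from the seed).
#' @param radius Ball radius for atom positions (default 4.5 Angstrom).
#' @return A [molecule()].
#' @export
make_toy_molecule <- function(seed, n_atoms, mw_target,
                              id = sprintf("SYN%07d", seed), radius = 4.5) {
  if (n_atoms < 3) stop("n_atoms must be >= 3", call. = FALSE)
  masses <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06, Cl = 35.45)
  if (mw_target < n_atoms * masses["C"] - 5 ||
      mw_target > n_atoms * masses["Cl"] + 5) {
    stop("mw_target ", mw_target, " infeasible for ", n_atoms,
         " atoms of {C, N, O, S, Cl}", call. = FALSE)
  }
  elements <- rep("C", n_atoms)
  # greedy element upgrades close the mass deficit to within +/- 2.5 amu
  increments <- sort(masses[c("Cl", "S", "O", "N")] - masses["C"],
                     decreasing = TRUE)
  deficit <- mw_target - n_atoms * masses["C"]
  slot <- 1L
  while (deficit > 2.5 && slot <= n_atoms) {
    step <- increments[increments <= deficit + 2.5][1]
    if (is.na(step)) break
    elements[slot] <- names(step)
    deficit <- deficit - step
    slot <- slot + 1L
  }
  with_preserved_seed({
    set.seed(as.integer(seed))
    elements <- sample(elements)
    # uniform in a ball via radius ~ U^(1/3)
    u <- stats::runif(n_atoms)^(1 / 3) * radius
    dir <- matrix(stats::rnorm(3 * n_atoms), n_atoms, 3)
    dir <- dir / sqrt(rowSums(dir^2))
    coords <- dir * u
    q <- stats::runif(n_atoms, -0.45, 0.45)
  })
  q <- q - mean(q)
  q <- q * min(1, 0.5 / max(abs(q)))
  q <- q - mean(q)                       # re-zero after any rescale
  molecule(id, tibble::tibble(
    element = elements,
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    charge = q))
}

#' Specification of a synthetic activity benchmark
#'
#' Describes the study conditions of the synthetic dataset: seven
#' molecular-weight subsets of 70 molecules spanning 250-600 amu, a
#' linear teacher acting on the leading PCA scores of the true ESP
#' descriptors, activities mapped into a 3.5-9.0 pIC50 range, optional
#' Gaussian activity noise, and the desk-scale grid parameters on which
#' the ground-truth descriptors are computed.
#'
#' @param n_subsets Number of molecular-weight subsets (default 7).
#' @param members_per_subset Molecules per subset (default 70).
#' @param mw_min,bin_width Weight-bin layout (defaults 250, 50 amu).
#' @param teacher `"linear"` (weights over the leading `n_scores` PCA
#'   scores) or `"network"` (a random teacher net of the production
#'   architecture applied to the leading scores).
#' @param n_scores Number of leading PCA scores the teacher sees
#'   (default 5).
#' @param noise_sd Gaussian noise added to the activities, pIC50 units
#'   (default 0).
#' @param pic50_range Activity range the teacher output is mapped into
#'   (default c(3.5, 9.0), inside the experimentally observed span).
#' @param spacing_align,margin,width_scale Grid parameters for the
#'   ground-truth descriptor computation (desk-scale defaults 0.4, 2.7,
#'   0.5).
#' @param hard_mode Apply a random rigid perturbation to every
#'   non-template molecule after truth generation, so the alignment stage
#'   must recover the pose (default FALSE).
#' @param seed Master seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_benchmark_spec <- function(n_subsets = 7, members_per_subset = 70,
                                     mw_min = 250, bin_width = 50,
                                     teacher = c("linear", "network"),
                                     n_scores = 5, noise_sd = 0,
                                     pic50_range = c(3.5, 9.0),
                                     spacing_align = 0.4, margin = 2.7,
                                     width_scale = 0.5, hard_mode = FALSE,
                                     seed = 1) {
  teacher <- match.arg(teacher)
  structure(
    list(n_subsets = n_subsets, members_per_subset = members_per_subset,
         mw_min = mw_min, bin_width = bin_width, teacher = teacher,
         n_scores = n_scores, noise_sd = noise_sd,
         pic50_range = pic50_range, spacing_align = spacing_align,
         margin = margin, width_scale = width_scale,
         hard_mode = hard_mode, seed = seed),
    class = "synthetic_spec"
  )
}

#' Generate the synthetic benchmark dataset
#'
#' For each molecular-weight subset: generates toy molecules with targets
#' spread across the subset's weight range, computes their true ESP
#' descriptors on the spec's grids (molecules are emitted already posed
#' in the common frame), fits a subset-level PCA, applies the teacher to
#' the leading scores, min-max maps the result into the spec's pIC50
#' range and adds seeded Gaussian noise.  The teacher weights, true
#' scores and noise draws are kept as ground truth for recovery tests.
#' With `hard_mode = TRUE` every non-template molecule is additionally
#' rigidly perturbed after truth generation.
#'
#' @param spec A [synthetic_benchmark_spec()].
#' @param dir Optional directory; when given, writes `structures.sdf`,
#'   `activities.csv` and `truth.json` there.
#' @return List with `molecules` (named list, generation pose),
#'   `activities` (tibble: id, mw, subset, pic50), `truth` (per-subset
#'   teacher weights, scores, noise, grids) and `spec`.
#' @export
make_benchmark <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  molecules <- list()
  activities <- list()
  truth <- list(subsets = list(), spec_seed = spec$seed)
  base_seed <- (as.integer(spec$seed) * 1009L) %% 1000000L
  for (s in seq_len(spec$n_subsets)) {
    lo <- spec$mw_min + spec$bin_width * (s - 1)
    n <- spec$members_per_subset
    # weight targets spread over the bin interior, deterministic order;
    # the 3-amu inset keeps every realized mw (target +/- 2.5) inside the bin
    targets <- lo + 3 + (spec$bin_width - 6) * (seq_len(n) - 0.5) / n
    mols <- vector("list", n)
    for (k in seq_len(n)) {
      mseed <- base_seed + s * 1000L + k
      n_atoms <- max(8L, as.integer(round(targets[k] / 16)))
      mols[[k]] <- make_toy_molecule(
        mseed, n_atoms, targets[k],
        id = sprintf("SYN%d_%03d", s, k))
    }
    names(mols) <- purrr::map_chr(mols, "id")
    grid <- build_common_box(mols, spacing = spec$spacing_align,
                             margin = spec$margin)
    dgrid <- descriptor_grid(grid)
    backend <- promolecule_backend(spec$width_scale)
    X <- suppressWarnings(esp_descriptor_matrix(mols, dgrid, backend))
    pca <- pca_fit(X, n_comp = min(nrow(X), spec$n_scores))
    scores <- pca_project(pca, X)[, seq_len(spec$n_scores), drop = FALSE]
    with_preserved_seed({
      set.seed(base_seed + s)
      w <- stats::runif(spec$n_scores, -1, 1)
      raw <- if (spec$teacher == "linear") {
        drop(scores %*% w)
      } else {
        tn <- ann_train(matrix(0, 2, spec$n_scores), c(0, 1),
                        n_hidden = 8, seed = base_seed + s, max_iter = 0,
                        record_trace = FALSE)$model
        ann_forward(tn, scores)
      }
      noise <- stats::rnorm(n, 0, spec$noise_sd)
    })
    span <- diff(range(raw))
    if (span == 0) span <- 1
    pic50 <- spec$pic50_range[1] +
      (raw - min(raw)) / span * diff(spec$pic50_range) + noise
    perturb <- NULL
    if (spec$hard_mode) {
      rot <- hopf_rotations(256)
      with_preserved_seed({
        set.seed(base_seed + 31L * s)
        tpl_id <- select_template(tibble::tibble(
          id = names(mols), mw = purrr::map_dbl(mols, "mw")), mols)$id
        perturb <- list()
        for (id in setdiff(names(mols), tpl_id)) {
          ri <- sample(2:rot$count, 1)
          sh <- sample(-2:2, 3, replace = TRUE)
          mols[[id]] <- plant_transform(mols[[id]], ri, sh, rot, grid)$molecule
          perturb[[id]] <- list(rotamer = ri, shift = sh)
        }
      })
    }
    for (k in seq_len(n)) mols[[k]]$pic50 <- pic50[k]
    molecules <- c(molecules, mols)
    activities[[s]] <- tibble::tibble(
      id = names(mols), mw = purrr::map_dbl(mols, "mw"),
      subset = s, pic50 = pic50)
    truth$subsets[[s]] <- list(
      teacher_weights = w, scores = scores, noise = noise,
      grid = grid, descriptor_grid = dgrid, perturbations = perturb)
  }
  out <- list(molecules = molecules,
              activities = dplyr::bind_rows(activities),
              truth = truth, spec = spec)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_sdf(out$molecules, file.path(dir, "structures.sdf"))
    readr::write_csv(out$activities[, c("id", "pic50", "mw")],
                     file.path(dir, "activities.csv"))
    jsonlite::write_json(
      list(seed = spec$seed, noise_sd = spec$noise_sd,
           teacher = spec$teacher,
           teacher_weights = lapply(truth$subsets, `[[`, "teacher_weights")),
      file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE)
  }
  out
}

#' Apply a known sampled rotation and integer-cell shift to a molecule
#'
#' Oracle support for alignment tests: transforms a molecule so that
#' [best_alignment()] searching the same rotation set on the same grid
#' can recover it exactly - the planted pose is
#' `R^T (x + shift * spacing - c) + c` with R the sampled rotation and c
#' the grid center, the exact preimage of the search's
#' rotate-then-translate move.
#'
#' @param molecule A [molecule()] posed in the box.
#' @param rotation_index Index into the rotation set (1 = identity).
#' @param shift_cells Integer length-3 cell shift.
#' @param rotations A [hopf_rotations()] set.
#' @param grid The [grid_spec()] box.
#' @return List with `molecule` (transformed) and `truth`
#'   (rotation_index, shift_cells, quaternion).
#' @export
plant_transform <- function(molecule, rotation_index, shift_cells,
                            rotations, grid) {
  q <- rotations$quaternions[rotation_index, ]
  cen <- grid_center(grid)
  shifted <- translate_molecule(molecule, shift_cells * grid$spacing)
  planted <- rotate_molecule(shifted, quat_conjugate(q), cen)
  if (!molecule_in_box(planted, grid)) {
    stop("planted transform pushes ", molecule$id, " outside the box",
         call. = FALSE)
  }
  list(molecule = planted,
       truth = list(rotation_index = rotation_index,
                    shift_cells = as.integer(shift_cells),
                    quaternion = q))
}
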
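#' Descriptor grid: the alignment grid subsampled by stride 2
#'
#' Descriptor ESP values live on every second node of the alignment grid
#' (0.106 -> 0.212 Angstrom at study scale), same origin, so descriptor
#' nodes are an exact subset of alignment nodes.
#'
#' @param align_grid The alignment [grid_spec()].
#' @param stride Integer subsampling factor (default 2).
#' @return A [grid_spec()].
#' @export
descriptor_grid <- function(align_grid, stride = 2L) {
  stride <- as.integer(stride)
  stopifnot(stride >= 1)
  grid_spec(align_grid$origin, align_grid$spacing * stride,
            ((align_grid$npoints - 1L) %/% stride) + 1L)
}

#' ESP descriptor vector of an aligned molecule
#'
#' Solves Poisson's equation for the molecule's charge density on the
#' descriptor grid and flattens the potential in fixed x-fastest node
#' order into a K-vector (K = product of the grid's node counts; the
#' study-scale 106-per-axis grid gives K = 106^3 = 1,191,016).
#'
#' @param aligned_molecule A [molecule()] already posed in the common box.
#' @param desc_grid The [descriptor_grid()].
#' @param backend Density backend.
#' @return Numeric K-vector of ESP values (e/Angstrom).
#' @export
esp_descriptor <- function(aligned_molecule, desc_grid,
                           backend = promolecule_backend()) {
  if (!molecule_in_box(aligned_molecule, desc_grid)) {
    warning("molecule ", aligned_molecule$id,
            " has atoms outside the descriptor box", call. = FALSE)
  }
  rho <- backend$density(aligned_molecule, desc_grid)
  as.vector(solve_poisson(rho)$values)
}

#' Descriptor matrix of a set of aligned molecules
#'
#' @param molecules Named list of aligned [molecule()] objects.
#' @param desc_grid The [descriptor_grid()].
#' @param backend Density backend.
#' @return Numeric matrix, one row per molecule (rownames = ids), K
#'   columns.
#' @export
esp_descriptor_matrix <- function(molecules, desc_grid,
                                  backend = promolecule_backend()) {
  rows <- lapply(molecules, esp_descriptor, desc_grid = desc_grid,
                 backend = backend)
  X <- do.call(rbind, rows)
  rownames(X) <- names(molecules)
  X
}

#' Fit a PCA model to training descriptor rows
#'
#' Mean-centered singular value decomposition of the n x K training
#' matrix.  Components are ordered by decreasing explained variance and
#' their sign is fixed so each component's largest-magnitude loading is
#' positive.  When the requested number of components exceeds the matrix
#' rank (for centered data the rank is at most n - 1), only `rank`
#' components are stored and projections are zero-padded to `n_comp`, so
#' the descriptor width presented to the regression stage stays fixed.
#'
#' @param train_matrix n x K matrix (rows = training molecules).
#' @param n_comp Number of scores to emit (default n, the training-set
#'   size, mirroring the 56-wide network input at study scale).
#' @return An `esp_pca` model: `mean`, `components` (K x rank,
#'   orthonormal), `explained_variance`, `n_comp`, `rank`.
#' @export
pca_fit <- function(train_matrix, n_comp = nrow(train_matrix)) {
  n <- nrow(train_matrix)
  if (n_comp < 1) stop("n_comp must be >= 1", call. = FALSE)
  if (n_comp > n) stop("n_comp cannot exceed the number of samples",
                       call. = FALSE)
  mu <- colMeans(train_matrix)
  Xc <- sweep(train_matrix, 2, mu)
  sv <- svd(Xc, nu = 0, nv = min(n, ncol(Xc)))
  tol <- max(dim(Xc)) * .Machine$double.eps * max(sv$d, 0)
  rank <- min(sum(sv$d > tol), n_comp)
  comps <- sv$v[, seq_len(rank), drop = FALSE]
  # sign convention: largest |loading| positive
  for (j in seq_len(rank)) {
    peak <- which.max(abs(comps[, j]))
    if (comps[peak, j] < 0) comps[, j] <- -comps[, j]
  }
  structure(
    list(mean = mu, components = comps,
         explained_variance = sv$d[seq_len(rank)]^2 / (n - 1),
         n_comp = as.integer(n_comp), rank = as.integer(rank)),
    class = "esp_pca"
  )
}

#' @export
print.esp_pca <- function(x, ...) {
  cat(sprintf("<esp_pca: %d component(s) (rank %d) over K = %d descriptors>\n",
              x$n_comp, x$rank, length(x$mean)))
  invisible(x)
}

#' Project descriptor vectors onto fitted principal components
#'
#' `scores = t(components) %*% (x - mean)`, applied unchanged to test
#' molecules (no refit); scores beyond the fitted rank are zero.
#'
#' @param model An [pca_fit()] model.
#' @param x A K-vector, or an m x K matrix of descriptor rows.
#' @return An `n_comp`-vector, or an m x n_comp score matrix.
#' @export
pca_project <- function(model, x) {
  if (is.matrix(x)) {
    if (ncol(x) != length(model$mean)) stop("descriptor length mismatch",
                                            call. = FALSE)
    sc <- sweep(x, 2, model$mean) %*% model$components
    out <- matrix(0, nrow(x), model$n_comp)
    out[, seq_len(model$rank)] <- sc
    rownames(out) <- rownames(x)
    out
  } else {
    if (length(x) != length(model$mean)) stop("descriptor length mismatch",
                                              call. = FALSE)
    out <- numeric(model$n_comp)
    out[seq_len(model$rank)] <- drop(crossprod(model$components,
                                               x - model$mean))
    out
  }
}

#' Reconstruct descriptor vectors from PCA scores
#'
#' @param model An [pca_fit()] model.
#' @param scores n_comp-vector or m x n_comp matrix.
#' @return Reconstructed K-vector or m x K matrix.
#' @export
pca_reconstruct <- function(model, scores) {
  if (is.matrix(scores)) {
    sweep(scores[, seq_len(model$rank), drop = FALSE] %*% t(model$components),
          2, model$mean, "+")
  } else {
    drop(model$components %*% scores[seq_len(model$rank)]) + model$mean
  }
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an ESP PCA model
#'
#' @param x An `esp_pca` model.
#' @param ... Unused.
#' @return Tibble with one row per fitted component: `component`,
#'   `explained_variance`, `prop_variance`, `cum_prop`.
#' @export
#' @exportS3Method
tidy.esp_pca <- function(x, ...) {
  ev <- x$explained_variance
  tibble::tibble(
    component = seq_along(ev),
    explained_variance = ev,
    prop_variance = ev / sum(ev),
    cum_prop = cumsum(ev) / sum(ev)
  )
}
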
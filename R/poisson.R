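#' Solve Poisson's equation for the electrostatic potential
#'
#' Computes the free-space electrostatic potential of a charge-density
#' field under the Coulomb convention with constant 1 (charge in e, length
#' in Angstrom): \eqn{\phi(x) = \sum_y \rho(y) / |x - y| \, dV}.  The
#' convolution with the 1/r kernel is evaluated spectrally on a grid
#' zero-padded by a factor of 2 per axis, so the result carries open
#' (isolated-system) boundaries rather than periodic images.  The kernel's
#' singular cell is replaced by the self-potential of a uniformly charged
#' sphere of equal volume.
#'
#' For an isolated Gaussian charge q of width sigma the result approaches
#' the closed form \eqn{q\,\mathrm{erf}(r/(\sigma\sqrt2))/r}.
#'
#' @param density A [scalar_field()] of kind `"density"`.
#' @return A [scalar_field()] of kind `"potential"` on the same grid
#'   (e/Angstrom).
#' @export
solve_poisson <- function(density) {
  stopifnot(inherits(density, "scalar_field"))
  if (!all(is.finite(density$values))) stop("non-finite density values",
                                            call. = FALSE)
  grid <- density$grid
  np <- grid$npoints
  m <- 2L * np
  h <- grid$spacing
  rho <- array(0, m)
  rho[seq_len(np[1]), seq_len(np[2]), seq_len(np[3])] <- density$values
  kf <- coulomb_kernel_fft(m, h)
  phi_pad <- Re(fft(fft(rho) * kf, inverse = TRUE)) / prod(m)
  phi <- phi_pad[seq_len(np[1]), seq_len(np[2]), seq_len(np[3])] * h^3
  scalar_field(grid, phi, "potential")
}

# FFT of the circulant 1/r kernel on an m-point padded grid with spacing h;
# the r = 0 cell uses the equal-volume-sphere self term 3 / (2 a).
# Cached because the same padded grid recurs for every molecule of a subset.
coulomb_kernel_fft <- function(m, h) {
  key <- paste0(paste(m, collapse = "x"), "@", format(h, digits = 17))
  cached <- kernel_cache[[key]]
  if (!is.null(cached)) return(cached)
  ax <- lapply(m, function(n) {
    i <- 0:(n - 1)
    pmin(i, n - i) * h             # circulant (minimum-image) distance
  })
  r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+")
  k <- 1 / sqrt(r2)
  a <- (3 * h^3 / (4 * pi))^(1 / 3)
  k[1, 1, 1] <- 1.5 / a
  kf <- fft(k)
  if (length(kernel_cache) < 16) kernel_cache[[key]] <- kf
  kf
}

kernel_cache <- new.env(parent = emptyenv())
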
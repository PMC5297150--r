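# Rice / Rayleigh noise models: densities, simulation, and scale estimation.
#
# Magnitude MR data are Rice distributed; as the underlying signal-to-noise
# ratio b/sigma tends to zero the Rice density collapses onto a Rayleigh one.
# The denoiser works in that low-SNR regime, where acquisition is modeled as
# additive: a = b + n with n Rayleigh(sigma).

check_sigma <- function(sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0) {
    stop("'sigma' must be a single finite positive number", call. = FALSE)
  }
  sigma
}

#' Rice probability density
#'
#' Density of the magnitude of a complex Gaussian measurement with noise-free
#' amplitude `b` and noise scale `sigma`:
#' `a/sigma^2 * exp(-(a^2 + b^2) / (2 sigma^2)) * I0(a b / sigma^2)` for
#' `a >= 0`, where `I0` is the modified Bessel function of the first kind of
#' order zero. At `b = 0` this reduces exactly to the Rayleigh density.
#'
#' The exponentially scaled Bessel function is used internally so the density
#' is computed stably even at large `a*b/sigma^2`.
#'
#' @param a Observed magnitude(s), vectorized.
#' @param b Noise-free amplitude (scalar or vector), `b >= 0`.
#' @param sigma Noise scale parameter, `> 0`.
#' @return Density value(s); 0 for `a < 0`.
#' @export
rice_pdf <- function(a, b, sigma) {
  check_sigma(sigma)
  if (any(b < 0)) stop("'b' must be nonnegative", call. = FALSE)
  s2 <- sigma^2
  # besselI(..., expon.scaled) returns exp(-x) I0(x); fold the factor back
  # into the exponent to avoid overflow of I0 at high SNR.
  x <- a * b / s2
  dens <- (a / s2) * exp(-(a - b)^2 / (2 * s2)) * besselI(pmax(x, 0), 0, expon.scaled = TRUE)
  dens[a < 0] <- 0
  dens
}

#' Rayleigh probability density
#'
#' `n/sigma^2 * exp(-n^2 / (2 sigma^2))` for `n >= 0`, zero for negative
#' arguments. This is the noise density of the additive low-SNR acquisition
#' model and the `b = 0` limit of [rice_pdf()].
#'
#' @param n Noise value(s), vectorized.
#' @param sigma Noise scale parameter, `> 0`.
#' @return Density value(s).
#' @export
rayleigh_pdf <- function(n, sigma) {
  check_sigma(sigma)
  dens <- (n / sigma^2) * exp(-n^2 / (2 * sigma^2))
  dens[n < 0] <- 0
  dens
}

#' Draw a Rayleigh noise field
#'
#' i.i.d. Rayleigh(sigma) draws arranged as a 3D array, generated by the
#' inverse-CDF transform `n = sigma * sqrt(-2 log U)`, `U ~ Uniform(0,1)`.
#' The global RNG state is left untouched when a seed is supplied.
#'
#' @param dims Integer length-3 array dimensions.
#' @param sigma Noise scale, `> 0`.
#' @param seed Optional integer seed for reproducible fields.
#' @return 3D array of nonnegative noise values.
#' @export
sample_rayleigh <- function(dims, sigma, seed = NULL) {
  check_sigma(sigma)
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 1L)) {
    stop("'dims' must be 3 positive integers", call. = FALSE)
  }
  u <- with_rng_seed(seed, stats::runif(prod(dims)))
  u[u == 0] <- .Machine$double.eps  # guard the log at the open endpoint
  array(sigma * sqrt(-2 * log(u)), dim = dims)
}

# Run expr under a temporary RNG state seeded with `seed`; restore afterwards.
with_rng_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Corrupt a volume with Rayleigh noise
#'
#' Applies the additive acquisition model `a = b + n` with
#' `n ~ Rayleigh(sigma)` i.i.d. per voxel. Because Rayleigh noise is
#' nonnegative, `a >= b` everywhere.
#'
#' @param b An [image_stack()] (noise-free volume).
#' @param sigma Noise scale, `> 0`.
#' @param seed Optional integer seed.
#' @return An [image_stack()] with the same spacing.
#' @export
add_noise <- function(b, sigma, seed = NULL) {
  stopifnot(inherits(b, "image_stack"))
  check_sigma(sigma)
  n <- sample_rayleigh(dim(b), sigma, seed = seed)
  image_stack(unclass(b) + n, spacing = stack_spacing(b))
}

#' Estimate the Rayleigh scale from background voxels
#'
#' In a pure-noise background region (no underlying signal) the acquired
#' magnitudes are Rayleigh(sigma), whose maximum-likelihood scale estimate is
#' `sigma_hat = sqrt(sum(a^2) / (2 N))`. At least 100 background voxels are
#' required for a usable estimate.
#'
#' @param a An [image_stack()] (acquired, noisy volume).
#' @param background_mask Logical array, same dims as `a`, `TRUE` on voxels
#'   assumed to contain noise only.
#' @return Estimated `sigma` (scalar).
#' @export
estimate_sigma <- function(a, background_mask) {
  stopifnot(inherits(a, "image_stack"))
  if (!is.logical(background_mask) || !identical(dim(background_mask), dim(a))) {
    stop("'background_mask' must be a logical array matching dim(a)", call. = FALSE)
  }
  n_mask <- sum(background_mask)
  if (n_mask < 100L) {
    stop(sprintf(
      "background mask selects only %d voxels; at least 100 are needed for a stable Rayleigh scale estimate",
      n_mask
    ), call. = FALSE)
  }
  sqrt(sum(unclass(a)[background_mask]^2) / (2 * n_mask))
}

#' Background mask from volume corner patches
#'
#' Convenience heuristic for [estimate_sigma()] when no explicit background
#' mask is available: takes cubic patches at the eight volume corners, which
#' in head acquisitions usually lie in air. The caller should verify the
#' assumption for unusual fields of view.
#'
#' @param a An [image_stack()].
#' @param patch Patch edge length in voxels (clamped to the volume size).
#' @return Logical array mask.
#' @export
corner_background_mask <- function(a, patch = 8L) {
  d <- dim(a)
  patch <- pmin(as.integer(patch), d)
  m <- array(FALSE, d)
  for (i in list(seq_len(patch[1]), seq.int(d[1] - patch[1] + 1L, d[1]))) {
    for (j in list(seq_len(patch[2]), seq.int(d[2] - patch[2] + 1L, d[2]))) {
      for (k in list(seq_len(patch[3]), seq.int(d[3] - patch[3] + 1L, d[3]))) {
        m[i, j, k] <- TRUE
      }
    }
  }
  m
}
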
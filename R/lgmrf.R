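# Local Gaussian Markov random field prior.
#
# The prior is a Gibbs distribution exp(-E(b, theta)) whose energy penalizes
# squared differences between each voxel and its 26-voxel neighborhood,
# weighted by pairwise hyperparameters theta^2_{k,q} and the squared physical
# distance d^2_{k,q}:
#
#   E(b, theta) = sum_k sum_{q in N_k} (b_k - b_q)^2 / (2 theta^2_{k,q} d^2_{k,q})
#
# The double sum is taken literally: each unordered pair contributes once
# from k's sum and once from q's. Hyperparameters are local: theta^2_k is the
# mean squared difference of voxel k to its neighbors (a local variance
# proxy), and the pairwise value is the arithmetic mean of the two voxel
# values. Small theta^2 (flat region) => strong smoothing; large theta^2
# (edge) => the pair is effectively decoupled.

#' Hyperparameter field for the local Gaussian MRF
#'
#' Wraps a per-voxel `theta^2` map (units: intensity squared) with the small
#' positive floor applied to it. The pairwise `theta^2_{k,q}` used in the
#' energy is never stored: it is derived on demand as the mean of the two
#' per-voxel values (see [pair_hyperparameter()]).
#'
#' @param theta2 3D array of per-voxel `theta^2` values.
#' @param floor Positive lower bound applied to `theta2` (guards the division
#'   in the energy in perfectly flat regions).
#' @return A `hyperparameter_field` (list with `theta2`, `floor`).
#' @export
hyperparameter_field <- function(theta2, floor = 1e-12) {
  if (!is.array(theta2) || length(dim(theta2)) != 3L) {
    stop("'theta2' must be a 3D array", call. = FALSE)
  }
  if (!is.finite(floor) || floor <= 0) stop("'floor' must be > 0", call. = FALSE)
  structure(list(theta2 = pmax(theta2, floor), floor = floor),
            class = "hyperparameter_field")
}

#' @export
print.hyperparameter_field <- function(x, ...) {
  cat(sprintf("<hyperparameter_field> %s, theta^2 range [%.4g, %.4g], floor %.3g\n",
              paste(dim(x$theta2), collapse = " x "),
              min(x$theta2), max(x$theta2), x$floor))
  invisible(x)
}

# Floor convention: relative to the intensity variance of the acquired
# volume, with an absolute backstop for degenerate (constant) inputs.
theta2_floor <- function(a) max(1e-6 * stats::var(as.vector(a)), 1e-12)

#' Distance-weighted prior energy
#'
#' Evaluates the LGMRF energy of a volume under a hyperparameter field:
#' each ordered neighbor pair (k, q) contributes
#' `(b_k - b_q)^2 / (2 theta^2_{k,q} d^2_{k,q})`, with
#' `theta^2_{k,q} = (theta^2_k + theta^2_q) / 2`. The energy depends only on
#' intensity differences, is nonnegative, and vanishes exactly on constant
#' volumes.
#'
#' @param b An [image_stack()].
#' @param h A [hyperparameter_field()] with matching dimensions.
#' @param nsys A [neighborhood_system()] (distances in mm from the spacing).
#' @return Scalar energy.
#' @export
lgmrf_energy <- function(b, h, nsys = neighborhood_system(stack_spacing(b))) {
  stopifnot(inherits(b, "image_stack"), inherits(h, "hyperparameter_field"))
  if (!identical(dim(b), dim(h$theta2))) {
    stop("hyperparameter field dimensions do not match the volume", call. = FALSE)
  }
  dims <- dim(b)
  bv <- unclass(b)
  th <- h$theta2
  e <- 0
  for (m in seq_len(nrow(nsys$offsets))) {
    r <- offset_ranges(dims, nsys$offsets[m, ])
    d2 <- nsys$distances[m]^2
    bd <- sub3(bv, r$dst); bs <- sub3(bv, r$src)
    t2 <- (sub3(th, r$dst) + sub3(th, r$src)) / 2
    e <- e + sum((bd - bs)^2 / (2 * t2 * d2))
  }
  e
}

#' Re-estimate per-voxel hyperparameters from the current image estimate
#'
#' For each voxel the hyperparameter is the mean squared difference to its
#' neighbors: `theta^2_k = (1/26) * sum_q (b_k - b_q)^2` over the 26-voxel
#' neighborhood. At clipped boundary voxels the divisor is the number of
#' in-bounds neighbors (so `theta^2` stays an unbiased local variance proxy);
#' for reduced 6/18-connectivity systems the divisor is likewise the system
#' size. Results are floored at `floor`.
#'
#' @param b_hat An [image_stack()] (current estimate).
#' @param nsys A [neighborhood_system()].
#' @param floor Positive floor for `theta^2`; defaults to
#'   `max(1e-6 * var(b_hat), 1e-12)`.
#' @return A [hyperparameter_field()].
#' @export
update_hyperparameters <- function(b_hat,
                                   nsys = neighborhood_system(stack_spacing(b_hat)),
                                   floor = theta2_floor(b_hat)) {
  stopifnot(inherits(b_hat, "image_stack"))
  dims <- dim(b_hat)
  bv <- unclass(b_hat)
  acc <- array(0, dims)
  cnt <- array(0, dims)
  for (m in seq_len(nrow(nsys$offsets))) {
    r <- offset_ranges(dims, nsys$offsets[m, ])
    d2 <- (sub3(bv, r$dst) - sub3(bv, r$src))^2
    sub3(acc, r$dst) <- sub3(acc, r$dst) + d2
    sub3(cnt, r$dst) <- sub3(cnt, r$dst) + 1
  }
  hyperparameter_field(acc / cnt, floor = floor)
}

#' Pairwise hyperparameter
#'
#' The pairwise `theta^2_{k,q}` coupling two neighboring voxels is the
#' arithmetic mean of their per-voxel values; it is symmetric in its
#' arguments by construction.
#'
#' @param theta2_k,theta2_q Per-voxel `theta^2` values (vectorized).
#' @return `(theta2_k + theta2_q) / 2`.
#' @export
pair_hyperparameter <- function(theta2_k, theta2_q) {
  (theta2_k + theta2_q) / 2
}

#' Initial (uninformative) hyperparameter field
#'
#' The iteration starts with the hyperparameters set uniformly to a high
#' value `H = 1e6 * var(a)` so that the prior term is numerically negligible
#' in the first minimization: the first estimate is then driven by the
#' likelihood alone, and the hyperparameters are subsequently learned from
#' it. `H` scales with the variance of the input so the behavior is
#' independent of the intensity units.
#'
#' @param a An [image_stack()] (acquired volume).
#' @return A [hyperparameter_field()] with constant `theta^2 = H`.
#' @export
initialize_hyperparameters <- function(a) {
  stopifnot(inherits(a, "image_stack"))
  H <- 1e6 * max(stats::var(as.vector(a)), .Machine$double.eps)
  hyperparameter_field(array(H, dim(a)), floor = theta2_floor(a))
}
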
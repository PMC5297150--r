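# Synthetic 3D head-like phantom and acquisition simulator.
#
# The phantom is a piecewise-constant nested-ellipsoid volume: an outer
# head/skull shell, a brain compartment, ventricle-like cavities, two
# internal structures of differing intensity, and a handful of 1-voxel
# high-contrast details that probe detail preservation. Geometry is defined
# in normalized coordinates [-1, 1] per axis so a spec is resolution
# independent. The default grid is 27 slices of 128 x 128 voxels.

#' Phantom specification
#'
#' @param dims Volume dimensions (rows, columns, slices). Default
#'   `c(128, 128, 27)`.
#' @param spacing Voxel spacing in mm. Default unit isotropic `c(1, 1, 1)`:
#'   the simulated study is defined on the voxel grid with no physical
#'   spacing, so distances are in voxel units. Anisotropic spacing (e.g. a
#'   coarse slice direction) is the realm of real acquisitions and can be
#'   set explicitly.
#' @param ellipsoids List of ellipsoids, each a list with `center` (normalized
#'   coords), `semiaxes` (normalized), `angle_deg` (rotation about the slice
#'   axis) and `value` (additive intensity). An ellipsoid extending beyond
#'   the volume is clipped with a warning unless it sets `allow_clip = TRUE`
#'   (the default head shell does: it is intentionally taller than the slab,
#'   so the head is cut by the first and last slice). `NULL` selects the
#'   default head geometry with foreground intensities in `[20, 100]`.
#' @param details List of point details, each a list with `center` (normalized
#'   coords) and `value` (additive intensity); every detail occupies a single
#'   voxel. `NULL` selects six default high-contrast details.
#' @param texture Optional list with `region` (index of the ellipsoid to
#'   texture), `amplitude` and `period` (voxels) adding a smooth sinusoidal
#'   modulation; `NULL` (default) for a purely piecewise-constant phantom.
#' @param seed Integer seed recorded with the spec (the geometry itself is
#'   deterministic; the seed feeds derived simulations).
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(dims = c(128L, 128L, 27L),
                         spacing = c(1, 1, 1),
                         ellipsoids = NULL,
                         details = NULL,
                         texture = NULL,
                         seed = 1L) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 1L)) stop("'dims' must be 3 positive integers", call. = FALSE)
  if (is.null(ellipsoids)) ellipsoids <- default_head_ellipsoids()
  if (is.null(details)) details <- default_head_details()
  structure(list(dims = dims, spacing = as.numeric(spacing),
                 ellipsoids = ellipsoids, details = details,
                 texture = texture, seed = as.integer(seed)),
            class = "phantom_spec")
}

default_head_ellipsoids <- function() {
  list(
    # outer head/skull shell; slightly taller than the slab so the head is
    # cut by the first and last slice, as in a typical axial acquisition
    list(center = c(0, 0, 0),      semiaxes = c(0.90, 0.88, 1.05), angle_deg = 0,   value = 30,
         allow_clip = TRUE),
    # brain compartment
    list(center = c(0, 0, 0),      semiaxes = c(0.74, 0.70, 0.82), angle_deg = 0,   value = 40),
    # ventricle-like cavities (darker)
    list(center = c(-0.20, 0, 0),  semiaxes = c(0.10, 0.26, 0.38), angle_deg = 18,  value = -25),
    list(center = c(0.20, 0, 0),   semiaxes = c(0.10, 0.26, 0.38), angle_deg = -18, value = -25),
    # bright lesion-like structure
    list(center = c(0.30, 0.32, 0.20), semiaxes = c(0.13, 0.11, 0.16), angle_deg = 0, value = 30),
    # intermediate-intensity deep structure
    list(center = c(0, -0.38, -0.15), semiaxes = c(0.16, 0.11, 0.14), angle_deg = 0, value = 20)
  )
}

default_head_details <- function() {
  list(
    list(center = c(-0.38,  0.30,  0.10), value = 30),
    list(center = c(-0.40, -0.28, -0.20), value = 30),
    list(center = c( 0.05,  0.45,  0.30), value = -30),
    list(center = c( 0.42, -0.10,  0.00), value = 30),
    list(center = c(-0.10,  0.10,  0.45), value = 30),
    list(center = c( 0.12, -0.18, -0.40), value = -30)
  )
}

# Normalized coordinate grids for a dims volume: each axis maps to [-1, 1].
norm_coords <- function(dims) {
  lapply(1:3, function(ax) {
    n <- dims[ax]
    if (n == 1L) 0 else (seq_len(n) - (n + 1) / 2) / ((n - 1) / 2)
  })
}

ellipsoid_mask <- function(dims, center, semiaxes, angle_deg = 0) {
  co <- norm_coords(dims)
  x <- co[[1]]; y <- co[[2]]; z <- co[[3]]
  phi <- angle_deg * pi / 180
  xc <- x - center[1]
  yc <- y - center[2]
  zc <- z - center[3]
  # rotate in-plane about the slice axis
  xr <- outer(xc,  cos(phi) * rep(1, dims[2])) + outer(rep(1, dims[1]),  sin(phi) * yc)
  yr <- outer(xc, -sin(phi) * rep(1, dims[2])) + outer(rep(1, dims[1]),  cos(phi) * yc)
  q2d <- (xr / semiaxes[1])^2 + (yr / semiaxes[2])^2
  m <- array(FALSE, dims)
  for (k in seq_len(dims[3])) {
    m[, , k] <- q2d + (zc[k] / semiaxes[3])^2 <= 1
  }
  m
}

#' Generate the synthetic head phantom
#'
#' Renders the nested-ellipsoid geometry of a [phantom_spec()] into a
#' noise-free [image_stack()] (the ground truth `b`). Ellipsoid intensities
#' are additive, so nested structures carve contrast steps; point details are
#' applied last. Ellipsoids that extend beyond the volume are clipped with a
#' warning. Generation is deterministic.
#'
#' The returned stack carries the spec and construction metadata (largest
#' flat region, detail count/sizes) as attributes, used by [brain_mask()]
#' and by validity checks.
#'
#' @param spec A [phantom_spec()].
#' @return An [image_stack()] ground-truth volume.
#' @examples
#' b <- generate_head_phantom(phantom_spec(dims = c(32, 32, 9)))
#' range(b)
#' @export
generate_head_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- spec$dims
  vol <- array(0, dims)
  masks <- vector("list", length(spec$ellipsoids))
  for (i in seq_along(spec$ellipsoids)) {
    e <- spec$ellipsoids[[i]]
    if (!isTRUE(e$allow_clip) && any(abs(e$center) + e$semiaxes > 1)) {
      warning(sprintf("ellipsoid %d extends beyond the volume; clipped at the faces", i))
    }
    m <- ellipsoid_mask(dims, e$center, e$semiaxes, e$angle_deg)
    masks[[i]] <- m
    vol[m] <- vol[m] + e$value
  }
  if (!is.null(spec$texture)) {
    tx <- spec$texture
    m <- masks[[tx$region]]
    co <- expand_index(dims)
    mod <- tx$amplitude * sin(2 * pi * co$i / tx$period) * sin(2 * pi * co$j / tx$period)
    vol[m] <- vol[m] + mod[m]
  }
  detail_sizes <- integer(0)
  for (dpt in spec$details) {
    idx <- pmax(pmin(round((dpt$center + 1) / 2 * (dims - 1)) + 1, dims), 1)
    # keep details inside the brain so they probe preservation, not the mask
    if (length(masks) >= 2L && !masks[[2]][idx[1], idx[2], idx[3]]) next
    vol[idx[1], idx[2], idx[3]] <- vol[idx[1], idx[2], idx[3]] + dpt$value
    detail_sizes <- c(detail_sizes, 1L)
  }
  vol <- pmax(vol, 0)
  out <- image_stack(vol, spacing = spec$spacing)
  flat_region <- if (length(masks)) {
    # interior of the brain compartment away from any internal structure
    flat <- if (length(masks) >= 2L) masks[[2]] else masks[[1]]
    if (length(masks) > 2L) for (i in 3:length(masks)) flat <- flat & !masks[[i]]
    sum(flat)
  } else 0L
  attr(out, "phantom_spec") <- spec
  attr(out, "phantom_meta") <- list(
    n_details = length(detail_sizes),
    detail_sizes = detail_sizes,
    flat_region_voxels = flat_region
  )
  out
}

expand_index <- function(dims) {
  list(
    i = array(rep(seq_len(dims[1]), times = dims[2] * dims[3]), dims),
    j = array(rep(rep(seq_len(dims[2]), each = dims[1]), times = dims[3]), dims)
  )
}

#' Simulate an acquisition of the phantom
#'
#' Corrupts a ground-truth volume with additive Rayleigh noise (the low-SNR
#' magnitude acquisition model) via [add_noise()]. The studied noise range
#' for the default phantom intensities (foreground 20-100) is
#' `sigma` in `[0.5, 8]`, spanning high to low SNR. `sigma` and `seed` are
#' recorded as attributes of the result.
#'
#' @param b Ground-truth [image_stack()].
#' @param sigma Noise scale, `> 0`.
#' @param seed Integer seed.
#' @return Noisy [image_stack()].
#' @export
simulate_acquisition <- function(b, sigma, seed = 1L) {
  stopifnot(inherits(b, "image_stack"))
  check_sigma(sigma)
  a <- add_noise(b, sigma, seed = seed)
  attr(a, "sigma") <- sigma
  attr(a, "seed") <- as.integer(seed)
  attr(a, "phantom_spec") <- attr(b, "phantom_spec")
  a
}

#' Evaluation mask of a generated phantom
#'
#' The region inside the outermost ellipsoid of the phantom spec (head
#' region), over which the quality indexes (MSE, SSIM) are computed. An
#' empty ellipsoid list yields an empty mask.
#'
#' @param b A phantom generated by [generate_head_phantom()], or any
#'   [image_stack()] carrying a `phantom_spec` attribute.
#' @param spec Optionally, the [phantom_spec()] (required if `b` has no
#'   attached spec).
#' @return Logical array, `TRUE` inside the head region.
#' @export
brain_mask <- function(b, spec = attr(b, "phantom_spec")) {
  if (is.null(spec)) stop("no phantom spec available; pass 'spec' explicitly", call. = FALSE)
  dims <- spec$dims
  if (!length(spec$ellipsoids)) return(array(FALSE, dims))
  e <- spec$ellipsoids[[1]]
  ellipsoid_mask(dims, e$center, e$semiaxes, e$angle_deg)
}
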
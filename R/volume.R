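# Core 3D volume container and neighborhood geometry shared by all modules.

#' Create a 3D image stack
#'
#' An `image_stack` is a 3D numeric array of nonnegative voxel intensities
#' with physical voxel spacing in millimetres attached. The array axes are
#' (row, column, slice); the slice axis is the third axis.
#'
#' @param values 3D numeric array of finite, nonnegative intensities
#'   (arbitrary units).
#' @param spacing Numeric length-3 vector of strictly positive voxel
#'   dimensions in mm: (row, column, slice). Slice spacing is typically the
#'   slice thickness and is often several times the in-plane spacing.
#' @return An `image_stack` object (a numeric array with a `spacing`
#'   attribute).
#' @examples
#' vol <- image_stack(array(1, c(4, 4, 3)), spacing = c(0.45, 0.45, 4.5))
#' dim(vol)
#' stack_spacing(vol)
#' @export
image_stack <- function(values, spacing = c(1, 1, 1)) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("'values' must be a 3D array", call. = FALSE)
  }
  if (!is.numeric(values)) stop("'values' must be numeric", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values))) {
    stop("intensities must all be finite", call. = FALSE)
  }
  if (any(values < 0)) {
    stop("intensities must be nonnegative (magnitude data)", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("'spacing' must be 3 strictly positive mm values", call. = FALSE)
  }
  if (any(dim(values) < 1L)) stop("all dimensions must be positive", call. = FALSE)
  structure(values + 0, spacing = spacing, class = c("image_stack", "array"))
}

#' @rdname image_stack
#' @param x An `image_stack`.
#' @export
stack_spacing <- function(x) {
  sp <- attr(x, "spacing")
  if (is.null(sp)) {
    warning("no spacing metadata; assuming unit isotropic spacing (1,1,1) mm")
    sp <- c(1, 1, 1)
  }
  sp
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x)
  sp <- stack_spacing(x)
  cat(sprintf(
    "<image_stack> %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm\n",
    d[1], d[2], d[3], sp[1], sp[2], sp[3]
  ))
  cat(sprintf(
    "  intensity range [%.4g, %.4g], mean %.4g\n",
    min(x), max(x), mean(x)
  ))
  invisible(x)
}

#' Build a 3D neighborhood system
#'
#' The neighborhood system holds the integer index offsets of the
#' 26-connected neighborhood (all voxels differing by at most 1 along each
#' axis) together with the physical Euclidean distance of each offset, given
#' the voxel spacing. Reduced 6- and 18-connected systems are available as a
#' convenience; the full 26-voxel system is the default used by the denoiser.
#'
#' @param spacing Voxel spacing in mm (length 3).
#' @param connectivity One of 26 (default), 18, or 6.
#' @return A `neighborhood_system`: list with `offsets` (n x 3 integer
#'   matrix), `distances` (mm, per offset), `spacing` and `connectivity`.
#' @examples
#' ns <- neighborhood_system(c(0.45, 0.45, 4.5))
#' nrow(ns$offsets)  # 26
#' range(ns$distances)
#' @export
neighborhood_system <- function(spacing = c(1, 1, 1), connectivity = 26) {
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("'spacing' must be 3 strictly positive mm values", call. = FALSE)
  }
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L)) {
    stop("'connectivity' must be 6, 18 or 26", call. = FALSE)
  }
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  ord <- rowSums(abs(g))   # 1 = face, 2 = edge, 3 = corner neighbors
  keep <- switch(as.character(connectivity),
    "6"  = ord == 1,
    "18" = ord <= 2,
    "26" = rep(TRUE, nrow(g))
  )
  offsets <- g[keep, , drop = FALSE]
  storage.mode(offsets) <- "integer"
  dimnames(offsets) <- NULL
  distances <- sqrt(colSums((t(offsets) * spacing)^2))
  structure(
    list(offsets = offsets, distances = distances,
         spacing = spacing, connectivity = connectivity),
    class = "neighborhood_system"
  )
}

#' @export
print.neighborhood_system <- function(x, ...) {
  cat(sprintf(
    "<neighborhood_system> %d-connected, spacing %.4g x %.4g x %.4g mm, distances [%.4g, %.4g] mm\n",
    x$connectivity, x$spacing[1], x$spacing[2], x$spacing[3],
    min(x$distances), max(x$distances)
  ))
  invisible(x)
}

#' In-bounds neighbors of a voxel
#'
#' Returns the members of the (by default 26-voxel) neighborhood of `k` that
#' fall inside the volume. Neighborhoods are clipped at the volume faces: no
#' padding or wrap-around is applied, so face, edge and corner voxels have
#' 17, 11 and 7 neighbors respectively in the full system.
#'
#' @param k Integer length-3 voxel index (1-based: row, column, slice).
#' @param dims Integer length-3 volume dimensions.
#' @param nsys A [neighborhood_system()]; connectivity is taken from it.
#' @return Integer matrix with one in-bounds neighbor index per row.
#' @examples
#' nrow(neighbors(c(3, 3, 3), c(5, 5, 5)))  # 26 (interior)
#' nrow(neighbors(c(1, 1, 1), c(5, 5, 5)))  # 7 (corner)
#' @export
neighbors <- function(k, dims, nsys = neighborhood_system()) {
  k <- as.integer(k); dims <- as.integer(dims)
  if (length(k) != 3L || length(dims) != 3L) {
    stop("'k' and 'dims' must have length 3", call. = FALSE)
  }
  if (any(k < 1L) || any(k > dims)) {
    stop(sprintf("voxel index (%d,%d,%d) out of bounds for dims (%d,%d,%d)",
                 k[1], k[2], k[3], dims[1], dims[2], dims[3]), call. = FALSE)
  }
  q <- sweep(nsys$offsets, 2L, k, `+`)
  inb <- q[, 1] >= 1L & q[, 1] <= dims[1] &
         q[, 2] >= 1L & q[, 2] <= dims[2] &
         q[, 3] >= 1L & q[, 3] <= dims[3]
  q[inb, , drop = FALSE]
}

#' Physical distance between two neighboring voxels
#'
#' Euclidean distance in mm between voxel centres,
#' `sqrt(sum((dindex * spacing)^2))`. This is the distance weight entering
#' the prior energy; with anisotropic spacing, cross-slice neighbors are
#' physically farther and therefore contribute less smoothing.
#'
#' @param k,q Integer length-3 voxel indices; must differ.
#' @param spacing Voxel spacing in mm.
#' @return Distance in mm (scalar).
#' @examples
#' pair_distance(c(1, 1, 1), c(1, 1, 2), c(0.45, 0.45, 4.5))  # 4.5
#' @export
pair_distance <- function(k, q, spacing = c(1, 1, 1)) {
  k <- as.numeric(k); q <- as.numeric(q)
  if (all(k == q)) stop("'k' and 'q' must be distinct voxels", call. = FALSE)
  sqrt(sum(((k - q) * as.numeric(spacing))^2))
}

# --- internal shift machinery -----------------------------------------------

# Index ranges such that x[dst] and x[src] align voxel k with neighbor k+o.
offset_ranges <- function(dims, o) {
  dst <- vector("list", 3L)
  src <- vector("list", 3L)
  for (ax in 1:3) {
    d <- o[ax]
    lo <- max(1L, 1L - d)
    hi <- min(dims[ax], dims[ax] - d)
    i <- if (lo > hi) integer(0) else seq.int(lo, hi)
    dst[[ax]] <- i
    src[[ax]] <- i + d
  }
  list(dst = dst, src = src)
}

# Apply f(center_block, neighbor_block) accumulating over all offsets.
# Used by the vectorized energy / hyperparameter / solver code paths.
sub3 <- function(x, idx) x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]

`sub3<-` <- function(x, idx, value) {
  x[idx[[1]], idx[[2]], idx[[3]]] <- value
  x
}
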
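# Quality indexes: masked MSE, slice-wise SSIM, SNR in dB, residual maps.

check_pair_mask <- function(x, y, mask) {
  if (!identical(dim(x), dim(y))) stop("volume dimensions do not match", call. = FALSE)
  if (!is.null(mask)) {
    if (!is.logical(mask) || !identical(dim(mask), dim(x))) {
      stop("'mask' must be a logical array matching the volumes", call. = FALSE)
    }
    if (!any(mask)) stop("'mask' is empty", call. = FALSE)
  }
}

#' Masked mean square error
#'
#' Mean of `(x - y)^2` over the masked voxels (all voxels when `mask` is
#' `NULL`). Units: intensity squared.
#'
#' @param x,y Volumes ([image_stack()] or plain 3D arrays) of equal dims.
#' @param mask Optional logical array selecting the evaluation region.
#' @return Scalar MSE.
#' @export
masked_mse <- function(x, y, mask = NULL) {
  check_pair_mask(x, y, mask)
  d2 <- (unclass(x) - unclass(y))^2
  if (is.null(mask)) mean(d2) else mean(d2[mask])
}

gauss_kernel_1d <- function(size = 11L, sd = 1.5) {
  h <- (size - 1L) / 2
  k <- exp(-((-h:h)^2) / (2 * sd^2))
  k / sum(k)
}

# Separable Gaussian filtering of a matrix with edge renormalization: near
# the borders the kernel is re-scaled to the in-bounds mass, so local means
# remain unbiased.
filter2_gauss <- function(x, kernel) {
  h <- (length(kernel) - 1L) / 2
  one_axis <- function(m) {
    n <- nrow(m)
    acc <- matrix(0, n, ncol(m))
    norm <- matrix(0, n, ncol(m))
    for (s in -h:h) {
      w <- kernel[s + h + 1L]
      lo <- max(1L, 1L - s)
      hi <- min(n, n - s)
      if (lo > hi) next
      dst <- seq.int(lo, hi)
      src <- dst + s
      acc[dst, ] <- acc[dst, ] + w * m[src, , drop = FALSE]
      norm[dst, ] <- norm[dst, ] + w
    }
    acc / norm
  }
  t(one_axis(t(one_axis(x))))
}

#' Masked structural similarity index
#'
#' Single-scale SSIM with the standard constants (Gaussian window of size 11,
#' window sd 1.5, K1 = 0.01, K2 = 0.03), computed slice-wise in 2D and
#' averaged over the masked voxels. The dynamic range `L` defaults to the
#' range of the two volumes jointly; pass the noise-free ground truth's range
#' for evaluations against a reference.
#'
#' @inheritParams masked_mse
#' @param data_range Dynamic range `L`; `NULL` infers `diff(range(x, y))`.
#' @return Scalar SSIM in `[-1, 1]` (1 for identical volumes).
#' @export
masked_ssim <- function(x, y, mask = NULL, data_range = NULL) {
  check_pair_mask(x, y, mask)
  xv <- unclass(x); yv <- unclass(y)
  if (is.null(data_range)) data_range <- max(xv, yv) - min(xv, yv)
  if (data_range <= 0) data_range <- 1
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  k <- gauss_kernel_1d()
  dims <- dim(xv)
  ssim_map <- array(NA_real_, dims)
  for (s in seq_len(dims[3])) {
    xs <- xv[, , s]; ys <- yv[, , s]
    mux <- filter2_gauss(xs, k)
    muy <- filter2_gauss(ys, k)
    vx <- pmax(filter2_gauss(xs^2, k) - mux^2, 0)
    vy <- pmax(filter2_gauss(ys^2, k) - muy^2, 0)
    cxy <- filter2_gauss(xs * ys, k) - mux * muy
    ssim_map[, , s] <- ((2 * mux * muy + C1) * (2 * cxy + C2)) /
      ((mux^2 + muy^2 + C1) * (vx + vy + C2))
  }
  if (is.null(mask)) mean(ssim_map) else mean(ssim_map[mask])
}

#' Residual map (before minus after)
#'
#' Signed voxelwise difference between a volume before and after filtering.
#' Applied to (noisy, denoised) it shows what the filter removed; applied to
#' (denoised, truth) it is the residual error map.
#'
#' @param before,after Volumes of equal dims.
#' @return An [image_stack()]-shaped array of signed differences (may be
#'   negative, so it is returned as a plain array with a `spacing`
#'   attribute).
#' @export
residual_map <- function(before, after) {
  check_pair_mask(before, after, NULL)
  out <- unclass(before) - unclass(after)
  attr(out, "spacing") <- attr(before, "spacing")
  out
}

#' Signal-to-noise ratio in dB
#'
#' `10 * log10(mean(b^2 over mask) / (2 sigma^2))`: the mean squared signal
#' in the evaluation region over the Rayleigh noise second moment
#' `E[n^2] = 2 sigma^2`. This convention is pinned so SNR figures are
#' comparable across runs of this package; other conventions differ by
#' constant offsets.
#'
#' @param b Noise-free volume.
#' @param sigma Noise scale.
#' @param mask Optional logical evaluation mask.
#' @return SNR in dB.
#' @export
snr_db <- function(b, sigma, mask = NULL) {
  check_sigma(sigma)
  bv <- unclass(b)
  if (!is.null(mask)) {
    if (!any(mask)) stop("'mask' is empty", call. = FALSE)
    bv <- bv[mask]
  }
  10 * log10(mean(bv^2) / (2 * sigma^2))
}

#' Evaluation report
#'
#' Bundles the quality indexes for a (truth, test) volume pair over an
#' evaluation mask. Serializes losslessly to/from JSON via
#' [report_to_json()] and [report_from_json()].
#'
#' @param truth Noise-free reference volume.
#' @param test Volume under evaluation (noisy or denoised).
#' @param mask Logical evaluation mask.
#' @param sigma Optional noise scale; adds `snr_db` to the report.
#' @return An `evaluation_report` list: `mse`, `ssim`, `snr_db` (or `NA`),
#'   `n_voxels`.
#' @export
evaluation_report <- function(truth, test, mask = NULL, sigma = NULL) {
  structure(list(
    mse = masked_mse(truth, test, mask),
    ssim = masked_ssim(truth, test, mask,
                       data_range = max(unclass(truth)) - min(unclass(truth))),
    snr_db = if (is.null(sigma)) NA_real_ else snr_db(truth, sigma, mask),
    n_voxels = if (is.null(mask)) length(unclass(truth)) else sum(mask)
  ), class = "evaluation_report")
}

#' @rdname evaluation_report
#' @param report An `evaluation_report`.
#' @param path File path for the JSON document.
#' @export
report_to_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname evaluation_report
#' @export
report_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$snr_db <- if (is.null(x$snr_db)) NA_real_ else x$snr_db
  structure(x[c("mse", "ssim", "snr_db", "n_voxels")], class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> n = %d voxels\n  MSE  %.6g\n  SSIM %.6g\n",
              x$n_voxels, x$mse, x$ssim))
  if (is.finite(x$snr_db)) cat(sprintf("  SNR  %.4g dB\n", x$snr_db))
  invisible(x)
}
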
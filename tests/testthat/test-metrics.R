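test_that("masked MSE: identities, constant offsets, loop oracle, mask handling", {
  set.seed(51)
  dims <- c(6, 5, 4)
  x <- image_stack(array(runif(prod(dims), 0, 10), dims))
  y <- image_stack(array(runif(prod(dims), 0, 10), dims))
  mask <- array(runif(prod(dims)) > 0.4, dims)

  expect_equal(masked_mse(x, x, mask), 0)
  expect_equal(masked_mse(x, image_stack(unclass(x) + 2), mask), 4)

  # naive two-pass loop oracle
  acc <- 0; n <- 0
  for (i in seq_len(prod(dims))) {
    if (mask[i]) { acc <- acc + (unclass(x)[i] - unclass(y)[i])^2; n <- n + 1 }
  }
  expect_equal(masked_mse(x, y, mask), acc / n, tolerance = 1e-12)

  expect_error(masked_mse(x, y, array(FALSE, dims)), "empty")
  expect_error(masked_mse(x, image_stack(array(1, c(2, 2, 2)))), "dimensions")
})

test_that("SSIM: self-similarity, symmetry, range", {
  set.seed(52)
  dims <- c(24, 24, 3)
  x <- image_stack(array(runif(prod(dims), 20, 100), dims))
  y <- add_noise(x, 5, seed = 1)
  expect_equal(masked_ssim(x, x), 1.0)
  expect_equal(masked_ssim(x, y), masked_ssim(y, x))
  s <- masked_ssim(x, y)
  expect_gt(s, -1)
  expect_lte(s, 1)
})

test_that("SSIM degrades monotonically with growing noise", {
  b <- generate_head_phantom(phantom_spec(dims = c(64, 64, 3)))
  L <- diff(range(unclass(b)))
  vals <- sapply(c(1, 2, 4, 8), function(sg) {
    a <- add_noise(b, sg, seed = 77)
    masked_ssim(b, a, data_range = L)
  })
  expect_true(all(diff(vals) < 0))
})

test_that("SSIM matches scikit-image's implementation on interior windows", {
  set.seed(53)
  x <- matrix(runif(32 * 32, 20, 100), 32)
  y <- pmax(x + matrix(rnorm(32 * 32, 0, 5), 32), 0)
  mask <- array(FALSE, c(32, 32, 1)); mask[7:26, 7:26, 1] <- TRUE
  ours <- masked_ssim(image_stack(array(x, c(32, 32, 1))),
                      image_stack(array(y, c(32, 32, 1))),
                      mask, data_range = 80)
  td <- tempfile(); dir.create(td)
  utils::write.csv(x, file.path(td, "x.csv"), row.names = FALSE)
  utils::write.csv(y, file.path(td, "y.csv"), row.names = FALSE)
  script <- paste(
    "import numpy as np",
    "from skimage.metrics import structural_similarity",
    sprintf("x = np.genfromtxt(r'%s', delimiter=',', skip_header=1)", file.path(td, "x.csv")),
    sprintf("y = np.genfromtxt(r'%s', delimiter=',', skip_header=1)", file.path(td, "y.csv")),
    "s, m = structural_similarity(x, y, gaussian_weights=True, sigma=1.5,",
    "    use_sample_covariance=False, data_range=80, full=True)",
    "print(repr(float(m[6:26, 6:26].mean())))",
    sep = "\n")
  out <- system2("python", c("-c", shQuote(script)), stdout = TRUE)
  theirs <- as.numeric(out[length(out)])
  expect_equal(ours, theirs, tolerance = 1e-9)
})

test_that("residual map is the exact signed difference", {
  set.seed(54)
  dims <- c(5, 5, 3)
  before <- image_stack(array(runif(prod(dims), 0, 10), dims))
  after <- image_stack(array(runif(prod(dims), 0, 10), dims))
  r <- residual_map(before, after)
  expect_equal(unclass(before) - r, unclass(after) + 0, tolerance = 0)
  expect_true(all(residual_map(before, before) == 0))
})

test_that("SNR in dB follows the pinned Rayleigh-second-moment convention", {
  dims <- c(4, 4, 4)
  # mean(b^2) = 2 sigma^2 gives 0 dB
  b <- image_stack(array(sqrt(2) * 3, dims))
  expect_equal(snr_db(b, 3), 0)
  # doubling sigma costs 20*log10(2) dB
  b2 <- image_stack(array(10, dims))
  expect_equal(snr_db(b2, 2) - snr_db(b2, 4), 20 * log10(2))
  sgs <- c(0.5, 1, 2, 4, 8)
  expect_true(all(diff(sapply(sgs, function(s) snr_db(b2, s))) < 0))
})

test_that("evaluation reports round-trip through JSON losslessly", {
  ref <- reference_phantom_run()
  rep <- evaluation_report(ref$truth, ref$noisy, ref$mask, sigma = ref$sigma)
  expect_gte(rep$mse, 0)
  expect_lte(rep$ssim, 1)
  expect_gte(rep$n_voxels, 1L)
  f <- tempfile(fileext = ".json")
  report_to_json(rep, f)
  rt <- report_from_json(f)
  expect_equal(rt$mse, rep$mse)
  expect_equal(rt$ssim, rep$ssim)
  expect_equal(rt$snr_db, rep$snr_db)
  expect_equal(rt$n_voxels, rep$n_voxels)
})
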
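test_that("voxel objective: barrier, likelihood value at its minimizer, zero prior", {
  sigma <- 2
  ak <- 10
  # no neighbors: value at bk = ak - sigma is log(sigma) + 1/2
  expect_equal(voxel_objective(ak - sigma, ak, sigma), log(sigma) + 0.5)
  # infeasible candidates
  expect_identical(voxel_objective(c(-1, 0, ak, ak + 1), ak, sigma),
                   rep(Inf, 4))
  # objective diverges (logarithmically) approaching the right endpoint
  expect_gt(voxel_objective(ak - 1e-12, ak, sigma),
            voxel_objective(ak - 1e-6, ak, sigma))
  expect_gt(voxel_objective(ak - 1e-6, ak, sigma),
            voxel_objective(ak - 1e-2, ak, sigma))
  # neighbors equal to the candidate contribute nothing
  expect_equal(
    voxel_objective(5, ak, sigma, neighbor_values = rep(5, 4), pair_weights = rep(2, 4)),
    voxel_objective(5, ak, sigma)
  )
  expect_error(voxel_objective(5, ak, sigma, neighbor_values = 1, pair_weights = c(1, 2)),
               "equal length")
})

test_that("per-voxel minimizer: closed form, prior-dominated limit, grid oracle", {
  # likelihood only: stationary point at ak - sigma
  for (sigma in c(0.5, 2, 4)) {
    expect_lt(abs(minimize_voxel(20, sigma) - (20 - sigma)), 1e-8)
  }
  # overwhelming prior pulls to the common neighbor value
  v <- 6
  b <- minimize_voxel(20, 2, neighbor_values = rep(v, 6), pair_weights = rep(1e8, 6))
  expect_equal(b, v, tolerance = 1e-4)

  # random instances against a dense grid search
  set.seed(41)
  for (i in 1:50) {
    ak <- runif(1, 1, 100)
    sigma <- runif(1, 0.5, 8)
    nn <- sample(0:26, 1)
    nv <- runif(nn, 0, ak)
    w <- 10^runif(nn, -4, 2)
    bstar <- minimize_voxel(ak, sigma, nv, w, tol = 1e-10)
    grid <- seq(1e-6 * ak, ak * (1 - 1e-6), length.out = 1e5)
    fg <- voxel_objective(grid, ak, sigma, nv, w)
    expect_lt(abs(bstar - grid[which.min(fg)]), 2 * ak / 1e5)
  }
})

test_that("ICM sweeps decrease the global objective and reach a fixed point", {
  set.seed(42)
  for (trial in 1:10) {
    a <- random_stack(c(8, 8, 8), 10, 60)
    sigma <- runif(1, 1, 5)
    b <- image_stack(pmax(unclass(a) - sigma, 1e-6))
    h <- update_hyperparameters(b, floor = 0.1)
    nsys <- neighborhood_system()
    ord <- if (trial %% 2) "checkerboard" else "raster"
    cfg <- solver_config(sweep_order = ord)
    obj <- global_objective(b, a, sigma, h, nsys)
    for (s in 1:3) {
      b <- icm_sweep(b, a, sigma, h, nsys, cfg)
      obj_new <- global_objective(b, a, sigma, h, nsys)
      expect_lte(obj_new, obj + 1e-9 * abs(obj))
      obj <- obj_new
    }
    # iterate to the coordinate-wise minimum; a further sweep is then inert
    delta <- Inf
    it <- 0L
    while (delta > 1e-7 && it < 200L) {
      b_new <- icm_sweep(b, a, sigma, h, nsys, cfg)
      delta <- max(abs(unclass(b_new) - unclass(b)))
      b <- b_new
      it <- it + 1L
    }
    b2 <- icm_sweep(b, a, sigma, h, nsys, cfg)
    expect_lt(max(abs(unclass(b2) - unclass(b))), 1e-6)
  }
})

test_that("checkerboard and raster sweeps agree at the coordinate-wise minimum", {
  set.seed(43)
  a <- random_stack(c(6, 6, 6), 20, 50)
  sigma <- 3
  b0 <- image_stack(pmax(unclass(a) - sigma, 1e-6))
  h <- update_hyperparameters(b0, floor = 0.5)
  nsys <- neighborhood_system()
  run_to_fp <- function(ord) {
    b <- b0
    cfg <- solver_config(sweep_order = ord)
    for (s in 1:40) b <- icm_sweep(b, a, sigma, h, nsys, cfg)
    b
  }
  expect_lt(max(abs(unclass(run_to_fp("checkerboard")) - unclass(run_to_fp("raster")))),
            1e-6)
})

test_that("flat input denoises to the flat likelihood solution", {
  a <- image_stack(array(50, c(8, 8, 8)))
  res <- run_map_denoise(a, sigma = 2, cfg = solver_config(max_outer_iterations = 5))
  expect_lt(max(abs(unclass(res$b_hat) - 48)), 1e-5)
  expect_equal(diff(range(unclass(res$b_hat))), 0, tolerance = 1e-6)
})

test_that("denoising result satisfies its invariants and is deterministic", {
  ref <- reference_phantom_run()
  res <- ref$fit
  expect_true(all(unclass(res$b_hat) > 0))
  expect_true(all(unclass(res$b_hat) < unclass(ref$noisy)))
  expect_length(res$mean_correction_trace, res$iterations_run)
  expect_length(res$objective_trace, res$iterations_run)
  expect_true(all(is.finite(res$mean_correction_trace)))
  expect_true(all(res$mean_correction_trace >= 0))
  expect_true(res$converged)

  small <- image_stack(unclass(ref$noisy)[1:20, 1:20, 1:5],
                       spacing = stack_spacing(ref$noisy))
  r1 <- run_map_denoise(small, sigma = 4)
  r2 <- run_map_denoise(small, sigma = 4)
  expect_identical(r1$b_hat, r2$b_hat)
  expect_identical(r1$objective_trace, r2$objective_trace)
})

test_that("reduced neighborhood systems are accepted by the solver", {
  set.seed(44)
  a <- add_noise(image_stack(array(40, c(10, 10, 6))), 3, seed = 2)
  for (conn in c(6L, 18L)) {
    r <- run_map_denoise(a, sigma = 3,
                         cfg = solver_config(max_outer_iterations = 4, connectivity = conn))
    expect_true(all(unclass(r$b_hat) > 0 & unclass(r$b_hat) < unclass(a)))
  }
})

test_that("sigma is estimated from background when not supplied", {
  ref <- reference_phantom_run()
  # corners of the head phantom are air: pure Rayleigh noise
  res <- run_map_denoise(ref$noisy, sigma = NULL,
                         cfg = solver_config(max_outer_iterations = 2))
  expect_lt(abs(res$sigma - 4) / 4, 0.1)
})
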
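test_that("prior energy matches hand-computed and loop-oracle values", {
  # constant volume: zero energy
  b <- image_stack(array(7, c(4, 4, 4)))
  h <- hyperparameter_field(array(1, c(4, 4, 4)))
  expect_equal(lgmrf_energy(b, h), 0)

  # 2x1x1 volume with values (0, 1), unit spacing, theta^2 = 1: the single
  # unordered pair contributes from both directions, 2 * 1 / (2*1*1) = 1
  b2 <- image_stack(array(c(0, 1), c(2, 1, 1)))
  h2 <- hyperparameter_field(array(1, c(2, 1, 1)))
  expect_equal(lgmrf_energy(b2, h2), 1.0)

  # random volume vs brute-force loop oracle, anisotropic spacing
  set.seed(31)
  sp <- c(0.8, 1.1, 2.5)
  vol <- array(runif(3 * 4 * 3, 0, 10), c(3, 4, 3))
  th <- array(runif(3 * 4 * 3, 0.5, 2), c(3, 4, 3))
  bv <- image_stack(vol, spacing = sp)
  expect_equal(
    lgmrf_energy(bv, hyperparameter_field(th), neighborhood_system(sp)),
    oracle_energy(vol, th, sp),
    tolerance = 1e-12
  )
})

test_that("energy scales inversely with theta^2 and ignores global shifts", {
  set.seed(32)
  vol <- array(runif(60, 0, 5), c(5, 4, 3))
  th <- array(runif(60, 0.5, 2), c(5, 4, 3))
  b <- image_stack(vol)
  e1 <- lgmrf_energy(b, hyperparameter_field(th))
  e2 <- lgmrf_energy(b, hyperparameter_field(2 * th))
  expect_equal(e2, e1 / 2)
  expect_gt(e1, 0)
  b_shift <- image_stack(vol + 100)
  expect_equal(lgmrf_energy(b_shift, hyperparameter_field(th)), e1)
})

test_that("hyperparameter update equals the brute-force oracle exactly", {
  # integer volumes make the comparison exact (no summation-order effects)
  set.seed(33)
  for (trial in 1:5) {
    vol <- array(sample(0:9, 125, replace = TRUE), c(5, 5, 5))
    h <- update_hyperparameters(image_stack(vol), floor = 1e-300)
    expect_identical(h$theta2, oracle_theta2(vol))
  }
})

test_that("hyperparameter update: floored constants, center spike, edge response", {
  # constant volume: all raw values 0, floored
  h <- update_hyperparameters(image_stack(array(5, c(4, 4, 4))), floor = 1e-9)
  expect_true(all(h$theta2 == 1e-9))

  # 3x3x3 with center 1, rest 0: raw theta^2 at center = 26/26 = 1
  vol <- array(0, c(3, 3, 3)); vol[2, 2, 2] <- 1
  h2 <- update_hyperparameters(image_stack(vol), floor = 1e-12)
  expect_equal(h2$theta2[2, 2, 2], 1.0)

  # step edge: theta^2 strictly larger at the edge than in flat interiors
  vol3 <- array(0, c(8, 8, 8)); vol3[, 5:8, ] <- 10
  h3 <- update_hyperparameters(image_stack(vol3), floor = 1e-12)
  expect_gt(min(h3$theta2[, 4:5, ]), max(h3$theta2[, c(1:2, 7:8), ]))
})

test_that("pairwise hyperparameter is the symmetric arithmetic mean", {
  expect_equal(pair_hyperparameter(2, 4), 3)
  expect_equal(pair_hyperparameter(5, 5), 5)
  set.seed(34)
  x <- runif(20); y <- runif(20)
  expect_equal(pair_hyperparameter(x, y), pair_hyperparameter(y, x))
})

test_that("uninformative initialization makes the first estimate likelihood-driven", {
  set.seed(35)
  dims <- c(8, 8, 6)
  # moderate spatial variation (sd ~ 7 intensity units), low noise scale
  vol <- array(60 + 7 * sin(seq_len(prod(dims))), dims)
  a <- image_stack(vol)
  h <- initialize_hyperparameters(a)
  expect_equal(h$theta2[1, 1, 1], 1e6 * var(as.vector(vol)))
  expect_equal(length(unique(as.vector(h$theta2))), 1L)

  sigma <- 0.5
  b0 <- image_stack(pmax(unclass(a) - sigma, 1e-9 * max(a)))
  b1 <- icm_sweep(b0, a, sigma, h)
  expect_lt(max(abs(unclass(b1) - (unclass(a) - sigma))), 1e-6)
})
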
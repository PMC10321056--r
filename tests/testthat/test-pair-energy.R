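test_that("12-6 form has its root at sigma and minimum -eps at r_min", {
  p <- vdw_params(r_min = 4, epsilon = 0.25)
  sigma <- 4 / 2^(1 / 6)
  expect_equal(lj_12_6(sigma, p), 0, tolerance = 1e-12)
  expect_equal(lj_12_6(4, p), -0.25, tolerance = 1e-12)
  expect_lt(abs(lj_12_6(40, p)) / 0.25, 1e-4)
  expect_error(lj_12_6(0, p), "r must be")
})

test_that("buffered 14-7 form equals -eps at r_min and decays from below", {
  p <- vdw_params(3.8, 0.3, form = "buffered_14_7")
  expect_equal(buffered_14_7(3.8, p), -0.3, tolerance = 1e-12)
  far <- buffered_14_7(c(50, 100), p)
  expect_true(all(far < 0) && all(abs(far) < 1e-6))
  # softer core than 12-6 with the same (r_min, eps): lower on the
  # repulsive wall (direct evaluation at rho = 0.7, 0.8, 0.9)
  p126 <- vdw_params(3.8, 0.3)
  for (rho in c(0.7, 0.8, 0.9))
    expect_lt(buffered_14_7(rho * 3.8, p), lj_12_6(rho * 3.8, p126))
})

test_that("both vdW forms hit -eps at r_min for random parameter draws", {
  set.seed(1234)
  for (i in 1:100) {
    rmin <- runif(1, 2, 6)
    eps <- runif(1, 0.01, 1)
    expect_equal(lj_12_6(rmin, vdw_params(rmin, eps)), -eps,
                 tolerance = 1e-8)
    expect_equal(buffered_14_7(rmin, vdw_params(rmin, eps, "buffered_14_7")),
                 -eps, tolerance = 1e-8)
  }
})

test_that("pair energies are symmetric under particle exchange", {
  p1 <- vdw_params(3.2, 0.11)
  p2 <- vdw_params(4.4, 0.37)
  r <- seq(2.5, 9, 0.5)
  expect_equal(lj_12_6(r, p1, p2), lj_12_6(r, p2, p1))
  q1 <- vdw_params(3.2, 0.11, "buffered_14_7")
  q2 <- vdw_params(4.4, 0.37, "buffered_14_7")
  expect_equal(buffered_14_7(r, q1, q2), buffered_14_7(r, q2, q1))
})

test_that("Coulomb term follows the 332.0637/r law", {
  expect_equal(coulomb(3, 0, 1), 0)
  expect_equal(coulomb(3.32, 1, -1), -100.019, tolerance = 1e-4)
  expect_equal(coulomb(4, 1, 1), 2 * coulomb(8, 1, 1))
  expect_error(coulomb(0, 1, 1), "r must be")
})

test_that("fitting a 12-6 target to itself recovers the parameters", {
  target <- vdw_params(4.0, 0.1, form = "lj_12_6")
  fit <- fit_lj_to_14_7(target, r_range = c(3.2, 8))
  expect_equal(fit$params$r_min, 4.0, tolerance = 1e-6)
  expect_equal(fit$params$epsilon, 0.1, tolerance = 1e-6)
  expect_lt(fit$residual_norm, 1e-10)
})

test_that("12-6 fit to a buffered 14-7 curve finds the minimum region", {
  target <- vdw_params(4.0, 0.1, form = "buffered_14_7")
  fit <- fit_lj_to_14_7(target, r_range = c(3.4, 9), n_grid = 300)
  expect_lt(abs(fit$params$r_min - 4.0), 0.1)
  # grid-search oracle: the optimizer beats a dense parameter grid
  r <- fit$r_grid
  e_t <- fit$target_energy
  grid_best <- Inf
  for (rm in seq(3.6, 4.4, 0.02)) for (ep in seq(0.05, 0.2, 0.005)) {
    sse <- mean((lj_12_6(r, vdw_params(rm, ep)) - e_t)^2)
    grid_best <- min(grid_best, sse)
  }
  expect_lte(fit$residual_norm^2, grid_best * (1 + 1e-6))
})

test_that("weights concentrated at the minimum pin the fitted well depth", {
  target <- vdw_params(4.0, 0.1, form = "buffered_14_7")
  r <- seq(3.4, 9, length.out = 300)
  wts <- exp(-(r - 4.0)^2 / (2 * 0.05^2))
  fit <- fit_lj_to_14_7(target, r_range = c(3.4, 9), weights = wts,
                        n_grid = 300)
  expect_equal(fit$params$epsilon, 0.1, tolerance = 0.01)
})

test_that("interaction profile decomposes exactly and zeroes its reference", {
  host <- generate_host_geometry(3, 12, ring_charge = 0.05,
                                 ring_r_min = 3.8, ring_epsilon = 0.1)
  set.seed(66)
  z <- runif(2000, -2, 16)
  pos <- cbind(rnorm(2000, 0, 0.3), rnorm(2000, 0, 0.3), z)
  prof <- interaction_profile(pos, host, guest_charge = -1,
                              guest_vdw = vdw_params(4.4, 0.1),
                              reference_z = 15, bin_width = 0.5)
  occ <- prof$n_frames > 0
  expect_equal(prof$E_total[occ], prof$E_vdw[occ] + prof$E_coul[occ])
  # z = 15 lies in the bin centred at 15.25 (edges at multiples of 0.5)
  ref_bin <- which(prof$z == 15.25)
  expect_equal(prof$E_vdw[ref_bin], 0)
  expect_equal(prof$E_coul[ref_bin], 0)
})

test_that("neutral, epsilon-free host gives an identically zero profile", {
  host <- generate_host_geometry(3, 12, ring_charge = 0,
                                 ring_epsilon = 0)
  pos <- cbind(0, 0, seq(0, 16, 0.25))
  prof <- interaction_profile(pos, host, guest_charge = -1,
                              guest_vdw = vdw_params(4.4, 0),
                              reference_z = 15)
  occ <- prof$n_frames > 0
  expect_equal(prof$E_total[occ], rep(0, sum(occ)))
})

test_that("single axial charge reproduces the closed-form Coulomb curve", {
  host <- host_geometry(data.frame(x = 0, y = 0, z = 0, charge = 1,
                                   r_min = 3, epsilon = 0))
  zs <- seq(2.25, 15.75, 0.5)  # bin centres for bin_width 0.5
  pos <- cbind(0, 0, zs)
  prof <- interaction_profile(pos, host, guest_charge = -1,
                              guest_vdw = vdw_params(3, 0),
                              reference_z = 15, bin_width = 0.5)
  occ <- prof$n_frames > 0
  expected <- -332.0637 / zs
  # z = 15 lands in the bin centred at 15.25 (edges at multiples of 0.5)
  expected <- expected - expected[zs == 15.25]
  expect_equal(prof$E_coul[occ], expected, tolerance = 1e-9)
})
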
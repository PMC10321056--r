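make_window <- function(z, k_z = 0, z_center = 0, t = seq_along(z),
                        label = NULL) {
  umbrella_window(restraint_spec(z_center, k_z, label = label),
                  data.frame(t = t, z = z))
}

test_that("single unbiased window reduces WHAM to the histogram estimate", {
  set.seed(41)
  z <- c(rnorm(4000, -1.5, 0.7), rnorm(6000, 1.5, 0.9))
  w <- make_window(z)
  prof <- wham(list(w), bin_width = 0.25, reference_region = c(-1, 1))
  RT <- thermal_energy()
  grid <- prof$z
  h <- hist(z, breaks = c(grid - 0.125, max(grid) + 0.125), plot = FALSE)
  w_ref <- -RT * log(h$counts)
  w_ref[!is.finite(w_ref)] <- NA
  sel <- prof$occupied & grid >= -1 & grid <= 1
  w_ref <- w_ref - mean(w_ref[sel])
  expect_equal(prof$W[prof$occupied], w_ref[prof$occupied], tolerance = 1e-8)
})

test_that("duplicating every window leaves the estimate unchanged", {
  ds <- small_dataset()$windows[1:5]
  p1 <- wham(ds, reference_region = c(3, 4))
  p2 <- wham(c(ds, ds), reference_region = c(3, 4))
  expect_equal(p1$W, p2$W, tolerance = 1e-8)
})

test_that("disconnected window clusters are reported by name", {
  w1 <- make_window(rnorm(500, 0, 0.3), k_z = 1, z_center = 0, label = "a")
  w2 <- make_window(rnorm(500, 20, 0.3), k_z = 1, z_center = 20,
                    label = "b")
  expect_error(wham(list(w1, w2)), "disconnected")
  expect_error(wham(list(w1, w2)), "a")
})

test_that("WHAM recovers the landscape from the small biased dataset", {
  fx <- small_dataset()
  prof <- wham(fx$windows, reference_region = c(10, 12))
  ana <- analytic_pmf(fx$model, 2.5, prof$z, reference_region = c(10, 12))
  occ <- prof$occupied & prof$n_samples > 200
  rmse <- sqrt(mean((prof$W[occ] - ana$W[occ])^2))
  expect_lt(rmse, 0.35)
  # global minimum lands near the central well
  expect_lt(abs(prof$z[which.min(prof$W)]), 0.35)
})

test_that("histogram overlap has the documented limiting values", {
  set.seed(13)
  z <- rnorm(5000)
  w1 <- make_window(z, label = "w1")
  w2 <- make_window(z, z_center = 1e-9, label = "w2")
  ov <- histogram_overlap(list(w1, w2), bin_width = 0.2)
  expect_equal(ov$overlap, 1.0)
  w3 <- make_window(runif(500, 0, 1), label = "lo")
  w4 <- make_window(runif(500, 10, 11), z_center = 10, label = "hi")
  ov2 <- histogram_overlap(list(w3, w4), bin_width = 0.2)
  expect_equal(ov2$overlap, 0.0)
  expect_true(ov2$flagged)
})

test_that("overlap of unit Gaussians 2 A apart matches 2*pnorm(-1)", {
  set.seed(77)
  w1 <- make_window(rnorm(2e5, 0, 1), label = "g0")
  w2 <- make_window(rnorm(2e5, 2, 1), z_center = 2, label = "g2")
  ov <- histogram_overlap(list(w1, w2), bin_width = 0.1)
  expect_equal(ov$overlap, 2 * pnorm(-1), tolerance = 0.02)
})

test_that("referencing is idempotent, gauge-invariant and validated", {
  z <- seq(0, 10, 0.1)
  p <- pmf_profile(z, W = sin(z), reference_region = NULL)
  r1 <- set_reference(p, c(8, 10))
  expect_equal(set_reference(r1, c(8, 10))$W, r1$W, tolerance = 1e-12)
  expect_equal(mean(r1$W[z >= 8 & z <= 10]), 0, tolerance = 1e-12)
  # shifting by a constant then re-referencing recovers the profile
  shifted <- r1; shifted$W <- shifted$W + 7
  expect_equal(set_reference(shifted, c(8, 10))$W, r1$W, tolerance = 1e-12)
  # constant profile references to identically zero
  pc <- pmf_profile(z, W = rep(3.3, length(z)))
  expect_equal(set_reference(pc, c(0, 10))$W, rep(0, length(z)))
  expect_error(set_reference(r1, c(100, 101)), "no occupied bins")
})

test_that("blocks of duplicated data give zero block-to-block SD", {
  set.seed(55)
  pattern <- rnorm(600, 1, 0.5)
  w <- make_window(rep(pattern, 3), k_z = 0.5, z_center = 1,
                   t = 1:1800)
  bp <- block_pmfs(list(w), n_blocks = 3, bin_width = 0.25,
                   reference_region = c(0, 2))
  occ <- bp$mean$occupied
  expect_true(all(bp$mean$W_sd[occ] < 1e-9))
})

test_that("single-block mean equals one-pass WHAM and SD is absent", {
  ds <- small_dataset()$windows[1:4]
  bp <- block_pmfs(ds, n_blocks = 1, reference_region = c(2, 3))
  single <- wham(ds, reference_region = c(2, 3))
  expect_equal(bp$mean$W, single$W, tolerance = 1e-10)
  expect_true(all(is.na(bp$mean$W_sd)))
})

test_that("equilibration discard and empty blocks are validated", {
  w <- make_window(rnorm(100), k_z = 1, t = 1:100, label = "short")
  expect_error(block_pmfs(list(w), equil_discard = 1000), "no samples")
  # a window with a long sampling gap leaves its middle block empty
  w2 <- umbrella_window(restraint_spec(0, 1, label = "gappy"),
                        data.frame(t = c(seq(0.1, 10, 0.1), 100),
                                   z = rnorm(101)))
  w3 <- umbrella_window(restraint_spec(0, 1, label = "long"),
                        data.frame(t = seq(0.1, 100, 0.1), z = rnorm(1000)))
  expect_error(block_pmfs(list(w2, w3), n_blocks = 3), "gappy")
})

test_that("per-bin SD shrinks in expectation with longer blocks", {
  model <- default_landscape()
  lay <- umbrella_layout(0, 6, 1, k_z = 1.195, r_cyl = 2.5, k_fb = 11.95)
  mean_sd <- function(n_steps, seed) {
    ds <- generate_umbrella_dataset(
      model, lay, brownian_params(n_steps = n_steps, seed = seed))
    bp <- block_pmfs(ds, n_blocks = 3, reference_region = c(5, 6))
    occ <- bp$mean$occupied & bp$mean$n_samples > 100
    mean(bp$mean$W_sd[occ])
  }
  seeds <- 301:305
  short <- vapply(seeds, function(s) mean_sd(1.5e4, s), 0)
  long <- vapply(seeds, function(s) mean_sd(3e4, s), 0)
  expect_lt(mean(long), mean(short))
})
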
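# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# A small-but-real umbrella dataset on the default landscape: 13 windows
# over 0-12 A, 3e4 steps each.  Enough sampling for structural checks
# (overlap, gauge invariance, block machinery); the full-scale recovery
# checks live in test-acceptance.R.
small_dataset <- function() {
  fixture("small_dataset", function() {
    model <- default_landscape()
    layout <- umbrella_layout(0, 12, 1, k_z = 1.195, r_cyl = 2.5,
                              k_fb = 11.95)
    windows <- generate_umbrella_dataset(
      model, layout,
      brownian_params(n_steps = 3e4, seed = 7001))
    list(model = model, windows = windows)
  })
}

# Brute-force 2-D quadrature of the radial Boltzmann integral over the
# cylinder disc: independent oracle for analytic_pmf.
quadrature_pmf <- function(model, r_cyl, zs, n_xy = 801) {
  RT <- thermal_energy(model$temperature)
  xy <- seq(-r_cyl, r_cyl, length.out = n_xy)
  h <- xy[2] - xy[1]
  gx <- matrix(xy, n_xy, n_xy)
  gy <- t(gx)
  inside <- gx^2 + gy^2 < r_cyl^2
  radial <- exp(-0.5 * model$radial_k * (gx^2 + gy^2) / RT) * inside
  I_rad <- sum(radial) * h^2
  -RT * log(exp(-potential_z(model, zs) / RT) * I_rad)
}
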
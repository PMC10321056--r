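frame_at <- function(time, ion, waters) {
  structure(list(time = time, ion = ion,
                 waters = if (is.null(waters))
                   matrix(numeric(0), ncol = 3) else waters,
                 z_dist = ion[3]),
            class = "solvent_frame")
}

test_that("shell counting uses a closed-interval boundary", {
  ion <- c(0, 0, 0)
  expect_equal(unname(count_shell(frame_at(0, ion, NULL))), c(0, 0))
  at_cut <- frame_at(0, ion, matrix(c(3.4, 0, 0), ncol = 3))
  expect_equal(unname(count_shell(at_cut, water_cutoff = 3.4)[1]), 1)
  beyond <- frame_at(0, ion, matrix(c(3.4000001, 0, 0), ncol = 3))
  expect_equal(unname(count_shell(beyond, water_cutoff = 3.4)[1]), 0)
  # host contacts counted analogously
  host <- generate_host_geometry(3, 12)
  near <- frame_at(0, c(0, 0, 1), NULL)
  expect_equal(unname(count_shell(near, host = host)[2]), 12)
  far <- frame_at(0, c(0, 0, 40), NULL)
  expect_equal(unname(count_shell(far, host = host)[2]), 0)
})

test_that("Poisson-placed shell waters recover their expectation", {
  set.seed(90)
  lambda <- 6
  n <- 1e4
  counts <- vapply(seq_len(n), function(i) {
    k <- rpois(1, lambda)
    w <- if (k > 0) {
      u <- matrix(rnorm(3 * k), ncol = 3)
      u <- u / sqrt(rowSums(u^2)) * 3.4 * runif(k)^(1 / 3)
    } else NULL
    count_shell(frame_at(i, c(0, 0, 0), w), water_cutoff = 3.4)[1]
  }, integer(1))
  se <- sqrt(lambda / n)
  expect_lt(abs(mean(counts) - lambda), 3 * se)
})

test_that("hydration profile conserves frames and has exact SDs", {
  frames <- list(frame_at(1, c(0, 0, 0.2), matrix(c(1, 0, 0), ncol = 3)),
                 frame_at(2, c(0, 0, 0.3), matrix(c(1, 0, 0), ncol = 3)),
                 frame_at(3, c(0, 0, 5.0), NULL))
  hp <- hydration_profile(frames, bin_width = 1)
  expect_equal(sum(hp$n_frames), 3)
  occ <- hp$n_frames > 0
  expect_equal(hp$mean_water_count[occ], c(1, 0))
  expect_equal(hp$sd_water_count[occ], c(0, 0))
  # one giant bin swallows everything
  hp2 <- hydration_profile(frames, bin_width = 50)
  expect_equal(sum(hp2$n_frames > 0), 1)
  expect_equal(max(hp2$n_frames), 3)
})

test_that("generated frames reproduce the replacement curve per bin", {
  # flat landscape: the weak umbrella alone sets the z coverage
  model <- model_potential(NULL, radial_k = 0.25)
  host <- generate_host_geometry(3, 12)
  smodel <- solvent_model(bulk_count_mean = 6, replacement_halfwidth = 1,
                          k_wet = 0, k_dry = 1, cavity_radius = 3)
  w <- simulate_window(model, restraint_spec(6, 0.08, 2.5, 11.95),
                       brownian_params(n_steps = 4e4, seed = 17,
                                       initial_position = c(0, 0, 6)))
  frames <- generate_solvent_frames(smodel, w, host, seed = 18,
                                    frame_every = 10)
  # oracle expectation: mean of lambda(d) over the frames in each bin
  d <- vapply(frames, function(fr) sqrt(sum(fr$ion^2)), 0)
  lambda <- 6 * replacement_fraction(smodel, d)
  counts <- vapply(frames, function(fr)
    count_shell(fr, water_cutoff = smodel$shell_cutoff)[1], integer(1))
  z <- vapply(frames, `[[`, 0, "z_dist")
  bins <- floor(z / 0.5)
  for (b in unique(bins)) {
    sel <- bins == b
    if (sum(sel) < 50) next
    se <- sqrt(mean(lambda[sel]) / sum(sel))
    expect_lt(abs(mean(counts[sel]) - mean(lambda[sel])), 3.5 * se)
  }
  # far from the cavity the count approaches the bulk mean
  far <- d > 8
  expect_gt(sum(far), 100)
  expect_lt(abs(mean(counts[far]) - 6), 3 * sqrt(6 / sum(far)) + 6 * 0.005)
})

test_that("wetting classification applies the 3 A occupancy rule", {
  wet <- frame_at(1, c(0, 0, 10), matrix(c(2.9, 0, 0), ncol = 3))
  dry <- frame_at(2, c(0, 0, 10), matrix(c(3.1, 0, 0), ncol = 3))
  tr <- classify_wetting(list(wet, dry), cavity_cutoff = 3,
                         center = c(0, 0, 0))
  expect_equal(tr$wetted, c(TRUE, FALSE))
  expect_equal(tr$fraction_dewetted, 0.5)
  expect_error(classify_wetting(list(dry, wet), center = c(0, 0, 0)),
               "time-ordered")
})

test_that("wetting classification ignores water ordering within a frame", {
  set.seed(3)
  w <- matrix(rnorm(30, sd = 4), ncol = 3)
  f1 <- frame_at(1, c(0, 0, 0), w)
  f2 <- frame_at(1, c(0, 0, 0), w[sample(nrow(w)), ])
  expect_equal(classify_wetting(list(f1), center = c(0, 0, 0))$wetted,
               classify_wetting(list(f2), center = c(0, 0, 0))$wetted)
})

test_that("absorbing wet state: k_dry = 0 keeps every frame wetted", {
  model <- model_potential(NULL, radial_k = 0.25)
  host <- generate_host_geometry(3, 12)
  smodel <- solvent_model(k_wet = 0.05, k_dry = 0, cavity_radius = 3)
  w <- simulate_window(model, restraint_spec(12, 1, 2.5, 11.95),
                       brownian_params(n_steps = 2000, seed = 4,
                                       initial_position = c(0, 0, 12)))
  frames <- generate_solvent_frames(smodel, w, host, seed = 5)
  tr <- classify_wetting(frames, center = cavity_center(host))
  expect_equal(tr$fraction_dewetted, 0)
  expect_equal(tr$n_transitions, 0)
})

test_that("dwell statistics follow the two-state Markov closed forms", {
  model <- model_potential(NULL, radial_k = 0.25)
  host <- generate_host_geometry(3, 12)
  k <- 0.05  # 1/ps; symmetric rates -> stationary fraction 1/2
  smodel <- solvent_model(bulk_count_mean = 0, k_wet = k, k_dry = k,
                          cavity_radius = 3)
  w <- simulate_window(model, restraint_spec(15, 2, 2.5, 11.95),
                       brownian_params(n_steps = 2e4, seed = 6, dt = 1,
                                       diffusion = 0.01,
                                       initial_position = c(0, 0, 15)))
  frames <- generate_solvent_frames(smodel, w, host, seed = 7)
  tr <- classify_wetting(frames, center = cavity_center(host))
  n <- length(tr$wetted)
  dt_frame <- tr$frame_interval
  # correlated-series SE for the occupancy fraction: tau = 1/(k_wet+k_dry)
  se <- sqrt(0.25 * 2 * (1 / (2 * k)) / (n * dt_frame))
  expect_lt(abs(tr$fraction_dewetted - 0.5), 3 * se)
  # dwell means ~ dt/(1 - exp(-k dt)) for the frame-sampled chain
  expected_dwell <- dt_frame / (1 - exp(-k * dt_frame))
  expect_equal(mean(tr$dwell_wet), expected_dwell, tolerance = 0.1)
  expect_equal(mean(tr$dwell_dry), expected_dwell, tolerance = 0.1)
  # rates recovered from dwell means within 10%
  expect_equal(1 / mean(tr$dwell_dry), k, tolerance = 0.13)
})

test_that("wetting report summarises traces as documented", {
  all_wet <- lapply(1:50, function(i)
    frame_at(i, c(0, 0, 9), matrix(c(0.5, 0, 0), ncol = 3)))
  tr <- classify_wetting(all_wet, center = c(0, 0, 0))
  rep1 <- wetting_report(list(sys = tr))
  expect_equal(rep1$fraction_dewetted, 0)
  expect_equal(rep1$transitions_per_ns, 0)
  # alternating frames: a transition at every step
  alt <- lapply(1:40, function(i)
    frame_at(i, c(0, 0, 9),
             if (i %% 2) matrix(c(0.5, 0, 0), ncol = 3) else NULL))
  tra <- classify_wetting(alt, center = c(0, 0, 0))
  expect_equal(tra$n_transitions, 39)
  expect_equal(tra$fraction_dewetted, 0.5)
})
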
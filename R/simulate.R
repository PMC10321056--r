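#' Brownian-dynamics sampling parameters
#'
#' Parameters of the overdamped Langevin (Euler-Maruyama) integrator:
#' \deqn{\Delta r = -\frac{D}{RT}\nabla(U + U_{bias})\,\Delta t +
#'   \sqrt{2 D \Delta t}\,\xi, \qquad \xi \sim N(0, 1)^3.}
#' No inertia and no hydrodynamic anisotropy: only the equilibrium
#' distribution matters for PMF recovery, and Euler-Maruyama is the
#' simplest scheme with the right stationary law as \eqn{\Delta t \to 0}.
#'
#' @param diffusion diffusion constant D (A^2/ps, >= 0).
#' @param dt time step (ps, > 0).  Must keep per-step drift
#'   `D/RT * |grad U| * dt` below `max_step`.
#' @param n_steps number of integration steps.
#' @param seed RNG seed (integer); identical seeds give bit-identical
#'   trajectories.
#' @param initial_position numeric length-3 start `(x, y, z)` in A.
#' @param sample_every record every this-many steps (thinning; default 1).
#' @param max_step declared per-step stability bound in A (default 0.5);
#'   the integrator aborts with a diagnostic if the deterministic drift
#'   `D/RT * |F| * dt` of any step exceeds it.
#' @return an object of class `brownian_params`.
#' @export
brownian_params <- function(diffusion = 1.5, dt = 0.01, n_steps = 10000,
                            seed = 1, initial_position = c(0, 0, 0),
                            sample_every = 1, max_step = 0.5) {
  stopifnot(diffusion >= 0, dt > 0, n_steps >= 1,
            length(initial_position) == 3, all(is.finite(initial_position)),
            sample_every >= 1, max_step > 0)
  structure(list(diffusion = diffusion, dt = dt,
                 n_steps = as.integer(n_steps), seed = as.integer(seed),
                 initial_position = as.numeric(initial_position),
                 sample_every = as.integer(sample_every),
                 max_step = max_step),
            class = "brownian_params")
}

#' One biased umbrella window
#'
#' Bundle of a restraint and the reaction-coordinate time series sampled
#' under it.  `samples` has columns `t` (ps), `z`, `x`, `y` (A); times are
#' strictly increasing.
#'
#' @param restraint a [restraint_spec()].
#' @param samples data.frame with columns `t`, `z` and optionally `x`, `y`.
#' @param label window label.
#' @return an object of class `umbrella_window`.
#' @export
umbrella_window <- function(restraint, samples, label = restraint$label) {
  stopifnot(inherits(restraint, "restraint_spec"))
  samples <- as.data.frame(samples)
  stopifnot(all(c("t", "z") %in% names(samples)), nrow(samples) >= 1)
  if (is.unsorted(samples$t, strictly = TRUE))
    stop("sample times must be strictly increasing", call. = FALSE)
  if (!all(is.finite(samples$z)))
    stop("non-finite z samples", call. = FALSE)
  structure(list(restraint = restraint, samples = samples, label = label),
            class = "umbrella_window")
}

#' @export
print.umbrella_window <- function(x, ...) {
  cat(sprintf("Umbrella window '%s': %d samples over %.4g ps; <z> = %.3f A\n",
              x$label, nrow(x$samples), diff(range(x$samples$t)),
              mean(x$samples$z)))
  invisible(x)
}

#' Simulate one umbrella window by Brownian dynamics
#'
#' Runs an Euler-Maruyama trajectory of the ion on the model potential plus
#' the window restraint, returning the recorded `(t, z, x, y)` series as an
#' [umbrella_window()].  The RNG is seeded from `params$seed`, so the
#' trajectory is bit-for-bit reproducible.
#'
#' @param model a [model_potential()].
#' @param restraint a [restraint_spec()].
#' @param params a [brownian_params()].
#' @return an [umbrella_window()].
#' @export
simulate_window <- function(model, restraint, params) {
  stopifnot(inherits(model, "model_potential"),
            inherits(restraint, "restraint_spec"),
            inherits(params, "brownian_params"))
  RT <- thermal_energy(model$temperature)
  g <- model$gaussians
  set.seed(params$seed)
  m <- bd_trajectory_cpp(params$initial_position,
                         g[, "amplitude"], g[, "center"], g[, "width"],
                         model$radial_k, RT, params$diffusion, params$dt,
                         params$n_steps, params$sample_every,
                         restraint$z_center, restraint$k_z,
                         restraint$r_cyl, restraint$k_fb,
                         params$max_step)
  umbrella_window(restraint, as.data.frame(m))
}

#' Build a standard umbrella window layout
#'
#' Evenly spaced umbrella centres with a common force constant and common
#' flat-bottom cylinder, the standard protocol for pulling an ion along a
#' cavity axis (e.g. 26 windows over 0-25 A at 1 A spacing with
#' k = 1.195 kcal/mol/A^2, or 60 windows over -15..15 A at 0.5 A spacing
#' with k = 2 kcal/mol/A^2).
#'
#' @param z_min,z_max coordinate range (A).
#' @param spacing window spacing (A).
#' @param k_z umbrella force constant (kcal/mol/A^2).
#' @param r_cyl,k_fb flat-bottom cylinder radius and wall constant.
#' @return list of [restraint_spec()].
#' @export
umbrella_layout <- function(z_min, z_max, spacing, k_z,
                            r_cyl = 2.5,
                            k_fb = convert_force_constant(
                              5000, "kJ/mol/nm^2", "kcal/mol/A^2")) {
  centers <- seq(z_min, z_max, by = spacing)
  lapply(centers, restraint_spec, k_z = k_z, r_cyl = r_cyl, k_fb = k_fb)
}

#' Simulate a full umbrella-sampling dataset
#'
#' One Brownian-dynamics window per restraint.  Per-window seeds are
#' derived deterministically as `master seed + window index`, each window
#' starts on the cylinder axis at its umbrella centre, and the provenance
#' (model, seeds, parameter template) is attached to the result.
#'
#' @param model a [model_potential()].
#' @param windows list of [restraint_spec()] (e.g. from
#'   [umbrella_layout()]); duplicated centres are kept with a warning.
#' @param params a [brownian_params()] template; `seed` is the master seed
#'   and `initial_position` is overridden per window to `(0, 0, z_center)`.
#' @return list of [umbrella_window()] with attribute `provenance`.
#' @export
generate_umbrella_dataset <- function(model, windows, params) {
  stopifnot(inherits(model, "model_potential"), is.list(windows),
            inherits(params, "brownian_params"))
  if (length(windows) == 0) return(structure(list(), provenance = NULL))
  stopifnot(all(vapply(windows, inherits, TRUE, "restraint_spec")))
  centers <- vapply(windows, `[[`, 0, "z_center")
  if (anyDuplicated(centers))
    warning("duplicate window centers: ",
            paste(unique(centers[duplicated(centers)]), collapse = ", "),
            " (all windows kept)")
  out <- vector("list", length(windows))
  for (i in seq_along(windows)) {
    p <- params
    p$seed <- params$seed + i
    p$initial_position <- c(0, 0, windows[[i]]$z_center)
    out[[i]] <- simulate_window(model, windows[[i]], p)
  }
  attr(out, "provenance") <- list(
    master_seed = params$seed,
    window_seeds = params$seed + seq_along(windows),
    centers = centers,
    model = unclass(model),
    params = unclass(params))
  out
}
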
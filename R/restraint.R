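#' Umbrella restraint specification
#'
#' One biased window: a harmonic umbrella on the z reaction coordinate plus
#' a flat-bottom cylinder in the xy-plane.  Inside the cylinder
#' (`r_perp <= r_cyl`) the lateral restraint energy is zero; outside, a
#' half-harmonic wall pushes the ion back, so the bias is continuous and
#' once-differentiable at the wall.
#'
#' @param z_center umbrella centre on the z coordinate (A).
#' @param k_z umbrella force constant (kcal/mol/A^2, >= 0).
#' @param r_cyl flat-bottom cylinder radius (A, > 0; `Inf` disables the
#'   wall).
#' @param k_fb wall force constant (kcal/mol/A^2, >= 0).  The conventional
#'   GROMACS wall of 5000 kJ/mol/nm^2 is 11.95 kcal/mol/A^2
#'   (see [convert_force_constant()]).
#' @param label optional window label.
#' @return an object of class `restraint_spec`.
#' @export
restraint_spec <- function(z_center = 0, k_z = 0, r_cyl = Inf, k_fb = 0,
                           label = NULL) {
  stopifnot(is.numeric(z_center), length(z_center) == 1, is.finite(z_center),
            is.numeric(k_z), k_z >= 0,
            is.numeric(r_cyl), r_cyl > 0,
            is.numeric(k_fb), k_fb >= 0)
  structure(list(z_center = z_center, k_z = k_z, r_cyl = r_cyl, k_fb = k_fb,
                 label = label %||% sprintf("z%+.2f", z_center)),
            class = "restraint_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.restraint_spec <- function(x, ...) {
  cat(sprintf(
    "Restraint '%s': z-umbrella k=%.4g at %.3g A; cylinder r=%.3g A, wall k=%.4g\n",
    x$label, x$k_z, x$z_center, x$r_cyl, x$k_fb))
  invisible(x)
}

#' Restraint (bias) energy at a point on the reaction coordinate
#'
#' \deqn{U_{bias} = \tfrac12 k_z (z - z_c)^2 +
#'   \begin{cases} 0 & r_\perp \le r_{cyl} \\
#'   \tfrac12 k_{fb} (r_\perp - r_{cyl})^2 & r_\perp > r_{cyl}
#'   \end{cases}}
#' Vectorised over `z_dist` / `r_perp`.
#'
#' @param restraint a [restraint_spec()].
#' @param z_dist signed z reaction coordinate (A).
#' @param r_perp lateral distance from the cavity axis (A).
#' @return energy in kcal/mol (>= 0).
#' @export
bias_energy <- function(restraint, z_dist, r_perp = 0) {
  stopifnot(inherits(restraint, "restraint_spec"))
  ez <- 0.5 * restraint$k_z * (z_dist - restraint$z_center)^2
  over <- pmax(r_perp - restraint$r_cyl, 0)
  ez + 0.5 * restraint$k_fb * over^2
}

#' Gradient of the bias energy
#'
#' Returns the derivative with respect to z and to the lateral distance,
#' matching the analytic forces applied by [simulate_window()].
#'
#' @inheritParams bias_energy
#' @return list with `dz` and `dr` (kcal/mol/A).
#' @export
bias_gradient <- function(restraint, z_dist, r_perp = 0) {
  stopifnot(inherits(restraint, "restraint_spec"))
  over <- pmax(r_perp - restraint$r_cyl, 0)
  list(dz = restraint$k_z * (z_dist - restraint$z_center),
       dr = restraint$k_fb * over)
}
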
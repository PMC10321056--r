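#' Separable model potential for a synthetic host-guest system
#'
#' Ground-truth energy surface used by the Brownian-dynamics generator and as
#' the analytic oracle for PMF recovery.  The surface is separable,
#' \deqn{U(x,y,z) = U_z(z) + \tfrac12 k_r (x^2 + y^2),}
#' where \eqn{U_z} is a sum of Gaussians
#' \eqn{\sum_i A_i \exp(-(z-c_i)^2 / 2 w_i^2)} (negative amplitudes are
#' wells, positive are barriers) and the harmonic radial term confines the
#' particle about the cavity axis.  All Gaussian terms decay, so
#' \eqn{U_z \to 0} in bulk (large |z|).
#'
#' @param gaussians Gaussian terms acting on z: a data.frame / matrix with
#'   columns `amplitude` (kcal/mol), `center` (A), `width` (A), or a list of
#'   length-3 numeric vectors in that order.  May be empty (flat landscape).
#' @param radial_k harmonic confinement constant in x,y (kcal/mol/A^2),
#'   >= 0.
#' @param temperature temperature in K.
#' @return an object of class `model_potential`.
#' @seealso [default_landscape()], [analytic_pmf()], [simulate_window()]
#' @export
model_potential <- function(gaussians = NULL, radial_k = 0.25,
                            temperature = default_temperature()) {
  g <- normalize_gaussians(gaussians)
  stopifnot(is.numeric(radial_k), length(radial_k) == 1, radial_k >= 0,
            is.numeric(temperature), temperature > 0)
  if (nrow(g) > 0 && any(g[, "width"] <= 0))
    stop("Gaussian widths must be positive", call. = FALSE)
  structure(list(gaussians = g, radial_k = radial_k,
                 temperature = temperature),
            class = "model_potential")
}

normalize_gaussians <- function(gaussians) {
  if (is.null(gaussians) || (is.list(gaussians) && length(gaussians) == 0)) {
    g <- matrix(numeric(0), ncol = 3)
  } else if (is.data.frame(gaussians)) {
    g <- as.matrix(gaussians[, c("amplitude", "center", "width")])
  } else if (is.matrix(gaussians)) {
    stopifnot(ncol(gaussians) == 3)
    g <- gaussians
  } else if (is.list(gaussians)) {
    stopifnot(all(vapply(gaussians, length, 1L) == 3))
    g <- do.call(rbind, lapply(gaussians, as.numeric))
  } else stop("cannot interpret 'gaussians'", call. = FALSE)
  colnames(g) <- c("amplitude", "center", "width")
  storage.mode(g) <- "double"
  g
}

#' @export
print.model_potential <- function(x, ...) {
  cat("Model potential:", nrow(x$gaussians), "Gaussian term(s) on z,",
      "radial k =", x$radial_k, "kcal/mol/A^2, T =", x$temperature, "K\n")
  if (nrow(x$gaussians) > 0) print(round(x$gaussians, 4))
  invisible(x)
}

#' Default synthetic binding landscape
#'
#' A landscape qualitatively mimicking an anion PMF through a macrocycle
#' cavity: a central well of amplitude -6 kcal/mol at z = 0, flanking wells
#' of -4 kcal/mol at |z| = 3.5 A, and a flat bulk plateau beyond ~12 A.
#' Gaussian widths are 1.6 A so that the most negative curvature of U_z
#' stays above -1.195 kcal/mol/A^2: every window biased at the standard
#' umbrella strength then samples a unimodal distribution.
#'
#' @inheritParams model_potential
#' @return a `model_potential`.
#' @export
default_landscape <- function(radial_k = 0.25,
                              temperature = default_temperature()) {
  model_potential(
    gaussians = list(c(-6, 0, 1.6), c(-4, 3.5, 1.6), c(-4, -3.5, 1.6)),
    radial_k = radial_k, temperature = temperature)
}

#' Evaluate the model potential and its axial profile
#'
#' `potential_z()` evaluates \eqn{U_z(z)}; `potential_energy()` evaluates the
#' full separable \eqn{U(x,y,z)}; `potential_grad_z()` gives
#' \eqn{dU_z/dz}.  All are vectorised over positions.
#'
#' @param model a [model_potential()].
#' @param z,x,y coordinates in A.
#' @return energies in kcal/mol (or gradient in kcal/mol/A).
#' @export
potential_z <- function(model, z) {
  stopifnot(inherits(model, "model_potential"))
  g <- model$gaussians
  u <- numeric(length(z))
  for (i in seq_len(nrow(g)))
    u <- u + g[i, 1] * exp(-(z - g[i, 2])^2 / (2 * g[i, 3]^2))
  u
}

#' @rdname potential_z
#' @export
potential_energy <- function(model, x, y, z) {
  potential_z(model, z) + 0.5 * model$radial_k * (x^2 + y^2)
}

#' @rdname potential_z
#' @export
potential_grad_z <- function(model, z) {
  g <- model$gaussians
  du <- numeric(length(z))
  for (i in seq_len(nrow(g)))
    du <- du - g[i, 1] * (z - g[i, 2]) / g[i, 3]^2 *
      exp(-(z - g[i, 2])^2 / (2 * g[i, 3]^2))
  du
}

#' Analytic potential of mean force for a cylinder-restrained coordinate
#'
#' Ground-truth oracle: the exact free-energy profile along z for a particle
#' confined to the cylinder \eqn{x^2+y^2 < r_{cyl}^2},
#' \deqn{W(z) = -RT \ln \int\!\!\int_{x^2+y^2<r_{cyl}^2}
#'   e^{-U(x,y,z)/RT}\, dx\, dy + C.}
#' For the separable model the radial integral has the closed form
#' \eqn{(2\pi RT/k_r)(1 - e^{-k_r r_{cyl}^2/2RT})} (or \eqn{\pi r_{cyl}^2}
#' when \eqn{k_r = 0}), a z-independent constant, so W equals \eqn{U_z} up
#' to an additive constant.  C is chosen so that W averages to zero over
#' the declared bulk reference region.
#'
#' @param model a [model_potential()].
#' @param r_cyl cylinder radius in A (> 0; `Inf` allowed when
#'   `radial_k > 0`).
#' @param grid strictly increasing z values (A).
#' @param reference_region length-2 numeric `(z_lo, z_hi)`; default the
#'   outermost 2 A of the grid.
#' @return a [pmf_profile()] with zero uncertainty.
#' @export
analytic_pmf <- function(model, r_cyl, grid, reference_region = NULL) {
  stopifnot(inherits(model, "model_potential"),
            is.numeric(r_cyl), length(r_cyl) == 1, r_cyl > 0,
            is.numeric(grid), length(grid) >= 1)
  if (is.unsorted(grid, strictly = TRUE))
    stop("grid must be strictly increasing", call. = FALSE)
  RT <- thermal_energy(model$temperature)
  k <- model$radial_k
  if (!is.finite(r_cyl) && k <= 0)
    stop("radial integral diverges: radial_k = 0 with an unbounded ",
         "(r_cyl = Inf) domain", call. = FALSE)
  radial_integral <- if (k > 0) {
    (2 * pi * RT / k) * (1 - exp(-k * r_cyl^2 / (2 * RT)))
  } else {
    pi * r_cyl^2
  }
  w <- potential_z(model, grid) - RT * log(radial_integral)
  if (is.null(reference_region))
    reference_region <- c(max(grid) - 2, max(grid))
  prof <- pmf_profile(z = grid, W = w, W_sd = rep(0, length(grid)),
                      n_samples = rep(NA_integer_, length(grid)),
                      reference_region = reference_region,
                      temperature = model$temperature)
  set_reference(prof, reference_region)
}
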
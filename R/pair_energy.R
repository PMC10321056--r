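#' Van der Waals parameters for one atom type
#'
#' Parameterised by the minimum location `r_min` and well depth `epsilon`,
#' valid for both functional forms; for the 12-6 Lennard-Jones form the
#' zero-crossing is at `sigma = r_min / 2^(1/6)`.
#'
#' @param r_min potential minimum location (A, > 0).
#' @param epsilon well depth (kcal/mol, >= 0).
#' @param form `"lj_12_6"` or `"buffered_14_7"`.
#' @return an object of class `vdw_params`.
#' @export
vdw_params <- function(r_min, epsilon, form = c("lj_12_6", "buffered_14_7")) {
  stopifnot(r_min > 0, epsilon >= 0)
  structure(list(r_min = r_min, epsilon = epsilon, form = match.arg(form)),
            class = "vdw_params")
}

combine_lj <- function(p1, p2) {
  # Lorentz-Berthelot: arithmetic sigma, geometric epsilon
  s1 <- p1$r_min / 2^(1 / 6)
  s2 <- p2$r_min / 2^(1 / 6)
  list(sigma = (s1 + s2) / 2, epsilon = sqrt(p1$epsilon * p2$epsilon))
}

combine_14_7 <- function(p1, p2) {
  # AMOEBA conventions: cubic-mean r_min, HHG epsilon
  r1 <- p1$r_min; r2 <- p2$r_min
  rmin <- (r1^3 + r2^3) / (r1^2 + r2^2)
  se <- sqrt(p1$epsilon) + sqrt(p2$epsilon)
  eps <- if (se > 0) 4 * p1$epsilon * p2$epsilon / se^2 else 0
  list(r_min = rmin, epsilon = eps)
}

#' Pairwise van der Waals and Coulomb energies
#'
#' `lj_12_6()` is the 12-6 Lennard-Jones form
#' \eqn{4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6]} with Lorentz-Berthelot
#' combination; `buffered_14_7()` is Halgren's buffered 14-7 form
#' \deqn{\epsilon \left(\frac{1.07}{\rho + 0.07}\right)^7
#'   \left(\frac{1.12}{\rho^7 + 0.12} - 2\right), \quad \rho = r/r_{min},}
#' with the standard buffering constants (delta = 0.07, gamma = 0.12) and
#' AMOEBA combination rules (cubic-mean `r_min`, HHG `epsilon`);
#' `coulomb()` is the vacuum point-charge interaction
#' \eqn{332.0637\, q_1 q_2 / r} kcal/mol.  Both vdW forms evaluate to
#' exactly \eqn{-\epsilon} at \eqn{r = r_{min}} and are symmetric under
#' particle exchange.
#'
#' @param r interatomic distance(s) (A, > 0).
#' @param p1,p2 [vdw_params()] of the two atoms (`p2` defaults to `p1`).
#' @return energy in kcal/mol, vectorised over `r`.
#' @export
lj_12_6 <- function(r, p1, p2 = p1) {
  if (any(r <= 0)) stop("r must be > 0", call. = FALSE)
  cc <- combine_lj(p1, p2)
  sr6 <- (cc$sigma / r)^6
  4 * cc$epsilon * (sr6^2 - sr6)
}

#' @rdname lj_12_6
#' @export
buffered_14_7 <- function(r, p1, p2 = p1) {
  if (any(r <= 0)) stop("r must be > 0", call. = FALSE)
  cc <- combine_14_7(p1, p2)
  rho <- r / cc$r_min
  cc$epsilon * (1.07 / (rho + 0.07))^7 * (1.12 / (rho^7 + 0.12) - 2)
}

#' @rdname lj_12_6
#' @param q1,q2 partial charges (e).
#' @export
coulomb <- function(r, q1, q2) {
  if (any(r <= 0)) stop("r must be > 0", call. = FALSE)
  coulomb_constant() * q1 * q2 / r
}

vdw_energy <- function(r, p1, p2 = p1,
                       form = c("lj_12_6", "buffered_14_7")) {
  switch(match.arg(form),
         lj_12_6 = lj_12_6(r, p1, p2),
         buffered_14_7 = buffered_14_7(r, p1, p2))
}

#' Fit a 12-6 Lennard-Jones form to a buffered 14-7 target curve
#'
#' Weighted least squares of the 12-6 parameters `(r_min, epsilon)` to the
#' self-pair energy curve of `target` evaluated on a distance grid
#' (Levenberg-Marquardt via \pkg{minpack.lm}).  Deterministic given the
#' grid and starting point (the target's own parameters).  Fitting a
#' 12-6 target to itself recovers the parameters exactly.
#'
#' @param target [vdw_params()] of the curve to fit (usually
#'   `form = "buffered_14_7"`).
#' @param r_range `(r_lo, r_hi)` fitting range (A); must bracket the
#'   target minimum.
#' @param weights optional weight per grid point (length `n_grid`).
#' @param n_grid number of grid points (default 200).
#' @return list with `params` (fitted 12-6 [vdw_params()]),
#'   `residual_norm` (RMS residual, kcal/mol), `r_grid`, `target_energy`,
#'   `fitted_energy`.
#' @export
fit_lj_to_14_7 <- function(target, r_range, weights = NULL, n_grid = 200) {
  stopifnot(inherits(target, "vdw_params"), length(r_range) == 2,
            r_range[1] > 0, r_range[2] > r_range[1])
  if (target$r_min < r_range[1] || target$r_min > r_range[2])
    stop("r_range must cover the target minimum", call. = FALSE)
  r <- seq(r_range[1], r_range[2], length.out = n_grid)
  e_target <- vdw_energy(r, target, form = target$form)
  if (is.null(weights)) weights <- rep(1, n_grid)
  stopifnot(length(weights) == n_grid, all(weights >= 0))
  df <- data.frame(r = r, e = e_target)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      e ~ 4 * eps * (((rmin / 2^(1 / 6)) / r)^12 - ((rmin / 2^(1 / 6)) / r)^6),
      data = df, weights = weights,
      start = list(rmin = target$r_min, eps = max(target$epsilon, 1e-6)),
      lower = c(rmin = r_range[1] / 2, eps = 0),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14)),
    error = function(e)
      stop("12-6 fit did not converge: ", conditionMessage(e), call. = FALSE))
  cf <- stats::coef(fit)
  fitted_p <- vdw_params(cf[["rmin"]], cf[["eps"]], form = "lj_12_6")
  e_fit <- lj_12_6(r, fitted_p)
  list(params = fitted_p,
       residual_norm = sqrt(mean((e_fit - e_target)^2)),
       r_grid = r, target_energy = e_target, fitted_energy = e_fit)
}

#' Guest-host interaction-energy profile along the reaction coordinate
#'
#' For each frame (ion position), the total pairwise guest-host energy is
#' computed and split into van der Waals and Coulomb components using the
#' per-atom charges and vdW parameters stored in the host geometry.
#' Frames are binned by the z reaction coordinate and each component is
#' shifted so that its value in the bin containing `reference_z` is zero
#' (the conventional bulk reference: interaction energy set to zero far
#' from the cavity centre, by default 15 A).  The components sum exactly
#' to the total in every bin.
#'
#' @param positions ion positions: an [umbrella_window()] (its `x,y,z`
#'   samples) or an n x 3 matrix.
#' @param host a [host_geometry()] whose atoms carry `charge`, `r_min`,
#'   `epsilon`.
#' @param guest_charge guest charge (e).
#' @param guest_vdw guest [vdw_params()].
#' @param reference_z reference distance (A, default 15).
#' @param bin_width bin width (A).
#' @param form vdW functional form for the host-guest pairs.
#' @return data.frame with `z`, `E_vdw`, `E_coul`, `E_total` (kcal/mol,
#'   bin means, reference-shifted) and `n_frames`.
#' @export
interaction_profile <- function(positions, host, guest_charge, guest_vdw,
                                reference_z = 15, bin_width = 0.5,
                                form = c("lj_12_6", "buffered_14_7")) {
  form <- match.arg(form)
  stopifnot(inherits(host, "host_geometry"),
            inherits(guest_vdw, "vdw_params"))
  if (inherits(positions, "umbrella_window")) {
    s <- positions$samples
    if (is.null(s$x) || is.null(s$y))
      stop("window samples lack x, y coordinates", call. = FALSE)
    positions <- cbind(s$x, s$y, s$z)
  }
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3)
  center <- cavity_center(host)
  a <- host$atoms
  n_frames <- nrow(positions)
  # per-atom combined pair parameters, precomputed once
  if (form == "lj_12_6") {
    sig <- (guest_vdw$r_min + a$r_min) / 2 / 2^(1 / 6)
    eps <- sqrt(guest_vdw$epsilon * a$epsilon)
  } else {
    rmin <- (guest_vdw$r_min^3 + a$r_min^3) / (guest_vdw$r_min^2 + a$r_min^2)
    se <- sqrt(guest_vdw$epsilon) + sqrt(a$epsilon)
    eps <- ifelse(se > 0, 4 * guest_vdw$epsilon * a$epsilon / se^2, 0)
  }
  e_vdw <- e_coul <- numeric(n_frames)
  for (i in seq_len(n_frames)) {
    d <- sqrt((a$x - positions[i, 1])^2 + (a$y - positions[i, 2])^2 +
                (a$z - positions[i, 3])^2)
    if (form == "lj_12_6") {
      sr6 <- (sig / d)^6
      e_vdw[i] <- sum(4 * eps * (sr6^2 - sr6))
    } else {
      rho <- d / rmin
      e_vdw[i] <- sum(eps * (1.07 / (rho + 0.07))^7 *
                        (1.12 / (rho^7 + 0.12) - 2))
    }
    e_coul[i] <- sum(coulomb(d, guest_charge, a$charge))
  }
  z <- positions[, 3] - center[3]
  grid <- make_grid(range(c(z, reference_z)), bin_width)
  b <- findInterval(z, grid$edges, rightmost.closed = TRUE)
  nb <- length(grid$centers)
  mean_by_bin <- function(v) vapply(seq_len(nb), function(i) {
    x <- v[b == i]
    if (length(x) == 0) NA_real_ else mean(x)
  }, 0)
  mv <- mean_by_bin(e_vdw)
  mc <- mean_by_bin(e_coul)
  ref_bin <- findInterval(reference_z, grid$edges, rightmost.closed = TRUE)
  if (ref_bin < 1 || ref_bin > nb || is.na(mv[ref_bin]))
    stop("reference bin at z = ", reference_z, " A is unoccupied",
         call. = FALSE)
  mv <- mv - mv[ref_bin]
  mc <- mc - mc[ref_bin]
  data.frame(z = grid$centers, E_vdw = mv, E_coul = mc,
             E_total = mv + mc, n_frames = tabulate(b, nbins = nb))
}
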
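#' Pseudo-solvent model for synthetic hydration and wetting data
#'
#' Statistical model of the two solvent behaviours the analyses probe:
#' (a) a hydration shell whose expected water count decays from its bulk
#' value as the ion approaches the cavity (shell waters replaced by host
#' contacts), following the logistic replacement curve
#' \deqn{s(d) = 1 / (1 + e^{-(d - r_{cav})/h});}
#' (b) a two-state Markov wetted/de-wetted cavity with switching rates
#' `k_wet` (dry -> wet) and `k_dry` (wet -> dry), whose stationary wetted
#' fraction is `k_wet / (k_wet + k_dry)`.
#'
#' @param bulk_count_mean expected number of shell waters in bulk.
#' @param replacement_halfwidth logistic width h (A) of the replacement
#'   curve.
#' @param k_wet,k_dry switching rates (1/ps, >= 0).
#' @param cavity_radius cavity radius (A); also the midpoint of s(d).
#' @param shell_cutoff shell radius (A) within which the generator places
#'   its waters (should match the analysis `water_cutoff`).
#' @return an object of class `solvent_model`.
#' @export
solvent_model <- function(bulk_count_mean = 6, replacement_halfwidth = 1,
                          k_wet = 0.05, k_dry = 0.05, cavity_radius = 3,
                          shell_cutoff = 3.4) {
  stopifnot(bulk_count_mean >= 0, replacement_halfwidth > 0,
            k_wet >= 0, k_dry >= 0, cavity_radius > 0, shell_cutoff > 0)
  structure(list(bulk_count_mean = bulk_count_mean,
                 replacement_halfwidth = replacement_halfwidth,
                 k_wet = k_wet, k_dry = k_dry,
                 cavity_radius = cavity_radius,
                 shell_cutoff = shell_cutoff),
            class = "solvent_model")
}

#' Replacement curve of the pseudo-solvent model
#'
#' Fraction of the bulk hydration shell retained at ion-cavity distance d.
#'
#' @param smodel a [solvent_model()].
#' @param d ion-cavity distance(s) (A).
#' @return values in (0, 1).
#' @export
replacement_fraction <- function(smodel, d) {
  1 / (1 + exp(-(d - smodel$cavity_radius) / smodel$replacement_halfwidth))
}

# uniform points in a ball of given radius (n x 3)
runif_ball <- function(n, radius) {
  if (n == 0) return(matrix(numeric(0), ncol = 3))
  u <- matrix(stats::rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  u * radius * stats::runif(n)^(1 / 3)
}

#' Generate synthetic solvent frames along an umbrella window
#'
#' For each retained trajectory sample, pseudo-water oxygens are placed
#' around the ion so that the expected count within the model's shell
#' cutoff is `bulk_count_mean * s(d)` (Poisson-distributed, uniform in the
#' shell ball), where d is the ion-cavity distance; independently, the
#' cavity occupancy follows the two-state Markov chain sampled at the
#' frame interval, and a wetted cavity carries one water placed uniformly
#' within `cavity_radius` of the cavity centre.  The initial Markov state
#' is drawn from the stationary distribution.  Seeded and reproducible.
#'
#' @param smodel a [solvent_model()].
#' @param window an [umbrella_window()] providing ion positions (must have
#'   `x`, `y` columns).
#' @param host a [host_geometry()].
#' @param seed RNG seed.
#' @param frame_every keep every this-many window samples as frames.
#' @return list of `solvent_frame` objects (fields `time`, `ion`, `waters`,
#'   `z_dist`), with the host attached as attribute `host`.
#' @export
generate_solvent_frames <- function(smodel, window, host, seed = 1,
                                    frame_every = 1) {
  stopifnot(inherits(smodel, "solvent_model"),
            inherits(window, "umbrella_window"),
            inherits(host, "host_geometry"))
  s <- window$samples
  if (is.null(s$x) || is.null(s$y))
    stop("window samples lack x, y coordinates", call. = FALSE)
  keep <- seq(1, nrow(s), by = frame_every)
  s <- s[keep, , drop = FALSE]
  center <- cavity_center(host)
  set.seed(seed)
  # two-state Markov chain at the frame interval
  n <- nrow(s)
  dt_frame <- if (n > 1) diff(s$t[1:2]) else 1
  p_stat <- if (smodel$k_wet + smodel$k_dry > 0) {
    smodel$k_wet / (smodel$k_wet + smodel$k_dry)
  } else 1
  p_dry_to_wet <- 1 - exp(-smodel$k_wet * dt_frame)
  p_wet_to_dry <- 1 - exp(-smodel$k_dry * dt_frame)
  wetted <- logical(n)
  wetted[1] <- stats::runif(1) < p_stat
  if (n > 1) {
    u <- stats::runif(n - 1)
    for (i in 2:n) {
      wetted[i] <- if (wetted[i - 1]) u[i - 1] >= p_wet_to_dry
                   else u[i - 1] < p_dry_to_wet
    }
  }
  frames <- vector("list", n)
  for (i in seq_len(n)) {
    ion <- c(s$x[i], s$y[i], s$z[i])
    d <- sqrt(sum((ion - center)^2))
    lambda <- smodel$bulk_count_mean * replacement_fraction(smodel, d)
    n_shell <- stats::rpois(1, lambda)
    waters <- sweep(runif_ball(n_shell, smodel$shell_cutoff), 2, ion, `+`)
    if (wetted[i]) {
      cav <- center + runif_ball(1, smodel$cavity_radius)[1, ]
      waters <- rbind(waters, cav)
    }
    frames[[i]] <- structure(
      list(time = s$t[i], ion = ion, waters = waters,
           z_dist = ion[3] - center[3]),
      class = "solvent_frame")
  }
  attr(frames, "host") <- host
  attr(frames, "wetted_truth") <- wetted
  frames
}
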
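#' Count hydration-shell waters and host contacts around the ion
#'
#' Distances use a closed interval: a water at exactly the cutoff distance
#' is counted.  (The closed-boundary convention is fixed so counts are
#' bit-exactly testable.)
#'
#' @param frame a `solvent_frame` (fields `ion`, `waters`).
#' @param water_cutoff shell cutoff for waters (A, > 0; default 3.4, a
#'   typical first-shell oxygen distance).
#' @param host_cutoff cutoff for ion-host contacts (A, > 0; default 4.0).
#' @param host a [host_geometry()]; defaults to the host attached to the
#'   frame list by [generate_solvent_frames()] when counting via
#'   [hydration_profile()].
#' @return integer vector `c(n_waters, n_host_contacts)`.
#' @export
count_shell <- function(frame, water_cutoff = 3.4, host_cutoff = 4.0,
                        host = NULL) {
  stopifnot(water_cutoff > 0, host_cutoff > 0)
  w <- frame$waters
  n_w <- if (is.null(w) || nrow(w) == 0) 0L else {
    d2 <- (w[, 1] - frame$ion[1])^2 + (w[, 2] - frame$ion[2])^2 +
      (w[, 3] - frame$ion[3])^2
    sum(d2 <= water_cutoff^2)
  }
  n_h <- 0L
  if (!is.null(host)) {
    a <- host$atoms
    d2 <- (a$x - frame$ion[1])^2 + (a$y - frame$ion[2])^2 +
      (a$z - frame$ion[3])^2
    n_h <- sum(d2 <= host_cutoff^2)
  }
  c(n_waters = as.integer(n_w), n_host_contacts = as.integer(n_h))
}

#' Hydration-shell profile along the reaction coordinate
#'
#' For each frame the shell water count and host-contact count are
#' computed ([count_shell()]) and stored together with the frame's
#' reaction coordinate; frames are then binned by z and the per-bin mean
#' and standard deviation of both counts reported.  Every frame lands in
#' exactly one bin.
#'
#' @param frames list of `solvent_frame` (e.g. from
#'   [generate_solvent_frames()]).
#' @param bin_width bin width (A).
#' @param water_cutoff,host_cutoff distance cutoffs (A); see
#'   [count_shell()].
#' @param host a [host_geometry()]; default the attribute attached to
#'   `frames`.
#' @param fold fold the coordinate to |z| before binning (default `FALSE`:
#'   signed z).
#' @return an object of class `hydration_profile`: data.frame with
#'   `z` (bin centre), `mean_water_count`, `sd_water_count`,
#'   `mean_host_contacts`, `sd_host_contacts`, `n_frames`.
#' @export
hydration_profile <- function(frames, bin_width = 0.5, water_cutoff = 3.4,
                              host_cutoff = 4.0,
                              host = attr(frames, "host"), fold = FALSE) {
  stopifnot(length(frames) >= 1, bin_width > 0)
  z <- vapply(frames, `[[`, 0, "z_dist")
  if (fold) z <- abs(z)
  counts <- t(vapply(frames, count_shell, integer(2),
                     water_cutoff = water_cutoff,
                     host_cutoff = host_cutoff, host = host))
  grid <- make_grid(range(z), bin_width)
  b <- findInterval(z, grid$edges, rightmost.closed = TRUE)
  nb <- length(grid$centers)
  agg <- function(v, f) vapply(seq_len(nb), function(i) {
    x <- v[b == i]
    if (length(x) == 0) NA_real_ else f(x)
  }, 0)
  sd0 <- function(x) if (length(x) == 1) 0 else stats::sd(x)
  out <- data.frame(
    z = grid$centers,
    mean_water_count = agg(counts[, 1], mean),
    sd_water_count = agg(counts[, 1], sd0),
    mean_host_contacts = agg(counts[, 2], mean),
    sd_host_contacts = agg(counts[, 2], sd0),
    n_frames = tabulate(b, nbins = nb))
  attr(out, "cutoffs") <- c(water = water_cutoff, host = host_cutoff)
  attr(out, "fold") <- fold
  class(out) <- c("hydration_profile", "data.frame")
  out
}

#' Classify cavity wetting along a trajectory
#'
#' A frame is wetted when any water lies within `cavity_cutoff` of the
#' cavity centre (closed interval), de-wetted when none does — the
#' standard 3 A occupancy criterion for a small host cavity.  Dwell times
#' are the durations of constant-state runs at the native frame interval;
#' the censored first and last runs are excluded from the dwell-time lists
#' but included in the wetted/de-wetted fractions.
#'
#' @param frames time-ordered list of `solvent_frame`.
#' @param cavity_cutoff occupancy cutoff (A, default 3).
#' @param center cavity centre; default the centroid of the host attached
#'   to `frames`, else the origin.
#' @return an object of class `wetting_trace`: list with `times`, `wetted`
#'   (logical), `fraction_dewetted`, `n_transitions`, `dwell_wet`,
#'   `dwell_dry` (ps), `frame_interval`.
#' @export
classify_wetting <- function(frames, cavity_cutoff = 3, center = NULL) {
  stopifnot(length(frames) >= 1, cavity_cutoff > 0)
  times <- vapply(frames, `[[`, 0, "time")
  if (is.unsorted(times, strictly = TRUE))
    stop("frames must be strictly time-ordered", call. = FALSE)
  if (is.null(center)) {
    host <- attr(frames, "host")
    center <- if (!is.null(host)) cavity_center(host) else c(0, 0, 0)
  }
  wetted <- vapply(frames, function(fr) {
    w <- fr$waters
    if (is.null(w) || nrow(w) == 0) return(FALSE)
    d2 <- (w[, 1] - center[1])^2 + (w[, 2] - center[2])^2 +
      (w[, 3] - center[3])^2
    any(d2 <= cavity_cutoff^2)
  }, TRUE)
  dt <- if (length(times) > 1) stats::median(diff(times)) else NA_real_
  runs <- rle(wetted)
  n_trans <- length(runs$lengths) - 1L
  # drop censored edge runs from dwell statistics
  keep <- if (length(runs$lengths) > 2) 2:(length(runs$lengths) - 1) else integer(0)
  dwell_wet <- runs$lengths[keep][runs$values[keep]] * dt
  dwell_dry <- runs$lengths[keep][!runs$values[keep]] * dt
  structure(list(times = times, wetted = wetted,
                 fraction_dewetted = mean(!wetted),
                 n_transitions = n_trans,
                 dwell_wet = dwell_wet, dwell_dry = dwell_dry,
                 frame_interval = dt),
            class = "wetting_trace")
}

#' @export
print.wetting_trace <- function(x, ...) {
  cat(sprintf(
    "Wetting trace: %d frames, de-wetted %.1f%% of the time, %d transitions\n",
    length(x$wetted), 100 * x$fraction_dewetted, x$n_transitions))
  invisible(x)
}

#' Summarise wetting traces across systems
#'
#' @param traces named list of [classify_wetting()] results (one per
#'   system).
#' @return data.frame with per-system de-wetted fraction, transition rate
#'   (1/ns) and mean dwell times (ps).
#' @export
wetting_report <- function(traces) {
  if (inherits(traces, "wetting_trace")) traces <- list(trace = traces)
  stopifnot(length(traces) >= 1,
            all(vapply(traces, inherits, TRUE, "wetting_trace")))
  mean_or_na <- function(x) if (length(x) == 0) NA_real_ else mean(x)
  data.frame(
    system = names(traces) %||% as.character(seq_along(traces)),
    fraction_dewetted = vapply(traces, `[[`, 0, "fraction_dewetted"),
    transitions_per_ns = vapply(traces, function(tr) {
      span <- diff(range(tr$times))
      if (span > 0) 1000 * tr$n_transitions / span else NA_real_
    }, 0),
    mean_dwell_wet_ps = vapply(traces, function(tr) mean_or_na(tr$dwell_wet), 0),
    mean_dwell_dry_ps = vapply(traces, function(tr) mean_or_na(tr$dwell_dry), 0),
    row.names = NULL)
}
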
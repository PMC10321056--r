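#' Potential-of-mean-force profile
#'
#' A free-energy curve W(z) on a uniform z grid with per-point uncertainty,
#' an occupancy mask and a declared bulk reference region over which W
#' averages to zero.  W is defined only on occupied bins; empty bins are
#' masked (`NA`), never interpolated.
#'
#' @param z uniform grid of bin centres (A).
#' @param W free energy per bin (kcal/mol); `NA` on unoccupied bins.
#' @param W_sd per-bin standard deviation (kcal/mol, >= 0 or `NA`).
#' @param n_samples per-bin sample counts (may be `NA` for analytic
#'   profiles).
#' @param reference_region length-2 `(z_lo, z_hi)` bulk region, or `NULL`
#'   for a not-yet-referenced profile.
#' @param temperature temperature (K) the profile was estimated at.
#' @return an object of class `pmf_profile`.
#' @export
pmf_profile <- function(z, W, W_sd = rep(NA_real_, length(z)),
                        n_samples = rep(NA_integer_, length(z)),
                        reference_region = NULL,
                        temperature = default_temperature()) {
  stopifnot(length(W) == length(z), length(W_sd) == length(z),
            length(n_samples) == length(z))
  if (length(z) > 1) {
    dz <- diff(z)
    if (any(abs(dz - dz[1]) > 1e-8 * max(abs(dz))))
      stop("z grid must be uniform", call. = FALSE)
  }
  if (any(!is.na(W_sd) & W_sd < 0)) stop("W_sd must be >= 0", call. = FALSE)
  structure(list(z = as.numeric(z), W = as.numeric(W),
                 W_sd = as.numeric(W_sd),
                 n_samples = as.integer(round(n_samples)),
                 occupied = !is.na(W),
                 reference_region = reference_region,
                 temperature = temperature),
            class = "pmf_profile")
}

#' @export
print.pmf_profile <- function(x, ...) {
  occ <- x$occupied
  cat(sprintf("PMF profile: %d bins (%d occupied), z in [%.2f, %.2f] A\n",
              length(x$z), sum(occ), min(x$z), max(x$z)))
  if (any(occ))
    cat(sprintf("  min W = %.3f kcal/mol at z = %.2f A; reference region %s\n",
                min(x$W[occ]), x$z[occ][which.min(x$W[occ])],
                if (is.null(x$reference_region)) "<unset>"
                else sprintf("[%.2f, %.2f]", x$reference_region[1],
                             x$reference_region[2])))
  invisible(x)
}

#' @export
as.data.frame.pmf_profile <- function(x, ...) {
  data.frame(z = x$z, W = x$W, W_sd = x$W_sd, n_samples = x$n_samples)
}

#' @export
plot.pmf_profile <- function(x, add_sd = TRUE, ...) {
  occ <- x$occupied
  graphics::plot(x$z[occ], x$W[occ], type = "l",
                 xlab = "z (A)", ylab = "W(z) (kcal/mol)", ...)
  if (add_sd && any(!is.na(x$W_sd[occ]))) {
    graphics::lines(x$z[occ], x$W[occ] + x$W_sd[occ], lty = 3)
    graphics::lines(x$z[occ], x$W[occ] - x$W_sd[occ], lty = 3)
  }
  invisible(x)
}

#' Reference a PMF to its bulk region
#'
#' Subtracts the mean of W over the occupied bins inside `region`, making
#' the bulk the zero point.  Idempotent; adding any constant to W and
#' re-referencing recovers the same profile.
#'
#' @param profile a [pmf_profile()].
#' @param region length-2 `(z_lo, z_hi)`; defaults to the profile's
#'   existing reference region.
#' @return the referenced [pmf_profile()].
#' @export
set_reference <- function(profile, region = profile$reference_region) {
  stopifnot(inherits(profile, "pmf_profile"))
  if (is.null(region) || length(region) != 2)
    stop("a (z_lo, z_hi) reference region is required", call. = FALSE)
  region <- sort(as.numeric(region))
  sel <- profile$occupied & profile$z >= region[1] & profile$z <= region[2]
  if (!any(sel))
    stop("reference region [", region[1], ", ", region[2],
         "] contains no occupied bins", call. = FALSE)
  profile$W <- profile$W - mean(profile$W[sel])
  profile$reference_region <- region
  profile
}

# shared binning: uniform bins of width bin_width aligned to multiples of
# bin_width, covering 'range'
make_grid <- function(range, bin_width) {
  lo <- floor(range[1] / bin_width) * bin_width
  hi <- ceiling(range[2] / bin_width) * bin_width
  edges <- seq(lo, hi + bin_width / 2, by = bin_width)
  list(edges = edges, centers = edges[-length(edges)] + bin_width / 2)
}

window_histograms <- function(windows, grid) {
  nb <- length(grid$centers)
  H <- matrix(0, nrow = length(windows), ncol = nb)
  for (i in seq_along(windows)) {
    b <- findInterval(windows[[i]]$samples$z, grid$edges,
                      rightmost.closed = TRUE)
    b <- b[b >= 1 & b <= nb]
    H[i, ] <- tabulate(b, nbins = nb)
  }
  H
}

# connected components of the window-overlap graph (windows sharing an
# occupied bin); used to report disconnected clusters
overlap_components <- function(H) {
  n <- nrow(H)
  comp <- seq_len(n)
  occ <- H > 0
  for (b in seq_len(ncol(H))) {
    idx <- which(occ[, b])
    if (length(idx) > 1) comp[comp %in% comp[idx]] <- min(comp[idx])
  }
  match(comp, unique(comp))
}

#' Weighted histogram analysis of umbrella windows
#'
#' Binned WHAM: iterates the self-consistency equations
#' \deqn{p_b \propto \frac{\sum_i H_{ib}}{\sum_i N_i e^{(f_i - b_{ib})/RT}},
#'   \qquad e^{-f_i/RT} = \sum_b e^{-b_{ib}/RT} p_b}
#' until the largest change in any window free energy \eqn{f_i} falls below
#' `tol`, then returns \eqn{W = -RT \ln p} referenced to the bulk region.
#' Only the z-umbrella enters the bias \eqn{b_{ib}}; the xy flat-bottom
#' cylinder is common to all windows and is accounted for downstream by the
#' standard-state correction ([cylinder_correction()]).
#'
#' @param windows list of [umbrella_window()] (>= 1).
#' @param bin_width histogram bin width (A).
#' @param tol convergence tolerance on the window free energies (kcal/mol).
#' @param max_iter maximum self-consistency iterations.
#' @param temperature temperature (K).
#' @param reference_region bulk `(z_lo, z_hi)`; default the outermost 2 A
#'   of the sampled range.
#' @param grid_range optional `(z_lo, z_hi)` to fix the histogram grid
#'   (used by [block_pmfs()] to align blocks).
#' @return a referenced [pmf_profile()].
#' @export
wham <- function(windows, bin_width = 0.1, tol = 1e-7, max_iter = 1e5,
                 temperature = default_temperature(),
                 reference_region = NULL, grid_range = NULL) {
  stopifnot(is.list(windows), length(windows) >= 1,
            all(vapply(windows, inherits, TRUE, "umbrella_window")),
            bin_width > 0, tol > 0, max_iter >= 1)
  RT <- thermal_energy(temperature)
  if (is.null(grid_range))
    grid_range <- range(unlist(lapply(windows, function(w) range(w$samples$z))))
  grid <- make_grid(grid_range, bin_width)
  H <- window_histograms(windows, grid)
  comp <- overlap_components(H)
  if (max(comp) > 1) {
    groups <- split(vapply(windows, `[[`, "", "label"), comp)
    stop("umbrella windows form ", max(comp), " disconnected clusters ",
         "(no shared occupied bins): ",
         paste(vapply(groups, paste, "", collapse = ","), collapse = " | "),
         call. = FALSE)
  }
  Ni <- rowSums(H)
  Hb <- colSums(H)
  # z-bias energy of each window at each bin centre
  B <- t(vapply(windows, function(w)
    0.5 * w$restraint$k_z * (grid$centers - w$restraint$z_center)^2,
    numeric(length(grid$centers))))
  C <- exp(-B / RT)                       # n_win x n_bin
  f <- numeric(length(windows))
  occupied <- Hb > 0
  for (iter in seq_len(max_iter)) {
    denom <- as.vector((Ni * exp(f / RT)) %*% C)
    p <- ifelse(occupied & denom > 0, Hb / denom, 0)
    f_new <- -RT * log(as.vector(C %*% p))
    f_new <- f_new - f_new[1]
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) break
  }
  if (delta >= tol)
    stop(sprintf(
      "WHAM did not converge in %d iterations (final residual %.3g kcal/mol)",
      as.integer(max_iter), delta), call. = FALSE)
  W <- ifelse(occupied, -RT * log(p), NA_real_)
  if (is.null(reference_region)) {
    zocc <- grid$centers[occupied]
    reference_region <- c(max(zocc) - 2, max(zocc))
  }
  prof <- pmf_profile(z = grid$centers, W = W,
                      W_sd = rep(NA_real_, length(W)),
                      n_samples = Hb, reference_region = reference_region,
                      temperature = temperature)
  set_reference(prof, reference_region)
}

#' Pairwise histogram overlap between adjacent umbrella windows
#'
#' For each pair of windows adjacent in umbrella centre, the overlap
#' coefficient of their normalised z histograms,
#' \eqn{\sum_b \min(p_1(b), p_2(b)) \in [0, 1]}; pairs below `threshold`
#' are flagged as insufficient for WHAM to connect reliably.
#'
#' @inheritParams wham
#' @param threshold flagging threshold (default 0.03).
#' @return data.frame with one row per adjacent pair: labels, centres,
#'   `overlap` and `flagged`.
#' @export
histogram_overlap <- function(windows, bin_width = 0.1, threshold = 0.03) {
  stopifnot(is.list(windows), length(windows) >= 2,
            all(vapply(windows, inherits, TRUE, "umbrella_window")))
  ord <- order(vapply(windows, function(w) w$restraint$z_center, 0))
  windows <- windows[ord]
  rng <- range(unlist(lapply(windows, function(w) range(w$samples$z))))
  grid <- make_grid(rng, bin_width)
  H <- window_histograms(windows, grid)
  P <- H / rowSums(H)
  n <- length(windows)
  ov <- vapply(seq_len(n - 1), function(i)
    sum(pmin(P[i, ], P[i + 1, ])), 0)
  data.frame(
    window_1 = vapply(windows[-n], `[[`, "", "label"),
    window_2 = vapply(windows[-1], `[[`, "", "label"),
    center_1 = vapply(windows[-n], function(w) w$restraint$z_center, 0),
    center_2 = vapply(windows[-1], function(w) w$restraint$z_center, 0),
    overlap = ov,
    flagged = ov < threshold)
}

# restrict a window to samples with t in (t_lo, t_hi]
slice_window <- function(w, t_lo, t_hi) {
  keep <- w$samples$t > t_lo & w$samples$t <= t_hi
  if (!any(keep)) return(NULL)
  umbrella_window(w$restraint, w$samples[keep, , drop = FALSE], w$label)
}

#' Block-averaged PMF with per-bin uncertainty
#'
#' Discards an initial equilibration period from every window, splits the
#' remaining simulation time into `n_blocks` contiguous equal-duration
#' blocks, runs WHAM independently on each block, and reports the per-bin
#' mean across blocks as the PMF and the per-bin standard deviation as its
#' uncertainty (the standard three-block protocol: discard, split into
#' three sub-windows, average).  Splitting is by simulation time, not
#' sample count.  With `n_blocks = 1` the mean equals single-pass WHAM and
#' the SD is reported as `NA`.
#'
#' @inheritParams wham
#' @param n_blocks number of blocks (default 3).
#' @param equil_discard equilibration time discarded from the start of each
#'   window (ps).
#' @return list with `mean` (a [pmf_profile()]; bins occupied in every
#'   block carry values, others are masked) and `blocks` (per-block
#'   profiles).
#' @export
block_pmfs <- function(windows, n_blocks = 3, equil_discard = 0,
                       bin_width = 0.1, tol = 1e-7, max_iter = 1e5,
                       temperature = default_temperature(),
                       reference_region = NULL) {
  stopifnot(length(windows) >= 1, n_blocks >= 1, equil_discard >= 0)
  t0 <- min(vapply(windows, function(w) w$samples$t[1], 0))
  t_end <- min(vapply(windows, function(w) max(w$samples$t), 0))
  t_start <- t0 + equil_discard
  if (t_start >= t_end)
    stop("equilibration discard leaves no samples", call. = FALSE)
  edges <- seq(t_start, t_end, length.out = n_blocks + 1)
  # shift so the first block's lower edge is inclusive of the first
  # post-discard sample
  edges[1] <- edges[1] - 1e-9
  grid_range <- range(unlist(lapply(windows, function(w) range(w$samples$z))))
  blocks <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    wb <- lapply(windows, slice_window, t_lo = edges[b], t_hi = edges[b + 1])
    empty <- vapply(wb, is.null, TRUE)
    if (any(empty))
      stop("block ", b, " is empty for window(s): ",
           paste(vapply(windows[empty], `[[`, "", "label"), collapse = ", "),
           call. = FALSE)
    blocks[[b]] <- wham(wb, bin_width = bin_width, tol = tol,
                        max_iter = max_iter, temperature = temperature,
                        reference_region = reference_region,
                        grid_range = grid_range)
  }
  # align is guaranteed by the shared grid_range; reference all blocks to
  # the first block's region so their constants are comparable
  ref <- blocks[[1]]$reference_region
  blocks <- lapply(blocks, set_reference, region = ref)
  Wm <- do.call(rbind, lapply(blocks, `[[`, "W"))
  all_occ <- apply(!is.na(Wm), 2, all)
  W_mean <- ifelse(all_occ, colMeans(Wm), NA_real_)
  W_sd <- if (n_blocks > 1) {
    ifelse(all_occ, apply(Wm, 2, stats::sd), NA_real_)
  } else rep(NA_real_, ncol(Wm))
  n_tot <- Reduce(`+`, lapply(blocks, function(p)
    ifelse(is.na(p$n_samples), 0L, p$n_samples)))
  mean_prof <- pmf_profile(z = blocks[[1]]$z, W = W_mean, W_sd = W_sd,
                           n_samples = n_tot, reference_region = ref,
                           temperature = temperature)
  mean_prof <- set_reference(mean_prof, ref)
  list(mean = mean_prof, blocks = blocks)
}
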
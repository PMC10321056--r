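#' Write / read umbrella-window time series
#'
#' Windows are stored as whitespace-delimited text with `#`-prefixed
#' header lines carrying the restraint metadata and units, followed by
#' columns `time_ps z_A x_A y_A` (x, y optional).  `read_window_file()`
#' also reads two-column pull-style output (time + coordinate); declare
#' `length_unit = "nm"` for nm coordinates, which are converted to A
#' (factor 10).
#'
#' @param window an [umbrella_window()].
#' @param path file path.
#' @return `read_window_file()`: an [umbrella_window()].
#' @export
write_window_file <- function(window, path) {
  stopifnot(inherits(window, "umbrella_window"))
  r <- window$restraint
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# umbrella window '%s'", window$label),
    sprintf("# z_center_A= %.10g k_z_kcal_molA2= %.10g r_cyl_A= %.10g k_fb_kcal_molA2= %.10g",
            r$z_center, r$k_z, r$r_cyl, r$k_fb),
    "# time_ps z_A x_A y_A"), con)
  s <- window$samples
  if (is.null(s$x)) s$x <- NA_real_
  if (is.null(s$y)) s$y <- NA_real_
  utils::write.table(format(s[, c("t", "z", "x", "y")], digits = 12,
                            trim = TRUE, scientific = FALSE),
                     con, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

parse_window_header <- function(lines) {
  meta <- list(z_center = 0, k_z = 0, r_cyl = Inf, k_fb = 0, label = NULL)
  lab <- grep("^# umbrella window", lines, value = TRUE)
  if (length(lab) > 0)
    meta$label <- sub("^# umbrella window '(.*)'.*$", "\\1", lab[1])
  par <- grep("z_center_A=", lines, value = TRUE)
  if (length(par) > 0) {
    get <- function(key) {
      m <- regmatches(par[1],
                      regexpr(paste0(key, "=\\s*[-+0-9.eInf]+"), par[1]))
      if (length(m) == 0) return(NA_real_)
      as.numeric(sub(paste0(key, "=\\s*"), "", m))
    }
    meta$z_center <- get("z_center_A")
    meta$k_z <- get("k_z_kcal_molA2")
    meta$r_cyl <- get("r_cyl_A")
    meta$k_fb <- get("k_fb_kcal_molA2")
  }
  meta
}

#' @rdname write_window_file
#' @param length_unit `"A"` (default) or `"nm"`; nm coordinates are
#'   multiplied by 10.
#' @param restraint optional [restraint_spec()] overriding the header
#'   metadata (required for bare pull files without a header).
#' @export
read_window_file <- function(path, length_unit = c("A", "nm"),
                             restraint = NULL) {
  length_unit <- match.arg(length_unit)
  lines <- readLines(path)
  is_header <- grepl("^\\s*(#|@)", lines) | !nzchar(trimws(lines))
  data_idx <- which(!is_header)
  if (length(data_idx) == 0) stop("no data lines in ", path, call. = FALSE)
  fields <- strsplit(trimws(lines[data_idx]), "\\s+")
  ncol <- length(fields[[1]])
  if (!ncol %in% c(2, 4))
    stop("line ", data_idx[1], ": expected 2 or 4 columns, found ", ncol,
         call. = FALSE)
  bad <- which(vapply(fields, length, 1L) != ncol)
  if (length(bad) > 0)
    stop("line ", data_idx[bad[1]], ": expected ", ncol,
         " columns, found ", length(fields[[bad[1]]]), call. = FALSE)
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))),
              ncol = ncol, byrow = TRUE)
  nf <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(nf) > 0)
    stop("line ", data_idx[nf[1, 1]], ": non-finite value in column ",
         nf[1, 2], call. = FALSE)
  scale <- if (length_unit == "nm") 10 else 1
  samples <- if (ncol == 4) {
    data.frame(t = m[, 1], z = m[, 2] * scale, x = m[, 3] * scale,
               y = m[, 4] * scale)
  } else {
    data.frame(t = m[, 1], z = m[, 2] * scale)
  }
  if (is.null(restraint)) {
    meta <- parse_window_header(lines)
    if (any(is.na(c(meta$z_center, meta$k_z))))
      stop("no restraint metadata in header of ", path,
           "; supply 'restraint'", call. = FALSE)
    restraint <- restraint_spec(meta$z_center, meta$k_z,
                                r_cyl = if (is.na(meta$r_cyl)) Inf else meta$r_cyl,
                                k_fb = if (is.na(meta$k_fb)) 0 else meta$k_fb,
                                label = meta$label)
  }
  umbrella_window(restraint, samples)
}

#' Write an umbrella dataset with a manifest
#'
#' One window file per window plus a JSON manifest (`manifest.json`)
#' recording labels, restraints, file names and the provenance attached by
#' [generate_umbrella_dataset()].
#'
#' @param windows list of [umbrella_window()].
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
write_umbrella_dataset <- function(windows, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("window_%03d.dat", seq_along(windows))
  for (i in seq_along(windows))
    write_window_file(windows[[i]], file.path(dir, files[i]))
  manifest <- list(
    n_windows = length(windows),
    files = files,
    labels = vapply(windows, `[[`, "", "label"),
    restraints = lapply(windows, function(w) unclass(w$restraint)),
    provenance = attr(windows, "provenance"))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_umbrella_dataset
#' @export
read_umbrella_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  out <- lapply(file.path(dir, manifest$files), read_window_file)
  attr(out, "provenance") <- manifest$provenance
  out
}

#' Write / read a PMF profile as TSV
#'
#' Columns `z`, `W`, `W_sd`, `n_samples`; masked bins are written with
#' `NA` so gaps stay explicit.  Header comments carry the reference
#' region, temperature and units.
#'
#' @param profile a [pmf_profile()].
#' @param path file path.
#' @export
write_pmf <- function(profile, path) {
  stopifnot(inherits(profile, "pmf_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  ref <- profile$reference_region
  writeLines(c(
    "# PMF profile (z in A, W in kcal/mol)",
    sprintf("# temperature_K= %.6g", profile$temperature),
    if (!is.null(ref)) sprintf("# reference_region_A= %.6g %.6g",
                               ref[1], ref[2])), con)
  utils::write.table(as.data.frame(profile), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pmf
#' @export
read_pmf <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  temperature <- default_temperature()
  tl <- grep("temperature_K=", hdr, value = TRUE)
  if (length(tl) > 0)
    temperature <- as.numeric(sub(".*temperature_K=\\s*", "", tl[1]))
  ref <- NULL
  rl <- grep("reference_region_A=", hdr, value = TRUE)
  if (length(rl) > 0)
    ref <- as.numeric(strsplit(
      trimws(sub(".*reference_region_A=", "", rl[1])), "\\s+")[[1]])
  df <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                          sep = "\t")
  pmf_profile(z = df$z, W = df$W, W_sd = df$W_sd, n_samples = df$n_samples,
              reference_region = ref, temperature = temperature)
}

#' Write / read solvent frames as multi-frame XYZ
#'
#' Standard multi-frame XYZ: per frame an atom count, a comment line
#' `time_ps=<t>`, then one `element x y z` line per atom.  The guest ion
#' is labelled `X`, pseudo-water oxygens `O` and host atoms `C`.
#'
#' @param frames list of `solvent_frame`.
#' @param path file path.
#' @param include_host also write the host atoms in each frame.
#' @export
write_xyz_frames <- function(frames, path, include_host = FALSE) {
  host <- attr(frames, "host")
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(el, m)
    sprintf("%s %.6f %.6f %.6f", el, m[, 1], m[, 2], m[, 3])
  for (fr in frames) {
    w <- fr$waters
    nh <- if (include_host && !is.null(host)) nrow(host$atoms) else 0
    writeLines(as.character(1 + nrow(w) + nh), con)
    writeLines(sprintf("time_ps= %.6f", fr$time), con)
    writeLines(fmt("X", matrix(fr$ion, ncol = 3)), con)
    if (nrow(w) > 0) writeLines(fmt("O", w), con)
    if (nh > 0)
      writeLines(fmt("C", as.matrix(host$atoms[, c("x", "y", "z")])), con)
  }
  invisible(path)
}

#' @rdname write_xyz_frames
#' @param center cavity centre used to recompute `z_dist` (default
#'   origin).
#' @export
read_xyz_frames <- function(path, center = c(0, 0, 0)) {
  lines <- readLines(path)
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("line ", i, ": expected an atom count", call. = FALSE)
    tm <- suppressWarnings(as.numeric(sub(".*time_ps=\\s*", "", lines[i + 1])))
    atoms <- do.call(rbind, strsplit(trimws(lines[i + 2:(n + 1)]), "\\s+"))
    el <- atoms[, 1]
    xyz <- matrix(as.numeric(atoms[, 2:4]), ncol = 3)
    if (any(!is.finite(xyz)))
      stop("non-finite coordinate in frame starting at line ", i,
           call. = FALSE)
    ion <- xyz[el == "X", , drop = FALSE]
    if (nrow(ion) != 1)
      stop("frame starting at line ", i, ": expected exactly one ion (X)",
           call. = FALSE)
    frames[[length(frames) + 1]] <- structure(
      list(time = tm, ion = ion[1, ],
           waters = xyz[el == "O", , drop = FALSE],
           z_dist = ion[1, 3] - center[3]),
      class = "solvent_frame")
    i <- i + n + 2
  }
  frames
}

#' Read a run configuration from YAML
#'
#' The configuration nests the model, window layout, restraint, sampling
#' and analysis parameters that drive [run_pipeline()]; missing keys fall
#' back to [default_config()].  Round-trips through
#' `yaml::write_yaml()` unchanged.
#'
#' @param path YAML file path.
#' @return a nested list merged over [default_config()].
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  modifyList(default_config(), user, keep.null = TRUE)
}

#' @rdname read_config
#' @export
default_config <- function() {
  list(
    model = list(
      gaussians = list(c(-6, 0, 1.6), c(-4, 3.5, 1.6), c(-4, -3.5, 1.6)),
      radial_k = 0.25,
      temperature = 298.15),
    windows = list(z_min = 0, z_max = 25, spacing = 1, k_z = 1.195,
                   r_cyl = 2.5, k_fb = 11.95028681),
    sampling = list(diffusion = 1.5, dt = 0.01, n_steps = 200000,
                    sample_every = 1, equil_discard = 200, n_blocks = 3,
                    seed = 20260924),
    analysis = list(bin_width = 0.1, bulk_region = c(20, 25), tol = 1e-7,
                    max_iter = 100000, water_cutoff = 3.4,
                    host_cutoff = 4.0, cavity_cutoff = 3.0,
                    site_bounds = c(-2, 6)),
    solvent = list(enabled = TRUE, bulk_count_mean = 6,
                   replacement_halfwidth = 1, k_wet = 0.05, k_dry = 0.05,
                   cavity_radius = 3, frame_every = 50,
                   solvent_window = NULL),
    host = list(ring_radius = 3, n_ring = 12))
}
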
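#' Run the full synthetic umbrella-sampling analysis pipeline
#'
#' End-to-end orchestration: simulate the umbrella dataset on the
#' configured landscape, estimate the block-averaged PMF by WHAM, convert
#' the minimum to a standard-state binding free energy with the cylinder
#' correction, generate pseudo-solvent frames on a designated window and
#' run the hydration/wetting analyses, and (optionally) write everything
#' plus a provenance manifest to `output_dir`.  All randomness flows from
#' the single master seed, so reruns with the same config are
#' byte-identical.
#'
#' @param config nested configuration list (see [default_config()] /
#'   [read_config()]).
#' @param output_dir optional directory for TSV/JSON outputs; `NULL`
#'   computes in memory only.
#' @param quiet suppress progress messages.
#' @return list with `windows`, `pmf` (list `mean`, `blocks`), `overlap`,
#'   `binding`, `frames`, `hydration`, `wetting`, `config`.
#' @export
run_pipeline <- function(config = default_config(), output_dir = NULL,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  cfg <- modifyList(default_config(), config, keep.null = TRUE)
  model <- model_potential(cfg$model$gaussians, cfg$model$radial_k,
                           cfg$model$temperature)
  host <- generate_host_geometry(cfg$host$ring_radius, cfg$host$n_ring)

  say("stage simulate: ", with(cfg$windows, length(seq(z_min, z_max, spacing))),
      " windows, k_z = ", cfg$windows$k_z, " kcal/mol/A^2, r_cyl = ",
      cfg$windows$r_cyl, " A, ", cfg$sampling$n_steps, " steps/window")
  layout <- umbrella_layout(cfg$windows$z_min, cfg$windows$z_max,
                            cfg$windows$spacing, cfg$windows$k_z,
                            r_cyl = cfg$windows$r_cyl,
                            k_fb = cfg$windows$k_fb)
  params <- brownian_params(diffusion = cfg$sampling$diffusion,
                            dt = cfg$sampling$dt,
                            n_steps = cfg$sampling$n_steps,
                            seed = cfg$sampling$seed,
                            sample_every = cfg$sampling$sample_every)
  windows <- generate_umbrella_dataset(model, layout, params)

  say("stage pmf: WHAM, bin width ", cfg$analysis$bin_width, " A, ",
      cfg$sampling$n_blocks, " blocks, discard ",
      cfg$sampling$equil_discard, " ps")
  pmf <- block_pmfs(windows, n_blocks = cfg$sampling$n_blocks,
                    equil_discard = cfg$sampling$equil_discard,
                    bin_width = cfg$analysis$bin_width,
                    tol = cfg$analysis$tol,
                    max_iter = cfg$analysis$max_iter,
                    temperature = cfg$model$temperature,
                    reference_region = cfg$analysis$bulk_region)
  overlap <- histogram_overlap(windows, bin_width = cfg$analysis$bin_width)

  say("stage bind: cylinder correction at r_cyl = ", cfg$windows$r_cyl, " A")
  binding <- dg_from_minimum(pmf$mean, pmf$blocks,
                             r_cyl = cfg$windows$r_cyl,
                             temperature = cfg$model$temperature)

  frames <- hydration <- wetting <- NULL
  if (isTRUE(cfg$solvent$enabled)) {
    smodel <- solvent_model(cfg$solvent$bulk_count_mean,
                            cfg$solvent$replacement_halfwidth,
                            cfg$solvent$k_wet, cfg$solvent$k_dry,
                            cfg$solvent$cavity_radius,
                            shell_cutoff = cfg$analysis$water_cutoff)
    widx <- cfg$solvent$solvent_window %||% length(windows)
    say("stage solvation: frames from window ", widx,
        ", water cutoff ", cfg$analysis$water_cutoff,
        " A, host cutoff ", cfg$analysis$host_cutoff,
        " A, cavity cutoff ", cfg$analysis$cavity_cutoff, " A")
    frames <- generate_solvent_frames(smodel, windows[[widx]], host,
                                      seed = cfg$sampling$seed + 10000,
                                      frame_every = cfg$solvent$frame_every)
    hydration <- hydration_profile(frames,
                                   bin_width = 0.5,
                                   water_cutoff = cfg$analysis$water_cutoff,
                                   host_cutoff = cfg$analysis$host_cutoff,
                                   host = host)
    wetting <- wetting_report(list(
      synthetic = classify_wetting(frames,
                                   cavity_cutoff = cfg$analysis$cavity_cutoff,
                                   center = cavity_center(host))))
  }

  result <- list(windows = windows, pmf = pmf, overlap = overlap,
                 binding = binding, frames = frames,
                 hydration = hydration, wetting = wetting, config = cfg)

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_umbrella_dataset(windows, file.path(output_dir, "windows"))
    write_pmf(pmf$mean, file.path(output_dir, "pmf.tsv"))
    utils::write.table(overlap, file.path(output_dir, "overlap.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    bsum <- data.frame(system = "synthetic", method = binding$method,
                       dG_min = binding$dG_min, dG_corr = binding$dG_corr,
                       dG_total = binding$dG_total, dG_sd = binding$dG_sd,
                       z_min = binding$z_min, r_cyl = cfg$windows$r_cyl,
                       temperature = cfg$model$temperature)
    utils::write.table(bsum, file.path(output_dir, "binding.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(frames)) {
      write_xyz_frames(frames, file.path(output_dir, "solvent.xyz"))
      utils::write.table(as.data.frame(hydration),
                         file.path(output_dir, "hydration.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(wetting, file.path(output_dir, "wetting.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    cfg_path <- file.path(output_dir, "config.yaml")
    yaml::write_yaml(cfg, cfg_path)
    jsonlite::write_json(
      list(config_md5 = unname(tools::md5sum(cfg_path)),
           master_seed = cfg$sampling$seed,
           package_version = as.character(utils::packageVersion("umbrellabind")),
           r_version = R.version.string),
      file.path(output_dir, "provenance.json"),
      auto_unbox = TRUE, pretty = TRUE)
  }
  result
}
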
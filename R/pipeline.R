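# End-to-end orchestration: trajectory -> per-stage tables -> one condition
# summary row. Every geometric cutoff and block setting is a config value
# with the package defaults, never hard-coded in the stages.

#' Build a run configuration
#'
#' @param label a [condition_label()].
#' @param output_dir directory for stage outputs (created if missing).
#' @param trajectory an in-memory `trajectory`, or `NULL` to read from files.
#' @param topology_path,trajectory_path,trajectory_format file inputs used
#'   when `trajectory` is `NULL`.
#' @param frame_interval ps (file input only).
#' @param solvent_reference a [solvent_reference()], a bare number
#'   (mean water volume, A^3, taken at the run condition), or `NULL`.
#' @param hbond an [hbond_criteria()].
#' @param interior an [interior_water_criteria()].
#' @param blocks a [block_spec()].
#' @param superpose remove rigid-body motion in the MSF stage.
#' @param exclusion_threshold ps, lifetime-exclusion threshold.
#' @param min_tau ps, correlation-dataset lifetime filter.
#' @param seed recorded in the manifest.
#' @export
run_config <- function(label, output_dir,
                       trajectory = NULL,
                       topology_path = NULL, trajectory_path = NULL,
                       trajectory_format = "pdb", frame_interval = 1,
                       solvent_reference = NULL,
                       hbond = hbond_criteria(),
                       interior = interior_water_criteria(),
                       blocks = block_spec(),
                       superpose = TRUE,
                       exclusion_threshold = 1000,
                       min_tau = 2,
                       seed = 1) {
  if (is.null(trajectory)) {
    if (is.null(topology_path) || is.null(trajectory_path))
      stop_ptfluct("either a trajectory object or file paths are required",
                   "ptfluct_spec_error")
    for (p in c(topology_path, trajectory_path))
      if (!file.exists(p))
        stop_ptfluct(sprintf("input path does not exist: %s", p),
                     "ptfluct_spec_error")
  }
  if (is.numeric(solvent_reference))
    solvent_reference <- solvent_reference(solvent_reference,
                                           label$temperature, label$pressure,
                                           source = "config value")
  structure(list(label = label, output_dir = output_dir,
                 trajectory = trajectory, topology_path = topology_path,
                 trajectory_path = trajectory_path,
                 trajectory_format = trajectory_format,
                 frame_interval = frame_interval,
                 solvent_reference = solvent_reference, hbond = hbond,
                 interior = interior, blocks = blocks, superpose = superpose,
                 exclusion_threshold = exclusion_threshold, min_tau = min_tau,
                 seed = seed),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror [run_config()] arguments; criteria blocks are nested maps,
#' e.g. `hbond: {d_HA_max: 2.40, angle_min: 130}`.
#'
#' @param path YAML file.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  lab <- condition_label(y$protein_id, y$temperature, y$pressure)
  run_config(
    label = lab,
    output_dir = y$output_dir %||% ".",
    topology_path = y$topology_path,
    trajectory_path = y$trajectory_path,
    trajectory_format = y$trajectory_format %||% "pdb",
    frame_interval = y$frame_interval %||% 1,
    solvent_reference = y$solvent_reference,
    hbond = do.call(hbond_criteria, y$hbond %||% list()),
    interior = do.call(interior_water_criteria, y$interior %||% list()),
    blocks = do.call(block_spec, y$blocks %||% list()),
    superpose = y$superpose %||% TRUE,
    exclusion_threshold = y$exclusion_threshold %||% 1000,
    min_tau = y$min_tau %||% 2,
    seed = y$seed %||% 1
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_stage_tsv <- function(df, path, config_hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# ptfluct %s  config=%s",
                     as.character(utils::packageVersion("ptfluct")),
                     config_hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline for one condition
#'
#' Stages: MSF (block-averaged), apparent volume (when a solvent reference is
#' configured; otherwise skipped with a warning), interior waters, hydrogen
#' bonds (detection, events, pair lifetimes, summary, fluctuation-lifetime
#' correlation). All stage tables are written as TSV under
#' `config$output_dir`, plus a `condition_summary.tsv` row and a manifest.
#'
#' @param config a [run_config()].
#' @return list with elements `summary` (a [condition_summary()] row), `msf`,
#'   `volume` (or `NULL`), `interior`, `hbonds` (events/pairs/summary),
#'   `correlation`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  hashable <- config[setdiff(names(config), c("trajectory", "output_dir"))]
  cfg_hash <- substr(rlang::hash(hashable), 1, 12)
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tic <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      stop_ptfluct(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                   "ptfluct_stage_error")
    })
    message(sprintf("[%s] done in %.2f s", name,
                    as.numeric(difftime(Sys.time(), tic, units = "secs"))))
    out
  }
  traj <- config$trajectory
  if (is.null(traj)) {
    traj <- stage("read", {
      top <- read_topology(config$topology_path)
      read_trajectory(top, config$trajectory_path,
                      format = config$trajectory_format,
                      frame_interval = config$frame_interval,
                      label = config$label)
    })
  }
  if (is.null(traj$label)) traj$label <- config$label

  msf <- stage("msf", compute_msf(traj, config$blocks, config$superpose))
  write_stage_tsv(data.frame(atom = msf$atoms,
                             msf = as.numeric(msf$per_atom_mean)),
                  file.path(config$output_dir, "per_atom_msf.tsv"), cfg_hash)
  write_stage_tsv(msf$per_residue,
                  file.path(config$output_dir, "per_residue_msf.tsv"), cfg_hash)

  volume <- NULL
  if (!is.null(config$solvent_reference)) {
    volume <- stage("vapp",
                    compute_vapp(traj, config$solvent_reference, config$blocks))
    write_stage_tsv(data.frame(
      mean_box_volume = volume$mean_box_volume, n_waters = volume$n_waters,
      v_app = volume$v_app,
      v_app_per_heavy_atom = volume$v_app_per_heavy_atom,
      error = volume$error),
      file.path(config$output_dir, "volume.tsv"), cfg_hash)
  } else {
    warning("no solvent reference configured: apparent-volume column omitted",
            call. = FALSE)
  }

  interior <- stage("waterin",
                    count_interior_waters(traj, config$interior, config$blocks))
  write_stage_tsv(data.frame(
    time_ps = interior$sampled_times, count = interior$counts,
    residues = vapply(interior$identities, paste, character(1), collapse = ",")),
    file.path(config$output_dir, "interior_waters.tsv"), cfg_hash)

  hb <- stage("hbonds", {
    sets <- detect_hbonds(traj, config$hbond)
    tr <- track_events(sets, traj$frame_interval)
    summ <- summarize_lifetimes(tr$pairs, sets, traj$frame_interval,
                                config$blocks, config$exclusion_threshold)
    list(sets = sets, events = tr$events, pairs = tr$pairs, summary = summ)
  })
  ev <- hb$events
  ev$start_ps <- (ev$start_frame - 1) * traj$frame_interval
  write_stage_tsv(ev[, c("donor_h", "donor_heavy", "acceptor", "start_ps",
                         "duration", "truncated")],
                  file.path(config$output_dir, "hbond_events.tsv"), cfg_hash)
  write_stage_tsv(hb$pairs,
                  file.path(config$output_dir, "hbond_pairs.tsv"), cfg_hash)
  s <- hb$summary
  write_stage_tsv(data.frame(
    n_hb = s$n_hb, n_hb_err = s$n_hb_error, n_unique_pairs = s$n_unique_pairs,
    n_included_pairs = s$n_included_pairs, tau_hb = s$tau_hb,
    tau_hb_err = s$tau_hb_error,
    excluded = paste(sprintf("%d-%d", s$excluded_pairs$donor_h,
                             s$excluded_pairs$acceptor), collapse = ";")),
    file.path(config$output_dir, "hbond_summary.tsv"), cfg_hash)

  correlation <- fluctuation_lifetime_dataset(msf, hb$pairs, config$min_tau)
  write_stage_tsv(correlation,
                  file.path(config$output_dir, "hbond_correlation.tsv"), cfg_hash)

  summary_row <- condition_summary(
    traj$label,
    msf$global_msf, msf$global_error %||% NA_real_,
    if (is.null(volume)) NA_real_ else volume$v_app_per_heavy_atom,
    if (is.null(volume)) NA_real_ else volume$error,
    interior$n_w_in, interior$error,
    s$n_hb, s$n_hb_error, s$tau_hb, s$tau_hb_error)
  write_condition_summaries(summary_row,
                            file.path(config$output_dir, "condition_summary.tsv"))

  manifest <- c(
    sprintf("ptfluct version: %s", as.character(utils::packageVersion("ptfluct"))),
    sprintf("config hash: %s", cfg_hash),
    sprintf("condition: %s", format(traj$label)),
    sprintf("frames: %d (%g ps/frame)", n_frames(traj), traj$frame_interval),
    sprintf("seed: %s", config$seed),
    sprintf("elapsed_s: %.2f",
            as.numeric(difftime(Sys.time(), t0, units = "secs")))
  )
  writeLines(manifest, file.path(config$output_dir, "manifest.txt"))

  list(summary = summary_row, msf = msf, volume = volume, interior = interior,
       hbonds = hb[c("events", "pairs", "summary")], correlation = correlation)
}
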
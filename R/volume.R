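# Apparent protein volume from box-volume statistics:
#   V_app = <V_MD> - N_w * <V_w>
# where <V_MD> is the time-mean simulation-cell volume, N_w the number of
# water molecules in the system, and <V_w> the mean molecular volume of water
# from a pure-solvent simulation at the same temperature and pressure.
# V_app / N_HA (heavy atoms) is the average volume available per heavy atom.

#' Pure-solvent volume reference
#'
#' @param mean_water_volume mean molecular volume of one water, Angstrom^3.
#' @param temperature,pressure condition this reference is valid for (K, bar).
#' @param source free-text provenance.
#' @return a `solvent_reference`.
#' @export
solvent_reference <- function(mean_water_volume, temperature, pressure,
                              source = "user") {
  if (!is.finite(mean_water_volume) || mean_water_volume <= 0)
    stop_ptfluct("mean water volume must be > 0", "ptfluct_spec_error")
  structure(list(mean_water_volume = as.numeric(mean_water_volume),
                 temperature = as.numeric(temperature),
                 pressure = as.numeric(pressure), source = source),
            class = "solvent_reference")
}

#' Build a solvent reference from a pure-water volume series
#'
#' @param volume_series per-frame cell volumes of a pure-solvent run, Angstrom^3.
#' @param n_waters number of water molecules in that run.
#' @param label `condition_label` of the solvent run.
#' @export
pure_solvent_reference <- function(volume_series, n_waters, label) {
  if (!length(volume_series))
    stop_ptfluct("empty volume series", "ptfluct_coverage_error")
  if (n_waters <= 0)
    stop_ptfluct("n_waters must be > 0", "ptfluct_spec_error")
  if (length(volume_series) == 1L)
    warning("single-frame solvent series: no averaging possible", call. = FALSE)
  solvent_reference(mean(volume_series) / n_waters,
                    label$temperature, label$pressure,
                    source = sprintf("pure solvent series (%d frames)",
                                     length(volume_series)))
}

#' Apparent protein volume per heavy atom
#'
#' @param traj a `trajectory` with per-frame boxes and a `condition_label`.
#' @param ref a [solvent_reference()] at the matching condition.
#' @param blocks a [block_spec()] for the error estimate.
#' @param condition_tol relative tolerance for the (T, P) match check.
#' @return a `volume_result`: `mean_box_volume`, `n_waters`, `v_app`,
#'   `v_app_per_heavy_atom`, `error` (block SEM of V_app/N_HA), `n_heavy_atoms`.
#' @export
compute_vapp <- function(traj, ref, blocks = block_spec(),
                         condition_tol = 1e-6) {
  if (is.null(traj$boxes))
    stop_ptfluct("trajectory has no boxes", "ptfluct_missing_box_error")
  lab <- traj$label
  if (!is.null(lab)) {
    if (abs(lab$temperature - ref$temperature) > condition_tol * lab$temperature ||
        abs(lab$pressure - ref$pressure) > condition_tol * lab$pressure)
      stop_ptfluct(sprintf(
        "solvent reference condition (%g K, %g bar) does not match trajectory (%g K, %g bar)",
        ref$temperature, ref$pressure, lab$temperature, lab$pressure),
        "ptfluct_reference_error")
  }
  top <- traj$topology
  n_w <- length(unique(top$residue_index[top$is_water]))
  n_ha <- sum(top$is_protein & top$is_heavy)
  if (n_ha == 0)
    stop_ptfluct("no protein heavy atoms", "ptfluct_selection_error")
  v <- frame_volumes(traj)
  idx <- block_frame_indices(length(v), traj$frame_interval, blocks)
  block_means <- vapply(idx, function(i) mean(v[i]), numeric(1))
  v_md <- mean(v)
  v_app <- v_md - n_w * ref$mean_water_volume
  block_vapp_ha <- (block_means - n_w * ref$mean_water_volume) / n_ha
  structure(list(mean_box_volume = v_md, n_waters = n_w, v_app = v_app,
                 v_app_per_heavy_atom = v_app / n_ha,
                 error = block_sem(block_vapp_ha),
                 n_heavy_atoms = n_ha, solvent_reference = ref),
            class = "volume_result")
}

#' @export
print.volume_result <- function(x, ...) {
  cat(sprintf("V_app = %.5g A^3 (<V_MD> = %.6g, N_w = %d); V_app/N_HA = %.4g +/- %.2g A^3\n",
              x$v_app, x$mean_box_volume, x$n_waters, x$v_app_per_heavy_atom,
              ifelse(is.na(x$error), 0, x$error)))
  invisible(x)
}
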
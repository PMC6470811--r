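# Interior-water counting. A water molecule (located at its oxygen atom) is
# inside the protein in a given frame iff
#   (i)  its minimum-image distance to the nearest protein heavy atom is
#        strictly below d_protein_max (default 4.00 A), and
#   (ii) no other water oxygen lies strictly within d_water_min (default
#        3.36 A) of it, i.e. its nearest water neighbour is at >= d_water_min.
# Counts are taken on a coarse sampling grid (default every 100 ps) and
# reported as mean +/- block SEM.

#' Interior-water criteria
#'
#' @param d_protein_max max distance to the nearest protein heavy atom, A.
#' @param d_water_min exclusion distance to other water oxygens, A.
#' @param sample_interval sampling interval, ps.
#' @export
interior_water_criteria <- function(d_protein_max = 4.00, d_water_min = 3.36,
                                    sample_interval = 100) {
  if (any(c(d_protein_max, d_water_min, sample_interval) <= 0))
    stop_ptfluct("interior-water criteria must all be > 0", "ptfluct_spec_error")
  structure(list(d_protein_max = d_protein_max, d_water_min = d_water_min,
                 sample_interval = sample_interval),
            class = "interior_water_criteria")
}

## Interior water residue indices for one frame given oxygen positions `wpos`
## (rows aligned with `wres`), protein heavy positions `ppos`, and the box.
interior_waters_frame <- function(wpos, wres, ppos, box, crit) {
  if (is.null(dim(wpos))) wpos <- matrix(wpos, ncol = 3L)
  if (is.null(dim(ppos))) ppos <- matrix(ppos, ncol = 3L)
  nw <- nrow(wpos)
  if (nw == 0L) return(integer(0))
  dp <- min_image_cross_dist(wpos, ppos, box)
  near_protein <- apply(dp, 1L, min) < crit$d_protein_max
  if (nw == 1L) {
    lonely <- TRUE
  } else {
    dw <- min_image_cross_dist(wpos, wpos, box)
    diag(dw) <- Inf
    lonely <- apply(dw, 1L, min) >= crit$d_water_min
  }
  wres[near_protein & lonely]
}

#' Count interior water molecules
#'
#' @param traj a `trajectory` with waters and per-frame boxes.
#' @param crit an [interior_water_criteria()].
#' @param blocks a [block_spec()] for the error estimate.
#' @return an `interior_water_result`: `sampled_frames`, `counts`, `n_w_in`
#'   (mean count), `error` (block SEM), `identities` (list of interior water
#'   residue indices per sampled frame).
#' @export
count_interior_waters <- function(traj, crit = interior_water_criteria(),
                                  blocks = block_spec()) {
  top <- traj$topology
  w_ox <- which(top$is_water & top$element == "O")
  if (!length(w_ox))
    stop_ptfluct("no water oxygens in topology", "ptfluct_selection_error")
  p_heavy <- which(top$is_protein & top$is_heavy)
  if (!length(p_heavy))
    stop_ptfluct("no protein heavy atoms in topology", "ptfluct_selection_error")
  if (is.null(traj$boxes))
    stop_ptfluct("periodic boxes required", "ptfluct_missing_box_error")
  step <- crit$sample_interval / traj$frame_interval
  if (abs(step - round(step)) > 1e-9)
    stop_ptfluct("sample_interval must be a multiple of frame_interval",
                 "ptfluct_sampling_error")
  step <- max(1L, as.integer(round(step)))
  frames <- seq(1L, n_frames(traj), by = step)
  wres <- top$residue_index[w_ox]
  identities <- vector("list", length(frames))
  counts <- integer(length(frames))
  for (k in seq_along(frames)) {
    f <- frames[k]
    ids <- interior_waters_frame(traj$coords[f, w_ox, , drop = TRUE],
                                 wres,
                                 traj$coords[f, p_heavy, , drop = TRUE],
                                 traj$boxes[[f]], crit)
    identities[[k]] <- ids
    counts[k] <- length(ids)
  }
  ## block SEM over sampled frames grouped by trajectory time blocks
  err <- NA_real_
  blk <- tryCatch(block_frame_indices(n_frames(traj), traj$frame_interval, blocks),
                  error = function(e) NULL)
  if (!is.null(blk)) {
    bm <- vapply(blk, function(i) {
      sel <- frames %in% i
      if (any(sel)) mean(counts[sel]) else NA_real_
    }, numeric(1))
    err <- block_sem(bm[!is.na(bm)])
  }
  structure(list(sampled_frames = frames,
                 sampled_times = (frames - 1L) * traj$frame_interval,
                 counts = counts, n_w_in = mean(counts), error = err,
                 identities = identities, criteria = crit),
            class = "interior_water_result")
}

#' @export
print.interior_water_result <- function(x, ...) {
  cat(sprintf("N_w,in = %.3g +/- %.2g (over %d sampled frames)\n",
              x$n_w_in, ifelse(is.na(x$error), 0, x$error), length(x$counts)))
  invisible(x)
}
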
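# Geometric hydrogen-bond analysis for protein-protein hydrogen bonds.
#
# A donor-hydrogen/acceptor pair (i, j) is bonded in a frame iff the
# minimum-image H...A distance is strictly below d_HA_max (default 2.40 A)
# and the D-H...A angle (at the hydrogen) is strictly above angle_min
# (default 130 deg). Donors are protein hydrogens covalently bound to N/O/S;
# acceptors are protein N/O/S heavy atoms; charged moieties participate.
#
# An *event* is a maximal run of consecutive frames in which a pair is
# bonded ("continuously formed"). The pair lifetime is
#   tau_ij = (1/n_ij) * sum_n t_ij(n)
# over that pair's n_ij events, and the pair-averaged lifetime
#   tau_HB = (1/N') * sum_ij tau_ij
# averages tau_ij over unique pairs, excluding pairs with tau_ij above a
# threshold (default 1000 ps) from tau_HB but not from the bond population
# N_HB. Two bonds simultaneously formed with the same atom count as separate
# events (one per pair identity).

POLAR_ELEMENTS <- c("N", "O", "S")

#' Hydrogen-bond criteria
#'
#' @param d_HA_max maximum donor-hydrogen to acceptor distance, Angstrom.
#' @param angle_min minimum D-H...A angle, degrees.
#' @export
hbond_criteria <- function(d_HA_max = 2.40, angle_min = 130) {
  if (d_HA_max <= 0) stop_ptfluct("d_HA_max must be > 0", "ptfluct_spec_error")
  if (angle_min <= 0 || angle_min >= 180)
    stop_ptfluct("angle_min must be in (0, 180)", "ptfluct_spec_error")
  structure(list(d_HA_max = d_HA_max, angle_min = angle_min),
            class = "hbond_criteria")
}

## Donor hydrogens (protein H bound to a polar heavy atom) and acceptor
## candidates (protein polar heavy atoms).
hbond_participants <- function(top) {
  don_h <- which(top$element == "H" & top$is_protein & !top$is_virtual &
                   !is.na(top$h_parent) &
                   top$element[top$h_parent] %in% POLAR_ELEMENTS)
  acc <- which(top$is_protein & top$is_heavy & top$element %in% POLAR_ELEMENTS)
  list(donor_h = don_h, donor_heavy = top$h_parent[don_h], acceptor = acc)
}

#' Detect hydrogen bonds in one frame
#'
#' @param traj a `trajectory` whose topology includes protein hydrogens.
#' @param frame 1-based frame index.
#' @param crit an [hbond_criteria()].
#' @return integer matrix with columns `donor_h`, `donor_heavy`, `acceptor`
#'   (atom indices), one row per bonded pair. Bifurcated bonds appear as
#'   separate rows.
#' @export
detect_hbonds_frame <- function(traj, frame, crit = hbond_criteria()) {
  top <- traj$topology
  p <- hbond_participants(top)
  if (!length(p$donor_h))
    stop_ptfluct("topology has no polar protein hydrogens", "ptfluct_topology_error")
  box <- if (!is.null(traj$boxes)) traj$boxes[[frame]] else NULL
  xyz <- traj$coords[frame, , , drop = TRUE]
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
  hpos <- xyz[p$donor_h, , drop = FALSE]
  apos <- xyz[p$acceptor, , drop = FALSE]
  if (is.null(box)) {
    ia <- rep(seq_along(p$acceptor), each = length(p$donor_h))
    ih <- rep(seq_along(p$donor_h), times = length(p$acceptor))
    dmat <- matrix(sqrt(rowSums((apos[ia, , drop = FALSE] -
                                   hpos[ih, , drop = FALSE])^2)),
                   length(p$donor_h), length(p$acceptor))
  } else {
    dmat <- min_image_cross_dist(hpos, apos, box)
  }
  cand <- which(dmat < crit$d_HA_max, arr.ind = TRUE)
  if (!nrow(cand))
    return(matrix(integer(0), 0, 3,
                  dimnames = list(NULL, c("donor_h", "donor_heavy", "acceptor"))))
  dh <- p$donor_h[cand[, 1]]
  dheavy <- p$donor_heavy[cand[, 1]]
  ac <- p$acceptor[cand[, 2]]
  keep <- ac != dheavy & ac != dh
  dh <- dh[keep]; dheavy <- dheavy[keep]; ac <- ac[keep]
  if (!length(dh))
    return(matrix(integer(0), 0, 3,
                  dimnames = list(NULL, c("donor_h", "donor_heavy", "acceptor"))))
  ## D-H...A angle at the hydrogen, from minimum-image bond vectors
  vd <- xyz[dheavy, , drop = FALSE] - xyz[dh, , drop = FALSE]
  va <- xyz[ac, , drop = FALSE] - xyz[dh, , drop = FALSE]
  if (!is.null(box)) {
    vd <- min_image_displacement(vd, box)
    va <- min_image_displacement(va, box)
  }
  cosang <- rowSums(vd * va) / sqrt(rowSums(vd^2) * rowSums(va^2))
  ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  keep <- ang > crit$angle_min
  out <- cbind(donor_h = dh[keep], donor_heavy = dheavy[keep],
               acceptor = ac[keep])
  out[order(out[, "donor_h"], out[, "acceptor"]), , drop = FALSE]
}

#' Detect hydrogen bonds in every frame
#'
#' @inheritParams detect_hbonds_frame
#' @param frames frames to analyse (default all).
#' @return list of per-frame pair matrices (see [detect_hbonds_frame()]).
#' @export
detect_hbonds <- function(traj, crit = hbond_criteria(),
                          frames = seq_len(n_frames(traj))) {
  lapply(frames, function(f) detect_hbonds_frame(traj, f, crit))
}

#' Track continuous hydrogen-bond events
#'
#' Scans per-frame bond sets for maximal runs of consecutive frames in which
#' each (donor hydrogen, acceptor) pair is present. Events touching either
#' trajectory end are flagged `truncated` and included. A configurable gap
#' tolerance (default 0 frames, the strict reading of "continuously formed")
#' allows brief interruptions to be bridged for sensitivity analysis.
#'
#' @param per_frame_sets list of per-frame pair matrices from [detect_hbonds()].
#' @param frame_interval ps per frame.
#' @param gap_tolerance number of consecutive absent frames bridged (default 0).
#' @return list with `events` (data frame: donor_h, donor_heavy, acceptor,
#'   start_frame, end_frame half-open, duration ps, truncated) and `pairs`
#'   (data frame: donor_h, donor_heavy, acceptor, n_events, tau_ij ps).
#' @export
track_events <- function(per_frame_sets, frame_interval, gap_tolerance = 0) {
  nf <- length(per_frame_sets)
  if (nf == 0L)
    stop_ptfluct("empty frame sequence", "ptfluct_coverage_error")
  nrows <- vapply(per_frame_sets, nrow, integer(1))
  empty_events <- data.frame(donor_h = integer(0), donor_heavy = integer(0),
                             acceptor = integer(0), start_frame = integer(0),
                             end_frame = integer(0), duration = numeric(0),
                             truncated = logical(0))
  empty_pairs <- data.frame(donor_h = integer(0), donor_heavy = integer(0),
                            acceptor = integer(0), n_events = integer(0),
                            tau_ij = numeric(0))
  if (sum(nrows) == 0L)
    return(list(events = empty_events, pairs = empty_pairs))
  long <- data.frame(
    frame = rep.int(seq_len(nf), nrows),
    donor_h = unlist(lapply(per_frame_sets, function(m) m[, "donor_h"])),
    donor_heavy = unlist(lapply(per_frame_sets, function(m) m[, "donor_heavy"])),
    acceptor = unlist(lapply(per_frame_sets, function(m) m[, "acceptor"]))
  )
  ord <- order(long$donor_h, long$acceptor, long$frame)
  long <- long[ord, ]
  new_pair <- c(TRUE, long$donor_h[-1] != long$donor_h[-nrow(long)] |
                  long$acceptor[-1] != long$acceptor[-nrow(long)])
  gap <- c(0, diff(long$frame))
  new_event <- new_pair | gap > (gap_tolerance + 1L)
  eid <- cumsum(new_event)
  first <- tapply(long$frame, eid, min)
  last <- tapply(long$frame, eid, max)
  head_rows <- which(new_event)
  events <- data.frame(
    donor_h = long$donor_h[head_rows],
    donor_heavy = long$donor_heavy[head_rows],
    acceptor = long$acceptor[head_rows],
    start_frame = as.integer(first),
    end_frame = as.integer(last) + 1L,  # half-open
    duration = (as.numeric(last) - as.numeric(first) + 1) * frame_interval,
    truncated = as.integer(first) == 1L | as.integer(last) == nf
  )
  key <- paste(events$donor_h, events$acceptor)
  pairs <- do.call(rbind, lapply(split(seq_len(nrow(events)), key), function(i) {
    data.frame(donor_h = events$donor_h[i[1]],
               donor_heavy = events$donor_heavy[i[1]],
               acceptor = events$acceptor[i[1]],
               n_events = length(i),
               tau_ij = mean(events$duration[i]))
  }))
  pairs <- pairs[order(pairs$donor_h, pairs$acceptor), ]
  rownames(pairs) <- NULL
  rownames(events) <- NULL
  list(events = events, pairs = pairs)
}

#' Summarize hydrogen-bond population and lifetimes
#'
#' `N_HB` is the block-averaged per-frame bond count over *all* pairs;
#' `tau_HB` is the unweighted mean of `tau_ij` over unique pairs whose
#' lifetime does not exceed `exclusion_threshold` (default 1000 ps; pairs
#' above it lack statistics and are reported in `excluded_pairs` instead).
#' Block errors re-track events within each block.
#'
#' @param pairs pair table from [track_events()].
#' @param per_frame_sets the per-frame bond sets the pairs came from.
#' @param frame_interval ps per frame.
#' @param blocks a [block_spec()].
#' @param exclusion_threshold ps; pairs with `tau_ij` above it are excluded
#'   from `tau_HB` (never from `N_HB`).
#' @param gap_tolerance passed to the per-block re-tracking.
#' @return a `lifetime_summary`: `n_hb`, `n_hb_error`, `n_unique_pairs`,
#'   `n_included_pairs`, `tau_hb`, `tau_hb_error`, `excluded_pairs`.
#' @export
summarize_lifetimes <- function(pairs, per_frame_sets, frame_interval,
                                blocks = block_spec(),
                                exclusion_threshold = 1000,
                                gap_tolerance = 0) {
  counts <- vapply(per_frame_sets, nrow, integer(1))
  nf <- length(counts)
  blk <- block_frame_indices(nf, frame_interval, blocks)
  n_hb_blocks <- vapply(blk, function(i) mean(counts[i]), numeric(1))
  excluded <- pairs[pairs$tau_ij > exclusion_threshold, , drop = FALSE]
  included <- pairs[pairs$tau_ij <= exclusion_threshold, , drop = FALSE]
  if (nrow(pairs) && !nrow(included))
    stop_ptfluct("all hydrogen-bond pairs excluded by the lifetime threshold",
                 "ptfluct_degenerate_summary_error")
  if (nrow(excluded)) {
    excluded$reason <- sprintf("tau_ij > %g ps", exclusion_threshold)
  } else {
    excluded <- cbind(excluded, data.frame(reason = character(0)))
  }
  tau_blocks <- vapply(blk, function(i) {
    tr <- track_events(per_frame_sets[i], frame_interval, gap_tolerance)
    p <- tr$pairs
    p <- p[p$tau_ij <= exclusion_threshold, , drop = FALSE]
    if (nrow(p)) mean(p$tau_ij) else NA_real_
  }, numeric(1))
  structure(list(
    n_hb = mean(vapply(blk, function(i) mean(counts[i]), numeric(1))),
    n_hb_error = block_sem(n_hb_blocks),
    n_unique_pairs = nrow(pairs),
    n_included_pairs = nrow(included),
    tau_hb = if (nrow(included)) mean(included$tau_ij) else NA_real_,
    tau_hb_error = block_sem(tau_blocks[!is.na(tau_blocks)]),
    excluded_pairs = excluded,
    exclusion_threshold = exclusion_threshold
  ), class = "lifetime_summary")
}

#' @export
print.lifetime_summary <- function(x, ...) {
  cat(sprintf("N_HB = %.4g +/- %.2g; N = %d unique pairs (%d in tau_HB); tau_HB = %.4g +/- %.2g ps\n",
              x$n_hb, ifelse(is.na(x$n_hb_error), 0, x$n_hb_error),
              x$n_unique_pairs, x$n_included_pairs, x$tau_hb,
              ifelse(is.na(x$tau_hb_error), 0, x$tau_hb_error)))
  if (nrow(x$excluded_pairs))
    cat(sprintf("  %d pair(s) excluded from tau_HB (threshold %g ps)\n",
                nrow(x$excluded_pairs), x$exclusion_threshold))
  invisible(x)
}

#' Acceptor-level fluctuation-lifetime correlation dataset
#'
#' For every acceptor atom, averages the lifetime over all donors of that
#' acceptor (event-weighted by default: total bonded time divided by total
#' number of events; `weighting = "pair"` averages tau_ij unweighted) and
#' pairs it with the acceptor's inverse mean-square fluctuation. Acceptors
#' with average lifetime of at most `min_tau` (default 2 ps) are dropped.
#'
#' @param msf an `msf_result` from the same trajectory.
#' @param pairs pair table from [track_events()].
#' @param min_tau ps; keep acceptors with lifetime strictly above this.
#' @param weighting `"event"` (default) or `"pair"`.
#' @return data frame (`acceptor`, `tau_acceptor`, `inv_msf`, `ln_tau`) with
#'   attribute `pearson_r`, the Pearson correlation of `inv_msf` vs `ln_tau`.
#' @export
fluctuation_lifetime_dataset <- function(msf, pairs, min_tau = 2,
                                         weighting = c("event", "pair")) {
  weighting <- match.arg(weighting)
  if (!nrow(pairs)) {
    warning("no hydrogen-bond pairs: empty correlation dataset", call. = FALSE)
    out <- data.frame(acceptor = integer(0), tau_acceptor = numeric(0),
                      inv_msf = numeric(0), ln_tau = numeric(0))
    attr(out, "pearson_r") <- NA_real_
    return(out)
  }
  sp <- split(pairs, pairs$acceptor)
  tau_acc <- vapply(sp, function(p) {
    if (weighting == "event") sum(p$n_events * p$tau_ij) / sum(p$n_events)
    else mean(p$tau_ij)
  }, numeric(1))
  acc <- as.integer(names(sp))
  msf_acc <- msf$per_atom_mean[as.character(acc)]
  known <- !is.na(msf_acc)
  if (any(!known))
    warning(sprintf("%d acceptor(s) outside the MSF selection dropped",
                    sum(!known)), call. = FALSE)
  keep <- known & tau_acc > min_tau
  out <- data.frame(acceptor = acc[keep], tau_acceptor = tau_acc[keep],
                    inv_msf = 1 / msf_acc[keep], ln_tau = log(tau_acc[keep]))
  rownames(out) <- NULL
  if (!nrow(out))
    warning("no acceptors pass the lifetime filter: empty dataset", call. = FALSE)
  attr(out, "pearson_r") <- if (nrow(out) >= 3)
    stats::cor(out$inv_msf, out$ln_tau) else NA_real_
  out
}
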
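# Block-averaged mean-square fluctuations of protein heavy atoms.
#
# MSF = (1/N_HA) * sum_i <dr_i^2>, where <dr_i^2> is, for each heavy atom i,
# the block average over fixed-length intervals of the variance of the atom's
# position about its within-block mean position (summed over x, y, z).

## Kabsch least-squares rotation of `mov` (n x 3) onto `ref` (n x 3), both
## already centred. Returns the rotated coordinates.
kabsch_rotate <- function(mov, ref) {
  h <- crossprod(mov, ref)
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  r <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  mov %*% t(r)
}

## Superpose every frame of X (frames x atoms x 3) on a reference using the
## atoms in `fit_idx`; all atoms are transformed.
superpose_frames <- function(X, ref, fit_idx) {
  nf <- dim(X)[1]
  ref_fit <- ref[fit_idx, , drop = FALSE]
  ref_cen <- colMeans(ref_fit)
  ref_fit <- sweep(ref_fit, 2L, ref_cen)
  for (f in seq_len(nf)) {
    fr <- X[f, , , drop = TRUE]
    mov_fit <- fr[fit_idx, , drop = FALSE]
    cen <- colMeans(mov_fit)
    h <- crossprod(sweep(mov_fit, 2L, cen), ref_fit)
    s <- svd(h)
    d <- sign(det(s$v %*% t(s$u)))
    r <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
    X[f, , ] <- sweep(fr, 2L, cen) %*% t(r) + rep(ref_cen, each = nrow(fr))
  }
  X
}

#' Block-averaged mean-square fluctuations
#'
#' For each block, each selected atom's fluctuation is the variance of its
#' position about the within-block mean position (sum over x, y, z; population
#' variance). Per-atom values average the blocks; the global MSF averages the
#' per-atom means over all protein heavy atoms, and its error bar is the
#' standard error of the mean over per-block global values.
#'
#' With `superpose = TRUE` (default), frames of each block are least-squares
#' superposed on the protein heavy atoms: first onto the block's first frame,
#' then twice onto the refreshed within-block mean structure, so that
#' rigid-body tumbling does not inflate the fluctuations.
#'
#' @param traj a `trajectory`.
#' @param blocks a [block_spec()].
#' @param superpose remove rigid-body motion per block (default `TRUE`).
#' @param selection integer atom indices to analyse; default: protein heavy
#'   atoms (ligand/ion/virtual atoms excluded).
#' @return an object of class `msf_result` with elements `per_atom_per_block`
#'   (atoms x blocks matrix, Angstrom^2), `per_atom_mean`, `global_msf`,
#'   `global_error`, `per_residue` (data frame), `atoms`, `n_blocks`.
#' @export
compute_msf <- function(traj, blocks = block_spec(), superpose = TRUE,
                        selection = NULL) {
  top <- traj$topology
  if (is.null(selection))
    selection <- which(top$is_protein & top$is_heavy)
  if (!length(selection))
    stop_ptfluct("no protein heavy atoms selected", "ptfluct_selection_error")
  idx <- block_frame_indices(n_frames(traj), traj$frame_interval, blocks)
  nb <- length(idx)
  na <- length(selection)
  per_block <- matrix(0, na, nb)
  for (b in seq_len(nb)) {
    X <- traj$coords[idx[[b]], selection, , drop = FALSE]
    if (superpose) {
      fit_idx <- seq_len(na)  # selection is the fit set
      ref <- X[1, , , drop = TRUE]
      if (is.null(dim(ref))) ref <- matrix(ref, ncol = 3)
      X <- superpose_frames(X, ref, fit_idx)
      for (iter in 1:2) {
        ref <- apply(X, c(2, 3), mean)
        X <- superpose_frames(X, ref, fit_idx)
      }
    }
    mu <- apply(X, c(2, 3), mean)
    dev2 <- sweep(X, c(2, 3), mu)^2
    per_block[, b] <- apply(dev2, 2, mean) * 3  # mean over frames&dims * 3 dims
  }
  per_atom <- rowMeans(per_block)
  global_blocks <- colMeans(per_block)
  res_idx <- top$residue_index[selection]
  per_residue <- data.frame(
    residue_index = sort(unique(res_idx)),
    residue_name = top$residue_name[selection][match(sort(unique(res_idx)), res_idx)],
    msf = as.numeric(tapply(per_atom, res_idx, mean)[as.character(sort(unique(res_idx)))]),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(
    per_atom_per_block = per_block,
    per_atom_mean = stats::setNames(per_atom, selection),
    global_msf = mean(per_atom),
    global_error = block_sem(global_blocks),
    per_residue = per_residue,
    atoms = selection,
    n_blocks = nb,
    superpose = superpose
  ), class = "msf_result")
}

#' @export
print.msf_result <- function(x, ...) {
  cat(sprintf("MSF over %d protein heavy atoms, %d block(s): %.4g +/- %.2g A^2\n",
              length(x$atoms), x$n_blocks, x$global_msf,
              ifelse(is.na(x$global_error), 0, x$global_error)))
  invisible(x)
}

#' Per-residue fluctuation difference map between two conditions
#'
#' Computes `b - a` per residue and a normalized diverging colour coordinate
#' anchored at (-0.5, 0, 2.0) Angstrom^2 (low, mid, high): differences are
#' clipped to that range and scaled to -1..0 (negative side) and 0..1
#' (positive side).
#'
#' @param a,b `msf_result` objects for the two conditions (same residues).
#' @param anchors numeric length-3 colour anchors, Angstrom^2.
#' @return data frame: `residue_index`, `residue_name`, `delta_msf`,
#'   `clipped`, `color_coord`.
#' @export
delta_msf_map <- function(a, b, anchors = c(-0.5, 0, 2.0)) {
  ra <- a$per_residue; rb <- b$per_residue
  if (nrow(ra) != nrow(rb) ||
      any(ra$residue_index != rb$residue_index) ||
      any(ra$residue_name != rb$residue_name))
    stop_ptfluct("residue structures of the two conditions do not align",
                 "ptfluct_alignment_error")
  d <- rb$msf - ra$msf
  lo <- anchors[1]; mid <- anchors[2]; hi <- anchors[3]
  clipped <- pmin(pmax(d, lo), hi)
  cc <- ifelse(clipped >= mid, (clipped - mid) / (hi - mid),
               (clipped - mid) / (mid - lo))
  data.frame(residue_index = ra$residue_index, residue_name = ra$residue_name,
             delta_msf = d, clipped = clipped, color_coord = cc,
             stringsAsFactors = FALSE)
}
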
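# Synthetic-trajectory generators with known ground truth. These emulate the
# statistical structure the analysis stages assume -- stationary per-atom
# fluctuations, two-state hydrogen-bond occupancy with exponential dwells,
# planted interior/exterior waters, fluctuating box volumes -- not the
# physics of a force field. Every generator is reproducible from its seed.

## pseudo-protein topology: n_residues x atoms_per_residue carbon atoms
pseudo_protein_topology <- function(n_residues, atoms_per_residue) {
  n <- n_residues * atoms_per_residue
  build_topology(
    name = rep(c("CA", paste0("CB", seq_len(max(0, atoms_per_residue - 1)))),
               n_residues)[seq_len(n)],
    residue_index = rep(seq_len(n_residues), each = atoms_per_residue),
    residue_name = "ALA", element = rep("C", n)
  )
}

## lattice of well-separated sites inside a box
lattice_sites <- function(n, spacing = 6) {
  k <- ceiling(n^(1 / 3))
  g <- expand.grid(x = seq_len(k), y = seq_len(k), z = seq_len(k))
  as.matrix(g[seq_len(n), ]) * spacing
}

#' Generate an Ornstein-Uhlenbeck pseudo-protein trajectory
#'
#' Each heavy atom fluctuates independently about a fixed lattice site as an
#' overdamped harmonic (Ornstein-Uhlenbeck) process whose stationary 3D
#' mean-square fluctuation is `3 * KB_KCAL * temperature / kappa` -- the
#' generator's ground truth. `friction` is the relaxation rate of the
#' process in ps^-1 (correlation time `1/friction`); `kappa` sets only the
#' stationary variance. Sampling uses the exact AR(1) discretization, so any
#' frame interval is unbiased.
#'
#' @param n_residues,atoms_per_residue pseudo-protein size.
#' @param kappa per-atom spring constants, kcal mol^-1 A^-2 (recycled).
#' @param temperature K.
#' @param friction relaxation rate, ps^-1.
#' @param frame_interval ps.
#' @param n_frames frames to generate.
#' @param seed RNG seed.
#' @param label optional [condition_label()].
#' @param box periodic box (default: generous cube).
#' @return a `trajectory`; ground truth in attribute `ground_truth`
#'   (`msf_per_atom`, `kappa`, `sites`).
#' @export
generate_ou_protein <- function(n_residues, atoms_per_residue = 1, kappa,
                                temperature, friction = 1, frame_interval = 1,
                                n_frames = 1000, seed = 1,
                                label = NULL, box = NULL) {
  if (any(kappa <= 0) || friction <= 0)
    stop_ptfluct("kappa and friction must be > 0", "ptfluct_spec_error")
  top <- pseudo_protein_topology(n_residues, atoms_per_residue)
  n <- nrow(top)
  kappa <- rep_len(kappa, n)
  sites <- lattice_sites(n)
  if (is.null(box)) box <- cubic_box(max(sites) + 20)
  sigma2 <- KB_KCAL * temperature / kappa        # per-coordinate variance
  rho <- exp(-friction * frame_interval)         # AR(1) coefficient
  innov_sd <- sqrt(sigma2 * (1 - rho^2))
  set.seed(seed)
  coords <- array(0, dim = c(n_frames, n, 3))
  x <- matrix(stats::rnorm(n * 3, sd = sqrt(sigma2)), n, 3)  # stationary start
  for (f in seq_len(n_frames)) {
    coords[f, , ] <- sites + x
    x <- rho * x + matrix(stats::rnorm(n * 3), n, 3) * innov_sd
  }
  traj <- trajectory(top, coords, box, frame_interval, label)
  attr(traj, "ground_truth") <- list(msf_per_atom = 3 * sigma2, kappa = kappa,
                                     sites = sites, friction = friction)
  traj
}

#' Generate telegraph-process hydrogen-bond occupancies
#'
#' Each pair alternates between bonded and unbonded states with exponential
#' dwell times of means `tau_on` and `tau_off` ps (started in the stationary
#' state), observed on the frame grid. Returns the discretized per-frame pair
#' sets, the ground-truth run-length event list, and the continuous-time
#' switch points.
#'
#' The mean *observed* bonded-run duration differs from `tau_on` because of
#' discretization: the sampled chain is two-state Markov with
#' `p11 = p_on + p_off * exp(-lambda * dt)` (`lambda = 1/tau_on + 1/tau_off`,
#' `p_on = tau_on/(tau_on + tau_off)`), giving expected run duration
#' `dt / (1 - p11)`; see [telegraph_expected_run_duration()].
#'
#' @param n_pairs number of independent pairs.
#' @param tau_on,tau_off mean bonded/unbonded dwell times, ps (recycled).
#' @param duration total time, ps.
#' @param frame_interval ps.
#' @param seed RNG seed.
#' @return list: `per_frame_sets` (as from [detect_hbonds()], with synthetic
#'   atom indices), `occupancy` (frames x pairs logical), `pair_atoms`
#'   (donor_h/donor_heavy/acceptor indices per pair), `spec`.
#' @export
generate_hbond_occupancy <- function(n_pairs, tau_on, tau_off,
                                     duration, frame_interval = 1, seed = 1) {
  tau_on <- rep_len(tau_on, n_pairs)
  tau_off <- rep_len(tau_off, n_pairs)
  if (any(tau_on < frame_interval))
    warning("tau_on below frame_interval: strong discretization bias expected",
            call. = FALSE)
  nf <- as.integer(floor(duration / frame_interval))
  set.seed(seed)
  occupancy <- matrix(FALSE, nf, n_pairs)
  t_grid <- (seq_len(nf) - 1L) * frame_interval
  for (p in seq_len(n_pairs)) {
    p_on <- tau_on[p] / (tau_on[p] + tau_off[p])
    ## stationary start: state from the stationary law, first dwell a fresh
    ## exponential (memorylessness of the residual dwell)
    state0 <- stats::runif(1) < p_on
    means <- if (state0) c(tau_on[p], tau_off[p]) else c(tau_off[p], tau_on[p])
    dwells <- numeric(0)
    total <- 0
    while (total < duration) {
      k <- max(64L, ceiling((duration - total) / min(means)) * 2L)
      new <- stats::rexp(k, 1 / means[(length(dwells) + seq_len(k) - 1L) %% 2L + 1L])
      dwells <- c(dwells, new)
      total <- total + sum(new)
    }
    ## dwell index containing each grid time; odd indices carry state0
    idx <- findInterval(t_grid, cumsum(dwells)) + 1L
    occupancy[, p] <- xor(state0, idx %% 2L == 0L)
  }
  ## synthetic atom indices: pair p uses donor heavy 3p-2, donor H 3p-1,
  ## acceptor 3p (consistent with generate_hbond_geometry below)
  pair_atoms <- data.frame(pair = seq_len(n_pairs),
                           donor_heavy = 3L * seq_len(n_pairs) - 2L,
                           donor_h = 3L * seq_len(n_pairs) - 1L,
                           acceptor = 3L * seq_len(n_pairs))
  per_frame_sets <- lapply(seq_len(nf), function(f) {
    on <- which(occupancy[f, ])
    cbind(donor_h = pair_atoms$donor_h[on],
          donor_heavy = pair_atoms$donor_heavy[on],
          acceptor = pair_atoms$acceptor[on])
  })
  list(per_frame_sets = per_frame_sets, occupancy = occupancy,
       pair_atoms = pair_atoms,
       spec = list(n_pairs = n_pairs, tau_on = tau_on, tau_off = tau_off,
                   duration = duration, frame_interval = frame_interval,
                   seed = seed))
}

#' Expected observed bonded-run duration of a sampled telegraph process
#'
#' Closed form for the discretization-corrected mean continuous-run duration
#' when a telegraph process with exponential dwells (`tau_on`, `tau_off`) is
#' observed every `dt` ps: runs of the sampled two-state Markov chain are
#' geometric with persistence `p11`, so the expected run is `dt / (1 - p11)`.
#'
#' @param tau_on,tau_off mean dwell times, ps.
#' @param dt sampling interval, ps.
#' @return expected observed run duration, ps.
#' @export
telegraph_expected_run_duration <- function(tau_on, tau_off, dt) {
  lambda <- 1 / tau_on + 1 / tau_off
  p_on <- tau_on / (tau_on + tau_off)
  p11 <- p_on + (1 - p_on) * exp(-lambda * dt)
  dt / (1 - p11)
}

#' Realize a hydrogen-bond occupancy schedule as explicit geometry
#'
#' Builds a trajectory of donor/hydrogen/acceptor triplets (one per pair,
#' well separated) in which, at every frame, the acceptor sits at 1.9 A from
#' the hydrogen in the D-H direction (distance and angle criteria met) when
#' the schedule says bonded, and at `3.5` A (criterion failed) otherwise, so
#' [detect_hbonds_frame()] reproduces the schedule exactly.
#'
#' @param occ result of [generate_hbond_occupancy()].
#' @return a `trajectory`.
#' @export
generate_hbond_geometry <- function(occ) {
  n_pairs <- occ$spec$n_pairs
  nf <- nrow(occ$occupancy)
  n <- 3L * n_pairs
  top <- build_topology(
    name = rep(c("N", "H", "O"), n_pairs),
    residue_index = rep(seq_len(n_pairs), each = 3L),
    residue_name = "ALA",
    element = rep(c("N", "H", "O"), n_pairs),
    h_parent = as.integer(t(cbind(NA, 3L * seq_len(n_pairs) - 2L, NA)))
  )
  sites <- lattice_sites(n_pairs, spacing = 12)
  box <- cubic_box(max(sites) + 24)
  coords <- array(0, dim = c(nf, n, 3))
  for (p in seq_len(n_pairs)) {
    d <- sites[p, ]
    h <- d + c(1, 0, 0)                      # D-H along +x, 1.0 A
    coords[, 3 * p - 2, ] <- matrix(d, nf, 3, byrow = TRUE)
    coords[, 3 * p - 1, ] <- matrix(h, nf, 3, byrow = TRUE)
    on <- occ$occupancy[, p]
    a_on <- h + c(1.9, 0, 0)                 # angle 180 deg, 1.9 A
    a_off <- h + c(3.5, 0, 0)
    if (any(on))
      coords[on, 3 * p, ] <- matrix(a_on, sum(on), 3, byrow = TRUE)
    if (any(!on))
      coords[!on, 3 * p, ] <- matrix(a_off, sum(!on), 3, byrow = TRUE)
  }
  trajectory(top, coords, box, occ$spec$frame_interval)
}

#' Generate a solvated scene with a planted interior-water count
#'
#' Places a compact cluster of protein heavy atoms, then `n_interior` waters
#' that satisfy the interior rule by construction (3.4-3.9 A from a protein
#' atom, no other water within the exclusion distance) and `n_exterior`
#' waters that violate it (farther than `d_protein_max` from every protein
#' atom). Placement retries up to `max_tries` before failing.
#'
#' @param n_protein_atoms protein heavy atoms.
#' @param n_interior,n_exterior planted water counts.
#' @param box periodic box (default 40 A cube).
#' @param crit an [interior_water_criteria()] the construction must satisfy.
#' @param n_frames copies of the scene (static; default 1).
#' @param seed RNG seed.
#' @param max_tries placement retries per water.
#' @return a `trajectory`; planted interior residue indices in attribute
#'   `ground_truth$interior_residues`.
#' @export
generate_solvated_scene <- function(n_protein_atoms = 20, n_interior = 3,
                                    n_exterior = 40, box = cubic_box(40),
                                    crit = interior_water_criteria(),
                                    n_frames = 1, seed = 1, max_tries = 2000) {
  set.seed(seed)
  ## compact protein blob near the box centre
  centre <- colSums(unclass(box)) / 2
  ppos <- matrix(stats::rnorm(n_protein_atoms * 3, sd = 3), ncol = 3)
  ppos <- sweep(ppos, 2L, centre, "+")
  wpos <- matrix(numeric(0), 0, 3)
  place <- function(candidate_fun, accept_fun) {
    for (try in seq_len(max_tries)) {
      cand <- candidate_fun()
      if (accept_fun(cand)) return(cand)
    }
    stop_ptfluct("could not place water satisfying the planted constraints",
                 "ptfluct_construction_error")
  }
  dmin <- function(p, set) {
    if (!nrow(set)) return(Inf)
    min(minimum_image_distance(matrix(p, nrow(set), 3, byrow = TRUE), set, box))
  }
  for (k in seq_len(n_interior)) {
    wpos <- rbind(wpos, place(
      function() {
        anchor <- ppos[sample.int(nrow(ppos), 1), ]
        u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
        anchor + u * stats::runif(1, crit$d_water_min + 0.05,
                                  crit$d_protein_max - 0.05)
      },
      function(p) {
        dp <- dmin(p, ppos)
        dp < crit$d_protein_max && dp > 1.5 &&
          dmin(p, wpos) >= crit$d_water_min + 0.05
      }))
  }
  n_int_placed <- nrow(wpos)
  for (k in seq_len(n_exterior)) {
    wpos <- rbind(wpos, place(
      function() stats::runif(3) %*% unclass(box),
      function(p) dmin(p, ppos) > crit$d_protein_max + 0.05 &&
        dmin(p, wpos[seq_len(n_int_placed), , drop = FALSE]) >=
          crit$d_water_min + 0.05
    ))
  }
  nw <- nrow(wpos)
  np <- n_protein_atoms
  top <- build_topology(
    name = c(rep("CA", np), rep(c("O", "H1", "H2"), nw)),
    residue_index = c(rep(seq_len(np), each = 1),
                      np + rep(seq_len(nw), each = 3)),
    residue_name = c(rep("ALA", np), rep("HOH", 3 * nw)),
    element = c(rep("C", np), rep(c("O", "H", "H"), nw)),
    h_parent = c(rep(NA_integer_, np),
                 as.integer(t(cbind(NA, np + 3 * seq_len(nw) - 2,
                                    np + 3 * seq_len(nw) - 2))))
  )
  xyz <- matrix(0, np + 3 * nw, 3)
  xyz[seq_len(np), ] <- ppos
  for (w in seq_len(nw)) {
    o <- wpos[w, ]
    xyz[np + 3 * w - 2, ] <- o
    xyz[np + 3 * w - 1, ] <- o + c(0.96, 0, 0)
    xyz[np + 3 * w, ] <- o + c(-0.24, 0.93, 0)
  }
  coords <- array(0, dim = c(n_frames, nrow(xyz), 3))
  for (f in seq_len(n_frames)) coords[f, , ] <- xyz
  traj <- trajectory(top, coords, box, 1)
  attr(traj, "ground_truth") <- list(
    interior_residues = np + seq_len(n_interior),
    n_interior = n_interior, n_exterior = n_exterior)
  traj
}

#' Generate a Gaussian box-volume series
#'
#' @param mean,sd mean and standard deviation, Angstrom^3 (`sd >= 0`).
#' @param n_frames series length.
#' @param seed RNG seed.
#' @return numeric vector of per-frame volumes.
#' @export
generate_volume_series <- function(mean, sd, n_frames, seed = 1) {
  if (sd < 0) stop_ptfluct("sd must be >= 0", "ptfluct_spec_error")
  set.seed(seed)
  stats::rnorm(n_frames, mean, sd)
}

#' Attach a fluctuating box realizing a volume series
#'
#' Replaces a trajectory's boxes with orthorhombic cells whose per-frame
#' volumes equal `volumes` exactly (one axis carries the volume, so the
#' scalar triple product reproduces it without rounding), giving box-volume
#' statistics a known ground truth.
#'
#' @param traj a `trajectory`.
#' @param volumes per-frame volumes, Angstrom^3 (length `n_frames(traj)`).
#' @export
set_volume_series <- function(traj, volumes) {
  stopifnot(length(volumes) == n_frames(traj), all(volumes > 0))
  traj$boxes <- lapply(volumes, function(v) ortho_box(v, 1, 1))
  traj$constant_box <- FALSE
  traj
}
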
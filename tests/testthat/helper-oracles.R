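# Independent brute-force oracles used to cross-check the vectorized
# implementations. These deliberately use plain loops and explicit
# 27-image scans, sharing no code with the package internals.

## wrap a point into the central cell (fractional coordinates in [0, 1))
bf_wrap <- function(p, m) {
  f <- solve(t(m), p)
  drop(t(m) %*% (f - floor(f)))
}

bf_min_image_disp <- function(a, b, box) {
  m <- unclass(box)
  d0 <- bf_wrap(b, m) - bf_wrap(a, m)
  best <- NULL
  best_r2 <- Inf
  for (i in -2:2) for (j in -2:2) for (k in -2:2) {
    cand <- d0 + i * m[1, ] + j * m[2, ] + k * m[3, ]
    r2 <- sum(cand^2)
    if (r2 < best_r2) { best_r2 <- r2; best <- cand }
  }
  best
}

## exhaustive image scan after wrapping both points into the cell
bf_min_image_dist <- function(a, b, box, shell = 2) {
  m <- unclass(box)
  d0 <- bf_wrap(b, m) - bf_wrap(a, m)
  best <- Inf
  for (i in -shell:shell) for (j in -shell:shell) for (k in -shell:shell) {
    cand <- d0 + i * m[1, ] + j * m[2, ] + k * m[3, ]
    best <- min(best, sqrt(sum(cand^2)))
  }
  best
}

bf_detect_hbonds <- function(traj, frame, crit = hbond_criteria()) {
  top <- traj$topology
  box <- traj$boxes[[frame]]
  xyz <- traj$coords[frame, , , drop = TRUE]
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
  polar <- c("N", "O", "S")
  donors <- which(top$element == "H" & top$is_protein & !top$is_virtual &
                    !is.na(top$h_parent) & top$element[top$h_parent] %in% polar)
  acceptors <- which(top$is_protein & top$is_heavy & top$element %in% polar)
  out <- NULL
  for (h in donors) {
    d <- top$h_parent[h]
    for (a in acceptors) {
      if (a == d) next
      dha <- bf_min_image_dist(xyz[h, ], xyz[a, ], box)
      if (dha >= crit$d_HA_max) next
      vd <- bf_min_image_disp(xyz[h, ], xyz[d, ], box)
      va <- bf_min_image_disp(xyz[h, ], xyz[a, ], box)
      ang <- acos(max(-1, min(1, sum(vd * va) /
                                sqrt(sum(vd^2) * sum(va^2))))) * 180 / pi
      if (ang > crit$angle_min)
        out <- rbind(out, c(donor_h = h, donor_heavy = d, acceptor = a))
    }
  }
  if (is.null(out))
    out <- matrix(integer(0), 0, 3,
                  dimnames = list(NULL, c("donor_h", "donor_heavy", "acceptor")))
  out[order(out[, 1], out[, 3]), , drop = FALSE]
}

bf_interior_waters <- function(traj, frame, crit = interior_water_criteria()) {
  top <- traj$topology
  box <- traj$boxes[[frame]]
  xyz <- traj$coords[frame, , , drop = TRUE]
  w_ox <- which(top$is_water & top$element == "O")
  p_heavy <- which(top$is_protein & top$is_heavy)
  interior <- integer(0)
  for (w in w_ox) {
    near <- FALSE
    for (p in p_heavy)
      if (bf_min_image_dist(xyz[w, ], xyz[p, ], box) < crit$d_protein_max) {
        near <- TRUE; break
      }
    if (!near) next
    lonely <- TRUE
    for (w2 in setdiff(w_ox, w))
      if (bf_min_image_dist(xyz[w, ], xyz[w2, ], box) < crit$d_water_min) {
        lonely <- FALSE; break
      }
    if (lonely) interior <- c(interior, top$residue_index[w])
  }
  interior
}

## run-length scan of a logical occupancy matrix (frames x pairs)
bf_run_length_events <- function(occupancy, pair_atoms, frame_interval) {
  nf <- nrow(occupancy)
  per_pair <- lapply(seq_len(ncol(occupancy)), function(p) {
    r <- rle(occupancy[, p])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    on <- which(r$values)
    if (!length(on)) return(NULL)
    data.frame(
      donor_h = pair_atoms$donor_h[p],
      acceptor = pair_atoms$acceptor[p],
      start_frame = starts[on], end_frame = ends[on] + 1L,
      duration = r$lengths[on] * frame_interval,
      truncated = starts[on] == 1L | ends[on] == nf)
  })
  out <- do.call(rbind, per_pair)
  if (is.null(out))
    out <- data.frame(donor_h = integer(0), acceptor = integer(0),
                      start_frame = integer(0), end_frame = integer(0),
                      duration = numeric(0), truncated = logical(0))
  out[order(out$donor_h, out$acceptor, out$start_frame), , drop = FALSE]
}

## brute-force continuous-time telegraph simulation: observed mean run of
## the process sampled every dt. Independent of the package generator.
bf_telegraph_mean_run <- function(tau_on, tau_off, dt, total_time, seed) {
  set.seed(seed)
  t <- 0
  state <- runif(1) < tau_on / (tau_on + tau_off)
  nf <- floor(total_time / dt)
  obs <- logical(nf)
  grid <- (seq_len(nf) - 1) * dt
  while (t < total_time) {
    dwell <- rexp(1, 1 / (if (state) tau_on else tau_off))
    if (state) obs[grid >= t & grid < t + dwell] <- TRUE
    t <- t + dwell
    state <- !state
  }
  r <- rle(obs)
  mean(r$lengths[r$values]) * dt
}

## random compact triclinic box: cube edge ~L with modest off-diagonal skew
random_triclinic_box <- function(L = 20) {
  s <- L * 0.2
  box_from_vectors(c(L, 0, 0),
                   c(runif(1, -s, s), L, 0),
                   c(runif(1, -s, s), runif(1, -s, s), L))
}

## small water-box PDB text fixture
water_pdb_lines <- c(
  "CRYST1   20.000   20.000   20.000  90.00  90.00  90.00 P 1           1",
  "HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
  "HETATM    2  H1  HOH A   1       0.960   0.000   0.000  1.00  0.00           H",
  "HETATM    3  H2  HOH A   1      -0.240   0.930   0.000  1.00  0.00           H",
  "END")

## random frame of N-H-O triplets: a mix of donors and acceptors
random_polar_traj <- function(n_res, box, seed) {
  set.seed(seed)
  n <- 3 * n_res
  top <- build_topology(
    name = rep(c("N", "H", "O"), n_res),
    residue_index = rep(seq_len(n_res), each = 3),
    residue_name = "ALA",
    element = rep(c("N", "H", "O"), n_res),
    h_parent = as.integer(t(cbind(NA, 3 * seq_len(n_res) - 2, NA))))
  L <- unname(box_to_cell(box)["a"])
  xyz <- matrix(runif(n * 3, 0, L), ncol = 3)
  ## keep each H 1.0 A from its N so the bond vector is well defined
  for (r in seq_len(n_res)) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    xyz[3 * r - 1, ] <- xyz[3 * r - 2, ] + u
  }
  coords <- array(0, dim = c(1, n, 3))
  coords[1, , ] <- xyz
  trajectory(top, coords, box, 1)
}

## one donor (N-H) and one acceptor (O) placed at a chosen H...A distance and
## D-H...A angle (degrees), in a large cube: minimal H-bond test system
hbond_probe <- function(dist, angle) {
  theta <- (180 - angle) * pi / 180
  a_pos <- c(1 + dist * cos(theta), dist * sin(theta), 0)
  top <- build_topology(name = c("N", "H", "O"), residue_index = c(1, 1, 2),
                        residue_name = "ALA", element = c("N", "H", "O"),
                        h_parent = c(NA, 1L, NA))
  coords <- array(0, dim = c(1, 3, 3))
  coords[1, 1, ] <- c(0, 0, 0)
  coords[1, 2, ] <- c(1, 0, 0)
  coords[1, 3, ] <- a_pos
  trajectory(top, coords, cubic_box(60), 1)
}
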
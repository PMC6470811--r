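#' @keywords internal
"_PACKAGE"

## Unit conventions used throughout: length Angstrom, time ps, temperature K,
## pressure bar. Atom and frame indices are 1-based; frame ranges half-open
## [start, end).

#' Boltzmann constant in kcal mol^-1 K^-1
#'
#' Used to convert spring constants (kcal mol^-1 A^-2) into stationary
#' positional variances: a 3D harmonic well of stiffness kappa has
#' mean-square fluctuation 3 kB T / kappa.
#' @export
KB_KCAL <- 0.0019872041

#' Default residue-name sets used to classify atoms
#'
#' PDB dialects differ in how they name water and ions; these sets cover the
#' common CHARMM/GROMACS/AMBER conventions and can be overridden in
#' [read_topology()].
#' @name residue_classes
NULL

#' @rdname residue_classes
#' @export
WATER_RESNAMES <- c("HOH", "TIP4", "TIP4P", "WAT", "SOL", "TIP3", "SPC")

#' @rdname residue_classes
#' @export
ION_RESNAMES <- c("K", "CL", "NA", "MG", "ZN", "POT", "CLA", "SOD", "MGA",
                  "CAL", "K+", "CL-", "NA+")

#' @rdname residue_classes
#' @export
PROTEIN_RESNAMES <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "HSD", "HSE", "HSP", "HID", "HIE", "HIP", "CYX", "ASH", "GLH", "LYN"
)

## TIP4P-style massless virtual sites: excluded from every atom count and
## geometric criterion.
VIRTUAL_SITE_NAMES <- c("MW", "EPW", "EP", "EP1", "EP2", "LP", "LP1", "LP2", "OM")

stop_ptfluct <- function(msg, class) {
  stop(structure(class = c(class, "ptfluct_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# ---- condition labels -------------------------------------------------------

#' Label a simulation condition
#'
#' @param protein_id character identifier, e.g. `"EcDHFR"`.
#' @param temperature temperature in K (> 0).
#' @param pressure pressure in bar (> 0).
#' @return an object of class `condition_label`.
#' @export
condition_label <- function(protein_id, temperature, pressure) {
  stopifnot(is.character(protein_id), length(protein_id) == 1L)
  if (!is.finite(temperature) || temperature <= 0)
    stop_ptfluct("temperature must be > 0 K", "ptfluct_spec_error")
  if (!is.finite(pressure) || pressure <= 0)
    stop_ptfluct("pressure must be > 0 bar", "ptfluct_spec_error")
  structure(list(protein_id = protein_id,
                 temperature = as.numeric(temperature),
                 pressure = as.numeric(pressure)),
            class = "condition_label")
}

#' @export
format.condition_label <- function(x, ...) {
  sprintf("%s (%g K; %g bar)", x$protein_id, x$temperature, x$pressure)
}

#' @export
print.condition_label <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# ---- periodic boxes ---------------------------------------------------------

#' Construct a periodic box from three lattice vectors
#'
#' A box is a 3x3 matrix whose *rows* are the lattice vectors in Angstrom.
#' The cell volume is the absolute scalar triple product, i.e. `abs(det(box))`.
#'
#' @param a,b,c numeric length-3 lattice vectors, Angstrom.
#' @return a `box` matrix.
#' @export
box_from_vectors <- function(a, b, c) {
  m <- rbind(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c))
  if (ncol(m) != 3L || any(!is.finite(m)))
    stop_ptfluct("lattice vectors must be finite length-3 numerics",
                 "ptfluct_geometry_error")
  if (abs(det(m)) <= 1e-9)
    stop_ptfluct("degenerate box: zero cell volume", "ptfluct_geometry_error")
  structure(m, class = c("box", "matrix", "array"))
}

#' @rdname box_from_vectors
#' @param edge cubic edge length, Angstrom.
#' @export
cubic_box <- function(edge) box_from_vectors(c(edge, 0, 0), c(0, edge, 0), c(0, 0, edge))

#' @rdname box_from_vectors
#' @param lx,ly,lz orthorhombic edge lengths, Angstrom.
#' @export
ortho_box <- function(lx, ly, lz) box_from_vectors(c(lx, 0, 0), c(0, ly, 0), c(0, 0, lz))

#' Rhombic dodecahedral cell (square-face representation)
#'
#' The triclinic representation with lattice vectors (d, 0, 0), (0, d, 0),
#' (d/2, d/2, d/sqrt(2)) where `d` is the distance between the square faces
#' (equal to the minimum image distance). Cell volume is `d^3 * sqrt(2) / 2`.
#'
#' @param face_distance distance between square faces, Angstrom.
#' @export
rhombic_dodecahedron_box <- function(face_distance) {
  d <- face_distance
  box_from_vectors(c(d, 0, 0), c(0, d, 0), c(d / 2, d / 2, d * sqrt(2) / 2))
}

#' Cell volume of a box
#'
#' Computed as the scalar triple product `|a . (b x c)|` of the lattice
#' vectors (exact for axis-aligned cells, unlike a generic LU determinant).
#' @param box a `box` matrix.
#' @return volume in Angstrom^3.
#' @export
box_volume <- function(box) {
  m <- unclass(box)
  bxc <- c(m[2, 2] * m[3, 3] - m[2, 3] * m[3, 2],
           m[2, 3] * m[3, 1] - m[2, 1] * m[3, 3],
           m[2, 1] * m[3, 2] - m[2, 2] * m[3, 1])
  abs(sum(m[1, ] * bxc))
}

#' Convert cell parameters (a, b, c, alpha, beta, gamma) to lattice vectors
#'
#' Standard crystallographic convention: `a` along x, `b` in the xy plane.
#' Angles in degrees.
#' @param a,b,c cell edge lengths, Angstrom.
#' @param alpha,beta,gamma cell angles, degrees.
#' @export
cell_to_box <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  d2r <- pi / 180
  ca <- cos(alpha * d2r); cb <- cos(beta * d2r); cg <- cos(gamma * d2r)
  sg <- sin(gamma * d2r)
  v1 <- c(a, 0, 0)
  v2 <- c(b * cg, b * sg, 0)
  cx <- c * cb
  cy <- c * (ca - cb * cg) / sg
  cz <- sqrt(pmax(c^2 - cx^2 - cy^2, 0))
  box_from_vectors(v1, v2, c(cx, cy, cz))
}

#' Convert lattice vectors back to cell parameters
#' @param box a `box` matrix.
#' @return named numeric vector (a, b, c, alpha, beta, gamma), degrees.
#' @export
box_to_cell <- function(box) {
  m <- unclass(box)
  len <- unname(sqrt(rowSums(m^2)))
  ang <- function(u, v) acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
  c(a = len[1], b = len[2], c = len[3],
    alpha = ang(m[2, ], m[3, ]), beta = ang(m[1, ], m[3, ]),
    gamma = ang(m[1, ], m[2, ]))
}

# ---- minimum image geometry -------------------------------------------------

#' Minimum-image displacement vectors under periodic boundaries
#'
#' For each row displacement `d = b - a`, returns the shortest equivalent
#' displacement over all periodic images of a triclinic cell. The search wraps
#' fractional coordinates to the central cell and then scans the 27
#' surrounding images, which is exact for any cell whose minimum image
#' distance is realised within one lattice shell (true for MD-style compact
#' cells such as cubes and rhombic dodecahedra).
#'
#' @param d numeric matrix (n x 3) of raw Cartesian displacements, Angstrom.
#' @param box a `box` matrix.
#' @return matrix (n x 3) of minimum-image displacements.
#' @export
min_image_displacement <- function(d, box) {
  d <- matrix(as.numeric(d), ncol = 3L)
  m <- unclass(box)
  if (abs(det(m)) <= 1e-9)
    stop_ptfluct("degenerate box", "ptfluct_geometry_error")
  inv <- solve(m)
  f <- d %*% inv
  f <- f - round(f)
  d0 <- f %*% m
  best <- d0
  best_r2 <- rowSums(best^2)
  shifts <- as.matrix(expand.grid(i = -1:1, j = -1:1, k = -1:1))
  shifts <- shifts[rowSums(abs(shifts)) > 0, , drop = FALSE]
  for (s in seq_len(nrow(shifts))) {
    off <- drop(shifts[s, ] %*% m)
    cand <- sweep(d0, 2L, off, "+")
    r2 <- rowSums(cand^2)
    upd <- r2 < best_r2
    if (any(upd)) {
      best[upd, ] <- cand[upd, , drop = FALSE]
      best_r2[upd] <- r2[upd]
    }
  }
  best
}

#' Minimum-image distance between two points
#'
#' @param a,b positions (length-3, or n x 3 matrices), Angstrom.
#' @param box a `box` matrix.
#' @return numeric distance(s), Angstrom.
#' @export
minimum_image_distance <- function(a, b, box) {
  a <- matrix(as.numeric(a), ncol = 3L)
  b <- matrix(as.numeric(b), ncol = 3L)
  d <- min_image_displacement(b - a, box)
  sqrt(rowSums(d^2))
}

## All min-image distances between two point sets -> (nrow(a) x nrow(b)) matrix.
min_image_cross_dist <- function(a, b, box) {
  na <- nrow(a); nb <- nrow(b)
  d <- matrix(0, na, nb)
  ia <- rep(seq_len(na), times = nb)
  ib <- rep(seq_len(nb), each = na)
  dd <- min_image_displacement(b[ib, , drop = FALSE] - a[ia, , drop = FALSE], box)
  matrix(sqrt(rowSums(dd^2)), na, nb)
}

# ---- topology ---------------------------------------------------------------

derive_element <- function(name) {
  nm <- gsub("[^A-Za-z]", "", toupper(name))
  two <- substr(nm, 1, 2)
  el <- substr(nm, 1, 1)
  el[two %in% c("CL", "NA", "MG", "ZN", "FE", "BR")] <-
    two[two %in% c("CL", "NA", "MG", "ZN", "FE", "BR")]
  ## Hydrogens named like 1HB / 2HG1 in some dialects
  el[grepl("^[0-9]*H", toupper(name))] <- "H"
  el
}

#' Build a topology from per-atom fields
#'
#' A topology is a data frame with one row per atom and columns: `index`,
#' `name`, `element`, `residue_index`, `residue_name`, `chain`, `is_protein`,
#' `is_water`, `is_ion`, `is_virtual`, `is_heavy`, `h_parent` (for hydrogens:
#' the 1-based index of the covalent heavy-atom partner, `NA` otherwise).
#'
#' @param name atom names.
#' @param residue_index integer residue indices (1-based).
#' @param residue_name residue names.
#' @param chain chain identifiers.
#' @param element element symbols; derived from names when `NULL`.
#' @param h_parent covalent heavy partner index for hydrogens (`NA` elsewhere).
#' @param water_resnames,ion_resnames,protein_resnames classification sets.
#' @param validate check the hydrogen-partner invariants (disable only when
#'   partners are assigned in a later step, as the PDB reader does).
#' @return a `topology` data frame.
#' @export
build_topology <- function(name, residue_index, residue_name,
                           chain = "A", element = NULL, h_parent = NA_integer_,
                           water_resnames = WATER_RESNAMES,
                           ion_resnames = ION_RESNAMES,
                           protein_resnames = PROTEIN_RESNAMES,
                           validate = TRUE) {
  n <- length(name)
  if (is.null(element)) element <- derive_element(name)
  top <- data.frame(
    index = seq_len(n),
    name = as.character(name),
    element = toupper(as.character(element)),
    residue_index = as.integer(residue_index),
    residue_name = toupper(as.character(residue_name)),
    chain = rep_len(as.character(chain), n),
    stringsAsFactors = FALSE
  )
  top$is_water <- top$residue_name %in% water_resnames
  top$is_protein <- top$residue_name %in% protein_resnames & !top$is_water
  top$is_ion <- top$residue_name %in% ion_resnames
  top$is_virtual <- top$name %in% VIRTUAL_SITE_NAMES |
    top$element %in% c("M", "EP", "LP")
  top$is_heavy <- top$element != "H" & !top$is_virtual
  top$h_parent <- rep_len(as.integer(h_parent), n)
  class(top) <- c("topology", "data.frame")
  if (validate) validate_topology(top) else top
}

validate_topology <- function(top) {
  if (any(top$is_protein & top$is_water))
    stop_ptfluct("atoms classified as both protein and water",
                 "ptfluct_topology_error")
  hyd <- which(top$element == "H" & (top$is_protein | top$is_water))
  bad <- hyd[is.na(top$h_parent[hyd])]
  if (length(bad))
    stop_ptfluct(sprintf(
      "%d hydrogen(s) without a resolvable covalent heavy partner (first: atom %d %s/%s)",
      length(bad), bad[1], top$residue_name[bad[1]], top$name[bad[1]]),
      "ptfluct_topology_error")
  if (length(hyd)) {
    par <- top$h_parent[hyd]
    if (any(!top$is_heavy[par]))
      stop_ptfluct("hydrogen bonded partner is not a heavy atom",
                   "ptfluct_topology_error")
  }
  top
}

## Assign each protein/water hydrogen its covalent heavy partner: CONECT
## records when present, else nearest intra-residue heavy atom within `max_bond`.
assign_h_parents <- function(top, xyz, conect = NULL, max_bond = 1.2) {
  h_parent <- rep(NA_integer_, nrow(top))
  hyd <- which(top$element == "H" & (top$is_protein | top$is_water) & !top$is_virtual)
  if (!is.null(conect) && nrow(conect)) {
    for (i in hyd) {
      nb <- c(conect$to[conect$from == i], conect$from[conect$to == i])
      nb <- nb[nb >= 1 & nb <= nrow(top)]
      nb <- nb[top$is_heavy[nb]]
      if (length(nb)) h_parent[i] <- nb[1]
    }
  }
  todo <- hyd[is.na(h_parent[hyd])]
  for (i in todo) {
    cand <- which(top$residue_index == top$residue_index[i] &
                    top$chain == top$chain[i] & top$is_heavy)
    if (!length(cand)) next
    d <- sqrt(colSums((t(xyz[cand, , drop = FALSE]) - xyz[i, ])^2))
    j <- which.min(d)
    if (d[j] <= max_bond) h_parent[i] <- cand[j]
  }
  top$h_parent <- h_parent
  top
}

#' Read a topology from a PDB file
#'
#' Protein/water/ion classification is by residue name; hydrogens are linked
#' to their covalent heavy partner using CONECT records when present, else the
#' nearest intra-residue heavy atom within 1.2 Angstrom. TIP4P-style virtual
#' sites are flagged and excluded from all counts and criteria.
#'
#' @param path PDB file path.
#' @param format only `"pdb"` is supported.
#' @param water_resnames residue names classified as water.
#' @return a `topology` data frame.
#' @export
read_topology <- function(path, format = "pdb", water_resnames = WATER_RESNAMES) {
  format <- match.arg(format, "pdb")
  if (!file.exists(path))
    stop_ptfluct(sprintf("file not found: %s", path), "ptfluct_format_error")
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) stop_ptfluct(
      sprintf("unparseable PDB file %s: %s", path, conditionMessage(e)),
      "ptfluct_format_error"))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L)
    stop_ptfluct(sprintf("no atoms parsed from %s", path), "ptfluct_format_error")
  element <- at$elesy
  if (is.null(element) || all(is.na(element) | element == ""))
    element <- derive_element(at$elety)
  else {
    miss <- is.na(element) | element == ""
    element[miss] <- derive_element(at$elety[miss])
  }
  chain <- at$chain
  chain[is.na(chain) | chain == ""] <- "A"
  ## collapse (chain, resno, insert) into a dense 1-based residue index
  rid <- paste(chain, at$resno, ifelse(is.na(at$insert), "", at$insert))
  residue_index <- match(rid, unique(rid))
  top <- build_topology(name = at$elety, residue_index = residue_index,
                        residue_name = at$resid, chain = chain,
                        element = toupper(element),
                        water_resnames = water_resnames, validate = FALSE)
  xyz <- cbind(at$x, at$y, at$z)
  top <- assign_h_parents(top, xyz, conect = read_conect(path))
  validate_topology(top)
}

## CONECT records -> data.frame(from, to) in atom order (serials remapped).
read_conect <- function(path) {
  lines <- grep("^CONECT", readLines(path, warn = FALSE), value = TRUE)
  if (!length(lines)) return(NULL)
  serials <- NULL
  atoms <- grep("^(ATOM|HETATM)",
                readLines(path, warn = FALSE), value = TRUE)
  serials <- as.integer(substr(atoms, 7, 11))
  out <- list()
  for (ln in lines) {
    nums <- suppressWarnings(as.integer(strsplit(trimws(substr(ln, 7, 70)),
                                                 "\\s+")[[1]]))
    nums <- nums[!is.na(nums)]
    if (length(nums) >= 2)
      out[[length(out) + 1L]] <- cbind(from = nums[1], to = nums[-1])
  }
  if (!length(out)) return(NULL)
  m <- do.call(rbind, out)
  data.frame(from = match(m[, "from"], serials), to = match(m[, "to"], serials))
}

# ---- trajectory -------------------------------------------------------------

#' Construct a trajectory object
#'
#' @param topology a `topology` data frame.
#' @param coords numeric array frames x atoms x 3, Angstrom.
#' @param boxes either one `box` (constant cell) or a list of per-frame boxes.
#' @param frame_interval time between frames, ps (default 1).
#' @param label optional `condition_label`.
#' @param constant_box flag recording that the cell was not stored per frame.
#' @return a `trajectory` object.
#' @export
trajectory <- function(topology, coords, boxes, frame_interval = 1,
                       label = NULL, constant_box = FALSE) {
  stopifnot(inherits(topology, "topology"))
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    stop_ptfluct("coords must be a frames x atoms x 3 array", "ptfluct_shape_error")
  if (dim(coords)[2] != nrow(topology))
    stop_ptfluct(sprintf("coordinate atom count (%d) does not match topology (%d)",
                         dim(coords)[2], nrow(topology)), "ptfluct_shape_error")
  nf <- dim(coords)[1]
  if (inherits(boxes, "box")) {
    boxes <- rep(list(boxes), nf)
    constant_box <- TRUE
  }
  if (length(boxes) != nf)
    stop_ptfluct("box count must equal frame count", "ptfluct_shape_error")
  if (!is.finite(frame_interval) || frame_interval <= 0)
    stop_ptfluct("frame_interval must be > 0 ps", "ptfluct_spec_error")
  structure(list(topology = topology, coords = coords, boxes = boxes,
                 frame_interval = as.numeric(frame_interval), label = label,
                 constant_box = isTRUE(constant_box)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames x %d atoms, %g ps/frame\n",
              n_frames(x), n_atoms(x), x$frame_interval))
  if (!is.null(x$label)) cat("  condition:", format(x$label), "\n")
  cat(sprintf("  protein heavy atoms: %d, waters: %d\n",
              sum(x$topology$is_protein & x$topology$is_heavy),
              length(unique(x$topology$residue_index[x$topology$is_water]))))
  invisible(x)
}

#' @rdname trajectory
#' @param traj a trajectory.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' @rdname trajectory
#' @export
n_atoms <- function(traj) dim(traj$coords)[2]

#' Per-frame cell volumes of a trajectory
#' @param traj a trajectory.
#' @return numeric vector, Angstrom^3.
#' @export
frame_volumes <- function(traj) {
  if (is.null(traj$boxes))
    stop_ptfluct("trajectory has no box information", "ptfluct_missing_box_error")
  vapply(traj$boxes, box_volume, numeric(1))
}

#' Read trajectory frames into a trajectory object
#'
#' Multi-model PDB carries at most a single CRYST1 cell, which is applied to
#' every frame (flagged `constant_box`); DCD files carry per-frame unit cells.
#'
#' @param topology the matching `topology`.
#' @param path trajectory file.
#' @param format `"pdb"` (multi-model) or `"dcd"`.
#' @param frame_interval ps between stored frames.
#' @param box fallback `box` for files without cell records.
#' @param label optional `condition_label`.
#' @return a `trajectory`.
#' @export
read_trajectory <- function(topology, path, format = c("pdb", "dcd"),
                            frame_interval = 1, box = NULL, label = NULL) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop_ptfluct(sprintf("file not found: %s", path), "ptfluct_format_error")
  if (format == "pdb") {
    pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    natom <- ncol(xyz) / 3
    if (natom != nrow(topology))
      stop_ptfluct(sprintf("frame atom count (%d) does not match topology (%d)",
                           natom, nrow(topology)), "ptfluct_shape_error")
    nf <- nrow(xyz)
    coords <- array(0, dim = c(nf, natom, 3))
    coords[, , 1] <- xyz[, seq(1, 3 * natom, 3), drop = FALSE]
    coords[, , 2] <- xyz[, seq(2, 3 * natom, 3), drop = FALSE]
    coords[, , 3] <- xyz[, seq(3, 3 * natom, 3), drop = FALSE]
    cb <- read_cryst1(path)
    if (is.null(cb)) {
      if (is.null(box)) {
        boxes <- vector("list", 0)
        traj <- structure(list(topology = topology, coords = coords,
                               boxes = NULL, frame_interval = frame_interval,
                               label = label, constant_box = TRUE),
                          class = "trajectory")
        warning("no CRYST1 record and no fallback box: volume/periodic analyses unavailable")
        return(traj)
      }
      cb <- box
    }
    warning("constant box applied to all frames (multi-model PDB stores one cell)",
            call. = FALSE)
    trajectory(topology, coords, cb, frame_interval, label)
  } else {
    xyz <- suppressWarnings(bio3d::read.dcd(path, verbose = FALSE))
    cell <- tryCatch(
      suppressWarnings(bio3d::read.dcd(path, cell = TRUE, verbose = FALSE)),
      error = function(e) NULL)
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    natom <- ncol(xyz) / 3
    if (natom != nrow(topology))
      stop_ptfluct(sprintf("frame atom count (%d) does not match topology (%d)",
                           natom, nrow(topology)), "ptfluct_shape_error")
    nf <- nrow(xyz)
    coords <- array(0, dim = c(nf, natom, 3))
    coords[, , 1] <- xyz[, seq(1, 3 * natom, 3), drop = FALSE]
    coords[, , 2] <- xyz[, seq(2, 3 * natom, 3), drop = FALSE]
    coords[, , 3] <- xyz[, seq(3, 3 * natom, 3), drop = FALSE]
    if (!is.null(cell) && nrow(cell) == nf) {
      cell <- unclass(cell)  # columns: a, b, c, alpha, beta, gamma
      boxes <- lapply(seq_len(nf), function(i)
        cell_to_box(cell[i, 1], cell[i, 2], cell[i, 3],
                    cell[i, 4], cell[i, 5], cell[i, 6]))
      trajectory(topology, coords, boxes, frame_interval, label)
    } else if (!is.null(box)) {
      warning("DCD lacks per-frame cells; constant fallback box applied", call. = FALSE)
      trajectory(topology, coords, box, frame_interval, label)
    } else {
      stop_ptfluct("DCD has no unit-cell records and no fallback box supplied",
                   "ptfluct_missing_box_error")
    }
  }
}

read_cryst1 <- function(path) {
  ln <- grep("^CRYST1", readLines(path, warn = FALSE), value = TRUE)
  if (!length(ln)) return(NULL)
  v <- suppressWarnings(as.numeric(strsplit(trimws(substr(ln[1], 7, 54)),
                                            "\\s+")[[1]]))
  if (length(v) < 6 || any(is.na(v[1:6])) || any(v[1:3] <= 0)) return(NULL)
  cell_to_box(v[1], v[2], v[3], v[4], v[5], v[6])
}

# ---- trajectory writers (fixture generation) --------------------------------

#' Write a trajectory to disk
#'
#' `"pdb"` writes a multi-model PDB with a CRYST1 record from the first frame's
#' cell; `"dcd"` writes a CHARMM-style binary DCD with per-frame unit cells
#' (readable by standard DCD readers).
#'
#' @param traj a `trajectory`.
#' @param path output file.
#' @param format `"pdb"` or `"dcd"`.
#' @export
write_trajectory <- function(traj, path, format = c("pdb", "dcd")) {
  format <- match.arg(format)
  if (format == "pdb") write_trajectory_pdb(traj, path) else write_trajectory_dcd(traj, path)
  invisible(path)
}

write_trajectory_pdb <- function(traj, path) {
  top <- traj$topology
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(traj$boxes)) {
    cell <- box_to_cell(traj$boxes[[1]])
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                       cell["a"], cell["b"], cell["c"],
                       cell["alpha"], cell["beta"], cell["gamma"]), con)
  }
  rec <- ifelse(top$is_protein, "ATOM  ", "HETATM")
  nf <- n_frames(traj)
  for (f in seq_len(nf)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- traj$coords[f, , , drop = TRUE]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    name4 <- ifelse(nchar(top$name) >= 4, substr(top$name, 1, 4),
                    sprintf(" %-3s", top$name))
    lines <- sprintf("%s%5d %s %-4s%s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                     rec, top$index %% 100000L, name4,
                     substr(top$residue_name, 1, 4), substr(top$chain, 1, 1),
                     top$residue_index %% 10000L,
                     xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, top$element)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
}

## CHARMM DCD writer with CRYSTAL records: header flag icntrl[11] = 1, cell
## stored per frame as 6 doubles (a, cos(gamma), b, cos(beta), cos(alpha), c).
write_trajectory_dcd <- function(traj, path) {
  if (is.null(traj$boxes))
    stop_ptfluct("DCD writer requires boxes", "ptfluct_missing_box_error")
  con <- file(path, "wb")
  on.exit(close(con))
  nf <- n_frames(traj); na <- n_atoms(traj)
  wrec <- function(writer) {
    tmp <- raw(0)
    rc <- rawConnection(tmp, "wb")
    writer(rc)
    payload <- rawConnectionValue(rc)
    close(rc)
    writeBin(length(payload), con, size = 4L, endian = "little")
    writeBin(payload, con)
    writeBin(length(payload), con, size = 4L, endian = "little")
  }
  icntrl <- integer(20)
  icntrl[1] <- nf          # NFILE
  icntrl[2] <- 1L          # ISTART
  icntrl[3] <- 1L          # NSAVC
  icntrl[4] <- nf          # NSTEP
  icntrl[10] <- 0L
  icntrl[11] <- 1L         # crystal (unit cell) records present
  icntrl[20] <- 24L        # CHARMM version
  wrec(function(rc) {
    writeChar("CORD", rc, nchars = 4, eos = NULL)
    writeBin(icntrl, rc, size = 4L, endian = "little")
  })
  wrec(function(rc) {
    writeBin(1L, rc, size = 4L, endian = "little")
    writeChar(formatC("written by ptfluct", width = 80, flag = "-"), rc,
              nchars = 80, eos = NULL)
  })
  wrec(function(rc) writeBin(na, rc, size = 4L, endian = "little"))
  d2r <- pi / 180
  for (f in seq_len(nf)) {
    cell <- box_to_cell(traj$boxes[[f]])
    wrec(function(rc) writeBin(as.numeric(c(
      cell["a"], cos(cell["gamma"] * d2r), cell["b"],
      cos(cell["beta"] * d2r), cos(cell["alpha"] * d2r), cell["c"])),
      rc, size = 8L, endian = "little"))
    for (k in 1:3) {
      vals <- as.numeric(traj$coords[f, , k])
      wrec(function(rc) writeBin(vals, rc, size = 4L, endian = "little"))
    }
  }
  invisible(path)
}

# ---- block specification ----------------------------------------------------

#' Block-averaging specification
#'
#' Statistics are reported as the mean over consecutive fixed-length blocks
#' with the standard error of the mean over blocks as the error bar.
#'
#' @param block_length block length in ps (default 10000, i.e. 10 ns).
#' @param n_blocks number of blocks (default 5).
#' @export
block_spec <- function(block_length = 10000, n_blocks = 5) {
  if (!is.finite(block_length) || block_length <= 0)
    stop_ptfluct("block_length must be > 0 ps", "ptfluct_spec_error")
  if (!is.finite(n_blocks) || n_blocks < 1)
    stop_ptfluct("n_blocks must be >= 1", "ptfluct_spec_error")
  structure(list(block_length = as.numeric(block_length),
                 n_blocks = as.integer(n_blocks)), class = "block_spec")
}

## Split frame indices 1..nf into blocks of block_length/frame_interval frames.
## Trailing frames that do not fill a block are dropped. Returns a list of
## integer vectors (one per block).
block_frame_indices <- function(nf, frame_interval, blocks) {
  fpb <- blocks$block_length / frame_interval
  if (abs(fpb - round(fpb)) > 1e-9)
    stop_ptfluct("block_length must be divisible by frame_interval",
                 "ptfluct_spec_error")
  fpb <- as.integer(round(fpb))
  avail <- nf %/% fpb
  if (avail < 1L)
    stop_ptfluct(sprintf("trajectory (%d frames) shorter than one block (%d frames)",
                         nf, fpb), "ptfluct_coverage_error")
  nb <- min(avail, blocks$n_blocks)
  if (avail < blocks$n_blocks)
    warning(sprintf("only %d full blocks available (%d requested)", avail,
                    blocks$n_blocks), call. = FALSE)
  lapply(seq_len(nb), function(b) ((b - 1L) * fpb + 1L):(b * fpb))
}

block_sem <- function(block_means) {
  if (length(block_means) < 2) return(NA_real_)
  stats::sd(block_means) / sqrt(length(block_means))
}
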
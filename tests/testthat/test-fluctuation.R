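make_static_traj <- function(coords_list, box = cubic_box(100)) {
  n <- nrow(coords_list[[1]])
  top <- build_topology(name = rep("CA", n), residue_index = seq_len(n),
                        residue_name = "ALA", element = rep("C", n))
  coords <- array(0, dim = c(length(coords_list), n, 3))
  for (f in seq_along(coords_list)) coords[f, , ] <- coords_list[[f]]
  trajectory(top, coords, box, 1)
}

test_that("identical frames give exactly zero MSF", {
  x <- matrix(c(0, 0, 0, 5, 5, 5), 2, 3, byrow = TRUE)
  tr <- make_static_traj(rep(list(x), 10))
  m <- compute_msf(tr, block_spec(5, 2), superpose = FALSE)
  expect_identical(m$global_msf, 0)
  expect_true(all(m$per_atom_per_block == 0))
})

test_that("two frames at x = 0 and x = 2 give MSF of exactly 1 A^2", {
  tr <- make_static_traj(list(matrix(c(0, 0, 0), 1), matrix(c(2, 0, 0), 1)))
  m <- compute_msf(tr, block_spec(2, 1), superpose = FALSE)
  expect_equal(m$global_msf, 1.0)
})

test_that("OU per-atom fluctuations recover the analytic stationary variance", {
  kappa <- KB_KCAL * 279 * 3 / c(0.4, 0.65, 1.0)  # MSF targets 0.4/0.65/1.0 A^2
  tr <- generate_ou_protein(30, 1, kappa = kappa, temperature = 279,
                            friction = 2, n_frames = 10000, seed = 101)
  truth <- attr(tr, "ground_truth")$msf_per_atom
  m <- compute_msf(tr, block_spec(2000, 5), superpose = FALSE)
  rel <- abs(m$per_atom_mean - truth) / truth
  expect_gt(mean(rel < 0.05), 0.95)
  expect_lt(abs(m$global_msf - mean(truth)) / mean(truth), 0.02)
})

test_that("explicit double-loop recomputation reproduces the vectorized MSF", {
  tr <- generate_ou_protein(6, 2, kappa = 4, temperature = 300,
                            n_frames = 60, seed = 5)
  m <- compute_msf(tr, block_spec(20, 3), superpose = FALSE)
  sel <- m$atoms
  blocks <- list(1:20, 21:40, 41:60)
  oracle <- matrix(0, length(sel), 3)
  for (ai in seq_along(sel)) {
    for (b in 1:3) {
      fr <- blocks[[b]]
      mu <- c(mean(tr$coords[fr, sel[ai], 1]), mean(tr$coords[fr, sel[ai], 2]),
              mean(tr$coords[fr, sel[ai], 3]))
      acc <- 0
      for (f in fr)
        acc <- acc + sum((tr$coords[f, sel[ai], ] - mu)^2)
      oracle[ai, b] <- acc / length(fr)
    }
  }
  expect_equal(m$per_atom_per_block, oracle, tolerance = 1e-10)
  expect_equal(m$global_msf, mean(rowMeans(oracle)), tolerance = 1e-12)
})

test_that("random rigid-body motion is removed by superposition", {
  tr <- generate_ou_protein(12, 1, kappa = 4, temperature = 300,
                            n_frames = 200, seed = 7)
  m0 <- compute_msf(tr, block_spec(100, 2), superpose = TRUE)
  set.seed(99)
  tr2 <- tr
  for (f in seq_len(n_frames(tr))) {
    q <- matrix(rnorm(9), 3)
    qr_ <- qr(q)
    R <- qr.Q(qr_)
    if (det(R) < 0) R[, 1] <- -R[, 1]
    shift <- runif(3, -20, 20)
    tr2$coords[f, , ] <- tr$coords[f, , ] %*% R +
      matrix(shift, n_atoms(tr), 3, byrow = TRUE)
  }
  m1 <- compute_msf(tr2, block_spec(100, 2), superpose = TRUE)
  expect_lt(abs(m1$global_msf - m0$global_msf) / m0$global_msf, 1e-6)
})

test_that("MSF is invariant to consistent atom relabeling", {
  tr <- generate_ou_protein(8, 1, kappa = 3, temperature = 300,
                            n_frames = 100, seed = 13)
  perm <- sample(n_atoms(tr))
  tr2 <- tr
  tr2$coords <- tr$coords[, perm, , drop = FALSE]
  tr2$topology <- tr$topology[perm, ]
  tr2$topology$index <- seq_len(nrow(tr2$topology))
  class(tr2$topology) <- class(tr$topology)
  m1 <- compute_msf(tr, block_spec(50, 2), superpose = FALSE)
  m2 <- compute_msf(tr2, block_spec(50, 2), superpose = FALSE)
  expect_equal(sort(m2$per_atom_mean), sort(m1$per_atom_mean),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(m2$global_msf, m1$global_msf, tolerance = 1e-12)
})

test_that("block error shrinks with more blocks of fixed length", {
  tr <- generate_ou_protein(10, 1, kappa = 3, temperature = 300, friction = 5,
                            n_frames = 8000, seed = 21)
  short <- tr
  short$coords <- tr$coords[1:2000, , , drop = FALSE]
  short$boxes <- tr$boxes[1:2000]
  few <- compute_msf(short, block_spec(500, 4), superpose = FALSE)
  many <- compute_msf(tr, block_spec(500, 16), superpose = FALSE)
  expect_lt(many$global_error, few$global_error)
})

test_that("coverage and selection failures raise typed errors", {
  tr <- generate_ou_protein(4, 1, kappa = 3, temperature = 300,
                            n_frames = 5, seed = 1)
  expect_error(compute_msf(tr, block_spec(100, 5)), class = "ptfluct_coverage_error")
  expect_error(compute_msf(tr, block_spec(5, 1), selection = integer(0)),
               class = "ptfluct_selection_error")
})

test_that("fluctuation difference maps subtract per residue and clip colors", {
  tr <- generate_ou_protein(10, 2, kappa = 4, temperature = 300,
                            n_frames = 200, seed = 31)
  m <- compute_msf(tr, block_spec(100, 2), superpose = FALSE)
  expect_true(all(delta_msf_map(m, m)$delta_msf == 0))
  ## one residue's fluctuation doubles: positive entry at that residue only
  kappa2 <- rep(4, 20); kappa2[1:2] <- 2  # residue 1 softer -> larger MSF
  tr2 <- generate_ou_protein(10, 2, kappa = kappa2, temperature = 300,
                             n_frames = 200, seed = 31)
  m2 <- compute_msf(tr2, block_spec(100, 2), superpose = FALSE)
  dm <- delta_msf_map(m, m2)
  expect_gt(dm$delta_msf[1], 0.02)
  expect_lt(max(abs(dm$delta_msf[-1])), dm$delta_msf[1])
  ## clipping at the +2.0 anchor, -0.5 anchor, and scaling
  fake_a <- m; fake_b <- m
  fake_b$per_residue$msf <- m$per_residue$msf + 3.0
  dm2 <- delta_msf_map(fake_a, fake_b)
  expect_true(all(dm2$clipped == 2.0))
  expect_true(all(dm2$color_coord == 1.0))
  fake_b$per_residue$msf <- m$per_residue$msf - 0.25
  dm3 <- delta_msf_map(fake_a, fake_b)
  expect_true(all(abs(dm3$color_coord + 0.5) < 1e-12))
})

test_that("difference maps require aligned residue structures", {
  tr <- generate_ou_protein(5, 1, kappa = 3, temperature = 300,
                            n_frames = 100, seed = 1)
  tr2 <- generate_ou_protein(6, 1, kappa = 3, temperature = 300,
                             n_frames = 100, seed = 1)
  m1 <- compute_msf(tr, block_spec(50, 2), superpose = FALSE)
  m2 <- compute_msf(tr2, block_spec(50, 2), superpose = FALSE)
  expect_error(delta_msf_map(m1, m2), class = "ptfluct_alignment_error")
})
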
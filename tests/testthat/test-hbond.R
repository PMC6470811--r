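test_that("the distance and angle criteria are applied with strict bounds", {
  bonded <- function(dist, angle)
    nrow(detect_hbonds_frame(hbond_probe(dist, angle), 1)) == 1L
  expect_true(bonded(2.0, 150))
  expect_false(bonded(2.0, 120))
  expect_false(bonded(2.40, 150))   # "smaller than 2.40" is strict
  expect_true(bonded(2.39, 150))
  expect_false(bonded(2.41, 150))
  expect_false(bonded(2.0, 130))    # "larger than 130" is strict
  expect_true(bonded(2.0, 131))
  expect_false(bonded(2.0, 129))
})

test_that("frame detection matches the brute-force all-triples oracle", {
  set.seed(2024)
  for (rep in 1:10) {
    box <- if (rep %% 2) cubic_box(runif(1, 12, 18)) else
      random_triclinic_box(runif(1, 12, 18))
    tr <- random_polar_traj(12, box, seed = 3000 + rep)
    got <- detect_hbonds_frame(tr, 1)
    want <- bf_detect_hbonds(tr, 1)
    expect_equal(unname(got), unname(want))
  }
})

test_that("event tracking reproduces hand-counted occupancy runs", {
  mk_sets <- function(occ) lapply(occ, function(on)
    if (on) cbind(donor_h = 2L, donor_heavy = 1L, acceptor = 5L)
    else cbind(donor_h = integer(0), donor_heavy = integer(0),
               acceptor = integer(0)))
  tr <- track_events(mk_sets(c(1, 1, 1, 0, 0, 1, 1) == 1), 1)
  expect_equal(nrow(tr$events), 2L)
  expect_equal(tr$events$duration, c(3, 2))
  expect_equal(tr$events$truncated, c(TRUE, TRUE))  # touch both ends
  expect_equal(tr$pairs$n_events, 2L)
  expect_equal(tr$pairs$tau_ij, 2.5)
  ## all-zero occupancy: pair absent
  tr0 <- track_events(mk_sets(rep(FALSE, 5)), 1)
  expect_equal(nrow(tr0$pairs), 0L)
  ## interior event is not truncated
  tr1 <- track_events(mk_sets(c(0, 1, 1, 0) == 1), 1)
  expect_false(tr1$events$truncated)
  expect_error(track_events(list(), 1), class = "ptfluct_coverage_error")
})

test_that("gap tolerance bridges single-frame interruptions", {
  sets <- lapply(c(1, 1, 0, 1, 1) == 1, function(on)
    if (on) cbind(donor_h = 2L, donor_heavy = 1L, acceptor = 5L)
    else cbind(donor_h = integer(0), donor_heavy = integer(0),
               acceptor = integer(0)))
  strict <- track_events(sets, 1)
  expect_equal(strict$pairs$n_events, 2L)
  bridged <- track_events(sets, 1, gap_tolerance = 1)
  expect_equal(bridged$pairs$n_events, 1L)
  expect_equal(bridged$events$duration, 5)
})

test_that("telegraph occupancies recover the discretization-corrected lifetime", {
  occ <- generate_hbond_occupancy(n_pairs = 60, tau_on = 25, tau_off = 25,
                                  duration = 10000, frame_interval = 1, seed = 202)
  tr <- track_events(occ$per_frame_sets, 1)
  ## event list identical to an independent run-length scan
  oracle <- bf_run_length_events(occ$occupancy, occ$pair_atoms, 1)
  got <- tr$events[order(tr$events$donor_h, tr$events$acceptor,
                         tr$events$start_frame),
                   c("donor_h", "acceptor", "start_frame", "end_frame",
                     "duration", "truncated")]
  expect_equal(unname(as.matrix(got)), unname(as.matrix(oracle)))
  ## closed-form expectation agrees with an independent continuous simulation
  expect_cf <- telegraph_expected_run_duration(25, 25, 1)
  bf <- bf_telegraph_mean_run(25, 25, 1, 4e5, seed = 7)
  expect_lt(abs(bf - expect_cf) / expect_cf, 0.05)
  ## estimator within 3 SEM of the expectation (thousands of events)
  durs <- tr$events$duration
  sem <- sd(durs) / sqrt(length(durs))
  expect_lt(abs(mean(durs) - expect_cf), 3 * sem)
})

test_that("event bookkeeping conserves total occupancy exactly", {
  occ <- generate_hbond_occupancy(n_pairs = 20, tau_on = 10, tau_off = 30,
                                  duration = 2000, frame_interval = 2, seed = 31)
  tr <- track_events(occ$per_frame_sets, 2)
  total_time <- sum(tr$pairs$n_events * tr$pairs$tau_ij)
  occupancy_time <- 2 * sum(vapply(occ$per_frame_sets, nrow, integer(1)))
  expect_lt(abs(total_time - occupancy_time), 1e-9)
  expect_identical(sum(tr$events$duration), occupancy_time)
})

test_that("tracking is invariant to pair enumeration order within frames", {
  occ <- generate_hbond_occupancy(n_pairs = 8, tau_on = 5, tau_off = 5,
                                  duration = 300, frame_interval = 1, seed = 11)
  shuffled <- lapply(occ$per_frame_sets, function(m)
    m[sample(nrow(m)), , drop = FALSE])
  a <- track_events(occ$per_frame_sets, 1)
  b <- track_events(shuffled, 1)
  expect_equal(a$pairs, b$pairs)
  expect_equal(a$events, b$events)
})

test_that("lifetime summary separates population from pair averages", {
  mk_pair_sets <- function(occ_mat) {
    lapply(seq_len(nrow(occ_mat)), function(f) {
      on <- which(occ_mat[f, ])
      cbind(donor_h = 2L * on, donor_heavy = 2L * on - 1L, acceptor = 100L + on)
    })
  }
  ## two pairs with tau 2 and 4 ps
  occ <- matrix(FALSE, 12, 2)
  occ[1:2, 1] <- TRUE; occ[5:8, 2] <- TRUE
  sets <- mk_pair_sets(occ)
  tr <- track_events(sets, 1)
  s <- summarize_lifetimes(tr$pairs, sets, 1, block_spec(6, 2))
  expect_equal(s$tau_hb, 3)
  expect_equal(s$n_unique_pairs, 2L)
  ## add a long-lived pair: excluded from tau_HB, counted in N_HB
  occ3 <- cbind(occ, TRUE)  # bonded every frame
  sets3 <- mk_pair_sets(occ3)
  tr3 <- track_events(sets3, 1)
  tr3$pairs$tau_ij[tr3$pairs$acceptor == 103L] <- 1500  # planted lifetime
  s3 <- summarize_lifetimes(tr3$pairs, sets3, 1, block_spec(6, 2))
  expect_equal(s3$tau_hb, 3)
  expect_equal(nrow(s3$excluded_pairs), 1L)
  expect_equal(s3$excluded_pairs$acceptor, 103L)
  expect_match(s3$excluded_pairs$reason, "1000")
  expect_gt(s3$n_hb, s$n_hb)
  ## all pairs excluded -> degenerate summary
  tr3$pairs$tau_ij[] <- 2000
  expect_error(summarize_lifetimes(tr3$pairs, sets3, 1, block_spec(6, 2)),
               class = "ptfluct_degenerate_summary_error")
})

test_that("pair-average lifetime equals a brute-force recomputation", {
  occ <- generate_hbond_occupancy(n_pairs = 50, tau_on = runif(50, 3, 40),
                                  tau_off = runif(50, 5, 50),
                                  duration = 3000, frame_interval = 1, seed = 41)
  tr <- track_events(occ$per_frame_sets, 1)
  s <- summarize_lifetimes(tr$pairs, occ$per_frame_sets, 1, block_spec(600, 5))
  oracle_events <- bf_run_length_events(occ$occupancy, occ$pair_atoms, 1)
  key <- paste(oracle_events$donor_h, oracle_events$acceptor)
  taus <- vapply(split(oracle_events$duration, key), mean, numeric(1))
  expect_equal(s$tau_hb, mean(taus[taus <= 1000]), tolerance = 1e-10)
})

test_that("correlation dataset filters, transforms, and correlates", {
  pairs <- data.frame(donor_h = c(2L, 4L, 6L), donor_heavy = c(1L, 3L, 5L),
                      acceptor = c(10L, 10L, 11L),
                      n_events = c(3L, 1L, 4L), tau_ij = c(12, 4, 1.5))
  msf <- structure(list(per_atom_mean = c(`10` = 0.5, `11` = 0.8)),
                   class = "msf_result")
  out <- fluctuation_lifetime_dataset(msf, pairs)
  ## acceptor 10: event-weighted tau = (3*12 + 1*4)/4 = 10; acceptor 11 filtered
  expect_equal(out$acceptor, 10L)
  expect_equal(out$tau_acceptor, 10)
  expect_equal(out$inv_msf, 2.0)
  expect_equal(out$ln_tau, log(10))
  ## pair weighting switch
  out2 <- fluctuation_lifetime_dataset(msf, pairs, weighting = "pair")
  expect_equal(out2$tau_acceptor, 8)
  ## tau at the 2 ps boundary is excluded ("longer than 2 ps")
  pairs$tau_ij <- c(2, 2, 2)
  expect_warning(out3 <- fluctuation_lifetime_dataset(msf, pairs),
                 "no acceptors")
  expect_equal(nrow(out3), 0L)
})

test_that("a constructed inverse relation yields a strong Pearson correlation", {
  set.seed(61)
  n <- 120
  tau <- exp(runif(n, log(3), log(400)))
  msf_vals <- 1 / log(tau) * exp(rnorm(n, 0, 0.05))
  pairs <- data.frame(donor_h = 2L * seq_len(n), donor_heavy = 2L * seq_len(n) - 1L,
                      acceptor = 1000L + seq_len(n),
                      n_events = 5L, tau_ij = tau)
  msf <- structure(list(per_atom_mean = stats::setNames(msf_vals,
                                                        1000L + seq_len(n))),
                   class = "msf_result")
  out <- fluctuation_lifetime_dataset(msf, pairs)
  expect_gt(attr(out, "pearson_r"), 0.95)
})
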
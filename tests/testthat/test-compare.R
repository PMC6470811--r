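fixture_path <- system.file("extdata", "dhfr_pt_condition_summaries.tsv",
                            package = "ptfluct")

test_that("the packaged condition table parses into eight summaries", {
  s <- load_condition_summaries(fixture_path)
  expect_equal(nrow(s), 8L)
  expect_setequal(unique(s$protein_id), c("EcDHFR", "MpDHFR"))
  expect_setequal(unique(s$temperature), c(279, 310))
  expect_setequal(unique(s$pressure), c(1, 220))
  expect_equal(s$msf[s$protein_id == "EcDHFR" & s$temperature == 279 &
                       s$pressure == 1], 0.65)
  expect_equal(s$tau_hb_err[s$protein_id == "MpDHFR" & s$temperature == 310 &
                              s$pressure == 1], 0.6)
})

test_that("empty and malformed tables raise parse errors", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), p)
  expect_error(load_condition_summaries(p), class = "ptfluct_parse_error")
  writeLines(c("Protein (T, K; P, bar)\tMSF\tV\tN\tN\tt",
               "nonsense\t1\t2\t3\t4\t5"), p)
  expect_error(load_condition_summaries(p), class = "ptfluct_parse_error")
})

test_that("summaries survive a write/read round trip", {
  s <- load_condition_summaries(fixture_path)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_condition_summaries(s, p)
  s2 <- load_condition_summaries(p)
  for (col in c("protein_id", "temperature", "pressure", "msf", "msf_err",
                "v_app_per_heavy_atom", "n_w_in", "n_hb", "tau_hb"))
    expect_equal(s2[[col]], s[[col]], info = col)
})

test_that("unicode minus and ASCII +- are both accepted", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Protein (T, K; P, bar)\tMSF\tV\tNw\tNHB\ttau",
               "X (279; 1)\t−0.5 +- 0.1\t17 ± 1\t2 ± 1\t100 ± 1\t20 ± 1"),
             p, useBytes = FALSE)
  s <- load_condition_summaries(p)
  expect_equal(s$msf, -0.5)
  expect_equal(s$msf_err, 0.1)
})

test_that("identical endpoint summaries give an all-zero change row", {
  lab1 <- condition_label("X", 279, 1)
  lab2 <- condition_label("X", 310, 1)
  row1 <- condition_summary(lab1, 1, 0, 10, 0, 2, 0, 100, 0, 20, 0)
  row2 <- condition_summary(lab2, 1, 0, 10, 0, 2, 0, 100, 0, 20, 0)
  dt <- delta_table(rbind(row1, row2), "temperature")
  expect_equal(unlist(dt[, c("pct_msf", "pct_vapp", "delta_n_w_in",
                             "delta_n_hb", "pct_tau_hb")]),
               c(pct_msf = 0, pct_vapp = 0, delta_n_w_in = 0,
                 delta_n_hb = 0, pct_tau_hb = 0))
})

test_that("missing endpoints raise a pairing error", {
  s <- load_condition_summaries(fixture_path)
  expect_error(delta_table(s[-1, ], "temperature"),
               class = "ptfluct_pairing_error")
})

test_that("the packaged table reproduces every printed temperature-change cell", {
  s <- load_condition_summaries(fixture_path)
  dt <- delta_table(s, "temperature")
  pick <- function(prot, p) dt[dt$protein_id == prot & dt$held_value == p, ]
  expect_equal(unlist(pick("EcDHFR", 1)[, c("pct_msf", "pct_vapp",
                                            "delta_n_w_in", "delta_n_hb", "pct_tau_hb")],
                      use.names = FALSE), c(43, 3, 0.40, -1, -58))
  expect_equal(unlist(pick("EcDHFR", 220)[, c("pct_msf", "pct_vapp",
                                              "delta_n_w_in", "delta_n_hb", "pct_tau_hb")],
                      use.names = FALSE), c(46, 2, 0.39, -1, -56))
  expect_equal(unlist(pick("MpDHFR", 1)[, c("pct_msf", "pct_vapp",
                                            "delta_n_w_in", "delta_n_hb", "pct_tau_hb")],
                      use.names = FALSE), c(83, 3, 0.96, -2, -63))
  expect_equal(unlist(pick("MpDHFR", 220)[, c("pct_msf", "pct_vapp",
                                              "delta_n_w_in", "delta_n_hb", "pct_tau_hb")],
                      use.names = FALSE), c(80, 3, -0.02, -3, -51))
})

test_that("the packaged table reproduces every printed pressure-change cell", {
  s <- load_condition_summaries(fixture_path)
  dp <- delta_table(s, "pressure")
  pick <- function(prot, t) dp[dp$protein_id == prot & dp$held_value == t, ]
  expect_equal(unlist(pick("EcDHFR", 279)[, c("pct_msf", "pct_vapp",
                                              "delta_n_w_in", "delta_n_hb", "pct_tau_hb")],
                      use.names = FALSE), c(9, 1, 0.12, -2, -8))
  expect_equal(unlist(pick("EcDHFR", 310)[, c("pct_msf", "pct_vapp",
                                              "delta_n_w_in", "delta_n_hb", "pct_tau_hb")],
                      use.names = FALSE), c(12, 0, 0.11, -2, -3))
  expect_equal(unlist(pick("MpDHFR", 279)[, c("pct_msf", "pct_vapp",
                                              "delta_n_w_in", "delta_n_hb", "pct_tau_hb")],
                      use.names = FALSE), c(9, 0, 0.03, 1, -26))
  expect_equal(unlist(pick("MpDHFR", 310)[, c("pct_msf", "pct_vapp",
                                              "delta_n_w_in", "delta_n_hb", "pct_tau_hb")],
                      use.names = FALSE), c(7, 0, -0.95, 0, -1))
})

test_that("forward and reverse changes are antisymmetric before rounding", {
  s <- load_condition_summaries(fixture_path)
  fwd <- delta_table(s, "temperature")
  rev_s <- s
  rev_s$temperature <- ifelse(s$temperature == 279, 310, 279)  # swap roles
  rev <- delta_table(rev_s, "temperature")
  rev <- rev[match(paste(fwd$protein_id, fwd$held_value),
                   paste(rev$protein_id, rev$held_value)), ]
  expect_equal(rev$delta_n_w_in_raw, -fwd$delta_n_w_in_raw, tolerance = 1e-12)
  expect_equal(rev$delta_n_hb_raw, -fwd$delta_n_hb_raw, tolerance = 1e-12)
  for (col in c("pct_msf_raw", "pct_vapp_raw", "pct_tau_hb_raw"))
    expect_equal((1 + fwd[[col]] / 100) * (1 + rev[[col]] / 100),
                 rep(1, nrow(fwd)), tolerance = 1e-12, info = col)
})
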
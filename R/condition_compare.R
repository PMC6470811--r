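# Cross-condition comparison tables. One condition summary holds the five
# headline observables for one (protein, T, P) state; delta tables report the
# change along one axis (temperature at fixed pressure, or pressure at fixed
# temperature), as percentages of the low-T / low-P state for MSF,
# V_app/N_HA and tau_HB (rounded half-away-from-zero to integers) and as
# signed differences for N_w,in (2 decimals) and N_HB (integers).

#' Assemble one condition summary row
#'
#' @param label a [condition_label()].
#' @param msf,msf_err global MSF and error, Angstrom^2.
#' @param v_app_per_heavy_atom,v_app_err apparent volume per heavy atom, A^3.
#' @param n_w_in,n_w_in_err interior-water count.
#' @param n_hb,n_hb_err hydrogen-bond population.
#' @param tau_hb,tau_hb_err pair-averaged lifetime, ps.
#' @return one-row `condition_summary` data frame.
#' @export
condition_summary <- function(label, msf, msf_err, v_app_per_heavy_atom,
                              v_app_err, n_w_in, n_w_in_err, n_hb, n_hb_err,
                              tau_hb, tau_hb_err) {
  errs <- c(msf_err, v_app_err, n_w_in_err, n_hb_err, tau_hb_err)
  if (any(errs < 0, na.rm = TRUE))
    stop_ptfluct("errors must be >= 0", "ptfluct_spec_error")
  out <- data.frame(
    protein_id = label$protein_id, temperature = label$temperature,
    pressure = label$pressure,
    msf = msf, msf_err = msf_err,
    v_app_per_heavy_atom = v_app_per_heavy_atom, v_app_err = v_app_err,
    n_w_in = n_w_in, n_w_in_err = n_w_in_err,
    n_hb = n_hb, n_hb_err = n_hb_err,
    tau_hb = tau_hb, tau_hb_err = tau_hb_err,
    stringsAsFactors = FALSE
  )
  class(out) <- c("condition_summary", "data.frame")
  out
}

## round half away from zero (the convention that reproduces the printed
## comparison tables; R's round() is banker's rounding)
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

fmt_pm <- function(v, e, digits) {
  sprintf(paste0("%.", digits, "f ± %.", digits, "f"), v, e)
}

#' Read condition summaries from a TSV table
#'
#' The table mirrors the condition-summary layout: a first column
#' `Protein (T, K; P, bar)` holding e.g. `"EcDHFR (279; 1)"`, then columns
#' `MSF (A^2)`, `Vapp/NHA (A^3)`, `Nw,in`, `NHB`, `tauHB (ps)` with cells of
#' the form `value ± error` (ASCII `+-` and Unicode minus accepted).
#'
#' @param path TSV file.
#' @return a `condition_summary` data frame (one row per condition).
#' @export
load_condition_summaries <- function(path) {
  raw <- tryCatch(
    utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                      fileEncoding = "UTF-8"),
    error = function(e) stop_ptfluct(
      sprintf("cannot parse %s: %s", path, conditionMessage(e)),
      "ptfluct_parse_error"))
  if (nrow(raw) == 0L || ncol(raw) < 6L)
    stop_ptfluct(sprintf("condition table %s is empty or lacks columns", path),
                 "ptfluct_parse_error")
  parse_pm <- function(s, line) {
    s <- gsub("−", "-", s)          # unicode minus
    s <- gsub("\\+/?-", "±", s)     # ASCII +- / +/-
    parts <- strsplit(s, "±")[[1]]
    v <- suppressWarnings(as.numeric(trimws(parts[1])))
    e <- if (length(parts) > 1)
      suppressWarnings(as.numeric(trimws(parts[2]))) else 0
    if (is.na(v))
      stop_ptfluct(sprintf("malformed value '%s' on line %d of %s", s, line, path),
                   "ptfluct_parse_error")
    c(v, e)
  }
  out <- NULL
  for (i in seq_len(nrow(raw))) {
    lab <- as.character(raw[i, 1])
    m <- regmatches(lab, regexec(
      "^\\s*(\\S+)\\s*\\(\\s*([0-9.]+)\\s*;\\s*([0-9.]+)\\s*\\)\\s*$", lab))[[1]]
    if (length(m) != 4)
      stop_ptfluct(sprintf("malformed condition label '%s' on line %d of %s",
                           lab, i + 1L, path), "ptfluct_parse_error")
    cl <- condition_label(m[2], as.numeric(m[3]), as.numeric(m[4]))
    vals <- lapply(2:6, function(j) parse_pm(as.character(raw[i, j]), i + 1L))
    row <- condition_summary(cl,
                             vals[[1]][1], vals[[1]][2], vals[[2]][1], vals[[2]][2],
                             vals[[3]][1], vals[[3]][2], vals[[4]][1], vals[[4]][2],
                             vals[[5]][1], vals[[5]][2])
    out <- if (is.null(out)) row else rbind(out, row)
  }
  class(out) <- c("condition_summary", "data.frame")
  out
}

#' Write condition summaries in the same TSV layout
#'
#' @param summaries a `condition_summary` data frame.
#' @param path output TSV.
#' @export
write_condition_summaries <- function(summaries, path) {
  df <- data.frame(
    check.names = FALSE, stringsAsFactors = FALSE,
    `Protein (T, K; P, bar)` = sprintf("%s (%g; %g)", summaries$protein_id,
                                       summaries$temperature, summaries$pressure),
    `MSF (A^2)` = fmt_pm(summaries$msf, summaries$msf_err, 2),
    `Vapp/NHA (A^3)` = fmt_pm(summaries$v_app_per_heavy_atom,
                              summaries$v_app_err, 2),
    `Nw,in` = fmt_pm(summaries$n_w_in, summaries$n_w_in_err, 2),
    `NHB` = fmt_pm(summaries$n_hb, summaries$n_hb_err, 0),
    `tauHB (ps)` = fmt_pm(summaries$tau_hb, summaries$tau_hb_err, 1)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Condition-change (delta) tables
#'
#' For `axis = "temperature"`, pairs conditions sharing (protein, pressure)
#' and reports the change from the low-T to the high-T state; for
#' `axis = "pressure"`, pairs conditions sharing (protein, temperature).
#' Percent changes are `100 * (high - low) / low` with respect to the low
#' state. Printed-style columns follow the conventions above; unrounded
#' values are kept in `*_raw` columns and propagated errors (quadrature) in
#' `*_err` columns.
#'
#' @param summaries a `condition_summary` data frame.
#' @param axis `"temperature"` or `"pressure"`.
#' @return a `delta_table` data frame, one row per (protein, fixed value).
#' @export
delta_table <- function(summaries, axis = c("temperature", "pressure")) {
  axis <- match.arg(axis)
  vary <- axis
  fixed <- if (axis == "temperature") "pressure" else "temperature"
  key <- paste(summaries$protein_id, summaries[[fixed]])
  rows <- lapply(unique(key), function(k) {
    g <- summaries[key == k, , drop = FALSE]
    if (nrow(g) != 2L)
      stop_ptfluct(sprintf(
        "need exactly the two endpoint conditions for %s along %s (got %d)",
        k, vary, nrow(g)), "ptfluct_pairing_error")
    g <- g[order(g[[vary]]), ]
    lo <- g[1, ]; hi <- g[2, ]
    pct <- function(col) 100 * (hi[[col]] - lo[[col]]) / lo[[col]]
    pct_err <- function(col, err) {
      ## first-order propagation of independent block errors
      r <- hi[[col]] / lo[[col]]
      100 * abs(r) * sqrt((hi[[err]] / hi[[col]])^2 + (lo[[err]] / lo[[col]])^2)
    }
    data.frame(
      protein_id = lo$protein_id,
      held_fixed = fixed,
      held_value = lo[[fixed]],
      from = lo[[vary]], to = hi[[vary]],
      pct_msf = round_half_away(pct("msf")),
      pct_vapp = round_half_away(pct("v_app_per_heavy_atom")),
      delta_n_w_in = round_half_away(hi$n_w_in - lo$n_w_in, 2),
      delta_n_hb = round_half_away(hi$n_hb - lo$n_hb),
      pct_tau_hb = round_half_away(pct("tau_hb")),
      pct_msf_raw = pct("msf"),
      pct_vapp_raw = pct("v_app_per_heavy_atom"),
      delta_n_w_in_raw = hi$n_w_in - lo$n_w_in,
      delta_n_hb_raw = hi$n_hb - lo$n_hb,
      pct_tau_hb_raw = pct("tau_hb"),
      pct_msf_err = pct_err("msf", "msf_err"),
      pct_vapp_err = pct_err("v_app_per_heavy_atom", "v_app_err"),
      delta_n_w_in_err = sqrt(hi$n_w_in_err^2 + lo$n_w_in_err^2),
      delta_n_hb_err = sqrt(hi$n_hb_err^2 + lo$n_hb_err^2),
      pct_tau_hb_err = pct_err("tau_hb", "tau_hb_err"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("delta_table", "data.frame")
  out
}

#' Printed-style view of a delta table
#'
#' Drops the raw/error bookkeeping columns, keeping only the conventionally
#' rounded values.
#' @param dt a `delta_table`.
#' @export
delta_table_printed <- function(dt) {
  dt[, c("protein_id", "held_fixed", "held_value", "pct_msf", "pct_vapp",
         "delta_n_w_in", "delta_n_hb", "pct_tau_hb")]
}
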
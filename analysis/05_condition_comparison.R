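#!/usr/bin/env Rscript

# Assembles the synthetic condition-summary table from the stage outputs of
# scripts 02-04 and computes the temperature- and pressure-change tables.
# Also recomputes the same change tables from the packaged published
# condition summaries for the two DHFR homologs (EcDHFR/MpDHFR), which is
# the exactness check for the comparison arithmetic.

source("analysis/00_conditions.R")

msf <- read.delim("results/msf_by_condition.tsv")
vol <- read.delim("results/volume_interior_by_condition.tsv")
hb <- read.delim("results/hbond_by_condition.tsv")

summaries <- NULL
for (i in seq_len(nrow(targets))) {
  row <- targets[i, ]
  tag <- condition_tag(row)
  lab <- condition_label(row$protein, row$temperature, row$pressure)
  m <- msf[msf$condition == tag, ]
  v <- vol[vol$condition == tag, ]
  h <- hb[hb$condition == tag, ]
  cs <- condition_summary(lab, m$msf_est, m$msf_err,
                          v$vapp_ha_est, v$vapp_ha_err,
                          v$n_w_in_est, 0,
                          h$n_hb_est, h$n_hb_err,
                          h$tau_hb_est, h$tau_hb_err)
  summaries <- if (is.null(summaries)) cs else rbind(summaries, cs)
}
class(summaries) <- c("condition_summary", "data.frame")
write_condition_summaries(summaries, "results/synthetic_condition_summaries.tsv")

dT <- delta_table(summaries, "temperature")
dP <- delta_table(summaries, "pressure")
write.table(delta_table_printed(dT), "results/synthetic_delta_T.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(delta_table_printed(dP), "results/synthetic_delta_P.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("synthetic temperature changes (percent of the 279 K state):\n")
print(delta_table_printed(dT))

## published condition summaries -> published change tables
pub <- load_condition_summaries(system.file(
  "extdata", "dhfr_pt_condition_summaries.tsv", package = "ptfluct"))
pub_dT <- delta_table(pub, "temperature")
pub_dP <- delta_table(pub, "pressure")
write.table(delta_table_printed(pub_dT), "results/published_delta_T.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(delta_table_printed(pub_dP), "results/published_delta_P.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("\npublished temperature changes:\n")
print(delta_table_printed(pub_dT))
cat("\npublished pressure changes:\n")
print(delta_table_printed(pub_dP))
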
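# Shared definition of the synthetic condition grid used by the analysis
# scripts. Two synthetic DHFR-like homologs ("SynEc", mesophile-like, and
# "SynMp", psychropiezophile-like) are emulated at the 2x2 grid of growth
# temperatures (279, 310 K) and pressures (1, 220 bar). Generator targets are
# set once, to the magnitudes a 50-ns solvated-protein simulation of this
# kind produces: per-atom fluctuation scale, hydrogen-bond population and
# lifetime scale, interior-water count, and volume per heavy atom. Everything
# downstream recovers these known targets from the generated data.

suppressMessages(library(ptfluct))

N_ATOMS <- 100          # heavy atoms in the pseudo-protein
N_RESIDUES <- 50        # two heavy atoms per residue
N_FRAMES <- 50000       # 50 ns at 1 ps/frame
BLOCKS <- block_spec(10000, 5)
N_PAIRS <- 150          # distinct donor/acceptor pairs in the bond pool
N_WATERS <- 500         # waters for the volume bookkeeping
V_WATER <- 30.0         # mean molecular volume of water, A^3

conditions <- expand.grid(protein = c("SynEc", "SynMp"),
                          temperature = c(279, 310), pressure = c(1, 220),
                          stringsAsFactors = FALSE)
conditions <- conditions[order(conditions$protein, conditions$temperature,
                               conditions$pressure), ]
## per-condition generator targets (columns follow the condition order above)
targets <- data.frame(
  conditions,
  msf = c(0.65, 0.71, 0.93, 1.04,     # SynEc: T up, P up -> softer wells
          0.76, 0.83, 1.39, 1.49),    # SynMp: softer still
  tau_on = c(27.7, 25.5, 11.6, 11.2,  # bonded dwell scale, ps
             30.6, 22.5, 11.2, 11.1),
  n_hb = c(107, 105, 106, 104,        # mean simultaneous bond count
           103, 104, 101, 101),
  n_w_in = c(2, 2, 2, 2, 3, 3, 4, 3), # planted interior waters
  vapp_ha = c(17.38, 17.55, 17.87, 17.82,  # volume per heavy atom, A^3
              17.73, 17.77, 18.26, 18.25)
)
targets$seed <- 100 + seq_len(nrow(targets))

condition_tag <- function(row)
  sprintf("%s_%gK_%gbar", row$protein, row$temperature, row$pressure)

dir.create("results", showWarnings = FALSE)
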
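# ptfluct

Trajectory analysis of pressure and temperature effects on protein dynamics
in molecular dynamics (MD) simulations.

Proteins from extremophiles — here the motivating system is dihydrofolate
reductase (DHFR) from the psychropiezophile *Moritella profunda* compared
with its *Escherichia coli* homolog — balance stability against the
flexibility their enzymatic function needs. In solution-phase MD, that
balance shows up in a small set of coupled observables: atomic fluctuations
grow with temperature *and* (surprisingly) with sub-kilobar pressure, while
intra-protein hydrogen bonds weaken. `ptfluct` implements the complete
analysis chain that quantifies this from trajectories:

- **Mean-square fluctuations (MSF).** For each protein heavy atom *i*,
  `⟨Δr_i²⟩` is the block average (default five 10-ns blocks) of the variance
  of its position about the within-block mean, and
  `MSF = (1/N_HA) Σ_i ⟨Δr_i²⟩` over the `N_HA` heavy atoms, with block
  standard errors. Optional least-squares superposition removes rigid-body
  tumbling. Per-residue difference maps between conditions are exported on a
  fixed diverging colour scale (−0.5 … 2.0 Å²).
- **Apparent protein volume.** `V_app = ⟨V_MD⟩ − N_w·⟨V_w⟩`, where `⟨V_MD⟩`
  is the mean simulation-cell volume, `N_w` the number of waters, and
  `⟨V_w⟩` the molecular volume of water from a pure-solvent run at the same
  (T, P); reported per heavy atom as `V_app/N_HA`.
- **Interior waters.** A water (by its oxygen) is inside the protein in a
  frame iff it is within 4.00 Å of a protein heavy atom *and* no other water
  oxygen lies within 3.36 Å; counts are sampled every 100 ps (`N_w,in`).
- **Hydrogen bonds.** Geometric criterion: H···A distance < 2.40 Å and
  D–H···A angle > 130°, donors/acceptors being protein N/O/S (charged groups
  included, bifurcated bonds counted per pair). `N_HB` is the block-averaged
  simultaneous bond count. Each pair's continuous lifetime is
  `τ_ij = (1/n_ij) Σ_n t_ij(n)` over its `n_ij` maximal runs of consecutive
  bonded frames, and `τ_HB = (1/N′) Σ τ_ij` averages unique pairs, excluding
  (but reporting) pairs with `τ_ij` > 1 ns. A per-acceptor dataset of
  `1/MSF` versus `ln τ` with a > 2 ps filter exposes the inverse
  fluctuation–lifetime relationship.
- **Condition comparison.** Per-protein change tables along the temperature
  axis (279 → 310 K) or pressure axis (1 → 220 bar): percent changes of MSF,
  `V_app/N_HA` and `τ_HB` relative to the low state (rounded
  half-away-from-zero to integers), signed differences for `N_w,in` (two
  decimals) and `N_HB` (integers).

Because raw 50-ns trajectories of this kind are rarely redistributable, the
package ships synthetic generators with exact ground truth — independent
Ornstein–Uhlenbeck pseudo-proteins (stationary per-atom MSF `3k_BT/κ_i`),
telegraph hydrogen-bond occupancies with exponential dwells (including the
closed-form discretization-corrected run length), planted interior/exterior
water scenes, and Gaussian box-volume series — so every stage is validated
end to end without any download.

## Worked example

```r
library(ptfluct)

# fluctuations of a harmonic pseudo-protein with known ground truth
tr <- generate_ou_protein(n_residues = 50, atoms_per_residue = 2,
                          kappa = KB_KCAL * 279 * 3 / 0.65,  # target 0.65 A^2
                          temperature = 279, friction = 2,
                          n_frames = 20000, seed = 42)
msf <- compute_msf(tr, block_spec(block_length = 4000, n_blocks = 5),
                   superpose = FALSE)
print(msf)
#> MSF over 100 protein heavy atoms, 5 block(s): 0.6499 +/- 0.00039 A^2

# hydrogen-bond lifetimes from two-state occupancies (25 ps bonded dwells)
occ <- generate_hbond_occupancy(n_pairs = 50, tau_on = 25, tau_off = 50,
                                duration = 20000, frame_interval = 1, seed = 42)
ev <- track_events(occ$per_frame_sets, frame_interval = 1)
summ <- summarize_lifetimes(ev$pairs, occ$per_frame_sets, 1,
                            block_spec(4000, 5))
print(summ)
#> N_HB = 16.7 +/- 0.15; N = 50 unique pairs (50 in tau_HB); tau_HB = 25.72 +/- 0.23 ps
telegraph_expected_run_duration(25, 50, 1)
#> [1] 25.75817

# published condition summaries -> temperature-change table
s <- load_condition_summaries(system.file(
  "extdata", "dhfr_pt_condition_summaries.tsv", package = "ptfluct"))
delta_table_printed(delta_table(s, "temperature"))
#>   protein_id held_fixed held_value pct_msf pct_vapp delta_n_w_in delta_n_hb pct_tau_hb
#> 1     EcDHFR   pressure          1      43        3         0.40         -1        -58
#> 2     MpDHFR   pressure          1      83        3         0.96         -2        -63
#> 3     EcDHFR   pressure        220      46        2         0.39         -1        -56
#> 4     MpDHFR   pressure        220      80        3        -0.02         -3        -51
```

The MSF line reports the block-averaged fluctuation over the 100 heavy
atoms with its standard error over blocks — here recovering the 0.65 Å²
stationary ground truth of the generator. The lifetime summary shows the
mean simultaneous bond count (`n_pairs × τ_on/(τ_on+τ_off) = 16.7`), and a
pair-averaged lifetime of 25.7 ps, matching the closed-form expectation for
a 25 ps exponential dwell observed on a 1 ps frame grid. The change table
reports, e.g., that EcDHFR's fluctuations grow 43 % from 279 to 310 K at
1 bar while its mean bond lifetime drops 58 %.

## Analysis workflow

The `analysis/` directory holds numbered drivers that reproduce the whole
study design on synthetic data: `01_simulate.R` (condition grid and
generator targets), `02_fluctuations.R` (MSF and per-residue difference
maps), `03_volume_interior.R` (apparent volume and interior waters),
`04_hbond_lifetimes.R` (populations, lifetimes, correlation dataset) and
`05_condition_comparison.R` (condition summaries and change tables, both
synthetic and published). Each writes its tables under `results/`. Run them
from the repository root:

```sh
for f in analysis/0*.R; do Rscript "$f"; done
```

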
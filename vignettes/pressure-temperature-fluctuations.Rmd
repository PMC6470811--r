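---
title: "Quantifying pressure and temperature effects on protein dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying pressure and temperature effects on protein dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptfluct)
```

## The analysis model

`ptfluct` treats a solvated-protein MD trajectory as a stationary time
series of atomic positions with a periodic cell, and asks how four coupled
observables respond when temperature or hydrostatic pressure changes:
atomic mean-square fluctuations (MSF), the apparent volume available per
heavy atom, the number of waters inside the protein, and the population and
continuous lifetime of intra-protein hydrogen bonds. The working hypothesis
these quantities probe is mechanical: each atom sits in an effective
potential well formed by its neighbours; thermal energy, thermal expansion,
and hydrogen-bond weakening soften the wells with temperature, while
pressure steepens them directly but can still soften them indirectly by
weakening hydrogen bonds. Shorter bond lifetimes alongside larger
fluctuations — and, per acceptor atom, an inverse relation between `1/MSF`
and `ln τ` — are the signatures the pipeline extracts.

### Block averaging

Every headline quantity is reported as a mean with a block-averaging error
bar: the trajectory is cut into consecutive fixed-length blocks
(`block_spec()`, default 10 000 ps × 5 blocks, matching a 50-ns production
run), the statistic is computed per block, and the error is the standard
error of the mean over blocks (`sd/√n`). SEM was chosen over the sample
standard deviation because the reported value is itself the across-block
mean; with only five blocks either convention is defensible, and the block
values are retained so users can reform the bars. Trailing frames that do
not fill a block are dropped (with a message), since a ragged final block
would not be exchangeable with the others.

### Mean-square fluctuations

For each selected atom and block, `compute_msf()` takes the variance of the
atom's position about its *within-block mean position*, summed over x, y, z
(population variance). The within-block mean — not a crystal structure — is
the reference, so the measure reflects fluctuations about the conformation
actually sampled during that 10 ns. Per-atom values average the blocks;
the global MSF averages protein heavy atoms (ligand, ion and virtual sites
excluded by default; the selection is a parameter).

Rigid-body motion is removed by default (`superpose = TRUE`): within each
block, frames are least-squares superposed (Kabsch) on the protein heavy
atoms — first onto the block's first frame, then twice onto the refreshed
within-block mean. Anchoring on the first frame makes the procedure exactly
equivariant under arbitrary per-frame rotations and translations of the
input, which the test suite checks to below 1e-6 relative. Without
superposition, tumbling would dominate a 10-ns window for a free protein.
The flag exists because the right choice depends on how the trajectory was
post-processed upstream; comparisons across conditions must use one
setting. When validating against the harmonic generator (below), the
package's own analyses run with `superpose = FALSE`: the generator's atoms
fluctuate independently about fixed sites, so there is no rigid-body motion
to remove, and fitting would absorb ~6/(3N) of the true variance into the
alignment degrees of freedom, biasing the analytic comparison.

Per-residue difference maps (`delta_msf_map()`) subtract per-residue means
between two conditions and attach a diverging colour coordinate clipped to
the fixed anchors (−0.5, 0, 2.0) Å² — a numeric stand-in for structure
colouring, so that maps from different condition pairs share one scale.

### Apparent volume

`V_app = ⟨V_MD⟩ − N_w·⟨V_w⟩` converts cell-volume statistics into an
effective protein volume using a pure-solvent reference `⟨V_w⟩` at the
matching temperature and pressure (`compute_vapp()` refuses a mismatched
reference). The reference can be a bare number or be derived from a
pure-water volume series (`pure_solvent_reference()`). Ion volumes are not
subtracted; this biases absolute `V_app` slightly but cancels in
cross-condition differences, which are the quantity of interest. Surface- or
cavity-based volume definitions are deliberately out of scope: the apparent
volume is the measure that connects to experiment and responds to
fluctuations of the structure. Cell volumes are computed as the scalar
triple product of the lattice vectors, which is exact for axis-aligned
cells and supports the triclinic (rhombic dodecahedral) cells common in
protein MD.

### Interior waters

A water is *inside* the protein in a sampled frame iff its oxygen is
strictly within 4.00 Å of some protein heavy atom and its nearest other
water oxygen is at least 3.36 Å away. Both distances use the minimum-image
convention in the frame's cell. The water–water distance is oxygen–oxygen
(the standard hydration-structure convention; an any-atom variant is a
criterion parameter). Counting samples the trajectory every 100 ps: the
criterion is a sharp indicator, and adjacent 1-ps frames would contribute
nothing but correlated noise. Boundary semantics are documented and tested:
"within 4.00" is a strict `<`; exclusion by a neighbour requires that
neighbour strictly inside 3.36 Å, so a neighbour at exactly the cutoff does
not disqualify. Ties are measure-zero on real data; the tests construct
them with dyadic coordinates so the tie is exact in floating point.

### Hydrogen bonds and lifetimes

Donors are protein hydrogens covalently bound to N/O/S (C–H donors are
excluded); acceptors are protein N/O/S heavy atoms; charged moieties
participate on both sides. A pair is bonded in a frame iff the
minimum-image H···A distance is strictly below 2.40 Å and the D–H···A angle
(at the hydrogen) strictly above 130°. One atom may appear in several
simultaneous pairs; each pair identity is tracked separately, so a
bifurcated bond is two events.

An *event* is a maximal run of consecutive bonded frames — continuity is
strict, with a configurable gap tolerance (default 0 frames) available for
sensitivity analysis. Events that touch either trajectory end are flagged
`truncated` but included in the statistics: at 50-ns scale, discarding them
would bias against exactly the long-lived pairs the analysis cares about,
and the flag makes recomputation without them a one-liner. The pair
lifetime `τ_ij` is the mean event duration; the pair-averaged `τ_HB` is the
unweighted mean of `τ_ij` over unique pairs, excluding pairs with `τ_ij`
above 1000 ps (they have too few events for a meaningful mean). The
threshold is applied identically at every condition, and the excluded pairs
are reported with identities so that condition-specific exclusion
conventions can be reproduced exactly. The bond population `N_HB` is block
averaged over every stored frame and always includes the excluded pairs —
`N` (unique pairs over the run) and `N_HB` (mean simultaneous count) are
different quantities and both are reported.

The exact bookkeeping identity `Σ_ij n_ij·τ_ij = Δt · Σ_frames |bonds|`
links the event statistics to the population and is asserted in the tests.
Autocorrelation-based lifetime definitions are deliberately not offered:
protein pairs span lifetimes from ps to beyond 10 ns, which makes a single
correlation-decay fit impractical; the continuous-event measure tracks
relative changes, which is what cross-condition tables need.

For the fluctuation–lifetime dataset, each acceptor's lifetime aggregates
its pairs across donors, event-weighted by default (total bonded time over
total events — a per-event mean; an unweighted per-donor mean is a switch).
Acceptors at or below 2 ps are dropped — at a 1-ps frame interval those
lifetimes are dominated by discretization. The emitted table carries
`1/MSF` and `ln τ` with the Pearson correlation as an attribute.

### Condition-change tables

`delta_table()` pairs condition summaries that share (protein, fixed
variable) and reports changes from the low to the high state of the varying
axis: percentages of the low state for MSF, `V_app/N_HA` and `τ_HB`, signed
differences for `N_w,in` and `N_HB`. Printed-style rounding is
half-away-from-zero to integers (two decimals for `N_w,in`) — R's
`round()` is banker's rounding and does not reproduce conventional table
formatting. Unrounded values and quadrature-propagated errors stay in
`*_raw`/`*_err` columns; the printed view omits them, matching how such
tables are conventionally presented. Forward and reverse changes satisfy
`(1 + p_fwd/100)(1 + p_rev/100) = 1` before rounding, which the tests use
as an internal consistency check. The packaged
`dhfr_pt_condition_summaries.tsv` table carries the published per-condition
summaries for the two DHFR homologs; feeding it through `delta_table()`
reproduces every published change cell exactly, which pins down the
rounding conventions.

## What the synthetic generators emulate

The study's raw trajectories are not redistributable, so the package
validates against generated data with exact ground truth:

- `generate_ou_protein()`: each heavy atom is an independent
  Ornstein–Uhlenbeck process about a fixed lattice site, sampled with the
  exact AR(1) discretization, so any frame interval is unbiased. The
  stationary 3-D MSF is `3 k_B T / κ_i` with
  `k_B = 0.0019872041 kcal mol⁻¹ K⁻¹`. The `friction` parameter is the
  relaxation *rate* (ps⁻¹; correlation time `1/friction`), decoupled from
  `κ`, which sets only the variance — this makes "block length ≫ relaxation
  time" directly checkable.
- `generate_hbond_occupancy()`: per-pair telegraph processes with
  exponential bonded/unbonded dwells, started from the stationary law and
  observed on the frame grid. The sampled process is a two-state Markov
  chain, so the expected *observed* run duration has the closed form
  `Δt/(1 − p₁₁)` with `p₁₁ = p_on + (1 − p_on)e^(−λΔt)`
  (`telegraph_expected_run_duration()`); the test suite verifies this
  discretization correction against an independent continuous-time
  simulation before using it as the recovery target.
  `generate_hbond_geometry()` realizes any schedule as explicit
  donor/hydrogen/acceptor coordinates that the geometric detector
  reproduces frame-by-frame.
- `generate_solvated_scene()`: plants interior waters that satisfy the
  two-distance rule by construction and exterior waters that violate it,
  with bounded rejection sampling.
- `generate_volume_series()` and `set_volume_series()`: Gaussian cell-volume
  series attached as cells whose volumes reproduce the series exactly.

What the generators deliberately do **not** emulate: covalent geometry and
excluded volume (OU atoms are kinematically independent), force-field
energetics, pressure coupling, water structure, or correlated loop motions.
Passing the recovery tests therefore demonstrates that the *estimators* are
correct and unbiased at realistic statistics — not that any physical claim
about a particular protein is reproduced from raw dynamics. The analysis
scripts choose generator targets (fluctuation scale 0.3–1.5 Å², lifetimes
11–31 ps, populations ~100–107 bonds, 50 000 frames at 1 ps in five 10-ns
blocks) to match the magnitudes a 50-ns solvated DHFR run produces, so the
statistical regime — block counts, event counts, discretization ratios —
is the one the pipeline faces in practice.

## Numerical choices and degenerate inputs

- **Units and indexing.** Å, ps, K, bar throughout; atom and frame indices
  are 1-based (idiomatic R); frame ranges are half-open `[start, end)`.
- **Minimum image.** Displacements are wrapped in fractional coordinates
  and then refined over the 27 neighbouring images — exact for compact MD
  cells (cubes, orthorhombic, rhombic dodecahedra, and mildly skewed
  triclinic cells). Degenerate cells (zero triple product) are rejected.
- **Strict inequalities.** All geometric criteria use the strict bounds
  stated above; equalities at a cutoff behave deterministically and are
  tested, but on real (continuous) data they occur with probability zero.
- **File formats.** Multi-model PDB and DCD are read (via `bio3d`), with
  per-frame cells from DCD and a constant CRYST1 cell (flagged, with a
  warning) from PDB; both formats are written, the DCD writer emitting
  CHARMM-style crystal records. Trajectory formats without any cell
  information require an explicit fallback box. Hydrogens are linked to
  their covalent heavy atom by CONECT records when present, else by the
  nearest intra-residue heavy atom within 1.2 Å — robust without a
  force-field dictionary. TIP4P-style virtual sites are excluded from all
  counts and criteria; ions are classified as neither protein nor water and
  never enter any statistic.
- **Degenerate analyses.** A trajectory shorter than one block, an empty
  selection, absent waters, a non-commensurate sampling interval, an empty
  frame sequence, or a lifetime summary whose pairs are all excluded each
  raise a typed error (`ptfluct_*_error`) rather than returning partial
  numbers.
- **Pipeline orchestration.** `run_pipeline()` runs all stages on one
  trajectory, writes per-stage TSVs stamped with a configuration hash, and
  degrades gracefully (warning, omitted column) when no solvent reference
  is configured. Identical configurations produce byte-identical stage
  tables. There is no shell executable: the numbered scripts under
  `analysis/` and the exported functions are the interface.

## Limitations

Absolute `V_app` carries the unsubtracted ion volume; protein–water
hydrogen bonds are out of scope (the lifetime machinery tracks
protein–protein pairs); the interior-water definition becomes fuzzy for
partially unfolded states near melting, and no alternative definition is
offered; and the superposition question for published MSF values of any
given study must be resolved by the user's own convention, since both
settings are supported but must not be mixed within a comparison.
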
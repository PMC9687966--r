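# hydrochan

Channel hydration, water mobility and hydrogen-bond network analysis of
molecular dynamics trajectories.

Proton-conducting channels — such as the K-channel of cytochrome c
oxidase, named for its central lysine — work only when enough water is
present, suitably placed and suitably connected, to relay protons by the
Grotthuss mechanism. Deciding whether that is the case from an MD
trajectory takes several linked measurements: how many waters occupy the
channel, where along the channel axis they sit, how mobile they are at
each height, how long key residues stay hydrogen-bonded to *some* water,
and how often residues are linked by continuous hydrogen-bonded water
wires. hydrochan implements this pipeline as a tested, reusable R package
for structural biophysicists analysing channel or cavity hydration.

## The method

* **Channel region.** The channel is defined per frame as the convex
  polyhedron spanned by the centres of mass of user-chosen corner
  residues (the volume-maximal polyhedron on those vertices); waters
  whose oxygen ever enters it form the analysis set. For spatial
  statistics the polyhedron is enveloped by a cylinder (radius 9.5 Å,
  15 × 2 Å slices, radial rings at 1.0/3.5/5.0/9.5 Å, 30° segments)
  anchored on the median structure — the frame closest to the mean
  coordinates — with the axis through the Cα centres of the lowermost and
  uppermost residues, elongated by 10%.
* **Mobility.** Per-slice diffusion coefficients from a single-lag mean
  squared displacement, *D*ₛ = ⟨|Δx|²⟩ₛ / 6τ with τ = 2 ps, displacements
  credited to the starting slice, decomposed into axial/radial/angular
  parts; slices empty in > 95% of frames are flagged and reported as 0;
  replicas are combined Nₛ-weighted.
* **Hydrogen bonds.** Geometric criterion (donor–acceptor ≤ 3.5 Å,
  ≤ 35° deviation from linearity at the hydrogen). Lifetimes come from
  the continuous any-water survival function
  C(τ) = ⟨Σh(t₀)h(t₀+τ) / Σh(t₀)²⟩ over non-overlapping time origins
  (120 ps spacing, 100 ps maximal lag), fitted with
  C(t) = A·e^(−t/τ₁) + B·e^(−t/τ₂), A + B = 1; the reported lifetime is
  A·τ₁ + B·τ₂.
* **Connectivity.** Per frame, residues and waters are nodes of a graph
  whose edges are hydrogen bonds; a residue pair is connected when a
  shortest-path (Dijkstra) query finds any path. Connection
  probabilities are fractions of connected frames.
* **Conformers.** χ1–χ4 side-chain dihedral distributions (5° bins),
  inter-residue distances with Cα or polar-atom conventions, and
  up/down classification against a distance threshold.

All quantities are computed per replica and averaged with the standard
error of the replica means. A synthetic-trajectory generator (confined
Brownian waters, two-state Markov hydrogen-bond processes, analytic
scaffold geometry) provides exact ground truth for validation; see the
methods vignette (`vignettes/channel-hydration-methods.Rmd`) for every
convention and default.

## Worked example

Three replicas of twenty Brownian waters (D = 0.2 Å²/ps) in a synthetic
10 × 10 × 30 Å channel scaffold, with one donor/acceptor pair switching
with a 20 ps bonded dwell time:

```r
library(hydrochan)

spec <- synthetic_channel_spec(n_waters = 20, n_frames = 20000, seed = 42,
  hbond_pairs = data.frame(bonded_dwell = 20, unbonded_dwell = 20))
reps <- simulate_replicas(spec, 3)

corners <- data.frame(chain_id = "S", residue_id = 1:8)
polys <- lapply(reps, channel_polyhedra, corners)
cyl <- build_cylinder(reps[[1]], find_median_frame(reps[[1]], 1:5000),
                      bottom = data.frame(chain_id = "S", residue_id = 11L),
                      top = data.frame(chain_id = "S", residue_id = 12L))

hydration_summary(reps, polys, cyl)
#> hydration_summary (3 replicas)
#>   waters in polyhedron: 7.16 +/- 0.03
#>   waters in cylinder:   20.00 +/- 0.00
#>   polyhedron volume:    3.000 +/- 0.000 nm^3

dp <- diffusion_profile(lapply(reps, slice_msd, cyl))
head(dp$profile[, c("slice", "height", "ds", "ns")], 3)
#>   slice height        ds    ns
#> 1     1    -14 0.1768905 80104
#> 2     2    -12 0.1922607 81106
#> 3     3    -10 0.1928163 80841

fits <- lapply(reps, function(fs) {
  h <- bond_presence_series(fs, "D", 101L, partner_ids = 201L)
  fit_biexponential(survival_curve(h, dt = 2))
})
fits[[1]]
#> biexp_fit: A = 0.706 (tau1 = 19.02 ps), B = 0.294 (tau2 = 19.02 ps)
#>   weighted lifetime = 19.02 ps (rss 0.0104)
unlist(lifetime_summary(fits))
#>       mean         se   reported          n
#> 18.9440225  0.6153257 18.9440225  3.0000000
```

Reading the numbers: the 3.0 nm³ scaffold polyhedron holds on average
7.2 of the 20 confined waters (the rest are in the cylinder but outside
the box); the slice diffusion coefficients recover the generating
0.2 Å²/ps (the entrance slice reads slightly low because waters reflect
off the confinement there); and the fitted hydrogen-bond lifetime,
18.9 ± 0.6 ps across replicas, recovers the 20 ps Markov dwell time.

The same analyses run end-to-end from a YAML configuration with
`run_pipeline(config, out_dir)` (CSV/JSON tables; byte-identical on
rerun with the same seed), from PDB + DCD files via `load_trajectory()`,
or from the shell via `inst/scripts/hydrochan-cli.R` (`run-all`,
`simulate`).

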
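---
title: "Methods: channel hydration, water mobility and hydrogen-bond kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: channel hydration, water mobility and hydrogen-bond kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydrochan)
```

hydrochan quantifies how water behaves inside a protein channel — how many
waters occupy it, where they sit, how mobile they are, how long they stay
hydrogen-bonded to key residues, and whether they form continuous
hydrogen-bonded wires between residues. It was designed for proton-uptake
channels such as the K-channel of cytochrome c oxidase, where these
quantities decide whether a Grotthuss-style proton relay is feasible, but
every geometric element (corner residues, axis residues, cylinder
parameters) is configurable.

This vignette explains the models and conventions behind each stage, the
defaults and why they were chosen, and what the synthetic ground-truth
generator does and does not emulate.

## The channel region: polyhedron and cylinder

The channel has no sharp physical boundary, so it is *defined* by
geometry: a set of corner residues (for the K-channel, twelve residues of
subunit I and three of subunit II; see `kchannel_corner_residues()`) whose
centres of mass span a convex polyhedron in every frame
(`build_polyhedron()`). The convex hull is the unique volume-maximal
polyhedron on fixed vertices, which makes the definition unambiguous; its
volume is reported in nm³. Any water whose oxygen lies inside this
polyhedron in at least one frame (`track_channel_waters()`) belongs to the
channel analysis set — occupancy is instantaneous, but the *eligibility*
of a water is a property of the whole trajectory.

Because a per-frame polyhedron is awkward for spatial histograms, the
analyses are binned inside an enveloping cylinder (`build_cylinder()`)
anchored on a *median structure*: the frame with the smallest RMSD (no
refitting) to the coordinate-wise mean over an initial window
(`find_median_frame()`; the pipeline uses the first 10 ns of the analysed
span). The axis runs between the Cα centres of mass of the lowermost and
uppermost residues and is elongated by 10% so the channel mouth and exit
are covered; we split the elongation symmetrically (5% beyond each end),
which the axis definition itself does not dictate. Heights are signed,
with the origin at the axis midpoint and positive pointing to the top
(exit/BNC) end, so residues below the channel midpoint report negative
heights.

The cylinder (default radius 9.5 Å) is partitioned into 15 axial slices of
2 Å — thicker than a water molecule's internal H–H distance, thinner than
an O⋯H hydrogen-bond distance, so a water belongs to one slice at a time —
four radial rings with bounds 1.0, 3.5, 5.0, 9.5 Å, and 30° angular
segments. Slice intervals are half-open `[low, high)` with the topmost
slice closed; ring bounds are inclusive on their upper edge; a point
exactly on the axis belongs to segment 1. These boundary conventions are
frozen by tests. The sliced span is `n_slices × slice_thickness` centred
on the axis midpoint; if the elongated axis is shorter than the span a
warning is raised rather than rescaling the slices.

## Hydration

`hydration_summary()` reports the average instantaneous number of waters
in the polyhedron and in the cylinder, plus the average polyhedron volume.
Counts are averaged over frames within each replica, then across replicas,
with the standard error of the replica means — every replica-averaged
quantity in the package follows this pattern. A single replica reports SE
0 and a warning flag.

`occupancy_profile()` resolves the mean count by slice (summing the
profile recovers the total in-cylinder mean exactly),
`cumulative_profile()` accumulates it from the channel entrance upward,
and `occupancy_projection()` bins positions on a (height × in-plane
coordinate) grid normalised per frame. The projection plane is the signed
radial coordinate along a configurable azimuth; the choice of plane is a
visualisation convention, not part of the model.

## Water mobility

Per-slice diffusion coefficients use a single-lag mean-squared-displacement
estimator: for every consecutive frame pair, the squared displacement of
each water inside the cylinder at the start frame accrues to its
*starting* slice, and

$$D_s = \frac{\langle |\Delta x|^2 \rangle_s}{6\tau}, \qquad \tau = 2\ \mathrm{ps}.$$

All consecutive origins contribute (this maximises statistics; with a 2 ps
lag the windows are one frame apart by construction). Waters outside the
cylinder at the start frame contribute nothing, even if they enter by the
end frame. At the default parameters (D ≈ 0.2 Å²/ps, 2 Å slices) a water
crosses more than one slice per frame in well under 5% of steps, so the
starting-slice attribution is a mild approximation.

Each squared displacement is decomposed into axial (along the axis),
radial (change of axis distance) and angular (residual) parts that sum
exactly to the total, separating transmembrane transport from in-slice
rattling. Slices empty in more than 95% of frames carry $D_s = 0$ with an
`insufficient` flag — a deliberate sentinel, not a measurement; the rule
is applied per replica before averaging because a slice may be well
sampled in one replica and empty in another. Replica values are combined
as the $N_s$-weighted average with the $N_s$-weighted standard deviation
as the spread, so replicas with more observations dominate.

## Hydrogen bonds and lifetimes

A hydrogen bond exists when the donor–acceptor distance is ≤ 3.5 Å and
the D–H⋯A angle deviates from linearity by ≤ 35°; both boundaries are
inclusive and the angle is evaluated at the hydrogen. Donor/acceptor
typing comes from a small built-in chemistry table (hydroxyl, carboxylate,
amine/ammonium, imidazole, amide, water, hydronium, and the generator's
pseudo-groups); water and hydronium act as both donor and acceptor.
Per-residue bond counts (`mean_hbond_counts()`) count bonds, not distinct
partners: a water donating twice to the same residue contributes two.

Lifetimes use the *continuous, any-water* convention: the indicator
$h(t)$ is 1 when the residue is bonded to *some* water — the partner and
the bonding atoms may change — and an origin survives lag $\tau$ only if
$h$ stays 1 at every frame through $t_0+\tau$. The survival curve

$$C(\tau) = \left\langle \frac{\sum h(t_0)h(t_0+\tau)}{\sum h(t_0)^2} \right\rangle_{t_0}$$

is evaluated to a maximal lag of 100 ps with origins spaced 120 ps so the
windows never overlap (since $h$ is binary the denominator is simply the
number of bonded origins). $C$ is fit with
$C(t) = A e^{-t/\tau_1} + B e^{-t/\tau_2}$, $A + B = 1$, by bounded
Levenberg–Marquardt least squares from a multi-start grid
($\tau_1 \in \{2, 10\}$, $\tau_2 \in \{50, 200\}$ ps, $A \in \{0.3, 0.7\}$)
because the residual surface is multimodal; a Nelder–Mead fallback runs if
no start converges. Time constants are capped at ten times the longest
sampled lag: slower processes are unidentifiable from the window, and
without the cap a vanishing tail amplitude multiplied by an enormous
$\tau_2$ can dominate the reported lifetime. The lifetime is the weighted
sum $\tau = A\tau_1 + B\tau_2$, averaged across replicas; following the
reporting rule for poorly determined values, a lifetime whose standard
error exceeds its mean is reported as not available (in practice, with
three non-negative replica values the SE cannot exceed the mean, so this
triggers only through failed fits).

## Connectivity networks

For each frame, residues, waters and the hydronium are nodes of a simple
undirected graph whose edges are that frame's hydrogen bonds
(`build_hbond_graph()`); a residue pair is *connected* when a path exists
(`residues_connected()`, a unit-weight Dijkstra shortest-path query — on
an unweighted graph this is exactly reachability, which is all the
counting requires). `connection_probabilities()` reports, per residue
pair, the fraction of connected frames, replica-averaged with SE. The
probability matrix is symmetric with diagonal 1 by convention.

## Conformational statistics

`dihedral()` computes signed torsions in (−180°, 180°] with the
polymer-convention sign (trans = 180°, cis = 0°) that MDAnalysis and
bio3d share; the suite cross-checks against `bio3d::torsion.xyz` on random
geometries. `chi_distributions()` evaluates χ1–χ4 where defined (built-in
atom quadruples for Ser, Thr, Tyr, His, Glu, Lys) and histograms them on
5° bins normalised to integrate to 1; 5° resolves rotamer wells without
emptying bins at typical trajectory lengths. For the cross-linked
Tyr–His pair found in oxidase active sites the standard Tyr definitions
are used. `residue_distances()` supports the Cα convention for
channel-width measures and a polar-atom convention (hydroxyl O for
Ser/Thr/Tyr, Nζ for Lys, Cε1 for His — the carbon bridging both imidazole
nitrogens — and Cδ for Glu, bridging both carboxylate oxygens), which
keeps distances well defined when protonation states or ring flips swap
chemically equivalent atoms. `classify_up_down()` labels frames by a
distance threshold to a reference residue, default 11.5 Å — the midpoint
between the observed "up" (≈ 8–11 Å) and "down" (≈ 12.4–13.2 Å) distance
bands of the lysine gate; no cutoff is canonical, so it is a parameter.

## Synthetic ground truth

`simulate_channel()` generates trajectories whose statistical structure is
known exactly, so every stage can be validated without reference data:

* a **scaffold** of eight single-atom corner pseudo-residues at the
  vertices of a box (default 10 × 10 × 30 Å, hence an exactly 3.0 nm³
  polyhedron) plus axis-end residues placed so the elongated axis spans
  the box height;
* **waters** performing independent Gaussian random walks with per-axis
  step variance $2 D \Delta t$ (defaults D = 0.2 Å²/ps, Δt = 2 ps — a
  typical confined-water mobility at the frame spacing the analyses
  assume), confined to the cylinder by mirror reflection. Reflection
  keeps the stationary occupancy uniform, so hydration and diffusion
  expectations stay analytic; radial reflection folds the radius and
  preserves the azimuth, a faithful approximation when steps are small
  relative to the radius;
* optional donor/acceptor **pairs** whose acceptor toggles between a
  bonded geometry (2.8 Å, collinear) and an unbonded one (5.0 Å) under a
  two-state Markov chain. Per-frame switching probabilities are
  $1 - e^{-\Delta t/\bar\tau}$, the exact discretisation of exponential
  dwell times, which makes the continuous survival curve exactly
  $e^{-\tau/\bar\tau}$; the geometric dwell mean is then
  $\bar\tau + \mathcal{O}(\Delta t/2)$ (21.0 ps at $\bar\tau$ = 20 ps,
  Δt = 2 ps). Bond states are realised as coordinates so detection,
  survival and fitting are exercised end to end; the realised states
  travel along as an attribute for direct injection in unit tests;
* an optional fixed-oxygen **hydronium** particle.

The generator emulates the *statistics* the analyses assume — diffusive
confined water, exponential bond kinetics, stationary geometry. It does
not emulate force-field physics: no electrostatics, no water–water
correlations, no proton hopping, no protein flexibility. Passing tests
therefore certify the estimators (geometry, counting, MSD, survival,
fitting, graph logic), not the biology of any particular channel.

## Numerical choices and problem sizes

* Hull construction is incremental with tolerances scaled to the point
  cloud; boundary points count as inside.
* Degenerate inputs fail loudly: fewer than four or coplanar corner
  centres name the offending residues; zero-length axes, lags that are
  not multiples of the frame spacing, and donors without hydrogens are
  errors, not warnings.
* Reading a DCD whose header count disagrees with its content, or whose
  reader emits a warning, is an error — no silent partial trajectories.
* The pipeline (`run_pipeline()`) is a pure function of configuration and
  seed; reruns are byte-identical, which the suite asserts. By default
  the first 20% of each trajectory is discarded as residual
  equilibration.
* Validation sizes were chosen so that each property is measured well
  into its asymptotic regime while the whole suite stays interactive:
  diffusion with 50 waters × 10⁴ frames (recovery within 10%, linearity
  across D = 0.05–0.5 Å²/ps), lifetimes with 10⁵ frames (recovery within
  15% at ~800 independent origins), connectivity on 200 random graphs
  against a breadth-first oracle, and an end-to-end smoke run with 20
  waters × 500 frames × 3 replicas.

## Known limitations

* Single-lag MSD estimation assumes the 2 ps displacement is in the
  diffusive regime; subdiffusive water in tight confinement will read as
  a lower effective $D_s$.
* The cylinder is rigid over a replica; large-scale protein drift would
  smear slice assignments (the trajectories are expected to be
  pre-aligned — the package never refits).
* Lifetime constants beyond the 100 ps window are extrapolations of the
  bi-exponential form, bounded but not validated by data.
* Water residue ids must be unique across the topology; files that
  restart water numbering per chain need renumbering on import.
* XTC input is not supported (no installed reader); DCD is the exchange
  format, and the package writes the same dialect it reads.
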
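---
title: "Modelling two-stage mussel dispersal: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling two-stage mussel dispersal: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(musselflow)
```

## The biological problem

Green-lipped mussels (*Perna canaliculus*) disperse in two stages. Larvae
drift for three to five weeks before making a **primary settlement** onto
macroalgae or other substrata; the resulting spat can later detach and
drift along the seabed on floating material before a **secondary
settlement** onto an adult bed. The wild-spat fishery collects the spat
that wash up on an exposed beach, and the management question is where
that material comes from: which rocky-shore populations supply the beach,
and how strongly the populations along the coast are connected to each
other through either stage.

`musselflow` implements the full analysis chain for that question:

1. a Lagrangian particle-tracking core that integrates larvae and spat
   through a gridded flow field, forward or backward in time;
2. four preset release experiments — two backtracking runs that trace
   beach-collected spat to their primary settlement areas and then to
   their source populations, and two forward runs that estimate regional
   (larval) and secondary (spat) connectivity;
3. connectivity analytics: trajectory probability-density maps with
   high-density area extraction, primary/secondary/total connectivity
   matrices, dispersal kernels, and an EOF decomposition of inter-annual
   variability;
4. a genetics bridge that converts connectivity into a column-standardised
   migration matrix, projects it over generations, computes Nei's
   $D_A$ distances ("derived oceanographic resistance", DOR) and tests
   their correlation with pairwise $F_{ST}$ by Mantel permutation.

## The particle-tracking model

Particles move by classical 4th-order Runge–Kutta advection with a 900 s
step through velocities interpolated trilinearly in space and linearly in
time. Backtracking passes a negative step through the same kernel, which
is equivalent to reversing every current; stochastic terms are switched
off in backward mode (a random walk is not time-reversible), and forcing
them on raises a warning.

Unresolved turbulence is a Gaussian random walk with horizontal
diffusivity $K_h = 0.1176\ \mathrm{m^2\,s^{-1}}$ and vertical diffusivity
$K_v = 0.01\ \mathrm{m^2\,s^{-1}}$, the vertical part applied as
consecutive 90 s substeps; each axis gains variance $2Kt$. Spat and
sinking larvae deepen at $w_s = 0.001\ \mathrm{m\,s^{-1}}$. These values
are the calibration commonly used for bivalve larvae at 5 km grid
resolution.

The per-step operator order is: advection → horizontal diffusion →
substepped vertical diffusion → sinking → boundary rule → settlement
check. The boundary rule applies once to the final proposed position:
moves ending on land or below the seafloor are undone (the particle is
moved back to its previous position), surface breaches are clamped to
$z = 0$, and lateral exits from the grid count as open-boundary losses
(`removed`). A competent particle whose step ends over suitable habitat
settles there even where the boundary rule would otherwise intervene —
settlement is checked against the sites first, so the coastline rule only
applies "outside the availability of settlement habitat".

Settlement competency opens at 21 days and closes at the 35-day maximum
pelagic duration for larvae; spat may re-settle from day 10 up to day 30.
The beach-backtracking experiment adds a latitude-dependent age lag (0 at
the southern end to 5.5 days at the northern end, linear in between,
reflecting the alongshore gradient in collected spat sizes); the lag
extends each particle's tracked duration, not its competency window.

Particle accounting is strict: after any run, released = settled +
expired + removed, and the tests assert it for every experiment.

### Numerical choices

* Velocity interpolation is flat within the half-cell margin between the
  domain edge and the first cell center; positions outside the grid
  return an out-of-domain signal and the caller decides the particle's
  fate.
* A single seeded RNG stream drives each run, drawing a block of normals
  for the currently active cohort every step. A fixed seed therefore
  reproduces trajectories bit-for-bit. (Per-particle streams — which
  would additionally make results independent of batch partitioning —
  are not used; R has no cheap per-particle generator, and the
  determinism contract is what the analyses need.)
* Forward-then-backward advection over a smooth steady field returns to
  the start within $10^{-3}$ of the path length; the residual is the
  non-cancelling $O(\Delta t^5)$ local truncation of the two passes, a
  few times $10^{-5}$ m per step pair at oceanographic speeds.
* Release instants are snapped to the integration step grid ("released
  linearly in time" is implemented as $k$ evenly spaced instants at
  offsets $(i - \tfrac12)/k$ of each calendar month, using true month
  lengths of a non-leap year).

## The synthetic coastal scenario

No hydrodynamic hindcast ships with the package. Instead
`coastal_scenario()` builds a semi-realistic coastal flow whose
*statistical structure* matches what the analysis assumes, on a
300 × 600 km plane with 5 km cells, four depth levels (0, 10, 30, 100 m)
and a straight meridional coast:

* an **inshore band** (e-folding scale 10 km) flowing north along the
  coast, as bottom-drifting spat observations imply;
* an **offshore jet** (Gaussian, centered 100 km offshore) flowing south
  — the counterflowing shelf current;
* a **convergence zone** where the northward inshore band meets reversed
  flow, placed at a configurable latitude north of the habitat (the merge
  is a `tanh` of width 50 km);
* a compact **retention eddy** offshore of the bay at the southern end of
  the beach (Gaussian streamfunction bump, 15 km radius, 0.06 m s⁻¹ peak
  swirl);
* a **habitat gap**: 49 five-kilometre sites in 18 alongshore-contiguous
  populations (three sites per population in the south, two in the
  north, separated by 15 km sandy stretches), split into two blocks by a
  60 km beach with no settlement habitat — the spat-collection beach.

The horizontal velocity derives from a streamfunction differenced with
central differences, so the discrete divergence vanishes to machine
precision on interior cells; velocities decay with depth as
$e^{-z/100\,\mathrm{m}}$. Per-"year" realisations jitter the current
strengths by ±10% and the eddy centers by ±5 km under a seeded RNG, so a
decade of synthetic years exists without an archive; the same seed always
rebuilds the identical scenario.

Two emergent properties of these defaults carry the headline analyses:

* With corridor speeds of 0.012–0.018 m s⁻¹, the farthest a larva can
  travel within its 35-day window is ≈ 54 km — less than the 60 km beach
  gap. The **primary** connectivity matrix is therefore two diagonal
  blocks with essentially no between-block exchange.
* Backtracked beach spat retrace the inshore corridor, so the extracted
  primary settlement areas form a coastal ribbon spanning the southern
  sites and the lower half of the gap. Spat released there drift on
  north, and those starting inside the gap **bridge** it — the
  two-stage pathway reaches the northern block even though the larval
  stage cannot, which is exactly the stepping-stone role primary
  settlement areas are hypothesised to play. The total (primary +
  secondary) dispersal kernel consequently has a longer 95th-percentile
  reach than the primary kernel alone.

What the generator does **not** emulate: tides, wind events, river
plumes, vertical shear beyond a fixed depth decay, thermohaline
structure, larval behaviour other than constant sinking, and any
time-variability within a year (fields are steady per realisation;
the container supports hourly snapshots and the integrator interpolates
in time, but the scenario does not exercise it). Tests passing on this
scenario show the machinery is correct and the qualitative mechanisms
are reproducible — not that any particular real coastline behaves this
way.

## Density maps and settlement-area extraction

Trajectory probability maps bin recorded positions whose age falls in a
window (for beach backtracking: 10 days to 20 days + lag, per particle)
onto a 299 × 299 grid over the analysis box and normalise to sum 1. Areas
of aggregation are extracted by thresholding the *expected particle
density* — per-cell probability × released-particle count / cell area —
at 0.6 particles km⁻², labelling retained cells into 4-connected
components (diagonal contact does not join), and dilating each component
by a 500 m buffer. Component areas use the closed form for a rectilinear
polygon dilated by a disk ($A + Pr + \tfrac{\pi r^2}{4}c - r^2 f$ with
$c$ convex and $f$ reflex corners), exact while the buffer is below half
the minimum feature separation; components whose buffers overlap are
merged under the earlier label and measured by fine-grid sampling.

The threshold's unit deserves a note: probabilities are unitless, so the
package interprets "particles per km²" through the released-particle
count, both of which are explicit arguments.

## Connectivity, kernels, EOFs

`connectivity_matrix()` puts sources on rows and sinks on columns;
entry $(i, j)$ is settlers from $i$ arriving at $j$ divided by $i$'s
releases, local retention on the diagonal. Yearly matrices average
element-wise into a decadal matrix. Secondary connectivity is the product
of the site × area matrix (larval run) with the area × site matrix (spat
run); total connectivity is primary + secondary. Dispersal kernels bin
straight-line release-to-settlement distances (record-level) or
centroid-to-centroid distances weighted by release counts
(matrix-level); kernel mass equals the settled fraction, so kernels of
different stages are directly comparable. Inter-annual variability is
decomposed by SVD of mean-removed flattened yearly matrices (EOF modes
and explained-variance fractions); identical years yield a flagged empty
decomposition. Any log scaling is display-only and never stored.

## From connectivity to genetics

Downscaling to populations happens at settler-count level (fractions
× releases, summed over site groups, re-fractionalised by group
releases), which conserves the total settler count exactly — averaging
fractions would not when releases differ. Column standardisation yields
the migration matrix: column $j$ is the source profile of receiving
population $j$, the diagonal self-recruitment; all-zero columns are left
zero and flagged. Generational projection is the plain matrix power —
column-stochasticity is preserved automatically, so no renormalisation
is applied.

Nei's $D_A = 1 - \sum_k \sqrt{X_{ik} Y_{ik}}$ is applied to **columns**
of the migration matrix: each column is a probability distribution, and
one minus the Bhattacharyya coefficient of two distributions is
symmetric, zero on the diagonal and bounded in $[0, 1]$ — the stated
properties of the DOR matrix hold exactly only for this margin, since
rows of a column-standardised matrix need not sum to 1. A row-margin
variant exists behind `margin = "rows"` for sensitivity checks.
Degenerate populations sit at distance 1 from everyone.

The Mantel test correlates strict upper triangles and permutes rows and
columns of the second matrix simultaneously,
$p = (1 + \#\{r_\pi \ge r_{\mathrm{obs}}\})/(1 + n_\pi)$, one-tailed for
positive association (the isolation-by-resistance direction); a negative
observed correlation simply yields a large $p$. The permutation engine is
`vegan::mantel`, seeded; an independent hand-rolled permutation loop
serves as the oracle in the tests, and the type-I error rate of the test
is verified against its nominal level on independent random distance
matrices.

## Problem sizes used in the checks

The bundled checks run the whole chain at desk scale: 2 000 backtracked
spat for the density analysis, 3 000 backtracked larvae over three
synthetic years for source attribution, ≈ 2 × 10⁴ forward larvae for the
regional matrix and 4 000 spat for the secondary stage — about 1 000 to
4 000 particles per experiment-month against the preset 200 000. These
sizes were chosen as the smallest at which the qualitative structure
(two blocks, nearshore settlement ribbon, northern bridging) is stable
across seeds; contribution percentages at this scale carry a few percent
of Monte-Carlo noise, which the acceptance checks treat as such
(structural assertions, not digit matching).

## Known limitations

* The flow scenario is steady within a year and purely horizontal
  (`w = 0`); vertical advection support exists but is unexercised.
* Settlement geometry is axis-aligned (squares and buffered cell
  unions); arbitrary polygon habitats would need a point-in-polygon
  backend.
* The calendar ignores leap years; years are labels for seeded
  realisations, not astronomical years.
* Mantel power at six populations is intrinsically low; the package
  reports $r$ and $p$ and leaves interpretation to the user.
* No larval mortality, growth, temperature dependence, or active
  swimming beyond constant sinking.
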
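---
title: "Rotation-driven curvature sorting: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rotation-driven curvature sorting: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(curvsort)
```

## The scientific problem

ATP synthase couples proton flux to the rotation of its membrane-embedded
c-ring. `curvsort` implements the quantitative machinery needed to ask
whether that rotation changes how the protein interacts with membrane
shape: does a rotating ATP synthase seek curved membrane, cluster with its
neighbours, and deform the bilayer around it?

Two experimental windows inform the package design. On the *in vitro*
side, tether pulling from giant unilamellar vesicles (GUVs) probes
curvature preference directly: a nanotube of radius $r_t$ (curvature
$c = 1/r_t$) is pulled from a quasi-flat GUV, and the protein-to-lipid
composition of tube versus vesicle gives the sorting ratio

$$S \;=\; \frac{\mathrm{PCF}_1 \, (I^{tube}_{prot} / I^{GUV}_{prot})}
               {\mathrm{PCF}_2 \, (I^{tube}_{lip} / I^{GUV}_{lip})},$$

where the PCFs correct for dye-polarization effects in curved membrane.
On the simulation side, coarse-grained trajectories of a quasi-planar
bilayer strip hosting several rotary proteins are analysed for membrane
undulations, local curvature near and away from proteins, protein-protein
clustering and contact lifetimes, an effective interaction potential,
bilayer thickness and area-per-chain profiles, and protein tilt/rotation
kinematics.

Since the package cannot (and should not) run molecular dynamics, it
ships a synthetic trajectory generator whose every statistical feature is
planted with known ground truth. Each analysis is then validated by
parameter recovery: the estimator must read back what the generator wrote
in.

## The synthetic membrane generator

The generator builds a bilayer strip of lateral size $L_x \times L_y$
(default $52 \times 13$ nm, $2 \times 856$ lipids — the aspect ratio is
large so undulations develop essentially along one dimension). The
midsurface is a sum of sinusoidal modes

$$\bar z(x) = \sum_m A_m \sin(2\pi m x / L_x + \phi_m),$$

and the two phosphate leaflets are offset by $\pm d(x)/2$ along the local
surface normal, where $d(x)$ is the local thickness. Acyl-chain anchor
beads (two per lipid) sit 0.8 nm below the phosphates. Proteins are rigid
bead cylinders (shell radius 3 nm) whose centres follow overdamped
Langevin dynamics in a configurable pair potential; their axes tilt with
the local midsurface slope, and two anchor rings (bottom and top of the
rotor) advance according to a smooth or stepwise rotation model.

Key defaults and the reasoning behind them:

* **Baseline thickness** `d0 = 3.9` nm — bulk P–P distance of a POPC
  bilayer; **thinning** toward 3.2 nm near proteins in the rotating
  preset, with Gaussian decay $\sigma = 2.5$ nm so the perturbation spans
  roughly 7 nm, the range over which hydrophobic mismatch acts. Thinning
  depends on $x$ only (the membrane is quasi-1D) and saturates at full
  depth where the wells of clustered proteins overlap, so the planted
  minimum is exactly `d0 - depth` regardless of clustering.
* **Pair potential** — a Gaussian well (depth 1.5 kBT at 6 nm
  centre-to-centre, width 1 nm) plus a harmonic soft core below 4.5 nm.
  This is the membrane-mediated attraction regime: a weak, short-range
  minimum at a separation where one lipid shell still fits between the
  proteins.
* **Undulations** — the *control* (passive) preset draws a fresh
  single-mode amplitude each frame, $A \sim \mathcal N(1.5, 0.325)$ nm.
  Because no per-bead vertical noise is added, the per-frame peak-to-peak
  phosphate spread is exactly $2A + d_0$, so this choice realises a
  spread distribution with mean 6.9 nm and SD 0.65 nm by closed form.
  The *active* preset uses a persistent single-mode buckle of amplitude
  3.55 nm (spread $\approx 11$ nm) with a slow phase drift; an
  `active_twomode` variant realises the alternative two-mode buckled
  state.
* **Rotation** — 0.47 turns/µs in the active preset, stepped in tenths of
  a turn (one step per c-subunit) at exponential waiting times.
* **Diffusion** — 5 nm²/µs, a typical coarse-grained mobility for a small
  membrane protein; frame spacing 0.01 µs over 500 frames (5 µs).
* **Initial placement** — evenly spread in the control preset; a loose
  cluster (spacing ≈ 7 nm) in the active preset, consistent with the
  aggregation that rotation promotes. This also guarantees protein-free
  membrane beyond 10 nm, so far-field readouts are well defined.
* **Footprint exclusion** — lipids are pushed out of each protein
  footprint with the map $r' = \sqrt{r^2 + R^2}$, which is exactly
  area-preserving: lipid density (and hence Voronoi chain areas) away
  from the protein is untouched. An optional dilation field expands
  chain areas by a configured fraction (default 1% in the active preset)
  within 6 nm of a protein.

All randomness flows from a single integer seed through per-purpose
sub-streams; identical (config, seed) pairs give bit-identical
trajectories.

**What the generator does not emulate:** bead-level thermal roughness of
real phosphate positions, lipid exchange between leaflets, solvent,
electrostatics, and any feedback of protein position on membrane shape
(proteins do not *cause* the buckle; the buckle is imposed). Passing
recovery tests therefore demonstrate correctness of the estimators, not
fidelity of the generator to molecular reality.

## Estimators and numerical choices

**Membrane profile.** The phosphate $z$-profile along $x$ is computed per
frame on `n_bins` bins. A coarse pooled pass (≈ 3.5 nm bins) estimates a
midplane used to split beads into leaflets; the profile value is then the
mean of the two per-leaflet bin means. This balanced estimator equals the
pooled mean when leaflet counts per bin are equal and, unlike raw
pooling, does not jump by half a bilayer thickness when a narrow bin
catches only one leaflet. Bins missing a leaflet are filled by periodic
linear interpolation and flagged.

**Circumradius curvature.** The box is cut into 30 slices (the default
follows the trajectory-analysis convention of the study this package
operationalises); the profile values at slice boundaries form triangles
whose circumscribed circle gives $|c| = 1/R_{circ}$, signed positive when
the membrane bulges toward $+z$. On an analytic sinusoid the crest
curvature is recovered within ~1% at 30 slices and ~0.01% at 300; on
bead-derived profiles the profile resolution should exceed the slice
count by a factor of ≈ 3 or interpolation kinks dominate. Near/away
labelling uses a lateral cutoff of 3 nm (one protein radius) from any
protein centre; the cutoff is a documented choice, exposed as a
parameter, because no canonical value exists.

**Peak-to-peak undulation spread.** Per frame, max minus min of all
phosphate $z$ (leaflets pooled — the flat-membrane baseline then equals
the leaflet separation, which is what makes spread values like 6.9 nm
with a 3.9 nm baseline interpretable).

**Clustering and contacts.** Two thresholds on the minimum inter-bead
distance: 2 nm for loose clustering (lipid-mediated) and 0.7 nm for
close contact (no intervening lipid). Contact events are maximal
below-threshold runs, optionally debounced; events touching the
trajectory boundary are flagged and included by default (a switch
excludes them). The self-weighted lifetime is
$\sum \tau_i^2 / \sum \tau_i$. The cluster-fraction CI uses the
N/I bootstrap on the per-frame clustered-pair fraction, whose time mean
equals the reported fraction.

**Boltzmann inversion.** The centre-to-centre distance histogram
(0.25 nm bins, second half of the trajectory by default, so that the
slow approach to equilibrium does not contaminate the density) is
inverted as $V(l) = -k_BT \ln[p(l)/(2\pi l)] + \text{const}$. Dividing
by the $2\pi l$ Jacobian is the default because a non-interacting
(ideal-gas) pair in two dimensions has $p(l) \propto l$ and must invert
to a flat potential; the literal no-Jacobian form is available behind a
flag. The additive gauge is fixed by zeroing the mean of $V$ over the
outer 20% of the support; the well minimum is refined parabolically from
the minimum bin and its neighbours.

**Thickness and area per chain.** Thickness is the $z$-difference of the
two leaflet levels on an x-grid, multiplied by $\cos\theta_{loc}$ with
$\theta_{loc} = \arctan(\text{midplane slope})$ — the vertical cut
through a tilted bilayer overestimates the normal thickness by exactly
$1/\cos\theta$, so the cosine is the natural curvature correction (the
form used upstream is not documented; this one is exact for a locally
planar tilted patch and reduces to the identity on flat membrane).
Area per acyl chain uses a periodic 2D Voronoi tessellation over
chain-anchor seeds plus the protein beads of that leaflet, with
protein-seed cells excluded and the $1/\cos\theta$ projection correction;
Voronoi is the standard tool for per-lipid areas, and the cell areas tile
the box exactly (conservation is tested at $10^{-6}$ relative). Both
profiles are binned by lateral distance to the nearest protein centre of
mass (x-distance for the quasi-1D thickness grid, 2D for chain seeds),
0.5 nm bins by default.

**Kinematics.** Tilt is the angle between $+z$ and the vector joining
the bottom- and top-anchor ring centroids. Rotor angle is the azimuth of
a reference anchor bead about the ring centroid, measured in the plane
perpendicular to the protein axis, unwrapped by accumulating minimal
angular differences; the rate is the least-squares slope over $2\pi$
(regression, not endpoint difference, to stay robust to thermal wiggle
around the stepping trend). Steps of $\pi$ or more per frame raise an
aliasing error instead of silently folding.

**Resampling statistics.** Frames are autocorrelated, so the bootstrap
resamples only $\lceil N/I \rceil$ observations per replicate, where
$I = 1 + 2\sum_k \rho(k)$ is the autocorrelation integral, summed up to
the first non-positive autocorrelation (the initial-positive-sequence
rule — chosen because it is simple, bias-conservative, and the upstream
estimator is unspecified; it is isolated in one function and swappable).
With $I$ forced to 1 this reduces exactly to the ordinary bootstrap. The
weighted Welch test uses frequency-weight semantics, making integer
weights identical to replication, which is the convention required when
weighting contact lifetimes by themselves. The block sub-average test
averages each series over blocks of length $\lceil \max(I_a, I_b)\rceil$
(a pooled autocorrelation of two unrelated series is ill-defined, so the
conservative maximum is used) and Welch-tests the block means.

**Tether arithmetic.** Tube radius from aspiration uses
$r_t = -\frac{dL_p}{dL_t} \frac{R_p}{1 - R_p/R_V}$ with the slope fitted
by least squares; a non-negative slope is a geometry error, not a number.
The radius-fluorescence calibration factor is fitted through the origin.
Binned sorting curves report the mean and bootstrap CI per curvature bin
plus the headline window $r_t = 50 \pm 20$ nm. The e-fold relation is
implemented as $c_{shape} = k_BT / (A_p \kappa c_P)$ — the only reading
of the garbled printed expression that reproduces both of its published
evaluations — with $\kappa$ in kBT units, and
$c_P = \sin(\varphi_P/2)/R_P$ linking spontaneous curvature to the wedge
angle. The cluster radius convention is $R = \sqrt{A}$ (followed
literally from the source arithmetic, not $\sqrt{A/\pi}$).

## Degenerate inputs and edge behaviour

Collinear profile points give curvature 0; coincident points are an
error. Empty profile bins interpolate rather than fail, so sparse
synthetic systems remain analysable. Flat potentials report depth 0 with
an undefined location flag. A constant series yields a zero-width
bootstrap CI; zero-variance autocorrelation is an error at the estimator
level but handled above it. When a bootstrap has fewer than 5 effective
samples, analysis wrappers report `NA` intervals with a warning instead
of aborting a whole pipeline.

## Problem sizes

The shipped tests and the acceptance script run, per analysis: $10^5$
sampled pair distances for potential recovery; 500 frames of the active
preset (full lipid complement) for thickness; 1000 frames of the control
preset for undulation statistics; $10^5$ frames of the rotation series
for rate recovery; 500 AR(1) repetitions for bootstrap coverage; and a
few hundred lipids per leaflet for Voronoi-based area profiles, whose
tessellation is the most expensive step. These sizes were chosen so each
recovery sits well inside its sampling tolerance while the whole suite
runs in a couple of minutes on one CPU.

## Known limitations

* The generator's proteins do not feed back on membrane shape; curvature
  preference scenarios are constructed (pinned proteins on persistent
  buckles), not emergent.
* XTC trajectories are not read; GRO and multi-frame PDB cover the
  text-based interchange formats. Group metadata lives in a JSON sidecar
  with 1-based indices.
* The Langevin sampler equilibrates slowly at box scale, so
  potential-of-mean-force recovery from dynamics is validated
  qualitatively (monotone well deepening); quantitative recovery uses the
  exact inverse-CDF sampler.
* On a torus the ideal pair-distance measure deviates from $2\pi l$
  beyond half the short box length; Boltzmann inversions from periodic
  dynamics should restrict the support accordingly.
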
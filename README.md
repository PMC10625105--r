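# curvsort

Analysis toolkit for **rotation-driven curvature sorting of ATP
synthases** in lipid membranes.

ATP synthase makes ATP by spinning its membrane-embedded c-ring. Beyond
chemistry, that rotation perturbs the surrounding bilayer: it can thin
the membrane locally, create a membrane-mediated attraction between
neighbouring proteins, amplify undulations, and ultimately couple the
protein to membrane curvature. `curvsort` provides, in one package, the
computations used to quantify this coupling on both sides of the
problem:

* **Experiment side (tether pulling).** A lipid nanotube of radius
  `r_t` pulled from a giant unilamellar vesicle probes curvature
  `c = 1/r_t`. The sorting ratio

  ```
  S = [PCF1 * (I_tube_prot / I_GUV_prot)] / [PCF2 * (I_tube_lip / I_GUV_lip)]
  ```

  measures protein enrichment in the curved tube (`S = 1`: no
  preference). The package computes `S`, the tube radius from the
  aspiration trade-off `r_t = -(dL_p/dL_t) R_p / (1 - R_p/R_V)`, the
  fluorescence-radius calibration factor, binned sorting-versus-curvature
  curves, and the wedge-angle arithmetic connecting protein shape to
  sorting: spontaneous curvature `c_P = sin(phi/2)/R_P` and the e-fold
  sorting curvature `c_shape = kBT / (A_p * kappa * c_P)`.

* **Simulation side (coarse-grained trajectories).** Membrane z-profiles
  and 30-slice circumradius curvature, curvature preference near versus
  away from proteins, peak-to-peak undulation statistics, protein
  clustering frequencies (2 nm) and close-contact lifetimes (0.7 nm,
  self-weighted `sum(tau^2)/sum(tau)`), Boltzmann inversion of
  pair-distance distributions into an effective potential
  `V(l) = -kBT ln[p(l)/(2 pi l)] + const`, bilayer thickness and
  area-per-acyl-chain profiles versus distance to protein (with
  tilt-cosine curvature correction and periodic Voronoi tessellation),
  and protein tilt/rotation kinematics.

* **Statistics.** Simulation observables are autocorrelated, so the
  package ships an N/I subsampled bootstrap (resampling only `N/I`
  points per replicate, `I` = autocorrelation integral), a weighted
  Welch t-test with Satterthwaite degrees of freedom, and a block
  sub-average t-test.

* **Synthetic trajectories with ground truth.** A generator plants
  undulation modes, local thinning, an attractive pair potential,
  slope-coupled tilts and stepwise rotor rotation into bilayer+protein
  trajectories, so every estimator is testable by parameter recovery —
  no MD engine or external data needed.

## Worked example

```r
library(curvsort)

# Wedge-angle arithmetic: a 9-degree wedge on a 3 nm protein
cP     <- spontaneous_curvature_from_wedge(phi_P = 9, R_P = 3)
cshape <- efold_sorting_curvature(A_p = 25.6, kappa = 10, c_P = 0.03)
sprintf("monomer: c_P = %.3f 1/nm, c_shape = %.3f 1/nm", cP, cshape)
#> "monomer: c_P = 0.026 1/nm, c_shape = 0.130 1/nm"

# A rotating-condition synthetic trajectory (4 proteins, 52 x 13 nm bilayer)
sim <- generate_membrane_trajectory(generator_preset("active", seed = 42))
peak_to_peak(sim$trajectory)
#> peak-to-peak spread: <h> = 10.638 nm, SD = 0.081 nm (500 frames)

ds <- distance_series(sim$trajectory)
cf <- cluster_fraction(ds)            # fraction of pairs within 2 nm
sprintf("loose clustering frequency: %.2f (95%% CI %.2f-%.2f)",
        cf$fraction, cf$ci[1], cf$ci[2])
#> "loose clustering frequency: 0.38 (95% CI 0.31-0.44)"

tp <- thickness_profile(sim$trajectory)
sprintf("thickness: min %.2f nm near proteins, %.2f nm far field",
        min(tp$value), mean(tp$value[tp$r > 10]))
#> "thickness: min 3.20 nm near proteins, 3.90 nm far field"

# Boltzmann inversion recovers a planted 1.5 kBT well at 6 nm
d  <- sample_pair_distances(potential_spec(depth = 1.5, location = 6),
                            1e5, seed = 42)
wp <- well_parameters(boltzmann_invert(distance_histogram(d, 0.25)))
sprintf("recovered well: %.2f kBT at %.2f nm", wp$depth, wp$location)
#> "recovered well: 1.45 kBT at 6.00 nm"
```

The peak-to-peak spread of ~10.6 nm reflects the persistent buckle of
the rotating condition (the passive `"control"` preset fluctuates around
6.9 nm); the thickness profile shows the planted thinning from 3.9 nm to
3.2 nm near the proteins; and the inversion of 10^5 sampled distances
reads the attractive well back to within sampling error.

A full generate-analyze-report run is driven by one config:

```r
run_pipeline(list(seed = 1, output_dir = "out",
                  generator = list(preset = "active"),
                  analyses = list(undulations = TRUE, contacts = list(),
                                  potential = list(), kinematics = TRUE)))
```

which writes per-stage CSVs, a `summary.json`, a run log and the config
copy into `out/`.

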
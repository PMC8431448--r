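# smaggr

Small-molecule aggregation trajectory analysis and inhibition kinetics in R.

Metabolites such as adenine can self-assemble into amyloid-like fibrils, and
chemical chaperones (osmolytes like DMSO and TMAO, hydrophobic bile acids,
and designed sulfoxide/sulfone derivatives) can inhibit that assembly.
`smaggr` provides the computational side of such a study for structural
bioinformaticians and biophysicists: post-processing of molecular-dynamics
trajectories of self-assembling planar molecules, and quantitative analysis
of plate-reader aggregation kinetics, plus a synthetic-data generator so the
whole pipeline is testable without any simulation or assay data.

## What it computes

**Trajectory arm** (on XYZ or multi-model PDB trajectories with orthorhombic
periodic boxes):

* **Contacts.** Two molecules are in contact when their center-of-mass
  (COM) minimum-image distance is strictly below a cutoff (default 6 Å =
  0.6 nm). Molecules are made whole across the boundary before mass
  weighting. Detection uses a periodic cell list.
* **Aggregates.** Connected components of the contact graph, with size
  histograms per frame.
* **Stacking angles.** For each in-contact pair of planar molecules, the
  acute angle θ = arccos |n₁·n₂| between the unit normals n₁, n₂ of the
  least-squares planes through each molecule's ring atoms (smallest
  principal axis of the centered ring coordinates). θ ≈ 0° means ordered
  π-stacking; the *stacked fraction* is the share of pairs with θ below a
  threshold (default 30°).
* **Hydrogen bonds.** Geometric donor–H···acceptor detection (defaults:
  D–A ≤ 3.5 Å, D–H···A ≥ 120°) and per-acceptor-class *occupancy*: the
  fraction of analyzed configurations containing at least one bond of the
  class.
* **Metatrajectories.** Independent replicas are combined by retaining the
  last *T* ns of each (e.g. 4 × 200 ns → one 800 ns ensemble) before any of
  the above.

**Kinetics arm** (on fluorescence time series, e.g. Thioflavin-T assays):

* Sigmoidal growth fits, `y = baseline + amplitude / (1 + exp(-rate (t -
  t_half)))` (Gompertz optional), with lag time `t_half - 2/rate`.
* Endpoint percent inhibition `100 (1 - treated/control)` at a fixed
  endpoint (default 1000 min), on baseline-subtracted, replicate-averaged,
  linearly interpolated signals.
* The **relative concentration** potency statistic: inhibitor concentration
  divided by percent inhibition — the mM needed per 1 % inhibition; lower is
  more potent. Accelerators (negative inhibition) are flagged, not scored.
* Structure–property association: Spearman rank correlation between
  physicochemical descriptors (MW, logP, logS, HBD, HBA, rings, rotatable
  bonds, TPSA, flexibility) and potency, with permutation p-values.
  Molecular weights are computed from formulas with embedded standard
  atomic weights.

## Worked example

```r
library(smaggr)

pure  <- generate_trajectory(traj_gen_config(n_monomer = 44, n_frames = 50,
                                             stack_angle_sigma = 10, seed = 1))
inhib <- generate_trajectory(traj_gen_config(n_monomer = 40, n_inhibitor = 5,
                                             n_frames = 50, stack_angle_sigma = 10,
                                             hijack_fraction = 0.25,
                                             hbond_plant_rate = 0.06, seed = 2))
rep_pure  <- analyze_trajectory(pure$trajectory)
rep_inhib <- analyze_trajectory(inhib$trajectory)
compare_conditions(rep_pure, rep_inhib)
```

```
Heterogeneity comparison (b - a):
  mean angle:         +9.101 deg
  dispersion (sd):   +16.463 deg
  stacked fraction:   -0.158
  KS statistic:        0.178 (p = 0), n = 1577 vs 1322
  mean aggregate size: 3.531 -> 2.950 (diff -0.581)
```

The inhibitor condition shows the "hijacking" signature: adenine–adenine
stacking angles become larger and more widely distributed (higher
orientational heterogeneity) while aggregates get smaller. The inhibited
report also carries the hydrogen-bond occupancies per acceptor class
(sulfur-bound vs intra-ring oxygens of the inhibitor).

Kinetics and potency:

```r
gk <- generate_kinetics(kinetic_gen_config(doses = c(0.5, 8, 90),
                                           inhibition_map = c(60, 35, 10),
                                           noise_sigma = 20, n_replicates = 3,
                                           seed = 3))
potency_table(gk$curves)[, c("dose", "percent_inhibition", "relative_concentration")]
```

```
  dose percent_inhibition relative_concentration
1  0.5               61.1                0.00818
2  8.0               34.7                0.23055
3 90.0               13.3                6.76888
```

0.5 mM at 61 % inhibition needs ~0.008 mM per 1 % inhibition — the most
potent condition in the panel. `fit_sigmoid()` on the control curve recovers
baseline ≈ 53 a.u., amplitude ≈ 998 a.u., rate ≈ 0.021 /min, t½ ≈ 499 min
(true values 50, 1000, 0.02, 500 under 2 % noise).

A thin command-line front-end with `analyze-traj`, `potency`,
`simulate-traj` and `simulate-kinetics` subcommands is installed at
`inst/cli/smaggr.R`; an example topology configuration is in
`inst/extdata/mock_system.yaml`, and a synthetic descriptor table (real
formulas and counts, placeholder continuous descriptors) in
`inst/extdata/synthetic_dmso_derivatives.csv`.

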
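---
title: "Methods: stacking analysis of self-assembling small molecules and chaperone inhibition kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stacking analysis and inhibition kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smaggr)
```

## The problem

Low-molecular-weight metabolites such as adenine can assemble into ordered,
amyloid-like supramolecular structures. In solution, planar molecules stack
face to face; in simulations of such systems one wants to quantify (i) how
much of the ensemble is aggregated and how large the aggregates are, (ii)
how *ordered* the aggregates are — near-parallel ring planes indicate
π-stacking, broad angle distributions indicate disordered clusters — and
(iii) which specific interactions an inhibitor makes (e.g. hydrogen bonds to
particular acceptor atoms). In vitro, the same assembly process is followed
by dye-binding fluorescence over time, and inhibitors are compared by how
much signal they suppress at a fixed endpoint. `smaggr` implements both
arms as a reusable, tested pipeline.

## Trajectory model and conventions

A *system topology* lists molecular species with per-atom masses, ring-set
membership (the atoms defining the molecular plane) and hydrogen-bond roles.
A *trajectory* is a sequence of frames (coordinates in Å plus an
orthorhombic box); a *metatrajectory* concatenates the retained tails of
independent replicas (`build_metatrajectory()`), discarding each replica's
equilibration phase. A frame at time t is retained when
t > t_end − retain_tail; if the requested tail covers the whole replica, all
frames are kept. Frames are thereafter treated as an unordered ensemble of
configurations, which is why all ensemble statistics here are invariant to
frame and replica order.

Conventions worth stating explicitly:

* **Lengths in Å, times in ns.** The canonical contact cutoff of 0.6 nm is
  stored as 6.0 Å.
* **Minimum image everywhere.** Molecules are made whole across the
  periodic boundary (minimum-image displacement relative to their first
  atom) before the mass-weighted center of mass (COM) is computed; the COM
  is wrapped back into the primary box. COM–COM distances, hydrogen-bond
  distances and angle geometry all use minimum-image displacements. Boxes
  are restricted to orthorhombic — the target systems use cubic boxes, and
  triclinic support is out of scope.
* **Contacts use strict inequality** at the cutoff (`dist < cutoff`). For
  continuous coordinates a tie has probability zero; the choice is purely a
  documented convention.
* **Cell list with brute-force fallback.** Contact detection bins wrapped
  COMs into cells of at least the cutoff width; when a box is too small for
  three cells per edge the code falls back to all-pairs with minimum image.
  The test suite checks the cell list against an independently written
  all-pairs oracle on randomized configurations.
* **Aggregates** are connected components of the undirected contact graph
  (via igraph); the per-frame partition is asserted to cover every molecule
  exactly once.

## Stacking angles

For each molecule with at least three non-collinear ring atoms, the plane
normal is the principal axis of smallest variance of the centered ring
coordinates (SVD). Normals carry no physical sign, so pair angles are folded
axially: θ = arccos |n₁·n₂| ∈ [0°, 90°]; antiparallel normals are parallel
planes. The default histogram uses 18 bins of 5°, and the default *stacked
fraction* threshold is 30° — a conventional π-stacking tolerance; both are
parameters, not science. Under an isotropic orientation model the mean pair
angle is exactly 1 radian ≈ 57.3° (the expectation of arccos |u·v| for
independent uniform axes), a useful closed-form calibration point that the
tests verify by Monte Carlo.

Two dispersion summaries are reported. The sample standard deviation
(`dispersion`) is what the heterogeneity comparison uses. The RMS angle
about perfect alignment (`rms_angle`) is the natural estimator of the
generator's angular-noise scale: the generator tilts molecules by draws from
|N(0, σ)|, and E[θ²] = σ² for that model, so the RMS angle is a consistent
estimator of σ (folding at 90° biases it by under 3 % even at σ = 40°).
`heterogeneity_compare()` reports differences in mean, dispersion and
stacked fraction plus the two-sample Kolmogorov–Smirnov statistic on the raw
angle samples.

## Hydrogen bonds

No universally agreed geometric criterion exists; the package defaults to
the common choice of donor-heavy–acceptor distance ≤ 3.5 Å and
donor–hydrogen–acceptor angle ≥ 120°, fully configurable through
`hbond_criteria()`. *Occupancy* counts frames ("configurations") containing
at least one bond of an acceptor class, not total events — the phrasing used
for sporadic interactions in this field. Species without donor or acceptor
annotations (e.g. purely hydrophobic chaperones) flow through the same
pipeline and simply produce empty event sets and zero-row occupancy tables;
an explicit `require_annotations = TRUE` switch turns that into an error for
workflows where silence would hide a misconfigured topology.

## Kinetics and potency

Aggregation curves are fit by least squares (Levenberg–Marquardt via
minpack.lm) to a logistic sigmoid — the field's default for dye-binding
growth curves — with a Gompertz alternative behind a flag; neither form is
claimed to be mechanistic. Start values come from the signal range and the
25–75 % rise interval; non-convergence returns a flagged fit with
diagnostics rather than an error, and flat curves are flagged with zero
amplitude and undefined lag. The lag time is the tangent construction at the
inflection: t_half − 2/rate (logistic).

Percent inhibition at the endpoint (default 1000 min) is
100 (1 − treated/control) on baseline-subtracted signals; the endpoint value
is linearly interpolated between the bracketing samples, replicates are
averaged before the read, and per-replicate values provide the s.d. The
baseline is the first averaged sample by default (a fitted-baseline option
exists) — the read-out is then invariant to common rescaling of both curves.
Negative inhibition (acceleration) is allowed and propagates with its sign.
The *relative concentration* is concentration divided by percent inhibition
(mM per 1 % inhibition; lower = more potent); for non-positive inhibition it
is undefined and the compound is flagged a non-inhibitor rather than given a
number.

For structure–property association, descriptors other than molecular weight
are consumed from an input table (they come from external prediction
software in practice); only molecular weight is computed, from formulas and
embedded standard atomic weights. Potency enters as −log(relative
concentration) so that positive Spearman coefficients read "more of this
property, more potent". Significance uses a permutation null (shuffled
potency labels, fixed seed) rather than the asymptotic t approximation,
which is unreliable at panel sizes of 5–10 compounds. Compounds without a
defined relative concentration (accelerators) are excluded from the
association and listed separately. The bundled
`synthetic_dmso_derivatives.csv` carries real formulas and counting
descriptors but synthetic continuous descriptors, and is labelled as such.

## The synthetic-data generator

The generator exists so that every analysis stage can be validated against
known ground truth; it emulates the *statistical structure* the analysis
assumes, not molecular physics. Defaults mirror the study conditions this
package targets: 44 monomers (or 40 plus 5 inhibitors) in a 100 Å cubic box,
3.4 Å stacking rise.

* **Mock geometry.** The monomer is a rigid 9-atom ring (regular 9-gon of
  radius 1.4 Å with purine-like N/C masses) plus an exocyclic donor nitrogen
  and polar hydrogen; the inhibitor is a mock six-membered sulfur/oxygen
  ring with two sulfur-bound and one intra-ring acceptor oxygens. Fidelity
  to real adenine geometry is deliberately not attempted — plane fitting,
  COM contacts and hydrogen-bond geometry do not require it.
* **Stacks.** Molecules sit on a random axis at the configured rise with
  COMs exactly on-axis, so adjacent neighbours are in contact and second
  neighbours are not (the rise is validated to keep 2 × rise outside the
  6 Å cutoff). Within a stack, odd-indexed molecules align exactly with the
  axis and even-indexed ones are tilted by draws from |N(0, σ)| about random
  in-plane axes: every adjacent pair consists of one aligned and one tilted
  molecule, so each pair's true angle *equals its drawn perturbation* and is
  recorded in the truth log. Stack sizes are Poisson draws truncated to 1–6
  (size-1 draws become free monomers); the cap keeps the placement lattice
  (below) feasible at the default box size.
* **Hijacked pairs.** A configurable fraction of monomers is placed in
  inhibitor-capped pairs: two monomers in contact at 5 Å with independent
  isotropic orientations, plus an inhibitor 4 Å from one of them,
  perpendicular to the pair axis. This is what makes the inhibited
  condition's monomer–monomer angle distribution broader and its aggregates
  smaller. In the hijack-everything limit the monomer angle statistics
  approach the isotropic law (mean 57.3°, stacked fraction ≈ 1 − cos 30° ≈
  0.13 — low, but not zero, since isotropic pairs occasionally align).
* **Placement.** Units (stacks, pairs, free molecules) are placed on a
  randomly assigned, slightly jittered lattice whose spacing guarantees
  inter-unit COM separation beyond the 6 Å cutoff, with margins that keep
  every atom inside the primary box. This emulates separated nucleation
  clusters, not liquid structure — convenient because the ground-truth
  contact graph is then exactly the constructed one. Overcrowding (more
  units than lattice sites) is an error suggesting a larger box.
* **Hydrogen-bond planting.** In a configured fraction of frames the
  inhibitor's intra-ring oxygen is placed on a donor N–H axis at 2.9 Å
  (D–H···A = 180°), guaranteeing one event of that class; in all other
  frames inhibitor orientations are rejection-sampled so the intra-ring
  oxygen stays beyond 3.9 Å of every donor — outside the default 3.5 Å
  criterion with margin. Planted occupancy is therefore exactly recoverable,
  and the sulfur-bound class remains free to occur naturally. Recovery
  guarantees assume criteria no looser than ~3.9 Å.
* **Seeding.** A master seed spawns an independent substream per frame (and
  per curve in the kinetics generator), so regeneration is byte-identical
  and stable under partial regeneration.
* **Kinetics.** Control curves are logistic with configurable baseline,
  amplitude, rate and t½ (defaults 50 a.u., 1000 a.u., 0.02 /min, 500 min
  over 0–1500 min sampled every 10 min); each dose scales the amplitude by
  1 − inhibition/100, so the true endpoint inhibition is recovered exactly
  in the noiseless limit; Gaussian noise is added per point.

**What passing tests do and do not show.** Because frames are independent
and units are well separated, the generator exercises the geometry,
graph and statistics of the analysis exhaustively — but it says nothing
about correlated dynamics, diffuse contacts near the cutoff, solvent, or
real adenine energetics. Agreement on synthetic data validates the
*implementation*, not any simulation result.

## Numerical choices and degenerate inputs

* Plane fits reject collinear/degenerate ring sets (second singular value
  below 1e−8 of the first) and require ≥ 3 ring atoms.
* `pair_angle()` rejects zero vectors; dot products are clamped to [−1, 1]
  before arccos.
* A contact cutoff at or above half the smallest box edge is an error
  (minimum image undefined).
* An angle request with no contacts anywhere returns an `empty`-flagged
  distribution, not an exception; comparing with an empty distribution is an
  error.
* XYZ files carry `box=…`, `time=…`, `replica=…` tokens on the comment line;
  files without them fall back to the topology's box and uniform time
  spacing. PDB uses `CRYST1` and `MODEL`/`ENDMDL`; a truncated frame is a
  format error that names the frame and preserves the count of complete
  frames in the message.
* Replicas passed to `build_metatrajectory()` with colliding labels are
  renamed `r1..rK` to keep per-replica identity in the combined ensemble.

## Problem sizes used in the shipped checks

The validation suite and `scripts/acceptance.R` run metatrajectories of 500
frames (4 replicas × 125, or 4 × 50 in the script) of the 44-molecule
system for angular-noise recovery at σ ∈ {5°, 20°, 40°}, 500 frames of the
40 + 5 system for the 6 % planted-occupancy recovery, 100-case randomized
oracle comparisons (≤ 30 molecules), and 20-seed kinetics panels with noise
at 5 % of the amplitude and triplicate curves. These sizes give a few
thousand angle samples per condition and binomial standard errors near 1 %
on occupancy — comfortably sufficient for the 10–20 % tolerances tested,
while keeping a full run in the tens of seconds.

## Known limitations

Orthorhombic boxes only; no binary trajectory formats (DCD/XTC) — convert
to XYZ/PDB upstream; H-bond detection is geometric, not energetic;
descriptor prediction (logP/logS/TPSA) is out of scope; the logistic/Gompertz
forms are phenomenological; and the generator's independent-frame,
separated-cluster design intentionally does not reproduce liquid-state
contact statistics.
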
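---
title: "Quantifying annular lipid organization and dynamics around a membrane protein"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying annular lipid organization and dynamics around a membrane protein}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(annulipid)
```

## The scientific problem

A transmembrane protein does not sit in a passive lipid sea.  Preferential
interactions with particular species — anionic phosphatidylserine attracted
to basic residues, cholesterol packing against the transmembrane helices —
reorganize the bilayer locally, and the same contacts slow the lateral
diffusion of the lipids immediately around the protein (the "annular"
lipids).  Coarse-grained molecular dynamics of receptors in plasma-membrane
mimics (mixed POPC/POPS/POPE/sphingomyelin/cholesterol bilayers, patches of
roughly 19 × 19 nm, microsecond timescales) resolves these effects, but only
if the post-processing is done carefully: leaflets must be told apart,
cholesterol migrates between them, density maps need a defensible
normalization, and a diffusion coefficient measured "near the protein" needs
an explicit windowing convention.

`annulipid` implements that post-processing as a tested, reusable toolchain:

* per-leaflet, protein-centred 2D headgroup **density maps**;
* lateral **radial distribution functions** g(r) around the TM region;
* **annulus-resolved lateral diffusion** D(r, Δt) with block-averaged errors;
* per-residue **protein–lipid contact** tables, mapped onto structures;
* **cholesterol flip-flop** detection and leaflet accounting;
* a Brownian-dynamics **synthetic membrane generator** whose every parameter
  is ground truth for the estimators above.

## The estimators

### Reference frame

All lateral quantities are measured from the per-frame lateral centre of
mass of a protein selection, by convention the transmembrane region (the
ectodomain of a receptor sways far from the bilayer and would drag the
reference point around).  The centre is computed with the circular-mean
construction so a protein straddling the periodic boundary is handled
exactly.  The bilayer midplane is the mean z of all lipid reference beads —
never of the protein — so leaflet assignment cannot be biased by the
protein's vertical position.  Each lipid is represented by one reference
bead: the phosphate for phospholipids and sphingomyelin, the hydroxyl (ROH)
bead for cholesterol.

Coordinates are treated as wrapped; every displacement uses the minimum
image.  This is valid because the frame spacing is far below the box
traversal time, which `msd_lateral()` asserts by checking that no particle
moves more than L/4 between consecutive frames.  Only orthorhombic boxes
are supported; triclinic input is rejected explicitly.

### Density maps

`density_map_2d()` histograms reference-bead positions in the
protein-centred frame (the map is translated each frame so the protein is
at the origin; in a lab-fixed frame a drifting protein would smear its own
lipid ring into invisibility).  Counts are divided by bin area × number of
frames × number of lipids of that species in the leaflet.  The lipid count
uses the **last-frame** leaflet populations: for species that never change
leaflet this equals the fixed composition and the map integrates to exactly
1 over the box; for cholesterol, whose per-leaflet population drifts by
flip-flop, the last-frame count is the one well-defined choice, and the map
then integrates to (time-mean count)/(last-frame count) — a documented,
exactly testable identity rather than an approximation.

### Lateral RDFs

`rdf_lateral()` bins reference beads into radial shells around the protein
centre (default width 0.2 nm).  Shell areas are corrected analytically for
the part of a shell that leaves the periodic box, so shells out to the box
half-diagonal conserve every bead.  The bulk density divides the species
count by the box area **minus the protein cross-section**; without that
correction g(r) cannot plateau at 1 in an obstructed box.  Cholesterol must
be analysed over the whole bilayer — a per-leaflet cholesterol RDF is
refused — because flip-flop makes per-leaflet populations ill-defined over
a long trajectory.

Two subtleties that surface in validation and are worth knowing about:

* In a system with an attractive well, the *far-field* g sits slightly
  below 1, by exactly the factor that the well-bound excess contributes to
  the bulk normalization (≈ 0.92 for a 1 kT, 2 nm well in a 19 nm box).
  This is a property of the normalization, not an error.
* The distance axis is the distance to the TM centre of mass, matching the
  diffusion profiles, so density and mobility can be read off a shared
  axis.  A per-bead minimum-distance convention would shift features by
  roughly the protein radius but is not implemented.

### Annulus-resolved diffusion

The central analysis.  The 2D Einstein relation D(Δt) = MSD(Δt)/(4Δt) is
evaluated on a grid of timescales (default {1, 2, 4, 6, 10, 20} ns, with
6 ns the conventional reporting point) to separate short-time caged motion
from long-time transport; displacement windows may overlap (origin stride
of 1 frame by default) since error bars come from block averaging, not from
a naive per-window standard error.

For the radial profile, the space around the protein is divided into
annuli of width 1 nm — annulus 0 spans 0–1 nm — and every window is
assigned to **the annulus containing the lipid at the window's start
frame**.  The start-frame rule is one of several defensible conventions
(midpoint, both-endpoints-inside); it is the only one that never discards a
window and that the generator's ground truth can reproduce exactly, which
is why it is the implemented one.  Leaflet-resolved profiles likewise
evaluate leaflet membership at the window start.  Annuli with zero
observations report a missing value, never 0.

`d_ratio_profile()` divides by a bulk value, the observation-weighted mean
D over all annuli whose inner edge is ≥ 5 nm from the protein — the
far-field plateau.  `block_errors()` recomputes any analysis on equal
contiguous sub-trajectories (five by convention, e.g. 5 × 2 μs for a 10 μs
run) and reports the across-block **population** standard deviation; the
same n-denominator convention is used for cross-system contact errors.

### Contacts

A residue–lipid contact is counted at most once per (residue, molecule,
frame), however many bead pairs fall inside the cutoff — this prevents
species with more beads from inflating their counts.  The cutoff is a free
parameter (0.6 nm default, common coarse-grained practice) recorded in the
output.  Normalization divides by the single global maximum across the
whole complex, so exactly one residue maps to 1.0; `map_contacts_to_structure()`
writes the values into PDB B-factors for blue–white–red rendering.

### Cholesterol flip-flop

Leaflet labels follow the reference bead's side of the midplane, with beads
exactly on the midplane deterministically assigned to the inner leaflet.  A
flip is confirmed only when the new label persists for `min_dwell` frames
(default 10), suppressing midplane-crossing chatter.  What constitutes a
"completed" flip is genuinely underdetermined; the dwell rule is this
package's operationalization.  Hysteresis censors genuine flips that are
undone within the dwell window (both events vanish), deflating the raw
count by ≈ exp(−2 r τ) for true rate r and dwell time τ; `detect_flipflops()`
reports both the raw rate and the censoring-corrected rate (the fixed point
of r = r_raw · e^{2rτ}).  The corrected estimator is unbiased on synthetic
data, which the suite verifies across seeds.

## The synthetic membrane generator

`simulate_membrane()` produces the ground-truth data every estimator is
validated against.  Each lipid is a single reference bead performing
overdamped 2D Brownian motion in its leaflet plane inside a periodic
~19 × 19 nm patch:

* Gaussian proposals with per-axis variance 2 D(r) dt, with D a per-species
  piecewise-constant radial profile evaluated at the step start (Itô
  convention, no drift correction);
* radial reflection at a static disc of radius 0.5 nm at the box centre
  (the protein cross-section; the static-obstacle idealization is exact up
  to a frame change, since all analyses are computed relative to the
  protein centre anyway);
* Metropolis acceptance against a per-species radial square well (the
  enrichment potential), so the stationary density obeys the Boltzmann
  factor exactly where D is uniform;
* Poisson leaflet exchange at a per-species rate, every event logged;
* initial positions drawn from the analytic stationary density of the
  well, so no burn-in is needed.

The protein obstacle is marked by a ring of static beads, three per ring
position (outer-leaflet plane, midplane, inner-leaflet plane) sharing one
residue id, so contact analyses see a transmembrane span.

Defaults are chosen once to emulate the conditions of the study systems:
`preset_bilayer()` carries the post-insertion compositions of the three
model bilayers (asymmetric plasma-membrane mimic and its two symmetric
counterparts, 1297 lipids in the asymmetric patch), bulk diffusivities of
order 0.01 nm²/ns ≡ 1 × 10⁻⁷ cm²/s, a slowed annulus within 2.5 nm of the
protein surface with species-dependent factors (strongest for PS, ≈ 0.5),
a 1 kT / 2 nm PS well, a weaker 0.7 kT / 1 nm cholesterol well, and a
cholesterol flip rate of 10⁻³ ns⁻¹.  The integration step is 0.05 ns with
20 steps per stored frame (1 ns/frame); the constructor rejects any spec
whose rms substep exceeds 20 % of the narrowest radial feature, which
bounds discretization bias at radial boundaries.

Two deliberate idealizations deserve emphasis:

* **Itô piecewise diffusivity.**  With D evaluated at the step start and no
  drift correction, the stationary density in a region of reduced D is
  elevated by ≈ D_bulk/D_slow.  The spurious-drift term is zero almost
  everywhere for piecewise-constant profiles, and the annular estimator
  under test uses the same start-point convention, so ground truth and
  estimate agree by construction; but where a well and a D-step coexist,
  the realized enrichment exceeds the bare Boltzmann factor.  Calibration
  checks of the Boltzmann oracle therefore use uniform-D systems.
* **Flat leaflets.**  Leaflet planes carry no undulations, so leaflet
  assignment and flip detection can be validated against unambiguous
  truth.  Real bilayers undulate; passing these tests demonstrates
  correctness of the accounting, not robustness to curvature (a
  local-normal assignment is out of scope).

What the generator reproduces of real CG trajectories: the statistical
structure the analyses rest on (species- and position-dependent lateral
mobility, radial enrichment, leaflet exchange, periodic geometry, a
protein-excluded region).  What it does not: lipid–lipid interactions and
collective flows, lipid tails and entanglement, membrane curvature, protein
conformational dynamics, and any force-field physics.  Green tests certify
the estimators; they do not certify CG-MD itself.

## Validation strategy and numerical choices

Every estimator is checked three ways: exact brute-force oracles on
hand-built toys of a few frames (MSD window enumeration, pairwise contact
enumeration, centre-of-mass arithmetic, block-SD arithmetic); closed-form
statistical oracles on purpose-built synthetic systems (the Einstein
relation recovered within 2 % on a uniform-D membrane of 500 lipids ×
10⁴ frames; a two-level D(r) recovered in place within 10 %; square-well
enrichment matching e^depth; flip rates inside the 95 % Poisson interval
across seeds); and cross-consistency (radially averaged density maps
reproduce g(r) × bulk; leaflet-resolved window counts add up to the
whole-bilayer count; shell counts integrate to the species total).

Statistical checks respect two facts worth recording.  First, ideal-gas
density modes on the box scale decay over L²/4D (thousands of ns), so
time-block standard errors of g(r) from one run understate the truth; the
flatness calibration therefore uses independent replicate generations for
its standard errors.  Second, per-shell 3-SE checks across ~65 shells must
tolerate the occasional multiplicity exceedance; the suite allows isolated
ones and bounds their size.  Block-SD error bars, by contrast, estimate the
spread of a *single* sub-trajectory, several times the standard error of
the full-trajectory mean, so "within 3 block SDs" null checks are
conservative by construction.

Problem sizes in the suite were chosen so sampling error sits comfortably
below each tolerance: 10⁴-frame, 500–900-lipid runs for the diffusion
recoveries, 6 × 10³-frame runs for the RDF calibrations, ten replicate
10⁴-frame runs for flip-rate coverage.  The full suite and the acceptance
script each complete in a few minutes on one CPU.

Degenerate inputs have defined behaviour: a lipid exactly on the midplane
is inner; an annulus with no observations is missing, not zero; an all-zero
contact table normalizes to zeros with a warning; a frame with every lipid
on one side of the midplane warns but does not abort; zero-lipid topologies
and unmapped residue names abort with the offending names listed.

## Worked example

```{r demo, eval = FALSE}
library(annulipid)

# generate the asymmetric plasma-membrane mimic and run every analysis
demo <- demo_end_to_end(seed = 1, n_frames = 1500)
print(demo$summary, digits = 3)
#>   species first_shell_g annulus0_ratio n_flips
#> 1    CHOL          1.68          0.572     484
#> 2    POPC          1.49          0.617       0
#> 3    POPE          1.06          0.559       0
#> 4    POPS          3.63          0.485       0
#> 5      SM          1.01          0.634       0
```

(Numbers vary slightly with seed and length; the PS row shows the joint
fingerprint of binding — first-shell enrichment above every other
phospholipid together with the deepest diffusion slow-down, and only
cholesterol exchanges leaflets.)  The same pipeline runs on real data via
`run_all()` with a file-based config (GRO/PDB topology + DCD trajectory),
and each stage is available as a standalone function.

## Known limitations

* Trajectory input is GRO/PDB + DCD; compressed GROMACS formats (XTC/TRR)
  have no reader in this toolchain and must be converted upstream.
* The RDF/diffusion distance axis uses the TM centre of mass, not the
  minimum distance to the protein surface; features for elongated proteins
  are smeared accordingly.
* No curvature-aware leaflet assignment, no anomalous-diffusion exponents,
  no residence-time kinetics, no interaction energies.
* Whether sub-trajectory blocks should overlap is unspecified in common
  practice; blocks here are contiguous and non-overlapping.
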
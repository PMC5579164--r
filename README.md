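# annulipid

Quantify how a membrane protein reshapes its local lipid environment in
coarse-grained bilayer simulations.

Transmembrane receptors reorganize the lipids around them: anionic lipids
such as POPS cluster against basic residues, cholesterol packs near the
transmembrane helices, and the lipids in the first "annular" shell diffuse
markedly slower than the bulk.  `annulipid` is an R toolchain for measuring
exactly that from trajectories of a protein in a mixed
POPC/POPS/POPE/sphingomyelin/cholesterol patch (or any similar system):

* **2D density maps** — protein-centred, per-leaflet headgroup histograms,
  normalized by bin area × frames × leaflet lipid count (last-frame counts
  for cholesterol, which flip-flops between leaflets);
* **lateral RDFs** — g(r) of each species around the TM region, with
  periodic-box shell-area corrections and a bulk density that excludes the
  protein cross-section;
* **annulus-resolved diffusion** — the 2D Einstein relation
  D(Δt) = MSD(Δt)/(4Δt) evaluated per 1-nm annulus around the protein
  (windows assigned by their start-frame position), with D(r)/D_bulk
  ratios against the ≥ 5 nm plateau and block (sub-trajectory) error bars;
* **contacts** — one contact per residue/lipid/frame within a cutoff,
  globally max-normalized, cross-system SDs, and PDB B-factor structure
  mapping;
* **cholesterol flip-flop** — hysteresis-based event detection with a
  censoring-corrected rate estimator, plus per-leaflet counts under
  per-frame or last-frame policies;
* **synthetic membranes** — a Brownian-dynamics generator of two-leaflet
  periodic patches with known ground truth (piecewise D(r), radial
  enrichment wells, Poisson leaflet exchange, a reflective protein disc)
  that backs every estimator with closed-form oracles.

Inputs are GRO or PDB topologies plus DCD trajectories (`load_trajectory()`),
or generated membranes (`preset_bilayer()` carries the compositions of a
~19 × 19 nm asymmetric plasma-membrane mimic and its two symmetric
counterparts).  Internal units are nm/ns; diffusion coefficients are also
reported in cm²/s (1 nm²/ns = 10⁻⁵ cm²/s).

## Worked example

```r
library(annulipid)

# generate the asymmetric plasma-membrane mimic (1297 lipids, 1 ns/frame),
# run every analysis stage, and summarize the protein's lipid fingerprint
demo <- demo_end_to_end(seed = 1, n_frames = 1500)
print(demo$summary, digits = 3)
#>   species first_shell_g annulus0_ratio n_flips
#> 1    CHOL          1.68          0.572     484
#> 2    POPC          1.49          0.617       0
#> 3    POPE          1.06          0.559       0
#> 4    POPS          3.63          0.485       0
#> 5      SM          1.01          0.634       0
```

Reading the table: `first_shell_g` is the mean radial-distribution value
within 0.5–2 nm of the protein centre — POPS is strongly enriched (its
attractive well), SM and POPE are near 1 (indifferent).  `annulus0_ratio`
is D(0–1 nm)/D_bulk at Δt = 2 ns — every species is slowed near the
protein, POPS most (≈ 0.49).  Only cholesterol exchanges leaflets
(`n_flips`).  The run directory holds the full per-stage CSV/PDB outputs
(density grids, RDF curves, diffusion profiles with block SDs, contact
tables, flip events) and a manifest recording every effective parameter.

The same pipeline runs on files:

```r
run_all(list(
  input = list(topology = "system.gro", trajectory = "traj.dcd",
               dt_frame = 1),
  protein_tm = 1:24,          # TM residue ids for the reference centre
  out_dir = "results"
))
```

A thin CLI (`inst/scripts/annulipid`) exposes `synth`, `run-all` and `demo`
subcommands.

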
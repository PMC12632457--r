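# periloc

Quantitative pipeline for studying the subnuclear position and genetic
stability of repetitive gene loci — the kind of question asked of the
fission-yeast flocculin-like (*pfl*) genes, whose tandem intragenic repeats
sit at the nuclear periphery and recombine when untethered. The package is
aimed at cell biologists who image a lacO/lacI-GFP-tagged locus together
with a nuclear-envelope marker and want the whole measurement chain —
images to depth statistics to rate tables — reproducible and testable.

Five analysis layers, each exposed as plain functions returning classed S3
objects:

* **Spot localization** — maximum projection, robust candidate detection,
  and least-squares fitting of an axis-aligned 3D Gaussian
  `B + A·exp(−((x−x₀)²+(y−y₀)²)/2σ²xy − (z−z₀)²/2σ²z)` for sub-voxel locus
  positions (`localize_spots()`).
* **Envelope reconstruction** — an icosphere deformed to minimize
  `E = λ_b·Σ_v ‖v − mean(N(v))‖²/h² − λ_i·mean(Î(v))` (umbrella bending +
  image attraction), yielding a closed triangulated surface, nuclear volume
  and effective radius `R_eff = (3V/4π)^{1/3}` (`reconstruct_nucleus()`).
* **Radial density** — per-cell scaled depth `s = d/R_eff` (distance to the
  nearest surface point over effective radius) pooled into shells of width
  `w = 0.1`, with density `f = p/(4πr²w)`, `r = 1 − s`, and Poisson error
  `σ_f = √c/(N·4πr²w)` (`cohort_density()`, `radial_density()`).
* **Genomic proximity** — exact nearest-peak body-to-body distances and the
  fraction of features with a peak within a threshold (default 600 bp,
  inclusive; `proximity_fraction()`).
* **Fluctuation-assay rates** — per-cell event frequency
  `(c_sel/d_sel)/(c_perm/d_perm)` from selective/permissive plating counts,
  fold change versus the wild-type mean and its natural log
  (`rate_from_plating()`, `fold_change_ln()`).

A seeded synthetic generator (`render_nucleus_stack()`,
`sample_locus_positions()`, `make_interval_fixture()`,
`make_colony_fixture()`) produces ground-truthed stacks, interval sets and
plating tables so every stage is verified end to end without external data.
I/O covers multi-page 16-bit TIFF (+ JSON voxel sidecar), BED/GFF3
(converted to 0-based half-open internally), CSV tables, ASCII PLY meshes
and a JSON run manifest. `run_pipeline()` (or the thin `exec/periloc` CLI)
orchestrates the stages from a YAML config with fully derived seeds.

## Worked example

```r
library(periloc)

# one synthetic cell: nucleus R = 1.4 um, locus at scaled depth 0.3
sc <- synthetic_scene(nucleus_radii = c(1.4, 1.4, 1.4),
                      spot_scaled_depth = 0.3, seed = 42)
cell <- render_nucleus_stack(sc)

spot <- localize_spots(cell$stack)[[1]]
nuc  <- reconstruct_nucleus(cell$stack)
print(nuc)
#> nucleus_model: volume 10.999 um^3, effective radius 1.380 um
#>   center (3.409, 3.413, 5.199) um; 332 descent iterations; converged: TRUE
scaled_depth(spot, nuc)
#>           s distance_um exterior
#> 1 0.2856028   0.3940201    FALSE
cell$truth$true_scaled_depth
#> [1] 0.3
```

The reconstructed volume sits ~4 % below the analytic 11.494 µm³ (the
faceting bias of a 642-vertex mesh, documented in the vignette), and the
locus depth is recovered to ~0.014 of the nuclear radius. A cohort-level
run, pooling 200 such cells into the shell density with error bars, is one
call: `run_pipeline(pipeline_config(n_cells = 200, cohort = "uniform"))`.

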
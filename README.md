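# spinenano

Nanoscale organization analysis of synaptic protein clusters in dendritic
spines, for R.

Glutamatergic synapses are built from discrete, sub-diffraction clusters
("nanomodules") of scaffolding proteins and receptors. With STED
nanoscopy (~50 nm lateral resolution, 23–25 nm pixels, 150 nm z-steps)
these clusters can be segmented per channel, assigned to individual
GFP-filled spine heads, classified as synaptic or non-synaptic, and
related to spine size and to each other by 3D center-to-center distance.
spinenano implements that whole workflow as reusable, deterministic R
code, together with a ground-truthed synthetic scene generator so every
stage is testable without microscopy data.

For image analysts and synaptic physiologists, the package provides:

* **Spine masking** — Gaussian blur (σ = 2 px) of the cell-fill channel,
  global mean + 2 SD threshold, per-section components linked across z;
  head area from the maximal-area section.
* **Two independent nanocluster segmenters** — a threshold path
  (per-section local mean + 2 SD over 50 × 50 px windows, 8-connected
  components, 10–100 px / 0.002–0.15 µm² size filters, valley-based
  splitting of touching clusters at mean + 1.5 SD) and a seeded path
  (3D local maxima in a 3 px XY / 2-section z ellipsoid, simultaneous
  region growing with per-seed thresholds in the 10 000–20 000 AU range,
  8 px max radius, 3–20 000 voxel bounds).
* **Synapse assembly** — postsynaptic clusters assigned when entirely
  within the spine-head ROI in every occupied section, presynaptic when
  partially overlapping; mutual-nearest-neighbor juxtaposition pairing;
  receptor clusters synaptic iff colocalized with a juxtaposed scaffold
  cluster.
* **Distance metrics** — 3D center-to-center distances on physical nm
  coordinates (nearest-neighbor and colocalized-only modes), plus FWHM,
  bead peak-to-peak and chromatic-offset calibration operators.
* **Statistics** — Gaussian count-distribution fits with the extra
  sum-of-squares F test (and a calibrated multinomial LRT alternative),
  count-vs-area scaling regression, one-way ANCOVA on slopes,
  Kolmogorov–Smirnov and ANOVA/Tukey comparisons, the multivariable
  spine-size regression `area ~ n_A + n_B`, and the chemical-LTP
  potentiation classifier (sustained ≥10% area increase over baseline).

The statistical core in the field's notation: per-spine cluster count
*N* scales with head area *A* as *N = βA + ε* with β ≈ 2.3 clusters/µm²;
group differences in scaling are tested by the homogeneity-of-slopes
interaction in *N ~ A × group*; sub-synaptic positioning is summarized
by the 3D distance *d = ‖c₁ − c₂‖* between intensity-weighted cluster
centroids *c* in nm.

## Worked example

```r
library(spinenano)

# a ground-truthed synthetic field: 6 spines, 4 channels, 25 nm pixels
spec <- scene_spec(field_size_px = c(320L, 320L), n_sections = 9L,
                   n_spines = 6L, seed = 3)
scene <- generate_scene(spec)

res <- analyze_stack(scene$stack, default_config(),
                     rois = roi_from_truth(scene$truth, scene$stack))
res$records
#>   spine_id head_area_um2 n_PSD95 n_Bassoon n_GluA2 n_GluA2_nonsyn
#> 1        1     0.3709113       1         1       1              0
#> 2        2     0.5183583       3         3       3              0
#> 3        3     0.6828832       2         1       1              1
#> 4        4     0.3372632       2         2       1              0
#> 5        5     0.6617058       2         1       1              1
#> 6        6     0.6091056       2         2       1              1

fit <- scaling_regression(res$records$head_area_um2, res$records$n_PSD95)
round(c(slope = fit$slope, r_squared = fit$r_squared), 4)
#>     slope r_squared
#>    1.3457    0.0992

head(res$distances[["PSD95-GluA2"]], 4)
#>   id_a id_b distance_nm         relation
#> 1    3    6    181.3413 colocalized_only
#> 2    5    3    195.5499 colocalized_only
#> 3    5   11    215.4385 colocalized_only
#> 4    7    5    174.7085 colocalized_only
```

Each spine-record row is one spine: its head area (µm², maximal-area
section) and per-channel counts of synaptic (and for receptors,
non-synaptic) clusters. The scaling fit is the clusters-per-µm² slope —
noisy at n = 6 as here, while the validation battery recovers the planted
2.3 clusters/µm² within 10% over 200 spines. The distance table holds 3D
center-to-center distances (nm) between synaptic receptor clusters and
their colocalized scaffold clusters — planted here at 150–200 nm lateral
offsets and recovered within a few nm.

A command-line runner wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/spinenano.R", package="spinenano"))') \
    simulate --seed 7 --out scenes/
```

with subcommands `simulate`, `analyze`, `calibrate` and `report`.

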
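# punctaflux

Quantification of basal and damage-induced autophagic/mitophagic flux
from tandem-fluorescent LC3 (GFP/mRFP) confocal microscopy.

The tfLC3 reporter marks neutral-pH autophagosomes as puncta positive in
*both* the GFP and mRFP channels (GFP is quenched and degraded in acidic
autophagolysosomes, mRFP persists). Counting dual-positive puncta per
cell under lysosomal blockade (bafilomycin A1), and counting how many
lie at mitochondria, measures autophagic flux and mitophagy — but LC3
puncta must first be separated from a bright, diffuse cytosolic LC3
background that varies across channels, cells and time. punctaflux is an
R implementation of that whole measurement chain, for cell biologists
and imaging analysts working with tfLC3 (or similar punctate reporters)
in fixed cells or live time-lapse series.

## What it computes

- **Adaptive spot detection** — scale-normalized Laplacian-of-Gaussian
  filtering (σ = 3 px at 56.6 nm pixels) thresholded at μ + *z*·σ of the
  response over the cell; the *z*-score form makes detection invariant
  to affine intensity rescaling. Sub-resolution objects (≤ 25 px fixed,
  ≤ 4 px live) are removed. `detect_puncta()`, `autotune_detect()`.
- **Dual puncta** — GFP and mRFP objects sharing ≥ 1 pixel are merged
  (union) into one autophagosome; one-to-many overlaps resolve as
  connected components of the bipartite overlap graph.
  `build_dual_puncta()`.
- **Mitochondria association** — nearest-edge Euclidean distance;
  puncta within 5 px (≈ 250 nm resolution limit, inclusive) of a
  mitochondrial segment count as associated. `associate_with_mito()`.
- **Automated live-cell masks** — 90th-percentile suppression, median
  cascade (3/5/9), largest component, 4 × 2 px dilation + closing, with
  cross-channel consistency and border-rejection checks.
  `auto_cell_mask()`.
- **Live-cell QC filters** — Cohen's *d* ≥ 0 vs the cell, peak above the
  cell's Q3 + 1.5·IQR fence, area > 4 px. `apply_qc()`.
- **Potential ratios** — mean mitochondrial-dye intensity under each
  autophagosome relative to its adjacent segment and to all segments in
  the cell (< 1: fainter/lower-potential than average), pooled per cell
  as boxplot statistics. `compute_ratios()`, `summarize_ratios()`.
- **z sensitivity study** — per-cell counts across a *z* grid, pairwise
  Kruskal–Wallis tests per condition pair × cell line × *z*, Bonferroni
  correction over the full grid (reference design: m = 6 × 2 × 21 = 252,
  corrected α = 0.05/252). `run_sweep()`.
- **Synthetic microscopy** — ground-truthed scenes and drifting
  time-lapse movies (cell, cytosolic background, Gaussian puncta,
  tubular mitochondria with per-segment potential, Poisson + read
  noise), so the entire pipeline is testable without real data.
  `simulate_scene()`, `simulate_timelapse()`.

Results are tibbles designed for dplyr/ggplot2 workflows; fitted sweep
objects support `tidy()`, `glance()` and `autoplot()`. A thin CLI
(`inst/exec/punctaflux`, subcommands `simulate`, `detect`, `segment`,
`qc`, `associate`, `ratio`, `sweep`, `run`) wraps the same functions for
shell use on TIFF stacks.

## Worked example

Simulate one cell (10 dual puncta, half placed on mitochondria), then
run the fixed-cell pipeline against its mask:

```r
library(punctaflux)

sim <- simulate_scene(scene_spec(seed = 42))
cm  <- auto_cell_mask(sim$scene)
res <- run_pipeline(
  list(scene = list(sim$scene), roi = list(cm$mask), condition = "BafA1"),
  pipeline_config("fixed_cell"))
tidy(res)
#> # A tibble: 1 × 9
#>   cell_id condition cell_line timepoint n_gfp n_rfp n_dual n_dual_near_mito
#> 1 cell_1  BafA1     <NA>             NA    15    15     10                5
glance(res)
#> # A tibble: 1 × 5
#>   n_cells n_frames n_skipped mean_n_dual mean_fraction_near_mito
#> 1       1        1         0          10                     0.5
```

The default scene carries 10 dual + 5 GFP-only + 5 mRFP-only puncta:
the detector finds all 15 objects per channel, the overlap stage
recovers exactly the 10 dual puncta, and the association stage finds the
5 that were placed on mitochondrial segments (edge distance 0 in
`res$association`; the others sit 15–35 px away, beyond the 5 px
cutoff). `fraction_near_mito = 0.5` is the per-cell mitophagy-proximity
readout.

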
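---
title: "Quantifying mitophagic flux from tandem-fluorescent LC3 imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mitophagic flux from tandem-fluorescent LC3 imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(punctaflux)
```

## The measurement problem

The tandem-fluorescent LC3 reporter (tfLC3) fuses LC3 to both GFP and
mRFP. GFP fluorescence is quenched and degraded in acidic
autophagolysosomes while mRFP persists, so puncta positive in *both*
channels mark neutral-pH autophagosomes. When lysosomal acidification is
blocked (bafilomycin A1), dual-positive puncta accumulate at a rate set
by autophagic flux; counting them per cell — and counting how many sit at
mitochondria — turns confocal images into a flux and mitophagy readout.
The difficulty is that LC3 is largely cytosolic: puncta must be separated
from a bright, noisy, diffuse background that varies between channels,
cells and timepoints.

punctaflux implements the full quantification chain: adaptive spot
detection, dual-channel overlap, mitochondria association,
automated single-cell masking with object-level false-positive filters, a
mitochondrial-potential ratio statistic, and a threshold sensitivity
study with multiple-testing-corrected nonparametric tests. A synthetic
microscopy module generates ground-truthed scenes so that every stage is
testable without real data.

## Spot detection model

A frame is filtered with a negated, scale-normalized
Laplacian-of-Gaussian,

$$R = -\sigma^2\, (\nabla^2 G_\sigma) * I,$$

so bright blobs of scale $\sigma$ become positive response peaks. The
default $\sigma$ = 3 px is half the ~6 px (2 × 56.6 nm pixels per
precision unit, rounded) system precision; with matched scale a Gaussian
spot of peak amplitude $A$ responds with peak $A/2$. Scale
normalization by $\sigma^2$ keeps the response magnitude comparable
across choices of $\sigma$, and the kernel is mean-subtracted so a
constant frame responds exactly zero. Boundaries are reflected.

The response is thresholded adaptively at $\mu + z\sigma_R$, where $\mu$
and $\sigma_R$ are the mean and standard deviation of the response over a
support region (the cell mask when available, else the whole frame) and
*z* is the user's precision/recall preference. Because the decision is a
z-score of the response distribution, detection is invariant to affine
intensity rescaling of the input — the property that makes one threshold
setting transferable across channels with very different brightness.
Higher *z* raises precision and lowers recall; the default *z* = 1.75 was
selected by the sensitivity study described below. Connected components
of the binary mask (8-connectivity by default, configurable to 4) become
candidate objects; object intensities are always sampled from the raw
frame, never the response.

Two area filters remove sub-resolution artifacts, both *inclusive*
(objects of exactly the threshold area are removed): 25 px in fixed-cell
mode — a diffraction-limited ~250 nm spot at 56.6 nm pixels cannot
legitimately be smaller — and 4 px in live-cell mode, where the
subsequent intensity filters carry most of the specificity burden. The
boundary semantics ("threshold area or less is removed") are exposed as
`area_filter_inclusive` because the alternative strict reading changes
counts at exactly the boundary.

An important and sometimes counter-intuitive property of a *relative*
threshold: on a frame containing no true spots at all, $\mu + z\sigma_R$
still sits inside the noise distribution, so a fixed fraction
(~4% of support pixels at *z* = 1.75) exceeds it, and because the LoG
response of white noise is spatially correlated over ~$\sigma\sqrt2$
pixels those exceedances form blob-sized clusters that survive an area
filter. Adaptive detection therefore guarantees *relative*, not
absolute, specificity; on low-signal live-cell data the QC filters
below, not the threshold, provide the absolute guarantee.

## Autotuned live-cell mode and the QC filters

Live-cell series have strongly fluctuating intensity distributions, so a
fixed *z* is replaced by a deliberately permissive detection followed by
strict object-level filters. The recall/precision preference `ratio`
(default 3.75) maps to an effective threshold $z_\text{base}/\text{ratio}$;
this mapping is a documented design choice isolated in
`autotune_detect()` so it can be swapped — the literature on the
upstream detector does not pin down the mapping, only that larger
preference values recover more objects.

Three filters then prune the over-detection, each emitted per object in a
`QCRecord`:

1. **Effect size** — Cohen's *d* (pooled SD) of the object's intensity
   distribution against the whole cell's; negative *d* (dimmer than the
   cell) discards the object.
2. **Peak outlier** — the object's maximum intensity must exceed the
   upper Tukey fence $Q_3 + 1.5\,\mathrm{IQR}$ of the cell's intensity
   distribution (quartiles by linear interpolation, the sensitivity of
   these cutoffs to the quantile rule being why the rule is fixed and
   documented).
3. **Minimal area** — objects of 4 px or less are unobservable at the
   2 px system precision.

The cell distribution includes the object pixels themselves (the
alternative, excluding them, is not materially different at realistic
object/cell area ratios and is not what "with respect to that of the
cell" suggests).

Two measured properties of the fence are worth knowing. On signal-free
cells rendered with purely Gaussian camera noise, the fence falls at the
~99.9th percentile of cell pixels, *below* the expected maximum of the
thousands of pixels inside noise clusters — so a small number of noise
clusters per cell can pass all three filters. How many depends on the
mask composition: the fence is computed over the *refined* (dilated)
mask, and the dark dilation ring widens the IQR and raises the fence.
In the package's test scenes (cell ≈ 7000 px, ring ≈ 25% of the mask)
the three filters remove ≈ 99% of noise-only detections while removing
none of the true puncta on high-SNR scenes; at larger cell/ring ratios
(cell ≈ 18 000 px, ring ≈ 18%) removal drops to ≈ 93%. Real cytosol
contains bright real structure that lifts the fence well clear of the
noise, which is the regime the filters were designed for.

## Automated single-cell segmentation

Time-lapse mode cannot rely on hand-drawn ROIs, so the cell outline is
recovered per frame: pixels below the per-image 90th-percentile
intensity are zeroed (with a single bright cell covering ~10% of the
field, the surviving decile *is* the cell — the quantile rule again makes
the step scale-free), a cascade of median filters (3×3, 5×5, 9×9)
despeckles the survivor image, the result is binarized, and the largest
connected component is kept. The mask is widened by four dilations with
a 2 px disc (twice the system precision) so objects at the cell edge are
not clipped, then closed and hole-filled so a weakly labelled channel
region cannot punch holes in it.

Validity checks replace manual screening: the masks recovered
independently from each channel must agree (minimum pairwise Jaccard
0.8; the consensus is their union, again to avoid clipping edge
objects), and any frame whose mask touches the image border is
disregarded. The direction of the quantile step (suppress *below* the
quantile) and the choice of union consensus are decisions the method
description leaves open; both are isolated parameters
(`mask_params()`). The two LC3 channels are the default outline
channels: a mitochondrial dye labels a sparse tubular network, not the
cytosol, and segments the network rather than the cell. Manually drawn
fixed-cell ROIs bypass segmentation but still pass the border check.

## Dual puncta, association, and the potential ratio

A GFP and an mRFP object sharing ≥ 1 pixel mark one autophagosome; the
union of the overlapping puncta is the counted unit. One-to-many
overlaps are resolved as connected components of the bipartite overlap
graph — the pairwise description generalizes naturally, and the
construction is oracle-tested against brute force.

Distances between objects are Euclidean distances between closest edges
(minimum over pixel-center pairs; zero on overlap). Puncta within 5 px
(the ceiling of the precision, ~250 nm — the resolution limit) of a
mitochondrial segment cannot be distinguished from overlapping ones and
are counted as associated, *inclusively* at exactly 5 px. Mitochondria
are segmented with the same detector on the dye channel with no area
filter (a thin tubule fragment is still real signal); per-cell summaries
count objects whose pixels lie at least half inside the cell mask, the
dilated mask making this safe for genuine edge objects.

For each dual punctum overlapping the mitochondrial mask, the mean dye
intensity over the overlap pixels is divided by (a) the mean over the
*adjacent* segment — the one sharing the most overlap pixels, ties
broken by nearest centroid — and (b) the mean over all
mitochondria-positive pixels in the cell. Values below 1 mean the
autophagosome sits on mitochondria fainter (lower membrane potential)
than its segment or the cell average. Puncta with empty overlap yield no
record rather than a zero. Records pool across the 7 Z-slices and all
timepoints of a movie and are summarized per cell as boxplot statistics
(linear-interpolation quartiles, whiskers at the most extreme data
within 1.5 IQR). The package measures dye-intensity ratios only; any
statement about membrane potential is an interpretation of the dye.

## The z sensitivity study

Because *z* trades recall against precision, the package re-runs
detection and association across a *z* grid and asks where group
differences are stable. For every unordered pair of conditions, within
every cell line, at every *z*, per-cell counts are compared with a
Kruskal–Wallis test (tie-corrected H, chi-squared approximation); the
family of $m = \binom{c}{2} \times \text{lines} \times |z|$ hypotheses
is Bonferroni-controlled at $\alpha/m$. The reference design — 4
conditions, 2 cell lines, 21 z-values — gives $m = 6 \times 2 \times 21
= 252$ and a corrected level of $0.05/252$. `m` is always computed from
the grid, never user-supplied. The 21 default z-values span (0, 2]
uniformly; thresholds above 2 empty the masks on data like these, and
the exact grid is configurable because the original 21 values are not
part of the method's definition.

The unit of observation is the cell. Pairwise two-group tests are the
primary form, matching how condition pairs are reported; the k-group
omnibus test is exposed through the same `kruskal_test()`. The
chi-squared approximation is used at all sample sizes, as is common
practice; the test suite bounds its error against a 20 000-draw
permutation oracle at 60–80 cells per group, the regime where the
asymptotic approximation is relied upon. At 10–20 cells per group the
approximate p can deviate from the exact permutation p by up to ~0.02,
which is immaterial at the corrected level ($2\times10^{-4}$) but worth
remembering near nominal 0.05 decisions. Under a simulated null the
family-wise error of the full 252-test sweep is measured at ≈ 0.02–0.04,
comfortably within the Bonferroni guarantee.

## The synthetic microscopy module

`simulate_scene()` renders what the analysis assumes: one elliptical
cell (≈ 11% of the field, so the quantile segmentation behaves as on
real data) with a soft cytosolic edge (Gaussian falloff, σ = 6 px —
real confocal cell margins are not step edges, and a hard step would be
a strong artificial LoG edge), diffuse cytosolic fluorescence in both
LC3 channels, isotropic Gaussian puncta truncated at 4σ (the detector's
assumed spot model) in GFP-only, mRFP-only and coincident dual
configurations, a tubular mitochondrial network drawn as dilated
random-walk polylines whose per-segment intensity is
`mito_base × potential multiplier`, and camera noise applied last:
Poisson shot noise with gain 2 counts/photon plus Gaussian read noise
(SD 2 counts), rounded to integer counts so 16-bit TIFF round-trips are
exact. Spot amplitude is specified as peak SNR — peak divided by the
cytosol noise SD — so detectability is controlled explicitly.

Ground truth is consistent with the measurement by construction: "near
mito" dual puncta are placed *on* a segment (edge distance 0), "far"
ones beyond the association cutoff plus the punctum footprint plus a 4 px
safety margin, so no detection-mask wobble can flip a label; the test
suite re-derives every expected count from the puncta and segment pixel
sets with the association module's own metric. Placement is sequential
dart throwing with minimum center separation and whole-configuration
restarts; infeasible requests (too many puncta for the cell area) fail
loudly rather than degrade.

Time-lapse simulation translates the whole geometry rigidly per
timepoint, optionally jitters puncta, and renders each of the 7 Z-slices
(500 nm spacing) as an independent noise realization of the shared
geometry — no 3-D PSF, consistent with slices being analyzed
independently. A frame's ground-truth validity is geometric: the cell
ellipse widened by the 8 px mask-refinement margin must not reach the
border. Deliberately drifting fixtures exercise the border-rejection
path, and the suite checks the pipeline rejects *exactly* the
ground-truth-invalid frames.

What the generator does not emulate — optical PSF structure beyond
Gaussian spots, photobleaching, cytosolic texture, organelle
autofluorescence, multi-cell fields — bounds what green tests mean:
they certify the pipeline's logic and statistics on data matching its
assumptions, not performance on arbitrary real images. The two
measured QC regimes above are one example of a property that only
becomes visible when the simulation is *cleaner* than real data.

## Numerical and interface conventions

- Coordinates are 1-based (row, col) everywhere, the R convention;
  distances are in pixels, with nm appearing only in metadata.
- Quantiles use linear interpolation (R type 7) in the QC fence and all
  boxplot statistics.
- Labeling connectivity defaults to 8; the flood-fill oracle in the test
  suite pins both 4- and 8-connectivity semantics.
- Degenerate inputs are contracts, not crashes: zero response variance
  gives an empty mask with a warning; a flat frame is an invalid
  segmentation; a zero-mean segment drops its ratio record with a
  warning; `cohens_d` with fewer than 3 pixels is undefined and the
  object is discarded conservatively.
- Problem sizes in the test suite are chosen for desk-scale runs:
  256–480 px fields, 4–30 puncta per cell, 15–20 cells per group, 100–200
  replicates for calibration studies. All randomness is seeded; the same
  spec and seed reproduce outputs bit-identically.
- Tabular outputs are CSV with fixed headers; images and label maps are
  16-bit TIFF with a JSON sidecar declaring dimension order and channel
  names.

## Known limitations

Single cell per field; no tracking across frames beyond per-frame
masks; no sub-pixel localization or scale-space detection; no
pixel-correlation colocalization metrics (object overlap is the
construct of interest); no claim about membrane potential beyond dye
intensity. The effective brush of the morphology library is a discrete
disc, so dilation by "radius 2, four times" grows a single pixel to a
~249 px blob rather than exactly $\pi 8^2$ — the refinement oracle in
the tests pins the exact discrete semantics.
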
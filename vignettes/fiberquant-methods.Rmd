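---
title: "Quantifying sarcolemmal dystrophin per muscle fiber: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying sarcolemmal dystrophin per muscle fiber: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fiberquant)
library(dplyr)
```

## The measurement problem

Duchenne muscular dystrophy (DMD) is caused by loss of dystrophin at the
sarcolemma, the muscle fiber's plasma membrane. Therapies that aim to restore
dystrophin (for example exon skipping) need an assay that can detect modest
changes in dystrophin between two biopsies of the same patient. This is hard
for two reasons. First, dystrophin expression varies strongly from fiber to
fiber — even healthy muscle shows roughly threefold variation in per-fiber
mean intensity — so a biopsy cannot be summarised by a handful of manually
selected fields. Second, DMD muscle contains both near-ubiquitous *trace*
dystrophin (low intensity) and rare bright *revertant* fibers, so a robust
method must characterise the whole fiber population.

`fiberquant` implements a semi-automated answer: sections are co-stained for
dystrophin and for spectrin, a membrane protein expressed at the sarcolemma
regardless of dystrophin status. The spectrin channel locates each fiber's
membrane; dystrophin intensity is then measured inside that spectrin-defined
mask, fiber by fiber, over every fiber in every imaged field. Intensities are
arbitrary units (au) on the 12-bit acquisition scale (0–4095) and are
meaningful for *comparisons within one experiment*; the package deliberately
does not convert au to "percent of healthy control", because the au scale
moves with acquisition settings.

## Segmentation from the spectrin channel

`segment_fibers()` proceeds in four auditable steps:

1. **Smoothing.** The spectrin channel is smoothed with a Gaussian
   (`smoothing_sigma_px`, default 1 px) to suppress pixel noise.
2. **Membrane/interior separation.** A *relative* threshold (Otsu on the
   channel normalised to its maximum) separates membrane-positive pixels from
   fiber interiors. Because the threshold is computed on the normalised
   channel, multiplying the image by any gain g > 0 leaves the segmentation
   unchanged — important because detector gain is retuned per experiment. A
   fixed-au threshold is available (`threshold_method = "fixed"`).
3. **Seeding.** Each 4-connected low-intensity basin becomes a candidate
   fiber interior. Basins smaller than `seed_min_area_um2` (default
   100 µm², debris) or larger than `max_fiber_area_um2` (default
   25,000 µm², far above any physiological fiber cross-section) are
   discarded; the upper bound is what rejects open background regions, which
   have no bounded physiological size. A basin must also touch at least one
   membrane pixel, so a signal-free field yields zero fibers rather than an
   error.
4. **Membrane growth and splitting.** Membrane pixels are assigned to the
   fiber whose interior is geodesically nearest: a 4-connected front grows
   from all interiors simultaneously through the membrane mask, one pixel
   step per iteration, capped at `membrane_max_thickness_um` (default 3 µm)
   — the maximum predicted membrane thickness. Where two fibers touch, their
   shared wall is split down the middle; a wall of thickness 2t yields a
   band of thickness ≈ t on each side.

Ties — membrane pixels equally near two interiors — are broken by a fixed
direction priority (down, up, right, left in array coordinates). We chose
this over an id-based rule ("lower fiber id wins") deliberately: fiber
numbering is an artifact of labelling order, and an ownership rule that
depends on it changes results under relabelling. Direction priority is
equally deterministic but depends only on geometry, which is what makes
noiseless synthetic recovery exact (below).

Regions use 4-connectivity; the membrane-coverage QC check uses
8-connectivity for adjacency. `qc_filter()` flags (never deletes) fibers that
touch the image border, fall below `min_fiber_area_um2` (default 250 µm²),
or whose membrane covers less than `min_membrane_coverage` (default 0.6) of
their interior boundary. The coverage fraction is our construct — the
original operator practice ("sufficiently intact" fibers) is not defined
numerically anywhere we could anchor to — so it is configuration with a
documented default, not a constant.

## Per-fiber statistics

For each QC-passing fiber, dystrophin statistics are computed over the
membrane mask: mean, minimum, maximum, quantiles, and the **Q90-mean**. The
quantile convention is nearest-rank: the level-p quantile is the order
statistic at rank ⌈p·n⌉, i.e. the cut-off between the lowest p-fraction of
membrane pixels and the rest, with no interpolation — reproducible
bit-exactly and matching the cut-off definition of Q90. The Q90-mean is the
mean of the ⌈0.1·n⌉ brightest membrane pixels; it tracks the bright
sarcolemmal rim an observer sees and separates membrane signal from
cytoplasm with high contrast. Spectrin is summarised by its membrane mean.

Morphometry: cross-sectional area is (membrane + cytoplasm pixels)·pixel
size²; membrane thickness is membrane area divided by the length of the
membrane's inner contour. The contour length uses a Crofton-corrected
estimate (4-neighbour boundary edges × π/4), which is near-exact for the
round shapes fibers have; plain boundary-pixel counting underestimates
perimeters of smooth shapes by 10–20% and was rejected after failing an
analytic ring check. The area/perimeter thickness estimator is a
deterministic approximation to medial-axis thickness, chosen for speed and
reproducibility; it is biased upward when the band is thick relative to the
fiber radius.

## Population summaries

`summarize_biopsy()` averages fibers with *fiber weighting*: each fiber
counts once, so sections contribute in proportion to the fibers they
contain. Per-section means are retained separately because precision
statistics operate on them. Both the maximum over fibers of the per-fiber
mean and of the per-fiber maximum are reported (the two readings of "biopsy
maximum" are not interchangeable, so they are labelled distinctly).
Summaries excluding revertant-class fibers are reported alongside the full
averages, since a few bright revertants can dominate a trace-level mean;
whether to exclude them is a scientific choice the package does not make for
you.

`classify_fibers()` uses half-open intervals on the per-fiber mean:
below `trace_floor_au` → negative, `[trace_floor_au,
revertant_threshold_au)` → trace, at or above the threshold → revertant.
The defaults (200 and 800 au) reflect the ranges observed for trace and
revertant fibers at high-sensitivity (7% laser) settings; they are explicit
configuration because they are empirical observations at particular
settings, not physical constants.

`cumulative_distribution()` is the empirical CDF of per-fiber means scaled
to percent — the S-curve. Its slope encodes population homogeneity, and an
overall increase in dystrophin shifts the whole curve right.
`is_right_shifted()` implements that check as stochastic dominance: curve B
is right-shifted versus A when B's quantile function is at least A's at
every probed level. Histograms default to Freedman–Diaconis bins since no
bin convention is canonical.

## Precision and comparison statistics

**CV%** is standard deviation / mean × 100 with the *sample* (n−1) SD.
The choice is not cosmetic: with duplicate experiments (n = 2), the sample
SD reproduces the published inter-assay values (929 and 768 au → 13%;
58 and 82 au → 24%) whereas the population SD does not. Table-style output
rounds to integer percent, half away from zero; full precision is always
retained.

**Ranking**: biopsies are ranked within each experiment by mean intensity
(rank 1 = brightest); ties break deterministically by sample label and are
flagged. Experiments need not share all samples, so concordance is defined
pairwise: the ranking is concordant when no pair of samples is ordered
differently in two experiments.

**Percent dystrophin difference** is (post − pre)/pre × 100 on the biopsy
averages.

**The hierarchical visit test** fits, on per-image means of per-fiber
dystrophin means, the model `log(value) ~ visit + (1 | section)` by REML,
with Satterthwaite denominator degrees of freedom for the visit contrast.
The log transform stabilises the right-skewed intensity scale. Two modelling
notes: (i) with one value per image, the image-within-section effect *is*
the residual, so the reported "image" variance component is the residual
variance — the nesting images-within-sections-within-visits is fully
respected; (ii) slides are not modelled as a level distinct from sections —
when each slide carries one section the two are confounded, and we keep the
identifiable two-level structure. Because the original analysis software and
REML details are not recoverable, a distribution-free alternative is
provided: `permutation_visit_test()` permutes visit labels at the section
level (whole sections exchanged), enumerating all assignments exactly when
few enough, and falls back to image-level exchange (flagged
anti-conservative) only for degenerate single-section designs, which the
REML fit refuses with that advice.

## The synthetic generator

Real biopsies and the original images are not available, so every pipeline
stage is validated against `generate_section()`/`generate_study()`, which
emulate what matters for the measurement:

* **Geometry**: a seeded Voronoi tessellation with Lloyd relaxation (2
  iterations by default) gives packed convex polygons like a true fiber
  mosaic. Pixel size defaults per preset so the mean cross-sectional area
  matches typical values (healthy ≈ 4,400 µm², BMD ≈ 6,000 µm²,
  DMD ≈ 2,500 µm² — dystrophic fibers are smaller).
* **Membrane**: a band of fixed physical thickness (2 µm default) along
  every fiber–fiber boundary, positive in both channels. Fibers cut by the
  field edge have no membrane along the cut, as in real sections
  (`closed_border = TRUE` closes them for single-fiber fixtures).
* **Intensities**: per-fiber means drawn from presets anchored to reported
  ranges — healthy ≈ 500–1350 au, trace ≈ 200–800 au (upper-truncated),
  revertants uniform on 800–2500 au at 5% frequency. The log-normal family
  is a modelling choice (non-negative, right-skewed, like observed per-fiber
  histograms); the true family is unknown, so presets match ranges, not
  shapes. 80 fibers per field reflects a typical image load; five images per
  section then approximate the ~400 fibers per section of routine use.
* **Degradation**: Gaussian blur, then noise (Gaussian, default SD 20 au;
  optional Poisson), then 12-bit quantization — in that order, because the
  order affects recovery tolerances.

Membrane ownership in the generator uses the *same* nearest-interior rule as
the segmentation split, and band pixels are rendered with their owner's
intensity. This makes two things exact by construction: ground-truth
per-fiber means equal rendered noiseless membrane means, and the noiseless
pipeline (analysis smoothing off) recovers every drawn mean with zero error.
With noise but no blur the measured mask still equals the rendered band, so
recovery error is pure pixel noise and is bounded by 3·SEM. With blur on,
mask edges mix membrane and background signal, which introduces a bias that
is a property of the optics emulation, not of the estimator — recovery under
blur is therefore assessed by correlation and segmentation overlap, not
exactness.

**What passing these tests does and does not show.** The generator does not
simulate fibrosis or adipose regions, freezing artefacts, uneven
illumination, staining gradients, or isotype-control backgrounds beyond a
flat offset. Passing means the algorithms are correct on clean,
well-posed fields; performance on artefact-laden sections still depends on
the QC flags and operator review of fiber identification.

The hierarchical study generator draws section effects (log-scale SD 0.10)
and image effects (log-scale SD 0.10) around a biopsy baseline — intensity
CVs of about 10%, mid-range of observed intra-assay precision (2–13%) — with
4 sections per visit and 5 images per section by default. Under the null,
the REML visit test holds its nominal 0.05 size to within simulation error;
with a log(1.30) visit effect, the median estimate recovers the truth within
a few percent. These checks run at the design sizes above (1000 and 200
replicates), which the test suite executes in a few minutes.

## Numerical conventions

* Intensities validated to [0, 4095]; pixel coordinates are 0-based
  row/column at the I/O surface; areas convert to µm² via pixel size² only
  at output time.
* TIFF storage is 16-bit with au values written as value/65535 — integer au
  round-trips exactly.
* CSV fiber tables have a fixed column order (identifiers first) and empty
  fields for missing values; they round-trip at 6+ significant digits.
* All random generation is seeded; `generate_*` functions restore the
  caller's RNG state. Same seed, same platform ⇒ bitwise-identical images
  and label maps.

## Known limitations

* The thickness cap is applied in 4-connected pixel steps
  (⌈thickness/pixel size⌉), which slightly under-reaches along diagonal
  walls; the default cap (3 µm) is generous relative to the 2 µm band so
  this does not drop wall pixels in practice.
* The area/perimeter thickness estimate is an approximation; medial-axis
  thickness would be more faithful for very irregular fibers.
* Absolute au values are not comparable across experiments; all comparison
  statistics in the package are within-experiment by design.
* The mixed model treats sections as the only grouping level above images;
  designs with multiple slides per visit carrying multiple sections each
  would need an extra level the package does not currently fit.
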
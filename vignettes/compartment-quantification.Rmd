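---
title: "Methods: compartment-resolved quantification of protein redistribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compartment-resolved quantification of protein redistribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and data model

`compartquant` quantifies how two proteins — imaged in separate fluorescence
channels `A` and `B` alongside a DNA stain — distribute across nucleus,
nucleolus and cytoplasm in single cells, across experimental conditions
(typically an unstressed control, an acute heat shock, and recovery time
points). A field is a set of same-sized 2D intensity matrices in detector
units (ADU) with a pixel area in µm² (default 0.14). Compartments are
integer label images sharing cell IDs, with hard invariants enforced on
every output: nucleolus ⊆ nucleus per cell, nucleus ∩ cytoplasm = ∅,
nucleus ∪ cytoplasm ⊆ cell. The nuclear label covers the whole
DNA-demarcated area including nucleoli; `nucleus_excludes_nucleoli = TRUE`
switches to nucleoplasm-only measurement. We default to the inclusive
convention because the DNA stain demarcates the full nuclear area and the
nucleolar signal is reported separately anyway.

## Segmentation

**Background.** The camera background is the mean intensity over cell-free
pixels — the automated analogue of hand-picking an empty region. The
exclusion mask is the union of thresholded DNA and protein signal, dilated
by 4 px; at least 1% of pixels must remain free or the user is asked for a
manual ROI. Correction subtracts the level pixelwise and clamps at zero.
Clamping makes the corrected cell-free residual equal the folded-normal
mean σ/√(2π) rather than zero; the estimator itself is unbiased, which is
what the test suite asserts.

**Nuclei.** Gaussian smoothing (σ = 1 px), a global Otsu threshold
(256 bins over the data range, overridable), hole filling (so dark nucleoli
stay inside their nucleus), connected components, a 50 px minimum-area
filter, and removal of border-touching objects (reported, not silently
dropped). Distance-transform watershed splitting of touching nuclei is
available but off by default: on well-separated nuclei it can only
oversplit, and the intended imaging regime is sub-confluent.

**Nucleoli.** Dark holes within each nucleus: smoothed DNA intensity below
0.6 × the per-nucleus median, cleaned by a 3 px disc opening, minimum area
10 px, each component inheriting its nucleus's cell ID. The per-nucleus
median adapts the cutoff to cell-to-cell DNA staining variability. A
uniform nucleus legitimately yields zero nucleoli.

**Cytoplasm.** The imaging protocol gives no dedicated cell-outline
marker, so two strategies are provided. Default: the cell mask is the
thresholded sum of the two protein channels, partitioned among cells by
nucleus-seeded geodesic propagation (marker-based watershed); cytoplasm is
the cell minus the nucleus dilated by a 1 px guard ring, which keeps
nuclear edge bleed out of cytoplasmic means. Alternative: a fixed-width
annulus (default 8 px) around each nucleus, for sparse or dim cytoplasms.
Cells whose cytoplasm comes out empty are dropped with a warning.

## Quantification and normalization

Per-compartment means are plain sums over label pixels divided by pixel
counts, on background-corrected images. The N/C ratio is computed per cell
and then averaged (the single-cell convention; a ratio-of-means variant
would weight bright cells more — per-cell ratios are what the scatter and
profile plots need). Zero cytoplasmic mean flags the ratio `NA` rather than
producing an infinity.

Normalization divides every channel × compartment quantity (and each N/C
ratio) by its mean over control cells *of the same replicate experiment*,
never pooled: each experiment carries its own staining intensity, and
per-replicate normalization is what makes replicates commensurable. The
control mean is exactly 1 per replicate by construction; this is asserted,
not assumed. Condition summaries report mean + SEM either per cell or — the
default — per replicate (cells averaged within each experiment first, n =
number of experiments).

## Colocalization

Percent-area overlap at fixed thresholds, asymmetric in direction:
`pct_A_in_B = 100 |A∩B|/|A|`, `pct_B_in_A = 100 |A∩B|/|B|`, evaluated
separately in the nuclear and cytoplasmic ROI of every cell. Thresholding is
strict (`>`). One scalar threshold per channel is computed once from the
pooled pixels of the control fields (Otsu by default; fixed-value and
percentile methods are available for reproduction attempts) and then frozen
for the entire experiment — a condition-dependent threshold would
manufacture colocalization changes. Zero-denominator percentages are
flagged undefined and excluded from condition means, with the excluded
count reported; conditions with fewer than 10 analysed cells are flagged.
The conservation identity `pct_A_in_B·|A| = pct_B_in_A·|B| = 100·|A∩B|` is
exact in exact arithmetic and is tested to 1e-12 to absorb floating-point
rounding. Pixel-intensity correlation measures (Costes, Li) are
deliberately out of scope: the binary percent-area statistic is the one
this pipeline is built around.

## Statistics

`pearson_r` implements `cov(x, y)/(σ_x σ_y)` directly (the n vs n−1
convention cancels); `linear_fit` is closed-form OLS with
`R² = 1 − SS_res/SS_tot`; `one_way_anova` is the classical between/within
mean-square F with (k−1, N−k) degrees of freedom;
`bonferroni_vs_control` runs two-sided equal-variance t-tests of each group
against the control (Welch behind a flag) and multiplies raw p by the
number of comparisons, capped at 1. Degenerate inputs propagate as explicit
`NA` flags, never silent zeros: constant input makes r undefined, constant
y makes R² undefined (SS_tot = 0), all-identical groups make F undefined
(0/0), while zero-variance groups with equal means give t = 0, p = 1. The
test suite cross-checks every statistic against an independent route
(`cor`, `lm`, `aov`, `t.test`, and brute-force double-loop oracles).

The correlation grid pools per-replicate-normalized single-cell values
across experiments; since normalization is a per-replicate scale factor it
perturbs pooled r only through between-replicate scale differences, and the
per-replicate r values remain available for diagnostics.

## The synthetic generator

The generator is a first-class module, not a test fixture: it renders
fields with a fully known ground truth so that each pipeline stage is
validated by parameter recovery.

*Geometry.* Cells are ellipses (semi-axes 17–23 px) with concentric
elliptical nuclei (10–14 px) and 1–3 disk nucleoli (3–5 px), placed by
rejection sampling with no overlap and no border contact; placement failure
after bounded retries raises a "field too crowded" error. Real cell
morphology is irregular; simple geometry is the point — it makes Dice
scores interpretable as method error rather than morphology error.

*Intensity model.* Each condition has a µ table (ADU) per channel and
compartment. Each cell × channel × compartment carries a brightness factor
`max(1 + cv·z, 0.05)` with cv = 0.20 for protein channels and 0.05 for the
DNA stain. Within a compartment the standard-normal `z` of channels A and B
share a latent factor at weight √ρ, so their correlation equals the
configured `cross_cell_correlation` exactly at the latent level; the
truncation at 0.05 is ~4 SD away and negligible. Nucleoli render darker
than nucleoplasm in DNA (80 vs 200 ADU, i.e. 40%), brighter than
nucleoplasm in channel A during recovery, and dim in channel B throughout.
The default condition tables encode the study's qualitative trends —
channel A's N/C ratio rising monotonically from control through 3 h
recovery with a nucleolar peak early in recovery, channel B flat and
nucleolus-excluded — because no calibrated per-condition intensity
distributions exist to copy; they are mimics of the observed effect
directions, chosen once.

*Noise.* Gaussian read noise with SD = 2% of the brightest configured µ,
optional Poisson shot noise, background 40 ADU added everywhere, 16-bit
clipping with a saturation flag. Values are rounded to integer ADU so that
serialization through 16-bit TIFF is lossless and runs are bit-reproducible.

*Colocalization.* When enabled, each compartment receives equal-sized
A- and B-positive puncta sets (12% of compartment pixels each) drawn so
that `|A∩B|/|B|` hits the target fraction up to one pixel of rounding,
placed uniformly. Puncta add a fixed increment δ to the rendered intensity,
default 3× the brightest configured µ. δ is deliberately large relative to
the cell-to-cell dispersion of the diffuse signal: the analysis protocol
demands a *single global threshold per channel across all conditions*, and
an increment comparable to the noise SD would sit far inside the diffuse
signal's cell-to-cell spread, making the embedded fraction unrecoverable by
any global threshold. `coloc_threshold_suggest()` returns the midpoint of
the guaranteed separation gap.

*Experiments.* `generate_experiment()` derives per-(replicate, condition)
seeds deterministically from one master seed and writes channel TIFFs,
label-mask TIFFs, per-cell truth CSVs and a long-format manifest (one row
per channel file); identical master seeds reproduce all files
bit-identically.

What the generator does **not** emulate: point-spread-function optics,
photobleaching, intensity textures, 3D structure, touching or mitotic
cells, segmentation-hostile morphologies. Passing recovery tests therefore
demonstrate correctness of the measurement and statistics machinery on
resolvable inputs, not robustness to difficult real-world imagery.

## Problem sizes and runtime choices

The default study is 5 conditions × 3 replicates × 40 cells per 560×560
field (120 cells per condition, 40 per experiment — above the ≥115 and ≥35
working minima the population analyses are designed for). Correlation
recovery studies use 200-cell populations on 1250×1250 grids without
rendering (the generator exposes ground-truth means directly), 10
populations per ρ plus 40 null populations; colocalization recovery uses 50
cells per fraction at 640×640. These sizes put the whole validation suite
at a few minutes on one CPU while keeping every sampling-error tolerance
honest (e.g. ±0.06 on r at n = 200 is the 95% envelope of the estimator).

## Known limitations

- Cytoplasm demarcation depends on the protein channels themselves; a
  protein absent from the cytoplasm in some condition would shrink the cell
  mask there. The annulus strategy is the mitigation.
- The clamped background correction biases means upward by at most
  σ/√(2π) per fully-dark compartment; negligible against compartment
  signals but visible in empty regions.
- Otsu on strongly bimodal pools has a flat objective across the empty
  inter-mode gap; any threshold in the gap is equally valid and EBImage's
  plateau convention is used as-is.
- Replicate-level ANOVA with three experiments has little power; cell-level
  testing is available but treats cells as independent, which overstates n.
- Colocalization recovery assumes puncta-like signal; for diffuse co-varying
  signals percent-area overlap saturates and intensity-correlation methods
  (out of scope here) would be the right tool.
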
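---
title: "Methods: cell binning from boundary stains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell binning from boundary stains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models and numerical choices behind
`spatialcellbin`: what each stage assumes, which parameters matter,
what the synthetic-data generator does and does not emulate, and where
the design was genuinely open.

## The problem

Stereo-seq-style platforms deliver (a) a long-form "GEM" table of
molecule counts per capture spot, (b) nuclei staining image tiles, and
(c) membrane or cell-wall staining image tiles. The goal is a sparse
cell-by-gene count matrix. The key obstacle is registration: the
boundary stain shows cell outlines but not the chip's "track line"
fiducial, while the nuclei stain shows the fiducial but not the
outlines. The pipeline therefore registers boundary→nuclei (pure
translation; the chip does not move between exposures) and nuclei→map
(similarity transform anchored on the track lines), composes the two,
segments cells on the registered boundary image, and bins molecules by
mask lookup.

## Stitching

Pairwise tile offsets come from FFT phase correlation on the nominal
overlap strips, zero-padded to twice their width along the narrow axis:
stage jitter can displace two adjacent tiles by more than half the
strip width, which a circular (unpadded) correlation cannot
disambiguate. The correlation peak height (in `[0, 1]`) is used as
confidence: it is exactly 1 for a pure circular shift, 0.75–0.95 for
genuine crop overlaps, and below 0.1 for unrelated noise, so the
default fallback threshold of 0.3 separates the two regimes by a wide
margin. Pairs below threshold fall back to the nominal offset implied
by the overlap fraction — mandatory for featureless (blank) strips.
Global offsets accumulate along a maximum-confidence spanning tree
anchored at the top-left tile; seams take the later tile (row-major)
so boundaries stay unblurred for segmentation. Offsets are
integer-pixel by design; sub-pixel refinement belongs to registration,
not stitching.

## Registration

**Stage 1 (boundary → nuclei).** Mean subsampling (factor 4 by
default) gives a coarse offset, restored by multiplying with the
factor; a full-resolution search restricted to a window of ±2·factor
around the restored estimate refines it. Plain *phase* correlation is
the right tool when the two images share broadband content, but the
two stains are different modalities: boundaries are bright ridges in
one channel, nuclei are bright disks in the other, and spectral
whitening discards exactly the weak shared component. The offset score
is therefore a sum of normalised cross-correlation surfaces: a
tissue-envelope term (σ = 20 px blur of both channels) that anchors
the global position, plus a polarity-invariant band-pass term (|NCC|
of the 3–12 px band for the coarse stage; the 1–6 px band, anchored by
the envelope, for the fine stage). Taking the absolute value makes
dark-interior-on-bright-nucleus matches (cross-stain) score like
identical textures (same-stain, multi-channel case), so the same
estimator serves `register_channel_offsets`. The coarse peak is
interpolated to sub-pixel (parabolic) before restoring, which keeps
the fine window centred even when the true offset falls between
subsampled bins.

**Track-line detection.** The fiducial is modelled as two orthogonal
periodic line families. Orientation is found by maximising the
sharpness (variance) of the high-passed intensity projection profile
over angles modulo 90°; pitch comes from the profile's spectrum —
restricted to ±20% of the chip pitch when that metadata is available
(`chip_pitch_spots`), otherwise from the autocorrelation fundamental
(the narrow comb spreads power over harmonics, so the raw spectral
argmax is unreliable) — and is polished together with the angle
against a comb-correlation objective. Phases are comb offsets per
family. Detection thresholds are calibrated against the null: the
unhinted peak-ratio statistic reaches ~14 on structureless noise
(genuine combs score 40+, default threshold 20); the hinted band
statistic reaches ~3.1 on noise (threshold 3.6). Expression maps are
detected on the negated map with a tissue-envelope weight, since the
marker occludes capture spots (molecule-free lanes) and empty canvas
would otherwise dilute the profile. A σ = 1 pre-blur removes the
pixel-alternation alias that integer re-binning at non-unit scale
imprints on the map.

**Stage 2 (nuclei → map).** Scale is the ratio of the chip pitch in
map units to the detected pitch in stain pixels. The rotation is
decomposed as quadrant (0/90/180/270°) × fine angle (from the
track-line angle difference; sign flips under mirroring), and the flip
search is restricted to {none, horizontal} (a vertical flip is
horizontal flip + 180°). Each of the eight candidates is scored by a
sum of three NCC surfaces: lane-suppressed stain content against the
smoothed map (smoothing σ proportional to the map-frame cell size,
clamped to 3–10 px), the extracted bright line comb against the map's
lane deficit, and an anti-boundary term (−0.7 × NCC against the map's
gradient magnitude — nuclei sit away from membranes, so the blob image
anti-correlates with density discontinuities at the true pose). The
winning candidate's fine angle is polished by maximising the score
(with parabolic peak-height interpolation, keeping the objective
smooth), and the translation is the score peak refined to sub-pixel.
Track lanes are suppressed (replaced by the off-lane median) before
the content correlation because the marker is bright in the stain but
dark in the map; correlating the raw images would anti-correlate at
the true pose.

**Stage 3.** The membrane transform is the exact composition of the
stage-1 offset with the stage-2 transform; nothing is re-estimated.
With `pre_registered = TRUE` (multi-channel microscope), stage 1 is
skipped and the offset is zero.

## Segmentation

Large registered images are cut into tiles (default 2048 px, 128 px
overlap — the overlap must exceed a cell diameter) whose origins are
recorded. Per tile, the backend runs once per candidate diameter
(default 20/30/40/60 px) and the mask with the largest total cell area
wins, ties to the smaller diameter. The built-in classical backend is
a marker-controlled watershed: Gaussian smoothing at σ = diameter/8,
markers at local minima separated by ≥ diameter/2, seeded region
growing over the boundary intensity, then two cleanups — regions whose
separating ridge is shallower than 15% of the dynamic range above the
deeper basin are merged (the ridge level is the *median* along the
shared boundary, so bright endpoints where a spurious boundary meets
genuine walls do not disguise it), and basins whose rim-to-interior
contrast (rim mean minus the lower-quartile interior level, robust to
bright nuclear bleed-through inside the basin) is below the same 15%
are demoted to background, as are regions smaller than (diameter/4)².
Merging drops cells whose bounding box touches a tile edge shared with
a neighbour (the overlap guarantees another tile sees them whole),
pastes survivors at global coordinates, and deduplicates pairs with
IoU > 0.5 by keeping the copy whose centroid is farther from its
tile's border. Tissue filtering keeps cells with ≥ 50% of their area
on tissue (inclusive); the built-in tissue fallback is Otsu on a
heavily smoothed image keeping large components.

## Molecule labeling and QC

Each record takes the mask label at its spot; one spot = one pixel, no
sub-pixel splitting. Counts are conserved exactly at every stage
(assigned + unassigned = input total, integer arithmetic). The
optional rescue step fits one 2-D Gaussian per cell with ≥ 3 assigned
records (count-weighted mean and covariance, ridge-regularised with
1e-3 px²; weight ∝ total counts) and gives each unassigned record
within `max_radius_px` (default 3× the mean equivalent cell radius) of
an eligible centroid the label maximising weight × density. It never
relabels in-mask records and is off by default — boundary stains are
tightly packed and few molecules fall outside. QC removes cells with
< 10 expressed genes, < 3 total counts, or > 3% mitochondrial counts
(prefix-matched gene ids, default `mt-`, case-insensitive; boundaries
inclusive on the keep side), then genes present in < 3 surviving
cells; cell filter first, one pass each.

## Evaluation metrics

Pixel metrics treat label > 0 as foreground: precision TP/(TP+FP),
recall TP/(TP+FN), F1, and Dice 2·TP/(2·TP+FP+FN) (identical to F1
wherever both are defined — asserted to 1e-14 over 1000 random
quadruples). Each predicted cell is matched to the ground-truth object
sharing the most pixels (ties to the smaller label); Avg_J is the mean
per-cell IoU with unmatched cells contributing 0. Silhouette uses
Euclidean distance, b as the minimum over other clusters of the mean
distance to that cluster, and 0 for singletons. Moran's I follows the
classic form with W₀ the sum of all weights; for cluster-level spatial
coherence, each cluster's one-hot membership indicator over cells is
scored under row-standardised k-nearest-neighbour weights (k = 6) on
cell centroids — the literature leaves the cluster-level weight matrix
unspecified, so this declared, configurable choice is documented
behaviour rather than a convention claim. Cluster evaluation embeds
the library-size-normalised, log-transformed matrix in 10 principal
components and averages both scores across clusters.

## Synthetic data: what it emulates, and what it does not

Scenes are Voronoi partitions of seeded dart-throwing centroids
clipped to a circular tissue disk. Defaults: 512×512 px, 100 cells of
mean diameter 36 px (mammalian cells of 10–20 µm at a 500 nm pixel
pitch), 300 molecules per cell over 100 genes (bin-1-like density),
three gene programs with 8× enrichment, 3% mitochondrial gene ids, 5%
of molecules displaced onto background within 10 px, additive Gaussian
image noise at 5% of dynamic range, 2×2 tile grids with 10% overlap
and ≤ 3 px stage jitter, and a track-line pitch of 64 px — chosen so
at least eight lane periods remain visible at the smallest supported
registration scale (0.4), mirroring the sub-millimetre pitch of the
physical chip fiducial.

Three generator choices are load-bearing for registration and reflect
real image physics rather than convenience: the membrane channel
carries 10% nuclei bleed-through (fluorescence channels always have
cross-talk and cytoplasmic background — without *some* shared
structure, cross-stain translation estimation is information-
theoretically impossible); nuclei are sharp-edged disks, not Gaussian
blobs (DAPI nuclei have defined borders, and those edges are the
pixel-exact registration signal); and per-cell molecule totals and
cell areas vary, giving the map the per-cell density texture that
disambiguates the rotation quadrant. What the generator does *not*
emulate: optical PSFs and vignetting, illumination gradients, chip
defects, segmentation-hostile morphologies (elongated or overlapping
cells, multinucleation), ambient RNA gradients, or plant-vs-animal
wall thickness differences. Passing tests therefore demonstrate the
pipeline's correctness and numerical behaviour under controlled
conditions, not segmentation performance on real tissue — on real
data the deep-learning backend plugged into the same contract is
expected to carry segmentation quality.

## Problem sizes and determinism

The validation suite uses 512 px scenes of 50 cells for registration
recovery (20 random transforms: scale 0.4–2, quadrant + fine angle
≤ 2°, flip, integer translations; tolerances: scale 1%, angle 0.5°,
translation 0.5 px, flip/quadrant exact), 420 px sources for 3×3
stitching grids, and the generator defaults for the end-to-end run.
Translations are drawn as integers: stage placement in the simulated
acquisition is pixel-quantised, which makes exact-recovery assertions
meaningful; the estimator itself reports sub-pixel values. All
randomness flows from explicit seeds; re-running any pipeline
configuration reproduces byte-identical outputs (asserted on the
matrix, index and labelled-GEM files).

## Known limitations

Stage 1 assumes no rotation between stains (the chip is fixed; the
statement is taken literally, so only translation is estimated). The
rotation model is quadrant × fine angle within ±2°; free-angle
acquisition is out of scope. The track-line model is a plain periodic
crossed grid — real chips encode absolute position patterns this model
ignores, so translation disambiguation relies on image content rather
than the marker's position code. The classical backend is a genuine
segmentation method but tuned for ridge-like boundary stains; it will
under-perform deep backends on real tissue. GEM inputs larger than
memory are not streamed. The on-disk output schema (MatrixMarket +
TSVs + labelled GEM) is this package's own.
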
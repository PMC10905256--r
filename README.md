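# spatialcellbin

Single-cell binning of high-resolution spatial transcriptomics using
cell boundary staining images.

Sequencing-based spatial platforms such as Stereo-seq capture molecules
on a dense grid of spots, at sub-cellular pitch over centimetre fields
of view. Turning those per-spot counts into *per-cell* expression
profiles requires knowing where the cell boundaries are. Nuclei stains
(DAPI, ssDNA) locate cells but not their outlines; membrane (mIF, animal
tissue) and cell-wall (calcofluor white, plant tissue) stains show the
outlines but miss the chip's "track line" fiducial — the crossed
periodic marker needed to register an image onto the expression map.
`spatialcellbin` bridges the two: the nuclei stain is registered to the
expression map via the track lines, the boundary stain is registered to
the nuclei stain by pure translation (the chip does not move between
exposures), and the composed transform carries the segmented cell
boundaries into map coordinates, where every molecule is assigned to the
cell whose mask pixel it falls on.

The pipeline:

1. **Stitching** — microscope tile grids are assembled by FFT phase
   correlation on the nominal overlap strips, with a
   maximum-confidence spanning tree fixing global tile offsets.
2. **Registration** — three stages: (i) boundary→nuclei stain offset by
   coarse (mean-subsampled) and windowed fine FFT correlation; (ii)
   nuclei→map similarity transform (scale from the track-line pitch
   ratio, rotation quadrant and flip by normalised cross-correlation
   scoring, fine angle and sub-pixel translation by score refinement);
   (iii) exact composition onto the boundary stain.
3. **Segmentation** — tiled inference with overlap-aware merging and
   per-tile cell-diameter selection by maximal total cell area. The
   built-in backend is a marker-controlled watershed with ridge-depth
   region merging; any `(tile, diameter) -> label mask` function can be
   plugged in instead (e.g. a deep model).
4. **Molecule labeling** — direct mask lookup per molecule, optional
   Gaussian-density rescue of extra-cellular molecules, per-cell
   statistics, and the standard QC filter (cells: ≥ 10 genes, ≥ 3
   counts, ≤ 3% mitochondrial; genes: present in ≥ 3 cells).
5. **Evaluation** — pixel confusion metrics (precision, recall, F1,
   Dice = 2·TP/(2·TP+FP+FN)), per-cell IoU and average Jaccard
   (Avg_J = Σ IoU_i / n_s), silhouette coefficient, and Moran's I
   spatial autocorrelation
   (MI = (n/W₀)·Σ_kl ω_kl (y_k−ȳ)(y_l−ȳ) / Σ_k (y_k−ȳ)²).

A deterministic synthetic-data generator (`make_cells`,
`add_track_lines`, `make_tile_grid`, `make_expression`,
`make_registered_pair`, `simulate_dataset`) builds Voronoi tissue
scenes with known ground truth for every stage, so the whole pipeline
is testable without downloads.

## Worked example

```r
library(spatialcellbin)

td  <- tempfile()
sim <- simulate_dataset(file.path(td, "sim"), seed = 7)   # 100 cells, 2x2 tile grid

cfg <- pipeline_config(
  nuclei_tiles     = file.path(td, "sim", "nuclei"),
  membrane_tiles   = file.path(td, "sim", "membrane"),
  gem              = file.path(td, "sim", "data.gem.tsv"),
  out              = file.path(td, "out"),
  tissue           = "auto", rows = 2, cols = 2, overlap = 0.1,
  chip_pitch_spots = sim$chip_pitch_spots,
  gt_mask          = file.path(td, "sim", "truth", "mask_map.tif"),
  seed             = 7)
run_pipeline(cfg)
```

The run log reports each stage; the final lines of a real run:

```
stage segment done in 1.8s
stage label done in 0.6s
stage qc done in 0.0s
stage evaluate done in 0.1s
pipeline complete: 99 cells, 100 genes, 160 unassigned counts
```

and `out/metrics.json` holds the segmentation evaluation against the
ground-truth mask:

```json
{"precision":0.9976,"recall":0.9985,"f1":0.9981,"dice":0.9981,
 "avg_jaccard":0.9591,"n_cells_pred":101,"n_cells_gt":100}
```

`avg_jaccard` ≈ 0.96 means the average per-cell overlap between
recovered and true cells is 90%; the recovered transform in
`out/transform.json` matches the generator's truth (identity, plus the
known 6-, −4-pixel inter-stain offset) to a fraction of a pixel.
`out/` also contains the stitched mosaics, the registered boundary
image, the cell mask (16-bit TIFF), the cell-by-gene matrix
(MatrixMarket + index files + per-cell metadata), and the input GEM
with an appended per-molecule `label` column.

A command-line front end wrapping these functions is in
`inst/cli/spatialcellbin.R` (subcommands `simulate`, `stitch`,
`register`, `segment`, `label`, `evaluate`, `run`).

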
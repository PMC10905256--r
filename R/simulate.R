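#' Simulate a complete synthetic dataset on disk
#'
#' Builds a synthetic scene ([make_cells()]), renders the chip track
#' lines on the nuclei stain (boundary stains miss the marker), shifts
#' the membrane stain by a known inter-stain offset, cuts both stains
#' into jittered overlapping tile grids, emits per-cell gene expression
#' ([make_expression()]) and maps it into expression-map space through
#' a known similarity transform ([make_registered_pair()]).  Everything
#' a pipeline run needs is written under `out`:
#' `nuclei/r{r}_c{c}.tif`, `membrane/r{r}_c{c}.tif`, `data.gem.tsv`,
#' and a `truth/` directory with the ground-truth masks (stain and map
#' frame), the true transform and offsets (`transform.json`), per-cell
#' programs (`programs.tsv`) and the per-molecule emission log in map
#' coordinates (`emissions.tsv`).
#'
#' @param out Output directory.
#' @param seed Integer seed (drives every random choice).
#' @param n_cells,shape,mean_diameter_px Scene parameters
#'   (see [make_cells()]).
#' @param rows,cols,overlap_fraction,jitter_px Tile grid parameters.
#' @param n_genes,n_programs,counts_per_cell,displaced_fraction
#'   Expression parameters (see [make_expression()]).
#' @param transform True stain-to-map [similarity_transform()]
#'   (default identity).
#' @param pitch_px,line_width_px Track-line geometry in stain pixels.
#' @param stain_offset Known (dy, dx) offset of the membrane stain
#'   relative to the nuclei stain.
#' @return Invisibly, a list with the in-memory scene objects
#'   (`mask`, `mask_map`, `molecules`, `emissions`, `programs`,
#'   `transform`, `chip_pitch_spots`, tile `offsets`).
#' @export
simulate_dataset <- function(out, seed = 7L, n_cells = 100L,
                             shape = c(512L, 512L), mean_diameter_px = 36,
                             rows = 2L, cols = 2L, overlap_fraction = 0.1,
                             jitter_px = 3L, n_genes = 100L, n_programs = 3L,
                             counts_per_cell = 300,
                             displaced_fraction = 0.05,
                             transform = similarity_transform(),
                             pitch_px = 64, line_width_px = 3L,
                             stain_offset = c(6L, -4L)) {
  dir.create(file.path(out, "truth"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out, "nuclei"), showWarnings = FALSE)
  dir.create(file.path(out, "membrane"), showWarnings = FALSE)
  scene <- make_cells(n_cells, shape, mean_diameter_px, seed = seed)
  nuclei <- add_track_lines(scene$nuclei, pitch_px, 0, line_width_px)

  # membrane stain photographed with a small stage offset
  mem <- matrix(0, shape[1], shape[2])
  sy <- stain_offset[1]; sx <- stain_offset[2]
  ys <- max(1, 1 + sy):min(shape[1], shape[1] + sy)
  xs <- max(1, 1 + sx):min(shape[2], shape[2] + sx)
  mem[ys, xs] <- scene$membrane[ys - sy, xs - sx]

  gn <- make_tile_grid(nuclei, rows, cols, overlap_fraction, jitter_px,
                       seed = seed + 1L)
  gm <- make_tile_grid(mem, rows, cols, overlap_fraction, jitter_px,
                       seed = seed + 2L)
  for (k in seq_len(rows * cols)) {
    r <- gn$offsets$row[k]; c <- gn$offsets$col[k]
    write_image(gn$grid$tiles[[k]],
                file.path(out, "nuclei", sprintf("r%d_c%d.tif", r, c)))
    write_image(gm$grid$tiles[[k]],
                file.path(out, "membrane", sprintf("r%d_c%d.tif", r, c)))
  }

  ex <- make_expression(scene$mask, n_genes, n_programs, counts_per_cell,
                        seed = seed + 3L,
                        displaced_fraction = displaced_fraction)
  track <- list(pitch_px = pitch_px, angle_deg = 0,
                line_width_px = line_width_px, phase = c(0, 0))
  # per-molecule truth mapped alongside the GEM (same lane filtering)
  em <- ex$emissions
  u <- em$y; v <- em$x
  half <- line_width_px / 2
  du <- abs(((u + pitch_px / 2) %% pitch_px) - pitch_px / 2)
  dv <- abs(((v + pitch_px / 2) %% pitch_px) - pitch_px / 2)
  kept <- !(du <= half | dv <= half)
  em <- em[kept]
  p <- st_apply(transform, em$y, em$x)
  em$map_x <- as.integer(round(p$x)); em$map_y <- as.integer(round(p$y))

  pair <- make_registered_pair(ex$molecules, transform, track = track)
  write_gem(pair$molecules, file.path(out, "data.gem.tsv"))

  mask_map <- apply_transform(scene$mask, transform, dim(pair$map),
                              interpolation = "nearest")
  mask_map <- matrix(as.integer(mask_map), nrow(mask_map), ncol(mask_map))
  write_mask(scene$mask, file.path(out, "truth", "mask.tif"))
  write_mask(mask_map, file.path(out, "truth", "mask_map.tif"))
  chip_pitch <- transform$scale * pitch_px
  jsonlite::write_json(
    list(scale = transform$scale, rotation_deg = transform$rotation_deg,
         flip = transform$flip, ty = transform$ty, tx = transform$tx,
         chip_pitch_spots = chip_pitch, stain_offset = c(-sy, -sx),
         nuclei_tile_offsets = gn$offsets, membrane_tile_offsets = gm$offsets),
    file.path(out, "truth", "transform.json"), auto_unbox = TRUE, digits = NA)
  utils::write.table(
    data.frame(cell = sort(unique(scene$mask[scene$mask > 0])),
               program = ex$programs),
    file.path(out, "truth", "programs.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  data.table::fwrite(
    em[, c("cell", "gene", "map_x", "map_y", "count", "displaced")],
    file.path(out, "truth", "emissions.tsv"), sep = "\t")

  invisible(list(mask = scene$mask, mask_map = mask_map,
                 molecules = pair$molecules, emissions = em,
                 programs = ex$programs, transform = transform,
                 chip_pitch_spots = chip_pitch,
                 nuclei_offsets = gn$offsets, membrane_offsets = gm$offsets))
}
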
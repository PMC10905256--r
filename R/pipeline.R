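#' Build a pipeline configuration
#'
#' Collects paths and stage parameters for [run_pipeline()].  Any
#' argument may also be supplied through a flat `key = value` text file
#' via [read_config()]; explicit arguments win.
#'
#' @param nuclei_tiles,membrane_tiles Directories of stain tile images
#'   named `r{row}_c{col}.tif` (or single-image paths).
#' @param gem Path to the GEM TSV.
#' @param tissue Optional tissue mask image path, or `"auto"` for the
#'   built-in intensity-threshold fallback.
#' @param out Output directory.
#' @param rows,cols,overlap Tile grid layout and overlap fraction.
#' @param chip_pitch_spots Track-line pitch in map units (chip
#'   metadata; required for registration).
#' @param factor Stage-1 subsampling factor.
#' @param pre_registered If `TRUE`, stage-1 stain registration is
#'   skipped (multi-channel microscope case): the offset is zero.
#' @param diameters Candidate cell diameters (px).
#' @param tile_size,overlap_px Segmentation tiling parameters.
#' @param gmm If `TRUE`, rescue extra-cellular molecules
#'   ([gmm_assign_outside()]).  Off by default: boundary stains are
#'   tightly packed and rescue is rarely worth the cost.
#' @param max_radius_px Rescue radius (NULL = 3x mean cell radius).
#' @param mito_prefixes Mitochondrial gene-id prefixes for QC.
#' @param qc If `TRUE`, apply [qc_filter()] to the profile.
#' @param gt_mask Optional ground-truth mask path; triggers
#'   segmentation evaluation.
#' @param seed Integer seed echoed into the run log.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(nuclei_tiles, membrane_tiles, gem, out,
                            tissue = NULL, rows = 1L, cols = 1L,
                            overlap = 0.1, chip_pitch_spots = NULL,
                            factor = 4L, pre_registered = FALSE,
                            diameters = c(20L, 30L, 40L, 60L),
                            tile_size = 2048L, overlap_px = 128L,
                            gmm = FALSE, max_radius_px = NULL,
                            mito_prefixes = c("mt-"), qc = TRUE,
                            gt_mask = NULL, seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a flat key = value configuration file
#'
#' Lines are `key = value`; `#` starts a comment; vector values are
#' comma-separated.  Keys match [pipeline_config()] arguments.
#'
#' @param path Config file path.
#' @param ... Overrides applied after the file is read.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path, ...) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*=\\s*")
  vals <- stats::setNames(lapply(kv, function(p) {
    v <- strsplit(p[2], ",\\s*")[[1]]
    num <- suppressWarnings(as.numeric(v))
    if (!anyNA(num)) num
    else if (all(v %in% c("TRUE", "FALSE", "true", "false")))
      as.logical(toupper(v))
    else v
  }), vapply(kv, `[[`, "", 1L))
  over <- list(...)
  vals[names(over)] <- over
  do.call(pipeline_config, vals)
}

load_stain <- function(path, rows, cols, overlap) {
  if (dir.exists(path)) {
    tiles <- vector("list", rows * cols)
    for (r in seq_len(rows)) for (c in seq_len(cols)) {
      f <- list.files(path, pattern = sprintf("r%d_c%d\\.(tif|tiff|png)$", r, c),
                      full.names = TRUE)
      if (length(f) != 1L) stop("tile r", r, "_c", c, " not found in ", path)
      tiles[[(r - 1L) * cols + c]] <- read_image(f[1])
    }
    stitch_tiles(tile_grid(tiles, nrow = rows, ncol = cols, overlap = overlap))
  } else {
    list(mosaic = read_image(path), offsets = NULL)
  }
}

#' Run the full cell-binning pipeline
#'
#' Executes stitch, three-stage registration, tiled segmentation and
#' molecule labeling in order, writing every intermediate (mosaics,
#' transform JSON, registered membrane, cell mask, profile, optional
#' metrics) plus a `run.log` with the configuration echo, package
#' version and per-stage timings.  Re-running with identical config
#' and inputs reproduces identical outputs.  A stage failure aborts
#' with the stage name; partial outputs are retained next to a
#' `FAILED` marker file.
#'
#' @param config A [pipeline_config()] (or path to a config file).
#' @return Invisibly, the output directory.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  cfg <- config
  for (p in c(cfg$nuclei_tiles, cfg$membrane_tiles, cfg$gem))
    if (!file.exists(p) && !dir.exists(p)) stop("input not found: ", p)
  if (!is.null(cfg$tissue) && !identical(cfg$tissue, "auto") &&
      !file.exists(cfg$tissue)) stop("input not found: ", cfg$tissue)
  if (!dir.exists(cfg$out)) dir.create(cfg$out, recursive = TRUE)
  failed <- file.path(cfg$out, "FAILED")
  if (file.exists(failed)) file.remove(failed)
  logpath <- file.path(cfg$out, "run.log")
  logcon <- file(logpath, open = "wt")
  on.exit(close(logcon), add = TRUE)
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    writeLines(msg, logcon); message(msg)
  }
  say("spatialcellbin ",
      as.character(utils::packageVersion("spatialcellbin")))
  for (k in setdiff(names(cfg), "")) {
    v <- cfg[[k]]
    say("config ", k, " = ",
        if (is.null(v)) "NULL" else paste(format(v), collapse = ","))
  }
  set.seed(cfg$seed)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    r <- tryCatch(expr, error = function(e) {
      writeLines(paste0("stage ", name, ": ", conditionMessage(e)), failed)
      say("stage ", name, " FAILED: ", conditionMessage(e))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    say(sprintf("stage %s done in %.1fs", name,
                as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    r
  }

  nuc <- stage("stitch-nuclei",
               load_stain(cfg$nuclei_tiles, cfg$rows, cfg$cols, cfg$overlap))
  mem <- stage("stitch-membrane",
               load_stain(cfg$membrane_tiles, cfg$rows, cfg$cols, cfg$overlap))
  write_image(nuc$mosaic, file.path(cfg$out, "mosaic_nuclei.tif"))
  write_image(mem$mosaic, file.path(cfg$out, "mosaic_membrane.tif"))

  molecules <- stage("read-gem", read_gem(cfg$gem))
  expr_map <- stage("gem-to-map", gem_to_map(molecules))

  offset <- stage("register-stains", {
    if (isTRUE(cfg$pre_registered))
      structure(list(dy = 0L, dx = 0L, confidence = 1),
                class = "offset_estimate")
    else register_stain_pair(mem$mosaic, nuc$mosaic, factor = cfg$factor)
  })
  if (is.null(cfg$chip_pitch_spots))
    stop("chip_pitch_spots is required (chip geometry metadata)")
  t_n <- stage("register-map",
               register_nuclei_to_map(nuc$mosaic, expr_map,
                                      cfg$chip_pitch_spots))
  t_m <- stage("compose-membrane", compose_membrane_transform(offset, t_n))
  jsonlite::write_json(
    list(scale = t_m$scale, rotation_deg = t_m$rotation_deg, flip = t_m$flip,
         ty = t_m$ty, tx = t_m$tx,
         stage1_offset = c(offset$dy, offset$dx),
         nuclei_transform = list(scale = t_n$scale,
                                 rotation_deg = t_n$rotation_deg,
                                 flip = t_n$flip, ty = t_n$ty, tx = t_n$tx)),
    file.path(cfg$out, "transform.json"), auto_unbox = TRUE, digits = NA)

  reg_mem <- stage("transform-membrane",
                   apply_transform(mem$mosaic, t_m, dim(expr_map)))
  write_image(reg_mem, file.path(cfg$out, "registered_membrane.tif"))

  tissue <- stage("tissue-mask", {
    if (is.null(cfg$tissue)) NULL
    else if (identical(cfg$tissue, "auto")) threshold_tissue(reg_mem)
    else read_mask(cfg$tissue)
  })
  if (!is.null(tissue)) write_mask(tissue, file.path(cfg$out, "tissue.tif"))

  mask <- stage("segment",
                segment_cells(reg_mem, diameters = cfg$diameters,
                              tile_size = cfg$tile_size,
                              overlap_px = cfg$overlap_px, tissue = tissue))
  write_mask(mask, file.path(cfg$out, "cellmask.tif"))

  lab <- stage("label", {
    a <- assign_molecules(molecules, mask)
    if (isTRUE(cfg$gmm))
      a <- gmm_assign_outside(molecules, mask, a$labels, cfg$max_radius_px)
    a
  })
  prof <- lab$profile
  if (isTRUE(cfg$qc))
    prof <- stage("qc", qc_filter(prof, mito_prefixes = cfg$mito_prefixes))
  write_cell_profile(prof, cfg$out, molecules = molecules,
                     labels = lab$labels)

  if (!is.null(cfg$gt_mask)) {
    gt <- read_mask(cfg$gt_mask)
    met <- stage("evaluate", evaluate_segmentation(gt, mask))
    jsonlite::write_json(met, file.path(cfg$out, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  say("pipeline complete: ",
      nrow(prof$matrix), " cells, ", ncol(prof$matrix), " genes, ",
      lab$unassigned_counts, " unassigned counts")
  invisible(cfg$out)
}
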
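#' Plan overlapping tiles covering an image
#'
#' Large registered stain images are segmented tile by tile.  Row and
#' column origins advance at stride `tile_size - overlap_px`; the last
#' tile in each direction is clamped to the border so the union of
#' tiles covers the image exactly.  Every tile's origin is recorded for
#' reassembly.
#'
#' @param shape Image `(h, w)`.
#' @param tile_size Tile edge in pixels.
#' @param overlap_px Overlap between adjacent tiles (must be less than
#'   half the tile size; it should exceed a cell diameter so border
#'   cells are seen whole by at least one tile).
#' @return Object of class `tile_plan`: list with `tile_size`,
#'   `overlap_px` and `tiles`, a data frame of 0-based
#'   `(origin_y, origin_x, height, width)`.
#' @export
plan_tiles <- function(shape, tile_size = 2048L, overlap_px = 128L) {
  if (tile_size <= 2L * overlap_px) stop("tile_size must exceed 2 * overlap_px")
  origins <- function(extent) {
    if (extent <= tile_size) return(0L)
    o <- seq(0L, extent - 1L, by = tile_size - overlap_px)
    o <- o[o < extent - overlap_px]
    o[o > extent - tile_size] <- extent - tile_size
    unique(pmin(o, extent - tile_size))
  }
  oy <- origins(shape[1]); ox <- origins(shape[2])
  tiles <- expand.grid(origin_y = oy, origin_x = ox)
  tiles <- tiles[order(tiles$origin_y, tiles$origin_x), , drop = FALSE]
  tiles$height <- pmin(tile_size, shape[1] - tiles$origin_y)
  tiles$width <- pmin(tile_size, shape[2] - tiles$origin_x)
  rownames(tiles) <- NULL
  structure(list(tile_size = as.integer(tile_size),
                 overlap_px = as.integer(overlap_px),
                 shape = as.integer(shape), tiles = tiles),
            class = "tile_plan")
}

#' Built-in classical membrane/wall segmentation backend
#'
#' Marker-controlled watershed on the boundary stain: the tile is
#' smoothed with a Gaussian scaled to `diameter_px / 8`; markers are
#' local minima of the smoothed boundary signal separated by at least
#' `diameter_px / 2`; regions grow from the markers over the boundary
#' intensity topography (seeded watershed); basins whose rim-to-interior
#' contrast is below `min_rim_contrast` of the dynamic range (flat
#' background, not membrane-walled cells) and regions smaller than
#' `(diameter_px / 4)^2` pixels become background.  Deterministic for
#' fixed inputs.  Deep backends (e.g. Cellpose-style models) can be
#' supplied instead through any function with the same
#' `(tile, diameter_px) -> label matrix` contract.
#'
#' @param tile Numeric matrix; cell boundaries are bright ridges.
#' @param diameter_px Expected cell diameter in pixels.
#' @param min_rim_contrast Minimum rim-minus-interior intensity contrast,
#'   as a fraction of the smoothed tile's dynamic range, for a basin to
#'   count as a cell.
#' @return Integer label matrix (0 = background), same shape as `tile`.
#' @export
classical_backend <- function(tile, diameter_px = 40L,
                              min_rim_contrast = 0.15) {
  validate_image(tile)
  if (max(tile) == min(tile))
    return(matrix(0L, nrow(tile), ncol(tile)))
  sm <- as.matrix(EBImage::gblur(tile, sigma = max(1, diameter_px / 8)))
  # markers: pixels attaining the local minimum of the boundary signal
  # within a disk of radius diameter/2 (separation >= diameter/2)
  r <- max(3L, as.integer(diameter_px / 2))
  brush <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
  mx <- max(sm)   # EBImage grayscale morphology expects nonnegative input
  minf <- mx - as.matrix(EBImage::dilate(mx - sm, brush))
  markers <- sm <= minf + 1e-9
  mlab <- as.matrix(EBImage::bwlabel(markers))
  if (max(mlab) == 0L) return(matrix(0L, nrow(tile), ncol(tile)))
  seg <- matrix(as.integer(as.matrix(
    EBImage::propagate(sm, mlab, lambda = 1e-4))), nrow(tile), ncol(tile))
  seg <- merge_shallow_ridges(seg, sm, min_rim_contrast * (max(sm) - min(sm)))

  # a genuine cell is a basin walled by a bright membrane ridge: score
  # each region by the contrast between its rim and its interior
  # minimum, and demote weak basins (flat background) to background
  h <- nrow(seg); w <- ncol(seg)
  rim <- matrix(FALSE, h, w)
  rim[-h, ] <- rim[-h, ] | (seg[-h, ] != seg[-1, ])
  rim[-1, ] <- rim[-1, ] | (seg[-1, ] != seg[-h, ])
  rim[, -w] <- rim[, -w] | (seg[, -w] != seg[, -1])
  rim[, -1] <- rim[, -1] | (seg[, -1] != seg[, -w])
  rim[c(1, h), ] <- TRUE; rim[, c(1, w)] <- TRUE
  K <- max(seg)
  rimmean <- vapply(split(sm[rim], seg[rim]), mean, numeric(1))
  # lower-quartile interior level: robust to bright spots inside the
  # basin (nuclear bleed-through)
  minval <- vapply(split(sm, as.vector(seg)),
                   function(v) unname(stats::quantile(v, 0.25)), numeric(1))
  contrast <- rimmean[names(minval)] - minval
  contrast[is.na(contrast)] <- 0
  dr <- max(sm) - min(sm)
  weak <- as.integer(names(contrast)[contrast < min_rim_contrast * dr])
  if (length(weak)) seg[seg %in% weak] <- 0L

  areas <- tabulate(seg[seg > 0], nbins = max(seg))
  small <- which(areas < (diameter_px / 4)^2)
  if (length(small)) seg[seg %in% small] <- 0L
  compact_labels(seg)
}

#' Select the cell diameter yielding the highest total cell area
#'
#' Runs the backend once per candidate diameter and keeps the
#' segmentation whose foreground (total cell area) is largest; ties go
#' to the smaller diameter.
#'
#' @param tile Numeric matrix.
#' @param diameters Integer vector of candidate diameters (px).
#' @param backend Function `(tile, diameter_px) -> label matrix`.
#' @return List with `mask` (the winning label matrix) and
#'   `diameter` (the chosen candidate).
#' @export
select_diameter <- function(tile, diameters = c(20L, 30L, 40L, 60L),
                            backend = classical_backend) {
  if (length(diameters) == 0L) stop("empty diameter list")
  diameters <- sort(as.integer(diameters))
  best <- NULL
  for (d in diameters) {
    m <- backend(tile, d)
    area <- sum(m > 0)
    if (is.null(best) || area > best$area)
      best <- list(mask = m, diameter = d, area = area)
  }
  list(mask = best$mask, diameter = best$diameter)
}

# merge watershed regions whose separating ridge is shallower than
# `min_depth` above the deeper of the two basin minima (union-find)
merge_shallow_ridges <- function(seg, sm, min_depth) {
  K <- max(seg)
  if (K < 2L) return(seg)
  h <- nrow(seg); w <- ncol(seg)
  minval <- rep(Inf, K)
  agg <- vapply(split(sm, as.vector(seg)),
                function(v) unname(stats::quantile(v, 0.25)), numeric(1))
  minval[as.integer(names(agg))[as.integer(names(agg)) > 0]] <-
    agg[as.integer(names(agg)) > 0]
  pair_stats <- function(a, b, va, vb) {
    sel <- a != b & a > 0L & b > 0L
    key <- paste(pmin(a[sel], b[sel]), pmax(a[sel], b[sel]))
    ridge <- (va[sel] + vb[sel]) / 2
    list(key = key, ridge = ridge)
  }
  p1 <- pair_stats(seg[-h, ], seg[-1, ], sm[-h, ], sm[-1, ])
  p2 <- pair_stats(seg[, -w], seg[, -1], sm[, -w], sm[, -1])
  key <- c(p1$key, p2$key); ridge <- c(p1$ridge, p2$ridge)
  if (!length(key)) return(seg)
  # median, not mean: a spurious (noise) boundary often touches genuine
  # ridges at its endpoints, which must not disguise it as a wall
  mean_ridge <- vapply(split(ridge, key), stats::median, numeric(1))
  parent <- seq_len(K)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_along(mean_ridge)) {
    ab <- as.integer(strsplit(names(mean_ridge)[i], " ")[[1]])
    depth <- mean_ridge[i] - max(minval[ab[1]], minval[ab[2]])
    if (depth < min_depth) {
      ra <- find(ab[1]); rb <- find(ab[2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(K), find, integer(1))
  out <- seg
  out[seg > 0] <- root[seg[seg > 0]]
  out
}

# 1-based bounding box of each label: list(label -> c(y0, y1, x0, x1))
label_bboxes <- function(mask) {
  idx <- which(mask > 0)
  if (!length(idx)) return(list())
  lab <- mask[idx]
  y <- (idx - 1L) %% nrow(mask) + 1L
  x <- (idx - 1L) %/% nrow(mask) + 1L
  out <- list()
  for (l in sort(unique(lab))) {
    s <- lab == l
    out[[as.character(l)]] <- c(min(y[s]), max(y[s]), min(x[s]), max(x[s]))
  }
  out
}

#' Merge per-tile segmentations into a full-image mask
#'
#' Cells whose bounding box touches a tile edge shared with a
#' neighbouring tile are dropped from that tile (the overlap guarantees
#' a neighbouring tile sees them whole); survivors are pasted at global
#' coordinates with fresh labels.  Where two surviving cells from
#' different tiles overlap with IoU > 0.5 they are duplicates of the
#' same cell: the copy whose centroid lies farther from its own tile's
#' border is kept.  Output labels are compacted to 1..K.
#'
#' @param masks List of label matrices, one per planned tile (same
#'   order as `plan$tiles`).
#' @param plan The [plan_tiles()] object used to cut the tiles.
#' @return Integer label matrix of shape `plan$shape`.
#' @export
merge_tiles <- function(masks, plan) {
  if (length(masks) != nrow(plan$tiles))
    stop("mask/plan count mismatch: ", length(masks), " masks for ",
         nrow(plan$tiles), " tiles")
  H <- plan$shape[1]; W <- plan$shape[2]
  out <- matrix(0L, H, W)
  info <- list()   # per pasted cell: centroid, border distance
  nextlab <- 0L
  for (k in seq_len(nrow(plan$tiles))) {
    tl <- plan$tiles[k, ]
    m <- masks[[k]]
    if (!all(dim(m) == c(tl$height, tl$width)))
      stop("mask ", k, " does not match its planned tile shape")
    th <- tl$height; tw <- tl$width
    interior <- c(top = tl$origin_y > 0L,
                  bottom = tl$origin_y + th < H,
                  left = tl$origin_x > 0L,
                  right = tl$origin_x + tw < W)
    bbs <- label_bboxes(m)
    for (lc in names(bbs)) {
      bb <- bbs[[lc]]
      if ((interior["top"] && bb[1] == 1L) ||
          (interior["bottom"] && bb[2] == th) ||
          (interior["left"] && bb[3] == 1L) ||
          (interior["right"] && bb[4] == tw)) next   # seen whole elsewhere
      l <- as.integer(lc)
      idx <- which(m == l)
      y <- (idx - 1L) %% th + 1L
      x <- (idx - 1L) %/% th + 1L
      gy <- y + tl$origin_y; gx <- x + tl$origin_x
      cy <- mean(gy); cx <- mean(gx)
      borderdist <- min(mean(y), th + 1 - mean(y), mean(x), tw + 1 - mean(x))
      gidx <- gy + (gx - 1L) * H
      hit <- out[gidx]
      newlab <- nextlab + 1L
      dominated <- FALSE
      for (ol in unique(hit[hit > 0])) {
        ov <- sum(hit == ol)
        iou <- ov / (length(gidx) + info[[ol]]$size - ov)
        if (iou > 0.5) {
          if (borderdist > info[[ol]]$borderdist) {
            out[out == ol] <- 0L       # replace the earlier duplicate
          } else dominated <- TRUE
        }
      }
      if (dominated) next
      out[gidx] <- newlab
      info[[newlab]] <- list(size = length(gidx), borderdist = borderdist)
      nextlab <- newlab
    }
  }
  compact_labels(out)
}

#' Tiled segmentation of a registered membrane/wall image
#'
#' Convenience wrapper: plans tiles, runs diameter selection per tile
#' with the given backend, merges, and optionally filters by a tissue
#' mask.
#'
#' @param image Registered membrane/wall image.
#' @param diameters Candidate cell diameters (px).
#' @param backend Segmentation backend function.
#' @param tile_size,overlap_px Tiling parameters (see [plan_tiles()]).
#' @param tissue Optional tissue mask ([threshold_tissue()] or external).
#' @return Integer cell label matrix.
#' @export
segment_cells <- function(image, diameters = c(20L, 30L, 40L, 60L),
                          backend = classical_backend,
                          tile_size = 2048L, overlap_px = 128L,
                          tissue = NULL) {
  plan <- plan_tiles(dim(image), tile_size, overlap_px)
  masks <- vector("list", nrow(plan$tiles))
  for (k in seq_len(nrow(plan$tiles))) {
    tl <- plan$tiles[k, ]
    tile <- image[tl$origin_y + seq_len(tl$height),
                  tl$origin_x + seq_len(tl$width), drop = FALSE]
    masks[[k]] <- select_diameter(tile, diameters, backend)$mask
  }
  mask <- merge_tiles(masks, plan)
  if (!is.null(tissue)) mask <- filter_by_tissue(mask, tissue)
  mask
}

#' Filter a cell mask by a tissue mask
#'
#' Cells with less than half their area on tissue foreground are
#' removed (the 0.5 boundary is kept); labels are compacted.
#'
#' @param mask Cell label matrix.
#' @param tissue Binary (or labelled) tissue matrix; foreground = > 0.
#' @return Filtered, compacted label matrix.
#' @export
filter_by_tissue <- function(mask, tissue) {
  if (!all(dim(mask) == dim(tissue))) stop("mask and tissue shapes differ")
  labs <- mask[mask > 0]
  if (!length(labs)) return(compact_labels(mask))
  intis <- tissue[mask > 0] > 0
  tot <- tabulate(labs, nbins = max(labs))
  ok <- tabulate(labs[intis], nbins = max(labs))
  drop <- which(tot > 0 & ok / pmax(tot, 1L) < 0.5)
  if (length(drop)) mask[mask %in% drop] <- 0L
  compact_labels(mask)
}

#' Simple intensity-threshold tissue mask
#'
#' Fallback tissue segmentation: Otsu threshold on a heavily smoothed
#' image, keeping the large connected foreground components (at least
#' 10% of the largest component's area).
#'
#' @param image Stain image.
#' @param sigma Smoothing scale; default `min(dim) / 20`.
#' @return Binary integer matrix (1 = tissue).
#' @export
threshold_tissue <- function(image, sigma = NULL) {
  validate_image(image)
  if (max(image) == min(image))
    return(matrix(0L, nrow(image), ncol(image)))
  if (is.null(sigma)) sigma <- min(dim(image)) / 20
  sm <- as.matrix(EBImage::gblur(image, sigma = sigma))
  sm <- (sm - min(sm)) / (max(sm) - min(sm))
  th <- EBImage::otsu(EBImage::Image(sm))
  fg <- sm > th
  lab <- as.matrix(EBImage::bwlabel(fg))
  if (max(lab) == 0L) return(matrix(0L, nrow(image), ncol(image)))
  areas <- tabulate(lab[lab > 0], nbins = max(lab))
  keep <- which(areas >= 0.1 * max(areas))
  matrix(as.integer(lab %in% keep), nrow(image), ncol(image))
}
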
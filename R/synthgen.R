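# Deterministic synthetic fixtures emulating a Stereo-seq-style capture:
# Voronoi cell layouts with membrane boundaries and nuclei blobs, the
# chip's crossed track-line marker, jittered tile grids, known similarity
# transforms between stain and expression frames, and per-cell gene
# programs.  All randomness is driven by an explicit seed so outputs are
# reproducible bit-for-bit.

#' Generate a synthetic tissue scene: cell mask, membrane and nuclei stains
#'
#' Cell centroids are placed by seeded dart-throwing (Poisson-disc-like)
#' sampling at spacing about `mean_diameter_px` inside a circular tissue
#' disk; cells are the Voronoi regions of the centroids clipped to the
#' disk.  The membrane/wall image is a smoothed indicator of the region
#' boundaries plus a faint copy of the nuclei signal (fluorescence
#' channels always carry nuclear/cytoplasmic bleed-through, which is
#' also what makes cross-stain registration possible); the nuclei image
#' is a sum of Gaussian blobs at the centroids.  Both get additive
#' seeded Gaussian noise with standard deviation 5% of the dynamic
#' range.
#'
#' @param n_cells Number of cells (>= 1).
#' @param shape `(h, w)` of the rasters.
#' @param mean_diameter_px Target mean cell diameter in pixels.
#' @param seed Integer seed.
#' @param noise_sd Noise standard deviation as a fraction of dynamic range.
#' @param nuclei_bleed Fraction of the nuclei signal bleeding into the
#'   membrane channel.
#' @return List with `mask` (integer label matrix, 0 background),
#'   `membrane`, `nuclei` (numeric matrices in `[0, ~1]`) and
#'   `centroids` (n x 2 matrix of (y, x)).
#' @export
make_cells <- function(n_cells, shape = c(512L, 512L), mean_diameter_px = 40,
                       seed = 1L, noise_sd = 0.05, nuclei_bleed = 0.1) {
  if (n_cells < 1) stop("n_cells must be >= 1")
  h <- shape[1]; w <- shape[2]
  set.seed(seed)
  cy0 <- (h - 1) / 2; cx0 <- (w - 1) / 2
  radius <- 0.45 * min(h, w)
  spacing <- 0.8 * mean_diameter_px
  pts <- matrix(NA_real_, 0L, 2L)
  tries <- 0L
  while (nrow(pts) < n_cells) {
    tries <- tries + 1L
    if (tries > 200L * n_cells)
      stop("shape too small to place ", n_cells, " cells at spacing ", spacing)
    r <- radius * sqrt(runif(1)) * 0.95
    th <- runif(1, 0, 2 * pi)
    p <- c(cy0 + r * sin(th), cx0 + r * cos(th))
    if (nrow(pts) == 0L ||
        min((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2) >= spacing^2)
      pts <- rbind(pts, p)
  }
  # Voronoi labels inside the tissue disk (running nearest-centroid scan)
  X <- rep(0:(w - 1L), each = h)
  Y <- rep(0:(h - 1L), times = w)
  bestd <- rep(Inf, h * w); bestl <- integer(h * w)
  for (k in seq_len(n_cells)) {
    d <- (Y - pts[k, 1])^2 + (X - pts[k, 2])^2
    upd <- d < bestd
    bestd[upd] <- d[upd]; bestl[upd] <- k
  }
  indisk <- (Y - cy0)^2 + (X - cx0)^2 <= radius^2
  lab <- ifelse(indisk, bestl, 0L)
  mask <- matrix(as.integer(lab), h, w)

  # membrane: boundary indicator of the labelled partition (incl. disk edge)
  edge <- matrix(FALSE, h, w)
  edge[-h, ] <- edge[-h, ] | (mask[-h, ] != mask[-1, ])
  edge[-1, ] <- edge[-1, ] | (mask[-1, ] != mask[-h, ])
  edge[, -w] <- edge[, -w] | (mask[, -w] != mask[, -1])
  edge[, -1] <- edge[, -1] | (mask[, -1] != mask[, -w])
  edge <- edge & (mask > 0 | shift_mask_any(mask))
  membrane <- as.matrix(EBImage::gblur(edge * 1.0, sigma = 1.2))
  membrane <- membrane / max(membrane)

  # nuclei: sharp-edged disks at the centroids (DAPI/ssDNA nuclei have
  # defined borders; the edge sharpness is what cross-stain
  # registration keys on), softened by a 1 px blur
  rad <- mean_diameter_px / 5
  nuclei <- matrix(0, h, w)
  for (k in seq_len(n_cells)) {
    dy <- Y - pts[k, 1]; dx <- X - pts[k, 2]
    keep <- dy^2 + dx^2 <= rad^2
    nuclei[keep] <- 1
  }
  nuclei <- as.matrix(EBImage::gblur(nuclei, sigma = 1))

  membrane <- membrane + nuclei_bleed * nuclei +
    matrix(rnorm(h * w, 0, noise_sd), h, w)
  nuclei <- nuclei + matrix(rnorm(h * w, 0, noise_sd), h, w)
  list(mask = mask, membrane = pmax(membrane, 0), nuclei = pmax(nuclei, 0),
       centroids = unname(pts))
}

# TRUE where any 4-neighbour is foreground (used to keep the disk rim)
shift_mask_any <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  m <- mask > 0
  out <- matrix(FALSE, h, w)
  out[-1, ] <- out[-1, ] | m[-h, ]
  out[-h, ] <- out[-h, ] | m[-1, ]
  out[, -1] <- out[, -1] | m[, -w]
  out[, -w] <- out[, -w] | m[, -1]
  out
}

#' Superimpose a crossed track-line grid on an image
#'
#' Adds two orthogonal families of periodic bright lines (the chip's
#' registration fiducial) at the given pitch and orientation.  Line
#' intensity is 30% of the image's dynamic range, added.
#'
#' @param image Numeric matrix.
#' @param pitch_px Line period in pixels (> 2 * line_width_px).
#' @param angle_deg Orientation of one line family (0 = horizontal).
#' @param line_width_px Full line width in pixels.
#' @param phase `(py, px)` offsets of the line nearest the origin.
#' @return The image with lines added.
#' @export
add_track_lines <- function(image, pitch_px = 100, angle_deg = 0,
                            line_width_px = 3L, phase = c(0, 0)) {
  validate_image(image)
  if (pitch_px <= 2 * line_width_px) stop("pitch must exceed twice the line width")
  h <- nrow(image); w <- ncol(image)
  a <- angle_deg * pi / 180
  X <- rep(0:(w - 1L), each = h)
  Y <- rep(0:(h - 1L), times = w)
  u <- Y * cos(a) - X * sin(a)
  v <- X * cos(a) + Y * sin(a)
  half <- line_width_px / 2
  du <- abs(((u - phase[1] + pitch_px / 2) %% pitch_px) - pitch_px / 2)
  dv <- abs(((v - phase[2] + pitch_px / 2) %% pitch_px) - pitch_px / 2)
  lane <- du <= half | dv <= half
  dr <- max(image) - min(image)
  if (dr == 0) dr <- 1
  image + matrix(0.3 * dr * lane, h, w)
}

#' Cut an image into a jittered overlapping tile grid
#'
#' Tiles are cropped at nominal grid positions perturbed by seeded
#' uniform integer jitter, emulating microscope stage error.  The true
#' global offsets (crop positions relative to the top-left-most crop)
#' are returned for use as a stitching oracle.
#'
#' @param image Source image matrix.
#' @param rows,cols Grid dimensions.
#' @param overlap_fraction Nominal overlap fraction between neighbours.
#' @param jitter_px Maximum absolute jitter per axis (integer pixels).
#' @param seed Integer seed.
#' @return List with `grid` (a [tile_grid()]) and `offsets` (data frame
#'   `row`, `col`, `dy`, `dx`).
#' @export
make_tile_grid <- function(image, rows = 3L, cols = 3L, overlap_fraction = 0.1,
                           jitter_px = 0L, seed = 1L) {
  validate_image(image)
  set.seed(seed)
  H <- nrow(image); W <- ncol(image)
  th <- floor(H / (rows - (rows - 1) * overlap_fraction))
  tw <- floor(W / (cols - (cols - 1) * overlap_fraction))
  ovh <- round(th * overlap_fraction); ovw <- round(tw * overlap_fraction)
  if (min(ovh, ovw) - jitter_px < 4) stop("overlap after jitter < 4 px")
  oy <- matrix(0L, rows, cols); ox <- matrix(0L, rows, cols)
  for (r in seq_len(rows)) for (c in seq_len(cols)) {
    y0 <- (r - 1L) * (th - ovh); x0 <- (c - 1L) * (tw - ovw)
    if (jitter_px > 0 && !(r == 1L && c == 1L)) {
      y0 <- y0 + sample(-jitter_px:jitter_px, 1L)
      x0 <- x0 + sample(-jitter_px:jitter_px, 1L)
    }
    y0 <- max(0L, min(y0, H - th)); x0 <- max(0L, min(x0, W - tw))
    oy[r, c] <- y0; ox[r, c] <- x0
  }
  tiles <- vector("list", rows * cols)
  for (r in seq_len(rows)) for (c in seq_len(cols)) {
    tiles[[(r - 1L) * cols + c]] <-
      image[oy[r, c] + seq_len(th), ox[r, c] + seq_len(tw)]
  }
  offsets <- data.frame(row = rep(seq_len(rows), each = cols),
                        col = rep(seq_len(cols), times = rows),
                        dy = as.vector(t(oy)) - oy[1, 1],
                        dx = as.vector(t(ox)) - ox[1, 1])
  list(grid = tile_grid(tiles, nrow = rows, ncol = cols,
                        overlap = overlap_fraction),
       offsets = offsets)
}

#' Simulate per-cell gene expression as a molecule table
#'
#' Each cell is assigned one of `n_programs` gene programs (disjoint
#' enriched gene sets, 8x enriched over background); its total molecule
#' count is Poisson with mean `counts_per_cell`; molecule spots are
#' sampled uniformly from the cell's pixels.  A fraction of molecules is
#' displaced to background pixels within `displace_radius_px` of their
#' cell to exercise extracellular rescue.  3% of genes (at least one)
#' are flagged mitochondrial by the id prefix `mt-`.
#'
#' @param mask Ground-truth label mask.
#' @param n_genes Number of genes.
#' @param n_programs Number of gene programs.
#' @param counts_per_cell Mean total molecules per cell.
#' @param seed Integer seed.
#' @param displaced_fraction Fraction of molecules displaced outside
#'   their cell (default 0.05).
#' @param displace_radius_px Maximum displacement distance (default 10).
#' @return List with `molecules` (a [molecule_table()]), `programs`
#'   (integer program per cell), `gene_ids`, and `emissions` (the
#'   per-molecule truth log: `cell`, `gene`, `x`, `y`, `count`,
#'   `displaced`).
#' @export
make_expression <- function(mask, n_genes = 100L, n_programs = 3L,
                            counts_per_cell = 300, seed = 1L,
                            displaced_fraction = 0.05,
                            displace_radius_px = 10) {
  labs <- sort(unique(mask[mask > 0]))
  if (length(labs) < 1L) stop("mask has no cells")
  set.seed(seed)
  n_mito <- max(1L, round(0.03 * n_genes))
  gene_ids <- c(paste0("mt-", seq_len(n_mito)),
                sprintf("gene%03d", seq_len(n_genes - n_mito)))
  prog_genes <- split(sample(which(!startsWith(gene_ids, "mt-"))),
                      rep(seq_len(n_programs),
                          length.out = sum(!startsWith(gene_ids, "mt-"))))
  programs <- sample(seq_len(n_programs), length(labs), replace = TRUE)

  h <- nrow(mask); w <- ncol(mask)
  bg <- which(mask == 0)
  emit <- vector("list", length(labs))
  for (i in seq_along(labs)) {
    lab <- labs[i]
    px <- which(mask == lab)
    total <- rpois(1L, counts_per_cell)
    if (total == 0L) next
    wts <- rep(1, n_genes)
    wts[prog_genes[[programs[i]]]] <- 8
    g <- sample.int(n_genes, total, replace = TRUE, prob = wts)
    at <- px[sample.int(length(px), total, replace = TRUE)]
    y <- (at - 1L) %% h
    x <- (at - 1L) %/% h
    disp <- runif(total) < displaced_fraction
    if (any(disp) && length(bg)) {
      for (j in which(disp)) {
        # nearest background pixels within the displacement radius
        yy <- y[j] + sample(-displace_radius_px:displace_radius_px, 25L, TRUE)
        xx <- x[j] + sample(-displace_radius_px:displace_radius_px, 25L, TRUE)
        ok <- yy >= 0 & yy < h & xx >= 0 & xx < w
        yy <- yy[ok]; xx <- xx[ok]
        isbg <- mask[cbind(yy + 1L, xx + 1L)] == 0L
        if (any(isbg)) {
          pick <- which(isbg)[1]
          y[j] <- yy[pick]; x[j] <- xx[pick]
        } else disp[j] <- FALSE
      }
    }
    emit[[i]] <- data.table::data.table(cell = lab, gene = gene_ids[g],
                                        x = x, y = y, count = 1L,
                                        displaced = disp)
  }
  emissions <- data.table::rbindlist(emit)
  if (nrow(emissions) == 0L) {
    return(list(molecules = molecule_table(), programs = programs,
                gene_ids = gene_ids, emissions = emissions))
  }
  list(molecules = molecule_table(emissions$gene, emissions$x,
                                  emissions$y, emissions$count),
       programs = programs, gene_ids = gene_ids, emissions = emissions)
}

#' Map a synthetic scene's molecules into expression-map space
#'
#' Applies a known similarity transform (stain frame to map frame) to
#' the molecule coordinates, re-bins them at integer spots, and renders
#' the expression map raster.  Optionally the chip track lines are
#' emulated: molecules captured on a track lane are removed (the
#' physical marker occludes capture spots), leaving the molecule-free
#' lanes in the map that the registration detector looks for.  The lane
#' geometry is given in the stain frame — both the stain image and the
#' map show the same physical chip marker, so the map's lanes appear at
#' the transformed positions automatically.  Count totals are conserved
#' between the returned table and map.
#'
#' @param molecules A [molecule_table()] in stain-frame coordinates.
#' @param transform The true stain-to-map [similarity_transform()].
#' @param track Optional list `(pitch_px, angle_deg, line_width_px,
#'   phase)` describing the track lanes in *stain* coordinates (the
#'   parameters passed to [add_track_lines()] on the nuclei image), or
#'   `NULL` for no lanes.
#' @param shape Optional map `(h, w)`; default fits the mapped spots.
#' @return List with `map` (numeric matrix), `molecules` (transformed,
#'   re-binned [molecule_table()]).
#' @export
make_registered_pair <- function(molecules, transform, track = NULL,
                                 shape = NULL) {
  if (nrow(molecules) == 0L) stop("empty molecule table")
  keep <- rep(TRUE, nrow(molecules))
  if (!is.null(track)) {
    a <- track$angle_deg * pi / 180
    u <- molecules$y * cos(a) - molecules$x * sin(a)
    v <- molecules$x * cos(a) + molecules$y * sin(a)
    half <- track$line_width_px / 2
    ph <- if (is.null(track$phase)) c(0, 0) else track$phase
    du <- abs(((u - ph[1] + track$pitch_px / 2) %% track$pitch_px) - track$pitch_px / 2)
    dv <- abs(((v - ph[2] + track$pitch_px / 2) %% track$pitch_px) - track$pitch_px / 2)
    keep <- !(du <= half | dv <= half)
  }
  p <- st_apply(transform, molecules$y[keep], molecules$x[keep])
  X <- round(p$x); Y <- round(p$y)
  if (length(X) && (min(X) < 0 || min(Y) < 0))
    stop("transform maps spots to negative coordinates; adjust the translation")
  mt <- molecule_table(molecules$gene[keep], X, Y, molecules$count[keep])
  map <- gem_to_map(mt, shape = shape)
  list(map = map, molecules = mt)
}
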
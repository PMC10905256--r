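#' Estimate the translation between two images by FFT phase correlation
#'
#' Computes the normalised cross-power spectrum of the two images and
#' locates the peak of its inverse transform.  The returned `(dy, dx)`
#' is the integer translation such that `image_b` is (circularly)
#' `image_a` shifted down by `dy` rows and right by `dx` columns.
#' Confidence is the normalised phase-correlation peak height, clipped
#' to `[0, 1]`: exactly 1 for a pure circular translation, near 0 for
#' unrelated images (the peak of the correlation surface measures how
#' much of the cross-power spectrum is explained by one translation).
#'
#' @param image_a,image_b Numeric matrices of equal shape.
#' @param max_shift Optional bound: the peak search is restricted to
#'   `|dy|, |dx| <= max_shift`.
#' @param window Optional list `(dy, dx, halfwidth)` restricting the
#'   search to a window around a prior estimate (used for coarse-to-fine
#'   refinement).
#' @param subpixel If `TRUE`, also return `dy_sub`/`dx_sub`, the peak
#'   location refined by parabolic interpolation.
#' @return List of class `offset_estimate` with `dy`, `dx`,
#'   `confidence` (and `dy_sub`, `dx_sub` if requested).
#' @export
phase_correlation_offset <- function(image_a, image_b, max_shift = NULL,
                                     window = NULL, subpixel = FALSE) {
  validate_image(image_a); validate_image(image_b)
  if (!all(dim(image_a) == dim(image_b))) stop("images must have identical shapes")
  if (max(image_a) == min(image_a) || max(image_b) == min(image_b))
    stop("degenerate input: constant image has no correlation peak")
  h <- nrow(image_a); w <- ncol(image_a)
  Fa <- stats::fft(image_a); Fb <- stats::fft(image_b)
  R <- Fb * Conj(Fa)
  R <- R / pmax(Mod(R), .Machine$double.eps)
  surf <- Re(stats::fft(R, inverse = TRUE)) / (h * w)

  # wrapped shift value of each surface index
  dys <- ifelse(seq_len(h) - 1 <= h / 2, seq_len(h) - 1, seq_len(h) - 1 - h)
  dxs <- ifelse(seq_len(w) - 1 <= w / 2, seq_len(w) - 1, seq_len(w) - 1 - w)
  allowed <- matrix(TRUE, h, w)
  if (!is.null(max_shift)) {
    allowed <- outer(abs(dys) <= max_shift, abs(dxs) <= max_shift, "&")
  }
  if (!is.null(window)) {
    wrapdist <- function(v, c0, n) pmin(abs(v - c0), n - abs(v - c0))
    allowed <- allowed & outer(wrapdist(dys, window$dy, h) <= window$halfwidth,
                               wrapdist(dxs, window$dx, w) <= window$halfwidth, "&")
  }
  surf_allowed <- surf
  surf_allowed[!allowed] <- -Inf
  pk <- which.max(surf_allowed)
  pi_ <- (pk - 1L) %% h + 1L
  pj <- (pk - 1L) %/% h + 1L
  peak <- surf[pi_, pj]
  out <- list(dy = dys[pi_], dx = dxs[pj],
              confidence = min(max(peak, 0), 1))
  if (subpixel) {
    parab <- function(m, c0, p) {
      # 1-D parabolic refinement from the three wrapped neighbours
      den <- m - 2 * c0 + p
      if (c0 >= m && c0 >= p && den < 0) 0.5 * (m - p) / den else 0
    }
    im <- (pi_ - 2L) %% h + 1L; ip <- pi_ %% h + 1L
    jm <- (pj - 2L) %% w + 1L; jp <- pj %% w + 1L
    out$dy_sub <- out$dy + parab(surf[im, pj], peak, surf[ip, pj])
    out$dx_sub <- out$dx + parab(surf[pi_, jm], peak, surf[pi_, jp])
  }
  class(out) <- "offset_estimate"
  out
}

#' @export
print.offset_estimate <- function(x, ...) {
  cat(sprintf("offset_estimate: dy %d, dx %d (confidence %.3f)\n",
              x$dy, x$dx, x$confidence))
  invisible(x)
}

#' Construct a tile grid
#'
#' @param tiles List of image matrices in row-major order, or a list of
#'   lists (`tiles[[row]][[col]]`).
#' @param nrow,ncol Grid dimensions (required for flat row-major lists).
#' @param overlap Nominal overlap fraction between adjacent tiles,
#'   in (0, 0.5).
#' @return Object of class `tile_grid`.
#' @export
tile_grid <- function(tiles, nrow = NULL, ncol = NULL, overlap = 0.1) {
  if (is.list(tiles[[1]])) {
    nrow <- length(tiles); ncol <- length(tiles[[1]])
    tiles <- unlist(lapply(tiles, identity), recursive = FALSE)
    tiles <- tiles[order(rep(seq_len(nrow), each = ncol))]  # keep row-major
  }
  if (is.null(nrow) || is.null(ncol)) stop("nrow and ncol required")
  if (length(tiles) != nrow * ncol) stop("grid with missing tile: expected ",
                                         nrow * ncol, " tiles, got ", length(tiles))
  shp <- dim(tiles[[1]])
  for (t in tiles) {
    validate_image(t)
    if (!all(dim(t) == shp)) stop("inconsistent tile shapes")
  }
  if (overlap <= 0 || overlap >= 0.5) stop("overlap must be in (0, 0.5)")
  structure(list(tiles = tiles, nrow = nrow, ncol = ncol, overlap = overlap),
            class = "tile_grid")
}

grid_tile <- function(grid, r, c) grid$tiles[[(r - 1L) * grid$ncol + c]]

# offset of tile B relative to tile A from their nominal overlap strips.
# The strips are zero-padded to twice their width along the narrow axis,
# turning the circular correlation into a linear one: stage jitter can
# displace two adjacent tiles by more than half the strip width, which
# a circular correlation could not disambiguate.
# Returns list(dy, dx, confidence) where B's global origin = A's + (dy, dx).
pair_offset <- function(A, B, direction, overlap, conf_threshold) {
  th <- nrow(A); tw <- ncol(A)
  if (direction == "h") {
    ov <- max(4L, round(overlap * tw))
    stripA <- A[, (tw - ov + 1L):tw, drop = FALSE]
    stripB <- B[, 1:ov, drop = FALSE]
    padA <- cbind(stripA, matrix(0, th, ov))
    padB <- cbind(stripB, matrix(0, th, ov))
    nominal <- c(0L, tw - ov)
  } else {
    ov <- max(4L, round(overlap * th))
    stripA <- A[(th - ov + 1L):th, , drop = FALSE]
    stripB <- B[1:ov, , drop = FALSE]
    padA <- rbind(stripA, matrix(0, ov, tw))
    padB <- rbind(stripB, matrix(0, ov, tw))
    nominal <- c(th - ov, 0L)
  }
  ms <- max(2L, ov - 2L)
  est <- tryCatch(
    phase_correlation_offset(padA, padB, max_shift = ms),
    error = function(e) NULL)
  if (is.null(est) || est$confidence < conf_threshold) {
    return(list(dy = nominal[1], dx = nominal[2], confidence = 0,
                fallback = TRUE))
  }
  # stripB = shift(stripA, est) in strip frame; convert to tile origins:
  # B_origin = A_origin + nominal - est
  list(dy = nominal[1] - est$dy, dx = nominal[2] - est$dx,
       confidence = est$confidence, fallback = FALSE)
}

#' Stitch a tile grid into a mosaic
#'
#' Pairwise offsets between every horizontally and vertically adjacent
#' tile pair are estimated by phase correlation on their nominal overlap
#' strips.  Pairs whose correlation confidence falls below
#' `conf_threshold` fall back to the nominal offset implied by the tile
#' size and overlap fraction.  Global tile offsets are obtained by
#' anchoring tile (1,1) at the origin and accumulating offsets along a
#' maximum-confidence spanning tree of the grid adjacency graph.
#' Overlapping pixels are resolved by letting the later tile (row-major
#' order) win, keeping boundaries unblurred.
#'
#' @param grid A [tile_grid()].
#' @param conf_threshold Confidence below which a pair falls back to its
#'   nominal offset (default 0.3).
#' @return List with `mosaic` (numeric matrix) and `offsets` (data frame
#'   `row`, `col`, `dy`, `dx` of each tile's global offset, origin at
#'   the top-left-most tile).
#' @export
stitch_tiles <- function(grid, conf_threshold = 0.3) {
  if (!inherits(grid, "tile_grid")) stop("grid must be a tile_grid")
  nr <- grid$nrow; nc <- grid$ncol
  n <- nr * nc
  id <- function(r, c) (r - 1L) * nc + c

  # collect edges of the grid adjacency graph
  edges <- list()
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (c < nc) {
      po <- pair_offset(grid_tile(grid, r, c), grid_tile(grid, r, c + 1L),
                        "h", grid$overlap, conf_threshold)
      edges[[length(edges) + 1L]] <- list(a = id(r, c), b = id(r, c + 1L), o = po)
    }
    if (r < nr) {
      po <- pair_offset(grid_tile(grid, r, c), grid_tile(grid, r + 1L, c),
                        "v", grid$overlap, conf_threshold)
      edges[[length(edges) + 1L]] <- list(a = id(r, c), b = id(r + 1L, c), o = po)
    }
  }

  # maximum-confidence spanning tree (Prim), anchored at tile (1,1)
  off <- matrix(NA_real_, n, 2L)
  off[1L, ] <- c(0, 0)
  intree <- rep(FALSE, n); intree[1L] <- TRUE
  while (!all(intree)) {
    best <- NULL; bestconf <- -1
    for (e in edges) {
      if (intree[e$a] && !intree[e$b] && e$o$confidence >= bestconf) {
        best <- list(v = e$b, base = e$a, d = c(e$o$dy, e$o$dx)); bestconf <- e$o$confidence
      } else if (intree[e$b] && !intree[e$a] && e$o$confidence >= bestconf) {
        best <- list(v = e$a, base = e$b, d = -c(e$o$dy, e$o$dx)); bestconf <- e$o$confidence
      }
    }
    off[best$v, ] <- off[best$base, ] + best$d
    intree[best$v] <- TRUE
  }

  off[, 1] <- off[, 1] - min(off[, 1])
  off[, 2] <- off[, 2] - min(off[, 2])
  th <- nrow(grid$tiles[[1]]); tw <- ncol(grid$tiles[[1]])
  H <- max(off[, 1]) + th; W <- max(off[, 2]) + tw
  mosaic <- matrix(0, H, W)
  for (k in seq_len(n)) {   # row-major placement; later tile wins
    mosaic[off[k, 1] + seq_len(th), off[k, 2] + seq_len(tw)] <- grid$tiles[[k]]
  }
  offsets <- data.frame(row = rep(seq_len(nr), each = nc),
                        col = rep(seq_len(nc), times = nr),
                        dy = off[, 1], dx = off[, 2])
  list(mosaic = mosaic, offsets = offsets)
}
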
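#' Assign molecules to cells using the registered cell mask
#'
#' Each molecule record takes the label of the mask pixel at its spot
#' (0 for background or outside the mask canvas).  Counts are conserved
#' exactly: assigned plus unassigned counts equal the table total.
#'
#' @param molecules A canonical [molecule_table()] in the registered
#'   (mask) frame.
#' @param mask Integer cell label matrix.
#' @return List with `profile` (a [cell_profile()] over the labels
#'   present), `labels` (integer per record, 0 = unassigned) and
#'   `unassigned_counts`.
#' @export
assign_molecules <- function(molecules, mask) {
  validate_mask(mask)
  h <- nrow(mask); w <- ncol(mask)
  n <- nrow(molecules)
  labels <- integer(n)
  if (n) {
    inside <- molecules$y < h & molecules$x < w
    labels[inside] <- mask[cbind(molecules$y[inside] + 1L,
                                 molecules$x[inside] + 1L)]
  }
  profile <- build_profile(molecules, labels, mask)
  list(profile = profile, labels = labels,
       unassigned_counts = sum(molecules$count[labels == 0L]))
}

# cell-by-gene sparse profile from per-record labels + mask metadata
build_profile <- function(molecules, labels, mask) {
  genes <- sort(unique(molecules$gene))
  cells <- sort(unique(labels[labels > 0L]))
  regions <- mask_regions(mask)
  if (length(cells) == 0L || length(genes) == 0L) {
    m <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                              dims = c(length(cells), length(genes)),
                              dimnames = list(as.character(cells), genes))
    return(cell_profile(m, regions[regions$label %in% cells, , drop = FALSE]))
  }
  sel <- labels > 0L
  i <- match(labels[sel], cells)
  j <- match(molecules$gene[sel], genes)
  m <- Matrix::sparseMatrix(i = i, j = j, x = as.numeric(molecules$count[sel]),
                            dims = c(length(cells), length(genes)),
                            dimnames = list(as.character(cells), genes))
  cell_profile(m, regions[regions$label %in% cells, , drop = FALSE])
}

#' Rescue extra-cellular molecules by per-cell Gaussian density
#'
#' Optional step after [assign_molecules()]: each cell with at least 3
#' assigned records is summarised as a 2-D Gaussian (count-weighted
#' mean and covariance of its molecule coordinates, ridge-regularised
#' with `1e-3` px^2) weighted by its total counts.  Every unassigned
#' record within `max_radius_px` of at least one eligible cell centroid
#' is given the label of the cell with the highest
#' `weight x density` at its coordinate; farther records stay
#' unassigned.  Records already inside a cell are never relabelled.
#' Cell membranes/walls are usually tightly packed with few outside
#' molecules, so this rescue is off by default in the pipeline.
#'
#' @param molecules Canonical [molecule_table()].
#' @param mask Cell label matrix.
#' @param labels Per-record labels from [assign_molecules()].
#' @param max_radius_px Maximum centroid distance for rescue; default
#'   3x the mean equivalent cell radius from the mask.
#' @return List with updated `profile`, `labels`, `unassigned_counts`.
#' @export
gmm_assign_outside <- function(molecules, mask, labels, max_radius_px = NULL) {
  if (length(labels) != nrow(molecules))
    stop("labels length must match record count")
  if (is.null(max_radius_px)) {
    regions <- mask_regions(mask)
    max_radius_px <- 3 * mean(sqrt(regions$area_px / pi))
  }
  eligible <- names(which(table(labels[labels > 0L]) >= 3L))
  if (length(eligible) == 0L) {
    warning("no cell has >= 3 assigned records; rescue is a no-op")
    return(list(profile = build_profile(molecules, labels, mask),
                labels = labels,
                unassigned_counts = sum(molecules$count[labels == 0L])))
  }
  eligible <- as.integer(eligible)
  eps <- 1e-3
  fits <- lapply(eligible, function(l) {
    sel <- labels == l
    wts <- molecules$count[sel]
    y <- molecules$y[sel]; x <- molecules$x[sel]
    mu <- c(sum(wts * y), sum(wts * x)) / sum(wts)
    dy <- y - mu[1]; dx <- x - mu[2]
    W <- sum(wts)
    cv <- matrix(c(sum(wts * dy * dy), sum(wts * dy * dx),
                   sum(wts * dy * dx), sum(wts * dx * dx)), 2L, 2L) / W +
      diag(eps, 2L)
    ic <- solve(cv)
    list(label = l, mu = mu, inv = ic,
         logdet = determinant(cv)$modulus[1], weight = W)
  })
  out <- which(labels == 0L)
  for (r in out) {
    y <- molecules$y[r]; x <- molecules$x[r]
    bestscore <- -Inf; bestlab <- 0L; near <- FALSE
    for (f in fits) {
      dy <- y - f$mu[1]; dx <- x - f$mu[2]
      if (sqrt(dy * dy + dx * dx) > max_radius_px) next
      near <- TRUE
      q <- f$inv[1, 1] * dy * dy + 2 * f$inv[1, 2] * dy * dx +
        f$inv[2, 2] * dx * dx
      score <- log(f$weight) - 0.5 * (f$logdet + q)
      if (score > bestscore) { bestscore <- score; bestlab <- f$label }
    }
    if (near) labels[r] <- bestlab
  }
  list(profile = build_profile(molecules, labels, mask), labels = labels,
       unassigned_counts = sum(molecules$count[labels == 0L]))
}

#' Per-cell statistics table
#'
#' Recomputes, per cell of the profile: pixel area and centroid from
#' the mask, and gene number / total counts from the matrix.
#'
#' @param profile A [cell_profile()].
#' @param mask The cell label matrix the profile was built from.
#' @return Data frame with one row per cell: `label`, `area_px`,
#'   `centroid_y`, `centroid_x`, `n_genes`, `total_counts`.
#' @export
cell_stats <- function(profile, mask) {
  labs <- as.integer(rownames(profile$matrix))
  regions <- mask_regions(mask)
  miss <- setdiff(labs, regions$label)
  if (length(miss))
    stop("profile labels missing from mask: ", paste(miss, collapse = ", "))
  out <- regions[match(labs, regions$label), , drop = FALSE]
  out$n_genes <- as.integer(Matrix::rowSums(profile$matrix > 0))
  out$total_counts <- as.integer(Matrix::rowSums(profile$matrix))
  rownames(out) <- NULL
  out
}

#' Quality-control filter for single-cell profiles
#'
#' Removes cells with fewer than `min_genes` expressed genes, fewer
#' than `min_counts` total counts, or more than `max_mito` fraction of
#' mitochondrial counts; then removes genes expressed in fewer than
#' `min_cells` of the surviving cells.  One pass each, cells first.
#' Mitochondrial genes are matched by id prefix, case-insensitively.
#'
#' @param profile A [cell_profile()].
#' @param mito_prefixes Character vector of mitochondrial gene-id
#'   prefixes (default `"mt-"`, matched case-insensitively).
#' @param min_genes,min_counts,max_mito,min_cells Thresholds; defaults
#'   10 genes, 3 counts, 3% mitochondrial, 3 cells.
#' @return The filtered [cell_profile()].
#' @export
qc_filter <- function(profile, mito_prefixes = c("mt-"),
                      min_genes = 10L, min_counts = 3L,
                      max_mito = 0.03, min_cells = 3L) {
  m <- profile$matrix
  if (nrow(m) == 0L) return(profile)
  lg <- tolower(colnames(m))
  is_mito <- Reduce(`|`, lapply(tolower(mito_prefixes),
                                function(p) startsWith(lg, p)))
  tot <- Matrix::rowSums(m)
  ng <- Matrix::rowSums(m > 0)
  mito_frac <- if (any(is_mito))
    Matrix::rowSums(m[, is_mito, drop = FALSE]) / pmax(tot, 1) else rep(0, nrow(m))
  keep_cells <- ng >= min_genes & tot >= min_counts & mito_frac <= max_mito
  m <- m[keep_cells, , drop = FALSE]
  keep_genes <- Matrix::colSums(m > 0) >= min_cells
  m <- m[, keep_genes, drop = FALSE]
  meta <- profile$cell_meta[keep_cells, , drop = FALSE]
  cell_profile(m, meta)
}
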
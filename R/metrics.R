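# Evaluation metric suite for cell segmentation and downstream
# clustering: pixel confusion metrics, per-cell IoU / average Jaccard,
# silhouette coefficient, and Moran's I spatial autocorrelation.

#' Pixel confusion counts between two masks
#'
#' Foreground is label > 0 (the 255/0 convention of binary cell-mask
#' images maps to nonzero/zero labels).  TP/TN/FP/FN are exact pixel
#' counts: TP both foreground, TN both background, FP predicted-only,
#' FN ground-truth-only.
#'
#' @param gt,pred Label matrices of equal shape.
#' @return List with integer `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(gt, pred) {
  if (!all(dim(gt) == dim(pred))) stop("gt and pred shapes differ")
  g <- gt > 0; p <- pred > 0
  list(TP = sum(g & p), TN = sum(!g & !p),
       FP = sum(!g & p), FN = sum(g & !p))
}

#' Precision, recall, F1 and Dice from confusion counts
#'
#' Pre = TP/(TP+FP); Rec = TP/(TP+FN); F1 = 2 Pre Rec/(Pre+Rec);
#' Dc = 2 TP/(2 TP+FP+FN).  Metrics with zero denominators are
#' reported as `NA` (undefined).
#'
#' @param c List with `TP`, `TN`, `FP`, `FN` (see [confusion_counts()]).
#' @return List with `precision`, `recall`, `f1`, `dice`.
#' @export
pixel_metrics <- function(c) {
  pre <- if (c$TP + c$FP > 0) c$TP / (c$TP + c$FP) else NA_real_
  rec <- if (c$TP + c$FN > 0) c$TP / (c$TP + c$FN) else NA_real_
  f1 <- if (!is.na(pre) && !is.na(rec) && pre + rec > 0)
    2 * pre * rec / (pre + rec) else NA_real_
  dc <- if (2 * c$TP + c$FP + c$FN > 0)
    2 * c$TP / (2 * c$TP + c$FP + c$FN) else NA_real_
  list(precision = pre, recall = rec, f1 = f1, dice = dc)
}

#' Match segmented cells to ground-truth objects and compute per-cell IoU
#'
#' Each predicted cell is matched to the ground-truth object with which
#' it shares the most pixels (ties to the smaller ground-truth label; a
#' ground-truth object may be matched by several predictions).
#' Predictions overlapping no ground-truth object get IoU 0.
#'
#' @param gt,pred Label matrices of equal shape.
#' @return Data frame with one row per predicted cell: `pred_label`,
#'   `gt_label` (NA if unmatched), `overlap` (ao), `union` (au), `iou`.
#' @export
match_cells <- function(gt, pred) {
  if (!all(dim(gt) == dim(pred))) stop("gt and pred shapes differ")
  plabs <- sort(unique(pred[pred > 0]))
  if (length(plabs) == 0L)
    return(data.frame(pred_label = integer(), gt_label = integer(),
                      overlap = integer(), union = integer(), iou = numeric()))
  gt_area <- tabulate(gt[gt > 0], nbins = max(gt, 1L))
  out <- data.frame(pred_label = plabs, gt_label = NA_integer_,
                    overlap = 0L, union = 0L, iou = 0)
  for (i in seq_along(plabs)) {
    px <- pred == plabs[i]
    parea <- sum(px)
    gvals <- gt[px]
    gvals <- gvals[gvals > 0]
    if (length(gvals) == 0L) { out$union[i] <- parea; next }
    tb <- tabulate(gvals, nbins = max(gvals))
    gl <- which.max(tb)          # which.max takes the smallest on ties
    ao <- tb[gl]
    au <- parea + gt_area[gl] - ao
    out$gt_label[i] <- gl; out$overlap[i] <- ao
    out$union[i] <- au; out$iou[i] <- ao / au
  }
  out
}

#' Average Jaccard index over segmented cells
#'
#' The mean of the per-cell IoU values of [match_cells()] over all
#' segmented cells (unmatched cells contribute 0).
#'
#' @param match Data frame from [match_cells()].
#' @return Numeric scalar, or `NA` when no cells were segmented.
#' @export
avg_jaccard <- function(match) {
  if (nrow(match) == 0L) return(NA_real_)
  mean(match$iou)
}

#' Silhouette coefficient of a clustering
#'
#' For sample j, `a_j` is its mean Euclidean distance to the other
#' members of its cluster and `b_j` the smallest mean distance to the
#' members of any other cluster; `Sc_j = (b_j - a_j) / max(a_j, b_j)`.
#' Members of singleton clusters get `Sc = 0` by convention.
#'
#' @param X Numeric sample-by-feature matrix.
#' @param labels Cluster assignment (length `nrow(X)`).
#' @return List with `sc` (per-sample values) and `mean_sc`.
#' @export
silhouette_score <- function(X, labels) {
  X <- as.matrix(X)
  labels <- as.vector(labels)
  if (length(unique(labels)) < 2L) stop("silhouette needs >= 2 clusters")
  n <- nrow(X)
  d <- as.matrix(stats::dist(X))
  sc <- numeric(n)
  sizes <- table(labels)
  for (j in seq_len(n)) {
    own <- labels == labels[j]
    if (sizes[as.character(labels[j])] == 1L) { sc[j] <- 0; next }
    a <- sum(d[j, own]) / (sum(own) - 1L)      # excludes self (d=0)
    b <- min(vapply(setdiff(unique(labels), labels[j]),
                    function(l) mean(d[j, labels == l]), numeric(1)))
    sc[j] <- (b - a) / max(a, b)
  }
  list(sc = sc, mean_sc = mean(sc))
}

#' Moran's I spatial autocorrelation
#'
#' `MI = (n / W0) * sum_kl w_kl (y_k - ybar)(y_l - ybar) /
#' sum_k (y_k - ybar)^2`, with `W0` the sum of all spatial weights.
#'
#' @param y Numeric attribute vector (length n >= 2).
#' @param w n-by-n nonnegative spatial weight matrix, zero diagonal.
#' @return Numeric scalar; `NA` when `y` is constant.
#' @export
morans_i <- function(y, w) {
  n <- length(y)
  if (n < 2L) stop("Moran's I needs n >= 2")
  w <- as.matrix(w)
  if (!all(dim(w) == c(n, n))) stop("weight matrix must be n x n")
  diag(w) <- 0
  W0 <- sum(w)
  if (W0 <= 0) stop("W0 = 0: no nonzero spatial weights")
  z <- y - mean(y)
  denom <- sum(z^2)
  if (denom == 0) return(NA_real_)
  (n / W0) * (as.numeric(t(z) %*% w %*% z) / denom)
}

# row-standardised k-nearest-neighbour adjacency on point coordinates
knn_weights <- function(coords, k = 6L) {
  n <- nrow(coords)
  k <- min(k, n - 1L)
  d <- as.matrix(stats::dist(coords))
  w <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[2:(k + 1L)]
    w[i, nb] <- 1 / k
  }
  w
}

#' Clustering evaluation on a cell profile: silhouette and Moran's I
#'
#' The expression matrix is library-size normalised, log-transformed
#' and reduced by PCA (10 components, as in standard pipelines); the
#' silhouette is computed per cluster on that embedding and averaged
#' across clusters.  Spatial coherence is scored per cluster by
#' Moran's I of the cluster's one-hot membership indicator over cells,
#' under row-standardised k-nearest-neighbour weights on the cell
#' centroids, and averaged across clusters.
#'
#' @param profile A [cell_profile()] with centroid metadata.
#' @param labels Cluster assignment per cell (external; clustering
#'   itself is delegated to standard tools).
#' @param k_neighbors Number of spatial neighbours (default 6).
#' @param n_pcs Number of principal components (default 10).
#' @return List with `mean_sc`, `mean_mi`, and per-cluster vectors
#'   `sc_per_cluster`, `mi_per_cluster`.
#' @export
cluster_spatial_eval <- function(profile, labels, k_neighbors = 6L,
                                 n_pcs = 10L) {
  m <- as.matrix(profile$matrix)
  if (nrow(m) != length(labels)) stop("one cluster label per cell required")
  tot <- pmax(rowSums(m), 1)
  ln <- log1p(m / tot * stats::median(tot))
  n_pcs <- min(n_pcs, ncol(ln) - 1L, nrow(ln) - 1L)
  emb <- stats::prcomp(ln, rank. = n_pcs)$x
  sil <- silhouette_score(emb, labels)
  cl <- sort(unique(labels))
  sc_per <- vapply(cl, function(l) mean(sil$sc[labels == l]), numeric(1))
  coords <- cbind(profile$cell_meta$centroid_y, profile$cell_meta$centroid_x)
  w <- knn_weights(coords, k_neighbors)
  mi_per <- vapply(cl, function(l) morans_i(as.numeric(labels == l), w),
                   numeric(1))
  list(mean_sc = mean(sc_per), mean_mi = mean(mi_per),
       sc_per_cluster = stats::setNames(sc_per, cl),
       mi_per_cluster = stats::setNames(mi_per, cl))
}

#' Full segmentation evaluation against a ground-truth mask
#'
#' @param gt,pred Label matrices.
#' @return List with `precision`, `recall`, `f1`, `dice`,
#'   `avg_jaccard`, `n_cells_pred`, `n_cells_gt`.
#' @export
evaluate_segmentation <- function(gt, pred) {
  pm <- pixel_metrics(confusion_counts(gt, pred))
  mj <- avg_jaccard(match_cells(gt, pred))
  c(pm, list(avg_jaccard = mj,
             n_cells_pred = length(unique(pred[pred > 0])),
             n_cells_gt = length(unique(gt[gt > 0]))))
}
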
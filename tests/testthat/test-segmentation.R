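test_that("plan_tiles computes stride origins and clamps the last tile", {
  p1 <- plan_tiles(c(100L, 100L), tile_size = 100L, overlap_px = 10L)
  expect_equal(nrow(p1$tiles), 1L)
  expect_equal(unlist(p1$tiles[1, ], use.names = FALSE), c(0L, 0L, 100L, 100L))

  p2 <- plan_tiles(c(100L, 190L), tile_size = 100L, overlap_px = 10L)
  expect_equal(sort(unique(p2$tiles$origin_x)), c(0L, 90L))
  expect_equal(nrow(p2$tiles), 2L)
  expect_error(plan_tiles(c(50L, 50L), 20L, 10L), "exceed")
})

test_that("every pixel is covered by at least one planned tile", {
  set.seed(31)
  for (i in 1:5) {
    shape <- sample(150:700, 2)
    p <- plan_tiles(shape, tile_size = 128L, overlap_px = 32L)
    cov <- matrix(0L, shape[1], shape[2])
    for (k in seq_len(nrow(p$tiles))) {
      t <- p$tiles[k, ]
      cov[t$origin_y + seq_len(t$height), t$origin_x + seq_len(t$width)] <-
        cov[t$origin_y + seq_len(t$height), t$origin_x + seq_len(t$width)] + 1L
    }
    expect_true(all(cov >= 1L))
  }
})

test_that("classical backend splits two ridge-separated basins", {
  # two cells separated by one bright vertical ridge
  h <- 80L; w <- 80L
  ridge <- matrix(0, h, w)
  ridge[, 39:41] <- 1
  ridge[1:2, ] <- 1; ridge[(h - 1):h, ] <- 1   # frame: membrane all around
  ridge[, 1:2] <- 1; ridge[, (w - 1):w] <- 1
  tile <- as.matrix(EBImage::gblur(ridge, 1.5))
  set.seed(32)
  tile <- pmax(tile + matrix(rnorm(h * w, 0, 0.03), h, w), 0)
  seg <- classical_backend(tile, diameter_px = 40L)
  expect_equal(max(seg), 2L)
  gt <- matrix(0L, h, w); gt[, 1:40] <- 1L; gt[, 41:80] <- 2L
  ious <- matched_ious(seg, gt)
  expect_true(all(ious >= 0.8))

  expect_equal(max(classical_backend(matrix(5, 50, 50), 20L)), 0L)
})

test_that("oversized diameters under-segment (monotone direction)", {
  sc <- scene50()
  n_right <- max(classical_backend(sc$membrane, 40L))
  n_huge <- max(classical_backend(sc$membrane, 150L))
  expect_lt(n_huge, n_right)
})

test_that("diameter selection maximises total cell area with ties to smaller", {
  stub <- function(tile, d) {
    m <- matrix(0L, nrow(tile), ncol(tile))
    if (d == 30) m[seq_len(500)] <- 1L
    if (d == 50) m[seq_len(800)] <- 1L
    m
  }
  s <- select_diameter(matrix(runif(900), 30, 30), c(30L, 50L), stub)
  expect_equal(s$diameter, 50L)

  stub_tie <- function(tile, d) {
    m <- matrix(0L, nrow(tile), ncol(tile)); m[seq_len(400)] <- 1L; m
  }
  expect_equal(select_diameter(matrix(runif(900), 30, 30),
                               c(50L, 30L), stub_tie)$diameter, 30L)

  one <- select_diameter(matrix(runif(900), 30, 30), 30L, stub)
  expect_equal(one$diameter, 30L)
  expect_error(select_diameter(matrix(runif(900), 30, 30), integer(0), stub),
               "empty")
})

test_that("single-tile merge just compacts labels", {
  m <- matrix(0L, 40, 40); m[5:10, 5:10] <- 7L; m[20:30, 20:30] <- 3L
  plan <- plan_tiles(c(40L, 40L), 40L, 10L)
  out <- merge_tiles(list(m), plan)
  expect_setequal(unique(as.vector(out)), c(0L, 1L, 2L))
  expect_true(all(matched_ious(out, m) == 1))
  expect_error(merge_tiles(list(m, m), plan), "mismatch")
})

test_that("tiled oracle segmentation equals whole-image ground truth", {
  sc <- scene50()
  gt <- sc$mask
  plan <- plan_tiles(dim(gt), tile_size = 320L, overlap_px = 96L)
  masks <- lapply(seq_len(nrow(plan$tiles)), function(k) {
    t <- plan$tiles[k, ]
    gt[t$origin_y + seq_len(t$height), t$origin_x + seq_len(t$width)]
  })
  merged <- merge_tiles(masks, plan)
  expect_equal(max(merged), length(unique(gt[gt > 0])))
  ious <- matched_ious(merged, gt)
  expect_true(all(ious >= 0.99))
  # no two output cells overlap by construction (raster labels are disjoint)
  expect_equal(sum(merged > 0), sum(gt > 0))
})

test_that("a cell inside the overlap of two tiles appears exactly once", {
  gt <- matrix(0L, 60, 100)
  gt[25:35, 45:55] <- 1L          # centred in the shared overlap strip
  gt[10:20, 10:20] <- 2L
  gt[40:50, 80:90] <- 3L
  plan <- plan_tiles(c(60L, 100L), tile_size = 60L, overlap_px = 25L)
  masks <- lapply(seq_len(nrow(plan$tiles)), function(k) {
    t <- plan$tiles[k, ]
    gt[t$origin_y + seq_len(t$height), t$origin_x + seq_len(t$width)]
  })
  merged <- merge_tiles(masks, plan)
  expect_equal(max(merged), 3L)
})

test_that("segmentation commutes with translation (up to label names)", {
  sc <- scene50()
  base <- sc$membrane[101:356, 101:356]
  shifted <- sc$membrane[91:346, 106:361]   # translate by (+10, -5)
  seg_a <- classical_backend(base, 40L)
  seg_b <- classical_backend(shifted, 40L)
  # compare on the interior common frame
  a <- seg_a[31:226, 31:226]
  b <- seg_b[41:236, 26:221]
  common <- a > 0 & b > 0
  tab <- table(a[common], b[common])
  agree <- sum(apply(tab, 1, max)) / sum(tab)
  expect_gt(agree, 0.95)
})

test_that("tissue filtering keeps cells by majority overlap, inclusive at 0.5", {
  m <- matrix(0L, 10, 10); m[1:4, 1:4] <- 1L; m[6:9, 6:9] <- 2L
  all_t <- matrix(1L, 10, 10)
  expect_identical(filter_by_tissue(m, all_t), m)
  expect_equal(max(filter_by_tissue(m, matrix(0L, 10, 10))), 0L)

  half <- matrix(0L, 10, 10); half[, 1:2] <- 1L
  m2 <- matrix(0L, 10, 10); m2[1:4, 1:4] <- 1L   # 8/16 px on tissue
  out <- filter_by_tissue(m2, half)
  expect_equal(max(out), 1L)                      # kept at exactly 0.5
  expect_error(filter_by_tissue(m, matrix(0L, 9, 9)), "differ")
})

test_that("threshold_tissue recovers bright regions", {
  img <- matrix(0.05, 200, 200)
  yy <- rep(1:200, 200); xx <- rep(1:200, each = 200)
  disk <- (yy - 100)^2 + (xx - 60)^2 <= 40^2
  img[disk] <- 1
  set.seed(33)
  img <- img + matrix(rnorm(200 * 200, 0, 0.02), 200, 200)
  tis <- threshold_tissue(img, sigma = 5)
  iou <- sum(tis > 0 & disk) / sum(tis > 0 | disk)
  expect_gt(iou, 0.9)

  expect_equal(max(threshold_tissue(matrix(1, 50, 50))), 0L)

  img2 <- matrix(0.05, 200, 200)
  img2[(yy - 60)^2 + (xx - 60)^2 <= 30^2] <- 1
  img2[(yy - 140)^2 + (xx - 140)^2 <= 30^2] <- 1
  tis2 <- threshold_tissue(img2, sigma = 5)
  comp <- EBImage::bwlabel(tis2 > 0)
  expect_equal(max(comp), 2)
})

test_that("classical backend reaches IoU >= 0.7 on dense synthetic scenes", {
  sc <- scene50()
  s <- select_diameter(sc$membrane, c(20L, 30L, 40L, 60L))
  seg <- filter_by_tissue(s$mask, threshold_tissue(sc$membrane))
  expect_gt(mean(matched_ious(seg, sc$mask)), 0.7)
})
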
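test_that("molecules take the mask label at their spot", {
  whole <- matrix(1L, 8, 8)
  mt <- molecule_table(c("a", "a", "b", "c", "c"),
                       x = c(0L, 3L, 7L, 2L, 2L), y = c(0L, 3L, 7L, 5L, 5L),
                       count = c(1L, 2L, 3L, 1L, 2L))
  a <- assign_molecules(mt, whole)
  expect_equal(nrow(a$profile$matrix), 1L)
  expect_equal(sum(a$profile$matrix), 9)
  expect_equal(a$unassigned_counts, 0L)

  split <- matrix(0L, 8, 8)
  split[, 1:4] <- 1L; split[, 5:8] <- 2L
  mt2 <- molecule_table(c("g1", "g1", "g2"), x = c(1L, 6L, 6L),
                        y = c(1L, 1L, 6L), count = c(2L, 1L, 4L))
  a2 <- assign_molecules(mt2, split)
  m <- as.matrix(a2$profile$matrix)
  expect_equal(m["1", "g1"], 2)
  expect_equal(m["2", "g1"], 1)
  expect_equal(m["2", "g2"], 4)

  bg <- matrix(0L, 8, 8); bg[1:2, 1:2] <- 1L
  a3 <- assign_molecules(molecule_table("g", 7L, 7L, 5L), bg)
  expect_equal(a3$labels, 0L)
  expect_equal(a3$unassigned_counts, 5L)
})

test_that("records outside the canvas stay unassigned and counts conserve", {
  mask <- matrix(1L, 4, 4)
  mt <- molecule_table(c("a", "b"), x = c(2L, 9L), y = c(2L, 9L),
                       count = c(3L, 4L))
  a <- assign_molecules(mt, mask)
  expect_equal(sum(a$profile$matrix) + a$unassigned_counts, total_count(mt))
  expect_equal(a$labels, c(1L, 0L))
})

test_that("count conservation holds on seeded random scenes at every stage", {
  for (seed in 1:3) {
    sc <- make_cells(12, c(128L, 128L), 28, seed = seed)
    ex <- make_expression(sc$mask, n_genes = 40, counts_per_cell = 80,
                          seed = seed)
    tot <- total_count(ex$molecules)
    a <- assign_molecules(ex$molecules, sc$mask)
    expect_equal(sum(a$profile$matrix) + a$unassigned_counts, as.numeric(tot))
    g <- gmm_assign_outside(ex$molecules, sc$mask, a$labels)
    expect_equal(sum(g$profile$matrix) + g$unassigned_counts, as.numeric(tot))
  }
})

test_that("with the ground-truth mask, per-cell counts match the emission log", {
  sc <- make_cells(15, c(160L, 160L), 30, seed = 5)
  ex <- make_expression(sc$mask, n_genes = 50, counts_per_cell = 100,
                        seed = 5, displaced_fraction = 0)
  a <- assign_molecules(ex$molecules, sc$mask)
  rec <- Matrix::rowSums(a$profile$matrix)
  truth <- tapply(ex$emissions$count, ex$emissions$cell, sum)
  expect_equal(as.numeric(rec[names(truth)]), as.numeric(truth))
  expect_equal(a$unassigned_counts, 0L)
})

test_that("Gaussian rescue assigns nearby outside molecules to the right cell", {
  mask <- matrix(0L, 20, 20); mask[8:12, 8:12] <- 1L
  inside <- molecule_table(rep("g", 4), x = c(8L, 9L, 10L, 11L),
                           y = c(9L, 10L, 11L, 9L), count = rep(1L, 4))
  outside <- molecule_table("g", 14L, 14L, 1L)
  mt <- molecule_table(c(inside$gene, outside$gene), c(inside$x, outside$x),
                       c(inside$y, outside$y), c(inside$count, outside$count))
  a <- assign_molecules(mt, mask)
  g <- gmm_assign_outside(mt, mask, a$labels, max_radius_px = 20)
  expect_true(all(g$labels == 1L))

  far <- gmm_assign_outside(mt, mask, a$labels, max_radius_px = 2)
  expect_equal(sum(far$labels == 0L), 1L)
})

test_that("rescue never relabels in-mask records and warns with no eligible cell", {
  mask <- matrix(0L, 10, 10); mask[2:3, 2:3] <- 1L
  mt <- molecule_table(c("a", "b"), x = c(1L, 8L), y = c(1L, 8L),
                       count = c(1L, 1L))
  a <- assign_molecules(mt, mask)
  expect_warning(g <- gmm_assign_outside(mt, mask, a$labels), "no-op")
  expect_equal(g$labels, a$labels)
})

test_that("two-cloud rescue recovers >= 90% of held-out points", {
  acc <- vapply(1:10, function(seed) {
    set.seed(seed)
    centers <- list(c(30, 30), c(30, 70))     # 40 px apart
    mask <- matrix(0L, 100, 100)
    mask[28:32, 28:32] <- 1L; mask[28:32, 68:72] <- 2L
    gene <- character(0); xx <- integer(0); yy <- integer(0)
    truth <- integer(0)
    # anchor records inside each mask core drawn from the cloud shape
    for (k in 1:2) {
      n <- 60
      py <- pmin(pmax(round(rnorm(n, centers[[k]][1], 5)), 0), 99)
      px <- pmin(pmax(round(rnorm(n, centers[[k]][2], 5)), 0), 99)
      gene <- c(gene, rep("g", n)); yy <- c(yy, py); xx <- c(xx, px)
    }
    # held-out outside points
    ho_y <- integer(0); ho_x <- integer(0); ho_truth <- integer(0)
    while (length(ho_truth) < 100) {
      k <- sample(1:2, 1)
      py <- round(rnorm(1, centers[[k]][1], 5)); px <- round(rnorm(1, centers[[k]][2], 5))
      if (py < 0 || py > 99 || px < 0 || px > 99) next
      if (mask[py + 1, px + 1] != 0L) next
      ho_y <- c(ho_y, py); ho_x <- c(ho_x, px); ho_truth <- c(ho_truth, k)
    }
    mt <- molecule_table(c(gene, rep("h", 100)), c(xx, ho_x), c(yy, ho_y),
                         rep(1L, length(gene) + 100))
    a <- assign_molecules(mt, mask)
    g <- gmm_assign_outside(mt, mask, a$labels, max_radius_px = 30)
    # recover the held-out records in the canonical table
    key <- paste(mt$x, mt$y, mt$gene)
    got <- g$labels[match(paste(ho_x, ho_y, "h"), key)]
    mean(got == ho_truth)
  }, numeric(1))
  expect_gte(mean(acc), 0.9)
})

test_that("cell_stats agrees with brute-force per-pixel and per-record loops", {
  sc <- make_cells(8, c(96L, 96L), 26, seed = 9)
  ex <- make_expression(sc$mask, n_genes = 30, counts_per_cell = 60, seed = 9)
  a <- assign_molecules(ex$molecules, sc$mask)
  st <- cell_stats(a$profile, sc$mask)
  for (i in seq_len(nrow(st))) {
    l <- st$label[i]
    expect_equal(st$area_px[i], sum(sc$mask == l))
    sel <- a$labels == l
    expect_equal(st$total_counts[i], sum(ex$molecules$count[sel]))
    expect_equal(st$n_genes[i], length(unique(ex$molecules$gene[sel])))
  }
  bad <- a$profile
  rownames(bad$matrix)[1] <- "99999"
  expect_error(cell_stats(bad, sc$mask), "missing from mask")

  empty <- assign_molecules(molecule_table(), sc$mask)
  expect_equal(nrow(cell_stats(empty$profile, sc$mask)), 0L)
})

test_that("QC filter applies the stated thresholds at their boundaries", {
  genes <- c("mt-1", paste0("g", 1:19))
  row_of <- function(...) {
    v <- numeric(20); names(v) <- genes
    vals <- list(...)
    v[names(vals)] <- unlist(vals)
    v
  }
  m <- rbind(
    # 12 genes, 50 counts, 2% mito -> kept
    row_of(`mt-1` = 1, g1 = 39, g2 = 1, g3 = 1, g4 = 1, g5 = 1, g6 = 1,
           g7 = 1, g8 = 1, g9 = 1, g10 = 1, g11 = 1),
    # 5 genes, 50 counts -> removed (fewer than 10 genes)
    row_of(g1 = 10, g2 = 10, g3 = 10, g4 = 10, g5 = 10),
    # 20 genes, 100 counts, 4% mito -> removed (> 3% mito)
    {
      v <- numeric(20); names(v) <- genes
      v["mt-1"] <- 4; v[paste0("g", 1:19)] <- 1; v["g1"] <- 78; v
    },
    # 1 gene, 2 counts -> removed (fewer than 3 counts)
    row_of(g1 = 2))
  rownames(m) <- as.character(1:4)
  out <- qc_filter(cell_profile(m), min_cells = 1L)
  expect_equal(rownames(out$matrix), "1")

  # boundary cells: exactly 3% mito, exactly 10 genes, exactly 3 counts
  m2 <- rbind(
    { v <- numeric(20); names(v) <- genes
      v["mt-1"] <- 3; v[paste0("g", 1:10)] <- 1; v["g1"] <- 88; v },
    { v <- numeric(20); names(v) <- genes
      v[paste0("g", 1:10)] <- 1; v },
    { v <- numeric(20); names(v) <- genes
      v[paste0("g", 1:12)] <- 1; v })
  rownames(m2) <- as.character(1:3)
  out2 <- qc_filter(cell_profile(m2), min_cells = 1L)
  expect_equal(nrow(out2$matrix), 3L)

  # exactly 3 total counts sits on the keep side of the count rule
  # (gene rule relaxed so the count boundary is observable)
  m3 <- rbind(row_of(g1 = 1, g2 = 1, g3 = 1), row_of(g1 = 2))
  rownames(m3) <- c("1", "2")
  out3 <- qc_filter(cell_profile(m3), min_genes = 1L, min_cells = 1L)
  expect_equal(rownames(out3$matrix), "1")
})

test_that("genes expressed in fewer than 3 surviving cells are dropped", {
  genes <- c("mt-1", paste0("g", 1:12))
  m <- matrix(0, 4, 13, dimnames = list(as.character(1:4), genes))
  m[, paste0("g", 1:10)] <- 5            # all cells pass the cell filter
  m[1:3, "g11"] <- 1                     # in exactly 3 cells -> kept
  m[1:2, "g12"] <- 1                     # in 2 cells -> removed
  out <- qc_filter(cell_profile(m))
  expect_true("g11" %in% out$gene_ids)
  expect_false("g12" %in% out$gene_ids)

  empty <- cell_profile(matrix(0, 0, 0))
  expect_equal(nrow(qc_filter(empty)$matrix), 0L)
})

test_that("QC filtering is idempotent on seeded random profiles", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- 30; g <- 50
    m <- matrix(rpois(n * g, 3), n, g)
    colnames(m) <- c(paste0("mt-", 1:2), paste0("g", seq_len(g - 2)))
    rownames(m) <- as.character(seq_len(n))
    once <- qc_filter(cell_profile(m))
    twice <- qc_filter(once)
    expect_identical(as.matrix(twice$matrix), as.matrix(once$matrix))
  }
})
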
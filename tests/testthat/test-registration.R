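test_that("match_canvas cuts and zero-pads to the nuclei shape", {
  mem <- matrix(1, 100, 100); nuc <- matrix(0, 100, 100)
  expect_identical(match_canvas(mem, nuc), mem)

  mem2 <- matrix(2, 90, 110)
  out <- match_canvas(mem2, matrix(0, 100, 100))
  expect_equal(dim(out), c(100L, 100L))
  expect_true(all(out[91:100, ] == 0))      # padded rows
  expect_true(all(out[1:90, 1:100] == 2))   # retained block, columns cut

  z <- match_canvas(matrix(0, 50, 50), matrix(1, 80, 80))
  expect_true(all(z == 0))
  expect_equal(dim(z), c(80L, 80L))
})

test_that("mean_subsample equals the explicit block-mean oracle", {
  img <- matrix(runif(25, 1, 9), 5, 5)
  expect_identical(mean_subsample(img, 1L), img)
  expect_equal(mean_subsample(matrix(c(1, 3, 2, 4), 2, 2), 2L),
               matrix(2.5, 1, 1))
  set.seed(21)
  img5 <- matrix(runif(25), 5, 5)
  out <- mean_subsample(img5, 2L)
  oracle <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    rows <- (2 * i - 1):min(2 * i, 5); cols <- (2 * j - 1):min(2 * j, 5)
    oracle[i, j] <- mean(img5[rows, cols])
  }
  expect_equal(out, oracle, tolerance = 1e-9)
  expect_error(mean_subsample(img5, 0), "positive integer")
})

test_that("register_stain_pair recovers translations of a common texture", {
  set.seed(22)
  nuc <- matrix(runif(256 * 256), 256, 256)
  expect_equal(with(register_stain_pair(nuc, nuc, 4L), c(dy, dx)), c(0L, 0L))

  mem <- spatialcellbin:::shift_mat(nuc, -23, 11)
  # content moved by (-23, 11): membrane point p sits at nuclei p + (23, -11)
  o <- register_stain_pair(mem, nuc, factor = 4L)
  expect_equal(c(o$dy, o$dx), c(23L, -11L))

  mem2 <- spatialcellbin:::shift_mat(nuc, -3, 0)
  o2 <- register_stain_pair(mem2, nuc, factor = 8L)   # shift < factor
  expect_equal(c(o2$dy, o2$dx), c(3L, 0L))
})

test_that("register_stain_pair is pixel-exact across stain modalities", {
  sc <- make_cells(100, c(512L, 512L), 36, seed = 31)
  s <- c(6L, -4L)
  mem <- matrix(0, 512, 512)
  ys <- (1 + s[1]):512; xs <- 1:(512 + s[2])
  mem[ys, xs] <- sc$membrane[ys - s[1], xs - s[2]]
  o <- register_stain_pair(mem, sc$nuclei, 4L)
  expect_equal(c(o$dy, o$dx), -s)
})

test_that("register_channel_offsets registers each channel to the reference", {
  set.seed(23)
  img <- matrix(runif(128 * 128), 128, 128)
  sh <- spatialcellbin:::shift_mat(img, -4, -4)   # content at p maps to p+(4,4)
  offs <- register_channel_offsets(list(img, sh), reference_index = 1L)
  expect_equal(c(offs[[1]]$dy, offs[[1]]$dx), c(0L, 0L))
  expect_equal(c(offs[[2]]$dy, offs[[2]]$dx), c(4L, 4L))
  expect_error(register_channel_offsets(list(img)), ">= 2")
  offs3 <- register_channel_offsets(list(img, img, img), 1L)
  for (o in offs3) expect_equal(c(o$dy, o$dx), c(0L, 0L))
})

test_that("track-line detection recovers pitch, angle and rejects noise", {
  sc <- scene50()
  img <- add_track_lines(sc$nuclei, pitch_px = 100, angle_deg = 0,
                         line_width_px = 3L)
  tl <- detect_track_lines(img)
  expect_lt(abs(tl$pitch_px - 100) / 100, 0.01)
  expect_lt(abs(tl$angle_deg), 0.2)

  img3 <- add_track_lines(sc$nuclei, pitch_px = 100, angle_deg = 3,
                          line_width_px = 3L)
  tl3 <- detect_track_lines(img3)
  expect_gt(tl3$angle_deg, 2.8); expect_lt(tl3$angle_deg, 3.2)

  set.seed(24)
  nz <- matrix(runif(256 * 256), 256, 256)
  expect_error(detect_track_lines(nz), "no track lines")
})

test_that("noise images are rejected across many seeds", {
  rejected <- vapply(1:100, function(i) {
    set.seed(3000 + i)
    nz <- matrix(runif(128 * 128), 128, 128)
    inherits(tryCatch(detect_track_lines(nz), error = function(e) e), "error")
  }, logical(1))
  expect_true(all(rejected))
})

test_that("apply_transform handles identity, translation, and round-trips", {
  set.seed(25)
  img <- matrix(runif(64 * 64), 64, 64)
  out <- apply_transform(img, similarity_transform(), dim(img))
  expect_equal(out, img, tolerance = 1e-12)

  ramp <- matrix(seq_len(8), 1, 8)
  tr <- apply_transform(ramp, similarity_transform(tx = 3), c(1L, 8L))
  expect_equal(tr[1, 1:3], c(0, 0, 0))
  expect_equal(tr[1, 4:8], as.numeric(ramp[1, 1:5]))

  smooth <- as.matrix(EBImage::gblur(matrix(runif(96 * 96), 96, 96), 3))
  # keep the flipped/rotated content on the output canvas
  t <- similarity_transform(1.3, 17, "horizontal", ty = 8, tx = 150)
  fwd <- apply_transform(smooth, t, c(200L, 200L))
  back <- apply_transform(fwd, st_invert(t), dim(smooth))
  interior <- smooth[17:80, 17:80]
  err <- mean(abs(back[17:80, 17:80] - interior))
  expect_lt(err, 0.02 * diff(range(smooth)))
  expect_error(apply_transform(img, t, c(0L, 10L)), "positive")
})

test_that("nearest-neighbour interpolation preserves label values", {
  m <- matrix(0L, 20, 20); m[5:9, 5:9] <- 3L; m[12:15, 12:15] <- 7L
  w <- apply_transform(m, similarity_transform(tx = 2, ty = 1), c(22L, 22L),
                       interpolation = "nearest")
  expect_setequal(unique(as.vector(w)), c(0, 3, 7))
  expect_equal(sum(w == 3), 25)
})

test_that("composition with a stain offset equals sequential application", {
  off0 <- list(dy = 0, dx = 0)
  t_id <- similarity_transform()
  expect_equal(compose_membrane_transform(off0, t_id), t_id)

  off5 <- list(dy = 5, dx = 0)
  comp <- compose_membrane_transform(off5, t_id)
  p <- st_apply(comp, 0, 0)
  expect_equal(c(p$y, p$x), c(5, 0))

  set.seed(26)
  off <- list(dy = rnorm(1, 0, 10), dx = rnorm(1, 0, 10))
  t <- similarity_transform(1.4, 52, "horizontal", ty = 3.3, tx = -7.1)
  comp2 <- compose_membrane_transform(off, t)
  ys <- rnorm(100, 0, 40); xs <- rnorm(100, 0, 40)
  direct <- st_apply(comp2, ys, xs)
  seq_ <- st_apply(t, ys + off$dy, xs + off$dx)
  expect_lt(max(abs(direct$y - seq_$y), abs(direct$x - seq_$x)), 1e-9)
})

test_that("nuclei-to-map registration recovers known transforms", {
  run_case <- function(truth, seed) {
    sc <- make_cells(50, c(512L, 512L), 40, seed = seed)
    nuc <- add_track_lines(sc$nuclei, 64, 0, 3L)
    ex <- make_expression(sc$mask, counts_per_cell = 2000, seed = seed + 100,
                          displaced_fraction = 0)
    crn <- st_apply(truth, c(0, 0, 511, 511), c(0, 511, 0, 511))
    truth$ty <- truth$ty - min(crn$y); truth$tx <- truth$tx - min(crn$x)
    crn <- st_apply(truth, c(0, 0, 511, 511), c(0, 511, 0, 511))
    shape <- c(ceiling(max(crn$y)) + 2, ceiling(max(crn$x)) + 2)
    pair <- make_registered_pair(ex$molecules, truth,
                                 track = list(pitch_px = 64, angle_deg = 0,
                                              line_width_px = 3L),
                                 shape = shape)
    rec <- register_nuclei_to_map(nuc, pair$map, truth$scale * 64)
    list(rec = rec, truth = truth)
  }
  check <- function(r) {
    expect_lt(abs(r$rec$scale - r$truth$scale) / r$truth$scale, 0.01)
    expect_equal(r$rec$flip, r$truth$flip)
    dr <- (r$rec$rotation_deg - r$truth$rotation_deg) %% 360
    if (dr > 180) dr <- dr - 360
    expect_lt(abs(dr), 0.5)
    expect_lt(abs(r$rec$ty - r$truth$ty), 0.5)
    expect_lt(abs(r$rec$tx - r$truth$tx), 0.5)
  }
  check(run_case(similarity_transform(0.5, 90, "none", ty = 12, tx = -7), 41))
  check(run_case(similarity_transform(1, 0, "none"), 42))
  check(run_case(similarity_transform(0.5, 90, "horizontal", ty = 12, tx = -7), 43))
})
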
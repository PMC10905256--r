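# shared fixtures: built once per test run, in code (no stored data)

.fixture_env <- new.env(parent = emptyenv())

# memoised synthetic scene so several test files can share one build
scene50 <- function() {
  if (is.null(.fixture_env$scene50))
    .fixture_env$scene50 <- make_cells(50, c(512L, 512L), 40, seed = 3L)
  .fixture_env$scene50
}

# per-cell best-overlap IoU of a predicted mask against ground truth
matched_ious <- function(pred, gt) {
  m <- match_cells(gt, pred)
  m$iou
}

# brute-force oracle: best circular shift by exhaustive normalised
# cross-correlation (independent of the FFT implementation)
exhaustive_shift <- function(a, b) {
  h <- nrow(a); w <- ncol(a)
  best <- c(0L, 0L); bestv <- -Inf
  av <- a - mean(a)
  for (dy in 0:(h - 1L)) for (dx in 0:(w - 1L)) {
    s <- sum(av * (spatialcellbin:::shift_mat(b, -dy, -dx) - mean(b)))
    if (s > bestv) { bestv <- s; best <- c(dy, dx) }
  }
  c(ifelse(best[1] <= h / 2, best[1], best[1] - h),
    ifelse(best[2] <= w / 2, best[2], best[2] - w))
}

# small deterministic molecule table
toy_molecules <- function() {
  molecule_table(gene = c("g1", "g1", "g2", "g2"),
                 x = c(1L, 6L, 6L, 6L), y = c(1L, 1L, 6L, 6L),
                 count = c(2L, 1L, 2L, 2L))
}

# one seeded registration-recovery case at the study conditions
# (512 px scene, 50 cells of ~40 px, pitch-64 fiducial, 2000 counts/cell);
# draws scale in [0.4, 2], a rotation quadrant plus a fine angle in
# [-2, 2] deg, a flip, and an integer translation, then checks recovery
# within: scale 1%, fine angle 0.5 deg, translation 0.5 px, flip and
# quadrant exact.
registration_case <- function(seed) {
  set.seed(seed * 17)
  s <- runif(1, 0.4, 2.0)
  q <- sample(c(0, 90, 180, 270), 1)
  fine <- runif(1, -2, 2)
  fl <- sample(c("none", "horizontal"), 1)
  sc <- make_cells(50, c(512L, 512L), 40, seed = seed)
  nuc <- add_track_lines(sc$nuclei, 64, 0, 3L)
  ex <- make_expression(sc$mask, counts_per_cell = 2000, seed = seed + 100,
                        displaced_fraction = 0)
  truth <- similarity_transform(s, q + fine, fl, 0, 0)
  crn <- st_apply(truth, c(0, 0, 511, 511), c(0, 511, 0, 511))
  truth$ty <- -min(crn$y) + sample(0:50, 1)
  truth$tx <- -min(crn$x) + sample(0:50, 1)
  crn <- st_apply(truth, c(0, 0, 511, 511), c(0, 511, 0, 511))
  shape <- c(ceiling(max(crn$y)) + 2, ceiling(max(crn$x)) + 2)
  pair <- make_registered_pair(ex$molecules, truth,
                               track = list(pitch_px = 64, angle_deg = 0,
                                            line_width_px = 3L),
                               shape = shape)
  rec <- tryCatch(register_nuclei_to_map(nuc, pair$map, s * 64),
                  error = function(e) NULL)
  if (is.null(rec)) return(FALSE)
  dr <- (rec$rotation_deg - truth$rotation_deg) %% 360
  if (dr > 180) dr <- dr - 360
  abs(rec$scale - s) / s < 0.01 &&
    rec$flip == fl &&
    abs(dr) < 0.5 &&
    abs(rec$ty - truth$ty) <= 0.5 &&
    abs(rec$tx - truth$tx) <= 0.5
}
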
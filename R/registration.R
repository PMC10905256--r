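#' Match the membrane/wall canvas to the nuclei canvas
#'
#' The membrane/wall stain is photographed on the same chip as the
#' nuclei stain, so the two canvases differ only marginally in size.
#' The membrane image is cut and/or zero-padded at the bottom and right
#' to exactly the nuclei image's shape.
#'
#' @param membrane,nuclei Numeric image matrices.
#' @return The adjusted membrane image, with `dim(nuclei)`.
#' @export
match_canvas <- function(membrane, nuclei) {
  validate_image(membrane); validate_image(nuclei)
  h <- nrow(nuclei); w <- ncol(nuclei)
  out <- matrix(0, h, w)
  rh <- min(h, nrow(membrane)); rw <- min(w, ncol(membrane))
  out[1:rh, 1:rw] <- membrane[1:rh, 1:rw]
  out
}

#' Mean-based subsampling of an image
#'
#' Each output pixel is the arithmetic mean of its `factor x factor`
#' block; partial blocks at the bottom/right edge are averaged over the
#' pixels present.  Output shape is `ceiling(shape / factor)`.
#'
#' @param image Numeric matrix.
#' @param factor Positive integer subsampling factor.
#' @return Numeric matrix.
#' @export
mean_subsample <- function(image, factor) {
  validate_image(image)
  if (!is.numeric(factor) || length(factor) != 1L || factor < 1 || factor != round(factor))
    stop("factor must be a positive integer")
  factor <- as.integer(factor)
  if (factor == 1L) return(image)
  h <- nrow(image); w <- ncol(image)
  rg <- (seq_len(h) - 1L) %/% factor + 1L
  cg <- (seq_len(w) - 1L) %/% factor + 1L
  s <- rowsum(image, rg)              # sum rows within blocks
  s <- t(rowsum(t(s), cg))            # then columns
  cnt <- outer(tabulate(rg), tabulate(cg))
  out <- s / cnt
  dimnames(out) <- NULL
  out
}

#' Register the membrane/wall stain to the nuclei stain (stage 1)
#'
#' The two stains are photographed without moving the chip, so they
#' differ by a pure translation.  The offset is computed on mean
#' subsampled images by an FFT correlation score, restored to full
#' scale by multiplying with the subsampling factor, and refined by a
#' full-resolution correlation restricted to a window of half-width
#' `2 * factor` around the restored coarse estimate (wide enough to
#' absorb a one-bin error in the coarse peak).
#'
#' The score is built for the cross-modality case (boundary ridges in
#' one channel, nuclei blobs in the other share little direct
#' structure): it sums a tissue-envelope correlation (heavy blur of
#' both channels) and the absolute value of a band-pass structural
#' correlation.  Taking the absolute value makes the fine term
#' polarity-invariant, so dark cell interiors matching bright nuclei
#' (cross-stain) score as well as identical textures (same-stain or
#' multi-channel case).
#'
#' The returned offset is the translation taking membrane coordinates to
#' nuclei coordinates: content at membrane pixel `(y, x)` sits at nuclei
#' pixel `(y + dy, x + dx)`.
#'
#' @param membrane,nuclei Numeric image matrices (canvases matched via
#'   [match_canvas()] internally if needed).
#' @param factor Integer subsampling factor (default 4).
#' @return An `offset_estimate` (`dy`, `dx`, `confidence`), confidence
#'   being half the combined correlation peak (in `[0, 1]`).
#' @export
register_stain_pair <- function(membrane, nuclei, factor = 4L) {
  if (!all(dim(membrane) == dim(nuclei)))
    membrane <- match_canvas(membrane, nuclei)
  if (max(membrane) == min(membrane) || max(nuclei) == min(nuclei))
    stop("degenerate input: constant image")
  ms <- mean_subsample(membrane, factor)
  ns <- mean_subsample(nuclei, factor)
  coarse <- stain_offset_score(ms, ns, sigma_scale = 1 / factor)
  fine <- stain_offset_score(membrane, nuclei, fine = TRUE,
                             window = list(dy = round(coarse$dy_sub * factor),
                                           dx = round(coarse$dx_sub * factor),
                                           halfwidth = 2L * factor))
  # the windowed fine-band surface localises the offset; the coarse
  # composite score is the better reliability statistic
  fine$confidence <- max(fine$confidence, coarse$confidence)
  fine
}

# composite cross-modality correlation: tissue envelope + polarity-
# invariant band-pass structure.  sigma_scale shrinks the blur scales
# when operating on subsampled images.  With fine = TRUE (the windowed
# full-resolution refinement) only the sharpest band is used: the
# pixel-exact signal lives in the fine edges (nucleus borders,
# bleed-through), while the coarser bands carry smooth cross-stain
# anti-structure whose magnitude is flat near the true offset.
stain_offset_score <- function(a, b, sigma_scale = 1, window = NULL,
                               fine = FALSE) {
  g <- function(m, s) as.matrix(EBImage::gblur(m, max(s * sigma_scale, 0.5)))
  if (fine) {
    # sharpest band localises; the envelope term anchors the peak to
    # the global alignment, vetoing spurious fine-band matches a few
    # cell radii away
    hp_a <- g(a, 1) - g(a, 6); hp_b <- g(b, 1) - g(b, 6)
    surf <- abs(xcorr_surface(unit_var(hp_a), unit_var(hp_b))) +
      xcorr_surface(unit_var(g(a, 20)), unit_var(g(b, 20)))
  } else {
    env <- xcorr_surface(unit_var(g(a, 20)), unit_var(g(b, 20)))
    hp_a <- g(a, 3) - g(a, 12); hp_b <- g(b, 3) - g(b, 12)
    surf <- env + abs(xcorr_surface(unit_var(hp_a), unit_var(hp_b)))
  }
  h <- nrow(a); w <- ncol(a)
  if (!is.null(window)) {
    dys <- ifelse(seq_len(h) - 1 <= h / 2, seq_len(h) - 1, seq_len(h) - 1 - h)
    dxs <- ifelse(seq_len(w) - 1 <= w / 2, seq_len(w) - 1, seq_len(w) - 1 - w)
    wrapdist <- function(v, c0, n) pmin(abs(v - c0), n - abs(v - c0))
    allowed <- outer(wrapdist(dys, window$dy, h) <= window$halfwidth,
                     wrapdist(dxs, window$dx, w) <= window$halfwidth, "&")
    surf[!allowed] <- -Inf
  }
  pk <- which.max(surf)
  pi_ <- (pk - 1L) %% h + 1L; pj <- (pk - 1L) %/% h + 1L
  dy <- if (pi_ - 1L <= h / 2) pi_ - 1L else pi_ - 1L - h
  dx <- if (pj - 1L <= w / 2) pj - 1L else pj - 1L - w
  # sub-pixel peak (parabolic): a half-bin-accurate coarse estimate is
  # what keeps the restored full-resolution window centred on the truth
  parab <- function(m, c0, p) {
    den <- m - 2 * c0 + p
    if (c0 >= m && c0 >= p && den < 0) 0.5 * (m - p) / den else 0
  }
  im <- (pi_ - 2L) %% h + 1L; ip <- pi_ %% h + 1L
  jm <- (pj - 2L) %% w + 1L; jp <- pj %% w + 1L
  peak <- surf[pi_, pj]
  structure(list(dy = dy, dx = dx,
                 dy_sub = dy + parab(surf[im, pj], peak, surf[ip, pj]),
                 dx_sub = dx + parab(surf[pi_, jm], peak, surf[pi_, jp]),
                 confidence = min(max(peak / 2, 0), 1)),
            class = "offset_estimate")
}

#' Register several stain channels to a common reference (offsets only)
#'
#' For multi-channel immunofluorescence captured with the same
#' microscope, the channels differ only by translations.  Each channel
#' is registered to the reference channel with [register_stain_pair()].
#'
#' @param channels List of >= 2 image matrices with equal canvases.
#' @param reference_index Index of the reference channel.
#' @param factor Subsampling factor passed through.
#' @return List of `offset_estimate`, one per channel; the reference
#'   gets offset (0, 0) with confidence 1.
#' @export
register_channel_offsets <- function(channels, reference_index = 1L, factor = 4L) {
  if (length(channels) < 2L) stop("needs >= 2 channels")
  ref <- channels[[reference_index]]
  lapply(seq_along(channels), function(i) {
    if (i == reference_index)
      structure(list(dy = 0L, dx = 0L, confidence = 1), class = "offset_estimate")
    else
      register_stain_pair(channels[[i]], ref, factor = factor)
  })
}

# ---- track lines -----------------------------------------------------------

# (weighted) mean-per-bin projection profile of image intensities along
# direction perpendicular to a line family at `angle_deg` (0 = horizontal
# lines).  A weight image (e.g. a tissue envelope) restricts the mean to
# informative pixels so empty canvas does not dilute the line signal.
projection_profile <- function(image, angle_deg, weight = NULL) {
  h <- nrow(image); w <- ncol(image)
  a <- angle_deg * pi / 180
  x <- rep(0:(w - 1L), each = h)
  y <- rep(0:(h - 1L), times = w)
  u <- round(y * cos(a) - x * sin(a))
  keys <- u - min(u) + 1L
  if (is.null(weight)) {
    sums <- rowsum(as.vector(image), keys)
    cnts <- tabulate(keys)
    cnts <- cnts[cnts > 0]
    prof <- sums[, 1] / cnts
  } else {
    wv <- as.vector(weight)
    sums <- rowsum(as.vector(image) * wv, keys)
    wsum <- rowsum(wv, keys)
    prof <- sums[, 1] / pmax(wsum[, 1], .Machine$double.eps)
    prof[wsum[, 1] < 1] <- mean(prof[wsum[, 1] >= 1])
  }
  list(u0 = min(u), profile = prof)
}

# high-pass a projection profile: subtract a running mean so the slow
# tissue envelope does not drown the periodic line comb
detrend_profile <- function(p) {
  k <- max(5L, length(p) %/% 20L)
  trend <- stats::filter(p, rep(1 / k, k), sides = 2)
  nas <- which(is.na(trend))
  if (length(nas)) {
    ok <- which(!is.na(trend))
    if (length(ok) == 0L) return(p - mean(p))
    trend[nas] <- trend[ok[pmax(1L, findInterval(nas, ok))]]
    trend[nas[nas < ok[1]]] <- trend[ok[1]]
  }
  as.numeric(p - trend)
}

profile_sharpness <- function(image, angle_deg, weight = NULL) {
  stats::var(detrend_profile(projection_profile(image, angle_deg, weight)$profile))
}

comb_score <- function(profile, pitch, u0 = 0) {
  # best mean profile value over comb phases for a given pitch
  n <- length(profile)
  phases <- seq(0, pitch, by = max(0.25, pitch / 200))
  best <- -Inf; bestphase <- 0
  for (ph in phases) {
    if (ph > n - 1) break
    pos <- seq(ph, n - 1, by = pitch)
    idx <- round(pos) + 1
    idx <- idx[idx >= 1 & idx <= n]
    if (length(idx) < 2) next
    sc <- mean(profile[idx])
    if (sc > best) { best <- sc; bestphase <- ph }
  }
  list(score = best, phase = bestphase)
}

#' Detect the chip track-line grid in a staining image
#'
#' The Stereo-seq chip carries a crossed periodic line marker ("track
#' lines") used as a registration fiducial.  The line orientation is
#' found by maximising the sharpness (variance) of the intensity
#' projection profile over candidate angles (the crossed grid makes the
#' estimate periodic modulo 90 degrees); the pitch comes from the
#' dominant nonzero peak of the profile's FFT, refined by maximising the
#' comb correlation over a continuous pitch; the phase is the comb
#' offset of the nearest line to the origin, per family.
#'
#' @param image Numeric matrix containing bright periodic lines (for
#'   expression maps, pass the negated map: track lanes are
#'   molecule-free).
#' @param pitch_hint Optional approximate pitch in pixels (e.g. the chip
#'   pitch from instrument metadata); restricts the period search to
#'   within 20% and halves the detection threshold.
#' @param min_peak_ratio Detection threshold without a pitch hint:
#'   ratio of the dominant nonzero FFT peak of the projection profile
#'   to the median nonzero spectrum magnitude below which detection
#'   fails.  The default sits well above the null distribution of this
#'   statistic on structureless noise (max ~14 over seeds and canvas
#'   sizes; genuine combs score 40+).
#' @param hint_peak_ratio Detection threshold within the hinted pitch
#'   band (the band statistic has a much tighter null: max ~3.1 on
#'   noise).
#' @param weight Optional nonnegative weight image (e.g. a tissue
#'   envelope) restricting the projection profiles to informative
#'   pixels.
#' @return Object of class `track_line_model`: list with `pitch_px`,
#'   `angle_deg` (in (-45, 45], modulo 90), `phase` (`py`, `px`).
#' @export
detect_track_lines <- function(image, pitch_hint = NULL, min_peak_ratio = 20,
                               hint_peak_ratio = 3.6, weight = NULL) {
  validate_image(image)
  # light Gaussian pre-smoothing: expression maps binned at non-unit
  # scale carry a strong pixel-alternation alias which a sigma-1 blur
  # removes while leaving the multi-pixel line comb intact
  img <- as.matrix(EBImage::gblur(image, sigma = 1))
  img <- img - mean(img)
  # coarse angle search modulo 90, then local refinement (unweighted:
  # the tissue-envelope weight helps the pitch search but biases the
  # sharpness objective)
  coarse <- seq(-45, 44, by = 1)
  sharp <- vapply(coarse, function(a) profile_sharpness(img, a), numeric(1))
  a0 <- coarse[which.max(sharp)]
  opt <- stats::optimize(function(a) profile_sharpness(img, a),
                         interval = c(a0 - 1, a0 + 1), maximum = TRUE,
                         tol = 1e-3)
  # the variance objective can drift slightly under noise; keep whichever
  # of the coarse and refined angles yields the more dominant spectrum
  spec_ratio <- function(a) {
    prof <- detrend_profile(projection_profile(img, a, weight)$profile)
    n <- length(prof)
    spec <- Mod(stats::fft(prof))[2:floor(n / 2)]
    spec[seq_along(spec) < 2] <- 0
    med <- max(stats::median(spec[spec > 0]), .Machine$double.eps)
    if (!is.null(pitch_hint)) {
      band <- which(abs(n / seq_along(spec) - pitch_hint) / pitch_hint < 0.2)
      if (length(band) == 0L) return(0)
      max(spec[band]) / med
    } else max(spec) / med
  }
  angs <- c(a0, opt$maximum)
  angle <- angs[which.max(vapply(angs, spec_ratio, numeric(1)))]
  if (angle > 45) angle <- angle - 90
  if (angle <= -45) angle <- angle + 90

  pp <- projection_profile(img, angle, weight)
  prof <- detrend_profile(pp$profile)
  n <- length(prof)
  spec <- Mod(stats::fft(prof))[2:floor(n / 2)]
  ks <- seq_along(spec)                     # cycles over the profile
  spec[ks < 2] <- 0                         # require >= 2 periods in frame
  med <- max(stats::median(spec[spec > 0]), .Machine$double.eps)
  if (!is.null(pitch_hint)) {
    # restrict the peak search to periods within 20% of the hint
    band <- which(abs(n / ks - pitch_hint) / pitch_hint < 0.2)
    if (length(band) == 0L) stop("no track lines detected")
    pk <- band[which.max(spec[band])]
    if (spec[pk] / med < hint_peak_ratio)
      stop("no track lines detected")
    # scan integer pitches around the hint (the spectral bin is coarse
    # for long periods), then refine continuously
    cand <- seq(floor(pitch_hint * 0.85), ceiling(pitch_hint * 1.15))
    cand <- cand[cand > 2 & cand < n - 1]
    sc <- vapply(cand, function(p) comb_score(prof, p)$score, numeric(1))
    pitch0 <- cand[which.max(sc)]
  } else {
    pk <- which.max(spec)
    if (spec[pk] / med < min_peak_ratio)
      stop("no track lines detected")
    # a narrow line comb spreads power over harmonics; recover the
    # fundamental period from the autocorrelation of the profile
    ac <- stats::acf(prof, lag.max = floor(n / 2), plot = FALSE,
                     demean = FALSE)$acf[, 1, 1]
    lags <- seq_along(ac) - 1L
    cand <- which(lags >= 3)
    pk_lag <- cand[which.max(ac[cand])]
    lag0 <- lags[pk_lag]; pkv <- ac[pk_lag]
    for (k in rev(seq_len(max(floor(lag0 / 3), 1))[-1])) {  # smallest divisor wins
      sub <- lag0 / k
      if (abs(sub - round(sub)) > 0.01) next
      i <- round(sub) + 1L
      lo <- max(1L, i - 1L); hi <- min(length(ac), i + 1L)
      if (max(ac[lo:hi]) >= 0.7 * pkv) { lag0 <- round(sub); break }
    }
    pitch0 <- lag0
  }
  if (pitch0 <= 2) stop("no track lines detected")
  # polish the angle against the comb itself (sharper objective than
  # the projection variance), then the pitch, then read off the phase
  aopt <- stats::optimize(function(a) {
    comb_score(detrend_profile(projection_profile(img, a, weight)$profile),
               pitch0)$score
  }, interval = c(angle - 0.6, angle + 0.6), maximum = TRUE, tol = 5e-3)
  if (aopt$objective > comb_score(prof, pitch0)$score) {
    angle <- aopt$maximum
    pp <- projection_profile(img, angle, weight)
    prof <- detrend_profile(pp$profile)
  }
  refine <- stats::optimize(function(p) comb_score(prof, p)$score,
                            interval = c(pitch0 - 2, pitch0 + 2),
                            maximum = TRUE, tol = 1e-3)
  if (comb_score(prof, pitch0)$score > refine$objective) {
    pitch <- pitch0
  } else pitch <- refine$maximum
  phase_u <- comb_score(prof, pitch)$phase + pp$u0

  # orthogonal family for the x-phase
  pp2 <- projection_profile(img, angle + 90, weight)
  prof2 <- detrend_profile(pp2$profile)
  phase_v <- comb_score(prof2, pitch)$phase + pp2$u0

  structure(list(pitch_px = pitch, angle_deg = angle,
                 phase = c(py = phase_u %% pitch, px = phase_v %% pitch)),
            class = "track_line_model")
}

#' @export
print.track_line_model <- function(x, ...) {
  cat(sprintf("track_line_model: pitch %.2f px, angle %.3f deg, phase (%.2f, %.2f)\n",
              x$pitch_px, x$angle_deg, x$phase[1], x$phase[2]))
  invisible(x)
}

# replace track-line lane pixels by the median of off-lane pixels, so the
# final phase correlation is driven by tissue content, not the (possibly
# polarity-reversed) fiducial
suppress_track_lines <- function(image, model, halfwidth = NULL) {
  if (is.null(halfwidth)) halfwidth <- max(2, 0.05 * model$pitch_px)
  h <- nrow(image); w <- ncol(image)
  a <- model$angle_deg * pi / 180
  x <- rep(0:(w - 1L), each = h)
  y <- rep(0:(h - 1L), times = w)
  u <- y * cos(a) - x * sin(a)
  v <- x * cos(a) + y * sin(a)
  du <- abs(((u - model$phase[1] + model$pitch_px / 2) %% model$pitch_px) - model$pitch_px / 2)
  dv <- abs(((v - model$phase[2] + model$pitch_px / 2) %% model$pitch_px) - model$pitch_px / 2)
  lane <- du <= halfwidth | dv <= halfwidth
  out <- as.vector(image)
  out[lane] <- stats::median(out[!lane])
  matrix(out, h, w)
}

wrap90 <- function(a) {
  a <- a %% 90
  if (a > 45) a <- a - 90
  a
}

#' Register the nuclei stain to the spatial expression map (stage 2)
#'
#' Recovers the similarity transform (scale, rotation, flip,
#' translation) mapping nuclei-stain pixels to expression-map spots
#' using the chip track lines as fiducial.  The scale is
#' `chip_pitch_spots / pitch_px(nuclei)`; the fine rotation is the
#' track-line angle difference, disambiguated over the four 90-degree
#' quadrants and the horizontal flip by maximising a normalised
#' cross-correlation score of the transformed nuclei image against the
#' map; the translation is the score peak, refined to sub-pixel by
#' parabolic interpolation.  The score combines three FFT
#' cross-correlation surfaces: lane-suppressed stain content against the
#' smoothed map, the extracted bright line comb against the map's
#' molecule-free lane deficit (the marker is bright in the stain but
#' empty in the map, so the raw images must not be correlated directly),
#' and an anti-boundary term (nuclei blobs avoid the map's density
#' discontinuities at the true pose).
#'
#' @param nuclei Nuclei staining image (track lines visible).
#' @param expr_map Expression map raster (e.g. from [gem_to_map()]);
#'   its track lines are detected on the negated map.
#' @param chip_pitch_spots Track-line pitch in map units (chip
#'   geometry/instrument metadata; the synthetic generator provides it).
#' @param conf_threshold Minimum acceptable correlation score for the
#'   winning candidate.
#' @return A [similarity_transform()], with attributes `confidence` and
#'   `candidates` (the per-candidate confidence table).
#' @export
register_nuclei_to_map <- function(nuclei, expr_map, chip_pitch_spots,
                                   conf_threshold = 0.08) {
  tl_n <- detect_track_lines(nuclei)
  occ <- (expr_map > 0) * 1
  envelope <- as.matrix(EBImage::gblur(occ, 12))
  tl_m <- detect_track_lines(max(expr_map) - expr_map,
                             pitch_hint = chip_pitch_spots,
                             weight = envelope)
  scale <- chip_pitch_spots / tl_n$pitch_px

  # feature images.  Content: lane-suppressed, lightly smoothed stain vs
  # smoothed map (tissue envelope anchors the translation, per-cell
  # density texture carries the quadrant/flip information).  Lanes: the
  # extracted bright line excess of the stain vs the molecule-free lane
  # deficit of the map (sharp periodic comb, fixes the fine phase).
  # Boundaries: nuclei sit away from membranes, so the blob image
  # anti-correlates with the map's density discontinuities at the true
  # pose; the gradient-magnitude term scores that.
  sup <- suppress_track_lines(nuclei, tl_n)
  lines_n <- nuclei - sup
  # content smoothing proportional to the map-frame cell size: sparse
  # low-count maps need wide integration to reveal the per-cell density
  # texture, while strongly down-scaled maps need narrow kernels to
  # keep it
  sig_c <- min(max(8 * scale, 3), 10)
  nuc_c <- as.matrix(EBImage::gblur(sup, max(1, sig_c * 2 / 3)))
  map_c <- as.matrix(EBImage::gblur(expr_map, sig_c))
  occ_s <- as.matrix(EBImage::gblur(occ, 1.5))
  lane_m <- pmax(envelope - occ_s, 0)
  gm <- grad_mag(as.matrix(EBImage::gblur(expr_map, 2)))

  h <- nrow(expr_map); w <- ncol(expr_map)
  cn <- c((nrow(nuclei) - 1) / 2, (ncol(nuclei) - 1) / 2)   # (y, x)
  cm <- c((h - 1) / 2, (w - 1) / 2)
  map_cn <- unit_var(map_c); lane_mn <- unit_var(lane_m); gmn <- unit_var(gm)

  cands <- expand.grid(quadrant = c(0, 90, 180, 270),
                       flip = c("none", "horizontal"),
                       stringsAsFactors = FALSE)
  best <- NULL; bestconf <- -Inf; conftab <- numeric(nrow(cands))
  for (i in seq_len(nrow(cands))) {
    fl <- cands$flip[i]
    fine <- if (fl == "none") wrap90(tl_m$angle_deg - tl_n$angle_deg)
            else               wrap90(tl_m$angle_deg + tl_n$angle_deg)
    theta <- cands$quadrant[i] + fine
    t0 <- similarity_transform(scale, theta, fl, ty = 0, tx = 0)
    p <- st_apply(t0, cn[1], cn[2])
    t0$ty <- cm[1] - p$y; t0$tx <- cm[2] - p$x     # centre the content
    Wc <- unit_var(apply_transform(nuc_c, t0, c(h, w)))
    Wl <- unit_var(apply_transform(lines_n, t0, c(h, w)))
    surf <- xcorr_surface(Wc, map_cn) + xcorr_surface(Wl, lane_mn) -
      0.7 * xcorr_surface(Wc, gmn)
    pk <- which.max(surf)
    pi_ <- (pk - 1L) %% h + 1L; pj <- (pk - 1L) %/% h + 1L
    conftab[i] <- surf[pi_, pj]
    if (surf[pi_, pj] > bestconf) {
      bestconf <- surf[pi_, pj]
      best <- list(t0 = t0, surf = surf, pi = pi_, pj = pj)
    }
  }
  if (is.null(best) || bestconf < conf_threshold)
    stop("registration failed: no quadrant/flip candidate above confidence threshold")

  # the 1-D profile angle of the map is the least accurate ingredient;
  # polish the fine angle on the winning candidate by maximising the
  # 2-D correlation score directly
  score_at <- function(theta) {
    t0 <- similarity_transform(scale, theta, best$t0$flip, ty = 0, tx = 0)
    p <- st_apply(t0, cn[1], cn[2])
    t0$ty <- cm[1] - p$y; t0$tx <- cm[2] - p$x
    Wc <- unit_var(apply_transform(nuc_c, t0, c(h, w)))
    Wl <- unit_var(apply_transform(lines_n, t0, c(h, w)))
    surf <- xcorr_surface(Wc, map_cn) + xcorr_surface(Wl, lane_mn) -
      0.7 * xcorr_surface(Wc, gmn)
    # parabolic peak-height interpolation keeps the objective smooth in
    # theta (the raw max jumps between integer translations)
    pk <- which.max(surf)
    pi_ <- (pk - 1L) %% h + 1L; pj <- (pk - 1L) %/% h + 1L
    c0 <- surf[pi_, pj]
    elev <- function(m, p) {
      den <- m - 2 * c0 + p
      if (c0 >= m && c0 >= p && den < 0) -(m - p)^2 / (8 * den) else 0
    }
    im <- (pi_ - 2L) %% h + 1L; ip <- pi_ %% h + 1L
    jm <- (pj - 2L) %% w + 1L; jp <- pj %% w + 1L
    val <- c0 + elev(surf[im, pj], surf[ip, pj]) +
      elev(surf[pi_, jm], surf[pi_, jp])
    list(value = val, surf = surf, t0 = t0)
  }
  opt <- stats::optimize(function(a) score_at(a)$value,
                         interval = best$t0$rotation_deg + c(-1, 1),
                         maximum = TRUE, tol = 5e-3)
  fin <- score_at(opt$maximum)
  if (fin$value < bestconf) fin <- score_at(best$t0$rotation_deg)
  surf <- fin$surf
  pk <- which.max(surf)
  pi_ <- (pk - 1L) %% h + 1L; pj <- (pk - 1L) %/% h + 1L
  # integer peak -> wrapped shift, then parabolic sub-pixel refinement
  dy <- if (pi_ - 1L <= h / 2) pi_ - 1L else pi_ - 1L - h
  dx <- if (pj - 1L <= w / 2) pj - 1L else pj - 1L - w
  parab <- function(m, c0, p) {
    den <- m - 2 * c0 + p
    if (c0 >= m && c0 >= p && den < 0) 0.5 * (m - p) / den else 0
  }
  im <- (pi_ - 2L) %% h + 1L; ip <- pi_ %% h + 1L
  jm <- (pj - 2L) %% w + 1L; jp <- pj %% w + 1L
  peak <- surf[pi_, pj]
  dy <- dy + parab(surf[im, pj], peak, surf[ip, pj])
  dx <- dx + parab(surf[pi_, jm], peak, surf[pi_, jp])
  t <- fin$t0
  t$ty <- t$ty + dy
  t$tx <- t$tx + dx
  attr(t, "confidence") <- max(fin$value, bestconf)
  attr(t, "candidates") <- cbind(cands, confidence = conftab)
  attr(t, "track_lines") <- list(nuclei = tl_n, map = tl_m)
  t
}

# cross-correlation surface of two zero-mean unit-variance images; the
# peak sits at the (dy, dx) aligning a onto b
xcorr_surface <- function(a, b) {
  Re(stats::fft(stats::fft(b) * Conj(stats::fft(a)), inverse = TRUE)) /
    length(a)^2
}

unit_var <- function(m) {
  m <- m - mean(m)
  s <- stats::sd(as.vector(m))
  if (s > 0) m / s else m
}

grad_mag <- function(m) {
  h <- nrow(m); w <- ncol(m)
  gy <- matrix(0, h, w); gx <- matrix(0, h, w)
  gy[2:(h - 1), ] <- (m[3:h, ] - m[1:(h - 2), ]) / 2
  gx[, 2:(w - 1)] <- (m[, 3:w] - m[, 1:(w - 2)]) / 2
  sqrt(gy^2 + gx^2)
}
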
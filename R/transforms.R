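#' Similarity transform between the stain-image and expression-map frames
#'
#' A similarity transform maps stain-image pixel coordinates `(y, x)` to
#' expression-map coordinates by (in order) an optional horizontal flip
#' about the origin (`x -> -x`), a rotation by `rotation_deg` degrees,
#' an isotropic scaling, and a translation:
#' \deqn{(X, Y) = s \, R(\theta) \, F \, (x, y) + (t_x, t_y)}
#' Angles follow the image convention (y down): positive `rotation_deg`
#' rotates image content clockwise on screen.
#'
#' @param scale Positive scale factor (map pixels per stain pixel).
#' @param rotation_deg Rotation angle in degrees.
#' @param flip `"none"` or `"horizontal"`.
#' @param ty,tx Translation in map pixels.
#' @return An object of class `similarity_transform`.
#' @examples
#' t <- similarity_transform(0.5, 90, "none", ty = 12, tx = -7)
#' st_apply(t, y = 0, x = 0)
#' @export
similarity_transform <- function(scale = 1, rotation_deg = 0,
                                 flip = c("none", "horizontal"),
                                 ty = 0, tx = 0) {
  flip <- match.arg(flip)
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0)
    stop("scale must be a positive number")
  structure(list(scale = scale, rotation_deg = rotation_deg,
                 flip = flip, ty = ty, tx = tx),
            class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf(
    "similarity_transform: scale %.6g, rotation %.4g deg, flip %s, translation (ty %.4g, tx %.4g)\n",
    x$scale, x$rotation_deg, x$flip, x$ty, x$tx))
  invisible(x)
}

# 2x2 linear part acting on column vectors (x, y)
st_linear <- function(t) {
  th <- t$rotation_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
  F <- if (t$flip == "horizontal") diag(c(-1, 1)) else diag(2)
  t$scale * R %*% F
}

#' Apply a similarity transform to point coordinates
#'
#' @param t A [similarity_transform()].
#' @param y,x Numeric vectors of stain-frame coordinates.
#' @return List with numeric vectors `y` and `x` in map coordinates.
#' @export
st_apply <- function(t, y, x) {
  A <- st_linear(t)
  X <- A[1, 1] * x + A[1, 2] * y + t$tx
  Y <- A[2, 1] * x + A[2, 2] * y + t$ty
  list(y = Y, x = X)
}

#' Invert a similarity transform
#'
#' @param t A [similarity_transform()].
#' @return The inverse transform as a `similarity_transform` when
#'   representable (always, for this family), applied via [st_apply()].
#' @export
st_invert <- function(t) {
  A <- st_linear(t)
  Ai <- solve(A)
  ti <- -Ai %*% c(t$tx, t$ty)
  # inverse of s R F is (1/s) F^-1 R^-1 = (1/s) F R(-th * flipsign)
  if (t$flip == "none") {
    out <- similarity_transform(1 / t$scale, -t$rotation_deg, "none",
                                ty = ti[2], tx = ti[1])
  } else {
    # (s R F)^-1 = (1/s) F R(-th); and F R(-th) = R(th) F
    out <- similarity_transform(1 / t$scale, t$rotation_deg, "horizontal",
                                ty = ti[2], tx = ti[1])
  }
  stopifnot(max(abs(st_linear(out) - Ai)) < 1e-9)
  out
}

#' Compose a pixel offset with a similarity transform
#'
#' Builds the transform for a second stain channel: the channel is first
#' translated by `offset` into the reference (nuclei) stain frame, then
#' mapped to the expression map by `t`.  The composition is exact; no
#' re-estimation is performed.
#'
#' @param offset An offset estimate (list with `dy`, `dx`) such that a
#'   point `(y, x)` in the channel corresponds to `(y + dy, x + dx)` in
#'   the reference stain frame.
#' @param t The reference-stain-to-map [similarity_transform()].
#' @return The composed `similarity_transform`.
#' @export
compose_membrane_transform <- function(offset, t) {
  A <- st_linear(t)
  d <- A %*% c(offset$dx, offset$dy)
  similarity_transform(t$scale, t$rotation_deg, t$flip,
                       ty = t$ty + d[2], tx = t$tx + d[1])
}

#' Resample an image through a similarity transform
#'
#' The output is sampled on the target (map) grid by inverse mapping:
#' output pixel `(Y, X)` takes the value of the input image at
#' `t^{-1}(Y, X)`, interpolated bilinearly for intensity images or by
#' nearest neighbour for label masks.  Out-of-domain pixels are 0.
#'
#' @param image Numeric matrix (stain frame).
#' @param t A [similarity_transform()] mapping stain to map coordinates.
#' @param out_shape Integer `(h, w)` of the output raster.
#' @param interpolation `"bilinear"` or `"nearest"`.
#' @return Numeric matrix of shape `out_shape`.
#' @export
apply_transform <- function(image, t, out_shape,
                            interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  validate_image(image)
  if (length(out_shape) != 2L || any(out_shape < 1))
    stop("out_shape must be positive (h, w)")
  h <- as.integer(out_shape[1]); w <- as.integer(out_shape[2])
  ti <- st_invert(t)
  X <- rep(0:(w - 1L), each = h)
  Y <- rep(0:(h - 1L), times = w)
  p <- st_apply(ti, Y, X)
  sy <- p$y; sx <- p$x
  ih <- nrow(image); iw <- ncol(image)
  out <- numeric(h * w)
  if (interpolation == "nearest") {
    ry <- round(sy); rx <- round(sx)
    ok <- ry >= 0 & ry <= ih - 1L & rx >= 0 & rx <= iw - 1L
    out[ok] <- image[cbind(ry[ok] + 1L, rx[ok] + 1L)]
  } else {
    y0 <- floor(sy); x0 <- floor(sx)
    fy <- sy - y0;   fx <- sx - x0
    ok <- y0 >= -1 & y0 <= ih - 1L & x0 >= -1 & x0 <= iw - 1L
    # clamp the four corners; weights of out-of-range corners hit zeros
    gv <- function(yy, xx) {
      v <- numeric(sum(ok))
      in2 <- yy >= 0 & yy <= ih - 1L & xx >= 0 & xx <= iw - 1L
      v[in2] <- image[cbind(yy[in2] + 1L, xx[in2] + 1L)]
      v
    }
    y0k <- y0[ok]; x0k <- x0[ok]; fyk <- fy[ok]; fxk <- fx[ok]
    out[ok] <- gv(y0k, x0k) * (1 - fyk) * (1 - fxk) +
      gv(y0k + 1, x0k) * fyk * (1 - fxk) +
      gv(y0k, x0k + 1) * (1 - fyk) * fxk +
      gv(y0k + 1, x0k + 1) * fyk * fxk
  }
  matrix(out, h, w)
}
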
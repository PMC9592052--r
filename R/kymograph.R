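#' Long axis of a cell mask
#'
#' The line through the mask centroid along the principal direction of the
#' pixel second-moment matrix, clipped to the mask extent. Orientation
#' convention: angle in [0, pi), first endpoint at smaller x (ties broken by
#' smaller y). Coordinates are 0-based (x = column, y = row) pixel centres.
#'
#' @param mask Logical matrix with at least 10 TRUE pixels, or a vector of
#'   linear pixel indices plus `dim`.
#' @param dim Matrix dimensions when `mask` is an index vector.
#' @return List of class `axis_line`: `p1`, `p2` (each `c(x, y)`), `length`
#'   (px), `angle` (radians in [0, pi)), `aspect` (principal-axis ratio).
#'   Near-isotropic masks (aspect < 1.2) raise a warning but still return an
#'   axis.
#' @export
cell_long_axis <- function(mask, dim = NULL) {
  if (!is.matrix(mask)) {
    idx <- mask
    mask <- matrix(FALSE, dim[1], dim[2])
    mask[idx] <- TRUE
  }
  pix <- which(mask, arr.ind = TRUE)
  if (nrow(pix) < 10) stopf("mask has fewer than 10 pixels")
  x <- pix[, 2] - 1; y <- pix[, 1] - 1
  cx <- mean(x); cy <- mean(y)
  covm <- stats::cov(cbind(x, y))
  eg <- eigen(covm, symmetric = TRUE)
  v <- eg$vectors[, 1]
  aspect <- sqrt(max(eg$values[1], 0) / max(eg$values[2], 1e-12))
  if (aspect < 1.2)
    warnf("mask is nearly isotropic (aspect %.2f); long axis is ill-defined",
          aspect)
  angle <- atan2(v[2], v[1]) %% pi
  d <- c(cos(angle), sin(angle))
  t <- (x - cx) * d[1] + (y - cy) * d[2]
  tmin <- min(t) - 0.5; tmax <- max(t) + 0.5
  p1 <- c(cx, cy) + tmin * d
  p2 <- c(cx, cy) + tmax * d
  if (p2[1] < p1[1] || (p2[1] == p1[1] && p2[2] < p1[2])) {
    tmp <- p1; p1 <- p2; p2 <- tmp
  }
  structure(list(p1 = c(x = p1[1], y = p1[2]), p2 = c(x = p2[1], y = p2[2]),
                 length = tmax - tmin, angle = angle, aspect = aspect),
            class = "axis_line")
}

#' Build a kymograph along a line
#'
#' For each timepoint, intensity is sampled at unit steps along the line by
#' bilinear interpolation and averaged over `width` parallel lines offset
#' perpendicular to it (width must be odd). Row s of the result is position
#' s px from the line start; column t is frame t.
#'
#' @param series List of 2D matrices (one per timepoint), or a 3D array
#'   (t, y, x).
#' @param line An [cell_long_axis()] result, or a list with `p1`, `p2` in
#'   0-based (x, y) pixel coordinates.
#' @param width Odd integer; perpendicular averaging width in px.
#' @param pixel_size_nm,time_interval_s Optional calibration, attached to the
#'   result.
#' @return A `kymograph`: matrix (positions x timepoints) with attributes
#'   `um_per_px` and `s_per_frame`.
#' @export
build_kymograph <- function(series, line, width = 5, pixel_size_nm = NA,
                            time_interval_s = NA) {
  if (is.array(series) && length(dim(series)) == 3) {
    series <- lapply(seq_len(dim(series)[1]), function(t) {
      m <- series[t, , ]; dim(m) <- dim(series)[2:3]; m
    })
  }
  if (length(series) == 0) stopf("empty time series")
  if (width < 1 || width %% 2 == 0) stopf("width must be odd and >= 1")
  p1 <- line$p1; p2 <- line$p2
  len <- sqrt(sum((p2 - p1)^2))
  if (len <= 0) stopf("line has zero length")
  d <- (p2 - p1) / len
  n <- c(-d[2], d[1])
  npos <- ceiling(len)
  s <- seq(0, npos - 1)
  offs <- seq(-(width - 1) / 2, (width - 1) / 2)
  xs <- outer(p1[1] + s * d[1], offs * n[1], `+`)
  ys <- outer(p1[2] + s * d[2], offs * n[2], `+`)
  img1 <- series[[1]]
  nr <- nrow(img1); nc <- ncol(img1)
  if (any(xs < 0 | xs > nc - 1 | ys < 0 | ys > nr - 1)) {
    bad <- which(xs < 0 | xs > nc - 1 | ys < 0 | ys > nr - 1)[1]
    stopf("sampling line exits the image at (x=%.1f, y=%.1f)",
          xs[bad], ys[bad])
  }
  ky <- vapply(series, function(img) {
    v <- interp_bilinear(img, as.vector(xs), as.vector(ys))
    rowMeans(matrix(v, npos, length(offs)))
  }, numeric(npos))
  ky <- matrix(ky, nrow = npos)
  attr(ky, "um_per_px") <- if (is.na(pixel_size_nm)) NA_real_
  else pixel_size_nm / 1000
  attr(ky, "s_per_frame") <- time_interval_s
  class(ky) <- c("kymograph", class(ky))
  ky
}

#' Ridge position and velocity from a kymograph
#'
#' Per-column argmax with sub-pixel parabolic refinement, and a linear fit of
#' ridge position against frame index. A helper for velocity checks; the
#' kymograph itself is the primary output.
#'
#' @param kymo A [build_kymograph()] matrix.
#' @return List: `positions` (px, one per frame) and `velocity_px_per_frame`
#'   (slope of the linear fit).
#' @export
kymo_ridge <- function(kymo) {
  npos <- nrow(kymo)
  pos <- vapply(seq_len(ncol(kymo)), function(j) {
    col <- kymo[, j]
    i <- which.max(col)
    p <- i - 1
    if (i > 1 && i < npos) {
      den <- col[i - 1] - 2 * col[i] + col[i + 1]
      if (den != 0) p <- p + 0.5 * (col[i - 1] - col[i + 1]) / den
    }
    p
  }, numeric(1))
  fit <- stats::lm(pos ~ frame, data = data.frame(pos = pos,
                                                  frame = seq_along(pos) - 1))
  list(positions = pos,
       velocity_px_per_frame = unname(stats::coef(fit)[2]))
}
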
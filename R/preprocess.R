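#' Photobleaching correction of a time series
#'
#' Corrects intensity decay over time, per channel. `simple_ratio` rescales
#' every frame so its mean equals the first frame's mean. `exponential_fit`
#' fits `I(t) = a * exp(-k t) + c` to the frame means (t in frames) and
#' divides each frame by the fitted decay normalised to t = 0; the fitted
#' coefficients are attached as attribute `"fit"` (one row per channel). A
#' non-convergent fit falls back to `simple_ratio` with a warning.
#'
#' @param series An [image_stack()] with at least 3 timepoints.
#' @param mode `"simple_ratio"` (default) or `"exponential_fit"`.
#' @return A corrected [image_stack()]; for `exponential_fit` with attribute
#'   `"fit"` holding fitted `a`, `k`, `c` per channel.
#' @export
bleach_correct <- function(series, mode = c("simple_ratio", "exponential_fit")) {
  stopifnot(inherits(series, "image_stack"))
  mode <- match.arg(mode)
  d <- dim(series$data)
  if (d[1] < 3) stopf("bleach correction needs >= 3 timepoints, got %d", d[1])
  out <- series
  fits <- NULL
  for (ch in seq_len(d[2])) {
    m <- vapply(seq_len(d[1]), function(t) mean(series$data[t, ch, , , ]),
                numeric(1))
    if (any(m <= 0)) stopf("non-positive frame mean in channel %d", ch)
    if (mode == "simple_ratio") {
      scale <- m[1] / m
    } else {
      tt <- seq_len(d[1]) - 1
      fit <- tryCatch({
        k0 <- max(1e-4, -stats::coef(stats::lm(log(pmax(m - min(m) * 0.5,
                                                        1e-9)) ~ tt))[2])
        f <- minpack.lm::nlsLM(m ~ a * exp(-k * tt) + cc,
                               start = list(a = m[1] - min(m), k = k0,
                                            cc = min(m)),
                               lower = c(0, 0, 0),
                               control = minpack.lm::nls.lm.control(
                                 maxiter = 200))
        stats::coef(f)
      }, error = function(e) NULL)
      if (is.null(fit)) {
        warnf("exponential bleach fit did not converge in channel %d; falling back to simple_ratio",
              ch)
        scale <- m[1] / m
        fit <- c(a = NA_real_, k = NA_real_, cc = NA_real_)
      } else {
        decay <- (fit[["a"]] * exp(-fit[["k"]] * tt) + fit[["cc"]])
        scale <- decay[1] / decay
      }
      fits <- rbind(fits, data.frame(channel = ch, a = fit[["a"]],
                                     k = fit[["k"]], c = fit[["cc"]]))
    }
    for (t in seq_len(d[1])) {
      out$data[t, ch, , , ] <- series$data[t, ch, , , ] * scale[t]
    }
  }
  if (!is.null(fits)) attr(out, "fit") <- fits
  out
}

#' Estimate and apply a translation between two channels
#'
#' Estimates the translation of `moving` relative to `ref` by
#' cross-correlation (FFT-based, integer-pixel by default; optional subpixel
#' refinement by parabolic interpolation of the correlation peak), then
#' shifts `moving` by the negated shift so it aligns onto `ref`. Edge pixels
#' with no source data are set to `fill` and reported in `mask` so they can
#' be excluded from downstream statistics. Dual-camera misalignment is
#' treated as purely translational.
#'
#' @param ref,moving 2D numeric matrices of identical shape.
#' @param max_shift Maximum shift magnitude searched, in pixels per axis.
#' @param subpixel If `TRUE`, refine the estimate to subpixel precision and
#'   resample `moving` bilinearly.
#' @param fill Value for edge pixels without source data.
#' @return List with `shift` (named `c(dy, dx)`: the displacement of `moving`
#'   relative to `ref`), `aligned` (shifted `moving`), and `mask` (logical,
#'   `TRUE` where `aligned` holds real data).
#' @export
register_channels <- function(ref, moving, max_shift = 10, subpixel = FALSE,
                              fill = 0) {
  if (!is.matrix(ref) || !is.matrix(moving) ||
      !identical(dim(ref), dim(moving)))
    stopf("ref and moving must be matrices of identical shape")
  if (stats::sd(ref) == 0 || stats::sd(moving) == 0)
    stopf("no registration signal: at least one image is constant")
  nr <- nrow(ref); nc <- ncol(ref)
  r0 <- ref - mean(ref); m0 <- moving - mean(moving)
  # cc[dy, dx] = sum_x ref0(x) * moving0(x + d): peak at d = -true shift
  cc <- Re(stats::fft(stats::fft(m0) * Conj(stats::fft(r0)), inverse = TRUE))
  dys <- c(0:(nr - 1)); dys[dys > nr / 2] <- dys[dys > nr / 2] - nr
  dxs <- c(0:(nc - 1)); dxs[dxs > nc / 2] <- dxs[dxs > nc / 2] - nc
  allowed <- outer(abs(dys) <= max_shift, abs(dxs) <= max_shift)
  cc_in <- cc
  cc_in[!allowed] <- -Inf
  peak <- which(cc_in == max(cc_in), arr.ind = TRUE)[1, ]
  d_est <- c(dy = as.numeric(dys[peak[1]]), dx = as.numeric(dxs[peak[2]]))
  # clamped at the search boundary? then the true shift likely exceeds it
  cc_all <- cc
  peak_all <- which(cc_all == max(cc_all), arr.ind = TRUE)[1, ]
  if (!allowed[peak_all[1], peak_all[2]]) {
    warnf("correlation peak outside the +/-%d px search window; estimate clamped",
          max_shift)
  }
  if (subpixel) {
    # refine by evaluating the continuous correlation surface on a fine grid
    # around the integer peak (matrix DFT)
    X <- stats::fft(m0) * Conj(stats::fft(r0))
    fy <- 0:(nr - 1); fy[fy > nr / 2] <- fy[fy > nr / 2] - nr
    fx <- 0:(nc - 1); fx[fx > nc / 2] <- fx[fx > nc / 2] - nc
    uy <- d_est[["dy"]] + seq(-1, 1, by = 0.05)
    ux <- d_est[["dx"]] + seq(-1, 1, by = 0.05)
    Ey <- exp(2i * pi * outer(uy, fy) / nr)
    Ex <- exp(2i * pi * outer(ux, fx) / nc)
    S <- Re(Ey %*% X %*% t(Ex))
    pk <- which(S == max(S), arr.ind = TRUE)[1, ]
    d_est <- c(dy = uy[pk[1]], dx = ux[pk[2]])
  }
  aligned_mask <- shift_image(moving, -d_est["dy"], -d_est["dx"], fill)
  list(shift = d_est, aligned = aligned_mask$img, mask = aligned_mask$mask)
}

# shift a matrix by (dy, dx) pixels (non-circular); returns img + validity mask
shift_image <- function(img, dy, dx, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  if (dy == round(dy) && dx == round(dx)) {
    out <- matrix(fill, nr, nc); mask <- matrix(FALSE, nr, nc)
    sr <- seq_len(nr) - dy; sc <- seq_len(nc) - dx
    okr <- sr >= 1 & sr <= nr; okc <- sc >= 1 & sc <= nc
    out[okr, okc] <- img[sr[okr], sc[okc]]
    mask[okr, okc] <- TRUE
  } else {
    gx <- matrix(rep(seq_len(nc) - 1, each = nr), nr, nc) - dx
    gy <- matrix(rep(seq_len(nr) - 1, nc), nr, nc) - dy
    v <- interp_bilinear(img, as.vector(gx), as.vector(gy), fill = NA_real_)
    out <- matrix(v, nr, nc)
    mask <- !is.na(out)
    out[!mask] <- fill
  }
  list(img = out, mask = mask)
}
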
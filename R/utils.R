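#' Structure class palette
#'
#' Integer codes used throughout the package for per-pixel structure classes.
#' Label images are integer matrices with these codes; 0 is extracellular
#' background.
#'
#' @return Named integer vector mapping class name to code.
#' @export
class_codes <- function() {
  c(outside = 0L, cytoplasm = 1L, patch = 2L, cable = 3L, ring = 4L)
}

#' @rdname class_codes
#' @export
class_names <- function() names(class_codes())

code_of <- function(class) {
  cc <- class_codes()
  unname(cc[match(class, names(cc))])
}

name_of <- function(code) {
  class_names()[code + 1L]
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' 8-connected component labeling
#'
#' Labels connected components of a logical mask using 8-connectivity
#' (pixels sharing an edge or a corner belong to the same component).
#'
#' @param mask Logical matrix.
#' @return Integer matrix of the same shape; 0 for background, components
#'   numbered 1..k in raster-scan order of their first pixel.
#' @export
label_components <- function(mask) {
  if (!is.matrix(mask)) stopf("mask must be a matrix")
  mask <- mask & !is.na(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  todo <- which(mask)
  if (length(todo) == 0L) return(lab)
  # neighbour index offsets in column-major order (8-connectivity)
  off <- c(-1L, 1L, -nr, nr, -nr - 1L, -nr + 1L, nr - 1L, nr + 1L)
  inside <- matrix(FALSE, nr, nc)
  inside[mask] <- TRUE
  current <- 0L
  seen <- matrix(FALSE, nr, nc)
  for (start in todo) {
    if (seen[start]) next
    current <- current + 1L
    frontier <- start
    seen[start] <- TRUE
    while (length(frontier) > 0L) {
      lab[frontier] <- current
      # expand frontier; guard row wrap-around across matrix columns
      r <- ((frontier - 1L) %% nr) + 1L
      cand <- rep(frontier, each = 8L) + rep(off, times = length(frontier))
      rr <- rep(r, each = 8L) + rep(c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L),
                                    times = length(frontier))
      ok <- cand >= 1L & cand <= nr * nc & rr >= 1L & rr <= nr
      cand <- cand[ok]
      cand <- unique(cand[inside[cand] & !seen[cand]])
      seen[cand] <- TRUE
      frontier <- cand
    }
  }
  lab
}

# bilinear interpolation of matrix `img` at 0-based (x = col, y = row)
# coordinates; points outside the image return `fill` (NA by default).
interp_bilinear <- function(img, x, y, fill = NA_real_) {
  nr <- nrow(img); nc <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  ok <- x0 >= 0 & y0 >= 0 & x0 <= nc - 1 & y0 <= nr - 1
  # clamp upper edge so points exactly on the last row/col interpolate
  x1 <- pmin(x0 + 1, nc - 1); y1 <- pmin(y0 + 1, nr - 1)
  out <- rep(fill, length(x))
  if (!any(ok)) return(out)
  ix0 <- x0[ok]; iy0 <- y0[ok]; ix1 <- x1[ok]; iy1 <- y1[ok]
  gx <- fx[ok]; gy <- fy[ok]
  v00 <- img[cbind(iy0 + 1, ix0 + 1)]
  v01 <- img[cbind(iy0 + 1, ix1 + 1)]
  v10 <- img[cbind(iy1 + 1, ix0 + 1)]
  v11 <- img[cbind(iy1 + 1, ix1 + 1)]
  out[ok] <- (1 - gy) * ((1 - gx) * v00 + gx * v01) +
    gy * ((1 - gx) * v10 + gx * v11)
  out
}

# distance from points (px, py) to segment (ax,ay)-(bx,by); vectorised over
# points. All in the same units.
dist_to_segment <- function(px, py, ax, ay, bx, by) {
  vx <- bx - ax; vy <- by - ay
  len2 <- vx * vx + vy * vy
  if (len2 == 0) return(sqrt((px - ax)^2 + (py - ay)^2))
  t <- ((px - ax) * vx + (py - ay) * vy) / len2
  t <- pmin(1, pmax(0, t))
  sqrt((px - (ax + t * vx))^2 + (py - (ay + t * vy))^2)
}

# run code with a temporarily-set RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(code)
}
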
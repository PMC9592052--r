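#' Calibrated image stack
#'
#' Container for raw or rendered intensity data indexed
#' `(time, channel, z, y, x)` together with its physical calibration.
#' Singleton axes are allowed (a single 2D image is a 1x1x1xYxX stack).
#'
#' @param data Numeric array; 2D (y, x), 3D (z, y, x), 4D (c, z, y, x) or 5D
#'   (t, c, z, y, x). Lower-dimensional input gains singleton leading axes.
#' @param pixel_size_nm Lateral pixel size in nanometres; must be positive.
#' @param z_step_um Axial step in micrometres (NA if single plane).
#' @param time_interval_s Frame interval in seconds (NA if single timepoint).
#' @param channel_names Optional character vector, one per channel.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(data, pixel_size_nm, z_step_um = NA_real_,
                        time_interval_s = NA_real_, channel_names = NULL) {
  if (is.matrix(data)) dim(data) <- c(1L, 1L, 1L, dim(data))
  nd <- length(dim(data))
  if (nd < 2 || nd > 5) stopf("data must have 2 to 5 dimensions")
  if (nd < 5) dim(data) <- c(rep(1L, 5 - nd), dim(data))
  if (any(data < 0, na.rm = TRUE)) stopf("intensities must be >= 0")
  if (!is.numeric(pixel_size_nm) || pixel_size_nm <= 0)
    stopf("pixel_size_nm must be > 0")
  if (!is.null(channel_names) && length(channel_names) != dim(data)[2])
    stopf("channel_names length (%d) does not match channel axis (%d)",
          length(channel_names), dim(data)[2])
  structure(list(data = data,
                 pixel_size_nm = pixel_size_nm,
                 z_step_um = z_step_um,
                 time_interval_s = time_interval_s,
                 channel_names = channel_names),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("image_stack: %d t x %d c x %d z x %d y x %d x, %.0f nm/px",
              d[1], d[2], d[3], d[4], d[5], x$pixel_size_nm))
  if (!is.na(x$z_step_um)) cat(sprintf(", z-step %.2f um", x$z_step_um))
  if (!is.na(x$time_interval_s)) cat(sprintf(", dt %.1f s", x$time_interval_s))
  cat("\n")
  invisible(x)
}

# pull one 2D plane as a plain matrix
stack_plane <- function(stack, t = 1, c = 1, z = 1) {
  m <- stack$data[t, c, z, , ]
  dim(m) <- dim(stack$data)[4:5]
  m
}

#' Write / read a calibrated stack as multi-page TIFF
#'
#' Pixel data are written as 16-bit unsigned TIFF pages in TCZYX order
#' (z fastest); calibration metadata go to a JSON sidecar `<path>.json`.
#' Values are rounded to integers and clipped to 0..65535. A write/read
#' round trip preserves integer pixel values exactly.
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path.
#' @return `write_stack`: the path, invisibly. `read_stack`: an
#'   [image_stack()].
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  pages <- vector("list", d[1] * d[2] * d[3])
  i <- 0L
  for (t in seq_len(d[1])) for (ch in seq_len(d[2])) for (z in seq_len(d[3])) {
    i <- i + 1L
    pages[[i]] <- pmin(pmax(round(stack_plane(stack, t, ch, z)), 0), 65535) / 65535
  }
  ok <- tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(axes = "TCZYX", shape = as.integer(d),
               pixel_size_nm = stack$pixel_size_nm,
               z_step_um = stack$z_step_um,
               time_interval_s = stack$time_interval_s,
               channel_names = stack$channel_names)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_stack
#' @param shape Integer vector (t, c, z) page layout override, used when no
#'   JSON sidecar is present.
#' @param pixel_size_nm,z_step_um,time_interval_s,channel_names Metadata
#'   overrides; required when the sidecar is absent (pixel size at minimum).
#' @export
read_stack <- function(path, shape = NULL, pixel_size_nm = NULL,
                       z_step_um = NULL, time_interval_s = NULL,
                       channel_names = NULL) {
  if (!file.exists(path)) stopf("cannot read '%s': no such file", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
  else list()
  if (!is.null(meta$axes) && !identical(meta$axes, "TCZYX"))
    stopf("unsupported axis order '%s' in sidecar (expected TCZYX)", meta$axes)
  shp <- if (!is.null(shape)) as.integer(shape[1:3])
  else if (!is.null(meta$shape)) as.integer(meta$shape[1:3])
  else c(1L, 1L, length(pages))
  if (prod(shp) != length(pages))
    stopf("page layout (t=%d, c=%d, z=%d) does not match %d TIFF pages",
          shp[1], shp[2], shp[3], length(pages))
  px <- if (!is.null(pixel_size_nm)) pixel_size_nm else meta$pixel_size_nm
  if (is.null(px))
    stopf("pixel_size_nm missing: not in sidecar '%s' and no override given",
          side)
  zs <- if (!is.null(z_step_um)) z_step_um
  else if (!is.null(meta$z_step_um)) meta$z_step_um else NA_real_
  ti <- if (!is.null(time_interval_s)) time_interval_s
  else if (!is.null(meta$time_interval_s)) meta$time_interval_s else NA_real_
  cn <- if (!is.null(channel_names)) channel_names else meta$channel_names
  yx <- dim(pages[[1]])[1:2]
  data <- array(0, c(shp, yx))
  i <- 0L
  for (t in seq_len(shp[1])) for (ch in seq_len(shp[2]))
    for (z in seq_len(shp[3])) {
      i <- i + 1L
      pg <- pages[[i]]
      if (length(dim(pg)) == 3L) pg <- pg[, , 1]  # tolerate grey-as-RGB
      data[t, ch, z, , ] <- round(pg * 65535)
    }
  image_stack(data, pixel_size_nm = px, z_step_um = zs,
              time_interval_s = ti,
              channel_names = if (length(cn) > 0) cn else NULL)
}

#' Project a stack along z
#'
#' Collapses the z axis by the pixelwise mean or maximum, per timepoint and
#' channel. The quantification pipeline uses the average projection; maximum
#' projection is for display and kymographs.
#'
#' @param stack An [image_stack()].
#' @param mode `"average"` or `"maximum"`.
#' @return A `projected_image`: list with `data` (t, c, y, x array),
#'   `projection_mode`, and the source calibration.
#' @export
project <- function(stack, mode = c("average", "maximum")) {
  stopifnot(inherits(stack, "image_stack"))
  mode <- match.arg(mode)
  d <- dim(stack$data)
  out <- array(0, c(d[1], d[2], d[4], d[5]))
  for (t in seq_len(d[1])) for (ch in seq_len(d[2])) {
    planes <- stack$data[t, ch, , , , drop = FALSE]
    dim(planes) <- d[3:5]
    out[t, ch, , ] <- if (mode == "average") colMeans(planes, dims = 1)
    else apply(planes, c(2, 3), max)
  }
  structure(list(data = out, projection_mode = mode,
                 pixel_size_nm = stack$pixel_size_nm,
                 time_interval_s = stack$time_interval_s,
                 channel_names = stack$channel_names),
            class = "projected_image")
}

# pull one 2D channel plane from a projected image
proj_plane <- function(proj, t = 1, c = 1) {
  m <- proj$data[t, c, , ]
  dim(m) <- dim(proj$data)[3:4]
  m
}
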
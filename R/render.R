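#' Optics and camera noise model
#'
#' Parameters of the simulated microscope: pixel size, z-sampling, a
#' separable Gaussian approximation of the point-spread function, and a
#' shot-noise / read-noise camera model. Photon rates are converted to camera
#' counts as `counts = photons / photons_per_count + offset (+ read noise)`.
#'
#' @param pixel_size_nm Lateral pixel size in nanometres (default 69).
#' @param n_zplanes Number of z-planes (default 16); 1 gives the fast 2D mode.
#' @param z_step_um Axial step between planes in micrometres (default 0.4).
#' @param psf_sigma_xy Lateral PSF sigma in pixels.
#' @param psf_sigma_z Axial PSF sigma in planes.
#' @param poisson_noise Apply shot noise to the photon image?
#' @param read_noise_sd Gaussian read noise, in counts.
#' @param camera_offset Camera baseline, in counts.
#' @param photons_per_count Conversion gain (photons per camera count).
#' @return A list of class `optics_model`.
#' @export
optics_model <- function(pixel_size_nm = 69,
                         n_zplanes = 16,
                         z_step_um = 0.4,
                         psf_sigma_xy = 1.1,
                         psf_sigma_z = 1.0,
                         poisson_noise = TRUE,
                         read_noise_sd = 3,
                         camera_offset = 100,
                         photons_per_count = 1) {
  if (pixel_size_nm <= 0) stopf("pixel_size_nm must be > 0")
  if (psf_sigma_xy < 0 || psf_sigma_z < 0) stopf("psf sigmas must be >= 0")
  if (n_zplanes < 1) stopf("n_zplanes must be >= 1")
  out <- as.list(environment())
  class(out) <- "optics_model"
  out
}

# footprint half-width used for ground-truth labels: the structure's
# effective extent, 2 sigma (~86% encircled energy for a 2D Gaussian spot)
footprint_half <- function(sigma) 2 * sigma

# evaluate one cell's structure photon field and ground-truth labels on the
# pixel grid. Returns list(ch1 = matrix of structure photons, dec = matrix of
# per-pixel channel-2 fraction contributions, labels = integer matrix).
render_cell_structures <- function(cell, scene, px_um, nr, nc) {
  # bounding window of the cell (pixel indices, 1-based)
  ax <- capsule_axis(cell)
  pad <- cell$radius + 1
  xs <- range(ax$a[1], ax$b[1]) + c(-pad, pad)
  ys <- range(ax$a[2], ax$b[2]) + c(-pad, pad)
  c0 <- max(1L, floor(xs[1] / px_um) + 1L); c1 <- min(nc, ceiling(xs[2] / px_um) + 1L)
  r0 <- max(1L, floor(ys[1] / px_um) + 1L); r1 <- min(nr, ceiling(ys[2] / px_um) + 1L)
  if (c0 > c1 || r0 > r1)
    stopf("cell at (%.1f, %.1f) um lies outside the image bounds",
          cell$center[1], cell$center[2])
  rows <- r0:r1; cols <- c0:c1
  # pixel-centre coordinates in um (0-based convention: pixel (0,0) at origin)
  X <- matrix((cols - 1L) * px_um, length(rows), length(cols), byrow = TRUE)
  Y <- matrix((rows - 1L) * px_um, length(rows), length(cols))
  win_dim <- dim(X)

  s_patch <- matrix(0, win_dim[1], win_dim[2])
  s_patch_dec <- s_patch   # decorated patches only
  s_cable <- s_patch; s_ring <- s_patch
  lab <- matrix(0L, win_dim[1], win_dim[2])

  inside <- capsule_dist(cell, as.vector(X), as.vector(Y)) <= cell$radius
  inside <- matrix(inside, win_dim[1], win_dim[2])

  for (p in cell$patches) {
    if (p$amplitude_ch1 <= 0) next
    d2 <- (X - p$center[1])^2 + (Y - p$center[2])^2
    if (p$sigma_um < px_um / 2) {
      # point-like: deposit the full amplitude at the nearest pixel
      g <- matrix(0, win_dim[1], win_dim[2])
      g[which.min(d2)] <- p$amplitude_ch1
      foot <- g > 0
    } else {
      g <- p$amplitude_ch1 * exp(-d2 / (2 * p$sigma_um^2))
      foot <- d2 <= footprint_half(p$sigma_um)^2
    }
    s_patch <- s_patch + g
    if (isTRUE(p$decorated)) s_patch_dec <- s_patch_dec + g
    lab[foot & lab == 0L] <- code_of("patch")
  }
  for (cb in cell$cables) {
    v <- cb$vertices
    d <- rep(Inf, length(X))
    for (i in seq_len(nrow(v) - 1L)) {
      d <- pmin(d, dist_to_segment(as.vector(X), as.vector(Y),
                                   v[i, 1], v[i, 2], v[i + 1, 1], v[i + 1, 2]))
    }
    d <- matrix(d, win_dim[1], win_dim[2])
    s_cable <- s_cable + cb$amplitude_ch1 * exp(-d^2 / (2 * cb$sigma_um^2))
    foot <- d <= footprint_half(cb$sigma_um) & inside
    lab[foot & lab == 0L] <- code_of("cable")
  }
  if (!is.null(cell$ring)) {
    rg <- cell$ring
    # axial coordinate along the cell axis, measured from one capsule end
    tproj <- ((X - ax$a[1]) * ax$dir[1] + (Y - ax$a[2]) * ax$dir[2])
    seg_len <- sqrt(sum((ax$b - ax$a)^2))
    pos <- (rg$axial_position - 0.5) * seg_len + seg_len / 2
    dax <- abs(tproj - pos)
    g <- rg$amplitude_ch1 * exp(-dax^2 / (2 * rg$sigma_um^2))
    g[!inside] <- 0
    s_ring <- s_ring + g
    foot <- dax <= footprint_half(rg$sigma_um) & inside
    lab[foot] <- code_of("ring")   # ring wins over patch and cable
  }
  lab[lab == 0L & inside] <- code_of("cytoplasm")

  ratio <- scene$decoration_ratio
  ch1 <- s_patch + s_cable + s_ring
  ch2 <- ratio[["patch"]] * s_patch_dec + ratio[["cable"]] * s_cable +
    ratio[["ring"]] * s_ring
  list(rows = rows, cols = cols, ch1 = ch1, ch2 = ch2, lab = lab,
       inside = inside)
}

# 1D gaussian blur along the z axis of a (z, y, x) array
blur_z <- function(arr, sigma) {
  nz <- dim(arr)[1]
  if (sigma <= 0 || nz == 1) return(arr)
  half <- ceiling(3 * sigma)
  k <- exp(-(-half:half)^2 / (2 * sigma^2)); k <- k / sum(k)
  out <- array(0, dim(arr))
  for (j in seq_along(k)) {
    src <- pmin(pmax(seq_len(nz) + (j - half - 1L), 1L), nz)  # replicate edges
    out <- out + k[j] * arr[src, , , drop = FALSE]
  }
  out
}

#' Render a scene through the optics model
#'
#' Rasterises a [sample_scene()] ground truth into a two-channel image stack
#' plus a per-pixel ground-truth label image. Channel-2 structure amplitude is
#' `decoration_ratio[class] * channel-1 amplitude * expression_scale_ch2`
#' before blurring and noise; labels record each pixel's generating class
#' (within the structure profile's 2-sigma effective extent) before blurring, with
#' precedence ring > patch > cable > cytoplasm > outside. With noise off and
#' `psf_sigma_xy = 0` the rendered photon image is exactly the analytic sum of
#' outside level, cytoplasm level and structure profiles.
#'
#' In multi-plane mode the cell body occupies the z-planes within one cell
#' radius of the stack centre; structures sit in the central plane and are
#' spread axially by the PSF.
#'
#' @param scene A `scene_ground_truth`.
#' @param optics An [optics_model()].
#' @param seed Seed for the noise draw; defaults to `scene$seed + 1`.
#' @return List with `stack` (an [image_stack()], counts), `labels` (integer
#'   matrix, see [class_codes()]), and `photons` (noiseless, unblurred photon
#'   arrays per channel, for diagnostics).
#' @export
render_scene <- function(scene, optics, seed = scene$seed + 1L) {
  stopifnot(inherits(scene, "scene_ground_truth"),
            inherits(optics, "optics_model"))
  px_um <- optics$pixel_size_nm / 1000
  nr <- round(scene$fov_um[1] / px_um)
  nc <- round(scene$fov_um[2] / px_um)
  base1 <- matrix(scene$outside_level[["factin"]], nr, nc)
  base2 <- matrix(scene$outside_level[["tpm"]], nr, nc)
  s1 <- matrix(0, nr, nc); s2 <- matrix(0, nr, nc)
  inside_any <- matrix(FALSE, nr, nc)
  labels <- matrix(0L, nr, nc)
  for (cell in scene$cells) {
    rc <- render_cell_structures(cell, scene, px_um, nr, nc)
    s1[rc$rows, rc$cols] <- s1[rc$rows, rc$cols] + rc$ch1
    s2[rc$rows, rc$cols] <- s2[rc$rows, rc$cols] + rc$ch2
    inside_any[rc$rows, rc$cols] <- inside_any[rc$rows, rc$cols] | rc$inside
    # later cells do not overwrite earlier structure labels
    w <- labels[rc$rows, rc$cols]
    take <- rc$lab > w
    w[take] <- rc$lab[take]
    labels[rc$rows, rc$cols] <- w
  }
  s2 <- s2 * scene$expression_scale_ch2
  cyt1 <- scene$cytoplasm_level[["factin"]] - scene$outside_level[["factin"]]
  cyt2 <- (scene$cytoplasm_level[["tpm"]] - scene$outside_level[["tpm"]]) *
    scene$expression_scale_ch2
  ph1 <- base1 + cyt1 * inside_any + s1
  ph2 <- base2 + cyt2 * inside_any + s2

  nz <- optics$n_zplanes
  cell_r <- if (length(scene$cells) > 0)
    max(vapply(scene$cells, function(x) x$radius, numeric(1))) else 1.75
  mk_planes <- function(base_lvl, cyt_excess, s) {
    arr <- array(0, c(nz, nr, nc))
    zc <- (nz + 1) / 2
    in_cell_z <- abs(seq_len(nz) - zc) * optics$z_step_um <= cell_r
    if (nz == 1) in_cell_z <- TRUE
    for (z in seq_len(nz)) {
      arr[z, , ] <- base_lvl + if (in_cell_z[z]) cyt_excess * inside_any else 0
    }
    zmid <- round(zc)
    arr[zmid, , ] <- arr[zmid, , ] + s
    arr
  }
  a1 <- mk_planes(scene$outside_level[["factin"]], cyt1, s1)
  a2 <- mk_planes(scene$outside_level[["tpm"]], cyt2, s2)

  if (optics$psf_sigma_xy > 0) {
    for (z in seq_len(nz)) {
      a1[z, , ] <- EBImage::gblur(a1[z, , ], optics$psf_sigma_xy,
                                  boundary = "replicate")
      a2[z, , ] <- EBImage::gblur(a2[z, , ], optics$psf_sigma_xy,
                                  boundary = "replicate")
    }
  }
  if (nz > 1 && optics$psf_sigma_z > 0) {
    a1 <- blur_z(a1, optics$psf_sigma_z)
    a2 <- blur_z(a2, optics$psf_sigma_z)
  }

  data <- array(0, c(1, 2, nz, nr, nc))
  with_seed(if (is.null(seed)) NULL else as.integer(seed) %% .Machine$integer.max, {
    for (chan in 1:2) {
      a <- if (chan == 1) a1 else a2
      if (optics$poisson_noise) {
        a <- array(stats::rpois(length(a), pmax(a, 0)), dim(a))
      }
      counts <- a / optics$photons_per_count + optics$camera_offset
      if (optics$read_noise_sd > 0) {
        counts <- counts + stats::rnorm(length(counts), 0,
                                        optics$read_noise_sd)
      }
      data[1, chan, , , ] <- pmax(counts, 0)
    }
  })
  stack <- image_stack(data, pixel_size_nm = optics$pixel_size_nm,
                       z_step_um = optics$z_step_um,
                       channel_names = c("factin", "tpm"))
  list(stack = stack, labels = labels,
       photons = list(factin = ph1, tpm = ph2))
}
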
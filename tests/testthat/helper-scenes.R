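# Shared fixture builders. Everything is generated in code at test time.

# small fast scene: few cells in a compact field, 2D rendering
small_scene_config <- function(n_cells = 2, fov_um = c(18, 18), ...) {
  scene_config(n_cells = n_cells, fov_um = fov_um, ...)
}

fast_optics <- function(...) {
  optics_model(n_zplanes = 1, ...)
}

clean_optics <- function(psf_sigma_xy = 0, ...) {
  # noiseless, unblurred, no camera: rendered counts equal photons
  optics_model(n_zplanes = 1, psf_sigma_xy = psf_sigma_xy,
               poisson_noise = FALSE, read_noise_sd = 0, camera_offset = 0,
               ...)
}

render_small <- function(seed, config = small_scene_config(),
                         optics = fast_optics()) {
  render_scene(sample_scene(config, seed = seed), optics)
}

# pull the two projected channel planes of a 2D rendering
channels_of <- function(rendered) {
  d <- dim(rendered$stack$data)
  list(factin = matrix(rendered$stack$data[1, 1, 1, , ], d[4], d[5]),
       tpm = matrix(rendered$stack$data[1, 2, 1, , ], d[4], d[5]))
}

# piecewise-constant toy cell on a blank field:
#   a rectangular cell with a square structure ROI; intensities chosen per
#   channel for closed-form decoration ratios.
# Returns label image plus the two channel images.
toy_cell <- function(roi_f, cyt_f, out_f, cell_f = NULL,
                     roi_t, cyt_t, out_t, cell_t = NULL,
                     roi_class = "patch") {
  cc <- class_codes()
  lab <- matrix(cc[["outside"]], 60, 60)
  lab[11:50, 11:50] <- cc[["cytoplasm"]]
  lab[26:35, 26:35] <- cc[[roi_class]]
  f <- matrix(out_f, 60, 60); t2 <- matrix(out_t, 60, 60)
  f[11:50, 11:50] <- cyt_f; t2[11:50, 11:50] <- cyt_t
  f[26:35, 26:35] <- roi_f; t2[26:35, 26:35] <- roi_t
  list(labels = lab, factin = f, tpm = t2)
}

# brute-force 3x3 erosion oracle: a pixel survives iff all 8 neighbours and
# itself are in the mask (image border counts as background)
erode3_oracle <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  for (i in 2:(nr - 1)) for (j in 2:(nc - 1)) {
    out[i, j] <- all(mask[(i - 1):(i + 1), (j - 1):(j + 1)])
  }
  out
}

# sort-discard-average oracle for the one-sided trimmed mean
trimmed_mean_oracle <- function(v, q, side) {
  k <- floor(q * length(v))
  s <- sort(v)
  kept <- if (side == "lowest") s[seq(k + 1, length(s))]
  else s[seq_len(length(s) - k)]
  mean(kept)
}
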
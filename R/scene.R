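#' Generator settings for synthetic two-channel scenes
#'
#' Builds the configuration consumed by [sample_scene()]. The defaults emulate
#' fields of rod-shaped fission-yeast cells co-expressing a tropomyosin
#' reporter (channel 2) and an F-actin reporter (channel 1): capsule-shaped
#' cells 3.5 um wide and 7-14 um long carrying diffraction-limited endocytic
#' patches biased toward the cell tips, thin cables roughly parallel to the
#' long axis, and - in a fraction of (dividing) cells - a medial cytokinetic
#' ring.
#'
#' Channel-2 structure amplitude is `decoration_ratio[class] * channel-1
#' amplitude * expression_scale_ch2`, applied to the structure signal above
#' cytoplasm. Only a subset of patches (`patch_decorated_fraction`) carry any
#' channel-2 signal. Absolute intensity scales are free parameters of the
#' simulation; the defaults are plausible photon counts for 100 ms
#' spinning-disk imaging of fluorescent-protein fusions.
#'
#' Channel 2 is expressed in expression-normalised units: its cytoplasmic
#' excess above background equals channel 1's, and any true expression-level
#' difference is the single global factor `expression_scale_ch2`, which is
#' exactly what the decoration-ratio statistic's cell-level normalisation
#' cancels. This makes the configured `decoration_ratio` the quantity the
#' statistic estimates.
#'
#' @param n_cells Number of isolated (non-clump) cells to place.
#' @param n_clumps Number of deliberate cell clumps (each `clump_size`
#'   touching cells) placed so clump rejection is testable.
#' @param clump_size Cells per clump.
#' @param fov_um Field of view (y, x) in micrometres.
#' @param cell_radius_um Cell capsule radius (half the rod diameter).
#' @param cell_length_range_um Range cell lengths are drawn from (uniform).
#' @param decoration_ratio Named fractions for patch, cable, ring: channel-2
#'   structure amplitude as a fraction of channel-1 amplitude.
#' @param patch_decorated_fraction Fraction of patches carrying channel-2
#'   signal.
#' @param n_patches_mean Mean patches per cell (Poisson).
#' @param n_cables_range Range of cables per cell (uniform integer).
#' @param ring_fraction Fraction of cells carrying a medial ring.
#' @param patch_sigma_um Gaussian radius (sigma) of a patch.
#' @param cable_sigma_um Gaussian half-width (sigma) of a cable profile.
#' @param ring_sigma_um Gaussian half-thickness (sigma) of the ring band.
#' @param patch_amplitude,cable_amplitude,ring_amplitude Channel-1 peak
#'   amplitudes (photons above cytoplasm).
#' @param cytoplasm_level Per-channel cytoplasmic photon level
#'   (named factin, tpm).
#' @param outside_level Per-channel extracellular photon level.
#' @param expression_scale_ch2 Global multiplicative factor on channel 2.
#' @param min_clearance_um Minimum gap between non-clump cells.
#' @param max_place_tries Placement rejection-sampling budget per cell.
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(n_cells = 4,
                         n_clumps = 0,
                         clump_size = 4,
                         fov_um = c(35.328, 35.328),
                         cell_radius_um = 1.75,
                         cell_length_range_um = c(7, 14),
                         decoration_ratio = c(patch = 0.14, cable = 0.97,
                                              ring = 0.95),
                         patch_decorated_fraction = 0.5,
                         n_patches_mean = 5,
                         n_cables_range = c(2, 3),
                         ring_fraction = 0.3,
                         patch_sigma_um = 0.15,
                         cable_sigma_um = 0.09,
                         ring_sigma_um = 0.2,
                         patch_amplitude = 400,
                         cable_amplitude = 180,
                         ring_amplitude = 350,
                         cytoplasm_level = c(factin = 300, tpm = 300),
                         outside_level = c(factin = 10, tpm = 10),
                         expression_scale_ch2 = 1,
                         min_clearance_um = 0.5,
                         max_place_tries = 200) {
  cfg <- as.list(environment())
  stopifnot(length(cfg$fov_um) == 2, all(cfg$fov_um > 0))
  if (any(cfg$decoration_ratio < 0))
    stopf("decoration_ratio values must be >= 0")
  if (!all(c("patch", "cable", "ring") %in% names(cfg$decoration_ratio)))
    stopf("decoration_ratio must name patch, cable and ring")
  if (cfg$cytoplasm_level[["factin"]] <= cfg$outside_level[["factin"]])
    stopf("cytoplasm_level must exceed outside_level in channel 1 (factin)")
  class(cfg) <- "scene_config"
  cfg
}

# capsule axis endpoints (the segment whose r-neighbourhood is the cell)
capsule_axis <- function(cell) {
  half <- max(cell$length / 2 - cell$radius, 0)
  d <- c(cos(cell$orientation), sin(cell$orientation))
  list(a = cell$center - half * d, b = cell$center + half * d, dir = d)
}

# distance from a point to the cell's axis segment
capsule_dist <- function(cell, x, y) {
  ax <- capsule_axis(cell)
  dist_to_segment(x, y, ax$a[1], ax$a[2], ax$b[1], ax$b[2])
}

cells_overlap <- function(c1, c2, clearance = 0) {
  a1 <- capsule_axis(c1); a2 <- capsule_axis(c2)
  # min distance between the two axis segments via dense sampling
  t <- seq(0, 1, length.out = 25)
  p1x <- a1$a[1] + t * (a1$b[1] - a1$a[1])
  p1y <- a1$a[2] + t * (a1$b[2] - a1$a[2])
  d <- vapply(seq_along(t), function(i)
    min(dist_to_segment(p1x[i], p1y[i], a2$a[1], a2$a[2],
                        a2$b[1], a2$b[2])), numeric(1))
  min(d) < c1$radius + c2$radius + clearance
}

place_one_cell <- function(cfg, existing, overlap_with = NULL,
                           contact_ok = list()) {
  fov <- cfg$fov_um
  for (i in seq_len(cfg$max_place_tries)) {
    len <- stats::runif(1, cfg$cell_length_range_um[1],
                        cfg$cell_length_range_um[2])
    r <- cfg$cell_radius_um
    if (is.null(overlap_with)) {
      margin <- len / 2 + 0.3
      if (2 * margin >= min(fov)) next   # cell cannot fit at this length
      ctr <- c(stats::runif(1, margin, fov[2] - margin),
               stats::runif(1, margin, fov[1] - margin))
      theta <- stats::runif(1, 0, pi)
    } else {
      # attach against a random point of the anchor's surface (a clump)
      base <- overlap_with
      bax <- capsule_axis(base)
      half_b <- max(base$length / 2 - base$radius, 0)
      t <- stats::runif(1, -half_b, half_b)
      on_axis <- base$center + t * bax$dir
      phi <- stats::runif(1, 0, 2 * pi)
      u <- c(cos(phi), sin(phi))
      ctr <- on_axis + u * (base$radius + r - 0.15) +
        stats::runif(2, -0.3, 0.3)
      theta <- base$orientation + stats::runif(1, -0.7, 0.7)
    }
    cand <- list(center = ctr, orientation = theta %% pi, length = len,
                 radius = r)
    # must fit in the field of view
    ax <- capsule_axis(cand)
    pts <- rbind(ax$a, ax$b)
    if (any(pts[, 1] < r | pts[, 1] > fov[2] - r |
            pts[, 2] < r | pts[, 2] > fov[1] - r)) next
    clash <- FALSE
    for (e in existing) {
      is_anchor <- !is.null(overlap_with) && identical(e, overlap_with)
      is_member <- any(vapply(contact_ok, identical, logical(1), e))
      if (is_anchor) next
      if (is_member) {
        # fellow clump members may touch, but overlap at most ~20% of width
        if (cells_overlap(cand, e, -0.2 * (cand$radius + e$radius))) {
          clash <- TRUE; break
        }
      } else if (cells_overlap(cand, e, cfg$min_clearance_um)) {
        clash <- TRUE; break
      }
    }
    if (!clash &&
        (is.null(overlap_with) || cells_overlap(cand, overlap_with, 0)))
      return(cand)
  }
  NULL
}

# random point inside the capsule, optionally biased toward the tips
sample_point_in_cell <- function(cell, margin, tip_bias = 0) {
  ax <- capsule_axis(cell)
  half <- max(cell$length / 2 - cell$radius, 1e-6)
  repeat {
    if (tip_bias > 0 && stats::runif(1) < tip_bias) {
      # cortical tip patch: in the hemispherical cap dome, beyond the shaft
      t <- sample(c(-1, 1), 1) *
        (half + stats::runif(1, 0, max(cell$radius - margin, 0)))
    } else {
      t <- stats::runif(1, -half, half)
    }
    off <- stats::runif(1, -(cell$radius - margin), cell$radius - margin)
    n <- c(-ax$dir[2], ax$dir[1])
    p <- cell$center + t * ax$dir + off * n
    if (capsule_dist(cell, p[1], p[2]) <= cell$radius - margin) return(p)
  }
}

make_cable <- function(cell, cfg) {
  ax <- capsule_axis(cell)
  half <- max(cell$length / 2 - cell$radius, 0.5)
  n <- c(-ax$dir[2], ax$dir[1])
  lateral0 <- stats::runif(1, -0.6, 0.6) * cell$radius
  # cables span the cylindrical shaft; they end before the tip domes, where
  # the endocytic patches live
  ts <- seq(-half * 0.8, half * 0.8, length.out = max(4, ceiling(cell$length)))
  lat <- lateral0 + cumsum(stats::rnorm(length(ts), 0, 0.08))
  lat <- pmin(pmax(lat, -0.7 * cell$radius), 0.7 * cell$radius)
  verts <- t(vapply(seq_along(ts), function(i)
    cell$center + ts[i] * ax$dir + lat[i] * n, numeric(2)))
  list(vertices = verts, sigma_um = cfg$cable_sigma_um,
       amplitude_ch1 = cfg$cable_amplitude)
}

#' Sample a ground-truthed synthetic scene
#'
#' Draws a parametric description of cells and their actin structures from a
#' [scene_config()]. The same `(config, seed)` pair always yields an identical
#' scene. Cells are placed by rejection sampling with a minimum clearance;
#' clumps are placed deliberately (touching cells) at the configured rate so
#' downstream clump rejection can be exercised.
#'
#' @param config A [scene_config()].
#' @param seed Integer seed; required for reproducibility.
#' @return A list of class `scene_ground_truth`: `cells` (each with geometry,
#'   `patches`, `cables`, optional `ring`, and `clump_id`), the decoration
#'   ratios and intensity levels from `config`, and the seed.
#' @export
sample_scene <- function(config, seed) {
  stopifnot(inherits(config, "scene_config"))
  if (missing(seed) || is.null(seed)) stopf("a seed is required")
  with_seed(as.integer(seed), {
    cells <- list()
    clump_of <- integer(0)
    for (i in seq_len(config$n_cells)) {
      cand <- place_one_cell(config, cells)
      if (is.null(cand))
        stopf(paste("could not place cell %d within the overlap budget",
                    "(max_place_tries = %d); reduce n_cells or enlarge",
                    "fov_um"), i, config$max_place_tries)
      cells[[length(cells) + 1L]] <- cand
      clump_of <- c(clump_of, 0L)
    }
    for (k in seq_len(config$n_clumps)) {
      placed <- FALSE
      for (attempt in 1:8) {   # retry with a fresh seed cell if members won't fit
        seed_cell <- place_one_cell(config, cells)
        if (is.null(seed_cell))
          stopf("could not place clump %d within the overlap budget", k)
        members <- list(seed_cell)
        for (j in seq_len(config$clump_size - 1L)) {
          # attach to a random existing member so larger clumps form chains
          anchor <- members[[sample.int(length(members), 1)]]
          nb <- place_one_cell(config, c(cells, members),
                               overlap_with = anchor, contact_ok = members)
          if (is.null(nb)) break
          members[[length(members) + 1L]] <- nb
        }
        if (length(members) == config$clump_size) {
          cells <- c(cells, members)
          clump_of <- c(clump_of, rep(k, length(members)))
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stopf("could not assemble clump %d (%d touching cells) within the overlap budget",
              k, config$clump_size)
    }
    cells <- lapply(seq_along(cells), function(i) {
      cell <- cells[[i]]
      cell$clump_id <- clump_of[i]
      n_p <- stats::rpois(1, config$n_patches_mean)
      cell$patches <- lapply(seq_len(n_p), function(j) {
        p <- sample_point_in_cell(cell, margin = 2 * config$patch_sigma_um,
                                  tip_bias = 0.7)
        list(center = p, amplitude_ch1 = config$patch_amplitude,
             sigma_um = config$patch_sigma_um,
             decorated = stats::runif(1) < config$patch_decorated_fraction)
      })
      n_c <- if (diff(config$n_cables_range) == 0) config$n_cables_range[1]
      else sample(seq(config$n_cables_range[1], config$n_cables_range[2]), 1)
      cell$cables <- lapply(seq_len(n_c), function(j) make_cable(cell, config))
      cell$ring <- if (stats::runif(1) < config$ring_fraction)
        list(axial_position = 0.5, sigma_um = config$ring_sigma_um,
             amplitude_ch1 = config$ring_amplitude) else NULL
      cell
    })
    scene <- list(cells = cells,
                  decoration_ratio = config$decoration_ratio,
                  cytoplasm_level = config$cytoplasm_level,
                  outside_level = config$outside_level,
                  expression_scale_ch2 = config$expression_scale_ch2,
                  fov_um = config$fov_um,
                  seed = as.integer(seed))
    class(scene) <- "scene_ground_truth"
    scene
  })
}

#' @export
print.scene_ground_truth <- function(x, ...) {
  n_ring <- sum(vapply(x$cells, function(cc) !is.null(cc$ring), logical(1)))
  cat(sprintf("synthetic scene: %d cells (%d with ring, %d in clumps), fov %.1f x %.1f um, seed %d\n",
              length(x$cells), n_ring,
              sum(vapply(x$cells, function(cc) cc$clump_id > 0L, logical(1))),
              x$fov_um[1], x$fov_um[2], x$seed))
  cat(sprintf("decoration ratios: patch %.2f cable %.2f ring %.2f\n",
              x$decoration_ratio[["patch"]], x$decoration_ratio[["cable"]],
              x$decoration_ratio[["ring"]]))
  invisible(x)
}
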
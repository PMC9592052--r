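test_that("same config and seed give an identical scene", {
  cfg <- small_scene_config()
  s1 <- sample_scene(cfg, seed = 42)
  s2 <- sample_scene(cfg, seed = 42)
  expect_identical(s1, s2)
  s3 <- sample_scene(cfg, seed = 43)
  expect_false(identical(s1, s3))
})

test_that("configured decoration ratios are stored verbatim", {
  cfg <- small_scene_config(
    decoration_ratio = c(patch = 0.14, cable = 0.97, ring = 0.95))
  sc <- sample_scene(cfg, seed = 1)
  expect_equal(sc$decoration_ratio[["patch"]], 0.14)
  expect_equal(sc$decoration_ratio[["cable"]], 0.97)
  expect_equal(sc$decoration_ratio[["ring"]], 0.95)
})

test_that("an empty config gives an empty scene", {
  sc <- sample_scene(small_scene_config(n_cells = 0), seed = 1)
  expect_length(sc$cells, 0)
})

test_that("infeasible geometry raises an error naming the constraint", {
  cfg <- scene_config(n_cells = 40, fov_um = c(12, 12), max_place_tries = 30)
  expect_error(sample_scene(cfg, seed = 1), "overlap budget")
})

test_that("scene geometry invariants hold over seeds", {
  cfg <- small_scene_config(ring_fraction = 1)
  for (seed in 1:5) {
    sc <- sample_scene(cfg, seed = seed)
    for (cell in sc$cells) {
      for (p in cell$patches) {
        d <- tpmquant:::capsule_dist(cell, p$center[1], p$center[2])
        expect_lte(d, cell$radius)
      }
      for (cb in cell$cables) {
        d <- tpmquant:::capsule_dist(cell, cb$vertices[, 1], cb$vertices[, 2])
        expect_true(all(d <= cell$radius))
      }
      expect_true(cell$length >= 7 && cell$length <= 14)
    }
  }
})

test_that("deliberate clumps are recorded in the ground truth", {
  cfg <- scene_config(n_cells = 2, n_clumps = 1, clump_size = 3,
                      fov_um = c(30, 30))
  sc <- sample_scene(cfg, seed = 7)
  clump_ids <- vapply(sc$cells, function(x) x$clump_id, integer(1))
  expect_equal(sum(clump_ids > 0), 3)
  expect_equal(sum(clump_ids == 0), 2)
})

test_that("noiseless unblurred rendering equals the analytic photon image", {
  rd <- render_small(5, optics = clean_optics())
  expect_equal(matrix(rd$stack$data[1, 1, 1, , ],
                      dim(rd$stack$data)[4], dim(rd$stack$data)[5]),
               rd$photons$factin, tolerance = 1e-12)
})

test_that("unblurred structure pixels carry the configured channel ratio", {
  # single-structure-class scenes: where classes overlap, a pixel mixes two
  # decoration ratios by construction, so exact pixelwise checks need pure
  # scenes (patches only / cables only / ring only)
  variants <- list(
    patch = list(n_patches_mean = 6, n_cables_range = c(0, 0),
                 ring_fraction = 0),
    cable = list(n_patches_mean = 0, n_cables_range = c(2, 3),
                 ring_fraction = 0),
    ring = list(n_patches_mean = 0, n_cables_range = c(0, 0),
                ring_fraction = 1))
  ratios <- c(patch = 0.14, cable = 0.97, ring = 0.95)
  cc <- class_codes()
  for (cls in names(variants)) {
    cfg <- do.call(small_scene_config, c(
      list(decoration_ratio = ratios, patch_decorated_fraction = 1),
      variants[[cls]]))
    rd <- render_scene(sample_scene(cfg, seed = 8), clean_optics())
    ch <- channels_of(rd)
    pix <- rd$labels == cc[[cls]]
    expect_gt(sum(pix), 0)
    ratio <- (ch$tpm[pix] - cfg$cytoplasm_level[["tpm"]]) /
      (ch$factin[pix] - cfg$cytoplasm_level[["factin"]])
    expect_true(all(abs(ratio - ratios[[cls]]) < 1e-9),
                label = sprintf("%s pixel ratio", cls))
  }
})

test_that("decoration 1 with expression scale 2 doubles channel 2 pixelwise", {
  # outside_t = 2 * outside_f and expression-scaled cytoplasm excess equal to
  # twice channel 1's make the whole channel-2 image exactly 2 x channel 1
  cfg <- small_scene_config(
    decoration_ratio = c(patch = 1, cable = 1, ring = 1),
    patch_decorated_fraction = 1, expression_scale_ch2 = 2,
    cytoplasm_level = c(factin = 300, tpm = 310),
    outside_level = c(factin = 10, tpm = 20))
  rd <- render_scene(sample_scene(cfg, seed = 3), clean_optics())
  ch <- channels_of(rd)
  expect_equal(ch$tpm, 2 * ch$factin, tolerance = 1e-12)
})

test_that("channel-1 linearity: scaling amplitudes scales above-background signal", {
  k <- 3
  base <- small_scene_config()
  scaled <- small_scene_config(
    patch_amplitude = base$patch_amplitude * k,
    cable_amplitude = base$cable_amplitude * k,
    ring_amplitude = base$ring_amplitude * k,
    cytoplasm_level = c(factin = 10 + (base$cytoplasm_level[["factin"]] - 10) * k,
                        tpm = 10 + (base$cytoplasm_level[["tpm"]] - 10) * k))
  r1 <- render_scene(sample_scene(base, seed = 4), clean_optics())
  r2 <- render_scene(sample_scene(scaled, seed = 4), clean_optics())
  a <- channels_of(r1)$factin - 10
  b <- channels_of(r2)$factin - 10
  expect_equal(b, k * a, tolerance = 1e-9)
})

test_that("a blurred point patch integrates to amplitude times kernel sum", {
  # single point-like patch in the image centre, no cell background
  cfg <- small_scene_config(n_cells = 1, n_patches_mean = 0,
                            n_cables_range = c(0, 0), ring_fraction = 0,
                            cell_length_range_um = c(9, 9))
  sc <- sample_scene(cfg, seed = 2)
  A <- 500
  sc$cells[[1]]$patches <- list(list(center = sc$cells[[1]]$center,
                                     amplitude_ch1 = A, sigma_um = 0,
                                     decorated = TRUE))
  blurless <- render_scene(sc, clean_optics())
  blurred <- render_scene(sc, clean_optics(psf_sigma_xy = 1.5))
  diffim <- channels_of(blurred)$factin - {
    # same scene without the patch gives background only
    sc0 <- sc; sc0$cells[[1]]$patches <- list()
    channels_of(render_scene(sc0, clean_optics(psf_sigma_xy = 1.5)))$factin
  }
  # direct-summation oracle: the Gaussian kernel EBImage applies sums to ~1
  expect_equal(sum(diffim), A, tolerance = 1e-6 * A)
  expect_equal(max(channels_of(blurless)$factin) -
                 cfg$cytoplasm_level[["factin"]], A)
})

test_that("Poisson noise has variance close to mean over repeated renders", {
  cfg <- small_scene_config(n_cells = 1, fov_um = c(8, 8),
                            cell_length_range_um = c(7, 7))
  sc <- sample_scene(cfg, seed = 6)
  opt <- optics_model(n_zplanes = 1, psf_sigma_xy = 0, poisson_noise = TRUE,
                      read_noise_sd = 0, camera_offset = 0,
                      photons_per_count = 1)
  # probe a handful of pixels over many renders
  n <- 300
  probe <- cbind(c(20, 40, 60), c(20, 40, 60))
  vals <- matrix(0, n, nrow(probe))
  for (i in seq_len(n)) {
    rd <- render_scene(sc, opt, seed = 1000 + i)
    ch1 <- channels_of(rd)$factin
    vals[i, ] <- ch1[probe]
  }
  m <- colMeans(vals); v <- apply(vals, 2, var)
  expect_true(all(abs(v / m - 1) < 0.2))
})

test_that("generate_dataset writes files and reproduces them from its manifest", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- small_scene_config()
  generate_dataset(cfg, fast_optics(), d1, n_images = 2, seed = 9)
  expect_length(list.files(d1, pattern = "^img_\\d+\\.tif$"), 2)
  expect_length(list.files(d1, pattern = "_labels\\.tif$"), 2)
  regenerate_dataset(file.path(d1, "manifest.json"), d2)
  for (f in c("img_001.tif", "img_002.tif", "img_001_labels.tif")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7), label = f)
  }
})

test_that("generate_dataset creates out_dir and errors when a file blocks it", {
  base <- withr::local_tempdir()
  target <- file.path(base, "sub", "dir")
  generate_dataset(small_scene_config(n_cells = 1), fast_optics(), target,
                   n_images = 1, seed = 1)
  expect_true(dir.exists(target))
  blocker <- file.path(base, "blocked")
  writeLines("x", blocker)
  expect_error(
    generate_dataset(small_scene_config(n_cells = 1), fast_optics(), blocker,
                     n_images = 1, seed = 1),
    "file is in the way")
})
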
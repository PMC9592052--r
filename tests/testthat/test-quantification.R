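test_that("trimmed mean matches the sort-discard-average oracle", {
  expect_equal(trimmed_mean(1:10, 0.10, "lowest"), 6)
  expect_equal(trimmed_mean(1:10, 0.10, "highest"), 5)
  expect_equal(trimmed_mean(rep(4.2, 7), 0.3, "lowest"), 4.2)
  expect_equal(trimmed_mean(c(9, 1, 5), 0, "lowest"), 5)
  expect_error(trimmed_mean(numeric(0)), "empty")
  expect_error(trimmed_mean(1:5, 0.5), "fraction")

  set.seed(11)
  for (i in 1:1000) {
    n <- sample(1:60, 1)
    v <- switch(sample(3, 1),
                rnorm(n), rpois(n, 7), sample(0:3, n, replace = TRUE))
    q <- runif(1, 0, 0.49)
    side <- sample(c("lowest", "highest"), 1)
    expect_identical(trimmed_mean(v, q, side), trimmed_mean_oracle(v, q, side))
  }
})

test_that("for n < 10 at q = 0.10 nothing is discarded", {
  v <- c(100, 1, 2, 3, 4, 5, 6, 7, 8)
  expect_equal(trimmed_mean(v, 0.10, "lowest"), mean(v))
})

test_that("cable erosion matches a brute-force 3x3 neighbourhood oracle", {
  cc <- class_codes()
  set.seed(12)
  for (i in 1:100) {
    nr <- sample(8:20, 1); nc <- sample(8:20, 1)
    mask <- matrix(runif(nr * nc) < 0.55, nr, nc)
    lab <- matrix(cc[["outside"]], nr + 2, nc + 2)
    inner <- matrix(cc[["cytoplasm"]], nr, nc)
    inner[mask] <- cc[["cable"]]
    lab[2:(nr + 1), 2:(nc + 1)] <- inner
    cell <- list(cell_id = 1L, pixels = which(lab != cc[["outside"]]),
                 area = sum(lab != cc[["outside"]]), is_clump = FALSE)
    rois <- extract_rois(lab, list(cell), erode_cables = TRUE)
    # oracle on the full-image cable mask
    emask <- erode3_oracle(lab == cc[["cable"]])
    for (roi in rois) {
      pixmask <- matrix(FALSE, nr + 2, nc + 2)
      pixmask[roi$pixels] <- TRUE
      want <- which(erode3_oracle(pixmask))
      if (length(want) == 0) {
        expect_true(roi$erosion_fallback)
        expect_identical(roi$measured, roi$pixels)
      } else {
        expect_false(roi$erosion_fallback)
        expect_identical(sort(roi$measured), sort(want))
      }
    }
  }
})

test_that("a 3x3 cable erodes to its centre pixel; a thin line falls back", {
  cc <- class_codes()
  lab <- matrix(cc[["outside"]], 20, 20)
  lab[5:15, 5:15] <- cc[["cytoplasm"]]
  lab[7:9, 7:9] <- cc[["cable"]]
  cell <- list(cell_id = 1L, pixels = which(lab != cc[["outside"]]),
               area = 121, is_clump = FALSE)
  rois <- extract_rois(lab, list(cell))
  expect_length(rois, 1)
  expect_identical(rois[[1]]$measured, which(row(lab) == 8 & col(lab) == 8))

  lab[7:9, 7:9] <- cc[["cytoplasm"]]
  lab[12, 6:14] <- cc[["cable"]]   # 1 px wide line
  rois2 <- extract_rois(lab, list(cell))
  expect_true(rois2[[1]]$erosion_fallback)
  expect_identical(sort(rois2[[1]]$measured), sort(rois2[[1]]$pixels))

  # patches are never eroded
  lab[12, 6:14] <- cc[["cytoplasm"]]
  lab[6:8, 11:13] <- cc[["patch"]]
  rois3 <- extract_rois(lab, list(cell))
  expect_identical(sort(rois3[[1]]$measured), sort(rois3[[1]]$pixels))
})

test_that("clump cells contribute no ROIs", {
  cc <- class_codes()
  lab <- matrix(cc[["outside"]], 30, 30)
  lab[3:10, 3:10] <- cc[["cytoplasm"]]; lab[5:6, 5:6] <- cc[["patch"]]
  cells <- list(list(cell_id = 1L, pixels = which(lab != cc[["outside"]]),
                     area = 64, is_clump = TRUE))
  expect_length(extract_rois(lab, cells), 0)
})

test_that("piecewise-constant measurements reproduce the constants", {
  toy <- toy_cell(roi_f = 100, cyt_f = 10, out_f = 0,
                  roi_t = 50, cyt_t = 10, out_t = 0)
  cells <- detect_cells(toy$labels, min_area = 100)
  rois <- extract_rois(toy$labels, cells)
  m <- measure_roi(rois[[1]], toy$factin, toy$tpm, cells[[1]], toy$labels)
  expect_equal(m$roi_mean_factin, 100)
  expect_equal(m$roi_mean_tpm, 50)
  expect_equal(m$cyt_factin, 10)
  expect_equal(m$cyt_tpm, 10)
  expect_equal(m$out_factin, 0)
  expect_equal(m$area_px, 100)
})

test_that("measurements are invariant to pixel order", {
  rd <- render_small(41)
  ch <- channels_of(rd)
  cells <- detect_cells(rd$labels)
  rois <- extract_rois(rd$labels, cells)
  roi <- rois[[1]]
  m1 <- measure_roi(roi, ch$factin, ch$tpm, cells[[roi$cell_id]], rd$labels)
  roi2 <- roi
  set.seed(1)
  roi2$pixels <- sample(roi$pixels)
  roi2$measured <- sample(roi$measured)
  m2 <- measure_roi(roi2, ch$factin, ch$tpm, cells[[roi$cell_id]], rd$labels)
  expect_equal(m1$roi_mean_factin, m2$roi_mean_factin)
  expect_equal(m1$roi_mean_tpm, m2$roi_mean_tpm)
})

test_that("a cell without cytoplasm pixels is an error", {
  cc <- class_codes()
  lab <- matrix(cc[["outside"]], 10, 10)
  lab[3:6, 3:6] <- cc[["patch"]]
  cell <- list(cell_id = 1L, pixels = which(lab == cc[["patch"]]),
               area = 16, is_clump = FALSE)
  roi <- extract_rois(lab, list(cell))[[1]]
  expect_error(measure_roi(roi, matrix(1, 10, 10), matrix(1, 10, 10),
                           cell, lab), "cytoplasm")
})

test_that("the closed-form worked example gives r = 0.888...", {
  # num_tpm = 40, num_factin = 90, norm_factin = 40, norm_tpm = 20
  toy <- toy_cell(roi_f = 100, cyt_f = 10, out_f = 0,
                  roi_t = 50, cyt_t = 10, out_t = 0)
  cells <- detect_cells(toy$labels, min_area = 100)
  tab <- quantify_image(toy$labels, cells, toy$factin, toy$tpm)
  # cell means: (100*100 + 1500*10)/1600 = 15.625 (f); (50*100+1500*10)/1600 (t)
  m <- measure_roi(extract_rois(toy$labels, cells)[[1]],
                   toy$factin, toy$tpm, cells[[1]], toy$labels)
  num_t <- m$roi_mean_tpm - m$cyt_tpm          # 40
  num_f <- m$roi_mean_factin - m$cyt_factin    # 90
  expect_equal(num_t, 40); expect_equal(num_f, 90)
  d <- decoration_ratio(m)
  hand <- (num_t / num_f) * ((m$cell_factin - 0) / (m$cell_tpm - 0))
  expect_equal(d$r, hand, tolerance = 1e-12)
})

test_that("proportional channels give r = 1 exactly and scaling cancels", {
  rd <- render_small(42, optics = fast_optics())
  ch <- channels_of(rd)
  cells <- detect_cells(rd$labels)
  for (k in c(0.5, 1, 3)) {
    tab <- quantify_image(rd$labels, cells, ch$factin, k * ch$factin)
    ok <- tab[!is.na(tab$r), ]
    expect_gt(nrow(ok), 0)
    expect_true(all(abs(ok$r - 1) < 1e-6))
  }
  # scale invariance of either channel
  tab0 <- quantify_image(rd$labels, cells, ch$factin, ch$tpm)
  tab1 <- quantify_image(rd$labels, cells, 2.5 * ch$factin, ch$tpm)
  tab2 <- quantify_image(rd$labels, cells, ch$factin, 0.3 * ch$tpm)
  expect_equal(tab1$r, tab0$r, tolerance = 1e-9)
  expect_equal(tab2$r, tab0$r, tolerance = 1e-9)
})

test_that("adding a constant offset to a channel leaves r unchanged", {
  # the outside level is measured from the image, so offsetting an entire
  # channel offsets its recorded background with it and cancels exactly
  toy <- toy_cell(roi_f = 100, cyt_f = 10, out_f = 0,
                  roi_t = 50, cyt_t = 10, out_t = 0)
  cells <- detect_cells(toy$labels, min_area = 100)
  r0 <- quantify_image(toy$labels, cells, toy$factin, toy$tpm)$r
  r1 <- quantify_image(toy$labels, cells, toy$factin, toy$tpm + 25)$r
  r2 <- quantify_image(toy$labels, cells, toy$factin + 60, toy$tpm)$r
  expect_equal(r1, r0, tolerance = 1e-12)
  expect_equal(r2, r0, tolerance = 1e-12)
})

test_that("non-positive reference signals exclude the ROI with a reason", {
  # ROI darker than cytoplasm in the F-actin channel
  toy <- toy_cell(roi_f = 5, cyt_f = 10, out_f = 0,
                  roi_t = 50, cyt_t = 10, out_t = 0)
  cells <- detect_cells(toy$labels, min_area = 100)
  tab <- quantify_image(toy$labels, cells, toy$factin, toy$tpm)
  expect_true(is.na(tab$r[1]))
  expect_match(tab$exclusion_reason[1], "non-positive reference")
})

test_that("aggregation reports n, mean and the n-1 s.e.m. per class", {
  df <- data.frame(class = c("cable", "cable", "cable", "ring", "patch",
                             "patch"),
                   r = c(0.9, 1.0, 1.1, 0.8, NA, 0.2))
  a <- aggregate_ratios(df)
  cab <- a[a$class == "cable", ]
  expect_equal(cab$n, 3)
  expect_equal(cab$mean, 1.0)
  expect_equal(cab$sem, sd(c(0.9, 1, 1.1)) / sqrt(3))
  expect_equal(cab$sem, 0.1 / sqrt(3), tolerance = 1e-12)
  ring <- a[a$class == "ring", ]
  expect_equal(ring$n, 1)
  expect_true(is.na(ring$sem))          # undefined, not zero
  pat <- a[a$class == "patch", ]
  expect_equal(pat$n, 1)                # the NA ratio is excluded
  const <- aggregate_ratios(data.frame(class = "ring", r = c(2, 2, 2)))
  expect_equal(const$sem, 0)
})

test_that("monotonicity: raising channel-2 amplitude never lowers class means", {
  cfg0 <- small_scene_config(patch_decorated_fraction = 1, ring_fraction = 1)
  means <- vapply(c(0.2, 0.5, 0.8), function(rho) {
    cfg <- small_scene_config(
      decoration_ratio = c(patch = rho, cable = rho, ring = rho),
      patch_decorated_fraction = 1, ring_fraction = 1)
    rd <- render_scene(sample_scene(cfg, seed = 44), fast_optics())
    ch <- channels_of(rd)
    cells <- detect_cells(rd$labels)
    a <- aggregate_ratios(quantify_image(rd$labels, cells, ch$factin, ch$tpm))
    mean(a$mean)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})
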
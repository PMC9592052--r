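#' Per-pixel feature bank for trainable segmentation
#'
#' Computes the standard trainable-segmentation feature set on a 2D image:
#' raw intensity; Gaussian-smoothed intensity at several scales; gradient
#' magnitude and Laplacian of the smoothed image at each scale; and
#' difference-of-Gaussians between consecutive scales.
#'
#' @param image 2D numeric matrix.
#' @param scales Gaussian sigmas, in pixels.
#' @return Numeric matrix, one row per pixel (column-major order), one named
#'   column per feature.
#' @export
pixel_features <- function(image, scales = c(1, 2, 4, 8)) {
  stopifnot(is.matrix(image))
  smooth <- lapply(scales, function(s)
    EBImage::gblur(image, s, boundary = "replicate"))
  feats <- list(raw = as.vector(image))
  for (i in seq_along(scales)) {
    g <- smooth[[i]]
    nr <- nrow(g); nc <- ncol(g)
    # central differences with replicated edges
    gp <- rbind(g[1, ], g[-nr, ]); gn <- rbind(g[-1, ], g[nr, ])
    dy <- (gn - gp) / 2
    gl <- cbind(g[, 1], g[, -nc]); gr <- cbind(g[, -1], g[, nc])
    dx <- (gr - gl) / 2
    lap <- gn + gp + gl + gr - 4 * g
    feats[[sprintf("gauss_s%g", scales[i])]] <- as.vector(g)
    feats[[sprintf("gradmag_s%g", scales[i])]] <- as.vector(sqrt(dx^2 + dy^2))
    feats[[sprintf("laplace_s%g", scales[i])]] <- as.vector(lap)
  }
  for (i in seq_len(length(scales) - 1L)) {
    feats[[sprintf("dog_s%g_s%g", scales[i], scales[i + 1])]] <-
      as.vector(smooth[[i]] - smooth[[i + 1]])
  }
  do.call(cbind, feats)
}

#' Train a per-pixel structure classifier
#'
#' Fits a probability random forest to sparsely annotated pixels, the
#' in-package equivalent of interactive trainable-segmentation tools. A
#' held-out quarter of the labelled pixels (seeded split) estimates pixel
#' accuracy.
#'
#' @param images List of 2D matrices.
#' @param sparse_labels List of matrices, same shapes; integer class codes
#'   (see [class_codes()]) or class-name strings; `NA` or `< 0` = unlabelled.
#'   Pixels with classes outside `class_set` are ignored.
#' @param class_set Character vector of classes to learn; every class needs
#'   at least 50 labelled pixels.
#' @param seed Integer seed (forest and holdout split).
#' @param scales Feature scales in pixels; see [pixel_features()].
#' @param num_trees Trees in the forest.
#' @param pixel_size_nm Calibration the training images were acquired at;
#'   stored so prediction can verify compatibility.
#' @return An object of class `pixel_classifier` with the fitted model,
#'   `class_set`, `scales`, `holdout_accuracy`, and `seed`.
#' @export
train_classifier <- function(images, sparse_labels, class_set, seed,
                             scales = c(1, 2, 4, 8), num_trees = 60,
                             pixel_size_nm = NULL) {
  if (!is.list(images)) images <- list(images)
  if (!is.list(sparse_labels)) sparse_labels <- list(sparse_labels)
  stopifnot(length(images) == length(sparse_labels), length(class_set) > 0)
  xs <- list(); ys <- list()
  for (i in seq_along(images)) {
    lab <- sparse_labels[[i]]
    if (is.character(lab)) lab <- matrix(code_of(lab), nrow(lab), ncol(lab))
    if (is.character(as.vector(lab))) {
      lv <- code_of(as.vector(lab)); dim(lv) <- dim(lab); lab <- lv
    }
    idx <- which(!is.na(lab) & lab >= 0 & name_of(lab) %in% class_set)
    if (length(idx) == 0) next
    f <- pixel_features(images[[i]], scales)
    xs[[length(xs) + 1L]] <- f[idx, , drop = FALSE]
    ys[[length(ys) + 1L]] <- name_of(lab[idx])
  }
  y <- factor(unlist(ys), levels = class_set)
  x <- do.call(rbind, xs)
  counts <- table(y)
  low <- class_set[!(class_set %in% names(counts)) | counts[class_set] < 50]
  if (length(low) > 0)
    stopf("need >= 50 labelled pixels per class; too few for: %s",
          paste(low, collapse = ", "))
  df <- data.frame(.class = y, x, check.names = FALSE)
  n <- nrow(df)
  hold <- with_seed(seed, sample.int(n, size = max(1, floor(n / 4))))
  fit <- ranger::ranger(
    dependent.variable.name = ".class",
    data = df[-hold, , drop = FALSE],
    num.trees = num_trees, probability = TRUE,
    seed = seed, num.threads = 1, verbose = FALSE)
  ph <- predict(fit, df[hold, , drop = FALSE], num.threads = 1)$predictions
  pred_hold <- colnames(ph)[max.col(ph, ties.method = "first")]
  acc <- mean(pred_hold == as.character(df$.class[hold]))
  structure(list(model = fit, class_set = class_set, scales = scales,
                 num_trees = num_trees, seed = seed,
                 holdout_accuracy = acc, pixel_size_nm = pixel_size_nm),
            class = "pixel_classifier")
}

#' @export
print.pixel_classifier <- function(x, ...) {
  cat(sprintf("pixel_classifier: classes {%s}, %d trees, held-out accuracy %.3f\n",
              paste(x$class_set, collapse = ", "), x$num_trees,
              x$holdout_accuracy))
  invisible(x)
}

#' Classify every pixel of an image
#'
#' Assigns each pixel the argmax-posterior class of a trained
#' [train_classifier()] model. Deterministic for a fixed model and input.
#'
#' @param classifier A `pixel_classifier`.
#' @param image 2D numeric matrix.
#' @param pixel_size_nm Calibration of `image`; if both this and the
#'   classifier's training calibration are known they must agree within 10%.
#' @return Integer label matrix (codes from [class_codes()]).
#' @export
classify_pixels <- function(classifier, image, pixel_size_nm = NULL) {
  stopifnot(inherits(classifier, "pixel_classifier"), is.matrix(image))
  if (!is.null(pixel_size_nm) && !is.null(classifier$pixel_size_nm)) {
    rel <- abs(pixel_size_nm - classifier$pixel_size_nm) /
      classifier$pixel_size_nm
    if (rel > 0.10)
      stopf("pixel size %.1f nm differs from training calibration %.1f nm by more than 10%%",
            pixel_size_nm, classifier$pixel_size_nm)
  }
  f <- pixel_features(image, classifier$scales)
  pr <- predict(classifier$model, data.frame(f, check.names = FALSE),
                num.threads = 1)$predictions
  lab <- colnames(pr)[max.col(pr, ties.method = "first")]
  matrix(code_of(lab), nrow(image), ncol(image))
}

#' Merge the two channels' class maps
#'
#' Patches, cytoplasm and outside are taken from the F-actin channel's map;
#' cables and rings from the tropomyosin channel's map. Overlap precedence is
#' ring > patch > cable > cytoplasm > outside.
#'
#' @param factin_map Integer label matrix from the F-actin channel
#'   (patch / cytoplasm / outside).
#' @param tpm_map Integer label matrix from the tropomyosin channel; only its
#'   cable and ring labels are used.
#' @return Integer label matrix with attribute `"provenance"` naming the
#'   source channel of each structure class.
#' @export
merge_class_maps <- function(factin_map, tpm_map) {
  if (!identical(dim(factin_map), dim(tpm_map)))
    stopf("factin_map and tpm_map have different shapes")
  cc <- class_codes()
  merged <- factin_map
  merged[merged == cc[["cable"]] | merged == cc[["ring"]]] <- cc[["cytoplasm"]]
  cable <- tpm_map == cc[["cable"]] & merged != cc[["patch"]]
  merged[cable] <- cc[["cable"]]
  merged[tpm_map == cc[["ring"]]] <- cc[["ring"]]
  attr(merged, "provenance") <- c(patch = "factin", cable = "tpm",
                                  ring = "tpm")
  merged
}

#' Detect cell instances and flag clumps
#'
#' Connected components (8-connectivity) of non-outside pixels. Components
#' smaller than `min_area` are dropped; components larger than
#' `clump_area_factor` times the median retained component area are flagged
#' as clumps (kept in the output, excluded from quantification downstream).
#' A touching mother-daughter pair is by construction a single instance.
#'
#' @param label_image Integer label matrix.
#' @param min_area Minimum component area in px^2.
#' @param clump_area_factor Area multiple of the median above which a
#'   component is called a clump.
#' @return List of cell instances: `cell_id`, `pixels` (linear indices),
#'   `area`, `is_clump`.
#' @export
detect_cells <- function(label_image, min_area = 1000,
                         clump_area_factor = 2.5) {
  lab <- label_components(label_image != class_codes()[["outside"]])
  k <- max(lab)
  if (k == 0L) return(list())
  comps <- lapply(seq_len(k), function(i) which(lab == i))
  areas <- lengths(comps)
  keep <- areas >= min_area
  comps <- comps[keep]; areas <- areas[keep]
  if (length(comps) == 0L) return(list())
  med <- stats::median(areas)
  lapply(seq_along(comps), function(i) {
    list(cell_id = i, pixels = comps[[i]], area = areas[i],
         is_clump = areas[i] > clump_area_factor * med)
  })
}

#' Rule-based fallback segmentation
#'
#' Deterministic segmentation used when no training annotations exist.
#' The cell mask comes from an Otsu threshold on the smoothed F-actin
#' channel. Within cells, each channel is thresholded at
#' `cytoplasm + struct_frac * (bright-structure level - cytoplasm)`, where
#' the cytoplasm is the in-cell median and the bright-structure level the
#' in-cell 99.9th percentile: tropomyosin-channel detections are cables or
#' rings (separated by thickness: rings survive a disc erosion, cables do
#' not), F-actin-channel detections not already claimed by the tropomyosin
#' channel are patches.
#'
#' @param factin,tpm 2D matrices (average projections of the two channels).
#' @param params Rule thresholds: `struct_frac` (fraction of the
#'   bright-structure excess used as the detection threshold),
#'   `ring_brush` (erosion disc size deciding ring-vs-cable thickness),
#'   `smooth_sigma` (light pre-smoothing, px).
#' @return Integer label matrix over all five classes.
#' @export
threshold_segment <- function(factin, tpm,
                              params = list(struct_frac = 0.15,
                                            ring_brush = 11,
                                            smooth_sigma = 0.8)) {
  stopifnot(is.matrix(factin), identical(dim(factin), dim(tpm)))
  cc <- class_codes()
  nr <- nrow(factin); ncq <- ncol(factin)
  sm1 <- EBImage::gblur(factin, 2, boundary = "replicate")
  rng <- range(sm1)
  if (diff(rng) <= 1e-9 * max(abs(rng), 1))   # constant image: no cells
    return(matrix(cc[["outside"]], nr, ncq))
  norm <- (sm1 - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(norm))
  cellmask <- norm > thr
  cellmask <- EBImage::fillHull(EBImage::Image(cellmask * 1)) > 0.5
  cellmask <- matrix(as.logical(cellmask), nr, ncq)
  out <- matrix(cc[["outside"]], nr, ncq)
  out[cellmask] <- cc[["cytoplasm"]]
  if (!any(cellmask)) return(out)

  detect <- function(img) {
    g <- EBImage::gblur(img, params$smooth_sigma, boundary = "replicate")
    cyt <- stats::median(g[cellmask])
    bright <- stats::quantile(g[cellmask], 0.999, names = FALSE)
    if (bright <= cyt) return(matrix(FALSE, nr, ncq))
    g > cyt + params$struct_frac * (bright - cyt) & cellmask
  }
  struct2 <- detect(tpm)
  th1 <- detect(factin)
  patch <- th1 & !struct2
  # rings are thick enough to survive erosion; cables are not
  er <- EBImage::erode(struct2 * 1,
                       EBImage::makeBrush(params$ring_brush, "disc")) > 0.5
  ring <- EBImage::dilate(er * 1,
                          EBImage::makeBrush(params$ring_brush, "disc")) > 0.5
  ring <- matrix(as.logical(ring), nr, ncq) & struct2
  cable <- struct2 & !ring
  out[cable] <- cc[["cable"]]
  out[patch] <- cc[["patch"]]
  out[ring] <- cc[["ring"]]
  out
}
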
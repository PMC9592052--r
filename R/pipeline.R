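#' Pipeline configuration
#'
#' Collects every stage parameter of the end-to-end run with defaults
#' matching the package's documented choices. Exactly one of `input_dir`
#' (an existing dataset with a manifest, as written by [generate_dataset()])
#' or `generator` (settings to simulate one first) must be given.
#'
#' @param input_dir Existing dataset directory containing `manifest.json`.
#' @param generator List with `config` ([scene_config()] or its arguments),
#'   `optics` ([optics_model()] or its arguments) and `n_images`.
#' @param channel_roles Named integer vector mapping role to channel index;
#'   roles must be distinct channels.
#' @param trim_fraction Trim fraction q for ROI/cytoplasm means.
#' @param erode_cables Erode cable measured sets by 1 px?
#' @param min_area,clump_area_factor Cell instance filters; see
#'   [detect_cells()].
#' @param projection Projection used for quantification (average; maximum is
#'   reserved for display/kymographs).
#' @param register Estimate and apply channel translation registration?
#' @param max_shift Registration search window, px.
#' @param bleach_mode `"none"`, `"simple_ratio"` or `"exponential_fit"`
#'   (time series only).
#' @param segmentation `"ground_truth"` (use stored label images),
#'   `"classifier"` (train a pixel classifier on the first
#'   `train_images` images' ground truth, sparsely sampled), or
#'   `"threshold"` (rule-based fallback).
#' @param train_images Images used for classifier training.
#' @param train_px_per_class Labelled pixels sampled per class for training.
#' @param seed Integer seed for every stochastic stage.
#' @param out_dir Run output directory.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, generator = NULL,
                            channel_roles = c(factin = 1, tpm = 2),
                            trim_fraction = 0.10, erode_cables = TRUE,
                            min_area = 1000, clump_area_factor = 2.5,
                            projection = "average", register = FALSE,
                            max_shift = 10, bleach_mode = "none",
                            segmentation = c("ground_truth", "classifier",
                                             "threshold"),
                            train_images = 2, train_px_per_class = 1500,
                            seed = 1, out_dir = tempfile("tpmquant_run_")) {
  segmentation <- match.arg(segmentation)
  if (is.null(input_dir) == is.null(generator))
    stopf("give exactly one of input_dir or generator")
  if (!all(c("factin", "tpm") %in% names(channel_roles)))
    stopf("channel_roles must name factin and tpm")
  if (channel_roles[["factin"]] == channel_roles[["tpm"]])
    stopf("channel roles must map to distinct channels")
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

log_line <- function(con, fmt, ...) {
  msg <- sprintf(fmt, ...)
  writeLines(msg, con)
  message(msg)
}

#' Run the full quantification pipeline
#'
#' Executes simulate (optional) -> average projection -> registration
#' (optional) -> segmentation -> cell detection -> ROI quantification ->
#' per-class aggregation, writing per-ROI and per-class CSV tables, label
#' masks, a stage log, and a provenance manifest into the run directory.
#' Re-running from the manifest (see [rerun_from_manifest()]) reproduces
#' byte-identical tables. Any stage error halts the run naming the stage;
#' partial outputs are retained and flagged in the log.
#'
#' @param config A [pipeline_config()].
#' @return List: `per_roi` and `summary` data.frames, `out_dir`,
#'   `manifest_path`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$out_dir, "log.txt")
  con <- file(logf, open = "wt")
  on.exit(close(con), add = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      log_line(con, "STAGE FAILED [%s]: %s (partial outputs retained)",
               name, conditionMessage(e))
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  data_dir <- config$input_dir
  if (is.null(data_dir)) {
    data_dir <- file.path(config$out_dir, "images")
    stage("simulate", {
      g <- config$generator
      generate_dataset(g$config, g$optics, data_dir,
                       n_images = if (is.null(g$n_images)) 12 else g$n_images,
                       seed = config$seed)
      log_line(con, "simulate: wrote %d images to %s",
               if (is.null(g$n_images)) 12 else g$n_images, data_dir)
    })
  }
  ds <- jsonlite::read_json(file.path(data_dir, "manifest.json"),
                            simplifyVector = TRUE)
  img_files <- file.path(data_dir, ds$images$image)
  lab_files <- file.path(data_dir, ds$images$labels)
  n_img <- length(img_files)

  clf <- list(factin = NULL, tpm = NULL)
  if (config$segmentation == "classifier") {
    stage("train", {
      k <- min(config$train_images, n_img)
      tr_f <- list(); tr_t <- list(); lb_f <- list(); lb_t <- list()
      for (i in seq_len(k)) {
        st <- read_stack(img_files[i])
        pr <- project(st, "average")
        gt <- read_label_image(lab_files[i])
        tr_f[[i]] <- proj_plane(pr, 1, config$channel_roles[["factin"]])
        tr_t[[i]] <- proj_plane(pr, 1, config$channel_roles[["tpm"]])
        lb_f[[i]] <- sparse_labels_from_ground_truth(
          gt, c("patch", "cytoplasm", "outside"),
          n_per_class = config$train_px_per_class,
          seed = config$seed + 100 + i, collapse_to_cytoplasm = TRUE)
        lb_t[[i]] <- sparse_labels_from_ground_truth(
          gt, c("cable", "ring", "cytoplasm", "outside"),
          n_per_class = config$train_px_per_class,
          seed = config$seed + 200 + i)
      }
      clf$factin <- train_classifier(tr_f, lb_f,
                                     c("patch", "cytoplasm", "outside"),
                                     seed = config$seed + 1)
      clf$tpm <- train_classifier(tr_t, lb_t,
                                  c("cable", "ring", "cytoplasm", "outside"),
                                  seed = config$seed + 2)
      log_line(con, "train: factin acc %.3f, tpm acc %.3f",
               clf$factin$holdout_accuracy, clf$tpm$holdout_accuracy)
    })
  }

  per_roi <- list()
  for (i in seq_len(n_img)) {
    st <- stage("read", read_stack(img_files[i]))
    if (config$bleach_mode != "none" && dim(st$data)[1] >= 3) {
      st <- stage("bleach", bleach_correct(st, config$bleach_mode))
    }
    pr <- stage("project", project(st, config$projection))
    factin <- proj_plane(pr, 1, config$channel_roles[["factin"]])
    tpm <- proj_plane(pr, 1, config$channel_roles[["tpm"]])
    valid_mask <- NULL
    if (config$register) {
      reg <- stage("register",
                   register_channels(factin, tpm, config$max_shift))
      tpm <- reg$aligned
      valid_mask <- reg$mask
      log_line(con, "register[%d]: shift dy=%g dx=%g", i,
               reg$shift[["dy"]], reg$shift[["dx"]])
    }
    lab <- stage("segment", switch(
      config$segmentation,
      ground_truth = read_label_image(lab_files[i]),
      threshold = threshold_segment(factin, tpm),
      classifier = merge_class_maps(
        classify_pixels(clf$factin, factin),
        classify_pixels(clf$tpm, tpm))))
    write_label_image(lab, file.path(config$out_dir,
                                     sprintf("mask_%03d.tif", i)))
    cells <- stage("detect_cells",
                   detect_cells(lab, config$min_area,
                                config$clump_area_factor))
    n_clump <- sum(vapply(cells, `[[`, logical(1), "is_clump"))
    log_line(con, "image %d: %d cell instances (%d clumps excluded)",
             i, length(cells), n_clump)
    tab <- stage("quantify",
                 quantify_image(lab, cells, factin, tpm,
                                trim_fraction = config$trim_fraction,
                                erode_cables = config$erode_cables,
                                pixel_size_nm = st$pixel_size_nm,
                                valid_mask = valid_mask))
    if (nrow(tab) > 0) tab <- cbind(image = i, tab)
    for (j in which(!is.na(tab$exclusion_reason)))
      log_line(con, "image %d roi %d (%s): %s", i, tab$roi_id[j],
               tab$class[j], tab$exclusion_reason[j])
    per_roi[[i]] <- tab
  }
  per_roi <- do.call(rbind, per_roi[vapply(per_roi, nrow, integer(1)) > 0])
  summary <- stage("aggregate", aggregate_ratios(per_roi))
  utils::write.csv(per_roi, file.path(config$out_dir, "per_roi.csv"),
                   row.names = FALSE)
  utils::write.csv(summary, file.path(config$out_dir,
                                      "per_class_summary.csv"),
                   row.names = FALSE)
  manifest <- list(kind = "tpmquant_run",
                   package_version = as.character(
                     utils::packageVersion("tpmquant")),
                   config = serialize_config(config))
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  log_line(con, "done: %d ROIs, %d classes", nrow(per_roi), nrow(summary))
  list(per_roi = per_roi, summary = summary, out_dir = config$out_dir,
       manifest_path = manifest_path)
}

serialize_config <- function(config) {
  cfg <- unclass(config)
  cfg$channel_roles <- as.list(cfg$channel_roles)   # keep names in JSON
  if (!is.null(cfg$generator)) {
    g <- cfg$generator
    if (inherits(g$config, "scene_config")) g$config <- unclass(g$config)
    if (inherits(g$optics, "optics_model")) g$optics <- unclass(g$optics)
    for (nm in c("decoration_ratio", "cytoplasm_level", "outside_level"))
      if (!is.null(g$config[[nm]])) g$config[[nm]] <- as.list(g$config[[nm]])
    cfg$generator <- g
  }
  cfg
}

#' Re-run a pipeline from its provenance manifest
#'
#' Reads the manifest written by [run_pipeline()] and repeats the run into a
#' new directory. With a fixed seed the summary tables are byte-identical.
#'
#' @param manifest_path Path to a run `manifest.json`.
#' @param out_dir New output directory.
#' @return See [run_pipeline()].
#' @export
rerun_from_manifest <- function(manifest_path, out_dir) {
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  if (!identical(m$kind, "tpmquant_run"))
    stopf("'%s' is not a pipeline run manifest", manifest_path)
  cfg <- m$config
  cfg$out_dir <- out_dir
  cfg$channel_roles <- unlist(cfg$channel_roles)
  if (!is.null(cfg$generator)) {
    g <- cfg$generator
    for (nm in c("decoration_ratio", "cytoplasm_level", "outside_level"))
      if (!is.null(g$config[[nm]])) g$config[[nm]] <- unlist(g$config[[nm]])
    cfg$generator <- list(config = do.call(scene_config, as.list(g$config)),
                          optics = do.call(optics_model, as.list(g$optics)),
                          n_images = g$n_images)
  }
  keep <- intersect(names(cfg), names(formals(pipeline_config)))
  run_pipeline(do.call(pipeline_config, cfg[keep]))
}

#' Sparse training annotations from a ground-truth label image
#'
#' Samples up to `n_per_class` labelled pixels per class, emulating the
#' sparse scribbles an annotator would provide to a trainable-segmentation
#' tool. As an annotator would, non-structure classes spend half their
#' budget on hard negatives: pixels bordering a structure (within 4 px),
#' where the blurred structure tails make the class boundary hardest to
#' learn.
#'
#' @param gt Integer ground-truth label matrix.
#' @param classes Classes to sample.
#' @param n_per_class Maximum pixels per class.
#' @param seed Integer seed.
#' @param collapse_to_cytoplasm If TRUE, ground-truth cable/ring pixels are
#'   relabelled cytoplasm first (used when annotating the F-actin channel,
#'   whose classifier does not know those classes).
#' @return Integer matrix, `NA` where unlabelled.
#' @export
sparse_labels_from_ground_truth <- function(gt, classes, n_per_class = 1500,
                                            seed = 1,
                                            collapse_to_cytoplasm = FALSE) {
  cc <- class_codes()
  g <- gt
  if (collapse_to_cytoplasm)
    g[g == cc[["cable"]] | g == cc[["ring"]]] <- cc[["cytoplasm"]]
  struct <- matrix(g %in% cc[c("patch", "cable", "ring")], nrow(g), ncol(g))
  near_struct <- EBImage::dilate(struct * 1, EBImage::makeBrush(9, "box")) > 0.5
  near_struct <- matrix(as.logical(near_struct), nrow(g), ncol(g)) & !struct
  out <- matrix(NA_integer_, nrow(g), ncol(g))
  with_seed(seed, {
    for (cls in classes) {
      if (cls %in% c("cytoplasm", "outside")) {
        hard <- which(g == cc[[cls]] & near_struct)
        easy <- which(g == cc[[cls]] & !near_struct)
        idx <- c(if (length(hard) > n_per_class / 2)
          sample(hard, n_per_class / 2) else hard,
          if (length(easy) > n_per_class / 2)
            sample(easy, n_per_class / 2) else easy)
      } else {
        idx <- which(g == cc[[cls]])
        if (length(idx) > n_per_class) idx <- sample(idx, n_per_class)
      }
      out[idx] <- cc[[cls]]
    }
  })
  out
}
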
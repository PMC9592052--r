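#' Generate a synthetic dataset on disk
#'
#' Samples and renders `n_images` independent scenes, writing for each a
#' two-channel image stack (`img_NNN.tif`), a ground-truth label image
#' (`img_NNN_labels.tif`), and a JSON manifest recording every generator and
#' optics parameter plus the seed. Re-running from the manifest reproduces
#' byte-identical pixel data. Per-image seeds are derived deterministically
#' as `seed + image index`.
#'
#' @param config A [scene_config()], or a plain list of its arguments.
#' @param optics An [optics_model()], or a plain list of its arguments.
#' @param out_dir Output directory (created if missing).
#' @param n_images Number of image/label pairs.
#' @param seed Base integer seed.
#' @return Invisibly, the manifest as a list (with `$images` file table).
#' @export
generate_dataset <- function(config, optics, out_dir, n_images = 12, seed = 1) {
  if (!inherits(config, "scene_config")) config <- do.call(scene_config, config)
  if (!inherits(optics, "optics_model")) optics <- do.call(optics_model, optics)
  if (file.exists(out_dir) && !dir.exists(out_dir))
    stopf("cannot create output directory '%s': a file is in the way", out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stopf("could not create directory '%s'", out_dir)
  images <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    sc <- sample_scene(config, seed = seed + i)
    rend <- render_scene(sc, optics)
    img_path <- file.path(out_dir, sprintf("img_%03d.tif", i))
    lab_path <- file.path(out_dir, sprintf("img_%03d_labels.tif", i))
    write_stack(rend$stack, img_path)
    write_label_image(rend$labels, lab_path)
    images[[i]] <- list(image = basename(img_path),
                        labels = basename(lab_path),
                        seed = seed + i,
                        n_cells = length(sc$cells))
  }
  cfg_out <- unclass(config)
  for (nm in c("decoration_ratio", "cytoplasm_level", "outside_level"))
    cfg_out[[nm]] <- as.list(cfg_out[[nm]])   # jsonlite drops vector names
  manifest <- list(kind = "tpmquant_dataset",
                   package_version = as.character(utils::packageVersion("tpmquant")),
                   seed = seed, n_images = n_images,
                   scene_config = cfg_out,
                   optics = unclass(optics),
                   images = images)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(manifest)
}

#' @rdname generate_dataset
#' @param manifest_path Path to a dataset `manifest.json`.
#' @export
regenerate_dataset <- function(manifest_path, out_dir) {
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  if (!identical(m$kind, "tpmquant_dataset"))
    stopf("'%s' is not a dataset manifest", manifest_path)
  cfg <- m$scene_config
  cfg$max_place_tries <- as.integer(cfg$max_place_tries)
  for (nm in c("decoration_ratio", "cytoplasm_level", "outside_level"))
    cfg[[nm]] <- unlist(cfg[[nm]])
  opt <- m$optics
  generate_dataset(do.call(scene_config, cfg), do.call(optics_model, opt),
                   out_dir, n_images = m$n_images, seed = m$seed)
}

#' Write / read a label image as 16-bit TIFF
#'
#' Label TIFFs store the integer class codes directly; the class palette goes
#' to a JSON sidecar.
#'
#' @param labels Integer label matrix.
#' @param path Output path.
#' @export
write_label_image <- function(labels, path) {
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  jsonlite::write_json(list(kind = "tpmquant_labels",
                            palette = as.list(class_codes())),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_label_image
#' @export
read_label_image <- function(path) {
  pg <- tiff::readTIFF(path)
  matrix(as.integer(round(pg * 65535)), nrow(pg), ncol(pg))
}
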
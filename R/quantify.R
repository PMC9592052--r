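#' One-sided trimmed mean
#'
#' Mean after discarding `floor(fraction * n)` values from one extreme:
#' the darkest pixels of a structure ROI, or the brightest pixels of the
#' cytoplasm. Ties are broken by discarding exactly `floor(fraction * n)`
#' values after a stable sort. For n < 10 at the default fraction 0.10
#' nothing is discarded.
#'
#' @param values Numeric vector, nonempty.
#' @param fraction Fraction to discard, in [0, 0.5).
#' @param side `"lowest"` or `"highest"`: which extreme to discard.
#' @return The trimmed mean.
#' @export
trimmed_mean <- function(values, fraction = 0.10,
                         side = c("lowest", "highest")) {
  side <- match.arg(side)
  if (length(values) == 0) stopf("trimmed_mean: empty value list")
  if (fraction < 0 || fraction >= 0.5) stopf("fraction must be in [0, 0.5)")
  k <- floor(fraction * length(values))
  if (k == 0) return(mean(values))
  s <- sort(values, method = "radix")   # stable
  kept <- if (side == "lowest") s[(k + 1):length(s)] else s[1:(length(s) - k)]
  mean(kept)
}

#' Extract structure ROIs from a labelled image
#'
#' One ROI per 8-connected component of each structure class (patch, cable,
#' ring) within each non-clump cell. Cable ROIs carry a measured pixel set
#' eroded by 1 px (3x3 square structuring element) to strictly separate the
#' cable from surrounding cytoplasm; if erosion empties a cable ROI the
#' original set is retained and `erosion_fallback` is set.
#'
#' @param label_image Integer label matrix (see [class_codes()]).
#' @param cells Output of [detect_cells()]. Clump cells are skipped.
#' @param erode_cables Erode cable measured sets? (default TRUE).
#' @param min_roi_px Drop components smaller than this many pixels (default 0:
#'   keep everything). [quantify_image()] defaults to the PSF support area,
#'   since smaller components are not optically resolvable objects.
#' @return List of ROIs: `roi_id`, `class`, `cell_id`, `pixels`, `measured`
#'   (linear indices), `erosion_fallback`.
#' @export
extract_rois <- function(label_image, cells, erode_cables = TRUE,
                         min_roi_px = 0) {
  cc <- class_codes()
  nr <- nrow(label_image); ncq <- ncol(label_image)
  rois <- list()
  rid <- 0L
  for (cell in cells) {
    if (isTRUE(cell$is_clump)) next
    inmask <- matrix(FALSE, nr, ncq)
    inmask[cell$pixels] <- TRUE
    for (cls in c("patch", "cable", "ring")) {
      m <- inmask & label_image == cc[[cls]]
      if (!any(m)) next
      comp <- label_components(m)
      for (i in seq_len(max(comp))) {
        pix <- which(comp == i)
        if (length(pix) < min_roi_px) next
        measured <- pix
        fallback <- FALSE
        if (cls == "cable" && erode_cables) {
          # zero-pad so image-border pixels erode away (EBImage replicates
          # at borders, which would let them survive)
          cm <- matrix(0, nr + 2L, ncq + 2L)
          cm[2:(nr + 1L), 2:(ncq + 1L)][pix] <- 1
          er <- EBImage::erode(cm, EBImage::makeBrush(3, "box"))
          epix <- which(er[2:(nr + 1L), 2:(ncq + 1L)] > 0.5)
          if (length(epix) > 0) measured <- epix else fallback <- TRUE
        }
        rid <- rid + 1L
        rois[[rid]] <- list(roi_id = rid, class = cls,
                            cell_id = cell$cell_id, pixels = pix,
                            measured = measured,
                            erosion_fallback = fallback)
      }
    }
  }
  rois
}

#' Measure a structure ROI in both channels
#'
#' Computes the four intensity references the decoration ratio needs, per
#' channel: the ROI trimmed mean (lowest `trim_fraction` discarded), the
#' parent cell's cytoplasm trimmed mean (highest `trim_fraction` discarded),
#' the untrimmed mean over all pixels of the cell instance, and the untrimmed
#' mean over all outside pixels of the image.
#'
#' @param roi One ROI from [extract_rois()].
#' @param factin,tpm 2D matrices: average z-projections of the two channels,
#'   registration already applied.
#' @param cell The ROI's parent cell instance.
#' @param label_image Integer label matrix.
#' @param trim_fraction Trim fraction q (default 0.10).
#' @param pixel_size_nm Optional; adds `area_um2`.
#' @param valid_mask Optional logical matrix; `FALSE` pixels (e.g.
#'   registration edge fill) are excluded from every statistic.
#' @param boundary_margin_px Reference sets (cytoplasm, outside) exclude
#'   pixels within this distance of the cell edge, where the PSF rolls
#'   intensity off toward the other side; appearance-based segmentation never
#'   assigns these transitional pixels to either reference class, and the
#'   references are meant to estimate the levels away from the edge. ROI
#'   pixels are never excluded. Set 0 to disable.
#' @return List of class `channel_measurements`.
#' @export
measure_roi <- function(roi, factin, tpm, cell, label_image,
                        trim_fraction = 0.10, pixel_size_nm = NULL,
                        valid_mask = NULL, boundary_margin_px = 2) {
  cc <- class_codes()
  ok <- function(idx) {
    if (is.null(valid_mask)) idx else idx[valid_mask[idx]]
  }
  edge <- attr(label_image, "edge_zone")
  if (is.null(edge) && boundary_margin_px > 0)
    edge <- edge_zone(label_image, boundary_margin_px)
  away <- function(idx) {
    if (boundary_margin_px <= 0) return(idx)
    kept <- idx[!edge[idx]]
    if (length(kept) > 0) kept else idx   # degenerate cell: keep all
  }
  cyt_idx <- ok(cell$pixels[label_image[cell$pixels] == cc[["cytoplasm"]]])
  if (length(cyt_idx) == 0)
    stopf("cell %d has no cytoplasm pixels to reference against",
          cell$cell_id)
  cyt_idx <- away(cyt_idx)
  out_idx <- away(ok(which(label_image == cc[["outside"]])))
  meas <- ok(roi$measured)
  cellpix <- ok(cell$pixels)
  if (length(meas) == 0) stopf("ROI %d has no valid pixels", roi$roi_id)
  one <- function(img) {
    list(roi_mean = trimmed_mean(img[meas], trim_fraction, "lowest"),
         cyt = trimmed_mean(img[cyt_idx], trim_fraction, "highest"),
         cell = mean(img[cellpix]),
         out = if (length(out_idx) > 0) mean(img[out_idx]) else NA_real_)
  }
  f <- one(factin); t2 <- one(tpm)
  if (!is.na(f$out) && f$cell < f$out)
    warnf("cell %d: mean cell intensity below outside background in F-actin channel",
          cell$cell_id)
  m <- list(roi_id = roi$roi_id, class = roi$class, cell_id = roi$cell_id,
            area_px = length(roi$pixels),
            area_um2 = if (is.null(pixel_size_nm)) NA_real_
            else length(roi$pixels) * (pixel_size_nm / 1000)^2,
            erosion_fallback = roi$erosion_fallback,
            trim_fraction = trim_fraction,
            roi_mean_factin = f$roi_mean, cyt_factin = f$cyt,
            cell_factin = f$cell, out_factin = f$out,
            roi_mean_tpm = t2$roi_mean, cyt_tpm = t2$cyt,
            cell_tpm = t2$cell, out_tpm = t2$out)
  class(m) <- "channel_measurements"
  m
}

# pixels within `margin` px (chebyshev) of the cell edge, on either side
edge_zone <- function(label_image, margin) {
  o <- label_image == class_codes()[["outside"]]
  if (margin <= 0 || all(o) || !any(o))
    return(matrix(FALSE, nrow(label_image), ncol(label_image)))
  br <- EBImage::makeBrush(2 * margin + 1, "box")
  near_out <- EBImage::dilate(o * 1, br) > 0.5
  near_in <- EBImage::dilate((!o) * 1, br) > 0.5
  m <- near_out & near_in
  matrix(as.logical(m), nrow(label_image), ncol(label_image))
}

#' The normalized decoration ratio
#'
#' The per-ROI statistic: the ratio of the structure's above-cytoplasm
#' tropomyosin signal to its above-cytoplasm F-actin signal, normalised by
#' the parent cell's overall above-background channel ratio to cancel
#' expression-level differences:
#'
#' `r = [(roi_tpm - cyt_tpm) / (roi_factin - cyt_factin)] *
#'      [(cell_factin - out_factin) / (cell_tpm - out_tpm)]`
#'
#' ROIs whose above-cytoplasm F-actin signal or whose cell-level tropomyosin
#' signal above background is not positive (beyond `eps_rel` times the
#' outside level) are excluded with a reason, never silently zeroed.
#'
#' @param m A [measure_roi()] result.
#' @param eps_rel Relative tolerance on the reference signals (default 1e-6,
#'   scaled by the channel's outside level).
#' @return List: `r` (numeric, NA if excluded), `excluded` (logical),
#'   `reason` (string or NA).
#' @export
decoration_ratio <- function(m, eps_rel = 1e-6) {
  num_f <- m$roi_mean_factin - m$cyt_factin
  num_t <- m$roi_mean_tpm - m$cyt_tpm
  norm_f <- m$cell_factin - m$out_factin
  norm_t <- m$cell_tpm - m$out_tpm
  eps_f <- eps_rel * max(m$out_factin, 1e-12)
  eps_t <- eps_rel * max(m$out_tpm, 1e-12)
  if (is.na(num_f) || num_f <= eps_f)
    return(list(r = NA_real_, excluded = TRUE,
                reason = "excluded: non-positive reference signal (F-actin above cytoplasm)"))
  if (is.na(norm_t) || norm_t <= eps_t)
    return(list(r = NA_real_, excluded = TRUE,
                reason = "excluded: non-positive reference signal (cell tropomyosin above background)"))
  list(r = (num_t / num_f) * (norm_f / norm_t), excluded = FALSE,
       reason = NA_character_)
}

#' Quantify every structure ROI of one image
#'
#' Convenience wrapper: [extract_rois()], [measure_roi()] and
#' [decoration_ratio()] over all non-clump cells, returning a tidy per-ROI
#' table.
#'
#' @inheritParams extract_rois
#' @inheritParams measure_roi
#' @param min_roi_px Minimum ROI component area; the default (16 px) is the
#'   PSF support area pi * (2 * sigma_psf)^2 at sigma = 1.1 px - smaller
#'   components are segmentation speckle, not resolvable structures.
#' @return data.frame, one row per ROI: identifiers, areas, all channel
#'   means, `r`, and `exclusion_reason`.
#' @export
quantify_image <- function(label_image, cells, factin, tpm,
                           trim_fraction = 0.10, erode_cables = TRUE,
                           pixel_size_nm = NULL, valid_mask = NULL,
                           boundary_margin_px = 2, min_roi_px = 16) {
  rois <- extract_rois(label_image, cells, erode_cables, min_roi_px)
  if (boundary_margin_px > 0)
    attr(label_image, "edge_zone") <- edge_zone(label_image,
                                                boundary_margin_px)
  cellmap <- stats::setNames(cells, vapply(cells, function(x)
    as.character(x$cell_id), character(1)))
  rows <- lapply(rois, function(roi) {
    m <- measure_roi(roi, factin, tpm, cellmap[[as.character(roi$cell_id)]],
                     label_image, trim_fraction, pixel_size_nm, valid_mask,
                     boundary_margin_px)
    d <- decoration_ratio(m)
    data.frame(cell_id = m$cell_id, roi_id = m$roi_id, class = m$class,
               area_px = m$area_px, area_um2 = m$area_um2,
               erosion_fallback = m$erosion_fallback,
               roi_mean_factin = m$roi_mean_factin, cyt_factin = m$cyt_factin,
               cell_factin = m$cell_factin, out_factin = m$out_factin,
               roi_mean_tpm = m$roi_mean_tpm, cyt_tpm = m$cyt_tpm,
               cell_tpm = m$cell_tpm, out_tpm = m$out_tpm,
               r = d$r, exclusion_reason = if (d$excluded) d$reason
               else NA_character_,
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0) {
    return(data.frame(cell_id = integer(0), roi_id = integer(0),
                      class = character(0), area_px = integer(0),
                      area_um2 = numeric(0), erosion_fallback = logical(0),
                      roi_mean_factin = numeric(0), cyt_factin = numeric(0),
                      cell_factin = numeric(0), out_factin = numeric(0),
                      roi_mean_tpm = numeric(0), cyt_tpm = numeric(0),
                      cell_tpm = numeric(0), out_tpm = numeric(0),
                      r = numeric(0), exclusion_reason = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Aggregate decoration ratios per structure class
#'
#' Per-class mean, standard error of the mean (sample sd / sqrt(n), reported
#' as NA for n = 1) and n over the non-excluded ROIs.
#'
#' @param ratios data.frame with columns `class` and `r` (NA = excluded), as
#'   from [quantify_image()].
#' @return data.frame with columns `class`, `n`, `mean`, `sem`.
#' @export
aggregate_ratios <- function(ratios) {
  ok <- ratios[!is.na(ratios$r), , drop = FALSE]
  if (nrow(ok) == 0)
    return(data.frame(class = character(0), n = integer(0),
                      mean = numeric(0), sem = numeric(0),
                      stringsAsFactors = FALSE))
  parts <- lapply(split(ok$r, ok$class), function(v) {
    c(n = length(v), mean = mean(v),
      sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_)
  })
  out <- data.frame(class = names(parts),
                    n = vapply(parts, `[[`, numeric(1), "n"),
                    mean = vapply(parts, `[[`, numeric(1), "mean"),
                    sem = vapply(parts, `[[`, numeric(1), "sem"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(match(out$class, class_names())), , drop = FALSE]
}
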
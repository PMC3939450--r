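# colors for labeled regions: a fixed cyan->magenta sequential map
# (cool-style), so region identity is readable and never collides with the
# red partner outline, black SV pixels or white background
region_colors <- function(n) {
  if (n == 0L) return(matrix(numeric(0), 0, 3))
  t <- if (n == 1L) 0 else (seq_len(n) - 1) / (n - 1)
  cbind(t, 1 - t, 1)
}

#' Render a labeled overlap map with SV overlay
#'
#' Composes the classic end-of-pipeline display: white background, each
#' overlap region pseudocolored from a fixed sequential colormap, SV pixels
#' inside regions in black, and (optionally) the partner-cell perimeter
#' outlined in red.
#'
#' @param labeled an [compute_overlaps()] label map.
#' @param sv_mask binary SV mask sharing the map's geometry.
#' @param partner_mask optional partner-cell mask whose perimeter is drawn.
#' @return an `H x W x 3` RGB array in \[0,1\].
#' @export
render_overlay <- function(labeled, sv_mask, partner_mask = NULL) {
  g_sv <- mask_grid(sv_mask)
  check_same_dim(labeled, g_sv, what = "label map and SV mask")
  if (!is.null(partner_mask)) {
    check_same_dim(labeled, mask_grid(partner_mask), what = "label map and partner mask")
  }
  h <- nrow(labeled); w <- ncol(labeled)
  rgb <- array(1, dim = c(h, w, 3))
  if (!is.null(partner_mask)) {
    per <- which(mask_perimeter(partner_mask))
    rgb[per] <- 1
    rgb[per + h * w] <- 0
    rgb[per + 2L * h * w] <- 0
  }
  n <- n_regions(labeled)
  if (n > 0L) {
    cols <- region_colors(n)
    lab_pix <- which(labeled > 0L)
    l <- labeled[lab_pix]
    rgb[lab_pix] <- cols[l, 1]
    rgb[lab_pix + h * w] <- cols[l, 2]
    rgb[lab_pix + 2L * h * w] <- cols[l, 3]
    black <- lab_pix[g_sv[lab_pix]]
    rgb[black] <- 0
    rgb[black + h * w] <- 0
    rgb[black + 2L * h * w] <- 0
  }
  rgb
}

write_image_file <- function(arr, path) {
  ext <- tolower(tools::file_ext(path))
  ok <- tryCatch({
    if (ext %in% c("tif", "tiff")) {
      tiff::writeTIFF(arr, path, bits.per.sample = 8L)
    } else {
      png::writePNG(arr, path)
    }
    TRUE
  }, error = function(e) {
    abort(sprintf("cannot write image '%s': %s", path, conditionMessage(e)),
          class = "svpuncta_io_error")
  })
  invisible(path)
}

#' Write the overlap/SV overlay rendering
#'
#' [render_overlay()] written to disk as PNG (default) or TIFF, chosen by
#' file extension. Inputs are never modified.
#'
#' @inheritParams render_overlay
#' @param path output image path (`.png`, `.tif`/`.tiff`).
#' @return `path`, invisibly.
#' @export
write_overlay <- function(labeled, sv_mask, path, partner_mask = NULL) {
  write_image_file(render_overlay(labeled, sv_mask, partner_mask), path)
}

#' Render a detected-synapse map
#'
#' Black background, red neuronal-process outline, detected synapses as
#' white puncta.
#'
#' @param x a `synapse_map` from [detect_synapses()].
#' @return an `H x W x 3` RGB array in \[0,1\].
#' @export
render_synapse_map <- function(x) {
  stopifnot(inherits(x, "synapse_map"))
  h <- nrow(x$label_grid); w <- ncol(x$label_grid)
  rgb <- array(0, dim = c(h, w, 3))
  per <- which(mask_perimeter(x$masks$neuron_processes))
  rgb[per] <- 1
  syn <- which(x$label_grid > 0L)
  rgb[syn] <- 1
  rgb[syn + h * w] <- 1
  rgb[syn + 2L * h * w] <- 1
  rgb
}

#' Preview candidate binarizations of one channel
#'
#' Non-interactive replacement for cursor-driven threshold picking: renders
#' the binarization of an intensity image at several candidate thresholds
#' side by side (separated by gray gutters), so a fixed threshold can be
#' chosen for batch runs.
#'
#' @param image intensity matrix in \[0,1\].
#' @param thresholds candidate thresholds; default, Otsu's level and
#'   offsets around it.
#' @return grayscale matrix (the panel); attribute `thresholds` records the
#'   levels, left to right.
#' @export
render_threshold_preview <- function(image, thresholds = NULL) {
  if (is.null(thresholds)) {
    t0 <- auto_threshold(image)
    thresholds <- unique(pmin(pmax(t0 + c(-0.1, -0.05, 0, 0.05, 0.1), 0), 1))
  }
  h <- nrow(image); w <- ncol(image)
  k <- length(thresholds)
  panel <- matrix(0.5, h, k * (w + 1L) - 1L)
  for (i in seq_len(k)) {
    panel[, (i - 1L) * (w + 1L) + seq_len(w)] <- (image > thresholds[i]) * 1
  }
  structure(panel, thresholds = thresholds)
}

#' @rdname analyze_cocult
#' @param object a `cocult_result` (or `synapse_map`).
#' @export
autoplot.cocult_result <- function(object, ...) {
  arr <- render_overlay(object$overlaps, object$masks$marker,
                        partner_mask = object$masks$partner_dilated)
  s <- object$summary
  sub <- if (s$empty) "no overlap regions" else {
    sprintf("%d regions, frequency %.2f, density %.2f (mean)",
            s$n_regions, s$frequency, s$density_mean)
  }
  plot_rgb_array(arr, sprintf("SV clusters in contact zones: %s", object$field_id), sub)
}

#' @rdname detect_synapses
#' @param object a `synapse_map`.
#' @export
autoplot.synapse_map <- function(object, ...) {
  arr <- render_synapse_map(object)
  sub <- if (object$empty) "empty neuron mask" else {
    sprintf("%d synapses, %.3f per 100 um^2", object$n_synapses, object$density)
  }
  plot_rgb_array(arr, sprintf("Detected synapses: %s", object$field_id), sub)
}

plot_rgb_array <- function(arr, title, subtitle) {
  h <- dim(arr)[1]; w <- dim(arr)[2]
  ggplot2::ggplot() +
    ggplot2::annotation_raster(grDevices::as.raster(arr),
                               xmin = 0, xmax = w, ymin = 0, ymax = h) +
    ggplot2::xlim(0, w) +
    ggplot2::ylim(0, h) +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::theme_void() +
    ggplot2::labs(title = title, subtitle = subtitle)
}
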
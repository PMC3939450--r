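#' Segmentation configuration
#'
#' Collects every tunable of the binarization and mask clean-up stages.
#' Defaults are sized for 20x fields; `magnification = "63x"` applies the
#' high-magnification preset (linear sizes x3, pixel-count gates x9),
#' reflecting the finer sampling of the optics. Every value can be
#' overridden individually.
#'
#' @param threshold_mode `"auto"` (Otsu per channel) or `"fixed"`. Batch
#'   analysis should use fixed thresholds so segmentation output does not
#'   vary with per-field histograms.
#' @param fixed_thresholds named numeric vector of per-channel thresholds in
#'   \[0,1\]; names are the channel roles (`neuron`, `partner`, `marker` in
#'   co-culture mode; `neuron`, `pre`, `post` in synapse mode). Required when
#'   `threshold_mode = "fixed"`.
#' @param min_area_neuron,min_area_partner,min_area_sv minimum connected
#'   component size (pixels) retained in each channel mask.
#' @param cellbody_disk_radius radius (pixels) of the Euclidean-disk
#'   structuring element sized like a cell body; structures that contain the
#'   disk are removed from the neuron mask.
#' @param partner_dilation_radius radius (pixels) of the slight dilation of
#'   the partner-cell mask, so vesicle clusters hugging the cell edge fall
#'   inside the contact zone.
#' @param min_overlap_area overlap regions smaller than this (pixels) are
#'   discarded.
#' @param min_synapse_area minimum area (pixels) of a pre/post colocalized
#'   punctum counted as a synapse (synapse mode).
#' @param connectivity pixel connectivity for component labeling, 4 or 8.
#' @param magnification `"20x"` or `"63x"` preset.
#' @return a `seg_config` list.
#' @export
seg_config <- function(threshold_mode = c("auto", "fixed"),
                       fixed_thresholds = NULL,
                       min_area_neuron = NULL,
                       min_area_partner = NULL,
                       min_area_sv = NULL,
                       cellbody_disk_radius = NULL,
                       partner_dilation_radius = NULL,
                       min_overlap_area = NULL,
                       min_synapse_area = NULL,
                       connectivity = 8L,
                       magnification = c("20x", "63x")) {
  threshold_mode <- match.arg(threshold_mode)
  magnification <- match.arg(magnification)
  s <- if (magnification == "63x") 3L else 1L
  cfg <- list(
    threshold_mode = threshold_mode,
    fixed_thresholds = fixed_thresholds,
    min_area_neuron = as.integer(min_area_neuron %||% (20L * s^2)),
    min_area_partner = as.integer(min_area_partner %||% (50L * s^2)),
    min_area_sv = as.integer(min_area_sv %||% (4L * s^2)),
    cellbody_disk_radius = as.numeric(cellbody_disk_radius %||% (8L * s)),
    partner_dilation_radius = as.numeric(partner_dilation_radius %||% (2L * s)),
    min_overlap_area = as.integer(min_overlap_area %||% (10L * s^2)),
    min_synapse_area = as.integer(min_synapse_area %||% 3L),
    connectivity = check_connectivity(connectivity),
    magnification = magnification
  )
  validate_seg_config(cfg)
}

validate_seg_config <- function(cfg) {
  for (f in c("min_area_neuron", "min_area_partner", "min_area_sv",
              "min_overlap_area", "min_synapse_area",
              "partner_dilation_radius")) {
    if (cfg[[f]] < 0) abort(sprintf("`%s` must be >= 0.", f))
  }
  if (cfg$cellbody_disk_radius <= 0) {
    abort("`cellbody_disk_radius` must be > 0.")
  }
  if (cfg$threshold_mode == "fixed") {
    th <- cfg$fixed_thresholds
    if (is.null(th) || is.null(names(th)) || any(!nzchar(names(th)))) {
      abort("fixed threshold mode needs a named `fixed_thresholds` vector.")
    }
    if (any(th < 0 | th > 1)) abort("fixed thresholds must lie in [0,1].")
  }
  structure(cfg, class = "seg_config")
}

#' Automatic global threshold (Otsu)
#'
#' Computes the global intensity threshold maximizing the between-class
#' variance over a 256-bin histogram of the image, the classic Otsu
#' criterion on 8-bit-style binning. Intensities must already be normalized
#' to \[0,1\]. Ties between equally good split points are resolved by
#' averaging their positions.
#'
#' @param image numeric matrix with values in \[0,1\].
#' @return threshold in \[0,1\]; binarize with strict `>`.
#' @section Degenerate images: a constant image (all intensities in one
#'   histogram bin) has no meaningful split and raises an error of class
#'   `svpuncta_degenerate_histogram`; supply a fixed threshold instead.
#' @export
auto_threshold <- function(image) {
  v <- as.numeric(image)
  if (!length(v)) abort("`image` must be non-empty.")
  if (anyNA(v) || any(v < 0 | v > 1)) {
    abort("`image` intensities must lie in [0,1].")
  }
  bin <- pmin(floor(v * 256), 255)
  counts <- tabulate(bin + 1L, nbins = 256L)
  if (sum(counts > 0L) < 2L) {
    abort("image histogram is degenerate (constant image); use a fixed threshold.",
          class = "svpuncta_degenerate_histogram")
  }
  p <- counts / sum(counts)
  mids <- (seq_len(256) - 0.5) / 256
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_total <- mu[256]
  k <- seq_len(255)                       # class 0 = bins 1..k
  valid <- omega[k] > 0 & omega[k] < 1
  sigma_b <- rep(-Inf, 255)
  sigma_b[valid] <- (mu_total * omega[k][valid] - mu[k][valid])^2 /
    (omega[k][valid] * (1 - omega[k][valid]))
  best <- which(sigma_b >= max(sigma_b) - 1e-12)
  mean(best) / 256
}

#' Suggest a fixed threshold for a fluorescence channel
#'
#' Otsu's criterion fails on channels where the signal occupies a tiny
#' pixel fraction (a punctate vesicle stain can cover well under 1% of a
#' field), because both classes of its split end up inside the background
#' mode. This picker instead emulates what a user does on the intensity
#' histogram: estimate the background level robustly (median) and its
#' spread (MAD), take the pixels clearly above background
#' (median + 4 MAD) as signal, and place the threshold midway between the
#' background level and the median signal intensity. Channels without
#' appreciable signal fall back to [auto_threshold()].
#'
#' Intended for choosing fixed thresholds on a held-out trial field before
#' a batch run.
#'
#' @param image numeric matrix in \[0,1\].
#' @return threshold in \[0,1\].
#' @export
suggest_threshold <- function(image) {
  v <- as.numeric(image)
  if (anyNA(v) || !length(v)) abort("`image` must be non-empty without NA.")
  bg <- stats::median(v)
  s <- max(stats::mad(v), 1 / 256)
  hi <- v[v > bg + 4 * s]
  if (length(hi) < length(v) * 1e-5) {
    return(auto_threshold(image))
  }
  (bg + stats::median(hi)) / 2
}

#' Binarize an intensity image
#'
#' A pixel is foreground iff its intensity is strictly greater than the
#' threshold.
#'
#' @param image numeric matrix in \[0,1\].
#' @param threshold scalar in \[0,1\].
#' @param role role tag recorded on the resulting mask.
#' @return a [binary_mask()].
#' @export
binarize <- function(image, threshold, role = NA_character_) {
  if (length(threshold) != 1L || is.na(threshold) ||
      threshold < 0 || threshold > 1) {
    abort("`threshold` must be a scalar in [0,1].")
  }
  binary_mask(image > threshold, role = role, source_threshold = threshold)
}

#' Remove connected components below a minimum size
#'
#' Area opening: every connected component with fewer than `min_area`
#' foreground pixels is removed; all others pass unchanged.
#'
#' @param mask binary mask or logical matrix.
#' @param min_area minimum component size in pixels (>= 0).
#' @param connectivity 4 or 8.
#' @return mask of the same type and provenance.
#' @export
area_open <- function(mask, min_area, connectivity = 8L) {
  if (min_area < 0) abort("`min_area` must be >= 0.")
  g <- mask_grid(mask)
  if (min_area <= 1 || !any(g)) {
    return(binary_mask(g, role = mask_role(mask),
                       source_threshold = attr(mask, "source_threshold") %||% NA_real_))
  }
  lab <- label_components(g, connectivity)
  sizes <- tabulate(lab[lab > 0L])
  keep <- lab > 0L & sizes[pmax(lab, 1L)] >= min_area
  binary_mask(keep, role = mask_role(mask),
              source_threshold = attr(mask, "source_threshold") %||% NA_real_)
}

# exact Euclidean-disk erosion/dilation via the distance transform;
# outside the image counts as foreground for erosion and as background
# for dilation (the MATLAB padding convention)
erode_disk <- function(g, radius) {
  if (radius <= 0 || !any(g)) return(g)
  if (all(g)) return(g)
  d <- EBImage::imageData(EBImage::distmap(EBImage::Image(g * 1)))
  d > radius + 1e-7
}

dilate_disk <- function(g, radius) {
  if (radius <= 0 || !any(g)) return(g)
  if (all(g)) return(g)
  d <- EBImage::imageData(EBImage::distmap(EBImage::Image((!g) * 1)))
  d <= radius + 1e-7
}

open_disk <- function(g, radius) dilate_disk(erode_disk(g, radius), radius)

#' Eliminate cell bodies from the neuron mask
#'
#' Morphological opening with a Euclidean disk sized like a cell body
#' segments the cell bodies; these are subtracted from the input, leaving a
#' mask of neuronal processes only. Structures thinner than the disk in
#' every direction (axons, dendrites) are untouched.
#'
#' @param neuron_mask binary mask of the neuron channel.
#' @param disk_radius structuring-element radius in pixels (> 0).
#' @return a `binary_mask` with role `"neuron_processes"`.
#' @export
remove_cell_bodies <- function(neuron_mask, disk_radius) {
  if (disk_radius <= 0) abort("`disk_radius` must be > 0.")
  g <- mask_grid(neuron_mask)
  out <- g & !open_disk(g, disk_radius)
  binary_mask(out, role = "neuron_processes",
              source_threshold = attr(neuron_mask, "source_threshold") %||% NA_real_)
}

#' Dilate a mask with a Euclidean disk
#'
#' Used to slightly grow the partner-cell mask so vesicle clusters that form
#' along the cell edge are captured by the contact zone.
#'
#' @param mask binary mask or logical matrix.
#' @param radius disk radius in pixels (>= 0); 0 is the identity.
#' @return a `binary_mask`; role becomes `"partner_dilated"` when the input
#'   role was `"partner"`, otherwise the input role is kept.
#' @export
dilate_mask <- function(mask, radius) {
  if (radius < 0) abort("`radius` must be >= 0.")
  g <- mask_grid(mask)
  role <- mask_role(mask)
  if (identical(role, "partner")) role <- "partner_dilated"
  binary_mask(dilate_disk(g, radius), role = role,
              source_threshold = attr(mask, "source_threshold") %||% NA_real_)
}

# threshold for one role under a config: fixed lookup or Otsu
channel_threshold <- function(image, role, config) {
  if (config$threshold_mode == "fixed") {
    th <- config$fixed_thresholds
    if (!role %in% names(th)) {
      abort(sprintf("no fixed threshold supplied for channel role '%s'", role))
    }
    unname(th[[role]])
  } else {
    auto_threshold(image)
  }
}

#' Segment a co-culture channel stack into cleaned binary masks
#'
#' Runs the binarization and clean-up stages: threshold each channel
#' (Otsu or fixed), remove small objects from all three masks, eliminate
#' cell bodies from the neuron mask, and slightly dilate the partner mask.
#'
#' @param stack a [channel_stack()] with roles `neuron`, `partner`, `marker`.
#' @param config a [seg_config()].
#' @return list with masks `neuron_raw`, `neuron_processes`, `partner`,
#'   `partner_dilated`, `marker`, and the numeric `thresholds` used.
#' @export
segment_stack <- function(stack, config = seg_config()) {
  stopifnot(inherits(stack, "channel_stack"))
  for (role in c("neuron", "partner", "marker")) {
    if (is.null(stack$images[[role]])) {
      abort(sprintf("stack lacks required channel role '%s'", role))
    }
  }
  th <- vapply(c("neuron", "partner", "marker"), function(role) {
    channel_threshold(stack$images[[role]], role, config)
  }, numeric(1))
  conn <- config$connectivity
  neuron_raw <- area_open(
    binarize(stack$images$neuron, th[["neuron"]], role = "neuron_raw"),
    config$min_area_neuron, conn
  )
  partner <- area_open(
    binarize(stack$images$partner, th[["partner"]], role = "partner"),
    config$min_area_partner, conn
  )
  marker <- area_open(
    binarize(stack$images$marker, th[["marker"]], role = "marker"),
    config$min_area_sv, conn
  )
  list(
    neuron_raw = neuron_raw,
    neuron_processes = remove_cell_bodies(neuron_raw, config$cellbody_disk_radius),
    partner = partner,
    partner_dilated = dilate_mask(partner, config$partner_dilation_radius),
    marker = marker,
    thresholds = th
  )
}
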
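#' Labeled neurite/partner-cell overlap regions
#'
#' Intersects the neuronal-process mask with the (dilated) partner-cell mask
#' by a logical AND, labels the connected components of the intersection,
#' and discards components smaller than `min_overlap_area`. Survivors are
#' relabeled 1..N in raster-scan order of their first pixel, so output is
#' deterministic.
#'
#' @param process_mask binary mask of neuronal processes.
#' @param partner_dilated binary mask of (dilated) partner cells.
#' @param min_overlap_area regions with fewer pixels are discarded.
#' @param connectivity 4 or 8.
#' @return an `overlap_map`: integer label matrix with attributes
#'   `n_regions` and `min_overlap_area_used`.
#' @export
compute_overlaps <- function(process_mask, partner_dilated,
                             min_overlap_area = 10L, connectivity = 8L) {
  g1 <- mask_grid(process_mask)
  g2 <- mask_grid(partner_dilated)
  check_same_dim(g1, g2, what = "masks")
  both <- g1 & g2
  lab <- label_components(both, connectivity)
  n <- max(lab)
  if (n > 0L && min_overlap_area > 1L) {
    sizes <- tabulate(lab[lab > 0L], nbins = n)
    keep <- which(sizes >= min_overlap_area)
    remap <- integer(n)
    remap[keep] <- seq_along(keep)   # raster order preserved
    lab[lab > 0L] <- remap[lab[lab > 0L]]
    n <- length(keep)
  }
  structure(lab,
    n_regions = as.integer(n),
    min_overlap_area_used = as.integer(min_overlap_area),
    class = c("overlap_map", class(lab))
  )
}

#' @export
print.overlap_map <- function(x, ...) {
  cat(sprintf("<overlap_map> %dx%d, %d region(s), size gate %d px\n",
              nrow(x), ncol(x), attr(x, "n_regions"),
              attr(x, "min_overlap_area_used")))
  invisible(x)
}

n_regions <- function(labeled) {
  attr(labeled, "n_regions") %||% max(labeled)
}

#' Per-region synaptic-vesicle cluster features
#'
#' For every labeled overlap region, measures the synaptic-vesicle signal
#' falling inside it: number of SV clusters (connected components of the
#' cleaned SV mask with at least one pixel in the region — a cluster
#' straddling two regions counts once in each), SV-covered area, mean raw
#' marker intensity over SV pixels, and SV density (fraction of the region
#' covered). SV puncta outside every overlap region are ignored: they are
#' not cue-induced.
#'
#' @param labeled an [compute_overlaps()] label map.
#' @param sv_mask cleaned binary SV mask (area opening already applied).
#' @param marker_img raw (pre-binarization) marker intensity image.
#' @param connectivity 4 or 8.
#' @return tibble with one row per region: `region_label`,
#'   `region_area_px`, `sv_cluster_count`, `sv_area_px`,
#'   `sv_mean_intensity` (`NA` when the region holds no SV pixel),
#'   `sv_density`, `has_cluster`.
#' @export
extract_sv_features <- function(labeled, sv_mask, marker_img,
                                connectivity = 8L) {
  g_sv <- mask_grid(sv_mask)
  check_same_dim(labeled, g_sv, marker_img, what = "label map, SV mask and marker image")
  n <- n_regions(labeled)
  if (n == 0L) {
    return(tibble(
      region_label = integer(), region_area_px = integer(),
      sv_cluster_count = integer(), sv_area_px = integer(),
      sv_mean_intensity = double(), sv_density = double(),
      has_cluster = logical()
    ))
  }
  sv_lab <- label_components(g_sv, connectivity)
  rows <- vector("list", n)
  for (r in seq_len(n)) {
    pix <- which(labeled == r)
    svpix <- pix[g_sv[pix]]
    sv_area <- length(svpix)
    rows[[r]] <- tibble(
      region_label = r,
      region_area_px = length(pix),
      sv_cluster_count = length(unique(sv_lab[svpix])),
      sv_area_px = sv_area,
      sv_mean_intensity = if (sv_area > 0) mean(marker_img[svpix]) else NA_real_,
      sv_density = sv_area / length(pix),
      has_cluster = sv_area > 0
    )
  }
  bind_rows(rows)
}

#' Field-level summary of SV clustering
#'
#' Reduces a per-region feature table to the two headline statistics of
#' presynaptic induction: the fraction of overlap regions containing at
#' least one SV cluster (`frequency`) and the fraction of overlap-region
#' area covered by SV clusters (`density`). Density is reported both as the
#' unweighted mean of per-region fractions (`density_mean`, the headline
#' value) and pooled over pixels (`density_pooled` = total SV area / total
#' region area).
#'
#' @param regions tibble from [extract_sv_features()].
#' @return one-row tibble: `n_regions`, `n_with_cluster`, `frequency`,
#'   `density_mean`, `density_pooled`, `empty`. A field without overlap
#'   regions is flagged `empty = TRUE` and carries `NA` statistics — never
#'   silent zeros.
#' @export
summarize_field <- function(regions) {
  n <- nrow(regions)
  if (n == 0L) {
    return(tibble(
      n_regions = 0L, n_with_cluster = 0L, frequency = NA_real_,
      density_mean = NA_real_, density_pooled = NA_real_, empty = TRUE
    ))
  }
  tibble(
    n_regions = n,
    n_with_cluster = sum(regions$has_cluster),
    frequency = mean(regions$has_cluster),
    density_mean = mean(regions$sv_density),
    density_pooled = sum(regions$sv_area_px) / sum(regions$region_area_px),
    empty = FALSE
  )
}

#' Run the full co-culture pipeline on one field
#'
#' Segments the three channels ([segment_stack()]), forms size-gated
#' labeled overlap regions ([compute_overlaps()]), extracts per-region SV
#' features ([extract_sv_features()]) and summarizes the field
#' ([summarize_field()]).
#'
#' @param stack a [channel_stack()] with roles `neuron`, `partner`, `marker`.
#' @param config a [seg_config()].
#' @return a `cocult_result`: list with `field_id`, `masks`, `thresholds`,
#'   `overlaps` (label map), `regions` (tibble, including `field_id` and
#'   `region_area_um2`), `summary` (one-row tibble), `pixel_size`, `config`.
#' @export
analyze_cocult <- function(stack, config = seg_config()) {
  masks <- segment_stack(stack, config)
  overlaps <- compute_overlaps(
    masks$neuron_processes, masks$partner_dilated,
    min_overlap_area = config$min_overlap_area,
    connectivity = config$connectivity
  )
  regions <- extract_sv_features(
    overlaps, masks$marker, stack$images$marker,
    connectivity = config$connectivity
  )
  regions <- mutate(regions,
    field_id = stack$field_id,
    region_area_um2 = .data$region_area_px * stack$pixel_size^2,
    .before = 1
  )
  regions <- select(regions, "field_id", "region_label", "region_area_px",
                    "region_area_um2", "sv_cluster_count", "sv_area_px",
                    "sv_mean_intensity", "sv_density", "has_cluster")
  structure(
    list(
      field_id = stack$field_id,
      masks = masks,
      thresholds = masks$thresholds,
      overlaps = overlaps,
      regions = regions,
      summary = mutate(summarize_field(regions), field_id = stack$field_id,
                       .before = 1),
      pixel_size = stack$pixel_size,
      config = config
    ),
    class = "cocult_result"
  )
}

#' @export
print.cocult_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<cocult_result> field '%s': %d overlap region(s)\n",
              x$field_id, s$n_regions))
  if (!s$empty) {
    cat(sprintf("  SV cluster frequency: %.3f\n  SV cluster density: %.3f (mean), %.3f (pooled)\n",
                s$frequency, s$density_mean, s$density_pooled))
  } else {
    cat("  no overlap regions (field flagged empty)\n")
  }
  invisible(x)
}

#' @rdname analyze_cocult
#' @param x a `cocult_result`.
#' @param ... unused.
#' @export
tidy.cocult_result <- function(x, ...) x$regions

#' @rdname analyze_cocult
#' @export
glance.cocult_result <- function(x, ...) x$summary
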
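#' Synthetic field specification
#'
#' Parameters of the synthetic co-culture / mature-neuron field generator.
#' The generator draws curvilinear neuronal processes plus cell-body disks
#' (neuron channel), elliptical heterologous partner-cell blobs (partner
#' channel), and disk-shaped synaptic-vesicle puncta placed inside
#' neurite/partner contact zones (marker channel), then renders each
#' channel as constant foreground over constant background with additive
#' Gaussian noise. Ground truth (masks, labeled contact regions, per-region
#' cluster flags, realized frequency and density) is recorded before noise.
#'
#' Defaults describe the 20x co-culture regime the pipeline is benchmarked
#' in: 512x512 fields dense enough to carry 15+ gated contact regions,
#' target SV-cluster frequency 0.6 and density 0.2 (the magnitude of
#' manually scored values in this assay), and noise_sd 0.1 against a
#' minimum channel contrast of 0.5, i.e. a signal-to-noise ratio of 5.
#'
#' @param image_size `(H, W)` in pixels.
#' @param n_neurites number of random-walk neurites.
#' @param neurite_width neurite thickness in pixels.
#' @param n_cell_bodies,cell_body_radius neuronal somata (disks) added to
#'   the neuron channel.
#' @param n_partner_cells,partner_radius_range elliptical partner-cell
#'   blobs; semi-axes drawn uniformly from the range (pixels).
#' @param target_frequency probability that a contact region is marked as
#'   cluster-bearing (Bernoulli per region).
#' @param target_density per-region SV coverage fraction approached by
#'   greedy punctum placement; the realized value is recorded.
#' @param sv_cluster_radius_range SV punctum radius range (pixels).
#' @param min_sv_px minimum rendered (clipped) punctum size in pixels, so
#'   every planted cluster is resolvable by the size gates downstream.
#' @param channel_intensities named foreground amplitudes above background
#'   for `neuron`, `partner`, `marker`, each in (0, 1\].
#' @param noise_sd additive Gaussian noise sigma (>= 0).
#' @param background_level constant background intensity.
#' @param partner_dilation_radius,min_overlap_area,cellbody_disk_radius,connectivity
#'   geometry used to define the ground-truth contact regions; defaults
#'   mirror [seg_config()] at 20x.
#' @param pixel_size micrometres per pixel recorded on generated stacks.
#' @param seed RNG seed; generation is fully reproducible from it.
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(image_size = c(512L, 512L),
                       n_neurites = 40L,
                       neurite_width = 3L,
                       n_cell_bodies = 4L,
                       cell_body_radius = 10L,
                       n_partner_cells = 18L,
                       partner_radius_range = c(10, 18),
                       target_frequency = 0.6,
                       target_density = 0.2,
                       sv_cluster_radius_range = c(2, 4),
                       min_sv_px = 4L,
                       channel_intensities = c(neuron = 0.5, partner = 0.6,
                                               marker = 0.7),
                       noise_sd = 0.1,
                       background_level = 0.1,
                       partner_dilation_radius = 2L,
                       min_overlap_area = 10L,
                       cellbody_disk_radius = 8L,
                       connectivity = 8L,
                       pixel_size = 0.31,
                       seed = 1L) {
  spec <- list(
    image_size = as.integer(image_size),
    n_neurites = as.integer(n_neurites),
    neurite_width = neurite_width,
    n_cell_bodies = as.integer(n_cell_bodies),
    cell_body_radius = cell_body_radius,
    n_partner_cells = as.integer(n_partner_cells),
    partner_radius_range = partner_radius_range,
    target_frequency = target_frequency,
    target_density = target_density,
    sv_cluster_radius_range = sv_cluster_radius_range,
    min_sv_px = as.integer(min_sv_px),
    channel_intensities = channel_intensities,
    noise_sd = noise_sd,
    background_level = background_level,
    partner_dilation_radius = partner_dilation_radius,
    min_overlap_area = as.integer(min_overlap_area),
    cellbody_disk_radius = cellbody_disk_radius,
    connectivity = check_connectivity(connectivity),
    pixel_size = pixel_size,
    seed = as.integer(seed)
  )
  if (spec$target_frequency < 0 || spec$target_frequency > 1 ||
      spec$target_density < 0 || spec$target_density > 1) {
    abort("`target_frequency` and `target_density` must lie in [0,1].")
  }
  if (spec$noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (any(spec$channel_intensities <= 0 | spec$channel_intensities > 1)) {
    abort("`channel_intensities` must lie in (0,1].")
  }
  structure(spec, class = "scene_spec")
}

stamp_disk <- function(g, r0, c0, radius, restrict_idx = NULL) {
  off <- disk_offsets(radius)
  rr <- r0 + off[, 1]
  cc <- c0 + off[, 2]
  ok <- rr >= 1 & rr <= nrow(g) & cc >= 1 & cc <= ncol(g)
  idx <- (cc[ok] - 1L) * nrow(g) + rr[ok]
  if (!is.null(restrict_idx)) idx <- idx[restrict_idx[idx]]
  g[idx] <- TRUE
  g
}

# curvilinear neurite paths as correlated random walks
draw_neurites <- function(H, W, n_neurites, width) {
  path <- matrix(FALSE, H, W)
  steps <- round(0.75 * (H + W))
  for (i in seq_len(n_neurites)) {
    r0 <- runif(1, 1, H)
    c0 <- runif(1, 1, W)
    theta <- runif(1, 0, 2 * pi) + cumsum(rnorm(steps, 0, 0.12))
    rr <- round(r0 + cumsum(sin(theta)))
    cc <- round(c0 + cumsum(cos(theta)))
    out <- which(rr < 1 | rr > H | cc < 1 | cc > W)
    if (length(out)) {
      if (out[1] == 1L) next
      rr <- rr[seq_len(out[1] - 1L)]
      cc <- cc[seq_len(out[1] - 1L)]
    }
    path[cbind(rr, cc)] <- TRUE
  }
  if (width > 1) path <- dilate_disk(path, (width - 1) / 2) else path
}

rasterize_ellipse <- function(g, r0, c0, a, b, phi) {
  rmax <- ceiling(max(a, b))
  rs <- max(1, floor(r0 - rmax)):min(nrow(g), ceiling(r0 + rmax))
  cs <- max(1, floor(c0 - rmax)):min(ncol(g), ceiling(c0 + rmax))
  dr <- outer(rs - r0, rep(1, length(cs)))
  dc <- outer(rep(1, length(rs)), cs - c0)
  u <- (dr * cos(phi) + dc * sin(phi)) / a
  v <- (-dr * sin(phi) + dc * cos(phi)) / b
  g[rs, cs] <- g[rs, cs] | (u^2 + v^2 <= 1)
  g
}

render_channel <- function(mask, level, background, noise_sd) {
  img <- background + level * mask
  if (noise_sd > 0) {
    img <- img + matrix(rnorm(length(mask), 0, noise_sd), nrow(mask))
  }
  pmin(pmax(img, 0), 1)
}

#' Generate a ground-truthed synthetic co-culture field
#'
#' Draws the scene described by a [scene_spec()]: neurites and somata in
#' the neuron channel, elliptical partner cells (kept clear of somata, as
#' axon-partner contacts are) in the partner channel, and SV puncta in the
#' marker channel. Ground-truth contact regions are the size-gated
#' components of `processes AND dilated-partner` computed on the noiseless
#' masks; each region is independently marked cluster-bearing with
#' probability `target_frequency`, and marked regions receive hard-disk SV
#' puncta (clipped to the region) until coverage reaches `target_density`.
#'
#' @param spec a [scene_spec()].
#' @return list with `stack` (a [channel_stack()]) and `truth` (a
#'   `ground_truth` list: noiseless masks, the labeled `overlaps` map, a
#'   per-region tibble with `flagged`/realized densities, and
#'   `realized_frequency`, `realized_density_mean`,
#'   `realized_density_pooled`).
#' @section Feasibility: if a marked region cannot reach the target
#'   coverage (or host a punctum of `min_sv_px` pixels), an error of class
#'   `svpuncta_feasibility_error` names the offending region.
#' @export
generate_cocult_field <- function(spec = scene_spec()) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  H <- spec$image_size[1]
  W <- spec$image_size[2]

  neurite <- draw_neurites(H, W, spec$n_neurites, spec$neurite_width)
  body <- matrix(FALSE, H, W)
  body_centers <- NULL
  for (i in seq_len(spec$n_cell_bodies)) {
    m <- spec$cell_body_radius + 2
    ctr <- c(runif(1, m, H - m), runif(1, m, W - m))
    body_centers <- rbind(body_centers, ctr)
    body <- stamp_disk(body, round(ctr[1]), round(ctr[2]), spec$cell_body_radius)
  }
  neuron <- neurite | body

  # partner blobs clear of somata so contact zones involve processes only
  partner <- matrix(FALSE, H, W)
  clearance <- spec$cell_body_radius + max(spec$partner_radius_range) +
    spec$cellbody_disk_radius + spec$partner_dilation_radius + 2
  for (i in seq_len(spec$n_partner_cells)) {
    for (try in seq_len(200)) {
      a <- runif(1, spec$partner_radius_range[1], spec$partner_radius_range[2])
      b <- runif(1, spec$partner_radius_range[1], spec$partner_radius_range[2])
      m <- max(a, b) + 1
      ctr <- c(runif(1, m, H - m), runif(1, m, W - m))
      ok <- is.null(body_centers) ||
        all(sqrt((body_centers[, 1] - ctr[1])^2 +
                 (body_centers[, 2] - ctr[2])^2) > clearance)
      if (ok) break
      if (try == 200) {
        abort("cannot place partner cell clear of cell bodies; field too crowded",
              class = "svpuncta_feasibility_error")
      }
    }
    partner <- rasterize_ellipse(partner, ctr[1], ctr[2], a, b, runif(1, 0, pi))
  }

  process <- mask_grid(remove_cell_bodies(neuron, spec$cellbody_disk_radius))
  partner_dil <- dilate_disk(partner, spec$partner_dilation_radius)
  overlaps <- compute_overlaps(process, partner_dil,
                               min_overlap_area = spec$min_overlap_area,
                               connectivity = spec$connectivity)
  n <- n_regions(overlaps)
  flags <- if (n > 0) runif(n) < spec$target_frequency else logical(0)

  sv <- matrix(FALSE, H, W)
  in_region <- matrix(FALSE, H, W)
  for (r in which(flags)) {
    pix <- which(overlaps == r)
    in_region[] <- FALSE
    in_region[pix] <- TRUE
    need <- ceiling(spec$target_density * length(pix))
    attempts <- 0L
    while (sum(sv[pix]) < need) {
      attempts <- attempts + 1L
      if (attempts > 500L) {
        abort(sprintf("cannot reach target SV density in overlap region %d", r),
              class = "svpuncta_feasibility_error")
      }
      ctr <- pix[sample.int(length(pix), 1L)]
      rad <- runif(1, spec$sv_cluster_radius_range[1],
                   spec$sv_cluster_radius_range[2])
      cand <- stamp_disk(matrix(FALSE, H, W),
                         ((ctr - 1L) %% H) + 1L, ((ctr - 1L) %/% H) + 1L,
                         rad, restrict_idx = in_region)
      if (sum(cand) < spec$min_sv_px) next  # too clipped to resolve
      sv <- sv | cand
    }
  }

  region_tbl <- if (n > 0) {
    areas <- tabulate(overlaps[overlaps > 0L], nbins = n)
    sv_areas <- vapply(seq_len(n), function(r) sum(sv[overlaps == r]), integer(1))
    tibble(
      region_label = seq_len(n),
      area_px = as.integer(areas),
      flagged = flags,
      sv_area_px = sv_areas,
      sv_density = sv_areas / areas
    )
  } else {
    tibble(region_label = integer(), area_px = integer(),
           flagged = logical(), sv_area_px = integer(), sv_density = double())
  }

  stack <- channel_stack(
    list(
      neuron = render_channel(neuron, spec$channel_intensities[["neuron"]],
                              spec$background_level, spec$noise_sd),
      partner = render_channel(partner, spec$channel_intensities[["partner"]],
                               spec$background_level, spec$noise_sd),
      marker = render_channel(sv, spec$channel_intensities[["marker"]],
                              spec$background_level, spec$noise_sd)
    ),
    pixel_size = spec$pixel_size,
    field_id = sprintf("sim_cocult_seed%d", spec$seed),
    magnification_tag = "20x"
  )
  truth <- structure(list(
    neuron_mask = neuron,
    neurite_mask = neurite,
    body_mask = body,
    partner_mask = partner,
    process_mask = process,
    sv_mask = sv,
    overlaps = overlaps,
    regions = region_tbl,
    realized_frequency = if (n > 0) mean(region_tbl$sv_area_px > 0) else NA_real_,
    realized_density_mean = if (n > 0) mean(region_tbl$sv_density) else NA_real_,
    realized_density_pooled = if (n > 0) {
      sum(region_tbl$sv_area_px) / sum(region_tbl$area_px)
    } else NA_real_,
    spec = spec
  ), class = "ground_truth")
  list(stack = stack, truth = truth)
}

#' Generate a synthetic mature-neuron field with planted synapses
#'
#' Neurites and somata as in [generate_cocult_field()]; `n_true_synapses`
#' colocalized pre/post punctum pairs (identical disks in both marker
#' channels) are planted on neuronal processes, plus `n_pre_only` and
#' `n_post_only` decoy puncta with no counterpart. All puncta centers are
#' mutually separated by more than twice the punctum diameter, so decoys
#' never colocalize by accident and planted pairs never merge.
#'
#' @param spec a [scene_spec()]; `channel_intensities` roles map to
#'   neuron/pre(`marker` level)/post(`partner` level).
#' @param n_true_synapses,n_pre_only,n_post_only punctum counts (>= 0).
#' @param punctum_radius punctum disk radius in pixels.
#' @return list with `stack` (roles `neuron`, `pre`, `post`) and `truth`
#'   (masks, punctum centers, `n_true_synapses`).
#' @export
generate_synapse_field <- function(spec = scene_spec(), n_true_synapses,
                                   n_pre_only = 0L, n_post_only = 0L,
                                   punctum_radius = 2) {
  stopifnot(inherits(spec, "scene_spec"),
            n_true_synapses >= 0, n_pre_only >= 0, n_post_only >= 0)
  set.seed(spec$seed)
  H <- spec$image_size[1]
  W <- spec$image_size[2]
  neurite <- draw_neurites(H, W, spec$n_neurites, spec$neurite_width)
  body <- matrix(FALSE, H, W)
  body_centers <- NULL
  for (i in seq_len(spec$n_cell_bodies)) {
    m <- spec$cell_body_radius + 2
    ctr <- c(runif(1, m, H - m), runif(1, m, W - m))
    body_centers <- rbind(body_centers, ctr)
    body <- stamp_disk(body, round(ctr[1]), round(ctr[2]), spec$cell_body_radius)
  }
  neuron <- neurite | body
  process <- mask_grid(remove_cell_bodies(neuron, spec$cellbody_disk_radius))

  cand <- which(process)
  rr <- ((cand - 1L) %% H) + 1L
  cc <- ((cand - 1L) %/% H) + 1L
  margin <- punctum_radius + 1
  keep <- rr > margin & rr <= H - margin & cc > margin & cc <= W - margin
  if (!is.null(body_centers)) {
    guard <- spec$cell_body_radius + spec$cellbody_disk_radius + 2
    for (k in seq_len(nrow(body_centers))) {
      keep <- keep & (sqrt((rr - body_centers[k, 1])^2 +
                           (cc - body_centers[k, 2])^2) > guard)
    }
  }
  cand <- cand[keep]
  n_total <- n_true_synapses + n_pre_only + n_post_only
  sep <- 4 * punctum_radius + 2
  centers <- matrix(numeric(0), 0, 2)
  attempts <- 0L
  while (nrow(centers) < n_total) {
    attempts <- attempts + 1L
    if (attempts > 5000L || length(cand) == 0L) {
      abort("cannot place puncta with the required separation on the neurite mask",
            class = "svpuncta_feasibility_error")
    }
    i <- cand[sample.int(length(cand), 1L)]
    p <- c(((i - 1L) %% H) + 1L, ((i - 1L) %/% H) + 1L)
    if (nrow(centers) == 0L ||
        all(sqrt((centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2) >= sep)) {
      centers <- rbind(centers, p)
    }
  }
  grp <- rep(c("true", "pre", "post"),
             c(n_true_synapses, n_pre_only, n_post_only))
  pre_mask <- matrix(FALSE, H, W)
  post_mask <- matrix(FALSE, H, W)
  for (k in seq_len(n_total)) {
    if (grp[k] %in% c("true", "pre")) {
      pre_mask <- stamp_disk(pre_mask, centers[k, 1], centers[k, 2], punctum_radius)
    }
    if (grp[k] %in% c("true", "post")) {
      post_mask <- stamp_disk(post_mask, centers[k, 1], centers[k, 2], punctum_radius)
    }
  }

  stack <- channel_stack(
    list(
      neuron = render_channel(neuron, spec$channel_intensities[["neuron"]],
                              spec$background_level, spec$noise_sd),
      pre = render_channel(pre_mask, spec$channel_intensities[["marker"]],
                           spec$background_level, spec$noise_sd),
      post = render_channel(post_mask, spec$channel_intensities[["partner"]],
                            spec$background_level, spec$noise_sd)
    ),
    pixel_size = spec$pixel_size,
    field_id = sprintf("sim_synapse_seed%d", spec$seed),
    magnification_tag = "63x"
  )
  truth <- structure(list(
    neuron_mask = neuron,
    process_mask = process,
    pre_mask = pre_mask,
    post_mask = post_mask,
    centers = centers,
    groups = grp,
    n_true_synapses = as.integer(n_true_synapses),
    spec = spec
  ), class = "ground_truth")
  list(stack = stack, truth = truth)
}
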
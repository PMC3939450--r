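#' Detect endogenous synapses from pre/post marker colocalization
#'
#' Variant pipeline for mature neuron cultures imaged at high magnification:
#' a synapse is a colocalized pre-/post-synaptic punctum pair inside the
#' neuronal-process mask. Each channel is thresholded and area-opened, cell
#' bodies are removed from the neuron mask, and the synapse mask is the
#' triple intersection neuron AND pre AND post. Components smaller than
#' `min_synapse_area` are discarded. Colocalization is pixel overlap (at
#' least one shared pixel after clean-up), matching the mask-intersection
#' design of the co-culture pipeline, not a centroid-distance criterion.
#'
#' Synaptic density is reported as synapses per 100 um^2 of
#' neuronal-process area; the neuron-area normalization makes fields with
#' different amounts of dendrite comparable.
#'
#' @param stack a [channel_stack()] with roles `neuron`, `pre`, `post`.
#' @param config a [seg_config()]; pre/post channels use `min_area_sv` for
#'   small-object removal. With fixed thresholds, names `pre` and `post`
#'   select the marker thresholds.
#' @param min_synapse_area minimum colocalized-punctum size in pixels;
#'   default taken from `config`.
#' @return a `synapse_map`: list with `field_id`, `label_grid`,
#'   `n_synapses`, `neuron_area_px`, `neuron_area_um2`, `density`
#'   (per 100 um^2; `NA` when the neuron mask is empty), `empty` flag,
#'   `masks`, `thresholds`.
#' @export
detect_synapses <- function(stack, config = seg_config(magnification = "63x"),
                            min_synapse_area = config$min_synapse_area) {
  stopifnot(inherits(stack, "channel_stack"))
  for (role in c("neuron", "pre", "post")) {
    if (is.null(stack$images[[role]])) {
      abort(sprintf("stack lacks required channel role '%s'", role))
    }
  }
  if (min_synapse_area < 0) abort("`min_synapse_area` must be >= 0.")
  conn <- config$connectivity
  th <- vapply(c("neuron", "pre", "post"), function(role) {
    channel_threshold(stack$images[[role]], role, config)
  }, numeric(1))
  neuron_raw <- area_open(
    binarize(stack$images$neuron, th[["neuron"]], role = "neuron_raw"),
    config$min_area_neuron, conn
  )
  process <- remove_cell_bodies(neuron_raw, config$cellbody_disk_radius)
  pre <- area_open(binarize(stack$images$pre, th[["pre"]], role = "marker"),
                   config$min_area_sv, conn)
  post <- area_open(binarize(stack$images$post, th[["post"]], role = "marker"),
                    config$min_area_sv, conn)
  neuron_area_px <- sum(process)
  coloc <- mask_grid(process) & mask_grid(pre) & mask_grid(post)
  lab <- label_components(coloc, conn)
  n <- max(lab)
  if (n > 0L && min_synapse_area > 1L) {
    sizes <- tabulate(lab[lab > 0L], nbins = n)
    keep <- which(sizes >= min_synapse_area)
    remap <- integer(n)
    remap[keep] <- seq_along(keep)
    lab[lab > 0L] <- remap[lab[lab > 0L]]
    n <- length(keep)
  }
  empty <- neuron_area_px == 0L
  area_um2 <- neuron_area_px * stack$pixel_size^2
  structure(
    list(
      field_id = stack$field_id,
      label_grid = lab,
      n_synapses = as.integer(n),
      neuron_area_px = as.integer(neuron_area_px),
      neuron_area_um2 = area_um2,
      density = if (empty) NA_real_ else n / (area_um2 / 100),
      empty = empty,
      masks = list(neuron_processes = process, pre = pre, post = post),
      thresholds = th,
      pixel_size = stack$pixel_size
    ),
    class = "synapse_map"
  )
}

#' @export
print.synapse_map <- function(x, ...) {
  if (x$empty) {
    cat(sprintf("<synapse_map> field '%s': empty neuron mask (flagged)\n",
                x$field_id))
  } else {
    cat(sprintf(
      "<synapse_map> field '%s': %d synapse(s) over %.1f um^2 of processes (%.3f per 100 um^2)\n",
      x$field_id, x$n_synapses, x$neuron_area_um2, x$density
    ))
  }
  invisible(x)
}

#' @rdname detect_synapses
#' @param x a `synapse_map`.
#' @param ... unused.
#' @export
glance.synapse_map <- function(x, ...) {
  tibble(
    field_id = x$field_id,
    n_synapses = x$n_synapses,
    neuron_area_um2 = x$neuron_area_um2,
    density_per_100um2 = x$density,
    empty = x$empty
  )
}
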
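#' Batch run configuration
#'
#' Assembles and validates everything a batch run needs before any field is
#' touched. Modes: `"cocult"` (co-culture SV-cluster pipeline),
#' `"synapse"` (pre/post colocalization pipeline), `"simulate"` (write
#' synthetic fields plus ground truth). Batch analysis requires fixed
#' thresholds — per-field automatic thresholds would reintroduce
#' threshold-dependent variation across a batch — unless `preview = TRUE`,
#' which is the supported way to pick thresholds on a small trial set.
#'
#' @param mode `"cocult"`, `"synapse"` or `"simulate"`.
#' @param input_dir directory of TIFF fields (analysis modes).
#' @param output_dir directory for results; created if absent.
#' @param channel_map named plane indices for [read_stack()].
#' @param seg a [seg_config()].
#' @param pixel_size micrometres per pixel for all fields.
#' @param preview write threshold-preview panels and allow auto thresholds.
#' @param n_fields,scene simulate mode: number of fields and a list of
#'   [scene_spec()] overrides (`seed` is taken per field as
#'   `seed_base + field index`).
#' @param seed_base simulate mode: base seed.
#' @param log_level `"info"` or `"quiet"`.
#' @return a validated `run_config`.
#' @export
run_config <- function(mode = c("cocult", "synapse", "simulate"),
                       input_dir = NULL, output_dir,
                       channel_map = NULL, seg = seg_config(),
                       pixel_size = NULL, preview = FALSE,
                       n_fields = 6L, scene = list(), seed_base = 1L,
                       log_level = c("info", "quiet")) {
  mode <- match.arg(mode)
  log_level <- match.arg(log_level)
  cfg <- structure(list(
    mode = mode, input_dir = input_dir, output_dir = output_dir,
    channel_map = channel_map, seg = seg, pixel_size = pixel_size,
    preview = isTRUE(preview), n_fields = as.integer(n_fields),
    scene = scene, seed_base = as.integer(seed_base), log_level = log_level
  ), class = "run_config")
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  if (!inherits(cfg$seg, "seg_config")) abort("`seg` must be a seg_config().")
  if (cfg$mode %in% c("cocult", "synapse")) {
    if (is.null(cfg$input_dir) || !dir.exists(cfg$input_dir)) {
      abort("`input_dir` must be an existing directory.")
    }
    roles_needed <- if (cfg$mode == "cocult") {
      c("neuron", "partner", "marker")
    } else {
      c("neuron", "pre", "post")
    }
    if (is.null(cfg$channel_map) ||
        !all(roles_needed %in% names(cfg$channel_map))) {
      abort(sprintf("`channel_map` must name roles %s.",
                    paste(roles_needed, collapse = "/")))
    }
    if (is.null(cfg$pixel_size) || cfg$pixel_size <= 0) {
      abort("`pixel_size` must be a positive scalar.")
    }
    if (cfg$seg$threshold_mode == "auto" && !cfg$preview) {
      abort(paste("batch analysis requires fixed thresholds;",
                  "use preview = TRUE to explore automatic thresholds."))
    }
  }
  if (cfg$mode == "simulate" && cfg$n_fields < 1L) {
    abort("`n_fields` must be >= 1.")
  }
  cfg
}

#' Read a batch configuration from YAML
#'
#' Flat YAML mirroring [run_config()]; the `segmentation` block holds
#' [seg_config()] fields (`fixed_thresholds` as a role-named mapping) and
#' the `scene` block holds [scene_spec()] overrides for simulate mode.
#'
#' @param path YAML file.
#' @param ... [run_config()] overrides taking precedence over file values.
#' @return a validated `run_config`.
#' @export
read_run_config <- function(path, ...) {
  if (!file.exists(path)) {
    abort(sprintf("config file not found: %s", path),
          class = "svpuncta_io_error")
  }
  y <- yaml::read_yaml(path)
  seg_args <- y$segmentation %||% list()
  if (!is.null(seg_args$fixed_thresholds)) {
    seg_args$fixed_thresholds <- unlist(seg_args$fixed_thresholds)
  }
  args <- list(
    mode = y$mode %||% "cocult",
    input_dir = y$input_dir,
    output_dir = y$output_dir %||% ".",
    channel_map = if (!is.null(y$channel_map)) unlist(y$channel_map),
    seg = do.call(seg_config, seg_args),
    pixel_size = y$pixel_size,
    preview = isTRUE(y$preview),
    n_fields = y$n_fields %||% 6L,
    scene = y$scene %||% list(),
    seed_base = y$seed_base %||% 1L,
    log_level = y$log_level %||% "info"
  )
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(run_config, args)
}

batch_log <- function(cfg, fmt, ...) {
  if (identical(cfg$log_level, "info")) {
    message(sprintf(fmt, ...))
  }
}

seg_config_echo <- function(seg) {
  out <- unclass(seg)
  out$fixed_thresholds <- as.list(out$fixed_thresholds)
  out
}

#' Process a directory of fields end to end
#'
#' Applies the configured pipeline with identical settings to every TIFF in
#' `input_dir` (lexicographic order). Per field it writes a result CSV and
#' a rendering; at the end, an experiment summary CSV (one row per field)
#' and a manifest echoing the full configuration, the package version and
#' per-field region counts — enough to reproduce the run exactly.
#' Unreadable fields are logged and skipped, never fatal; a run with no
#' readable field fails. The pipeline draws no random numbers, so repeated
#' runs are byte-identical.
#'
#' @param config a [run_config()].
#' @return list with `status` (`"ok"` / `"completed_with_warnings"`),
#'   `n_processed`, `n_skipped`, `summary` tibble and `output_dir`.
#' @export
run_batch <- function(config) {
  config <- validate_run_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  if (config$mode == "simulate") {
    return(run_batch_simulate(config))
  }

  files <- sort(list.files(config$input_dir, pattern = "\\.tiff?$",
                           ignore.case = TRUE, full.names = TRUE))
  if (!length(files)) {
    abort(sprintf("no TIFF fields found in '%s'", config$input_dir))
  }
  rows <- list()
  processed <- list()
  skipped <- character()
  for (f in files) {
    res <- tryCatch({
      stack <- read_stack(f, config$channel_map, config$pixel_size,
                          magnification_tag = config$seg$magnification)
      base <- file.path(config$output_dir, stack$field_id)
      if (config$preview) {
        for (role in names(stack$images)) {
          panel <- render_threshold_preview(stack$images[[role]])
          png::writePNG(panel, paste0(base, "_preview_", role, ".png"))
        }
      }
      if (config$mode == "cocult") {
        r <- analyze_cocult(stack, config$seg)
        export_table(r$regions, paste0(base, "_regions.csv"))
        write_overlay(r$overlaps, r$masks$marker, paste0(base, "_overlay.png"),
                      partner_mask = r$masks$partner_dilated)
        list(row = glance(r), n = r$summary$n_regions)
      } else {
        r <- detect_synapses(stack, config$seg)
        write_image_file(render_synapse_map(r), paste0(base, "_synapses.png"))
        g <- glance(r)
        readr::write_csv(g, paste0(base, "_synapses.csv"), progress = FALSE)
        list(row = g, n = r$n_synapses)
      }
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped <- c(skipped, basename(f))
      batch_log(config, "skipping unreadable field '%s': %s",
                basename(f), conditionMessage(res))
    } else {
      rows[[length(rows) + 1L]] <- res$row
      processed[[basename(f)]] <- res$n
      batch_log(config, "processed '%s' (%d %s)", basename(f), res$n,
                if (config$mode == "cocult") "regions" else "synapses")
    }
  }
  if (!length(rows)) {
    abort("no readable fields; nothing was processed")
  }
  summary <- bind_rows(rows)
  export_summary(summary, file.path(config$output_dir, "summary.csv"))
  status <- if (length(skipped)) "completed_with_warnings" else "ok"
  manifest <- list(
    software = "svpuncta",
    version = as.character(utils::packageVersion("svpuncta")),
    mode = config$mode,
    status = status,
    pixel_size = config$pixel_size,
    channel_map = as.list(config$channel_map),
    segmentation = seg_config_echo(config$seg),
    preview = config$preview,
    fields_processed = processed,
    fields_skipped = as.list(skipped)
  )
  yaml::write_yaml(manifest, file.path(config$output_dir, "manifest.yaml"))
  invisible(list(status = status, n_processed = length(rows),
                 n_skipped = length(skipped), summary = summary,
                 output_dir = config$output_dir))
}

run_batch_simulate <- function(config) {
  truth_rows <- list()
  for (i in seq_len(config$n_fields)) {
    spec <- do.call(scene_spec,
                    c(config$scene, list(seed = config$seed_base + i)))
    gen <- generate_cocult_field(spec)
    base <- file.path(config$output_dir, sprintf("field_%03d", i))
    write_stack(gen$stack, paste0(base, ".tif"),
                roles = c("neuron", "partner", "marker"))
    tiff::writeTIFF(
      list(gen$truth$neuron_mask * 1, gen$truth$partner_mask * 1,
           gen$truth$sv_mask * 1),
      paste0(base, "_truth_masks.tif"), bits.per.sample = 8L
    )
    t <- gen$truth
    jsonlite::write_json(
      list(
        field = basename(paste0(base, ".tif")),
        seed = spec$seed,
        n_regions = n_regions(t$overlaps),
        realized_frequency = t$realized_frequency,
        realized_density_mean = t$realized_density_mean,
        realized_density_pooled = t$realized_density_pooled,
        regions = t$regions
      ),
      paste0(base, "_truth.json"), auto_unbox = TRUE, digits = NA
    )
    truth_rows[[i]] <- tibble(
      field_id = gen$stack$field_id, seed = spec$seed,
      n_regions = n_regions(t$overlaps),
      realized_frequency = t$realized_frequency,
      realized_density_pooled = t$realized_density_pooled
    )
    batch_log(config, "wrote synthetic field %d/%d", i, config$n_fields)
  }
  summary <- bind_rows(truth_rows)
  export_summary(summary, file.path(config$output_dir, "summary.csv"))
  invisible(list(status = "ok", n_processed = config$n_fields,
                 n_skipped = 0L, summary = summary,
                 output_dir = config$output_dir))
}
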
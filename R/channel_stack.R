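#' Channel stacks
#'
#' A `channel_stack` holds one imaging field: two to four registered 2-D
#' intensity images addressed by channel role, plus the pixel-size
#' calibration. Intensities are normalized to \[0,1\] (division by the
#' bit-depth maximum happens at load time in [read_stack()]). Co-culture
#' fields use roles `neuron` (cytoplasmic GFP), `partner` (heterologous-cell
#' mCherry) and `marker` (synaptic-vesicle immunostain); synapse-mode fields
#' use `neuron`, `pre` and `post`.
#'
#' @param images named list of numeric matrices with identical dimensions,
#'   values in \[0,1\]; names are channel roles.
#' @param pixel_size micrometres per pixel (> 0). The paper-style 20x and
#'   63x configurations do not imply a fixed value; calibration is a
#'   required user input.
#' @param field_id identifier used in result tables.
#' @param magnification_tag free-form text such as `"20x"` or `"63x"`.
#' @return a `channel_stack` object.
#' @export
channel_stack <- function(images, pixel_size, field_id = "field",
                          magnification_tag = "20x") {
  if (!is.list(images) || is.null(names(images)) ||
      any(!nzchar(names(images)))) {
    abort("`images` must be a named list of matrices.")
  }
  bad_role <- setdiff(names(images), c("neuron", "partner", "marker", "pre", "post"))
  if (length(bad_role)) {
    abort(sprintf("unknown channel role(s): %s", paste(bad_role, collapse = ", ")))
  }
  for (nm in names(images)) {
    img <- images[[nm]]
    if (!is.matrix(img) || !is.numeric(img)) {
      abort(sprintf("channel '%s' must be a numeric matrix", nm))
    }
    if (anyNA(img) || any(img < 0 | img > 1)) {
      abort(sprintf("channel '%s' must have intensities in [0,1]", nm))
    }
  }
  do.call(check_same_dim, c(unname(images), list(what = "channel images")))
  dims <- dim(images[[1]])
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L ||
      is.na(pixel_size) || pixel_size <= 0) {
    abort("`pixel_size` must be a positive scalar (micrometres per pixel).")
  }
  structure(
    list(
      field_id = as.character(field_id)[1],
      images = images,
      pixel_size = as.numeric(pixel_size),
      magnification_tag = as.character(magnification_tag)[1],
      dim = dims
    ),
    class = "channel_stack"
  )
}

#' @export
print.channel_stack <- function(x, ...) {
  cat(sprintf(
    "<channel_stack> '%s' %dx%d px, %.4g um/px (%s)\n  channels: %s\n",
    x$field_id, x$dim[1], x$dim[2], x$pixel_size, x$magnification_tag,
    paste(names(x$images), collapse = ", ")
  ))
  invisible(x)
}

# flatten a readTIFF(all = TRUE) result into a list of grayscale planes
tiff_planes <- function(pages) {
  planes <- list()
  for (p in pages) {
    if (is.matrix(p)) {
      planes[[length(planes) + 1L]] <- p
    } else if (length(dim(p)) == 3L) {
      for (k in seq_len(dim(p)[3])) {
        planes[[length(planes) + 1L]] <- p[, , k]
      }
    } else {
      abort("unsupported TIFF plane layout", class = "svpuncta_format_error")
    }
  }
  planes
}

#' Read a multi-channel field image
#'
#' Reads a multi-page or RGB TIFF into a [channel_stack()]. Channel roles
#' are assigned by the explicit `channel_map`, never guessed from color
#' order. Intensities are normalized by the file's bit-depth maximum
#' (255 or 65535), so fixed thresholds are comparable across fields.
#'
#' @param path TIFF file; 8- or 16-bit, multi-page grayscale or RGB.
#' @param channel_map named integer vector mapping channel roles to plane
#'   indices (1-based), e.g. `c(neuron = 1, partner = 2, marker = 3)`.
#'   An RGB file contributes planes 1 (red), 2 (green), 3 (blue).
#' @param pixel_size micrometres per pixel.
#' @param field_id field identifier; default, file name without extension.
#' @param magnification_tag stored verbatim.
#' @return a [channel_stack()].
#' @export
read_stack <- function(path, channel_map, pixel_size,
                       field_id = NULL, magnification_tag = "20x") {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "svpuncta_io_error")
  }
  if (is.null(names(channel_map)) || any(!nzchar(names(channel_map)))) {
    abort("`channel_map` must be a named vector of plane indices.")
  }
  roles <- names(channel_map)
  if (!(all(c("neuron", "partner", "marker") %in% roles) ||
        all(c("neuron", "pre", "post") %in% roles))) {
    abort("`channel_map` must cover roles neuron/partner/marker (co-culture) or neuron/pre/post (synapse).")
  }
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE),
    error = function(e) {
      abort(sprintf("cannot read TIFF '%s': %s", path, conditionMessage(e)),
            class = "svpuncta_format_error")
    }
  )
  planes <- tiff_planes(pages)
  if (length(planes) < max(channel_map)) {
    abort(sprintf("TIFF has %d plane(s); channel_map requires index %d",
                  length(planes), max(channel_map)),
          class = "svpuncta_format_error")
  }
  if (length(unique(lapply(planes, dim))) > 1L) {
    abort("TIFF planes have mismatched dimensions",
          class = "svpuncta_format_error")
  }
  images <- lapply(seq_along(channel_map), function(i) planes[[channel_map[[i]]]])
  names(images) <- roles
  channel_stack(
    images,
    pixel_size = pixel_size,
    field_id = field_id %||% tools::file_path_sans_ext(basename(path)),
    magnification_tag = magnification_tag
  )
}

#' Write a channel stack as a multi-page TIFF
#'
#' Inverse of [read_stack()] for package-generated (synthetic) fields: each
#' channel becomes one grayscale page, in the order of `roles`.
#'
#' @param stack a [channel_stack()].
#' @param path output file.
#' @param roles channel order in the file; default, the stack's own order.
#' @param bits 8 or 16 bits per sample.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, roles = names(stack$images), bits = 16L) {
  stopifnot(inherits(stack, "channel_stack"), bits %in% c(8L, 16L))
  pages <- lapply(roles, function(r) {
    img <- stack$images[[r]]
    if (is.null(img)) abort(sprintf("stack lacks channel role '%s'", r))
    # quantize to the target bit depth so the file round-trips exactly
    mx <- 2^bits - 1
    round(img * mx) / mx
  })
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits))
  invisible(path)
}
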
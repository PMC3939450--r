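#' Binary masks
#'
#' A `binary_mask` is a 2-D logical grid carrying two provenance attributes:
#' the `role` of the mask in the pipeline (`"neuron_raw"`,
#' `"neuron_processes"`, `"partner"`, `"partner_dilated"`, `"marker"`, or
#' a free-form label) and the `source_threshold` used to binarize it (`NA`
#' when not produced by thresholding). All mask-consuming functions in the
#' package also accept plain logical matrices.
#'
#' @param grid logical matrix (or coercible numeric matrix; non-zero is
#'   foreground).
#' @param role character scalar describing the processing step.
#' @param source_threshold numeric scalar in \[0,1\] or `NA`.
#' @return a `binary_mask` object (logical matrix subclass).
#' @export
binary_mask <- function(grid, role = NA_character_, source_threshold = NA_real_) {
  if (!is.matrix(grid)) abort("`grid` must be a matrix.")
  g <- matrix(as.logical(grid), nrow(grid), ncol(grid))
  if (anyNA(g)) abort("`grid` must not contain NA.")
  structure(g,
    role = as.character(role)[1],
    source_threshold = as.numeric(source_threshold)[1],
    class = c("binary_mask", class(g))
  )
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf(
    "<binary_mask> %dx%d  role: %s  threshold: %s  foreground: %d px\n",
    nrow(x), ncol(x), attr(x, "role"),
    format(attr(x, "source_threshold"), digits = 4), sum(x)
  ))
  invisible(x)
}

# strip to a bare logical matrix
mask_grid <- function(x) {
  if (!is.matrix(x)) abort("expected a matrix mask")
  matrix(as.logical(x), nrow(x), ncol(x))
}

mask_role <- function(x) attr(x, "role") %||% NA_character_

`%||%` <- function(a, b) if (is.null(a)) b else a

check_connectivity <- function(connectivity) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) abort("`connectivity` must be 4 or 8.")
  connectivity
}

check_same_dim <- function(..., what = "inputs") {
  dims <- lapply(list(...), dim)
  if (length(unique(lapply(dims, function(d) d[1:2]))) > 1L) {
    abort(sprintf("dimension mismatch: %s must share height x width", what),
          class = "svpuncta_dim_error")
  }
  invisible(TRUE)
}

# integer offsets (drow, dcol) of the Euclidean disk of radius r:
# pixel centers at distance <= r from the origin
disk_offsets <- function(radius) {
  rr <- floor(radius)
  d <- seq.int(-rr, rr)
  g <- expand.grid(dr = d, dc = d)
  keep <- g$dr^2 + g$dc^2 <= radius^2 + 1e-9
  as.matrix(g[keep, , drop = FALSE])
}

# matrix shifted by (dr, dc); vacated cells FALSE
shift_logical <- function(g, dr, dc) {
  h <- nrow(g); w <- ncol(g)
  out <- matrix(FALSE, h, w)
  rs <- max(1, 1 + dr):min(h, h + dr)
  cs <- max(1, 1 + dc):min(w, w + dc)
  if (length(rs) && length(cs)) {
    out[rs, cs] <- g[rs - dr, cs - dc, drop = FALSE]
  }
  out
}

#' Label connected foreground components
#'
#' Connected-component labeling of a binary mask with 4- or 8-connectivity.
#' Labels are assigned 1..N in raster-scan order (top-to-bottom,
#' left-to-right) of each component's first pixel, so the labeling is
#' deterministic and platform-independent.
#'
#' @param mask binary mask or logical matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix; 0 is background, components are 1..N.
#' @export
label_components <- function(mask, connectivity = 8L) {
  g <- mask_grid(mask)
  connectivity <- check_connectivity(connectivity)
  h <- nrow(g); w <- ncol(g)
  lab <- matrix(0L, h, w)
  idx <- which(g)
  n <- length(idx)
  if (n == 0L) return(lab)
  ord <- integer(h * w)
  ord[idx] <- seq_len(n)
  r <- ((idx - 1L) %% h) + 1L
  cc <- ((idx - 1L) %/% h) + 1L
  # each undirected neighbor pair is generated once
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  edges <- vector("list", length(offs))
  for (k in seq_along(offs)) {
    rr <- r + offs[[k]][1L]
    cw <- cc + offs[[k]][2L]
    ok <- rr >= 1L & rr <= h & cw >= 1L & cw <= w
    nb <- ord[(cw[ok] - 1L) * h + rr[ok]]
    keep <- nb > 0L
    edges[[k]] <- rbind(ord[idx[ok]][keep], nb[keep])
  }
  em <- do.call(cbind, edges)
  gph <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(em)) gph <- igraph::add_edges(gph, as.vector(em))
  memb <- as.integer(igraph::components(gph)$membership)
  key <- (r - 1L) * w + cc
  first <- vapply(split(key, memb), min, integer(1))
  rank <- integer(length(first))
  rank[order(first)] <- seq_along(first)
  lab[idx] <- rank[memb]
  lab
}

# 4-connected object perimeter (image border counts as outside)
mask_perimeter <- function(mask) {
  g <- mask_grid(mask)
  interior <- shift_logical(g, 1, 0) & shift_logical(g, -1, 0) &
    shift_logical(g, 0, 1) & shift_logical(g, 0, -1)
  g & !interior
}
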
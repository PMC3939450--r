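# Brute-force pixel-set oracles: every operation is restated here from its
# set-theoretic definition (explicit distance predicates, flood fill),
# independently of the package's implementation route.

ORACLE_EPS <- 1e-9

# flood-fill labeling; labels assigned in raster-scan (row-major) order
brute_label <- function(g, connectivity = 8) {
  h <- nrow(g); w <- ncol(g)
  offs <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8) {
    offs <- rbind(offs, c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  }
  lab <- matrix(0L, h, w)
  cur <- 0L
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (g[r, c] && lab[r, c] == 0L) {
      cur <- cur + 1L
      queue <- list(c(r, c))
      lab[r, c] <- cur
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (k in seq_len(nrow(offs))) {
          rr <- p[1] + offs[k, 1]; cc <- p[2] + offs[k, 2]
          if (rr >= 1 && rr <= h && cc >= 1 && cc <= w &&
              g[rr, cc] && lab[rr, cc] == 0L) {
            lab[rr, cc] <- cur
            queue[[length(queue) + 1]] <- c(rr, cc)
          }
        }
      }
    }
  }
  lab
}

brute_area_open <- function(g, min_area, connectivity = 8) {
  lab <- brute_label(g, connectivity)
  if (max(lab) == 0L || min_area <= 1) return(g)
  sizes <- tabulate(lab[lab > 0L])
  keep <- matrix(FALSE, nrow(g), ncol(g))
  keep[lab > 0L] <- sizes[lab[lab > 0L]] >= min_area
  keep
}

# dilation: p is foreground iff some in-bounds foreground pixel lies within
# Euclidean distance r of p
brute_dilate <- function(g, r) {
  if (r <= 0 || !any(g)) return(g)
  fg <- which(g, arr.ind = TRUE)
  out <- matrix(FALSE, nrow(g), ncol(g))
  for (rr in seq_len(nrow(g))) for (cc in seq_len(ncol(g))) {
    d2 <- (fg[, 1] - rr)^2 + (fg[, 2] - cc)^2
    out[rr, cc] <- any(d2 <= r^2 + ORACLE_EPS)
  }
  out
}

# erosion: p stays foreground iff no in-bounds background pixel lies within
# distance r (pixels beyond the border count as foreground)
brute_erode <- function(g, r) {
  if (r <= 0 || all(g)) return(g)
  bg <- which(!g, arr.ind = TRUE)
  out <- matrix(FALSE, nrow(g), ncol(g))
  fg <- which(g, arr.ind = TRUE)
  for (k in seq_len(nrow(fg))) {
    d2 <- (bg[, 1] - fg[k, 1])^2 + (bg[, 2] - fg[k, 2])^2
    out[fg[k, 1], fg[k, 2]] <- all(d2 > r^2 + ORACLE_EPS)
  }
  out
}

brute_open <- function(g, r) brute_dilate(brute_erode(g, r), r)

brute_remove_cell_bodies <- function(g, r) g & !brute_open(g, r)

brute_overlaps <- function(g1, g2, min_overlap_area, connectivity = 8) {
  both <- g1 & g2
  lab <- brute_label(both, connectivity)
  n <- max(lab)
  if (n == 0L) return(lab)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_overlap_area)
  out <- matrix(0L, nrow(lab), ncol(lab))
  for (i in seq_along(keep)) out[lab == keep[i]] <- i
  out
}

brute_sv_features <- function(labeled, sv, marker, connectivity = 8) {
  n <- max(labeled)
  sv_lab <- brute_label(sv, connectivity)
  out <- NULL
  for (r in seq_len(n)) {
    inr <- labeled == r
    svr <- inr & sv
    area <- sum(inr)
    sv_area <- sum(svr)
    out <- rbind(out, data.frame(
      region_label = r,
      region_area_px = area,
      sv_cluster_count = length(setdiff(unique(sv_lab[svr]), 0L)),
      sv_area_px = sv_area,
      sv_mean_intensity = if (sv_area > 0) mean(marker[svr]) else NA_real_,
      sv_density = sv_area / area,
      has_cluster = sv_area > 0
    ))
  }
  out
}

# random test mask with blob-and-speckle structure
random_mask <- function(h = 32, w = 32, p = 0.25) {
  g <- matrix(runif(h * w) < p, h, w)
  nb <- sample(0:3, 1)
  for (i in seq_len(nb)) {
    r0 <- sample(h, 1); c0 <- sample(w, 1); rad <- runif(1, 2, 6)
    for (rr in seq_len(h)) for (cc in seq_len(w)) {
      if ((rr - r0)^2 + (cc - c0)^2 <= rad^2) g[rr, cc] <- TRUE
    }
  }
  g
}

as_grid <- function(m) matrix(as.logical(m), nrow(m), ncol(m))

expect_same_mask <- function(actual, expected) {
  expect_identical(as_grid(actual), as_grid(expected))
}

rot90 <- function(m) t(m)[ncol(m):1, , drop = FALSE]

# integer translation with zero padding
translate <- function(m, dr, dc) {
  out <- matrix(if (is.logical(m[1])) FALSE else 0, nrow(m), ncol(m))
  rs <- max(1, 1 + dr):min(nrow(m), nrow(m) + dr)
  cs <- max(1, 1 + dc):min(ncol(m), ncol(m) + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}
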
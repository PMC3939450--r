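test_that("read_stack normalizes by bit depth and maps channels explicitly", {
  tmp <- withr::local_tempfile(fileext = ".tif")
  pages <- list(matrix(0, 8, 8), matrix(128 / 255, 8, 8), matrix(1, 8, 8))
  tiff::writeTIFF(pages, tmp, bits.per.sample = 8L)
  st <- read_stack(tmp, c(neuron = 1, partner = 2, marker = 3), pixel_size = 0.31)
  expect_equal(unique(as.numeric(st$images$neuron)), 0)
  expect_equal(unique(as.numeric(st$images$partner)), 128 / 255)
  expect_equal(unique(as.numeric(st$images$marker)), 1)
  expect_identical(st$dim, c(8L, 8L))
})

test_that("RGB planes are permuted by the channel map, not by color order", {
  tmp <- withr::local_tempfile(fileext = ".tif")
  arr <- array(0, dim = c(6, 6, 3))
  arr[, , 1] <- 30 / 255   # red = partner
  arr[, , 2] <- 60 / 255   # green = neuron
  arr[, , 3] <- 90 / 255   # blue = marker
  tiff::writeTIFF(arr, tmp, bits.per.sample = 8L)
  st <- read_stack(tmp, c(neuron = 2, partner = 1, marker = 3), pixel_size = 1)
  expect_equal(unique(as.numeric(st$images$neuron)), 60 / 255)
  expect_equal(unique(as.numeric(st$images$partner)), 30 / 255)
  expect_equal(unique(as.numeric(st$images$marker)), 90 / 255)
})

test_that("16-bit images normalize to exactly 1 at the dtype maximum", {
  tmp <- withr::local_tempfile(fileext = ".tif")
  img <- matrix(c(0, 0.25, 0.5, 1), 2, 2)
  tiff::writeTIFF(list(img, img, img), tmp, bits.per.sample = 16L)
  st <- read_stack(tmp, c(neuron = 1, partner = 2, marker = 3), pixel_size = 1)
  expect_identical(max(st$images$neuron), 1)
})

test_that("loading is lossless up to the bit-depth normalization", {
  tmp <- withr::local_tempfile(fileext = ".tif")
  set.seed(9)
  ints <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
  tiff::writeTIFF(list(ints / 255, ints / 255, ints / 255), tmp,
                  bits.per.sample = 8L)
  st <- read_stack(tmp, c(neuron = 1, partner = 2, marker = 3), pixel_size = 1)
  expect_identical(round(st$images$neuron * 255), ints * 1)
})

test_that("read_stack raises typed errors on bad inputs", {
  expect_error(read_stack(file.path(tempdir(), "absent.tif"),
                          c(neuron = 1, partner = 2, marker = 3), 1),
               class = "svpuncta_io_error")
  tmp <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(list(matrix(0.5, 4, 4)), tmp, bits.per.sample = 8L)
  expect_error(read_stack(tmp, c(neuron = 1, partner = 2, marker = 3), 1),
               class = "svpuncta_format_error")
  expect_error(read_stack(tmp, c(neuron = 1, partner = 1), 1),
               regexp = "channel_map")
})

test_that("write_stack / read_stack round-trips generated fields", {
  gen <- generate_cocult_field(scene_spec(image_size = c(64L, 64L),
                                          n_neurites = 6L, n_partner_cells = 2L,
                                          partner_radius_range = c(6, 9),
                                          n_cell_bodies = 0L, seed = 4L))
  tmp <- withr::local_tempfile(fileext = ".tif")
  write_stack(gen$stack, tmp, roles = c("neuron", "partner", "marker"))
  back <- read_stack(tmp, c(neuron = 1, partner = 2, marker = 3),
                     pixel_size = gen$stack$pixel_size)
  expect_lt(max(abs(back$images$marker - gen$stack$images$marker)), 1 / 65535)
})

test_that("export_table writes the fixed dialect and round-trips", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  empty <- tibble::tibble(
    field_id = character(), region_label = integer(),
    region_area_px = integer(), region_area_um2 = double(),
    sv_cluster_count = integer(), sv_area_px = integer(),
    sv_mean_intensity = double(), sv_density = double(),
    has_cluster = logical()
  )
  export_table(empty, tmp)
  lines <- readLines(tmp)
  expect_identical(length(lines), 1L)
  expect_identical(
    lines,
    "field_id,region_label,region_area_px,region_area_um2,sv_cluster_count,sv_area_px,sv_mean_intensity,sv_density,has_cluster"
  )

  one <- tibble::tibble(
    field_id = "f1", region_label = 1L, region_area_px = 100L,
    region_area_um2 = 100 * 0.31^2, sv_cluster_count = 1L, sv_area_px = 20L,
    sv_mean_intensity = 0.6, sv_density = 20 / 100, has_cluster = TRUE
  )
  export_table(one, tmp)
  expect_equal(parse_result_table(tmp)$sv_density, 0.2)

  set.seed(77)
  many <- tibble::tibble(
    field_id = sprintf("f%d", sample(9, 50, TRUE)),
    region_label = 1:50,
    region_area_px = sample.int(500, 50),
    region_area_um2 = runif(50, 1, 50),
    sv_cluster_count = sample(0:5, 50, TRUE),
    sv_area_px = sample.int(50, 50),
    sv_mean_intensity = runif(50),
    sv_density = runif(50),
    has_cluster = sample(c(TRUE, FALSE), 50, TRUE)
  )
  export_table(many, tmp)
  back <- parse_result_table(tmp)
  for (col in c("region_area_um2", "sv_mean_intensity", "sv_density")) {
    expect_equal(back[[col]], signif(many[[col]], 6))
  }
  expect_identical(back$region_area_px, many$region_area_px)
  expect_identical(back$has_cluster, many$has_cluster)
})

test_that("overlay renderings color regions, SV pixels and nothing else", {
  lab <- matrix(0L, 12, 12)
  lab[2:5, 2:5] <- 1L
  lab[8:11, 8:11] <- 2L
  attr(lab, "n_regions") <- 2L
  sv0 <- matrix(FALSE, 12, 12)
  arr <- render_overlay(lab, sv0)
  cols <- unique(apply(matrix(arr, ncol = 3)[which(lab > 0), ], 1, paste, collapse = ","))
  expect_identical(length(cols), 2L)
  expect_false(any(arr[, , 1] == 0 & arr[, , 2] == 0 & arr[, , 3] == 0))

  # empty label map renders plain background
  lab0 <- matrix(0L, 12, 12); attr(lab0, "n_regions") <- 0L
  expect_true(all(render_overlay(lab0, sv0) == 1))

  # SV intersecting region 2 only: black pixels confined to region 2
  lab3 <- lab; lab3[2:5, 8:11] <- 3L
  attr(lab3, "n_regions") <- 3L
  sv <- matrix(FALSE, 12, 12); sv[9:10, 9:10] <- TRUE
  arr3 <- render_overlay(lab3, sv)
  black <- arr3[, , 1] == 0 & arr3[, , 2] == 0 & arr3[, , 3] == 0
  expect_identical(which(black), which(sv & lab3 == 2L))

  # rendering is pure: inputs unchanged
  lab_before <- lab3 + 0L; sv_before <- sv | FALSE
  invisible(render_overlay(lab3, sv))
  expect_identical(lab3 + 0L, lab_before)
  expect_identical(sv | FALSE, sv_before)

  expect_error(render_overlay(lab, matrix(FALSE, 5, 5)),
               class = "svpuncta_dim_error")
})

test_that("overlay files are written for both supported formats", {
  lab <- matrix(0L, 6, 6); lab[2:4, 2:4] <- 1L
  attr(lab, "n_regions") <- 1L
  sv <- matrix(FALSE, 6, 6)
  p1 <- withr::local_tempfile(fileext = ".png")
  p2 <- withr::local_tempfile(fileext = ".tif")
  write_overlay(lab, sv, p1)
  write_overlay(lab, sv, p2, partner_mask = lab > 0)
  expect_true(file.exists(p1) && file.exists(p2))
  expect_equal(dim(png::readPNG(p1)), c(6, 6, 3))
})
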
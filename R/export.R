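result_table_cols <- c(
  "field_id", "region_label", "region_area_px", "region_area_um2",
  "sv_cluster_count", "sv_area_px", "sv_mean_intensity", "sv_density",
  "has_cluster"
)

#' Export a per-region result table to CSV
#'
#' Writes the per-region feature table with a fixed header, one row per
#' retained overlap region, floats at 6 significant digits, UTF-8 and LF
#' line endings — a spreadsheet-compatible hand-off for downstream
#' statistics.
#'
#' @param rows tibble with the columns of [analyze_cocult()]'s `regions`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_table <- function(rows, path) {
  missing_cols <- setdiff(result_table_cols, names(rows))
  if (length(missing_cols)) {
    abort(sprintf("result table lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  out <- rows[result_table_cols]
  out$region_area_um2 <- signif(out$region_area_um2, 6)
  out$sv_mean_intensity <- signif(out$sv_mean_intensity, 6)
  out$sv_density <- signif(out$sv_density, 6)
  tryCatch(
    readr::write_csv(out, path, na = "NA", progress = FALSE),
    error = function(e) {
      abort(sprintf("cannot write '%s': %s", path, conditionMessage(e)),
            class = "svpuncta_io_error")
    }
  )
  invisible(path)
}

#' @rdname export_table
#' @export
parse_result_table <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      field_id = readr::col_character(),
      region_label = readr::col_integer(),
      region_area_px = readr::col_integer(),
      region_area_um2 = readr::col_double(),
      sv_cluster_count = readr::col_integer(),
      sv_area_px = readr::col_integer(),
      sv_mean_intensity = readr::col_double(),
      sv_density = readr::col_double(),
      has_cluster = readr::col_logical()
    ),
    progress = FALSE
  )
}

export_summary <- function(summaries, path) {
  out <- summaries
  for (col in c("frequency", "density_mean", "density_pooled")) {
    if (col %in% names(out)) out[[col]] <- signif(out[[col]], 6)
  }
  readr::write_csv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}
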
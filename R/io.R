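measurement_cols <- c(
  "case_id", "a_mm", "b_mm", "c_mm",
  "z_cranial", "z_caudal", "z_basal", "z_vertex"
)

check_measurements <- function(data) {
  missing_cols <- setdiff(measurement_cols, names(data))
  if (length(missing_cols)) {
    stop(
      "measurement table lacks column(s): ",
      paste(missing_cols, collapse = ", ")
    )
  }
  bad <- which(data$z_vertex <= data$z_basal)
  if (length(bad)) {
    stop("z_vertex must exceed z_basal; violated in row(s) ", paste(bad, collapse = ", "))
  }
  bad <- which(data$z_cranial < data$z_caudal)
  if (length(bad)) {
    stop("z_cranial must be >= z_caudal; violated in row(s) ", paste(bad, collapse = ", "))
  }
  bad <- which(!(data$a_mm >= data$b_mm & data$b_mm > 0))
  if (length(bad)) {
    stop(
      "radii must satisfy a_mm >= b_mm > 0 (the length is the largest diameter); ",
      "violated in row(s) ", paste(bad, collapse = ", ")
    )
  }
  invisible(data)
}

#' Read or write a per-case measurement table
#'
#' The on-disk schema is one row per case with columns `case_id`, `a_mm`,
#' `b_mm`, `c_mm` (the three manually measured hematoma radii: half of the
#' length, thickness and cranial-caudal diameters) and the axial landmark
#' coordinates `z_cranial`, `z_caudal`, `z_basal`, `z_vertex`, all in mm.
#' CSV and JSON (array of records) mirrors of the same schema are supported,
#' chosen by file extension.
#'
#' @param path File path ending in `.csv` or `.json`.
#' @return `read_measurements()`: a validated tibble.
#' @export
read_measurements <- function(path) {
  data <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    tibble::as_tibble(jsonlite::fromJSON(path))
  } else {
    readr::read_csv(path, show_col_types = FALSE)
  }
  check_measurements(data)
  data
}

#' @rdname read_measurements
#' @param data A measurement table.
#' @return `write_measurements()`: `path`, invisibly.
#' @export
write_measurements <- function(data, path) {
  check_measurements(data)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(data, path, digits = NA, pretty = TRUE)
  } else {
    readr::write_csv(data, path)
  }
  invisible(path)
}
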
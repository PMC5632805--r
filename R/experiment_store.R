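# Tabular persistence of measurements and the multidimensional experiment
# structure (time x treatment x plate), plus platform capacity arithmetic.

#' Parse a platform image filename
#'
#' Filenames follow `<YYYYMMDD>T<HHMMSS>_x<int>_y<int>.png`, encoding the
#' acquisition time and the (x, y) camera coordinates.
#'
#' @param name Filename (no directory part required).
#' @return List with `acquisition_time` (POSIXct, UTC) and `camera_xy`
#'   (integer pair).
#' @seealso [format_filename()] for the exact inverse.
#' @examples
#' parse_filename("20170615T120000_x0123_y0456.png")
#' @export
parse_filename <- function(name) {
  m <- regmatches(name,
    regexec("^([0-9]{8})T([0-9]{6})_x([0-9]+)_y([0-9]+)\\.png$", name))[[1]]
  if (length(m) != 5) {
    part <- if (!grepl("^[0-9]{8}T[0-9]{6}", name)) "acquisition time"
            else "camera coordinates"
    stop(sprintf("malformed image filename '%s': cannot parse %s", name, part))
  }
  tm <- as.POSIXct(paste0(m[2], m[3]), format = "%Y%m%d%H%M%S", tz = "UTC")
  if (is.na(tm)) stop(sprintf(
    "malformed image filename '%s': invalid acquisition time", name))
  list(acquisition_time = tm,
       camera_xy = c(as.integer(m[4]), as.integer(m[5])))
}

#' Format a platform image filename
#' @param acquisition_time POSIXct (interpreted in UTC).
#' @param camera_xy Integer (x, y) camera coordinates.
#' @return Filename string.
#' @export
format_filename <- function(acquisition_time, camera_xy) {
  sprintf("%s_x%04d_y%04d.png",
    format(acquisition_time, "%Y%m%dT%H%M%S", tz = "UTC"),
    camera_xy[1], camera_xy[2])
}

#' Export a measurement table
#'
#' One row per image with columns exactly `filename, date, x, y,
#' area_1..area_n` (wells column-wise), written as CSV — the plain-text
#' twin of the platform's spreadsheet output. Re-import with
#' [import_table()] is lossless for integer areas.
#'
#' @param rows Measurement table from [analyze_directory()] (a `valid`
#'   column, if present, is dropped from the file) or any data frame with
#'   the schema columns.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
export_table <- function(rows, path) {
  area_cols <- grep("^area_[0-9]+$", names(rows), value = TRUE)
  if (!length(area_cols) && nrow(rows) > 0)
    stop("no area_<i> columns to export")
  need <- c("filename", "date", "x", "y")
  if (!all(need %in% names(rows)))
    stop("measurement table must have columns filename, date, x, y")
  n_areas <- length(area_cols)
  if (nrow(rows) > 0 && any(!stats::complete.cases(rows[area_cols])))
    stop("plate formats are mixed within one table")
  out <- rows[c(need, paste0("area_", seq_len(n_areas)))]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Import a measurement table written by [export_table()]
#' @param path CSV path.
#' @return Data frame with the exported schema.
#' @export
import_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(filename = "character", date = "character"))
}

#' Assemble experiment records from measurements and a design
#'
#' Joins each measurement row to its plate via the camera (x, y) table
#' position, and converts acquisition times to fractional days from the
#' earliest acquisition. One record per input row, preserving the
#' measurement table's multi-dimensional structure: time, treatment (label
#' and numeric code), plate type, table position and the green-area list.
#'
#' @param rows Measurement table ([analyze_directory()] / [import_table()]).
#' @param design An [experiment_design].
#' @return Data frame with columns `filename`, `time_from_start` (days),
#'   `treatment`, `code`, `plate_type`, `pos_x`, `pos_y`, `plate_id`, then
#'   `area_1..area_n`.
#' @export
build_experiment <- function(rows, design) {
  stopifnot(nrow(rows) >= 1)
  key <- paste(rows$x, rows$y)
  dkey <- paste(design$pos_x, design$pos_y)
  hit <- match(key, dkey)
  if (anyNA(hit))
    stop("camera position not in design for: ",
         toString(utils::head(rows$filename[is.na(hit)], 3)))
  tm <- as.POSIXct(rows$date, tz = "UTC")
  t0 <- min(tm)
  area_cols <- grep("^area_[0-9]+$", names(rows), value = TRUE)
  rec <- data.frame(
    filename = rows$filename,
    time_from_start = as.numeric(difftime(tm, t0, units = "days")),
    treatment = design$treatment[hit],
    code = design$code[hit],
    plate_type = design$format[hit],
    pos_x = design$pos_x[hit], pos_y = design$pos_y[hit],
    plate_id = design$plate_id[hit],
    rows[area_cols],
    stringsAsFactors = FALSE)
  rec[order(rec$plate_id, rec$time_from_start), , drop = FALSE]
}

#' Reshape experiment records to per-plant growth series
#'
#' @param records Output of [build_experiment()].
#' @return Long data frame with columns `plant` (plate:well), `treatment`,
#'   `plate_id`, `well`, `time`, `area` — the input to the growth and
#'   survival statistics.
#' @export
records_to_long <- function(records) {
  area_cols <- grep("^area_[0-9]+$", names(records), value = TRUE)
  n <- length(area_cols)
  long <- do.call(rbind, lapply(seq_len(n), function(w) {
    data.frame(
      plant = paste0(records$plate_id, ":w", w),
      treatment = records$treatment,
      plate_id = records$plate_id, well = w,
      time = records$time_from_start,
      area = records[[paste0("area_", w)]],
      stringsAsFactors = FALSE)
  }))
  long[order(long$plant, long$time), , drop = FALSE]
}

#' Platform capacity arithmetic
#'
#' How many plants and experimental variants one platform run can hold:
#' `total_plants = platform_plates * wells_per_plate` (one plant per well)
#' and `n_variants = floor(platform_plates / replicates_per_variant)`.
#'
#' @param format Plate format name.
#' @param platform_plates Plates the platform holds (default 480).
#' @param replicates_per_variant Plates per variant.
#' @return List with `total_plants` and `n_variants`.
#' @examples
#' capacity_plan("24-well", 480, 1)  # 11520 plants, 480 variants
#' @export
capacity_plan <- function(format, platform_plates = 480,
                          replicates_per_variant = 1) {
  stopifnot(platform_plates >= 0, replicates_per_variant >= 1)
  lay <- plate_layout(format)
  list(total_plants = platform_plates * lay$wells_per_plate,
       n_variants = platform_plates %/% replicates_per_variant)
}
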
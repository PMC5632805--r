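#' Geometry of a standard multi-well culture plate
#'
#' Builds the plate geometry used throughout the pipeline: grid shape, well
#' centres and radius in plate coordinates, and the positions of the blue
#' boundary (fiducial) marks on the tray. Plate coordinates are millimetres
#' with the origin at the top-left plate corner, x to the right, y downwards.
#'
#' Physical dimensions follow the ANSI/SLAS microplate footprint
#' (127.76 x 85.48 mm) with the well grid centred on the plate. The fiducial
#' marks sit just outside the plate rectangle; the first (top-left) mark is
#' shifted along the top edge so the mark quadrilateral is asymmetric and the
#' plate orientation is recoverable from the marks alone.
#'
#' @param format One of `"6-well"`, `"12-well"`, `"24-well"`.
#' @param mark_offset Outset of the boundary marks from the plate corners, mm.
#' @param key_shift Extra shift of the first mark along the top edge, mm.
#'   Breaks the 180-degree symmetry of the mark set.
#' @return An object of class `plate_layout`: a list with `format_name`,
#'   `n_rows`, `n_cols`, `wells_per_plate`, `plate_width`, `plate_height`,
#'   `well_radius`, `pitch`, `a1_center` and `mark_positions` (4 x 2 matrix,
#'   ordered top-left, top-right, bottom-right, bottom-left).
#' @examples
#' lay <- plate_layout("24-well")
#' lay$wells_per_plate
#' @export
plate_layout <- function(format = c("24-well", "12-well", "6-well"),
                         mark_offset = 6, key_shift = 22) {
  format <- match.arg(format)
  geom <- switch(format,
    "24-well" = list(n_rows = 4L, n_cols = 6L, radius = 7.8,  pitch = 19.30),
    "12-well" = list(n_rows = 3L, n_cols = 4L, radius = 11.0, pitch = 26.01),
    "6-well"  = list(n_rows = 2L, n_cols = 3L, radius = 17.4, pitch = 39.12)
  )
  pw <- 127.76
  ph <- 85.48
  a1 <- c(
    (pw - (geom$n_cols - 1L) * geom$pitch) / 2,
    (ph - (geom$n_rows - 1L) * geom$pitch) / 2
  )
  o <- mark_offset
  marks <- rbind(
    c(-o + key_shift, -o),
    c(pw + o, -o),
    c(pw + o, ph + o),
    c(-o, ph + o)
  )
  structure(list(
    format_name = format,
    n_rows = geom$n_rows, n_cols = geom$n_cols,
    wells_per_plate = geom$n_rows * geom$n_cols,
    plate_width = pw, plate_height = ph,
    well_radius = geom$radius, pitch = geom$pitch,
    a1_center = a1, mark_positions = marks
  ), class = "plate_layout")
}

#' Read a plate layout from a YAML configuration file
#'
#' The file may give `format` alone (one of the built-in layouts) and override
#' any scalar geometry field (`well_radius`, `pitch`, `mark_offset`,
#' `key_shift`, `plate_width`, `plate_height`). A commented example ships in
#' `system.file("extdata", "plate-layouts.yaml", package = "phenowell")`.
#'
#' @param path Path to a YAML file.
#' @return A [plate_layout] object.
#' @export
read_plate_layout <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$format))
    stop("layout config must name a plate 'format'")
  lay <- plate_layout(cfg$format,
    mark_offset = cfg$mark_offset %||% 6,
    key_shift = cfg$key_shift %||% 22)
  for (f in c("well_radius", "pitch", "plate_width", "plate_height"))
    if (!is.null(cfg[[f]])) lay[[f]] <- cfg[[f]]
  lay
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.plate_layout <- function(x, ...) {
  cat(sprintf("<plate_layout> %s: %d x %d grid, well radius %.1f mm, pitch %.2f mm\n",
    x$format_name, x$n_rows, x$n_cols, x$well_radius, x$pitch))
  invisible(x)
}

#' Column-wise linear well index
#'
#' Wells are numbered column-wise starting at the top-left well: down the
#' first column, then down the second, and so on.
#'
#' @param row,col 1-based grid position.
#' @param layout A [plate_layout].
#' @return Integer linear index in `1:wells_per_plate`.
#' @seealso [well_rowcol()] for the inverse.
#' @export
well_index <- function(row, col, layout) {
  if (any(row < 1L | row > layout$n_rows) || any(col < 1L | col > layout$n_cols))
    stop(sprintf("well (%s, %s) outside %d x %d grid",
      toString(row), toString(col), layout$n_rows, layout$n_cols))
  as.integer((col - 1L) * layout$n_rows + row)
}

#' Grid position of a linear well index
#' @param index Linear (column-wise) well index.
#' @param layout A [plate_layout].
#' @return List with elements `row` and `col`.
#' @export
well_rowcol <- function(index, layout) {
  if (any(index < 1L | index > layout$wells_per_plate))
    stop("well index out of range")
  idx <- as.integer(index) - 1L
  list(row = idx %% layout$n_rows + 1L, col = idx %/% layout$n_rows + 1L)
}

#' Well centres in plate coordinates, column-wise order
#' @param layout A [plate_layout].
#' @return A `wells_per_plate` x 2 matrix of (x, y) centres in mm, row `i`
#'   being the well with linear index `i`.
#' @export
well_centers <- function(layout) {
  idx <- seq_len(layout$wells_per_plate)
  rc <- well_rowcol(idx, layout)
  cbind(
    x = layout$a1_center[1] + (rc$col - 1L) * layout$pitch,
    y = layout$a1_center[2] + (rc$row - 1L) * layout$pitch
  )
}

#' Lay out an experiment design over the imaging platform
#'
#' Assigns one plate per replicate of each treatment, a numeric treatment
#' code, and an (x, y) table position used as the camera coordinate in image
#' filenames.
#'
#' @param treatments Character vector of treatment (variant) labels.
#' @param replicates Plates per treatment.
#' @param format Plate format for every plate (one design = one format).
#' @param codes Optional numeric codes, one per treatment; defaults to the
#'   rank of the sorted labels.
#' @return An object of class `experiment_design`: a data frame with columns
#'   `plate_id`, `treatment`, `code`, `format`, `pos_x`, `pos_y`.
#' @examples
#' experiment_design(c("control", "NaCl150"), replicates = 3)
#' @export
experiment_design <- function(treatments, replicates,
                              format = "24-well", codes = NULL) {
  stopifnot(replicates >= 1, length(treatments) >= 1)
  if (anyDuplicated(treatments)) stop("treatment labels must be unique")
  if (is.null(codes)) codes <- rank(treatments)
  if (anyDuplicated(codes)) stop("treatment codes must be unique")
  n <- length(treatments) * replicates
  i <- seq_len(n)
  structure(data.frame(
    plate_id = sprintf("P%02d", i),
    treatment = rep(treatments, each = replicates),
    code = rep(codes, each = replicates),
    format = format,
    pos_x = ((i - 1L) %% 24L + 1L) * 150L,
    pos_y = ((i - 1L) %/% 24L + 1L) * 100L,
    stringsAsFactors = FALSE
  ), class = c("experiment_design", "data.frame"))
}

#' Total number of plants in a design
#' @param design An [experiment_design].
#' @return Integer: plates times wells per plate (one plant per well).
#' @export
design_plant_count <- function(design) {
  sum(vapply(design$format,
    function(f) plate_layout(f)$wells_per_plate, integer(1)))
}
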
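# Per-image analysis: distortion correction, fiducial registration with
# ranked candidate transforms, HSV green segmentation, outside-well
# validation with retry, and per-well area extraction.

#' An RGB plate image with acquisition metadata
#'
#' @param pixels Numeric array `height x width x 3`, values in \[0, 1\].
#' @param filename Optional source filename (platform convention
#'   `<YYYYMMDD>T<HHMMSS>_x<int>_y<int>.png`).
#' @param acquisition_time,camera_xy Metadata; parsed from `filename` when
#'   omitted and the name follows the convention.
#' @return An object of class `plate_image`.
#' @export
plate_image <- function(pixels, filename = NA_character_,
                        acquisition_time = NULL, camera_xy = NULL) {
  stopifnot(is.array(pixels), length(dim(pixels)) == 3, dim(pixels)[3] == 3,
            all(dim(pixels)[1:2] > 0))
  if (!is.na(filename) && (is.null(acquisition_time) || is.null(camera_xy))) {
    meta <- parse_filename(basename(filename))
    acquisition_time <- acquisition_time %||% meta$acquisition_time
    camera_xy <- camera_xy %||% meta$camera_xy
  }
  structure(list(pixels = pixels, filename = filename,
    acquisition_time = acquisition_time, camera_xy = camera_xy),
    class = "plate_image")
}

#' @export
print.plate_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<plate_image> %d x %d px%s\n", d[2], d[1],
    if (is.na(x$filename)) "" else paste0(" [", basename(x$filename), "]")))
  invisible(x)
}

#' Read a plate PNG and its filename metadata
#' @param path Path to a PNG file named by the platform convention.
#' @return A [plate_image].
#' @export
read_plate_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  pix <- png::readPNG(path)
  if (length(dim(pix)) == 2) pix <- array(rep(pix, 3), dim = c(dim(pix), 3))
  if (dim(pix)[3] > 3) pix <- pix[, , 1:3, drop = FALSE]
  plate_image(pix, filename = path)
}

#' Segmentation and registration configuration
#'
#' Channel cut-offs use the 8-bit OpenCV-style HSV scaling: hue in 0-179
#' (degrees / 2), saturation and value in 0-255. The defaults select the
#' standard green-vegetation band against a white agar background; all are
#' camera-specific and meant to be tuned per platform.
#'
#' @param h_range,s_min,v_range Green band: hue window, minimum saturation,
#'   value window.
#' @param blue_h_range,blue_s_min,blue_v_min Fiducial (blue mark) band.
#' @param distortion_k Radial division-model coefficient of the camera
#'   (px^-2); 0 disables correction.
#' @param distortion_center Optional (x, y) distortion centre; image centre
#'   when `NULL`.
#' @param min_component Minimum connected-component size (px) kept in the
#'   green mask; suppresses single-pixel sensor noise.
#' @param mark_min_area Minimum blue component size (px) accepted as a mark.
#' @param outside_tolerance Green pixels allowed outside all wells before a
#'   registration is rejected.
#' @param crop_px_per_mm Reference scale of reported measurements and of
#'   registered crops, px/mm. Areas are normalised to this scale so images
#'   taken at slightly different camera heights are comparable. The default
#'   matches the platform's full-resolution optics (a 127.76 mm plate
#'   spanning 78% of a 2500 px frame).
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(h_range = c(35, 90), s_min = 60,
                                v_range = c(40, 255),
                                blue_h_range = c(100, 140),
                                blue_s_min = 80, blue_v_min = 60,
                                distortion_k = 0, distortion_center = NULL,
                                min_component = 5, mark_min_area = 20,
                                outside_tolerance = 0,
                                crop_px_per_mm = 0.78 * 2500 / 127.76) {
  stopifnot(h_range[1] <= h_range[2], v_range[1] <= v_range[2],
            outside_tolerance >= 0)
  structure(list(h_range = h_range, s_min = s_min, v_range = v_range,
    blue_h_range = blue_h_range, blue_s_min = blue_s_min,
    blue_v_min = blue_v_min, distortion_k = distortion_k,
    distortion_center = distortion_center, min_component = min_component,
    mark_min_area = mark_min_area, outside_tolerance = outside_tolerance,
    crop_px_per_mm = crop_px_per_mm), class = "segmentation_config")
}

#' Read a segmentation configuration from YAML
#' @param path YAML file whose keys match [segmentation_config()] arguments.
#' @return A `segmentation_config`.
#' @export
read_segmentation_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(segmentation_config))
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown config keys: ", toString(bad))
  do.call(segmentation_config, cfg)
}

pixel_hsv <- function(pixels) {
  d <- dim(pixels)
  m <- rbind(as.vector(pixels[, , 1]), as.vector(pixels[, , 2]),
             as.vector(pixels[, , 3]))
  grDevices::rgb2hsv(m, maxColorValue = 1)
}

#' Correct radial (fish-eye) lens distortion
#'
#' Inverts the single-coefficient radial division model about `center`:
#' a distorted point at radius `r_d` sits at undistorted radius
#' `r_u = r_d / (1 + k r_d^2)`. The output is the undistorted image at the
#' input dimensions, resampled by nearest neighbour; `k = 0` is the
#' identity and the centre pixel is a fixed point for any `k`.
#'
#' @param image A [plate_image] or pixel array.
#' @param k Radial coefficient, px^-2.
#' @param center Optional (x, y) centre; image centre when `NULL`.
#' @return Corrected image of the same class as the input.
#' @export
correct_fisheye <- function(image, k, center = NULL) {
  pix <- if (inherits(image, "plate_image")) image$pixels else image
  if (k == 0) return(image)
  H <- dim(pix)[1]; W <- dim(pix)[2]
  if (is.null(center)) center <- c(W / 2, H / 2)
  rmax2 <- max((c(0, W) - center[1])^2) + max((c(0, H) - center[2])^2)
  if (k > 0 && 4 * k * rmax2 >= 1)
    stop("distortion coefficient not invertible over this image")
  if (k < 0 && 1 + k * rmax2 <= 0.2)
    stop("distortion coefficient not invertible over this image")
  xu <- rep(seq_len(W) - 0.5, each = H) - center[1]
  yu <- rep(seq_len(H) - 0.5, times = W) - center[2]
  ru2 <- xu * xu + yu * yu
  ru <- sqrt(ru2)
  # solve r_u = r_d / (1 + k r_d^2) for r_d
  g <- ifelse(ru > 0, (1 - sqrt(pmax(1 - 4 * k * ru2, 0))) / (2 * k * ru2), 1)
  xd <- center[1] + xu * g
  yd <- center[2] + yu * g
  ci <- pmin(pmax(ceiling(xd), 1L), W)
  ri <- pmin(pmax(ceiling(yd), 1L), H)
  idx <- ri + (ci - 1L) * H
  out <- array(0, dim = dim(pix))
  np <- H * W
  for (ch in 1:3) out[, , ch] <- pix[idx + (ch - 1L) * np]
  if (inherits(image, "plate_image")) {
    image$pixels <- out
    image
  } else out
}

#' Threshold green plant tissue in HSV space
#'
#' Pure per-pixel banding: a pixel is plant iff hue lies in the green
#' window AND saturation exceeds its cut-off AND value lies in its window,
#' followed only by an optional minimum connected-component size filter.
#'
#' @param image A [plate_image] or pixel array.
#' @param config A [segmentation_config].
#' @return Logical `height x width` mask.
#' @export
segment_green <- function(image, config = segmentation_config()) {
  pix <- if (inherits(image, "plate_image")) image$pixels else image
  hsv <- pixel_hsv(pix)
  h <- hsv[1, ] * 180; s <- hsv[2, ] * 255; v <- hsv[3, ] * 255
  mask <- h >= config$h_range[1] & h <= config$h_range[2] &
    s >= config$s_min & v >= config$v_range[1] & v <= config$v_range[2]
  mask <- matrix(mask, nrow = dim(pix)[1])
  if (config$min_component > 1 && any(mask))
    mask <- drop_small_components(mask, config$min_component)
  mask
}

drop_small_components <- function(mask, min_size) {
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_size)
  mask & matrix(lab %in% keep, nrow = nrow(mask))
}

#' Detect blue boundary marks
#'
#' Thresholds the blue fiducial band in HSV, labels connected components,
#' drops components below `mark_min_area`, and returns their centroids
#' ordered by angle about the common centroid (clockwise from the negative
#' x axis in image coordinates).
#'
#' @param image A [plate_image] or pixel array.
#' @param config A [segmentation_config].
#' @return An n x 2 matrix of (x, y) centroids in pixel coordinates.
#' @export
detect_blue_marks <- function(image, config = segmentation_config()) {
  pix <- if (inherits(image, "plate_image")) image$pixels else image
  hsv <- pixel_hsv(pix)
  h <- hsv[1, ] * 180; s <- hsv[2, ] * 255; v <- hsv[3, ] * 255
  mask <- matrix(h >= config$blue_h_range[1] & h <= config$blue_h_range[2] &
    s >= config$blue_s_min & v >= config$blue_v_min, nrow = dim(pix)[1])
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0])
  comp <- which(sizes >= config$mark_min_area)
  if (length(comp) < 2)
    stop(sprintf("registration needs at least 2 boundary marks, found %d",
                 length(comp)))
  cent <- t(vapply(comp, function(ci) {
    ij <- which(lab == ci, arr.ind = TRUE)
    c(mean(ij[, 2]) - 0.5, mean(ij[, 1]) - 0.5)
  }, numeric(2)))
  colnames(cent) <- c("x", "y")
  ang <- atan2(cent[, 2] - mean(cent[, 2]), cent[, 1] - mean(cent[, 1]))
  cent[order(ang), , drop = FALSE]
}

# Least-squares similarity fit src -> dst (complex regression, proper
# rotation only). Returns a, b with dst ~ a * src + b, and the RMS residual.
fit_similarity <- function(src, dst) {
  zs <- complex(real = src[, 1], imaginary = src[, 2])
  zd <- complex(real = dst[, 1], imaginary = dst[, 2])
  zs_c <- zs - mean(zs); zd_c <- zd - mean(zd)
  denom <- sum(Mod(zs_c)^2)
  if (denom == 0) return(NULL)
  a <- sum(Conj(zs_c) * zd_c) / denom
  if (Mod(a) == 0) return(NULL)
  b <- mean(zd) - a * mean(zs)
  rms <- sqrt(mean(Mod(a * zs + b - zd)^2))
  list(a = a, b = b, rms = rms)
}

new_registration <- function(fitted, score = NULL, rank = NA_integer_) {
  structure(list(a = fitted$a, b = fitted$b,
    scale = Mod(fitted$a), rotation_deg = Arg(fitted$a) * 180 / pi,
    rms = fitted$rms, score = score, rank = rank),
    class = "plate_registration")
}

#' @export
print.plate_registration <- function(x, ...) {
  cat(sprintf(
    "<plate_registration> scale %.4f px/mm, rotation %.2f deg, score %.3f (rank %s)\n",
    x$scale, x$rotation_deg, x$score %||% NA, x$rank))
  invisible(x)
}

#' Map plate-coordinate points through a registration
#' @param points_mm n x 2 matrix of plate coordinates (mm).
#' @param registration A `plate_registration`.
#' @return n x 2 matrix of image pixel coordinates.
#' @export
plate_to_image <- function(points_mm, registration) {
  z <- registration$a * complex(real = points_mm[, 1],
                                imaginary = points_mm[, 2]) + registration$b
  cbind(x = Re(z), y = Im(z))
}

#' Propose ranked candidate registrations from detected marks
#'
#' Enumerates mark-to-template correspondence hypotheses — subsets when
#' spurious marks are present, all cyclic shifts, and reversed (flip)
#' orders — fits a similarity transform to each by least squares, and
#' scores candidates by normalised inverse residual, the plausibility
#' ordering in which [measure_plate()] tries them.
#'
#' @param marks n x 2 matrix of detected mark centroids (n >= 2).
#' @param layout A [plate_layout] providing the mark template.
#' @return List of `plate_registration` objects sorted by decreasing score
#'   (scores sum to 1), each carrying its `rank`.
#' @export
propose_registrations <- function(marks, layout) {
  n <- nrow(marks)
  if (is.null(n) || n < 2) stop("at least 2 marks required")
  tmpl <- layout$mark_positions
  k <- min(4L, n)
  mark_subsets <- utils::combn(n, k, simplify = FALSE)
  tmpl_subsets <- if (k == 4L) list(1:4) else utils::combn(4L, k, simplify = FALSE)
  angular_order <- function(p) {
    order(atan2(p[, 2] - mean(p[, 2]), p[, 1] - mean(p[, 1])))
  }
  cands <- list()
  for (ms in mark_subsets) {
    mpts <- marks[ms, , drop = FALSE]
    mpts <- mpts[angular_order(mpts), , drop = FALSE]
    for (ts in tmpl_subsets) {
      tpts <- tmpl[ts, , drop = FALSE]
      tpts <- tpts[angular_order(tpts), , drop = FALSE]
      for (rev in c(FALSE, TRUE)) {
        mp <- if (rev) mpts[k:1, , drop = FALSE] else mpts
        for (shift in 0:(k - 1)) {
          idx <- (seq_len(k) + shift - 1L) %% k + 1L
          fit <- fit_similarity(tpts, mp[idx, , drop = FALSE])
          if (!is.null(fit)) cands[[length(cands) + 1L]] <- fit
        }
      }
    }
  }
  if (!length(cands)) stop("no geometrically consistent registration found")
  key <- vapply(cands, function(f)
    paste(round(c(Re(f$a), Im(f$a), Re(f$b), Im(f$b)), 3), collapse = "/"),
    character(1))
  cands <- cands[!duplicated(key)]
  raw <- vapply(cands, function(f) 1 / (1 + f$rms), numeric(1))
  score <- raw / sum(raw)
  ord <- order(score, decreasing = TRUE)
  lapply(seq_along(ord), function(i)
    new_registration(cands[[ord[i]]], score = score[ord[i]], rank = i))
}

#' Register and crop an image to the plate rectangle
#'
#' Resamples the image (nearest neighbour) onto a raster covering exactly
#' the plate rectangle at a fixed reference scale, and maps the well discs
#' into that raster.
#'
#' @param image A [plate_image] or pixel array (already lens-corrected).
#' @param registration A `plate_registration`.
#' @param layout A [plate_layout].
#' @param px_per_mm Output scale; defaults to the configured reference
#'   scale of [segmentation_config()].
#' @return List with `image` (the cropped `plate_image`), `well_map`
#'   (list of `centers` in crop pixels, `radius`, `scale`), and `scale`.
#' @export
apply_registration <- function(image, registration, layout,
                               px_per_mm = NULL) {
  pix <- if (inherits(image, "plate_image")) image$pixels else image
  H <- dim(pix)[1]; W <- dim(pix)[2]
  s <- px_per_mm %||% segmentation_config()$crop_px_per_mm
  corners <- cbind(c(0, layout$plate_width, layout$plate_width, 0),
                   c(0, 0, layout$plate_height, layout$plate_height))
  cpx <- plate_to_image(corners, registration)
  if (any(cpx[, 1] < 0 | cpx[, 1] > W | cpx[, 2] < 0 | cpx[, 2] > H))
    stop("registration maps the plate partially outside the image")
  Wo <- round(layout$plate_width * s); Ho <- round(layout$plate_height * s)
  mmx <- (rep(seq_len(Wo) - 0.5, each = Ho)) / s
  mmy <- (rep(seq_len(Ho) - 0.5, times = Wo)) / s
  z <- registration$a * complex(real = mmx, imaginary = mmy) + registration$b
  ci <- pmin(pmax(ceiling(Re(z)), 1L), W)
  ri <- pmin(pmax(ceiling(Im(z)), 1L), H)
  idx <- ri + (ci - 1L) * H
  np <- H * W
  out <- array(0, dim = c(Ho, Wo, 3))
  for (ch in 1:3) out[, , ch] <- pix[idx + (ch - 1L) * np]
  list(image = plate_image(out),
       well_map = list(centers = well_centers(layout) * s,
                       radius = layout$well_radius * s, scale = s),
       scale = s)
}

# well map in the native frame of a registration
native_well_map <- function(registration, layout) {
  list(centers = plate_to_image(well_centers(layout), registration),
       radius = layout$well_radius * registration$scale,
       scale = registration$scale)
}

mask_coords <- function(mask) {
  idx <- which(mask)
  H <- nrow(mask)
  cbind(x = (idx - 1L) %/% H + 1L - 0.5, y = (idx - 1L) %% H + 1L - 0.5)
}

#' Count green pixels per well disc
#' @param mask Logical mask.
#' @param well_map List with `centers` (n x 2, px) and `radius` (px) in the
#'   mask's pixel frame.
#' @return Integer vector of per-well counts, column-wise well order.
#' @export
count_well_areas <- function(mask, well_map) {
  pts <- mask_coords(mask)
  r2 <- well_map$radius^2
  vapply(seq_len(nrow(well_map$centers)), function(w) {
    sum((pts[, 1] - well_map$centers[w, 1])^2 +
        (pts[, 2] - well_map$centers[w, 2])^2 <= r2)
  }, numeric(1))
}

#' Validate a registration by the green-outside-wells rule
#'
#' A registration is accepted only when the green pixels falling outside
#' every well disc do not exceed `outside_tolerance` — if plant tissue shows
#' up outside the wells, the registration was wrong.
#'
#' @param mask Logical green mask.
#' @param well_map Well disc map in the mask's frame (see
#'   [count_well_areas()]).
#' @param outside_tolerance Maximum green pixels allowed outside all wells.
#' @return `TRUE` or `FALSE`.
#' @export
validate_registration <- function(mask, well_map, outside_tolerance = 0) {
  sum(mask) - sum(count_well_areas(mask, well_map)) <= outside_tolerance
}

#' Measure per-well green areas of one plate image
#'
#' The full per-image routine: lens correction, mark detection, candidate
#' registrations in decreasing plausibility, green segmentation, and the
#' validation/retry loop — the first candidate leaving no green outside the
#' wells is accepted; if none passes, the best-scoring candidate is used and
#' the measurement flagged for manual review. Areas are counted in the
#' corrected image and normalised to the reference scale
#' `config$crop_px_per_mm` (so they are comparable across camera poses),
#' in column-wise well order.
#'
#' @param image A [plate_image].
#' @param layout A [plate_layout].
#' @param config A [segmentation_config].
#' @param preview Optional path; when given, a registered, segmented
#'   overlay PNG is written there.
#' @param max_candidates Candidates tried before giving up.
#' @return An object of class `plate_measurement`: `areas`,
#'   `registration_used`, `valid`, `n_tried`, `preview_path`, plus the
#'   image metadata.
#' @export
measure_plate <- function(image, layout, config = segmentation_config(),
                          preview = NULL, max_candidates = 12) {
  stopifnot(inherits(image, "plate_image"))
  corrected <- if (config$distortion_k != 0)
    correct_fisheye(image, config$distortion_k, config$distortion_center)
  else image
  marks <- detect_blue_marks(corrected, config)
  cands <- propose_registrations(marks, layout)
  mask <- segment_green(corrected, config)
  chosen <- NULL; valid <- FALSE; n_tried <- 0L
  for (reg in cands[seq_len(min(length(cands), max_candidates))]) {
    n_tried <- n_tried + 1L
    wm <- native_well_map(reg, layout)
    inside <- count_well_areas(mask, wm)
    if (sum(mask) - sum(inside) <= config$outside_tolerance) {
      chosen <- reg; valid <- TRUE
      areas <- round(inside * (config$crop_px_per_mm / reg$scale)^2)
      break
    }
  }
  if (!valid) {
    chosen <- cands[[1]]
    wm <- native_well_map(chosen, layout)
    areas <- round(count_well_areas(mask, wm) *
                   (config$crop_px_per_mm / chosen$scale)^2)
  }
  preview_path <- NA_character_
  if (!is.null(preview)) {
    preview_path <- write_preview(corrected, chosen, layout, config, preview)
  }
  structure(list(areas = as.numeric(areas), registration_used = chosen,
    valid = valid, n_tried = n_tried, preview_path = preview_path,
    filename = image$filename, acquisition_time = image$acquisition_time,
    camera_xy = image$camera_xy), class = "plate_measurement")
}

#' @export
print.plate_measurement <- function(x, ...) {
  cat(sprintf("<plate_measurement> %d wells, total green %d px, %s\n",
    length(x$areas), round(sum(x$areas)),
    if (x$valid) sprintf("valid (candidate %d of %d tried)",
                         x$registration_used$rank, x$n_tried)
    else "NOT validated - flagged for review"))
  invisible(x)
}

write_preview <- function(corrected, registration, layout, config, path) {
  crop <- apply_registration(corrected, registration, layout,
                             px_per_mm = config$crop_px_per_mm)
  pix <- crop$image$pixels
  mask <- segment_green(pix, config)
  # tint segmented pixels magenta, ring the wells in blue
  sel <- which(mask)
  np <- length(mask)
  pix[sel] <- 1; pix[sel + np] <- pix[sel + np] * 0.3; pix[sel + 2 * np] <- 1
  pts <- cbind(x = rep(seq_len(ncol(mask)) - 0.5, each = nrow(mask)),
               y = rep(seq_len(nrow(mask)) - 0.5, times = ncol(mask)))
  for (w in seq_len(nrow(crop$well_map$centers))) {
    d <- sqrt((pts[, 1] - crop$well_map$centers[w, 1])^2 +
              (pts[, 2] - crop$well_map$centers[w, 2])^2)
    ring <- which(abs(d - crop$well_map$radius) <= 1)
    pix[ring] <- 0.1; pix[ring + np] <- 0.3; pix[ring + 2 * np] <- 0.9
  }
  png::writePNG(pix, path)
  path
}

#' Analyze a directory of plate images
#'
#' Runs [measure_plate()] on every parseable PNG in a directory, in
#' acquisition-time order. Failures to validate are flagged, not fatal.
#'
#' @param input_dir Directory of platform-convention PNGs.
#' @param layout A [plate_layout].
#' @param config A [segmentation_config].
#' @param previews_dir Optional directory for preview overlays.
#' @return A measurement table: data frame with columns `filename`, `date`,
#'   `x`, `y`, `valid`, then `area_1..area_n`.
#' @export
analyze_directory <- function(input_dir, layout,
                              config = segmentation_config(),
                              previews_dir = NULL) {
  files <- list.files(input_dir, pattern = "\\.png$", full.names = TRUE)
  files <- files[vapply(files, function(f)
    !inherits(try(parse_filename(basename(f)), silent = TRUE), "try-error"),
    logical(1))]
  if (!length(files)) stop("no parseable PNG images in ", input_dir)
  times <- vapply(files, function(f)
    as.numeric(parse_filename(basename(f))$acquisition_time), numeric(1))
  files <- files[order(times)]
  if (!is.null(previews_dir))
    dir.create(previews_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(files, function(f) {
    img <- read_plate_image(f)
    pv <- if (is.null(previews_dir)) NULL else
      file.path(previews_dir, sub("\\.png$", "_preview.png", basename(f)))
    m <- measure_plate(img, layout, config, preview = pv)
    data.frame(filename = basename(f),
      date = format(m$acquisition_time, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
      x = m$camera_xy[1], y = m$camera_xy[2], valid = m$valid,
      t(stats::setNames(m$areas, paste0("area_", seq_along(m$areas)))),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
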
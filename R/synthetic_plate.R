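# Ground-truthed synthetic inputs: rendered plate images and simulated
# growth/stress experiments. The renderer and the analysis pipeline share no
# code path beyond the layout geometry, so pixel-count recovery is a real test.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# vectorised HSV (all in [0,1]) -> RGB
hsv_to_rgb <- function(h, s, v) {
  i <- floor(h * 6) %% 6
  f <- h * 6 - floor(h * 6)
  p <- v * (1 - s); q <- v * (1 - f * s); t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  cbind(r, g, b)
}

#' Stochastic exponential growth model with treatment effects and mortality
#'
#' Parametrises the per-plant green-area process
#' \deqn{A(t) = A_0 \exp(r_{\mathrm{eff}} G(t)) \cdot \varepsilon(t)}
#' where `r_eff = baseline_rgr * treatment_effects[treatment]`,
#' `G(t) = t` for `rgr_decay = 1` (pure exponential growth) or
#' `G(t) = (rgr_decay^t - 1)/log(rgr_decay)` for an RGR that declines
#' geometrically with seedling age, and `epsilon` is multiplicative
#' log-normal observation noise. Plants die with a fixed per-day hazard
#' starting the day after `mortality_onset`; death is absorbing and a dead
#' plant has green area 0.
#'
#' Defaults emulate unstressed seedlings transplanted at 4 days after
#' germination and imaged daily: initial rosettes of ~250 px (at the
#' platform's full 2500 x 2000 px resolution), a relative growth rate of
#' 0.4 day^-1, 8% observation noise and no mortality.
#'
#' @param a0_mean,a0_sd Mean and SD of the initial area, pixels (> 0).
#' @param baseline_rgr Relative growth rate of untreated plants, day^-1.
#' @param rgr_decay Daily multiplicative decay of the RGR (1 = constant).
#' @param treatment_effects Named vector of multiplicative RGR factors in
#'   \[0, 1\], one per treatment.
#' @param mortality_hazard Named vector of per-day death probabilities in
#'   \[0, 1\], one per treatment (treatments may be omitted; default 0).
#' @param mortality_onset Day from which the hazard applies.
#' @param noise_sd SD of the multiplicative log-normal observation noise.
#' @return An object of class `growth_model`.
#' @export
growth_model <- function(a0_mean = 250, a0_sd = 60, baseline_rgr = 0.4,
                         rgr_decay = 1,
                         treatment_effects = c(control = 1),
                         mortality_hazard = c(control = 0),
                         mortality_onset = 0, noise_sd = 0.08) {
  if (a0_mean <= 0) stop("initial area a0_mean must be positive")
  if (any(treatment_effects < 0 | treatment_effects > 1))
    stop("treatment RGR factors must lie in [0, 1]")
  if (any(mortality_hazard < 0 | mortality_hazard > 1))
    stop("mortality hazards must lie in [0, 1]")
  if (rgr_decay <= 0 || rgr_decay > 1) stop("rgr_decay must be in (0, 1]")
  structure(list(a0_mean = a0_mean, a0_sd = a0_sd,
    baseline_rgr = baseline_rgr, rgr_decay = rgr_decay,
    treatment_effects = treatment_effects,
    mortality_hazard = mortality_hazard,
    mortality_onset = mortality_onset, noise_sd = noise_sd),
    class = "growth_model")
}

#' Salt dose-response growth model
#'
#' A [growth_model] emulating a salinity dose series (0/50/75/100/150 mM
#' NaCl on full-strength MS medium): RGR reduced by 20/30/56/84% relative to
#' control, and lethal senescence at the highest dose (per-day hazard 0.125
#' from day 4, i.e. ~67% survival at day 7 falling to ~51% at day 9).
#' @export
salt_stress_model <- function() {
  growth_model(
    treatment_effects = c(control = 1, NaCl50 = 0.80, NaCl75 = 0.70,
                          NaCl100 = 0.44, NaCl150 = 0.16),
    mortality_hazard = c(NaCl150 = 0.125),
    mortality_onset = 4
  )
}

cumulative_growth <- function(t, decay) {
  if (decay == 1) t else (decay^t - 1) / log(decay)
}

#' Simulate per-plant green-area time series
#'
#' @param model A [growth_model].
#' @param n_plants Number of plants (>= 1).
#' @param treatment Treatment label; must appear in the model's
#'   `treatment_effects` (hazard defaults to 0 if unnamed there).
#' @param times Observation times in days (default daily for 9 days). The
#'   scalar form `times = d` expands to `0:(d-1)`.
#' @param seed RNG seed; simulations are reproducible per seed.
#' @return A long data frame with columns `plant`, `treatment`, `time`,
#'   `area`, `alive`. Dead plants have `area = 0` from their death day on.
#' @examples
#' sim <- simulate_growth(growth_model(noise_sd = 0), 3, times = 0:4)
#' @export
simulate_growth <- function(model, n_plants, treatment = "control",
                            times = 0:8, seed = 1) {
  stopifnot(inherits(model, "growth_model"), n_plants >= 1)
  if (length(times) == 1 && times >= 1 && times == round(times))
    times <- seq(0, times - 1)
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  eff <- model$treatment_effects[treatment]
  if (is.na(eff)) stop(sprintf("treatment '%s' not in model", treatment))
  hz <- model$mortality_hazard[treatment]
  if (is.na(hz)) hz <- 0
  r_eff <- model$baseline_rgr * eff
  G <- cumulative_growth(times, model$rgr_decay)
  with_seed(seed, {
    a0 <- stats::rnorm(n_plants, model$a0_mean, model$a0_sd)
    while (any(a0 <= 0))
      a0[a0 <= 0] <- stats::rnorm(sum(a0 <= 0), model$a0_mean, model$a0_sd)
    death <- if (hz > 0)
      model$mortality_onset + stats::rgeom(n_plants, hz) + 1 else rep(Inf, n_plants)
    noise <- if (model$noise_sd > 0)
      exp(stats::rnorm(n_plants * length(times), 0, model$noise_sd)) else 1
    area <- rep(a0, each = length(times)) * exp(r_eff * G) * noise
    alive <- rep(times, n_plants) < rep(death, each = length(times))
    data.frame(
      plant = rep(sprintf("plant%03d", seq_len(n_plants)), each = length(times)),
      treatment = treatment,
      time = rep(times, n_plants),
      area = ifelse(alive, area, 0),
      alive = alive,
      stringsAsFactors = FALSE
    )
  })
}

# Rosette blob model: a lobed star r <= c * rho(theta), rho normalised to
# max 1, with the radial threshold c calibrated on the canonical pixel grid
# so the rendered pixel count at the identity transform equals the target
# area exactly.
blob_threshold <- function(center_px, area, radius_px, lobes, amp, phase) {
  if (area == 0) return(-1)
  ix <- seq(floor(center_px[1] - radius_px - 1), ceiling(center_px[1] + radius_px + 1))
  iy <- seq(floor(center_px[2] - radius_px - 1), ceiling(center_px[2] + radius_px + 1))
  u <- rep(ix - 0.5, each = length(iy)) - center_px[1]
  v <- rep(iy - 0.5, times = length(ix)) - center_px[2]
  r <- sqrt(u^2 + v^2)
  keep <- r <= radius_px
  rho <- (1 + amp * cos(lobes * (atan2(v[keep], u[keep]) - phase))) / (1 + amp)
  keys <- sort(r[keep] / rho)
  if (area > length(keys)) stop("rosette area too large to fit the well")
  cc <- keys[area]
  if (cc > radius_px) stop("rosette area too large to fit the well")
  cc
}

#' Ground truth for one synthetic plate image
#'
#' Fixes everything [render_plate()] needs: per-well rosette areas (exact
#' pixel counts at the canonical, untransformed raster), per-well blob
#' shapes, the similarity transform mapping plate millimetres to image
#' pixels, the radial distortion coefficient, sensor noise, and the
#' (slightly jittered) positions of the blue boundary marks.
#'
#' The canonical scale is `fill * width / plate_width` px/mm, with the plate
#' centred in the image; `scale`, `rotation_deg` and `translation_px`
#' perturb that pose.
#'
#' @param layout A [plate_layout].
#' @param areas Integer vector of target green areas (pixels), one per well,
#'   in column-wise well order.
#' @param width,height Image size in pixels (platform default 2500 x 2000).
#' @param fill Fraction of the image width spanned by the plate.
#' @param scale,rotation_deg,translation_px Pose perturbation: relative
#'   scale factor, rotation in degrees, and (x, y) pixel offset.
#' @param distortion_k Radial division-model coefficient applied to the
#'   rendered image (px^-2; positive = barrel).
#' @param noise_sd Gaussian sensor noise SD in 8-bit intensity units.
#' @param mark_jitter_mm SD of the fiducial placement jitter, mm.
#' @param mark_radius_mm Radius of the blue boundary marks, mm.
#' @param extra_marks Optional n x 2 matrix of additional (spurious) blue
#'   blob positions in plate mm, e.g. to exercise the registration retry.
#' @param seed RNG seed controlling shapes, jitter and noise.
#' @return An object of class `ground_truth_plate`.
#' @export
ground_truth_plate <- function(layout, areas, width = 2500, height = 2000,
                               fill = 0.78, scale = 1, rotation_deg = 0,
                               translation_px = c(0, 0), distortion_k = 0,
                               noise_sd = 2, mark_jitter_mm = 0.1,
                               mark_radius_mm = 3.5, extra_marks = NULL,
                               seed = 1) {
  stopifnot(inherits(layout, "plate_layout"),
    length(areas) == layout$wells_per_plate, all(areas >= 0))
  s0 <- fill * width / layout$plate_width
  rmax2 <- (width / 2)^2 + (height / 2)^2
  if (distortion_k > 0 && 4 * distortion_k * rmax2 >= 1)
    stop("distortion coefficient not invertible over this image")
  if (distortion_k < 0 && 1 + distortion_k * rmax2 <= 0.2)
    stop("distortion coefficient not invertible over this image")
  a <- scale * s0 * exp(1i * rotation_deg * pi / 180)
  b <- complex(real = width / 2 + translation_px[1],
               imaginary = height / 2 + translation_px[2]) -
       a * complex(real = layout$plate_width / 2,
                   imaginary = layout$plate_height / 2)
  centers <- well_centers(layout)
  with_seed(seed, {
    lobes <- sample(4:8, layout$wells_per_plate, replace = TRUE)
    amp <- stats::runif(layout$wells_per_plate, 0.20, 0.35)
    phase <- stats::runif(layout$wells_per_plate, 0, 2 * pi)
    marks <- layout$mark_positions +
      matrix(stats::rnorm(8, 0, mark_jitter_mm), 4, 2)
    thr <- vapply(seq_len(layout$wells_per_plate), function(w) {
      q0 <- s0 * centers[w, ] +
        c(width / 2 - s0 * layout$plate_width / 2,
          height / 2 - s0 * layout$plate_height / 2)
      blob_threshold(q0, areas[w], layout$well_radius * s0,
                     lobes[w], amp[w], phase[w])
    }, numeric(1))
    structure(list(layout = layout, areas = as.numeric(areas),
      width = width, height = height, fill = fill, px_per_mm = s0,
      a = a, b = b, scale = scale, rotation_deg = rotation_deg,
      translation_px = translation_px, distortion_k = distortion_k,
      noise_sd = noise_sd, mark_positions_mm = marks,
      mark_radius_mm = mark_radius_mm, extra_marks = extra_marks,
      lobes = lobes, amp = amp, phase = phase, thresholds = thr,
      rng_seed = seed), class = "ground_truth_plate")
  })
}

#' Render a synthetic plate image
#'
#' Paints, per output pixel, the scene fixed by a [ground_truth_plate]:
#' grey tray, near-white agar inside the plate rectangle, green rosette
#' blobs, and blue boundary marks; then applies sensor noise and 8-bit
#' quantisation. The output raster is the *distorted* camera image: each
#' output pixel is mapped through the division-model distortion and the
#' inverse plate pose before the scene is evaluated, so
#' [correct_fisheye()] with the same coefficient undoes the distortion
#' exactly (up to resampling).
#'
#' Rendering is deterministic given the truth's `rng_seed`; at the identity
#' pose with zero distortion the per-well green pixel counts equal the
#' stored areas exactly.
#'
#' @param truth A [ground_truth_plate].
#' @return A `plate_image` (see [plate_image()]) with no filename metadata.
#' @export
render_plate <- function(truth) {
  W <- truth$width; H <- truth$height
  lay <- truth$layout
  x <- rep(seq_len(W) - 0.5, each = H)
  y <- rep(seq_len(H) - 0.5, times = W)
  k <- truth$distortion_k
  if (k != 0) {
    dx <- x - W / 2; dy <- y - H / 2
    f <- 1 / (1 + k * (dx * dx + dy * dy))
    x <- W / 2 + dx * f
    y <- H / 2 + dy * f
  }
  p <- (complex(real = x, imaginary = y) - truth$b) / truth$a
  px <- Re(p); py <- Im(p)
  rm(p, x, y)
  n <- W * H
  with_seed(truth$rng_seed + 1L, {
    R <- rep(0.78, n); G <- rep(0.78, n); B <- rep(0.77, n)
    on_plate <- px >= 0 & px <= lay$plate_width & py >= 0 & py <= lay$plate_height
    ii <- which(on_plate)
    v <- clamp(0.93 + stats::rnorm(length(ii), 0, 0.012), 0, 1)
    R[ii] <- v; G[ii] <- v * 0.995; B[ii] <- v * 0.965
    centers <- well_centers(lay)
    for (w in seq_len(lay$wells_per_plate)) {
      cw <- centers[w, ]
      jj <- ii[abs(px[ii] - cw[1]) <= lay$well_radius &
               abs(py[ii] - cw[2]) <= lay$well_radius]
      if (!length(jj)) next
      u <- (px[jj] - cw[1]) * truth$px_per_mm
      vv <- (py[jj] - cw[2]) * truth$px_per_mm
      r <- sqrt(u^2 + vv^2)
      in_well <- r <= lay$well_radius * truth$px_per_mm
      R[jj[in_well]] <- R[jj[in_well]] * 0.985
      B[jj[in_well]] <- B[jj[in_well]] * 0.99
      if (truth$thresholds[w] < 0) next
      rho <- (1 + truth$amp[w] * cos(truth$lobes[w] *
        (atan2(vv, u) - truth$phase[w]))) / (1 + truth$amp[w])
      gg <- jj[in_well & r / rho <= truth$thresholds[w]]
      if (!length(gg)) next
      col <- hsv_to_rgb(
        clamp(120 + stats::rnorm(length(gg), 0, 7), 100, 140) / 360,
        clamp(0.60 + stats::rnorm(length(gg), 0, 0.05), 0.35, 0.85),
        clamp(0.55 + stats::rnorm(length(gg), 0, 0.05), 0.30, 0.80))
      R[gg] <- col[, 1]; G[gg] <- col[, 2]; B[gg] <- col[, 3]
    }
    marks <- truth$mark_positions_mm
    if (!is.null(truth$extra_marks)) marks <- rbind(marks, truth$extra_marks)
    for (m in seq_len(nrow(marks))) {
      mm <- marks[m, ]
      near <- which(abs(px - mm[1]) <= truth$mark_radius_mm &
                    abs(py - mm[2]) <= truth$mark_radius_mm)
      near <- near[(px[near] - mm[1])^2 + (py[near] - mm[2])^2 <=
                   truth$mark_radius_mm^2]
      if (!length(near)) next
      col <- hsv_to_rgb(
        (240 + stats::rnorm(length(near), 0, 3)) / 360,
        clamp(0.80 + stats::rnorm(length(near), 0, 0.04), 0.6, 0.95),
        clamp(0.75 + stats::rnorm(length(near), 0, 0.04), 0.55, 0.9))
      R[near] <- col[, 1]; G[near] <- col[, 2]; B[near] <- col[, 3]
    }
    if (truth$noise_sd > 0) {
      s <- truth$noise_sd / 255
      R <- R + stats::rnorm(n, 0, s)
      G <- G + stats::rnorm(n, 0, s)
      B <- B + stats::rnorm(n, 0, s)
    }
    pix <- array(round(clamp(c(R, G, B), 0, 1) * 255) / 255, dim = c(H, W, 3))
    plate_image(pix)
  })
}

#' Generate a full synthetic imaging experiment
#'
#' Simulates growth for every plate of a design, renders one plate image per
#' imaging time with a randomised camera pose and lens distortion, writes
#' the PNGs with platform-convention filenames, and emits the ground-truth
#' area table the images were rendered from.
#'
#' Rendered areas are the simulated full-resolution areas rescaled by
#' `(width/2500)^2`, so reduced-resolution runs keep plants physically the
#' same size.
#'
#' @param design An [experiment_design].
#' @param model A [growth_model].
#' @param times Imaging times, days from experiment start.
#' @param out_dir Output directory (created if needed).
#' @param width,height Rendered image size in pixels.
#' @param start_time POSIXct acquisition time of the first imaging run.
#' @param distortion_k Radial distortion coefficient at the rendered
#'   resolution; default is the platform-typical 5e-9 px^-2 at full
#'   resolution, rescaled.
#' @param noise_sd Sensor noise SD, 8-bit units.
#' @param seed Master RNG seed.
#' @return Invisibly, a list with `truth` (the ground-truth data frame, also
#'   written to `ground_truth.csv`), `files`, and `dir`. A `manifest.yaml`
#'   records design, model and generation parameters.
#' @export
generate_experiment <- function(design, model, times = 0:8, out_dir,
                                width = 2500, height = round(width * 0.8),
                                start_time = as.POSIXct("2017-06-15 08:00:00",
                                                        tz = "UTC"),
                                distortion_k = NULL, noise_sd = 2, seed = 1) {
  stopifnot(inherits(design, "experiment_design"), inherits(model, "growth_model"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(distortion_k)) distortion_k <- 5e-9 * (2500 / width)^2
  fr <- (width / 2500)^2
  rows <- list(); files <- character(0)
  sub <- with_seed(seed, matrix(sample.int(.Machine$integer.max %/% 2,
    2 * nrow(design) * length(times)), nrow = nrow(design)))
  for (i in seq_len(nrow(design))) {
    lay <- plate_layout(design$format[i])
    sim <- simulate_growth(model, lay$wells_per_plate, design$treatment[i],
                           times, seed = sub[i, 1])
    amat <- matrix(sim$area, nrow = length(times))  # times x wells
    for (j in seq_along(times)) {
      areas_px <- round(amat[j, ] * fr)
      truth <- with_seed(sub[i, j + 1], ground_truth_plate(
        lay, areas_px, width = width, height = height,
        scale = stats::runif(1, 0.97, 1.03),
        rotation_deg = stats::runif(1, -3, 3),
        translation_px = stats::runif(2, -0.008 * width, 0.008 * width),
        distortion_k = distortion_k, noise_sd = noise_sd,
        seed = sub[i, j + 1]))
      img <- render_plate(truth)
      fn <- format_filename(start_time + times[j] * 86400,
                            c(design$pos_x[i], design$pos_y[i]))
      png::writePNG(img$pixels, file.path(out_dir, fn))
      files <- c(files, fn)
      rows[[length(rows) + 1L]] <- data.frame(
        filename = fn, plate_id = design$plate_id[i],
        treatment = design$treatment[i], time_days = times[j],
        px_per_mm = truth$px_per_mm,
        t(stats::setNames(areas_px, paste0("area_", seq_along(areas_px)))),
        stringsAsFactors = FALSE)
    }
  }
  truth_df <- do.call(rbind, rows)
  utils::write.csv(truth_df, file.path(out_dir, "ground_truth.csv"),
                   row.names = FALSE)
  yaml::write_yaml(list(
    design = as.list(as.data.frame(design)), times = times,
    width = width, height = height, distortion_k = distortion_k,
    noise_sd = noise_sd, seed = seed,
    model = model[setdiff(names(model), character(0))]),
    file.path(out_dir, "manifest.yaml"))
  invisible(list(truth = truth_df, files = files, dir = out_dir))
}
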
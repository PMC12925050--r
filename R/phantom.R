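# Digital phantom: simulates a lead-tip trajectory under a motion-management
# regime and renders the corresponding kV projection stack with ground truth.

MOTION_MODES <- c("DIBH", "FB", "AC", "HFV")

mode_defaults <- function(mode) {
  switch(mode,
    # Free breathing: dominant SI respiratory excursion with an end-exhale
    # dwell, plus cardiac contraction transmitted to the lead tip.
    FB = list(resp_amplitude = c(2, 8, 3), resp_period = 4),
    # Abdominal compression damps respiration but does not remove it.
    AC = list(resp_amplitude = c(1, 4, 1.5), resp_period = 4),
    # Breath-hold: slow low-amplitude residual drift of the held level.
    DIBH = list(resp_amplitude = c(0.5, 1, 0.5), resp_period = 10),
    # High-frequency ventilation: small fast oscillation (~240 cycles/min).
    HFV = list(resp_amplitude = c(0.3, 1, 0.5), resp_period = 0.25)
  )
}

#' Cardiorespiratory motion model
#'
#' Closed-form lead-tip motion: baseline + linear drift + respiratory wave +
#' cardiac sinusoid, each with a per-axis (lr, si, ap) amplitude. The
#' respiratory waveform depends on the motion-management mode: a cos^4 wave
#' (end-exhale dwell, standard in the radiotherapy motion literature) for FB
#' and AC, a slow low-amplitude sinusoid for DIBH residual motion, and a fast
#' small sinusoid for HFV. Cardiac motion is a single sinusoid at
#' `cardiac_rate` beats/min. Amplitudes are peak values per axis; the same
#' phase is shared across axes (the tip moves coherently), offset by
#' `resp_phase` / `cardiac_phase`.
#'
#' Amplitude/period defaults are mode-specific; see Details in the package
#' vignette. The trajectory is fully deterministic given its arguments.
#'
#' @param mode One of `"DIBH"`, `"FB"`, `"AC"`, `"HFV"`.
#' @param resp_amplitude Per-axis respiratory amplitude `c(lr, si, ap)`, mm.
#' @param resp_period Respiratory period, s.
#' @param cardiac_amplitude Per-axis cardiac amplitude `c(lr, si, ap)`, mm.
#' @param cardiac_rate Heart rate, beats per minute.
#' @param baseline Constant offset `c(lr, si, ap)` mm added to the planning
#'   position.
#' @param drift Linear drift `c(lr, si, ap)`, mm/s.
#' @param resp_phase,cardiac_phase Phase offsets, radians.
#' @return An object of class `motion_model`.
#' @export
motion_model <- function(mode = c("FB", "DIBH", "AC", "HFV"),
                         resp_amplitude = NULL, resp_period = NULL,
                         cardiac_amplitude = c(1, 1.5, 1), cardiac_rate = 70,
                         baseline = c(0, 0, 0), drift = c(0, 0, 0),
                         resp_phase = 0, cardiac_phase = 0) {
  mode <- match.arg(mode)
  def <- mode_defaults(mode)
  resp_amplitude <- as.numeric(resp_amplitude %||% def$resp_amplitude)
  resp_period <- resp_period %||% def$resp_period
  stopifnot(length(resp_amplitude) == 3, all(resp_amplitude >= 0),
            resp_period > 0,
            length(cardiac_amplitude) == 3, all(cardiac_amplitude >= 0),
            cardiac_rate > 0, length(baseline) == 3, length(drift) == 3)
  structure(
    list(mode = mode, resp_amplitude = resp_amplitude,
         resp_period = resp_period,
         cardiac_amplitude = as.numeric(cardiac_amplitude),
         cardiac_rate = cardiac_rate, baseline = as.numeric(baseline),
         drift = as.numeric(drift), resp_phase = resp_phase,
         cardiac_phase = cardiac_phase),
    class = "motion_model"
  )
}

#' @export
print.motion_model <- function(x, ...) {
  cat(sprintf("<motion_model> mode %s\n", x$mode))
  cat(sprintf("  resp  (%.1f, %.1f, %.1f) mm, period %.2f s\n",
              x$resp_amplitude[1], x$resp_amplitude[2], x$resp_amplitude[3],
              x$resp_period))
  cat(sprintf("  cardiac (%.1f, %.1f, %.1f) mm @ %g bpm\n",
              x$cardiac_amplitude[1], x$cardiac_amplitude[2],
              x$cardiac_amplitude[3], x$cardiac_rate))
  invisible(x)
}

# Respiratory waveform in [-1, 1]-ish units. cos^4 dwells near zero
# (end-exhale) and peaks at 1; sinusoidal modes span [-1, 1].
resp_wave <- function(t, mode, period, phase) {
  switch(mode,
    FB = ,
    AC = cos(pi * t / period + phase)^4,
    DIBH = sin(2 * pi * t / period + phase),
    HFV = sin(2 * pi * t / period + phase)
  )
}

#' Simulate a lead-tip trajectory
#'
#' Evaluates the motion model at each projection time and adds the planning
#' position, giving the ground-truth 3D trajectory of the tip.
#'
#' @param metas A [projection_meta()] tibble (`index`, `gantry_deg`, `time_s`).
#' @param model A [motion_model()].
#' @param lead A [lead_tip_model()]; its `planning_position` anchors the
#'   trajectory.
#' @return A tibble with columns `index`, `time_s`, `gantry_deg`, `lr_mm`,
#'   `si_mm`, `ap_mm`.
#' @export
simulate_trajectory <- function(metas, model, lead = lead_tip_model()) {
  validate_projection_meta(metas)
  t <- metas$time_s
  rw <- resp_wave(t, model$mode, model$resp_period, model$resp_phase)
  cw <- sin(2 * pi * model$cardiac_rate / 60 * t + model$cardiac_phase)
  pos <- function(ax) {
    lead$planning_position[ax] + model$baseline[ax] + model$drift[ax] * t +
      model$resp_amplitude[ax] * rw + model$cardiac_amplitude[ax] * cw
  }
  tibble(
    index = metas$index, time_s = t, gantry_deg = metas$gantry_deg,
    lr_mm = pos(1), si_mm = pos(2), ap_mm = pos(3)
  )
}

#' Render one kV projection of the lead tip
#'
#' Draws the chord-length projection of the cylinder on a zero background at
#' the nominal magnification, optionally adds straight high-contrast line
#' segments emulating overlapping wires/leads (clutter), then additive white
#' Gaussian noise.
#'
#' @param tip_position 3D tip position `c(lr, si, ap)` mm.
#' @param tip_axis Lead axis direction in room coordinates (unit 3-vector).
#' @param theta_deg Gantry angle, degrees.
#' @param geom A [beam_geometry()].
#' @param lead A [lead_tip_model()] supplying radius/length/contrast.
#' @param noise_sd Standard deviation of the additive Gaussian noise (same
#'   units as contrast * mm); 0 disables noise.
#' @param clutter Optional tibble/data frame with one wire per row: columns
#'   `offset_u_mm`, `offset_v_mm` (wire center offset from the projected tip,
#'   imager mm), `angle_deg` (in-plane direction), `width_mm`, `length_mm`,
#'   `contrast`.
#' @param supersample Integer subgrid factor for anti-aliasing (1 = pixel
#'   centers only).
#' @return A numeric matrix (rows x cols = imager rows x columns).
#' @export
render_projection <- function(tip_position, tip_axis, theta_deg, geom,
                              lead = lead_tip_model(), noise_sd = 0,
                              clutter = NULL, supersample = 1L) {
  uv <- project_point(as.numeric(tip_position), theta_deg, geom)
  ctr <- imager_mm_to_px(uv, geom)
  nc <- geom$imager_size[1]; nr <- geom$imager_size[2]
  if (ctr$col_px < 1 || ctr$col_px > nc || ctr$row_px < 1 || ctr$row_px > nr) {
    abort(sprintf(
      "tip projects outside the imager at gantry %g deg (col %.1f, row %.1f).",
      theta_deg, ctr$col_px, ctr$row_px))
  }
  img <- matrix(0, nrow = nr, ncol = nc)

  # Cylinder footprint: render only a bounding box around the projected tip.
  half_mm <- lead$length / 2 + lead$radius
  half_px <- ceiling(half_mm * magnification(geom) / geom$pixel_spacing) + 2L
  c0 <- max(1L, floor(ctr$col_px) - half_px)
  c1 <- min(nc, ceiling(ctr$col_px) + half_px)
  r0 <- max(1L, floor(ctr$row_px) - half_px)
  r1 <- min(nr, ceiling(ctr$row_px) + half_px)
  axis_beam <- room_to_beam_dir(tip_axis, theta_deg)
  patch <- render_cylinder_canvas(
    axis_beam, lead$radius, lead$length / 2, lead$contrast,
    center_px = c(ctr$col_px - c0 + 1, ctr$row_px - r0 + 1),
    dims_px = c(c1 - c0 + 1L, r1 - r0 + 1L), geom = geom,
    supersample = supersample)
  img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] + patch

  if (!is.null(clutter) && nrow(clutter) > 0) {
    img <- img + render_clutter(clutter, ctr, geom)
  }
  if (noise_sd > 0) {
    img <- img + matrix(rnorm(nr * nc, sd = noise_sd), nrow = nr, ncol = nc)
  }
  img
}

# Wires as thin rectangles: distance-to-segment test on the pixel grid,
# evaluated only inside each wire's bounding box.
render_clutter <- function(clutter, tip_ctr_px, geom) {
  nc <- geom$imager_size[1]; nr <- geom$imager_size[2]
  img <- matrix(0, nrow = nr, ncol = nc)
  sp <- geom$pixel_spacing
  for (i in seq_len(nrow(clutter))) {
    w <- clutter[i, ]
    cx <- tip_ctr_px$col_px + w$offset_u_mm / sp
    cy <- tip_ctr_px$row_px - w$offset_v_mm / sp
    th <- w$angle_deg * pi / 180
    hl <- w$length_mm / 2 / sp
    hw <- w$width_mm / 2 / sp
    ext <- ceiling(hl + hw) + 1L
    c0 <- max(1L, floor(cx - ext)); c1 <- min(nc, ceiling(cx + ext))
    r0 <- max(1L, floor(cy - ext)); r1 <- min(nr, ceiling(cy + ext))
    if (c0 > c1 || r0 > r1) next
    cols <- c0:c1; rows <- r0:r1
    dx <- rep(cols - cx, each = length(rows))
    dy <- rep(rows - cy, times = length(cols))
    # coordinates along/across the wire direction (row axis points down)
    along <- dx * cos(th) - dy * sin(th)
    across <- dx * sin(th) + dy * cos(th)
    inside <- abs(along) <= hl & abs(across) <= hw
    img[rows, cols] <- img[rows, cols] +
      matrix(w$contrast * inside, nrow = length(rows))
  }
  img
}

#' Simulate a complete CBCT scan of a moving lead tip
#'
#' Runs [simulate_trajectory()] and renders every projection, returning the
#' stack in memory together with the ground truth. All randomness (noise)
#' derives from `seed`, so the scan is reproducible.
#'
#' @inheritParams render_projection
#' @param metas A [projection_meta()] tibble.
#' @param model A [motion_model()].
#' @param seed Integer seed for the rendering noise.
#' @return A list of class `lead_scan` with elements `frames` (list of
#'   matrices), `truth` (tibble `index,time_s,gantry_deg,lr_mm,si_mm,ap_mm,
#'   u_px,v_px`, where `u_px`/`v_px` are the exact projected pixel
#'   coordinates of the tip), `geom`, `lead`, `model`, `metas`.
#' @export
simulate_scan <- function(metas = projection_meta(), model = motion_model("FB"),
                          lead = lead_tip_model(), geom = beam_geometry(),
                          noise_sd = 0.2, clutter = NULL, seed = 1L,
                          supersample = 1L) {
  traj <- simulate_trajectory(metas, model, lead)
  uv <- project_point(traj, traj$gantry_deg, geom)
  px <- imager_mm_to_px(uv, geom)
  truth <- dplyr::mutate(traj, u_px = px$col_px, v_px = px$row_px)

  set.seed(seed)
  frames <- purrr::map(seq_len(nrow(traj)), function(i) {
    render_projection(
      c(traj$lr_mm[i], traj$si_mm[i], traj$ap_mm[i]),
      lead$axis, traj$gantry_deg[i], geom, lead,
      noise_sd = noise_sd, clutter = clutter, supersample = supersample)
  })
  structure(
    list(frames = frames, truth = truth, geom = geom, lead = lead,
         model = model, metas = metas),
    class = "lead_scan"
  )
}

#' @export
print.lead_scan <- function(x, ...) {
  cat(sprintf("<lead_scan> %d projections, mode %s, imager %d x %d px\n",
              length(x$frames), x$model$mode,
              x$geom$imager_size[1], x$geom$imager_size[2]))
  invisible(x)
}

#' Generate a phantom dataset on disk
#'
#' Writes a self-consistent dataset: a multi-frame 16-bit TIFF projection
#' stack (`projections.tif`, with its quantization recorded in
#' `intensity.json`), the geometry descriptor (`geometry.json`), the
#' ground-truth trajectory (`truth.csv` with columns
#' `index,time_s,gantry_deg,lr_mm,si_mm,ap_mm,u_px,v_px`) and the planning
#' tip descriptor (`planning_tip.json`).
#'
#' @inheritParams simulate_scan
#' @param dir Output directory (created if needed).
#' @param overwrite Refuse to overwrite an existing dataset unless `TRUE`.
#' @return Invisibly, the `lead_scan` that was written.
#' @export
generate_dataset <- function(dir, metas = projection_meta(),
                             model = motion_model("FB"),
                             lead = lead_tip_model(), geom = beam_geometry(),
                             noise_sd = 0.2, clutter = NULL, seed = 1L,
                             overwrite = FALSE) {
  files <- file.path(dir, c("projections.tif", "intensity.json",
                            "geometry.json", "truth.csv", "planning_tip.json"))
  if (!overwrite && any(file.exists(files))) {
    abort(paste0("dataset files already exist in '", dir,
                 "'; use overwrite = TRUE to replace them."))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scan <- simulate_scan(metas, model, lead, geom, noise_sd = noise_sd,
                        clutter = clutter, seed = seed)
  write_projection_stack(scan$frames, files[1])
  write_geometry(geom, metas, files[3])
  readr::write_csv(scan$truth, files[4])
  write_planning_tip(lead, files[5])
  invisible(scan)
}

#' Read or write a planning-tip descriptor
#'
#' JSON with keys `position_mm` (3), `axis` (3), `radius_mm`, `length_mm`
#' and optional `contrast`.
#'
#' @param path Path to the JSON file.
#' @return `read_planning_tip()`: a [lead_tip_model()].
#' @export
read_planning_tip <- function(path) {
  if (!file.exists(path)) abort(sprintf("planning-tip file not found: %s", path))
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("position_mm", "axis", "radius_mm", "length_mm")
  missing <- setdiff(need, names(j))
  if (length(missing)) {
    abort(sprintf("planning-tip descriptor is missing key(s): %s",
                  paste(missing, collapse = ", ")))
  }
  lead_tip_model(radius = j$radius_mm, length = j$length_mm, axis = j$axis,
                 contrast = j$contrast %||% 1,
                 planning_position = j$position_mm)
}

#' @rdname read_planning_tip
#' @param lead A [lead_tip_model()].
#' @export
write_planning_tip <- function(lead, path) {
  jsonlite::write_json(
    list(position_mm = lead$planning_position, axis = lead$axis,
         radius_mm = lead$radius, length_mm = lead$length,
         contrast = lead$contrast),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
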
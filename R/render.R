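# Analytic projection of a finite cylinder (the lead tip) under a
# parallel-beam approximation within its small footprint: each pixel's value
# is the chord length (mm) of the ray through that pixel inside the cylinder,
# scaled by the lead contrast. Divergence across a ~10 mm object at
# SAD 1000 mm is negligible, so rays are taken parallel to the beam axis and
# the footprint is drawn at the nominal magnification sdd/sad.

#' Lead-tip cylinder model
#'
#' Geometry and contrast of the tracked object: the distal electrode of an
#' ICD lead, modeled as a solid cylinder. The axis is the lead direction at
#' planning, a unit 3-vector over (lr, si, ap). Dimensions default to a
#' typical RV electrode (radius 1 mm, length 8 mm); contrast is the
#' attenuation amplitude per mm of chord relative to the background.
#'
#' @param radius Cylinder radius, mm.
#' @param length Cylinder length, mm.
#' @param axis Lead axis direction, length-3 numeric (normalized internally).
#' @param contrast Attenuation amplitude per mm chord (dimensionless scale).
#' @param planning_position Planning 3D tip position `c(lr, si, ap)` mm
#'   relative to isocenter.
#' @return An object of class `lead_tip_model`.
#' @export
lead_tip_model <- function(radius = 1, length = 8,
                           axis = c(0.3, 0.9, 0.3),
                           contrast = 1,
                           planning_position = c(0, 0, 0)) {
  stopifnot(is.numeric(radius), length(radius) == 1, radius > 0,
            is.numeric(length), base::length(length) == 1, length > 0,
            is.numeric(contrast), base::length(contrast) == 1, contrast > 0)
  axis <- as.numeric(axis)
  if (base::length(axis) != 3 || !all(is.finite(axis))) {
    abort("`axis` must be a finite length-3 numeric.")
  }
  nrm <- sqrt(sum(axis^2))
  if (nrm < 1e-12) abort("`axis` must be nonzero.")
  planning_position <- as.numeric(planning_position)
  if (base::length(planning_position) != 3 || !all(is.finite(planning_position))) {
    abort("`planning_position` must be a finite length-3 numeric.")
  }
  structure(
    list(radius = radius, length = length, axis = axis / nrm,
         contrast = contrast, planning_position = planning_position),
    class = "lead_tip_model"
  )
}

#' @export
print.lead_tip_model <- function(x, ...) {
  cat(sprintf(
    "<lead_tip_model> r %.2f mm, L %.2f mm, axis (%.2f, %.2f, %.2f), contrast %g\n",
    x$radius, x$length, x$axis[1], x$axis[2], x$axis[3], x$contrast))
  cat(sprintf("  planning position (%.1f, %.1f, %.1f) mm\n",
              x$planning_position[1], x$planning_position[2], x$planning_position[3]))
  invisible(x)
}

# Chord length (mm) through a finite cylinder centered at the origin, for
# parallel rays along +z in a local (x, y, z) frame. u, v: ray offsets in the
# x-y plane (mm); axis: unit 3-vector in the local frame; radius/half_len: mm.
# Vectorized over u, v. The ray is p(t) = (u, v, t); the cylinder is
# { |d.p| <= h  and  |p - (d.p)d| <= r }.
cylinder_chord <- function(u, v, axis, radius, half_len) {
  al <- axis[1]; be <- axis[2]; ga <- axis[3]
  A <- 1 - ga^2
  out <- numeric(length(u))

  if (A < 1e-12) {
    # Axis along the beam: circular footprint, chord = full length.
    inside <- (u^2 + v^2) <= radius^2
    out[inside] <- 2 * half_len
    return(out)
  }

  m <- al * u + be * v                    # d . q for q = (u, v, 0)
  qx <- u - m * al
  qy <- v - m * be
  qz <- -m * ga
  # f(t) = (q - m d) + t (e - ga d), e = (0, 0, 1); |f(t)|^2 <= r^2.
  B <- 2 * (qx * (-ga * al) + qy * (-ga * be) + qz * A)
  C <- qx^2 + qy^2 + qz^2 - radius^2
  disc <- B^2 - 4 * A * C
  hit <- disc > 0
  if (!any(hit)) return(out)

  sq <- sqrt(disc[hit])
  t_lo <- (-B[hit] - sq) / (2 * A)
  t_hi <- (-B[hit] + sq) / (2 * A)

  if (abs(ga) < 1e-12) {
    # Axis in-plane: the slab condition |m| <= h doesn't involve t.
    ok <- abs(m[hit]) <= half_len
    chord <- ifelse(ok, t_hi - t_lo, 0)
  } else {
    s1 <- (-half_len - m[hit]) / ga
    s2 <- (half_len - m[hit]) / ga
    s_lo <- pmin(s1, s2)
    s_hi <- pmax(s1, s2)
    chord <- pmax(0, pmin(t_hi, s_hi) - pmax(t_lo, s_lo))
  }
  out[hit] <- chord
  out
}

# Render the chord-length image of a cylinder on a pixel canvas.
#   axis_beam: unit axis in beam coordinates (a, b, c components).
#   center_px: fractional (col, row) of the cylinder center on the canvas.
#   dims_px:   c(ncol, nrow) of the canvas.
# Rays hit pixel centers; pixel pitch at isocenter scale is
# pixel_spacing / magnification. Returns an nrow x ncol matrix of
# contrast * chord_mm. supersample > 1 averages an s x s subgrid per pixel.
render_cylinder_canvas <- function(axis_beam, radius, half_len, contrast,
                                   center_px, dims_px, geom, supersample = 1L) {
  nc <- dims_px[1]; nr <- dims_px[2]
  pitch <- geom$pixel_spacing / magnification(geom)   # mm per pixel at isocenter
  s <- as.integer(supersample)
  if (s <= 1L) {
    ucol <- (seq_len(nc) - center_px[1]) * pitch
    vrow <- (center_px[2] - seq_len(nr)) * pitch      # row increases downward
    u <- rep(ucol, each = nr)
    v <- rep(vrow, times = nc)
    ch <- cylinder_chord(u, v, axis_beam, radius, half_len)
    return(matrix(contrast * ch, nrow = nr, ncol = nc))
  }
  off <- (seq_len(s) - (s + 1) / 2) / s               # subpixel offsets
  acc <- matrix(0, nrow = nr, ncol = nc)
  for (du in off) {
    ucol <- (seq_len(nc) + du - center_px[1]) * pitch
    for (dv in off) {
      vrow <- (center_px[2] - (seq_len(nr) + dv)) * pitch
      u <- rep(ucol, each = nr)
      v <- rep(vrow, times = nc)
      acc <- acc + matrix(cylinder_chord(u, v, axis_beam, radius, half_len),
                          nrow = nr, ncol = nc)
    }
  }
  contrast * acc / (s * s)
}

# Express a room-frame direction in beam coordinates (a, b, c) at theta.
room_to_beam_dir <- function(dir_room, theta_deg) {
  fr <- beam_frame(theta_deg)
  as.numeric(fr %*% dir_room)
}
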
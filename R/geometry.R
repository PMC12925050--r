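# Projection geometry for a rotating kV source-imager pair.
#
# Room frame: right-handed (lr, si, ap) with origin at isocenter.
# The gantry rotates about the SI axis; at gantry angle 0 the source is
# anterior, so the beam travels anterior -> posterior. The flat panel sits
# opposite the source; its vertical axis stays aligned with SI at every
# gantry angle (true for a gantry-mounted panel rotating with the source).

#' CBCT acquisition geometry
#'
#' Constants shared by every projection of a scan: source-to-isocenter
#' distance (SAD), source-to-imager distance (SDD), imager pixel spacing and
#' panel size. The nominal magnification at isocenter is `sdd / sad`.
#'
#' Defaults describe a standard C-arm linac kV system: SAD 1000 mm,
#' SDD 1500 mm, 0.8 mm pixels (so 25 pixels correspond to 20 mm) on a
#' 512 x 384 panel.
#'
#' @param sad Source-to-isocenter distance, mm.
#' @param sdd Source-to-imager distance, mm. Must exceed `sad`.
#' @param pixel_spacing Imager pixel size, mm per pixel (square pixels).
#' @param imager_size Panel size as `c(columns, rows)`, pixels.
#' @return An object of class `beam_geometry`.
#' @examples
#' geom <- beam_geometry()
#' magnification(geom)
#' @export
beam_geometry <- function(sad = 1000, sdd = 1500, pixel_spacing = 0.8,
                          imager_size = c(512L, 384L)) {
  if (!(is.numeric(sad) && length(sad) == 1 && is.finite(sad) && sad > 0)) {
    abort("`sad` must be a single positive number (mm).")
  }
  if (!(is.numeric(sdd) && length(sdd) == 1 && is.finite(sdd) && sdd > sad)) {
    abort("`sdd` must be a single number (mm) greater than `sad`.")
  }
  if (!(is.numeric(pixel_spacing) && length(pixel_spacing) == 1 &&
        is.finite(pixel_spacing) && pixel_spacing > 0)) {
    abort("`pixel_spacing` must be a single positive number (mm/pixel).")
  }
  imager_size <- as.integer(imager_size)
  if (length(imager_size) != 2 || any(is.na(imager_size)) || any(imager_size < 1)) {
    abort("`imager_size` must be two integers >= 1: c(columns, rows).")
  }
  structure(
    list(sad = sad, sdd = sdd, pixel_spacing = pixel_spacing,
         imager_size = imager_size),
    class = "beam_geometry"
  )
}

#' @export
print.beam_geometry <- function(x, ...) {
  cat("<beam_geometry>\n")
  cat(sprintf("  SAD %.1f mm, SDD %.1f mm (magnification %.4f)\n",
              x$sad, x$sdd, x$sdd / x$sad))
  cat(sprintf("  imager %d x %d px @ %.3f mm/px\n",
              x$imager_size[1], x$imager_size[2], x$pixel_spacing))
  invisible(x)
}

#' @rdname beam_geometry
#' @param geom A `beam_geometry` object.
#' @export
magnification <- function(geom) geom$sdd / geom$sad

#' Beam-frame basis at a gantry angle
#'
#' Orthonormal triple spanning the room from the imager's point of view at
#' gantry angle `theta`: `a` is the resolved lateral direction (along the
#' imager u-axis), `b` the resolved vertical direction (imager v-axis, always
#' SI), and `c` the unresolved depth direction pointing from isocenter toward
#' the X-ray source. At `theta = 0` the source is anterior, so
#' `a = (1, 0, 0)`, `b = (0, 1, 0)`, `c = (0, 0, 1)` over (lr, si, ap).
#'
#' @param theta_deg Gantry angle in degrees.
#' @return A 3 x 3 numeric matrix with rows `a`, `b`, `c` and columns
#'   `lr`, `si`, `ap`.
#' @examples
#' beam_frame(0)
#' beam_frame(90)
#' @export
beam_frame <- function(theta_deg) {
  stopifnot(is.numeric(theta_deg), length(theta_deg) == 1, is.finite(theta_deg))
  th <- theta_deg * pi / 180
  m <- rbind(
    a = c(cos(th), 0, sin(th)),
    b = c(0, 1, 0),
    c = c(-sin(th), 0, cos(th))
  )
  colnames(m) <- c("lr", "si", "ap")
  m
}

# Vectorized beam-frame components for a vector of angles: list of numeric
# vectors a_lr, a_ap (a_si = 0), c_lr, c_ap. Used internally by the
# estimation code where per-angle 3x3 matrices would be wasteful.
beam_frame_components <- function(theta_deg) {
  th <- theta_deg * pi / 180
  list(a_lr = cos(th), a_ap = sin(th), c_lr = -sin(th), c_ap = cos(th))
}

as_point3 <- function(p, arg = "point") {
  if (is.data.frame(p)) {
    need <- c("lr_mm", "si_mm", "ap_mm")
    if (!all(need %in% names(p))) {
      abort(sprintf("`%s` data frame needs columns lr_mm, si_mm, ap_mm.", arg))
    }
    m <- cbind(p$lr_mm, p$si_mm, p$ap_mm)
  } else if (is.numeric(p) && length(p) == 3) {
    m <- matrix(p, nrow = 1)
  } else if (is.matrix(p) && ncol(p) == 3) {
    m <- p
  } else {
    abort(sprintf(
      "`%s` must be a length-3 numeric, an n x 3 matrix, or a data frame with lr_mm/si_mm/ap_mm.",
      arg))
  }
  if (!all(is.finite(m))) abort(sprintf("`%s` must be finite.", arg))
  m
}

#' Forward-project room points onto the imager plane
#'
#' Projects 3D points (mm relative to isocenter) onto the imager through the
#' source at gantry angle `theta_deg`, with the divergent-beam magnification
#' `sdd / (sad - w)` where `w` is the point's depth toward the source.
#'
#' @param points A length-3 numeric `c(lr, si, ap)`, an n x 3 matrix, or a
#'   data frame with columns `lr_mm`, `si_mm`, `ap_mm`.
#' @param theta_deg Gantry angle(s), degrees; length 1 or one per point.
#' @param geom A [beam_geometry()].
#' @return A tibble with columns `u_mm`, `v_mm`: imager-plane coordinates in
#'   mm from the imager center (`u` lateral, `v` vertical/superior).
#' @examples
#' geom <- beam_geometry()
#' project_point(c(10, 0, 0), 0, geom)  # magnified by sdd/sad
#' @export
project_point <- function(points, theta_deg, geom) {
  m <- as_point3(points, "points")
  n <- nrow(m)
  if (!(length(theta_deg) %in% c(1L, n))) {
    abort("`theta_deg` must have length 1 or one angle per point.")
  }
  fr <- beam_frame_components(rep_len(theta_deg, n))
  u <- fr$a_lr * m[, 1] + fr$a_ap * m[, 3]
  v <- m[, 2]
  w <- fr$c_lr * m[, 1] + fr$c_ap * m[, 3]
  bad <- w >= geom$sad
  if (any(bad)) {
    abort(sprintf(
      "%d point(s) at or behind the source (depth w >= sad = %g mm); cannot project.",
      sum(bad), geom$sad))
  }
  s <- geom$sdd / (geom$sad - w)
  tibble(u_mm = u * s, v_mm = v * s)
}

#' Back-project imager coordinates to isocenter scale
#'
#' Inverse of the in-plane part of [project_point()]: rescales imager-plane
#' coordinates to the resolved room coordinates `(a . p, b . p)` assuming the
#' point lies at depth `depth_mm` toward the source. With the default
#' `depth_mm = 0` this is the fixed nominal-magnification approximation used
#' to turn 2D segmentations into observations for the 3D fit.
#'
#' @param uv A length-2 numeric `c(u, v)`, an n x 2 matrix, or a data frame
#'   with columns `u_mm`, `v_mm` (imager-plane mm).
#' @param theta_deg Gantry angle(s), degrees (kept for interface symmetry;
#'   the rescaling itself is angle-independent).
#' @param geom A [beam_geometry()].
#' @param depth_mm Assumed depth toward the source, mm; must be `< sad`.
#' @return A tibble with columns `u_mm`, `v_mm` at isocenter scale.
#' @export
backproject_resolved <- function(uv, theta_deg, geom, depth_mm = 0) {
  if (is.data.frame(uv)) {
    if (!all(c("u_mm", "v_mm") %in% names(uv))) {
      abort("`uv` data frame needs columns u_mm, v_mm.")
    }
    m <- cbind(uv$u_mm, uv$v_mm)
  } else if (is.numeric(uv) && length(uv) == 2) {
    m <- matrix(uv, nrow = 1)
  } else if (is.matrix(uv) && ncol(uv) == 2) {
    m <- uv
  } else {
    abort("`uv` must be length-2 numeric, an n x 2 matrix, or a data frame with u_mm/v_mm.")
  }
  if (any(depth_mm >= geom$sad)) {
    abort(sprintf("`depth_mm` must be < sad = %g mm.", geom$sad))
  }
  s <- (geom$sad - depth_mm) / geom$sdd
  tibble(u_mm = m[, 1] * s, v_mm = m[, 2] * s)
}

#' Convert between imager mm and pixel coordinates
#'
#' Pixel coordinates are 1-based `(col, row)` with column increasing along
#' +u (resolved lateral) and row increasing downward, i.e. toward inferior;
#' the imager center is at `((ncol + 1) / 2, (nrow + 1) / 2)`.
#'
#' @param uv Tibble/data frame with `u_mm`, `v_mm` (or length-2 numeric).
#' @param geom A [beam_geometry()].
#' @return `imager_mm_to_px()`: tibble with `col_px`, `row_px` (fractional
#'   pixels); `imager_px_to_mm()`: tibble with `u_mm`, `v_mm`.
#' @export
imager_mm_to_px <- function(uv, geom) {
  if (is.numeric(uv) && length(uv) == 2) uv <- tibble(u_mm = uv[1], v_mm = uv[2])
  cx <- (geom$imager_size[1] + 1) / 2
  cy <- (geom$imager_size[2] + 1) / 2
  tibble(
    col_px = cx + uv$u_mm / geom$pixel_spacing,
    row_px = cy - uv$v_mm / geom$pixel_spacing
  )
}

#' @rdname imager_mm_to_px
#' @param colrow Tibble/data frame with `col_px`, `row_px` (or length-2 numeric).
#' @export
imager_px_to_mm <- function(colrow, geom) {
  if (is.numeric(colrow) && length(colrow) == 2) {
    colrow <- tibble(col_px = colrow[1], row_px = colrow[2])
  }
  cx <- (geom$imager_size[1] + 1) / 2
  cy <- (geom$imager_size[2] + 1) / 2
  tibble(
    u_mm = (colrow$col_px - cx) * geom$pixel_spacing,
    v_mm = (cy - colrow$row_px) * geom$pixel_spacing
  )
}

#' Projection metadata for a scan
#'
#' One row per projection: ordinal index, gantry angle and acquisition time.
#' The default emulates a typical CBCT acquisition: 368 projections uniformly
#' spaced over a full arc in 60 s.
#'
#' @param n_projections Number of projections.
#' @param arc_start_deg,arc_span_deg Start angle and signed arc span, degrees.
#'   Angles are `arc_start + arc_span * (0:(n-1)) / n` (half-open arc).
#' @param duration_s Scan duration, seconds; times are uniform over
#'   `[0, duration_s)`.
#' @return A tibble with columns `index` (0-based), `gantry_deg`, `time_s`.
#' @export
projection_meta <- function(n_projections = 368, arc_start_deg = 0,
                            arc_span_deg = 360, duration_s = 60) {
  stopifnot(n_projections >= 1, duration_s > 0)
  k <- seq_len(n_projections) - 1L
  tibble(
    index = k,
    gantry_deg = arc_start_deg + arc_span_deg * k / n_projections,
    time_s = duration_s * k / n_projections
  )
}

validate_projection_meta <- function(metas) {
  need <- c("index", "gantry_deg", "time_s")
  if (!is.data.frame(metas) || !all(need %in% names(metas))) {
    abort("projection metadata needs columns index, gantry_deg, time_s.")
  }
  if (nrow(metas) == 0) abort("projection metadata is empty.")
  if (anyDuplicated(metas$index) || is.unsorted(metas$index)) {
    abort("projection indices must be unique and ordered.")
  }
  if (is.unsorted(metas$time_s)) abort("projection times must be non-decreasing.")
  invisible(metas)
}

#' Read or write an acquisition-geometry descriptor
#'
#' The descriptor is JSON with keys `sad_mm`, `sdd_mm`, `pixel_spacing_mm`,
#' `imager_size_px` (2 integers), `angles_deg` (one per projection) and
#' optional `times_s`. Missing keys are rejected by name.
#'
#' @param path Path to the JSON file.
#' @return `read_geometry()`: a list with elements `geom` (a
#'   [beam_geometry()]) and `metas` (a [projection_meta()] tibble; if
#'   `times_s` is absent, times default to a 60 s uniform scan).
#' @export
read_geometry <- function(path) {
  if (!file.exists(path)) abort(sprintf("geometry file not found: %s", path))
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("sad_mm", "sdd_mm", "pixel_spacing_mm", "imager_size_px", "angles_deg")
  missing <- setdiff(need, names(j))
  if (length(missing)) {
    abort(sprintf("geometry descriptor is missing key(s): %s",
                  paste(missing, collapse = ", ")))
  }
  geom <- beam_geometry(sad = j$sad_mm, sdd = j$sdd_mm,
                        pixel_spacing = j$pixel_spacing_mm,
                        imager_size = j$imager_size_px)
  n <- length(j$angles_deg)
  times <- j$times_s %||% (60 * (seq_len(n) - 1) / n)
  if (length(times) != n) {
    abort(sprintf("times_s has %d entries but angles_deg has %d.",
                  length(times), n))
  }
  metas <- tibble(index = seq_len(n) - 1L, gantry_deg = as.numeric(j$angles_deg),
                  time_s = as.numeric(times))
  validate_projection_meta(metas)
  list(geom = geom, metas = metas)
}

#' @rdname read_geometry
#' @param geom A [beam_geometry()].
#' @param metas A [projection_meta()] tibble.
#' @export
write_geometry <- function(geom, metas, path) {
  validate_projection_meta(metas)
  jsonlite::write_json(
    list(sad_mm = geom$sad, sdd_mm = geom$sdd,
         pixel_spacing_mm = geom$pixel_spacing,
         imager_size_px = geom$imager_size,
         angles_deg = metas$gantry_deg, times_s = metas$time_s),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
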
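# Per-projection 2D lead-tip localization: search-region extraction around
# the forward-projected planning position, cylinder template bank with 5
# degree rotations and multiple scales, and normalized cross-correlation
# matching. NCC is computed exactly (Pearson over the template footprint)
# via an im2col patch matrix and BLAS matrix products, so one patch matrix
# per frame serves the whole bank.

SEARCH_REGION_SIZE <- 70L

#' Expected 2D position of the planning tip
#'
#' Forward-projects the planning 3D tip coordinate onto the imager at a
#' gantry angle and returns pixel coordinates; this centers the search
#' region for each projection.
#'
#' @param planning_tip A [lead_tip_model()] or a length-3 numeric
#'   `c(lr, si, ap)` mm.
#' @param theta_deg Gantry angle(s), degrees.
#' @param geom A [beam_geometry()].
#' @return A tibble with columns `col_px`, `row_px` (fractional pixels).
#' @export
expected_2d_position <- function(planning_tip, theta_deg, geom) {
  p <- if (inherits(planning_tip, "lead_tip_model")) {
    planning_tip$planning_position
  } else {
    planning_tip
  }
  pts <- matrix(as.numeric(p), nrow = length(theta_deg), ncol = 3, byrow = TRUE)
  uv <- project_point(pts, theta_deg, geom)
  px <- imager_mm_to_px(uv, geom)
  nc <- geom$imager_size[1]; nr <- geom$imager_size[2]
  bad <- px$col_px < 1 | px$col_px > nc | px$row_px < 1 | px$row_px > nr
  if (any(bad)) {
    abort(sprintf(
      "planning tip projects outside the imager for %d angle(s) (first: %g deg).",
      sum(bad), theta_deg[which(bad)[1]]))
  }
  px
}

#' Extract a search region around an expected position
#'
#' Crops a fixed 70 x 70 pixel window centered at the rounded expected
#' position. If the centered window would cross the image border it is
#' shifted to stay fully inside (no padding), and the recorded origin maps
#' region-local coordinates back to the imager exactly:
#' `imager = origin + local - 1`.
#'
#' @param image Projection image matrix (rows x cols).
#' @param center_px Expected position, `c(col, row)` or a one-row tibble with
#'   `col_px`, `row_px`.
#' @param size Window size in pixels (default 70).
#' @return An object of class `search_region`: list with `pixels`
#'   (size x size matrix), `origin` (`c(col, row)` of the top-left pixel,
#'   1-based imager coordinates).
#' @export
extract_search_region <- function(image, center_px, size = SEARCH_REGION_SIZE) {
  if (is.data.frame(center_px)) center_px <- c(center_px$col_px[1], center_px$row_px[1])
  nr <- nrow(image); nc <- ncol(image)
  if (nr < size || nc < size) {
    abort(sprintf("image (%d x %d) is smaller than the %d x %d search region.",
                  nr, nc, size, size))
  }
  half <- size %/% 2
  c0 <- round(center_px[1]) - half
  r0 <- round(center_px[2]) - half
  c0 <- min(max(1, c0), nc - size + 1)
  r0 <- min(max(1, r0), nr - size + 1)
  structure(
    list(pixels = image[r0:(r0 + size - 1), c0:(c0 + size - 1)],
         origin = c(col = c0, row = r0)),
    class = "search_region"
  )
}

#' Build the cylinder template bank for one projection angle
#'
#' The base template is the noiseless chord-length projection of the lead
#' cylinder as seen at gantry angle `theta_deg` (same renderer as the
#' phantom). The bank holds in-plane rotations of the base at consecutive 5
#' degree offsets symmetric about the planning orientation -- 8 rotations for
#' DIBH, 20 for FB/AC/HFV -- each at isotropic scales 0.9, 1.0 and 1.1.
#' Every template is rendered analytically (the cylinder axis is rotated in
#' the imager plane before projection) on a shared canvas sized to the
#' largest footprint plus a 2-pixel margin.
#'
#' @param lead A [lead_tip_model()].
#' @param theta_deg Gantry angle, degrees.
#' @param geom A [beam_geometry()].
#' @param mode Motion-management mode (`"DIBH"` uses 8 rotations; `"FB"`,
#'   `"AC"`, `"HFV"` use 20).
#' @param n_rotations Override the mode's rotation count.
#' @param rotation_step_deg Rotation increment, degrees (default 5).
#' @param scales Isotropic scale factors applied to the cylinder dimensions.
#' @param supersample Anti-aliasing factor passed to the renderer.
#' @return An object of class `template_bank`: list with `templates` (list of
#'   matrices, one canvas size), `meta` (tibble `rot_deg`, `scale`,
#'   `centroid_col`, `centroid_row`, ordered by matching priority), `dims`,
#'   `theta_deg`, `mode`.
#' @export
build_template_bank <- function(lead, theta_deg, geom,
                                mode = c("FB", "DIBH", "AC", "HFV"),
                                n_rotations = NULL, rotation_step_deg = 5,
                                scales = c(0.9, 1, 1.1), supersample = 1L) {
  mode <- match.arg(mode)
  n_rot <- n_rotations %||% (if (mode == "DIBH") 8L else 20L)
  offsets <- (seq_len(n_rot) - 1 - (n_rot - 1) / 2) * rotation_step_deg

  axis_beam <- room_to_beam_dir(lead$axis, theta_deg)
  # Shared canvas: largest scaled footprint + 2 px margin.
  half_mm <- (lead$length / 2 + lead$radius) * max(scales)
  half_px <- ceiling(half_mm * magnification(geom) / geom$pixel_spacing) + 2L
  dim_px <- 2L * half_px + 1L
  if (dim_px >= SEARCH_REGION_SIZE) {
    abort(sprintf(
      "template canvas (%d px) is not smaller than the %d px search region; lead too large for this geometry.",
      dim_px, SEARCH_REGION_SIZE))
  }
  ctr <- (dim_px + 1) / 2

  grid <- tidyr::expand_grid(rot_deg = offsets, scale = scales)
  # Matching priority: smallest |rotation|, then negative offset first, then
  # scale closest to 1, then smaller scale. Makes tie-breaking deterministic.
  grid <- dplyr::arrange(grid, abs(.data$rot_deg), .data$rot_deg,
                         abs(.data$scale - 1), .data$scale)

  templates <- vector("list", nrow(grid))
  cen <- matrix(NA_real_, nrow(grid), 2)
  for (i in seq_len(nrow(grid))) {
    d <- grid$rot_deg[i] * pi / 180
    s <- grid$scale[i]
    ax <- c(axis_beam[1] * cos(d) - axis_beam[2] * sin(d),
            axis_beam[1] * sin(d) + axis_beam[2] * cos(d),
            axis_beam[3])
    tpl <- render_cylinder_canvas(ax, lead$radius * s, lead$length / 2 * s,
                                  lead$contrast, center_px = c(ctr, ctr),
                                  dims_px = c(dim_px, dim_px), geom = geom,
                                  supersample = supersample)
    if (max(tpl) - min(tpl) <= 0) {
      abort(sprintf(
        "degenerate template (zero variance) at rotation %g deg, scale %g.",
        grid$rot_deg[i], s))
    }
    templates[[i]] <- tpl
    cen[i, ] <- footprint_centroid(tpl)
  }
  structure(
    list(templates = templates,
         meta = dplyr::mutate(grid, centroid_col = cen[, 1],
                              centroid_row = cen[, 2]),
         dims = c(dim_px, dim_px), theta_deg = theta_deg, mode = mode),
    class = "template_bank"
  )
}

#' @export
print.template_bank <- function(x, ...) {
  cat(sprintf("<template_bank> %d templates (%d x %d px) at gantry %g deg\n",
              length(x$templates), x$dims[1], x$dims[2], x$theta_deg))
  invisible(x)
}

# Intensity-weighted centroid (col, row) of the above-threshold footprint.
footprint_centroid <- function(img, rel_threshold = 1e-9) {
  w <- img
  w[w <= rel_threshold * max(img)] <- 0
  tot <- sum(w)
  c(sum(rep(seq_len(ncol(img)), each = nrow(img)) * w) / tot,
    sum(rep(seq_len(nrow(img)), times = ncol(img)) * w) / tot)
}

# im2col: linear indices of every valid placement's patch. Placements are
# ordered row-major (placement row varies slowest is FALSE: row-major index
# = (r - 1) * n_col_placements + c, so c varies fastest). Columns follow R's
# column-major template vectorization. Cached per (region dims, template
# dims) pair since the grids never change within a scan.
.im2col_cache <- new.env(parent = emptyenv())

im2col_indices <- function(region_dim, template_dim) {
  key <- paste(region_dim[1], region_dim[2], template_dim[1], template_dim[2],
               sep = "x")
  hit <- .im2col_cache[[key]]
  if (!is.null(hit)) return(hit)
  nr <- region_dim[1]
  tr <- template_dim[1]; tc <- template_dim[2]
  n_pr <- region_dim[1] - tr + 1L
  n_pc <- region_dim[2] - tc + 1L
  pr <- rep(seq_len(n_pr), each = n_pc)   # row-major placement order
  pc <- rep(seq_len(n_pc), times = n_pr)
  base <- pr + (pc - 1L) * nr
  di <- rep(seq_len(tr) - 1L, times = tc) # column-major within template
  dj <- rep(seq_len(tc) - 1L, each = tr)
  off <- di + dj * nr
  out <- list(idx = outer(base, off, `+`), n_pr = n_pr, n_pc = n_pc,
              pr = pr, pc = pc)
  .im2col_cache[[key]] <- out
  out
}

# Exact sliding Pearson correlation of one or more equally-sized templates
# against a region. Returns Np x k score matrix (placements row-major) plus
# the placement grid. Zero-variance patches score 0 for every template.
ncc_scores <- function(region, templates) {
  tdim <- dim(templates[[1]])
  rdim <- dim(region)
  if (!(tdim[1] < rdim[1] && tdim[2] < rdim[2])) {
    abort(sprintf(
      "template (%d x %d) must be strictly smaller than the region (%d x %d).",
      tdim[1], tdim[2], rdim[1], rdim[2]))
  }
  g <- im2col_indices(rdim, tdim)
  r0 <- region - mean(region)            # Pearson-invariant; conditions sums
  patch <- matrix(r0[g$idx], nrow = nrow(g$idx))
  n <- prod(tdim)
  s1 <- rowSums(patch)
  s2 <- rowSums(patch * patch)
  var_p <- s2 - s1^2 / n
  flat <- var_p <= 1e-12 * s2            # constant patches (incl. all-zero)
  var_p[flat] <- Inf

  tmat <- vapply(templates, function(tt) {
    v <- as.vector(tt)
    v - mean(v)
  }, numeric(n))
  sst <- colSums(tmat * tmat)
  if (any(sst <= 0)) abort("template with zero intensity variance.")

  num <- patch %*% tmat
  scores <- sweep(num / sqrt(var_p), 2, sqrt(sst), `/`)
  scores[flat, ] <- 0
  list(scores = scores, n_pr = g$n_pr, n_pc = g$n_pc, pr = g$pr, pc = g$pc)
}

#' Sliding normalized cross-correlation map
#'
#' Pearson correlation between the template and the covered region patch at
#' every valid placement, both mean-subtracted and unit-normalized over the
#' template footprint. Placements where the patch has zero variance score 0.
#'
#' @param region Region image matrix, or a `search_region`.
#' @param template Template matrix, strictly smaller than the region in both
#'   dimensions.
#' @return A numeric matrix of size `(nrow(region) - nrow(template) + 1) x
#'   (ncol(region) - ncol(template) + 1)`; entry `[r, c]` is the correlation
#'   with the template's top-left pixel at region pixel `(r, c)`. Values lie
#'   in `[-1, 1]`.
#' @export
ncc_map <- function(region, template) {
  if (inherits(region, "search_region")) region <- region$pixels
  sc <- ncc_scores(region, list(template))
  matrix(sc$scores[, 1], nrow = sc$n_pr, ncol = sc$n_pc, byrow = TRUE)
}

#' Match a template bank against a search region
#'
#' Finds the global best normalized cross-correlation over all placements,
#' rotations and scales. Exact score ties are broken by smallest absolute
#' rotation offset, then scale closest to 1, then smallest row-major
#' placement index. The reported centroid is the intensity-weighted centroid
#' of the winning template's footprint placed at the winning position, in
#' imager pixel coordinates.
#'
#' @param region A `search_region` from [extract_search_region()].
#' @param bank A [build_template_bank()] result.
#' @return A one-row tibble: `col_px`, `row_px` (centroid), `ncc`, `rot_deg`,
#'   `scale`.
#' @export
match_template <- function(region, bank) {
  if (!inherits(region, "search_region")) {
    abort("`region` must be a search_region (see extract_search_region()).")
  }
  if (length(bank$templates) == 0) abort("empty template bank.")
  sc <- ncc_scores(region$pixels, bank$templates)
  best <- max(sc$scores)
  hits <- which(sc$scores == best, arr.ind = TRUE)
  # bank meta is already in priority order; placements are row-major rows.
  j <- min(hits[, 2])
  p <- min(hits[hits[, 2] == j, 1])
  meta <- bank$meta[j, ]
  tibble(
    col_px = unname(region$origin["col"]) + (sc$pc[p] - 1) + meta$centroid_col - 1,
    row_px = unname(region$origin["row"]) + (sc$pr[p] - 1) + meta$centroid_row - 1,
    ncc = best, rot_deg = meta$rot_deg, scale = meta$scale
  )
}

#' Segment a full projection stack
#'
#' Runs the 2D localization over every projection: forward-projects the
#' planning position, extracts the 70 x 70 search region, builds the
#' angle-specific template bank and records the best NCC match.
#'
#' @param frames List of projection matrices (or a `lead_scan`).
#' @param metas A [projection_meta()] tibble, one row per frame.
#' @param geom A [beam_geometry()].
#' @param lead A [lead_tip_model()] carrying the planning position and the
#'   cylinder geometry.
#' @param mode Motion-management mode; sets the rotation count.
#' @param min_ncc Optional visibility threshold: matches scoring below it are
#'   flagged `visible = FALSE` (no threshold by default; every frame emits a
#'   match plus its score).
#' @param ... Passed to [build_template_bank()].
#' @return A tibble with one row per projection: `index`, `gantry_deg`,
#'   `col_px`, `row_px`, `ncc`, `rot_deg`, `scale`, `visible`, `accepted`
#'   (`NA` until filtered).
#' @export
segment_scan <- function(frames, metas = NULL, geom = NULL, lead = NULL,
                         mode = c("FB", "DIBH", "AC", "HFV"),
                         min_ncc = NULL, ...) {
  if (inherits(frames, "lead_scan")) {
    scan <- frames
    metas <- metas %||% scan$metas
    geom <- geom %||% scan$geom
    lead <- lead %||% scan$lead
    frames <- scan$frames
  }
  mode <- match.arg(mode)
  validate_projection_meta(metas)
  if (length(frames) != nrow(metas)) {
    abort(sprintf("stack has %d frames but metadata lists %d projections.",
                  length(frames), nrow(metas)))
  }
  expected <- expected_2d_position(lead, metas$gantry_deg, geom)
  rows <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    res <- tryCatch({
      region <- extract_search_region(frames[[i]], c(expected$col_px[i],
                                                     expected$row_px[i]))
      bank <- build_template_bank(lead, metas$gantry_deg[i], geom, mode, ...)
      match_template(region, bank)
    }, error = function(e) {
      abort(sprintf("segmentation failed at frame index %d (gantry %g deg): %s",
                    metas$index[i], metas$gantry_deg[i], conditionMessage(e)))
    })
    rows[[i]] <- res
  }
  out <- dplyr::bind_rows(rows)
  tibble(
    index = metas$index, gantry_deg = metas$gantry_deg,
    col_px = out$col_px, row_px = out$row_px, ncc = out$ncc,
    rot_deg = out$rot_deg, scale = out$scale,
    visible = if (is.null(min_ncc)) TRUE else out$ncc >= min_ncc,
    accepted = NA
  )
}
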
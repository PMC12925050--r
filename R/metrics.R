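# Evaluation quantities: 2D segmentation success against ground truth,
# motion-displacement percentile summaries, 3D estimation error fractions,
# and the exact Wilcoxon signed-rank comparison of filtered vs raw errors.

axis_percentiles <- function(values, probs = c(0.05, 0.5, 0.95)) {
  quantile(values, probs, names = FALSE, type = 7)
}

#' 2D segmentation success against ground truth
#'
#' Per-frame signed errors between segmented centroids and the ground-truth
#' 2D projections, in mm (pixel difference times pixel spacing). A frame is
#' successful when the absolute error is strictly below the threshold in
#' BOTH the lateral (x) and vertical (y) direction.
#'
#' @param segs Segmentations tibble (`index`, `col_px`, `row_px`).
#' @param truth_2d Ground-truth tibble (`index`, `u_px`, `v_px`).
#' @param geom A [beam_geometry()] (supplies the pixel spacing).
#' @param threshold_mm Success threshold, mm (default 2, the planning-CT
#'   slice thickness).
#' @return A list of class `segmentation_success`: `fraction` (successes /
#'   evaluated frames), `n`, `per_axis` (tibble of 5th/50th/95th error
#'   percentiles per axis, mm), `errors` (per-frame tibble with `err_x_mm`,
#'   `err_y_mm`, `success`).
#' @export
segmentation_success <- function(segs, truth_2d, geom, threshold_mm = 2) {
  d <- dplyr::inner_join(
    dplyr::select(segs, "index", "col_px", "row_px"),
    dplyr::select(truth_2d, "index", "u_px", "v_px"),
    by = "index"
  )
  if (nrow(d) == 0) abort("no overlapping frame indices between segmentations and truth.")
  sp <- geom$pixel_spacing
  d <- dplyr::mutate(
    d,
    err_x_mm = (.data$col_px - .data$u_px) * sp,
    err_y_mm = (.data$v_px - .data$row_px) * sp,  # v points superior (up)
    success = abs(.data$err_x_mm) < threshold_mm &
      abs(.data$err_y_mm) < threshold_mm
  )
  per_axis <- tibble(
    axis = c("x", "y"),
    p5_mm = c(axis_percentiles(d$err_x_mm)[1], axis_percentiles(d$err_y_mm)[1]),
    median_mm = c(axis_percentiles(d$err_x_mm)[2], axis_percentiles(d$err_y_mm)[2]),
    p95_mm = c(axis_percentiles(d$err_x_mm)[3], axis_percentiles(d$err_y_mm)[3])
  )
  structure(
    list(fraction = mean(d$success), n = nrow(d), threshold_mm = threshold_mm,
         per_axis = per_axis, errors = d),
    class = "segmentation_success"
  )
}

#' @export
print.segmentation_success <- function(x, ...) {
  cat(sprintf("<segmentation_success> %.1f%% of %d frames within %g mm (both axes)\n",
              100 * x$fraction, x$n, x$threshold_mm))
  invisible(x)
}

#' Motion-displacement summary of a trajectory
#'
#' The scan-mean position is subtracted per axis; motion displacement is the
#' absolute deviation from that mean. Summaries are the 5th percentile,
#' median and 95th percentile of the displacement per axis (linear
#' interpolation between order statistics), which excludes the top and
#' bottom 5% of values from the reported range.
#'
#' @param traj Trajectory tibble with `lr_mm`, `si_mm`, `ap_mm` (at least 2
#'   rows).
#' @return A tibble with columns `axis` (`lr`, `si`, `ap`), `p5_mm`,
#'   `median_mm`, `p95_mm`.
#' @export
displacement_summary <- function(traj) {
  need <- c("lr_mm", "si_mm", "ap_mm")
  if (!is.data.frame(traj) || !all(need %in% names(traj))) {
    abort("`traj` needs columns lr_mm, si_mm, ap_mm.")
  }
  if (nrow(traj) < 2) abort("trajectory needs at least 2 points.")
  purrr::map_dfr(c(lr = "lr_mm", si = "si_mm", ap = "ap_mm"), function(col) {
    x <- traj[[col]]
    disp <- abs(x - mean(x))
    q <- axis_percentiles(disp)
    tibble(p5_mm = q[1], median_mm = q[2], p95_mm = q[3])
  }, .id = "axis")
}

#' 3D estimation errors against a reference trajectory
#'
#' Signed per-axis differences between an estimated trajectory and a
#' reference on their common frames, the fraction of frames with absolute
#' error strictly below the threshold on ALL three axes, and per-axis error
#' percentiles.
#'
#' @param est,ref Trajectory tibbles (`index`, `lr_mm`, `si_mm`, `ap_mm`).
#' @param threshold_mm All-axes success threshold, mm (default 2).
#' @return A list of class `estimation_errors`: `fraction_lt_threshold`,
#'   `n`, `per_axis` (tibble of signed-error percentiles), `errors`
#'   (per-frame tibble `d_lr_mm`, `d_si_mm`, `d_ap_mm`, `within`).
#' @export
estimation_errors <- function(est, ref, threshold_mm = 2) {
  d <- dplyr::inner_join(
    dplyr::select(est, "index", est_lr = "lr_mm", est_si = "si_mm",
                  est_ap = "ap_mm"),
    dplyr::select(ref, "index", ref_lr = "lr_mm", ref_si = "si_mm",
                  ref_ap = "ap_mm"),
    by = "index"
  )
  if (nrow(d) == 0) abort("estimate and reference share no frame indices.")
  d <- dplyr::mutate(
    d,
    d_lr_mm = .data$est_lr - .data$ref_lr,
    d_si_mm = .data$est_si - .data$ref_si,
    d_ap_mm = .data$est_ap - .data$ref_ap,
    within = abs(.data$d_lr_mm) < threshold_mm &
      abs(.data$d_si_mm) < threshold_mm &
      abs(.data$d_ap_mm) < threshold_mm
  )
  per_axis <- purrr::map_dfr(
    c(lr = "d_lr_mm", si = "d_si_mm", ap = "d_ap_mm"),
    function(col) {
      q <- axis_percentiles(d[[col]])
      tibble(p5_mm = q[1], median_mm = q[2], p95_mm = q[3])
    }, .id = "axis")
  structure(
    list(fraction_lt_threshold = mean(d$within), n = nrow(d),
         threshold_mm = threshold_mm, per_axis = per_axis,
         errors = dplyr::select(d, "index", "d_lr_mm", "d_si_mm", "d_ap_mm",
                                "within")),
    class = "estimation_errors"
  )
}

#' @export
print.estimation_errors <- function(x, ...) {
  cat(sprintf("<estimation_errors> %.1f%% of %d frames < %g mm on all axes\n",
              100 * x$fraction_lt_threshold, x$n, x$threshold_mm))
  invisible(x)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Signed-rank statistic with midranks for tied absolute differences; zero
#' differences are dropped. The two-sided p-value is exact (full enumeration
#' of the 2^n sign assignments) for n <= 12 effective pairs, and uses the
#' normal approximation with tie correction (no continuity correction)
#' otherwise. The exact two-sided p doubles the smaller tail probability,
#' capped at 1.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @return A one-row tibble: `statistic` (V, the positive-rank sum),
#'   `p_value`, `n_effective` (pairs after dropping zeros), `method`
#'   (`"exact"` or `"normal"`).
#' @export
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) abort("all paired differences are zero; the test is undefined.")
  r <- rank(abs(d))                     # midranks
  v <- sum(r[d > 0])
  if (n <= 12) {
    # Exact null distribution of V over all sign assignments of the ranks.
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    vs <- as.numeric(signs %*% r)
    p_le <- mean(vs <= v)
    p_ge <- mean(vs >= v)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - mu) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  tibble(statistic = v, p_value = p, n_effective = n, method = method)
}
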
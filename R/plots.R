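# ggplot2 views of the pipeline's result tables.

#' Plot trajectories per axis
#'
#' Faceted LR/SI/AP position vs time (or projection index when no `time_s`
#' column is present). Multiple variants can be overlaid by passing a named
#' list of trajectory tibbles.
#'
#' @param traj A trajectory tibble, or a named list of them (names become
#'   the legend, e.g. `list(truth = ..., filtered = ...)`).
#' @return A ggplot object.
#' @export
plot_trajectory <- function(traj) {
  if (is.data.frame(traj)) traj <- list(estimate = traj)
  d <- purrr::imap_dfr(traj, function(tr, nm) {
    if (is.null(tr)) return(NULL)
    tr <- as_tibble(tr)
    tr$source <- nm
    tr$x <- if ("time_s" %in% names(tr)) tr$time_s else tr$index
    tr
  })
  xlab <- if ("time_s" %in% names(d) && !anyNA(d$x)) "time (s)" else "projection index"
  long <- tidyr::pivot_longer(
    dplyr::select(d, "x", "source", "lr_mm", "si_mm", "ap_mm"),
    c("lr_mm", "si_mm", "ap_mm"), names_to = "axis", values_to = "mm")
  long$axis <- factor(long$axis, levels = c("lr_mm", "si_mm", "ap_mm"),
                      labels = c("LR", "SI", "AP"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$mm,
                                     colour = .data$source)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$axis), scales = "free_y") +
    ggplot2::labs(x = xlab, y = "position (mm)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-projection segmentation scores
#'
#' NCC score vs projection index, colored by the SI-filter decision.
#'
#' @param segs Segmentations tibble (ideally after [filter_scan()]).
#' @return A ggplot object.
#' @export
plot_segmentation_scores <- function(segs) {
  d <- as_tibble(segs)
  if (!"accepted" %in% names(d) || anyNA(d$accepted)) d$accepted <- TRUE
  ggplot2::ggplot(d, ggplot2::aes(x = .data$index, y = .data$ncc,
                                  colour = .data$accepted)) +
    ggplot2::geom_point(size = 0.7) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#2c7fb8",
                                            `FALSE` = "#d95f02"),
                                 labels = c(`TRUE` = "accepted",
                                            `FALSE` = "rejected")) +
    ggplot2::labs(x = "projection index", y = "NCC score", colour = NULL) +
    ggplot2::ylim(-1, 1) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_gaussian_ml ggplot of the fitted per-angle projected mean
#'   with a 2-sigma band, overlaid on the observations (u and v panels).
#' @param object A `gauss_pdf_fit`.
#' @param obs The observations the fit was made from.
#' @param ... Ignored.
#' @export
autoplot.gauss_pdf_fit <- function(object, obs, ...) {
  th <- seq(0, 360, by = 2)
  band <- purrr::map_dfr(th, function(t) {
    pg <- project_gaussian(object, t)
    tibble(gantry_deg = t,
           coord = c("u", "v"),
           mean = pg$mean,
           sd = sqrt(diag(pg$cov)))
  })
  pts <- tidyr::pivot_longer(
    dplyr::select(obs, "gantry_deg", u = "u_mm", v = "v_mm"),
    c("u", "v"), names_to = "coord", values_to = "value")
  ggplot2::ggplot(band, ggplot2::aes(x = .data$gantry_deg)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - 2 * .data$sd,
                                      ymax = .data$mean + 2 * .data$sd),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean), colour = "grey30") +
    ggplot2::geom_point(data = pts, ggplot2::aes(y = .data$value),
                        size = 0.5, colour = "#2c7fb8") +
    ggplot2::facet_wrap(ggplot2::vars(.data$coord), ncol = 1,
                        scales = "free_y",
                        labeller = ggplot2::as_labeller(
                          c(u = "resolved lateral u (mm)",
                            v = "vertical v (mm)"))) +
    ggplot2::labs(x = "gantry angle (deg)", y = "isocenter-scale mm") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
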
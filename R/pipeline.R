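# End-to-end driver: segment -> filter -> fit -> estimate -> evaluate.

log_stage <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(fmt, ...))
}

#' Run the full tracking pipeline on a dataset
#'
#' Reads a dataset (projection stack, geometry descriptor, planning tip and
#' optionally ground truth), segments every projection, filters SI
#' outliers, fits the 3D Gaussian, estimates the three trajectory variants
#' -- reference from 2D ground truth, filtered segmentations, raw
#' segmentations -- and evaluates segmentation success, displacement and 3D
#' estimation errors.
#'
#' @param dir Dataset directory as written by [generate_dataset()]
#'   (`projections.tif`, `geometry.json`, `planning_tip.json` and optional
#'   `truth.csv`). Individual paths can be overridden.
#' @param projections,geometry,planning_tip,truth Explicit file paths
#'   (override `dir`). `truth = NULL` and absent file skips evaluation.
#' @param mode Motion-management mode tag (`DIBH`, `FB`, `AC`, `HFV`).
#' @param out_dir If non-`NULL`, artifacts are written there:
#'   `segmentations.csv`, `trajectories.csv` (all variants stacked) and
#'   `report.json`.
#' @param filter_threshold_px,warmup SI-filter settings; see [filter_scan()].
#' @param apply_filter If `FALSE`, the filtered variant is skipped.
#' @param min_ncc Optional NCC visibility threshold; see [segment_scan()].
#' @param meas_var,refine_passes Estimation settings; see
#'   [fit_gaussian_ml()] and [estimate_3d()].
#' @param threshold_mm Success threshold for the 2D and 3D metrics, mm.
#' @param verbose Log per-stage summaries to stderr.
#' @return A list of class `tracking_report`: segmentations, trajectories
#'   (`truth`/`filtered`/`raw` tibbles), fits, and a `metrics` list with
#'   segmentation success, rejection rate, displacement summary and
#'   estimation errors (filtered and raw, plus the Wilcoxon comparison)
#'   when ground truth is available.
#' @export
run_pipeline <- function(dir = NULL, projections = NULL, geometry = NULL,
                         planning_tip = NULL, truth = NULL,
                         mode = c("FB", "DIBH", "AC", "HFV"), out_dir = NULL,
                         filter_threshold_px = 25, warmup = 10,
                         apply_filter = TRUE, min_ncc = NULL, meas_var = 0.25,
                         refine_passes = 1L, threshold_mm = 2,
                         verbose = TRUE) {
  mode <- match.arg(mode)
  pick <- function(explicit, name) {
    p <- explicit %||% (if (!is.null(dir)) file.path(dir, name) else NULL)
    p
  }
  projections <- pick(projections, "projections.tif")
  geometry <- pick(geometry, "geometry.json")
  planning_tip <- pick(planning_tip, "planning_tip.json")
  truth <- pick(truth, "truth.csv")
  for (p in c(projections, geometry, planning_tip)) {
    if (is.null(p) || !file.exists(p)) {
      abort(sprintf("required input not found: %s", p %||% "(unspecified)"))
    }
  }

  gj <- read_geometry(geometry)
  geom <- gj$geom; metas <- gj$metas
  lead <- read_planning_tip(planning_tip)
  frames <- read_projection_stack(projections)
  if (length(frames) != nrow(metas)) {
    abort(sprintf(
      "stack '%s' has %d frames but the geometry descriptor lists %d angles.",
      projections, length(frames), nrow(metas)))
  }
  log_stage(verbose, "[segment] %d projections, mode %s", length(frames), mode)
  t0 <- proc.time()[3]
  segs <- segment_scan(frames, metas, geom, lead, mode, min_ncc = min_ncc)
  log_stage(verbose, "[segment] done in %.1f s (median NCC %.3f)",
            proc.time()[3] - t0, stats::median(segs$ncc))

  segs <- filter_scan(segs, threshold_px = filter_threshold_px,
                      warmup = warmup)
  rej <- rejection_rate(segs)
  log_stage(verbose, "[filter] rejected %d/%d (%.1f%%)",
            sum(!segs$accepted), nrow(segs), 100 * rej)

  track <- function(rows) {
    obs <- as_observations(rows, geom)
    fit <- fit_gaussian_ml(obs, meas_var = meas_var)
    traj <- estimate_3d(fit, obs, geom, refine_passes = refine_passes)
    list(fit = fit, traj = traj)
  }
  raw <- track(segs)
  log_stage(verbose, "[track/raw] NLL %.1f over %d frames", raw$fit$nll,
            raw$fit$n_obs)
  filtered <- if (apply_filter) track(segs[segs$accepted, ]) else NULL
  if (apply_filter) {
    log_stage(verbose, "[track/filtered] NLL %.1f over %d frames",
              filtered$fit$nll, filtered$fit$n_obs)
  }

  truth_2d <- if (!is.null(truth) && file.exists(truth)) read_truth(truth) else NULL
  reference <- metrics <- NULL
  if (!is.null(truth_2d)) {
    reference <- estimate_from_ground_truth(truth_2d, geom,
                                            refine_passes = refine_passes,
                                            meas_var = meas_var)
    seg_succ <- segmentation_success(segs, truth_2d, geom, threshold_mm)
    seg_succ_filt <- segmentation_success(segs[segs$accepted, ], truth_2d,
                                          geom, threshold_mm)
    disp <- displacement_summary(reference)
    err_raw <- estimation_errors(raw$traj, reference, threshold_mm)
    err_filt <- if (apply_filter) {
      estimation_errors(filtered$traj, reference, threshold_mm)
    } else NULL
    wil <- if (apply_filter) {
      common <- dplyr::inner_join(
        dplyr::select(err_raw$errors, "index", raw_lr = "d_lr_mm",
                      raw_si = "d_si_mm", raw_ap = "d_ap_mm"),
        dplyr::select(err_filt$errors, "index", f_lr = "d_lr_mm",
                      f_si = "d_si_mm", f_ap = "d_ap_mm"),
        by = "index")
      raw_mag <- pmax(abs(common$raw_lr), abs(common$raw_si), abs(common$raw_ap))
      f_mag <- pmax(abs(common$f_lr), abs(common$f_si), abs(common$f_ap))
      tryCatch(wilcoxon_signed_rank(raw_mag, f_mag),
               error = function(e) NULL)   # identical trajectories
    } else NULL
    metrics <- list(
      segmentation_success = seg_succ,
      segmentation_success_filtered = seg_succ_filt,
      rejection_rate = rej,
      displacement = disp,
      errors_filtered = err_filt,
      errors_raw = err_raw,
      wilcoxon_raw_vs_filtered = wil
    )
    log_stage(verbose, "[evaluate] 2D success %.1f%%; 3D <%g mm: %.1f%% raw%s",
              100 * seg_succ$fraction, threshold_mm,
              100 * err_raw$fraction_lt_threshold,
              if (apply_filter) sprintf(", %.1f%% filtered",
                                        100 * err_filt$fraction_lt_threshold)
              else "")
  }

  report <- structure(
    list(segmentations = segs,
         trajectories = list(truth = reference,
                             filtered = if (apply_filter) filtered$traj else NULL,
                             raw = raw$traj),
         fits = list(filtered = if (apply_filter) filtered$fit else NULL,
                     raw = raw$fit,
                     truth = if (!is.null(reference)) attr(reference, "fit")
                             else NULL),
         metrics = metrics, mode = mode, geom = geom),
    class = "tracking_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.tracking_report <- function(x, ...) {
  cat(sprintf("<tracking_report> mode %s, %d projections\n", x$mode,
              nrow(x$segmentations)))
  if (!is.null(x$metrics)) {
    m <- x$metrics
    cat(sprintf("  2D success %.1f%% (filtered %.1f%%), rejection %.1f%%\n",
                100 * m$segmentation_success$fraction,
                100 * m$segmentation_success_filtered$fraction,
                100 * m$rejection_rate))
    if (!is.null(m$errors_filtered)) {
      cat(sprintf("  3D errors < %g mm: %.1f%% filtered, %.1f%% raw\n",
                  m$errors_filtered$threshold_mm,
                  100 * m$errors_filtered$fraction_lt_threshold,
                  100 * m$errors_raw$fraction_lt_threshold))
    }
  }
  invisible(x)
}

# Serialize the report's artifacts: CSVs plus a JSON summary.
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_segmentations(report$segmentations,
                      file.path(out_dir, "segmentations.csv"))
  trajs <- purrr::imap(report$trajectories, function(tr, src) {
    if (is.null(tr)) return(NULL)
    tr$source <- src
    dplyr::select(tr, dplyr::all_of(TRAJ_HEADER))
  })
  readr::write_csv(dplyr::bind_rows(trajs),
                   file.path(out_dir, "trajectories.csv"))
  m <- report$metrics
  if (!is.null(m)) {
    jsonlite::write_json(
      list(
        mode = report$mode,
        n_projections = nrow(report$segmentations),
        rejection_rate = m$rejection_rate,
        segmentation_success = list(
          fraction = m$segmentation_success$fraction,
          fraction_filtered = m$segmentation_success_filtered$fraction,
          threshold_mm = m$segmentation_success$threshold_mm,
          per_axis = m$segmentation_success$per_axis),
        displacement = m$displacement,
        estimation_errors = list(
          fraction_lt_threshold_filtered =
            if (!is.null(m$errors_filtered)) m$errors_filtered$fraction_lt_threshold,
          fraction_lt_threshold_raw = m$errors_raw$fraction_lt_threshold,
          per_axis_filtered =
            if (!is.null(m$errors_filtered)) m$errors_filtered$per_axis,
          per_axis_raw = m$errors_raw$per_axis),
        wilcoxon_raw_vs_filtered = m$wilcoxon_raw_vs_filtered
      ),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "rows")
  }
  invisible(out_dir)
}
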
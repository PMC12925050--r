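# 2D -> 3D conversion. Each accepted 2D segmentation is an observation of
# the target's resolved coordinates (lateral u along the rotating a-axis,
# vertical v along SI) at isocenter scale. A single 3D Gaussian over target
# position is fitted by maximum likelihood to all observations of a scan;
# each frame's unresolved depth is then the conditional mean of the Gaussian
# given that frame's (u, v).

SIGMA_FLOOR <- 1e-4  # mm^2, variance floor on the diagonal of Sigma

#' Turn segmentations into 2D observations
#'
#' Converts segmentation pixel centroids to imager-plane mm and back-projects
#' them to isocenter scale at the nominal magnification, producing the inputs
#' of the maximum-likelihood fit. Also works on ground-truth tables (columns
#' `u_px`, `v_px`) to build the reference trajectory.
#'
#' @param segs Tibble with `index`, `gantry_deg` and either `col_px`/`row_px`
#'   (segmentations) or `u_px`/`v_px` (ground truth).
#' @param geom A [beam_geometry()].
#' @return A tibble: `index`, `gantry_deg`, `u_img_mm`, `v_img_mm`
#'   (imager plane) and `u_mm`, `v_mm` (isocenter scale).
#' @export
as_observations <- function(segs, geom) {
  if (!all(c("index", "gantry_deg") %in% names(segs))) {
    abort("`segs` needs `index` and `gantry_deg` columns.")
  }
  cr <- if (all(c("col_px", "row_px") %in% names(segs))) {
    tibble(col_px = segs$col_px, row_px = segs$row_px)
  } else if (all(c("u_px", "v_px") %in% names(segs))) {
    tibble(col_px = segs$u_px, row_px = segs$v_px)
  } else {
    abort("`segs` needs col_px/row_px (or u_px/v_px) columns.")
  }
  img <- imager_px_to_mm(cr, geom)
  iso <- backproject_resolved(img, segs$gantry_deg, geom, depth_mm = 0)
  tibble(
    index = segs$index, gantry_deg = segs$gantry_deg,
    u_img_mm = img$u_mm, v_img_mm = img$v_mm,
    u_mm = iso$u_mm, v_mm = iso$v_mm
  )
}

# Sigma = L L' + floor * I from the 6 factor parameters
# (log-diagonal l1..l3, off-diagonal l21, l31, l32).
sigma_from_par <- function(par6) {
  L <- diag(exp(par6[1:3]))
  L[2, 1] <- par6[4]; L[3, 1] <- par6[5]; L[3, 2] <- par6[6]
  L %*% t(L) + SIGMA_FLOOR * diag(3)
}

#' Marginal of the 3D position Gaussian on the imager-resolved plane
#'
#' Projects the fitted 3D Gaussian onto the resolved (u, v) coordinates at
#' gantry angle `theta_deg`: mean `(a'mu, b'mu)` and covariance
#' `[[a'Sa, a'Sb], [b'Sa, b'Sb]] + meas_var * I`, where `a`, `b` are the
#' beam-frame resolved axes and `meas_var` the isotropic measurement-noise
#' variance.
#'
#' @param params A `gauss_pdf_fit` (from [fit_gaussian_ml()]) or a list with
#'   `mu` (3-vector mm), `sigma` (3 x 3 mm^2) and optionally `meas_var`.
#' @param theta_deg Gantry angle, degrees.
#' @return A list with `mean` (length 2) and `cov` (2 x 2).
#' @export
project_gaussian <- function(params, theta_deg) {
  mu <- params$mu; S <- params$sigma
  mv <- params$meas_var %||% 0
  fr <- beam_frame(theta_deg)
  H <- unname(fr[c("a", "b"), ])
  list(mean = as.numeric(H %*% mu),
       cov = unname(H %*% S %*% t(H)) + mv * diag(2))
}

# Vectorized NLL over observations; obs needs gantry_deg, u_mm, v_mm.
nll_terms <- function(mu, S, mv, obs) {
  fr <- beam_frame_components(obs$gantry_deg)
  ca <- fr$a_lr; sa <- fr$a_ap
  c11 <- S[1, 1] * ca^2 + 2 * S[1, 3] * ca * sa + S[3, 3] * sa^2 + mv
  c12 <- S[1, 2] * ca + S[2, 3] * sa
  c22 <- S[2, 2] + mv
  det <- c11 * c22 - c12^2
  ru <- obs$u_mm - (ca * mu[1] + sa * mu[3])
  rv <- obs$v_mm - mu[2]
  quad <- (c22 * ru^2 - 2 * c12 * ru * rv + c11 * rv^2) / det
  0.5 * (2 * log(2 * pi) + log(det) + quad)
}

#' Negative log-likelihood of 2D observations under a 3D Gaussian
#'
#' Sum over observations of the bivariate normal negative log density of
#' `(u, v)` under the Gaussian's marginal at each observation's gantry angle
#' (including the log-determinant term).
#'
#' @inheritParams project_gaussian
#' @param obs Observations tibble from [as_observations()].
#' @return A scalar.
#' @export
negative_log_likelihood <- function(params, obs) {
  mv <- params$meas_var %||% 0
  sum(nll_terms(params$mu, params$sigma, mv, obs))
}

#' Maximum-likelihood fit of the 3D position Gaussian
#'
#' Fits mean and covariance of the 3D target-position distribution to the
#' scan's 2D observations by quasi-Newton (BFGS) minimization of the
#' negative log-likelihood. The covariance is parameterized by a
#' lower-triangular factor with log-diagonal (9 parameters total), which
#' keeps it positive semidefinite without constraints; a variance floor of
#' 1e-4 mm^2 is added to the diagonal. Initialization: `mu_si` from the mean
#' vertical coordinate, `(mu_lr, mu_ap)` by least squares of
#' `u = cos(theta) mu_lr + sin(theta) mu_ap`, and `Sigma = 25 mm^2 * I`.
#'
#' @param obs Observations tibble from [as_observations()] (accepted frames
#'   only); needs at least 2 distinct gantry angles. A warning is issued when
#'   the observations span less than 30 degrees of arc, where the depth
#'   direction is barely resolved.
#' @param meas_var Isotropic measurement-noise variance added to the
#'   projected covariance, mm^2. Default 0.25 (about half-pixel noise at
#'   isocenter scale).
#' @param fix_offdiag If `TRUE`, freeze the cross-covariances at zero and fit
#'   6 parameters.
#' @param max_iter Maximum BFGS iterations.
#' @return An object of class `gauss_pdf_fit`: list with `mu` (named
#'   3-vector), `sigma` (3 x 3), `meas_var`, `nll`, `n_obs`, `convergence`,
#'   `counts`, `arc_span_deg`.
#' @export
fit_gaussian_ml <- function(obs, meas_var = 0.25, fix_offdiag = FALSE,
                            max_iter = 500) {
  if (!is.data.frame(obs) || nrow(obs) == 0) abort("no observations to fit.")
  need <- c("gantry_deg", "u_mm", "v_mm")
  if (!all(need %in% names(obs))) {
    abort("`obs` needs columns gantry_deg, u_mm, v_mm (see as_observations()).")
  }
  ang <- sort(unique(obs$gantry_deg %% 360))
  if (length(ang) < 2) {
    abort("observations from a single gantry angle: the depth axis is unidentifiable.")
  }
  # Arc span on the circle: 360 minus the largest angular gap.
  gaps <- diff(c(ang, ang[1] + 360))
  span <- 360 - max(gaps)
  if (span < 30) {
    warn(sprintf(
      "observations span only %.1f degrees of gantry arc; depth variance is weakly identified.",
      span))
  }

  fr <- beam_frame_components(obs$gantry_deg)
  X <- cbind(fr$a_lr, fr$a_ap)
  mu_la <- qr.solve(crossprod(X), crossprod(X, obs$u_mm))
  mu0 <- c(mu_la[1], mean(obs$v_mm), mu_la[2])
  par0 <- c(mu0, rep(log(5), 3), rep(0, 3))  # Sigma init = 25 mm^2 * I

  free <- if (fix_offdiag) 1:6 else 1:9
  fn <- function(p) {
    par <- par0
    par[free] <- p
    S <- sigma_from_par(par[4:9])
    sum(nll_terms(par[1:3], S, meas_var, obs))
  }
  fit <- optim(par0[free], fn, method = "BFGS",
               control = list(maxit = max_iter, reltol = 1e-14))
  if (fit$convergence != 0) {
    abort(sprintf(
      "ML fit did not converge (optim code %d) after %d function evaluations; last NLL %.6g.",
      fit$convergence, fit$counts[1], fit$value))
  }
  par <- par0
  par[free] <- fit$par
  mu <- setNames(par[1:3], c("lr", "si", "ap"))
  sigma <- sigma_from_par(par[4:9])
  dimnames(sigma) <- list(c("lr", "si", "ap"), c("lr", "si", "ap"))
  structure(
    list(mu = mu, sigma = sigma, meas_var = meas_var, nll = fit$value,
         n_obs = nrow(obs), convergence = fit$convergence,
         counts = fit$counts, arc_span_deg = span,
         fix_offdiag = fix_offdiag),
    class = "gauss_pdf_fit"
  )
}

#' @export
print.gauss_pdf_fit <- function(x, ...) {
  cat("<gauss_pdf_fit> 3D target-position Gaussian (maximum likelihood)\n")
  cat(sprintf("  mu    (%.2f, %.2f, %.2f) mm (lr, si, ap)\n",
              x$mu[1], x$mu[2], x$mu[3]))
  cat(sprintf("  sigma (%.2f, %.2f, %.2f) mm (marginal sd)\n",
              sqrt(x$sigma[1, 1]), sqrt(x$sigma[2, 2]), sqrt(x$sigma[3, 3])))
  cat(sprintf("  NLL %.3f over %d observations (arc %.0f deg)\n",
              x$nll, x$n_obs, x$arc_span_deg))
  invisible(x)
}

#' @export
tidy.gauss_pdf_fit <- function(x, ...) {
  ax <- c("lr", "si", "ap")
  sig <- x$sigma
  tibble(
    term = c(paste0("mu_", ax),
             paste0("sigma_", ax[c(1, 2, 3, 1, 1, 2)], "_",
                    ax[c(1, 2, 3, 2, 3, 3)])),
    estimate = unname(c(x$mu, sig[1, 1], sig[2, 2], sig[3, 3],
                        sig[1, 2], sig[1, 3], sig[2, 3])),
    unit = c(rep("mm", 3), rep("mm^2", 6))
  )
}

#' @export
glance.gauss_pdf_fit <- function(x, ...) {
  tibble(nll = x$nll, n_obs = x$n_obs, arc_span_deg = x$arc_span_deg,
         meas_var = x$meas_var, converged = x$convergence == 0,
         n_evals = unname(x$counts[1]))
}

#' Per-projection 3D position estimates by Gaussian conditioning
#'
#' For each observation, the resolved coordinates are kept and the
#' unresolved depth toward the source is estimated as the conditional mean
#' of the fitted Gaussian given `(u, v)`:
#' `w = c'mu + k' C^-1 ((u, v) - m_uv)` with `C` the projected covariance
#' (including measurement variance) and `k` the depth cross-covariance.
#' An optional refinement pass re-scales the raw imager measurement with the
#' magnification at the estimated depth and re-conditions.
#'
#' @param fit A `gauss_pdf_fit` from [fit_gaussian_ml()].
#' @param obs Observations tibble from [as_observations()].
#' @param geom A [beam_geometry()]; required for the refinement pass (it
#'   supplies SAD/SDD), otherwise optional.
#' @param refine_passes Number of depth-refinement passes (default 1; 0
#'   keeps the nominal-magnification coordinates untouched). Refinement
#'   needs `geom` and the raw imager coordinates (`u_img_mm`, `v_img_mm`)
#'   in `obs`.
#' @return A tibble: `index`, `gantry_deg`, `lr_mm`, `si_mm`, `ap_mm`.
#' @export
estimate_3d <- function(fit, obs, geom = NULL, refine_passes = 1L) {
  if (!inherits(fit, "gauss_pdf_fit")) abort("`fit` must be a gauss_pdf_fit.")
  if (nrow(obs) == 0) abort("no observations to estimate from.")
  S <- unname(fit$sigma); mu <- unname(fit$mu); mv <- fit$meas_var
  fr <- beam_frame_components(obs$gantry_deg)
  ca <- fr$a_lr; sa <- fr$a_ap        # a = (ca, 0, sa); c = (-sa, 0, ca)

  c11 <- S[1, 1] * ca^2 + 2 * S[1, 3] * ca * sa + S[3, 3] * sa^2 + mv
  c12 <- S[1, 2] * ca + S[2, 3] * sa
  c22 <- S[2, 2] + mv
  det <- c11 * c22 - c12^2
  # k = (a' S c, b' S c); c' S c is not needed for the conditional mean.
  k1 <- -S[1, 1] * ca * sa + S[1, 3] * (ca^2 - sa^2) + S[3, 3] * ca * sa
  k2 <- -S[1, 2] * sa + S[2, 3] * ca
  m_u <- ca * mu[1] + sa * mu[3]
  m_v <- mu[2]
  m_w <- -sa * mu[1] + ca * mu[3]

  condition_depth <- function(u, v) {
    ru <- u - m_u; rv <- v - m_v
    # k' C^-1 r with C^-1 = [[c22, -c12], [-c12, c11]] / det
    m_w + (k1 * (c22 * ru - c12 * rv) + k2 * (c11 * rv - c12 * ru)) / det
  }
  u <- obs$u_mm; v <- obs$v_mm
  w <- condition_depth(u, v)

  can_refine <- refine_passes > 0 && !is.null(geom) &&
    all(c("u_img_mm", "v_img_mm") %in% names(obs))
  if (can_refine) {
    for (pass in seq_len(refine_passes)) {
      s <- (geom$sad - w) / geom$sdd   # magnification at the estimated depth
      u <- obs$u_img_mm * s
      v <- obs$v_img_mm * s
      w <- condition_depth(u, v)
    }
  }
  tibble(
    index = obs$index, gantry_deg = obs$gantry_deg,
    lr_mm = u * ca - w * sa,
    si_mm = v,
    ap_mm = u * sa + w * ca
  )
}

#' Reference trajectory from 2D ground truth
#'
#' Runs the identical fit-and-condition path on ground-truth 2D projections
#' (columns `u_px`, `v_px`), producing the reference trajectory against
#' which segmentation-based estimates are scored.
#'
#' @param truth_2d Ground-truth tibble with `index`, `gantry_deg`, `u_px`,
#'   `v_px` (as written by [generate_dataset()]).
#' @param geom A [beam_geometry()].
#' @param ... Passed to [fit_gaussian_ml()] and [estimate_3d()]
#'   (`meas_var`, `refine_passes`, ...).
#' @param refine_passes See [estimate_3d()].
#' @return A trajectory tibble (`index`, `gantry_deg`, `lr_mm`, `si_mm`,
#'   `ap_mm`) with the `gauss_pdf_fit` attached as attribute `"fit"`.
#' @export
estimate_from_ground_truth <- function(truth_2d, geom, refine_passes = 1L, ...) {
  if (!is.data.frame(truth_2d) || nrow(truth_2d) == 0) {
    abort("`truth_2d` must be a non-empty ground-truth data frame.")
  }
  obs <- as_observations(truth_2d, geom)
  fit <- fit_gaussian_ml(obs, ...)
  traj <- estimate_3d(fit, obs, geom, refine_passes = refine_passes)
  attr(traj, "fit") <- fit
  traj
}
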
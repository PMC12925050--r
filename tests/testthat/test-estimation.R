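# Observations sampled from a known 3D Gaussian at given angles, optionally
# with measurement noise; built directly from the beam-frame algebra.
gaussian_obs <- function(n, mu, sd3, angles = 360 * (0:(n - 1)) / n,
                         noise_sd = 0) {
  p <- cbind(rnorm(n, mu[1], sd3[1]), rnorm(n, mu[2], sd3[2]),
             rnorm(n, mu[3], sd3[3]))
  th <- angles * pi / 180
  tibble::tibble(
    index = seq_len(n) - 1L, gantry_deg = angles,
    u_mm = cos(th) * p[, 1] + sin(th) * p[, 3] + rnorm(n, 0, noise_sd),
    v_mm = p[, 2] + rnorm(n, 0, noise_sd)
  )
}

test_that("projected Gaussian is rotation-invariant for isotropic covariance", {
  params <- list(mu = c(1, 2, 3), sigma = 4 * diag(3), meas_var = 0.25)
  for (th in c(0, 33, 90, 217)) {
    pg <- project_gaussian(params, th)
    expect_equal(pg$cov, 4.25 * diag(2), tolerance = 1e-12)
  }
  pg0 <- project_gaussian(params, 0)
  expect_equal(pg0$mean, c(1, 2))
})

test_that("projected covariance at zero angle picks the lr/si block", {
  S <- matrix(c(9, 1, 2, 1, 25, 3, 2, 3, 4), 3, 3)
  params <- list(mu = c(0, 0, 0), sigma = S, meas_var = 0.25)
  pg <- project_gaussian(params, 0)
  expect_equal(pg$cov, matrix(c(9.25, 1, 1, 25.25), 2, 2), tolerance = 1e-12)
})

test_that("projected covariance matches a Monte-Carlo estimate", {
  set.seed(55)
  S <- random_spd3()
  mu <- c(2, -1, 4)
  th <- 143
  params <- list(mu = mu, sigma = S, meas_var = 0.25)
  pg <- project_gaussian(params, th)
  n <- 1e6
  L <- t(chol(S))
  p <- t(mu + L %*% matrix(rnorm(3 * n), 3))
  f <- beam_frame(th)
  u <- p %*% f["a", ] + rnorm(n, 0, 0.5)
  v <- p %*% f["b", ] + rnorm(n, 0, 0.5)
  expect_equal(pg$mean, c(mean(u), mean(v)), tolerance = 0.02)
  expect_equal(pg$cov, stats::cov(cbind(u, v)), tolerance = 0.02,
               ignore_attr = TRUE)
})

test_that("likelihood reproduces the bivariate normal density", {
  # density at the mode with unit projected covariance: NLL = log(2*pi)
  params <- list(mu = c(1, -2, 3), sigma = 0.75 * diag(3), meas_var = 0.25)
  th <- 67
  pg <- project_gaussian(params, th)
  obs <- tibble::tibble(index = 0L, gantry_deg = th, u_mm = pg$mean[1],
                        v_mm = pg$mean[2])
  expect_equal(negative_log_likelihood(params, obs), log(2 * pi),
               tolerance = 1e-12)
  # additivity
  obs2 <- dplyr::bind_rows(obs, obs)
  expect_equal(negative_log_likelihood(params, obs2), 2 * log(2 * pi),
               tolerance = 1e-12)
})

test_that("likelihood equals independent dense-matrix evaluation", {
  set.seed(56)
  for (i in 1:20) {
    S <- random_spd3()
    mu <- rnorm(3, 0, 3)
    mv <- runif(1, 0.05, 1)
    params <- list(mu = mu, sigma = S, meas_var = mv)
    obs <- gaussian_obs(7, mu, c(2, 3, 1), angles = runif(7, 0, 360))
    # oracle: per-observation 2x2 multivariate normal via solve/determinant
    want <- sum(sapply(seq_len(7), function(k) {
      f <- beam_frame(obs$gantry_deg[k])
      H <- f[c("a", "b"), ]
      C <- H %*% S %*% t(H) + mv * diag(2)
      r <- c(obs$u_mm[k], obs$v_mm[k]) - as.numeric(H %*% mu)
      0.5 * (2 * log(2 * pi) + log(det(C)) + sum(r * solve(C, r)))
    }))
    expect_equal(negative_log_likelihood(params, obs), want,
                 tolerance = 1e-10)
  }
})

test_that("a static noiseless target collapses the fit to its position", {
  set.seed(57)
  n <- 360
  obs <- gaussian_obs(n, c(3, -2, 5), c(0, 0, 0))
  fit <- fit_gaussian_ml(obs)
  expect_equal(unname(fit$mu), c(3, -2, 5), tolerance = 0.05)
  expect_equal(unname(diag(fit$sigma)), rep(1e-4, 3), tolerance = 1e-6)
})

test_that("parameters are recovered from noisy rotational observations", {
  set.seed(58)
  obs <- gaussian_obs(600, c(3, -2, 5), c(3, 5, 2), noise_sd = 0.5)
  fit <- fit_gaussian_ml(obs)
  expect_lt(max(abs(fit$mu - c(3, -2, 5))), 0.5)
  expect_lt(max(abs(sqrt(diag(fit$sigma)) / c(3, 5, 2) - 1)), 0.15)
  expect_true(glance(fit)$converged)
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "mu_si"], unname(fit$mu["si"]))
})

test_that("single-angle input errors and narrow arcs warn", {
  set.seed(59)
  obs1 <- gaussian_obs(20, c(0, 0, 0), c(1, 1, 1), angles = rep(45, 20))
  expect_error(fit_gaussian_ml(obs1), "single gantry angle")
  obs2 <- gaussian_obs(40, c(0, 0, 0), c(1, 1, 1),
                       angles = seq(10, 30, length.out = 40), noise_sd = 0.3)
  expect_warning(fit_gaussian_ml(obs2), "arc")
  expect_error(fit_gaussian_ml(obs1[0, ]), "no observations")
})

test_that("mean estimate tightens as the observation count grows", {
  set.seed(60)
  errs <- sapply(c(100, 400, 1600), function(n) {
    obs <- gaussian_obs(n, c(3, -2, 5), c(2, 3, 1))
    fit <- fit_gaussian_ml(obs)
    max(abs(fit$mu - c(3, -2, 5)))
  })
  expect_true(all(diff(errs) <= 0))
})

test_that("conditioning leaves resolved coordinates untouched without refinement", {
  set.seed(61)
  S <- random_spd3()
  fit <- structure(list(mu = c(lr = 1, si = 2, ap = 3), sigma = S,
                        meas_var = 0.25), class = "gauss_pdf_fit")
  obs <- gaussian_obs(25, c(1, 2, 3), c(2, 2, 2), angles = runif(25, 0, 360))
  est <- estimate_3d(fit, obs, refine_passes = 0)
  for (k in seq_len(25)) {
    f <- beam_frame(obs$gantry_deg[k])
    p <- c(est$lr_mm[k], est$si_mm[k], est$ap_mm[k])
    expect_equal(sum(f["a", ] * p), obs$u_mm[k], tolerance = 1e-10)
    expect_equal(sum(f["b", ] * p), obs$v_mm[k], tolerance = 1e-10)
  }
})

test_that("an observation at the projected mean estimates mu itself", {
  params <- structure(list(mu = c(lr = 2, si = -1, ap = 4), sigma = 3 * diag(3),
                           meas_var = 0.25), class = "gauss_pdf_fit")
  th <- 112
  pg <- project_gaussian(params, th)
  obs <- tibble::tibble(index = 0L, gantry_deg = th, u_mm = pg$mean[1],
                        v_mm = pg$mean[2])
  est <- estimate_3d(params, obs, refine_passes = 0)
  expect_equal(c(est$lr_mm, est$si_mm, est$ap_mm), unname(params$mu),
               tolerance = 1e-10)
})

test_that("conditional depth matches 1D quadrature along the observation ray", {
  set.seed(62)
  for (i in 1:20) {
    S <- random_spd3()
    mu <- rnorm(3, 0, 4)
    mv <- 0.25
    th <- runif(1, 0, 360)
    y <- rnorm(2, 0, 4)
    fit <- structure(list(mu = setNames(mu, c("lr", "si", "ap")), sigma = S,
                          meas_var = mv), class = "gauss_pdf_fit")
    obs <- tibble::tibble(index = 0L, gantry_deg = th, u_mm = y[1], v_mm = y[2])
    est <- estimate_3d(fit, obs, refine_passes = 0)
    f <- beam_frame(th)
    w_impl <- sum(f["c", ] * c(est$lr_mm, est$si_mm, est$ap_mm))
    Sb <- f %*% S %*% t(f) + diag(c(mv, mv, 0))
    mb <- as.numeric(f %*% mu)
    dens <- function(w) sapply(w, function(wi) {
      z <- c(y, wi) - mb
      exp(-0.5 * sum(z * solve(Sb, z)))
    })
    lo <- mb[3] - 20 * sqrt(Sb[3, 3]); hi <- mb[3] + 20 * sqrt(Sb[3, 3])
    den <- integrate(dens, lo, hi, rel.tol = 1e-12, abs.tol = 0,
                     subdivisions = 400L)$value
    num <- integrate(function(w) w * dens(w), lo, hi, rel.tol = 1e-12,
                     abs.tol = 0, subdivisions = 400L)$value
    expect_equal(w_impl, num / den, tolerance = 1e-8)
  }
})

test_that("rotating the acquisition rotates the fit equivariantly", {
  set.seed(63)
  n <- 300
  angles <- 360 * (0:(n - 1)) / n
  p <- cbind(rnorm(n, 3, 2), rnorm(n, -2, 3), rnorm(n, 5, 1.5))
  noise <- cbind(rnorm(n, 0, 0.3), rnorm(n, 0, 0.3))
  th <- angles * pi / 180
  u <- cos(th) * p[, 1] + sin(th) * p[, 3] + noise[, 1]
  v <- p[, 2] + noise[, 2]
  mkobs <- function(shift) {
    tibble::tibble(index = seq_len(n) - 1L, gantry_deg = angles + shift,
                   u_mm = u, v_mm = v)
  }
  f0 <- fit_gaussian_ml(mkobs(0))
  delta <- 40 * pi / 180
  f1 <- fit_gaussian_ml(mkobs(40))
  # the same measurements tagged with shifted angles describe a target
  # rotated by the same angle about the SI axis
  R <- matrix(c(cos(delta), 0, sin(delta), 0, 1, 0,
                -sin(delta), 0, cos(delta)), 3, 3)
  expect_equal(unname(f1$mu), as.numeric(R %*% f0$mu), tolerance = 0.01)
  expect_equal(unname(f1$sigma), R %*% unname(f0$sigma) %*% t(R),
               tolerance = 0.02)
})

test_that("full pipeline on a noiseless breathing phantom stays below 1 mm RMSE", {
  geom <- beam_geometry()
  lead <- lead_tip_model(planning_position = c(3, -2, 5))
  metas <- projection_meta(180)
  model <- motion_model("FB", resp_amplitude = c(2, 8, 3),
                        cardiac_amplitude = c(0, 0, 0))
  traj <- simulate_trajectory(metas, model, lead)
  uv <- project_point(traj, traj$gantry_deg, geom)
  px <- imager_mm_to_px(uv, geom)
  truth <- dplyr::mutate(traj, u_px = px$col_px, v_px = px$row_px)
  est <- estimate_from_ground_truth(truth, geom)
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  expect_lt(rmse(est$lr_mm, traj$lr_mm), 1)
  expect_lt(rmse(est$si_mm, traj$si_mm), 1)
  expect_lt(rmse(est$ap_mm, traj$ap_mm), 1)
})

test_that("reference from exact 2D truth beats the segmentation-based estimate", {
  scan <- small_static_scan(n = 60, noise_sd = 0.4, seed = 2)
  truth3d <- dplyr::select(scan$truth, "index", "lr_mm", "si_mm", "ap_mm")
  est1 <- estimate_from_ground_truth(scan$truth, scan$geom)
  segs <- segment_scan(scan)
  obs <- as_observations(segs, scan$geom)
  fit <- fit_gaussian_ml(obs)
  est2 <- estimate_3d(fit, obs, scan$geom)
  err <- function(est) {
    e <- estimation_errors(est, truth3d)
    mean(abs(e$errors$d_lr_mm) + abs(e$errors$d_si_mm) + abs(e$errors$d_ap_mm))
  }
  expect_lte(err(est1), err(est2) + 1e-9)
  # shared code path: same input gives identical output
  again <- estimate_from_ground_truth(scan$truth, scan$geom)
  expect_equal(est1$ap_mm, again$ap_mm, tolerance = 1e-12)
})
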
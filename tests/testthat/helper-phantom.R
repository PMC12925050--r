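# Shared fixture builders. Small geometries keep rendering cheap; the
# acceptance tests use the full-size defaults.

small_geometry <- function() {
  beam_geometry(imager_size = c(160L, 160L))
}

static_model <- function(mode = "FB") {
  motion_model(mode, resp_amplitude = c(0, 0, 0),
               cardiac_amplitude = c(0, 0, 0))
}

# A small noiseless scan of a static tip, enough for end-to-end checks.
small_static_scan <- function(n = 24, tip = c(3, -2, 5), noise_sd = 0,
                              seed = 1L) {
  simulate_scan(projection_meta(n), static_model(),
                lead_tip_model(planning_position = tip),
                small_geometry(), noise_sd = noise_sd, seed = seed)
}

# Random symmetric positive-definite 3x3 matrix.
random_spd3 <- function(jitter = 0.5) {
  A <- matrix(rnorm(9), 3)
  A %*% t(A) + jitter * diag(3)
}

expect_tibble_cols <- function(x, cols) {
  expect_s3_class(x, "tbl_df")
  expect_true(all(cols %in% names(x)))
}
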
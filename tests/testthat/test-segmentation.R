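# Double-loop Pearson oracle for sliding NCC, independent of the package's
# im2col implementation.
ncc_oracle <- function(region, template) {
  tr <- nrow(template); tc <- ncol(template)
  out <- matrix(0, nrow(region) - tr + 1, ncol(region) - tc + 1)
  tv <- as.vector(template)
  for (r in seq_len(nrow(out))) {
    for (cl in seq_len(ncol(out))) {
      patch <- as.vector(region[r:(r + tr - 1), cl:(cl + tc - 1)])
      if (stats::var(patch) == 0) next
      out[r, cl] <- stats::cor(patch, tv)
    }
  }
  out
}

test_that("expected 2D position reduces to the forward projection", {
  geom <- small_geometry()
  iso <- expected_2d_position(c(0, 0, 0), 77, geom)
  expect_equal(iso$col_px, (geom$imager_size[1] + 1) / 2)
  expect_equal(iso$row_px, (geom$imager_size[2] + 1) / 2)
  lead <- lead_tip_model(planning_position = c(4, -1, 2))
  set.seed(21)
  for (th in runif(10, 0, 360)) {
    got <- expected_2d_position(lead, th, geom)
    want <- imager_mm_to_px(project_point(c(4, -1, 2), th, geom), geom)
    expect_equal(got$col_px, want$col_px, tolerance = 1e-10)
    expect_equal(got$row_px, want$row_px, tolerance = 1e-10)
  }
})

test_that("search region crops 70x70 and records an exact origin", {
  img <- matrix(rnorm(768 * 1024), 768, 1024)
  reg <- extract_search_region(img, c(512, 384))
  expect_equal(dim(reg$pixels), c(70L, 70L))
  expect_equal(unname(reg$origin), c(512 - 35, 384 - 35))
  # boundary policy: shift to fit, never pad
  edge <- extract_search_region(img, c(10, 384))
  expect_equal(unname(edge$origin["col"]), 1)
  expect_equal(dim(edge$pixels), c(70L, 70L))
  far <- extract_search_region(img, c(1020, 760))
  expect_equal(unname(far$origin), c(1024 - 69, 768 - 69))
  # region-local -> imager round trip
  local <- c(17, 43)  # (col, row) within the crop
  expect_equal(reg$pixels[local[2], local[1]],
               img[reg$origin["row"] + local[2] - 1,
                   reg$origin["col"] + local[1] - 1])
  expect_error(extract_search_region(matrix(0, 50, 90), c(25, 25)), "smaller")
})

test_that("template bank has the mode-specific size and 5-degree spacing", {
  geom <- beam_geometry()
  lead <- lead_tip_model()
  dibh <- build_template_bank(lead, 30, geom, "DIBH")
  fb <- build_template_bank(lead, 30, geom, "FB")
  expect_equal(length(dibh$templates), 8 * 3)
  expect_equal(length(fb$templates), 20 * 3)
  offs <- sort(unique(fb$meta$rot_deg))
  expect_equal(diff(offs), rep(5, 19))
  expect_equal(offs, -offs[length(offs):1])  # symmetric about planning
  expect_equal(sort(unique(fb$meta$scale)), c(0.9, 1, 1.1))
  expect_true(all(sapply(fb$templates, function(t) sd(t) > 0)))
  expect_true(all(dim(fb$templates[[1]]) < 70))
})

test_that("rotation 0 at scale 1 reproduces the base rendering", {
  geom <- beam_geometry()
  lead <- lead_tip_model()
  # odd rotation count puts a 0-degree offset in the bank
  bank <- build_template_bank(lead, 55, geom, "FB", n_rotations = 5)
  i0 <- which(bank$meta$rot_deg == 0 & bank$meta$scale == 1)
  base <- leadtrack:::render_cylinder_canvas(
    leadtrack:::room_to_beam_dir(lead$axis, 55), lead$radius, lead$length / 2,
    lead$contrast, center_px = rep((bank$dims[1] + 1) / 2, 2),
    dims_px = bank$dims, geom = geom)
  expect_equal(bank$templates[[i0]], base, tolerance = 1e-12)
})

test_that("template elongation reflects the cylinder aspect ratio", {
  geom <- beam_geometry()
  # axis perpendicular to the beam at theta = 0: in the imager plane;
  # generous dimensions so pixel quantization barely affects the ratio
  lead <- lead_tip_model(radius = 2, length = 16, axis = c(0, 1, 0))
  bank <- build_template_bank(lead, 0, geom, "FB", n_rotations = 1,
                              scales = 1)
  tpl <- bank$templates[[1]]
  rows <- range(which(rowSums(tpl) > 0))
  cols <- range(which(colSums(tpl) > 0))
  elong <- (rows[2] - rows[1] + 1) / (cols[2] - cols[1] + 1)
  expect_equal(elong, lead$length / (2 * lead$radius), tolerance = 0.15)
})

test_that("ncc_map equals the double-loop Pearson oracle", {
  set.seed(31)
  for (i in 1:20) {
    region <- matrix(runif(32 * 32), 32, 32)
    template <- matrix(runif(9 * 9), 9, 9)
    got <- ncc_map(region, template)
    want <- ncc_oracle(region, template)
    expect_equal(dim(got), c(24L, 24L))
    expect_lt(max(abs(got - want)), 1e-10)
  }
})

test_that("ncc_map peaks at 1 on an embedded copy and -1 on its negation", {
  set.seed(32)
  template <- matrix(runif(64), 8, 8)
  region <- matrix(runif(900), 30, 30)
  region[11:18, 21:28] <- template
  m <- ncc_map(region, template)
  expect_equal(max(m), 1, tolerance = 1e-12)
  expect_equal(unname(which(m == max(m), arr.ind = TRUE)[1, ]), c(11, 21))
  region[11:18, 21:28] <- -template
  expect_equal(min(ncc_map(region, template)), -1, tolerance = 1e-12)
})

test_that("ncc is invariant to shifting and positive rescaling of the region", {
  set.seed(33)
  region <- matrix(runif(30 * 30), 30, 30)
  template <- matrix(runif(7 * 7), 7, 7)
  base <- ncc_map(region, template)
  expect_lt(max(abs(ncc_map(region + 17.3, template) - base)), 1e-10)
  expect_lt(max(abs(ncc_map(region * 4.2, template) - base)), 1e-10)
  expect_lt(max(abs(ncc_map(3 - 0.5 * region, template) + base)), 1e-10)
})

test_that("constant patches score zero instead of dividing by zero", {
  region <- matrix(5, 20, 20)
  region[8:12, 8:12] <- matrix(runif(25), 5, 5)
  template <- matrix(runif(16), 4, 4)
  m <- ncc_map(region, template)
  expect_equal(m[1, 1], 0)
  expect_true(all(is.finite(m)))
  expect_error(ncc_map(region, matrix(1, 4, 4)), "zero intensity variance")
  expect_error(ncc_map(matrix(0, 5, 5), matrix(runif(25), 5, 5)), "smaller")
})

test_that("matching ties resolve to the smallest row-major placement", {
  geom <- beam_geometry()
  lead <- lead_tip_model()
  bank <- build_template_bank(lead, 0, geom, "DIBH")
  tpl <- bank$templates[[1]]
  td <- dim(tpl)
  region_px <- matrix(0, 70, 70)
  region_px[3:(2 + td[1]), 5:(4 + td[2])] <- tpl
  region_px[30:(29 + td[1]), 40:(39 + td[2])] <- tpl  # identical second copy
  region <- structure(list(pixels = region_px, origin = c(col = 1, row = 1)),
                      class = "search_region")
  hit <- match_template(region, bank)
  expect_equal(hit$ncc, 1, tolerance = 1e-9)
  # first (row-major) placement wins; centroid lies inside the first copy
  expect_lt(hit$row_px, 20)
  expect_lt(hit$col_px, 25)
  expect_equal(hit$rot_deg, bank$meta$rot_deg[1])
})

test_that("bank-wide best score dominates every single-template score", {
  set.seed(34)
  geom <- small_geometry()
  lead <- lead_tip_model()
  img <- render_projection(c(2, -1, 3), lead$axis, 40, geom, lead,
                           noise_sd = 0.3)
  region <- extract_search_region(
    img, expected_2d_position(c(2, -1, 3), 40, geom))
  bank <- build_template_bank(lead, 40, geom, "FB")
  best <- match_template(region, bank)$ncc
  singles <- sapply(bank$templates, function(t) max(ncc_map(region, t)))
  expect_equal(best, max(singles), tolerance = 1e-12)
  expect_true(all(best >= singles - 1e-12))
})

test_that("matched rotation is the bank element nearest the true rotation", {
  geom <- small_geometry()
  set.seed(35)
  # at theta = 0 the imaging plane is lr-si: an axis (cos, sin, 0) rotated
  # in-plane by delta has in-plane angle exactly delta
  n_ok <- 0; n_tried <- 0
  offsets <- (0:19 - 9.5) * 5
  for (i in 1:80) {
    delta <- runif(1, -15, 15)
    gap <- abs(delta - offsets)
    nearest <- offsets[which.min(gap)]
    # integer-pixel matching cannot resolve rotations close to the midpoint
    # between neighbouring bank offsets; keep poses near an offset
    if (sort(gap)[2] - sort(gap)[1] < 3.5) next
    n_tried <- n_tried + 1
    base <- c(cos(80 * pi / 180), sin(80 * pi / 180), 0)
    d <- delta * pi / 180
    rot_axis <- c(base[1] * cos(d) - base[2] * sin(d),
                  base[1] * sin(d) + base[2] * cos(d), 0)
    lead <- lead_tip_model(axis = base)
    img <- render_projection(c(0, 0, 0), rot_axis, 0, geom, lead)
    region <- extract_search_region(img, expected_2d_position(c(0, 0, 0), 0, geom))
    bank <- build_template_bank(lead, 0, geom, "FB")
    hit <- match_template(region, bank)
    if (hit$rot_deg == nearest) n_ok <- n_ok + 1
  }
  expect_gte(n_tried, 10)
  expect_equal(n_ok, n_tried)
})

test_that("a noiseless static scan is segmented within a pixel everywhere", {
  scan <- small_static_scan(n = 24)
  segs <- segment_scan(scan)
  expect_equal(nrow(segs), 24)
  expect_lt(max(abs(segs$col_px - scan$truth$u_px)), 1)
  expect_lt(max(abs(segs$row_px - scan$truth$v_px)), 1)
  # the symmetric 20-rotation bank has no 0-degree member, so the best
  # score sits slightly below 1 even on noiseless frames
  expect_true(all(segs$ncc > 0.9))
})

test_that("frame/metadata count mismatches are rejected with both counts", {
  scan <- small_static_scan(n = 6)
  expect_error(
    segment_scan(scan$frames[1:5], scan$metas, scan$geom, scan$lead, "FB"),
    "5 frames.*6 projections")
})

test_that("decoy clutter lowers scores or displaces matches on hit frames", {
  geom <- small_geometry()
  lead <- lead_tip_model(planning_position = c(1, 0, 2))
  clutter <- tibble::tibble(offset_u_mm = 0, offset_v_mm = 10, angle_deg = 15,
                            width_mm = 3, length_mm = 12, contrast = 6)
  metas <- projection_meta(12)
  clean <- simulate_scan(metas, static_model(), lead, geom, noise_sd = 0.25,
                         seed = 8)
  dirty <- simulate_scan(metas, static_model(), lead, geom, noise_sd = 0.25,
                         clutter = clutter, seed = 8)
  segs_clean <- segment_scan(clean)
  segs_dirty <- segment_scan(dirty)
  moved <- abs(segs_dirty$row_px - segs_clean$row_px) > 2
  score_drop <- segs_dirty$ncc < segs_clean$ncc - 0.02
  expect_true(any(moved | score_drop))
})

test_that("the visibility threshold flags low-score frames without dropping them", {
  scan <- small_static_scan(n = 8, noise_sd = 3)  # heavy noise, low scores
  segs <- segment_scan(scan, min_ncc = 0.99)
  expect_equal(nrow(segs), 8)
  expect_true(any(!segs$visible))
})
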
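intr <- camera_intrinsics(600, 600, 256, 256)

test_that("back-projection follows the pinhole model", {
  expect_equal(as.numeric(back_project(256, 256, 500, intr)), c(0, 0, 500))
  p <- back_project(316, 256, 600, intr)
  expect_equal(as.numeric(p), c(60, 0, 600))
  # homogeneity: scaling depth scales all coordinates
  p1 <- back_project(300, 310, 400, intr)
  p2 <- back_project(300, 310, 800, intr)
  expect_equal(as.numeric(p2), 2 * as.numeric(p1))
  expect_error(back_project(1, 1, 0, intr), class = "tp_domain_error")
  # re-projection is the identity
  set.seed(2)
  for (i in 1:20) {
    u <- runif(1, 0, 511); v <- runif(1, 0, 511); d <- runif(1, 300, 900)
    uv <- project_point(back_project(u, v, d, intr), intr)
    expect_equal(as.numeric(uv), c(u, v), tolerance = 1e-9)
  }
})

test_that("pixel length and area conversions are metric and homogeneous", {
  K <- camera_intrinsics(500, 500, 256, 256)
  expect_equal(pixel_length_to_mm(c(10, 20), c(10, 20), 500, K), 0)
  expect_equal(pixel_length_to_mm(c(100, 50), c(200, 50), 500, K), 100)
  l1 <- pixel_length_to_mm(c(0, 0), c(30, 40), 400, K)
  expect_equal(pixel_length_to_mm(c(0, 0), c(30, 40), 800, K), 2 * l1)
  expect_equal(pixel_area_to_mm2(100, 500, K), 100)
  expect_equal(pixel_area_to_mm2(0, 500, K), 0)
  expect_equal(pixel_area_to_mm2(7, 1000, K), 4 * pixel_area_to_mm2(7, 500, K))
  expect_error(pixel_area_to_mm2(1, -5, K), class = "tp_domain_error")
})

test_that("minimum-area rectangle is exact on rectangles and disks", {
  m <- rect_mask(128, w = 60, h = 25)
  r <- min_area_rect(m)
  expect_equal(r$width, 60, tolerance = 1)
  expect_equal(r$height, 25, tolerance = 1)

  # same rectangle rotated 30 degrees keeps its side lengths
  s <- 192
  u <- matrix(rep(0:(s - 1), each = s), s, s); v <- matrix(rep(0:(s - 1), times = s), s, s)
  a <- 30 * pi / 180
  xr <- (u - 95.5) * cos(a) + (v - 95.5) * sin(a)
  yr <- -(u - 95.5) * sin(a) + (v - 95.5) * cos(a)
  mrot <- abs(xr) <= 30 & abs(yr) <= 12.5
  rrot <- min_area_rect(mrot)
  expect_equal(rrot$width, 60, tolerance = 1.5)
  expect_equal(rrot$height, 25, tolerance = 1.5)

  d <- min_area_rect(disk_mask(256, 100))
  expect_equal(d$width, 200, tolerance = 2)
  expect_equal(d$height, 200, tolerance = 2)
  expect_error(min_area_rect(matrix(FALSE, 4, 4)), class = "tp_empty_error")
})

test_that("min-area rectangle never exceeds the axis-aligned bounding box", {
  set.seed(21)
  for (i in 1:20) {
    mask <- random_convex_mask(96)
    r <- min_area_rect(mask)
    idx <- which(mask, arr.ind = TRUE)
    aabb <- (diff(range(idx[, 1])) + 1) * (diff(range(idx[, 2])) + 1)
    # oblique pixel-corner spans may exceed the axis-aligned box by up to a
    # half-pixel dilation per side; allow exactly that much slack
    dil <- (sqrt(2) - 1) * (r$width + r$height) / 2 + 3
    expect_lte(r$width * r$height, aabb + dil)
  }
})

test_that("ray casting hits analytic circles at sub-pixel accuracy", {
  m <- disk_mask(256, 100)
  ct <- mask_contour(m)
  origin <- c(127.5, 127.5)
  for (ang in seq(0, 2 * pi, length.out = 13)[-13]) {
    hit <- cast_ray(origin, c(cos(ang), sin(ang)), ct)
    expect_true(hit$hit)
    expect_equal(hit$t, 100, tolerance = 0.5)
    # intersection lies on the contour polyline
    d2seg <- min(colSums((t(ct) - hit$point)^2))
    expect_lt(sqrt(d2seg), 1.5)
  }
  # origin outside pointing away -> miss
  miss <- cast_ray(c(300, 300), c(1, 1), ct)
  expect_false(miss$hit)
})

test_that("metric outputs are invariant to image translation", {
  m1 <- disk_mask(200, 40, cx = 70, cy = 80)
  m2 <- disk_mask(200, 40, cx = 120, cy = 95)
  K1 <- camera_intrinsics(600, 600, 70, 80)
  K2 <- camera_intrinsics(600, 600, 120, 95)
  r1 <- min_area_rect(m1); r2 <- min_area_rect(m2)
  expect_equal(px_len_mm(r1$width, r1$axes["width", ], 500, K1),
               px_len_mm(r2$width, r2$axes["width", ], 500, K2), tolerance = 1e-6)
  expect_equal(pixel_area_to_mm2(sum(m1), 500, K1), pixel_area_to_mm2(sum(m2), 500, K2))
})

test_that("rectangle-equivalent moment extents are sub-pixel accurate", {
  s <- 160
  u <- matrix(rep(0:(s - 1), each = s), s, s); v <- matrix(rep(0:(s - 1), times = s), s, s)
  for (ang_deg in c(0, 10, 37)) {
    a <- ang_deg * pi / 180
    xr <- (u - 79.5) * cos(a) + (v - 79.5) * sin(a)
    yr <- -(u - 79.5) * sin(a) + (v - 79.5) * cos(a)
    m <- abs(xr) <= 55 / 2 & abs(yr) <= 21 / 2
    e <- rect_equivalent_extents(m)
    expect_equal(e$extents[1], 55, tolerance = 0.6)
    expect_equal(e$extents[2], 21, tolerance = 0.6)
  }
})
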
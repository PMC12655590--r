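test_that("locules are enumerated clockwise from 12 o'clock", {
  r <- fx_transverse()
  locs <- enumerate_locules(r$labels$locule_map, r$labels$fruit)
  expect_s3_class(locs, "locule_set")
  expect_length(locs$masks, 6L)
  expect_true(all(diff(locs$angles_deg) > 0))
  expect_true(all(vapply(seq_along(locs$masks), function(j)
    all(locs$masks[[j]] <= r$labels$fruit), logical(1))))   # inside the fruit
  # rotating a 6-fold-symmetric section by 60 degrees preserves the count
  sp60 <- section_spec("transverse", rotation_deg = 60, depth_noise_sd = 0)
  r60 <- render_section(sp60)
  locs60 <- enumerate_locules(r60$labels$locule_map, r60$labels$fruit)
  expect_length(locs60$masks, 6L)
  expect_warning(enumerate_locules(matrix(0L, 32, 32), disk_mask(32, 10)),
                 class = "tp_empty_locules_warning")
})

test_that("mesocarp thickness matches the analytic annulus", {
  # concentric disks: fruit radius 200, locule ring outer radius 150,
  # 0.5 mm/px -> 25 mm of flesh
  K <- camera_intrinsics(1000, 1000, 255.5, 255.5)   # 0.5 mm/px at d = 500
  fruit <- disk_mask(512, 200)
  loc_map <- matrix(0L, 512, 512)
  loc_map[disk_mask(512, 150) & !disk_mask(512, 60)] <- 1L
  locs <- enumerate_locules(loc_map, fruit)
  th <- mesocarp_thickness(fruit, locs, 500, K)
  expect_equal(th$fruit_mean_mm, 25, tolerance = 0.5)
  # zero offset makes all three rays identical
  th0 <- mesocarp_thickness(fruit, locs, 500, K, offset_deg = 0)
  th_central <- th0$per_locule_px
  expect_equal(th0$per_locule_mm, th_central * 0.5, tolerance = 1e-9)
})

test_that("thickness and areas are invariant to image translation", {
  mk <- function(cx, cy) {
    fruit <- disk_mask(300, 90, cx, cy)
    lm <- matrix(0L, 300, 300)
    lm[disk_mask(300, 60, cx, cy) & !disk_mask(300, 25, cx, cy)] <- 1L
    K <- camera_intrinsics(600, 600, cx, cy)
    locs <- enumerate_locules(lm, fruit)
    c(mesocarp_thickness(fruit, locs, 500, K)$fruit_mean_mm,
      locule_areas(locs, 500, K, fruit))
  }
  expect_equal(mk(110, 120), mk(170, 150), tolerance = 1e-6)
})

test_that("locule areas convert pixel counts at the representative depth", {
  r <- fx_transverse()
  locs <- enumerate_locules(r$labels$locule_map, r$labels$fruit)
  K <- r$spec$intrinsics
  areas <- locule_areas(locs, r$spec$plane_depth_mm, K, r$labels$fruit)
  pxcounts <- vapply(locs$masks, sum, numeric(1))
  expect_equal(areas, pxcounts * (600 / K$fx) * (600 / K$fy))
  expect_lte(sum(pxcounts), sum(r$labels$fruit))
  empty <- enumerate_locules(matrix(0L, 32, 32), disk_mask(32, 10)) |> suppressWarnings()
  expect_identical(locule_areas(empty, 500, K, disk_mask(32, 10)), numeric(0))
})

test_that("section colors recover flat tissue paint and stay inside the flesh", {
  r <- fx_transverse()
  locs <- enumerate_locules(r$labels$locule_map, r$labels$fruit)
  cols <- section_colors(r$rgb, r$labels$fruit, locs)
  expect_equal(cols$mesocarp_rgb, r$spec$flesh_rgb, tolerance = 1)
  expect_equal(cols$locule_rgb, r$spec$locule_rgb, tolerance = 1)
  expect_true(all(cols$band_mask <= (r$labels$fruit & r$labels$locule_map == 0)))
  # uniform gray image: mesocarp and locule colors coincide
  gray <- array(0.5, dim(r$rgb))
  cg <- section_colors(gray, r$labels$fruit, locs)
  expect_equal(cg$mesocarp_rgb, cg$locule_rgb, tolerance = 1e-9)
})

test_that("longitudinal measurements resolve axes via the scar and scale to mm", {
  r <- fx_longitudinal()
  m <- measure_longitudinal(r$labels$fruit, r$labels$scar,
                            r$spec$plane_depth_mm, r$spec$intrinsics)
  t <- r$truth
  expect_equal(m$longitudinal_diameter_mm, t$longitudinal_diameter_mm, tolerance = 0.02 * t$longitudinal_diameter_mm)
  expect_equal(m$transverse_diameter_mm, t$transverse_diameter_mm, tolerance = 0.02 * t$transverse_diameter_mm)
  expect_equal(m$shape_index, m$longitudinal_diameter_mm / m$transverse_diameter_mm,
               tolerance = 1e-9)
  expect_equal(m$scar_width_mm, t$scar_width_mm, tolerance = 0.02 * t$scar_width_mm)
  expect_equal(m$scar_depth_mm, t$scar_depth_mm, tolerance = 0.02 * t$scar_depth_mm)
  # a circular fruit has shape index 1 (axis choice immaterial)
  circ <- disk_mask(300, 100)
  scar <- rect_mask(300, w = 40, h = 14, r0 = 55, c0 = 130)
  mc <- measure_longitudinal(circ, scar & circ, 600, camera_intrinsics(900, 900, 149.5, 149.5))
  expect_equal(mc$shape_index, 1, tolerance = 0.02)
  # empty scar: traits omitted with a warning, diameters still reported
  expect_warning(m0 <- measure_longitudinal(r$labels$fruit, matrix(FALSE, 512, 512),
                                            600, r$spec$intrinsics),
                 class = "tp_empty_scar_warning")
  expect_null(m0$scar_width_mm)
  expect_false(is.null(m0$shape_index))
})

test_that("mesocarp thickness decreases as the locule ring grows", {
  vals <- vapply(c(100, 120, 140), function(r1) {
    sp <- section_spec("transverse", locule_r1 = r1, depth_noise_sd = 0)
    r <- render_section(sp)
    locs <- enumerate_locules(r$labels$locule_map, r$labels$fruit)
    mesocarp_thickness(r$labels$fruit, locs, sp$plane_depth_mm,
                       sp$intrinsics)$fruit_mean_mm
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("a full transverse record is internally consistent", {
  r <- fx_transverse()
  rec <- measure_section(r$rgb, r$spec$plane_depth_mm, r$spec$intrinsics,
                         "transverse", r$labels$fruit, r$labels$locule_map,
                         sample_label = "fx", fruit_id = 2L)
  expect_identical(rec$locule_count, length(rec$locule_areas_mm2))
  expect_identical(rec$locule_count, length(rec$mesocarp_thickness_per_locule_mm))
  expect_true(all(rec$locule_areas_mm2 > 0))
  expect_null(rec$shape_index)        # not defined for transverse sections
  expect_identical(rec$fruit_id, 2L)
})
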
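test_that("binarization isolates colored fruit from a white tray", {
  # pure white -> empty mask with warning
  white <- array(1, c(64, 64, 3))
  expect_warning(m <- binarize_section(white), class = "tp_empty_mask_warning")
  expect_false(any(m))

  # red disk of radius 100: area within 2% of pi r^2
  img <- disk_rgb(256, 100)
  m <- binarize_section(img)
  ncomp <- max(EBImage::imageData(EBImage::bwlabel(EBImage::Image(m * 1))))
  expect_equal(ncomp, 1, ignore_attr = TRUE)
  expect_lt(abs(sum(m) - pi * 100^2) / (pi * 100^2), 0.02)

  # two disks separated by more than twice the kernel -> two components
  img2 <- array(250 / 255, c(200, 200, 3))
  for (ch in 1:3) {
    img2[, , ch][disk_mask(200, 35, cx = 55, cy = 100)] <- c(200, 40, 30)[ch] / 255
    img2[, , ch][disk_mask(200, 35, cx = 145, cy = 100)] <- c(200, 40, 30)[ch] / 255
  }
  m2 <- binarize_section(img2)
  ncomp2 <- max(EBImage::imageData(EBImage::bwlabel(EBImage::Image(m2 * 1))))
  expect_equal(ncomp2, 2, ignore_attr = TRUE)
})

test_that("binarization is invariant to background intensity in [230, 255]", {
  masks <- lapply(c(230, 242, 255), function(bg)
    binarize_section(disk_rgb(128, 40, bg = rep(bg, 3))))
  expect_identical(masks[[1]], masks[[2]])
  expect_identical(masks[[1]], masks[[3]])
})

test_that("fruit crops are centered, ordered by reading order, and scale-aware", {
  cfg <- list(tile_size = 96L, min_area = 50L)
  img <- disk_rgb(256, 30, fg = c(200, 40, 30))
  mask <- disk_mask(256, 30)
  crops <- crop_fruits(img, mask, cfg)
  expect_length(crops, 1L)
  # centroid re-centered at the tile center within 1 px
  cm <- mask_centroid(crops[[1]]$mask_tile)
  expect_lt(max(abs(cm - (96 - 1) / 2)), 1)

  # 6 disks in a 2 x 3 grid -> ids 1..6 in reading order
  big <- array(250 / 255, c(300, 400, 3))
  mask6 <- matrix(FALSE, 300, 400)
  centers <- expand.grid(cy = c(80, 220), cx = c(70, 200, 330))
  centers <- centers[order(centers$cy, centers$cx), ]
  for (i in seq_len(6)) {
    dm <- disk_mask2(300, 400, 25, centers$cx[i], centers$cy[i])
    mask6 <- mask6 | dm
    for (ch in 1:3) big[, , ch][dm] <- c(200, 40, 30)[ch] / 255
  }
  crops6 <- crop_fruits(big, mask6, cfg)
  expect_length(crops6, 6L)
  got <- t(vapply(crops6, function(cr) unname(cr$offset) + (96 - 1) / 2, numeric(2)))
  expect_equal(got[, 1], centers$cy, tolerance = 1.5)
  expect_equal(got[, 2], centers$cx, tolerance = 1.5)
  expect_identical(vapply(crops6, `[[`, integer(1), "fruit_id"), 1:6)

  expect_length(crop_fruits(img, matrix(FALSE, 256, 256), cfg), 0L)
})

test_that("crop then reassemble is lossless on component support", {
  cfg <- list(tile_size = 96L, min_area = 50L)
  img <- disk_rgb(256, 30)
  mask <- disk_mask(256, 30)
  crops <- crop_fruits(img, mask, cfg)
  preds <- lapply(crops, function(cr) cr$mask_tile * 1L)
  back <- reassemble(preds, crops, c(256, 256))
  expect_identical(back > 0, mask)

  # oversized component is downscaled and pastes back within 1 px
  cfg2 <- list(tile_size = 64L, min_area = 50L)
  crops2 <- crop_fruits(img, mask, cfg2)
  expect_lt(crops2[[1]]$scale, 1)
  back2 <- reassemble(lapply(crops2, function(cr) cr$mask_tile * 1L), crops2, c(256, 256))
  mism <- sum(xor(back2 > 0, mask))
  border <- sum(mask) - sum(EBImage::imageData(EBImage::erode(EBImage::Image(mask * 1),
                                                              EBImage::makeBrush(5, "disc"))) > 0.5)
  expect_lt(mism, border)              # disagreement confined to a ~1-px rim

  # disjoint tiles never overwrite each other
  t1 <- matrix(1L, 4, 4); t2 <- matrix(2L, 4, 4)
  c1 <- list(offset = c(row = 0, col = 0), region = c(4, 4), scale = 1)
  c2 <- list(offset = c(row = 10, col = 10), region = c(4, 4), scale = 1)
  out <- reassemble(list(t1, t2), list(c1, c2), c(20, 20))
  expect_identical(sum(out == 1L), 16L)
  expect_identical(sum(out == 2L), 16L)
  cbad <- list(offset = c(row = 50, col = 0), region = c(4, 4), scale = 1)
  expect_error(reassemble(list(t1), list(cbad), c(20, 20)), class = "tp_bounds_error")
})

test_that("dataset splitting is deterministic, disjoint and exhaustive", {
  items <- sprintf("img%02d", 1:10)
  sp <- split_dataset(items, c(0.7, 0.2, 0.1), seed = 42)
  expect_length(sp$train, 7L)
  expect_length(sp$val, 2L)
  expect_length(sp$test, 1L)
  expect_setequal(unlist(sp), items)
  expect_length(intersect(sp$train, sp$val), 0L)
  sp2 <- split_dataset(items, c(0.7, 0.2, 0.1), seed = 42)
  expect_identical(sp, sp2)
  expect_error(split_dataset(items, c(0.5, 0.4, 0.2)), class = "tp_format_error")
  expect_error(split_dataset(list("a"), c(0.4, 0.3, 0.3)), class = "tp_format_error")
})

test_that("augmentation transforms image and mask coherently", {
  r <- fixture("aug_section", function()
    render_section(section_spec("transverse", size = 128, a = 50, b = 45,
                                locule_r0 = 14, locule_r1 = 30,
                                intrinsics = camera_intrinsics(900, 900, 63.5, 63.5))))
  tile <- r$rgb; mask <- (r$labels$locule_map > 0) * 1L
  ident <- augment(tile, mask, "eval",
                   params = list(angle = 0, scale = 1, shift = c(0, 0), brightness = 0))
  expect_equal(ident$tile, tile, tolerance = 1e-12)
  expect_identical(ident$mask, mask)

  rot90 <- augment(tile, mask, "eval",
                   params = list(angle = 90, scale = 1, shift = c(0, 0), brightness = 0))
  expect_identical(sum(rot90$mask), sum(mask))

  # pure brightness change never alters the mask
  br <- augment(tile, mask, "train",
                params = list(angle = 0, scale = 1, shift = c(0, 0), brightness = 0.12))
  expect_identical(br$mask, mask)
  expect_gt(mean(br$tile), mean(tile))

  # identical seeds give identical draws; rotation conserves mask area to 2%
  a1 <- augment(tile, mask, "train", seed = 5)
  a2 <- augment(tile, mask, "train", seed = 5)
  expect_identical(a1$tile, a2$tile)
  expect_identical(a1$mask, a2$mask)
  rot <- augment(tile, mask, "eval",
                 params = list(angle = 23, scale = 1, shift = c(0, 0), brightness = 0))
  expect_lt(abs(sum(rot$mask) - sum(mask)) / sum(mask), 0.02)
  # scaling rescales the mask area by scale^2 (within resampling tolerance)
  sc <- augment(tile, mask, "eval",
                params = list(angle = 0, scale = 1.08, shift = c(0, 0), brightness = 0))
  expect_lt(abs(sum(sc$mask) - 1.08^2 * sum(mask)) / sum(mask), 0.05)
})
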
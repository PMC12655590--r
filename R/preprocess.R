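#' Default preprocessing configuration
#'
#' All tunables of the fruit-isolation pipeline: HSV thresholds (fruit
#' tissue is saturated and/or dark against the white tray), morphology
#' kernel size, erosion rounds (with matching restoration dilation so
#' measured extents stay unbiased), Canny thresholds and the minimum
#' component area.
#'
#' @return named list of defaults.
#' @export
preprocess_config <- function() {
  list(sat_min = 0.25, val_max = 0.55,
       kernel_size = 5L, erode_iter = 3L, restore_extent = TRUE,
       canny_sigma = 1.5, canny_low = 0.05, canny_high = 0.15,
       min_area = 200L, tile_size = 512L, seed = 42L)
}

ebi_brush <- function(size) EBImage::makeBrush(size, shape = "disc")

#' Isolate fruit foreground from a tray image
#'
#' Pipeline: HSV threshold (saturation >= `sat_min` OR value <= `val_max`)
#' -> morphological closing -> opening -> Canny edges + filled external
#' contours, unioned with the color mask -> opening -> `erode_iter`
#' erosions, then (by default) the same number of dilations to restore the
#' fruit extent.
#'
#' @param rgb H x W x 3 array in `[0, 1]`.
#' @param config list as from [preprocess_config()] (partial lists are
#'   merged over the defaults).
#' @return logical fruit mask; empty (with a warning) when no foreground
#'   is found.
#' @export
binarize_section <- function(rgb, config = preprocess_config()) {
  cfg <- modifyList(preprocess_config(), config)
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  px <- rbind(as.vector(rgb[, , 1]), as.vector(rgb[, , 2]), as.vector(rgb[, , 3]))
  hsv <- rgb2hsv(px, maxColorValue = 1)
  mask <- matrix(hsv[2, ] >= cfg$sat_min | hsv[3, ] <= cfg$val_max, h, w)
  if (!any(mask)) {
    tp_warn("no foreground found", "tp_empty_mask_warning")
    return(mask)
  }
  br <- ebi_brush(cfg$kernel_size)
  m <- EBImage::closing(EBImage::Image(mask * 1), br)
  m <- EBImage::opening(m, br)
  gray <- 0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
  edges <- canny_edges(gray, cfg$canny_sigma, cfg$canny_low, cfg$canny_high)
  filled <- EBImage::fillHull(EBImage::Image((EBImage::imageData(m) > 0.5) | edges))
  m <- EBImage::opening(filled, br)
  md <- EBImage::imageData(m) > 0.5
  if (cfg$erode_iter > 0) {
    for (i in seq_len(cfg$erode_iter)) md <- EBImage::imageData(EBImage::erode(EBImage::Image(md * 1), br)) > 0.5
    if (isTRUE(cfg$restore_extent))
      for (i in seq_len(cfg$erode_iter)) md <- EBImage::imageData(EBImage::dilate(EBImage::Image(md * 1), br)) > 0.5
  }
  if (!any(md)) tp_warn("no foreground found after morphology", "tp_empty_mask_warning")
  matrix(md, h, w)
}

# Canny edge detector: Gaussian smoothing, Sobel gradients, quantized
# non-maximum suppression, double threshold with hysteresis via connected
# components of the weak-edge map
canny_edges <- function(gray, sigma = 1.5, low = 0.05, high = 0.15) {
  g <- EBImage::imageData(EBImage::gblur(EBImage::Image(gray), sigma))
  sx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
  gx <- EBImage::imageData(EBImage::filter2(EBImage::Image(g), sx))
  gy <- EBImage::imageData(EBImage::filter2(EBImage::Image(g), t(sx)))
  mag <- sqrt(gx^2 + gy^2)
  h <- nrow(g); w <- ncol(g)
  shift <- function(m, dr, dc) {
    out <- matrix(0, h, w)
    rs <- max(1, 1 + dr):min(h, h + dr); cs <- max(1, 1 + dc):min(w, w + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  ang <- atan2(gy, gx)
  sector <- (round(ang / (pi / 4)) %% 4)  # 0:E-W, 1:NE-SW, 2:N-S, 3:NW-SE
  n1 <- shift(mag, 0, 1) * (sector == 0) + shift(mag, 1, 1) * (sector == 1) +
    shift(mag, 1, 0) * (sector == 2) + shift(mag, 1, -1) * (sector == 3)
  n2 <- shift(mag, 0, -1) * (sector == 0) + shift(mag, -1, -1) * (sector == 1) +
    shift(mag, -1, 0) * (sector == 2) + shift(mag, -1, 1) * (sector == 3)
  nms <- mag * (mag >= n1 & mag >= n2)
  strong <- nms > high
  weak <- nms > low
  if (!any(weak)) return(weak)
  lab <- EBImage::bwlabel(EBImage::Image(weak * 1))
  keep <- unique(EBImage::imageData(lab)[strong])
  keep <- keep[keep > 0]
  matrix(EBImage::imageData(lab) %in% keep, h, w)
}

#' Crop per-fruit tiles from a tray image
#'
#' Each connected foreground component above `min_area` becomes one
#' `tile_size` x `tile_size` tile centered on the component centroid, padded
#' with the background color at image borders. Components too large for the
#' tile are downscaled to fit and the scale factor recorded so predictions
#' can be pasted back exactly. Fruit ids follow reading order (top-to-bottom
#' then left-to-right of centroids).
#'
#' @param rgb H x W x 3 array in `[0, 1]`.
#' @param mask logical fruit mask from [binarize_section()].
#' @param config see [preprocess_config()].
#' @param background_rgb border padding color in `[0, 1]`; defaults to the
#'   median border color of `rgb`.
#' @return list of fruit crops: `tile` (array), `mask_tile` (logical),
#'   `offset` (0-based (row, col) of the source region origin), `region`
#'   (source region size, rows x cols), `scale` (<= 1), `fruit_id`.
#' @export
crop_fruits <- function(rgb, mask, config = preprocess_config(), background_rgb = NULL) {
  cfg <- modifyList(preprocess_config(), config)
  ts <- cfg$tile_size
  if (!any(mask)) return(list())
  if (is.null(background_rgb)) {
    border <- rbind(rgb[1, , ], rgb[nrow(mask), , ], rgb[, 1, ], rgb[, ncol(mask), ])
    background_rgb <- apply(border, 2, median)
  }
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  sizes <- tabulate(lab)
  ids <- which(sizes >= cfg$min_area)
  if (!length(ids)) return(list())
  cent <- t(vapply(ids, function(i) {
    idx <- which(lab == i, arr.ind = TRUE)
    c(r = mean(idx[, 1]), c = mean(idx[, 2]),
      er = diff(range(idx[, 1])) + 1, ec = diff(range(idx[, 2])) + 1)
  }, numeric(4)))
  ord <- order(round(cent[, "r"] / 8), cent[, "c"])  # reading order
  ids <- ids[ord]; cent <- cent[ord, , drop = FALSE]
  h <- nrow(mask); w <- ncol(mask)
  out <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    extent <- max(cent[k, "er"], cent[k, "ec"])
    scale <- min(1, (ts - 8) / extent)
    region <- if (scale < 1) ceiling(ts / scale) else ts
    r0 <- round(cent[k, "r"] - 1 - (region - 1) / 2)  # 0-based origin
    c0 <- round(cent[k, "c"] - 1 - (region - 1) / 2)
    tile_rgb <- array(rep(background_rgb, each = region * region), c(region, region, 3))
    tile_mask <- matrix(FALSE, region, region)
    rs <- max(0, r0):min(h - 1, r0 + region - 1)
    cs <- max(0, c0):min(w - 1, c0 + region - 1)
    comp <- lab == ids[k]
    for (ch in 1:3) {
      src <- rgb[rs + 1, cs + 1, ch]
      src[!comp[rs + 1, cs + 1]] <- background_rgb[ch]  # suppress neighbors
      tile_rgb[rs - r0 + 1, cs - c0 + 1, ch] <- src
    }
    tile_mask[rs - r0 + 1, cs - c0 + 1] <- comp[rs + 1, cs + 1]
    if (scale < 1) {
      tile_rgb2 <- array(0, c(ts, ts, 3))
      for (ch in 1:3) tile_rgb2[, , ch] <-
        EBImage::imageData(EBImage::resize(EBImage::Image(tile_rgb[, , ch]), ts, ts))
      tile_mask <- EBImage::imageData(EBImage::resize(EBImage::Image(tile_mask * 1),
                                                      ts, ts, filter = "none")) > 0.5
      tile_rgb <- tile_rgb2
    }
    out[[k]] <- list(tile = tile_rgb, mask_tile = tile_mask,
                     offset = c(row = r0, col = c0),
                     region = c(region, region), scale = scale, fruit_id = k)
  }
  out
}

#' Reassemble tile predictions into the source layout
#'
#' Pastes per-tile label maps back at their recorded offsets, inverting any
#' crop-time downscaling with nearest-neighbor resampling. Where tiles
#' overlap, the higher class index wins (foreground over background).
#'
#' @param tile_preds list of integer label maps (`tile_size` square).
#' @param crops the crop list from [crop_fruits()] (offsets, regions,
#'   scales).
#' @param source_shape `c(rows, cols)` of the original image.
#' @return integer label map of shape `source_shape`.
#' @export
reassemble <- function(tile_preds, crops, source_shape) {
  stopifnot(length(tile_preds) == length(crops))
  h <- source_shape[1]; w <- source_shape[2]
  canvas <- matrix(0L, h, w)
  for (k in seq_along(crops)) {
    cr <- crops[[k]]
    pred <- tile_preds[[k]]
    if (cr$offset[1] >= h || cr$offset[2] >= w ||
        cr$offset[1] + cr$region[1] <= 0 || cr$offset[2] + cr$region[2] <= 0)
      tp_stop("tile offset outside the source image", "tp_bounds_error")
    if (cr$scale < 1) {
      pred <- EBImage::imageData(EBImage::resize(EBImage::Image(pred),
                                                 cr$region[1], cr$region[2],
                                                 filter = "none"))
      pred <- round(pred)
    }
    r0 <- cr$offset[1]; c0 <- cr$offset[2]
    rs <- max(0, r0):min(h - 1, r0 + nrow(pred) - 1)
    cs <- max(0, c0):min(w - 1, c0 + ncol(pred) - 1)
    patch <- pred[rs - r0 + 1, cs - c0 + 1, drop = FALSE]
    cur <- canvas[rs + 1, cs + 1, drop = FALSE]
    canvas[rs + 1, cs + 1] <- pmax(cur, patch)
  }
  storage.mode(canvas) <- "integer"
  canvas
}

#' Deterministic train/val/test split
#'
#' Random partition under a fixed seed: validation and test sizes are the
#' rounded ratio shares, the remainder goes to training; subsets are
#' disjoint and exhaustive.
#'
#' @param items vector or list of items.
#' @param ratios `(train, val, test)` fractions summing to 1.
#' @param seed RNG seed.
#' @return list with `train`, `val`, `test` (same type as `items`).
#' @export
split_dataset <- function(items, ratios = c(0.7, 0.2, 0.1), seed = 42L) {
  if (abs(sum(ratios) - 1) > 1e-9) tp_stop("ratios must sum to 1", "tp_format_error")
  n <- length(items)
  if (n < sum(ratios > 0)) tp_stop("fewer items than subsets", "tp_format_error")
  n_val <- round(n * ratios[2]); n_test <- round(n * ratios[3])
  n_train <- n - n_val - n_test
  set.seed(seed)
  perm <- sample.int(n)
  idx <- list(train = perm[seq_len(n_train)],
              val = perm[n_train + seq_len(n_val)],
              test = perm[n_train + n_val + seq_len(n_test)])
  lapply(idx, function(i) items[sort(i)])
}

#' Augment a tile (and its mask) deterministically
#'
#' Training-role augmentation draws random rotation, scale, crop jitter and
#' brightness shift; evaluation role omits the brightness shift. The mask
#' receives exactly the same geometric transform with nearest-neighbor
#' resampling and is never touched by photometric changes. A fixed seed
#' gives identical output.
#'
#' @param tile H x W x 3 array in `[0, 1]`.
#' @param mask optional integer/logical label map of the same H x W.
#' @param role `"train"` or `"eval"`.
#' @param seed RNG seed.
#' @param params optional explicit list
#'   (`angle`, `scale`, `shift` (row, col), `brightness`) overriding the
#'   random draws; `angle = 0, scale = 1, shift = c(0,0), brightness = 0`
#'   is the identity.
#' @return list with `tile` and (if given) `mask`, plus the realized
#'   `params`.
#' @export
augment <- function(tile, mask = NULL, role = c("train", "eval"), seed = 42L,
                    params = NULL) {
  role <- match.arg(role)
  h <- dim(tile)[1]; w <- dim(tile)[2]
  if (is.null(params)) {
    set.seed(seed)
    params <- list(angle = runif(1, -25, 25), scale = runif(1, 0.9, 1.1),
                   shift = round(runif(2, -0.05, 0.05) * c(h, w)),
                   brightness = if (role == "train") runif(1, -0.15, 0.15) else 0)
  }
  geom_one <- function(m, nearest) {
    img <- EBImage::Image(m)
    filt <- if (nearest) "none" else "bilinear"
    if (params$scale != 1) {
      img <- EBImage::resize(img, round(h * params$scale), round(w * params$scale),
                             filter = filt)
      img <- center_crop_pad(img, h, w)
    }
    if (params$angle != 0)
      img <- EBImage::rotate(img, params$angle, filter = filt,
                             output.dim = c(h, w), bg.col = 0)
    m2 <- EBImage::imageData(img)
    if (any(params$shift != 0)) m2 <- shift_matrix(m2, params$shift[1], params$shift[2])
    m2
  }
  out_tile <- array(0, dim(tile))
  for (ch in 1:3) out_tile[, , ch] <- geom_one(tile[, , ch], nearest = FALSE)
  if (params$brightness != 0)
    out_tile <- pmin(1, pmax(0, out_tile + params$brightness))
  res <- list(tile = out_tile, params = params)
  if (!is.null(mask)) {
    m2 <- round(geom_one(mask + 0, nearest = TRUE))
    storage.mode(m2) <- "integer"
    res$mask <- m2
  }
  res
}

center_crop_pad <- function(img, h, w) {
  m <- EBImage::imageData(img)
  hh <- nrow(m); ww <- ncol(m)
  out <- matrix(0, h, w)
  rs <- seq_len(min(h, hh)); cs <- seq_len(min(w, ww))
  r_src <- floor((hh - length(rs)) / 2) + rs
  c_src <- floor((ww - length(cs)) / 2) + cs
  r_dst <- floor((h - length(rs)) / 2) + rs
  c_dst <- floor((w - length(cs)) / 2) + cs
  out[r_dst, c_dst] <- m[r_src, c_src]
  out
}

shift_matrix <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  rs <- max(1, 1 + dr):min(h, h + dr); cs <- max(1, 1 + dc):min(w, w + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}
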
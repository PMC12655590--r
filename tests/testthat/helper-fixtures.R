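# shared fixtures, built once per test run and cached

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# a clean transverse section with default (4K-scale) geometry, no depth noise
fx_transverse <- function() fixture("transverse", function() {
  render_section(section_spec("transverse", depth_noise_sd = 0))
})

fx_longitudinal <- function() fixture("longitudinal", function() {
  render_section(section_spec("longitudinal", a = 210, b = 170, depth_noise_sd = 0))
})

# filled disk mask of radius r centered in an s x s image
disk_mask <- function(s, r, cx = (s - 1) / 2, cy = (s - 1) / 2) {
  u <- matrix(rep(0:(s - 1), each = s), s, s)
  v <- matrix(rep(0:(s - 1), times = s), s, s)
  (u - cx)^2 + (v - cy)^2 <= r^2
}

# filled axis-aligned rectangle mask (w x h pixels)
rect_mask <- function(s, w, h, r0 = (s - h) %/% 2, c0 = (s - w) %/% 2) {
  m <- matrix(FALSE, s, s)
  m[r0 + seq_len(h), c0 + seq_len(w)] <- TRUE
  m
}

# rgb array of a flat-color disk on a light background
disk_rgb <- function(s, r, fg = c(200, 40, 30), bg = c(250, 250, 250)) {
  m <- disk_mask(s, r)
  a <- array(0, c(s, s, 3))
  for (ch in 1:3) a[, , ch] <- ifelse(m, fg[ch], bg[ch]) / 255
  a
}

# chunky 3-locule fixtures that a lightweight model can overfit pixel-sharp
overfit_fixture <- function(n = 4L, size = 64L) {
  imgs <- vector("list", n); tgts <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- section_spec("transverse", size = size,
                       a = 27 * size / 64, b = 25 * size / 64,
                       locule_count = 3L,
                       locule_r0 = 7 * size / 64, locule_r1 = 19 * size / 64,
                       wedge_half_angle_deg = 38,
                       locule_phase_deg = c(0, 30, 60, 90)[(i - 1L) %% 4L + 1L],
                       intrinsics = camera_intrinsics(450, 450, (size - 1) / 2, (size - 1) / 2),
                       seed = 200L + i)
    r <- render_section(sp)
    imgs[[i]] <- r$rgb
    tgts[[i]] <- (r$labels$locule_map > 0) * 1L
  }
  list(images = imgs, targets = tgts)
}

# tiny network configuration for fast structural/gradient tests
tiny_config <- function(num_classes = 2L) {
  mlla_config("a", num_classes = num_classes,
              embed_dims = c(4L, 4L, 8L, 8L), depths = c(1L, 1L, 1L, 1L),
              num_heads = c(1L, 1L, 2L, 2L), dropout = 0, decoder_dim = 8L)
}

# rasterized random convex polygon mask
random_convex_mask <- function(s, npts = 12L) {
  pts <- cbind(runif(npts, s * 0.15, s * 0.85), runif(npts, s * 0.15, s * 0.85))
  hull <- pts[grDevices::chull(pts[, 1], pts[, 2]), , drop = FALSE]
  rasterize_polygon(hull, c(s, s))
}

# disk mask in a non-square image
disk_mask2 <- function(h, w, r, cx, cy) {
  u <- matrix(rep(0:(w - 1), each = h), h, w)
  v <- matrix(rep(0:(h - 1), times = w), h, w)
  (u - cx)^2 + (v - cy)^2 <= r^2
}
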
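#' Specification of a synthetic tomato section
#'
#' Describes an idealized sectioned tomato on a white tray, imaged top-down
#' by an RGB-D camera: an elliptical silhouette, wedge-shaped locules on a
#' ring (transverse sections), a rectangular stem-scar notch at the top of
#' the long axis (longitudinal sections), flat tissue colors, and a constant
#' true depth plane whose camera measurement is distorted by the inverse of
#' the HDRM parametric bias plus Gaussian noise (so a perfectly calibrated
#' HDRM recovers the true plane).
#'
#' Geometry is in pixels of the rendered image; `a` is the semi-axis along
#' the image u direction before rotation, `b` along v. Defaults emulate a
#' ~70 mm tomato at 600 mm under a 3600 px focal length (the native scale
#' of a 4K RGB-D camera, ~0.17 mm/px), sectioned and laid on a white tray.
#'
#' @param section_kind `"longitudinal"` or `"transverse"`.
#' @param size rendered image side (square), px.
#' @param a,b ellipse semi-axes, px.
#' @param rotation_deg in-plane rotation of the fruit (degrees, clockwise).
#' @param locule_count number of locules (transverse), in `[2, 10]`.
#' @param locule_r0,locule_r1 inner/outer radius of the locule ring, px.
#' @param wedge_half_angle_deg angular half-width of each locule wedge.
#' @param locule_phase_deg angle of locule 1's center, clockwise from
#'   12 o'clock.
#' @param scar_width,scar_depth stem-scar notch size, px (longitudinal).
#' @param scar_inset notch top inset from the fruit apex, px.
#' @param flesh_rgb,locule_rgb,scar_rgb,background_rgb 8-bit colors.
#' @param plane_depth_mm true depth of the section plane, mm.
#' @param bias_coeffs parametric depth-bias coefficients
#'   (`alpha`, `beta`, `phi`, `gamma`).
#' @param gamma_form see [predict_parametric()].
#' @param depth_noise_sd per-pixel Gaussian depth noise, mm.
#' @param intrinsics a [camera_intrinsics()]; default centered, fx = fy = 3600.
#' @param antialias blend RGB edges (label maps stay hard); off by default
#'   so region-mean colors are exact oracles.
#' @param seed RNG seed for the depth noise.
#' @return object of class `section_spec`.
#' @export
section_spec <- function(section_kind = c("transverse", "longitudinal"),
                         size = 512L,
                         a = 210, b = 200,
                         rotation_deg = 0,
                         locule_count = 6L,
                         locule_r0 = 55, locule_r1 = 120,
                         wedge_half_angle_deg = 18,
                         locule_phase_deg = 0,
                         scar_width = 78, scar_depth = 28,
                         scar_inset = 12,
                         flesh_rgb = c(200, 40, 30),
                         locule_rgb = c(240, 180, 60),
                         scar_rgb = c(235, 220, 170),
                         background_rgb = c(250, 250, 250),
                         plane_depth_mm = 600,
                         bias_coeffs = c(alpha = 0.03, beta = 1e-5, phi = 8, gamma = 0.5),
                         gamma_form = "sqrt",
                         depth_noise_sd = 2,
                         intrinsics = NULL,
                         antialias = FALSE,
                         seed = 42L) {
  section_kind <- match.arg(section_kind)
  if (is.null(intrinsics))
    intrinsics <- camera_intrinsics(3600, 3600, (size - 1) / 2, (size - 1) / 2)
  spec <- structure(as.list(environment()), class = "section_spec")
  validate_section_spec(spec)
  spec
}

validate_section_spec <- function(spec) {
  with(spec, {
    if (a <= 0 || b <= 0) tp_stop("ellipse semi-axes must be positive", "tp_spec_error")
    if (max(a, b) * 2 + 4 > size)
      tp_stop("fruit does not fit in the image", "tp_spec_error")
    if (section_kind == "transverse") {
      if (locule_count < 2L || locule_count > 10L)
        tp_stop("locule_count must be in [2, 10]", "tp_spec_error")
      if (locule_r1 >= min(a, b) - 2)
        tp_stop("locule ring must lie inside the fruit", "tp_spec_error")
      if (locule_r0 >= locule_r1)
        tp_stop("locule_r0 must be smaller than locule_r1", "tp_spec_error")
      if (wedge_half_angle_deg * 2 >= 360 / locule_count)
        tp_stop("locule wedges overlap", "tp_spec_error")
    } else {
      half_w_max <- a * sqrt(pmax(0, 1 - ((b - scar_inset) / b)^2))
      if (scar_width / 2 >= half_w_max)
        tp_stop("scar notch wider than the fruit at its inset", "tp_spec_error")
      if (scar_inset + scar_depth >= b)
        tp_stop("scar notch deeper than the fruit", "tp_spec_error")
    }
    if (any(c(flesh_rgb, locule_rgb, scar_rgb, background_rgb) < 0) ||
        any(c(flesh_rgb, locule_rgb, scar_rgb, background_rgb) > 255))
      tp_stop("colors must be valid 8-bit values", "tp_spec_error")
    if (plane_depth_mm <= 0) tp_stop("plane depth must be positive", "tp_spec_error")
  })
  invisible(spec)
}

# ellipse radius (px) along fruit-frame polar angle psi (clockwise from
# 12 o'clock): direction (sin psi, -cos psi) in fruit coordinates
ellipse_radius <- function(psi, a, b) {
  1 / sqrt((sin(psi) / a)^2 + (cos(psi) / b)^2)
}

# numerically invert the parametric bias: d_c such that d_param(d_c) = d_b
invert_parametric <- function(d_b, coeffs, gamma_form = "sqrt") {
  vapply(d_b, function(target) {
    f <- function(x) predict_parametric(x, coeffs, gamma_form) - target
    lo <- max(1e-6, target * 0.3); hi <- target * 2 + 100
    if (f(lo) > 0 || f(hi) < 0)
      tp_stop("bias coefficients not invertible on this range", "tp_spec_error")
    uniroot(f, c(lo, hi), tol = 1e-10)$root
  }, numeric(1))
}

#' Render a synthetic section with exact ground truth
#'
#' Produces the RGB image, the camera depth map (true plane distorted by the
#' inverse parametric bias plus noise, rounded to integer mm), hard label
#' maps, and a ground-truth record computed analytically from the spec
#' (diameters, shape index, scar size, locule areas, mesocarp thickness and
#' colors, all in physical units at the true plane depth).
#'
#' @param spec a [section_spec()].
#' @return list with `rgb` (H x W x 3 in `[0, 1]`), `depth` (integer mm),
#'   `labels` (list: `fruit`, plus `scar` or `locule_map`), `truth`, `spec`.
#' @export
render_section <- function(spec) {
  validate_section_spec(spec)
  s <- spec$size
  cx0 <- (s - 1) / 2; cy0 <- (s - 1) / 2
  u <- matrix(rep(0:(s - 1), each = s), s, s)   # u varies by column
  v <- matrix(rep(0:(s - 1), times = s), s, s)  # v varies by row
  rot <- spec$rotation_deg * pi / 180
  du <- u - cx0; dv <- v - cy0
  xr <- du * cos(rot) + dv * sin(rot)
  yr <- -du * sin(rot) + dv * cos(rot)
  fruit <- (xr / spec$a)^2 + (yr / spec$b)^2 <= 1

  labels <- list(fruit = fruit)
  col_idx <- matrix(0L, s, s)          # 0 bg, 1 flesh, 2 locule, 3 scar
  col_idx[fruit] <- 1L

  if (spec$section_kind == "transverse") {
    rho <- sqrt(xr^2 + yr^2)
    psi <- atan2(xr, -yr)              # clockwise from 12 o'clock
    k <- spec$locule_count
    half <- spec$wedge_half_angle_deg * pi / 180
    phase <- spec$locule_phase_deg * pi / 180
    locule_map <- matrix(0L, s, s)
    for (j in seq_len(k)) {
      phi_j <- phase + (j - 1) * 2 * pi / k
      dpsi <- atan2(sin(psi - phi_j), cos(psi - phi_j))
      wedge <- fruit & rho >= spec$locule_r0 & rho <= spec$locule_r1 & abs(dpsi) <= half
      locule_map[wedge] <- j
    }
    labels$locule_map <- locule_map
    col_idx[locule_map > 0L] <- 2L
  } else {
    scar <- fruit & abs(xr) <= spec$scar_width / 2 &
      yr >= -spec$b + spec$scar_inset &
      yr <= -spec$b + spec$scar_inset + spec$scar_depth
    labels$scar <- scar
    col_idx[scar] <- 3L
  }

  pal <- rbind(spec$background_rgb, spec$flesh_rgb, spec$locule_rgb, spec$scar_rgb) / 255
  rgb <- array(0, c(s, s, 3))
  for (ch in 1:3) rgb[, , ch] <- matrix(pal[col_idx + 1L, ch], s, s)
  if (isTRUE(spec$antialias)) {
    kern <- matrix(1, 3, 3) / 9
    for (ch in 1:3) rgb[, , ch] <- as.matrix(EBImage::filter2(rgb[, , ch], kern))
  }

  set.seed(spec$seed)
  d_c0 <- invert_parametric(spec$plane_depth_mm, spec$bias_coeffs, spec$gamma_form)
  depth <- matrix(round(d_c0 + rnorm(s * s, sd = spec$depth_noise_sd)), s, s)
  depth[depth < 1] <- 1L
  storage.mode(depth) <- "integer"

  truth <- section_truth(spec)
  list(rgb = rgb, depth = depth, labels = labels, truth = truth, spec = spec)
}

# analytic ground truth in physical units (true plane depth)
section_truth <- function(spec) {
  K <- spec$intrinsics; d <- spec$plane_depth_mm
  rot <- spec$rotation_deg * pi / 180
  # absolute image direction of fruit-frame unit direction (sin psi, -cos psi)
  abs_dir <- function(psi) {
    fx <- sin(psi); fy <- -cos(psi)
    c(fx * cos(rot) - fy * sin(rot), fx * sin(rot) + fy * cos(rot))
  }
  ax_u <- abs_dir(pi / 2)   # fruit-frame u axis (a direction)
  ax_v <- abs_dir(pi)       # fruit-frame v axis (b direction), pointing down
  len_a <- px_len_mm(2 * spec$a, ax_u, d, K)
  len_b <- px_len_mm(2 * spec$b, ax_v, d, K)
  truth <- list(section_kind = spec$section_kind,
                plane_depth_mm = d,
                camera_depth_mm = invert_parametric(d, spec$bias_coeffs, spec$gamma_form),
                flesh_rgb = spec$flesh_rgb, locule_rgb = spec$locule_rgb,
                fruit_area_px = pi * spec$a * spec$b)
  if (spec$section_kind == "longitudinal") {
    truth$transverse_diameter_mm <- len_a
    truth$longitudinal_diameter_mm <- len_b
    truth$shape_index <- len_b / len_a
    truth$scar_width_mm <- px_len_mm(spec$scar_width, ax_u, d, K)
    truth$scar_depth_mm <- px_len_mm(spec$scar_depth, ax_v, d, K)
  } else {
    truth$transverse_diameter_mm <- max(len_a, len_b)
    truth$locule_count <- spec$locule_count
    half <- spec$wedge_half_angle_deg * pi / 180
    area_px <- 0.5 * (spec$locule_r1^2 - spec$locule_r0^2) * 2 * half
    truth$locule_areas_mm2 <- rep(area_px * (d / K$fx) * (d / K$fy), spec$locule_count)
    offs <- c(-12, 0, 12) * pi / 180
    per_loc <- vapply(seq_len(spec$locule_count), function(j) {
      phi_j <- spec$locule_phase_deg * pi / 180 + (j - 1) * 2 * pi / spec$locule_count
      vals <- vapply(offs, function(o) {
        if (abs(o) > half) return(NA_real_)  # side ray misses the wedge arc
        psi <- phi_j + o
        t_px <- ellipse_radius(psi, spec$a, spec$b) - spec$locule_r1
        px_len_mm(t_px, abs_dir(psi), d, K)
      }, numeric(1))
      mean(vals, na.rm = TRUE)
    }, numeric(1))
    # order per-locule values the way measurement numbers locules: by
    # image-frame centroid angle, clockwise from 12 o'clock
    img_angle <- (spec$locule_phase_deg + (seq_len(spec$locule_count) - 1) *
                    360 / spec$locule_count + spec$rotation_deg) %% 360
    ord <- order(img_angle)
    truth$locule_angles_deg <- img_angle[ord]
    truth$mesocarp_thickness_per_locule_mm <- per_loc[ord]
    truth$mesocarp_thickness_mm <- mean(per_loc)
  }
  truth
}

#' Generate paired (camera, reference) depth samples
#'
#' Reference depths `d_b` are drawn uniformly on `range_mm`; camera depths
#' are obtained by numerically inverting the parametric bias at
#' `d_b - structure` and adding Gaussian noise, where `structure` is an
#' optional smooth sinusoidal residual surface
#' (`structure_amp * sin(2 pi d_b / structure_period)`) that lies outside
#' the parametric family and is the component the random-forest stage is
#' meant to capture.
#'
#' @param n number of pairs.
#' @param coeffs parametric bias coefficients (`alpha`, `beta`, `phi`,
#'   `gamma`).
#' @param noise_sd Gaussian noise on the camera depth, mm.
#' @param range_mm length-2 range of reference depths, within `(0, 5000]`.
#' @param seed RNG seed.
#' @param gamma_form see [predict_parametric()].
#' @param structure_amp,structure_period smooth non-parametric residual
#'   component (mm; amplitude 0 disables it).
#' @return data.frame with columns `d_c`, `d_b`.
#' @export
make_depth_pairs <- function(n, coeffs = c(alpha = 0.03, beta = 1e-5, phi = 8, gamma = 0.5),
                             noise_sd = 0, range_mm = c(450, 900), seed = 42L,
                             gamma_form = "sqrt",
                             structure_amp = 0, structure_period = 150) {
  if (any(range_mm <= 0) || any(range_mm > 5000))
    tp_stop("range_mm must lie within (0, 5000]", "tp_domain_error")
  set.seed(seed)
  d_b <- runif(n, range_mm[1], range_mm[2])
  target <- d_b - structure_amp * sin(2 * pi * d_b / structure_period)
  d_c <- invert_parametric(target, coeffs, gamma_form) + rnorm(n, sd = noise_sd)
  data.frame(d_c = d_c, d_b = d_b)
}

# randomized but seeded section spec for dataset generation
random_section_spec <- function(kind, size = 128L, seed = 1L, plane_depth_mm = 600,
                                depth_noise_sd = 2) {
  set.seed(seed)
  half_span <- size / 2 - 4
  b <- runif(1, 0.55, 0.85) * half_span
  a <- b * runif(1, 1.0, 1.25)
  a <- min(a, half_span)
  if (kind == "transverse") {
    k <- sample(2:8, 1)
    r1 <- runif(1, 0.55, 0.72) * min(a, b)
    r0 <- runif(1, 0.3, 0.5) * r1
    half_angle <- min(0.75 * 180 / k, 28)
    section_spec("transverse", size = size, a = a, b = b,
                 rotation_deg = runif(1, -30, 30),
                 locule_count = k, locule_r0 = r0, locule_r1 = r1,
                 wedge_half_angle_deg = max(half_angle, 13),
                 locule_phase_deg = runif(1, 0, 360),
                 flesh_rgb = round(c(runif(1, 170, 220), runif(1, 25, 70), runif(1, 20, 60))),
                 locule_rgb = round(c(runif(1, 220, 250), runif(1, 150, 205), runif(1, 40, 90))),
                 plane_depth_mm = plane_depth_mm,
                 depth_noise_sd = depth_noise_sd,
                 intrinsics = camera_intrinsics(3600 * size / 512, 3600 * size / 512,
                                                (size - 1) / 2, (size - 1) / 2),
                 seed = seed)
  } else {
    section_spec("longitudinal", size = size, a = a, b = b,
                 rotation_deg = runif(1, -20, 20),
                 scar_width = runif(1, 0.25, 0.45) * a,
                 scar_depth = runif(1, 0.12, 0.2) * b,
                 scar_inset = 0.08 * b,
                 flesh_rgb = round(c(runif(1, 170, 220), runif(1, 25, 70), runif(1, 20, 60))),
                 plane_depth_mm = plane_depth_mm,
                 depth_noise_sd = depth_noise_sd,
                 intrinsics = camera_intrinsics(3600 * size / 512, 3600 * size / 512,
                                                (size - 1) / 2, (size - 1) / 2),
                 seed = seed)
  }
}

#' Generate a segmentation training set on disk
#'
#' Renders `n_sections` synthetic sections for the given task
#' (`"scar"` = longitudinal, target class stem scar; `"locule"` =
#' transverse, target class locule), splits them 7:2:1 at the section level
#' and writes `train/ val/ test/` directories each holding `images/`
#' (8-bit RGB PNG) and `masks/` (8-bit PNG, pixel value = class/instance
#' code). Deterministic: the same seed regenerates byte-identical files.
#'
#' @param out_dir output directory.
#' @param n_sections number of sections to render.
#' @param task `"scar"` or `"locule"`.
#' @param seed RNG seed.
#' @param size rendered image side, px.
#' @param ratios train/val/test fractions.
#' @return manifest data.frame (`name`, `subset`, `kind`), invisibly.
#' @export
make_training_set <- function(out_dir, n_sections, task = c("scar", "locule"),
                              seed = 42L, size = 128L, ratios = c(0.7, 0.2, 0.1)) {
  task <- match.arg(task)
  kind <- if (task == "scar") "longitudinal" else "transverse"
  items <- seq_len(n_sections)
  sp <- split_dataset(items, ratios = ratios, seed = seed)
  subset_of <- character(n_sections)
  subset_of[sp$train] <- "train"; subset_of[sp$val] <- "val"; subset_of[sp$test] <- "test"
  for (sub in c("train", "val", "test")) {
    dir.create(file.path(out_dir, sub, "images"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(out_dir, sub, "masks"), recursive = TRUE, showWarnings = FALSE)
  }
  names <- sprintf("%s_%04d", task, items)
  for (i in items) {
    spec <- random_section_spec(kind, size = size, seed = seed * 1000L + i)
    r <- render_section(spec)
    mask <- if (task == "scar") matrix(as.integer(r$labels$scar), size, size)
            else r$labels$locule_map
    sub <- subset_of[i]
    png::writePNG(aperm(r$rgb, c(1, 2, 3)),
                  file.path(out_dir, sub, "images", paste0(names[i], ".png")))
    png::writePNG(mask / 255,
                  file.path(out_dir, sub, "masks", paste0(names[i], ".png")))
  }
  invisible(data.frame(name = names, subset = subset_of, kind = kind,
                       stringsAsFactors = FALSE))
}
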
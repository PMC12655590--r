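#' Enumerate locules from a segmentation label map
#'
#' Connected components of the locule class above `min_area` become locule
#' instances. Ids 1..n are assigned by the polar angle of each locule
#' centroid about the fruit centroid, starting at 12 o'clock and proceeding
#' clockwise, so numbering is stable and reproducible across images.
#'
#' @param locule_label_map integer map (> 0 = locule pixels; distinct codes
#'   are allowed but connectivity defines instances).
#' @param fruit_mask logical fruit mask.
#' @param min_area minimum component area in px (suppresses specks).
#' @return list of class `locule_set`: `masks` (list of logical masks in id
#'   order), `centroids` (n x 2, 0-based (u, v)), `fruit_centroid`,
#'   `angles_deg` (clockwise from 12 o'clock); empty set (with warning) if
#'   no locule survives.
#' @export
enumerate_locules <- function(locule_label_map, fruit_mask, min_area = 50L) {
  fg <- locule_label_map > 0
  cen_f <- mask_centroid(fruit_mask)
  if (!any(fg)) {
    tp_warn("no locules found", "tp_empty_locules_warning")
    return(structure(list(masks = list(), centroids = matrix(numeric(0), 0, 2),
                          fruit_centroid = cen_f, angles_deg = numeric(0)),
                     class = "locule_set"))
  }
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(fg * 1)))
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_area)
  if (!length(keep)) {
    tp_warn("no locules above the minimum area", "tp_empty_locules_warning")
    return(structure(list(masks = list(), centroids = matrix(numeric(0), 0, 2),
                          fruit_centroid = cen_f, angles_deg = numeric(0)),
                     class = "locule_set"))
  }
  cents <- t(vapply(keep, function(i) mask_centroid(lab == i), numeric(2)))
  ang <- (atan2(cents[, 1] - cen_f[1], -(cents[, 2] - cen_f[2])) * 180 / pi) %% 360
  ord <- order(ang)
  structure(list(masks = lapply(keep[ord], function(i) lab == i),
                 centroids = cents[ord, , drop = FALSE],
                 fruit_centroid = cen_f,
                 angles_deg = ang[ord]),
            class = "locule_set")
}

#' Mesocarp (pericarp wall) thickness by centroid ray casting
#'
#' For each locule, three rays leave the fruit centroid: one through the
#' locule centroid and two offset by +/- `offset_deg`. Per ray, the
#' farthest crossing with the locule contour and the crossings with the
#' fruit outer contour beyond it are found; the ray's thickness is the
#' minimum distance between that locule crossing and an outer crossing.
#' The per-locule value is the mean over its (hitting) rays, the fruit
#' value the mean over locules; distances are converted to millimeters at
#' the representative depth.
#'
#' @param fruit_mask logical fruit mask.
#' @param locules a `locule_set` from [enumerate_locules()].
#' @param depth integer depth map (mm) or a single representative depth.
#' @param intrinsics a [camera_intrinsics()].
#' @param offset_deg side-ray offset from the central ray, degrees.
#' @param hdrm optional fitted [hdrm_fit()] model applied to the
#'   representative depth.
#' @return list with `per_locule_mm` (NA where all rays missed),
#'   `fruit_mean_mm`, `per_locule_px`, `depth_mm`.
#' @export
mesocarp_thickness <- function(fruit_mask, locules, depth, intrinsics,
                               offset_deg = 12, hdrm = NULL) {
  d_use <- resolve_depth(depth, fruit_mask, hdrm)
  outer <- mask_contour(fruit_mask)
  cen <- locules$fruit_centroid
  rot2 <- function(vec, deg) {
    a <- deg * pi / 180
    c(vec[1] * cos(a) - vec[2] * sin(a), vec[1] * sin(a) + vec[2] * cos(a))
  }
  per_px <- rep(NA_real_, length(locules$masks))
  per_mm <- rep(NA_real_, length(locules$masks))
  for (j in seq_along(locules$masks)) {
    lc <- mask_contour(locules$masks[[j]])
    dir0 <- locules$centroids[j, ] - cen
    if (sqrt(sum(dir0^2)) < 1e-9) dir0 <- c(0, -1)
    dir0 <- dir0 / sqrt(sum(dir0^2))
    vals_px <- vals_mm <- c()
    for (off in c(-offset_deg, 0, offset_deg)) {
      dir <- rot2(dir0, off)
      hit_loc <- cast_ray(cen, dir, lc, all = TRUE)
      if (nrow(hit_loc) == 0L) next                 # ray misses the locule
      t_loc <- max(hit_loc[, "t"])
      hit_out <- cast_ray(cen, dir, outer, all = TRUE)
      t_out <- hit_out[hit_out[, "t"] > t_loc + 1e-9, "t"]
      if (!length(t_out)) next
      t_px <- min(t_out) - t_loc
      vals_px <- c(vals_px, t_px)
      vals_mm <- c(vals_mm, px_len_mm(t_px, dir, d_use, intrinsics))
    }
    if (length(vals_px)) {
      per_px[j] <- mean(vals_px)
      per_mm[j] <- mean(vals_mm)
    }
  }
  list(per_locule_mm = per_mm,
       fruit_mean_mm = if (all(is.na(per_mm))) NA_real_ else mean(per_mm, na.rm = TRUE),
       per_locule_px = per_px, depth_mm = d_use)
}

#' Locule areas in square millimeters
#'
#' Pixel counts converted via the per-pixel footprint at the representative
#' depth.
#'
#' @inheritParams mesocarp_thickness
#' @return numeric vector of areas (mm^2), in locule id order.
#' @export
locule_areas <- function(locules, depth, intrinsics, fruit_mask = NULL, hdrm = NULL) {
  if (!length(locules$masks)) return(numeric(0))
  if (is.null(fruit_mask)) fruit_mask <- Reduce(`|`, locules$masks)
  d_use <- resolve_depth(depth, fruit_mask, hdrm)
  vapply(locules$masks, function(m) pixel_area_to_mm2(sum(m), d_use, intrinsics),
         numeric(1))
}

#' Mean tissue colors of a section
#'
#' Locule color: per-channel mean over each locule mask (and over their
#' union). Mesocarp color: the flesh mask (fruit minus locules) intersected
#' with an edge band of width `band_px` obtained by eroding the fruit mask,
#' i.e. the pericarp region near the outer wall. The band is inset by
#' `margin_px` from the mask edge so segmentation boundary noise (mixed
#' background pixels) does not bias the mean. Colors are reported as sRGB
#' means on the 0-255 scale.
#'
#' @param rgb H x W x 3 array in `[0, 1]`.
#' @param fruit_mask logical fruit mask.
#' @param locules a `locule_set` (may be empty for longitudinal sections).
#' @param band_px pericarp band width in px.
#' @param margin_px inset of the band from the fruit-mask edge, px.
#' @param exclude_mask optional mask of non-flesh tissue (e.g. the stem
#'   scar on longitudinal sections) removed from the flesh mask before
#'   color sampling.
#' @return list with `mesocarp_rgb`, `locule_rgb` (overall),
#'   `locule_rgb_per_locule` (n x 3 matrix), `band_mask`.
#' @export
section_colors <- function(rgb, fruit_mask, locules = NULL, band_px = 15L,
                           margin_px = 3L, exclude_mask = NULL) {
  mean_color <- function(mask) {
    if (!any(mask)) return(rep(NA_real_, 3))
    vapply(1:3, function(ch) mean(rgb[, , ch][mask]) * 255, numeric(1))
  }
  loc_union <- if (!is.null(locules) && length(locules$masks))
    Reduce(`|`, locules$masks) else matrix(FALSE, nrow(fruit_mask), ncol(fruit_mask))
  flesh <- fruit_mask & !loc_union
  if (!is.null(exclude_mask)) flesh <- flesh & !exclude_mask
  erode_by <- function(mask, px) {
    if (px <= 0) return(mask)
    EBImage::imageData(EBImage::erode(EBImage::Image(mask * 1),
                                      ebi_brush(2L * as.integer(px) + 1L))) > 0.5
  }
  band_of <- function(bp) {
    outer_lim <- erode_by(fruit_mask, margin_px)
    inner_lim <- erode_by(fruit_mask, margin_px + bp)
    flesh & outer_lim & !inner_lim
  }
  band <- band_of(band_px)
  if (!any(band)) band <- band_of(2L * band_px)   # widen once
  if (!any(band)) {
    tp_warn("empty pericarp band", "tp_empty_band_warning")
    meso <- rep(NA_real_, 3)
  } else meso <- mean_color(band)
  per_loc <- if (length(locules$masks))
    t(vapply(locules$masks, mean_color, numeric(3))) else matrix(numeric(0), 0, 3)
  list(mesocarp_rgb = meso,
       locule_rgb = mean_color(loc_union),
       locule_rgb_per_locule = per_loc,
       band_mask = band)
}

#' Longitudinal-section measurements
#'
#' Fits an oriented bounding rectangle to the fruit (principal-axis
#' orientation, corner-span extents); the rectangle axis most parallel to
#' the fruit-centroid-to-scar-centroid direction is the longitudinal axis (tomatoes are typically oblate, so axis order cannot
#' be inferred from length). Its extent is the longitudinal diameter, the
#' perpendicular extent the transverse diameter; shape index is their
#' ratio. The stem scar gets its own minimum-area rectangle; its side most
#' parallel to the longitudinal axis is the scar depth, the other the scar
#' width. All lengths are converted to millimeters at the (optionally
#' HDRM-corrected) representative depth.
#'
#' @param fruit_mask,scar_mask logical masks (scar may be empty).
#' @param depth integer depth map (mm) or a representative depth value.
#' @param intrinsics a [camera_intrinsics()].
#' @param hdrm optional [hdrm_fit()] model.
#' @return list with `transverse_diameter_mm`, `longitudinal_diameter_mm`,
#'   `shape_index`, `scar_width_mm`, `scar_depth_mm` (NULL when the scar
#'   mask is empty), `depth_mm`.
#' @export
measure_longitudinal <- function(fruit_mask, scar_mask, depth, intrinsics,
                                 hdrm = NULL) {
  d_use <- resolve_depth(depth, fruit_mask, hdrm)
  rect <- oriented_extents(fruit_mask)
  cen_f <- mask_centroid(fruit_mask)
  have_scar <- !is.null(scar_mask) && any(scar_mask)
  if (have_scar) {
    scar_dir <- mask_centroid(scar_mask) - cen_f
    scar_dir <- scar_dir / sqrt(sum(scar_dir^2))
  } else {
    tp_warn("empty stem-scar mask; scar traits omitted, assuming upright fruit",
            "tp_empty_scar_warning")
    scar_dir <- c(0, -1)   # upright placement: scar points up
  }
  w_dir <- rect$axes["width", ]; h_dir <- rect$axes["height", ]
  long_is_width <- abs(sum(w_dir * scar_dir)) >= abs(sum(h_dir * scar_dir))
  long_dir <- if (long_is_width) w_dir else h_dir
  perp_dir <- if (long_is_width) h_dir else w_dir
  long_px <- if (long_is_width) rect$width else rect$height
  trans_px <- if (long_is_width) rect$height else rect$width
  long_mm <- px_len_mm(long_px, long_dir, d_use, intrinsics)
  trans_mm <- px_len_mm(trans_px, perp_dir, d_use, intrinsics)
  out <- list(transverse_diameter_mm = trans_mm,
              longitudinal_diameter_mm = long_mm,
              shape_index = long_mm / trans_mm,
              scar_width_mm = NULL, scar_depth_mm = NULL,
              depth_mm = d_use)
  if (have_scar) {
    # sub-pixel rectangle-equivalent extents: scars span few pixels, where
    # hull calipers carry an O(1 px) rasterization bias
    sext <- rect_equivalent_extents(scar_mask)
    d1 <- sext$dirs[1, ]; d2 <- sext$dirs[2, ]
    depth_is_first <- abs(sum(d1 * long_dir)) >= abs(sum(d2 * long_dir))
    if (depth_is_first) {
      out$scar_depth_mm <- px_len_mm(sext$extents[1], d1, d_use, intrinsics)
      out$scar_width_mm <- px_len_mm(sext$extents[2], d2, d_use, intrinsics)
    } else {
      out$scar_depth_mm <- px_len_mm(sext$extents[2], d2, d_use, intrinsics)
      out$scar_width_mm <- px_len_mm(sext$extents[1], d1, d_use, intrinsics)
    }
  }
  out
}

# representative depth resolution: matrix -> masked median; scalar passes
# through; optional HDRM correction
resolve_depth <- function(depth, mask, hdrm = NULL) {
  d <- if (is.matrix(depth)) representative_depth(depth, mask) else as.numeric(depth)
  if (is.na(d)) tp_stop("no valid depth inside the fruit mask", "tp_domain_error")
  if (!is.null(hdrm)) d <- correct_depth(hdrm, d)
  d
}

#' Classical color-threshold segmenter
#'
#' Labels the pixels whose color lies within `tol` (Euclidean distance in
#' RGB, 0-1 scale) of a target color. A simple deterministic baseline for
#' flat-colored sections.
#'
#' @param rgb H x W x 3 array in `[0, 1]`.
#' @param target_rgb length-3 target color, 0-255 scale.
#' @param tol color tolerance on the 0-255 scale.
#' @return logical mask.
#' @export
segment_by_color <- function(rgb, target_rgb, tol = 40) {
  d2 <- (rgb[, , 1] - target_rgb[1] / 255)^2 +
    (rgb[, , 2] - target_rgb[2] / 255)^2 +
    (rgb[, , 3] - target_rgb[3] / 255)^2
  d2 <= (tol / 255)^2
}

#' Measure all traits of one sectioned fruit
#'
#' Orchestrates the section-kind-specific workflow and returns one
#' phenotype record (the row schema of [write_phenotypes()]). Fields not
#' applicable to the section kind are `NULL`.
#'
#' @param rgb H x W x 3 array in `[0, 1]`.
#' @param depth integer depth map (mm) or representative depth.
#' @param intrinsics a [camera_intrinsics()].
#' @param section_kind `"longitudinal"` or `"transverse"`.
#' @param fruit_mask logical fruit mask.
#' @param seg_mask stem-scar mask (longitudinal) or locule label map
#'   (transverse), from the network or a classical segmenter.
#' @param sample_label,fruit_id identifiers for the record.
#' @param hdrm optional [hdrm_fit()] model for depth correction.
#' @param offset_deg,band_px,min_locule_area trait-extraction tunables.
#' @return a phenotype record list.
#' @export
measure_section <- function(rgb, depth, intrinsics,
                            section_kind = c("longitudinal", "transverse"),
                            fruit_mask, seg_mask,
                            sample_label = "sample", fruit_id = 1L,
                            hdrm = NULL, offset_deg = 12, band_px = 15L,
                            min_locule_area = 50L) {
  section_kind <- match.arg(section_kind)
  rec <- list(sample_label = sample_label, fruit_id = fruit_id,
              section_kind = section_kind)
  if (section_kind == "longitudinal") {
    m <- measure_longitudinal(fruit_mask, seg_mask > 0, depth, intrinsics, hdrm)
    rec <- c(rec, m[c("transverse_diameter_mm", "longitudinal_diameter_mm",
                      "shape_index", "scar_width_mm", "scar_depth_mm")])
    cols <- section_colors(rgb, fruit_mask, NULL, band_px,
                           exclude_mask = seg_mask > 0)
    rec$mesocarp_rgb <- cols$mesocarp_rgb
  } else {
    locs <- enumerate_locules(seg_mask, fruit_mask, min_locule_area)
    d_use <- resolve_depth(depth, fruit_mask, hdrm)
    rect <- oriented_extents(fruit_mask)
    rec$transverse_diameter_mm <- px_len_mm(rect$width, rect$axes["width", ],
                                            d_use, intrinsics)
    rec$locule_count <- length(locs$masks)
    rec$locule_areas_mm2 <- locule_areas(locs, d_use, intrinsics, fruit_mask)
    th <- mesocarp_thickness(fruit_mask, locs, d_use, intrinsics, offset_deg)
    rec$mesocarp_thickness_mm <- th$fruit_mean_mm
    rec$mesocarp_thickness_per_locule_mm <- th$per_locule_mm
    cols <- section_colors(rgb, fruit_mask, locs, band_px)
    rec$mesocarp_rgb <- cols$mesocarp_rgb
    rec$locule_rgb <- cols$locule_rgb
    rec$locule_rgb_per_locule <- cols$locule_rgb_per_locule
  }
  rec
}
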
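#' Back-project a pixel to camera coordinates
#'
#' Maps a pixel `(u, v)` with depth `d` (mm) to 3-D camera-frame
#' coordinates using the pinhole model:
#' \deqn{(x, y, z) = \left(\frac{(u - c_x) d}{f_x}, \frac{(v - c_y) d}{f_y}, d\right)}
#'
#' @param u,v 0-based pixel coordinates (u = column, v = row); vectorized.
#' @param d depth in millimeters, `> 0`.
#' @param intrinsics a [camera_intrinsics()] object.
#' @return numeric matrix with columns x, y, z (mm).
#' @export
back_project <- function(u, v, d, intrinsics) {
  if (any(d <= 0)) tp_stop("depth must be positive", "tp_domain_error")
  cbind(x = (u - intrinsics$cx) * d / intrinsics$fx,
        y = (v - intrinsics$cy) * d / intrinsics$fy,
        z = d + numeric(length(u)))
}

#' @rdname back_project
#' @param p numeric matrix with columns x, y, z (mm).
#' @return for `project_point`, a matrix with columns u, v.
#' @export
project_point <- function(p, intrinsics) {
  p <- rbind(p)
  cbind(u = p[, 1] * intrinsics$fx / p[, 3] + intrinsics$cx,
        v = p[, 2] * intrinsics$fy / p[, 3] + intrinsics$cy)
}

#' Convert a pixel distance to millimeters
#'
#' Both endpoints are back-projected at the same representative depth (the
#' section is assumed planar and fronto-parallel) and the Euclidean distance
#' of the 3-D points is returned.
#'
#' @param p1,p2 length-2 vectors, 0-based (u, v).
#' @param d representative depth in mm, `> 0`.
#' @param intrinsics a [camera_intrinsics()] object.
#' @return distance in millimeters.
#' @export
pixel_length_to_mm <- function(p1, p2, d, intrinsics) {
  a <- back_project(p1[1], p1[2], d, intrinsics)
  b <- back_project(p2[1], p2[2], d, intrinsics)
  sqrt(sum((a - b)^2))
}

#' Convert a pixel count to an area in square millimeters
#'
#' Each pixel at depth `d` has a physical footprint of
#' `(d / fx) x (d / fy)` mm.
#'
#' @param n_pixels pixel count.
#' @param d representative depth in mm, `> 0`.
#' @param intrinsics a [camera_intrinsics()] object.
#' @return area in mm^2.
#' @export
pixel_area_to_mm2 <- function(n_pixels, d, intrinsics) {
  if (any(d <= 0)) tp_stop("depth must be positive", "tp_domain_error")
  n_pixels * (d / intrinsics$fx) * (d / intrinsics$fy)
}

#' Millimeters of a pixel length along a direction
#'
#' Converts a pixel length `L` measured along unit image direction
#' `(du, dv)` into millimeters at depth `d`, honoring anisotropic focal
#' lengths.
#'
#' @param L length in pixels.
#' @param dirvec unit direction (du, dv).
#' @param d depth in mm.
#' @param intrinsics a [camera_intrinsics()].
#' @return length in mm.
#' @export
px_len_mm <- function(L, dirvec, d, intrinsics) {
  L * sqrt((dirvec[1] * d / intrinsics$fx)^2 + (dirvec[2] * d / intrinsics$fy)^2)
}

#' Minimum-area oriented bounding rectangle of a mask
#'
#' Exact rotating-calipers solution over the convex hull of the component's
#' boundary pixel *corners* (each boundary pixel contributes its four unit
#' square corners, so the hull bounds the pixel footprint in every
#' direction): the minimal rectangle has a side collinear with a hull edge,
#' so all hull-edge-aligned boxes are scored and the smallest returned. An
#' axis-aligned filled `w x h` rectangle measures exactly `w x h`.
#'
#' @param mask logical matrix (single component expected).
#' @return list with `center` (0-based (u, v)), `width`, `height` (px,
#'   `width >= height`), `angle` (degrees in `[-90, 90)`, direction of the
#'   width side), and `axes` (2 x 2 matrix; rows are unit vectors of the
#'   width and height directions).
#' @export
min_area_rect <- function(mask) {
  cpts <- boundary_points(mask)
  if (is.null(cpts) || nrow(cpts) == 0L) tp_stop("empty mask", "tp_empty_error")
  # orientation search on the pixel-center hull: the corner dilation is
  # anisotropic (larger for oblique boxes) and would bias the chosen angle
  # toward axis alignment on near-square shapes
  hull <- cpts[chull(cpts[, 1], cpts[, 2]), , drop = FALSE]
  best <- NULL
  n <- nrow(hull)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    e <- hull[j, ] - hull[i, ]
    len <- sqrt(sum(e^2))
    if (len < 1e-12) next
    ex <- e / len                      # unit vector along this hull edge
    ey <- c(-ex[2], ex[1])
    s <- hull %*% cbind(ex, ey)
    area <- (max(s[, 1]) - min(s[, 1])) * (max(s[, 2]) - min(s[, 2]))
    if (is.null(best) || area < best$area - 1e-9) best <- list(area = area, ex = ex, ey = ey)
  }
  # extents and center at the chosen orientation from the pixel corners
  # (full footprint), so an axis-aligned filled w x h block measures w x h
  corners <- corner_points(mask)
  s <- corners %*% cbind(best$ex, best$ey)
  w <- max(s[, 1]) - min(s[, 1])
  h <- max(s[, 2]) - min(s[, 2])
  cen_s <- c((max(s[, 1]) + min(s[, 1])) / 2, (max(s[, 2]) + min(s[, 2])) / 2)
  best <- list(area = w * h, width = w, height = h,
               center = cen_s[1] * best$ex + cen_s[2] * best$ey,
               ex = best$ex, ey = best$ey)
  if (best$width < best$height) {
    best <- list(area = best$area, width = best$height, height = best$width,
                 center = best$center, ex = best$ey, ey = best$ex)
  }
  ang <- atan2(best$ex[2], best$ex[1]) * 180 / pi
  while (ang >= 90) ang <- ang - 180
  while (ang < -90) ang <- ang + 180
  # keep axes consistent with the normalized angle
  ar <- ang * pi / 180
  ex <- c(cos(ar), sin(ar)); ey <- c(-sin(ar), cos(ar))
  list(center = as.numeric(best$center), width = best$width,
       height = best$height, angle = ang, axes = rbind(width = ex, height = ey))
}

# 0-based (u, v) centers of boundary pixels (mask minus its 4-neighborhood
# erosion); falls back to all pixels for tiny components
boundary_points <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- mask
  core <- pad[2:(h + 1L), 2:(w + 1L)] &
    pad[1:h, 2:(w + 1L)] & pad[3:(h + 2L), 2:(w + 1L)] &
    pad[2:(h + 1L), 1:w] & pad[2:(h + 1L), 3:(w + 2L)]
  b <- mask & !core
  bidx <- which(b, arr.ind = TRUE)
  if (nrow(bidx) == 0L) bidx <- idx
  cbind(u = bidx[, 2] - 1, v = bidx[, 1] - 1)
}

# the four unit-square corners of every boundary pixel, 0-based (u, v);
# their hull bounds the pixel footprint exactly in every direction
corner_points <- function(mask) {
  p <- boundary_points(mask)
  if (is.null(p)) return(NULL)
  rbind(cbind(p[, 1] - 0.5, p[, 2] - 0.5), cbind(p[, 1] + 0.5, p[, 2] - 0.5),
        cbind(p[, 1] - 0.5, p[, 2] + 0.5), cbind(p[, 1] + 0.5, p[, 2] + 0.5))
}

#' Oriented bounding-box extents along a mask's principal axes
#'
#' Bounding-box extents (pixel-corner spans) along the principal axes of
#' the mask's pixel centers. For near-circular fruits the minimum-area
#' criterion of [min_area_rect()] is degenerate under rasterization (many
#' orientations tie within quantization noise), whereas the moment-based
#' orientation is sub-pixel stable; extents along those axes estimate the
#' axis diameters of smooth convex sections reliably.
#'
#' @param mask logical matrix.
#' @return list as in [min_area_rect()] (`center`, `width >= height`,
#'   `angle`, `axes`).
#' @export
oriented_extents <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) tp_stop("empty mask", "tp_empty_error")
  P <- cbind(idx[, 2] - 1, idx[, 1] - 1)
  Pc <- sweep(P, 2, colMeans(P))
  ev <- eigen(crossprod(Pc) / nrow(Pc), symmetric = TRUE)
  ex <- ev$vectors[, 1]; ey <- ev$vectors[, 2]
  corners <- corner_points(mask)
  s <- corners %*% cbind(ex, ey)
  w <- max(s[, 1]) - min(s[, 1]); h <- max(s[, 2]) - min(s[, 2])
  cen_s <- c((max(s[, 1]) + min(s[, 1])) / 2, (max(s[, 2]) + min(s[, 2])) / 2)
  center <- cen_s[1] * ex + cen_s[2] * ey
  if (w < h) { tmp <- w; w <- h; h <- tmp; tmp <- ex; ex <- ey; ey <- tmp }
  ang <- atan2(ex[2], ex[1]) * 180 / pi
  while (ang >= 90) ang <- ang - 180
  while (ang < -90) ang <- ang + 180
  ar <- ang * pi / 180
  list(center = as.numeric(center), width = w, height = h, angle = ang,
       axes = rbind(width = c(cos(ar), sin(ar)), height = c(-sin(ar), cos(ar))))
}

#' Rectangle-equivalent extents of a blob from second-order moments
#'
#' Principal-axis side lengths of the rectangle with the same second-order
#' moments as the region sampled by the mask's pixel centers
#' (`side = sqrt(12 lambda)` per principal variance `lambda`). Unlike
#' hull-based calipers this estimator is sub-pixel and unbiased under
#' rasterization, which matters for small structures such as stem scars.
#'
#' @param mask logical matrix.
#' @return list with `extents` (length 2, decreasing), `dirs` (2 x 2; rows
#'   are the unit principal directions matching `extents`), `center`
#'   (0-based (u, v)).
#' @export
rect_equivalent_extents <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) tp_stop("empty mask", "tp_empty_error")
  P <- cbind(idx[, 2] - 1, idx[, 1] - 1)
  ctr <- colMeans(P)
  P <- sweep(P, 2, ctr)
  C <- crossprod(P) / nrow(P)
  ev <- eigen(C, symmetric = TRUE)
  # + 1/12: a unit-square pixel contributes 1/12 variance beyond its center
  ext <- sqrt(12 * pmax(ev$values, 0) + 1)
  list(extents = ext, dirs = t(ev$vectors), center = c(u = ctr[1], v = ctr[2]))
}

#' Extract the outer contour of a mask as a closed polyline
#'
#' Oriented contour of the largest connected component as 0-based (u, v)
#' coordinates. The traced boundary-pixel centers lie half a pixel inside
#' the region's footprint, so the polyline is lightly smoothed (3-point
#' moving average, removing the rasterization staircase) and offset
#' outward by half a pixel along the vertex normals; on analytic shapes
#' the result tracks the true region boundary at sub-pixel accuracy.
#'
#' @param mask logical matrix.
#' @param offset outward normal offset in pixels (0 gives the raw
#'   pixel-center trace).
#' @return n x 2 matrix of (u, v); the polyline is implicitly closed.
#' @export
mask_contour <- function(mask, offset = 0.5) {
  if (!any(mask)) tp_stop("empty mask", "tp_empty_error")
  lab <- EBImage::bwlabel(EBImage::Image(t(mask)))
  tab <- tabulate(as.integer(EBImage::imageData(lab)))
  keep <- which.max(tab)
  oc <- EBImage::ocontour(lab)[[keep]]
  # EBImage images are transposed (x = first dim) and ocontour coordinates
  # are 0-based, so (x, y) already equals our 0-based (u, v)
  p <- cbind(u = oc[, 1], v = oc[, 2])
  n <- nrow(p)
  if (n < 5L || offset == 0) return(p)
  nxt <- c(2:n, 1L); prv <- c(n, 1:(n - 1L))
  p <- (p[prv, ] + p + p[nxt, ]) / 3          # staircase smoothing
  tx <- p[nxt, 1] - p[prv, 1]; ty <- p[nxt, 2] - p[prv, 2]
  len <- pmax(sqrt(tx^2 + ty^2), 1e-12)
  # shoelace sign fixes which side the outward normal lies on
  area2 <- sum(p[, 1] * p[nxt, 2] - p[nxt, 1] * p[, 2])
  sgn <- if (area2 > 0) 1 else -1
  cbind(u = p[, 1] + sgn * offset * ty / len,
        v = p[, 2] - sgn * offset * tx / len)
}

#' Cast a ray from a point and find its first contour intersection
#'
#' Solves the ray/segment intersection for every segment of the closed
#' contour polyline and returns the nearest intersection with positive ray
#' parameter (sub-pixel precision).
#'
#' @param origin length-2 vector, 0-based (u, v).
#' @param direction length-2 direction vector (normalized internally).
#' @param contour n x 2 matrix of (u, v) vertices (closed implicitly).
#' @param all if `TRUE`, return every crossing sorted by distance instead of
#'   the first.
#' @return list with `hit` (logical), `point` (u, v), `t` (distance along
#'   the ray, px); with `all = TRUE`, a matrix with columns t, u, v
#'   (zero rows on a miss).
#' @export
cast_ray <- function(origin, direction, contour, all = FALSE) {
  dir <- direction / sqrt(sum(direction^2))
  a <- contour
  b <- contour[c(2:nrow(contour), 1L), , drop = FALSE]
  # solve origin + t*dir = a + s*(b - a), t > 0, s in [0, 1]
  ex <- b[, 1] - a[, 1]; ey <- b[, 2] - a[, 2]
  den <- dir[1] * (-ey) - dir[2] * (-ex)
  ok <- abs(den) > 1e-12
  wx <- a[, 1] - origin[1]; wy <- a[, 2] - origin[2]
  t <- (wx * (-ey) - wy * (-ex)) / den
  s <- (dir[1] * wy - dir[2] * wx) / den
  ok <- ok & t > 1e-9 & s >= -1e-9 & s <= 1 + 1e-9
  if (!any(ok)) {
    if (all) return(matrix(numeric(0), 0, 3, dimnames = list(NULL, c("t", "u", "v"))))
    return(list(hit = FALSE, point = c(NA_real_, NA_real_), t = NA_real_))
  }
  tt <- t[ok]
  pts <- cbind(origin[1] + tt * dir[1], origin[2] + tt * dir[2])
  o <- order(tt)
  if (all) {
    m <- cbind(t = tt[o], u = pts[o, 1], v = pts[o, 2])
    return(m)
  }
  list(hit = TRUE, point = pts[o[1], ], t = tt[o[1]])
}

#' Representative depth of a fruit
#'
#' Median of the valid (non-zero) depth pixels inside the fruit mask; robust
#' to specular dropouts.
#'
#' @param depth integer depth matrix (mm, 0 = invalid).
#' @param mask logical fruit mask.
#' @return depth in mm, or `NA` if no valid pixel.
#' @export
representative_depth <- function(depth, mask) {
  d <- depth[mask & depth > 0]
  if (!length(d)) return(NA_real_)
  median(as.numeric(d))
}

#' Centroid of a mask
#'
#' @param mask logical matrix.
#' @return length-2 vector, 0-based (u, v).
#' @export
mask_centroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) tp_stop("empty mask", "tp_empty_error")
  c(u = mean(idx[, 2]) - 1, v = mean(idx[, 1]) - 1)
}
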
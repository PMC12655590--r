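#' Read a 16-bit depth PNG
#'
#' Depth maps are stored as single-channel 16-bit PNG files whose pixel
#' values are integer millimeters (Kinect-style); the value 0 marks pixels
#' with no valid depth.
#'
#' @param path path to a 16-bit single-channel PNG file.
#' @return integer matrix (rows x cols) of depth in millimeters.
#' @export
read_depth_png <- function(path) {
  if (!file.exists(path)) tp_stop(sprintf("depth file not found: %s", path), "tp_io_error")
  hdr <- readBin(path, "raw", n = 26L)
  sig <- as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a))
  if (length(hdr) < 26L || !identical(hdr[1:8], sig))
    tp_stop(sprintf("not a PNG file: %s", path), "tp_format_error")
  bit_depth <- as.integer(hdr[25L])
  color_type <- as.integer(hdr[26L])
  if (bit_depth != 16L)
    tp_stop(sprintf("depth PNG must be 16-bit, got %d-bit: %s", bit_depth, path),
            "tp_format_error")
  if (color_type != 0L)
    tp_stop(sprintf("depth PNG must be single-channel grayscale (color type 0), got color type %d: %s",
                    color_type, path), "tp_format_error")
  img <- png::readPNG(path)
  d <- round(img * 65535)
  storage.mode(d) <- "integer"
  d
}

#' Write a depth map as a 16-bit grayscale PNG
#'
#' Values are written verbatim as 16-bit unsigned integers (millimeters), so
#' `read_depth_png(write_depth_png(d, p))` round-trips bit-exactly.
#'
#' @param depth numeric/integer matrix with values in `[0, 65535]`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_depth_png <- function(depth, path) {
  if (!is.matrix(depth)) tp_stop("depth must be a matrix", "tp_format_error")
  d <- round(depth)
  if (any(!is.finite(d)) || any(d < 0) || any(d > 65535))
    tp_stop("depth values must be finite and within [0, 65535]", "tp_format_error")
  h <- nrow(d); w <- ncol(d)
  # scanlines: per row a filter byte (0) then big-endian 16-bit samples
  hi <- as.raw(t(d) %/% 256L)
  lo <- as.raw(t(d) %% 256L)
  inter <- matrix(raw(1), nrow = 2L * w, ncol = h)
  inter[seq(1L, 2L * w, by = 2L), ] <- matrix(hi, nrow = w, ncol = h)
  inter[seq(2L, 2L * w, by = 2L), ] <- matrix(lo, nrow = w, ncol = h)
  scan <- rbind(matrix(as.raw(0L), 1L, h), inter)
  idat <- memCompress(as.vector(scan), type = "gzip")  # zlib stream per RFC 1950

  ihdr <- c(int_to_raw_be(w), int_to_raw_be(h),
            as.raw(c(16L, 0L, 0L, 0L, 0L)))  # 16-bit, grayscale, default codes
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)), con)
  write_png_chunk(con, "IHDR", ihdr)
  write_png_chunk(con, "IDAT", idat)
  write_png_chunk(con, "IEND", raw(0))
  invisible(path)
}

int_to_raw_be <- function(x) {
  writeBin(as.integer(x), raw(), size = 4L, endian = "big")
}

write_png_chunk <- function(con, type, data) {
  type_raw <- charToRaw(type)
  writeBin(int_to_raw_be(length(data)), con)
  body <- c(type_raw, data)
  writeBin(body, con)
  writeBin(crc32_raw(body), con)
}

# table-driven CRC-32 (polynomial 0xEDB88320), returned as 4 big-endian bytes
crc32_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      t <- integer(256L)
      for (n in 0:255) {
        c <- n
        for (k in 1:8) {
          c <- if (bitwAnd(c, 1L) != 0L) bitwXor(-306674912L, bitwShiftR(c, 1L)) else bitwShiftR(c, 1L)
        }
        t[n + 1L] <- c
      }
      tab <<- t
    }
    tab
  }
})

crc32_raw <- function(bytes) {
  tab <- crc32_table()
  crc <- -1L
  b <- as.integer(bytes)
  for (i in seq_along(b)) {
    crc <- bitwXor(tab[bitwAnd(bitwXor(crc, b[i]), 255L) + 1L], bitwShiftR(crc, 8L))
  }
  writeBin(bitwXor(crc, -1L), raw(), size = 4L, endian = "big")
}

#' Camera intrinsics
#'
#' Pinhole intrinsics of the RGB-D camera: focal lengths `fx`, `fy` (pixels)
#' and principal point `cx`, `cy` (pixels, 0-based image coordinates with
#' u = column, v = row).
#'
#' @param fx,fy focal lengths in pixels; must be positive.
#' @param cx,cy principal point in pixels.
#' @return an object of class `camera_intrinsics`.
#' @export
camera_intrinsics <- function(fx, fy, cx, cy) {
  if (!is.numeric(fx) || fx <= 0 || !is.numeric(fy) || fy <= 0)
    tp_stop("focal lengths fx, fy must be positive", "tp_domain_error")
  structure(list(fx = as.numeric(fx), fy = as.numeric(fy),
                 cx = as.numeric(cx), cy = as.numeric(cy)),
            class = "camera_intrinsics")
}

#' Read camera intrinsics from JSON
#'
#' Expects a JSON object `{"fx":..,"fy":..,"cx":..,"cy":..}`.
#'
#' @param path path to the JSON file.
#' @return a [camera_intrinsics()] object.
#' @export
read_intrinsics <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("fx", "fy", "cx", "cy")
  if (!all(need %in% names(j)))
    tp_stop(sprintf("intrinsics JSON must contain %s", paste(need, collapse = ", ")),
            "tp_format_error")
  camera_intrinsics(j$fx, j$fy, j$cx, j$cy)
}

#' @rdname read_intrinsics
#' @param intr a [camera_intrinsics()] object.
#' @export
write_intrinsics <- function(intr, path) {
  stopifnot(inherits(intr, "camera_intrinsics"))
  jsonlite::write_json(unclass(intr), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Bundle one co-registered RGB + depth section image
#'
#' @param rgb H x W x 3 array with values in `[0, 1]`.
#' @param depth H x W integer matrix of millimeters (0 = invalid).
#' @param intrinsics a [camera_intrinsics()] object.
#' @param section_kind `"longitudinal"` or `"transverse"`.
#' @param sample_label string identifier for the tray photo.
#' @return an object of class `rgbd_section`.
#' @export
rgbd_section <- function(rgb, depth, intrinsics,
                         section_kind = c("longitudinal", "transverse"),
                         sample_label = "sample") {
  section_kind <- match.arg(section_kind)
  if (length(dim(rgb)) != 3L || dim(rgb)[3] != 3L)
    tp_stop("rgb must be an H x W x 3 array", "tp_format_error")
  if (!identical(dim(rgb)[1:2], dim(depth)))
    tp_stop("rgb and depth must share H x W dimensions", "tp_format_error")
  if (any(depth < 0)) tp_stop("depth values must be non-negative", "tp_domain_error")
  structure(list(rgb = rgb, depth = depth, intrinsics = intrinsics,
                 section_kind = section_kind, sample_label = sample_label),
            class = "rgbd_section")
}
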
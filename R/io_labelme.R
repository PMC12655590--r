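#' Read LabelMe-style polygon annotations
#'
#' Parses a LabelMe-style JSON file (a `shapes` array whose entries carry a
#' `label` and a list of `points`) and rasterizes the polygons into an
#' integer label map. Polygons are filled with the even-odd rule; pixels
#' whose center lies exactly on a polygon edge are included (closed fill),
#' matching common annotation-tool behavior. Point coordinates are 0-based
#' `(u = column, v = row)`.
#'
#' Label codes in the map: 0 = background; `stem_scar` polygons get 1;
#' `locule` polygons get instance codes 1..n in file order. Unknown labels
#' are kept in the polygon list and reported via a warning, but are not
#' rasterized.
#'
#' @param path path to the JSON file.
#' @param image_shape integer vector `c(rows, cols)` of the annotated image.
#' @return a list with `polygons` (list of polygon annotations: `label`,
#'   `points` as an n x 2 matrix of (u, v)), `label_map` (integer matrix),
#'   and `unknown_labels` (character).
#' @export
read_labelme <- function(path, image_shape) {
  j <- tryCatch(jsonlite::read_json(path),
                error = function(e) tp_stop(sprintf("malformed JSON in %s: %s",
                                                    path, conditionMessage(e)),
                                            "tp_parse_error"))
  shapes <- j$shapes
  if (is.null(shapes)) shapes <- list()
  h <- as.integer(image_shape[1]); w <- as.integer(image_shape[2])
  known <- c("stem_scar", "locule")
  polys <- list()
  unknown <- character(0)
  for (s in shapes) {
    pts <- do.call(rbind, lapply(s$points, function(p) as.numeric(unlist(p))))
    if (is.null(pts) || nrow(pts) < 3L)
      tp_stop("polygon must have at least 3 vertices", "tp_format_error")
    lab <- as.character(s$label)
    if (any(pts[, 1] < 0 | pts[, 1] > w - 1 | pts[, 2] < 0 | pts[, 2] > h - 1)) {
      tp_warn(sprintf("polygon '%s' extends outside image bounds; clipping", lab),
              "tp_clip_warning")
      pts[, 1] <- pmin(pmax(pts[, 1], 0), w - 1)
      pts[, 2] <- pmin(pmax(pts[, 2], 0), h - 1)
    }
    if (!(lab %in% known)) unknown <- c(unknown, lab)
    polys[[length(polys) + 1L]] <- list(label = lab, points = pts)
  }
  if (length(unknown))
    tp_warn(sprintf("unknown annotation labels: %s",
                    paste(unique(unknown), collapse = ", ")), "tp_label_warning")
  label_map <- matrix(0L, h, w)
  code <- 0L
  for (p in polys) {
    if (!(p$label %in% known)) next
    code <- code + 1L
    m <- rasterize_polygon(p$points, c(h, w))
    label_map[m] <- if (identical(p$label, "stem_scar")) 1L else code
  }
  list(polygons = polys, label_map = label_map, unknown_labels = unique(unknown))
}

#' Rasterize a polygon into a logical mask
#'
#' Even-odd fill over pixel centers, with pixels whose center lies exactly on
#' an edge included (closed-polygon convention).
#'
#' @param points n x 2 matrix of polygon vertices as 0-based (u, v).
#' @param image_shape `c(rows, cols)`.
#' @return logical matrix of shape `image_shape`.
#' @export
rasterize_polygon <- function(points, image_shape) {
  h <- as.integer(image_shape[1]); w <- as.integer(image_shape[2])
  mask <- matrix(FALSE, h, w)
  u0 <- max(0L, floor(min(points[, 1]))); u1 <- min(w - 1L, ceiling(max(points[, 1])))
  v0 <- max(0L, floor(min(points[, 2]))); v1 <- min(h - 1L, ceiling(max(points[, 2])))
  if (u1 < u0 || v1 < v0) return(mask)
  uu <- rep(u0:u1, each = v1 - v0 + 1L)
  vv <- rep(v0:v1, times = u1 - u0 + 1L)
  n <- nrow(points)
  xs <- points[, 1]; ys <- points[, 2]
  inside <- rep(FALSE, length(uu))
  on_edge <- rep(FALSE, length(uu))
  for (i in seq_len(n)) {
    j <- if (i == 1L) n else i - 1L
    xi <- xs[i]; yi <- ys[i]; xj <- xs[j]; yj <- ys[j]
    # even-odd ray crossing (horizontal ray toward +u)
    crosses <- ((yi > vv) != (yj > vv)) &
      (uu < (xj - xi) * (vv - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    # point-on-segment test (collinear and within bounding box)
    dx <- xj - xi; dy <- yj - yi
    cross <- (uu - xi) * dy - (vv - yi) * dx
    within <- pmin(xi, xj) - 1e-9 <= uu & uu <= pmax(xi, xj) + 1e-9 &
      pmin(yi, yj) - 1e-9 <= vv & vv <= pmax(yi, yj) + 1e-9
    on_edge <- on_edge | (abs(cross) < 1e-9 & within)
  }
  sel <- inside | on_edge
  mask[cbind(vv[sel] + 1L, uu[sel] + 1L)] <- TRUE
  mask
}

# fixed phenotype CSV schema (union of longitudinal and transverse fields);
# list-valued cells are serialized as JSON arrays
phenotype_columns <- c(
  "sample_label", "fruit_id", "section_kind",
  "transverse_diameter_mm", "longitudinal_diameter_mm", "shape_index",
  "scar_width_mm", "scar_depth_mm",
  "locule_count", "locule_areas_mm2",
  "mesocarp_thickness_mm", "mesocarp_thickness_per_locule_mm",
  "mesocarp_r", "mesocarp_g", "mesocarp_b",
  "locule_r", "locule_g", "locule_b", "locule_rgb_per_locule"
)

#' Write phenotype records to CSV
#'
#' One row per fruit; per-locule values (areas, thicknesses, colors) are
#' serialized as JSON list cells. The header is fixed to the union schema of
#' longitudinal and transverse traits; fields not applicable to a section
#' kind are empty.
#'
#' @param records a list of phenotype record lists (as produced by
#'   [measure_section()]), possibly empty.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(records, path) {
  ser <- function(x) {
    if (is.null(x) || (is.atomic(x) && length(x) == 1 && is.na(x))) return(NA)
    as.character(jsonlite::toJSON(x, digits = NA))
  }
  rows <- lapply(records, function(r) {
    if (!all(c("sample_label", "fruit_id", "section_kind") %in% names(r)))
      tp_stop("record does not follow the phenotype schema", "tp_schema_error")
    data.frame(
      sample_label = r$sample_label,
      fruit_id = r$fruit_id,
      section_kind = r$section_kind,
      transverse_diameter_mm = r$transverse_diameter_mm %||% NA_real_,
      longitudinal_diameter_mm = r$longitudinal_diameter_mm %||% NA_real_,
      shape_index = r$shape_index %||% NA_real_,
      scar_width_mm = r$scar_width_mm %||% NA_real_,
      scar_depth_mm = r$scar_depth_mm %||% NA_real_,
      locule_count = r$locule_count %||% NA_integer_,
      locule_areas_mm2 = ser(r$locule_areas_mm2),
      mesocarp_thickness_mm = r$mesocarp_thickness_mm %||% NA_real_,
      mesocarp_thickness_per_locule_mm = ser(r$mesocarp_thickness_per_locule_mm),
      mesocarp_r = (r$mesocarp_rgb %||% rep(NA_real_, 3))[1],
      mesocarp_g = (r$mesocarp_rgb %||% rep(NA_real_, 3))[2],
      mesocarp_b = (r$mesocarp_rgb %||% rep(NA_real_, 3))[3],
      locule_r = (r$locule_rgb %||% rep(NA_real_, 3))[1],
      locule_g = (r$locule_rgb %||% rep(NA_real_, 3))[2],
      locule_b = (r$locule_rgb %||% rep(NA_real_, 3))[3],
      locule_rgb_per_locule = ser(r$locule_rgb_per_locule),
      stringsAsFactors = FALSE
    )
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(as.data.frame(matrix(nrow = 0, ncol = length(phenotype_columns))),
                    phenotype_columns)
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_phenotypes
#' @return for `read_phenotypes`, a list of phenotype records with list
#'   cells deserialized.
#' @export
read_phenotypes <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(sample_label = "character"))
  deser <- function(x) {
    if (is.na(x) || !nzchar(x)) return(NULL)
    jsonlite::fromJSON(x, simplifyVector = TRUE)
  }
  lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    list(
      sample_label = r$sample_label, fruit_id = r$fruit_id,
      section_kind = r$section_kind,
      transverse_diameter_mm = na_null(r$transverse_diameter_mm),
      longitudinal_diameter_mm = na_null(r$longitudinal_diameter_mm),
      shape_index = na_null(r$shape_index),
      scar_width_mm = na_null(r$scar_width_mm),
      scar_depth_mm = na_null(r$scar_depth_mm),
      locule_count = na_null(r$locule_count),
      locule_areas_mm2 = deser(r$locule_areas_mm2),
      mesocarp_thickness_mm = na_null(r$mesocarp_thickness_mm),
      mesocarp_thickness_per_locule_mm = deser(r$mesocarp_thickness_per_locule_mm),
      mesocarp_rgb = if (is.na(r$mesocarp_r)) NULL else c(r$mesocarp_r, r$mesocarp_g, r$mesocarp_b),
      locule_rgb = if (is.na(r$locule_r)) NULL else c(r$locule_r, r$locule_g, r$locule_b),
      locule_rgb_per_locule = deser(r$locule_rgb_per_locule)
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
na_null <- function(x) if (is.na(x)) NULL else x
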
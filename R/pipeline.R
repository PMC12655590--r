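#' Write a simulated RGB-D section set to disk
#'
#' Renders `n` synthetic sections and writes the directory layout consumed
#' by [run_pipeline()]: `images/` (8-bit RGB PNG), `depth/` (16-bit mm
#' PNG), `masks/` (8-bit label PNG: ground-truth class/instance codes),
#' `truth/` (per-section ground-truth JSON incl. tissue colors) and a
#' shared `intrinsics.json`.
#'
#' @param out_dir output directory.
#' @param n number of sections.
#' @param kind `"longitudinal"` or `"transverse"`.
#' @param seed RNG seed (deterministic regeneration).
#' @param size image side, px.
#' @return manifest data.frame (`name`, `kind`), invisibly.
#' @export
simulate_section_set <- function(out_dir, n, kind = c("transverse", "longitudinal"),
                                 seed = 42L, size = 512L) {
  kind <- match.arg(kind)
  for (d in c("images", "depth", "masks", "truth"))
    dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
  names <- sprintf("section_%03d", seq_len(n))
  intr <- NULL
  for (i in seq_len(n)) {
    spec <- random_section_spec(kind, size = size, seed = seed * 1000L + i)
    r <- render_section(spec)
    png::writePNG(r$rgb, file.path(out_dir, "images", paste0(names[i], ".png")))
    write_depth_png(r$depth, file.path(out_dir, "depth", paste0(names[i], ".png")))
    mask <- if (kind == "longitudinal") matrix(as.integer(r$labels$scar), size, size)
            else r$labels$locule_map
    png::writePNG(mask / 255, file.path(out_dir, "masks", paste0(names[i], ".png")))
    tr <- r$truth
    tr$flesh_rgb <- spec$flesh_rgb
    tr$locule_rgb <- spec$locule_rgb
    tr$scar_rgb <- spec$scar_rgb
    jsonlite::write_json(tr, file.path(out_dir, "truth", paste0(names[i], ".json")),
                         auto_unbox = TRUE, digits = NA)
    intr <- spec$intrinsics
  }
  write_intrinsics(intr, file.path(out_dir, "intrinsics.json"))
  invisible(data.frame(name = names, kind = kind, stringsAsFactors = FALSE))
}

#' Save / load a trained segmentation model
#'
#' Serializes the model (config + parameters) with `saveRDS`.
#'
#' @param model a `segformer_mlla`.
#' @param path file path.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "segformer_mlla")) tp_stop("not a segformer_mlla checkpoint", "tp_format_error")
  m
}

#' Default pipeline configuration
#'
#' Every tunable of the measurement pipeline with its default: paths,
#' seeds, segmentation method (classical color thresholds or a trained
#' model checkpoint), HDRM options and trait-extraction options.
#'
#' @return named list.
#' @export
pipeline_config <- function() {
  list(input_dir = NULL, out_dir = NULL,
       section_kind = "transverse",
       segmentation = list(method = "color", weights = NULL,
                           locule_rgb = NULL, scar_rgb = NULL, tol = 40),
       hdrm = list(pairs_csv = NULL, seed = 42L, gamma_form = "sqrt", ntree = 200L),
       offset_deg = 12, band_px = 15L, min_locule_area = 50L,
       seed = 42L)
}

#' Run the full measurement pipeline on a section directory
#'
#' For every image: isolate the fruit ([binarize_section()]), segment the
#' internal structure (classical color thresholds or a trained
#' SegFormer-MLLA checkpoint), correct the representative depth with a
#' fitted HDRM (when calibration pairs are provided), extract the traits
#' ([measure_section()]) and append one phenotype record. Writes
#' `phenotypes.csv`, `metrics.json` (segmentation metrics, when
#' ground-truth masks are present) and `run_log.txt` (seed, config hash,
#' package version) under `out_dir`.
#'
#' @param config list as from [pipeline_config()] (partial lists merged
#'   over the defaults) or the path to a YAML file with the same fields.
#' @return list with `records`, `metrics` (or NULL), `paths`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- modifyList(pipeline_config(), config)
  if (is.null(cfg$input_dir) || !dir.exists(cfg$input_dir))
    tp_stop("missing input artifact: input_dir", "tp_missing_error")
  if (is.null(cfg$out_dir)) tp_stop("missing output artifact: out_dir", "tp_missing_error")
  intr_path <- file.path(cfg$input_dir, "intrinsics.json")
  if (!file.exists(intr_path))
    tp_stop("missing input artifact: intrinsics", "tp_missing_error")
  intr <- read_intrinsics(intr_path)
  img_files <- sort(list.files(file.path(cfg$input_dir, "images"), "\\.png$",
                               full.names = TRUE))
  if (!length(img_files)) tp_stop("missing input artifact: images", "tp_missing_error")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  model <- NULL
  if (identical(cfg$segmentation$method, "model")) {
    if (is.null(cfg$segmentation$weights) || !file.exists(cfg$segmentation$weights))
      tp_stop("missing input artifact: weights", "tp_missing_error")
    model <- load_model(cfg$segmentation$weights)
  }
  hdrm <- NULL
  if (!is.null(cfg$hdrm$pairs_csv)) {
    if (!file.exists(cfg$hdrm$pairs_csv))
      tp_stop("missing input artifact: hdrm pairs", "tp_missing_error")
    pairs <- read.csv(cfg$hdrm$pairs_csv)
    hdrm <- hdrm_fit(pairs$d_c, pairs$d_b, gamma_form = cfg$hdrm$gamma_form,
                     seed = cfg$hdrm$seed, ntree = cfg$hdrm$ntree)
  }

  records <- list()
  preds <- list(); truths <- list()
  for (f in img_files) {
    name <- sub("\\.png$", "", basename(f))
    rgb <- png::readPNG(f)
    if (length(dim(rgb)) == 3L && dim(rgb)[3] == 4L) rgb <- rgb[, , 1:3]
    depth_f <- file.path(cfg$input_dir, "depth", paste0(name, ".png"))
    depth <- if (file.exists(depth_f)) read_depth_png(depth_f) else NULL
    fruit <- binarize_section(rgb)
    if (!any(fruit)) next
    seg <- pipeline_segment(rgb, fruit, cfg, model, name)
    d_for_measure <- if (is.null(depth)) NULL else depth
    if (is.null(d_for_measure))
      tp_stop(sprintf("missing input artifact: depth map for %s", name),
              "tp_missing_error")
    rec <- measure_section(rgb, depth, intr, cfg$section_kind, fruit, seg,
                           sample_label = name, fruit_id = 1L, hdrm = hdrm,
                           offset_deg = cfg$offset_deg, band_px = cfg$band_px,
                           min_locule_area = cfg$min_locule_area)
    records[[length(records) + 1L]] <- rec
    mask_f <- file.path(cfg$input_dir, "masks", paste0(name, ".png"))
    if (file.exists(mask_f)) {
      truth <- round(png::readPNG(mask_f) * 255)
      preds[[length(preds) + 1L]] <- (seg > 0) * 1L
      truths[[length(truths) + 1L]] <- (truth > 0) * 1L
    }
  }
  csv_path <- file.path(cfg$out_dir, "phenotypes.csv")
  write_phenotypes(records, csv_path)
  metrics <- NULL
  if (length(preds)) {
    metrics <- evaluate_segmentation(preds, truths, class = 1L)
    metrics$counts <- NULL
    jsonlite::write_json(metrics, file.path(cfg$out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  log_path <- file.path(cfg$out_dir, "run_log.txt")
  writeLines(c(
    sprintf("tomatopheno %s", as.character(utils::packageVersion("tomatopheno"))),
    sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    sprintf("seed: %d", cfg$seed),
    sprintf("config_hash: %s", config_hash(cfg)),
    sprintf("images: %d, records: %d", length(img_files), length(records))
  ), log_path)
  list(records = records, metrics = metrics,
       paths = list(phenotypes = csv_path, log = log_path))
}

# class-structure segmentation for one image under the configured method
pipeline_segment <- function(rgb, fruit, cfg, model, name) {
  if (identical(cfg$segmentation$method, "model")) {
    seg <- segment_image(model, rgb)
    return(seg * (fruit * 1L))
  }
  target <- if (cfg$section_kind == "transverse") cfg$segmentation$locule_rgb
            else cfg$segmentation$scar_rgb
  if (is.null(target)) {
    truth_f <- file.path(cfg$input_dir, "truth", paste0(name, ".json"))
    if (file.exists(truth_f)) {
      tr <- jsonlite::read_json(truth_f, simplifyVector = TRUE)
      target <- if (cfg$section_kind == "transverse") tr$locule_rgb else tr$scar_rgb
    }
  }
  if (is.null(target))
    tp_stop("missing input artifact: segmentation target color", "tp_missing_error")
  (segment_by_color(rgb, target, cfg$segmentation$tol) & fruit) * 1L
}

# stable fingerprint of the effective configuration (no digest dependency)
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE, force = TRUE)
  bytes <- as.integer(charToRaw(as.character(s)))
  h1 <- 5381; h2 <- 52711
  for (b in bytes) {
    h1 <- (h1 * 33 + b) %% 4294967291
    h2 <- (h2 * 31 + b) %% 4294967279
  }
  paste0(format(as.hexmode(as.integer(h1 %% 2147483647)), width = 8),
         format(as.hexmode(as.integer(h2 %% 2147483647)), width = 8))
}
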
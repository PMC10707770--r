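# Dataset emission: synthetic stained sections written as TIFF images with
# metadata encoded in filenames (treatment_stage_tree_fruit_sector_zone_idx)
# plus a CSV manifest, per-cell and per-field truth tables, and a YAML
# parameter sidecar.

#' Write a synthetic stained-section dataset to disk
#'
#' Emits `plan_totals(plan)` images per treatment, with per-zone generator
#' parameters (e.g. a higher cluster density in the inner zone), together
#' with a manifest CSV, ground-truth tables (per cell and per field) and a
#' parameter sidecar. Per-image seeds are derived deterministically from
#' `seed`.
#'
#' @param plan a [sampling_plan()].
#' @param zone_params named list (`In`, `Md`, `Ex`, or the plan's zones) of
#'   [tissue_params()]; a single `tissue_params` is recycled to all zones.
#' @param out_dir output directory (created if needed).
#' @param treatments character vector of treatment labels.
#' @param stage stage label recorded in metadata (`"I"` or `"II"`).
#' @param seed base seed for the per-image seed stream.
#' @return invisibly, the manifest tibble (one row per written image).
#' @export
make_dataset <- function(plan, zone_params, out_dir,
                         treatments = c("control", "RDI"),
                         stage = "I", seed = 1L) {
  validate_sampling_plan(plan)
  if (inherits(zone_params, "tissue_params")) {
    zone_params <- stats::setNames(rep(list(zone_params), length(plan$zones)),
                                   plan$zones)
  }
  stopifnot(all(plan$zones %in% names(zone_params)))
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop("I/O error: cannot create output directory ", out_dir, call. = FALSE)
  }

  manifest <- list(); cells <- list(); fields <- list()
  img_i <- 0L
  for (trt in treatments) {
    for (tree in seq_len(plan$trees_per_treatment)) {
      for (fruit in seq_len(plan$fruits_per_tree)) {
        for (sector in seq_len(plan$sectors_per_fruit)) {
          for (zone in plan$zones) {
            for (idx in seq_len(plan$images_per_zone)) {
              img_i <- img_i + 1L
              # distinct, reproducible seed per image (< 2^31)
              img_seed <- (as.integer(seed) + 7919L * img_i) %% .Machine$integer.max
              zp <- zone_params[[zone]]
              zp$seed <- img_seed
              fname <- sprintf("%s_%s_t%d_f%d_s%d_%s_%d.tif",
                               trt, stage, tree, fruit, sector, zone, idx)
              fld <- implant_stone_clusters(generate_mosaic(zp), zp)
              img <- render_stained_image(fld)
              tiff::writeTIFF(img, file.path(out_dir, fname),
                              bits.per.sample = 8)
              meta <- tibble::tibble(
                image_id = fname, treatment = trt, stage = stage,
                tree = tree, fruit = fruit, sector = sector, zone = zone,
                image_index = idx, pixel_size_um = zp$pixel_size_um,
                field_area_cm2 = fld$field$field_area_cm2, seed = img_seed
              )
              manifest[[img_i]] <- meta
              cells[[img_i]] <- dplyr::mutate(fld$cells, image_id = fname,
                                              .before = 1)
              fields[[img_i]] <- dplyr::bind_cols(
                tibble::tibble(image_id = fname), fld$field)
            }
          }
        }
      }
    }
  }
  manifest <- dplyr::bind_rows(manifest)
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  readr::write_csv(dplyr::bind_rows(cells), file.path(out_dir, "truth_cells.csv"))
  readr::write_csv(dplyr::bind_rows(fields), file.path(out_dir, "truth_fields.csv"))
  sidecar <- lapply(zone_params, function(zp) unclass(zp))
  yaml::write_yaml(list(stage = stage, seed = seed, zones = sidecar),
                   file.path(out_dir, "params.yaml"))
  invisible(manifest)
}

#' Read a section image with its metadata
#'
#' Accepts TIFF or PNG. Metadata is parsed from the filename convention
#' `treatment_stage_t<tree>_f<fruit>_s<sector>_<zone>_<idx>.(tif|png)`
#' unless a manifest row is supplied.
#'
#' @param path image path.
#' @param pixel_size_um pixel calibration; taken from `meta` if present.
#' @param meta optional one-row manifest data frame for this image.
#' @return a `section_image` list: `img` (RGB array), `pixel_size_um`,
#'   `meta` (tibble).
#' @export
read_section <- function(path, pixel_size_um = NULL, meta = NULL) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("format error: unsupported image format: ", ext, call. = FALSE)
  )
  if (length(dim(img)) != 3 || dim(img)[3] < 3) {
    stop("format error: expected an RGB image", call. = FALSE)
  }
  img <- img[, , 1:3]
  if (is.null(meta)) {
    meta <- parse_image_filename(basename(path))
  } else {
    meta <- tibble::as_tibble(meta)
  }
  psz <- pixel_size_um %||%
    (if ("pixel_size_um" %in% names(meta)) meta$pixel_size_um else NULL)
  if (is.null(psz) || !is.finite(psz) || psz <= 0) {
    stop("manifest error: positive pixel_size_um required for ", path,
         call. = FALSE)
  }
  structure(list(img = img, pixel_size_um = psz, meta = meta),
            class = "section_image")
}

parse_image_filename <- function(fname) {
  stem <- tools::file_path_sans_ext(fname)
  parts <- strsplit(stem, "_", fixed = TRUE)[[1]]
  if (length(parts) != 7 || !grepl("^t[0-9]+$", parts[3]) ||
      !grepl("^f[0-9]+$", parts[4]) || !grepl("^s[0-9]+$", parts[5])) {
    stop("manifest error: cannot parse metadata from filename: ", fname,
         call. = FALSE)
  }
  tibble::tibble(
    image_id = fname, treatment = parts[1], stage = parts[2],
    tree = as.integer(sub("t", "", parts[3])),
    fruit = as.integer(sub("f", "", parts[4])),
    sector = as.integer(sub("s", "", parts[5])),
    zone = parts[6], image_index = as.integer(parts[7])
  )
}
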
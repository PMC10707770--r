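# End-to-end orchestration: analyze single sections, run whole datasets
# (segment -> quantify -> aggregate -> stats), and validate automatic
# measurements against a reference table.

#' Pipeline run configuration
#'
#' @param input_dir directory of section images (and optionally
#'   `manifest.csv`).
#' @param output_dir directory for result tables, manifest and log.
#' @param pixel_size_um fallback pixel calibration when the manifest has
#'   none.
#' @param thresholds stain thresholds, see [stain_thresholds()].
#' @param adjacency_px stone cell adjacency tolerance (pixels).
#' @param texture_soft_max,texture_coarse_min texture class boundaries (um).
#' @param zone_weights `"area"` or `"geometric"` global weighting mode.
#' @param geometric_weights named zone weights for the geometric mode.
#' @param alpha significance level for the statistics stage.
#' @param seed seed recorded in the manifest (the analysis itself is
#'   deterministic).
#' @return a `run_config` list, validated.
#' @export
run_config <- function(input_dir, output_dir,
                       pixel_size_um = NULL,
                       thresholds = stain_thresholds(),
                       adjacency_px = 3L,
                       texture_soft_max = 150, texture_coarse_min = 250,
                       zone_weights = c("area", "geometric"),
                       geometric_weights = NULL,
                       alpha = 0.05, seed = 1L) {
  zone_weights <- match.arg(zone_weights)
  if (texture_soft_max >= texture_coarse_min) {
    stop("config error: texture thresholds must be ordered", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) stop("config error: alpha in (0,1)", call. = FALSE)
  if (adjacency_px < 1) stop("config error: adjacency_px >= 1", call. = FALSE)
  structure(list(
    input_dir = input_dir, output_dir = output_dir,
    pixel_size_um = pixel_size_um, thresholds = thresholds,
    adjacency_px = as.integer(adjacency_px),
    texture_soft_max = texture_soft_max,
    texture_coarse_min = texture_coarse_min,
    zone_weights = zone_weights, geometric_weights = geometric_weights,
    alpha = alpha, seed = as.integer(seed)
  ), class = "run_config")
}

#' Analyze one stained section
#'
#' Runs stain separation, stone cell and parenchyma segmentation, adjacency
#' grouping and contact classification on one RGB section image.
#'
#' @param img RGB array in [0, 1] (or a `section_image` from
#'   [read_section()]).
#' @param pixel_size_um pixel calibration (taken from a `section_image`).
#' @param thresholds stain thresholds.
#' @param adjacency_px stone cell adjacency tolerance in pixels.
#' @return a `section_analysis` list: `stones`, `parenchyma` (instance
#'   tibbles), `groups`, `masks`, `summary` (one-row tibble with field area,
#'   SCC presence and parenchyma means).
#' @export
analyze_section <- function(img, pixel_size_um = NULL,
                            thresholds = stain_thresholds(),
                            adjacency_px = 3L) {
  meta <- NULL
  if (inherits(img, "section_image")) {
    pixel_size_um <- img$pixel_size_um
    meta <- img$meta
    img <- img$img
  }
  stopifnot(is.numeric(pixel_size_um), pixel_size_um > 0)
  masks <- separate_stains(img, thresholds)
  stones <- segment_stone_cells(masks, pixel_size_um, thresholds)
  parenchyma <- segment_parenchyma(masks, attr(stones, "labels"),
                                   pixel_size_um)
  groups <- group_stone_cells(stones, adjacency_px = adjacency_px)
  par_meas <- measure_parenchyma(parenchyma, keep_border = TRUE)
  par_meas <- classify_contact(par_meas, groups, attr(stones, "labels"),
                               par_labels = attr(parenchyma, "labels"),
                               dilate_px = adjacency_px)
  field_cm2 <- prod(dim(masks$lignin)) * pixel_size_um^2 / 1e8
  presence <- zone_presence(groups, field_cm2)
  interior_scc <- groups$classification == "SCC" & !groups$border
  par_ok <- !par_meas$border
  summary <- tibble::tibble(
    field_area_cm2 = field_cm2,
    n_stone_cells = nrow(stones),
    n_scc = sum(groups$classification == "SCC"),
    n_isolated_groups = sum(groups$classification == "isolated"),
    scc_percent_area = presence$scc_percent_area,
    scc_count_per_cm2 = presence$scc_count_per_cm2,
    mean_scc_size_um2 = if (any(interior_scc))
      mean(groups$total_area_um2[interior_scc]) else NA_real_,
    mean_cells_per_scc = if (any(interior_scc))
      mean(groups$n_cells[interior_scc]) else NA_real_,
    mean_parenchyma_area_um2 = if (any(par_ok))
      mean(par_meas$area_um2[par_ok]) else NA_real_,
    mean_parenchyma_circularity = if (any(par_ok))
      mean(par_meas$circularity[par_ok]) else NA_real_
  )
  structure(list(stones = stones, parenchyma = parenchyma, groups = groups,
                 par_measures = par_meas, masks = masks, meta = meta,
                 pixel_size_um = pixel_size_um, summary = summary),
            class = "section_analysis")
}

#' @export
print.section_analysis <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<section_analysis> %.4f cm^2: %d stone cells in %d SCC + %d isolated groups (%.2f%% area), %d parenchyma\n",
    s$field_area_cm2, s$n_stone_cells, s$n_scc, s$n_isolated_groups,
    s$scc_percent_area, nrow(x$parenchyma)))
  invisible(x)
}

#' @rdname analyze_section
#' @param x a `section_analysis`.
#' @param ... unused.
#' @export
tidy.section_analysis <- function(x, ...) {
  st <- tibble::as_tibble(x$stones)
  st$contact_class <- rep(NA_character_, nrow(st))
  pr <- tibble::as_tibble(x$parenchyma)
  pr <- dplyr::left_join(
    pr, x$par_measures[c("cell_id", "contact_class")], by = "cell_id")
  dplyr::bind_rows(st, pr)
}

#' @rdname analyze_section
#' @export
glance.section_analysis <- function(x, ...) x$summary

#' Run the full pipeline over a dataset directory
#'
#' Reads every TIFF/PNG in `config$input_dir` (metadata from `manifest.csv`
#' when present, else from filenames), analyzes each section, and writes
#' per-cell, per-group, per-image, per-zone and global metric CSVs plus a
#' JSON run manifest. Unreadable or unparseable images are quarantined and
#' listed in the manifest, not silently dropped. When at least two treatment
#' levels with two fruits each are present, the statistics stage (nested
#' repeated-measures ANOVA with Tukey letters per metric) is run and written
#' too. Reruns with the same configuration and inputs are byte-identical.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the result tables and the quarantine list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$output_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  logmsg <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    writeLines(msg, log_con)
    message(msg)
  }

  files <- list.files(config$input_dir, pattern = "\\.(tif|tiff|png)$",
                      ignore.case = TRUE)
  files <- sort(files)
  if (!length(files)) stop("no images found in ", config$input_dir, call. = FALSE)
  manifest_path <- file.path(config$input_dir, "manifest.csv")
  manifest <- if (file.exists(manifest_path)) {
    readr::read_csv(manifest_path, show_col_types = FALSE)
  } else NULL

  cells <- list(); groups <- list(); images <- list(); quarantine <- list()
  for (f in files) {
    res <- tryCatch({
      meta <- if (!is.null(manifest)) {
        row <- manifest[manifest$image_id == f, ]
        if (nrow(row) != 1) stop("manifest error: no manifest row for ", f)
        row
      } else NULL
      sec <- read_section(file.path(config$input_dir, f),
                          pixel_size_um = config$pixel_size_um, meta = meta)
      validate_zones(sec$meta$zone)
      an <- analyze_section(sec, thresholds = config$thresholds,
                            adjacency_px = config$adjacency_px)
      list(meta = sec$meta, an = an)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      quarantine[[f]] <- conditionMessage(res)
      logmsg("QUARANTINE ", f, ": ", conditionMessage(res))
      next
    }
    meta <- res$meta; an <- res$an
    key <- meta[c("image_id", "treatment", "stage", "tree", "fruit",
                  "sector", "zone")]
    add_key <- function(tab) dplyr::bind_cols(key[rep(1L, nrow(tab)), ], tab)
    cells[[f]] <- add_key(tidy(an))
    if (nrow(an$groups) > 0) {
      g <- tibble::as_tibble(an$groups)
      g$members <- vapply(g$members, paste, "", collapse = ";")
      groups[[f]] <- add_key(g)
    }
    n_border_excluded <- sum(an$parenchyma$border)
    images[[f]] <- dplyr::bind_cols(
      key, an$summary,
      tibble::tibble(analyzed_area_cm2 = an$summary$field_area_cm2,
                     n_border_parenchyma_excluded = n_border_excluded))
    logmsg("analyzed ", f, ": ", an$summary$n_stone_cells, " stone cells, ",
           nrow(an$parenchyma), " parenchyma")
  }
  if (!length(images)) stop("all images failed analysis", call. = FALSE)
  cells <- dplyr::bind_rows(cells)
  groups <- dplyr::bind_rows(groups)
  images <- dplyr::bind_rows(images)
  if (nrow(groups) == 0) {
    groups <- tibble::tibble(
      image_id = character(0), treatment = character(0), stage = character(0),
      tree = integer(0), fruit = integer(0), sector = integer(0),
      zone = character(0), group_id = integer(0), n_cells = integer(0),
      total_area_um2 = numeric(0), eq_diameter_um = numeric(0),
      classification = character(0), border = logical(0),
      members = character(0))
  }

  # per treatment x stage x zone metrics, then global per treatment x stage
  zone_tabs <- list(); global_tabs <- list(); texture_tabs <- list()
  for (ts in split(images, interaction(images$treatment, images$stage,
                                       drop = TRUE))) {
    trt <- ts$treatment[1]; stg <- ts$stage[1]
    g_ts <- groups[groups$treatment == trt & groups$stage == stg, ]
    # recompute parenchyma measures with contact class from the cells table
    p_ts <- cells[cells$treatment == trt & cells$stage == stg &
                    cells$type == "parenchyma" & !cells$border, ]
    p_ts$circularity <- p_ts$feret_min_um / p_ts$feret_max_um
    zm <- compute_zone_metrics(
      dplyr::transmute(ts, image_id, zone, analyzed_area_cm2),
      g_ts, p_ts)
    gm <- tryCatch(
      aggregate_global(zm, weights = config$zone_weights,
                       geometric_weights = config$geometric_weights),
      error = function(e) {
        logmsg("global aggregation skipped for ", trt, "/", stg, ": ",
               conditionMessage(e))
        NULL
      })
    zone_tabs[[paste(trt, stg)]] <- dplyr::bind_cols(
      tibble::tibble(treatment = trt, stage = stg), zm)
    if (!is.null(gm)) {
      global_tabs[[paste(trt, stg)]] <- dplyr::bind_cols(
        tibble::tibble(treatment = trt, stage = stg), gm)
    }
    scc_ts <- g_ts[g_ts$classification == "SCC", ]
    texture_tabs[[paste(trt, stg)]] <- tibble::tibble(
      treatment = trt, stage = stg,
      texture = if (nrow(scc_ts)) texture_class(
        2 * sqrt(mean(scc_ts$total_area_um2) / pi),
        config$texture_soft_max, config$texture_coarse_min)
      else factor(NA, levels = levels(texture_class(1)))
    )
  }
  zone_metrics <- dplyr::bind_rows(zone_tabs)
  global_metrics <- dplyr::bind_rows(global_tabs)
  texture <- dplyr::bind_rows(texture_tabs)

  stats_tabs <- run_pipeline_stats(images, config, logmsg)

  readr::write_csv(cells, file.path(config$output_dir, "cells.csv"))
  readr::write_csv(groups, file.path(config$output_dir, "groups.csv"))
  readr::write_csv(images, file.path(config$output_dir, "images.csv"))
  readr::write_csv(zone_metrics, file.path(config$output_dir, "zone_metrics.csv"))
  readr::write_csv(global_metrics, file.path(config$output_dir, "global_metrics.csv"))
  readr::write_csv(texture, file.path(config$output_dir, "texture.csv"))
  if (!is.null(stats_tabs$effects)) {
    readr::write_csv(stats_tabs$effects,
                     file.path(config$output_dir, "anova_effects.csv"))
  }
  if (!is.null(stats_tabs$letters)) {
    readr::write_csv(stats_tabs$letters,
                     file.path(config$output_dir, "tukey_letters.csv"))
  }

  run_manifest <- list(
    package_version = as.character(utils::packageVersion("stonecellr")),
    config_hash = rlang::hash(unclass(config)),
    n_images_analyzed = nrow(images),
    n_quarantined = length(quarantine),
    quarantine = quarantine,
    rows = list(cells = nrow(cells), groups = nrow(groups),
                images = nrow(images), zone_metrics = nrow(zone_metrics))
  )
  jsonlite::write_json(run_manifest,
                       file.path(config$output_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(cells = cells, groups = groups, images = images,
                 zone_metrics = zone_metrics, global_metrics = global_metrics,
                 texture = texture, stats = stats_tabs,
                 quarantine = quarantine))
}

# Statistics stage of the pipeline: per-image metrics analyzed by nested
# RM-ANOVA when the design supports it (>= 2 treatments, >= 2 fruits each).
run_pipeline_stats <- function(images, config, logmsg = message) {
  metrics <- c("scc_percent_area", "scc_count_per_cm2", "mean_scc_size_um2",
               "mean_cells_per_scc", "mean_parenchyma_area_um2",
               "mean_parenchyma_circularity")
  if (length(unique(images$treatment)) < 2) {
    logmsg("statistics stage skipped: fewer than 2 treatment levels")
    return(list(effects = NULL, letters = NULL))
  }
  between <- if (length(unique(images$stage)) > 1) c("treatment", "stage")
             else "treatment"
  # fruit ids repeat across trees; build a tree-unique fruit identifier
  images$fruit_uid <- paste(images$tree, images$fruit, sep = "_")
  eff <- list(); let <- list()
  for (m in metrics) {
    d <- images[is.finite(images[[m]]), ]
    fit <- tryCatch({
      resp <- m
      if (m == "scc_percent_area") {
        d$.resp <- arcsine_transform(pmin(pmax(d[[m]] / 100, 0), 1))
        resp <- ".resp"
      }
      nested_rm_anova(d, resp, between = between, unit = "fruit_uid",
                      alpha = config$alpha)
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      logmsg("ANOVA for ", m, " skipped: ", conditionMessage(fit))
      next
    }
    eff[[m]] <- dplyr::mutate(fit$effects, metric = m, .before = 1)
    grp_means <- tapply(fit$fruit_means$.y,
                        fit$fruit_means[[between[1]]], mean)
    grp_n <- table(fit$fruit_means[[between[1]]])
    lt <- tryCatch(
      tukey_letters(grp_means, as.numeric(grp_n),
                    fit$strata$between$ms / fit$n_zone,
                    fit$strata$between$df, alpha = config$alpha),
      error = function(e) NULL)
    if (!is.null(lt)) {
      let[[m]] <- dplyr::mutate(tibble::as_tibble(lt), metric = m,
                                factor = between[1], .before = 1)
    }
  }
  list(effects = if (length(eff)) dplyr::bind_rows(eff) else NULL,
       letters = if (length(let)) dplyr::bind_rows(let) else NULL)
}

#' Validate automatic measurements against a reference table
#'
#' Joins automatic and reference (manual or ground-truth) measurements by
#' key columns and reports the squared Pearson correlation per metric. On
#' synthetic benchmarks the reference is the generator truth and R^2 >= 0.9
#' is the customary pass line for automated histological measurement.
#'
#' @param auto,reference data frames with the key columns and metrics.
#' @param keys join key column names (default `"image_id"`).
#' @param metrics metric column names to correlate; defaults to the numeric
#'   columns common to both tables.
#' @return tibble with `metric`, `n`, `r_squared`.
#' @export
validate_against_manual <- function(auto, reference, keys = "image_id",
                                    metrics = NULL) {
  joined <- dplyr::inner_join(tibble::as_tibble(auto),
                              tibble::as_tibble(reference),
                              by = keys, suffix = c("_auto", "_ref"))
  if (nrow(joined) == 0) {
    stop("join error: no overlapping keys between automatic and reference ",
         "tables", call. = FALSE)
  }
  if (is.null(metrics)) {
    num_a <- names(auto)[vapply(auto, is.numeric, TRUE)]
    num_r <- names(reference)[vapply(reference, is.numeric, TRUE)]
    metrics <- setdiff(intersect(num_a, num_r), keys)
  }
  purrr::map_dfr(metrics, function(m) {
    x <- joined[[paste0(m, "_auto")]]
    y <- joined[[paste0(m, "_ref")]]
    r2 <- tryCatch(r_squared(x, y), error = function(e) NA_real_)
    tibble::tibble(metric = m, n = sum(is.finite(x) & is.finite(y)),
                   r_squared = r2)
  })
}
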
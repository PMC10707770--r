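# Zonal partitioning and aggregation: sectors are divided at equal distances
# along the radius into three concentric zones (In, interior; Md, middle;
# Ex, exterior); global values weight each zone by its tissue-area
# contribution so that, with analyzed-area weights, they equal a pooled
# single-pass computation.

zone_levels <- c("In", "Md", "Ex")

#' Partition a sector mask into three concentric zones
#'
#' Splits a sector into three bands of equal radial extent. With an `origin`
#' (the interior apex of a wedge-shaped sector, in `(row, col)` pixels),
#' bands are concentric rings of the radial distance; without one, the
#' sector is split along its columns (a rectangular strip whose interior end
#' is the left edge by convention). Zone `In` is nearest the origin/interior.
#'
#' @param mask logical matrix of sector tissue pixels.
#' @param origin optional `(row, col)` of the interior apex.
#' @return integer matrix: 0 outside the mask, 1/2/3 for In/Md/Ex, with
#'   levels attached as attribute `"zones"`.
#' @export
partition_zones <- function(mask, origin = NULL) {
  stopifnot(is.matrix(mask))
  mask <- mask > 0
  if (!any(mask)) stop("empty sector mask", call. = FALSE)
  ny <- nrow(mask); nx <- ncol(mask)
  idx <- which(mask)
  rows <- ((idx - 1L) %% ny) + 1L
  cols <- ((idx - 1L) %/% ny) + 1L
  r <- if (is.null(origin)) {
    cols
  } else {
    sqrt((rows - origin[1])^2 + (cols - origin[2])^2)
  }
  lo <- min(r); hi <- max(r)
  band <- pmin(3L, pmax(1L, 1L + floor(3 * (r - lo) / (hi - lo + 1e-9))))
  out <- matrix(0L, ny, nx)
  out[idx] <- band
  attr(out, "zones") <- zone_levels
  out
}

#' Validate per-image zone metadata
#'
#' @param zone character vector of zone labels.
#' @return the input, normalized, or a validation error for unknown labels.
#' @export
validate_zones <- function(zone) {
  bad <- setdiff(unique(zone), zone_levels)
  if (length(bad)) {
    stop("validation error: unknown zone label(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  factor(zone, levels = zone_levels)
}

#' SCC presence in an analyzed area
#'
#' @param groups group tibble from [group_stone_cells()]; isolated groups
#'   are excluded from both measures.
#' @param analyzed_area_cm2 analyzed tissue area in cm^2.
#' @return one-row tibble: `scc_percent_area` (100 x total SCC area /
#'   analyzed area) and `scc_count_per_cm2`.
#' @export
zone_presence <- function(groups, analyzed_area_cm2) {
  if (!is.numeric(analyzed_area_cm2) || analyzed_area_cm2 <= 0) {
    stop("division error: analyzed area must be positive", call. = FALSE)
  }
  scc <- groups[groups$classification == "SCC", ]
  tibble::tibble(
    scc_percent_area = 100 * sum(scc$total_area_um2) / (analyzed_area_cm2 * 1e8),
    scc_count_per_cm2 = nrow(scc) / analyzed_area_cm2
  )
}

#' Per-zone summary metrics from per-image tables
#'
#' Pools the per-image group and parenchyma tables of one treatment x stage
#' into one row per zone: analyzed area, SCC presence (percent area, count
#' per cm^2), cluster composition (mean SCC size, cells per SCC, mean stone
#' cell size), isolated percentage, and parenchyma size/shape split by
#' contact class. Carries the pooling denominators (`n_scc`, cell counts) so
#' that [aggregate_global()] can reproduce pooled statistics exactly.
#'
#' @param images per-image tibble with columns `image_id`, `zone`,
#'   `analyzed_area_cm2`.
#' @param groups per-image group tibble (with `image_id`, `zone` columns).
#' @param parenchyma per-image parenchyma tibble (with `image_id`, `zone`,
#'   `area_um2`, `circularity`, `contact_class`).
#' @return tibble with one row per zone.
#' @export
compute_zone_metrics <- function(images, groups, parenchyma) {
  images <- dplyr::mutate(images, zone = validate_zones(zone))
  zones <- images |>
    dplyr::group_by(zone) |>
    dplyr::summarise(analyzed_area_cm2 = sum(analyzed_area_cm2),
                     n_images = dplyr::n(), .groups = "drop")

  gstats <- groups |>
    dplyr::mutate(zone = validate_zones(zone)) |>
    dplyr::group_by(zone) |>
    dplyr::summarise(
      n_scc = sum(classification == "SCC"),
      n_scc_interior = sum(classification == "SCC" & !border),
      scc_area_um2 = sum(total_area_um2[classification == "SCC"]),
      scc_cells = sum(n_cells[classification == "SCC"]),
      isolated_cells = sum(n_cells[classification == "isolated"]),
      mean_scc_size_um2 = mean(total_area_um2[classification == "SCC" & !border]),
      mean_cells_per_scc = mean(n_cells[classification == "SCC" & !border]),
      .groups = "drop"
    )

  pstats <- parenchyma |>
    dplyr::mutate(zone = validate_zones(zone)) |>
    dplyr::group_by(zone) |>
    dplyr::summarise(
      n_parenchyma = dplyr::n(),
      n_par_general = sum(contact_class == "general"),
      n_par_around = sum(contact_class == "around_cluster"),
      mean_par_area_general_um2 = mean(area_um2[contact_class == "general"]),
      mean_par_area_around_um2 = mean(area_um2[contact_class == "around_cluster"]),
      mean_circularity_general = mean(circularity[contact_class == "general"]),
      mean_circularity_around = mean(circularity[contact_class == "around_cluster"]),
      .groups = "drop"
    )

  zones |>
    dplyr::left_join(gstats, by = "zone") |>
    dplyr::left_join(pstats, by = "zone") |>
    dplyr::mutate(
      n_scc = dplyr::coalesce(n_scc, 0L),
      n_scc_interior = dplyr::coalesce(n_scc_interior, 0L),
      scc_area_um2 = dplyr::coalesce(scc_area_um2, 0),
      scc_cells = dplyr::coalesce(scc_cells, 0L),
      isolated_cells = dplyr::coalesce(isolated_cells, 0L),
      scc_percent_area = 100 * scc_area_um2 / (analyzed_area_cm2 * 1e8),
      scc_count_per_cm2 = n_scc / analyzed_area_cm2,
      mean_stone_cell_size_um2 = ifelse(scc_cells > 0, scc_area_um2 / scc_cells, NA_real_),
      isolated_percentage = ifelse(scc_cells > 0, 100 * isolated_cells / scc_cells,
                                   NA_real_)
    )
}

#' Aggregate zone metrics into whole-flesh global values
#'
#' Global values consider the proportional area contribution of each zone.
#' With `weights = "area"` (default) every metric is a ratio of pooled sums:
#' presence metrics are weighted by analyzed area, per-cluster metrics by
#' cluster counts and per-cell metrics by cell counts, which reproduces a
#' pooled single-pass computation over all images exactly. With
#' `weights = "geometric"` all metrics are weighted by the supplied
#' geometric zone areas (e.g. annulus areas of the whole fruit).
#'
#' @param zm zone metrics tibble from [compute_zone_metrics()].
#' @param weights `"area"` or `"geometric"`.
#' @param geometric_weights named numeric vector of zone weights (required
#'   for `weights = "geometric"`).
#' @return one-row tibble of global metrics.
#' @export
aggregate_global <- function(zm, weights = c("area", "geometric"),
                             geometric_weights = NULL) {
  weights <- match.arg(weights)
  if (!all(zone_levels %in% as.character(zm$zone))) {
    stop("aggregation error: missing zone(s): ",
         paste(setdiff(zone_levels, as.character(zm$zone)), collapse = ", "),
         call. = FALSE)
  }
  wmean <- function(x, w) {
    ok <- !is.na(x) & w > 0
    if (!any(ok)) return(NA_real_)
    sum(x[ok] * w[ok]) / sum(w[ok])
  }
  if (weights == "geometric") {
    if (is.null(geometric_weights)) {
      stop("aggregation error: geometric weights required", call. = FALSE)
    }
    w <- geometric_weights[as.character(zm$zone)]
    if (any(is.na(w)) || any(w <= 0)) {
      stop("aggregation error: weights must be positive for every zone",
           call. = FALSE)
    }
    wa <- ws <- wc <- wp <- w
  } else {
    wa <- zm$analyzed_area_cm2           # presence metrics
    ws <- zm$n_scc_interior              # per-cluster metrics (border excluded)
    wc <- zm$scc_cells                   # per-stone-cell metrics
    wp <- zm$n_parenchyma                # per-parenchyma metrics
  }
  tibble::tibble(
    analyzed_area_cm2 = sum(zm$analyzed_area_cm2),
    scc_percent_area = wmean(zm$scc_percent_area, wa),
    scc_count_per_cm2 = wmean(zm$scc_count_per_cm2, wa),
    mean_scc_size_um2 = wmean(zm$mean_scc_size_um2, ws),
    mean_cells_per_scc = wmean(zm$mean_cells_per_scc, ws),
    mean_stone_cell_size_um2 = wmean(zm$mean_stone_cell_size_um2, wc),
    isolated_percentage = wmean(zm$isolated_percentage, wc),
    mean_par_area_general_um2 = wmean(zm$mean_par_area_general_um2,
                                      if (weights == "area") zm$n_par_general else wp),
    mean_par_area_around_um2 = wmean(zm$mean_par_area_around_um2,
                                     if (weights == "area") zm$n_par_around else wp),
    mean_circularity_general = wmean(zm$mean_circularity_general,
                                     if (weights == "area") zm$n_par_general else wp),
    mean_circularity_around = wmean(zm$mean_circularity_around,
                                    if (weights == "area") zm$n_par_around else wp)
  )
}

#' Classify flesh texture from SCC equivalent diameter
#'
#' Clusters with equivalent diameters exceeding 250 um yield a coarse,
#' gritty flesh texture; between 150 and 250 um (inclusive) a soft texture
#' with slight grittiness; below 150 um a highly soft texture.
#'
#' @param diameter_um positive numeric vector of SCC equivalent diameters.
#' @param soft_max,coarse_min class boundaries in um (defaults 150 and 250).
#' @return factor with levels `highly_soft`, `soft_slight_gritty`,
#'   `coarse_gritty`.
#' @export
texture_class <- function(diameter_um, soft_max = 150, coarse_min = 250) {
  if (any(!is.finite(diameter_um)) || any(diameter_um <= 0)) {
    stop("validation error: diameters must be positive and finite",
         call. = FALSE)
  }
  if (soft_max >= coarse_min) {
    stop("validation error: texture thresholds must be ordered", call. = FALSE)
  }
  cls <- ifelse(diameter_um > coarse_min, "coarse_gritty",
                ifelse(diameter_um >= soft_max, "soft_slight_gritty",
                       "highly_soft"))
  factor(cls, levels = c("highly_soft", "soft_slight_gritty", "coarse_gritty"))
}
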
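# Grouping of stone cells into clusters (SCCs) versus isolated cells, and
# per-cell morphometry. The operational definitions: a stone cell cluster
# contains more than three adjoining stone cells; single stone cells and
# groups of two or three, separated from other stone cells by at least one
# parenchyma cell, are isolated. "Adjoining" means instances whose pixel
# sets come within one wall-band dilation of each other.

#' Group stone cells into clusters and isolated groups
#'
#' Builds the adjacency graph of stone cell instances (pixel sets within
#' Chebyshev distance `adjacency_px` of each other) and takes its connected
#' components as groups. Groups with more than three members are classified
#' as SCCs, the rest as isolated.
#'
#' @param instances stone instance tibble from [segment_stone_cells()].
#' @param labels instance label raster; defaults to the `"labels"` attribute
#'   of `instances`.
#' @param adjacency_px adjacency tolerance in pixels (one wall band plus one;
#'   default 3 matches the default 2 px wall).
#' @return tibble of groups: `group_id`, `n_cells`, `total_area_um2`,
#'   `eq_diameter_um` (`2*sqrt(area/pi)`), `classification` (`"SCC"` or
#'   `"isolated"`), `border`, and `members` (list-column of cell ids). The
#'   per-cell group assignment is attached as attribute `"membership"`.
#' @export
group_stone_cells <- function(instances, labels = attr(instances, "labels"),
                              adjacency_px = 3L) {
  empty <- tibble::tibble(
    group_id = integer(0), n_cells = integer(0), total_area_um2 = numeric(0),
    eq_diameter_um = numeric(0), classification = character(0),
    border = logical(0), members = list()
  )
  if (is.null(instances) || nrow(instances) == 0) {
    return(structure(empty, membership = tibble::tibble(
      cell_id = integer(0), group_id = integer(0))))
  }
  stopifnot(!is.null(labels))
  ids <- instances$cell_id
  pairs <- label_adjacency_pairs(labels, radius = as.integer(adjacency_px))
  comp <- union_find_components(ids, pairs)
  membership <- tibble::tibble(cell_id = ids, group_id = comp)
  groups <- instances |>
    dplyr::mutate(group_id = comp) |>
    dplyr::group_by(group_id) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      total_area_um2 = sum(area_um2),
      border = any(border),
      members = list(cell_id),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      eq_diameter_um = 2 * sqrt(total_area_um2 / pi),
      classification = ifelse(n_cells > 3, "SCC", "isolated")
    ) |>
    dplyr::select(group_id, n_cells, total_area_um2, eq_diameter_um,
                  classification, border, members)
  structure(groups, membership = membership)
}

#' Cluster-level metrics for SCCs
#'
#' For each stone cell cluster: its size (total area), cell count, mean
#' stone cell size (size / count) and equivalent-circle diameter. The mean
#' stone cell size times the cell count reproduces the cluster size exactly.
#'
#' @param groups group tibble from [group_stone_cells()]; all rows must be
#'   classified `"SCC"` (subset first).
#' @return tibble with `group_id`, `size_um2`, `n_cells`,
#'   `mean_stone_cell_size_um2`, `eq_diameter_um`.
#' @export
scc_metrics <- function(groups) {
  if (nrow(groups) > 0 && any(groups$classification != "SCC")) {
    stop("classification error: scc_metrics() applies to SCC groups only ",
         "(isolated groups supplied)", call. = FALSE)
  }
  tibble::tibble(
    group_id = groups$group_id,
    size_um2 = groups$total_area_um2,
    n_cells = groups$n_cells,
    mean_stone_cell_size_um2 = groups$total_area_um2 / groups$n_cells,
    eq_diameter_um = groups$eq_diameter_um
  )
}

#' Percentage of isolated stone cells relative to cells within SCCs
#'
#' @param groups group tibble from [group_stone_cells()].
#' @return `100 * (cells in isolated groups) / (cells in SCC groups)`.
#'   Signals an error when there are no SCC cells (the ratio is undefined).
#' @export
isolated_percentage <- function(groups) {
  n_scc <- sum(groups$n_cells[groups$classification == "SCC"])
  n_iso <- sum(groups$n_cells[groups$classification == "isolated"])
  if (n_scc == 0) {
    stop("division error: no stone cells within SCCs; isolated percentage ",
         "is undefined", call. = FALSE)
  }
  100 * n_iso / n_scc
}

#' Measure parenchyma cell size and circularity
#'
#' The circularity shape index is the ratio of the smallest to the largest
#' Feret diameter, in (0, 1]: values near 1 indicate a circular cell, values
#' near 0 an elongated one. Instances touching the image border are excluded
#' (their size and shape are truncated by the field of view); degenerate
#' instances (a single pixel) are excluded with a warning.
#'
#' @param instances parenchyma instance tibble from [segment_parenchyma()].
#' @param keep_border keep border-touching instances (default drops them).
#' @return tibble with `cell_id`, `area_um2`, `circularity`, `border`.
#' @export
measure_parenchyma <- function(instances, keep_border = FALSE) {
  x <- tibble::as_tibble(instances)
  degenerate <- x$feret_min_um <= 0 | x$area_um2 <= 0
  if (any(degenerate)) {
    warning(sum(degenerate), " degenerate parenchyma instance(s) excluded")
    x <- x[!degenerate, ]
  }
  if (!keep_border) x <- x[!x$border, ]
  tibble::tibble(
    cell_id = x$cell_id,
    area_um2 = x$area_um2,
    circularity = x$feret_min_um / x$feret_max_um,
    border = x$border
  )
}

#' Classify parenchyma cells by contact with stone cell clusters
#'
#' A parenchyma cell is `"around_cluster"` if its lumen comes within one
#' wall-band dilation of any SCC member pixel (it shares a wall with the
#' cluster), `"general"` otherwise. Isolated stone cells do not confer
#' around-cluster status.
#'
#' @param parenchyma parenchyma instance tibble (attribute `"labels"` or
#'   `par_labels` must supply the lumen raster).
#' @param groups group tibble from [group_stone_cells()].
#' @param stone_labels stone instance raster.
#' @param par_labels parenchyma lumen raster.
#' @param dilate_px dilation radius in pixels (wall band + 1).
#' @return the parenchyma tibble with a `contact_class` column.
#' @export
classify_contact <- function(parenchyma, groups, stone_labels,
                             par_labels = attr(parenchyma, "labels"),
                             dilate_px = 3L) {
  stopifnot(!is.null(par_labels))
  out <- tibble::as_tibble(parenchyma)
  scc_members <- unlist(groups$members[groups$classification == "SCC"])
  if (length(scc_members) == 0 || is.null(stone_labels)) {
    out$contact_class <- "general"
    return(out)
  }
  scc_mask <- matrix(stone_labels %in% scc_members,
                     nrow(stone_labels), ncol(stone_labels))
  near <- dilate_mask(scc_mask, as.integer(dilate_px))
  touching <- unique(par_labels[near & par_labels > 0L])
  out$contact_class <- ifelse(out$cell_id %in% touching,
                              "around_cluster", "general")
  out
}
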
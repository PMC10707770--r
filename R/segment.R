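# Instance segmentation of stone cells and parenchyma lumina from stain
# masks. Stone cells inside a cluster are visually fused by lignified seams;
# they are split along that internal boundary evidence when present, with a
# distance-transform watershed as fallback for seam-free fusions.

#' Segment stone cell instances from stain masks
#'
#' Connected lignin regions are split into individual stone cells along
#' internal seam evidence: lignified walls between adjoining stone cells are
#' darker than cell bodies, so lignin pixels below `seam_value_max`
#' brightness are removed before labeling. Components without any seam
#' evidence that still look like fusions (solid, not ring-shaped) are split
#' by a watershed on the distance transform. Ring-stage cells (a lignified
#' annulus around an unstained lumen) are detected by comparing the filled
#' to the stained area, and are closed by filling so their area is the
#' whole-cell area.
#'
#' @param masks a `stain_masks` from [separate_stains()].
#' @param pixel_size_um micrometres per pixel.
#' @param thresholds see [stain_thresholds()] (`seam_value_max` is used).
#' @param min_area_um2 instances smaller than this are discarded as debris.
#' @param ring_fill_ratio filled/stained area ratio above which an instance
#'   is classified as a ring-stage cell.
#' @return tibble of stone cell instances (`cell_id`, `area_um2`,
#'   `feret_max_um`, `feret_min_um`, `lignification`, centroid, `border`),
#'   with the filled instance label raster attached as attribute `"labels"`.
#' @export
segment_stone_cells <- function(masks, pixel_size_um,
                                thresholds = stain_thresholds(),
                                min_area_um2 = 150,
                                ring_fill_ratio = 1.25) {
  stopifnot(inherits(masks, "stain_masks"), pixel_size_um > 0)
  L <- masks$lignin
  ny <- nrow(L); nx <- ncol(L)
  out_labels <- matrix(0L, ny, nx)
  empty <- tibble::tibble(
    cell_id = integer(0), type = character(0), area_um2 = numeric(0),
    feret_max_um = numeric(0), feret_min_um = numeric(0),
    lignification = character(0), centroid_row = numeric(0),
    centroid_col = numeric(0), border = logical(0)
  )
  if (!any(L)) return(structure(empty, labels = out_labels))

  seam <- L & masks$value < thresholds$seam_value_max
  cores <- L & !seam
  lab <- EBImage::bwlabel(cores)
  min_px <- max(1, round(min_area_um2 / pixel_size_um^2))
  ncomp <- max(lab)
  if (ncomp == 0) return(structure(empty, labels = out_labels))
  sizes <- tabulate(lab[lab > 0], nbins = ncomp)
  keep <- which(sizes >= min_px)
  if (!length(keep)) return(structure(empty, labels = out_labels))
  med_size <- stats::median(sizes[keep])

  rows_list <- list()
  next_id <- 0L
  idx_by_comp <- split(which(lab > 0), lab[lab > 0])
  for (comp in keep) {
    idx <- idx_by_comp[[as.character(comp)]]
    rws <- ((idx - 1L) %% ny) + 1L
    cls <- ((idx - 1L) %/% ny) + 1L
    r0 <- max(1L, min(rws) - 2L); r1 <- min(ny, max(rws) + 2L)
    c0 <- max(1L, min(cls) - 2L); c1 <- min(nx, max(cls) + 2L)
    crop <- matrix(FALSE, r1 - r0 + 1L, c1 - c0 + 1L)
    crop[cbind(rws - r0 + 1L, cls - c0 + 1L)] <- TRUE
    filled <- EBImage::fillHull(crop) > 0
    fill_ratio <- sum(filled) / sum(crop)
    is_ring <- fill_ratio >= ring_fill_ratio

    # seam evidence adjacent to this component?
    seam_crop <- seam[r0:r1, c0:c1]
    has_seam <- any(dilate_mask(crop, 1L) & seam_crop)

    pieces <- list(filled)
    if (!is_ring && !has_seam && sum(filled) > 2.2 * med_size) {
      dm <- EBImage::distmap(filled)
      ws <- EBImage::watershed(dm, tolerance = 1 + 0.2 * max(dm))
      nseg <- max(ws)
      if (nseg > 1) {
        seg_sizes <- tabulate(ws[ws > 0], nbins = nseg)
        if (all(seg_sizes >= min_px)) {
          pieces <- lapply(seq_len(nseg), function(k) ws == k)
        }
      }
    }

    for (piece in pieces) {
      apx <- sum(piece)
      if (apx < min_px) next
      next_id <- next_id + 1L
      pidx <- which(piece)
      prw <- ((pidx - 1L) %% nrow(piece)) + r0
      pcl <- ((pidx - 1L) %/% nrow(piece)) + c0
      out_labels[cbind(prw, pcl)] <- next_id
      fer <- feret_diameters(cbind(prw, pcl), pixel_size_um)
      rows_list[[next_id]] <- tibble::tibble(
        cell_id = next_id, type = "stone",
        area_um2 = apx * pixel_size_um^2,
        feret_max_um = fer[["feret_max_um"]],
        feret_min_um = fer[["feret_min_um"]],
        lignification = if (is_ring) "ring" else "full",
        centroid_row = mean(prw), centroid_col = mean(pcl),
        border = any(prw == 1L | prw == ny | pcl == 1L | pcl == nx)
      )
    }
  }
  if (!length(rows_list)) return(structure(empty, labels = out_labels))
  structure(dplyr::bind_rows(rows_list), labels = out_labels)
}

#' Segment parenchyma lumina
#'
#' Every enclosed unstained region not occupied by a stone cell becomes one
#' parenchyma instance; its area is the internal (lumen) area, excluding the
#' wall band. Instances touching the image border are flagged so they can be
#' excluded from per-cell size and shape statistics.
#'
#' @param masks a `stain_masks` from [separate_stains()].
#' @param stone_labels filled stone instance raster (attribute `"labels"` of
#'   [segment_stone_cells()] output), or `NULL` if there are no stone cells.
#' @param pixel_size_um micrometres per pixel.
#' @param min_area_um2 lumina smaller than this are discarded as debris.
#' @return tibble of parenchyma instances (same schema as stone instances,
#'   `lignification = "none"`), label raster attached as attribute
#'   `"labels"`.
#' @export
segment_parenchyma <- function(masks, stone_labels = NULL, pixel_size_um,
                               min_area_um2 = 100) {
  stopifnot(inherits(masks, "stain_masks"), pixel_size_um > 0)
  bg <- masks$background
  if (!is.null(stone_labels)) bg <- bg & stone_labels == 0L
  lab <- EBImage::bwlabel(bg)
  storage.mode(lab) <- "integer"
  ny <- nrow(lab); nx <- ncol(lab)
  min_px <- max(2, round(min_area_um2 / pixel_size_um^2))
  ncomp <- max(lab)
  if (ncomp == 0) {
    return(structure(tibble::tibble(
      cell_id = integer(0), type = character(0), area_um2 = numeric(0),
      feret_max_um = numeric(0), feret_min_um = numeric(0),
      lignification = character(0), centroid_row = numeric(0),
      centroid_col = numeric(0), border = logical(0)
    ), labels = lab))
  }
  sizes <- tabulate(lab[lab > 0], nbins = ncomp)
  drop <- which(sizes < min_px)
  if (length(drop)) lab[lab %in% drop] <- 0L
  cells <- measure_truth_cells(lab, pixel_size_um, type = "parenchyma")
  cells$lignification <- "none"
  cells <- cells[, c("cell_id", "type", "area_um2", "feret_max_um",
                     "feret_min_um", "lignification", "centroid_row",
                     "centroid_col", "border")]
  structure(cells, labels = lab)
}
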
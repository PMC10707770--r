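#' Parameters of the synthetic stained-section generator
#'
#' Bundles the study conditions emulated by the generator: the physical field
#' of view (defaults to the 0.06 cm^2 square field used for micrograph
#' acquisition, ~2449 um per side), pixel calibration, the target parenchyma
#' cell statistics, stone cell cluster (SCC) density and composition, and the
#' lignification mode of the developmental stage being emulated.
#'
#' Defaults describe an end-of-Stage-I (cell-division phase) flesh field:
#' parenchyma lumina around 2800 um^2 with circularity ~0.65, stone cells
#' around 2000 um^2 that no longer grow after lignification, roughly 25
#' clusters per cm^2, a small share of isolated stone cells, and mixed
#' lignification (fully lignified cells at cluster centers, ring-stage cells
#' at the periphery). Use [stage_params()] for zone- and stage-specific sets.
#'
#' @param field_width_um,field_height_um physical field size in micrometres.
#' @param pixel_size_um micrometres per pixel (camera calibration).
#' @param mean_parenchyma_area_um2 target mean parenchyma lumen area (um^2).
#' @param parenchyma_circularity target mean circularity (min/max Feret
#'   diameter) of parenchyma cells, in (0, 1].
#' @param scc_density_per_cm2 expected number of SCCs per cm^2 of tissue.
#' @param cells_per_scc mean number of stone cells per SCC (always > 3).
#' @param cells_per_scc_dispersion negative-binomial size parameter of the
#'   cells-per-SCC distribution (smaller = more overdispersed).
#' @param stone_cell_area_um2 mean stone cell area (um^2); stone cells stop
#'   expanding once lignified, so this does not track parenchyma size.
#' @param isolated_fraction expected share of stone cells found in isolated
#'   groups (groups of three or fewer), in [0, 1).
#' @param lignification_mode `"mixed"` (Stage-I-like: full centers, ring
#'   periphery) or `"full"` (Stage-II-like: all cells fully lignified).
#' @param wall_px wall band width between neighboring cells, in pixels.
#' @param seed integer RNG seed; all generator randomness is local to it.
#' @return a `tissue_params` list, validated.
#' @export
tissue_params <- function(field_width_um = 2449,
                          field_height_um = 2449,
                          pixel_size_um = 3,
                          mean_parenchyma_area_um2 = 2800,
                          parenchyma_circularity = 0.65,
                          scc_density_per_cm2 = 25,
                          cells_per_scc = 12,
                          cells_per_scc_dispersion = 4,
                          stone_cell_area_um2 = 2000,
                          isolated_fraction = 0.05,
                          lignification_mode = c("mixed", "full"),
                          wall_px = 2,
                          seed = 1L) {
  lignification_mode <- match.arg(lignification_mode)
  p <- list(
    field_width_um = field_width_um, field_height_um = field_height_um,
    pixel_size_um = pixel_size_um,
    mean_parenchyma_area_um2 = mean_parenchyma_area_um2,
    parenchyma_circularity = parenchyma_circularity,
    scc_density_per_cm2 = scc_density_per_cm2,
    cells_per_scc = cells_per_scc,
    cells_per_scc_dispersion = cells_per_scc_dispersion,
    stone_cell_area_um2 = stone_cell_area_um2,
    isolated_fraction = isolated_fraction,
    lignification_mode = lignification_mode,
    wall_px = wall_px, seed = as.integer(seed)
  )
  class(p) <- "tissue_params"
  validate_tissue_params(p)
  p
}

validate_tissue_params <- function(p) {
  pos <- c("field_width_um", "field_height_um", "pixel_size_um",
           "mean_parenchyma_area_um2", "stone_cell_area_um2",
           "cells_per_scc_dispersion")
  for (f in pos) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1 || !is.finite(p[[f]]) ||
        p[[f]] <= 0) {
      stop("tissue_params: `", f, "` must be a single positive number",
           call. = FALSE)
    }
  }
  if (p$scc_density_per_cm2 < 0) {
    stop("tissue_params: `scc_density_per_cm2` must be >= 0", call. = FALSE)
  }
  if (p$cells_per_scc <= 3) {
    stop("tissue_params: `cells_per_scc` must exceed 3 (the SCC definition)",
         call. = FALSE)
  }
  if (p$parenchyma_circularity <= 0 || p$parenchyma_circularity > 1) {
    stop("tissue_params: `parenchyma_circularity` must be in (0, 1]",
         call. = FALSE)
  }
  if (p$isolated_fraction < 0 || p$isolated_fraction >= 1) {
    stop("tissue_params: `isolated_fraction` must be in [0, 1)", call. = FALSE)
  }
  if (p$wall_px < 1) stop("tissue_params: `wall_px` must be >= 1", call. = FALSE)
  invisible(p)
}

#' @export
print.tissue_params <- function(x, ...) {
  cat("<tissue_params>\n")
  cat(sprintf("  field: %.0f x %.0f um at %.2g um/px (%.4f cm^2)\n",
              x$field_width_um, x$field_height_um, x$pixel_size_um,
              x$field_width_um * x$field_height_um / 1e8))
  cat(sprintf("  parenchyma: %.0f um^2, circularity %.2f\n",
              x$mean_parenchyma_area_um2, x$parenchyma_circularity))
  cat(sprintf("  SCC: %.3g per cm^2, %.3g cells each, stone cell %.0f um^2\n",
              x$scc_density_per_cm2, x$cells_per_scc, x$stone_cell_area_um2))
  cat(sprintf("  isolated fraction %.2f, lignification %s, seed %d\n",
              x$isolated_fraction, x$lignification_mode, x$seed))
  invisible(x)
}

#' Stage- and zone-specific generator parameter sets
#'
#' Encodes the developmental and spatial structure the analysis assumes:
#' Stage I has small, round parenchyma and a strong inner-zone SCC density
#' gradient (largest, most numerous clusters near the core); Stage II
#' parenchyma has expanded roughly fourfold and become less circular, which
#' dilutes SCC presence to roughly one fifth, with full lignification and
#' near-uniform zone densities. Parenchyma areas per zone follow the reported
#' means of the control treatment; the remaining values are the package's own
#' emulation choices (see the methods vignette).
#'
#' @param stage `"I"` or `"II"`.
#' @param zone `"In"`, `"Md"` or `"Ex"` (interior, middle, exterior).
#' @param seed RNG seed passed to [tissue_params()].
#' @param ... overrides forwarded to [tissue_params()].
#' @return a `tissue_params` object.
#' @export
stage_params <- function(stage = c("I", "II"), zone = c("In", "Md", "Ex"),
                         seed = 1L, ...) {
  stage <- match.arg(stage)
  zone <- match.arg(zone)
  base <- list(
    I = list(
      In = list(mean_parenchyma_area_um2 = 2150, scc_density_per_cm2 = 35,
                cells_per_scc = 16),
      Md = list(mean_parenchyma_area_um2 = 3050, scc_density_per_cm2 = 18,
                cells_per_scc = 12),
      Ex = list(mean_parenchyma_area_um2 = 3150, scc_density_per_cm2 = 28,
                cells_per_scc = 9)
    ),
    II = list(
      In = list(mean_parenchyma_area_um2 = 9400, scc_density_per_cm2 = 6,
                cells_per_scc = 14),
      Md = list(mean_parenchyma_area_um2 = 13400, scc_density_per_cm2 = 4,
                cells_per_scc = 11),
      Ex = list(mean_parenchyma_area_um2 = 13100, scc_density_per_cm2 = 5,
                cells_per_scc = 8)
    )
  )[[stage]][[zone]]
  base$parenchyma_circularity <- if (stage == "I") 0.67 else 0.56
  base$lignification_mode <- if (stage == "I") "mixed" else "full"
  args <- utils::modifyList(c(base, list(seed = seed)), list(...))
  do.call(tissue_params, args)
}

#' Image sampling plan for one treatment
#'
#' Describes how many micrographs are acquired per treatment: fruits are
#' sampled from trees, wedge-shaped sectors are cut per fruit, each sector is
#' divided into three concentric zones, and a fixed number of square fields
#' is imaged per zone.
#'
#' @param trees_per_treatment,fruits_per_tree sampled trees and fruits/tree.
#' @param sectors_per_fruit radial sectors cut per fruit.
#' @param images_per_zone square fields imaged per zone.
#' @param zones zone labels (three concentric bands by design).
#' @return a `sampling_plan` list.
#' @examples
#' plan_totals(sampling_plan(3, 3, 1, 2)) # Stage I acquisition: 54
#' plan_totals(sampling_plan(2, 2, 2, 6)) # Stage II acquisition: 144
#' @export
sampling_plan <- function(trees_per_treatment, fruits_per_tree,
                          sectors_per_fruit, images_per_zone,
                          zones = c("In", "Md", "Ex")) {
  plan <- list(
    trees_per_treatment = as.integer(trees_per_treatment),
    fruits_per_tree = as.integer(fruits_per_tree),
    fruits_per_treatment = as.integer(trees_per_treatment * fruits_per_tree),
    sectors_per_fruit = as.integer(sectors_per_fruit),
    images_per_zone = as.integer(images_per_zone),
    zones = zones
  )
  class(plan) <- "sampling_plan"
  validate_sampling_plan(plan)
  plan
}

validate_sampling_plan <- function(plan) {
  counts <- c("trees_per_treatment", "fruits_per_tree", "sectors_per_fruit",
              "images_per_zone")
  for (f in counts) {
    if (!is.numeric(plan[[f]]) || plan[[f]] < 1) {
      stop("sampling_plan: `", f, "` must be >= 1", call. = FALSE)
    }
  }
  if (plan$fruits_per_treatment !=
      plan$trees_per_treatment * plan$fruits_per_tree) {
    stop("sampling_plan: fruits_per_treatment must equal trees x fruits/tree",
         call. = FALSE)
  }
  if (length(plan$zones) < 1) stop("sampling_plan: no zones", call. = FALSE)
  invisible(plan)
}

#' Total images per treatment implied by a sampling plan
#'
#' @param plan a [sampling_plan()].
#' @return integer: fruits x sectors x zones x images per zone.
#' @export
plan_totals <- function(plan) {
  validate_sampling_plan(plan)
  plan$fruits_per_treatment * plan$sectors_per_fruit * length(plan$zones) *
    plan$images_per_zone
}
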
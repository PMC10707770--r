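# Rendering follows the safranin / fast green color convention of stained
# pear sections: lignified material in a red hue family, unlignified cell
# walls in blue, lumina and cytoplasm in a pale neutral. Exact RGB values are
# config constants; only the hue families are meaningful.

#' Stain palette used by the synthetic renderer
#'
#' @return named list of RGB triplets in [0, 1]: `background` (lumina),
#'   `wall` (unlignified walls, blue), `stone` (lignified stone cell body,
#'   red), `seam` (lignified wall between two stone cells, dark red).
#' @export
stain_palette <- function() {
  list(
    background = c(0.96, 0.94, 0.92),
    wall = c(0.27, 0.27, 0.75),
    stone = c(0.78, 0.18, 0.18),
    seam = c(0.49, 0.06, 0.06)
  )
}

#' Render a stained-section image from a synthetic field
#'
#' Produces an 8-bit-style RGB raster (values in [0, 1]) of the field:
#' parenchyma walls in blue, fully lignified stone cells as solid red bodies,
#' ring-stage stone cells as a red annulus around an unstained lumen, and
#' walls shared by two stone cells as a dark red seam (the lignified middle
#' lamella that visually fuses a cluster). A small amount of Gaussian sensor
#' noise is added, reproducibly from the field's seed.
#'
#' @param field a `tissue_field` from [implant_stone_clusters()] (a bare
#'   `tissue_mosaic` renders with no red pixels).
#' @param noise_sd standard deviation of additive Gaussian noise (0 disables).
#' @param palette color constants, see [stain_palette()].
#' @return numeric array `height x width x 3` in [0, 1].
#' @export
render_stained_image <- function(field, noise_sd = 0.015,
                                 palette = stain_palette()) {
  if (inherits(field, "tissue_mosaic")) {
    field <- structure(list(labels = field$labels, wall = field$wall,
                            cells = field$cells, params = field$params,
                            nx = field$nx, ny = field$ny,
                            n_parenchyma_labels = max(field$labels)),
                       class = "tissue_field")
    field$cells$lignification <- "none"
  }
  stopifnot(inherits(field, "tissue_field"))
  cells <- field$cells
  if (any(!cells$lignification %in% c("none", "ring", "full"))) {
    stop("rendering error: unknown lignification state", call. = FALSE)
  }
  labels <- field$labels
  ny <- nrow(labels); nx <- ncol(labels)
  p <- field$params$pixel_size_um
  wall_px <- field$params$wall_px

  r <- matrix(palette$background[1], ny, nx)
  g <- matrix(palette$background[2], ny, nx)
  b <- matrix(palette$background[3], ny, nx)

  # walls: blue by default, dark red seam where both sides are stone
  wall <- field$wall
  stone_ids <- cells$cell_id[cells$type == "stone"]
  stone_mask <- matrix(labels %in% stone_ids, ny, nx)
  radius <- max(1L, round(wall_px / 2))
  par_mask <- labels > 0L & !stone_mask
  near_stone <- dilate_mask(stone_mask, radius + 1L)
  near_par <- dilate_mask(par_mask, radius + 1L)
  seam <- wall & near_stone & !near_par
  blue_wall <- wall & !seam
  r[blue_wall] <- palette$wall[1]; g[blue_wall] <- palette$wall[2]
  b[blue_wall] <- palette$wall[3]
  r[seam] <- palette$seam[1]; g[seam] <- palette$seam[2]
  b[seam] <- palette$seam[3]

  # stone cell bodies: solid red for full cells, red annulus for ring cells
  full_ids <- cells$cell_id[cells$type == "stone" & cells$lignification == "full"]
  full_mask <- matrix(labels %in% full_ids, ny, nx)
  r[full_mask] <- palette$stone[1]; g[full_mask] <- palette$stone[2]
  b[full_mask] <- palette$stone[3]

  ring_ids <- cells$cell_id[cells$type == "stone" & cells$lignification == "ring"]
  if (length(ring_ids)) {
    ring_mask <- matrix(labels %in% ring_ids, ny, nx)
    # annulus: ring-cell pixels within `ring_w` of anything outside the cell
    ring_w <- max(2L, round(6 / p))  # ~6 um of lignified wall
    interior <- ring_mask & !dilate_mask(!ring_mask, ring_w)
    annulus <- ring_mask & !interior
    r[annulus] <- palette$stone[1]; g[annulus] <- palette$stone[2]
    b[annulus] <- palette$stone[3]
  }

  img <- array(c(r, g, b), dim = c(ny, nx, 3))
  if (noise_sd > 0) {
    withr::with_seed(field$params$seed + 2L, {
      img <- img + array(stats::rnorm(length(img), 0, noise_sd), dim = dim(img))
    })
  }
  img[img < 0] <- 0; img[img > 1] <- 1
  img
}
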
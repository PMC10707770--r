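#' Default thresholds for hue-saturation stain separation
#'
#' Pixels are classified by hue (red = lignin, blue = unlignified wall) after
#' a minimum-saturation gate that sends pale lumina and background to the
#' background class. Hue is on the [0, 1) circle (0 = red, 2/3 = blue).
#'
#' @param saturation_min minimum saturation for a pixel to count as stained.
#' @param lignin_hue_halfwidth half-width of the red hue band around 0.
#' @param wall_hue hue band (length-2) assigned to the wall stain.
#' @param seam_value_max brightness (HSV value) below which lignin pixels are
#'   treated as lignified walls between stone cells (seams) by the
#'   segmentation stage.
#' @return list of thresholds.
#' @export
stain_thresholds <- function(saturation_min = 0.20,
                             lignin_hue_halfwidth = 0.12,
                             wall_hue = c(0.45, 0.85),
                             seam_value_max = 0.62) {
  stopifnot(saturation_min > 0, saturation_min < 1,
            lignin_hue_halfwidth > 0, length(wall_hue) == 2,
            wall_hue[1] < wall_hue[2])
  list(saturation_min = saturation_min,
       lignin_hue_halfwidth = lignin_hue_halfwidth,
       wall_hue = wall_hue,
       seam_value_max = seam_value_max)
}

#' Separate lignin, wall and background stain classes
#'
#' Assigns every pixel of an RGB micrograph to exactly one of three classes:
#' `lignin` (red-stained lignified material), `wall` (blue-stained
#' unlignified cell walls) or `background` (unstained lumina and background).
#' Classification is a hue-saturation rule in HSV space: unsaturated pixels
#' are background; saturated pixels are lignin if their hue falls in the red
#' band, wall if in the blue band, and background otherwise.
#'
#' @param img RGB array `height x width x 3` with values in [0, 1] (or 0-255,
#'   rescaled automatically).
#' @param thresholds see [stain_thresholds()].
#' @return a `stain_masks` list of three disjoint logical matrices (`lignin`,
#'   `wall`, `background`) plus the HSV `value` channel (used downstream to
#'   detect dark lignified seams between stone cells).
#' @export
separate_stains <- function(img, thresholds = stain_thresholds()) {
  if (length(dim(img)) != 3 || dim(img)[3] != 3) {
    stop("format error: expected an RGB raster with 3 channels", call. = FALSE)
  }
  if (max(img) > 1) img <- img / 255
  ny <- dim(img)[1]; nx <- dim(img)[2]
  hsv <- grDevices::rgb2hsv(rbind(as.vector(img[, , 1]),
                                  as.vector(img[, , 2]),
                                  as.vector(img[, , 3])),
                            maxColorValue = 1)
  h <- hsv[1, ]; s <- hsv[2, ]; v <- hsv[3, ]
  stained <- s >= thresholds$saturation_min
  red <- stained & (h <= thresholds$lignin_hue_halfwidth |
                      h >= 1 - thresholds$lignin_hue_halfwidth)
  blue <- stained & !red & h >= thresholds$wall_hue[1] &
    h <= thresholds$wall_hue[2]
  bg <- !(red | blue)
  structure(list(
    lignin = matrix(red, ny, nx),
    wall = matrix(blue, ny, nx),
    background = matrix(bg, ny, nx),
    value = matrix(v, ny, nx)
  ), class = "stain_masks")
}

#' @export
print.stain_masks <- function(x, ...) {
  n <- length(x$lignin)
  cat(sprintf("<stain_masks> %d x %d px: %.1f%% lignin, %.1f%% wall, %.1f%% background\n",
              nrow(x$lignin), ncol(x$lignin), 100 * sum(x$lignin) / n,
              100 * sum(x$wall) / n, 100 * sum(x$background) / n))
  invisible(x)
}
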
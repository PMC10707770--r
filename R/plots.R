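# ggplot2 displays for the main result types.

#' Plot a section image with segmented instances
#'
#' Renders the RGB section with stone cell centroids and cluster outlines
#' marked, for a quick visual check of the segmentation.
#'
#' @param object a `section_analysis` from [analyze_section()].
#' @param img optional RGB array to use as backdrop (e.g. the source image).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.section_analysis <- function(object, img = NULL, ...) {
  ny <- nrow(object$masks$lignin); nx <- ncol(object$masks$lignin)
  pl <- ggplot2::ggplot() +
    ggplot2::coord_fixed(xlim = c(0, nx), ylim = c(0, ny), expand = FALSE) +
    ggplot2::labs(x = NULL, y = NULL)
  if (!is.null(img)) {
    pl <- pl + ggplot2::annotation_raster(
      grDevices::as.raster(img), xmin = 0, xmax = nx, ymin = 0, ymax = ny)
  }
  st <- tibble::as_tibble(object$stones)
  if (nrow(st)) {
    memb <- attr(object$groups, "membership")
    st <- dplyr::left_join(st, memb, by = "cell_id")
    st <- dplyr::left_join(
      st, object$groups[c("group_id", "classification")], by = "group_id")
    pl <- pl + ggplot2::geom_point(
      data = st,
      ggplot2::aes(x = centroid_col, y = ny - centroid_row,
                   shape = lignification, color = classification),
      size = 2)
  }
  pl + ggplot2::theme_minimal()
}

#' Bar plot of a zone metric by treatment
#'
#' @param zm zone metrics tibble from [compute_zone_metrics()] (optionally
#'   with `treatment`/`stage` columns from [run_pipeline()]).
#' @param metric metric column name to display.
#' @return a ggplot object.
#' @export
plot_zone_metrics <- function(zm, metric = "scc_percent_area") {
  stopifnot(metric %in% names(zm))
  aes <- if ("treatment" %in% names(zm)) {
    ggplot2::aes(x = zone, y = .data[[metric]], fill = treatment)
  } else {
    ggplot2::aes(x = zone, y = .data[[metric]])
  }
  pl <- ggplot2::ggplot(zm, aes) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::labs(x = "Zone (In = interior, Md = middle, Ex = exterior)",
                  y = metric) +
    ggplot2::theme_minimal()
  if ("stage" %in% names(zm) && length(unique(zm$stage)) > 1) {
    pl <- pl + ggplot2::facet_wrap(~stage, labeller = ggplot2::label_both)
  }
  pl
}

#' Scatter plot of automatic versus reference measurements
#'
#' @param bench a `scc_benchmark` from [synthetic_benchmark()].
#' @param what `"count"` or `"size"`.
#' @return a ggplot object.
#' @export
plot_validation <- function(bench, what = c("count", "size")) {
  what <- match.arg(what)
  pf <- bench$per_field
  if (what == "count") {
    x <- pf$truth_n_scc; y <- pf$auto_n_scc; lab <- "SCCs per field"
  } else {
    x <- pf$truth_mean_scc_size_um2; y <- pf$auto_mean_scc_size_um2
    lab <- "mean SCC size (um^2)"
  }
  ggplot2::ggplot(tibble::tibble(truth = x, auto = y),
                  ggplot2::aes(truth, auto)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = paste("truth", lab), y = paste("automatic", lab)) +
    ggplot2::theme_minimal()
}
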
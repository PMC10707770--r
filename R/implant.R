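# Stone cell cluster implantation. Clusters are carved into the parenchyma
# mosaic as their own mini-tessellations: stone cells differentiate early and
# stop expanding once the lignified secondary wall forms, so their size is
# decoupled from the (continuously expanding) host parenchyma. This is also
# what makes the Stage I -> II dilution mechanism reproducible: the same
# stone-cell truth can be planted into mosaics of different parenchyma size.

#' Implant stone cell clusters and isolated stone cells into a mosaic
#'
#' Draws the number of stone cell clusters (SCCs) from a Poisson law at the
#' requested per-cm^2 density, the number of cells per cluster from a shifted
#' negative binomial (always > 3, the SCC definition), and per-cell areas
#' from a lognormal around `stone_cell_area_um2`. Each group occupies a
#' roughly circular footprint tessellated into its member cells. Isolated
#' stone cells (groups of three or fewer) are added so that their expected
#' share of all stone cells is `isolated_fraction`. Group footprints are kept
#' at least one parenchyma-cell diameter apart so truth group identity is
#' unambiguous.
#'
#' In `lignification_mode = "mixed"` (Stage-I-like), cells touching the
#' footprint boundary are in the ring stage (a thin lignified annulus around
#' a still-living lumen) while interior cells are fully lignified, matching
#' the centre-outward progression of sclerification; in `"full"` mode every
#' cell is fully lignified. Isolated cells, which differentiate earliest, are
#' always rendered fully lignified.
#'
#' @param mosaic a `tissue_mosaic` from [generate_mosaic()].
#' @param params a [tissue_params()]; density/cluster fields are used here.
#' @param groups_spec optional tibble with columns `n_cells` and `class`
#'   (`"SCC"`/`"isolated"`) and optionally `cell_area_um2`, fixing the group
#'   composition instead of sampling it (used for paired-design experiments).
#' @param max_tries placement retries per group before a placement error.
#' @return a `tissue_field` list: `labels` (0 = wall, parenchyma ids,
#'   stone ids), `wall`, `cells` (truth tibble for both cell types, with
#'   lignification state, group id/class and contact flags), `groups` (truth
#'   group table), `field` (one-row tibble: field area, true SCC count, true
#'   % area occupied by SCCs), `params`.
#' @export
implant_stone_clusters <- function(mosaic, params = mosaic$params,
                                   groups_spec = NULL, max_tries = 500) {
  stopifnot(inherits(mosaic, "tissue_mosaic"))
  validate_tissue_params(params)
  p <- params$pixel_size_um
  ny <- mosaic$ny; nx <- mosaic$nx
  field_cm2 <- nx * ny * p^2 / 1e8

  withr::with_seed(params$seed + 1L, {
    if (is.null(groups_spec)) {
      n_scc <- stats::rpois(1, params$scc_density_per_cm2 * field_cm2)
      scc_sizes <- if (n_scc > 0) {
        4L + stats::rnbinom(n_scc, mu = params$cells_per_scc - 4,
                            size = params$cells_per_scc_dispersion)
      } else integer(0)
      # isolated cells: expected share `f` of all stone cells
      f <- params$isolated_fraction
      iso_target <- if (f > 0) round(f / (1 - f) * sum(scc_sizes)) else 0L
      iso_sizes <- integer(0)
      while (sum(iso_sizes) < iso_target) {
        iso_sizes <- c(iso_sizes, sample(1:3, 1, prob = c(0.6, 0.3, 0.1)))
      }
      groups_spec <- tibble::tibble(
        n_cells = c(scc_sizes, iso_sizes),
        class = rep(c("SCC", "isolated"), c(length(scc_sizes), length(iso_sizes)))
      )
    } else {
      groups_spec <- tibble::as_tibble(groups_spec)
      stopifnot(all(c("n_cells", "class") %in% names(groups_spec)))
      if (any(groups_spec$n_cells <= 3 & groups_spec$class == "SCC") ||
          any(groups_spec$n_cells > 3 & groups_spec$class == "isolated")) {
        stop("groups_spec: SCC groups must have > 3 cells, isolated <= 3",
             call. = FALSE)
      }
    }

    labels <- mosaic$raw_labels
    next_label <- max(labels) + 1L
    cv <- 0.25
    sdlog <- sqrt(log(1 + cv^2))
    sep_um <- 2 * sqrt(params$mean_parenchyma_area_um2 / pi)
    placed <- list()
    stone_rows <- list()

    if (nrow(groups_spec) > 0) {
      # big groups first: easier packing
      groups_spec <- groups_spec[order(-groups_spec$n_cells), ]
      for (g in seq_len(nrow(groups_spec))) {
        k <- groups_spec$n_cells[g]
        mean_area <- if ("cell_area_um2" %in% names(groups_spec)) {
          groups_spec$cell_area_um2[g]
        } else params$stone_cell_area_um2
        cell_areas <- stats::rlnorm(k, log(mean_area) - sdlog^2 / 2, sdlog)
        # footprint: disk holding the cells plus the wall band each cell
        # loses along its perimeter (hexagon perimeter ~ 3.72*sqrt(A))
        wall_um <- params$wall_px * p
        A_g <- sum(cell_areas + 1.12 * 3.72 * sqrt(cell_areas) * wall_um / 2)
        R_um <- sqrt(A_g / pi)
        R_px <- R_um / p
        ok <- FALSE
        for (try in seq_len(max_tries)) {
          cr <- stats::runif(1, R_px + 2, ny - R_px - 1)
          cc <- stats::runif(1, R_px + 2, nx - R_px - 1)
          clear <- TRUE
          for (q in placed) {
            d <- sqrt((cr - q$cr)^2 + (cc - q$cc)^2) * p
            if (d < R_um + q$R_um + sep_um) { clear <- FALSE; break }
          }
          if (clear) { ok <- TRUE; break }
        }
        if (!ok) {
          stop("placement error: could not place stone cell group ", g,
               " without violating separation after ", max_tries, " tries",
               call. = FALSE)
        }
        placed[[length(placed) + 1]] <- list(cr = cr, cc = cc, R_um = R_um)

        # carve footprint and tessellate it into k stone cells
        rr <- max(1L, floor(cr - R_px)):min(ny, ceiling(cr + R_px))
        ccs <- max(1L, floor(cc - R_px)):min(nx, ceiling(cc + R_px))
        sub_r <- rep(rr, times = length(ccs))
        sub_c <- rep(ccs, each = length(rr))
        inside <- (sub_r - cr)^2 + (sub_c - cc)^2 <= R_px^2
        fr <- sub_r[inside]; fc <- sub_c[inside]
        # k seeds by dart throwing with a minimum separation
        min_sep <- 1.4 * R_px / sqrt(k)
        sr <- numeric(0); sc <- numeric(0)
        guard <- 0
        while (length(sr) < k && guard < 4000) {
          guard <- guard + 1
          a <- stats::runif(1, 0, 2 * pi)
          r2 <- R_px * sqrt(stats::runif(1)) * 0.97
          yy <- cr + r2 * sin(a); xx <- cc + r2 * cos(a)
          if (length(sr) == 0 || min((sr - yy)^2 + (sc - xx)^2) >= min_sep^2) {
            sr <- c(sr, yy); sc <- c(sc, xx)
          }
        }
        while (length(sr) < k) {  # relax separation if dart throwing stalls
          a <- stats::runif(1, 0, 2 * pi); r2 <- R_px * sqrt(stats::runif(1))
          sr <- c(sr, cr + r2 * sin(a)); sc <- c(sc, cc + r2 * cos(a))
        }
        # weighted nearest-seed assignment: larger drawn areas get larger cells
        w <- sqrt(cell_areas / mean(cell_areas))
        d2 <- outer(fr, sr, "-")^2 + outer(fc, sc, "-")^2
        d2 <- sweep(d2, 2, w^2, "/")
        assign <- max.col(-d2, ties.method = "first")
        ids <- next_label:(next_label + k - 1L)
        labels[cbind(fr, fc)] <- ids[assign]
        # lignification: ring at the footprint periphery in mixed mode
        seed_r2 <- (sr - cr)^2 + (sc - cc)^2
        if (groups_spec$class[g] == "isolated") {
          state <- rep("full", k)
        } else if (params$lignification_mode == "full") {
          state <- rep("full", k)
        } else {
          state <- ifelse(sqrt(seed_r2) > 0.55 * R_px, "ring", "full")
          state[which.min(seed_r2)] <- "full"
        }
        stone_rows[[length(stone_rows) + 1]] <- tibble::tibble(
          cell_id = ids, group_id = g, group_class = groups_spec$class[g],
          lignification = state
        )
        next_label <- next_label + k
      }
    }

    stone_truth <- if (length(stone_rows)) dplyr::bind_rows(stone_rows) else
      tibble::tibble(cell_id = integer(0), group_id = integer(0),
                     group_class = character(0), lignification = character(0))
  })

  # rebuild the wall band over the updated tessellation
  radius <- max(1L, round(params$wall_px / 2))
  wall <- boundary_band(labels, radius)
  lumen <- labels
  lumen[wall] <- 0L

  # drop parenchyma slivers left at footprint edges (below 150 um^2): they
  # become wall so segmentation sees no spurious micro-lumina
  n_par <- max(mosaic$labels)
  areas_px <- label_areas_px(lumen, max(lumen))
  sliver <- which(areas_px * p^2 < 150 & seq_along(areas_px) <= n_par)
  if (length(sliver)) {
    kill <- lumen %in% sliver
    wall[kill] <- TRUE
    lumen[kill] <- 0L
    labels[labels %in% sliver] <- 0L
  }

  cells <- measure_truth_cells(lumen, p, type = "parenchyma")
  cells$type[cells$cell_id > n_par] <- "stone"
  cells <- dplyr::left_join(cells, stone_truth, by = "cell_id")
  cells$lignification[cells$type == "parenchyma"] <- "none"
  cells$group_class[cells$type == "parenchyma"] <- NA_character_

  # contact flag: parenchyma lumina within one wall-band dilation of an SCC
  scc_ids <- cells$cell_id[cells$type == "stone" & cells$group_class == "SCC"]
  scc_mask <- matrix(lumen %in% scc_ids, nrow(lumen), ncol(lumen))
  near <- dilate_mask(scc_mask, radius = params$wall_px + 1L)
  touching <- unique(lumen[near & lumen > 0L])
  cells$contact_scc <- cells$cell_id %in% setdiff(touching, cells$cell_id[cells$type == "stone"]) &
    cells$type == "parenchyma"

  groups <- cells |>
    dplyr::filter(type == "stone") |>
    dplyr::group_by(group_id, group_class) |>
    dplyr::summarise(n_cells = dplyr::n(), total_area_um2 = sum(area_um2),
                     .groups = "drop") |>
    dplyr::mutate(eq_diameter_um = 2 * sqrt(total_area_um2 / pi))

  field_area_um2 <- nx * ny * p^2
  scc_area <- sum(groups$total_area_um2[groups$group_class == "SCC"])
  field <- tibble::tibble(
    field_area_um2 = field_area_um2,
    field_area_cm2 = field_area_um2 / 1e8,
    n_scc = sum(groups$group_class == "SCC"),
    n_isolated_groups = sum(groups$group_class == "isolated"),
    scc_percent_area = 100 * scc_area / field_area_um2,
    scc_count_per_cm2 = sum(groups$group_class == "SCC") / (field_area_um2 / 1e8)
  )

  structure(list(labels = lumen, wall = wall, cells = cells, groups = groups,
                 field = field, params = params, nx = nx, ny = ny,
                 n_parenchyma_labels = n_par),
            class = "tissue_field")
}

#' @export
print.tissue_field <- function(x, ...) {
  cat(sprintf(
    "<tissue_field> %d x %d px, %d parenchyma + %d stone cells, %d SCC (%.2f%% area)\n",
    x$ny, x$nx, sum(x$cells$type == "parenchyma"), sum(x$cells$type == "stone"),
    x$field$n_scc, x$field$scc_percent_area))
  invisible(x)
}
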
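# Parameter-recovery benchmark: generate synthetic fields with known truth,
# run the full analysis chain, and compare recovered quantities with the
# generator's truth tables.

#' Segmentation recovery benchmark on synthetic fields
#'
#' Generates `n_fields` stained-section fields from `params` (per-field
#' seeds derived from `seed`), analyzes each with the full pipeline (stain
#' separation, segmentation, grouping, morphometry) and compares the
#' recovered quantities with the generator truth: SCC count per cm^2,
#' percent area occupied by SCCs, cells per SCC, mean parenchyma area and
#' circularity, and per-field SCC size/count for correlation checks.
#'
#' @param n_fields number of fields to simulate.
#' @param params generator parameters ([tissue_params()]); per-field seeds
#'   override `params$seed`.
#' @param seed base seed for the per-field seed stream.
#' @param thresholds stain thresholds for the analysis side.
#' @return a `scc_benchmark` list with `per_field` (tibble of truth and
#'   recovered values per field) and `summary` (one-row tibble of the
#'   aggregate recovery measures).
#' @export
synthetic_benchmark <- function(n_fields = 100, params = tissue_params(),
                                seed = 42L,
                                thresholds = stain_thresholds()) {
  rows <- vector("list", n_fields)
  for (i in seq_len(n_fields)) {
    zp <- params
    zp$seed <- (as.integer(seed) + 104729L * i) %% .Machine$integer.max
    fld <- implant_stone_clusters(generate_mosaic(zp), zp)
    img <- render_stained_image(fld)
    an <- analyze_section(img, zp$pixel_size_um, thresholds = thresholds)

    truth_groups <- fld$groups
    truth_scc <- truth_groups[truth_groups$group_class == "SCC", ]
    truth_par <- fld$cells[fld$cells$type == "parenchyma" & !fld$cells$border, ]
    s <- an$summary
    rows[[i]] <- tibble::tibble(
      field = i, seed = zp$seed,
      field_area_cm2 = fld$field$field_area_cm2,
      truth_n_scc = fld$field$n_scc,
      auto_n_scc = s$n_scc,
      truth_scc_percent_area = fld$field$scc_percent_area,
      auto_scc_percent_area = s$scc_percent_area,
      truth_mean_scc_size_um2 = if (nrow(truth_scc)) mean(truth_scc$total_area_um2) else NA_real_,
      auto_mean_scc_size_um2 = s$mean_scc_size_um2,
      truth_mean_cells_per_scc = if (nrow(truth_scc)) mean(truth_scc$n_cells) else NA_real_,
      auto_mean_cells_per_scc = s$mean_cells_per_scc,
      truth_mean_par_area_um2 = mean(truth_par$area_um2),
      auto_mean_par_area_um2 = s$mean_parenchyma_area_um2,
      truth_mean_par_circularity = mean(truth_par$circularity),
      auto_mean_par_circularity = s$mean_parenchyma_circularity
    )
  }
  per_field <- dplyr::bind_rows(rows)
  area_tot <- sum(per_field$field_area_cm2)
  summary <- tibble::tibble(
    n_fields = n_fields,
    truth_count_per_cm2 = sum(per_field$truth_n_scc) / area_tot,
    auto_count_per_cm2 = sum(per_field$auto_n_scc) / area_tot,
    count_rel_error = abs(sum(per_field$auto_n_scc) - sum(per_field$truth_n_scc)) /
      max(1, sum(per_field$truth_n_scc)),
    truth_percent_area = stats::weighted.mean(per_field$truth_scc_percent_area,
                                              per_field$field_area_cm2),
    auto_percent_area = stats::weighted.mean(per_field$auto_scc_percent_area,
                                             per_field$field_area_cm2),
    percent_area_error_pp = abs(stats::weighted.mean(per_field$auto_scc_percent_area,
                                                     per_field$field_area_cm2) -
                                  stats::weighted.mean(per_field$truth_scc_percent_area,
                                                       per_field$field_area_cm2)),
    cells_per_scc_error = abs(mean(per_field$auto_mean_cells_per_scc, na.rm = TRUE) -
                                mean(per_field$truth_mean_cells_per_scc, na.rm = TRUE)),
    par_area_rel_error = abs(mean(per_field$auto_mean_par_area_um2) -
                               mean(per_field$truth_mean_par_area_um2)) /
      mean(per_field$truth_mean_par_area_um2),
    circularity_error = abs(mean(per_field$auto_mean_par_circularity) -
                              params$parenchyma_circularity),
    r2_scc_count = tryCatch(r_squared(per_field$truth_n_scc,
                                      per_field$auto_n_scc),
                            error = function(e) NA_real_),
    r2_scc_size = tryCatch(r_squared(per_field$truth_mean_scc_size_um2,
                                     per_field$auto_mean_scc_size_um2),
                           error = function(e) NA_real_)
  )
  structure(list(per_field = per_field, summary = summary, params = params),
            class = "scc_benchmark")
}

#' @export
print.scc_benchmark <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<scc_benchmark> %d fields\n", s$n_fields))
  cat(sprintf("  SCC count/cm^2: truth %.2f, auto %.2f (rel err %.1f%%)\n",
              s$truth_count_per_cm2, s$auto_count_per_cm2,
              100 * s$count_rel_error))
  cat(sprintf("  %% area: truth %.2f, auto %.2f (err %.2f pp)\n",
              s$truth_percent_area, s$auto_percent_area,
              s$percent_area_error_pp))
  cat(sprintf("  cells/SCC err %.2f; parenchyma area rel err %.1f%%; circ err %.3f\n",
              s$cells_per_scc_error, 100 * s$par_area_rel_error,
              s$circularity_error))
  cat(sprintf("  R^2: SCC count %.3f, SCC size %.3f\n",
              s$r2_scc_count, s$r2_scc_size))
  invisible(x)
}
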
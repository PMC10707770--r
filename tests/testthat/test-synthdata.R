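# Synthetic stained-section generator: parameter recovery, truth
# consistency, determinism, rendering conventions.

test_that("mosaic recovers target mean area and circularity", {
  pm <- tissue_params(field_width_um = 500, field_height_um = 500,
                      pixel_size_um = 1, mean_parenchyma_area_um2 = 2500,
                      parenchyma_circularity = 0.65, seed = 1)
  m <- generate_mosaic(pm)
  nb <- m$cells[!m$cells$border, ]
  # oracle: per-label pixel counting
  counts <- table(m$labels[m$labels > 0])
  expect_equal(unname(counts[as.character(nb$cell_id)]),
               nb$area_um2, ignore_attr = TRUE)  # 1 um pixels: px == um^2
  expect_lt(abs(mean(nb$area_um2) - 2500) / 2500, 0.15)
  expect_lt(abs(mean(nb$circularity) - 0.65), 0.1)
})

test_that("mosaic is deterministic for a fixed seed", {
  pm <- tissue_params(field_width_um = 500, field_height_um = 500,
                      pixel_size_um = 2, seed = 3,
                      mean_parenchyma_area_um2 = 2000)
  m1 <- generate_mosaic(pm)
  m2 <- generate_mosaic(pm)
  expect_identical(m1$labels, m2$labels)
  expect_identical(m1$cells, m2$cells)
})

test_that("degenerate generator parameters are rejected", {
  expect_error(tissue_params(mean_parenchyma_area_um2 = 0), "positive")
  expect_error(tissue_params(pixel_size_um = -1), "positive")
  expect_error(tissue_params(parenchyma_circularity = 1.5), "0, 1")
  expect_error(tissue_params(isolated_fraction = 1), "0, 1")
  expect_error(tissue_params(cells_per_scc = 3), "exceed 3")
  # field smaller than 10 mean cell diameters
  pm <- tissue_params(field_width_um = 300, field_height_um = 300,
                      pixel_size_um = 1, mean_parenchyma_area_um2 = 2500)
  expect_error(generate_mosaic(pm), "too small")
})

test_that("every SCC group in truth has more than three adjoining cells", {
  fld <- small_field()
  grp <- fld$cells[fld$cells$type == "stone", ]
  sizes <- table(grp$group_id, grp$group_class)
  for (g in unique(grp$group_id)) {
    n <- sum(grp$group_id == g)
    cls <- grp$group_class[grp$group_id == g][1]
    expect_true(if (cls == "SCC") n > 3 else n <= 3)
  }
  # drawn cluster sizes respect the rule across seeds too
  for (s in 1:5) {
    pm <- tissue_params(field_width_um = 600, field_height_um = 600,
                        pixel_size_um = 3, mean_parenchyma_area_um2 = 1600,
                        scc_density_per_cm2 = 300, stone_cell_area_um2 = 800,
                        cells_per_scc = 6, seed = s)
    fld2 <- implant_stone_clusters(generate_mosaic(pm), pm)
    g2 <- fld2$groups
    expect_true(all(g2$n_cells[g2$group_class == "SCC"] > 3))
    expect_true(all(g2$n_cells[g2$group_class == "isolated"] <= 3))
  }
})

test_that("isolated_fraction = 0 yields no isolated groups", {
  pm <- tissue_params(field_width_um = 600, field_height_um = 600,
                      pixel_size_um = 3, mean_parenchyma_area_um2 = 1600,
                      scc_density_per_cm2 = 800, stone_cell_area_um2 = 800,
                      cells_per_scc = 5, isolated_fraction = 0, seed = 2)
  fld <- implant_stone_clusters(generate_mosaic(pm), pm)
  expect_gt(nrow(fld$groups), 0)
  expect_true(all(fld$groups$group_class == "SCC"))
})

test_that("realized SCC counts follow the requested Poisson density", {
  # 20 SCCs/cm^2 in a 0.06 cm^2 field: expectation 1.2 groups per field
  counts <- vapply(1:60, function(s) {
    pm <- tissue_params(pixel_size_um = 8, scc_density_per_cm2 = 20,
                        mean_parenchyma_area_um2 = 3500,
                        stone_cell_area_um2 = 2000, cells_per_scc = 8,
                        isolated_fraction = 0, seed = s)
    fld <- implant_stone_clusters(generate_mosaic(pm), pm)
    fld$field$n_scc
  }, numeric(1))
  expected <- 20 * 0.0599  # realized field is 2448 um (rounded pixels)
  se <- sqrt(expected / length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("truth percent area equals independent pixel counting", {
  fld <- small_field()
  scc_ids <- fld$cells$cell_id[fld$cells$type == "stone" &
                                 fld$cells$group_class == "SCC"]
  px <- sum(fld$labels %in% scc_ids)
  p <- fld$params$pixel_size_um
  expect_equal(fld$field$scc_percent_area,
               100 * px * p^2 / (fld$nx * fld$ny * p^2))
  # per-cell truth areas are pixel counts too
  st <- fld$cells[fld$cells$type == "stone", ]
  for (i in seq_len(nrow(st))) {
    expect_equal(st$area_um2[i], sum(fld$labels == st$cell_id[i]) * p^2)
  }
})

test_that("truth tables are byte-identical across regeneration", {
  pm <- tissue_params(field_width_um = 500, field_height_um = 500,
                      pixel_size_um = 2, mean_parenchyma_area_um2 = 1600,
                      stone_cell_area_um2 = 1000, scc_density_per_cm2 = 150,
                      seed = 21)
  f1 <- implant_stone_clusters(generate_mosaic(pm), pm)
  f2 <- implant_stone_clusters(generate_mosaic(pm), pm)
  expect_identical(f1$cells, f2$cells)
  expect_identical(f1$labels, f2$labels)
})

test_that("rendering follows the stain color convention", {
  fld <- small_field()
  img <- render_stained_image(fld, noise_sd = 0)
  pal <- stain_palette()
  # one full stone cell: red region matches its truth area within 2%
  full_id <- fld$cells$cell_id[fld$cells$type == "stone" &
                                 fld$cells$lignification == "full"][1]
  cell_px <- fld$labels == full_id
  red <- img[, , 1] > 0.5 & img[, , 2] < 0.4 & img[, , 3] < 0.4
  expect_lt(abs(sum(red & cell_px) - sum(cell_px)) / sum(cell_px), 0.02)
  # ring cells: annulus red, interior not red
  ring_ids <- fld$cells$cell_id[fld$cells$type == "stone" &
                                  fld$cells$lignification == "ring"]
  if (length(ring_ids)) {
    rid <- ring_ids[1]
    rmask <- fld$labels == rid
    expect_gt(sum(red & rmask), 0)            # annulus present
    expect_lt(sum(red & rmask), sum(rmask))   # interior unstained
  }
  # parenchyma walls are blue-family
  blue <- img[, , 3] > 0.5 & img[, , 1] < 0.45
  expect_gt(sum(blue & fld$wall) / sum(fld$wall), 0.8)
})

test_that("a mosaic with no stone cells renders with zero red pixels", {
  pm <- tissue_params(field_width_um = 450, field_height_um = 450,
                      pixel_size_um = 3, mean_parenchyma_area_um2 = 2000,
                      seed = 5)
  m <- generate_mosaic(pm)
  img <- render_stained_image(m, noise_sd = 0)
  red <- img[, , 1] > 0.5 & img[, , 2] < 0.4 & img[, , 3] < 0.4
  expect_equal(sum(red), 0)
})

test_that("unknown lignification state is a rendering error", {
  fld <- small_field()
  fld$cells$lignification[1] <- "bogus"
  expect_error(render_stained_image(fld), "lignification")
})

test_that("stage parameter sets encode the developmental contrasts", {
  sI <- stage_params("I", "In")
  sII <- stage_params("II", "In")
  expect_gt(sII$mean_parenchyma_area_um2 / sI$mean_parenchyma_area_um2, 3)
  expect_lt(sII$scc_density_per_cm2, sI$scc_density_per_cm2)
  expect_lt(sII$parenchyma_circularity, sI$parenchyma_circularity)
  expect_identical(sI$lignification_mode, "mixed")
  expect_identical(sII$lignification_mode, "full")
  # inner zone has the densest clusters at Stage I
  expect_gt(stage_params("I", "In")$scc_density_per_cm2,
            stage_params("I", "Md")$scc_density_per_cm2)
})
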
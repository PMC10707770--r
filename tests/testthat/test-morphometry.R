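# Grouping, cluster metrics and parenchyma morphometry.

# Build a fake instance tibble + label raster from painted disks.
instances_from_labels <- function(lab, pixel_size_um = 1) {
  ids <- sort(unique(lab[lab > 0]))
  rows <- lapply(ids, function(i) {
    px <- which(lab == i, arr.ind = TRUE)
    fer <- feret_diameters(px, pixel_size_um)
    tibble::tibble(
      cell_id = i, type = "stone", area_um2 = nrow(px) * pixel_size_um^2,
      feret_max_um = fer[[1]], feret_min_um = fer[[2]],
      lignification = "full", centroid_row = mean(px[, 1]),
      centroid_col = mean(px[, 2]),
      border = any(px[, 1] %in% c(1, nrow(lab)) | px[, 2] %in% c(1, ncol(lab)))
    )
  })
  structure(dplyr::bind_rows(rows), labels = lab)
}

test_that("five adjoining stone cells form one SCC", {
  # five disks in a tight row, 1 px apart
  ctr <- cbind(rep(25, 5), seq(10, 58, by = 12))
  lab <- paint_disks(50, 70, ctr, rep(5, 5))
  inst <- instances_from_labels(lab)
  g <- group_stone_cells(inst, adjacency_px = 3)
  expect_equal(nrow(g), 1)
  expect_equal(g$n_cells, 5L)
  expect_equal(g$classification, "SCC")
})

test_that("three adjoining stone cells are isolated; four make an SCC", {
  for (k in 3:4) {
    ctr <- cbind(rep(20, k), seq(10, by = 11, length.out = k))
    lab <- paint_disks(40, 60, ctr, rep(5, k))
    inst <- instances_from_labels(lab)
    g <- group_stone_cells(inst, adjacency_px = 3)
    expect_equal(nrow(g), 1)
    expect_equal(g$classification, if (k > 3) "SCC" else "isolated")
  }
})

test_that("groups separated by a parenchyma cell are never merged", {
  # two rows of five cells, separated by ~20 px (>= one parenchyma cell)
  ctr <- rbind(cbind(rep(15, 5), seq(10, 58, by = 12)),
               cbind(rep(45, 5), seq(10, 58, by = 12)))
  lab <- paint_disks(60, 70, ctr, rep(5, 10))
  inst <- instances_from_labels(lab)
  g <- group_stone_cells(inst, adjacency_px = 3)
  expect_equal(nrow(g), 2)
  expect_true(all(g$classification == "SCC"))
  # oracle: exhaustive pairwise adjacency + transitive closure
  bf <- brute_force_groups(lab, radius = 3)
  memb <- attr(g, "membership")
  expect_equal(length(unique(bf)), 2)
  agree <- table(memb$group_id, bf[as.character(memb$cell_id)])
  expect_true(all(rowSums(agree > 0) == 1))
})

test_that("adjacency grouping matches brute-force closure on random fields", {
  set.seed(99)
  for (rep in 1:60) {
    k <- sample(3:9, 1)
    ctr <- cbind(runif(k, 8, 52), runif(k, 8, 52))
    lab <- paint_disks(60, 60, ctr, runif(k, 2.5, 5))
    ids <- sort(unique(lab[lab > 0]))
    if (length(ids) < 2) next
    inst <- instances_from_labels(lab)
    g <- group_stone_cells(inst, adjacency_px = 2)
    memb <- attr(g, "membership")
    bf <- brute_force_groups(lab, radius = 2)
    # same partition: group ids must be a relabeling of each other
    tab <- table(memb$group_id, bf[as.character(memb$cell_id)])
    expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
    # classification boundary is exactly the >3 rule
    expect_equal(g$classification, ifelse(g$n_cells > 3, "SCC", "isolated"))
  }
})

test_that("scc_metrics computes size, count and mean cell size", {
  g <- tibble::tibble(group_id = 1L, n_cells = 4L, total_area_um2 = 400,
                      eq_diameter_um = 2 * sqrt(400 / pi),
                      classification = "SCC", border = FALSE,
                      members = list(1:4))
  m <- scc_metrics(g)
  expect_equal(m$size_um2, 400)
  expect_equal(m$mean_stone_cell_size_um2, 100)
  # mean size x count reproduces size exactly
  expect_equal(m$mean_stone_cell_size_um2 * m$n_cells, m$size_um2)
  g$classification <- "isolated"
  expect_error(scc_metrics(g), "classification error")
})

test_that("recovered SCC composition matches truth on a synthetic field", {
  fld <- small_field()
  an <- small_analysis()
  truth <- fld$groups[fld$groups$group_class == "SCC", ]
  auto <- an$groups[an$groups$classification == "SCC", ]
  expect_equal(nrow(auto), nrow(truth))
  expect_lt(abs(sum(auto$total_area_um2) - sum(truth$total_area_um2)) /
              sum(truth$total_area_um2), 0.05)
  expect_lte(max(abs(sort(auto$n_cells) - sort(truth$n_cells))), 1)
})

test_that("ring cells contribute their filled area to cluster size", {
  fld <- small_field()
  an <- small_analysis()
  # truth areas are whole-cell areas; a cluster with ring cells must still
  # recover its total area, so annulus-only areas would fail this
  truth <- sum(fld$groups$total_area_um2[fld$groups$group_class == "SCC"])
  auto <- sum(an$groups$total_area_um2[an$groups$classification == "SCC"])
  has_ring <- any(fld$cells$lignification == "ring", na.rm = TRUE)
  expect_true(has_ring)
  expect_lt(abs(auto - truth) / truth, 0.05)
})

test_that("isolated percentage follows its definition", {
  g <- tibble::tibble(
    group_id = 1:3, n_cells = c(20L, 20L, 2L),
    total_area_um2 = c(2000, 2000, 200), eq_diameter_um = 1,
    classification = c("SCC", "SCC", "isolated"), border = FALSE,
    members = list(1:20, 21:40, 41:42))
  expect_equal(isolated_percentage(g), 5)
  expect_equal(isolated_percentage(g[1:2, ]), 0)
  expect_error(isolated_percentage(g[3, ]), "division error")
})

test_that("circularity is smallest over largest Feret diameter", {
  # a disk is circular
  lab <- paint_disks(60, 60, cbind(30, 30), 20)
  inst <- instances_from_labels(lab)
  inst$type <- "parenchyma"
  m <- measure_parenchyma(inst)
  expect_gt(m$circularity, 0.95)
  expect_lte(m$circularity, 1)
  # an ellipse with axes 80 and 40 um has circularity 0.5
  lab2 <- matrix(0L, 100, 120)
  for (r in 1:100) for (c in 1:120) {
    if (((r - 50) / 20)^2 + ((c - 60) / 40)^2 <= 1) lab2[r, c] <- 1L
  }
  inst2 <- instances_from_labels(lab2)
  inst2$type <- "parenchyma"
  m2 <- measure_parenchyma(inst2)
  expect_lt(abs(m2$circularity - 0.5), 0.03)
})

test_that("parenchyma circularity recovery stays within 0.1 of target", {
  pm <- tissue_params(field_width_um = 500, field_height_um = 500,
                      pixel_size_um = 2, mean_parenchyma_area_um2 = 1600,
                      parenchyma_circularity = 0.65, seed = 17)
  m <- generate_mosaic(pm)
  img <- render_stained_image(m, noise_sd = 0)
  pr <- segment_parenchyma(separate_stains(img), NULL, 2)
  meas <- measure_parenchyma(pr)
  expect_lt(abs(mean(meas$circularity) - 0.65), 0.1)
})

test_that("contact classification flags cells sharing a wall with an SCC", {
  fld <- small_field()
  an <- small_analysis()
  truth <- fld$cells[fld$cells$type == "parenchyma", ]
  auto <- an$par_measures
  # match auto instances to truth cells by centroid proximity
  pr <- tibble::as_tibble(an$parenchyma)
  pr <- pr[match(auto$cell_id, pr$cell_id), ]
  nn <- vapply(seq_len(nrow(auto)), function(i) {
    d2 <- (truth$centroid_row - pr$centroid_row[i])^2 +
      (truth$centroid_col - pr$centroid_col[i])^2
    which.min(d2)
  }, integer(1))
  truth_contact <- truth$contact_scc[nn]
  auto_contact <- auto$contact_class == "around_cluster"
  agreement <- mean(truth_contact == auto_contact)
  expect_gte(agreement, 0.95)
  # no stone cells at all: every cell is general
  pal <- stain_palette()
  img <- array(rep(pal$background, each = 1600), dim = c(40, 40, 3))
  img[, 20, ] <- rep(pal$wall, each = 40)
  masks <- separate_stains(img)
  pr2 <- segment_parenchyma(masks, NULL, 1)
  g0 <- group_stone_cells(NULL)
  cc <- classify_contact(measure_parenchyma(pr2, keep_border = TRUE), g0,
                         NULL, par_labels = attr(pr2, "labels"))
  expect_true(all(cc$contact_class == "general"))
})

test_that("isolated stone cells do not confer around-cluster status", {
  # one isolated pair of stone cells surrounded by parenchyma
  pal <- stain_palette()
  ny <- 80; nx <- 80
  img <- array(rep(pal$background, each = ny * nx), dim = c(ny, nx, 3))
  img[40, , ] <- rep(pal$wall, each = nx)
  img[, 40, ] <- rep(pal$wall, each = ny)
  for (r in 1:ny) for (c in 1:nx) {
    if ((r - 20)^2 + (c - 20)^2 <= 8^2) img[r, c, ] <- pal$stone
  }
  masks <- separate_stains(img)
  st <- segment_stone_cells(masks, 1)
  pr <- segment_parenchyma(masks, attr(st, "labels"), 1)
  g <- group_stone_cells(st)
  expect_equal(g$classification, "isolated")
  cc <- classify_contact(measure_parenchyma(pr, keep_border = TRUE), g,
                         attr(st, "labels"), par_labels = attr(pr, "labels"))
  expect_true(all(cc$contact_class == "general"))
})
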
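# Shared fixtures: small synthetic fields so unit tests stay fast. Built
# once per test run and cached in this environment.

.fixtures <- new.env(parent = emptyenv())

# A 500x500 um Stage-I-like field at 2 um/px with a fixed cluster layout.
small_field <- function() {
  if (is.null(.fixtures$small_field)) {
    pm <- tissue_params(field_width_um = 500, field_height_um = 500,
                        pixel_size_um = 2, mean_parenchyma_area_um2 = 1600,
                        parenchyma_circularity = 0.7,
                        stone_cell_area_um2 = 1200, seed = 7)
    spec <- tibble::tibble(n_cells = c(8L, 2L), class = c("SCC", "isolated"))
    fld <- implant_stone_clusters(generate_mosaic(pm), pm, groups_spec = spec)
    .fixtures$small_field <- fld
  }
  .fixtures$small_field
}

# The 100-field parameter-recovery benchmark at the generator defaults,
# shared between the recovery and validation acceptance checks.
acceptance_benchmark <- function() {
  if (is.null(.fixtures$acceptance_benchmark)) {
    .fixtures$acceptance_benchmark <- synthetic_benchmark(
      n_fields = 100, params = tissue_params(), seed = 42L)
  }
  .fixtures$acceptance_benchmark
}

small_analysis <- function() {
  if (is.null(.fixtures$small_analysis)) {
    fld <- small_field()
    img <- render_stained_image(fld)
    .fixtures$small_analysis <- analyze_section(img, fld$params$pixel_size_um)
  }
  .fixtures$small_analysis
}

# Paint filled disks into an integer label matrix (later disks overwrite).
paint_disks <- function(ny, nx, centers, radii) {
  lab <- matrix(0L, ny, nx)
  for (i in seq_len(nrow(centers))) {
    rr <- pmax(1, floor(centers[i, 1] - radii[i])):
      pmin(ny, ceiling(centers[i, 1] + radii[i]))
    cc <- pmax(1, floor(centers[i, 2] - radii[i])):
      pmin(nx, ceiling(centers[i, 2] + radii[i]))
    for (r in rr) for (c in cc) {
      if ((r - centers[i, 1])^2 + (c - centers[i, 2])^2 <= radii[i]^2) {
        lab[r, c] <- i
      }
    }
  }
  lab
}

# Brute-force transitive closure of pairwise label adjacency: two labels are
# adjacent if any two of their pixels are within Chebyshev distance `radius`.
brute_force_groups <- function(lab, radius) {
  ids <- sort(unique(lab[lab > 0]))
  k <- length(ids)
  coords <- lapply(ids, function(i) which(lab == i, arr.ind = TRUE))
  adj <- diag(k) > 0
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (j <= i) next
      a <- coords[[i]]; b <- coords[[j]]
      dmin <- min(pmax(abs(outer(a[, 1], b[, 1], "-")),
                       abs(outer(a[, 2], b[, 2], "-"))))
      adj[i, j] <- adj[j, i] <- dmin <= radius
    }
  }
  # reachability by repeated boolean multiplication
  reach <- adj
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  comp <- integer(k)
  cid <- 0
  for (i in seq_len(k)) {
    if (comp[i] == 0) {
      cid <- cid + 1
      comp[reach[i, ]] <- cid
    }
  }
  stats::setNames(comp, ids)
}

# Letter-display soundness: sharing a letter <=> pair not significant.
letters_encode_matrix <- function(lt) {
  sig <- attr(lt, "significant")
  groups <- lt$group
  for (i in seq_along(groups)) {
    for (j in seq_along(groups)) {
      if (i == j) next
      li <- strsplit(lt$letters[lt$group == groups[i]], "")[[1]]
      lj <- strsplit(lt$letters[lt$group == groups[j]], "")[[1]]
      share <- length(intersect(li, lj)) > 0
      if (share == sig[groups[i], groups[j]]) return(FALSE)
    }
  }
  TRUE
}
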
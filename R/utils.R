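# Internal raster helpers shared by the generator and the segmentation stage.
# Rasters are plain integer/logical matrices indexed [row, col]; physical
# coordinates are pixel centers, (col - 0.5, row - 0.5) * pixel_size_um.

# Shift a matrix by (dr, dc), padding with `fill`.
shift_mat <- function(m, dr, dc, fill = 0L) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  sr <- max(1L, 1L + dr):min(nr, nr + dr)
  sc <- max(1L, 1L + dc):min(nc, nc + dc)
  out[sr, sc] <- m[sr - dr, sc - dc, drop = FALSE]
  out
}

# Offsets (dr, dc) with Chebyshev distance in 1..radius, excluding (0,0),
# keeping one of each +/- pair (adjacency is symmetric).
chebyshev_offsets <- function(radius) {
  grid <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  grid <- grid[!(grid$dr == 0 & grid$dc == 0), ]
  grid <- grid[grid$dr > 0 | (grid$dr == 0 & grid$dc > 0), ]
  grid
}

# Pairs of distinct positive labels that come within Chebyshev distance
# `radius` of each other. Returns a 2-column matrix (a < b), deduplicated.
label_adjacency_pairs <- function(labels, radius = 1L) {
  # crop to the bounding box of labeled pixels (plus margin): stone cells
  # usually occupy a small part of the field
  idx <- which(labels > 0L)
  if (!length(idx)) return(matrix(integer(0), ncol = 2))
  nr <- nrow(labels)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  r0 <- max(1L, min(rows) - radius); r1 <- min(nr, max(rows) + radius)
  c0 <- max(1L, min(cols) - radius); c1 <- min(ncol(labels), max(cols) + radius)
  labels <- labels[r0:r1, c0:c1, drop = FALSE]
  offs <- chebyshev_offsets(radius)
  pairs <- vector("list", nrow(offs))
  for (i in seq_len(nrow(offs))) {
    sh <- shift_mat(labels, offs$dr[i], offs$dc[i], fill = 0L)
    keep <- labels > 0L & sh > 0L & labels != sh
    if (any(keep)) {
      a <- labels[keep]; b <- sh[keep]
      pairs[[i]] <- cbind(pmin(a, b), pmax(a, b))
    }
  }
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs)) return(matrix(integer(0), ncol = 2))
  unique(pairs)
}

# Union-find over integer ids; returns component id per element of `ids`.
union_find_components <- function(ids, pairs) {
  parent <- stats::setNames(ids, ids)
  find <- function(x) {
    while (parent[[as.character(x)]] != x) {
      parent[[as.character(x)]] <<- parent[[as.character(parent[[as.character(x)]])]]
      x <- parent[[as.character(x)]]
    }
    x
  }
  if (nrow(pairs) > 0) {
    for (i in seq_len(nrow(pairs))) {
      a <- pairs[i, 1]; b <- pairs[i, 2]
      if (!a %in% ids || !b %in% ids) next
      ra <- find(a); rb <- find(b)
      if (ra != rb) parent[[as.character(max(ra, rb))]] <- min(ra, rb)
    }
  }
  roots <- vapply(ids, find, numeric(1))
  match(roots, sort(unique(roots)))
}

# Mask of pixels whose Chebyshev-`radius` neighborhood contains a different
# positive label (the wall band between tessellation cells).
boundary_band <- function(labels, radius = 1L) {
  wall <- matrix(FALSE, nrow(labels), ncol(labels))
  offs <- chebyshev_offsets(radius)
  for (i in seq_len(nrow(offs))) {
    for (sgn in c(1L, -1L)) {
      sh <- shift_mat(labels, sgn * offs$dr[i], sgn * offs$dc[i], fill = -1L)
      wall <- wall | (sh >= 0L & sh != labels)
    }
  }
  wall
}

# Dilate a logical mask by Chebyshev radius (box structuring element).
dilate_mask <- function(mask, radius) {
  side <- 2L * as.integer(radius) + 1L
  out <- EBImage::dilate(mask * 1, EBImage::makeBrush(side, shape = "box"))
  out > 0
}

# Per-label pixel counts for labels 1..nmax (0 = background excluded).
label_areas_px <- function(labels, nmax = max(labels)) {
  if (nmax < 1L) return(integer(0))
  tabulate(labels[labels > 0L], nbins = nmax)
}

# row/col coordinates of pixels for each label, as a list of 2-col matrices.
label_coords <- function(labels) {
  idx <- which(labels > 0L)
  if (length(idx) == 0) return(list())
  nr <- nrow(labels)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  split.data.frame(cbind(row = rows, col = cols), labels[idx])
}

labels_on_border <- function(labels) {
  edge <- c(labels[1, ], labels[nrow(labels), ], labels[, 1], labels[, ncol(labels)])
  sort(unique(edge[edge > 0L]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
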
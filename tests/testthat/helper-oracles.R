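# Independent brute-force oracles used across the suite. They deliberately
# work on coordinate sets (Minkowski sums/differences) rather than array
# shifts, so they share no code path with the implementation.

# Coordinates (n x 3 integer matrix) of TRUE voxels.
grid_coords <- function(grid) which(grid, arr.ind = TRUE)

coords_to_grid <- function(coords, dm) {
  g <- array(FALSE, dm)
  keep <- coords[, 1] >= 1 & coords[, 1] <= dm[1] &
          coords[, 2] >= 1 & coords[, 2] <= dm[2] &
          coords[, 3] >= 1 & coords[, 3] <= dm[3]
  coords <- coords[keep, , drop = FALSE]
  g[coords] <- TRUE
  g
}

element_offsets_oracle <- function(element) {
  ctr <- (dim(element) + 1L) / 2L
  w <- which(element, arr.ind = TRUE)
  sweep(w, 2L, ctr)
}

# Minkowski-sum dilation: union of the mask translated by every element
# offset, clipped to the grid.
minkowski_dilate <- function(grid, element) {
  off <- element_offsets_oracle(element)
  pts <- grid_coords(grid)
  out <- do.call(rbind, lapply(seq_len(nrow(off)), function(k)
    sweep(pts, 2L, off[k, ], `+`)))
  coords_to_grid(out, dim(grid))
}

# Erosion by per-voxel membership test: voxel kept iff every translated
# element offset lands inside the grid on an occupied voxel.
minkowski_erode <- function(grid, element) {
  off <- element_offsets_oracle(element)
  dm <- dim(grid)
  out <- array(FALSE, dm)
  pts <- grid_coords(grid)
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]
    ok <- TRUE
    for (k in seq_len(nrow(off))) {
      q <- p + off[k, ]
      if (any(q < 1L) || any(q > dm) || !grid[q[1], q[2], q[3]]) {
        ok <- FALSE
        break
      }
    }
    out[p[1], p[2], p[3]] <- ok
  }
  out
}

# ZOT by direct Minkowski operations, iterated.
minkowski_zot <- function(grid, element, iterations = 2L) {
  d <- grid
  e <- grid
  for (i in seq_len(iterations)) {
    d <- minkowski_dilate(d, element)
    e <- minkowski_erode(e, element)
  }
  list(dilated = d, eroded = e, zot = d & !e)
}

# Pair-counting AUC oracle (ties at 1/2), quadratic on purpose.
pair_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Random connected-ish blob mask on a small grid: a few overlapping digital
# balls, interior-safe by a margin.
random_blob_grid <- function(dm, margin = 3L, n_balls = 3L) {
  g <- array(FALSE, dm)
  ctr_lo <- margin + 2L
  for (b in seq_len(n_balls)) {
    c0 <- vapply(1:3, function(a)
      sample(ctr_lo:(dm[a] - margin - 1L), 1L), integer(1))
    r <- sample(1:3, 1L)
    ax <- lapply(1:3, function(a) (seq_len(dm[a]) - c0[a])^2)
    d2 <- outer(outer(ax[[1]], ax[[2]], `+`), ax[[3]], `+`)
    g <- g | (d2 <= r^2)
  }
  g
}

# Tiny planted/null tables for GA and evaluation tests.
small_table <- function(n = 30, p = 8, k = 1, effect = 2, seed = 1,
                        fractions = c(0.5, 0.5)) {
  generate_feature_table(table_spec(
    n_samples = n, n_features = p, class_fractions = fractions,
    k_informative = k, effect_size = effect, seed = seed))
}

# Table whose single informative column equals the label exactly.
perfect_table <- function(n = 20, p = 5, seed = 4) {
  tb <- small_table(n = n, p = p, k = 0, effect = 0, seed = seed)
  tb[[3]] <- as.numeric(ft_labels(tb))  # first feature column = label
  new_feature_table(as.data.frame(tb), provenance = list(source = "perfect"))
}
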
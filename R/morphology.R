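#' Build a 3D structuring element
#'
#' The "ball" of size 3 is the 7-voxel face-connected cross: the discretized
#' Euclidean ball of radius 1 on a 3x3x3 grid (the only circular shape that
#' grid can hold). Larger odd sizes give the digital ball of radius
#' `(size-1)/2`. `cross` is the city-block ball of the same radius and `cube`
#' the full box.
#'
#' @param kind One of `"ball"`, `"cross"`, `"cube"`.
#' @param size Odd integer edge length, >= 3.
#' @return A 3D logical array of dimension `size^3`, symmetric about its
#'   center.
#' @examples
#' sum(make_structuring_element("ball", 3))   # 7
#' sum(make_structuring_element("cube", 3))   # 27
#' @export
make_structuring_element <- function(kind = c("ball", "cross", "cube"),
                                     size = 3L) {
  kind <- match.arg(kind)
  size <- as.integer(size)
  if (size < 3L || size %% 2L == 0L) stop("size must be an odd integer >= 3")
  r <- (size - 1L) / 2L
  off <- seq(-r, r)
  d <- expand.grid(x = off, y = off, z = off)
  keep <- switch(kind,
    ball  = d$x^2 + d$y^2 + d$z^2 <= r^2 + 1e-9,
    cross = abs(d$x) + abs(d$y) + abs(d$z) <= r,
    cube  = rep(TRUE, nrow(d)))
  array(keep, c(size, size, size))
}

# Offsets (rows of an integer matrix) of the TRUE voxels of an element,
# relative to its center.
element_offsets <- function(element) {
  stopifnot(length(dim(element)) == 3L, all(dim(element) %% 2L == 1L))
  ctr <- (dim(element) + 1L) / 2L
  w <- which(element, arr.ind = TRUE)
  sweep(w, 2L, ctr)
}

# One binary dilation/erosion pass by shift-and-combine over element offsets.
# Out-of-grid space is background: dilation is clipped to the grid, erosion
# treats the outside as empty.
morph_once <- function(grid, offsets, op = c("dilate", "erode")) {
  op <- match.arg(op)
  dm <- dim(grid)
  acc <- NULL
  for (k in seq_len(nrow(offsets))) {
    sh <- shift_grid(grid, offsets[k, ], fill = FALSE)
    acc <- if (is.null(acc)) sh else if (op == "dilate") acc | sh else acc & sh
  }
  acc
}

# Translate a logical 3D array by integer offset `by`, filling with `fill`.
shift_grid <- function(grid, by, fill = FALSE) {
  dm <- dim(grid)
  out <- array(fill, dm)
  src <- dst <- vector("list", 3L)
  for (a in 1:3) {
    s <- by[[a]]
    if (abs(s) >= dm[a]) return(out)
    if (s >= 0) { dst[[a]] <- (1 + s):dm[a]; src[[a]] <- 1:(dm[a] - s) }
    else        { dst[[a]] <- 1:(dm[a] + s); src[[a]] <- (1 - s):dm[a] }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- grid[src[[1]], src[[2]], src[[3]]]
  out
}

#' Extract the zone of transition (ZOT) from a tumor mask
#'
#' Applies `iterations` morphological 3D dilations and erosions of the binary
#' tumor mask with the given structuring element and returns the ZOT as the
#' set difference dilated minus eroded: the shell that straddles the tumor
#' boundary, where attenuation transitions between lesion and surrounding
#' parenchyma.
#'
#' Small masks may erode to nothing (thin T1a lesions at coarse slice
#' spacing); this is not an error: the ZOT then equals the dilated mask and a
#' warning is logged. Dilation is clipped at the grid boundary, with a
#' warning when clipping actually occurs. Morphology runs in voxel space on
#' the native grid; spacing and origin propagate unchanged.
#'
#' @param mask A [voxel_mask()] with at least one occupied voxel.
#' @param element 3D logical structuring element from
#'   [make_structuring_element()].
#' @param iterations Positive integer number of dilation/erosion passes
#'   (default 2).
#' @return An object of class `zot_result`: list with `voxel_mask` fields
#'   `original`, `eroded`, `dilated`, `zot`. Invariants: eroded is a subset
#'   of original is a subset of dilated, and `zot = dilated \ eroded`.
#' @examples
#' g <- array(FALSE, c(9, 9, 9)); g[5, 5, 5] <- TRUE
#' z <- extract_zot(voxel_mask(g), iterations = 2)
#' sum(z$zot$grid)  # 25: city-block ball of radius 2
#' @export
extract_zot <- function(mask, element = make_structuring_element("ball", 3),
                        iterations = 2L) {
  stopifnot(inherits(mask, "voxel_mask"))
  if (!any(mask$grid)) stop("empty input mask")
  iterations <- as.integer(iterations)
  if (iterations < 1L) stop("iterations must be >= 1")
  off <- element_offsets(element)
  reach <- iterations * max(abs(off))

  # Dilate on a padded grid so boundary clipping is detected exactly.
  dm <- dim(mask$grid)
  pad <- array(FALSE, dm + 2L * reach)
  idx <- lapply(1:3, function(a) (reach + 1L):(reach + dm[a]))
  pad[idx[[1]], idx[[2]], idx[[3]]] <- mask$grid
  dil_pad <- pad
  for (i in seq_len(iterations)) dil_pad <- morph_once(dil_pad, off, "dilate")
  clipped <- sum(dil_pad) > {
    inside <- dil_pad[idx[[1]], idx[[2]], idx[[3]]]
    sum(inside)
  }
  if (clipped)
    warning("dilation clipped by the grid boundary; out-of-grid voxels dropped")
  dilated <- dil_pad[idx[[1]], idx[[2]], idx[[3]]]

  eroded <- mask$grid
  for (i in seq_len(iterations)) eroded <- morph_once(eroded, off, "erode")
  if (!any(eroded))
    warning("erosion emptied the mask; ZOT equals the dilated mask")

  as_vm <- function(g) voxel_mask(g, mask$spacing_mm, mask$origin)
  structure(list(original = mask, eroded = as_vm(eroded),
                 dilated = as_vm(dilated), zot = as_vm(dilated & !eroded)),
            class = "zot_result")
}

#' @export
print.zot_result <- function(x, ...) {
  cat("<zot_result> original", sum(x$original$grid),
      "| eroded", sum(x$eroded$grid),
      "| dilated", sum(x$dilated$grid),
      "| zot", sum(x$zot$grid), "voxels\n")
  invisible(x)
}

#' Shell-thickness QC profile of a ZOT
#'
#' Counts ZOT voxels along the six axis-aligned rays leaving the centroid of
#' the original mask, a quick sanity check that the extracted shell has the
#' expected width (for a large digital ball, ball-3 element and 2 iterations
#' the shell is 2 voxels outward + 2 inward = 4 along each axis). When
#' erosion emptied the mask the ray crosses the whole dilated extent, so the
#' maximum spans it.
#'
#' @param result A `zot_result` with non-empty ZOT.
#' @return List with `per_ray` (named integer vector, 6 rays), `min`,
#'   `median`, `max`.
#' @export
zot_thickness_profile <- function(result) {
  stopifnot(inherits(result, "zot_result"))
  z <- result$zot$grid
  if (!any(z)) stop("empty ZOT")
  w <- which(result$original$grid, arr.ind = TRUE)
  ctr <- round(colMeans(w))
  dm <- dim(z)
  rays <- list(`x+` = c(1, 1), `x-` = c(1, -1), `y+` = c(2, 1),
               `y-` = c(2, -1), `z+` = c(3, 1), `z-` = c(3, -1))
  thick <- vapply(rays, function(r) {
    axis <- r[1]; dir <- r[2]
    pos <- ctr
    steps <- if (dir > 0) seq(ctr[axis], dm[axis]) else seq(ctr[axis], 1)
    hits <- 0L
    for (s in steps) {
      pos[axis] <- s
      if (z[pos[1], pos[2], pos[3]]) hits <- hits + 1L
    }
    hits
  }, integer(1))
  list(per_ray = thick, min = min(thick),
       median = stats::median(thick), max = max(thick))
}
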
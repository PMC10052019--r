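#' Extraction configuration
#'
#' Controls which feature classes and filter images the extraction engine
#' computes. The shipped defaults define the package's standard catalogue:
#' 18 shape descriptors of the mask plus, for each of 12 images (the
#' original, 8 undecimated Haar wavelet subbands, and Laplacian-of-Gaussian
#' responses at 3 sigmas), 19 named first-order statistics and 81 percentiles
#' (p10..p90 in steps of 1) — exactly 1218 named features per region and
#' 2436 per patient once tumor and ZOT regions are combined.
#'
#' @param feature_classes Subset of `c("shape", "firstorder", "percentiles")`.
#' @param wavelet_subbands Character vector of Haar subband tags to compute
#'   (subset of LLL..HHH), or `character(0)` for none.
#' @param log_sigmas_mm Numeric vector of Laplacian-of-Gaussian sigmas (mm).
#' @param percentile_grid Integer percentile grid for the `percentiles`
#'   class.
#' @param bin_width Fixed intensity bin width for entropy/uniformity
#'   discretization (HU-like units).
#' @param engine `"native"` or the name of an engine registered with
#'   [set_extraction_engine()].
#' @param pad_voxels Crop padding around the mask bounding box before
#'   filtering; must cover the largest filter support.
#' @return An `extraction_config` object.
#' @examples
#' cfg <- extraction_config()
#' extraction_feature_count(cfg)  # 1218
#' @export
extraction_config <- function(feature_classes = c("shape", "firstorder",
                                                  "percentiles"),
                              wavelet_subbands = c("LLL", "LLH", "LHL", "LHH",
                                                   "HLL", "HLH", "HHL", "HHH"),
                              log_sigmas_mm = c(1, 2, 3),
                              percentile_grid = 10:90,
                              bin_width = 25,
                              engine = "native",
                              pad_voxels = NULL) {
  feature_classes <- match.arg(feature_classes, several.ok = TRUE)
  stopifnot(all(wavelet_subbands %in% c("LLL", "LLH", "LHL", "LHH",
                                        "HLL", "HLH", "HHL", "HHH")),
            all(log_sigmas_mm > 0), bin_width > 0)
  if (is.null(pad_voxels))
    pad_voxels <- max(4, if (length(log_sigmas_mm))
      ceiling(4 * max(log_sigmas_mm)) + 2 else 0)
  cfg <- structure(list(feature_classes = feature_classes,
                        wavelet_subbands = wavelet_subbands,
                        log_sigmas_mm = log_sigmas_mm,
                        percentile_grid = as.integer(percentile_grid),
                        bin_width = bin_width, engine = engine,
                        pad_voxels = as.integer(pad_voxels)),
                   class = "extraction_config")
  cfg$hash <- content_hash(unclass(cfg))
  cfg
}

#' @rdname extraction_config
#' @param config An `extraction_config`.
#' @export
extraction_feature_count <- function(config) {
  n_img <- 1L + length(config$wavelet_subbands) + length(config$log_sigmas_mm)
  n_fo <- (if ("firstorder" %in% config$feature_classes) 19L else 0L) +
    (if ("percentiles" %in% config$feature_classes)
       length(config$percentile_grid) else 0L)
  n_shape <- if ("shape" %in% config$feature_classes) 18L else 0L
  n_shape + n_img * n_fo
}

# Engine registry ------------------------------------------------------------

.engines <- new.env(parent = emptyenv())

#' Register an external extraction engine
#'
#' The extraction layer is pluggable: an engine is a function
#' `function(volume, mask, config)` returning a named numeric feature
#' vector. The shipped engine is `"native"`; an adapter to an external
#' radiomics engine can be registered under any other name.
#'
#' @param name Engine name.
#' @param fun Engine function.
#' @export
set_extraction_engine <- function(name, fun) {
  stopifnot(is.character(name), is.function(fun))
  assign(name, fun, envir = .engines)
  invisible(name)
}

get_extraction_engine <- function(name) {
  if (name == "native") return(native_engine_features)
  if (!exists(name, envir = .engines))
    stop("extraction engine '", name, "' is unavailable; register it with ",
         "set_extraction_engine() or fall back to the native backend ",
         "(engine = 'native')")
  get(name, envir = .engines)
}

# First-order statistics -----------------------------------------------------

# 19 named first-order statistics of a value vector. Population moments;
# skewness/kurtosis of a (near-)constant region are defined as 0.
first_order_stats <- function(v, bin_width, voxel_volume) {
  n <- length(v)
  mu <- mean(v)
  m2 <- mean((v - mu)^2)
  qs <- quantile(v, c(0.05, 0.10, 0.25, 0.75, 0.90, 0.95), names = FALSE,
                 type = 7)
  sk <- if (m2 > 1e-12) mean((v - mu)^3) / m2^1.5 else 0
  ku <- if (m2 > 1e-12) mean((v - mu)^4) / m2^2 else 0
  # fixed-bin-width histogram for entropy/uniformity
  lo <- floor(min(v) / bin_width) * bin_width
  cuts <- seq(lo, max(v) + bin_width, by = bin_width)
  p <- tabulate(findInterval(v, cuts, rightmost.closed = TRUE),
                nbins = length(cuts)) / n
  p <- p[p > 0]
  v1090 <- v[v >= qs[2] & v <= qs[5]]
  c(firstorder_Mean = mu,
    firstorder_Median = median(v),
    firstorder_Variance = m2,
    firstorder_Skewness = sk,
    firstorder_Kurtosis = ku,
    firstorder_Energy = sum(v^2),
    firstorder_TotalEnergy = voxel_volume * sum(v^2),
    firstorder_RootMeanSquared = sqrt(mean(v^2)),
    firstorder_Entropy = -sum(p * log2(p)),
    firstorder_Uniformity = sum(p^2),
    firstorder_Minimum = min(v),
    firstorder_Maximum = max(v),
    firstorder_Range = max(v) - min(v),
    firstorder_InterquartileRange = qs[4] - qs[3],
    firstorder_RobustRange = qs[5] - qs[2],
    firstorder_MeanAbsoluteDeviation = mean(abs(v - mu)),
    firstorder_RobustMeanAbsoluteDeviation =
      if (length(v1090)) mean(abs(v1090 - mean(v1090))) else 0,
    firstorder_P05 = qs[1],
    firstorder_P95 = qs[6])
}

percentile_stats <- function(v, grid) {
  out <- quantile(v, grid / 100, names = FALSE, type = 7)
  names(out) <- sprintf("firstorder_P%02d", grid)
  out
}

# Shape descriptors ----------------------------------------------------------

# 18 shape descriptors of a binary mask with physical spacing.
shape_stats <- function(mask) {
  g <- mask$grid
  sp <- mask$spacing_mm
  vox <- prod(sp)
  n <- sum(g)
  vol <- n * vox
  # face-connected surface: exposed faces per axis
  exposed <- 0
  area <- 0
  surf <- array(FALSE, dim(g))
  for (axis in 1:3) {
    face_area <- vox / sp[axis]
    for (dir in c(-1L, 1L)) {
      off <- c(0L, 0L, 0L); off[axis] <- dir
      nb <- shift_grid(g, off, fill = FALSE)
      open_face <- g & !nb
      area <- area + sum(open_face) * face_area
      surf <- surf | open_face
    }
  }
  w <- which(g, arr.ind = TRUE)
  coords <- sweep(w, 2L, sp, `*`)
  bbox <- apply(coords, 2L, range)
  bbox_dims <- (bbox[2, ] - bbox[1, ]) + sp  # voxel extents inclusive
  bbox_vol <- prod(bbox_dims)
  # principal axis lengths from the coordinate covariance (4*sqrt(eigval))
  if (n > 1) {
    ev <- sort(eigen(stats::cov(coords), symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    ev <- pmax(ev, 0)
  } else ev <- c(0, 0, 0)
  axis_len <- 4 * sqrt(ev)
  elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0
  flat <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0
  # maximum 3D diameter over surface voxels (deterministic subsample cap)
  sw <- which(surf, arr.ind = TRUE)
  if (nrow(sw) > 3000)
    sw <- sw[seq(1, nrow(sw), length.out = 3000), , drop = FALSE]
  sc <- sweep(sw, 2L, sp, `*`)
  maxdiam <- if (nrow(sc) > 1) sqrt(max(as.matrix(stats::dist(sc))^2)) else 0
  r_eq <- (3 * vol / (4 * pi))^(1 / 3)
  c(shape_VoxelCount = n,
    shape_VolumeMM3 = vol,
    shape_SurfaceVoxelCount = sum(surf),
    shape_SurfaceAreaMM2 = area,
    shape_SurfaceVolumeRatio = area / vol,
    shape_Sphericity = (pi^(1 / 3) * (6 * vol)^(2 / 3)) / area,
    shape_Compactness1 = vol / (sqrt(pi) * area^1.5),
    shape_Compactness2 = 36 * pi * vol^2 / area^3,
    shape_SphericalDisproportion = area / (4 * pi * r_eq^2),
    shape_EquivalentSphereDiameter = 2 * r_eq,
    shape_MajorAxisLength = axis_len[1],
    shape_MinorAxisLength = axis_len[2],
    shape_LeastAxisLength = axis_len[3],
    shape_Elongation = elong,
    shape_Flatness = flat,
    shape_Maximum3DDiameter = maxdiam,
    shape_BoundingBoxVolumeMM3 = bbox_vol,
    shape_Extent = vol / bbox_vol)
}

# Native engine --------------------------------------------------------------

# Full native engine: filter bank + first-order/percentile statistics over
# the mask, plus shape descriptors. Filters see only in-mask intensities:
# the volume is cropped to the padded mask bounding box and out-of-mask
# voxels are replaced by the in-mask mean before filtering, so features are
# a function of the masked intensities and the mask geometry alone.
native_engine_features <- function(volume, mask, config) {
  g <- mask$grid
  vox <- prod(mask$spacing_mm)
  out <- numeric(0)
  if ("shape" %in% config$feature_classes) out <- c(out, shape_stats(mask))

  fo_classes <- intersect(config$feature_classes,
                          c("firstorder", "percentiles"))
  if (length(fo_classes)) {
    cr <- crop_to_mask(volume, g, config$pad_voxels)
    base <- cr$volume
    base[!cr$mask] <- mean(base[cr$mask])
    images <- stats::setNames(list(base), "")
    if (length(config$wavelet_subbands)) {
      wb <- haar_subbands(base)
      for (sb in config$wavelet_subbands)
        images[[paste0("W-", sb)]] <- wb[[sb]]
    }
    for (s in config$log_sigmas_mm)
      images[[sprintf("L-%.1f", s)]] <-
        log_filter(base, s, mask$spacing_mm)
    tags <- names(images)
    for (i in seq_along(images)) {
      tag <- tags[i]
      v <- images[[i]][cr$mask]
      stats <- c(
        if ("firstorder" %in% fo_classes)
          first_order_stats(v, config$bin_width, vox),
        if ("percentiles" %in% fo_classes)
          percentile_stats(v, config$percentile_grid))
      if (tag != "") names(stats) <- paste0(tag, "_", names(stats))
      out <- c(out, stats)
    }
  }
  out
}

# Crop volume and mask to the mask bounding box padded by `pad` voxels.
crop_to_mask <- function(volume, grid, pad) {
  w <- which(grid, arr.ind = TRUE)
  dm <- dim(grid)
  idx <- lapply(1:3, function(a)
    max(1L, min(w[, a]) - pad):min(dm[a], max(w[, a]) + pad))
  list(volume = volume[idx[[1]], idx[[2]], idx[[3]], drop = FALSE],
       mask = grid[idx[[1]], idx[[2]], idx[[3]], drop = FALSE])
}

#' Minimal documented native feature set
#'
#' The reduced backend used where a small, fully hand-checkable vector is
#' wanted: 12 first-order statistics of the masked intensities plus 3 shape
#' descriptors (voxel count, physical volume, face-connected boundary voxel
#' count). Bit-reproducible.
#'
#' @param values Numeric vector of in-mask intensities (>= 1 voxel).
#' @param mask The [voxel_mask()] the values came from.
#' @param bin_width Intensity bin width for the entropy histogram.
#' @return Named numeric vector of 15 features.
#' @export
native_backend_features <- function(values, mask, bin_width = 25) {
  if (length(values) < 1L) stop("empty region")
  stopifnot(inherits(mask, "voxel_mask"))
  fo <- first_order_stats(values, bin_width, prod(mask$spacing_mm))
  sh <- shape_stats(mask)
  c(fo[c("firstorder_Mean", "firstorder_Median", "firstorder_Variance",
         "firstorder_Skewness", "firstorder_Kurtosis", "firstorder_Energy",
         "firstorder_Entropy", "firstorder_Minimum", "firstorder_Maximum")],
    firstorder_P10 = quantile(values, 0.10, names = FALSE),
    firstorder_P90 = quantile(values, 0.90, names = FALSE),
    firstorder_RobustRange = unname(fo["firstorder_RobustRange"]),
    sh[c("shape_VoxelCount", "shape_VolumeMM3", "shape_SurfaceVoxelCount")])
}

# Region extraction ----------------------------------------------------------

#' Extract named radiomic features for one region
#'
#' Runs the configured extraction engine on a volume restricted to a mask.
#' Region tags are left unset; [build_patient_vector()] sets them.
#'
#' @param volume 3D numeric array sharing the mask's grid.
#' @param mask A [voxel_mask()], non-empty.
#' @param config An [extraction_config()].
#' @return Named numeric vector; with the default configuration, exactly
#'   1218 entries.
#' @export
extract_region_features <- function(volume, mask, config = extraction_config()) {
  stopifnot(inherits(mask, "voxel_mask"), inherits(config, "extraction_config"))
  if (!identical(dim(volume), dim(mask$grid)))
    stop("volume and mask grid shapes differ")
  if (!any(mask$grid)) stop("empty region mask")
  engine <- get_extraction_engine(config$engine)
  engine(volume, mask, config)
}

#' Build the combined tumor + ZOT feature vector for one patient
#'
#' Extracts the same feature set from the tumor region and from the
#' zone-of-transition region, tags them `TUMOR` (no suffix) and `ZOT`
#' (rendered `(ZOT)` suffix), sorts each block lexicographically by rendered
#' name, and concatenates tumor block then ZOT block. With the default
#' configuration the result has 2436 entries.
#'
#' @param volume 3D numeric array.
#' @param tumor_mask,zot_mask [voxel_mask()]s on the same grid.
#' @param config An [extraction_config()].
#' @return Named numeric vector of length `2 * extraction_feature_count(config)`.
#' @export
build_patient_vector <- function(volume, tumor_mask, zot_mask,
                                 config = extraction_config()) {
  check_same_geometry(dim(tumor_mask$grid), tumor_mask$spacing_mm,
                      tumor_mask$origin, dim(zot_mask$grid),
                      zot_mask$spacing_mm, zot_mask$origin)
  tum <- extract_region_features(volume, tumor_mask, config)
  zot <- extract_region_features(volume, zot_mask, config)
  names(zot) <- paste0(names(zot), "(ZOT)")
  c(tum[sort(names(tum), method = "radix")],
    zot[sort(names(zot), method = "radix")])
}

#' Extract a feature table for a whole phantom cohort
#'
#' For each cohort item: extract the ZOT from the tumor mask, build the
#' combined tumor+ZOT vector, and assemble rows into a [new_feature_table()].
#'
#' @param cohort As returned by [generate_cohort()].
#' @param config An [extraction_config()].
#' @param element,iterations ZOT morphology settings (see [extract_zot()]).
#' @return A `feature_table` with one row per cohort item.
#' @export
extract_cohort_table <- function(cohort, config = extraction_config(),
                                 element = make_structuring_element("ball", 3),
                                 iterations = 2L) {
  rows <- lapply(cohort, function(ph) {
    zr <- extract_zot(ph$mask, element, iterations)
    build_patient_vector(ph$volume, ph$mask, zr$zot, config)
  })
  X <- do.call(rbind, rows)
  df <- data.frame(
    patient_id = vapply(cohort, function(p) p$patient_id, character(1)),
    label = vapply(cohort, function(p) p$label, integer(1)),
    check.names = FALSE)
  df <- cbind(df, as.data.frame(X, check.names = FALSE))
  new_feature_table(df, provenance = list(source = "phantom_cohort",
                                          config_hash = config$hash,
                                          engine = config$engine))
}
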
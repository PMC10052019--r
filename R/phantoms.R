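#' Specification of a synthetic renal-lesion phantom
#'
#' Describes a spherical lesion embedded in uniform parenchyma on a regular
#' voxel grid, in two flavours mirroring the radiological contrast between
#' renal histotypes: an oncocytoma-like lesion (`"RO-like"`) meets the
#' parenchyma directly, while a clear-cell-carcinoma-like lesion
#' (`"ccRCC-like"`) compresses it into a hyperattenuating pseudocapsule — a
#' thin bright rim placed strictly outside the tumor mask, where a
#' zone-of-transition shell will capture it. Intensities are HU-like free
#' choices of the simulator, not estimates of any cohort.
#'
#' @param class_label `"RO-like"` or `"ccRCC-like"`.
#' @param tumor_radius_mm Positive lesion radius in mm.
#' @param rim_thickness_mm Rim (pseudocapsule) thickness in mm; must be 0 for
#'   RO-like and > 0 for ccRCC-like lesions.
#' @param tumor_intensity,rim_intensity,background_intensity HU-like
#'   intensities.
#' @param noise_sd Standard deviation of additive iid Gaussian noise (>= 0).
#' @param grid_shape Integer length-3 grid dimensions.
#' @param spacing_mm Positive numeric length-3 voxel spacing in mm.
#' @return A validated `phantom_spec` object.
#' @examples
#' phantom_spec("ccRCC-like")
#' @export
phantom_spec <- function(class_label = c("RO-like", "ccRCC-like"),
                         tumor_radius_mm = 10,
                         rim_thickness_mm = if (match.arg(class_label) ==
                           "ccRCC-like") 2 else 0,
                         tumor_intensity = 40,
                         rim_intensity = 90,
                         background_intensity = 20,
                         noise_sd = 10,
                         grid_shape = c(48L, 48L, 48L),
                         spacing_mm = c(1, 1, 1)) {
  class_label <- match.arg(class_label)
  stopifnot(tumor_radius_mm > 0, rim_thickness_mm >= 0, noise_sd >= 0,
            length(grid_shape) == 3L, all(grid_shape >= 1),
            length(spacing_mm) == 3L, all(spacing_mm > 0))
  if ((rim_thickness_mm == 0) != (class_label == "RO-like"))
    stop("rim_thickness_mm must be 0 iff class_label is 'RO-like'")
  spec <- structure(list(
    class_label = class_label, tumor_radius_mm = tumor_radius_mm,
    rim_thickness_mm = rim_thickness_mm, tumor_intensity = tumor_intensity,
    rim_intensity = rim_intensity, background_intensity = background_intensity,
    noise_sd = noise_sd, grid_shape = as.integer(grid_shape),
    spacing_mm = as.numeric(spacing_mm)), class = "phantom_spec")
  # The lesion (rim included) must leave a 4-voxel margin on every axis so
  # two dilation passes can never touch the grid border.
  reach_vox <- (tumor_radius_mm + rim_thickness_mm) / spec$spacing_mm
  margin <- (spec$grid_shape - 1) / 2 - reach_vox
  if (any(margin < 4))
    stop("lesion too large for grid: needs a >= 4-voxel margin on every axis")
  spec
}

# Physical distance of every voxel center from the grid center, in mm.
grid_center_distance <- function(grid_shape, spacing_mm) {
  ctr <- (grid_shape + 1) / 2
  ax <- lapply(1:3, function(a) ((seq_len(grid_shape[a]) - ctr[a]) *
                                   spacing_mm[a])^2)
  d2 <- outer(outer(ax[[1]], ax[[2]], `+`), ax[[3]], `+`)
  sqrt(d2)
}

#' Generate one phantom volume with its tumor mask
#'
#' The mask is the set of voxels whose centers lie within `tumor_radius_mm`
#' (physical distance) of the grid center. The volume is
#' `background_intensity` everywhere, `tumor_intensity` inside the mask and,
#' for ccRCC-like specs, `rim_intensity` in the shell of `rim_thickness_mm`
#' just outside the mask, plus iid Gaussian noise. Deterministic given
#' `(spec, seed)`.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed for the noise field.
#' @return List with `volume` (3D numeric array), `mask` (a [voxel_mask()]),
#'   and `label` (0 for RO-like, 1 for ccRCC-like).
#' @export
generate_phantom <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- grid_center_distance(spec$grid_shape, spec$spacing_mm)
  inside <- d <= spec$tumor_radius_mm
  vol <- array(spec$background_intensity, spec$grid_shape)
  if (spec$rim_thickness_mm > 0) {
    rim <- !inside & d <= spec$tumor_radius_mm + spec$rim_thickness_mm
    vol[rim] <- spec$rim_intensity
  }
  vol[inside] <- spec$tumor_intensity
  if (spec$noise_sd > 0)
    vol <- vol + with_seed(seed, array(rnorm(length(vol), 0, spec$noise_sd),
                                       spec$grid_shape))
  list(volume = vol,
       mask = voxel_mask(inside, spacing_mm = spec$spacing_mm),
       label = if (spec$class_label == "ccRCC-like") 1L else 0L)
}

#' Generate a labelled cohort of phantoms
#'
#' Produces `n_per_class[1]` RO-like followed by `n_per_class[2]` ccRCC-like
#' phantoms. Each item's noise seed is derived from the master seed and the
#' item index with [derive_seed()], so any single item can be regenerated
#' independently of the others.
#'
#' @param n_per_class Integer pair `(n_RO, n_ccRCC)`.
#' @param phantom_specs List of two [phantom_spec()]s (RO-like, ccRCC-like).
#' @param seed Master integer seed.
#' @return List of length `sum(n_per_class)`; each element as returned by
#'   [generate_phantom()] plus a `patient_id` string.
#' @export
generate_cohort <- function(n_per_class = c(30L, 47L),
                            phantom_specs = list(phantom_spec("RO-like"),
                                                 phantom_spec("ccRCC-like")),
                            seed = 1L) {
  stopifnot(length(n_per_class) == 2L, all(n_per_class >= 1),
            length(phantom_specs) == 2L)
  labs <- vapply(phantom_specs, function(s) s$class_label, character(1))
  if (!identical(labs, c("RO-like", "ccRCC-like")))
    stop("phantom_specs must be list(RO-like spec, ccRCC-like spec)")
  n <- sum(n_per_class)
  cls <- rep(1:2, times = n_per_class)
  lapply(seq_len(n), function(i) {
    ph <- generate_phantom(phantom_specs[[cls[i]]],
                           seed = derive_seed(seed, i, "phantom"))
    ph$patient_id <- sprintf("P%03d", i)
    ph
  })
}

#' Write a phantom cohort to disk as NIfTI plus a CSV manifest
#'
#' @param cohort As returned by [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest data frame (`patient_id`, `label`,
#'   `volume_path`, `mask_path`), also written to `dir/manifest.csv`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort, function(ph) {
    vp <- file.path(dir, paste0(ph$patient_id, "_volume.nii.gz"))
    mp <- file.path(dir, paste0(ph$patient_id, "_mask.nii.gz"))
    write_volume_nifti(ph$volume, vp, spacing_mm = ph$mask$spacing_mm)
    write_mask_nifti(ph$mask, mp)
    data.frame(patient_id = ph$patient_id, label = ph$label,
               volume_path = vp, mask_path = mp)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
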
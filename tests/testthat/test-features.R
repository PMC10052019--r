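make_test_phantom <- function(class_label = "ccRCC-like", noise_sd = 5,
                              seed = 3) {
  sp <- if (class_label == "ccRCC-like")
    phantom_spec("ccRCC-like", tumor_radius_mm = 6, rim_thickness_mm = 2,
                 noise_sd = noise_sd, grid_shape = c(28, 28, 28))
  else
    phantom_spec("RO-like", tumor_radius_mm = 6, noise_sd = noise_sd,
                 grid_shape = c(28, 28, 28))
  generate_phantom(sp, seed)
}

test_that("default configuration meets the feature-count contract", {
  cfg <- extraction_config()
  expect_equal(extraction_feature_count(cfg), 1218)
  ph <- make_test_phantom()
  zr <- extract_zot(ph$mask)
  tum <- extract_region_features(ph$volume, ph$mask, cfg)
  expect_length(tum, 1218)
  expect_false(anyDuplicated(names(tum)) > 0)
  vec <- build_patient_vector(ph$volume, ph$mask, zr$zot, cfg)
  expect_length(vec, 2436)
  expect_equal(sum(grepl("\\(ZOT\\)$", names(vec))), 1218)
  expect_false(anyDuplicated(names(vec)) > 0)
  expect_true(all(is.finite(vec)))
})

test_that("extraction is deterministic and name ordering is stable", {
  ph <- make_test_phantom()
  zr <- extract_zot(ph$mask)
  v1 <- build_patient_vector(ph$volume, ph$mask, zr$zot)
  v2 <- build_patient_vector(ph$volume, ph$mask, zr$zot)
  expect_identical(v1, v2)
  # tumor block first, each block sorted lexicographically (C collation)
  n <- length(v1) / 2
  expect_false(any(grepl("\\(ZOT\\)$", names(v1)[1:n])))
  expect_identical(names(v1)[1:n],
                   sort(names(v1)[1:n], method = "radix"))
})

test_that("native first-order statistics match hand-computed oracles", {
  g <- array(FALSE, c(5, 5, 5)); g[2:4, 3, 3] <- TRUE
  m <- voxel_mask(g)
  v <- native_backend_features(c(1, 2, 3), m)
  expect_equal(unname(v["firstorder_Mean"]), 2)
  expect_equal(unname(v["firstorder_Energy"]), 14)  # 1 + 4 + 9
  expect_equal(unname(v["firstorder_Median"]), 2)
  expect_equal(unname(v["shape_VoxelCount"]), 3)
  expect_equal(unname(v["shape_VolumeMM3"]), 3)  # 1 mm^3 voxels
  expect_equal(unname(v["shape_SurfaceVoxelCount"]), 3)
  # population skewness of (1,2,3,4,100): third standardized moment
  x <- c(1, 2, 3, 4, 100)
  mu <- mean(x); m2 <- mean((x - mu)^2); m3 <- mean((x - mu)^3)
  g5 <- array(FALSE, c(9, 9, 9)); g5[3:7, 5, 5] <- TRUE
  v5 <- native_backend_features(x, voxel_mask(g5))
  expect_equal(unname(v5["firstorder_Skewness"]), m3 / m2^1.5)
  # degenerate region: constant values
  vc <- native_backend_features(rep(5, 4), m)
  expect_equal(unname(vc["firstorder_Variance"]), 0)
  expect_equal(unname(vc["firstorder_Entropy"]), 0)
  expect_error(native_backend_features(numeric(0), m), "empty")
})

test_that("physical volume scales with voxel spacing", {
  g <- array(FALSE, c(6, 6, 6)); g[2:3, 2:3, 2:3] <- TRUE
  m1 <- voxel_mask(g, spacing_mm = c(1, 1, 1))
  m2 <- voxel_mask(g, spacing_mm = c(1, 1, 2.5))
  expect_equal(unname(native_backend_features(rep(1, 8), m1)["shape_VolumeMM3"]), 8)
  expect_equal(unname(native_backend_features(rep(1, 8), m2)["shape_VolumeMM3"]), 20)
})

test_that("features ignore intensities outside the masked region", {
  ph <- make_test_phantom()
  cfg <- extraction_config()
  zr <- extract_zot(ph$mask)
  base <- extract_region_features(ph$volume, ph$mask, cfg)
  vol2 <- ph$volume
  outside <- !zr$dilated$grid
  vol2[outside] <- vol2[outside] + 500  # arbitrary change beyond dilation
  again <- extract_region_features(vol2, ph$mask, cfg)
  expect_identical(base, again)
})

test_that("swapping masks swaps region tags but preserves values", {
  ph <- make_test_phantom()
  zr <- extract_zot(ph$mask)
  cfg <- extraction_config()
  ab <- build_patient_vector(ph$volume, ph$mask, zr$zot$grid |>
                               voxel_mask(ph$mask$spacing_mm), cfg)
  ba <- build_patient_vector(ph$volume,
                             voxel_mask(zr$zot$grid, ph$mask$spacing_mm),
                             ph$mask, cfg)
  expect_setequal(round(unname(ab), 9), round(unname(ba), 9))
  expect_identical(sub("\\(ZOT\\)$", "", names(ab)),
                   sub("\\(ZOT\\)$", "", names(ba)))
})

test_that("ZOT-region mean discriminates phantom classes; tumor mean does not", {
  cfg <- extraction_config(feature_classes = c("firstorder"),
                           wavelet_subbands = character(0),
                           log_sigmas_mm = numeric(0))
  diffs_zot <- diffs_tum <- numeric(5)
  for (i in 1:5) {
    ro <- make_test_phantom("RO-like", noise_sd = 0, seed = i)
    cc <- make_test_phantom("ccRCC-like", noise_sd = 0, seed = i)
    mz <- function(ph) {
      z <- extract_zot(ph$mask)
      extract_region_features(ph$volume, z$zot, cfg)["firstorder_Mean"]
    }
    mt <- function(ph)
      extract_region_features(ph$volume, ph$mask, cfg)["firstorder_Mean"]
    diffs_zot[i] <- mz(cc) - mz(ro)
    diffs_tum[i] <- mt(cc) - mt(ro)
  }
  expect_true(all(diffs_zot > 5))
  expect_true(all(abs(diffs_tum) < 1e-9))
})

test_that("clean_table drops exactly the non-finite columns", {
  tb <- small_table(n = 12, p = 6, k = 0, seed = 5)
  tb2 <- tb
  tb2[[4]][3] <- NaN
  tb2[[6]][1] <- Inf
  tb2 <- new_feature_table(as.data.frame(tb2), provenance = list())
  expect_message(cleaned <- clean_table(tb2), "2 column")
  expect_equal(ncol(ft_features(cleaned)), 4)
  expect_identical(cleaned$patient_id, tb$patient_id)
  # all-finite table is the identity
  expect_identical(clean_table(tb), tb)
  # constant columns are retained
  tb3 <- tb
  tb3[[3]] <- 1.5
  tb3 <- new_feature_table(as.data.frame(tb3), provenance = list())
  expect_identical(clean_table(tb3), tb3)
  # a table reduced to zero columns errors
  tb4 <- small_table(n = 8, p = 1, k = 0, seed = 6)
  tb4[[3]][1] <- NA_real_
  tb4 <- new_feature_table(as.data.frame(tb4), provenance = list())
  expect_error(suppressMessages(clean_table(tb4)), "every feature")
})

test_that("geometry mismatches and unknown engines raise errors", {
  ph <- make_test_phantom()
  small <- voxel_mask(array(TRUE, c(4, 4, 4)))
  expect_error(extract_region_features(ph$volume, small), "shapes differ")
  cfg <- extraction_config(engine = "external_radiomics")
  expect_error(extract_region_features(ph$volume, ph$mask, cfg),
               "native backend")
  # a registered engine is picked up
  set_extraction_engine("toy", function(volume, mask, config)
    c(firstorder_Mean = mean(volume[mask$grid])))
  cfg2 <- extraction_config(engine = "toy")
  out <- extract_region_features(ph$volume, ph$mask, cfg2)
  expect_named(out, "firstorder_Mean")
})

test_that("feature names render and parse as documented", {
  fn <- feature_name("firstorder_Mean", "W-LLH", "ZOT")
  expect_identical(render_feature_name(fn), "W-LLH_firstorder_Mean(ZOT)")
  back <- parse_feature_name("W-LLH_firstorder_Mean(ZOT)")
  expect_identical(back$base_name, "firstorder_Mean")
  expect_identical(back$filter_tag, "W-LLH")
  expect_identical(back$region_tag, "ZOT")
  cases <- c("firstorder_Mean", "L-2.0_shape_VoxelCount",
             "W-HHH_firstorder_P37(ZOT)", "shape_Extent",
             "L-1.0_firstorder_Entropy")
  for (nm in cases)
    expect_identical(render_feature_name(parse_feature_name(nm)), nm)
})
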
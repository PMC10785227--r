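test_that("phantom generation anchors tissue classes and is seed-deterministic", {
  spec <- phantom_spec(seed = 1)
  case <- make_phantom(spec)
  expect_s3_class(case, "phantom_case")
  # labels partition the body into fat/soft/bone
  expect_setequal(unique(as.vector(case$labels[case$body_truth])), c(1L, 2L, 3L))
  # air anchor
  expect_true(all(case$ct[case$labels == 0L] == -1000))
  # same spec, same seed: bit-identical
  case2 <- make_phantom(spec)
  expect_identical(case, case2)
  expect_true(check_phantom_case(case))
})

test_that("lesion uptake multiplier is recovered from the generated arrays", {
  spec <- phantom_spec(
    lesion_specs = list(list(center = c(0, -30, 10), radius_mm = 8,
                             contrast = 4, class = "soft")),
    seed = 3)
  case <- make_phantom(spec)
  les <- case$lesions[[1]]
  expect_gt(nrow(les$voxels), 0)
  lesion_mean <- mean(case$activity[les$voxels])
  in_lesion <- array(FALSE, dim(case$activity)); in_lesion[les$voxels] <- TRUE
  bg_soft <- case$labels == 2L & !in_lesion
  ratio <- lesion_mean / mean(case$activity[bg_soft])
  expect_gte(ratio, 3.5)
  expect_lte(ratio, 4.5)
})

test_that("metal artifact yields MR signal void, high-HU core, unchanged activity", {
  spec <- phantom_spec(
    implant_spec = list(center = c(0, 0, 0), radius_mm = 6, hu = 3000,
                        halo_mm = 20),
    seed = 7)
  clean_spec <- spec; clean_spec$implant_spec <- NULL
  clean <- make_phantom(clean_spec)
  case <- make_phantom(spec)
  halo <- case$halo_mask
  expect_true(any(halo))
  for (ch in 1:3) expect_true(all(case$mr[, , , ch][halo] < 0.05))
  expect_gte(min(case$ct[case$implant_mask]), 3000)
  # activity unchanged except the core itself is cleared
  keep <- !case$implant_mask
  expect_equal(case$activity[keep], clean$activity[keep])
  # deterministic re-application
  case3 <- apply_metal_artifact(clean, spec)
  case4 <- apply_metal_artifact(clean, spec)
  expect_identical(case3, case4)
  # artifact is confined to the halo radius
  expect_equal(case$ct[!halo & !case$implant_mask], clean$ct[!halo & !clean$implant_mask])
  expect_error(apply_metal_artifact(clean, clean_spec), "absent")
})

test_that("spec validation rejects inconsistent geometry and lesion/implant overlap", {
  expect_error(phantom_spec(grid_shape = c(1, 16, 64)), "32")
  expect_error(phantom_spec(lesion_specs = list(
    list(center = c(0, 0, 0), radius_mm = 5, contrast = 0.5, class = "soft"))),
    "contrast")
  expect_error(phantom_spec(implant_spec = list(center = c(0, 0, 0),
    radius_mm = 6, hu = 500, halo_mm = 20)), "implant HU")
  overlap <- phantom_spec(
    lesion_specs = list(list(center = c(0, 0, 0), radius_mm = 8,
                             contrast = 2, class = "soft")),
    implant_spec = list(center = c(0, 0, 0), radius_mm = 6, hu = 3000,
                        halo_mm = 20),
    seed = 2)
  expect_error(make_phantom(overlap), "overlaps")
})

test_that("datasets are distinct, implant-free by default, and split correctly", {
  ds <- make_dataset(10, phantom_spec(seed = 1), seed = 7)
  expect_length(ds$cases, 10)
  cts <- lapply(ds$cases, `[[`, "ct")
  for (i in 1:9) for (j in (i + 1):10)
    expect_false(identical(cts[[i]], cts[[j]]))
  expect_equal(ds$train_idx, 1:8)
  expect_equal(ds$val_idx, 9:10)
  for (cs in ds$cases) {
    expect_true(check_phantom_case(cs))
    expect_false(any(cs$labels == 4L))
  }
  # bit-reproducible for a fixed seed
  ds2 <- make_dataset(10, phantom_spec(seed = 1), seed = 7)
  expect_identical(ds$cases, ds2$cases)
})
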
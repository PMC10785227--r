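test_that("masked error statistics match hand arithmetic and the RMSE identity", {
  est <- c(1, 2, 3); ref <- c(1, 1, 1)
  dim(est) <- c(1, 1, 3); dim(ref) <- c(1, 1, 3)
  mask <- array(TRUE, c(1, 1, 3))
  st <- masked_error_stats(est, ref, mask)
  expect_equal(st$mean_error, 1)
  expect_equal(st$mae, 1)
  expect_equal(st$sd_error, sqrt(2 / 3))
  expect_equal(st$rmse, sqrt(5 / 3))
  expect_equal(st$n_voxels, 3)
  st0 <- masked_error_stats(est, est, mask)
  expect_equal(st0$rmse, 0)
  expect_equal(st0$mae, 0)
  # identity on random data
  set.seed(9)
  for (k in 1:5) {
    a <- array(rnorm(60), c(1, 6, 10)); b <- array(rnorm(60), c(1, 6, 10))
    m <- array(runif(60) > 0.3, c(1, 6, 10))
    s <- masked_error_stats(a, b, m)
    expect_lt(abs(s$rmse^2 - (s$mean_error^2 + s$sd_error^2)) /
                max(s$rmse^2, 1e-12), 1e-10)
  }
  expect_error(masked_error_stats(est, ref, array(FALSE, c(1, 1, 3))), "empty")
})

test_that("lesion classification applies the 10 mm bone rule and slice overlap", {
  gs <- c(8, 20, 20)
  bone <- array(FALSE, gs); bone[, 4:6, 4:6] <- TRUE
  vox_size <- c(2.5, 2, 2)
  mk <- function(rows, cols, slices = 4) {
    v <- as.matrix(expand.grid(slices, rows, cols))
    colnames(v) <- NULL
    list(voxels = v)
  }
  # fully inside bone
  expect_equal(classify_lesion(mk(5, 5), bone, NULL, vox_size)$tissue, "bone")
  # boundary 9.9 vs 10.1 mm from the nearest bone voxel (2 mm in-plane voxels):
  # lesion at column 6 + d voxels, same rows -> distance d*2 mm
  near <- classify_lesion(mk(5, 11), bone, NULL, vox_size)   # 10 mm exactly
  expect_equal(near$tissue, "bone")
  far <- classify_lesion(mk(5, 12), bone, NULL, vox_size)    # 12 mm
  expect_equal(far$tissue, "soft")
  # in-plane iff axial slice ranges intersect
  implant <- array(FALSE, gs); implant[3:5, 10, 10] <- TRUE
  les_in <- list(voxels = as.matrix(expand.grid(4:6, 15, 15)))
  les_out <- list(voxels = as.matrix(expand.grid(7:8, 15, 15)))
  expect_equal(classify_lesion(les_in, bone, implant, vox_size)$plane, "in_plane")
  expect_equal(classify_lesion(les_out, bone, implant, vox_size)$plane, "out_plane")
  # invariant to voxel ordering
  shuf <- les_in; shuf$voxels <- shuf$voxels[sample(nrow(shuf$voxels)), , drop = FALSE]
  expect_equal(classify_lesion(shuf, bone, implant, vox_size),
               classify_lesion(les_in, bone, implant, vox_size))
  expect_error(classify_lesion(list(voxels = matrix(0, 0, 3)), bone), "empty")
})

test_that("SUVmax scales, picks the hottest voxel, and is monotone", {
  pet <- array(1, c(1, 5, 5))
  les <- list(voxels = cbind(1, 2:4, 2:4))
  expect_equal(suvmax(pet, les, suv_scale = 2.5), 2.5)
  pet[1, 3, 3] <- 2
  expect_equal(suvmax(pet, les), 2)
  expect_equal(suvmean(pet, les), mean(c(1, 2, 1)))
  pet2 <- pet + abs(array(rnorm(25), c(1, 5, 5)))
  expect_gte(suvmax(pet2, les), suvmax(pet, les))
})

test_that("Wilcoxon signed-rank: conventions, exact enumeration, symmetry", {
  expect_equal(wilcoxon_signed_rank(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_equal(wilcoxon_signed_rank(c(2, 4, 6), c(1, 2, 3)), 0.25)
  a <- c(1.2, 0.8, 2.5, 3.1, 0.3); b <- c(0.9, 1.4, 2.0, 2.8, 0.6)
  expect_equal(wilcoxon_signed_rank(a, b), wilcoxon_signed_rank(b, a))
  # exact p matches stats::wilcox.test on tie-free data
  set.seed(4)
  for (k in 1:8) {
    n <- sample(4:10, 1)
    x <- rnorm(n); y <- rnorm(n)
    ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value
    expect_equal(wilcoxon_signed_rank(x, y), ref, tolerance = 1e-12)
  }
  # large-sample normal approximation agrees with wilcox.test
  set.seed(5)
  x <- rnorm(40); y <- rnorm(40, 0.3)
  ref <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE,
                            correct = TRUE)$p.value
  expect_equal(wilcoxon_signed_rank(x, y), ref, tolerance = 1e-8)
})
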
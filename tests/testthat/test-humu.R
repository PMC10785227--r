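test_that("bilinear conversion anchors, continuity and hand-evaluated values", {
  m <- bilinear_model()
  expect_equal(hu_to_mu(-1000, m), 0)
  expect_equal(hu_to_mu(-2000, m), 0)  # clamped below air
  # continuity at the breakpoint from both segments
  eps <- 1e-9
  expect_equal(hu_to_mu(m$breakpoint_hu - eps, m),
               hu_to_mu(m$breakpoint_hu + eps, m), tolerance = 1e-6)
  # water and bone values recomputed independently from the stored slopes
  expect_equal(hu_to_mu(0, m), 9.6e-5 * 1000)
  expected_1000 <- 9.6e-5 * (47 + 1000) + 5.1e-5 * (1000 - 47)
  expect_equal(hu_to_mu(1000, m), expected_1000)
  # monotone non-decreasing over a sweep
  hu <- seq(-1500, 3000, by = 7)
  expect_true(all(diff(hu_to_mu(hu, m)) >= 0))
  expect_error(hu_to_mu(c(0, NA)), "finite")
})

test_that("body mask erodes, fills per-slice holes, ignores speckles", {
  n <- 32
  ct <- matrix(-1000, n, n)
  xc <- outer(rep(1, n), seq_len(n) - 16.5)
  yc <- outer(seq_len(n) - 16.5, rep(1, n))
  disk <- (xc^2 + yc^2) <= 10^2
  ct[disk] <- 40
  ct[15:17, 15:17] <- -1000          # interior hole
  bm <- body_mask(ct)
  # hole filled
  expect_true(all(bm[15:17, 15:17]))
  # boundary shrunk by one voxel: mask matches independent 4-neighbour erosion
  thr <- ct > -400
  oracle <- thr
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (thr[i, j]) {
      nb <- c(if (i > 1) thr[i - 1, j] else FALSE,
              if (i < n) thr[i + 1, j] else FALSE,
              if (j > 1) thr[i, j - 1] else FALSE,
              if (j < n) thr[i, j + 1] else FALSE)
      oracle[i, j] <- all(nb)
    }
  }
  # after erosion the only non-oracle voxels are the filled hole
  hole <- matrix(FALSE, n, n); hole[15:17, 15:17] <- TRUE
  hole_grown <- hole
  hole_grown[14:18, 15:17] <- TRUE; hole_grown[15:17, 14:18] <- TRUE
  expect_true(all(bm[!hole_grown] == oracle[!hole_grown]))
  # isolated speckle outside the body does not change the mask
  ct2 <- ct; ct2[2, 2] <- 40
  expect_equal(body_mask(ct2), bm, ignore_attr = TRUE)
  # degenerate inputs
  expect_error(body_mask(matrix(-1000, 8, 8)), "no body")
  single <- matrix(-1000, 8, 8); single[4, 4] <- 40
  expect_error(body_mask(single), "no body")
})

test_that("evaluation masks use strict thresholds and match phantom truth", {
  ct <- c(-951, -950, -949.9, 40)
  mu <- c(0.0096, 0.01, 0.0104, 0.096)
  dim(ct) <- c(1, 2, 2); dim(mu) <- c(1, 2, 2)
  em <- eval_masks(ct, mu)
  expect_equal(as.vector(em$hu_eval), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(as.vector(em$mu_eval), c(FALSE, FALSE, TRUE, TRUE))
  # all-soft-tissue phantom: hu_eval reproduces the body ground truth
  spec <- phantom_spec(organ_ellipses = list(
    list(center = c(0, 0, 0), semi_axes = c(Inf, 60, 70), class = "soft")),
    seed = 5)
  case <- make_phantom(spec)
  em2 <- eval_masks(case$ct, hu_to_mu(case$ct))
  expect_equal(as.vector(em2$hu_eval), as.vector(case$body_truth))
})
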
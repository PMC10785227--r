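test_that("forward projection: zero image, chord length, TOF marginalization", {
  sys <- small_sys()
  n <- 48; pix <- 3
  expect_equal(max(abs(forward_project(matrix(0, n, n), sys, TRUE))), 0)
  xc <- outer(rep(1, n), (1:n - (n + 1) / 2) * pix)
  yc <- outer(((n + 1) / 2 - 1:n) * pix, rep(1, n))
  R_mm <- 60
  img <- (xc^2 + yc^2 <= R_mm^2) * 1
  p <- forward_project(img, sys, tof = FALSE)
  # central radial bin at a grid-aligned angle: chord 2R = 12 cm
  centre_bin <- sys$geom$n_radial / 2
  chord <- 2 * sqrt(R_mm^2 - (pix / 2)^2) / 10   # bin centre sits pix/2 off axis
  expect_equal(p[1, centre_bin], chord, tolerance = 0.05)
  pt <- forward_project(img, sys, tof = TRUE)
  expect_lt(max(abs(apply(pt, c(1, 2), sum) - p)) / max(p), 1e-10)
})

test_that("back projection is the exact adjoint, with and without TOF", {
  sys <- small_sys()
  set.seed(2)
  x <- matrix(runif(48 * 48), 48, 48)
  for (tof in c(TRUE, FALSE)) {
    px <- forward_project(x, sys, tof)
    y <- array(runif(length(px)), dim(px))
    lhs <- sum(px * y)
    rhs <- sum(x * back_project(y, sys, tof))
    expect_lt(abs(lhs - rhs) / abs(lhs), 1e-8)
  }
  expect_equal(max(abs(back_project(array(0, dim(forward_project(x, sys, TRUE))),
                                    sys, TRUE))), 0)
  expect_error(forward_project(matrix(0, 10, 10), sys), "grid")
  expect_error(back_project(array(0, c(2, 2)), sys), "mismatch")
})

test_that("attenuation factors follow the closed form and are monotone in mu", {
  sys <- small_sys()
  n <- 48; pix <- 3
  expect_true(all(attenuation_factors(matrix(0, n, n), sys) == 1))
  xc <- outer(rep(1, n), (1:n - (n + 1) / 2) * pix)
  yc <- outer(((n + 1) / 2 - 1:n) * pix, rep(1, n))
  disk <- (xc^2 + yc^2 <= 60^2)
  mu <- disk * 0.096
  af <- attenuation_factors(mu, sys)
  L <- forward_project(disk * 1, sys, tof = FALSE)[1, 24]
  expect_equal(af[1, 24], exp(-0.096 * L), tolerance = 1e-12)
  # increasing mu anywhere on the chord strictly decreases the factor
  mu2 <- mu; mu2[24, 16] <- mu2[24, 16] + 0.05  # pixel on the bin-24 chord
  af2 <- attenuation_factors(mu2, sys)
  expect_true(all(af2 <= af + 1e-15))
  expect_lt(af2[1, 24], af[1, 24])
})

test_that("emission simulation is seeded and matches its expectation", {
  sys <- small_sys()
  imgs <- toy_phantom_images()
  expect_equal(sum(simulate_emission(matrix(0, 48, 48), imgs$mu, sys,
                                     total_counts = 0)$counts), 0)
  s1 <- simulate_emission(imgs$activity, imgs$mu, sys, 1e5, seed = 42)
  s2 <- simulate_emission(imgs$activity, imgs$mu, sys, 1e5, seed = 42)
  expect_identical(s1$counts, s2$counts)
  expect_error(simulate_emission(matrix(0, 48, 48), imgs$mu, sys, 100),
               "zero total expectation")
  # Monte-Carlo check of one bin: 100 replicates within 5 sigma/sqrt(100)
  bin <- which.max(s1$expected)
  draws <- vapply(1:100, function(k)
    simulate_emission(imgs$activity, imgs$mu, sys, 1e5, seed = 1000 + k)$counts[bin],
    numeric(1))
  mu_bin <- s1$expected[bin]
  expect_lt(abs(mean(draws) - mu_bin), 5 * sqrt(mu_bin) / sqrt(100))
})

test_that("subset partition is disjoint, covering, equal-sized, interleaved", {
  sys <- small_sys()
  subs <- sys$subsets
  all_angles <- sort(unlist(subs))
  expect_equal(all_angles, 1:48)
  expect_true(all(lengths(subs) == 48 / 8))
  # interleaving: consecutive angles fall in different subsets
  expect_true(all(diff(subs[[1]]) == 8))
  # bit-reversed processing order visits distant subsets first
  expect_equal(sort(sys$sub_order), 1:8)
  expect_false(all(sys$sub_order == 1:8))
  expect_error(scanner_geometry(n_angles = 50, n_subsets = 8), "n_subsets")
})
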
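test_that("OSEM leaves consistent noiseless data at the fixed point", {
  sys <- small_sys()
  imgs <- toy_phantom_images()
  sino <- noiseless_sino(imgs$activity, imgs$mu, sys)
  l1 <- osem_activity_update(imgs$activity, sino, imgs$mu, sys)
  expect_lt(max(abs(l1 - imgs$activity)) / max(imgs$activity), 1e-10)
})

test_that("all-zero data drives the activity to zero in one pass", {
  sys <- small_sys()
  imgs <- toy_phantom_images()
  zero <- noiseless_sino(imgs$activity, imgs$mu, sys)
  zero$counts[] <- 0
  l1 <- osem_activity_update(imgs$activity, zero, imgs$mu, sys)
  expect_equal(max(l1), 0)
})

test_that("one OSEM update matches hand-computed MLEM on a 2-voxel toy system", {
  # toy: 2 pixels, 2 LORs, no TOF, one subset; system matrix chosen by hand
  Amat <- Matrix::Matrix(matrix(c(1, 0.5, 0.3, 1), 2, 2), sparse = TRUE)
  sub <- list(list(angles = 1:2, rows_notof = 1:2, rows_tof = 1:2,
                   An = Amat, At = Amat,
                   Ant = Matrix::t(Amat), Att = Matrix::t(Amat)))
  geom <- structure(list(n_angles = 2L, n_radial = 1L, n_tof = 1L,
                         psf_fwhm_mm = 0, n_subsets = 1L,
                         radial_bin_mm = 1, tof_fwhm_mm = 1),
                    class = "scanner_geometry")
  sys <- structure(list(geom = geom, grid_dim = c(2L, 1L), pixel_mm = 1,
                        A_tof = Amat, A_notof = Amat,
                        At_t = Matrix::t(Amat), An_t = Matrix::t(Amat),
                        subsets = list(1:2), sub = sub, sub_order = 1L,
                        gamma = Matrix::rowSums(Amat)),
                   class = "pet_system")
  lam <- matrix(c(2, 1), 2, 1)
  mu <- matrix(c(0.1, 0.2), 2, 1)
  y <- c(3, 4)
  sino <- structure(list(counts = array(y, c(2, 1, 1)), scale = 1,
                         background = 0, geom = geom), class = "sinogram")
  # hand-computed MLEM step
  a <- exp(-as.vector(Amat %*% as.vector(mu)))
  ybar <- a * as.vector(Amat %*% as.vector(lam))
  num <- as.vector(Matrix::t(Amat) %*% (a * y / ybar))
  sens <- as.vector(Matrix::t(Amat) %*% a)
  expected <- as.vector(lam) * num / sens
  got <- osem_activity_update(lam, sino, mu, sys)
  expect_equal(as.vector(got), expected, tolerance = 1e-12)
})

test_that("attenuation pass is prior-dominated in the strong-beta limit", {
  sys <- small_sys()
  imgs <- toy_phantom_images()
  sino <- noiseless_sino(imgs$activity, imgs$mu, sys)
  beta_huge <- matrix(0, 48, 48); beta_huge[imgs$body] <- 1e12
  mu1 <- ostr_attenuation_update(imgs$mu, sino, imgs$activity, beta_huge,
                                 imgs$mu, beta_smooth = 0, sys, imgs$body,
                                 n_passes = 5)
  expect_lt(max(abs(mu1 - imgs$mu)) / max(imgs$mu), 1e-3)
})

test_that("noiseless truth is near-stationary without priors", {
  sys <- small_sys1()
  imgs <- toy_phantom_images()
  sino <- noiseless_sino(imgs$activity, imgs$mu, sys)
  zero_beta <- matrix(0, 48, 48)
  obj0 <- upctmlaa:::penalized_objective(imgs$activity, imgs$mu, sino, sys,
                                         zero_beta, imgs$mu, 0, imgs$body)
  mu1 <- ostr_attenuation_update(imgs$mu, sino, imgs$activity, zero_beta,
                                 imgs$mu, beta_smooth = 0, sys, imgs$body,
                                 n_passes = 1)
  obj1 <- upctmlaa:::penalized_objective(imgs$activity, mu1, sino, sys,
                                         zero_beta, imgs$mu, 0, imgs$body)
  expect_gte(obj1, obj0 - 1e-8 * abs(obj0))
})

test_that("mode equivalences: constant betamap = uniform; zero beta = naive", {
  sys <- small_sys()
  imgs <- toy_phantom_images()
  sino <- simulate_emission(imgs$activity, imgs$mu, sys, 2e5, seed = 3)
  cfg <- recon_config(outer_iterations = 2)
  bconst <- matrix(0, 48, 48); bconst[imgs$body] <- 7e5
  r_up <- mlaa_run(sino, sys, "upct", cfg, imgs$body, betamap = bconst,
                   mu_mr = imgs$mu)
  r_reg <- mlaa_run(sino, sys, "regularized", cfg, imgs$body, beta = 7e5,
                    mu_mr = imgs$mu)
  expect_equal(r_up$lambda, r_reg$lambda, tolerance = 1e-12)
  expect_equal(r_up$mu, r_reg$mu, tolerance = 1e-12)
  # beta = 0 with a water-initialized mu matches naive mode
  water <- matrix(0, 48, 48); water[imgs$body] <- 0.096
  r_zero <- mlaa_run(sino, sys, "upct", cfg, imgs$body,
                     betamap = matrix(0, 48, 48), mu_mr = water)
  r_naive <- mlaa_run(sino, sys, "naive", cfg, imgs$body)
  expect_equal(r_zero$lambda, r_naive$lambda, tolerance = 1e-12)
  expect_equal(r_zero$mu, r_naive$mu, tolerance = 1e-12)
  expect_error(mlaa_run(sino, sys, "upct", cfg, imgs$body), "requires")
})

test_that("reconstructions are deterministic and respect bounds", {
  sys <- small_sys()
  imgs <- toy_phantom_images()
  sino <- simulate_emission(imgs$activity, imgs$mu, sys, 2e5, seed = 3)
  lam1 <- osem_reconstruct(sino, imgs$mu, sys, iterations = 2, body = imgs$body)
  lam2 <- osem_reconstruct(sino, imgs$mu, sys, iterations = 2, body = imgs$body)
  expect_identical(lam1, lam2)
  expect_true(all(lam1 >= 0))
  res <- mlaa_run(sino, sys, "naive", recon_config(outer_iterations = 2),
                  imgs$body)
  expect_true(all(res$lambda >= 0))
  expect_true(all(res$mu >= 0 & res$mu <= 0.5))
  # attenuation under-correction goes in the expected direction
  lam_noat <- osem_reconstruct(sino, matrix(0, 48, 48), sys, 2, imgs$body)
  expect_lt(mean(lam_noat[imgs$body]), mean(lam1[imgs$body]))
})
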
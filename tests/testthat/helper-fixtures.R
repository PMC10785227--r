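# Shared fixtures, built in code. Heavy objects (sparse system matrices) are
# memoised per session so several test files can reuse them.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, builder(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# small 48x48 system, 8 subsets (radial bin = pixel so grid-aligned chords
# are exact)
small_sys <- function() memo("small_sys", function() {
  pet_system(scanner_geometry(n_angles = 48, n_radial = 64, radial_bin_mm = 3,
                              n_tof = 7, tof_fwhm_mm = 60, n_subsets = 8),
             grid_dim = c(48, 48), pixel_mm = 3)
})

# same geometry, single subset (monotone-surrogate configuration)
small_sys1 <- function() memo("small_sys1", function() {
  pet_system(scanner_geometry(n_angles = 48, n_radial = 64, radial_bin_mm = 3,
                              n_tof = 7, tof_fwhm_mm = 60, n_subsets = 1),
             grid_dim = c(48, 48), pixel_mm = 3)
})

# reference-size 64x64 system (default geometry), 8 subsets and 1 subset
full_sys <- function() memo("full_sys", function() {
  pet_system(scanner_geometry(), grid_dim = c(64, 64), pixel_mm = 3)
})
full_sys1 <- function() memo("full_sys1", function() {
  pet_system(scanner_geometry(n_subsets = 1), grid_dim = c(64, 64), pixel_mm = 3)
})

# simple 48x48 activity/attenuation pair on an elliptical body
toy_body <- function(n = 48, pix = 3) {
  xc <- outer(rep(1, n), (seq_len(n) - (n + 1) / 2) * pix)
  yc <- outer(((n + 1) / 2 - seq_len(n)) * pix, rep(1, n))
  list(body = (xc^2 / 55^2 + yc^2 / 65^2) <= 1, xc = xc, yc = yc)
}

toy_phantom_images <- function(n = 48, pix = 3) {
  tb <- toy_body(n, pix)
  act <- tb$body * 1
  act[(tb$xc - 20)^2 + tb$yc^2 <= 10^2] <- 3
  mu <- tb$body * 0.096
  mu[(tb$xc + 20)^2 + tb$yc^2 <= 12^2] <- 0.14
  list(activity = act, mu = mu, body = tb$body)
}

# noiseless (expectation-valued) sinogram for fixed-point style tests
noiseless_sino <- function(activity, mu, sys) {
  af <- attenuation_factors(mu, sys)
  pt <- forward_project(activity, sys, tof = TRUE)
  Tn <- sys$geom$n_tof
  E <- array(as.vector(pt) * rep(as.vector(af), times = Tn), dim(pt))
  if (length(dim(E)) == 2) dim(E) <- c(dim(E), 1L)
  structure(list(counts = E, expected = E, scale = 1, background = 0,
                 geom = sys$geom), class = "sinogram")
}

# implant phantom used by the recovery experiments: hip-scale implant
# (10 mm radius core, 24 mm artifact halo) plus one soft-tissue lesion
# close to the implant and one bone lesion
implant_case <- function(seed = 11) {
  spec <- phantom_spec(
    lesion_specs = list(
      list(center = c(0, -30, 10), radius_mm = 8, contrast = 4, class = "soft"),
      list(center = c(0, 5, -45), radius_mm = 6, contrast = 4, class = "bone")),
    implant_spec = list(center = c(0, 15, 20), radius_mm = 10, hu = 3000,
                        halo_mm = 24),
    seed = seed)
  suppressWarnings(make_phantom(spec))
}

# desk-scale training configuration used wherever a trained network is needed
desk_net_config <- function() net_config(depth = 3, base_channels = 8,
                                         dropout = 0.2, patch = c(32, 32))
desk_train_config <- function(iterations, seed) {
  train_config(lr = 1e-3, iterations = iterations, seed = seed)
}

tiny_trained_model <- function() memo("tiny_model", function() {
  ds <- make_dataset(3, phantom_spec(seed = 1), seed = 21)
  bcnn_train(ds$cases[1:2], desk_net_config(), desk_train_config(40, seed = 5))
})
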
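# Volume I/O (NIfTI), sinogram persistence, run configuration and the
# end-to-end pipeline: simulate -> train -> MC-dropout inference -> priors ->
# PET simulation -> comparator reconstructions -> evaluation.

#' Write a volume to NIfTI
#'
#' Stored as float64 so a write/read round trip is bit-identical; the
#' voxel size (mm) is carried in the header pixdim.
#'
#' @param img matrix or 3-D array (slice, row, column axes).
#' @param path output path (.nii or .nii.gz).
#' @param voxel_size voxel dimensions in mm.
#' @export
write_volume <- function(img, path, voxel_size = c(1, 1, 1)) {
  v <- as_volume(img)
  attr(v, "pixdim") <- voxel_size
  nii <- RNifti::asNifti(v, datatype = "double")
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' Read a volume from NIfTI
#'
#' @param path NIfTI file path.
#' @return plain array with attribute \code{voxel_size} (mm).
#' @export
read_volume <- function(path) {
  nii <- RNifti::readNifti(path)
  out <- array(as.numeric(nii), dim(nii))
  attr(out, "voxel_size") <- RNifti::pixdim(nii)
  out
}

#' Persist / load a sinogram with its geometry
#'
#' @param sino a \code{sinogram} object.
#' @param path file path (.rds).
#' @export
save_sinogram <- function(sino, path) {
  stopifnot(inherits(sino, "sinogram"))
  saveRDS(sino, path)
  invisible(path)
}

#' @rdname save_sinogram
#' @export
load_sinogram <- function(path) {
  s <- readRDS(path)
  stopifnot(inherits(s, "sinogram"))
  s
}

default_run_config <- function() {
  list(
    seed = 1L,
    phantom = list(n_cases = 6L, grid = c(1L, 64L, 64L), voxel_mm = c(3, 3, 3),
                   noise = 0.02, split = 0.8,
                   train_with_implants = FALSE,
                   test_implant = list(center = c(0, 15, 20), radius_mm = 10,
                                       hu = 3000, halo_mm = 24),
                   lesions = list(list(center = c(0, -30, 10), radius_mm = 8,
                                       contrast = 4, class = "soft"))),
    train = list(depth = 3L, base_channels = 8L, dropout = 0.2,
                 patch = c(32L, 32L), lr = 1e-3, iterations = 400L,
                 batch_size = 4L, lambda_gdl = 0.01, lambda_ldl = 0.01,
                 weight_decay = 1e-5),
    mc = list(n_samples = 32L),
    prior = list(beta_min = 1e3, beta_max = 5e6, scaling = "minmax"),
    geometry = list(n_angles = 96L, n_radial = 128L, radial_bin_mm = 2,
                    n_tof = 11L, tof_fwhm_mm = 60, psf_fwhm_mm = 0,
                    n_subsets = 8L),
    recon = list(outer_iterations = 5L, ostr_passes_per_outer = 5L,
                 beta_smooth = 2e4, mu_max = 0.5, total_counts = 1e7,
                 background = 0, osem_iterations = 2L,
                 uniform_beta = 7e5),
    eval = list(suv_scale = 1)
  )
}

merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(user) || !is.list(defaults)) return(user)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s",
                 paste0(path, unknown, collapse = ", ")), call. = FALSE)
  for (nm in names(user))
    defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]],
                                   paste0(path, nm, "."))
  defaults
}

#' Load and validate a run configuration
#'
#' YAML (or list) configuration, schema-checked against the defaults:
#' unknown keys are rejected, missing keys fall back to the documented
#' defaults.
#'
#' @param config path to a YAML file, a list of overrides, or NULL for
#'   the defaults.
#' @return validated configuration list of class \code{run_config}.
#' @export
run_config <- function(config = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_run_config(), config)
  structure(cfg, class = "run_config")
}

write_manifest <- function(dir, stage, cfg_hash, seed, extra = list()) {
  man <- c(list(stage = stage, config_hash = cfg_hash, seed = seed,
                package_version = as.character(utils::packageVersion("upctmlaa")),
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
           extra)
  jsonlite::write_json(man, file.path(dir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run the full uncertainty-guided reconstruction pipeline
#'
#' Executes, on seeded synthetic data: phantom simulation, pseudo-CT
#' network training (implant-free cases only), Monte Carlo Dropout
#' inference on an implant test case, prior-strength map construction,
#' TOF emission simulation, the comparator reconstructions (OSEM with
#' ground-truth attenuation, OSEM with the pseudo-CT attenuation, naive
#' MLAA, uniform-beta regularized MLAA, uncertainty-weighted MLAA), and
#' the evaluation report. Every stage writes its artifacts plus a JSON
#' manifest carrying the configuration hash and seed; if a completed
#' manifest with the same hash already exists in \code{out_dir} the run
#' is skipped (idempotent re-runs).
#'
#' @param cfg a \code{\link{run_config}}.
#' @param out_dir output directory (created if needed).
#' @return (invisibly) list with the evaluation table and paths.
#' @export
run_pipeline <- function(cfg = run_config(), out_dir = tempfile("upctmlaa_run_")) {
  stopifnot(inherits(cfg, "run_config"))
  if (isTRUE(cfg$phantom$train_with_implants))
    stop(paste("configuration requests implants in the training set;",
               "the pseudo-CT network must be trained on implant-free cases",
               "so that implants remain out-of-distribution"), call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- object_hash(unclass(cfg))
  final_man <- file.path(out_dir, "evaluate_manifest.json")
  if (file.exists(final_man)) {
    man <- jsonlite::read_json(final_man)
    if (identical(man$config_hash, cfg_hash)) {
      message("run with identical configuration already present; skipping")
      return(invisible(list(out_dir = out_dir, skipped = TRUE)))
    }
  }
  seed <- cfg$seed
  vox <- cfg$phantom$voxel_mm

  ## 1. phantoms
  base <- phantom_spec(grid_shape = cfg$phantom$grid, voxel_size = vox,
                       lesion_specs = cfg$phantom$lesions,
                       noise = cfg$phantom$noise, seed = derive_seed(seed, "base"))
  ds <- make_dataset(cfg$phantom$n_cases, base, seed = derive_seed(seed, "data"),
                     split = cfg$phantom$split)
  ispec <- phantom_spec(grid_shape = cfg$phantom$grid, voxel_size = vox,
                        lesion_specs = cfg$phantom$lesions,
                        implant_spec = cfg$phantom$test_implant,
                        noise = cfg$phantom$noise,
                        seed = derive_seed(seed, "test"))
  icase <- make_phantom(ispec)
  write_volume(icase$ct, file.path(out_dir, "test_ct.nii.gz"), vox)
  write_volume(icase$activity, file.path(out_dir, "test_activity.nii.gz"), vox)
  jsonlite::write_json(
    list(lesions = lapply(icase$lesions, function(l)
      list(class = l$class, uptake = l$uptake, n_voxels = nrow(l$voxels)))),
    file.path(out_dir, "test_lesions.json"), auto_unbox = TRUE)
  write_manifest(out_dir, "phantom", cfg_hash, seed,
                 list(n_cases = cfg$phantom$n_cases))

  ## 2. train the pseudo-CT network (implant-free policy enforced)
  ncfg <- net_config(depth = cfg$train$depth,
                     base_channels = cfg$train$base_channels,
                     dropout = cfg$train$dropout, patch = cfg$train$patch)
  tcfg <- train_config(lambda_gdl = cfg$train$lambda_gdl,
                       lambda_ldl = cfg$train$lambda_ldl, lr = cfg$train$lr,
                       weight_decay = cfg$train$weight_decay,
                       batch_size = cfg$train$batch_size,
                       iterations = cfg$train$iterations,
                       seed = derive_seed(seed, "train"))
  model <- bcnn_train(ds, ncfg, tcfg)
  saveRDS(model, file.path(out_dir, "bcnn_model.rds"))
  write_manifest(out_dir, "train", cfg_hash, seed,
                 list(final_loss = model$history[length(model$history)]))

  ## 3. Monte Carlo Dropout inference on the implant case
  mc <- mc_dropout_infer(model, icase$mr,
                         mc_config(cfg$mc$n_samples, derive_seed(seed, "mc")))
  write_volume(mc$pct, file.path(out_dir, "pct.nii.gz"), vox)
  write_volume(mc$variance, file.path(out_dir, "variance.nii.gz"), vox)
  write_manifest(out_dir, "mc", cfg_hash, seed)

  ## 4. priors: body mask, attenuation prior, beta map
  body <- body_mask(mc$pct)
  mu_mr <- hu_to_mu(mc$pct)
  w <- variance_to_weight(mc$variance)
  betamap <- weight_to_beta(w, body, cfg$prior$beta_min, cfg$prior$beta_max,
                            cfg$prior$scaling)
  write_volume(betamap, file.path(out_dir, "betamap.nii.gz"), vox)
  write_volume(mu_mr, file.path(out_dir, "mu_mr.nii.gz"), vox)
  write_manifest(out_dir, "prior", cfg_hash, seed)

  ## 5. emission simulation on the ground truth (single axial plane)
  geo <- cfg$geometry
  geom <- scanner_geometry(geo$n_angles, geo$n_radial, geo$radial_bin_mm,
                           geo$n_tof, geo$tof_fwhm_mm, geo$psf_fwhm_mm,
                           geo$n_subsets)
  sl <- 1L
  sys <- pet_system(geom, dim(icase$ct)[2:3], vox[2])
  mu_true <- hu_to_mu(icase$ct[sl, , ])
  sim <- simulate_emission(icase$activity[sl, , ], mu_true, sys,
                           cfg$recon$total_counts, cfg$recon$background,
                           derive_seed(seed, "emission"))
  save_sinogram(sim, file.path(out_dir, "sinogram.rds"))
  write_manifest(out_dir, "petsim", cfg_hash, seed,
                 list(counts = sum(sim$counts)))

  ## 6. reconstructions
  rc <- recon_config(cfg$recon$outer_iterations,
                     ostr_passes_per_outer = cfg$recon$ostr_passes_per_outer,
                     beta_smooth = cfg$recon$beta_smooth,
                     mu_max = cfg$recon$mu_max,
                     background = cfg$recon$background)
  body2d <- body[sl, , ]
  mu_mr2d <- mu_mr[sl, , ]
  beta2d <- betamap[sl, , ]
  recons <- list(
    ctac_osem = osem_reconstruct(sim, mu_true, sys, cfg$recon$osem_iterations,
                                 body2d, cfg$recon$background),
    bpct_osem = osem_reconstruct(sim, mu_mr2d, sys, cfg$recon$osem_iterations,
                                 body2d, cfg$recon$background))
  mlaa_naive <- mlaa_run(sim, sys, "naive", rc, body2d)
  mlaa_reg <- mlaa_run(sim, sys, "regularized", rc, body2d,
                       mu_mr = mu_mr2d, beta = cfg$recon$uniform_beta)
  mlaa_upct <- mlaa_run(sim, sys, "upct", rc, body2d,
                        betamap = beta2d, mu_mr = mu_mr2d)
  recons$mlaa_naive <- mlaa_naive$lambda
  recons$mlaa_reg <- mlaa_reg$lambda
  recons$upct_mlaa <- mlaa_upct$lambda
  mus <- list(ctac_osem = mu_true, bpct_osem = mu_mr2d,
              mlaa_naive = mlaa_naive$mu, mlaa_reg = mlaa_reg$mu,
              upct_mlaa = mlaa_upct$mu)
  for (nm in names(recons))
    write_volume(recons[[nm]], file.path(out_dir, paste0("lambda_", nm, ".nii.gz")), vox)
  for (nm in names(mus))
    write_volume(mus[[nm]], file.path(out_dir, paste0("mu_", nm, ".nii.gz")), vox)
  jsonlite::write_json(list(upct = mlaa_upct$trace, naive = mlaa_naive$trace,
                            regularized = mlaa_reg$trace),
                       file.path(out_dir, "objective_trace.json"), digits = NA)
  write_manifest(out_dir, "reconstruct", cfg_hash, seed)

  ## 7. evaluation
  masks <- eval_masks(icase$ct[sl, , ], mu_true)
  bone_mask <- icase$labels == TISSUE_CLASSES["bone"]
  rows <- list()
  for (nm in names(mus)) {
    st <- masked_error_stats(mus[[nm]], mu_true, masks$mu_eval)
    rows[[length(rows) + 1L]] <-
      data.frame(method = nm, metric = "mu_rmse_cm1", value = st$rmse)
  }
  ref_lambda <- recons$ctac_osem
  for (li in seq_along(icase$lesions)) {
    les <- icase$lesions[[li]]
    les2d <- list(voxels = les$voxels)
    cl <- classify_lesion(les, bone_mask, icase$implant_mask, vox)
    ref <- suvmax(ref_lambda, list(voxels = les$voxels[, 2:3, drop = FALSE]),
                  cfg$eval$suv_scale)
    for (nm in names(recons)) {
      sv <- suvmax(recons[[nm]], list(voxels = les$voxels[, 2:3, drop = FALSE]),
                   cfg$eval$suv_scale)
      rows[[length(rows) + 1L]] <-
        data.frame(method = nm,
                   metric = sprintf("lesion%d_%s_%s_suvmax_bias", li,
                                    cl$tissue, cl$plane),
                   value = sv / ref - 1)
    }
  }
  report <- do.call(rbind, rows)
  write.csv(report, file.path(out_dir, "evaluation.csv"), row.names = FALSE)
  write_manifest(out_dir, "evaluate", cfg_hash, seed)
  invisible(list(out_dir = out_dir, report = report, recons = recons,
                 mus = mus, mc = mc, case = icase, model = model,
                 betamap = betamap, body = body, sim = sim, sys = sys,
                 mu_true = mu_true))
}
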
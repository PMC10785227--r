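# Seeded pelvis-like numerical phantoms: paired 3-channel pseudo-MR volumes
# (in-phase / fat-fraction / water-fraction analogues), ground-truth CT in HU,
# activity with lesions, tissue label map, and optional metal-implant cases
# reproducing the MR-signal-void / CT-high-HU discrepancy that motivates
# emission-based attenuation recovery.

TISSUE_CLASSES <- c(air = 0L, fat = 1L, soft = 2L, bone = 3L, implant = 4L)

# Per-class generative tables. HU jitter is Gaussian, truncated to the
# class-plausible range; uptake is relative to soft tissue = 1.
CLASS_HU <- list(
  air  = c(mean = -1000, sd = 0,   lo = -1000, hi = -1000),
  fat  = c(mean = -100,  sd = 15,  lo = -150,  hi = -50),
  soft = c(mean = 40,    sd = 15,  lo = -20,   hi = 100),
  bone = c(mean = 950,   sd = 120, lo = 700,   hi = 1200)
)
CLASS_UPTAKE <- c(air = 0, fat = 0.25, soft = 1.0, bone = 0.5, implant = 0)
# MR channel signal per class: in-phase, fat fraction, water fraction.
CLASS_MR <- rbind(
  air     = c(0.00, 0.00, 0.00),
  fat     = c(0.90, 0.90, 0.10),
  soft    = c(0.85, 0.08, 0.90),
  bone    = c(0.15, 0.05, 0.05),
  implant = c(0.00, 0.00, 0.00)
)

#' Specification of a synthetic pelvis-like phantom
#'
#' Geometry is defined by ellipses painted in order (later entries
#' overwrite earlier ones) on a grid with axes (slice, row, column) and
#' voxel size in mm. The default layout is a fat-rimmed soft-tissue body
#' with two cortical-bone structures. Lesions are spherical uptake
#' multipliers; an optional implant adds a high-HU core with a radial
#' streak pattern in CT and a signal void (halo) in all MR channels.
#'
#' @param grid_shape voxels per axis (slice, row, column); in-plane axes
#'   must be at least 32.
#' @param voxel_size mm per axis.
#' @param organ_ellipses list of lists with fields \code{center} (mm,
#'   relative to grid centre), \code{semi_axes} (mm) and \code{class}.
#' @param lesion_specs list of lists with fields \code{center} (mm),
#'   \code{radius_mm}, \code{contrast} (> 1) and \code{class}
#'   ("bone"/"soft").
#' @param implant_spec optional list with fields \code{center} (mm),
#'   \code{radius_mm}, \code{hu} (> 1000) and \code{halo_mm}
#'   (> radius_mm).
#' @param noise MR channel noise standard deviation as a fraction of the
#'   tissue signal.
#' @param noise_floor additive magnitude-noise floor on the MR channels
#'   (MR magnitude images are noisy even where there is no signal, so
#'   voids are never exactly zero).
#' @param seed integer seed; the full case is bit-reproducible for a
#'   fixed seed.
#' @return object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(grid_shape = c(1, 64, 64),
                         voxel_size = c(3, 3, 3),
                         organ_ellipses = default_pelvis_organs(),
                         lesion_specs = list(),
                         implant_spec = NULL,
                         noise = 0.02,
                         noise_floor = 0.01,
                         seed = 1L) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 1),
            all(grid_shape[2:3] >= 32), length(voxel_size) == 3,
            all(voxel_size > 0))
  for (l in lesion_specs) {
    if (l$contrast <= 1) stop("lesion contrast multiplier must exceed 1", call. = FALSE)
    if (!l$class %in% c("bone", "soft")) stop("lesion class must be bone or soft", call. = FALSE)
  }
  if (!is.null(implant_spec)) {
    if (implant_spec$hu <= 1000) stop("implant HU must exceed 1000", call. = FALSE)
    if (implant_spec$halo_mm <= implant_spec$radius_mm)
      stop("implant halo must exceed the implant radius", call. = FALSE)
  }
  half_fov <- grid_shape[2:3] * voxel_size[2:3] / 2
  for (e in organ_ellipses) {
    if (any(abs(e$center[2:3]) + e$semi_axes[2:3] > half_fov))
      stop("organ ellipse extends outside the grid", call. = FALSE)
  }
  structure(list(grid_shape = as.integer(grid_shape), voxel_size = voxel_size,
                 organ_ellipses = organ_ellipses, lesion_specs = lesion_specs,
                 implant_spec = implant_spec, noise = noise,
                 noise_floor = noise_floor,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default pelvis-like organ layout
#'
#' A fat outer body ellipse, a soft-tissue interior, and two lateral
#' cortical-bone structures, sized for a 192 mm in-plane field of view.
#' @export
default_pelvis_organs <- function() {
  list(
    list(center = c(0, 0, 0),  semi_axes = c(Inf, 70, 85), class = "fat"),
    list(center = c(0, 0, 0),  semi_axes = c(Inf, 60, 74), class = "soft"),
    list(center = c(0, 5, -45), semi_axes = c(Inf, 14, 12), class = "bone"),
    list(center = c(0, 5, 45),  semi_axes = c(Inf, 14, 12), class = "bone")
  )
}

# Physical coordinates (mm) of voxel centres, axes (slice,row,col), origin at
# the grid centre.
grid_coords <- function(grid_shape, voxel_size) {
  lapply(1:3, function(ax) {
    (seq_len(grid_shape[ax]) - (grid_shape[ax] + 1) / 2) * voxel_size[ax]
  })
}

ellipsoid_mask <- function(grid_shape, voxel_size, center, semi_axes) {
  co <- grid_coords(grid_shape, voxel_size)
  q <- array(0, grid_shape)
  for (ax in 1:3) {
    if (is.finite(semi_axes[ax])) {
      d <- (co[[ax]] - center[ax]) / semi_axes[ax]
      perm <- c(ax, setdiff(1:3, ax))
      q <- q + aperm(array(d^2, grid_shape[perm]), order(perm))
    }
  }
  q <= 1
}

sphere_voxels <- function(grid_shape, voxel_size, center, radius_mm) {
  m <- ellipsoid_mask(grid_shape, voxel_size, center, rep(radius_mm, 3))
  which(m, arr.ind = TRUE)
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  pmin(pmax(x, lo), hi)
}

#' Generate one synthetic phantom case
#'
#' Deterministic for a fixed seed. Tissue-class HU values are drawn from
#' truncated Gaussians (air exactly -1000 HU); activity follows the
#' per-class uptake table with lesion multipliers applied; MR channels are
#' computed from class composition plus Gaussian noise scaled by the
#' class signal and clamped to [0, 1]. If an implant is specified the
#' metal artifact (high-HU core, streaks, MR signal void) is applied via
#' \code{\link{apply_metal_artifact}}.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return object of class \code{phantom_case} with fields \code{mr}
#'   (array slice x row x col x 3), \code{ct}, \code{activity},
#'   \code{labels}, \code{lesions}, \code{implant_mask},
#'   \code{halo_mask}, \code{body_truth}, \code{voxel_size}, \code{spec}.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  gs <- spec$grid_shape
  labels <- array(TISSUE_CLASSES["air"], gs)
  for (e in spec$organ_ellipses) {
    m <- ellipsoid_mask(gs, spec$voxel_size, e$center, e$semi_axes)
    labels[m] <- TISSUE_CLASSES[e$class]
  }
  ct <- array(-1000, gs)
  for (cl in c("fat", "soft", "bone")) {
    idx <- which(labels == TISSUE_CLASSES[cl])
    if (length(idx)) {
      p <- CLASS_HU[[cl]]
      ct[idx] <- rtrunc_norm(length(idx), p["mean"], p["sd"], p["lo"], p["hi"])
    }
  }
  activity <- array(0, gs)
  for (cl in names(CLASS_UPTAKE)) {
    idx <- which(labels == TISSUE_CLASSES[cl])
    if (length(idx)) activity[idx] <- CLASS_UPTAKE[cl]
  }
  lesions <- list()
  for (l in spec$lesion_specs) {
    vox <- sphere_voxels(gs, spec$voxel_size, l$center, l$radius_mm)
    inside <- labels[vox] != TISSUE_CLASSES["air"]
    vox <- vox[inside, , drop = FALSE]
    if (nrow(vox) == 0L) stop("lesion lies outside the body", call. = FALSE)
    if (!is.null(spec$implant_spec)) {
      core <- sphere_voxels(gs, spec$voxel_size, spec$implant_spec$center,
                            spec$implant_spec$radius_mm)
      if (nrow(merge(as.data.frame(vox), as.data.frame(core))) > 0)
        stop("lesion overlaps the implant; adjust the spec", call. = FALSE)
    }
    activity[vox] <- activity[vox] * l$contrast
    lesions[[length(lesions) + 1L]] <-
      list(voxels = vox, class = l$class, uptake = l$contrast)
  }
  mr <- array(0, c(gs, 3L))
  for (ch in 1:3) {
    base <- array(CLASS_MR[labels + 1L, ch], gs)
    noisy <- base + rnorm(length(base), 0, spec$noise) * base +
      abs(rnorm(length(base), 0, spec$noise_floor))   # magnitude noise floor
    mr[, , , ch] <- pmin(pmax(noisy, 0), 1)
  }
  case <- structure(list(mr = mr, ct = ct, activity = activity,
                         labels = labels, lesions = lesions,
                         implant_mask = array(FALSE, gs),
                         halo_mask = array(FALSE, gs),
                         body_truth = labels != TISSUE_CLASSES["air"],
                         voxel_size = spec$voxel_size, spec = spec),
                    class = "phantom_case")
  if (!is.null(spec$implant_spec)) case <- apply_metal_artifact(case, spec)
  case
}

#' Apply a metal-implant artifact to a phantom case
#'
#' Attenuates all MR channels to the magnitude-noise floor inside the
#' artifact halo (the signal void; values stay below 0.05), writes the
#' high-HU implant core into CT and the label map, and
#' adds a deterministic seeded radial-spoke streak perturbation to CT
#' confined to the halo radius. Ground-truth activity is unchanged. A
#' halo extending beyond the body is clipped with a warning.
#'
#' @param case a \code{\link{make_phantom}} case.
#' @param spec the phantom spec carrying \code{implant_spec}.
#' @return the modified \code{phantom_case}.
#' @export
apply_metal_artifact <- function(case, spec) {
  imp <- spec$implant_spec
  if (is.null(imp)) stop("implant_spec is absent", call. = FALSE)
  set.seed(derive_seed(spec$seed, "implant"))
  gs <- spec$grid_shape
  co <- grid_coords(gs, spec$voxel_size)
  # in-plane distance from the implant axis, per slice within the core extent
  r2 <- outer((co[[2]] - imp$center[2])^2, (co[[3]] - imp$center[3])^2, `+`)
  r <- sqrt(r2)
  theta <- atan2(outer(co[[2]] - imp$center[2], rep(1, gs[3])),
                 outer(rep(1, gs[2]), co[[3]] - imp$center[3]))
  slice_in <- abs(co[[1]] - imp$center[1]) <= imp$halo_mm | gs[1] == 1L
  core2d <- r <= imp$radius_mm
  halo2d <- r <= imp$halo_mm
  phase <- runif(1, 0, 2 * pi)
  n_spokes <- 8
  tau <- (imp$halo_mm - imp$radius_mm) / 2
  streak2d <- 400 * cos(n_spokes * theta + phase) *
    exp(-(r - imp$radius_mm) / tau)
  clipped <- 0L
  for (s in which(slice_in)) {
    core_s <- core2d & abs(co[[1]][s] - imp$center[1]) <= imp$radius_mm |
      (gs[1] == 1L & core2d)
    body_s <- case$body_truth[s, , ]
    halo_s <- halo2d
    clipped <- clipped + sum(halo_s & !body_s)
    halo_s <- halo_s & body_s
    ct_s <- case$ct[s, , ]
    ring <- halo_s & !core_s
    ct_s[ring] <- pmin(pmax(ct_s[ring] + streak2d[ring], -1000), 2000)
    ct_s[core_s] <- imp$hu + abs(rnorm(sum(core_s), 0, 50))
    case$ct[s, , ] <- ct_s
    lab_s <- case$labels[s, , ]
    lab_s[core_s] <- TISSUE_CLASSES["implant"]
    case$labels[s, , ] <- lab_s
    case$implant_mask[s, , ] <- case$implant_mask[s, , ] | core_s
    case$halo_mask[s, , ] <- case$halo_mask[s, , ] | halo_s
    # signal void: attenuated to the magnitude-noise floor, never exactly zero
    for (ch in 1:3)
      case$mr[s, , , ch][halo_s] <-
        pmin(abs(rnorm(sum(halo_s), 0, spec$noise_floor)), 0.049)
    act_s <- case$activity[s, , ]
    act_s[core_s] <- 0
    case$activity[s, , ] <- act_s
  }
  if (clipped > 0)
    warning(sprintf("implant halo clipped at the body boundary (%d voxels)", clipped))
  case
}

#' Validate the structural invariants of a phantom case
#'
#' Checks grid consistency, the air/implant HU anchors, MR range and the
#' signal void inside the artifact halo. Returns \code{TRUE} invisibly or
#' stops with a diagnostic.
#' @param case a \code{phantom_case}.
#' @export
check_phantom_case <- function(case) {
  gs <- dim(case$ct)
  stopifnot(identical(dim(case$activity), gs),
            identical(dim(case$labels), gs),
            identical(dim(case$mr)[1:3], gs))
  if (any(case$ct[case$labels == TISSUE_CLASSES["air"]] > -900))
    stop("air voxels must be at most -900 HU")
  if (any(case$implant_mask)) {
    floor_hu <- case$spec$implant_spec$hu
    if (min(case$ct[case$implant_mask]) < floor_hu)
      stop("implant voxels below the implant HU floor")
    if (any(case$mr[, , , 1][case$halo_mask] > 0.05))
      stop("MR signal not void inside the artifact halo")
  }
  if (min(case$mr) < 0 || max(case$mr) > 1) stop("MR channels outside [0,1]")
  for (l in case$lesions) if (nrow(l$voxels) == 0L) stop("empty lesion ROI")
  invisible(TRUE)
}

#' @export
print.phantom_case <- function(x, ...) {
  gs <- dim(x$ct)
  cat(sprintf("phantom case %d x %d x %d (%.1f mm voxels), %d lesion(s)%s\n",
              gs[1], gs[2], gs[3], x$voxel_size[2], length(x$lesions),
              if (any(x$implant_mask)) ", metal implant" else ""))
  invisible(x)
}

#' Generate a jittered dataset of phantom cases with a train/val split
#'
#' Case-to-case variability comes from seeded jitter of the organ-ellipse
#' centres and semi-axes plus fresh within-class HU/MR noise. Datasets
#' are implant-free by default, matching the training policy of fitting
#' the pseudo-CT network only on implant-free anatomy.
#'
#' @param n_cases number of cases (>= 2).
#' @param base_spec template \code{\link{phantom_spec}}.
#' @param seed dataset seed.
#' @param split training fraction (by case order).
#' @param center_jitter_mm,axis_jitter_frac geometry jitter rules.
#' @param include_implant keep the template implant in every case
#'   (default \code{FALSE}).
#' @return list with \code{cases}, \code{train_idx}, \code{val_idx}.
#' @export
make_dataset <- function(n_cases, base_spec, seed = 1L, split = 0.8,
                         center_jitter_mm = 4, axis_jitter_frac = 0.08,
                         include_implant = FALSE) {
  stopifnot(n_cases >= 2)
  cases <- vector("list", n_cases)
  for (i in seq_len(n_cases)) {
    si <- base_spec
    si$seed <- derive_seed(seed, "case", i)
    set.seed(derive_seed(seed, "jitter", i))
    for (k in seq_along(si$organ_ellipses)) {
      e <- si$organ_ellipses[[k]]
      e$center[2:3] <- e$center[2:3] + runif(2, -center_jitter_mm, center_jitter_mm)
      e$semi_axes[2:3] <- e$semi_axes[2:3] *
        (1 + runif(2, -axis_jitter_frac, axis_jitter_frac))
      si$organ_ellipses[[k]] <- e
    }
    if (!include_implant) si$implant_spec <- NULL
    cases[[i]] <- make_phantom(si)
  }
  n_train <- max(1L, min(n_cases - 1L, round(split * n_cases)))
  list(cases = cases, train_idx = seq_len(n_train),
       val_idx = seq.int(n_train + 1L, n_cases))
}
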
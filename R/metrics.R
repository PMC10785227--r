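#' Masked error statistics between two images
#'
#' Computes the signed-error mean \eqn{\mu}, population standard deviation
#' \eqn{\sigma} (divisor \eqn{n}), mean absolute error and RMSE of
#' \code{est - ref} over the voxels selected by \code{mask}. With the
#' population standard deviation the decomposition
#' \eqn{RMSE^2 = \mu^2 + \sigma^2} holds exactly.
#'
#' @param est,ref images on one grid.
#' @param mask logical mask selecting evaluated voxels.
#' @return object of class \code{error_stats} with fields \code{mean_error},
#'   \code{sd_error}, \code{mae}, \code{rmse}, \code{n_voxels}.
#' @export
masked_error_stats <- function(est, ref, mask) {
  stopifnot_grid(est, ref, mask)
  err <- (est - ref)[mask]
  n <- length(err)
  if (n == 0L) stop("empty evaluation mask", call. = FALSE)
  m <- mean(err)
  s <- sqrt(mean((err - m)^2))
  structure(list(mean_error = m,
                 sd_error = s,
                 mae = mean(abs(err)),
                 rmse = sqrt(mean(err^2)),
                 n_voxels = n),
            class = "error_stats")
}

#' @export
print.error_stats <- function(x, ...) {
  cat(sprintf("error stats over %d voxels: RMSE %.4g (mu %.4g +/- sigma %.4g), MAE %.4g\n",
              x$n_voxels, x$rmse, x$mean_error, x$sd_error, x$mae))
  invisible(x)
}

lesion_boundary <- function(lesion, grid_dim) {
  inside <- array(FALSE, grid_dim)
  inside[lesion$voxels] <- TRUE
  interior <- erode_ball1(inside)
  b <- which(inside & !interior, arr.ind = TRUE)
  if (nrow(b) == 0L) b <- which(inside, arr.ind = TRUE)
  b
}

#' Classify a lesion by tissue context and implant plane relation
#'
#' A lesion counts as a bone lesion if any of its voxels lie inside the
#' bone mask or any boundary voxel lies within 10 mm (Euclidean, in
#' physical units) of a bone voxel; otherwise it is a soft-tissue lesion.
#' A lesion is in-plane with the implant when its axial-slice range
#' intersects the slice range occupied by the implant mask, out-of-plane
#' otherwise (and always out-of-plane when no implant is present).
#'
#' @param lesion lesion ROI: list with integer voxel-index matrix
#'   \code{voxels} (columns slice, row, column).
#' @param bone_mask logical bone mask.
#' @param implant_mask logical implant mask, or \code{NULL}.
#' @param voxel_size voxel dimensions in mm, length 3 (slice, row, column).
#' @param bone_margin_mm proximity rule for bone lesions (default 10 mm).
#' @return list with elements \code{tissue} ("bone"/"soft") and
#'   \code{plane} ("in_plane"/"out_plane").
#' @export
classify_lesion <- function(lesion, bone_mask, implant_mask = NULL,
                            voxel_size = c(1, 1, 1), bone_margin_mm = 10) {
  if (is.null(lesion$voxels) || nrow(lesion$voxels) == 0L)
    stop("empty lesion", call. = FALSE)
  bone_mask <- as_volume(bone_mask)
  vox <- lesion$voxels
  inside_bone <- any(bone_mask[vox])
  if (inside_bone) {
    tissue <- "bone"
  } else {
    bone_idx <- which(bone_mask, arr.ind = TRUE)
    if (nrow(bone_idx) == 0L) {
      tissue <- "soft"
    } else {
      b <- lesion_boundary(lesion, dim(bone_mask))
      bmm <- sweep(b, 2, voxel_size, `*`)
      kmm <- sweep(bone_idx, 2, voxel_size, `*`)
      # min distance boundary -> bone, brute force in mm
      dmin <- Inf
      for (i in seq_len(nrow(bmm))) {
        d2 <- (kmm[, 1] - bmm[i, 1])^2 + (kmm[, 2] - bmm[i, 2])^2 +
          (kmm[, 3] - bmm[i, 3])^2
        dmin <- min(dmin, sqrt(min(d2)))
        if (dmin == 0) break
      }
      tissue <- if (dmin <= bone_margin_mm) "bone" else "soft"
    }
  }
  plane <- "out_plane"
  if (!is.null(implant_mask) && any(implant_mask)) {
    imp_slices <- range(which(apply(as_volume(implant_mask), 1, any)))
    les_slices <- range(vox[, 1])
    if (les_slices[1] <= imp_slices[2] && imp_slices[1] <= les_slices[2])
      plane <- "in_plane"
  }
  list(tissue = tissue, plane = plane)
}

#' Maximum standardized uptake over a lesion
#'
#' On phantoms no injected dose or body weight exists, so \code{suv_scale}
#' is a configured constant; reported biases are ratios and the scale
#' cancels.
#'
#' @param pet activity image.
#' @param lesion lesion ROI (list with voxel-index matrix \code{voxels}).
#' @param suv_scale multiplicative SUV calibration constant.
#' @return SUVmax (scalar).
#' @export
suvmax <- function(pet, lesion, suv_scale = 1) {
  if (is.null(lesion$voxels) || nrow(lesion$voxels) == 0L)
    stop("empty lesion", call. = FALSE)
  vox <- lesion$voxels
  if (ncol(vox) != length(dim(pet))) pet <- as_volume(pet)
  max(pet[vox]) * suv_scale
}

#' Mean standardized uptake over a lesion
#' @inheritParams suvmax
#' @export
suvmean <- function(pet, lesion, suv_scale = 1) {
  if (is.null(lesion$voxels) || nrow(lesion$voxels) == 0L)
    stop("empty lesion", call. = FALSE)
  vox <- lesion$voxels
  if (ncol(vox) != length(dim(pet))) pet <- as_volume(pet)
  mean(pet[vox]) * suv_scale
}

#' Two-sided Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped before ranking and midranks are used for
#' ties. For n <= 25 retained pairs the exact null distribution of the
#' positive rank sum is computed over all 2^n sign assignments (via the
#' rank-sum recursion, with ranks doubled so midranks stay integral);
#' above that a normal approximation with tie correction and continuity
#' correction is used. If every difference is zero the test is degenerate
#' and p = 1 by convention.
#'
#' @param a,b paired numeric vectors of equal length.
#' @return two-sided p-value.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 1)
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(1.0)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= 25L) {
    r2 <- as.integer(round(2 * r))
    tot <- sum(r2)
    # distribution of 2*W over sign assignments: polynomial product
    f <- c(1, rep(0, tot))
    for (rk in r2) {
      g <- f
      g[(rk + 1):(tot + 1)] <- g[(rk + 1):(tot + 1)] + f[1:(tot + 1 - rk)]
      f <- g
    }
    w2 <- as.integer(round(2 * W))
    total <- 2^n
    p_ge <- sum(f[(w2 + 1):(tot + 1)]) / total
    p_le <- sum(f[1:(w2 + 1)]) / total
    return(min(1, 2 * min(p_ge, p_le)))
  }
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (W - mu - 0.5 * sign(W - mu)) / sqrt(sig2)
  min(1, 2 * pnorm(-abs(z)))
}
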
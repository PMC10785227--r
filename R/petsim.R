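# Toy 2-D parallel-beam TOF PET system model. Forward and back projection are
# one explicit sparse matrix and its transpose, so the pair is an exactly
# matched adjoint by construction -- the property the joint-estimation update
# derivations assume. Path lengths are in cm so attenuation maps in cm^-1 need
# no unit conversion.

#' Scanner geometry for the toy TOF system
#'
#' @param n_angles number of projection angles over 180 degrees.
#' @param n_radial number of radial bins.
#' @param radial_bin_mm radial bin width in mm.
#' @param n_tof number of TOF bins (odd; 1 disables TOF weighting).
#' @param tof_fwhm_mm FWHM of the Gaussian TOF localization kernel in mm.
#' @param psf_fwhm_mm optional isotropic Gaussian PSF FWHM in mm (0 = off).
#' @param n_subsets ordered-subsets count; must divide \code{n_angles}.
#' @return object of class \code{scanner_geometry}.
#' @export
scanner_geometry <- function(n_angles = 96, n_radial = 128, radial_bin_mm = 2,
                             n_tof = 11, tof_fwhm_mm = 60, psf_fwhm_mm = 0,
                             n_subsets = 8) {
  stopifnot(n_angles %% n_subsets == 0, n_tof >= 1, n_tof %% 2 == 1,
            radial_bin_mm > 0, tof_fwhm_mm > 0)
  structure(list(n_angles = as.integer(n_angles),
                 n_radial = as.integer(n_radial),
                 radial_bin_mm = radial_bin_mm,
                 n_tof = as.integer(n_tof),
                 tof_fwhm_mm = tof_fwhm_mm,
                 psf_fwhm_mm = psf_fwhm_mm,
                 n_subsets = as.integer(n_subsets)),
            class = "scanner_geometry")
}

#' @export
print.scanner_geometry <- function(x, ...) {
  cat(sprintf("scanner: %d angles x %d radial (%.1f mm), %d TOF bins (FWHM %.0f mm), %d subsets\n",
              x$n_angles, x$n_radial, x$radial_bin_mm, x$n_tof, x$tof_fwhm_mm,
              x$n_subsets))
  invisible(x)
}

bit_reverse_order <- function(n) {
  # processing order of subsets; n need not be a power of two (stable fallback)
  bits <- ceiling(log2(max(n, 2)))
  idx <- 0:(n - 1)
  rev_bits <- vapply(idx, function(i) {
    r <- 0
    for (b in 0:(bits - 1)) if (bitwAnd(i, bitwShiftL(1, b)) != 0)
      r <- r + bitwShiftL(1, bits - 1 - b)
    r
  }, numeric(1))
  order(rev_bits, idx)
}

#' Build the sparse system model for an image grid
#'
#' Pixel-driven parallel-beam projector: each pixel centre projects to a
#' radial coordinate and is spread over the two nearest radial bins by
#' linear interpolation, weighted by pixel area / bin width (in cm) so
#' sinogram values approximate line integrals in cm. With TOF, each
#' pixel's contribution is further distributed over TOF bins by a
#' Gaussian kernel centred at the pixel's position along the line,
#' truncated at 3.5 sigma and renormalized to unit sum, so TOF bins
#' marginalize exactly to the non-TOF projection. The returned object
#' holds the TOF and non-TOF matrices, their per-subset row blocks
#' (interleaved angles, processed in bit-reversed order), and transposes.
#'
#' @param geom a \code{\link{scanner_geometry}}.
#' @param grid_dim image dimensions (rows, columns).
#' @param pixel_mm pixel size in mm.
#' @return object of class \code{pet_system}.
#' @export
pet_system <- function(geom, grid_dim = c(64, 64), pixel_mm = 3) {
  stopifnot(inherits(geom, "scanner_geometry"), length(grid_dim) == 2)
  nr <- grid_dim[1]; nc <- grid_dim[2]; npix <- nr * nc
  A <- geom$n_angles; R <- geom$n_radial; Tn <- geom$n_tof
  ds <- geom$radial_bin_mm
  # pixel centres (mm); pixel index p = row + nr*(col-1), column-major
  xc <- rep((seq_len(nc) - (nc + 1) / 2) * pixel_mm, each = nr)
  yc <- rep(((nr + 1) / 2 - seq_len(nr)) * pixel_mm, times = nc)
  wgeom <- pixel_mm^2 / ds / 10   # cm
  sigma <- geom$tof_fwhm_mm / (2 * sqrt(2 * log(2)))
  tof_centers <- (seq_len(Tn) - (Tn + 1) / 2) * (R * ds / Tn)
  theta <- (seq_len(A) - 1) * pi / A

  ii <- jj <- xx <- vector("list", A)       # TOF triplets
  ii0 <- jj0 <- xx0 <- vector("list", A)    # non-TOF triplets
  for (a in seq_len(A)) {
    s <- xc * cos(theta[a]) + yc * sin(theta[a])
    l <- -xc * sin(theta[a]) + yc * cos(theta[a])
    u <- s / ds + (R + 1) / 2
    i0 <- floor(u); f <- u - i0
    # two radial taps per pixel
    rad <- c(i0, i0 + 1)
    wr <- c(1 - f, f) * wgeom
    pix <- rep(seq_len(npix), 2)
    keep <- rad >= 1 & rad <= R & wr > 0
    rad <- rad[keep]; wr <- wr[keep]; pix <- pix[keep]
    ii0[[a]] <- a + A * (rad - 1)
    jj0[[a]] <- pix
    xx0[[a]] <- wr
    if (Tn > 1) {
      G <- exp(-outer(l, tof_centers, `-`)^2 / (2 * sigma^2))
      G[G < exp(-3.5^2 / 2)] <- 0
      rs <- rowSums(G)
      none <- rs == 0
      if (any(none)) {   # always keep the nearest bin
        nb <- pmin(pmax(round(l / (R * ds / Tn) + (Tn + 1) / 2), 1), Tn)
        G[cbind(which(none), nb[none])] <- 1
        rs <- rowSums(G)
      }
      G <- G / rs
      nzt <- which(G > 0, arr.ind = TRUE)
      # combine radial taps (per pixel) with TOF taps (per pixel)
      gp <- nzt[, 1]; gt <- nzt[, 2]; gw <- G[nzt]
      ord <- order(gp)
      gp <- gp[ord]; gt <- gt[ord]; gw <- gw[ord]
      cnt <- tabulate(gp, npix)
      reps <- cnt[pix]
      rad_r <- rep(rad, reps); wr_r <- rep(wr, reps); pix_r <- rep(pix, reps)
      pos <- c(0, cumsum(cnt))
      off <- sequence(reps)
      tap <- pos[pix_r] + off
      ii[[a]] <- a + A * (rad_r - 1) + A * R * (gt[tap] - 1)
      jj[[a]] <- pix_r
      xx[[a]] <- wr_r * gw[tap]
    }
  }
  A_notof <- Matrix::sparseMatrix(i = unlist(ii0), j = unlist(jj0),
                                  x = unlist(xx0), dims = c(A * R, npix))
  A_tof <- if (Tn > 1) {
    Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                         dims = c(A * R * Tn, npix))
  } else A_notof

  M <- geom$n_subsets
  sub_order <- bit_reverse_order(M)
  subsets <- lapply(seq_len(M), function(s) seq.int(s, A, by = M))
  sub <- vector("list", M)
  gamma_full <- Matrix::rowSums(A_notof)
  for (s in seq_len(M)) {
    ang <- subsets[[s]]
    rows_n <- as.vector(outer(ang, A * (seq_len(R) - 1), `+`))
    rows_t <- as.vector(outer(rows_n, A * R * (seq_len(Tn) - 1), `+`))
    An <- A_notof[rows_n, , drop = FALSE]
    At <- if (Tn > 1) A_tof[rows_t, , drop = FALSE] else An
    sub[[s]] <- list(angles = ang, rows_notof = rows_n, rows_tof = rows_t,
                     An = An, At = At,
                     Ant = Matrix::t(An), Att = if (Tn > 1) Matrix::t(At) else Matrix::t(An))
  }
  structure(list(geom = geom, grid_dim = grid_dim, pixel_mm = pixel_mm,
                 A_tof = A_tof, A_notof = A_notof,
                 At_t = Matrix::t(A_tof), An_t = Matrix::t(A_notof),
                 subsets = subsets, sub = sub, sub_order = sub_order,
                 gamma = gamma_full),
            class = "pet_system")
}

#' @export
print.pet_system <- function(x, ...) {
  cat(sprintf("pet_system: %d x %d grid (%.1f mm), %s; nnz(TOF) = %d\n",
              x$grid_dim[1], x$grid_dim[2], x$pixel_mm,
              format(x$geom), length(x$A_tof@x)))
  invisible(x)
}

#' @export
format.scanner_geometry <- function(x, ...) {
  sprintf("%d angles x %d radial x %d TOF", x$n_angles, x$n_radial, x$n_tof)
}

psf_kernel <- function(fwhm_mm, pixel_mm) {
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / pixel_mm
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-half:half)^2 / (2 * sigma^2))
  k / sum(k)
}

# separable symmetric zero-padded blur (self-adjoint)
psf_blur <- function(img, fwhm_mm, pixel_mm) {
  if (fwhm_mm <= 0) return(img)
  k <- psf_kernel(fwhm_mm, pixel_mm)
  half <- (length(k) - 1) / 2
  blur1 <- function(m) {
    out <- m * k[half + 1]
    for (o in seq_len(half)) {
      nrm <- nrow(m)
      up <- rbind(m[-seq_len(o), , drop = FALSE], matrix(0, o, ncol(m)))
      dn <- rbind(matrix(0, o, ncol(m)), m[seq_len(nrm - o), , drop = FALSE])
      out <- out + k[half + 1 + o] * (up + dn)
    }
    out
  }
  t(blur1(t(blur1(img))))
}

img_vec <- function(img, sys) {
  if (!identical(dim(img), as.integer(sys$grid_dim)) &&
      !identical(dim(img), sys$grid_dim))
    stop("image does not match the system grid", call. = FALSE)
  as.vector(img)
}

#' Forward projection
#'
#' Line-integral model (lengths in cm). With \code{tof = TRUE} each line
#' integral is distributed across TOF bins by the normalized Gaussian
#' kernel centred at the emission position along the line.
#'
#' @param img image matrix on the system grid (non-negative for activity).
#' @param sys a \code{\link{pet_system}}.
#' @param tof distribute over TOF bins?
#' @return sinogram array (angle, radial) or (angle, radial, tof).
#' @export
forward_project <- function(img, sys, tof = TRUE) {
  if (sys$geom$psf_fwhm_mm > 0) img <- psf_blur(img, sys$geom$psf_fwhm_mm, sys$pixel_mm)
  x <- img_vec(img, sys)
  A <- sys$geom$n_angles; R <- sys$geom$n_radial; Tn <- sys$geom$n_tof
  if (tof && Tn > 1) {
    array(as.numeric(sys$A_tof %*% x), c(A, R, Tn))
  } else {
    array(as.numeric(sys$A_notof %*% x), c(A, R))
  }
}

#' Back projection (exact adjoint of \code{\link{forward_project}})
#'
#' @param sino sinogram array matching the geometry (with or without a
#'   TOF axis, matching \code{tof}).
#' @param sys a \code{\link{pet_system}}.
#' @param tof was the sinogram TOF-binned?
#' @return image matrix on the system grid.
#' @export
back_project <- function(sino, sys, tof = TRUE) {
  A <- sys$geom$n_angles; R <- sys$geom$n_radial; Tn <- sys$geom$n_tof
  y <- as.vector(sino)
  M <- if (tof && Tn > 1) sys$At_t else sys$An_t
  if (length(y) != ncol(M)) stop("sinogram shape mismatch", call. = FALSE)
  img <- matrix(as.numeric(M %*% y), sys$grid_dim[1], sys$grid_dim[2])
  if (sys$geom$psf_fwhm_mm > 0) img <- psf_blur(img, sys$geom$psf_fwhm_mm, sys$pixel_mm)
  img
}

#' Attenuation survival factors from an attenuation map
#'
#' \eqn{a_i = \exp(-[P\mu]_i)} per (angle, radial) line of response, in
#' (0, 1]; broadcast across TOF bins downstream. Depends only on
#' \eqn{\mu} and the geometry.
#'
#' @param mu attenuation map in cm^-1 (non-negative).
#' @param sys a \code{\link{pet_system}}.
#' @return matrix (angle, radial) of survival probabilities.
#' @export
attenuation_factors <- function(mu, sys) {
  if (any(mu < 0)) stop("mu must be non-negative", call. = FALSE)
  exp(-forward_project(mu, sys, tof = FALSE))
}

#' Simulate a Poisson TOF emission acquisition
#'
#' The expectation is \eqn{a_i [P\lambda]_{i,t}} scaled so its total
#' equals \code{total_counts}, plus a uniform additive background
#' expectation per bin; counts are a seeded Poisson draw.
#'
#' @param activity activity image (non-negative).
#' @param mu attenuation map in cm^-1.
#' @param sys a \code{\link{pet_system}}.
#' @param total_counts target expected total true counts.
#' @param background uniform additive expectation per TOF bin.
#' @param seed integer seed.
#' @return object of class \code{sinogram}: list with \code{counts}
#'   (angle, radial, tof), \code{expected}, \code{scale} (activity-to-
#'   counts scale factor), \code{background}.
#' @export
simulate_emission <- function(activity, mu, sys, total_counts = 1e6,
                              background = 0, seed = 1L) {
  if (any(activity < 0)) stop("activity must be non-negative", call. = FALSE)
  A <- sys$geom$n_angles; R <- sys$geom$n_radial; Tn <- sys$geom$n_tof
  af <- attenuation_factors(mu, sys)
  p <- forward_project(activity, sys, tof = TRUE)
  E <- as.vector(p) * rep(as.vector(af), times = if (Tn > 1) Tn else 1)
  tot <- sum(E)
  if (tot <= 0 && total_counts > 0)
    stop("zero total expectation with positive target counts", call. = FALSE)
  scale <- if (tot > 0) total_counts / tot else 0
  E <- E * scale + background
  set.seed(seed)
  counts <- rpois(length(E), E)
  dims <- if (Tn > 1) c(A, R, Tn) else c(A, R, 1L)
  structure(list(counts = array(counts, dims),
                 expected = array(E, dims),
                 scale = scale, background = background,
                 geom = sys$geom),
            class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("sinogram %s, %.3g counts (background %.3g/bin)\n",
              paste(dim(x$counts), collapse = " x "), sum(x$counts),
              x$background))
  invisible(x)
}
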
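#' Bilinear CT-to-attenuation conversion model
#'
#' Piecewise-linear mapping from CT numbers (Hounsfield units) to linear
#' attenuation coefficients at 511 keV, anchored so that air
#' (\eqn{-1000} HU) maps to 0 cm\eqn{^{-1}}. The default coefficients are
#' the standard 120-kVp model: slope \eqn{9.6\times 10^{-5}}
#' cm\eqn{^{-1}}/HU below the soft-tissue/bone breakpoint at +47 HU (so
#' water at 0 HU maps to 0.096 cm\eqn{^{-1}}) and
#' \eqn{5.1\times 10^{-5}} cm\eqn{^{-1}}/HU above it, continuous at the
#' breakpoint.
#'
#' @param breakpoint_hu breakpoint between the two linear segments, in HU.
#' @param slope_below slope below the breakpoint (cm^-1 per HU).
#' @param slope_above slope above the breakpoint (cm^-1 per HU).
#' @return an object of class \code{bilinear_model}.
#' @export
bilinear_model <- function(breakpoint_hu = 47,
                           slope_below = 9.6e-5,
                           slope_above = 5.1e-5) {
  stopifnot(slope_below >= 0, slope_above >= 0)
  structure(list(breakpoint_hu = breakpoint_hu,
                 slope_below = slope_below,
                 slope_above = slope_above,
                 mu_at_break = slope_below * (breakpoint_hu + 1000)),
            class = "bilinear_model")
}

#' @export
print.bilinear_model <- function(x, ...) {
  cat("Bilinear HU -> mu(511 keV) model\n")
  cat(sprintf("  mu(-1000 HU) = 0; slope %.3g /HU below %g HU, %.3g /HU above\n",
              x$slope_below, x$breakpoint_hu, x$slope_above))
  cat(sprintf("  mu(0 HU, water) = %.4f cm^-1\n", x$slope_below * 1000))
  invisible(x)
}

#' Convert a CT volume in HU to a 511-keV attenuation map
#'
#' Values below \eqn{-1000} HU are clamped to \eqn{\mu = 0}; the map is
#' continuous and non-decreasing.
#'
#' @param ct CT volume in Hounsfield units (matrix or 3-D array).
#' @param model a \code{\link{bilinear_model}}.
#' @return attenuation map in cm^-1, same shape as \code{ct}.
#' @export
hu_to_mu <- function(ct, model = bilinear_model()) {
  if (any(!is.finite(ct))) stop("non-finite HU values", call. = FALSE)
  mu <- ifelse(ct <= model$breakpoint_hu,
               model$slope_below * (ct + 1000),
               model$mu_at_break + model$slope_above * (ct - model$breakpoint_hu))
  mu[mu < 0] <- 0
  if (!is.null(dim(ct))) dim(mu) <- dim(ct)
  mu
}

#' Body mask from a pseudo-CT estimate
#'
#' Thresholds the pseudo-CT at \eqn{> -400} HU, erodes the result by a
#' 1-voxel-radius ball in index space (in-plane only for single-slice
#' volumes), then fills enclosed holes on each axial slice. The mask
#' bounds reconstruction and zeroes prior weights outside the body.
#'
#' @param pct pseudo-CT volume in HU.
#' @return logical mask with attribute \code{provenance = "body"}.
#' @export
body_mask <- function(pct) {
  v <- as_volume(pct)
  m <- v > -400
  if (!any(m)) stop("no body found", call. = FALSE)
  m <- erode_ball1(m)
  if (!any(m)) stop("no body found", call. = FALSE)
  m <- fill_holes_slicewise(m)
  if (is.matrix(pct)) m <- m[1, , ]
  attr(m, "provenance") <- "body"
  m
}

#' Evaluation masks for error statistics
#'
#' Error statistics over CT-like images are restricted to voxels with
#' reference CT above \eqn{-950} HU (excluding air); attenuation-map
#' statistics to reference \eqn{\mu > 0.01} cm\eqn{^{-1}}. Both thresholds
#' are strict.
#'
#' @param ct_ref ground-truth CT in HU.
#' @param mu_ref ground-truth attenuation map in cm^-1.
#' @return list with logical masks \code{hu_eval} and \code{mu_eval}.
#' @export
eval_masks <- function(ct_ref, mu_ref) {
  stopifnot_grid(ct_ref, mu_ref)
  hu_eval <- ct_ref > -950
  mu_eval <- mu_ref > 0.01
  attr(hu_eval, "provenance") <- "hu_eval"
  attr(mu_eval, "provenance") <- "mu_eval"
  list(hu_eval = hu_eval, mu_eval = mu_eval)
}
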
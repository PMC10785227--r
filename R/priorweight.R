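#' Sigmoid transform from predictive variance to a weight map
#'
#' Maps the Monte Carlo predictive variance \eqn{\sigma^2(r)} (HU^2) to a
#' weight in (0, 1) via
#' \deqn{w(r) = \frac{1}{1 + \exp(0.1(\sigma^2(r)/1000 - 25))}}
#' so that \eqn{w = 1/2} exactly at \eqn{\sigma^2 = 25{,}000} HU^2, the
#' transition band covers in-body variances up to roughly
#' \eqn{10^5} HU^2, and the transform saturates near 0 for the very high
#' variances typical of metal-artifact regions. The constants are fixed
#' calibration values, not tunables.
#'
#' @param var voxelwise predictive variance in HU^2 (array).
#' @return weight map in (0, 1), same shape.
#' @export
variance_to_weight <- function(var) {
  if (any(!is.finite(var))) stop("non-finite variance", call. = FALSE)
  if (any(var < 0)) stop("negative variance", call. = FALSE)
  # plogis is an overflow-safe logistic: w = 1/(1+exp(0.1*(var/1000 - 25)))
  w <- plogis(0.1 * (25 - var / 1000))
  if (!is.null(dim(var))) dim(w) <- dim(var)
  w
}

#' Rescale a weight map to a prior-strength (beta) map
#'
#' Affinely rescales the in-body weights so their minimum maps to
#' \code{beta_min} and their maximum to \code{beta_max} (default range
#' \eqn{10^3} to \eqn{5\times 10^6}); voxels outside the body are set to 0
#' and carry no prior. With \code{scaling = "fixed"} the map
#' \eqn{\beta = \beta_{min} + w(\beta_{max}-\beta_{min})} is used instead
#' (this never attains \eqn{\beta_{max}} since \eqn{w \le 0.9241} for
#' \eqn{\sigma^2 \ge 0}).
#'
#' A constant in-body weight map carries no contrast to rescale; it is
#' assigned \code{beta_max} everywhere inside the body with a warning.
#'
#' @param w weight map from \code{\link{variance_to_weight}}.
#' @param body logical body mask on the same grid.
#' @param beta_min,beta_max endpoints of the prior-strength range.
#' @param scaling \code{"minmax"} (default) or \code{"fixed"}.
#' @return voxelwise prior-strength map (0 outside the body).
#' @export
weight_to_beta <- function(w, body, beta_min = 1e3, beta_max = 5e6,
                           scaling = c("minmax", "fixed")) {
  scaling <- match.arg(scaling)
  stopifnot_grid(w, body)
  stopifnot(beta_min <= beta_max)
  beta <- array(0, dim(as_volume(w)))
  if (!is.null(dim(w))) dim(beta) <- dim(w)
  wb <- w[body]
  if (length(wb) == 0L) stop("empty body mask", call. = FALSE)
  if (scaling == "fixed") {
    beta[body] <- beta_min + wb * (beta_max - beta_min)
    return(beta)
  }
  rng <- range(wb)
  if (diff(rng) == 0) {
    warning("constant in-body weight map; assigning beta_max throughout the body")
    beta[body] <- beta_max
  } else {
    beta[body] <- beta_min + (wb - rng[1]) / (rng[2] - rng[1]) * (beta_max - beta_min)
  }
  beta
}
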
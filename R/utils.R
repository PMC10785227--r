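#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif rpois plogis pnorm sd
#' @importFrom methods as
#' @importFrom utils head tail write.csv
NULL

# Deterministic seed fan-out: one global seed expands to per-stage / per-case
# seeds through a small integer hash, kept below 2^31 so set.seed() accepts it.
derive_seed <- function(seed, ...) {
  parts <- c(seed, unlist(lapply(list(...), function(p) {
    if (is.character(p)) sum(utf8ToInt(p) * seq_along(utf8ToInt(p))) else as.numeric(p)
  })))
  h <- 0
  for (p in parts) h <- (h * 69069 + (as.numeric(p) %% 2147483647)) %% 2147483647
  as.integer(h)
}

# Volumes are 3-D arrays with axes (slice, row, column); a plain matrix is
# accepted everywhere and treated as a single axial slice.
as_volume <- function(x) {
  if (is.matrix(x)) array(x, dim = c(1L, nrow(x), ncol(x))) else x
}

same_grid <- function(...) {
  dims <- lapply(list(...), function(x) dim(as_volume(x)))
  all(vapply(dims, identical, logical(1), dims[[1]]))
}

stopifnot_grid <- function(...) {
  if (!same_grid(...)) stop("arrays do not share one grid", call. = FALSE)
}

# Shift a 3-D logical/numeric volume by one voxel along axis, padding with `fill`.
shift1 <- function(x, axis, dir, fill = FALSE) {
  d <- dim(x)
  out <- array(fill, d)
  idx_src <- idx_dst <- lapply(d, seq_len)
  if (d[axis] > 1L) {
    if (dir > 0) {
      idx_src[[axis]] <- 1:(d[axis] - 1L); idx_dst[[axis]] <- 2:d[axis]
    } else {
      idx_src[[axis]] <- 2:d[axis]; idx_dst[[axis]] <- 1:(d[axis] - 1L)
    }
    out <- do.call(`[<-`, c(list(out), idx_dst, list(do.call(`[`, c(list(x), idx_src)))))
  }
  out
}

# Index-space ball of radius 1 (6-neighbourhood; 4-neighbourhood on a single
# slice, where no through-plane neighbours exist).
erode_ball1 <- function(mask) {
  m <- as_volume(mask)
  axes <- if (dim(m)[1] > 1L) 1:3 else 2:3
  out <- m
  for (ax in axes) {
    out <- out & shift1(m, ax, +1, FALSE) & shift1(m, ax, -1, FALSE)
  }
  out
}

dilate_ball1 <- function(mask) {
  m <- as_volume(mask)
  axes <- if (dim(m)[1] > 1L) 1:3 else 2:3
  out <- m
  for (ax in axes) {
    out <- out | shift1(m, ax, +1, FALSE) | shift1(m, ax, -1, FALSE)
  }
  out
}

# Fill enclosed background per axial slice: background connected to the slice
# border stays background, the rest becomes foreground.
fill_holes_slicewise <- function(mask) {
  m <- as_volume(mask)
  d <- dim(m)
  for (s in seq_len(d[1])) {
    sl <- m[s, , ]
    bg <- !sl
    reach <- matrix(FALSE, d[2], d[3])
    reach[1, ] <- bg[1, ]; reach[d[2], ] <- bg[d[2], ]
    reach[, 1] <- reach[, 1] | bg[, 1]; reach[, d[3]] <- reach[, d[3]] | bg[, d[3]]
    repeat {
      grown <- reach
      grown[-1, ] <- grown[-1, ] | reach[-d[2], ]
      grown[-d[2], ] <- grown[-d[2], ] | reach[-1, ]
      grown[, -1] <- grown[, -1] | reach[, -d[3]]
      grown[, -d[3]] <- grown[, -d[3]] | reach[, -1]
      grown <- grown & bg
      if (identical(grown, reach)) break
      reach <- grown
    }
    m[s, , ] <- sl | (bg & !reach)
  }
  if (is.matrix(mask)) m[1, , ] else m
}

# FNV-1a hash of a serialised R object, reported as hex; used for run manifests.
object_hash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  h <- 2166136261
  for (b in as.integer(raw)) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", h)
}
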
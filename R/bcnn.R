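# Dropout-equipped encoder-decoder pseudo-CT regressor: composite training
# loss (L1 + gradient-difference + Laplacian-difference), seeded Adam training
# on random patches, and Monte Carlo Dropout inference yielding the
# pseudo-CT sample mean and the voxelwise predictive variance.

#' Network configuration for the pseudo-CT regressor
#'
#' Encoder-decoder with two 3x3 convolution + leaky-ReLU + dropout blocks per
#' level, 2x2 mean pooling between encoder levels, nearest-neighbour
#' upsampling with skip concatenation in the decoder, and a linear 1x1
#' output head. Dropout follows every convolution except the output
#' head. The desk-scale default is 2-D 64x64 patches, depth 3, 16 base
#' channels.
#'
#' @param depth number of resolution levels.
#' @param base_channels channels at the finest level (doubled per level).
#' @param dropout dropout rate p applied after every convolution block.
#' @param patch patch size (rows, cols); must be divisible by
#'   \code{2^(depth-1)}.
#' @param in_channels,out_channels fixed at 3 MR channels in, 1 CT out.
#' @return list of class \code{net_config}.
#' @export
net_config <- function(depth = 3, base_channels = 16, dropout = 0.2,
                       patch = c(64, 64), in_channels = 3, out_channels = 1) {
  stopifnot(depth >= 1, base_channels >= 1, dropout >= 0, dropout < 1,
            length(patch) == 2, all(patch %% 2^(depth - 1) == 0))
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 dropout = dropout, patch = as.integer(patch),
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels)),
            class = "net_config")
}

#' Training configuration
#'
#' Optimizer defaults follow the reference training protocol: Adam with
#' learning rate \eqn{10^{-5}}, \eqn{\beta_1 = 0.9},
#' \eqn{\beta_2 = 0.999}, \eqn{\epsilon = 10^{-8}}, L2 weight decay
#' \eqn{10^{-5}}, minibatch 4, loss weights
#' \eqn{\lambda_{GDL} = \lambda_{LDL} = 0.01}. The iteration count is a
#' desk-scale default; CT targets are scaled by 1/1000 internally.
#'
#' @param lambda_gdl,lambda_ldl loss weights (>= 0).
#' @param lr,beta1,beta2,eps Adam hyper-parameters.
#' @param weight_decay L2 penalty on convolution weights.
#' @param batch_size patches per iteration.
#' @param iterations training iterations.
#' @param seed RNG seed for init, patch sampling and dropout.
#' @return list of class \code{train_config}.
#' @export
train_config <- function(lambda_gdl = 0.01, lambda_ldl = 0.01, lr = 1e-5,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         weight_decay = 1e-5, batch_size = 4,
                         iterations = 2000, seed = 1L) {
  stopifnot(lambda_gdl >= 0, lambda_ldl >= 0, lr > 0, batch_size >= 1,
            iterations >= 1)
  structure(list(lambda_gdl = lambda_gdl, lambda_ldl = lambda_ldl, lr = lr,
                 beta1 = beta1, beta2 = beta2, eps = eps,
                 weight_decay = weight_decay, batch_size = as.integer(batch_size),
                 iterations = as.integer(iterations), seed = as.integer(seed)),
            class = "train_config")
}

#' Monte Carlo Dropout configuration
#'
#' @param n_samples number of stochastic forward passes N (>= 2 for a
#'   variance; the faithful configuration uses 243, the desk-scale
#'   default 32).
#' @param seed RNG seed for the dropout masks.
#' @export
mc_config <- function(n_samples = 32, seed = 1L) {
  stopifnot(n_samples >= 2)
  structure(list(n_samples = as.integer(n_samples), seed = as.integer(seed)),
            class = "mc_config")
}

axis_diff <- function(x, axis) {
  # valid-region forward difference along one axis of an n-d array
  d <- dim(x); n <- d[axis]
  if (n < 2) return(NULL)
  idx_hi <- idx_lo <- lapply(d, seq_len)
  idx_hi[[axis]] <- 2:n; idx_lo[[axis]] <- 1:(n - 1)
  do.call(`[`, c(list(x), idx_hi, list(drop = FALSE))) -
    do.call(`[`, c(list(x), idx_lo, list(drop = FALSE)))
}

axis_lap <- function(x) {
  # discrete Laplacian on the joint interior (all axes with length >= 3)
  d <- dim(x)
  axes <- which(d >= 3)
  if (length(axes) == 0) return(NULL)
  interior <- lapply(seq_along(d), function(a)
    if (a %in% axes) 2:(d[a] - 1) else seq_len(d[a]))
  ctr <- do.call(`[`, c(list(x), interior, list(drop = FALSE)))
  lap <- -2 * length(axes) * ctr
  for (a in axes) {
    up <- interior; up[[a]] <- up[[a]] + 1
    dn <- interior; dn[[a]] <- dn[[a]] - 1
    lap <- lap + do.call(`[`, c(list(x), up, list(drop = FALSE))) +
      do.call(`[`, c(list(x), dn, list(drop = FALSE)))
  }
  lap
}

#' Composite pseudo-CT training loss
#'
#' \deqn{L = \langle|y - \hat y|\rangle
#'  + \lambda_{GDL} \sum_a \langle(\nabla_a y - \nabla_a \hat y)^2\rangle
#'  + \lambda_{LDL} \langle(\Delta y - \Delta \hat y)^2\rangle}
#' with voxel-mean reduction per term, valid-region forward differences
#' for the gradients and the (2 x ndim + 1)-point interior stencil for
#' the Laplacian, so a constant offset contributes only through the L1
#' term.
#'
#' @param y,yhat same-shape numeric arrays (patches).
#' @param lambda_gdl,lambda_ldl loss weights.
#' @return scalar loss.
#' @export
composite_loss <- function(y, yhat, lambda_gdl = 0.01, lambda_ldl = 0.01) {
  if (!identical(dim(y) %||% length(y), dim(yhat) %||% length(yhat)))
    stop("shape mismatch", call. = FALSE)
  d <- y - yhat
  if (is.null(dim(d))) dim(d) <- length(d)
  loss <- mean(abs(d))
  if (lambda_gdl > 0) {
    for (a in seq_along(dim(d))) {
      g <- axis_diff(d, a)
      if (!is.null(g)) loss <- loss + lambda_gdl * mean(g^2)
    }
  }
  if (lambda_ldl > 0) {
    l <- axis_lap(d)
    if (!is.null(l)) loss <- loss + lambda_ldl * mean(l^2)
  }
  if (!is.finite(loss)) stop("non-finite loss", call. = FALSE)
  loss
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# loss + gradient wrt yhat for one 2-D patch (used by the training loop)
loss_and_grad_2d <- function(y, yhat, lg, ll) {
  d <- yhat - y
  H <- nrow(d); W <- ncol(d)
  n <- H * W
  loss <- mean(abs(d))
  grad <- sign(d) / n
  if (lg > 0) {
    if (H >= 2) {
      gv <- d[-1, , drop = FALSE] - d[-H, , drop = FALSE]
      loss <- loss + lg * mean(gv^2)
      c2 <- 2 * lg / length(gv)
      grad[-1, ] <- grad[-1, ] + c2 * gv
      grad[-H, ] <- grad[-H, ] - c2 * gv
    }
    if (W >= 2) {
      gh <- d[, -1, drop = FALSE] - d[, -W, drop = FALSE]
      loss <- loss + lg * mean(gh^2)
      c2 <- 2 * lg / length(gh)
      grad[, -1] <- grad[, -1] + c2 * gh
      grad[, -W] <- grad[, -W] - c2 * gh
    }
  }
  if (ll > 0 && H >= 3 && W >= 3) {
    ri <- 2:(H - 1); ci <- 2:(W - 1)
    lap <- d[ri + 1, ci] + d[ri - 1, ci] + d[ri, ci + 1] + d[ri, ci - 1] -
      4 * d[ri, ci]
    loss <- loss + ll * mean(lap^2)
    c2 <- 2 * ll / length(lap)
    grad[ri + 1, ci] <- grad[ri + 1, ci] + c2 * lap
    grad[ri - 1, ci] <- grad[ri - 1, ci] + c2 * lap
    grad[ri, ci + 1] <- grad[ri, ci + 1] + c2 * lap
    grad[ri, ci - 1] <- grad[ri, ci - 1] + c2 * lap
    grad[ri, ci] <- grad[ri, ci] - 4 * c2 * lap
  }
  list(loss = loss, grad = grad)
}

# Collect (input, target) axial slices from phantom cases; targets in kHU.
training_slices <- function(cases, allow_implant = FALSE) {
  xs <- list(); ys <- list()
  for (cs in cases) {
    if (!allow_implant && any(cs$implant_mask))
      stop("training cases must be implant-free (pass allow_implant = TRUE to override)",
           call. = FALSE)
    S <- dim(cs$ct)[1]
    for (s in seq_len(S)) {
      xs[[length(xs) + 1L]] <- cs$mr[s, , , ]
      ys[[length(ys) + 1L]] <- cs$ct[s, , ] / 1000
    }
  }
  list(x = xs, y = ys)
}

#' Train the pseudo-CT regressor
#'
#' Seeded Adam training on randomly sampled 2-D patches with dropout
#' active; by default only implant-free cases are accepted (the network
#' must extrapolate on implant artifacts at test time, so they are
#' excluded from training). Training aborts with a diagnostic if the
#' loss becomes non-finite.
#'
#' @param cases list of \code{phantom_case} objects (or a
#'   \code{\link{make_dataset}} result, in which case its training split
#'   is used).
#' @param net_cfg a \code{\link{net_config}}.
#' @param train_cfg a \code{\link{train_config}}.
#' @param allow_implant permit implant cases in training (default FALSE).
#' @return object of class \code{bcnn_model} with the parameters, both
#'   configs, the loss history and the training seed.
#' @export
bcnn_train <- function(cases, net_cfg = net_config(),
                       train_cfg = train_config(), allow_implant = FALSE) {
  if (!is.null(cases$cases)) cases <- cases$cases[cases$train_idx]
  if (inherits(cases, "phantom_case")) cases <- list(cases)
  stopifnot(length(cases) >= 1)
  ds <- training_slices(cases, allow_implant)
  ph <- net_cfg$patch[1]; pw <- net_cfg$patch[2]
  dims <- dim(ds$x[[1]])
  if (dims[1] < ph || dims[2] < pw)
    stop("patch size exceeds the image grid", call. = FALSE)
  set.seed(train_cfg$seed)
  params <- net_init_params(net_cfg)
  state <- adam_init(params)
  B <- train_cfg$batch_size
  history <- numeric(train_cfg$iterations)
  for (it in seq_len(train_cfg$iterations)) {
    xb <- array(0, c(ph, pw, net_cfg$in_channels, B))
    yb <- array(0, c(ph, pw, B))
    for (b in seq_len(B)) {
      k <- sample.int(length(ds$x), 1)
      r0 <- sample.int(dims[1] - ph + 1, 1) - 1L
      c0 <- sample.int(dims[2] - pw + 1, 1) - 1L
      xb[, , , b] <- ds$x[[k]][r0 + (1:ph), c0 + (1:pw), ]
      yb[, , b] <- ds$y[[k]][r0 + (1:ph), c0 + (1:pw)]
    }
    fw <- net_forward(params, net_cfg, xb, net_cfg$dropout, keep_cache = TRUE)
    dout <- array(0, c(ph, pw, 1, B))
    loss <- 0
    for (b in seq_len(B)) {
      lg <- loss_and_grad_2d(yb[, , b], fw$y[, , 1, b],
                             train_cfg$lambda_gdl, train_cfg$lambda_ldl)
      loss <- loss + lg$loss / B
      dout[, , 1, b] <- lg$grad / B
    }
    if (!is.finite(loss))
      stop(sprintf("training diverged at iteration %d (non-finite loss)", it),
           call. = FALSE)
    grads <- net_backward(params, net_cfg, fw$caches, dout)
    upd <- adam_step(params, grads, state, it, train_cfg$lr, train_cfg$beta1,
                     train_cfg$beta2, train_cfg$eps, train_cfg$weight_decay)
    params <- upd$params; state <- upd$state
    history[it] <- loss
  }
  structure(list(params = params, net_cfg = net_cfg, train_cfg = train_cfg,
                 history = history, hu_scale = 1000,
                 seed = train_cfg$seed),
            class = "bcnn_model")
}

#' @export
print.bcnn_model <- function(x, ...) {
  cat(sprintf("pseudo-CT regressor: depth %d, base %d channels, dropout p = %.2f\n",
              x$net_cfg$depth, x$net_cfg$base_channels, x$net_cfg$dropout))
  cat(sprintf("  trained %d iterations (seed %d), loss %.4g -> %.4g\n",
              length(x$history), x$seed, x$history[1],
              x$history[length(x$history)]))
  invisible(x)
}

# Assemble a full-slice prediction from overlapping patches (stride = half
# patch, uniform-average blending). One stochastic forward per tile batch.
infer_slice <- function(model, x_img, p) {
  cfg <- model$net_cfg
  d <- dim(x_img)
  ph <- min(cfg$patch[1], d[1]); pw <- min(cfg$patch[2], d[2])
  ph <- ph - ph %% 2^(cfg$depth - 1); pw <- pw - pw %% 2^(cfg$depth - 1)
  rs <- unique(c(seq(1, d[1] - ph + 1, by = max(1, ph %/% 2)), d[1] - ph + 1))
  cs <- unique(c(seq(1, d[2] - pw + 1, by = max(1, pw %/% 2)), d[2] - pw + 1))
  tiles <- expand.grid(r = rs, c = cs)
  B <- nrow(tiles)
  xb <- array(0, c(ph, pw, d[3], B))
  for (b in seq_len(B))
    xb[, , , b] <- x_img[tiles$r[b] + (1:ph) - 1, tiles$c[b] + (1:pw) - 1, ]
  yb <- net_forward(model$params, cfg, xb, p, keep_cache = FALSE)$y
  acc <- matrix(0, d[1], d[2]); cnt <- matrix(0, d[1], d[2])
  for (b in seq_len(B)) {
    ri <- tiles$r[b] + (1:ph) - 1; ci <- tiles$c[b] + (1:pw) - 1
    acc[ri, ci] <- acc[ri, ci] + yb[, , 1, b]
    cnt[ri, ci] <- cnt[ri, ci] + 1
  }
  acc / cnt
}

#' Monte Carlo Dropout inference
#'
#' Performs N stochastic forward passes with dropout active and returns
#' the pseudo-CT estimate \eqn{pCT = \frac{1}{N}\sum_i f_i(x)} and the
#' voxelwise predictive variance
#' \eqn{\sigma^2 = \frac{1}{N}\sum_i (f_i(x) - pCT)^2} (biased, divisor
#' N), both in HU / HU^2. Full slices are assembled from overlapping
#' patches averaged with uniform weights at half-patch stride. With
#' dropout rate 0 all samples coincide, the variance is identically zero
#' and the mean equals the deterministic forward pass.
#'
#' @param model a \code{\link{bcnn_train}} model.
#' @param mr input MR channels: array (rows, cols, 3) for one slice or
#'   (slices, rows, cols, 3) for a stack.
#' @param mc a \code{\link{mc_config}} (N >= 2).
#' @param keep_samples also return the N per-voxel samples.
#' @return list with \code{pct} (HU), \code{variance} (HU^2) and
#'   optionally \code{samples} (N x rows x cols per slice).
#' @export
mc_dropout_infer <- function(model, mr, mc = mc_config(),
                             keep_samples = FALSE) {
  if (mc$n_samples < 2) stop("at least 2 Monte Carlo samples required", call. = FALSE)
  single <- length(dim(mr)) == 3
  if (single) dim(mr) <- c(1, dim(mr))
  d <- dim(mr)
  p <- model$net_cfg$dropout
  pct <- array(0, d[1:3]); var <- array(0, d[1:3])
  samples <- if (keep_samples) array(0, c(mc$n_samples, d[1:3])) else NULL
  for (s in seq_len(d[1])) {
    stack <- array(0, c(mc$n_samples, d[2], d[3]))
    for (i in seq_len(mc$n_samples)) {
      set.seed(derive_seed(mc$seed, "mc", s, i))
      stack[i, , ] <- infer_slice(model, mr[s, , , ], p) * model$hu_scale
    }
    m <- apply(stack, c(2, 3), mean)
    pct[s, , ] <- m
    var[s, , ] <- apply(sweep(stack, c(2, 3), m)^2, c(2, 3), mean)
    if (keep_samples) samples[, s, , ] <- stack
  }
  if (single) {
    dim(pct) <- d[2:3]; dim(var) <- d[2:3]
    if (keep_samples) dim(samples) <- c(mc$n_samples, d[2], d[3])
  }
  out <- list(pct = pct, variance = var)
  if (keep_samples) out$samples <- samples
  out
}

#' Deterministic pseudo-CT prediction (dropout disabled)
#'
#' @param object a \code{bcnn_model}.
#' @param mr MR input as in \code{\link{mc_dropout_infer}}.
#' @param ... unused.
#' @return pseudo-CT in HU.
#' @export
predict.bcnn_model <- function(object, mr, ...) {
  single <- length(dim(mr)) == 3
  if (single) dim(mr) <- c(1, dim(mr))
  d <- dim(mr)
  out <- array(0, d[1:3])
  for (s in seq_len(d[1]))
    out[s, , ] <- infer_slice(object, mr[s, , , ], 0) * object$hu_scale
  if (single) dim(out) <- d[2:3]
  out
}
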
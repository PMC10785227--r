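# Minimal dense encoder-decoder machinery on plain R arrays. Activations are
# stored as (H, W, C, B) arrays; 3x3 convolutions are evaluated as an im2col
# matrix product (column blocks ordered offset-major, channel-minor), which
# keeps every flop inside BLAS. Only what the pseudo-CT regressor needs is
# implemented: 3x3/1x1 convolution, ReLU, inverted dropout, 2x2 mean pooling,
# nearest-neighbour upsampling, channel concatenation, and Adam.

im2col3 <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]
  xp <- array(0, c(H + 2, W + 2, C, B))
  xp[2:(H + 1), 2:(W + 1), , ] <- x
  cols <- matrix(0, H * W * B, 9 * C)
  k <- 0L
  for (dx in 0:2) for (dy in 0:2) {
    blk <- xp[dy + (1:H), dx + (1:W), , , drop = FALSE]
    cols[, k * C + (1:C)] <- matrix(aperm(blk, c(1, 2, 4, 3)), H * W * B, C)
    k <- k + 1L
  }
  cols
}

col2im3 <- function(dcols, H, W, C, B) {
  dxp <- array(0, c(H + 2, W + 2, C, B))
  k <- 0L
  for (dx in 0:2) for (dy in 0:2) {
    blk <- aperm(array(dcols[, k * C + (1:C)], c(H, W, B, C)), c(1, 2, 4, 3))
    dxp[dy + (1:H), dx + (1:W), , ] <- dxp[dy + (1:H), dx + (1:W), , ] + blk
    k <- k + 1L
  }
  dxp[2:(H + 1), 2:(W + 1), , , drop = FALSE]
}

conv_fwd <- function(x, layer) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]
  Cout <- ncol(layer$W)
  if (layer$ksize == 3L) {
    cols <- im2col3(x)
  } else {
    cols <- matrix(aperm(x, c(1, 2, 4, 3)), H * W * B, C)
  }
  out <- cols %*% layer$W
  out <- out + rep(layer$b, each = nrow(out))
  list(y = aperm(array(out, c(H, W, B, Cout)), c(1, 2, 4, 3)), cols = cols)
}

conv_bwd <- function(dy, cols, layer, in_dim) {
  d <- dim(dy); H <- d[1]; W <- d[2]; Cout <- d[3]; B <- d[4]
  C <- in_dim[3]
  dmat <- matrix(aperm(dy, c(1, 2, 4, 3)), H * W * B, Cout)
  dW <- crossprod(cols, dmat)
  db <- colSums(dmat)
  dcols <- tcrossprod(dmat, layer$W)
  dx <- if (layer$ksize == 3L) {
    col2im3(dcols, H, W, C, B)
  } else {
    aperm(array(dcols, c(H, W, B, C)), c(1, 2, 4, 3))
  }
  list(dx = dx, dW = dW, db = db)
}

# leaky rectifier (slope 0.1 on the negative side): avoids dead units, which
# a small network is prone to under aggressive training and which would make
# whole regions invisible to dropout (zero activations carry no dropout
# variance)
LEAK <- 0.1
relu_fwd <- function(x) pmax(x, 0) + LEAK * pmin(x, 0)

drop_mask <- function(dims, p) {
  array((runif(prod(dims)) >= p) / (1 - p), dims)
}

pool2_fwd <- function(x) {
  d <- dim(x)
  o1 <- seq(1, d[1], 2); o2 <- seq(1, d[2], 2)
  (x[o1, o2, , , drop = FALSE] + x[o1 + 1, o2, , , drop = FALSE] +
     x[o1, o2 + 1, , , drop = FALSE] + x[o1 + 1, o2 + 1, , , drop = FALSE]) / 4
}

pool2_bwd <- function(dy, in_dim) {
  dx <- array(0, in_dim)
  o1 <- seq(1, in_dim[1], 2); o2 <- seq(1, in_dim[2], 2)
  g <- dy / 4
  dx[o1, o2, , ] <- g; dx[o1 + 1, o2, , ] <- g
  dx[o1, o2 + 1, , ] <- g; dx[o1 + 1, o2 + 1, , ] <- g
  dx
}

up2_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , , drop = FALSE]
}

up2_bwd <- function(dy) {
  d <- dim(dy)
  o1 <- seq(1, d[1], 2); o2 <- seq(1, d[2], 2)
  dy[o1, o2, , , drop = FALSE] + dy[o1 + 1, o2, , , drop = FALSE] +
    dy[o1, o2 + 1, , , drop = FALSE] + dy[o1 + 1, o2 + 1, , , drop = FALSE]
}

concat_c <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

he_init_layer <- function(cin, cout, ksize) {
  fan_in <- ksize * ksize * cin
  list(W = matrix(rnorm(fan_in * cout, 0, sqrt(2 / fan_in)), fan_in, cout),
       b = rep(0, cout), ksize = as.integer(ksize))
}

adam_init <- function(params) {
  lapply(params, function(l) list(mW = l$W * 0, vW = l$W * 0,
                                  mb = l$b * 0, vb = l$b * 0))
}

adam_step <- function(params, grads, state, t, lr, beta1, beta2, eps, wd) {
  for (nm in names(params)) {
    gW <- grads[[nm]]$dW + wd * params[[nm]]$W   # L2 on weights only
    gb <- grads[[nm]]$db
    st <- state[[nm]]
    st$mW <- beta1 * st$mW + (1 - beta1) * gW
    st$vW <- beta2 * st$vW + (1 - beta2) * gW^2
    st$mb <- beta1 * st$mb + (1 - beta1) * gb
    st$vb <- beta2 * st$vb + (1 - beta2) * gb^2
    mhW <- st$mW / (1 - beta1^t); vhW <- st$vW / (1 - beta2^t)
    mhb <- st$mb / (1 - beta1^t); vhb <- st$vb / (1 - beta2^t)
    params[[nm]]$W <- params[[nm]]$W - lr * mhW / (sqrt(vhW) + eps)
    params[[nm]]$b <- params[[nm]]$b - lr * mhb / (sqrt(vhb) + eps)
    state[[nm]] <- st
  }
  list(params = params, state = state)
}

# Encoder-decoder topology: per level two 3x3 conv + ReLU + dropout blocks,
# 2x2 mean pool between encoder levels, nearest upsampling + skip concat in
# the decoder, linear 1x1 output head (no dropout after the output conv).
net_param_names <- function(depth) {
  nms <- character(0)
  for (lev in seq_len(depth)) nms <- c(nms, paste0("enc", lev, c("a", "b")))
  if (depth > 1)
    for (lev in seq.int(depth - 1, 1)) nms <- c(nms, paste0("dec", lev, c("a", "b")))
  c(nms, "out")
}

net_init_params <- function(cfg) {
  ch <- cfg$base_channels * 2^(seq_len(cfg$depth) - 1)
  p <- list()
  for (lev in seq_len(cfg$depth)) {
    cin <- if (lev == 1) cfg$in_channels else ch[lev - 1]
    p[[paste0("enc", lev, "a")]] <- he_init_layer(cin, ch[lev], 3)
    p[[paste0("enc", lev, "b")]] <- he_init_layer(ch[lev], ch[lev], 3)
  }
  if (cfg$depth > 1) {
    for (lev in seq.int(cfg$depth - 1, 1)) {
      p[[paste0("dec", lev, "a")]] <- he_init_layer(ch[lev] + ch[lev + 1], ch[lev], 3)
      p[[paste0("dec", lev, "b")]] <- he_init_layer(ch[lev], ch[lev], 3)
    }
  }
  p[["out"]] <- he_init_layer(ch[1], cfg$out_channels, 1)
  p
}

# One conv + ReLU + dropout block. RNG is consumed only when p > 0, so p = 0
# forward passes are bit-identical to the deterministic network.
block_fwd <- function(x, layer, p, keep_cache) {
  cf <- conv_fwd(x, layer)
  a <- relu_fwd(cf$y)
  mask <- NULL
  if (p > 0) {
    mask <- drop_mask(dim(a), p)
    a <- a * mask
  }
  list(y = a, cache = if (keep_cache)
    list(cols = cf$cols, pre = cf$y, mask = mask, in_dim = dim(x)) else NULL)
}

block_bwd <- function(dy, cache, layer) {
  if (!is.null(cache$mask)) dy <- dy * cache$mask
  dy <- dy * ((cache$pre > 0) + LEAK * (cache$pre <= 0))
  conv_bwd(dy, cache$cols, layer, cache$in_dim)
}

net_forward <- function(params, cfg, x, p, keep_cache = FALSE) {
  depth <- cfg$depth
  caches <- list(); skips <- list(); pool_dims <- list()
  h <- x
  for (lev in seq_len(depth)) {
    for (sub in c("a", "b")) {
      nm <- paste0("enc", lev, sub)
      bl <- block_fwd(h, params[[nm]], p, keep_cache)
      h <- bl$y; caches[[nm]] <- bl$cache
    }
    if (lev < depth) {
      skips[[lev]] <- h
      pool_dims[[lev]] <- dim(h)
      h <- pool2_fwd(h)
    }
  }
  if (depth > 1) {
    for (lev in seq.int(depth - 1, 1)) {
      h <- up2_fwd(h)
      caches[[paste0("cat", lev)]] <- if (keep_cache) dim(skips[[lev]])[3] else NULL
      h <- concat_c(h, skips[[lev]])
      for (sub in c("a", "b")) {
        nm <- paste0("dec", lev, sub)
        bl <- block_fwd(h, params[[nm]], p, keep_cache)
        h <- bl$y; caches[[nm]] <- bl$cache
      }
    }
  }
  cf <- conv_fwd(h, params[["out"]])
  if (keep_cache) caches[["out"]] <- list(cols = cf$cols, in_dim = dim(h),
                                          pool_dims = pool_dims)
  list(y = cf$y, caches = caches)
}

net_backward <- function(params, cfg, caches, dout) {
  depth <- cfg$depth
  grads <- list()
  oc <- caches[["out"]]
  cb <- conv_bwd(dout, oc$cols, params[["out"]], oc$in_dim)
  grads[["out"]] <- list(dW = cb$dW, db = cb$db)
  dh <- cb$dx
  dskip <- vector("list", depth)
  if (depth > 1) {
    for (lev in seq.int(1, depth - 1)) {
      for (sub in c("b", "a")) {
        nm <- paste0("dec", lev, sub)
        cb <- block_bwd(dh, caches[[nm]], params[[nm]])
        grads[[nm]] <- list(dW = cb$dW, db = cb$db)
        dh <- cb$dx
      }
      # split concat: first block is the upsampled path, second the skip
      n_up <- dim(dh)[3] - caches[[paste0("cat", lev)]]
      dskip[[lev]] <- dh[, , n_up + seq_len(dim(dh)[3] - n_up), , drop = FALSE]
      dh <- up2_bwd(dh[, , seq_len(n_up), , drop = FALSE])
    }
  }
  for (lev in seq.int(depth, 1)) {
    if (lev < depth) {
      dh <- pool2_bwd(dh, oc$pool_dims[[lev]])
      dh <- dh + dskip[[lev]]
    }
    for (sub in c("b", "a")) {
      nm <- paste0("enc", lev, sub)
      cb <- block_bwd(dh, caches[[nm]], params[[nm]])
      grads[[nm]] <- list(dW = cb$dW, db = cb$db)
      dh <- cb$dx
    }
  }
  grads
}
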
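# ---- network building blocks -----------------------------------------------
#
# Feature tensors are numeric arrays with dim (W, H, T, C, N); convolution
# weights have dim (KW, KH, KT, Cin, Cout). Kernel/stride/pad arguments in
# the R API are given in (t, h, w) order and flipped at the C++ boundary.

he_init <- function(dims, fan_in) {
  array(rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)
}

nn_conv <- function(cin, cout, kernel = c(3, 3, 3), stride = c(1, 1, 1),
                    pad = NULL) {
  if (is.null(pad)) pad <- floor(kernel / 2)
  fan_in <- cin * prod(kernel)
  list(type = "conv",
       W = he_init(c(rev(kernel), cin, cout), fan_in),
       b = rep(0, cout),
       stride = rev(stride), pad = rev(pad))
}

nn_bn <- function(c) {
  list(type = "bn", gamma = rep(1, c), beta = rep(0, c),
       run_mean = rep(0, c), run_var = rep(1, c),
       eps = 1e-5, momentum = 0.1)
}

nn_block <- function(cin, cout, stride = c(1, 1, 1)) {
  proj <- !identical(as.numeric(stride), c(1, 1, 1)) || cin != cout
  list(type = "block",
       conv1 = nn_conv(cin, cout, stride = stride),
       bn1 = nn_bn(cout),
       conv2 = nn_conv(cout, cout),
       bn2 = nn_bn(cout),
       proj_conv = if (proj) nn_conv(cin, cout, kernel = c(1, 1, 1),
                                     stride = stride, pad = c(0, 0, 0)),
       proj_bn = if (proj) nn_bn(cout))
}

#' Build a residual-network classifier
#'
#' Three variants share one engine: `"spatial_2d"`, an 18-layer residual
#' network with purely spatial kernels operating on single frames;
#' `"spatiotemporal_3d"`, its counterpart with 3D spatio-temporal kernels
#' operating on k-frame clips; and `"tiny_3d"`, a reduced-width 4-block 3D
#' residual network sized for CPU-scale experiments and tests. All end in
#' global average pooling and a linear head emitting `num_classes` logits.
#' Weight initialisation is He-normal; batch normalisation follows every
#' convolution. Pretrained initialisation is not bundled with the package,
#' so `pretrained = TRUE` is refused.
#'
#' @param variant one of `"spatial_2d"`, `"spatiotemporal_3d"`, `"tiny_3d"`.
#' @param num_classes 2 or 3.
#' @param in_channels input channels (1 for grayscale).
#' @param pretrained must be `FALSE`; no published weights ship with the
#'   package.
#' @return A model object of class `neoecho_model`.
#' @export
build_model <- function(variant = c("tiny_3d", "spatiotemporal_3d",
                                    "spatial_2d"),
                        num_classes = 3, in_channels = 1,
                        pretrained = FALSE) {
  variant <- tryCatch(match.arg(variant), error = function(e) {
    stop(sprintf("unknown model variant '%s'", variant[1]), call. = FALSE)
  })
  if (pretrained) {
    stop("pretrained initialisation is not available in this package; ",
         "use pretrained = FALSE for He-normal initialisation", call. = FALSE)
  }
  layers <- switch(variant,
    tiny_3d = {
      c(list(nn_conv(in_channels, 8, kernel = c(3, 3, 3),
                     stride = c(1, 2, 2)),
             nn_bn(8), list(type = "relu")),
        list(nn_block(8, 8),
             nn_block(8, 16, stride = c(2, 2, 2)),
             nn_block(16, 16),
             nn_block(16, 32, stride = c(2, 2, 2))))
    },
    spatiotemporal_3d = {
      c(list(nn_conv(in_channels, 64, kernel = c(3, 7, 7),
                     stride = c(1, 2, 2)),
             nn_bn(64), list(type = "relu")),
        list(nn_block(64, 64), nn_block(64, 64),
             nn_block(64, 128, stride = c(2, 2, 2)), nn_block(128, 128),
             nn_block(128, 256, stride = c(2, 2, 2)), nn_block(256, 256),
             nn_block(256, 512, stride = c(2, 2, 2)), nn_block(512, 512)))
    },
    spatial_2d = {
      c(list(nn_conv(in_channels, 64, kernel = c(1, 7, 7),
                     stride = c(1, 2, 2)),
             nn_bn(64), list(type = "relu")),
        list(nn_block2d(64, 64), nn_block2d(64, 64),
             nn_block2d(64, 128, 2), nn_block2d(128, 128),
             nn_block2d(128, 256, 2), nn_block2d(256, 256),
             nn_block2d(256, 512, 2), nn_block2d(512, 512)))
    }
  )
  cfeat <- switch(variant, tiny_3d = 32, 512)
  structure(list(
    variant = variant, num_classes = num_classes, in_channels = in_channels,
    layers = layers,
    fc = list(W = matrix(rnorm(num_classes * cfeat, 0, sqrt(2 / cfeat)),
                         num_classes, cfeat),
              b = rep(0, num_classes)),
    norm = list(mean = 0, std = 1)
  ), class = "neoecho_model")
}

nn_block2d <- function(cin, cout, s = 1) {
  blk <- list(type = "block",
              conv1 = nn_conv(cin, cout, kernel = c(1, 3, 3),
                              stride = c(1, s, s)),
              bn1 = nn_bn(cout),
              conv2 = nn_conv(cout, cout, kernel = c(1, 3, 3)),
              bn2 = nn_bn(cout),
              proj_conv = NULL, proj_bn = NULL)
  if (s != 1 || cin != cout) {
    blk$proj_conv <- nn_conv(cin, cout, kernel = c(1, 1, 1),
                             stride = c(1, s, s), pad = c(0, 0, 0))
    blk$proj_bn <- nn_bn(cout)
  }
  blk
}

#' @export
print.neoecho_model <- function(x, ...) {
  np <- sum(vapply(unlist(x$layers, recursive = TRUE), length, numeric(1)))
  cat(sprintf("<neoecho_model> %s, %d classes, %d input channel(s)\n",
              x$variant, x$num_classes, x$in_channels))
  invisible(x)
}

# ---- forward / backward -----------------------------------------------------

conv_forward <- function(layer, x) {
  d <- dim(x)
  out <- conv3d_fw(as.numeric(x), as.integer(d), as.numeric(layer$W),
                   as.integer(dim(layer$W)), layer$b,
                   as.integer(layer$stride), as.integer(layer$pad))
  list(y = array(out$y, out$ydim), cache = list(x = x))
}

conv_backward <- function(layer, cache, dy) {
  d <- dim(cache$x)
  out <- conv3d_bw(as.numeric(cache$x), as.integer(d), as.numeric(layer$W),
                   as.integer(dim(layer$W)), as.numeric(dy),
                   as.integer(layer$stride), as.integer(layer$pad))
  list(dx = array(out$dx, d),
       grads = list(W = array(out$dw, dim(layer$W)), b = out$db))
}

bn_forward <- function(layer, x, train) {
  d <- dim(x)
  nwht <- prod(d[1:3]); C <- d[4]; N <- d[5]
  M <- matrix(x, nrow = nwht)
  if (train) {
    cm <- colMeans(M)
    cv <- colMeans(M^2)
    mu <- rowMeans(matrix(cm, C, N))
    ex2 <- rowMeans(matrix(cv, C, N))
    va <- ex2 - mu^2
    layer$run_mean <- (1 - layer$momentum) * layer$run_mean + layer$momentum * mu
    layer$run_var <- (1 - layer$momentum) * layer$run_var + layer$momentum * va
  } else {
    mu <- layer$run_mean
    va <- layer$run_var
  }
  invstd <- 1 / sqrt(va + layer$eps)
  mu_col <- rep(mu, times = N)
  is_col <- rep(invstd, times = N)
  xhat <- sweep(sweep(M, 2, mu_col, "-"), 2, is_col, "*")
  y <- sweep(sweep(xhat, 2, rep(layer$gamma, times = N), "*"),
             2, rep(layer$beta, times = N), "+")
  list(y = array(y, d), layer = layer,
       cache = list(xhat = xhat, invstd = invstd, d = d))
}

bn_backward <- function(layer, cache, dy) {
  d <- cache$d
  nwht <- prod(d[1:3]); C <- d[4]; N <- d[5]
  m <- nwht * N
  Dy <- matrix(dy, nrow = nwht)
  xhat <- cache$xhat
  sum_by_c <- function(M) rowSums(matrix(colSums(M), C, N))
  dgamma <- sum_by_c(Dy * xhat)
  dbeta <- sum_by_c(Dy)
  dxhat <- sweep(Dy, 2, rep(layer$gamma, times = N), "*")
  s1 <- sum_by_c(dxhat)
  s2 <- sum_by_c(dxhat * xhat)
  t1 <- sweep(dxhat, 2, rep(s1 / m, times = N), "-")
  t2 <- sweep(xhat, 2, rep(s2 / m, times = N), "*")
  dx <- sweep(t1 - t2, 2, rep(cache$invstd, times = N), "*")
  list(dx = array(dx, d), grads = list(gamma = dgamma, beta = dbeta))
}

layer_forward <- function(layer, x, train) {
  switch(layer$type,
    conv = {
      r <- conv_forward(layer, x)
      list(y = r$y, layer = layer, cache = r$cache)
    },
    bn = bn_forward(layer, x, train),
    relu = list(y = pmax(x, 0), layer = layer, cache = list(mask = x > 0)),
    block = {
      r1 <- conv_forward(layer$conv1, x)
      r2 <- bn_forward(layer$bn1, r1$y, train)
      layer$bn1 <- r2$layer
      a1 <- pmax(r2$y, 0)
      r3 <- conv_forward(layer$conv2, a1)
      r4 <- bn_forward(layer$bn2, r3$y, train)
      layer$bn2 <- r4$layer
      if (!is.null(layer$proj_conv)) {
        rp <- conv_forward(layer$proj_conv, x)
        rpb <- bn_forward(layer$proj_bn, rp$y, train)
        layer$proj_bn <- rpb$layer
        sc <- rpb$y
        proj_cache <- list(conv = rp$cache, bn = rpb$cache)
      } else {
        sc <- x
        proj_cache <- NULL
      }
      pre <- r4$y + sc
      list(y = pmax(pre, 0), layer = layer,
           cache = list(c1 = r1$cache, b1 = r2$cache, m1 = r2$y > 0,
                        c2 = r3$cache, b2 = r4$cache, proj = proj_cache,
                        out_mask = pre > 0))
    },
    stop("unknown layer type")
  )
}

layer_backward <- function(layer, cache, dy) {
  switch(layer$type,
    conv = conv_backward(layer, cache, dy),
    bn = bn_backward(layer, cache, dy),
    relu = list(dx = dy * cache$mask, grads = NULL),
    block = {
      dpre <- dy * cache$out_mask
      g4 <- bn_backward(layer$bn2, cache$b2, dpre)
      g3 <- conv_backward(layer$conv2, cache$c2, g4$dx)
      da1 <- g3$dx * cache$m1
      g2 <- bn_backward(layer$bn1, cache$b1, da1)
      g1 <- conv_backward(layer$conv1, cache$c1, g2$dx)
      dx <- g1$dx
      grads <- list(conv1 = g1$grads, bn1 = g2$grads,
                    conv2 = g3$grads, bn2 = g4$grads)
      if (!is.null(cache$proj)) {
        gpb <- bn_backward(layer$proj_bn, cache$proj$bn, dpre)
        gpc <- conv_backward(layer$proj_conv, cache$proj$conv, gpb$dx)
        dx <- dx + gpc$dx
        grads$proj_conv <- gpc$grads
        grads$proj_bn <- gpb$grads
      } else {
        dx <- dx + dpre
      }
      list(dx = dx, grads = grads)
    }
  )
}

# forward through all layers; returns logits (K x N), the final feature map
# A (input of GAP), pooled features, per-layer caches and BN-updated model
net_forward <- function(model, x, train = FALSE, keep_acts = FALSE) {
  caches <- vector("list", length(model$layers))
  acts <- if (keep_acts) vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    r <- layer_forward(model$layers[[i]], x, train)
    model$layers[[i]] <- r$layer
    caches[[i]] <- r$cache
    x <- r$y
    if (keep_acts) acts[[i]] <- x
  }
  d <- dim(x)
  nwht <- prod(d[1:3])
  feat <- matrix(colMeans(matrix(x, nrow = nwht)), d[4], d[5])
  logits <- model$fc$W %*% feat + model$fc$b
  list(logits = logits, feat_map = x, feat = feat, caches = caches,
       model = model, map_dim = d, acts = if (keep_acts) acts)
}

# backward from dlogits (K x N); stop_at = index of the layer whose OUTPUT
# gradient should be returned (0 = propagate all the way to the input)
net_backward <- function(model, fwd, dlogits, stop_at = 0) {
  feat <- fwd$feat
  grads <- list(fc = list(W = dlogits %*% t(feat),
                          b = rowSums(dlogits)))
  dfeat <- t(model$fc$W) %*% dlogits
  d <- fwd$map_dim
  nwht <- prod(d[1:3])
  # GAP backward: spread each channel gradient uniformly
  dmap <- array(rep(as.numeric(dfeat), each = nwht) / nwht, d)
  layer_grads <- vector("list", length(model$layers))
  dy <- dmap
  for (i in rev(seq_along(model$layers))) {
    if (i == stop_at) {
      return(list(grads = grads, layer_grads = layer_grads, d_at_stop = dy))
    }
    r <- layer_backward(model$layers[[i]], fwd$caches[[i]], dy)
    # note: list[[i]] <- NULL would delete the slot, so guard parameter-free
    # layers (relu) to keep indices aligned
    if (!is.null(r$grads)) layer_grads[[i]] <- r$grads
    dy <- r$dx
  }
  list(grads = grads, layer_grads = layer_grads, d_at_stop = dy)
}

softmax_cols <- function(logits) {
  z <- sweep(logits, 2, apply(logits, 2, max), "-")
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# ---- optimiser --------------------------------------------------------------

adam_update_tensor <- function(par, g, st, lr, wd, b1, b2, eps, t) {
  g <- g + wd * par
  if (is.null(st)) st <- list(m = 0 * g, v = 0 * g)
  st$m <- b1 * st$m + (1 - b1) * g
  st$v <- b2 * st$v + (1 - b2) * g^2
  mh <- st$m / (1 - b1^t)
  vh <- st$v / (1 - b2^t)
  list(par = par - lr * mh / (sqrt(vh) + eps), st = st)
}

adam_step_layer <- function(layer, grads, state, opt) {
  if (is.null(grads)) return(list(layer = layer, state = state))
  if (is.null(state)) state <- list()
  if (layer$type == "conv") {
    for (nm in c("W", "b")) {
      u <- adam_update_tensor(layer[[nm]], grads[[nm]], state[[nm]],
                              opt$lr, opt$wd, opt$b1, opt$b2, opt$eps, opt$t)
      layer[[nm]] <- u$par; state[[nm]] <- u$st
    }
  } else if (layer$type == "bn") {
    for (nm in c("gamma", "beta")) {
      u <- adam_update_tensor(layer[[nm]], grads[[nm]], state[[nm]],
                              opt$lr, 0, opt$b1, opt$b2, opt$eps, opt$t)
      layer[[nm]] <- u$par; state[[nm]] <- u$st
    }
  } else if (layer$type == "block") {
    subs <- c("conv1", "bn1", "conv2", "bn2", "proj_conv", "proj_bn")
    for (snm in subs) {
      if (is.null(layer[[snm]]) || is.null(grads[[snm]])) next
      u <- adam_step_layer(layer[[snm]], grads[[snm]], state[[snm]], opt)
      layer[[snm]] <- u$layer; state[[snm]] <- u$state
    }
  }
  list(layer = layer, state = state)
}

adam_step <- function(model, grads, layer_grads, state, opt) {
  for (i in seq_along(model$layers)) {
    if (is.null(layer_grads[[i]])) next
    u <- adam_step_layer(model$layers[[i]], layer_grads[[i]],
                         state$layers[[i]], opt)
    model$layers[[i]] <- u$layer
    state$layers[[i]] <- u$state
  }
  for (nm in c("W", "b")) {
    u <- adam_update_tensor(model$fc[[nm]], grads$fc[[nm]], state$fc[[nm]],
                            opt$lr, opt$wd, opt$b1, opt$b2, opt$eps, opt$t)
    model$fc[[nm]] <- u$par; state$fc[[nm]] <- u$st
  }
  list(model = model, state = state)
}
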
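# Minimal neural-network engine for 20 x 50 binding matrices.
#
# Activations are stored column-major as 4-D arrays (H, W, C, N) for the
# convolutional part and as (features, N) matrices after flattening.  All
# heavy lifting is BLAS matrix products over im2col patch matrices, so the
# engine is fast enough for desk-scale training on one CPU while remaining
# R-driven (deterministic under set.seed, double precision throughout).
#
# Layers are plain lists with a `type`; `nn_forward` / `nn_backward`
# dispatch on it.  Supported: conv (5x5/3x3 'same', stride 1), bn2d, bn1d,
# lrelu, maxpool2 (2x2, stride 2), dropout, flatten, gap (global average
# pool), dense, resblock (two 3x3 convs + batch norm with a skip
# connection, 1x1 projection when the channel count changes).

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

## ---- layer constructors ---------------------------------------------------

nn_conv <- function(cin, cout, kh = 5L, kw = 5L) {
  list(type = "conv", cin = cin, cout = cout, kh = as.integer(kh),
       kw = as.integer(kw), params = NULL)
}

nn_bn2d <- function(channels) list(type = "bn2d", channels = channels,
                                   params = NULL,
                                   run_mean = rep(0, channels),
                                   run_var = rep(1, channels))

nn_bn1d <- function(channels) list(type = "bn1d", channels = channels,
                                   params = NULL,
                                   run_mean = rep(0, channels),
                                   run_var = rep(1, channels))

nn_lrelu <- function(alpha = 0.3) list(type = "lrelu", alpha = alpha)

nn_maxpool2 <- function() list(type = "maxpool2")

nn_dropout <- function(rate = 0.3) list(type = "dropout", rate = rate)

nn_flatten <- function() list(type = "flatten")

nn_gap <- function() list(type = "gap")

nn_dense <- function(din, dout) list(type = "dense", din = din, dout = dout,
                                     params = NULL)

nn_resblock <- function(cin, cout, alpha = 0.3) {
  list(type = "resblock", cin = cin, cout = cout, alpha = alpha,
       conv1 = nn_conv(cin, cout, 3L, 3L), bn1 = nn_bn2d(cout),
       conv2 = nn_conv(cout, cout, 3L, 3L), bn2 = nn_bn2d(cout),
       proj = if (cin != cout) nn_conv(cin, cout, 1L, 1L) else NULL,
       proj_bn = if (cin != cout) nn_bn2d(cout) else NULL)
}

## ---- parameter initialization (He for conv/dense, unit bn) ---------------

init_layer <- function(layer) {
  switch(layer$type,
    conv = {
      fan_in <- layer$kh * layer$kw * layer$cin
      layer$params <- list(
        W = matrix(stats::rnorm(fan_in * layer$cout, 0, sqrt(2 / fan_in)),
                   fan_in, layer$cout),
        b = rep(0, layer$cout))
      layer
    },
    dense = {
      layer$params <- list(
        W = matrix(stats::rnorm(layer$dout * layer$din, 0,
                                sqrt(2 / layer$din)),
                   layer$dout, layer$din),
        b = rep(0, layer$dout))
      layer
    },
    bn2d = , bn1d = {
      layer$params <- list(gamma = rep(1, layer$channels),
                           beta = rep(0, layer$channels))
      layer$run_mean <- rep(0, layer$channels)
      layer$run_var <- rep(1, layer$channels)
      layer
    },
    resblock = {
      layer$conv1 <- init_layer(layer$conv1)
      layer$bn1 <- init_layer(layer$bn1)
      layer$conv2 <- init_layer(layer$conv2)
      layer$bn2 <- init_layer(layer$bn2)
      if (!is.null(layer$proj)) {
        layer$proj <- init_layer(layer$proj)
        layer$proj_bn <- init_layer(layer$proj_bn)
      }
      layer
    },
    layer)
}

nn_init <- function(net) {
  net$layers <- lapply(net$layers, init_layer)
  net
}

## ---- conv via im2col ------------------------------------------------------

# Patch-gather index for 'same' conv: maps (kh*kw*cin, oh*ow) patch elements
# into the zero-padded (Hp*Wp*C) feature space.  Cached per layer geometry.
conv_idx_cache <- new.env(parent = emptyenv())

conv_gather_idx <- function(H, W, C, kh, kw) {
  key <- paste(H, W, C, kh, kw, sep = "_")
  got <- conv_idx_cache[[key]]
  if (!is.null(got)) return(got)
  ph <- (kh - 1L) %/% 2L
  pw <- (kw - 1L) %/% 2L
  Hp <- H + 2L * ph
  Wp <- W + 2L * pw
  # patch element order: dh fastest, then dw, then c  (must match W rows)
  dh <- rep(seq_len(kh), times = kw * C)
  dw <- rep(rep(seq_len(kw), each = kh), times = C)
  cc <- rep(seq_len(C), each = kh * kw)
  base <- (dh - 1L) + Hp * (dw - 1L) + Hp * Wp * (cc - 1L)  # 0-based
  # output position order: oh fastest, then ow
  oh <- rep(seq_len(H), times = W)
  ow <- rep(seq_len(W), each = H)
  off <- (oh - 1L) + Hp * (ow - 1L)
  idx <- outer(base, off, `+`) + 1L            # (patch, pos) 1-based
  out <- list(idx = as.integer(idx), Hp = Hp, Wp = Wp, ph = ph, pw = pw,
              patch = kh * kw * C, npos = H * W)
  conv_idx_cache[[key]] <- out
  out
}

pad_input <- function(x, ph, pw) {
  d <- dim(x)
  if (ph == 0L && pw == 0L) return(x)
  xp <- array(0, c(d[1] + 2L * ph, d[2] + 2L * pw, d[3], d[4]))
  xp[ph + seq_len(d[1]), pw + seq_len(d[2]), , ] <- x
  xp
}

conv_forward_ref <- function(layer, x) {
  d <- dim(x)                                   # (H, W, C, N)
  g <- conv_gather_idx(d[1], d[2], d[3], layer$kh, layer$kw)
  xp <- pad_input(x, g$ph, g$pw)
  dim(xp) <- c(g$Hp * g$Wp * d[3], d[4])
  P <- xp[g$idx, , drop = FALSE]                # (patch*npos, N)
  dim(P) <- c(g$patch, g$npos * d[4])
  out <- crossprod(P, layer$params$W)           # (npos*N, cout)
  out <- sweep(out, 2L, layer$params$b, `+`)
  dim(out) <- c(d[1], d[2], d[4], layer$cout)   # pos order (oh, ow), then N
  out <- aperm(out, c(1L, 2L, 4L, 3L))          # -> (H, W, cout, N)
  list(out = out, cache = list(P = P, dims = d, g = g))
}

conv_backward_ref <- function(layer, dout, cache) {
  d <- cache$dims
  g <- cache$g
  N <- d[4]
  D <- aperm(dout, c(1L, 2L, 4L, 3L))           # (H, W, N, cout)
  dim(D) <- c(g$npos * N, layer$cout)
  P <- cache$P                                  # (patch, npos*N)
  dW <- P %*% D
  db <- colSums(D)
  dP <- tcrossprod(layer$params$W, D)           # (patch, npos*N)
  dim(dP) <- c(g$patch * g$npos, N)
  acc <- rowsum(dP, group = g$idx, reorder = TRUE)
  dxp <- matrix(0, g$Hp * g$Wp * d[3], N)
  dxp[as.integer(rownames(acc)), ] <- acc
  dim(dxp) <- c(g$Hp, g$Wp, d[3], N)
  dx <- dxp[g$ph + seq_len(d[1]), g$pw + seq_len(d[2]), , , drop = FALSE]
  list(dx = dx, grads = list(W = dW, b = db))
}

## ---- batch norm -----------------------------------------------------------

# x arranged as (m, C) matrix: rows are all (spatial x batch) observations.
bn_core_forward <- function(xm, gamma, beta, run_mean, run_var, training) {
  if (training) {
    mu <- colMeans(xm)
    xc <- sweep(xm, 2L, mu)
    va <- colMeans(xc * xc)
    invstd <- 1 / sqrt(va + BN_EPS)
    xhat <- sweep(xc, 2L, invstd, `*`)
    new_mean <- BN_MOMENTUM * run_mean + (1 - BN_MOMENTUM) * mu
    new_var <- BN_MOMENTUM * run_var + (1 - BN_MOMENTUM) * va
    out <- sweep(sweep(xhat, 2L, gamma, `*`), 2L, beta, `+`)
    list(out = out, xhat = xhat, invstd = invstd,
         run_mean = new_mean, run_var = new_var)
  } else {
    invstd <- 1 / sqrt(run_var + BN_EPS)
    xhat <- sweep(sweep(xm, 2L, run_mean), 2L, invstd, `*`)
    out <- sweep(sweep(xhat, 2L, gamma, `*`), 2L, beta, `+`)
    list(out = out, xhat = NULL, invstd = NULL,
         run_mean = run_mean, run_var = run_var)
  }
}

bn_core_backward <- function(dm, xhat, invstd, gamma) {
  m <- nrow(dm)
  dgamma <- colSums(dm * xhat)
  dbeta <- colSums(dm)
  dxhat <- sweep(dm, 2L, gamma, `*`)
  t1 <- colSums(dxhat)
  t2 <- colSums(dxhat * xhat)
  dx <- sweep(dxhat, 2L, t1 / m) - sweep(xhat, 2L, t2 / m, `*`)
  dx <- sweep(dx, 2L, invstd, `*`)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

bn2d_forward_ref <- function(layer, x, training) {
  d <- dim(x)
  xm <- aperm(x, c(1L, 2L, 4L, 3L))
  dim(xm) <- c(d[1] * d[2] * d[4], d[3])
  r <- bn_core_forward(xm, layer$params$gamma, layer$params$beta,
                       layer$run_mean, layer$run_var, training)
  out <- r$out
  dim(out) <- c(d[1], d[2], d[4], d[3])
  out <- aperm(out, c(1L, 2L, 4L, 3L))
  list(out = out,
       cache = list(xhat = r$xhat, invstd = r$invstd, dims = d),
       run_mean = r$run_mean, run_var = r$run_var)
}

bn2d_backward_ref <- function(layer, dout, cache) {
  d <- cache$dims
  dm <- aperm(dout, c(1L, 2L, 4L, 3L))
  dim(dm) <- c(d[1] * d[2] * d[4], d[3])
  r <- bn_core_backward(dm, cache$xhat, cache$invstd, layer$params$gamma)
  dx <- r$dx
  dim(dx) <- c(d[1], d[2], d[4], d[3])
  dx <- aperm(dx, c(1L, 2L, 4L, 3L))
  list(dx = dx, grads = list(gamma = r$dgamma, beta = r$dbeta))
}

bn1d_forward <- function(layer, x, training) {
  r <- bn_core_forward(t(x), layer$params$gamma, layer$params$beta,
                       layer$run_mean, layer$run_var, training)
  list(out = t(r$out), cache = list(xhat = r$xhat, invstd = r$invstd),
       run_mean = r$run_mean, run_var = r$run_var)
}

bn1d_backward <- function(layer, dout, cache) {
  r <- bn_core_backward(t(dout), cache$xhat, cache$invstd,
                        layer$params$gamma)
  list(dx = t(r$dx), grads = list(gamma = r$dgamma, beta = r$dbeta))
}

## ---- pooling, activations, dropout, flatten, gap, dense -------------------

maxpool2_forward_ref <- function(x) {
  d <- dim(x)
  OH <- d[1] %/% 2L
  OW <- d[2] %/% 2L
  if (OH < 1L || OW < 1L)
    stop(sprintf("cannot 2x2-pool a %dx%d map", d[1], d[2]), call. = FALSE)
  xc <- x[seq_len(2L * OH), seq_len(2L * OW), , , drop = FALSE]
  CN <- d[3] * d[4]
  dim(xc) <- c(2L, OH, 2L * OW, CN)
  a1 <- xc[1L, , , , drop = TRUE]
  a2 <- xc[2L, , , , drop = TRUE]
  dim(a1) <- dim(a2) <- c(OH, 2L * OW, CN)
  take1 <- a1 >= a2
  m1 <- pmax(a1, a2)
  dim(m1) <- c(OH, 2L, OW, CN)
  c1 <- m1[, 1L, , , drop = TRUE]
  c2 <- m1[, 2L, , , drop = TRUE]
  dim(c1) <- dim(c2) <- c(OH, OW, CN)
  take2 <- c1 >= c2
  out <- pmax(c1, c2)
  dim(out) <- c(OH, OW, d[3], d[4])
  list(out = out, cache = list(dims = d, OH = OH, OW = OW,
                               take1 = take1, take2 = take2))
}

maxpool2_backward_ref <- function(dout, cache) {
  d <- cache$dims
  OH <- cache$OH
  OW <- cache$OW
  CN <- d[3] * d[4]
  dm <- dout
  dim(dm) <- c(OH, OW, CN)
  dm1 <- array(0, c(OH, 2L, OW, CN))
  dm1[, 1L, , ] <- dm * cache$take2
  dm1[, 2L, , ] <- dm * !cache$take2
  dim(dm1) <- c(OH, 2L * OW, CN)
  dxc <- array(0, c(2L, OH, 2L * OW, CN))
  dxc[1L, , , ] <- dm1 * cache$take1
  dxc[2L, , , ] <- dm1 * !cache$take1
  dim(dxc) <- c(2L * OH, 2L * OW, d[3], d[4])
  if (2L * OH == d[1] && 2L * OW == d[2]) return(dxc)
  dx <- array(0, d)
  dx[seq_len(2L * OH), seq_len(2L * OW), , ] <- dxc
  dx
}

lrelu_forward_ref <- function(layer, x) {
  neg <- x < 0
  out <- x
  out[neg] <- layer$alpha * x[neg]
  list(out = out, cache = neg)
}

lrelu_backward_ref <- function(layer, dout, neg) {
  dout[neg] <- layer$alpha * dout[neg]
  dout
}

dropout_forward <- function(layer, x, training) {
  if (!training || layer$rate == 0) return(list(out = x, cache = NULL))
  keep <- 1 - layer$rate
  mask <- array((stats::runif(length(x)) < keep) / keep, dim(x))
  list(out = x * mask, cache = mask)
}

gap_forward <- function(x) {
  d <- dim(x)
  xm <- x
  dim(xm) <- c(d[1] * d[2], d[3] * d[4])
  out <- colMeans(xm)
  dim(out) <- c(d[3], d[4])
  list(out = out, cache = d)
}

gap_backward <- function(dout, d) {
  hw <- d[1] * d[2]
  dx <- array(rep(as.numeric(dout) / hw, each = hw), d)
  dx
}


## ---- compiled fast paths (see src/nn_kernels.cpp) -------------------------

bn2d_forward <- function(layer, x, training) {
  d <- as.integer(dim(x))
  if (training) {
    st <- cpp_bn2d_stats(x, d)
    invstd <- 1 / sqrt(st$var + BN_EPS)
    out <- cpp_bn2d_norm(x, d, layer$params$gamma, layer$params$beta,
                         st$mean, invstd)
    list(out = out,
         cache = list(x = x, dims = d, mean = st$mean, invstd = invstd),
         run_mean = BN_MOMENTUM * layer$run_mean + (1 - BN_MOMENTUM) * st$mean,
         run_var = BN_MOMENTUM * layer$run_var + (1 - BN_MOMENTUM) * st$var)
  } else {
    invstd <- 1 / sqrt(layer$run_var + BN_EPS)
    out <- cpp_bn2d_norm(x, d, layer$params$gamma, layer$params$beta,
                         layer$run_mean, invstd)
    list(out = out, cache = NULL,
         run_mean = layer$run_mean, run_var = layer$run_var)
  }
}

bn2d_backward <- function(layer, dout, cache) {
  r <- cpp_bn2d_bwd(cache$x, cache$dims, dout, layer$params$gamma,
                    cache$mean, cache$invstd)
  list(dx = r$dx, grads = list(gamma = r$dgamma, beta = r$dbeta))
}


# The *_ref functions above are the plain-R reference implementations; the
# compiled kernels below are exact counterparts (same layouts, same
# tie-breaks) and are cross-checked against the references in the tests.

conv_forward <- function(layer, x) {
  d <- dim(x)
  out <- cpp_conv_fwd(x, as.integer(d), layer$params$W, layer$params$b,
                      layer$kh, layer$kw)
  list(out = out, cache = list(x = x, dims = as.integer(d)))
}

conv_backward <- function(layer, dout, cache) {
  r <- cpp_conv_bwd(cache$x, cache$dims, dout, layer$params$W,
                    layer$kh, layer$kw)
  list(dx = r$dx, grads = list(W = r$dW, b = as.numeric(r$db)))
}

maxpool2_forward <- function(x) {
  d <- dim(x)
  r <- cpp_maxpool_fwd(x, as.integer(d))
  list(out = r$out, cache = list(which = r$which, dims = as.integer(d)))
}

maxpool2_backward <- function(dout, cache) {
  cpp_maxpool_bwd(dout, cache$which, cache$dims)
}

lrelu_forward <- function(layer, x) {
  list(out = cpp_lrelu_fwd(x, layer$alpha), cache = x)
}

lrelu_backward <- function(layer, dout, x) {
  cpp_lrelu_bwd(dout, x, layer$alpha)
}

## ---- forward / backward over a layer list --------------------------------

# Returns logits (1 x N matrix for the standard sigmoid head) plus caches.
# `net$layers` is mutated only through the returned `net` (bn running stats).
nn_forward <- function(net, x, training = FALSE) {
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    layer <- net$layers[[i]]
    r <- switch(layer$type,
      conv = conv_forward(layer, x),
      bn2d = {
        rr <- bn2d_forward(layer, x, training)
        if (training) {
          net$layers[[i]]$run_mean <- rr$run_mean
          net$layers[[i]]$run_var <- rr$run_var
        }
        rr
      },
      bn1d = {
        rr <- bn1d_forward(layer, x, training)
        if (training) {
          net$layers[[i]]$run_mean <- rr$run_mean
          net$layers[[i]]$run_var <- rr$run_var
        }
        rr
      },
      lrelu = lrelu_forward(layer, x),
      maxpool2 = maxpool2_forward(x),
      dropout = dropout_forward(layer, x, training),
      flatten = {
        d <- dim(x)
        out <- x
        dim(out) <- c(prod(d[1:3]), d[4])
        list(out = out, cache = d)
      },
      gap = gap_forward(x),
      dense = list(out = sweep(layer$params$W %*% x, 1L, layer$params$b, `+`),
                   cache = x),
      resblock = resblock_forward(net, i, x, training),
      stop(sprintf("unknown layer type '%s'", layer$type))
    )
    if (layer$type == "resblock") {
      net <- r$net
      r <- r$r
    }
    x <- r$out
    caches[[i]] <- r$cache
  }
  list(out = x, caches = caches, net = net)
}

nn_backward <- function(net, caches, dout) {
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    layer <- net$layers[[i]]
    cache <- caches[[i]]
    r <- switch(layer$type,
      conv = conv_backward(layer, dout, cache),
      bn2d = bn2d_backward(layer, dout, cache),
      bn1d = bn1d_backward(layer, dout, cache),
      lrelu = list(dx = lrelu_backward(layer, dout, cache), grads = NULL),
      maxpool2 = list(dx = maxpool2_backward(dout, cache), grads = NULL),
      dropout = list(dx = if (is.null(cache)) dout else dout * cache,
                     grads = NULL),
      flatten = { dim(dout) <- cache; list(dx = dout, grads = NULL) },
      gap = list(dx = gap_backward(dout, cache), grads = NULL),
      dense = list(dx = crossprod(layer$params$W, dout),
                   grads = list(W = tcrossprod(dout, cache),
                                b = rowSums(dout))),
      resblock = resblock_backward(layer, dout, cache))
    dout <- r$dx
    grads[i] <- list(r$grads)   # [[<-]] with NULL would drop the slot
  }
  grads
}

## ---- residual block -------------------------------------------------------

resblock_forward <- function(net, i, x, training) {
  layer <- net$layers[[i]]
  c1 <- conv_forward(layer$conv1, x)
  b1 <- bn2d_forward(layer$bn1, c1$out, training)
  a1 <- lrelu_forward(layer, b1$out)
  c2 <- conv_forward(layer$conv2, a1$out)
  b2 <- bn2d_forward(layer$bn2, c2$out, training)
  if (is.null(layer$proj)) {
    skip <- x
    pc <- NULL
    pb <- NULL
  } else {
    pc <- conv_forward(layer$proj, x)
    pb <- bn2d_forward(layer$proj_bn, pc$out, training)
    skip <- pb$out
  }
  s <- b2$out + skip
  a2 <- lrelu_forward(layer, s)
  if (training) {
    net$layers[[i]]$bn1$run_mean <- b1$run_mean
    net$layers[[i]]$bn1$run_var <- b1$run_var
    net$layers[[i]]$bn2$run_mean <- b2$run_mean
    net$layers[[i]]$bn2$run_var <- b2$run_var
    if (!is.null(pb)) {
      net$layers[[i]]$proj_bn$run_mean <- pb$run_mean
      net$layers[[i]]$proj_bn$run_var <- pb$run_var
    }
  }
  list(net = net,
       r = list(out = a2$out,
                cache = list(c1 = c1$cache, b1 = b1$cache, a1 = a1$cache,
                             c2 = c2$cache, b2 = b2$cache,
                             pc = if (is.null(pc)) NULL else pc$cache,
                             pb = if (is.null(pb)) NULL else pb$cache,
                             a2 = a2$cache)))
}

resblock_backward <- function(layer, dout, cache) {
  ds <- lrelu_backward(layer, dout, cache$a2)
  rb2 <- bn2d_backward(layer$bn2, ds, cache$b2)
  rc2 <- conv_backward(layer$conv2, rb2$dx, cache$c2)
  da1 <- lrelu_backward(layer, rc2$dx, cache$a1)
  rb1 <- bn2d_backward(layer$bn1, da1, cache$b1)
  rc1 <- conv_backward(layer$conv1, rb1$dx, cache$c1)
  if (is.null(layer$proj)) {
    dskip <- ds
    proj_grads <- NULL
  } else {
    rpb <- bn2d_backward(layer$proj_bn, ds, cache$pb)
    rpc <- conv_backward(layer$proj, rpb$dx, cache$pc)
    dskip <- rpc$dx
    proj_grads <- list(proj = rpc$grads, proj_bn = rpb$grads)
  }
  list(dx = rc1$dx + dskip,
       grads = c(list(conv1 = rc1$grads, bn1 = rb1$grads,
                      conv2 = rc2$grads, bn2 = rb2$grads), proj_grads))
}

## ---- loss and optimizer ---------------------------------------------------

# Numerically stable binary cross-entropy on logits; supports soft targets.
# Returns mean loss and d(loss)/d(logits).
bce_with_logits <- function(z, y) {
  n <- length(z)
  loss <- mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
  p <- stats::plogis(z)
  list(loss = loss, dz = (p - y) / n)
}

# Flat walk over all parameter arrays of a net (for Adam and coef()).
param_paths <- function(net) {
  paths <- list()
  for (i in seq_along(net$layers)) {
    layer <- net$layers[[i]]
    if (layer$type == "resblock") {
      subs <- c("conv1", "bn1", "conv2", "bn2",
                if (!is.null(layer$proj)) c("proj", "proj_bn"))
      for (s in subs)
        for (p in names(layer[[s]]$params))
          paths[[length(paths) + 1L]] <- c(i, s, p)
    } else if (!is.null(layer$params)) {
      for (p in names(layer$params))
        paths[[length(paths) + 1L]] <- c(i, NA, p)
    }
  }
  paths
}

get_param <- function(net, path) {
  i <- as.integer(path[1])
  if (is.na(path[2])) net$layers[[i]]$params[[path[3]]]
  else net$layers[[i]][[path[2]]]$params[[path[3]]]
}

set_param <- function(net, path, value) {
  i <- as.integer(path[1])
  if (is.na(path[2])) net$layers[[i]]$params[[path[3]]] <- value
  else net$layers[[i]][[path[2]]]$params[[path[3]]] <- value
  net
}

get_grad <- function(grads, path) {
  i <- as.integer(path[1])
  if (is.na(path[2])) grads[[i]][[path[3]]]
  else grads[[i]][[path[2]]][[path[3]]]
}

adam_init <- function(net) {
  paths <- param_paths(net)
  list(paths = paths, t = 0L,
       m = lapply(paths, function(p) get_param(net, p) * 0),
       v = lapply(paths, function(p) get_param(net, p) * 0))
}

adam_step <- function(net, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (j in seq_along(state$paths)) {
    p <- state$paths[[j]]
    g <- get_grad(grads, p)
    state$m[[j]] <- beta1 * state$m[[j]] + (1 - beta1) * g
    state$v[[j]] <- beta2 * state$v[[j]] + (1 - beta2) * g * g
    upd <- lr * (state$m[[j]] / bc1) / (sqrt(state$v[[j]] / bc2) + eps)
    net <- set_param(net, p, get_param(net, p) - upd)
  }
  list(net = net, state = state)
}

nn_count_params <- function(net) {
  sum(vapply(param_paths(net), function(p) length(get_param(net, p)),
             numeric(1)))
}

## ---- prediction -----------------------------------------------------------

# x: (20, 50, 1, N) array -> probability vector of length N.
nn_predict_probs <- function(net, x, batch_size = 256L) {
  N <- dim(x)[4]
  if (N == 0L) return(numeric(0))
  out <- numeric(N)
  for (s in seq(1L, N, by = batch_size)) {
    e <- min(s + batch_size - 1L, N)
    xb <- x[, , , s:e, drop = FALSE]
    z <- nn_forward(net, xb, training = FALSE)$out
    out[s:e] <- stats::plogis(as.numeric(z))
  }
  out
}
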
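# Minimal convolutional-network engine (pure R, im2col convolutions).
#
# Feature maps are numeric arrays [H, W, C]. A convolution weight is stored
# as a matrix (Cout x k*k*Cin), column index ki + (kj-1)*k + (c-1)*k^2, so
# forward passes are single matrix products against the im2col matrix.
# Transposed convolutions reuse the same machinery with the roles of
# forward and backward-data swapped. Everything is deterministic; all
# randomness (weight init, epoch shuffling) flows from the training seed.

nnIm2col <- function(x, k, stride, pad) {
  d <- dim(x); h <- d[1]; w <- d[2]; cc <- d[3]
  ho <- (h + 2L * pad - k) %/% stride + 1L
  wo <- (w + 2L * pad - k) %/% stride + 1L
  xp <- if (pad > 0L) {
    tmp <- array(0, c(h + 2L * pad, w + 2L * pad, cc))
    tmp[(pad + 1L):(pad + h), (pad + 1L):(pad + w), ] <- x
    tmp
  } else x
  oi <- (seq_len(ho) - 1L) * stride
  oj <- (seq_len(wo) - 1L) * stride
  col <- matrix(0, k * k * cc, ho * wo)
  for (c3 in seq_len(cc)) for (kj in seq_len(k)) for (ki in seq_len(k)) {
    r <- ki + (kj - 1L) * k + (c3 - 1L) * k * k
    col[r, ] <- xp[oi + ki, oj + kj, c3]
  }
  list(col = col, ho = ho, wo = wo, dimIn = d)
}

nnCol2im <- function(col, dimIn, k, stride, pad, ho, wo) {
  h <- dimIn[1]; w <- dimIn[2]; cc <- dimIn[3]
  xp <- array(0, c(h + 2L * pad, w + 2L * pad, cc))
  oi <- (seq_len(ho) - 1L) * stride
  oj <- (seq_len(wo) - 1L) * stride
  for (c3 in seq_len(cc)) for (kj in seq_len(k)) for (ki in seq_len(k)) {
    r <- ki + (kj - 1L) * k + (c3 - 1L) * k * k
    xp[oi + ki, oj + kj, c3] <- xp[oi + ki, oj + kj, c3] +
      matrix(col[r, ], ho, wo)
  }
  xp[(pad + 1L):(pad + h), (pad + 1L):(pad + w), , drop = FALSE]
}

nnConvForward <- function(x, W, b, k, stride, pad) {
  ic <- nnIm2col(x, k, stride, pad)
  ym <- W %*% ic$col + b
  y <- array(as.vector(t(ym)), c(ic$ho, ic$wo, nrow(W)))
  list(y = y, col = ic$col, ho = ic$ho, wo = ic$wo, dimIn = ic$dimIn)
}

nnConvBackward <- function(dy, W, cache, k, stride, pad) {
  co <- dim(dy)[3]
  dym <- t(matrix(dy, cache$ho * cache$wo, co))
  db <- rowSums(dym)
  dW <- dym %*% t(cache$col)
  dcol <- t(W) %*% dym
  dx <- nnCol2im(dcol, cache$dimIn, k, stride, pad, cache$ho, cache$wo)
  list(dx = dx, dW = dW, db = db)
}

# transposed convolution: output spatial size (H-1)*stride - 2*pad + k;
# weight V is (Cin x k*k*Cout), the layout of a conv mapping output -> input
nnConvTForward <- function(x, V, b, k, stride, pad) {
  d <- dim(x); h <- d[1]; w <- d[2]; ci <- d[3]
  ho <- (h - 1L) * stride - 2L * pad + k
  wo <- (w - 1L) * stride - 2L * pad + k
  co <- ncol(V) / (k * k)
  xm <- t(matrix(x, h * w, ci))
  ycol <- t(V) %*% xm
  y <- nnCol2im(ycol, c(ho, wo, co), k, stride, pad, h, w)
  y <- y + array(rep(b, each = ho * wo), c(ho, wo, co))
  list(y = y, xm = xm, hin = h, win = w)
}

nnConvTBackward <- function(dy, V, cache, k, stride, pad) {
  ic <- nnIm2col(dy, k, stride, pad)       # positions match the input grid
  dxm <- V %*% ic$col
  dx <- array(as.vector(t(dxm)), c(cache$hin, cache$win, nrow(V)))
  dV <- cache$xm %*% t(ic$col)
  db <- apply(dy, 3, sum)
  list(dx = dx, dV = dV, db = db)
}

# instance normalization over each channel's spatial extent
nnInormForward <- function(x, g, be, eps = 1e-5) {
  d <- dim(x); n <- d[1] * d[2]
  xm <- matrix(x, n, d[3])
  mu <- colMeans(xm)
  xc <- sweep(xm, 2, mu)
  v <- colMeans(xc^2)
  ivar <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, ivar, `*`)
  y <- sweep(sweep(xhat, 2, g, `*`), 2, be, `+`)
  list(y = array(y, d), xhat = xhat, ivar = ivar, dimIn = d)
}

nnInormBackward <- function(dy, g, cache) {
  d <- cache$dimIn; n <- d[1] * d[2]
  dym <- matrix(dy, n, d[3])
  dg <- colSums(dym * cache$xhat)
  dbe <- colSums(dym)
  dxhat <- sweep(dym, 2, g, `*`)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  dxm <- sweep(dxhat, 2, s1 / n) - sweep(cache$xhat, 2, s2 / n, `*`)
  dxm <- sweep(dxm, 2, cache$ivar, `*`)
  list(dx = array(dxm, d), dg = dg, dbe = dbe)
}

nnAct <- function(x, act) {
  switch(act,
         lrelu = ifelse(x > 0, x, 0.2 * x),
         relu = pmax(x, 0),
         tanh = tanh(x),
         none = x)
}

nnActBackward <- function(dy, x, y, act) {
  switch(act,
         lrelu = dy * ifelse(x > 0, 1, 0.2),
         relu = dy * (x > 0),
         tanh = dy * (1 - y^2),
         none = dy)
}

bceWithLogits <- function(z, target) {
  mean(pmax(z, 0) - z * target + log1p(exp(-abs(z))))
}

bceWithLogitsGrad <- function(z, target) {
  (1 / (1 + exp(-z)) - target) / length(z)
}

# ---- layer blocks -------------------------------------------------------

newConvLayer <- function(cin, cout, k = 4L, stride = 2L, pad = 1L,
                         norm = TRUE, act = "lrelu", transpose = FALSE) {
  sdW <- 0.02
  W <- if (transpose) {
    matrix(rnorm(cin * k * k * cout, 0, sdW), cin, k * k * cout)
  } else {
    matrix(rnorm(cout * k * k * cin, 0, sdW), cout, k * k * cin)
  }
  list(W = W, b = numeric(cout),
       g = rep(1, cout), be = numeric(cout),
       k = k, stride = stride, pad = pad, norm = norm, act = act,
       transpose = transpose, cout = cout)
}

blockForward <- function(layer, x) {
  if (layer$transpose) {
    cf <- nnConvTForward(x, layer$W, layer$b, layer$k, layer$stride,
                         layer$pad)
  } else {
    cf <- nnConvForward(x, layer$W, layer$b, layer$k, layer$stride,
                        layer$pad)
  }
  h <- cf$y
  normed <- layer$norm && prod(dim(h)[1:2]) > 1L
  nf <- NULL
  if (normed) {
    nf <- nnInormForward(h, layer$g, layer$be)
    h <- nf$y
  }
  out <- nnAct(h, layer$act)
  list(out = out,
       cache = list(conv = cf, norm = nf, normed = normed,
                    preAct = h, postAct = out))
}

blockBackward <- function(layer, cache, dout) {
  dh <- nnActBackward(dout, cache$preAct, cache$postAct, layer$act)
  dg <- numeric(layer$cout); dbe <- numeric(layer$cout)
  if (cache$normed) {
    nb <- nnInormBackward(dh, layer$g, cache$norm)
    dh <- nb$dx; dg <- nb$dg; dbe <- nb$dbe
  }
  if (layer$transpose) {
    cb <- nnConvTBackward(dh, layer$W, cache$conv, layer$k, layer$stride,
                          layer$pad)
    list(dx = cb$dx, grads = list(W = cb$dV, b = cb$db, g = dg, be = dbe))
  } else {
    cb <- nnConvBackward(dh, layer$W, cache$conv, layer$k, layer$stride,
                         layer$pad)
    list(dx = cb$dx, grads = list(W = cb$dW, b = cb$db, g = dg, be = dbe))
  }
}

bindChannels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  array(c(a, b), c(da[1], da[2], da[3] + db[3]))
}

# ---- generator (U-Net with skip connections, no dropout) ----------------

initGenerator <- function(depth, nf, inCh = 3L, outCh = 3L) {
  encCh <- nf * pmin(2^(seq_len(depth) - 1L), 8L)
  enc <- vector("list", depth)
  cin <- inCh
  for (i in seq_len(depth)) {
    enc[[i]] <- newConvLayer(cin, encCh[i], norm = i > 1L, act = "lrelu")
    cin <- encCh[i]
  }
  dec <- if (depth > 1L) vector("list", depth - 1L) else list()
  for (j in seq_len(max(depth - 1L, 0L))) {
    cinD <- if (j == 1L) encCh[depth] else 2L * encCh[depth - j + 1L]
    dec[[j]] <- newConvLayer(cinD, encCh[depth - j], norm = TRUE,
                             act = "relu", transpose = TRUE)
  }
  cinF <- if (depth > 1L) 2L * encCh[1] else encCh[1]
  fin <- newConvLayer(cinF, outCh, norm = FALSE, act = "tanh",
                      transpose = TRUE)
  list(enc = enc, dec = dec, fin = fin, depth = depth)
}

gForward <- function(G, x) {
  d <- G$depth
  skips <- vector("list", d)
  caches <- list(enc = vector("list", d), dec = vector("list", length(G$dec)))
  h <- x
  for (i in seq_len(d)) {
    bf <- blockForward(G$enc[[i]], h)
    caches$enc[[i]] <- bf$cache
    h <- bf$out
    skips[[i]] <- h
  }
  for (j in seq_along(G$dec)) {
    bf <- blockForward(G$dec[[j]], h)
    caches$dec[[j]] <- bf$cache
    h <- bindChannels(bf$out, skips[[d - j]])
  }
  bf <- blockForward(G$fin, h)
  caches$fin <- bf$cache
  list(out = bf$out, caches = caches)
}

gBackward <- function(G, caches, dout) {
  d <- G$depth
  grads <- list(enc = vector("list", d), dec = vector("list", length(G$dec)))
  dskip <- vector("list", d)
  bb <- blockBackward(G$fin, caches$fin, dout)
  grads$fin <- bb$grads
  dh <- bb$dx
  for (j in rev(seq_along(G$dec))) {
    chT <- G$dec[[j]]$cout
    dT <- dh[, , seq_len(chT), drop = FALSE]
    dS <- dh[, , -seq_len(chT), drop = FALSE]
    dskip[[d - j]] <- if (is.null(dskip[[d - j]])) dS else dskip[[d - j]] + dS
    bb <- blockBackward(G$dec[[j]], caches$dec[[j]], dT)
    grads$dec[[j]] <- bb$grads
    dh <- bb$dx
  }
  # dh now holds the gradient w.r.t. the deepest encoder output
  dacc <- dh
  for (i in rev(seq_len(d))) {
    if (!is.null(dskip[[i]])) dacc <- dacc + dskip[[i]]
    bb <- blockBackward(G$enc[[i]], caches$enc[[i]], dacc)
    grads$enc[[i]] <- bb$grads
    dacc <- bb$dx
  }
  grads
}

# ---- discriminator (PatchGAN over concatenated H&E/CK input) ------------

initDiscriminator <- function(nLayers, ndf, inCh = 6L) {
  layers <- list()
  cin <- inCh
  for (i in seq_len(nLayers)) {
    cout <- ndf * min(2^(i - 1L), 8L)
    layers[[i]] <- newConvLayer(cin, cout, stride = 2L, norm = i > 1L,
                                act = "lrelu")
    cin <- cout
  }
  cout <- ndf * min(2^nLayers, 8L)
  layers[[nLayers + 1L]] <- newConvLayer(cin, cout, stride = 1L,
                                         norm = TRUE, act = "lrelu")
  layers[[nLayers + 2L]] <- newConvLayer(cout, 1L, stride = 1L,
                                         norm = FALSE, act = "none")
  list(layers = layers)
}

dForward <- function(D, xy) {
  caches <- vector("list", length(D$layers))
  h <- xy
  for (i in seq_along(D$layers)) {
    bf <- blockForward(D$layers[[i]], h)
    caches[[i]] <- bf$cache
    h <- bf$out
  }
  list(logits = h, caches = caches)
}

dBackward <- function(D, caches, dlogits) {
  grads <- vector("list", length(D$layers))
  dh <- dlogits
  for (i in rev(seq_along(D$layers))) {
    bb <- blockBackward(D$layers[[i]], caches[[i]], dh)
    grads[[i]] <- bb$grads
    dh <- bb$dx
  }
  list(grads = list(layers = grads), dInput = dh)
}

# ---- Adam over arbitrarily nested parameter lists -----------------------

.paramLeaves <- c("W", "b", "g", "be")

adamInit <- function(params) {
  walk <- function(p) {
    out <- list()
    for (nm in names(p)) {
      if (nm %in% .paramLeaves && is.numeric(p[[nm]])) {
        out[[nm]] <- list(m = p[[nm]] * 0, v = p[[nm]] * 0)
      } else if (is.list(p[[nm]])) out[[nm]] <- walk(p[[nm]])
    }
    if (is.null(names(p)) && length(p)) {
      out <- lapply(p, walk)
    }
    out
  }
  list(s = walk(params), t = 0L)
}

adamStep <- function(params, grads, state, lr, beta1 = 0.5, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  walk <- function(p, g, s) {
    if (is.null(names(p)) && is.list(p)) {
      for (i in seq_along(p)) {
        r <- walk(p[[i]], g[[i]], s[[i]])
        p[[i]] <- r$p; s[[i]] <- r$s
      }
      return(list(p = p, s = s))
    }
    for (nm in names(p)) {
      if (nm %in% .paramLeaves && is.numeric(p[[nm]])) {
        s[[nm]]$m <- beta1 * s[[nm]]$m + (1 - beta1) * g[[nm]]
        s[[nm]]$v <- beta2 * s[[nm]]$v + (1 - beta2) * g[[nm]]^2
        mhat <- s[[nm]]$m / (1 - beta1^t)
        vhat <- s[[nm]]$v / (1 - beta2^t)
        p[[nm]] <- p[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      } else if (is.list(p[[nm]]) && !is.null(g[[nm]])) {
        r <- walk(p[[nm]], g[[nm]], s[[nm]])
        p[[nm]] <- r$p; s[[nm]] <- r$s
      }
    }
    list(p = p, s = s)
  }
  r <- walk(params, grads, state$s)
  list(params = r$p, state = list(s = r$s, t = t))
}
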
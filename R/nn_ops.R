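# Neural-network primitives on token matrices (N tokens x C channels) and
# H x W x C arrays, each with a hand-derived backward pass. Token order is
# column-major (R array order): token t = (c - 1) * h + r for 1-based
# spatial (r, c), so token matrices reshape to arrays without transposes.

.tp_nn_cache <- new.env(parent = emptyenv())

tp_cached <- function(key, builder) {
  if (is.null(.tp_nn_cache[[key]])) .tp_nn_cache[[key]] <- builder()
  .tp_nn_cache[[key]]
}

# truncated-normal initializer (transformer convention)
init_trunc_normal <- function(n, sd = 0.02) {
  x <- rnorm(n * 2, sd = sd)
  x <- x[abs(x) <= 2 * sd]
  while (length(x) < n) {
    y <- rnorm(n, sd = sd)
    x <- c(x, y[abs(y) <= 2 * sd])
  }
  x[seq_len(n)]
}

init_linear <- function(din, dout, sd = 0.02) {
  list(W = matrix(init_trunc_normal(din * dout, sd), din, dout),
       b = numeric(dout))
}

linear_fwd <- function(x, W, b) {
  list(out = x %*% W + rep(b, each = nrow(x)), x = x)
}

linear_bwd <- function(cache, dout, W) {
  list(dx = dout %*% t(W), dW = crossprod(cache$x, dout), db = colSums(dout))
}

silu_fwd <- function(x) {
  s <- 1 / (1 + exp(-x))
  list(out = x * s, x = x, s = s)
}

silu_bwd <- function(cache, dout) {
  dout * (cache$s * (1 + cache$x * (1 - cache$s)))
}

layernorm_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * inv
  list(out = xhat * rep(g, each = nrow(x)) + rep(b, each = nrow(x)),
       xhat = xhat, inv = inv)
}

layernorm_bwd <- function(cache, dout, g) {
  xhat <- cache$xhat
  dxh <- dout * rep(g, each = nrow(dout))
  dx <- cache$inv * (dxh - rowMeans(dxh) - xhat * rowMeans(dxh * xhat))
  list(dx = dx, dg = colSums(dout * xhat), db = colSums(dout))
}

# ---- strided convolution (patch embedding) via im2col -----------------------

conv_geom <- function(hin, win, cin, k, stride, pad) {
  key <- paste("conv", hin, win, cin, k, stride, pad, sep = "_")
  tp_cached(key, function() {
    hout <- (hin + 2 * pad - k) %/% stride + 1
    wout <- (win + 2 * pad - k) %/% stride + 1
    hp <- hin + 2 * pad; wp <- win + 2 * pad
    n <- hout * wout
    # token t column-major over (r_out, c_out); column block per (kr, kc, ch)
    r0 <- rep(seq_len(hout), times = wout)  # output row per token
    c0 <- rep(seq_len(wout), each = hout)
    idx <- matrix(0L, n, k * k * cin)
    col <- 0L
    for (ch in seq_len(cin)) for (kr in seq_len(k)) for (kc in seq_len(k)) {
      col <- col + 1L
      rr <- (r0 - 1L) * stride + kr          # 1-based row in padded input
      cc <- (c0 - 1L) * stride + kc
      idx[, col] <- rr + (cc - 1L) * hp + (ch - 1L) * hp * wp
    }
    list(hout = hout, wout = wout, idx = idx, hp = hp, wp = wp)
  })
}

conv2d_fwd <- function(x, W, b, k, stride, pad) {
  hin <- dim(x)[1]; win <- dim(x)[2]; cin <- dim(x)[3]
  g <- conv_geom(hin, win, cin, k, stride, pad)
  xp <- array(0, c(g$hp, g$wp, cin))
  xp[pad + seq_len(hin), pad + seq_len(win), ] <- x
  cols <- matrix(as.vector(xp)[g$idx], nrow(g$idx), ncol(g$idx))
  out <- cols %*% W + rep(b, each = nrow(cols))
  list(out = out, cols = cols, geom = g,
       dims = c(hin = hin, win = win, cin = cin, k = k, stride = stride, pad = pad))
}

conv2d_bwd <- function(cache, dout, W) {
  g <- cache$geom; d <- cache$dims
  dW <- crossprod(cache$cols, dout)
  db <- colSums(dout)
  dcols <- dout %*% t(W)
  dxp <- numeric(g$hp * g$wp * d[["cin"]])
  for (j in seq_len(ncol(g$idx))) {
    ii <- g$idx[, j]
    dxp[ii] <- dxp[ii] + dcols[, j]
  }
  dxp <- array(dxp, c(g$hp, g$wp, d[["cin"]]))
  dx <- dxp[d[["pad"]] + seq_len(d[["hin"]]), d[["pad"]] + seq_len(d[["win"]]), , drop = FALSE]
  list(dx = dx, dW = dW, db = db)
}

# ---- 3x3 depthwise convolution on token matrices ----------------------------

dw_geom <- function(h, w) {
  key <- paste("dw", h, w, sep = "_")
  tp_cached(key, function() {
    r <- rep(seq_len(h), times = w)
    c <- rep(seq_len(w), each = h)
    idx <- vector("list", 9L)
    o <- 0L
    for (dr in -1:1) for (dc in -1:1) {
      o <- o + 1L
      rr <- r + dr; cc <- c + dc
      ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
      ii <- integer(h * w)          # 0 = out of bounds -> zero row
      ii[ok] <- (cc[ok] - 1L) * h + rr[ok]
      idx[[o]] <- ii
    }
    idx
  })
}

# X: N x C tokens; Wd: 9 x C per-channel kernel; bd: length C
dwconv_fwd <- function(X, h, w, Wd, bd) {
  idx <- dw_geom(h, w)
  n <- nrow(X); C <- ncol(X)
  Xp <- rbind(numeric(C), X)        # row 1 is the zero row
  out <- rep(bd, each = n)
  dim(out) <- c(n, C)
  for (o in 1:9) out <- out + Xp[idx[[o]] + 1L, , drop = FALSE] *
      rep(Wd[o, ], each = n)
  list(out = out, X = X, h = h, w = w)
}

dwconv_bwd <- function(cache, dout, Wd) {
  idx <- dw_geom(cache$h, cache$w)
  n <- nrow(dout); C <- ncol(dout)
  Xp <- rbind(numeric(C), cache$X)
  dW <- matrix(0, 9, C)
  dXp <- matrix(0, n + 1L, C)
  for (o in 1:9) {
    Xs <- Xp[idx[[o]] + 1L, , drop = FALSE]
    dW[o, ] <- colSums(Xs * dout)
    contrib <- dout * rep(Wd[o, ], each = n)
    tgt <- idx[[o]] + 1L
    keep <- tgt > 1L
    dXp[tgt[keep], ] <- dXp[tgt[keep], , drop = FALSE] + contrib[keep, , drop = FALSE]
  }
  list(dx = dXp[-1L, , drop = FALSE], dW = dW, db = colSums(dout))
}

# ---- bilinear resampling as a cached sparse operator ------------------------

bilinear_op <- function(hin, win, hout, wout) {
  key <- paste("bilin", hin, win, hout, wout, sep = "_")
  tp_cached(key, function() {
    sy <- hin / hout; sx <- win / wout
    r <- rep(seq_len(hout), times = wout)
    c <- rep(seq_len(wout), each = hout)
    fy <- pmin(pmax((r - 0.5) * sy - 0.5, 0), hin - 1)
    fx <- pmin(pmax((c - 0.5) * sx - 0.5, 0), win - 1)
    y0 <- floor(fy); x0 <- floor(fx)
    y1 <- pmin(y0 + 1, hin - 1); x1 <- pmin(x0 + 1, win - 1)
    wy <- fy - y0; wx <- fx - x0
    n <- hout * wout
    rows <- rep(seq_len(n), 4L)
    cols <- c(x0 * hin + y0, x1 * hin + y0, x0 * hin + y1, x1 * hin + y1) + 1
    vals <- c((1 - wy) * (1 - wx), (1 - wy) * wx, wy * (1 - wx), wy * wx)
    Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(n, hin * win))
  })
}

upsample_fwd <- function(X, hin, win, hout, wout) {
  A <- bilinear_op(hin, win, hout, wout)
  list(out = as.matrix(A %*% X), A = A)
}

upsample_bwd <- function(cache, dout) {
  as.matrix(Matrix::crossprod(cache$A, dout))
}

# token matrix <-> spatial array (column-major token order: free reshape)
tok2arr <- function(X, h, w) {
  array(X, c(h, w, ncol(X)))
}

arr2tok <- function(a) {
  d <- dim(a)
  matrix(a, d[1] * d[2], d[3])
}
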
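#' Positive kernel feature map for linear attention
#'
#' `elu(x) + 1`: strictly positive for all finite inputs, so the linear
#' attention denominator never vanishes; approaches 0+ monotonically for
#' large negative inputs and is identity + 1 on the positive side.
#'
#' @param x numeric vector/matrix.
#' @return same shape as `x`, strictly positive.
#' @export
kernel_phi <- function(x) {
  exp(pmin(x, 0)) + pmax(x, 0)
}

kernel_phi_grad <- function(x) {
  exp(pmin(x, 0))
}

#' Linear attention (factored, quadratic-reference and recurrent forms)
#'
#' Kernelized attention without softmax:
#' \deqn{y_i = \frac{\sum_j (Q_i K_j^\top) V_j}{\sum_j Q_i K_j^\top}
#'           = \frac{Q_i (\sum_j K_j^\top V_j)}{Q_i (\sum_j K_j^\top)}}
#' The factored (`parallel`) form accumulates the key-value summary
#' `S = sum K_j^T V_j` and key summary `Z = sum K_j` once, giving O(N)
#' cost; `quadratic` evaluates the left-hand double sum directly (O(N^2)
#' reference); `recurrent` performs the running-state updates
#' `S_i = S_{i-1} + K_i^T V_i`, `Z_i = Z_{i-1} + K_i`. With
#' `causal = TRUE` token i attends to tokens `1..i` (the running-state
#' semantics); otherwise all tokens attend to the full sequence. All three
#' forms are algebraically identical in either setting.
#'
#' @param Q,K nonnegative feature-mapped queries/keys (apply [kernel_phi()]
#'   first), N x d matrices.
#' @param V values, N x dv.
#' @param mode evaluation strategy (results agree to numerical precision).
#' @param causal restrict attention of token i to tokens `1..i`.
#' @param eps denominator guard.
#' @return N x dv output matrix.
#' @export
linear_attention <- function(Q, K, V,
                             mode = c("parallel", "quadratic", "recurrent"),
                             causal = FALSE, eps = 1e-6) {
  mode <- match.arg(mode)
  n <- nrow(Q)
  if (n < 1L) tp_stop("sequence length must be >= 1", "tp_format_error")
  if (mode == "quadratic") {
    Aff <- Q %*% t(K)
    if (causal) Aff[upper.tri(Aff)] <- 0
    return((Aff %*% V) / (rowSums(Aff) + eps))
  }
  if (mode == "recurrent") {
    S <- matrix(0, ncol(Q), ncol(V))
    Z <- numeric(ncol(Q))
    out <- matrix(0, n, ncol(V))
    for (i in seq_len(n)) {
      S <- S + tcrossprod(K[i, ], V[i, ])
      Z <- Z + K[i, ]
      if (causal) out[i, ] <- (Q[i, ] %*% S) / (sum(Q[i, ] * Z) + eps)
    }
    if (!causal) {
      num <- Q %*% S
      out <- num / (Q %*% Z + eps)[, 1]
    }
    return(out)
  }
  if (causal) {
    out <- matrix(0, n, ncol(V))
    S <- matrix(0, ncol(Q), ncol(V))
    Z <- numeric(ncol(Q))
    for (i in seq_len(n)) {            # parallel-causal via prefix sums
      S <- S + tcrossprod(K[i, ], V[i, ])
      Z <- Z + K[i, ]
      out[i, ] <- (Q[i, ] %*% S) / (sum(Q[i, ] * Z) + eps)
    }
    return(out)
  }
  S <- crossprod(K, V)
  Z <- colSums(K)
  num <- Q %*% S
  num / (Q %*% Z + eps)[, 1]
}

# differentiable single-head linear attention (full, non-causal)
lin_attn_fwd <- function(Q, K, V, eps = 1e-6) {
  S <- crossprod(K, V)
  Z <- colSums(K)
  num <- Q %*% S
  den <- (Q %*% Z + eps)[, 1]
  list(out = num / den, Q = Q, K = K, V = V, S = S, Z = Z, num = num, den = den)
}

lin_attn_bwd <- function(cache, dout) {
  den <- cache$den
  dnum <- dout / den
  dden <- -rowSums(dout * cache$num) / den^2
  dQ <- dnum %*% t(cache$S) + outer(dden, cache$Z)
  dS <- crossprod(cache$Q, dnum)
  dZ <- crossprod(cache$Q, dden)[, 1]
  dK <- cache$V %*% t(dS) + matrix(dZ, nrow(cache$K), ncol(cache$K), byrow = TRUE)
  dV <- cache$K %*% dS
  list(dQ = dQ, dK = dK, dV = dV)
}

#' Rotary position embedding over 2-D positions
#'
#' Rotates consecutive feature pairs by position-dependent angles so that
#' query-key inner products encode relative position. The feature dimension
#' is split in half: the first half's pairs rotate with the row coordinate,
#' the second half's with the column coordinate; pair `f` (within a half of
#' `d/4` pairs) uses frequency `theta_base^-(f-1)/(d/4)`. The map is
#' norm-preserving and position 0 is the identity.
#'
#' @param x N x d feature matrix, `d` divisible by 4.
#' @param positions N x 2 matrix of (row, col) token positions (any real
#'   units).
#' @param theta_base frequency base.
#' @return rotated N x d matrix.
#' @export
rope_encode <- function(x, positions, theta_base = 10000) {
  d <- ncol(x)
  if (d %% 4 != 0) tp_stop("feature dimension must be divisible by 4", "tp_config_error")
  positions <- rbind(positions)
  ang <- rope_angles(positions, d, theta_base)
  rope_apply(x, ang$cosA, ang$sinA)
}

rope_angles <- function(positions, d, theta_base = 10000) {
  npair <- d / 4
  freqs <- theta_base^(-(seq_len(npair) - 1) / npair)
  A <- cbind(outer(positions[, 1], freqs), outer(positions[, 2], freqs))
  list(cosA = cos(A), sinA = sin(A))
}

# pairs are (2p-1, 2p); angle matrix is N x d/2
rope_apply <- function(x, cosA, sinA) {
  d <- ncol(x)
  odd <- seq(1, d, by = 2); even <- seq(2, d, by = 2)
  x1 <- x[, odd, drop = FALSE]; x2 <- x[, even, drop = FALSE]
  out <- x
  out[, odd] <- x1 * cosA - x2 * sinA
  out[, even] <- x1 * sinA + x2 * cosA
  out
}

# backward = rotation by the negative angle
rope_apply_bwd <- function(dout, cosA, sinA) {
  rope_apply(dout, cosA, -sinA)
}

# cached per-head angle tables for an h x w token grid (column-major order)
rope_tables <- function(h, w, dh, theta_base = 10000) {
  key <- paste("rope", h, w, dh, theta_base, sep = "_")
  tp_cached(key, function() {
    pos <- cbind(rep(seq_len(h) - 1, times = w), rep(seq_len(w) - 1, each = h))
    rope_angles(pos, dh, theta_base)
  })
}

#' Locally-enhanced positional encoding
#'
#' `LePE(x) = x + DWConv(x) W_L`: the identity plus a depthwise 3x3
#' convolution of the value tokens (in their 2-D spatial layout) mixed by a
#' learned pointwise matrix. With zero-initialized kernel or `W_L` it is
#' the identity.
#'
#' @param v N x C value tokens, N = h * w in row-major order.
#' @param h,w spatial layout of the token sequence.
#' @param dw 9 x C (or 3 x 3 x C) depthwise kernel.
#' @param W_L C x C pointwise mixing matrix.
#' @param b length-C bias of the depthwise convolution.
#' @return N x C position-enhanced values.
#' @export
lepe <- function(v, h, w, dw, W_L, b = numeric(ncol(v))) {
  if (nrow(v) != h * w)
    tp_stop("token count does not factor into the given spatial shape", "tp_config_error")
  if (length(dim(dw)) == 3L) dw <- matrix(dw, 9, dim(dw)[3])
  d <- dwconv_fwd(v, h, w, dw, b)
  v + d$out %*% W_L
}
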
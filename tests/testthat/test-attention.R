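test_that("the attention kernel is strictly positive and well-behaved", {
  expect_equal(kernel_phi(0), 1)
  x <- seq(-30, 30, by = 0.25)
  expect_true(all(kernel_phi(x) > 0))
  expect_true(all(diff(kernel_phi(x)) > 0))      # monotone
  expect_lt(kernel_phi(-30), 1e-12)              # -> 0+ for large negative input
  expect_equal(kernel_phi(5), 6)                 # identity + 1 on the positive side
})

test_that("factored, quadratic and recurrent linear attention agree", {
  set.seed(17)
  for (rep in 1:50) {
    n <- sample(1:16, 1); d <- sample(c(2, 4, 8), 1); dv <- sample(c(2, 4, 8), 1)
    Q <- kernel_phi(matrix(rnorm(n * d), n, d))
    K <- kernel_phi(matrix(rnorm(n * d), n, d))
    V <- matrix(rnorm(n * dv), n, dv)
    yp <- linear_attention(Q, K, V, "parallel")
    expect_lt(max(abs(yp - linear_attention(Q, K, V, "quadratic"))), 1e-5)
    expect_lt(max(abs(yp - linear_attention(Q, K, V, "recurrent"))), 1e-5)
    # running-state (causal) semantics agree across all three forms too
    yc <- linear_attention(Q, K, V, "parallel", causal = TRUE)
    expect_lt(max(abs(yc - linear_attention(Q, K, V, "quadratic", causal = TRUE))), 1e-5)
    expect_lt(max(abs(yc - linear_attention(Q, K, V, "recurrent", causal = TRUE))), 1e-5)
  }
})

test_that("a single token passes its value through attention", {
  set.seed(3)
  Q <- kernel_phi(matrix(rnorm(4), 1, 4))
  K <- kernel_phi(matrix(rnorm(4), 1, 4))
  V <- matrix(rnorm(6), 1, 6)
  expect_equal(linear_attention(Q, K, V), V, tolerance = 1e-5)
})

test_that("rotary embedding preserves norms and encodes relative position", {
  set.seed(5)
  x <- matrix(rnorm(6 * 8), 6, 8)
  pos <- cbind(c(0, 1, 2, 0, 3, 5), c(0, 0, 1, 4, 2, 2))
  xr <- rope_encode(x, pos)
  # position (0, 0) is the identity
  expect_equal(xr[1, ], x[1, ])
  expect_equal(sqrt(rowSums(xr^2)), sqrt(rowSums(x^2)), tolerance = 1e-6)
  expect_error(rope_encode(matrix(rnorm(10), 2, 5), cbind(0:1, 0:1)),
               class = "tp_config_error")

  # <RoPE(q,p1), RoPE(k,p2)> depends only on p1 - p2
  q <- matrix(rnorm(8), 1, 8); k <- matrix(rnorm(8), 1, 8)
  ip <- function(p1, p2) sum(rope_encode(q, rbind(p1)) * rope_encode(k, rbind(p2)))
  for (shift in list(c(1, 0), c(2, 3), c(-1, 4))) {
    expect_equal(ip(c(2, 1), c(5, 3)),
                 ip(c(2, 1) + shift, c(5, 3) + shift), tolerance = 1e-10)
  }
})

test_that("LePE is an identity-plus-local-convolution enhancement", {
  set.seed(8)
  v <- matrix(rnorm(24 * 4), 24, 4)
  zero_dw <- matrix(0, 9, 4); zero_WL <- matrix(0, 4, 4)
  expect_equal(lepe(v, 4, 6, zero_dw, zero_WL), v)
  dw <- matrix(rnorm(36), 9, 4); WL <- matrix(rnorm(16), 4, 4)
  out <- lepe(v, 4, 6, dw, WL)
  expect_identical(dim(out), dim(v))
  expect_error(lepe(v, 5, 6, dw, WL), class = "tp_config_error")
})

test_that("depthwise convolution matches a direct nested-loop oracle", {
  set.seed(12)
  h <- 5; w <- 7; C <- 3
  X <- matrix(rnorm(h * w * C), h * w, C)
  Wd <- matrix(rnorm(9 * C), 9, C)
  bd <- rnorm(C)
  got <- tomatopheno:::dwconv_fwd(X, h, w, Wd, bd)$out
  # oracle: direct zero-padded 3x3 depthwise convolution, column-major tokens
  want <- matrix(0, h * w, C)
  for (ch in seq_len(C)) {
    img <- matrix(X[, ch], h, w)
    o <- 0
    acc <- matrix(bd[ch], h, w)
    for (dr in -1:1) for (dc in -1:1) {
      o <- o + 1
      for (r in 1:h) for (cc in 1:w) {
        rr <- r + dr; c2 <- cc + dc
        if (rr >= 1 && rr <= h && c2 >= 1 && c2 <= w)
          acc[r, cc] <- acc[r, cc] + img[rr, c2] * Wd[o, ch]
      }
    }
    want[, ch] <- as.vector(acc)
  }
  expect_equal(got, want, tolerance = 1e-12)
  # constant input with an averaging kernel stays constant in the interior
  Xc <- matrix(2, h * w, C)
  avg <- matrix(1 / 9, 9, C)
  oc <- tomatopheno:::dwconv_fwd(Xc, h, w, avg, numeric(C))$out
  interior <- as.vector(matrix(seq_len(h * w), h, w)[2:(h - 1), 2:(w - 1)])
  expect_equal(oc[interior, ], matrix(2, length(interior), C), ignore_attr = TRUE)
})
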
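test_that("configuration validates its invariants", {
  expect_error(mlla_config("a", embed_dims = c(30L, 64L, 160L, 256L)),
               class = "tp_config_error")     # not divisible by heads
  expect_error(mlla_config("a", dropout = 1), class = "tp_config_error")
  cfg <- mlla_config("b")
  expect_identical(cfg$embed_dims, c(64L, 128L, 320L, 512L))
  expect_identical(cfg$depths, c(3L, 4L, 6L, 3L))
  expect_identical(cfg$downsample_rates, c(4L, 8L, 16L, 32L))
})

test_that("the encoder produces the 1/4, 1/8, 1/16, 1/32 pyramid and full-size logits", {
  m <- segformer_mlla(tiny_config(), seed = 1)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3))
  fw <- segformer_forward(m, x)
  expect_equal(fw$stage_dims[, 1], c(16, 8, 4, 2))
  expect_equal(fw$stage_dims[, 2], c(16, 8, 4, 2))
  expect_identical(dim(fw$logits), c(64L * 64L, 2L))
  expect_error(segformer_forward(m, array(0, c(50, 50, 3))), class = "tp_config_error")
  # deterministic without dropout
  fw2 <- segformer_forward(m, x)
  expect_identical(fw$logits, fw2$logits)
  lab <- segment_image(m, x)
  expect_identical(dim(lab), c(64L, 64L))
  expect_true(all(lab %in% c(0L, 1L)))
})

test_that("hybrid loss matches its component formulas", {
  set.seed(2)
  n <- 40
  target <- sample(0:1, n, TRUE)
  logits <- matrix(rnorm(n * 2), n, 2)
  # CE-only and Dice-only reduce to independent direct evaluations
  p <- exp(logits) / rowSums(exp(logits))
  ce_direct <- -mean(log(p[cbind(1:n, target + 1)]))
  expect_equal(hybrid_loss(logits, target, w_ce = 1, w_dice = 0)$loss, ce_direct)
  pc <- p[, 2]; tc <- as.numeric(target == 1)
  dice_direct <- 1 - (2 * sum(pc * tc) + 1e-6) / (sum(pc) + sum(tc) + 1e-6)
  expect_equal(hybrid_loss(logits, target, w_ce = 0, w_dice = 1)$loss, dice_direct)
  full <- hybrid_loss(logits, target)
  expect_equal(full$loss, 0.7 * ce_direct + 0.3 * dice_direct)
  expect_gte(full$loss, 0)
  # near-perfect logits drive the loss to ~0
  sharp <- cbind(ifelse(target == 0, 30, -30), ifelse(target == 1, 30, -30))
  expect_lt(hybrid_loss(sharp, target)$loss, 1e-5)
})

test_that("analytic gradients match finite differences through the whole network", {
  m <- segformer_mlla(tiny_config(), seed = 3)
  set.seed(9)
  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  tgt <- matrix(sample(0:1, 32 * 32, TRUE), 32, 32)
  fw <- segformer_forward(m, x, train = TRUE)
  ls <- hybrid_loss(fw$logits, tgt, return_grad = TRUE)
  G <- segformer_backward(m, fw, ls$dlogits)
  gf <- unlist(G, use.names = FALSE)
  pf <- unlist(m$params, use.names = FALSE)
  expect_identical(length(gf), length(pf))
  set.seed(33)
  d <- rnorm(length(pf)); h <- 1e-6
  m1 <- m; m1$params <- tomatopheno:::tree_refill(m$params, pf + h * d)
  m2 <- m; m2$params <- tomatopheno:::tree_refill(m$params, pf - h * d)
  l1 <- hybrid_loss(segformer_forward(m1, x)$logits, tgt)$loss
  l2 <- hybrid_loss(segformer_forward(m2, x)$logits, tgt)$loss
  num <- (l1 - l2) / (2 * h)
  expect_lt(abs(sum(gf * d) - num) / abs(num), 1e-6)
})

test_that("poly decay starts at the base rate and anneals to zero", {
  expect_equal(poly_lr(1e-3, 0, 2000), 1e-3)
  expect_lt(poly_lr(1e-3, 1999, 2000), 1e-5)
  expect_equal(poly_lr(1e-3, 2000, 2000), 0)
  lrs <- poly_lr(1e-3, 0:99, 100)
  expect_true(all(diff(lrs) < 0))
})

test_that("a tiny training run overfits in trend with batch size 4", {
  fx <- overfit_fixture(n = 4L, size = 32L)
  m <- segformer_mlla(tiny_config(), seed = 11)
  res <- train_segmenter(m, fx$images, fx$targets, iters = 60, batch_size = 4,
                         seed = 5)
  expect_identical(nrow(res$history), 60L)
  expect_equal(res$history$lr[1], 1e-3)
  expect_lt(median(tail(res$history$loss, 20)), median(head(res$history$loss, 20)))
  # deterministic under a fixed seed
  res2 <- train_segmenter(segformer_mlla(tiny_config(), seed = 11),
                          fx$images, fx$targets, iters = 5, seed = 5)
  res3 <- train_segmenter(segformer_mlla(tiny_config(), seed = 11),
                          fx$images, fx$targets, iters = 5, seed = 5)
  expect_identical(res2$history$loss, res3$history$loss)
})

test_that("parameter counts order as lightweight < large", {
  na <- count_parameters(segformer_mlla(mlla_config("a"), seed = 1))
  nb <- count_parameters(segformer_mlla(mlla_config("b"), seed = 1))
  expect_lt(na, nb)
  expect_lt(na, 3.5e6)
  expect_gt(nb, 1e7)
})
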
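#' SegFormer-MLLA configuration
#'
#' A hierarchical 4-stage transformer encoder with downsampling rates 4, 8,
#' 16, 32 whose attention is a Mamba-like linear attention (MLLA) block
#' (kernelized linear attention + rotary position embedding on Q/K +
#' locally-enhanced positional encoding on V), decoded by an all-MLP head.
#' Variant `a` inherits the lightweight B0-class embedding dimensions
#' (32, 64, 160, 256) and depths (2, 2, 2, 2); variant `b` the B2-class
#' (64, 128, 320, 512) with depths (3, 4, 6, 3).
#'
#' @param variant `"a"` (lightweight) or `"b"` (larger).
#' @param num_classes output classes (background included).
#' @param embed_dims,depths,num_heads per-stage overrides.
#' @param mlp_ratio feed-forward expansion ratio.
#' @param dropout dropout probability in `[0, 1)`.
#' @param decoder_dim unified decoder embedding dimension.
#' @param theta_base rotary embedding frequency base.
#' @param eps attention denominator guard.
#' @return list of class `mlla_config`.
#' @export
mlla_config <- function(variant = c("a", "b"), num_classes = 2L,
                        embed_dims = NULL, depths = NULL,
                        num_heads = c(1L, 2L, 5L, 8L),
                        mlp_ratio = 3, dropout = 0.1,
                        decoder_dim = 128L, theta_base = 10000, eps = 1e-6) {
  variant <- match.arg(variant)
  if (is.null(embed_dims))
    embed_dims <- if (variant == "a") c(32L, 64L, 160L, 256L) else c(64L, 128L, 320L, 512L)
  if (is.null(depths))
    depths <- if (variant == "a") c(2L, 2L, 2L, 2L) else c(3L, 4L, 6L, 3L)
  if (any(embed_dims %% num_heads != 0))
    tp_stop("embed_dims must be divisible by num_heads", "tp_config_error")
  if (any(embed_dims %/% num_heads %% 4 != 0))
    tp_stop("head dimension must be divisible by 4 (2-D rotary pairs)", "tp_config_error")
  if (dropout < 0 || dropout >= 1) tp_stop("dropout must be in [0, 1)", "tp_config_error")
  structure(list(variant = variant, num_classes = as.integer(num_classes),
                 embed_dims = embed_dims, depths = depths, num_heads = num_heads,
                 downsample_rates = c(4L, 8L, 16L, 32L),
                 mlp_ratio = mlp_ratio, dropout = dropout,
                 decoder_dim = as.integer(decoder_dim),
                 theta_base = theta_base, eps = eps),
            class = "mlla_config")
}

#' Instantiate a SegFormer-MLLA model
#'
#' @param config an [mlla_config()].
#' @param seed RNG seed for weight initialization.
#' @return object of class `segformer_mlla` with `config` and `params`.
#' @export
segformer_mlla <- function(config = mlla_config("a"), seed = 42L) {
  set.seed(seed)
  dims <- config$embed_dims
  params <- list(stages = vector("list", 4L))
  cin <- 3L
  for (s in 1:4) {
    C <- dims[s]
    k <- if (s == 1) 7L else 3L
    emb <- init_linear(k * k * cin, C)
    blocks <- lapply(seq_len(config$depths[s]), function(i) init_block_params(C, config$mlp_ratio))
    params$stages[[s]] <- list(
      embed = c(emb, list(ln_g = rep(1, C), ln_b = numeric(C))),
      blocks = blocks,
      norm = list(g = rep(1, C), b = numeric(C)))
    cin <- C
  }
  D <- config$decoder_dim
  params$decoder <- list(
    proj = lapply(dims, function(C) init_linear(C, D)),
    fuse = init_linear(4L * D, D),
    cls = init_linear(D, config$num_classes))
  structure(list(config = config, params = params), class = "segformer_mlla")
}

init_block_params <- function(C, mlp_ratio) {
  hid <- round(C * mlp_ratio)
  c(list(ln1_g = rep(1, C), ln1_b = numeric(C)),
    setNames(init_linear(C, C), c("Wp", "bp")),
    setNames(init_linear(C, C), c("Wq", "bq")),
    setNames(init_linear(C, C), c("Wk", "bk")),
    setNames(init_linear(C, C), c("Wv", "bv")),
    list(dw = matrix(init_trunc_normal(9 * C), 9, C), dwb = numeric(C)),
    setNames(init_linear(C, C), c("WL", "bL")),
    list(ln2_g = rep(1, C), ln2_b = numeric(C)),
    setNames(init_linear(C, hid), c("W1", "b1")),
    list(dw2 = matrix(init_trunc_normal(9 * hid), 9, hid), dw2b = numeric(hid)),
    setNames(init_linear(hid, C), c("W2", "b2")))
}

#' Count trainable parameters
#'
#' @param model a `segformer_mlla` model.
#' @return total number of trainable scalars.
#' @export
count_parameters <- function(model) {
  count <- 0L
  walk <- function(x) {
    if (is.list(x)) {
      for (e in x) walk(e)
    } else if (is.numeric(x)) count <<- count + length(x)
  }
  walk(model$params)
  count
}

# dropout helper (inverted scaling); returns mask or NULL
make_dropout_mask <- function(n, m, p, train) {
  if (!train || p <= 0) return(NULL)
  matrix((runif(n * m) >= p) / (1 - p), n, m)
}

# ---- MLLA block -------------------------------------------------------------

mlla_block_fwd <- function(x, h, w, p, cfg, train = FALSE) {
  N <- nrow(x); C <- ncol(x)
  ln1 <- layernorm_fwd(x, p$ln1_g, p$ln1_b)
  proj <- linear_fwd(ln1$out, p$Wp, p$bp)
  act <- silu_fwd(proj$out)
  ql <- linear_fwd(act$out, p$Wq, p$bq)
  kl <- linear_fwd(act$out, p$Wk, p$bk)
  q <- kernel_phi(ql$out); k <- kernel_phi(kl$out)
  vl <- linear_fwd(proj$out, p$Wv, p$bv)
  dwv <- dwconv_fwd(vl$out, h, w, p$dw, p$dwb)
  wl <- linear_fwd(dwv$out, p$WL, p$bL)
  vle <- vl$out + wl$out                       # LePE(V)
  nh <- attr(p, "nh")
  dh <- C %/% nh
  rt <- rope_tables(h, w, dh, cfg$theta_base)
  heads <- vector("list", nh)
  y <- matrix(0, N, C)
  for (hd in seq_len(nh)) {
    cols <- (hd - 1L) * dh + seq_len(dh)
    qr <- rope_apply(q[, cols, drop = FALSE], rt$cosA, rt$sinA)
    kr <- rope_apply(k[, cols, drop = FALSE], rt$cosA, rt$sinA)
    at <- lin_attn_fwd(qr, kr, vle[, cols, drop = FALSE], cfg$eps)
    y[, cols] <- at$out
    heads[[hd]] <- at
  }
  m1 <- make_dropout_mask(N, C, cfg$dropout, train)
  x2 <- x + if (is.null(m1)) y else y * m1
  ln2 <- layernorm_fwd(x2, p$ln2_g, p$ln2_b)
  f1 <- linear_fwd(ln2$out, p$W1, p$b1)
  dwf <- dwconv_fwd(f1$out, h, w, p$dw2, p$dw2b)
  a2 <- silu_fwd(dwf$out)
  f2 <- linear_fwd(a2$out, p$W2, p$b2)
  m2 <- make_dropout_mask(N, C, cfg$dropout, train)
  out <- x2 + if (is.null(m2)) f2$out else f2$out * m2
  list(out = out,
       cache = list(ln1 = ln1, proj = proj, act = act, ql = ql, kl = kl,
                    q = q, k = k, vl = vl, dwv = dwv, wl = wl,
                    heads = heads, nh = nh, dh = dh, rt = rt, m1 = m1,
                    ln2 = ln2, f1 = f1, dwf = dwf, a2 = a2, f2 = f2, m2 = m2,
                    h = h, w = w))
}

mlla_block_bwd <- function(cache, dout, p) {
  g <- new_block_grads(p)
  # FFN branch
  dff <- if (is.null(cache$m2)) dout else dout * cache$m2
  b2 <- linear_bwd(cache$f2, dff, p$W2)
  g$W2 <- b2$dW; g$b2 <- b2$db
  da2 <- silu_bwd(cache$a2, b2$dx)
  bdw2 <- dwconv_bwd(cache$dwf, da2, p$dw2)
  g$dw2 <- bdw2$dW; g$dw2b <- bdw2$db
  b1 <- linear_bwd(cache$f1, bdw2$dx, p$W1)
  g$W1 <- b1$dW; g$b1 <- b1$db
  bln2 <- layernorm_bwd(cache$ln2, b1$dx, p$ln2_g)
  g$ln2_g <- bln2$dg; g$ln2_b <- bln2$db
  dx2 <- dout + bln2$dx
  # attention branch
  dy <- if (is.null(cache$m1)) dx2 else dx2 * cache$m1
  N <- nrow(dy); C <- ncol(dy)
  dq <- matrix(0, N, C); dk <- matrix(0, N, C); dvle <- matrix(0, N, C)
  for (hd in seq_len(cache$nh)) {
    cols <- (hd - 1L) * cache$dh + seq_len(cache$dh)
    bat <- lin_attn_bwd(cache$heads[[hd]], dy[, cols, drop = FALSE])
    dq[, cols] <- rope_apply_bwd(bat$dQ, cache$rt$cosA, cache$rt$sinA)
    dk[, cols] <- rope_apply_bwd(bat$dK, cache$rt$cosA, cache$rt$sinA)
    dvle[, cols] <- bat$dV
  }
  # LePE: vle = v + dwconv(v) WL
  bwl <- linear_bwd(cache$wl, dvle, p$WL)
  g$WL <- bwl$dW; g$bL <- bwl$db
  bdw <- dwconv_bwd(cache$dwv, bwl$dx, p$dw)
  g$dw <- bdw$dW; g$dwb <- bdw$db
  dv <- dvle + bdw$dx
  bv <- linear_bwd(cache$vl, dv, p$Wv)
  g$Wv <- bv$dW; g$bv <- bv$db
  # kernelized Q/K projections
  dql <- dq * kernel_phi_grad(cache$ql$out)
  dkl <- dk * kernel_phi_grad(cache$kl$out)
  bq <- linear_bwd(cache$ql, dql, p$Wq)
  bk <- linear_bwd(cache$kl, dkl, p$Wk)
  g$Wq <- bq$dW; g$bq <- bq$db
  g$Wk <- bk$dW; g$bk <- bk$db
  dact <- silu_bwd(cache$act, bq$dx + bk$dx)
  dproj <- dact + bv$dx
  bp <- linear_bwd(cache$proj, dproj, p$Wp)
  g$Wp <- bp$dW; g$bp <- bp$db
  bln1 <- layernorm_bwd(cache$ln1, bp$dx, p$ln1_g)
  g$ln1_g <- bln1$dg; g$ln1_b <- bln1$db
  list(dx = dx2 + bln1$dx, grads = g)
}

new_block_grads <- function(p) {
  lapply(p, function(e) if (is.numeric(e)) array(0, dim(e) %||% length(e)) else e)
}

# ---- full model forward / backward -----------------------------------------

#' Forward pass of the SegFormer-MLLA network
#'
#' Runs the 4-stage encoder and all-MLP decoder on one image; logits are
#' produced at 1/4 resolution and bilinearly upsampled to the input size.
#'
#' @param model a `segformer_mlla`.
#' @param x H x W x 3 array in `[0, 1]` (H, W divisible by 32).
#' @param train keep caches and apply dropout.
#' @return list with `logits` ((H*W) x num_classes, column-major tokens),
#'   `stage_dims`, and (when `train`) `cache`.
#' @export
segformer_forward <- function(model, x, train = FALSE) {
  cfg <- model$config
  P <- model$params
  h_in <- dim(x)[1]; w_in <- dim(x)[2]
  if (h_in %% 32 != 0 || w_in %% 32 != 0)
    tp_stop("input size must be divisible by 32", "tp_config_error")
  feats <- vector("list", 4L)
  dims <- matrix(0L, 4, 2)
  caches <- vector("list", 4L)
  cur <- x
  for (s in 1:4) {
    ps <- P$stages[[s]]
    k_s <- if (s == 1) 7L else 3L
    emb <- conv2d_fwd(cur, ps$embed$W, ps$embed$b, k_s,
                      stride = if (s == 1) 4L else 2L, pad = if (s == 1) 3L else 1L)
    h <- emb$geom$hout; w <- emb$geom$wout
    lne <- layernorm_fwd(emb$out, ps$embed$ln_g, ps$embed$ln_b)
    tok <- lne$out
    bcaches <- vector("list", length(ps$blocks))
    for (b in seq_along(ps$blocks)) {
      pb <- ps$blocks[[b]]
      attr(pb, "nh") <- cfg$num_heads[s]
      r <- mlla_block_fwd(tok, h, w, pb, cfg, train)
      tok <- r$out
      bcaches[[b]] <- r$cache
    }
    lns <- layernorm_fwd(tok, ps$norm$g, ps$norm$b)
    feats[[s]] <- lns$out
    dims[s, ] <- c(h, w)
    caches[[s]] <- list(emb = emb, lne = lne, blocks = bcaches, lns = lns,
                        h = h, w = w)
    cur <- tok2arr(lns$out, h, w)
  }
  # all-MLP decoder at stage-1 resolution
  h1 <- dims[1, 1]; w1 <- dims[1, 2]
  dprj <- vector("list", 4L); dup <- vector("list", 4L)
  parts <- vector("list", 4L)
  for (s in 1:4) {
    dprj[[s]] <- linear_fwd(feats[[s]], P$decoder$proj[[s]]$W, P$decoder$proj[[s]]$b)
    dup[[s]] <- upsample_fwd(dprj[[s]]$out, dims[s, 1], dims[s, 2], h1, w1)
    parts[[s]] <- dup[[s]]$out
  }
  cat4 <- do.call(cbind, parts)
  fuse <- linear_fwd(cat4, P$decoder$fuse$W, P$decoder$fuse$b)
  factv <- silu_fwd(fuse$out)
  clsl <- linear_fwd(factv$out, P$decoder$cls$W, P$decoder$cls$b)
  upf <- upsample_fwd(clsl$out, h1, w1, h_in, w_in)
  out <- list(logits = upf$out, stage_dims = dims,
              input_dim = c(h_in, w_in))
  if (train)
    out$cache <- list(stages = caches, dprj = dprj, dup = dup, fuse = fuse,
                      factv = factv, clsl = clsl, upf = upf, dims = dims,
                      h1 = h1, w1 = w1)
  out
}

segformer_backward <- function(model, fwd, dlogits) {
  cfg <- model$config
  P <- model$params
  cc <- fwd$cache
  G <- list(stages = vector("list", 4L), decoder = NULL)
  dcls_tok <- upsample_bwd(cc$upf, dlogits)
  bcls <- linear_bwd(cc$clsl, dcls_tok, P$decoder$cls$W)
  dfa <- silu_bwd(cc$factv, bcls$dx)
  bfuse <- linear_bwd(cc$fuse, dfa, P$decoder$fuse$W)
  D <- cfg$decoder_dim
  dfeat <- vector("list", 4L)
  Gdec <- list(proj = vector("list", 4L),
               fuse = list(W = bfuse$dW, b = bfuse$db),
               cls = list(W = bcls$dW, b = bcls$db))
  for (s in 1:4) {
    dpart <- bfuse$dx[, (s - 1L) * D + seq_len(D), drop = FALSE]
    dproj_out <- upsample_bwd(cc$dup[[s]], dpart)
    bprj <- linear_bwd(cc$dprj[[s]], dproj_out, P$decoder$proj[[s]]$W)
    Gdec$proj[[s]] <- list(W = bprj$dW, b = bprj$db)
    dfeat[[s]] <- bprj$dx
  }
  G$decoder <- Gdec
  darr_next <- NULL
  for (s in 4:1) {
    sc <- cc$stages[[s]]
    ps <- P$stages[[s]]
    dtok_out <- dfeat[[s]]
    if (!is.null(darr_next)) dtok_out <- dtok_out + arr2tok(darr_next)
    blns <- layernorm_bwd(sc$lns, dtok_out, ps$norm$g)
    dtok <- blns$dx
    Gb <- vector("list", length(ps$blocks))
    for (b in rev(seq_along(ps$blocks))) {
      pb <- ps$blocks[[b]]
      r <- mlla_block_bwd(sc$blocks[[b]], dtok, pb)
      dtok <- r$dx
      Gb[[b]] <- r$grads
    }
    blne <- layernorm_bwd(sc$lne, dtok, ps$embed$ln_g)
    bemb <- conv2d_bwd(sc$emb, blne$dx, ps$embed$W)
    # field order mirrors the parameter tree so unlist() aligns flat views
    G$stages[[s]] <- list(
      embed = list(W = bemb$dW, b = bemb$db, ln_g = blne$dg, ln_b = blne$db),
      blocks = Gb,
      norm = list(g = blns$dg, b = blns$db))
    darr_next <- if (s > 1) bemb$dx else NULL
  }
  G
}

#' Segment an image with a trained model
#'
#' @param model a `segformer_mlla`.
#' @param x H x W x 3 array in `[0, 1]`.
#' @return integer label matrix (argmax class per pixel, 0-based codes).
#' @export
segment_image <- function(model, x) {
  fw <- segformer_forward(model, x, train = FALSE)
  lab <- max.col(fw$logits) - 1L
  matrix(lab, dim(x)[1], dim(x)[2])   # column-major tokens
}
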
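#' Hybrid cross-entropy / Dice segmentation loss
#'
#' `w_ce * CE + w_dice * (1 - mean soft-Dice over foreground classes)`,
#' the class-imbalance-aware objective used for training: cross-entropy
#' dominates per-pixel calibration while the Dice term rewards overlap of
#' small foreground structures (stem scars occupy a few percent of pixels).
#'
#' @param logits N x num_classes matrix (row-major pixel tokens).
#' @param target integer vector of 0-based class labels (length N) or a
#'   label matrix (converted row-major).
#' @param w_ce,w_dice loss weights.
#' @param return_grad also return `dlogits`.
#' @param eps smoothing term of the soft-Dice ratio.
#' @return list with `loss`, `ce`, `dice` (and `dlogits` on request).
#' @export
hybrid_loss <- function(logits, target, w_ce = 0.7, w_dice = 0.3,
                        return_grad = FALSE, eps = 1e-6) {
  if (is.matrix(target)) target <- as.vector(target)  # column-major tokens
  n <- nrow(logits); ncls <- ncol(logits)
  if (length(target) != n) tp_stop("target length mismatch", "tp_format_error")
  m <- logits[, 1]
  for (j in seq_len(ncls)[-1]) m <- pmax(m, logits[, j])
  ex <- exp(logits - m)
  p <- ex / rowSums(ex)
  ti <- cbind(seq_len(n), target + 1L)
  ce <- -mean(log(pmax(p[ti], 1e-12)))
  fg <- seq_len(ncls - 1L)             # foreground classes 1..ncls-1
  dice_terms <- numeric(length(fg))
  dLdp <- matrix(0, n, ncls)
  for (i in seq_along(fg)) {
    cls <- fg[i]
    pc <- p[, cls + 1L]
    tc <- as.numeric(target == cls)
    num <- 2 * sum(pc * tc) + eps
    den <- sum(pc) + sum(tc) + eps
    dice_terms[i] <- num / den
    if (return_grad)
      dLdp[, cls + 1L] <- dLdp[, cls + 1L] -
        w_dice / length(fg) * (2 * tc * den - num) / den^2
  }
  dice_loss <- 1 - mean(dice_terms)
  out <- list(loss = w_ce * ce + w_dice * dice_loss, ce = ce, dice = dice_loss)
  if (return_grad) {
    onehot <- matrix(0, n, ncls); onehot[ti] <- 1
    dl_ce <- w_ce * (p - onehot) / n
    # chain the dice dL/dp through the softmax
    dl_dice <- p * (dLdp - rowSums(dLdp * p))
    out$dlogits <- dl_ce + dl_dice
  }
  out
}

#' Polynomial learning-rate decay
#'
#' `lr(t) = lr0 * (1 - t / T)^power` for iteration t in `0..T-1`.
#'
#' @param lr0 base learning rate.
#' @param iter 0-based iteration.
#' @param total total iterations T.
#' @param power decay exponent.
#' @return learning rate at `iter`.
#' @export
poly_lr <- function(lr0, iter, total, power = 0.9) {
  lr0 * (1 - iter / total)^power
}

# ---- parameter-tree utilities ----------------------------------------------

# name-aware: grad trees may order fields differently than parameter trees
tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- a
    nms <- names(a)
    if (!is.null(nms) && all(nzchar(nms))) {
      for (nm in nms) out[[nm]] <- tree_map2(f, a[[nm]], b[[nm]])
    } else {
      for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    }
    out
  } else if (is.numeric(a)) f(a, b) else a
}

tree_map <- function(f, a) {
  if (is.list(a)) {
    out <- a
    for (i in seq_along(a)) out[[i]] <- tree_map(f, a[[i]])
    out
  } else if (is.numeric(a)) f(a) else a
}

tree_reduce_sum <- function(f, a) {
  acc <- 0
  walk <- function(x) {
    if (is.list(x)) for (e in x) walk(e)
    else if (is.numeric(x)) acc <<- acc + f(x)
  }
  walk(a)
  acc
}

adamw_init <- function(params) {
  n <- length(unlist(params, use.names = FALSE))
  list(m = numeric(n), v = numeric(n), t = 0L)
}

# refill a parameter tree from a flat vector (cursor walk; leaves keep
# their dims). Inverse of unlist(params, use.names = FALSE).
tree_refill <- function(skel, flat) {
  cursor <- 0L
  walk <- function(x) {
    if (is.list(x)) {
      for (i in seq_along(x)) x[[i]] <- walk(x[[i]])
      x
    } else if (is.numeric(x)) {
      n <- length(x)
      v <- flat[cursor + seq_len(n)]
      cursor <<- cursor + n
      if (!is.null(dim(x))) dim(v) <- dim(x)
      v
    } else x
  }
  walk(skel)
}

# flat-vector AdamW: gradient trees are emitted in parameter order, so
# unlist() gives aligned flat views and the update is a handful of
# vectorized operations over all 2.8M+ parameters
adamw_step <- function(params, grads_list, state, lr, weight_decay = 0.01,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  g <- unlist(grads_list[[1]], use.names = FALSE)
  if (length(grads_list) > 1L)
    for (k in 2:length(grads_list)) g <- g + unlist(grads_list[[k]], use.names = FALSE)
  state$m <- beta1 * state$m + (1 - beta1) * g
  state$v <- beta2 * state$v + (1 - beta2) * g * g
  pflat <- unlist(params, use.names = FALSE)
  pflat <- pflat - lr * ((state$m / bc1) / (sqrt(state$v / bc2) + eps)) -
    lr * weight_decay * pflat
  list(params = tree_refill(params, pflat), state = state)
}

#' Train a SegFormer-MLLA model
#'
#' AdamW (base learning rate 1e-3, weight decay 0.01) with polynomial
#' learning-rate decay (power 0.9) and the 0.7/0.3 hybrid
#' cross-entropy/Dice loss; batches of `batch_size` images. Deterministic
#' under a fixed seed. Training aborts with diagnostics if the loss becomes
#' non-finite.
#'
#' @param model a `segformer_mlla`.
#' @param images list of H x W x 3 arrays in `[0, 1]`.
#' @param targets list of integer label matrices (0-based classes).
#' @param iters total iterations.
#' @param batch_size images per iteration.
#' @param lr base learning rate.
#' @param poly_power decay exponent.
#' @param weight_decay AdamW decoupled weight decay.
#' @param seed RNG seed (batch sampling, dropout).
#' @param stop_iou optional early-stop: training aborts successfully once
#'   the mean foreground IoU on `images` reaches this value (checked every
#'   `eval_every` iterations).
#' @param eval_every evaluation cadence for `stop_iou`.
#' @param verbose print progress lines.
#' @return list with `model`, `history` (data.frame iter/lr/loss/ce/dice),
#'   `stopped_at` (iteration of early stop or `NA`).
#' @export
train_segmenter <- function(model, images, targets, iters = 200L,
                            batch_size = 4L, lr = 1e-3, poly_power = 0.9,
                            weight_decay = 0.01, seed = 42L,
                            stop_iou = NULL, eval_every = 50L,
                            verbose = FALSE) {
  stopifnot(length(images) == length(targets), length(images) >= 1L)
  set.seed(seed)
  state <- adamw_init(model$params)
  h_iter <- integer(iters); h_lr <- h_loss <- h_ce <- h_dice <- numeric(iters)
  n_hist <- 0L
  stopped_at <- NA_integer_
  for (it in seq_len(iters)) {
    lr_t <- poly_lr(lr, it - 1L, iters, poly_power)
    idx <- if (length(images) <= batch_size) {
      rep_len(sample(length(images)), batch_size)
    } else sample(length(images), batch_size)
    grads_list <- vector("list", length(idx))
    loss_acc <- ce_acc <- dice_acc <- 0
    for (bi in seq_along(idx)) {
      i <- idx[bi]
      fw <- segformer_forward(model, images[[i]], train = TRUE)
      ls <- hybrid_loss(fw$logits, targets[[i]], return_grad = TRUE)
      if (!is.finite(ls$loss))
        tp_stop(sprintf("non-finite loss at iteration %d (image %d): ce=%g dice=%g",
                        it, i, ls$ce, ls$dice), "tp_train_error")
      grads_list[[bi]] <- segformer_backward(model, fw, ls$dlogits / length(idx))
      loss_acc <- loss_acc + ls$loss / length(idx)
      ce_acc <- ce_acc + ls$ce / length(idx)
      dice_acc <- dice_acc + ls$dice / length(idx)
    }
    st <- adamw_step(model$params, grads_list, state, lr_t, weight_decay)
    model$params <- st$params
    state <- st$state
    n_hist <- n_hist + 1L
    h_iter[n_hist] <- it; h_lr[n_hist] <- lr_t; h_loss[n_hist] <- loss_acc
    h_ce[n_hist] <- ce_acc; h_dice[n_hist] <- dice_acc
    if (verbose && it %% 25L == 0L)
      message(sprintf("iter %d lr %.2e loss %.4f (ce %.4f dice %.4f)",
                      it, lr_t, loss_acc, ce_acc, dice_acc))
    if (!is.null(stop_iou) && it %% eval_every == 0L) {
      iou <- training_foreground_iou(model, images, targets)
      if (verbose) message(sprintf("iter %d train fg IoU %.4f", it, iou))
      if (iou >= stop_iou) { stopped_at <- it; break }
    }
  }
  keep <- seq_len(n_hist)
  list(model = model,
       history = data.frame(iter = h_iter[keep], lr = h_lr[keep],
                            loss = h_loss[keep], ce = h_ce[keep],
                            dice = h_dice[keep]),
       stopped_at = stopped_at)
}

#' Mean foreground IoU of a model on an image set
#'
#' Aggregated confusion counts over all foreground classes and images.
#'
#' @inheritParams train_segmenter
#' @return IoU in `[0, 1]`.
#' @export
training_foreground_iou <- function(model, images, targets) {
  tp <- fp <- fn <- 0
  for (i in seq_along(images)) {
    pred <- segment_image(model, images[[i]])
    cc <- confusion_counts(pred > 0, targets[[i]] > 0)
    tp <- tp + cc$tp; fp <- fp + cc$fp; fn <- fn + cc$fn
  }
  seg_metrics(tp, fp, fn)$iou
}
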
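#' @name reference_convnet
#' @title The reference convolutional network backend
#' @description
#' A deliberately small convolutional binary classifier: three blocks of
#' 3x3 convolution (zero padding, stride 1) + ReLU + 2x2 average pooling,
#' with channel widths 8/16/32, followed by global average pooling and a
#' linear head with a logistic link. Trained end-to-end with Adam on the
#' binomial deviance, early-stopped on validation AUC. Inputs are scaled to
#' \[-1, 1\]; image sides must be multiples of 8. The forward and backward
#' passes are im2col gathers plus dense matrix products, so training is
#' minutes-scale on one CPU at 64x64. The architecture is a stand-in for
#' the large ImageNet-class models used in full-scale audits; the shortcut
#' signal is global and architecture choice is not load-bearing.
#' @keywords internal
NULL

cn_widths <- c(8L, 16L, 32L)

## Row indices of the H x W interior inside the (H+2) x (W+2) zero-padded
## plane, replicated across a batch of size B.
cn_interior_idx <- function(H, W, B) {
  Hp <- H + 2L
  ii <- rep(seq_len(H), times = W) + 1L
  jj <- rep(seq_len(W), each = H)
  base <- ii + Hp * jj # jj already equals (padded column - 1) - 1 + 1
  as.vector(outer(base, (seq_len(B) - 1L) * (Hp * (W + 2L)), "+"))
}

## Gather vector for im2col: for offset t = dy + 3*dx + 1 (dy, dx in 0:2),
## block t holds the padded row index of every (output pixel, batch item).
cn_gather_idx <- function(H, W, B) {
  Hp <- H + 2L; Wp <- W + 2L
  ii <- rep(seq_len(H), times = W)
  jj <- rep(seq_len(W), each = H)
  off <- (seq_len(B) - 1L) * (Hp * Wp)
  blocks <- vector("list", 9L)
  for (dx in 0:2) for (dy in 0:2) {
    t <- dy + 3L * dx + 1L
    base <- (ii + dy) + Hp * (jj + dx - 1L)
    blocks[[t]] <- as.vector(outer(base, off, "+"))
  }
  unlist(blocks, use.names = FALSE)
}

## 2x2 average-pool index quadruple; input rows ordered (i, j, b).
cn_pool_idx <- function(H, W, B) {
  Ho <- H %/% 2L; Wo <- W %/% 2L
  io <- rep(seq_len(Ho), times = Wo)
  jo <- rep(seq_len(Wo), each = Ho)
  off <- (seq_len(B) - 1L) * (H * W)
  mk <- function(di, dj) {
    base <- (2L * io - 1L + di) + H * (2L * jo - 2L + dj)
    as.vector(outer(base, off, "+"))
  }
  list(mk(0L, 0L), mk(1L, 0L), mk(0L, 1L), mk(1L, 1L))
}

cn_conv_forward <- function(A, H, W, B, Cin, Wmat, bias) {
  Hp <- H + 2L; Wp <- W + 2L
  Apad <- matrix(0, Hp * Wp * B, Cin)
  interior <- cn_interior_idx(H, W, B)
  Apad[interior, ] <- A
  gvec <- cn_gather_idx(H, W, B)
  G <- Apad[gvec, , drop = FALSE]
  dim(G) <- c(H * W * B, 9L * Cin)
  Z <- G %*% Wmat
  Z <- sweep(Z, 2L, bias, "+")
  list(Z = Z, M = G, gvec = gvec, interior = interior,
       pad_rows = Hp * Wp * B, H = H, W = W, B = B, Cin = Cin)
}

cn_conv_backward <- function(dZ, cache, Wmat, need_dx = TRUE) {
  dW <- crossprod(cache$M, dZ)
  db <- colSums(dZ)
  dA <- NULL
  if (need_dx) {
    dM <- dZ %*% t(Wmat)
    hwb <- cache$H * cache$W * cache$B
    dApad <- matrix(0, cache$pad_rows, cache$Cin)
    for (t in 1:9) {
      rows <- cache$gvec[((t - 1L) * hwb + 1L):(t * hwb)]
      cols <- t + 9L * (seq_len(cache$Cin) - 1L)
      dApad[rows, ] <- dApad[rows, ] + dM[, cols, drop = FALSE]
    }
    dA <- dApad[cache$interior, , drop = FALSE]
  }
  list(dW = dW, db = db, dA = dA)
}

cn_init <- function(H, W) {
  widths <- cn_widths
  cins <- c(1L, widths[1:2])
  params <- list()
  for (l in 1:3) {
    fan_in <- 9L * cins[l]
    params[[paste0("W", l)]] <-
      matrix(stats::rnorm(fan_in * widths[l], sd = sqrt(2 / fan_in)),
             fan_in, widths[l])
    params[[paste0("b", l)]] <- numeric(widths[l])
  }
  params$Wh <- matrix(0, widths[3], 1L)
  params$bh <- 0
  params
}

## Stack a list of H x W images into the (H*W*B) x 1 input matrix,
## scaled to [-1, 1].
cn_stack <- function(images) {
  matrix(unlist(images, use.names = FALSE) / 127.5 - 1, ncol = 1L)
}

cn_forward <- function(params, A0, H, W, B, keep_cache = FALSE) {
  A <- A0
  h <- H; w <- W
  caches <- if (keep_cache) vector("list", 3L) else NULL
  cins <- c(1L, cn_widths[1:2])
  for (l in 1:3) {
    cc <- cn_conv_forward(A, h, w, B, cins[l],
                          params[[paste0("W", l)]], params[[paste0("b", l)]])
    Zr <- pmax(cc$Z, 0)
    pid <- cn_pool_idx(h, w, B)
    P <- (Zr[pid[[1]], , drop = FALSE] + Zr[pid[[2]], , drop = FALSE] +
            Zr[pid[[3]], , drop = FALSE] + Zr[pid[[4]], , drop = FALSE]) / 4
    if (keep_cache) {
      caches[[l]] <- list(conv = cc, mask = cc$Z > 0, pid = pid,
                          h = h, w = w)
    }
    A <- P
    h <- h %/% 2L; w <- w %/% 2L
  }
  group <- rep(seq_len(B), each = h * w)
  Fmat <- rowsum(A, group, reorder = FALSE) / (h * w)
  logits <- as.numeric(Fmat %*% params$Wh + params$bh)
  list(probs = stats::plogis(logits), Fmat = Fmat, caches = caches,
       group = group, gap_hw = h * w)
}

cn_backward <- function(params, fw, y, B) {
  grads <- list()
  dlogit <- matrix((fw$probs - y) / B, ncol = 1L)
  grads$Wh <- crossprod(fw$Fmat, dlogit)
  grads$bh <- sum(dlogit)
  dF <- dlogit %*% t(params$Wh)
  dA <- dF[fw$group, , drop = FALSE] / fw$gap_hw
  for (l in 3:1) {
    cc <- fw$caches[[l]]
    hwb <- cc$h * cc$w * B
    dZr <- matrix(0, hwb, ncol(dA))
    for (k in 1:4) dZr[cc$pid[[k]], ] <- dA / 4
    dZ <- dZr * cc$mask
    bk <- cn_conv_backward(dZ, cc$conv, params[[paste0("W", l)]],
                           need_dx = (l > 1L))
    grads[[paste0("W", l)]] <- bk$dW
    grads[[paste0("b", l)]] <- bk$db
    dA <- bk$dA
  }
  grads
}

cn_adam_step <- function(params, grads, state, lr, t,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

fit_convnet <- function(images, y, val_images, val_y,
                        max_epochs = 15, patience = 3,
                        learning_rate = 3e-3, batch_size = 32, seed = 1) {
  H <- nrow(images[[1]]); W <- ncol(images[[1]])
  if (H %% 8L != 0L || W %% 8L != 0L) {
    stop("reference_convnet requires image sides divisible by 8", call. = FALSE)
  }
  n <- length(images)
  has_val <- length(val_images) > 0L && length(unique(val_y)) == 2L
  with_seed(seed, {
    params <- cn_init(H, W)
    state <- list(m = lapply(params, function(p) p * 0),
                  v = lapply(params, function(p) p * 0))
    best <- list(params = params, val_auc = -Inf, epoch = 0L)
    t_step <- 0L
    stale <- 0L
    for (epoch in seq_len(max_epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        B <- length(idx)
        A0 <- cn_stack(images[idx])
        fw <- cn_forward(params, A0, H, W, B, keep_cache = TRUE)
        grads <- cn_backward(params, fw, y[idx], B)
        t_step <- t_step + 1L
        upd <- cn_adam_step(params, grads, state, learning_rate, t_step)
        params <- upd$params
        state <- upd$state
      }
      if (has_val) {
        vp <- cn_predict_params(params, val_images, H, W)
        va <- compute_auc(vp, val_y)
        if (va > best$val_auc) {
          best <- list(params = params, val_auc = va, epoch = epoch)
          stale <- 0L
        } else {
          stale <- stale + 1L
          if (stale >= patience) break
        }
      } else {
        best <- list(params = params, val_auc = NA_real_, epoch = epoch)
      }
    }
    list(type = "reference_convnet", params = best$params,
         H = H, W = W, val_auc = best$val_auc, best_epoch = best$epoch)
  })
}

cn_predict_params <- function(params, images, H, W, batch_size = 64L) {
  n <- length(images)
  out <- numeric(n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    A0 <- cn_stack(images[idx])
    out[idx] <- cn_forward(params, A0, H, W, length(idx))$probs
  }
  out
}

predict_convnet <- function(fit, images) {
  cn_predict_params(fit$params, images, fit$H, fit$W)
}
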
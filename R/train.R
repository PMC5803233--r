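# Backpropagation and Adam optimisation for the encoder-decoder network.

# Backward pass. fwd: cache from cnn_forward(..., cache = TRUE); GY: gradient
# of the loss w.r.t. the network output. Returns per-layer weight/bias
# gradients. Skip merges route gradient both into the decoder trunk and back
# into the encoder activations they were copied from.
cnn_backward <- function(model, fwd, GY) {
  spec <- model$spec
  n_enc <- length(spec$encoder)
  ifc <- n_enc + 1L
  n_lay <- length(model$layers)
  grads <- vector("list", n_lay)
  enc_pending <- vector("list", n_enc)  # grads arriving via skip merges
  g <- GY
  for (j in rev(seq_along(spec$decoder))) {
    i <- ifc + j
    l <- model$layers[[i]]
    link <- spec$merge_links[as.character(j)]
    if (!is.na(link) && length(link)) {
      # output of layer i was concatenated with encoder map `link`
      rows_self <- seq_len(nrow(fwd$outputs[[i]]))
      g_skip <- g[-rows_self, , drop = FALSE]
      enc_pending[[link]] <- if (is.null(enc_pending[[link]])) g_skip else
        enc_pending[[link]] + g_skip
      g <- g[rows_self, , drop = FALSE]
    }
    g <- g * (fwd$outputs[[i]] > 0)
    d <- fwd$dims[[i]]
    bw <- cpp_deconv_bwd(fwd$inputs[[i]], l$W, g, d[1], d[2], l$cin, l$stride)
    grads[[i]] <- list(W = bw$gw, b = as.numeric(bw$gb))
    g <- bw$gx
  }
  lfc <- model$layers[[ifc]]
  g <- g * (fwd$outputs[[ifc]] > 0)
  grads[[ifc]] <- list(W = g %*% t(fwd$inputs[[ifc]]), b = rowSums(g))
  g <- crossprod(lfc$W, g)
  for (i in rev(seq_len(n_enc))) {
    l <- model$layers[[i]]
    if (!is.null(enc_pending[[i]])) g <- g + enc_pending[[i]]
    g <- g * (fwd$outputs[[i]] > 0)
    d <- fwd$dims[[i]]
    bw <- cpp_conv_bwd(fwd$inputs[[i]], l$W, g, d[1], d[2], l$cin, l$stride)
    grads[[i]] <- list(W = bw$gw, b = as.numeric(bw$gb))
    g <- bw$gx
  }
  grads
}

adam_init <- function(model) {
  list(t = 0L,
       m = lapply(model$layers, function(l)
         list(W = array(0, dim(l$W)), b = numeric(length(l$b)))),
       v = lapply(model$layers, function(l)
         list(W = array(0, dim(l$W)), b = numeric(length(l$b)))))
}

adam_step <- function(model, grads, opt, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  c1 <- 1 - beta1^opt$t
  c2 <- 1 - beta2^opt$t
  for (i in seq_along(model$layers)) {
    for (p in c("W", "b")) {
      gp <- grads[[i]][[p]]
      opt$m[[i]][[p]] <- beta1 * opt$m[[i]][[p]] + (1 - beta1) * gp
      opt$v[[i]][[p]] <- beta2 * opt$v[[i]][[p]] + (1 - beta2) * gp^2
      model$layers[[i]][[p]] <- model$layers[[i]][[p]] -
        lr * (opt$m[[i]][[p]] / c1) / (sqrt(opt$v[[i]][[p]] / c2) + eps)
    }
  }
  list(model = model, opt = opt)
}

# gradient of 1/PSNR w.r.t. the prediction (see psnr_loss); the scale factor
# is clamped so a batch that starts at PSNR < 1 dB cannot blow up the step
psnr_loss_grad <- function(pred, target, i_max = 1, mse_floor = 1e-12) {
  r <- pred - target
  mse <- max(mean(r^2), mse_floor)
  p <- 10 * log10(i_max / mse)
  scale <- 10 / (max(p, 1)^2 * mse * log(10))
  scale * 2 * r / length(r)
}

#' Assemble low/high-dose training pairs from two projection sets
#'
#' Picks the images at the requested training angles from an aligned pair of
#' stacks (same angle grid), e.g. a noisy and a clean synthetic scan, or a
#' short- and long-exposure measurement.
#'
#' @param low,high `projection_set`s sharing the angle grid of `low` at least
#'   at `angles`.
#' @param angles training angles in degrees; must be present in both sets.
#' @return list of `list(low =, high =)` image matrices.
#' @export
training_pairs <- function(low, high, angles = c(0, 45)) {
  stopifnot(inherits(low, "projection_set"), inherits(high, "projection_set"))
  lapply(angles, function(a) {
    il <- which(abs(low$angles - a) < 1e-9)
    ih <- which(abs(high$angles - a) < 1e-9)
    if (length(il) != 1 || length(ih) != 1) {
      stop("training angle ", a, " not found in both stacks")
    }
    list(low = low$images[, , il], high = high$images[, , ih])
  })
}

#' Train the enhancement network on low/high-dose image pairs
#'
#' Normalizes each pair with the two-step scheme — the statistics come from
#' the low-dose image and are applied to both sides, so the learned mapping
#' lives in the same intensity frame that [enhance()] later inverts — then
#' extracts aligned overlapping patches from both sides and minimises the
#' inverse-PSNR objective ([psnr_loss()]) over the patch pairs with
#' mini-batch Adam. A
#' fraction of the patches is held out and its plain MSE is logged per epoch
#' as the validation error. Two or three angle pairs are typically enough,
#' because patches from a couple of projections already cover the local
#' feature statistics of the whole scan.
#'
#' @param model a `tomo_cnn` from [build_network()].
#' @param pairs list of `list(low =, high =)` image matrices, e.g. from
#'   [training_pairs()].
#' @param epochs number of passes over the training patches.
#' @param batch_size mini-batch size.
#' @param lr Adam learning rate.
#' @param patch_stride anchor stride for training patch extraction.
#' @param val_frac fraction of patches held out for the validation MSE.
#' @param seed RNG seed for the split and the shuffling.
#' @param snapshot_epochs integer vector; after each listed epoch a copy of
#'   the weights is stored in `model$snapshots[[as.character(epoch)]]`.
#' @param verbose print per-epoch losses.
#' @return the trained `tomo_cnn`, with a per-epoch `log` tibble
#'   (`epoch`, `train_loss`, `train_mse`, `val_mse`).
#' @export
train_cnn <- function(model, pairs, epochs = 40, batch_size = 32, lr = 1e-3,
                      patch_stride = 16, val_frac = 0.1, seed = 1,
                      snapshot_epochs = integer(0), verbose = FALSE) {
  stopifnot(inherits(model, "tomo_cnn"))
  if (length(pairs) < 1) stop("need at least one training pair")
  e <- model$patch_edge
  xs <- list(); ys <- list()
  for (p in pairs) {
    if (!identical(dim(p$low), dim(p$high))) {
      stop("shape mismatch within a training pair")
    }
    nl <- normalize_two_step(p$low)
    # the target is mapped with the *input's* normalization parameters:
    # enhancement later de-normalizes with the input's parameters, so input
    # and target must share one intensity frame for that to be exact
    hi <- apply_normalization(p$high, nl$params)
    pl <- extract_patches(nl$image, e, patch_stride)
    ph <- extract_patches(hi, e, patch_stride)
    n <- dim(pl$patches)[3]
    xs[[length(xs) + 1L]] <- matrix(pl$patches, e * e, n)
    ys[[length(ys) + 1L]] <- matrix(ph$patches, e * e, n)
  }
  X <- do.call(cbind, xs)
  Y <- do.call(cbind, ys)
  n <- ncol(X)
  if (n == 0) stop("zero patches extracted")
  opt <- adam_init(model)
  log <- vector("list", epochs)
  snaps <- list()
  with_seed(seed, {
    n_val <- max(if (val_frac > 0) 1L else 0L, floor(val_frac * n))
    val_idx <- if (n_val > 0) sample.int(n, n_val) else integer(0)
    tr_idx <- setdiff(seq_len(n), val_idx)
    for (ep in seq_len(epochs)) {
      ord <- sample(tr_idx)
      losses <- c(); mses <- c()
      for (s in seq(1, length(ord), by = batch_size)) {
        idx <- ord[s:min(s + batch_size - 1, length(ord))]
        xb <- X[, idx, drop = FALSE]
        yb <- Y[, idx, drop = FALSE]
        fwd <- cnn_forward(model, xb, cache = TRUE)
        losses <- c(losses, psnr_loss(fwd$out, yb))
        mses <- c(mses, mean((fwd$out - yb)^2))
        grads <- cnn_backward(model, fwd, psnr_loss_grad(fwd$out, yb))
        st <- adam_step(model, grads, opt, lr = lr)
        model <- st$model; opt <- st$opt
      }
      val_mse <- if (length(val_idx)) {
        pv <- predict_batched(model, X[, val_idx, drop = FALSE])
        mean((pv - Y[, val_idx, drop = FALSE])^2)
      } else NA_real_
      log[[ep]] <- tibble::tibble(epoch = ep, train_loss = mean(losses),
                                  train_mse = mean(mses), val_mse = val_mse)
      if (verbose) {
        message(sprintf("epoch %3d  loss %.5f  mse %.2e  val %.2e",
                        ep, mean(losses), mean(mses), val_mse))
      }
      if (ep %in% snapshot_epochs) {
        snaps[[as.character(ep)]] <- model$layers
      }
    }
  })
  model$trained <- TRUE
  model$log <- dplyr::bind_rows(log)
  model$snapshots <- if (length(snaps)) snaps else NULL
  model
}

# forward pass in manageable batches (no cache)
predict_batched <- function(model, X, batch_size = 64) {
  out <- matrix(0, nrow(X), ncol(X))
  for (s in seq(1, ncol(X), by = batch_size)) {
    idx <- s:min(s + batch_size - 1, ncol(X))
    out[, idx] <- cnn_forward(model, X[, idx, drop = FALSE])
  }
  out
}

#' Restore a stored weight snapshot
#'
#' Returns a copy of the model with the weights it had after the requested
#' epoch (recorded via `snapshot_epochs` in [train_cnn()]).
#'
#' @param model a trained `tomo_cnn` with snapshots.
#' @param epoch epoch number of the stored snapshot.
#' @export
model_at_epoch <- function(model, epoch) {
  key <- as.character(epoch)
  if (is.null(model$snapshots[[key]])) {
    stop("no snapshot stored for epoch ", epoch)
  }
  model$layers <- model$snapshots[[key]]
  model$log <- model$log[model$log$epoch <= epoch, ]
  model
}
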
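# Training loop (SGD + Nesterov momentum, polynomial learning-rate policy,
# deep supervision, one memory-bank push per optimizer step), deterministic
# inference, checkpointing, and the ablation harness.

#' Training configuration
#'
#' Defaults follow the full-scale schedule (1000 epochs of 250 iterations,
#' 2D batch 12, Nesterov momentum 0.99, poly power 0.9, Dice and
#' cross-entropy equally weighted); scale them down for desk-size
#' experiments.
#'
#' @param epochs Number of epochs.
#' @param iters_per_epoch Optimizer steps per epoch.
#' @param batch_size 2D slice batch size.
#' @param batch_3d 3D patch batch size (carried for 3D pipelines; the
#'   reference trainer is 2D).
#' @param base_lr Base learning rate.
#' @param momentum Nesterov momentum, in (0, 1).
#' @param poly_power Exponent of the polynomial learning-rate policy.
#' @param dice_weight,ce_weight Loss mixing weights (1:1 by default).
#' @param dice_eps Dice denominator smoothing.
#' @param val_slice_cap Maximum number of validation slices scored per epoch
#'   for the log's running DSC.
#' @param seed Seed governing batch sampling (and everything downstream).
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 1000L, iters_per_epoch = 250L,
                         batch_size = 12L, batch_3d = 2L, base_lr = 0.01,
                         momentum = 0.99, poly_power = 0.9,
                         dice_weight = 1, ce_weight = 1, dice_eps = 1e-5,
                         val_slice_cap = 16L, seed = 1L) {
  if (epochs < 1L) stop("`epochs` must be at least 1")
  if (momentum <= 0 || momentum >= 1) stop("`momentum` must lie in (0, 1)")
  structure(list(epochs = as.integer(epochs),
                 iters_per_epoch = as.integer(iters_per_epoch),
                 batch_size = as.integer(batch_size),
                 batch_3d = as.integer(batch_3d),
                 base_lr = base_lr, momentum = momentum,
                 poly_power = poly_power, dice_weight = dice_weight,
                 ce_weight = ce_weight, dice_eps = dice_eps,
                 val_slice_cap = as.integer(val_slice_cap),
                 seed = as.integer(seed)),
            class = "train_config")
}

one_hot <- function(t, k) {
  v <- matrix(0, length(t), k)
  v[cbind(seq_along(t), as.integer(t) + 1L)] <- 1
  v
}

# Nearest-neighbour downsampling of a (H, W, N) label stack by factor f.
downsample_labels <- function(y, f) {
  if (f == 1L) return(y)
  y[seq(1L, dim(y)[1], by = f), seq(1L, dim(y)[2], by = f), , drop = FALSE]
}

# Per-batch loss and per-scale logit gradients under deep supervision.
batch_loss_grad <- function(fw, y, cfg, tc) {
  ds <- ds_scales(cfg)
  n <- dim(y)[3]
  k <- cfg$n_classes
  dlogits <- vector("list", length(fw$logits))
  loss <- 0
  for (si in seq_along(ds$scales)) {
    j <- ds$scales[si]
    w <- ds$weights[si]
    lg <- fw$logits[[j]]
    yj <- downsample_labels(y, 2L^(j - 1L))
    dl <- lg * 0
    for (i in seq_len(n)) {
      v <- one_hot(as.vector(yj[, , i]), k)
      r <- total_loss_grad_logits(sample_mat(lg, i), v, tc$dice_eps,
                                  tc$dice_weight, tc$ce_weight)
      loss <- loss + w * r$loss / n
      dl[, , i, ] <- (w / n) * r$grad
    }
    dlogits[[j]] <- dl
  }
  list(loss = loss, dlogits = dlogits)
}

# Per-position argmax class over the channel axis of a (H, W, N, L) array.
argmax_channels <- function(probs) {
  d <- dim(probs)
  cls <- max.col(as_feat_mat(probs), ties.method = "first") - 1L
  dim(cls) <- d[1:3]
  cls
}

# Fast mean 2D DSC of argmax predictions against labels on a slice batch.
slice_dsc <- function(probs_main, y) {
  pred <- argmax_channels(probs_main)
  vals <- vapply(seq_len(dim(y)[3]), function(i) {
    tp <- sum(pred[, , i] == 1L & y[, , i] == 1L)
    fp <- sum(pred[, , i] == 1L & y[, , i] == 0L)
    fn <- sum(pred[, , i] == 0L & y[, , i] == 1L)
    if (tp + fp + fn == 0) NA_real_ else 100 * 2 * tp / (fp + fn + 2 * tp)
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}

slices_to_batch <- function(slices, idx) {
  h <- nrow(slices[[idx[1]]]$image)
  w <- ncol(slices[[idx[1]]]$image)
  x <- array(0, c(h, w, length(idx), 1L))
  y <- array(0L, c(h, w, length(idx)))
  for (i in seq_along(idx)) {
    x[, , i, 1] <- slices[[idx[i]]]$image
    y[, , i] <- slices[[idx[i]]]$mask
  }
  list(x = x, y = y)
}

#' Train an MCM-UNet
#'
#' Runs `epochs * iters_per_epoch` steps of SGD with Nesterov momentum on the
#' deep-supervision Dice + cross-entropy objective, with the learning rate
#' following the polynomial policy per epoch. When the memory bank is
#' enabled, the batch-mean fused bottleneck feature is pushed once per
#' optimizer step (FIFO). Fully reproducible for a given seed on one device.
#'
#' @param model A [mcm_unet()].
#' @param data Training slices: a list of `list(image, mask)` 2D pairs
#'   matching the configured patch size (e.g. from [make_slices_2d()]).
#' @param tc A [train_config()].
#' @param val_data Optional validation slices in the same format, scored
#'   (capped at `tc$val_slice_cap` slices) once per epoch.
#' @param verbose Print per-epoch progress.
#' @return An object of class `mcm_unet_fit`: the trained model, the two
#'   configs, and a per-epoch log (`epoch`, `lr`, `loss`, `val_dsc`).
#' @export
train_mcm_unet <- function(model, data, tc = train_config(), val_data = NULL,
                           verbose = FALSE) {
  if (!inherits(model, "mcm_unet")) stop("`model` must be a mcm_unet")
  if (length(data) == 0L) stop("empty training dataset")
  cfg <- model$cfg
  params <- model$params
  bank <- model$bank
  state <- NULL
  log <- vector("list", tc$epochs)
  val_batch <- NULL
  if (!is.null(val_data) && length(val_data) > 0L) {
    vi <- seq_len(min(tc$val_slice_cap, length(val_data)))
    val_batch <- slices_to_batch(val_data, vi)
  }
  with_seed(tc$seed, {
    for (epoch in seq_len(tc$epochs)) {
      lr <- tc$base_lr * poly_lr(epoch - 1L, tc$epochs, tc$poly_power)
      epoch_loss <- 0
      for (it in seq_len(tc$iters_per_epoch)) {
        idx <- sample.int(length(data), tc$batch_size, replace = TRUE)
        b <- slices_to_batch(data, idx)
        m_cur <- list(cfg = cfg, params = params, bank = bank)
        class(m_cur) <- "mcm_unet"
        fw <- net_forward(m_cur, b$x, train = TRUE)
        lg <- batch_loss_grad(fw, b$y, cfg, tc)
        if (!is.finite(lg$loss))
          stop(sprintf("non-finite loss at epoch %d, iteration %d", epoch, it))
        grads <- net_backward(m_cur, fw, lg$dlogits)
        upd <- sgd_step(params, grads, state, lr, tc$momentum)
        params <- upd$p
        state <- upd$v
        if (!is.null(bank) && fw$flags$use_mb) {
          fused_mean <- Reduce(`+`, fw$fused) / length(fw$fused)
          bank <- bank_update(bank, fused_mean)
        }
        epoch_loss <- epoch_loss + lg$loss
      }
      epoch_loss <- epoch_loss / tc$iters_per_epoch
      val_dsc <- NA_real_
      if (!is.null(val_batch)) {
        m_cur <- structure(list(cfg = cfg, params = params, bank = bank),
                           class = "mcm_unet")
        fv <- net_forward(m_cur, val_batch$x, train = FALSE)
        val_dsc <- slice_dsc(fv$probs[[1]], val_batch$y)
      }
      log[[epoch]] <- data.frame(epoch = epoch, lr = lr, loss = epoch_loss,
                                 val_dsc = val_dsc)
      if (verbose)
        message(sprintf("epoch %3d  lr %.5f  loss %8.4f  val DSC %s",
                        epoch, lr, epoch_loss,
                        if (is.na(val_dsc)) "-" else sprintf("%.2f", val_dsc)))
    }
  })
  model$params <- params
  model$bank <- bank
  structure(list(model = model, train_config = tc, log = do.call(rbind, log)),
            class = "mcm_unet_fit")
}

#' @export
print.mcm_unet_fit <- function(x, ...) {
  n <- nrow(x$log)
  cat(sprintf("<mcm_unet_fit> %d epochs x %d iterations, final loss %.4f%s\n",
              n, x$train_config$iters_per_epoch, x$log$loss[n],
              if (is.na(x$log$val_dsc[n])) "" else
                sprintf(", final val DSC %.2f%%", x$log$val_dsc[n])))
  print(x$model)
  invisible(x)
}

#' @export
summary.mcm_unet_fit <- function(object, ...) {
  cat("Training log (first/last epochs):\n")
  lg <- object$log
  print(utils::head(lg, 3), row.names = FALSE)
  if (nrow(lg) > 6) cat("...\n")
  print(utils::tail(lg, 3), row.names = FALSE)
  invisible(object$log)
}

#' @export
plot.mcm_unet_fit <- function(x, ...) {
  graphics::plot(x$log$epoch, x$log$loss, type = "l", xlab = "epoch",
                 ylab = "training loss", main = "MCM-UNet training", ...)
  invisible(x)
}

#' Segment a volume with a trained model
#'
#' Applies the preprocessing chain (optional resampling to the training
#' spacing, Z-score normalization, symmetric padding/cropping of axial
#' slices to the patch size), runs the network in eval mode (memory bank
#' frozen), takes the per-pixel argmax, and restores the mask to the input
#' volume's original grid.
#'
#' @param object A `mcm_unet_fit` (or a bare [mcm_unet()] via
#'   `predict(fit, ...)` semantics).
#' @param volume A [as_volume()] object (or rank-3 array).
#' @param target_spacing Optional spacing the model was trained at; when
#'   given, the volume is resampled before inference and the mask resampled
#'   back (nearest-neighbour).
#' @param chunk Number of slices per forward pass.
#' @param ... Unused.
#' @return An integer mask `volume` aligned with the input.
#' @export
predict.mcm_unet_fit <- function(object, volume, target_spacing = NULL,
                                 chunk = 8L, ...) {
  model <- object$model
  if (!inherits(volume, "volume")) volume <- as_volume(volume)
  orig <- volume
  if (!is.null(target_spacing)) volume <- resample(volume, target_spacing)
  v <- znorm(volume)
  d <- dim(v$grid)
  ps <- model$cfg$patch_size
  nz <- d[3]
  pred <- array(0L, c(ps, nz))
  for (lo in seq(1L, nz, by = chunk)) {
    ks <- lo:min(lo + chunk - 1L, nz)
    x <- array(0, c(ps, length(ks), 1L))
    for (i in seq_along(ks))
      x[, , i, 1] <- pad_crop_2d(v$grid[, , ks[i]], ps[1])
    fw <- net_forward(model, x, train = FALSE)
    pred[, , ks] <- argmax_channels(fw$probs[[1]])
  }
  # undo the symmetric pad/crop back to the (resampled) grid
  restored <- array(0L, d)
  for (k in seq_len(nz))
    restored[, , k] <- unpad_2d(pred[, , k], d[1:2])
  out <- as_volume(restored, volume$spacing, volume$affine)
  if (!is.null(target_spacing)) {
    g <- restored
    for (ax in 1:3) {
      at <- (seq_len(dim(orig$grid)[ax]) - 1) * orig$spacing[ax] /
        volume$spacing[ax] + 1
      g <- interp_axis(g, ax, at, "nearest")
    }
    storage.mode(g) <- "integer"
    out <- as_volume(g, orig$spacing, orig$affine)
  }
  out
}

# Invert pad_crop_2d: recover a d_out-shaped matrix from a square `size`
# canvas produced by symmetric padding/cropping.
unpad_2d <- function(m, d_out) {
  size <- dim(m)
  out <- matrix(0L, d_out[1], d_out[2])
  for (ax in 1:2) {
    n <- d_out[ax]
    if (n <= size[ax]) {
      lo <- (size[ax] - n) %/% 2
      m <- if (ax == 1) m[lo + seq_len(n), , drop = FALSE] else
        m[, lo + seq_len(n), drop = FALSE]
    } else {
      lo <- (n - size[ax]) %/% 2
      if (ax == 1) {
        tmp <- matrix(0L, n, ncol(m)); tmp[lo + seq_len(size[ax]), ] <- m
      } else {
        tmp <- matrix(0L, nrow(m), n); tmp[, lo + seq_len(size[ax])] <- m
      }
      m <- tmp
    }
  }
  m
}

#' Save / load a model checkpoint
#'
#' Checkpoints embed the network config, parameters, memory-bank state,
#' training config and log.
#'
#' @param object A `mcm_unet` or `mcm_unet_fit`.
#' @param path Destination file.
#' @return `path` (save) or the restored object (load).
#' @export
save_checkpoint <- function(object, path) {
  if (!inherits(object, c("mcm_unet", "mcm_unet_fit")))
    stop("`object` must be a mcm_unet or mcm_unet_fit")
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)

#' Train and evaluate the four ablation configurations
#'
#' Trains the backbone alone, backbone + CM, backbone + MB, and the full
#' model under identical seeds and data, then scores each on held-out cases.
#'
#' @param cfg Base [mcm_unet_config()] (its `use_cm`/`use_mb` are overridden
#'   per row).
#' @param tc A [train_config()].
#' @param data Training slices (see [train_mcm_unet()]).
#' @param val_cases Held-out cases: list of `list(volume, mask)` pairs.
#' @return Data frame with one row per configuration (`use_cm`, `use_mb`,
#'   mean `assd_voxel`, `hd95_voxel`, `jaccard_pct`, `dsc_pct`), with the
#'   per-config fits in attribute `"fits"`.
#' @export
ablation_run <- function(cfg, tc, data, val_cases) {
  combos <- expand.grid(use_cm = c(FALSE, TRUE), use_mb = c(FALSE, TRUE))
  fits <- list()
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    ci <- cfg
    ci$use_cm <- combos$use_cm[i]
    ci$use_mb <- combos$use_mb[i]
    fit <- train_mcm_unet(mcm_unet(ci), data, tc)
    fits[[i]] <<- fit
    mets <- vapply(val_cases, function(vc) {
      pr <- predict(fit, vc$volume)
      gt <- if (inherits(vc$mask, "volume")) vc$mask$grid else vc$mask
      if (!any(pr$grid > 0))
        return(c(assd_voxel = NA_real_, hd95_voxel = NA_real_,
                 jaccard_pct = 0, dsc_pct = 0))
      c(assd_voxel = assd(gt, pr$grid), hd95_voxel = hd95(gt, pr$grid),
        jaccard_pct = jaccard(gt, pr$grid), dsc_pct = dsc(gt, pr$grid))
    }, numeric(4))
    data.frame(use_cm = combos$use_cm[i], use_mb = combos$use_mb[i],
               t(rowMeans(mets, na.rm = TRUE)))
  })
  structure(do.call(rbind, rows), fits = fits)
}
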
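# MCM-UNet: nnU-Net-style 2D encoder-decoder with two conv-norm-nonlinearity
# blocks per stage, strided-conv downsampling, transposed-conv upsampling,
# instance normalization and leaky rectifiers; a deep-supervision head at
# every decoder scale; a CM attention block on each decoder skip connection
# (except the full-resolution step); and a FIFO memory bank fusing
# dataset-level features into the deepest stage.

#' Network configuration
#'
#' @param n_stages Number of resolution stages (encoder depth).
#' @param base_channels Channels at full resolution; doubled per stage.
#' @param max_channels Channel cap.
#' @param patch_size In-plane input size; must be divisible by
#'   `2^(n_stages - 1)`.
#' @param in_channels Input image channels (1 for T2W).
#' @param n_classes Output classes (2: background, prostate).
#' @param n_cm_modules Number of CM insertions, counted from the deepest
#'   decoder step; the full-resolution step never carries one, so at most
#'   `n_stages - 2` take effect.
#' @param bank_capacity Memory-bank capacity `m` (>= 3 when `use_mb`).
#' @param use_cm,use_mb Ablation switches for the CM modules and the memory
#'   bank.
#' @param attn_scale Attention logit scaling, `"C"` or `"sqrtC"` (see
#'   [attention_similarity()]).
#' @param seed Integer seed governing parameter initialization.
#' @return A `mcm_unet_config` list.
#' @export
mcm_unet_config <- function(n_stages = 6L, base_channels = 32L,
                            max_channels = 320L, patch_size = c(512L, 512L),
                            in_channels = 1L, n_classes = 2L,
                            n_cm_modules = 6L, bank_capacity = 64L,
                            use_cm = TRUE, use_mb = TRUE,
                            attn_scale = c("C", "sqrtC"), seed = 1L) {
  attn_scale <- match.arg(attn_scale)
  n_stages <- as.integer(n_stages)
  patch_size <- rep(as.integer(patch_size), length.out = 2L)
  if (n_stages < 2L) stop("at least 2 stages are required")
  if (any(patch_size %% 2L^(n_stages - 1L) != 0L))
    stop("patch_size must be divisible by 2^(n_stages - 1)")
  if (use_mb && bank_capacity < 3L)
    stop("bank capacity must be at least 3 when the memory bank is enabled")
  if (n_cm_modules < 0L) stop("n_cm_modules must be nonnegative")
  cfg <- list(n_stages = n_stages, base_channels = as.integer(base_channels),
              max_channels = as.integer(max_channels),
              patch_size = patch_size, in_channels = as.integer(in_channels),
              n_classes = as.integer(n_classes),
              n_cm_modules = as.integer(n_cm_modules),
              bank_capacity = as.integer(bank_capacity),
              use_cm = isTRUE(use_cm), use_mb = isTRUE(use_mb),
              attn_scale = attn_scale, seed = as.integer(seed))
  class(cfg) <- "mcm_unet_config"
  cfg
}

stage_channels <- function(cfg, j) {
  pmin(cfg$base_channels * 2L^(j - 1L), cfg$max_channels)
}

# Decoder scales (1 = full resolution) carrying a CM block.
cm_scales <- function(cfg, use_cm = cfg$use_cm) {
  if (!use_cm || cfg$n_cm_modules == 0L) return(integer(0))
  eligible <- seq(cfg$n_stages - 1L, 2L)  # deepest decoder step first
  if (cfg$n_stages < 3L) return(integer(0))
  eligible[seq_len(min(cfg$n_cm_modules, length(eligible)))]
}

# Decoder scales included in the deep-supervision loss: all of them when
# there are at most 3, otherwise all but the two lowest-resolution ones
# (nnU-Net convention). Weights halve with each downsampling, normalized.
ds_scales <- function(cfg) {
  n_dec <- cfg$n_stages - 1L
  scales <- seq_len(if (n_dec > 3L) n_dec - 2L else n_dec)
  w <- 2^(-(scales - 1))
  list(scales = scales, weights = w / sum(w))
}

init_block_params <- function(cin, cout) {
  list(conv1 = list(W = he_weights(9 * cin, cout, 9 * cin),
                    b = numeric(cout)),
       in1 = list(gamma = rep(1, cout), beta = numeric(cout)),
       conv2 = list(W = he_weights(9 * cout, cout, 9 * cout),
                    b = numeric(cout)),
       in2 = list(gamma = rep(1, cout), beta = numeric(cout)))
}

#' Construct an MCM-UNet model
#'
#' Parameters are initialized from `cfg$seed`; backbone parameters are drawn
#' before CM and memory-bank parameters, so models built with different
#' ablation flags but the same seed share an identical backbone.
#'
#' @param cfg A [mcm_unet_config()].
#' @return An object of class `mcm_unet`: `list(cfg, params, bank)`.
#' @export
mcm_unet <- function(cfg = mcm_unet_config()) {
  if (!inherits(cfg, "mcm_unet_config")) stop("`cfg` must be a mcm_unet_config")
  s <- cfg$n_stages
  params <- with_seed(cfg$seed, {
    p <- list(enc = vector("list", s), dec = vector("list", s - 1L))
    for (j in seq_len(s)) {
      cin <- if (j == 1L) cfg$in_channels else stage_channels(cfg, j - 1L)
      p$enc[[j]] <- init_block_params(cin, stage_channels(cfg, j))
    }
    for (j in seq(s - 1L, 1L)) {
      cj <- stage_channels(cfg, j)
      cj1 <- stage_channels(cfg, j + 1L)
      p$dec[[j]] <- c(
        list(up = list(W = he_weights(cj1, 4L * cj, cj1),
                       b = numeric(cj))),
        init_block_params(2L * cj, cj),
        list(head = list(W = he_weights(cj, cfg$n_classes, cj),
                         b = numeric(cfg$n_classes))))
    }
    if (cfg$use_cm) {
      p$cm <- list()
      for (j in cm_scales(cfg)) p$cm[[as.character(j)]] <-
          init_cm_params(stage_channels(cfg, j))
    }
    if (cfg$use_mb) p$mb <- init_fuse_params(stage_channels(cfg, s))
    p
  })
  structure(list(cfg = cfg, params = params,
                 bank = if (cfg$use_mb) memory_bank(cfg$bank_capacity)),
            class = "mcm_unet")
}

#' @export
print.mcm_unet <- function(x, ...) {
  cfg <- x$cfg
  n_par <- sum(unlist(rapply(x$params, length, how = "list")))
  cat(sprintf(paste0("<mcm_unet> %d stages, base %d channels, patch %dx%d, ",
                     "%s CM module(s), memory bank %s (m = %d), ",
                     "%s parameters\n"),
              cfg$n_stages, cfg$base_channels, cfg$patch_size[1],
              cfg$patch_size[2], length(cm_scales(cfg)),
              if (cfg$use_mb) "on" else "off", cfg$bank_capacity,
              format(n_par, big.mark = ",")))
  invisible(x)
}

block_fwd <- function(x, bp, stride1) {
  c1 <- conv_fwd(x, bp$conv1$W, bp$conv1$b, stride = stride1)
  n1 <- instnorm_fwd(c1$y, bp$in1$gamma, bp$in1$beta)
  a1 <- lrelu_fwd(n1$y)
  c2 <- conv_fwd(a1$y, bp$conv2$W, bp$conv2$b, stride = 1L)
  n2 <- instnorm_fwd(c2$y, bp$in2$gamma, bp$in2$beta)
  a2 <- lrelu_fwd(n2$y)
  list(y = a2$y, cache = list(c1 = c1$cache, n1 = n1$cache, a1 = a1$cache,
                              c2 = c2$cache, n2 = n2$cache, a2 = a2$cache))
}

block_bwd <- function(dy, bp, cache) {
  d <- lrelu_bwd(dy, cache$a2)
  i2 <- instnorm_bwd(d, cache$n2)
  cb2 <- conv_bwd(i2$dx, bp$conv2$W, cache$c2)
  d <- lrelu_bwd(cb2$dx, cache$a1)
  i1 <- instnorm_bwd(d, cache$n1)
  cb1 <- conv_bwd(i1$dx, bp$conv1$W, cache$c1)
  list(dx = cb1$dx,
       g = list(conv1 = list(W = cb1$dW, b = cb1$db),
                in1 = list(gamma = i1$dgamma, beta = i1$dbeta),
                conv2 = list(W = cb2$dW, b = cb2$db),
                in2 = list(gamma = i2$dgamma, beta = i2$dbeta)))
}

sample_mat <- function(arr, n) {
  d <- dim(arr)
  f <- arr[, , n, , drop = FALSE]
  dim(f) <- c(d[1] * d[2], d[4])
  f
}

check_finite <- function(x, where) {
  if (!is.finite(sum(x)))
    stop("non-finite activations at ", where)
  invisible(x)
}

#' Run the network forward
#'
#' @param model A [mcm_unet()] (or a trained `mcm_unet_fit`, whose model is
#'   used).
#' @param x Input batch: `(H, W, N)` or `(H, W, N, C_in)` array matching the
#'   configured patch size.
#' @param train Logical; `TRUE` keeps layer caches for the backward pass and
#'   returns the fused bottleneck features for a bank update. In eval mode
#'   (`FALSE`) the bank is frozen and two passes over the same input are
#'   identical.
#' @param use_cm,use_mb Optional runtime overrides of the ablation flags
#'   (only disabling is possible; modules whose parameters were never built
#'   cannot be switched on).
#' @return List with `probs` and `logits` (per decoder scale, element 1 =
#'   full-resolution main head, each `(H_j, W_j, N, L)`), `fused` (per-sample
#'   fused bottleneck feature matrices, when `use_mb`), and `caches` (when
#'   `train`).
#' @export
net_forward <- function(model, x, train = FALSE, use_cm = NULL,
                        use_mb = NULL) {
  if (inherits(model, "mcm_unet_fit")) model <- model$model
  cfg <- model$cfg
  p <- model$params
  use_cm <- (use_cm %||% cfg$use_cm) && !is.null(p$cm)
  use_mb <- (use_mb %||% cfg$use_mb) && !is.null(p$mb)
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  if (d[1] != cfg$patch_size[1] || d[2] != cfg$patch_size[2] ||
      d[4] != cfg$in_channels)
    stop("input shape does not match the configured patch size")
  s <- cfg$n_stages
  n <- d[3]

  enc <- vector("list", s)
  cache <- list(enc = vector("list", s), dec = vector("list", s - 1L))
  cur <- x
  for (j in seq_len(s)) {
    bf <- block_fwd(cur, p$enc[[j]], stride1 = if (j == 1L) 1L else 2L)
    check_finite(bf$y, paste0("encoder stage ", j))
    enc[[j]] <- bf$y
    if (train) cache$enc[[j]] <- bf$cache
    cur <- bf$y
  }

  fused <- NULL
  if (use_mb) {
    db <- dim(cur)
    fused_arr <- cur
    fused <- vector("list", n)
    cache$mb <- vector("list", n)
    for (i in seq_len(n)) {
      f <- sample_mat(cur, i)
      sel <- bank_query(model$bank, f)
      fw <- fuse_forward(sel, f, p$mb)
      fused_arr[, , i, ] <- fw$out
      fused[[i]] <- fw$out
      if (train) cache$mb[[i]] <- fw$cache
    }
    check_finite(fused_arr, "memory-bank fusion")
    cur <- fused_arr
  }

  logits <- vector("list", s - 1L)
  cm_js <- if (use_cm) cm_scales(cfg) else integer(0)
  for (j in seq(s - 1L, 1L)) {
    dp <- p$dec[[j]]
    up <- upconv_fwd(cur, dp$up$W, dp$up$b)
    cat_in <- concat_channels(up$y, enc[[j]])
    bf <- block_fwd(cat_in, dp, stride1 = 1L)
    check_finite(bf$y, paste0("decoder scale ", j))
    hd <- conv1x1_fwd(bf$y, dp$head$W, dp$head$b)
    logits[[j]] <- hd$y
    st_cache <- list(up = up$cache, block = bf$cache, head = hd$cache,
                     c_up = dim(up$y)[4])
    if (j %in% cm_js) {
      cmp <- p$cm[[as.character(j)]]
      out_arr <- bf$y
      st_cache$cm <- vector("list", n)
      for (i in seq_len(n)) {
        cf <- cm_forward(sample_mat(bf$y, i), sample_mat(hd$y, i), cmp,
                         cfg$attn_scale)
        out_arr[, , i, ] <- cf$out
        if (train) st_cache$cm[[i]] <- cf$cache
      }
      check_finite(out_arr, paste0("CM block at decoder scale ", j))
      cur <- out_arr
    } else {
      cur <- bf$y
    }
    if (train) cache$dec[[j]] <- st_cache
  }

  list(logits = logits,
       # softmaxed maps are only materialized outside training steps, where
       # the loss gradient works on the logits directly
       probs = if (!train) lapply(logits, softmax_channels),
       fused = fused,
       caches = if (train) cache,
       flags = list(use_cm = use_cm, use_mb = use_mb, cm_js = cm_js))
}

zero_like <- function(x) if (is.list(x)) lapply(x, zero_like) else x * 0

add_grads <- function(a, b) {
  if (is.list(a)) Map(add_grads, a, b) else a + b
}

# Backward pass through the whole network. `fw` is a net_forward(train=TRUE)
# result; `dlogits` a list over decoder scales (NULL entries mean no direct
# loss gradient at that scale; CM blocks still route gradient into their
# logits). Returns parameter gradients mirroring model$params.
net_backward <- function(model, fw, dlogits) {
  cfg <- model$cfg
  p <- model$params
  s <- cfg$n_stages
  cache <- fw$caches
  cm_js <- fw$flags$cm_js
  use_mb <- fw$flags$use_mb
  grads <- list(enc = vector("list", s), dec = vector("list", s - 1L))
  if (!is.null(p$cm)) grads$cm <- lapply(p$cm, zero_like)
  if (!is.null(p$mb)) grads$mb <- zero_like(p$mb)

  d_skip <- vector("list", s)
  d_out <- NULL  # gradient w.r.t. the current decoder stage's output
  for (j in seq_len(s - 1L)) {
    dp <- p$dec[[j]]
    st <- cache$dec[[j]]
    dl <- dlogits[[j]]
    if (is.null(dl)) dl <- fw$logits[[j]] * 0
    if (j == 1L) {
      d_fsf <- NULL  # nothing consumes the full-resolution stage output
    }
    if (j %in% cm_js) {
      n <- dim(dl)[3]
      d_fsf_arr <- d_out * 0
      cmp <- p$cm[[as.character(j)]]
      for (i in seq_len(n)) {
        cb <- cm_backward(sample_mat(d_out, i), cmp, st$cm[[i]])
        d_fsf_arr[, , i, ] <- cb$dfsf
        dl[, , i, ] <- sample_mat(dl, i) + cb$dlogits
        grads$cm[[as.character(j)]]$Wc <-
          grads$cm[[as.character(j)]]$Wc + cb$dWc
        grads$cm[[as.character(j)]]$bc <-
          grads$cm[[as.character(j)]]$bc + cb$dbc
      }
      d_fsf <- d_fsf_arr
    } else if (j > 1L) {
      d_fsf <- d_out
    }
    hb <- conv1x1_bwd(dl, dp$head$W, st$head)
    d_fsf <- if (is.null(d_fsf)) hb$dx else d_fsf + hb$dx
    bb <- block_bwd(d_fsf, dp, st$block)
    c_up <- st$c_up
    d_cat <- bb$dx
    d_up_y <- d_cat[, , , seq_len(c_up), drop = FALSE]
    d_skip[[j]] <- d_cat[, , , c_up + seq_len(dim(d_cat)[4] - c_up),
                         drop = FALSE]
    ub <- upconv_bwd(d_up_y, dp$up$W, st$up)
    grads$dec[[j]] <- c(list(up = list(W = ub$dW, b = ub$db)), bb$g,
                        list(head = list(W = hb$dW, b = hb$db)))
    d_out <- ub$dx
  }

  # d_out now holds the gradient w.r.t. the (possibly fused) bottleneck
  if (use_mb) {
    d_bot <- d_out * 0
    n <- dim(d_out)[3]
    for (i in seq_len(n)) {
      fb <- fuse_backward(sample_mat(d_out, i), p$mb, cache$mb[[i]])
      d_bot[, , i, ] <- fb$dfsf
      grads$mb$Wd <- grads$mb$Wd + fb$dWd
      grads$mb$bd <- grads$mb$bd + fb$dbd
    }
    d_out <- d_bot
  }

  d_enc <- d_out  # gradient w.r.t. enc[[s]]
  for (j in seq(s, 1L)) {
    if (j < s) d_enc <- d_enc + d_skip[[j]]
    bb <- block_bwd(d_enc, p$enc[[j]], cache$enc[[j]])
    grads$enc[[j]] <- bb$g
    d_enc <- bb$dx
  }
  grads
}
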
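# Optimization: polynomial learning-rate schedule and stochastic gradient
# descent with Nesterov momentum, applied over the nested parameter lists.

#' Polynomial learning-rate multiplier
#'
#' `(1 - epoch/epoch_max)^power`, evaluated once per epoch (no intra-epoch
#' decay).
#'
#' @param epoch Current epoch, `0 <= epoch <= epoch_max`.
#' @param epoch_max Total number of epochs.
#' @param power Decay exponent (default 0.9).
#' @return Multiplier in `[0, 1]`: 1 at epoch 0, 0 at `epoch_max`.
#' @export
poly_lr <- function(epoch, epoch_max, power = 0.9) {
  if (any(epoch < 0) || any(epoch > epoch_max))
    stop("`epoch` must lie in [0, epoch_max]")
  (1 - epoch / epoch_max)^power
}

# One SGD step with Nesterov momentum over nested parameter/gradient lists:
#   v <- mu * v + g;  p <- p - lr * (g + mu * v)
sgd_step <- function(params, grads, state, lr, momentum = 0.99) {
  if (is.null(state)) state <- zero_like(params)
  walk <- function(p, g, v) {
    if (is.list(p)) {
      out_p <- p; out_v <- v
      for (nm in seq_along(p)) {
        r <- walk(p[[nm]], g[[nm]], v[[nm]])
        out_p[[nm]] <- r$p
        out_v[[nm]] <- r$v
      }
      list(p = out_p, v = out_v)
    } else {
      v <- momentum * v + g
      list(p = p - lr * (g + momentum * v), v = v)
    }
  }
  walk(params, grads, state)
}

scale_grads <- function(g, f) if (is.list(g)) lapply(g, scale_grads, f) else g * f
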
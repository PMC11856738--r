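# Compound training objective: batch-averaged Dice loss plus per-pixel
# cross-entropy, equally weighted, applied at every deep-supervision scale.
# `u` is the softmax output (I pixels x K classes, rows summing to 1) and `v`
# the one-hot ground truth of the same shape.

check_uv <- function(u, v) {
  if (!is.matrix(u)) u <- as.matrix(u)
  if (!is.matrix(v)) v <- as.matrix(v)
  if (!all(dim(u) == dim(v))) stop("`u` and `v` shapes differ")
  if (ncol(u) < 2) stop("at least 2 classes are required")
  if (max(abs(rowSums(u) - 1)) > 1e-4)
    stop("`u` rows must sum to 1 (softmax output expected)")
  if (!all(v %in% c(0, 1)) || any(rowSums(v) != 1))
    stop("`v` must be one-hot")
  list(u = u, v = v)
}

#' Soft Dice loss
#'
#' `-(2/K) * sum_k  sum_i(u_ik v_ik) / (sum_i u_ik + sum_i v_ik + eps)`,
#' ranging from -1 (perfect, for one-hot `u == v`) to 0 (no overlap in any
#' class). The per-class sum runs over background as well as foreground. The
#' smoothing `eps` enters the denominator only, so that batches with an empty
#' class stay finite.
#'
#' @param u Numeric `I x K` matrix of per-pixel class probabilities (rows sum
#'   to 1).
#' @param v `I x K` one-hot ground-truth matrix.
#' @param eps Denominator smoothing (default `1e-5`).
#' @return Scalar in `[-1, 0]`.
#' @export
dice_loss <- function(u, v, eps = 1e-5) {
  m <- check_uv(u, v)
  k <- ncol(m$u)
  num <- colSums(m$u * m$v)
  den <- colSums(m$u) + colSums(m$v) + eps
  -(2 / k) * sum(num / den)
}

#' Mean per-pixel cross-entropy
#'
#' `-(1/I) * sum_i sum_k v_ik log(u_ik)`, with probabilities clipped below at
#' `eps` so the loss stays finite when the network assigns (numerically) zero
#' probability to the true class.
#'
#' @inheritParams dice_loss
#' @param eps Probability clipping floor (default `1e-7`).
#' @return Nonnegative scalar.
#' @export
cross_entropy <- function(u, v, eps = 1e-7) {
  m <- check_uv(u, v)
  -mean(rowSums(m$v * log(pmax(m$u, eps))))
}

#' Compound Dice + cross-entropy loss (1:1 weighting)
#'
#' @inheritParams dice_loss
#' @param dice_eps,ce_eps Smoothing constants passed to [dice_loss()] and
#'   [cross_entropy()].
#' @return Scalar; approaches -1 as `u` approaches the one-hot truth.
#' @export
total_loss <- function(u, v, dice_eps = 1e-5, ce_eps = 1e-7) {
  dice_loss(u, v, dice_eps) + cross_entropy(u, v, ce_eps)
}

#' Deep-supervision loss across decoder scales
#'
#' Weighted sum of [total_loss()] over per-scale `(u, v)` pairs; weights are
#' normalized to sum to 1.
#'
#' @param pairs List of `list(u = , v = )` pairs, one per supervised scale.
#' @param weights Numeric vector of the same length as `pairs`.
#' @return Scalar.
#' @export
deep_supervision_loss <- function(pairs, weights) {
  if (length(pairs) != length(weights))
    stop("number of scales and number of weights differ")
  w <- weights / sum(weights)
  sum(vapply(seq_along(pairs), function(i)
    w[i] * total_loss(pairs[[i]]$u, pairs[[i]]$v), numeric(1)))
}

# Gradient of total_loss with respect to pre-softmax logits (I x K).
# The Dice part is chained through the softmax Jacobian; the cross-entropy
# part uses the exact fused softmax-CE gradient (u - v)/I (clipping only
# affects the reported loss value, not the analytic gradient away from the
# floor).
total_loss_grad_logits <- function(logits, v, dice_eps = 1e-5,
                                   dice_w = 1, ce_w = 1) {
  u <- row_softmax(logits)
  i_n <- nrow(u); k <- ncol(u)
  num <- colSums(u * v)
  den <- colSums(u) + colSums(v) + dice_eps
  # dL_dice/du_ik = -(2/K) * (v_ik * den_k - num_k) / den_k^2
  ddice_du <- cmul(cadd(cmul(v, den), -num), -(2 / k) / den^2)
  ddice <- u * (ddice_du - rowSums(ddice_du * u))
  dce <- (u - v) / i_n
  list(loss = dice_w * dice_loss(u, v, dice_eps) + ce_w * cross_entropy(u, v),
       grad = dice_w * ddice + ce_w * dce, u = u)
}

# Numerically stable row-wise softmax of a matrix. Vector-matrix recycling
# runs down columns, so subtracting/dividing by a length-nrow vector is a
# row-wise operation.
row_softmax <- function(x) {
  mx <- x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  e <- exp(x - mx)
  e / rowSums(e)
}
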
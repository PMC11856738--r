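# Context-modeling (CM) attention block. Operating on one decoder scale, it
# (1) forms per-class region representations as probability-weighted spatial
# averages of the image-level features, (2) redistributes them to pixels
# through the per-position class distribution, (3) computes pixel-to-pixel
# attention between the image-level features and this class-aware map, and
# (4) aggregates the image-level features under that attention before a 1x1
# compression back to the input width. Feature maps here are (HW x C)
# matrices: rows are spatial positions, columns channels.

#' Class-region context features
#'
#' For each class `l`, forms the region representation `R_l` as the spatially
#' normalized, probability-weighted average of the feature rows, then returns
#' the class-aware map whose row `i` is `sum_l probs[i, l] * R_l`.
#'
#' @param fsf Numeric `HW x C` feature matrix (image-level features).
#' @param probs Numeric `HW x L` per-position class distribution (rows sum
#'   to 1, e.g. softmaxed deep-supervision logits).
#' @return `HW x C` matrix (`f_seg`), with attribute `"regions"`: the `L x C`
#'   matrix of region representations.
#' @export
region_context <- function(fsf, probs) {
  if (nrow(fsf) != nrow(probs))
    stop("`fsf` and `probs` must share the number of positions")
  col_tot <- colSums(probs)
  m <- cmul(probs, 1 / pmax(col_tot, 1e-12))  # spatial normalization
  regions <- crossprod(m, fsf)                     # L x C
  fseg <- probs %*% regions
  structure(fseg, regions = regions)
}

#' Attention similarity between image-level and class-aware features
#'
#' Row-softmax of `(fsf %*% t(fseg)) / C` (or `/ sqrt(C)` when
#' `scale = "sqrtC"`); row `i` holds the attention of position `i` over all
#' positions.
#'
#' @param fsf,fseg Numeric `HW x C` matrices with identical dimensions.
#' @param scale `"C"` (divide logits by the channel count, the default) or
#'   `"sqrtC"`.
#' @return `HW x HW` matrix with nonnegative entries and unit row sums.
#' @export
attention_similarity <- function(fsf, fseg, scale = c("C", "sqrtC")) {
  scale <- match.arg(scale)
  if (!all(dim(fsf) == dim(fseg))) stop("`fsf` and `fseg` shapes differ")
  if (!all(is.finite(fsf)) || !all(is.finite(fseg)))
    stop("non-finite values in attention inputs")
  s <- if (scale == "C") ncol(fsf) else sqrt(ncol(fsf))
  row_softmax(tcrossprod(fsf, fseg) / s)
}

#' Aggregate features under attention weights
#'
#' `R_sf = w %*% fsf`: each output position is a convex combination of the
#' input positions.
#'
#' @param w `HW x HW` attention matrix (unit row sums).
#' @param fsf `HW x C` feature matrix.
#' @return `HW x C` matrix.
#' @export
aggregate_context <- function(w, fsf) {
  if (ncol(w) != nrow(fsf) || nrow(w) != nrow(fsf))
    stop("attention and feature shapes are incompatible")
  w %*% fsf
}

#' Initialize the parameters of a CM block
#'
#' @param channels Feature width `C` at the block's scale.
#' @return `list(Wc, bc)`: the `2C x C` compression weights (applied to the
#'   concatenation `[R_sf | fsf]`) and its bias.
#' @export
init_cm_params <- function(channels) {
  list(Wc = he_weights(2 * channels, channels, 2 * channels),
       bc = numeric(channels))
}

#' Apply a CM block to one feature map
#'
#' Normalizes the deep-supervision logits to a per-position class
#' distribution, runs [region_context()], [attention_similarity()] and
#' [aggregate_context()], then concatenates the aggregated context with the
#' input features and compresses channels back to the input width.
#'
#' @param fsf `HW x C` feature matrix.
#' @param logits `HW x L` deep-supervision logits at the same scale.
#' @param params Block parameters from [init_cm_params()].
#' @param scale Attention logit scaling, see [attention_similarity()].
#' @return `HW x C` matrix of refined features.
#' @export
cm_block <- function(fsf, logits, params, scale = "C") {
  cm_forward(fsf, logits, params, scale)$out
}

cm_forward <- function(fsf, logits, params, scale = "C") {
  probs <- row_softmax(logits)
  col_tot <- pmax(colSums(probs), 1e-12)
  m <- cmul(probs, 1 / col_tot)
  regions <- crossprod(m, fsf)
  fseg <- probs %*% regions
  s <- if (identical(scale, "C")) ncol(fsf) else sqrt(ncol(fsf))
  w <- row_softmax(tcrossprod(fsf, fseg) / s)
  rsf <- w %*% fsf
  cat2 <- cbind(rsf, fsf)
  out <- cadd(cat2 %*% params$Wc, params$bc)
  list(out = out,
       cache = list(fsf = fsf, probs = probs, col_tot = col_tot, m = m,
                    regions = regions, fseg = fseg, w = w, cat2 = cat2,
                    s = s))
}

# Backward pass of cm_forward. Returns gradients w.r.t. fsf, the logits and
# the block parameters.
cm_backward <- function(dout, params, cache) {
  cc <- ncol(cache$fsf)
  dWc <- crossprod(cache$cat2, dout)
  dbc <- colSums(dout)
  dcat <- tcrossprod(dout, params$Wc)
  drsf <- dcat[, seq_len(cc), drop = FALSE]
  dfsf <- dcat[, cc + seq_len(cc), drop = FALSE]
  # rsf = w %*% fsf
  dw <- tcrossprod(drsf, cache$fsf)
  dfsf <- dfsf + crossprod(cache$w, drsf)
  # w = row_softmax(logitsW); logitsW = fsf %*% t(fseg) / s
  dlw <- cache$w * (dw - rowSums(dw * cache$w))
  dfsf <- dfsf + (dlw %*% cache$fseg) / cache$s
  dfseg <- crossprod(dlw, cache$fsf) / cache$s
  # fseg = probs %*% regions
  dprobs <- tcrossprod(dfseg, cache$regions)
  dregions <- crossprod(cache$probs, dfseg)
  # regions = t(m) %*% fsf ; m_il = probs_il / col_tot_l
  dfsf <- dfsf + cache$m %*% dregions
  dm <- tcrossprod(cache$fsf, dregions)
  dprobs <- dprobs +
    cmul(cadd(dm, -colSums(dm * cache$m)), 1 / cache$col_tot)
  # probs = row_softmax(logits)
  dlogits <- cache$probs * (dprobs - rowSums(dprobs * cache$probs))
  list(dfsf = dfsf, dlogits = dlogits, dWc = dWc, dbc = dbc)
}
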
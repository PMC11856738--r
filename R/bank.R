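# First-in-first-out memory bank of dataset-level features. Entries are
# feature matrices (HW x C) at the deepest network scale, stored without
# gradient history. Retrieval ranks entries by cosine similarity between
# spatially average-pooled channel descriptors; the three best are fused with
# the incoming image-level feature by a learned 1x1 channel compression.

#' Create an empty memory bank
#'
#' @param capacity Maximum number of stored entries (`m`); at least 3.
#' @return An object of class `memory_bank` with fields `entries` (ordered
#'   list, oldest first) and `capacity`.
#' @export
memory_bank <- function(capacity = 64L) {
  capacity <- as.integer(capacity)
  if (capacity < 3L) stop("bank capacity must be at least 3")
  structure(list(entries = list(), capacity = capacity),
            class = "memory_bank")
}

#' @export
print.memory_bank <- function(x, ...) {
  cat(sprintf("<memory_bank> %d / %d entries\n", length(x$entries),
              x$capacity))
  invisible(x)
}

#' @export
length.memory_bank <- function(x) length(x$entries)

pooled_descriptor <- function(f) colMeans(f)

cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Retrieve the entries most similar to a query feature
#'
#' Ranks stored entries by cosine similarity between spatially
#' average-pooled channel descriptors of the query and each entry, breaking
#' ties by lower (older) bank index, and returns the best `k`.
#'
#' @param bank A [memory_bank()].
#' @param fsf Query feature matrix (`HW x C`).
#' @param k Number of entries to retrieve (default 3).
#' @return List of up to `k` entries (fewer if the bank holds fewer; empty
#'   for an empty bank), with attribute `"indices"` giving their bank
#'   positions.
#' @export
bank_query <- function(bank, fsf, k = 3L) {
  n <- length(bank$entries)
  if (n == 0L) return(structure(list(), indices = integer(0)))
  q <- pooled_descriptor(fsf)
  sims <- vapply(bank$entries, function(e) cosine_sim(q, pooled_descriptor(e)),
                 numeric(1))
  ord <- order(-sims, seq_len(n))[seq_len(min(k, n))]
  structure(bank$entries[ord], indices = ord)
}

#' Initialize the fusion transform of the memory bank
#'
#' @param channels Feature width `C` at the deepest scale.
#' @return `list(Wd, bd)`: `4C x C` compression weights applied to the
#'   concatenation of the three retrieved entries with the query, and bias.
#' @export
init_fuse_params <- function(channels) {
  list(Wd = he_weights(4 * channels, channels, 4 * channels),
       bd = numeric(channels))
}

#' Fuse retrieved bank entries with a query feature
#'
#' Concatenates the (up to three) retrieved entries with `fsf` along
#' channels and compresses `4C -> C` with the learned transform; when fewer
#' than three entries are available the missing blocks are padded by
#' repeating `fsf` (so an empty bank degenerates to a transform of `fsf`
#' alone). Gradients flow into the transform parameters and `fsf`, never
#' into stored entries.
#'
#' @param selected List of up to 3 entries (e.g. from [bank_query()]), each
#'   sharing `fsf`'s shape.
#' @param fsf Query feature matrix (`HW x C`).
#' @param params Fusion parameters from [init_fuse_params()].
#' @return `HW x C` fused feature matrix.
#' @export
bank_fuse <- function(selected, fsf, params) {
  fuse_forward(selected, fsf, params)$out
}

fuse_forward <- function(selected, fsf, params) {
  if (length(selected) > 3L) selected <- selected[1:3]
  n_pad <- 3L - length(selected)
  for (e in selected)
    if (!all(dim(e) == dim(fsf))) stop("bank entry shape differs from query")
  blocks <- c(selected, rep(list(fsf), n_pad), list(fsf))
  cat4 <- do.call(cbind, blocks)
  out <- cadd(cat4 %*% params$Wd, params$bd)
  list(out = out, cache = list(cat4 = cat4, n_pad = n_pad, cc = ncol(fsf)))
}

fuse_backward <- function(dout, params, cache) {
  dWd <- crossprod(cache$cat4, dout)
  dbd <- colSums(dout)
  dcat <- tcrossprod(dout, params$Wd)
  cc <- cache$cc
  # fsf occupies the last block plus any padded blocks; entries get nothing
  dfsf <- dcat[, 3L * cc + seq_len(cc), drop = FALSE]
  if (cache$n_pad > 0L)
    for (p in seq_len(cache$n_pad))
      dfsf <- dfsf + dcat[, (3L - p) * cc + seq_len(cc), drop = FALSE]
  list(dfsf = dfsf, dWd = dWd, dbd = dbd)
}

#' Push a new entry into the bank (FIFO)
#'
#' Appends `entry` (stored detached from any gradient context) and, if the
#' capacity is exceeded, removes the oldest entry.
#'
#' @param bank A [memory_bank()].
#' @param entry Feature matrix with the bank's entry shape.
#' @return The updated bank.
#' @export
bank_update <- function(bank, entry) {
  if (!inherits(bank, "memory_bank")) stop("`bank` must be a memory_bank")
  if (!is.matrix(entry)) stop("bank entries must be HW x C matrices")
  if (length(bank$entries) > 0L &&
      !all(dim(entry) == dim(bank$entries[[1]])))
    stop("entry shape differs from existing bank entries")
  bank$entries <- c(bank$entries, list(entry))
  if (length(bank$entries) > bank$capacity)
    bank$entries <- bank$entries[-1L]
  bank
}
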
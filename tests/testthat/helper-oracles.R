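# Shared fixtures and independent oracles.

# Random binary mask with at least one foreground voxel.
rand_mask <- function(dim3, p = 0.3) {
  repeat {
    m <- array(as.integer(stats::runif(prod(dim3)) < p), dim3)
    if (any(m == 1L)) return(m)
  }
}

# Brute-force boundary set: foreground voxels with a 6-neighbour that is
# background or outside, found by explicit per-voxel neighbourhood checks.
brute_boundary <- function(mask) {
  d <- dim(mask)
  coords <- which(mask == 1L, arr.ind = TRUE)
  on_bd <- apply(coords, 1, function(v) {
    for (ax in 1:3) for (dd in c(-1L, 1L)) {
      nb <- v
      nb[ax] <- nb[ax] + dd
      if (any(nb < 1L) || any(nb > d)) return(TRUE)
      if (mask[nb[1], nb[2], nb[3]] == 0L) return(TRUE)
    }
    FALSE
  })
  coords[on_bd, , drop = FALSE] - 1L
}

# All-pairs directed nearest-boundary distances (the O(|SA|*|SB|) oracle).
brute_directed <- function(from, to, spacing = c(1, 1, 1)) {
  toS <- t(to) * spacing
  vapply(seq_len(nrow(from)), function(i)
    sqrt(min(colSums((toS - from[i, ] * spacing)^2))), numeric(1))
}

brute_surface <- function(a, b, spacing = c(1, 1, 1)) {
  sa <- brute_boundary(a)
  sb <- brute_boundary(b)
  list(a_to_b = brute_directed(sa, sb, spacing),
       b_to_a = brute_directed(sb, sa, spacing))
}

brute_assd <- function(a, b, spacing = c(1, 1, 1)) {
  d <- brute_surface(a, b, spacing)
  (sum(d$a_to_b) + sum(d$b_to_a)) / (length(d$a_to_b) + length(d$b_to_a))
}

brute_hd95 <- function(a, b, spacing = c(1, 1, 1)) {
  d <- brute_surface(a, b, spacing)
  max(stats::quantile(d$a_to_b, 0.95, type = 7, names = FALSE),
      stats::quantile(d$b_to_a, 0.95, type = 7, names = FALSE))
}

brute_hausdorff <- function(a, b) {
  d <- brute_surface(a, b)
  max(d$a_to_b, d$b_to_a)
}

one_hot_mat <- function(labels, k = 2L) {
  v <- matrix(0, length(labels), k)
  v[cbind(seq_along(labels), labels + 1L)] <- 1
  v
}

# Tiny network configuration exercising CM (scale 2) and the memory bank.
tiny_cfg <- function(seed = 7L, bank_capacity = 3L, ...) {
  mcm_unet_config(n_stages = 3L, base_channels = 4L, max_channels = 16L,
                  patch_size = c(8L, 8L), bank_capacity = bank_capacity,
                  seed = seed, ...)
}

tiny_batch <- function(seed = 1L, n = 2L, size = 8L) {
  mcmunet:::with_seed(seed, {
    x <- array(stats::rnorm(size * size * n), c(size, size, n, 1L))
    y <- array(0L, c(size, size, n))
    for (i in seq_len(n)) {
      c0 <- sample(3:(size - 2), 2)
      y[(c0[1] - 1):(c0[1] + 1), (c0[2] - 1):(c0[2] + 1), i] <- 1L
      x[, , i, 1] <- x[, , i, 1] + 2 * y[, , i]
    }
    list(x = x, y = y)
  })
}

# mean in-plane gradient magnitude across the organ boundary of one slice
boundary_gradient <- function(img, mk) {
  gx <- img[-1, ] - img[-nrow(img), ]
  gy <- img[, -1] - img[, -ncol(img)]
  gm <- sqrt(gx[, -ncol(gx)]^2 + gy[-nrow(gy), ]^2)
  bd <- mk[-nrow(mk), -ncol(mk)] != mk[-1, -ncol(mk)] |
    mk[-nrow(mk), -ncol(mk)] != mk[-nrow(mk), -1]
  mean(gm[bd])
}

# boundary-gradient strength at the apex/base slices vs mid-gland
apex_base_vs_mid <- function(seed) {
  ph <- generate_phantom(phantom_spec(seed = seed))
  mk <- ph$mask$grid
  occ <- which(apply(mk, 3, sum) > 0)
  ends <- c(min(occ), max(occ))
  mid <- occ[ceiling(length(occ) / 2)]
  g_end <- mean(vapply(ends, function(k)
    boundary_gradient(ph$volume$grid[, , k], mk[, , k]), numeric(1)))
  g_mid <- boundary_gradient(ph$volume$grid[, , mid], mk[, , mid])
  c(ends = g_end, mid = g_mid)
}
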
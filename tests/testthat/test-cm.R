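# Context-modeling attention block.

test_that("region context reproduces degenerate and hand cases", {
  # probability 1 for class 1 everywhere -> every row is the spatial mean
  fsf <- matrix(c(1, 3, 2, 6), 2, 2)
  probs <- cbind(0, 1)[rep(1, 2), , drop = FALSE]
  probs <- matrix(c(0, 0, 1, 1), 2, 2)
  fseg <- region_context(fsf, probs)
  expect_equal(unname(fseg[1, ]), colMeans(fsf))
  expect_equal(unname(fseg[2, ]), colMeans(fsf))

  # single channel [1; 3] with uniform class-1 weights: R_1 = 2
  fsf1 <- matrix(c(1, 3), 2, 1)
  pr <- matrix(c(0.5, 0.5, 0.5, 0.5), 2, 2)
  fs <- region_context(fsf1, pr)
  expect_equal(unname(attr(fs, "regions")[2, ]), 2)

  # constant features: output constant regardless of probs
  fsfc <- matrix(5, 4, 3)
  prr <- mcmunet:::row_softmax(matrix(rnorm(8), 4, 2))
  expect_equal(unname(region_context(fsfc, prr)), fsfc,
               ignore_attr = TRUE)
  expect_error(region_context(fsf1, pr[1, , drop = FALSE]), "positions")
})

test_that("attention similarity is the row-softmax of fsf fseg' / C", {
  # C = 1, fsf = [1; 0], fseg = [1; 0]: logits [[1,0],[0,0]]
  fsf <- matrix(c(1, 0), 2, 1)
  w <- attention_similarity(fsf, fsf)
  expect_equal(w[1, ], c(exp(1), 1) / (exp(1) + 1), tolerance = 1e-12)
  expect_equal(w[2, ], c(0.5, 0.5))

  # constant fseg -> uniform rows
  set.seed(61)
  fsf2 <- matrix(rnorm(12), 4, 3)
  w2 <- attention_similarity(fsf2, matrix(1, 4, 3))
  expect_equal(unname(w2), matrix(0.25, 4, 4))

  # rows always sum to 1; sqrtC scaling changes temperature only
  for (r in 1:10) {
    a <- matrix(rnorm(5 * 4), 5, 4)
    b <- matrix(rnorm(5 * 4), 5, 4)
    expect_equal(rowSums(attention_similarity(a, b)), rep(1, 5),
                 tolerance = 1e-6)
    expect_equal(rowSums(attention_similarity(a, b, scale = "sqrtC")),
                 rep(1, 5), tolerance = 1e-6)
  }
  expect_error(attention_similarity(a, matrix(Inf, 5, 4)), "non-finite")
})

test_that("aggregation is a convex recombination of feature rows", {
  set.seed(71)
  fsf <- matrix(rnorm(8), 4, 2)
  expect_equal(aggregate_context(diag(4), fsf), fsf)
  wu <- matrix(0.25, 4, 4)
  f1 <- matrix(c(2, 0, 2, 0), 4, 1)
  expect_equal(unname(aggregate_context(matrix(0.25, 4, 4), f1)),
               matrix(1, 4, 1))
  w <- mcmunet:::row_softmax(matrix(rnorm(16), 4, 4))
  r <- aggregate_context(w, fsf)
  for (ch in 1:2) expect_lte(max(abs(r[, ch])), max(abs(fsf[, ch])) + 1e-12)
  expect_error(aggregate_context(w[, 1:3], fsf), "incompatible")
})

test_that("cm_block preserves shape and admits an identity wiring", {
  set.seed(81)
  fsf <- matrix(rnorm(16 * 4), 16, 4)
  logits <- matrix(rnorm(16 * 2), 16, 2)
  params <- init_cm_params(4L)
  out <- cm_block(fsf, logits, params)
  expect_identical(dim(out), dim(fsf))
  # compression initialized to pass through the fsf half: output == fsf
  id_params <- list(Wc = rbind(matrix(0, 4, 4), diag(4)), bc = numeric(4))
  expect_equal(cm_block(fsf, logits, id_params), fsf)
})

test_that("a full CM pass matches a straight-line hand implementation", {
  set.seed(91)
  for (r in 1:5) {
    hw <- 6L; cc <- 3L
    fsf <- matrix(rnorm(hw * cc), hw, cc)
    logits <- matrix(rnorm(hw * 2), hw, 2)
    params <- init_cm_params(cc)

    # straight-line reference, written independently of the block internals
    pr <- exp(logits) / rowSums(exp(logits))
    r1 <- colSums(fsf * pr[, 1]) / sum(pr[, 1])
    r2 <- colSums(fsf * pr[, 2]) / sum(pr[, 2])
    fseg <- pr[, 1] %o% r1 + pr[, 2] %o% r2
    lw <- (fsf %*% t(fseg)) / cc
    w <- exp(lw) / rowSums(exp(lw))
    rsf <- w %*% fsf
    ref <- cbind(rsf, fsf) %*% params$Wc +
      matrix(params$bc, hw, cc, byrow = TRUE)

    expect_equal(region_context(fsf, pr), fseg, ignore_attr = TRUE,
                 tolerance = 1e-12)
    expect_equal(attention_similarity(fsf, fseg), w, tolerance = 1e-12)
    expect_equal(aggregate_context(w, fsf), rsf, tolerance = 1e-12)
    expect_equal(cm_block(fsf, logits, params), ref, tolerance = 1e-12)
  }
})

test_that("CM backward matches finite differences", {
  set.seed(101)
  fsf <- matrix(rnorm(8 * 3), 8, 3)
  logits <- matrix(rnorm(8 * 2), 8, 2)
  params <- init_cm_params(3L)
  # scalar objective: sum of squares of the block output
  fwd <- function(fsf, logits, params)
    sum(mcmunet:::cm_forward(fsf, logits, params)$out^2)
  f0 <- mcmunet:::cm_forward(fsf, logits, params)
  gr <- mcmunet:::cm_backward(2 * f0$out, params, f0$cache)
  e <- 1e-6
  num_grad <- function(get, set) {
    x <- get()
    g <- x * 0
    for (i in seq_along(x)) {
      xp <- x; xp[i] <- xp[i] + e
      xm <- x; xm[i] <- xm[i] - e
      g[i] <- (fwd(set(fsf, logits, params, xp)$fsf,
                   set(fsf, logits, params, xp)$logits,
                   set(fsf, logits, params, xp)$params) -
                 fwd(set(fsf, logits, params, xm)$fsf,
                     set(fsf, logits, params, xm)$logits,
                     set(fsf, logits, params, xm)$params)) / (2 * e)
    }
    g
  }
  g_fsf <- num_grad(function() fsf, function(f, l, p, x)
    list(fsf = x, logits = l, params = p))
  expect_equal(gr$dfsf, g_fsf, tolerance = 1e-5)
  g_lg <- num_grad(function() logits, function(f, l, p, x)
    list(fsf = f, logits = x, params = p))
  expect_equal(gr$dlogits, g_lg, tolerance = 1e-5)
  g_wc <- num_grad(function() params$Wc, function(f, l, p, x) {
    p$Wc <- x; list(fsf = f, logits = l, params = p)
  })
  expect_equal(gr$dWc, g_wc, tolerance = 1e-5)
})
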
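# Training loop, schedule, inference, reporting, ablation harness.

test_that("the polynomial schedule matches its closed form", {
  expect_equal(poly_lr(0, 1000), 1)
  expect_equal(poly_lr(1000, 1000), 0)
  expect_equal(poly_lr(500, 1000), 0.5^0.9)
  expect_error(poly_lr(-1, 10), "epoch")
  expect_error(poly_lr(11, 10), "epoch")
})

make_toy_slices <- function(n = 4L, size = 8L, seed = 1L) {
  b <- tiny_batch(seed = seed, n = n, size = size)
  lapply(seq_len(n), function(i)
    list(image = b$x[, , i, 1], mask = b$y[, , i], index = i))
}

test_that("a smoke run completes, logs, and writes a checkpoint", {
  slices <- make_toy_slices(4L)
  tc <- train_config(epochs = 1L, iters_per_epoch = 2L, batch_size = 2L,
                     seed = 1L)
  fit <- train_mcm_unet(mcm_unet(tiny_cfg()), slices, tc,
                        val_data = slices[1:2])
  expect_s3_class(fit, "mcm_unet_fit")
  expect_identical(nrow(fit$log), 1L)
  expect_named(fit$log, c("epoch", "lr", "loss", "val_dsc"))
  expect_true(is.finite(fit$log$loss))
  expect_true(is.finite(fit$log$val_dsc))
  f <- tempfile(fileext = ".rds")
  save_checkpoint(fit, f)
  fit2 <- load_checkpoint(f)
  expect_identical(fit2$model$cfg, fit$model$cfg)
  expect_identical(fit2$model$params, fit$model$params)
  expect_error(train_mcm_unet(mcm_unet(tiny_cfg()), list(), tc), "empty")
})

test_that("training overfits a repeated batch (loss decreases)", {
  slices <- make_toy_slices(2L, seed = 5L)
  tc <- train_config(epochs = 5L, iters_per_epoch = 10L, batch_size = 2L,
                     base_lr = 0.01, seed = 2L)
  fit <- train_mcm_unet(mcm_unet(tiny_cfg(seed = 5L)), slices, tc)
  expect_lt(fit$log$loss[5], fit$log$loss[1] - 0.1)
})

test_that("the same seed reproduces the loss trajectory exactly", {
  slices <- make_toy_slices(4L, seed = 9L)
  tc <- train_config(epochs = 2L, iters_per_epoch = 3L, batch_size = 2L,
                     seed = 4L)
  f1 <- train_mcm_unet(mcm_unet(tiny_cfg(seed = 9L)), slices, tc)
  f2 <- train_mcm_unet(mcm_unet(tiny_cfg(seed = 9L)), slices, tc)
  expect_identical(f1$log, f2$log)
  expect_identical(f1$model$params, f2$model$params)
  expect_identical(f1$model$bank$entries, f2$model$bank$entries)
})

test_that("the bank receives exactly one push per optimizer step", {
  slices <- make_toy_slices(4L)
  tc <- train_config(epochs = 1L, iters_per_epoch = 2L, batch_size = 2L,
                     seed = 1L)
  fit <- train_mcm_unet(mcm_unet(tiny_cfg(bank_capacity = 16L)), slices, tc)
  expect_length(fit$model$bank, 2L)  # 2 steps -> 2 entries
  tc2 <- train_config(epochs = 2L, iters_per_epoch = 3L, batch_size = 2L,
                      seed = 1L)
  fit2 <- train_mcm_unet(mcm_unet(tiny_cfg(bank_capacity = 4L)), slices, tc2)
  expect_length(fit2$model$bank, 4L)  # 6 steps, FIFO-capped at capacity
})

test_that("prediction restores the input grid and is deterministic", {
  slices <- make_toy_slices(4L)
  tc <- train_config(epochs = 1L, iters_per_epoch = 2L, batch_size = 2L,
                     seed = 1L)
  fit <- train_mcm_unet(mcm_unet(tiny_cfg()), slices, tc)
  set.seed(10)
  vol <- as_volume(array(rnorm(6 * 7 * 3, sd = 2), c(6, 7, 3)))
  p1 <- predict(fit, vol)
  expect_identical(dim(p1$grid), dim(vol$grid))
  expect_true(all(p1$grid %in% c(0L, 1L)))
  p2 <- predict(fit, vol)
  expect_identical(p1$grid, p2$grid)
})

test_that("evaluate_cases reports per-case rows, means, and empty-pred policy", {
  dir_gt <- tempfile("gt"); dir_pr <- tempfile("pr")
  dir.create(dir_gt); dir.create(dir_pr)
  set.seed(11)
  masks <- lapply(1:3, function(i) rand_mask(c(8, 8, 4)))
  for (i in 1:3) {
    write_volume(as_volume(masks[[i]]), file.path(dir_gt, sprintf("c%d.nii.gz", i)))
    write_volume(as_volume(masks[[i]]), file.path(dir_pr, sprintf("c%d.nii.gz", i)))
  }
  rep1 <- evaluate_cases(dir_pr, dir_gt)
  expect_identical(nrow(rep1), 4L)
  expect_equal(rep1$dsc_pct, rep(100, 4))
  expect_equal(rep1$assd_voxel, rep(0, 4))

  # perturbed predictions: aggregate row is the arithmetic mean
  pert <- masks
  pert[[2]][1, 1, 1] <- 1L - pert[[2]][1, 1, 1]
  for (i in 1:3)
    write_volume(as_volume(pert[[i]]), file.path(dir_pr, sprintf("c%d.nii.gz", i)))
  rep2 <- evaluate_cases(dir_pr, dir_gt)
  expect_equal(rep2$dsc_pct[4], mean(rep2$dsc_pct[1:3]))
  expect_equal(rep2$assd_voxel[4], mean(rep2$assd_voxel[1:3]))

  # empty prediction: overlap 0, distances NA and excluded, with a warning
  write_volume(as_volume(array(0L, c(8, 8, 4))),
               file.path(dir_pr, "c2.nii.gz"))
  expect_warning(rep3 <- evaluate_cases(dir_pr, dir_gt), "empty prediction")
  expect_equal(rep3$dsc_pct[2], 0)
  expect_true(is.na(rep3$assd_voxel[2]))
  expect_equal(rep3$assd_voxel[4], mean(rep3$assd_voxel[c(1, 3)]))

  # unmatched ids are an error naming the missing files
  file.remove(file.path(dir_pr, "c3.nii.gz"))
  expect_error(evaluate_cases(dir_pr, dir_gt), "c3")

  # pooled aggregation recomputes overlap from pooled voxel counts
  for (i in 1:3)
    write_volume(as_volume(pert[[i]]), file.path(dir_pr, sprintf("c%d.nii.gz", i)))
  rep4 <- evaluate_cases(dir_pr, dir_gt, aggregate = "pooled")
  tp <- sum(mapply(function(a, b) sum(a & b), masks, pert))
  un <- sum(mapply(function(a, b) sum(a | b), masks, pert))
  expect_equal(rep4$jaccard_pct[4], 100 * tp / un)
})

test_that("config YAML round-trips through read_config", {
  nc <- mcm_unet_config(n_stages = 4L, base_channels = 16L,
                        patch_size = c(64L, 64L), bank_capacity = 16L,
                        use_cm = FALSE, seed = 3L)
  tc <- train_config(epochs = 7L, batch_size = 3L, seed = 3L)
  f <- tempfile(fileext = ".yaml")
  write_config(nc, tc, f)
  got <- read_config(f)
  expect_equal(unclass(got$network), unclass(nc))
  expect_equal(unclass(got$training), unclass(tc))
})

test_that("ablation_run emits one row per flag combination", {
  slices <- make_toy_slices(4L)
  tc <- train_config(epochs = 1L, iters_per_epoch = 1L, batch_size = 2L,
                     seed = 1L)
  set.seed(12)
  gt <- array(0L, c(8, 8, 2)); gt[3:6, 3:6, ] <- 1L
  vol <- as_volume(array(rnorm(8 * 8 * 2), c(8, 8, 2)) + 2 * gt)
  res <- ablation_run(tiny_cfg(), tc, slices,
                      list(list(volume = vol, mask = gt)))
  expect_identical(nrow(res), 4L)
  expect_identical(colnames(res),
                   c("use_cm", "use_mb", "assd_voxel", "hd95_voxel",
                     "jaccard_pct", "dsc_pct"))
  expect_identical(nrow(unique(res[, 1:2])), 4L)
  expect_length(attr(res, "fits"), 4L)
})
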
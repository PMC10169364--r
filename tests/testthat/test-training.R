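test_that("learning-rate schedule halves at the published epochs", {
  cfg <- train_config(total_epochs = 300)
  expect_equal(lr_at_epoch(0, cfg), 0.003)
  expect_equal(lr_at_epoch(99, cfg), 0.003)
  expect_equal(lr_at_epoch(100, cfg), 0.0015)
  expect_equal(lr_at_epoch(150, cfg), 0.0015)
  expect_equal(lr_at_epoch(220, cfg), 0.00075)
  expect_equal(lr_at_epoch(299, cfg), 0.000375)
  expect_error(lr_at_epoch(300, cfg), "range")
  expect_error(lr_at_epoch(-1, cfg), "range")
  # short toy runs never reach a halving point
  short <- train_config(total_epochs = 20, patch_size = c(16, 16, 16))
  expect_equal(lr_at_epoch(19, short), 0.003)
})

test_that("positive-centred patches always contain tumor", {
  cfg <- tiny_phantom_config()
  ph <- generate_phantom(cfg, 3)
  tcfg <- train_config(patch_size = c(16, 16, 16), pos_neg_ratio = 1,
                       total_epochs = 1)
  set.seed(1)
  for (i in 1:10) {
    pt <- sample_patch(ph$image, ph$mask, tcfg)
    expect_equal(dim(pt$image), c(16, 16, 16))
    expect_identical(dim(pt$image), dim(pt$mask))
    expect_gt(sum(pt$mask), 0)
  }
  empty <- mask_volume(array(0, dim(ph$mask$voxels)), ph$mask$spacing)
  expect_error(sample_patch(ph$image, empty, tcfg), "empty")
})

test_that("class-balanced sampling reaches the configured tumor fraction", {
  cfg <- tiny_phantom_config()
  ph <- generate_phantom(cfg, 3)
  tcfg <- train_config(patch_size = c(16, 16, 16), pos_neg_ratio = 0.5,
                       total_epochs = 1)
  set.seed(42)
  hits <- sum(vapply(1:200, function(i) {
    sum(sample_patch(ph$image, ph$mask, tcfg)$mask) > 0
  }, TRUE))
  expect_gte(hits / 200, 0.5)
})

test_that("volumes smaller than the patch are padded up", {
  v <- image_volume(array(rnorm(8^3), c(8, 8, 8)))
  m <- mask_volume(array(c(rep(0, 8^3 - 1), 1), c(8, 8, 8)))
  tcfg <- train_config(patch_size = c(16, 16, 12), pos_neg_ratio = 1,
                       total_epochs = 1)
  set.seed(2)
  pt <- sample_patch(v, m, tcfg)
  expect_equal(dim(pt$image), c(16, 16, 12))
  expect_equal(sum(pt$mask), 1)
})

test_that("augmentation honours probabilities and keeps pairs congruent", {
  set.seed(3)
  img <- array(rnorm(16^3), c(16, 16, 16))
  msk <- array(0, c(16, 16, 16))
  msk[6:11, 6:11, 6:11] <- 1

  off <- augment_config(affine_prob = 0, contrast_prob = 0, noise_prob = 0)
  a0 <- augment(img, msk, off)
  expect_identical(a0$image, img)
  expect_identical(a0$mask, msk)

  on <- augment_config(affine_prob = 1, contrast_prob = 1, noise_prob = 1)
  a1 <- augment(img, msk, on)
  expect_true(all(a1$mask %in% c(0, 1)))
  expect_identical(dim(a1$image), dim(a1$mask))

  # pure rotation roughly preserves the foreground count
  rot <- augment_config(rotation_deg = 10, scale_range = c(1, 1),
                        translation_vox = 0, affine_prob = 1,
                        contrast_prob = 0, noise_prob = 0)
  set.seed(4)
  a2 <- augment(img, msk, rot)
  expect_lt(abs(sum(a2$mask) - sum(msk)) / sum(msk), 0.2)
})

test_that("the patch and augmentation stream is bit-reproducible", {
  cfg <- tiny_phantom_config()
  ph <- generate_phantom(cfg, 5)
  tcfg <- train_config(patch_size = c(16, 16, 16), total_epochs = 1)
  acfg <- augment_config()
  draw_stream <- function() {
    set.seed(tcfg$seed)
    lapply(1:5, function(i) {
      pt <- sample_patch(ph$image, ph$mask, tcfg)
      augment(pt$image, pt$mask, acfg)
    })
  }
  expect_identical(draw_stream(), draw_stream())
})

test_that("training a tiny model runs, logs faithfully, and is seeded", {
  cfg <- tiny_phantom_config()
  pair <- function(s) {
    ph <- generate_phantom(cfg, s)
    list(image = ph$image, mask = ph$mask)
  }
  tr <- list(pair(1), pair(2))
  va <- list(pair(3))
  ncfg <- tiny_network_config()
  tcfg <- train_config(patch_size = c(16, 16, 16), total_epochs = 3,
                       augmentation = NULL, pos_neg_ratio = 0.8,
                       samples_per_volume_per_epoch = 1, val_interval = 1,
                       seed = 9)
  icfg <- inference_config(window_size = c(16, 16, 16))
  fit <- train(tr, va, ncfg, tcfg, icfg = icfg)
  h <- fit$history
  expect_equal(nrow(h), 3)
  expect_equal(h$lr, vapply(0:2, lr_at_epoch, 1.0, cfg = tcfg))
  expect_equal(fit$model$extra$best_val_dsc, max(h$val_dsc, na.rm = TRUE))
  expect_s3_class(fit$model, "vs_model")
  # rerun reproduces the history exactly
  fit2 <- train(tr, va, ncfg, tcfg, icfg = icfg)
  expect_identical(fit$history, fit2$history)
})

test_that("ablation configurations train and yield loadable checkpoints", {
  cfg <- tiny_phantom_config()
  ph <- generate_phantom(cfg, 11)
  set_ <- list(list(image = ph$image, mask = ph$mask))
  tcfg <- train_config(patch_size = c(16, 16, 16), total_epochs = 1,
                       augmentation = NULL, samples_per_volume_per_epoch = 1,
                       seed = 2)
  icfg <- inference_config(window_size = c(16, 16, 16))
  for (abl in list(list(sa = FALSE, dsv = TRUE),
                   list(sa = TRUE, dsv = FALSE))) {
    ncfg <- network_config(channels = c(4, 8), dropout_rate = 0,
                           enable_spatial_attention = abl$sa,
                           enable_deep_supervision = abl$dsv, seed = 3)
    fit <- train(set_, set_, ncfg, tcfg, icfg = icfg)
    p <- file.path(withr::local_tempdir(), "ck.rds")
    save_checkpoint(fit$model, p)
    reloaded <- load_checkpoint(p)
    prob <- sliding_window_predict(reloaded, ph$image, icfg)
    expect_true(all(prob$voxels >= 0 & prob$voxels <= 1))
  }
})
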
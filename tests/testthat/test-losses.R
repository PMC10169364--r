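test_that("dice loss reproduces hand-computed values", {
  m <- array(0, c(2, 2, 2))
  m[1:2, 1:2, 1] <- 1 # 4 foreground voxels
  # uniform 0.5 prediction over 8 voxels: 1 - (2*2)/(4+4) = 0.5
  expect_equal(dice_loss(array(0.5, c(2, 2, 2)), m, smooth = 0), 0.5)
  # perfect overlap
  expect_lt(dice_loss(m, m), 1e-4)
  # no overlap tends to 1 as smoothing vanishes
  expect_equal(dice_loss(array(0, c(2, 2, 2)), m, smooth = 0), 1)
  expect_lt(dice_loss(array(0, c(2, 2, 2)), m, smooth = 1e-5), 1)
  expect_error(dice_loss(array(0, c(2, 2, 2)), array(0, c(2, 2, 4))),
               "shape")
})

test_that("dice loss is symmetric for binary arguments and decreases with
           overlap", {
  set.seed(1)
  a <- array(as.numeric(runif(6^3) > 0.7), c(6, 6, 6))
  b <- array(as.numeric(runif(6^3) > 0.7), c(6, 6, 6))
  expect_equal(dice_loss(a, b), dice_loss(b, a))
  # a fixed 3-cube translated toward the target monotonically lowers loss
  # (shift range chosen so every step changes the overlap)
  target <- array(0, c(6, 6, 20))
  target[2:4, 2:4, 9:11] <- 1
  losses <- sapply(3:6, function(shift) {
    pred <- array(0, c(6, 6, 20))
    pred[2:4, 2:4, (3:5) + shift] <- 1
    dice_loss(pred, target)
  })
  expect_true(all(diff(losses) < 0))
})

test_that("max-pooled supervision targets never lose a tumor", {
  m <- array(0, c(16, 16, 16))
  m[7, 9, 3] <- 1 # single foreground voxel
  tg <- downsample_targets(m, 3)
  expect_length(tg, 3)
  expect_equal(sapply(tg, function(x) dim(x)[1]), c(16, 8, 4))
  expect_true(all(sapply(tg, sum) >= 1))
  expect_true(all(unlist(lapply(tg, function(x) x %in% c(0, 1)))))

  z <- downsample_targets(array(0, c(8, 8, 8)), 3)
  expect_true(all(sapply(z, sum) == 0))

  # 2x2x2 cube at the origin pools to exactly one corner voxel
  c8 <- array(0, c(8, 8, 8))
  c8[1:2, 1:2, 1:2] <- 1
  p <- downsample_targets(c8, 2)[[2]]
  expect_equal(sum(p), 1)
  expect_equal(p[1, 1, 1], 1)

  expect_error(downsample_targets(array(0, c(6, 8, 8)), 3), "divisible")
})

test_that("total loss equals an independently scripted sum", {
  set.seed(5)
  lvl <- list(array(runif(16^3), c(16, 16, 16)),
              array(runif(8^3), c(8, 8, 8)))
  att <- list(array(runif(16^3), c(16, 16, 16)),
              array(runif(8^3), c(8, 8, 8)))
  gt <- array(as.numeric(runif(16^3) > 0.9), c(16, 16, 16))
  tg <- downsample_targets(gt, 2)
  outputs <- structure(list(final_map = lvl[[1]], level_maps = lvl,
                            attention_maps = att, cache = NULL),
                       class = "forward_outputs")
  params <- list(g1 = list(w = array(rnorm(12), c(2, 2, 3)), b = rnorm(3)),
                 g2 = list(w = array(rnorm(4), c(2, 2))))
  lb <- total_loss(outputs, tg, params, l2_weight = 1e-7)
  # hand-scripted recomputation from the raw definition
  hand_dice <- function(p, t) {
    s <- 1e-5
    1 - (2 * sum(p * t) + s) / (sum(p) + sum(t) + s)
  }
  expected <- hand_dice(lvl[[1]], tg[[1]]) + hand_dice(lvl[[2]], tg[[2]]) +
    hand_dice(att[[1]], tg[[1]]) + hand_dice(att[[2]], tg[[2]]) +
    1e-7 * (sum(params$g1$w^2) + sum(params$g1$b^2) + sum(params$g2$w^2))
  expect_equal(lb$total, expected, tolerance = 1e-6)
  expect_equal(lb$total,
               sum(lb$ds_losses) + sum(lb$sa_losses) + 1e-7 * lb$l2_term,
               tolerance = 1e-9)
  expect_true(all(c(lb$ds_losses, lb$sa_losses) >= 0 &
                    c(lb$ds_losses, lb$sa_losses) <= 1))
})

test_that("degenerate configurations reduce to the plain Dice loss", {
  set.seed(6)
  gt <- array(as.numeric(runif(8^3) > 0.8), c(8, 8, 8))
  tg <- downsample_targets(gt, 1)
  outputs <- structure(list(final_map = tg[[1]], level_maps = list(tg[[1]]),
                            attention_maps = list(), cache = NULL),
                       class = "forward_outputs")
  lb <- total_loss(outputs, tg, NULL, 0)
  expect_lt(lb$total, 1e-3)
  expect_length(lb$sa_losses, 0)
  expect_equal(lb$l2_term, 0)
})

test_that("one gradient step on a single case lowers the total loss", {
  ncfg <- network_config(channels = c(3, 4), dropout_rate = 0, seed = 21)
  model <- build_model(ncfg)
  set.seed(22)
  x <- array(rnorm(8^3), c(8, 8, 8))
  gt <- array(0, c(8, 8, 8))
  gt[3:6, 3:6, 3:6] <- 1
  tg <- downsample_targets(gt, 1)
  out <- model_forward(model, x, keep_cache = TRUE)
  l0 <- total_loss(out, tg, model$params, 1e-7)$total
  gl <- vsseg:::total_loss_grads(out, tg)
  grads <- vsseg:::model_backward(model, out, gl$d_level_maps, gl$d_att_maps)
  st <- vsseg:::adam_step(model$params, grads, vsseg:::adam_init(model$params),
                          lr = 0.003)
  model$params <- st$params
  l1 <- total_loss(model_forward(model, x), tg, model$params, 1e-7)$total
  expect_lt(l1, l0)
})
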
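test_that("forward outputs have the contracted shapes and ranges", {
  ncfg <- network_config(channels = c(4, 6, 8), dropout_rate = 0, seed = 1)
  model <- build_model(ncfg)
  x <- array(rnorm(16 * 16 * 8), c(16, 16, 8))
  out <- model_forward(model, x)
  expect_equal(dim(out$final_map), c(16, 16, 8))
  expect_length(out$level_maps, 2)
  expect_equal(dim(out$level_maps[[1]]), c(16, 16, 8))
  expect_equal(dim(out$level_maps[[2]]), c(8, 8, 4))
  expect_length(out$attention_maps, 2)
  expect_equal(dim(out$attention_maps[[1]]), c(16, 16, 8))
  expect_equal(dim(out$attention_maps[[2]]), c(8, 8, 4))
  for (m in c(out$level_maps, out$attention_maps)) {
    expect_true(all(m >= 0 & m <= 1))
  }
  expect_identical(out$final_map, out$level_maps[[1]])
  # non-divisible input is rejected with a shape error
  expect_error(model_forward(model, array(0, c(10, 16, 8))), "divisible")
})

test_that("disabling deep supervision leaves only the final map", {
  ncfg <- network_config(channels = c(4, 6, 8), dropout_rate = 0,
                         enable_deep_supervision = FALSE, seed = 1)
  out <- model_forward(build_model(ncfg), array(rnorm(8^3), c(8, 8, 8)))
  expect_length(out$level_maps, 1)
  expect_identical(out$final_map, out$level_maps[[1]])
})

test_that("parameter count is a pure function of the config and shrinks
           under ablation", {
  base <- network_config(channels = c(4, 6, 8), seed = 1)
  n0 <- n_parameters(build_model(base))
  expect_identical(n0, n_parameters(build_model(base)))
  # same architecture, different init seed: same count
  expect_identical(
    n0, n_parameters(build_model(network_config(channels = c(4, 6, 8),
                                                seed = 99))))
  no_sa <- network_config(channels = c(4, 6, 8),
                          enable_spatial_attention = FALSE, seed = 1)
  no_dsv <- network_config(channels = c(4, 6, 8),
                           enable_deep_supervision = FALSE, seed = 1)
  expect_lt(n_parameters(build_model(no_sa)), n0)
  expect_lt(n_parameters(build_model(no_dsv)), n0)
  # deep supervision heads: one (1x1x1 conv + bias) head per level below
  # the top disappears when disabled
  ch <- c(4, 6, 8)
  expect_equal(n0 - n_parameters(build_model(no_dsv)), ch[2] + 1)
})

test_that("weight init and evaluation-mode forward are deterministic", {
  ncfg <- network_config(channels = c(4, 6), dropout_rate = 0.3, seed = 7)
  m1 <- build_model(ncfg)
  m2 <- build_model(ncfg)
  x <- array(rnorm(8^3), c(8, 8, 8))
  o1 <- model_forward(m1, x)
  o2 <- model_forward(m2, x)
  expect_identical(o1$final_map, o2$final_map)
  # dropout inactive in evaluation mode: repeat calls agree bit-wise
  o3 <- model_forward(m1, x)
  expect_identical(o1$final_map, o3$final_map)
})

test_that("spatial attention maps lie in (0,1) and gate multiplicatively", {
  set.seed(3)
  f <- array(rnorm(6 * 6 * 6 * 4), c(6, 6, 6, 4))
  pp <- list(w1 = array(rnorm(27 * 4 * 2, 0, 0.2), c(3, 3, 3, 4, 2)),
             b1 = rnorm(2),
             w2 = array(rnorm(2, 0, 0.5), c(1, 1, 1, 2, 1)), b2 = 0.1)
  sa <- spatial_attention(f, pp)
  expect_gt(min(sa$attention_map), 0)
  expect_lt(max(sa$attention_map), 1)
  expect_equal(dim(sa$attention_map), dim(f)[1:3])
  # brute-force elementwise product over channels
  manual <- f
  for (c_ in 1:4) manual[, , , c_] <- f[, , , c_] * sa$attention_map
  expect_equal(sa$scaled_features, manual, tolerance = 1e-12)
  # an all-ones map is the multiplicative identity
  pp1 <- pp
  pp1$w2[] <- 0
  pp1$b2 <- 1e4 # sigmoid saturates to 1
  sa1 <- spatial_attention(f, pp1)
  expect_equal(sa1$scaled_features, f, tolerance = 1e-12)
})

test_that("analytic gradients match finite differences on a tiny model", {
  ncfg <- network_config(channels = c(3, 4), dropout_rate = 0, seed = 11)
  model <- build_model(ncfg)
  set.seed(12)
  x <- array(rnorm(6 * 6 * 4), c(6, 6, 4))
  gt <- array(as.numeric(array(rnorm(6 * 6 * 4), c(6, 6, 4)) > 0.8),
              c(6, 6, 4))
  tg <- downsample_targets(gt, 1)
  out <- model_forward(model, x, keep_cache = TRUE)
  gl <- vsseg:::total_loss_grads(out, tg)
  grads <- vsseg:::model_backward(model, out, gl$d_level_maps, gl$d_att_maps)
  loss_of <- function(m) total_loss(model_forward(m, x), tg, NULL, 0)$total
  eps <- 1e-6
  set.seed(13)
  for (gn in sample(names(grads), 4)) {
    pn <- sample(names(grads[[gn]]), 1)
    i <- sample(length(grads[[gn]][[pn]]), 1)
    m2 <- model
    m2$params[[gn]][[pn]][i] <- m2$params[[gn]][[pn]][i] + eps
    lp <- loss_of(m2)
    m2$params[[gn]][[pn]][i] <- m2$params[[gn]][[pn]][i] - 2 * eps
    lm <- loss_of(m2)
    fd <- (lp - lm) / (2 * eps)
    an <- grads[[gn]][[pn]][i]
    expect_lt(abs(fd - an), 1e-4 * max(1, abs(fd)))
  }
})

test_that("checkpoints embed the config and round-trip through disk", {
  ncfg <- tiny_network_config()
  model <- build_model(ncfg)
  p <- file.path(withr::local_tempdir(), "ck.rds")
  save_checkpoint(model, p, extra = list(note = 1))
  m2 <- load_checkpoint(p)
  expect_identical(m2$cfg$channels, ncfg$channels)
  x <- array(rnorm(8^3), c(8, 8, 8))
  expect_identical(model_forward(model, x)$final_map,
                   model_forward(m2, x)$final_map)
  expect_error(load_checkpoint(file.path(tempdir(), "none.rds")),
               "not found")
})
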
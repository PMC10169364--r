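#' Data augmentation configuration
#'
#' Random affine transformation (rotation, isotropic scaling, translation),
#' multiplicative contrast (gamma) adjustment, and additive Gaussian noise.
#' The same affine transform is applied to the image (trilinear
#' interpolation) and the mask (nearest neighbour) so the pair stays
#' congruent; contrast and noise touch the image only.
#'
#' @param rotation_deg Max rotation per axis, degrees.
#' @param scale_range Length-2 isotropic scale factor range.
#' @param translation_vox Max translation per axis, voxels.
#' @param affine_prob Probability of applying the affine draw.
#' @param gamma_range Length-2 multiplicative contrast factor range.
#' @param contrast_prob Probability of applying contrast adjustment.
#' @param noise_sd_range Length-2 range of the Gaussian noise standard
#'   deviation (in normalized intensity units).
#' @param noise_prob Probability of adding noise.
#' @return An `augment_config` list.
#' @export
augment_config <- function(rotation_deg = 10, scale_range = c(0.9, 1.1),
                           translation_vox = 5, affine_prob = 0.5,
                           gamma_range = c(0.8, 1.2), contrast_prob = 0.5,
                           noise_sd_range = c(0, 0.1), noise_prob = 0.5) {
  stopifnot(rotation_deg >= 0, length(scale_range) == 2L,
            scale_range[1] <= scale_range[2], translation_vox >= 0,
            affine_prob >= 0, affine_prob <= 1,
            length(gamma_range) == 2L, gamma_range[1] <= gamma_range[2],
            contrast_prob >= 0, contrast_prob <= 1,
            length(noise_sd_range) == 2L,
            noise_sd_range[1] <= noise_sd_range[2],
            noise_prob >= 0, noise_prob <= 1)
  structure(list(rotation_deg = rotation_deg, scale_range = scale_range,
                 translation_vox = translation_vox,
                 affine_prob = affine_prob, gamma_range = gamma_range,
                 contrast_prob = contrast_prob,
                 noise_sd_range = noise_sd_range, noise_prob = noise_prob),
            class = "augment_config")
}

#' Training configuration
#'
#' Defaults follow the full-scale training recipe: 128x128x96 patches,
#' batch size 1, Adam starting at learning rate 0.003 halved at epochs 100
#' and 200 and every 50 epochs thereafter for 300 epochs total, L2 weight
#' 1e-7, and class-balanced negative-positive patch cropping. CPU-scale
#' experiments use far smaller patches and epoch counts.
#'
#' @param patch_size Integer length-3 training patch dims; must be
#'   divisible by `2^(levels-1)` of the paired network.
#' @param batch_size Patches per optimizer step.
#' @param base_lr Initial Adam learning rate.
#' @param total_epochs Number of epochs.
#' @param lr_halve_first_every Halve the learning rate every this many
#'   epochs initially...
#' @param lr_halve_switch_epoch ...until this epoch, after which...
#' @param lr_halve_then_every ...it is halved every this many epochs.
#' @param l2_weight L2 regularization weight.
#' @param pos_neg_ratio Probability in `(0,1]` that a sampled patch is
#'   centred on a foreground voxel.
#' @param augmentation An [augment_config()], or `NULL` to disable.
#' @param samples_per_volume_per_epoch Patches drawn from each training
#'   volume per epoch.
#' @param val_interval Validate every this many epochs.
#' @param seed Integer seed for the patch/augmentation stream.
#' @return A `train_config` list.
#' @export
train_config <- function(patch_size = c(128, 128, 96), batch_size = 1,
                         base_lr = 0.003, total_epochs = 300,
                         lr_halve_first_every = 100,
                         lr_halve_switch_epoch = 200,
                         lr_halve_then_every = 50,
                         l2_weight = 1e-7, pos_neg_ratio = 0.5,
                         augmentation = augment_config(),
                         samples_per_volume_per_epoch = 1,
                         val_interval = 1, seed = 7L) {
  stopifnot(length(patch_size) == 3L, all(patch_size >= 4),
            batch_size >= 1, base_lr > 0, total_epochs >= 1,
            l2_weight >= 0, pos_neg_ratio > 0, pos_neg_ratio <= 1,
            is.null(augmentation) || inherits(augmentation, "augment_config"),
            samples_per_volume_per_epoch >= 1, val_interval >= 1)
  structure(list(patch_size = as.integer(patch_size),
                 batch_size = as.integer(batch_size), base_lr = base_lr,
                 total_epochs = as.integer(total_epochs),
                 lr_halve_first_every = lr_halve_first_every,
                 lr_halve_switch_epoch = lr_halve_switch_epoch,
                 lr_halve_then_every = lr_halve_then_every,
                 l2_weight = l2_weight, pos_neg_ratio = pos_neg_ratio,
                 augmentation = augmentation,
                 samples_per_volume_per_epoch =
                   as.integer(samples_per_volume_per_epoch),
                 val_interval = as.integer(val_interval),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Learning rate at a given epoch
#'
#' Piecewise-constant schedule: the base rate is halved at every halving
#' point at or before `epoch`. With the defaults (halve every 100 epochs up
#' to epoch 200, every 50 thereafter, 300 epochs total) the halving points
#' are 100, 200 and 250, giving 0.003 / 0.0015 / 0.00075 / 0.000375.
#'
#' @param epoch Zero-based epoch index in `[0, total_epochs)`.
#' @param cfg A [train_config()].
#' @return The learning rate.
#' @export
lr_at_epoch <- function(epoch, cfg) {
  stopifnot(inherits(cfg, "train_config"))
  if (epoch < 0 || epoch >= cfg$total_epochs) {
    stop("epoch ", epoch, " out of range [0, ", cfg$total_epochs, ")",
         call. = FALSE)
  }
  pts_early <- seq(cfg$lr_halve_first_every, cfg$lr_halve_switch_epoch,
                   by = cfg$lr_halve_first_every)
  first_late <- cfg$lr_halve_switch_epoch + cfg$lr_halve_then_every
  pts_late <- if (first_late < cfg$total_epochs) {
    seq(first_late, cfg$total_epochs, by = cfg$lr_halve_then_every)
  } else {
    numeric(0)
  }
  pts <- c(pts_early, pts_late)
  pts <- pts[pts < cfg$total_epochs]
  cfg$base_lr * 0.5^sum(pts <= epoch)
}

# symmetric zero-padding of a 3D array up to at least `size`;
# returns the padded array and the lower offsets (for stripping later)
pad_to <- function(a, size) {
  d <- dim(a)
  need <- pmax(size - d, 0)
  lo <- floor(need / 2)
  if (all(need == 0)) return(list(a = a, lo = c(0L, 0L, 0L), orig = d))
  out <- array(0, d + need)
  out[lo[1] + seq_len(d[1]), lo[2] + seq_len(d[2]), lo[3] + seq_len(d[3])] <- a
  list(a = out, lo = as.integer(lo), orig = d)
}

#' Sample a training patch by negative-positive cropping
#'
#' With probability `pos_neg_ratio` the patch is centred on a uniformly
#' drawn tumor voxel, otherwise on a uniformly drawn background voxel —
#' the class-balancing crop used during training. Volumes smaller than the
#' patch are symmetrically zero-padded first; the centre is clamped so the
#' patch lies inside the (padded) volume. Consumes the R RNG stream.
#'
#' @param img An [image_volume()] (typically already z-normalized).
#' @param mask The paired [mask_volume()].
#' @param cfg A [train_config()].
#' @return List with 3D arrays `image` and `mask` of dims
#'   `cfg$patch_size`.
#' @export
sample_patch <- function(img, mask, cfg) {
  stopifnot_congruent(img, mask)
  ps <- cfg$patch_size
  pi_ <- pad_to(img$voxels, ps)
  pm_ <- pad_to(mask$voxels, ps)
  a <- pi_$a
  m <- pm_$a
  d <- dim(a)
  positive <- stats::runif(1) < cfg$pos_neg_ratio
  idx_pool <- if (positive) which(m != 0) else which(m == 0)
  if (positive && length(idx_pool) == 0) {
    stop("cannot sample a positive patch: mask is empty", call. = FALSE)
  }
  pick <- idx_pool[sample.int(length(idx_pool), 1)]
  ctr <- arrayInd(pick, d)[1, ]
  lo <- pmin(pmax(ctr - floor(ps / 2), 1), d - ps + 1)
  ix <- lo[1]:(lo[1] + ps[1] - 1)
  iy <- lo[2]:(lo[2] + ps[2] - 1)
  iz <- lo[3]:(lo[3] + ps[3] - 1)
  list(image = a[ix, iy, iz], mask = m[ix, iy, iz])
}

#' Augment a congruent image/mask patch pair
#'
#' Applies (each with its own probability) a random affine transform —
#' identical for image and mask, trilinear for the image and nearest
#' neighbour for the mask so the mask stays binary — then a multiplicative
#' contrast factor and additive Gaussian noise to the image only. All draws
#' come from the R RNG stream, so the pipeline is reproducible from the
#' seed.
#'
#' @param image 3D image patch array.
#' @param mask 3D binary mask patch array.
#' @param cfg An [augment_config()].
#' @return List with transformed `image` and `mask`.
#' @export
augment <- function(image, mask, cfg) {
  stopifnot(inherits(cfg, "augment_config"),
            identical(dim(image), dim(mask)))
  d <- dim(image)
  if (stats::runif(1) < cfg$affine_prob) {
    ang <- stats::runif(3, -cfg$rotation_deg, cfg$rotation_deg) * pi / 180
    sc <- stats::runif(1, cfg$scale_range[1], cfg$scale_range[2])
    tr <- stats::runif(3, -cfg$translation_vox, cfg$translation_vox)
    rx <- matrix(c(1, 0, 0,
                   0, cos(ang[1]), -sin(ang[1]),
                   0, sin(ang[1]), cos(ang[1])), 3, byrow = TRUE)
    ry <- matrix(c(cos(ang[2]), 0, sin(ang[2]),
                   0, 1, 0,
                   -sin(ang[2]), 0, cos(ang[2])), 3, byrow = TRUE)
    rz <- matrix(c(cos(ang[3]), -sin(ang[3]), 0,
                   sin(ang[3]), cos(ang[3]), 0,
                   0, 0, 1), 3, byrow = TRUE)
    # pull-back map: output index -> input index, about the patch centre
    A <- solve(rz %*% ry %*% rx) / sc
    ctr <- (d - 1) / 2
    t0 <- ctr - A %*% (ctr + tr)
    image <- affine_resample(image, A, as.numeric(t0), 0L)
    mask <- affine_resample(mask, A, as.numeric(t0), 1L)
  }
  if (stats::runif(1) < cfg$contrast_prob) {
    gamma <- stats::runif(1, cfg$gamma_range[1], cfg$gamma_range[2])
    image <- image * gamma
  }
  if (stats::runif(1) < cfg$noise_prob) {
    sdn <- stats::runif(1, cfg$noise_sd_range[1], cfg$noise_sd_range[2])
    if (sdn > 0) image <- image + array(stats::rnorm(prod(d), 0, sdn), d)
  }
  list(image = image, mask = mask)
}

# ---- Adam over the nested parameter list ----

adam_init <- function(params) {
  zeros <- function(g) lapply(g, function(a) array(0, dim(a) %||% length(a)))
  list(m = lapply(params, zeros), v = lapply(params, zeros), t = 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (gn in names(grads)) {
    for (pn in names(grads[[gn]])) {
      g <- grads[[gn]][[pn]]
      m <- state$m[[gn]][[pn]] * beta1 + (1 - beta1) * g
      v <- state$v[[gn]][[pn]] * beta2 + (1 - beta2) * g * g
      state$m[[gn]][[pn]] <- m
      state$v[[gn]][[pn]] <- v
      params[[gn]][[pn]] <- params[[gn]][[pn]] -
        lr * (m / bc1) / (sqrt(v / bc2) + eps)
    }
  }
  list(params = params, state = state)
}

# add the L2 gradient 2*w*l2_weight to every parameter gradient
add_l2_grads <- function(grads, params, l2_weight) {
  if (l2_weight == 0) return(grads)
  for (gn in names(grads)) {
    for (pn in names(grads[[gn]])) {
      grads[[gn]][[pn]] <- grads[[gn]][[pn]] +
        2 * l2_weight * params[[gn]][[pn]]
    }
  }
  grads
}

#' Train the segmentation network
#'
#' Runs the full training loop: per epoch, draws
#' `samples_per_volume_per_epoch` class-balanced patches from every
#' training volume (augmented when configured), takes one Adam step per
#' batch on the composite multi-scale Dice + attention + L2 loss, then — at
#' `val_interval` epochs — computes the mean validation Dice coefficient by
#' full-volume sliding-window inference binarized at 0.5. The checkpoint
#' with the best validation Dice is returned as the final model. The whole
#' run is reproducible from `tcfg$seed` and `ncfg$seed`.
#'
#' Volumes are z-normalized internally; pass raw-intensity volumes.
#'
#' @param train_set,val_set Lists of `list(image =, mask =)` pairs
#'   ([image_volume()] / [mask_volume()]).
#' @param ncfg A [network_config()].
#' @param tcfg A [train_config()].
#' @param icfg An [inference_config()] used for validation (defaults to a
#'   window equal to the training patch).
#' @param verbose Print a per-epoch summary line.
#' @return List with `model` (best checkpoint, a `vs_model` whose `extra`
#'   records the best epoch and validation DSC) and `history` (one row per
#'   epoch: mean loss components, learning rate, validation DSC or `NA` on
#'   non-validation epochs).
#' @export
train <- function(train_set, val_set, ncfg, tcfg,
                  icfg = inference_config(window_size = tcfg$patch_size),
                  verbose = FALSE) {
  stopifnot(length(train_set) >= 1, length(val_set) >= 1,
            inherits(ncfg, "network_config"), inherits(tcfg, "train_config"))
  L <- length(ncfg$channels)
  if (any(tcfg$patch_size %% 2^(L - 1) != 0)) {
    stop("patch_size must be divisible by 2^(levels-1)", call. = FALSE)
  }
  model <- build_model(ncfg)
  astate <- adam_init(model$params)

  norm_set <- function(set) {
    lapply(set, function(pr) list(image = znormalize(pr$image),
                                  mask = pr$mask))
  }
  tr <- norm_set(train_set)
  va <- norm_set(val_set)

  history <- data.frame(epoch = integer(), lr = numeric(),
                        loss_total = numeric(), loss_ds = numeric(),
                        loss_sa = numeric(), loss_l2 = numeric(),
                        val_dsc = numeric())
  best <- list(dsc = -Inf, params = NULL, epoch = NA_integer_)

  set.seed(tcfg$seed)
  n_levels <- L - 1 # supervised decoder levels for a depth-L model
  for (epoch in seq_len(tcfg$total_epochs) - 1L) {
    lr <- lr_at_epoch(epoch, tcfg)
    order_idx <- rep(sample(length(tr)), tcfg$samples_per_volume_per_epoch)
    tot <- dssum <- sasum <- l2v <- 0
    nit <- 0L
    for (vi in order_idx) {
      pr <- tr[[vi]]
      pt <- sample_patch(pr$image, pr$mask, tcfg)
      if (!is.null(tcfg$augmentation)) {
        pt2 <- augment(pt$image, pt$mask, tcfg$augmentation)
        pt$image <- pt2$image
        pt$mask <- pt2$mask
      }
      n_sup <- if (ncfg$enable_deep_supervision) n_levels else 1L
      n_tg <- max(n_sup, if (ncfg$enable_spatial_attention) n_levels else 0L)
      targets <- downsample_targets(pt$mask, max(n_tg, 1L))
      out <- model_forward(model, pt$image, train = TRUE, keep_cache = TRUE)
      lb <- total_loss(out, targets, model$params, tcfg$l2_weight)
      if (!is.finite(lb$total)) {
        stop("training diverged: non-finite loss at epoch ", epoch,
             ", iteration ", nit + 1, call. = FALSE)
      }
      gl <- total_loss_grads(out, targets)
      grads <- model_backward(model, out, gl$d_level_maps, gl$d_att_maps)
      grads <- add_l2_grads(grads, model$params, tcfg$l2_weight)
      st <- adam_step(model$params, grads, astate, lr)
      model$params <- st$params
      astate <- st$state
      tot <- tot + lb$total
      dssum <- dssum + sum(lb$ds_losses)
      sasum <- sasum + sum(lb$sa_losses)
      l2v <- l2v + lb$l2_term
      nit <- nit + 1L
    }
    val_dsc <- NA_real_
    if ((epoch + 1L) %% tcfg$val_interval == 0L ||
        epoch == tcfg$total_epochs - 1L) {
      val_dsc <- mean(vapply(va, function(pr) {
        prob <- sliding_window_predict(model, pr$image, icfg,
                                       normalized = TRUE)
        pm <- binarize(prob, icfg$threshold)
        if (sum(pm$voxels) == 0 && sum(pr$mask$voxels) > 0) return(0)
        dsc(pm, pr$mask)
      }, 1.0))
      if (val_dsc > best$dsc) {
        best <- list(dsc = val_dsc, params = model$params, epoch = epoch)
      }
    }
    history <- rbind(history, data.frame(
      epoch = epoch, lr = lr, loss_total = tot / nit,
      loss_ds = dssum / nit, loss_sa = sasum / nit, loss_l2 = l2v / nit,
      val_dsc = val_dsc))
    if (verbose) {
      message(sprintf("epoch %3d  lr %.5f  loss %.4f  val DSC %s", epoch,
                      lr, tot / nit,
                      if (is.na(val_dsc)) "-" else sprintf("%.4f", val_dsc)))
    }
  }
  best_model <- structure(list(cfg = ncfg, params = best$params,
                               extra = list(best_epoch = best$epoch,
                                            best_val_dsc = best$dsc)),
                          class = "vs_model")
  list(model = best_model, history = history)
}
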
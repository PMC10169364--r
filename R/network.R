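#' Network architecture configuration
#'
#' Hyperparameters of the residual 3D U-Net. The default is the full-size
#' model: five resolution levels with channel widths 16, 32, 64, 80 and 96
#' from the top (full-resolution) level to the bottleneck, 3x3x3
#' convolutions, dropout rate 0.3, spatial attention and deep supervision
#' enabled. Smaller configurations (fewer levels, narrower channels) are
#' used for CPU-scale experiments.
#'
#' Normalization is per-channel over the spatial grid of the single volume
#' being processed (instance statistics). With the training batch size of
#' one, batch statistics and instance statistics coincide during training;
#' using instance statistics at evaluation keeps train and test behaviour
#' consistent and makes inference fully deterministic.
#'
#' @param channels Integer vector, channel width per level, top to bottom.
#' @param conv_kernel Integer length-3 convolution kernel (default 3x3x3).
#' @param dropout_rate Spatial dropout rate inside each residual block.
#' @param enable_spatial_attention Include the supervised spatial-attention
#'   gate at every decoder level.
#' @param enable_deep_supervision Attach a segmentation head (1x1x1
#'   convolution + sigmoid) to every decoder level; with it disabled only
#'   the top-level head remains and produces the final map.
#' @param input_channels Number of input image channels (1 for T1W MR).
#' @param norm Normalization flavour; `"instance"` as described above.
#' @param seed Integer seed for deterministic weight initialization.
#' @return A `network_config` list.
#' @export
network_config <- function(channels = c(16, 32, 64, 80, 96),
                           conv_kernel = c(3, 3, 3),
                           dropout_rate = 0.3,
                           enable_spatial_attention = TRUE,
                           enable_deep_supervision = TRUE,
                           input_channels = 1,
                           norm = "instance",
                           seed = 42L) {
  channels <- as.integer(channels)
  stopifnot(length(channels) >= 2L, all(channels > 0),
            length(conv_kernel) == 3L, all(conv_kernel >= 1),
            dropout_rate >= 0, dropout_rate < 1, input_channels >= 1)
  norm <- match.arg(norm, "instance")
  cfg <- list(channels = channels, conv_kernel = as.integer(conv_kernel),
              dropout_rate = dropout_rate,
              enable_spatial_attention = isTRUE(enable_spatial_attention),
              enable_deep_supervision = isTRUE(enable_deep_supervision),
              input_channels = as.integer(input_channels), norm = norm,
              seed = as.integer(seed))
  class(cfg) <- "network_config"
  cfg
}

# He-style normal initialization for a conv weight of dims (k1,k2,k3,Cin,Cout)
init_conv <- function(kd, cin, cout) {
  fan_in <- prod(kd) * cin
  w <- array(stats::rnorm(prod(kd) * cin * cout, 0, sqrt(2 / fan_in)),
             c(kd, cin, cout))
  list(w = w, b = rep(0, cout))
}

init_norm <- function(c) list(g = rep(1, c), bt = rep(0, c))

#' Build the residual 3D U-Net
#'
#' Constructs the model parameters for the given [network_config()].
#' Encoder: one residual block per level, each block being two
#' convolution-normalization-ReLU units with an additive skip across the
#' pair (a 1x1x1 projection on the skip path when the block changes channel
#' count), with spatial dropout after the first unit; a 3x3x3 stride-2
#' convolution (with normalization and ReLU) halves the resolution between
#' levels. Decoder, per level from the bottleneck up: a stride-2 transpose
#' convolution doubles the resolution, the result is concatenated with the
#' encoder features of that level, the spatial-attention gate (two
#' convolutions with ReLU then sigmoid producing a one-channel map that
#' rescales the concatenated features) is applied when enabled, and a
#' residual block reduces back to the level's width. A 1x1x1 convolution +
#' sigmoid head produces a probability map at every decoder level when deep
#' supervision is enabled (always at the top level, whose map is the final
#' segmentation map). Weight initialization is deterministic given
#' `cfg$seed`.
#'
#' @param cfg A [network_config()].
#' @return A `vs_model` object (parameters plus configuration).
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "network_config"))
  with_seed(cfg$seed, {
    L <- length(cfg$channels)
    ch <- cfg$channels
    kd <- cfg$conv_kernel
    p <- list()
    resblock_params <- function(cin, cout) {
      pr <- c(init_conv(kd, cin, cout), suffix_names(init_norm(cout), "1"))
      names(pr)[1:2] <- c("w1", "b1")
      pr2 <- c(init_conv(kd, cout, cout), suffix_names(init_norm(cout), "2"))
      names(pr2)[1:2] <- c("w2", "b2")
      out <- c(pr, pr2)
      if (cin != cout) {
        proj <- init_conv(c(1, 1, 1), cin, cout)
        out$wp <- proj$w
        out$bp <- proj$b
      }
      out
    }
    for (l in seq_len(L)) {
      cin <- if (l == 1) cfg$input_channels else ch[l]
      if (l > 1) {
        dn <- c(init_conv(kd, ch[l - 1], ch[l]), init_norm(ch[l]))
        p[[paste0("enc", l, ".down")]] <- dn
      }
      p[[paste0("enc", l, ".block")]] <- resblock_params(cin, ch[l])
    }
    for (l in seq(L - 1, 1)) {
      p[[paste0("dec", l, ".up")]] <- init_conv(c(2, 2, 2), ch[l + 1], ch[l])
      if (cfg$enable_spatial_attention) {
        att <- c(init_conv(kd, 2 * ch[l], ch[l]),
                 suffix_names(init_conv(c(1, 1, 1), ch[l], 1), "2"))
        names(att)[1:2] <- c("w1", "b1")
        p[[paste0("dec", l, ".att")]] <- att
      }
      p[[paste0("dec", l, ".block")]] <- resblock_params(2 * ch[l], ch[l])
      if (cfg$enable_deep_supervision || l == 1) {
        p[[paste0("head", l)]] <- init_conv(c(1, 1, 1), ch[l], 1)
      }
    }
    structure(list(cfg = cfg, params = p), class = "vs_model")
  })
}

suffix_names <- function(x, s) {
  names(x) <- paste0(names(x), s)
  x
}

#' @export
print.vs_model <- function(x, ...) {
  cat(sprintf(
    "<vs_model> %d levels, channels %s, SA=%s, DSV=%s, %s parameters\n",
    length(x$cfg$channels), paste(x$cfg$channels, collapse = "/"),
    x$cfg$enable_spatial_attention, x$cfg$enable_deep_supervision,
    format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Total number of trainable parameters
#' @param model A `vs_model`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params,
             function(g) sum(vapply(g, length, 1L)), 1L))
}

# ---- differentiable layer primitives (forward returns y + cache) ----
# normalization, ReLU and sigmoid run in compiled single-pass kernels;
# the ReLU backward derives its gate from the cached *output*.

nz_sigmoid <- function(x) sigmoid_fwd(x)

# residual block forward; pp is the parameter sub-list
resblock_fwd <- function(x, pp, kd, dropout_rate, train) {
  pad <- as.integer((kd - 1) / 2)
  c1 <- conv3d_fwd(x, pp$w1, pp$b1, 1L, pad)
  n1 <- norm3d_fwd(c1, pp$g1, pp$bt1, 1e-5)
  r1 <- relu_fwd(n1$y)
  dmask <- NULL
  d1 <- r1
  if (train && dropout_rate > 0) {
    ch <- dim(r1)[4]
    keep <- stats::runif(ch) >= dropout_rate
    dmask <- as.numeric(keep) / (1 - dropout_rate)
    d1 <- r1 * rep(dmask, each = prod(dim(r1)[1:3]))
  }
  c2 <- conv3d_fwd(d1, pp$w2, pp$b2, 1L, pad)
  n2 <- norm3d_fwd(c2, pp$g2, pp$bt2, 1e-5)
  if (!is.null(pp$wp)) {
    skip <- conv3d_fwd(x, pp$wp, pp$bp, 1L, c(0L, 0L, 0L))
  } else {
    skip <- x
  }
  y <- add_relu(n2$y, skip)
  list(y = y,
       cache = list(x = x, c1 = c1, mu1 = n1$mu, is1 = n1$invstd, r1 = r1,
                    dmask = dmask, d1 = d1, c2 = c2, mu2 = n2$mu,
                    is2 = n2$invstd, y = y, pad = pad,
                    has_proj = !is.null(pp$wp)))
}

resblock_bwd <- function(cache, pp, dy) {
  ds <- relu_bwd(cache$y, dy)
  nb2 <- norm3d_bwd(cache$c2, pp$g2, cache$mu2, cache$is2, ds)
  cb2 <- conv3d_bwd(cache$d1, pp$w2, nb2$dx, 1L, cache$pad, TRUE)
  dd1 <- cb2$dx
  if (!is.null(cache$dmask)) {
    dd1 <- dd1 * rep(cache$dmask, each = prod(dim(dd1)[1:3]))
  }
  dr1 <- relu_bwd(cache$r1, dd1)
  nb1 <- norm3d_bwd(cache$c1, pp$g1, cache$mu1, cache$is1, dr1)
  cb1 <- conv3d_bwd(cache$x, pp$w1, nb1$dx, 1L, cache$pad, TRUE)
  dx <- cb1$dx
  grads <- list(w1 = cb1$dw, b1 = cb1$db, g1 = nb1$dg, bt1 = nb1$dbt,
                w2 = cb2$dw, b2 = cb2$db, g2 = nb2$dg, bt2 = nb2$dbt)
  if (cache$has_proj) {
    pb <- conv3d_bwd(cache$x, pp$wp, ds, 1L, c(0L, 0L, 0L), TRUE)
    dx <- dx + pb$dx
    grads$wp <- pb$dw
    grads$bp <- pb$db
  } else {
    dx <- dx + ds
  }
  list(dx = dx, grads = grads)
}

#' Spatial attention gate
#'
#' Computes a one-channel spatial attention map from concatenated decoder
#' features — a 3x3x3 convolution halving the channel count followed by
#' ReLU, then a 1x1x1 convolution followed by sigmoid — and rescales the
#' features voxel-wise by the map (broadcast over channels). The map is
#' interpreted as the per-voxel probability of belonging to the tumor and
#' is directly supervised against the downsampled ground truth during
#' training.
#'
#' @param features 4D array (D,H,W,C) of concatenated decoder features.
#' @param pp Parameter list with `w1`, `b1` (first convolution) and `w2`,
#'   `b2` (second convolution).
#' @return A list with `attention_map` (3D array, values in (0,1)) and
#'   `scaled_features` (4D array, `features` times the map).
#' @export
spatial_attention <- function(features, pp) {
  fa <- attention_fwd(features, pp)
  list(attention_map = array(fa$amap, dim(features)[1:3]),
       scaled_features = fa$y)
}

attention_fwd <- function(x, pp) {
  kd <- dim(pp$w1)[1:3]
  pad <- as.integer((kd - 1) / 2)
  a1 <- conv3d_fwd(x, pp$w1, pp$b1, 1L, pad)
  r1 <- relu_fwd(a1)
  z <- conv3d_fwd(r1, pp$w2, pp$b2, 1L, c(0L, 0L, 0L))
  amap <- nz_sigmoid(z)
  y <- x * as.vector(amap) # map recycled across channels
  list(y = y, amap = amap,
       cache = list(x = x, r1 = r1, amap = amap, pad = pad))
}

# dy: grad wrt scaled features; damap_extra: grad flowing directly into the
# attention map from its supervision loss (3D array or NULL)
attention_bwd <- function(cache, pp, dy, damap_extra = NULL) {
  x <- cache$x
  d <- dim(x)
  n <- prod(d[1:3])
  am <- as.vector(cache$amap)
  dx_gate <- dy * am # recycled across channels
  dym <- matrix(dy, n, d[4])
  xm <- matrix(x, n, d[4])
  damap <- rowSums(dym * xm)
  if (!is.null(damap_extra)) damap <- damap + as.vector(damap_extra)
  dz <- damap * am * (1 - am)
  dz <- array(dz, c(d[1:3], 1L))
  cb2 <- conv3d_bwd(cache$r1, pp$w2, dz, 1L, c(0L, 0L, 0L), TRUE)
  dr1 <- relu_bwd(cache$r1, cb2$dx)
  cb1 <- conv3d_bwd(x, pp$w1, dr1, 1L, cache$pad, TRUE)
  list(dx = dx_gate + cb1$dx,
       grads = list(w1 = cb1$dw, b1 = cb1$db, w2 = cb2$dw, b2 = cb2$db))
}

#' Forward pass of the network
#'
#' Runs the full encoder-decoder forward pass on one input volume.
#'
#' @param model A `vs_model` from [build_model()].
#' @param x 3D array (a patch or window, spatial dims divisible by
#'   `2^(levels-1)`) or 4D array (D,H,W,C).
#' @param train Logical; enables dropout (stochastic, consumes RNG draws).
#'   Evaluation mode (`FALSE`, default) is fully deterministic.
#' @param keep_cache Keep all intermediate activations for a subsequent
#'   backward pass (memory-heavy; only needed for training).
#' @return A `forward_outputs` list: `final_map` (3D probability array at
#'   input resolution), `level_maps` (list of probability maps, one per
#'   supervised decoder level, full resolution first, each half the
#'   previous), `attention_maps` (list of attention maps per decoder level,
#'   same resolutions, empty when attention is disabled), and `cache` when
#'   requested.
#' @export
model_forward <- function(model, x, train = FALSE, keep_cache = FALSE) {
  cfg <- model$cfg
  p <- model$params
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  L <- length(cfg$channels)
  sd3 <- dim(x)[1:3]
  if (any(sd3 %% 2^(L - 1) != 0)) {
    stop("input spatial dims (", paste(sd3, collapse = "x"),
         ") must be divisible by 2^(levels-1) = ", 2^(L - 1), call. = FALSE)
  }
  kd <- cfg$conv_kernel
  pad <- as.integer((kd - 1) / 2)
  cache <- if (keep_cache) list(enc = vector("list", L),
                                dec = vector("list", L - 1)) else NULL

  enc <- vector("list", L)
  h <- x
  for (l in seq_len(L)) {
    if (l > 1) {
      nm <- paste0("enc", l, ".down")
      cd <- conv3d_fwd(h, p[[nm]]$w, p[[nm]]$b, 2L, pad)
      nd <- norm3d_fwd(cd, p[[nm]]$g, p[[nm]]$bt, 1e-5)
      hd <- relu_fwd(nd$y)
      if (keep_cache) {
        cache$enc[[l]]$down <- list(x = h, cd = cd, mu = nd$mu,
                                    is = nd$invstd, hd = hd)
      }
      h <- hd
    }
    rb <- resblock_fwd(h, p[[paste0("enc", l, ".block")]], kd,
                       cfg$dropout_rate, train)
    if (keep_cache) cache$enc[[l]]$block <- rb$cache
    h <- rb$y
    enc[[l]] <- h
  }

  level_maps <- list()
  attention_maps <- list()
  d <- enc[[L]]
  for (l in seq(L - 1, 1)) {
    nm <- paste0("dec", l, ".up")
    u <- convt3d_fwd(d, p[[nm]]$w, p[[nm]]$b)
    f <- abind4(u, enc[[l]])
    if (keep_cache) cache$dec[[l]]$up_x <- d
    if (cfg$enable_spatial_attention) {
      fa <- attention_fwd(f, p[[paste0("dec", l, ".att")]])
      attention_maps[[as.character(l)]] <- array(fa$amap, dim(f)[1:3])
      if (keep_cache) cache$dec[[l]]$att <- fa$cache
      f <- fa$y
    }
    rb <- resblock_fwd(f, p[[paste0("dec", l, ".block")]], kd,
                       cfg$dropout_rate, train)
    if (keep_cache) cache$dec[[l]]$block <- rb$cache
    d <- rb$y
    if (cfg$enable_deep_supervision || l == 1) {
      hn <- paste0("head", l)
      z <- conv3d_fwd(d, p[[hn]]$w, p[[hn]]$b, 1L, c(0L, 0L, 0L))
      pm <- nz_sigmoid(z)
      level_maps[[as.character(l)]] <- array(pm, dim(pm)[1:3])
      if (keep_cache) cache$dec[[l]]$head_x <- d
    }
  }

  ord <- as.character(sort(as.integer(names(level_maps))))
  level_maps <- level_maps[ord]
  if (length(attention_maps)) {
    orda <- as.character(sort(as.integer(names(attention_maps))))
    attention_maps <- attention_maps[orda]
  }
  structure(list(final_map = level_maps[[1]],
                 level_maps = unname(level_maps),
                 attention_maps = unname(attention_maps),
                 cache = cache),
            class = "forward_outputs")
}

# concatenate two (D,H,W,C) arrays along the channel axis
abind4 <- function(a, b) {
  da <- dim(a)
  db <- dim(b)
  stopifnot(all(da[1:3] == db[1:3]))
  array(c(a, b), c(da[1:3], da[4] + db[4]))
}

# Backward pass: d_level_maps / d_att_maps are gradients of the loss with
# respect to each probability/attention map (same list layout as the forward
# outputs). Returns gradients as a nested list congruent with model$params.
model_backward <- function(model, outputs, d_level_maps,
                           d_att_maps = NULL) {
  cfg <- model$cfg
  p <- model$params
  cache <- outputs$cache
  if (is.null(cache)) stop("forward pass was run without keep_cache")
  L <- length(cfg$channels)
  kd <- cfg$conv_kernel
  pad <- as.integer((kd - 1) / 2)
  grads <- list()
  denc <- vector("list", L) # gradient wrt each encoder skip output

  dd <- NULL # gradient wrt current decoder state, flowing upward in l
  supervised <- if (cfg$enable_deep_supervision) seq_len(L - 1) else 1L
  for (l in seq_len(L - 1)) {
    # accumulate head gradient at this level, then pass through the block
    if (l %in% supervised) {
      pm <- outputs$level_maps[[match(l, supervised)]]
      dpm <- d_level_maps[[match(l, supervised)]]
      dz <- dpm * pm * (1 - pm)
      dz <- array(dz, c(dim(pm), 1L))
      hn <- paste0("head", l)
      hb <- conv3d_bwd(cache$dec[[l]]$head_x, p[[hn]]$w, dz, 1L,
                       c(0L, 0L, 0L), TRUE)
      grads[[hn]] <- list(w = hb$dw, b = hb$db)
      dd <- if (is.null(dd)) hb$dx else dd + hb$dx
    }
    bn <- paste0("dec", l, ".block")
    rb <- resblock_bwd(cache$dec[[l]]$block, p[[bn]], dd)
    grads[[bn]] <- rb$grads
    df <- rb$dx
    if (cfg$enable_spatial_attention) {
      an <- paste0("dec", l, ".att")
      dam <- if (!is.null(d_att_maps)) d_att_maps[[l]] else NULL
      ab <- attention_bwd(cache$dec[[l]]$att, p[[an]], df, dam)
      grads[[an]] <- ab$grads
      df <- ab$dx
    }
    # split concat gradient into upsampled part and encoder skip part
    cu <- cfg$channels[l]
    dfu <- df[, , , seq_len(cu), drop = FALSE]
    denc[[l]] <- df[, , , cu + seq_len(cu), drop = FALSE]
    un <- paste0("dec", l, ".up")
    ub <- convt3d_bwd(cache$dec[[l]]$up_x, p[[un]]$w, dfu)
    grads[[un]] <- list(w = ub$dw, b = ub$db)
    dd <- ub$dx # gradient wrt decoder state of level l+1 (or enc[L] at top)
  }
  # encoder, from the bottleneck down
  dh <- dd
  for (l in seq(L, 1)) {
    if (l < L && !is.null(denc[[l]])) dh <- dh + denc[[l]]
    bn <- paste0("enc", l, ".block")
    rb <- resblock_bwd(cache$enc[[l]]$block, p[[bn]], dh)
    grads[[bn]] <- rb$grads
    dh <- rb$dx
    if (l > 1) {
      nm <- paste0("enc", l, ".down")
      cd <- cache$enc[[l]]$down
      dpre <- relu_bwd(cd$hd, dh)
      nb <- norm3d_bwd(cd$cd, p[[nm]]$g, cd$mu, cd$is, dpre)
      cb <- conv3d_bwd(cd$x, p[[nm]]$w, nb$dx, 2L, pad, TRUE)
      grads[[nm]] <- list(w = cb$dw, b = cb$db, g = nb$dg, bt = nb$dbt)
      dh <- cb$dx
    }
  }
  grads
}

#' Save a model checkpoint
#'
#' Serializes the parameters together with the embedded [network_config()]
#' so inference never needs a separate architecture description.
#'
#' @param model A `vs_model`.
#' @param path Destination file.
#' @param extra Optional list of additional metadata to store.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path, extra = NULL) {
  stopifnot(inherits(model, "vs_model"))
  saveRDS(list(cfg = model$cfg, params = model$params, extra = extra), path)
  invisible(path)
}

#' Load a model checkpoint
#' @param path Checkpoint file written by [save_checkpoint()].
#' @return A `vs_model`.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) {
    stop("checkpoint not found: ", path, call. = FALSE)
  }
  obj <- readRDS(path)
  if (!is.list(obj) || is.null(obj$cfg) || is.null(obj$params)) {
    stop("not a valid checkpoint file: ", path, call. = FALSE)
  }
  structure(list(cfg = obj$cfg, params = obj$params, extra = obj$extra),
            class = "vs_model")
}
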
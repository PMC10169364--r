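#' Dice loss
#'
#' The soft Dice loss `1 - (2*sum(p*t) + s) / (sum(p) + sum(t) + s)`
#' between a probability map and a binary target. The smoothing constant
#' `s` appears in both numerator and denominator so the loss is defined
#' (and near zero) when both maps are empty, which happens on
#' background-centred training crops.
#'
#' @param pred Array of probabilities in `[0,1]`.
#' @param target Binary array of the same shape.
#' @param smooth Small positive smoothing constant (default `1e-5`).
#' @return A scalar in `[0,1]`.
#' @export
dice_loss <- function(pred, target, smooth = 1e-5) {
  if (!identical(dim(pred), dim(target)) ||
      (is.null(dim(pred)) && length(pred) != length(target))) {
    stop("dice_loss: pred and target shapes differ", call. = FALSE)
  }
  i <- sum(pred * target)
  1 - (2 * i + smooth) / (sum(pred) + sum(target) + smooth)
}

# gradient of dice_loss with respect to pred
dice_loss_grad <- function(pred, target, smooth = 1e-5) {
  i <- sum(pred * target)
  denom <- sum(pred) + sum(target) + smooth
  g <- -(2 * target * denom - (2 * i + smooth)) / denom^2
  array(g, dim(pred))
}

#' Multi-scale ground-truth targets for deep supervision
#'
#' Downsamples a binary mask to each supervised decoder resolution by
#' repeated 2x2x2 max-pooling. Max-pooling (rather than strided
#' subsampling) guarantees that a nonempty tumor stays nonempty at every
#' scale — essential for very small lesions that would otherwise vanish
#' from the coarse supervision targets.
#'
#' @param gt A [mask_volume()] or binary 3D array with dims divisible by
#'   `2^(n_levels-1)`.
#' @param n_levels Number of scales (full resolution plus
#'   `n_levels - 1` halvings).
#' @return List of binary arrays, full resolution first.
#' @export
downsample_targets <- function(gt, n_levels) {
  m <- if (inherits(gt, "mask_volume")) gt$voxels else gt
  d <- dim(m)
  if (any(d %% 2^(n_levels - 1) != 0)) {
    stop("mask dims (", paste(d, collapse = "x"),
         ") not divisible by 2^(n_levels-1) = ", 2^(n_levels - 1),
         call. = FALSE)
  }
  out <- vector("list", n_levels)
  out[[1]] <- m
  for (k in seq_len(n_levels - 1)) {
    m <- maxpool2_3d(m)
    out[[k + 1]] <- m
  }
  out
}

#' Composite training loss
#'
#' The total training objective: the unweighted sum of the Dice losses of
#' every deep-supervision map against the ground truth downsampled to its
#' resolution, plus the Dice losses of every spatial-attention map against
#' the same targets, plus L2 regularization of all model parameters with
#' weight `l2_weight`.
#'
#' @param outputs A `forward_outputs` object from [model_forward()].
#' @param targets List of binary arrays from [downsample_targets()] (full
#'   resolution first; must provide one target per supervised map).
#' @param params Model parameter list (`model$params`), used for the L2
#'   term; may be `NULL` to skip it.
#' @param l2_weight L2 weight (default `1e-7`).
#' @param smooth Dice smoothing constant.
#' @return A `loss_breakdown` list: `ds_losses`, `sa_losses`, `l2_term`,
#'   `total`.
#' @export
total_loss <- function(outputs, targets, params = NULL, l2_weight = 1e-7,
                       smooth = 1e-5) {
  nmap <- length(outputs$level_maps)
  if (length(targets) < nmap) {
    stop("total_loss: ", nmap, " output maps but only ", length(targets),
         " targets", call. = FALSE)
  }
  ds <- vapply(seq_len(nmap), function(k) {
    dice_loss(outputs$level_maps[[k]], targets[[k]], smooth)
  }, 1.0)
  sa <- numeric(0)
  if (length(outputs$attention_maps)) {
    sa <- vapply(seq_along(outputs$attention_maps), function(k) {
      dice_loss(outputs$attention_maps[[k]], targets[[k]], smooth)
    }, 1.0)
  }
  l2 <- 0
  if (!is.null(params) && l2_weight != 0) {
    l2 <- sum(vapply(params, function(g) {
      sum(vapply(g, function(a) sum(a * a), 1.0))
    }, 1.0))
  }
  structure(list(ds_losses = ds, sa_losses = sa, l2_term = l2,
                 total = sum(ds) + sum(sa) + l2_weight * l2),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("<loss_breakdown> total %.5f  (ds: %s | sa: %s | l2: %.3g)\n",
              x$total, paste(sprintf("%.4f", x$ds_losses), collapse = " "),
              if (length(x$sa_losses))
                paste(sprintf("%.4f", x$sa_losses), collapse = " ")
              else "-",
              x$l2_term))
  invisible(x)
}

# gradients of the composite loss with respect to every output map;
# returns lists aligned with outputs$level_maps / outputs$attention_maps
total_loss_grads <- function(outputs, targets, smooth = 1e-5) {
  dlm <- lapply(seq_along(outputs$level_maps), function(k) {
    dice_loss_grad(outputs$level_maps[[k]], targets[[k]], smooth)
  })
  dam <- NULL
  if (length(outputs$attention_maps)) {
    dam <- lapply(seq_along(outputs$attention_maps), function(k) {
      dice_loss_grad(outputs$attention_maps[[k]], targets[[k]], smooth)
    })
  }
  list(d_level_maps = dlm, d_att_maps = dam)
}
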
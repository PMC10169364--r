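#' Sliding-window inference configuration
#'
#' Whole volumes are predicted by tiling overlapping fixed-size windows;
#' the full-scale setting is a 128x128x96 window with 25% overlap and a
#' binarization threshold of 0.5. Overlapping window predictions are
#' averaged with uniform (`"constant"`) weights by default; `"gaussian"`
#' weights (down-weighting window borders) are available as an option.
#'
#' @param window_size Integer length-3 window dims; must be divisible by
#'   `2^(levels-1)` of the model.
#' @param overlap_fraction Fractional overlap between adjacent windows, in
#'   `[0, 1)`.
#' @param blend `"constant"` or `"gaussian"` blending weights.
#' @param threshold Binarization threshold in `(0, 1)`.
#' @return An `inference_config` list.
#' @export
inference_config <- function(window_size = c(128, 128, 96),
                             overlap_fraction = 0.25,
                             blend = c("constant", "gaussian"),
                             threshold = 0.5) {
  blend <- match.arg(blend)
  stopifnot(length(window_size) == 3L, all(window_size >= 4),
            overlap_fraction >= 0, overlap_fraction < 1,
            threshold > 0, threshold < 1)
  structure(list(window_size = as.integer(window_size),
                 overlap_fraction = overlap_fraction, blend = blend,
                 threshold = threshold),
            class = "inference_config")
}

#' Window start indices for sliding-window tiling
#'
#' Computes the (1-based) start indices of the windows covering a volume.
#' The stride per axis is `round(window * (1 - overlap_fraction))`; the
#' last window on each axis is clamped so it ends exactly at the volume
#' boundary, guaranteeing every voxel is covered by at least one window.
#'
#' @param volume_dims Integer length-3 volume dims (each `>=` window).
#' @param cfg An [inference_config()].
#' @return A matrix with one row per window and 3 columns of start indices.
#' @export
window_starts <- function(volume_dims, cfg) {
  stopifnot(inherits(cfg, "inference_config"))
  w <- cfg$window_size
  if (any(volume_dims < w)) {
    stop("volume (", paste(volume_dims, collapse = "x"),
         ") smaller than window; pad first", call. = FALSE)
  }
  stride <- pmax(round(w * (1 - cfg$overlap_fraction)), 1)
  axis_starts <- lapply(1:3, function(i) {
    s <- seq(1L, volume_dims[i] - w[i] + 1L, by = stride[i])
    last <- volume_dims[i] - w[i] + 1L
    if (s[length(s)] != last) s <- c(s, last)
    unique(s)
  })
  as.matrix(expand.grid(d = axis_starts[[1]], h = axis_starts[[2]],
                        w = axis_starts[[3]]))
}

gaussian_window_weights <- function(w, sigma_scale = 0.25) {
  g <- lapply(1:3, function(i) {
    ctr <- (w[i] - 1) / 2
    exp(-((seq_len(w[i]) - 1 - ctr)^2) / (2 * (sigma_scale * w[i])^2))
  })
  outer(outer(g[[1]], g[[2]]), g[[3]])
}

#' Whole-volume prediction by sliding-window tiling
#'
#' Z-normalizes the volume (unless told it already is), zero-pads it up to
#' the window size if needed, runs the model on every window from
#' [window_starts()], blends overlapping window predictions by
#' weight-normalized averaging (weights sum to one at every voxel,
#' including clamped border windows), and strips the padding, returning a
#' probability volume on the input grid. Deterministic: the model runs in
#' evaluation mode.
#'
#' @param model A `vs_model`.
#' @param img An [image_volume()].
#' @param cfg An [inference_config()].
#' @param normalized Set `TRUE` if `img` is already z-normalized.
#' @return An [image_volume()] of per-voxel tumor probabilities in
#'   `[0, 1]`.
#' @export
sliding_window_predict <- function(model, img, cfg = inference_config(),
                                   normalized = FALSE) {
  stopifnot(inherits(model, "vs_model") || is.function(model),
            inherits(img, "image_volume"))
  L <- if (is.function(model)) NULL else length(model$cfg$channels)
  if (!is.null(L) && any(cfg$window_size %% 2^(L - 1) != 0)) {
    stop("window_size must be divisible by 2^(levels-1)", call. = FALSE)
  }
  v <- if (normalized) img else znormalize(img)
  padded <- pad_to(v$voxels, cfg$window_size)
  a <- padded$a
  d <- dim(a)
  starts <- window_starts(d, cfg)
  w <- cfg$window_size
  wts <- if (cfg$blend == "gaussian") gaussian_window_weights(w)
         else array(1, w)
  acc <- array(0, d)
  wacc <- array(0, d)
  for (r in seq_len(nrow(starts))) {
    s <- starts[r, ]
    ix <- s[1]:(s[1] + w[1] - 1)
    iy <- s[2]:(s[2] + w[2] - 1)
    iz <- s[3]:(s[3] + w[3] - 1)
    patch <- a[ix, iy, iz]
    pred <- if (is.function(model)) {
      model(patch)
    } else {
      model_forward(model, patch)$final_map
    }
    if (any(!is.finite(pred))) {
      stop("non-finite model output in window starting at (",
           paste(s, collapse = ","), ")", call. = FALSE)
    }
    acc[ix, iy, iz] <- acc[ix, iy, iz] + pred * wts
    wacc[ix, iy, iz] <- wacc[ix, iy, iz] + wts
  }
  prob <- acc / wacc
  lo <- padded$lo
  od <- padded$orig
  prob <- prob[lo[1] + seq_len(od[1]), lo[2] + seq_len(od[2]),
               lo[3] + seq_len(od[3]), drop = FALSE]
  image_volume(array(prob, od), img$spacing, img$header)
}

#' Binarize a probability volume
#'
#' A voxel is foreground iff its probability is strictly greater than the
#' threshold; a map that is exactly 0.5 everywhere therefore binarizes to
#' an empty mask at the default threshold.
#'
#' @param prob An [image_volume()] of probabilities (or a 3D array).
#' @param threshold Threshold in `(0, 1)`.
#' @return A [mask_volume()].
#' @export
binarize <- function(prob, threshold = 0.5) {
  if (inherits(prob, "image_volume")) {
    mask_volume((prob$voxels > threshold) * 1, prob$spacing, prob$header)
  } else {
    mask_volume((prob > threshold) * 1)
  }
}

#' Largest connected component of a mask
#'
#' Optional post-processing: keep only the largest 6-connected foreground
#' component. Off by default in the pipeline — the method is evaluated on
#' the raw thresholded output.
#'
#' @param m A [mask_volume()].
#' @return A [mask_volume()] containing only the largest component.
#' @export
largest_component <- function(m) {
  stopifnot(inherits(m, "mask_volume"))
  if (sum(m$voxels) == 0) return(m)
  lab <- label_components6(m$voxels)
  tab <- tabulate(lab[lab > 0])
  keep <- which.max(tab)
  mask_volume((lab == keep) * 1, m$spacing, m$header)
}

# 6-connected component labelling (small volumes; flood fill in R)
label_components6 <- function(vox) {
  d <- dim(vox)
  lab <- array(0L, d)
  cur <- 0L
  idx_fg <- which(vox != 0)
  for (s in idx_fg) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    lab[s] <- cur
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      co <- arrayInd(v, d)
      for (ax in 1:3) {
        for (dir in c(-1L, 1L)) {
          nb <- co
          nb[ax] <- nb[ax] + dir
          if (nb[ax] < 1 || nb[ax] > d[ax]) next
          ni <- nb[1] + d[1] * ((nb[2] - 1) + d[2] * (nb[3] - 1))
          if (vox[ni] != 0 && lab[ni] == 0L) {
            lab[ni] <- cur
            stack <- c(stack, ni)
          }
        }
      }
    }
  }
  lab
}
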
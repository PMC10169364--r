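#' Read a NIfTI volume
#'
#' Reads a NIfTI-1 file (optionally gzip-compressed) into an
#' [image_volume()], taking the voxel spacing from the header `pixdim`.
#' Orientation metadata is kept opaquely on the object so a write/read
#' round-trip preserves it; the segmentation method itself works in voxel
#' space plus spacing.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return An [image_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read volume: file not found: ", path, call. = FALSE)
  }
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) {
                    stop("cannot read NIfTI file ", path, ": ",
                         conditionMessage(e), call. = FALSE)
                  })
  a <- as.array(img)
  if (is.null(dim(a)) || length(dim(a)) != 3L) {
    stop("not a 3D volume: ", path, " has ",
         length(dim(a)), " dimensions", call. = FALSE)
  }
  sp <- RNifti::pixdim(img)[seq_len(3)]
  image_volume(a, sp, header = RNifti::niftiHeader(img))
}

#' Read a NIfTI binary mask
#'
#' As [read_volume()], but validates that all voxel values are 0 or 1.
#'
#' @inheritParams read_volume
#' @return A [mask_volume()].
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  mask_volume(v$voxels, v$spacing, v$header)
}

#' Write a volume or mask to NIfTI
#'
#' Images are written as float64 so the round-trip is bit-exact; masks as
#' uint8. Spacing goes to the header `pixdim`.
#'
#' @param v An [image_volume()] or [mask_volume()].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "image_volume"))
  a <- v$voxels
  attr(a, "pixdim") <- v$spacing
  dtype <- if (inherits(v, "mask_volume")) "uint8" else "double"
  RNifti::writeNifti(a, path, datatype = dtype)
  invisible(path)
}

#' Z-score intensity normalization
#'
#' Subtracts the mean and divides by the standard deviation of the whole
#' volume, the standard preprocessing applied to every MR volume before
#' training and inference. The statistics are computed over all voxels (no
#' brain mask), using the population (divide-by-n) standard deviation.
#'
#' @param v An [image_volume()].
#' @return An [image_volume()] with zero mean and unit standard deviation.
#' @export
znormalize <- function(v) {
  stopifnot(inherits(v, "image_volume"))
  x <- v$voxels
  mu <- mean(x)
  sd_ <- sqrt(mean((x - mu)^2))
  if (!is.finite(sd_) || sd_ <= 0) {
    stop("cannot z-normalize a constant volume (standard deviation is 0)",
         call. = FALSE)
  }
  image_volume((x - mu) / sd_, v$spacing, v$header)
}

#' Resample a volume to a target voxel spacing
#'
#' Regrids the volume so its voxel spacing becomes `target_spacing`,
#' preserving the physical extent to within one voxel per axis. The output
#' grid has `round(dim * spacing / target_spacing)` voxels per axis. Use
#' `mode = "linear"` (trilinear) for images and `mode = "nearest"` for
#' masks; nearest-neighbour interpolation never introduces values outside
#' the input's value set, so binary masks stay binary.
#'
#' @param v An [image_volume()] or [mask_volume()].
#' @param target_spacing Numeric length-3, mm per voxel, all positive.
#' @param mode `"linear"` or `"nearest"`.
#' @return A volume of the same class as `v` on the new grid.
#' @export
resample_to_spacing <- function(v, target_spacing,
                                mode = c("linear", "nearest")) {
  stopifnot(inherits(v, "image_volume"))
  mode <- match.arg(mode)
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) != 3L || any(target_spacing <= 0)) {
    stop("target_spacing must be 3 positive values (mm)", call. = FALSE)
  }
  d <- dim(v$voxels)
  out_dim <- as.integer(round(d * v$spacing / target_spacing))
  if (any(out_dim < 1L)) {
    stop("resampling would produce an empty grid (target spacing too coarse)",
         call. = FALSE)
  }
  ratio <- target_spacing / v$spacing
  out <- resample_grid(v$voxels, out_dim, ratio,
                       if (mode == "linear") 0L else 1L)
  if (inherits(v, "mask_volume")) {
    mask_volume(out, target_spacing, v$header)
  } else {
    image_volume(out, target_spacing, v$header)
  }
}
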
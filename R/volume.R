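#' 3D image volume with voxel spacing
#'
#' An `image_volume` bundles a 3D array of scalar intensities with the
#' physical voxel spacing in millimetres along each axis. It is the unit of
#' all I/O, preprocessing and inference in the package. Orientation metadata
#' read from a NIfTI header is carried opaquely (attribute `header`) and
#' written back on output; all geometry used by the method itself is voxel
#' indices plus spacing.
#'
#' @param voxels 3D numeric array of intensities (arbitrary units).
#' @param spacing Numeric length-3, mm per voxel along each array axis.
#'   All components must be positive.
#' @param header Optional opaque NIfTI header template, preserved through
#'   write/read round-trips.
#' @return An object of class `image_volume` with elements `voxels`,
#'   `spacing` and `header`.
#' @export
image_volume <- function(voxels, spacing = c(1, 1, 1), header = NULL) {
  voxels <- as_voxel_array(voxels)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be 3 positive finite values (mm)", call. = FALSE)
  }
  structure(list(voxels = voxels, spacing = spacing, header = header),
            class = "image_volume")
}

#' Binary mask volume
#'
#' A `mask_volume` is a binary (0/1) 3D grid geometrically aligned with an
#' [image_volume()]: same array shape, same spacing. Ground-truth tumor
#' contours and model predictions are both represented this way.
#'
#' @param voxels 3D array whose values are exactly 0 or 1.
#' @inheritParams image_volume
#' @return An object of class `mask_volume`.
#' @export
mask_volume <- function(voxels, spacing = c(1, 1, 1), header = NULL) {
  voxels <- as_voxel_array(voxels)
  u <- unique(as.vector(voxels))
  if (!all(u %in% c(0, 1))) {
    stop("mask voxels must be exactly 0 or 1; found other values",
         call. = FALSE)
  }
  v <- image_volume(voxels, spacing, header)
  class(v) <- c("mask_volume", "image_volume")
  v
}

as_voxel_array <- function(voxels) {
  d <- dim(voxels)
  if (is.null(d) || length(d) != 3L) {
    stop("not a 3D volume: voxel grid must have exactly 3 dimensions",
         call. = FALSE)
  }
  if (any(d < 1L)) stop("every dimension must be >= 1", call. = FALSE)
  # plain double array: strip any foreign class/attributes (e.g. NIfTI)
  array(as.double(voxels), d)
}

#' @export
print.image_volume <- function(x, ...) {
  kind <- if (inherits(x, "mask_volume")) "mask_volume" else "image_volume"
  cat(sprintf("<%s> %s voxels, spacing %s mm\n", kind,
              paste(dim(x$voxels), collapse = "x"),
              paste(format(x$spacing, digits = 4), collapse = " x ")))
  if (kind == "mask_volume") {
    cat(sprintf("  foreground: %d voxels (%.3f cm^3)\n",
                sum(x$voxels != 0), volume_cm3(x)))
  } else {
    cat(sprintf("  intensity range: [%.4g, %.4g]\n",
                min(x$voxels), max(x$voxels)))
  }
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$voxels)

#' Physical volume of a voxel in mm^3
#' @param v An [image_volume()] or [mask_volume()].
#' @return Voxel volume in cubic millimetres.
#' @export
voxel_volume_mm3 <- function(v) prod(v$spacing)

#' Foreground volume of a mask in cm^3
#' @param m A [mask_volume()].
#' @return Foreground voxel count times voxel volume, in cubic centimetres.
#' @export
volume_cm3 <- function(m) {
  sum(m$voxels != 0) * voxel_volume_mm3(m) / 1000
}

stopifnot_congruent <- function(a, b) {
  if (!identical(dim(a$voxels), dim(b$voxels))) {
    stop("volumes are not congruent: shapes differ (",
         paste(dim(a$voxels), collapse = "x"), " vs ",
         paste(dim(b$voxels), collapse = "x"), ")", call. = FALSE)
  }
  if (max(abs(a$spacing - b$spacing)) > 1e-6) {
    stop("volumes are not congruent: spacings differ", call. = FALSE)
  }
  invisible(TRUE)
}
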
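#' Configuration for synthetic head phantoms
#'
#' The phantom generator emulates the kind of data the segmentation model is
#' meant for: near-isotropic (default 0.8 x 0.8 x 1.0 mm) contrast-enhanced
#' T1-like volumes containing a single bright, lobulated tumor on a smooth
#' head-shaped background with a low-frequency intensity bias and additive
#' Gaussian noise. Tumor volumes are drawn log-uniformly from
#' `tumor_volume_range`; the clinical population this mirrors spans 0.03 to
#' 17.75 cm^3 with a median well below the arithmetic mid-range, which a
#' log-uniform draw reproduces (its median over the default range is about
#' 0.73 cm^3). A fraction of tumors is "cystic": an interior sub-region is
#' hypointense relative to the background while the mask still covers the
#' whole lesion, mimicking mixed cystic tumors with inhomogeneous contrast
#' enhancement.
#'
#' @param grid_shape Integer length-3, voxels per axis.
#' @param spacing Numeric length-3, mm per voxel.
#' @param tumor_volume_range Length-2, min and max tumor volume in cm^3.
#' @param cystic_fraction Probability in `[0,1]` that a tumor has a
#'   hypointense core.
#' @param enhancement_contrast Tumor-to-local-background mean intensity
#'   ratio (> 0); contrast-enhancing tumors are brighter than brain.
#' @param noise_sigma Standard deviation of additive Gaussian noise, in
#'   units of the unit background intensity.
#' @param bias_field_amplitude Relative amplitude of the multiplicative
#'   low-frequency bias field (0 disables it).
#' @param seed Integer master seed; per-case seeds are derived from it.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(grid_shape = c(96, 96, 72),
                           spacing = c(0.8, 0.8, 1.0),
                           tumor_volume_range = c(0.03, 17.75),
                           cystic_fraction = 0.2,
                           enhancement_contrast = 2.0,
                           noise_sigma = 0.05,
                           bias_field_amplitude = 0.2,
                           seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 8L),
            length(spacing) == 3L, all(spacing > 0),
            length(tumor_volume_range) == 2L,
            all(tumor_volume_range > 0),
            tumor_volume_range[1] <= tumor_volume_range[2],
            cystic_fraction >= 0, cystic_fraction <= 1,
            enhancement_contrast > 0, noise_sigma >= 0,
            bias_field_amplitude >= 0)
  cfg <- list(grid_shape = grid_shape, spacing = as.numeric(spacing),
              tumor_volume_range = as.numeric(tumor_volume_range),
              cystic_fraction = cystic_fraction,
              enhancement_contrast = enhancement_contrast,
              noise_sigma = noise_sigma,
              bias_field_amplitude = bias_field_amplitude,
              seed = as.integer(seed))
  class(cfg) <- "phantom_config"
  cfg
}

# Deterministic per-case seed: a stable integer hash of (master seed, index),
# kept below 2^31 so cohorts can be extended without reshuffling earlier cases.
case_seed_for <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) * 1000003 + 7919 * as.numeric(index)) %%
               2147483629)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate one synthetic head phantom with a paired tumor mask
#'
#' Builds a smooth ellipsoidal head on a dark background, multiplies in a
#' low-frequency bias field, carves a single connected, randomly lobulated
#' ellipsoidal tumor placed off-centre inside the head at
#' `enhancement_contrast` times the local background intensity (optionally
#' with a hypointense cystic core), and adds Gaussian noise. The realized
#' mask volume is corrected to lie within a few percent of the volume drawn
#' from `tumor_volume_range`. Identical `(cfg, case_seed)` reproduce the
#' volume bit-exactly; the caller's RNG state is left untouched.
#'
#' @param cfg A [phantom_config()].
#' @param case_seed Integer seed for this case.
#' @return A list with elements `image` ([image_volume()]), `mask`
#'   ([mask_volume()]) and `meta` (drawn and realized tumor volume in cm^3,
#'   cystic flag, centre in voxel coordinates).
#' @export
generate_phantom <- function(cfg, case_seed) {
  stopifnot(inherits(cfg, "phantom_config"))
  with_seed(as.integer(case_seed), {
    d <- cfg$grid_shape
    sp <- cfg$spacing
    fov <- d * sp
    half <- fov / 2
    head_semi <- 0.45 * fov

    # physical coordinates of voxel centres, origin at grid centre
    cx <- (seq_len(d[1]) - 1) * sp[1] - half[1] + sp[1] / 2
    cy <- (seq_len(d[2]) - 1) * sp[2] - half[2] + sp[2] / 2
    cz <- (seq_len(d[3]) - 1) * sp[3] - half[3] + sp[3] / 2

    # smooth head: soft ellipsoid edge between radial coords 0.95 and 1.05
    rx2 <- (cx / head_semi[1])^2
    ry2 <- (cy / head_semi[2])^2
    rz2 <- (cz / head_semi[3])^2
    r2 <- outer(outer(rx2, ry2, `+`), rz2, `+`)
    r <- sqrt(r2)
    tflat <- pmin(pmax((1.05 - r) / 0.1, 0), 1)
    head <- 0.05 + 0.95 * (tflat * tflat * (3 - 2 * tflat))

    # multiplicative low-frequency bias: a few random low-order cosine modes
    bias <- 1
    if (cfg$bias_field_amplitude > 0) {
      f <- array(0, d)
      ug <- list((seq_len(d[1]) - 1) / d[1], (seq_len(d[2]) - 1) / d[2],
                 (seq_len(d[3]) - 1) / d[3])
      for (q in 1:3) {
        k <- sample(0:2, 3, replace = TRUE)
        ph <- runif(3, 0, 2 * pi)
        amp <- runif(1, 0.3, 1)
        gx <- cos(2 * pi * k[1] * ug[[1]] + ph[1])
        gy <- cos(2 * pi * k[2] * ug[[2]] + ph[2])
        gz <- cos(2 * pi * k[3] * ug[[3]] + ph[3])
        f <- f + amp * outer(outer(gx, gy), gz)
      }
      f <- f / max(abs(f), 1e-12)
      bias <- 1 + cfg$bias_field_amplitude * f
    }

    # tumor geometry
    target_v <- exp(runif(1, log(cfg$tumor_volume_range[1]),
                          log(cfg$tumor_volume_range[2]))) # cm^3
    target_mm3 <- target_v * 1000
    r0 <- (3 * target_mm3 / (4 * pi))^(1 / 3)
    aniso <- exp(runif(3, -0.25, 0.25))
    aniso <- aniso / prod(aniso)^(1 / 3)
    pert <- runif(6, -0.12, 0.12) # lobulation coefficients
    extent <- max(r0 * aniso) * 1.15
    if (extent >= min(head_semi)) {
      stop("requested tumor cannot fit in the phantom grid (volume ",
           signif(target_v, 3), " cm^3)", call. = FALSE)
    }
    off_box <- pmax(head_semi * 0.75 - extent, 0)
    centre <- runif(3, -1, 1) * off_box
    cystic <- runif(1) < cfg$cystic_fraction

    tumor_indicator <- function(scale) {
      semi <- r0 * aniso * scale
      bb_lo <- pmax(ceiling((centre - 1.2 * max(semi) + half) / sp), 1)
      bb_hi <- pmin(floor((centre + 1.2 * max(semi) + half) / sp) + 1, d)
      ix <- bb_lo[1]:bb_hi[1]; iy <- bb_lo[2]:bb_hi[2]; iz <- bb_lo[3]:bb_hi[3]
      px <- cx[ix] - centre[1]; py <- cy[iy] - centre[2]; pz <- cz[iz] - centre[3]
      nx <- length(ix); ny <- length(iy); nz <- length(iz)
      X <- array(px, c(nx, ny, nz))
      Y <- aperm(array(py, c(ny, nx, nz)), c(2, 1, 3))
      Z <- aperm(array(pz, c(nz, nx, ny)), c(2, 3, 1))
      rad <- sqrt(X^2 + Y^2 + Z^2)
      rad[rad == 0] <- 1e-9
      n1 <- X / rad; n2 <- Y / rad; n3 <- Z / rad
      # smooth quadratic-harmonic lobulation of the radius
      g <- pert[1] * (n1^2 - 1 / 3) + pert[2] * (n2^2 - 1 / 3) +
        pert[3] * (n3^2 - 1 / 3) + pert[4] * n1 * n2 +
        pert[5] * n1 * n3 + pert[6] * n2 * n3
      rho <- sqrt((X / semi[1])^2 + (Y / semi[2])^2 + (Z / semi[3])^2)
      list(inside = rho <= 1 + g, ix = ix, iy = iy, iz = iz,
           rho = rho, g = g)
    }

    # correct the ellipsoid scale so the voxelized volume matches the draw
    scale <- 1
    for (it in 1:3) {
      ti <- tumor_indicator(scale)
      nvox <- sum(ti$inside)
      if (nvox == 0) { scale <- scale * 1.5; next }
      vreal <- nvox * prod(sp)
      scale <- scale * (target_mm3 / vreal)^(1 / 3)
    }
    ti <- tumor_indicator(scale)
    nvox <- sum(ti$inside)
    if (nvox == 0) {
      stop("requested tumor volume too small to voxelize on this grid",
           call. = FALSE)
    }

    mask <- array(0, d)
    sub <- array(0, dim(ti$inside))
    sub[ti$inside] <- 1
    mask[ti$ix, ti$iy, ti$iz] <- pmax(mask[ti$ix, ti$iy, ti$iz], sub)

    img <- head * bias
    block <- img[ti$ix, ti$iy, ti$iz]
    tum <- block * cfg$enhancement_contrast
    if (cystic) {
      core <- ti$rho <= 0.55 * (1 + ti$g)
      tum[core] <- block[core] * 0.4
    }
    block[ti$inside] <- tum[ti$inside]
    img[ti$ix, ti$iy, ti$iz] <- block

    if (cfg$noise_sigma > 0) {
      img <- img + array(stats::rnorm(prod(d), 0, cfg$noise_sigma), d)
    }

    list(image = image_volume(img, sp),
         mask = mask_volume(mask, sp),
         meta = list(target_volume_cm3 = target_v,
                     realized_volume_cm3 = nvox * prod(sp) / 1000,
                     cystic = cystic,
                     centre_mm = centre))
  })
}

#' Generate a phantom cohort on disk
#'
#' Writes `n` image/mask NIfTI pairs (`<case>_img.nii.gz`,
#' `<case>_mask.nii.gz`) plus a CSV manifest. Per-case seeds are derived
#' deterministically from `cfg$seed` and the case index, so rerunning with
#' the same configuration reproduces identical files and extending a cohort
#' never reshuffles existing cases.
#'
#' @param n Number of cases.
#' @param cfg A [phantom_config()].
#' @param out_dir Output directory (created if missing).
#' @return The manifest data frame (case id, seed, tumor volume in cm^3,
#'   cystic flag, file names), invisibly written to `manifest.csv`.
#' @export
generate_cohort <- function(n, cfg, out_dir) {
  stopifnot(inherits(cfg, "phantom_config"), n >= 1)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("case%03d", i)
    seed_i <- case_seed_for(cfg$seed, i)
    ph <- generate_phantom(cfg, seed_i)
    img_file <- paste0(id, "_img.nii.gz")
    mask_file <- paste0(id, "_mask.nii.gz")
    write_volume(ph$image, file.path(out_dir, img_file))
    write_volume(ph$mask, file.path(out_dir, mask_file))
    rows[[i]] <- data.frame(case_id = id, seed = seed_i,
                            volume_cm3 = ph$meta$realized_volume_cm3,
                            cystic = ph$meta$cystic,
                            image = img_file, mask = mask_file,
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
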
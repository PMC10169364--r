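test_that("DSC reproduces analytic overlap values", {
  sp <- c(1, 1, 1)
  a <- cube_mask(c(8, 8, 8), c(2, 2, 2), 2, sp)
  expect_equal(dsc(a, a), 1.0)
  b <- cube_mask(c(8, 8, 8), c(6, 6, 6), 2, sp)
  expect_equal(dsc(a, b), 0.0)
  # 2x2x2 cube shifted one voxel: |A|=|B|=8, |A n B|=4 -> 0.5
  shifted <- cube_mask(c(8, 8, 8), c(3, 2, 2), 2, sp)
  expect_equal(dsc(a, shifted), 0.5)
  expect_equal(dsc(shifted, a), 0.5)
  empty <- mask_volume(array(0, c(8, 8, 8)), sp)
  expect_error(dsc(empty, empty), "empty")
})

test_that("surface voxels are the 6-neighbourhood border", {
  one <- array(0, c(5, 5, 5))
  one[3, 3, 3] <- 1
  expect_equal(unname(surface_voxels(mask_volume(one))[1, ]), c(3, 3, 3))
  # solid 3-cube: 26 of 27 voxels are border
  solid <- cube_mask(c(7, 7, 7), c(3, 3, 3), 3)
  sv <- surface_voxels(solid)
  expect_equal(nrow(sv), 26)
  expect_false(any(sv[, 1] == 4 & sv[, 2] == 4 & sv[, 3] == 4))
  # a 1-voxel-thick slab is all border (top face touches background)
  slab <- array(0, c(6, 6, 6))
  slab[, , 2] <- 1
  expect_equal(nrow(surface_voxels(mask_volume(slab))), 36)
  # foreground on the array boundary counts as border
  edge <- array(1, c(1, 3, 3))
  expect_equal(nrow(surface_voxels(mask_volume(edge))), 9)
  expect_error(surface_voxels(mask_volume(array(0, c(3, 3, 3)))), "empty")
})

test_that("single-voxel pairs give exact point distances", {
  sp <- c(1, 1, 1)
  a <- array(0, c(9, 9, 9)); a[2, 2, 2] <- 1
  b <- array(0, c(9, 9, 9)); b[5, 2, 2] <- 1
  am <- mask_volume(a, sp); bm <- mask_volume(b, sp)
  expect_equal(hd95(am, bm), 3.0)
  expect_equal(assd(am, bm), 3.0)
  expect_equal(hd95(am, am), 0)
  expect_equal(assd(am, am), 0)
  # anisotropic spacing scales the axis
  am2 <- mask_volume(a, c(0.8, 0.8, 1)); bm2 <- mask_volume(b, c(0.8, 0.8, 1))
  expect_equal(hd95(am2, bm2), 2.4)
  empty <- mask_volume(array(0, c(9, 9, 9)), sp)
  expect_error(hd95(am, empty), "empty")
  expect_error(assd(empty, am), "empty")
})

test_that("surface distances match the all-pairs brute-force oracle", {
  set.seed(31)
  for (i in 1:50) {
    dims <- sample(6:12, 3, replace = TRUE)
    sp <- round(runif(3, 0.5, 2), 2)
    a <- random_blob_mask(dims)
    b <- random_blob_mask(dims)
    am <- mask_volume(a, sp)
    bm <- mask_volume(b, sp)
    expect_equal(hd95(am, bm), brute_hd95(a, b, sp), tolerance = 1e-9)
    expect_equal(assd(am, bm), brute_assd(a, b, sp), tolerance = 1e-9)
  }
})

test_that("distance metrics are symmetric; spacing scales them linearly", {
  set.seed(32)
  dims <- c(10, 10, 10)
  a <- random_blob_mask(dims)
  b <- random_blob_mask(dims)
  sp <- c(0.8, 0.8, 1)
  am <- mask_volume(a, sp); bm <- mask_volume(b, sp)
  expect_equal(hd95(am, bm), hd95(bm, am))
  expect_equal(assd(am, bm), assd(bm, am))
  s <- 2.5
  am2 <- mask_volume(a, sp * s); bm2 <- mask_volume(b, sp * s)
  expect_equal(hd95(am2, bm2), s * hd95(am, bm), tolerance = 1e-12)
  expect_equal(assd(am2, bm2), s * assd(am, bm), tolerance = 1e-12)
  expect_equal(dsc(am2, bm2), dsc(am, bm))
  expect_equal(ravd(am2, bm2), ravd(am, bm))
})

test_that("RAVD reproduces hand arithmetic and flags total misses", {
  sp <- c(1, 1, 1)
  gt <- array(0, c(6, 6, 6)); gt[1:10] <- 1
  pr <- array(0, c(6, 6, 6)); pr[1:8] <- 1
  expect_equal(ravd(mask_volume(pr, sp), mask_volume(gt, sp)), 0.2)
  expect_equal(ravd(mask_volume(gt, sp), mask_volume(gt, sp)), 0)
  empty <- mask_volume(array(0, c(6, 6, 6)), sp)
  expect_equal(ravd(empty, mask_volume(gt, sp)), 1.0)
  expect_error(ravd(mask_volume(gt, sp), empty), "empty")
})

test_that("dilating a perfect prediction degrades dsc and ravd strictly", {
  m <- cube_mask(c(10, 10, 10), c(4, 4, 4), 3)
  dil <- m$voxels
  fg <- which(m$voxels == 1, arr.ind = TRUE)
  for (r in seq_len(nrow(fg))) {
    for (ax in 1:3) for (dd in c(-1, 1)) {
      nb <- fg[r, ]; nb[ax] <- nb[ax] + dd
      if (all(nb >= 1 & nb <= 10)) dil[nb[1], nb[2], nb[3]] <- 1
    }
  }
  dm <- mask_volume(dil)
  expect_lt(dsc(dm, m), 1)
  expect_gt(ravd(dm, m), 0)
})

test_that("cohort evaluation stratifies, aggregates, and excludes misses", {
  sp <- c(1, 1, 1)
  mk_vol <- function(n_vox, dims = c(24, 24, 24)) {
    m <- array(0, dims)
    m[seq_len(n_vox)] <- 1
    mask_volume(m, sp)
  }
  # gt volumes 0.05, 0.5, 7.0 cm^3 -> 50, 500, 7000 voxels at 1 mm^3
  gts <- list(mk_vol(50), mk_vol(500), mk_vol(7000))
  perfect <- lapply(gts, function(g) list(pred = g, gt = g))
  rep1 <- evaluate_cohort(perfect)
  s <- rep1$summary
  overall <- s[s$stratum == "all", ]
  expect_equal(overall$mean[overall$metric == "dsc"], 1.0)
  expect_equal(overall$mean[overall$metric == "hd95_mm"], 0.0)
  expect_equal(overall$mean[overall$metric == "assd_mm"], 0.0)
  expect_equal(rep1$n_detected, 3)
  expect_setequal(as.character(unique(rep1$per_case$stratum)),
                  c("<0.1", "0.1-6", ">6"))

  # one missed tumor among five perfect cases
  gt5 <- lapply(c(100, 200, 300, 400, 500), mk_vol)
  pairs <- lapply(gt5, function(g) list(pred = g, gt = g))
  pairs[[3]]$pred <- mk_vol(0)
  rep2 <- evaluate_cohort(pairs)
  expect_equal(rep2$n_detected, 4)
  s2 <- rep2$summary
  expect_equal(s2$n[s2$stratum == "all" & s2$metric == "hd95_mm"], 4L)
  expect_equal(s2$n[s2$stratum == "all" & s2$metric == "dsc"], 5L)
  pc3 <- rep2$per_case[3, ]
  expect_false(pc3$detected)
  expect_equal(pc3$dsc, 0)
  expect_equal(pc3$ravd, 1)
  expect_true(is.na(pc3$hd95_mm))
})
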
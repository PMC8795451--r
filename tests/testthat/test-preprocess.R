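test_that("clip_and_scale maps the lung window onto [0, 255]", {
  v <- volume(array(c(-1200, 600, -300, -2000, 1000, 0), c(6, 1, 1)))
  out <- clip_and_scale(v)
  expect_equal(out$voxels[, 1, 1],
               c(0, 255, 127.5, 0, 255, (1200 / 1800) * 255))
  expect_identical(out$unit, "normalized_0_255")
  expect_error(clip_and_scale(out), "HU")
})

test_that("clip_and_scale is monotone and idempotent on clipped data", {
  set.seed(3)
  x <- sort(runif(100, -3000, 2000))
  v <- volume(array(x, c(100, 1, 1)))
  y <- clip_and_scale(v)$voxels
  expect_true(all(diff(as.vector(y)) >= 0))
  # idempotence: rescaling the already-clipped HU data changes nothing
  clipped <- volume(array(pmin(pmax(x, -1200), 600), c(100, 1, 1)))
  expect_equal(clip_and_scale(clipped)$voxels, y)
})

test_that("segment_lung covers the phantom lungs (Dice >= 0.9)", {
  ph <- generate_phantom(phantom_spec(seed = 5))
  m <- segment_lung(ph$volume)
  gt <- ph$lung_mask$voxels
  dice <- 2 * sum(m$voxels & gt) / (sum(m$voxels) + sum(gt))
  expect_gte(dice, 0.9)
  # mask covers >= 95% of the true lung voxels
  expect_gte(sum(m$voxels & gt) / sum(gt), 0.95)
  # every nodule center lies inside the (dilated) mask
  va <- nodulemsa:::annotations_to_voxel(ph$volume, ph$annotations)
  idx <- cbind(round(va$vz) + 1, round(va$vy) + 1, round(va$vx) + 1)
  expect_true(all(m$voxels[idx]))
})

test_that("an all-tissue volume yields an empty mask with a warning", {
  v <- volume(array(40, c(24, 24, 24)))
  m <- segment_lung(v)
  expect_false(any(m$voxels))
  expect_match(m$warning, "no lung")
})

test_that("apply_mask_and_crop preserves world positions and pads outside", {
  ph <- desk_phantom()
  vol <- clip_and_scale(ph$volume)
  m <- segment_lung(ph$volume)
  out <- apply_mask_and_crop(vol, m, pad_value = 170)
  # same voxel content at annotation world positions before/after cropping
  va_old <- round(world_to_voxel(vol, cbind(ph$annotations$x,
                                            ph$annotations$y,
                                            ph$annotations$z)))
  va_new <- round(world_to_voxel(out, cbind(ph$annotations$x,
                                            ph$annotations$y,
                                            ph$annotations$z)))
  for (i in seq_len(nrow(va_old))) {
    expect_equal(out$voxels[va_new[i, 1] + 1, va_new[i, 2] + 1, va_new[i, 3] + 1],
                 vol$voxels[va_old[i, 1] + 1, va_old[i, 2] + 1, va_old[i, 3] + 1])
  }
  # a voxel outside the mask is exactly the pad value
  outside <- which(!m$voxels, arr.ind = TRUE)[1, ]
  w <- voxel_to_world(vol, outside - 1)
  vn <- round(world_to_voxel(out, w))
  if (all(vn >= 0 & vn < dim(out$voxels)))
    expect_equal(out$voxels[vn[1] + 1, vn[2] + 1, vn[3] + 1], 170)
})

test_that("an all-ones mask makes cropping an identity up to margin", {
  v <- volume(array(runif(8^3), c(8, 8, 8)), unit = "normalized_0_255")
  m <- lung_mask(array(TRUE, c(8, 8, 8)))
  out <- apply_mask_and_crop(v, m, margin = 2)
  expect_identical(out$voxels, v$voxels)
  expect_identical(out$origin, v$origin)
  expect_error(apply_mask_and_crop(v, lung_mask(array(TRUE, c(4, 4, 4)))),
               "shapes differ")
})

test_that("resample_isotropic preserves shape on 1mm input and constants", {
  v <- volume(array(rnorm(10^3), c(10, 10, 10)), spacing = c(1, 1, 1))
  expect_identical(dim(resample_isotropic(v, 1)$voxels), c(10L, 10L, 10L))
  cv <- volume(array(7, c(6, 8, 10)), spacing = c(2, 1.5, 1.25))
  out <- resample_isotropic(cv, 1)
  expect_equal(dim(out$voxels), c(12, 12, 12))
  expect_true(all(abs(out$voxels - 7) < 1e-12))
})

test_that("a 20mm sphere on 2.5mm slices resamples to 20 +- 2 mm along z", {
  d <- c(24, 60, 60)                       # (z,y,x), 2.5mm slices
  sp <- c(2.5, 1, 1)
  ctr <- (d - 1) / 2
  z <- (seq_len(d[1]) - 1 - ctr[1]) * sp[1]
  y <- (seq_len(d[2]) - 1 - ctr[2]) * sp[2]
  x <- (seq_len(d[3]) - 1 - ctr[3]) * sp[3]
  r <- sqrt(outer(outer(z^2, y^2, "+"), x^2, "+"))
  v <- volume(array(ifelse(r <= 10, 100, -1000), dim = d), spacing = sp)
  out <- resample_isotropic(v, 1)
  ctr_v <- round(world_to_voxel(out, c(ctr[3] * 1, ctr[2] * 1, ctr[1] * 2.5)))
  prof <- out$voxels[, ctr_v[2] + 1, ctr_v[3] + 1]
  measured <- sum(prof > -450)             # half-contrast threshold
  expect_gte(measured, 18)
  expect_lte(measured, 22)
})

test_that("crop_patch obeys the center-inside ownership rule and pads", {
  v <- volume(array(runif(16^3, 0, 255), c(16, 16, 16)),
              unit = "normalized_0_255")
  # identity crop
  cp <- crop_patch(v, c(8, 8, 8), 16)
  expect_equal(cp$patch, v$voxels)
  # boundary ownership: center inside vs outside
  ann <- tibble::tibble(vz = c(3.9, 4.0, 11.9, 12.0), vy = rep(8, 4),
                        vx = rep(8, 4), diameter = rep(6, 4))
  cp <- crop_patch(v, c(8, 8, 8), 8, annotations = ann)
  expect_equal(nrow(cp$annotations), 2)    # 4.0 and 11.9 are inside [0, 8)
  expect_equal(cp$annotations$vz, c(0, 7.9))
  # pad fill at the volume edge
  cp <- crop_patch(v, c(0, 0, 0), 8, pad_value = 170)
  expect_true(all(cp$patch[1:3, , ] == 170))
  expect_equal(cp$patch[5, 5, 5], v$voxels[1, 1, 1])
})
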
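test_that("phantom generation is bit-identical for a fixed seed", {
  s <- desk_phantom_spec(seed = 42)
  a <- generate_phantom(s)
  b <- generate_phantom(s)
  expect_identical(a$volume$voxels, b$volume$voxels)
  expect_identical(a$annotations, b$annotations)
  expect_identical(a$lung_mask$voxels, b$lung_mask$voxels)
})

test_that("a zero-nodule spec still has lungs but no annotations", {
  ph <- generate_phantom(desk_phantom_spec(seed = 2, n_nodules = 0))
  expect_equal(nrow(ph$annotations), 0)
  expect_gt(sum(ph$lung_mask$voxels), 1000)
})

test_that("requested diameters are echoed exactly in the annotations", {
  spec <- phantom_spec(shape = c(120, 110, 110),
                       diameters = c(4, 6, 8, 10, 15, 22), seed = 9,
                       n_vessels = 2)
  ph <- generate_phantom(spec)
  expect_equal(nrow(ph$annotations), 6)
  expect_setequal(ph$annotations$diameter, c(4, 6, 8, 10, 15, 22))
})

test_that("nodule centers are in-lung and pairwise separated", {
  ph <- desk_phantom(seed = 12)
  va <- nodulemsa:::annotations_to_voxel(ph$volume, ph$annotations)
  idx <- cbind(round(va$vz) + 1, round(va$vy) + 1, round(va$vx) + 1)
  expect_true(all(ph$lung_mask$voxels[idx]))
  n <- nrow(va)
  if (n >= 2) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      sep <- sqrt(sum((c(va$vz[i], va$vy[i], va$vx[i]) -
                         c(va$vz[j], va$vy[j], va$vx[j]))^2))
      expect_gte(sep, max(va$diameter[i], va$diameter[j]) - 1e-9)
    }
  }
})

test_that("rendered nodule FWHM matches the annotated diameter within 1 mm", {
  spec <- desk_phantom_spec(seed = 21, n_nodules = 1)
  spec$noise_sd <- 0          # measure the clean radial profile
  ph <- generate_phantom(spec)
  va <- nodulemsa:::annotations_to_voxel(ph$volume, ph$annotations)
  ctr <- c(va$vz[1], va$vy[1], va$vx[1])
  R <- va$diameter[1] / 2
  d <- dim(ph$volume$voxels)
  # spherically averaged radial profile in 0.25 mm shells
  ext <- ceiling(R + 3)
  iz <- max(0, floor(ctr[1] - ext)):min(d[1] - 1, ceiling(ctr[1] + ext))
  iy <- max(0, floor(ctr[2] - ext)):min(d[2] - 1, ceiling(ctr[2] + ext))
  ix <- max(0, floor(ctr[3] - ext)):min(d[3] - 1, ceiling(ctr[3] + ext))
  r <- sqrt(outer(outer((iz - ctr[1])^2, (iy - ctr[2])^2, "+"),
                  (ix - ctr[3])^2, "+"))
  vals <- ph$volume$voxels[iz + 1, iy + 1, ix + 1]
  shells <- cut(r, seq(0, ext, by = 0.25))
  prof <- tapply(vals, shells, mean)
  mids <- seq(0.125, ext - 0.125, by = 0.25)[seq_along(prof)]
  ok <- !is.na(prof)
  prof <- prof[ok]; mids <- mids[ok]
  peak <- max(prof); base <- -850
  half <- base + (peak - base) / 2
  fwhm_r <- mids[max(which(prof >= half))]
  expect_lt(abs(2 * fwhm_r - va$diameter[1]), 1)
})

test_that("solid nodules carry >= 200 HU contrast against lung", {
  spec <- desk_phantom_spec(seed = 23, n_nodules = 2)
  spec$noise_sd <- 0
  ph <- generate_phantom(spec)
  va <- nodulemsa:::annotations_to_voxel(ph$volume, ph$annotations)
  for (i in seq_len(nrow(va))) {
    center_val <- ph$volume$voxels[round(va$vz[i]) + 1, round(va$vy[i]) + 1,
                                   round(va$vx[i]) + 1]
    expect_gte(center_val - (-850), 200)
  }
})

test_that("generate_dataset writes scans, pooled CSV and a stable manifest", {
  dir1 <- file.path(tempdir(), "phantoms1")
  dir2 <- file.path(tempdir(), "phantoms2")
  spec <- desk_phantom_spec()
  m1 <- generate_dataset(3, dir1, spec, seed = 5)
  m2 <- generate_dataset(3, dir2, spec, seed = 5)
  expect_length(list.files(dir1, pattern = "\\.mhd$"), 3)
  ann <- read_annotations(file.path(dir1, "annotations.csv"))
  expect_equal(nrow(ann), sum(m1$n_nodules))
  # same seed -> identical manifest and annotations
  expect_identical(readLines(file.path(dir1, "manifest.csv")),
                   readLines(file.path(dir2, "manifest.csv")))
  expect_identical(readLines(file.path(dir1, "annotations.csv")),
                   readLines(file.path(dir2, "annotations.csv")))
  # a written scan reads back with matching annotations in-lung
  v <- read_metaimage(file.path(dir1, m1$file[1]))
  expect_equal(dim(v$voxels), c(96, 96, 96))
})
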
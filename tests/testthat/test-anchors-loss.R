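test_that("iou3d matches hand geometry and the voxel-counting oracle", {
  expect_equal(iou3d(c(0, 0, 0), 10, c(0, 0, 0), 10), 1.0)
  expect_equal(iou3d(c(0, 0, 0), 10, c(30, 0, 0), 10), 0.0)
  # side-10 cubes offset 5 along one axis: 500 / 1500 = 1/3
  expect_equal(iou3d(c(0, 0, 0), 10, c(5, 0, 0), 10), 1 / 3)
  set.seed(20)
  for (i in 1:50) {
    ca <- runif(3, -10, 10); cb <- ca + runif(3, -8, 8)
    da <- runif(1, 4, 12); db <- runif(1, 4, 12)
    expect_lt(abs(iou3d(ca, da, cb, db) -
                    iou3d_voxel_oracle(ca, da, cb, db)), 0.01)
  }
  # symmetry and bounds
  set.seed(21)
  for (i in 1:20) {
    ca <- runif(3, 0, 5); cb <- runif(3, 0, 5)
    da <- runif(1, 1, 8); db <- runif(1, 1, 8)
    a <- iou3d(ca, da, cb, db); b <- iou3d(cb, db, ca, da)
    expect_equal(a, b)
    expect_gte(a, 0); expect_lte(a, 1)
  }
})

test_that("assign_labels applies the 0.5 / 0.02 thresholds and force-match", {
  grid <- anchor_grid(8, 4, c(5, 10, 20))
  # anchor exactly equal to a nodule box -> positive
  ann <- tibble::tibble(vz = grid$centers[4], vy = grid$centers[4],
                        vx = grid$centers[4], diameter = 10)
  lab <- assign_labels(grid, ann)
  expect_equal(lab$p_star[4, 4, 4, 2], 1)
  # empty annotation list -> all anchors negative
  lab0 <- assign_labels(grid, ann[0, ])
  expect_true(all(lab0$p_star == 0))
  # partition: positives, negatives and ignored cover all anchors
  ann2 <- tibble::tibble(vz = 13, vy = 17, vx = 9, diameter = 7)
  lab2 <- assign_labels(grid, ann2)
  n <- length(lab2$p_star)
  expect_equal(sum(lab2$p_star == 1, na.rm = TRUE) +
                 sum(lab2$p_star == 0, na.rm = TRUE) +
                 sum(is.na(lab2$p_star)), n)
  # intermediate IoU -> ignored (unless force-matched)
  forced <- which(lab2$p_star == 1)
  mid <- setdiff(which(lab2$best_iou >= 0.02 & lab2$best_iou <= 0.5), forced)
  expect_true(all(is.na(lab2$p_star[mid])))
  # a small nodule still gets a positive anchor through force-match
  ann3 <- tibble::tibble(vz = 10, vy = 10, vx = 10, diameter = 3)
  lab3 <- assign_labels(grid, ann3)
  expect_gte(sum(lab3$p_star == 1, na.rm = TRUE), 1)
  lab3n <- assign_labels(grid, ann3, force_match = FALSE)
  expect_equal(sum(lab3n$p_star == 1, na.rm = TRUE), 0)
})

test_that("box encoding matches the parameterization and inverts exactly", {
  expect_equal(encode_box(c(0, 0, 0), 10, c(0, 0, 0), 10), c(0, 0, 0, 0))
  expect_equal(encode_box(c(5, 0, 0), 20, c(0, 0, 0), 10),
               c(0.5, 0, 0, log(2)))
  set.seed(22)
  for (i in 1:100) {
    ctr <- runif(3, -50, 50); d <- runif(1, 2, 30)
    ac <- runif(3, -50, 50); ad <- sample(c(5, 10, 20), 1)
    dec <- decode_box(encode_box(ctr, d, ac, ad), ac, ad)
    expect_lt(max(abs(dec$center - ctr)), 1e-9)
    expect_lt(abs(dec$diameter - d), 1e-9)
  }
  expect_error(encode_box(c(0, 0, 0), -1, c(0, 0, 0), 10), "positive")
})

test_that("classification loss matches the closed forms", {
  expect_equal(classification_loss(0.5, 1), log(2))
  expect_equal(classification_loss(0.5, 0), log(2))
  expect_equal(classification_loss(0.9, 0), -log(0.1))
  expect_lt(classification_loss(1 - 1e-7, 1), 1e-6)
  expect_true(all(classification_loss(runif(20), rbinom(20, 1, 0.5)) >= 0))
})

test_that("smooth L1 matches its fixtures and is continuous at the switch", {
  expect_equal(smooth_l1(rep(0, 4), rep(0, 4)), 0)
  expect_equal(smooth_l1(c(0.5, 0, 0, 0), rep(0, 4)), 0.125)
  expect_equal(smooth_l1(c(2, 0, 0, 0), rep(0, 4)), 1.5)
  eps <- 1e-9
  below <- smooth_l1(c(1 - eps, 0, 0, 0), rep(0, 4))
  above <- smooth_l1(c(1 + eps, 0, 0, 0), rep(0, 4))
  expect_lt(abs(below - above), 1e-6)
})

test_that("multitask loss handles negatives, positives and ignores", {
  # one negative anchor at p = 0.5 -> lambda * ln 2
  expect_equal(multitask_loss(0.5, rep(0, 4), 0, rep(0, 4)), 0.5 * log(2))
  # perfect positive -> ~0
  expect_lt(multitask_loss(1 - 1e-7, c(0.1, 0, 0, 0), 1, c(0.1, 0, 0, 0)), 1e-6)
  # all ignored -> 0
  expect_equal(multitask_loss(c(0.3, 0.7), matrix(1, 2, 4),
                              c(NA, NA), matrix(0, 2, 4)), 0)
  # regression only on positives
  l <- multitask_loss(c(0.5, 0.5), rbind(c(2, 0, 0, 0), c(2, 0, 0, 0)),
                      c(1, 0), matrix(0, 2, 4))
  expect_equal(l, 0.5 * log(2) + 1.5)
})

test_that("multitask loss gradients match finite differences within 1e-4", {
  set.seed(23)
  n <- 6
  p <- runif(n, 0.2, 0.8)
  t <- matrix(rnorm(n * 4, sd = 0.8), n, 4)
  p_star <- c(1, 1, 0, 0, NA, 0)
  t_star <- matrix(rnorm(n * 4, sd = 0.8), n, 4)
  gr <- multitask_loss_grad(p, t, p_star, t_star)
  eps <- 1e-6
  for (i in seq_len(n)) {
    pp <- p; pp[i] <- pp[i] + eps
    pm <- p; pm[i] <- pm[i] - eps
    fd <- (multitask_loss(pp, t, p_star, t_star) -
             multitask_loss(pm, t, p_star, t_star)) / (2 * eps)
    expect_lt(abs(fd - gr$dp[i]) / max(1e-4, abs(fd)), 1e-4)
    for (j in 1:4) {
      tp <- t; tp[i, j] <- tp[i, j] + eps
      tm <- t; tm[i, j] <- tm[i, j] - eps
      fd <- (multitask_loss(p, tp, p_star, t_star) -
               multitask_loss(p, tm, p_star, t_star)) / (2 * eps)
      expect_lt(abs(fd - gr$dt[i, j]) / max(1e-4, abs(fd)), 1e-4)
    }
  }
})
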
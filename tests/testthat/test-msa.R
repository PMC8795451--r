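fwd <- nodulemsa:::nn_forward
bwd <- nodulemsa:::nn_backward

test_that("preact_conv: zero input and frozen seams match a plain convolution", {
  set.seed(1)
  pc <- layer_preact_conv(1, 2, k = 3)
  x0 <- array(0, c(5, 5, 5, 1))
  expect_equal(fwd(pc, x0, training = FALSE), array(0, c(5, 5, 5, 2)))
  # spatial shape preserved for arbitrary dims
  x <- array(rnorm(3 * 4 * 6), c(3, 4, 6, 1))
  expect_equal(dim(fwd(pc, x)), c(3, 4, 6, 2))
  # with BN frozen to identity and ReLU bypassed, equals the brute-force
  # convolution oracle
  pc$children$bn$identity <- TRUE
  pc$children$relu$bypass <- TRUE
  x <- array(rnorm(4^3), c(4, 4, 4, 1))
  expect_equal(fwd(pc, x), conv3d_oracle(x, pc$children$conv$W, 1),
               tolerance = 1e-12)
})

test_that("res2net with identity filters unrolls the split-transform exactly", {
  set.seed(2)
  r <- layer_res2net(32, identity_filters = TRUE)
  x <- array(rnorm(3 * 3 * 3 * 32), c(3, 3, 3, 32))
  y <- fwd(r, x)
  g <- function(i) x[, , , ((i - 1) * 8 + 1):(i * 8), drop = FALSE]
  expected <- array(0, dim(x))
  expected[, , , 1:8] <- g(1)
  expected[, , , 9:16] <- g(2)
  expected[, , , 17:24] <- g(2) + g(3)
  expected[, , , 25:32] <- g(2) + g(3) + g(4)
  expect_equal(y, expected, tolerance = 1e-14)
})

test_that("res2net splits 32 channels into four 8-channel subsets", {
  r <- layer_res2net(32)
  expect_equal(r$m, 8)
  x <- array(rnorm(2 * 2 * 2 * 32), c(2, 2, 2, 32))
  expect_equal(dim(fwd(r, x, training = TRUE)), dim(x))
  expect_error(layer_res2net(30), "divisible")
  # zero input with bias-free filters -> zero output (BN of zeros is zero)
  nodulemsa:::set_bn_identity(r)
  expect_equal(fwd(r, array(0, c(2, 2, 2, 32))), array(0, c(2, 2, 2, 32)))
})

test_that("z_pool stacks [max, mean] over channels", {
  x <- array(c(1, 2, 3), c(1, 1, 1, 3))
  expect_equal(z_pool(x)[1, 1, 1, ], c(3, 2))
  # single channel: both outputs equal the input
  x1 <- array(rnorm(27), c(3, 3, 3, 1))
  zp <- z_pool(x1)
  expect_equal(zp[, , , 1], x1[, , , 1])
  expect_equal(zp[, , , 2], x1[, , , 1])
  # constant input c -> both channels c
  xc <- array(4.2, c(2, 2, 2, 5))
  expect_true(all(z_pool(xc) == 4.2))
  # channel 1 (max) >= channel 2 (mean) always
  xr <- array(rnorm(3 * 3 * 3 * 6), c(3, 3, 3, 6))
  zr <- z_pool(xr)
  expect_true(all(zr[, , , 1] >= zr[, , , 2]))
})

test_that("cqam branch and module reduce to 0.5 x input with zeroed convs", {
  set.seed(3)
  x <- array(rnorm(3 * 4 * 5 * 8), c(3, 4, 5, 8))
  for (b in 1:4) {
    br <- layer_cqam_branch(b, k = 3)
    nodulemsa:::zero_weights(br)
    nodulemsa:::set_bn_identity(br)
    expect_equal(fwd(br, x), 0.5 * x, tolerance = 1e-12)
    expect_equal(dim(fwd(layer_cqam_branch(b, k = 3), x, training = TRUE)),
                 dim(x))
  }
  m <- layer_cqam(k = 3)
  nodulemsa:::zero_weights(m)
  nodulemsa:::set_bn_identity(m)
  expect_equal(fwd(m, x), 0.5 * x, tolerance = 1e-12)
  # multiplicative attention: zero input -> zero output
  m2 <- layer_cqam(k = 3)
  expect_equal(fwd(m2, array(0, dim(x)), training = TRUE), array(0, dim(x)))
})

test_that("cqam parameter count is 4(2k^3 + 2), independent of channels", {
  expect_equal(count_parameters(layer_cqam(7))$trainable_count, 2752)
  expect_equal(count_parameters(layer_cqam(3))$trainable_count,
               4 * (2 * 27 + 2))
  # independence of channel count: the module has no channel-sized weights
  x8 <- array(rnorm(2 * 2 * 2 * 8), c(2, 2, 2, 8))
  x32 <- array(rnorm(2 * 2 * 2 * 32), c(2, 2, 2, 32))
  m <- layer_cqam(7)
  invisible(fwd(m, x8, training = TRUE))
  invisible(fwd(m, x32, training = TRUE))
  expect_equal(count_parameters(m)$trainable_count, 2752)
})

test_that("cqam attention is bounded: |output| <= |input| with identity BN", {
  set.seed(4)
  m <- layer_cqam(k = 3)
  nodulemsa:::set_bn_identity(m)
  x <- array(rnorm(3 * 3 * 3 * 4), c(3, 3, 3, 4))
  y <- fwd(m, x)
  expect_true(all(abs(y) <= abs(x) + 1e-12))
})

test_that("msa_block is a residual identity under zeroed weights", {
  set.seed(5)
  b <- msa_block(8, 8, k_att = 3)
  nodulemsa:::zero_weights(b)
  nodulemsa:::set_bn_identity(b)
  x <- array(rnorm(4 * 4 * 4 * 8), c(4, 4, 4, 8))
  expect_equal(fwd(b, x), x, tolerance = 1e-12)
  # spatial dims preserved, channel change via projection shortcut
  b2 <- msa_block(4, 8, k_att = 3)
  expect_equal(dim(fwd(b2, array(rnorm(3 * 5 * 4 * 4), c(3, 5, 4, 4)),
                       training = TRUE)), c(3, 5, 4, 8))
})

test_that("msa_block backward matches central finite differences", {
  set.seed(6)
  b <- msa_block(4, 4, k_att = 3)
  x <- array(rnorm(4 * 4 * 4 * 4, sd = 0.5), c(4, 4, 4, 4))
  g <- array(rnorm(4 * 4 * 4 * 4), c(4, 4, 4, 4))
  y <- fwd(b, x, training = TRUE)
  nodulemsa:::nn_zero_grad(b)
  dx <- bwd(b, g)
  eps <- 1e-5
  for (i in sample(length(x), 10)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    fd <- (sum(fwd(b, xp, training = TRUE) * g) -
             sum(fwd(b, xm, training = TRUE) * g)) / (2 * eps)
    expect_lt(abs(fd - dx[i]) / max(1e-4, abs(fd)), 1e-4)
  }
})

test_that("parameter gradients match finite differences through a block", {
  set.seed(7)
  b <- msa_block(4, 4, k_att = 3)
  x <- array(rnorm(4 * 4 * 4 * 4, sd = 0.5), c(4, 4, 4, 4))
  g <- array(rnorm(4 * 4 * 4 * 4), c(4, 4, 4, 4))
  invisible(fwd(b, x, training = TRUE))
  nodulemsa:::nn_zero_grad(b)
  invisible(bwd(b, g))
  slots <- nodulemsa:::nn_parameters(b)
  eps <- 1e-5
  for (s in sample(length(slots), 4)) {
    e <- slots[[s]]$env; nm <- slots[[s]]$name
    i <- sample(length(e[[nm]]), 1)
    orig <- e[[nm]][i]
    e[[nm]][i] <- orig + eps
    fp <- sum(fwd(b, x, training = TRUE) * g)
    e[[nm]][i] <- orig - eps
    fm <- sum(fwd(b, x, training = TRUE) * g)
    e[[nm]][i] <- orig
    fd <- (fp - fm) / (2 * eps)
    expect_lt(abs(fd - e[[paste0("g_", nm)]][i]) / max(1e-3, abs(fd)), 1e-3)
  }
})

test_that("blocks are deterministic in inference mode", {
  set.seed(8)
  b <- msa_block(4, 4, k_att = 3)
  x <- array(rnorm(4^4), c(4, 4, 4, 4))
  invisible(fwd(b, x, training = TRUE))   # populate running stats
  expect_identical(fwd(b, x, training = FALSE), fwd(b, x, training = FALSE))
})

test_that("count_parameters follows the 4-byte size model", {
  cv <- nodulemsa:::layer_conv3d(1, 1, k = 3)
  cp <- count_parameters(cv)
  expect_equal(cp$trainable_count, 27)
  expect_equal(cp$size_mb, 4 * 27 / 2^20)
  # CQAM adds a channel-independent 2752 per block; an SE unit would add
  # 2 C^2 / r (C = 64, r = 16 -> 512, growing quadratically with C)
  expect_lt(abs(count_parameters(layer_cqam(7))$size_mb), 0.1)
})
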
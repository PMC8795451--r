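# The multi-scale attention (MSA) building block:
#   pre-activated convolutions (BN -> ReLU -> conv),
#   the Res2Net hierarchical channel split-transform,
#   Z-Pool channel reduction,
#   the four-branch convolutional quadruplet attention module (CQAM),
#   and the assembled residual block.
#
# Feature maps are stored (D1, D2, D3, C) = (length, width, height, channels):
# the channel dimension is the LAST array dimension (memory layout of the
# conv kernels); all channel-wise semantics below (splitting, Z-Pool, the
# attention rotations) are expressed relative to that dimension.

#' Pre-activated 3D convolution unit
#'
#' Builds the `BN -> ReLU -> 3x3x3 convolution` unit (stride 1, zero padding
#' `(k-1)/2`, no bias) that fronts every convolution inside an MSA block.
#' Placing normalization and activation before the convolution keeps every
#' convolution input standardized, which curbs over-fitting in small-sample
#' medical imaging.
#'
#' @param in_ch,out_ch input/output channel counts.
#' @param k cubic kernel size (default 3).
#' @return A network module; run it with the internal engine (see
#'   [msa_block()]) or via the assembled networks.
#' @export
layer_preact_conv <- function(in_ch, out_ch, k = 3) {
  m <- nn_sequential(list(bn = layer_bn(in_ch), relu = layer_relu(),
                          conv = layer_conv3d(in_ch, out_ch, k)))
  class(m) <- c("preact_conv", class(m))
  m
}

#' Z-Pool: reduce the channel dimension to [max, mean]
#'
#' Concatenates per-location channel-wise max pooling and average pooling,
#' reducing the channel dimension (stored last) to 2 while keeping a rich
#' summary of the map. Output channel 1 is the max, channel 2 the mean, in
#' that fixed order.
#'
#' @param x 4D array `(D1, D2, D3, C)`.
#' @return 4D array `(D1, D2, D3, 2)`.
#' @examples
#' x <- array(c(1, 2, 3), c(1, 1, 1, 3))
#' z_pool(x)[1, 1, 1, ]  # 3, 2
#' @export
z_pool <- function(x) {
  stopifnot(length(dim(x)) == 4L)
  z_pool_fwd(x)$y
}

z_pool_fwd <- function(x) {
  d <- dim(x); C <- d[4]
  xm <- matrix(x, ncol = C)
  mx <- do.call(pmax, lapply(seq_len(C), function(j) xm[, j]))
  am <- max.col(xm, ties.method = "first")
  av <- rowMeans(xm)
  y <- array(c(mx, av), c(d[1:3], 2))
  list(y = y, argmax = am, C = C, d = d)
}

z_pool_bwd <- function(cache, dy) {
  d <- cache$d; C <- cache$C
  n <- prod(d[1:3])
  dym <- matrix(dy, ncol = 2)
  dx <- matrix(dym[, 2] / C, nrow = n, ncol = C)      # mean path
  idx <- cbind(seq_len(n), cache$argmax)              # max path
  dx[idx] <- dx[idx] + dym[, 1]
  array(dx, d)
}

#' Res2Net hierarchical split-transform
#'
#' Splits the input channels (stored last) into `scale = 4` contiguous,
#' equally sized subsets `x1..x4` and connects them in a hierarchical
#' residual-like cascade:
#' `y1 = x1`, `y2 = K2(x2)`, `yi = Ki(y_{i-1} + xi)` for `i = 3, 4`,
#' then concatenates `y1..y4` along channels. Each `Ki` is a pre-activated
#' `3x3x3` convolution of `m = n/4` channels, so one large n-channel filter
#' is replaced by a set of small filters whose composition sees increasing
#' receptive fields — multi-scale features at a granular level.
#'
#' @param channels total channel count `n`; must be divisible by 4.
#' @param identity_filters if TRUE the filters `Ki` are replaced by identity
#'   maps (a test seam: the module then computes
#'   `concat(x1, x2, x2 + x3, x2 + x3 + x4)`).
#' @return A network module.
#' @export
layer_res2net <- function(channels, identity_filters = FALSE) {
  if (channels %% 4 != 0)
    stop("res2net: channel count ", channels, " not divisible by scale 4")
  m <- channels / 4
  ks <- if (identity_filters) list() else
    list(K2 = layer_preact_conv(m, m), K3 = layer_preact_conv(m, m),
         K4 = layer_preact_conv(m, m))
  new_layer("res2net", m = m, identity_filters = identity_filters,
            children = ks)
}

#' @exportS3Method
nn_forward.res2net <- function(layer, x, training = FALSE) {
  d <- dim(x); m <- layer$m
  if (d[4] != 4 * m) stop("res2net: expected ", 4 * m, " channels, got ", d[4])
  grp <- function(i) x[, , , ((i - 1) * m + 1):(i * m), drop = FALSE]
  x1 <- grp(1); x2 <- grp(2); x3 <- grp(3); x4 <- grp(4)
  if (layer$identity_filters) {
    y2 <- x2; y3 <- y2 + x3; y4 <- y3 + x4
  } else {
    y2 <- nn_forward(layer$children$K2, x2, training)
    y3 <- nn_forward(layer$children$K3, y2 + x3, training)
    y4 <- nn_forward(layer$children$K4, y3 + x4, training)
  }
  layer$d <- d
  out <- array(0, d)
  out[, , , 1:m] <- x1
  out[, , , (m + 1):(2 * m)] <- y2
  out[, , , (2 * m + 1):(3 * m)] <- y3
  out[, , , (3 * m + 1):(4 * m)] <- y4
  out
}

#' @exportS3Method
nn_backward.res2net <- function(layer, dy) {
  d <- layer$d; m <- layer$m
  grp <- function(i) dy[, , , ((i - 1) * m + 1):(i * m), drop = FALSE]
  d1 <- grp(1); d2 <- grp(2); d3 <- grp(3); d4 <- grp(4)
  if (layer$identity_filters) {
    du4 <- d4                 # y4 = y3 + x4
    dy3 <- d3 + du4           # y3 = y2 + x3
    du3 <- dy3
    dy2 <- d2 + du3
    dx2 <- dy2; dx3 <- du3; dx4 <- du4
  } else {
    du4 <- nn_backward(layer$children$K4, d4)
    dx4 <- du4
    dy3 <- d3 + du4
    du3 <- nn_backward(layer$children$K3, dy3)
    dx3 <- du3
    dy2 <- d2 + du3
    dx2 <- nn_backward(layer$children$K2, dy2)
  }
  out <- array(0, d)
  out[, , , 1:m] <- d1
  out[, , , (m + 1):(2 * m)] <- dx2
  out[, , , (2 * m + 1):(3 * m)] <- dx3
  out[, , , (3 * m + 1):(4 * m)] <- dx4
  out
}

# Permutations bringing each reduced dimension into the channel (last)
# position; cqam_perms[[1]] is the identity (spatial-attention) branch, the
# others rotate the channel dimension against length/width/height.
cqam_perms <- list(c(1, 2, 3, 4), c(4, 2, 3, 1), c(1, 4, 3, 2), c(1, 2, 4, 3))

inverse_perm <- function(p) order(p)

#' One branch of the quadruplet attention module
#'
#' `permute -> Z-Pool -> k x k x k conv (2 -> 1 channel, no bias) -> BN ->
#' sigmoid -> multiply the weights onto the permuted input (broadcast over
#' its channel dim) -> inverse permute`. Branch 1 (identity permutation)
#' reduces over channels and captures spatial dependencies; branches 2-4
#' rotate the channel dimension against one spatial dimension each, capturing
#' cross-dimension interactions. Output shape equals input shape.
#'
#' @param branch branch index 1-4 (selects the permutation).
#' @param k attention kernel size (default 7, padding `(k-1)/2`).
#' @return A network module.
#' @export
layer_cqam_branch <- function(branch, k = 7) {
  stopifnot(branch %in% 1:4)
  new_layer("cqam_branch", perm = cqam_perms[[branch]], k = k,
            children = list(conv = layer_conv3d(2, 1, k),
                            bn = layer_bn(1)))
}

#' @exportS3Method
nn_forward.cqam_branch <- function(layer, x, training = FALSE) {
  xp <- aperm(x, layer$perm)
  zc <- z_pool_fwd(xp)
  h <- nn_forward(layer$children$conv, zc$y, training)
  h <- nn_forward(layer$children$bn, h, training)
  a <- 1 / (1 + exp(-h))
  y <- xp * as.vector(a)        # broadcast across the permuted channel dim
  layer$cache <- list(xp = xp, zc = zc, a = a, d = dim(x))
  aperm(y, inverse_perm(layer$perm))
}

#' @exportS3Method
nn_backward.cqam_branch <- function(layer, dy) {
  cc <- layer$cache
  dyp <- aperm(dy, layer$perm)
  dp <- dim(cc$xp)
  # grad wrt attention map: sum the broadcast over the permuted channel dim
  da <- rowSums(matrix(dyp * cc$xp, ncol = dp[4]))
  dh <- array(da * cc$a * (1 - cc$a), c(dp[1:3], 1))
  dh <- nn_backward(layer$children$bn, dh)
  dz <- nn_backward(layer$children$conv, dh)
  dxp <- z_pool_bwd(cc$zc, dz) + dyp * as.vector(cc$a)
  aperm(dxp, inverse_perm(layer$perm))
}

#' Convolutional quadruplet attention module (CQAM)
#'
#' Averages the outputs of the four permutation branches
#' ([layer_cqam_branch()]). The module is almost parameter-free: each branch
#' owns one `2 -> 1` channel convolution (`2 k^3` weights) and a 1-channel BN
#' (2 parameters), so the trainable count is `4 (2 k^3 + 2)` = 2752 for
#' `k = 7`, independent of the input channel count — unlike
#' squeeze-and-excitation units whose parameter count grows as `2 C^2 / r`.
#'
#' @param k attention kernel size (default 7).
#' @return A network module.
#' @export
layer_cqam <- function(k = 7) {
  new_layer("cqam", children = lapply(1:4, layer_cqam_branch, k = k))
}

#' @exportS3Method
nn_forward.cqam <- function(layer, x, training = FALSE) {
  y <- nn_forward(layer$children[[1]], x, training)
  for (i in 2:4) y <- y + nn_forward(layer$children[[i]], x, training)
  y / 4
}

#' @exportS3Method
nn_backward.cqam <- function(layer, dy) {
  dy4 <- dy / 4
  dx <- nn_backward(layer$children[[1]], dy4)
  for (i in 2:4) dx <- dx + nn_backward(layer$children[[i]], dy4)
  dx
}

#' The assembled multi-scale attention block
#'
#' `pre-activated 3x3x3 conv (n_in -> n)` -> Res2Net split-transform ->
#' `pre-activated 1x1x1 fuse conv (n -> n_out)` -> CQAM -> residual shortcut
#' (identity when `n_in == n_out`, else a 1x1x1 projection). Spatial
#' dimensions are always preserved; down-sampling is done by external
#' max-pool layers, never inside the block.
#'
#' @param n_in input channels.
#' @param n internal width (divisible by 4); defaults to `n_out`.
#' @param n_out output channels.
#' @param k_att CQAM kernel size.
#' @param attention_order `"pre_residual"` (default; attention applied before
#'   the shortcut addition) or `"post_residual"` (attention applied to the
#'   sum).
#' @return A network module.
#' @export
msa_block <- function(n_in, n_out, n = n_out, k_att = 7,
                      attention_order = c("pre_residual", "post_residual")) {
  attention_order <- match.arg(attention_order)
  ch <- list(entry = layer_preact_conv(n_in, n, 3),
             r2n = layer_res2net(n),
             fuse = layer_preact_conv(n, n_out, 1),
             att = layer_cqam(k_att))
  if (n_in != n_out) ch$proj <- layer_conv3d(n_in, n_out, 1)
  new_layer("msa_block", order = attention_order, n_in = n_in, n_out = n_out,
            children = ch)
}

#' @exportS3Method
nn_forward.msa_block <- function(layer, x, training = FALSE) {
  h <- nn_forward(layer$children$entry, x, training)
  h <- nn_forward(layer$children$r2n, h, training)
  h <- nn_forward(layer$children$fuse, h, training)
  s <- if (is.null(layer$children$proj)) x else
    nn_forward(layer$children$proj, x, training)
  if (layer$order == "pre_residual") {
    nn_forward(layer$children$att, h, training) + s
  } else {
    nn_forward(layer$children$att, h + s, training)
  }
}

#' @exportS3Method
nn_backward.msa_block <- function(layer, dy) {
  if (layer$order == "pre_residual") {
    dh <- nn_backward(layer$children$att, dy)
    ds <- dy
  } else {
    dsum <- nn_backward(layer$children$att, dy)
    dh <- dsum
    ds <- dsum
  }
  dh <- nn_backward(layer$children$fuse, dh)
  dh <- nn_backward(layer$children$r2n, dh)
  dx <- nn_backward(layer$children$entry, dh)
  dx + if (is.null(layer$children$proj)) ds else
    nn_backward(layer$children$proj, ds)
}
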
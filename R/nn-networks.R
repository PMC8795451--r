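# Candidate-detection backbone + RPN head, and the false-positive-reduction
# classifier, assembled from MSA blocks.

#' Configuration of the candidate-detection network
#'
#' The detector maps a cubic patch (1 channel) to a per-anchor prediction
#' grid. Four stride-2 max-pools shrink the patch 16-fold (96 -> 48 -> 24 ->
#' 12 -> 6 for the full profile); two 2x2x2 deconvolutions restore it to a
#' quarter of the input (6 -> 12 -> 24), so the detection stride is 4 voxels.
#' Decoder features are concatenated with the matching-resolution encoder
#' features U-Net style. The head is a 1x1x1 convolution emitting, per grid
#' cell and anchor, 5 values (objectness logit + 4 box-regression terms).
#'
#' @param input_size patch edge in voxels; must be divisible by 16.
#' @param widths channel widths: stem and the four encoder stages.
#' @param blocks_per_stage MSA blocks per encoder stage.
#' @param decoder_blocks MSA blocks after each decoder merge.
#' @param decoder_channels channel width of the decoder stages.
#' @param anchors anchor cube side lengths in mm.
#' @param k_att CQAM kernel size.
#' @return A `detector_config` list.
#' @export
detector_config <- function(input_size = 96, widths = c(24, 32, 64, 64, 64),
                            blocks_per_stage = 2, decoder_blocks = 3,
                            decoder_channels = 64, anchors = c(5, 10, 20),
                            k_att = 7) {
  if (input_size %% 16 != 0)
    stop("detector input_size must be divisible by 16, got ", input_size)
  if (length(widths) != 5) stop("widths must have 5 entries (stem + 4 stages)")
  structure(list(input_size = input_size, widths = widths,
                 blocks_per_stage = blocks_per_stage,
                 decoder_blocks = decoder_blocks,
                 decoder_channels = decoder_channels,
                 anchors = anchors, k_att = k_att, stride = 4),
            class = "detector_config")
}

post_conv <- function(in_ch, out_ch, k = 3) {
  nn_sequential(list(conv = layer_conv3d(in_ch, out_ch, k),
                     bn = layer_bn(out_ch), relu = layer_relu()))
}

#' Build the candidate-detection network
#'
#' @param config a [detector_config()].
#' @return A `detector` network object; run with [detector_forward()].
#' @export
build_detector <- function(config = detector_config()) {
  w <- config$widths
  dc <- config$decoder_channels
  ka <- config$k_att
  stage <- function(n_in, n_out, n_blocks) {
    blocks <- vector("list", n_blocks)
    for (i in seq_len(n_blocks))
      blocks[[i]] <- msa_block(if (i == 1) n_in else n_out, n_out, k_att = ka)
    nn_sequential(blocks)
  }
  ch <- list(
    stem = nn_sequential(list(c1 = post_conv(1, w[1]), c2 = post_conv(w[1], w[1]))),
    pool1 = layer_maxpool2(), enc1 = stage(w[1], w[2], config$blocks_per_stage),
    pool2 = layer_maxpool2(), enc2 = stage(w[2], w[3], config$blocks_per_stage),
    pool3 = layer_maxpool2(), enc3 = stage(w[3], w[4], config$blocks_per_stage),
    pool4 = layer_maxpool2(), enc4 = stage(w[4], w[5], config$blocks_per_stage),
    up1 = layer_deconv2(w[5], dc),
    dec1 = stage(dc + w[4], dc, config$decoder_blocks),
    up2 = layer_deconv2(dc, dc),
    dec2 = stage(dc + w[3], dc, config$decoder_blocks),
    head = layer_conv3d(dc, 5 * length(config$anchors), k = 1)
  )
  net <- new_layer("detector", config = config, children = ch)
  net
}

#' Run the detector forward / backward
#'
#' `detector_forward` maps a patch array `(S, S, S)` or `(S, S, S, 1)` to the
#' raw output grid `(S/4, S/4, S/4, 5 * n_anchors)`; `detector_backward`
#' propagates a gradient of the same shape (training-mode forward required
#' first).
#'
#' @param net a [build_detector()] network.
#' @param x input patch, already intensity-normalized to about `[-1, 1]`.
#' @param training logical; enables batch statistics and gradient caches.
#' @return The raw output grid.
#' @export
detector_forward <- function(net, x, training = FALSE) {
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1)
  ch <- net$children
  h <- nn_forward(ch$stem, x, training)
  h <- nn_forward(ch$enc1, nn_forward(ch$pool1, h, training), training)
  e2 <- nn_forward(ch$enc2, nn_forward(ch$pool2, h, training), training)
  e3 <- nn_forward(ch$enc3, nn_forward(ch$pool3, e2, training), training)
  e4 <- nn_forward(ch$enc4, nn_forward(ch$pool4, e3, training), training)
  u1 <- nn_forward(ch$up1, e4, training)
  net$ncat1 <- c(dim(u1)[4], dim(e3)[4])
  d1 <- nn_forward(ch$dec1, bind4(u1, e3), training)
  u2 <- nn_forward(ch$up2, d1, training)
  net$ncat2 <- c(dim(u2)[4], dim(e2)[4])
  d2 <- nn_forward(ch$dec2, bind4(u2, e2), training)
  nn_forward(ch$head, d2, training)
}

#' @rdname detector_forward
#' @param dout gradient w.r.t. the raw output grid.
#' @export
detector_backward <- function(net, dout) {
  ch <- net$children
  dd2 <- nn_backward(ch$head, dout)
  dcat2 <- nn_backward(ch$dec2, dd2)
  du2 <- dcat2[, , , seq_len(net$ncat2[1]), drop = FALSE]
  de2_skip <- dcat2[, , , net$ncat2[1] + seq_len(net$ncat2[2]), drop = FALSE]
  dd1 <- nn_backward(ch$up2, du2)
  dcat1 <- nn_backward(ch$dec1, dd1)
  du1 <- dcat1[, , , seq_len(net$ncat1[1]), drop = FALSE]
  de3_skip <- dcat1[, , , net$ncat1[1] + seq_len(net$ncat1[2]), drop = FALSE]
  de4 <- nn_backward(ch$up1, du1)
  de3 <- nn_backward(ch$pool4, nn_backward(ch$enc4, de4)) + de3_skip
  de2 <- nn_backward(ch$pool3, nn_backward(ch$enc3, de3)) + de2_skip
  dh <- nn_backward(ch$pool2, nn_backward(ch$enc2, de2))
  dh <- nn_backward(ch$pool1, nn_backward(ch$enc1, dh))
  nn_backward(ch$stem, dh)
}

bind4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1:3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}

#' Configuration of the false-positive-reduction classifier
#'
#' A cube cropped at a candidate's center passes through two plain 3x3x3
#' convolution layers, then three `{max-pool + MSA block}` stages, a final
#' max-pool, global average pooling, dropout and a single-logit fully
#' connected head (sigmoid probability). Spatial trajectory for the full
#' profile: 48 -> 24 -> 12 -> 6 -> 3.
#'
#' @param input_size cube edge in voxels (divisible by 16).
#' @param widths channel widths of the three MSA stages.
#' @param stem_width channels of the two stem convolutions.
#' @param dropout dropout rate before the head (training mode only).
#' @param k_att CQAM kernel size.
#' @return An `fpr_config` list.
#' @export
fpr_config <- function(input_size = 48, widths = c(16, 32, 64),
                       stem_width = 16, dropout = 0.5, k_att = 7) {
  if (input_size %% 16 != 0)
    stop("fpr input_size must be divisible by 16, got ", input_size)
  if (length(widths) != 3) stop("widths must have 3 entries")
  structure(list(input_size = input_size, widths = widths,
                 stem_width = stem_width, dropout = dropout, k_att = k_att),
            class = "fpr_config")
}

#' Build the false-positive-reduction network
#'
#' @param config an [fpr_config()].
#' @return An `fpr_net` object; run with [fpr_forward()].
#' @export
build_fpr <- function(config = fpr_config()) {
  w <- config$widths; sw <- config$stem_width; ka <- config$k_att
  ch <- list(
    stem = nn_sequential(list(c1 = post_conv(1, sw), c2 = post_conv(sw, sw))),
    pool1 = layer_maxpool2(), msa1 = msa_block(sw, w[1], k_att = ka),
    pool2 = layer_maxpool2(), msa2 = msa_block(w[1], w[2], k_att = ka),
    pool3 = layer_maxpool2(), msa3 = msa_block(w[2], w[3], k_att = ka),
    pool4 = layer_maxpool2(),
    gap = layer_gap(),
    drop = layer_dropout(config$dropout),
    fc = layer_linear(w[3], 1)
  )
  new_layer("fpr_net", config = config, children = ch)
}

#' Run the FPR classifier
#'
#' @param net a [build_fpr()] network.
#' @param x cube array `(S, S, S)` or `(S, S, S, 1)`, intensity-normalized.
#' @param training logical; enables dropout and batch statistics.
#' @return `fpr_forward`: the scalar logit; `fpr_probability`: the sigmoid
#'   probability in (0, 1).
#' @export
fpr_forward <- function(net, x, training = FALSE) {
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1)
  ch <- net$children
  h <- nn_forward(ch$stem, x, training)
  h <- nn_forward(ch$msa1, nn_forward(ch$pool1, h, training), training)
  h <- nn_forward(ch$msa2, nn_forward(ch$pool2, h, training), training)
  h <- nn_forward(ch$msa3, nn_forward(ch$pool3, h, training), training)
  h <- nn_forward(ch$pool4, h, training)
  h <- nn_forward(ch$gap, h, training)
  h <- nn_forward(ch$drop, h, training)
  nn_forward(ch$fc, h, training)
}

#' @rdname fpr_forward
#' @export
fpr_probability <- function(net, x) {
  1 / (1 + exp(-fpr_forward(net, x, training = FALSE)))
}

fpr_backward <- function(net, dlogit) {
  ch <- net$children
  dh <- nn_backward(ch$fc, dlogit)
  dh <- nn_backward(ch$drop, dh)
  dh <- nn_backward(ch$gap, dh)
  dh <- nn_backward(ch$pool4, dh)
  dh <- nn_backward(ch$pool3, nn_backward(ch$msa3, dh))
  dh <- nn_backward(ch$pool2, nn_backward(ch$msa2, dh))
  dh <- nn_backward(ch$pool1, nn_backward(ch$msa1, dh))
  nn_backward(ch$stem, dh)
}

#' Flatten a raw detector output grid into per-anchor records
#'
#' Applies the sigmoid to the objectness channel, passes the regression
#' channels through, and attaches each record's anchor identity (0-based
#' grid indices + anchor size). Record count is `grid^3 * n_anchors`
#' (41472 for a 96^3 patch).
#'
#' @param out raw output grid from [detector_forward()].
#' @param anchors anchor side lengths in mm.
#' @return A tibble with grid indices `gz, gy, gx`, `anchor_mm`, `logit`,
#'   `p`, and regression terms `tz, ty, tx, tlogd`.
#' @export
detector_output_to_grid_predictions <- function(out, anchors = c(5, 10, 20)) {
  d <- dim(out)
  na <- length(anchors)
  stopifnot(d[4] == 5 * na)
  g <- d[1:3]
  cells <- expand.grid(gz = 0:(g[1] - 1), gy = 0:(g[2] - 1), gx = 0:(g[3] - 1))
  res <- vector("list", na)
  for (a in seq_len(na)) {
    ch0 <- (a - 1) * 5
    logit <- as.vector(out[, , , ch0 + 1])
    res[[a]] <- tibble::tibble(
      gz = cells$gz, gy = cells$gy, gx = cells$gx,
      anchor = a, anchor_mm = anchors[a],
      logit = logit, p = 1 / (1 + exp(-logit)),
      tz = as.vector(out[, , , ch0 + 2]),
      ty = as.vector(out[, , , ch0 + 3]),
      tx = as.vector(out[, , , ch0 + 4]),
      tlogd = as.vector(out[, , , ch0 + 5]))
  }
  dplyr::bind_rows(res)
}
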
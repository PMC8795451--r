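# The multi-task detection loss: binary cross-entropy for anchor
# classification plus smooth-L1 box regression on positive anchors,
# balanced by lambda = 0.5.

#' Binary cross-entropy classification loss
#'
#' `-(p* log p + (1 - p*) log(1 - p))`, elementwise, with `p` clamped to
#' `[1e-7, 1 - 1e-7]`. (The loss is the negative log-likelihood of the
#' label: minimized, non-negative, zero only in the limit `p -> p*`.)
#'
#' @param p predicted probabilities in (0, 1).
#' @param p_star labels in `{0, 1}`.
#' @return Elementwise loss values (>= 0).
#' @examples
#' classification_loss(0.5, 1)  # log(2)
#' classification_loss(0.9, 0)  # -log(0.1)
#' @export
classification_loss <- function(p, p_star) {
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  -(p_star * log(p) + (1 - p_star) * log(1 - p))
}

#' Smooth-L1 (Huber-type) regression loss
#'
#' Per component: `0.5 diff^2 / sigma^2` when `|diff| < 1 / sigma^2`, else
#' `|diff| - 0.5`; summed over the 4 regression components. Continuous at
#' the switch point for `sigma = 1`.
#'
#' @param t predicted regression 4-vector, or an n x 4 matrix.
#' @param t_star target of the same shape.
#' @param sigma transition parameter (default 1).
#' @return Scalar (or length-n vector) loss.
#' @examples
#' smooth_l1(c(0.5, 0, 0, 0), rep(0, 4))  # 0.125
#' smooth_l1(c(2, 0, 0, 0), rep(0, 4))    # 1.5
#' @export
smooth_l1 <- function(t, t_star, sigma = 1) {
  stopifnot(sigma > 0)
  if (is.null(dim(t))) { t <- matrix(t, nrow = 1); t_star <- matrix(t_star, nrow = 1) }
  diff <- t - t_star
  cut <- 1 / sigma^2
  comp <- ifelse(abs(diff) < cut, 0.5 * diff^2 / sigma^2, abs(diff) - 0.5)
  out <- rowSums(comp)
  if (length(out) == 1) out[[1]] else out
}

smooth_l1_grad <- function(t, t_star, sigma = 1) {
  if (is.null(dim(t))) { t <- matrix(t, nrow = 1); t_star <- matrix(t_star, nrow = 1) }
  diff <- t - t_star
  cut <- 1 / sigma^2
  ifelse(abs(diff) < cut, diff / sigma^2, sign(diff))
}

#' Multi-task anchor loss
#'
#' `lambda * L_cls + L_reg`: the classification term is binary cross-entropy
#' averaged over the non-ignored anchors passed in (the training loop passes
#' positives plus a sampled subset of negatives); the regression term is
#' smooth-L1 averaged over positive anchors only (0 when there are none).
#' Anchors with `p_star = NA` (ignored) contribute nothing.
#'
#' @param p predicted probabilities, length n.
#' @param t predicted regression terms, n x 4.
#' @param p_star labels in `{1, 0, NA}`.
#' @param t_star regression targets, n x 4.
#' @param lambda classification/regression balance (0.5).
#' @param sigma smooth-L1 transition (1).
#' @return Scalar loss (>= 0).
#' @export
multitask_loss <- function(p, t, p_star, t_star, lambda = 0.5, sigma = 1) {
  if (is.null(dim(t))) { t <- matrix(t, nrow = 1); t_star <- matrix(t_star, nrow = 1) }
  sampled <- !is.na(p_star)
  if (!any(sampled)) return(0)
  l_cls <- mean(classification_loss(p[sampled], p_star[sampled]))
  pos <- which(sampled & p_star == 1)
  l_reg <- if (length(pos))
    mean(smooth_l1(t[pos, , drop = FALSE], t_star[pos, , drop = FALSE], sigma))
  else 0
  lambda * l_cls + l_reg
}

#' @rdname multitask_loss
#' @return `multitask_loss_grad`: list with `dp` (length n) and `dt`
#'   (n x 4), the analytic gradients of [multitask_loss()] w.r.t. `p` and
#'   `t`.
#' @export
multitask_loss_grad <- function(p, t, p_star, t_star, lambda = 0.5, sigma = 1) {
  if (is.null(dim(t))) { t <- matrix(t, nrow = 1); t_star <- matrix(t_star, nrow = 1) }
  dp <- numeric(length(p))
  dt <- matrix(0, nrow(t), 4)
  sampled <- which(!is.na(p_star))
  if (!length(sampled)) return(list(dp = dp, dt = dt))
  pc <- pmin(pmax(p[sampled], 1e-7), 1 - 1e-7)
  dp[sampled] <- lambda * (pc - p_star[sampled]) / (pc * (1 - pc)) / length(sampled)
  pos <- which(!is.na(p_star) & p_star == 1)
  if (length(pos)) {
    dt[pos, ] <- smooth_l1_grad(t[pos, , drop = FALSE],
                                t_star[pos, , drop = FALSE], sigma) / length(pos)
  }
  list(dp = dp, dt = dt)
}

# Loss + gradient on a raw detector output grid. Positives all enter the
# classification term; negatives are subsampled (min(cap, 2 * n_pos + 32),
# drawn with the current RNG) to bound the ~41k-anchor class imbalance.
# Returns the scalar loss and the gradient w.r.t. the raw grid (logits and
# regression channels), plus the component values.
detector_loss <- function(out, grid, labels, targets, lambda = 0.5, sigma = 1,
                          neg_cap = 64) {
  d <- dim(out)
  na <- length(grid$sizes)
  g3 <- prod(d[1:3])
  p_star <- labels$p_star
  pos <- which(!is.na(p_star) & p_star == 1)
  neg <- which(!is.na(p_star) & p_star == 0)
  n_take <- min(min(neg_cap, 2 * length(pos) + 32), length(neg))
  neg_s <- if (n_take > 0) sample(neg, n_take) else integer()
  sel <- c(pos, neg_s)
  if (!length(sel)) {
    return(list(loss = 0, dout = array(0, d), n_pos = 0,
                cls_loss = 0, reg_loss = 0))
  }
  # map flat anchor index -> (cell index within grid, anchor index)
  cell <- (sel - 1) %% g3 + 1
  aidx <- (sel - 1) %/% g3 + 1
  logit_flat <- matrix(out, ncol = d[4])
  z <- logit_flat[cbind(cell, (aidx - 1) * 5 + 1)]
  pr <- 1 / (1 + exp(-z))
  lab <- p_star[sel]
  l_cls <- mean(classification_loss(pr, lab))
  dout <- array(0, d)
  dout_flat <- matrix(dout, ncol = d[4])
  # d BCE / d logit = sigmoid(z) - label
  dz <- lambda * (pr - lab) / length(sel)
  dout_flat[cbind(cell, (aidx - 1) * 5 + 1)] <- dz
  l_reg <- 0
  if (length(pos)) {
    cell_p <- (pos - 1) %% g3 + 1
    aidx_p <- (pos - 1) %/% g3 + 1
    tmat <- sapply(2:5, function(j) logit_flat[cbind(cell_p, (aidx_p - 1) * 5 + j)])
    tmat <- matrix(tmat, ncol = 4)
    tgt_flat <- matrix(targets, ncol = 4)
    tstar <- tgt_flat[pos, , drop = FALSE]
    l_reg <- mean(smooth_l1(tmat, tstar, sigma))
    gr <- smooth_l1_grad(tmat, tstar, sigma) / length(pos)
    for (j in 1:4)
      dout_flat[cbind(cell_p, (aidx_p - 1) * 5 + 1 + j)] <- gr[, j]
  }
  dim(dout_flat) <- d
  list(loss = lambda * l_cls + l_reg, dout = dout_flat,
       n_pos = length(pos), cls_loss = l_cls, reg_loss = l_reg)
}
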
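# Minimal 3D neural-network engine with explicit reverse-mode gradients.
#
# Feature maps are 4D arrays of dim (D1, D2, D3, C): spatial-first,
# channels-last (matches the memory layout of the C++ kernels). Layers are
# environments carrying parameters (name), gradients (g_<name>) and momentum
# buffers (v_<name>); composite modules list their children in $children.
# nn_forward() caches whatever nn_backward() needs; a forward in training
# mode must precede each backward.

new_layer <- function(class, ..., params = character(), children = list()) {
  e <- new.env(parent = emptyenv())
  list2env(list(...), e)
  e$param_names <- params
  e$children <- children
  for (p in params) {
    e[[paste0("g_", p)]] <- array(0, dim(e[[p]]) %||% length(e[[p]]))
    e[[paste0("v_", p)]] <- array(0, dim(e[[p]]) %||% length(e[[p]]))
  }
  class(e) <- c(class, "nn_layer")
  e
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.nn_layer <- function(x, ...) {
  cat(sprintf("<%s> %s trainable parameters\n", class(x)[1],
              format(count_parameters(x)$trainable_count, big.mark = ",")))
  invisible(x)
}

nn_forward <- function(layer, x, training = FALSE) UseMethod("nn_forward")
nn_backward <- function(layer, dy) UseMethod("nn_backward")

# All (env, name) parameter slots of a module tree.
nn_parameters <- function(layer) {
  out <- lapply(layer$param_names, function(p) list(env = layer, name = p))
  for (ch in layer$children) out <- c(out, nn_parameters(ch))
  out
}

nn_zero_grad <- function(layer) {
  for (slot in nn_parameters(layer)) {
    g <- paste0("g_", slot$name)
    slot$env[[g]][] <- 0
  }
  invisible(layer)
}

#' Count trainable parameters of a network or layer
#'
#' `size_mb` assumes 4-byte (single precision) storage:
#' `4 * trainable_count / 2^20`.
#'
#' @param network any layer, block or network built by this package.
#' @return list with `trainable_count` and `size_mb`.
#' @export
count_parameters <- function(network) {
  n <- sum(vapply(nn_parameters(network),
                  function(s) length(s$env[[s$name]]), numeric(1)))
  list(trainable_count = n, size_mb = 4 * n / 2^20)
}

he_init <- function(dims, fan_in) {
  array(rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

# ---- leaf layers -----------------------------------------------------------

layer_conv3d <- function(in_ch, out_ch, k = 3, pad = (k - 1) %/% 2, sd = NULL) {
  W <- if (is.null(sd)) he_init(c(k, k, k, in_ch, out_ch), k^3 * in_ch) else
    array(rnorm(k^3 * in_ch * out_ch, sd = sd), c(k, k, k, in_ch, out_ch))
  new_layer("conv3d", W = W, k = k, pad = pad, in_ch = in_ch, out_ch = out_ch,
            params = "W")
}

#' @exportS3Method
nn_forward.conv3d <- function(layer, x, training = FALSE) {
  d <- dim(x)
  if (d[4] != layer$in_ch)
    stop("conv3d: input has ", d[4], " channels, weights expect ", layer$in_ch)
  layer$x <- x
  y <- cpp_conv3d_fwd(x, d[1], d[2], d[3], d[4], layer$W, layer$k,
                      layer$out_ch, layer$pad)
  array(y, c(d[1:3], layer$out_ch))
}

#' @exportS3Method
nn_backward.conv3d <- function(layer, dy) {
  d <- dim(layer$x)
  dw <- cpp_conv3d_bwd_weight(layer$x, d[1], d[2], d[3], d[4], dy,
                              layer$out_ch, layer$k, layer$pad)
  layer$g_W <- layer$g_W + array(dw, dim(layer$W))
  dx <- cpp_conv3d_bwd_input(dy, d[1], d[2], d[3], layer$out_ch, layer$W,
                             layer$k, d[4], layer$pad)
  array(dx, d)
}

layer_bn <- function(channels, momentum = 0.1, eps = 1e-5) {
  new_layer("bn3d",
            gamma = rep(1, channels), beta = rep(0, channels),
            r_mean = rep(0, channels), r_var = rep(1, channels),
            momentum = momentum, eps = eps, channels = channels,
            identity = FALSE, params = c("gamma", "beta"))
}

#' @exportS3Method
nn_forward.bn3d <- function(layer, x, training = FALSE) {
  if (layer$identity) { layer$mode <- "identity"; return(x) }
  d <- dim(x); C <- layer$channels
  xm <- matrix(x, ncol = C)
  if (training) {
    mu <- colMeans(xm)
    xc <- sweep(xm, 2, mu, "-")
    va <- colMeans(xc^2)
    inv_sd <- 1 / sqrt(va + layer$eps)
    xhat <- sweep(xc, 2, inv_sd, "*")
    layer$r_mean <- (1 - layer$momentum) * layer$r_mean + layer$momentum * mu
    layer$r_var <- (1 - layer$momentum) * layer$r_var + layer$momentum * va
    layer$cache <- list(xhat = xhat, inv_sd = inv_sd, d = d)
    layer$mode <- "train"
    y <- sweep(sweep(xhat, 2, layer$gamma, "*"), 2, layer$beta, "+")
  } else {
    inv_sd <- 1 / sqrt(layer$r_var + layer$eps)
    xhat <- sweep(sweep(xm, 2, layer$r_mean, "-"), 2, inv_sd, "*")
    layer$cache <- list(xhat = xhat, inv_sd = inv_sd, d = d)
    layer$mode <- "eval"
    y <- sweep(sweep(xhat, 2, layer$gamma, "*"), 2, layer$beta, "+")
  }
  array(y, d)
}

#' @exportS3Method
nn_backward.bn3d <- function(layer, dy) {
  if (identical(layer$mode, "identity")) return(dy)
  cache <- layer$cache
  d <- cache$d; C <- layer$channels
  dym <- matrix(dy, ncol = C)
  layer$g_gamma <- layer$g_gamma + colSums(dym * cache$xhat)
  layer$g_beta <- layer$g_beta + colSums(dym)
  dxhat <- sweep(dym, 2, layer$gamma, "*")
  if (identical(layer$mode, "eval")) {
    dx <- sweep(dxhat, 2, cache$inv_sd, "*")
    return(array(dx, d))
  }
  n <- nrow(dym)
  # batch-statistics backward
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * cache$xhat)
  dx <- sweep(dxhat, 2, m1, "-") - sweep(cache$xhat, 2, m2, "*")
  dx <- sweep(dx, 2, cache$inv_sd, "*")
  array(dx, d)
}

layer_relu <- function(bypass = FALSE) new_layer("relu", bypass = bypass)

#' @exportS3Method
nn_forward.relu <- function(layer, x, training = FALSE) {
  if (layer$bypass) { layer$mask <- NULL; return(x) }
  layer$mask <- x > 0
  x * layer$mask
}

#' @exportS3Method
nn_backward.relu <- function(layer, dy) {
  if (is.null(layer$mask)) dy else dy * layer$mask
}

layer_maxpool2 <- function() new_layer("maxpool2")

#' @exportS3Method
nn_forward.maxpool2 <- function(layer, x, training = FALSE) {
  d <- dim(x)
  if (any(d[1:3] %% 2 != 0)) stop("maxpool2: odd spatial dims ", paste(d[1:3], collapse = "x"))
  r <- cpp_maxpool2_fwd(x, d[1], d[2], d[3], d[4])
  layer$argmax <- r$argmax
  layer$n_in <- length(x)
  layer$d_out <- c(d[1:3] %/% 2, d[4])
  array(r$y, layer$d_out)
}

#' @exportS3Method
nn_backward.maxpool2 <- function(layer, dy) {
  dx <- cpp_maxpool2_bwd(dy, layer$argmax, layer$n_in)
  array(dx, c(layer$d_out[1:3] * 2, layer$d_out[4]))
}

layer_deconv2 <- function(in_ch, out_ch) {
  W <- he_init(c(2, 2, 2, in_ch, out_ch), 8 * in_ch)
  new_layer("deconv2", W = W, in_ch = in_ch, out_ch = out_ch, params = "W")
}

#' @exportS3Method
nn_forward.deconv2 <- function(layer, x, training = FALSE) {
  d <- dim(x)
  layer$x <- x
  y <- cpp_deconv2_fwd(x, d[1], d[2], d[3], d[4], layer$W, layer$out_ch)
  array(y, c(d[1:3] * 2, layer$out_ch))
}

#' @exportS3Method
nn_backward.deconv2 <- function(layer, dy) {
  d <- dim(layer$x)
  r <- cpp_deconv2_bwd(layer$x, d[1], d[2], d[3], d[4], layer$W,
                       layer$out_ch, dy)
  layer$g_W <- layer$g_W + array(r$dw, dim(layer$W))
  array(r$dx, d)
}

layer_dropout <- function(p = 0.5) new_layer("dropout", p = p)

#' @exportS3Method
nn_forward.dropout <- function(layer, x, training = FALSE) {
  if (!training || layer$p <= 0) { layer$mask <- NULL; return(x) }
  layer$mask <- (runif(length(x)) >= layer$p) / (1 - layer$p)
  x * layer$mask
}

#' @exportS3Method
nn_backward.dropout <- function(layer, dy) {
  if (is.null(layer$mask)) dy else dy * layer$mask
}

layer_gap <- function() new_layer("gap")

#' @exportS3Method
nn_forward.gap <- function(layer, x, training = FALSE) {
  d <- dim(x)
  layer$d <- d
  colMeans(matrix(x, ncol = d[4]))
}

#' @exportS3Method
nn_backward.gap <- function(layer, dy) {
  d <- layer$d
  n <- prod(d[1:3])
  array(rep(dy / n, each = n), d)
}

layer_linear <- function(in_n, out_n) {
  new_layer("linear", W = he_init(c(in_n, out_n), in_n), b = rep(0, out_n),
            params = c("W", "b"))
}

#' @exportS3Method
nn_forward.linear <- function(layer, x, training = FALSE) {
  layer$x <- x
  drop(x %*% layer$W) + layer$b
}

#' @exportS3Method
nn_backward.linear <- function(layer, dy) {
  layer$g_W <- layer$g_W + outer(layer$x, dy)
  layer$g_b <- layer$g_b + dy
  drop(layer$W %*% dy)
}

nn_sequential <- function(...) {
  layers <- list(...)
  if (length(layers) == 1 && is.list(layers[[1]]) &&
      !inherits(layers[[1]], "nn_layer")) layers <- layers[[1]]
  new_layer("sequential", children = layers)
}

#' @exportS3Method
nn_forward.sequential <- function(layer, x, training = FALSE) {
  for (ch in layer$children) x <- nn_forward(ch, x, training)
  x
}

#' @exportS3Method
nn_backward.sequential <- function(layer, dy) {
  for (ch in rev(layer$children)) dy <- nn_backward(ch, dy)
  dy
}

# ---- optimizer -------------------------------------------------------------

# SGD with classical momentum and decoupled-from-nothing L2 weight decay
# (decay added to the gradient, the paper's "weight attenuation coefficient").
sgd_step <- function(network, lr, momentum = 0.9, weight_decay = 1e-4) {
  for (slot in nn_parameters(network)) {
    e <- slot$env; p <- slot$name
    g <- e[[paste0("g_", p)]] + weight_decay * e[[p]]
    v <- momentum * e[[paste0("v_", p)]] + g
    e[[paste0("v_", p)]] <- v
    e[[p]] <- e[[p]] - lr * v
  }
  invisible(network)
}

# Tail (Polyak) weight averaging: accumulate a running mean of every
# parameter over the final training steps and write it back at the end.
# Cuts the step-to-step variance of short, small-batch SGD runs.
swa_init <- function(network) {
  lapply(nn_parameters(network), function(s) s$env[[s$name]] * 0)
}

swa_accumulate <- function(network, acc, k) {
  slots <- nn_parameters(network)
  for (i in seq_along(slots)) {
    s <- slots[[i]]
    acc[[i]] <- acc[[i]] + (s$env[[s$name]] - acc[[i]]) / k
  }
  acc
}

swa_apply <- function(network, acc) {
  slots <- nn_parameters(network)
  for (i in seq_along(slots)) {
    s <- slots[[i]]
    s$env[[s$name]] <- acc[[i]]
  }
  invisible(network)
}

# Set every BN child of a module tree to identity (test seam) or back.
set_bn_identity <- function(layer, identity = TRUE) {
  if (inherits(layer, "bn3d")) layer$identity <- identity
  for (ch in layer$children) set_bn_identity(ch, identity)
  invisible(layer)
}

# Zero every conv/deconv/linear weight of a module tree (test seam).
zero_weights <- function(layer) {
  for (slot in nn_parameters(layer)) {
    if (slot$name %in% c("W", "b")) slot$env[[slot$name]][] <- 0
  }
  invisible(layer)
}
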
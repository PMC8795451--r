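# Single-file, versioned network checkpoints.

cache_fields <- c("x", "cache", "mask", "argmax", "d", "d_out", "n_in",
                  "mode", "ncat1", "ncat2")

clear_caches <- function(layer) {
  for (f in cache_fields) if (!is.null(layer[[f]])) rm(list = f, envir = layer)
  for (ch in layer$children) clear_caches(ch)
  invisible(layer)
}

#' Save / load a network checkpoint
#'
#' Writes the full network (weights, BN running statistics, configuration)
#' to a single versioned file; forward caches are stripped first.
#'
#' @param net a [build_detector()] or [build_fpr()] network.
#' @param path checkpoint file path.
#' @return `save_network`: `path`, invisibly. `load_network`: the network.
#' @export
save_network <- function(net, path) {
  clear_caches(net)
  kind <- if (inherits(net, "detector")) "detector" else
    if (inherits(net, "fpr_net")) "fpr" else class(net)[1]
  saveRDS(list(format = "nodulemsa-checkpoint", version = 1L, kind = kind,
               net = net), path)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "nodulemsa-checkpoint"))
    stop("not a nodulemsa checkpoint: ", path)
  if (ck$version > 1L) stop("checkpoint version ", ck$version, " not supported")
  ck$net
}
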
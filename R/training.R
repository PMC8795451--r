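# Training orchestration: optimizer schedule, augmentation, patch sampling,
# cross-validation folds, and the desk-scale end-to-end experiment.

#' Training configuration
#'
#' Both networks train with SGD (momentum 0.9, weight decay 1e-4), initial
#' learning rate 0.01 and piecewise-constant decay: the detector drops to
#' 0.001 at epoch 50 (batch 16, 100 epochs); the false-positive-reduction
#' net drops to 0.001 at epoch 40 and 0.0001 at epoch 80 (batch 128, 100
#' epochs). Positive samples are augmented by random axis flips and
#' isotropic rescaling in `[0.75, 1.25]`.
#'
#' @param detector,fpr per-network overrides (lists with any of `epochs`,
#'   `batch_size`, `lr0`, `milestones`, `lr_values`).
#' @param momentum,weight_decay SGD parameters.
#' @param folds cross-validation fold count.
#' @param seed run seed; all randomness flows from it.
#' @return A `train_config` list.
#' @export
train_config <- function(detector = list(), fpr = list(), momentum = 0.9,
                         weight_decay = 1e-4, folds = 10, seed = 1) {
  det <- utils::modifyList(
    list(epochs = 100, batch_size = 16, lr0 = 0.01,
         milestones = 50, lr_values = 0.001), detector)
  fp <- utils::modifyList(
    list(epochs = 100, batch_size = 128, lr0 = 0.01,
         milestones = c(40, 80), lr_values = c(0.001, 0.0001)), fpr)
  structure(list(detector = det, fpr = fp, momentum = momentum,
                 weight_decay = weight_decay, folds = folds, seed = seed,
                 scale_range = c(0.75, 1.25)),
            class = "train_config")
}

#' Learning rate at a given epoch
#'
#' Piecewise-constant schedule; epochs are 0-based, so the detector uses
#' 0.01 for epochs 0-49 and 0.001 from epoch 50 on.
#'
#' @param config a [train_config()].
#' @param network `"detector"` or `"fpr"`.
#' @param epoch 0-based epoch index.
#' @return The learning rate.
#' @examples
#' lr_at_epoch(train_config(), "detector", 49)  # 0.01
#' lr_at_epoch(train_config(), "fpr", 85)       # 1e-4
#' @export
lr_at_epoch <- function(config, network = c("detector", "fpr"), epoch) {
  network <- match.arg(network)
  cf <- config[[network]]
  lr <- cf$lr0
  for (i in seq_along(cf$milestones))
    if (epoch >= cf$milestones[i]) lr <- cf$lr_values[i]
  lr
}

#' Random flip + isotropic-scale augmentation of a training patch
#'
#' Each axis is independently mirrored with probability 0.5 and one
#' isotropic scale factor is drawn uniformly from `scale_range` and applied
#' by trilinear resampling about the patch center (content zoom on a fixed
#' grid). Annotation centers and diameters transform consistently; a flip
#' maps voxel coordinate `c` to `(extent - 1) - c`, a scale `s` maps it to
#' `center + s (c - center)` and multiplies the diameter by `s`. Pass
#' explicit `flip` / `scale` to pin the transform; otherwise they are drawn
#' from the current RNG.
#'
#' @param patch 3D array.
#' @param annotations patch-frame annotation tibble (`vz, vy, vx, diameter`)
#'   or NULL.
#' @param flip logical length 3, or NULL to draw.
#' @param scale scalar factor, or NULL to draw.
#' @param scale_range sampling range for `scale`.
#' @return list with `patch`, `annotations`, `flip`, `scale`.
#' @export
augment_patch <- function(patch, annotations = NULL, flip = NULL, scale = NULL,
                          scale_range = c(0.75, 1.25)) {
  d <- dim(patch)
  if (is.null(flip)) flip <- runif(3) < 0.5
  if (is.null(scale)) scale <- runif(1, scale_range[1], scale_range[2])
  out <- patch
  if (flip[1]) out <- out[d[1]:1, , , drop = FALSE]
  if (flip[2]) out <- out[, d[2]:1, , drop = FALSE]
  if (flip[3]) out <- out[, , d[3]:1, drop = FALSE]
  ann <- annotations
  if (!is.null(ann) && nrow(ann)) {
    if (flip[1]) ann$vz <- (d[1] - 1) - ann$vz
    if (flip[2]) ann$vy <- (d[2] - 1) - ann$vy
    if (flip[3]) ann$vx <- (d[3] - 1) - ann$vx
  }
  if (abs(scale - 1) > 1e-12) {
    ctr <- (d - 1) / 2
    # output voxel t samples input ctr + (t - ctr)/s
    out <- array(cpp_trilinear(out, d[1], d[2], d[3], d[1], d[2], d[3],
                               rep(1 / scale, 3), ctr * (1 - 1 / scale)), d)
    if (!is.null(ann) && nrow(ann)) {
      ann$vz <- ctr[1] + scale * (ann$vz - ctr[1])
      ann$vy <- ctr[2] + scale * (ann$vy - ctr[2])
      ann$vx <- ctr[3] + scale * (ann$vx - ctr[3])
      ann$diameter <- ann$diameter * scale
      inside <- ann$vz >= 0 & ann$vz < d[1] & ann$vy >= 0 & ann$vy < d[2] &
        ann$vx >= 0 & ann$vx < d[3]
      ann <- ann[inside, , drop = FALSE]
    }
  }
  list(patch = out, annotations = ann, flip = flip, scale = scale)
}

#' Sample labelled training patches from a preprocessed dataset
#'
#' Alternates nodule-centered crops (center jittered so the nodule stays
#' inside the patch) and random lung-interior negative crops at the given
#' ratio, applies positive-sample augmentation, and computes anchor labels
#' and regression targets. Deterministic for a fixed seed. A dataset
#' without nodules yields negatives only, with a warning.
#'
#' @param dataset list of scans, each a list with `volume` (preprocessed
#'   [volume()]) and `annotations` (world-mm tibble).
#' @param n number of patches.
#' @param patch_size patch edge (voxels).
#' @param ratio positive:negative mix, as the probability of drawing a
#'   nodule-centered patch (default 0.5, i.e. 1:1).
#' @param anchors anchor sizes (mm); stride fixed at 4.
#' @param augment apply [augment_patch()] to nodule-centered crops.
#' @param seed RNG seed, or NULL to use the current stream.
#' @return list of samples: `patch`, `annotations` (patch frame), `labels`,
#'   `targets`, `positive`.
#' @export
sample_training_patches <- function(dataset, n, patch_size = 96, ratio = 0.5,
                                    anchors = c(5, 10, 20), augment = TRUE,
                                    seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  has_nodules <- vapply(dataset, function(s) nrow(s$annotations) > 0, logical(1))
  if (!any(has_nodules))
    warning("dataset has no nodules; sampling negative patches only")
  grid <- anchor_grid(patch_size / 4, 4, anchors)
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    want_pos <- any(has_nodules) && runif(1) < ratio
    scan <- dataset[[if (want_pos) sample(which(has_nodules), 1) else
      sample(length(dataset), 1)]]
    vann <- annotations_to_voxel(scan$volume, scan$annotations)
    d <- dim(scan$volume$voxels)
    if (want_pos) {
      r <- sample(nrow(vann), 1)
      ctr <- c(vann$vz[r], vann$vy[r], vann$vx[r])
      margin <- vann$diameter[r] / 2 + 2
      jit_max <- pmax(patch_size / 2 - margin, 0)
      ctr <- ctr + runif(3, -1, 1) * pmin(jit_max, patch_size / 4)
    } else {
      ctr <- c(runif(1, 0, d[1]), runif(1, 0, d[2]), runif(1, 0, d[3]))
    }
    cp <- crop_patch(scan$volume, ctr, patch_size, annotations = vann)
    patch <- cp$patch; ann <- cp$annotations
    if (want_pos && augment) {
      aug <- augment_patch(patch, ann)
      patch <- aug$patch; ann <- aug$annotations
    }
    labels <- assign_labels(grid, ann)
    targets <- make_regression_targets(grid, labels, ann)
    samples[[i]] <- list(patch = patch, annotations = ann, labels = labels,
                         targets = targets, positive = want_pos)
  }
  samples
}

#' Deterministic k-fold split of series ids
#'
#' Disjoint, exhaustive, size-balanced to within one scan, shuffled by the
#' seed.
#'
#' @param series_ids character vector of scan ids.
#' @param k fold count (`k <= length(series_ids)`).
#' @param seed RNG seed.
#' @return A tibble `series_id, fold` (folds 1..k).
#' @export
make_folds <- function(series_ids, k = 10, seed = 1) {
  stopifnot(k <= length(series_ids))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  ids <- sample(series_ids)
  tibble::tibble(series_id = ids,
                 fold = rep_len(seq_len(k), length(ids))) |>
    dplyr::arrange(.data$series_id)
}

#' Train the candidate detector
#'
#' Plain SGD over patches drawn by [sample_training_patches()]; the
#' classification term samples `min(64, 2 n_pos + 32)` negative anchors per
#' patch. Intended for desk-scale runs (small patches, thin networks); the
#' full-profile schedule is configured by [train_config()] but needs
#' GPU-scale data and compute.
#'
#' @param net a [build_detector()] network.
#' @param dataset preprocessed scans (see [sample_training_patches()]).
#' @param steps SGD steps.
#' @param batch_size patches per step.
#' @param lr learning rate (scalar, or vector of per-step rates).
#' @param config a [train_config()] for momentum/weight decay.
#' @param swa_from average the weights over steps `swa_from..steps` (tail
#'   Polyak averaging) and install the average at the end; NULL disables.
#'   Cuts the run-to-run variance of short small-batch SGD.
#' @param seed run seed.
#' @param verbose print progress every 25 steps.
#' @return list with `net` and `log` (tibble: step, loss, cls, reg, n_pos).
#' @export
train_detector <- function(net, dataset, steps = 150, batch_size = 4,
                           lr = 0.01, config = train_config(),
                           swa_from = NULL, seed = 1, verbose = FALSE) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  cfg <- net$config
  lr <- rep_len(lr, steps)
  log <- vector("list", steps)
  swa <- NULL
  for (s in seq_len(steps)) {
    batch <- sample_training_patches(dataset, batch_size, cfg$input_size,
                                     anchors = cfg$anchors)
    nn_zero_grad(net)
    tot <- cls <- reg <- np <- 0
    grid <- anchor_grid(cfg$input_size / 4, 4, cfg$anchors)
    for (b in batch) {
      outp <- detector_forward(net, normalize_patch(b$patch), training = TRUE)
      l <- detector_loss(outp, grid, b$labels, b$targets)
      detector_backward(net, l$dout / batch_size)
      tot <- tot + l$loss / batch_size
      cls <- cls + l$cls_loss / batch_size
      reg <- reg + l$reg_loss / batch_size
      np <- np + l$n_pos
    }
    sgd_step(net, lr[s], config$momentum, config$weight_decay)
    if (!is.null(swa_from) && s >= swa_from) {
      if (is.null(swa)) swa <- swa_init(net)
      swa <- swa_accumulate(net, swa, s - swa_from + 1)
    }
    log[[s]] <- tibble::tibble(step = s, loss = tot, cls = cls, reg = reg,
                               n_pos = np, lr = lr[s])
    if (verbose && s %% 25 == 0)
      message(sprintf("step %d: loss %.4f (cls %.4f reg %.4f)", s, tot, cls, reg))
  }
  if (!is.null(swa)) swa_apply(net, swa)
  list(net = net, log = dplyr::bind_rows(log))
}

#' Build the false-positive-reduction training set
#'
#' Labels each detection-stage candidate by the hit criterion (1 iff it
#' hits an annotation under [match_hits()]) and prepares cube crops at the
#' candidate centers.
#'
#' @param candidates candidate tibble from the detection stage.
#' @param annotations reference annotations.
#' @param volumes named list (by series id) of preprocessed [volume()]s.
#' @param cube_size cube edge (voxels) fed to the network.
#' @param fov_mm physical crop size (mm), resampled down to `cube_size` when
#'   larger (see [rescore_with_fpr()]); defaults to `cube_size`.
#' @param annotation_positives also include cubes cropped at the reference
#'   annotation centers (plus `jitter_copies` randomly jittered copies of
#'   each) as positive examples — the labelled positives the reference
#'   standard itself provides, which matters when the detector yields few
#'   positive candidates.
#' @param jitter_copies jittered copies per annotation (jitter up to 1/6 of
#'   the diameter per axis).
#' @return A tibble `series_id, x, y, z, probability, label` plus a
#'   list-column `cube` of normalized arrays.
#' @export
train_fpr_dataset <- function(candidates, annotations, volumes,
                              cube_size = 48, fov_mm = NULL,
                              annotation_positives = FALSE,
                              jitter_copies = 3) {
  m <- match_hits(candidates, annotations)
  cand <- m$candidates
  cubes <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    vol <- volumes[[cand$series_id[i]]]
    vox <- world_to_voxel(vol, c(cand$x[i], cand$y[i], cand$z[i]))
    cubes[[i]] <- fpr_cube(vol, vox, cube_size, fov_mm)
  }
  cand$label <- as.integer(cand$is_tp)
  cand$cube <- cubes
  if (annotation_positives && nrow(annotations)) {
    extra <- list()
    for (r in seq_len(nrow(annotations))) {
      a <- annotations[r, ]
      vol <- volumes[[a$series_id]]
      if (is.null(vol)) next
      for (j in 0:jitter_copies) {
        jit <- if (j == 0) c(0, 0, 0) else runif(3, -1, 1) * a$diameter / 6
        vox <- world_to_voxel(vol, c(a$x, a$y, a$z)) + jit
        extra[[length(extra) + 1]] <- tibble::tibble(
          series_id = a$series_id, x = a$x, y = a$y, z = a$z,
          diameter = a$diameter, probability = 1, is_tp = TRUE,
          matched_ann = NA_integer_, label = 1L,
          cube = list(fpr_cube(vol, vox, cube_size, fov_mm)))
      }
    }
    cand <- dplyr::bind_rows(cand, dplyr::bind_rows(extra))
  }
  cand
}


#' Train the false-positive-reduction classifier
#'
#' SGD on binary cross-entropy over labelled candidate cubes; positive
#' cubes are augmented by random flips. Classes are sampled in balance when
#' both are present. After `mine_after` steps the remaining steps draw half
#' of their negatives from the currently highest-scoring (hardest)
#' negatives — the bootstrapped hard-negative emphasis that false-positive
#' reduction stages rely on when easy negatives dominate the candidate
#' pool. Set `mine_after = NULL` to disable.
#'
#' @param net a [build_fpr()] network.
#' @param fpr_data output of [train_fpr_dataset()].
#' @param steps SGD steps.
#' @param batch_size cubes per step.
#' @param lr learning rate (scalar or per-step vector).
#' @param config a [train_config()].
#' @param mine_after step after which hard-negative mining starts
#'   (default: halfway).
#' @param mine_sample at most this many negatives are scored when the hard
#'   set is formed (bounds the mining cost).
#' @param swa_from tail weight averaging start step (see [train_detector()]);
#'   NULL disables.
#' @param seed run seed.
#' @return list with `net` and `log`.
#' @export
train_fpr <- function(net, fpr_data, steps = 100, batch_size = 8, lr = 0.01,
                      config = train_config(), mine_after = floor(steps / 2),
                      mine_sample = 600, swa_from = NULL, seed = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  pos <- which(fpr_data$label == 1)
  neg <- which(fpr_data$label == 0)
  hard <- integer()
  lr <- rep_len(lr, steps)
  log <- vector("list", steps)
  swa <- NULL
  for (s in seq_len(steps)) {
    if (!is.null(mine_after) && s == mine_after + 1 && length(neg) > batch_size) {
      pool <- if (length(neg) > mine_sample) sample(neg, mine_sample) else neg
      p_neg <- vapply(pool, function(i)
        fpr_probability(net, fpr_data$cube[[i]]), numeric(1))
      hard <- pool[order(-p_neg)][seq_len(min(length(pool),
                                              max(50, length(pool) %/% 10)))]
    }
    n_neg_take <- floor(batch_size / 2)
    neg_take <- if (length(hard)) {
      nh <- ceiling(n_neg_take / 2)
      c(sample(hard, nh, replace = TRUE),
        if (length(neg)) sample(neg, n_neg_take - nh, replace = TRUE))
    } else if (length(neg)) sample(neg, n_neg_take, replace = TRUE)
    take <- c(if (length(pos)) sample(pos, ceiling(batch_size / 2), replace = TRUE),
              neg_take)
    nn_zero_grad(net)
    tot <- 0
    for (i in take) {
      cube <- fpr_data$cube[[i]]
      if (fpr_data$label[i] == 1) {
        cube <- augment_patch(cube, scale = 1)$patch
      }
      z <- fpr_forward(net, cube, training = TRUE)
      p <- 1 / (1 + exp(-z))
      tot <- tot + classification_loss(p, fpr_data$label[i]) / length(take)
      fpr_backward(net, (p - fpr_data$label[i]) / length(take))
    }
    sgd_step(net, lr[s], config$momentum, config$weight_decay)
    if (!is.null(swa_from) && s >= swa_from) {
      if (is.null(swa)) swa <- swa_init(net)
      swa <- swa_accumulate(net, swa, s - swa_from + 1)
    }
    log[[s]] <- tibble::tibble(step = s, loss = tot, lr = lr[s])
  }
  if (!is.null(swa)) swa_apply(net, swa)
  list(net = net, log = dplyr::bind_rows(log))
}
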
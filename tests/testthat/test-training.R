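test_that("learning-rate schedules follow the printed milestones", {
  cfg <- train_config()
  expect_equal(lr_at_epoch(cfg, "detector", 0), 0.01)
  expect_equal(lr_at_epoch(cfg, "detector", 49), 0.01)
  expect_equal(lr_at_epoch(cfg, "detector", 50), 0.001)
  expect_equal(lr_at_epoch(cfg, "fpr", 39), 0.01)
  expect_equal(lr_at_epoch(cfg, "fpr", 40), 0.001)
  expect_equal(lr_at_epoch(cfg, "fpr", 85), 1e-4)
  # schedules are non-increasing
  for (k in c("detector", "fpr")) {
    lrs <- vapply(0:99, function(e) lr_at_epoch(cfg, k, e), numeric(1))
    expect_true(all(diff(lrs) <= 0))
  }
})

test_that("augment_patch transforms patch and annotations consistently", {
  set.seed(40)
  patch <- array(runif(16^3, 0, 255), c(16, 16, 16))
  ann <- tibble::tibble(vz = 4, vy = 8, vx = 12, diameter = 8)
  # pinned no-op
  id <- augment_patch(patch, ann, flip = c(FALSE, FALSE, FALSE), scale = 1)
  expect_identical(id$patch, patch)
  expect_identical(id$annotations, ann)
  # flip along z mirrors the voxel coordinate, diameter unchanged
  fl <- augment_patch(patch, ann, flip = c(TRUE, FALSE, FALSE), scale = 1)
  expect_equal(fl$annotations$vz, 15 - 4)
  expect_equal(fl$annotations$diameter, 8)
  expect_equal(fl$patch[1, , ], patch[16, , ])
  # scale 1.25 turns an 8 mm nodule into 10 mm
  sc <- augment_patch(patch, ann, flip = c(FALSE, FALSE, FALSE), scale = 1.25)
  expect_equal(sc$annotations$diameter, 10)
  # center stays fixed under scaling
  ctr_ann <- tibble::tibble(vz = 7.5, vy = 7.5, vx = 7.5, diameter = 8)
  sc2 <- augment_patch(patch, ctr_ann, flip = c(FALSE, FALSE, FALSE),
                       scale = 1.2)
  expect_equal(sc2$annotations$vz, 7.5)
})

test_that("patch sampling yields positive anchors for nodule-centered crops", {
  scan <- list(volume = desk_preprocessed(), annotations = desk_phantom()$annotations)
  smp <- sample_training_patches(list(scan), n = 6, patch_size = 32,
                                 ratio = 1, seed = 3)
  for (s in smp) {
    expect_gte(sum(s$labels$p_star == 1, na.rm = TRUE), 1)
    expect_equal(dim(s$patch), c(32, 32, 32))
  }
  # negatives-only stream from a nodule-free dataset, with a warning
  empty <- list(volume = desk_preprocessed(),
                annotations = desk_phantom()$annotations[0, ])
  expect_warning(neg <- sample_training_patches(list(empty), n = 3,
                                                patch_size = 32, seed = 3),
                 "no nodules")
  for (s in neg) expect_equal(sum(s$labels$p_star == 1, na.rm = TRUE), 0)
  # determinism per seed
  a <- sample_training_patches(list(scan), n = 3, patch_size = 32, seed = 5)
  b <- sample_training_patches(list(scan), n = 3, patch_size = 32, seed = 5)
  expect_identical(a[[2]]$patch, b[[2]]$patch)
  expect_identical(a[[2]]$labels$p_star, b[[2]]$labels$p_star)
})

test_that("make_folds is disjoint, exhaustive and balanced", {
  ids <- sprintf("s%03d", 1:10)
  f <- make_folds(ids, k = 10, seed = 1)
  expect_true(all(table(f$fold) == 1))
  ids2 <- sprintf("s%04d", 1:888)
  f2 <- make_folds(ids2, k = 10, seed = 2)
  expect_setequal(f2$series_id, ids2)
  expect_equal(nrow(f2), 888)
  sizes <- as.vector(table(f2$fold))
  expect_true(all(sizes %in% c(88, 89)))
  # deterministic per seed
  expect_identical(make_folds(ids2, k = 10, seed = 2), f2)
  expect_false(identical(make_folds(ids2, k = 10, seed = 3), f2))
})

test_that("train_fpr_dataset labels candidates by the hit criterion", {
  vol <- desk_preprocessed()
  ann <- desk_phantom()$annotations
  sid <- ann$series_id[1]
  hit <- make_candidates(sid, ann$x[1], ann$y[1], ann$z[1], 8, 0.9)
  miss <- make_candidates(sid, ann$x[1] + 40, ann$y[1], ann$z[1], 8, 0.8)
  data <- train_fpr_dataset(dplyr::bind_rows(hit, miss), ann,
                            setNames(list(vol), sid), cube_size = 16)
  expect_equal(sort(data$label), c(0, 1))
  expect_equal(dim(data$cube[[1]]), c(16, 16, 16))
  # label balance matches a hand count on a 10-candidate fixture
  cand10 <- dplyr::bind_rows(lapply(1:10, function(i) {
    on_nodule <- i <= 4
    j <- ((i - 1) %% nrow(ann)) + 1
    make_candidates(sid, ann$x[j] + ifelse(on_nodule, 0, 35),
                    ann$y[j], ann$z[j], 8, runif(1))
  }))
  d10 <- train_fpr_dataset(cand10, ann, setNames(list(vol), sid),
                           cube_size = 16)
  expect_equal(sum(d10$label), 3)   # 4 on-nodule candidates, 3 distinct nodules
})

test_that("a short toy training run halves the detector loss", {
  set.seed(41)
  scan <- list(volume = desk_preprocessed(),
               annotations = desk_phantom()$annotations)
  cfg <- detector_config(input_size = 16, widths = c(4, 4, 4, 8, 8),
                         blocks_per_stage = 1, decoder_blocks = 1,
                         decoder_channels = 8, k_att = 3)
  net <- build_detector(cfg)
  tr <- train_detector(net, list(scan), steps = 120, batch_size = 2,
                       lr = c(rep(0.01, 80), rep(0.001, 40)), seed = 4)
  first <- mean(head(tr$log$loss, 5))
  last <- mean(tail(tr$log$loss, 5))
  expect_lt(last, 0.5 * first)
})

test_that("FPR training separates nodule cubes from background cubes", {
  set.seed(42)
  vol <- desk_preprocessed()
  ann <- desk_phantom()$annotations
  sid <- ann$series_id[1]
  # candidates: the true nodules plus random background spots
  pos <- make_candidates(sid, ann$x, ann$y, ann$z, ann$diameter, 0.9)
  d <- dim(vol$voxels)
  bg_vox <- cbind(runif(6, 8, d[1] - 8), runif(6, 8, d[2] - 8),
                  runif(6, 8, d[3] - 8))
  bg_w <- voxel_to_world(vol, bg_vox)
  neg <- make_candidates(sid, bg_w[, 1], bg_w[, 2], bg_w[, 3], 8, 0.5)
  neg <- match_hits(neg, ann)$candidates
  neg <- neg[!neg$is_tp, names(pos)]
  data <- train_fpr_dataset(dplyr::bind_rows(pos, neg), ann,
                            setNames(list(vol), sid), cube_size = 16)
  net <- build_fpr(desk_fpr_config())
  tr <- train_fpr(net, data, steps = 60, batch_size = 6, lr = 0.01, seed = 5)
  p_pos <- vapply(which(data$label == 1),
                  function(i) fpr_probability(net, data$cube[[i]]), numeric(1))
  p_neg <- vapply(which(data$label == 0),
                  function(i) fpr_probability(net, data$cube[[i]]), numeric(1))
  expect_gt(mean(p_pos), mean(p_neg))
})
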
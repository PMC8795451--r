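test_that("filter_and_nms applies the strict 0.12 cut and greedy suppression", {
  cand <- make_candidates("s", c(0, 0, 30), c(0, 0, 0), c(0, 0, 0),
                          c(10, 10, 10), c(0.9, 0.8, 0.12))
  out <- filter_and_nms(cand)
  # coincident pair keeps only the stronger; p = 0.12 exactly is dropped
  expect_equal(nrow(out), 1)
  expect_equal(out$probability, 0.9)
  # IoU below the threshold keeps both
  cand2 <- make_candidates("s", c(0, 9), c(0, 0), c(0, 0), c(10, 10),
                           c(0.9, 0.8))
  expect_lt(iou3d(c(0, 0, 0), 10, c(9, 0, 0), 10), 0.1)
  expect_equal(nrow(filter_and_nms(cand2)), 2)
  # idempotence
  once <- filter_and_nms(cand2)
  expect_equal(filter_and_nms(once), once)
})

test_that("greedy NMS equals the exhaustive fixed-point oracle", {
  set.seed(30)
  for (rep in 1:5) {
    n <- sample(4:7, 1)
    cand <- make_candidates("s", runif(n, 0, 15), runif(n, 0, 15),
                            runif(n, 0, 15), runif(n, 6, 14),
                            round(runif(n, 0.2, 0.99), 3))
    got <- filter_and_nms(cand, prob_threshold = 0, iou_threshold = 0.1)
    oracle <- nms_exhaustive_oracle(cand, 0.1)
    expect_equal(dplyr::arrange(got, .data$probability)$x,
                 dplyr::arrange(oracle, .data$probability)$x)
  }
})

test_that("match_hits uses the center-within-radius criterion, single match", {
  ann <- make_annotations("s", 0, 0, 0, 10)
  # candidate exactly at the center -> TP
  m <- match_hits(make_candidates("s", 0, 0, 0, 8, 0.9), ann)
  expect_true(m$candidates$is_tp)
  # candidate 6 mm from a 10 mm nodule (radius 5) -> FP
  m2 <- match_hits(make_candidates("s", 6, 0, 0, 8, 0.9), ann)
  expect_false(m2$candidates$is_tp)
  # two candidates hitting one annotation -> one TP (higher p) + one FP
  m3 <- match_hits(make_candidates("s", c(1, -1), c(0, 0), c(0, 0),
                                   c(8, 8), c(0.7, 0.9)), ann)
  expect_equal(sum(m3$candidates$is_tp), 1)
  expect_true(m3$candidates$is_tp[m3$candidates$probability == 0.9])
  # cross-series candidates never match
  m4 <- match_hits(make_candidates("other", 0, 0, 0, 8, 0.9), ann)
  expect_false(m4$candidates$is_tp)
})

test_that("sensitivity is TP/(TP+FN) with a guarded denominator", {
  expect_equal(sensitivity(9, 1), 0.9)
  expect_equal(sensitivity(0, 5), 0)
  expect_equal(sensitivity(5, 0), 1)
  expect_error(sensitivity(0, 0), "undefined")
})

test_that("froc reproduces hand-computed operating points and CPM", {
  # 2 scans, 4 nodules; candidates constructed so the threshold sweep is
  # fully known: hits at p .9/.8/.6/.3, FPs at p .7/.5/.4/.2 x2
  ann <- make_annotations(rep(c("a", "b"), each = 2),
                          c(0, 50, 0, 50), c(0, 0, 0, 0), c(0, 0, 0, 0),
                          rep(10, 4))
  cand <- dplyr::bind_rows(
    make_candidates("a", c(0, 50), 0, 0, 8, c(0.9, 0.8)),
    make_candidates("b", c(0, 50), 0, 0, 8, c(0.6, 0.3)),
    make_candidates("a", c(100, 120, 140), 0, 0, 8, c(0.7, 0.5, 0.2)),
    make_candidates("b", c(100, 120, 140), 0, 0, 8, c(0.7, 0.4, 0.2)))
  fc <- froc(cand, ann, n_scans = 2)
  # threshold .8: 2 hits, 0 FP -> sens .5 up to 0.5 FP/scan
  # threshold .6: 3 hits, 1 FP/scan; threshold .3: 4 hits, 2 FP/scan
  expect_equal(fc$points$sensitivity, c(0.5, 0.5, 0.5, 0.75, 1, 1, 1))
  expect_equal(fc$cpm, mean(c(0.5, 0.5, 0.5, 0.75, 1, 1, 1)))
  # every annotation hit by a p=1 candidate, no FPs -> all ones
  perfect <- make_candidates(ann$series_id, ann$x, ann$y, ann$z, 8, 1)
  fp <- froc(perfect, ann, n_scans = 2)
  expect_true(all(fp$points$sensitivity == 1))
  expect_equal(fp$cpm, 1)
  expect_error(froc(cand, ann[0, ]), "zero annotations")
})

test_that("froc sensitivities are monotone and cpm is their exact mean", {
  set.seed(31)
  ann <- make_annotations(rep(letters[1:4], each = 3), runif(12, 0, 100),
                          runif(12, 0, 100), runif(12, 0, 100),
                          runif(12, 5, 15))
  cand <- dplyr::bind_rows(
    make_candidates(ann$series_id, ann$x + rnorm(12), ann$y, ann$z, 8,
                    runif(12)),
    make_candidates(rep(letters[1:4], each = 10), runif(40, 200, 400),
                    runif(40, 0, 100), runif(40, 0, 100), 8, runif(40)))
  fc <- froc(cand, ann, n_scans = 4)
  expect_true(all(diff(fc$points$sensitivity) >= 0))
  expect_equal(fc$cpm, mean(fc$points$sensitivity), tolerance = 1e-12)
  expect_equal(cpm(fc), fc$cpm)
})

test_that("bootstrap band brackets the point estimate", {
  set.seed(32)
  ann <- make_annotations(rep(letters[1:5], each = 2), runif(10, 0, 100),
                          runif(10, 0, 100), runif(10, 0, 100), 10)
  cand <- dplyr::bind_rows(
    make_candidates(ann$series_id, ann$x, ann$y, ann$z, 8,
                    runif(10, 0.5, 1)),
    make_candidates(rep(letters[1:5], 3), runif(15, 200, 300),
                    runif(15, 0, 100), runif(15, 0, 100), 8,
                    runif(15, 0, 0.6)))
  fc <- froc(cand, ann, n_scans = 5, n_bootstrap = 200, seed = 7)
  expect_false(is.null(fc$band))
  expect_lte(fc$band$cpm[[1]], fc$cpm + 1e-9)
  expect_gte(fc$band$cpm[[2]], fc$cpm - 1e-9)
  td <- tidy(fc)
  expect_true(all(c("lower", "upper") %in% names(td)))
  gl <- glance(fc)
  expect_equal(gl$cpm, fc$cpm)
})

test_that("size-stratified CPM respects the bin edges and reduces to global", {
  ann <- make_annotations("a", c(0, 50, 100), 0, 0, c(4, 5, 25))
  cand <- make_candidates("a", c(0, 50, 100), 0, 0, 8, c(0.9, 0.8, 0.7))
  out <- size_stratified_cpm(cand, ann, n_scans = 1)
  expect_setequal(out$bin, c("small", "medium", "large"))
  # the 5.0 mm nodule falls in the medium bin
  expect_equal(out$n_nodules[out$bin == "medium"], 1)
  # all annotations in one bin: bin CPM equals the global CPM
  ann_m <- make_annotations("a", c(0, 50), 0, 0, c(8, 12))
  cand_m <- make_candidates("a", c(0, 120, 50), 0, 0, 8, c(0.9, 0.5, 0.8))
  global <- froc(cand_m, ann_m, n_scans = 1)$cpm
  strat <- size_stratified_cpm(cand_m, ann_m, n_scans = 1)
  expect_equal(nrow(strat), 1)
  expect_equal(strat$cpm, global)
  # per-bin hand count on a 6-nodule fixture: small nodules missed,
  # medium/large hit with no FPs -> cpm 0 / 1 / 1
  ann6 <- make_annotations("a", seq(0, 250, by = 50), 0, 0,
                           c(3, 4, 8, 12, 22, 26))
  cand6 <- make_candidates("a", seq(100, 250, by = 50), 0, 0, 8,
                           c(0.9, 0.85, 0.8, 0.75))
  s6 <- size_stratified_cpm(cand6, ann6, n_scans = 1)
  expect_equal(s6$cpm[s6$bin == "small"], 0)
  expect_equal(s6$cpm[s6$bin == "medium"], 1)
  expect_equal(s6$cpm[s6$bin == "large"], 1)
})

test_that("tile_starts covers every voxel for volumes >= one patch", {
  for (n in c(32, 33, 40, 56, 57, 96, 100)) {
    s <- nodulemsa:::tile_starts(n, 32, 24)
    covered <- sort(unique(unlist(lapply(s, function(z) z + 0:31))))
    expect_equal(covered, 0:(n - 1))
    expect_true(all(s + 32 <= n))
  }
  expect_equal(nodulemsa:::tile_starts(20, 32, 24), 0L)
})

test_that("sliding window on a constant volume respects the threshold gate", {
  set.seed(33)
  net <- build_detector(desk_detector_config())
  nodulemsa:::zero_weights(net$children$head)
  vol <- volume(array(170, c(40, 40, 40)), unit = "normalized_0_255")
  # head zeroed -> all logits 0 -> p = 0.5 everywhere; a 0.5 gate drops all
  out <- sliding_window_detect(net, vol, prob_threshold = 0.5)
  expect_equal(nrow(out), 0)
  out2 <- sliding_window_detect(net, vol, prob_threshold = 0.4)
  expect_gt(nrow(out2), 0)
  expect_true(all(out2$probability == 0.5))
})

test_that("rescoring preserves candidate count and membership", {
  set.seed(34)
  net <- build_fpr(desk_fpr_config())
  vol <- volume(array(runif(32^3, 0, 255), c(32, 32, 32)),
                unit = "normalized_0_255")
  cand <- make_candidates("s", c(5, 15, 25), c(5, 15, 25), c(5, 15, 25),
                          10, c(0.2, 0.5, 0.9))
  out <- rescore_with_fpr(cand, vol, net)
  expect_equal(nrow(out), 3)
  expect_setequal(out$x, cand$x)
  expect_true(all(out$probability > 0 & out$probability < 1))
  expect_equal(nrow(rescore_with_fpr(cand[0, ], vol, net)), 0)
})
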
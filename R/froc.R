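# Hit matching, FROC / CPM evaluation, bootstrap confidence bands.

#' Match candidates against reference annotations
#'
#' The hit criterion is the LUNA16 convention: a candidate hits an
#' annotation when the Euclidean distance between their centers is at most
#' the annotation's radius (`radius_multiplier * diameter / 2`); the
#' predicted diameter plays no role. Each annotation is matched at most
#' once, to its highest-probability hitting candidate; all remaining
#' candidates are false positives, unhit annotations are false negatives.
#'
#' @param candidates candidate tibble (world mm, with `probability`).
#' @param annotations annotation tibble (world mm).
#' @param radius_multiplier scales the hit radius (default 1).
#' @return list with `candidates` (input + logical `is_tp` + `matched_ann`
#'   row index) and `annotations` (input + logical `hit` + `hit_probability`).
#' @export
match_hits <- function(candidates, annotations, radius_multiplier = 1) {
  cand <- dplyr::arrange(candidates, dplyr::desc(.data$probability),
                         .data$x, .data$y, .data$z)
  cand$is_tp <- FALSE
  cand$matched_ann <- NA_integer_
  ann <- annotations
  ann$hit <- FALSE
  ann$hit_probability <- NA_real_
  if (nrow(cand) && nrow(ann)) {
    for (i in seq_len(nrow(cand))) {
      same <- which(ann$series_id == cand$series_id[i] & !ann$hit)
      if (!length(same)) next
      dist <- sqrt((ann$x[same] - cand$x[i])^2 + (ann$y[same] - cand$y[i])^2 +
                     (ann$z[same] - cand$z[i])^2)
      r <- radius_multiplier * ann$diameter[same] / 2
      hits <- which(dist <= r)
      if (length(hits)) {
        j <- same[hits[which.min(dist[hits])]]
        cand$is_tp[i] <- TRUE
        cand$matched_ann[i] <- j
        ann$hit[j] <- TRUE
        ann$hit_probability[j] <- cand$probability[i]
      }
    }
  }
  list(candidates = cand, annotations = ann)
}

#' Detection sensitivity
#'
#' `TP / (TP + FN)`: the fraction of reference nodules detected.
#'
#' @param tp,fn true-positive and false-negative counts; `tp + fn > 0`.
#' @return Fraction in `[0, 1]`.
#' @export
sensitivity <- function(tp, fn) {
  if (tp + fn <= 0) stop("sensitivity undefined: no positive nodules (TP + FN = 0)")
  tp / (tp + fn)
}

#' Free-response ROC curve and CPM score
#'
#' Matches candidates globally ([match_hits()]), sweeps the probability
#' threshold, and reads off sensitivity at the seven operating false
#' positive rates 0.125, 0.25, 0.5, 1, 2, 4 and 8 FP/scan using step-wise
#' interpolation: the sensitivity at an abscissa is that of the lowest
#' threshold whose mean FP/scan does not exceed it. The CPM (competition
#' performance metric) is the arithmetic mean of the seven sensitivities.
#' Optionally a scan-level bootstrap (resampling scans with replacement)
#' yields a percentile 95% confidence band.
#'
#' @param candidates candidate tibble across scans (world mm).
#' @param annotations annotation tibble across the same scans; must contain
#'   at least one nodule.
#' @param n_scans number of scans evaluated; defaults to the number of
#'   distinct series among annotations and candidates.
#' @param fp_per_scan operating abscissae.
#' @param n_bootstrap bootstrap resamples (0 = none; the paper-scale setting
#'   is 1000).
#' @param seed RNG seed for the bootstrap.
#' @param radius_multiplier hit-radius scaling, see [match_hits()].
#' @return A `froc` object: operating points, `cpm`, per-scan counts, and
#'   optionally `band` (per-abscissa 2.5% / 97.5% sensitivity quantiles and
#'   the CPM band).
#' @export
froc <- function(candidates, annotations, n_scans = NULL,
                 fp_per_scan = c(0.125, 0.25, 0.5, 1, 2, 4, 8),
                 n_bootstrap = 0, seed = 1, radius_multiplier = 1) {
  if (nrow(annotations) == 0)
    stop("FROC undefined: zero annotations (sensitivity has no denominator)")
  series <- unique(c(annotations$series_id, candidates$series_id))
  if (is.null(n_scans)) n_scans <- length(series)
  m <- match_hits(candidates, annotations, radius_multiplier)
  pts <- froc_points(m$candidates, m$annotations, n_scans, fp_per_scan)
  band <- NULL
  if (n_bootstrap > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    sens_bs <- matrix(NA_real_, n_bootstrap, length(fp_per_scan))
    cpm_bs <- numeric(n_bootstrap)
    cand_by <- split(m$candidates, m$candidates$series_id)
    ann_by <- split(m$annotations, m$annotations$series_id)
    for (b in seq_len(n_bootstrap)) {
      take <- sample(series, n_scans, replace = TRUE)
      cb <- dplyr::bind_rows(cand_by[take])
      ab <- dplyr::bind_rows(ann_by[take])
      if (is.null(ab) || !nrow(ab)) { cpm_bs[b] <- NA; next }
      pb <- froc_points(cb, ab, n_scans, fp_per_scan)
      sens_bs[b, ] <- pb$sensitivity
      cpm_bs[b] <- mean(pb$sensitivity)
    }
    qs <- apply(sens_bs, 2, quantile, probs = c(0.025, 0.975), na.rm = TRUE)
    band <- list(lower = qs[1, ], upper = qs[2, ],
                 cpm = quantile(cpm_bs, c(0.025, 0.975), na.rm = TRUE))
  }
  structure(list(points = pts, cpm = mean(pts$sensitivity),
                 n_scans = n_scans,
                 n_annotations = nrow(annotations),
                 tp = sum(m$annotations$hit),
                 fn = sum(!m$annotations$hit),
                 fp = sum(!m$candidates$is_tp),
                 band = band,
                 matched = m),
            class = "froc")
}

# Operating points from matched candidates/annotations: step-wise threshold
# sweep. A hit annotation is detected at threshold t iff its matching
# candidate has probability >= t; FP/scan counts unmatched candidates with
# probability >= t.
froc_points <- function(cand, ann, n_scans, fp_per_scan) {
  n_ann <- nrow(ann)
  th <- sort(unique(cand$probability), decreasing = TRUE)
  if (!length(th)) {
    return(tibble::tibble(fp_per_scan = fp_per_scan, sensitivity = 0))
  }
  hit_p <- ann$hit_probability[ann$hit]
  fp_p <- cand$probability[!cand$is_tp]
  sens_at <- vapply(th, function(t) sum(hit_p >= t) / n_ann, numeric(1))
  fps_at <- vapply(th, function(t) sum(fp_p >= t) / n_scans, numeric(1))
  sens <- vapply(fp_per_scan, function(f) {
    ok <- which(fps_at <= f)
    if (!length(ok)) 0 else max(sens_at[ok])
  }, numeric(1))
  # enforce monotone non-decreasing in the abscissa
  sens <- cummax(sens)
  tibble::tibble(fp_per_scan = fp_per_scan, sensitivity = sens)
}

#' Competition performance metric
#'
#' The mean of the sensitivities at 0.125, 0.25, 0.5, 1, 2, 4 and 8
#' FP/scan. Accepts either a fitted [froc()] object or the seven operating
#' sensitivities directly.
#'
#' @param x a `froc` object or a numeric vector of operating sensitivities.
#' @return The CPM score in `[0, 1]`.
#' @examples
#' cpm(c(0.836, 0.898, 0.930, 0.945, 0.953, 0.962, 0.962))  # 0.927 (rounded)
#' @export
cpm <- function(x) UseMethod("cpm")

#' @exportS3Method
cpm.froc <- function(x) x$cpm

#' @exportS3Method
cpm.numeric <- function(x) mean(x)

#' @export
print.froc <- function(x, ...) {
  cat(sprintf("<froc> %d scans, %d nodules: TP %d, FN %d, FP %d\n",
              x$n_scans, x$n_annotations, x$tp, x$fn, x$fp))
  pts <- x$points
  cat("  sensitivity @ FP/scan:",
      paste(sprintf("%.3f@%.3g", pts$sensitivity, pts$fp_per_scan),
            collapse = " "), "\n")
  cat(sprintf("  CPM = %.4f", x$cpm))
  if (!is.null(x$band))
    cat(sprintf("  [95%% CI %.4f, %.4f]", x$band$cpm[1], x$band$cpm[2]))
  cat("\n")
  invisible(x)
}

#' @exportS3Method
tidy.froc <- function(x, ...) {
  out <- x$points
  if (!is.null(x$band)) {
    out$lower <- x$band$lower
    out$upper <- x$band$upper
  }
  out
}

#' @exportS3Method
glance.froc <- function(x, ...) {
  tibble::tibble(cpm = x$cpm, n_scans = x$n_scans,
                 n_annotations = x$n_annotations,
                 tp = x$tp, fn = x$fn, fp = x$fp,
                 cpm_low = if (is.null(x$band)) NA_real_ else x$band$cpm[[1]],
                 cpm_high = if (is.null(x$band)) NA_real_ else x$band$cpm[[2]])
}

#' @exportS3Method
autoplot.froc <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$fp_per_scan,
                                        y = .data$sensitivity)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10(breaks = df$fp_per_scan,
                           labels = signif(df$fp_per_scan, 3)) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "False positives per scan", y = "Sensitivity",
                  title = sprintf("FROC (CPM = %.3f)", object$cpm)) +
    ggplot2::theme_minimal()
  if (!is.null(object$band)) {
    p <- p + ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                               ymax = .data$upper),
                                  alpha = 0.2)
  }
  p
}

#' Size-stratified CPM
#'
#' Candidates are matched globally once; the FROC is then restricted to the
#' annotations of each diameter bin — small `[0, 5)` mm, medium `[5, 20]`
#' mm, large `(20, Inf)` mm by default. False positives (candidates hitting
#' no annotation at all) count against every bin. Empty bins are absent
#' from the result rather than an error.
#'
#' @param candidates,annotations as for [froc()].
#' @param breaks the two interior diameter cut points (mm).
#' @param n_scans number of scans; defaults as in [froc()].
#' @param fp_per_scan operating abscissae.
#' @return A tibble with one row per non-empty bin: `bin, n_nodules, cpm`.
#' @export
size_stratified_cpm <- function(candidates, annotations, breaks = c(5, 20),
                                n_scans = NULL,
                                fp_per_scan = c(0.125, 0.25, 0.5, 1, 2, 4, 8)) {
  series <- unique(c(annotations$series_id, candidates$series_id))
  if (is.null(n_scans)) n_scans <- length(series)
  m <- match_hits(candidates, annotations)
  bin_of <- function(d) ifelse(d < breaks[1], "small",
                               ifelse(d <= breaks[2], "medium", "large"))
  ann <- m$annotations
  ann$bin <- bin_of(ann$diameter)
  rows <- list()
  for (b in c("small", "medium", "large")) {
    ab <- ann[ann$bin == b, , drop = FALSE]
    if (!nrow(ab)) next
    # keep global FPs; drop candidates matched to other bins' annotations
    keep <- !m$candidates$is_tp |
      (m$candidates$matched_ann %in% which(ann$bin == b))
    cb <- m$candidates[keep, , drop = FALSE]
    pts <- froc_points(cb, ab, n_scans, fp_per_scan)
    rows[[b]] <- tibble::tibble(bin = b, n_nodules = nrow(ab),
                                cpm = mean(pts$sensitivity))
  }
  dplyr::bind_rows(rows)
}
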
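# Shared fixtures, built once per test run.

# a small desk-scale phantom + its preprocessed volume (memoised)
fixture_env <- new.env()

desk_phantom <- function(seed = 11) {
  key <- paste0("ph", seed)
  if (is.null(fixture_env[[key]]))
    fixture_env[[key]] <- generate_phantom(desk_phantom_spec(seed = seed))
  fixture_env[[key]]
}

desk_preprocessed <- function(seed = 11) {
  key <- paste0("pp", seed)
  if (is.null(fixture_env[[key]]))
    fixture_env[[key]] <- preprocess_scan(desk_phantom(seed)$volume)
  fixture_env[[key]]
}

# direct 6-nested-loop 3D convolution oracle (channels-last layout)
conv3d_oracle <- function(x, W, pad) {
  d <- dim(x); k <- dim(W)[1]; O <- dim(W)[5]
  y <- array(0, c(d[1:3], O))
  for (o in seq_len(O)) for (t3 in seq_len(d[3])) for (t2 in seq_len(d[2]))
    for (t1 in seq_len(d[1])) {
      s <- 0
      for (c in seq_len(d[4])) for (a in seq_len(k)) for (b in seq_len(k))
        for (dd in seq_len(k)) {
          u1 <- t1 + a - 1 - pad; u2 <- t2 + b - 1 - pad; u3 <- t3 + dd - 1 - pad
          if (u1 >= 1 && u1 <= d[1] && u2 >= 1 && u2 <= d[2] &&
              u3 >= 1 && u3 <= d[3])
            s <- s + x[u1, u2, u3, c] * W[a, b, dd, c, o]
        }
      y[t1, t2, t3, o] <- s
    }
  y
}

# Monte-Carlo / voxel-counting IoU oracle for axis-aligned cubes
iou3d_voxel_oracle <- function(ca, da, cb, db, res = 120) {
  lo <- pmin(ca - da / 2, cb - db / 2)
  hi <- pmax(ca + da / 2, cb + db / 2)
  # sample cell midpoints so boundary cells are counted half-and-half
  gs <- lapply(1:3, function(j) {
    h <- (hi[j] - lo[j]) / res
    seq(lo[j] + h / 2, hi[j] - h / 2, length.out = res)
  })
  ina <- outer(outer(abs(gs[[1]] - ca[1]) <= da / 2,
                     abs(gs[[2]] - ca[2]) <= da / 2),
               abs(gs[[3]] - ca[3]) <= da / 2)
  inb <- outer(outer(abs(gs[[1]] - cb[1]) <= db / 2,
                     abs(gs[[2]] - cb[2]) <= db / 2),
               abs(gs[[3]] - cb[3]) <= db / 2)
  sum(ina & inb) / sum(ina | inb)
}

# exhaustive NMS oracle: the unique subset S such that a candidate is kept
# iff its IoU with every higher-probability kept candidate is <= thr
nms_exhaustive_oracle <- function(cand, thr) {
  n <- nrow(cand)
  ord <- order(-cand$probability, cand$x, cand$y, cand$z)
  cand <- cand[ord, ]
  best <- NULL
  for (mask in 0:(2^n - 1)) {
    keep <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    ok <- TRUE
    for (i in seq_len(n)) {
      higher <- which(keep & seq_len(n) < i)
      ious <- if (length(higher))
        iou3d(matrix(unlist(cand[i, c("x", "y", "z")]), length(higher), 3,
                     byrow = TRUE), cand$diameter[i],
              as.matrix(cand[higher, c("x", "y", "z")]),
              cand$diameter[higher]) else numeric()
      should_keep <- all(ious <= thr)
      if (keep[i] != should_keep) { ok <- FALSE; break }
    }
    if (ok) { best <- cand[keep, ]; break }
  }
  best
}

make_candidates <- function(series, x, y, z, d, p) {
  tibble::tibble(series_id = series, x = x, y = y, z = z, diameter = d,
                 probability = p)
}

make_annotations <- function(series, x, y, z, d) {
  tibble::tibble(series_id = series, x = x, y = y, z = z, diameter = d)
}
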
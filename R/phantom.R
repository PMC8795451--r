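# Seeded synthetic CT phantoms: lung-shaped low-attenuation regions inside a
# soft-tissue body on an air background, spherical nodules with smooth
# (Gaussian-profile) edges, and vessel-like tube distractors, emitted with
# LUNA16-dialect annotations so the whole pipeline is testable without
# external data.

#' Specification of a synthetic CT phantom
#'
#' Defaults emulate thoracic CT at 1 mm isotropic spacing: air background
#' (-1000 HU), a soft-tissue body (+40 HU), two ellipsoidal lungs (-850 HU,
#' additive Gaussian noise sd 30 HU), solid nodules reaching +30 HU at their
#' center (ground-glass nodules -500 HU), and vessel-like tubes of radius
#' 1-3 mm at soft-tissue density. Nodule diameters are drawn log-uniformly
#' over `diameter_range` (default 3-28 mm, the LUNA16 span). Nodule centers
#' lie inside the lung ellipsoids with at least `min_lung_fraction` of the
#' sphere inside the lung, and are pairwise separated by at least the larger
#' of the two diameters.
#'
#' @param shape volume shape `(z, y, x)` voxels.
#' @param spacing voxel spacing `(z, y, x)` mm.
#' @param n_nodules nodule count per phantom.
#' @param diameter_range nodule diameter range, mm.
#' @param diameters optional explicit diameter vector (mm); overrides the
#'   sampler and `n_nodules`.
#' @param body_hu,lung_hu,air_hu,nodule_hu,gg_hu tissue attenuations (HU).
#' @param gg_fraction fraction of nodules rendered ground-glass.
#' @param noise_sd additive Gaussian noise sd (HU).
#' @param n_vessels vessel distractor count.
#' @param vessel_radius vessel radius range, mm.
#' @param min_lung_fraction minimum fraction of each nodule sphere inside
#'   the lung (keeps juxtapleural nodules mostly intrapulmonary).
#' @param randomize_origin draw a random world origin per scan (exercises
#'   coordinate handling).
#' @param seed RNG seed; the generator is deterministic for a fixed spec.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(160, 128, 128), spacing = c(1, 1, 1),
                         n_nodules = 3, diameter_range = c(3, 28),
                         diameters = NULL,
                         body_hu = 40, lung_hu = -850, air_hu = -1000,
                         nodule_hu = 30, gg_hu = -500, gg_fraction = 0.2,
                         noise_sd = 30, n_vessels = 6,
                         vessel_radius = c(1, 3), min_lung_fraction = 0.6,
                         randomize_origin = TRUE, seed = 1) {
  if (!is.null(diameters)) n_nodules <- length(diameters)
  structure(list(shape = shape, spacing = spacing, n_nodules = n_nodules,
                 diameter_range = diameter_range, diameters = diameters,
                 body_hu = body_hu,
                 lung_hu = lung_hu, air_hu = air_hu, nodule_hu = nodule_hu,
                 gg_hu = gg_hu, gg_fraction = gg_fraction,
                 noise_sd = noise_sd, n_vessels = n_vessels,
                 vessel_radius = vessel_radius,
                 min_lung_fraction = min_lung_fraction,
                 randomize_origin = randomize_origin, seed = seed),
            class = "phantom_spec")
}

#' Desk-scale phantom specification
#'
#' A scaled-down phantom for CPU-sized end-to-end experiments: 96^3 voxels,
#' two to three solid nodules in the 8-16 mm (medium-nodule) band, and four
#' vessel distractors. The shrunken detector's output grid cannot sub-voxel
#' localize 3 mm nodules, so the desk experiment deliberately uses the
#' medium band; the full-profile default keeps the 3-28 mm span.
#'
#' @param seed RNG seed.
#' @param n_nodules nodules per phantom.
#' @return A `phantom_spec`.
#' @export
desk_phantom_spec <- function(seed = 1, n_nodules = 3) {
  phantom_spec(shape = c(96, 96, 96), n_nodules = n_nodules,
               diameter_range = c(8, 16), gg_fraction = 0, n_vessels = 4,
               seed = seed)
}

# normalized ellipsoid "radius" field for one lung: <= 1 inside
ellipsoid_field <- function(shape, center, semi) {
  z <- ((seq_len(shape[1]) - 1) - center[1]) / semi[1]
  y <- ((seq_len(shape[2]) - 1) - center[2]) / semi[2]
  x <- ((seq_len(shape[3]) - 1) - center[3]) / semi[3]
  outer(outer(z^2, y^2, "+"), x^2, "+")
}

#' Generate one synthetic CT phantom
#'
#' Deterministic for a fixed spec (bit-identical volumes for the same seed).
#' Nodules are rendered with a Gaussian-profile edge: the added contrast at
#' radius `r` is `delta * pnorm((R - r) / w)` with edge width `w = 0.5` mm,
#' so the full-width-at-half-maximum of the radial profile equals the
#' annotated diameter `2R`. Placement uses rejection sampling; an infeasible
#' spec fails after 1000 attempts per nodule.
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` (HU [volume()]), `annotations` (tibble in
#'   world mm: `series_id, x, y, z, diameter`), and `lung_mask` (the
#'   ground-truth [lung_mask()]).
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  d <- spec$shape
  origin <- if (spec$randomize_origin) round(runif(3, -250, 0), 1) else c(0, 0, 0)
  vox <- array(spec$air_hu, d)

  # soft-tissue body: elliptic cylinder along z
  by <- (seq_len(d[2]) - 1 - (d[2] - 1) / 2) / (0.46 * d[2])
  bx <- (seq_len(d[3]) - 1 - (d[3] - 1) / 2) / (0.46 * d[3])
  body2d <- outer(by^2, bx^2, "+") <= 1
  zin <- seq_len(d[1]) > 1 & seq_len(d[1]) < d[1]
  body <- array(FALSE, d)
  body[zin, , ] <- rep(body2d, each = sum(zin))
  vox[body] <- spec$body_hu

  # two ellipsoidal lungs
  lungs <- list(
    list(center = c((d[1] - 1) / 2, (d[2] - 1) * 0.5, (d[3] - 1) * 0.30),
         semi = c(0.40 * d[1], 0.30 * d[2], 0.17 * d[3])),
    list(center = c((d[1] - 1) / 2, (d[2] - 1) * 0.5, (d[3] - 1) * 0.70),
         semi = c(0.40 * d[1], 0.30 * d[2], 0.17 * d[3]))
  )
  lung_field <- pmin(ellipsoid_field(d, lungs[[1]]$center, lungs[[1]]$semi),
                     ellipsoid_field(d, lungs[[2]]$center, lungs[[2]]$semi))
  lmask <- array(lung_field <= 1, d)
  vox[lmask] <- spec$lung_hu

  # vessel-like tubes: random walks rendered as stacked spheres, soft-tissue
  # density, clipped to the lung
  sp <- spec$spacing
  for (v in seq_len(spec$n_vessels)) {
    r_mm <- runif(1, spec$vessel_radius[1], spec$vessel_radius[2])
    repeat {
      start <- c(runif(1, 0, d[1] - 1), runif(1, 0, d[2] - 1), runif(1, 0, d[3] - 1))
      if (lung_field[round(start[1]) + 1, round(start[2]) + 1, round(start[3]) + 1] <= 0.7)
        break
    }
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    pos <- start
    for (step in seq_len(30)) {
      vox <- render_ball(vox, pos, 2 * r_mm, sp, spec$body_hu, lmask_only = lmask,
                         edge_w = 0.3)
      dir <- dir + rnorm(3, sd = 0.3); dir <- dir / sqrt(sum(dir^2))
      pos <- pos + dir * (1.2 * r_mm / sp)
      inb <- all(pos >= 0 & pos <= d - 1)
      if (!inb) break
      if (lung_field[round(pos[1]) + 1, round(pos[2]) + 1, round(pos[3]) + 1] > 1) break
    }
  }

  # nodules: rejection placement inside the lungs
  n <- spec$n_nodules
  centers <- matrix(NA_real_, n, 3)
  diams <- numeric(n)
  if (n > 0) {
    lr <- log(spec$diameter_range)
    for (i in seq_len(n)) {
      di <- if (!is.null(spec$diameters)) spec$diameters[i] else
        exp(runif(1, lr[1], lr[2]))
      ok <- FALSE
      for (attempt in seq_len(1000)) {
        cand <- c(runif(1, 0, d[1] - 1), runif(1, 0, d[2] - 1), runif(1, 0, d[3] - 1))
        if (lung_field[round(cand[1]) + 1, round(cand[2]) + 1, round(cand[3]) + 1] > 1)
          next
        if (sphere_lung_fraction(cand, di, sp, lmask) < spec$min_lung_fraction)
          next
        if (i > 1) {
          prev <- seq_len(i - 1)
          sep_mm <- sqrt(colSums((t(centers[prev, , drop = FALSE]) - cand)^2 * sp^2))
          if (any(sep_mm < pmax(diams[prev], di))) next
        }
        ok <- TRUE
        centers[i, ] <- cand
        diams[i] <- di
        break
      }
      if (!ok) stop("phantom nodule placement infeasible after 1000 attempts")
    }
    is_gg <- runif(n) < spec$gg_fraction
    for (i in seq_len(n)) {
      target <- if (is_gg[i]) spec$gg_hu else spec$nodule_hu
      vox <- render_ball(vox, centers[i, ], diams[i], sp, target, edge_w = 0.5)
    }
  }

  vox <- vox + rnorm(length(vox), sd = spec$noise_sd)
  dim(vox) <- d
  vol <- volume(vox, spacing = sp, origin = origin, unit = "HU")
  ann <- if (n > 0) {
    w <- voxel_to_world(vol, centers)
    tibble::tibble(series_id = sprintf("phantom-%06d", spec$seed),
                   x = w[, 1], y = w[, 2], z = w[, 3], diameter = diams)
  } else {
    tibble::tibble(series_id = character(), x = numeric(), y = numeric(),
                   z = numeric(), diameter = numeric())
  }
  list(volume = vol, annotations = ann, lung_mask = lung_mask(lmask))
}

# Add a smooth-edged ball of the given diameter (mm) at a voxel center:
# voxel value v -> max(v, target scaled by the Gaussian-profile edge).
render_ball <- function(vox, center, diameter, spacing, target_hu,
                        lmask_only = NULL, edge_w = 0.5) {
  d <- dim(vox)
  R <- diameter / 2
  ext <- ceiling((R + 3 * edge_w) / spacing)
  lo <- pmax(floor(center - ext), 0); hi <- pmin(ceiling(center + ext), d - 1)
  if (any(lo > hi)) return(vox)
  iz <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; ix <- lo[3]:hi[3]
  dz <- (iz - center[1]) * spacing[1]
  dy <- (iy - center[2]) * spacing[2]
  dx <- (ix - center[3]) * spacing[3]
  r <- sqrt(outer(outer(dz^2, dy^2, "+"), dx^2, "+"))
  frac <- pnorm((R - r) / edge_w)
  sub <- vox[iz + 1, iy + 1, ix + 1, drop = FALSE]
  cand <- sub * (1 - frac) + target_hu * frac
  upd <- pmax(sub, cand)
  if (!is.null(lmask_only)) {
    msub <- lmask_only[iz + 1, iy + 1, ix + 1, drop = FALSE]
    upd[!msub] <- sub[!msub]
  }
  vox[iz + 1, iy + 1, ix + 1] <- upd
  vox
}

sphere_lung_fraction <- function(center, diameter, spacing, lmask) {
  d <- dim(lmask)
  R <- diameter / 2
  ext <- ceiling(R / spacing)
  lo <- pmax(floor(center - ext), 0); hi <- pmin(ceiling(center + ext), d - 1)
  iz <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; ix <- lo[3]:hi[3]
  dz <- (iz - center[1]) * spacing[1]
  dy <- (iy - center[2]) * spacing[2]
  dx <- (ix - center[3]) * spacing[3]
  r2 <- outer(outer(dz^2, dy^2, "+"), dx^2, "+")
  inside <- r2 <= R^2
  if (!any(inside)) return(0)
  msub <- lmask[iz + 1, iy + 1, ix + 1, drop = FALSE]
  sum(msub[inside]) / sum(inside)
}

#' Generate a directory of phantom scans with pooled annotations
#'
#' Writes `scan-<i>.mhd/.raw` (MET_FLOAT), a pooled `annotations.csv`
#' (LUNA16 dialect) and a `manifest.csv` (series_id, file, per-scan seed,
#' nodule count). Per-scan seeds are `seed + index`, so any scan (and its
#' ground-truth lung mask) can be regenerated from the manifest alone.
#'
#' @param n_scans number of phantoms.
#' @param out_dir output directory (created if needed).
#' @param spec template [phantom_spec()]; its seed is overridden per scan.
#' @param seed base seed.
#' @return The manifest tibble, invisibly.
#' @export
generate_dataset <- function(n_scans, out_dir, spec = phantom_spec(), seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", n_scans)
  anns <- vector("list", n_scans)
  for (i in seq_len(n_scans)) {
    spec$seed <- seed + i
    ph <- generate_phantom(spec)
    sid <- ph$annotations$series_id[1] %||% sprintf("phantom-%06d", spec$seed)
    if (is.na(sid) || !length(sid)) sid <- sprintf("phantom-%06d", spec$seed)
    f <- file.path(out_dir, sprintf("scan-%03d.mhd", i))
    write_metaimage(ph$volume, f, element_type = "MET_FLOAT")
    rows[[i]] <- tibble::tibble(series_id = sprintf("phantom-%06d", spec$seed),
                                file = basename(f), seed = spec$seed,
                                n_nodules = nrow(ph$annotations))
    anns[[i]] <- ph$annotations
  }
  manifest <- dplyr::bind_rows(rows)
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"), progress = FALSE)
  write_annotations(dplyr::bind_rows(anns), file.path(out_dir, "annotations.csv"))
  invisible(manifest)
}
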
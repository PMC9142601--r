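# Synthetic data generators: textured ellipsoidal CT phantoms with masks,
# families of perturbed segmentations (a stand-in for public
# multi-segmentation datasets), and feature cohorts with planted ground
# truth. Every generator is a pure function of its spec, seed included.

#' Specify a textured ellipsoid CT phantom
#'
#' Defaults emulate a contrast-enhanced head-and-neck tumor on planning
#' CT: a 20 mm-radius tumor of smoothly varying soft-tissue texture
#' (mean 60 HU, SD 25 HU, 1.5 mm correlation scale) embedded in a
#' uniform background of -100 HU.
#'
#' @param shape volume dimensions in voxels, default `c(64, 64, 48)`.
#' @param spacing voxel spacing in mm, default 1 mm isotropic.
#' @param center tumor center in voxel indices (default volume center).
#' @param semiaxes_mm ellipsoid semi-axes in mm, default `c(20, 16, 12)`.
#' @param hu_mean,hu_sd tumor texture mean and SD in HU.
#' @param smooth_mm texture correlation scale (Gaussian sigma, mm).
#' @param background_hu uniform background value.
#' @param seed integer seed.
#' @return list with class `PhantomSpec`.
#' @export
phantomSpec <- function(shape = c(64, 64, 48), spacing = c(1, 1, 1),
                        center = NULL, semiaxes_mm = c(20, 16, 12),
                        hu_mean = 60, hu_sd = 25, smooth_mm = 1.5,
                        background_hu = -100, seed = 1L) {
  center <- center %||% (shape + 1) / 2
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 center = as.numeric(center),
                 semiaxes_mm = as.numeric(semiaxes_mm),
                 hu_mean = hu_mean, hu_sd = hu_sd, smooth_mm = smooth_mm,
                 background_hu = background_hu, seed = as.integer(seed)),
            class = "PhantomSpec")
}

#' Generate a textured ellipsoidal tumor phantom and its mask
#'
#' The mask is the voxelized ellipsoid; tumor voxels carry seeded
#' Gaussian HU texture smoothed at the spec's correlation scale (the SD
#' is restored after smoothing), the background is constant. The tumor
#' must fit inside the volume.
#'
#' @param spec a [phantomSpec()].
#' @return list with `vol` ([CTVolume-class]) and `mask`
#'   ([SegMask-class]).
#' @export
makePhantom <- function(spec = phantomSpec()) {
  d <- spec$shape
  sp <- spec$spacing
  semiax_vox <- spec$semiaxes_mm / sp
  if (any(spec$center - semiax_vox < 1) ||
      any(spec$center + semiax_vox > d))
    stop("tumor does not fit inside the volume", call. = FALSE)
  ax <- (seq_len(d[1]) - spec$center[1]) / semiax_vox[1]
  ay <- (seq_len(d[2]) - spec$center[2]) / semiax_vox[2]
  az <- (seq_len(d[3]) - spec$center[3]) / semiax_vox[3]
  r2 <- outer(outer(ax^2, ay^2, "+"), az^2, "+")
  msk <- (r2 <= 1) * 1
  noise <- withLocalSeed(spec$seed, array(rnorm(prod(d)), dim = d))
  sm <- .gaussSmooth3D(noise, spec$smooth_mm / mean(sp))
  sm <- (sm - mean(sm)) / sd(sm)      # restore unit SD after smoothing
  vox <- array(spec$background_hu, dim = d)
  vox[msk == 1] <- spec$hu_mean + spec$hu_sd * sm[msk == 1]
  list(vol = CTVolume(vox, spacing = sp), mask = SegMask(msk, spacing = sp))
}

#' Generate a family of perturbed segmentations
#'
#' Emulates inter-observer contouring variability: each rater's mask is
#' the 0.5 level set of the smoothed original mask shifted by a seeded
#' offset and a smooth spatial noise field, both scaled by `magnitude`.
#' Magnitude 0 reproduces the input mask for every rater; the overlap
#' (Dice) with the original decreases as magnitude grows.
#'
#' @param mask a nonempty [SegMask-class].
#' @param n_raters number of alternative segmentations, default 9.
#' @param magnitude perturbation strength, roughly the boundary
#'   displacement in mm; default 1.
#' @param seed integer seed.
#' @return list of `n_raters` [SegMask-class] objects.
#' @export
perturbSegmentations <- function(mask, n_raters = 9L, magnitude = 1,
                                 seed = 1L) {
  msk <- voxels(mask)
  stopifnot2(sum(msk) > 0, "mask has no foreground voxels")
  d <- dim(msk)
  f <- .gaussSmooth3D(msk, 1.5)
  # the smoothed indicator falls off by roughly this much per mm near the
  # boundary, so level shifts of size `slope * magnitude` displace the
  # 0.5 level set by about `magnitude` mm
  slope <- 0.15
  lapply(seq_len(n_raters), function(r) {
    if (magnitude == 0) return(SegMask(msk, spacing = spacing(mask)))
    pert <- withLocalSeed(deriveSeed(seed, "rater", r), {
      offs <- rnorm(1, sd = 0.5)
      field <- .gaussSmooth3D(array(rnorm(prod(d)), dim = d), 3)
      field <- field / sd(field)
      slope * magnitude * (offs + field)
    })
    m2 <- ((f + pert) > 0.5) * 1
    if (sum(m2) == 0)
      stop("perturbation erased the mask; reduce magnitude",
           call. = FALSE)
    SegMask(m2, spacing = spacing(mask))
  })
}

#' Dice overlap of two masks
#' @param a,b [SegMask-class] objects on the same grid.
#' @return scalar in `[0, 1]`.
#' @export
diceOverlap <- function(a, b) {
  va <- voxels(a); vb <- voxels(b)
  2 * sum(va * vb) / (sum(va) + sum(vb))
}

#' Specify a synthetic feature cohort with planted ground truth
#'
#' Defaults mirror the primary-tumor study conditions this pipeline
#' targets: 96 patients, a balanced median-split outcome, 50 candidate
#' features of which a few carry a moderate standardized class shift
#' (delta = 1), a few are noisy copies of informative features at high
#' rank correlation, and the rest are independent noise.
#'
#' @param n samples, default 96.
#' @param p features, default 50.
#' @param n_informative informative features, default 3.
#' @param delta standardized between-class mean shift, default 1.
#' @param n_redundant redundant copies, default 5.
#' @param redundant_rho target Spearman correlation of each copy with its
#'   parent, default 0.9.
#' @param balance class-1 fraction, default 0.5.
#' @param seed integer seed.
#' @return list with class `CohortSpec`.
#' @export
cohortSpec <- function(n = 96L, p = 50L, n_informative = 3L, delta = 1,
                       n_redundant = 5L, redundant_rho = 0.9,
                       balance = 0.5, seed = 1L) {
  stopifnot2(n_informative + n_redundant <= p,
             "informative + redundant must not exceed p")
  stopifnot2(delta >= 0, "delta must be >= 0")
  stopifnot2(n_redundant == 0 || n_informative > 0,
             "redundant features need an informative parent")
  structure(list(n = as.integer(n), p = as.integer(p),
                 n_informative = as.integer(n_informative), delta = delta,
                 n_redundant = as.integer(n_redundant),
                 redundant_rho = redundant_rho, balance = balance,
                 seed = as.integer(seed)),
            class = "CohortSpec")
}

# Noise scale tau such that parent + tau * noise has the target Spearman
# correlation with the parent, via the Gaussian rank-correlation identity
# rho_S = (6/pi) asin(rho_P / 2).
.redundantTau <- function(rho_s) {
  if (rho_s <= 0 || rho_s >= 1)
    stop("target Spearman correlation must lie in (0, 1)", call. = FALSE)
  rho_p <- 2 * sin(pi * rho_s / 6)
  sqrt(1 / rho_p^2 - 1)
}

#' Generate a feature cohort with known ground truth
#'
#' Informative features are unit-variance Gaussians whose class means
#' differ by `delta`; redundant features are informative parents plus
#' Gaussian noise scaled to hit the target Spearman correlation (via the
#' Gaussian rank-correlation identity); the remainder is independent
#' noise. Labels are a seeded permutation with `round(n * balance)`
#' positives.
#'
#' @param spec a [cohortSpec()].
#' @return list with `features` (a [FeatureMatrix-class]), `labels`
#'   (0/1), and `truth` (feature roles: `informative`, `redundant` with
#'   parent map, `noise`).
#' @export
makeFeatureCohort <- function(spec = cohortSpec()) {
  n <- spec$n; p <- spec$p
  ni <- spec$n_informative; nr <- spec$n_redundant
  withLocalSeed(spec$seed, {
    n1 <- round(n * spec$balance)
    y <- sample(c(rep(1L, n1), rep(0L, n - n1)))
    X <- matrix(rnorm(n * p), n, p)
    if (ni > 0) {
      shift <- spec$delta * (y - 0.5)  # class means differ by delta
      for (j in seq_len(ni)) X[, j] <- X[, j] + shift
    }
    parents <- integer(0)
    if (nr > 0) {
      tau <- .redundantTau(spec$redundant_rho)
      parents <- rep(seq_len(ni), length.out = nr)
      for (k in seq_len(nr)) {
        # noise scaled by the parent SD so the rank-correlation target
        # holds whether or not the parent carries a class shift
        X[, ni + k] <- X[, parents[k]] +
          tau * sd(X[, parents[k]]) * rnorm(n)
      }
    }
    nm <- sprintf("feature_%04d", seq_len(p))
    colnames(X) <- nm
    truth <- list(
      informative = nm[seq_len(ni)],
      redundant = if (nr > 0)
        structure(nm[parents], names = nm[ni + seq_len(nr)])
      else character(),
      noise = if (ni + nr < p) nm[(ni + nr + 1):p] else character())
    list(features = FeatureMatrix(X, normalized = FALSE,
                                  provenance = list(kind = "synthetic")),
         labels = y, truth = truth)
  })
}

#' Multi-segmentation feature set from perturbed masks
#'
#' Convenience builder for the robustness-filter input: extracts deep
#' features for every (phantom, rater mask) pair and stacks them as a
#' subjects-by-raters-by-features array.
#'
#' @param phantoms list of `list(vol, mask)` pairs (subjects).
#' @param n_raters alternative segmentations per subject.
#' @param magnitude perturbation strength in mm.
#' @param extractor an [extractorSpec()].
#' @param cfg a [preprocessConfig()].
#' @param seed integer seed.
#' @return 3D array, subjects x raters x features.
#' @export
multiSegFeatureSet <- function(phantoms, n_raters = 9L, magnitude = 1,
                               extractor = extractorSpec(),
                               cfg = preprocessConfig(), seed = 1L) {
  ns <- length(phantoms)
  out <- NULL
  for (s in seq_len(ns)) {
    ph <- phantoms[[s]]
    masks <- perturbSegmentations(ph$mask, n_raters, magnitude,
                                  seed = deriveSeed(seed, "subject", s))
    crops <- lapply(masks, function(m) preprocessTumor(ph$vol, m, cfg))
    fm <- featureValues(extractFeatures(crops, extractor))
    if (is.null(out))
      out <- array(NA_real_, dim = c(ns, n_raters, ncol(fm)),
                   dimnames = list(NULL, NULL, colnames(fm)))
    out[s, , ] <- fm
  }
  out
}
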
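# Handcrafted radiomics backend ------------------------------------------
#
# 107 features in seven families: shape (14), first-order (18), GLCM (24),
# GLRLM (16), GLDM (14), GLSZM (16), NGTDM (5); 75 texture features in
# total. Computed in 3D on the 1 mm resampled grid with a fixed bin width
# (default 25 HU), gray levels discretized from the ROI minimum. Texture
# matrices are accumulated over the 13 unique 3D directions (GLCM, GLRLM)
# or the full 26-neighbourhood (GLDM, GLSZM zones, NGTDM), with
# direction-dependent families averaged over directions.

.EPS <- 2.2e-16

.offsets26 <- local({
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g[!(g[, 1] == 0 & g[, 2] == 0 & g[, 3] == 0), , drop = FALSE]
})
# unique directions: lexicographically positive half of the 26 offsets
.offsets13 <- local({
  o <- .offsets26
  keep <- o[, 3] > 0 | (o[, 3] == 0 & o[, 2] > 0) |
    (o[, 3] == 0 & o[, 2] == 0 & o[, 1] > 0)
  o[keep, , drop = FALSE]
})

# linear indices of all voxels having a valid neighbour at +off, and of
# that neighbour
.shiftValid <- function(d, off) {
  xr <- seq.int(max(1L, 1L - off[1]), min(d[1], d[1] - off[1]))
  yr <- seq.int(max(1L, 1L - off[2]), min(d[2], d[2] - off[2]))
  zr <- seq.int(max(1L, 1L - off[3]), min(d[3], d[3] - off[3]))
  if (!length(xr) || !length(yr) || !length(zr))
    return(list(src = integer(), dst = integer()))
  src <- outer(outer(xr, (yr - 1L) * d[1], "+"),
               (zr - 1L) * d[1] * d[2], "+")
  src <- as.integer(src)
  list(src = src,
       dst = src + as.integer(off[1] + off[2] * d[1] +
                                off[3] * d[1] * d[2]))
}

.xlog2 <- function(p) ifelse(p > 0, p * log2(p), 0)

# --- shape ---------------------------------------------------------------

.shapeFeatures <- function(msk, sp) {
  d <- dim(msk)
  idx <- which(msk == 1)
  n <- length(idx)
  voxvol <- prod(sp)
  V <- n * voxvol

  # surface area by the coarea formula: integral of |grad| of the gently
  # smoothed indicator (sigma 0.8 voxels); within ~1% of the analytic
  # area for sphere-like masks at 1 mm
  f <- .gaussSmooth3D(msk, 0.8)
  cd <- function(a, ax) {
    dd <- dim(a)
    up <- function(i, nn) pmin.int(i + 1L, nn)
    dn <- function(i, nn) pmax.int(i - 1L, 1L)
    switch(ax,
      (a[up(seq_len(dd[1]), dd[1]), , , drop = FALSE] -
         a[dn(seq_len(dd[1]), dd[1]), , , drop = FALSE]) / 2,
      (a[, up(seq_len(dd[2]), dd[2]), , drop = FALSE] -
         a[, dn(seq_len(dd[2]), dd[2]), , drop = FALSE]) / 2,
      (a[, , up(seq_len(dd[3]), dd[3]), drop = FALSE] -
         a[, , dn(seq_len(dd[3]), dd[3]), drop = FALSE]) / 2)
  }
  A <- sum(sqrt((cd(f, 1L) / sp[1])^2 + (cd(f, 2L) / sp[2])^2 +
                  (cd(f, 3L) / sp[3])^2)) * voxvol
  if (A <= 0) A <- .EPS

  coords <- arrayInd(idx, d)
  phys <- sweep(coords - 1, 2, sp, "*")

  # principal axis lengths from the coordinate covariance
  if (n > 1) {
    ev <- sort(eigen(stats::cov(phys), symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    ev[ev < 0] <- 0
  } else ev <- c(0, 0, 0)
  major <- 4 * sqrt(ev[1]); minor <- 4 * sqrt(ev[2])
  least <- 4 * sqrt(ev[3])
  elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1
  flat <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 1

  # boundary voxels: at least one 6-neighbour outside the mask (or edge)
  cnt6 <- array(0L, d)
  for (k in which(rowSums(abs(.offsets26)) == 1)) {
    sv <- .shiftValid(d, .offsets26[k, ])
    inMask <- msk[sv$dst] == 1
    cnt6[sv$src] <- cnt6[sv$src] + as.integer(inMask)
  }
  bnd <- idx[cnt6[idx] < 6L]
  bphys <- sweep(arrayInd(bnd, d) - 1, 2, sp, "*")

  maxPair <- function(m) if (nrow(m) >= 2) max(stats::dist(m)) else 0
  max3d <- maxPair(bphys)
  planeMax <- function(groupAxis, keep) {
    gr <- split(seq_len(nrow(bphys)), bphys[, groupAxis])
    mx <- 0
    for (g in gr) {
      if (length(g) < 2) next
      mx <- max(mx, maxPair(bphys[g, keep, drop = FALSE]))
    }
    mx
  }
  max2dSlice <- planeMax(3, c(1, 2))   # axial plane
  max2dColumn <- planeMax(2, c(1, 3))  # coronal plane
  max2dRow <- planeMax(1, c(2, 3))     # sagittal plane

  c(shape_MeshVolume = V,  # voxel-count approximation of the mesh volume
    shape_VoxelVolume = V,
    shape_SurfaceArea = A,
    shape_SurfaceVolumeRatio = A / V,
    shape_Sphericity = (pi^(1 / 3)) * (6 * V)^(2 / 3) / A,
    shape_Maximum3DDiameter = max3d,
    shape_Maximum2DDiameterSlice = max2dSlice,
    shape_Maximum2DDiameterColumn = max2dColumn,
    shape_Maximum2DDiameterRow = max2dRow,
    shape_MajorAxisLength = major,
    shape_MinorAxisLength = minor,
    shape_LeastAxisLength = least,
    shape_Elongation = elong,
    shape_Flatness = flat)
}

# --- first order ---------------------------------------------------------

.firstOrderFeatures <- function(x, bins, Ng, voxvol) {
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  p <- tabulate(bins, nbins = Ng) / n
  p10 <- as.numeric(quantile(x, 0.10, type = 7))
  p90 <- as.numeric(quantile(x, 0.90, type = 7))
  mid <- x[x >= p10 & x <= p90]
  c(firstorder_Energy = sum(x^2),
    firstorder_TotalEnergy = voxvol * sum(x^2),
    firstorder_Entropy = -sum(.xlog2(p)),
    firstorder_Minimum = min(x),
    firstorder_Percentile10 = p10,
    firstorder_Percentile90 = p90,
    firstorder_Maximum = max(x),
    firstorder_Mean = mu,
    firstorder_Median = median(x),
    firstorder_InterquartileRange =
      as.numeric(quantile(x, 0.75) - quantile(x, 0.25)),
    firstorder_Range = max(x) - min(x),
    firstorder_MeanAbsoluteDeviation = mean(abs(x - mu)),
    firstorder_RobustMeanAbsoluteDeviation =
      if (length(mid)) mean(abs(mid - mean(mid))) else 0,
    firstorder_RootMeanSquared = sqrt(mean(x^2)),
    firstorder_Skewness =
      if (m2 > 0) mean((x - mu)^3) / m2^1.5 else 0,
    firstorder_Kurtosis =
      if (m2 > 0) mean((x - mu)^4) / m2^2 else 0,
    firstorder_Variance = m2,
    firstorder_Uniformity = sum(p^2))
}

# --- GLCM ----------------------------------------------------------------

.glcmOne <- function(P) {
  Ng <- nrow(P)
  lv <- seq_len(Ng)
  I <- matrix(lv, Ng, Ng)
  J <- t(I)
  px <- rowSums(P); py <- colSums(P)
  ux <- sum(lv * px); uy <- sum(lv * py)
  sigx <- sqrt(sum((lv - ux)^2 * px)); sigy <- sqrt(sum((lv - uy)^2 * py))
  sumIdx <- I + J      # 2 .. 2Ng
  diffIdx <- abs(I - J)
  psum <- vapply(2:(2 * Ng), function(k) sum(P[sumIdx == k]), numeric(1))
  pdiff <- vapply(0:(Ng - 1), function(k) sum(P[diffIdx == k]), numeric(1))
  ks <- 2:(2 * Ng); kd <- 0:(Ng - 1)
  DA <- sum(kd * pdiff)
  HX <- -sum(.xlog2(px)); HY <- -sum(.xlog2(py))
  HXY <- -sum(.xlog2(P))
  pxpy <- outer(px, py)
  HXY1 <- -sum(ifelse(pxpy > 0, P * log2(pmax(pxpy, .EPS)), 0))
  HXY2 <- -sum(.xlog2(pxpy))
  imc1 <- if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else 0
  imc2 <- sqrt(pmax(1 - exp(-2 * (HXY2 - HXY)), 0))
  corr <- if (sigx > 0 && sigy > 0)
    (sum(I * J * P) - ux * uy) / (sigx * sigy) else 1
  # MCC: sqrt of the second-largest eigenvalue of Q
  keep <- px > 0
  mcc <- if (sum(keep) < 2) 1 else {
    Pk <- P[keep, keep, drop = FALSE]
    pxk <- px[keep]; pyk <- py[keep]
    Q <- (Pk / pxk) %*% t(Pk / matrix(pyk, nrow(Pk), ncol(Pk),
                                      byrow = TRUE))
    evq <- sort(Re(eigen(Q, only.values = TRUE)$values),
                decreasing = TRUE)
    sqrt(pmax(evq[2], 0))
  }
  offd <- diffIdx != 0
  c(glcm_Autocorrelation = sum(I * J * P),
    glcm_JointAverage = ux,
    glcm_ClusterProminence = sum((I + J - ux - uy)^4 * P),
    glcm_ClusterShade = sum((I + J - ux - uy)^3 * P),
    glcm_ClusterTendency = sum((I + J - ux - uy)^2 * P),
    glcm_Contrast = sum((I - J)^2 * P),
    glcm_Correlation = corr,
    glcm_DifferenceAverage = DA,
    glcm_DifferenceEntropy = -sum(.xlog2(pdiff)),
    glcm_DifferenceVariance = sum((kd - DA)^2 * pdiff),
    glcm_JointEnergy = sum(P^2),
    glcm_JointEntropy = HXY,
    glcm_Imc1 = imc1,
    glcm_Imc2 = imc2,
    glcm_Idm = sum(P / (1 + (I - J)^2)),
    glcm_Idmn = sum(P / (1 + ((I - J) / Ng)^2)),
    glcm_Id = sum(P / (1 + abs(I - J))),
    glcm_Idn = sum(P / (1 + abs(I - J) / Ng)),
    glcm_InverseVariance = sum(P[offd] / (I[offd] - J[offd])^2),
    glcm_MaximumProbability = max(P),
    glcm_SumAverage = sum(ks * psum),
    glcm_SumEntropy = -sum(.xlog2(psum)),
    glcm_SumSquares = sum((I - ux)^2 * P),
    glcm_MCC = mcc)
}

.glcmFeatures <- function(L, Ng, d) {
  acc <- NULL
  nd <- 0L
  for (k in seq_len(nrow(.offsets13))) {
    sv <- .shiftValid(d, .offsets13[k, ])
    a <- L[sv$src]; b <- L[sv$dst]
    ok <- a > 0L & b > 0L
    if (!any(ok)) next
    counts <- tabulate((b[ok] - 1L) * Ng + a[ok], nbins = Ng * Ng)
    P <- matrix(counts, Ng, Ng)
    P <- P + t(P)
    P <- P / sum(P)
    f <- .glcmOne(P)
    acc <- if (is.null(acc)) f else acc + f
    nd <- nd + 1L
  }
  if (nd == 0L) {
    f <- .glcmOne(matrix(1, 1, 1))
    nd <- 1L
    acc <- f
  }
  acc / nd
}

# --- GLRLM ---------------------------------------------------------------

.glrlmOne <- function(L, Ng, d, off, Np) {
  sv <- .shiftValid(d, off)
  predLevel <- array(0L, d)
  if (length(sv$src)) predLevel[sv$dst] <- L[sv$src]
  hasSucc <- array(FALSE, d)
  if (length(sv$src)) hasSucc[sv$src] <- TRUE
  offLin <- as.integer(off[1] + off[2] * d[1] + off[3] * d[1] * d[2])
  inMask <- which(L > 0L)
  starts <- inMask[predLevel[inMask] != L[inMask]]
  g <- L[starts]
  pos <- starts
  len <- rep(1L, length(starts))
  alive <- seq_along(starts)
  while (length(alive)) {
    p <- pos[alive]
    can <- hasSucc[p] & L[p + offLin] == g[alive]
    adv <- alive[can]
    if (!length(adv)) break
    pos[adv] <- pos[adv] + offLin
    len[adv] <- len[adv] + 1L
    alive <- adv
  }
  maxLen <- max(len)
  R <- matrix(tabulate((len - 1L) * Ng + g, nbins = Ng * maxLen),
              Ng, maxLen)
  Nr <- sum(R)
  lv <- seq_len(Ng); ll <- seq_len(maxLen)
  ri <- rowSums(R); rl <- colSums(R)
  pr <- R / Nr
  gv <- sum(lv * rowSums(pr))
  lva <- sum(ll * colSums(pr))
  c(glrlm_ShortRunEmphasis = sum(sweep(R, 2, ll^2, "/")) / Nr,
    glrlm_LongRunEmphasis = sum(sweep(R, 2, ll^2, "*")) / Nr,
    glrlm_GrayLevelNonUniformity = sum(ri^2) / Nr,
    glrlm_GrayLevelNonUniformityNormalized = sum(ri^2) / Nr^2,
    glrlm_RunLengthNonUniformity = sum(rl^2) / Nr,
    glrlm_RunLengthNonUniformityNormalized = sum(rl^2) / Nr^2,
    glrlm_RunPercentage = Nr / Np,
    glrlm_GrayLevelVariance = sum(outer((lv - gv)^2, rep(1, maxLen)) * pr),
    glrlm_RunVariance = sum(outer(rep(1, Ng), (ll - lva)^2) * pr),
    glrlm_RunEntropy = -sum(.xlog2(pr)),
    glrlm_LowGrayLevelRunEmphasis = sum(sweep(R, 1, lv^2, "/")) / Nr,
    glrlm_HighGrayLevelRunEmphasis = sum(sweep(R, 1, lv^2, "*")) / Nr,
    glrlm_ShortRunLowGrayLevelEmphasis =
      sum(R / outer(lv^2, ll^2)) / Nr,
    glrlm_ShortRunHighGrayLevelEmphasis =
      sum(R * outer(lv^2, 1 / ll^2)) / Nr,
    glrlm_LongRunLowGrayLevelEmphasis =
      sum(R * outer(1 / lv^2, ll^2)) / Nr,
    glrlm_LongRunHighGrayLevelEmphasis =
      sum(R * outer(lv^2, ll^2)) / Nr)
}

.glrlmFeatures <- function(L, Ng, d) {
  Np <- sum(L > 0L)
  acc <- NULL
  for (k in seq_len(nrow(.offsets13))) {
    f <- .glrlmOne(L, Ng, d, .offsets13[k, ], Np)
    acc <- if (is.null(acc)) f else acc + f
  }
  acc / nrow(.offsets13)
}

# --- GLSZM ---------------------------------------------------------------

# 26-connected zone sizes per gray level
.zoneSizes <- function(L, Ng, d) {
  lab <- array(0L, d)
  cur <- 0L
  sizes <- integer()
  levels <- integer()
  nbLin <- as.integer(.offsets26[, 1] + .offsets26[, 2] * d[1] +
                        .offsets26[, 3] * d[1] * d[2])
  nr <- d[1]; nc <- d[2]; nz <- d[3]
  coordOK <- function(ii, off) {
    a <- arrayInd(ii, d)
    rr <- a[, 1] + off[1]; cc <- a[, 2] + off[2]; zz <- a[, 3] + off[3]
    rr >= 1 & rr <= nr & cc >= 1 & cc <= nc & zz >= 1 & zz <= nz
  }
  fg <- which(L > 0L)
  for (s in fg) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    g <- L[s]
    lab[s] <- cur
    frontier <- s
    sz <- 1L
    while (length(frontier)) {
      nxt <- integer()
      for (k in seq_along(nbLin)) {
        ok <- coordOK(frontier, .offsets26[k, ])
        cand <- frontier[ok] + nbLin[k]
        cand <- cand[L[cand] == g & lab[cand] == 0L]
        if (length(cand)) {
          lab[cand] <- cur
          nxt <- c(nxt, cand)
        }
      }
      nxt <- unique(nxt)
      sz <- sz + length(nxt)
      frontier <- nxt
    }
    sizes <- c(sizes, sz)
    levels <- c(levels, g)
  }
  list(sizes = sizes, levels = levels)
}

.glszmFeatures <- function(L, Ng, d) {
  z <- .zoneSizes(L, Ng, d)
  Np <- sum(L > 0L)
  maxS <- max(z$sizes)
  Z <- matrix(tabulate((z$sizes - 1L) * Ng + z$levels,
                       nbins = Ng * maxS), Ng, maxS)
  Nz <- sum(Z)
  lv <- seq_len(Ng); sv <- seq_len(maxS)
  zi <- rowSums(Z); zs <- colSums(Z)
  pz <- Z / Nz
  gmean <- sum(lv * rowSums(pz))
  smean <- sum(sv * colSums(pz))
  c(glszm_SmallAreaEmphasis = sum(sweep(Z, 2, sv^2, "/")) / Nz,
    glszm_LargeAreaEmphasis = sum(sweep(Z, 2, sv^2, "*")) / Nz,
    glszm_GrayLevelNonUniformity = sum(zi^2) / Nz,
    glszm_GrayLevelNonUniformityNormalized = sum(zi^2) / Nz^2,
    glszm_SizeZoneNonUniformity = sum(zs^2) / Nz,
    glszm_SizeZoneNonUniformityNormalized = sum(zs^2) / Nz^2,
    glszm_ZonePercentage = Nz / Np,
    glszm_GrayLevelVariance = sum(outer((lv - gmean)^2, rep(1, maxS)) * pz),
    glszm_ZoneVariance = sum(outer(rep(1, Ng), (sv - smean)^2) * pz),
    glszm_ZoneEntropy = -sum(.xlog2(pz)),
    glszm_LowGrayLevelZoneEmphasis = sum(sweep(Z, 1, lv^2, "/")) / Nz,
    glszm_HighGrayLevelZoneEmphasis = sum(sweep(Z, 1, lv^2, "*")) / Nz,
    glszm_SmallAreaLowGrayLevelEmphasis =
      sum(Z / outer(lv^2, sv^2)) / Nz,
    glszm_SmallAreaHighGrayLevelEmphasis =
      sum(Z * outer(lv^2, 1 / sv^2)) / Nz,
    glszm_LargeAreaLowGrayLevelEmphasis =
      sum(Z * outer(1 / lv^2, sv^2)) / Nz,
    glszm_LargeAreaHighGrayLevelEmphasis =
      sum(Z * outer(lv^2, sv^2)) / Nz)
}

# --- GLDM ----------------------------------------------------------------

.gldmFeatures <- function(L, Ng, d) {
  dep <- array(0L, d)
  for (k in seq_len(nrow(.offsets26))) {
    sv <- .shiftValid(d, .offsets26[k, ])
    eq <- L[sv$src] > 0L & L[sv$src] == L[sv$dst]
    dep[sv$src[eq]] <- dep[sv$src[eq]] + 1L
  }
  idx <- which(L > 0L)
  j <- dep[idx] + 1L   # dependence size including the center voxel
  g <- L[idx]
  maxJ <- max(j)
  P <- matrix(tabulate((j - 1L) * Ng + g, nbins = Ng * maxJ), Ng, maxJ)
  Nd <- sum(P)
  lv <- seq_len(Ng); jv <- seq_len(maxJ)
  pi_ <- rowSums(P); pj <- colSums(P)
  pp <- P / Nd
  gmean <- sum(lv * rowSums(pp))
  jmean <- sum(jv * colSums(pp))
  c(gldm_SmallDependenceEmphasis = sum(sweep(P, 2, jv^2, "/")) / Nd,
    gldm_LargeDependenceEmphasis = sum(sweep(P, 2, jv^2, "*")) / Nd,
    gldm_GrayLevelNonUniformity = sum(pi_^2) / Nd,
    gldm_DependenceNonUniformity = sum(pj^2) / Nd,
    gldm_DependenceNonUniformityNormalized = sum(pj^2) / Nd^2,
    gldm_GrayLevelVariance = sum(outer((lv - gmean)^2, rep(1, maxJ)) * pp),
    gldm_DependenceVariance = sum(outer(rep(1, Ng), (jv - jmean)^2) * pp),
    gldm_DependenceEntropy = -sum(.xlog2(pp)),
    gldm_LowGrayLevelEmphasis = sum(sweep(P, 1, lv^2, "/")) / Nd,
    gldm_HighGrayLevelEmphasis = sum(sweep(P, 1, lv^2, "*")) / Nd,
    gldm_SmallDependenceLowGrayLevelEmphasis =
      sum(P / outer(lv^2, jv^2)) / Nd,
    gldm_SmallDependenceHighGrayLevelEmphasis =
      sum(P * outer(lv^2, 1 / jv^2)) / Nd,
    gldm_LargeDependenceLowGrayLevelEmphasis =
      sum(P * outer(1 / lv^2, jv^2)) / Nd,
    gldm_LargeDependenceHighGrayLevelEmphasis =
      sum(P * outer(lv^2, jv^2)) / Nd)
}

# --- NGTDM ---------------------------------------------------------------

.ngtdmFeatures <- function(L, Ng, d) {
  sumNb <- array(0, d)
  cntNb <- array(0L, d)
  for (k in seq_len(nrow(.offsets26))) {
    sv <- .shiftValid(d, .offsets26[k, ])
    inb <- L[sv$dst] > 0L
    src <- sv$src[inb]
    sumNb[src] <- sumNb[src] + L[sv$dst[inb]]
    cntNb[src] <- cntNb[src] + 1L
  }
  idx <- which(L > 0L & cntNb > 0L)
  g <- L[idx]
  Abar <- sumNb[idx] / cntNb[idx]
  N <- length(idx)
  ni <- tabulate(g, nbins = Ng)
  si <- vapply(seq_len(Ng), function(i) sum(abs(i - Abar[g == i])),
               numeric(1))
  p <- ni / N
  pres <- which(p > 0)
  Ngp <- length(pres)
  coarseDen <- sum(p * si)
  coarseness <- if (coarseDen > .EPS) 1 / coarseDen else 1e6
  contrast <- if (Ngp > 1) {
    (sum(outer(p[pres], p[pres]) *
           outer(pres, pres, function(a, b) (a - b)^2)) /
       (Ngp * (Ngp - 1))) * (sum(si) / N)
  } else 0
  busyDen <- sum(abs(outer(pres * p[pres], pres * p[pres], "-")))
  busyness <- if (busyDen > .EPS) sum(p * si) / busyDen else 0
  complexity <- if (Ngp > 0) {
    sum(outer(pres, pres, function(a, b) abs(a - b)) *
          outer(p[pres] * si[pres], p[pres] * si[pres], "+") /
          outer(p[pres], p[pres], "+")) / N
  } else 0
  strength <- if (sum(si) > .EPS) {
    sum(outer(p[pres], p[pres], "+") *
          outer(pres, pres, function(a, b) (a - b)^2)) / sum(si)
  } else 0
  c(ngtdm_Coarseness = coarseness,
    ngtdm_Contrast = contrast,
    ngtdm_Busyness = busyness,
    ngtdm_Complexity = complexity,
    ngtdm_Strength = strength)
}

# --- backend registry and user-facing op --------------------------------

.radiomicsBackends <- new.env(parent = emptyenv())

#' Register a handcrafted radiomics backend
#'
#' A backend is a function `(vol, mask, bin_width)` returning a named
#' numeric vector of 107 features with family prefixes. The built-in
#' `"internal"` backend computes the standard 14 shape / 18 first-order /
#' 75 texture catalogue directly in R.
#'
#' @param name backend name.
#' @param fn extraction function.
#' @return `name`, invisibly.
#' @export
registerRadiomicsBackend <- function(name, fn) {
  assign(name, fn, envir = .radiomicsBackends)
  invisible(name)
}

.internalRadiomics <- function(vol, mask, bin_width = 25) {
  vox <- voxels(vol)
  msk <- voxels(mask)
  d <- dim(vox)
  idx <- which(msk == 1)
  stopifnot2(length(idx) > 0, "mask has no foreground voxels")
  x <- vox[idx]
  bins <- as.integer(floor((x - min(x)) / bin_width)) + 1L
  Ng <- max(bins)
  L <- array(0L, d)
  L[idx] <- bins
  c(.shapeFeatures(msk, spacing(vol)),
    .firstOrderFeatures(x, bins, Ng, prod(spacing(vol))),
    .glcmFeatures(L, Ng, d),
    .glrlmFeatures(L, Ng, d),
    .gldmFeatures(L, Ng, d),
    .glszmFeatures(L, Ng, d),
    .ngtdmFeatures(L, Ng, d))
}

#' Extract the 107 handcrafted radiomics features of one tumor
#'
#' Resamples volume and mask to 1 mm isotropic (nearest neighbour),
#' discretizes intensities at a fixed bin width (default 25 HU) and
#' computes the standard handcrafted catalogue: 14 shape, 18 first-order
#' and 75 texture features (GLCM 24, GLRLM 16, GLDM 14, GLSZM 16,
#' NGTDM 5), all in 3D. Feature names carry family prefixes
#' (`shape_`, `firstorder_`, `glcm_`, `glrlm_`, `gldm_`, `glszm_`,
#' `ngtdm_`).
#'
#' @param vol a [CTVolume-class].
#' @param mask the paired [SegMask-class].
#' @param backend backend name; `"internal"` (default) is built in, others
#'   must be registered with [registerRadiomicsBackend()].
#' @param bin_width discretization bin width in HU, default 25.
#' @param sample_id row identifier of the returned matrix.
#' @return A 1-row [FeatureMatrix-class] with 107 named features.
#' @export
handcraftedFeatures <- function(vol, mask, backend = "internal",
                                bin_width = 25, sample_id = "tumor") {
  fn <- if (backend == "internal") {
    .internalRadiomics
  } else if (exists(backend, envir = .radiomicsBackends)) {
    get(backend, envir = .radiomicsBackends)
  } else {
    stop(sprintf(
      "handcrafted feature backend '%s' is unavailable; the pipeline can still run in deep-feature-only mode",
      backend), call. = FALSE)
  }
  rs <- resampleIsotropic(vol, mask, preprocessConfig())
  feats <- fn(rs$vol, rs$mask, bin_width)
  m <- matrix(feats, nrow = 1,
              dimnames = list(sample_id, names(feats)))
  FeatureMatrix(m, normalized = FALSE,
                provenance = list(backend = backend,
                                  bin_width = bin_width))
}
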
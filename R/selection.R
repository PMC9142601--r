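# Two-step feature selection: robustness filtering across alternative
# segmentations (ICC), Spearman collinearity pruning, then five filter
# rankers producing top-k candidate lists.

#' Selection configuration
#'
#' @param icc_threshold robustness cut (strict `>`), default 0.7.
#' @param corr_threshold Spearman collinearity cut on `|rho|` (strict `>`),
#'   default 0.8.
#' @param top_k number of features each ranker returns, default 10.
#' @param chsq_bins quantile bins used to discretize features for the
#'   chi-square ranker, default 10.
#' @param relieff_k neighbours per class for ReliefF, default 10.
#' @param nca_lambda ridge penalty for NCA; `NULL` means `1/n`.
#' @param inffs_alpha mixing weight between the relevance and
#'   anti-redundancy terms of the infinite-feature-selection adjacency,
#'   default 0.5.
#' @param inffs_r_factor damping as a fraction of the reciprocal spectral
#'   radius, default 0.9.
#' @param seed seed for the (seeded) NCA optimization.
#' @return list with class `SelectionConfig`.
#' @export
selectionConfig <- function(icc_threshold = 0.7, corr_threshold = 0.8,
                            top_k = 10L, chsq_bins = 10L, relieff_k = 10L,
                            nca_lambda = NULL, inffs_alpha = 0.5,
                            inffs_r_factor = 0.9, seed = 1L) {
  stopifnot2(icc_threshold > 0 && icc_threshold < 1,
             "icc_threshold must lie in (0,1)")
  stopifnot2(corr_threshold > 0 && corr_threshold < 1,
             "corr_threshold must lie in (0,1)")
  stopifnot2(top_k >= 1, "top_k must be >= 1")
  structure(list(icc_threshold = icc_threshold,
                 corr_threshold = corr_threshold, top_k = as.integer(top_k),
                 chsq_bins = as.integer(chsq_bins),
                 relieff_k = as.integer(relieff_k),
                 nca_lambda = nca_lambda, inffs_alpha = inffs_alpha,
                 inffs_r_factor = inffs_r_factor, seed = as.integer(seed)),
            class = "SelectionConfig")
}

#' Intraclass correlation, two-way mixed, absolute agreement, single rater
#'
#' ICC(3,A,1) in the McGraw-Wong convention, computed from the two-way
#' ANOVA mean squares of a subjects-by-raters matrix:
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n) (MSC - MSE))`
#' with `MSR` the between-subject, `MSC` the between-rater and `MSE` the
#' residual mean square.
#'
#' @param m numeric matrix, subjects in rows, raters (alternative
#'   segmentations) in columns; at least 2 of each.
#' @return scalar ICC in (-Inf, 1]; `NaN` with a warning when the matrix
#'   has no variance at all.
#' @export
iccCase3A <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m); k <- ncol(m)
  stopifnot2(n >= 2 && k >= 2, "need >= 2 subjects and >= 2 raters")
  stopifnot2(!anyNA(m), "matrix must have no missing cells")
  mu <- mean(m)
  rowm <- rowMeans(m)
  colm <- colMeans(m)
  SSR <- k * sum((rowm - mu)^2)
  SSC <- n * sum((colm - mu)^2)
  SST <- sum((m - mu)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  den <- MSR + (k - 1) * MSE + (k / n) * (MSC - MSE)
  if (abs(den) < 1e-300 || SST == 0) {
    warning("ICC undefined: no variance in the subjects-by-raters matrix")
    return(NaN)
  }
  (MSR - MSE) / den
}

#' Retain features that are robust across alternative segmentations
#'
#' A feature is retained iff its ICC across raters is strictly greater
#' than the threshold; features whose ICC is undefined are dropped.
#'
#' @param ms 3D array of feature values, subjects x raters x features
#'   (features named along the third dimension), or a named list of
#'   subjects-by-raters matrices.
#' @param cfg a [selectionConfig()].
#' @return character vector of retained feature names.
#' @export
filterRobust <- function(ms, cfg = selectionConfig()) {
  if (is.list(ms)) {
    nm <- names(ms)
    iccs <- vapply(ms, function(m)
      suppressWarnings(iccCase3A(m)), numeric(1))
  } else {
    stopifnot2(length(dim(ms)) == 3L,
               "ms must be subjects x raters x features")
    nm <- dimnames(ms)[[3]] %||% sprintf("feature_%04d", seq_len(dim(ms)[3]))
    iccs <- vapply(seq_len(dim(ms)[3]), function(j)
      suppressWarnings(iccCase3A(ms[, , j])), numeric(1))
  }
  nm[!is.na(iccs) & iccs > cfg$icc_threshold]
}

#' Prune collinear features by Spearman correlation
#'
#' Repeatedly finds the most-correlated offending pair
#' (`|rho_S| >` threshold among retained features), computes for its two
#' members the mean `|rho_S|` against all other retained features, and
#' eliminates the member with the higher mean (ties drop the higher
#' column index). Terminates when no retained pair exceeds the threshold.
#'
#' @param F a [FeatureMatrix-class] or samples-by-features matrix with
#'   at least one feature column.
#' @param cfg a [selectionConfig()].
#' @return character vector of retained feature names (original order).
#' @export
pruneCollinear <- function(F, cfg = selectionConfig()) {
  vals <- if (is(F, "FeatureMatrix")) featureValues(F) else as.matrix(F)
  p <- ncol(vals)
  if (p < 2) return(colnames(vals))
  rho <- abs(suppressWarnings(cor(vals, method = "spearman")))
  rho[!is.finite(rho)] <- 0
  diag(rho) <- 0
  keep <- seq_len(p)
  while (length(keep) >= 2) {
    sub <- rho[keep, keep, drop = FALSE]
    mx <- max(sub)
    if (mx <= cfg$corr_threshold) break
    hit <- which(sub == mx, arr.ind = TRUE)[1, ]
    a <- keep[hit[1]]; b <- keep[hit[2]]
    meanAbs <- function(i) mean(rho[i, setdiff(keep, i)])
    ma <- meanAbs(a); mb <- meanAbs(b)
    drop <- if (ma > mb) a else if (mb > ma) b else max(a, b)
    keep <- setdiff(keep, drop)
  }
  colnames(vals)[keep]
}

# --- rankers -------------------------------------------------------------

.chsqScores <- function(X, y, bins) {
  apply(X, 2, function(x) {
    br <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1),
                          type = 7))
    if (length(br) < 2) return(0)
    g <- cut(x, breaks = br, include.lowest = TRUE)
    tab <- table(g, y)
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    if (nrow(tab) < 2) return(0)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    stat <- sum((tab - e)^2 / e)
    df <- (nrow(tab) - 1) * (ncol(tab) - 1)
    -log10(pmax(pchisq(stat, df, lower.tail = FALSE), 1e-300))
  })
}

.wlcxScores <- function(X, y) {
  apply(X, 2, function(x) {
    p <- suppressWarnings(
      wilcox.test(x[y == 1], x[y == 0], exact = FALSE)$p.value)
    if (!is.finite(p)) p <- 1
    -log10(pmax(p, 1e-300))
  })
}

# Diagonal neighbourhood component analysis: learn non-negative feature
# weights (squared parametrization) maximizing the expected leave-one-out
# stochastic-neighbour classification accuracy with a ridge penalty.
.ncaWeights <- function(X, y, lambda = NULL, seed = 1L) {
  n <- nrow(X); p <- ncol(X)
  if (is.null(lambda)) lambda <- 1 / n
  same <- outer(y, y, "==")
  diag(same) <- FALSE
  # per-feature absolute difference tensors, n x n each
  D <- lapply(seq_len(p), function(j) abs(outer(X[, j], X[, j], "-")))
  objgrad <- function(w) {
    w2 <- w^2
    dist <- Reduce("+", Map(function(Dj, wj) wj * Dj, D, w2))
    diag(dist) <- Inf
    K <- exp(-(dist - apply(dist, 1, min)))  # row-stabilized kernel
    diag(K) <- 0
    rs <- rowSums(K)
    rs[rs == 0] <- 1
    Pm <- K / rs
    pi_ <- rowSums(Pm * same)
    f <- mean(pi_) - lambda * sum(w2)
    # gradient wrt w2: d pi_i / d w2_j = sum_k p_ik (pi_i - same_ik) D_jik
    g2 <- vapply(seq_len(p), function(j) {
      mean(rowSums(Pm * (pi_ - same) * D[[j]]))
    }, numeric(1))
    g <- 2 * w * (g2 - lambda)
    list(f = f, g = g)
  }
  w0 <- rep(1, p)
  res <- withLocalSeed(seed, {
    optim(w0, fn = function(w) -objgrad(w)$f,
          gr = function(w) -objgrad(w)$g,
          method = "L-BFGS-B", control = list(maxit = 100))
  })
  res$par^2
}

# ReliefF with k nearest hits/misses over all instances, Manhattan
# distance; miss contributions weighted by class prior odds.
.relieffWeights <- function(X, y, k = 10L) {
  n <- nrow(X); p <- ncol(X)
  rng <- apply(X, 2, function(x) diff(range(x)))
  rng[rng == 0] <- 1
  Dm <- as.matrix(dist(X, method = "manhattan"))
  diag(Dm) <- Inf
  priors <- table(factor(y, levels = c(0, 1))) / n
  W <- numeric(p)
  for (i in seq_len(n)) {
    for (cls in c(0, 1)) {
      pool <- which(y == cls & seq_len(n) != i)
      if (!length(pool)) next
      kk <- min(k, length(pool))
      nb <- pool[order(Dm[i, pool])[seq_len(kk)]]
      contrib <- colMeans(abs(X[nb, , drop = FALSE] -
                                matrix(X[i, ], kk, p, byrow = TRUE)) /
                            matrix(rng, kk, p, byrow = TRUE))
      if (cls == y[i]) {
        W <- W - contrib / n
      } else {
        pc <- as.numeric(priors[as.character(cls)])
        pyi <- as.numeric(priors[as.character(y[i])])
        W <- W + (pc / (1 - pyi)) * contrib / n
      }
    }
  }
  W
}

# Infinite feature selection: score features by summing weighted paths of
# all lengths through the feature-feature adjacency
#   a_ij = alpha * max(s_i, s_j) + (1 - alpha) * (1 - |rho_S(i,j)|)
# where s_i is a normalized class-separation (Fisher-type) relevance score
# and the damping r keeps the geometric series (I - rA)^{-1} - I finite.
.inffsScores <- function(X, y, alpha = 0.5, r_factor = 0.9) {
  p <- ncol(X)
  if (p == 1L) return(structure(1, names = colnames(X)))
  mu0 <- colMeans(X[y == 0, , drop = FALSE])
  mu1 <- colMeans(X[y == 1, , drop = FALSE])
  v0 <- apply(X[y == 0, , drop = FALSE], 2, var)
  v1 <- apply(X[y == 1, , drop = FALSE], 2, var)
  n0 <- sum(y == 0); n1 <- sum(y == 1)
  spool <- sqrt(((n0 - 1) * v0 + (n1 - 1) * v1) / (n0 + n1 - 2))
  sep <- abs(mu1 - mu0) / pmax(spool, .EPS)
  s <- if (max(sep) > 0) sep / max(sep) else rep(0, p)
  rho <- abs(suppressWarnings(cor(X, method = "spearman")))
  rho[!is.finite(rho)] <- 0
  A <- alpha * outer(s, s, pmax) + (1 - alpha) * (1 - rho)
  diag(A) <- 0
  specRad <- max(abs(eigen(A, only.values = TRUE)$values))
  r <- if (specRad > 0) r_factor / specRad else r_factor
  S <- solve(diag(p) - r * A) - diag(p)
  structure(rowSums(S), names = colnames(X))
}

#' Rank features with one of five filter methods
#'
#' Supported rankers: `CHSQ` (chi-square independence of the
#' quantile-binned feature vs the class, scored `-log10 p`), `WLCX`
#' (two-sample Wilcoxon rank-sum, scored `-log10 p`), `NCA` (learned
#' non-negative diagonal feature weights), `ReliefF` (expected margin over
#' k nearest hits/misses), and `infFS` (infinite feature selection: path
#' sums through a relevance/anti-redundancy adjacency). Scores are sorted
#' descending; ties are broken by feature index, so the ordering is
#' deterministic given the configuration seed.
#'
#' @param F a [FeatureMatrix-class] or samples-by-features matrix.
#' @param labels binary 0/1 vector with both classes present.
#' @param method one of `"CHSQ"`, `"WLCX"`, `"NCA"`, `"ReliefF"`,
#'   `"infFS"`.
#' @param cfg a [selectionConfig()]; `top_k` features are returned (all,
#'   ranked, when fewer are available).
#' @return list with class `RankerResult`: `method`, `ranking` (ordered
#'   feature names, length `min(top_k, p)`), `scores` (full named score
#'   vector).
#' @export
rankFeatures <- function(F, labels,
                         method = c("CHSQ", "WLCX", "NCA", "ReliefF",
                                    "infFS"),
                         cfg = selectionConfig()) {
  method <- match.arg(method)
  X <- if (is(F, "FeatureMatrix")) featureValues(F) else as.matrix(F)
  y <- as.integer(labels)
  stopifnot2(length(unique(y)) == 2, "labels must contain both classes")
  stopifnot2(length(y) == nrow(X), "labels must align with samples")
  sc <- switch(method,
    CHSQ = .chsqScores(X, y, cfg$chsq_bins),
    WLCX = .wlcxScores(X, y),
    NCA = .ncaWeights(X, y, lambda = cfg$nca_lambda, seed = cfg$seed),
    ReliefF = .relieffWeights(X, y, k = cfg$relieff_k),
    infFS = .inffsScores(X, y, alpha = cfg$inffs_alpha,
                         r_factor = cfg$inffs_r_factor))
  names(sc) <- colnames(X)
  # order on 10 significant digits so numerically degenerate score ties
  # (identical features through eigen/optimization round-off) fall back
  # to the index tie-break deterministically
  ord <- order(-signif(sc, 10), seq_along(sc))
  kk <- min(cfg$top_k, ncol(X))
  structure(list(method = method,
                 ranking = colnames(X)[ord[seq_len(kk)]],
                 scores = sc),
            class = "RankerResult")
}

#' The five ranker names of the selection step
#' @return character vector.
#' @export
rankerMethods <- function() c("CHSQ", "WLCX", "NCA", "ReliefF", "infFS")
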
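# Evaluation machinery: Mann-Whitney AUC, the 0.632+ bootstrap estimator,
# greedy forward feature selection maximizing it, the ranker-by-classifier
# model grid, the corrected resampled paired t-test, and the under-sampled
# threshold sweep.

#' Bootstrap configuration
#'
#' @param B number of bootstrap replicates, default 1000.
#' @param seed master seed; per-replicate seeds are derived
#'   deterministically from it.
#' @return list with class `BootstrapConfig`.
#' @export
bootstrapConfig <- function(B = 1000L, seed = 1L) {
  stopifnot2(B >= 1, "B must be >= 1")
  structure(list(B = as.integer(B), seed = as.integer(seed)),
            class = "BootstrapConfig")
}

#' Mann-Whitney AUC of continuous scores against binary labels
#'
#' Fraction of (positive, negative) pairs in which the positive sample
#' scores higher, ties counting one half.
#'
#' @param scores numeric score vector.
#' @param labels binary 0/1 vector; both classes must be present.
#' @return scalar in `[0, 1]`.
#' @export
aucScore <- function(scores, labels) {
  y <- as.integer(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  stopifnot2(n1 > 0 && n0 > 0, "labels must contain both classes")
  r <- rank(scores)                 # average ranks handle ties
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Draw seeded bootstrap replicates
#'
#' Each in-bag multiset is drawn i.i.d. uniform with replacement, size N;
#' the out-of-bag set is the complement of the in-bag support.
#' Reproducible from the master seed.
#'
#' @param N cohort size (>= 1).
#' @param cfg a [bootstrapConfig()].
#' @return list of `B` elements, each `list(inbag, oob)` of integer
#'   indices.
#' @export
bootstrapReplicates <- function(N, cfg = bootstrapConfig()) {
  stopifnot2(N >= 1, "N must be >= 1")
  withLocalSeed(deriveSeed(cfg$seed, "bootstrap"), {
    lapply(seq_len(cfg$B), function(b) {
      inbag <- sample.int(N, N, replace = TRUE)
      list(inbag = inbag, oob = setdiff(seq_len(N), inbag))
    })
  })
}

#' Relative weight of the out-of-bag term in the 0.632+ estimator
#'
#' `a(b) = 0.632 / (1 - 0.368 R(b))`; equals 0.632 when the relative
#' overfitting rate is zero and 1 when it is one.
#'
#' @param R overfitting rate(s) in `[0, 1]`.
#' @return numeric weight(s) in `[0.632, 1]`.
#' @export
bootstrapWeight <- function(R) 0.632 / (1 - 0.368 * R)

#' Relative overfitting rate of one bootstrap replicate
#'
#' 1 when the out-of-bag AUC is at or below chance,
#' `(apparent - oob) / (apparent - 0.5)` when `apparent > oob > 0.5`,
#' and 0 otherwise.
#'
#' @param apparent resubstitution AUC.
#' @param oob out-of-bag AUC.
#' @return scalar in `[0, 1]`.
#' @export
relativeOverfitRate <- function(apparent, oob) {
  if (oob <= 0.5) return(1)
  if (apparent > oob && oob > 0.5) return((apparent - oob) / (apparent - 0.5))
  0
}

#' Single-replicate 0.632+ value from its apparent and out-of-bag AUC
#'
#' `(1 - a) * apparent + a * max(0.5, oob)` with
#' `a = 0.632 / (1 - 0.368 R)`.
#'
#' @inheritParams relativeOverfitRate
#' @return scalar replicate value.
#' @export
replicateValue632 <- function(apparent, oob) {
  R <- relativeOverfitRate(apparent, oob)
  a <- bootstrapWeight(R)
  (1 - a) * apparent + a * max(0.5, oob)
}

.sensSpec <- function(scores, labels, threshold) {
  pred <- as.integer(scores > threshold)
  y <- as.integer(labels)
  c(sens = if (sum(y == 1)) sum(pred == 1 & y == 1) / sum(y == 1) else NA,
    spec = if (sum(y == 0)) sum(pred == 0 & y == 0) / sum(y == 0) else NA)
}

# Core 0.632+ computation over a fixed replicate list (shared replicates
# enable common random numbers across candidate subsets in forward
# selection). The apparent AUC is computed once: it does not depend on b.
.auc632Core <- function(X, y, spec, features, replicates, fitSeedBase) {
  Xf <- X[, features, drop = FALSE]
  appSpec <- spec
  appSpec$seed <- deriveSeed(fitSeedBase, "apparent")
  appModel <- fitClassifier(appSpec, Xf, y)
  appScores <- predictScores(appModel, Xf)
  apparent <- aucScore(appScores, y)
  appSS <- .sensSpec(appScores, y, appModel$threshold)
  B <- length(replicates)
  rep_apparent <- rep(apparent, B)
  oobAuc <- aucPrime <- Rb <- ab <- value <- sensb <- specb <- rep(NA_real_, B)
  skipped <- character(B)
  for (b in seq_len(B)) {
    inbag <- replicates[[b]]$inbag
    oob <- replicates[[b]]$oob
    if (length(unique(y[inbag])) < 2) { skipped[b] <- "single-class in-bag"; next }
    if (length(oob) == 0 || length(unique(y[oob])) < 2) {
      skipped[b] <- "single-class OOB"; next
    }
    bSpec <- spec
    bSpec$seed <- deriveSeed(fitSeedBase, "replicate", b)
    model <- fitClassifier(bSpec, Xf[inbag, , drop = FALSE], y[inbag])
    sc <- predictScores(model, Xf[oob, , drop = FALSE])
    oobAuc[b] <- aucScore(sc, y[oob])
    aucPrime[b] <- max(0.5, oobAuc[b])
    Rb[b] <- relativeOverfitRate(apparent, oobAuc[b])
    ab[b] <- bootstrapWeight(Rb[b])
    value[b] <- (1 - ab[b]) * apparent + ab[b] * aucPrime[b]
    ss <- .sensSpec(sc, y[oob], model$threshold)
    sensb[b] <- (1 - ab[b]) * appSS["sens"] + ab[b] * ss["sens"]
    specb[b] <- (1 - ab[b]) * appSS["spec"] + ab[b] * ss["spec"]
  }
  ok <- skipped == ""
  if (!any(ok)) stop("all bootstrap replicates were degenerate",
                     call. = FALSE)
  diag_df <- data.frame(apparent = rep_apparent, oob = oobAuc,
                        aucPrime = aucPrime, R = Rb, a = ab, value = value,
                        sensitivity = sensb, specificity = specb,
                        skipped = skipped, stringsAsFactors = FALSE)
  new("Auc632Result",
      auc = mean(value[ok]),
      sensitivity = mean(sensb[ok], na.rm = TRUE),
      specificity = mean(specb[ok], na.rm = TRUE),
      features = features, replicates = diag_df,
      effectiveB = sum(ok))
}

#' 0.632+ bootstrap AUC of one feature subset and classifier
#'
#' Per replicate the estimator blends the apparent (resubstitution) AUC
#' with the clamped out-of-bag AUC `AUC' = max(0.5, AUC_oob)` using the
#' weight `a(b) = 0.632 / (1 - 0.368 R(b))`, where the relative
#' overfitting rate `R(b)` is 1 when the out-of-bag AUC falls at or below
#' chance, `(apparent - oob) / (apparent - 0.5)` when
#' `apparent > oob > 0.5`, and 0 otherwise. The estimate is the mean of
#' the replicate values. Replicates whose in-bag or out-of-bag set holds
#' a single class are skipped and logged in the diagnostics; the 0.632+
#' weighted sensitivity and specificity at each model's default decision
#' threshold are reported alongside.
#'
#' @param X samples-by-features matrix or [FeatureMatrix-class].
#' @param y binary 0/1 labels.
#' @param spec a [classifierSpec()].
#' @param features feature-name subset to evaluate (default all).
#' @param cfg a [bootstrapConfig()].
#' @param replicates optional precomputed [bootstrapReplicates()] list
#'   (for common random numbers across calls).
#' @return An [Auc632Result-class].
#' @export
auc632plus <- function(X, y, spec = classifierSpec("LDA"),
                       features = NULL, cfg = bootstrapConfig(),
                       replicates = NULL) {
  X <- if (is(X, "FeatureMatrix")) featureValues(X) else as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- sprintf("x%d", seq_len(ncol(X)))
  features <- features %||% colnames(X)
  stopifnot2(length(features) > 0, "feature subset must be non-empty")
  stopifnot2(all(features %in% colnames(X)), "unknown feature names")
  y <- as.integer(y)
  stopifnot2(length(unique(y)) == 2, "labels must contain both classes")
  replicates <- replicates %||% bootstrapReplicates(length(y), cfg)
  .auc632Core(X, y, spec, features, replicates,
              fitSeedBase = cfg$seed)
}

#' Sensitivity and specificity of a bootstrap evaluation
#' @param result an [Auc632Result-class].
#' @return named numeric vector `c(sensitivity, specificity)`.
#' @export
sensitivitySpecificity <- function(result) {
  c(sensitivity = result@sensitivity, specificity = result@specificity)
}

#' Greedy forward feature selection maximizing the 0.632+ bootstrap AUC
#'
#' Starting from the empty subset, each step adds the candidate that
#' maximizes the 0.632+ AUC of the augmented subset; all candidate
#' subsets share one replicate list (common random numbers), which makes
#' the search deterministic given the master seed. The search stops when
#' no candidate strictly improves the running best AUC (ties do not
#' extend the subset), and the reported AUC is the maximum over visited
#' subsets.
#'
#' @param X samples-by-features matrix or [FeatureMatrix-class].
#' @param y binary 0/1 labels.
#' @param spec a [classifierSpec()].
#' @param candidates character vector of candidate feature names
#'   (typically a ranker's top 10).
#' @param cfg a [bootstrapConfig()].
#' @return The best subset's [Auc632Result-class].
#' @export
forwardSelect <- function(X, y, spec = classifierSpec("LDA"),
                          candidates, cfg = bootstrapConfig()) {
  stopifnot2(length(candidates) > 0, "candidate list must be non-empty")
  X <- if (is(X, "FeatureMatrix")) featureValues(X) else as.matrix(X)
  y <- as.integer(y)
  replicates <- bootstrapReplicates(length(y), cfg)
  selected <- character()
  best <- NULL
  remaining <- candidates
  while (length(remaining)) {
    stepResults <- lapply(remaining, function(f)
      .auc632Core(X, y, spec, c(selected, f), replicates,
                  fitSeedBase = cfg$seed))
    aucs <- vapply(stepResults, function(r) r@auc, numeric(1))
    jbest <- which.max(aucs)       # ties: first (lowest candidate index)
    if (is.null(best) || aucs[jbest] > best@auc) {
      best <- stepResults[[jbest]]
      selected <- c(selected, remaining[jbest])
      remaining <- setdiff(remaining, remaining[jbest])
    } else break
  }
  best
}

#' Evaluate the full ranker-by-classifier model grid
#'
#' For each ranker, ranks the features and takes its top-k candidates;
#' for each classifier, runs [forwardSelect()] on those candidates. The
#' default 5 x 5 grid yields 25 models; the summary is the arithmetic
#' mean and SD of the completed cell AUCs (failed cells are recorded as
#' `NA` with a warning).
#'
#' @param F a [FeatureMatrix-class] or samples-by-features matrix
#'   (normalized).
#' @param labels binary 0/1 vector.
#' @param rankers ranker names, default all five.
#' @param algorithms classifier names, default all five.
#' @param selCfg a [selectionConfig()].
#' @param bootCfg a [bootstrapConfig()].
#' @return A [ModelGridResult-class].
#' @export
evaluateGrid <- function(F, labels, rankers = rankerMethods(),
                         algorithms = classifierAlgorithms(),
                         selCfg = selectionConfig(),
                         bootCfg = bootstrapConfig()) {
  X <- if (is(F, "FeatureMatrix")) featureValues(F) else as.matrix(F)
  y <- as.integer(labels)
  nr <- length(rankers); nc <- length(algorithms)
  aucM <- sensM <- specM <- matrix(NA_real_, nr, nc,
                                   dimnames = list(rankers, algorithms))
  cells <- vector("list", nr * nc)
  dim(cells) <- c(nr, nc)
  dimnames(cells) <- list(rankers, algorithms)
  for (ri in seq_len(nr)) {
    cand <- rankFeatures(X, y, method = rankers[ri], cfg = selCfg)$ranking
    for (ci in seq_len(nc)) {
      res <- tryCatch(
        forwardSelect(X, y, classifierSpec(algorithms[ci]),
                      candidates = cand, cfg = bootCfg),
        error = function(e) e)
      if (inherits(res, "error")) {
        warning(sprintf("grid cell %s x %s failed: %s", rankers[ri],
                        algorithms[ci], conditionMessage(res)))
      } else {
        aucM[ri, ci] <- res@auc
        sensM[ri, ci] <- res@sensitivity
        specM[ri, ci] <- res@specificity
        cells[[ri, ci]] <- res
      }
    }
  }
  vals <- aucM[!is.na(aucM)]
  new("ModelGridResult", auc = aucM, sensitivity = sensM,
      specificity = specM,
      meanAuc = mean(vals),
      sdAuc = if (length(vals) > 1) sd(vals) else 0,
      cells = cells[seq_along(cells)])
}

#' Corrected resampled paired t-test on per-replicate AUC differences
#'
#' `t = mean(d) / sqrt((1/K + n_test/n_train) * s_d^2)` with the sample
#' variance of the differences, `K - 1` degrees of freedom and a
#' one-tailed upper-tail p-value (alternative: the first model performs
#' better). The `n_test/n_train` correction compensates the overlap of
#' resampled training sets; with bootstrap resampling the mean in-bag and
#' out-of-bag sizes over the replicates are used.
#'
#' @param d paired differences, one per resampling replicate.
#' @param n_train average training-set size.
#' @param n_test average test-set size.
#' @return list with class `TTestResult`: `t`, `df`, `p` (one-tailed),
#'   `ratio`, `degenerate` flag.
#' @export
correctedResampledTTest <- function(d, n_train, n_test) {
  K <- length(d)
  stopifnot2(K >= 2, "need at least two paired differences")
  md <- mean(d)
  s2 <- var(d)
  factor <- 1 / K + n_test / n_train
  degenerate <- s2 == 0
  t <- if (degenerate) {
    if (md == 0) 0 else sign(md) * Inf
  } else md / sqrt(factor * s2)
  p <- pt(t, df = K - 1, lower.tail = FALSE)
  structure(list(t = t, df = K - 1, p = p, ratio = n_test / n_train,
                 degenerate = degenerate),
            class = "TTestResult")
}

#' Threshold sweep with random under-sampling of the majority class
#'
#' For each labeling threshold (in % volume loss per treatment day), the
#' cohort is relabeled, the majority class is repeatedly down-sampled
#' without replacement to the minority size, and the 0.632+ AUC is
#' averaged over the under-samplings. Already balanced thresholds reduce
#' to a single plain evaluation; thresholds that empty one class are
#' skipped with a warning.
#'
#' @param X samples-by-features matrix or [FeatureMatrix-class].
#' @param rates per-sample regression rates (% per treatment day).
#' @param thresholds numeric vector of thresholds; the canonical sweep
#'   lists are `c(0.46, 0.8, 1.2, 2.0, 2.4, 2.8, 3.2)` for primary and
#'   `c(1.4, 1.7, 2.1, 2.5, 2.9, 3.3, 4.1)` for nodal tumors.
#' @param spec a [classifierSpec()].
#' @param features feature subset (default all).
#' @param cfg a [bootstrapConfig()].
#' @param U number of under-samplings, default 100 (reducible for
#'   desk-scale runs).
#' @return data.frame with threshold, mean AUC, effective U and class
#'   sizes.
#' @export
undersampleSweep <- function(X, rates, thresholds, spec = classifierSpec("LDA"),
                             features = NULL, cfg = bootstrapConfig(),
                             U = 100L) {
  X <- if (is(X, "FeatureMatrix")) featureValues(X) else as.matrix(X)
  out <- data.frame(threshold = thresholds, auc = NA_real_,
                    U = NA_integer_, n_minority = NA_integer_,
                    n_majority = NA_integer_)
  for (ti in seq_along(thresholds)) {
    y <- as.integer(rates > thresholds[ti])
    n1 <- sum(y == 1); n0 <- sum(y == 0)
    if (n1 == 0 || n0 == 0) {
      warning(sprintf("threshold %.3g leaves a single class; skipped",
                      thresholds[ti]))
      next
    }
    out$n_minority[ti] <- min(n1, n0)
    out$n_majority[ti] <- max(n1, n0)
    if (n1 == n0) {
      res <- auc632plus(X, y, spec, features, cfg)
      out$auc[ti] <- res@auc
      out$U[ti] <- 1L
      next
    }
    minority <- if (n1 < n0) 1L else 0L
    minIdx <- which(y == minority)
    majIdx <- which(y != minority)
    vals <- numeric(U)
    for (u in seq_len(U)) {
      keepMaj <- withLocalSeed(
        deriveSeed(cfg$seed, sprintf("undersample_t%d", ti), u),
        sample(majIdx, length(minIdx)))
      sel <- sort(c(minIdx, keepMaj))
      uCfg <- bootstrapConfig(B = cfg$B,
                              seed = deriveSeed(cfg$seed, "sweep_boot", u))
      res <- auc632plus(X[sel, , drop = FALSE], y[sel], spec, features,
                        uCfg)
      vals[u] <- res@auc
    }
    out$auc[ti] <- mean(vals)
    out$U[ti] <- U
  }
  out
}

#' Spearman correlation of selected features with tumor volume
#'
#' Useful image features are known to correlate with tumor volume; this
#' check reports the rank correlation of each feature with the initial
#' tumor volume so volume-surrogate features can be flagged.
#'
#' @param F a [FeatureMatrix-class] or samples-by-features matrix.
#' @param volumes per-sample tumor volumes, aligned with rows.
#' @return data.frame with feature name and Spearman rho (`NA` for
#'   constant features).
#' @export
volumeCorrelationCheck <- function(F, volumes) {
  vals <- if (is(F, "FeatureMatrix")) featureValues(F) else as.matrix(F)
  if (is.null(colnames(vals)))
    colnames(vals) <- sprintf("x%d", seq_len(ncol(vals)))
  stopifnot2(length(volumes) == nrow(vals),
             "volumes must align with samples")
  rho <- vapply(seq_len(ncol(vals)), function(j) {
    x <- vals[, j]
    if (sd(x) == 0 || sd(volumes) == 0) return(NA_real_)
    suppressWarnings(cor(x, volumes, method = "spearman"))
  }, numeric(1))
  data.frame(feature = colnames(vals), rho = rho,
             stringsAsFactors = FALSE)
}
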
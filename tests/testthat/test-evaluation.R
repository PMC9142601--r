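test_that("the Mann-Whitney AUC matches exhaustive pair enumeration", {
  expect_equal(aucScore(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(aucScore(rep(0.4, 6), rep(c(0, 1), 3)), 0.5)
  expect_equal(aucScore(c(0.9, 0.4, 0.6, 0.2), c(1, 1, 0, 0)), 0.75)
  set.seed(6)
  for (rep_ in 1:8) {
    n <- sample(6:30, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- round(rnorm(n), 1)               # coarse scores force ties
    expect_equal(aucScore(s, y), aucByEnumeration(s, y),
                 tolerance = 1e-12)
  }
  expect_error(aucScore(1:4, rep(1, 4)), "both classes")
})

test_that("bootstrap replicates have the expected in-bag/out-of-bag structure", {
  reps <- bootstrapReplicates(96, bootstrapConfig(B = 1000, seed = 123))
  nin <- vapply(reps, function(r) length(unique(r$inbag)), integer(1))
  noob <- vapply(reps, function(r) length(r$oob), integer(1))
  expect_equal(round(mean(nin)), 61)
  expect_equal(round(mean(noob)), 35)
  expect_true(all(vapply(reps, function(r) length(r$inbag), integer(1)) == 96))
  expect_true(all(mapply(function(r)
    setequal(r$oob, setdiff(1:96, r$inbag)), reps)))

  reps79 <- bootstrapReplicates(79, bootstrapConfig(B = 1000, seed = 123))
  expect_equal(round(mean(vapply(reps79, function(r)
    length(unique(r$inbag)), integer(1)))), 50)
  expect_equal(round(mean(vapply(reps79, function(r)
    length(r$oob), integer(1)))), 29)

  r1 <- bootstrapReplicates(1, bootstrapConfig(B = 3, seed = 1))
  expect_identical(r1[[1]]$inbag, 1L)
  expect_length(r1[[1]]$oob, 0L)
  # reproducible from the master seed
  expect_identical(bootstrapReplicates(20, bootstrapConfig(B = 5, seed = 9)),
                   bootstrapReplicates(20, bootstrapConfig(B = 5, seed = 9)))
})

test_that("the 0.632+ replicate equations reproduce hand-evaluated cases", {
  expect_equal(bootstrapWeight(0), 0.632)
  expect_equal(bootstrapWeight(1), 1)
  # apparent = OOB = 0.8: no overfitting, weights blend back to 0.8
  expect_equal(replicateValue632(0.8, 0.8), 0.8, tolerance = 1e-12)
  # total overfit: apparent 1.0, OOB 0.4 -> AUC' = 0.5, R = 1, a = 1
  expect_equal(relativeOverfitRate(1.0, 0.4), 1)
  expect_equal(replicateValue632(1.0, 0.4), 0.5, tolerance = 1e-12)
  # intermediate: apparent 0.9, OOB 0.7 -> R = 0.5, a = 0.632/0.816
  expect_equal(relativeOverfitRate(0.9, 0.7), 0.5)
  a <- 0.632 / 0.816
  expect_equal(replicateValue632(0.9, 0.7), (1 - a) * 0.9 + a * 0.7,
               tolerance = 1e-12)
  # weight range invariant
  for (R in seq(0, 1, by = 0.1)) {
    w <- bootstrapWeight(R)
    expect_true(w >= 0.632 && w <= 1)
  }
})

test_that("auc632plus honors its per-replicate accounting", {
  co <- makeFeatureCohort(cohortSpec(n = 60, p = 4, n_informative = 1,
                                     delta = 2, n_redundant = 0, seed = 8))
  X <- featureValues(zscoreNormalize(co$features))
  res <- auc632plus(X, co$labels, classifierSpec("LDA"),
                    features = "feature_0001",
                    cfg = bootstrapConfig(B = 60, seed = 4))
  d <- res@replicates
  ok <- d$skipped == ""
  expect_equal(res@auc, mean(d$value[ok]))
  expect_true(all(d$aucPrime[ok] >= 0.5))
  expect_true(all(d$R[ok] >= 0 & d$R[ok] <= 1))
  expect_true(all(d$a[ok] >= 0.632 & d$a[ok] <= 1))
  expect_equal(res@effectiveB, sum(ok))
  expect_true(res@auc >= 0 && res@auc <= 1)
  # when R = 0 everywhere the estimate is 0.632 mean(AUC') + 0.368 apparent
  r0 <- d$R[ok] == 0
  if (any(r0)) {
    expect_equal(d$value[ok][r0],
                 0.368 * d$apparent[ok][r0] + 0.632 * d$aucPrime[ok][r0],
                 tolerance = 1e-12)
  }
})

test_that("label-independent classifiers concentrate near chance", {
  co <- makeFeatureCohort(cohortSpec(n = 80, p = 3, n_informative = 0,
                                     delta = 0, n_redundant = 0, seed = 19))
  X <- featureValues(zscoreNormalize(co$features))
  res <- auc632plus(X, co$labels, classifierSpec("LDA"),
                    cfg = bootstrapConfig(B = 200, seed = 7))
  expect_true(abs(res@auc - 0.5) < 0.07)
})

test_that("sensitivity and specificity track degenerate classifiers correctly", {
  y <- rep(c(0, 1), each = 20)
  Xsep <- cbind(f = c(rnorm(20, -6, 0.1), rnorm(20, 6, 0.1)))
  perfect <- auc632plus(Xsep, y, classifierSpec("LDA"),
                        cfg = bootstrapConfig(B = 40, seed = 2))
  expect_equal(unname(sensitivitySpecificity(perfect)), c(1, 1),
               tolerance = 1e-9)

  # an all-positive scorer: sensitivity 1, specificity 0
  allpos <- list(spec = classifierSpec("LDA"), features = "f",
                 fit = list(w = matrix(0), b = 10), threshold = 0.5)
  class(allpos) <- "TrainedModel"
  sc <- predictScores(allpos, Xsep)
  ss <- DLRadiomics:::.sensSpec(sc, y, 0.5)
  expect_equal(unname(ss), c(1, 0))
})

test_that("seed stability: different master seeds move the estimate only slightly", {
  co <- makeFeatureCohort(cohortSpec(n = 96, p = 5, n_informative = 1,
                                     delta = 1.5, n_redundant = 0, seed = 12))
  X <- featureValues(zscoreNormalize(co$features))
  r1 <- auc632plus(X, co$labels, classifierSpec("LDA"),
                   features = "feature_0001",
                   cfg = bootstrapConfig(B = 150, seed = 1))
  r2 <- auc632plus(X, co$labels, classifierSpec("LDA"),
                   features = "feature_0001",
                   cfg = bootstrapConfig(B = 150, seed = 999))
  expect_lt(abs(r1@auc - r2@auc), 0.03)
  expect_lt(abs(r1@sensitivity - r2@sensitivity), 0.05)
})

test_that("forward selection finds informative features and rejects duplicates", {
  co <- makeFeatureCohort(cohortSpec(n = 100, p = 10, n_informative = 1,
                                     delta = 2, n_redundant = 0, seed = 23))
  X <- featureValues(zscoreNormalize(co$features))
  res <- forwardSelect(X, co$labels, classifierSpec("LDA"),
                       candidates = colnames(X),
                       cfg = bootstrapConfig(B = 40, seed = 3))
  expect_true("feature_0001" %in% res@features)

  # identical copies add nothing to a rank-based AUC: subset stays size 1
  dup <- X[, rep(1, 5)]
  colnames(dup) <- paste0("copy", 1:5)
  resd <- forwardSelect(dup, co$labels, classifierSpec("LDA"),
                        candidates = colnames(dup),
                        cfg = bootstrapConfig(B = 40, seed = 3))
  expect_length(resd@features, 1L)

  # common random numbers make the search deterministic
  res2 <- forwardSelect(X, co$labels, classifierSpec("LDA"),
                        candidates = colnames(X),
                        cfg = bootstrapConfig(B = 40, seed = 3))
  expect_identical(res@features, res2@features)
  expect_identical(res@auc, res2@auc)
  expect_error(forwardSelect(X, co$labels, classifierSpec("LDA"),
                             candidates = character(0)), "non-empty")
})

test_that("the model grid has the declared shape and summary", {
  co <- makeFeatureCohort(cohortSpec(n = 50, p = 8, n_informative = 1,
                                     delta = 1.5, n_redundant = 1, seed = 31))
  Fz <- zscoreNormalize(co$features)
  grid <- evaluateGrid(Fz, co$labels,
                       rankers = c("WLCX", "CHSQ"),
                       algorithms = c("LDA", "NB", "KNN"),
                       selCfg = selectionConfig(top_k = 3),
                       bootCfg = bootstrapConfig(B = 15, seed = 5))
  expect_equal(dim(grid@auc), c(2L, 3L))
  expect_equal(grid@meanAuc, mean(grid@auc))
  expect_equal(grid@sdAuc, sd(as.numeric(grid@auc)))
  expect_true(all(grid@auc >= 0 & grid@auc <= 1))
})

test_that("the corrected resampled t-test matches hand arithmetic", {
  z <- correctedResampledTTest(rep(0, 5), 61, 35)
  expect_equal(z$t, 0)
  expect_equal(z$p, 0.5)

  d <- c(0.1, 0.2, 0.0, 0.1)
  res <- correctedResampledTTest(d, 61, 35)
  tHand <- mean(d) / sqrt((1 / 4 + 35 / 61) * var(d))
  expect_equal(res$t, tHand, tolerance = 1e-12)
  expect_equal(res$t, 1.35, tolerance = 0.01)
  expect_equal(res$df, 3)
  expect_equal(res$p, pt(tHand, 3, lower.tail = FALSE), tolerance = 1e-12)

  # t is invariant to positive scaling of the differences
  expect_equal(correctedResampledTTest(10 * d, 61, 35)$t, res$t,
               tolerance = 1e-12)
  degen <- correctedResampledTTest(rep(0.2, 4), 61, 35)
  expect_true(degen$degenerate)
  expect_equal(degen$p, 0)
  expect_error(correctedResampledTTest(0.1, 61, 35), "at least two")
})

test_that("the under-sampling sweep reduces to a plain evaluation when balanced", {
  co <- makeFeatureCohort(cohortSpec(n = 60, p = 4, n_informative = 1,
                                     delta = 1.5, n_redundant = 0, seed = 41))
  X <- featureValues(zscoreNormalize(co$features))
  rates <- co$labels + runif(60, -0.4, 0.4)  # median split reproduces labels
  thr <- 0.5
  cfg <- bootstrapConfig(B = 25, seed = 11)
  sw <- undersampleSweep(X, rates, thresholds = thr,
                         spec = classifierSpec("LDA"), cfg = cfg, U = 5)
  plain <- auc632plus(X, as.integer(rates > thr), classifierSpec("LDA"),
                      cfg = cfg)
  expect_equal(sw$auc[1], plain@auc)
  expect_equal(sw$U[1], 1L)

  # imbalanced threshold: U under-samplings, still chance level on noise
  nullco <- makeFeatureCohort(cohortSpec(n = 80, p = 3, n_informative = 0,
                                         delta = 0, n_redundant = 0, seed = 2))
  Xn <- featureValues(zscoreNormalize(nullco$features))
  set.seed(10)
  rn <- rnorm(80, 1, 1)
  swn <- undersampleSweep(Xn, rn, thresholds = c(0.2, 1.8),
                          spec = classifierSpec("LDA"),
                          cfg = bootstrapConfig(B = 20, seed = 6), U = 8)
  expect_true(all(abs(swn$auc - 0.5) < 0.1))
  expect_warning(undersampleSweep(Xn, rn, thresholds = 99,
                                  cfg = bootstrapConfig(B = 5, seed = 1),
                                  U = 2),
                 "single class")
})

test_that("volume correlation reports exact rank correlations", {
  vol <- c(5, 9, 2, 14, 7, 11)
  F <- cbind(exact = vol, reversed = -vol, noise = c(3, 1, 4, 1, 5, 9),
             const = rep(2, 6))
  vc <- volumeCorrelationCheck(F, vol)
  expect_equal(vc$rho[vc$feature == "exact"], 1)
  expect_equal(vc$rho[vc$feature == "reversed"], -1)
  expect_true(is.na(vc$rho[vc$feature == "const"]))
  set.seed(70)
  Fn <- matrix(rnorm(96 * 5), 96, 5)
  vcn <- volumeCorrelationCheck(Fn, rnorm(96))
  expect_true(all(abs(vcn$rho) < 0.3))
})
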
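test_that("ICC(3,A,1) matches its defining agreement cases", {
  # identical rater columns with subject variance: perfect agreement
  base <- c(1, 3, 7, 2)
  expect_equal(iccCase3A(cbind(base, base, base)), 1)

  # constant rater offset: strictly below 1, equal to the ANOVA oracle
  m <- cbind(base, base + 1, base + 2)
  expect_lt(iccCase3A(m), 1)
  expect_equal(iccCase3A(m), iccByAov(m), tolerance = 1e-12)

  expect_warning(icc0 <- iccCase3A(matrix(5, 4, 3)), "undefined")
  expect_true(is.nan(icc0))
  expect_error(iccCase3A(matrix(1:3, 3, 1)), "raters")
})

test_that("ICC matches the brute-force ANOVA oracle on random matrices", {
  set.seed(404)
  for (n in c(4, 7, 10)) {
    for (k in c(3, 6, 9)) {
      m <- matrix(rnorm(n * k), n, k) +
        rnorm(n) * 1.5 +                 # subject effects
        rep(rnorm(k) * 0.5, each = n)    # rater effects
      expect_equal(iccCase3A(m), iccByAov(m), tolerance = 1e-10)
    }
  }
})

test_that("robustness filtering keeps reproducible features and drops noisy ones", {
  set.seed(7)
  ns <- 12; nr <- 9
  subj <- rnorm(ns, sd = 3)
  ms <- array(NA_real_, c(ns, nr, 3),
              dimnames = list(NULL, NULL, c("stable", "noisy", "boundary")))
  ms[, , "stable"] <- subj                        # identical across raters
  ms[, , "noisy"] <- rnorm(ns * nr)               # fresh noise per rater
  # a feature with moderate rater noise: its own ICC used as the
  # threshold must drop it (strict >)
  ms[, , "boundary"] <- subj + matrix(rnorm(ns * nr, sd = 0.5), ns, nr)
  cfg <- selectionConfig()
  kept <- filterRobust(ms, cfg)
  expect_true("stable" %in% kept)
  expect_false("noisy" %in% kept)

  icc_b <- iccCase3A(ms[, , "boundary"])
  expect_identical(filterRobust(list(atcut = ms[, , "boundary"]),
                                selectionConfig(icc_threshold = icc_b)),
                   character(0))                  # strict inequality
  # sample-permutation invariance
  perm <- sample(ns)
  expect_identical(sort(filterRobust(ms[perm, , ], cfg)), sort(kept))
})

test_that("collinearity pruning reproduces the worked three-feature case", {
  X <- cbind(A = 1:5, B = 1:5, C = c(5, 1, 4, 2, 3))
  # rho(A,B) = 1, rho(A,C) = rho(B,C) = -0.3; mean |rho| ties at 0.65,
  # so the higher-index member of the offending pair (B) is dropped
  expect_identical(pruneCollinear(X), c("A", "C"))

  set.seed(21)
  noise <- matrix(rnorm(60 * 8), 60, 8,
                  dimnames = list(NULL, paste0("n", 1:8)))
  expect_identical(pruneCollinear(noise), colnames(noise))

  single <- matrix(1:5, ncol = 1, dimnames = list(NULL, "only"))
  expect_identical(pruneCollinear(single), "only")
})

test_that("pruning terminates with no retained pair above the threshold", {
  set.seed(90)
  base <- matrix(rnorm(50 * 4), 50, 4)
  X <- cbind(base,
             base + matrix(rnorm(50 * 4, sd = 0.1), 50, 4),  # near-copies
             matrix(rnorm(50 * 4), 50, 4))
  colnames(X) <- sprintf("f%02d", 1:12)
  kept <- pruneCollinear(X)
  rho <- abs(cor(X[, kept], method = "spearman"))
  diag(rho) <- 0
  expect_true(all(rho <= 0.8))                    # exhaustive pair scan
  # anti-correlated duplicates are equally redundant
  Y <- cbind(a = 1:20 + rnorm(20, sd = 0.01), b = -(1:20) + rnorm(20, sd = 0.01))
  expect_length(pruneCollinear(Y), 1L)
})

test_that("WLCX ranks a cleanly separated feature first", {
  set.seed(33)
  y <- rep(c(0, 1), each = 3)
  X <- cbind(sep = c(1, 2, 3, 7, 8, 9),
             matrix(rnorm(6 * 6), 6, 6, dimnames = list(NULL, paste0("n", 1:6))))
  rr <- rankFeatures(X, y, method = "WLCX", cfg = selectionConfig(top_k = 3))
  expect_equal(rr$ranking[1], "sep")

  # rank-based statistic: invariant under strictly monotone transforms
  Xe <- X; Xe[, "sep"] <- exp(X[, "sep"])
  expect_equal(rankFeatures(Xe, y, method = "WLCX")$scores,
               rankFeatures(X, y, method = "WLCX")$scores)
})

test_that("identical features fall back to a stable index tie-break", {
  y <- rep(c(0, 1), each = 5)
  X <- matrix(rep(c(1:5, 6:10), 4), ncol = 4,
              dimnames = list(NULL, paste0("dup", 1:4)))
  for (m in rankerMethods()) {
    rr <- rankFeatures(X, y, method = m, cfg = selectionConfig(top_k = 4))
    expect_identical(rr$ranking, paste0("dup", 1:4))
  }
})

test_that("all five rankers recover a planted informative feature among noise", {
  hits <- sapply(1:6, function(s) {
    co <- makeFeatureCohort(cohortSpec(n = 200, p = 51, n_informative = 1,
                                       delta = 2, n_redundant = 0, seed = s))
    Fz <- featureValues(zscoreNormalize(co$features))
    sapply(rankerMethods(), function(m) {
      "feature_0001" %in%
        rankFeatures(Fz, co$labels, method = m)$ranking
    })
  })
  expect_true(all(rowMeans(hits) >= 5 / 6))
})

test_that("infFS path sums match a truncated geometric-series oracle", {
  co <- makeFeatureCohort(cohortSpec(n = 80, p = 12, n_informative = 2,
                                     delta = 1.5, n_redundant = 2, seed = 17))
  Fz <- featureValues(zscoreNormalize(co$features))
  y <- co$labels
  sc <- rankFeatures(Fz, y, method = "infFS")$scores

  # rebuild the documented adjacency and sum the power series directly
  mu0 <- colMeans(Fz[y == 0, ]); mu1 <- colMeans(Fz[y == 1, ])
  v0 <- apply(Fz[y == 0, ], 2, var); v1 <- apply(Fz[y == 1, ], 2, var)
  n0 <- sum(y == 0); n1 <- sum(y == 1)
  spool <- sqrt(((n0 - 1) * v0 + (n1 - 1) * v1) / (n0 + n1 - 2))
  s <- abs(mu1 - mu0) / spool; s <- s / max(s)
  rho <- abs(cor(Fz, method = "spearman"))
  A <- 0.5 * outer(s, s, pmax) + 0.5 * (1 - rho)
  diag(A) <- 0
  r <- 0.9 / max(abs(eigen(A, only.values = TRUE)$values))
  Spow <- matrix(0, 12, 12)
  term <- diag(12)
  for (l in 1:200) {
    term <- term %*% (r * A)
    Spow <- Spow + term
  }
  expect_equal(unname(sc), unname(rowSums(Spow)), tolerance = 1e-8)
})

test_that("NCA ranking is deterministic given the configuration seed", {
  co <- makeFeatureCohort(cohortSpec(n = 60, p = 8, n_informative = 1,
                                     delta = 2, n_redundant = 0, seed = 3))
  Fz <- featureValues(zscoreNormalize(co$features))
  r1 <- rankFeatures(Fz, co$labels, method = "NCA",
                     cfg = selectionConfig(seed = 5))
  r2 <- rankFeatures(Fz, co$labels, method = "NCA",
                     cfg = selectionConfig(seed = 5))
  expect_identical(r1$scores, r2$scores)
  expect_equal(r1$ranking[1], "feature_0001")
  expect_error(rankFeatures(Fz, rep(1, 60), method = "NCA"), "both classes")
})
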
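test_that("phantoms are seeded ellipsoids with the analytic volume", {
  sp <- spherePhantom(radius_mm = 10, seed = 3)
  expect_equal(sum(voxels(sp$mask)), 4 / 3 * pi * 10^3, tolerance = 0.05)
  sp2 <- spherePhantom(radius_mm = 10, seed = 3)
  expect_identical(voxels(sp2$vol), voxels(sp$vol))     # pure in the seed
  expect_false(identical(voxels(spherePhantom(10, 4)$vol), voxels(sp$vol)))

  # equatorial slice is the max-area slice (counting oracle)
  areas <- apply(voxels(sp$mask), 3, sum)
  expect_equal(selectMaxAreaSlice(sp$mask), which.max(areas))
  # background constant, tumor textured
  vox <- voxels(sp$vol)
  expect_equal(unique(vox[voxels(sp$mask) == 0]), -100)
  expect_gt(sd(vox[voxels(sp$mask) == 1]), 0)

  expect_error(makePhantom(phantomSpec(shape = c(20, 20, 20),
                                       semiaxes_mm = c(15, 15, 15))),
               "fit")
})

test_that("perturbed segmentations degrade smoothly with magnitude", {
  sp <- spherePhantom(radius_mm = 8, seed = 5)
  id <- perturbSegmentations(sp$mask, n_raters = 9, magnitude = 0, seed = 1)
  expect_length(id, 9L)
  for (m in id) expect_identical(voxels(m), voxels(sp$mask))

  small <- perturbSegmentations(sp$mask, n_raters = 9, magnitude = 0.5,
                                seed = 1)
  dices <- utils::combn(9, 2, function(ij)
    diceOverlap(small[[ij[1]]], small[[ij[2]]]))
  expect_true(all(dices > 0.8))

  # mask-volume robustness: ICC near 1 at small magnitude, decreasing;
  # subjects must differ in size for between-subject variance to exist
  radii <- c(6, 7, 8, 9, 10, 11)
  volFeature <- function(magnitude) {
    sapply(seq_along(radii), function(s) {
      ph <- spherePhantom(radius_mm = radii[s], seed = 100 + s)
      masks <- perturbSegmentations(ph$mask, 9, magnitude, seed = s)
      vapply(masks, function(m) sum(voxels(m)), numeric(1))
    })
  }
  iccSmall <- iccCase3A(t(volFeature(0.3)))
  iccLarge <- iccCase3A(t(volFeature(3)))
  expect_gt(iccSmall, 0.9)
  expect_gt(iccSmall, iccLarge)
})

test_that("feature cohorts plant the declared ground truth", {
  spec <- cohortSpec(n = 2000, p = 4, n_informative = 1, delta = 2,
                     n_redundant = 1, redundant_rho = 0.95, seed = 99)
  co <- makeFeatureCohort(spec)
  X <- featureValues(co$features)
  y <- co$labels
  # raw informative feature has the closed-form binormal AUC
  expect_equal(aucScore(X[, "feature_0001"], y), pnorm(2 / sqrt(2)),
               tolerance = 0.02)
  # redundant copy hits its target Spearman correlation
  expect_equal(cor(X[, "feature_0001"], X[, "feature_0002"],
                   method = "spearman"), 0.95, tolerance = 0.02)
  expect_identical(co$truth$informative, "feature_0001")
  expect_identical(names(co$truth$redundant), "feature_0002")

  # pruning removes exactly one member of the redundant pair
  kept <- pruneCollinear(featureValues(zscoreNormalize(co$features)))
  expect_length(setdiff(c("feature_0001", "feature_0002"), kept), 1L)

  # determinism and label balance
  co2 <- makeFeatureCohort(spec)
  expect_identical(featureValues(co2$features), X)
  expect_equal(sum(y), 1000)

  expect_error(makeFeatureCohort(cohortSpec(p = 3, n_informative = 2,
                                            n_redundant = 2)),
               "exceed")
  expect_error(makeFeatureCohort(cohortSpec(redundant_rho = 1.2)), "(0, 1)")
})

test_that("a null cohort carries no signal", {
  co <- makeFeatureCohort(cohortSpec(n = 1000, p = 5, n_informative = 0,
                                     delta = 0, n_redundant = 0, seed = 50))
  X <- featureValues(co$features)
  tr <- 1:500; te <- 501:1000
  m <- fitClassifier(classifierSpec("LDA"), X[tr, ], co$labels[tr])
  expect_lt(abs(aucScore(predictScores(m, X[te, ]), co$labels[te]) - 0.5),
            0.07)
})

test_that("multi-segmentation feature sets have the declared shape", {
  phantoms <- lapply(1:3, function(s)
    makePhantom(phantomSpec(shape = c(48, 48, 40),
                            semiaxes_mm = c(10, 9, 8), seed = s)))
  ms <- multiSegFeatureSet(phantoms, n_raters = 4, magnitude = 0.5,
                           extractor = extractorSpec(dim = 25L), seed = 1)
  expect_equal(dim(ms), c(3L, 4L, 25L))
  expect_false(anyNA(ms))
})
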
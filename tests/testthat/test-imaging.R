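test_that("isotropic resampling covers the physical extent and keeps masks binary", {
  # already isotropic: identity
  v <- CTVolume(array(rnorm(4 * 5 * 6), c(4, 5, 6)))
  m <- SegMask(array(rbinom(4 * 5 * 6, 1, 0.4), c(4, 5, 6)))
  rs <- resampleIsotropic(v, m)
  expect_identical(voxels(rs$vol), voxels(v))
  expect_identical(voxels(rs$mask), voxels(m))

  # 4 axial slices at 2.5 mm span 10 mm -> 10 slices at 1 mm
  v2 <- CTVolume(array(rnorm(3 * 3 * 4), c(3, 3, 4)), spacing = c(1, 1, 2.5))
  m2 <- SegMask(array(1, c(3, 3, 4)), spacing = c(1, 1, 2.5))
  rs2 <- resampleIsotropic(v2, m2)
  expect_equal(dim(voxels(rs2$vol))[3], 10)
  expect_equal(spacing(rs2$vol), c(1, 1, 1))
  # nearest-neighbour from the origin-anchored grid: slice z maps to input
  # round((z-1)/2.5)+1
  expect_equal(voxels(rs2$vol)[1, 1, ],
               voxels(v2)[1, 1, pmin(round(((1:10) - 1) / 2.5) + 1, 4)])

  # nearest neighbour preserves the label set
  v3 <- CTVolume(array(rnorm(6 * 6 * 6), c(6, 6, 6)), spacing = c(1.3, 0.7, 2))
  m3 <- SegMask(array(rbinom(216, 1, 0.5), c(6, 6, 6)), spacing = c(1.3, 0.7, 2))
  rs3 <- resampleIsotropic(v3, m3)
  expect_true(all(voxels(rs3$mask) %in% c(0, 1)))

  expect_error(CTVolume(array(0, c(2, 2, 2)), spacing = c(1, -1, 1)),
               "positive")
})

test_that("maximum-area slice selection is an argmax over mask areas with low-index ties", {
  a <- array(0, c(6, 6, 3))
  a[1:3, 1, 1] <- 1          # area 3
  a[1:5, 1:2, 2] <- 1        # area 10
  a[1:6, 1, 3] <- 1; a[1, 2, 3] <- 1  # area 7
  expect_equal(selectMaxAreaSlice(SegMask(a)), 2L)

  b <- array(0, c(4, 4, 5)); b[2, 3, 4] <- 1
  expect_equal(selectMaxAreaSlice(SegMask(b)), 4L)

  # tie broken by the lowest slice index
  tie <- array(0, c(4, 4, 4)); tie[1:2, 1, 2] <- 1; tie[1:2, 1, 3] <- 1
  expect_equal(selectMaxAreaSlice(SegMask(tie)), 2L)

  # digital ellipsoid: agrees with a per-slice counting oracle and is
  # intensity-invariant (it never sees the CT volume)
  ph <- makePhantom(phantomSpec(seed = 11))
  areas <- apply(voxels(ph$mask), 3, sum)
  expect_equal(selectMaxAreaSlice(ph$mask), which.max(areas))

  expect_error(selectMaxAreaSlice(SegMask(array(0, c(3, 3, 3)))),
               "foreground")
})

test_that("crop centering follows the center of gravity and re-centers on the largest component", {
  cfg <- preprocessConfig()
  # single disc: center = rounded centroid
  sl <- discSlice(200, 200, list(c(80, 120)), 5)
  cr <- cropCentered(sl * 40, sl, cfg, fill = -100)
  expect_equal(cr$center, c(80, 120))
  expect_equal(dim(cr$pixels), c(100, 100))

  # two discs with areas ~50 and ~20 inside the initial crop: final
  # center is the centroid of the larger disc
  sl2 <- discSlice(200, 200, list(c(100, 90), c(100, 130)), c(4, 2.5))
  big <- discSlice(200, 200, list(c(100, 90)), 4)
  small <- discSlice(200, 200, list(c(100, 130)), 2.5)
  expect_gt(sum(big), sum(small))
  cr2 <- cropCentered(sl2 * 40, sl2, cfg, fill = -100)
  bigCog <- colMeans(which(big == 1, arr.ind = TRUE))
  expect_equal(cr2$center, unname(ceiling(bigCog - 0.5)))

  # tumor near the volume edge: declared size retained, border padded
  sl3 <- discSlice(60, 60, list(c(5, 5)), 3)
  cr3 <- cropCentered(sl3 * 40 - 100 * (1 - sl3), sl3, cfg, fill = -1000)
  expect_equal(dim(cr3$pixels), c(100, 100))
  expect_true(any(cr3$pixels == -1000))

  expect_error(cropCentered(matrix(0, 9, 9), matrix(0, 9, 9), cfg, 0),
               "empty")
})

test_that("background masking alters exactly the background pixel set", {
  px <- matrix(rnorm(100, 50, 20), 10, 10)
  mk <- matrix(rbinom(100, 1, 0.5), 10, 10)
  out <- maskBackground(px, mk, fill = -77)
  expect_true(all(out[mk == 0] == -77))          # pixelwise oracle
  expect_identical(out[mk == 1], px[mk == 1])
  expect_identical(maskBackground(px, matrix(1, 10, 10), -77), px)
  expect_true(all(maskBackground(px, matrix(0, 10, 10), -77) == -77))
})

test_that("intensity windowing maps [-125, 225] HU onto [0, 1] with clipping", {
  cfg <- preprocessConfig()
  expect_equal(windowIntensity(-125, cfg), 0)
  expect_equal(windowIntensity(225, cfg), 1)
  expect_equal(windowIntensity(50, cfg), 0.5)
  expect_equal(windowIntensity(-1000, cfg), 0)
  x <- seq(-1500, 1500, by = 7)
  w <- windowIntensity(x, cfg)
  expect_true(all(diff(w) >= 0))                  # monotone
  expect_identical(windowIntensity(w * 350 - 125, cfg), w)  # idempotent
  expect_error(preprocessConfig(window_width_hu = 0), "width")
})

test_that("model-input conversion resizes bilinearly and replicates channels", {
  cfg <- preprocessConfig(model_input_px = 37L)
  cst <- matrix(0.5, 100, 100)
  tc <- toModelInput(cst, cfg)
  expect_equal(dim(tc@pixels), c(37, 37, 3))
  expect_true(all(tc@pixels == 0.5))              # constants preserved
  rnd <- matrix(runif(100 * 100), 100, 100)
  tc2 <- toModelInput(rnd, cfg)
  expect_identical(tc2@pixels[, , 1], tc2@pixels[, , 2])
  expect_identical(tc2@pixels[, , 1], tc2@pixels[, , 3])

  # 2x2 checkerboard up to 3x3: center equals the mean of the corners
  chk <- matrix(c(0, 1, 1, 0), 2, 2)
  up <- toModelInput(chk, preprocessConfig(model_input_px = 3L))
  expect_equal(up@pixels[2, 2, 1], mean(chk))
  expect_equal(up@pixels[1, 1, 1], chk[1, 1])
  expect_error(toModelInput(cst, preprocessConfig(model_input_px = 0L)),
               "model_input_px")
})

test_that("the preprocessing chain is deterministic and shape-stable", {
  ph <- makePhantom(phantomSpec(seed = 5))
  c1 <- preprocessTumor(ph$vol, ph$mask)
  c2 <- preprocessTumor(ph$vol, ph$mask)
  expect_identical(c1@pixels, c2@pixels)
  expect_identical(c1@sliceIndex, c2@sliceIndex)
  expect_true(all(c1@pixels >= 0 & c1@pixels <= 1))
})

test_that("crops round-trip through NIfTI, CSV and PNG writers", {
  ph <- makePhantom(phantomSpec(shape = c(48, 48, 40),
                                semiaxes_mm = c(12, 10, 8), seed = 9))
  tf <- tempfile(fileext = ".nii.gz")
  tm <- tempfile(fileext = ".nii.gz")
  writeNiftiVolume(ph$vol, tf)
  writeNiftiVolume(ph$mask, tm)
  v2 <- readCTVolume(tf)
  m2 <- readSegMask(tm)
  expect_equal(voxels(v2), voxels(ph$vol), tolerance = 1e-6)
  expect_identical(voxels(m2), voxels(ph$mask))

  cr <- preprocessTumor(ph$vol, ph$mask)
  csv <- tempfile(fileext = ".csv")
  writeCropCSV(cr, csv)
  back <- readCropCSV(csv)
  expect_equal(back@pixels[, , 1], cr@pixels[, , 1], tolerance = 1e-12)
  png <- tempfile(fileext = ".png")
  expect_silent(writeCropPNG(cr, png))
  expect_true(file.exists(png))
})
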
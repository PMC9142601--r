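#' Read a CT volume or segmentation mask from NIfTI
#'
#' Masks may be any one-label NIfTI (e.g. exported from an RT structure set
#' by external tools); nonzero voxels are treated as foreground.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A [CTVolume-class] (`readCTVolume`) or [SegMask-class]
#'   (`readSegMask`).
#' @export
readCTVolume <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  CTVolume(unclass(img)[, , , drop = FALSE], spacing = sp)
}

#' @rdname readCTVolume
#' @export
readSegMask <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  vox <- unclass(img)[, , , drop = FALSE]
  SegMask((vox != 0) * 1, spacing = sp)
}

#' Write a CT volume or mask as NIfTI
#' @param x a [CTVolume-class] or [SegMask-class].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
writeNiftiVolume <- function(x, path) {
  img <- RNifti::asNifti(voxels(x), pixdim = spacing(x))
  RNifti::writeNifti(img, path)
  invisible(path)
}

# Nearest-neighbour index map for one axis: output voxel centers anchored at
# the input origin (first voxel center), extent covering the input physical
# extent n*spacing.
.nnAxisMap <- function(n_in, sp_in, sp_out) {
  n_out <- max(1L, as.integer(ceiling(n_in * sp_in / sp_out)))
  pos <- (seq_len(n_out) - 1) * sp_out
  idx <- round(pos / sp_in) + 1
  pmin.int(pmax.int(idx, 1L), n_in)
}

#' Resample a CT volume and its mask to an isotropic grid
#'
#' Nearest-neighbour resampling of both the HU volume and the mask onto the
#' same isotropic output grid (default 1 x 1 x 1 mm). The output grid is
#' anchored at the input origin and its extent covers the input physical
#' extent, so e.g. 4 slices at 2.5 mm (10 mm extent) become 10 slices at
#' 1 mm.
#'
#' @param vol a [CTVolume-class].
#' @param mask the paired [SegMask-class] on the same grid.
#' @param cfg a [preprocessConfig()].
#' @return list with elements `vol` and `mask`, both resampled.
#' @export
resampleIsotropic <- function(vol, mask, cfg = preprocessConfig()) {
  stopifnot2(is(vol, "CTVolume") && is(mask, "SegMask"),
             "vol must be a CTVolume and mask a SegMask")
  stopifnot2(identical(dim(voxels(vol)), dim(voxels(mask))),
             "mask grid must match its CTVolume")
  sp <- spacing(vol)
  stopifnot2(all(sp > 0), "spacings must be positive")
  tgt <- cfg$target_spacing_mm
  d <- dim(voxels(vol))
  ix <- .nnAxisMap(d[1], sp[1], tgt)
  iy <- .nnAxisMap(d[2], sp[2], tgt)
  iz <- .nnAxisMap(d[3], sp[3], tgt)
  v <- voxels(vol)[ix, iy, iz, drop = FALSE]
  m <- voxels(mask)[ix, iy, iz, drop = FALSE]
  list(vol = CTVolume(v, spacing = rep(tgt, 3)),
       mask = SegMask(m, spacing = rep(tgt, 3)))
}

#' Select the axial slice with maximum tumor cross-sectional area
#'
#' Depends on the mask only; ties are broken by the lowest slice index.
#'
#' @param mask a [SegMask-class] with at least one foreground voxel.
#' @return integer slice index (third array axis).
#' @export
selectMaxAreaSlice <- function(mask) {
  m <- voxels(mask)
  areas <- apply(m, 3, sum)
  stopifnot2(sum(areas) > 0, "mask has no foreground voxels")
  which.max(areas) # which.max returns the first maximum: lowest index
}

# Round to nearest index with exact .5 ties rounding toward the lower index.
.roundHalfDown <- function(x) ceiling(x - 0.5)

# 8-connected component labelling of a 2D binary matrix (queue-based).
.labelComponents8 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  off <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
               dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  fg <- which(m != 0)
  for (s in fg) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    while (length(queue)) {
      q <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r0 <- ((q - 1L) %% nr) + 1L
      c0 <- ((q - 1L) %/% nr) + 1L
      rr <- r0 + off[, 1]; cc <- c0 + off[, 2]
      ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
      nb <- (cc[ok] - 1L) * nr + rr[ok]
      nb <- nb[m[nb] != 0 & lab[nb] == 0L]
      if (length(nb)) {
        lab[nb] <- cur
        queue <- c(queue, nb)
      }
    }
  }
  lab
}

# Extract a size x size window centered at (cr, cc) from 2D matrix m,
# padding out-of-bounds pixels with `fill`. For even sizes the center pixel
# sits at position size/2 (rows cr-size/2+1 .. cr+size/2).
.extractWindow <- function(m, cr, cc, size, fill) {
  half <- size %/% 2L
  rows <- (cr - half + 1L):(cr + (size - half))
  cols <- (cc - half + 1L):(cc + (size - half))
  out <- matrix(fill, size, size)
  rok <- rows >= 1 & rows <= nrow(m)
  cok <- cols >= 1 & cols <= ncol(m)
  out[which(rok), which(cok)] <- m[rows[rok], cols[cok], drop = FALSE]
  out
}

#' Extract a crop centered on the tumor center of gravity
#'
#' Extracts a `crop_size_mm` square (at 1 mm/px) centered on the foreground
#' center of gravity of the slice. If the initial crop contains more than
#' one 8-connected foreground component, the crop is re-centered once on
#' the center of gravity of the largest-area component inside the crop.
#' Out-of-volume pixels are padded with `fill`. The center of gravity is
#' rounded to the nearest pixel index, half-way ties rounding toward the
#' lower index.
#'
#' @param vol_slice 2D numeric matrix (HU) at 1 mm spacing.
#' @param mask_slice 2D binary matrix, same shape, nonempty.
#' @param cfg a [preprocessConfig()].
#' @param fill background fill value; use the global minimum of the
#'   resampled volume (see [maskBackground()]).
#' @return list with `pixels` (crop), `mask` (crop mask) and `center`
#'   (row, col index of the final center).
#' @export
cropCentered <- function(vol_slice, mask_slice, cfg = preprocessConfig(),
                         fill = min(vol_slice)) {
  stopifnot2(sum(mask_slice) > 0, "slice mask is empty")
  size <- as.integer(round(cfg$crop_size_mm / cfg$target_spacing_mm))
  fgidx <- which(mask_slice != 0, arr.ind = TRUE)
  cog <- colMeans(fgidx)
  cr <- .roundHalfDown(cog[1]); cc <- .roundHalfDown(cog[2])
  cmask <- .extractWindow(mask_slice, cr, cc, size, 0)
  lab <- .labelComponents8(cmask)
  ncomp <- max(lab)
  if (ncomp > 1L) {
    sizes <- tabulate(lab[lab > 0L], nbins = ncomp)
    big <- which.max(sizes) # ties: lowest label = first-encountered
    bidx <- which(lab == big, arr.ind = TRUE)
    # back to full-slice coordinates
    half <- size %/% 2L
    bcog <- colMeans(bidx) + c(cr - half, cc - half)
    cr <- .roundHalfDown(bcog[1]); cc <- .roundHalfDown(bcog[2])
    cmask <- .extractWindow(mask_slice, cr, cc, size, 0)
  }
  cpix <- .extractWindow(vol_slice, cr, cc, size, fill)
  list(pixels = cpix, mask = cmask, center = unname(c(cr, cc)))
}

#' Set non-tumor pixels to the background fill value
#'
#' @param crop_pixels 2D crop matrix (HU).
#' @param crop_mask matching binary matrix.
#' @param fill fill value; by convention the global minimum HU of the
#'   resampled volume, so the background is stable across crops of one
#'   patient.
#' @return crop with background pixels replaced by `fill`.
#' @export
maskBackground <- function(crop_pixels, crop_mask, fill) {
  stopifnot2(identical(dim(crop_pixels), dim(crop_mask)),
             "crop and mask dimensions differ")
  crop_pixels[crop_mask == 0] <- fill
  crop_pixels
}

#' Apply a linear intensity window
#'
#' Maps the HU interval `[level - width/2, level + width/2]` linearly onto
#' `[0, 1]`, clipping outside. The default 50/350 window maps -125 HU to 0
#' and 225 HU to 1.
#'
#' @param crop_pixels numeric matrix or array of HU values.
#' @param cfg a [preprocessConfig()].
#' @return values in `[0, 1]`.
#' @export
windowIntensity <- function(crop_pixels, cfg = preprocessConfig()) {
  W <- cfg$window_width_hu
  stopifnot2(W > 0, "window width must be > 0")
  lo <- cfg$window_level_hu - W / 2
  pmin(pmax((crop_pixels - lo) / W, 0), 1)
}

# Bilinear resize of a 2D matrix to n x n, endpoints aligned (the corner
# pixels of the output coincide with the corner pixels of the input).
.bilinearResize <- function(m, n) {
  nr <- nrow(m); nc <- ncol(m)
  if (n == nr && n == nc) return(m)
  mapAxis <- function(n_in) {
    if (n == 1L) return(list(i0 = 1L, i1 = 1L, w = 0))
    pos <- (seq_len(n) - 1) * (n_in - 1) / (n - 1) + 1
    i0 <- pmin.int(floor(pos), n_in - 1L)
    if (n_in == 1L) i0 <- rep(1L, n)
    i1 <- pmin.int(i0 + 1L, n_in)
    list(i0 = as.integer(i0), i1 = as.integer(i1), w = pos - i0)
  }
  rx <- mapAxis(nr); cx <- mapAxis(nc)
  wr <- matrix(rx$w, n, n); wc <- matrix(cx$w, n, n, byrow = TRUE)
  m00 <- m[rx$i0, cx$i0, drop = FALSE]
  m10 <- m[rx$i1, cx$i0, drop = FALSE]
  m01 <- m[rx$i0, cx$i1, drop = FALSE]
  m11 <- m[rx$i1, cx$i1, drop = FALSE]
  (1 - wr) * (1 - wc) * m00 + wr * (1 - wc) * m10 +
    (1 - wr) * wc * m01 + wr * wc * m11
}

#' Convert a windowed crop into a model-ready TumorCrop
#'
#' Resizes the crop to the backbone's input size with bilinear
#' interpolation and replicates the grayscale image into three identical
#' channels, matching the three-channel input convention of
#' natural-image-pretrained networks.
#'
#' @param crop_pixels windowed 2D matrix with values in `[0, 1]`.
#' @param cfg a [preprocessConfig()]; `model_input_px` sets the target size.
#' @param sliceIndex,center provenance carried into the result.
#' @return A [TumorCrop-class].
#' @export
toModelInput <- function(crop_pixels, cfg = preprocessConfig(),
                         sliceIndex = NA_integer_, center = c(NA, NA)) {
  npx <- cfg$model_input_px
  stopifnot2(npx >= 1, "model_input_px must be >= 1")
  r <- .bilinearResize(crop_pixels, as.integer(npx))
  r <- pmin(pmax(r, 0), 1)
  new("TumorCrop",
      pixels = array(rep(r, 3), dim = c(nrow(r), ncol(r), 3)),
      sliceIndex = as.integer(sliceIndex), center = as.numeric(center),
      sizePx = as.integer(npx))
}

#' Run the full crop preprocessing chain on one tumor
#'
#' resample -> max-area slice -> center-of-gravity crop -> background
#' masking (global minimum HU of the resampled volume) -> 50/350 windowing
#' -> bilinear resize -> three-channel TumorCrop. Deterministic: identical
#' inputs give a bit-identical crop.
#'
#' @param vol a [CTVolume-class].
#' @param mask the paired [SegMask-class].
#' @param cfg a [preprocessConfig()].
#' @return A [TumorCrop-class].
#' @export
preprocessTumor <- function(vol, mask, cfg = preprocessConfig()) {
  rs <- resampleIsotropic(vol, mask, cfg)
  zi <- selectMaxAreaSlice(rs$mask)
  fill <- min(voxels(rs$vol))
  cr <- cropCentered(voxels(rs$vol)[, , zi], voxels(rs$mask)[, , zi],
                     cfg, fill = fill)
  px <- maskBackground(cr$pixels, cr$mask, fill)
  px <- windowIntensity(px, cfg)
  toModelInput(px, cfg, sliceIndex = zi, center = cr$center)
}

#' Write a TumorCrop as an 8-bit PNG for inspection
#'
#' Pixel values are encoded as `round(255 * value)`. The PNG is for visual
#' checking only; use [writeCropCSV()] for the lossless numeric form the
#' feature stage consumes.
#'
#' @param crop a [TumorCrop-class].
#' @param path output `.png` path.
#' @return `path`, invisibly.
#' @export
writeCropPNG <- function(crop, path) {
  png::writePNG(round(255 * crop@pixels[, , 1]) / 255, path)
  invisible(path)
}

#' Lossless text round-trip for crops
#'
#' @param crop a [TumorCrop-class].
#' @param path output `.csv` path (single channel, full precision).
#' @return `path` invisibly (`writeCropCSV`); a [TumorCrop-class]
#'   (`readCropCSV`).
#' @export
writeCropCSV <- function(crop, path) {
  utils::write.table(crop@pixels[, , 1], path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeCropCSV
#' @export
readCropCSV <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(m) <- NULL
  new("TumorCrop", pixels = array(rep(m, 3), c(nrow(m), ncol(m), 3)),
      sliceIndex = NA_integer_, center = c(NA_real_, NA_real_),
      sizePx = as.integer(nrow(m)))
}
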
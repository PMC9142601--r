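#' @import methods
#' @importFrom stats cor sd var median quantile rnorm runif qnorm pnorm pt
#'   pchisq wilcox.test optim dist plogis predict rgamma dnorm
#' @importFrom utils head read.csv write.csv
NULL

#' CT volume in Hounsfield units
#'
#' A 3D scalar voxel grid with per-axis spacing in millimetres. Axial slices
#' run along the third array axis.
#'
#' @slot voxels 3D numeric array of HU values.
#' @slot spacing numeric length-3, mm per voxel along (x, y, z).
#' @export
setClass("CTVolume",
  representation(voxels = "array", spacing = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@voxels)) != 3L)
      msg <- c(msg, "voxels must be a 3D array")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      msg <- c(msg, "spacing must be three positive finite values (mm)")
    if (any(!is.finite(object@voxels)))
      msg <- c(msg, "voxel values must be finite")
    if (length(msg)) msg else TRUE
  }
)

#' Binary segmentation mask on the grid of its CT volume
#'
#' @slot voxels 3D array with values in {0, 1}.
#' @slot spacing numeric length-3, mm per voxel.
#' @export
setClass("SegMask",
  representation(voxels = "array", spacing = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@voxels)) != 3L)
      msg <- c(msg, "voxels must be a 3D array")
    if (!all(object@voxels %in% c(0, 1)))
      msg <- c(msg, "mask values must be 0 or 1")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      msg <- c(msg, "spacing must be three positive values (mm)")
    if (length(msg)) msg else TRUE
  }
)

#' Constructor for CTVolume
#' @param voxels 3D numeric array (HU).
#' @param spacing numeric length-3 spacing in mm.
#' @return A [CTVolume-class] object.
#' @export
CTVolume <- function(voxels, spacing = c(1, 1, 1)) {
  new("CTVolume", voxels = voxels, spacing = as.numeric(spacing))
}

#' Constructor for SegMask
#' @param voxels 3D array of 0/1 values (logicals are coerced).
#' @param spacing numeric length-3 spacing in mm.
#' @return A [SegMask-class] object.
#' @export
SegMask <- function(voxels, spacing = c(1, 1, 1)) {
  storage.mode(voxels) <- "double"
  new("SegMask", voxels = voxels, spacing = as.numeric(spacing))
}

#' Model-ready 2D tumor crop
#'
#' Windowed, background-masked crop with three identical channels and
#' provenance of where in the volume it came from.
#'
#' @slot pixels 3D array (rows x cols x 3), values in [0, 1]; channels
#'   identical until a backbone adapter applies its own normalization.
#' @slot sliceIndex integer index of the source axial slice.
#' @slot center numeric length-2, crop center as (row, col) voxel index on
#'   the resampled 1 mm grid.
#' @slot sizePx integer edge length after resizing.
#' @export
setClass("TumorCrop",
  representation(pixels = "array", sliceIndex = "integer",
                 center = "numeric", sizePx = "integer"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@pixels)
    if (length(d) != 3L || d[3] != 3L)
      msg <- c(msg, "pixels must be rows x cols x 3")
    if (any(object@pixels < -1e-9) || any(object@pixels > 1 + 1e-9))
      msg <- c(msg, "pixel values must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  }
)

#' Preprocessing configuration
#'
#' Defaults follow the standard soft-tissue protocol used for head-and-neck
#' planning CT: 1 mm isotropic resampling, a 100 mm crop around the tumor
#' center of gravity, and a 50/350 HU window.
#'
#' @param target_spacing_mm isotropic output spacing (mm), default 1.
#' @param crop_size_mm crop edge length (mm), default 100.
#' @param window_level_hu window level (HU), default 50.
#' @param window_width_hu window width (HU), default 350.
#' @param model_input_px backbone input edge length (px), default 100
#'   (i.e. no resize for the stub backbone).
#' @return A list with class `PreprocessConfig`.
#' @export
preprocessConfig <- function(target_spacing_mm = 1, crop_size_mm = 100,
                             window_level_hu = 50, window_width_hu = 350,
                             model_input_px = 100L) {
  stopifnot2(crop_size_mm > 0, "crop_size_mm must be > 0")
  stopifnot2(window_width_hu > 0, "window_width_hu must be > 0")
  stopifnot2(target_spacing_mm > 0, "target_spacing_mm must be > 0")
  structure(list(target_spacing_mm = target_spacing_mm,
                 crop_size_mm = crop_size_mm,
                 window_level_hu = window_level_hu,
                 window_width_hu = window_width_hu,
                 model_input_px = as.integer(model_input_px)),
            class = "PreprocessConfig")
}

#' Feature matrix of samples by named features
#'
#' Thin wrapper around [SummarizedExperiment::SummarizedExperiment] holding
#' one assay of features (rows) by samples (columns), plus a normalization
#' flag in the metadata. Most user code works with the samples-by-features
#' orientation returned by [featureValues()].
#'
#' @export
#' @import SummarizedExperiment
setClass("FeatureMatrix", contains = "SummarizedExperiment")

#' Construct a FeatureMatrix from a samples-by-features matrix
#'
#' @param values numeric matrix, samples in rows, features in columns;
#'   column names are feature names, row names are sample identifiers
#'   (generated if absent).
#' @param normalized logical flag recording whether columns are z-scored.
#' @param provenance optional list (backbone name, settings, ...).
#' @return A [FeatureMatrix-class] object.
#' @export
FeatureMatrix <- function(values, normalized = FALSE, provenance = list()) {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("feature_%04d", seq_len(ncol(values)))
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("sample_%03d", seq_len(nrow(values)))
  if (anyDuplicated(colnames(values)))
    stop("feature names must be unique", call. = FALSE)
  if (any(!is.finite(values)))
    stop("feature values must be finite (no missing values)", call. = FALSE)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(values = t(values)),
    metadata = list(normalized = isTRUE(normalized), provenance = provenance)
  )
  new("FeatureMatrix", se)
}

#' 0.632+ bootstrap evaluation result
#'
#' @slot auc numeric 0.632+ point estimate of the AUC.
#' @slot sensitivity numeric mean 0.632+-weighted sensitivity.
#' @slot specificity numeric mean 0.632+-weighted specificity.
#' @slot features character, feature subset evaluated.
#' @slot replicates data.frame of per-replicate diagnostics (apparent and
#'   out-of-bag AUC, clamped AUC', overfitting rate R, weight a, value,
#'   skip reason).
#' @slot effectiveB integer number of non-degenerate replicates used.
#' @export
setClass("Auc632Result",
  representation(auc = "numeric", sensitivity = "numeric",
                 specificity = "numeric", features = "character",
                 replicates = "data.frame", effectiveB = "integer"),
  validity = function(object) {
    if (length(object@auc) == 1L && is.finite(object@auc) &&
        (object@auc < -1e-9 || object@auc > 1 + 1e-9))
      "auc estimate must lie in [0, 1]" else TRUE
  }
)

#' Ranker-by-classifier model grid result
#'
#' @slot auc numeric matrix, rankers in rows, classifiers in columns.
#' @slot sensitivity numeric matrix of per-cell sensitivities.
#' @slot specificity numeric matrix of per-cell specificities.
#' @slot meanAuc arithmetic mean over completed cells.
#' @slot sdAuc standard deviation over completed cells.
#' @slot cells list of per-cell [Auc632Result-class] objects.
#' @export
setClass("ModelGridResult",
  representation(auc = "matrix", sensitivity = "matrix",
                 specificity = "matrix", meanAuc = "numeric",
                 sdAuc = "numeric", cells = "list")
)

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("CTVolume: %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3]))
  cat(sprintf("  HU range [%.1f, %.1f]\n", min(object@voxels),
              max(object@voxels)))
})

setMethod("show", "SegMask", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("SegMask: %d x %d x %d voxels, %d foreground\n",
              d[1], d[2], d[3], sum(object@voxels)))
})

setMethod("show", "TumorCrop", function(object) {
  d <- dim(object@pixels)
  cat(sprintf(
    "TumorCrop: %d x %d x 3, slice %d, center (%.0f, %.0f)\n",
    d[1], d[2], object@sliceIndex, object@center[1], object@center[2]))
})

setMethod("show", "Auc632Result", function(object) {
  cat(sprintf("0.632+ bootstrap result (B = %d effective)\n",
              object@effectiveB))
  cat(sprintf("  AUC %.4f | sensitivity %.4f | specificity %.4f\n",
              object@auc, object@sensitivity, object@specificity))
  cat("  features:", paste(object@features, collapse = ", "), "\n")
})

setMethod("show", "ModelGridResult", function(object) {
  cat(sprintf("Model grid: %d rankers x %d classifiers\n",
              nrow(object@auc), ncol(object@auc)))
  cat(sprintf("  mean AUC %.4f (SD %.4f)\n", object@meanAuc, object@sdAuc))
  print(round(object@auc, 3))
})
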
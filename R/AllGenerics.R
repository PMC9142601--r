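#' Accessors for voxel data and spacing
#'
#' @param x a [CTVolume-class] or [SegMask-class].
#' @return `voxels()` the 3D array; `spacing()` the mm spacing vector.
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' @rdname voxels
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @rdname voxels
#' @export
setMethod("voxels", "CTVolume", function(x) x@voxels)
#' @rdname voxels
#' @export
setMethod("voxels", "SegMask", function(x) x@voxels)
#' @rdname voxels
#' @export
setMethod("spacing", "CTVolume", function(x) x@spacing)
#' @rdname voxels
#' @export
setMethod("spacing", "SegMask", function(x) x@spacing)

#' Accessors for FeatureMatrix
#'
#' `featureValues()` returns the samples-by-features numeric matrix,
#' `featureNames()` the feature names, `sampleIDs()` the sample identifiers
#' and `isNormalized()` the z-score flag.
#'
#' @param x a [FeatureMatrix-class].
#' @return See description.
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname featureValues
#' @export
setMethod("featureValues", "FeatureMatrix", function(x) {
  t(SummarizedExperiment::assay(x, "values"))
})

#' @rdname featureValues
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))

#' @rdname featureValues
#' @export
setMethod("featureNames", "FeatureMatrix", function(x) rownames(x))

#' @rdname featureValues
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' @rdname featureValues
#' @export
setMethod("sampleIDs", "FeatureMatrix", function(x) colnames(x))

#' @rdname featureValues
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' @rdname featureValues
#' @export
setMethod("isNormalized", "FeatureMatrix", function(x) {
  isTRUE(S4Vectors::metadata(x)$normalized)
})
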
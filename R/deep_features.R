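# Registry of backbone adapters. An adapter is a function(pixels3d, spec)
# returning a numeric feature vector of length spec$dim. Pretrained CNN
# weights are never bundled; real backbones are registered by the user at
# run time, while the deterministic "stub" backbone ships with the package
# as the reference test backend.
.backbones <- new.env(parent = emptyenv())

#' Describe a deep-feature extractor
#'
#' @param backbone backbone name; `"stub"` is the built-in deterministic
#'   backend. Any other name must have been registered with
#'   [registerBackbone()].
#' @param layer which layer the adapter taps: the last fully connected
#'   layer, or (for architectures without one) the layer before the final
#'   softmax.
#' @param dim output feature dimension, default 1000.
#' @param seed integer seed (used by the stub backbone only).
#' @return list with class `ExtractorSpec`.
#' @export
extractorSpec <- function(backbone = "stub",
                          layer = c("last_fully_connected", "pre_softmax"),
                          dim = 1000L, seed = 1L) {
  stopifnot2(dim >= 1, "output dimension must be >= 1")
  structure(list(backbone = backbone, layer = match.arg(layer),
                 dim = as.integer(dim), seed = as.integer(seed)),
            class = "ExtractorSpec")
}

#' Register a backbone adapter
#'
#' @param name backbone name used in [extractorSpec()].
#' @param fn function(pixels, spec) -> numeric vector of length `spec$dim`;
#'   `pixels` is the rows x cols x 3 crop array.
#' @return `name`, invisibly.
#' @export
registerBackbone <- function(name, fn) {
  stopifnot2(is.function(fn), "adapter must be a function(pixels, spec)")
  assign(name, fn, envir = .backbones)
  invisible(name)
}

# cache for stub projection matrices keyed by seed/dim/input size
.stubCache <- new.env(parent = emptyenv())

#' Deterministic stub feature extractor
#'
#' A fixed, seeded random linear projection of the flattened image followed
#' by a tanh nonlinearity: `tanh(W x + b)` with `W`, `b` drawn once from a
#' seeded normal stream. Pure (no hidden state between calls) and identical
#' across runs and platforms for a given seed, so the whole pipeline is
#' testable without pretrained CNN weights. Not scale-invariant: scaling
#' the image changes the output.
#'
#' @param image 2D matrix or rows x cols x 3 array (channel 1 is used).
#' @param seed integer seed defining the projection.
#' @param dim output length, default 1000.
#' @return numeric vector of length `dim`.
#' @export
stubExtractor <- function(image, seed = 1L, dim = 1000L) {
  if (length(base::dim(image)) == 3L) image <- image[, , 1]
  x <- as.numeric(image)
  key <- sprintf("s%d_d%d_n%d", seed, dim, length(x))
  if (!exists(key, envir = .stubCache)) {
    Wb <- withLocalSeed(seed, {
      list(W = matrix(rnorm(dim * length(x), sd = 1 / sqrt(length(x))),
                      nrow = dim),
           b = rnorm(dim, sd = 0.1))
    })
    assign(key, Wb, envir = .stubCache)
  }
  Wb <- get(key, envir = .stubCache)
  as.numeric(tanh(Wb$W %*% x + Wb$b))
}

#' Extract deep features from a list of tumor crops
#'
#' Runs the (frozen) backbone adapter on every crop and stacks the results
#' into a [FeatureMatrix-class] with one row per crop and
#' `spec$dim` named features. Deterministic for fixed adapter weights and
#' inputs.
#'
#' @param crops list of [TumorCrop-class] objects, all sized to the
#'   backbone's input.
#' @param spec an [extractorSpec()].
#' @param sample_ids optional character vector of sample identifiers.
#' @return A [FeatureMatrix-class] (not yet normalized).
#' @export
extractFeatures <- function(crops, spec = extractorSpec(),
                            sample_ids = NULL) {
  if (is(crops, "TumorCrop")) crops <- list(crops)
  adapter <- if (spec$backbone == "stub") {
    function(px, sp) stubExtractor(px, seed = sp$seed, dim = sp$dim)
  } else if (exists(spec$backbone, envir = .backbones)) {
    get(spec$backbone, envir = .backbones)
  } else {
    stop(sprintf("backbone '%s' is not registered", spec$backbone),
         call. = FALSE)
  }
  sizes <- vapply(crops, function(cr) dim(cr@pixels)[1], integer(1))
  if (length(unique(sizes)) > 1L)
    stop("all crops must share the backbone input size", call. = FALSE)
  vals <- t(vapply(crops, function(cr) {
    v <- adapter(cr@pixels, spec)
    if (length(v) != spec$dim)
      stop("adapter returned wrong feature dimension", call. = FALSE)
    as.numeric(v)
  }, numeric(spec$dim)))
  colnames(vals) <- sprintf("%s_f%04d", spec$backbone, seq_len(spec$dim))
  if (!is.null(sample_ids)) rownames(vals) <- sample_ids
  FeatureMatrix(vals, normalized = FALSE,
                provenance = list(backbone = spec$backbone,
                                  layer = spec$layer, dim = spec$dim))
}

#' Z-score normalize feature columns
#'
#' Each column is centered and scaled to unit sample standard deviation
#' (n - 1 denominator), computed over the full cohort. Constant columns
#' map to all-zeros with a warning rather than failing, so degenerate
#' features cannot crash the pipeline. Note that normalizing on the full
#' analysis cohort before any resampling mirrors the internal-validation
#' workflow this pipeline targets and carries the optimistic bias that
#' workflow is known for.
#'
#' @param F a [FeatureMatrix-class] or samples-by-features matrix with
#'   at least two rows.
#' @return A normalized [FeatureMatrix-class].
#' @export
zscoreNormalize <- function(F) {
  prov <- list()
  if (is(F, "FeatureMatrix")) {
    prov <- S4Vectors::metadata(F)$provenance
    vals <- featureValues(F)
  } else {
    vals <- as.matrix(F)
  }
  stopifnot2(nrow(vals) >= 2, "z-score needs at least two samples")
  mu <- colMeans(vals)
  sdv <- apply(vals, 2, sd)
  const <- sdv == 0 | !is.finite(sdv)
  if (any(const)) {
    warning(sprintf("%d constant feature column(s) mapped to zeros",
                    sum(const)))
    sdv[const] <- 1
  }
  out <- sweep(sweep(vals, 2, mu, "-"), 2, sdv, "/")
  out[, const] <- 0
  FeatureMatrix(out, normalized = TRUE, provenance = prov)
}

#' Serialize a FeatureMatrix as CSV
#'
#' One-line header; sample identifiers in the first column; values written
#' at full precision so the round-trip is lossless.
#'
#' @param F a [FeatureMatrix-class].
#' @param path output path.
#' @return `path` invisibly (`writeFeatureCSV`); a
#'   [FeatureMatrix-class] (`readFeatureCSV`).
#' @export
writeFeatureCSV <- function(F, path) {
  vals <- featureValues(F)
  df <- data.frame(sample_id = rownames(vals), vals,
                   check.names = FALSE, stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("sample_id", colnames(vals)), collapse = ","), con)
  utils::write.table(
    data.frame(df$sample_id,
               format(vals, digits = 17, scientific = TRUE, trim = TRUE)),
    con, sep = ",", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeFeatureCSV
#' @param normalized flag to record on the object read back.
#' @export
readFeatureCSV <- function(path, normalized = FALSE) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character")
  ids <- df[[1]]
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- ids
  FeatureMatrix(vals, normalized = normalized)
}
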
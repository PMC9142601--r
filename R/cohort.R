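# Cohort handling: regression rates, median-split labels, and ordinal
# encoding of clinical factor tables for the comparator model.

#' Tumor regression rate in percent per treatment day
#'
#' `100 * ((v_init - v_boost) / v_init) / days`: the relative volume
#' change between the initial and boost planning CT divided by the number
#' of treatment days delivered before the boost scan. Negative when the
#' tumor grew.
#'
#' @param v_init initial GTV volume (cm^3), > 0.
#' @param v_boost boost GTV volume (cm^3).
#' @param days treatment days before the boost CT, >= 1.
#' @return rate(s) in % per day.
#' @export
deltaGTVRate <- function(v_init, v_boost, days) {
  stopifnot2(all(v_init > 0), "initial volume must be > 0")
  stopifnot2(all(days >= 1), "treatment days must be >= 1")
  100 * ((v_init - v_boost) / v_init) / days
}

#' Binary regression labels from a rate threshold
#'
#' Label 1 (regression) iff the rate is strictly greater than the
#' threshold; the default threshold is the cohort median, which splits
#' the cohort into groups differing in size by at most one when all
#' rates are distinct. Explicit thresholds are accepted for sweeps.
#'
#' @param rates per-patient regression rates (% per day), >= 2 values.
#' @param threshold labeling threshold; default `median(rates)`.
#' @return list with class `LabelSet`: `rate`, `threshold`, `label`.
#' @export
labelByThreshold <- function(rates, threshold = median(rates)) {
  stopifnot2(length(rates) >= 2, "need at least two patients")
  if (length(unique(rates)) == 1)
    stop("all rates equal: no split possible", call. = FALSE)
  structure(list(rate = rates, threshold = threshold,
                 label = as.integer(rates > threshold)),
            class = "LabelSet")
}

#' Default clinical factor catalogue
#'
#' Twelve factors with declared category sets; continuous factors are
#' declared as `NULL`. HPV status is a three-level factor
#' (positive/negative/not applicable) so non-oropharynx patients encode
#' cleanly.
#'
#' @return named list of allowed category vectors.
#' @export
clinicalFactorLevels <- function() {
  list(
    age = NULL,
    sex = c("female", "male"),
    site = c("nasopharynx", "oropharynx", "hypopharynx", "oral_cavity",
             "larynx", "paranasal_sinus"),
    t_stage = c("T0", "T1", "T2", "T3", "T4"),
    n_stage = c("N0", "N1", "N2", "N3"),
    m_stage = c("M0", "M1"),
    strategy = c("radical", "postoperative_recurrence"),
    multiple_cancers = c("no", "yes"),
    peg = c("no", "yes"),
    chemotherapy = c("no", "yes"),
    gtvp_volume = NULL,
    gtvn_volume = NULL,
    hpv = c("negative", "positive", "not_applicable")
  )
}

#' Encode a clinical factor table as a feature matrix
#'
#' Categorical factors are encoded as ordinal codes (one column per
#' factor, 0-based in the declared category order) so the table flows
#' directly into the filter rankers; clinical factors skip the ICC and
#' collinearity steps by design because the factor list is already small.
#'
#' @param records data.frame of patient records; character/factor columns
#'   are encoded, numeric columns pass through.
#' @param levels named list of allowed categories per factor, default
#'   [clinicalFactorLevels()] (restricted to columns present).
#' @return A [FeatureMatrix-class] with one column per factor.
#' @export
clinicalTablePrepare <- function(records, levels = clinicalFactorLevels()) {
  stopifnot2(is.data.frame(records), "records must be a data.frame")
  cols <- setdiff(colnames(records), "id")
  out <- matrix(NA_real_, nrow(records), length(cols),
                dimnames = list(records$id %||% rownames(records), cols))
  for (cn in cols) {
    v <- records[[cn]]
    if (is.numeric(v)) {
      out[, cn] <- v
    } else {
      lv <- levels[[cn]]
      stopifnot2(!is.null(lv),
                 sprintf("no declared categories for factor '%s'", cn))
      v <- as.character(v)
      bad <- setdiff(unique(v), lv)
      if (length(bad))
        stop(sprintf("unknown category '%s' in '%s'; allowed: %s",
                     bad[1], cn, paste(lv, collapse = ", ")),
             call. = FALSE)
      out[, cn] <- match(v, lv) - 1
    }
  }
  FeatureMatrix(out, normalized = FALSE,
                provenance = list(kind = "clinical"))
}

#' Read and write patient volume records
#'
#' CSV with header `id,v_init,v_boost,days` plus optional clinical factor
#' columns. `writeLabelCSV` persists a [labelByThreshold()] result as
#' `id,rate,threshold,label`.
#'
#' @param path file path.
#' @return data.frame (`readPatientRecords`); `path` invisibly
#'   (`writeLabelCSV`).
#' @export
readPatientRecords <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "v_init", "v_boost", "days")
  stopifnot2(all(need %in% colnames(df)),
             sprintf("patient records need columns: %s",
                     paste(need, collapse = ", ")))
  df
}

#' @rdname readPatientRecords
#' @param labels a `LabelSet` from [labelByThreshold()].
#' @param ids patient identifiers aligned with the rates.
#' @export
writeLabelCSV <- function(labels, ids, path) {
  utils::write.csv(
    data.frame(id = ids, rate = labels$rate,
               threshold = labels$threshold, label = labels$label),
    path, row.names = FALSE)
  invisible(path)
}
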
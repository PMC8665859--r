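#' @title Accessors for BetaSet and InactiveXMatrix
#' @description `betaValues()` returns the beta assay; `mValues()`
#'   returns the logit2-transformed matrix (clipped, always finite);
#'   `detectionP()` / `beadCount()` return the companion assays or
#'   `NULL`; `sampleSheet()` and `probeAnnotation()` return the column
#'   and row metadata as plain `data.frame`s; `xiBeta()` extracts the
#'   inactive-X estimates.
#' @param object a [BetaSet] (or [InactiveXMatrix] for `xiBeta`).
#' @param ... passed on to methods.
#' @return matrix or data.frame as described.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("betaValues", function(object, ...) standardGeneric("betaValues"))

#' @rdname accessors
#' @export
setMethod("betaValues", "BetaSet", function(object, ...)
  assay(object, "beta"))

#' @rdname accessors
#' @param epsilon clip bound applied before the logit transform.
#' @export
setGeneric("mValues", function(object, ...) standardGeneric("mValues"))

#' @rdname accessors
#' @export
setMethod("mValues", "BetaSet", function(object, epsilon = 0.001, ...)
  betaToM(assay(object, "beta"), epsilon = epsilon))

#' @rdname accessors
#' @export
setGeneric("detectionP", function(object, ...) standardGeneric("detectionP"))

#' @rdname accessors
#' @export
setMethod("detectionP", "BetaSet", function(object, ...)
  if ("detectionP" %in% assayNames(object)) assay(object, "detectionP")
  else NULL)

#' @rdname accessors
#' @export
setGeneric("beadCount", function(object, ...) standardGeneric("beadCount"))

#' @rdname accessors
#' @export
setMethod("beadCount", "BetaSet", function(object, ...)
  if ("beadCount" %in% assayNames(object)) assay(object, "beadCount")
  else NULL)

#' @rdname accessors
#' @export
setGeneric("sampleSheet", function(object, ...) standardGeneric("sampleSheet"))

#' @rdname accessors
#' @export
setMethod("sampleSheet", "BetaSet", function(object, ...) {
  df <- as.data.frame(colData(object))
  if (!"sample_id" %in% colnames(df) && ncol(object))
    df$sample_id <- colnames(object)
  df
})

#' @rdname accessors
#' @export
setGeneric("probeAnnotation", function(object, ...)
  standardGeneric("probeAnnotation"))

#' @rdname accessors
#' @export
setMethod("probeAnnotation", "BetaSet", function(object, ...) {
  df <- as.data.frame(rowData(object))
  if (!"probe_id" %in% colnames(df) && nrow(object))
    df$probe_id <- rownames(object)
  df
})

#' @rdname accessors
#' @export
setGeneric("xiBeta", function(object, ...) standardGeneric("xiBeta"))

#' @rdname accessors
#' @export
setMethod("xiBeta", "InactiveXMatrix", function(object, ...) object@xiBeta)

#' @rdname accessors
#' @export
setGeneric("maleReference", function(object, ...)
  standardGeneric("maleReference"))

#' @rdname accessors
#' @export
setMethod("maleReference", "InactiveXMatrix", function(object, ...)
  setNames(object@referenceMaleMean, rownames(object@xiBeta)))

#' @rdname accessors
#' @export
setGeneric("qcSamples", function(object, ...) standardGeneric("qcSamples"))

#' @rdname accessors
#' @export
setMethod("qcSamples", "QCReport", function(object, ...) object@samples)

#' @rdname accessors
#' @export
setGeneric("qcProbes", function(object, ...) standardGeneric("qcProbes"))

#' @rdname accessors
#' @export
setMethod("qcProbes", "QCReport", function(object, ...) object@probes)

#' Ground truth of a simulated data set
#'
#' Simulated [BetaSet]s carry their generating truth in `rowData()`
#' (columns prefixed `truth_`) and, for crossover designs, per-sample
#' participant intercepts in `colData()`. `simTruth()` collects these
#' into a list of plain data.frames suitable for serialisation with
#' [writeSimTruth()].
#'
#' @param object a simulated [BetaSet] or `SummarizedExperiment`.
#' @return list with elements `probes` (per-probe truth), `samples`
#'   (per-sample truth columns, if any).
#' @export
simTruth <- function(object) {
  rd <- as.data.frame(rowData(object))
  cd <- as.data.frame(colData(object))
  tp <- rd[, grepl("^truth_", colnames(rd)), drop = FALSE]
  if (nrow(tp)) tp <- cbind(probe_id = rownames(object), tp)
  ts <- cd[, grepl("^truth_", colnames(cd)), drop = FALSE]
  if (nrow(ts)) ts <- cbind(sample_id = colnames(object), ts)
  list(probes = tp, samples = ts)
}

#' @rdname simTruth
#' @param path directory or file stem; writes `<path>_probes.tsv` and
#'   `<path>_samples.tsv`.
#' @export
writeSimTruth <- function(object, path) {
  tr <- simTruth(object)
  writeResultTable(tr$probes, paste0(path, "_probes.tsv"))
  writeResultTable(tr$samples, paste0(path, "_samples.tsv"))
  invisible(tr)
}
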
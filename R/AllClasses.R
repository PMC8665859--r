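#' BetaSet: methylation beta values with probe and sample metadata
#'
#' `BetaSet` extends [SummarizedExperiment::SummarizedExperiment] with a
#' mandatory `"beta"` assay of methylation fractions in `[0,1]` and
#' optional `"detectionP"` and `"beadCount"` companion assays of
#' identical dimension. Probe annotation (chromosome, position, genes,
#' genomic feature, distance to TSS, promoter CpG-density class,
#' platform membership) lives in `rowData()`; the sample sheet (sex,
#' age, tissue, participant id, disease, exposure condition, COVID
#' status, batch) lives in `colData()`.
#'
#' @slot .. see `SummarizedExperiment`; no additional slots.
#' @aliases BetaSet-class
#' @exportClass BetaSet
setClass("BetaSet", contains = "SummarizedExperiment")

setValidity("BetaSet", function(object) {
  msg <- character()
  if (!"beta" %in% assayNames(object))
    msg <- c(msg, "assay 'beta' is required")
  else {
    b <- assay(object, "beta")
    bad <- which(!is.na(b) & (b < 0 | b > 1))
    if (length(bad)) {
      idx <- arrayInd(bad[1], dim(b))
      msg <- c(msg, sprintf(
        "beta values outside [0,1]: %d cell(s), first at probe '%s', sample '%s' (value %g)",
        length(bad), rownames(b)[idx[1]], colnames(b)[idx[2]],
        b[bad[1]]))
    }
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicated probe ids")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicated sample ids")
  if ("beadCount" %in% assayNames(object)) {
    bc <- assay(object, "beadCount")
    if (any(!is.na(bc) & bc < 0))
      msg <- c(msg, "negative bead counts")
  }
  cd <- colData(object)
  if ("sex" %in% colnames(cd)) {
    bad <- setdiff(unique(as.character(cd$sex[!is.na(cd$sex)])),
                   .SEX_LEVELS)
    if (length(bad))
      msg <- c(msg, paste0("invalid sex value(s): ",
                           paste(bad, collapse = ", ")))
  }
  if ("exposure" %in% colnames(cd)) {
    bad <- setdiff(unique(as.character(cd$exposure[!is.na(cd$exposure)])),
                   .EXPOSURE_LEVELS)
    if (length(bad))
      msg <- c(msg, paste0("invalid exposure value(s): ",
                           paste(bad, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a BetaSet
#'
#' @param beta numeric matrix of methylation fractions in `[0,1]`,
#'   probes in rows (rownames = probe ids), samples in columns
#'   (colnames = sample ids).
#' @param sampleSheet optional `data.frame` of per-sample metadata with
#'   a `sample_id` column matching `colnames(beta)` (order-matched if
#'   absent).
#' @param probeAnnotation optional `data.frame` of per-probe annotation
#'   with a `probe_id` column matching `rownames(beta)`.
#' @param detectionP optional detection p-value matrix, same dimension
#'   and dimnames as `beta`.
#' @param beadCount optional bead-count matrix, same dimension and
#'   dimnames as `beta`.
#'
#' @return a validated [BetaSet].
#' @examples
#' b <- matrix(c(.1, .9, .5, .4), 2, 2,
#'             dimnames = list(c("cg1", "cg2"), c("s1", "s2")))
#' bs <- BetaSet(b, sampleSheet = data.frame(sample_id = c("s1", "s2"),
#'                                           sex = c("F", "M")))
#' betaValues(bs)
#' @export
BetaSet <- function(beta, sampleSheet = NULL, probeAnnotation = NULL,
                    detectionP = NULL, beadCount = NULL) {
  beta <- as.matrix(beta)
  if (!is.numeric(beta)) stop("beta must be numeric")
  assays <- list(beta = beta)
  for (nm in c("detectionP", "beadCount")) {
    comp <- get(nm)
    if (!is.null(comp)) {
      comp <- as.matrix(comp)
      if (!identical(dim(comp), dim(beta)))
        stop(sprintf("%s dimensions (%d x %d) do not match beta (%d x %d)",
                     nm, nrow(comp), ncol(comp), nrow(beta), ncol(beta)))
      dimnames(comp) <- dimnames(beta)
      assays[[nm]] <- comp
    }
  }
  cd <- if (is.null(sampleSheet)) {
    DataFrame(row.names = colnames(beta))
  } else {
    ss <- as.data.frame(sampleSheet)
    if ("sample_id" %in% colnames(ss)) {
      if (anyDuplicated(ss$sample_id)) stop("duplicated sample_id")
      if (!is.null(colnames(beta))) {
        if (!setequal(ss$sample_id, colnames(beta)))
          stop("sampleSheet sample_id does not match beta columns")
        ss <- ss[match(colnames(beta), ss$sample_id), , drop = FALSE]
      }
      rownames(ss) <- ss$sample_id
    } else rownames(ss) <- colnames(beta)
    DataFrame(ss)
  }
  rd <- if (is.null(probeAnnotation)) {
    DataFrame(row.names = rownames(beta))
  } else {
    pa <- as.data.frame(probeAnnotation)
    if ("probe_id" %in% colnames(pa)) {
      if (anyDuplicated(pa$probe_id)) stop("duplicated probe_id")
      keep <- intersect(rownames(beta), pa$probe_id)
      if (!is.null(rownames(beta)) &&
          length(keep) < nrow(beta))
        stop("probeAnnotation is missing ",
             nrow(beta) - length(keep), " probe(s)")
      pa <- pa[match(rownames(beta), pa$probe_id), , drop = FALSE]
      rownames(pa) <- pa$probe_id
    } else rownames(pa) <- rownames(beta)
    DataFrame(pa)
  }
  se <- SummarizedExperiment(assays = assays, colData = cd, rowData = rd)
  new("BetaSet", se)
}

#' Analysis thresholds and constants
#'
#' Bundles the statistical (FDR) and biological (delta-beta) thresholds
#' used across the analysis families, plus the logit-clipping epsilon.
#' Defaults follow common dual-threshold practice: autosomal
#' FDR < 0.05 with |delta-beta| > 0.05; X-linked FDR < 0.05 with
#' |delta-beta| > 0.10; XCI escape calls at promoter beta < 0.15 and
#' between-sex delta-beta < 0.10; exposure FDR < 0.10 with
#' |delta-beta| > 0.025; COPD-style lenient FDR < 0.20.
#'
#' @param fdr_threshold,delta_beta_threshold autosomal dual rule.
#' @param x_fdr_threshold,x_delta_beta_threshold X-linked dual rule.
#' @param xci_low_beta promoter beta below which both sexes are called
#'   unmethylated (escape rule).
#' @param xci_delta_beta between-sex promoter delta-beta separating
#'   escape from subject.
#' @param exposure_fdr,exposure_delta_beta exposure dual rule.
#' @param copd_fdr lenient FDR for small two-group comparisons.
#' @param beta_clip_epsilon clip bound applied before the logit
#'   transform, in (0, 0.5).
#' @param rng_seed integer seed recorded for downstream use.
#' @return an object of class `AnalysisConfig`.
#' @examples
#' analysisConfig()
#' @export
analysisConfig <- function(fdr_threshold = 0.05,
                           delta_beta_threshold = 0.05,
                           x_fdr_threshold = 0.05,
                           x_delta_beta_threshold = 0.10,
                           xci_low_beta = 0.15,
                           xci_delta_beta = 0.10,
                           exposure_fdr = 0.10,
                           exposure_delta_beta = 0.025,
                           copd_fdr = 0.20,
                           beta_clip_epsilon = 0.001,
                           rng_seed = 1L) {
  cfg <- list(fdr_threshold = fdr_threshold,
              delta_beta_threshold = delta_beta_threshold,
              x_fdr_threshold = x_fdr_threshold,
              x_delta_beta_threshold = x_delta_beta_threshold,
              xci_low_beta = xci_low_beta,
              xci_delta_beta = xci_delta_beta,
              exposure_fdr = exposure_fdr,
              exposure_delta_beta = exposure_delta_beta,
              copd_fdr = copd_fdr,
              beta_clip_epsilon = beta_clip_epsilon,
              rng_seed = as.integer(rng_seed))
  thr <- unlist(cfg[setdiff(names(cfg), c("rng_seed", "beta_clip_epsilon"))])
  if (any(thr <= 0 | thr >= 1))
    stop("all thresholds must lie in (0, 1)")
  if (beta_clip_epsilon <= 0 || beta_clip_epsilon >= 0.5)
    stop("beta_clip_epsilon must lie in (0, 0.5)")
  structure(cfg, class = "AnalysisConfig")
}

#' @describeIn analysisConfig read a config from a YAML file whose keys
#'   mirror the `analysisConfig()` arguments.
#' @param path path to a YAML file.
#' @export
readAnalysisConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysisConfig))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  do.call(analysisConfig, vals)
}

#' @export
print.AnalysisConfig <- function(x, ...) {
  cat("AnalysisConfig\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Inactive-X methylation estimates for female samples
#'
#' Holds per-probe, per-female-sample estimates of inactive-X (Xi)
#' methylation obtained from the composite female array signal and a
#' male active-X reference (see [estimateInactiveX()]).
#'
#' @slot xiBeta matrix (X-linked probes x female samples) of estimated
#'   Xi beta values, clamped into `[0,1]`.
#' @slot referenceMaleMean per-probe mean male beta used as the
#'   active-X proxy.
#' @aliases InactiveXMatrix-class
#' @exportClass InactiveXMatrix
setClass("InactiveXMatrix",
         representation(xiBeta = "matrix", referenceMaleMean = "numeric"))

setValidity("InactiveXMatrix", function(object) {
  msg <- character()
  if (any(object@xiBeta < 0 | object@xiBeta > 1, na.rm = TRUE))
    msg <- c(msg, "xiBeta values outside [0,1]")
  if (length(object@referenceMaleMean) != nrow(object@xiBeta))
    msg <- c(msg, "referenceMaleMean length != nrow(xiBeta)")
  if (length(msg)) msg else TRUE
})

#' Quality-control report
#'
#' Per-sample and per-probe QC decisions with the supporting fractions.
#'
#' @slot samples data.frame with one row per input sample.
#' @slot probes data.frame with one row per input probe.
#' @aliases QCReport-class
#' @exportClass QCReport
setClass("QCReport",
         representation(samples = "data.frame", probes = "data.frame"))

setMethod("show", "BetaSet", function(object) {
  callNextMethod()
  cat(sprintf("companions: %s\n",
              paste(setdiff(assayNames(object), "beta"),
                    collapse = ", ")))
})

setMethod("show", "InactiveXMatrix", function(object) {
  cat(sprintf("InactiveXMatrix: %d X-linked probes x %d female samples\n",
              nrow(object@xiBeta), ncol(object@xiBeta)))
})

setMethod("show", "QCReport", function(object) {
  cat(sprintf("QCReport: %d samples (%d flagged), %d probes (%d dropped)\n",
              nrow(object@samples),
              if (nrow(object@samples))
                sum(rowSums(object@samples[, grepl("_fail$|^outlier$|mismatch",
                    colnames(object@samples)), drop = FALSE] == TRUE,
                    na.rm = TRUE) > 0) else 0L,
              nrow(object@probes),
              if (nrow(object@probes)) sum(!object@probes$keep) else 0L))
})
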
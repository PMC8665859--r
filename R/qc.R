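# Sample and probe quality control: detection-p / bead-count rules,
# methylation-based sex prediction, sample-to-sample correlation.
# All boundary rules are strict inequalities as stated: a sample fails
# when MORE than 1% of its probes are bad; a probe is dropped when bad
# in MORE than 5% of samples.

#' Flag poorly performing samples
#'
#' A sample is flagged `detection_fail` when its detection p-value
#' exceeds 0.01 at more than 1% of probes, and `bead_fail` when more
#' than 1% of its probes have fewer than 3 beads. A missing companion
#' matrix skips the corresponding check with a logged notice.
#'
#' @param object a [BetaSet].
#' @param detectionP_cut per-cell detection p threshold (default 0.01).
#' @param sample_frac per-sample failing fraction above which the
#'   sample is flagged (default 0.01, strict `>`).
#' @param min_beads minimum acceptable bead count (default 3).
#' @return a [QCReport] whose `qcSamples()` table carries the failing
#'   fractions and flags.
#' @export
flagSamples <- function(object, detectionP_cut = 0.01,
                        sample_frac = 0.01, min_beads = 3) {
  det <- detectionP(object)
  bead <- beadCount(object)
  n <- ncol(object)
  fracDet <- fracBead <- rep(NA_real_, n)
  if (is.null(det)) .log("no detection p-values: detection check skipped")
  else fracDet <- colMeans(det > detectionP_cut, na.rm = TRUE)
  if (is.null(bead)) .log("no bead counts: bead check skipped")
  else fracBead <- colMeans(bead < min_beads, na.rm = TRUE)
  samples <- data.frame(
    sample_id = colnames(object),
    frac_detection_fail = fracDet,
    frac_low_bead = fracBead,
    detection_fail = !is.na(fracDet) & fracDet > sample_frac,
    bead_fail = !is.na(fracBead) & fracBead > sample_frac,
    stringsAsFactors = FALSE)
  new("QCReport", samples = samples,
      probes = data.frame(probe_id = character(), keep = logical(),
                          reason = character()))
}

#' Drop poorly performing probes
#'
#' A probe is dropped when its detection p-value exceeds 0.01 in more
#' than 5% of samples, or its bead count falls below 3 in more than 5%
#' of samples (the bead rule mirrors the detection rule so a single
#' failed cell does not kill a probe observed well elsewhere).
#'
#' @inheritParams flagSamples
#' @param probe_frac per-probe failing sample fraction above which the
#'   probe is dropped (default 0.05, strict `>`).
#' @return list with `betaset` (kept probes) and `report` (a
#'   [QCReport] whose `qcProbes()` table records per-probe decisions
#'   and reasons).
#' @export
filterProbes <- function(object, detectionP_cut = 0.01,
                         probe_frac = 0.05, min_beads = 3) {
  det <- detectionP(object)
  bead <- beadCount(object)
  n <- nrow(object)
  fracDet <- fracBead <- rep(NA_real_, n)
  if (is.null(det)) .log("no detection p-values: detection check skipped")
  else fracDet <- rowMeans(det > detectionP_cut, na.rm = TRUE)
  if (is.null(bead)) .log("no bead counts: bead check skipped")
  else fracBead <- rowMeans(bead < min_beads, na.rm = TRUE)
  dropDet <- !is.na(fracDet) & fracDet > probe_frac
  dropBead <- !is.na(fracBead) & fracBead > probe_frac
  keep <- !(dropDet | dropBead)
  reason <- rep("", n)
  reason[dropDet] <- "detection"
  reason[dropBead] <- ifelse(dropDet[dropBead], "detection+bead", "bead")
  probes <- data.frame(
    probe_id = rownames(object),
    frac_detection_fail = fracDet,
    frac_low_bead = fracBead,
    keep = keep, reason = reason,
    stringsAsFactors = FALSE)
  if (any(!keep))
    .log(sum(!keep), " probe(s) dropped by QC")
  list(betaset = object[keep, ],
       report = new("QCReport",
                    samples = data.frame(sample_id = character()),
                    probes = probes))
}

#' Predict sample sex from X-chromosome methylation
#'
#' Because the female X-linked array signal is the composite of an
#' active and a (highly methylated) inactive X, female samples show a
#' higher mean X-chromosome beta than males. Samples are split into two
#' groups by agglomerative clustering of their mean X beta; the
#' higher-mean cluster is labelled `F`. When all samples are identical
#' the split is meaningless and the prediction abstains
#' (`indeterminate`). Predictions are compared against the sample
#' sheet's `sex` column (if present) to set `sex_mismatch`.
#'
#' @param object a [BetaSet] with X-chromosome probes annotated
#'   (`chrom == "X"` in the probe annotation).
#' @param annotation optional probe annotation data.frame overriding
#'   `probeAnnotation(object)`.
#' @return data.frame with `sample_id`, `mean_x_beta`,
#'   `predicted_sex` (`M`, `F` or `indeterminate`) and `sex_mismatch`.
#' @export
predictSex <- function(object, annotation = NULL) {
  if (ncol(object) < 2) stop("need at least 2 samples")
  an <- if (is.null(annotation)) probeAnnotation(object) else annotation
  if (!"chrom" %in% colnames(an))
    stop("probe annotation lacks a 'chrom' column")
  xprobes <- an$probe_id[!is.na(an$chrom) & an$chrom == "X"]
  xprobes <- intersect(xprobes, rownames(object))
  if (!length(xprobes)) stop("no X-chromosome probes present")
  mx <- colMeans(betaValues(object)[xprobes, , drop = FALSE],
                 na.rm = TRUE)
  if (diff(range(mx)) == 0) {
    pred <- rep("indeterminate", length(mx))
  } else {
    cl <- cutree(hclust(dist(mx), method = "average"), k = 2)
    hi <- which.max(tapply(mx, cl, mean))
    pred <- ifelse(cl == hi, "F", "M")
  }
  out <- data.frame(sample_id = colnames(object), mean_x_beta = mx,
                    predicted_sex = pred, stringsAsFactors = FALSE,
                    row.names = NULL)
  ss <- sampleSheet(object)
  if ("sex" %in% colnames(ss)) {
    out$sheet_sex <- ss$sex
    out$sex_mismatch <- !is.na(ss$sex) &
      (pred == "indeterminate" | pred != ss$sex)
  }
  out
}

#' Flag samples with low mean sample-to-sample correlation
#'
#' Computes each sample's mean Pearson correlation against all other
#' samples (on beta values) and flags samples falling below the
#' threshold. Constant (zero-variance) samples cannot be correlated and
#' are flagged `"constant"`.
#'
#' @param object a [BetaSet] with at least 3 samples.
#' @param threshold flag samples whose mean correlation is below this
#'   value (default 0.90).
#' @return data.frame with `sample_id`, `mean_correlation`, `outlier`
#'   and `reason`.
#' @export
correlationOutliers <- function(object, threshold = 0.90) {
  if (ncol(object) < 3) stop("need at least 3 samples")
  b <- betaValues(object)
  sds <- apply(b, 2, sd, na.rm = TRUE)
  const <- sds == 0 | is.na(sds)
  meanCor <- rep(NA_real_, ncol(b))
  ok <- which(!const)
  if (length(ok) >= 2) {
    cm <- cor(b[, ok, drop = FALSE], use = "pairwise.complete.obs")
    diag(cm) <- NA
    meanCor[ok] <- rowMeans(cm, na.rm = TRUE)
  }
  outlier <- const | (!is.na(meanCor) & meanCor < threshold)
  data.frame(sample_id = colnames(b), mean_correlation = meanCor,
             outlier = outlier,
             reason = ifelse(const, "constant",
                             ifelse(outlier, "low_correlation", "")),
             stringsAsFactors = FALSE, row.names = NULL)
}
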
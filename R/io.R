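# Readers/writers for the plain-text interchange formats, the beta/M
# transforms and the cross-platform probe intersection.

#' Logit transforms between beta and M values
#'
#' Methylation fractions (beta) are clipped into `[epsilon, 1-epsilon]`
#' and logit2-transformed: `M = log2(beta/(1-beta))`. The clip keeps M
#' finite when a beta of exactly 0 or 1 occurs (possible in synthetic
#' data, not on real arrays). `mToBeta()` is the exact inverse on the
#' clipped domain: `beta = 2^M/(1+2^M)`.
#'
#' @param beta numeric vector/matrix in `[0,1]`.
#' @param m numeric vector/matrix of finite M values.
#' @param epsilon clip bound, in (0, 0.5).
#' @return transformed object of the same shape.
#' @examples
#' betaToM(0.8)            # 2
#' mToBeta(betaToM(0.37))  # 0.37
#' @export
betaToM <- function(beta, epsilon = 0.001) {
  if (epsilon <= 0 || epsilon >= 0.5)
    stop("epsilon must lie in (0, 0.5)")
  if (any(beta < 0 | beta > 1, na.rm = TRUE))
    stop("beta values outside [0,1]")
  b <- .clip(beta, epsilon, 1 - epsilon)
  log2(b / (1 - b))
}

#' @rdname betaToM
#' @export
mToBeta <- function(m) {
  ## numerically symmetric form, stable for large |m|
  1 / (1 + 2^(-m))
}

#' Read a beta matrix (with optional companions) from TSV/CSV
#'
#' Expects a delimited file whose first column (`probe_id`) holds probe
#' identifiers and whose remaining columns are samples. Values must be
#' numeric fractions in `[0,1]`; out-of-range cells are reported with
#' their probe and sample ids. Optional detection p-value and
#' bead-count files must share dimensions and ordering exactly.
#'
#' @param path beta matrix file (TSV or CSV, sniffed from extension).
#' @param detectionPath,beadPath optional companion matrix files.
#' @param sampleSheet,probeAnnotation optional metadata passed through
#'   to [BetaSet()].
#' @return a validated [BetaSet].
#' @export
readBetaMatrix <- function(path, detectionPath = NULL, beadPath = NULL,
                           sampleSheet = NULL, probeAnnotation = NULL) {
  beta <- .readMatrix(path)
  bad <- which(!is.na(beta) & (beta < 0 | beta > 1))
  if (length(bad)) {
    idx <- arrayInd(bad, dim(beta))
    cells <- paste0(rownames(beta)[idx[, 1]], "/",
                    colnames(beta)[idx[, 2]], "=",
                    signif(beta[bad], 4))
    stop("beta values outside [0,1] at: ",
         paste(head(cells, 5), collapse = ", "),
         if (length(cells) > 5) sprintf(" (and %d more)",
                                        length(cells) - 5) else "")
  }
  det <- if (!is.null(detectionPath)) .readMatrix(detectionPath) else NULL
  bead <- if (!is.null(beadPath)) .readMatrix(beadPath) else NULL
  for (comp in list(detection = det, bead = bead)) {
    if (!is.null(comp)) {
      if (!identical(dim(comp), dim(beta)) ||
          !identical(dimnames(comp), dimnames(beta)))
        stop("companion matrix does not share the beta matrix's ",
             "dimensions and id ordering")
    }
  }
  BetaSet(beta, sampleSheet = sampleSheet,
          probeAnnotation = probeAnnotation,
          detectionP = det, beadCount = bead)
}

.readMatrix <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!ncol(df) || colnames(df)[1] != "probe_id")
    stop("first column must be 'probe_id' in ", path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicated probe id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (anyDuplicated(colnames(df)[-1]))
    stop("duplicated sample id(s) in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- colnames(df)[-1][!vapply(df[, -1, drop = FALSE],
                                    is.numeric, logical(1))]
    stop("non-numeric cells in column(s): ", paste(bad, collapse = ", "))
  }
  rownames(m) <- ids
  m
}

#' Read a sample sheet
#'
#' CSV with headers `sample_id,participant_id,sex,age,tissue,disease,`
#' `exposure,covid_status,batch` (extra columns are kept; the listed
#' ones are optional except `sample_id`). Categorical fields are
#' checked against strict vocabularies: sex in `{M,F}`, disease in
#' `{none,asthma,COPD,other}`, exposure in
#' `{FA+S,FA+A,DE+A,PDDE+A}`, covid_status in `{positive,negative}`.
#'
#' @param path CSV file.
#' @return a `data.frame` with one row per sample.
#' @export
readSampleSheet <- function(path) {
  ss <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample_id" %in% colnames(ss))
    stop("sample sheet must have a 'sample_id' column")
  if (anyDuplicated(ss$sample_id))
    stop("duplicated sample_id in sample sheet")
  if ("sex" %in% colnames(ss)) .checkVocab(ss$sex, .SEX_LEVELS, "sex")
  if ("disease" %in% colnames(ss))
    .checkVocab(ss$disease, .DISEASE_LEVELS, "disease")
  if ("exposure" %in% colnames(ss))
    .checkVocab(ss$exposure, .EXPOSURE_LEVELS, "exposure")
  if ("covid_status" %in% colnames(ss))
    .checkVocab(ss$covid_status, .COVID_LEVELS, "covid_status")
  ss
}

#' Read a probe annotation table
#'
#' TSV with headers `probe_id,chrom,pos,genes,feature,dist_to_tss,`
#' `promoter_density,platform_450k,platform_epic`; `genes` is
#' semicolon-separated (a probe counts toward every listed gene).
#' Positions are 1-based. `promoter_density` must be defined (HC, IC
#' or LC) whenever `feature` is `promoter`.
#'
#' @param path TSV file.
#' @return a `data.frame` with one row per probe.
#' @export
readAnnotation <- function(path) {
  an <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("probe_id", "chrom", "pos")
  miss <- setdiff(req, colnames(an))
  if (length(miss))
    stop("annotation is missing required column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(an$probe_id)) stop("duplicated probe_id in annotation")
  .checkVocab(an$chrom, c(as.character(1:22), "X", "Y"), "chrom")
  if ("feature" %in% colnames(an))
    .checkVocab(an$feature, .FEATURE_LEVELS, "feature")
  if ("promoter_density" %in% colnames(an)) {
    .checkVocab(an$promoter_density, .DENSITY_LEVELS, "promoter_density")
    if ("feature" %in% colnames(an)) {
      bad <- !is.na(an$feature) & an$feature == "promoter" &
        (is.na(an$promoter_density) | an$promoter_density == "none")
      if (any(bad))
        stop("promoter probes lack a promoter_density class: ",
             paste(head(an$probe_id[bad], 5), collapse = ", "))
    }
  }
  for (pcol in c("platform_450k", "platform_epic"))
    if (pcol %in% colnames(an)) an[[pcol]] <- as.logical(an[[pcol]])
  an
}

#' Split semicolon-separated gene lists
#' @param genes character vector of `;`-separated gene symbols.
#' @return list of character vectors (empty for blank/NA entries).
#' @export
splitGenes <- function(genes) {
  out <- strsplit(ifelse(is.na(genes), "", genes), ";", fixed = TRUE)
  lapply(out, function(g) g[nzchar(g)])
}

#' Write a result table to TSV
#' @param results data.frame of results.
#' @param path output file.
#' @export
writeResultTable <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writeResultTable
#' @param object a [BetaSet] whose beta assay should be written in the
#'   interchange format (first column `probe_id`).
#' @export
writeBetaMatrix <- function(object, path) {
  b <- betaValues(object)
  df <- data.frame(probe_id = rownames(b), b, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict data sets to the probes shared between array platforms
#'
#' Cross-platform comparisons (450K vs EPIC-style universes) are
#' performed on the intersection of the probe sets. Inputs may be
#' [BetaSet]s or character vectors of probe ids; all outputs are
#' restricted to the common probes, preserving the probe order of the
#' first input.
#'
#' @param ... two or more [BetaSet]s and/or character vectors.
#' @return a list of the inputs subset to the shared probes (a single
#'   character vector of probe ids if all inputs were vectors).
#' @export
intersectPlatforms <- function(...) {
  inputs <- list(...)
  if (length(inputs) == 1 && is.list(inputs[[1]]) &&
      !is(inputs[[1]], "BetaSet"))
    inputs <- inputs[[1]]
  if (length(inputs) < 2) stop("need at least two inputs")
  ids <- lapply(inputs, function(x)
    if (is(x, "BetaSet")) rownames(x) else as.character(x))
  common <- Reduce(intersect, ids[-1], ids[[1]])
  if (!length(common))
    stop("platform probe sets have an empty intersection")
  ## preserve the first input's order
  common <- ids[[1]][ids[[1]] %in% common]
  out <- lapply(inputs, function(x)
    if (is(x, "BetaSet")) x[common, ] else common)
  if (all(!vapply(inputs, is, logical(1), "BetaSet"))) return(common)
  out
}
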
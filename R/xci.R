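# X-chromosome inactivation: inactive-X estimation from the composite
# female array signal, promoter-based per-gene XCI status calls, and
# male-X vs female-inactive-X differential methylation for genes
# without an evaluable promoter.

#' Estimate female inactive-X methylation
#'
#' On the array, a female's X-linked beta is the composite of her
#' active X (approximated by the male X, which is lowly methylated at
#' CpG-island promoters) and her inactive X. With the male mean beta
#' `r_j` at probe `j` as the active-X proxy, the inactive-X estimate
#' for female `i` is `xi_ij = 2*beta_ij - r_j`, clamped into `[0,1]`.
#' The estimate is exact in expectation: `E[2*betaF - r] = Xi` under
#' the composite model `betaF = (Xa + Xi)/2`.
#'
#' @param object a [BetaSet] with X-chromosome probes and a `sex`
#'   column in the sheet; males and females are assumed
#'   tissue-matched.
#' @param annotation optional annotation override.
#' @return an [InactiveXMatrix] (X probes x female samples).
#' @export
estimateInactiveX <- function(object, annotation = NULL) {
  an <- if (is.null(annotation)) probeAnnotation(object) else annotation
  if (!"chrom" %in% colnames(an))
    stop("probe annotation lacks a 'chrom' column")
  xprobes <- an$probe_id[!is.na(an$chrom) & an$chrom == "X"]
  xprobes <- intersect(rownames(object), xprobes)
  if (!length(xprobes)) stop("no X-chromosome probes present")
  ss <- sampleSheet(object)
  males <- which(ss$sex == "M"); females <- which(ss$sex == "F")
  if (!length(males)) stop("no male samples: active-X reference undefined")
  if (!length(females)) stop("no female samples")
  b <- betaValues(object)[xprobes, , drop = FALSE]
  ref <- rowMeans(b[, males, drop = FALSE], na.rm = TRUE)
  xi <- 2 * b[, females, drop = FALSE] - ref
  xi <- .clip(xi, 0, 1)
  new("InactiveXMatrix", xiBeta = xi, referenceMaleMean = unname(ref))
}

#' Promoter probe set and CpG-density class for a gene
#'
#' Collects the gene's probes that are annotated `feature == promoter`
#' or lie within the promoter window around the TSS (default -1500 to
#' +500 bp, negative = upstream). The promoter class is the best
#' CpG-density class among them (HC beats IC); genes whose promoter
#' probes are all low-density (LC), or that have no promoter probes,
#' are `none_evaluable` - XCI status cannot be confidently predicted
#' from such promoters.
#'
#' @param gene gene symbol.
#' @param annotation probe annotation data.frame (`genes` may be
#'   semicolon-separated; a probe counts toward every listed gene).
#' @param window promoter window around the TSS, `c(upstream,
#'   downstream)` in signed bp.
#' @return list with `probes` (character) and `promoter_class`
#'   (`"HC"`, `"IC"` or `"none_evaluable"`).
#' @export
promoterProbeSet <- function(gene, annotation, window = c(-1500, 500)) {
  gl <- splitGenes(annotation$genes)
  hasGene <- vapply(gl, function(g) gene %in% g, logical(1))
  if (!any(hasGene)) stop("gene not present in annotation: ", gene)
  an <- annotation[hasGene, , drop = FALSE]
  inProm <- (!is.na(an$feature) & an$feature == "promoter")
  if ("dist_to_tss" %in% colnames(an))
    inProm <- inProm | (!is.na(an$dist_to_tss) &
                          an$dist_to_tss >= window[1] &
                          an$dist_to_tss <= window[2])
  an <- an[inProm, , drop = FALSE]
  dens <- an$promoter_density
  cls <- if (any(dens == "HC", na.rm = TRUE)) "HC"
  else if (any(dens == "IC", na.rm = TRUE)) "IC"
  else "none_evaluable"
  keep <- if (cls == "none_evaluable") character()
  else an$probe_id[!is.na(dens) & dens == cls]
  list(probes = keep, promoter_class = cls)
}

#' Classify a gene's X-inactivation status from promoter methylation
#'
#' Applies the promoter rules to measured male and female beta values
#' (the composite female signal), in this order:
#' 1. *subject* - promoter mean delta-beta (female minus male)
#'    exceeds 0.10 and the smallest promoter q-value is below 0.05
#'    (promoter hypermethylated on the inactive X);
#' 2. *escape* - both sex means below 0.15, or the per-sex ranges of
#'    per-sample promoter-mean beta overlap, or the ranges are
#'    disjoint with |delta-beta| below 0.10;
#' 3. otherwise *not_evaluable* (`rule_fired = "indeterminate"`).
#' Genes without an HC/IC promoter are `not_evaluable` up front.
#' Exactly one rule fires per call; the firing branch is recorded.
#'
#' @param gene gene symbol.
#' @param object a [BetaSet] with both sexes.
#' @param promoterSet result of [promoterProbeSet()] for the gene.
#' @param qvalues named per-probe q-values from a male/female
#'   differential methylation fit over the X probe family.
#' @param config an [analysisConfig()] carrying `xci_low_beta` (0.15),
#'   `xci_delta_beta` (0.10) and `x_fdr_threshold` (0.05).
#' @return one-row data.frame: `gene, promoter_class, status,
#'   promoter_male_mean_beta, promoter_female_mean_beta,
#'   promoter_delta_beta, min_q, n_promoter_probes, rule_fired`.
#' @export
classifyXci <- function(gene, object, promoterSet, qvalues = NULL,
                        config = analysisConfig()) {
  cls <- promoterSet$promoter_class
  probes <- intersect(promoterSet$probes, rownames(object))
  base <- data.frame(gene = gene, promoter_class = cls,
                     status = "not_evaluable",
                     promoter_male_mean_beta = NA_real_,
                     promoter_female_mean_beta = NA_real_,
                     promoter_delta_beta = NA_real_,
                     min_q = NA_real_,
                     n_promoter_probes = length(probes),
                     rule_fired = "no_hc_ic_promoter",
                     stringsAsFactors = FALSE)
  if (cls == "none_evaluable" || !length(probes)) return(base)
  ss <- sampleSheet(object)
  males <- ss$sex == "M"; females <- ss$sex == "F"
  if (!any(males) || !any(females)) stop("both sexes required")
  b <- betaValues(object)[probes, , drop = FALSE]
  ## per-sample promoter-mean beta, then per-sex summaries
  perSample <- colMeans(b, na.rm = TRUE)
  mMean <- mean(perSample[males]); fMean <- mean(perSample[females])
  delta <- fMean - mMean
  minq <- if (!is.null(qvalues)) {
    qq <- qvalues[probes]
    if (all(is.na(qq))) NA_real_ else min(qq, na.rm = TRUE)
  } else NA_real_
  rngM <- range(perSample[males]); rngF <- range(perSample[females])
  overlap <- rngM[1] <= rngF[2] && rngF[1] <= rngM[2]

  out <- base
  out$promoter_male_mean_beta <- mMean
  out$promoter_female_mean_beta <- fMean
  out$promoter_delta_beta <- delta
  out$min_q <- minq
  if (delta > config$xci_delta_beta && !is.na(minq) &&
      minq < config$x_fdr_threshold) {
    out$status <- "subject"
    out$rule_fired <- "delta_gt_threshold_and_fdr"
  } else if (mMean < config$xci_low_beta &&
             fMean < config$xci_low_beta) {
    out$status <- "escape"
    out$rule_fired <- "both_sexes_low_beta"
  } else if (overlap) {
    out$status <- "escape"
    out$rule_fired <- "overlapping_ranges"
  } else if (abs(delta) < config$xci_delta_beta) {
    out$status <- "escape"
    out$rule_fired <- "disjoint_small_delta"
  } else {
    out$rule_fired <- "indeterminate"
  }
  out
}

#' Differential methylation between male X and female inactive X
#'
#' For genes without an evaluable promoter, compares the estimated
#' female inactive-X beta against male X beta probe-by-probe: a
#' two-group linear model on M-transformed values (reusing the
#' [fitProbeLm()] machinery), BH-FDR across the probe family,
#' delta-beta = mean(female Xi beta) - mean(male beta), and the
#' X-linked dual rule `q < 0.05` and `|delta_beta| > 0.10`.
#'
#' @param xi an [InactiveXMatrix] from [estimateInactiveX()].
#' @param object the [BetaSet] providing the male samples.
#' @param probes probe subset (default: all probes of `xi`).
#' @param config an [analysisConfig()].
#' @param moderate empirical-Bayes moderation flag.
#' @return data.frame in [dmAnalysis()] layout.
#' @export
xDiffMeth <- function(xi, object, probes = rownames(xiBeta(xi)),
                      config = analysisConfig(), moderate = TRUE) {
  xb <- xiBeta(xi)
  probes <- intersect(probes, rownames(xb))
  probes <- intersect(probes, rownames(object))
  if (!length(probes)) stop("shared probe set is empty")
  ss <- sampleSheet(object)
  males <- which(ss$sex == "M")
  if (!length(males)) stop("no male samples")
  bm <- betaValues(object)[probes, males, drop = FALSE]
  bx <- xb[probes, , drop = FALSE]
  comb <- cbind(bx, bm)
  colnames(comb) <- make.unique(c(paste0("xi_", colnames(bx)),
                                  colnames(bm)))
  grp <- data.frame(group = rep(c("female_xi", "male_x"),
                                c(ncol(bx), ncol(bm))))
  m <- betaToM(comb, epsilon = config$beta_clip_epsilon)
  res <- fitProbeLm(m, sampleSheet = grp, mainEffect = "group",
                    moderate = moderate)
  res$q <- bhFdr(res$p)
  res$delta_beta <- rowMeans(bx) - rowMeans(bm)
  callSignificant(res, config$x_fdr_threshold,
                  config$x_delta_beta_threshold)
}

#' Per-gene XCI analysis of a data set
#'
#' Runs the full X-inactivation workflow: male/female differential
#' methylation over the X probe family (for the promoter q-values),
#' promoter probe collection and [classifyXci()] for every X-linked
#' gene in the annotation.
#'
#' @param object a [BetaSet] with X probes and both sexes.
#' @param window promoter window for [promoterProbeSet()].
#' @param config an [analysisConfig()].
#' @param moderate empirical-Bayes moderation flag.
#' @return data.frame of [classifyXci()] rows, one per X-linked gene.
#' @export
xciAnalysis <- function(object, window = c(-1500, 500),
                        config = analysisConfig(), moderate = TRUE) {
  an <- probeAnnotation(object)
  xsel <- !is.na(an$chrom) & an$chrom == "X"
  if (!any(xsel)) stop("no X-chromosome probes present")
  xan <- an[xsel, , drop = FALSE]
  xbs <- object[xan$probe_id, ]
  dm <- fitProbeLm(xbs, mainEffect = "sex", moderate = moderate,
                   epsilon = config$beta_clip_epsilon)
  qv <- setNames(bhFdr(dm$p), dm$probe_id)
  genes <- sort(unique(unlist(splitGenes(xan$genes))))
  do.call(rbind, lapply(genes, function(g) {
    ps <- promoterProbeSet(g, xan, window = window)
    classifyXci(g, xbs, ps, qvalues = qv, config = config)
  }))
}
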
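# Sex-biased differential expression: Welch t test per gene with
# BH-FDR and male-minus-female log-fold-change reporting.

#' Welch two-sample t test (unequal variances)
#'
#' `t = (mean_a - mean_b) / sqrt(s_a^2/n_a + s_b^2/n_b)` with
#' Welch-Satterthwaite degrees of freedom
#' `df = (s_a^2/n_a + s_b^2/n_b)^2 / ((s_a^2/n_a)^2/(n_a-1) +
#' (s_b^2/n_b)^2/(n_b-1))` and a two-sided p-value from the t
#' distribution. With zero variance in both groups and equal means the
#' statistic is undefined and reported missing.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return list with `t`, `df`, `p`.
#' @examples
#' welchT(c(4, 5, 6), c(1, 2, 3))  # t = 3.674, df = 4
#' @export
welchT <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("each group needs at least 2 values")
  va <- var(a) / na; vb <- var(b) / nb
  se2 <- va + vb
  if (se2 == 0)
    return(list(t = NA_real_, df = NA_real_, p = NA_real_))
  tt <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  list(t = tt, df = df, p = 2 * pt(-abs(tt), df))
}

#' Sex-biased differential expression
#'
#' Per-gene Welch t test between male and female samples on a
#' log-scale expression matrix, BH-FDR across genes, and the
#' male-minus-female log2 fold change. Count-valued matrices are
#' `log2(x + 1)`-transformed first when `logTransformCounts = TRUE`
#' (logged).
#'
#' @param object a `SummarizedExperiment` (first assay used, `sex` in
#'   `colData`) or a genes-by-samples matrix.
#' @param sampleSheet data.frame with a `sex` column (required for a
#'   plain matrix).
#' @param fdr significance threshold on q (default 0.05; small cohorts
#'   commonly use a lenient 0.20).
#' @param logTransformCounts apply `log2(x + 1)` before testing.
#' @return data.frame with `gene, lfc, t, df, p, q, significant`.
#' @export
sexdiffExpression <- function(object, sampleSheet = NULL, fdr = 0.05,
                              logTransformCounts = FALSE) {
  if (is(object, "SummarizedExperiment")) {
    expr <- assay(object)
    if (is.null(sampleSheet))
      sampleSheet <- as.data.frame(colData(object))
  } else expr <- as.matrix(object)
  if (is.null(sampleSheet) || !"sex" %in% colnames(sampleSheet))
    stop("a sample sheet with a 'sex' column is required")
  sex <- as.character(sampleSheet$sex)
  im <- which(sex == "M"); if_ <- which(sex == "F")
  if (length(im) < 2 || length(if_) < 2)
    stop("need at least 2 samples of each sex")
  if (logTransformCounts) {
    .log("applying log2(x + 1) to count-valued expression")
    expr <- log2(expr + 1)
  }
  res <- t(apply(expr, 1, function(x) {
    w <- welchT(x[im], x[if_])
    c(w$t, w$df, w$p)
  }))
  lfc <- rowMeans(expr[, im, drop = FALSE]) -
    rowMeans(expr[, if_, drop = FALSE])
  out <- data.frame(gene = rownames(expr), lfc = lfc,
                    t = res[, 1], df = res[, 2], p = res[, 3],
                    stringsAsFactors = FALSE, row.names = NULL)
  out$q <- bhFdr(out$p)
  out$significant <- !is.na(out$q) & out$q < fdr
  out
}
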
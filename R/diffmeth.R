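# Per-probe linear-model differential methylation on M values with
# empirical-Bayes variance moderation, Benjamini-Hochberg FDR and the
# dual statistical/biological (delta-beta) significance rule.

## reference levels so a 2-level main effect is coded control = 0,
## making the M-scale coefficient sign agree with the male-minus-female
## (or case-minus-control) delta-beta sign
.REF_LEVELS <- c(sex = "F", disease = "none", covid_status = "negative",
                 exposure = "FA+S")

.designFrame <- function(ss, vars) {
  df <- ss[, vars, drop = FALSE]
  for (v in vars) {
    x <- df[[v]]
    if (is.character(x) || is.factor(x)) {
      x <- as.character(x)
      lev <- unique(x[!is.na(x)])
      ref <- unname(.REF_LEVELS[v])
      if (!is.na(ref) && ref %in% lev)
        lev <- c(ref, setdiff(lev, ref))
      df[[v]] <- factor(x, levels = lev)
    }
  }
  df
}

#' Per-probe linear models on M values
#'
#' Fits, for every probe, an ordinary least-squares model of the
#' M value on a main effect plus covariates (e.g. sex as the main
#' effect with age and disease status as covariates). Samples with a
#' missing value in any model variable are dropped (complete-case,
#' with a logged count). With `moderate = TRUE` (default) the
#' per-probe residual variances are shrunk toward a common prior by
#' empirical Bayes: the posterior variance is
#' `s2_post = (d0*s0^2 + d*s^2) / (d0 + d)` with hyperparameters
#' `d0`, `s0^2` estimated by method of moments on `log s^2`
#' (see [moderateVariances()]); t statistics are recomputed with
#' `d0 + d` degrees of freedom. Two-level factors are coded with the
#' control level (F, none, negative) as baseline, so the main-effect
#' coefficient sign matches the corresponding delta-beta convention.
#'
#' @param object a [BetaSet] (M values computed internally) or a
#'   numeric M-value matrix (probes x samples).
#' @param sampleSheet data.frame of per-sample covariates; defaults to
#'   `sampleSheet(object)` for a BetaSet.
#' @param mainEffect column name of the main effect (2-level factor or
#'   numeric).
#' @param covariates character vector of adjustment columns.
#' @param moderate apply empirical-Bayes variance moderation.
#' @param priorDf optional fixed prior degrees of freedom `d0`
#'   overriding the method-of-moments estimate (`0` reproduces the
#'   unmoderated fit exactly).
#' @param epsilon logit clip bound for the beta-to-M transform.
#' @return data.frame with `probe_id, coef, se, t, df, p` for the main
#'   effect (first non-intercept coefficient). Probes with zero
#'   residual variance and df get `p = NA`.
#' @export
fitProbeLm <- function(object, sampleSheet = NULL, mainEffect = "sex",
                       covariates = character(), moderate = TRUE,
                       priorDf = NULL, epsilon = 0.001) {
  if (is(object, "BetaSet")) {
    m <- mValues(object, epsilon = epsilon)
    if (is.null(sampleSheet)) sampleSheet <- sampleSheet(object)
  } else m <- as.matrix(object)
  vars <- c(mainEffect, covariates)
  miss <- setdiff(vars, colnames(sampleSheet))
  if (length(miss))
    stop("sample sheet lacks column(s): ", paste(miss, collapse = ", "))
  df <- .designFrame(sampleSheet, vars)
  cc <- complete.cases(df)
  if (any(!cc))
    .log(sum(!cc), " sample(s) dropped (missing covariate values)")
  df <- df[cc, , drop = FALSE]
  m <- m[, cc, drop = FALSE]
  X <- model.matrix(~ ., df)
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient")
  n <- nrow(X); p <- ncol(X)
  d <- n - p
  if (d < 0) stop("more coefficients than samples")
  XtXi <- solve(crossprod(X))
  B <- XtXi %*% crossprod(X, t(m))          # p x probes
  res <- t(m) - X %*% B
  s2 <- colSums(res^2) / max(d, 1)
  j <- 2L                                    # main effect coefficient
  coef <- B[j, ]
  unscaled <- sqrt(XtXi[j, j])
  if (moderate) {
    mv <- moderateVariances(s2, d, priorDf = priorDf)
    s2use <- mv$s2_post
    dfuse <- d + mv$df_prior
  } else {
    s2use <- s2
    dfuse <- rep(d, length(s2))
  }
  se <- sqrt(s2use) * unscaled
  t <- coef / se
  pval <- 2 * pt(-abs(t), dfuse)
  pval[d == 0 | !is.finite(t)] <- NA_real_
  dfuse <- rep_len(dfuse, length(t))
  data.frame(probe_id = rownames(m), coef = coef, se = se, t = t,
             df = dfuse, p = pval, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Empirical-Bayes moderation of per-probe variances
#'
#' Shrinks observed residual variances `s^2` (on `df` residual degrees
#' of freedom each) toward a common prior `s0^2` with prior degrees of
#' freedom `d0`, assuming `s^2 ~ s0^2 * F(df, d0)`. `d0` and `s0^2` are
#' estimated by method of moments on `log s^2`: with
#' `e = log(s^2) - digamma(df/2) + log(df/2)`,
#' `var(e) = trigamma(df/2) + trigamma(d0/2)` identifies `d0` via the
#' inverse trigamma, and `mean(e)` then identifies `s0^2`. When the
#' observed spread is no larger than the sampling spread, `d0` is
#' infinite and every posterior variance equals `s0^2`.
#'
#' @param s2 per-probe residual variances.
#' @param df residual degrees of freedom (scalar).
#' @param priorDf optional fixed `d0` (bypasses estimation; `0` means
#'   no shrinkage, `Inf` total shrinkage).
#' @return list with `df_prior`, `s2_prior` and per-probe `s2_post`.
#' @export
moderateVariances <- function(s2, df, priorDf = NULL) {
  df <- df[1]
  if (!is.null(priorDf)) {
    d0 <- priorDf
    if (d0 == 0)
      return(list(df_prior = 0, s2_prior = NA_real_, s2_post = s2))
    ## with a fixed d0, centre the prior on the mean log-variance
    e <- log(pmax(s2, 1e-300)) - digamma(df / 2) + log(df / 2)
    s0 <- if (is.finite(d0))
      exp(mean(e) + digamma(d0 / 2) - log(d0 / 2)) else exp(mean(e))
  } else {
    e <- log(pmax(s2, 1e-300)) - digamma(df / 2) + log(df / 2)
    evar <- var(e)
    excess <- evar - trigamma(df / 2)
    if (is.na(excess) || excess <= 0) {
      d0 <- Inf
      s0 <- exp(mean(e))
    } else {
      d0 <- 2 * .trigammaInverse(excess)
      s0 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    }
  }
  post <- if (is.finite(d0)) (d0 * s0 + df * s2) / (d0 + df)
  else rep(s0, length(s2))
  list(df_prior = d0, s2_prior = s0, s2_post = post)
}

## Newton solve of trigamma(y) = x
.trigammaInverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment: with ordered p-values `p_(1) <= ... <= p_(m)`,
#' `q_(i) = min_{j >= i} (m * p_(j) / j)`, capped at 1. Missing
#' p-values propagate as missing and do not count toward `m`.
#'
#' @param p numeric vector of p-values in `[0,1]` (NA allowed).
#' @return q-values in the original order.
#' @examples
#' bhFdr(c(0.001, 0.01, 0.02, 0.04))
#' @export
bhFdr <- function(p) {
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  pp <- p[ok]
  if (any(pp < 0 | pp > 1)) stop("p-values outside [0,1]")
  m <- length(pp)
  if (!m) return(q)
  o <- order(pp, decreasing = TRUE)
  qq <- numeric(m)
  qq[o] <- pmin(1, cummin(m / seq(m, 1) * pp[o]))
  q[ok] <- qq
  q
}

#' Group difference in mean beta (delta-beta)
#'
#' Per-probe difference of unadjusted group mean beta values.
#' Conventions: `"male_minus_female"` (mean beta of males minus mean
#' beta of females, the autosomal sign convention) and
#' `"case_minus_control"` for disease/COVID contrasts. The X-linked
#' inactive-X-minus-male convention is handled by [xDiffMeth()].
#'
#' @param object a [BetaSet] or beta matrix.
#' @param groups per-sample group labels; defaults to the sheet's
#'   `sex` column for the male/female convention.
#' @param convention sign convention, one of `"male_minus_female"`,
#'   `"case_minus_control"`.
#' @param case,control group labels for the case/control convention.
#' @return named numeric vector of per-probe delta-beta.
#' @export
deltaBeta <- function(object, groups = NULL,
                      convention = c("male_minus_female",
                                     "case_minus_control"),
                      case = NULL, control = NULL) {
  convention <- match.arg(convention)
  b <- if (is(object, "BetaSet")) betaValues(object) else as.matrix(object)
  if (is.null(groups)) {
    if (!is(object, "BetaSet"))
      stop("groups required for a plain matrix")
    groups <- sampleSheet(object)$sex
  }
  groups <- as.character(groups)
  if (convention == "male_minus_female") {
    a <- "M"; bgrp <- "F"
  } else {
    if (is.null(case) || is.null(control))
      stop("case and control labels required")
    a <- case; bgrp <- control
  }
  ia <- which(groups == a); ib <- which(groups == bgrp)
  if (!length(ia) || !length(ib))
    stop(sprintf("empty group ('%s': %d, '%s': %d samples)",
                 a, length(ia), bgrp, length(ib)))
  rowMeans(b[, ia, drop = FALSE], na.rm = TRUE) -
    rowMeans(b[, ib, drop = FALSE], na.rm = TRUE)
}

#' Dual statistical/biological significance call
#'
#' A probe is significant when it passes both the statistical rule
#' (BH-FDR `q < fdr_threshold`) and the biological rule
#' (`|delta_beta| > delta_beta_threshold`).
#'
#' @param results data.frame with columns `q` and `delta_beta` (e.g.
#'   from [dmAnalysis()]).
#' @param fdr_threshold,delta_beta_threshold the dual thresholds
#'   (autosomal default 0.05/0.05).
#' @return `results` with a logical `significant` column.
#' @export
callSignificant <- function(results, fdr_threshold = 0.05,
                            delta_beta_threshold = 0.05) {
  stopifnot(all(c("q", "delta_beta") %in% colnames(results)))
  results$significant <- !is.na(results$q) &
    results$q < fdr_threshold &
    !is.na(results$delta_beta) &
    abs(results$delta_beta) > delta_beta_threshold
  results
}

#' Differential methylation analysis with the dual rule
#'
#' Convenience wrapper: [fitProbeLm()] on M values, [bhFdr()] across
#' the probe family, [deltaBeta()] on the raw beta values, and
#' [callSignificant()]. FDR adjustment is performed within the supplied
#' probe family (one tissue x one probe set).
#'
#' @inheritParams fitProbeLm
#' @param convention,case,control passed to [deltaBeta()].
#' @param fdr_threshold,delta_beta_threshold dual thresholds.
#' @return data.frame with `probe_id, coef, se, t, df, p, q,
#'   delta_beta, significant`.
#' @export
dmAnalysis <- function(object, mainEffect = "sex",
                       covariates = character(), moderate = TRUE,
                       convention = c("male_minus_female",
                                      "case_minus_control"),
                       case = NULL, control = NULL,
                       fdr_threshold = 0.05,
                       delta_beta_threshold = 0.05,
                       epsilon = 0.001) {
  convention <- match.arg(convention)
  res <- fitProbeLm(object, mainEffect = mainEffect,
                    covariates = covariates, moderate = moderate,
                    epsilon = epsilon)
  res$q <- bhFdr(res$p)
  groups <- sampleSheet(object)[[mainEffect]]
  res$delta_beta <- deltaBeta(object, groups = groups,
                              convention = convention,
                              case = case, control = control)
  callSignificant(res, fdr_threshold, delta_beta_threshold)
}

#' Probes concordantly sex-biased across tissues
#'
#' Given per-tissue differential methylation tables over a shared probe
#' universe, reports probes significant in at least `k` tissues with
#' (optionally) the same delta-beta sign in every tissue where they are
#' significant.
#'
#' @param results named list of data.frames with `probe_id`,
#'   `delta_beta`, `significant`.
#' @param k minimum number of tissues (default: all).
#' @param requireSameSign require a common delta-beta sign among the
#'   significant tissues.
#' @return data.frame with per-tissue delta-beta columns,
#'   `n_significant` and the `concordant` flag.
#' @export
crossTissueConcordance <- function(results, k = length(results),
                                   requireSameSign = TRUE) {
  if (length(results) < 2) stop("need at least two result tables")
  if (k > length(results))
    stop("k exceeds the number of tissues")
  if (is.null(names(results)))
    names(results) <- paste0("tissue", seq_along(results))
  ids <- results[[1]]$probe_id
  for (r in results[-1])
    if (!setequal(r$probe_id, ids))
      stop("result tables do not share a probe universe")
  sig <- sapply(results, function(r)
    r$significant[match(ids, r$probe_id)])
  db <- sapply(results, function(r)
    r$delta_beta[match(ids, r$probe_id)])
  nSig <- rowSums(sig, na.rm = TRUE)
  sameSign <- vapply(seq_along(ids), function(i) {
    s <- which(sig[i, ])
    length(s) <= 1 || length(unique(sign(db[i, s]))) == 1
  }, logical(1))
  conc <- nSig >= k & (!requireSameSign | sameSign)
  out <- data.frame(probe_id = ids, n_significant = nSig,
                    sign_concordant = sameSign, concordant = conc,
                    stringsAsFactors = FALSE)
  colnames(db) <- paste0("delta_beta_", names(results))
  cbind(out, db)
}

#' Age-stratified sex differences in methylation
#'
#' Splits samples into left-closed/right-open age bins (default
#' `[0,20) [20,30) [30,40) [40,50) [50,Inf)`) and reports the
#' male-minus-female delta-beta per probe within each bin. Bins missing
#' a sex are reported as missing, with sample counts.
#'
#' @param object a [BetaSet] whose sheet has `sex` and `age`.
#' @param breaks ascending bin edges (last bin unbounded above when the
#'   final edge is `Inf`).
#' @return list with `delta` (probes x bins matrix, NA for
#'   unevaluable bins) and `counts` (per-bin male/female counts).
#' @export
ageStratifiedDelta <- function(object, breaks = c(0, 20, 30, 40, 50, Inf)) {
  ss <- sampleSheet(object)
  stopifnot(all(c("sex", "age") %in% colnames(ss)))
  bins <- cut(ss$age, breaks = breaks, right = FALSE)
  labs <- levels(bins)
  b <- betaValues(object)
  delta <- matrix(NA_real_, nrow(b), length(labs),
                  dimnames = list(rownames(b), labs))
  counts <- data.frame(bin = labs, n_male = 0L, n_female = 0L,
                       evaluated = FALSE)
  for (i in seq_along(labs)) {
    inBin <- !is.na(bins) & bins == labs[i]
    nm <- sum(inBin & ss$sex == "M"); nf <- sum(inBin & ss$sex == "F")
    counts$n_male[i] <- nm; counts$n_female[i] <- nf
    if (nm >= 1 && nf >= 1) {
      counts$evaluated[i] <- TRUE
      delta[, i] <- deltaBeta(b[, inBin, drop = FALSE],
                              groups = ss$sex[inBin])
    } else {
      .log(sprintf("age bin %s skipped (%d male, %d female)",
                   labs[i], nm, nf))
    }
  }
  list(delta = delta, counts = counts)
}

#' Sex-stratified case/control comparison at candidate probes
#'
#' Within each sex separately, compares COVID-positive against
#' COVID-negative samples at a supplied candidate probe set: Welch t
#' test on M values, delta-beta = mean beta(positive) - mean
#' beta(negative). A probe is flagged under the exploratory rule
#' (unadjusted `p <= 0.05` and `|delta_beta| > 0.05`); all values are
#' reported regardless. A sex with fewer than 2 samples per status is
#' reported missing.
#'
#' @param object a [BetaSet] whose sheet has `sex` and `covid_status`.
#' @param probes candidate probe ids (default: all probes).
#' @param statusColumn sheet column holding the two-level status.
#' @param case,control status labels.
#' @param p_cut,delta_cut exploratory flagging thresholds.
#' @param epsilon logit clip bound.
#' @return data.frame with one row per probe per sex.
#' @export
sexStratifiedStatus <- function(object, probes = rownames(object),
                                statusColumn = "covid_status",
                                case = "positive", control = "negative",
                                p_cut = 0.05, delta_cut = 0.05,
                                epsilon = 0.001) {
  ss <- sampleSheet(object)
  stopifnot(all(c("sex", statusColumn) %in% colnames(ss)))
  probes <- intersect(probes, rownames(object))
  if (!length(probes)) stop("no candidate probes present")
  b <- betaValues(object)[probes, , drop = FALSE]
  m <- betaToM(b, epsilon = epsilon)
  out <- list()
  for (sx in c("M", "F")) {
    iCase <- which(ss$sex == sx & ss[[statusColumn]] %in% case)
    iCtrl <- which(ss$sex == sx & ss[[statusColumn]] %in% control)
    if (length(iCase) < 2 || length(iCtrl) < 2) {
      .log(sprintf("sex %s stratum not evaluable (%d case, %d control)",
                   sx, length(iCase), length(iCtrl)))
      out[[sx]] <- data.frame(
        probe_id = probes, sex = sx, n_case = length(iCase),
        n_control = length(iCtrl), delta_beta = NA_real_,
        t = NA_real_, df = NA_real_, p = NA_real_, flagged = NA,
        stringsAsFactors = FALSE)
      next
    }
    wt <- t(apply(m, 1, function(x) {
      w <- welchT(x[iCase], x[iCtrl])
      c(w$t, w$df, w$p)
    }))
    db <- rowMeans(b[, iCase, drop = FALSE]) -
      rowMeans(b[, iCtrl, drop = FALSE])
    out[[sx]] <- data.frame(
      probe_id = probes, sex = sx, n_case = length(iCase),
      n_control = length(iCtrl), delta_beta = db,
      t = wt[, 1], df = wt[, 2], p = wt[, 3],
      flagged = !is.na(wt[, 3]) & wt[, 3] <= p_cut & abs(db) > delta_cut,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
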
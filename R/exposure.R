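# Crossover exposure designs: per-probe random-intercept mixed models
# (ML, via lme4), likelihood-ratio tests for a fixed main effect, and
# Dunnett-style many-to-one post-hoc contrasts against the FA+S
# control (via multcomp), with the exposure dual rule
# (FDR < 0.1, |delta-beta| > 0.025 vs control).

#' Fit a random-intercept model for one probe
#'
#' Gaussian linear mixed model on M values with a participant random
#' intercept, fitted by maximum likelihood (not REML - required for
#' likelihood-ratio tests on fixed effects).
#'
#' @param y numeric M values, one per sample.
#' @param sampleSheet data.frame with `participant_id` and the fixed
#'   effect columns.
#' @param fixed character vector of fixed-effect column names (e.g.
#'   `c("exposure", "sex", "disease", "age")`); constant columns are
#'   dropped with a notice.
#' @return list with `fit` (the `lmerMod`), `logLik`, `fixef`,
#'   `sigma_u` (participant intercept sd, floored at 0 by the fitter),
#'   `sigma_e`, `fixed` (the columns actually used) and `converged`.
#' @export
fitLmm <- function(y, sampleSheet, fixed = c("exposure", "sex",
                                             "disease", "age")) {
  ss <- as.data.frame(sampleSheet)
  if (!"participant_id" %in% colnames(ss))
    stop("sample sheet lacks participant_id")
  tab <- table(ss$participant_id)
  if (sum(tab >= 2) < 3)
    stop("model degenerate: need >= 3 participants with >= 2 ",
         "observations each")
  miss <- setdiff(fixed, colnames(ss))
  if (length(miss))
    stop("sample sheet lacks column(s): ", paste(miss, collapse = ", "))
  keep <- fixed[vapply(fixed, function(v)
    length(unique(ss[[v]][!is.na(ss[[v]])])) > 1, logical(1))]
  dropped <- setdiff(fixed, keep)
  if (length(dropped))
    .log("constant fixed effect(s) dropped: ",
         paste(dropped, collapse = ", "))
  df <- .designFrame(ss, c(keep, "participant_id"))
  df$.y <- y
  cc <- complete.cases(df)
  df <- df[cc, , drop = FALSE]
  rhs <- if (length(keep)) paste(keep, collapse = " + ") else "1"
  form <- as.formula(paste(".y ~", rhs, "+ (1 | participant_id)"))
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(form, data = df, REML = FALSE,
               control = lme4::lmerControl(calc.derivs = FALSE,
                                           check.conv.singular =
                                             "ignore"))))
  .lmmSummary(fit, keep)
}

.lmmSummary <- function(fit, fixed) {
  vc <- lme4::VarCorr(fit)
  conv <- is.null(fit@optinfo$conv$lme4$code) ||
    fit@optinfo$conv$lme4$code == 0
  list(fit = fit, logLik = as.numeric(logLik(fit)),
       fixef = lme4::fixef(fit),
       sigma_u = attr(vc$participant_id, "stddev")[[1]],
       sigma_e = stats::sigma(fit),
       fixed = fixed, reml = FALSE, converged = conv)
}

#' Likelihood-ratio test between nested ML fits
#'
#' `stat = 2 * (logLik_full - logLik_reduced)`, floored at 0, compared
#' against a chi-square with df equal to the difference in
#' fixed-effect coefficient counts. Both models must be fitted by ML
#' on the same data; REML fits are refused, as are non-nested
#' fixed-effect sets.
#'
#' @param full,reduced results of [fitLmm()].
#' @return list with `stat`, `df`, `p`.
#' @export
lrtMainEffect <- function(full, reduced) {
  if (isTRUE(full$reml) || isTRUE(reduced$reml))
    stop("likelihood-ratio tests require ML fits")
  if (!all(reduced$fixed %in% full$fixed))
    stop("reduced model is not nested in the full model")
  dfDiff <- length(full$fixef) - length(reduced$fixef)
  if (dfDiff <= 0) {
    stat <- max(0, 2 * (full$logLik - reduced$logLik))
    return(list(stat = stat, df = 0L, p = 1))
  }
  stat <- max(0, 2 * (full$logLik - reduced$logLik))
  list(stat = stat, df = dfDiff,
       p = pchisq(stat, df = dfDiff, lower.tail = FALSE))
}

#' Many-to-one post-hoc contrasts against the control condition
#'
#' Single-step (Dunnett-style) comparisons of each non-control exposure
#' level against the control, using the joint normal approximation of
#' the fixed-effect estimator over the three correlated contrasts
#' (via `multcomp::glht`). Adjusted p-values are never smaller than
#' the unadjusted ones.
#'
#' @param full a [fitLmm()] result whose fixed effects include
#'   `exposure`.
#' @param control control level (default `"FA+S"`).
#' @return data.frame with `contrast`, `estimate` (M scale), `se`,
#'   `p_adjusted`.
#' @export
posthocVsControl <- function(full, control = "FA+S") {
  if (!"exposure" %in% full$fixed)
    stop("exposure is not a fixed effect in this fit")
  lev <- levels(full$fit@frame$exposure)
  if (!control %in% lev) stop("control level absent: ", control)
  if (lev[1] != control)
    stop("exposure factor must have the control as reference level")
  gl <- multcomp::glht(full$fit,
                       linfct = multcomp::mcp(exposure = "Dunnett"))
  sm <- summary(gl)   # single-step adjustment (joint max-|z|)
  data.frame(contrast = names(sm$test$coefficients),
             estimate = as.numeric(sm$test$coefficients),
             se = as.numeric(sm$test$sigma),
             p_adjusted = as.numeric(sm$test$pvalues),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-probe exposure (or asthma) analysis of a crossover study
#'
#' For each probe: fits the full random-intercept model on M values
#' (fixed effects: exposure, sex, disease, age by default) and the
#' reduced model without the main effect, runs the likelihood-ratio
#' test, BH-adjusts p across the converged probe family, computes the
#' per-condition delta-beta against the control (mean beta difference)
#' and, optionally, Dunnett-adjusted contrasts. A probe is significant
#' when `q < exposure_fdr` and the largest per-contrast `|delta_beta|`
#' exceeds `exposure_delta_beta`. Non-converged probes are excluded
#' from the FDR family with a logged count.
#'
#' @param object a [BetaSet] from a crossover design
#'   (`participant_id`, `exposure` populated).
#' @param mainEffect the fixed effect tested by LRT (`"exposure"` or
#'   `"disease"` for the asthma mirror).
#' @param covariates additional fixed effects.
#' @param posthoc compute Dunnett contrasts per probe (only meaningful
#'   for `mainEffect = "exposure"`).
#' @param control control exposure level.
#' @param config an [analysisConfig()].
#' @return data.frame with `probe_id, lrt_stat, lrt_df, p, q,
#'   delta_beta_<condition>..., padj_<condition>... (if requested),
#'   max_abs_delta_beta, significant, converged`.
#' @export
exposureAnalysis <- function(object, mainEffect = "exposure",
                             covariates = c("sex", "disease", "age"),
                             posthoc = (mainEffect == "exposure"),
                             control = "FA+S",
                             config = analysisConfig()) {
  ss <- sampleSheet(object)
  m <- mValues(object, epsilon = config$beta_clip_epsilon)
  b <- betaValues(object)
  covariates <- setdiff(covariates, mainEffect)
  fixedFull <- c(mainEffect, covariates)
  ## per-level delta-beta of the tested main effect vs its control
  ## level (raw group mean differences)
  groups <- as.character(ss[[mainEffect]])
  ctrlLevel <- if (mainEffect == "exposure") control
  else {
    ref <- unname(.REF_LEVELS[mainEffect])
    if (!is.na(ref) && ref %in% groups) ref
    else sort(unique(groups[!is.na(groups)]))[1]
  }
  conds <- if (mainEffect == "exposure")
    intersect(setdiff(.EXPOSURE_LEVELS, ctrlLevel), groups)
  else setdiff(unique(groups[!is.na(groups)]), ctrlLevel)
  if (!ctrlLevel %in% groups)
    stop("control level absent: ", ctrlLevel)
  ctrlIdx <- which(groups == ctrlLevel)
  db <- sapply(conds, function(cd)
    rowMeans(b[, groups == cd, drop = FALSE]) -
      rowMeans(b[, ctrlIdx, drop = FALSE]))
  if (is.null(dim(db))) db <- matrix(db, nrow = 1)

  nP <- nrow(m)
  out <- data.frame(probe_id = rownames(m), lrt_stat = NA_real_,
                    lrt_df = NA_integer_, p = NA_real_,
                    converged = FALSE, stringsAsFactors = FALSE)
  padj <- if (posthoc)
    matrix(NA_real_, nP, length(conds),
           dimnames = list(NULL, paste0("padj_", conds))) else NULL
  ## template fits, re-used via refit() for speed: the design is the
  ## same for every probe, only the response changes (M values are
  ## always finite, so the complete-case row set is probe-invariant)
  tmplF <- tmplR <- NULL
  for (i in seq_len(nP)) {
    if (is.null(tmplF)) {
      fitF <- try(fitLmm(m[i, ], ss, fixed = fixedFull), silent = TRUE)
      fitR <- try(fitLmm(m[i, ], ss, fixed = covariates),
                  silent = TRUE)
      if (!inherits(fitF, "try-error")) tmplF <- fitF
      if (!inherits(fitR, "try-error")) tmplR <- fitR
    } else if (nrow(tmplF$fit@frame) == ncol(m) &&
               nrow(tmplR$fit@frame) == ncol(m)) {
      fitF <- try(suppressMessages(suppressWarnings(
        .lmmSummary(lme4::refit(tmplF$fit, m[i, ]), tmplF$fixed))),
        silent = TRUE)
      fitR <- try(suppressMessages(suppressWarnings(
        .lmmSummary(lme4::refit(tmplR$fit, m[i, ]), tmplR$fixed))),
        silent = TRUE)
    } else {
      ## rows were dropped by complete-case filtering: fit afresh
      fitF <- try(fitLmm(m[i, ], ss, fixed = fixedFull), silent = TRUE)
      fitR <- try(fitLmm(m[i, ], ss, fixed = covariates),
                  silent = TRUE)
    }
    if (inherits(fitF, "try-error") || inherits(fitR, "try-error") ||
        !fitF$converged || !fitR$converged) next
    lrt <- lrtMainEffect(fitF, fitR)
    out$lrt_stat[i] <- lrt$stat
    out$lrt_df[i] <- lrt$df
    out$p[i] <- lrt$p
    out$converged[i] <- TRUE
    if (posthoc && "exposure" %in% fitF$fixed) {
      ph <- try(posthocVsControl(fitF, control = control),
                silent = TRUE)
      if (!inherits(ph, "try-error")) {
        idx <- match(paste0("padj_", sub(" - .*$", "", ph$contrast)),
                     colnames(padj))
        padj[i, idx[!is.na(idx)]] <- ph$p_adjusted[!is.na(idx)]
      }
    }
  }
  nBad <- sum(!out$converged)
  if (nBad) .log(nBad, " probe(s) excluded (model did not converge)")
  out$q <- NA_real_
  out$q[out$converged] <- bhFdr(out$p[out$converged])
  colnames(db) <- paste0("delta_beta_", conds)
  out <- cbind(out, db)
  if (posthoc) out <- cbind(out, padj)
  out$max_abs_delta_beta <- apply(abs(db), 1, max)
  exposureSignificance(out, config)
}

#' Apply the exposure dual significance rule
#'
#' `significant` iff `q < exposure_fdr` and the largest per-contrast
#' `|delta_beta|` against the control exceeds `exposure_delta_beta`.
#'
#' @param results data.frame with `q` and `max_abs_delta_beta` (or
#'   `delta_beta_*` columns).
#' @param config an [analysisConfig()].
#' @return `results` with the `significant` column set.
#' @export
exposureSignificance <- function(results, config = analysisConfig()) {
  if (!"max_abs_delta_beta" %in% colnames(results)) {
    dbc <- grep("^delta_beta_", colnames(results), value = TRUE)
    if (!length(dbc)) stop("no delta_beta columns present")
    results$max_abs_delta_beta <-
      apply(abs(results[, dbc, drop = FALSE]), 1, max)
  }
  results$significant <- !is.na(results$q) &
    results$q < config$exposure_fdr &
    results$max_abs_delta_beta > config$exposure_delta_beta
  results
}
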
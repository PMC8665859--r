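# Synthetic methylation-array generator with known ground truth.
#
# Beta values are drawn from a mean/precision-parameterised Beta
# distribution, beta ~ Beta(mu*phi, (1-mu)*phi): the natural noise
# model for array methylation fractions (support [0,1], variance
# mu(1-mu)/(phi+1) shrinking toward the boundaries, as on real
# arrays). Sex effects are injected on the beta scale so the recorded
# truth is directly comparable to estimated delta-beta; exposure,
# batch and participant effects are injected on the M scale, where the
# corresponding models operate.

#' Simulation settings
#'
#' Collects every knob of the synthetic generators. Defaults emulate a
#' mid-sized candidate-gene cohort: 50 samples per sex, bimodal probe
#' baselines (70% lowly methylated around beta 0.1, 30% highly
#' methylated around 0.85), Beta-noise precision `beta_precision = 100`
#' (per-sample sd about 0.03 at beta 0.1), a 10% sex-affected probe
#' fraction at |delta-beta| 0.05, X-linked genes whose female signal is
#' the active/inactive-X composite (active-X mean 0.05; inactive-X
#' promoter mean 0.80 for genes subject to XCI, 0.05 for escape genes),
#' and a 12-participant four-condition crossover with participant
#' intercept sd 0.5 and residual sd 0.2 on the M scale.
#'
#' @param n_male,n_female samples per sex (per tissue).
#' @param n_tissues number of tissue replicates of the cohort (same
#'   probe truth across tissues).
#' @param n_autosomal_probes autosomal probe count.
#' @param fraction_sex_affected fraction of autosomal probes given a
#'   sex effect.
#' @param sex_delta_beta target |male mean - female mean| on the beta
#'   scale at affected probes (random sign per probe).
#' @param beta_precision Beta-distribution precision phi (> 2).
#' @param baseline_mix_prop,baseline_means,baseline_precision bimodal
#'   baseline mixture: probability of the low component and the two
#'   component means, with the Beta precision used to draw per-probe
#'   baselines around them.
#' @param n_x_genes number of X-linked genes.
#' @param x_promoter_probes,x_body_probes probes per X gene by feature.
#' @param xci_escape_fraction fraction of X genes escaping XCI.
#' @param xi_subject_mean,xi_escape_mean inactive-X mean beta by XCI
#'   state.
#' @param xa_mean active-X (and male X) mean beta.
#' @param n_participants crossover participants (each receives all four
#'   exposure conditions once).
#' @param sigma_u participant random-intercept sd, M scale.
#' @param sigma_e residual sd of the crossover model, M scale.
#' @param exposure_effect M-scale shift at exposure-affected probes.
#' @param exposure_affected_fraction fraction of probes affected.
#' @param exposure_condition condition carrying the effect.
#' @param asthma_fraction fraction of crossover participants with an
#'   asthma diagnosis.
#' @param covid_affected_fraction fraction of autosomal probes with a
#'   COVID-status effect.
#' @param covid_delta_male,covid_delta_female beta-scale
#'   positive-minus-negative shift within each sex at affected probes.
#' @param covid_positive_fraction fraction of samples COVID-positive.
#' @param n_batches,batch_sd batch count and M-scale batch offset sd.
#' @param detection_fail_fraction,low_bead_fraction fractions of cells
#'   injected with failing detection p-values (> 0.01) or low bead
#'   counts (< 3); companions are only emitted when a fraction is > 0
#'   or `emit_qc = TRUE`.
#' @param emit_qc force emission of detection-p and bead-count assays.
#' @param age_range uniform age range (years).
#' @param n_genes,n_affected_genes,expr_lfc,expr_sd,expr_mean_range
#'   expression generator: gene count, sex-affected gene count,
#'   male-minus-female log2 fold change, residual sd, range of gene
#'   mean log2 expression.
#' @param seed master RNG seed; named substreams are derived from it so
#'   each component (sample covariates, probe effects, noise) has its
#'   own stream.
#' @return a validated `SimConfig` list.
#' @export
simConfig <- function(n_male = 50, n_female = 50, n_tissues = 1,
                      n_autosomal_probes = 1000,
                      fraction_sex_affected = 0.1,
                      sex_delta_beta = 0.05,
                      beta_precision = 100,
                      baseline_mix_prop = 0.7,
                      baseline_means = c(low = 0.1, high = 0.85),
                      baseline_precision = 20,
                      n_x_genes = 0,
                      x_promoter_probes = 4, x_body_probes = 4,
                      xci_escape_fraction = 0.5,
                      xi_subject_mean = 0.80, xi_escape_mean = 0.05,
                      xa_mean = 0.05,
                      n_participants = 12,
                      sigma_u = 0.5, sigma_e = 0.2,
                      exposure_effect = 0.3,
                      exposure_affected_fraction = 0.05,
                      exposure_condition = "PDDE+A",
                      asthma_fraction = 0.3,
                      covid_affected_fraction = 0,
                      covid_delta_male = 0, covid_delta_female = 0,
                      covid_positive_fraction = 0.5,
                      n_batches = 1, batch_sd = 0,
                      detection_fail_fraction = 0,
                      low_bead_fraction = 0,
                      emit_qc = FALSE,
                      age_range = c(20, 60),
                      n_genes = 2000, n_affected_genes = 50,
                      expr_lfc = -0.5, expr_sd = 0.3,
                      expr_mean_range = c(4, 10),
                      seed = 1L) {
  cfg <- as.list(environment())
  fr <- c(fraction_sex_affected, xci_escape_fraction,
          exposure_affected_fraction, asthma_fraction,
          covid_affected_fraction, covid_positive_fraction,
          detection_fail_fraction, low_bead_fraction,
          baseline_mix_prop)
  if (any(fr < 0 | fr > 1)) stop("all fractions must lie in [0,1]")
  if (beta_precision <= 2) stop("beta_precision must exceed 2")
  if (any(baseline_means <= 0 | baseline_means >= 1) ||
      any(c(xi_subject_mean, xi_escape_mean, xa_mean) <= 0) ||
      any(c(xi_subject_mean, xi_escape_mean, xa_mean) >= 1))
    stop("all means must lie in (0,1)")
  if (!exposure_condition %in% .EXPOSURE_LEVELS)
    stop("unknown exposure_condition")
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "SimConfig")
}

## draw from Beta(mu*phi, (1-mu)*phi), guarding mu into (0,1)
.rbetaMP <- function(n, mu, phi) {
  mu <- .clip(mu, 1e-4, 1 - 1e-4)
  rbeta(n, mu * phi, (1 - mu) * phi)
}

## clip mean into the simulator's admissible band, warning when an
## injected effect pushed it outside
.clipMu <- function(mu, what) {
  out <- .clip(mu, 0.001, 0.999)
  n <- sum(out != mu)
  if (n) .log(sprintf("%d %s mean(s) clipped into (0.001, 0.999)",
                      n, what))
  out
}

#' Simulate a methylation cohort with sex, XCI and COVID structure
#'
#' Draws `beta[i,j] ~ Beta(mu[i,j]*phi, (1-mu[i,j])*phi)`. Autosomal
#' probe means are the bimodal baseline plus, at affected probes, a
#' beta-scale sex effect of configured magnitude and random sign
#' (male mean minus female mean equals the signed delta). X-linked
#' probe means follow the composite-signal model: males show the
#' active-X mean; females show the average of the active-X mean and the
#' gene's inactive-X mean, which is set by its XCI state. Batch offsets
#' (if any) are added on the M scale and back-transformed. Ground truth
#' is stored in `rowData()` columns prefixed `truth_`.
#'
#' @param config a [simConfig()] object.
#' @return a [BetaSet] with annotation, sample sheet and embedded truth.
#' @examples
#' bs <- simulateMethylation(simConfig(n_male = 5, n_female = 5,
#'                                     n_autosomal_probes = 20, seed = 7))
#' dim(bs)
#' @export
simulateMethylation <- function(config = simConfig()) {
  stopifnot(is(config, "SimConfig"))
  cf <- config

  ## ---- probe universe -------------------------------------------------
  nA <- cf$n_autosomal_probes
  nXperGene <- cf$x_promoter_probes + cf$x_body_probes
  nX <- cf$n_x_genes * nXperGene
  probes <- .withSubstream(cf$seed, "probes", {
    auto_ids <- sprintf("cg%07d", seq_len(nA))
    comp <- rbinom(nA, 1, 1 - cf$baseline_mix_prop)  # 1 = high mode
    mu0 <- ifelse(comp == 1,
                  .rbetaMP(nA, cf$baseline_means[["high"]],
                           cf$baseline_precision),
                  .rbetaMP(nA, cf$baseline_means[["low"]],
                           cf$baseline_precision))
    nAffect <- round(cf$fraction_sex_affected * nA)
    affected <- sample(nA, nAffect)
    sign <- integer(nA)
    sign[affected] <- sample(c(-1L, 1L), nAffect, replace = TRUE)
    covAffect <- sample(nA, round(cf$covid_affected_fraction * nA))
    covid <- logical(nA); covid[covAffect] <- TRUE

    anno <- data.frame(
      probe_id = auto_ids,
      chrom = as.character(sample(1:22, nA, replace = TRUE)),
      pos = sample.int(1e8, nA),
      genes = sprintf("AG%05d", ceiling(seq_len(nA) / 4)),
      feature = sample(.FEATURE_LEVELS, nA, replace = TRUE),
      dist_to_tss = sample(-5000:5000, nA, replace = TRUE),
      promoter_density = "none",
      platform_450k = TRUE, platform_epic = TRUE,
      stringsAsFactors = FALSE)
    anno$promoter_density[anno$feature == "promoter"] <-
      sample(c("HC", "IC", "LC"),
             sum(anno$feature == "promoter"), replace = TRUE)
    list(anno = anno, mu0 = mu0, sign = sign, covid = covid)
  })

  xinfo <- NULL
  if (cf$n_x_genes > 0) {
    xinfo <- .withSubstream(cf$seed, "xgenes", {
      genes <- sprintf("XG%03d", seq_len(cf$n_x_genes))
      nEsc <- round(cf$xci_escape_fraction * cf$n_x_genes)
      state <- rep("subject", cf$n_x_genes)
      state[sample(cf$n_x_genes, nEsc)] <- "escape"
      xi <- ifelse(state == "escape", cf$xi_escape_mean,
                   cf$xi_subject_mean)
      tss <- sort(sample.int(1.5e8, cf$n_x_genes))
      anno <- do.call(rbind, lapply(seq_len(cf$n_x_genes), function(g) {
        np <- cf$x_promoter_probes; nb <- cf$x_body_probes
        data.frame(
          probe_id = sprintf("cgX%03d_%02d", g, seq_len(np + nb)),
          chrom = "X",
          pos = tss[g] + c(seq(-400, 100, length.out = np),
                           seq(2000, 20000, length.out = nb)),
          genes = genes[g],
          feature = rep(c("promoter", "body"), c(np, nb)),
          dist_to_tss = c(seq(-400, 100, length.out = np),
                          seq(2000, 20000, length.out = nb)),
          promoter_density = rep(c("HC", "none"), c(np, nb)),
          platform_450k = TRUE, platform_epic = TRUE,
          stringsAsFactors = FALSE)
      }))
      list(genes = genes, state = state, xi = xi, anno = anno)
    })
  }

  ## ---- samples --------------------------------------------------------
  nPerTissue <- cf$n_male + cf$n_female
  nS <- nPerTissue * cf$n_tissues
  samples <- .withSubstream(cf$seed, "samples", {
    sex <- rep(rep(c("M", "F"), c(cf$n_male, cf$n_female)),
               cf$n_tissues)
    tissue <- rep(sprintf("tissue%02d", seq_len(cf$n_tissues)),
                  each = nPerTissue)
    covid <- ifelse(runif(nS) < cf$covid_positive_fraction,
                    "positive", "negative")
    data.frame(
      sample_id = sprintf("S%04d", seq_len(nS)),
      participant_id = NA_character_,
      sex = sex,
      age = round(runif(nS, cf$age_range[1], cf$age_range[2]), 1),
      tissue = tissue,
      disease = "none",
      exposure = NA_character_,
      covid_status = covid,
      batch = sprintf("batch%02d",
                      sample.int(cf$n_batches, nS, replace = TRUE)),
      stringsAsFactors = FALSE)
  })

  ## ---- mean matrix ----------------------------------------------------
  isM <- samples$sex == "M"
  isPos <- samples$covid_status == "positive"
  half <- cf$sex_delta_beta / 2
  muM <- .clipMu(probes$mu0 + probes$sign * half, "male autosomal")
  muF <- .clipMu(probes$mu0 - probes$sign * half, "female autosomal")
  mu <- matrix(0, nA + nX, nS)
  mu[seq_len(nA), isM] <- muM
  mu[seq_len(nA), !isM] <- muF
  if (cf$covid_affected_fraction > 0) {
    for (j in which(isPos)) {
      d <- if (isM[j]) cf$covid_delta_male else cf$covid_delta_female
      mu[seq_len(nA), j][probes$covid] <-
        .clip(mu[seq_len(nA), j][probes$covid] + d, 0.001, 0.999)
    }
  }
  anno <- probes$anno
  truth <- data.frame(
    truth_effect = ifelse(probes$sign != 0, "sex", "null"),
    truth_delta_beta = muM - muF,
    truth_mu_male = muM,
    truth_mu_female = muF,
    truth_covid = probes$covid,
    truth_xci = NA_character_,
    truth_xi_mean = NA_real_,
    stringsAsFactors = FALSE)
  if (nX > 0) {
    geneIdx <- rep(seq_len(cf$n_x_genes), each = nXperGene)
    xiMean <- xinfo$xi[geneIdx]
    muXM <- rep(cf$xa_mean, nX)
    muXF <- (cf$xa_mean + xiMean) / 2     # composite female signal
    mu[nA + seq_len(nX), isM] <- muXM
    mu[nA + seq_len(nX), !isM] <- muXF
    anno <- rbind(anno, xinfo$anno)
    truth <- rbind(truth, data.frame(
      truth_effect = "x_linked",
      truth_delta_beta = muXM - muXF,
      truth_mu_male = muXM,
      truth_mu_female = muXF,
      truth_covid = FALSE,
      truth_xci = xinfo$state[geneIdx],
      truth_xi_mean = xiMean,
      stringsAsFactors = FALSE))
  }

  if (cf$batch_sd > 0) {
    offs <- .withSubstream(cf$seed, "batch",
                           rnorm(cf$n_batches, 0, cf$batch_sd))
    bix <- as.integer(factor(samples$batch,
                             levels = sprintf("batch%02d",
                                              seq_len(cf$n_batches))))
    m <- betaToM(mu)
    mu <- mToBeta(sweep(m, 2, offs[bix], "+"))
  }

  beta <- .withSubstream(cf$seed, "noise", {
    matrix(.rbetaMP(length(mu), mu, cf$beta_precision),
           nrow(mu), ncol(mu))
  })
  rownames(beta) <- anno$probe_id
  colnames(beta) <- samples$sample_id

  det <- bead <- NULL
  if (cf$emit_qc || cf$detection_fail_fraction > 0 ||
      cf$low_bead_fraction > 0) {
    qc <- .withSubstream(cf$seed, "qc", {
      det <- matrix(runif(length(beta), 0, 0.005),
                    nrow(beta), ncol(beta), dimnames = dimnames(beta))
      nf <- round(cf$detection_fail_fraction * length(det))
      if (nf) det[sample(length(det), nf)] <- runif(nf, 0.02, 0.9)
      bead <- matrix(rpois(length(beta), 12) + 3L,
                     nrow(beta), ncol(beta), dimnames = dimnames(beta))
      nl <- round(cf$low_bead_fraction * length(bead))
      if (nl) bead[sample(length(bead), nl)] <-
          sample(0:2, nl, replace = TRUE)
      list(det = det, bead = bead)
    })
    det <- qc$det; bead <- qc$bead
  }

  bs <- BetaSet(beta, sampleSheet = samples,
                probeAnnotation = cbind(anno, truth),
                detectionP = det, beadCount = bead)
  metadata(bs)$simConfig <- cf
  bs
}

#' Simulate a four-condition crossover exposure study
#'
#' Every participant contributes one sample under each of the four
#' exposure conditions (FA+S, FA+A, DE+A, PDDE+A). On the M scale,
#' `M[probe, sample] = baseline + u[participant] + effect * I(condition
#' affected) + noise`, with participant intercepts
#' `u ~ N(0, sigma_u^2)` and residual `N(0, sigma_e^2)`; values are
#' back-transformed to beta. Exposure effects hit a configured probe
#' fraction in `exposure_condition` only. Per-sample participant
#' intercepts are recorded as `truth_intercept` in `colData()`.
#'
#' @param config a [simConfig()] object.
#' @return a [BetaSet] of `4 * n_participants` samples.
#' @export
simulateCrossover <- function(config = simConfig()) {
  stopifnot(is(config, "SimConfig"))
  cf <- config
  nP <- cf$n_participants
  if (nP < 3) stop("need at least 3 participants")
  nA <- cf$n_autosomal_probes

  parts <- .withSubstream(cf$seed, "participants", {
    data.frame(
      participant_id = sprintf("P%03d", seq_len(nP)),
      sex = sample(rep(c("M", "F"), length.out = nP)),
      age = round(runif(nP, cf$age_range[1], cf$age_range[2]), 1),
      disease = ifelse(runif(nP) < cf$asthma_fraction, "asthma",
                       "none"),
      u = rnorm(nP, 0, cf$sigma_u),
      stringsAsFactors = FALSE)
  })
  cond <- rep(.EXPOSURE_LEVELS, nP)
  pidx <- rep(seq_len(nP), each = 4)
  samples <- data.frame(
    sample_id = sprintf("%s_%s", parts$participant_id[pidx],
                        gsub("\\+", "", cond)),
    participant_id = parts$participant_id[pidx],
    sex = parts$sex[pidx],
    age = parts$age[pidx],
    tissue = "BAL",
    disease = parts$disease[pidx],
    exposure = cond,
    covid_status = NA_character_,
    batch = NA_character_,
    truth_intercept = parts$u[pidx],
    stringsAsFactors = FALSE)

  pr <- .withSubstream(cf$seed, "probes", {
    comp <- rbinom(nA, 1, 1 - cf$baseline_mix_prop)
    mu0 <- ifelse(comp == 1,
                  .rbetaMP(nA, cf$baseline_means[["high"]],
                           cf$baseline_precision),
                  .rbetaMP(nA, cf$baseline_means[["low"]],
                           cf$baseline_precision))
    eff <- numeric(nA)
    idx <- sample(nA, round(cf$exposure_affected_fraction * nA))
    eff[idx] <- cf$exposure_effect
    list(mu0 = mu0, eff = eff)
  })
  base_m <- betaToM(pr$mu0)

  m <- .withSubstream(cf$seed, "noise", {
    nSamp <- nrow(samples)
    mm <- matrix(base_m, nA, nSamp)
    mm <- sweep(mm, 2, samples$truth_intercept, "+")
    hit <- samples$exposure == cf$exposure_condition
    mm[, hit] <- mm[, hit] + pr$eff
    mm + matrix(rnorm(nA * nSamp, 0, cf$sigma_e), nA, nSamp)
  })
  beta <- mToBeta(m)
  rownames(beta) <- sprintf("cg%07d", seq_len(nA))
  colnames(beta) <- samples$sample_id

  anno <- data.frame(
    probe_id = rownames(beta),
    chrom = as.character(sample(1:22, nA, replace = TRUE)),
    pos = seq_len(nA) * 1000L,
    genes = sprintf("AG%05d", ceiling(seq_len(nA) / 4)),
    feature = "body", dist_to_tss = 5000L,
    promoter_density = "none",
    platform_450k = TRUE, platform_epic = TRUE,
    truth_exposure_effect = pr$eff,
    truth_exposure_condition = ifelse(pr$eff != 0,
                                      cf$exposure_condition, NA),
    stringsAsFactors = FALSE)
  bs <- BetaSet(beta, sampleSheet = samples, probeAnnotation = anno)
  metadata(bs)$simConfig <- cf
  bs
}

#' Simulate a log2 expression matrix with sex effects
#'
#' Gene means are uniform over `expr_mean_range`; a configured subset
#' of genes receives a male-minus-female log2 fold change (males
#' shifted `+lfc/2`, females `-lfc/2`); Gaussian noise with sd
#' `expr_sd` is added. Truth (affected flag and signed LFC) is stored
#' in `rowData()`.
#'
#' @param config a [simConfig()] object.
#' @return a `SummarizedExperiment` with assay `log2expr`.
#' @export
simulateExpression <- function(config = simConfig()) {
  stopifnot(is(config, "SimConfig"))
  cf <- config
  nG <- cf$n_genes
  nS <- cf$n_male + cf$n_female
  genes <- .withSubstream(cf$seed, "expr_genes", {
    mu <- runif(nG, cf$expr_mean_range[1], cf$expr_mean_range[2])
    lfc <- numeric(nG)
    lfc[sample(nG, min(cf$n_affected_genes, nG))] <- cf$expr_lfc
    list(mu = mu, lfc = lfc)
  })
  sex <- rep(c("M", "F"), c(cf$n_male, cf$n_female))
  expr <- .withSubstream(cf$seed, "expr_noise", {
    shift <- outer(genes$lfc / 2, ifelse(sex == "M", 1, -1))
    matrix(genes$mu, nG, nS) + shift +
      matrix(rnorm(nG * nS, 0, cf$expr_sd), nG, nS)
  })
  rownames(expr) <- sprintf("G%05d", seq_len(nG))
  colnames(expr) <- sprintf("E%04d", seq_len(nS))
  SummarizedExperiment(
    assays = list(log2expr = expr),
    colData = DataFrame(sample_id = colnames(expr), sex = sex,
                        row.names = colnames(expr)),
    rowData = DataFrame(gene = rownames(expr),
                        truth_affected = genes$lfc != 0,
                        truth_lfc = genes$lfc,
                        row.names = rownames(expr)))
}
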
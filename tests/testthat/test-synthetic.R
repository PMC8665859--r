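# The generators: determinism, injected structure, convergence to the
# configured means.

test_that("simulation is deterministic given the seed", {
  cfg <- simConfig(n_male = 8, n_female = 8, n_autosomal_probes = 50,
                   n_x_genes = 2, emit_qc = TRUE, seed = 11)
  a <- simulateMethylation(cfg)
  b <- simulateMethylation(cfg)
  expect_identical(betaValues(a), betaValues(b))
  expect_identical(detectionP(a), detectionP(b))
  c1 <- simulateCrossover(simConfig(n_autosomal_probes = 20, seed = 4))
  c2 <- simulateCrossover(simConfig(n_autosomal_probes = 20, seed = 4))
  expect_identical(betaValues(c1), betaValues(c2))
  e1 <- simulateExpression(simConfig(n_genes = 30, seed = 4))
  e2 <- simulateExpression(simConfig(n_genes = 30, seed = 4))
  expect_identical(SummarizedExperiment::assay(e1),
                   SummarizedExperiment::assay(e2))
})

test_that("null simulation shows no sex difference", {
  bs <- simulateMethylation(simConfig(n_male = 50, n_female = 50,
                                      n_autosomal_probes = 300,
                                      fraction_sex_affected = 0,
                                      beta_precision = 100, seed = 21))
  d <- deltaBeta(bs)
  expect_lt(mean(abs(d)), 0.01)
})

test_that("X-linked composite signal has the stated arithmetic", {
  bs <- simulateMethylation(simConfig(
    n_male = 60, n_female = 60, n_autosomal_probes = 10,
    n_x_genes = 1, xci_escape_fraction = 0, xi_subject_mean = 0.80,
    xa_mean = 0.05, beta_precision = 200, seed = 31))
  an <- probeAnnotation(bs)
  prom <- an$probe_id[an$chrom == "X" & an$feature == "promoter"]
  # truth records the composite female mean (Xa + Xi)/2
  expect_equal(unique(an$truth_mu_female[an$chrom == "X"]), 0.425)
  expect_equal(unique(an$truth_mu_male[an$chrom == "X"]), 0.05)
  ss <- sampleSheet(bs)
  b <- betaValues(bs)[prom, , drop = FALSE]
  expect_equal(mean(b[, ss$sex == "F"]), 0.425, tolerance = 0.01)
  expect_equal(mean(b[, ss$sex == "M"]), 0.05, tolerance = 0.01)
})

test_that("escape genes with Xa = Xi show no sex difference", {
  bs <- simulateMethylation(simConfig(
    n_male = 50, n_female = 50, n_autosomal_probes = 10,
    n_x_genes = 4, xci_escape_fraction = 1, xi_escape_mean = 0.05,
    xa_mean = 0.05, beta_precision = 100, seed = 32))
  an <- probeAnnotation(bs)
  xsel <- an$chrom == "X"
  d <- deltaBeta(bs)[xsel]
  expect_lt(max(abs(d)), 0.02)
})

test_that("per-probe means converge to the configured mu", {
  bs <- simulateMethylation(simConfig(n_male = 60, n_female = 60,
                                      n_autosomal_probes = 400,
                                      fraction_sex_affected = 0.2,
                                      beta_precision = 100, seed = 33))
  an <- probeAnnotation(bs)
  ss <- sampleSheet(bs)
  b <- betaValues(bs)
  set.seed(1)
  idx <- sample(nrow(b), 100)
  for (sx in c("M", "F")) {
    cols <- ss$sex == sx
    mu <- if (sx == "M") an$truth_mu_male else an$truth_mu_female
    emp <- rowMeans(b[idx, cols, drop = FALSE])
    sdv <- apply(b[idx, cols, drop = FALSE], 1, sd)
    bound <- 3 * sdv / sqrt(sum(cols)) + 1e-6
    expect_true(all(abs(emp - mu[idx]) < pmax(bound, 0.02)))
  }
  expect_true(all(b >= 0 & b <= 1))
})

test_that("crossover bookkeeping and effect injection are correct", {
  cfg <- simConfig(n_autosomal_probes = 50, n_participants = 12,
                   exposure_affected_fraction = 0.1,
                   exposure_effect = 0.3, sigma_u = 0.5,
                   sigma_e = 0.2, seed = 41)
  bs <- simulateCrossover(cfg)
  ss <- sampleSheet(bs)
  expect_equal(ncol(bs), 48L)
  expect_true(all(table(ss$participant_id) == 4))
  expect_true(all(table(ss$participant_id, ss$exposure) == 1))

  # injected M-scale shift recovered at larger n
  cfgBig <- simConfig(n_autosomal_probes = 40, n_participants = 60,
                      exposure_affected_fraction = 0.5,
                      exposure_effect = 0.3, sigma_u = 0.3,
                      sigma_e = 0.2, seed = 42)
  bb <- simulateCrossover(cfgBig)
  sb <- sampleSheet(bb)
  m <- mValues(bb)
  eff <- probeAnnotation(bb)$truth_exposure_effect
  hit <- which(eff != 0)
  dm <- rowMeans(m[hit, sb$exposure == "PDDE+A", drop = FALSE]) -
    rowMeans(m[hit, sb$exposure == "FA+S", drop = FALSE])
  expect_equal(mean(dm), 0.3, tolerance = 0.05)
})

test_that("crossover with sigma_u = 0 has no participant component", {
  bs <- simulateCrossover(simConfig(n_autosomal_probes = 30,
                                    n_participants = 20, sigma_u = 0,
                                    exposure_affected_fraction = 0,
                                    sigma_e = 0.3, seed = 43))
  ss <- sampleSheet(bs)
  m <- mValues(bs)
  # between-participant variance of participant means should be about
  # sigma_e^2 / 4 (pure noise), i.e. the intraclass correlation ~ 0;
  # compare pooled within- vs between-participant mean squares
  f <- factor(ss$participant_id)
  ratios <- apply(m, 1, function(y) {
    aovt <- anova(lm(y ~ f))
    aovt$`Mean Sq`[1] / aovt$`Mean Sq`[2]
  })
  expect_equal(mean(ratios), 1, tolerance = 0.35)
  expect_error(simulateCrossover(simConfig(n_participants = 2)),
               "participants")
})

test_that("expression generator injects the configured sex LFC", {
  se <- simulateExpression(simConfig(n_male = 30, n_female = 30,
                                     n_genes = 500,
                                     n_affected_genes = 50,
                                     expr_lfc = -0.5, expr_sd = 0.3,
                                     seed = 51))
  expr <- SummarizedExperiment::assay(se)
  sex <- SummarizedExperiment::colData(se)$sex
  truth <- SummarizedExperiment::rowData(se)
  lfcHat <- rowMeans(expr[, sex == "M"]) - rowMeans(expr[, sex == "F"])
  aff <- truth$truth_affected
  expect_lt(abs(mean(lfcHat[aff]) - (-0.5)), 0.04)
  expect_true(all(abs(lfcHat[aff] - (-0.5)) < 0.3))
  expect_lt(mean(abs(lfcHat[!aff])), 0.08)
})

test_that("simulated truth serialises alongside the data", {
  bs <- simulateMethylation(simConfig(n_male = 4, n_female = 4,
                                      n_autosomal_probes = 20,
                                      seed = 61))
  tr <- simTruth(bs)
  expect_equal(nrow(tr$probes), 20)
  expect_true(all(c("truth_effect", "truth_delta_beta") %in%
                    colnames(tr$probes)))
  stem <- tempfile()
  writeSimTruth(bs, stem)
  back <- read.delim(paste0(stem, "_probes.tsv"))
  expect_equal(back$truth_delta_beta, tr$probes$truth_delta_beta,
               tolerance = 1e-9)
})
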
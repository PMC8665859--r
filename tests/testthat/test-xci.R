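# Inactive-X estimation, promoter classes, XCI status rules,
# male-X vs female-inactive-X differential methylation.

test_that("inactive-X estimate follows 2*betaF - maleMean, clamped", {
  maleB <- rbind(c(0.10, 0.10), c(0.20, 0.20), c(0.07, 0.07))
  femB <- rbind(c(0.60, 0.60), c(0.45, 0.45), c(0.07, 0.07))
  bs <- mkXGeneSet(maleB, femB)
  xi <- estimateInactiveX(bs)
  xb <- xiBeta(xi)
  expect_equal(unname(xb[1, ]), c(1.0, 1.0))   # 1.10 clamped to 1
  expect_equal(unname(xb[2, ]), c(0.70, 0.70))
  expect_equal(unname(xb[3, ]), c(0.07, 0.07)) # identity when equal
  expect_equal(unname(maleReference(xi)), c(0.10, 0.20, 0.07))
  expect_true(all(xb >= 0 & xb <= 1))
})

test_that("the estimate is monotone in female beta and male reference", {
  set.seed(201)
  bf <- sort(runif(50))
  r <- 0.3
  xi <- pmin(pmax(2 * bf - r, 0), 1)
  expect_true(all(diff(xi) >= 0))
  rs <- sort(runif(50))
  xi2 <- pmin(pmax(2 * 0.5 - rs, 0), 1)
  expect_true(all(diff(xi2) <= 0))
})

test_that("estimator needs males, females and X probes", {
  maleB <- rbind(c(0.1, 0.1)); femB <- rbind(c(0.5, 0.5))
  bs <- mkXGeneSet(maleB, femB)
  onlyF <- bs[, sampleSheet(bs)$sex == "F"]
  expect_error(estimateInactiveX(onlyF), "no male")
  auto <- BetaSet(mkBeta(runif(4), 2, 2),
                  sampleSheet = data.frame(
                    sample_id = c("s01", "s02"), sex = c("M", "F")),
                  probeAnnotation = data.frame(
                    probe_id = c("cg001", "cg002"), chrom = "2",
                    pos = 1:2))
  expect_error(estimateInactiveX(auto), "no X-chromosome")
})

test_that("promoter probe sets and density classes are resolved", {
  an <- data.frame(
    probe_id = sprintf("p%d", 1:7),
    chrom = "X", pos = 1:7,
    genes = c("G1", "G1", "G1", "G1", "G2", "G2", "G3;G1"),
    feature = c("promoter", "promoter", "promoter", "promoter",
                "promoter", "body", "body"),
    dist_to_tss = c(-100L, -50L, 10L, 50L, -10L, 4000L, 9000L),
    promoter_density = c("HC", "HC", "HC", "HC", "LC", "none", "none"))
  g1 <- promoterProbeSet("G1", an)
  expect_equal(g1$promoter_class, "HC")
  expect_equal(g1$probes, sprintf("p%d", 1:4))
  # LC-only promoter cannot support a call
  expect_equal(promoterProbeSet("G2", an)$promoter_class,
               "none_evaluable")
  # body-only gene likewise
  expect_equal(promoterProbeSet("G3", an)$promoter_class,
               "none_evaluable")
  expect_error(promoterProbeSet("G9", an), "not present")
  # a probe inside the TSS window counts even without a promoter flag
  an2 <- an; an2$feature <- "5'UTR"; an2$dist_to_tss <- -800L
  expect_equal(promoterProbeSet("G1", an2)$promoter_class, "HC")
})

test_that("XCI rules fire in the documented order", {
  cfg <- analysisConfig()
  # escape: both sexes < 15% methylated
  bs <- mkXGeneSet(mkBeta(0.06, 2, 5), mkBeta(0.09, 2, 5))
  ps <- list(probes = rownames(bs), promoter_class = "HC")
  out <- classifyXci("GENE1", bs, ps)
  expect_equal(out$status, "escape")
  expect_equal(out$rule_fired, "both_sexes_low_beta")

  # subject: delta > 0.10 with significant promoter probes
  set.seed(202)
  bs2 <- mkXGeneSet(mkBeta(rnorm(10, .08, .01), 2, 5),
                    mkBeta(rnorm(10, .42, .01), 2, 5))
  q <- setNames(c(1e-8, 1e-8), rownames(bs2))
  out2 <- classifyXci("GENE1", bs2, ps, qvalues = q)
  expect_equal(out2$status, "subject")
  expect_equal(out2$rule_fired, "delta_gt_threshold_and_fdr")

  # escape via overlapping per-sample ranges
  bs3 <- mkXGeneSet(mkBeta(c(.28, .32, .30, .29, .33, .31, .27, .35,
                             .30, .31), 2, 5),
                    mkBeta(c(.31, .36, .33, .30, .35, .34, .32, .37,
                             .33, .34), 2, 5))
  out3 <- classifyXci("GENE1", bs3, ps)
  expect_equal(out3$status, "escape")
  expect_equal(out3$rule_fired, "overlapping_ranges")

  # escape via disjoint ranges but small delta
  bs4 <- mkXGeneSet(mkBeta(rep(c(.30, .301), 5), 2, 5),
                    mkBeta(rep(c(.35, .351), 5), 2, 5))
  out4 <- classifyXci("GENE1", bs4, ps)
  expect_equal(out4$status, "escape")
  expect_equal(out4$rule_fired, "disjoint_small_delta")

  # indeterminate: large delta but no FDR support
  bs5 <- mkXGeneSet(mkBeta(rep(c(.20, .201), 5), 2, 5),
                    mkBeta(rep(c(.45, .451), 5), 2, 5))
  out5 <- classifyXci("GENE1", bs5, ps,
                      qvalues = setNames(c(.5, .5), rownames(bs5)))
  expect_equal(out5$status, "not_evaluable")
  expect_equal(out5$rule_fired, "indeterminate")

  # no HC/IC promoter short-circuits
  out6 <- classifyXci("GENE1", bs5,
                      list(probes = character(),
                           promoter_class = "none_evaluable"))
  expect_equal(out6$status, "not_evaluable")
  expect_equal(out6$rule_fired, "no_hc_ic_promoter")
})

test_that("exactly one rule fires per classified gene", {
  bs <- simulateMethylation(simConfig(n_male = 20, n_female = 20,
                                      n_autosomal_probes = 10,
                                      n_x_genes = 12,
                                      beta_precision = 100,
                                      seed = 203))
  calls <- xciAnalysis(bs)
  known <- c("delta_gt_threshold_and_fdr", "both_sexes_low_beta",
             "overlapping_ranges", "disjoint_small_delta",
             "indeterminate", "no_hc_ic_promoter")
  expect_true(all(calls$rule_fired %in% known))
  expect_equal(nrow(calls), 12)
  # determinism
  calls2 <- xciAnalysis(bs)
  expect_identical(calls, calls2)
})

test_that("male-X vs inactive-X modelling recovers subject genes", {
  bs <- simulateMethylation(simConfig(
    n_male = 30, n_female = 30, n_autosomal_probes = 10,
    n_x_genes = 2, xci_escape_fraction = 0,
    xi_subject_mean = 0.80, xa_mean = 0.05,
    beta_precision = 100, seed = 204))
  xi <- estimateInactiveX(bs)
  res <- xDiffMeth(xi, bs)
  # truth: Xi mean 0.80 vs male 0.05 -> delta ~ +0.75 everywhere
  expect_equal(mean(res$delta_beta), 0.75, tolerance = 0.03)
  expect_true(all(res$significant))

  # identical inputs give zero delta and nothing significant
  ssM <- sampleSheet(bs)$sex == "M"
  bMale <- betaValues(bs)[rownames(xiBeta(xi)), ssM, drop = FALSE]
  xiSame <- new("InactiveXMatrix", xiBeta = bMale,
                referenceMaleMean = rowMeans(bMale))
  resSame <- xDiffMeth(xiSame, bs)
  expect_true(all(abs(resSame$delta_beta) < 1e-12))
  expect_false(any(resSame$significant))
})

test_that("the X-linked dual rule needs |delta| > 0.10", {
  df <- data.frame(q = c(0.001, 0.001), delta_beta = c(0.08, 0.12))
  out <- callSignificant(df, 0.05, 0.10)
  expect_equal(out$significant, c(FALSE, TRUE))
})

test_that("Xi estimate converges to the true inactive-X mean", {
  bs <- simulateMethylation(simConfig(
    n_male = 50, n_female = 50, n_autosomal_probes = 10,
    n_x_genes = 8, xci_escape_fraction = 0.5,
    beta_precision = 400, seed = 205))
  xi <- estimateInactiveX(bs)
  an <- probeAnnotation(bs)
  xan <- an[an$chrom == "X", ]
  est <- rowMeans(xiBeta(xi))[xan$probe_id]
  byGene <- tapply(est - xan$truth_xi_mean, xan$genes, mean)
  expect_lt(max(abs(byGene)), 0.02)
})
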
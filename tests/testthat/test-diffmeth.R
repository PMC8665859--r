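# Per-probe linear models, empirical-Bayes moderation, BH-FDR,
# delta-beta, the dual rule, concordance and stratified comparisons.

test_that("per-probe OLS matches the lm() oracle", {
  set.seed(101)
  n <- 6
  ss <- data.frame(sex = c("F", "M", "F", "M", "F", "M"),
                   age = c(30, 40, 25, 55, 60, 35))
  m <- matrix(rnorm(5 * n), 5, n,
              dimnames = list(sprintf("cg%d", 1:5), sprintf("s%d", 1:n)))
  res <- fitProbeLm(m, ss, mainEffect = "sex", covariates = "age",
                    moderate = FALSE)
  for (i in 1:5) {
    or <- summary(lm(m[i, ] ~ factor(ss$sex, levels = c("F", "M")) +
                       ss$age))$coefficients
    expect_equal(res$coef[i], or[2, 1], tolerance = 1e-10)
    expect_equal(res$se[i], or[2, 2], tolerance = 1e-10)
    expect_equal(res$p[i], or[2, 4], tolerance = 1e-10)
  }
  expect_equal(res$df, rep(3, 5))
})

test_that("equal group means give zero coefficient and p = 1", {
  ss <- data.frame(sex = rep(c("F", "M"), each = 3))
  m <- matrix(rep(c(1, 2, 3, 1, 2, 3), 2), 2, 6, byrow = TRUE,
              dimnames = list(c("a", "b"), sprintf("s%d", 1:6)))
  res <- fitProbeLm(m, ss, mainEffect = "sex", moderate = FALSE)
  expect_equal(res$coef, c(0, 0))
  expect_equal(res$p, c(1, 1))
})

test_that("rank-deficient designs and missing covariates are handled", {
  ss <- data.frame(sex = rep(c("F", "M"), 5),
                   dup = rep(c("F", "M"), 5),
                   age = c(NA, 21:29))
  m <- matrix(rnorm(30), 3, 10,
              dimnames = list(letters[1:3], sprintf("s%d", 1:10)))
  expect_error(fitProbeLm(m, ss, mainEffect = "sex",
                          covariates = "dup"), "rank deficient")
  expect_message(fitProbeLm(m, ss, mainEffect = "sex",
                            covariates = "age"), "1 sample")
})

test_that("moderation with d0 = 0 reproduces the unmoderated fit", {
  set.seed(102)
  ss <- data.frame(sex = rep(c("F", "M"), each = 10))
  m <- matrix(rnorm(50 * 20), 50, 20,
              dimnames = list(sprintf("cg%d", 1:50), NULL))
  un <- fitProbeLm(m, ss, moderate = FALSE)
  z0 <- fitProbeLm(m, ss, moderate = TRUE, priorDf = 0)
  expect_equal(z0$t, un$t, tolerance = 1e-12)
  expect_equal(z0$p, un$p, tolerance = 1e-12)
})

test_that("variances collapse to the prior as d0 grows", {
  set.seed(103)
  s2 <- rchisq(200, 5) / 5
  at6 <- moderateVariances(s2, 18, priorDf = 1e6)
  expect_lt(max(abs(at6$s2_post / at6$s2_prior - 1)), 1e-3)
  at12 <- moderateVariances(s2, 18, priorDf = 1e12)
  expect_lt(max(abs(at12$s2_post / at12$s2_prior - 1)), 1e-9)
})

test_that("moderated fit agrees with the limma cross-check", {
  skip_if_not_installed("limma")
  set.seed(104)
  ss <- data.frame(sex = rep(c("F", "M"), each = 12))
  m <- matrix(rnorm(300 * 24, sd = rep(sqrt(rchisq(300, 8) / 8), 24)),
              300, 24, dimnames = list(sprintf("cg%d", 1:300), NULL))
  mine <- fitProbeLm(m, ss, moderate = TRUE)
  design <- model.matrix(~ factor(ss$sex, levels = c("F", "M")))
  fit <- limma::eBayes(limma::lmFit(m, design))
  expect_equal(unname(mine$t), unname(fit$t[, 2]), tolerance = 1e-6)
  expect_equal(unname(mine$p), unname(fit$p.value[, 2]),
               tolerance = 1e-6)
  mv <- moderateVariances(fit$sigma^2, fit$df.residual[1])
  expect_equal(mv$df_prior, fit$df.prior, tolerance = 1e-4)
  expect_equal(mv$s2_prior, fit$s2.prior, tolerance = 1e-6)
})

test_that("bhFdr implements the step-up and matches p.adjust", {
  expect_equal(bhFdr(c(0.001, 0.01, 0.02, 0.04)),
               c(0.004, 0.02, 4 * 0.02 / 3, 0.04))
  expect_equal(bhFdr(rep(1, 5)), rep(1, 5))
  expect_equal(bhFdr(0.03), 0.03)
  expect_error(bhFdr(c(0.1, 1.3)), "outside")
  expect_equal(bhFdr(c(0.01, NA, 0.5)),
               c(p.adjust(c(0.01, 0.5), "BH")[1], NA,
                 p.adjust(c(0.01, 0.5), "BH")[2]))
  set.seed(105)
  for (i in 1:1000) {
    p <- runif(sample(1:200, 1))^sample(1:3, 1)
    expect_equal(bhFdr(p), p.adjust(p, method = "BH"),
                 tolerance = 1e-12)
  }
})

test_that("deltaBeta follows the male-minus-female convention", {
  b <- rbind(cg1 = c(0.30, 0.40, 0.10, 0.20))
  colnames(b) <- sprintf("s%d", 1:4)
  expect_equal(unname(deltaBeta(b, groups = c("M", "M", "F", "F"))),
               0.20)
  expect_equal(unname(deltaBeta(b, groups = c("F", "F", "M", "M"))),
               -0.20)
  bb <- rbind(cg1 = c(0.3, 0.3, 0.3, 0.3))
  colnames(bb) <- sprintf("s%d", 1:4)
  expect_equal(unname(deltaBeta(bb, groups = c("M", "M", "F", "F"))), 0)
  expect_error(deltaBeta(b, groups = rep("M", 4)), "empty group")
  expect_equal(unname(deltaBeta(b, groups = c("case", "case", "ctl", "ctl"),
                                convention = "case_minus_control",
                                case = "case", control = "ctl")), 0.20)
})

test_that("the dual rule requires both thresholds", {
  df <- data.frame(q = c(0.01, 0.01, 0.06),
                   delta_beta = c(0.06, 0.04, 0.10))
  out <- callSignificant(df, 0.05, 0.05)
  expect_equal(out$significant, c(TRUE, FALSE, FALSE))
})

test_that("injected sex effects are recovered with the dual rule", {
  bs <- simulateMethylation(simConfig(n_male = 30, n_female = 30,
                                      n_autosomal_probes = 500,
                                      fraction_sex_affected = 0.2,
                                      sex_delta_beta = 0.10,
                                      beta_precision = 100,
                                      seed = 106))
  res <- dmAnalysis(bs, covariates = "age")
  tr <- simTruth(bs)$probes
  aff <- tr$truth_effect == "sex"
  # signed recovery: align estimate with the true sign
  err <- res$delta_beta[aff] - tr$truth_delta_beta[aff]
  expect_lt(abs(mean(err)), 0.01)
  expect_gt(mean(res$significant[aff]), 0.8)
  expect_lt(mean(res$significant[!aff]), 0.05)
})

test_that("cross-tissue concordance requires shared sign", {
  mk <- function(db, sig) data.frame(probe_id = c("a", "b", "c"),
                                     delta_beta = db, significant = sig)
  res <- list(t1 = mk(c(-0.06, 0.08, 0.02), c(TRUE, TRUE, FALSE)),
              t2 = mk(c(-0.07, -0.09, 0.01), c(TRUE, TRUE, FALSE)),
              t3 = mk(c(-0.08, 0.07, 0.03), c(TRUE, FALSE, TRUE)))
  out <- crossTissueConcordance(res, k = 3)
  expect_equal(out$concordant, c(TRUE, FALSE, FALSE))
  # probe b: significant twice with opposite signs -> excluded even at k=2
  out2 <- crossTissueConcordance(res, k = 2)
  expect_false(out2$concordant[out2$probe_id == "b"])
  # k = 1 is the union of significant probes (sign trivially shared
  # only where a single tissue is significant)
  out1 <- crossTissueConcordance(res[1:2], k = 1)
  expect_equal(out1$concordant, c(TRUE, FALSE, FALSE))
  expect_error(crossTissueConcordance(res, k = 4), "exceeds")
})

test_that("age stratification uses left-closed bins and reports gaps", {
  set.seed(107)
  nm <- 75; nf <- 75      # 15 per sex in each of the five bins
  ages <- rep(rep(c(10, 25, 35, 45, 55), each = 15), 2)
  ages[1] <- 20            # boundary: belongs to [20,30)
  b <- mkBeta(runif(20 * 150), 20, 150)
  eff <- 0.08
  sex <- rep(c("M", "F"), c(nm, nf))
  b[, sex == "M"] <- .5 + eff / 2 +
    matrix(rnorm(20 * nm, 0, 0.015), 20)
  b[, sex == "F"] <- .5 - eff / 2 +
    matrix(rnorm(20 * nf, 0, 0.015), 20)
  bs <- BetaSet(pmin(pmax(b, 0), 1),
                sampleSheet = data.frame(sample_id = colnames(b),
                                         sex = sex, age = ages))
  out <- ageStratifiedDelta(bs)
  expect_true(all(out$counts$evaluated))
  expect_true(all(abs(out$delta[, out$counts$evaluated] - eff) < 0.02))
  # the age-20 sample landed in [20,30)
  expect_equal(as.character(cut(20, c(0, 20, 30, 40, 50, Inf),
                                right = FALSE)), "[20,30)")
  # a bin with one sex only is reported missing with counts
  ssOnlyM <- data.frame(sample_id = colnames(b), sex = sex,
                        age = ifelse(sex == "M", 10, 40))
  bs2 <- BetaSet(pmin(pmax(b, 0), 1), sampleSheet = ssOnlyM)
  expect_message(out2 <- ageStratifiedDelta(bs2), "skipped")
  expect_true(all(is.na(out2$delta[, "[0,20)"])))
  expect_equal(out2$counts$n_female[1], 0)
})

test_that("sex-stratified status comparison flags per-sex effects", {
  bs <- simulateMethylation(simConfig(
    n_male = 30, n_female = 30, n_autosomal_probes = 100,
    fraction_sex_affected = 0, covid_affected_fraction = 0.1,
    covid_delta_male = 0.06, covid_delta_female = 0,
    beta_precision = 200, seed = 108))
  tr <- simTruth(bs)$probes
  res <- sexStratifiedStatus(bs)
  aff <- tr$probe_id[tr$truth_covid]
  mrows <- res[res$sex == "M" & res$probe_id %in% aff, ]
  frows <- res[res$sex == "F" & res$probe_id %in% aff, ]
  expect_gt(mean(mrows$flagged), 0.7)
  expect_lt(mean(frows$flagged), 0.2)
  # dual rule: small delta is reported but not flagged even if p small
  nullrows <- res[!res$probe_id %in% aff, ]
  expect_true(all(abs(nullrows$delta_beta[nullrows$flagged]) > 0.05))
})

test_that("identical status groups give zero delta and p = 1", {
  b <- mkBeta(rep(c(.2, .4, .6), 8), 3, 8)
  ss <- data.frame(sample_id = colnames(b),
                   sex = rep(c("M", "F"), each = 4),
                   covid_status = rep(c("positive", "positive",
                                        "negative", "negative"), 2))
  # per sex: case betas equal control betas exactly
  bs <- BetaSet(b, sampleSheet = ss)
  res <- sexStratifiedStatus(bs)
  expect_true(all(res$delta_beta == 0))
  expect_true(all(is.na(res$p) | res$p == 1))
  # a stratum with < 2 per status is reported missing
  ss2 <- ss; ss2$covid_status[1:4] <- c("positive", rep("negative", 3))
  res2 <- suppressMessages(
    sexStratifiedStatus(BetaSet(b, sampleSheet = ss2)))
  expect_true(all(is.na(res2$p[res2$sex == "M"])))
})
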
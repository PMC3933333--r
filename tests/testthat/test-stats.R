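test_that("Levene statistic matches the independent implementation", {
  x <- c(1, 2, 3, 4); y <- c(10, 20, 30, 40)
  lev <- leveneW(x, y)
  ref <- car::leveneTest(c(x, y), factor(rep(1:2, each = 4)),
                         center = mean)
  expect_equal(lev$W, ref[1, "F value"], tolerance = 1e-10)
  expect_equal(lev$p, ref[1, "Pr(>F)"], tolerance = 1e-10)
  # degenerate groups: equal spread -> W = 0
  expect_identical(leveneW(c(5, 5, 5), c(9, 9, 9))$W, 0)
  withr::with_seed(2, for (i in 1:20) {
    p <- leveneW(rnorm(6), rnorm(8, sd = runif(1, 0.2, 5)))$p
    expect_gte(p, 0); expect_lte(p, 1)
  })
})

test_that("Levene-gated comparison reproduces the case-table brain-weight contrast", {
  t1 <- loadTable1()
  bwM <- t1$brain_weight_g[t1$sex == "M"]
  bwM <- bwM[!is.na(bwM)]
  bwF <- t1$brain_weight_g[t1$sex == "F"]
  cmp <- twoGroupCompare(bwM, bwF, labels = c("male", "female"))
  expect_equal(cmp@percentDifference, 13.5, tolerance = 0.005)
  expect_identical(cmp@flavor, "pooled_t")
  expect_equal(abs(cmp@t), 2.867, tolerance = 1e-3)
  expect_identical(cmp@df, 13)
  expect_match(cmp@label, "^male vs female")
})

test_that("identical samples compare as a null contrast; tiny groups error", {
  x <- c(3, 4, 5, 6)
  cmp <- twoGroupCompare(x, x)
  expect_equal(cmp@t, 0)
  expect_equal(cmp@percentDifference, 0)
  expect_error(twoGroupCompare(1, c(2, 3)),
               class = "stereoPC_insufficient_data")
})

test_that("equal weights reproduce the unweighted factorial fit", {
  sim <- simulateCohort(seed = 31)
  long <- defaultLongTable(sim)
  f1 <- weightedFactorialAnalysis(long, weights = "none")
  f2 <- weightedFactorialAnalysis(long, weights = rep(2, nrow(long)))
  expect_equal(f1@terms$F, f2@terms$F, tolerance = 1e-6)
  expect_setequal(f1@terms$term,
                  c("diagnosis", "sex", "region", "diagnosis:sex",
                    "diagnosis:region", "sex:region",
                    "diagnosis:sex:region"))
  expect_true(all(f1@terms$F >= 0))
})

test_that("an empty design cell is a singular-design error", {
  sim <- simulateCohort(seed = 32)
  long <- defaultLongTable(sim)
  long <- long[!(long$diagnosis == "control" & long$sex == "F"), ]
  expect_error(weightedFactorialAnalysis(long),
               class = "stereoPC_singular_design")
})

test_that("the brain-weight covariate drops cases missing it, with a note", {
  sim <- simulateCohort(seed = 33)
  long <- defaultLongTable(sim)
  long$brain_weight_g[long$case_id == long$case_id[1]] <- NA
  expect_message(f <- weightedFactorialAnalysis(long, weights = "volume",
                                                covariate = "brain_weight_g"),
                 "dropping")
  expect_identical(f@nCases, 15L)
  expect_true("brain_weight_g" %in% f@terms$term)
})

test_that("the factorial type-I error is controlled under the null", {
  spec <- defaultCohortSpec()
  spec@diagnosisEffect[] <- 1; spec@maleEffect <- 1
  spec@ageLogSlope <- 0; spec@bwGamma <- 0
  rej <- withr::with_seed(34, replicate(150, {
    long <- defaultLongTable(simulateCohort(spec))
    f <- weightedFactorialAnalysis(long, weights = "volume")
    f@terms$p[f@terms$term == "diagnosis"] < 0.05
  }))
  expect_lte(mean(rej), 0.05 + 3 * sqrt(0.05 * 0.95 / 150))
})

test_that("a planted all-region diagnosis effect is detected in most cohorts", {
  spec <- defaultCohortSpec()
  spec@diagnosisEffect[] <- 0.802; spec@maleEffect <- 1
  spec@ageLogSlope <- 0; spec@bwGamma <- 0
  ps <- withr::with_seed(35, replicate(120, {
    long <- defaultLongTable(simulateCohort(spec))
    f <- weightedFactorialAnalysis(long, weights = "volume")
    c(diag = f@terms$p[f@terms$term == "diagnosis"],
      int = f@terms$p[f@terms$term == "diagnosis:sex"])
  }))
  expect_gt(mean(ps["diag", ] < 0.05), 0.5)
  # interaction terms stay near the null rate
  expect_lte(mean(ps["int", ] < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 120))
})

test_that("BH step-up flags the right hypotheses", {
  r <- bhFdr(c(0.01, 0.02, 0.04), 0.05)
  expect_true(all(r$flags))
  expect_equal(r$cutoff, 0.04)
  # the four regional p-values: textbook BH flags none at q = 0.05 and
  # exactly the two smallest at q = 0.10
  p4 <- c(lobulesIV_VI = 0.512, crusI = 0.039, crusII = 0.032,
          lobuleX = 0.173)
  expect_false(any(bhFdr(p4, 0.05)$flags))
  expect_identical(unname(bhFdr(p4, 0.10)$flags),
                   c(FALSE, TRUE, TRUE, FALSE))
  expect_false(any(bhFdr(rep(1, 5), 0.05)$flags))
  expect_identical(bhFdr(numeric())$flags, logical())
})

test_that("BH flagging is monotone in the p-values", {
  withr::with_seed(36, for (i in 1:30) {
    p <- runif(8)
    f1 <- bhFdr(p, 0.1)$flags
    j <- sample(8, 1)
    p2 <- p; p2[j] <- p2[j] * runif(1)
    f2 <- bhFdr(p2, 0.1)$flags
    expect_true(all(f2[f1]))  # nothing flagged before becomes unflagged
  })
})

test_that("Spearman rho matches a brute-force rank computation", {
  x <- c(2.1, 5.3, 1.0, 8.8, 4.4, 9.9, 7.2)
  y <- c(3.0, 1.1, 6.5, 0.4, 2.2, 0.1, 1.9)
  byHand <- cor(rank(x), rank(y))
  r <- spearmanBootstrap(x, y, nBoot = 200, seed = 1)
  expect_equal(r@rho, byHand, tolerance = 1e-12)
  expect_lte(r@ciLow, r@rho); expect_gte(r@ciHigh, r@rho)
  # perfect monotone association and monotone-transform invariance
  expect_equal(spearmanBootstrap(1:6, c(2, 4, 5, 7, 8, 11), nBoot = 50,
                                 seed = 2)@rho, 1)
  expect_equal(spearmanBootstrap(exp(x), y, nBoot = 50, seed = 3)@rho,
               r@rho)
  expect_warning(cc <- spearmanBootstrap(rep(1, 5), y[1:5], nBoot = 50,
                                         seed = 4), "constant")
  expect_true(is.na(cc@rho))
})

test_that("observed power of the 2x2 interaction reproduces the reported value", {
  expect_lt(abs(interactionPower(0.36, 16) - 0.24), 0.005)
  expect_equal(interactionPower(0, 16), 0.05, tolerance = 1e-9)
  # strictly increasing in f and n
  f <- seq(0, 1, 0.1)
  expect_true(all(diff(sapply(f, interactionPower, nTotal = 16)) > 0))
  n <- c(8, 16, 32, 64)
  expect_true(all(diff(sapply(n, function(k)
    interactionPower(0.36, k))) > 0))
  expect_error(interactionPower(0.3, 4), class = "stereoPC_config")
})

test_that("the noncentral-F power matches the Monte-Carlo ANOVA oracle", {
  sim <- interactionPowerSim(0.36, 16, nrep = 20000, seed = 5)
  expect_lt(abs(sim - interactionPower(0.36, 16, ncp = "sample")), 0.02)
})

test_that("covariate adjustment: error paths and null behaviour", {
  withr::with_seed(6, {
    y <- rnorm(20); g <- rep(c("a", "b"), 10)
  })
  expect_error(covariateAdjustedComparison(y, g, rep(3, 20)),
               class = "stereoPC_config")
  # covariate unrelated to outcome: adjusted p close to unadjusted p
  dd <- withr::with_seed(7, replicate(100, {
    y <- rnorm(20); g <- rep(c("a", "b"), 10); cv <- rnorm(20)
    r <- covariateAdjustedComparison(y, g, cv)
    abs(r$adjusted$p - r$unadjusted@p)
  }))
  expect_lt(median(dd), 0.1)
})

test_that("a fully mediated group effect vanishes after adjustment", {
  rej <- withr::with_seed(8, replicate(150, {
    g <- rep(c(0, 1), each = 10)
    cv <- rnorm(20) + g * 2          # group shifts the covariate...
    y <- cv * 1.5 + rnorm(20, 0, 0.5)  # ...and y depends only on cv
    covariateAdjustedComparison(y, factor(g), cv)$adjusted$p < 0.05
  }))
  expect_lte(mean(rej), 0.05 + 3 * sqrt(0.05 * 0.95 / 150))
})

test_that("lobule X sex contrast is brain-weight mediated in default cohorts", {
  med <- withr::with_seed(9, t(replicate(60, {
    sim <- simulateCohort(defaultCohortSpec())
    p <- sim$profiles; d <- sim$densities
    lobx <- d[d$region == "lobuleX", ]
    lx <- lobx$measured[match(p$case_id, lobx$case_id)]
    aut <- p$diagnosis == "autism"
    r <- covariateAdjustedComparison(lx[aut], p$sex[aut],
                                     p$brain_weight_g[aut])
    cI <- d[d$region == "crusI", ]
    ci <- cI$measured[match(p$case_id, cI$case_id)]
    r2 <- covariateAdjustedComparison(ci, p$diagnosis, p$brain_weight_g)
    c(lobXun = r$unadjusted@p, lobXadj = r$adjusted$p,
      crusIun = r2$unadjusted@p, crusIadj = r2$adjusted$p)
  })))
  # adjustment erases the lobule X sex contrast...
  expect_gt(mean(med[, "lobXadj"] > med[, "lobXun"]), 0.7)
  expect_lt(median(med[, "lobXun"]), 0.05)
  expect_gt(median(med[, "lobXadj"]), 0.1)
  # ...but leaves the crus I diagnosis contrast essentially unchanged
  expect_lt(median(abs(med[, "crusIadj"] - med[, "crusIun"])), 0.05)
})

test_that("the full analysis battery runs and reports every piece", {
  sim <- simulateCohort(seed = 41)
  res <- suppressMessages(analyzeCohort(sim, seed = 2))
  expect_length(res$factorial, 4)
  expect_identical(res$factorial$test1@weighting, "WLS by regional volume")
  expect_setequal(names(res$regional),
                  c("crusI", "crusII", "lobulesIV_VI", "lobuleX"))
  expect_true(all(vapply(res$regional, function(x)
    x@flavor %in% c("pooled_t", "welch_t"), TRUE)))
  expect_true(all(!is.na(vapply(res$regional, function(x) x@passedFdr,
                                TRUE))))
  expect_s4_class(res$correlations$crusI_crusII, "CorrelationResult")
})
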
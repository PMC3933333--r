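test_that("the packaged case table loads and matches the published rows", {
  t1 <- loadTable1()
  expect_identical(nrow(t1), 16L)
  b6403 <- t1[t1$case_id == "B-6403", ]
  expect_identical(b6403$diagnosis, "autism")
  expect_identical(b6403$sex, "M")
  expect_identical(b6403$age_years, 7L)
  expect_identical(b6403$brain_weight_g, 1610L)
  expect_equal(b6403$pmi_h, 25)
  expect_identical(sum(t1$diagnosis == "autism" & t1$sex == "F"), 3L)
  expect_identical(sum(!is.na(t1$brain_weight_g)), 15L)
  expect_true(is.na(t1$brain_weight_g[t1$case_id == "UMB-1576"]))
})

test_that("simulated demographics match the study composition", {
  spec <- defaultCohortSpec()
  prof <- generateDemographics(spec, seed = 1)
  tab <- table(prof$diagnosis, prof$sex)
  expect_identical(unname(tab["autism", "M"]), 5L)
  expect_identical(unname(tab["autism", "F"]), 3L)
  expect_identical(unname(tab["control", "M"]), 5L)
  expect_identical(unname(tab["control", "F"]), 3L)
  expect_identical(prof, generateDemographics(spec, seed = 1))
  expect_false(identical(prof, generateDemographics(spec, seed = 2)))
})

test_that("comorbidity rates match the planted 38% over many cohorts", {
  spec <- defaultCohortSpec()
  flags <- withr::with_seed(7, unlist(replicate(125, {
    p <- generateDemographics(spec)
    p$mr[p$diagnosis == "autism"]
  }, simplify = FALSE)))
  n <- length(flags)
  expect_identical(n, 1000L)
  expect_lt(abs(mean(flags) - 0.375), 3 * sqrt(0.375 * 0.625 / n))
})

test_that("with unit effects and zero noise every case sits at the regional baseline", {
  spec <- defaultCohortSpec()
  spec@diagnosisEffect[] <- 1; spec@maleEffect <- 1
  spec@ageLogSlope <- 0; spec@bwGamma <- 0
  spec@caseSd <- 0; spec@residSd <- 0
  prof <- generateDemographics(spec, seed = 3)
  truth <- generateCaseTruth(prof, spec, seed = 4)
  for (r in names(spec@baselineDensity))
    expect_equal(truth$trueDensity[truth$region == r],
                 rep(spec@baselineDensity[[r]], 16), tolerance = 1e-12)
})

test_that("the planted crus I effect is recovered as a density ratio", {
  spec <- defaultCohortSpec()
  ratios <- withr::with_seed(9, replicate(300, {
    prof <- generateDemographics(spec)
    truth <- generateCaseTruth(prof, spec)
    cI <- truth[truth$region == "crusI", ]
    d <- cI$trueDensity[match(prof$case_id, cI$case_id)]
    mean(d[prof$diagnosis == "autism"]) / mean(d[prof$diagnosis == "control"])
  }))
  # observed-contrast calibration: the raw ratio centres on 0.802
  expect_lt(abs(mean(ratios) - 0.802), 4 * sd(ratios) / sqrt(300) + 0.01)
})

test_that("truth generation requires brain weight", {
  spec <- defaultCohortSpec()
  prof <- generateDemographics(spec, seed = 5)
  prof$brain_weight_g[3] <- NA
  expect_error(generateCaseTruth(prof, spec), class = "stereoPC_config")
})

test_that("noise-free ADI-R scores decrease monotonically with lobule X density", {
  spec <- defaultCohortSpec(adirNoiseSd = 0)
  prof <- generateDemographics(spec, seed = 11)
  truth <- generateCaseTruth(prof, spec, seed = 12)
  prof2 <- generateAdirScores(prof, truth, spec, seed = 13)
  aut <- prof2$diagnosis == "autism" & !is.na(prof2$adir_q50)
  lobx <- truth[truth$region == "lobuleX", ]
  d <- lobx$trueDensity[match(prof2$case_id, lobx$case_id)]
  o <- order(d[aut])
  expect_true(all(diff(prof2$adir_q50[aut][o]) <= 0))
  expect_true(all(prof2$adir_q50[aut] %in% 0:3))
  # exactly one autism case flagged missing; controls all missing
  expect_identical(sum(prof2$diagnosis == "autism" & is.na(prof2$adir_q50)), 1L)
  expect_true(all(is.na(prof2$adir_q50[prof2$diagnosis == "control"])))
})

test_that("ADI-R generation refuses a cohort without autism cases", {
  spec <- defaultCohortSpec()
  prof <- generateDemographics(spec, seed = 14)
  ctl <- prof[prof$diagnosis == "control", ]
  truth <- generateCaseTruth(ctl, spec, seed = 15)
  expect_error(generateAdirScores(ctl, truth, spec),
               class = "stereoPC_domain")
})

test_that("fast surrogate measurement has the configured CV and is exact at CV 0", {
  spec <- defaultCohortSpec()
  truth <- data.frame(case_id = sprintf("c%d", 1:1000), region = "crusI",
                      trueDensity = 300)
  m <- measureCohort(truth, spec, "fast_surrogate", seed = 16)
  ratio <- m$measured / m$trueDensity
  expect_lt(abs(sd(ratio) / mean(ratio) - 0.053), 0.008)
  expect_lt(abs(mean(ratio) - 1), 0.01)
  spec0 <- spec; spec0@measurementCV <- 0
  m0 <- measureCohort(truth, spec0, "fast_surrogate", seed = 17)
  expect_equal(m0$measured, m0$trueDensity, tolerance = 1e-12)
})

test_that("full-pipeline measurement tracks the planted truth on a small region", {
  spec <- defaultCohortSpec()
  truth <- data.frame(case_id = "c1", region = "lobuleX",
                      trueDensity = 250)
  m <- withr::with_seed(18, t(replicate(12, unlist(
    measureCohort(truth, spec, "full_pipeline",
                  regionScale = 1)[, c("measured", "ce")]))))
  expect_lt(abs(mean(m[, "measured"]) / 250 - 1), 0.05)
  expect_true(all(m[, "ce"] < 0.1))
})

test_that("the full-pipeline resource guard trips on oversized requests", {
  spec <- defaultCohortSpec()
  truth <- data.frame(case_id = sprintf("c%d", 1:16), region = "crusI",
                      trueDensity = 277)
  expect_error(measureCohort(truth, spec, "full_pipeline", maxSomata = 1e5),
               class = "stereoPC_resource_guard")
})

test_that("cohort simulation is deterministic per seed at every stage", {
  s1 <- simulateCohort(seed = 21)
  s2 <- simulateCohort(seed = 21)
  s3 <- simulateCohort(seed = 22)
  expect_identical(s1$profiles, s2$profiles)
  expect_identical(s1$densities, s2$densities)
  expect_false(identical(s1$densities, s3$densities))
})
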
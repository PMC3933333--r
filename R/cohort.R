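#' Load the packaged postmortem case table
#'
#' Reads the packaged 16-case clinical table (8 autism, 8 control; 5 males
#' and 3 females each) with age, fresh brain weight (one control male
#' missing), postmortem interval and comorbidity annotations, and validates
#' its integrity against frozen structural checks.
#'
#' @return data.frame with one row per case.
#' @export
loadTable1 <- function() {
  path <- system.file("extdata", "table1_cases.csv", package = "stereoPC")
  df <- read.csv(path, stringsAsFactors = FALSE)
  okStructure <- nrow(df) == 16L &&
    sum(df$diagnosis == "autism" & df$sex == "F") == 3L &&
    sum(df$diagnosis == "autism" & df$sex == "M") == 5L &&
    sum(!is.na(df$brain_weight_g)) == 15L &&
    isTRUE(all.equal(sum(df$age_years), 377)) &&
    isTRUE(all.equal(sum(df$brain_weight_g, na.rm = TRUE), 21256)) &&
    isTRUE(all.equal(sum(df$pmi_h), 284.4))
  if (!okStructure)
    stopMsg("stereoPC_fixture_corruption",
            "packaged case table failed its integrity checks")
  df
}

.CohortRegions <- c("crusI", "crusII", "lobulesIV_VI", "lobuleX")

# cell-wise normal fit (mean, sd) of a column by diagnosis x sex
.cellFit <- function(df, col) {
  out <- list()
  for (dg in c("autism", "control")) for (sx in c("M", "F")) {
    v <- df[df$diagnosis == dg & df$sex == sx, col]
    v <- v[!is.na(v)]
    out[[paste0(dg, sx)]] <- c(mean = mean(v), sd = sd(v))
  }
  out
}

#' Default paper-calibrated cohort configuration
#'
#' Builds the packaged study conditions for the simulated 16-case cohort.
#' Demographics (age, brain weight, PMI) are normal fits to the packaged
#' case table, per diagnosis-by-sex cell. The density model is log-linear
#' and multiplicative; its direct coefficients are derived so that the
#' OBSERVED group contrasts of a simulated cohort centre on the published
#' effect sizes given the demographic structure (e.g. the raw male-female
#' contrast includes both the direct sex coefficient and the sex difference
#' in age):
#' \itemize{
#'   \item crus I and crus II autism/control density ratios 0.802 and 0.783
#'     (19.8\% and 21.7\% lower), lobules IV-VI mildly affected (0.94),
#'   \item overall male/female ratio 0.79 (21\% lower),
#'   \item the lobule X deficit of autism males is routed entirely through
#'     brain weight (elasticity calibrated so autism males sit 31.5\% below
#'     autism females),
#'   \item a common age slope reproducing the overall age-density
#'     correlation of about -0.39,
#'   \item case-level and regional residual noise sized to the reported
#'     between-case spread, with an elevated crus I-crus II residual
#'     correlation,
#'   \item fast-surrogate measurement CV equal to the survey's mean CE
#'     (0.053).
#' }
#'
#' @param crusCor residual crus I-crus II correlation (calibrated so the
#'   measured cross-case correlation centres on the published 0.832).
#' @param adirNoiseSd,adirThresholds latent-noise SD and cut points of the
#'   ordinal ADI-R eye-contact item link (calibrated so the measured
#'   Spearman correlation with lobule X density centres on -0.75).
#' @param lobXDirect optional direct multiplicative lobule X effect for
#'   autism males (1 = fully brain-weight-mediated, the default).
#' @return a [CohortSpec-class].
#' @export
defaultCohortSpec <- function(crusCor = 0.54, adirNoiseSd = 0.70,
                              adirThresholds = c(-0.85, -0.1, 0.75),
                              lobXDirect = 1.0) {
  t1 <- loadTable1()
  ages <- .cellFit(t1, "age_years")
  bws <- .cellFit(t1, "brain_weight_g")
  pmis <- c(mean = mean(t1$pmi_h), sd = sd(t1$pmi_h))
  cellSizes <- c(autismM = 5L, autismF = 3L, controlM = 5L, controlF = 3L)

  caseSd <- 0.10
  residSd <- 0.127
  measurementCV <- 0.053
  ageRef <- mean(t1$age_years)
  bwRef <- mean(t1$brain_weight_g, na.rm = TRUE)
  # age slope reproducing the overall age-density correlation (~ -0.39)
  sdLog <- sqrt(caseSd^2 + residSd^2 + measurementCV^2)
  ageSlope <- -0.39 * sdLog / sd(t1$age_years)

  # expected cell demographics of the generator
  ageA <- (5 * ages$autismM["mean"] + 3 * ages$autismF["mean"]) / 8
  ageC <- (5 * ages$controlM["mean"] + 3 * ages$controlF["mean"]) / 8
  ageM <- (ages$autismM["mean"] + ages$controlM["mean"]) / 2
  ageF <- (ages$autismF["mean"] + ages$controlF["mean"]) / 2
  elog <- function(f) unname(log(f["mean"]) - f["sd"]^2 / (2 * f["mean"]^2))

  # direct coefficients backing the observed contrast targets
  diagTarget <- c(crusI = 0.802, crusII = 0.783, lobulesIV_VI = 0.94,
                  lobuleX = 1.0)
  ageFacAC <- exp(ageSlope * (ageA - ageC))
  diagDirect <- diagTarget / ifelse(names(diagTarget) == "lobuleX", 1,
                                    unname(ageFacAC))
  maleDirect <- 0.79 / exp(ageSlope * (ageM - ageF))
  # lobule X brain-weight elasticity from the autism male-female target
  # (31.5% lower in autism males), fully mediated by default
  t9Target <- 1 - 0.315
  gamma <- (log(t9Target) - log(maleDirect) - log(lobXDirect) -
              ageSlope * (ages$autismM["mean"] - ages$autismF["mean"])) /
    (elog(bws$autismM) - elog(bws$autismF))
  diagDirect["lobuleX"] <- 1.0

  baseline <- setNames(.REGION_TABLE$density, .REGION_TABLE$region)
  vols <- setNames(.REGION_TABLE$xLen * .REGION_TABLE$yLen *
                     (1200 * round(.REGION_TABLE$zLen / 1200)) / UM3_PER_MM3,
                   .REGION_TABLE$region)

  new("CohortSpec", cellSizes = cellSizes,
      baselineDensity = baseline[.CohortRegions],
      regionalVolumeMm3 = vols[.CohortRegions],
      diagnosisEffect = diagDirect[.CohortRegions],
      maleEffect = unname(maleDirect), ageLogSlope = unname(ageSlope),
      ageRef = ageRef, bwGamma = unname(gamma), bwRef = bwRef,
      caseSd = caseSd, residSd = residSd, crusCor = crusCor,
      adirScale = 1, adirNoiseSd = adirNoiseSd,
      adirThresholds = adirThresholds, measurementCV = measurementCV,
      demographics = list(age = ages, bw = bws, pmi = pmis,
                          lobXDirect = lobXDirect),
      rates = list(mr = 0.375, epilepsy = 0.375, regression = 0.375))
}

.rtnorm <- function(n, mean, sd, lower) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x < lower)) x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

#' Generate simulated case demographics
#'
#' Draws a cohort of case profiles matching the packaged study's
#' composition: diagnosis-by-sex cell sizes, ages and brain weights from
#' sex- and diagnosis-specific normal fits to the case table, PMI from the
#' pooled fit, and comorbidity flags (MR, epilepsy, regression) at the
#' study's autism-group rates.
#'
#' @param spec a [CohortSpec-class].
#' @param seed optional RNG seed.
#' @return data.frame of case profiles.
#' @export
generateDemographics <- function(spec, seed = NULL) {
  withSeed(seed, {
    rows <- list()
    demo <- spec@demographics
    for (cell in names(spec@cellSizes)) {
      n <- spec@cellSizes[[cell]]
      dg <- if (startsWith(cell, "autism")) "autism" else "control"
      sx <- substr(cell, nchar(cell), nchar(cell))
      a <- demo$age[[cell]]
      b <- demo$bw[[cell]]
      rows[[cell]] <- data.frame(
        case_id = sprintf("sim-%s-%s-%d", substr(dg, 1, 3), sx, seq_len(n)),
        diagnosis = dg, sex = sx,
        age_years = round(.rtnorm(n, a["mean"], a["sd"], 2), 1),
        brain_weight_g = round(.rtnorm(n, b["mean"], b["sd"], 800)),
        pmi_h = round(.rtnorm(n, demo$pmi["mean"], demo$pmi["sd"], 1), 1),
        stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, rows)
    rownames(df) <- NULL
    aut <- df$diagnosis == "autism"
    df$mr <- df$epilepsy <- df$regression <- NA
    df$mr[aut] <- runif(sum(aut)) < spec@rates$mr
    df$epilepsy[aut] <- runif(sum(aut)) < spec@rates$epilepsy
    df$regression[aut] <- runif(sum(aut)) < spec@rates$regression
    df$adir_q50 <- NA_integer_
    df
  })
}

#' Generate planted per-region true densities for a cohort
#'
#' The log-linear density model: log D = log mu_r + autism * log a_r +
#' male * log g + beta_age (age - ageRef) + [lobule X] gamma log(BW/BWref)
#' + u_case + e_case_r, with e correlated between crus I and crus II. The
#' lobule X diagnosis effect enters only through the brain-weight path by
#' default (a gender-by-diagnosis structure mediated by tissue volume).
#'
#' @param profiles data.frame from [generateDemographics()] (needs
#'   diagnosis, sex, age_years, brain_weight_g).
#' @param spec a [CohortSpec-class].
#' @param seed optional RNG seed.
#' @return long data.frame: case_id, region, trueDensity (PC/mm^3).
#' @export
generateCaseTruth <- function(profiles, spec, seed = NULL) {
  if (any(is.na(profiles$brain_weight_g)))
    stopMsg("stereoPC_config",
            "brain weight must be present (or imputed) for the lobule X path")
  withSeed(seed, {
    n <- nrow(profiles)
    regions <- names(spec@baselineDensity)
    aut <- profiles$diagnosis == "autism"
    male <- profiles$sex == "M"
    u <- rnorm(n, 0, spec@caseSd)
    # residuals with the crus I-crus II correlation
    e <- matrix(rnorm(n * length(regions), 0, spec@residSd), n,
                dimnames = list(NULL, regions))
    if (all(c("crusI", "crusII") %in% regions)) {
      rho <- spec@crusCor
      z <- rnorm(n, 0, spec@residSd)
      e[, "crusII"] <- rho * e[, "crusI"] + sqrt(1 - rho^2) * z
    }
    lobXdir <- spec@demographics$lobXDirect %||% 1
    out <- lapply(regions, function(r) {
      lg <- log(spec@baselineDensity[[r]]) +
        aut * log(spec@diagnosisEffect[[r]]) +
        male * log(spec@maleEffect) +
        spec@ageLogSlope * (profiles$age_years - spec@ageRef) +
        u + e[, r]
      if (r == "lobuleX") {
        lg <- lg + spec@bwGamma *
          (log(profiles$brain_weight_g) - log(spec@bwRef)) +
          (aut & male) * log(lobXdir)
      }
      data.frame(case_id = profiles$case_id, region = r,
                 trueDensity = exp(lg), stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, out)
    rownames(df) <- NULL
    df
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate ordinal ADI-R eye-contact item scores
#'
#' For autism cases only: a latent impairment score is negatively and
#' monotonically linked to the case's true lobule X density (standardised
#' within the autism group) plus Gaussian noise, then cut into the ordinal
#' 0-3 item score (higher = more impaired eye contact). One autism case per
#' cohort is flagged as missing ADI-R data. Three ADI-R domain totals
#' (communication, social, repetitive behaviour) are generated as noisy
#' sums unrelated to density.
#'
#' @param profiles data.frame of case profiles.
#' @param truth data.frame from [generateCaseTruth()].
#' @param spec a [CohortSpec-class].
#' @param seed optional RNG seed.
#' @return `profiles` with adir_q50 (NA for controls and the flagged
#'   missing case) and domain-total columns.
#' @export
generateAdirScores <- function(profiles, truth, spec, seed = NULL) {
  aut <- profiles$diagnosis == "autism"
  if (!any(aut))
    stopMsg("stereoPC_domain", "ADI-R scores are generated for autism cases only")
  withSeed(seed, {
    lobx <- truth[truth$region == "lobuleX", ]
    ld <- log(lobx$trueDensity[match(profiles$case_id, lobx$case_id)])
    zsc <- -(ld - mean(ld[aut])) / max(sd(ld[aut]), 1e-12)
    latent <- spec@adirScale * zsc + rnorm(nrow(profiles), 0, spec@adirNoiseSd)
    score <- findInterval(latent, spec@adirThresholds)
    profiles$adir_q50 <- ifelse(aut, as.integer(score), NA_integer_)
    drop1 <- sample(which(aut), 1)
    profiles$adir_q50[drop1] <- NA_integer_
    for (dom in c("adir_communication", "adir_social", "adir_rrb"))
      profiles[[dom]] <- ifelse(aut, pmax(0, round(rnorm(nrow(profiles),
                                                         20, 4))), NA)
    profiles
  })
}

#' Measure a cohort's densities
#'
#' `fast_surrogate` (the desk-scale default) multiplies each true density
#' by mean-preserving lognormal noise with CV equal to the design's mean
#' Gundersen CE. `full_pipeline` builds a phantom per case and region (the
#' default region spec with its surface density rescaled to the case truth)
#' and runs the sectioning / disector / estimation pipeline.
#'
#' @param truth data.frame from [generateCaseTruth()].
#' @param spec a [CohortSpec-class].
#' @param mode "fast_surrogate" or "full_pipeline".
#' @param seed optional RNG seed.
#' @param regionScale phantom scale factor for full_pipeline mode.
#' @param maxSomata resource guard for full_pipeline: error if the expected
#'   total soma count across all phantoms exceeds this.
#' @return `truth` with columns measured (PC/mm^3) and ce.
#' @export
measureCohort <- function(truth, spec, mode = c("fast_surrogate",
                                                "full_pipeline"),
                          seed = NULL, regionScale = 1, maxSomata = 6e6) {
  mode <- match.arg(mode)
  withSeed(seed, {
    if (mode == "fast_surrogate") {
      cv <- spec@measurementCV
      sdlog <- sqrt(log(1 + cv^2))
      truth$measured <- truth$trueDensity *
        rlnorm(nrow(truth), -sdlog^2 / 2, sdlog)
      truth$ce <- cv
    } else {
      expected <- sum(vapply(seq_len(nrow(truth)), function(i) {
        row <- .REGION_TABLE[.REGION_TABLE$region == truth$region[i], ]
        truth$trueDensity[i] * row$xLen * row$yLen * row$zLen *
          regionScale^2 / UM3_PER_MM3
      }, 0))
      if (expected > maxSomata)
        stopMsg("stereoPC_resource_guard",
                "full pipeline would generate ~%.0f somata (> %g budget)",
                expected, maxSomata)
      truth$measured <- NA_real_
      truth$ce <- NA_real_
      for (i in seq_len(nrow(truth))) {
        rs <- defaultRegionSpec(truth$region[i], scale = regionScale,
                                rngSeed = sample.int(2^30, 1))
        rs@targetSurfaceDensity <- rs@targetSurfaceDensity *
          truth$trueDensity[i] /
          .REGION_TABLE$density[.REGION_TABLE$region == truth$region[i]]
        reg <- assembleRegion(rs)
        est <- estimateDensity(sampleRegion(reg))
        truth$measured[i] <- pcDensity(est)
        truth$ce[i] <- ceValue(est)
      }
    }
    truth
  })
}

#' Simulate one complete cohort
#'
#' demographics -> planted truths -> ADI-R scores -> measurement.
#'
#' @param spec a [CohortSpec-class] (default [defaultCohortSpec()]).
#' @param seed optional RNG seed.
#' @param mode measurement mode, see [measureCohort()].
#' @return list with `profiles` (case table) and `densities` (long table:
#'   case_id, region, trueDensity, measured, ce).
#' @export
simulateCohort <- function(spec = defaultCohortSpec(), seed = NULL,
                           mode = "fast_surrogate") {
  withSeed(seed, {
    prof <- generateDemographics(spec)
    truth <- generateCaseTruth(prof, spec)
    prof <- generateAdirScores(prof, truth, spec)
    dens <- measureCohort(truth, spec, mode)
    list(profiles = prof, densities = dens, spec = spec)
  })
}

.pctDiff <- function(ref, other) (mean(ref) - mean(other)) / mean(ref) * 100

#' Summary contrasts of one simulated cohort
#'
#' Computes the study's headline quantities from a simulated cohort's
#' measured densities: the volume-weighted overall autism deficit, the
#' regional crus I / crus II deficits, the overall male deficit, the two
#' lobule X contrasts, the crus I-crus II cross-case correlation of log
#' densities, and the Spearman correlation of lobule X density with the
#' ADI-R eye-contact item among autism cases with ADI-R data.
#'
#' @param sim result of [simulateCohort()].
#' @return named numeric vector (percent differences in %, correlations
#'   unitless).
#' @export
cohortContrasts <- function(sim) {
  prof <- sim$profiles
  dens <- sim$densities
  spec <- sim$spec
  wide <- do.call(cbind, lapply(names(spec@baselineDensity), function(r) {
    d <- dens[dens$region == r, ]
    setNames(data.frame(d$measured[match(prof$case_id, d$case_id)]), r)
  }))
  overall <- apply(wide, 1, function(v)
    overallWeightedDensity(setNames(v, colnames(wide)),
                           spec@regionalVolumeMm3))
  aut <- prof$diagnosis == "autism"
  male <- prof$sex == "M"
  autM <- aut & male; autF <- aut & !male
  c(overallDiagnosisPct = .pctDiff(overall[!aut], overall[aut]),
    crusIPct = .pctDiff(wide$crusI[!aut], wide$crusI[aut]),
    crusIIPct = .pctDiff(wide$crusII[!aut], wide$crusII[aut]),
    overallMalePct = .pctDiff(overall[!male], overall[male]),
    lobXAutismMalePct = .pctDiff(wide$lobuleX[autF], wide$lobuleX[autM]),
    lobXMaleDiagPct = .pctDiff(wide$lobuleX[!aut & male],
                               wide$lobuleX[autM]),
    crusCorr = cor(log(wide$crusI), log(wide$crusII)),
    adirSpearman = {
      ok <- aut & !is.na(prof$adir_q50)
      suppressWarnings(cor(wide$lobuleX[ok], prof$adir_q50[ok],
                           method = "spearman"))
    })
}
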
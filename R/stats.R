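#' Levene's test of equality of variances (two groups)
#'
#' Classical Levene statistic: a one-way ANOVA on absolute deviations from
#' the group centre (mean by default, median optionally).
#'
#' @param x,y numeric samples (n >= 2 each).
#' @param center "mean" (classical) or "median" (Brown-Forsythe).
#' @return list with W (the F statistic), df and p.
#' @export
leveneW <- function(x, y, center = c("mean", "median")) {
  center <- match.arg(center)
  stopifnot(length(x) >= 2, length(y) >= 2)
  cf <- if (center == "mean") mean else median
  zx <- abs(x - cf(x)); zy <- abs(y - cf(y))
  nx <- length(zx); ny <- length(zy); n <- nx + ny
  zbar <- mean(c(zx, zy))
  num <- (n - 2) * (nx * (mean(zx) - zbar)^2 + ny * (mean(zy) - zbar)^2)
  den <- sum((zx - mean(zx))^2) + sum((zy - mean(zy))^2)
  if (den <= 0) return(list(W = 0, df = c(1L, n - 2L), p = 1))
  W <- num / den
  list(W = W, df = c(1L, n - 2L), p = 1 - pf(W, 1, n - 2))
}

#' Levene-gated two-group comparison
#'
#' Runs Levene's test on the two samples; a pooled-variance t-test is used
#' when variances are compatible (Levene p >= alpha), Welch's t otherwise.
#' The percent difference is (mean_ref - mean_other) / mean_ref * 100, with
#' the reference being the larger-mean group (named first in the label).
#'
#' @param x,y numeric samples (n >= 2 each).
#' @param alpha gate level for Levene's test.
#' @param labels names of the two groups, in (x, y) order.
#' @return a [ComparisonResult-class].
#' @export
twoGroupCompare <- function(x, y, alpha = 0.05, labels = c("x", "y")) {
  if (length(x) < 2 || length(y) < 2)
    stopMsg("stereoPC_insufficient_data",
            "both groups need n >= 2 (got %d and %d)", length(x), length(y))
  lev <- leveneW(x, y)
  pooled <- lev$p >= alpha
  tt <- t.test(x, y, var.equal = pooled)
  if (mean(x) >= mean(y)) { ref <- x; oth <- y; lab <- labels
  } else { ref <- y; oth <- x; lab <- rev(labels) }
  new("ComparisonResult",
      label = sprintf("%s vs %s", lab[1], lab[2]),
      n = c(length(ref), length(oth)),
      flavor = if (pooled) "pooled_t" else "welch_t",
      t = unname(tt$statistic), df = unname(tt$parameter),
      p = tt$p.value,
      percentDifference = .pctDiff(ref, oth),
      passedFdr = NA)
}

#' Volume-weighted factorial mixed-model analysis of regional densities
#'
#' Fits the study's linear mixed model by maximum likelihood: fixed effects
#' diagnosis * gender * region (all interactions, type-III tests with sum
#' contrasts), a random intercept per case (clustering the four regional
#' measures of each case), optional brain-weight covariate, and optional
#' observation weights proportional to the regional volume (the WLS
#' correction, giving larger regions more influence).
#'
#' @param data data.frame with columns case_id, diagnosis, sex, region,
#'   logDensity, and regionalVolume if `weights = "volume"`; brain_weight_g
#'   if a covariate is requested.
#' @param weights "volume", "none", or a numeric vector.
#' @param covariate optional covariate column name (e.g. "brain_weight_g");
#'   cases missing it are dropped with a message.
#' @return a [FactorialResult-class].
#' @export
weightedFactorialAnalysis <- function(data, weights = c("volume", "none"),
                                      covariate = NULL) {
  if (is.character(weights)) weights <- match.arg(weights)
  need <- c("case_id", "diagnosis", "sex", "region", "logDensity")
  stopifnot(all(need %in% names(data)))
  if (!is.null(covariate)) {
    drop <- is.na(data[[covariate]])
    if (any(drop)) {
      lost <- unique(data$case_id[drop])
      message(sprintf("dropping %d case(s) missing %s: %s", length(lost),
                      covariate, paste(lost, collapse = ", ")))
      data <- data[!drop, ]
    }
  }
  tab <- table(data$diagnosis, data$sex)
  if (any(tab == 0))
    stopMsg("stereoPC_singular_design",
            "empty diagnosis x sex cell; the factorial design is singular")
  data$diagnosis <- factor(data$diagnosis)
  data$sex <- factor(data$sex)
  data$region <- factor(data$region)
  w <- switch(if (is.character(weights)) weights else "custom",
              volume = data$regionalVolume / mean(data$regionalVolume),
              none = rep(1, nrow(data)),
              custom = weights / mean(weights))
  fml <- if (is.null(covariate))
    logDensity ~ diagnosis * sex * region + (1 | case_id)
  else
    as.formula(paste("logDensity ~ diagnosis * sex * region +", covariate,
                     "+ (1 | case_id)"))
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  data$.w <- w
  fit <- lmerTest::lmer(fml, data = data, weights = .w, REML = FALSE)
  a <- suppressMessages(anova(fit, type = 3))
  terms <- data.frame(term = rownames(a), F = a[, "F value"],
                      df1 = a[, "NumDF"], df2 = a[, "DenDF"],
                      p = a[, "Pr(>F)"], row.names = NULL)
  new("FactorialResult", terms = terms,
      weighting = if (identical(weights, "volume"))
        "WLS by regional volume" else "unweighted",
      nCases = length(unique(data$case_id)))
}

#' Benjamini-Hochberg step-up false discovery rate control
#'
#' Flags the hypotheses with p <= p_(k*), where k* is the largest k with
#' p_(k) <= k q / m.
#'
#' @param p p-values in [0, 1].
#' @param q FDR level.
#' @return list: `flags` (logical, in input order), `cutoff` (the largest
#'   rejected p, or NA if none), `adjusted` (BH-adjusted p-values).
#' @export
bhFdr <- function(p, q = 0.05) {
  if (!length(p)) return(list(flags = logical(), cutoff = NA_real_,
                              adjusted = numeric()))
  stopifnot(all(p >= 0 & p <= 1))
  m <- length(p)
  o <- order(p)
  thr <- seq_len(m) * q / m
  pass <- p[o] <= thr
  kstar <- if (any(pass)) max(which(pass)) else 0L
  cutoff <- if (kstar > 0L) p[o][kstar] else NA_real_
  flags <- if (kstar > 0L) p <= cutoff else rep(FALSE, m)
  list(flags = flags, cutoff = cutoff, adjusted = p.adjust(p, "BH"))
}

#' Spearman correlation with percentile bootstrap confidence interval
#'
#' Spearman rho with mid-ranks for ties; two-sided p from the
#' t-approximation (exact p is unavailable with ties); 95% CI by
#' percentile bootstrap over cases.
#'
#' @param x,y numeric vectors (n >= 4).
#' @param nBoot bootstrap replications.
#' @param seed optional RNG seed.
#' @param vars variable names for the report.
#' @return a [CorrelationResult-class]; rho is NA (flagged) when either
#'   variable is constant.
#' @export
spearmanBootstrap <- function(x, y, nBoot = 1000, seed = NULL,
                              vars = c("x", "y")) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  stopifnot(n >= 4, nBoot >= 1)
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant variable; rho undefined", call. = FALSE)
    return(new("CorrelationResult", variables = vars, rho = NA_real_,
               p = NA_real_, ciLow = NA_real_, ciHigh = NA_real_,
               nBoot = as.integer(nBoot), n = as.integer(n)))
  }
  rho <- cor(x, y, method = "spearman")
  tstat <- rho * sqrt((n - 2) / max(1e-12, 1 - rho^2))
  p <- 2 * pt(-abs(tstat), n - 2)
  boot <- withSeed(seed, replicate(nBoot, {
    i <- sample.int(n, n, replace = TRUE)
    suppressWarnings(cor(x[i], y[i], method = "spearman"))
  }))
  ci <- quantile(boot, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  new("CorrelationResult", variables = vars, rho = rho, p = p,
      ciLow = min(ci[1], rho), ciHigh = max(ci[2], rho),
      nBoot = as.integer(nBoot), n = as.integer(n))
}

#' Observed power of the 2x2 interaction F test
#'
#' power = P(F'(df1, df2, lambda) > F_crit) for the gender-by-diagnosis
#' interaction in a two-way factorial with `nTotal` cases: df1 = 1, df2 =
#' nTotal - 4. Two noncentrality conventions are available: "spss"
#' (lambda = f^2 (df1 + df2 + 1), the observed-power convention of the
#' study's statistics package) and "sample" (lambda = f^2 nTotal, the
#' population convention matched by [interactionPowerSim()]).
#'
#' @param f Cohen's f effect size (>= 0).
#' @param nTotal total cases (> 4).
#' @param alpha test level.
#' @param ncp noncentrality convention.
#' @return the power.
#' @examples
#' interactionPower(0.36, 16)          # ~0.24
#' interactionPower(0.36, 16, ncp = "sample")  # ~0.26
#' @export
interactionPower <- function(f, nTotal, alpha = 0.05,
                             ncp = c("spss", "sample")) {
  ncp <- match.arg(ncp)
  stopifnot(f >= 0)
  df2 <- nTotal - 4
  if (df2 <= 0) stopMsg("stereoPC_config", "nTotal must exceed 4")
  lambda <- if (ncp == "spss") f^2 * (1 + df2 + 1) else f^2 * nTotal
  1 - pf(qf(1 - alpha, 1, df2), 1, df2, ncp = lambda)
}

#' Monte-Carlo power of the 2x2 interaction
#'
#' Independent simulation oracle for [interactionPower()]: balanced 2x2
#' cells with a pure interaction pattern of Cohen's f, unit error SD,
#' classical two-way ANOVA F for the interaction.
#'
#' @param f Cohen's f.
#' @param nTotal total cases (multiple of 4).
#' @param alpha test level.
#' @param nrep replications.
#' @param seed optional RNG seed.
#' @return rejection rate.
#' @export
interactionPowerSim <- function(f, nTotal, alpha = 0.05, nrep = 20000,
                                seed = NULL) {
  stopifnot(nTotal %% 4 == 0)
  nc <- nTotal / 4
  # cell means +f, -f, -f, +f give interaction effect size f (sd of cell
  # means around additive structure = f, error sd = 1)
  mu <- c(f, -f, -f, f)
  withSeed(seed, {
    y <- matrix(rnorm(nrep * nTotal), nrep) +
      matrix(rep(mu, each = nc), nrep, nTotal, byrow = TRUE)
    cellIdx <- rep(seq_len(4), each = nc)
    cellMeans <- sapply(1:4, function(k)
      rowMeans(y[, cellIdx == k, drop = FALSE]))
    inter <- (cellMeans[, 1] - cellMeans[, 2] - cellMeans[, 3] +
                cellMeans[, 4]) / 4
    ssInt <- nTotal * inter^2
    fitted <- cellMeans[, cellIdx]
    sse <- rowSums((y - fitted)^2)
    Fstat <- ssInt / (sse / (nTotal - 4))
    mean(Fstat > qf(1 - alpha, 1, nTotal - 4))
  })
}

#' Covariate-adjusted group comparison
#'
#' The study's generalized-linear-model covariate check: the group contrast
#' on values adjusted for a numeric covariate (linear model outcome ~ group
#' + covariate), reported next to the unadjusted two-group comparison.
#'
#' @param y outcome values.
#' @param group two-level factor (or coercible).
#' @param covariate numeric covariate; cases with NA are dropped with a
#'   message.
#' @return list with `adjusted` (group t, df, p from the linear model),
#'   `unadjusted` (a [ComparisonResult-class]), and `nUsed`.
#' @export
covariateAdjustedComparison <- function(y, group, covariate) {
  group <- factor(group)
  stopifnot(nlevels(group) == 2, is.numeric(covariate))
  keep <- complete.cases(y, group, covariate)
  if (any(!keep)) message(sprintf("dropping %d case(s) with missing data",
                                  sum(!keep)))
  y <- y[keep]; group <- droplevels(group[keep]); covariate <- covariate[keep]
  if (sd(covariate) == 0)
    stopMsg("stereoPC_config", "covariate has zero variance")
  rv <- resid(lm(covariate ~ group))
  if (var(rv) < 1e-12 * var(covariate))
    stopMsg("stereoPC_config",
            "covariate is collinear with the group indicator")
  fit <- lm(y ~ group + covariate)
  sm <- summary(fit)$coefficients
  g1 <- levels(group)[1]; g2 <- levels(group)[2]
  un <- twoGroupCompare(y[group == g1], y[group == g2],
                        labels = c(g1, g2))
  list(adjusted = list(t = sm[2, "t value"], df = fit$df.residual,
                       p = sm[2, "Pr(>|t|)"]),
       unadjusted = un, nUsed = length(y))
}

#' Run the study's statistical battery on a simulated cohort
#'
#' Reproduces the analysis table structure: the four factorial mixed-model
#' tests (with/without volume weighting, with/without brain-weight
#' covariate), Levene-gated regional t-tests with BH FDR over the regional
#' family, and the two headline correlations.
#'
#' @param sim result of [simulateCohort()].
#' @param q FDR level for the regional family.
#' @param seed seed for the bootstrap CIs.
#' @return list: `factorial` (list of 4 [FactorialResult-class]),
#'   `regional` (list of [ComparisonResult-class] with FDR flags),
#'   `correlations` (list of [CorrelationResult-class]).
#' @export
analyzeCohort <- function(sim, q = 0.05, seed = NULL) {
  prof <- sim$profiles
  dens <- sim$densities
  spec <- sim$spec
  long <- merge(dens, prof[, c("case_id", "diagnosis", "sex",
                               "brain_weight_g", "adir_q50")], by = "case_id")
  long$logDensity <- log(long$measured)
  long$regionalVolume <- spec@regionalVolumeMm3[long$region]
  fact <- list(
    test1 = weightedFactorialAnalysis(long, weights = "volume"),
    test2 = weightedFactorialAnalysis(long, weights = "volume",
                                      covariate = "brain_weight_g"),
    test3 = weightedFactorialAnalysis(long, weights = "none"),
    test4 = weightedFactorialAnalysis(long, weights = "none",
                                      covariate = "brain_weight_g"))
  regions <- names(spec@baselineDensity)
  regional <- lapply(regions, function(r) {
    d <- long[long$region == r, ]
    twoGroupCompare(d$measured[d$diagnosis == "control"],
                    d$measured[d$diagnosis == "autism"],
                    labels = c("control", "autism"))
  })
  names(regional) <- regions
  fdr <- bhFdr(vapply(regional, function(cr) cr@p, 0), q)
  for (i in seq_along(regional)) regional[[i]]@passedFdr <- fdr$flags[i]
  lobx <- long[long$region == "lobuleX", ]
  autX <- lobx[lobx$diagnosis == "autism", ]
  crus <- merge(long[long$region == "crusI", c("case_id", "logDensity")],
                long[long$region == "crusII", c("case_id", "logDensity")],
                by = "case_id")
  correlations <- list(
    crusI_crusII = spearmanBootstrap(crus$logDensity.x, crus$logDensity.y,
                                     seed = seed,
                                     vars = c("crusI", "crusII")),
    lobuleX_adir = spearmanBootstrap(autX$measured, autX$adir_q50,
                                     seed = seed,
                                     vars = c("lobuleX", "adir_q50")))
  list(factorial = fact, regional = regional, correlations = correlations,
       fdrCutoff = fdr$cutoff)
}
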
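#' @useDynLib stereoPC, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats rnorm runif rpois rlnorm rbinom qf pf qnorm pnorm cor
#'   cor.test t.test sd var anova lm resid aov pt p.adjust quantile rmultinom
#'   setNames complete.cases median as.formula
#' @importFrom utils read.csv write.csv head
NULL

# Evaluate `expr` under a fixed RNG seed when `seed` is non-NULL, leaving the
# global RNG stream untouched; otherwise evaluate with the current stream.
withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) {
    force(expr)
  } else {
    withr::with_seed(as.integer(seed), expr)
  }
}

# micrometre^3 per mm^3
UM3_PER_MM3 <- 1e9
# micrometre^2 per mm^2
UM2_PER_MM2 <- 1e6

stopMsg <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "stereoPC_error")))
}
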
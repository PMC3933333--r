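#' Accessors for stereoPC classes
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x an object of the documented class.
#' @return the documented component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("somata", function(x) standardGeneric("somata"))
#' @rdname accessors
#' @export
setGeneric("trueDensity", function(x) standardGeneric("trueDensity"))
#' @rdname accessors
#' @export
setGeneric("regionVolume", function(x) standardGeneric("regionVolume"))
#' @rdname accessors
#' @export
setGeneric("monolayerArea", function(x) standardGeneric("monolayerArea"))
#' @rdname accessors
#' @export
setGeneric("regionName", function(x) standardGeneric("regionName"))
#' @rdname accessors
#' @export
setGeneric("frameCounts", function(x) standardGeneric("frameCounts"))
#' @rdname accessors
#' @export
setGeneric("sampledVolume", function(x) standardGeneric("sampledVolume"))
#' @rdname accessors
#' @export
setGeneric("pcDensity", function(x) standardGeneric("pcDensity"))
#' @rdname accessors
#' @export
setGeneric("ceValue", function(x) standardGeneric("ceValue"))

#' @rdname accessors
setMethod("somata", "VirtualRegion", function(x) x@somata)
#' @rdname accessors
setMethod("trueDensity", "VirtualRegion",
          function(x) nrow(x@somata) / x@volumeMm3)
#' @rdname accessors
setMethod("regionVolume", "VirtualRegion", function(x) x@volumeMm3)
#' @rdname accessors
setMethod("monolayerArea", "VirtualRegion", function(x) x@monolayerAreaMm2)
#' @rdname accessors
setMethod("regionName", "VirtualRegion", function(x) x@spec@name)
#' @rdname accessors
setMethod("regionName", "RegionSample", function(x) x@region)
#' @rdname accessors
setMethod("frameCounts", "RegionSample", function(x) x@q)
#' @rdname accessors
setMethod("sampledVolume", "RegionSample", function(x) x@sampledVolumeMm3)
#' @rdname accessors
setMethod("regionName", "DensityEstimate", function(x) x@region)
#' @rdname accessors
setMethod("pcDensity", "DensityEstimate", function(x) x@density)
#' @rdname accessors
setMethod("ceValue", "DensityEstimate", function(x) x@ce)

setMethod("show", "VirtualRegion", function(object) {
  cat("VirtualRegion '", object@spec@name, "'\n", sep = "")
  cat("  folia:          ", length(object@spec@foliumSpecs), "\n", sep = "")
  cat(sprintf("  volume:          %.2f mm^3 (%s contour)\n",
              object@volumeMm3, object@spec@contour))
  cat(sprintf("  monolayer area:  %.2f mm^2\n", object@monolayerAreaMm2))
  cat(sprintf("  somata:          %d (true density %.1f PC/mm^3)\n",
              nrow(object@somata), trueDensity(object)))
})

setMethod("show", "RegionSample", function(object) {
  cat("RegionSample '", object@region, "'\n", sep = "")
  cat(sprintf("  sections: %d   frames: %d   sum(Q): %d\n",
              length(object@q), as.integer(sum(object@nFrames)),
              as.integer(sum(object@q))))
  cat(sprintf("  sampled volume: %.4f mm^3\n", object@sampledVolumeMm3))
})

setMethod("show", "DensityEstimate", function(object) {
  cat("DensityEstimate '", object@region, "'\n", sep = "")
  cat(sprintf("  Q = %d in %.4f mm^3 -> %.1f PC/mm^3 (CE %s)\n",
              as.integer(object@qTotal), object@vSampledMm3, object@density,
              ifelse(is.na(object@ce), "undefined",
                     sprintf("%.3f", object@ce))))
})

setMethod("show", "ComparisonResult", function(object) {
  cat("ComparisonResult: ", object@label, "\n", sep = "")
  cat(sprintf("  %s: t = %.3f, df = %.4g, p = %.4g\n", object@flavor,
              object@t, object@df, object@p))
  cat(sprintf("  percent difference = %.1f%% (n = %s)%s\n",
              object@percentDifference, paste(object@n, collapse = "/"),
              ifelse(is.na(object@passedFdr), "",
                     ifelse(object@passedFdr, "  [passed FDR]", "  [not FDR]"))))
})

setMethod("show", "FactorialResult", function(object) {
  cat("FactorialResult (", object@weighting, ", n = ", object@nCases,
      " cases)\n", sep = "")
  print(object@terms, row.names = FALSE)
})

setMethod("show", "CorrelationResult", function(object) {
  cat("CorrelationResult: ", paste(object@variables, collapse = " ~ "),
      "\n", sep = "")
  cat(sprintf("  rho = %.3f, p = %.4g, 95%% CI [%.3f, %.3f] (%d bootstrap, n = %d)\n",
              object@rho, object@p, object@ciLow, object@ciHigh,
              object@nBoot, object@n))
})

setMethod("show", "CohortSpec", function(object) {
  cat("CohortSpec:", sum(object@cellSizes), "cases (",
      paste(sprintf("%s=%d", names(object@cellSizes), object@cellSizes),
            collapse = ", "), ")\n")
  cat("  regions:", paste(names(object@baselineDensity), collapse = ", "), "\n")
  cat(sprintf("  male effect %.3f, age slope %.4f/yr, lobule X BW elasticity %.3f\n",
              object@maleEffect, object@ageLogSlope, object@bwGamma))
})
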
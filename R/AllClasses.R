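#' Specification of a single cerebellar folium phantom
#'
#' A folium is modelled as a tube (white-matter core plus cortical layers)
#' swept along a centerline polyline, with the Purkinje cell monolayer lying
#' on a coaxial surface `pcOffset` micrometres beneath the pial (outer)
#' surface. All lengths are micrometres.
#'
#' @slot centerline numeric matrix (n x 3) of control points (um), n >= 2.
#' @slot radius tube radius from centerline to pial surface (um).
#' @slot pcOffset radial depth of the PC monolayer beneath the pial surface (um).
#' @slot jitterSd SD of the radial Gaussian scatter of somata about the
#'   monolayer (um); models the variable position of PCs within the layer.
#' @slot somaDiamMean,somaDiamSd lognormal soma diameter parameters (um). The
#'   human PC soma scale (~25 um) is a modelling default; the diameter is
#'   clipped to [10, mean + 4 sd].
#' @exportClass FoliumSpec
setClass("FoliumSpec",
  representation(centerline = "matrix", radius = "numeric",
                 pcOffset = "numeric", jitterSd = "numeric",
                 somaDiamMean = "numeric", somaDiamSd = "numeric"))

setValidity("FoliumSpec", function(object) {
  msgs <- character()
  cl <- object@centerline
  if (!is.numeric(cl) || ncol(cl) != 3L || nrow(cl) < 2L)
    msgs <- c(msgs, "centerline must be a numeric matrix with >= 2 rows and 3 columns")
  else {
    seg <- diff(cl)
    if (any(sqrt(rowSums(seg^2)) < 1e-9))
      msgs <- c(msgs, "degenerate centerline: coincident consecutive control points")
  }
  if (object@radius <= 0) msgs <- c(msgs, "radius must be > 0")
  if (object@pcOffset <= 0 || object@pcOffset >= object@radius)
    msgs <- c(msgs, "must have radius > pcOffset > 0")
  if (object@jitterSd < 0) msgs <- c(msgs, "jitterSd must be >= 0")
  if (object@somaDiamMean <= 0) msgs <- c(msgs, "somaDiamMean must be > 0")
  if (object@somaDiamSd < 0) msgs <- c(msgs, "somaDiamSd must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' A generated folium solid
#'
#' Produced by [generateFolium()]. Carries the analytic tube volume and
#' monolayer surface area (flat end caps: volume = pi r^2 L, monolayer area =
#' 2 pi (r - pcOffset) L, exact for straight tubes and accurate for gently
#' curved centerlines whose curvature radius greatly exceeds the tube radius).
#'
#' @slot spec the [FoliumSpec-class] it was built from.
#' @slot segLen per-segment centerline lengths (um).
#' @slot length total centerline length (um).
#' @slot volumeUm3 analytic solid volume (um^3).
#' @slot monolayerAreaUm2 analytic monolayer surface area (um^2).
#' @exportClass Folium
setClass("Folium",
  representation(spec = "FoliumSpec", segLen = "numeric", length = "numeric",
                 volumeUm3 = "numeric", monolayerAreaUm2 = "numeric"))

#' Specification of a virtual cerebellar region
#'
#' @slot name region label; the packaged defaults use "crusI", "crusII",
#'   "lobulesIV_VI" and "lobuleX".
#' @slot foliumSpecs list of [FoliumSpec-class] objects.
#' @slot boundingBox 2 x 3 numeric matrix, rows min/max, columns x/y/z (um).
#'   z is the sectioning axis.
#' @slot targetSurfaceDensity Purkinje cells per mm^2 of monolayer surface.
#' @slot minSeparation hard-core minimum 3D separation between soma centres
#'   (um); `NA` means "use the mean soma diameter" (default), 0 disables the
#'   hard-core constraint.
#' @slot contour "box" (the anatomical contour is the bounding box, so the
#'   reference volume includes interfolial tissue) or "folia" (contour hugs
#'   the folium solids; reference volume is their union).
#' @slot rngSeed integer seed making the assembled region reproducible.
#' @exportClass RegionSpec
setClass("RegionSpec",
  representation(name = "character", foliumSpecs = "list",
                 boundingBox = "matrix", targetSurfaceDensity = "numeric",
                 minSeparation = "numeric", contour = "character",
                 rngSeed = "integer"))

setValidity("RegionSpec", function(object) {
  msgs <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msgs <- c(msgs, "name must be a single non-empty string")
  if (!all(vapply(object@foliumSpecs, is, TRUE, "FoliumSpec")))
    msgs <- c(msgs, "foliumSpecs must all be FoliumSpec objects")
  bb <- object@boundingBox
  if (!identical(dim(bb), c(2L, 3L)) || any(bb[2, ] <= bb[1, ]))
    msgs <- c(msgs, "boundingBox must be a 2x3 matrix with max > min")
  else for (fs in object@foliumSpecs) {
    r <- fs@radius
    cl <- fs@centerline
    bad <- FALSE
    for (i in seq_len(nrow(cl) - 1L)) {
      a <- cl[i, ]; b2 <- cl[i + 1L, ]
      u <- (b2 - a) / sqrt(sum((b2 - a)^2))
      # flat-capped tube: radial extent r * sqrt(1 - u_c^2) per coordinate
      ext <- r * sqrt(pmax(0, 1 - u^2))
      lo <- pmin(a, b2) - ext
      hi <- pmax(a, b2) + ext
      if (any(lo < bb[1, ] - 1e-6) || any(hi > bb[2, ] + 1e-6)) { bad <- TRUE; break }
    }
    if (bad) {
      msgs <- c(msgs, "boundingBox must strictly contain all folium solids")
      break
    }
  }
  if (object@targetSurfaceDensity < 0)
    msgs <- c(msgs, "targetSurfaceDensity must be >= 0")
  if (!object@contour %in% c("box", "folia"))
    msgs <- c(msgs, "contour must be 'box' or 'folia'")
  if (length(msgs)) msgs else TRUE
})

#' A virtual cerebellar region with known ground truth
#'
#' The phantom against which the sampling and estimation pipeline is
#' validated: somata positions are known exactly, as are the analytic region
#' volume and monolayer area, so the true density is known by construction.
#'
#' @slot spec the [RegionSpec-class] used.
#' @slot somata data.frame with columns x, y, z, diameter (um) and folium.
#' @slot volumeMm3 analytic reference volume (mm^3).
#' @slot monolayerAreaMm2 analytic monolayer area (mm^2).
#' @exportClass VirtualRegion
setClass("VirtualRegion",
  representation(spec = "RegionSpec", somata = "data.frame",
                 volumeMm3 = "numeric", monolayerAreaMm2 = "numeric"))

setValidity("VirtualRegion", function(object) {
  msgs <- character()
  if (object@volumeMm3 <= 0) msgs <- c(msgs, "volumeMm3 must be > 0")
  s <- object@somata
  need <- c("x", "y", "z", "diameter")
  if (!all(need %in% names(s))) {
    msgs <- c(msgs, "somata must have columns x, y, z, diameter")
  } else if (nrow(s)) {
    if (any(s$diameter <= 0)) msgs <- c(msgs, "soma diameters must be > 0")
    bb <- object@spec@boundingBox
    if (any(s$x < bb[1, 1] | s$x > bb[2, 1] | s$y < bb[1, 2] |
            s$y > bb[2, 2] | s$z < bb[1, 3] | s$z > bb[2, 3]))
      msgs <- c(msgs, "all somata must lie inside the bounding box")
  }
  if (length(msgs)) msgs else TRUE
})

#' Systematic serial-section series
#'
#' Defaults mirror celloidin processing for postmortem cerebellar surveys:
#' 200 um sections with every 6th retained (1.2 mm increments), with a single
#' uniform-random start within one period.
#'
#' @slot thickness section thickness (um).
#' @slot period keep every `period`-th section.
#' @slot startOffset series start within one period (um); `NA` = draw
#'   uniformly at sectioning time.
#' @exportClass SectionSeries
setClass("SectionSeries",
  representation(thickness = "numeric", period = "integer",
                 startOffset = "numeric"))

setValidity("SectionSeries", function(object) {
  msgs <- character()
  if (object@thickness <= 0) msgs <- c(msgs, "thickness must be > 0")
  if (object@period < 1L) msgs <- c(msgs, "period must be >= 1")
  off <- object@startOffset
  if (!is.na(off) && (off < 0 || off >= object@period * object@thickness))
    msgs <- c(msgs, "startOffset must lie in [0, period * thickness)")
  if (length(msgs)) msgs else TRUE
})

#' A sectioned virtual region
#'
#' Result of [cutSections()] (and input/output of [applyDegradation()]).
#' Sections are ordered by z position; each soma is assigned to the section
#' containing its leading edge (minimum-z point of the soma sphere), or to
#' none if its leading edge falls between retained sections.
#'
#' @slot region the sectioned [VirtualRegion-class].
#' @slot zTop z of each retained section top (um), ascending.
#' @slot thickness,period the series parameters used.
#' @slot areaMm2 planimetric cross-section area at each section top (mm^2).
#' @slot footprints list (one per section) of rectangle matrices
#'   (columns xmin, xmax, ymin, ymax, um) giving the region footprint within
#'   the thick section; frames are placed against these.
#' @slot somaSection integer index of the retained section owning each soma
#'   (NA when the soma lies in a discarded section of the series).
#' @exportClass SectionSet
setClass("SectionSet",
  representation(region = "VirtualRegion", zTop = "numeric",
                 thickness = "numeric", period = "integer",
                 areaMm2 = "numeric", footprints = "list",
                 somaSection = "integer"))

#' Optical-disector sampling design
#'
#' Defaults are the published survey parameters: 19,600 um^2 frames, 5 um
#' guard, 75 um disector depth, and region-specific grid pitches.
#'
#' @slot frameArea counting-frame area (um^2); the frame is square.
#' @slot guardDepth guard depth below the section top (um).
#' @slot disectorHeight disector z-extent below the guard (um).
#' @slot pitch named numeric vector of grid pitches per region (um), or a
#'   single unnamed value used for every region.
#' @slot frameRule "centroid" places a frame in every grid cell whose frame
#'   centre falls inside the section footprint (keeps the expected frame
#'   count at area/pitch^2 and the density estimator unbiased); "intersect"
#'   places a frame whenever the frame footprint touches the region.
#' @exportClass SamplingDesign
setClass("SamplingDesign",
  representation(frameArea = "numeric", guardDepth = "numeric",
                 disectorHeight = "numeric", pitch = "numeric",
                 frameRule = "character"))

setValidity("SamplingDesign", function(object) {
  msgs <- character()
  if (object@frameArea <= 0) msgs <- c(msgs, "frameArea must be > 0")
  side <- sqrt(object@frameArea)
  if (any(object@pitch < side))
    msgs <- c(msgs, "grid pitch must be >= frame side (frames must not overlap)")
  if (object@guardDepth < 0) msgs <- c(msgs, "guardDepth must be >= 0")
  if (object@disectorHeight <= 0) msgs <- c(msgs, "disectorHeight must be > 0")
  if (!object@frameRule %in% c("centroid", "intersect"))
    msgs <- c(msgs, "frameRule must be 'centroid' or 'intersect'")
  if (length(msgs)) msgs else TRUE
})

#' Raw output of disector sampling of one region
#'
#' @slot region region name.
#' @slot zTop section tops (um), ascending (the SURS order used by the
#'   Gundersen CE serial covariances).
#' @slot q per-section disector counts.
#' @slot nFrames per-section number of counting frames placed.
#' @slot areaMm2 per-section planimetric areas (mm^2), for Cavalieri volumes.
#' @slot frameAreaUm2,disectorHeightUm design parameters used.
#' @slot sampledVolumeMm3 total disector volume = sum(nFrames) * frameArea *
#'   disectorHeight.
#' @exportClass RegionSample
setClass("RegionSample",
  representation(region = "character", zTop = "numeric", q = "numeric",
                 nFrames = "numeric", areaMm2 = "numeric",
                 frameAreaUm2 = "numeric", disectorHeightUm = "numeric",
                 sampledVolumeMm3 = "numeric"))

setValidity("RegionSample", function(object) {
  msgs <- character()
  if (any(object@q < 0)) msgs <- c(msgs, "counts must be >= 0")
  expV <- sum(object@nFrames) * object@frameAreaUm2 *
    object@disectorHeightUm / UM3_PER_MM3
  if (abs(expV - object@sampledVolumeMm3) > 1e-8 * max(1, expV))
    msgs <- c(msgs, "sampledVolumeMm3 must equal nFrames * frameArea * disectorHeight")
  if (length(object@zTop) != length(object@q))
    msgs <- c(msgs, "zTop and q must have equal length")
  if (length(msgs)) msgs else TRUE
})

#' A Purkinje cell density estimate for one region
#'
#' @slot region region name.
#' @slot qTotal total disector count.
#' @slot vSampledMm3 summed disector volume (mm^3).
#' @slot density PC per mm^3 (qTotal / vSampledMm3).
#' @slot ce Gundersen (m = 1) coefficient of error; NA (flagged) when the
#'   count is zero or fewer than 3 sections were sampled.
#' @slot nFrames,nSections sampling effort.
#' @exportClass DensityEstimate
setClass("DensityEstimate",
  representation(region = "character", qTotal = "numeric",
                 vSampledMm3 = "numeric", density = "numeric", ce = "numeric",
                 nFrames = "numeric", nSections = "numeric"))

setValidity("DensityEstimate", function(object) {
  msgs <- character()
  if (object@vSampledMm3 <= 0) msgs <- c(msgs, "vSampledMm3 must be > 0")
  if (object@density < 0) msgs <- c(msgs, "density must be >= 0")
  if (abs(object@density - object@qTotal / object@vSampledMm3) >
      1e-8 * max(1, object@density))
    msgs <- c(msgs, "density must equal qTotal / vSampledMm3")
  if (!is.na(object@ce) && object@ce < 0) msgs <- c(msgs, "ce must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Configuration of the simulated postmortem cohort
#'
#' Encodes the study conditions of a 16-case (8 autism / 8 control, 5M/3F
#' each) postmortem cerebellar survey: demographics fitted to the packaged
#' case table, and a multiplicative (log-linear) regional density model with
#' planted diagnosis, sex, age and brain-weight effects. See
#' [defaultCohortSpec()] for the calibrated defaults and the meaning of each
#' parameter.
#'
#' @slot cellSizes named integer vector: autismM, autismF, controlM, controlF.
#' @slot baselineDensity named baseline density per region (PC/mm^3; reference
#'   = control female at the reference age and brain weight).
#' @slot regionalVolumeMm3 named planimetric regional volumes used as
#'   composite weights (mm^3).
#' @slot diagnosisEffect named DIRECT multiplicative diagnosis effect per
#'   region (autism vs control).
#' @slot maleEffect direct multiplicative male effect (applies to all regions).
#' @slot ageLogSlope additive log-density slope per year of age.
#' @slot ageRef reference age (years) at which baselines apply.
#' @slot bwGamma elasticity of lobule X density with respect to brain weight
#'   (log-log slope); the diagnosis effect on lobule X is routed entirely
#'   through brain weight by default.
#' @slot bwRef reference brain weight (g).
#' @slot caseSd SD of the shared per-case log-density effect.
#' @slot residSd SD of the per-case-per-region residual.
#' @slot crusCor residual correlation between crus I and crus II.
#' @slot adirScale,adirNoiseSd,adirThresholds latent-variable link from lobule
#'   X log density to the ordinal ADI-R eye-contact item (0-3).
#' @slot measurementCV coefficient of variation of the fast surrogate
#'   measurement (matches the survey's mean Gundersen CE).
#' @slot demographics list of per-cell age / brain-weight normal parameters
#'   and the PMI distribution.
#' @slot rates list of comorbidity rates (mr, epilepsy, regression) for the
#'   autism group.
#' @exportClass CohortSpec
setClass("CohortSpec",
  representation(cellSizes = "integer", baselineDensity = "numeric",
                 regionalVolumeMm3 = "numeric", diagnosisEffect = "numeric",
                 maleEffect = "numeric", ageLogSlope = "numeric",
                 ageRef = "numeric", bwGamma = "numeric", bwRef = "numeric",
                 caseSd = "numeric", residSd = "numeric", crusCor = "numeric",
                 adirScale = "numeric", adirNoiseSd = "numeric",
                 adirThresholds = "numeric", measurementCV = "numeric",
                 demographics = "list", rates = "list"))

setValidity("CohortSpec", function(object) {
  msgs <- character()
  if (any(object@cellSizes < 1L)) msgs <- c(msgs, "all cell sizes must be >= 1")
  if (any(object@diagnosisEffect <= 0) || object@maleEffect <= 0)
    msgs <- c(msgs, "multiplicative effects must be > 0")
  if (abs(object@crusCor) > 1) msgs <- c(msgs, "crusCor must be in [-1, 1]")
  if (object@caseSd < 0 || object@residSd < 0 || object@measurementCV < 0)
    msgs <- c(msgs, "variance components must be >= 0")
  if (!identical(sort(names(object@baselineDensity)),
                 sort(names(object@regionalVolumeMm3))))
    msgs <- c(msgs, "baselineDensity and regionalVolumeMm3 must cover the same regions")
  if (length(msgs)) msgs else TRUE
})

#' A two-group statistical contrast
#'
#' @slot label contrast description; the reference (larger-mean) group is
#'   named first.
#' @slot n per-group sample sizes.
#' @slot flavor "pooled_t" or "welch_t" (chosen by the Levene gate).
#' @slot t,df,p test statistic, degrees of freedom, two-sided p.
#' @slot percentDifference (mean_ref - mean_other) / mean_ref * 100.
#' @slot passedFdr logical flag (NA when no FDR family was applied).
#' @exportClass ComparisonResult
setClass("ComparisonResult",
  representation(label = "character", n = "integer", flavor = "character",
                 t = "numeric", df = "numeric", p = "numeric",
                 percentDifference = "numeric", passedFdr = "logical"))

setValidity("ComparisonResult", function(object) {
  msgs <- character()
  if (!is.na(object@p) && (object@p < 0 || object@p > 1))
    msgs <- c(msgs, "p must be in [0, 1]")
  if (!is.na(object@df) && object@df <= 0) msgs <- c(msgs, "df must be > 0")
  if (!object@flavor %in% c("pooled_t", "welch_t"))
    msgs <- c(msgs, "flavor must be pooled_t or welch_t")
  if (length(msgs)) msgs else TRUE
})

#' Per-term results of the volume-weighted factorial mixed-model analysis
#'
#' @slot terms data.frame with columns term, F, df1, df2, p.
#' @slot weighting description of the residual weighting used.
#' @slot nCases number of cases in the fit.
#' @exportClass FactorialResult
setClass("FactorialResult",
  representation(terms = "data.frame", weighting = "character",
                 nCases = "integer"))

#' A Spearman correlation with bootstrap confidence interval
#'
#' @slot variables the two variable names.
#' @slot rho Spearman rank correlation (mid-ranks for ties).
#' @slot p two-sided p (t approximation).
#' @slot ciLow,ciHigh percentile bootstrap interval.
#' @slot nBoot bootstrap replications; @slot n cases used.
#' @exportClass CorrelationResult
setClass("CorrelationResult",
  representation(variables = "character", rho = "numeric", p = "numeric",
                 ciLow = "numeric", ciHigh = "numeric", nBoot = "integer",
                 n = "integer"))

setValidity("CorrelationResult", function(object) {
  msgs <- character()
  if (!is.na(object@rho) && abs(object@rho) > 1 + 1e-12)
    msgs <- c(msgs, "rho must be in [-1, 1]")
  if (!is.na(object@rho) && !is.na(object@ciLow) && !is.na(object@ciHigh) &&
      (object@rho < object@ciLow - 1e-9 || object@rho > object@ciHigh + 1e-9))
    msgs <- c(msgs, "bootstrap CI must contain rho")
  if (length(msgs)) msgs else TRUE
})
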
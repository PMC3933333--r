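#' Create an optical-disector sampling design
#'
#' Defaults are the published survey parameters: square 19,600 um^2 counting
#' frames, a 5 um guard below the section top, a 75 um disector depth, and
#' region-specific grid pitches (the spacing of frames along both X and Y).
#'
#' @param frameArea frame area (um^2).
#' @param guardDepth guard depth (um).
#' @param disectorHeight disector z extent (um).
#' @param pitch named vector of per-region grid pitches (um) or one value.
#' @param frameRule "centroid" (default) or "intersect"; see
#'   [SamplingDesign-class].
#' @return a [SamplingDesign-class].
#' @export
SamplingDesign <- function(frameArea = 19600, guardDepth = 5,
                           disectorHeight = 75,
                           pitch = c(crusI = 2500, crusII = 2200,
                                     lobuleX = 400, lobulesIV_VI = 1400),
                           frameRule = c("centroid", "intersect")) {
  new("SamplingDesign", frameArea = frameArea, guardDepth = guardDepth,
      disectorHeight = disectorHeight, pitch = pitch,
      frameRule = match.arg(frameRule))
}

.pitchFor <- function(design, region) {
  p <- design@pitch
  if (length(p) == 1L && is.null(names(p))) return(unname(p))
  if (!is.null(names(p)) && region %in% names(p)) return(unname(p[region]))
  if (length(p) == 1L) return(unname(p))
  stopMsg("stereoPC_config", "no grid pitch configured for region '%s'", region)
}

# Grid cells (ix, iy) of pitch `p` with origin offset (ox, oy) whose frame
# qualifies against the footprint rectangles under the design's frame rule.
# The frame is anchored at the cell corner (ox + ix p, oy + iy p).
.placedCells <- function(rects, ox, oy, p, side, frameRule) {
  if (is.null(rects) || !nrow(rects)) return(matrix(integer(), 0, 2))
  out <- NULL
  for (k in seq_len(nrow(rects))) {
    if (frameRule == "centroid") {
      # frame centre inside the rectangle
      ixs <- seq.int(ceiling((rects[k, 1] - ox - side / 2) / p - 1e-9),
                     floor((rects[k, 2] - ox - side / 2) / p + 1e-9))
      iys <- seq.int(ceiling((rects[k, 3] - oy - side / 2) / p - 1e-9),
                     floor((rects[k, 4] - oy - side / 2) / p + 1e-9))
    } else {
      # frame footprint intersects the rectangle
      ixs <- seq.int(ceiling((rects[k, 1] - side - ox) / p - 1e-9),
                     floor((rects[k, 2] - ox) / p + 1e-9))
      iys <- seq.int(ceiling((rects[k, 3] - side - oy) / p - 1e-9),
                     floor((rects[k, 4] - oy) / p + 1e-9))
    }
    if (!length(ixs) || !length(iys)) next
    out <- rbind(out, cbind(rep(ixs, each = length(iys)),
                            rep(iys, times = length(ixs))))
  }
  if (is.null(out)) return(matrix(integer(), 0, 2))
  unique(out)
}

#' Place counting frames on one section
#'
#' Imposes a square grid of the region's pitch with the given (or uniform
#' random) offset and places one frame per qualifying grid cell, anchored at
#' the cell corner.
#'
#' @param sections a [SectionSet-class].
#' @param sectionIndex which section (1-based, in z order).
#' @param design a [SamplingDesign-class].
#' @param offset length-2 grid offset in [0, pitch)^2, or NULL to draw
#'   uniformly.
#' @param seed optional RNG seed.
#' @return data.frame with one row per frame: x0, y0 (lower-left corner, um),
#'   side (um), zLow, zHigh (the disector z window, um, half-open (zLow,
#'   zHigh]).
#' @export
placeFrames <- function(sections, sectionIndex, design = SamplingDesign(),
                        offset = NULL, seed = NULL) {
  validObject(design)
  region <- regionName(sections@region)
  p <- .pitchFor(design, region)
  side <- sqrt(design@frameArea)
  if (design@guardDepth + design@disectorHeight > sections@thickness)
    stopMsg("stereoPC_config",
            "guard (%g) + disector height (%g) exceed section thickness (%g)",
            design@guardDepth, design@disectorHeight, sections@thickness)
  if (is.null(offset)) offset <- withSeed(seed, runif(2, 0, p))
  cells <- .placedCells(sections@footprints[[sectionIndex]],
                        offset[1], offset[2], p, side, design@frameRule)
  z0 <- sections@zTop[sectionIndex]
  if (!nrow(cells))
    return(data.frame(x0 = numeric(), y0 = numeric(), side = numeric(),
                      zLow = numeric(), zHigh = numeric()))
  data.frame(x0 = offset[1] + cells[, 1] * p,
             y0 = offset[2] + cells[, 2] * p,
             side = side,
             zLow = z0 + design@guardDepth,
             zHigh = z0 + design@guardDepth + design@disectorHeight)
}

# Vectorised unbiased-counting-frame rule for somata relative to one frame
# anchored at (0,0) with side `s`. (u, v) is the soma centre, `rho` its
# maximal XY profile radius. Inclusion: the profile disk intersects the
# closed frame square. Exclusion (dominates ties): the disk touches the
# forbidden line - the left edge with its upward extension, the bottom edge,
# or the downward extension at the bottom-right corner.
.frameCounts <- function(u, v, rho, s) {
  dx <- pmax(0, pmax(-u, u - s))
  dy <- pmax(0, pmax(-v, v - s))
  hit <- dx^2 + dy^2 <= rho^2
  dLeft2 <- u^2 + pmin(v, 0)^2
  dBottom2 <- dx^2 + v^2
  dRight2 <- (u - s)^2 + pmax(v, 0)^2
  forb <- pmin(dLeft2, dBottom2, dRight2) <= rho^2
  hit & !forb
}

#' Apply the optical-disector counting rule to one frame
#'
#' A soma is counted iff (a) its maximal XY profile disk intersects the
#' closed counting frame, (b) it does not touch the forbidden line (left
#' edge and its upward extension, bottom edge, and the downward extension at
#' the bottom-right corner), and (c) its leading edge - the minimum-z point
#' of the soma sphere, the first to come into focus when focusing down -
#' lies in the frame's disector window (zLow, zHigh]. Exclusion dominates
#' ties, which is what makes an exhaustive frame tiling count every soma
#' exactly once.
#'
#' @param frame one row of the data.frame from [placeFrames()] (or any list
#'   with x0, y0, side, zLow, zHigh).
#' @param somata data.frame with columns x, y, z, diameter (um).
#' @return integer count Q for this frame.
#' @export
countFrame <- function(frame, somata) {
  if (!nrow(somata)) return(0L)
  zLead <- somata$z - somata$diameter / 2
  inZ <- zLead > frame$zLow & zLead <= frame$zHigh
  if (!any(inZ)) return(0L)
  s <- somata[inZ, ]
  sum(.frameCounts(s$x - frame$x0, s$y - frame$y0, s$diameter / 2,
                   frame$side))
}

# Count all somata of one section against the placed frame grid.
# `cells` is the matrix from .placedCells. Returns the section total Q and
# the per-soma number of frames that counted it (for identity tracking).
.countSection <- function(som, ox, oy, p, side, cells, zLow, zHigh) {
  if (!nrow(som) || !nrow(cells)) return(list(q = 0L, perSoma = integer(0)))
  zLead <- som$z - som$diameter / 2
  keep <- zLead > zLow & zLead <= zHigh
  som <- som[keep, , drop = FALSE]
  if (!nrow(som)) return(list(q = 0L, perSoma = integer(0)))
  rho <- som$diameter / 2
  key <- (cells[, 1] + 8192) * 2^15 + (cells[, 2] + 8192)
  ixHi <- floor((som$x - ox + rho) / p)
  iyHi <- floor((som$y - oy + rho) / p)
  timesCounted <- integer(nrow(som))
  for (a in 0:2) for (b in 0:2) {
    ix <- ixHi - a
    iy <- iyHi - b
    placed <- !is.na(match((ix + 8192) * 2^15 + (iy + 8192), key))
    if (!any(placed)) next
    u <- som$x - (ox + ix * p)
    v <- som$y - (oy + iy * p)
    counted <- placed & .frameCounts(u, v, rho, side)
    timesCounted <- timesCounted + counted
  }
  list(q = sum(timesCounted > 0L), perSoma = timesCounted)
}

#' Sample a virtual region with the full optical-disector design
#'
#' Runs the pipeline section cutting -> (optional) degradation -> frame
#' placement -> disector counting over all sections, with fresh uniform
#' random grid offsets per section, and records the ordered per-section
#' counts and the summed disector volume.
#'
#' @param region a [VirtualRegion-class].
#' @param series a [SectionSeries-class].
#' @param design a [SamplingDesign-class].
#' @param lossFraction,frayDepthUm optional degradation (defaults off).
#' @param seed optional RNG seed controlling the section start, section loss
#'   and all grid offsets.
#' @return a [RegionSample-class].
#' @export
sampleRegion <- function(region, series = SectionSeries(),
                         design = SamplingDesign(), lossFraction = 0,
                         frayDepthUm = 0, seed = NULL) {
  validObject(design)
  withSeed(seed, {
    ss <- cutSections(region, series)
    if (lossFraction > 0 || frayDepthUm > 0)
      ss <- applyDegradation(ss, lossFraction, frayDepthUm)
    p <- .pitchFor(design, regionName(region))
    side <- sqrt(design@frameArea)
    if (design@guardDepth + design@disectorHeight > ss@thickness)
      stopMsg("stereoPC_config",
              "guard (%g) + disector height (%g) exceed section thickness (%g)",
              design@guardDepth, design@disectorHeight, ss@thickness)
    nSec <- length(ss@zTop)
    q <- numeric(nSec)
    nFrames <- numeric(nSec)
    som <- ss@region@somata
    for (i in seq_len(nSec)) {
      off <- runif(2, 0, p)
      cells <- .placedCells(ss@footprints[[i]], off[1], off[2], p, side,
                            design@frameRule)
      nFrames[i] <- nrow(cells)
      secSom <- som[which(ss@somaSection == i), , drop = FALSE]
      res <- .countSection(secSom, off[1], off[2], p, side, cells,
                           ss@zTop[i] + design@guardDepth,
                           ss@zTop[i] + design@guardDepth +
                             design@disectorHeight)
      q[i] <- res$q
    }
    new("RegionSample", region = regionName(region), zTop = ss@zTop, q = q,
        nFrames = nFrames, areaMm2 = ss@areaMm2,
        frameAreaUm2 = design@frameArea,
        disectorHeightUm = design@disectorHeight,
        sampledVolumeMm3 = sum(nFrames) * design@frameArea *
          design@disectorHeight / UM3_PER_MM3)
  })
}
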
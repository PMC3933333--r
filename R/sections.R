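#' Create a systematic section series
#'
#' @param thickness section thickness (um).
#' @param period keep every `period`-th section (period 6 with 200 um
#'   sections = 1.2 mm increments).
#' @param startOffset start of the series within one period (um); NA draws a
#'   uniform random start at sectioning time (the SURS random start).
#' @return a [SectionSeries-class].
#' @export
SectionSeries <- function(thickness = 200, period = 6L,
                          startOffset = NA_real_) {
  new("SectionSeries", thickness = thickness, period = as.integer(period),
      startOffset = startOffset)
}

# Footprint rectangles (xmin, xmax, ymin, ymax) and planimetric area of a
# region within a section. `z0`/`z1` delimit the thick section (slab) for the
# footprint; the plane area is evaluated at the section top `z0`.
# Exact for the packaged phantoms (horizontal straight tubes / box contour);
# AABB-conservative for oblique folia.
.sectionGeometry <- function(region, z0, z1) {
  spec <- region@spec
  bb <- spec@boundingBox
  if (spec@contour == "box") {
    rect <- matrix(c(bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2]), 1,
                   dimnames = list(NULL, c("xmin", "xmax", "ymin", "ymax")))
    inZ <- z0 >= bb[1, 3] && z0 < bb[2, 3]
    area <- if (inZ) (bb[2, 1] - bb[1, 1]) * (bb[2, 2] - bb[1, 2]) /
      UM2_PER_MM2 else 0
    return(list(rects = rect, areaMm2 = area))
  }
  rects <- NULL
  area <- 0
  for (fs in spec@foliumSpecs) {
    cl <- fs@centerline
    r <- fs@radius
    for (i in seq_len(nrow(cl) - 1L)) {
      a <- cl[i, ]; b <- cl[i + 1L, ]
      zlo <- min(a[3], b[3]); zhi <- max(a[3], b[3])
      # slab distance for the footprint
      dzSlab <- max(0, zlo - z1, z0 - zhi)
      if (dzSlab < r) {
        w <- sqrt(r^2 - dzSlab^2)
        rects <- rbind(rects,
                       c(min(a[1], b[1]) - w, max(a[1], b[1]) + w,
                         min(a[2], b[2]) - w, max(a[2], b[2]) + w))
      }
      # plane chord at the section top
      dzPlane <- max(0, zlo - z0, z0 - zhi)
      if (dzPlane < r) {
        wp <- sqrt(r^2 - dzPlane^2)
        lxy <- sqrt(sum((b[1:2] - a[1:2])^2))
        area <- area + 2 * wp * lxy / UM2_PER_MM2
      }
    }
  }
  if (!is.null(rects)) colnames(rects) <- c("xmin", "xmax", "ymin", "ymax")
  list(rects = rects, areaMm2 = area)
}

#' Cut a virtual region into a systematic section series
#'
#' Sections of the given thickness are taken at `period * thickness`
#' increments from a uniform random start; a section is retained when its
#' top plane lies inside the region's z extent. Each soma is assigned to the
#' section
#' containing its leading edge (minimum-z point of the soma sphere, the
#' unique "comes into focus" event); somata whose leading edge falls in a
#' discarded section of the series belong to no retained section.
#'
#' @param region a [VirtualRegion-class].
#' @param series a [SectionSeries-class].
#' @param seed optional RNG seed (used when the series start is random).
#' @return a [SectionSet-class].
#' @export
cutSections <- function(region, series = SectionSeries(), seed = NULL) {
  validObject(series)
  t <- series@thickness
  tp <- t * series@period
  bb <- region@spec@boundingBox
  zmin <- bb[1, 3]; zmax <- bb[2, 3]
  if (zmax - zmin <= 0 || tp > (zmax - zmin) + t)
    stopMsg("stereoPC_empty_series",
            "section series (period %g um) thicker than region z extent (%g um)",
            tp, zmax - zmin)
  off <- series@startOffset
  if (is.na(off)) off <- withSeed(seed, runif(1, 0, tp))
  # retain the sections whose top plane lies inside the region z extent;
  # with an extent that is a whole number of periods this gives the same
  # section count for every random start
  kmax <- floor((zmax - (zmin + off)) / tp - 1e-12)
  if (kmax < 0)
    stopMsg("stereoPC_empty_series", "no section top falls inside the region")
  zTop <- zmin + off + seq.int(0, kmax) * tp
  geo <- lapply(zTop, function(z) .sectionGeometry(region, z, z + t))
  s <- region@somata
  if (nrow(s)) {
    zLead <- s$z - s$diameter / 2
    idx <- floor((zLead - (zmin + off)) / tp)
    pos <- zLead - (zmin + off) - idx * tp
    secZ <- zmin + off + idx * tp
    somaSection <- match(round(secZ, 6), round(zTop, 6))
    somaSection[pos >= t] <- NA_integer_
  } else somaSection <- integer()
  new("SectionSet", region = region, zTop = zTop, thickness = t,
      period = series@period,
      areaMm2 = vapply(geo, function(g) g$areaMm2, 0),
      footprints = lapply(geo, function(g) g$rects),
      somaSection = as.integer(somaSection))
}

#' Degrade a sectioned region: tissue loss and folia fraying
#'
#' Removes whole sections at random to the requested loss fraction, and
#' erodes each remaining section's footprint boundary by `frayDepthUm`,
#' deleting both the eroded area and the somata inside the eroded shell, so
#' density remains approximately estimable from the degraded material.
#'
#' @param sections a [SectionSet-class].
#' @param lossFraction fraction of sections lost in [0, 1).
#' @param frayDepthUm lateral erosion depth (um) at the folia edges.
#' @param seed optional RNG seed.
#' @return a degraded [SectionSet-class].
#' @export
applyDegradation <- function(sections, lossFraction = 0.10,
                             frayDepthUm = 50, seed = NULL) {
  stopifnot(lossFraction >= 0, lossFraction < 1, frayDepthUm >= 0)
  n <- length(sections@zTop)
  nRemove <- round(lossFraction * n)
  if (n - nRemove < 3L)
    stopMsg("stereoPC_insufficient_sections",
            "degradation would leave %d sections (< 3)", n - nRemove)
  withSeed(seed, {
    keep <- sort(sample.int(n, n - nRemove))
    map <- match(seq_len(n), keep)
    somaSection <- map[sections@somaSection]
    zTop <- sections@zTop[keep]
    areas <- sections@areaMm2[keep]
    fp <- sections@footprints[keep]
    if (frayDepthUm > 0) {
      s <- sections@region@somata
      for (i in seq_along(fp)) {
        r <- fp[[i]]
        if (is.null(r)) next
        er <- cbind(r[, 1] + frayDepthUm, r[, 2] - frayDepthUm,
                    r[, 3] + frayDepthUm, r[, 4] - frayDepthUm)
        ok <- er[, 2] > er[, 1] & er[, 4] > er[, 3]
        a0 <- sum(pmax(0, r[, 2] - r[, 1]) * pmax(0, r[, 4] - r[, 3]))
        er <- er[ok, , drop = FALSE]
        a1 <- sum(pmax(0, er[, 2] - er[, 1]) * pmax(0, er[, 4] - er[, 3]))
        areas[i] <- areas[i] * if (a0 > 0) a1 / a0 else 0
        colnames(er) <- c("xmin", "xmax", "ymin", "ymax")
        fp[[i]] <- if (nrow(er)) er else NULL
        # somata of this section falling outside every eroded rectangle
        inSec <- which(somaSection == i)
        if (length(inSec)) {
          insideAny <- rep(FALSE, length(inSec))
          if (!is.null(fp[[i]])) for (k in seq_len(nrow(er)))
            insideAny <- insideAny |
              (s$x[inSec] >= er[k, 1] & s$x[inSec] <= er[k, 2] &
               s$y[inSec] >= er[k, 3] & s$y[inSec] <= er[k, 4])
          somaSection[inSec[!insideAny]] <- NA_integer_
        }
      }
    }
    new("SectionSet", region = sections@region, zTop = zTop,
        thickness = sections@thickness, period = sections@period,
        areaMm2 = areas, footprints = fp,
        somaSection = as.integer(somaSection))
  })
}
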
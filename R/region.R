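#' Create a region specification
#'
#' @param name region label.
#' @param foliumSpecs list of [FoliumSpec-class] objects.
#' @param boundingBox 2 x 3 matrix (rows min/max, cols x/y/z, um).
#' @param targetSurfaceDensity PC per mm^2 of monolayer surface.
#' @param minSeparation hard-core soma separation (um); NA = mean soma
#'   diameter, 0 = off.
#' @param contour "box" or "folia"; see [RegionSpec-class].
#' @param rngSeed integer seed for reproducible assembly.
#' @return a [RegionSpec-class].
#' @export
RegionSpec <- function(name, foliumSpecs, boundingBox,
                       targetSurfaceDensity, minSeparation = NA_real_,
                       contour = c("box", "folia"), rngSeed = 1L) {
  new("RegionSpec", name = name, foliumSpecs = foliumSpecs,
      boundingBox = boundingBox, targetSurfaceDensity = targetSurfaceDensity,
      minSeparation = as.numeric(minSeparation),
      contour = match.arg(contour), rngSeed = as.integer(rngSeed))
}

# Region calibration constants.
#
# Target volumetric densities (PC/mm^3) follow from the published survey
# arithmetic: ~450 PCs counted per region in `nFrames` disector boxes of
# 19,600 um^2 x 75 um: D = 450 / (nFrames * 1.47e-3 mm^3). Phantom bounding
# boxes are sized so that the default 1-in-6 series of 200 um sections and the
# region-specific grid pitches reproduce those frame counts (nFrames ~=
# nSections * footprintArea / pitch^2).
.REGION_TABLE <- data.frame(
  region  = c("crusI", "crusII", "lobuleX", "lobulesIV_VI"),
  pitch   = c(2500, 2200, 400, 1400),            # um
  nFrames = c(1106, 818, 1392, 1690),
  xLen    = c(19800, 14670, 5570, 13150),        # um
  yLen    = c(10000, 9000, 4000, 9000),          # um
  zLen    = c(42000, 36000, 12000, 33600),       # um
  rBase   = c(450, 450, 330, 450),               # tube caliber range base (um)
  rVar    = c(150, 150, 120, 150),
  pcOff   = c(300, 300, 220, 300),               # monolayer depth (um)
  azimuth = c(27, 63, 41, 72) * pi / 180,        # lattice azimuth in xy
  slope   = c(0.16, 0.2, 0.55, 0.22),            # lattice z slope
  stringsAsFactors = FALSE)
.REGION_TABLE$density <- 450 / (.REGION_TABLE$nFrames * 19600 * 75 / 1e9)

#' Names and design defaults of the four surveyed cerebellar regions
#'
#' @return a data.frame with one row per region: grid pitch (um), target
#'   frame count, phantom bounding-box extents (um), and the calibrated true
#'   density (PC/mm^3).
#' @export
regionDefaults <- function() .REGION_TABLE

#' Default calibrated phantom specification for a surveyed region
#'
#' Builds the packaged phantom for one of the four regions: a bounding-box
#' contour filled with straight folium tubes of varying caliber (500-700 um
#' radius, PC monolayer 300 um beneath the pial surface) laid out in z-rows
#' with row-specific azimuths. The surface density is set so the expected
#' soma count equals the calibrated volumetric density times the box volume,
#' and tubes stay one radius clear of the box faces so every soma's counting
#' frame lies inside the contour.
#'
#' @param name one of "crusI", "crusII", "lobuleX", "lobulesIV_VI".
#' @param scale linear scale factor applied to the x and z extents (desk-scale
#'   phantoms for quick experiments; 1 = survey scale).
#' @param rngSeed seed stored in the spec.
#' @return a [RegionSpec-class].
#' @export
defaultRegionSpec <- function(name, scale = 1, rngSeed = 1L) {
  row <- .REGION_TABLE[.REGION_TABLE$region == name, ]
  if (!nrow(row))
    stopMsg("stereoPC_config", "unknown region name '%s'", name)
  xL <- row$xLen * scale
  zL <- max(row$zLen * scale, 2400)
  zL <- 1200 * round(zL / 1200)          # whole number of series periods
  yL <- row$yLen
  # The folia form a sheared parallel lattice: every tube runs at the
  # region's oblique azimuth in the xy-plane and climbs in z with a common
  # slope, so each tube's monolayer sweeps through one or more full section
  # periods (its soma z profile is smooth against the 1.2 mm lattice) while
  # rigid inter-tube gaps rule out overlap. Tube calibers vary over a
  # golden-ratio sequence, emulating folia of different sizes cut at
  # arbitrary angles; lobule X uses finer folia and a steeper pitch,
  # matching its small flocculonodular leaflets. The oblique azimuth keeps
  # the in-section soma strips from resonating with the counting-frame
  # grid; the shear keeps the soma z profile from resonating with the
  # section series.
  phi <- 0.6180339887
  sl <- row$slope
  rmax <- row$rBase + row$rVar
  # parallel vertical planes of tubes, spaced so tubes never touch
  lateral <- 2 * rmax + 60
  zs <- lateral * sqrt(1 + sl^2)
  margin <- rmax + 40
  u <- c(cos(row$azimuth), sin(row$azimuth))
  pv <- c(-u[2], u[1])
  ctr <- c(xL, yL) / 2
  half <- sqrt(xL^2 + yL^2)
  jmax <- ceiling(half / lateral)
  # row centres span beyond the box; the z clip trims each tube
  zcAll <- seq(margin - sl * half, zL - margin + sl * half, by = zs)
  folia <- list()
  areaUm2 <- 0
  idx <- 0L
  for (k in seq_along(zcAll)) for (j in -jmax:jmax) {
    idx <- idx + 1L
    rk <- row$rBase + row$rVar * ((idx * phi) %% 1)
    lo <- c(rk, rk); hi <- c(xL - rk, yL - rk)
    base <- ctr + j * lateral * pv
    # clip the line base + t*u (xy) to the shrunk rect
    t0 <- -half; t1 <- half
    for (d in 1:2) {
      if (abs(u[d]) < 1e-12) {
        if (base[d] < lo[d] || base[d] > hi[d]) { t0 <- 1; t1 <- 0; break }
      } else {
        ta <- (lo[d] - base[d]) / u[d]; tb <- (hi[d] - base[d]) / u[d]
        t0 <- max(t0, min(ta, tb)); t1 <- min(t1, max(ta, tb))
      }
    }
    # clip in z: z(t) = zc + slope * t must stay within [rk+40, zL-rk-40]
    t0 <- max(t0, (rk + 40 - zcAll[k]) / sl)
    t1 <- min(t1, (zL - rk - 40 - zcAll[k]) / sl)
    if (t1 - t0 < 1500) next
    a <- c(base + t0 * u, zcAll[k] + sl * t0)
    b <- c(base + t1 * u, zcAll[k] + sl * t1)
    folia[[length(folia) + 1L]] <-
      FoliumSpec(rbind(a, b), radius = rk, pcOffset = row$pcOff)
    areaUm2 <- areaUm2 + 2 * pi * (rk - row$pcOff) *
      (t1 - t0) * sqrt(1 + sl^2)
  }
  boxVolMm3 <- xL * yL * zL / UM3_PER_MM3
  areaMm2 <- areaUm2 / UM2_PER_MM2
  sigma <- row$density * boxVolMm3 / areaMm2
  RegionSpec(name = name, foliumSpecs = folia,
             boundingBox = rbind(c(0, 0, 0), c(xL, yL, zL)),
             targetSurfaceDensity = sigma, contour = "box",
             rngSeed = rngSeed)
}

#' Assemble a virtual region from its specification
#'
#' Instantiates every folium, places somata at the spec's target surface
#' density, pools and labels them, and records the analytic reference volume
#' and monolayer area. Deterministic for a fixed `rngSeed` in the spec.
#'
#' @param spec a [RegionSpec-class].
#' @param overlapTolerance warn if two folium centerlines approach closer
#'   than this fraction of the sum of radii (analytic union volume would be
#'   overstated under the "folia" contour).
#' @return a [VirtualRegion-class].
#' @export
assembleRegion <- function(spec, overlapTolerance = 0.999) {
  validObject(spec)
  folia <- lapply(spec@foliumSpecs, generateFolium)
  # cheap overlap screen on centerline control points
  if (spec@contour == "folia" && length(folia) > 1L) {
    for (i in seq_along(folia)[-1]) for (j in seq_len(i - 1L)) {
      pi_ <- folia[[i]]@spec@centerline
      pj <- folia[[j]]@spec@centerline
      dmin <- min(sqrt(outer(rowSums(pi_^2), rowSums(pj^2), "+") -
                         2 * pi_ %*% t(pj)))
      if (dmin < overlapTolerance *
            (folia[[i]]@spec@radius + folia[[j]]@spec@radius))
        warning(sprintf("folia %d and %d overlap; analytic union volume is overstated",
                        j, i), call. = FALSE)
    }
  }
  somaList <- withSeed(spec@rngSeed, {
    lapply(seq_along(folia), function(i) {
      s <- placeSomata(folia[[i]], spec@targetSurfaceDensity,
                       minSeparation = spec@minSeparation)
      if (nrow(s)) s$folium <- i
      s
    })
  })
  somaDf <- do.call(rbind, somaList[vapply(somaList, nrow, 0L) > 0])
  if (is.null(somaDf))
    somaDf <- data.frame(x = numeric(), y = numeric(), z = numeric(),
                         diameter = numeric(), folium = integer())
  rownames(somaDf) <- NULL
  bb <- spec@boundingBox
  vol <- if (spec@contour == "box") prod(bb[2, ] - bb[1, ]) / UM3_PER_MM3
         else sum(vapply(folia, foliumVolume, 0)) / UM3_PER_MM3
  area <- sum(vapply(folia, foliumMonolayerArea, 0)) / UM2_PER_MM2
  new("VirtualRegion", spec = spec, somata = somaDf, volumeMm3 = vol,
      monolayerAreaMm2 = area)
}

#' Export somata to CSV
#'
#' @param region a [VirtualRegion-class].
#' @param file path of the CSV to write.
#' @return the file path, invisibly.
#' @export
exportSomata <- function(region, file) {
  df <- somata(region)
  df$region <- regionName(region)
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}
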
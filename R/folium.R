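#' Create a folium specification
#'
#' @param centerline numeric matrix (n x 3) of centerline control points (um).
#' @param radius tube radius, centerline to pial surface (um).
#' @param pcOffset radial depth of the Purkinje cell monolayer beneath the
#'   pial surface (um).
#' @param jitterSd radial scatter (SD, um) of somata about the monolayer.
#' @param somaDiamMean,somaDiamSd soma diameter distribution (um).
#' @return a [FoliumSpec-class].
#' @examples
#' fs <- FoliumSpec(rbind(c(0, 0, 0), c(10000, 0, 0)), radius = 1000)
#' @export
FoliumSpec <- function(centerline, radius, pcOffset = 300, jitterSd = 20,
                       somaDiamMean = 25, somaDiamSd = 2.5) {
  new("FoliumSpec", centerline = as.matrix(centerline), radius = radius,
      pcOffset = pcOffset, jitterSd = jitterSd, somaDiamMean = somaDiamMean,
      somaDiamSd = somaDiamSd)
}

# Orthonormal frame (u, n, b) for each centerline segment.
.segmentFrames <- function(centerline) {
  a <- centerline[-nrow(centerline), , drop = FALSE]
  b <- centerline[-1, , drop = FALSE]
  seg <- b - a
  len <- sqrt(rowSums(seg^2))
  u <- seg / len
  # pick a reference axis not parallel to u
  ref <- ifelse(abs(u[, 1]) < 0.9, 1L, 2L)
  e <- matrix(0, nrow(u), 3)
  e[cbind(seq_len(nrow(u)), ref)] <- 1
  n <- e - u * rowSums(e * u)
  n <- n / sqrt(rowSums(n^2))
  bb <- cbind(u[, 2] * n[, 3] - u[, 3] * n[, 2],
              u[, 3] * n[, 1] - u[, 1] * n[, 3],
              u[, 1] * n[, 2] - u[, 2] * n[, 1])
  list(a = a, u = u, n = n, b = bb, len = len)
}

#' Generate a folium solid with analytic volume and monolayer area
#'
#' The solid is the tube of radius `radius` swept along the centerline with
#' flat end caps, so volume = pi r^2 L and monolayer area = 2 pi (r -
#' pcOffset) L with L the centerline length. These are exact for straight
#' tubes and accurate for gently curved centerlines (curvature radius much
#' larger than the tube radius); [mcVolume()] provides an independent
#' Monte-Carlo check.
#'
#' @param spec a [FoliumSpec-class].
#' @return a [Folium-class].
#' @examples
#' f <- generateFolium(FoliumSpec(rbind(c(0, 0, 0), c(10000, 0, 0)), 1000))
#' foliumVolume(f) / (pi * 1000^2 * 10000)  # ~1
#' @export
generateFolium <- function(spec) {
  validObject(spec)
  fr <- .segmentFrames(spec@centerline)
  L <- sum(fr$len)
  rho <- spec@radius - spec@pcOffset
  new("Folium", spec = spec, segLen = fr$len, length = L,
      volumeUm3 = pi * spec@radius^2 * L,
      monolayerAreaUm2 = 2 * pi * rho * L)
}

#' @rdname generateFolium
#' @param folium a [Folium-class].
#' @export
foliumVolume <- function(folium) folium@volumeUm3

#' @rdname generateFolium
#' @export
foliumMonolayerArea <- function(folium) folium@monolayerAreaUm2

# Is each point (matrix n x 3, um) inside the folium solid?
.insideFolium <- function(pts, folium) {
  fr <- .segmentFrames(folium@spec@centerline)
  r2 <- folium@spec@radius^2
  inside <- rep(FALSE, nrow(pts))
  for (i in seq_along(fr$len)) {
    w <- sweep(pts, 2, fr$a[i, ])
    t <- w %*% fr$u[i, ]
    rad2 <- rowSums(w^2) - t^2
    inside <- inside | (t >= 0 & t <= fr$len[i] & rad2 <= r2)
  }
  inside
}

#' Monte-Carlo volume of a folium or region
#'
#' Estimates the solid volume by uniform point sampling in the bounding box;
#' an independent check on the analytic tube volume.
#'
#' @param x a [Folium-class] or [VirtualRegion-class].
#' @param n number of sample points.
#' @param seed optional RNG seed.
#' @return estimated volume in um^3 (Folium) or mm^3 (VirtualRegion).
#' @export
mcVolume <- function(x, n = 1e5, seed = NULL) {
  withSeed(seed, {
    if (is(x, "Folium")) {
      cl <- x@spec@centerline
      r <- x@spec@radius
      lo <- apply(cl, 2, min) - r
      hi <- apply(cl, 2, max) + r
      pts <- cbind(runif(n, lo[1], hi[1]), runif(n, lo[2], hi[2]),
                   runif(n, lo[3], hi[3]))
      mean(.insideFolium(pts, x)) * prod(hi - lo)
    } else if (is(x, "VirtualRegion")) {
      bb <- x@spec@boundingBox
      pts <- cbind(runif(n, bb[1, 1], bb[2, 1]), runif(n, bb[1, 2], bb[2, 2]),
                   runif(n, bb[1, 3], bb[2, 3]))
      if (x@spec@contour == "box") {
        prod(bb[2, ] - bb[1, ]) / UM3_PER_MM3
      } else {
        inside <- rep(FALSE, n)
        for (fs in x@spec@foliumSpecs)
          inside <- inside | .insideFolium(pts, generateFolium(fs))
        mean(inside) * prod(bb[2, ] - bb[1, ]) / UM3_PER_MM3
      }
    } else stop("mcVolume needs a Folium or VirtualRegion")
  })
}

# Uniform points on the monolayer surface (segment chosen by length, angle
# uniform), radius displaced by N(0, jitterSd). Returns n x 3 matrix.
.surfacePoints <- function(folium, n, jitterSd) {
  if (n == 0L) return(matrix(numeric(), 0, 3))
  fr <- .segmentFrames(folium@spec@centerline)
  rho <- folium@spec@radius - folium@spec@pcOffset
  seg <- sample.int(length(fr$len), n, replace = TRUE, prob = fr$len)
  t <- runif(n) * fr$len[seg]
  th <- runif(n, 0, 2 * pi)
  rr <- rho + rnorm(n, 0, jitterSd)
  fr$a[seg, , drop = FALSE] + fr$u[seg, , drop = FALSE] * t +
    fr$n[seg, , drop = FALSE] * (rr * cos(th)) +
    fr$b[seg, , drop = FALSE] * (rr * sin(th))
}

#' Place Purkinje somata on a folium monolayer
#'
#' Somata are a Poisson process on the monolayer surface (expected count =
#' `surfaceDensity` x area), displaced radially by Normal(0, jitterSd), with
#' an optional hard-core minimum 3D separation enforced by sequential dart
#' throwing (candidates violating the separation against already-kept somata
#' are discarded and regenerated, up to a bounded retry budget).
#'
#' @param folium a [Folium-class].
#' @param surfaceDensity somata per mm^2 of monolayer surface (> 0 unless 0
#'   somata wanted).
#' @param jitterSd radial scatter SD (um); default from the spec.
#' @param minSeparation hard-core separation (um); 0 disables; default the
#'   spec's mean soma diameter.
#' @param seed optional RNG seed.
#' @return data.frame with columns x, y, z, diameter (um).
#' @export
placeSomata <- function(folium, surfaceDensity, jitterSd = NULL,
                        minSeparation = NULL, seed = NULL) {
  stopifnot(surfaceDensity >= 0)
  spec <- folium@spec
  if (is.null(jitterSd)) jitterSd <- spec@jitterSd
  if (is.null(minSeparation) || is.na(minSeparation))
    minSeparation <- spec@somaDiamMean
  withSeed(seed, {
    areaMm2 <- folium@monolayerAreaUm2 / UM2_PER_MM2
    nTarget <- rpois(1, surfaceDensity * areaMm2)
    if (nTarget == 0L)
      return(data.frame(x = numeric(), y = numeric(), z = numeric(),
                        diameter = numeric()))
    kept <- matrix(numeric(), 0, 3)
    if (minSeparation <= 0) {
      kept <- .surfacePoints(folium, nTarget, jitterSd)
    } else {
      tries <- 0L
      while (nrow(kept) < nTarget && tries < 12L) {
        need <- nTarget - nrow(kept)
        cand <- .surfacePoints(folium, ceiling(1.6 * need) + 20L, jitterSd)
        pool <- rbind(kept, cand)
        idx <- .hardcoreSelect(pool, minSeparation, nTarget)
        kept <- pool[idx, , drop = FALSE]
        tries <- tries + 1L
      }
      if (nrow(kept) < nTarget)
        stopMsg("stereoPC_packing_failure",
                "hard-core separation %.1f um too large to reach %d somata (%d placed)",
                minSeparation, nTarget, nrow(kept))
    }
    # lognormal diameters, clipped
    m <- spec@somaDiamMean; s <- spec@somaDiamSd
    if (s > 0) {
      sdlog <- sqrt(log(1 + (s / m)^2))
      d <- rlnorm(nTarget, log(m) - sdlog^2 / 2, sdlog)
      d <- pmin(pmax(d, 10), m + 4 * s)
    } else d <- rep(m, nTarget)
    data.frame(x = kept[, 1], y = kept[, 2], z = kept[, 3], diameter = d)
  })
}
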
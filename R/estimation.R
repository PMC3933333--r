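#' Estimate Purkinje cell density from a region sample
#'
#' Density is the total disector count divided by the summed volume of the
#' counting boxes (PC/mm^3), with precision summarised by the Gundersen
#' (m = 1) coefficient of error over the ordered per-section counts.
#'
#' @param sample a [RegionSample-class].
#' @return a [DensityEstimate-class]. The CE is NA (flagged with a warning)
#'   when the total count is zero; estimating with zero frames is an error.
#' @examples
#' # 450 PCs in 1106 boxes of 19,600 um^2 x 75 um -> ~276.8 PC/mm^3
#' 450 / (1106 * 19600 * 75 / 1e9)
#' @export
estimateDensity <- function(sample) {
  validObject(sample)
  if (sum(sample@nFrames) == 0)
    stopMsg("stereoPC_undefined_density",
            "no counting frames were placed; density undefined")
  qTot <- sum(sample@q)
  ce <- if (length(sample@q) >= 3L) gundersenCE(sample@q) else {
    warning("fewer than 3 sections; CE undefined", call. = FALSE)
    NA_real_
  }
  new("DensityEstimate", region = sample@region, qTotal = qTot,
      vSampledMm3 = sample@sampledVolumeMm3,
      density = qTot / sample@sampledVolumeMm3, ce = ce,
      nFrames = sum(sample@nFrames), nSections = length(sample@q))
}

#' Gundersen (m = 1) coefficient of error for SURS counts
#'
#' For per-section counts Q_i ordered by section position, the estimator
#' combines a Poisson "noise" term with a smoothed serial-covariance term:
#' noise = sum(Q_i), A = sum(Q_i^2), B = sum(Q_i Q_{i+1}),
#' C = sum(Q_i Q_{i+2}), Var_SURS = (3 (A - noise) - 4 B + C) / 240, and
#' CE = sqrt(noise + Var_SURS) / sum(Q_i). The section order must be the
#' anatomical (SURS) order, not magnitude order.
#'
#' @param q per-section counts in section order (>= 3 sections).
#' @return the CE; NA with a warning when all counts are zero.
#' @examples
#' gundersenCE(c(10, 10, 10, 10, 10))  # ~0.1417
#' @export
gundersenCE <- function(q) {
  if (length(q) < 3L)
    stopMsg("stereoPC_insufficient_sections",
            "Gundersen CE needs >= 3 sections (got %d)", length(q))
  total <- sum(q)
  if (total == 0) {
    warning("zero total count; CE undefined", call. = FALSE)
    return(NA_real_)
  }
  A <- sum(q^2)
  B <- sum(q[-length(q)] * q[-1])
  C <- if (length(q) >= 3L) sum(q[seq_len(length(q) - 2L)] *
                                  q[-(1:2)]) else 0
  varSurs <- max(0, (3 * (A - total) - 4 * B + C) / 240)
  sqrt(total + varSurs) / total
}

#' Cavalieri regional volume from planimetric section areas
#'
#' volume = sum(area_i) x thickness x period, unbiased under the systematic
#' uniform random section start.
#'
#' @param areasMm2 per-section planimetric areas (mm^2).
#' @param thicknessUm section thickness (um).
#' @param period series period (1-in-`period` sections).
#' @return volume in mm^3.
#' @examples
#' cavalieriVolume(c(2, 2, 2), 200, 6)  # 7.2 mm^3
#' @export
cavalieriVolume <- function(areasMm2, thicknessUm = 200, period = 6) {
  if (!length(areasMm2) || all(areasMm2 <= 0))
    stopMsg("stereoPC_zero_volume", "no section with positive area")
  sum(areasMm2) * thicknessUm * period / 1e3
}

#' @rdname cavalieriVolume
#' @param sample a [RegionSample-class] (areas and design taken from it).
#' @export
cavalieriVolumeOf <- function(sample, thicknessUm = 200, period = 6) {
  cavalieriVolume(sample@areaMm2, thicknessUm, period)
}

#' Regional-volume-weighted overall density
#'
#' The composite overall PC density sum(V_r D_r) / sum(V_r); regions with a
#' missing density or volume are excluded from both sums (cases with
#' incompletely sampled regions contribute only their sampled regions).
#'
#' @param densities named (or positional) densities per region (PC/mm^3);
#'   NA = missing.
#' @param volumes matching regional volumes (mm^3).
#' @return the weighted overall density.
#' @examples
#' overallWeightedDensity(c(100, 200), c(1, 3))  # 175
#' @export
overallWeightedDensity <- function(densities, volumes) {
  if (!is.null(names(densities)) && !is.null(names(volumes)))
    volumes <- volumes[names(densities)]
  ok <- is.finite(densities) & is.finite(volumes) & volumes > 0
  if (!any(ok))
    stopMsg("stereoPC_no_regions", "no region with both density and volume")
  sum(densities[ok] * volumes[ok]) / sum(volumes[ok])
}
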
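# Shared fixtures, built once per test run and cached.

.cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.cache[[key]])) .cache[[key]] <- builder()
  .cache[[key]]
}

# survey-scale lobule X phantom (smallest full-scale region, ~59k somata)
lobXRegion <- function() cached("lobX", function()
  assembleRegion(defaultRegionSpec("lobuleX", rngSeed = 42)))

# a single straight horizontal cylinder with its own ("folia") contour:
# radius 1 mm, monolayer at 700 um, 10 mm long, centred in a roomy box
cylinderSpec <- function(density = 300, seed = 7) {
  fs <- FoliumSpec(rbind(c(300, 2000, 2000), c(10300, 2000, 2000)),
                   radius = 1000)
  RegionSpec("cylinder", list(fs),
             boundingBox = rbind(c(0, 0, 0), c(10600, 4000, 4000)),
             targetSurfaceDensity = density * (pi * 1000^2 * 10000 / 1e9) /
               (2 * pi * 700 * 10000 / 1e6),
             contour = "folia", rngSeed = seed)
}

cylinderRegion <- function() cached("cylinder", function()
  assembleRegion(cylinderSpec()))

# small box phantom with a single monolayer plane of somata for fast
# counting-rule tests: somata at given xy positions, fixed z
pointSetRegion <- function(xy, diameter = 1, z = 600, box = c(4000, 4000, 2400)) {
  fs <- FoliumSpec(rbind(c(500, box[2] / 2, box[3] / 2),
                         c(box[1] - 500, box[2] / 2, box[3] / 2)),
                   radius = 450, pcOffset = 300)
  spec <- RegionSpec("pointset", list(fs),
                     boundingBox = rbind(c(0, 0, 0), box),
                     targetSurfaceDensity = 0, contour = "box", rngSeed = 1L)
  reg <- assembleRegion(spec)
  reg@somata <- data.frame(x = xy[, 1], y = xy[, 2],
                           z = rep_len(z, nrow(xy)),
                           diameter = rep_len(diameter, nrow(xy)),
                           folium = 1L)
  validObject(reg)
  reg
}

defaultLongTable <- function(sim) {
  spec <- sim$spec
  long <- merge(sim$densities,
                sim$profiles[, c("case_id", "diagnosis", "sex",
                                 "brain_weight_g")], by = "case_id")
  long$logDensity <- log(long$measured)
  long$regionalVolume <- spec@regionalVolumeMm3[long$region]
  long
}
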
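test_that("a 12 mm region cut at 200 um / period 6 yields 10 sections", {
  reg <- pointSetRegion(cbind(2000, 2000), box = c(4000, 4000, 12000),
                        z = 600)
  ss <- cutSections(reg, SectionSeries(200, 6, startOffset = 0))
  expect_length(ss@zTop, 10)
  # and for arbitrary random starts the count is unchanged (extent is a
  # whole number of periods)
  for (seed in 1:5)
    expect_length(cutSections(reg, SectionSeries(200, 6), seed = seed)@zTop,
                  10)
})

test_that("period 1 with zero offset partitions every soma into exactly one section", {
  xy <- cbind(runif(200, 600, 3400), runif(200, 600, 3400))
  reg <- pointSetRegion(xy, z = runif(200, 100, 2300))
  ss <- cutSections(reg, SectionSeries(200, 1, startOffset = 0))
  expect_false(anyNA(ss@somaSection))
  expect_identical(length(ss@somaSection), nrow(somata(reg)))
  # each soma in the section containing its leading edge
  zl <- somata(reg)$z - somata(reg)$diameter / 2
  expect_true(all(zl >= ss@zTop[ss@somaSection] &
                    zl < ss@zTop[ss@somaSection] + 200))
})

test_that("Cavalieri sum of section areas is consistent with the analytic volume", {
  reg <- cylinderRegion()
  vols <- withr::with_seed(21, replicate(200, {
    ss <- cutSections(reg, SectionSeries(200, 6))
    sum(ss@areaMm2) * 200 * 6 / 1e3
  }))
  expect_lt(abs(mean(vols) / regionVolume(reg) - 1), 0.05)
})

test_that("degradation with zero loss and fray is the identity", {
  reg <- lobXRegion()
  ss <- cutSections(reg, SectionSeries(startOffset = 100))
  dg <- applyDegradation(ss, 0, 0, seed = 1)
  expect_identical(dg@zTop, ss@zTop)
  expect_identical(dg@somaSection, ss@somaSection)
  expect_identical(dg@areaMm2, ss@areaMm2)
})

test_that("10% loss removes the right number of sections; too much loss errors", {
  xy <- cbind(runif(50, 600, 3400), runif(50, 600, 3400))
  reg <- pointSetRegion(xy, z = runif(50, 100, 47900),
                        box = c(4000, 4000, 48000))
  ss <- cutSections(reg, SectionSeries(200, 6, startOffset = 0))
  expect_length(ss@zTop, 40)
  dg <- applyDegradation(ss, 0.10, 0, seed = 3)
  expect_length(dg@zTop, 36)
  expect_error(applyDegradation(ss, 0.95, 0, seed = 3),
               class = "stereoPC_insufficient_sections")
})

test_that("density remains approximately estimable after loss and fraying", {
  reg <- lobXRegion()
  des <- SamplingDesign()
  est <- withr::with_seed(31, replicate(60, {
    pcDensity(estimateDensity(sampleRegion(reg, design = des,
                                           lossFraction = 0.10,
                                           frayDepthUm = 50)))
  }))
  expect_lt(abs(mean(est) / trueDensity(reg) - 1), 0.05)
})

test_that("frame placement: 4x4 grid on a 10x10 mm footprint at 2.5 mm pitch", {
  xy <- cbind(5000, 5000)
  reg <- pointSetRegion(xy, box = c(10000, 10000, 2400), z = 600)
  ss <- cutSections(reg, SectionSeries(200, 6, startOffset = 0))
  fr <- placeFrames(ss, 1, SamplingDesign(pitch = 2500), offset = c(0, 0))
  expect_identical(nrow(fr), 16L)
  expect_true(all(fr$side == 140))
})

test_that("no frames are placed on a section without region footprint", {
  reg <- pointSetRegion(cbind(2000, 2000), box = c(4000, 4000, 2400))
  ss <- cutSections(reg, SectionSeries(200, 1, startOffset = 0))
  empty <- ss
  empty@footprints[1] <- list(NULL)
  fr <- placeFrames(empty, 1, SamplingDesign(pitch = 400), offset = c(0, 0))
  expect_identical(nrow(fr), 0L)
})

test_that("expected frame count equals footprint area / pitch^2", {
  reg <- pointSetRegion(cbind(2000, 2000), box = c(9000, 7000, 2400))
  ss <- cutSections(reg, SectionSeries(200, 1, startOffset = 0))
  des <- SamplingDesign(pitch = 1300)
  n <- withr::with_seed(41, replicate(300, nrow(placeFrames(ss, 1, des))))
  expected <- 9000 * 7000 / 1300^2
  expect_lt(abs(mean(n) - expected), 3 * sd(n) / sqrt(length(n)))
})

test_that("disector counting rule: guard, inclusion and exclusion edges", {
  som <- data.frame(x = 2000, y = 2000, z = 630, diameter = 20)
  frame <- list(x0 = 1950, y0 = 1950, side = 140, zLow = 605, zHigh = 680)
  # leading edge z = 620, inside (605, 680] -> counted
  expect_identical(countFrame(frame, som), 1L)
  # leading edge inside the guard -> not counted
  som2 <- transform(som, z = 610)  # leading edge 600 < 605
  expect_identical(countFrame(frame, som2), 0L)
  expect_identical(countFrame(frame, som[0, ]), 0L)
  # touching the exclusion (left) edge excludes even if inside the frame
  som3 <- data.frame(x = 1955, y = 2000, z = 630, diameter = 20)
  expect_identical(countFrame(frame, som3), 0L)
  # touching the inclusion (top) edge counts
  som4 <- data.frame(x = 2000, y = 2095, z = 630, diameter = 20)
  expect_identical(countFrame(frame, som4), 1L)
})

test_that("exhaustive tiling counts every soma exactly once", {
  for (seed in c(2, 12, 22)) {
    withr::with_seed(seed, {
      n <- 400
      xy <- cbind(runif(n, 200, 3800), runif(n, 200, 3800))
      reg <- pointSetRegion(xy, diameter = runif(n, 5, 30),
                            z = runif(n, 120, 2280))
    })
    ss <- cutSections(reg, SectionSeries(2400, 1, startOffset = 0))
    som <- somata(reg)
    cells <- stereoPC:::.placedCells(ss@footprints[[1]], 37, 59, 140, 140,
                                     "centroid")
    res <- stereoPC:::.countSection(som, 37, 59, 140, 140, cells,
                                    0, 2400)
    expect_identical(res$q, nrow(som))
    expect_true(all(res$perSoma == 1L))
  }
})

test_that("counting is translation-consistent", {
  withr::with_seed(5, {
    xy <- cbind(runif(200, 500, 3500), runif(200, 500, 3500))
    reg <- pointSetRegion(xy, diameter = 10, z = runif(200, 120, 2280))
  })
  ss <- cutSections(reg, SectionSeries(2400, 1, startOffset = 0))
  som <- somata(reg)
  count <- function(som, ox, oy) {
    cells <- stereoPC:::.placedCells(rbind(c(-1000, 5000, -1000, 5000)),
                                     ox, oy, 500, 140, "centroid")
    stereoPC:::.countSection(som, ox, oy, 500, 140, cells, 0, 2400)$q
  }
  q1 <- count(som, 100, 200)
  som2 <- transform(som, x = x + 321, y = y - 77)
  q2 <- count(som2, 100 + 321, 200 - 77)
  expect_identical(q1, q2)
})

test_that("batch counting agrees with countFrame frame by frame", {
  withr::with_seed(6, {
    xy <- cbind(runif(300, 300, 3700), runif(300, 300, 3700))
    reg <- pointSetRegion(xy, diameter = runif(300, 8, 28),
                          z = runif(300, 100, 2300))
  })
  ss <- cutSections(reg, SectionSeries(200, 1, startOffset = 0))
  des <- SamplingDesign(pitch = 400)
  for (i in c(2, 5, 9)) {
    fr <- placeFrames(ss, i, des, offset = c(55, 210))
    som <- somata(reg)[which(ss@somaSection == i), , drop = FALSE]
    single <- sum(vapply(seq_len(nrow(fr)), function(k)
      countFrame(fr[k, ], som), 0L))
    cells <- stereoPC:::.placedCells(ss@footprints[[i]], 55, 210, 400, 140,
                                     "centroid")
    batch <- stereoPC:::.countSection(som, 55, 210, 400, 140, cells,
                                      fr$zLow[1], fr$zHigh[1])$q
    expect_identical(batch, single)
  }
})

test_that("summed disector volume is exactly nFrames x frame area x height", {
  samp <- sampleRegion(lobXRegion(), seed = 3)
  expect_equal(sampledVolume(samp),
               sum(samp@nFrames) * 19600 * 75 / 1e9, tolerance = 1e-12)
  expect_equal(sampledVolume(samp) / sum(samp@nFrames) * 1e9, 1.47e6)
})

test_that("a degenerate exhaustive design recovers the section census", {
  withr::with_seed(8, {
    xy <- cbind(runif(250, 200, 3800), runif(250, 200, 3800))
    reg <- pointSetRegion(xy, diameter = 10, z = runif(250, 150, 2250))
  })
  des <- SamplingDesign(frameArea = 19600, guardDepth = 0,
                        disectorHeight = 2400, pitch = 140)
  samp <- sampleRegion(reg, SectionSeries(2400, 1, startOffset = 0), des,
                       seed = 4)
  expect_identical(as.integer(sum(frameCounts(samp))), nrow(somata(reg)))
})

test_that("invalid designs are rejected", {
  expect_error(SamplingDesign(pitch = 100), "pitch")
  expect_error(sampleRegion(lobXRegion(), SectionSeries(70, 6),
                            SamplingDesign(pitch = 400)),
               class = "stereoPC_config")
})
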
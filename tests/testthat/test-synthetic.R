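# The synthetic generator: determinism, emission calibration and ground
# truth bookkeeping.

test_that("the generator is deterministic given its seed", {
  spec <- syntheticSpec(variables = c(canonicalGroups(), "SST"),
                        nWeeks = 60, seed = 31)
  t1 <- sampleTimeseries(spec)
  t2 <- sampleTimeseries(spec)
  expect_identical(sampleValues(t1), sampleValues(t2))
  expect_identical(sampleDates(t1), sampleDates(t2))
  t3 <- sampleTimeseries(syntheticSpec(variables = c(canonicalGroups(),
                                                     "SST"),
                                       nWeeks = 60, seed = 32))
  expect_false(identical(sampleValues(t1), sampleValues(t3)))
})

test_that("specs validate their emission parameters", {
  expect_error(syntheticSpec(emission = list(piLow = 0.2, piHigh = 0.01,
                                             muLow = 10, muHigh = 5,
                                             size = 1)), "muLow")
  expect_error(syntheticSpec(emission = list(piLow = 1.2, piHigh = 0.01,
                                             muLow = 1, muHigh = 5,
                                             size = 1)), "zero-inflation")
  expect_error(syntheticSpec(samplesPerWeek = 0:2), "samplesPerWeek")
  expect_error(syntheticSpec(variables = c("Shelf Sea")), "parent")
  expect_error(syntheticSpec(variables = c("Kraken", "SST")), "unknown")
})

test_that("weekly-averaged zero mass sits near the calibrated 39%", {
  spec <- syntheticSpec(seed = 33)   # default: ~30 years, ~1565 weeks
  wk <- weeklyAverage(sampleTimeseries(spec))
  expect_gte(nrow(wk), 1500L)
  zf <- mean(sampleValues(wk)[, canonicalGroups()] == 0)
  expect_lt(abs(zf - 0.39), 0.03)
})

test_that("HIGH-state weeks out-count LOW-state weeks for every group", {
  spec <- syntheticSpec(variables = c(canonicalGroups(), "SST"),
                        nWeeks = 400, seed = 34)
  wk <- weeklyAverage(sampleTimeseries(spec))
  d <- discretizeThreeBins(wk)
  for (g in canonicalGroups()) {
    v <- sampleValues(wk)[, g]
    s <- stateMatrix(d)[, g]
    expect_gt(mean(v[s == 3L]), mean(v[s == 2L]))
  }
})

test_that("the SST sinusoid has the configured annual cycle", {
  spec <- syntheticSpec(variables = c(canonicalGroups(), "SST"),
                        nYears = 4, regimeShiftYear = NA, seed = 35)
  st <- sampleTimeseries(spec)
  sstv <- sampleValues(st)[, "SST"]
  mo <- as.integer(format(sampleDates(st), "%m"))
  expect_gt(mean(sstv[mo == 8]), mean(sstv[mo == 2]) + 4)
})

test_that("spatial snapshots have the configured station count", {
  sp <- spatialSpec(seed = 36)
  st <- sampleSpatial(sp)
  expect_equal(nrow(st), 144L)
  expect_length(st@lon, 144L)
  st2 <- sampleSpatial(spatialSpec(nStations = 20, seed = 36))
  expect_equal(nrow(st2), 20L)
  # determinism
  expect_identical(sampleValues(sampleSpatial(sp)),
                   sampleValues(sampleSpatial(sp)))
})

test_that("negative Aurelia-Warm Temperate dependence shows in the states", {
  hits <- 0L
  nSeeds <- 10L
  for (sd in seq_len(nSeeds)) {
    st <- sampleSpatial(spatialSpec(seed = 200 + sd))
    d <- discretizeThreeBins(st)
    s <- stateMatrix(d)
    hits <- hits + (cor(s[, "Aurelia aurita"], s[, "Warm Temperate"]) < 0)
  }
  expect_gte(hits / nSeeds, 0.9)
})

test_that("severing the jellyfish edges leaves states independent", {
  # null calibration: with no generating edge, the dependence test should
  # not fire beyond its nominal rate
  ps <- vapply(1:15, function(sd) {
    sp <- spatialSpec(seed = 300 + sd)
    sp$truth@edges <- matrix(character(0), 0, 2,
                             dimnames = list(NULL, c("parent", "child")))
    sp$truth@cpts[["Aurelia aurita"]] <-
      structure(c(ZERO = 1, LOW = 1, HIGH = 1) / 3,
                parents = character(0), configWeights = 1)
    sp$truth@cpts[["Other jellyfish"]] <-
      structure(c(ZERO = 1, LOW = 1, HIGH = 1) / 3,
                parents = character(0), configWeights = 1)
    st <- sampleSpatial(sp)
    d <- discretizeThreeBins(st)
    bl <- contingencyFilter(d)
    t <- bl@tests
    t$p[t$var1 == "Aurelia aurita" & t$var2 == "Warm Temperate"]
  }, numeric(1))
  # p-values roughly uniform: no pile-up below 0.05
  expect_lte(mean(ps < 0.05), 0.25)
  expect_gt(mean(ps), 0.2)
})

test_that("ground-truth edges report the generating structure", {
  spec <- syntheticSpec(seed = 37)
  pre <- groundTruthEdges(spec, "pre")
  post <- groundTruthEdges(spec, "post")
  expect_true(any(pre[, 1] == "SST" & pre[, 2] == "Warm Temperate"))
  # the regime shift joins the two sub-networks
  expect_true(any(post[, 1] == "Shelf Sea" &
                    post[, 2] == "Warm Temperate Oceanic"))
  expect_false(any(pre[, 1] == "Shelf Sea" &
                     pre[, 2] == "Warm Temperate Oceanic"))
  sp <- spatialSpec(seed = 38)
  gt <- groundTruthEdges(sp)
  expect_true(any(gt[, 2] == "Aurelia aurita"))
})

test_that("a synthetic catch series follows its driver monotonically", {
  spec <- syntheticSpec(variables = c(canonicalGroups(), "SST"),
                        nYears = 8, regimeShiftYear = NA, seed = 39)
  st <- sampleTimeseries(spec)
  catch <- syntheticHerring(st, "Shelf Sea")
  yearly <- yearlyAverageFromSeptember(st)
  v <- sampleValues(yearly)[, "Shelf Sea"]
  expect_equal(order(catch$catch), order(v))
  expect_equal(catch$year, as.integer(rownames(sampleValues(yearly))) + 1L)
})
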
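test_that("degenerate generator parameters give the constant baseline", {
  specs <- genusProcessSpec("A", baseline = 40)
  gen <- generateSeries(syntheticTruth(specs, seed = 1, length = 30))
  expect_true(all(abundanceMatrix(gen$series) == 40))
  expect_identical(nrow(gen$labels), 0L)
})

test_that("events are applied post-noise and labelled exactly", {
  specs <- genusProcessSpec(c("A", "B"), baseline = c(100, 50))
  ev <- shiftEvent(20, "A", kind = "spike", magnitude = 3)
  gen <- generateSeries(syntheticTruth(specs, events = ev, seed = 2,
                                       length = 40))
  m <- abundanceMatrix(gen$series)
  expect_equal(m[20, "A"], 300)
  expect_equal(m[19, "A"], 100)
  expect_true(all(m[, "B"] == 50))
  expect_identical(gen$labels,
                   data.frame(timestep = 20L, genus = "A",
                              kind = "spike", stringsAsFactors = FALSE))

  ## level shift in noise-sd units and dropout to zero
  specs2 <- genusProcessSpec("A", baseline = 100, noiseSd = 10)
  ev2 <- rbind(shiftEvent(5, "A", "level_shift", magnitude = 5),
               shiftEvent(9, "A", "dropout", magnitude = 1))
  gen2 <- generateSeries(syntheticTruth(specs2, events = ev2, seed = 3,
                                        length = 12))
  m2 <- abundanceMatrix(gen2$series)
  expect_equal(m2[9, "A"], 0)
  expect_identical(nrow(gen2$labels), 2L)
})

test_that("generation is bit-identical under the same seed", {
  lib <- scenarioLibrary()
  g1 <- generateSeries(lib$gut_dense, T = 60)
  g2 <- generateSeries(lib$gut_dense, T = 60)
  expect_identical(abundanceMatrix(g1$series), abundanceMatrix(g2$series))
  expect_identical(g1$labels, g2$labels)
  g3 <- generateSeries(lib$wastewater_weekly, T = 60)
  g4 <- generateSeries(lib$wastewater_weekly, T = 60)
  expect_identical(abundanceMatrix(g3$series), abundanceMatrix(g4$series))
  expect_identical(g3$metadata, g4$metadata)
})

test_that("presets match their sampling designs", {
  lib <- scenarioLibrary()
  expect_named(lib, c("gut_dense", "wastewater_monthly_gappy",
                      "wastewater_weekly"))
  expect_identical(lib$gut_dense@length, 396L)
  expect_length(lib$gut_dense@covariates, 0)
  gd <- generateSeries(lib$gut_dense)
  expect_identical(ncol(gd$series), 396L)
  expect_true(all(abundanceMatrix(gd$series) >= 0))
  expect_true(all(abundanceMatrix(gd$series) ==
                  round(abundanceMatrix(gd$series))))

  ## monthly preset drops every winter month
  mg <- generateSeries(lib$wastewater_monthly_gappy)
  kept <- as.integer(timeStamps(mg$series))
  month <- ((kept - 1) %% 12) + 1    # step 1 = January
  expect_false(any(month %in% c(12, 1, 2)))
  expect_true(all(c("temperature", "precipitation") %in%
                  colnames(covariateMatrix(mg$series))))
})

test_that("AR coefficient and seasonal period are recoverable", {
  ## lag-1 autocorrelation of a pure AR(1) genus approaches phi
  phi <- 0.6
  specs <- genusProcessSpec("A", baseline = 1000, arCoefficient = phi,
                            noiseSd = 40)
  gen <- generateSeries(syntheticTruth(specs, seed = 7, length = 3000))
  x <- abundanceMatrix(gen$series)[, 1]
  expect_equal(stats::acf(x, plot = FALSE)$acf[2], phi, tolerance = 0.08)

  ## dominant seasonal period recovered from the ACF peak
  specs2 <- genusProcessSpec("A", baseline = 1000,
                             seasonalAmplitude = 300,
                             seasonalPeriod = 24, noiseSd = 20)
  gen2 <- generateSeries(syntheticTruth(specs2, seed = 8, length = 480))
  x2 <- abundanceMatrix(gen2$series)[, 1]
  a <- stats::acf(x2, lag.max = 40, plot = FALSE)$acf[-1]
  ## peak away from the origin sits at the period
  expect_identical(which.max(a[10:40]) + 9L, 24L)
})

test_that("row-wise missingness drops whole samples and their labels", {
  specs <- genusProcessSpec(c("A", "B"), baseline = c(100, 50),
                            noiseSd = c(5, 2))
  truth <- syntheticTruth(specs, seed = 9, length = 100,
                          missingProb = 0.3)
  gen <- generateSeries(truth)
  expect_lt(ncol(gen$series), 100L)
  kept <- as.integer(timeStamps(gen$series))
  expect_true(all(gen$labels$timestep %in% kept))
  ## timestamps expose the gaps but remain strictly increasing
  expect_true(all(diff(kept) >= 1))
})

test_that("synthetic datasets round-trip through the canonical writers", {
  dir <- withr::local_tempdir()
  lib <- scenarioLibrary()
  gen <- generateSeries(lib$gut_dense, T = 40)
  paths <- writeSyntheticDataset(gen, dir)
  back <- readAbundanceTable(paths["table"])
  expect_equal(abundanceMatrix(back), abundanceMatrix(gen$series))
  meta <- readSampleMetadata(paths["metadata"])
  expect_identical(nrow(meta), ncol(gen$series))
})
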
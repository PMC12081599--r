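test_that("scaler fits per-genus min-max on the training partition only", {
  m <- cbind(A = c(0, 5, 10), B = c(2, 2, 6))
  params <- fitScaler(m)
  expect_equal(params@mins[["A"]], 0)
  expect_equal(params@maxs[["A"]], 10)
  expect_equal(params@mins[["B"]], 2)
  ## independent per-genus params match direct column-wise min/max
  expect_equal(unname(params@mins), apply(m, 2, min), ignore_attr = TRUE)
  expect_equal(unname(params@maxs), apply(m, 2, max), ignore_attr = TRUE)

  ## constant genus is degenerate and transforms to 0
  mc <- cbind(A = c(0, 5, 10), C = c(3, 3, 3))
  pc <- fitScaler(mc)
  expect_true(pc@degenerate[["C"]])
  sc <- scaleAbundance(mc, pc)
  expect_true(all(sc[, "C"] == 0))
  expect_true(all(inverseScale(sc, pc)[, "C"] == 3))

  ## leakage guard: fitted through a split, test values can leave [0,1]
  T <- 20
  mm <- matrix(seq_len(T), ncol = 1, dimnames = list(NULL, "A"))
  s <- AbundanceSeries(mm)
  p <- fitScaler(s, split = splitSpec(0.8, 0))
  full <- scaleAbundance(s, p)
  trainRows <- full[1:16, ]
  expect_true(all(trainRows >= 0 & trainRows <= 1))
  expect_gt(max(full[17:20, ]), 1)    # not clipped, visible to the detector
})

test_that("transform and inverse are exact and unclipped", {
  params <- fitScaler(cbind(A = c(0, 5, 10)))
  expect_equal(as.numeric(scaleAbundance(cbind(A = c(0, 5, 10)), params)),
               c(0, 0.5, 1.0))
  ## out-of-range value scales past 1 without clipping
  expect_equal(as.numeric(scaleAbundance(cbind(A = 20), params)), 2.0)
  ## round trip on a random non-constant matrix
  set.seed(3)
  m <- matrix(runif(200, 0, 50), 20,
              dimnames = list(NULL, sprintf("g%02d", 1:10)))
  p <- fitScaler(m)
  expect_lt(max(abs(inverseScale(scaleAbundance(m, p), p) - m)), 1e-9)
  ## unseen genus is an error
  expect_error(scaleAbundance(cbind(Zzz = 1), p), "not seen")
})

test_that("chronological split yields ordered contiguous disjoint blocks", {
  s <- toySeries(T = 100)
  parts <- chronologicalSplit(s, splitSpec(0.8, 0.1))
  expect_identical(ncol(parts$test), 20L)           # last 20 points
  expect_identical(ncol(parts$train), 72L)
  expect_identical(ncol(parts$validation), 8L)
  idx <- parts$indices
  expect_identical(c(idx$train, idx$validation, idx$test), 1:100)

  s10 <- toySeries(T = 10)
  p10 <- chronologicalSplit(s10, splitSpec(0.8, 0))
  expect_identical(ncol(p10$train), 8L)
  expect_null(p10$validation)
  expect_identical(ncol(p10$test), 2L)

  s4 <- toySeries(T = 4)
  expect_error(chronologicalSplit(s4, splitSpec(0.8, 0),
                                  window = windowConfig(lag = 3)),
               "cannot form a window")
})

test_that("windowing obeys the count law and the target alignment", {
  set.seed(4)
  sc <- matrix(runif(20), 10, 2, dimnames = list(NULL, c("A", "B")))
  w <- makeWindows(sc, windowConfig(lag = 3))
  expect_identical(dim(w@inputs)[1], 7L)            # T - lag
  ## brute-force enumeration: first target is row 4 of the partition
  expect_equal(w@targets[1, ], sc[4, ])
  expect_equal(matrix(w@inputs[1, , ], 3), sc[1:3, ], ignore_attr = TRUE)
  expect_equal(w@targets[7, ], sc[10, ])
  expect_identical(w@targetSteps, 4:10)

  ## count law over randomized (T, lag)
  set.seed(5)
  for (i in 1:25) {
    T <- sample(5:40, 1)
    lag <- sample(1:(T - 1), 1)
    m <- matrix(runif(T * 2), T, 2, dimnames = list(NULL, c("A", "B")))
    wi <- makeWindows(m, windowConfig(lag = lag))
    expect_identical(dim(wi@inputs)[1], T - lag)
  }
  expect_error(makeWindows(sc[1:3, ], windowConfig(lag = 3)),
               "must exceed lag")
})

test_that("covariate columns widen windows and missing covariates error", {
  sc <- matrix(runif(20), 10, 2, dimnames = list(NULL, c("A", "B")))
  cov <- matrix(rnorm(10), 10, 1, dimnames = list(NULL, "temperature"))
  w <- makeWindows(sc, windowConfig(lag = 3,
                                    covariateNames = "temperature"),
                   covariates = cov)
  expect_identical(dim(w@inputs)[3], 3L)            # 2 genera + 1 covariate
  expect_identical(ncol(w@targets), 2L)             # targets: genera only
  cov[5, 1] <- NA
  expect_error(makeWindows(sc, windowConfig(lag = 3,
                                            covariateNames = "temperature"),
                           covariates = cov),
               "covariate missing for time step 5")
})

test_that("split-aware windowing gives validation/test full lag context", {
  set.seed(6)
  sc <- matrix(runif(60), 30, 2, dimnames = list(NULL, c("A", "B")))
  s <- AbundanceSeries(matrix(rpois(60, 10), 30,
                              dimnames = list(NULL, c("A", "B"))))
  parts <- chronologicalSplit(s, splitSpec(0.8, 0.1))
  wins <- windowSplits(sc, parts$indices, windowConfig(lag = 3))
  ## every test row is a prediction target
  expect_identical(wins$test@targetSteps, parts$indices$test)
  expect_identical(wins$validation@targetSteps, parts$indices$validation)
  ## a test window's lags are the immediately preceding rows of the series
  firstTest <- parts$indices$test[1]
  expect_equal(matrix(wins$test@inputs[1, , ], 3),
               sc[(firstTest - 3):(firstTest - 1), ], ignore_attr = TRUE)
})
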
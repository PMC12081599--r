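test_that("mock forecasters satisfy the one-step contract", {
  g <- c("A", "B")
  w <- matrix(1:6, 3, 2, dimnames = list(NULL, g))
  expect_equal(predictStep(identityMock(g), w), c(3, 6))
  expect_equal(predictStep(constantMock(g, 7), w), c(7, 7))
  expect_error(predictStep(identityMock(g), w[1:2, ]), "window shape")
  wNA <- w; wNA[1, 1] <- NA
  expect_error(predictStep(identityMock(g), wNA), "NaN/NA")
})

test_that("random forest learns an exactly computable lag relationship", {
  ## noiseless construction: target = mean of the 3 preceding values
  set.seed(11)
  x <- runif(120)
  sc <- cbind(A = x)
  w <- makeWindows(sc, windowConfig(lag = 3))
  w@targets[, 1] <- vapply(seq_len(nrow(w@targets)), function(i)
    mean(w@inputs[i, , 1]), numeric(1))
  rf <- fitForecaster(rfConfig(nTrees = 100, seed = 1), w)
  trainMae <- mae(w@targets, predictWindows(rf, w))
  expect_lt(trainMae, 0.05)   # far below the sd of the target (~0.17)

  ## constant series -> constant prediction (all leaves identical)
  wc <- w
  wc@inputs[] <- 0.5
  wc@targets[] <- 0.5
  rfc <- fitForecaster(rfConfig(nTrees = 20, seed = 1), wc)
  expect_equal(unname(predictStep(rfc, matrix(0.5, 3, 1))), 0.5)
})

test_that("random forest fits are deterministic given the seed", {
  set.seed(12)
  sc <- matrix(runif(80), 40, 2, dimnames = list(NULL, c("A", "B")))
  w <- makeWindows(sc, windowConfig(lag = 3))
  f1 <- fitForecaster(rfConfig(nTrees = 50, seed = 9), w)
  f2 <- fitForecaster(rfConfig(nTrees = 50, seed = 9), w)
  expect_identical(predictWindows(f1, w), predictWindows(f2, w))
  f3 <- fitForecaster(rfConfig(nTrees = 50, seed = 10), w)
  expect_false(identical(predictWindows(f1, w), predictWindows(f3, w)))
})

test_that("recurrent backends honour epoch caps, early stopping and seeds", {
  set.seed(13)
  sc <- matrix(runif(100), 50, 2, dimnames = list(NULL, c("A", "B")))
  w <- makeWindows(sc[1:40, ], windowConfig(lag = 3))
  v <- makeWindows(sc[38:50, ], windowConfig(lag = 3))

  one <- fitForecaster(recurrentConfig("lstm", cells = 8, maxEpochs = 1,
                                       dropoutRate = 0, seed = 1), w, v)
  expect_identical(nrow(one@trainingLog), 1L)

  ## plateau by duplicated windows: early stopping fires before the cap
  wdup <- w
  wdup@targets[] <- 0.5
  vdup <- v
  vdup@targets[] <- 0.5
  es <- fitForecaster(recurrentConfig("lstm", cells = 8, maxEpochs = 200,
                                      patience = 5, dropoutRate = 0,
                                      seed = 1), wdup, vdup)
  expect_lt(es@stoppedEpoch, 200L)

  ## seeded determinism of the full loss curve (single-threaded)
  a <- fitForecaster(recurrentConfig("gru", cells = 8, maxEpochs = 20,
                                     seed = 4), w, v)
  b <- fitForecaster(recurrentConfig("gru", cells = 8, maxEpochs = 20,
                                     seed = 4), w, v)
  expect_identical(a@trainingLog, b@trainingLog)
  expect_identical(predictWindows(a, v), predictWindows(b, v))
})

test_that("recurrent training reduces the loss on learnable structure", {
  set.seed(14)
  t <- 1:80
  sc <- cbind(A = 0.5 + 0.4 * sin(2 * pi * t / 16),
              B = 0.5 + 0.4 * cos(2 * pi * t / 16))
  w <- makeWindows(sc[1:64, ], windowConfig(lag = 3))
  v <- makeWindows(sc[62:80, ], windowConfig(lag = 3))
  fit <- fitForecaster(recurrentConfig("lstm", cells = 16,
                                       maxEpochs = 150, dropoutRate = 0,
                                       seed = 2), w, v)
  log <- fit@trainingLog
  expect_lt(log$train_mae[nrow(log)], log$train_mae[1] / 2)
  expect_true(all(is.finite(log$train_mae)))
})

test_that("iterative and teacher-forced forecasting follow the contract", {
  g <- c("A", "B")
  hist <- matrix(runif(20), 10, 2, dimnames = list(NULL, g))

  ## iterative identity-mock repeats the last observed row indefinitely
  it <- forecastSeries(identityMock(g), hist, steps = 4,
                       mode = "iterative")
  expect_equal(unname(it),
               matrix(rep(hist[10, ], each = 4), 4), tolerance = 1e-12)

  ## iterative 2-step mean-mock, hand-unrolled recursion
  mm <- meanMock(g)
  it2 <- forecastSeries(mm, hist, steps = 2, mode = "iterative")
  s1 <- colMeans(hist[8:10, ])
  s2 <- colMeans(rbind(hist[9:10, ], s1))
  expect_equal(unname(it2[1, ]), unname(s1))
  expect_equal(unname(it2[2, ]), unname(s2))

  ## teacher-forced predictions at t are invariant to rows >= t
  set.seed(15)
  sc <- matrix(runif(60), 30, 2, dimnames = list(NULL, g))
  w <- makeWindows(sc[1:20, ], windowConfig(lag = 3))
  rf <- fitForecaster(rfConfig(nTrees = 30, seed = 3), w)
  base <- forecastSeries(rf, sc, steps = 8, mode = "teacher_forced")
  pert <- sc
  pert[26:30, ] <- pert[26:30, ] + 100       # future of the 3rd target row
  after <- forecastSeries(rf, pert, steps = 8, mode = "teacher_forced")
  ## rows 23..25 predicted from lags 20..24 only: unaffected
  expect_identical(base[1:3, ], after[1:3, ])
  expect_error(forecastSeries(rf, sc, steps = 0), "steps must be positive")
})
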
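test_that("interval construction matches the closed form", {
  members <- array(c(1, 2, 3), dim = c(3, 1, 1),
                   dimnames = list(NULL, NULL, "A"))
  cfg <- ensembleConfig(nMembers = 3, coverage = 0.95, seed = 1)
  fc <- buildInterval(members, cfg, scale = "absolute")
  expect_equal(as.numeric(fc@mean), 2)
  expect_equal(as.numeric(fc@std), 1)          # sample sd, ddof = 1
  expect_equal(as.numeric(fc@lower), 2 - 1.96, tolerance = 1e-3)
  expect_equal(as.numeric(fc@upper), 2 + 1.96, tolerance = 1e-3)

  ## identical members collapse the interval to the point
  same <- array(5, dim = c(4, 2, 1), dimnames = list(NULL, NULL, "A"))
  cfg4 <- ensembleConfig(nMembers = 4, seed = 1)
  fc2 <- buildInterval(same, cfg4, scale = "absolute")
  expect_true(all(fc2@std == 0))
  expect_true(all(fc2@lower == fc2@upper))

  ## NaN members are named
  bad <- members; bad[2, 1, 1] <- NA
  expect_error(buildInterval(bad, cfg, scale = "absolute"),
               "member 2")
})

test_that("member mean and sd recover i.i.d. draw parameters", {
  set.seed(31)
  N <- 50; T <- 40; G <- 10
  members <- array(rnorm(N * T * G, 3, 0.5), dim = c(N, T, G),
                   dimnames = list(NULL, NULL, sprintf("g%02d", 1:G)))
  cfg <- ensembleConfig(nMembers = N, seed = 1)
  fc <- buildInterval(members, cfg, scale = "absolute")
  expect_equal(mean(fc@mean), 3, tolerance = 0.01)
  expect_equal(mean(fc@std), 0.5, tolerance = 0.01)
})

test_that("interval width is monotone in z and in the member spread", {
  set.seed(32)
  members <- array(rnorm(5 * 20 * 3), dim = c(5, 20, 3),
                   dimnames = list(NULL, NULL, c("A", "B", "C")))
  w90 <- buildInterval(members, ensembleConfig(5, coverage = 0.90,
                                               seed = 1),
                       scale = "absolute")
  w99 <- buildInterval(members, ensembleConfig(5, coverage = 0.99,
                                               seed = 1),
                       scale = "absolute")
  expect_true(all(w99@upper - w99@lower >= w90@upper - w90@lower))
  wide <- members * 3
  w95 <- buildInterval(members, ensembleConfig(5, seed = 1),
                       scale = "absolute")
  w95w <- buildInterval(wide, ensembleConfig(5, seed = 1),
                        scale = "absolute")
  expect_true(all(w95w@upper - w95w@lower >=
                  3 * (w95@upper - w95@lower) - 1e-9))
})

test_that("ensemble training produces distinct members and guards config", {
  set.seed(33)
  sc <- matrix(runif(120) + rnorm(120, 0, 0.2), 60, 2,
               dimnames = list(NULL, c("A", "B")))
  w <- makeWindows(sc, windowConfig(lag = 3))
  cfg <- ensembleConfig(nMembers = 2, seed = 5)
  models <- trainEnsemble(cfg, rfConfig(nTrees = 25), w)
  expect_length(models, 2)
  expect_false(identical(predictWindows(models[[1]], w),
                         predictWindows(models[[2]], w)))
  expect_error(ensembleConfig(nMembers = 2, seeds = c(7L, 7L)),
               "distinct")
  expect_error(ensembleConfig(nMembers = 1, seeds = 1L), "nMembers")
})

test_that("outlier rule is strict and reports direction and exceedance", {
  fc <- buildInterval(array(c(1, 2, 3), dim = c(3, 1, 1),
                            dimnames = list(NULL, NULL, "A")),
                      ensembleConfig(3, seed = 1), scale = "absolute")
  lo <- as.numeric(fc@lower); up <- as.numeric(fc@upper)

  flag <- detectOutliers(matrix(5, 1, 1, dimnames = list(NULL, "A")), fc)
  expect_identical(nrow(flag), 1L)
  expect_identical(flag$direction, "above")
  expect_equal(flag$exceedance, 5 - up)

  ## boundary equality is NOT an outlier
  atBound <- detectOutliers(matrix(up, 1, 1,
                                   dimnames = list(NULL, "A")), fc)
  expect_identical(nrow(atBound), 0L)
  below <- detectOutliers(matrix(lo - 0.5, 1, 1,
                                 dimnames = list(NULL, "A")), fc)
  expect_identical(below$direction, "below")
  expect_equal(below$exceedance, 0.5, tolerance = 1e-9)

  ## inside the interval: no flag
  expect_identical(nrow(detectOutliers(
    matrix(2, 1, 1, dimnames = list(NULL, "A")), fc)), 0L)

  ## missing observation rows are skipped, not flagged
  fc2 <- buildInterval(array(rep(c(1, 2, 3), each = 2),
                             dim = c(3, 2, 1),
                             dimnames = list(NULL, NULL, "A")),
                       ensembleConfig(3, seed = 1), scale = "absolute")
  obs <- matrix(c(NA, 99), 2, 1, dimnames = list(NULL, "A"))
  expect_message(rep2 <- detectOutliers(obs, fc2), "skipping 1 missing")
  expect_identical(nrow(rep2), 1L)
  expect_identical(rep2$time_step, 2L)
})

test_that("back-transform commutes with interval construction", {
  set.seed(34)
  G <- 4
  m <- matrix(runif(40, 0, 100), 10, G,
              dimnames = list(NULL, sprintf("g%d", 1:G)))
  params <- fitScaler(m)
  members <- array(runif(6 * 8 * G), dim = c(6, 8, G),
                   dimnames = list(NULL, NULL, sprintf("g%d", 1:G)))
  cfg <- ensembleConfig(6, seed = 2)
  scaledFc <- buildInterval(members, cfg, scale = "scaled")
  absFc <- backTransformForecast(scaledFc, params)
  ## oracle: build the interval from back-transformed members directly
  absMembers <- members
  for (i in 1:6) absMembers[i, , ] <- inverseScale(members[i, , ], params)
  oracle <- buildInterval(absMembers, cfg, scale = "absolute")
  expect_equal(absFc@mean, oracle@mean, tolerance = 1e-10)
  expect_equal(absFc@std, oracle@std, tolerance = 1e-10)
  expect_equal(absFc@lower, oracle@lower, tolerance = 1e-10)
  expect_equal(absFc@upper, oracle@upper, tolerance = 1e-10)
})

test_that("derived sub-seeds are reproducible and well spread", {
  a <- deriveSeed(1, "ensemble-member", 1)
  expect_identical(a, deriveSeed(1, "ensemble-member", 1))
  seeds <- vapply(1:100, function(i) deriveSeed(1, "ensemble-member", i),
                  integer(1))
  expect_identical(anyDuplicated(seeds), 0L)
  expect_false(deriveSeed(2, "ensemble-member", 1) == a)
})
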
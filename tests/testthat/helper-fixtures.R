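# shared fixtures: tiny series, mock forecasters, small synthetic scenes

toyCounts <- function() {
  matrix(c(0, 5, 10, 0, 2, 3), nrow = 3, byrow = TRUE,
         dimnames = list(paste0("s", 1:3), c("Blautia", "Dorea")))
}

toySeries <- function(T = 20, G = 3, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(T * G, lambda = 50), nrow = T,
              dimnames = list(sprintf("s%02d", seq_len(T)),
                              sprintf("Genus%02d", seq_len(G))))
  AbundanceSeries(m)
}

identityMock <- function(genera, lag = 3L) {
  functionForecaster(function(w) w[nrow(w), seq_along(genera)],
                     genera = genera, lag = lag, label = "identity-mock")
}

constantMock <- function(genera, value, lag = 3L) {
  functionForecaster(function(w) rep(value, length(genera)),
                     genera = genera, lag = lag, label = "constant-mock")
}

meanMock <- function(genera, lag = 3L) {
  functionForecaster(function(w) colMeans(w[, seq_along(genera),
                                            drop = FALSE]),
                     genera = genera, lag = lag, label = "mean-mock")
}

## low-noise seasonal community: deterministic structure, rounding as the
## only measurement noise — the regime where ensemble spread dominates
lowNoiseSpecs <- function(G = 10) {
  set.seed(55)
  baseline <- round(exp(rnorm(G, log(400), 0.7)))
  genusProcessSpec(sprintf("Genus%02d", seq_len(G)), baseline,
                   seasonalAmplitude = 0.3 * baseline,
                   seasonalPeriod = 25,
                   phase = runif(G, 0, 2 * pi),
                   arCoefficient = 0.5, noiseSd = 0)
}

## one spike-recovery run: returns sensitivity and clean false-flag rate
spikeRecoveryRun <- function(seed, spike = TRUE, nMembers = 10,
                             nTrees = 100, T = 150) {
  specs <- lowNoiseSpecs()
  testStart <- floor(T * 0.8) + 1
  ev <- if (spike) {
    set.seed(seed + 1000)
    shiftEvent(sample(testStart:T, 8),
               sample(specs$genus, 8, replace = TRUE),
               kind = "spike", magnitude = 3)
  } else NULL
  truth <- syntheticTruth(specs, events = ev, seed = seed, length = T)
  gen <- generateSeries(truth)
  s <- gen$series
  parts <- chronologicalSplit(s, splitSpec())
  params <- fitScaler(parts$train)
  sc <- scaleAbundance(s, params)
  wins <- windowSplits(sc, parts$indices, windowConfig())
  ecfg <- ensembleConfig(nMembers = nMembers, seed = seed)
  models <- trainEnsemble(ecfg, rfConfig(nTrees = nTrees), wins$train,
                          wins$validation)
  fc <- buildInterval(memberPredictions(models, wins$test), ecfg,
                      targetSteps = wins$test@targetSteps)
  obs <- abundanceMatrix(s)[match(wins$test@targetSteps, timeSteps(s)), ]
  rep <- detectOutliers(obs, fc, params)
  flagged <- paste(rep$time_step, rep$genus)
  lab <- gen$labels[gen$labels$timestep %in% wins$test@targetSteps, ]
  truthCells <- paste(lab$timestep, lab$genus)
  fp <- setdiff(flagged, truthCells)
  list(sensitivity = if (length(truthCells)) mean(truthCells %in% flagged)
                     else NA_real_,
       falseFlagRate = length(fp) /
         (attr(rep, "nCells") - length(truthCells)))
}
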
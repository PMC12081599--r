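#' @include AllClasses.R AllGenerics.R
NULL

#' @rdname RecurrentConfig-class
#' @param cellType,layers,cells,activation,dropoutRate,learningRate,maxEpochs,patience,seed
#'   see slot documentation.
#' @export
recurrentConfig <- function(cellType = c("lstm", "gru"), cells = 2048L,
                            layers = 1L, activation = c("relu", "tanh"),
                            dropoutRate = 0.2, learningRate = 0.01,
                            maxEpochs = 200L, patience = 10L, seed = 1L) {
  methods::new("RecurrentConfig", cellType = match.arg(cellType),
               layers = as.integer(layers), cells = as.integer(cells),
               activation = match.arg(activation),
               dropoutRate = dropoutRate, learningRate = learningRate,
               maxEpochs = as.integer(maxEpochs),
               patience = as.integer(patience), seed = as.integer(seed))
}

#' @rdname RfConfig-class
#' @param nTrees,splitCriterion,seed see slot documentation.
#' @export
rfConfig <- function(nTrees = 100L, splitCriterion = "variance",
                     seed = 1L) {
  methods::new("RfConfig", nTrees = as.integer(nTrees),
               splitCriterion = splitCriterion, seed = as.integer(seed))
}

#' @rdname VarmaConfig-class
#' @param p,d,q,trend,gridP,gridQ,stationarityAlpha see slot documentation.
#' @export
varmaConfig <- function(p = NA_integer_, d = NA_integer_, q = NA_integer_,
                        trend = c("linear", "constant", "none"),
                        gridP = 0:3, gridQ = 0:3,
                        stationarityAlpha = 0.05) {
  methods::new("VarmaConfig", p = as.integer(p), d = as.integer(d),
               q = as.integer(q), trend = match.arg(trend),
               gridP = as.integer(gridP), gridQ = as.integer(gridQ),
               stationarityAlpha = stationarityAlpha)
}

## ---- function-backed forecasters (baselines and mocks) ------------------

#' Forecaster from a window function
#'
#' Wraps a deterministic function of the lag window (a lag x width matrix,
#' oldest row first) returning one prediction per genus. Used for
#' baselines and for testing the forecasting contract.
#'
#' @param fn function(window) -> numeric of length G.
#' @param genera genus names (model outputs).
#' @param lag window length.
#' @param covariateNames covariate input columns.
#' @param label display label.
#' @return a [FunctionForecaster-class].
#' @export
functionForecaster <- function(fn, genera, lag = 3L,
                               covariateNames = character(),
                               label = "function") {
  G <- length(genera)
  methods::new("FunctionForecaster", fn = fn, label = label,
               genera = genera, covariateNames = covariateNames,
               lag = as.integer(lag),
               inputWidth = as.integer(G + length(covariateNames)),
               outputWidth = as.integer(G))
}

#' Last-value persistence baseline
#'
#' Predicts the next abundance of each genus as its most recent observed
#' value. The reference any learned forecaster must beat.
#'
#' @inheritParams functionForecaster
#' @return a [FunctionForecaster-class].
#' @export
persistenceForecaster <- function(genera, lag = 3L,
                                  covariateNames = character()) {
  G <- length(genera)
  functionForecaster(function(window) window[nrow(window), seq_len(G)],
                     genera = genera, lag = lag,
                     covariateNames = covariateNames, label = "persistence")
}

#' @rdname predictStep
#' @export
setMethod("predictStep", "FunctionForecaster", function(object, window) {
  window <- as.matrix(window)
  .checkWindowShape(object, window)
  out <- as.numeric(object@fn(window))
  stopifnot(length(out) == object@outputWidth)
  out
})

.checkWindowShape <- function(object, window) {
  if (anyNA(window))
    stop("NaN/NA in prediction window", call. = FALSE)
  if (nrow(window) != object@lag || ncol(window) != object@inputWidth)
    stop(sprintf("window shape %dx%d does not match training shape %dx%d",
                 nrow(window), ncol(window), object@lag, object@inputWidth),
         call. = FALSE)
  invisible(TRUE)
}

## ---- batch prediction over a windowed dataset ---------------------------

#' Predict every window of a dataset
#'
#' @param object a fitted [Forecaster-class].
#' @param windows a [WindowedDataset-class].
#' @return matrix N x G of one-step predictions.
#' @export
setGeneric("predictWindows", function(object, windows)
  standardGeneric("predictWindows"))

#' @rdname predictWindows
#' @export
setMethod("predictWindows", "Forecaster", function(object, windows) {
  n <- dim(windows@inputs)[1]
  out <- matrix(NA_real_, nrow = n, ncol = object@outputWidth,
                dimnames = list(NULL, object@genera))
  for (i in seq_len(n)) {
    out[i, ] <- predictStep(object,
                            matrix(windows@inputs[i, , ],
                                   nrow = windows@lag))
  }
  out
})

## ---- multi-step forecasting ---------------------------------------------

#' Forecast a series, teacher-forced or iteratively
#'
#' Teacher-forced mode produces one-step-ahead predictions for the last
#' `steps` rows of `history`, each conditioned only on the observed lag
#' rows preceding it (the mode used for outlier detection). Iterative mode
#' starts from the final lag rows of `history` and feeds its own
#' predictions back into the window for `steps` future rows (the mode used
#' for trajectory extrapolation plots).
#'
#' @param model a fitted [Forecaster-class].
#' @param history samples x genera matrix on the model's training scale;
#'   teacher-forced mode requires `lag + steps` rows or more.
#' @param steps number of prediction rows.
#' @param mode "teacher_forced" or "iterative".
#' @param covariates covariate matrix aligned row-wise to `history`
#'   (teacher-forced) — required when the model was trained with covariates.
#' @param futureCovariates steps x covariates matrix for iterative mode.
#' @return matrix steps x G of predictions.
#' @export
forecastSeries <- function(model, history, steps,
                           mode = c("teacher_forced", "iterative"),
                           covariates = NULL, futureCovariates = NULL) {
  mode <- match.arg(mode)
  history <- as.matrix(history)
  if (steps <= 0) stop("steps must be positive", call. = FALSE)
  lag <- model@lag
  G <- model@outputWidth
  nCov <- length(model@covariateNames)
  joinCov <- function(rows, covBlock) {
    if (nCov == 0) return(rows)
    cbind(rows, as.matrix(covBlock))
  }
  out <- matrix(NA_real_, nrow = steps, ncol = G,
                dimnames = list(NULL, model@genera))
  if (mode == "teacher_forced") {
    T <- nrow(history)
    if (T < lag + steps)
      stop(sprintf("history of %d rows too short for %d teacher-forced steps (need lag + steps = %d)",
                   T, steps, lag + steps), call. = FALSE)
    if (nCov > 0 && is.null(covariates))
      stop("model uses covariates; supply `covariates` aligned to history",
           call. = FALSE)
    first <- T - steps + 1L
    for (s in seq_len(steps)) {
      t <- first + s - 1L
      rows <- history[(t - lag):(t - 1L), seq_len(G), drop = FALSE]
      win <- joinCov(rows, if (nCov > 0)
        covariates[(t - lag):(t - 1L), model@covariateNames, drop = FALSE])
      out[s, ] <- predictStep(model, win)
    }
  } else {
    if (nrow(history) < lag)
      stop("history shorter than lag", call. = FALSE)
    if (nCov > 0 && is.null(futureCovariates))
      stop("iterative mode with covariates requires futureCovariates",
           call. = FALSE)
    if (nCov > 0 && is.null(covariates))
      stop("model uses covariates; supply `covariates` aligned to history",
           call. = FALSE)
    buf <- history[(nrow(history) - lag + 1L):nrow(history),
                   seq_len(G), drop = FALSE]
    covBuf <- if (nCov > 0)
      covariates[(nrow(history) - lag + 1L):nrow(history),
                 model@covariateNames, drop = FALSE]
    for (s in seq_len(steps)) {
      win <- joinCov(buf, covBuf)
      pred <- predictStep(model, win)
      out[s, ] <- pred
      buf <- rbind(buf[-1, , drop = FALSE], pred)
      if (nCov > 0)
        covBuf <- rbind(covBuf[-1, , drop = FALSE],
                        as.matrix(futureCovariates)[s, model@covariateNames,
                                                    drop = FALSE])
    }
  }
  out
}

setMethod("show", "Forecaster", function(object) {
  cat(sprintf("%s: lag %d, input width %d -> %d genera\n",
              class(object), object@lag, object@inputWidth,
              object@outputWidth))
  invisible(object)
})
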
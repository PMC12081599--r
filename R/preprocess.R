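#' @include AllClasses.R AllGenerics.R
NULL

#' @rdname SplitSpec-class
#' @param trainValFraction,valFractionOfTrain see slot documentation.
#' @export
splitSpec <- function(trainValFraction = 0.8, valFractionOfTrain = 0.1) {
  methods::new("SplitSpec", trainValFraction = trainValFraction,
               valFractionOfTrain = valFractionOfTrain)
}

#' @rdname WindowConfig-class
#' @param lag,horizon,covariateNames see slot documentation.
#' @export
windowConfig <- function(lag = 3L, horizon = 1L,
                         covariateNames = character()) {
  methods::new("WindowConfig", lag = as.integer(lag),
               horizon = as.integer(horizon),
               covariateNames = as.character(covariateNames))
}

.asAbundanceMatrix <- function(x) {
  if (methods::is(x, "AbundanceSeries")) abundanceMatrix(x) else as.matrix(x)
}

## ---- min-max scaler -----------------------------------------------------

#' Fit per-genus min-max scaling parameters
#'
#' Computes per-genus minimum and maximum from the training partition only,
#' so that no information from validation or test samples leaks into the
#' transform. Constant (degenerate) genera are recorded and map to 0 under
#' the forward transform.
#'
#' @param x training data: an [AbundanceSeries-class] or samples x genera
#'   matrix. When `split` is supplied, `x` is the full series and the
#'   training partition is extracted first.
#' @param split optional [SplitSpec-class]; parameters are then fitted on
#'   the train block of [chronologicalSplit()].
#' @return a [ScalerParams-class].
#' @export
fitScaler <- function(x, split = NULL) {
  if (!is.null(split)) {
    parts <- chronologicalSplit(x, split)
    x <- parts$train
    fittedOn <- "train"
  } else {
    fittedOn <- "supplied"
  }
  m <- .asAbundanceMatrix(x)
  if (nrow(m) == 0) stop("empty training partition", call. = FALSE)
  mins <- apply(m, 2, min)
  maxs <- apply(m, 2, max)
  methods::new("ScalerParams", mins = mins, maxs = maxs,
               degenerate = maxs == mins, fittedOn = fittedOn)
}

.checkScalerAxes <- function(m, params) {
  if (is.null(colnames(m)))
    colnames(m) <- names(params@mins)[seq_len(ncol(m))]
  unseen <- setdiff(colnames(m), names(params@mins))
  if (length(unseen) > 0)
    stop("genus not seen by scaler: ", paste(unseen, collapse = ", "),
         call. = FALSE)
  m
}

#' Forward min-max transform
#'
#' `(x - min) / (max - min)` per genus. Values outside the fitted range
#' (e.g. on test data) are NOT clipped: out-of-range observations must stay
#' visible to the outlier detector. Degenerate genera map to 0.
#'
#' @param x an [AbundanceSeries-class] or samples x genera matrix.
#' @param params a [ScalerParams-class].
#' @return numeric matrix, samples x genera, on the \[0,1\]-anchored scale.
#' @export
scaleAbundance <- function(x, params) {
  m <- .checkScalerAxes(.asAbundanceMatrix(x), params)
  g <- colnames(m)
  rng <- params@maxs[g] - params@mins[g]
  rng[params@degenerate[g]] <- 1  # transform of a constant column is 0
  out <- sweep(sweep(m, 2, params@mins[g]), 2, rng, "/")
  if (any(params@degenerate[g])) out[, params@degenerate[g]] <- 0
  out
}

#' Inverse min-max transform
#'
#' Exact inverse of [scaleAbundance()] on non-degenerate genera; degenerate
#' genera return their constant. Monotone, so interval bounds may be
#' back-transformed directly.
#'
#' @param scaled samples x genera matrix on the scaled scale.
#' @param params a [ScalerParams-class].
#' @return matrix on the absolute-abundance scale.
#' @export
inverseScale <- function(scaled, params) {
  m <- .checkScalerAxes(as.matrix(scaled), params)
  g <- colnames(m)
  rng <- params@maxs[g] - params@mins[g]
  out <- sweep(sweep(m, 2, rng, "*"), 2, params@mins[g], "+")
  deg <- params@degenerate[g]
  if (any(deg))
    out[, deg] <- matrix(params@mins[g][deg], nrow = nrow(m),
                         ncol = sum(deg), byrow = TRUE)
  out
}

## ---- chronological split ------------------------------------------------

#' Split a series chronologically into train / validation / test
#'
#' Contiguous blocks in time order, no shuffling: the first
#' `trainValFraction` of samples are train+validation (the final
#' `valFractionOfTrain` of that block is validation, used for early
#' stopping), the remainder is test.
#'
#' @param series an [AbundanceSeries-class].
#' @param split a [SplitSpec-class].
#' @param window optional [WindowConfig-class]; when given, partition
#'   lengths are checked against the lag/horizon requirements.
#' @return list with elements `train`, `validation` (NULL when empty),
#'   `test` (each an [AbundanceSeries-class]) and `indices` (integer
#'   positions of each block).
#' @export
chronologicalSplit <- function(series, split = splitSpec(), window = NULL) {
  n <- ncol(series)
  nTrainVal <- as.integer(floor(n * split@trainValFraction))
  nVal <- as.integer(floor(nTrainVal * split@valFractionOfTrain))
  nTrain <- nTrainVal - nVal
  nTest <- n - nTrainVal
  if (nTrain < 1 || nTest < 1)
    stop(sprintf(
      "series too short to split: %d samples yield train %d / test %d (need >= 1 each)",
      n, nTrain, nTest), call. = FALSE)
  if (!is.null(window)) {
    need <- window@lag + window@horizon
    if (nTrain < need)
      stop(sprintf(
        "train partition of %d samples cannot form a window (need >= lag + horizon = %d)",
        nTrain, need), call. = FALSE)
  }
  idx <- list(train = seq_len(nTrain),
              validation = if (nVal > 0) nTrain + seq_len(nVal) else integer(),
              test = nTrainVal + seq_len(nTest))
  list(train = series[, idx$train],
       validation = if (nVal > 0) series[, idx$validation] else NULL,
       test = series[, idx$test],
       indices = idx)
}

## ---- windowing ----------------------------------------------------------

#' Frame a scaled series as lag-window supervised examples
#'
#' For each admissible target row t, the input is the `lag` preceding rows
#' over all genera (plus covariate columns aligned to those rows when
#' configured) and the target is row t over all genera. With horizon 1 the
#' window count is exactly `T - lag`.
#'
#' @param scaled samples x genera matrix (scaled scale).
#' @param cfg a [WindowConfig-class].
#' @param covariates optional samples x covariates matrix aligned row-wise
#'   to `scaled`; an NA covariate inside any window is an error naming the
#'   time step.
#' @param timeSteps optional integer time step per row (default 1..T).
#' @return a [WindowedDataset-class].
#' @export
makeWindows <- function(scaled, cfg = windowConfig(), covariates = NULL,
                        timeSteps = NULL) {
  scaled <- as.matrix(scaled)
  T <- nrow(scaled)
  G <- ncol(scaled)
  lag <- cfg@lag
  h <- cfg@horizon
  if (T <= lag)
    stop(sprintf("partition length %d must exceed lag %d", T, lag),
         call. = FALSE)
  if (is.null(timeSteps)) timeSteps <- seq_len(T)
  covNames <- cfg@covariateNames
  if (length(covNames) > 0) {
    if (is.null(covariates))
      stop("window config names covariates but none supplied", call. = FALSE)
    covariates <- as.matrix(covariates)[, covNames, drop = FALSE]
    stopifnot(nrow(covariates) == T)
  } else {
    covariates <- matrix(0, nrow = T, ncol = 0)
  }
  width <- G + ncol(covariates)
  nW <- T - lag - h + 1L
  if (nW < 1)
    stop("partition too short for the configured lag and horizon",
         call. = FALSE)
  inputs <- array(NA_real_, dim = c(nW, lag, width))
  targets <- matrix(NA_real_, nrow = nW, ncol = G,
                    dimnames = list(NULL, colnames(scaled)))
  for (w in seq_len(nW)) {
    rows <- seq.int(w, length.out = lag)
    block <- cbind(scaled[rows, , drop = FALSE],
                   covariates[rows, , drop = FALSE])
    if (anyNA(block[, G + seq_len(ncol(covariates)), drop = FALSE])) {
      bad <- rows[which(rowSums(is.na(
        covariates[rows, , drop = FALSE])) > 0)][1]
      stop(sprintf("covariate missing for time step %d", timeSteps[bad]),
           call. = FALSE)
    }
    inputs[w, , ] <- block
    targets[w, ] <- scaled[lag + w + h - 1L, ]
  }
  dimnames(inputs) <- list(NULL, NULL, c(colnames(scaled), covNames))
  methods::new("WindowedDataset", inputs = inputs, targets = targets,
               genera = colnames(scaled), covariateNames = covNames,
               lag = lag,
               targetSteps = as.integer(timeSteps[lag + seq_len(nW) + h - 1L]))
}

#' Window every split with full lag context
#'
#' Builds train / validation / test [WindowedDataset-class]s from a full
#' scaled series and split indices. Train windows are formed within the
#' train block; validation and test windows take their lag context from
#' the preceding rows of the full series, so every validation/test row is
#' a prediction target.
#'
#' @param scaled full samples x genera matrix (scaled scale).
#' @param indices the `indices` element of [chronologicalSplit()].
#' @param cfg a [WindowConfig-class].
#' @param covariates optional full samples x covariates matrix.
#' @return list of [WindowedDataset-class] (`validation` NULL when empty).
#' @export
windowSplits <- function(scaled, indices, cfg = windowConfig(),
                         covariates = NULL) {
  scaled <- as.matrix(scaled)
  withContext <- function(idx) {
    if (length(idx) == 0) return(NULL)
    ctx <- seq.int(max(1L, min(idx) - cfg@lag - cfg@horizon + 1L), max(idx))
    w <- makeWindows(scaled[ctx, , drop = FALSE], cfg,
                     covariates = if (is.null(covariates)) NULL else
                       covariates[ctx, , drop = FALSE],
                     timeSteps = ctx)
    keep <- w@targetSteps %in% idx
    methods::new("WindowedDataset",
                 inputs = w@inputs[keep, , , drop = FALSE],
                 targets = w@targets[keep, , drop = FALSE],
                 genera = w@genera, covariateNames = w@covariateNames,
                 lag = w@lag, targetSteps = w@targetSteps[keep])
  }
  train <- makeWindows(scaled[indices$train, , drop = FALSE], cfg,
                       covariates = if (is.null(covariates)) NULL else
                         covariates[indices$train, , drop = FALSE],
                       timeSteps = indices$train)
  list(train = train,
       validation = withContext(indices$validation),
       test = withContext(indices$test))
}
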
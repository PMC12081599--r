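#' @include AllClasses.R AllGenerics.R forecast-common.R
NULL

#' Derive a reproducible sub-seed
#'
#' Hashes (global seed, component label, index) with FNV-1a so that every
#' random operation in a pipeline draws a distinct, reproducible seed from
#' one global seed.
#'
#' @param seed global integer seed.
#' @param component component label, e.g. "ensemble".
#' @param index member / repetition index.
#' @return integer in \[1, 2^31 - 2\].
#' @export
deriveSeed <- function(seed, component, index = 1L) {
  key <- sprintf("%d:%s:%d", as.integer(seed), component, as.integer(index))
  h <- 2166136261
  for (b in utf8ToInt(key)) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (as.numeric(h) * 16777619) %% 2^31
  }
  as.integer(h %% (2^31 - 2)) + 1L
}

#' @rdname EnsembleConfig-class
#' @param nMembers,coverage,stdDdof see slot documentation.
#' @param seeds distinct member seeds; by default derived from `seed` via
#'   [deriveSeed()].
#' @param seed global seed used when `seeds` is NULL.
#' @export
ensembleConfig <- function(nMembers = 50L, coverage = 0.95, seeds = NULL,
                           stdDdof = 1L, seed = 1L) {
  nMembers <- as.integer(nMembers)
  if (is.null(seeds))
    seeds <- vapply(seq_len(nMembers), function(i)
      deriveSeed(seed, "ensemble-member", i), integer(1))
  methods::new("EnsembleConfig", nMembers = nMembers, coverage = coverage,
               z = stats::qnorm(1 - (1 - coverage) / 2),
               seeds = as.integer(seeds), stdDdof = as.integer(stdDdof))
}

#' Train an ensemble of same-architecture forecasters
#'
#' Fits `nMembers` models that differ only by their seed. The inter-model
#' spread of their predictions quantifies model uncertainty and feeds the
#' z-based prediction interval.
#'
#' @param cfg an [EnsembleConfig-class].
#' @param backendConfig a [RecurrentConfig-class] or [RfConfig-class]; its
#'   seed slot is replaced by each member seed.
#' @param windows training [WindowedDataset-class].
#' @param validation optional validation [WindowedDataset-class].
#' @param onFailure "fail-fast" (default) or "drop-member".
#' @return list of fitted [Forecaster-class] objects.
#' @export
trainEnsemble <- function(cfg, backendConfig, windows, validation = NULL,
                          onFailure = c("fail-fast", "drop-member")) {
  onFailure <- match.arg(onFailure)
  models <- vector("list", cfg@nMembers)
  ok <- logical(cfg@nMembers)
  for (i in seq_len(cfg@nMembers)) {
    bc <- backendConfig
    bc@seed <- cfg@seeds[i]
    fit <- tryCatch(fitForecaster(bc, windows, validation),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      if (onFailure == "fail-fast")
        stop(sprintf("ensemble member %d failed to fit: %s", i,
                     conditionMessage(fit)), call. = FALSE)
      warning(sprintf("dropping ensemble member %d: %s", i,
                      conditionMessage(fit)))
    } else {
      models[[i]] <- fit
      ok[i] <- TRUE
    }
  }
  models <- models[ok]
  if (length(models) < 2)
    stop("fewer than 2 ensemble members fitted", call. = FALSE)
  models
}

#' Collect member predictions over a windowed dataset
#'
#' Teacher-forced one-step predictions of every member on every window.
#'
#' @param models list of fitted forecasters (see [trainEnsemble()]).
#' @param windows a [WindowedDataset-class].
#' @return array N_members x T x G.
#' @export
memberPredictions <- function(models, windows) {
  preds <- lapply(models, predictWindows, windows = windows)
  arr <- array(NA_real_, dim = c(length(models), nrow(preds[[1]]),
                                 ncol(preds[[1]])),
               dimnames = list(NULL, NULL, colnames(preds[[1]])))
  for (i in seq_along(preds)) arr[i, , ] <- preds[[i]]
  arr
}

#' Build a z-based prediction interval from member forecasts
#'
#' Per time point and genus: mean across members, member standard
#' deviation (sample sd by default, `stdDdof = 1`), and the interval
#' `mean +/- z * std`. The interval quantifies inter-model variance only;
#' no observation-noise term is added.
#'
#' @param members array N x T x G of member predictions (N = ensemble
#'   size), or a list of T x G matrices.
#' @param cfg an [EnsembleConfig-class] (its `nMembers` must match N).
#' @param scale "scaled" or "absolute" label recorded on the result.
#' @param targetSteps optional integer time step per forecast row.
#' @return an [EnsembleForecast-class].
#' @export
buildInterval <- function(members, cfg, scale = "scaled",
                          targetSteps = NULL) {
  if (is.list(members)) {
    arr <- array(NA_real_, dim = c(length(members), nrow(members[[1]]),
                                   ncol(members[[1]])),
                 dimnames = list(NULL, NULL, colnames(members[[1]])))
    for (i in seq_along(members)) arr[i, , ] <- members[[i]]
    members <- arr
  }
  d <- dim(members)
  if (anyNA(members)) {
    bad <- which(is.na(members), arr.ind = TRUE)[1, ]
    stop(sprintf("NaN in member %d at time row %d, genus column %d",
                 bad[1], bad[2], bad[3]), call. = FALSE)
  }
  N <- d[1]
  mu <- apply(members, c(2, 3), mean)
  ss <- apply(members, c(2, 3), function(v) sum((v - mean(v))^2))
  sd <- sqrt(ss / (N - cfg@stdDdof))
  lower <- mu - cfg@z * sd
  upper <- mu + cfg@z * sd
  g <- dimnames(members)[[3]]
  dimnames(mu) <- dimnames(sd) <- dimnames(lower) <- dimnames(upper) <-
    list(NULL, g)
  if (is.null(targetSteps)) targetSteps <- seq_len(d[2])
  methods::new("EnsembleForecast", memberPredictions = members,
               mean = mu, std = sd, lower = lower, upper = upper,
               z = cfg@z, coverage = cfg@coverage, scale = scale,
               targetSteps = as.integer(targetSteps))
}

#' Back-transform an ensemble forecast to absolute abundances
#'
#' Applies the inverse min-max transform per genus to the members, mean
#' and bounds. The scaler is affine and monotone, so the interval computed
#' in scaled space maps exactly onto the interval computed from
#' back-transformed members.
#'
#' @param forecast an [EnsembleForecast-class] on the scaled scale.
#' @param params the [ScalerParams-class] used for scaling.
#' @return an [EnsembleForecast-class] on the absolute scale.
#' @export
backTransformForecast <- function(forecast, params) {
  if (forecast@scale == "absolute") return(forecast)
  inv <- function(m) inverseScale(m, params)
  members <- forecast@memberPredictions
  for (i in seq_len(dim(members)[1]))
    members[i, , ] <- inv(members[i, , , drop = TRUE])
  g <- colnames(forecast@mean)
  rng <- params@maxs[g] - params@mins[g]
  deg <- params@degenerate[g]
  scaleFac <- ifelse(deg, 0, rng)
  newStd <- sweep(forecast@std, 2, scaleFac, "*")
  methods::new("EnsembleForecast", memberPredictions = members,
               mean = inv(forecast@mean), std = newStd,
               lower = inv(forecast@lower), upper = inv(forecast@upper),
               z = forecast@z, coverage = forecast@coverage,
               scale = "absolute", targetSteps = forecast@targetSteps)
}

#' Flag observations outside the prediction interval
#'
#' The strict-inequality rule: an observation is an outlier iff it lies
#' strictly below the lower or strictly above the upper interval bound;
#' boundary-equal values are not flagged. Rows with missing observations
#' are skipped (logged, never flagged). Degenerate genera have point
#' intervals, so any deviation flags — intentionally sensitive.
#'
#' @param observed T x G matrix of absolute abundances aligned to the
#'   forecast rows (NA rows = missing samples).
#' @param forecast an [EnsembleForecast-class]; if on the scaled scale,
#'   `params` is used to back-transform first.
#' @param params [ScalerParams-class] (required when the forecast is on
#'   the scaled scale).
#' @param timestamps optional labels per forecast row (default: the
#'   forecast target steps).
#' @return data.frame of class `outlierReport`, sorted by time then genus:
#'   columns time_step, timestamp, genus, observed, lower, upper,
#'   direction ("above"/"below"), exceedance (distance beyond the violated
#'   bound, >= 0).
#' @export
detectOutliers <- function(observed, forecast, params = NULL,
                           timestamps = NULL) {
  if (forecast@scale == "scaled") {
    if (is.null(params))
      stop("forecast is on the scaled scale; supply scaler params",
           call. = FALSE)
    forecast <- backTransformForecast(forecast, params)
  }
  observed <- as.matrix(observed)
  stopifnot(nrow(observed) == nrow(forecast@mean),
            ncol(observed) == ncol(forecast@mean))
  g <- colnames(forecast@mean)
  steps <- forecast@targetSteps
  if (is.null(timestamps)) timestamps <- as.character(steps)
  missingRows <- which(apply(observed, 1, function(r) all(is.na(r))))
  if (length(missingRows) > 0)
    message("skipping ", length(missingRows),
            " missing observation row(s): steps ",
            paste(steps[missingRows], collapse = ", "))
  above <- !is.na(observed) & observed > forecast@upper
  below <- !is.na(observed) & observed < forecast@lower
  idx <- which(above | below, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    rep <- data.frame(time_step = integer(), timestamp = character(),
                      genus = character(), observed = numeric(),
                      lower = numeric(), upper = numeric(),
                      direction = character(), exceedance = numeric(),
                      stringsAsFactors = FALSE)
  } else {
    o <- observed[idx]
    up <- above[idx]
    rep <- data.frame(
      time_step = steps[idx[, 1]],
      timestamp = timestamps[idx[, 1]],
      genus = g[idx[, 2]],
      observed = o,
      lower = forecast@lower[idx],
      upper = forecast@upper[idx],
      direction = ifelse(up, "above", "below"),
      exceedance = ifelse(up, o - forecast@upper[idx],
                          forecast@lower[idx] - o),
      stringsAsFactors = FALSE)
    rep <- rep[order(rep$time_step, rep$genus), ]
    rownames(rep) <- NULL
  }
  attr(rep, "nCells") <- sum(!is.na(observed))
  class(rep) <- c("outlierReport", "data.frame")
  rep
}

#' Write an outlier report as TSV
#'
#' @param report result of [detectOutliers()].
#' @param path output path.
#' @export
writeOutlierReport <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Plot an ensemble forecast for one genus
#'
#' Observed abundance over time with the ensemble mean prediction and the
#' shaded prediction interval; optional train/validation predictions are
#' overlaid so the full trajectory (train, validation, test + interval)
#' can be inspected per genus.
#'
#' @param forecast an [EnsembleForecast-class] (absolute scale, or supply
#'   `params`).
#' @param observed T x G matrix aligned to the forecast rows.
#' @param genus genus to plot.
#' @param params optional [ScalerParams-class] for back-transform.
#' @param trainObserved,trainPredicted optional matrices of earlier rows
#'   (with `trainSteps` giving their time steps).
#' @param trainSteps integer steps for the train block.
#' @return a ggplot object.
#' @export
plotEnsembleForecast <- function(forecast, observed, genus, params = NULL,
                                 trainObserved = NULL,
                                 trainPredicted = NULL,
                                 trainSteps = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  if (forecast@scale == "scaled")
    forecast <- backTransformForecast(forecast, params)
  j <- match(genus, colnames(forecast@mean))
  if (is.na(j)) stop("genus not in forecast: ", genus, call. = FALSE)
  df <- data.frame(step = forecast@targetSteps,
                   observed = as.matrix(observed)[, genus],
                   mean = forecast@mean[, j],
                   lower = forecast@lower[, j],
                   upper = forecast@upper[, j])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$step)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                      ymax = .data$upper),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean),
                       colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), size = 0.8) +
    ggplot2::labs(x = "time step", y = "absolute abundance",
                  title = genus,
                  subtitle = sprintf("%.0f%% ensemble prediction interval",
                                     100 * forecast@coverage)) +
    ggplot2::theme_minimal()
  if (!is.null(trainObserved) && !is.null(trainSteps)) {
    tdf <- data.frame(step = trainSteps,
                      observed = as.matrix(trainObserved)[, genus])
    p <- p + ggplot2::geom_point(data = tdf,
                                 ggplot2::aes(y = .data$observed),
                                 size = 0.8, colour = "grey50")
    if (!is.null(trainPredicted)) {
      tdf$pred <- as.matrix(trainPredicted)[, genus]
      p <- p + ggplot2::geom_line(data = tdf,
                                  ggplot2::aes(y = .data$pred),
                                  colour = "darkorange")
    }
  }
  p
}
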
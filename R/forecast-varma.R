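#' @include AllClasses.R AllGenerics.R forecast-common.R
NULL

## MacKinnon (2010) response-surface critical values for the Dickey-Fuller
## tau statistic: cval = b0 + b1/T + b2/T^2 + b3/T^3.
.dfCritTable <- list(
  none = rbind(`0.01` = c(-2.56574, -2.2358, -3.627, 0),
               `0.05` = c(-1.94100, -0.2686, -3.365, 31.223),
               `0.10` = c(-1.61682, 0.2656, -2.714, 25.364)),
  constant = rbind(`0.01` = c(-3.43035, -6.5393, -16.786, -79.433),
                   `0.05` = c(-2.86154, -2.8903, -4.234, -40.040),
                   `0.10` = c(-2.56677, -1.5384, -2.809, 0)),
  trend = rbind(`0.01` = c(-3.95877, -9.0531, -28.428, -134.155),
                `0.05` = c(-3.41049, -4.3904, -9.036, -45.374),
                `0.10` = c(-3.12705, -2.5856, -3.925, -22.380)))

#' Dickey-Fuller unit-root test
#'
#' Tests the null of a unit root (non-stationarity) in one series via the
#' regression of the first difference on the lagged level (plus optional
#' deterministic terms and augmentation lags). The tau statistic is
#' compared against MacKinnon response-surface critical values.
#'
#' @param x numeric vector.
#' @param type deterministic terms: "constant" (default), "none" or "trend".
#' @param lags augmentation lags (0 = the plain Dickey-Fuller test).
#' @param alpha significance level for the reported decision (one of
#'   0.01, 0.05, 0.10, or interpolated between them).
#' @return list with `statistic`, `criticalValues` (1/5/10%), `alpha`,
#'   `criticalValue` at `alpha`, and `stationary` (TRUE = unit root
#'   rejected).
#' @export
dickeyFullerTest <- function(x, type = c("constant", "none", "trend"),
                             lags = 0L, alpha = 0.05) {
  type <- match.arg(type)
  x <- as.numeric(x)
  n <- length(x)
  if (n < 10 + lags) stop("series too short for the unit-root test",
                          call. = FALSE)
  dx <- diff(x)
  xl <- x[-n]
  t0 <- seq_along(dx)
  X <- switch(type,
              none = cbind(xlag = xl),
              constant = cbind(xlag = xl, const = 1),
              trend = cbind(xlag = xl, const = 1, trend = t0))
  y <- dx
  if (lags > 0) {
    dlag <- sapply(seq_len(lags), function(k) {
      c(rep(NA, k), dx[seq_len(length(dx) - k)])
    })
    X <- cbind(X, dlag)
    keep <- stats::complete.cases(X)
    X <- X[keep, , drop = FALSE]
    y <- y[keep]
  }
  fit <- stats::lm.fit(X, y)
  res <- fit$residuals
  df <- length(y) - ncol(X)
  s2 <- sum(res^2) / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(s2 * XtXinv[1, 1])
  stat <- fit$coefficients["xlag"] / se
  Tn <- length(y)
  tab <- .dfCritTable[[type]]
  cvals <- tab[, 1] + tab[, 2] / Tn + tab[, 3] / Tn^2 + tab[, 4] / Tn^3
  names(cvals) <- rownames(tab)
  probs <- c(0.01, 0.05, 0.10)
  cv <- if (alpha %in% probs) cvals[as.character(alpha)]
        else stats::approx(probs, cvals, xout = alpha, rule = 2)$y
  list(statistic = unname(stat), criticalValues = cvals, alpha = alpha,
       criticalValue = unname(cv), stationary = unname(stat < cv))
}

## design matrix for the Hannan-Rissanen stage-2 regression
.varmaDesign <- function(w, e, p, q, trend, rows) {
  Tn <- nrow(w)
  blocks <- list()
  if (trend %in% c("constant", "linear"))
    blocks$const <- matrix(1, length(rows), 1)
  if (trend == "linear")
    blocks$t <- matrix(rows, ncol = 1)
  for (i in seq_len(p))
    blocks[[paste0("ar", i)]] <- w[rows - i, , drop = FALSE]
  for (j in seq_len(q))
    blocks[[paste0("ma", j)]] <- e[rows - j, , drop = FALSE]
  if (length(blocks) == 0)
    return(matrix(0, length(rows), 0))
  do.call(cbind, blocks)
}

.olsMultiresponse <- function(X, Y) {
  if (ncol(X) == 0) {
    return(list(B = matrix(0, 0, ncol(Y)), resid = Y))
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("singular design", call. = FALSE)
  B <- qr.coef(qrX, Y)
  list(B = B, resid = Y - X %*% B)
}

#' Fit the VARMA baseline
#'
#' Pipeline: (1) Dickey-Fuller unit-root test per genus column; (2) if any
#' column is non-stationary at the configured level, the series is
#' differenced once (d = 1) and retested; (3) (p, q) are selected from the
#' configured grid by AIC using Hannan-Rissanen two-stage estimation (a
#' long VAR supplies innovation estimates, then each candidate order is an
#' OLS regression on lagged values and lagged innovations over a common
#' effective sample); ties are broken toward the smaller p + q; (4) the
#' model is fitted with the configured trend. Forecasts are integrated
#' back to the undifferenced scale.
#'
#' Ill-conditioned fits drop the lowest-variance genus (with a warning)
#' and retry.
#'
#' @param train samples x genera matrix (scaled scale), at least 20 rows.
#' @param cfg a [VarmaConfig-class].
#' @return a [VarmaForecaster-class]; slot `gridAic` holds the AIC table.
#' @export
fitVarma <- function(train, cfg = varmaConfig()) {
  x <- as.matrix(train)
  if (is.null(colnames(x))) colnames(x) <- paste0("g", seq_len(ncol(x)))
  if (nrow(x) < 20)
    stop("VARMA needs at least 20 time points", call. = FALSE)
  generaAll <- colnames(x)
  repeat {
    fitted <- tryCatch(.fitVarmaCore(x, cfg), error = function(e) e)
    if (!inherits(fitted, "error")) break
    if (ncol(x) <= 1) stop(fitted)
    drop <- which.min(apply(x, 2, stats::var))
    warning(sprintf(
      "ill-conditioned VARMA fit (%s); dropping lowest-variance genus '%s'",
      conditionMessage(fitted), colnames(x)[drop]))
    x <- x[, -drop, drop = FALSE]
  }
  fitted
}

.fitVarmaCore <- function(x, cfg) {
  G <- ncol(x)
  Tn <- nrow(x)
  alpha <- cfg@stationarityAlpha
  ## stationarity check and differencing
  if (is.na(cfg@d)) {
    st0 <- apply(x, 2, function(col)
      dickeyFullerTest(col, "constant", alpha = alpha)$stationary)
    d <- if (all(st0)) 0L else 1L
  } else {
    d <- cfg@d
  }
  w <- if (d > 0) diff(x, differences = d) else x
  stationaryAfter <- apply(w, 2, function(col)
    dickeyFullerTest(col, "constant", alpha = alpha)$stationary)
  ## stage 1: long VAR for innovation estimates
  maxP <- if (is.na(cfg@p)) max(cfg@gridP) else cfg@p
  maxQ <- if (is.na(cfg@q)) max(cfg@gridQ) else cfg@q
  h <- min(max(4L, maxP + maxQ + 1L), floor((nrow(w) - 1) / 3))
  rows1 <- (h + 1):nrow(w)
  X1 <- .varmaDesign(w, matrix(0, nrow(w), G), h, 0L, "constant", rows1)
  e <- matrix(0, nrow(w), G)
  e[rows1, ] <- .olsMultiresponse(X1, w[rows1, , drop = FALSE])$resid
  ## stage 2: grid search over (p, q) on a common effective sample
  grid <- expand.grid(p = if (is.na(cfg@p)) cfg@gridP else cfg@p,
                      q = if (is.na(cfg@q)) cfg@gridQ else cfg@q)
  grid <- grid[order(grid$p + grid$q, grid$p, grid$q), ]
  start <- max(maxP, h + maxQ) + 1L
  if (start >= nrow(w))
    stop("series too short for the configured order grid", call. = FALSE)
  rows <- start:nrow(w)
  nEff <- length(rows)
  fits <- vector("list", nrow(grid))
  aics <- rep(NA_real_, nrow(grid))
  for (k in seq_len(nrow(grid))) {
    p <- grid$p[k]; q <- grid$q[k]
    Xk <- .varmaDesign(w, e, p, q, cfg@trend, rows)
    fk <- tryCatch(.olsMultiresponse(Xk, w[rows, , drop = FALSE]),
                   error = function(err) NULL)
    if (is.null(fk)) next
    Sigma <- crossprod(fk$resid) / nEff
    ld <- determinant(Sigma, logarithm = TRUE)
    if (ld$sign <= 0) next
    kPar <- ncol(Xk) * G
    aics[k] <- as.numeric(ld$modulus) + 2 * kPar / nEff
    fits[[k]] <- fk
  }
  if (all(is.na(aics)))
    stop("order grid exhausted without a valid fit", call. = FALSE)
  best <- which.min(aics)   # grid pre-sorted: ties fall to smaller p + q
  p <- grid$p[best]; q <- grid$q[best]
  fit <- fits[[best]]
  ## residuals over the full working series for forecasting state
  resid <- matrix(0, nrow(w), G)
  resid[rows, ] <- fit$resid
  gridAic <- data.frame(p = grid$p, q = grid$q, aic = aics)
  methods::new("VarmaForecaster",
               coef = list(B = fit$B, trend = cfg@trend, d = d,
                           stationaryAfter = stationaryAfter),
               order = c(p = as.integer(p), d = as.integer(d),
                         q = as.integer(q)),
               trend = cfg@trend,
               trainSeries = x, trainResiduals = resid,
               aic = aics[best], gridAic = gridAic,
               genera = colnames(x), covariateNames = character(),
               lag = as.integer(max(p + d, 1L)),
               inputWidth = G, outputWidth = G)
}

## one-step conditional mean on the working (differenced) scale
.varmaStep <- function(model, wHist, eHist, tIdx) {
  p <- model@order["p"]; q <- model@order["q"]
  B <- model@coef$B
  G <- model@outputWidth
  xrow <- numeric(0)
  if (model@trend %in% c("constant", "linear")) xrow <- c(xrow, 1)
  if (model@trend == "linear") xrow <- c(xrow, tIdx)
  for (i in seq_len(p)) xrow <- c(xrow, wHist[nrow(wHist) - i + 1L, ])
  for (j in seq_len(q)) xrow <- c(xrow, eHist[nrow(eHist) - j + 1L, ])
  if (length(xrow) == 0) return(rep(0, G))
  as.numeric(matrix(xrow, nrow = 1) %*% B)
}

#' Forecast with a fitted VARMA baseline
#'
#' Iterative mode extrapolates `steps` rows beyond the training series
#' (future innovations set to zero). Teacher-forced mode takes `newdata`,
#' the observed continuation of the training series, updates innovations
#' recursively, and returns one-step-ahead predictions for each new row.
#' Forecasts on a differenced fit are integrated back to the original
#' scale.
#'
#' @param model a [VarmaForecaster-class].
#' @param steps number of iterative steps (ignored in teacher-forced mode).
#' @param newdata observed continuation, samples x genera (teacher-forced).
#' @param mode "iterative" or "teacher_forced".
#' @return matrix of predictions on the training scale.
#' @export
varmaForecast <- function(model, steps = 1L, newdata = NULL,
                          mode = c("iterative", "teacher_forced")) {
  mode <- match.arg(mode)
  d <- model@order["d"]
  x <- model@trainSeries
  w <- if (d > 0) diff(x, differences = d) else x
  e <- model@trainResiduals
  tLast <- nrow(w)
  G <- model@outputWidth
  if (mode == "iterative") {
    preds <- matrix(NA_real_, steps, G, dimnames = list(NULL, model@genera))
    lastX <- x[nrow(x), ]
    for (s in seq_len(steps)) {
      wHat <- .varmaStep(model, w, e, tLast + s)
      w <- rbind(w, wHat)
      e <- rbind(e, rep(0, G))
      lastX <- if (d > 0) lastX + wHat else wHat
      preds[s, ] <- lastX
    }
    preds
  } else {
    stopifnot(!is.null(newdata))
    newdata <- as.matrix(newdata)
    n <- nrow(newdata)
    preds <- matrix(NA_real_, n, G, dimnames = list(NULL, model@genera))
    xFull <- rbind(x, newdata)
    for (s in seq_len(n)) {
      tNew <- nrow(x) + s
      wHat <- .varmaStep(model, w, e, tLast + s)
      preds[s, ] <- if (d > 0) xFull[tNew - 1, ] + wHat else wHat
      wObs <- if (d > 0) xFull[tNew, ] - xFull[tNew - 1, ] else xFull[tNew, ]
      w <- rbind(w, wObs)
      e <- rbind(e, wObs - wHat)
    }
    preds
  }
}

#' @rdname predictStep
#' @details For the VARMA baseline, `predictStep` conditions on the window
#'   levels only (innovations outside the training range are set to zero)
#'   and assumes the step follows the training series; full recursive
#'   prediction goes through [varmaForecast()].
#' @export
setMethod("predictStep", "VarmaForecaster", function(object, window) {
  window <- as.matrix(window)
  .checkWindowShape(object, window)
  d <- object@order["d"]
  w <- if (d > 0) diff(window) else window
  e <- matrix(0, max(object@order["q"], 1L), object@outputWidth)
  wHat <- .varmaStep(object, w, e, nrow(object@trainSeries) + 1L -
                       (d > 0))
  if (d > 0) window[nrow(window), ] + wHat else wHat
})

setMethod("show", "VarmaForecaster", function(object) {
  cat(sprintf("VarmaForecaster: order (%d,%d,%d), trend '%s', %d genera, AIC %.3f\n",
              object@order["p"], object@order["d"], object@order["q"],
              object@trend, object@outputWidth, object@aic))
  invisible(object)
})
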
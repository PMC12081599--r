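#' @include AllClasses.R AllGenerics.R forecast-common.R
NULL

## Compact native implementation of single-layer gated recurrent networks
## (LSTM / GRU) for short lag windows: full-batch backpropagation through
## time with Adam and MAE loss. Sequence length equals the lag (default 3),
## so exact BPTT is cheap even for wide layers.

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

.act <- function(x, kind) if (kind == "relu") pmax(x, 0) else tanh(x)
.dactPre <- function(pre, post, kind) {
  if (kind == "relu") (pre > 0) * 1 else 1 - post^2
}
## derivative of act evaluated at argument `x` (used for act(c) in LSTM)
.dactArg <- function(x, kind) {
  if (kind == "relu") (x > 0) * 1 else 1 - tanh(x)^2
}

.glorot <- function(nin, nout) {
  s <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -s, s), nrow = nin, ncol = nout)
}

.initRecurrentWeights <- function(cellType, W, H, G) {
  if (cellType == "lstm") {
    b <- rep(0, 4 * H)
    b[H + seq_len(H)] <- 1          # forget-gate bias
    list(Wx = .glorot(W, 4 * H), Wh = .glorot(H, 4 * H), b = b,
         Wy = .glorot(H, G), by = rep(0, G))
  } else {
    list(Wx = .glorot(W, 3 * H), Wh = .glorot(H, 3 * H), b = rep(0, 3 * H),
         Wy = .glorot(H, G), by = rep(0, G))
  }
}

## forward pass; returns caches when backward = TRUE
.recurrentForward <- function(weights, xs, cellType, actKind,
                              backward = FALSE) {
  N <- nrow(xs[[1]])
  H <- nrow(weights$Wy)
  h <- matrix(0, N, H)
  c <- matrix(0, N, H)
  caches <- if (backward) vector("list", length(xs))
  for (t in seq_along(xs)) {
    X <- xs[[t]]
    z <- X %*% weights$Wx + h %*% weights$Wh +
      matrix(weights$b, N, length(weights$b), byrow = TRUE)
    if (cellType == "lstm") {
      i <- .sigmoid(z[, seq_len(H), drop = FALSE])
      f <- .sigmoid(z[, H + seq_len(H), drop = FALSE])
      o <- .sigmoid(z[, 2 * H + seq_len(H), drop = FALSE])
      gPre <- z[, 3 * H + seq_len(H), drop = FALSE]
      g <- .act(gPre, actKind)
      cNew <- f * c + i * g
      actC <- .act(cNew, actKind)
      hNew <- o * actC
      if (backward)
        caches[[t]] <- list(X = X, hPrev = h, cPrev = c, i = i, f = f,
                            o = o, g = g, gPre = gPre, c = cNew,
                            actC = actC)
      h <- hNew; c <- cNew
    } else {
      zg <- .sigmoid(z[, seq_len(H), drop = FALSE])          # update
      r <- .sigmoid(z[, H + seq_len(H), drop = FALSE])       # reset
      nPre <- X %*% weights$Wx[, 2 * H + seq_len(H), drop = FALSE] +
        (r * h) %*% weights$Wh[, 2 * H + seq_len(H), drop = FALSE] +
        matrix(weights$b[2 * H + seq_len(H)], N, H, byrow = TRUE)
      n <- .act(nPre, actKind)
      hNew <- zg * h + (1 - zg) * n
      if (backward)
        caches[[t]] <- list(X = X, hPrev = h, z = zg, r = r,
                            nPre = nPre, n = n)
      h <- hNew
    }
  }
  list(h = h, caches = caches)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.recurrentPredictCore <- function(weights, xs, cellType, actKind) {
  fw <- .recurrentForward(weights, xs, cellType, actKind)
  sweep(fw$h %*% weights$Wy, 2, weights$by, "+")
}

## full gradient of the MAE loss wrt all weights for one batch
.recurrentGrad <- function(weights, xs, y, cellType, actKind, dropMask) {
  N <- nrow(y); G <- ncol(y); H <- nrow(weights$Wy)
  L <- length(xs)
  fw <- .recurrentForward(weights, xs, cellType, actKind, backward = TRUE)
  hOut <- fw$h * dropMask
  yhat <- sweep(hOut %*% weights$Wy, 2, weights$by, "+")
  dy <- sign(yhat - y) / (N * G)
  grads <- list(Wx = 0 * weights$Wx, Wh = 0 * weights$Wh,
                b = 0 * weights$b, Wy = t(hOut) %*% dy,
                by = colSums(dy))
  dh <- (dy %*% t(weights$Wy)) * dropMask
  dc <- matrix(0, N, H)
  for (t in rev(seq_len(L))) {
    cc <- fw$caches[[t]]
    if (cellType == "lstm") {
      do <- dh * cc$actC
      dc <- dc + dh * cc$o * .dactArg(cc$c, actKind)
      di <- dc * cc$g
      dg <- dc * cc$i
      df <- dc * cc$cPrev
      dcPrev <- dc * cc$f
      dzi <- di * cc$i * (1 - cc$i)
      dzf <- df * cc$f * (1 - cc$f)
      dzo <- do * cc$o * (1 - cc$o)
      dzg <- dg * .dactPre(cc$gPre, cc$g, actKind)
      dz <- cbind(dzi, dzf, dzo, dzg)
      grads$Wx <- grads$Wx + t(cc$X) %*% dz
      grads$Wh <- grads$Wh + t(cc$hPrev) %*% dz
      grads$b <- grads$b + colSums(dz)
      dh <- dz %*% t(weights$Wh)
      dc <- dcPrev
    } else {
      iz <- seq_len(H); ir <- H + seq_len(H); inn <- 2 * H + seq_len(H)
      dzGate <- dh * (cc$hPrev - cc$n)
      dn <- dh * (1 - cc$z)
      dhPrev <- dh * cc$z
      dnPre <- dn * .dactPre(cc$nPre, cc$n, actKind)
      grads$Wx[, inn] <- grads$Wx[, inn] + t(cc$X) %*% dnPre
      grads$Wh[, inn] <- grads$Wh[, inn] + t(cc$r * cc$hPrev) %*% dnPre
      grads$b[inn] <- grads$b[inn] + colSums(dnPre)
      drh <- dnPre %*% t(weights$Wh[, inn, drop = FALSE])
      dr <- drh * cc$hPrev
      dhPrev <- dhPrev + drh * cc$r
      dzPre <- dzGate * cc$z * (1 - cc$z)
      drPre <- dr * cc$r * (1 - cc$r)
      dzr <- cbind(dzPre, drPre)
      grads$Wx[, c(iz, ir)] <- grads$Wx[, c(iz, ir)] + t(cc$X) %*% dzr
      grads$Wh[, c(iz, ir)] <- grads$Wh[, c(iz, ir)] + t(cc$hPrev) %*% dzr
      grads$b[c(iz, ir)] <- grads$b[c(iz, ir)] + colSums(dzr)
      dh <- dzr %*% t(weights$Wh[, c(iz, ir), drop = FALSE]) + dhPrev
    }
  }
  list(grads = grads, loss = mean(abs(yhat - y)))
}

.adamStep <- function(weights, grads, state, lr, step,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(weights)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^step)
    vhat <- state$v[[nm]] / (1 - beta2^step)
    weights[[nm]] <- weights[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(weights = weights, state = state)
}

.splitTimeSlices <- function(inputs) {
  L <- dim(inputs)[2]
  lapply(seq_len(L), function(t)
    matrix(inputs[, t, ], nrow = dim(inputs)[1]))
}

#' @rdname fitForecaster
#' @details The recurrent backends train with full-batch Adam on the MAE
#'   loss over genus outputs; dropout (inverted, re-drawn per epoch) acts
#'   on the recurrent output, and early stopping restores the best weights
#'   by validation MAE. Runs are deterministic given the configuration seed
#'   under single-threaded execution.
#' @export
setMethod("fitForecaster", "RecurrentConfig", function(config, windows,
                                                       validation = NULL) {
  xs <- .splitTimeSlices(windows@inputs)
  y <- windows@targets
  if (anyNA(windows@inputs) || anyNA(y))
    stop("NaN/NA in training windows", call. = FALSE)
  W <- dim(windows@inputs)[3]
  G <- ncol(y)
  H <- config@cells
  act <- config@activation
  type <- config@cellType
  useVal <- !is.null(validation)
  if (useVal) {
    xsVal <- .splitTimeSlices(validation@inputs)
    yVal <- validation@targets
  } else if (config@patience < config@maxEpochs) {
    ## early stopping configured but nothing to monitor
    if (config@patience > 0 && is.null(validation) &&
        config@maxEpochs > 1L)
      warning("no validation set: early stopping disabled")
  }
  .withSeed(config@seed, {
    weights <- .initRecurrentWeights(type, W, H, G)
    state <- list(m = lapply(weights, function(w) 0 * w),
                  v = lapply(weights, function(w) 0 * w))
    best <- weights
    bestVal <- Inf
    sinceBest <- 0L
    log <- data.frame(epoch = integer(), train_mae = numeric(),
                      val_mae = numeric())
    stopped <- config@maxEpochs
    for (epoch in seq_len(config@maxEpochs)) {
      keep <- 1 - config@dropoutRate
      dropMask <- if (config@dropoutRate > 0)
        matrix(stats::rbinom(nrow(y) * H, 1, keep) / keep, nrow(y), H)
      else matrix(1, nrow(y), H)
      bp <- .recurrentGrad(weights, xs, y, type, act, dropMask)
      if (!is.finite(bp$loss))
        stop(sprintf("non-finite training loss at epoch %d", epoch),
             call. = FALSE)
      upd <- .adamStep(weights, bp$grads, state, config@learningRate, epoch)
      weights <- upd$weights
      state <- upd$state
      valMae <- NA_real_
      if (useVal) {
        pv <- .recurrentPredictCore(weights, xsVal, type, act)
        valMae <- mean(abs(pv - yVal))
        if (valMae < bestVal - 1e-12) {
          bestVal <- valMae
          best <- weights
          sinceBest <- 0L
        } else {
          sinceBest <- sinceBest + 1L
        }
      }
      log <- rbind(log, data.frame(epoch = epoch, train_mae = bp$loss,
                                   val_mae = valMae))
      if (useVal && sinceBest >= config@patience) {
        stopped <- epoch
        break
      }
      stopped <- epoch
    }
    if (useVal) weights <- best
    methods::new("RecurrentForecaster",
                 weights = weights, config = config, trainingLog = log,
                 stoppedEpoch = as.integer(stopped),
                 genera = windows@genera,
                 covariateNames = windows@covariateNames,
                 lag = windows@lag, inputWidth = as.integer(W),
                 outputWidth = as.integer(G))
  })
})

#' @rdname predictStep
#' @export
setMethod("predictStep", "RecurrentForecaster", function(object, window) {
  window <- as.matrix(window)
  .checkWindowShape(object, window)
  xs <- lapply(seq_len(nrow(window)), function(t)
    matrix(window[t, ], nrow = 1))
  as.numeric(.recurrentPredictCore(object@weights, xs,
                                   object@config@cellType,
                                   object@config@activation))
})

#' @rdname predictWindows
#' @export
setMethod("predictWindows", "RecurrentForecaster",
          function(object, windows) {
  xs <- .splitTimeSlices(windows@inputs)
  out <- .recurrentPredictCore(object@weights, xs,
                               object@config@cellType,
                               object@config@activation)
  dimnames(out) <- list(NULL, object@genera)
  out
})
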
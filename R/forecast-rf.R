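#' @include AllClasses.R AllGenerics.R forecast-common.R
#' @importFrom ranger ranger
NULL

.flattenWindows <- function(inputs) {
  d <- dim(inputs)                      # N x lag x width
  m <- matrix(inputs, nrow = d[1], ncol = d[2] * d[3])
  colnames(m) <- paste0("f", seq_len(ncol(m)))
  m
}

.flattenWindow <- function(window) {
  v <- as.numeric(window)
  names(v) <- paste0("f", seq_along(v))
  v
}

#' @rdname fitForecaster
#' @details For the random forest backend the lag window is flattened to a
#'   `lag * width` feature vector and one regression forest is grown per
#'   output genus (`ranger`, single-threaded, seeded: fits are deterministic
#'   given the configuration seed).
#' @export
setMethod("fitForecaster", "RfConfig", function(config, windows,
                                                validation = NULL) {
  x <- .flattenWindows(windows@inputs)
  if (anyNA(x) || anyNA(windows@targets))
    stop("NaN/NA in training windows", call. = FALSE)
  G <- length(windows@genera)
  models <- vector("list", G)
  names(models) <- windows@genera
  for (j in seq_len(G)) {
    df <- data.frame(.y = windows@targets[, j], x, check.names = FALSE)
    models[[j]] <- ranger::ranger(
      dependent.variable.name = ".y", data = df,
      num.trees = config@nTrees, num.threads = 1L,
      seed = config@seed + j - 1L, verbose = FALSE)
  }
  methods::new("RandomForestForecaster",
               models = models, config = config,
               genera = windows@genera,
               covariateNames = windows@covariateNames,
               lag = windows@lag,
               inputWidth = as.integer(dim(windows@inputs)[3]),
               outputWidth = as.integer(G))
})

#' @rdname predictWindows
#' @export
setMethod("predictWindows", "RandomForestForecaster",
          function(object, windows) {
  x <- as.data.frame(.flattenWindows(windows@inputs))
  if (anyNA(x)) stop("NaN/NA in prediction windows", call. = FALSE)
  out <- vapply(object@models, function(m)
    stats::predict(m, data = x, num.threads = 1L)$predictions,
    numeric(nrow(x)))
  out <- matrix(out, nrow = nrow(x),
                dimnames = list(NULL, object@genera))
  out
})

#' @rdname predictStep
#' @export
setMethod("predictStep", "RandomForestForecaster", function(object, window) {
  window <- as.matrix(window)
  .checkWindowShape(object, window)
  newdata <- as.data.frame(t(.flattenWindow(window)))
  vapply(object@models, function(m)
    stats::predict(m, data = newdata, num.threads = 1L)$predictions,
    numeric(1))
})
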
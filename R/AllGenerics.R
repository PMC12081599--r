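#' @include AllClasses.R
NULL

#' Abundance matrix in modeling orientation (samples x genera)
#'
#' @param x an [AbundanceSeries-class].
#' @return numeric matrix, rows = samples in time order, columns = genera.
#' @export
setGeneric("abundanceMatrix", function(x) standardGeneric("abundanceMatrix"))

#' Genus names of an object
#' @param x an object carrying a genus axis.
#' @export
setGeneric("genera", function(x) standardGeneric("genera"))

#' Canonical integer time steps
#' @param x an [AbundanceSeries-class].
#' @export
setGeneric("timeSteps", function(x) standardGeneric("timeSteps"))

#' Original timestamp labels
#' @param x an [AbundanceSeries-class].
#' @export
setGeneric("timeStamps", function(x) standardGeneric("timeStamps"))

#' Subject / sampling-site identifier
#' @param x an [AbundanceSeries-class].
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' Covariate matrix aligned to samples
#' @param x an [AbundanceSeries-class].
#' @param names covariates to extract; default all numeric covariate columns.
#' @export
setGeneric("covariateMatrix", function(x, names = NULL)
  standardGeneric("covariateMatrix"))

#' Fit a forecaster backend on a windowed dataset
#'
#' @param config a backend configuration ([RecurrentConfig-class] or
#'   [RfConfig-class]; the VARMA baseline is fitted from the raw matrix
#'   via [fitVarma()]).
#' @param windows training [WindowedDataset-class].
#' @param validation optional validation [WindowedDataset-class] (required
#'   for early stopping).
#' @return a fitted [Forecaster-class].
#' @export
setGeneric("fitForecaster", function(config, windows, validation = NULL)
  standardGeneric("fitForecaster"))

#' One-step prediction from a lag window
#'
#' @param object a fitted [Forecaster-class].
#' @param window numeric matrix lag x inputWidth (rows in time order,
#'   oldest first).
#' @return numeric vector of length `outputWidth` (one value per genus).
#' @export
setGeneric("predictStep", function(object, window)
  standardGeneric("predictStep"))
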
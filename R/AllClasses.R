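#' @import methods
#' @importFrom stats predict
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame
NULL

#' AbundanceSeries: a time-indexed genus-level feature table
#'
#' Container for a longitudinal genus-level abundance table from one subject
#' or sampling site. Extends [SummarizedExperiment::SummarizedExperiment]
#' with genera as rows and samples (time points) as columns; the `counts`
#' assay holds non-negative abundances (reads per OTU aggregated to genus).
#' Column data carry the canonical integer time step, the original timestamp
#' label, the subject/site identifier, an optional health flag, and any
#' numeric environmental covariates (precipitation, temperature, flow, TSS,
#' ammonium, BOD5, phosphorus, ...).
#'
#' Samples are kept as an ordered sequence of observed time points; missing
#' time points are represented by absence of a column, never by NA columns,
#' and irregular spacing is not resampled.
#'
#' @slot .Data inherited SummarizedExperiment structure.
#' @export
setClass("AbundanceSeries", contains = "SummarizedExperiment")

.validAbundanceSeries <- function(object) {
  msgs <- character()
  a <- SummarizedExperiment::assay(object, "counts")
  if (any(!is.finite(a)))
    msgs <- c(msgs, "counts contain non-finite values")
  neg <- which(a < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    msgs <- c(msgs, sprintf(
      "negative abundance at genus '%s', sample '%s'",
      rownames(a)[neg[1, 1]], colnames(a)[neg[1, 2]]))
  }
  g <- rownames(object)
  if (is.null(g) || anyDuplicated(g))
    msgs <- c(msgs, "genus names must be present and unique")
  ts <- object$time_step
  if (is.null(ts)) {
    msgs <- c(msgs, "colData must contain a 'time_step' column")
  } else if (length(ts) > 1 && any(diff(ts) <= 0)) {
    msgs <- c(msgs, "time steps must be strictly increasing")
  }
  if (length(msgs) > 0) msgs else TRUE
}
setValidity("AbundanceSeries", .validAbundanceSeries)

#' Per-genus min-max scaling parameters
#'
#' Fitted on the training partition only. Genera whose training column is
#' constant are recorded as degenerate: their forward transform maps to 0
#' and the inverse returns the constant.
#'
#' @slot mins named numeric, per-genus training minimum.
#' @slot maxs named numeric, per-genus training maximum.
#' @slot degenerate named logical, TRUE where max == min on the fit data.
#' @slot fittedOn label of the partition the parameters were fitted on.
#' @export
setClass("ScalerParams", representation(
  mins = "numeric", maxs = "numeric",
  degenerate = "logical", fittedOn = "character"))

setValidity("ScalerParams", function(object) {
  if (length(object@mins) != length(object@maxs))
    return("mins and maxs differ in length")
  if (any(object@maxs < object@mins))
    return("max < min for at least one genus")
  TRUE
})

#' Lag-window framing configuration
#'
#' @slot lag number of preceding time steps used as input (default 3).
#' @slot horizon forecast horizon in steps (default 1).
#' @slot covariateNames metadata covariates appended to each input row.
#' @export
setClass("WindowConfig", representation(
  lag = "integer", horizon = "integer", covariateNames = "character"))

setValidity("WindowConfig", function(object) {
  if (object@lag < 1L) return("lag must be >= 1")
  if (object@horizon < 1L) return("horizon must be >= 1")
  TRUE
})

#' Chronological split specification
#'
#' The series is cut into contiguous, time-ordered train / validation /
#' test blocks with no shuffling: the first `trainValFraction` of samples
#' form the train+validation block (of which the final `valFractionOfTrain`
#' is validation, used for early stopping), the remainder is the test block.
#'
#' @slot trainValFraction fraction of samples for train+validation (default 0.8).
#' @slot valFractionOfTrain fraction of the train+validation block held out
#'   as validation (default 0.1); 0 disables the validation block.
#' @export
setClass("SplitSpec", representation(
  trainValFraction = "numeric", valFractionOfTrain = "numeric"))

setValidity("SplitSpec", function(object) {
  if (object@trainValFraction <= 0 || object@trainValFraction >= 1)
    return("trainValFraction must be in (0, 1)")
  if (object@valFractionOfTrain < 0 || object@valFractionOfTrain >= 1)
    return("valFractionOfTrain must be in [0, 1)")
  TRUE
})

#' Lag-window supervised dataset
#'
#' @slot inputs array N x lag x width (genera then covariate columns).
#' @slot targets matrix N x G of next-step genus values.
#' @slot genera genus names (the model outputs).
#' @slot covariateNames covariate input columns, possibly empty.
#' @slot lag window length.
#' @slot targetSteps integer time step of each target row.
#' @export
setClass("WindowedDataset", representation(
  inputs = "array", targets = "matrix", genera = "character",
  covariateNames = "character", lag = "integer", targetSteps = "integer"))

#' Genus roster for harmonization
#'
#' Ordered, unique genus names with a per-name provenance tag: "observed"
#' (seen in at least one table) or "supplement" (added from an external
#' list, e.g. baseline gut taxa or sepsis-associated genera).
#'
#' @slot names ordered unique genus names.
#' @slot provenance per-name tag, "observed" or "supplement".
#' @export
setClass("GenusRoster", representation(
  names = "character", provenance = "character"))

setValidity("GenusRoster", function(object) {
  if (anyDuplicated(object@names)) return("roster names must be unique")
  if (length(object@provenance) != length(object@names))
    return("provenance must match names in length")
  if (!all(object@provenance %in% c("observed", "supplement")))
    return("provenance must be 'observed' or 'supplement'")
  TRUE
})

## ---- forecaster configs -----------------------------------------------

#' Recurrent network configuration (LSTM or GRU)
#'
#' Single-layer recurrent architectures: gated cells over the lag window,
#' ReLU cell activation, a linear dense output layer of width G, MAE loss
#' on the genus outputs, Adam optimisation, dropout on the recurrent
#' output, early stopping on validation loss.
#'
#' @slot cellType "lstm" or "gru".
#' @slot layers number of recurrent layers (currently 1).
#' @slot cells hidden units per layer (the published architecture uses 2048;
#'   small series are well served by far fewer).
#' @slot activation cell activation, "relu" (default) or "tanh".
#' @slot dropoutRate dropout on the recurrent output during training.
#' @slot learningRate Adam step size.
#' @slot maxEpochs training epoch cap.
#' @slot patience early-stopping patience in epochs (monitor: validation MAE).
#' @slot seed RNG seed for weight initialisation and dropout.
#' @export
setClass("RecurrentConfig", representation(
  cellType = "character", layers = "integer", cells = "integer",
  activation = "character", dropoutRate = "numeric",
  learningRate = "numeric", maxEpochs = "integer", patience = "integer",
  seed = "integer"))

setValidity("RecurrentConfig", function(object) {
  if (!object@cellType %in% c("lstm", "gru"))
    return("cellType must be 'lstm' or 'gru'")
  if (object@cells < 1L) return("cells must be >= 1")
  if (object@dropoutRate < 0 || object@dropoutRate >= 1)
    return("dropoutRate must be in [0, 1)")
  TRUE
})

#' Random forest configuration
#'
#' The lag window is flattened to a feature vector (lag x width columns);
#' one regression forest is grown per output genus. The published setup
#' uses 100 estimators with a mean-absolute-error split criterion; the
#' forests here use variance splitting (the criterion field is recorded
#' for provenance).
#'
#' @slot nTrees trees per forest (default 100).
#' @slot splitCriterion recorded criterion label.
#' @slot seed RNG seed; fits are deterministic given the seed.
#' @export
setClass("RfConfig", representation(
  nTrees = "integer", splitCriterion = "character", seed = "integer"))

setValidity("RfConfig", function(object) {
  if (object@nTrees < 1L) return("nTrees must be >= 1")
  TRUE
})

#' VARMA baseline configuration
#'
#' @slot p autoregressive order (NA = select from grid).
#' @slot d differencing order applied after the stationarity check.
#' @slot q moving-average order (NA = select from grid).
#' @slot trend "none", "constant" or "linear".
#' @slot gridP,gridQ candidate orders for the AIC grid search.
#' @slot stationarityAlpha significance level of the Dickey-Fuller check.
#' @export
setClass("VarmaConfig", representation(
  p = "integer", d = "integer", q = "integer", trend = "character",
  gridP = "integer", gridQ = "integer", stationarityAlpha = "numeric"))

setValidity("VarmaConfig", function(object) {
  if (!object@trend %in% c("none", "constant", "linear"))
    return("trend must be 'none', 'constant' or 'linear'")
  if (length(object@gridP) == 0 || length(object@gridQ) == 0)
    return("order grid must be non-empty")
  if (object@stationarityAlpha <= 0 || object@stationarityAlpha >= 1)
    return("stationarityAlpha must be in (0, 1)")
  TRUE
})

## ---- fitted forecasters -----------------------------------------------

#' Virtual parent of all fitted forecasters
#'
#' A fitted forecaster maps a lag x width input window to one row of G
#' genus predictions. `inputWidth` = number of genera plus covariates;
#' `outputWidth` = number of genera.
#'
#' @export
setClass("Forecaster", representation(
  "VIRTUAL",
  genera = "character", covariateNames = "character",
  lag = "integer", inputWidth = "integer", outputWidth = "integer"))

#' @describeIn Forecaster random forest backend (one `ranger` forest per genus).
#' @export
setClass("RandomForestForecaster", contains = "Forecaster",
  representation(models = "list", config = "RfConfig"))

#' @describeIn Forecaster native recurrent backend (LSTM or GRU weights).
#' @export
setClass("RecurrentForecaster", contains = "Forecaster",
  representation(weights = "list", config = "RecurrentConfig",
                 trainingLog = "data.frame", stoppedEpoch = "integer"))

#' @describeIn Forecaster VARMA baseline (Hannan-Rissanen regression fit).
#' @export
setClass("VarmaForecaster", contains = "Forecaster",
  representation(coef = "list", order = "integer", trend = "character",
                 trainSeries = "matrix", trainResiduals = "matrix",
                 aic = "numeric", gridAic = "data.frame"))

#' @describeIn Forecaster deterministic forecaster wrapping a user function
#'   of the lag window; used for baselines (persistence) and testing mocks.
#' @export
setClass("FunctionForecaster", contains = "Forecaster",
  representation(fn = "function", label = "character"))

## ---- ensemble / interval ----------------------------------------------

#' Ensemble configuration for prediction intervals
#'
#' @slot nMembers ensemble size (default 50, as in the published interval).
#' @slot coverage two-sided interval coverage (default 0.95).
#' @slot z standard-normal critical value consistent with `coverage`
#'   (1.959964 for 0.95).
#' @slot seeds distinct member seeds, length `nMembers`.
#' @slot stdDdof degrees-of-freedom convention for the member standard
#'   deviation: 1 (sample sd, default) or 0.
#' @export
setClass("EnsembleConfig", representation(
  nMembers = "integer", coverage = "numeric", z = "numeric",
  seeds = "integer", stdDdof = "integer"))

setValidity("EnsembleConfig", function(object) {
  if (object@nMembers < 2L) return("nMembers must be >= 2")
  if (object@coverage <= 0 || object@coverage >= 1)
    return("coverage must be in (0, 1)")
  zref <- stats::qnorm(1 - (1 - object@coverage) / 2)
  if (abs(object@z - zref) > 1e-3)
    return(sprintf("z = %.4f inconsistent with coverage %.3f (expect %.4f)",
                   object@z, object@coverage, zref))
  if (length(object@seeds) != object@nMembers)
    return("seeds must have length nMembers")
  if (anyDuplicated(object@seeds)) return("member seeds must be distinct")
  if (!object@stdDdof %in% c(0L, 1L)) return("stdDdof must be 0 or 1")
  TRUE
})

#' Ensemble forecast with z-based prediction interval
#'
#' Per time point and genus: the member predictions, their mean and
#' standard deviation, and the interval `mean +/- z * std`.
#'
#' @slot memberPredictions array N x T x G.
#' @slot mean,std,lower,upper matrices T x G.
#' @slot z,coverage interval parameters.
#' @slot scale "scaled" or "absolute".
#' @slot targetSteps integer time step of each forecast row.
#' @export
setClass("EnsembleForecast", representation(
  memberPredictions = "array", mean = "matrix", std = "matrix",
  lower = "matrix", upper = "matrix", z = "numeric", coverage = "numeric",
  scale = "character", targetSteps = "integer"))

setValidity("EnsembleForecast", function(object) {
  if (any(object@lower > object@mean + 1e-12) ||
      any(object@upper < object@mean - 1e-12))
    return("interval must satisfy lower <= mean <= upper")
  TRUE
})

## ---- synthetic truth ---------------------------------------------------

#' Ground-truth description of a synthetic community
#'
#' Per-genus latent process parameters (baseline, seasonality,
#' autocorrelation, noise, zero-inflation), a list of injected shift
#' events, covariate generator settings and the master seed. Regeneration
#' from the same object is bit-identical.
#'
#' @slot specs data.frame, one row per genus: genus, baseline,
#'   seasonal_amplitude, seasonal_period, phase, ar_coefficient, noise_sd,
#'   zero_inflation_prob, dispersion.
#' @slot events data.frame of shift events: timestep, genus, kind
#'   ("spike" | "level_shift" | "dropout"), magnitude, duration.
#' @slot covariates character, subset of c("temperature", "precipitation").
#' @slot seed master seed.
#' @slot label preset name.
#' @slot length default series length T.
#' @slot missingProb probability that a sample (whole row) is missing.
#' @slot maskSteps time steps that are always dropped (e.g. winter months
#'   with no sampling).
#' @export
setClass("SyntheticTruth", representation(
  specs = "data.frame", events = "data.frame", covariates = "character",
  seed = "integer", label = "character", length = "integer",
  missingProb = "numeric", maskSteps = "integer"))

setValidity("SyntheticTruth", function(object) {
  s <- object@specs
  need <- c("genus", "baseline", "seasonal_amplitude", "seasonal_period",
            "phase", "ar_coefficient", "noise_sd", "zero_inflation_prob",
            "dispersion")
  if (!all(need %in% names(s)))
    return(paste("specs must contain columns:", paste(need, collapse = ", ")))
  if (any(s$baseline < 0)) return("baseline must be >= 0")
  if (any(abs(s$ar_coefficient) >= 1)) return("|ar_coefficient| must be < 1")
  if (any(s$noise_sd < 0)) return("noise_sd must be >= 0")
  if (any(s$zero_inflation_prob < 0 | s$zero_inflation_prob >= 1))
    return("zero_inflation_prob must be in [0, 1)")
  e <- object@events
  if (nrow(e) > 0) {
    if (!all(e$kind %in% c("spike", "level_shift", "dropout")))
      return("event kind must be spike, level_shift or dropout")
    if (any(e$magnitude <= 0)) return("event magnitude must be > 0")
    if (!all(e$genus %in% s$genus)) return("event genus not in specs")
  }
  TRUE
})

## ---- network ------------------------------------------------------------

#' Genus-genus co-occurrence correlation network
#'
#' Undirected network over genera; an edge is retained when the absolute
#' correlation coefficient reaches the threshold and (optionally) the
#' BH-adjusted p-value passes the FDR level. Genera without any retained
#' edge are excluded from the node set.
#'
#' @slot metric "spearman", "pearson" or "kendall".
#' @slot nodes genera with at least one retained edge.
#' @slot edges data.frame: genus_a, genus_b (a < b), coefficient, p_value,
#'   q_value.
#' @slot edgeThreshold minimum |coefficient|.
#' @slot fdrAlpha FDR level (NA when disabled).
#' @export
setClass("CorrelationNetwork", representation(
  metric = "character", nodes = "character", edges = "data.frame",
  edgeThreshold = "numeric", fdrAlpha = "numeric"))

#' Evaluation metrics report
#'
#' MAE / RMSE / NRMSE per split (pooled over all time x genus cells) and
#' per genus per split, with test/train overfit ratios and flag.
#'
#' @slot perSplit data.frame: split, mae, rmse, nrmse.
#' @slot perGenus data.frame: split, genus, mae, rmse, nrmse.
#' @slot overfitRatios named numeric test/train ratios (NA where undefined).
#' @slot overfitFlag logical.
#' @slot threshold ratio threshold used for the flag.
#' @slot scale "absolute" or "scaled".
#' @export
setClass("MetricsReport", representation(
  perSplit = "data.frame", perGenus = "data.frame",
  overfitRatios = "numeric", overfitFlag = "logical",
  threshold = "numeric", scale = "character"))
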
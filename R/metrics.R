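#' @include AllClasses.R
NULL

#' Mean absolute error
#'
#' @param observed,predicted numeric vectors or matrices of equal size.
#' @return mean of `|observed - predicted|` over all cells.
#' @export
mae <- function(observed, predicted) {
  o <- as.numeric(observed); p <- as.numeric(predicted)
  if (length(o) == 0) stop("empty input", call. = FALSE)
  if (length(o) != length(p)) stop("length mismatch", call. = FALSE)
  mean(abs(o - p))
}

#' Root mean squared error
#'
#' @inheritParams mae
#' @return `sqrt(mean((observed - predicted)^2))`.
#' @export
rmse <- function(observed, predicted) {
  o <- as.numeric(observed); p <- as.numeric(predicted)
  if (length(o) == 0) stop("empty input", call. = FALSE)
  if (length(o) != length(p)) stop("length mismatch", call. = FALSE)
  sqrt(mean((o - p)^2))
}

#' Normalized root mean squared error
#'
#' RMSE divided by the standard deviation of the *predicted* values (the
#' convention used throughout this package: it makes errors comparable
#' across genera of very different abundance, since a common affine
#' rescaling of both vectors leaves it unchanged). Note the denominator is
#' the predictions' spread, not the observations' — the documented
#' contract here.
#'
#' When the predictions are constant their standard deviation is zero and
#' the NRMSE is undefined: `NA` is returned with a warning, never
#' infinity.
#'
#' @inheritParams mae
#' @param ddof denominator degrees of freedom for the standard deviation
#'   (1 = sample sd, default).
#' @return NRMSE, or `NA_real_` when undefined.
#' @export
nrmse <- function(observed, predicted, ddof = 1L) {
  p <- as.numeric(predicted)
  if (length(p) < 2) stop("need at least 2 predictions", call. = FALSE)
  n <- length(p)
  s <- sqrt(sum((p - mean(p))^2) / (n - ddof))
  if (s == 0) {
    warning("constant predictions: NRMSE undefined")
    return(NA_real_)
  }
  rmse(observed, p) / s
}

.metricRow <- function(obs, pred) {
  data.frame(mae = mae(obs, pred), rmse = rmse(obs, pred),
             nrmse = suppressWarnings(nrmse(obs, pred)))
}

#' Evaluate predictions across splits
#'
#' Computes MAE, RMSE and NRMSE pooled over all (time, genus) cells per
#' split, and the same three metrics per genus per split, plus the
#' overfit diagnostic (test/train ratios).
#'
#' @param observed named list of observed matrices per split (subset of
#'   `train`, `validation`, `test`), each T x G, absolute scale.
#' @param predicted named list of prediction matrices matching `observed`.
#' @param threshold overfit ratio threshold (default 3).
#' @param scale label recorded on the report ("absolute" or "scaled").
#' @return a [MetricsReport-class].
#' @export
evaluateForecast <- function(observed, predicted, threshold = 3,
                             scale = "absolute") {
  splits <- names(observed)
  stopifnot(!is.null(splits), all(splits %in% names(predicted)))
  perSplit <- do.call(rbind, lapply(splits, function(s) {
    cbind(split = s, .metricRow(observed[[s]], predicted[[s]]))
  }))
  perGenus <- do.call(rbind, lapply(splits, function(s) {
    o <- as.matrix(observed[[s]]); p <- as.matrix(predicted[[s]])
    do.call(rbind, lapply(seq_len(ncol(o)), function(j) {
      cbind(split = s, genus = colnames(o)[j] %||% paste0("g", j),
            .metricRow(o[, j], p[, j]))
    }))
  }))
  od <- overfitDiagnostic(perSplit, threshold = threshold)
  methods::new("MetricsReport", perSplit = perSplit, perGenus = perGenus,
               overfitRatios = od$ratios, overfitFlag = od$flag,
               threshold = threshold, scale = scale)
}

#' Overfit diagnostic from train/test metrics
#'
#' Flags overfitting when the test metric exceeds the training metric by
#' more than `threshold` times, for MAE or RMSE. A zero training metric
#' makes that ratio undefined (reported NA); the flag is then decided on
#' the remaining metrics.
#'
#' @param metrics either a per-split data.frame with columns `split`,
#'   `mae`, `rmse` (rows "train" and "test"), or a named numeric vector
#'   `c(mae_train=, mae_test=, rmse_train=, rmse_test=)` (rmse optional).
#' @param threshold ratio threshold, default 3 (a stricter convention of 2
#'   is sometimes used; the threshold is configurable).
#' @return list with `ratios` (named numeric, NA where undefined) and
#'   `flag` (logical).
#' @export
overfitDiagnostic <- function(metrics, threshold = 3) {
  if (is.data.frame(metrics)) {
    tr <- metrics[metrics$split == "train", , drop = FALSE]
    te <- metrics[metrics$split == "test", , drop = FALSE]
    if (nrow(tr) == 0 || nrow(te) == 0)
      return(list(ratios = c(mae = NA_real_, rmse = NA_real_),
                  flag = FALSE))
    v <- c(mae_train = tr$mae[1], mae_test = te$mae[1],
           rmse_train = tr$rmse[1], rmse_test = te$rmse[1])
  } else {
    v <- metrics
  }
  ratio1 <- function(trainV, testV) {
    trainV <- unname(trainV); testV <- unname(testV)
    if (length(trainV) == 0 || length(testV) == 0) return(NA_real_)
    if (is.na(trainV) || is.na(testV) || trainV == 0) return(NA_real_)
    testV / trainV
  }
  ratios <- c(mae = ratio1(v["mae_train"], v["mae_test"]),
              rmse = ratio1(v["rmse_train"], v["rmse_test"]))
  flag <- isTRUE(any(ratios > threshold, na.rm = TRUE))
  list(ratios = ratios, flag = flag)
}

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport (%s scale)\n", object@scale))
  ps <- object@perSplit
  for (i in seq_len(nrow(ps)))
    cat(sprintf("  %-10s MAE %.2f  RMSE %.2f  NRMSE %s\n",
                ps$split[i], ps$mae[i], ps$rmse[i],
                ifelse(is.na(ps$nrmse[i]), "undefined",
                       sprintf("%.2f", ps$nrmse[i]))))
  r <- object@overfitRatios
  cat(sprintf("  overfit (test/train > %.1f): %s [MAE ratio %s, RMSE ratio %s]\n",
              object@threshold,
              ifelse(object@overfitFlag, "FLAGGED", "no"),
              ifelse(is.na(r["mae"]), "undefined", sprintf("%.2f", r["mae"])),
              ifelse(is.na(r["rmse"]), "undefined",
                     sprintf("%.2f", r["rmse"]))))
  invisible(object)
})

#' Write a metrics report
#'
#' JSON summary (full precision) plus a per-genus TSV next to it.
#'
#' @param report a [MetricsReport-class].
#' @param path output path for the JSON file; the per-genus table goes to
#'   `<path>.per_genus.tsv`.
#' @export
writeMetricsReport <- function(report, path) {
  jsonlite::write_json(
    list(scale = report@scale,
         per_split = report@perSplit,
         overfit_ratios = as.list(report@overfitRatios),
         overfit_flag = report@overfitFlag,
         threshold = report@threshold),
    path, auto_unbox = TRUE, digits = NA, na = "null", dataframe = "rows")
  utils::write.table(report@perGenus, paste0(path, ".per_genus.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
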
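#' @include AllClasses.R AllGenerics.R forecast-recurrent.R
NULL

#' Per-genus latent process parameters
#'
#' Builds the specs table of a [SyntheticTruth-class]: each genus follows
#' a seasonal sinusoid plus an AR(1) deviation process with Gaussian
#' innovations, rounded to non-negative counts, with optional
#' zero-inflation and Poisson-like dispersion jitter.
#'
#' @param genus genus names.
#' @param baseline mean abundance (counts).
#' @param seasonalAmplitude amplitude of the seasonal sinusoid (counts).
#' @param seasonalPeriod period in time steps.
#' @param phase phase offset (radians).
#' @param arCoefficient AR(1) coefficient of the deviation process,
#'   |phi| < 1.
#' @param noiseSd innovation standard deviation (counts).
#' @param zeroInflationProb probability a cell is masked to zero.
#' @param dispersion extra count jitter: sd = dispersion * sqrt(latent).
#' @return data.frame, one row per genus (recycled arguments allowed).
#' @export
genusProcessSpec <- function(genus, baseline, seasonalAmplitude = 0,
                             seasonalPeriod = 12, phase = 0,
                             arCoefficient = 0, noiseSd = 0,
                             zeroInflationProb = 0, dispersion = 0) {
  data.frame(genus = genus, baseline = baseline,
             seasonal_amplitude = seasonalAmplitude,
             seasonal_period = seasonalPeriod, phase = phase,
             ar_coefficient = arCoefficient, noise_sd = noiseSd,
             zero_inflation_prob = zeroInflationProb,
             dispersion = dispersion, stringsAsFactors = FALSE)
}

#' Injected shift events
#'
#' Ground-truth perturbations applied to the latent series after the noise
#' draw, so truth labels are unambiguous: `spike` multiplies the value by
#' `magnitude`, `level_shift` adds `magnitude * noise_sd`, `dropout` sets
#' the value to zero. Each lasts `duration` steps.
#'
#' @param timestep first affected time step.
#' @param genus affected genus.
#' @param kind "spike", "level_shift" or "dropout".
#' @param magnitude multiplicative factor (spike) or additive size in
#'   noise-sd units (level_shift); ignored for dropout (use 1).
#' @param duration steps affected (default 1).
#' @return data.frame of events (vectorized over arguments).
#' @export
shiftEvent <- function(timestep, genus, kind = "spike", magnitude = 3,
                       duration = 1L) {
  data.frame(timestep = as.integer(timestep), genus = genus, kind = kind,
             magnitude = magnitude, duration = as.integer(duration),
             stringsAsFactors = FALSE)
}

#' @rdname SyntheticTruth-class
#' @param specs,events,covariates,seed,label,length,missingProb,maskSteps
#'   see slot documentation.
#' @export
syntheticTruth <- function(specs, events = NULL, covariates = character(),
                           seed = 1L, label = "custom", length = 100L,
                           missingProb = 0, maskSteps = integer()) {
  if (is.null(events))
    events <- shiftEvent(integer(), character(), character(), numeric(),
                         integer())
  methods::new("SyntheticTruth", specs = specs, events = events,
               covariates = covariates, seed = as.integer(seed),
               label = label, length = as.integer(length),
               missingProb = missingProb,
               maskSteps = as.integer(maskSteps))
}

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf(
    "SyntheticTruth '%s': %d genera, T = %d, %d event(s), seed %d\n",
    object@label, nrow(object@specs), object@length, nrow(object@events),
    object@seed))
  if (length(object@covariates) > 0)
    cat("  covariates:", paste(object@covariates, collapse = ", "), "\n")
  invisible(object)
})

#' Generate a synthetic community time series
#'
#' Per genus, the latent value is
#' `x_t = baseline + amplitude * sin(2 * pi * t / period + phase) + s_t`
#' with AR(1) deviations `s_t = phi * s_{t-1} + eps_t`,
#' `eps_t ~ N(0, noise_sd^2)`; counts are `max(0, round(x_t))` after
#' optional dispersion jitter and zero-inflation masking. Shift events are
#' applied after the noise draw and their surviving cells are the truth
#' labels. Rows are dropped with probability `missingProb` (plus the
#' preset's fixed mask) to emulate sampling gaps. Regeneration from the
#' same truth object is bit-identical.
#'
#' @param truth a [SyntheticTruth-class].
#' @param T series length (default: the truth's configured length).
#' @param missingProb row-missingness probability (default: the truth's).
#' @return list with `series` (an [AbundanceSeries-class]; integer
#'   timestamps reveal gaps), `metadata` (data.frame with sample_id,
#'   timestamp, health_flag and covariates), `labels` (data.frame
#'   timestep, genus, kind of surviving event cells) and `latent` (the
#'   noiseless-masking count matrix including all rows).
#' @export
generateSeries <- function(truth, T = truth@length,
                           missingProb = truth@missingProb) {
  specs <- truth@specs
  G <- nrow(specs)
  .withSeed(truth@seed, {
    lat <- matrix(0, nrow = T, ncol = G,
                  dimnames = list(NULL, specs$genus))
    for (j in seq_len(G)) {
      sp <- specs[j, ]
      t <- seq_len(T)
      det <- sp$baseline + sp$seasonal_amplitude *
        sin(2 * pi * t / sp$seasonal_period + sp$phase)
      eps <- stats::rnorm(T, 0, sp$noise_sd)
      s <- numeric(T)
      s[1] <- eps[1]
      for (k in 2:T) s[k] <- sp$ar_coefficient * s[k - 1] + eps[k]
      x <- det + s
      if (sp$dispersion > 0)
        x <- x + stats::rnorm(T, 0, sp$dispersion * sqrt(pmax(x, 1)))
      if (sp$zero_inflation_prob > 0) {
        mask <- stats::runif(T) < sp$zero_inflation_prob
        x[mask] <- 0
      }
      lat[, j] <- x
    }
    ## events applied after the latent draw
    ev <- truth@events
    labelList <- list()
    if (nrow(ev) > 0) {
      for (i in seq_len(nrow(ev))) {
        steps <- ev$timestep[i] + seq_len(ev$duration[i]) - 1L
        steps <- steps[steps >= 1 & steps <= T]
        j <- match(ev$genus[i], specs$genus)
        sd <- specs$noise_sd[j]
        for (st in steps) {
          lat[st, j] <- switch(ev$kind[i],
            spike = lat[st, j] * ev$magnitude[i],
            level_shift = lat[st, j] + ev$magnitude[i] * sd,
            dropout = 0)
        }
        labelList[[i]] <- data.frame(timestep = steps,
                                     genus = ev$genus[i],
                                     kind = ev$kind[i],
                                     stringsAsFactors = FALSE)
      }
    }
    labels <- if (length(labelList) > 0) do.call(rbind, labelList)
              else data.frame(timestep = integer(), genus = character(),
                              kind = character(), stringsAsFactors = FALSE)
    counts <- pmax(round(lat), 0)
    ## covariates
    covs <- NULL
    if (length(truth@covariates) > 0) {
      period <- max(specs$seasonal_period)
      covs <- data.frame(row.names = seq_len(T))
      if ("temperature" %in% truth@covariates)
        covs$temperature <- 12 + 10 * sin(2 * pi * seq_len(T) / period) +
          stats::rnorm(T, 0, 1.5)
      if ("precipitation" %in% truth@covariates)
        covs$precipitation <- stats::rgamma(T, shape = 1.5, scale = 20)
    }
    ## row-wise missingness: whole samples absent
    keep <- rep(TRUE, T)
    if (missingProb > 0) keep <- stats::runif(T) >= missingProb
    keep[truth@maskSteps[truth@maskSteps <= T]] <- FALSE
    kept <- which(keep)
    m <- counts[kept, , drop = FALSE]
    rownames(m) <- sprintf("s%04d", kept)
    series <- AbundanceSeries(
      m, timestamps = kept, subjectId = truth@label,
      covariates = if (!is.null(covs)) covs[kept, , drop = FALSE],
      healthFlag = rep(FALSE, length(kept)))
    labels <- labels[labels$timestep %in% kept, , drop = FALSE]
    rownames(labels) <- NULL
    meta <- data.frame(sample_id = rownames(m), timestamp = kept,
                       health_flag = FALSE, stringsAsFactors = FALSE)
    if (!is.null(covs)) meta <- cbind(meta, covs[kept, , drop = FALSE])
    list(series = series, metadata = meta, labels = labels,
         latent = counts)
  })
}

#' Preset synthetic scenarios
#'
#' Fully parameterized, seeded presets mirroring the sampling designs the
#' method targets:
#' * `gut_dense` — a densely sampled human-gut-like series: 20 genera over
#'   396 time points, no covariates, abundances spanning two orders of
#'   magnitude, weak day-to-day persistence and a slow seasonal component.
#' * `wastewater_monthly_gappy` — six years of monthly influent sampling
#'   with an annual cycle, temperature and precipitation covariates, and
#'   all winter months (December-February) missing.
#' * `wastewater_weekly` — two years of weekly sampling with an annual
#'   cycle, covariates and occasional random gaps.
#'
#' @return named list of [SyntheticTruth-class] objects.
#' @export
scenarioLibrary <- function() {
  gutSpecs <- .withSeed(101L, {
    G <- 20
    baseline <- round(exp(stats::rnorm(G, mean = log(300), sd = 1)))
    genusProcessSpec(
      genus = sprintf("Genus%02d", seq_len(G)),
      baseline = baseline,
      seasonalAmplitude = 0.25 * baseline,
      seasonalPeriod = 30,
      phase = stats::runif(G, 0, 2 * pi),
      arCoefficient = 0.4,
      noiseSd = 0.15 * baseline,
      zeroInflationProb = ifelse(baseline < 100, 0.05, 0))
  })
  wwSpecs <- function(seedOffset, period) .withSeed(202L + seedOffset, {
    G <- 15
    baseline <- round(exp(stats::rnorm(G, mean = log(500), sd = 0.8)))
    genusProcessSpec(
      genus = sprintf("Genus%02d", seq_len(G)),
      baseline = baseline,
      seasonalAmplitude = 0.35 * baseline,
      seasonalPeriod = period,
      phase = stats::runif(G, 0, 2 * pi),
      arCoefficient = 0.5,
      noiseSd = 0.2 * baseline,
      zeroInflationProb = 0.02)
  })
  Tmonthly <- 72L
  winter <- which(((seq_len(Tmonthly) - 1L) %% 12L) %in% c(11L, 0L, 1L))
  list(
    gut_dense = syntheticTruth(
      gutSpecs, covariates = character(), seed = 11L,
      label = "gut_dense", length = 396L),
    wastewater_monthly_gappy = syntheticTruth(
      wwSpecs(0L, 12), covariates = c("temperature", "precipitation"),
      seed = 12L, label = "wastewater_monthly_gappy", length = Tmonthly,
      maskSteps = winter),
    wastewater_weekly = syntheticTruth(
      wwSpecs(1L, 52), covariates = c("temperature", "precipitation"),
      seed = 13L, label = "wastewater_weekly", length = 104L,
      missingProb = 0.05))
}

#' Write a synthetic dataset to disk
#'
#' Emits the same TSV formats the readers consume: the feature table, the
#' sample metadata, and the truth labels.
#'
#' @param generated result of [generateSeries()].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths.
#' @export
writeSyntheticDataset <- function(generated, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(table = file.path(dir, "feature_table.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             labels = file.path(dir, "labels.tsv"))
  writeAbundanceTable(generated$series, paths["table"])
  utils::write.table(generated$metadata, paths["metadata"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(generated$labels, paths["labels"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths
}
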
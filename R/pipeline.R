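#' @include AllClasses.R AllGenerics.R ensemble.R synthetic.R
NULL

.defaultRunConfig <- function() {
  list(
    seed = 1L,
    output_dir = "microshift_out",
    input = list(table = NULL, metadata = NULL, scenario = "gut_dense",
                 orientation = "samples-as-columns"),
    split = list(train_val_fraction = 0.8, val_fraction_of_train = 0.1),
    window = list(lag = 3L, horizon = 1L, covariates = list()),
    backend = list(type = "rf", n_trees = 100L, cells = 32L,
                   dropout_rate = 0.2, max_epochs = 200L, patience = 10L,
                   learning_rate = 0.01),
    ensemble = list(n_members = 50L, coverage = 0.95, std_ddof = 1L),
    metrics = list(overfit_threshold = 3),
    network = list(metric = "spearman", edge_threshold = 0.6,
                   fdr_alpha = 0.05))
}

.mergeConfig <- function(base, user, path = character()) {
  for (nm in names(user)) {
    if (!nm %in% names(base))
      stop("unknown config key: ", paste(c(path, nm), collapse = "."),
           call. = FALSE)
    if (is.list(base[[nm]]) && is.list(user[[nm]]) &&
        !is.null(names(base[[nm]])))
      base[[nm]] <- .mergeConfig(base[[nm]], user[[nm]], c(path, nm))
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Read / write a run configuration
#'
#' YAML run configuration covering input paths, split, window, backend,
#' ensemble, metric and network options plus the global seed. Unknown keys
#' are rejected with their key path; omitted keys take package defaults.
#' Every random operation in the pipeline derives its seed from the global
#' seed via [deriveSeed()].
#'
#' @param path YAML file path.
#' @return nested configuration list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  cfg <- .mergeConfig(.defaultRunConfig(), user)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' @rdname readRunConfig
#' @param config configuration list.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

.backendConfigFromRun <- function(cfg, seed) {
  b <- cfg$backend
  switch(b$type,
    rf = rfConfig(nTrees = b$n_trees, seed = seed),
    lstm = recurrentConfig("lstm", cells = b$cells,
                           dropoutRate = b$dropout_rate,
                           learningRate = b$learning_rate,
                           maxEpochs = b$max_epochs,
                           patience = b$patience, seed = seed),
    gru = recurrentConfig("gru", cells = b$cells,
                          dropoutRate = b$dropout_rate,
                          learningRate = b$learning_rate,
                          maxEpochs = b$max_epochs,
                          patience = b$patience, seed = seed),
    stop("unsupported ensemble backend type: ", b$type, call. = FALSE))
}

.scalerHash <- function(params) {
  key <- paste(c(names(params@mins),
                 sprintf("%.10g", c(params@mins, params@maxs))),
               collapse = "|")
  h <- 2166136261
  for (b in utf8ToInt(key)) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (as.numeric(h) * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

.writeScaler <- function(params, path) {
  utils::write.table(
    data.frame(genus = names(params@mins), min = params@mins,
               max = params@maxs, degenerate = params@degenerate),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.readScaler <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  methods::new("ScalerParams",
               mins = stats::setNames(df$min, df$genus),
               maxs = stats::setNames(df$max, df$genus),
               degenerate = stats::setNames(df$degenerate, df$genus),
               fittedOn = "train")
}

.logRun <- function(dir, lines) {
  con <- file(file.path(dir, "run.log"), "a")
  on.exit(close(con))
  stamped <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                     lines)
  writeLines(stamped, con)
  message(paste(lines, collapse = "\n"))
}

.loadInputSeries <- function(cfg) {
  if (!is.null(cfg$input$table)) {
    series <- readAbundanceTable(cfg$input$table,
                                 orientation = cfg$input$orientation)
    if (!is.null(cfg$input$metadata)) {
      meta <- readSampleMetadata(cfg$input$metadata)
      series <- attachMetadata(series, meta)
      if (!is.null(series$health_flag) &&
          any(series$health_flag, na.rm = TRUE))
        series <- filterSickDays(series)
    }
    series
  } else {
    lib <- scenarioLibrary()
    truth <- lib[[cfg$input$scenario]]
    if (is.null(truth))
      stop("unknown scenario: ", cfg$input$scenario, call. = FALSE)
    truth@seed <- deriveSeed(cfg$seed, "simulate", 1L)
    generateSeries(truth)$series
  }
}

## shared preparation: split, scale, window
.prepare <- function(series, cfg) {
  split <- splitSpec(cfg$split$train_val_fraction,
                     cfg$split$val_fraction_of_train)
  wcfg <- windowConfig(lag = cfg$window$lag, horizon = cfg$window$horizon,
                       covariateNames = unlist(cfg$window$covariates))
  parts <- chronologicalSplit(series, split, window = wcfg)
  params <- fitScaler(parts$train)
  scaled <- scaleAbundance(series, params)
  covs <- if (length(wcfg@covariateNames) > 0)
    covariateMatrix(series, wcfg@covariateNames)
  wins <- windowSplits(scaled, parts$indices, wcfg, covariates = covs)
  list(series = series, split = split, wcfg = wcfg, parts = parts,
       params = params, scaled = scaled, covs = covs, wins = wins)
}

#' Pipeline commands
#'
#' Command-style entry points wiring the pipeline end to end from one run
#' configuration (see [readRunConfig()]); also exposed by the
#' `inst/scripts/microshift` command-line wrapper. Each command is
#' idempotent given identical config and seed; partial outputs are removed
#' on failure.
#'
#' * `cmdSimulate` generates a synthetic dataset from the configured
#'   scenario and writes feature table, metadata and truth labels.
#' * `cmdTrain` prepares the data (sick-day exclusion, chronological
#'   split, min-max scaling, lag windows), trains the configured ensemble
#'   and saves the model directory (config, scaler + hash, members) plus a
#'   deterministic test-prediction TSV.
#' * `cmdDetect` loads a saved ensemble, forecasts new observations
#'   teacher-forced and writes the outlier report.
#' * `cmdEvaluate` recomputes train/validation/test predictions and writes
#'   the metrics report.
#' * `cmdNetwork` builds the co-occurrence network and writes the edge
#'   list; with a model directory it also writes the permutation
#'   importance and the hub-versus-importance comparison.
#'
#' @param config configuration list from [readRunConfig()] (or a path).
#' @param modelDir model directory written by `cmdTrain`.
#' @param observations path to a feature table of new observations.
#' @return paths of the written artifacts, invisibly.
#' @name pipeline-commands
NULL

.asConfig <- function(config) {
  if (is.character(config)) readRunConfig(config)
  else .mergeConfig(.defaultRunConfig(), config)
}

.withCleanup <- function(paths, expr) {
  tryCatch(expr, error = function(e) {
    for (p in paths) unlink(p, recursive = TRUE)
    stop(e)
  })
}

#' @rdname pipeline-commands
#' @export
cmdSimulate <- function(config) {
  cfg <- .asConfig(config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  outDir <- file.path(cfg$output_dir, "simulated")
  .withCleanup(outDir, {
    lib <- scenarioLibrary()
    truth <- lib[[cfg$input$scenario]]
    if (is.null(truth))
      stop("unknown scenario: ", cfg$input$scenario, call. = FALSE)
    truth@seed <- deriveSeed(cfg$seed, "simulate", 1L)
    gen <- generateSeries(truth)
    paths <- writeSyntheticDataset(gen, outDir)
    .logRun(cfg$output_dir, sprintf(
      "simulate: scenario %s seed %d -> %s", cfg$input$scenario,
      truth@seed, outDir))
    invisible(paths)
  })
}

#' @rdname pipeline-commands
#' @export
cmdTrain <- function(config) {
  cfg <- .asConfig(config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  modelDir <- file.path(cfg$output_dir, "model")
  .withCleanup(modelDir, {
    prep <- .prepare(.loadInputSeries(cfg), cfg)
    ecfg <- ensembleConfig(nMembers = cfg$ensemble$n_members,
                           coverage = cfg$ensemble$coverage,
                           stdDdof = cfg$ensemble$std_ddof,
                           seed = cfg$seed)
    backend <- .backendConfigFromRun(cfg, seed = cfg$seed)
    models <- trainEnsemble(ecfg, backend, prep$wins$train,
                            prep$wins$validation)
    dir.create(modelDir, showWarnings = FALSE)
    .writeScaler(prep$params, file.path(modelDir, "scaler.tsv"))
    meta <- list(backend = cfg$backend, ensemble = cfg$ensemble,
                 window = cfg$window, seed = cfg$seed,
                 scaler_hash = .scalerHash(prep$params),
                 genera = genera(prep$series),
                 package_version = as.character(
                   utils::packageVersion("microShift")))
    yaml::write_yaml(meta, file.path(modelDir, "model.yaml"))
    saveRDS(models, file.path(modelDir, "members.rds"))
    ## context tail for detection on future observations
    utils::write.table(
      utils::tail(abundanceMatrix(prep$series), prep$wcfg@lag),
      file.path(modelDir, "context_tail.tsv"), sep = "\t", quote = FALSE)
    ## deterministic test predictions (ensemble mean, absolute scale)
    fc <- buildInterval(memberPredictions(models, prep$wins$test), ecfg,
                        targetSteps = prep$wins$test@targetSteps)
    fcAbs <- backTransformForecast(fc, prep$params)
    predPath <- file.path(modelDir, "test_predictions.tsv")
    utils::write.table(
      data.frame(time_step = fcAbs@targetSteps,
                 round(fcAbs@mean, 6), check.names = FALSE),
      predPath, sep = "\t", quote = FALSE, row.names = FALSE)
    .logRun(cfg$output_dir, sprintf(
      "train: backend %s, %d members, seed %d, scaler hash %s",
      cfg$backend$type, ecfg@nMembers, cfg$seed,
      .scalerHash(prep$params)))
    invisible(modelDir)
  })
}

#' Load a saved ensemble model directory
#'
#' Refuses to load when the scaler file does not match the hash recorded
#' at training time (guard against mismatched inference).
#'
#' @param modelDir directory written by [cmdTrain()].
#' @return list with `models`, `params`, `meta`, `contextTail`.
#' @export
loadEnsembleModel <- function(modelDir) {
  meta <- yaml::read_yaml(file.path(modelDir, "model.yaml"))
  params <- .readScaler(file.path(modelDir, "scaler.tsv"))
  if (!identical(.scalerHash(params), meta$scaler_hash))
    stop("scaler hash mismatch: model directory is inconsistent ",
         "(refusing to predict with a mismatched scaler)", call. = FALSE)
  ct <- as.matrix(utils::read.table(
    file.path(modelDir, "context_tail.tsv"), sep = "\t", header = TRUE,
    check.names = FALSE))
  list(models = readRDS(file.path(modelDir, "members.rds")),
       params = params, meta = meta, contextTail = ct)
}

#' @rdname pipeline-commands
#' @export
cmdDetect <- function(config, modelDir, observations) {
  cfg <- .asConfig(config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  outPath <- file.path(cfg$output_dir, "outliers.tsv")
  .withCleanup(outPath, {
    model <- loadEnsembleModel(modelDir)
    series <- readAbundanceTable(observations,
                                 orientation = cfg$input$orientation)
    obs <- abundanceMatrix(series)[, model$meta$genera, drop = FALSE]
    params <- model$params
    wcfg <- windowConfig(lag = model$meta$window$lag,
                         horizon = model$meta$window$horizon)
    full <- rbind(scaleAbundance(model$contextTail, params),
                  scaleAbundance(obs, params))
    wins <- makeWindows(full, wcfg)
    keep <- wins@targetSteps > wcfg@lag
    ecfg <- ensembleConfig(nMembers = model$meta$ensemble$n_members,
                           coverage = model$meta$ensemble$coverage,
                           stdDdof = model$meta$ensemble$std_ddof,
                           seed = model$meta$seed)
    arr <- memberPredictions(model$models, wins)
    fc <- buildInterval(arr[, keep, , drop = FALSE], ecfg,
                        targetSteps = which(keep))
    report <- detectOutliers(obs[keep, , drop = FALSE], fc, params,
                             timestamps = timeStamps(series)[keep])
    writeOutlierReport(report, outPath)
    .logRun(cfg$output_dir, sprintf(
      "detect: %d observation rows, %d outlier flags -> %s",
      sum(keep), nrow(report), outPath))
    invisible(outPath)
  })
}

#' @rdname pipeline-commands
#' @export
cmdEvaluate <- function(config, modelDir) {
  cfg <- .asConfig(config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  outPath <- file.path(cfg$output_dir, "metrics.json")
  .withCleanup(c(outPath, paste0(outPath, ".per_genus.tsv")), {
    model <- loadEnsembleModel(modelDir)
    prep <- .prepare(.loadInputSeries(cfg), cfg)
    obs <- list(); pred <- list()
    for (s in c("train", "validation", "test")) {
      w <- prep$wins[[s]]
      if (is.null(w)) next
      arr <- memberPredictions(model$models, w)
      mu <- apply(arr, c(2, 3), mean)
      colnames(mu) <- genera(prep$series)
      pred[[s]] <- inverseScale(mu, prep$params)
      obs[[s]] <- abundanceMatrix(prep$series)[w@targetSteps, ,
                                               drop = FALSE]
    }
    report <- evaluateForecast(obs, pred,
                               threshold = cfg$metrics$overfit_threshold)
    writeMetricsReport(report, outPath)
    .logRun(cfg$output_dir, sprintf(
      "evaluate: test MAE %.3f, overfit %s -> %s",
      report@perSplit$mae[report@perSplit$split == "test"],
      report@overfitFlag, outPath))
    invisible(outPath)
  })
}

#' @rdname pipeline-commands
#' @export
cmdNetwork <- function(config, modelDir = NULL) {
  cfg <- .asConfig(config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  outPath <- file.path(cfg$output_dir, "network_edges.tsv")
  .withCleanup(outPath, {
    series <- .loadInputSeries(cfg)
    net <- buildNetwork(series, metric = cfg$network$metric,
                        edgeThreshold = cfg$network$edge_threshold,
                        fdrAlpha = cfg$network$fdr_alpha)
    writeNetwork(net, outPath)
    written <- outPath
    if (!is.null(modelDir) && nrow(net@edges) > 0) {
      model <- loadEnsembleModel(modelDir)
      prep <- .prepare(series, cfg)
      imp <- permutationImportance(model$models[[1]], prep$wins$train,
                                   seed = deriveSeed(cfg$seed,
                                                     "importance", 1L))
      impPath <- file.path(cfg$output_dir, "importance.tsv")
      utils::write.table(as.data.frame(imp), impPath, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      cmp <- compareRankings(imp, net)
      cmpPath <- file.path(cfg$output_dir, "ranking_comparison.json")
      jsonlite::write_json(cmp, cmpPath, auto_unbox = TRUE, digits = NA)
      written <- c(written, impPath, cmpPath)
    }
    .logRun(cfg$output_dir, sprintf(
      "network: %s, %d nodes, %d edges -> %s", net@metric,
      length(net@nodes), nrow(net@edges), outPath))
    invisible(written)
  })
}
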
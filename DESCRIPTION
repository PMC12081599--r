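Package: microShift
Title: Forecasting Microbial Abundance Trajectories and Detecting
    Critical Community Shifts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for early-warning monitoring of longitudinal microbiome
    data. Genus-level abundance time series (16S rRNA amplicon feature
    tables aggregated to genus) are scaled, split chronologically, and
    framed as lag-window supervised examples; per-dataset forecasters
    (single-layer LSTM or GRU networks, random forest regression, and a
    VARMA baseline with stationarity testing and differencing) predict
    abundances one step ahead or iteratively. Ensembles of independently
    seeded models yield z-based 95% prediction intervals per genus and
    time point, and observations falling outside the interval are flagged
    as candidate critical community shifts. Includes MAE/RMSE/NRMSE
    evaluation with overfit diagnostics, genus co-occurrence correlation
    networks with hub-versus-importance comparison, a synthetic community
    generator with injected ground-truth shift events, and a command-line
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    ranger,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'data-io.R'
    'forecast-common.R'
    'ensemble.R'
    'forecast-recurrent.R'
    'forecast-rf.R'
    'forecast-varma.R'
    'metrics.R'
    'network.R'
    'synthetic.R'
    'pipeline.R'
    'preprocess.R'
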
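#' @include AllClasses.R AllGenerics.R
NULL

## timestamp parsing: ISO-8601 dates or plain integer indices ------------

.parseTimestamps <- function(labels, sampleIds) {
  lab <- trimws(as.character(labels))
  if (all(grepl("^-?[0-9]+$", lab))) {
    return(as.numeric(lab))
  }
  d <- suppressWarnings(as.Date(lab, format = "%Y-%m-%d"))
  bad <- which(is.na(d) | !grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$", lab))
  if (length(bad) > 0) {
    stop(sprintf(
      "unparseable timestamp '%s' for sample '%s' (expect ISO-8601 date or integer)",
      lab[bad[1]], sampleIds[bad[1]]), call. = FALSE)
  }
  as.numeric(d)
}

#' Construct an AbundanceSeries
#'
#' @param counts numeric matrix, samples x genera (rows in time order once
#'   timestamps are applied); rownames = sample ids, colnames = genus names.
#' @param timestamps time labels, one per sample: ISO-8601 dates
#'   (`"2014-03-01"`), integers, or `NULL` to use observation order.
#' @param subjectId subject or sampling-site label.
#' @param covariates optional data.frame of numeric covariates, one row per
#'   sample (same order as `counts`).
#' @param healthFlag optional logical vector: reported illness on the
#'   sampling day.
#' @return an [AbundanceSeries-class] with samples ordered by timestamp.
#' @examples
#' m <- matrix(c(0, 5, 10, 0, 2, 3), nrow = 3, byrow = TRUE,
#'             dimnames = list(paste0("s", 1:3), c("Blautia", "Dorea")))
#' AbundanceSeries(m)
#' @export
AbundanceSeries <- function(counts, timestamps = NULL,
                            subjectId = "subject1", covariates = NULL,
                            healthFlag = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("sample", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    stop("counts must have genus column names", call. = FALSE)
  n <- nrow(counts)
  labels <- if (is.null(timestamps)) as.character(seq_len(n))
            else as.character(timestamps)
  if (length(labels) != n)
    stop("timestamps must have one entry per sample", call. = FALSE)
  tv <- .parseTimestamps(labels, rownames(counts))
  if (anyDuplicated(tv)) {
    dup <- labels[duplicated(tv)][1]
    stop(sprintf("duplicated timestamp '%s'", dup), call. = FALSE)
  }
  ord <- order(tv)
  counts <- counts[ord, , drop = FALSE]
  cd <- S4Vectors::DataFrame(
    time_step = seq_len(n),
    timestamp = labels[ord],
    time_value = tv[ord],
    subject_id = rep(subjectId, n),
    row.names = rownames(counts))
  if (!is.null(healthFlag)) {
    stopifnot(length(healthFlag) == n)
    cd$health_flag <- as.logical(healthFlag)[ord]
  }
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == n)
    for (nm in names(covariates)) cd[[nm]] <- covariates[[nm]][ord]
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = t(counts)), colData = cd)
  methods::new("AbundanceSeries", se)
}

## ---- accessors ----------------------------------------------------------

#' @rdname abundanceMatrix
#' @export
setMethod("abundanceMatrix", "AbundanceSeries", function(x) {
  t(SummarizedExperiment::assay(x, "counts"))
})

#' @rdname genera
#' @export
setMethod("genera", "AbundanceSeries", function(x) rownames(x))

#' @rdname genera
#' @export
setMethod("genera", "GenusRoster", function(x) x@names)

#' @rdname timeSteps
#' @export
setMethod("timeSteps", "AbundanceSeries", function(x) x$time_step)

#' @rdname timeStamps
#' @export
setMethod("timeStamps", "AbundanceSeries", function(x) x$timestamp)

#' @rdname subjectId
#' @export
setMethod("subjectId", "AbundanceSeries", function(x)
  unique(x$subject_id)[1])

.covariateColumns <- function(x) {
  reserved <- c("time_step", "timestamp", "time_value", "subject_id",
                "health_flag")
  cd <- SummarizedExperiment::colData(x)
  nm <- setdiff(colnames(cd), reserved)
  nm[vapply(nm, function(n) is.numeric(cd[[n]]), logical(1))]
}

#' @rdname covariateMatrix
#' @export
setMethod("covariateMatrix", "AbundanceSeries", function(x, names = NULL) {
  avail <- .covariateColumns(x)
  if (is.null(names)) names <- avail
  missing <- setdiff(names, avail)
  if (length(missing) > 0)
    stop("covariate(s) not present: ", paste(missing, collapse = ", "),
         call. = FALSE)
  cd <- SummarizedExperiment::colData(x)
  m <- do.call(cbind, lapply(names, function(n) cd[[n]]))
  if (is.null(m)) m <- matrix(0, nrow = ncol(x), ncol = 0)
  dimnames(m) <- list(colnames(x), names)
  m
})

setMethod("show", "AbundanceSeries", function(object) {
  cat(sprintf("AbundanceSeries: %d genera x %d samples (subject '%s')\n",
              nrow(object), ncol(object), subjectId(object)))
  ts <- timeStamps(object)
  if (length(ts) > 0)
    cat(sprintf("  time span: %s .. %s\n", ts[1], ts[length(ts)]))
  cv <- .covariateColumns(object)
  if (length(cv) > 0)
    cat("  covariates:", paste(cv, collapse = ", "), "\n")
  if (!is.null(object$health_flag))
    cat(sprintf("  health flags: %d of %d samples flagged\n",
                sum(object$health_flag, na.rm = TRUE), ncol(object)))
  invisible(object)
})

setMethod("show", "GenusRoster", function(object) {
  cat(sprintf("GenusRoster: %d genera (%d observed, %d supplement)\n",
              length(object@names), sum(object@provenance == "observed"),
              sum(object@provenance == "supplement")))
  invisible(object)
})

#' Build a genus roster
#'
#' Combines the genera observed across tables with an external supplement
#' list (e.g. baseline human-gut taxa or sepsis-associated genera), keeping
#' first-appearance order and tagging provenance.
#'
#' @param observed character vector of observed genus names (may repeat).
#' @param supplement character vector of supplementary genus names.
#' @return a [GenusRoster-class].
#' @export
genusRoster <- function(observed = character(), supplement = character()) {
  observed <- unique(trimws(observed))
  supplement <- setdiff(unique(trimws(supplement)), observed)
  methods::new("GenusRoster",
    names = c(observed, supplement),
    provenance = c(rep("observed", length(observed)),
                   rep("supplement", length(supplement))))
}

## ---- file IO ------------------------------------------------------------

.sniffSep <- function(path) {
  for (line in readLines(path, n = 5L)) {
    if (startsWith(line, "# ")) next
    if (grepl("\t", line)) return("\t")
    if (grepl(",", line)) return(",")
  }
  "\t"
}

#' Read a genus-level feature table
#'
#' Reads a TSV/CSV feature table (QIIME2/BIOM TSV export dialect: a leading
#' `# Constructed from biom file` comment and an `#OTU ID` header column
#' are tolerated) into an [AbundanceSeries-class].
#'
#' @param path file path.
#' @param orientation `"samples-as-columns"` (BIOM export convention,
#'   rows = genera; default) or `"samples-as-rows"`.
#' @param timestamps optional explicit time labels, one per sample; by
#'   default sample ids are parsed as ISO dates or integers, falling back
#'   to observation order.
#' @param subjectId subject/site label stored with the series.
#' @return an [AbundanceSeries-class]; integer counts are preserved exactly.
#' @export
readAbundanceTable <- function(path,
                               orientation = c("samples-as-columns",
                                               "samples-as-rows"),
                               timestamps = NULL, subjectId = "subject1") {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "# ")]
  if (length(lines) > 0 && startsWith(lines[1], "#OTU ID"))
    lines[1] <- sub("^#OTU ID", "OTU_ID", lines[1])
  sep <- if (grepl("\t", lines[1])) "\t" else ","
  df <- utils::read.table(text = lines, sep = sep, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  labels <- trimws(as.character(df[[1]]))
  body <- df[, -1, drop = FALSE]
  if (!all(vapply(body, is.numeric, logical(1))))
    stop("feature table body must be numeric", call. = FALSE)
  m <- as.matrix(body)
  rownames(m) <- labels
  if (orientation == "samples-as-columns") m <- t(m)
  ## now m is samples x genera
  if (anyDuplicated(colnames(m))) {
    dup <- colnames(m)[duplicated(colnames(m))][1]
    stop(sprintf("duplicate genus name '%s'", dup), call. = FALSE)
  }
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop(sprintf("negative abundance at sample '%s', genus '%s'",
                 rownames(m)[neg[1, 1]], colnames(m)[neg[1, 2]]),
         call. = FALSE)
  if (is.null(timestamps)) {
    ids <- rownames(m)
    parsed <- tryCatch(.parseTimestamps(ids, ids), error = function(e) NULL)
    if (is.null(parsed)) {
      message("sample ids not parseable as timestamps; using observation order")
      timestamps <- seq_len(nrow(m))
    } else {
      timestamps <- ids
    }
  }
  AbundanceSeries(m, timestamps = timestamps, subjectId = subjectId)
}

#' Write a feature table as canonical TSV
#'
#' Genera as rows, samples as columns (BIOM TSV export orientation), so
#' that [readAbundanceTable()] round-trips integer tables bit-exactly.
#'
#' @param series an [AbundanceSeries-class].
#' @param path output path.
#' @export
writeAbundanceTable <- function(series, path) {
  m <- SummarizedExperiment::assay(series, "counts")
  df <- data.frame(`OTU_ID` = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' TSV/CSV keyed by sample id, with optional `timestamp`, `health_flag`
#' and numeric covariate columns.
#'
#' @param path file path.
#' @return data.frame with a `sample_id` column.
#' @export
readSampleMetadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- .sniffSep(path)
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  names(df)[1] <- "sample_id"
  if ("health_flag" %in% names(df))
    df$health_flag <- as.logical(df$health_flag)
  df
}

#' Attach sample metadata to a series
#'
#' Joins metadata rows (health flag, covariates) to samples by sample id.
#' Each metadata row joins to at most one sample.
#'
#' @param series an [AbundanceSeries-class].
#' @param meta data.frame from [readSampleMetadata()].
#' @return the series with enriched column data.
#' @export
attachMetadata <- function(series, meta) {
  stopifnot(is.data.frame(meta), "sample_id" %in% names(meta))
  if (anyDuplicated(meta$sample_id))
    stop("metadata contains duplicated sample ids", call. = FALSE)
  idx <- match(colnames(series), meta$sample_id)
  for (nm in setdiff(names(meta), c("sample_id", "timestamp"))) {
    col <- meta[[nm]][idx]
    SummarizedExperiment::colData(series)[[nm]] <- col
  }
  series
}

## ---- harmonization ------------------------------------------------------

#' Harmonize tables onto a shared genus axis
#'
#' Re-indexes every table on the union of all observed genera plus roster
#' supplements; genera absent from a table are assigned zero abundance.
#' Column order is identical across outputs. Row sums per sample are
#' unchanged (zero-fill adds nothing).
#'
#' @param tables list of [AbundanceSeries-class] objects (length >= 1).
#' @param roster optional [GenusRoster-class] of supplementary genera.
#' @param normalizeCase if TRUE, case-variant genus names are merged by
#'   case-insensitive match (first spelling wins); if FALSE (default),
#'   conflicting case variants across tables are an error.
#' @return list of harmonized [AbundanceSeries-class] objects.
#' @export
harmonizeGenera <- function(tables, roster = NULL, normalizeCase = FALSE) {
  stopifnot(length(tables) >= 1)
  allNames <- unlist(lapply(tables, genera), use.names = FALSE)
  union <- unique(allNames)
  if (!is.null(roster)) union <- c(union, setdiff(genera(roster), union))
  low <- tolower(union)
  if (anyDuplicated(low)) {
    if (!normalizeCase) {
      clash <- union[low %in% low[duplicated(low)]]
      stop("conflicting case-variant genus names: ",
           paste(clash, collapse = ", "),
           " (set normalizeCase = TRUE to merge)", call. = FALSE)
    }
    union <- union[!duplicated(low)]
  }
  canon <- function(nm) if (normalizeCase) union[match(tolower(nm), tolower(union))] else nm
  lapply(tables, function(tab) {
    m <- abundanceMatrix(tab)
    colnames(m) <- canon(colnames(m))
    if (normalizeCase && anyDuplicated(colnames(m))) {
      m <- t(rowsum(t(m), group = colnames(m), reorder = FALSE))
    }
    out <- matrix(0, nrow = nrow(m), ncol = length(union),
                  dimnames = list(rownames(m), union))
    out[, colnames(m)] <- m
    cd <- SummarizedExperiment::colData(tab)
    cov <- as.data.frame(cd[, .covariateColumns(tab), drop = FALSE])
    AbundanceSeries(out, timestamps = tab$timestamp,
                    subjectId = subjectId(tab),
                    covariates = if (ncol(cov) > 0) cov else NULL,
                    healthFlag = tab$health_flag)
  })
}

#' Exclude samples flagged as sick days
#'
#' Removes samples whose health flag records reported illness on the
#' sampling day, so that models are trained on data from healthy periods
#' only. Samples with no flag information are kept (with a warning) or
#' dropped according to `unmatched`.
#'
#' @param series an [AbundanceSeries-class] carrying a `health_flag`
#'   column (see [attachMetadata()]).
#' @param meta optional metadata data.frame to attach first.
#' @param unmatched policy for samples with missing flag: "keep" (default)
#'   or "drop".
#' @return the filtered series; removed sample ids are reported via message.
#' @export
filterSickDays <- function(series, meta = NULL,
                           unmatched = c("keep", "drop")) {
  unmatched <- match.arg(unmatched)
  if (!is.null(meta)) series <- attachMetadata(series, meta)
  flag <- series$health_flag
  if (is.null(flag))
    stop("series carries no health_flag; attach metadata first",
         call. = FALSE)
  na <- is.na(flag)
  if (any(na)) {
    if (unmatched == "keep") {
      warning(sprintf("%d sample(s) without health metadata kept", sum(na)))
      flag[na] <- FALSE
    } else {
      flag[na] <- TRUE
    }
  }
  if (all(flag))
    stop("empty series after sick-day exclusion (cannot train)",
         call. = FALSE)
  if (any(flag))
    message("excluded sick-day sample(s): ",
            paste(colnames(series)[flag], collapse = ", "))
  series[, !flag]
}
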
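#' @include AllClasses.R AllGenerics.R forecast-common.R
NULL

#' Build a genus-genus co-occurrence correlation network
#'
#' Tests every genus pair with the chosen correlation coefficient
#' (Spearman by default, following the common |rho| > 0.6 edge
#' convention), corrects p-values with Benjamini-Hochberg, and retains an
#' edge iff the absolute coefficient reaches `edgeThreshold` and (when
#' `fdrAlpha` is not NA) the q-value passes the FDR level. Genera with no
#' retained edge are excluded from the node set; constant genera are
#' excluded from testing with a log entry.
#'
#' @param series an [AbundanceSeries-class] or samples x genera matrix
#'   (>= 10 samples, >= 2 genera).
#' @param metric "spearman" (default), "pearson" or "kendall".
#' @param edgeThreshold minimum |coefficient| (default 0.6).
#' @param fdrAlpha BH FDR level (default 0.05; NA disables the FDR
#'   criterion).
#' @return a [CorrelationNetwork-class].
#' @export
buildNetwork <- function(series, metric = c("spearman", "pearson",
                                            "kendall"),
                         edgeThreshold = 0.6, fdrAlpha = 0.05) {
  metric <- match.arg(metric)
  fdrAlpha <- as.numeric(fdrAlpha)
  m <- .asAbundanceMatrix(series)
  if (nrow(m) < 10) stop("need at least 10 samples", call. = FALSE)
  if (ncol(m) < 2) stop("need at least 2 genera", call. = FALSE)
  if (is.null(colnames(m))) colnames(m) <- paste0("g", seq_len(ncol(m)))
  constant <- apply(m, 2, function(v) stats::var(v) == 0)
  if (any(constant)) {
    message("excluding constant genus/genera from correlation testing: ",
            paste(colnames(m)[constant], collapse = ", "))
    m <- m[, !constant, drop = FALSE]
  }
  g <- colnames(m)
  pairs <- utils::combn(length(g), 2)
  coef <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    ct <- suppressWarnings(stats::cor.test(
      m[, pairs[1, k]], m[, pairs[2, k]], method = metric, exact = FALSE))
    coef[k] <- unname(ct$estimate)
    p[k] <- ct$p.value
  }
  q <- stats::p.adjust(p, method = "BH")
  keep <- abs(coef) >= edgeThreshold
  if (!is.na(fdrAlpha)) keep <- keep & q <= fdrAlpha
  edges <- data.frame(
    genus_a = g[pairs[1, keep]], genus_b = g[pairs[2, keep]],
    coefficient = coef[keep], p_value = p[keep], q_value = q[keep],
    stringsAsFactors = FALSE)
  ## canonical a < b order
  swap <- edges$genus_a > edges$genus_b
  if (any(swap)) {
    tmp <- edges$genus_a[swap]
    edges$genus_a[swap] <- edges$genus_b[swap]
    edges$genus_b[swap] <- tmp
  }
  edges <- edges[order(edges$genus_a, edges$genus_b), , drop = FALSE]
  rownames(edges) <- NULL
  methods::new("CorrelationNetwork", metric = metric,
               nodes = sort(unique(c(edges$genus_a, edges$genus_b))),
               edges = edges, edgeThreshold = edgeThreshold,
               fdrAlpha = fdrAlpha)
}

setMethod("show", "CorrelationNetwork", function(object) {
  cat(sprintf(
    "CorrelationNetwork (%s, |coef| >= %.2f%s): %d nodes, %d edges\n",
    object@metric, object@edgeThreshold,
    if (is.na(object@fdrAlpha)) "" else
      sprintf(", FDR <= %.2f", object@fdrAlpha),
    length(object@nodes), nrow(object@edges)))
  invisible(object)
})

#' Node centralities: degree and summed absolute coefficient
#'
#' Hub ("keystone") genera are those with the largest number of
#' connections or the highest summed correlation strength. Rank ties are
#' broken lexicographically by genus name.
#'
#' @param network a [CorrelationNetwork-class].
#' @return data.frame with columns genus, degree, strength, ordered by
#'   decreasing strength.
#' @export
nodeStrength <- function(network) {
  e <- network@edges
  if (nrow(e) == 0)
    return(data.frame(genus = character(), degree = integer(),
                      strength = numeric(), stringsAsFactors = FALSE))
  nodes <- network@nodes
  deg <- str <- stats::setNames(numeric(length(nodes)), nodes)
  for (k in seq_len(nrow(e))) {
    for (v in c(e$genus_a[k], e$genus_b[k])) {
      deg[v] <- deg[v] + 1
      str[v] <- str[v] + abs(e$coefficient[k])
    }
  }
  out <- data.frame(genus = nodes, degree = as.integer(deg),
                    strength = unname(str), stringsAsFactors = FALSE)
  out[order(-out$strength, out$genus), , drop = FALSE]
}

#' Permutation feature importance of a fitted forecaster
#'
#' Native importance provider: the score of an input genus is the increase
#' in window-level MAE when that genus's lag columns are permuted across
#' windows (same permutation applied to all lag positions of the genus),
#' averaged over `repeats` seeded permutations. Constant features score 0
#' by definition. An externally computed Shapley-value table can be used
#' instead via [readImportance()].
#'
#' @param model a fitted [Forecaster-class].
#' @param windows a [WindowedDataset-class] with >= 10 windows.
#' @param repeats permutation repeats (default 5).
#' @param seed RNG seed.
#' @return data.frame of class `importanceRanking`: genus, importance,
#'   ordered by decreasing importance (ties broken by genus name);
#'   attribute `provider = "native-permutation"`.
#' @export
permutationImportance <- function(model, windows, repeats = 5L,
                                  seed = 1L) {
  n <- dim(windows@inputs)[1]
  if (n < 10) stop("need at least 10 windows", call. = FALSE)
  base <- mae(windows@targets, predictWindows(model, windows))
  G <- length(windows@genera)
  scores <- stats::setNames(numeric(G), windows@genera)
  .withSeed(seed, {
    for (j in seq_len(G)) {
      constant <- all(apply(windows@inputs[, , j, drop = FALSE], 2,
                            function(v) max(v) == min(v)))
      if (constant) next   # degenerate feature: score 0 by definition
      inflation <- numeric(repeats)
      for (r in seq_len(repeats)) {
        perm <- sample.int(n)
        shuffled <- windows
        shuffled@inputs[, , j] <- windows@inputs[perm, , j]
        inflation[r] <- mae(windows@targets,
                            predictWindows(model, shuffled)) - base
      }
      scores[j] <- mean(inflation)
    }
  })
  out <- data.frame(genus = names(scores), importance = unname(scores),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance, out$genus), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "provider") <- "native-permutation"
  class(out) <- c("importanceRanking", "data.frame")
  out
}

#' Read an externally computed importance ranking
#'
#' Two-column TSV (genus, score), e.g. Shapley values computed by an
#' external explanation tool. Ranking is by absolute score (direction is
#' retained in the `importance` column).
#'
#' @param path TSV path.
#' @return data.frame of class `importanceRanking` with attribute
#'   `provider = "external"`.
#' @export
readImportance <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  names(df)[1:2] <- c("genus", "importance")
  df <- df[order(-abs(df$importance), df$genus), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "provider") <- "external"
  class(df) <- c("importanceRanking", "data.frame")
  df
}

#' Compare importance and network-hub rankings
#'
#' Reports the top-k genus sets by model importance, by network degree and
#' by network strength, with pairwise overlap counts and Jaccard indices —
#' the check that the model's most influential inputs coincide with the
#' community's hub taxa.
#'
#' @param importance an importance ranking (see [permutationImportance()]
#'   or [readImportance()]).
#' @param network a [CorrelationNetwork-class].
#' @param k top-list size (default 10; clamped to the node count with a
#'   warning).
#' @return list with `k`, `topImportance`, `topDegree`, `topStrength`,
#'   and `overlap` (data.frame of pairwise overlap and Jaccard index).
#' @export
compareRankings <- function(importance, network, k = 10L) {
  ns <- nodeStrength(network)
  if (nrow(ns) == 0) stop("network has no nodes", call. = FALSE)
  if (k > nrow(ns)) {
    warning(sprintf("k = %d larger than node count %d; clamped", k,
                    nrow(ns)))
    k <- nrow(ns)
  }
  rankBy <- function(df, col) {
    df[order(-df[[col]], df$genus), "genus"][seq_len(min(k, nrow(df)))]
  }
  topImp <- importance$genus[seq_len(min(k, nrow(importance)))]
  topDeg <- rankBy(ns, "degree")
  topStr <- rankBy(ns, "strength")
  sets <- list(importance = topImp, degree = topDeg, strength = topStr)
  pairs <- utils::combn(names(sets), 2)
  overlap <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    a <- sets[[pairs[1, i]]]; b <- sets[[pairs[2, i]]]
    inter <- length(intersect(a, b))
    data.frame(set_a = pairs[1, i], set_b = pairs[2, i],
               overlap = inter,
               jaccard = inter / length(union(a, b)),
               stringsAsFactors = FALSE)
  }))
  list(k = k, topImportance = topImp, topDegree = topDeg,
       topStrength = topStr, overlap = overlap)
}

#' Export a network as an edge-list TSV and GraphML
#'
#' @param network a [CorrelationNetwork-class].
#' @param path edge-list TSV path; a GraphML file is written alongside
#'   when `graphml = TRUE`.
#' @param graphml also write `<path>.graphml`.
#' @export
writeNetwork <- function(network, path, graphml = TRUE) {
  utils::write.table(network@edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (graphml) {
    gpath <- paste0(path, ".graphml")
    con <- file(gpath, "w")
    on.exit(close(con))
    writeLines(c(
      '<?xml version="1.0" encoding="UTF-8"?>',
      '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
      '  <key id="w" for="edge" attr.name="coefficient" attr.type="double"/>',
      '  <graph edgedefault="undirected">'), con)
    for (n in network@nodes)
      writeLines(sprintf('    <node id="%s"/>', n), con)
    e <- network@edges
    for (i in seq_len(nrow(e)))
      writeLines(sprintf(
        '    <edge source="%s" target="%s"><data key="w">%.6f</data></edge>',
        e$genus_a[i], e$genus_b[i], e$coefficient[i]), con)
    writeLines(c('  </graph>', '</graphml>'), con)
  }
  invisible(path)
}
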
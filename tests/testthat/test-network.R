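test_that("perfect monotone relationships give unit-coefficient edges", {
  set.seed(51)
  x <- rnorm(30)
  m <- cbind(A = x, B = x, C = -x^3, D = rnorm(30))
  net <- buildNetwork(m, metric = "spearman")
  e <- net@edges
  ab <- e[e$genus_a == "A" & e$genus_b == "B", ]
  expect_equal(ab$coefficient, 1.0)
  ## anti-monotone pair retained through the absolute threshold
  ac <- e[e$genus_a == "A" & e$genus_b == "C", ]
  expect_equal(ac$coefficient, -1.0)
  ## canonical order and no self edges
  expect_true(all(e$genus_a < e$genus_b))
  expect_false("D" %in% net@nodes || !all(abs(e$coefficient) >= 0.6))
})

test_that("constant genera are excluded from testing with a log entry", {
  set.seed(52)
  m <- cbind(A = rnorm(20), B = rnorm(20), C = rep(5, 20))
  expect_message(net <- buildNetwork(m), "constant")
  expect_false("C" %in% net@nodes)
})

test_that("independent noise yields empty networks at the defaults", {
  set.seed(53)
  zero <- replicate(30, {
    m <- matrix(rnorm(100 * 20), 100, 20,
                dimnames = list(NULL, sprintf("g%02d", 1:20)))
    nrow(buildNetwork(m)@edges) == 0
  })
  expect_gte(mean(zero), 0.95)
})

test_that("Spearman and Kendall networks ignore monotone rescaling", {
  set.seed(54)
  n <- 40
  f <- rnorm(n)
  m <- cbind(A = f + rnorm(n, 0, 0.3), B = f + rnorm(n, 0, 0.3),
             C = rnorm(n))
  for (metric in c("spearman", "kendall")) {
    net1 <- buildNetwork(m, metric = metric)
    m2 <- m
    m2[, "A"] <- exp(m[, "A"])          # monotone per-genus rescale
    m2[, "B"] <- m[, "B"]^3
    net2 <- buildNetwork(m2, metric = metric)
    expect_equal(net1@edges$coefficient, net2@edges$coefficient)
  }
})

test_that("BH-adjusted q-values are monotone in p-value rank", {
  set.seed(55)
  f <- rnorm(50)
  m <- sapply(1:8, function(i) f * (i <= 4) + rnorm(50, 0, 1))
  colnames(m) <- sprintf("g%d", 1:8)
  net <- buildNetwork(m, edgeThreshold = 0, fdrAlpha = NA)
  e <- net@edges[order(net@edges$p_value), ]
  expect_true(all(diff(e$q_value) >= -1e-12))
})

test_that("node strength identifies planted hubs", {
  ## star graph: hub with three unit edges
  e <- data.frame(genus_a = c("h", "a", "b"), genus_b = c("x", "h", "h"),
                  coefficient = 1, p_value = 0, q_value = 0)
  net <- methods::new("CorrelationNetwork", metric = "spearman",
                      nodes = c("a", "b", "h", "x"), edges = e,
                      edgeThreshold = 0.6, fdrAlpha = 0.05)
  ns <- nodeStrength(net)
  expect_identical(ns$genus[1], "h")
  expect_identical(ns$degree[1], 3L)
  expect_equal(ns$strength[1], 3)

  ## empty network -> empty map
  empty <- methods::new("CorrelationNetwork", metric = "spearman",
                        nodes = character(),
                        edges = e[0, ], edgeThreshold = 0.6,
                        fdrAlpha = 0.05)
  expect_identical(nrow(nodeStrength(empty)), 0L)

  ## planted correlated block occupies the top strength ranks
  set.seed(56)
  n <- 100
  f <- rnorm(n)
  m <- matrix(rnorm(n * 20), n, 20,
              dimnames = list(NULL, sprintf("g%02d", 1:20)))
  for (j in 1:5) m[, j] <- f + rnorm(n, 0, 0.5)
  ns2 <- nodeStrength(buildNetwork(m))
  expect_setequal(head(ns2$genus, 5), sprintf("g%02d", 1:5))
})

test_that("permutation importance isolates the features a model reads", {
  set.seed(57)
  G <- 3
  sc <- matrix(runif(90), 30, G, dimnames = list(NULL, c("A", "B", "C")))
  w <- makeWindows(sc, windowConfig(lag = 3))
  ## mock reads only genus A (most recent lag), doubled
  mock <- functionForecaster(function(win) rep(2 * win[3, 1], G),
                             genera = c("A", "B", "C"), lag = 3)
  imp <- permutationImportance(mock, w, repeats = 3, seed = 5)
  expect_identical(imp$genus[1], "A")
  expect_gt(imp$importance[imp$genus == "A"], 0)
  expect_equal(imp$importance[imp$genus == "B"], 0)
  expect_equal(imp$importance[imp$genus == "C"], 0)

  ## reproducible under a fixed seed
  imp2 <- permutationImportance(mock, w, repeats = 3, seed = 5)
  expect_identical(imp, imp2)

  ## brute-force oracle: replay the seeded permutations independently
  baseMae <- mae(w@targets, predictWindows(mock, w))
  n <- dim(w@inputs)[1]
  expected <- local({
    set.seed(5)
    infl <- numeric(3)
    for (r in 1:3) {
      perm <- sample.int(n)
      shuf <- w
      shuf@inputs[, , 1] <- w@inputs[perm, , 1]
      infl[r] <- mae(w@targets, predictWindows(mock, shuf)) - baseMae
    }
    mean(infl)
  })
  expect_equal(imp$importance[imp$genus == "A"], expected)
})

test_that("ranking comparison reports overlaps and clamps k", {
  set.seed(58)
  n <- 80
  f <- rnorm(n)
  m <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, letters[1:8]))
  for (j in 1:4) m[, j] <- f + rnorm(n, 0, 0.4)
  net <- buildNetwork(m)
  imp <- data.frame(genus = letters[1:8], importance = 8:1)
  class(imp) <- c("importanceRanking", "data.frame")
  expect_warning(cmp <- compareRankings(imp, net, k = 50), "clamped")
  expect_lte(cmp$k, length(net@nodes))
  ## identical rankings -> Jaccard 1
  imp2 <- data.frame(genus = nodeStrength(net)$genus,
                     importance = seq(1, 0,
                                      length.out = length(net@nodes)))
  class(imp2) <- c("importanceRanking", "data.frame")
  cmp2 <- compareRankings(imp2, net, k = length(net@nodes))
  j <- cmp2$overlap$jaccard[cmp2$overlap$set_a == "importance" &
                            cmp2$overlap$set_b == "strength"]
  expect_equal(j, 1.0)
})

test_that("external importance tables load ranked by absolute score", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("genus\tshapley", "A\t0.1", "B\t-0.9", "C\t0.5"), tf)
  imp <- readImportance(tf)
  expect_identical(imp$genus, c("B", "C", "A"))
  expect_identical(attr(imp, "provider"), "external")
})
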
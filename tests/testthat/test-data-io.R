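test_that("feature tables round-trip losslessly in both orientations", {
  m <- toyCounts()
  s <- AbundanceSeries(m)
  expect_identical(unname(abundanceMatrix(s)), unname(m))
  expect_identical(genera(s), c("Blautia", "Dorea"))

  tf <- withr::local_tempfile(fileext = ".tsv")
  writeAbundanceTable(s, tf)
  s2 <- readAbundanceTable(tf)               # samples-as-columns
  expect_equal(abundanceMatrix(s2), abundanceMatrix(s))
  expect_identical(genera(s2), genera(s))

  ## same table transposed + orientation flag flipped -> identical series
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(sample = rownames(m), m, check.names = FALSE)
  write.table(df, tf2, sep = "\t", quote = FALSE, row.names = FALSE)
  s3 <- readAbundanceTable(tf2, orientation = "samples-as-rows")
  expect_equal(abundanceMatrix(s3), abundanceMatrix(s2))

  ## QIIME2-export dialect with comment and #OTU ID header
  tf3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# Constructed from biom file",
               "#OTU ID\ts1\ts2\ts3",
               "Blautia\t0\t10\t2",
               "Dorea\t5\t0\t3"), tf3)
  s4 <- readAbundanceTable(tf3)
  expect_equal(abundanceMatrix(s4), abundanceMatrix(s))
})

test_that("invalid tables are rejected with located errors", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("OTU_ID\ts1\ts2", "Blautia\t1\t-1", "Dorea\t0\t2"), tf)
  expect_error(readAbundanceTable(tf), "negative.*s2.*Blautia|Blautia.*s2")

  tf2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("OTU_ID\ts1\ts2", "Blautia\t1\t1", "Blautia\t0\t2"), tf2)
  expect_error(readAbundanceTable(tf2), "duplicate genus")

  m <- toyCounts()
  expect_error(AbundanceSeries(m, timestamps = c("2024-01-01", "oops",
                                                 "2024-01-03")),
               "unparseable timestamp 'oops' for sample 's2'")
  expect_error(AbundanceSeries(m, timestamps = c(1, 1, 2)), "duplicated")
  m[2, 1] <- -3
  expect_error(AbundanceSeries(m), "negative")
})

test_that("timestamps canonicalize to ordered integer steps", {
  m <- toyCounts()
  s <- AbundanceSeries(m, timestamps = c("2024-03-05", "2024-03-01",
                                         "2024-03-03"))
  expect_identical(timeStamps(s), c("2024-03-01", "2024-03-03",
                                    "2024-03-05"))
  expect_identical(timeSteps(s), 1:3)
  ## rows reordered with their timestamps
  expect_identical(unname(abundanceMatrix(s)[1, ]), c(10, 0))
})

test_that("harmonization zero-fills the genus union and preserves row sums", {
  a <- AbundanceSeries(matrix(c(1, 2, 3, 4, 5, 6), 3,
                              dimnames = list(NULL, c("A", "B"))))
  b <- AbundanceSeries(matrix(c(7, 8, 9, 10), 2,
                              dimnames = list(NULL, c("B", "C"))))
  out <- harmonizeGenera(list(a, b))
  expect_identical(genera(out[[1]]), c("A", "B", "C"))
  expect_identical(genera(out[[2]]), c("A", "B", "C"))
  expect_true(all(abundanceMatrix(out[[1]])[, "C"] == 0))
  expect_true(all(abundanceMatrix(out[[2]])[, "A"] == 0))
  expect_equal(rowSums(abundanceMatrix(out[[1]])),
               rowSums(abundanceMatrix(a)), ignore_attr = TRUE)

  ## roster supplement observed nowhere -> zero column everywhere
  roster <- genusRoster(observed = c("A", "B", "C"), supplement = "D")
  out2 <- harmonizeGenera(list(a, b), roster = roster)
  expect_identical(genera(out2[[1]]), c("A", "B", "C", "D"))
  expect_true(all(abundanceMatrix(out2[[2]])[, "D"] == 0))
  ## union axis cardinality is exact
  expect_identical(length(genera(out2[[1]])),
                   length(union(union(genera(a), genera(b)), "D")))

  ## single table, no roster -> unchanged counts
  out3 <- harmonizeGenera(list(a))
  expect_identical(abundanceMatrix(out3[[1]]), abundanceMatrix(a))

  ## case-variant clash rejected unless normalization enabled
  cc <- AbundanceSeries(matrix(1:2, 2, dimnames = list(NULL, "blautia")))
  dd <- AbundanceSeries(matrix(1:2, 2, dimnames = list(NULL, "Blautia")))
  expect_error(harmonizeGenera(list(cc, dd)), "case-variant")
  outN <- harmonizeGenera(list(cc, dd), normalizeCase = TRUE)
  expect_identical(length(genera(outN[[1]])), 1L)
})

test_that("sick-day exclusion removes flagged samples and guards emptiness", {
  T <- 10
  m <- matrix(rpois(T * 2, 20), T,
              dimnames = list(sprintf("s%02d", 1:T), c("A", "B")))
  flags <- rep(FALSE, T); flags[c(3, 7)] <- TRUE
  s <- AbundanceSeries(m, healthFlag = flags)
  expect_message(f <- filterSickDays(s), "s03, s07")
  expect_identical(ncol(f), 8L)
  expect_true(all(diff(timeSteps(f)) > 0))

  ## no flags -> identity
  s0 <- AbundanceSeries(m, healthFlag = rep(FALSE, T))
  expect_identical(ncol(filterSickDays(s0)), 10L)

  ## all flagged -> degenerate, cannot train
  s1 <- AbundanceSeries(m, healthFlag = rep(TRUE, T))
  expect_error(filterSickDays(s1), "empty series")

  ## metadata join path with a missing sample kept by default
  meta <- data.frame(sample_id = sprintf("s%02d", 1:(T - 1)),
                     health_flag = flags[1:(T - 1)])
  s2 <- AbundanceSeries(m)
  expect_warning(f2 <- filterSickDays(s2, meta), "without health metadata")
  expect_identical(ncol(f2), 8L)
})
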
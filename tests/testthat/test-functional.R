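test_that("motif libraries load, skipping unsupported regex constructs", {
  path <- writeTestLibrary()
  lib <- loadMotifLibrary(path)
  expect_equal(nrow(lib), 5L)
  expect_equal(attr(lib, "skipped"), 0L)
  expect_equal(lib$go_terms[[2]], c("GO:0005515", "GO:0019899"))

  path2 <- writeTestLibrary(extraRows = "BAD_1\tA{2,3}B\tLIG\tGO:1")
  expect_warning(lib2 <- loadMotifLibrary(path2), "skipped")
  expect_equal(nrow(lib2), 5L)
  expect_equal(attr(lib2, "skipped"), 1L)

  path3 <- writeTestLibrary(extraRows = "NOCLASS_1\tACDE\t\tGO:1")
  expect_error(loadMotifLibrary(path3), "NOCLASS_1")
})

test_that("pattern comparison scores shared information content over the best overlap", {
  # identical all-literal patterns: one IC unit per position
  hit <- comparePatternPair("ADEAT", "ADEAT")
  expect_equal(hit$cm_score, 5)
  expect_equal(hit$offset, 0L)
  expect_equal(hit$matched_positions, 5L)
  # sliding alignment picks out the contained motif
  hit2 <- comparePatternPair("ADEAT", "DEA")
  expect_equal(hit2$cm_score, 3)
  expect_equal(hit2$offset, 1L)
  expect_equal(hit2$matched_positions, 3L)
  # nothing in common
  expect_null(comparePatternPair("YFT", "KRG"))
  # class elements contribute reduced information content
  hit3 <- comparePatternPair("[AG]DE", "ADE")
  expect_equal(hit3$cm_score, (1 - log(2) / log(20)) + 2, tolerance = 1e-12)
  # an incompatible aligned pair vetoes the offset entirely
  expect_null(comparePatternPair("ADEK", "ADER", minShared = 3))
})

test_that("comparison is symmetric and self-score is maximal", {
  pats <- c("ADEAT", "G.[AG][DE]K", "W.HKY", "[ILMV]A.DE")
  for (a in pats) for (b in pats) {
    ha <- comparePatternPair(a, b)
    hb <- comparePatternPair(b, a)
    if (is.null(ha)) {
      expect_null(hb)
    } else {
      expect_equal(ha$cm_score, hb$cm_score, tolerance = 1e-12)
    }
  }
  for (a in pats) {
    self <- comparePatternPair(a, a)$cm_score
    for (b in setdiff(pats, a)) {
      hb <- comparePatternPair(a, b)
      if (!is.null(hb)) expect_lte(hb$cm_score, self + 1e-12)
    }
  }
})

test_that("class profiles count a pattern at most once per class", {
  hits <- data.frame(
    pattern = c("p1", "p1", "p1", "p2", "p2", "p3", "p3"),
    motif_id = c("L1", "L2", "L3", "L1", "M1", "L1", "M2"),
    class = c("LIG", "LIG", "LIG", "LIG", "MOD", "LIG", "MOD"))
  prof <- classProfile(hits)
  expect_equal(unname(prof["LIG"]), 3L)  # p1 counted once despite 3 LIG hits
  expect_equal(unname(prof["MOD"]), 2L)
  expect_equal(unname(prof["TRG"]), 0L)
  empty <- classProfile(hits[0, ])
  expect_true(all(empty == 0L))
})

test_that("enrichment chi-square is exact on proportional counts and matches chisq.test", {
  expected <- c(TRG = 0.13, MOD = 0.25, LIG = 0.54, CLV = 0.07)
  # the published class percentages are rounded and sum to 99%; the test
  # renormalises, so proportional counts still give a null result
  expect_equal(sum(expected), 0.99)
  obs <- expected * 200
  enr <- motifEnrichment(obs, expected)
  expect_equal(enr$chi2, 0)
  expect_equal(enr$p_value, 1)
  expect_false(enr$significant)
  expect_equal(enr$df, 3L)

  # hand evaluation of the chi-square sum on a skewed profile
  obs2 <- c(TRG = 15, MOD = 15, LIG = 80, CLV = 5)
  enr2 <- motifEnrichment(obs2, expected)
  e2 <- expected / sum(expected) * 115
  expect_equal(enr2$chi2, sum((obs2 - e2)^2 / e2), tolerance = 1e-12)

  # reference implementation agreement on random tables
  set.seed(99)
  for (i in 1:20) {
    o <- as.integer(rmultinom(1, sample(50:400, 1), prob = runif(4) + 0.1))
    names(o) <- names(expected)
    enr3 <- motifEnrichment(o, expected)
    ref <- suppressWarnings(stats::chisq.test(o, p = expected, rescale.p = TRUE))
    expect_equal(enr3$chi2, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(enr3$p_value, unname(ref$p.value), tolerance = 1e-9)
  }

  expect_error(motifEnrichment(c(TRG = 0, MOD = 0, LIG = 0, CLV = 0), expected),
               "at least 1")
  expect_error(motifEnrichment(obs2, c(TRG = 0.3, MOD = 0.3, LIG = 0.4,
                                       CLV = 0)), "expected count of 0")
})

test_that("library comparison of retained patterns produces classed hits", {
  lib <- loadMotifLibrary(writeTestLibrary())
  hits <- compareToLibrary(c("ADEAT", "QQQQQ"), lib)
  expect_true(all(c("pattern", "motif_id", "class", "cm_score") %in% names(hits)))
  expect_true("LIG_TEST_1" %in% hits$motif_id[hits$pattern == "ADEAT"])
  expect_false("QQQQQ" %in% hits$pattern)
})
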
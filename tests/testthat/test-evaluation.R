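test_that("propensity score has its stated fixed points", {
  # zero trans matches pin the score at 1 regardless of sizes
  expect_equal(scScore(4, 0, 318, 685716), 1)
  expect_equal(scScore(1, 0, 10, 10), 1)
  # exactly proportional representation gives the neutral 0.5
  expect_equal(scScore(3, 3, 100, 100), 0.5)
  expect_equal(scScore(2, 2 * 685716 / 318, 318, 685716), 0.5)
  # direct evaluation at the study's dataset sizes
  expect_equal(scScore(2, 1000, 318, 685716),
               2 / (2 + (318 / 685716) * 1000), tolerance = 1e-12)
  expect_equal(round(scScore(2, 1000, 318, 685716), 4), 0.8118)
  expect_error(scScore(0, 5, 10, 10), "c must be")
})

test_that("propensity score is strictly monotone in c and t", {
  for (c0 in c(1, 2, 7)) {
    sc <- scScore(c0, 0:50, 318, 685716)
    expect_true(all(diff(sc) < 0))
  }
  for (t0 in c(1, 10, 400)) {
    sc <- scScore(1:50, t0, 318, 685716)
    expect_true(all(diff(sc) > 0))
  }
})

test_that("threshold filtering is strict and order-preserving", {
  stats <- data.frame(pattern = c("p1", "p2", "p3", "p4"),
                      c = 1L, t = 0L,
                      sc_score = c(1.0, 0.95, 0.90, 0.50))
  kept <- filterPatterns(stats, 0.90)
  expect_equal(kept$pattern, c("p1", "p2"))  # 0.90 itself is discarded
  expect_equal(nrow(filterPatterns(stats, 0)), 4L)
  expect_equal(nrow(filterPatterns(stats[0, ], 0.9)), 0L)
})

test_that("log-likelihood matches closed forms under a uniform background", {
  bg <- uniformBackground()
  expect_equal(logLikelihood("A", bg), log10(1 / 20), tolerance = 1e-12)
  expect_equal(logLikelihood("A.C", bg), log10(1 / 400), tolerance = 1e-12)
  expect_equal(logLikelihood("[AG]", bg), -1, tolerance = 1e-12)
})

## independent oracle: enumerate every matching string, sum chain-rule
## probabilities
enumLogLik <- function(pattern, bg) {
  toks <- parsePattern(pattern, allowNegation = TRUE)
  sets <- lapply(toks, tokenResidues, letters = bg@letters)
  grid <- expand.grid(sets, stringsAsFactors = FALSE)
  tot <- 0
  for (r in seq_len(nrow(grid))) {
    s <- unlist(grid[r, ], use.names = FALSE)
    i <- match(s, bg@letters)
    p <- 1
    for (j in seq_along(i)) {
      pv <- if (j == 1 || bg@order == 0) bg@p0
            else if (j == 2 || bg@order == 1) bg@p1[i[j - 1], ]
            else bg@p2[i[j - 2], i[j - 1], ]
      p <- p * pv[[i[j]]]
    }
    tot <- tot + p
  }
  log10(tot)
}

test_that("log-likelihood DP equals exhaustive enumeration on a fitted model", {
  set.seed(33)
  corpus <- vapply(1:30, function(i) {
    paste(sample(c("A", "C", "D", "E", "F", "G"), 40, replace = TRUE),
          collapse = "")
  }, character(1))
  for (ord in 0:2) {
    bg <- fitBackground(corpus, order = ord)
    for (p in c("ACD", "[AG].C", "A..D", "[DE][DE]", "G", "F.[ACD]G")) {
      expect_equal(logLikelihood(p, bg), enumLogLik(p, bg), tolerance = 1e-9,
                   info = paste(ord, p))
    }
  }
})

test_that("background fitting smooths and normalises", {
  bg0 <- fitBackground("AAAA", order = 0)
  expect_equal(sum(bg0@p0), 1, tolerance = 1e-12)
  expect_equal(unname(bg0@p0[["A"]]), 5 / 24)  # (4+1)/(4+20) under add-one
  bg2 <- fitBackground(c("ACACACAC", "DEDEDEDE"), order = 2)
  sums <- apply(bg2@p2, c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_error(fitBackground(character()), "empty")
})

test_that("greedy selection claims each region once and drops zero-gain patterns", {
  cnp <- BondRegions(c("AAABBBCC", "AAABBBCD", "AAACCCDD", "DDDCCCAA"),
                     "CIS", region_id = paste0("r", 1:4))
  tnp <- BondRegions(c("GGGGGGGG", "HHHHHHHH"), "TRANS",
                     region_id = paste0("t", 1:2))
  # P1 (higher score) matches r1-r3; P2 matches r3, r4; P3 only r1, r2
  stats <- data.frame(pattern = c("AAA", "CCC", "AAAB"),
                      c = c(3L, 2L, 2L), t = c(0L, 0L, 0L),
                      sc_score = c(1, 0.99, 0.98))
  sel <- selectNonredundant(stats, cnp, tnp)
  ret <- retainedPatterns(sel)
  expect_equal(ret$pattern, c("AAA", "CCC"))  # P3 claims nothing new
  asg <- assignmentTable(sel)
  expect_false(any(duplicated(asg$region_id)))
  expect_equal(sort(asg$region_id[asg$pattern == "CCC"]), "r4")
  expect_equal(coveragePct(sel), 100)
  expect_equal(fdrPct(sel), 0)
})

test_that("selection is idempotent on its own retained list", {
  spec <- cleanPlantedSpec(nCis = 14L, nTrans = 300L, seed = 21L)
  d <- generateSynthetic(spec)
  sc <- scorePatterns(discoverPatterns(d$cnp), d$cnp, d$tnp)
  sel1 <- selectNonredundant(filterPatterns(sc, 0.9), d$cnp, d$tnp)
  sel2 <- selectNonredundant(retainedPatterns(sel1), d$cnp, d$tnp)
  expect_equal(assignmentTable(sel2), assignmentTable(sel1))
  expect_equal(retainedPatterns(sel2)$pattern, retainedPatterns(sel1)$pattern)
})

test_that("coverage and FDR percentages follow their formulas", {
  cf <- fdrAndCoverage(318, 46560, 318, 685716)
  expect_equal(unname(cf["coverage_pct"]), 100)
  expect_equal(unname(cf["fdr_pct"]), 100 * 46560 / 685716)
  expect_equal(round(unname(cf["fdr_pct"]), 2), 6.79)
  expect_equal(unname(fdrAndCoverage(0, 0, 10, 10)["fdr_pct"]), 0)
})

test_that("residue/class frequencies count literals and classes over the literal total", {
  f1 <- residueFrequencies("ADEAT")
  expect_equal(f1$percent[f1$element == "A"], 40)
  expect_equal(sum(f1$percent), 100)
  f2 <- residueFrequencies("YFT...I")
  expect_equal(nrow(f2), 4L)
  expect_true(all(f2$percent == 25))
  f3 <- residueFrequencies("G.[AG][DE].K..SL")
  expect_equal(sum(f3$count), 6L)  # wildcards excluded from the denominator
  expect_true(all(c("[AG]", "[DE]") %in% f3$element))
  expect_equal(sum(f3$percent), 100)
  expect_error(residueFrequencies(character()), "empty")
})

test_that("bond-position frequencies sum to 100 over the centre column", {
  r <- BondRegions(rep("AAAAAGAAAAA", 10), "CIS")
  f <- bondPositionFrequencies(r)
  expect_equal(f$bond_pct[f$residue == "G"], 100)
  expect_equal(sum(f$bond_pct), 100)
  expect_equal(sum(f$preceding_pct), 100)
  expect_equal(f$preceding_pct[f$residue == "A"], 100)
  # the published scale: 52 of 318 centre glycines is ~16%
  expect_equal(round(100 * 52 / 318), 16)
  expect_error(bondPositionFrequencies(BondRegions(character(), character())),
               "empty")
})
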
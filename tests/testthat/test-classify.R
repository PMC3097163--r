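test_that("the split rounds 2/3 half-up and keeps control and test pools apart", {
  spec <- cleanPlantedSpec(nCis = 18L, nTrans = 400L, seed = 3L)
  d <- generateSynthetic(spec)
  sp <- splitRegions(d$cnp, d$tnp, seed = 9L)
  expect_equal(length(sp$train_cis), 12L)   # round(2/3 * 18)
  expect_equal(length(sp$test_cis), 6L)
  expect_equal(length(sp$train_trans_control), 12L)
  expect_equal(length(sp$test_trans_resamples), 5L)
  for (r in sp$test_trans_resamples) {
    expect_equal(length(r), 6L)
    # no leakage of control windows into testing
    expect_length(intersect(regionIds(r), regionIds(sp$train_trans_control)), 0L)
    # sampled without replacement within a resample
    expect_false(any(duplicated(regionIds(r))))
  }
  # train and test cis partition the cis set
  expect_setequal(c(regionIds(sp$train_cis), regionIds(sp$test_cis)),
                  regionIds(d$cnp))
})

test_that("splitting a 3-window cis set gives 2 train / 1 test", {
  cnp <- BondRegions(c("AAAAA", "CCCCC", "DDDDD"), "CIS")
  tnp <- BondRegions(replicate(30, paste(sample(AA_STANDARD, 5, TRUE),
                                         collapse = "")), "TRANS")
  sp <- splitRegions(cnp, tnp, seed = 1L, nTestResamples = 2L)
  expect_equal(length(sp$train_cis), 2L)
  expect_equal(length(sp$test_cis), 1L)
  expect_error(splitRegions(cnp[1], tnp, seed = 1L), "too small")
})

test_that("the split is deterministic under its seed", {
  spec <- cleanPlantedSpec(nCis = 18L, nTrans = 400L, seed = 3L)
  d <- generateSynthetic(spec)
  a <- splitRegions(d$cnp, d$tnp, seed = 42L)
  b <- splitRegions(d$cnp, d$tnp, seed = 42L)
  expect_identical(lapply(a$test_trans_resamples, regionIds),
                   lapply(b$test_trans_resamples, regionIds))
  expect_identical(regionIds(a$train_cis), regionIds(b$train_cis))
  c <- splitRegions(d$cnp, d$tnp, seed = 43L)
  expect_false(identical(regionIds(a$train_cis), regionIds(c$train_cis)))
})

test_that("prediction is any-match and monotone in the pattern list", {
  regions <- c("QADEATKLMNS", "GGGGGGGGGGG", "WAHKYGGGGGG")
  expect_equal(predictRegions(character(), regions),
               rep("TRANS", 3))  # no pattern, everything trans
  p1 <- predictRegions("ADEAT", regions)
  expect_equal(p1, c("CIS", "TRANS", "TRANS"))
  # adding patterns never flips CIS back to TRANS
  p2 <- predictRegions(c("ADEAT", "W.HKY", "GGG"), regions)
  expect_true(all(p2[p1 == "CIS"] == "CIS"))
  expect_equal(p2, c("CIS", "CIS", "CIS"))
})

test_that("metrics follow the confusion-matrix formulas and average per resample", {
  # one resample with the stated confusion matrix
  pats <- "ADEAT"
  cisWin <- c(rep("AAADEATAAAA", 70), rep("GGGGGGGGGGG", 23))
  transWin <- c(rep("CCCCCCCCCCC", 58), rep("AADEATAAAAA", 35))
  res <- evaluateClassifier(pats, BondRegions(cisWin, "CIS"),
                            list(BondRegions(transWin, "TRANS")))
  expect_equal(res$confusion$TP, 70)
  expect_equal(res$confusion$FN, 23)
  expect_equal(res$confusion$TN, 58)
  expect_equal(res$confusion$FP, 35)
  expect_equal(res$sensitivity_pct, 100 * 70 / 93, tolerance = 1e-12)
  expect_equal(res$specificity_pct, 100 * 58 / 93, tolerance = 1e-12)
  expect_equal(res$accuracy_pct, 100 * 128 / 186, tolerance = 1e-12)
  expect_equal(round(res$sensitivity_pct, 2), 75.27)
  expect_equal(round(res$specificity_pct, 2), 62.37)
  expect_equal(round(res$accuracy_pct, 2), 68.82)
})

test_that("averaged metrics equal the mean of per-resample metrics", {
  spec <- cleanPlantedSpec(nCis = 18L, nTrans = 500L, seed = 8L)
  d <- generateSynthetic(spec)
  cls <- runClassification(d$cnp, d$tnp, seed = 4L)
  expect_equal(cls$specificity_pct, mean(cls$confusion$specificity_pct),
               tolerance = 1e-12)
  expect_equal(cls$accuracy_pct, mean(cls$confusion$accuracy_pct),
               tolerance = 1e-12)
})

test_that("an all-trans predictor scores 0/100/50 on balanced sets", {
  cisWin <- BondRegions(rep("AAAAAAAAAAA", 10), "CIS")
  transWin <- BondRegions(rep("CCCCCCCCCCC", 10), "TRANS")
  res <- evaluateClassifier(character(), cisWin, list(transWin, transWin))
  expect_equal(res$sensitivity_pct, 0)
  expect_equal(res$specificity_pct, 100)
  expect_equal(res$accuracy_pct, 50)
})

test_that("planted motifs are recovered with score 1 and drive near-perfect held-out calls", {
  spec <- cleanPlantedSpec(nCis = 24L, nTrans = 800L, seed = 13L)
  d <- generateSynthetic(spec)
  cls <- runClassification(d$cnp, d$tnp, seed = 2L)
  expect_gte(cls$sensitivity_pct, 95)
  expect_gte(cls$specificity_pct, 95)
  # the trained pattern list pins every planted window
  expect_gt(length(cls$patterns), 0L)
})
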
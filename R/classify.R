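## Pattern-based cis/trans classification: split, train, predict, evaluate.

withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

roundHalfUp <- function(x) floor(x + 0.5)

#' Split cis/trans windows for classifier evaluation
#'
#' The cis set is split into a training part (`trainFrac`, rounded half
#' up) and a test part. An equal-sized trans control group for training is
#' sampled without replacement; trans test sets of the cis-test size are
#' resampled `nTestResamples` times (without replacement within a
#' resample) from the trans windows not used in the training control, so
#' control windows never leak into testing. Fully reproducible from
#' `seed`.
#'
#' @param cnp,tnp [BondRegions-class] objects.
#' @param trainFrac fraction of cis windows used for training.
#' @param nTestResamples number of trans test resamples.
#' @param seed integer RNG seed.
#' @return list with `train_cis`, `train_trans_control`, `test_cis`,
#'   `test_trans_resamples` (list), and `seed`.
#' @export
splitRegions <- function(cnp, tnp, trainFrac = 2 / 3, nTestResamples = 5L,
                         seed = 1L) {
  stopifnot(trainFrac > 0, trainFrac < 1, nTestResamples >= 1L)
  nC <- length(cnp); nT <- length(tnp)
  nTrain <- as.integer(roundHalfUp(trainFrac * nC))
  nTest <- nC - nTrain
  if (nTrain < 1L || nTest < 1L) stop("cis dataset too small to split")
  if (nT < nTrain + nTest) stop("trans dataset too small for control and testing")
  withSeed(seed, {
    trainIdx <- sort(sample.int(nC, nTrain))
    testIdx <- setdiff(seq_len(nC), trainIdx)
    ctrlIdx <- sort(sample.int(nT, nTrain))
    pool <- setdiff(seq_len(nT), ctrlIdx)
    if (length(pool) < nTest) stop("trans pool too small for test resamples")
    resamples <- lapply(seq_len(nTestResamples), function(k) {
      tnp[sort(pool[sample.int(length(pool), nTest)])]
    })
    list(train_cis = cnp[trainIdx], train_trans_control = tnp[ctrlIdx],
         test_cis = cnp[testIdx], test_trans_resamples = resamples,
         seed = seed)
  })
}

#' Train the pattern-based classifier
#'
#' Runs the full pipeline on the training windows only: maximal pattern
#' discovery on the cis training set, propensity scoring against the
#' equal-sized trans control, strict threshold filtering, and greedy
#' non-redundant selection.
#'
#' @param train_cis,train_trans_control [BondRegions-class] training sets.
#' @param W,L,K,alphabet discovery parameters, see [discoverPatterns()].
#' @param threshold [filterPatterns()] cutoff (strict `>`).
#' @return list with `patterns` (character vector of retained patterns),
#'   `selection` ([SelectionResult-class]) and `scored` (data.frame).
#' @export
trainPatternClassifier <- function(train_cis, train_trans_control,
                                   W = 11L, L = 3L, K = 2L,
                                   alphabet = "none", threshold = 0.90) {
  ps <- discoverPatterns(train_cis, W = W, L = L, K = K, alphabet = alphabet)
  if (!length(ps)) {
    return(list(patterns = character(),
                selection = selectNonredundant(
                  data.frame(pattern = character(), c = integer(),
                             t = integer(), sc_score = numeric()),
                  train_cis, train_trans_control),
                scored = data.frame()))
  }
  scored <- scorePatterns(ps, train_cis, train_trans_control)
  kept <- filterPatterns(scored, threshold)
  sel <- selectNonredundant(kept, train_cis, train_trans_control)
  list(patterns = retainedPatterns(sel)$pattern, selection = sel,
       scored = scored)
}

#' Predict cis/trans labels by pattern matching
#'
#' A window is called `CIS` iff at least one pattern matches it; with no
#' matching pattern it is called `TRANS`. No vote counting.
#'
#' @param pats character vector of patterns (or [PatternSet-class]).
#' @param regions [BondRegions-class] or character vector.
#' @return character vector of `"CIS"`/`"TRANS"` labels.
#' @export
predictRegions <- function(pats, regions) {
  seqs <- if (methods::is(regions, "BondRegions")) regionSequences(regions) else regions
  if (methods::is(pats, "PatternSet")) pats <- patterns(pats)
  hit <- logical(length(seqs))
  for (p in pats) {
    if (all(hit)) break
    hit <- hit | patternMatches(p, seqs)
  }
  ifelse(hit, "CIS", "TRANS")
}

#' Evaluate the classifier on held-out windows
#'
#' Sensitivity is computed once on the cis test set; specificity is
#' computed per trans resample and averaged; accuracy per resample (pairing
#' the fixed cis predictions with each resample) and averaged.
#'
#' @param pats retained patterns.
#' @param test_cis [BondRegions-class] cis test windows.
#' @param test_trans_resamples list of [BondRegions-class] trans test sets,
#'   each the size of `test_cis`.
#' @return list with `sensitivity_pct`, `specificity_pct`, `accuracy_pct`
#'   and `confusion` (data.frame of per-resample TP/FP/TN/FN).
#' @export
evaluateClassifier <- function(pats, test_cis, test_trans_resamples) {
  predCis <- predictRegions(pats, test_cis)
  TP <- sum(predCis == "CIS"); FN <- sum(predCis == "TRANS")
  conf <- lapply(seq_along(test_trans_resamples), function(k) {
    predT <- predictRegions(pats, test_trans_resamples[[k]])
    TN <- sum(predT == "TRANS"); FP <- sum(predT == "CIS")
    data.frame(resample = k, TP = TP, FP = FP, TN = TN, FN = FN,
               specificity_pct = 100 * TN / (TN + FP),
               accuracy_pct = 100 * (TP + TN) / (TP + FP + TN + FN))
  })
  conf <- do.call(rbind, conf)
  list(sensitivity_pct = 100 * TP / (TP + FN),
       specificity_pct = mean(conf$specificity_pct),
       accuracy_pct = mean(conf$accuracy_pct),
       confusion = conf)
}

#' Split, train and evaluate in one call
#'
#' @inheritParams splitRegions
#' @inheritParams trainPatternClassifier
#' @return the [evaluateClassifier()] result plus the trained `patterns`,
#'   the `split` sizes and the `seed`.
#' @export
runClassification <- function(cnp, tnp, W = 11L, L = 3L, K = 2L,
                              alphabet = "none", threshold = 0.90,
                              trainFrac = 2 / 3, nTestResamples = 5L,
                              seed = 1L) {
  sp <- splitRegions(cnp, tnp, trainFrac = trainFrac,
                     nTestResamples = nTestResamples, seed = seed)
  fit <- trainPatternClassifier(sp$train_cis, sp$train_trans_control,
                                W = W, L = L, K = K, alphabet = alphabet,
                                threshold = threshold)
  res <- evaluateClassifier(fit$patterns, sp$test_cis,
                            sp$test_trans_resamples)
  res$patterns <- fit$patterns
  res$split <- c(n_train_cis = length(sp$train_cis),
                 n_test_cis = length(sp$test_cis))
  res$seed <- seed
  res
}
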
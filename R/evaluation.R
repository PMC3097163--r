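#' Cis-propensity score of a pattern
#'
#' Balances the pattern's representation in the small cis set against the
#' large trans set: `sc = c / (c + norm * t)` with `norm = |CNP| / |TNP|`.
#' Equals 1 when the pattern never matches a trans window, 0.5 when its
#' representation is exactly proportional to the dataset sizes
#' (`t / c = |TNP| / |CNP|`), and is strictly increasing in `c`, strictly
#' decreasing in `t`. This normalisation handles the extreme class
#' imbalance without subsampling the trans windows.
#'
#' @param c cis match count (>= 1; patterns originate from the cis set).
#' @param t trans match count (>= 0).
#' @param n_cnp,n_tnp dataset sizes (>= 1).
#' @return numeric in (0, 1].
#' @examples
#' scScore(2, 1000, 318, 685716)
#' @export
scScore <- function(c, t, n_cnp, n_tnp) {
  stopifnot(n_cnp >= 1, n_tnp >= 1, all(t >= 0))
  if (any(c < 1)) stop("c must be >= 1: a scored pattern originates from CNP")
  norm <- n_cnp / n_tnp
  c / (c + norm * t)
}

#' Score a pattern set against cis and trans regions
#'
#' Computes per-pattern cis/trans distinct-region match counts, the
#' [scScore()], and (when a background model is given) the background
#' [logLikelihood()].
#'
#' @param pats [PatternSet-class], character vector of patterns, or a
#'   data.frame with a `pattern` column.
#' @param cnp,tnp [BondRegions-class] objects (or character vectors).
#' @param background optional [MarkovBackground-class].
#' @return data.frame with columns `pattern`, `c`, `t`, `sc_score` and, if
#'   a background is given, `log_likelihood`.
#' @export
scorePatterns <- function(pats, cnp, tnp, background = NULL) {
  pat <- if (methods::is(pats, "PatternSet")) patterns(pats)
         else if (is.data.frame(pats)) pats$pattern
         else as.character(pats)
  cisSeq <- if (methods::is(cnp, "BondRegions")) regionSequences(cnp) else cnp
  trnSeq <- if (methods::is(tnp, "BondRegions")) regionSequences(tnp) else tnp
  cc <- integer(length(pat)); tt <- integer(length(pat))
  for (i in seq_along(pat)) {
    cc[i] <- sum(patternMatches(pat[i], cisSeq))
    tt[i] <- sum(patternMatches(pat[i], trnSeq))
  }
  out <- data.frame(pattern = pat, c = cc, t = tt,
                    sc_score = scScore(cc, tt, max(length(cisSeq), 1L),
                                       max(length(trnSeq), 1L)),
                    stringsAsFactors = FALSE)
  if (!is.null(background)) {
    out$log_likelihood <- vapply(pat, logLikelihood, numeric(1),
                                 bg = background, USE.NAMES = FALSE)
  }
  out
}

#' Keep patterns scoring strictly above a threshold
#'
#' @param stats data.frame from [scorePatterns()].
#' @param threshold keep rows with `sc_score > threshold` (strict).
#' @return filtered data.frame, input order preserved.
#' @export
filterPatterns <- function(stats, threshold = 0.90) {
  stopifnot(threshold >= 0, threshold <= 1)
  stats[stats$sc_score > threshold, , drop = FALSE]
}

#' Greedy non-redundant pattern selection
#'
#' Patterns are sorted by descending `sc_score` (ties: larger `c`, then
#' more literals, then lexicographic pattern) and processed in turn; each
#' claims the not-yet-claimed cis and trans windows it matches, so every
#' window ends up assigned to at most one pattern (a 1-N pattern-to-region
#' relationship). A pattern claiming no new cis window is dropped.
#' Selection stops at 100% cis coverage or when the list is exhausted.
#'
#' @param stats data.frame from [scorePatterns()] (needs `pattern`,
#'   `sc_score`, and ideally `c`).
#' @param cnp,tnp [BondRegions-class] objects the stats were computed
#'   against.
#' @return a [SelectionResult-class] object.
#' @export
selectNonredundant <- function(stats, cnp, tnp) {
  if (!methods::is(cnp, "BondRegions")) cnp <- BondRegions(cnp, "CIS")
  if (!methods::is(tnp, "BondRegions")) tnp <- BondRegions(tnp, "TRANS")
  nC <- length(cnp); nT <- length(tnp)
  cisSeq <- regionSequences(cnp); trnSeq <- regionSequences(tnp)
  if (nrow(stats)) {
    lit <- vapply(stats$pattern, patternLiteralCount, integer(1),
                  USE.NAMES = FALSE)
    cKey <- if ("c" %in% names(stats)) stats$c else rep(0L, nrow(stats))
    ord <- order(-stats$sc_score, -cKey, -lit, stats$pattern, method = "radix")
    stats <- stats[ord, , drop = FALSE]
  }
  claimedC <- logical(nC); claimedT <- logical(nT)
  rows <- list(); asg <- list(); kept <- 0L
  for (i in seq_len(nrow(stats))) {
    if (nC && all(claimedC)) break
    p <- stats$pattern[i]
    mC <- patternMatches(p, cisSeq)
    newC <- mC & !claimedC
    if (!any(newC)) next
    mT <- patternMatches(p, trnSeq)
    newT <- mT & !claimedT
    claimedC <- claimedC | newC
    claimedT <- claimedT | newT
    kept <- kept + 1L
    rows[[kept]] <- data.frame(
      pattern = p,
      c = sum(mC), t = sum(mT),
      sc_score = if ("sc_score" %in% names(stats)) stats$sc_score[i] else NA_real_,
      claimed_cis = sum(newC), claimed_trans = sum(newT),
      stringsAsFactors = FALSE)
    asg[[kept]] <- data.frame(
      region_id = c(regionIds(cnp)[newC], regionIds(tnp)[newT]),
      label = c(rep("CIS", sum(newC)), rep("TRANS", sum(newT))),
      pattern = p, stringsAsFactors = FALSE)
  }
  retained <- if (kept) do.call(rbind, rows) else
    data.frame(pattern = character(), c = integer(), t = integer(),
               sc_score = numeric(), claimed_cis = integer(),
               claimed_trans = integer(), stringsAsFactors = FALSE)
  assignment <- if (kept) do.call(rbind, asg) else
    data.frame(region_id = character(), label = character(),
               pattern = character(), stringsAsFactors = FALSE)
  cf <- fdrAndCoverage(sum(claimedC), sum(claimedT), max(nC, 1L), max(nT, 1L))
  methods::new("SelectionResult", retained = retained, assignment = assignment,
               coverage_pct = unname(cf["coverage_pct"]),
               fdr_pct = unname(cf["fdr_pct"]),
               n_cnp = nC, n_tnp = nT)
}

#' Coverage and false discovery rate of a selection
#'
#' Coverage is the percentage of cis windows claimed by retained patterns;
#' FDR the percentage of trans windows claimed.
#'
#' @param assigned_cis,assigned_trans distinct claimed window counts, or a
#'   [SelectionResult-class] as first argument.
#' @param n_cnp,n_tnp dataset sizes.
#' @return named numeric vector `coverage_pct`, `fdr_pct`.
#' @examples
#' fdrAndCoverage(318, 46560, 318, 685716)
#' @export
fdrAndCoverage <- function(assigned_cis, assigned_trans = NULL,
                           n_cnp = NULL, n_tnp = NULL) {
  if (methods::is(assigned_cis, "SelectionResult")) {
    r <- assigned_cis
    a <- assignmentTable(r)
    assigned_trans <- sum(a$label == "TRANS")
    n_cnp <- n_cnp %||% r@n_cnp
    n_tnp <- n_tnp %||% r@n_tnp
    assigned_cis <- sum(a$label == "CIS")
  }
  stopifnot(n_cnp >= 1, n_tnp >= 1)
  c(coverage_pct = 100 * assigned_cis / n_cnp,
    fdr_pct = 100 * assigned_trans / n_tnp)
}

#' Residue and class frequencies over a pattern list
#'
#' Tallies every literal letter and every character-class token across the
#' patterns; wildcards are excluded from the denominator, so percentages
#' sum to 100.
#'
#' @param pats [PatternSet-class], character vector, or data.frame with a
#'   `pattern` column.
#' @return data.frame `element`, `count`, `percent`, sorted by descending
#'   count then element.
#' @examples
#' residueFrequencies(c("YFT...I"))
#' @export
residueFrequencies <- function(pats) {
  pat <- if (methods::is(pats, "PatternSet")) patterns(pats)
         else if (is.data.frame(pats)) pats$pattern
         else as.character(pats)
  if (!length(pat)) stop("empty pattern list")
  toks <- unlist(lapply(pat, parsePattern))
  toks <- toks[toks != "."]
  tab <- table(toks)
  df <- data.frame(element = names(tab), count = as.integer(tab),
                   percent = 100 * as.integer(tab) / sum(tab),
                   stringsAsFactors = FALSE)
  df[order(-df$count, df$element), , drop = FALSE]
}

#' Residue frequencies at and before the bond position
#'
#' For windows of odd width the bond-bearing residue sits at the centre
#' (position 6 of 11); the preceding residue is the one before it. Returns
#' both frequency distributions over the 20 standard residues, each in
#' percent.
#'
#' @param regions [BondRegions-class] or character vector of equal-width
#'   windows.
#' @return data.frame `residue`, `bond_count`, `preceding_count`,
#'   `bond_pct`, `preceding_pct`.
#' @export
bondPositionFrequencies <- function(regions) {
  seqs <- if (methods::is(regions, "BondRegions")) regionSequences(regions) else regions
  if (!length(seqs)) stop("empty region list: frequency distribution undefined")
  w <- nchar(seqs[1L])
  center <- (w + 1L) %/% 2L
  atBond <- substr(seqs, center, center)
  atPrev <- substr(seqs, center - 1L, center - 1L)
  cb <- table(factor(atBond, levels = AA_STANDARD))
  cp <- table(factor(atPrev, levels = AA_STANDARD))
  data.frame(residue = AA_STANDARD,
             bond_count = as.integer(cb),
             preceding_count = as.integer(cp),
             bond_pct = 100 * as.integer(cb) / length(seqs),
             preceding_pct = 100 * as.integer(cp) / length(seqs),
             stringsAsFactors = FALSE)
}
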
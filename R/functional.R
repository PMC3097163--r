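## Comparison of retained patterns against a functional motif library
## (ELM-like: short linear motifs with TRG/MOD/LIG/CLV classes), plus a
## chi-square enrichment test of the recovered class profile.

MOTIF_CLASSES <- c("TRG", "MOD", "LIG", "CLV")

#' Load an ELM-like motif library
#'
#' TSV with header `motif_id  pattern  class  go_terms` (`go_terms`
#' semicolon-separated, may be empty; `#` comment lines allowed). Only the
#' regex subset used by the comparison is supported: literals, `.`,
#' classes `[..]` and negated classes `[^..]`. Entries using quantifiers,
#' anchors or alternation are skipped with a warning; the skip count is
#' attached as attribute `skipped`.
#'
#' @param path TSV file path.
#' @return data.frame `motif_id`, `pattern`, `class`, `go_terms` (list
#'   column).
#' @export
loadMotifLibrary <- function(path) {
  df <- tryCatch(
    utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                      colClasses = "character"),
    error = function(e) stop("unparseable motif library ", path, ": ",
                             conditionMessage(e)))
  need <- c("motif_id", "pattern", "class", "go_terms")
  if (!all(need[1:3] %in% names(df))) {
    stop("motif library must have columns motif_id, pattern, class")
  }
  if (!"go_terms" %in% names(df)) df$go_terms <- ""
  blank <- !nzchar(trimws(df$class))
  if (any(blank)) {
    stop("empty functional class for motif row(s): ",
         paste(df$motif_id[blank], collapse = ", "))
  }
  bad <- !df$class %in% MOTIF_CLASSES
  if (any(bad)) {
    stop("unknown functional class ", sQuote(df$class[bad][1L]),
         " for motif ", df$motif_id[bad][1L])
  }
  parseable <- vapply(df$pattern, function(p) {
    !inherits(tryCatch(parsePattern(p, allowNegation = TRUE),
                       error = function(e) e), "error")
  }, logical(1), USE.NAMES = FALSE)
  if (any(!parseable)) {
    warning(sum(!parseable), " motif(s) skipped: unsupported pattern syntax (",
            paste(utils::head(df$motif_id[!parseable], 3L), collapse = ", "),
            if (sum(!parseable) > 3L) ", ..." else "", ")")
  }
  out <- df[parseable, need, drop = FALSE]
  out$go_terms <- strsplit(out$go_terms, ";", fixed = TRUE)
  rownames(out) <- NULL
  attr(out, "skipped") <- sum(!parseable)
  out
}

## information content of one element: 1 for a literal, 0 for the wildcard
elementIC <- function(tok, letters = AA_STANDARD) {
  1 - log(length(tokenResidues(tok, letters))) / log(length(letters))
}

#' Compare two patterns by shared information content
#'
#' Slides one pattern over the other and scores every overlap: aligned
#' element pairs are compatible iff their allowed-residue sets intersect;
#' an incompatible non-wildcard pair vetoes the offset. A qualifying
#' offset needs at least `minShared` compatible pairs in which both
#' elements are non-wildcards; its score is the sum over those pairs of
#' `min(IC_query, IC_motif)`, where the information content of an element
#' allowing `s` of the 20 residues is `1 - log(s)/log(20)` (1 for a
#' literal, 0 for the wildcard). The hit reports the best offset.
#'
#' @param query pattern string or token vector (discovery output).
#' @param motif motif pattern string (may contain `[^..]`).
#' @param minShared minimum shared non-wildcard positions.
#' @return `NULL` when no offset qualifies, otherwise a list with
#'   `cm_score`, `offset` (motif start relative to query start, 0-based),
#'   `matched_positions`.
#' @examples
#' comparePatternPair("ADEAT", "DEA")
#' @export
comparePatternPair <- function(query, motif, minShared = 3L) {
  qt <- if (length(query) == 1L) parsePattern(query, allowNegation = TRUE) else query
  mt <- if (length(motif) == 1L) parsePattern(motif, allowNegation = TRUE) else motif
  qs <- lapply(qt, tokenResidues)
  ms <- lapply(mt, tokenResidues)
  qic <- vapply(qt, elementIC, numeric(1))
  mic <- vapply(mt, elementIC, numeric(1))
  qw <- qt == "."; mw <- mt == "."
  nq <- length(qt); nm <- length(mt)
  best <- NULL
  for (d in (-(nm - 1L)):(nq - 1L)) {   # motif start offset rel. query start
    qi <- max(1L, d + 1L):min(nq, d + nm)
    mi <- qi - d
    score <- 0; shared <- 0L; vetoed <- FALSE
    for (k in seq_along(qi)) {
      a <- qi[k]; b <- mi[k]
      if (qw[a] || mw[b]) next
      if (!length(intersect(qs[[a]], ms[[b]]))) { vetoed <- TRUE; break }
      shared <- shared + 1L
      score <- score + min(qic[a], mic[b])
    }
    if (vetoed || shared < minShared) next
    if (is.null(best) || score > best$cm_score) {
      best <- list(cm_score = score, offset = d, matched_positions = shared)
    }
  }
  best
}

#' Compare many patterns against a motif library
#'
#' @param pats [PatternSet-class], data.frame with a `pattern` column, or
#'   character vector.
#' @param library motif library data.frame from [loadMotifLibrary()].
#' @param minShared see [comparePatternPair()].
#' @return data.frame of hits: `pattern`, `motif_id`, `class`, `cm_score`,
#'   `offset`, `matched_positions`.
#' @export
compareToLibrary <- function(pats, library, minShared = 3L) {
  pat <- if (methods::is(pats, "PatternSet")) patterns(pats)
         else if (is.data.frame(pats)) pats$pattern
         else as.character(pats)
  rows <- list(); n <- 0L
  for (p in pat) {
    for (i in seq_len(nrow(library))) {
      hit <- comparePatternPair(p, library$pattern[i], minShared = minShared)
      if (is.null(hit)) next
      n <- n + 1L
      rows[[n]] <- data.frame(pattern = p, motif_id = library$motif_id[i],
                              class = library$class[i],
                              cm_score = hit$cm_score, offset = hit$offset,
                              matched_positions = hit$matched_positions,
                              stringsAsFactors = FALSE)
    }
  }
  if (!n) {
    return(data.frame(pattern = character(), motif_id = character(),
                      class = character(), cm_score = numeric(),
                      offset = integer(), matched_positions = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Functional-class profile of comparison hits
#'
#' A query pattern contributes at most once per functional class, however
#' many same-class motifs it hits; one pattern may contribute to several
#' classes.
#'
#' @param hits data.frame from [compareToLibrary()].
#' @return named integer vector of counts over `TRG`, `MOD`, `LIG`, `CLV`.
#' @export
classProfile <- function(hits) {
  u <- unique(hits[, c("pattern", "class"), drop = FALSE])
  tab <- table(factor(u$class, levels = MOTIF_CLASSES))
  stats::setNames(as.integer(tab), MOTIF_CLASSES)
}

#' Chi-square enrichment of observed class counts
#'
#' Goodness-of-fit test of the observed functional-class counts against
#' the class composition of the motif library (expected fractions), with
#' df = number of classes - 1.
#'
#' @param observed named integer vector of class counts.
#' @param expected_fractions named numeric vector of class fractions; by
#'   default the library-wide class representation TRG 13%, MOD 25%,
#'   LIG 54%, CLV 7%. Rounded percentages are accepted: the fractions may
#'   deviate from a unit sum by up to 0.05 and are renormalised before the
#'   test (so counts exactly proportional to the stated fractions always
#'   give a zero statistic).
#' @param alpha significance level.
#' @return list with `observed`, `expected_fractions`, `expected_counts`,
#'   `chi2`, `df`, `p_value`, `alpha`, `significant`.
#' @export
motifEnrichment <- function(observed,
                            expected_fractions = c(TRG = 0.13, MOD = 0.25,
                                                   LIG = 0.54, CLV = 0.07),
                            alpha = 0.01) {
  if (!is.null(names(observed)) && !is.null(names(expected_fractions))) {
    expected_fractions <- expected_fractions[names(observed)]
  }
  stopifnot(length(observed) == length(expected_fractions))
  total <- sum(observed)
  if (total < 1) stop("observed counts must total at least 1")
  if (abs(sum(expected_fractions) - 1) > 0.05) {
    stop("expected fractions must sum to 1 (up to percentage rounding)")
  }
  expected_fractions <- expected_fractions / sum(expected_fractions)
  expected <- expected_fractions * total
  if (any(expected == 0)) stop("expected count of 0: class cannot be tested")
  chi2 <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  p <- stats::pchisq(chi2, df = df, lower.tail = FALSE)
  list(observed = observed, expected_fractions = expected_fractions,
       expected_counts = expected, chi2 = chi2, df = df, p_value = p,
       alpha = alpha, significant = p < alpha)
}
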
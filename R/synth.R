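#' Specification for a synthetic window dataset
#'
#' Describes a ground-truth dataset for exercising the whole pipeline: a
#' large set of trans windows drawn i.i.d. from a residue background model
#' and a small cis set in which degenerate motifs are planted at known
#' positions.
#'
#' @param nCis,nTrans window counts.
#' @param windowLen window width (the bond-window studies use 11).
#' @param background a [MarkovBackground-class] (default uniform order 0).
#' @param planted list of `list(pattern =, fraction =)` entries; fractions
#'   in (0, 1] and summing to at most 1 (at most one planted motif per cis
#'   window).
#' @param noise per-position probability of corrupting an instantiated
#'   motif residue to a random one, in \[0, 1).
#' @param clean when `TRUE`, trans windows are rejection-sampled so that no
#'   planted pattern matches any of them (known-zero false positives);
#'   when `FALSE`, chance matches are allowed.
#' @param seed integer RNG seed.
#' @return list of class `SynthSpec`.
#' @export
synthSpec <- function(nCis, nTrans, windowLen = 11L,
                      background = uniformBackground(),
                      planted = list(), noise = 0, clean = TRUE, seed = 1L) {
  stopifnot(nCis >= 0L, nTrans >= 0L, windowLen >= 1L,
            noise >= 0, noise < 1)
  for (p in planted) {
    stopifnot(!is.null(p$pattern), !is.null(p$fraction),
              p$fraction > 0, p$fraction <= 1)
    if (length(parsePattern(p$pattern)) > windowLen) {
      stop("planted pattern ", sQuote(p$pattern), " longer than the window")
    }
  }
  if (length(planted) && sum(vapply(planted, `[[`, numeric(1), "fraction")) > 1 + 1e-9) {
    stop("planted fractions must sum to at most 1 (one motif per window)")
  }
  structure(list(nCis = as.integer(nCis), nTrans = as.integer(nTrans),
                 windowLen = as.integer(windowLen), background = background,
                 planted = planted, noise = noise, clean = clean,
                 seed = as.integer(seed)),
            class = "SynthSpec")
}

## instantiate one pattern: classes -> uniform member, wildcards -> a
## background marginal draw, then per-position corruption noise
instantiatePattern <- function(toks, bg, noise) {
  letters <- bg@letters
  res <- vapply(toks, function(tk) {
    if (tk == ".") sample(letters, 1L, prob = bg@p0)
    else {
      members <- tokenResidues(tk, letters)
      if (length(members) == 1L) members else sample(members, 1L)
    }
  }, character(1), USE.NAMES = FALSE)
  if (noise > 0) {
    lit <- which(toks != ".")
    flip <- lit[stats::runif(length(lit)) < noise]
    if (length(flip)) res[flip] <- sample(letters, length(flip), replace = TRUE)
  }
  res
}

#' Generate a synthetic cis/trans window dataset
#'
#' Trans windows are i.i.d. draws from the background (rejection-sampled
#' against the planted patterns in clean mode). Each planted pattern is
#' instantiated, at a uniform random offset, in its share of the cis
#' windows (shares assigned by rounding `fraction * nCis`, windows
#' shuffled); remaining cis windows are pure background. Deterministic
#' given the spec's seed.
#'
#' @param spec a [synthSpec()] object.
#' @return list with `cnp`, `tnp` ([BondRegions-class]) and `truth`
#'   (data.frame `region_id`, `pattern`; `NA` pattern for background-only
#'   cis windows).
#' @export
generateSynthetic <- function(spec) {
  stopifnot(inherits(spec, "SynthSpec"))
  bg <- spec$background
  wl <- spec$windowLen
  withSeed(spec$seed, {
    planted <- spec$planted
    patStr <- vapply(planted, `[[`, character(1), "pattern")

    ## trans windows
    tseq <- sampleBackground(bg, spec$nTrans, wl)
    if (spec$clean && length(planted) && spec$nTrans) {
      for (iter in seq_len(1000L)) {
        bad <- rep(FALSE, length(tseq))
        for (p in patStr) bad <- bad | patternMatches(p, tseq)
        if (!any(bad)) break
        tseq[bad] <- sampleBackground(bg, sum(bad), wl)
        if (iter == 1000L) stop("rejection sampling failed: planted patterns too generic for a clean trans set")
      }
    }

    ## cis windows: background first, motifs written over
    cseq <- sampleBackground(bg, spec$nCis, wl)
    truthPat <- rep(NA_character_, spec$nCis)
    if (length(planted) && spec$nCis) {
      counts <- roundHalfUp(vapply(planted, `[[`, numeric(1), "fraction") * spec$nCis)
      counts <- pmin(counts, spec$nCis)
      while (sum(counts) > spec$nCis) counts[which.max(counts)] <- counts[which.max(counts)] - 1L
      slots <- sample.int(spec$nCis)  # shuffled window order
      pos <- 1L
      for (k in seq_along(planted)) {
        toks <- parsePattern(patStr[k])
        maxOff <- wl - length(toks) + 1L
        for (j in seq_len(counts[k])) {
          w <- slots[pos]; pos <- pos + 1L
          off <- sample.int(maxOff, 1L)
          inst <- instantiatePattern(toks, bg, spec$noise)
          s <- strsplit(cseq[w], "")[[1L]]
          s[off:(off + length(inst) - 1L)] <- inst
          cseq[w] <- paste(s, collapse = "")
          truthPat[w] <- patStr[k]
        }
      }
    }
    cnp <- BondRegions(cseq, "CIS",
                       region_id = if (spec$nCis) sprintf("cis%05d", seq_len(spec$nCis)) else NULL)
    tnp <- BondRegions(tseq, "TRANS",
                       region_id = if (spec$nTrans) sprintf("trans%06d", seq_len(spec$nTrans)) else NULL)
    list(cnp = cnp, tnp = tnp,
         truth = data.frame(region_id = regionIds(cnp), pattern = truthPat,
                            stringsAsFactors = FALSE))
  })
}
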
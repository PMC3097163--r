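## Maximal pattern discovery over equal-width residue windows.
##
## A pattern is a token sequence (literal / equivalency-class / wildcard)
## that never starts or ends with a wildcard. Discovery enumerates, by
## depth-first rightward extension of occurrence lists, every pattern with
## distinct-region support >= K, length <= W and >= L literals, then keeps
## only the maximal ones: a pattern is dropped iff some strictly more
## specific pattern (an element specialised, or the pattern extended at
## either end) matches exactly the same set of regions. Support-set
## equality is the whole maximality check because specialisation can only
## shrink the support set.

#' Discover maximal patterns in a set of regions
#'
#' TEIRESIAS-style enumeration: elementary single-symbol patterns above the
#' support threshold are progressively extended to the right with literals,
#' equivalency-class symbols and wildcards, pruning any branch whose
#' distinct-region support drops below `K`. Emitted patterns are then
#' reduced to the maximal ones. Support counts distinct regions (a region
#' counts once however many times a pattern occurs in it).
#'
#' @param regions a [BondRegions-class] object or character vector of
#'   equal-width residue windows.
#' @param W maximum pattern length (elements).
#' @param L minimum number of literals (non-wildcard elements; classes
#'   count).
#' @param K minimum support (distinct regions).
#' @param alphabet an [equivalencyAlphabet()] name or object; class symbols
#'   from its groups compete with literals, and maximality arbitrates.
#' @return a [PatternSet-class], ordered by descending support then
#'   lexicographic pattern.
#' @examples
#' discoverPatterns(c("ACDEF", "ACDGF"), W = 5, L = 3, K = 2)
#' @export
discoverPatterns <- function(regions, W = 11L, L = 3L, K = 2L,
                             alphabet = "none") {
  alphabet <- asAlphabet(alphabet)
  if (methods::is(regions, "BondRegions")) regions <- regionSequences(regions)
  stopifnot(L >= 1L, L <= W, K >= 1L)
  n <- length(regions)
  if (!n) return(PatternSet(character(), integer(), alphabet$name))
  chars <- strsplit(regions, "")
  lens <- nchar(regions)

  symbols <- c(as.list(AA_STANDARD), lapply(alphabetClassTokens(alphabet), identity))
  symSets <- lapply(symbols, function(s) tokenResidues(s))
  symTok <- unlist(symbols)

  ## per-region per-position symbol membership, precomputed once
  matchPos <- function(si, reg, pos) chars[[reg]][pos] %in% symSets[[si]]

  out_pat <- list(); out_reg <- list(); out_support <- integer()
  emitCount <- 0L

  extend <- function(toks, litCount, reg, pos, lastLit) {
    ## reg/pos: occurrence list (start positions) of the current prefix
    plen <- length(toks)
    if (lastLit && litCount >= L) {
      supportSet <- unique.default(reg)
      if (length(supportSet) >= K) {
        emitCount <<- emitCount + 1L
        out_pat[[emitCount]] <<- toks
        out_reg[[emitCount]] <<- supportSet
        out_support[[emitCount]] <<- length(supportSet)
      }
    }
    if (plen >= W) return(invisible())
    nxt <- pos + plen
    ok <- nxt <= lens[reg]
    if (!any(ok)) return(invisible())
    reg <- reg[ok]; pos <- pos[ok]; nxt <- nxt[ok]
    resAt <- vapply(seq_along(reg), function(j) chars[[reg[j]]][nxt[j]],
                    character(1))
    ## wildcard extension keeps every surviving occurrence; only useful if a
    ## literal can still follow within W
    if (plen + 1L < W && length(unique.default(reg)) >= K) {
      extend(c(toks, "."), litCount, reg, pos, FALSE)
    }
    for (si in seq_along(symbols)) {
      keep <- resAt %in% symSets[[si]]
      if (!any(keep)) next
      r2 <- reg[keep]
      if (length(unique.default(r2)) < K) next
      extend(c(toks, symTok[[si]]), litCount + 1L, r2, pos[keep], TRUE)
    }
    invisible()
  }

  ## seeds: every non-wildcard symbol at every position
  for (si in seq_along(symbols)) {
    occ_r <- integer(); occ_p <- integer()
    for (r in seq_len(n)) {
      hits <- which(chars[[r]] %in% symSets[[si]])
      occ_r <- c(occ_r, rep.int(r, length(hits)))
      occ_p <- c(occ_p, hits)
    }
    if (length(unique.default(occ_r)) < K) next
    extend(symTok[[si]], 1L, occ_r, occ_p, TRUE)
  }

  if (!emitCount) return(PatternSet(character(), integer(), alphabet$name))
  keep <- maximalityFilter(out_pat[seq_len(emitCount)],
                           out_reg[seq_len(emitCount)])
  pat <- vapply(out_pat[keep], serializePattern, character(1))
  sup <- out_support[keep]
  ord <- order(-sup, pat, method = "radix")
  PatternSet(pat[ord], sup[ord], alphabet$name)
}

## keep indices of patterns not strictly refined by another pattern with the
## same support set
maximalityFilter <- function(tokList, regSets) {
  masks <- lapply(tokList, function(tk) vapply(tk, tokenMask, integer(1),
                                               USE.NAMES = FALSE))
  key <- vapply(regSets, function(s) paste(sort(s), collapse = ","),
                character(1))
  keep <- rep(TRUE, length(tokList))
  for (grp in split(seq_along(tokList), key)) {
    if (length(grp) < 2L) next
    for (i in grp) {
      for (j in grp) {
        if (i != j && patternRefines(masks[[j]], masks[[i]], strict = TRUE)) {
          keep[i] <- FALSE
          break
        }
      }
    }
  }
  keep
}

#' Exhaustive-enumeration discovery oracle
#'
#' Same contract as [discoverPatterns()], computed the slow transparent
#' way: every candidate pattern is generated from the windows themselves
#' (at each aligned position the options are the residue, any equivalency
#' class containing it, or the wildcard), its support is recomputed by
#' regex matching, and non-maximal patterns are removed by pairwise
#' subsumption. Intended as an independent test oracle on tiny instances;
#' refuses instances whose candidate space is too large.
#'
#' @inheritParams discoverPatterns
#' @param maxCandidates refuse to run above this candidate-pattern count.
#' @return a [PatternSet-class], ordered as [discoverPatterns()].
#' @export
bruteForceDiscover <- function(regions, W = 11L, L = 3L, K = 2L,
                               alphabet = "none", maxCandidates = 3e5) {
  alphabet <- asAlphabet(alphabet)
  if (methods::is(regions, "BondRegions")) regions <- regionSequences(regions)
  n <- length(regions)
  if (!n) return(PatternSet(character(), integer(), alphabet$name))
  if (n > 8L || max(nchar(regions)) > 9L) {
    stop("bruteForceDiscover is an oracle for tiny instances only")
  }
  classTok <- alphabetClassTokens(alphabet)
  classOf <- function(res) classTok[vapply(alphabet$groups,
                                           function(g) res %in% g, logical(1))]
  cands <- new.env(parent = emptyenv())
  total <- 0L
  for (r in seq_len(n)) {
    cs <- strsplit(regions[[r]], "")[[1L]]
    len <- length(cs)
    for (off in seq_len(len)) {
      for (plen in seq_len(min(W, len - off + 1L))) {
        opts <- lapply(seq_len(plen), function(k) {
          res <- cs[off + k - 1L]
          o <- c(res, classOf(res))
          if (k > 1L && k < plen) o <- c(o, ".")
          o
        })
        grid <- expand.grid(opts, stringsAsFactors = FALSE)
        lits <- rowSums(grid != ".")
        grid <- grid[lits >= L, , drop = FALSE]
        if (!nrow(grid)) next
        total <- total + nrow(grid)
        if (total > maxCandidates) stop("candidate space too large for oracle")
        ser <- do.call(paste0, grid)
        for (s in ser) assign(s, TRUE, envir = cands)
      }
    }
  }
  pat <- ls(cands)
  if (!length(pat)) return(PatternSet(character(), integer(), alphabet$name))
  sets <- lapply(pat, function(p) which(patternMatches(p, regions)))
  sup <- lengths(sets)
  ok <- sup >= K
  pat <- pat[ok]; sets <- sets[ok]; sup <- sup[ok]
  if (!length(pat)) return(PatternSet(character(), integer(), alphabet$name))

  ## subsumption: drop p if a strictly more specific q has the same support set
  toksets <- lapply(pat, function(p) lapply(parsePattern(p), tokenResidues))
  key <- vapply(sets, paste, character(1), collapse = ",")
  moreSpecific <- function(q, p) {  # q refines p?
    nq <- length(q); np <- length(p)
    if (np > nq) return(FALSE)
    for (d in 0:(nq - np)) {
      seg <- q[(d + 1L):(d + np)]
      sub <- all(vapply(seq_len(np),
                        function(k) all(seg[[k]] %in% p[[k]]), logical(1)))
      if (sub) {
        strict <- nq > np || any(vapply(seq_len(np), function(k)
          length(seg[[k]]) < length(p[[k]]), logical(1)))
        if (strict) return(TRUE)
      }
    }
    FALSE
  }
  keep <- rep(TRUE, length(pat))
  for (grp in split(seq_along(pat), key)) {
    if (length(grp) < 2L) next
    for (i in grp) for (j in grp) {
      if (i != j && moreSpecific(toksets[[j]], toksets[[i]])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  pat <- pat[keep]; sup <- sup[keep]
  ord <- order(-sup, pat, method = "radix")
  PatternSet(pat[ord], sup[ord], alphabet$name)
}
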
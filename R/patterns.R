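## Pattern tokens: a pattern is an ordered vector of element tokens,
## each one of  "A"  (literal),  "[DE]"  (character class, sorted members),
## "[^DE]"  (negated class, motif libraries only)  or  "."  (wildcard).

#' The 20 standard amino-acid one-letter codes
#'
#' Alphabetical vector of the standard residue letters used throughout the
#' package (pattern wildcards range over exactly this set).
#'
#' @export
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Parse a pattern string into element tokens
#'
#' Splits a PROSITE-like pattern string into its elements: single uppercase
#' letters (literals), bracketed character classes such as `[DE]`, negated
#' classes such as `[^DE]`, and the `.` wildcard. Class members are
#' canonicalised to sorted order so that parsing and serialisation
#' round-trip.
#'
#' @param x a single pattern string, e.g. `"G.[AG][DE].K..SL"`.
#' @param allowNegation accept `[^..]` classes (used for motif libraries;
#'   discovery patterns never contain them).
#' @return character vector of element tokens.
#' @examples
#' parsePattern("G.[AG][DE].K..SL")
#' @export
parsePattern <- function(x, allowNegation = FALSE) {
  stopifnot(is.character(x), length(x) == 1L, !is.na(x), nzchar(x))
  rx <- "\\[\\^?[A-Z]+\\]|\\.|[A-Z]"
  m <- gregexpr(rx, x, perl = TRUE)[[1L]]
  toks <- regmatches(x, list(m))[[1L]]
  if (sum(nchar(toks)) != nchar(x)) {
    stop("unsupported pattern syntax in ", sQuote(x))
  }
  toks <- vapply(toks, canonicalToken, character(1), USE.NAMES = FALSE)
  if (!allowNegation && any(startsWith(toks, "[^"))) {
    stop("negated classes are not allowed here: ", sQuote(x))
  }
  toks
}

canonicalToken <- function(tok) {
  if (tok == "." || nchar(tok) == 1L) return(tok)
  neg <- startsWith(tok, "[^")
  body <- gsub("[][^]", "", tok)
  letters <- sort(unique(strsplit(body, "")[[1L]]))
  if (length(letters) < 1L) stop("empty character class")
  paste0(if (neg) "[^" else "[", paste(letters, collapse = ""), "]")
}

#' Serialise pattern tokens back to a string
#' @param tokens character vector of element tokens.
#' @return single pattern string.
#' @export
serializePattern <- function(tokens) paste(tokens, collapse = "")

#' Residues allowed by one pattern element
#'
#' @param tok a single element token.
#' @param letters the full residue alphabet (wildcards and negations range
#'   over this set).
#' @return character vector of allowed residue letters.
#' @export
tokenResidues <- function(tok, letters = AA_STANDARD) {
  if (tok == ".") return(letters)
  if (nchar(tok) == 1L) return(tok)
  body <- strsplit(gsub("[][^]", "", tok), "")[[1L]]
  if (startsWith(tok, "[^")) setdiff(letters, body) else body
}

## bitmask over `letters` for fast subset tests during maximality filtering
tokenMask <- function(tok, letters = AA_STANDARD) {
  idx <- match(tokenResidues(tok, letters), letters)
  sum(bitwShiftL(1L, idx - 1L))
}

#' Number of literal (non-wildcard) elements in a pattern
#'
#' Literals in the discovery sense: single residues and character classes
#' both count; only the `.` wildcard does not.
#'
#' @param x pattern string or token vector.
#' @return integer count.
#' @export
patternLiteralCount <- function(x) {
  toks <- if (length(x) == 1L && !identical(x, ".")) parsePattern(x, allowNegation = TRUE) else x
  sum(toks != ".")
}

#' Compile a pattern to a regular expression
#'
#' The element tokens are already valid PCRE pieces, so compilation is a
#' concatenation; matching is substring matching (no anchors).
#'
#' @param x pattern string or token vector.
#' @return single regex string.
#' @export
patternToRegex <- function(x) {
  toks <- if (length(x) == 1L) parsePattern(x, allowNegation = TRUE) else x
  paste(toks, collapse = "")
}

#' Match a pattern against sequences
#'
#' Substring semantics: `TRUE` for a sequence iff the pattern matches at
#' some offset. A pattern longer than the sequence simply does not match.
#'
#' @param pattern pattern string or token vector.
#' @param sequences character vector of residue strings (or a
#'   [BondRegions] object).
#' @return logical vector, one element per sequence.
#' @examples
#' patternMatches("YFT...I", c("YFTAAAIGGGG", "YFTAAIGGGGG"))
#' @export
patternMatches <- function(pattern, sequences) {
  if (methods::is(sequences, "BondRegions")) sequences <- regionSequences(sequences)
  grepl(patternToRegex(pattern), sequences, perl = TRUE)
}

## TRUE iff pattern `q` (tokens) is the same as or more specific than `p`:
## p occurs contiguously inside q with every aligned q element's residue set
## a subset of p's. Strict refinement additionally requires q != p.
patternRefines <- function(qMasks, pMasks, strict = TRUE) {
  nq <- length(qMasks); np <- length(pMasks)
  if (np > nq) return(FALSE)
  for (d in 0:(nq - np)) {
    seg <- qMasks[(d + 1L):(d + np)]
    if (all(bitwAnd(pMasks, seg) == seg)) {
      if (!strict || nq > np || any(seg != pMasks)) return(TRUE)
    }
  }
  FALSE
}
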
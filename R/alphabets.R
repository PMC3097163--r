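#' Residue equivalency alphabets for pattern discovery
#'
#' Returns the groups of residues treated as interchangeable during
#' discovery. The chemical grouping collects residues with similar side
#' chain chemistry; the structural grouping collects residues with similar
#' backbone/steric behaviour. Residues outside every group (e.g. P and W
#' under the chemical alphabet) can only appear as literals.
#'
#' @param name one of `"none"`, `"chemical"`, `"structural"`.
#' @return an object of class `EquivalencyAlphabet`: a list with elements
#'   `name` and `groups` (a possibly empty list of character vectors,
#'   pairwise disjoint).
#' @examples
#' equivalencyAlphabet("chemical")$groups
#' @export
equivalencyAlphabet <- function(name = c("none", "chemical", "structural")) {
  name <- match.arg(name)
  groups <- switch(name,
    none = list(),
    chemical = lapply(c("AG", "DE", "FY", "KR", "ILMV", "QN", "ST"),
                      function(s) sort(strsplit(s, "")[[1L]])),
    structural = lapply(c("CS", "DLN", "EQ", "FHWY", "ITV", "KMR"),
                        function(s) sort(strsplit(s, "")[[1L]]))
  )
  all <- unlist(groups)
  if (anyDuplicated(all)) {
    stop("equivalency groups must be pairwise disjoint")
  }
  structure(list(name = name, groups = groups), class = "EquivalencyAlphabet")
}

asAlphabet <- function(alphabet) {
  if (inherits(alphabet, "EquivalencyAlphabet")) {
    all <- unlist(alphabet$groups)
    if (anyDuplicated(all)) stop("equivalency groups must be pairwise disjoint")
    return(alphabet)
  }
  equivalencyAlphabet(alphabet)
}

## class tokens ("[AG]" etc.) for an alphabet
alphabetClassTokens <- function(alphabet) {
  vapply(alphabet$groups,
         function(g) paste0("[", paste(g, collapse = ""), "]"),
         character(1))
}

#' @export
print.EquivalencyAlphabet <- function(x, ...) {
  cat("EquivalencyAlphabet:", x$name, "\n")
  if (length(x$groups)) {
    cat(" ", paste(alphabetClassTokens(x), collapse = " "), "\n")
  }
  invisible(x)
}
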
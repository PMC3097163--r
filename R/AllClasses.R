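#' Labelled peptide-bond sequence windows
#'
#' An S4 container for fixed-width residue windows centred on a peptide
#' bond, each labelled `CIS` or `TRANS`, with provenance (source chain and
#' 1-based centre position). All windows in one object have equal width.
#'
#' @slot region_id character, unique identifiers.
#' @slot label character, `"CIS"` or `"TRANS"` per window.
#' @slot sequence character, residue strings of equal width.
#' @slot protein_id character, source chain identifier (`NA` for synthetic
#'   or anonymous windows).
#' @slot center_index integer, 1-based position of the bond-bearing residue
#'   in the source chain (`NA` when not applicable).
#' @export
setClass("BondRegions",
  representation(region_id = "character", label = "character",
                 sequence = "character", protein_id = "character",
                 center_index = "integer"),
  prototype(region_id = character(), label = character(),
            sequence = character(), protein_id = character(),
            center_index = integer()))

setValidity("BondRegions", function(object) {
  n <- length(object@region_id)
  if (length(object@label) != n || length(object@sequence) != n ||
      length(object@protein_id) != n || length(object@center_index) != n)
    return("slot lengths differ")
  if (anyDuplicated(object@region_id))
    return("region_id values must be unique")
  if (n && !all(object@label %in% c("CIS", "TRANS")))
    return("label must be CIS or TRANS")
  w <- unique(nchar(object@sequence))
  if (length(w) > 1L)
    return("all window sequences must have equal width")
  TRUE
})

#' Construct a BondRegions object
#'
#' @param sequence character vector of equal-width residue windows.
#' @param label `"CIS"`/`"TRANS"`, recycled if scalar.
#' @param region_id identifiers; autogenerated when `NULL`.
#' @param protein_id,center_index provenance, recycled; may be `NA`.
#' @return a [BondRegions-class] object.
#' @examples
#' BondRegions(c("QADEATKLMNS", "YFTAAAIGGGG"), label = "CIS")
#' @export
BondRegions <- function(sequence, label, region_id = NULL,
                        protein_id = NA_character_, center_index = NA_integer_) {
  n <- length(sequence)
  if (is.null(region_id)) {
    region_id <- if (n) sprintf("R%05d", seq_len(n)) else character()
  }
  methods::new("BondRegions",
    region_id = as.character(region_id),
    label = rep_len(as.character(label), n),
    sequence = as.character(sequence),
    protein_id = rep_len(as.character(protein_id), n),
    center_index = rep_len(as.integer(center_index), n))
}

#' A set of discovered patterns with their support
#'
#' Ordered collection of serialised patterns and the number of distinct
#' regions each one matches.
#'
#' @slot pattern character, serialised patterns.
#' @slot support integer, distinct-region support counts.
#' @slot alphabet character, name of the equivalency alphabet used.
#' @export
setClass("PatternSet",
  representation(pattern = "character", support = "integer",
                 alphabet = "character"),
  prototype(pattern = character(), support = integer(), alphabet = "none"))

setValidity("PatternSet", function(object) {
  if (length(object@pattern) != length(object@support))
    return("pattern and support lengths differ")
  if (anyDuplicated(object@pattern))
    return("patterns must be unique")
  if (length(object@support) && any(object@support < 1L))
    return("support must be >= 1")
  TRUE
})

#' Construct a PatternSet
#' @param pattern character vector of serialised patterns.
#' @param support integer vector of distinct-region support counts.
#' @param alphabet equivalency alphabet name used during discovery.
#' @return a [PatternSet-class] object.
#' @export
PatternSet <- function(pattern, support = rep(1L, length(pattern)),
                       alphabet = "none") {
  methods::new("PatternSet", pattern = as.character(pattern),
               support = as.integer(support), alphabet = alphabet)
}

#' Markov background model over residue strings
#'
#' Order 0, 1 or 2 Markov model of protein sequence, with conditional
#' residue probabilities for each context length up to the order (lower
#' order tables serve the first positions of a string).
#'
#' @slot order integer, 0/1/2.
#' @slot letters character, model alphabet.
#' @slot p0 numeric named vector, marginal residue probabilities.
#' @slot p1 matrix `[prev, cur]` (order >= 1, else 0x0).
#' @slot p2 array `[prev2, prev1, cur]` (order 2, else empty).
#' @export
setClass("MarkovBackground",
  representation(order = "integer", letters = "character",
                 p0 = "numeric", p1 = "matrix", p2 = "array"))

setValidity("MarkovBackground", function(object) {
  if (!object@order %in% 0:2) return("order must be 0, 1 or 2")
  tol <- 1e-9
  if (abs(sum(object@p0) - 1) > tol) return("p0 must sum to 1")
  if (object@order >= 1L && any(abs(rowSums(object@p1) - 1) > tol))
    return("p1 rows must sum to 1")
  if (object@order >= 2L &&
      any(abs(apply(object@p2, c(1, 2), sum) - 1) > tol))
    return("p2 conditional distributions must sum to 1")
  TRUE
})

#' Result of greedy non-redundant pattern selection
#'
#' Patterns retained in processing order, the unique region-to-pattern
#' assignment (each region claimed by at most one pattern), and the
#' resulting coverage and false discovery rate percentages.
#'
#' @slot retained data.frame with columns `pattern`, `c`, `t`, `sc_score`,
#'   `claimed_cis`, `claimed_trans`.
#' @slot assignment data.frame with columns `region_id`, `label`, `pattern`.
#' @slot coverage_pct numeric, 100 * claimed CIS regions / |CNP|.
#' @slot fdr_pct numeric, 100 * claimed TRANS regions / |TNP|.
#' @slot n_cnp,n_tnp integer dataset sizes.
#' @export
setClass("SelectionResult",
  representation(retained = "data.frame", assignment = "data.frame",
                 coverage_pct = "numeric", fdr_pct = "numeric",
                 n_cnp = "integer", n_tnp = "integer"))

setValidity("SelectionResult", function(object) {
  if (anyDuplicated(object@assignment$region_id))
    return("each region may be assigned to at most one pattern")
  TRUE
})
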
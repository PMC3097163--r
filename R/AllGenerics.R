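#' @export
setGeneric("regionIds", function(x) standardGeneric("regionIds"))
#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))
#' @export
setGeneric("regionSequences", function(x) standardGeneric("regionSequences"))
#' @export
setGeneric("patterns", function(x) standardGeneric("patterns"))
#' @export
setGeneric("patternSupport", function(x) standardGeneric("patternSupport"))
#' @export
setGeneric("retainedPatterns", function(x) standardGeneric("retainedPatterns"))
#' @export
setGeneric("assignmentTable", function(x) standardGeneric("assignmentTable"))
#' @export
setGeneric("coveragePct", function(x) standardGeneric("coveragePct"))
#' @export
setGeneric("fdrPct", function(x) standardGeneric("fdrPct"))

#' Accessors for BondRegions
#'
#' @param x a [BondRegions-class] object.
#' @return `regionIds`, `regionLabels`, `regionSequences` return character
#'   vectors; `length` the number of windows.
#' @name BondRegions-accessors
#' @aliases regionIds regionLabels regionSequences
NULL

#' @rdname BondRegions-accessors
#' @export
setMethod("regionIds", "BondRegions", function(x) x@region_id)
#' @rdname BondRegions-accessors
#' @export
setMethod("regionLabels", "BondRegions", function(x) x@label)
#' @rdname BondRegions-accessors
#' @export
setMethod("regionSequences", "BondRegions", function(x) x@sequence)

#' @export
setMethod("length", "BondRegions", function(x) length(x@region_id))

#' @export
setMethod("[", "BondRegions", function(x, i, j, ..., drop = TRUE) {
  methods::new("BondRegions", region_id = x@region_id[i], label = x@label[i],
               sequence = x@sequence[i], protein_id = x@protein_id[i],
               center_index = x@center_index[i])
})

#' @export
setMethod("show", "BondRegions", function(object) {
  n <- length(object)
  w <- if (n) nchar(object@sequence[1L]) else NA_integer_
  cat(sprintf("BondRegions: %d window(s), width %s (%d CIS, %d TRANS)\n",
              n, ifelse(is.na(w), "-", w),
              sum(object@label == "CIS"), sum(object@label == "TRANS")))
  if (n) {
    k <- min(n, 5L)
    for (i in seq_len(k)) {
      cat(sprintf("  %s  %-5s %s\n", object@region_id[i], object@label[i],
                  object@sequence[i]))
    }
    if (n > k) cat("  ...\n")
  }
  invisible(NULL)
})

#' Convert BondRegions to a data.frame
#' @param x a [BondRegions-class] object.
#' @param ... unused.
#' @export
setMethod("as.data.frame", "BondRegions", function(x, ...) {
  data.frame(region_id = x@region_id, label = x@label, sequence = x@sequence,
             protein_id = x@protein_id, center_index = x@center_index,
             stringsAsFactors = FALSE)
})

#' Accessors for PatternSet
#'
#' @param x a [PatternSet-class] object.
#' @name PatternSet-accessors
#' @aliases patterns patternSupport
NULL

#' @rdname PatternSet-accessors
#' @export
setMethod("patterns", "PatternSet", function(x) x@pattern)
#' @rdname PatternSet-accessors
#' @export
setMethod("patternSupport", "PatternSet", function(x) {
  stats::setNames(x@support, x@pattern)
})

#' @export
setMethod("length", "PatternSet", function(x) length(x@pattern))

#' @export
setMethod("[", "PatternSet", function(x, i, j, ..., drop = TRUE) {
  methods::new("PatternSet", pattern = x@pattern[i], support = x@support[i],
               alphabet = x@alphabet)
})

#' @export
setMethod("show", "PatternSet", function(object) {
  cat(sprintf("PatternSet: %d pattern(s), alphabet '%s'\n",
              length(object), object@alphabet))
  k <- min(length(object), 8L)
  for (i in seq_len(k)) {
    cat(sprintf("  %-20s support %d\n", object@pattern[i], object@support[i]))
  }
  if (length(object) > k) cat("  ...\n")
  invisible(NULL)
})

#' @export
setMethod("as.data.frame", "PatternSet", function(x, ...) {
  data.frame(pattern = x@pattern, support = x@support, stringsAsFactors = FALSE)
})

#' Accessors for SelectionResult
#'
#' @param x a [SelectionResult-class] object.
#' @return `retainedPatterns` the retained-pattern data.frame;
#'   `assignmentTable` the unique region-to-pattern assignment;
#'   `coveragePct`/`fdrPct` the percentages.
#' @name SelectionResult-accessors
#' @aliases retainedPatterns assignmentTable coveragePct fdrPct
NULL

#' @rdname SelectionResult-accessors
#' @export
setMethod("retainedPatterns", "SelectionResult", function(x) x@retained)
#' @rdname SelectionResult-accessors
#' @export
setMethod("assignmentTable", "SelectionResult", function(x) x@assignment)
#' @rdname SelectionResult-accessors
#' @export
setMethod("coveragePct", "SelectionResult", function(x) x@coverage_pct)
#' @rdname SelectionResult-accessors
#' @export
setMethod("fdrPct", "SelectionResult", function(x) x@fdr_pct)

#' @export
setMethod("show", "SelectionResult", function(object) {
  cat(sprintf(paste0("SelectionResult: %d retained pattern(s); ",
                     "coverage %.2f%% of %d CIS, FDR %.4f%% of %d TRANS\n"),
              nrow(object@retained), object@coverage_pct, object@n_cnp,
              object@fdr_pct, object@n_tnp))
  invisible(NULL)
})

#' @export
setMethod("show", "MarkovBackground", function(object) {
  cat(sprintf("MarkovBackground: order %d over %d letters\n",
              object@order, length(object@letters)))
  invisible(NULL)
})
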
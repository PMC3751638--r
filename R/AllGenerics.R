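#' Accessors for TagLibrary and TssProfile
#'
#' `tagPositions()` returns the `GRanges` of tag positions; `totalCount()`
#' the number of tags (the denominator of tags-per-million normalization);
#' `sampleId()`, `sampleCondition()` and `tagRole()` the library's identity;
#' `profileTable()` a `data.frame` view of a [TssProfile].
#'
#' @param x a `TagLibrary` (or `TssProfile` for `profileTable`).
#' @return see the individual descriptions.
#' @examples
#' lib <- TagLibrary(tags = GenomicRanges::GRanges("chr1",
#'   IRanges::IRanges(100, width = 1), strand = "+"))
#' totalCount(lib)
#' @name tag-accessors
NULL

#' @rdname tag-accessors
#' @export
setGeneric("tagPositions", function(x) standardGeneric("tagPositions"))
#' @rdname tag-accessors
#' @export
setMethod("tagPositions", "TagLibrary", function(x) x@tags)

#' @rdname tag-accessors
#' @export
setGeneric("totalCount", function(x) standardGeneric("totalCount"))
#' @rdname tag-accessors
#' @export
setMethod("totalCount", "TagLibrary", function(x) length(x@tags))

#' @rdname tag-accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @rdname tag-accessors
#' @export
setMethod("sampleId", "TagLibrary", function(x) x@sampleId)

#' @rdname tag-accessors
#' @export
setGeneric("sampleCondition", function(x) standardGeneric("sampleCondition"))
#' @rdname tag-accessors
#' @export
setMethod("sampleCondition", "TagLibrary", function(x) x@condition)

#' @rdname tag-accessors
#' @export
setGeneric("tagRole", function(x) standardGeneric("tagRole"))
#' @rdname tag-accessors
#' @export
setMethod("tagRole", "TagLibrary", function(x) x@role)

#' @rdname tag-accessors
#' @export
setGeneric("profileTable", function(x) standardGeneric("profileTable"))
#' @rdname tag-accessors
#' @export
setMethod("profileTable", "TssProfile", function(x) {
  data.frame(bin_start = x@binStart,
             bin_end = x@binStart + x@binwidth,
             count = x@counts,
             density_per_million = x@density)
})
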
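#' @rdname totalBases
#' @export
setGeneric("totalBases", function(x) standardGeneric("totalBases"))

#' @rdname accessors
#' @export
setGeneric("targetRanges", function(x) standardGeneric("targetRanges"))

#' @rdname accessors
#' @export
setGeneric("targetLabel", function(x) standardGeneric("targetLabel"))

#' @rdname accessors
#' @export
setGeneric("isMerged", function(x) standardGeneric("isMerged"))

#' @rdname accessors
#' @export
setGeneric("profileDepth", function(x) standardGeneric("profileDepth"))

#' @rdname accessors
#' @export
setGeneric("readRecords", function(x) standardGeneric("readRecords"))

#' @rdname accessors
#' @export
setGeneric("isDuplicate", function(x) standardGeneric("isDuplicate"))

#' @rdname accessors
#' @export
setGeneric("pileupCalls", function(x) standardGeneric("pileupCalls"))

#' @rdname accessors
#' @export
setGeneric("pileupPositions", function(x) standardGeneric("pileupPositions"))

#' @rdname accessors
#' @export
setGeneric("variantRecords", function(x) standardGeneric("variantRecords"))

#' @rdname accessors
#' @export
setGeneric("reaRecords", function(x) standardGeneric("reaRecords"))

#' @rdname accessors
#' @export
setGeneric("simParams", function(x) standardGeneric("simParams"))

#' @rdname accessors
#' @export
setGeneric("concordanceCells", function(x) standardGeneric("concordanceCells"))

#' @rdname accessors
#' @export
setGeneric("concordanceOverall", function(x) standardGeneric("concordanceOverall"))
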
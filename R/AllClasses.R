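#' @import methods
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
#' @importFrom GenomeInfoDb seqlevels seqlevels<- seqnames
#' @importFrom stats dbinom rbinom rnorm runif setNames
#' @importFrom utils read.delim write.table
NULL

#' TargetSet: a labelled set of capture target regions
#'
#' Container for the genomic footprint of a capture design (or any region
#' set, e.g. exon annotations).  Regions are held as a \link[GenomicRanges]{GRanges};
#' the \code{merged} flag records that the set has been reduced to sorted,
#' pairwise-disjoint, non-adjacent regions, which all set-algebra operations
#' require.
#'
#' @slot label single character design name (may be \code{NA}).
#' @slot ranges \code{GRanges} with the member regions.
#' @slot merged logical scalar; \code{TRUE} after \code{\link{mergeIntervals}}.
#' @aliases TargetSet-class
#' @exportClass TargetSet
setClass("TargetSet",
    slots = c(label = "character", ranges = "GRanges", merged = "logical"),
    prototype = prototype(label = NA_character_, merged = FALSE))

setValidity("TargetSet", function(object) {
    msg <- character()
    if (length(object@label) != 1L)
        msg <- c(msg, "'label' must be a single string")
    if (length(object@merged) != 1L || is.na(object@merged))
        msg <- c(msg, "'merged' must be TRUE or FALSE")
    if (isTRUE(object@merged) && length(object@ranges) > 0L) {
        red <- reduce(object@ranges, ignore.strand = TRUE)
        srt <- sort(object@ranges, ignore.strand = TRUE)
        if (length(red) != length(object@ranges) ||
            !identical(start(srt), start(object@ranges)))
            msg <- c(msg,
                "a merged TargetSet must be sorted with disjoint, non-adjacent regions")
    }
    if (length(msg)) msg else TRUE
})

#' CoverageProfile: per-base sequencing depth over a target set
#'
#' Depth of aligned, non-duplicate read bases at every base of a merged
#' \linkS4class{TargetSet}, stored as one integer vector in target order
#' (regions sorted by chromosome then start; bases left to right).  Zero-depth
#' bases are represented explicitly so the 0x coverage class is countable.
#'
#' @slot target merged \linkS4class{TargetSet} the profile is taken over.
#' @slot depth integer vector, one entry per target base.
#' @aliases CoverageProfile-class
#' @exportClass CoverageProfile
setClass("CoverageProfile",
    slots = c(target = "TargetSet", depth = "integer"))

setValidity("CoverageProfile", function(object) {
    msg <- character()
    if (!isTRUE(object@target@merged))
        msg <- c(msg, "'target' must be merged")
    if (length(object@depth) != sum(width(object@target@ranges)))
        msg <- c(msg, "'depth' length must equal totalBases(target)")
    if (length(object@depth) && any(object@depth < 0L, na.rm = TRUE))
        msg <- c(msg, "'depth' must be non-negative")
    if (length(msg)) msg else TRUE
})

#' AlignedReadSet: aligned paired-end reads
#'
#' Lightweight container for aligned reads as consumed by the pileup engine,
#' duplicate marking, REA detection and the capture metrics.  One row per
#' read; mates are linked through \code{qname}.  Sequences are stored in
#' reference (forward-strand) orientation, qualities as Sanger Phred+33
#' strings, exactly as in a SAM file.
#'
#' @slot reads \code{DataFrame} with columns \code{qname}, \code{mate} (1 or
#'   2), \code{chrom}, \code{pos} (1-based leftmost aligned position),
#'   \code{strand}, \code{cigar}, \code{seq}, \code{qual},
#'   \code{mateChrom}, \code{matePos}, \code{mateStrand},
#'   \code{isDuplicate}.
#' @slot seqlengths named integer vector of reference sequence lengths.
#' @aliases AlignedReadSet-class
#' @exportClass AlignedReadSet
setClass("AlignedReadSet",
    slots = c(reads = "DFrame", seqlengths = "integer"))

.ars_cols <- c("qname", "mate", "chrom", "pos", "strand", "cigar", "seq",
    "qual", "mateChrom", "matePos", "mateStrand", "isDuplicate")

setValidity("AlignedReadSet", function(object) {
    miss <- setdiff(.ars_cols, colnames(object@reads))
    if (length(miss))
        return(paste("missing read columns:", paste(miss, collapse = ", ")))
    if (nrow(object@reads) &&
        any(nchar(object@reads$seq) != nchar(object@reads$qual)))
        return("seq and qual lengths differ")
    TRUE
})

#' PileupTable: per-position, per-read base calls
#'
#' Result of \code{\link{buildPileup}}.  \code{positions} lists every emitted
#' column (including zero-depth columns when positions were requested
#' explicitly); \code{calls} holds one row per aligned read base, keyed into
#' \code{positions} by \code{posIndex}.  Soft-clipped bases contribute no
#' call but their sequence is recorded on the boundary call of the read.
#'
#' @slot positions \code{DataFrame}: \code{chrom}, \code{pos} (1-based),
#'   \code{ref}.
#' @slot calls \code{DataFrame}: \code{posIndex}, \code{readId}, \code{base},
#'   \code{qual} (numeric allele quality), \code{startsHere},
#'   \code{endsHere}, \code{softclip} (\code{NA} when none).
#' @aliases PileupTable-class
#' @exportClass PileupTable
setClass("PileupTable",
    slots = c(positions = "DFrame", calls = "DFrame"))

#' VariantCalls: quality-ratio recalled SNVs
#'
#' @slot calls \code{DataFrame}: \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt}, \code{depth}, \code{variantQuality}, \code{qualityRatio},
#'   \code{genotype} (e.g. \code{"A/G"}), \code{genotypeClass} (one of
#'   \code{reference}, \code{heterozygous}, \code{homozygous_variant},
#'   \code{multiallelic}).
#' @aliases VariantCalls-class
#' @exportClass VariantCalls
setClass("VariantCalls", slots = c(calls = "DFrame"))

#' ReaCalls: read-end anomalies
#'
#' @slot calls \code{DataFrame}: \code{chrom}, \code{pos}, \code{side}
#'   (\code{"start"} or \code{"end"}), \code{support}, \code{depth},
#'   \code{fraction}, \code{softclips} (\code{CharacterList} of clip
#'   sequences from supporting reads).
#' @aliases ReaCalls-class
#' @exportClass ReaCalls
setClass("ReaCalls", slots = c(calls = "DFrame"))

#' ConcordanceTable: sequencing vs SNP-chip genotype agreement
#'
#' @slot cells \code{DataFrame}: \code{bin}, \code{chipClass},
#'   \code{concordant}, \code{discordant}, \code{correlation}.
#' @slot overall \code{DataFrame}: \code{bin}, \code{n}, \code{concordant},
#'   \code{discordant}, \code{correlation}.
#' @slot uncallable integer count of chip SNPs with no sequence coverage.
#' @aliases ConcordanceTable-class
#' @exportClass ConcordanceTable
setClass("ConcordanceTable",
    slots = c(cells = "DFrame", overall = "DFrame", uncallable = "integer"))

#' SimConfig: parameters of the synthetic capture experiment
#'
#' Created by \code{\link{simConfig}}; see that constructor for the meaning,
#' units and defaults of every field.
#'
#' @slot params named list of generator parameters.
#' @aliases SimConfig-class
#' @exportClass SimConfig
setClass("SimConfig", slots = c(params = "list"))

setValidity("SimConfig", function(object) {
    p <- object@params
    msg <- character()
    frac <- c("hetFraction", "referenceBias", "duplicateRate", "offTargetRate",
        "bTailRate", "chipDiscordanceRate", "chipMinusStrandFraction",
        "chipLowCallRateFraction", "chipMultiMapFraction")
    for (f in frac)
        if (p[[f]] < 0 || p[[f]] > 1)
            msg <- c(msg, sprintf("'%s' must be in [0, 1]", f))
    if (p$readLength < 36L)
        msg <- c(msg, "'readLength' must be >= 36")
    if (p$meanDepth <= 0)
        msg <- c(msg, "'meanDepth' must be > 0")
    if (is.null(names(p$chromLengths)) || any(p$chromLengths < 1000))
        msg <- c(msg, "'chromLengths' must be named and >= 1000")
    if (length(msg)) msg else TRUE
})
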
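#' @importFrom GenomicAlignments cigarWidthAlongReferenceSpace
#'   cigarRangesAlongReferenceSpace cigarRangesAlongQuerySpace
#'   explodeCigarOps explodeCigarOpLengths
#' @importFrom Rsamtools asBam scanBam ScanBamParam scanBamHeader
NULL

#' Construct an AlignedReadSet
#'
#' @param reads A \code{data.frame} or \code{DataFrame} with the columns
#'   documented in \linkS4class{AlignedReadSet}; \code{mateChrom},
#'   \code{matePos}, \code{mateStrand} and \code{isDuplicate} are filled
#'   with defaults when absent.
#' @param seqlengths Named integer vector of reference lengths.
#' @return An \linkS4class{AlignedReadSet}.
#' @export
AlignedReadSet <- function(reads, seqlengths = integer()) {
    df <- as(as.data.frame(reads, stringsAsFactors = FALSE), "DataFrame")
    n <- nrow(df)
    if (is.null(df$mateChrom)) df$mateChrom <- rep(NA_character_, n)
    if (is.null(df$matePos)) df$matePos <- rep(NA_integer_, n)
    if (is.null(df$mateStrand)) df$mateStrand <- rep(NA_character_, n)
    if (is.null(df$isDuplicate)) df$isDuplicate <- rep(FALSE, n)
    df$pos <- as.integer(df$pos)
    df$mate <- as.integer(df$mate)
    new("AlignedReadSet", reads = df[, .ars_cols],
        seqlengths = setNames(as.integer(seqlengths), names(seqlengths)))
}

#' @rdname accessors
#' @export
setMethod("readRecords", "AlignedReadSet", function(x) x@reads)

#' @rdname accessors
#' @export
setMethod("isDuplicate", "AlignedReadSet", function(x) x@reads$isDuplicate)

#' @rdname accessors
#' @export
setMethod("length", "AlignedReadSet", function(x) nrow(x@reads))

setMethod("show", "AlignedReadSet", function(object) {
    cat(sprintf(
        "AlignedReadSet: %d read(s), %d fragment(s), %d flagged duplicate\n",
        nrow(object@reads), length(unique(object@reads$qname)),
        sum(object@reads$isDuplicate)))
})

# 1-based inclusive [alignedStart, alignedEnd] span of each read (M/=/X and
# D ops consume reference; soft clips do not shift the boundary).
.alignedSpan <- function(ars) {
    df <- ars@reads
    w <- cigarWidthAlongReferenceSpace(df$cigar)
    data.frame(chrom = df$chrom, start = df$pos, end = df$pos + w - 1L,
        strand = df$strand)
}

# Aligned (M/=/X) blocks of every read with reference and query coordinates.
# Returns data.frame(readIdx, chrom, refStart, refEnd, qStart).
.alignedBlocks <- function(ars, dropDuplicates = TRUE) {
    df <- ars@reads
    idx <- seq_len(nrow(df))
    if (dropDuplicates) idx <- idx[!df$isDuplicate]
    if (!length(idx))
        return(data.frame(readIdx = integer(), chrom = character(),
            refStart = integer(), refEnd = integer(), qStart = integer()))
    cig <- df$cigar[idx]
    refR <- cigarRangesAlongReferenceSpace(cig, pos = df$pos[idx],
        ops = c("M", "=", "X"))
    qryR <- cigarRangesAlongQuerySpace(cig, ops = c("M", "=", "X"))
    n <- elementNROWS(refR)
    refU <- unlist(refR, use.names = FALSE)
    qryU <- unlist(qryR, use.names = FALSE)
    ri <- rep(idx, n)
    data.frame(readIdx = ri, chrom = df$chrom[ri],
        refStart = start(refU), refEnd = end(refU), qStart = start(qryU))
}

# Leading / trailing soft-clip lengths per cigar.
.softClips <- function(cigar) {
    ops <- explodeCigarOps(cigar)
    lens <- explodeCigarOpLengths(cigar)
    lead <- mapply(function(o, l) if (length(o) && o[1L] == "S") l[1L] else 0L,
        ops, lens)
    trail <- mapply(function(o, l) {
        k <- length(o)
        if (k && o[k] == "S") l[k] else 0L
    }, ops, lens)
    data.frame(lead = as.integer(lead), trail = as.integer(trail))
}

#' Mark PCR duplicate fragments
#'
#' Fragments are grouped by chromosome, fragment outer coordinates and
#' orientation; in every group larger than one, all pairs except the one
#' with the highest summed base quality are flagged (ties broken by read
#' name, deterministically).  Flagged reads are excluded by the pileup,
#' variant, REA and depth machinery.
#'
#' @param ars An \linkS4class{AlignedReadSet} with paired reads.
#' @param mode \code{"outer"} (default): key on both fragment ends plus
#'   orientation; \code{"leftmost"}: key on the leftmost coordinate and
#'   orientation only.
#' @return The \linkS4class{AlignedReadSet} with \code{isDuplicate} set.
#' @export
markDuplicates <- function(ars, mode = c("outer", "leftmost")) {
    mode <- match.arg(mode)
    df <- ars@reads
    if (!nrow(df)) return(ars)
    span <- .alignedSpan(ars)

    # per-read summed base quality via one pass over concatenated strings
    allq <- utf8ToInt(paste(df$qual, collapse = "")) - 33L
    ends <- cumsum(nchar(df$qual))
    cq <- cumsum(as.numeric(allq))
    readScore <- cq[ends] - c(0, cq[head(ends, -1L)])

    # fragment grouping: reads sorted by (qname, start, mate); fragments
    # are read pairs (or singletons) sharing a qname
    qf <- factor(df$qname)
    o <- order(qf, span$start, df$mate)
    gid <- as.integer(qf)[o]
    first <- o[!duplicated(gid)]
    last <- o[!duplicated(gid, fromLast = TRUE)]
    if (any(df$chrom[first] != df$chrom[last]))
        stop("inconsistent mate information (mates on different ",
            "chromosomes): ",
            df$qname[first][df$chrom[first] != df$chrom[last]][1L])
    outerStart <- span$start[first]
    outerEnd <- pmax(span$end[first], span$end[last])
    orient <- paste0(span$strand[first], span$strand[last])
    key <- if (mode == "outer")
        paste(df$chrom[first], outerStart, outerEnd, orient, sep = ":")
    else paste(df$chrom[first], outerStart, orient, sep = ":")
    fragScore <- as.numeric(rowsum(readScore, as.integer(qf)))
    fragName <- levels(qf)

    # within each key keep the best-scoring fragment (ties: first by name)
    ord <- order(key, -fragScore, fragName)
    dupFrag <- logical(length(key))
    dupFrag[ord] <- duplicated(key[ord])
    df$isDuplicate <- dupFrag[as.integer(qf)]
    initialize(ars, reads = df)
}

.samFlag <- function(df) {
    paired <- !is.na(df$matePos)
    flag <- ifelse(paired, 1L, 0L)
    flag <- flag + ifelse(df$strand == "-", 16L, 0L)
    flag <- flag + ifelse(paired & !is.na(df$mateStrand) &
        df$mateStrand == "-", 32L, 0L)
    flag <- flag + ifelse(paired & df$mate == 1L, 64L, 0L)
    flag <- flag + ifelse(paired & df$mate == 2L, 128L, 0L)
    flag + ifelse(df$isDuplicate, 1024L, 0L)
}

#' Write an AlignedReadSet as a SAM file
#'
#' Emits a coordinate-unsorted text SAM with \code{@SQ} header lines from
#' the set's \code{seqlengths}; the duplicate flag is written as SAM flag
#' bit 0x400.
#'
#' @param ars An \linkS4class{AlignedReadSet}.
#' @param path Output path.
#' @export
writeSam <- function(ars, path) {
    df <- ars@reads
    sl <- ars@seqlengths
    hdr <- c("@HD\tVN:1.6",
        sprintf("@SQ\tSN:%s\tLN:%d", names(sl), sl))
    flag <- .samFlag(df)
    rnext <- ifelse(is.na(df$mateChrom), "*",
        ifelse(df$mateChrom == df$chrom, "=", df$mateChrom))
    pnext <- ifelse(is.na(df$matePos), 0L, df$matePos)
    lines <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t%s\t%d\t0\t%s\t%s",
        df$qname, flag, df$chrom, df$pos, df$cigar, rnext, pnext,
        df$seq, df$qual)
    writeLines(c(hdr, lines), path)
    invisible(path)
}

#' Read a SAM file into an AlignedReadSet
#'
#' The SAM is converted to BAM in a temporary location and scanned with
#' Rsamtools; strand, mate and duplicate information are decoded from the
#' SAM flag.  Note the reads come back coordinate sorted.
#'
#' @param path SAM path.
#' @return An \linkS4class{AlignedReadSet}.
#' @export
readSam <- function(path) {
    bam <- suppressMessages(asBam(path, tempfile(), overwrite = TRUE,
        indexDestination = FALSE))
    hdr <- scanBamHeader(bam)[[1L]]$targets
    res <- scanBam(bam, param = ScanBamParam(what = c("qname", "flag",
        "rname", "strand", "pos", "cigar", "seq", "qual", "mrnm",
        "mpos")))[[1L]]
    flag <- res$flag
    paired <- bitwAnd(flag, 1L) > 0L
    df <- DataFrame(
        qname = res$qname,
        mate = ifelse(!paired, 0L, ifelse(bitwAnd(flag, 64L) > 0L, 1L, 2L)),
        chrom = as.character(res$rname),
        pos = res$pos,
        strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
        cigar = res$cigar,
        seq = as.character(res$seq),
        qual = as.character(res$qual),
        mateChrom = ifelse(paired, as.character(res$mrnm), NA_character_),
        matePos = ifelse(paired, res$mpos, NA_integer_),
        mateStrand = ifelse(paired,
            ifelse(bitwAnd(flag, 32L) > 0L, "-", "+"), NA_character_),
        isDuplicate = bitwAnd(flag, 1024L) > 0L)
    new("AlignedReadSet", reads = df,
        seqlengths = setNames(as.integer(hdr), names(hdr)))
}
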
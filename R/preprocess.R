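#' @importFrom Biostrings DNAStringSet BStringSet QualityScaledDNAStringSet
#'   PhredQuality quality readQualityScaledDNAStringSet writeXStringSet
#'   reverseComplement letterFrequency
#' @importFrom XVector subseq
NULL

.qOffset <- c(phred33 = 33L, phred64 = 64L)

#' Convert between FASTQ quality encodings
#'
#' Shifts the character offset of a quality string between Sanger Phred+33
#' and Illumina Phred+64; the numeric scores are unchanged, so converting
#' there and back is the identity.
#'
#' @param qual Character vector of per-read quality strings.
#' @param from,to \code{"phred33"} or \code{"phred64"}.
#' @param ids Optional read ids used in error messages.
#' @return Character vector of re-encoded quality strings.
#' @examples
#' convertQuality("hh", "phred64", "phred33")  # "II" (Q40)
#' @export
convertQuality <- function(qual, from = c("phred64", "phred33"),
                           to = c("phred33", "phred64"), ids = NULL) {
    from <- match.arg(from); to <- match.arg(to)
    offF <- .qOffset[[from]]; offT <- .qOffset[[to]]
    vapply(seq_along(qual), function(i) {
        v <- utf8ToInt(qual[[i]]) - offF
        if (any(v < 0 | v > 62)) {
            p <- which(v < 0 | v > 62)[1L]
            id <- if (is.null(ids)) i else ids[[i]]
            stop(sprintf(
                "quality character outside %s range in read %s, position %d",
                from, id, p))
        }
        intToUtf8(v + offT)
    }, character(1L))
}

.qualInts <- function(x) as(quality(x), "IntegerList")

#' Trim trailing B blocks from reads
#'
#' Removes the maximal trailing run of bases whose quality equals the Q2
#' read-segment marker (the \code{'B'} character of Phred+64 FASTQ, \code{'#'}
#' in Phred+33) from the end of each read.  Bases and qualities are
#' shortened together; internal Q2 runs are untouched.  The operation is
#' idempotent, and a fully-marked read becomes length 0 (to be removed by the
#' pair length filter).
#'
#' @param x A \code{QualityScaledDNAStringSet} (Phred scale).
#' @param q2 The marker quality score (default 2).
#' @return The trimmed \code{QualityScaledDNAStringSet}.
#' @export
trimBBlocks <- function(x, q2 = 2L) {
    q <- .qualInts(x)
    keep <- vapply(q, function(v) {
        n <- length(v)
        while (n > 0L && v[n] == q2) n <- n - 1L
        n
    }, integer(1L))
    subseq(x, 1L, keep)
}

#' Trim reads to a fixed length
#'
#' Keeps the first \code{min(n, length)} bases and qualities of each read.
#'
#' @param x A \code{QualityScaledDNAStringSet}.
#' @param n Maximum read length (>= 1).
#' @export
trimToLength <- function(x, n) {
    if (n < 1L) stop("'n' must be >= 1")
    subseq(x, 1L, pmin(width(x), as.integer(n)))
}

#' Pair length filter
#'
#' A read pair is dropped when either mate is shorter than \code{minLen}
#' bases; both mates always share the verdict.  A (36, 36) pair is kept:
#' 36 is not shorter than 36.
#'
#' @param r1,r2 Mate-1 and mate-2 \code{QualityScaledDNAStringSet}s
#'   (parallel order).
#' @param minLen Minimum mate length (default 36).
#' @return Logical keep vector, one entry per pair.
#' @export
filterShortPairs <- function(r1, r2, minLen = 36L) {
    stopifnot(length(r1) == length(r2))
    width(r1) >= minLen & width(r2) >= minLen
}

#' Run the fixed read-cleanup pipeline on a read pair set
#'
#' Applies, in this order: fixed-length trimming (when \code{trimTo} is
#' given, before any other action), B-block trimming, and the pair length
#' filter.  This order is fixed; reads must be quality-converted to the
#' Phred+33 scale on input (see \code{\link{readFastqReads}}).
#'
#' @param r1,r2 Mate \code{QualityScaledDNAStringSet}s.
#' @param trimTo Optional fixed length applied first.
#' @param minLen Pair length filter threshold (default 36).
#' @return List with trimmed, filtered \code{r1}, \code{r2}, the logical
#'   \code{keep} vector and counts \code{nIn}/\code{nKept}.
#' @export
preprocessReads <- function(r1, r2, trimTo = NULL, minLen = 36L) {
    stopifnot(length(r1) == length(r2))
    if (!is.null(trimTo)) {
        r1 <- trimToLength(r1, trimTo)
        r2 <- trimToLength(r2, trimTo)
    }
    r1 <- trimBBlocks(r1)
    r2 <- trimBBlocks(r2)
    keep <- filterShortPairs(r1, r2, minLen = minLen)
    list(r1 = r1[keep], r2 = r2[keep], keep = keep,
        nIn = length(keep), nKept = sum(keep))
}

#' Read a FASTQ file into quality-scaled reads
#'
#' @param path FASTQ path.
#' @param encoding \code{"phred33"} (Sanger) or \code{"phred64"}
#'   (Illumina 1.3--1.7).  Scores are decoded accordingly; downstream the
#'   package always works on the Phred scale.
#' @return A \code{QualityScaledDNAStringSet}.
#' @export
readFastqReads <- function(path, encoding = c("phred33", "phred64")) {
    encoding <- match.arg(encoding)
    scoring <- if (encoding == "phred33") "phred" else "illumina"
    x <- suppressWarnings(
        readQualityScaledDNAStringSet(path, quality.scoring = scoring))
    if (encoding == "phred64") {
        # normalize to the Sanger Phred+33 container used package-wide
        ints <- as(quality(x), "IntegerList")
        q33 <- PhredQuality(vapply(ints, function(v)
            intToUtf8(v + 33L), character(1L)))
        seqs <- suppressWarnings(DNAStringSet(x))
        names(seqs) <- names(x)
        x <- QualityScaledDNAStringSet(seqs, q33)
    }
    x
}

#' Write quality-scaled reads as FASTQ
#'
#' @param x A \code{QualityScaledDNAStringSet} (Phred-scale qualities).
#' @param path Output path.
#' @param encoding Output encoding (offset 33 or 64).
#' @export
writeFastqReads <- function(x, path, encoding = c("phred33", "phred64")) {
    encoding <- match.arg(encoding)
    off <- .qOffset[[encoding]]
    qual <- vapply(as(quality(x), "IntegerList"), function(v)
        if (length(v)) intToUtf8(v + off) else "", character(1L))
    seqs <- suppressWarnings(DNAStringSet(x))
    names(seqs) <- names(x)
    writeXStringSet(seqs, path, format = "fastq", qualities = BStringSet(qual))
    invisible(path)
}

#' Seeded downsampling of read pairs or aligned fragments
#'
#' Sampling is by fragment: for FASTQ pairs both mates are kept together,
#' and for an \linkS4class{AlignedReadSet} all reads of a sampled fragment
#' (same \code{qname}) are retained.  The same seed always yields the same
#' subset.
#'
#' @param x A list with elements \code{r1}, \code{r2}
#'   (\code{QualityScaledDNAStringSet}s) or an \linkS4class{AlignedReadSet}.
#' @param n Number of fragments to keep (<= available fragments).
#' @param seed Integer seed.
#' @return Object of the same shape as \code{x}.
#' @export
downsampleReads <- function(x, n, seed) {
    if (is(x, "AlignedReadSet")) {
        frags <- unique(x@reads$qname)
        if (n > length(frags))
            stop("'n' exceeds the number of available fragments")
        keepQ <- .withSeed(seed, sample(frags, n))
        return(new("AlignedReadSet",
            reads = x@reads[x@reads$qname %in% keepQ, , drop = FALSE],
            seqlengths = x@seqlengths))
    }
    stopifnot(is.list(x), length(x$r1) == length(x$r2))
    if (n > length(x$r1))
        stop("'n' exceeds the number of available fragments")
    idx <- .withSeed(seed, sort(sample(length(x$r1), n)))
    list(r1 = x$r1[idx], r2 = x$r2[idx])
}

# Evaluate expr under a local RNG state seeded with `seed`.
.withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv()))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    expr
}
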
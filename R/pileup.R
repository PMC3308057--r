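#' Build a per-position pileup from aligned reads
#'
#' For every covered position (or every requested position) the pileup
#' records one call per overlapping, non-duplicate read: the called base,
#' its allele quality (the base Phred quality), whether the read's aligned
#' span starts or ends at the column, and any soft-clipped sequence hanging
#' off that boundary.  Soft-clipped and deleted bases contribute no call;
#' duplicate-flagged reads are excluded throughout.
#'
#' @param ars An \linkS4class{AlignedReadSet} (duplicates flagged).
#' @param reference Named \code{DNAStringSet} of reference chromosomes.
#' @param at Optional \code{data.frame(chrom, pos)} restricting the pileup
#'   to those positions; requested positions with no coverage are emitted
#'   with depth 0.
#' @param minBaseQuality Drop calls below this Phred quality (default 0,
#'   i.e. no floor).
#' @param includeDuplicates Keep duplicate-flagged reads (default
#'   \code{FALSE}).
#' @return A \linkS4class{PileupTable}.
#' @export
buildPileup <- function(ars, reference, at = NULL, minBaseQuality = 0,
                        includeDuplicates = FALSE) {
    df <- ars@reads
    if (nrow(df) && !all(df$chrom %in% names(reference)))
        stop("read aligned to unknown chromosome: ",
            setdiff(df$chrom, names(reference))[1L])
    blocks <- .alignedBlocks(ars, dropDuplicates = !includeDuplicates)

    if (is.null(at)) {
        if (nrow(blocks)) {
            n <- blocks$refEnd - blocks$refStart + 1L
            callPos <- unlist(mapply(seq.int, blocks$refStart, blocks$refEnd,
                SIMPLIFY = FALSE), use.names = FALSE)
            bIdx <- rep(seq_len(nrow(blocks)), n)
        } else {
            callPos <- integer(); bIdx <- integer()
        }
        posTab <- unique(data.frame(chrom = blocks$chrom[bIdx],
            pos = callPos))
        posTab <- posTab[order(posTab$chrom, posTab$pos), , drop = FALSE]
    } else {
        posTab <- unique(data.frame(chrom = as.character(at$chrom),
            pos = as.integer(at$pos)))
        posTab <- posTab[order(posTab$chrom, posTab$pos), , drop = FALSE]
        if (nrow(blocks)) {
            bgr <- GRanges(blocks$chrom,
                IRanges(blocks$refStart, blocks$refEnd))
            pgr <- GRanges(posTab$chrom, IRanges(posTab$pos, posTab$pos))
            hits <- findOverlaps(bgr, pgr)
            bIdx <- queryHits(hits)
            callPos <- posTab$pos[subjectHits(hits)]
        } else {
            bIdx <- integer(); callPos <- integer()
        }
    }
    rownames(posTab) <- NULL

    readIdx <- blocks$readIdx[bIdx]
    qOff <- blocks$qStart[bIdx] + (callPos - blocks$refStart[bIdx])

    # per-call base and quality via global offsets into concatenated strings
    seqcat <- paste(df$seq, collapse = "")
    qualcat <- paste(df$qual, collapse = "")
    lens <- nchar(df$seq)
    starts0 <- cumsum(c(0L, lens))[seq_len(nrow(df))]
    gOff <- starts0[readIdx] + qOff
    base <- substring(seqcat, gOff, gOff)
    qual <- utf8ToInt(qualcat)[gOff] - 33L
    if (!length(gOff)) qual <- numeric(0)

    # read boundary flags and soft-clip sequences
    aggStart <- tapply(blocks$refStart, blocks$readIdx, min)
    aggEnd <- tapply(blocks$refEnd, blocks$readIdx, max)
    aStart <- as.integer(aggStart[as.character(readIdx)])
    aEnd <- as.integer(aggEnd[as.character(readIdx)])
    startsHere <- callPos == aStart
    endsHere <- callPos == aEnd
    clips <- .softClips(df$cigar)
    sc <- rep(NA_character_, length(readIdx))
    if (length(readIdx)) {
        leadClip <- clips$lead[readIdx]
        trailClip <- clips$trail[readIdx]
        iL <- which(startsHere & leadClip > 0L)
        sc[iL] <- substring(df$seq[readIdx[iL]], 1L, leadClip[iL])
        iT <- which(endsHere & trailClip > 0L)
        scT <- substring(df$seq[readIdx[iT]],
            lens[readIdx[iT]] - trailClip[iT] + 1L, lens[readIdx[iT]])
        sc[iT] <- ifelse(is.na(sc[iT]), scT, paste(sc[iT], scT, sep = ";"))
    }

    keep <- if (length(qual)) qual >= minBaseQuality else logical(0)
    posKey <- paste(posTab$chrom, posTab$pos)
    posIndex <- match(paste(blocks$chrom[bIdx], callPos), posKey)[keep]

    refBase <- character(nrow(posTab))
    for (ch in unique(posTab$chrom)) {
        i <- which(posTab$chrom == ch)
        refBase[i] <- strsplit(as.character(Biostrings::extractAt(
            reference[[ch]],
            IRanges(min(posTab$pos[i]), max(posTab$pos[i]))))[[1]], "")[[1]][
                posTab$pos[i] - min(posTab$pos[i]) + 1L]
    }

    positions <- DataFrame(chrom = posTab$chrom, pos = posTab$pos,
        ref = refBase)
    calls <- DataFrame(
        posIndex = posIndex,
        readId = paste0(df$qname[readIdx[keep]], "/", df$mate[readIdx[keep]]),
        base = base[keep],
        qual = as.numeric(qual[keep]),
        startsHere = startsHere[keep],
        endsHere = endsHere[keep],
        softclip = sc[keep])
    o <- order(calls$posIndex)
    new("PileupTable", positions = positions, calls = calls[o, , drop = FALSE])
}

#' @rdname accessors
#' @export
setMethod("pileupCalls", "PileupTable", function(x) x@calls)

#' @rdname accessors
#' @export
setMethod("pileupPositions", "PileupTable", function(x) x@positions)

setMethod("show", "PileupTable", function(object) {
    cat(sprintf("PileupTable: %d column(s), %d call(s)\n",
        nrow(object@positions), nrow(object@calls)))
})

#' Summarize pileup columns
#'
#' @param pt A \linkS4class{PileupTable}.
#' @return \code{data.frame} with \code{chrom}, \code{pos}, \code{ref} and
#'   \code{depth} (number of calls) per emitted column.
#' @export
pileupColumns <- function(pt) {
    depth <- tabulate(pt@calls$posIndex, nbins = nrow(pt@positions))
    data.frame(chrom = pt@positions$chrom, pos = pt@positions$pos,
        ref = pt@positions$ref, depth = depth)
}

#' Write a pileup as a samtools-like TSV
#'
#' Basic columns are chrom, pos, ref, depth, call bases and Phred+33
#' qualities; \code{extended} adds per-column read-start/read-end counts and
#' the soft-clip sequences.
#'
#' @param pt A \linkS4class{PileupTable}.
#' @param path Output path.
#' @param extended Add boundary/soft-clip columns.
#' @export
writePileupTsv <- function(pt, path, extended = FALSE) {
    cols <- pileupColumns(pt)
    calls <- pt@calls
    grp <- factor(calls$posIndex, levels = seq_len(nrow(cols)))
    bases <- vapply(split(calls$base, grp), paste, character(1L),
        collapse = "")
    quals <- vapply(split(intToUtf8(calls$qual + 33L, multiple = TRUE), grp),
        paste, character(1L), collapse = "")
    out <- cbind(cols, bases = bases, quals = quals)
    if (extended) {
        out$nStart <- vapply(split(calls$startsHere, grp), sum, numeric(1L))
        out$nEnd <- vapply(split(calls$endsHere, grp), sum, numeric(1L))
        out$softclips <- vapply(split(calls$softclip, grp), function(s)
            paste(s[!is.na(s)], collapse = ";"), character(1L))
    }
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

.covRle <- function(ars, includeDuplicates = FALSE) {
    blocks <- .alignedBlocks(ars, dropDuplicates = !includeDuplicates)
    if (!nrow(blocks)) return(RleList(compress = TRUE))
    coverage(GRanges(blocks$chrom, IRanges(blocks$refStart, blocks$refEnd)))
}

#' Depth profile over a target set
#'
#' Depth at each target base is the number of aligned (match/mismatch)
#' bases of non-duplicate reads covering it: soft clips and spanned
#' deletions do not count.
#'
#' @param ars An \linkS4class{AlignedReadSet}.
#' @param target A merged \linkS4class{TargetSet}.
#' @param includeDuplicates Keep duplicate-flagged reads.
#' @return A \linkS4class{CoverageProfile}.
#' @export
depthProfile <- function(ars, target, includeDuplicates = FALSE) {
    .checkMerged(target)
    cov <- .covRle(ars, includeDuplicates)
    gr <- .asGR(target)
    depth <- integer(0)
    for (i in seq_along(gr)) {
        ch <- as.character(seqnames(gr))[i]
        s <- start(gr)[i]; e <- end(gr)[i]
        if (ch %in% names(cov)) {
            r <- cov[[ch]]
            avail <- min(e, length(r))
            d <- if (s <= avail) as.integer(window(r, s, avail)) else integer(0)
            d <- c(d, integer(e - s + 1L - length(d)))
        } else d <- integer(e - s + 1L)
        depth <- c(depth, d)
    }
    new("CoverageProfile", target = target, depth = depth)
}

#' @rdname accessors
#' @export
setMethod("profileDepth", "CoverageProfile", function(x) x@depth)

#' @rdname totalBases
#' @export
setMethod("totalBases", "CoverageProfile", function(x) length(x@depth))

setMethod("show", "CoverageProfile", function(object) {
    cat(sprintf("CoverageProfile over %d bp, mean depth %.2f\n",
        length(object@depth), mean(object@depth)))
})

#' Depth lookup at positions of a coverage profile
#'
#' @param profile A \linkS4class{CoverageProfile}.
#' @param chrom,pos Parallel vectors of 1-based positions.
#' @return Integer depths; \code{NA} for positions outside the profiled
#'   target.
#' @export
profileDepthAt <- function(profile, chrom, pos) {
    gr <- .asGR(profile@target)
    offsets <- cumsum(c(0L, width(gr)))[seq_along(gr)]
    pgr <- GRanges(chrom, IRanges(pos, pos))
    hits <- findOverlaps(pgr, gr)
    out <- rep(NA_integer_, length(pgr))
    i <- queryHits(hits); j <- subjectHits(hits)
    out[i] <- profile@depth[offsets[j] + (pos[i] - start(gr)[j]) + 1L]
    out
}

#' Write a coverage profile as bedGraph
#'
#' @param profile A \linkS4class{CoverageProfile}.
#' @param path Output path.
#' @export
writeProfileBedGraph <- function(profile, path) {
    gr <- .asGR(profile@target)
    pieces <- lapply(seq_along(gr), function(i) {
        w <- width(gr)[i]
        off <- cumsum(c(0L, width(gr)))[i]
        d <- profile@depth[off + seq_len(w)]
        r <- rle(d)
        ends <- cumsum(r$lengths)
        data.frame(chrom = as.character(seqnames(gr))[i],
            start = start(gr)[i] - 1L + c(0L, head(ends, -1L)),
            end = start(gr)[i] - 1L + ends, score = r$values)
    })
    out <- do.call(rbind, pieces)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
        col.names = FALSE)
    invisible(path)
}
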
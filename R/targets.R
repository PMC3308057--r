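#' Construct a TargetSet
#'
#' @param intervals A \code{GRanges}, or a data frame with columns
#'   \code{chrom}, \code{start}, \code{end} and optionally \code{name} and
#'   \code{strand}.
#' @param label Optional design name.
#' @param zeroBased If \code{TRUE} (BED convention) data-frame starts are
#'   0-based and ends exclusive; internally everything is converted to the
#'   1-based closed \code{GRanges} convention.
#' @param merged Mark the set as already merged (validated).
#'
#' @details Malformed intervals (empty or negative width) raise an error
#'   naming the offending record.  Strand is carried but ignored by all set
#'   algebra.
#' @return A \linkS4class{TargetSet}.
#' @examples
#' ts <- TargetSet(data.frame(chrom = "chr1", start = 0, end = 10),
#'                 zeroBased = TRUE)
#' totalBases(mergeIntervals(ts))
#' @export
TargetSet <- function(intervals, label = NA_character_, zeroBased = FALSE,
                      merged = FALSE) {
    if (is(intervals, "GRanges")) {
        gr <- intervals
    } else {
        df <- as.data.frame(intervals)
        stopifnot(all(c("chrom", "start", "end") %in% colnames(df)))
        start1 <- if (zeroBased) df$start + 1L else df$start
        end1 <- df$end
        bad <- which(end1 < start1 | (zeroBased & df$start < 0))
        if (length(bad))
            stop(sprintf("malformed interval in record %d: %s:%s-%s",
                bad[1L], df$chrom[bad[1L]], df$start[bad[1L]], df$end[bad[1L]]))
        if (nrow(df) == 0L) {
            gr <- GRanges()
        } else {
            gr <- GRanges(df$chrom, IRanges(start1, end1),
                strand = if ("strand" %in% colnames(df)) df$strand else "*")
            if ("name" %in% colnames(df)) names(gr) <- df$name
        }
    }
    if (any(width(gr) < 1L))
        stop("malformed interval: empty range at record ",
            which(width(gr) < 1L)[1L])
    new("TargetSet", label = as.character(label), ranges = gr,
        merged = merged)
}

.asGR <- function(x) {
    if (is(x, "TargetSet")) x@ranges
    else if (is(x, "GRanges")) x
    else targetRanges(TargetSet(x))
}

.checkMerged <- function(x, what = "target set") {
    if (is(x, "TargetSet") && !isTRUE(x@merged))
        stop(what, " must be merged (see mergeIntervals())")
    invisible(TRUE)
}

#' @rdname totalBases
#' @param x A \linkS4class{TargetSet} or \linkS4class{CoverageProfile}.
#' @details For a merged set this is the number of distinct base pairs
#'   covered (the quantity reported as "base pairs covered" for a capture
#'   design).
#' @export
setMethod("totalBases", "TargetSet", function(x) sum(width(x@ranges)))

#' Accessors for capeval classes
#'
#' @param x An object of the documented class.
#' @name accessors
#' @rdname accessors
NULL

#' @rdname accessors
#' @export
setMethod("targetRanges", "TargetSet", function(x) x@ranges)

#' @rdname accessors
#' @export
setMethod("targetLabel", "TargetSet", function(x) x@label)

#' @rdname accessors
#' @export
setMethod("isMerged", "TargetSet", function(x) x@merged)

setMethod("show", "TargetSet", function(object) {
    cat(sprintf("TargetSet '%s': %d region(s), %d bp%s\n",
        object@label, length(object@ranges), totalBases(object),
        if (object@merged) ", merged" else ""))
})

#' @rdname accessors
#' @export
setMethod("length", "TargetSet", function(x) length(x@ranges))

#' Merge intervals into a non-redundant target set
#'
#' Reduces a collection of genomic intervals to their union: sorted,
#' pairwise disjoint regions.  Overlapping and abutting intervals (no gap
#' between them) are merged into one region; strand is discarded, so regions
#' are merged regardless of strandedness.
#'
#' @param x A \linkS4class{TargetSet}, \code{GRanges} or interval data frame
#'   (see \code{\link{TargetSet}}).
#' @param label Label for the result (defaults to the input's label).
#' @param zeroBased Passed to \code{\link{TargetSet}} for data-frame input.
#' @return A merged \linkS4class{TargetSet} covering exactly the union of the
#'   input base pairs.
#' @examples
#' ts <- mergeIntervals(data.frame(chrom = "chr1",
#'                                 start = c(0, 5), end = c(10, 15)),
#'                      zeroBased = TRUE)
#' totalBases(ts)  # 15, not 20
#' @export
mergeIntervals <- function(x, label = NA_character_, zeroBased = FALSE) {
    if (is(x, "TargetSet")) {
        if (is.na(label)) label <- x@label
        gr <- x@ranges
    } else if (is(x, "GRanges")) {
        gr <- x
    } else {
        gr <- targetRanges(TargetSet(x, zeroBased = zeroBased))
    }
    red <- reduce(gr, ignore.strand = TRUE)
    seqlevels(red) <- sort(seqlevels(red))
    red <- sort(red)
    new("TargetSet", label = as.character(label), ranges = red, merged = TRUE)
}

#' Per-interval overlap verdicts between two merged target sets
#'
#' A query region is "included" in the subject design when its intersection
#' with the subject totals at least \code{minBp} base pairs (default 1: the
#' one-base-pair-or-more rule used for design comparison).
#'
#' @param query,subject Merged \linkS4class{TargetSet}s.
#' @param minBp Minimum total overlap in base pairs (>= 1).
#' @return A \code{data.frame} with one row per query region: \code{chrom},
#'   \code{start}, \code{end} (1-based closed), \code{overlapBp},
#'   \code{included}.
#' @export
targetOverlaps <- function(query, subject, minBp = 1L) {
    if (minBp < 1L) stop("'minBp' must be >= 1")
    .checkMerged(query, "query"); .checkMerged(subject, "subject")
    q <- .asGR(query); s <- .asGR(subject)
    hits <- findOverlaps(q, s, ignore.strand = TRUE)
    ovw <- width(pintersect(q[queryHits(hits)], s[subjectHits(hits)],
        ignore.strand = TRUE))
    tot <- integer(length(q))
    if (length(hits)) {
        agg <- tapply(ovw, queryHits(hits), sum)
        tot[as.integer(names(agg))] <- as.integer(agg)
    }
    data.frame(chrom = as.character(seqnames(q)), start = start(q),
        end = end(q), overlapBp = tot, included = tot >= minBp)
}

#' Expand a target set by flanking bases
#'
#' Every region is expanded by \code{flankBp} on both sides (clamped at the
#' chromosome start) and the result re-merged, producing e.g. the
#' "CTR + flank" region when \code{flankBp = 100}.
#'
#' @param target A merged \linkS4class{TargetSet}.
#' @param flankBp Number of flanking bases (>= 0).
#' @return A merged \linkS4class{TargetSet}.
#' @export
addFlank <- function(target, flankBp) {
    if (flankBp < 0) stop("'flankBp' must be >= 0")
    .checkMerged(target)
    gr <- .asGR(target)
    if (flankBp == 0) return(mergeIntervals(gr, label = target@label))
    start(gr) <- pmax(1L, start(gr) - as.integer(flankBp))
    end(gr) <- end(gr) + as.integer(flankBp)
    mergeIntervals(gr, label = target@label)
}

#' Common target region of several capture designs
#'
#' Base-pair intersection across all designs: the region targeted by every
#' compared capture kit.
#'
#' @param designs List of at least two merged \linkS4class{TargetSet}s.
#' @param label Label for the result.
#' @return A merged \linkS4class{TargetSet} (possibly empty).
#' @export
commonTarget <- function(designs, label = "common") {
    if (length(designs) < 2L)
        stop("'designs' must contain at least two merged target sets")
    lapply(designs, .checkMerged, what = "design")
    grs <- lapply(designs, .asGR)
    common <- Reduce(function(a, b)
        GenomicRanges::intersect(a, b, ignore.strand = TRUE), grs)
    mergeIntervals(common, label = label)
}

#' Count query regions per design-membership pattern
#'
#' For each region of a combined query (annotation plus designs, pooled and
#' merged), records which designs include it under the
#' \code{\link{targetOverlaps}} rule and tabulates the membership patterns.
#' Patterns partition the query, so pattern counts sum to the number of
#' query regions.
#'
#' @param query Merged \linkS4class{TargetSet} (the combined query).
#' @param designs Named list of merged \linkS4class{TargetSet}s.
#' @param minBp Minimum overlap per design (default 1 bp).
#' @return A list with \code{membership} (logical matrix, regions x designs),
#'   \code{pattern} (character vector per region; design names joined by
#'   \code{"+"}, or \code{"none"}) and \code{counts} (data frame
#'   \code{pattern}, \code{n}).
#' @export
regionMembershipCounts <- function(query, designs, minBp = 1L) {
    stopifnot(length(designs) >= 1L, !is.null(names(designs)))
    .checkMerged(query, "query")
    mem <- vapply(designs, function(d)
        targetOverlaps(query, d, minBp = minBp)$included,
        logical(length(.asGR(query))))
    mem <- matrix(mem, nrow = length(.asGR(query)),
        dimnames = list(NULL, names(designs)))
    pattern <- apply(mem, 1L, function(r)
        if (!any(r)) "none" else paste(names(designs)[r], collapse = "+"))
    tab <- table(pattern)
    list(membership = mem, pattern = pattern,
        counts = data.frame(pattern = names(tab), n = as.integer(tab)))
}

.targetSeqs <- function(target, reference) {
    gr <- .asGR(target)
    chroms <- as.character(seqnames(gr))
    if (!all(chroms %in% names(reference)))
        stop("unknown chromosome: ",
            setdiff(chroms, names(reference))[1L])
    maxend <- width(reference)[match(chroms, names(reference))]
    if (any(end(gr) > maxend))
        stop("interval beyond chromosome end at record ",
            which(end(gr) > maxend)[1L])
    out <- vector("list", length(gr))
    for (ch in unique(chroms)) {
        i <- which(chroms == ch)
        out[i] <- as.list(Biostrings::extractAt(reference[[ch]],
            IRanges(start(gr)[i], end(gr)[i])))
    }
    as(Biostrings::DNAStringSet(out), "DNAStringSet")
}

#' Per-target and mean GC content
#'
#' GC fraction of each target region, computed over unambiguous bases only
#' (A/C/G/T, case-insensitive; Ns and other ambiguity codes are excluded
#' from the denominator).  The summary is the unweighted mean of per-target
#' fractions, i.e. the mean percentage of G and C bases in the targets;
#' \code{weighted = TRUE} switches to base-pair-weighted pooling.
#'
#' @param target A \linkS4class{TargetSet}.
#' @param reference Named \code{DNAStringSet}, one entry per chromosome.
#' @param weighted Pool G+C and A+C+G+T counts over all targets instead of
#'   averaging per-target fractions.
#' @param perTarget Return the per-target fractions instead of the summary.
#' @return Numeric scalar in [0, 1] (or a vector when \code{perTarget}).
#' @export
gcContent <- function(target, reference, weighted = FALSE,
                      perTarget = FALSE) {
    seqs <- .targetSeqs(target, reference)
    cnt <- Biostrings::letterFrequency(seqs, c("A", "C", "G", "T"))
    gc <- cnt[, "C"] + cnt[, "G"]
    denom <- rowSums(cnt)
    frac <- ifelse(denom > 0, gc / denom, NA_real_)
    if (perTarget) return(unname(frac))
    if (weighted) sum(gc) / sum(denom) else mean(frac, na.rm = TRUE)
}

#' Mean mapability over a target set
#'
#' Per-base mean of a mapability track (1.0 = the underlying k-mer matches
#' one place in the genome, 0.5 = two places, ...) over all target bases.
#'
#' @param target A merged \linkS4class{TargetSet}.
#' @param track \code{GRanges} with a numeric \code{score} column (e.g. from
#'   \code{\link{readBedGraph}}); overlapping track ranges are not allowed.
#' @param uncovered Policy for target bases missing from the track:
#'   \code{"error"} (default) or \code{"zero"} (score 0).
#' @return Mean mapability in [0, 1].
#' @export
meanMapability <- function(target, track, uncovered = c("error", "zero")) {
    uncovered <- match.arg(uncovered)
    .checkMerged(target)
    gr <- .asGR(target)
    if (!isDisjoint(track)) stop("mapability track has overlapping ranges")
    hits <- findOverlaps(gr, track, ignore.strand = TRUE)
    ovw <- width(pintersect(gr[queryHits(hits)], track[subjectHits(hits)],
        ignore.strand = TRUE))
    covered <- sum(ovw)
    total <- totalBases(target)
    if (covered < total && uncovered == "error")
        stop(sprintf("%d target base(s) not covered by the mapability track",
            total - covered))
    sum(ovw * track$score[subjectHits(hits)]) / total
}

#' Read BED3/BED6 regions
#'
#' @param path BED file (0-based half-open starts, as usual for BED).
#' @param label Design label for the resulting set.
#' @param merge Merge the regions after reading (default \code{TRUE}).
#' @return A \linkS4class{TargetSet}.
#' @export
readBed <- function(path, label = basename(path), merge = TRUE) {
    gr <- rtracklayer::import(path, format = "BED")
    ts <- TargetSet(gr, label = label)
    if (merge) mergeIntervals(ts) else ts
}

#' Write a target set as BED
#'
#' @param target A \linkS4class{TargetSet}.
#' @param path Output path.
#' @export
writeBed <- function(target, path) {
    gr <- .asGR(target)
    df <- data.frame(chrom = as.character(seqnames(gr)),
        start = start(gr) - 1L, end = end(gr),
        name = if (is.null(names(gr)))
            paste0("region_", seq_along(gr)) else names(gr))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
        col.names = FALSE)
    invisible(path)
}

#' Read a bedGraph score track
#'
#' @param path bedGraph file.
#' @return \code{GRanges} with a \code{score} column.
#' @export
readBedGraph <- function(path) {
    rtracklayer::import(path, format = "bedGraph")
}

#' Read transcript models from an exon table
#'
#' Expects a tab-separated file with columns \code{transcript_id},
#' \code{gene_id}, \code{chrom}, \code{start}, \code{end} (BED-style 0-based
#' starts).  Exons of a transcript must share one chromosome and be
#' non-overlapping; they are returned sorted.
#'
#' @param path TSV path.
#' @return A named \code{GRangesList}, one element per transcript, each with
#'   a \code{gene_id} metadata column.
#' @export
readExonTable <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    stopifnot(all(c("transcript_id", "gene_id", "chrom", "start", "end")
        %in% colnames(df)))
    transcriptModels(df$transcript_id, df$gene_id, df$chrom,
        df$start + 1L, df$end)
}

#' Build transcript models from vectors
#'
#' @param transcriptId,geneId,chrom Character vectors, one entry per exon.
#' @param start,end 1-based closed exon coordinates.
#' @return A named \code{GRangesList} of exons per transcript.
#' @export
transcriptModels <- function(transcriptId, geneId, chrom, start, end) {
    gr <- GRanges(chrom, IRanges(as.integer(start), as.integer(end)))
    mcols(gr)$gene_id <- geneId
    grl <- split(gr, transcriptId)
    grl <- endoapply(grl, sort)
    ok <- vapply(grl, function(g)
        length(unique(as.character(seqnames(g)))) == 1L && isDisjoint(g),
        logical(1L))
    if (!all(ok))
        stop("transcript(s) with multi-chromosome or overlapping exons: ",
            paste(names(grl)[!ok], collapse = ", "))
    grl
}
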
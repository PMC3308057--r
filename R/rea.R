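#' Detect read-end anomalies (REAs)
#'
#' A REA is a position where at least \code{minSupport} non-duplicate reads
#' share an identical aligned start (side \code{"start"}) or aligned end
#' (side \code{"end"}), contributing at least \code{minFraction} of the
#' total aligned-base coverage at that position.  Soft clips do not shift
#' the boundary; their sequences from supporting reads are attached to the
#' call.  Start-side and end-side calls at the same position are reported
#' separately.
#'
#' @param ars An \linkS4class{AlignedReadSet} with duplicates flagged
#'   (flagged reads never support or count).
#' @param minSupport Minimum boundary-sharing reads (default 5).
#' @param minFraction Minimum support / depth fraction (default 0.30).
#' @return A \linkS4class{ReaCalls}.
#' @export
detectReas <- function(ars, minSupport = 5L, minFraction = 0.30) {
    df <- ars@reads
    keep <- which(!df$isDuplicate)
    empty <- DataFrame(chrom = character(), pos = integer(),
        side = character(), support = integer(), depth = integer(),
        fraction = numeric(), softclips = CharacterList())
    if (!length(keep)) return(new("ReaCalls", calls = empty))
    span <- .alignedSpan(ars)[keep, , drop = FALSE]
    clips <- .softClips(df$cigar[keep])
    lens <- nchar(df$seq[keep])
    cov <- .covRle(ars)

    scanSide <- function(side) {
        bnd <- if (side == "start") span$start else span$end
        key <- paste(span$chrom, bnd)
        tab <- table(key)
        cand <- names(tab)[tab >= minSupport]
        if (!length(cand)) return(NULL)
        rows <- lapply(cand, function(k) {
            i <- which(key == k)
            ch <- span$chrom[i[1L]]; p <- bnd[i[1L]]
            depth <- if (ch %in% names(cov) && p <= length(cov[[ch]]))
                as.integer(cov[[ch]][p]) else 0L
            frac <- length(i) / depth
            if (frac < minFraction) return(NULL)
            sc <- if (side == "start") {
                j <- i[clips$lead[i] > 0L]
                substring(df$seq[keep][j], 1L, clips$lead[j])
            } else {
                j <- i[clips$trail[i] > 0L]
                substring(df$seq[keep][j], lens[j] - clips$trail[j] + 1L,
                    lens[j])
            }
            DataFrame(chrom = ch, pos = p, side = side,
                support = length(i), depth = depth, fraction = frac,
                softclips = CharacterList(list(sc)))
        })
        rows <- rows[!vapply(rows, is.null, logical(1L))]
        if (length(rows)) do.call(rbind, rows) else NULL
    }
    parts <- Filter(Negate(is.null), list(scanSide("start"),
        scanSide("end")))
    if (!length(parts)) return(new("ReaCalls", calls = empty))
    out <- do.call(rbind, parts)
    o <- order(out$chrom, out$pos, out$side)
    new("ReaCalls", calls = out[o, , drop = FALSE])
}

#' @rdname accessors
#' @export
setMethod("reaRecords", "ReaCalls", function(x) x@calls)

#' @rdname accessors
#' @export
setMethod("length", "ReaCalls", function(x) nrow(x@calls))

setMethod("show", "ReaCalls", function(object) {
    cat(sprintf("ReaCalls: %d call(s) (%d start-side, %d end-side)\n",
        nrow(object@calls), sum(object@calls$side == "start"),
        sum(object@calls$side == "end")))
})

#' Annotate REA calls with overlapping tracks
#'
#' Labels each call with every named track (e.g. known copy-number-variant
#' regions) containing its position.
#'
#' @param calls A \linkS4class{ReaCalls}.
#' @param tracks Named list of merged \linkS4class{TargetSet}s.
#' @return The \linkS4class{ReaCalls} with one logical column per track and
#'   a \code{labels} column (comma-joined track names, \code{""} if none).
#' @export
annotateReas <- function(calls, tracks) {
    df <- calls@calls
    if (length(tracks) && is.null(names(tracks)))
        stop("'tracks' must be named")
    pgr <- GRanges(df$chrom, IRanges(df$pos, df$pos))
    hitmat <- matrix(FALSE, nrow(df), length(tracks),
        dimnames = list(NULL, names(tracks)))
    for (nm in names(tracks)) {
        .checkMerged(tracks[[nm]], paste0("track '", nm, "'"))
        hitmat[, nm] <- overlapsAny(pgr, .asGR(tracks[[nm]]))
        df[[nm]] <- hitmat[, nm]
    }
    df$labels <- if (length(tracks)) apply(hitmat, 1L, function(r)
        paste(colnames(hitmat)[r], collapse = ",")) else
        character(nrow(df))
    new("ReaCalls", calls = df)
}

#' Write REA calls as TSV
#'
#' @param calls A \linkS4class{ReaCalls}.
#' @param path Output path.
#' @export
writeReas <- function(calls, path) {
    df <- as.data.frame(calls@calls[, setdiff(colnames(calls@calls),
        "softclips")])
    df$softclips <- vapply(calls@calls$softclips, paste, character(1L),
        collapse = ";")
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
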
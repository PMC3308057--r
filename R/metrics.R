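#' Fraction of reads aligned to a target region
#'
#' A read counts as on-target when its aligned span overlaps the target by
#' at least one base pair (\code{mode = "contain"} requires full
#' containment).  By default all reads, duplicates included, form the
#' denominator, matching the convention of reporting the on-target
#' percentage of high-quality reads before duplicate removal; set
#' \code{includeDuplicates = FALSE} for the duplicate-excluded variant.
#'
#' @param ars An \linkS4class{AlignedReadSet}.
#' @param target A merged \linkS4class{TargetSet}.
#' @param includeDuplicates Keep duplicate-flagged reads (default
#'   \code{TRUE}).
#' @param mode \code{"overlap"} (>= 1 bp, default) or \code{"contain"}.
#' @return Fraction in [0, 1].
#' @export
onTargetFraction <- function(ars, target, includeDuplicates = TRUE,
                             mode = c("overlap", "contain")) {
    mode <- match.arg(mode)
    .checkMerged(target)
    df <- ars@reads
    if (!includeDuplicates) df <- df[!df$isDuplicate, , drop = FALSE]
    if (!nrow(df)) stop("no reads: on-target fraction undefined")
    sub <- new("AlignedReadSet", reads = df, seqlengths = ars@seqlengths)
    span <- .alignedSpan(sub)
    rgr <- GRanges(span$chrom, IRanges(span$start, span$end))
    hit <- overlapsAny(rgr, .asGR(target),
        type = if (mode == "contain") "within" else "any")
    mean(hit)
}

#' Fraction of target bases covered at a depth threshold
#'
#' @param profile A \linkS4class{CoverageProfile}.
#' @param k Depth threshold; at \code{k = 0} the fraction is 1 by
#'   definition.
#' @return Fraction in [0, 1].
#' @export
basesCoveredAtThreshold <- function(profile, k) {
    mean(profile@depth >= k)
}

#' Mean coverage of an exon
#'
#' The sum of sequencing coverage on every nucleotide of the exon divided
#' by the exon length (the per-exon summary used for transcript
#' completeness; an arithmetic mean, whatever its historical label).
#'
#' @param profile A \linkS4class{CoverageProfile} whose target contains the
#'   exon.
#' @param exon A single-range \code{GRanges}, or a list/data.frame row with
#'   \code{chrom}, \code{start}, \code{end} (1-based closed).
#' @return Mean depth (numeric).
#' @export
exonMeanCoverage <- function(profile, exon) {
    if (is(exon, "GRanges")) {
        stopifnot(length(exon) == 1L)
        ch <- as.character(seqnames(exon)); s <- start(exon); e <- end(exon)
    } else {
        ch <- exon$chrom; s <- exon$start; e <- exon$end
    }
    d <- profileDepthAt(profile, rep(ch, e - s + 1L), s:e)
    if (anyNA(d)) stop("exon extends outside the profiled region: ",
        sprintf("%s:%d-%d", ch, s, e))
    mean(d)
}

#' Completely covered transcripts at a depth threshold
#'
#' A transcript is completely covered when every annotated exon has a mean
#' coverage of at least \code{threshold}; at threshold 0 every transcript
#' qualifies.
#'
#' @param transcripts A \code{GRangesList} of exons per transcript (see
#'   \code{\link{transcriptModels}}).
#' @param profile A \linkS4class{CoverageProfile} covering all exons.
#' @param threshold Depth threshold.
#' @return List with \code{count} and named logical \code{verdicts}.
#' @export
completeTranscripts <- function(transcripts, profile, threshold) {
    if (any(elementNROWS(transcripts) == 0L))
        stop("transcript without exons")
    verdicts <- vapply(seq_along(transcripts), function(i) {
        ex <- transcripts[[i]]
        all(vapply(seq_along(ex), function(j)
            exonMeanCoverage(profile, ex[j]) >= threshold, logical(1L)))
    }, logical(1L))
    names(verdicts) <- names(transcripts)
    list(count = sum(verdicts), verdicts = verdicts)
}

#' Mean target GC content stratified by coverage class
#'
#' Each target region is assigned to every coverage class its mean depth
#' satisfies; the default classes (0x, <10x, >=10x, >=20x) overlap by
#' construction, mirroring the usual presentation of capture-success
#' stratification.  Per class the unweighted mean of per-target GC
#' fractions is reported.
#'
#' @param targets The merged \linkS4class{TargetSet} the profile was built
#'   over.
#' @param profile \linkS4class{CoverageProfile} over \code{targets}.
#' @param reference Named \code{DNAStringSet}.
#' @param classes Named list of predicate functions of the per-target mean
#'   depth.
#' @return \code{data.frame(class, nTargets, meanGC)}.
#' @export
gcByCoverageClass <- function(targets, profile, reference,
    classes = list("0x" = function(m) m == 0,
                   "<10x" = function(m) m < 10,
                   ">=10x" = function(m) m >= 10,
                   ">=20x" = function(m) m >= 20)) {
    gr <- .asGR(targets)
    stopifnot(identical(gr, .asGR(profile@target)))
    offsets <- cumsum(c(0L, width(gr)))
    meanDepth <- vapply(seq_along(gr), function(i)
        mean(profile@depth[(offsets[i] + 1L):offsets[i + 1L]]), numeric(1L))
    gc <- gcContent(targets, reference, perTarget = TRUE)
    rows <- lapply(names(classes), function(nm) {
        sel <- classes[[nm]](meanDepth)
        data.frame(class = nm, nTargets = sum(sel),
            meanGC = if (any(sel)) mean(gc[sel], na.rm = TRUE) else NA_real_)
    })
    do.call(rbind, rows)
}

.alleleBalance <- function(variants, pileup, mode = c("quality", "count")) {
    mode <- match.arg(mode)
    v <- as.data.frame(variants@calls)
    v <- v[v$genotypeClass == "heterozygous" & v$alt %in% c("A", "C", "G", "T"), ,
        drop = FALSE]
    cols <- pileup@positions
    key <- paste(cols$chrom, cols$pos)
    pidx <- match(paste(v$chrom, v$pos), key)
    calls <- pileup@calls
    idxSplit <- split(seq_len(nrow(calls)), calls$posIndex)
    bal <- rep(NA_real_, nrow(v)); depth <- rep(NA_integer_, nrow(v))
    for (i in seq_len(nrow(v))) {
        if (is.na(pidx[i])) next
        j <- idxSplit[[as.character(pidx[i])]]
        b <- calls$base[j]; q <- calls$qual[j]
        isRef <- b == v$ref[i]; isVar <- b == v$alt[i]
        a <- if (mode == "quality") sum(q[isRef]) else sum(isRef)
        bb <- if (mode == "quality") sum(q[isVar]) else sum(isVar)
        if (a + bb > 0) bal[i] <- a / (a + bb)
        depth[i] <- length(j)
    }
    cbind(v, balance = bal, pileupDepth = depth)
}

#' Mean allele balance of heterozygous SNVs by region and depth
#'
#' The balance of a heterozygous site is A/(A+B) with A the
#' reference-supporting evidence, so values above 0.5 indicate an excess of
#' reference bases (the direction expected from capture-probe reference
#' bias).  Evidence is the allele-quality sum by default; \code{mode =
#' "count"} uses read counts instead.
#'
#' @param variants A \linkS4class{VariantCalls}.
#' @param pileup A \linkS4class{PileupTable} covering the variant
#'   positions.
#' @param regions Named list of merged \linkS4class{TargetSet}s; a
#'   \code{NULL} element means genome-wide.
#' @param minDepths Integer vector of minimum-depth strata.
#' @param mode Evidence type (\code{"quality"} or \code{"count"}).
#' @return \code{data.frame(region, minDepth, n, meanBalance)}; strata with
#'   no qualifying site have \code{n = 0} and \code{NA} mean.
#' @export
alleleBalanceSummary <- function(variants, pileup,
                                 regions = list(genome = NULL),
                                 minDepths = 0L,
                                 mode = c("quality", "count")) {
    ab <- .alleleBalance(variants, pileup, mode)
    pgr <- GRanges(ab$chrom, IRanges(ab$pos, ab$pos))
    rows <- list()
    for (rn in names(regions)) {
        inR <- if (is.null(regions[[rn]])) rep(TRUE, nrow(ab))
            else overlapsAny(pgr, .asGR(regions[[rn]]))
        for (md in minDepths) {
            sel <- inR & !is.na(ab$balance) & ab$pileupDepth >= md
            rows[[length(rows) + 1L]] <- data.frame(region = rn,
                minDepth = md, n = sum(sel),
                meanBalance = if (any(sel)) mean(ab$balance[sel]) else
                    NA_real_)
        }
    }
    do.call(rbind, rows)
}

#' Variant sharing between capture designs
#'
#' Restricts each call set to a region and minimum depth, then tabulates
#' the union of variant positions by the subset of designs that found them,
#' and counts, per pattern, the positions on which all finding designs
#' agree on the genotype.
#'
#' @param variantSets Named list of \linkS4class{VariantCalls}.
#' @param region Optional merged \linkS4class{TargetSet} restriction.
#' @param minDepth Minimum call depth (default 0).
#' @return List with \code{patterns}
#'   (\code{data.frame(pattern, n, nGenotypeConcordant)}), \code{total}
#'   union size, and \code{sharedByAll} count.
#' @export
variantSharing <- function(variantSets, region = NULL, minDepth = 0L) {
    stopifnot(length(variantSets) >= 1L, !is.null(names(variantSets)))
    sets <- lapply(variantSets, function(v) {
        df <- as.data.frame(v@calls)
        df <- df[df$depth >= minDepth, , drop = FALSE]
        if (!is.null(region)) {
            keep <- overlapsAny(GRanges(df$chrom, IRanges(df$pos, df$pos)),
                .asGR(region))
            df <- df[keep, , drop = FALSE]
        }
        df
    })
    keys <- sort(unique(unlist(lapply(sets, function(df)
        paste(df$chrom, df$pos)))))
    mem <- vapply(sets, function(df)
        keys %in% paste(df$chrom, df$pos), logical(length(keys)))
    mem <- matrix(mem, nrow = length(keys),
        dimnames = list(keys, names(sets)))
    pattern <- apply(mem, 1L, function(r)
        paste(names(sets)[r], collapse = "+"))
    geno <- vapply(seq_along(keys), function(i) {
        who <- which(mem[i, ])
        g <- vapply(who, function(j) {
            df <- sets[[j]]
            df$genotype[paste(df$chrom, df$pos) == keys[i]][1L]
        }, character(1L))
        length(unique(g)) == 1L
    }, logical(1L))
    tab <- split(seq_along(keys), pattern)
    patterns <- data.frame(pattern = names(tab),
        n = vapply(tab, length, integer(1L)),
        nGenotypeConcordant = vapply(tab, function(i) sum(geno[i]),
            integer(1L)))
    rownames(patterns) <- NULL
    list(patterns = patterns, total = length(keys),
        sharedByAll = sum(rowSums(mem) == length(sets)))
}

.revcompAlleles <- function(x) chartr("ACGT", "TGCA", x)

#' Read SNP-chip genotypes from TSV
#'
#' Expects columns \code{snpId}, \code{chrom}, \code{pos} (1-based),
#' \code{alleleA}, \code{alleleB}, \code{genotype} (\code{"A/G"} style),
#' \code{flankStrand} (\code{+}/\code{-}), \code{callRate},
#' \code{mappingCount}.
#'
#' @param path TSV path.
#' @return \code{data.frame} of chip genotypes.
#' @export
readChipTsv <- function(path) {
    read.delim(path, stringsAsFactors = FALSE,
        colClasses = list(chrom = "character"))
}

#' Harmonize SNP-chip genotypes for sequencing comparison
#'
#' Drops SNPs with a genotyping success rate below \code{minCallRate}
#' (default 95\%) and SNPs whose flanking sequence maps to several genomic
#' positions or none (\code{mappingCount != 1}); genotypes of SNPs whose
#' flank maps to the minus strand are replaced by their reverse
#' complements, as are their declared alleles.
#'
#' @param chip \code{data.frame} as returned by \code{\link{readChipTsv}}.
#' @param minCallRate Minimum genotyping success rate (default 0.95).
#' @return The filtered, strand-harmonized \code{data.frame}, with attributes
#'   \code{nDroppedCallRate} and \code{nDroppedMapping}.
#' @export
harmonizeChip <- function(chip, minCallRate = 0.95) {
    if (!all(grepl("^[ACGT](/[ACGT])?$", c(chip$alleleA, chip$alleleB))))
        stop("unknown allele characters in chip table")
    dropCR <- chip$callRate < minCallRate
    dropMap <- chip$mappingCount != 1L
    out <- chip[!dropCR & !dropMap, , drop = FALSE]
    minus <- out$flankStrand == "-"
    out$alleleA[minus] <- .revcompAlleles(out$alleleA[minus])
    out$alleleB[minus] <- .revcompAlleles(out$alleleB[minus])
    out$genotype[minus] <- .revcompAlleles(out$genotype[minus])
    rownames(out) <- NULL
    attr(out, "nDroppedCallRate") <- sum(dropCR)
    attr(out, "nDroppedMapping") <- sum(dropMap & !dropCR)
    out
}

.sortGenotype <- function(g) {
    vapply(strsplit(g, "/", fixed = TRUE), function(a)
        paste(sort(a), collapse = "/"), character(1L))
}

#' Genotype concordance against SNP-chip calls, by depth bin
#'
#' The sequenced genotype at a chip position is the re-called variant
#' genotype when a call exists there, otherwise homozygous reference when
#' the pileup depth reaches \code{minHomRefDepth} (default 1).  Chip SNPs
#' with no coverage are uncallable and excluded from every bin but counted.
#' Genotype correlation is concordant / (concordant + discordant), reported
#' per depth bin and chip genotype class and overall per bin.
#'
#' @param variants A \linkS4class{VariantCalls}.
#' @param pileup A \linkS4class{PileupTable} built at the chip positions.
#' @param chip Harmonized chip \code{data.frame}
#'   (\code{\link{harmonizeChip}}).
#' @param bins List of \code{c(lo, hi)} depth bins (closed; \code{Inf}
#'   allowed), or, when \code{cumulative = TRUE}, a vector of minimum
#'   coverages for accumulative-minimum curves.
#' @param cumulative Use >= k bins for every k in \code{bins}.
#' @param minHomRefDepth Minimum depth to assert a homozygous-reference
#'   sequenced genotype.
#' @return A \linkS4class{ConcordanceTable}.
#' @export
chipConcordance <- function(variants, pileup, chip,
    bins = list(c(1, 5), c(6, 10), c(11, 15), c(16, 20), c(21, Inf)),
    cumulative = FALSE, minHomRefDepth = 1L) {
    cols <- pileupColumns(pileup)
    key <- paste(cols$chrom, cols$pos)
    idx <- match(paste(chip$chrom, chip$pos), key)
    if (anyNA(idx))
        stop("pileup does not cover all chip positions; build it 'at' them")
    depth <- cols$depth[idx]
    ref <- cols$ref[idx]
    v <- as.data.frame(variants@calls)
    vidx <- match(paste(chip$chrom, chip$pos), paste(v$chrom, v$pos))
    seqGeno <- ifelse(!is.na(vidx), .sortGenotype(v$genotype[vidx]),
        ifelse(depth >= minHomRefDepth, paste(ref, ref, sep = "/"),
            NA_character_))
    chipGeno <- .sortGenotype(chip$genotype)
    chipAl <- strsplit(chipGeno, "/", fixed = TRUE)
    chipClass <- vapply(seq_along(chipAl), function(i) {
        a <- chipAl[[i]]
        if (a[1L] != a[2L]) "het"
        else if (a[1L] == ref[i]) "hom-ref" else "hom-var"
    }, character(1L))
    callable <- !is.na(seqGeno)
    conc <- callable & seqGeno == chipGeno

    binDef <- if (cumulative)
        lapply(bins, function(k) c(k, Inf)) else bins
    binName <- vapply(binDef, function(b) {
        if (cumulative || is.infinite(b[2L])) paste0(">=", b[1L])
        else paste0(b[1L], "-", b[2L])
    }, character(1L))
    cells <- list(); overall <- list()
    for (bi in seq_along(binDef)) {
        inBin <- callable & depth >= binDef[[bi]][1L] &
            depth <= binDef[[bi]][2L]
        for (cl in c("het", "hom-ref", "hom-var")) {
            sel <- inBin & chipClass == cl
            nC <- sum(conc[sel]); nD <- sum(sel) - nC
            cells[[length(cells) + 1L]] <- DataFrame(bin = binName[bi],
                chipClass = cl, concordant = nC, discordant = nD,
                correlation = if (nC + nD > 0) nC / (nC + nD) else NA_real_)
        }
        nC <- sum(conc[inBin]); nD <- sum(inBin) - nC
        overall[[length(overall) + 1L]] <- DataFrame(bin = binName[bi],
            n = sum(inBin), concordant = nC, discordant = nD,
            correlation = if (nC + nD > 0) nC / (nC + nD) else NA_real_)
    }
    new("ConcordanceTable", cells = do.call(rbind, cells),
        overall = do.call(rbind, overall),
        uncallable = sum(!callable))
}

#' @rdname accessors
#' @export
setMethod("concordanceCells", "ConcordanceTable",
    function(x) as.data.frame(x@cells))

#' @rdname accessors
#' @export
setMethod("concordanceOverall", "ConcordanceTable",
    function(x) as.data.frame(x@overall))

setMethod("show", "ConcordanceTable", function(object) {
    cat("ConcordanceTable\n")
    print(as.data.frame(object@overall))
    cat(sprintf("uncallable chip SNPs: %d\n", object@uncallable))
})

#' Coverage and alleles at a list of loci
#'
#' @param profile A \linkS4class{CoverageProfile}.
#' @param loci \code{data.frame(chrom, pos)} of 1-based loci.
#' @param variants Optional \linkS4class{VariantCalls}; observed alternate
#'   alleles at each locus are reported when supplied.
#' @return \code{data.frame(chrom, pos, depth, ge10, ge20, alleles)};
#'   depth 0 for covered-by-no-read loci inside the profile.  Loci on
#'   chromosomes absent from the profile raise an error.
#' @export
coverageAtLoci <- function(profile, loci, variants = NULL) {
    chroms <- unique(as.character(seqnames(.asGR(profile@target))))
    if (!all(loci$chrom %in% chroms))
        stop("locus on unknown chromosome: ",
            setdiff(loci$chrom, chroms)[1L])
    d <- profileDepthAt(profile, loci$chrom, loci$pos)
    d[is.na(d)] <- 0L
    alleles <- rep(NA_character_, nrow(loci))
    if (!is.null(variants)) {
        v <- as.data.frame(variants@calls)
        m <- match(paste(loci$chrom, loci$pos), paste(v$chrom, v$pos))
        alleles[!is.na(m)] <- v$alt[m[!is.na(m)]]
    }
    data.frame(chrom = loci$chrom, pos = loci$pos, depth = d,
        ge10 = d >= 10L, ge20 = d >= 20L, alleles = alleles)
}
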
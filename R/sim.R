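#' Configure a synthetic capture experiment
#'
#' Bundles every parameter of the seeded generator that emulates a targeted
#' (exome-like) capture sequencing experiment at desk scale: off-target
#' spillover, PCR duplicates, reference-biased allele sampling at
#' heterozygous sites, GC-dependent coverage depression, trailing
#' low-quality (Q2) read tails, planted read-end anomalies and a SNP-chip
#' panel.  All downstream generators (\code{\link{makeGenome}},
#' \code{\link{plantVariants}}, \code{\link{simulateReads}},
#' \code{\link{makeChip}}) are deterministic given the seed.
#'
#' @param seed Integer seed; each generator derives its own fixed stream
#'   from it.
#' @param chromLengths Named vector of chromosome lengths (bp).
#' @param windowSize GC window size (bp) for genome composition and
#'   coverage bias.
#' @param gcProfile Per-window GC target fractions, recycled over windows;
#'   \code{NULL} (default) cycles 0.35--0.65 so targets span realistic GC.
#' @param nTargets Number of capture target regions.
#' @param targetSizeRange \code{c(min, max)} target sizes (bp); exome
#'   probe footprints are a few hundred bp.
#' @param variantDensity Truth SNVs per bp (desk-scale compressed relative
#'   to the human ~1/1000).
#' @param hetFraction Fraction of truth variants that are heterozygous.
#' @param referenceBias Probability that a fragment at a heterozygous site
#'   carries the reference allele (0.5 = unbiased; capture probes pull
#'   slightly above 0.5).
#' @param duplicateRate Fraction of final fragments that are PCR duplicate
#'   re-emissions.
#' @param offTargetRate Fraction of fragments originating outside every
#'   target region.
#' @param readLength Read length (bp), default 82.
#' @param fragmentSizeMean,fragmentSizeSd Fragment size distribution,
#'   truncated to [readLength, 2*readLength + 300].
#' @param meanDepth Mean on-target sequencing depth.
#' @param gcBiasStrength Linear depression of a target's sampling weight
#'   with |GC - 0.5| (1 drives GC extremes toward zero coverage).
#' @param bTailRate Fraction of reads given a trailing Q2 block.
#' @param bTailLengthRange \code{c(min, max)} Q2 tail length.
#' @param reaPlants \code{data.frame(chrom, pos, side, support,
#'   withSoftclip)} of read-end anomalies to plant.
#' @param chipSnpCount SNPs on the synthetic genotyping chip.
#' @param chipDiscordanceRate Fraction of chip SNPs given a deliberately
#'   wrong genotype (hidden truth column).
#' @param chipMinusStrandFraction Fraction reported on the minus strand
#'   (pre-flipped, so harmonization must invert them).
#' @param chipLowCallRateFraction,chipMultiMapFraction Fractions given a
#'   call rate below 0.95 or several genomic placements, to exercise the
#'   chip filters.
#' @param baseQuality Constant Phred base quality (default 30).
#' @param maxBases Refuse configurations implying more sequenced bases
#'   than this (desk-scale guard).
#' @return A \linkS4class{SimConfig}.
#' @export
simConfig <- function(seed,
    chromLengths = c(chr1 = 90000L, chr2 = 60000L),
    windowSize = 1000L,
    gcProfile = NULL,
    nTargets = 80L,
    targetSizeRange = c(150L, 400L),
    variantDensity = 0.01,
    hetFraction = 0.67,
    referenceBias = 0.5,
    duplicateRate = 0.10,
    offTargetRate = 0.40,
    readLength = 82L,
    fragmentSizeMean = 250,
    fragmentSizeSd = 30,
    meanDepth = 30,
    gcBiasStrength = 1.0,
    bTailRate = 0.05,
    bTailLengthRange = c(3L, 12L),
    reaPlants = data.frame(),
    chipSnpCount = 2000L,
    chipDiscordanceRate = 0.01,
    chipMinusStrandFraction = 0.30,
    chipLowCallRateFraction = 0.02,
    chipMultiMapFraction = 0.02,
    baseQuality = 30L,
    maxBases = 5e8) {
    if (is.null(gcProfile)) gcProfile <- seq(0.35, 0.65, length.out = 7L)
    p <- list(seed = as.integer(seed), chromLengths = chromLengths,
        windowSize = as.integer(windowSize), gcProfile = gcProfile,
        nTargets = as.integer(nTargets),
        targetSizeRange = as.integer(targetSizeRange),
        variantDensity = variantDensity, hetFraction = hetFraction,
        referenceBias = referenceBias, duplicateRate = duplicateRate,
        offTargetRate = offTargetRate, readLength = as.integer(readLength),
        fragmentSizeMean = fragmentSizeMean,
        fragmentSizeSd = fragmentSizeSd, meanDepth = meanDepth,
        gcBiasStrength = gcBiasStrength, bTailRate = bTailRate,
        bTailLengthRange = as.integer(bTailLengthRange),
        reaPlants = reaPlants, chipSnpCount = as.integer(chipSnpCount),
        chipDiscordanceRate = chipDiscordanceRate,
        chipMinusStrandFraction = chipMinusStrandFraction,
        chipLowCallRateFraction = chipLowCallRateFraction,
        chipMultiMapFraction = chipMultiMapFraction,
        baseQuality = as.integer(baseQuality), maxBases = maxBases)
    new("SimConfig", params = p)
}

#' @rdname accessors
#' @export
setMethod("simParams", "SimConfig", function(x) x@params)

setMethod("show", "SimConfig", function(object) {
    p <- object@params
    cat(sprintf(paste0("SimConfig: seed %d, genome %d bp, %d targets, ",
        "depth %gx, off-target %.2f, duplicates %.2f, ref bias %.2f\n"),
        p$seed, sum(p$chromLengths), p$nTargets, p$meanDepth,
        p$offTargetRate, p$duplicateRate, p$referenceBias))
})

# Margin kept free around each target (and to chromosome ends).
.simMargin <- 300L

#' Generate a synthetic reference genome with capture annotation
#'
#' Draws chromosome sequences window by window with the configured GC
#' composition, places non-overlapping capture targets (one per equal-width
#' slot, with at least 300 bp between targets and to chromosome ends),
#' groups consecutive targets into transcript models, and emits a
#' mapability track stub (1.0 everywhere except periodic 0.5 windows).
#' Deterministic for a fixed seed.
#'
#' @param config A \linkS4class{SimConfig}.
#' @return List with \code{reference} (\code{DNAStringSet}),
#'   \code{targets} (merged \linkS4class{TargetSet}), \code{transcripts}
#'   (\code{GRangesList}), \code{mapability} (\code{GRanges} with score)
#'   and \code{config}.
#' @export
makeGenome <- function(config) {
    p <- config@params
    .withSeed(p$seed, {
        chroms <- names(p$chromLengths)
        seqs <- lapply(p$chromLengths, function(len) {
            nw <- ceiling(len / p$windowSize)
            gc <- rep_len(p$gcProfile, nw)
            chunks <- vapply(seq_len(nw), function(w) {
                n <- min(p$windowSize, len - (w - 1L) * p$windowSize)
                paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                    prob = c((1 - gc[w]) / 2, gc[w] / 2, gc[w] / 2,
                        (1 - gc[w]) / 2)), collapse = "")
            }, character(1L))
            paste(chunks, collapse = "")
        })
        reference <- Biostrings::DNAStringSet(unlist(seqs))
        names(reference) <- chroms

        nPer <- setNames(pmax(1L, round(p$nTargets * p$chromLengths /
            sum(p$chromLengths))), names(p$chromLengths))
        tgt <- list()
        for (ch in chroms) {
            n <- nPer[[ch]]
            slot <- floor(p$chromLengths[[ch]] / n)
            size <- sample(seq(p$targetSizeRange[1L], p$targetSizeRange[2L]),
                n, replace = TRUE)
            if (slot < max(size) + 2L * .simMargin)
                stop("chromosome too short for the requested target count/size")
            off <- floor(runif(n, .simMargin,
                slot - size - .simMargin + 1L))
            start <- (seq_len(n) - 1L) * slot + off + 1L
            tgt[[ch]] <- GRanges(ch, IRanges(start, width = size))
        }
        tgtGR <- sort(suppressWarnings(Reduce(c, tgt)))
        names(tgtGR) <- sprintf("target_%04d", seq_along(tgtGR))
        targets <- mergeIntervals(tgtGR, label = "sim")

        # transcripts: consecutive same-chromosome targets as exons
        exN <- integer(0); txIds <- character(0)
        i <- 1L; t <- 0L
        exonTx <- character(length(tgtGR))
        while (i <= length(tgtGR)) {
            t <- t + 1L
            k <- sample(1:5, 1L)
            j <- i
            while (j < length(tgtGR) && j - i + 1L < k &&
                as.character(seqnames(tgtGR))[j + 1L] ==
                as.character(seqnames(tgtGR))[i]) j <- j + 1L
            exonTx[i:j] <- sprintf("tx%04d", t)
            i <- j + 1L
        }
        ex <- granges(tgtGR)
        mcols(ex)$gene_id <- sub("tx", "g", exonTx)
        transcripts <- split(ex, exonTx)

        nw <- ceiling(p$chromLengths / p$windowSize)
        mp <- lapply(chroms, function(ch) {
            w <- seq_len(nw[[ch]])
            GRanges(ch, IRanges((w - 1L) * p$windowSize + 1L,
                pmin(w * p$windowSize, p$chromLengths[[ch]])),
                score = ifelse(w %% 11L == 0L, 0.5, 1.0))
        })
        mapability <- suppressWarnings(Reduce(c, mp))
        list(reference = reference, targets = targets,
            transcripts = transcripts, mapability = mapability,
            config = config)
    })
}

#' Plant truth variants in a synthetic genome
#'
#' Samples unique SNV positions genome-wide at the configured density and
#' assigns zygosity (heterozygous with probability \code{hetFraction}) and
#' a random alternate allele.
#'
#' @param config A \linkS4class{SimConfig}.
#' @param genome Result of \code{\link{makeGenome}}.
#' @return \code{data.frame(chrom, pos, ref, alt, zygosity)}.
#' @export
plantVariants <- function(config, genome) {
    p <- config@params
    .withSeed(p$seed + 1L, {
        rows <- lapply(names(p$chromLengths), function(ch) {
            n <- round(p$variantDensity * p$chromLengths[[ch]])
            if (n == 0L) return(NULL)
            pos <- sort(sample.int(p$chromLengths[[ch]], n))
            ref <- strsplit(as.character(Biostrings::extractAt(
                genome$reference[[ch]], IRanges(1L,
                    p$chromLengths[[ch]])))[[1]], "")[[1]][pos]
            alt <- vapply(ref, function(r)
                sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1L))
            data.frame(chrom = ch, pos = pos, ref = ref, alt = alt)
        })
        truth <- do.call(rbind, rows)
        if (is.null(truth))
            return(data.frame(chrom = character(), pos = integer(),
                ref = character(), alt = character(),
                zygosity = character()))
        truth$zygosity <- ifelse(runif(nrow(truth)) < p$hetFraction,
            "het", "hom")
        rownames(truth) <- NULL
        truth
    })
}

#' Simulate capture reads from a synthetic genome
#'
#' Paired 82-bp (configurable) reads are drawn fragment-wise: a fragment is
#' on-target with probability \code{1 - offTargetRate}, in which case it is
#' placed so that both mates overlap the chosen target region (targets
#' weighted by size and GC-depressed sampling weight); otherwise it is
#' placed uniformly in the inter-target space, overlapping no target.
#' Fragments at heterozygous truth sites carry the reference allele with
#' probability \code{referenceBias} (per site; PCR duplicate re-emissions
#' copy their template's alleles).  Duplicates, trailing Q2 tails and
#' configured read-end-anomaly plants are then added.  Alignments are
#' emitted directly as ground truth (no aligner); Q2 tails appear trimmed
#' in the alignments but intact in the FASTQ export.
#'
#' @param config A \linkS4class{SimConfig}.
#' @param genome Result of \code{\link{makeGenome}}.
#' @param truth Result of \code{\link{plantVariants}}.
#' @return List with \code{reads} (an \linkS4class{AlignedReadSet}, no
#'   duplicate flags set -- run \code{\link{markDuplicates}}),
#'   \code{fastq} (\code{r1}, \code{r2}
#'   \code{QualityScaledDNAStringSet}s), and \code{truth}
#'   (\code{fragments} with on/off-target and duplicate labels,
#'   \code{carriage} per fragment x variant allele assignments, plus the
#'   configured rates).
#' @export
simulateReads <- function(config, genome, truth) {
    p <- config@params
    .withSeed(p$seed + 2L, {
        rl <- p$readLength
        tgtGR <- .asGR(genome$targets)
        span <- sum(width(tgtGR))
        nOn <- round(span * p$meanDepth / (2 * rl))
        nTot <- if (p$offTargetRate < 1)
            round(nOn / (1 - p$offTargetRate)) else stop("offTargetRate = 1")
        nOff <- nTot - nOn
        nDup <- round(nTot * p$duplicateRate / (1 - p$duplicateRate))
        if ((nTot + nDup) * 2 * rl > p$maxBases)
            stop("configuration implies more than 'maxBases' sequenced bases")

        maxFrag <- 2L * rl + 300L
        fragLen <- as.integer(pmin(pmax(round(rnorm(nTot,
            p$fragmentSizeMean, p$fragmentSizeSd)), rl), maxFrag))

        # --- on-target placement: both mates must touch the target
        gcT <- gcContent(genome$targets, genome$reference, perTarget = TRUE)
        wgt <- width(tgtGR) * pmax(0.02,
            1 - p$gcBiasStrength * 2 * abs(gcT - 0.5))
        ti <- sample.int(length(tgtGR), nOn, replace = TRUE, prob = wgt)
        fLenOn <- pmin(fragLen[seq_len(nOn)],
            width(tgtGR)[ti] + 2L * rl - 2L)
        lo <- start(tgtGR)[ti] - rl + 1L
        hi <- end(tgtGR)[ti] + rl - fLenOn
        sOn <- lo + floor(runif(nOn) * (hi - lo + 1L))
        fragOn <- data.frame(chrom = as.character(seqnames(tgtGR))[ti],
            start = as.integer(sOn), len = fLenOn, onTarget = TRUE)

        # --- off-target placement: confined to inter-target gaps
        fragOff <- NULL
        if (nOff > 0L) {
            gapsL <- lapply(names(p$chromLengths), function(ch) {
                t <- tgtGR[seqnames(tgtGR) == ch]
                s <- c(1L, end(t) + 1L)
                e <- c(start(t) - 1L, p$chromLengths[[ch]])
                keep <- (e - s + 1L) >= maxFrag
                data.frame(chrom = ch, start = s[keep], end = e[keep])
            })
            gaps <- do.call(rbind, gapsL)
            fLenOff <- fragLen[nOn + seq_len(nOff)]
            gi <- sample.int(nrow(gaps), nOff, replace = TRUE,
                prob = gaps$end - gaps$start + 1L)
            sOff <- gaps$start[gi] + floor(runif(nOff) *
                (gaps$end[gi] - gaps$start[gi] + 1L - fLenOff + 1L))
            fragOff <- data.frame(chrom = gaps$chrom[gi],
                start = as.integer(sOff), len = fLenOff, onTarget = FALSE)
        }
        frag <- rbind(fragOn, fragOff)
        frag$end <- frag$start + frag$len - 1L
        nF <- nrow(frag)

        # --- allele carriage per (fragment, varith variant)
        carriage <- data.frame(frag = integer(), var = integer())
        if (nrow(truth)) {
            fgr <- GRanges(frag$chrom, IRanges(frag$start, frag$end))
            vgr <- GRanges(truth$chrom, IRanges(truth$pos, truth$pos))
            ov <- findOverlaps(fgr, vgr)
            fh <- queryHits(ov); vh <- subjectHits(ov)
            het <- truth$zygosity[vh] == "het"
            carriesAlt <- !het | runif(length(fh)) >= p$referenceBias
            carriage <- data.frame(frag = fh[carriesAlt],
                var = vh[carriesAlt])
        }

        # --- duplicates: re-emit fragments (alleles copied)
        dupOrig <- if (nDup > 0L) sample.int(nF, nDup, replace = TRUE)
            else integer(0)
        allFrag <- rbind(frag, frag[dupOrig, , drop = FALSE])
        allOrigin <- c(seq_len(nF), dupOrig)
        isDupTruth <- c(rep(FALSE, nF), rep(TRUE, nDup))
        nA <- nrow(allFrag)
        qname <- c(sprintf("frag%06d", seq_len(nF)),
            sprintf("frag%06dd%d", dupOrig, seq_len(nDup)))

        # --- read windows (reference orientation)
        r1s <- allFrag$start; r1e <- r1s + rl - 1L
        r2e <- allFrag$end; r2s <- r2e - rl + 1L
        getSeqs <- function(chrom, s, e) {
            out <- character(length(s))
            for (ch in unique(chrom)) {
                i <- which(chrom == ch)
                out[i] <- as.character(Biostrings::extractAt(
                    genome$reference[[ch]], IRanges(s[i], e[i])))
            }
            out
        }
        seq1 <- getSeqs(allFrag$chrom, r1s, r1e)
        seq2 <- getSeqs(allFrag$chrom, r2s, r2e)

        # --- apply carried alternate alleles to read windows
        if (nrow(carriage)) {
            carAll <- merge(data.frame(a = seq_len(nA), frag = allOrigin),
                carriage, by = "frag")
            if (!is.null(carAll) && nrow(carAll)) {
                vpos <- truth$pos[carAll$var]
                valt <- truth$alt[carAll$var]
                applySubs <- function(seqs, ws, rows, off, alt) {
                    if (!length(rows)) return(seqs)
                    o <- order(rows)
                    rows <- rows[o]; off <- off[o]; alt <- alt[o]
                    wave <- stats::ave(rows, rows, FUN = seq_along)
                    for (k in seq_len(max(wave))) {
                        i <- which(wave == k)
                        s <- seqs[rows[i]]
                        substr(s, off[i], off[i]) <- alt[i]
                        seqs[rows[i]] <- s
                    }
                    seqs
                }
                in1 <- vpos >= r1s[carAll$a] & vpos <= r1e[carAll$a]
                seq1 <- applySubs(seq1, r1s, carAll$a[in1],
                    (vpos - r1s[carAll$a])[in1] + 1L, valt[in1])
                in2 <- vpos >= r2s[carAll$a] & vpos <= r2e[carAll$a]
                seq2 <- applySubs(seq2, r2s, carAll$a[in2],
                    (vpos - r2s[carAll$a])[in2] + 1L, valt[in2])
            }
        }

        qchar <- intToUtf8(33L + p$baseQuality)
        qual0 <- strrep(qchar, rl)

        # --- FASTQ view (sequencing orientation, Q2 tails intact)
        fq1 <- seq1
        fq2 <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAStringSet(seq2)))
        fqq1 <- rep(qual0, nA); fqq2 <- rep(qual0, nA)
        tail1 <- integer(nA); tail2 <- integer(nA)
        if (p$bTailRate > 0) {
            pickTail <- function() {
                sel <- which(runif(nA) < p$bTailRate)
                tl <- integer(nA)
                tl[sel] <- sample(seq(p$bTailLengthRange[1L],
                    p$bTailLengthRange[2L]), length(sel), replace = TRUE)
                tl
            }
            tail1 <- pickTail(); tail2 <- pickTail()
            q2char <- intToUtf8(33L + 2L)
            mk <- function(tl) paste0(strrep(qchar, rl - tl),
                strrep(q2char, tl))
            fqq1 <- mk(tail1); fqq2 <- mk(tail2)
        }

        # --- SAM view: Q2 tails trimmed off the sequenced read end
        # read1 (+): tail at high coordinates; read2 (-): tail at low ones
        s1 <- substr(seq1, 1L, rl - tail1)
        p1 <- r1s
        c1 <- sprintf("%dM", rl - tail1)
        s2 <- substr(seq2, tail2 + 1L, rl)
        p2 <- r2s + tail2
        c2 <- sprintf("%dM", rl - tail2)
        q1 <- strrep(qchar, rl - tail1)
        q2 <- strrep(qchar, rl - tail2)

        reads <- data.frame(
            qname = rep(qname, 2L),
            mate = rep(c(1L, 2L), each = nA),
            chrom = rep(allFrag$chrom, 2L),
            pos = c(p1, p2),
            strand = rep(c("+", "-"), each = nA),
            cigar = c(c1, c2),
            seq = c(s1, s2),
            qual = c(q1, q2),
            mateChrom = rep(allFrag$chrom, 2L),
            matePos = c(p2, p1),
            mateStrand = rep(c("-", "+"), each = nA),
            isDuplicate = FALSE, stringsAsFactors = FALSE)

        # --- planted read-end anomalies
        plants <- p$reaPlants
        if (NROW(plants)) {
            prow <- list(); pfq <- list()
            for (i in seq_len(nrow(plants))) {
                sup <- plants$support[i]
                clip <- if (isTRUE(plants$withSoftclip[i])) 10L else 0L
                clipSeq <- paste(sample(c("A", "C", "G", "T"), clip,
                    replace = TRUE), collapse = "")
                fl <- 2L * rl + 20L + 9L * seq_len(sup)
                ch <- as.character(plants$chrom[i]); pp <- plants$pos[i]
                # supporters share only the planted boundary: the aligned
                # width varies (as after B-tail trimming), the clip
                # sequence -- the shared breakpoint evidence -- does not
                aw <- rl - clip - (seq_len(sup) - 1L) %% 6L
                qualA <- strrep(intToUtf8(33L + p$baseQuality), clip + aw)
                if (plants$side[i] == "start") {
                    fend <- pp + fl - 1L
                    focal <- data.frame(qname = sprintf("reaP%ds%d", i,
                        seq_len(sup)), mate = 1L, chrom = ch, pos = pp,
                        strand = "+",
                        cigar = if (clip) sprintf("%dS%dM", clip, aw)
                            else sprintf("%dM", aw),
                        seq = paste0(clipSeq, getSeqs(rep(ch, sup),
                            rep(pp, sup), pp + aw - 1L)),
                        qual = qualA, mateChrom = ch,
                        matePos = fend - rl + 1L, mateStrand = "-",
                        isDuplicate = FALSE)
                    mate <- data.frame(qname = focal$qname, mate = 2L,
                        chrom = ch, pos = fend - rl + 1L, strand = "-",
                        cigar = sprintf("%dM", rl),
                        seq = getSeqs(rep(ch, sup), fend - rl + 1L, fend),
                        qual = qual0, mateChrom = ch, matePos = pp,
                        mateStrand = "+", isDuplicate = FALSE)
                } else {
                    fstart <- pp - fl + 1L
                    focal <- data.frame(qname = sprintf("reaP%de%d", i,
                        seq_len(sup)), mate = 2L, chrom = ch,
                        pos = pp - aw + 1L, strand = "-",
                        cigar = if (clip) sprintf("%dM%dS", aw, clip)
                            else sprintf("%dM", aw),
                        seq = paste0(getSeqs(rep(ch, sup),
                            pp - aw + 1L, rep(pp, sup)), clipSeq),
                        qual = qualA, mateChrom = ch, matePos = fstart,
                        mateStrand = "+", isDuplicate = FALSE)
                    mate <- data.frame(qname = focal$qname, mate = 1L,
                        chrom = ch, pos = fstart, strand = "+",
                        cigar = sprintf("%dM", rl),
                        seq = getSeqs(rep(ch, sup), fstart,
                            fstart + rl - 1L),
                        qual = qual0, mateChrom = ch,
                        matePos = pp - aw + 1L,
                        mateStrand = "-", isDuplicate = FALSE)
                }
                prow[[i]] <- rbind(focal, mate)
            }
            reads <- rbind(reads, do.call(rbind, prow))
        }

        ars <- AlignedReadSet(reads,
            seqlengths = setNames(as.integer(p$chromLengths),
                names(p$chromLengths)))
        fq <- list(
            r1 = Biostrings::QualityScaledDNAStringSet(
                setNames(Biostrings::DNAStringSet(fq1), qname),
                Biostrings::PhredQuality(fqq1)),
            r2 = Biostrings::QualityScaledDNAStringSet(
                setNames(Biostrings::DNAStringSet(fq2), qname),
                Biostrings::PhredQuality(fqq2)))
        list(reads = ars, fastq = fq,
            truth = list(
                fragments = data.frame(qname = qname, allFrag,
                    origin = allOrigin, isDuplicate = isDupTruth),
                carriage = carriage,
                nOnTarget = nOn, nOffTarget = nOff, nDuplicates = nDup))
    })
}

#' Generate synthetic SNP-chip genotypes
#'
#' Chip SNPs are drawn from in-target truth variants plus invariant
#' in-target positions.  A configured fraction is reported on the minus
#' strand with pre-flipped (reverse-complemented) alleles and genotypes, a
#' fraction is given a deliberately wrong genotype (recorded in the hidden
#' \code{truthDiscordant} column), and small fractions get a call rate
#' below 0.95 or several genomic mappings so the harmonization filters
#' have work to do.
#'
#' @param config A \linkS4class{SimConfig}.
#' @param genome Result of \code{\link{makeGenome}}.
#' @param truth Result of \code{\link{plantVariants}}.
#' @return \code{data.frame} in \code{\link{readChipTsv}} layout plus
#'   \code{truthDiscordant}.
#' @export
makeChip <- function(config, genome, truth) {
    p <- config@params
    .withSeed(p$seed + 3L, {
        tgtGR <- .asGR(genome$targets)
        inT <- overlapsAny(GRanges(truth$chrom,
            IRanges(truth$pos, truth$pos)), tgtGR)
        vIdx <- which(inT)
        nVar <- min(length(vIdx), round(p$chipSnpCount / 2))
        nInv <- p$chipSnpCount - nVar
        # invariant candidate positions inside targets, avoiding truth sites
        allPos <- do.call(rbind, lapply(seq_along(tgtGR), function(i)
            data.frame(chrom = as.character(seqnames(tgtGR))[i],
                pos = start(tgtGR)[i]:end(tgtGR)[i])))
        allPos <- allPos[!paste(allPos$chrom, allPos$pos) %in%
            paste(truth$chrom, truth$pos), , drop = FALSE]
        if (nInv > nrow(allPos))
            stop("'chipSnpCount' exceeds available in-target sites")
        vSel <- sample(vIdx, nVar)
        iSel <- allPos[sample.int(nrow(allPos), nInv), , drop = FALSE]

        refAt <- function(chrom, pos) {
            out <- character(length(pos))
            for (ch in unique(chrom)) {
                i <- which(chrom == ch)
                out[i] <- as.character(Biostrings::extractAt(
                    genome$reference[[ch]], IRanges(pos[i], pos[i])))
            }
            out
        }
        chip <- rbind(
            data.frame(chrom = truth$chrom[vSel], pos = truth$pos[vSel],
                alleleA = truth$ref[vSel], alleleB = truth$alt[vSel],
                genotype = ifelse(truth$zygosity[vSel] == "het",
                    paste(truth$ref[vSel], truth$alt[vSel], sep = "/"),
                    paste(truth$alt[vSel], truth$alt[vSel], sep = "/"))),
            data.frame(chrom = iSel$chrom, pos = iSel$pos,
                alleleA = refAt(iSel$chrom, iSel$pos),
                alleleB = NA_character_, genotype = NA_character_))
        inv <- is.na(chip$alleleB)
        chip$alleleB[inv] <- vapply(chip$alleleA[inv], function(r)
            sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1L))
        chip$genotype[inv] <- paste(chip$alleleA[inv], chip$alleleA[inv],
            sep = "/")
        n <- nrow(chip)
        chip <- chip[sample.int(n), , drop = FALSE]
        chip$snpId <- sprintf("snp%05d", seq_len(n))
        chip$truthDiscordant <- FALSE
        nDis <- round(p$chipDiscordanceRate * n)
        if (nDis > 0L) {
            di <- sample.int(n, nDis)
            chip$truthDiscordant[di] <- TRUE
            chip$genotype[di] <- vapply(di, function(i) {
                opts <- c(paste(chip$alleleA[i], chip$alleleA[i], sep = "/"),
                    paste(chip$alleleA[i], chip$alleleB[i], sep = "/"),
                    paste(chip$alleleB[i], chip$alleleB[i], sep = "/"))
                sample(setdiff(opts, chip$genotype[i]), 1L)
            }, character(1L))
        }
        chip$flankStrand <- ifelse(runif(n) < p$chipMinusStrandFraction,
            "-", "+")
        minus <- chip$flankStrand == "-"
        chip$alleleA[minus] <- .revcompAlleles(chip$alleleA[minus])
        chip$alleleB[minus] <- .revcompAlleles(chip$alleleB[minus])
        chip$genotype[minus] <- .revcompAlleles(chip$genotype[minus])
        chip$callRate <- runif(n, 0.96, 1.0)
        low <- runif(n) < p$chipLowCallRateFraction
        chip$callRate[low] <- runif(sum(low), 0.85, 0.9499)
        chip$mappingCount <- ifelse(runif(n) < p$chipMultiMapFraction,
            2L, 1L)
        rownames(chip) <- NULL
        chip[, c("snpId", "chrom", "pos", "alleleA", "alleleB", "genotype",
            "flankStrand", "callRate", "mappingCount", "truthDiscordant")]
    })
}

#' Write the synthetic experiment as analysis-ready files
#'
#' Emits FASTA reference, target BED, exon TSV, mapability bedGraph, truth
#' SAM, FASTQ pair, truth variant TSV and chip TSV into a directory.
#'
#' @param genome Result of \code{\link{makeGenome}}.
#' @param sim Result of \code{\link{simulateReads}}.
#' @param truth Result of \code{\link{plantVariants}}.
#' @param chip Optional result of \code{\link{makeChip}}.
#' @param dir Output directory (created if needed).
#' @param encoding FASTQ quality encoding to write.
#' @return The directory, invisibly.
#' @export
writeSimFixtures <- function(genome, sim, truth, chip = NULL, dir,
                             encoding = "phred33") {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    Biostrings::writeXStringSet(genome$reference,
        file.path(dir, "reference.fa"))
    writeBed(genome$targets, file.path(dir, "targets.bed"))
    ex <- unlist(genome$transcripts)
    write.table(data.frame(transcript_id = names(ex),
        gene_id = mcols(ex)$gene_id,
        chrom = as.character(seqnames(ex)),
        start = start(ex) - 1L, end = end(ex)),
        file.path(dir, "exons.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    mp <- genome$mapability
    write.table(data.frame(chrom = as.character(seqnames(mp)),
        start = start(mp) - 1L, end = end(mp), score = mp$score),
        file.path(dir, "mapability.bedGraph"), sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = FALSE)
    writeSam(sim$reads, file.path(dir, "reads.sam"))
    writeFastqReads(sim$fastq$r1, file.path(dir, "reads_1.fastq"), encoding)
    writeFastqReads(sim$fastq$r2, file.path(dir, "reads_2.fastq"), encoding)
    write.table(truth, file.path(dir, "truth_variants.tsv"), sep = "\t",
        quote = FALSE, row.names = FALSE)
    if (!is.null(chip))
        write.table(chip, file.path(dir, "chip.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
    invisible(dir)
}
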
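# Independent brute-force oracles and fixture builders.  These deliberately
# use naive per-base / per-column computations so they share no code path
# with the package implementations they check.

# --- per-base boolean occupancy over toy chromosomes ------------------------

# intervals: data.frame(chrom, start, end), 1-based closed
occupancyVectors <- function(df, chromLen) {
    occ <- lapply(chromLen, function(n) logical(n))
    for (i in seq_len(nrow(df))) {
        ch <- df$chrom[i]
        occ[[ch]][df$start[i]:df$end[i]] <- TRUE
    }
    occ
}

occupancyToIntervals <- function(occ) {
    out <- list()
    for (ch in names(occ)) {
        r <- rle(occ[[ch]])
        e <- cumsum(r$lengths)
        s <- e - r$lengths + 1L
        keep <- r$values
        if (any(keep))
            out[[ch]] <- data.frame(chrom = ch, start = s[keep],
                end = e[keep])
    }
    if (!length(out))
        return(data.frame(chrom = character(), start = integer(),
            end = integer()))
    do.call(rbind, out)
}

grToDf <- function(gr) {
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
        start = GenomicRanges::start(gr), end = GenomicRanges::end(gr))
}

randomIntervals <- function(n, chromLen, maxWidth = 120L) {
    ch <- sample(names(chromLen), n, replace = TRUE)
    len <- unlist(chromLen)[ch]
    w <- sample.int(maxWidth, n, replace = TRUE)
    s <- mapply(function(l, wi) sample.int(l - wi + 1L, 1L), len, w)
    data.frame(chrom = ch, start = as.integer(s),
        end = as.integer(s + w - 1L))
}

# --- aligned-read fixtures --------------------------------------------------

# Build an AlignedReadSet from compact read specs.  Each row: chrom, pos,
# cigar, strand; seq/qual generated to match unless given.
makeReads <- function(df, seqlengths = c(chrT = 10000L), qualChar = "?") {
    n <- nrow(df)
    if (is.null(df$qname)) df$qname <- sprintf("r%04d", seq_len(n))
    if (is.null(df$mate)) df$mate <- rep(1L, n)
    if (is.null(df$strand)) df$strand <- rep("+", n)
    qw <- GenomicAlignments::cigarWidthAlongQuerySpace(df$cigar)
    if (is.null(df$seq))
        df$seq <- vapply(qw, function(w) paste(sample(c("A", "C", "G", "T"),
            w, replace = TRUE), collapse = ""), character(1L))
    if (is.null(df$qual)) df$qual <- strrep(qualChar, qw)
    if (is.null(df$isDuplicate)) df$isDuplicate <- rep(FALSE, n)
    AlignedReadSet(df, seqlengths = seqlengths)
}

randomReference <- function(chromLen) {
    ref <- Biostrings::DNAStringSet(vapply(chromLen, function(n)
        paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
            collapse = ""), character(1L)))
    names(ref) <- names(chromLen)
    ref
}

# naive per-base depth: loop over reads and their aligned blocks
oracleDepth <- function(ars, chromLen) {
    depth <- lapply(chromLen, function(n) integer(n))
    df <- as.data.frame(readRecords(ars))
    for (i in seq_len(nrow(df))) {
        if (df$isDuplicate[i]) next
        ops <- GenomicAlignments::explodeCigarOps(df$cigar[i])[[1L]]
        lens <- GenomicAlignments::explodeCigarOpLengths(df$cigar[i])[[1L]]
        p <- df$pos[i]
        for (k in seq_along(ops)) {
            if (ops[k] %in% c("M", "=", "X")) {
                depth[[df$chrom[i]]][p:(p + lens[k] - 1L)] <-
                    depth[[df$chrom[i]]][p:(p + lens[k] - 1L)] + 1L
                p <- p + lens[k]
            } else if (ops[k] %in% c("D", "N")) {
                p <- p + lens[k]
            }
        }
    }
    depth
}

# naive REA scan: per position and side, count boundary-sharing reads
oracleReas <- function(ars, chromLen, minSupport = 5L, minFraction = 0.30) {
    df <- as.data.frame(readRecords(ars))
    df <- df[!df$isDuplicate, , drop = FALSE]
    w <- GenomicAlignments::cigarWidthAlongReferenceSpace(df$cigar)
    st <- df$pos; en <- df$pos + w - 1L
    depth <- oracleDepth(ars, chromLen)
    out <- list()
    for (ch in names(chromLen)) {
        i <- which(df$chrom == ch)
        for (p in unique(c(st[i], en[i]))) {
            for (side in c("start", "end")) {
                sup <- if (side == "start") sum(st[i] == p)
                    else sum(en[i] == p)
                d <- depth[[ch]][p]
                if (sup >= minSupport && d > 0L && sup / d >= minFraction)
                    out[[length(out) + 1L]] <- data.frame(chrom = ch,
                        pos = p, side = side, support = sup, depth = d)
            }
        }
    }
    if (!length(out))
        return(data.frame(chrom = character(), pos = integer(),
            side = character(), support = integer(), depth = integer()))
    res <- do.call(rbind, out)
    res[order(res$chrom, res$pos, res$side), , drop = FALSE]
}

# independent per-column SNV caller: candidacy, ratio and class computed
# directly from the call vectors
oracleSnvColumn <- function(bases, quals, ref, minVQ = 20) {
    drop <- bases == "N"
    bases <- bases[!drop]; quals <- quals[!drop]
    varIdx <- bases != ref
    if (!any(varIdx)) return(NULL)
    if (max(quals[varIdx]) < minVQ) return(NULL)
    alleles <- unique(bases)
    if (length(alleles) > 2L) {
        ratio <- -1
    } else if (any(bases == ref)) {
        a <- 0; b <- 0
        for (j in seq_along(bases)) {
            if (bases[j] == ref) a <- a + quals[j] else b <- b + quals[j]
        }
        ratio <- a / (a + b)
    } else if (length(alleles) == 2L) {
        s1 <- sum(quals[bases == alleles[1L]])
        s2 <- sum(quals[bases == alleles[2L]])
        ratio <- max(s1, s2) / (s1 + s2)
    } else {
        ratio <- 0
    }
    cls <- if (ratio == -1) "multiallelic"
        else if (ratio > 0.8) "reference"
        else if (ratio < 0.2) "homozygous_variant"
        else "heterozygous"
    list(ratio = ratio, class = cls)
}

# Assemble a PileupTable directly from a list of columns
# (each: list(chrom, pos, ref, bases, quals)).
columnsToPileup <- function(cols) {
    positions <- S4Vectors::DataFrame(
        chrom = vapply(cols, `[[`, character(1L), "chrom"),
        pos = vapply(cols, `[[`, integer(1L), "pos"),
        ref = vapply(cols, `[[`, character(1L), "ref"))
    nb <- vapply(cols, function(cc) length(cc$bases), integer(1L))
    calls <- S4Vectors::DataFrame(
        posIndex = rep(seq_along(cols), nb),
        readId = paste0("r", seq_len(sum(nb))),
        base = unlist(lapply(cols, `[[`, "bases")),
        qual = as.numeric(unlist(lapply(cols, `[[`, "quals"))),
        startsHere = FALSE, endsHere = FALSE,
        softclip = NA_character_)
    new("PileupTable", positions = positions, calls = calls)
}

# Enumerate every pileup column with depth <= maxDepth over a fixed allele
# and quality alphabet (ref plus two alternates, two quality levels).
enumerateColumns <- function(maxDepth = 6L, ref = "A",
                             alts = c("C", "G"), quals = c(10, 30)) {
    opts <- expand.grid(base = c(ref, alts), qual = quals,
        stringsAsFactors = FALSE)
    cols <- list()
    pos <- 0L
    for (d in seq_len(maxDepth)) {
        idx <- do.call(expand.grid, rep(list(seq_len(nrow(opts))), d))
        for (r in seq_len(nrow(idx))) {
            pick <- as.integer(idx[r, ])
            pos <- pos + 1L
            cols[[pos]] <- list(chrom = "chrE", pos = pos, ref = ref,
                bases = opts$base[pick], quals = opts$qual[pick])
        }
    }
    cols
}

# --- shared synthetic experiments (built once per test run) -----------------

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
    if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
    .fixtures[[name]]
}

accConfig <- function(seed, referenceBias = 0.5, meanDepth = 40) {
    simConfig(seed = seed,
        chromLengths = c(chr1 = 200000L, chr2 = 100000L),
        nTargets = 150L, targetSizeRange = c(300L, 500L),
        variantDensity = 0.025, hetFraction = 0.75,
        referenceBias = referenceBias, duplicateRate = 0.10,
        offTargetRate = 0.40, meanDepth = meanDepth,
        chipSnpCount = 2000L, chipDiscordanceRate = 0.01)
}

# full pipeline on a configuration: genome, truth, reads, dedup, pileup at
# truth positions, variant calls
runPipeline <- function(cfg) {
    g <- makeGenome(cfg)
    truth <- plantVariants(cfg, g)
    sim <- simulateReads(cfg, g, truth)
    ars <- markDuplicates(sim$reads)
    pt <- buildPileup(ars, g$reference, at = truth[, c("chrom", "pos")])
    calls <- callSnvs(pt)
    list(cfg = cfg, genome = g, truth = truth, sim = sim, ars = ars,
        pileup = pt, calls = calls)
}

pipelineA <- function() fixture("pipeA", function()
    runPipeline(accConfig(101L)))
pipelineB <- function() fixture("pipeB", function()
    runPipeline(accConfig(202L, referenceBias = 0.52, meanDepth = 50)))
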
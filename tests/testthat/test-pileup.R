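test_that("duplicate marking keys on fragment outer coordinates", {
    pair <- function(qn, pos1, pos2, chrom = "chrT", q1 = "?", q2 = "?") {
        data.frame(qname = qn, mate = c(1L, 2L), chrom = chrom,
            pos = c(pos1, pos2), strand = c("+", "-"),
            cigar = "10M", seq = strrep("A", 10),
            qual = c(strrep(q1, 10), strrep(q2, 10)),
            mateChrom = chrom, matePos = c(pos2, pos1),
            mateStrand = c("-", "+"), isDuplicate = FALSE)
    }
    # identical outer coordinates and orientation: exactly one pair flagged
    ars <- makeReads(rbind(pair("a", 100, 200), pair("b", 100, 200)))
    md <- markDuplicates(ars)
    flagged <- unique(readRecords(md)$qname[isDuplicate(md)])
    expect_length(flagged, 1L)
    # the higher-quality pair survives
    ars2 <- makeReads(rbind(pair("a", 100, 200, q1 = "5"),
        pair("b", 100, 200)))
    md2 <- markDuplicates(ars2)
    expect_identical(unique(readRecords(md2)$qname[isDuplicate(md2)]), "a")
    # same start, different end: not duplicates in outer mode...
    ars3 <- makeReads(rbind(pair("a", 100, 200), pair("b", 100, 210)))
    expect_false(any(isDuplicate(markDuplicates(ars3))))
    # ...but flagged in leftmost mode
    expect_equal(sum(isDuplicate(markDuplicates(ars3,
        mode = "leftmost"))), 2L)
    # non-flagged fragments have pairwise distinct keys
    set.seed(41)
    many <- do.call(rbind, lapply(1:60, function(i)
        pair(sprintf("f%02d", i), sample(100:110, 1), sample(200:205, 1))))
    md4 <- markDuplicates(makeReads(many))
    df <- as.data.frame(readRecords(md4))
    kept <- df[!df$isDuplicate, ]
    keys <- tapply(kept$pos, kept$qname, function(p)
        paste(sort(p), collapse = ":"))
    expect_false(any(duplicated(keys)))
    # inconsistent mate information is rejected
    bad <- pair("x", 100, 200)
    bad$chrom <- c("chrT", "chrU")
    expect_error(markDuplicates(makeReads(bad,
        seqlengths = c(chrT = 10000L, chrU = 10000L))),
        "inconsistent mate")
})

test_that("SAM writing and reading round-trip all read fields", {
    dir <- withr::local_tempdir()
    df <- data.frame(qname = c("a", "a", "b"), mate = c(1L, 2L, 1L),
        chrom = "chrT", pos = c(100L, 180L, 400L),
        strand = c("+", "-", "+"), cigar = c("8M", "5S8M", "6M2S"),
        seq = c("ACGTACGT", "TTTTTACGTACGT", "ACGTACGT"),
        qual = c("IIIIIIII", "IIIIIIIIIIIII", "IIIIIIII"),
        mateChrom = c("chrT", "chrT", NA), matePos = c(180L, 100L, NA),
        mateStrand = c("-", "+", NA), isDuplicate = c(FALSE, TRUE, FALSE))
    ars <- makeReads(df)
    f <- file.path(dir, "t.sam")
    writeSam(ars, f)
    back <- readSam(f)
    d2 <- as.data.frame(readRecords(back))
    d2 <- d2[order(d2$qname, d2$mate), ]
    expect_identical(d2$seq, df$seq)
    expect_identical(d2$cigar, df$cigar)
    expect_identical(d2$pos, df$pos)
    expect_identical(d2$strand, df$strand)
    expect_identical(d2$isDuplicate, df$isDuplicate)
})

test_that("pileup columns carry calls, boundaries and soft clips", {
    ref <- Biostrings::DNAStringSet(c(chrT = strrep("ACGT", 2500)))
    df <- data.frame(chrom = "chrT", pos = c(101L, 101L, 105L),
        cigar = c("10M", "10M", "5S10M"),
        seq = c(strrep("A", 10), strrep("C", 10), strrep("G", 15)),
        qual = c(strrep("I", 10), strrep("I", 10), strrep("I", 15)))
    pt <- buildPileup(makeReads(df), ref)
    cols <- pileupColumns(pt)
    expect_equal(cols$depth[cols$pos == 105], 3L)
    # soft-clipped bases contribute no call before the aligned start
    expect_equal(cols$depth[cols$pos == 104], 2L)
    calls <- pileupCalls(pt)
    scRow <- calls[!is.na(calls$softclip), ]
    expect_equal(nrow(scRow), 1L)
    expect_identical(scRow$softclip, "GGGGG")
    expect_true(scRow$startsHere)
    expect_equal(pt@positions$pos[scRow$posIndex], 105L)
    # start/end flags occur exactly once per read
    expect_equal(sum(calls$startsHere), 3L)
    expect_equal(sum(calls$endsHere), 3L)
    # duplicate reads are excluded
    df$isDuplicate <- c(TRUE, FALSE, FALSE)
    pt2 <- buildPileup(makeReads(df), ref)
    expect_equal(max(pileupColumns(pt2)$depth), 2L)
    expect_error(buildPileup(makeReads(transform(df, chrom = "chrZ"),
        seqlengths = c(chrZ = 10000L)), ref), "unknown chromosome")
})

test_that("deletions contribute no call at the deleted positions", {
    ref <- Biostrings::DNAStringSet(c(chrT = strrep("A", 1000)))
    df <- data.frame(chrom = "chrT", pos = 101L, cigar = "4M3D4M",
        seq = "CCCCGGGG", qual = "IIIIIIII")
    pt <- buildPileup(makeReads(df), ref)
    cols <- pileupColumns(pt)
    expect_identical(cols$pos, c(101:104, 108:111))
    calls <- pileupCalls(pt)
    expect_identical(calls$base, c(rep("C", 4), rep("G", 4)))
    # the aligned span still ends after the deletion
    expect_equal(pt@positions$pos[calls$posIndex[calls$endsHere]], 111L)
})

test_that("pileup depth equals the nested-loop oracle on a random fixture", {
    set.seed(42)
    chromLen <- c(chrT = 2000L)
    ref <- randomReference(chromLen)
    n <- 200L
    df <- data.frame(chrom = "chrT",
        pos = sample.int(1800L, n, replace = TRUE),
        cigar = sample(c("30M", "10S25M", "20M5S", "12M4D14M", "15M2I13M"),
            n, replace = TRUE))
    ars <- makeReads(df)
    drop <- sample.int(n, 20L)
    rr <- readRecords(ars)
    rr$isDuplicate[drop] <- TRUE
    ars@reads <- rr
    pt <- buildPileup(ars, ref)
    cols <- pileupColumns(pt)
    odepth <- oracleDepth(ars, chromLen)[["chrT"]]
    expect_equal(cols$depth, odepth[cols$pos])
    expect_true(all(odepth[-cols$pos] == 0L))
    # depth profile agrees with pileup at every target base
    ts <- mergeIntervals(data.frame(chrom = "chrT", start = 1L,
        end = 2000L))
    prof <- depthProfile(ars, ts)
    expect_identical(profileDepth(prof), odepth)
    # total depth equals the summed aligned span of non-duplicate reads
    w <- GenomicAlignments::cigarWidthAlongReferenceSpace(df$cigar)
    dels <- vapply(seq_len(n), function(i) {
        ops <- GenomicAlignments::explodeCigarOps(df$cigar[i])[[1]]
        lens <- GenomicAlignments::explodeCigarOpLengths(df$cigar[i])[[1]]
        sum(lens[ops == "D"])
    }, numeric(1))
    expect_equal(sum(profileDepth(prof)), sum((w - dels)[-drop]))
})

test_that("depth profiles cover zero-coverage targets explicitly", {
    ref <- Biostrings::DNAStringSet(c(chrT = strrep("A", 1000)))
    ts <- mergeIntervals(data.frame(chrom = "chrT", start = c(100L, 500L),
        end = c(109L, 509L)))
    df <- data.frame(chrom = "chrT", pos = 100L, cigar = "10M",
        seq = strrep("C", 10), qual = strrep("I", 10))
    prof <- depthProfile(makeReads(df), ts)
    expect_identical(profileDepth(prof), c(rep(1L, 10), rep(0L, 10)))
    none <- depthProfile(makeReads(df[0, , drop = FALSE]), ts)
    expect_identical(profileDepth(none), rep(0L, 20))
    expect_identical(profileDepthAt(prof, c("chrT", "chrT", "chrT"),
        c(105L, 505L, 300L)), c(1L, 0L, NA_integer_))
})
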
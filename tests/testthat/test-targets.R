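test_that("merging unions overlapping and abutting intervals", {
    ts <- mergeIntervals(data.frame(chrom = "chr1", start = c(0, 5),
        end = c(10, 15)), zeroBased = TRUE)
    expect_equal(totalBases(ts), 15)
    expect_equal(length(ts), 1L)

    # disjoint chromosomes stay apart, sorted
    ts2 <- mergeIntervals(data.frame(chrom = c("chr2", "chr1"),
        start = c(0, 0), end = c(10, 10)), zeroBased = TRUE)
    expect_equal(as.character(GenomicRanges::seqnames(targetRanges(ts2))),
        c("chr1", "chr2"))
    expect_equal(totalBases(ts2), 20)

    # half-open adjacency means contiguity: [0,10)+[10,20) is one region
    ts3 <- mergeIntervals(data.frame(chrom = "chr1", start = c(0, 10),
        end = c(10, 20)), zeroBased = TRUE)
    expect_equal(length(ts3), 1L)

    # idempotence
    expect_identical(targetRanges(mergeIntervals(ts3)), targetRanges(ts3))

    # malformed interval names the record
    expect_error(TargetSet(data.frame(chrom = "chr1", start = 10, end = 10),
        zeroBased = TRUE), "record 1")
})

test_that("random merges equal the per-base occupancy oracle", {
    set.seed(11)
    chromLen <- c(c1 = 1000L)
    for (rep in 1:20) {
        df <- randomIntervals(50L, chromLen)
        ts <- mergeIntervals(TargetSet(df))
        expect_identical(grToDf(targetRanges(ts)),
            occupancyToIntervals(occupancyVectors(df, chromLen)),
            ignore_attr = TRUE)
        expect_lte(totalBases(ts), sum(df$end - df$start + 1L))
    }
})

test_that("overlap verdicts follow the one-base-pair rule", {
    q <- mergeIntervals(data.frame(chrom = "chr1", start = 100, end = 200),
        zeroBased = TRUE)
    sIn <- mergeIntervals(data.frame(chrom = "chr1", start = 199, end = 300),
        zeroBased = TRUE)
    sOut <- mergeIntervals(data.frame(chrom = "chr1", start = 200, end = 300),
        zeroBased = TRUE)
    expect_true(targetOverlaps(q, sIn)$included)
    expect_equal(targetOverlaps(q, sIn)$overlapBp, 1L)
    expect_false(targetOverlaps(q, sOut)$included)
    expect_error(targetOverlaps(q, sIn, minBp = 0), "minBp")
    expect_error(targetOverlaps(TargetSet(data.frame(chrom = "chr1",
        start = 1, end = 5)), sIn), "merged")
})

test_that("random overlap verdicts equal the per-base AND oracle", {
    set.seed(12)
    chromLen <- c(c1 = 2000L)
    for (rep in 1:10) {
        q <- mergeIntervals(TargetSet(randomIntervals(20L, chromLen)))
        s <- mergeIntervals(TargetSet(randomIntervals(20L, chromLen)))
        sOcc <- occupancyVectors(grToDf(targetRanges(s)), chromLen)
        got <- targetOverlaps(q, s, minBp = 3L)
        qdf <- grToDf(targetRanges(q))
        for (i in seq_len(nrow(qdf))) {
            ov <- sum(sOcc[[qdf$chrom[i]]][qdf$start[i]:qdf$end[i]])
            expect_equal(got$overlapBp[i], ov)
            expect_equal(got$included[i], ov >= 3L)
        }
    }
})

test_that("flanking expands, clamps at the chromosome start and re-merges", {
    t1 <- mergeIntervals(data.frame(chrom = "chr1", start = 200, end = 300),
        zeroBased = TRUE)
    expect_identical(grToDf(targetRanges(addFlank(t1, 100))),
        data.frame(chrom = "chr1", start = 101L, end = 400L))
    t2 <- mergeIntervals(data.frame(chrom = "chr1", start = 50, end = 60),
        zeroBased = TRUE)
    expect_identical(grToDf(targetRanges(addFlank(t2, 100))),
        data.frame(chrom = "chr1", start = 1L, end = 160L))
    t3 <- mergeIntervals(data.frame(chrom = "chr1", start = c(0, 250),
        end = c(100, 300)), zeroBased = TRUE)
    f3 <- addFlank(t3, 100)
    expect_equal(length(f3), 1L)
    expect_equal(totalBases(f3), 400)
    # zero flank is the identity
    expect_identical(targetRanges(addFlank(t3, 0)), targetRanges(t3))
    expect_error(addFlank(t3, -1), "flankBp")
})

test_that("common target is the base-pair intersection of all designs", {
    a <- mergeIntervals(data.frame(chrom = "chr1", start = 0, end = 10),
        zeroBased = TRUE)
    b <- mergeIntervals(data.frame(chrom = "chr1", start = 5, end = 15),
        zeroBased = TRUE)
    cm <- commonTarget(list(a, b))
    expect_identical(grToDf(targetRanges(cm)),
        data.frame(chrom = "chr1", start = 6L, end = 10L))
    d <- mergeIntervals(data.frame(chrom = "chr1", start = 100, end = 120),
        zeroBased = TRUE)
    expect_equal(totalBases(commonTarget(list(a, d))), 0)
    expect_error(commonTarget(list(a)), "at least two")

    set.seed(13)
    chromLen <- c(c1 = 1500L)
    designs <- lapply(1:4, function(i)
        mergeIntervals(TargetSet(randomIntervals(15L, chromLen,
            maxWidth = 300L))))
    occ <- Reduce(function(x, y) list(c1 = x$c1 & y$c1),
        lapply(designs, function(d)
            occupancyVectors(grToDf(targetRanges(d)), chromLen)))
    expect_identical(grToDf(targetRanges(commonTarget(designs))),
        occupancyToIntervals(occ), ignore_attr = TRUE)
    # common target is a subset of every design
    for (d in designs) {
        dOcc <- occupancyVectors(grToDf(targetRanges(d)), chromLen)
        expect_true(all(!occ$c1 | dOcc$c1))
    }
})

test_that("membership patterns partition the combined query", {
    q <- mergeIntervals(data.frame(chrom = "chr1",
        start = c(0, 100, 200), end = c(50, 150, 250)), zeroBased = TRUE)
    A <- mergeIntervals(data.frame(chrom = "chr1", start = c(10, 110),
        end = c(20, 120)), zeroBased = TRUE)
    B <- mergeIntervals(data.frame(chrom = "chr1", start = c(110, 210),
        end = c(120, 220)), zeroBased = TRUE)
    res <- regionMembershipCounts(q, list(A = A, B = B))
    cnt <- setNames(res$counts$n, res$counts$pattern)
    expect_equal(cnt[["A"]], 1L)
    expect_equal(cnt[["A+B"]], 1L)
    expect_equal(cnt[["B"]], 1L)
    expect_equal(sum(res$counts$n), 3L)

    empty <- mergeIntervals(data.frame(chrom = "chr1", start = 900,
        end = 950), zeroBased = TRUE)
    res2 <- regionMembershipCounts(q, list(A = empty))
    expect_equal(res2$counts$pattern, "none")
    expect_equal(res2$counts$n, 3L)

    # randomized: patterns equal an exhaustive per-region overlap loop
    set.seed(14)
    chromLen <- c(c1 = 3000L)
    qs <- mergeIntervals(TargetSet(randomIntervals(25L, chromLen)))
    ds <- lapply(1:3, function(i)
        mergeIntervals(TargetSet(randomIntervals(10L, chromLen))))
    names(ds) <- c("X", "Y", "Z")
    res3 <- regionMembershipCounts(qs, ds)
    qdf <- grToDf(targetRanges(qs))
    for (i in seq_len(nrow(qdf))) {
        expected <- vapply(ds, function(d) {
            occ <- occupancyVectors(grToDf(targetRanges(d)), chromLen)
            sum(occ[[qdf$chrom[i]]][qdf$start[i]:qdf$end[i]]) >= 1L
        }, logical(1L))
        expect_equal(unname(res3$membership[i, ]), unname(expected))
    }
    expect_equal(sum(res3$counts$n), nrow(qdf))
})

test_that("GC content averages per-target fractions over A/C/G/T", {
    ref <- Biostrings::DNAStringSet(c(chr1 = "GGCCATATACGTAATTNNNN"))
    one <- function(s, e) mergeIntervals(data.frame(chrom = "chr1",
        start = s, end = e))
    expect_equal(gcContent(one(1, 4), ref), 1.0)
    expect_equal(gcContent(one(5, 8), ref), 0.0)
    two <- mergeIntervals(data.frame(chrom = "chr1", start = c(9, 13),
        end = c(12, 16)))
    expect_equal(gcContent(two, ref), (0.5 + 0.0) / 2)
    expect_equal(gcContent(two, ref, weighted = TRUE), 2 / 8)
    # ambiguous bases are excluded from the denominator
    expect_equal(gcContent(one(13, 20), ref), 0.0)
    expect_error(gcContent(one(15, 25), ref), "beyond chromosome end")
    expect_error(gcContent(mergeIntervals(data.frame(chrom = "chrX",
        start = 1, end = 5)), ref), "unknown chromosome")
})

test_that("mean mapability averages track scores per target base", {
    track <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(c(1, 101), c(100, 200)), score = c(1.0, 0.5))
    ts <- mergeIntervals(data.frame(chrom = "chr1", start = 1, end = 200))
    expect_equal(meanMapability(ts, track), 0.75)
    uni <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 5000),
        score = 1.0)
    ts2 <- mergeIntervals(data.frame(chrom = "chr1", start = c(10, 900),
        end = c(50, 1200)))
    expect_equal(meanMapability(ts2, uni), 1.0)
    short <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100),
        score = 1.0)
    expect_error(meanMapability(ts, short), "not covered")
    expect_equal(meanMapability(ts, short, uncovered = "zero"), 0.5)

    # random track vs per-base averaging
    set.seed(15)
    pieces <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(seq(1, 951, by = 50), width = 50),
        score = round(runif(20), 2))
    ts3 <- mergeIntervals(TargetSet(randomIntervals(10L, c(chr1 = 1000L))))
    perBase <- rep(pieces$score, each = 50)
    tdf <- grToDf(targetRanges(ts3))
    expected <- mean(unlist(lapply(seq_len(nrow(tdf)), function(i)
        perBase[tdf$start[i]:tdf$end[i]])))
    expect_equal(meanMapability(ts3, pieces), expected)
})

test_that("total bases sums merged interval sizes", {
    ts <- mergeIntervals(data.frame(chrom = "chr1", start = c(0, 20),
        end = c(10, 25)), zeroBased = TRUE)
    expect_equal(totalBases(ts), 15)
    expect_equal(totalBases(mergeIntervals(data.frame(chrom = character(),
        start = integer(), end = integer()))), 0)
})

test_that("BED and exon-table I/O round-trip through files", {
    dir <- withr::local_tempdir()
    ts <- mergeIntervals(data.frame(chrom = c("chr1", "chr2"),
        start = c(10, 5), end = c(60, 105)), zeroBased = TRUE)
    bed <- file.path(dir, "t.bed")
    writeBed(ts, bed)
    back <- readBed(bed)
    expect_identical(grToDf(targetRanges(back)), grToDf(targetRanges(ts)))

    exf <- file.path(dir, "ex.tsv")
    writeLines(c("transcript_id\tgene_id\tchrom\tstart\tend",
        "t1\tg1\tchr1\t0\t100", "t1\tg1\tchr1\t200\t300",
        "t2\tg2\tchr2\t50\t80"), exf)
    tx <- readExonTable(exf)
    expect_equal(length(tx), 2L)
    expect_equal(GenomicRanges::start(tx[["t1"]]), c(1L, 201L))
    # overlapping exons rejected
    expect_error(transcriptModels(c("t", "t"), c("g", "g"),
        c("chr1", "chr1"), c(1, 50), c(100, 120)), "overlapping")
})
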
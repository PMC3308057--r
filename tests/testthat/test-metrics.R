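profileFromDepths <- function(depths, start = 101L, chrom = "chrT") {
    ts <- mergeIntervals(data.frame(chrom = chrom, start = start,
        end = start + length(depths) - 1L))
    new("CoverageProfile", target = ts, depth = as.integer(depths))
}

test_that("on-target fraction counts reads overlapping by one base pair", {
    rows <- data.frame(chrom = "chrT",
        pos = c(seq(100, 350, by = 50), 2000L, 2100L, 2200L, 2300L),
        cigar = "50M")
    ars <- makeReads(rows)   # 6 reads overlap [100,400], 4 do not
    target <- mergeIntervals(data.frame(chrom = "chrT", start = 100L,
        end = 400L))
    expect_equal(onTargetFraction(ars, target), 0.6)
    genome <- mergeIntervals(data.frame(chrom = "chrT", start = 1L,
        end = 10000L))
    expect_equal(onTargetFraction(ars, genome), 1.0)
    # containment is stricter than overlap
    edge <- mergeIntervals(data.frame(chrom = "chrT", start = 120L,
        end = 400L))
    expect_gt(onTargetFraction(ars, edge),
        onTargetFraction(ars, edge, mode = "contain"))
    none <- makeReads(rows[0, , drop = FALSE])
    expect_error(onTargetFraction(none, target), "no reads")
})

test_that("threshold coverage is exact and non-increasing in k", {
    prof <- profileFromDepths(c(rep(25L, 50), rep(5L, 30), rep(0L, 20)))
    expect_equal(basesCoveredAtThreshold(prof, 20), 0.5)
    expect_equal(basesCoveredAtThreshold(prof, 0), 1.0)
    expect_equal(basesCoveredAtThreshold(prof, 1), 0.8)
    set.seed(71)
    rprof <- profileFromDepths(sample(0:40, 500, replace = TRUE))
    ks <- 0:45
    fr <- vapply(ks, function(k) basesCoveredAtThreshold(rprof, k),
        numeric(1))
    expect_equal(fr, vapply(ks, function(k)
        sum(profileDepth(rprof) >= k) / 500, numeric(1)))
    expect_true(all(diff(fr) <= 0))
})

test_that("exon mean coverage is the depth sum over the exon length", {
    prof <- profileFromDepths(c(10L, 20L, 30L, 40L))
    exon <- GenomicRanges::GRanges("chrT", IRanges::IRanges(101, 104))
    expect_equal(exonMeanCoverage(prof, exon), 25.0)
    zero <- profileFromDepths(rep(0L, 10))
    expect_equal(exonMeanCoverage(zero,
        list(chrom = "chrT", start = 101L, end = 110L)), 0.0)
    expect_error(exonMeanCoverage(prof,
        list(chrom = "chrT", start = 101L, end = 120L)), "outside")
    set.seed(72)
    d <- sample(0:50, 200, replace = TRUE)
    rp <- profileFromDepths(d)
    expect_equal(exonMeanCoverage(rp,
        list(chrom = "chrT", start = 121L, end = 180L)),
        sum(d[21:80]) / 60)
})

test_that("transcript completeness needs every exon at the threshold", {
    prof <- profileFromDepths(c(rep(25L, 10), rep(19L, 10), rep(21L, 10)))
    txA <- GenomicRanges::GRanges("chrT",
        IRanges::IRanges(c(101, 111), c(110, 120)))   # means 25, 19
    txB <- GenomicRanges::GRanges("chrT",
        IRanges::IRanges(c(101, 121), c(110, 130)))   # means 25, 21
    txs <- GenomicRanges::GRangesList(A = txA, B = txB)
    res <- completeTranscripts(txs, prof, 20)
    expect_identical(unname(res$verdicts), c(FALSE, TRUE))
    expect_equal(res$count, 1L)
    expect_equal(completeTranscripts(txs, prof, 0)$count, 2L)
    counts <- vapply(1:30, function(th)
        completeTranscripts(txs, prof, th)$count, integer(1))
    expect_true(all(diff(counts) <= 0L))
    expect_error(completeTranscripts(GenomicRanges::GRangesList(
        E = GenomicRanges::GRanges()), prof, 1), "without exons")
})

test_that("GC stratification by coverage class matches hand computation", {
    # two 4-bp targets: GC 1.0 and 0.0, coverages 25 and 0
    ref <- Biostrings::DNAStringSet(c(chrT = paste0(strrep("N", 100),
        "GGCC", strrep("N", 96), "ATAT", strrep("N", 96))))
    ts <- mergeIntervals(data.frame(chrom = "chrT",
        start = c(101L, 201L), end = c(104L, 204L)))
    prof <- new("CoverageProfile", target = ts,
        depth = c(rep(25L, 4), rep(0L, 4)))
    res <- gcByCoverageClass(ts, prof, ref)
    expect_equal(res$nTargets, c(1L, 1L, 1L, 1L))
    expect_equal(res$meanGC[res$class == "0x"], 0.0)
    expect_equal(res$meanGC[res$class == "<10x"], 0.0)
    expect_equal(res$meanGC[res$class == ">=10x"], 1.0)
    expect_equal(res$meanGC[res$class == ">=20x"], 1.0)
})

test_that("allele balance averages reference-weighted evidence", {
    cols <- list(
        list(chrom = "c", pos = 10L, ref = "A",
            bases = c("A", "G"), quals = c(30, 30)),          # 0.50
        list(chrom = "c", pos = 20L, ref = "A",
            bases = c("A", "A", "G", "G"), quals = c(30, 24, 23, 23)))
    pt <- columnsToPileup(cols)
    v <- callSnvs(pt)
    res <- alleleBalanceSummary(v, pt, regions = list(genome = NULL),
        minDepths = 0L)
    expect_equal(res$n, 2L)
    expect_equal(res$meanBalance, (0.5 + 54 / 100) / 2)
    # count mode weighs reads, not qualities
    resC <- alleleBalanceSummary(v, pt, regions = list(genome = NULL),
        minDepths = 0L, mode = "count")
    expect_equal(resC$meanBalance, 0.5)
    # empty stratum is flagged with n = 0 and NA mean
    res2 <- alleleBalanceSummary(v, pt, regions = list(genome = NULL),
        minDepths = c(0L, 50L))
    expect_equal(res2$n[res2$minDepth == 50], 0L)
    expect_true(is.na(res2$meanBalance[res2$minDepth == 50]))
})

test_that("variant sharing tabulates subset patterns and agreement", {
    mkCalls <- function(pos, geno) {
        df <- S4Vectors::DataFrame(chrom = "c", pos = as.integer(pos),
            ref = "A", alt = "G", depth = 30L, variantQuality = 30,
            qualityRatio = 0.5, genotype = geno,
            genotypeClass = "heterozygous")
        new("VariantCalls", calls = df)
    }
    A <- mkCalls(c(100, 200), c("A/G", "A/G"))
    B <- mkCalls(c(200, 300), c("A/G", "A/G"))
    res <- variantSharing(list(A = A, B = B))
    expect_equal(res$total, 3L)
    expect_equal(res$sharedByAll, 1L)
    cnt <- setNames(res$patterns$n, res$patterns$pattern)
    expect_equal(cnt[["A"]], 1L)
    expect_equal(cnt[["B"]], 1L)
    expect_equal(cnt[["A+B"]], 1L)
    # identical sets: everything shared with full genotype agreement
    res2 <- variantSharing(list(A = A, A2 = A))
    expect_equal(res2$sharedByAll, 2L)
    expect_equal(res2$patterns$nGenotypeConcordant, 2L)
    # disagreeing genotype at the shared position
    B2 <- mkCalls(c(200, 300), c("G/G", "A/G"))
    res3 <- variantSharing(list(A = A, B = B2))
    shared <- res3$patterns[res3$patterns$pattern == "A+B", ]
    expect_equal(shared$nGenotypeConcordant, 0L)
})

test_that("chip harmonization filters and strand-flips genotypes", {
    chip <- data.frame(snpId = sprintf("s%d", 1:4), chrom = "c",
        pos = c(10L, 20L, 30L, 40L),
        alleleA = c("A", "A", "A", "A"), alleleB = c("G", "G", "G", "C"),
        genotype = c("A/G", "A/G", "A/G", "A/C"),
        flankStrand = c("+", "+", "+", "-"),
        callRate = c(0.99, 0.94, 0.99, 0.99),
        mappingCount = c(1L, 1L, 2L, 1L))
    h <- harmonizeChip(chip)
    expect_identical(h$snpId, c("s1", "s4"))
    expect_equal(attr(h, "nDroppedCallRate"), 1L)
    expect_equal(attr(h, "nDroppedMapping"), 1L)
    # minus-strand A/C becomes T/G
    expect_identical(h$genotype[h$snpId == "s4"], "T/G")
    expect_identical(h$alleleA[h$snpId == "s4"], "T")
    chip$alleleA[1] <- "Z"
    expect_error(harmonizeChip(chip), "allele characters")
})

test_that("chip concordance tabulates by depth bin and genotype class", {
    # 100 het chip SNPs at depth 30; 98 sequenced het, 2 hom-ref
    n <- 100L
    cols <- lapply(seq_len(n), function(i) {
        bases <- if (i <= 98) c(rep("A", 15), rep("G", 15))
            else rep("A", 30)
        list(chrom = "c", pos = i * 10L, ref = "A", bases = bases,
            quals = rep(30, length(bases)))
    })
    pt <- columnsToPileup(cols)
    v <- callSnvs(pt)
    chip <- data.frame(snpId = sprintf("s%03d", 1:n), chrom = "c",
        pos = seq_len(n) * 10L, alleleA = "A", alleleB = "G",
        genotype = "A/G", flankStrand = "+", callRate = 1,
        mappingCount = 1L)
    ct <- chipConcordance(v, pt, chip, bins = list(c(21, Inf)))
    ov <- concordanceOverall(ct)
    expect_equal(ov$n, 100L)
    expect_equal(ov$correlation, 0.98)
    cells <- concordanceCells(ct)
    het <- cells[cells$chipClass == "het", ]
    expect_equal(het$concordant, 98L)
    expect_equal(het$discordant, 2L)
    # per-cell counts sum to the bin total
    expect_equal(sum(cells$concordant + cells$discordant), ov$n)
    # empty bins are defined but flagged NA
    ct2 <- chipConcordance(v, pt, chip, bins = list(c(1, 5)))
    expect_true(is.na(concordanceOverall(ct2)$correlation))
    expect_equal(concordanceOverall(ct2)$n, 0L)
})

test_that("locus coverage lookups report depth, flags and alleles", {
    prof <- profileFromDepths(c(rep(12L, 10), rep(30L, 10), rep(0L, 10)))
    loci <- data.frame(chrom = "chrT", pos = c(105L, 115L, 125L))
    res <- coverageAtLoci(prof, loci)
    expect_equal(res$depth, c(12L, 30L, 0L))
    expect_identical(res$ge10, c(TRUE, TRUE, FALSE))
    expect_identical(res$ge20, c(FALSE, TRUE, FALSE))
    expect_error(coverageAtLoci(prof,
        data.frame(chrom = "chrZ", pos = 1L)), "unknown chromosome")
    # alleles joined from variant calls
    cols <- list(list(chrom = "chrT", pos = 115L, ref = "A",
        bases = c("A", "G"), quals = c(30, 30)))
    pt <- columnsToPileup(cols)
    v <- callSnvs(pt)
    res2 <- coverageAtLoci(prof, loci, variants = v)
    expect_identical(res2$alleles, c(NA, "G", NA))
})
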
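#' Allele-quality ratio of a pileup column
#'
#' The ratio A/(A+B) over summed allele qualities that drives genotype
#' re-calling.  The rules, applied in order:
#' \enumerate{
#'   \item calls spanning more than two distinct alleles: ratio -1
#'     (multiallelic, filtered downstream);
#'   \item both reference and one variant allele present: A = sum of
#'     reference call qualities, B = sum of variant call qualities;
#'   \item two distinct variant alleles, no reference call: A = the larger
#'     allele-quality sum, B = the smaller (ties broken lexicographically;
#'     the ratio is 0.5 either way);
#'   \item all calls one variant allele: ratio 0.
#' }
#' \code{N} calls are ignored for allele accounting.  A reference-only
#' column is not a variant and raises an error.
#'
#' @param bases Character vector of call bases at the column.
#' @param quals Numeric allele qualities, parallel to \code{bases}.
#' @param ref The reference base.
#' @return A list: \code{ratio} (in [0,1] or -1), \code{a}, \code{b} (the
#'   alleles whose quality sums form the numerator and the rest of the
#'   denominator; \code{NA} where not applicable).
#' @examples
#' qualityRatio(c("A", "A", "G", "G"), c(30, 30, 30, 30), "A")$ratio  # 0.5
#' @export
qualityRatio <- function(bases, quals, ref) {
    stopifnot(length(bases) == length(quals))
    keep <- bases != "N"
    bases <- bases[keep]; quals <- quals[keep]
    alleles <- unique(bases)
    varAlleles <- setdiff(alleles, ref)
    if (!length(varAlleles))
        stop("column has reference-only calls: not a variant position")
    if (length(alleles) > 2L)
        return(list(ratio = -1, a = NA_character_, b = NA_character_))
    if (ref %in% alleles) {
        a <- sum(quals[bases == ref])
        b <- sum(quals[bases == varAlleles])
        return(list(ratio = a / (a + b), a = ref, b = varAlleles))
    }
    if (length(varAlleles) == 2L) {
        sums <- vapply(varAlleles, function(v) sum(quals[bases == v]),
            numeric(1L))
        o <- order(-sums, varAlleles)
        sums <- sums[o]; varAlleles <- varAlleles[o]
        return(list(ratio = unname(sums[1L] / sum(sums)),
            a = varAlleles[1L], b = varAlleles[2L]))
    }
    list(ratio = 0, a = ref, b = varAlleles)
}

#' Genotype class from a quality ratio
#'
#' A ratio of more than 0.8 is considered a reference call (filtered from
#' the variant list); between 0.2 and 0.8 inclusive, heterozygous; below
#' 0.2, homozygous variant; -1, multiallelic (filtered).  Band edges are
#' configurable.
#'
#' @param ratio Numeric vector of quality ratios (in [0,1] or -1).
#' @param lower,upper Heterozygous band edges (closed interval).
#' @return Character vector with values \code{"reference"},
#'   \code{"heterozygous"}, \code{"homozygous_variant"},
#'   \code{"multiallelic"}.
#' @export
classifyGenotype <- function(ratio, lower = 0.2, upper = 0.8) {
    bad <- !(ratio == -1 | (ratio >= 0 & ratio <= 1))
    if (any(bad)) stop("quality ratio outside [0,1] and not -1: ",
        ratio[bad][1L])
    ifelse(ratio == -1, "multiallelic",
        ifelse(ratio > upper, "reference",
            ifelse(ratio >= lower, "heterozygous", "homozygous_variant")))
}

.genotypeString <- function(class, ref, a, b) {
    switch(class,
        heterozygous = if (identical(a, ref)) paste(ref, b, sep = "/")
            else paste(sort(c(a, b)), collapse = "/"),
        homozygous_variant = if (identical(a, ref)) paste(b, b, sep = "/")
            else paste(a, a, sep = "/"),
        reference = paste(ref, ref, sep = "/"),
        multiallelic = NA_character_)
}

#' Call and re-genotype SNVs from a pileup
#'
#' A column is a candidate when it has at least one variant (non-reference,
#' non-N) call whose variant allele quality reaches
#' \code{minVariantQuality}.  Each candidate receives a
#' \code{\link{qualityRatio}} and a \code{\link{classifyGenotype}} class;
#' columns classified \code{reference} or \code{multiallelic} are filtered
#' from the returned list unless \code{includeFiltered = TRUE}.
#'
#' @param pileup A \linkS4class{PileupTable}.
#' @param minVariantQuality Candidate threshold on the variant allele
#'   quality (default 20).
#' @param qualityMode \code{"max"} (default): the variant allele quality is
#'   the maximum single-call quality of any variant allele; \code{"sum"}:
#'   the maximum per-allele quality sum.
#' @param lower,upper Heterozygous band (see \code{\link{classifyGenotype}}).
#' @param includeFiltered Keep filtered classes in the output.
#' @return A \linkS4class{VariantCalls}.
#' @export
callSnvs <- function(pileup, minVariantQuality = 20, qualityMode = c("max",
                     "sum"), lower = 0.2, upper = 0.8,
                     includeFiltered = FALSE) {
    qualityMode <- match.arg(qualityMode)
    calls <- pileup@calls
    posn <- pileup@positions
    baseSplit <- split(calls$base, calls$posIndex)
    qualSplit <- split(calls$qual, calls$posIndex)
    pidxs <- as.integer(names(baseSplit))
    n <- length(pidxs)
    keep <- logical(n)
    alt <- geno <- cls <- character(n)
    vqual <- ratio <- numeric(n)
    depth <- integer(n)
    for (k in seq_len(n)) {
        pidx <- pidxs[k]
        ref <- posn$ref[pidx]
        bases <- baseSplit[[k]]; quals <- qualSplit[[k]]
        isVar <- bases != ref & bases != "N"
        if (!any(isVar)) next
        vq <- if (qualityMode == "max") max(quals[isVar])
            else max(rowsum(quals[isVar], bases[isVar]))
        if (vq < minVariantQuality) next
        qr <- qualityRatio(bases, quals, ref)
        gcls <- classifyGenotype(qr$ratio, lower, upper)
        keep[k] <- TRUE
        depth[k] <- length(bases)
        vqual[k] <- vq
        ratio[k] <- qr$ratio
        cls[k] <- gcls
        alt[k] <- if (gcls == "multiallelic")
            paste(sort(unique(bases[isVar])), collapse = ",")
            else if (identical(qr$a, ref)) qr$b
            else paste(sort(c(qr$a, qr$b)), collapse = ",")
        geno[k] <- .genotypeString(gcls, ref, qr$a, qr$b)
    }
    out <- data.frame(chrom = posn$chrom[pidxs], pos = posn$pos[pidxs],
        ref = posn$ref[pidxs], alt = alt, depth = depth,
        variantQuality = vqual, qualityRatio = ratio, genotype = geno,
        genotypeClass = cls,
        stringsAsFactors = FALSE)[keep, , drop = FALSE]
    if (!includeFiltered)
        out <- out[!(out$genotypeClass %in% c("reference", "multiallelic")), ,
            drop = FALSE]
    out <- out[order(out$chrom, out$pos), , drop = FALSE]
    rownames(out) <- NULL
    new("VariantCalls", calls = as(out, "DataFrame"))
}

#' @rdname accessors
#' @export
setMethod("variantRecords", "VariantCalls",
    function(x) as.data.frame(x@calls))

#' @rdname accessors
#' @export
setMethod("length", "VariantCalls", function(x) nrow(x@calls))

setMethod("show", "VariantCalls", function(object) {
    cls <- table(object@calls$genotypeClass)
    cat(sprintf("VariantCalls: %d call(s) [%s]\n", nrow(object@calls),
        paste(names(cls), as.integer(cls), sep = ":", collapse = ", ")))
})

#' Filter indel candidates
#'
#' An indel is kept when its call quality reaches \code{minQuality}
#' (default 50) and no alleles other than the indel allele and the
#' reference allele were observed at the position.
#'
#' @param indels \code{data.frame} with at least \code{quality},
#'   \code{refAllele}, \code{indelAllele} and a list column
#'   \code{observedAlleles} (character vectors of distinct alleles seen at
#'   the position).
#' @param minQuality Minimum call quality (default 50).
#' @return The kept rows, with the \code{observedAlleles} column intact.
#' @export
filterIndels <- function(indels, minQuality = 50) {
    stopifnot(all(c("quality", "refAllele", "indelAllele",
        "observedAlleles") %in% colnames(indels)))
    cleanAlleles <- mapply(function(obs, ref, ind)
        all(obs %in% c(ref, ind)),
        indels$observedAlleles, indels$refAllele, indels$indelAllele)
    indels[indels$quality >= minQuality & cleanAlleles, , drop = FALSE]
}

#' Exact heterozygote-call probability by depth
#'
#' With equal base qualities the quality ratio at a truly heterozygous site
#' reduces to the fraction of reads sampling the reference allele, so the
#' probability that the site is classified heterozygous is an exact
#' binomial tail sum: \eqn{P(lower \le X/d \le upper)} with
#' \eqn{X \sim Binomial(d, samplingProb)}.  At depth 1 the ratio is 0 or 1
#' and the probability is 0.
#'
#' @param depths Integer vector of depths (> 0).
#' @param samplingProb Probability that a read carries the reference allele
#'   (0.5 for unbiased sampling).
#' @param lower,upper Heterozygous band edges.
#' @return \code{data.frame(depth, pHet)}.
#' @examples
#' hetCallAccuracyCurve(11)$pHet  # 1914/2048
#' @export
hetCallAccuracyCurve <- function(depths, samplingProb = 0.5, lower = 0.2,
                                 upper = 0.8) {
    if (any(depths <= 0)) stop("'depths' must be positive")
    pHet <- vapply(as.integer(depths), function(d) {
        k <- 0:d
        sum(dbinom(k[k / d >= lower & k / d <= upper], d, samplingProb))
    }, numeric(1L))
    data.frame(depth = as.integer(depths), pHet = pHet)
}

#' Write variant calls as TSV or minimal VCF
#'
#' @param x A \linkS4class{VariantCalls}.
#' @param path Output path.
#' @param format \code{"tsv"} or \code{"vcf"} (GT and DP plus the quality
#'   ratio as an INFO key).
#' @export
writeVariants <- function(x, path, format = c("tsv", "vcf")) {
    format <- match.arg(format)
    df <- as.data.frame(x@calls)
    if (format == "tsv") {
        write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
        return(invisible(path))
    }
    gt <- vapply(seq_len(nrow(df)), function(i) {
        al <- strsplit(df$genotype[i], "/", fixed = TRUE)[[1L]]
        alts <- strsplit(df$alt[i], ",", fixed = TRUE)[[1L]]
        paste(match(al, c(df$ref[i], alts)) - 1L, collapse = "/")
    }, character(1L))
    lines <- c("##fileformat=VCFv4.2",
        "##INFO=<ID=QR,Number=1,Type=Float,Description=\"Allele quality ratio\">",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
        "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsample",
        sprintf("%s\t%d\t.\t%s\t%s\t%.0f\tPASS\tQR=%g\tGT:DP\t%s:%d",
            df$chrom, df$pos, df$ref, df$alt, df$variantQuality,
            df$qualityRatio, gt, df$depth))
    writeLines(lines, path)
    invisible(path)
}
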
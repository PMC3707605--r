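#' Clip adaptor sequence from small-RNA reads
#'
#' Removes the adaptor from one end of each read. On the 3' side, the clip
#' starts at the leftmost position where the rest of the read matches a
#' prefix of the adaptor (a full internal occurrence clips everything from
#' there to the read end — adapter read-through — and a partial adaptor
#' prefix may overlap the read's 3' end). On the 5' side, a partial
#' adaptor suffix overlapping the read start is removed. Clipping always
#' starts from one of the ends; when both ends match, the longer clip wins
#' (ties go to the 3' end). Reads shorter than \code{minLen} after
#' clipping are dropped (returned as \code{NA}).
#'
#' @param reads character vector of read sequences.
#' @param adaptor non-empty adaptor sequence.
#' @param minLen minimum surviving read length (default 16 bp).
#' @param minMatch minimum number of matching adaptor bases required to
#'   clip (default 1: any end-overlap of the adaptor is removed).
#' @return Character vector of clipped reads; \code{NA} marks dropped reads.
#' @examples
#' clipAdaptor(c("ACGTACGTACGTACGTACGTAA", "ACGTACGTACGTACGTTTTTTT"),
#'             adaptor = "TTTTTTTTTT")
#' @export
clipAdaptor <- function(reads, adaptor, minLen = 16L, minMatch = 1L) {
    if (!is.character(adaptor) || length(adaptor) != 1 || !nzchar(adaptor))
        stop("adaptor must be a non-empty string")
    stopifnot(all(nzchar(reads)))
    clip3len <- function(read, ad) {
        L <- nchar(read); la <- nchar(ad)
        for (p in seq_len(L)) {
            mlen <- min(L - p + 1L, la)
            if (mlen < minMatch) break
            if (substr(read, p, p + mlen - 1L) == substr(ad, 1L, mlen))
                return(L - p + 1L)
        }
        0L
    }
    clip5len <- function(read, ad) {
        L <- nchar(read); la <- nchar(ad)
        for (q in rev(seq_len(min(L, la)))) {
            if (q < minMatch) break
            if (substr(read, 1L, q) == substr(ad, la - q + 1L, la))
                return(q)
        }
        0L
    }
    vapply(reads, function(rd) {
        c3 <- clip3len(rd, adaptor)
        c5 <- clip5len(rd, adaptor)
        L <- nchar(rd)
        out <- if (c3 >= c5 && c3 > 0L) substr(rd, 1L, L - c3)
               else if (c5 > 0L) substr(rd, c5 + 1L, L)
               else rd
        if (nchar(out) < minLen) NA_character_ else out
    }, character(1), USE.NAMES = FALSE)
}

#' Count reads on miRNA target regions
#'
#' A read is "on target" if it overlaps the target region by at least one
#' base; a read overlapping several targets increments each of them.
#'
#' @param alignments \code{GRanges} of aligned reads.
#' @param targets named \code{GRanges} of miRNA target regions.
#' @param ignoreStrand overlap test ignores strand (default TRUE).
#' @return Named integer vector of on-target read counts (one count-matrix
#'   column).
#' @examples
#' fx <- generateAlignments(nReads = 10, nTargets = 2, seed = 3)
#' countOnTarget(fx$alignments, fx$targets)
#' @export
countOnTarget <- function(alignments, targets, ignoreStrand = TRUE) {
    stopifnot(is(alignments, "GRanges"), is(targets, "GRanges"))
    if (is.null(names(targets)))
        stop("targets must be named")
    badA <- which(GenomicRanges::width(alignments) < 1)
    if (length(badA))
        stop("malformed (empty) alignment interval at record ",
             badA[1])
    badT <- which(GenomicRanges::width(targets) < 1)
    if (length(badT))
        stop("malformed (empty) target interval: ", names(targets)[badT[1]])
    cts <- GenomicRanges::countOverlaps(targets, alignments,
                                        minoverlap = 1L,
                                        ignore.strand = ignoreStrand)
    stats::setNames(as.integer(cts), names(targets))
}

matchComparison <- function(comparison) {
    comparison <- match.arg(comparison, c("T/N", "M/N", "M/T"))
    list(label = comparison,
         num = substr(comparison, 1, 1),
         den = substr(comparison, 3, 3))
}

#' Per-patient log2 count ratios for a tissue comparison
#'
#' For each patient with both tissues of the comparison, computes
#' \code{log2((cNum + pseudocount) / (cDen + pseudocount))} per miRNA.
#'
#' @param counts a \linkS4class{MirnaCounts}.
#' @param comparison one of \code{"T/N"}, \code{"M/N"}, \code{"M/T"}.
#' @param pseudocount added to both counts (default 1); with pseudocount 0
#'   any zero count is an error.
#' @return Numeric matrix miRNA x patient of log2 ratios.
#' @export
log2RatioTable <- function(counts, comparison = "T/N", pseudocount = 1) {
    stopifnot(is(counts, "MirnaCounts"))
    cmp <- matchComparison(comparison)
    cd <- colData(counts)
    cts <- SummarizedExperiment::assay(counts, "counts")
    patients <- unique(cd$patient)
    cols <- lapply(patients, function(p) {
        iN <- which(cd$patient == p & cd$tissue == cmp$num)
        iD <- which(cd$patient == p & cd$tissue == cmp$den)
        if (length(iN) != 1 || length(iD) != 1) return(NULL)
        a <- cts[, iN] + pseudocount
        b <- cts[, iD] + pseudocount
        if (any(a <= 0) || any(b <= 0))
            stop("zero counts with pseudocount ", pseudocount,
                 "; use a positive pseudocount")
        log2(a / b)
    })
    keep <- !vapply(cols, is.null, logical(1))
    if (!any(keep))
        stop("no patient has both tissues of comparison ", cmp$label)
    out <- do.call(cbind, cols[keep])
    dimnames(out) <- list(rownames(cts), patients[keep])
    out
}

#' Center log2 ratios so the per-comparison median is zero
#'
#' Subtracts the median of the full ratio collection (one scalar per
#' comparison), the normalization used between matched tissues. Idempotent.
#'
#' @param ratios numeric matrix (or vector) of log2 ratios.
#' @return Centered ratios of the same shape.
#' @export
medianCenter <- function(ratios) {
    ratios - stats::median(ratios, na.rm = TRUE)
}

#' Differential-expression t-test on per-patient log2 ratios
#'
#' One-sample two-sided t-test of each miRNA's centered per-patient log2
#' ratios against zero (the paired design: each ratio compares two tissues
#' of one patient). miRNAs with fewer than two finite ratios or zero
#' variance get p = 1 and are flagged.
#'
#' @param ratios numeric matrix miRNA x patient of (centered) log2 ratios.
#' @return data.frame with \code{mirna}, \code{meanRatio}, \code{t},
#'   \code{p}, \code{n} (finite ratios used), \code{flag} (TRUE when the
#'   test was degenerate).
#' @export
differentialTest <- function(ratios) {
    ratios <- as.matrix(ratios)
    if (is.null(rownames(ratios)))
        rownames(ratios) <- paste0("row", seq_len(nrow(ratios)))
    res <- lapply(seq_len(nrow(ratios)), function(i) {
        x <- ratios[i, ]
        x <- x[is.finite(x)]
        m <- if (length(x)) mean(x) else NA_real_
        if (length(x) < 2 || stats::sd(x) == 0)
            return(data.frame(meanRatio = m, t = NA_real_, p = 1,
                              n = length(x), flag = TRUE))
        tt <- stats::t.test(x, mu = 0, alternative = "two.sided")
        data.frame(meanRatio = m, t = unname(tt$statistic),
                   p = tt$p.value, n = length(x), flag = FALSE)
    })
    out <- do.call(rbind, res)
    out <- cbind(data.frame(mirna = rownames(ratios),
                            stringsAsFactors = FALSE), out)
    rownames(out) <- NULL
    out
}

#' Full differential-expression pipeline for one comparison
#'
#' Chains [log2RatioTable()], [medianCenter()] and a test. The default
#' (\code{"ratio-t"}) is the one-sample t-test on per-patient centered
#' ratios; \code{"group-t"} is the unpaired two-sample alternative on
#' per-sample log2 counts.
#'
#' @inheritParams log2RatioTable
#' @param method \code{"ratio-t"} (paired, default) or \code{"group-t"}.
#' @param center median-center the ratios first (default TRUE).
#' @param adjust apply Benjamini-Hochberg correction and add a
#'   \code{pAdjusted} column (default FALSE: raw p-values with fixed
#'   thresholds are reported).
#' @return The [differentialTest()] data.frame plus a \code{comparison}
#'   column; the centered ratio matrix is attached as attribute
#'   \code{"ratios"}.
#' @examples
#' cohort <- generateCountCohort(CohortSpec(nMirnas = 40, seed = 2))
#' head(differentialExpression(cohort$counts, "T/N"))
#' @export
differentialExpression <- function(counts, comparison = "T/N",
                                   pseudocount = 1,
                                   method = c("ratio-t", "group-t"),
                                   center = TRUE, adjust = FALSE) {
    method <- match.arg(method)
    rat <- log2RatioTable(counts, comparison, pseudocount)
    if (center) rat <- medianCenter(rat)
    if (method == "ratio-t") {
        out <- differentialTest(rat)
    } else {
        cmp <- matchComparison(comparison)
        cd <- colData(counts)
        cts <- SummarizedExperiment::assay(counts, "counts")
        lg <- log2(cts + pseudocount)
        a <- lg[, cd$tissue == cmp$num, drop = FALSE]
        b <- lg[, cd$tissue == cmp$den, drop = FALSE]
        res <- lapply(seq_len(nrow(lg)), function(i) {
            xa <- a[i, ]; xb <- b[i, ]
            if (stats::sd(c(xa, xb)) == 0)
                return(data.frame(meanRatio = mean(rat[i, ]), t = NA_real_,
                                  p = 1, n = length(c(xa, xb)), flag = TRUE))
            tt <- stats::t.test(xa, xb)
            data.frame(meanRatio = mean(rat[i, ]), t = unname(tt$statistic),
                       p = tt$p.value, n = length(c(xa, xb)), flag = FALSE)
        })
        out <- cbind(data.frame(mirna = rownames(lg)), do.call(rbind, res))
    }
    out$comparison <- comparison
    if (adjust) out$pAdjusted <- stats::p.adjust(out$p, method = "BH")
    attr(out, "ratios") <- rat
    out
}

#' Partition detected miRNAs into tissue-specificity Venn regions
#'
#' A miRNA is "detected" in a tissue class if it has at least one read in
#' at least one sample of that class (\code{allSamples = TRUE} instead
#' requires every sample of the class). The seven Venn regions over
#' \{N, T, M\} partition the detected set; all-zero miRNAs fall in no
#' region.
#'
#' @param counts a \linkS4class{MirnaCounts}.
#' @param allSamples require detection in every sample of the class.
#' @return Named list of the seven regions (\code{"N"}, \code{"T"},
#'   \code{"M"}, \code{"NT"}, \code{"NM"}, \code{"TM"}, \code{"NTM"}),
#'   each a character vector of miRNA names.
#' @export
detectionPartition <- function(counts, allSamples = FALSE) {
    stopifnot(is(counts, "MirnaCounts"))
    cd <- colData(counts)
    cts <- SummarizedExperiment::assay(counts, "counts")
    det <- sapply(c("N", "T", "M"), function(tt) {
        idx <- which(cd$tissue == tt)
        if (!length(idx)) return(rep(FALSE, nrow(cts)))
        sub <- cts[, idx, drop = FALSE] > 0
        if (allSamples) rowSums(sub) == length(idx) else rowSums(sub) > 0
    })
    rn <- rownames(cts)
    reg <- function(n, t, m)
        rn[det[, "N"] == n & det[, "T"] == t & det[, "M"] == m]
    list(N = reg(TRUE, FALSE, FALSE), T = reg(FALSE, TRUE, FALSE),
         M = reg(FALSE, FALSE, TRUE), NT = reg(TRUE, TRUE, FALSE),
         NM = reg(TRUE, FALSE, TRUE), TM = reg(FALSE, TRUE, TRUE),
         NTM = reg(TRUE, TRUE, TRUE))
}

#' Top up- and down-regulated miRNAs
#'
#' Filters to p <= \code{pMax}, ranks by mean centered log2 ratio and
#' returns the \code{k} most up- and most down-regulated miRNAs. Ties break
#' by smaller p, then lexical name.
#'
#' @param results a [differentialTest()]/[differentialExpression()] result.
#' @param k list length per direction (default 25).
#' @param pMax p-value threshold (default 0.05).
#' @return List with data.frames \code{up} and \code{down}.
#' @export
topRegulated <- function(results, k = 25L, pMax = 0.05) {
    stopifnot(k >= 0)
    keep <- results[results$p <= pMax & is.finite(results$meanRatio), ,
                    drop = FALSE]
    ord <- function(decreasing) {
        o <- order(if (decreasing) -keep$meanRatio else keep$meanRatio,
                   keep$p, keep$mirna)
        keep[o, , drop = FALSE]
    }
    up <- ord(TRUE); down <- ord(FALSE)
    list(up = utils::head(up[up$meanRatio > 0, , drop = FALSE], k),
         down = utils::head(down[down$meanRatio < 0, , drop = FALSE], k))
}

#' Relative quantification by the delta-delta-Ct method
#'
#' Per sample, \eqn{\Delta Ct = Ct_{target} - Ct_{reference}}; per target
#' and tissue, \eqn{\Delta\Delta Ct = \overline{\Delta Ct}(tissue) -
#' \overline{\Delta Ct}(baseline)} and fold change \eqn{2^{-\Delta\Delta Ct}}.
#'
#' @param ct data.frame with columns \code{sample}, \code{tissue},
#'   \code{gene}, \code{ct}.
#' @param referenceGene internal control gene name (default "RNU44").
#' @param baselineTissue tissue the others are compared to (default "N").
#' @return List: \code{deltaCt} (per-sample data.frame) and \code{result}
#'   (data.frame \code{gene}, \code{tissue}, \code{deltaDeltaCt},
#'   \code{foldChange}).
#' @examples
#' tab <- generateCtTable(nSamples = 4, seed = 1)
#' deltaDeltaCt(tab$ct)$result
#' @export
deltaDeltaCt <- function(ct, referenceGene = "RNU44", baselineTissue = "N") {
    stopifnot(all(c("sample", "tissue", "gene", "ct") %in% colnames(ct)))
    if (!referenceGene %in% ct$gene)
        stop("reference gene '", referenceGene, "' not in table")
    ref <- ct[ct$gene == referenceGene, ]
    refCt <- stats::setNames(ref$ct, ref$sample)
    tg <- ct[ct$gene != referenceGene, ]
    if (any(!tg$sample %in% names(refCt)))
        stop("reference gene missing for some samples")
    tg$deltaCt <- tg$ct - refCt[tg$sample]
    agg <- aggregate(deltaCt ~ gene + tissue, tg, mean)
    base <- agg[agg$tissue == baselineTissue, ]
    if (!nrow(base)) stop("baseline tissue '", baselineTissue, "' absent")
    baseMap <- stats::setNames(base$deltaCt, base$gene)
    res <- agg[agg$tissue != baselineTissue, , drop = FALSE]
    res$deltaDeltaCt <- res$deltaCt - baseMap[res$gene]
    res$foldChange <- 2^(-res$deltaDeltaCt)
    res$deltaCt <- NULL
    rownames(res) <- NULL
    list(deltaCt = tg[, c("sample", "tissue", "gene", "deltaCt")],
         result = res)
}
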
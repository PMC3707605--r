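#' Generate synthetic read alignments, target intervals and expected counts
#'
#' Builds a single synthetic reference with \code{nTargets} disjoint
#' miRNA-style target intervals and \code{nReads} aligned reads, then adds
#' two deterministic boundary reads for the first target: one overlapping it
#' by exactly one base (which the on-target rule must count) and one ending
#' exactly one base before it (zero overlap, never counted). Expected
#' per-target counts are computed by construction with an explicit
#' interval-overlap enumeration.
#'
#' @param nReads number of random reads.
#' @param nTargets number of target regions.
#' @param refLength reference length in bases.
#' @param readLength read length (default 22 nt, mature miRNA size).
#' @param seed integer RNG seed.
#' @return A list: \code{alignments} (\code{GRanges} with \code{qname}),
#'   \code{targets} (named \code{GRanges}), \code{expected} (named integer
#'   vector of on-target counts, >=1-base overlap rule).
#' @examples
#' fx <- generateAlignments(nReads = 20, nTargets = 3, seed = 3)
#' fx$expected
#' @export
generateAlignments <- function(nReads = 50L, nTargets = 5L,
                               refLength = 10000L, readLength = 22L,
                               seed = 1L) {
    stopifnot(nReads >= 0, nTargets >= 1,
              refLength > nTargets * 4L * readLength)
    withSeed(seed, {
        ref <- "refS"
        # evenly spaced disjoint targets
        gap <- refLength %/% nTargets
        tStart <- (seq_len(nTargets) - 1L) * gap + gap %/% 3L
        targets <- GenomicRanges::GRanges(
            ref, IRanges::IRanges(tStart, width = readLength), strand = "+")
        names(targets) <- sprintf("miR-sim-%03d", seq_len(nTargets))

        starts <- sample.int(refLength - readLength, nReads, replace = TRUE)
        # deterministic boundary reads against target 1:
        # one with exactly 1 base of overlap, one with exactly none
        starts <- c(starts,
                    tStart[1] - readLength + 1L,   # overlap = 1 base
                    tStart[1] - readLength)        # overlap = 0
        aln <- GenomicRanges::GRanges(
            ref, IRanges::IRanges(starts, width = readLength), strand = "+")
        S4Vectors::mcols(aln)$qname <- sprintf("read%04d", seq_along(aln))
        GenomeInfoDb::seqlengths(aln) <- refLength
        GenomeInfoDb::seqlengths(targets) <- refLength

        # truth by construction: explicit pairwise enumeration
        expected <- vapply(seq_along(targets), function(i) {
            ts <- GenomicRanges::start(targets)[i]
            te <- GenomicRanges::end(targets)[i]
            sum(pmin(GenomicRanges::end(aln), te) -
                pmax(GenomicRanges::start(aln), ts) + 1L >= 1L)
        }, integer(1))
        names(expected) <- names(targets)
        list(alignments = aln, targets = targets, expected = expected)
    })
}
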
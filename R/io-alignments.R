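#' Read a SAM file of mapped single-end reads as genomic ranges
#'
#' Supports the minimal dialect used for small-RNA quantification: a header
#' with \code{@SQ} lines plus mapped, single-segment records. The file is
#' converted to BAM internally and loaded with
#' \code{GenomicAlignments::readGAlignments}; reference-space widths honour
#' the CIGAR string.
#'
#' @param path path to a SAM file.
#' @return A \code{GRanges} with one range per mapped read and a
#'   \code{qname} metadata column.
#' @seealso [countOnTarget()], [generateAlignments()]
#' @export
readSamAlignments <- function(path) {
    stopifnot(file.exists(path))
    bam <- Rsamtools::asBam(path,
                            destination = tempfile(fileext = ""),
                            overwrite = TRUE, indexDestination = TRUE)
    ga <- GenomicAlignments::readGAlignments(
        bam, param = Rsamtools::ScanBamParam(what = "qname"))
    gr <- GenomicRanges::granges(ga)
    S4Vectors::mcols(gr)$qname <- S4Vectors::mcols(ga)$qname
    gr
}

#' Read a BED file of miRNA target regions
#'
#' BED intervals (0-based half-open on disk) are converted to the package's
#' internal 1-based closed \code{GRanges} convention by \code{rtracklayer}.
#' Region names must be unique.
#'
#' @param path path to a BED6 (or BED4) file.
#' @return A named \code{GRanges}.
#' @export
readTargetBed <- function(path) {
    gr <- rtracklayer::import(path, format = "BED")
    if (is.null(gr$name) || anyDuplicated(gr$name))
        stop("target regions must carry unique names")
    names(gr) <- gr$name
    gr
}

#' Write alignments as a minimal SAM file
#'
#' Emits a valid header (\code{@HD}, one \code{@SQ} per reference) and one
#' mapped forward/reverse single-segment record per range, with a
#' full-match CIGAR.
#'
#' @param alignments a \code{GRanges}; names (or a \code{qname} column) give
#'   read ids.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeSamFile <- function(alignments, path) {
    qn <- S4Vectors::mcols(alignments)$qname
    if (is.null(qn)) qn <- names(alignments)
    if (is.null(qn)) qn <- sprintf("read%04d", seq_along(alignments))
    sl <- GenomeInfoDb::seqlengths(alignments)
    if (any(is.na(sl)))
        sl[is.na(sl)] <- vapply(names(sl)[is.na(sl)], function(s) {
            max(GenomicRanges::end(alignments)[
                as.character(GenomicRanges::seqnames(alignments)) == s])
        }, numeric(1))
    hdr <- c("@HD\tVN:1.6\tSO:unsorted",
             sprintf("@SQ\tSN:%s\tLN:%d", names(sl), as.integer(sl)))
    flag <- ifelse(as.character(GenomicRanges::strand(alignments)) == "-",
                   16L, 0L)
    w <- GenomicRanges::width(alignments)
    rec <- sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*",
                   qn, flag,
                   as.character(GenomicRanges::seqnames(alignments)),
                   GenomicRanges::start(alignments), w,
                   vapply(w, function(n)
                       paste(rep("A", n), collapse = ""), character(1)))
    writeLines(c(hdr, rec), path)
    invisible(path)
}

#' Write target regions as BED6
#'
#' @param targets a named \code{GRanges}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeTargetBed <- function(targets, path) {
    if (is.null(names(targets)))
        stop("targets must be named")
    x <- targets
    x$name <- names(x)
    rtracklayer::export(x, path, format = "BED")
    invisible(path)
}
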
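markerGroups <- function(counts, comparison, pseudocount = 1) {
    comparison <- match.arg(comparison, c("T/N", "M/N", "T/M", "TM/N"))
    cd <- colData(counts)
    lg <- log2(SummarizedExperiment::assay(counts, "counts") + pseudocount)
    tis <- list("T/N" = list("T", "N"), "M/N" = list("M", "N"),
                "T/M" = list("T", "M"),
                "TM/N" = list(c("T", "M"), "N"))[[comparison]]
    A <- lg[, cd$tissue %in% tis[[1]], drop = FALSE]
    B <- lg[, cd$tissue %in% tis[[2]], drop = FALSE]
    if (!ncol(A) || !ncol(B))
        stop("comparison ", comparison, " has an empty group")
    list(A = A, B = B, label = comparison)
}

#' Rank miRNA biomarkers by Mann-Whitney p-value
#'
#' Scores every miRNA by a two-sided Mann-Whitney U test between the two
#' sample groups of a comparison, on log2 expression. The exact
#' distribution is used for group sizes up to 12; above that the normal
#' approximation. Ranking is ascending by p, ties broken by larger
#' |median difference|, then name; the \code{top} best-scoring miRNAs are
#' attached.
#'
#' @param counts a \linkS4class{MirnaCounts}.
#' @param comparison one of \code{"T/N"}, \code{"M/N"}, \code{"T/M"},
#'   \code{"TM/N"} (tumor and metastasis pooled against normal).
#' @param top size of the best-scoring subset (default 50).
#' @param pseudocount added before log2 (default 1).
#' @return data.frame \code{mirna}, \code{U}, \code{p}, \code{medianDiff},
#'   \code{rank}, ordered by rank, with the top subset's names in attribute
#'   \code{"top"}.
#' @examples
#' cohort <- generateCountCohort(CohortSpec(nMirnas = 30, seed = 5))
#' head(rankMarkers(cohort$counts, "T/N", top = 10))
#' @export
rankMarkers <- function(counts, comparison = "T/N", top = 50L,
                        pseudocount = 1) {
    grp <- markerGroups(counts, comparison, pseudocount)
    exact <- ncol(grp$A) <= 12 && ncol(grp$B) <= 12
    res <- lapply(seq_len(nrow(grp$A)), function(i) {
        x <- grp$A[i, ]; y <- grp$B[i, ]
        wt <- suppressWarnings(
            stats::wilcox.test(x, y, alternative = "two.sided",
                               exact = exact, correct = !exact))
        p <- wt$p.value
        if (!is.finite(p)) p <- 1  # fully tied groups carry no signal
        data.frame(U = unname(wt$statistic), p = p,
                   medianDiff = stats::median(x) - stats::median(y))
    })
    out <- cbind(data.frame(mirna = rownames(grp$A)), do.call(rbind, res))
    o <- order(out$p, -abs(out$medianDiff), out$mirna)
    out <- out[o, , drop = FALSE]
    out$rank <- seq_len(nrow(out))
    rownames(out) <- NULL
    attr(out, "top") <- utils::head(out$mirna, top)
    attr(out, "comparison") <- grp$label
    out
}

#' Strict linear separability of two 2-D point sets
#'
#' Tests whether a direction \eqn{w \neq 0} exists such that every
#' projection of group A lies strictly below every projection of group B
#' (or vice versa) — strict linear separability of the two point clouds,
#' equivalently disjointness of their convex hulls. Solved exactly with a
#' finite candidate set: the max-margin separating direction is always
#' either a difference of one point from each group or an edge normal of
#' one of the two convex hulls, so only those directions need checking.
#' Boundary-touching point sets count as overlapping (not separable); set
#' \code{strict = FALSE} to accept a shared boundary.
#'
#' @param pointsA,pointsB numeric matrices (n x 2) of expression points.
#' @param strict require strict separation (default TRUE).
#' @return List: \code{separable} (logical) and \code{witness} (unit
#'   2-vector such that all of A projects below all of B, or NULL).
#' @examples
#' pairSeparable(rbind(c(0, 0), c(1, 0)), rbind(c(0, 1), c(1, 1)))
#' @export
pairSeparable <- function(pointsA, pointsB, strict = TRUE) {
    A <- matrix(as.numeric(pointsA), ncol = 2)
    B <- matrix(as.numeric(pointsB), ncol = 2)
    if (!nrow(A) || !nrow(B)) stop("both groups need at least one point")
    if (any(!is.finite(A)) || any(!is.finite(B)))
        stop("non-finite coordinates")
    hullEdgeNormals <- function(P) {
        h <- unique(P[grDevices::chull(P), , drop = FALSE])
        if (nrow(h) < 2) return(NULL)
        e <- h[c(seq_len(nrow(h))[-1], 1), , drop = FALSE] - h
        cbind(-e[, 2], e[, 1])
    }
    diffs <- matrix(rep(t(B), nrow(A)), ncol = 2, byrow = TRUE) -
             A[rep(seq_len(nrow(A)), each = nrow(B)), , drop = FALSE]
    cand <- rbind(diffs, hullEdgeNormals(A), hullEdgeNormals(B))
    nz <- rowSums(cand^2) > 0
    cand <- cand[nz, , drop = FALSE]
    for (i in seq_len(nrow(cand))) {
        w <- cand[i, ] / sqrt(sum(cand[i, ]^2))
        pa <- as.numeric(A %*% w); pb <- as.numeric(B %*% w)
        # margin must clear numerical noise: exact ties count as overlap
        tol <- 1e-9 * (max(abs(c(pa, pb))) + 1)
        lim <- if (strict) tol else -tol
        if (min(pb) - max(pa) > lim)
            return(list(separable = TRUE, witness = as.numeric(w)))
        if (min(pa) - max(pb) > lim)
            return(list(separable = TRUE, witness = as.numeric(-w)))
    }
    list(separable = FALSE, witness = NULL)
}

#' Screen all two-miRNA combinations for group separation
#'
#' Evaluates every unordered pair from the top-ranked miRNA list of a
#' comparison: the pair's 2-D per-sample log2-expression points are tested
#' with [pairSeparable()]; separable pairs are called "promising".
#'
#' @inheritParams rankMarkers
#' @param scores optional precomputed [rankMarkers()] result for this
#'   comparison (saves recomputation).
#' @param strict passed to [pairSeparable()].
#' @return List: \code{calls} (data.frame \code{mirna1}, \code{mirna2},
#'   \code{separable}, \code{w1}, \code{w2}, in deterministic rank order)
#'   and \code{nPromising}.
#' @examples
#' cohort <- generateCountCohort(CohortSpec(nMirnas = 25, seed = 5))
#' screenPairs(cohort$counts, "T/N", top = 8)$nPromising
#' @export
screenPairs <- function(counts, comparison = "T/N", top = 50L,
                        pseudocount = 1, scores = NULL, strict = TRUE) {
    grp <- markerGroups(counts, comparison, pseudocount)
    if (is.null(scores))
        scores <- rankMarkers(counts, comparison, top, pseudocount)
    sel <- attr(scores, "top")
    if (length(sel) < 2)
        return(list(calls = data.frame(mirna1 = character(),
                                       mirna2 = character(),
                                       separable = logical(),
                                       w1 = numeric(), w2 = numeric()),
                    nPromising = 0L))
    pairsIdx <- utils::combn(seq_along(sel), 2)
    calls <- lapply(seq_len(ncol(pairsIdx)), function(k) {
        m1 <- sel[pairsIdx[1, k]]; m2 <- sel[pairsIdx[2, k]]
        ps <- pairSeparable(cbind(grp$A[m1, ], grp$A[m2, ]),
                            cbind(grp$B[m1, ], grp$B[m2, ]),
                            strict = strict)
        data.frame(mirna1 = m1, mirna2 = m2, separable = ps$separable,
                   w1 = if (ps$separable) ps$witness[1] else NA_real_,
                   w2 = if (ps$separable) ps$witness[2] else NA_real_)
    })
    calls <- do.call(rbind, calls)
    list(calls = calls, nPromising = sum(calls$separable))
}
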
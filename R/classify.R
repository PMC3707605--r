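#' The ten therapeutic-effect subgroups (plus "none")
#'
#' Five effect groups — desired, weak, side effect, aggravated, flip — each
#' split by the direction of the initial tumor/normal de-regulation
#' ("plus": up in the tumor, "minus": down). Components sub-threshold in
#' both comparisons are "none".
#' @return Character vector of the eleven labels.
#' @export
effectLabels <- function() {
    c("desired+", "desired-", "weak+", "weak-", "side+", "side-",
      "aggravated+", "aggravated-", "flip+-", "flip-+", "none")
}

#' Classify a component's expression shift under treatment
#'
#' Given the log2 ratios of tumor vs normal (\code{lambdaTN}) and treated
#' vs normal (\code{lambdaMN}), assigns exactly one therapeutic-effect
#' label using a log2 cutoff \code{c} (default 0.58, about 1.5-fold):
#' for an initially up-regulated component (\code{lambdaTN > c}),
#' \code{lambdaMN > lambdaTN} is "aggravated+", \code{c < lambdaMN <=
#' lambdaTN} is "weak+", \code{|lambdaMN| <= c} is "desired+" (back to
#' normal), and \code{lambdaMN < -c} is "flip+-" (overshoot past normal);
#' mirrored for \code{lambdaTN < -c}. Components initially within the
#' normal band (\code{|lambdaTN| <= c}) become "side+"/"side-" when the
#' treatment pushes them out of it, else "none". Ties sit with the milder
#' label: \code{lambdaMN == lambdaTN} is weak, \code{|lambda| == c} is
#' inside the band.
#'
#' @param lambdaTN,lambdaMN numeric vectors of log2 ratios (recycled).
#' @param cutoff positive log2 cutoff (default 0.58).
#' @return Factor over [effectLabels()], one label per input pair.
#' @examples
#' classifyEffect(c(1, 1, 1, 0), c(0, 2, -1, 1))
#' @export
classifyEffect <- function(lambdaTN, lambdaMN, cutoff = 0.58) {
    stopifnot(cutoff > 0)
    n <- max(length(lambdaTN), length(lambdaMN))
    tn <- rep_len(lambdaTN, n); mn <- rep_len(lambdaMN, n)
    if (any(!is.finite(tn)) || any(!is.finite(mn)))
        stop("log2 ratios must be finite")
    lab <- character(n)
    up <- tn > cutoff; dn <- tn < -cutoff; mid <- !up & !dn
    lab[up & mn > tn] <- "aggravated+"
    lab[up & mn > cutoff & mn <= tn] <- "weak+"
    lab[up & abs(mn) <= cutoff] <- "desired+"
    lab[up & mn < -cutoff] <- "flip+-"
    lab[dn & mn < tn] <- "aggravated-"
    lab[dn & mn < -cutoff & mn >= tn] <- "weak-"
    lab[dn & abs(mn) <= cutoff] <- "desired-"
    lab[dn & mn > cutoff] <- "flip-+"
    lab[mid & mn > cutoff] <- "side+"
    lab[mid & mn < -cutoff] <- "side-"
    lab[mid & abs(mn) <= cutoff] <- "none"
    factor(lab, levels = effectLabels())
}

#' Extract per-component changes from a dose-series ensemble
#'
#' @param ensemble an \linkS4class{EnsembleResult} with pairs
#'   \code{"T0/N0"}, \code{"Tx/N0"}, \code{"Tx/T0"} (as produced per dose
#'   by [doseSeries()]).
#' @param targetComponents component ids of direct miRNA target genes.
#' @return data.frame \code{component}, \code{lambdaTN}, \code{lambdaMN},
#'   \code{lambdaMT}, \code{isDirectTarget}.
#' @export
componentChanges <- function(ensemble, targetComponents = character()) {
    stopifnot(is(ensemble, "EnsembleResult"),
              all(c("T0/N0", "Tx/N0", "Tx/T0") %in% ensemble@pairs))
    agg <- ensemble@aggregate
    data.frame(component = rownames(agg),
               lambdaTN = agg[, "T0/N0"],
               lambdaMN = agg[, "Tx/N0"],
               lambdaMT = agg[, "Tx/T0"],
               isDirectTarget = rownames(agg) %in% targetComponents,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Summarize effect-subgroup counts and frequencies at one dose
#'
#' Direct miRNA targets are excluded first; the remaining components are
#' kept only when the treatment actually moved them relative to the
#' untreated disease state: fold change \eqn{2^{\lambda_{MT}}} above
#' \code{filterBounds[2]} (1.2) or below \code{filterBounds[1]} (0.8).
#' (Set \code{filterOn = "lambdaTN"} to filter on the tumor/normal change
#' instead.) Each kept component contributes one label; frequency = count /
#' total kept.
#'
#' @param changes a [componentChanges()] data.frame (columns
#'   \code{lambdaTN}, \code{lambdaMN}, \code{lambdaMT},
#'   \code{isDirectTarget}).
#' @param dose dose factor annotation carried into the output.
#' @param cutoff classification log2 cutoff (default 0.58).
#' @param filterBounds lower/upper linear fold-change bounds (default
#'   \code{c(0.8, 1.2)}).
#' @param filterOn column the fold-change filter applies to (default
#'   \code{"lambdaMT"}, the treated-vs-untreated change).
#' @param excludeTargets drop direct targets first (default TRUE).
#' @return data.frame \code{dose}, \code{label}, \code{count},
#'   \code{frequency} (NA frequencies when nothing passes the filter);
#'   attributes \code{totalFiltered} and \code{nExcluded}.
#' @examples
#' ch <- data.frame(component = letters[1:3], lambdaTN = c(1, 1, 0),
#'                  lambdaMN = c(0, 2, 0), lambdaMT = c(-1, 1, 0),
#'                  isDirectTarget = FALSE)
#' summarizeEffects(ch, dose = 2)
#' @export
summarizeEffects <- function(changes, dose = NA_real_, cutoff = 0.58,
                             filterBounds = c(0.8, 1.2),
                             filterOn = c("lambdaMT", "lambdaTN"),
                             excludeTargets = TRUE) {
    filterOn <- match.arg(filterOn)
    stopifnot(filterBounds[1] < filterBounds[2])
    x <- changes
    nExcluded <- 0L
    if (excludeTargets) {
        nExcluded <- sum(x$isDirectTarget)
        x <- x[!x$isDirectTarget, , drop = FALSE]
    }
    fc <- 2^x[[filterOn]]
    keep <- is.finite(fc) & (fc > filterBounds[2] | fc < filterBounds[1])
    x <- x[keep, , drop = FALSE]
    total <- nrow(x)
    counts <- table(factor(character(), levels = effectLabels()))
    if (total > 0)
        counts <- table(classifyEffect(x$lambdaTN, x$lambdaMN, cutoff))
    out <- data.frame(dose = dose, label = names(counts),
                      count = as.integer(counts),
                      frequency = if (total > 0)
                          as.integer(counts) / total else NA_real_)
    attr(out, "totalFiltered") <- total
    attr(out, "nExcluded") <- nExcluded
    out
}

#' Dose-response table of effect-subgroup frequencies
#'
#' Classifies every dose of a [doseSeries()] result and stacks the per-dose
#' summaries into one long table mirroring a frequency-by-dose scatter
#' layout.
#'
#' @param series a \code{DoseSeriesResult}.
#' @param ... passed to [summarizeEffects()] (cutoff, filter settings).
#' @return data.frame \code{dose}, \code{label}, \code{count},
#'   \code{frequency}, ordered by dose then label.
#' @export
doseResponse <- function(series, ...) {
    stopifnot(inherits(series, "DoseSeriesResult"))
    out <- lapply(names(series$ensembles), function(d) {
        ch <- componentChanges(series$ensembles[[d]],
                               series$targetComponents)
        summarizeEffects(ch, dose = as.numeric(d), ...)
    })
    do.call(rbind, out)
}

#' Plot a dose-response frequency table
#'
#' Frequency of each therapeutic-effect subgroup against dose (log scale),
#' one point per (dose, label), lines per label.
#'
#' @param dr a [doseResponse()] table.
#' @return A ggplot object.
#' @export
plotDoseResponse <- function(dr) {
    if (!requireNamespace("ggplot2", quietly = TRUE))
        stop("ggplot2 is required for plotting")
    dr <- dr[dr$label != "none" & is.finite(dr$frequency), , drop = FALSE]
    dose <- frequency <- label <- NULL  # data-masked aes columns
    ggplot2::ggplot(dr, ggplot2::aes(x = dose, y = frequency,
                                     colour = label)) +
        ggplot2::geom_point() + ggplot2::geom_line() +
        ggplot2::scale_x_log10() +
        ggplot2::labs(x = "dose factor", y = "frequency",
                      colour = "effect subgroup") +
        ggplot2::theme_bw()
}
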
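#' Dose grid for in-silico miRNA perturbation
#'
#' Treatment mode emulates a miRNA increase by down-regulating the
#' synthesis rate of its target genes; depletion emulates a miRNA decrease
#' symmetrically (synthesis up). Factors span 1.01- to 100-fold.
#'
#' @param mode \code{"treatment"} (miRNA increase) or \code{"depletion"}.
#' @param factors dose factors, each within [1.01, 100]; sorted ascending.
#' @return Validated list of class \code{"DoseGrid"}.
#' @export
DoseGrid <- function(mode = c("treatment", "depletion"),
                     factors = defaultDoseFactors()) {
    mode <- match.arg(mode)
    if (any(factors < 1.01) || any(factors > 100))
        stop("dose factors must lie within [1.01, 100]")
    structure(list(mode = mode, factors = sort(as.numeric(factors))),
              class = "DoseGrid")
}

#' Default dose factors
#'
#' Spans the full 1.01- to 100-fold range with extra resolution in the
#' 1.2-1.6 and 1.6-4 windows where therapeutic-window effects concentrate.
#' @return Numeric vector of dose factors.
#' @export
defaultDoseFactors <- function() c(1.01, 1.1, 1.2, 1.5, 1.6, 2, 4, 10, 100)

#' Intersect a miRNA target list with a model's genes
#'
#' @param targets character vector of target gene symbols (e.g. from
#'   [readTargetList()]), or a list with element \code{genes}.
#' @param model a \linkS4class{NetworkModel}.
#' @return Sorted character vector of target symbols present in the model's
#'   gene annotation; the count is its length.
#' @examples
#' toy <- generateToyNetwork(ToyNetworkSpec(nGenes = 4, nMirnaTargets = 2))
#' intersectTargets(toy$targets, toy$model)
#' @export
intersectTargets <- function(targets, model) {
    if (is.list(targets)) targets <- targets$genes
    stopifnot(is.character(targets), is(model, "NetworkModel"))
    genes <- unique(model@components$gene)
    sort(intersect(unique(targets), genes[!is.na(genes)]))
}

#' Read a one-symbol-per-line target gene list
#'
#' @param path text file, one gene symbol per line; blank lines and lines
#'   starting with \code{#} are ignored.
#' @return Character vector of unique symbols.
#' @export
readTargetList <- function(path) {
    if (!file.exists(path)) stop("target list file not found: ", path)
    x <- trimws(readLines(path, warn = FALSE))
    unique(x[nzchar(x) & !startsWith(x, "#")])
}

# synthesis reactions of a gene: those producing one of its transcripts
synthesisReactionsOf <- function(model, gene, kind = "transcript") {
    comp <- model@components
    rnaIds <- comp$id[comp$kind == kind & !is.na(comp$gene) &
                      comp$gene == gene]
    which(vapply(model@reactions, function(rx)
        any(rx$products$species %in% rnaIds), logical(1)))
}

#' Apply a miRNA dose to a model's target genes
#'
#' Scales the rate constant of each target gene's synthesis
#' (transcript-producing) reaction: treatment divides by \code{factor}
#' (miRNA increase represses its targets), depletion multiplies by it.
#' All other parameters are untouched; the input model is not modified.
#'
#' @param model a \linkS4class{NetworkModel}.
#' @param targets character vector of in-model target gene symbols.
#' @param factor positive dose factor.
#' @param mode \code{"treatment"} or \code{"depletion"}.
#' @param scaleTranslation also scale the targets' protein-producing
#'   reactions (default FALSE: miRNA action is modeled at the transcript
#'   synthesis rate).
#' @return A perturbed \linkS4class{NetworkModel} copy.
#' @examples
#' toy <- generateToyNetwork(ToyNetworkSpec(nGenes = 3, nMirnaTargets = 1))
#' p <- applyDose(toy$model, toy$targets, factor = 2, mode = "treatment")
#' modelParameters(p)[paste0("k_tx_", toy$targets)]
#' @export
applyDose <- function(model, targets, factor,
                      mode = c("treatment", "depletion"),
                      scaleTranslation = FALSE) {
    mode <- match.arg(mode)
    stopifnot(is(model, "NetworkModel"), factor > 0)
    scale <- if (mode == "treatment") 1 / factor else factor
    missing <- character()
    out <- model
    for (g in targets) {
        idx <- synthesisReactionsOf(model, g)
        if (scaleTranslation)
            idx <- union(idx, synthesisReactionsOf(model, g, "protein"))
        if (!length(idx)) { missing <- c(missing, g); next }
        for (j in idx) {
            p <- model@reactions[[j]]$param
            out@parameters[p] <- out@parameters[p] * scale
        }
    }
    if (length(missing))
        stop("target gene(s) without a synthesis reaction: ",
             paste(missing, collapse = ", "))
    out
}

# steady states of one model across a parameter-multiplier ensemble
ensembleStatesFor <- function(model, ensemble, ...) {
    ids <- model@components$id
    nominal <- model@parameters
    nS <- ncol(ensemble)
    states <- matrix(NA_real_, length(ids), nS, dimnames = list(ids, NULL))
    converged <- logical(nS)
    for (s in seq_len(nS)) {
        ss <- runToSteadyState(model,
                               parameters = nominal * ensemble[names(nominal), s],
                               ...)
        states[, s] <- ss$state
        converged[s] <- ss$converged
    }
    list(states = states, converged = converged)
}

#' Dose-response ensemble series for a miRNA perturbation
#'
#' Runs one paired Monte Carlo ensemble per dose factor: the normal (N0)
#' and untreated disease (T0) baselines are integrated once per parameter
#' sample and shared across doses; each dose adds the treated disease model
#' at that factor. Per-dose results carry the three comparisons needed for
#' effect classification: T0/N0, treated/N0 and treated/T0.
#'
#' @param normal the baseline \linkS4class{NetworkModel} (condition N0).
#' @param disease the untreated disease variant (condition T0); may also be
#'   an expression-initialized state from [initializeState()].
#' @param targets in-model miRNA target gene symbols (see
#'   [intersectTargets()]).
#' @param grid a [DoseGrid()].
#' @param spec a [SamplingSpec()].
#' @param epsilonRatio pseudo-abundance for log2 ratios.
#' @param aggregate \code{"median"} (default) or \code{"mean"}.
#' @param ... passed to [runToSteadyState()].
#' @return A list of class \code{"DoseSeriesResult"}: \code{grid},
#'   \code{targets}, \code{targetComponents} (component ids of target
#'   genes), \code{baseline} (the shared N0/T0 steady states; with an
#'   empty grid only these are computed) and \code{ensembles}, a named
#'   list (one
#'   \linkS4class{EnsembleResult} per dose factor) with conditions
#'   \code{N0}, \code{T0} and \code{Tx} (treated).
#' @export
doseSeries <- function(normal, disease, targets, grid = DoseGrid(),
                       spec = SamplingSpec(), epsilonRatio = 1e-9,
                       aggregate = c("median", "mean"), ...) {
    stopifnot(inherits(grid, "DoseGrid"), inherits(spec, "SamplingSpec"))
    aggregate <- match.arg(aggregate)
    aggFun <- if (aggregate == "median") stats::median else mean
    ensemble <- sampleParameters(normal, spec)
    base <- ensembleStatesFor(normal, ensemble, ...)
    dis <- ensembleStatesFor(disease, ensemble, ...)
    ids <- normal@components$id
    comp <- normal@components
    targetComponents <- comp$id[!is.na(comp$gene) & comp$gene %in% targets]

    results <- lapply(grid$factors, function(f) {
        treated <- applyDose(disease, targets, f, mode = grid$mode)
        trt <- ensembleStatesFor(treated, ensemble, ...)
        states <- array(c(base$states, dis$states, trt$states),
                        dim = c(length(ids), ncol(ensemble), 3),
                        dimnames = list(ids, NULL, c("N0", "T0", "Tx")))
        conv <- cbind(N0 = base$converged, T0 = dis$converged,
                      Tx = trt$converged)
        pairs <- c("T0/N0", "Tx/N0", "Tx/T0")
        num <- list(2, 3, 3); den <- list(1, 1, 2)
        ratios <- list(); agg <- matrix(NA_real_, length(ids), 3,
                                        dimnames = list(ids, pairs))
        pv <- agg
        for (pi in 1:3) {
            ok <- conv[, num[[pi]]] & conv[, den[[pi]]]
            r <- log2((states[, , num[[pi]]] + epsilonRatio) /
                      (states[, , den[[pi]]] + epsilonRatio))
            r[, !ok] <- NA_real_
            ratios[[pairs[pi]]] <- r
            if (any(ok)) {
                agg[, pi] <- apply(r[, ok, drop = FALSE], 1, aggFun)
                pv[, pi] <- apply(r[, ok, drop = FALSE], 1, pairedWilcoxP)
            }
        }
        new("EnsembleResult", conditions = c("N0", "T0", "Tx"),
            states = states, converged = conv, pairs = pairs,
            ratios = ratios, aggregate = agg, pvalue = pv)
    })
    names(results) <- as.character(grid$factors)
    structure(list(grid = grid, targets = targets,
                   targetComponents = targetComponents,
                   baseline = list(N0 = base, T0 = dis),
                   ensembles = results),
              class = "DoseSeriesResult")
}
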
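#' Monte Carlo kinetic-parameter sampling specification
#'
#' Parameters are drawn i.i.d. log-uniformly over
#' \eqn{[10^{-r}, 10^{r}]} (r decades) and act as multipliers on each
#' model's nominal rate constants, so a perturbation expressed in the
#' nominal values (a lesion or a dose) is preserved in every draw and the
#' design stays paired across conditions.
#'
#' @param nSamples ensemble size (default 100).
#' @param decades half-width r of the log10-uniform range (default 1).
#' @param seed integer RNG seed.
#' @return Validated list of class \code{"SamplingSpec"}.
#' @export
SamplingSpec <- function(nSamples = 100L, decades = 1, seed = 1L) {
    spec <- list(nSamples = as.integer(nSamples), decades = decades,
                 seed = as.integer(seed))
    if (spec$nSamples < 1) stop("nSamples must be >= 1")
    if (spec$decades <= 0) stop("decades must be > 0")
    class(spec) <- "SamplingSpec"
    spec
}

#' Sample a kinetic-parameter ensemble
#'
#' @param model a \linkS4class{NetworkModel} (defines the parameter names).
#' @param spec a [SamplingSpec()].
#' @return Numeric matrix parameters x samples of log-uniform multipliers
#'   in \eqn{[10^{-r}, 10^{r}]}; reproducible for a given seed.
#' @examples
#' toy <- generateToyNetwork(ToyNetworkSpec(nGenes = 2, cascadeDepth = 1))
#' dim(sampleParameters(toy$model, SamplingSpec(nSamples = 5, seed = 3)))
#' @export
sampleParameters <- function(model, spec) {
    stopifnot(is(model, "NetworkModel"), inherits(spec, "SamplingSpec"))
    pn <- names(model@parameters)
    withSeed(spec$seed, {
        matrix(10^stats::runif(length(pn) * spec$nSamples,
                               -spec$decades, spec$decades),
               nrow = length(pn), dimnames = list(pn, NULL))
    })
}

#' Initialize a model state from a per-gene expression table
#'
#' Sets each gene-template (fixed) component's amount to the gene's
#' normalized expression value; every non-fixed component starts at a
#' uniform basal amount. Expression entries whose gene symbol is absent
#' from the model are skipped with a message (not an error).
#'
#' @param model a \linkS4class{NetworkModel}.
#' @param expression named numeric vector, or data.frame with columns
#'   \code{gene} and \code{value}; values must be >= 0.
#' @param label condition label (e.g. "N0", "T0", "M0"), stored as
#'   attribute \code{"label"}.
#' @param basalAmount starting amount of non-fixed components (default 1).
#' @return A \linkS4class{NetworkModel} copy with updated initial amounts.
#' @export
initializeState <- function(model, expression, label = "state",
                            basalAmount = 1) {
    stopifnot(is(model, "NetworkModel"))
    if (is.data.frame(expression))
        expression <- stats::setNames(expression$value, expression$gene)
    if (any(expression < 0)) stop("expression values must be >= 0")
    comp <- model@components
    comp$initial[!comp$fixed] <- basalAmount
    tpl <- which(comp$kind == "gene-template")
    geneOf <- comp$gene[tpl]
    unmatched <- setdiff(names(expression), geneOf)
    if (length(unmatched))
        message("skipping ", length(unmatched),
                " expression entries without a model gene: ",
                paste(utils::head(unmatched, 5), collapse = ", "),
                if (length(unmatched) > 5) ", ...")
    hit <- geneOf %in% names(expression)
    comp$initial[tpl[hit]] <- unname(expression[geneOf[hit]])
    model@components <- comp
    attr(model, "label") <- label
    model
}

#' Integrate a model to steady state
#'
#' Advances the stiff integrator (\code{deSolve::lsoda}) over doubling time
#' chunks until the relative derivative criterion
#' \eqn{\max_i |dx_i/dt| / (|x_i| + \epsilon) < tol} holds or \code{tMax}
#' is reached. Non-convergence is returned flagged, never silently used.
#'
#' @param model a \linkS4class{NetworkModel}.
#' @param parameters optional named overrides of the rate constants.
#' @param state optional named initial state (defaults to the model's
#'   initial amounts); must be finite and non-negative.
#' @param tol convergence tolerance on the relative derivative (default 1e-6).
#' @param tMax maximum integration time, model time units (default 1e6).
#' @param rtol,atol integrator tolerances.
#' @param epsilon floor in the convergence denominator.
#' @return List: \code{state} (named numeric), \code{converged} (logical),
#'   \code{time} (integration time reached).
#' @examples
#' toy <- generateToyNetwork(ToyNetworkSpec(nGenes = 1, cascadeDepth = 1))
#' runToSteadyState(toy$model)$converged
#' @export
runToSteadyState <- function(model, parameters = NULL, state = NULL,
                             tol = 1e-6, tMax = 1e6, rtol = 1e-8,
                             atol = 1e-10, epsilon = 1e-9) {
    f <- buildRateFunction(model, parameters)
    comp <- model@components
    x <- if (is.null(state)) stats::setNames(comp$initial, comp$id)
         else state[comp$id]
    if (any(!is.finite(x)) || any(x < 0))
        stop("initial state must be finite and non-negative")
    relRate <- function(x) max(abs(f(x)) / (abs(x) + epsilon))
    tReached <- 0
    if (relRate(x) >= tol) {
        # integrate with a root function that stops at quiescence
        jac <- attr(f, "jacobian")
        # lsodar warns when maxsteps is hit; the converged flag below is
        # the authoritative report, so those warnings are silenced
        sol <- try(suppressWarnings(deSolve::lsodar(
            y = x, times = c(0, tMax),
            func = function(t, y, p) list(f(pmax(y, 0))),
            jacfunc = function(t, y, p) jac(pmax(y, 0)),
            jactype = "fullusr",
            rootfunc = function(t, y, p) {
                yy <- pmax(y, 0)
                max(abs(f(yy)) / (abs(yy) + epsilon)) - tol
            },
            parms = NULL, rtol = rtol, atol = atol, maxsteps = 50000)),
            silent = TRUE)
        if (inherits(sol, "try-error") || nrow(sol) < 2)
            return(list(state = stats::setNames(as.numeric(x), comp$id),
                        converged = FALSE, time = tReached))
        x <- pmax(sol[nrow(sol), -1], 0)
        tReached <- sol[nrow(sol), 1]
    }
    list(state = stats::setNames(as.numeric(x), comp$id),
         converged = relRate(x) < tol, time = tReached)
}

# wilcoxon signed-rank p across paired samples; 1 when all ties at zero
pairedWilcoxP <- function(diffs) {
    d <- diffs[is.finite(diffs)]
    if (length(d) < 2 || all(abs(d) < 1e-12)) return(1)
    suppressWarnings(stats::wilcox.test(d, mu = 0, exact = FALSE)$p.value)
}

#' Paired Monte Carlo steady-state ensemble over conditions
#'
#' Integrates every condition model under every sampled parameter vector
#' (the multipliers of \code{ensemble} applied to each condition's nominal
#' rate constants — a fully paired design), computes per-sample log2
#' steady-state ratios for each condition pair with a pseudo-abundance
#' guard, aggregates them per component (median over samples converged in
#' both conditions; optionally mean) and attaches Wilcoxon signed-rank
#' p-values across samples. Non-converged runs are excluded from ratios and
#' reported in the \code{converged} slot.
#'
#' @param conditions named list of \linkS4class{NetworkModel}s with
#'   identical component and parameter names (e.g. \code{N0}, \code{T0},
#'   treated variants).
#' @param ensemble parameter-multiplier matrix from [sampleParameters()].
#' @param pairs character vector of \code{"A/B"} condition-label pairs to
#'   compare; default: every condition against the first.
#' @param aggregate \code{"median"} (default) or \code{"mean"}.
#' @param epsilonRatio pseudo-abundance added to both sides of each ratio
#'   (default 1e-9).
#' @param ... passed to [runToSteadyState()].
#' @return An \linkS4class{EnsembleResult}.
#' @export
simulateEnsemble <- function(conditions, ensemble, pairs = NULL,
                             aggregate = c("median", "mean"),
                             epsilonRatio = 1e-9, ...) {
    aggregate <- match.arg(aggregate)
    stopifnot(is.list(conditions), length(conditions) >= 1,
              !is.null(names(conditions)))
    labs <- names(conditions)
    ids <- conditions[[1]]@components$id
    for (m in conditions)
        if (!identical(m@components$id, ids) ||
            !identical(sort(names(m@parameters)),
                       sort(names(conditions[[1]]@parameters))))
            stop("all condition models must share components and parameters")
    nS <- ncol(ensemble); nC <- length(conditions)
    states <- array(NA_real_, c(length(ids), nS, nC),
                    dimnames = list(ids, NULL, labs))
    converged <- matrix(FALSE, nS, nC, dimnames = list(NULL, labs))
    for (ci in seq_len(nC)) {
        nominal <- conditions[[ci]]@parameters
        for (s in seq_len(nS)) {
            eff <- nominal * ensemble[names(nominal), s]
            ss <- runToSteadyState(conditions[[ci]], parameters = eff, ...)
            states[, s, ci] <- ss$state
            converged[s, ci] <- ss$converged
        }
    }
    if (is.null(pairs) && nC > 1)
        pairs <- paste0(labs[-1], "/", labs[1])
    if (is.null(pairs)) pairs <- character()
    ratios <- list()
    aggM <- matrix(NA_real_, length(ids), length(pairs),
                   dimnames = list(ids, pairs))
    pM <- aggM
    aggFun <- if (aggregate == "median") stats::median else mean
    for (pi in seq_along(pairs)) {
        parts <- strsplit(pairs[pi], "/", fixed = TRUE)[[1]]
        if (length(parts) != 2 || !all(parts %in% labs))
            stop("unknown condition pair: ", pairs[pi])
        a <- match(parts[1], labs); b <- match(parts[2], labs)
        ok <- converged[, a] & converged[, b]
        r <- log2((states[, , a, drop = FALSE][, , 1] + epsilonRatio) /
                  (states[, , b, drop = FALSE][, , 1] + epsilonRatio))
        r <- matrix(r, nrow = length(ids))
        r[, !ok] <- NA_real_
        ratios[[pairs[pi]]] <- r
        if (any(ok)) {
            aggM[, pi] <- apply(r[, ok, drop = FALSE], 1, aggFun)
            pM[, pi] <- apply(r[, ok, drop = FALSE], 1, pairedWilcoxP)
        }
    }
    new("EnsembleResult", conditions = labs, states = states,
        converged = converged, pairs = as.character(pairs),
        ratios = ratios, aggregate = aggM, pvalue = pM)
}
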
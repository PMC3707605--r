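#' Model statistics
#'
#' Counts of reactions, components, variables (non-fixed components), fixed
#' components, kinetic parameters and distinct annotated genes.
#'
#' @param object a \linkS4class{NetworkModel}.
#' @return A list with elements \code{nReactions}, \code{nComponents},
#'   \code{nVariables}, \code{nFixed}, \code{nParameters}, \code{nGenes}
#'   (\code{NA} when no gene annotation is present).
#' @examples
#' modelStats(generateToyNetwork(ToyNetworkSpec(nGenes = 4))$model)
#' @export
setGeneric("modelStats", function(object) standardGeneric("modelStats"))

#' Accessors for NetworkModel slots
#'
#' @param object a \linkS4class{NetworkModel}.
#' @return \code{modelComponents}: the component data.frame;
#'   \code{modelReactions}: the reaction list; \code{modelParameters}: the
#'   named numeric vector of rate constants.
#' @name model-accessors
#' @export
setGeneric("modelComponents", function(object) standardGeneric("modelComponents"))

#' @rdname model-accessors
#' @export
setGeneric("modelReactions", function(object) standardGeneric("modelReactions"))

#' @rdname model-accessors
#' @export
setGeneric("modelParameters", function(object) standardGeneric("modelParameters"))

#' Accessors for EnsembleResult slots
#'
#' @param object an \linkS4class{EnsembleResult}.
#' @return \code{ensembleAggregate}: components x pairs matrix of aggregate
#'   log2 ratios; \code{ensemblePvalue}: matching Wilcoxon signed-rank
#'   p-values; \code{ensembleStates}: the components x samples x conditions
#'   steady-state array; \code{ensembleConverged}: samples x conditions
#'   logical matrix.
#' @name ensemble-accessors
#' @export
setGeneric("ensembleAggregate", function(object) standardGeneric("ensembleAggregate"))

#' @rdname ensemble-accessors
#' @export
setGeneric("ensemblePvalue", function(object) standardGeneric("ensemblePvalue"))

#' @rdname ensemble-accessors
#' @export
setGeneric("ensembleStates", function(object) standardGeneric("ensembleStates"))

#' @rdname ensemble-accessors
#' @export
setGeneric("ensembleConverged", function(object) standardGeneric("ensembleConverged"))

setMethod("modelComponents", "NetworkModel", function(object) object@components)
setMethod("modelReactions", "NetworkModel", function(object) object@reactions)
setMethod("modelParameters", "NetworkModel", function(object) object@parameters)
setMethod("ensembleAggregate", "EnsembleResult", function(object) object@aggregate)
setMethod("ensemblePvalue", "EnsembleResult", function(object) object@pvalue)
setMethod("ensembleStates", "EnsembleResult", function(object) object@states)
setMethod("ensembleConverged", "EnsembleResult", function(object) object@converged)
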
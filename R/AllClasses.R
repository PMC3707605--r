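#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

#' Container for a miRNA count matrix with cohort metadata
#'
#' A thin \linkS4class{SummarizedExperiment} subclass holding non-negative
#' integer read counts (assay \code{"counts"}, miRNAs in rows) with mandatory
#' per-sample \code{patient} and \code{tissue} annotation. Tissues follow the
#' matched-cohort design: \code{"N"} (normal), \code{"T"} (tumor),
#' \code{"M"} (metastasis).
#'
#' @slot ... inherited from \code{SummarizedExperiment}.
#' @seealso [MirnaCounts()] for construction, [generateCountCohort()] for
#'   simulation with planted effects.
#' @export
setClass("MirnaCounts", contains = "SummarizedExperiment")

setValidity("MirnaCounts", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cts <- SummarizedExperiment::assay(object, "counts")
        if (any(!is.finite(cts)) || any(cts < 0))
            msg <- c(msg, "counts must be finite and non-negative")
        if (any(cts != round(cts)))
            msg <- c(msg, "counts must be integers")
    }
    cd <- colData(object)
    if (!all(c("patient", "tissue") %in% colnames(cd)))
        msg <- c(msg, "colData must contain 'patient' and 'tissue'")
    else if (!all(cd$tissue %in% c("N", "T", "M")))
        msg <- c(msg, "tissue must be one of 'N', 'T', 'M'")
    if (length(msg)) msg else TRUE
})

#' Construct a MirnaCounts object
#'
#' @param counts integer matrix, miRNAs x samples, with rownames (miRNA
#'   names) and colnames (sample ids).
#' @param patient character/factor of patient ids, one per column.
#' @param tissue character vector over \code{c("N","T","M")}, one per column.
#' @return A \linkS4class{MirnaCounts} object.
#' @examples
#' m <- matrix(0:5, nrow = 2, dimnames = list(c("miR-a", "miR-b"), NULL))
#' MirnaCounts(m, patient = c("P1", "P1", "P2"), tissue = c("N", "T", "N"))
#' @export
MirnaCounts <- function(counts, patient, tissue) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "integer"
    if (is.null(colnames(counts)))
        colnames(counts) <- paste0(patient, "_", tissue)
    se <- SummarizedExperiment(
        assays = list(counts = counts),
        colData = DataFrame(patient = as.character(patient),
                            tissue = as.character(tissue),
                            row.names = colnames(counts)))
    new("MirnaCounts", se)
}

setMethod("show", "MirnaCounts", function(object) {
    cat("MirnaCounts:", nrow(object), "miRNAs x", ncol(object), "samples\n")
    tb <- table(colData(object)$tissue)
    cat("  tissues:", paste(names(tb), tb, sep = "=", collapse = " "), "\n")
    cat("  patients:", length(unique(colData(object)$patient)), "\n")
})

#' Mass-action reaction network model
#'
#' Components (species) with kinds (gene-template, transcript, protein,
#' complex, ligand, other), a fixed flag (boundary species whose level never
#' changes during integration), initial amounts and optional gene symbols;
#' reactions with integer stoichiometry, multiplicative modifiers and one
#' rate-constant parameter each; and a named vector of kinetic parameters.
#' Kinetics are generalized mass action: the rate of reaction j is
#' \eqn{v_j = k_j \prod x_r^{s_r} \prod x_m} over reactants r (stoichiometry
#' \eqn{s_r}) and modifiers m.
#'
#' @slot components data.frame with columns \code{id}, \code{name},
#'   \code{kind}, \code{fixed} (logical), \code{initial} (numeric >= 0),
#'   \code{gene} (character, may be NA).
#' @slot reactions list; each element a list with \code{id},
#'   \code{reactants} and \code{products} (data.frames with \code{species},
#'   \code{stoich}), \code{modifiers} (character), \code{param} (name of the
#'   rate constant).
#' @slot parameters named numeric vector of non-negative rate constants.
#' @seealso [readSBML()], [writeSBML()], [modelStats()], [buildRateFunction()]
#' @export
setClass("NetworkModel",
    representation(components = "data.frame",
                   reactions = "list",
                   parameters = "numeric"))

setValidity("NetworkModel", function(object) {
    msg <- character()
    comp <- object@components
    need <- c("id", "name", "kind", "fixed", "initial", "gene")
    if (!all(need %in% colnames(comp)))
        return(paste("components must have columns:",
                     paste(need, collapse = ", ")))
    if (anyDuplicated(comp$id))
        msg <- c(msg, "component ids must be unique")
    if (any(comp$initial < 0, na.rm = TRUE))
        msg <- c(msg, "initial amounts must be >= 0")
    if (length(object@parameters) &&
        (is.null(names(object@parameters)) || anyDuplicated(names(object@parameters))))
        msg <- c(msg, "parameters must be uniquely named")
    if (any(object@parameters < 0))
        msg <- c(msg, "rate constants must be >= 0")
    for (rx in object@reactions) {
        refs <- c(rx$reactants$species, rx$products$species, rx$modifiers)
        bad <- setdiff(refs, comp$id)
        if (length(bad))
            msg <- c(msg, paste0("reaction '", rx$id,
                                 "' references unknown species: ",
                                 paste(bad, collapse = ",")))
        if (!rx$param %in% names(object@parameters))
            msg <- c(msg, paste0("reaction '", rx$id,
                                 "' references unknown parameter '",
                                 rx$param, "'"))
        if (nrow(rx$reactants) + nrow(rx$products) == 0)
            msg <- c(msg, paste0("reaction '", rx$id, "' has no participants"))
        if (any(c(rx$reactants$stoich, rx$products$stoich) < 1))
            msg <- c(msg, paste0("reaction '", rx$id, "' has stoichiometry < 1"))
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "NetworkModel", function(object) {
    st <- modelStats(object)
    cat("NetworkModel:", st$nComponents, "components (",
        st$nFixed, "fixed ),", st$nReactions, "reactions,",
        st$nParameters, "parameters\n")
    if (!is.na(st$nGenes)) cat("  genes:", st$nGenes, "\n")
})

#' Result of a paired Monte Carlo steady-state ensemble
#'
#' Stores, for each simulated condition and each sampled kinetic-parameter
#' vector, the steady-state component levels, convergence flags, the
#' per-sample log2 ratios for each requested condition pair (paired across
#' the shared parameter vector), their per-component aggregate (median by
#' default) and a Wilcoxon signed-rank p-value across samples.
#'
#' @slot conditions character vector of condition labels.
#' @slot states numeric array components x samples x conditions.
#' @slot converged logical matrix samples x conditions.
#' @slot pairs character vector of "A/B" pair labels.
#' @slot ratios list of numeric matrices (components x samples), one per pair.
#' @slot aggregate numeric matrix components x pairs (median log2 ratio over
#'   converged samples).
#' @slot pvalue numeric matrix components x pairs.
#' @seealso [simulateEnsemble()], [doseSeries()]
#' @export
setClass("EnsembleResult",
    representation(conditions = "character",
                   states = "array",
                   converged = "matrix",
                   pairs = "character",
                   ratios = "list",
                   aggregate = "matrix",
                   pvalue = "matrix"))

setValidity("EnsembleResult", function(object) {
    d <- dim(object@states)
    if (length(d) != 3)
        return("states must be a 3-d array (components x samples x conditions)")
    if (d[3] != length(object@conditions))
        return("third dimension of states must match conditions")
    if (!all(dim(object@converged) == d[2:3]))
        return("converged must be samples x conditions")
    if (length(object@ratios) != length(object@pairs))
        return("one ratio matrix per pair required")
    TRUE
})

setMethod("show", "EnsembleResult", function(object) {
    d <- dim(object@states)
    cat("EnsembleResult:", d[1], "components,", d[2], "parameter samples,",
        d[3], "conditions (", paste(object@conditions, collapse = ", "), ")\n")
    cat("  converged:", sum(object@converged), "/", length(object@converged),
        "runs\n")
    if (length(object@pairs))
        cat("  pairs:", paste(object@pairs, collapse = ", "), "\n")
})
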
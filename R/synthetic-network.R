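#' Specification of a layered toy signaling network
#'
#' Describes a small ligand -> receptor -> cascade -> transcription-factor
#' style gene network. Genes are assigned to \code{cascadeDepth} layers;
#' each gene contributes a fixed gene template, a transcript and a protein.
#' Transcription of a first-layer gene is driven by a fixed ligand; deeper
#' genes are driven by the proteins of \code{nParents} genes from the layer
#' above (catalytic mass-action modifiers), so the cascade is cycle-free by
#' construction. A disease variant scales the transcription rate constants
#' of lesioned genes; a set of genes is annotated as miRNA-1 targets.
#'
#' @param nGenes number of genes (>= cascadeDepth).
#' @param cascadeDepth number of layers.
#' @param nMirnaTargets number of genes annotated as miRNA-1 targets (the
#'   first \code{nMirnaTargets} genes in layer order, deterministically).
#' @param tumorLesion named numeric vector gene -> synthesis scale factor
#'   (> 0) applied to the disease variant's transcription rate constants.
#' @param nParents upstream drivers per non-first-layer gene.
#' @param basalAmount initial amount of every non-fixed component.
#' @param seed integer RNG seed (wiring choice).
#' @return A validated list of class \code{"ToyNetworkSpec"}.
#' @export
ToyNetworkSpec <- function(nGenes, cascadeDepth = 3L, nMirnaTargets = 2L,
                           tumorLesion = numeric(), nParents = 1L,
                           basalAmount = 1, seed = 1L) {
    spec <- list(nGenes = as.integer(nGenes),
                 cascadeDepth = as.integer(cascadeDepth),
                 nMirnaTargets = as.integer(nMirnaTargets),
                 tumorLesion = tumorLesion, nParents = as.integer(nParents),
                 basalAmount = basalAmount, seed = as.integer(seed))
    if (spec$nGenes < 1 || spec$cascadeDepth < 1 || spec$nParents < 1)
        stop("nGenes, cascadeDepth and nParents must be >= 1")
    if (spec$cascadeDepth > spec$nGenes)
        stop("cascadeDepth must not exceed nGenes (cycle-free layering)")
    if (spec$nMirnaTargets > spec$nGenes)
        stop("nMirnaTargets must not exceed nGenes")
    if (length(tumorLesion) &&
        (is.null(names(tumorLesion)) || any(tumorLesion <= 0)))
        stop("tumorLesion must be a named vector of positive scale factors")
    class(spec) <- "ToyNetworkSpec"
    spec
}

# gene -> layer assignment: contiguous, every layer non-empty
toyLayers <- function(spec) {
    sort(rep_len(seq_len(spec$cascadeDepth), spec$nGenes))
}

#' Generate a layered toy signaling network model
#'
#' Builds the \linkS4class{NetworkModel} described by a [ToyNetworkSpec()]:
#' per gene a fixed template, a transcript and a protein, with mass-action
#' synthesis (template and upstream drivers as multiplicative modifiers),
#' first-order degradation of transcript and protein, and catalytic
#' translation. All nominal rate constants are 1, so perturbations are
#' expressed as relative scalings. Component and reaction counts are closed
#' forms of the spec: \code{3*nGenes + 1} components (one fixed ligand,
#' \code{nGenes + 1} fixed in total), \code{4*nGenes} reactions and
#' \code{4*nGenes} parameters.
#'
#' @param spec a [ToyNetworkSpec()].
#' @return A list: \code{model} (base \linkS4class{NetworkModel}),
#'   \code{disease} (variant with \code{tumorLesion} applied to the
#'   transcription rate constants), \code{targets} (character vector of
#'   miRNA-1 target gene symbols), \code{parents} (named list of upstream
#'   driver genes, for truth checks).
#' @examples
#' toy <- generateToyNetwork(ToyNetworkSpec(nGenes = 5, cascadeDepth = 2))
#' modelStats(toy$model)
#' @export
generateToyNetwork <- function(spec) {
    stopifnot(inherits(spec, "ToyNetworkSpec"))
    withSeed(spec$seed, {
        genes <- sprintf("G%02d", seq_len(spec$nGenes))
        layer <- toyLayers(spec)

        comp <- data.frame(
            id = "LIG", name = "ligand", kind = "ligand", fixed = TRUE,
            initial = 1, gene = NA_character_, stringsAsFactors = FALSE)
        for (g in genes) {
            comp <- rbind(comp, data.frame(
                id = paste0(g, c("_tpl", "_rna", "_prot")),
                name = paste(g, c("template", "transcript", "protein")),
                kind = c("gene-template", "transcript", "protein"),
                fixed = c(TRUE, FALSE, FALSE),
                initial = c(1, spec$basalAmount, spec$basalAmount),
                gene = g, stringsAsFactors = FALSE))
        }

        parents <- vector("list", spec$nGenes)
        names(parents) <- genes
        for (i in seq_len(spec$nGenes)) {
            if (layer[i] == 1L) { parents[[i]] <- character(); next }
            pool <- genes[layer == layer[i] - 1L]
            k <- min(spec$nParents, length(pool))
            parents[[i]] <- sort(sample(pool, k))
        }

        reactions <- list()
        params <- numeric()
        for (i in seq_len(spec$nGenes)) {
            g <- genes[i]
            drivers <- if (layer[i] == 1L) "LIG"
                       else paste0(parents[[i]], "_prot")
            kTx <- paste0("k_tx_", g); kDr <- paste0("k_degr_", g)
            kTl <- paste0("k_tl_", g); kDp <- paste0("k_degp_", g)
            params[c(kTx, kDr, kTl, kDp)] <- 1
            emptyPart <- data.frame(species = character(),
                                    stoich = numeric())
            reactions <- c(reactions, list(
                list(id = paste0("tx_", g), reactants = emptyPart,
                     products = data.frame(species = paste0(g, "_rna"),
                                           stoich = 1),
                     modifiers = c(paste0(g, "_tpl"), drivers), param = kTx),
                list(id = paste0("degr_", g),
                     reactants = data.frame(species = paste0(g, "_rna"),
                                            stoich = 1),
                     products = emptyPart, modifiers = character(),
                     param = kDr),
                list(id = paste0("tl_", g), reactants = emptyPart,
                     products = data.frame(species = paste0(g, "_prot"),
                                           stoich = 1),
                     modifiers = paste0(g, "_rna"), param = kTl),
                list(id = paste0("degp_", g),
                     reactants = data.frame(species = paste0(g, "_prot"),
                                            stoich = 1),
                     products = emptyPart, modifiers = character(),
                     param = kDp)))
        }
        model <- new("NetworkModel", components = comp,
                     reactions = reactions, parameters = params)
        validObject(model)

        disease <- model
        if (length(spec$tumorLesion)) {
            bad <- setdiff(names(spec$tumorLesion), genes)
            if (length(bad))
                stop("tumorLesion names not in model: ",
                     paste(bad, collapse = ", "))
            for (g in names(spec$tumorLesion)) {
                key <- paste0("k_tx_", g)
                disease@parameters[key] <-
                    disease@parameters[key] * spec$tumorLesion[g]
            }
        }
        list(model = model, disease = disease,
             targets = genes[seq_len(spec$nMirnaTargets)],
             parents = parents)
    })
}
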
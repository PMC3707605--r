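SBML_L3_NS <- "http://www.sbml.org/sbml/level3/version1/core"
MATHML_NS <- "http://www.w3.org/1998/Math/MathML"
ANNOT_NS <- "https://mirtherapy.example.org/annotation"

#' Write a NetworkModel as SBML Level 3
#'
#' Serializes components as species (the \code{fixed} flag becomes
#' \code{boundaryCondition}), rate constants as global parameters, and each
#' reaction's generalized mass-action kinetic law as an explicit MathML
#' product \eqn{k \prod x_r^{s_r} \prod x_m}. Component kind and gene symbol
#' are stored in a small annotation element so that a round trip is lossless
#' for the supported subset. Serialization is deterministic.
#'
#' @param model a \linkS4class{NetworkModel}.
#' @param path output file path.
#' @param modelId id attribute of the SBML model element.
#' @return \code{path}, invisibly.
#' @seealso [readSBML()]
#' @export
writeSBML <- function(model, path, modelId = "networkModel") {
    stopifnot(is(model, "NetworkModel"))
    num <- function(x) sprintf("%.17g", x)
    doc <- xml2::xml_new_root("sbml", xmlns = SBML_L3_NS,
                              level = "3", version = "1")
    mdl <- xml2::xml_add_child(doc, "model", id = modelId)
    lc <- xml2::xml_add_child(mdl, "listOfCompartments")
    xml2::xml_add_child(lc, "compartment", id = "cell", size = "1",
                        constant = "true")
    ls <- xml2::xml_add_child(mdl, "listOfSpecies")
    comp <- model@components
    for (i in seq_len(nrow(comp))) {
        sp <- xml2::xml_add_child(ls, "species",
            id = comp$id[i], name = comp$name[i], compartment = "cell",
            initialAmount = num(comp$initial[i]),
            hasOnlySubstanceUnits = "true",
            boundaryCondition = tolower(comp$fixed[i]),
            constant = "false")
        ann <- xml2::xml_add_child(sp, "annotation")
        info <- xml2::xml_add_child(ann, "info", xmlns = ANNOT_NS,
                                    kind = comp$kind[i])
        if (!is.na(comp$gene[i]))
            xml2::xml_set_attr(info, "gene", comp$gene[i])
    }
    lp <- xml2::xml_add_child(mdl, "listOfParameters")
    for (p in names(model@parameters))
        xml2::xml_add_child(lp, "parameter", id = p,
                            value = num(model@parameters[[p]]),
                            constant = "true")
    lr <- xml2::xml_add_child(mdl, "listOfReactions")
    for (rx in model@reactions) {
        rn <- xml2::xml_add_child(lr, "reaction", id = rx$id,
                                  reversible = "false", fast = "false")
        if (nrow(rx$reactants)) {
            l <- xml2::xml_add_child(rn, "listOfReactants")
            for (i in seq_len(nrow(rx$reactants)))
                xml2::xml_add_child(l, "speciesReference",
                    species = rx$reactants$species[i],
                    stoichiometry = num(rx$reactants$stoich[i]),
                    constant = "true")
        }
        if (nrow(rx$products)) {
            l <- xml2::xml_add_child(rn, "listOfProducts")
            for (i in seq_len(nrow(rx$products)))
                xml2::xml_add_child(l, "speciesReference",
                    species = rx$products$species[i],
                    stoichiometry = num(rx$products$stoich[i]),
                    constant = "true")
        }
        if (length(rx$modifiers)) {
            l <- xml2::xml_add_child(rn, "listOfModifiers")
            for (m in rx$modifiers)
                xml2::xml_add_child(l, "modifierSpeciesReference",
                                    species = m)
        }
        kl <- xml2::xml_add_child(rn, "kineticLaw")
        math <- xml2::xml_add_child(kl, "math", xmlns = MATHML_NS)
        factors <- rx$reactants
        nFac <- nrow(factors) + length(rx$modifiers)
        addCi <- function(parent, id)
            xml2::xml_add_child(parent, "ci", id)
        if (nFac == 0) {
            addCi(math, rx$param)
        } else {
            ap <- xml2::xml_add_child(math, "apply")
            xml2::xml_add_child(ap, "times")
            addCi(ap, rx$param)
            for (i in seq_len(nrow(factors))) {
                if (factors$stoich[i] == 1) {
                    addCi(ap, factors$species[i])
                } else {
                    pw <- xml2::xml_add_child(ap, "apply")
                    xml2::xml_add_child(pw, "power")
                    addCi(pw, factors$species[i])
                    xml2::xml_add_child(pw, "cn", num(factors$stoich[i]))
                }
            }
            for (m in rx$modifiers) addCi(ap, m)
        }
    }
    xml2::write_xml(doc, path)
    invisible(path)
}

# parse one kinetic-law math node into list(param=..., value=..., factors=
# data.frame(species, power)); errors mention the reaction id.
parseMassActionMath <- function(mathNode, rxId, speciesIds, paramIds) {
    factors <- data.frame(species = character(), power = numeric())
    params <- character()
    constants <- numeric()
    walkFactor <- function(node) {
        nm <- xml2::xml_name(node)
        if (nm == "ci") {
            id <- trimws(xml2::xml_text(node))
            if (id %in% paramIds) params <<- c(params, id)
            else if (id %in% speciesIds)
                factors <<- rbind(factors,
                                  data.frame(species = id, power = 1))
            else stop("reaction '", rxId, "': unknown identifier '", id,
                      "' in kinetic law")
        } else if (nm == "cn") {
            constants <<- c(constants, as.numeric(xml2::xml_text(node)))
        } else if (nm == "apply") {
            ch <- xml2::xml_children(node)
            op <- xml2::xml_name(ch[[1]])
            if (op == "times") {
                for (k in ch[-1]) walkFactor(k)
            } else if (op == "power") {
                if (length(ch) != 3 || xml2::xml_name(ch[[2]]) != "ci" ||
                    xml2::xml_name(ch[[3]]) != "cn")
                    stop("reaction '", rxId,
                         "': unsupported power expression in kinetic law")
                id <- trimws(xml2::xml_text(ch[[2]]))
                if (!id %in% speciesIds)
                    stop("reaction '", rxId, "': power of non-species '",
                         id, "'")
                factors <<- rbind(factors, data.frame(
                    species = id, power = as.numeric(xml2::xml_text(ch[[3]]))))
            } else {
                stop("reaction '", rxId, "': unsupported MathML operator <",
                     op, ">; only products of species times a constant ",
                     "are supported")
            }
        } else {
            stop("reaction '", rxId, "': unsupported MathML element <",
                 nm, ">")
        }
    }
    kids <- xml2::xml_children(mathNode)
    if (length(kids) != 1)
        stop("reaction '", rxId, "': malformed kinetic law math")
    walkFactor(kids[[1]])
    if (length(params) > 1)
        stop("reaction '", rxId,
             "': more than one rate-constant parameter in kinetic law")
    list(param = if (length(params)) params else NA_character_,
         constant = prod(constants), hasConstant = length(constants) > 0,
         factors = factors)
}

#' Read an SBML file into a NetworkModel
#'
#' Supports the generalized mass-action subset of SBML Level 2/3: species
#' (with \code{boundaryCondition} or \code{constant} mapped to the
#' \code{fixed} flag), reactions with integer-like stoichiometry and
#' modifiers, global and local kinetic parameters, and kinetic laws that are
#' products of species (optionally powered by a constant) times one rate
#' constant. Any other MathML is rejected with an error naming the reaction.
#' Component kind and gene symbol are taken from the package's annotation
#' element when present, with a documented fallback: ids matching
#' \code{<gene>_tpl|_rna|_prot} yield kind and gene symbol; everything else
#' is kind \code{"other"} with no gene.
#'
#' @param path path to an SBML file.
#' @return A \linkS4class{NetworkModel}.
#' @examples
#' toy <- generateToyNetwork(ToyNetworkSpec(nGenes = 3))
#' f <- tempfile(fileext = ".xml")
#' writeSBML(toy$model, f)
#' modelStats(readSBML(f))
#' @export
readSBML <- function(path) {
    stopifnot(file.exists(path))
    doc <- xml2::read_xml(path)
    xml2::xml_ns_strip(doc)
    mdl <- xml2::xml_find_first(doc, "./model")
    if (inherits(mdl, "xml_missing")) stop("no <model> element found")

    spNodes <- xml2::xml_find_all(mdl, "./listOfSpecies/species")
    if (!length(spNodes)) stop("model contains no species")
    attrOr <- function(nodes, a, default) {
        v <- xml2::xml_attr(nodes, a)
        ifelse(is.na(v), default, v)
    }
    ids <- xml2::xml_attr(spNodes, "id")
    nameA <- attrOr(spNodes, "name", ids)
    amount <- suppressWarnings(as.numeric(
        attrOr(spNodes, "initialAmount",
               attrOr(spNodes, "initialConcentration", "0"))))
    amount[is.na(amount)] <- 0
    fixed <- attrOr(spNodes, "boundaryCondition", "false") == "true" |
             attrOr(spNodes, "constant", "false") == "true"
    kind <- rep("other", length(ids))
    gene <- rep(NA_character_, length(ids))
    for (i in seq_along(spNodes)) {
        info <- xml2::xml_find_first(spNodes[[i]], ".//info")
        if (!inherits(info, "xml_missing")) {
            k <- xml2::xml_attr(info, "kind")
            g <- xml2::xml_attr(info, "gene")
            if (!is.na(k)) kind[i] <- k
            if (!is.na(g)) gene[i] <- g
        } else if (grepl("^(.+)_(tpl|rna|prot)$", ids[i])) {
            gene[i] <- sub("^(.+)_(tpl|rna|prot)$", "\\1", ids[i])
            suffix <- sub("^(.+)_(tpl|rna|prot)$", "\\2", ids[i])
            kind[i] <- c(tpl = "gene-template", rna = "transcript",
                         prot = "protein")[suffix]
        }
    }
    comp <- data.frame(id = ids, name = nameA, kind = kind, fixed = fixed,
                       initial = amount, gene = gene,
                       stringsAsFactors = FALSE)

    params <- numeric()
    pNodes <- xml2::xml_find_all(mdl, "./listOfParameters/parameter")
    for (p in pNodes)
        params[xml2::xml_attr(p, "id")] <-
            as.numeric(xml2::xml_attr(p, "value"))

    reactions <- list()
    rxNodes <- xml2::xml_find_all(mdl, "./listOfReactions/reaction")
    for (rn in rxNodes) {
        rxId <- xml2::xml_attr(rn, "id")
        getRefs <- function(xp) {
            refs <- xml2::xml_find_all(rn, xp)
            if (!length(refs))
                return(data.frame(species = character(), stoich = numeric()))
            data.frame(
                species = xml2::xml_attr(refs, "species"),
                stoich = as.numeric(attrOr(refs, "stoichiometry", "1")),
                stringsAsFactors = FALSE)
        }
        reactants <- getRefs("./listOfReactants/speciesReference")
        products <- getRefs("./listOfProducts/speciesReference")
        modifiers <- xml2::xml_attr(
            xml2::xml_find_all(rn, "./listOfModifiers/modifierSpeciesReference"),
            "species")
        bad <- setdiff(c(reactants$species, products$species, modifiers), ids)
        if (length(bad))
            stop("reaction '", rxId, "': unresolved species reference(s): ",
                 paste(bad, collapse = ", "))

        kl <- xml2::xml_find_first(rn, "./kineticLaw")
        if (inherits(kl, "xml_missing"))
            stop("reaction '", rxId, "': missing kinetic law")
        # local parameters (L3: localParameter, L2: parameter)
        locNodes <- c(xml2::xml_find_all(kl,
                          "./listOfLocalParameters/localParameter"),
                      xml2::xml_find_all(kl, "./listOfParameters/parameter"))
        localIds <- character()
        for (p in locNodes) {
            lid <- xml2::xml_attr(p, "id")
            gid <- if (lid %in% names(params)) paste0(rxId, "_", lid) else lid
            params[gid] <- as.numeric(xml2::xml_attr(p, "value"))
            localIds <- c(localIds, lid)
            names(localIds)[length(localIds)] <- gid
        }
        math <- xml2::xml_find_first(kl, "./math")
        if (inherits(math, "xml_missing"))
            stop("reaction '", rxId, "': kinetic law has no math")
        parsed <- parseMassActionMath(math, rxId, ids,
                                      union(names(params), localIds))
        pName <- parsed$param
        if (!is.na(pName) && pName %in% localIds)
            pName <- names(localIds)[match(pName, localIds)]
        if (is.na(pName)) {
            # constant-only rate law: materialize a parameter
            if (!parsed$hasConstant)
                stop("reaction '", rxId,
                     "': kinetic law has no rate constant")
            pName <- paste0("k_", rxId)
            params[pName] <- parsed$constant
        } else if (parsed$hasConstant) {
            stop("reaction '", rxId, "': mixed numeric constant and named ",
                 "rate parameter are not supported")
        }
        # mass-action consistency: math factors must equal reactants
        # (with stoichiometric powers) plus modifiers
        expFac <- rbind(
            if (nrow(reactants))
                data.frame(species = reactants$species,
                           power = reactants$stoich) else NULL,
            if (length(modifiers))
                data.frame(species = modifiers, power = 1) else NULL)
        norm <- function(df) {
            if (is.null(df) || !nrow(df))
                return(data.frame(species = character(), power = numeric()))
            agg <- aggregate(power ~ species, df, sum)
            agg[order(agg$species), , drop = FALSE]
        }
        a <- norm(parsed$factors); b <- norm(expFac)
        if (!isTRUE(all.equal(a$species, b$species)) ||
            !isTRUE(all.equal(a$power, b$power)))
            stop("reaction '", rxId, "': kinetic law is not mass action ",
                 "over its reactants and modifiers")
        reactions <- c(reactions, list(list(
            id = rxId, reactants = reactants, products = products,
            modifiers = as.character(modifiers), param = pName)))
    }
    model <- new("NetworkModel", components = comp, reactions = reactions,
                 parameters = params)
    validObject(model)
    model
}
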
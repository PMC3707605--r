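singleReactionSBML <- function() {
    # hand-written L2v4 document: A -> B with local rate constant k = 2
    f <- tempfile(fileext = ".xml")
    writeLines(c(
        '<?xml version="1.0" encoding="UTF-8"?>',
        '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
        ' <model id="single">',
        '  <listOfCompartments><compartment id="cell" size="1"/></listOfCompartments>',
        '  <listOfSpecies>',
        '   <species id="A" compartment="cell" initialAmount="3"/>',
        '   <species id="B" compartment="cell" initialAmount="0"/>',
        '  </listOfSpecies>',
        '  <listOfReactions>',
        '   <reaction id="conv" reversible="false">',
        '    <listOfReactants><speciesReference species="A"/></listOfReactants>',
        '    <listOfProducts><speciesReference species="B"/></listOfProducts>',
        '    <kineticLaw>',
        '     <math xmlns="http://www.w3.org/1998/Math/MathML">',
        '      <apply><times/><ci> k </ci><ci> A </ci></apply>',
        '     </math>',
        '     <listOfParameters><parameter id="k" value="2"/></listOfParameters>',
        '    </kineticLaw>',
        '   </reaction>',
        '  </listOfReactions>',
        ' </model>',
        '</sbml>'), f)
    f
}

test_that("a hand-written single-reaction SBML file parses correctly", {
    m <- readSBML(singleReactionSBML())
    st <- modelStats(m)
    expect_identical(st$nReactions, 1L)
    expect_identical(st$nComponents, 2L)
    expect_identical(st$nParameters, 1L)
    expect_identical(st$nFixed, 0L)
    rx <- modelReactions(m)[[1]]
    expect_identical(rx$reactants$species, "A")
    expect_identical(rx$products$species, "B")
    expect_equal(unname(modelParameters(m)[rx$param]), 2)
})

test_that("SBML round trip preserves structure and statistics", {
    toy <- generateToyNetwork(ToyNetworkSpec(nGenes = 6, cascadeDepth = 2,
                                             nMirnaTargets = 2, nParents = 2,
                                             seed = 2))
    f <- tempfile(fileext = ".xml")
    writeSBML(toy$model, f)
    m2 <- readSBML(f)
    expect_identical(modelStats(m2), modelStats(toy$model))
    expect_equal(modelComponents(m2), modelComponents(toy$model))
    expect_equal(modelParameters(m2)[names(modelParameters(toy$model))],
                 modelParameters(toy$model))
    ids1 <- vapply(modelReactions(toy$model), `[[`, "", "id")
    ids2 <- vapply(modelReactions(m2), `[[`, "", "id")
    expect_identical(ids2, ids1)
    # second round trip is stable
    f2 <- tempfile(fileext = ".xml")
    writeSBML(m2, f2)
    expect_identical(modelStats(readSBML(f2)), modelStats(toy$model))
})

test_that("unsupported MathML is rejected with the reaction named", {
    f <- singleReactionSBML()
    txt <- sub("<apply><times/><ci> k </ci><ci> A </ci></apply>",
               "<apply><plus/><ci> k </ci><ci> A </ci></apply>",
               readLines(f), fixed = TRUE)
    f2 <- tempfile(fileext = ".xml"); writeLines(txt, f2)
    expect_error(readSBML(f2), "conv.*plus|plus.*conv")
    # unresolved species reference
    txt2 <- sub('species="A"/></listOfReactants>',
                'species="Z"/></listOfReactants>',
                readLines(f), fixed = TRUE)
    f3 <- tempfile(fileext = ".xml"); writeLines(txt2, f3)
    expect_error(readSBML(f3), "conv")
})

test_that("model statistics count an empty model as all zeros", {
    empty <- new("NetworkModel",
                 components = data.frame(id = character(),
                                         name = character(),
                                         kind = character(),
                                         fixed = logical(),
                                         initial = numeric(),
                                         gene = character()),
                 reactions = list(), parameters = numeric())
    st <- modelStats(empty)
    expect_identical(st$nReactions, 0L)
    expect_identical(st$nComponents, 0L)
    expect_identical(st$nVariables, 0L)
    expect_identical(st$nParameters, 0L)
    expect_true(is.na(st$nGenes))
})

test_that("the mass-action right-hand side matches hand arithmetic", {
    m <- readSBML(singleReactionSBML())
    f <- buildRateFunction(m)
    d <- f(c(A = 3, B = 0))
    expect_equal(unname(d["A"]), -6)   # v = k x_A = 2*3
    expect_equal(unname(d["B"]), 6)
    expect_error(f(c(A = -1, B = 0)), "non-negative")

    # fixed components have derivative pinned to zero
    m@components$fixed[m@components$id == "A"] <- TRUE
    f2 <- buildRateFunction(m)
    expect_equal(unname(f2(c(A = 3, B = 0))["A"]), 0)
})

test_that("S v equals per-reaction brute-force accumulation on toy models", {
    toy <- generateToyNetwork(ToyNetworkSpec(nGenes = 7, cascadeDepth = 3,
                                             nMirnaTargets = 0, nParents = 2,
                                             seed = 5))
    model <- toy$model
    f <- buildRateFunction(model)
    comp <- modelComponents(model)
    set.seed(1)
    for (rep in 1:5) {
        x <- setNames(runif(nrow(comp), 0, 3), comp$id)
        # oracle: accumulate every reaction independently
        acc <- setNames(numeric(nrow(comp)), comp$id)
        for (rx in modelReactions(model)) {
            v <- modelParameters(model)[[rx$param]]
            for (i in seq_len(nrow(rx$reactants)))
                v <- v * x[[rx$reactants$species[i]]]^rx$reactants$stoich[i]
            for (mm in rx$modifiers) v <- v * x[[mm]]
            for (i in seq_len(nrow(rx$reactants))) {
                s <- rx$reactants$species[i]
                acc[s] <- acc[s] - rx$reactants$stoich[i] * v
            }
            for (i in seq_len(nrow(rx$products))) {
                s <- rx$products$species[i]
                acc[s] <- acc[s] + rx$products$stoich[i] * v
            }
        }
        acc[comp$fixed] <- 0
        expect_equal(f(x), acc, tolerance = 1e-12)
    }
})

test_that("a closed two-species cycle conserves its total mass", {
    comp <- data.frame(id = c("A", "B"), name = c("A", "B"),
                       kind = "other", fixed = FALSE,
                       initial = c(10, 0), gene = NA_character_)
    rxns <- list(
        list(id = "fwd", reactants = data.frame(species = "A", stoich = 1),
             products = data.frame(species = "B", stoich = 1),
             modifiers = character(), param = "kf"),
        list(id = "rev", reactants = data.frame(species = "B", stoich = 1),
             products = data.frame(species = "A", stoich = 1),
             modifiers = character(), param = "kr"))
    cyc <- new("NetworkModel", components = comp, reactions = rxns,
               parameters = c(kf = 1, kr = 1))
    ss <- runToSteadyState(cyc, tol = 1e-9)
    expect_true(ss$converged)
    expect_lt(abs(sum(ss$state) - 10) / 10, 1e-8)     # A + B conserved
    expect_equal(unname(ss$state["A"]), 5, tolerance = 1e-6)
    expect_equal(unname(ss$state["B"]), 5, tolerance = 1e-6)
})
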
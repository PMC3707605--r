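toy1 <- function() generateToyNetwork(
    ToyNetworkSpec(nGenes = 1, cascadeDepth = 1, nMirnaTargets = 0))

test_that("parameter sampling is seeded, bounded and log-centered", {
    toy <- generateToyNetwork(ToyNetworkSpec(nGenes = 3, nMirnaTargets = 0,
                                             cascadeDepth = 1))
    sp <- SamplingSpec(nSamples = 50, decades = 1, seed = 4)
    e1 <- sampleParameters(toy$model, sp)
    e2 <- sampleParameters(toy$model, sp)
    expect_identical(e1, e2)
    expect_true(all(e1 >= 0.1 & e1 <= 10))
    expect_identical(rownames(e1), names(modelParameters(toy$model)))
    # median of log10 draws ~ 0 at n = 10^4
    big <- sampleParameters(toy$model,
                            SamplingSpec(nSamples = 1000, seed = 8))
    expect_lt(abs(median(log10(big))), 0.1)
})

test_that("state initialization maps expression onto gene templates only", {
    toy <- generateToyNetwork(ToyNetworkSpec(nGenes = 3, cascadeDepth = 1,
                                             nMirnaTargets = 0))
    expr <- c(G01 = 2, G02 = 2, G03 = 2)
    st <- initializeState(toy$model, expr, label = "N0")
    comp <- modelComponents(st)
    expect_true(all(comp$initial[comp$kind == "gene-template"] == 2))
    # doubling one gene doubles that template only
    st2 <- initializeState(toy$model, c(G01 = 4, G02 = 2, G03 = 2))
    c2 <- modelComponents(st2)
    expect_equal(c2$initial[c2$id == "G01_tpl"], 4)
    expect_equal(c2$initial[c2$id == "G02_tpl"], 2)
    # unmatched symbols are skipped with a message, not an error
    expect_message(st3 <- initializeState(toy$model, c(G01 = 3, NOPE = 1)),
                   "NOPE")
    c3 <- modelComponents(st3)
    expect_equal(c3$initial[c3$id == "G01_tpl"], 3)
    expect_equal(c3$initial[c3$id == "G02_tpl"], 1)
    expect_error(initializeState(toy$model, c(G01 = -1)), ">= 0")
})

test_that("steady states hit analytic fixed points", {
    # synthesis-degradation: x* = k_s / k_d
    ss <- runToSteadyState(toy1()$model,
                           parameters = c(k_tx_G01 = 2, k_degr_G01 = 1),
                           tol = 1e-9)
    expect_true(ss$converged)
    expect_equal(unname(ss$state["G01_rna"]), 2, tolerance = 1e-6)
    # steady state is an attractor: independent of the basal start
    spec <- ToyNetworkSpec(nGenes = 4, cascadeDepth = 2, nMirnaTargets = 0,
                           nParents = 2, seed = 3)
    a <- runToSteadyState(generateToyNetwork(spec)$model, tol = 1e-9)
    specB <- ToyNetworkSpec(nGenes = 4, cascadeDepth = 2, nMirnaTargets = 0,
                            nParents = 2, basalAmount = 0.05, seed = 3)
    b <- runToSteadyState(generateToyNetwork(specB)$model, tol = 1e-9)
    keep <- a$state > 0
    expect_lt(max(abs(a$state[keep] - b$state[keep]) / a$state[keep]), 1e-4)
})

test_that("toy cascade steady state matches the layer-by-layer closed form", {
    spec <- ToyNetworkSpec(nGenes = 6, cascadeDepth = 3, nMirnaTargets = 0,
                           nParents = 2, seed = 6)
    toy <- generateToyNetwork(spec)
    mult <- setNames(10^runif(length(modelParameters(toy$model)), -1, 1),
                     names(modelParameters(toy$model)))
    ss <- runToSteadyState(toy$model,
                           parameters = modelParameters(toy$model) * mult,
                           tol = 1e-10)
    expect_true(ss$converged)
    oracle <- toyClosedForm(toy, multipliers = mult)
    rel <- abs(ss$state - oracle) / (abs(oracle) + 1e-12)
    expect_lt(max(rel), 1e-5)
})

test_that("paired ensembles of identical conditions give null ratios", {
    toy <- generateToyNetwork(ToyNetworkSpec(nGenes = 2, cascadeDepth = 1,
                                             nMirnaTargets = 0))
    ens <- sampleParameters(toy$model, SamplingSpec(nSamples = 8, seed = 2))
    res <- simulateEnsemble(list(N0 = toy$model, T0 = toy$model), ens)
    expect_true(all(ensembleConverged(res)))
    expect_true(all(abs(ensembleAggregate(res)) < 1e-9))
    expect_true(all(ensemblePvalue(res) >= 0.99))
})

test_that("a halved synthesis constant shows up as a -1 log2 ratio", {
    toy <- generateToyNetwork(ToyNetworkSpec(nGenes = 2, cascadeDepth = 1,
                                             nMirnaTargets = 0))
    dis <- toy$model
    dis@parameters["k_tx_G01"] <- dis@parameters["k_tx_G01"] / 2
    ens <- sampleParameters(toy$model, SamplingSpec(nSamples = 6, seed = 3))
    res <- simulateEnsemble(list(N0 = toy$model, T0 = dis), ens)
    agg <- ensembleAggregate(res)
    expect_equal(unname(agg["G01_rna", "T0/N0"]), -1, tolerance = 0.2)
    expect_lt(abs(agg["G02_rna", "T0/N0"]), 0.05)
    # fixed seed: bit-stable result
    res2 <- simulateEnsemble(list(N0 = toy$model, T0 = dis), ens)
    expect_identical(ensembleAggregate(res2), agg)
})

test_that("condition order only flips ratio signs", {
    toy <- generateToyNetwork(ToyNetworkSpec(nGenes = 2, cascadeDepth = 1,
                                             nMirnaTargets = 0))
    dis <- toy$model
    dis@parameters["k_tx_G02"] <- dis@parameters["k_tx_G02"] * 4
    ens <- sampleParameters(toy$model, SamplingSpec(nSamples = 5, seed = 9))
    ab <- simulateEnsemble(list(A = toy$model, B = dis), ens,
                           pairs = "B/A")
    ba <- simulateEnsemble(list(B = dis, A = toy$model), ens,
                           pairs = "A/B")
    expect_equal(ensembleAggregate(ab)[, "B/A"],
                 -ensembleAggregate(ba)[, "A/B"], tolerance = 1e-9)
})
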
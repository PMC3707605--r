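#' @describeIn modelStats counts for a mass-action network model. Note that
#'   a model may report both a total component count and a smaller count of
#'   components carrying expression (non-fixed); both views are derivable
#'   from \code{nComponents}, \code{nFixed} and \code{nVariables}
#'   (\code{nVariables + nFixed = nComponents} always holds).
#' @export
setMethod("modelStats", "NetworkModel", function(object) {
    comp <- object@components
    genes <- unique(comp$gene[!is.na(comp$gene)])
    list(nReactions = length(object@reactions),
         nComponents = nrow(comp),
         nVariables = sum(!comp$fixed),
         nFixed = sum(comp$fixed),
         nParameters = length(object@parameters),
         nGenes = if (length(genes)) length(genes) else NA_integer_)
})

#' Build the mass-action ODE right-hand side of a model
#'
#' Constructs \eqn{dx/dt = S v(x; k)} with per-reaction rates
#' \eqn{v_j = k_j \prod_r x_r^{s_r} \prod_m x_m} (reactants r with
#' stoichiometry \eqn{s_r}, modifiers m). Derivatives of fixed components
#' are pinned to zero. The returned function is suitable for
#' \code{deSolve} integrators.
#'
#' @param model a \linkS4class{NetworkModel}.
#' @param parameters optional named numeric vector overriding the model's
#'   rate constants (must cover every reaction's parameter).
#' @return A function \code{f(x)} mapping a named (or model-ordered) state
#'   vector to the derivative vector; it errors on negative states. The
#'   stoichiometric matrix is attached as attribute \code{"stoichiometry"}
#'   and the rate-vector function as attribute \code{"rates"}.
#' @examples
#' toy <- generateToyNetwork(ToyNetworkSpec(nGenes = 2, cascadeDepth = 1))
#' f <- buildRateFunction(toy$model)
#' f(modelComponents(toy$model)$initial)
#' @export
buildRateFunction <- function(model, parameters = NULL) {
    stopifnot(is(model, "NetworkModel"))
    comp <- model@components
    n <- nrow(comp)
    ids <- comp$id
    k <- model@parameters
    if (!is.null(parameters)) k[names(parameters)] <- parameters
    nr <- length(model@reactions)
    kVec <- numeric(nr)
    # per-reaction indices and powers, plus sparse stoichiometry triplets
    facIdx <- vector("list", nr); facPow <- vector("list", nr)
    si <- integer(); sj <- integer(); sx <- numeric()
    for (j in seq_len(nr)) {
        rx <- model@reactions[[j]]
        kVec[j] <- k[[rx$param]]
        idx <- c(match(rx$reactants$species, ids),
                 match(rx$modifiers, ids))
        pow <- c(rx$reactants$stoich, rep(1, length(rx$modifiers)))
        facIdx[[j]] <- idx; facPow[[j]] <- pow
        if (nrow(rx$reactants)) {
            si <- c(si, match(rx$reactants$species, ids))
            sj <- c(sj, rep(j, nrow(rx$reactants)))
            sx <- c(sx, -rx$reactants$stoich)
        }
        if (nrow(rx$products)) {
            si <- c(si, match(rx$products$species, ids))
            sj <- c(sj, rep(j, nrow(rx$products)))
            sx <- c(sx, rx$products$stoich)
        }
    }
    S <- matrix(0, n, nr, dimnames = list(ids, vapply(model@reactions,
                                                      `[[`, "", "id")))
    for (t in seq_along(si)) S[si[t], sj[t]] <- S[si[t], sj[t]] + sx[t]
    S[comp$fixed, ] <- 0  # fixed components never change

    # dense power matrix: rate_j = k_j * prod_i x_i^P[j,i]; evaluated in
    # log space so one matrix product covers all reactions
    P <- matrix(0, nr, n)
    for (j in seq_len(nr)) {
        idx <- facIdx[[j]]
        for (t in seq_along(idx))
            P[j, idx[t]] <- P[j, idx[t]] + facPow[[j]][t]
    }
    hasFac <- rowSums(P != 0) > 0
    rates <- function(x) {
        lx <- log(pmax(x, .Machine$double.xmin))
        v <- kVec * exp(as.numeric(P %*% lx))
        # exact zeros: any zero state with positive power kills the rate
        if (any(x == 0)) {
            z <- which(x == 0)
            v[rowSums(P[, z, drop = FALSE] > 0) > 0] <- 0
        }
        v
    }
    f <- function(x) {
        if (length(x) != n)
            stop("state vector must have length ", n)
        if (!is.null(names(x))) x <- x[ids]
        if (any(!is.finite(x)) || any(x < -1e-12))
            stop("state must be finite and non-negative")
        d <- as.numeric(S %*% rates(pmax(x, 0)))
        names(d) <- ids
        d
    }
    attr(f, "stoichiometry") <- S
    attr(f, "rates") <- rates
    # analytic jacobian of S v(x): d v_j / d x_i = v_j P[j,i] / x_i
    attr(f, "jacobian") <- function(x) {
        x <- pmax(x, 1e-12)
        v <- rates(x)
        S %*% (P * outer(v, 1 / x))
    }
    f
}
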
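# Independent oracles used across the suite. Each is deliberately written
# from the definition, not from the package's implementation path.

# on-target counting by naive pairwise enumeration over integer coordinates
bruteOverlapCounts <- function(alignments, targets) {
    as <- GenomicRanges::start(alignments); ae <- GenomicRanges::end(alignments)
    out <- integer(length(targets))
    for (i in seq_along(targets)) {
        ts <- GenomicRanges::start(targets)[i]
        te <- GenomicRanges::end(targets)[i]
        n <- 0L
        for (j in seq_along(alignments)) {
            ov <- min(ae[j], te) - max(as[j], ts) + 1L
            if (ov >= 1L) n <- n + 1L
        }
        out[i] <- n
    }
    names(out) <- names(targets)
    out
}

# strict linear separability by sweeping candidate directions: normals to
# every point-pair difference (plus the differences themselves and small
# angular perturbations to resolve vertex-vertex margins)
bruteSeparable <- function(A, B) {
    P <- rbind(A, B)
    idx <- utils::combn(nrow(P), 2)
    d <- P[idx[1, ], , drop = FALSE] - P[idx[2, ], , drop = FALSE]
    d <- d[rowSums(d^2) > 0, , drop = FALSE]
    if (!nrow(d)) return(FALSE)  # all points coincide
    rot <- function(m, th) cbind(cos(th) * m[, 1] - sin(th) * m[, 2],
                                 sin(th) * m[, 1] + cos(th) * m[, 2])
    cand <- rbind(d, rot(d, pi / 2),
                  rot(d, pi / 2 + 1e-7), rot(d, pi / 2 - 1e-7))
    for (i in seq_len(nrow(cand))) {
        w <- cand[i, ] / sqrt(sum(cand[i, ]^2))
        pa <- drop(A %*% w); pb <- drop(B %*% w)
        tol <- 1e-9 * (max(abs(c(pa, pb))) + 1)  # exact ties overlap
        if (max(pa) < min(pb) - tol || max(pb) < min(pa) - tol)
            return(TRUE)
    }
    FALSE
}

# region-by-region predicate for the ten-subgroup classifier
bruteClassify <- function(tn, mn, cc = 0.58) {
    if (tn > cc) {
        if (mn > tn) "aggravated+"
        else if (mn > cc) "weak+"
        else if (mn >= -cc) "desired+"
        else "flip+-"
    } else if (tn < -cc) {
        if (mn < tn) "aggravated-"
        else if (mn < -cc) "weak-"
        else if (mn <= cc) "desired-"
        else "flip-+"
    } else {
        if (mn > cc) "side+"
        else if (mn < -cc) "side-"
        else "none"
    }
}

# closed-form steady state of the layered toy motif, computed layer by
# layer from the generator's parent wiring: rna* = k_tx * tpl * prod(
# driver proteins) / k_degr ; prot* = k_tl * rna* / k_degp
toyClosedForm <- function(toy, model = toy$model, multipliers = NULL) {
    comp <- modelComponents(model)
    k <- modelParameters(model)
    if (!is.null(multipliers)) k <- k * multipliers[names(k)]
    genes <- comp$gene[comp$kind == "gene-template"]
    tpl <- setNames(comp$initial[comp$kind == "gene-template"], genes)
    lig <- comp$initial[comp$id == "LIG"]
    rna <- prot <- setNames(rep(NA_real_, length(genes)), genes)
    remaining <- genes
    while (length(remaining)) {
        for (g in remaining) {
            par <- toy$parents[[g]]
            if (length(par) && any(is.na(prot[par]))) next
            drive <- if (length(par)) prod(prot[par]) else lig
            rna[g] <- k[paste0("k_tx_", g)] * tpl[g] * drive /
                k[paste0("k_degr_", g)]
            prot[g] <- k[paste0("k_tl_", g)] * rna[g] /
                k[paste0("k_degp_", g)]
        }
        remaining <- genes[is.na(rna)]
    }
    st <- setNames(comp$initial, comp$id)
    st[paste0(genes, "_rna")] <- rna
    st[paste0(genes, "_prot")] <- prot
    st
}

# exact two-sided Mann-Whitney p by enumerating all group labelings
enumerateMannWhitneyP <- function(x, y) {
    pooled <- c(x, y)
    nx <- length(x)
    U <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
    obs <- U(x, y)
    combos <- utils::combn(length(pooled), nx)
    us <- apply(combos, 2, function(ii) U(pooled[ii], pooled[-ii]))
    mu <- nx * (length(pooled) - nx) / 2
    mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}

# small helper: MirnaCounts from a plain matrix of per-tissue counts
makeCounts <- function(mat, patient, tissue) {
    MirnaCounts(mat, patient = patient, tissue = tissue)
}
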
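#' Specification of a synthetic matched miRNA-Seq cohort
#'
#' Describes a cohort of matched normal/tumor/metastasis small-RNA samples
#' with planted differential expression, emulating an 8-patient x 3-tissue
#' sequencing design. Counts follow a negative-binomial model; per-miRNA
#' baseline means are log-normal across miRNAs and each sample carries a
#' mild log-normal library-size factor.
#'
#' @param nPatients number of patients (default 8, the matched-cohort size).
#' @param tissues tissue labels, subset of \code{c("N","T","M")}.
#' @param nMirnas number of miRNAs (default 724, the number of miRNAs
#'   detectable in such a cohort).
#' @param nPlantedUp,nPlantedDown numbers of miRNAs planted up-/down-regulated
#'   in tumor and metastasis relative to normal.
#' @param plantedLog2fc absolute planted effect, log2 units (default 3).
#' @param dispersion negative-binomial dispersion (1/size); 0 gives Poisson.
#' @param meanLog,meanSdLog log-normal parameters of per-miRNA baseline means.
#' @param librarySdLog sd(log) of per-sample library-size factors.
#' @param seed integer RNG seed.
#' @return A validated list of class \code{"CohortSpec"}.
#' @export
CohortSpec <- function(nPatients = 8L, tissues = c("N", "T", "M"),
                       nMirnas = 724L, nPlantedUp = 25L, nPlantedDown = 25L,
                       plantedLog2fc = 3, dispersion = 0.1,
                       meanLog = log(100), meanSdLog = 1.5,
                       librarySdLog = 0.1, seed = 1L) {
    spec <- list(nPatients = as.integer(nPatients), tissues = tissues,
                 nMirnas = as.integer(nMirnas),
                 nPlantedUp = as.integer(nPlantedUp),
                 nPlantedDown = as.integer(nPlantedDown),
                 plantedLog2fc = plantedLog2fc, dispersion = dispersion,
                 meanLog = meanLog, meanSdLog = meanSdLog,
                 librarySdLog = librarySdLog, seed = as.integer(seed))
    if (spec$nPatients < 1 || spec$nMirnas < 0 ||
        spec$nPlantedUp < 0 || spec$nPlantedDown < 0)
        stop("cohort dimensions must be non-negative (>=1 patient)")
    if (spec$nPlantedUp + spec$nPlantedDown > spec$nMirnas)
        stop("nPlantedUp + nPlantedDown must not exceed nMirnas")
    if (!all(tissues %in% c("N", "T", "M")) || !length(tissues))
        stop("tissues must be a non-empty subset of c('N','T','M')")
    if (spec$dispersion < 0) stop("dispersion must be >= 0")
    class(spec) <- "CohortSpec"
    spec
}

#' Generate a matched miRNA-Seq count cohort with planted effects
#'
#' Draws a negative-binomial count matrix for \code{nPatients} patients x
#' \code{tissues}, planting \code{nPlantedUp} miRNAs with expected
#' tumor/normal and metastasis/normal log2 ratio \code{+plantedLog2fc} and
#' \code{nPlantedDown} with \code{-plantedLog2fc}. Identical specs (same
#' seed) yield identical output.
#'
#' @param spec a [CohortSpec()].
#' @return A list: \code{counts} (a \linkS4class{MirnaCounts}) and
#'   \code{truth} (data.frame \code{mirna}, \code{direction} in
#'   \code{c("up","down","none")}, \code{log2fc}).
#' @examples
#' cohort <- generateCountCohort(CohortSpec(nMirnas = 50, seed = 7))
#' table(cohort$truth$direction)
#' @export
generateCountCohort <- function(spec) {
    stopifnot(inherits(spec, "CohortSpec"))
    withSeed(spec$seed, {
        nm <- spec$nMirnas
        mirnas <- sprintf("miR-sim-%03d", seq_len(nm))
        direction <- rep("none", nm)
        if (spec$nPlantedUp > 0) direction[seq_len(spec$nPlantedUp)] <- "up"
        if (spec$nPlantedDown > 0)
            direction[spec$nPlantedUp + seq_len(spec$nPlantedDown)] <- "down"
        log2fc <- ifelse(direction == "up", spec$plantedLog2fc,
                  ifelse(direction == "down", -spec$plantedLog2fc, 0))
        baseMean <- exp(rnorm(nm, spec$meanLog, spec$meanSdLog))

        patient <- rep(sprintf("P%d", seq_len(spec$nPatients)),
                       each = length(spec$tissues))
        tissue <- rep(spec$tissues, times = spec$nPatients)
        nSamp <- length(patient)
        libFactor <- exp(rnorm(nSamp, 0, spec$librarySdLog))

        counts <- matrix(0L, nm, nSamp,
                         dimnames = list(mirnas, paste0(patient, "_", tissue)))
        for (j in seq_len(nSamp)) {
            eff <- if (tissue[j] == "N") rep(1, nm) else 2^log2fc
            mu <- baseMean * libFactor[j] * eff
            counts[, j] <- as.integer(rCounts(nm, mu, spec$dispersion))
        }
        list(counts = MirnaCounts(counts, patient, tissue),
             truth = data.frame(mirna = mirnas, direction = direction,
                                log2fc = log2fc))
    })
}

#' Generate a synthetic qPCR Ct table with a reference gene
#'
#' Emulates stem-loop RT-PCR validation data: per-sample cycle-threshold
#' values for target miRNAs and a stably expressed reference small RNA
#' (an RNU44 analog) in normal and tumor tissue, with known planted fold
#' changes (tumor vs normal, linear scale).
#'
#' @param nSamples samples per tissue.
#' @param seed integer RNG seed.
#' @param foldChanges named numeric vector of planted tumor/normal fold
#'   changes per target (default: one 8-fold-down and one 9-fold-up miRNA,
#'   typical magnitudes for de-regulated miRNAs in this design).
#' @param referenceGene name of the reference gene.
#' @param noiseSd technical noise sd in cycles.
#' @return A list: \code{ct} (data.frame \code{sample}, \code{tissue},
#'   \code{gene}, \code{ct}) and \code{truth} (data.frame \code{gene},
#'   \code{foldChange}).
#' @export
generateCtTable <- function(nSamples, seed = 1L,
                            foldChanges = c("miR-sim-dn" = 1 / 8,
                                            "miR-sim-up" = 9),
                            referenceGene = "RNU44", noiseSd = 0.15) {
    stopifnot(nSamples >= 1, all(foldChanges > 0))
    withSeed(seed, {
        tissues <- rep(c("N", "T"), each = nSamples)
        samples <- paste0("S", seq_along(tissues), "_", tissues)
        genes <- c(referenceGene, names(foldChanges))
        baseCt <- c(25, 28 + seq_along(foldChanges))  # ref then targets
        names(baseCt) <- genes
        rows <- lapply(genes, function(g) {
            ct <- baseCt[g] + rnorm(length(samples), 0, noiseSd)
            if (g != referenceGene)  # higher expression -> lower Ct
                ct <- ct - ifelse(tissues == "T", log2(foldChanges[g]), 0)
            data.frame(sample = samples, tissue = tissues, gene = g, ct = ct)
        })
        list(ct = do.call(rbind, rows),
             truth = data.frame(gene = names(foldChanges),
                                foldChange = unname(foldChanges)))
    })
}
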
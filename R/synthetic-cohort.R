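#' Configuration for the synthetic paired-cohort generator
#'
#' Builds and validates the parameter set controlling [simulateCohort()].
#' Defaults emulate the study conditions of a paired primary-metastasis
#' breast cancer cohort: 55 participants, about a third with more than
#' one metastasis, metastatic sites weighted toward liver/lung/lymph
#' node/brain, a basal-enriched subtype mix, fresh-frozen metastases with
#' largely FFPE primaries, and tumor purity between 0.3 and 0.95 (tumors
#' below 30% tumor nuclei would not pass pathology review).
#'
#' @param nParticipants number of participants; each contributes one
#'   primary tumor and at least one metastasis.
#' @param extraMetProb probability that a participant has more than one
#'   metastasis profiled.
#' @param maxExtraMets maximum number of additional metastases.
#' @param subtypeMix named proportions over the five intrinsic subtypes
#'   `LumA`, `LumB`, `HER2E`, `Basal`, `Normal-like`; must sum to 1.
#' @param siteWeights named weights for metastatic sites `liver`, `lung`,
#'   `lymph node`, `brain`, `other`.
#' @param nGenes,nProbes,nVariants,nCnBins sizes of the simulated gene,
#'   CpG probe, somatic variant and copy-ratio bin universes.
#' @param deltaBeta planted methylation effect size (beta-value units)
#'   for hypo-/hypermethylated CpGs in metastases.
#' @param nHypoProbes,nHyperProbes numbers of planted hypo-/hyper-
#'   methylated CpGs.
#' @param batchLog2Sd standard deviation of gene-specific FFPE-vs-FF
#'   log2 offsets.
#' @param receptorShiftSd standard deviation of the gene-specific
#'   ER-status expression shift over the classifier genes (the nuisance
#'   that ER/HER2 subgroup-specific centering removes).
#' @param contaminationLog2 log2 elevation of site-specific normal-tissue
#'   contamination genes in metastases at the matching site (and in the
#'   matching normal tissue).
#' @param nContamGenes contamination genes per site (liver, lung, brain).
#' @param noiseSd log2-scale biological noise standard deviation for
#'   expression.
#' @param participantGeneSd standard deviation of gene-specific
#'   participant effects (the individual tumor profile shared between a
#'   primary and its metastases, which drives pair concordance).
#' @param dispersion negative-binomial size parameter for counts
#'   (larger = less overdispersed).
#' @param purityRange range of the uniform tumor-purity distribution.
#' @param artifactFraction fraction of simulated variants that are FFPE
#'   artifacts.
#' @param methNoiseSd measurement noise SD added to observed beta
#'   values (0 makes the purity-mixture relation exact).
#' @param betaMaskRate fraction of beta cells masked as detection
#'   failures.
#' @param cnNoiseSd per-bin noise SD of denoised log2 copy ratios.
#' @param focalDeletionDepth planted log2 depth of HLA-locus focal
#'   deletions.
#' @param ffpePrimaryProb,ffpeMetProb probability that a primary /
#'   metastasis sample is FFPE-preserved.
#' @param seed integer random seed; one global seed spawns fixed-offset
#'   substreams per data type so that adding one data type never
#'   perturbs another's draws.
#' @return A validated list of class `syntheticConfig`.
#' @export
syntheticConfig <- function(nParticipants = 55,
                            extraMetProb = 0.35,
                            maxExtraMets = 3,
                            subtypeMix = c(LumA = 0.20, LumB = 0.15,
                                           HER2E = 0.10, Basal = 0.40,
                                           `Normal-like` = 0.15),
                            siteWeights = c(liver = 28, lung = 13,
                                            `lymph node` = 12, brain = 11,
                                            other = 16),
                            nGenes = 2000, nProbes = 2000,
                            nVariants = 500, nCnBins = 3000,
                            deltaBeta = 0.3,
                            nHypoProbes = 50, nHyperProbes = 30,
                            batchLog2Sd = 0.5, receptorShiftSd = 0.5,
                            contaminationLog2 = 2, nContamGenes = 30,
                            noiseSd = 0.25, dispersion = 20,
                            participantGeneSd = 0.5,
                            purityRange = c(0.3, 0.95),
                            artifactFraction = 0.3,
                            methNoiseSd = 0.02, betaMaskRate = 0.005,
                            cnNoiseSd = 0.05,
                            focalDeletionDepth = -1.2,
                            ffpePrimaryProb = 0.6, ffpeMetProb = 0.1,
                            seed = 1L) {
    cfg <- as.list(environment())
    counts <- c(nParticipants = nParticipants, nGenes = nGenes,
                nProbes = nProbes, nVariants = nVariants,
                nCnBins = nCnBins)
    if (any(counts <= 0) || any(counts != round(counts)))
        stop("configuration error: counts must be positive integers")
    if (nCnBins < 400)
        stop("configuration error: nCnBins must be >= 400 (the locus ",
             "layout needs room for genes, flanks and planted events)")
    if (abs(sum(subtypeMix) - 1) > 1e-8 || any(subtypeMix < 0))
        stop("configuration error: subtypeMix must be nonnegative and sum to 1")
    if (!setequal(names(subtypeMix),
                  c("LumA", "LumB", "HER2E", "Basal", "Normal-like")))
        stop("configuration error: subtypeMix must name the five subtypes")
    if (artifactFraction < 0 || artifactFraction > 1)
        stop("configuration error: artifactFraction must lie in [0, 1]")
    if (any(purityRange < 0) || any(purityRange > 1) ||
        purityRange[1] > purityRange[2])
        stop("configuration error: purityRange must be within [0, 1]")
    if (deltaBeta < 0 || deltaBeta > 1)
        stop("configuration error: deltaBeta must lie in [0, 1]")
    structure(cfg, class = "syntheticConfig")
}

.SUBTYPES <- c("LumA", "LumB", "HER2E", "Basal", "Normal-like")
.MHC_GENES <- c("HLA_A", "HLA_B", "HLA_C", "B2M", "TAP1", "TAP2", "NLRC5")
.CONTAM_SITES <- c("liver", "lung", "brain")
.N_IMMUNE_SIGS <- 16L
.IMMUNE_GENES_PER_SIG <- 8L

## Fixed substream offsets: the skeleton uses the seed itself, each data
## type its own offset, so adding a data type never shifts another's draws.
.substream <- function(config, k) set.seed(config$seed + k)

## Gene universe shared by the expression and variant simulators.
.geneUniverse <- function(config) {
    pam <- sprintf("PAMG%02d", 1:50)
    receptor <- c("ESR1", "ERBB2")
    imm <- as.vector(outer(sprintf("g%02d", seq_len(.IMMUNE_GENES_PER_SIG)),
                           sprintf("IMM%02d", seq_len(.N_IMMUNE_SIGS)),
                           function(g, s) paste0(s, "_", g)))
    contam <- unlist(lapply(.CONTAM_SITES, function(s)
        sprintf("CONTAM_%s_%02d", s, seq_len(config$nContamGenes))))
    core <- c(pam, receptor, .MHC_GENES, imm, contam)
    nFill <- max(0L, config$nGenes - length(core))
    genes <- c(core, sprintf("GENE%04d", seq_len(nFill)))
    list(genes = genes, pam = pam, receptor = receptor, mhc = .MHC_GENES,
         immune = split(imm, rep(seq_len(.N_IMMUNE_SIGS),
                                 each = .IMMUNE_GENES_PER_SIG)),
         contam = stats::setNames(
             lapply(.CONTAM_SITES, function(s)
                 sprintf("CONTAM_%s_%02d", s, seq_len(config$nContamGenes))),
             .CONTAM_SITES))
}

#' Simulate a paired primary-metastasis cohort with recorded ground truth
#'
#' Generates the full synthetic cohort: a sample sheet of paired
#' primary/metastasis tumors, a count-stage expression matrix plus normal
#' tissue reference matrices, a CpG beta matrix with probe annotation and
#' an 8-tissue normal methylation panel, somatic variant records with
#' read-level evidence, denoised copy-ratio tracks with segment
#' definitions, and a `truth` list recording every planted parameter
#' (subtype labels, methylation effects, contamination genes, artifact
#' status, copy-number events, preservation labels and purity).  All
#' randomness derives from `config$seed`; two runs with the same
#' configuration are bit-identical.
#'
#' @param config a [syntheticConfig()] object.
#' @return list with elements `samples` (data.frame sample sheet),
#'   `expression`, `normals`, `beta`, `normalPanel`, `variants`,
#'   `copyRatios`, `geneLog2`, `segments`, `geneRanges`, `centroids`
#'   and `truth`.
#' @examples
#' cohort <- simulateCohort(syntheticConfig(nParticipants = 4,
#'     nGenes = 400, nProbes = 200, nVariants = 20, nCnBins = 500))
#' head(cohort$samples)
#' @export
simulateCohort <- function(config) {
    stopifnot(inherits(config, "syntheticConfig"))
    truth <- .simulateSkeleton(config)
    expr <- simulateExpression(truth, config)
    truth <- expr$truth
    meth <- simulateMethylation(truth, config)
    truth <- meth$truth
    vars <- simulateReadEvidence(truth, config)
    truth <- vars$truth
    cn <- simulateCopyRatios(truth, config)
    truth <- cn$truth
    list(samples = truth$samples,
         expression = expr$expression, normals = expr$normals,
         beta = meth$beta, normalPanel = meth$normalPanel,
         variants = vars$variants,
         copyRatios = cn$tracks, geneLog2 = cn$geneLog2,
         segments = cn$segments, geneRanges = cn$geneRanges,
         centroids = truth$centroids,
         truth = truth)
}

## Sample sheet + per-sample truth (subtype, site, purity, preservation).
.simulateSkeleton <- function(config) {
    .substream(config, 0L)
    nP <- config$nParticipants
    pid <- sprintf("P%03d", seq_len(nP))
    subtype <- sample(.SUBTYPES, nP, replace = TRUE,
                      prob = config$subtypeMix[.SUBTYPES])
    nMets <- 1L + stats::rbinom(nP, config$maxExtraMets,
                                config$extraMetProb / config$maxExtraMets)
    rows <- lapply(seq_len(nP), function(i) {
        sites <- sample(names(config$siteWeights), nMets[i], replace = TRUE,
                        prob = config$siteWeights)
        data.frame(
            sample = c(paste0(pid[i], "_P"),
                       paste0(pid[i], "_M", seq_len(nMets[i]))),
            participant = pid[i],
            type = c("primary", rep("metastasis", nMets[i])),
            site = c("breast", sites),
            stringsAsFactors = FALSE)
    })
    samples <- do.call(rbind, rows)
    rownames(samples) <- samples$sample
    isPrim <- samples$type == "primary"
    samples$preservation <- ifelse(
        stats::runif(nrow(samples)) <
            ifelse(isPrim, config$ffpePrimaryProb, config$ffpeMetProb),
        "FFPE", "FF")
    samples$purity <- stats::runif(nrow(samples), config$purityRange[1],
                                   config$purityRange[2])
    samples$subtype <- subtype[match(samples$participant, pid)]
    ## clinical receptor status: probabilistically linked to the intrinsic
    ## subtype (ER+ dominates luminal, HER2+ the HER2-enriched phenotype,
    ## with realistic crossover), constant within a participant;
    ## metastases frequently lack clinical values
    erProb <- c(LumA = 0.95, LumB = 0.90, HER2E = 0.50, Basal = 0.10,
                `Normal-like` = 0.50)
    her2Prob <- c(LumA = 0.10, LumB = 0.15, HER2E = 0.80, Basal = 0.05,
                  `Normal-like` = 0.10)
    erPos <- stats::runif(nP) < erProb[subtype]
    her2Pos <- stats::runif(nP) < her2Prob[subtype]
    erTrue <- ifelse(erPos[match(samples$participant, pid)],
                     "positive", "negative")
    her2True <- ifelse(her2Pos[match(samples$participant, pid)],
                       "positive", "negative")
    missRate <- ifelse(isPrim, 0.05, 0.35)
    samples$erStatus <- ifelse(stats::runif(nrow(samples)) < missRate,
                               NA_character_, erTrue)
    samples$her2Status <- ifelse(stats::runif(nrow(samples)) < missRate,
                                 NA_character_, her2True)
    list(samples = samples, participants = pid,
         subtype = stats::setNames(samples$subtype, samples$sample),
         erTruth = stats::setNames(erTrue, samples$sample),
         her2Truth = stats::setNames(her2True, samples$sample))
}

#' Simulate the expression component of a synthetic cohort
#'
#' Each tumor sample's expected log2 profile is the sum of a gene
#' baseline, the sample's subtype centroid over the 50 classifier genes,
#' a participant random effect, a gene-specific FFPE batch offset, a
#' site-matched contamination elevation for metastases, and an
#' immune-activity component over the immune-signature and MHC class I
#' genes.  Counts are negative binomial around the exponentiated log
#' means.  Normal-tissue reference matrices (liver, lung, brain, breast)
#' are generated alongside for the contamination-signature chain.
#'
#' @param truth cohort truth skeleton (from [simulateCohort()]).
#' @param config a [syntheticConfig()].
#' @return list with `expression` (a counts-stage [StagedExpression-class]),
#'   `normals` (named list of normal-tissue count matrices) and the
#'   augmented `truth` (adds `centroids`, `logMeans`, `batchOffsets`,
#'   `immuneActivity`, `contamGenes`, `immuneSignatures`).
#' @export
simulateExpression <- function(truth, config) {
    .substream(config, 1L)
    uni <- .geneUniverse(config)
    genes <- uni$genes
    samples <- truth$samples
    nG <- length(genes); nS <- nrow(samples)

    baseline <- stats::setNames(stats::runif(nG, 3, 8), genes)
    centroids <- matrix(stats::rnorm(50L * 5L, 0, 2), 50L, 5L,
                        dimnames = list(uni$pam, .SUBTYPES))
    partEff <- stats::setNames(stats::rnorm(length(truth$participants), 0, 0.3),
                               truth$participants)
    ## gene-specific individual profile shared within a participant
    partGeneEff <- matrix(stats::rnorm(nG * length(truth$participants), 0,
                                       config$participantGeneSd),
                          nG, length(truth$participants),
                          dimnames = list(genes, truth$participants))
    batchOffsets <- stats::setNames(stats::rnorm(nG, 0, config$batchLog2Sd),
                                    genes)
    immuneActivity <- stats::setNames(stats::rnorm(nS, 0, 1), samples$sample)
    immuneGenes <- unlist(uni$immune)

    logMeans <- matrix(baseline, nG, nS,
                       dimnames = list(genes, samples$sample))
    logMeans[uni$pam, ] <- logMeans[uni$pam, ] +
        centroids[, samples$subtype, drop = FALSE]
    logMeans <- sweep(logMeans, 2, partEff[samples$participant], `+`)
    logMeans <- logMeans + partGeneEff[, samples$participant]
    ffpe <- samples$preservation == "FFPE"
    logMeans[, ffpe] <- logMeans[, ffpe] + batchOffsets
    for (site in .CONTAM_SITES) {
        hit <- samples$type == "metastasis" & samples$site == site
        if (any(hit))
            logMeans[uni$contam[[site]], hit] <-
                logMeans[uni$contam[[site]], hit] + config$contaminationLog2
    }
    erPos <- truth$erTruth[samples$sample] == "positive"
    her2Pos <- truth$her2Truth[samples$sample] == "positive"
    logMeans["ESR1", erPos] <- logMeans["ESR1", erPos] + 3
    logMeans["ERBB2", her2Pos] <- logMeans["ERBB2", her2Pos] + 3
    ## ER-driven nuisance over the classifier genes, shared by all ER+
    ## samples regardless of subtype
    erShift <- stats::setNames(stats::rnorm(length(uni$pam), 0,
                                            config$receptorShiftSd),
                               uni$pam)
    logMeans[uni$pam, erPos] <- logMeans[uni$pam, erPos] + erShift
    truth$erShift <- erShift
    logMeans[immuneGenes, ] <- sweep(logMeans[immuneGenes, , drop = FALSE],
                                     2, 0.8 * immuneActivity, `+`)
    logMeans[uni$mhc, ] <- sweep(logMeans[uni$mhc, , drop = FALSE],
                                 2, 0.5 * immuneActivity, `+`)

    mu <- 2^(logMeans + matrix(stats::rnorm(nG * nS, 0, config$noiseSd),
                               nG, nS))
    counts <- matrix(stats::rnbinom(nG * nS, mu = mu,
                                    size = config$dispersion),
                     nG, nS, dimnames = dimnames(logMeans))

    normalN <- c(liver = 8L, lung = 7L, brain = 10L, breast = 5L)
    normals <- lapply(names(normalN), function(tis) {
        n <- normalN[[tis]]
        lm0 <- matrix(baseline, nG, n,
                      dimnames = list(genes,
                                      sprintf("N_%s_%02d", tis, seq_len(n))))
        if (tis %in% .CONTAM_SITES)
            lm0[uni$contam[[tis]], ] <- lm0[uni$contam[[tis]], ] +
                config$contaminationLog2
        mu0 <- 2^(lm0 + matrix(stats::rnorm(nG * n, 0, config$noiseSd),
                               nG, n))
        matrix(stats::rnbinom(nG * n, mu = mu0, size = config$dispersion),
               nG, n, dimnames = dimnames(lm0))
    })
    names(normals) <- names(normalN)

    truth$centroids <- centroids
    truth$logMeans <- logMeans
    truth$batchOffsets <- batchOffsets
    truth$immuneActivity <- immuneActivity
    truth$contamGenes <- uni$contam
    truth$immuneSignatures <- stats::setNames(
        uni$immune, sprintf("IMM%02d", seq_len(.N_IMMUNE_SIGS)))
    list(expression = StagedExpression(counts, "counts",
                                       colData = DataFrame(samples)),
         normals = normals, truth = truth)
}

#' Simulate the DNA-methylation component of a synthetic cohort
#'
#' CpG probes fall into constitutively methylated distal-enhancer
#' backgrounds, constitutively unmethylated backgrounds, tissue-variable
#' probes, FFPE preservation-biased probes and promoter-island probes of
#' the MHC class I genes.  The observed tumor beta value is the purity
#' mixture `purity * tumor_beta + (1 - purity) * stroma_beta`, where the
#' stromal component is the normal-panel value of the sample's tissue
#' site.  Hypomethylation effects (`deltaBeta`) are planted in metastasis
#' tumor cells at constitutively methylated dELS probes, hypermethylation
#' at constitutively unmethylated probes, and HLA-A-like promoter
#' methylation in a subset of participants.
#'
#' @inheritParams simulateExpression
#' @return list with `beta` (a [BetaSet-class]), `normalPanel` (probe x
#'   8-tissue matrix of normal mean beta values) and augmented `truth`
#'   (adds `probeStatus`, `probeDelta`, `preservationBiasedProbes`,
#'   `hlaMethylatedSamples`, `tumorBeta`, `stromaBeta`).
#' @export
simulateMethylation <- function(truth, config) {
    .substream(config, 2L)
    samples <- truth$samples
    nS <- nrow(samples)
    nP <- config$nProbes
    tissues <- c("liver", "lung", "brain", "breast", "adrenal", "skin",
                 "blood", "ovary")

    ## probe layout
    promGenes <- c(HLA_A = 8L, HLA_B = 14L, HLA_C = 12L, B2M = 6L)
    nProm <- sum(promGenes)
    nHypo <- config$nHypoProbes
    nHyper <- config$nHyperProbes
    nBias <- max(10L, round(0.05 * nP))
    nVar <- max(10L, round(0.10 * nP))
    nHighExtra <- max(0L, round(0.35 * nP) - nHypo)
    nNearTss <- 20L   # dELS-like but too close to a TSS: must be screened out
    used <- nProm + nHypo + nHyper + nBias + nVar + nHighExtra + nNearTss
    if (used > nP)
        stop("configuration error: nProbes too small for the probe layout")
    nLow <- nP - used
    class <- c(rep("promoter", nProm),
               rep("hypo", nHypo), rep("high", nHighExtra),
               rep("nearTss", nNearTss),
               rep("hyper", nHyper), rep("low", nLow),
               rep("variable", nVar), rep("bias", nBias))
    probes <- sprintf("cg%06d", seq_len(nP))
    promGene <- rep(names(promGenes), promGenes)

    ## normal 8-tissue panel of mean beta values
    center <- numeric(nP)
    center[class %in% c("hypo", "high", "nearTss")] <-
        stats::runif(sum(class %in% c("hypo", "high", "nearTss")), 0.88, 0.97)
    center[class %in% c("hyper", "low")] <-
        stats::runif(sum(class %in% c("hyper", "low")), 0.03, 0.12)
    center[class == "variable"] <- stats::runif(sum(class == "variable"),
                                                0.2, 0.8)
    center[class == "bias"] <- stats::runif(sum(class == "bias"), 0.15, 0.3)
    center[class == "promoter"] <- stats::runif(nProm, 0.03, 0.08)
    ## constitutive probes are constitutive: identical mean beta in every
    ## tissue (this is what the >0.8 / <=0.2 screens select for); only
    ## the tissue-variable class differs between tissues
    panel <- matrix(center, nP, 8, dimnames = list(probes, tissues))
    vSel <- class == "variable"
    panel[vSel, ] <- matrix(stats::runif(sum(vSel) * 8, 0.05, 0.95),
                            sum(vSel), 8)

    ## annotation (0-based positions)
    ann <- data.frame(
        chrom = "chr1", pos = (seq_len(nP) - 1L) * 500L,
        dELS = class %in% c("hypo", "high", "nearTss"),
        tssDistance = ifelse(class == "promoter", 150L,
                      ifelse(class == "nearTss", 1500L,
                             sample(2500:50000, nP, replace = TRUE))),
        nearestGene = ifelse(class == "promoter", promGene,
                             sample(sprintf("GENE%04d", 1:200), nP,
                                    replace = TRUE)),
        promoterIsland = class == "promoter",
        row.names = probes)

    ## planted effects
    status <- rep("null", nP)
    status[class == "hypo"] <- "hypo_in_met"
    status[class == "hyper"] <- "hyper_in_met"
    delta <- ifelse(status == "hypo_in_met", -config$deltaBeta,
                    ifelse(status == "hyper_in_met", config$deltaBeta, 0))
    hlaParticipants <- sample(truth$participants,
                              max(1L, round(0.2 * length(truth$participants))))
    hlaSamples <- samples$sample[samples$participant %in% hlaParticipants &
                                     samples$type == "metastasis"]

    ## tumor-cell beta and purity-diluted observed beta
    tumorBeta <- matrix(center, nP, nS,
                        dimnames = list(probes, samples$sample))
    isMet <- samples$type == "metastasis"
    tumorBeta[, isMet] <- tumorBeta[, isMet] + delta
    hlaA <- class == "promoter" & promGene[match(probes,
        probes[class == "promoter"])] == "HLA_A"
    hlaA[is.na(hlaA)] <- FALSE
    tumorBeta[hlaA, samples$sample %in% hlaSamples] <- 0.9
    stromaTissue <- ifelse(samples$type == "primary", "breast",
                           ifelse(samples$site %in% tissues, samples$site,
                                  "breast"))
    stromaBeta <- panel[, stromaTissue, drop = FALSE]
    colnames(stromaBeta) <- samples$sample
    pur <- samples$purity
    beta <- sweep(tumorBeta, 2, pur, `*`) +
        sweep(stromaBeta, 2, 1 - pur, `*`)
    if (config$methNoiseSd > 0)
        beta <- beta + matrix(stats::rnorm(nP * nS, 0, config$methNoiseSd),
                              nP, nS)
    biasSel <- class == "bias"
    ffpe <- samples$preservation == "FFPE"
    beta[biasSel, ffpe] <- beta[biasSel, ffpe] + 0.4
    beta <- pmin(pmax(beta, 0), 1)
    if (config$betaMaskRate > 0)
        beta[matrix(stats::runif(nP * nS) < config$betaMaskRate,
                    nP, nS)] <- NA

    truth$probeStatus <- stats::setNames(status, probes)
    truth$probeDelta <- stats::setNames(delta, probes)
    truth$probeClass <- stats::setNames(class, probes)
    truth$preservationBiasedProbes <- probes[biasSel]
    truth$hlaMethylatedSamples <- hlaSamples
    truth$tumorBeta <- tumorBeta
    truth$stromaBeta <- stromaBeta
    list(beta = BetaSet(beta, ann), normalPanel = panel, truth = truth)
}

.CLASS_WHITELIST <- c("Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del",
                      "In_Frame_Ins", "Missense_Mutation",
                      "Nonsense_Mutation", "Nonstop_Mutation",
                      "Splice_Site", "Translation_Start_Site")

#' Simulate somatic variant records with read-level evidence
#'
#' Real variants carry dispersed soft-trimmed read coordinates and clean
#' pileup windows; FFPE artifacts (a configurable fraction, assigned to
#' FFPE samples) are drawn in one of three modes mirroring the targeted
#' failure signatures: (a) few unique read start positions, (b) few
#' unique variant-proximal read ends, (c) noisy +/-10-bp mismatch window
#' depressing the corrected allele frequency below 4%.
#'
#' @inheritParams simulateExpression
#' @return list with `variants` (a `DataFrame` with list columns
#'   `readStarts`/`readEnds`) and augmented `truth` (adds
#'   `variantStatus`, `artifactMode`).
#' @export
simulateReadEvidence <- function(truth, config) {
    .substream(config, 3L)
    samples <- truth$samples
    nV <- config$nVariants
    readLen <- 100L
    genePool <- c("TP53", "PIK3CA", "KMT2C", "FLG", "ESR1", "GATA3",
                  sprintf("GENE%04d", 1:44))
    ffpeSamples <- samples$sample[samples$preservation == "FFPE"]
    if (!length(ffpeSamples)) ffpeSamples <- samples$sample

    isArtifact <- stats::runif(nV) < config$artifactFraction
    mode <- ifelse(isArtifact, sample(c("a", "b", "c"), nV, replace = TRUE),
                   NA_character_)
    rows <- lapply(seq_len(nV), function(i) {
        pos <- sample.int(1e6, 1L)
        base <- sample(c("A", "C", "G", "T"), 2L)
        if (!isArtifact[i]) {
            smp <- sample(samples$sample, 1L)
            depth <- sample(50:300, 1L)
            vaf <- stats::runif(1, 0.08, 0.6)
            n <- max(2L, round(vaf * depth))
            starts <- pos - sample(5:(readLen - 5L), n, replace = TRUE)
            ends <- starts + readLen
            mmRate <- stats::runif(1, 0, 0.005)
        } else {
            smp <- sample(ffpeSamples, 1L)
            if (mode[i] == "c") {
                depth <- sample(100:300, 1L)
                vaf <- stats::runif(1, 0.02, 0.07)
                n <- max(2L, round(vaf * depth))
                starts <- pos - sample(5:(readLen - 5L), n, replace = TRUE)
                ends <- starts + readLen
                mmRate <- stats::runif(1, 0.06, 0.2)
            } else {
                n <- sample(16:40, 1L)
                vaf <- stats::runif(1, 0.1, 0.4)
                depth <- max(n, round(n / vaf))
                mmRate <- stats::runif(1, 0, 0.005)
                u <- sample(1:3, 1L)
                if (mode[i] == "a") {
                    us <- pos - sample(20:80, u)
                    starts <- us[sample.int(u, n, replace = TRUE)]
                    starts[seq_len(u)] <- us   # every unique value used
                    ends <- starts + readLen
                } else {   # mode b: ends cluster at the variant
                    ue <- pos + sample(2:6, u)
                    ends <- ue[sample.int(u, n, replace = TRUE)]
                    ends[seq_len(u)] <- ue
                    starts <- ends - sample(80:(readLen), n, replace = TRUE)
                }
            }
        }
        wTotal <- as.integer(round(depth) * 20)
        wMis <- stats::rbinom(1L, wTotal, mmRate)
        list(chrom = "chr17", pos = pos, ref = base[1], alt = base[2],
             vaf = vaf, sample = smp,
             gene = sample(genePool, 1L),
             classification = sample(c(.CLASS_WHITELIST,
                                       "Silent", "3'UTR", "Intron"), 1L,
                                     prob = c(rep(0.85 / 9, 9),
                                              rep(0.05, 3))),
             readStarts = starts, readEnds = ends,
             windowMismatch = wMis, windowTotal = wTotal)
    })
    variants <- DataFrame(
        variantId = sprintf("var%04d", seq_len(nV)),
        chrom = vapply(rows, `[[`, "", "chrom"),
        pos = vapply(rows, `[[`, 0L, "pos"),
        ref = vapply(rows, `[[`, "", "ref"),
        alt = vapply(rows, `[[`, "", "alt"),
        vaf = vapply(rows, `[[`, 0, "vaf"),
        sample = vapply(rows, `[[`, "", "sample"),
        gene = vapply(rows, `[[`, "", "gene"),
        classification = vapply(rows, `[[`, "", "classification"),
        windowMismatch = vapply(rows, `[[`, 0L, "windowMismatch"),
        windowTotal = vapply(rows, `[[`, 0L, "windowTotal"))
    variants$readStarts <- lapply(rows, function(r) as.integer(r$readStarts))
    variants$readEnds <- lapply(rows, function(r) as.integer(r$readEnds))
    truth$variantStatus <- stats::setNames(
        ifelse(isArtifact, "ffpe_artifact", "real"), variants$variantId)
    truth$artifactMode <- stats::setNames(mode, variants$variantId)
    list(variants = variants, truth = truth)
}

#' Simulate denoised copy-ratio tracks and segment-level gene values
#'
#' Per-sample tumor tracks are 1-kb bins on a single chromosome with
#' Gaussian noise around log2 = 0; planted focal deletions span
#' contiguous bins at or just upstream of an HLA-A-like locus at the
#' configured depth, and matched normal tracks carry noise only.  A
#' separate gene-by-sample matrix of gene-level log2 values carries
#' planted whole-segment gains and losses for the segment-scoring chain.
#'
#' @inheritParams simulateExpression
#' @return list with `tracks` (per-sample list of `tumor`/`normal`
#'   `GRanges` with a `log2` column), `geneLog2` (gene x sample matrix),
#'   `segments` (named list of member-gene vectors), `geneRanges`
#'   (`GRanges` of locus genes) and augmented `truth` (adds
#'   `focalDeletionSamples`, `focalDeletionBins`, `segmentEvents`).
#' @export
simulateCopyRatios <- function(truth, config) {
    .substream(config, 4L)
    samples <- truth$samples
    nB <- config$nCnBins
    binW <- 1000L
    starts <- (seq_len(nB) - 1L) * binW
    grid <- GRanges("chr6", IRanges(start = starts + 1L, width = binW))

    ## locus genes placed proportionally along the track
    ## (0-based bins -> 1-based GRanges)
    geneBins <- list(
        HLA_B = seq(floor(0.43 * nB), length.out = 6L),
        HLA_C = seq(floor(0.445 * nB), length.out = 5L),
        HLA_A = seq(floor(0.50 * nB), length.out = 10L),
        HLA_DRB5 = seq(floor(0.57 * nB), length.out = 5L),
        B2M = seq(floor(0.83 * nB), length.out = 5L))
    geneRanges <- GRanges("chr6", IRanges(
        start = vapply(geneBins, function(b) min(b) * binW + 1L, 0),
        end = vapply(geneBins, function(b) (max(b) + 1L) * binW, 0)))
    names(geneRanges) <- names(geneBins)

    isMet <- samples$type == "metastasis"
    delSamples <- sample(samples$sample[isMet],
                         max(1L, round(0.2 * sum(isMet))))
    eventLen <- 150L
    hlaStart <- min(geneBins$HLA_A)
    ## events start 10-40 kb upstream of the gene and run across it, so
    ## after 50-fold smoothing at least one fully-deleted bin lies within
    ## the 40-kb proximity window of the gene span
    delBins <- lapply(delSamples, function(s) {
        st <- hlaStart - sample(10:40, 1L)
        seq(st, st + eventLen - 1L)
    })
    names(delBins) <- delSamples

    tracks <- lapply(seq_len(nrow(samples)), function(i) {
        s <- samples$sample[i]
        tum <- grid
        v <- stats::rnorm(nB, 0, config$cnNoiseSd)
        if (s %in% delSamples)
            v[delBins[[s]] + 1L] <- v[delBins[[s]] + 1L] +
                config$focalDeletionDepth
        S4Vectors::mcols(tum)$log2 <- v
        nrm <- grid
        S4Vectors::mcols(nrm)$log2 <- stats::rnorm(nB, 0, config$cnNoiseSd)
        list(tumor = tum, normal = nrm)
    })
    names(tracks) <- samples$sample

    ## gene-level matrix for segment scoring
    nSeg <- 20L; perSeg <- 10L
    segGenes <- outer(sprintf("SEG%02d", seq_len(nSeg)),
                      sprintf("G%02d", seq_len(perSeg)), paste, sep = "_")
    segments <- stats::setNames(split(segGenes, row(segGenes)),
                                sprintf("SEG%02d", seq_len(nSeg)))
    allGenes <- c(unlist(segments, use.names = FALSE), names(geneBins))
    geneLog2 <- matrix(stats::rnorm(length(allGenes) * nrow(samples), 0,
                                    config$cnNoiseSd),
                       length(allGenes), nrow(samples),
                       dimnames = list(allGenes, samples$sample))
    gainSegs <- c("SEG03", "SEG07"); lossSegs <- c("SEG11", "SEG15")
    events <- list()
    for (sg in c(gainSegs, lossSegs)) {
        eff <- if (sg %in% gainSegs) 0.5 else -0.5
        hit <- samples$sample[(isMet & stats::runif(nrow(samples)) < 0.5) |
                              (!isMet & stats::runif(nrow(samples)) < 0.1)]
        geneLog2[segments[[sg]], hit] <- geneLog2[segments[[sg]], hit] + eff
        events[[sg]] <- list(effect = eff, samples = hit)
    }
    truth$focalDeletionSamples <- delSamples
    truth$focalDeletionBins <- delBins
    truth$segmentEvents <- events
    list(tracks = tracks, geneLog2 = geneLog2, segments = segments,
         geneRanges = geneRanges, truth = truth)
}
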
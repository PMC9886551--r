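## Log-scale helper used for reference matrices outside the staged chain
## (same rule as log2FilterTransform: log2 of positive values, 0 for 0).
.log2m <- function(m) ifelse(m > 0, log2(m), 0)

#' Run the full paired-cohort analysis pipeline
#'
#' Orchestrates an end-to-end run on a synthetic cohort: simulation;
#' the expression chain (upper-quartile normalization, expressed-gene
#' filter and log2 transform, FFPE/FF batch correction, normal-tissue
#' contamination signature derivation and removal, signature/metagene
#' scoring, pair concordance); receptor inference, subgroup centering
#' and nearest-centroid subtype calls with the switch table; the
#' methylation screens (constitutively methylated / unmethylated
#' universes, preservation-biased probe removal, mixed-model hypo- and
#' hypermethylation screens, HLA promoter methylation calls); FFPE
#' variant filtering, mutation-matrix construction, pair restriction
#' and mutation-frequency comparison; and copy-number segment scoring,
#' binarization, group comparison and HLA-locus focal-deletion calls.
#' Every stage consumes the previous stage's objects; all randomness
#' comes from `config$seed`, so a rerun with the same configuration
#' yields an identical report.
#'
#' @param config a [syntheticConfig()]; thresholds below are the
#'   screen/filter defaults and may be overridden.
#' @param screenFdr FDR threshold for the methylation screens.
#' @param cnaCutoff gain/loss binarization cutoff.
#' @param mutationMinSamples minimum mutated samples per gene row.
#' @param outDir optional directory; when given, the cohort files and a
#'   `report.json` are written there.
#' @return list `report` components plus the underlying `cohort` and
#'   stage objects.
#' @export
runPipeline <- function(config = syntheticConfig(), screenFdr = 0.05,
                        cnaCutoff = 0.2, mutationMinSamples = 10L,
                        outDir = NULL) {
    cohort <- simulateCohort(config)
    samples <- cohort$samples
    pairs <- do.call(rbind, lapply(split(samples, samples$participant),
        function(d) data.frame(
            participant = d$participant[1],
            primary = d$sample[d$type == "primary"][1],
            metastasis = d$sample[d$type == "metastasis"])))
    onePair <- pairs[!duplicated(pairs$participant), ]

    ## --- expression chain (level 1 -> 4)
    uq <- upperQuartileNormalize(cohort$expression)
    lg <- log2FilterTransform(uq)
    bc <- correctBatchEffect(lg, samples$preservation)
    sig <- deriveNormalTissueSignature(
        normalsBySite = lapply(cohort$normals[c("liver", "lung", "brain")],
                               .log2m),
        normalBreast = .log2m(cohort$normals$breast),
        primaries = assay(lg)[, samples$type == "primary", drop = FALSE])
    adj <- removeSignatureGenes(bc, sig$finalSet)
    sigScores <- t(vapply(cohort$truth$immuneSignatures,
                          function(g) scoreSignature(adj, g),
                          numeric(ncol(adj))))
    gp2 <- metageneScore(sigScores, rownames(sigScores))
    mhc <- scoreSignature(adj, .MHC_GENES)
    conc <- pairConcordance(assay(adj), onePair)

    ## --- receptor inference, centering, subtype calls
    er <- inferReceptorStatus(assay(lg)["ESR1", ],
                              stats::setNames(samples$erStatus,
                                              samples$sample))
    her2 <- inferReceptorStatus(assay(lg)["ERBB2", ],
                                stats::setNames(samples$her2Status,
                                                samples$sample))
    subgroup <- paste0(
        ifelse(er$status %in% c("positive", "inferred_positive"),
               "ER+", "ER-"), "/",
        ifelse(her2$status %in% c("positive", "inferred_positive"),
               "HER2+", "HER2-"))
    norm50 <- pam50Normalize(assay(lg), samples$preservation)
    centered <- subgroupCenter(norm50, subgroup)
    calls <- pam50Classify(centered, cohort$centroids)
    switch <- subtypeSwitchTable(
        stats::setNames(calls$call, rownames(calls)), pairs)

    ## --- methylation screens
    beta <- assay(cohort$beta, "beta")
    biased <- removePreservationBiasedProbes(beta, samples$preservation)
    panel <- cohort$normalPanel
    hypoUniverse <- setdiff(
        selectConstitutivelyMethylated(panel, probeAnnotation(cohort$beta)),
        biased)
    hyperUniverse <- setdiff(selectUnmethylatedBackground(panel), biased)
    hypo <- methylationScreen(beta, hypoUniverse, samples$type,
                              samples$participant, samples$purity,
                              direction = "hypo", fdr = screenFdr)
    hyper <- methylationScreen(beta, hyperUniverse, samples$type,
                               samples$participant, samples$purity,
                               direction = "hyper", fdr = screenFdr)
    ann <- probeAnnotation(cohort$beta)
    promoter <- S4Vectors::mcols(ann)$promoterIsland
    hlaCalls <- lapply(c("HLA_A", "HLA_B", "HLA_C", "B2M"), function(g) {
        pr <- names(ann)[promoter & S4Vectors::mcols(ann)$nearestGene == g]
        callGeneMethylation(beta[pr, , drop = FALSE])
    })
    names(hlaCalls) <- c("HLA_A", "HLA_B", "HLA_C", "B2M")

    ## --- variant filtering and mutation comparison
    pres <- stats::setNames(samples$preservation, samples$sample)
    filt <- applyFfpeFilters(cohort$variants, pres)
    keptVariants <- filt[filt$keep, , drop = FALSE]
    mut <- buildMutationMatrix(keptVariants, samples = samples$sample,
                               minSamples = mutationMinSamples)
    restricted <- pairRestrictPrimaryCalls(keptVariants, pairs)
    mutRestricted <- buildMutationMatrix(restricted,
                                         samples = samples$sample,
                                         minSamples = mutationMinSamples)
    mutCompare <- if (nrow(mutRestricted))
        compareMutationFrequencies(mutRestricted, pairs) else NULL

    ## --- copy number
    scores <- segmentScores(cohort$geneLog2, cohort$segments)
    bin <- binarizeCna(scores, cnaCutoff)
    segCompare <- compareSegments(bin, samples$type)
    focal <- lapply(names(cohort$copyRatios), function(s) {
        tr <- cohort$copyRatios[[s]]
        calls <- callFocalDeletions(binCopyRatio(tr$tumor),
                                    binCopyRatio(tr$normal),
                                    cohort$geneRanges)
        calls$sample <- s
        calls
    })
    focal <- do.call(rbind, focal)

    report <- list(
        nParticipants = length(unique(samples$participant)),
        nSamples = nrow(samples),
        signatureSizes = as.list(sig$sizes),
        pairConcordance = conc$concordance,
        receptorAuc = list(ER = er$auc, HER2 = her2$auc),
        subtypeSwitch = switch[c("nPairs", "nSwitched",
                                 "nSwitchedExcludingNormal")],
        methylation = list(
            nPreservationBiased = length(biased),
            hypoUniverse = length(hypoUniverse),
            hyperUniverse = length(hyperUniverse),
            nHypoSignificant = sum(hypo$significant),
            nHyperSignificant = sum(hyper$significant),
            hlaMethylatedTumors = vapply(hlaCalls, function(x)
                sum(x == "methylated", na.rm = TRUE), 0)),
        variants = list(
            nVariants = nrow(cohort$variants),
            nKept = nrow(keptVariants),
            nGenesTested = if (is.null(mutCompare)) 0L
                           else nrow(mutCompare)),
        copyNumber = list(
            nSegmentsGainSignificant = sum(segCompare$gainQ < 0.05,
                                           na.rm = TRUE),
            nFocalDeletionSamples = length(unique(
                focal$sample[focal$called & focal$gene == "HLA_A"]))))
    if (!is.null(outDir)) {
        writeCohort(cohort, outDir)
        jsonlite::write_json(report, file.path(outDir, "report.json"),
                             auto_unbox = TRUE, digits = NA)
    }
    list(report = report, cohort = cohort,
         expression = list(log2 = lg, corrected = bc, adjusted = adj,
                           signature = sig, gp2 = gp2, mhcScore = mhc),
         subtype = list(calls = calls, switch = switch, er = er,
                        her2 = her2),
         methylation = list(hypo = hypo, hyper = hyper,
                            hlaCalls = hlaCalls, biased = biased),
         variants = list(filtered = filt, matrix = mutRestricted,
                         compare = mutCompare),
         copyNumber = list(scores = scores, compare = segCompare,
                           focal = focal),
         pairs = pairs)
}
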
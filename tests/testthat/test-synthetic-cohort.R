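test_that("configuration validation rejects malformed inputs", {
    expect_error(syntheticConfig(subtypeMix = c(LumA = 0.5, LumB = 0.5,
                                                HER2E = 0.2, Basal = 0.1,
                                                `Normal-like` = 0.1)),
                 "sum to 1")
    expect_error(syntheticConfig(nParticipants = 0), "positive")
    expect_error(syntheticConfig(artifactFraction = 1.2), "artifactFraction")
    expect_error(syntheticConfig(purityRange = c(0.5, 1.4)), "purityRange")
})

test_that("a fixed seed gives a bit-identical cohort", {
    cfg <- syntheticConfig(nParticipants = 4, nGenes = 300, nProbes = 250,
                           nVariants = 30, nCnBins = 500, seed = 99)
    expect_identical(simulateCohort(cfg), simulateCohort(cfg))
})

test_that("cohort structure: pairing, identifiers, purity, degenerate mix", {
    co <- smallCohort()
    s <- co$samples
    for (d in split(s, s$participant)) {
        expect_equal(sum(d$type == "primary"), 1L)
        expect_gte(sum(d$type == "metastasis"), 1L)
    }
    expect_identical(colnames(assay(co$expression)), s$sample)
    expect_identical(colnames(assay(co$beta, "beta")), s$sample)
    expect_identical(names(co$copyRatios), s$sample)
    expect_true(all(s$purity >= 0 & s$purity <= 1))
    ## truth covers every simulated record
    expect_setequal(names(co$truth$variantStatus), co$variants$variantId)
    expect_identical(names(co$truth$probeStatus),
                     rownames(assay(co$beta, "beta")))
    ## degenerate subtype mix
    cfgB <- syntheticConfig(nParticipants = 5, nGenes = 300, nProbes = 250,
                            nVariants = 20, nCnBins = 500,
                            subtypeMix = c(LumA = 0, LumB = 0, HER2E = 0,
                                           Basal = 1, `Normal-like` = 0),
                            seed = 1)
    coB <- simulateCohort(cfgB)
    expect_true(all(coB$truth$subtype == "Basal"))
})

test_that("artifact count falls in the binomial 99% interval", {
    cfg <- syntheticConfig(nParticipants = 6, nGenes = 300, nProbes = 250,
                           nVariants = 1000, nCnBins = 500,
                           artifactFraction = 0.3, seed = 13)
    co <- simulateCohort(cfg)
    nArt <- sum(co$truth$variantStatus == "ffpe_artifact")
    bounds <- qbinom(c(0.005, 0.995), 1000, 0.3)
    expect_gte(nArt, bounds[1]); expect_lte(nArt, bounds[2])
})

test_that("expression log-means follow centroid + batch + contamination", {
    ## noiseless construction: each sample's classifier-gene profile
    ## correlates best with its own subtype centroid
    cfg <- syntheticConfig(nParticipants = 10, nGenes = 300, nProbes = 250,
                           nVariants = 20, nCnBins = 500, noiseSd = 0,
                           participantGeneSd = 0, batchLog2Sd = 0,
                           receptorShiftSd = 0, seed = 21)
    co <- simulateCohort(cfg)
    pam <- rownames(co$centroids)
    lm0 <- co$truth$logMeans[pam, ]
    for (smp in co$samples$sample) {
        cors <- cor(lm0[, smp], co$centroids)
        expect_equal(colnames(co$centroids)[which.max(cors)],
                     unname(co$truth$subtype[smp]))
    }
    ## contamination genes elevated only in site-matched metastases
    co2 <- smallCohort()
    s <- co2$samples
    liverMets <- s$sample[s$type == "metastasis" & s$site == "liver"]
    if (length(liverMets)) {
        lg <- co2$truth$logMeans
        liverGenes <- co2$truth$contamGenes$liver
        for (m in liverMets) {
            p <- s$sample[s$participant ==
                              s$participant[s$sample == m] &
                              s$type == "primary"]
            expect_true(all(lg[liverGenes, m] > lg[liverGenes, p]))
        }
    }
    ## planted FFPE batch offset recovered within 3 SE on a filler gene
    cfg3 <- syntheticConfig(nParticipants = 30, nGenes = 300, nProbes = 250,
                            nVariants = 20, nCnBins = 500,
                            participantGeneSd = 0, seed = 23)
    co3 <- simulateCohort(cfg3)
    lg3 <- log2(assay(co3$expression) + 1)
    ffpe <- co3$samples$preservation == "FFPE"
    g <- names(which.max(abs(co3$truth$batchOffsets[
        grep("^GENE", rownames(lg3), value = TRUE)])))
    tt <- t.test(lg3[g, ffpe], lg3[g, !ffpe])
    se <- tt$stderr
    expect_lt(abs((mean(lg3[g, ffpe]) - mean(lg3[g, !ffpe])) -
                      co3$truth$batchOffsets[g]), 3 * se)
})

test_that("observed beta is the exact purity mixture when noiseless", {
    base <- list(nParticipants = 5, nGenes = 300, nProbes = 250,
                 nVariants = 20, nCnBins = 500, methNoiseSd = 0,
                 betaMaskRate = 0, seed = 31)
    ## probes without a planted FFPE preservation shift obey the mixture
    clean <- function(co) setdiff(rownames(assay(co$beta, "beta")),
                                  co$truth$preservationBiasedProbes)
    ## purity 1: observed equals the tumor-cell beta
    co1 <- simulateCohort(do.call(syntheticConfig,
                                  c(base, list(purityRange = c(1, 1)))))
    k1 <- clean(co1)
    expect_equal(unname(assay(co1$beta, "beta")[k1, ]),
                 unname(co1$truth$tumorBeta[k1, ]), tolerance = 1e-12)
    ## purity 0: observed equals the stromal beta
    co0 <- simulateCohort(do.call(syntheticConfig,
                                  c(base, list(purityRange = c(0, 0)))))
    k0 <- clean(co0)
    expect_equal(unname(assay(co0$beta, "beta")[k0, ]),
                 unname(co0$truth$stromaBeta[k0, ]), tolerance = 1e-12)
    ## general mixture
    com <- simulateCohort(do.call(syntheticConfig, base))
    km <- clean(com)
    pur <- com$samples$purity
    expected <- sweep(com$truth$tumorBeta, 2, pur, `*`) +
        sweep(com$truth$stromaBeta, 2, 1 - pur, `*`)
    expected <- pmin(pmax(expected, 0), 1)
    expect_equal(unname(assay(com$beta, "beta")[km, ]),
                 unname(expected[km, ]), tolerance = 1e-12)
})

test_that("planted hypomethylation shows up as the diluted paired difference", {
    cfg <- syntheticConfig(nParticipants = 30, extraMetProb = 0,
                           nGenes = 300, nProbes = 400, nVariants = 20,
                           nCnBins = 500, seed = 33)
    co <- simulateCohort(cfg)
    b <- assay(co$beta, "beta")
    s <- co$samples
    hypo <- names(co$truth$probeStatus)[
        co$truth$probeStatus == "hypo_in_met"]
    prim <- s$sample[s$type == "primary"]
    mets <- s$sample[s$type == "metastasis"][
        match(s$participant[s$type == "primary"],
              s$participant[s$type == "metastasis"])]
    dPer <- colMeans(b[hypo, mets], na.rm = TRUE) -
        colMeans(b[hypo, prim], na.rm = TRUE)
    ## expected: -deltaBeta scaled by metastasis purity, plus small
    ## stroma differences between sites; use truth-based expectation
    expTumor <- -cfg$deltaBeta * s$purity[match(mets, s$sample)]
    strDiff <- colMeans(co$truth$stromaBeta[hypo, mets] *
                        (1 - s$purity[match(mets, s$sample)])) -
        colMeans(co$truth$stromaBeta[hypo, prim] *
                 (1 - s$purity[match(prim, s$sample)]))
    se <- sd(dPer) / sqrt(length(dPer))
    expect_lt(abs(mean(dPer) - mean(expTumor + strDiff)), 3 * se)
    expect_lt(mean(dPer), -0.05)   # planted loss survives dilution
})

test_that("read evidence construction matches the artifact modes", {
    co <- smallCohort()
    v <- co$variants
    st <- co$truth$variantStatus
    md <- co$truth$artifactMode
    modeA <- which(st == "ffpe_artifact" & md == "a")
    for (i in modeA)
        expect_lte(length(unique(v$readStarts[[i]])), 3L)
    ## invariants: start < end, mismatch <= total
    for (i in seq_len(nrow(v))) {
        expect_true(all(v$readStarts[[i]] < v$readEnds[[i]]))
        expect_lte(v$windowMismatch[i], v$windowTotal[i])
    }
    ## real variant with clean window keeps corrected VAF comfortably
    ## above the 4% filter floor
    real <- which(st == "real")
    lmr <- localMismatchRate(v$windowMismatch[real], v$windowTotal[real])
    expect_true(all(v$vaf[real] - lmr >= 0.04))
})

test_that("copy-ratio construction: neutral bins, planted depths, gains", {
    co <- smallCohort()
    ## normal tracks: 50-fold binned means all within +/- 0.2
    for (s in head(co$samples$sample, 4)) {
        bn <- binCopyRatio(co$copyRatios[[s]]$normal)
        expect_true(all(abs(S4Vectors::mcols(bn)$log2) < 0.2))
    }
    ## planted deletion produces a binned mean below -0.75
    del <- co$truth$focalDeletionSamples[1]
    bt <- binCopyRatio(co$copyRatios[[del]]$tumor)
    expect_true(any(S4Vectors::mcols(bt)$log2 < -0.75))
    ## planted whole-segment gain scores above the 0.2 cutoff
    sc <- segmentScores(co$geneLog2, co$segments)
    ev <- co$truth$segmentEvents
    gainSeg <- names(ev)[vapply(ev, function(e) e$effect > 0, TRUE)][1]
    hit <- intersect(ev[[gainSeg]]$samples, colnames(sc))
    expect_true(all(sc[gainSeg, hit] > 0.2))
})
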
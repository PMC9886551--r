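mkSE <- function(m) StagedExpression(m, "counts")

test_that("upper-quartile normalization is scale-free and matches hand math", {
    m <- matrix(c(10, 20, 30, 40,
                  20, 40, 60, 80,
                  10, 20, 30, 40), 4, 3,
                dimnames = list(paste0("g", 1:4), c("A", "B", "C")))
    out <- assay(upperQuartileNormalize(mkSE(m)))
    expect_equal(out[, "A"], out[, "B"])         # B = 2 x A
    expect_equal(out[, "A"], out[, "C"])         # identical samples
    ## fixed target: UQ(A) = 32.5 (type-7 quantile), scale = 35 / 32.5
    out35 <- assay(upperQuartileNormalize(mkSE(m), target = 35))
    expect_equal(out35[, "A"], m[, "A"] * 35 / 32.5)
    ## all-zero sample errors by name
    m0 <- cbind(m, Z = 0)
    expect_error(upperQuartileNormalize(mkSE(m0)), "Z")
})

test_that("median-of-ratios size factors match the brute-force definition", {
    set.seed(10)
    ## odd gene count keeps the median a single observed ratio, so the
    ## log-space and ratio-space median conventions coincide exactly
    m <- matrix(rpois(44, 100) + 1, 11, 4,
                dimnames = list(paste0("g", 1:11), paste0("s", 1:4)))
    res <- medianOfRatiosNormalize(mkSE(m), minMeanCount = 0)
    ## brute force: per sample, median over all-nonzero genes of
    ## count / geometric mean
    gm <- exp(rowMeans(log(m)))
    sfRef <- apply(sweep(m, 1, gm, `/`), 2, median)
    expect_equal(res$sizeFactors, sfRef)
    ## identical samples -> all size factors equal; tripled sample ratio 3
    m2 <- cbind(a = m[, 1], b = m[, 1], c = 3 * m[, 1])
    sf2 <- medianOfRatiosNormalize(mkSE(m2), minMeanCount = 0)$sizeFactors
    expect_equal(sf2[["b"]] / sf2[["a"]], 1)
    expect_equal(sf2[["c"]] / sf2[["a"]], 3)
    ## low-expression flagging
    m3 <- rbind(m, low = 1L)
    res3 <- medianOfRatiosNormalize(mkSE(m3), minMeanCount = 10)
    expect_true("low" %in% res3$lowExpressed)
    expect_false("low" %in% rownames(res3$normalized))
})

test_that("log2 filter keeps genes expressed in >= 70% and maps 0 to 0", {
    m <- matrix(8, 3, 100,
                dimnames = list(c("a", "b", "c"), paste0("s", 1:100)))
    m["b", 1:31] <- 0      # expressed in 69% -> dropped
    m["c", 1:30] <- 0      # expressed in 70% -> kept
    se <- StagedExpression(m, "normalized")
    out <- log2FilterTransform(se)
    expect_setequal(rownames(out), c("a", "c"))
    expect_equal(unname(assay(out)["a", 1]), 3)
    expect_equal(unname(assay(out)["c", 1]), 0)
    ## filter criterion is idempotent on its own output
    expect_true(all(rowMeans(assay(out) > 0) >= 0.69))
})

test_that("batch correction removes planted offsets, preserves grand means", {
    set.seed(11)
    m <- matrix(rnorm(50 * 20, 8), 50, 20,
                dimnames = list(paste0("g", 1:50), paste0("s", 1:20)))
    batch <- rep(c("FF", "FFPE"), each = 10)
    delta <- 1.7
    m["g1", batch == "FFPE"] <- m["g1", batch == "FFPE"] + delta
    se <- StagedExpression(m, "log2")
    out <- assay(correctBatchEffect(se, batch))
    expect_lt(abs(mean(out["g1", batch == "FFPE"]) -
                      mean(out["g1", batch == "FF"])), 1e-8)
    expect_equal(rowMeans(out), rowMeans(m), tolerance = 1e-8)
    ## agrees with the standard linear-model batch removal up to a
    ## per-gene constant
    ref <- limma::removeBatchEffect(m, batch = batch)
    expect_equal(out - rowMeans(out), ref - rowMeans(ref),
                 tolerance = 1e-8)
    expect_error(correctBatchEffect(se, rep("FF", 20)), "two batches")
    expect_error(correctBatchEffect(se, c(rep("FF", 19), "FFPE")),
                 "single sample")
})

test_that("normal-tissue signature set algebra and recovery on truth", {
    ## strong tissue-restricted contamination (tissue marker genes are
    ## orders of magnitude higher in their own tissue)
    co <- simulateCohort(syntheticConfig(
        nParticipants = 8, nGenes = 500, nProbes = 250, nVariants = 20,
        nCnBins = 500, contaminationLog2 = 5, noiseSd = 0.2, seed = 77))
    lgm <- function(m) ifelse(m > 0, log2(m), 0)
    s <- co$samples
    prim <- lgm(assay(co$expression)[, s$type == "primary", drop = FALSE])
    sig <- deriveNormalTissueSignature(
        lapply(co$normals[c("liver", "lung", "brain")], lgm),
        lgm(co$normals$breast), prim)
    expect_equal(unname(sig$sizes["final"]),
                 unname(sig$sizes["union"] - sig$sizes["overlap"]))
    expect_setequal(sig$finalSet, setdiff(sig$siteUnion, sig$primarySet))
    ## planted contamination genes dominate the recovered signature
    planted <- unlist(co$truth$contamGenes)
    expect_gte(length(intersect(sig$finalSet, planted)),
               0.9 * length(planted))
    expect_lte(length(setdiff(sig$siteUnion, planted)), 5)
    expect_error(deriveNormalTissueSignature(list(), NULL, prim),
                 "normal breast")
})

test_that("signature derivation on null data returns (near-)empty sets", {
    ## no contamination planted: FDR control keeps the signature empty
    co <- simulateCohort(syntheticConfig(
        nParticipants = 8, nGenes = 500, nProbes = 250, nVariants = 20,
        nCnBins = 500, contaminationLog2 = 0, seed = 78))
    lgm <- function(m) ifelse(m > 0, log2(m), 0)
    s <- co$samples
    prim <- lgm(assay(co$expression)[, s$type == "primary", drop = FALSE])
    sig <- deriveNormalTissueSignature(
        lapply(co$normals[c("liver", "lung", "brain")], lgm),
        lgm(co$normals$breast), prim)
    expect_lte(length(sig$finalSet), 2)
})

test_that("signature removal, scoring and metagenes behave as contracts", {
    m <- matrix(rnorm(20, 5), 4, 5,
                dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
    se <- StagedExpression(m, "batch_corrected")
    expect_equal(assay(removeSignatureGenes(se, character(0))), m)
    expect_error(removeSignatureGenes(se, rownames(m)), "empty")
    out <- suppressMessages(removeSignatureGenes(se, c("g1", "absent")))
    expect_setequal(rownames(out), c("g2", "g3", "g4"))
    expect_equal(assay(out), m[c("g2", "g3", "g4"), ])
    ## scoring
    m2 <- matrix(c(1, 3, 5), 3, 2,
                 dimnames = list(c("a", "b", "c"), c("s1", "s2")))
    expect_equal(as.numeric(scoreSignature(m2, "a")), unname(m2["a", ]))
    expect_equal(as.numeric(scoreSignature(m2, c("a", "b", "c"))), c(3, 3))
    sc <- scoreSignature(m2, c("a", "zz"))
    expect_equal(attr(sc, "missingGenes"), "zz")
    expect_true(all(is.nan(scoreSignature(m2, "zz"))))
    ## sample reordering commutes
    expect_equal(as.numeric(scoreSignature(m2[, 2:1],
                                           c("a", "b"))[c("s1", "s2")]),
                 as.numeric(scoreSignature(m2,
                                           c("a", "b"))[c("s1", "s2")]))
    ## metagene
    sm <- rbind(sig1 = c(0.2, 0.6), sig2 = c(0.4, 0.8))
    colnames(sm) <- c("s1", "s2")
    expect_equal(as.numeric(metageneScore(sm, "sig1")), c(0.2, 0.6))
    expect_equal(as.numeric(metageneScore(sm, c("sig1", "sig2"))),
                 c(0.3, 0.7))
    expect_true(all(is.nan(metageneScore(sm, c("sig1", "gone")))))
})

test_that("immune metagene tracks the planted immune activity", {
    co <- smallCohort()
    lg <- log2(assay(co$expression) + 1)
    scores <- t(vapply(co$truth$immuneSignatures,
                       function(g) scoreSignature(lg, g),
                       numeric(ncol(lg))))
    gp2 <- metageneScore(scores, rownames(scores))
    expect_gt(cor(gp2, co$truth$immuneActivity[names(gp2)]), 0.7)
})

test_that("pair concordance: duplicates, constant samples", {
    set.seed(12)
    base <- matrix(rnorm(100 * 8), 100, 8)
    colnames(base) <- paste0(rep(c("P", "M"), 4), rep(1:4, each = 2))
    rownames(base) <- paste0("g", 1:100)
    ## make each M a near duplicate of its P
    for (i in 1:4) base[, 2 * i] <- base[, 2 * i - 1] + rnorm(100, 0, 0.01)
    pairs <- data.frame(primary = paste0("P", 1:4),
                        metastasis = paste0("M", 1:4))
    colnames(base) <- c(rbind(paste0("P", 1:4), paste0("M", 1:4)))
    pc <- pairConcordance(base, pairs)
    expect_equal(pc$concordance, 1)
    ## constant member excludes the pair with a flag
    base2 <- base; base2[, "P1"] <- 1
    pc2 <- pairConcordance(base2, pairs)
    expect_equal(nrow(pc2$excluded), 1)
    expect_equal(pc2$excluded$primary, "P1")
    expect_error(pairConcordance(base, pairs[1, , drop = FALSE]),
                 "two pairs")
})
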
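test_that("beta computation masks failed detections and zero totals", {
    M <- matrix(c(100, 300, 0, 50), 2, 2,
                dimnames = list(c("p1", "p2"), c("s1", "s2")))
    U <- matrix(c(100, 100, 0, 150), 2, 2, dimnames = dimnames(M))
    dp <- matrix(0.01, 2, 2, dimnames = dimnames(M))
    b <- computeBeta(M, U, dp)
    expect_equal(b["p1", "s1"], 0.5)
    expect_equal(b["p2", "s1"], 0.75)
    expect_true(is.na(b["p1", "s2"]))          # zero total intensity
    expect_equal(b["p2", "s2"], 0.25)
    ## detection p above threshold masks regardless of intensities
    dp2 <- dp; dp2["p2", "s1"] <- 0.06
    expect_true(is.na(computeBeta(M, U, dp2)["p2", "s1"]))
    expect_error(computeBeta(-M, U, dp), "negative")
    ## complementarity: beta(M, U) + beta(U, M) = 1
    expect_equal(computeBeta(M, U, dp) + computeBeta(U, M, dp),
                 matrix(1, 2, 2, dimnames = dimnames(M)) * ifelse(M + U > 0, 1, NA))
})

test_that("constitutively methylated / unmethylated selection rules", {
    panel <- rbind(high = c(0.95, 0.92, 0.96),
                   edge = c(0.95, 0.79, 0.96),     # one tissue at 0.79
                   near = c(0.95, 0.95, 0.95),     # dELS but close to TSS
                   low = c(0.05, 0.10, 0.02),
                   lowEdge = c(0.21, 0.10, 0.02),  # one tissue above 0.2
                   zero = c(0, 0, 0))
    colnames(panel) <- c("liver", "lung", "brain")
    ann <- data.frame(dELS = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                      tssDistance = c(3000, 3000, 1500, 500, 500, 500),
                      row.names = rownames(panel))
    expect_equal(selectConstitutivelyMethylated(panel, ann), "high")
    expect_setequal(selectUnmethylatedBackground(panel),
                    c("low", "zero"))
    ## the two universes can never intersect (0.2 < 0.8)
    expect_length(intersect(selectConstitutivelyMethylated(panel, ann),
                            selectUnmethylatedBackground(panel)), 0)
    expect_error(selectConstitutivelyMethylated(
        panel[, 1, drop = FALSE], ann), "2 normal tissue")
})

test_that("preservation-biased probe removal needs both criteria", {
    set.seed(30)
    n <- 12
    pres <- rep(c("FF", "FFPE"), each = n / 2)
    mk <- function(ffMean, ffpeMean, sd) c(rnorm(n / 2, ffMean, sd),
                                           rnorm(n / 2, ffpeMean, sd))
    beta <- rbind(biased = mk(0.2, 0.6, 0.02),    # big delta, tiny p
                  ## big delta but spread so wide the t-test cannot call it
                  noisy = c(0.05, 0.95, 0.05, 0.95, 0.05, 0.2,
                            0.95, 0.95, 0.05, 0.95, 0.95, 0.2),
                  subtle = mk(0.2, 0.3, 0.005),   # tiny delta, tiny p
                  null = mk(0.4, 0.4, 0.02))
    beta <- pmin(pmax(beta, 0), 1)
    colnames(beta) <- paste0("s", 1:n)
    expect_gt(abs(mean(beta["noisy", pres == "FFPE"]) -
                      mean(beta["noisy", pres == "FF"])), 0.25)
    removed <- removePreservationBiasedProbes(beta, pres)
    expect_equal(removed, "biased")
    expect_warning(removePreservationBiasedProbes(beta, rep("FF", n)),
                   "single preservation class")
})

test_that("top variable probes: determinism, ties and bounds", {
    beta <- rbind(a = c(0, 1, 0, 1), b = c(0.5, 0.5, 0.5, 0.5),
                  cc = c(0, 0, 1, 1), d = c(0.4, 0.6, 0.4, 0.6))
    colnames(beta) <- paste0("s", 1:4)
    expect_setequal(topVariableProbes(beta, 4), rownames(beta))
    expect_false("b" %in% topVariableProbes(beta, 3))
    ## a and cc tie on variance: lexicographic order decides
    expect_equal(topVariableProbes(beta, 2), c("a", "cc"))
    expect_error(topVariableProbes(beta, 5), "exceeds")
})

test_that("methylation screen is sign-gated and reports failures", {
    set.seed(31)
    nP <- 15
    group <- rep(c("primary", "metastasis"), nP)
    part <- rep(sprintf("p%02d", 1:nP), each = 2)
    purity <- runif(2 * nP, 0.4, 0.9)
    met <- group == "metastasis"
    beta <- rbind(
        hypo1 = 0.9 - 0.3 * met * purity + rnorm(2 * nP, 0, 0.02),
        hyper1 = 0.1 + 0.3 * met * purity + rnorm(2 * nP, 0, 0.02),
        null1 = 0.5 + rnorm(2 * nP, 0, 0.02),
        null2 = 0.5 + rnorm(2 * nP, 0, 0.02))
    beta <- pmin(pmax(beta, 0), 1)
    colnames(beta) <- paste0("s", 1:(2 * nP))
    hypo <- methylationScreen(beta, rownames(beta), group, part, purity,
                              "hypo")
    expect_true(hypo$significant[hypo$probe == "hypo1"])
    ## a hyper effect never appears in a hypo-direction screen
    expect_false(hypo$significant[hypo$probe == "hyper1"])
    hyper <- methylationScreen(beta, rownames(beta), group, part, purity,
                               "hyper")
    expect_true(hyper$significant[hyper$probe == "hyper1"])
    expect_false(hyper$significant[hyper$probe == "hypo1"])
    expect_error(methylationScreen(beta, "absent", group, part, purity),
                 "absent")
})

test_that("TFBS enrichment matches a brute-force table on small instances", {
    set.seed(32)
    nProbes <- 80
    pos <- sort(sample.int(100000, nProbes))
    ann <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(start = pos, width = 1))
    names(ann) <- sprintf("cg%03d", seq_len(nProbes))
    background <- names(ann)
    significant <- sample(background, 25)
    sites <- list(
        fA = GenomicRanges::GRanges("chr1",
            IRanges::IRanges(start = sample.int(100000, 40), width = 60)),
        fB = GenomicRanges::GRanges("chr1",
            IRanges::IRanges(start = sample.int(100000, 10), width = 30)))
    res <- tfbsEnrichment(significant, sites, background, ann)
    ## brute force: count overlaps of the 200-bp windows by arithmetic
    for (f in names(sites)) {
        st <- GenomicRanges::start(sites[[f]])
        en <- st + GenomicRanges::width(sites[[f]]) - 1
        hit <- vapply(seq_len(nProbes), function(i) {
            w1 <- pos[i] - 100; w2 <- pos[i] + 99   # closed 1-based window
            any(st <= w2 & en >= w1)
        }, logical(1))
        a <- sum(hit & background %in% significant)
        c0 <- sum(hit & !background %in% significant)
        expect_equal(res$overlapSig[res$factor == f], a)
        expect_equal(res$overlapBg[res$factor == f], c0)
        tab <- matrix(c(a, 25 - a, c0, nProbes - 25 - c0), 2, byrow = TRUE)
        expect_equal(res$p[res$factor == f], fisherExactTwoSided(tab)$p)
    }
    ## extreme table: all significant overlap, no background-only overlap
    allSig <- list(f = GenomicRanges::GRanges("chr1",
        IRanges::IRanges(start = pos[match(significant, background)],
                         width = 1)))
    resX <- tfbsEnrichment(significant, allSig, background, ann)
    expect_true(resX$orCapped)
    expect_lt(resX$p, 1e-10)
    expect_error(tfbsEnrichment(c(significant, "cgXXX"), sites,
                                background, ann), "background")
})

test_that("window boundary follows 0-based half-open overlap", {
    ## probe at 0-based position 1000: window [900, 1100)
    ann <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(start = 1001, width = 1))
    names(ann) <- "cg1"
    mkSite <- function(s, e)   # 0-based half-open input
        list(f = GenomicRanges::GRanges("chr1",
            IRanges::IRanges(start = s + 1, end = e)))
    ## interval [1100, 1200): empty intersection with [900, 1100)
    r1 <- tfbsEnrichment("cg1", mkSite(1100, 1200), "cg1", ann)
    expect_equal(r1$overlapSig, 0)
    ## interval [1099, 1200): one shared base
    r2 <- tfbsEnrichment("cg1", mkSite(1099, 1200), "cg1", ann)
    expect_equal(r2$overlapSig, 1)
})

test_that("putative target mapping honors the per-side and distance caps", {
    genes <- data.frame(
        gene = c("near", sprintf("up%02d", 1:11), "far"),
        chrom = "chr1",
        tss = c(500500, 500000 - (1:11) * 1000, 500000 + 1001000))
    probes <- c(cg1 = 500000)
    wl <- genes$gene
    res <- suppressMessages(mapPutativeTargets(probes, genes, wl))
    expect_true("near" %in% res$gene)             # 500 bp downstream
    expect_true("up10" %in% res$gene)             # 10th nearest upstream
    expect_false("up11" %in% res$gene)            # 11th nearest: capped
    expect_false("far" %in% res$gene)             # beyond 1 Mb
    ## whitelist intersection
    res2 <- suppressMessages(mapPutativeTargets(probes, genes, "near"))
    expect_equal(res2$gene, "near")
})

test_that("over-representation test pinpoints the loaded term", {
    universe <- sprintf("g%03d", 1:200)
    terms <- list(loaded = universe[1:8],
                  big = universe[1:100],
                  other = universe[150:180],
                  empty = c("x1", "x2"))
    res <- suppressMessages(
        overrepresentationTest(universe[1:8], terms, universe))
    expect_false("empty" %in% res$term)           # no universe genes
    expect_equal(res$term[which.min(res$p)], "loaded")
    ## direct hypergeometric check for the loaded term
    expect_equal(res$p[res$term == "loaded"],
                 fisher.test(matrix(c(8, 0, 0, 192), 2),
                             alternative = "greater")$p.value)
    expect_equal(nrow(overrepresentationTest(character(0), terms,
                                             universe)), 0)
})

test_that("gene methylation calls use the >= 0.4 aggregate rule", {
    beta <- rbind(p1 = c(0.40, 0.05, NA), p2 = c(0.40, 0.05, NA))
    colnames(beta) <- c("sA", "sB", "sC")
    st <- callGeneMethylation(beta)
    expect_equal(unname(st), c("methylated", "unmethylated", NA))
    ## max aggregation
    beta2 <- rbind(p1 = c(0.9, 0.1), p2 = c(0.1, 0.1))
    colnames(beta2) <- c("sA", "sB")
    expect_equal(unname(callGeneMethylation(beta2, aggregate = "max")),
                 c("methylated", "unmethylated"))
    expect_equal(unname(callGeneMethylation(beta2, aggregate = "mean")),
                 c("methylated", "unmethylated"))
    expect_error(callGeneMethylation(beta[0, , drop = FALSE]), "promoter")
})

test_that("planted HLA promoter methylation is recovered from the cohort", {
    co <- smallCohort()
    ann <- probeAnnotation(co$beta)
    pr <- names(ann)[S4Vectors::mcols(ann)$promoterIsland &
                         S4Vectors::mcols(ann)$nearestGene == "HLA_A"]
    calls <- callGeneMethylation(assay(co$beta, "beta")[pr, , drop = FALSE])
    hla <- co$truth$hlaMethylatedSamples
    ## purity dilutes the observed promoter beta; the 0.4 call is only
    ## reachable when enough of the specimen is tumor
    pur <- setNames(co$samples$purity, co$samples$sample)
    detectable <- hla[pur[hla] >= 0.45]
    expect_true(all(calls[detectable] == "methylated", na.rm = TRUE))
    others <- setdiff(co$samples$sample, hla)
    expect_true(mean(calls[others] == "unmethylated", na.rm = TRUE) > 0.9)
    ## paired contrast: a methylated metastasis differs from its primary
    sA <- co$samples
    for (m in detectable) {
        p <- sA$sample[sA$participant == sA$participant[sA$sample == m] &
                           sA$type == "primary"]
        expect_false(identical(calls[[m]], calls[[p]]))
    }
})

test_that("heatmap ordering follows the four rules deterministically", {
    samples <- data.frame(
        sample = c("A_P", "A_M1", "A_M2", "B_P", "B_M1", "C_P", "C_M1"),
        participant = c("A", "A", "A", "B", "B", "C", "C"),
        type = c("primary", "metastasis", "metastasis", "primary",
                 "metastasis", "primary", "metastasis"),
        purity = c(0.5, 0.3, 0.8, 0.6, 0.4, 0.7, 0.2))
    calls <- c(A = "Basal", B = "Basal", C = "LumA")
    beta <- matrix(c(0.4, 0.5, 0.5, 0.6, 0.5, 0.5, 0.5), 1, 7,
                   dimnames = list("p1", samples$sample))
    ord <- heatmapSampleOrder(samples, calls, beta)
    ## LumA stratum first; B before A (primary median 0.6 > 0.4);
    ## primary first within case; mets by decreasing purity
    expect_equal(ord, c("C_P", "C_M1", "B_P", "B_M1",
                        "A_P", "A_M2", "A_M1"))
    ## input order is irrelevant
    perm <- samples[c(3, 1, 7, 2, 5, 4, 6), ]
    expect_equal(heatmapSampleOrder(perm, calls, beta), ord)
    ## missing purity flagged, treated as 0
    samples2 <- samples; samples2$purity[3] <- NA
    expect_warning(ord2 <- heatmapSampleOrder(samples2, calls, beta),
                   "purity")
    expect_equal(ord2, c("C_P", "C_M1", "B_P", "B_M1",
                         "A_P", "A_M1", "A_M2"))
})
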
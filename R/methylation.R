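#' Compute beta values from methylated/unmethylated intensities
#'
#' beta = M / (M + U) per probe and sample.  Cells whose detection
#' p-value exceeds `threshold`, and cells with zero total intensity, are
#' masked as missing.
#'
#' @param M,U nonnegative matrices of methylated / unmethylated signal
#'   intensities with identical dimnames.
#' @param detectionP matrix of detection p-values, same shape.
#' @param threshold mask cells with detection p above this (default
#'   0.05).
#' @param annotation optional probe annotation (see [BetaSet()]); when
#'   supplied a [BetaSet-class] is returned instead of a matrix.
#' @return beta matrix (or [BetaSet-class]) with masked cells NA.
#' @export
computeBeta <- function(M, U, detectionP, threshold = 0.05,
                        annotation = NULL) {
    stopifnot(identical(dim(M), dim(U)),
              identical(dim(M), dim(detectionP)))
    if (any(M < 0, na.rm = TRUE) || any(U < 0, na.rm = TRUE))
        stop("negative intensities are not allowed")
    tot <- M + U
    beta <- M / tot
    beta[tot == 0] <- NA
    beta[detectionP > threshold] <- NA
    dimnames(beta) <- dimnames(M)
    if (is.null(annotation)) beta else BetaSet(beta, annotation)
}

## Per-tissue mean beta matrix from a normal panel given either as
## probe x tissue means or as probe x sample values plus tissue labels.
.tissueMeans <- function(panel, tissueLabels = NULL) {
    if (is.null(tissueLabels)) return(panel)
    tiss <- unique(tissueLabels)
    out <- vapply(tiss, function(t)
        rowMeans(panel[, tissueLabels == t, drop = FALSE], na.rm = TRUE),
        numeric(nrow(panel)))
    dimnames(out) <- list(rownames(panel), tiss)
    out
}

#' Select CpGs constitutively methylated across normal tissues
#'
#' Probes whose mean beta value exceeds `betaMin` in EVERY normal tissue
#' type, restricted to distal enhancer-like signature (dELS) probes more
#' than 2 kb from the nearest transcription start site.  These probes
#' form the screening universe for metastasis-associated
#' hypomethylation: loss of methylation there cannot be explained by
#' stromal contamination from the metastatic target tissue.
#'
#' @param panel probe-by-tissue matrix of normal mean beta values (or
#'   probe-by-sample values plus `tissueLabels`).
#' @param annotation `GRanges` probe annotation (see [probeAnnotation()])
#'   or a data.frame with `dELS` and `tssDistance` columns and probe row
#'   names.
#' @param betaMin per-tissue mean beta must exceed this (default 0.8).
#' @param minTssDistance dELS probes must be further than this from a
#'   TSS (default 2000).
#' @param tissueLabels optional tissue label per panel column.
#' @return character vector of probe names.
#' @export
selectConstitutivelyMethylated <- function(panel, annotation,
                                           betaMin = 0.8,
                                           minTssDistance = 2000,
                                           tissueLabels = NULL) {
    means <- .tissueMeans(panel, tissueLabels)
    if (ncol(means) < 2L) stop("need >= 2 normal tissue types")
    ann <- if (is(annotation, "GRanges"))
        as.data.frame(S4Vectors::mcols(annotation),
                      row.names = names(annotation))
    else annotation
    const <- rownames(means)[apply(means > betaMin, 1, all)]
    distal <- rownames(ann)[ann$dELS & ann$tssDistance > minTssDistance]
    intersect(const, distal)
}

#' Select CpGs unmethylated in all normal tissues
#'
#' Probes whose mean beta value stays at or below `betaMax` in every
#' normal tissue type: the background universe for the
#' metastasis-associated promoter hypermethylation screen (probes with
#' tissue-specific methylation, mean beta above the cutoff in any
#' tissue, are eliminated).
#'
#' @inheritParams selectConstitutivelyMethylated
#' @param betaMax per-tissue mean beta must not exceed this (default
#'   0.2).
#' @return character vector of probe names.
#' @export
selectUnmethylatedBackground <- function(panel, betaMax = 0.2,
                                         tissueLabels = NULL) {
    means <- .tissueMeans(panel, tissueLabels)
    if (ncol(means) < 2L) stop("need >= 2 normal tissue types")
    rownames(means)[apply(means <= betaMax, 1, all)]
}

## Vectorized per-probe Welch t-test (two groups across columns).
.rowWelchT <- function(a, b) {
    n1 <- rowSums(!is.na(a)); n2 <- rowSums(!is.na(b))
    m1 <- rowMeans(a, na.rm = TRUE); m2 <- rowMeans(b, na.rm = TRUE)
    v1 <- apply(a, 1, stats::var, na.rm = TRUE)
    v2 <- apply(b, 1, stats::var, na.rm = TRUE)
    se2 <- v1 / n1 + v2 / n2
    t <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    p <- 2 * stats::pt(-abs(t), df)
    data.frame(delta = m1 - m2, t = t, df = df, p = p)
}

#' Identify preservation-biased probes
#'
#' Probes differentially methylated between FF and FFPE samples are
#' technical artifacts of preservation chemistry.  A probe is removed
#' only when BOTH criteria hold: Welch t-test FDR below `fdr` AND
#' absolute mean beta difference above `delta`.
#'
#' @param beta probe-by-sample beta matrix or [BetaSet-class].
#' @param preservation character per sample, `"FF"` / `"FFPE"`.
#' @param fdr,delta joint removal thresholds (defaults 0.01 and 0.25).
#' @return character vector of removed probe names; with both classes
#'   absent the call is a no-op with a warning.
#' @export
removePreservationBiasedProbes <- function(beta, preservation,
                                           fdr = 0.01, delta = 0.25) {
    m <- if (is(beta, "BetaSet")) assay(beta, "beta") else beta
    pres <- as.character(preservation)
    if (length(unique(pres)) < 2L) {
        warning("single preservation class: no probes removed")
        return(character(0))
    }
    res <- .rowWelchT(m[, pres == "FFPE", drop = FALSE],
                      m[, pres == "FF", drop = FALSE])
    q <- benjaminiHochberg(res$p)
    rownames(m)[!is.na(q) & q < fdr & abs(res$delta) > delta]
}

#' Most variably methylated probes
#'
#' Top `k` probes by beta-value variance across samples, with a
#' deterministic lexicographic probe-id tie-break.
#'
#' @param beta probe-by-sample beta matrix or [BetaSet-class].
#' @param k number of probes to select.
#' @return character vector of `k` probe names.
#' @export
topVariableProbes <- function(beta, k = 5000L) {
    m <- if (is(beta, "BetaSet")) assay(beta, "beta") else beta
    if (k > nrow(m)) stop("k exceeds the number of probes available")
    v <- apply(m, 1, stats::var, na.rm = TRUE)
    ord <- order(-v, rownames(m))
    rownames(m)[ord[seq_len(k)]]
}

#' Probe-wise mixed-model screen for differential methylation
#'
#' Fits [lmmPaired()] (beta ~ group + purity + (1 | participant)) for
#' every probe in the screening set, adjusts p-values across the set
#' with Benjamini-Hochberg, and marks probes significant at `fdr` whose
#' coefficient sign matches the screen direction (hypo: metastasis
#' coefficient negative; hyper: positive).  Probes whose fit fails are
#' reported with missing statistics, never silently dropped.
#'
#' @param beta probe-by-sample beta matrix or [BetaSet-class].
#' @param probes probe names forming the screening set.
#' @param group per-sample `primary`/`metastasis` labels.
#' @param participant per-sample participant ids.
#' @param purity per-sample tumor purity (optional but recommended: low
#'   purity dilutes tumor-intrinsic methylation signal).
#' @param direction `"hypo"` or `"hyper"`.
#' @param fdr significance threshold on q (default 0.05).
#' @return data.frame with columns `probe`, `estimate`, `se`, `df`, `p`,
#'   `q`, `direction`, `degenerate` and `significant`.
#' @export
methylationScreen <- function(beta, probes, group, participant,
                              purity = NULL,
                              direction = c("hypo", "hyper"),
                              fdr = 0.05) {
    direction <- match.arg(direction)
    m <- if (is(beta, "BetaSet")) assay(beta, "beta") else beta
    miss <- setdiff(probes, rownames(m))
    if (length(miss)) stop("probe(s) absent from the beta matrix: ",
                           paste(utils::head(miss, 5), collapse = ", "))
    fits <- lapply(probes, function(p) {
        r <- tryCatch(lmmPaired(m[p, ], group, participant, purity),
                      error = function(e) NULL)
        if (is.null(r))
            r <- list(estimate = NA_real_, se = NA_real_, df = NA_real_,
                      p = NA_real_, degenerate = TRUE)
        data.frame(probe = p, estimate = r$estimate, se = r$se,
                   df = r$df, p = r$p, degenerate = isTRUE(r$degenerate))
    })
    res <- do.call(rbind, fits)
    res$q <- benjaminiHochberg(res$p)
    res$direction <- direction
    signOk <- if (direction == "hypo") res$estimate < 0 else res$estimate > 0
    res$significant <- !is.na(res$q) & res$q < fdr & signOk
    res
}

#' Transcription-factor binding-site enrichment at significant CpGs
#'
#' For each DNA-binding factor, builds the 2x2 table of (significant vs
#' background-only probes) x (overlapping vs not overlapping the
#' factor's binding intervals), where a probe overlaps when its
#' `window`-bp window centered on the CpG ([pos - window/2, pos +
#' window/2) in 0-based half-open coordinates) intersects any interval.
#' Two-sided Fisher tests with Benjamini-Hochberg adjustment across
#' factors.  Infinite odds ratios are reported capped with a flag.
#'
#' @param significant probe names of the significant set.
#' @param sites named list (or `GRangesList`) of binding-site `GRanges`
#'   per factor.
#' @param background probe names of the background universe (must
#'   contain the significant set).
#' @param annotation probe `GRanges` (1-based width-1 positions, as from
#'   [probeAnnotation()]) covering all background probes.
#' @param window window width in bp centered on each CpG (default 200).
#' @param orCap value reported for infinite odds ratios.
#' @return data.frame per factor: `factor`, `overlapSig`,
#'   `overlapBg`, `oddsRatio`, `orCapped`, `p`, `q`.
#' @export
tfbsEnrichment <- function(significant, sites, background, annotation,
                           window = 200L, orCap = Inf) {
    if (!all(significant %in% background))
        stop("background must contain the significant set")
    if (!length(significant)) {
        message("empty significant set: nothing to test")
        return(data.frame(factor = character(0)))
    }
    pr <- annotation[background]
    win <- GRanges(GenomicRanges::seqnames(pr),
                   IRanges(start = GenomicRanges::start(pr) - window %/% 2L,
                           width = window))
    names(win) <- background
    isSig <- background %in% significant
    rows <- lapply(names(sites), function(f) {
        hit <- IRanges::overlapsAny(win, sites[[f]])
        a <- sum(hit & isSig);  b <- sum(!hit & isSig)
        c <- sum(hit & !isSig); d <- sum(!hit & !isSig)
        or <- (a * d) / (b * c)
        data.frame(factor = f, overlapSig = a, overlapBg = c,
                   oddsRatio = if (is.finite(or)) or else orCap,
                   orCapped = !is.finite(or),
                   p = fisherExactTwoSided(matrix(c(a, b, c, d), 2,
                                                  byrow = TRUE))$p)
    })
    res <- do.call(rbind, rows)
    res$q <- benjaminiHochberg(res$p)
    res
}

#' Map significant CpGs to putative enhancer target genes
#'
#' For each probe, collects up to `maxPerSide` nearest genes within
#' `maxDistance` on each side (upstream = TSS before the CpG,
#' downstream = after; strand is ignored when absent, with a flag), then
#' intersects the union with a predicted-target whitelist.
#'
#' @param probes named integer vector of CpG positions (0-based) or a
#'   probe `GRanges`.
#' @param geneAnnotation data.frame with columns `gene`, `chrom`, `tss`
#'   (position) and optionally `strand`.
#' @param whitelist character vector of predicted target genes.
#' @param maxPerSide maximum genes per side (default 10).
#' @param maxDistance maximum TSS distance in bp (default 1e6).
#' @return data.frame `gene`, `nProbes`, `probes` (comma-joined
#'   supporting probes), restricted to the whitelist.
#' @export
mapPutativeTargets <- function(probes, geneAnnotation, whitelist,
                               maxPerSide = 10L, maxDistance = 1e6) {
    if (is(probes, "GRanges")) {
        pos <- stats::setNames(GenomicRanges::start(probes) - 1L,
                               names(probes))
        chr <- stats::setNames(as.character(
            GenomicRanges::seqnames(probes)), names(probes))
    } else {
        pos <- probes
        chr <- stats::setNames(rep(geneAnnotation$chrom[1], length(probes)),
                               names(probes))
    }
    if (is.null(geneAnnotation$strand))
        message("gene annotation lacks strand; distances computed to TSS ",
                "ignoring strand")
    hits <- list()
    for (p in names(pos)) {
        g <- geneAnnotation[geneAnnotation$chrom == chr[[p]], ]
        d <- g$tss - pos[[p]]
        up <- g[d < 0 & abs(d) <= maxDistance, ]
        dn <- g[d > 0 & d <= maxDistance, ]
        up <- up[order(abs(up$tss - pos[[p]])), ]
        dn <- dn[order(abs(dn$tss - pos[[p]])), ]
        sel <- c(utils::head(up$gene, maxPerSide),
                 utils::head(dn$gene, maxPerSide))
        for (gene in sel) hits[[gene]] <- c(hits[[gene]], p)
    }
    keep <- intersect(names(hits), whitelist)
    if (!length(keep))
        return(data.frame(gene = character(0), nProbes = integer(0),
                          probes = character(0)))
    data.frame(gene = keep,
               nProbes = vapply(hits[keep], length, 0L),
               probes = vapply(hits[keep], paste, "", collapse = ","),
               row.names = NULL)
}

#' Term over-representation test
#'
#' One-sided (enrichment) Fisher exact test per annotation term for a
#' gene list against a universe, with Benjamini-Hochberg adjustment
#' across terms.  Terms with no universe genes are skipped with a
#' notice.
#'
#' @param genes character gene list (must be contained in `universe`).
#' @param termGenes named list of gene vectors per term.
#' @param universe character background gene universe.
#' @return data.frame `term`, `hits`, `termSize`, `p`, `q`,
#'   `genes` (comma-joined hits).
#' @export
overrepresentationTest <- function(genes, termGenes, universe) {
    if (!all(genes %in% universe))
        stop("gene list must be contained in the universe")
    if (!length(genes))
        return(data.frame(term = character(0)))
    rows <- lapply(names(termGenes), function(tm) {
        tset <- intersect(termGenes[[tm]], universe)
        if (!length(tset)) return(NULL)
        k <- length(intersect(genes, tset))
        tab <- matrix(c(k, length(genes) - k,
                        length(tset) - k,
                        length(universe) - length(genes) - length(tset) + k),
                      2, byrow = TRUE)
        p <- stats::fisher.test(tab, alternative = "greater")$p.value
        data.frame(term = tm, hits = k, termSize = length(tset), p = p,
                   genes = paste(intersect(genes, tset), collapse = ","))
    })
    res <- do.call(rbind, rows)
    if (is.null(res)) {
        message("no term has universe genes")
        return(data.frame(term = character(0)))
    }
    res$q <- benjaminiHochberg(res$p)
    res
}

#' Call gene-level promoter methylation status
#'
#' Aggregates a gene's promoter CpG beta values per sample (mean by
#' default, or max) and calls the sample methylated when the aggregate
#' is at or above `threshold`.  Samples with all promoter probes masked
#' receive a missing status.
#'
#' @param beta promoter-probe-by-sample beta matrix (rows = the gene's
#'   promoter CpGs).
#' @param threshold call threshold on the aggregate beta (default 0.4).
#' @param aggregate `"mean"` or `"max"`.
#' @return named character vector per sample: `"methylated"`,
#'   `"unmethylated"` or NA.
#' @export
callGeneMethylation <- function(beta, threshold = 0.4,
                                aggregate = c("mean", "max")) {
    aggregate <- match.arg(aggregate)
    if (!nrow(beta)) stop("at least one promoter probe is required")
    agg <- apply(beta, 2, function(v) {
        v <- v[!is.na(v)]
        if (!length(v)) return(NA_real_)
        if (aggregate == "mean") mean(v) else max(v)
    })
    out <- ifelse(is.na(agg), NA_character_,
                  ifelse(agg >= threshold, "methylated", "unmethylated"))
    stats::setNames(out, colnames(beta))
}

#' Deterministic heatmap sample ordering
#'
#' Orders tumor samples for a methylation heat map by four rules: (1)
#' cases stratified by the primary tumor's intrinsic subtype call (fixed
#' subtype order); (2) within subtype, cases by decreasing median beta
#' value of the primary; (3) within a case, the primary first, then its
#' metastases; (4) metastases ordered by decreasing tumor purity.
#' Remaining ties break by participant then sample id.  Missing purity
#' is treated as 0 and flagged with a warning.
#'
#' @param samples data.frame with columns `sample`, `participant`,
#'   `type` (`primary`/`metastasis`) and `purity`.
#' @param primaryCalls named character vector: subtype call of each
#'   participant's primary.
#' @param beta probe-by-sample beta matrix used for the primary median.
#' @return character vector of ordered sample names.
#' @export
heatmapSampleOrder <- function(samples, primaryCalls, beta) {
    if (anyNA(samples$purity)) {
        warning("missing purity treated as 0")
        samples$purity[is.na(samples$purity)] <- 0
    }
    primMed <- vapply(split(samples, samples$participant), function(d) {
        p <- d$sample[d$type == "primary"]
        stats::median(beta[, p], na.rm = TRUE)
    }, numeric(1))
    call <- primaryCalls[samples$participant]
    ord <- order(match(call, .SUBTYPE_ORDER),
                 -primMed[samples$participant],
                 samples$participant,
                 samples$type != "primary",    # primary first within case
                 -samples$purity,
                 samples$sample)
    samples$sample[ord]
}
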
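#' Upper-quartile normalization of RNA-seq counts
#'
#' Scales every sample so that the upper quartile of its nonzero gene
#' counts equals a fixed target.  The default target is the geometric
#' mean of the per-sample upper quartiles, so normalization is
#' scale-free: a sample that is an exact multiple of another maps onto
#' identical columns.
#'
#' @param x a counts-stage [StagedExpression-class].
#' @param target optional fixed upper-quartile target; default the
#'   geometric mean of per-sample upper quartiles of nonzero counts.
#' @return a normalized-stage [StagedExpression-class].
#' @export
upperQuartileNormalize <- function(x, target = NULL) {
    stopifnot(is(x, "StagedExpression"), exprStage(x) == "counts")
    m <- assay(x)
    uq <- apply(m, 2, function(v) {
        v <- v[v > 0]
        if (!length(v)) return(NA_real_)
        stats::quantile(v, 0.75, names = FALSE)
    })
    if (anyNA(uq))
        stop("sample(s) with all-zero counts: ",
             paste(colnames(m)[is.na(uq)], collapse = ", "))
    if (is.null(target)) target <- exp(mean(log(uq)))
    out <- sweep(m, 2, target / uq, `*`)
    StagedExpression(out, "normalized", colData = colData(x))
}

#' Median-of-ratios normalization of RNA-seq counts
#'
#' Size factors are computed with the median-of-ratios method (each
#' sample's median, over genes nonzero in all samples, of the ratio of
#' its count to the gene's geometric mean), as implemented in DESeq2;
#' counts are divided by the size factors.  Genes whose mean normalized
#' count falls below `minMeanCount` are flagged for removal.
#'
#' @param x a counts-stage [StagedExpression-class].
#' @param minMeanCount flag genes with mean normalized count below this.
#' @return list with `normalized` (a normalized-stage
#'   [StagedExpression-class] with low-expressed genes removed),
#'   `sizeFactors`, and `lowExpressed` (the flagged gene names).
#' @export
medianOfRatiosNormalize <- function(x, minMeanCount = 10) {
    stopifnot(is(x, "StagedExpression"), exprStage(x) == "counts")
    m <- assay(x)
    sf <- tryCatch(DESeq2::estimateSizeFactorsForMatrix(m),
                   error = function(e)
                       stop("median-of-ratios undefined: no gene has ",
                            "nonzero counts in every sample"))
    norm <- sweep(m, 2, sf, `/`)
    low <- rownames(norm)[rowMeans(norm) < minMeanCount]
    keep <- setdiff(rownames(norm), low)
    y <- StagedExpression(norm[keep, , drop = FALSE], "normalized",
                          colData = colData(x))
    list(normalized = y, sizeFactors = sf, lowExpressed = low)
}

#' Expression filter and log2 transform
#'
#' Keeps genes with a positive value in at least `expressedFraction` of
#' samples, then maps each value v to log2(v) for v > 0 and to 0 for
#' v = 0 (zeros are returned to the empty cells after transformation).
#'
#' @param x a normalized-stage [StagedExpression-class].
#' @param expressedFraction minimum fraction of samples with value > 0.
#' @return a log2-stage [StagedExpression-class].
#' @export
log2FilterTransform <- function(x, expressedFraction = 0.70) {
    stopifnot(is(x, "StagedExpression"), exprStage(x) == "normalized")
    m <- assay(x)
    keep <- rowMeans(m > 0) >= expressedFraction
    if (!any(keep)) stop("no gene passes the expressed-fraction filter")
    m <- m[keep, , drop = FALSE]
    out <- ifelse(m > 0, log2(m), 0)
    StagedExpression(out, "log2", colData = colData(x))
}

#' Remove an additive batch effect
#'
#' Per gene, fits the least-squares batch means and subtracts the batch
#' component re-centered so that the gene's grand mean is preserved
#' exactly.  With a planted constant offset on one batch this removes
#' the offset completely.
#'
#' @param x a log2-stage [StagedExpression-class].
#' @param batch character/factor of batch labels, one per sample.
#' @return a batch_corrected-stage [StagedExpression-class].
#' @export
correctBatchEffect <- function(x, batch) {
    stopifnot(is(x, "StagedExpression"), exprStage(x) == "log2")
    batch <- factor(batch)
    if (nlevels(batch) < 2L)
        stop("need at least two batches")
    if (any(table(batch) < 2L))
        stop("batch confounded with a single sample: ",
             paste(levels(batch)[table(batch) < 2L], collapse = ", "))
    m <- assay(x)
    grand <- rowMeans(m)
    out <- m
    for (b in levels(batch)) {
        sel <- batch == b
        out[, sel] <- m[, sel] - rowMeans(m[, sel, drop = FALSE]) + grand
    }
    StagedExpression(out, "batch_corrected", colData = colData(x))
}

## Vectorized per-gene two-group equal-variance linear model
## (lm(gene ~ group) t-test on the group coefficient).
.rowPooledT <- function(a, b) {
    n1 <- ncol(a); n2 <- ncol(b)
    m1 <- rowMeans(a); m2 <- rowMeans(b)
    v1 <- rowSums((a - m1)^2); v2 <- rowSums((b - m2)^2)
    df <- n1 + n2 - 2
    sp2 <- (v1 + v2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    t <- (m1 - m2) / se
    p <- 2 * stats::pt(-abs(t), df)
    data.frame(delta = m1 - m2, t = t, p = p)
}

#' Derive the normal-tissue contamination signature
#'
#' For each normal metastatic-site tissue, genes significantly
#' upregulated versus normal breast (per-gene two-group linear model,
#' Benjamini-Hochberg FDR below `fdrSite`) form site signatures whose
#' union is the candidate contamination set.  Genes also upregulated in
#' primary tumors versus normal breast (FDR below `fdrPrimary`) are not
#' unique to normal tissue and are subtracted, giving the final
#' signature: |final| = |union| - |overlap| by construction.
#'
#' @param normalsBySite named list of log-scale gene-by-sample matrices,
#'   one per normal metastatic-site tissue.
#' @param normalBreast log-scale matrix of normal breast samples.
#' @param primaries log-scale matrix of primary tumor samples.
#' @param fdrSite,fdrPrimary FDR thresholds for the site and
#'   primary-tumor comparisons.
#' @return list with `siteSets`, `siteUnion`, `primarySet`, `overlap`,
#'   `finalSet` and `sizes`.
#' @export
deriveNormalTissueSignature <- function(normalsBySite, normalBreast,
                                        primaries,
                                        fdrSite = 1e-5,
                                        fdrPrimary = 0.01) {
    if (is.null(normalBreast)) stop("normal breast reference is required")
    stopifnot(is.list(normalsBySite), length(normalsBySite) >= 1L)
    lapply(c(normalsBySite, list(normalBreast, primaries)), function(m)
        if (ncol(m) < 2L) stop("each comparison needs >= 2 samples per group"))
    genes <- Reduce(intersect, lapply(c(normalsBySite, list(primaries)),
                                      rownames),
                    rownames(normalBreast))
    normalBreast <- normalBreast[genes, , drop = FALSE]
    upSet <- function(a, fdr) {
        res <- .rowPooledT(a[genes, , drop = FALSE], normalBreast)
        q <- benjaminiHochberg(res$p)
        genes[!is.na(q) & q < fdr & res$delta > 0]
    }
    siteSets <- lapply(normalsBySite, upSet, fdr = fdrSite)
    siteUnion <- sort(unique(unlist(siteSets)))
    primarySet <- upSet(primaries, fdrPrimary)
    overlap <- intersect(siteUnion, primarySet)
    finalSet <- setdiff(siteUnion, overlap)
    list(siteSets = siteSets, siteUnion = siteUnion,
         primarySet = primarySet, overlap = overlap, finalSet = finalSet,
         sizes = c(union = length(siteUnion), overlap = length(overlap),
                   final = length(finalSet)))
}

#' Remove signature genes from an expression matrix
#'
#' Deletes the listed genes (the normal-tissue contamination signature)
#' from a batch-corrected matrix; all remaining values are unchanged and
#' the result is tagged normal_adjusted.  Genes absent from the matrix
#' are ignored with a notice.
#'
#' @param x a batch_corrected-stage [StagedExpression-class].
#' @param genes character vector of gene names to remove.
#' @return a normal_adjusted-stage [StagedExpression-class].
#' @export
removeSignatureGenes <- function(x, genes) {
    stopifnot(is(x, "StagedExpression"), exprStage(x) == "batch_corrected")
    absent <- setdiff(genes, rownames(x))
    if (length(absent))
        message(length(absent), " signature gene(s) not in the matrix")
    keep <- setdiff(rownames(x), genes)
    if (!length(keep)) stop("removal would empty the matrix")
    m <- assay(x)[keep, , drop = FALSE]
    StagedExpression(m, "normal_adjusted", colData = colData(x))
}

#' Score a gene signature per sample
#'
#' The signature score is the mean (default) or median of the member
#' genes' values in each sample.  Members missing from the matrix are
#' reported via the `missingGenes` attribute; if no member is present
#' the scores are NaN.
#'
#' @param x gene-by-sample numeric matrix or [StagedExpression-class].
#' @param genes signature member gene names.
#' @param method `"mean"` or `"median"`.
#' @return named numeric vector of per-sample scores with attribute
#'   `missingGenes`.
#' @export
scoreSignature <- function(x, genes, method = c("mean", "median")) {
    method <- match.arg(method)
    m <- if (is(x, "StagedExpression")) assay(x) else x
    present <- intersect(genes, rownames(m))
    missing <- setdiff(genes, present)
    if (!length(present)) {
        out <- stats::setNames(rep(NaN, ncol(m)), colnames(m))
    } else {
        sub <- m[present, , drop = FALSE]
        out <- if (method == "mean") colMeans(sub)
               else apply(sub, 2, stats::median)
    }
    attr(out, "missingGenes") <- missing
    out
}

#' Combine signature scores into a metagene score
#'
#' The metagene score of a sample is the mean of its member signature
#' scores (for example, the immune metagene built from 16 correlated
#' immune signatures, or the MHC class I metagene built directly from
#' the antigen-presentation genes).  Any member signature entirely
#' missing from the score matrix yields NaN with a report.
#'
#' @param scores signature-by-sample numeric matrix of module scores.
#' @param members names of the member signatures (rows of `scores`).
#' @return named numeric vector of per-sample metagene scores with
#'   attribute `missingMembers`.
#' @export
metageneScore <- function(scores, members) {
    missing <- setdiff(members, rownames(scores))
    if (length(missing)) {
        out <- stats::setNames(rep(NaN, ncol(scores)), colnames(scores))
    } else {
        out <- colMeans(scores[members, , drop = FALSE])
    }
    attr(out, "missingMembers") <- missing
    out
}

#' Primary-metastasis pair concordance
#'
#' For each primary-metastasis pair, computes the Pearson correlation of
#' each member (over the supplied gene subset) to every other sample in
#' the matrix; a pair is concordant when each member's top-correlated
#' other sample is its partner.  Constant sample vectors have undefined
#' correlation and exclude the pair with a flag.
#'
#' @param x gene-by-sample numeric matrix (log scale) or
#'   [StagedExpression-class].
#' @param pairs data.frame with columns `primary` and `metastasis`
#'   holding sample names.
#' @param genes gene subset used for the correlations (e.g. an intrinsic
#'   gene list); default all genes.
#' @return list with `concordance` (fraction of evaluable pairs mutually
#'   top-correlated), `detail` (per-pair data.frame) and `excluded`
#'   (pairs dropped for constant members).
#' @export
pairConcordance <- function(x, pairs, genes = NULL) {
    m <- if (is(x, "StagedExpression")) assay(x) else x
    if (!is.null(genes)) {
        genes <- intersect(genes, rownames(m))
        if (!length(genes)) stop("no subset gene present in the matrix")
        m <- m[genes, , drop = FALSE]
    }
    if (nrow(pairs) < 2L) stop("need at least two pairs")
    miss <- setdiff(c(pairs$primary, pairs$metastasis), colnames(m))
    if (length(miss)) stop("pair sample(s) absent from the matrix: ",
                           paste(miss, collapse = ", "))
    constant <- apply(m, 2, function(v) stats::sd(v) == 0)
    cc <- suppressWarnings(stats::cor(m))
    diag(cc) <- -Inf
    topOther <- function(s) colnames(cc)[which.max(cc[s, ])]
    ok <- !(constant[pairs$primary] | constant[pairs$metastasis])
    detail <- data.frame(pairs,
                         topOfPrimary = NA_character_,
                         topOfMetastasis = NA_character_,
                         concordant = NA)
    for (i in which(ok)) {
        detail$topOfPrimary[i] <- topOther(pairs$primary[i])
        detail$topOfMetastasis[i] <- topOther(pairs$metastasis[i])
        detail$concordant[i] <-
            detail$topOfPrimary[i] == pairs$metastasis[i] &&
            detail$topOfMetastasis[i] == pairs$primary[i]
    }
    list(concordance = mean(detail$concordant[ok]),
         detail = detail,
         excluded = pairs[!ok, , drop = FALSE])
}
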
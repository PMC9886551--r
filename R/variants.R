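#' Local mismatch rate around a variant
#'
#' The number of mismatched bases among all reads aligned within a
#' 10-bp window on each side of the variant position, divided by the
#' total number of aligned bases in that region.  The variant's own
#' column is excluded from both counts by the callers in this package,
#' so the variant allele never counts as mismatch against itself.  A
#' zero total gives an undefined (NA) rate, which automatically fails
#' the corrected-VAF filter.
#'
#' @param mismatch,total window mismatch and total aligned base counts
#'   (vectorized).
#' @return numeric local mismatch rate(s) in [0, 1], NA where `total`
#'   is 0.
#' @export
localMismatchRate <- function(mismatch, total) {
    stopifnot(all(mismatch <= total, na.rm = TRUE),
              all(mismatch >= 0, na.rm = TRUE))
    ifelse(total > 0, mismatch / total, NA_real_)
}

#' Corrected-VAF (LMR) filter
#'
#' The local mismatch rate is subtracted from the variant allele
#' frequency; the variant fails when the corrected value falls below 4%
#' ("below" is strict: exactly 0.04 passes).  An undefined LMR fails.
#'
#' @param vaf variant allele frequency in [0, 1] (vectorized).
#' @param lmr local mismatch rate from [localMismatchRate()].
#' @param minCorrected threshold (default 0.04).
#' @return logical: TRUE = pass.
#' @export
lmrVafFilter <- function(vaf, lmr, minCorrected = 0.04) {
    pass <- (vaf - lmr) >= minCorrected
    pass[is.na(lmr)] <- FALSE
    pass
}

## Shared bucket rule for read-diversity filters: variants with more
## than 15 supporting reads need >= 4 unique positions, those with more
## than 5 need >= 2; 5 or fewer supporting reads pass unconditionally.
.diversityPass <- function(n, u) {
    if (n > 15L) u >= 4L
    else if (n > 5L) u >= 2L
    else TRUE
}

#' Read start diversity (RSD) filter
#'
#' Counts unique soft-trimmed start positions among a variant's
#' supporting reads.  FFPE artifacts tend to be supported by stacks of
#' reads starting at identical positions.
#'
#' @param readStarts integer vector of soft-trimmed supporting-read
#'   start positions.
#' @return logical: TRUE = pass.
#' @export
rsdFilter <- function(readStarts) {
    .diversityPass(length(readStarts), length(unique(readStarts)))
}

#' Unique nearest read end (URE) filter
#'
#' For each supporting read, records whichever of its soft-trimmed
#' start or end position lies closest to the variant (ties go to the
#' start, for determinism) and counts the unique recorded positions,
#' with the same bucket thresholds as the read start diversity filter.
#'
#' @param readStarts,readEnds integer vectors of soft-trimmed read
#'   coordinates (start < end per read).
#' @param pos the variant position (same coordinate system).
#' @return logical: TRUE = pass.
#' @export
ureFilter <- function(readStarts, readEnds, pos) {
    stopifnot(length(readStarts) == length(readEnds),
              all(readStarts < readEnds))
    nearest <- ifelse(abs(readStarts - pos) <= abs(readEnds - pos),
                      readStarts, readEnds)
    .diversityPass(length(nearest), length(unique(nearest)))
}

#' Apply the three FFPE artifact filters to a variant set
#'
#' Runs the corrected-VAF, read-start-diversity and unique-nearest-end
#' filters on every variant from an FFPE-preserved sample; a variant is
#' kept when it passes all three.  Variants from fresh-frozen samples
#' pass through untouched, annotated `not_applicable` (the failure
#' modes targeted are formalin-fixation chemistry).
#'
#' @param variants `DataFrame`/data.frame with columns `pos`, `vaf`,
#'   `windowMismatch`, `windowTotal`, `sample` and list columns
#'   `readStarts`, `readEnds` (as produced by [simulateReadEvidence()]
#'   or [readVariantEvidence()]).
#' @param preservation named character vector, `FF`/`FFPE` per sample.
#' @return the input with added columns `applied`, `lmr`, `lmrPass`,
#'   `rsdPass`, `urePass` and `keep`.
#' @export
applyFfpeFilters <- function(variants, preservation) {
    miss <- setdiff(unique(variants$sample), names(preservation))
    if (length(miss))
        stop("missing preservation label for sample(s): ",
             paste(miss, collapse = ", "))
    n <- nrow(variants)
    isFFPE <- unname(preservation[variants$sample] == "FFPE")
    lmr <- localMismatchRate(variants$windowMismatch, variants$windowTotal)
    lmrPass <- lmrVafFilter(variants$vaf, lmr)
    rsdPass <- vapply(seq_len(n), function(i)
        rsdFilter(variants$readStarts[[i]]), logical(1))
    urePass <- vapply(seq_len(n), function(i)
        ureFilter(variants$readStarts[[i]], variants$readEnds[[i]],
                  variants$pos[i]), logical(1))
    variants$applied <- ifelse(isFFPE, "ffpe", "not_applicable")
    variants$lmr <- lmr
    variants$lmrPass <- ifelse(isFFPE, lmrPass, NA)
    variants$rsdPass <- ifelse(isFFPE, rsdPass, NA)
    variants$urePass <- ifelse(isFFPE, urePass, NA)
    variants$keep <- !isFFPE | (lmrPass & rsdPass & urePass)
    variants
}

#' Build a binary gene-by-sample mutation matrix
#'
#' Variants are restricted to the nine protein-altering classification
#' classes (frame-shift indels, in-frame indels, missense, nonsense,
#' nonstop, splice-site, translation start site); all other
#' classifications are dropped and tallied.  A gene row is retained
#' only when mutated in at least `minSamples` samples.  Every 1 in the
#' matrix is traceable to its variant records via the `provenance`
#' attribute.
#'
#' @param variants `DataFrame`/data.frame with `gene`, `sample`,
#'   `classification` and `variantId` columns.
#' @param samples optional sample universe for the columns (defaults to
#'   the samples present in `variants`).
#' @param minSamples minimum mutated samples per retained gene
#'   (default 10).
#' @return binary integer matrix (genes x samples) with attributes
#'   `provenance` (list gene -> sample -> variant ids) and
#'   `droppedClassifications` (named tally).
#' @export
buildMutationMatrix <- function(variants, samples = NULL,
                                minSamples = 10L) {
    v <- as.data.frame(variants[, c("variantId", "gene", "sample",
                                    "classification")])
    drop <- !v$classification %in% .CLASS_WHITELIST
    tally <- table(v$classification[drop])
    v <- v[!drop, , drop = FALSE]
    if (is.null(samples)) samples <- sort(unique(v$sample))
    genes <- sort(unique(v$gene))
    m <- matrix(0L, length(genes), length(samples),
                dimnames = list(genes, samples))
    m[cbind(v$gene, v$sample)] <- 1L
    keep <- rowSums(m) >= minSamples
    prov <- lapply(split(v, v$gene)[genes[keep]], function(d)
        lapply(split(d$variantId, d$sample), identity))
    m <- m[keep, , drop = FALSE]
    attr(m, "provenance") <- prov
    attr(m, "droppedClassifications") <- tally
    m
}

#' Restrict primary mutation calls to those shared with a metastasis
#'
#' Removes any variant called in a primary sample that is not also
#' called (same chrom, pos, ref, alt) in at least one of the same
#' participant's metastasis samples — FFPE artifacts arise mainly in
#' the (often FFPE-preserved) primaries.  Metastasis calls are never
#' touched; primaries without a paired metastasis are removed entirely.
#'
#' @param variants `DataFrame`/data.frame with `chrom`, `pos`, `ref`,
#'   `alt`, `sample` columns.
#' @param pairs data.frame with columns `participant`, `primary`,
#'   `metastasis` (one row per metastasis).
#' @return the restricted variant set (same columns).
#' @export
pairRestrictPrimaryCalls <- function(variants, pairs) {
    key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = ":")
    v <- variants
    k <- key(v)
    pairedPrimaries <- unique(pairs$primary)
    isPrim <- v$sample %in% pairedPrimaries
    unpairedPrim <- setdiff(
        grep("_P$", unique(v$sample), value = TRUE), pairedPrimaries)
    keep <- rep(TRUE, nrow(v))
    keep[v$sample %in% unpairedPrim] <- FALSE
    for (i in which(isPrim)) {
        part <- pairs$participant[match(v$sample[i], pairs$primary)]
        mets <- pairs$metastasis[pairs$participant == part]
        inMet <- any(k == k[i] & v$sample %in% mets)
        if (!inMet) keep[i] <- FALSE
    }
    v[keep, , drop = FALSE]
}

#' Compare per-gene mutation frequencies between primaries and
#' metastases
#'
#' Metastasis calls are aggregated per participant (mutated if ANY of
#' the participant's metastases is mutated).  For each gene a 2x2 table
#' of mutated / non-mutated participants (primary row vs aggregated
#' metastasis row) is tested with the two-sided Fisher exact test and
#' adjusted across genes with Benjamini-Hochberg.
#'
#' @param x binary gene-by-sample mutation matrix (from
#'   [buildMutationMatrix()]).
#' @param pairs data.frame with columns `participant`, `primary`,
#'   `metastasis` (one row per metastasis).
#' @return data.frame per gene: `gene`, `primaryCount`,
#'   `metastasisCount`, `n` (participants), `p`, `q`.
#' @export
compareMutationFrequencies <- function(x, pairs) {
    parts <- unique(pairs$participant)
    if (length(parts) < 2L) stop("need >= 2 pairs")
    prim <- stats::setNames(pairs$primary[match(parts, pairs$participant)],
                            parts)
    metOf <- split(pairs$metastasis, pairs$participant)[parts]
    ok <- prim %in% colnames(x)
    parts <- parts[ok]; prim <- prim[ok]; metOf <- metOf[ok]
    n <- length(parts)
    rows <- lapply(rownames(x), function(g) {
        pmut <- sum(x[g, prim] == 1L)
        mmut <- sum(vapply(metOf, function(ms)
            any(x[g, intersect(ms, colnames(x))] == 1L),
            logical(1)))
        tab <- matrix(c(pmut, n - pmut, mmut, n - mmut), 2, byrow = TRUE)
        data.frame(gene = g, primaryCount = pmut, metastasisCount = mmut,
                   n = n, p = fisherExactTwoSided(tab)$p)
    })
    res <- do.call(rbind, rows)
    res$q <- benjaminiHochberg(res$p)
    res
}
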
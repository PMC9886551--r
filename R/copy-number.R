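#' Segment-level copy-number scores
#'
#' The score of a recurrent segment in a sample is the mean of the
#' gene-level denoised log2 copy-ratio values over the segment's member
#' genes; segments with no member gene present get a missing score.
#'
#' @param geneLog2 gene-by-sample matrix of gene-level log2 copy
#'   ratios.
#' @param segments named list of member-gene vectors per segment.
#' @return segment-by-sample numeric matrix.
#' @export
segmentScores <- function(geneLog2, segments) {
    out <- t(vapply(segments, function(genes) {
        present <- intersect(genes, rownames(geneLog2))
        if (!length(present)) return(rep(NA_real_, ncol(geneLog2)))
        colMeans(geneLog2[present, , drop = FALSE], na.rm = TRUE)
    }, numeric(ncol(geneLog2))))
    dimnames(out) <- list(names(segments), colnames(geneLog2))
    out
}

#' Binarize segment scores into gains and losses
#'
#' Gain: score strictly above `cutoff`; loss: strictly below
#' `-cutoff`; scores within `[-cutoff, cutoff]` are neutral (neither).
#'
#' @param scores segment-by-sample score matrix.
#' @param cutoff gain/loss threshold (default 0.2).
#' @return list with logical matrices `gain` and `loss`.
#' @export
binarizeCna <- function(scores, cutoff = 0.2) {
    list(gain = scores > cutoff, loss = scores < -cutoff)
}

#' Per-segment comparison of alteration frequencies between groups
#'
#' For each segment and each direction (gain, loss), builds the 2x2
#' table of altered / unaltered samples in the primary versus
#' metastasis groups and applies the two-sided Fisher exact test;
#' q-values are Benjamini-Hochberg adjusted across segments within
#' each direction.  Degenerate margins give p = 1 (flagged by the
#' underlying test).
#'
#' @param binary list with `gain` and `loss` logical matrices (from
#'   [binarizeCna()]).
#' @param groups character per sample (column), `primary` /
#'   `metastasis`.
#' @return data.frame per segment: alteration counts, `gainP`,
#'   `gainQ`, `lossP`, `lossQ`.
#' @export
compareSegments <- function(binary, groups) {
    isPrim <- groups == "primary"
    if (!any(isPrim) || all(isPrim)) stop("both groups must be nonempty")
    testDir <- function(m) {
        vapply(rownames(m), function(s) {
            a <- sum(m[s, isPrim], na.rm = TRUE)
            b <- sum(!m[s, isPrim], na.rm = TRUE)
            c <- sum(m[s, !isPrim], na.rm = TRUE)
            d <- sum(!m[s, !isPrim], na.rm = TRUE)
            fisherExactTwoSided(matrix(c(a, b, c, d), 2, byrow = TRUE))$p
        }, numeric(1))
    }
    gp <- testDir(binary$gain); lp <- testDir(binary$loss)
    data.frame(segment = rownames(binary$gain),
               gainPrimary = rowSums(binary$gain[, isPrim, drop = FALSE],
                                     na.rm = TRUE),
               gainMetastasis = rowSums(binary$gain[, !isPrim,
                                                    drop = FALSE],
                                        na.rm = TRUE),
               lossPrimary = rowSums(binary$loss[, isPrim, drop = FALSE],
                                     na.rm = TRUE),
               lossMetastasis = rowSums(binary$loss[, !isPrim,
                                                    drop = FALSE],
                                        na.rm = TRUE),
               gainP = gp, gainQ = benjaminiHochberg(gp),
               lossP = lp, lossQ = benjaminiHochberg(lp),
               row.names = NULL)
}

#' Smooth a copy-ratio track by fixed-fold binning
#'
#' Merges consecutive runs of `reduction` records into one bin per
#' chromosome, assigning each bin the mean log2 value; a final partial
#' bin is kept at its actual size and flagged.
#'
#' @param track `GRanges` with a numeric `log2` metadata column,
#'   sorted, non-overlapping.
#' @param reduction number of records merged per bin (default 50).
#' @return `GRanges` of bins with metadata `log2` (bin mean),
#'   `nRecords` and `partial`.
#' @export
binCopyRatio <- function(track, reduction = 50L) {
    if (!length(track)) return(track)
    perChr <- lapply(split(track, GenomicRanges::seqnames(track)),
                     function(tr) {
        if (!length(tr)) return(NULL)
        idx <- ceiling(seq_along(tr) / reduction)
        starts <- tapply(GenomicRanges::start(tr), idx, min)
        ends <- tapply(GenomicRanges::end(tr), idx, max)
        val <- tapply(S4Vectors::mcols(tr)$log2, idx, mean)
        nrec <- tapply(seq_along(tr), idx, length)
        out <- GRanges(as.character(GenomicRanges::seqnames(tr))[1],
                       IRanges(start = as.integer(starts),
                               end = as.integer(ends)))
        S4Vectors::mcols(out) <- DataFrame(
            log2 = as.numeric(val), nRecords = as.integer(nrec),
            partial = as.integer(nrec) < reduction)
        out
    })
    out <- do.call(c, unname(perChr[!vapply(perChr, is.null, TRUE)]))
    out
}

#' Call focal deletions near genes of interest
#'
#' A focal deletion is called at a gene when some bin lying within
#' `proximity` bp of the gene span (overlap or flank, either side) has
#' tumor log2 below `log2Max` AND exceeds the matched normal at that
#' bin by more than `diffMin` (normal minus tumor), so germline losses
#' present in the normal are never called somatic.
#'
#' @param tumorBinned,normalBinned binned tracks from [binCopyRatio()]
#'   on the same grid.
#' @param genes named `GRanges` of gene spans.
#' @param log2Max tumor log2 must be strictly below this (default
#'   -0.75).
#' @param diffMin normal - tumor must strictly exceed this (default
#'   0.25).
#' @param proximity maximum distance from the gene span in bp (default
#'   40000).
#' @return data.frame per gene: `gene`, `called`, `minLog2` (most
#'   deleted qualifying-region bin), `diff` (normal - tumor at that
#'   bin), `distance` (bp from gene to that bin).
#' @export
callFocalDeletions <- function(tumorBinned, normalBinned, genes,
                               log2Max = -0.75, diffMin = 0.25,
                               proximity = 40000L) {
    same <- length(tumorBinned) == length(normalBinned) &&
        all(GenomicRanges::start(tumorBinned) ==
                GenomicRanges::start(normalBinned)) &&
        all(GenomicRanges::end(tumorBinned) ==
                GenomicRanges::end(normalBinned))
    if (!same) stop("tumor and normal tracks must share the binning grid")
    tv <- S4Vectors::mcols(tumorBinned)$log2
    nv <- S4Vectors::mcols(normalBinned)$log2
    rows <- lapply(names(genes), function(g) {
        d <- GenomicRanges::distance(tumorBinned, genes[g])
        near <- which(!is.na(d) & d <= proximity)
        if (!length(near))
            return(data.frame(gene = g, called = FALSE,
                              minLog2 = NA_real_, diff = NA_real_,
                              distance = NA_real_))
        qual <- near[tv[near] < log2Max & (nv[near] - tv[near]) > diffMin]
        if (length(qual)) {
            i <- qual[which.min(tv[qual])]
            data.frame(gene = g, called = TRUE, minLog2 = tv[i],
                       diff = nv[i] - tv[i], distance = d[i])
        } else {
            i <- near[which.min(tv[near])]
            data.frame(gene = g, called = FALSE, minLog2 = tv[i],
                       diff = nv[i] - tv[i], distance = d[i])
        }
    })
    do.call(rbind, rows)
}

#' Purity-adjusted deletion call for a single gene
#'
#' Tumor purity dilutes the observed log2 ratio roughly linearly at
#' small deviations; the observed value is divided by purity and a
#' deletion is called when the adjusted value falls strictly below
#' `threshold`.  The adjustment rule is configurable because the
#' dilution model is an approximation.
#'
#' @param log2 observed gene-level log2 copy ratio.
#' @param purity tumor purity in (0, 1].
#' @param threshold adjusted-value call threshold (default -0.4).
#' @return list with `adjusted`, `called` and `degenerate` (TRUE when
#'   purity is not in (0, 1]).
#' @export
b2mPurityAdjustedCall <- function(log2, purity, threshold = -0.4) {
    if (is.na(purity) || purity <= 0 || purity > 1)
        return(list(adjusted = NA_real_, called = NA, degenerate = TRUE))
    adj <- log2 / purity
    list(adjusted = adj, called = adj < threshold, degenerate = FALSE)
}
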
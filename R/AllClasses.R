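#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowRanges colData
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
NULL

.EXPR_STAGES <- c("counts", "normalized", "log2", "batch_corrected",
                  "normal_adjusted")

#' Expression matrix with a processing-stage tag
#'
#' A \linkS4class{SummarizedExperiment} carrying a single assay of
#' gene-by-sample expression values together with a tag recording where the
#' matrix sits in the processing chain: raw \code{counts}, library-size
#' \code{normalized} values, \code{log2}-transformed values,
#' \code{batch_corrected} values, and finally \code{normal_adjusted} values
#' with the normal-tissue contamination signature removed.  Stage
#' transitions are only permitted in that order, which prevents, for
#' example, log-transforming twice or batch-correcting raw counts.
#'
#' @slot stage character(1), one of \code{counts}, \code{normalized},
#'   \code{log2}, \code{batch_corrected}, \code{normal_adjusted}.
#'
#' @seealso [StagedExpression()] for construction, [exprStage()] for the
#'   accessor.
#' @export
setClass("StagedExpression",
         contains = "SummarizedExperiment",
         representation(stage = "character"))

setValidity("StagedExpression", function(object) {
    msg <- NULL
    if (length(object@stage) != 1L || !object@stage %in% .EXPR_STAGES)
        msg <- c(msg, sprintf("stage must be one of: %s",
                              paste(.EXPR_STAGES, collapse = ", ")))
    if (length(assays(object)) < 1L)
        msg <- c(msg, "an assay is required")
    else {
        m <- assay(object)
        if (identical(object@stage, "counts")) {
            v <- m[!is.na(m)]
            if (length(v) && (any(v < 0) || any(v != round(v))))
                msg <- c(msg, "counts stage requires nonnegative integers")
        }
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a StagedExpression object
#'
#' @param values numeric matrix, genes in rows, samples in columns; row and
#'   column names are required.
#' @param stage character(1) processing stage tag.
#' @param colData optional `DataFrame` of per-sample annotation.
#' @return A [StagedExpression-class] object.
#' @examples
#' m <- matrix(rpois(20, 50), 4, 5,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
#' se <- StagedExpression(m, "counts")
#' exprStage(se)
#' @export
StagedExpression <- function(values, stage = "counts", colData = NULL) {
    if (is.null(rownames(values)) || is.null(colnames(values)))
        stop("'values' must have row (gene) and column (sample) names")
    if (is.null(colData))
        colData <- DataFrame(row.names = colnames(values))
    se <- SummarizedExperiment(assays = list(exprs = values),
                               colData = colData)
    new("StagedExpression", se, stage = stage)
}

#' Get the processing stage of a StagedExpression
#' @param x a [StagedExpression-class] object.
#' @return character(1) stage tag.
#' @export
exprStage <- function(x) {
    stopifnot(is(x, "StagedExpression"))
    x@stage
}

## Internal: advance the stage tag, enforcing the stated order.
.advanceStage <- function(x, to) {
    from <- match(x@stage, .EXPR_STAGES)
    dest <- match(to, .EXPR_STAGES)
    if (is.na(dest)) stop("unknown stage: ", to)
    if (dest <= from)
        stop(sprintf("illegal stage transition: %s -> %s", x@stage, to))
    x@stage <- to
    validObject(x)
    x
}

setMethod("show", "StagedExpression", function(object) {
    cat(sprintf("StagedExpression [stage: %s] %d genes x %d samples\n",
                object@stage, nrow(object), ncol(object)))
    callNextMethod()
})

#' CpG beta-value matrix with genomic probe annotation
#'
#' A \linkS4class{RangedSummarizedExperiment} holding a probe-by-sample
#' matrix of methylation beta values (fraction methylated, in [0, 1],
#' missing values allowed for masked cells) whose \code{rowRanges} carry
#' the probe annotation: position (width-1 ranges, 0-based input
#' coordinates converted to 1-based `GRanges`), distal enhancer-like
#' signature (dELS) membership, distance to the nearest transcription
#' start site, the nearest/assigned gene, a promoter-CpG-island flag and
#' a general mask flag.
#'
#' @seealso [BetaSet()] for construction.
#' @export
setClass("BetaSet", contains = "RangedSummarizedExperiment")

setValidity("BetaSet", function(object) {
    msg <- NULL
    if (!"beta" %in% names(assays(object)))
        msg <- c(msg, "assay 'beta' is required")
    else {
        b <- assay(object, "beta")
        v <- b[!is.na(b)]
        if (length(v) && (any(v < 0) || any(v > 1)))
            msg <- c(msg, "beta values must lie in [0, 1]")
    }
    need <- c("dELS", "tssDistance", "nearestGene", "promoterIsland",
              "masked")
    miss <- setdiff(need, names(S4Vectors::mcols(rowRanges(object))))
    if (length(miss))
        msg <- c(msg, paste("missing probe annotation column(s):",
                            paste(miss, collapse = ", ")))
    if (is.null(msg)) TRUE else msg
})

#' Construct a BetaSet
#'
#' @param beta numeric matrix of beta values in [0,1] (NA allowed), probes
#'   in rows, samples in columns; dimnames required.
#' @param annotation a `data.frame` or `DataFrame` with one row per probe
#'   (matching `rownames(beta)`) and columns `chrom`, `pos` (0-based
#'   position), `dELS` (logical), `tssDistance`, `nearestGene`,
#'   `promoterIsland` (logical), and optionally `masked` (logical,
#'   defaults to FALSE).
#' @return A [BetaSet-class] object.
#' @export
BetaSet <- function(beta, annotation) {
    annotation <- as.data.frame(annotation)
    if (nrow(annotation) != nrow(beta))
        stop("annotation must have one row per probe")
    if (is.null(annotation$masked)) annotation$masked <- FALSE
    gr <- GRanges(annotation$chrom,
                  IRanges(start = annotation$pos + 1L, width = 1L))
    names(gr) <- rownames(beta)
    S4Vectors::mcols(gr) <- DataFrame(
        dELS = annotation$dELS,
        tssDistance = annotation$tssDistance,
        nearestGene = annotation$nearestGene,
        promoterIsland = annotation$promoterIsland,
        masked = annotation$masked)
    se <- SummarizedExperiment(assays = list(beta = beta), rowRanges = gr)
    new("BetaSet", se)
}

#' Probe annotation of a BetaSet as a GRanges
#' @param x a [BetaSet-class] object.
#' @return `GRanges` with probe annotation columns.
#' @export
probeAnnotation <- function(x) {
    stopifnot(is(x, "BetaSet"))
    rowRanges(x)
}

setMethod("show", "BetaSet", function(object) {
    b <- assay(object, "beta")
    cat(sprintf("BetaSet: %d probes x %d samples (%.1f%% masked/missing)\n",
                nrow(object), ncol(object), 100 * mean(is.na(b))))
    callNextMethod()
})
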
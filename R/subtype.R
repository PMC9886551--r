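.SUBTYPE_ORDER <- c("LumA", "LumB", "HER2E", "Basal", "Normal-like")

#' Infer missing receptor status from an mRNA surrogate
#'
#' Fits a ROC/Youden cutoff for a marker gene (e.g. ESR1 for ER, ERBB2
#' for HER2) on the samples with known clinical status, then assigns
#' `inferred_positive` / `inferred_negative` to samples with missing
#' status by thresholding the marker.  Known statuses are never
#' overwritten.  If one labeled class is absent, inference is disabled
#' and missing statuses remain missing.
#'
#' @param marker named numeric vector of marker expression per sample.
#' @param status named character vector per sample, values `positive`,
#'   `negative` or NA (missing).
#' @return list with `status` (completed vector using
#'   `inferred_positive`/`inferred_negative` for filled values),
#'   `cutoff`, `auc`, and `inferenceDisabled`.
#' @export
inferReceptorStatus <- function(marker, status) {
    stopifnot(length(marker) == length(status))
    known <- !is.na(status)
    if (!any(status[known] == "positive") ||
        !any(status[known] == "negative")) {
        return(list(status = status, cutoff = NA_real_, auc = NA_real_,
                    inferenceDisabled = TRUE))
    }
    yc <- youdenCutoff(marker[known], status[known] == "positive")
    out <- status
    fill <- !known
    out[fill] <- ifelse(marker[fill] >= yc$cutoff,
                        "inferred_positive", "inferred_negative")
    list(status = out, cutoff = yc$cutoff, auc = yc$auc,
         inferenceDisabled = FALSE)
}

#' HER2/ER subgroup-specific gene centering
#'
#' Per gene, subtracts a subgroup-specific centering value determined by
#' each sample's ER/HER2 subgroup.  The default calibration computes
#' each subgroup's gene median from the input cohort itself; an external
#' calibration table (gene-by-subgroup matrix) may be supplied instead.
#' A subgroup with no samples takes its centering values from the
#' calibration table or, failing that, the global gene median (logged).
#'
#' @param x gene-by-sample log2 matrix or [StagedExpression-class].
#' @param subgroup character per sample, e.g. `"ER+/HER2-"`; any
#'   labelling into the four ER/HER2 subgroups works.
#' @param calibration optional gene-by-subgroup matrix of centering
#'   values (0 rows = identity for listed subgroups).
#' @return centered matrix (plain matrix).
#' @export
subgroupCenter <- function(x, subgroup, calibration = NULL) {
    m <- if (is(x, "StagedExpression")) assay(x) else x
    stopifnot(ncol(m) == length(subgroup))
    out <- m
    for (g in unique(subgroup)) {
        sel <- subgroup == g
        ctr <- if (!is.null(calibration) && g %in% colnames(calibration)) {
            calibration[rownames(m), g]
        } else {
            apply(m[, sel, drop = FALSE], 1, stats::median)
        }
        out[, sel] <- m[, sel] - ctr
    }
    out
}

#' Read / write a centroid table
#'
#' Centroid tables are TSV files with gene identifiers in the first
#' column and one column of centroid values per intrinsic subtype.
#'
#' @param path file path.
#' @return `readCentroids`: numeric gene-by-subtype matrix.
#' @export
readCentroids <- function(path) {
    d <- utils::read.delim(path, check.names = FALSE)
    m <- as.matrix(d[, -1, drop = FALSE])
    rownames(m) <- d[[1]]
    m
}

#' @rdname readCentroids
#' @param centroids gene-by-subtype centroid matrix.
#' @export
writeCentroids <- function(centroids, path) {
    d <- data.frame(gene = rownames(centroids), centroids,
                    check.names = FALSE)
    utils::write.table(d, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Row-median centering and column standardization for classification
#'
#' The classification-specific normalization branch: within each
#' preservation group (FF/FFPE) separately, each gene (row) is median
#' centered and each sample (column) is standardized to unit variance.
#'
#' @param x gene-by-sample log2 matrix.
#' @param groups character per sample (e.g. FF/FFPE); a single group
#'   standardizes the whole matrix at once.
#' @return normalized matrix.
#' @export
pam50Normalize <- function(x, groups = rep("all", ncol(x))) {
    out <- x
    for (g in unique(groups)) {
        sel <- groups == g
        sub <- x[, sel, drop = FALSE]
        sub <- sub - apply(sub, 1, stats::median)
        sub <- scale(sub)    # column standardization
        out[, sel] <- sub
    }
    out
}

#' Nearest-centroid intrinsic subtype classification
#'
#' Assigns each sample the subtype of the centroid with maximal
#' correlation (Spearman by default) over the classifier genes.  All
#' five correlations are reported; the confidence is the margin between
#' the best and second-best correlation.  Ties are broken by the fixed
#' subtype order LumA, LumB, HER2E, Basal, Normal-like and flagged;
#' constant sample vectors receive no call.  Classification aborts with
#' a coverage report when fewer than `minGenes` centroid genes are
#' present in the data.
#'
#' @param x gene-by-sample matrix of (centered) expression values.
#' @param centroids gene-by-subtype centroid matrix.
#' @param method correlation method, `"spearman"` (default) or
#'   `"pearson"`.
#' @param minGenes minimum number of centroid genes that must be present.
#' @return data.frame with `call`, one correlation column per subtype,
#'   `confidence` and `tie`/`noCall` flags; row names are samples.
#' @export
pam50Classify <- function(x, centroids, method = c("spearman", "pearson"),
                          minGenes = 40L) {
    method <- match.arg(method)
    if (anyDuplicated(rownames(centroids)))
        stop("duplicate genes in the centroid set")
    common <- intersect(rownames(centroids), rownames(x))
    if (length(common) < minGenes)
        stop(sprintf(
            "centroid coverage too low: %d of %d genes present (need >= %d)",
            length(common), nrow(centroids), minGenes))
    subtypes <- colnames(centroids)
    cors <- suppressWarnings(
        stats::cor(x[common, , drop = FALSE],
                   centroids[common, , drop = FALSE], method = method))
    ord <- intersect(.SUBTYPE_ORDER, subtypes)
    cors <- cors[, c(ord, setdiff(subtypes, ord)), drop = FALSE]
    res <- data.frame(row.names = colnames(x))
    res$call <- NA_character_
    res$tie <- FALSE
    res$noCall <- FALSE
    for (i in seq_len(ncol(x))) {
        r <- cors[i, ]
        if (all(is.na(r))) { res$noCall[i] <- TRUE; next }
        best <- max(r, na.rm = TRUE)
        hits <- which(r == best)
        res$call[i] <- colnames(cors)[hits[1L]]  # fixed-order tie-break
        res$tie[i] <- length(hits) > 1L
    }
    conf <- apply(cors, 1, function(r) {
        r <- sort(r, decreasing = TRUE)
        if (length(r) < 2L || is.na(r[1])) NA_real_ else r[1] - r[2]
    })
    cbind(res, as.data.frame(cors), confidence = conf)
}

#' Tabulate subtype switching between paired primaries and metastases
#'
#' A participant counts as switched when ANY of their metastases is
#' called a different subtype than the primary.  A second count ignores
#' transitions into or out of the Normal-like group (which typically
#' reflects low tumor cellularity rather than biology).  Pairs with an
#' uncalled member are excluded and reported.
#'
#' @param calls named character vector of subtype calls per sample (NA =
#'   no call).
#' @param pairs data.frame with columns `participant`, `primary` (sample
#'   name) and `metastasis`; multiple rows per participant for multiple
#'   metastases.
#' @return list with `nPairs`, `nSwitched`,
#'   `nSwitchedExcludingNormal`, `transitions` (per-participant
#'   data.frame) and `excluded`.
#' @export
subtypeSwitchTable <- function(calls, pairs) {
    byPart <- split(pairs, pairs$participant)
    rows <- lapply(byPart, function(d) {
        prim <- unique(d$primary)
        stopifnot(length(prim) == 1L)
        pc <- calls[[prim]]
        mc <- unname(calls[d$metastasis])
        if (is.null(pc) || is.na(pc) || any(is.na(mc)))
            return(data.frame(participant = d$participant[1],
                              primaryCall = NA, metCalls = NA,
                              switched = NA, switchedExclNormal = NA))
        sw <- any(mc != pc)
        nonNormal <- mc[mc != "Normal-like"]
        swEx <- if (pc == "Normal-like") FALSE else any(nonNormal != pc)
        data.frame(participant = d$participant[1], primaryCall = pc,
                   metCalls = paste(mc, collapse = ","),
                   switched = sw, switchedExclNormal = swEx)
    })
    tr <- do.call(rbind, rows)
    ok <- !is.na(tr$switched)
    list(nPairs = sum(ok),
         nSwitched = sum(tr$switched[ok]),
         nSwitchedExcludingNormal = sum(tr$switchedExclNormal[ok]),
         transitions = tr[ok, , drop = FALSE],
         excluded = tr$participant[!ok])
}
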
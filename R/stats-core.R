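#' Two-sided Fisher exact test for a 2x2 table
#'
#' Two-sided p-value under the minimum-likelihood convention: with all
#' margins fixed, the p-value sums the hypergeometric probabilities of
#' every table whose point probability does not exceed that of the
#' observed table (the convention used by `stats::fisher.test`).
#'
#' @param table 2x2 matrix of nonnegative integer counts (rows =
#'   condition, columns = status), or a length-4 vector `c(a, b, c, d)`
#'   filled by row.
#' @return A list with `p` (the two-sided p-value) and `degenerate`
#'   (TRUE when a margin is zero, in which case `p = 1` by convention:
#'   the table carries no information about association).
#' @examples
#' fisherExactTwoSided(matrix(c(26, 13, 13, 26), 2, byrow = TRUE))$p
#' @export
fisherExactTwoSided <- function(table) {
    if (!is.matrix(table)) {
        stopifnot(length(table) == 4L)
        table <- matrix(table, 2L, 2L, byrow = TRUE)
    }
    stopifnot(dim(table) == c(2L, 2L))
    if (any(is.na(table)) || any(table < 0) || any(table != round(table)))
        stop("table entries must be nonnegative integers")
    if (any(rowSums(table) == 0) || any(colSums(table) == 0))
        return(list(p = 1, degenerate = TRUE))
    list(p = stats::fisher.test(table)$p.value, degenerate = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up false-discovery-rate adjustment with enforced monotonicity.
#' Missing values propagate as missing and are excluded from the number
#' of tests, so they never corrupt their neighbours' q-values.
#'
#' @param p numeric vector of p-values in [0, 1] (NA/NaN allowed).
#' @return numeric vector of q-values, same length and order as `p`.
#' @export
benjaminiHochberg <- function(p) {
    q <- rep(NA_real_, length(p))
    ok <- !is.na(p)
    if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
    q[ok] <- stats::p.adjust(p[ok], method = "BH")
    q
}

#' Welch's two-sided two-sample t-test
#'
#' Unequal-variance t-test with Welch-Satterthwaite degrees of freedom.
#'
#' @param x,y numeric samples, each of length >= 2.
#' @return list with `statistic`, `df`, `p` and `degenerate` (TRUE when
#'   both groups have zero variance, in which case `p` is NA).
#' @export
welchTTest <- function(x, y) {
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2L || length(y) < 2L)
        stop("each group needs at least two observations")
    if (stats::sd(x) == 0 && stats::sd(y) == 0)
        return(list(statistic = NA_real_, df = NA_real_, p = NA_real_,
                    degenerate = TRUE))
    tt <- stats::t.test(x, y, var.equal = FALSE)
    list(statistic = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, degenerate = FALSE)
}

#' Paired-design linear mixed model with purity covariate
#'
#' Fits `response ~ group + purity + (1 | participant)` by REML and
#' returns the metastasis-versus-primary coefficient with its standard
#' error, Satterthwaite degrees of freedom and p-value.  This is the
#' probe-/signature-level workhorse for every paired primary-metastasis
#' screen in the package.  When the random-intercept variance collapses
#' to zero (singular fit) the model degrades to an ordinary linear model
#' of the fixed part, and the result is flagged; a constant response is
#' flagged as degenerate with a zero estimate.
#'
#' @param response numeric per-sample response (missing values dropped).
#' @param group factor or character, coded `primary` / `metastasis`
#'   (anything not `"primary"` counts as metastasis).
#' @param participant factor or character participant identifier.
#' @param purity optional numeric tumor purity per sample; ignored when
#'   constant (it would be collinear with the intercept).
#' @return list with `estimate`, `se`, `df`, `p`, `converged`,
#'   `degenerate` and `method` (`"lmm"` or `"lm"`).
#' @export
lmmPaired <- function(response, group, participant, purity = NULL) {
    grp <- factor(ifelse(as.character(group) == "primary",
                         "primary", "metastasis"),
                  levels = c("primary", "metastasis"))
    dat <- data.frame(y = response, grp = grp,
                      participant = factor(participant))
    usePurity <- !is.null(purity)
    if (usePurity) {
        dat$purity <- purity
        if (anyNA(dat$purity)) stop("missing purity values are not allowed")
        if (stats::sd(dat$purity) == 0) usePurity <- FALSE
    }
    dat <- dat[!is.na(dat$y), , drop = FALSE]
    both <- table(dat$participant, dat$grp)
    if (sum(rowSums(both > 0) == 2L) < 2L)
        stop("need >= 2 participants contributing both groups")
    bad <- list(estimate = 0, se = NA_real_, df = NA_real_, p = NA_real_,
                converged = FALSE, degenerate = TRUE, method = "none")
    if (stats::sd(dat$y) == 0) return(bad)
    fml <- if (usePurity) y ~ grp + purity + (1 | participant)
           else y ~ grp + (1 | participant)
    fit <- tryCatch(
        suppressMessages(suppressWarnings(
            lmerTest::lmer(fml, data = dat, REML = TRUE))),
        error = function(e) NULL)
    if (!is.null(fit) && !lme4::isSingular(fit, tol = 1e-5)) {
        co <- stats::coef(summary(fit))
        row <- co["grpmetastasis", ]
        return(list(estimate = unname(row["Estimate"]),
                    se = unname(row["Std. Error"]),
                    df = unname(row["df"]),
                    p = unname(row["Pr(>|t|)"]),
                    converged = TRUE, degenerate = FALSE, method = "lmm"))
    }
    ## degenerate path: zero (or inestimable) random variance -> plain LM
    lfml <- if (usePurity) y ~ grp + purity else y ~ grp
    lfit <- stats::lm(lfml, data = dat)
    co <- stats::coef(summary(lfit))
    if (!"grpmetastasis" %in% rownames(co)) return(bad)
    row <- co["grpmetastasis", ]
    list(estimate = unname(row["Estimate"]), se = unname(row["Std. Error"]),
         df = lfit$df.residual, p = unname(row["Pr(>|t|)"]),
         converged = TRUE, degenerate = TRUE, method = "lm")
}

#' ROC analysis with the Youden cutoff
#'
#' Candidate cutoffs are the midpoints between consecutive sorted unique
#' marker values; a sample is predicted positive when its marker value is
#' at or above the cutoff (higher marker = positive class).  The returned
#' cutoff maximizes Youden's J = sensitivity + specificity - 1; ties are
#' broken toward the smaller cutoff for determinism.  The AUC is the
#' trapezoid area under the empirical ROC curve (equivalently the
#' normalized Mann-Whitney statistic).
#'
#' @param marker numeric per-sample marker values.
#' @param labels logical (or 0/1) per-sample class labels, TRUE =
#'   positive.
#' @return list with `cutoff`, `auc` and `J` (the maximal Youden index).
#' @export
youdenCutoff <- function(marker, labels) {
    labels <- as.logical(labels)
    keep <- !is.na(marker) & !is.na(labels)
    marker <- marker[keep]; labels <- labels[keep]
    if (!any(labels) || all(labels))
        stop("both label classes must be present")
    pos <- marker[labels]; neg <- marker[!labels]
    u <- sort(unique(marker))
    if (length(u) < 2L) stop("marker is constant")
    cand <- (u[-1L] + u[-length(u)]) / 2
    J <- vapply(cand, function(ct) {
        mean(pos >= ct) + mean(neg < ct) - 1
    }, numeric(1))
    best <- which.max(J)   # which.max returns the first (smallest) maximum
    r <- rank(c(pos, neg))
    auc <- (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
        (length(pos) * length(neg))
    list(cutoff = cand[best], auc = auc, J = J[best])
}
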
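## Shared small synthetic cohort, built once per test run.
smallCohort <- local({
    cache <- NULL
    function() {
        if (is.null(cache))
            cache <<- simulateCohort(syntheticConfig(
                nParticipants = 8, nGenes = 500, nProbes = 400,
                nVariants = 120, nCnBins = 600, seed = 42))
        cache
    }
})

## Independent Fisher oracle: enumerate all tables with the observed
## margins, point probabilities by binomial coefficients, and sum those
## not exceeding the observed table's probability.
enumFisherP <- function(tab) {
    r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
    n <- sum(tab)
    ks <- max(0, c1 - r2):min(r1, c1)
    pr <- choose(r1, ks) * choose(r2, c1 - ks) / choose(n, c1)
    obs <- choose(r1, tab[1, 1]) * choose(r2, tab[2, 1]) / choose(n, c1)
    sum(pr[pr <= obs * (1 + 1e-7)])
}

## One primary + one metastasis per participant, as a pairs data.frame.
cohortPairs <- function(cohort) {
    s <- cohort$samples
    do.call(rbind, lapply(split(s, s$participant), function(d)
        data.frame(participant = d$participant[1],
                   primary = d$sample[d$type == "primary"][1],
                   metastasis = d$sample[d$type == "metastasis"])))
}
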
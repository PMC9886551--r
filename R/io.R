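#' Write a synthetic cohort to plain-text files
#'
#' Serializes every component of a [simulateCohort()] result into
#' standard text formats under `dir`: sample sheet, counts and beta
#' matrices and the normal methylation panel as TSV; probe annotation
#' as a BED-like TSV (0-based, half-open); variants as a VCF with the
#' read-level evidence in INFO fields plus a sidecar evidence TSV;
#' copy-ratio tracks and gene-level log2 values as TSV; segment
#' definitions as TSV; and the planted truth labels as JSON.  Output is
#' byte-identical for identical cohorts, so a fixed seed round-trips to
#' identical files.
#'
#' @param cohort list from [simulateCohort()].
#' @param dir output directory (created if absent).
#' @return invisibly, the named vector of written file paths.
#' @export
writeCohort <- function(cohort, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(dir, f)
    wtsv <- function(d, f, rn = FALSE)
        utils::write.table(d, p(f), sep = "\t", quote = FALSE,
                           row.names = rn, col.names = TRUE)
    wtsv(cohort$samples, "samples.tsv")
    wtsv(as.data.frame(assay(cohort$expression)), "counts.tsv", rn = TRUE)
    wtsv(as.data.frame(assay(cohort$beta, "beta")), "beta.tsv", rn = TRUE)
    wtsv(as.data.frame(cohort$normalPanel), "normal_panel.tsv", rn = TRUE)
    ann <- probeAnnotation(cohort$beta)
    bed <- data.frame(chrom = as.character(GenomicRanges::seqnames(ann)),
                      start = GenomicRanges::start(ann) - 1L,
                      end = GenomicRanges::end(ann),
                      name = names(ann),
                      dELS = S4Vectors::mcols(ann)$dELS,
                      tssDistance = S4Vectors::mcols(ann)$tssDistance,
                      nearestGene = S4Vectors::mcols(ann)$nearestGene,
                      promoterIsland = S4Vectors::mcols(ann)$promoterIsland)
    wtsv(bed, "probes.bed.tsv")
    writeVariantEvidence(cohort$variants, p("variants.vcf"),
                         p("evidence.tsv"))
    tracks <- do.call(rbind, lapply(names(cohort$copyRatios), function(s) {
        do.call(rbind, lapply(c("tumor", "normal"), function(w) {
            gr <- cohort$copyRatios[[s]][[w]]
            data.frame(sample = s, track = w,
                       chrom = as.character(GenomicRanges::seqnames(gr)),
                       start = GenomicRanges::start(gr) - 1L,
                       end = GenomicRanges::end(gr),
                       log2 = S4Vectors::mcols(gr)$log2)
        }))
    }))
    wtsv(tracks, "copy_ratios.tsv")
    wtsv(as.data.frame(cohort$geneLog2), "gene_log2.tsv", rn = TRUE)
    wtsv(data.frame(segment = rep(names(cohort$segments),
                                  lengths(cohort$segments)),
                    gene = unlist(cohort$segments, use.names = FALSE)),
         "segments.tsv")
    truthOut <- cohort$truth[c("subtype", "erTruth", "her2Truth",
                               "probeStatus", "probeDelta",
                               "preservationBiasedProbes",
                               "hlaMethylatedSamples", "variantStatus",
                               "artifactMode", "focalDeletionSamples")]
    jsonlite::write_json(truthOut, p("truth.json"), auto_unbox = FALSE,
                         digits = NA, na = "null")
    invisible(vapply(list.files(dir, full.names = TRUE), identity, ""))
}

#' Write variant records with read evidence as VCF plus sidecar TSV
#'
#' The VCF carries one record per somatic call with INFO fields for the
#' sample, gene, classification, allele frequency and window mismatch
#' counts; the soft-trimmed supporting-read coordinates go both into
#' comma-list INFO fields (`RS`, `RE`) and a sidecar TSV keyed by
#' variant id.
#'
#' @param variants variant `DataFrame` (see [simulateReadEvidence()]).
#' @param vcfPath,evidencePath output file paths (`evidencePath = NULL`
#'   skips the sidecar).
#' @return invisibly, `vcfPath`.
#' @export
writeVariantEvidence <- function(variants, vcfPath, evidencePath = NULL) {
    hdr <- c("##fileformat=VCFv4.2",
             "##source=metapair",
             "##contig=<ID=chr17>",
             "##INFO=<ID=SMP,Number=1,Type=String,Description=\"Sample id\">",
             "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
             "##INFO=<ID=CLS,Number=1,Type=String,Description=\"Variant classification\">",
             "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Variant allele frequency\">",
             "##INFO=<ID=MM,Number=1,Type=Integer,Description=\"Window mismatch bases\">",
             "##INFO=<ID=TB,Number=1,Type=Integer,Description=\"Window total aligned bases\">",
             "##INFO=<ID=RS,Number=.,Type=Integer,Description=\"Soft-trimmed supporting read starts\">",
             "##INFO=<ID=RE,Number=.,Type=Integer,Description=\"Soft-trimmed supporting read ends\">",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    info <- vapply(seq_len(nrow(variants)), function(i) sprintf(
        "SMP=%s;GENE=%s;CLS=%s;VAF=%.6g;MM=%d;TB=%d;RS=%s;RE=%s",
        variants$sample[i], variants$gene[i],
        gsub("[;=, ]", "_", variants$classification[i]),
        variants$vaf[i], variants$windowMismatch[i],
        variants$windowTotal[i],
        paste(variants$readStarts[[i]], collapse = ","),
        paste(variants$readEnds[[i]], collapse = ",")), "")
    rec <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t%s",
                   variants$chrom, variants$pos, variants$variantId,
                   variants$ref, variants$alt, info)
    writeLines(c(hdr, rec), vcfPath)
    if (!is.null(evidencePath)) {
        ev <- data.frame(
            variantId = variants$variantId,
            readStarts = vapply(variants$readStarts, paste, "",
                                collapse = ","),
            readEnds = vapply(variants$readEnds, paste, "",
                              collapse = ","),
            windowMismatch = variants$windowMismatch,
            windowTotal = variants$windowTotal)
        utils::write.table(ev, evidencePath, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    invisible(vcfPath)
}

#' Read variant records with read evidence from VCF
#'
#' Parses a VCF written by [writeVariantEvidence()] (or any VCF whose
#' INFO fields follow the same keys) back into the variant `DataFrame`
#' used by [applyFfpeFilters()].
#'
#' @param vcfPath VCF file path.
#' @return a `DataFrame` with the variant columns and `readStarts` /
#'   `readEnds` list columns.
#' @export
readVariantEvidence <- function(vcfPath) {
    vcf <- VariantAnnotation::readVcf(vcfPath)
    rr <- SummarizedExperiment::rowRanges(vcf)
    info <- VariantAnnotation::info(vcf)
    out <- DataFrame(
        variantId = names(rr),
        chrom = as.character(GenomicRanges::seqnames(rr)),
        pos = GenomicRanges::start(rr),
        ref = as.character(rr$REF),
        alt = vapply(rr$ALT, function(a) as.character(a)[1], ""),
        vaf = as.numeric(info$VAF),
        sample = as.character(info$SMP),
        gene = as.character(info$GENE),
        classification = as.character(info$CLS),
        windowMismatch = as.integer(info$MM),
        windowTotal = as.integer(info$TB))
    out$readStarts <- as.list(info$RS)
    out$readEnds <- as.list(info$RE)
    rownames(out) <- NULL
    out
}

#' Read / write a gene-signature library in GMT format
#'
#' GMT: one set per line, tab-separated as
#' `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path file path.
#' @return `readSignatureLibrary`: named list of gene vectors, with the
#'   descriptions in the `descriptions` attribute.
#' @export
readSignatureLibrary <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- lengths(parts) < 3L
    if (any(bad))
        stop("malformed GMT line(s): a set needs a name, a description ",
             "and at least one gene")
    sets <- lapply(parts, function(p) p[-(1:2)])
    names(sets) <- vapply(parts, `[[`, "", 1L)
    attr(sets, "descriptions") <- stats::setNames(
        vapply(parts, `[[`, "", 2L), names(sets))
    sets
}

#' @rdname readSignatureLibrary
#' @param sets named list of gene vectors.
#' @param descriptions optional per-set description strings.
#' @export
writeSignatureLibrary <- function(sets, path, descriptions = NULL) {
    if (is.null(descriptions))
        descriptions <- rep("na", length(sets))
    writeLines(vapply(seq_along(sets), function(i)
        paste(c(names(sets)[i], descriptions[i], sets[[i]]),
              collapse = "\t"), ""), path)
    invisible(path)
}
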
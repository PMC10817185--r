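#' Read heterozygous biallelic SNPs for one sample from a VCF
#'
#' Applies the divergence-analysis variant filters: any record whose
#' FILTER field contains the `RefCall` label (as a whole, case-sensitive
#' token in the semicolon-separated list) is dropped, and only biallelic
#' single-nucleotide substitutions with a heterozygous genotype for
#' `sampleId` are retained.
#'
#' @param path path to a VCF file.
#' @param sampleId sample to extract; must be present in the VCF.
#' @return `GRanges` of SNP positions (width 1) with metadata columns
#'   `ref` and `alt`; `metadata()$sampleId` records the sample.
#' @seealso [snpDensity()], [regionSummary()]
#' @export
readHetSnps <- function(path, sampleId) {
    vcf <- VariantAnnotation::readVcf(path)
    if (!sampleId %in% colnames(vcf))
        stop("sample '", sampleId, "' not present in ", path, call. = FALSE)

    filt <- VariantAnnotation::filt(vcf)
    filt[is.na(filt)] <- "."
    refcall <- vapply(strsplit(filt, ";", fixed = TRUE),
                      function(f) "RefCall" %in% f, logical(1))

    ref <- as.character(VariantAnnotation::ref(vcf))
    altList <- VariantAnnotation::alt(vcf)
    nAlt <- S4Vectors::elementNROWS(altList)
    alt <- rep(NA_character_, length(vcf))
    alt[nAlt == 1L] <- as.character(unlist(altList[nAlt == 1L]))

    gt <- VariantAnnotation::geno(vcf)$GT[, sampleId]
    het <- gt %in% c("0/1", "1/0", "0|1", "1|0")

    keep <- !refcall & nAlt == 1L & het &
        nchar(ref) == 1L & !is.na(alt) & nchar(alt) == 1L &
        ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")

    gr <- granges(SummarizedExperiment::rowRanges(vcf))[keep]
    mcols(gr) <- S4Vectors::DataFrame(ref = ref[keep], alt = alt[keep])
    names(gr) <- NULL
    metadata(gr)$sampleId <- sampleId
    gr
}

#' Write a heterozygous SNP table as a minimal VCF
#'
#' Emits a deterministic VCFv4.2 file (no timestamps) with a single
#' sample carrying `0/1` genotypes, suitable for re-reading with
#' [readHetSnps()]. Used by the synthetic-data generator and for
#' round-trip testing.
#'
#' @param snps `GRanges` with `ref`/`alt` metadata columns, as returned by
#'   [readHetSnps()] or [simulateSnps()].
#' @param path output path.
#' @param sampleId sample name for the genotype column; defaults to the
#'   `metadata()$sampleId` of `snps`.
#' @param chromLengths optional named vector of chromosome lengths for
#'   `##contig` header lines (taken from `seqlengths(snps)` when set).
#' @return `path`, invisibly.
#' @export
writeHetSnpsVcf <- function(snps, path, sampleId = NULL,
                            chromLengths = NULL) {
    if (is.null(sampleId)) sampleId <- metadata(snps)$sampleId
    if (is.null(sampleId)) sampleId <- "sample1"
    if (is.null(chromLengths)) {
        sl <- seqlengths(snps)
        if (length(sl) && !any(is.na(sl))) chromLengths <- sl
    }
    hdr <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
    if (!is.null(chromLengths))
        hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                              names(chromLengths),
                              as.integer(chromLengths)))
    hdr <- c(hdr, paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
                         "\tFORMAT\t", sampleId))
    ord <- order(as.character(seqnames(snps)), start(snps))
    snps <- snps[ord]
    body <- sprintf("%s\t%d\t.\t%s\t%s\t30\tPASS\t.\tGT\t0/1",
                    as.character(seqnames(snps)), start(snps),
                    snps$ref, snps$alt)
    writeLines(c(hdr, body), path)
    invisible(path)
}
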
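#' Construct a HaplotypePanel from components
#'
#' @param haplotypes integer matrix of 0/1 alleles, sites x haplotypes
#'   (allele 1 = ALT). Row count must equal \code{length(pos)}.
#' @param chrom single chromosome name.
#' @param pos 1-based positions, strictly increasing.
#' @param ids variant identifiers (e.g. rsids), unique.
#' @param ref,alt single-base reference / alternate alleles.
#' @param population free-text population label (default "EUR").
#'
#' @return a [HaplotypePanel-class].
#' @examples
#' m <- cbind(c(1L, 1L), c(1L, 0L), c(0L, 1L), c(0L, 0L))
#' HaplotypePanel(m, "chr1", c(100L, 200L), c("rsA", "rsB"),
#'                ref = c("A", "C"), alt = c("G", "T"))
#' @export
HaplotypePanel <- function(haplotypes, chrom, pos, ids, ref, alt,
                           population = "EUR") {
    haplotypes <- matrix(as.integer(haplotypes), nrow = nrow(haplotypes),
                         dimnames = list(ids, colnames(haplotypes)))
    rr <- GRanges(chrom, IRanges(start = as.integer(pos), width = 1L))
    names(rr) <- ids
    mcols(rr)$ref <- as.character(ref)
    mcols(rr)$alt <- as.character(alt)
    se <- SummarizedExperiment(assays = list(haplotypes = haplotypes),
                               rowRanges = rr)
    obj <- new("HaplotypePanel", se)
    metadata(obj)$population <- population
    obj
}

#' @rdname HaplotypePanel-class
#' @export
setMethod("hapMatrix", "HaplotypePanel",
          function(x) SummarizedExperiment::assay(x, "haplotypes"))

#' @rdname HaplotypePanel-class
#' @export
setMethod("variantIds", "HaplotypePanel", function(x) rownames(x))

#' @rdname HaplotypePanel-class
#' @export
setMethod("refAllele", "HaplotypePanel",
          function(x) stats::setNames(mcols(rowRanges(x))$ref, rownames(x)))

#' @rdname HaplotypePanel-class
#' @export
setMethod("altAllele", "HaplotypePanel",
          function(x) stats::setNames(mcols(rowRanges(x))$alt, rownames(x)))

#' @rdname HaplotypePanel-class
#' @export
setMethod("nHaplotypes", "HaplotypePanel", function(x) ncol(x))

#' @rdname HaplotypePanel-class
#' @export
setMethod("populationLabel", "HaplotypePanel",
          function(x) metadata(x)$population)

setMethod("show", "HaplotypePanel", function(object) {
    cat(sprintf("HaplotypePanel: %d sites x %d haplotypes (%s, %s)\n",
                nrow(object), ncol(object),
                if (nrow(object)) as.character(seqnames(rowRanges(object)))[1L]
                else "no chrom",
                populationLabel(object) %||% "unlabelled"))
    if (nrow(object)) {
        p <- range(start(rowRanges(object)))
        cat(sprintf("  positions %d..%d\n", p[1L], p[2L]))
    }
})

`%||%` <- function(a, b) if (is.null(a)) b else a

.hapAlleles <- function(panel, rsid) {
    if (!rsid %in% rownames(panel))
        stop(sprintf("variant '%s' is not in the panel", rsid), call. = FALSE)
    hapMatrix(panel)[rsid, ]
}

#' Load a phased haplotype window around an index SNP from VCF
#'
#' Reads a VCF, restricts to a window centered on the index SNP, keeps
#' phased biallelic SNVs and returns a [HaplotypePanel-class]. Multiallelic
#' and non-SNV records are skipped (counts reported via \code{message}).
#' Sites carrying any unphased or missing genotype among retained samples
#' are handled by \code{missingPolicy}: \code{"site"} (default) drops the
#' site, \code{"sample"} drops the offending samples panel-wide. The window
#' is clamped at position 1 at the chromosome start.
#'
#' @param vcf path to a VCF (plain or bgzipped).
#' @param indexRsid id of the index SNP; must be present in the VCF.
#' @param windowBp total window size in bp; the panel spans
#'   \code{[pos - windowBp/2, pos + windowBp/2]}. Default 1 Mb.
#' @param samples optional character vector of sample ids to retain.
#' @param missingPolicy \code{"site"} or \code{"sample"}.
#' @param population label stored on the panel.
#'
#' @return a [HaplotypePanel-class] containing the index SNP.
#' @export
loadPhasedWindow <- function(vcf, indexRsid, windowBp = 1e6, samples = NULL,
                             missingPolicy = c("site", "sample"),
                             population = "EUR") {
    missingPolicy <- match.arg(missingPolicy)
    v <- VariantAnnotation::readVcf(vcf)
    rr <- SummarizedExperiment::rowRanges(v)
    ids <- names(rr)
    if (!indexRsid %in% ids)
        stop(sprintf("index SNP '%s' absent from VCF '%s'", indexRsid, vcf),
             call. = FALSE)
    ipos <- start(rr[indexRsid])
    ichrom <- as.character(seqnames(rr[indexRsid]))
    lo <- max(1, ipos - windowBp / 2)
    hi <- ipos + windowBp / 2
    keep <- as.character(seqnames(rr)) == ichrom &
        start(rr) >= lo & start(rr) <= hi
    # biallelic SNVs only
    refc <- as.character(VariantAnnotation::ref(v))
    altl <- VariantAnnotation::alt(v)
    nalt <- S4Vectors::elementNROWS(altl)
    alt1 <- rep(NA_character_, length(rr))
    alt1[nalt == 1L] <- as.character(unlist(altl[nalt == 1L]))
    snv <- nalt == 1L & nchar(refc) == 1L & !is.na(alt1) & nchar(alt1) == 1L &
        refc %in% c("A", "C", "G", "T") & alt1 %in% c("A", "C", "G", "T")
    nskip <- sum(keep & !snv)
    if (nskip)
        message(sprintf("loadPhasedWindow: skipped %d multiallelic/non-SNV record(s)",
                        nskip))
    keep <- keep & snv
    gt <- VariantAnnotation::geno(v)$GT
    if (!is.null(samples)) {
        missing <- setdiff(samples, colnames(gt))
        if (length(missing))
            stop(sprintf("sample(s) not in VCF: %s",
                         paste(missing, collapse = ", ")), call. = FALSE)
        gt <- gt[, samples, drop = FALSE]
    }
    if (ncol(gt) == 0L)
        stop("zero phased samples retained", call. = FALSE)
    gt <- gt[keep, , drop = FALSE]
    rr <- rr[keep]
    phased_ok <- matrix(grepl("^[01]\\|[01]$", gt), nrow = nrow(gt))
    if (missingPolicy == "sample") {
        bad <- colSums(!phased_ok) > 0L
        if (all(bad))
            stop("zero phased samples retained after dropping samples with unphased/missing genotypes",
                 call. = FALSE)
        if (any(bad))
            message(sprintf("loadPhasedWindow: dropped %d sample(s) with unphased/missing genotypes",
                            sum(bad)))
        gt <- gt[, !bad, drop = FALSE]
        phased_ok <- phased_ok[, !bad, drop = FALSE]
    }
    site_ok <- rowSums(!phased_ok) == 0L
    if (any(!site_ok))
        message(sprintf("loadPhasedWindow: dropped %d site(s) with unphased/missing genotypes",
                        sum(!site_ok)))
    gt <- gt[site_ok, , drop = FALSE]
    rr <- rr[site_ok]
    if (!indexRsid %in% names(rr))
        stop(sprintf("index SNP '%s' was removed by filtering", indexRsid),
             call. = FALSE)
    a1 <- substr(gt, 1L, 1L)
    a2 <- substr(gt, 3L, 3L)
    m <- matrix(0L, nrow = nrow(gt), ncol = 2L * ncol(gt))
    m[, seq(1L, ncol(m), by = 2L)] <- as.integer(a1)
    m[, seq(2L, ncol(m), by = 2L)] <- as.integer(a2)
    colnames(m) <- paste0(rep(colnames(gt), each = 2L), c("_h1", "_h2"))
    o <- order(start(rr))
    refc <- as.character(VariantAnnotation::ref(v))[keep][site_ok]
    altc <- alt1[keep][site_ok]
    HaplotypePanel(m[o, , drop = FALSE], ichrom, start(rr)[o],
                   names(rr)[o], refc[o], altc[o], population = population)
}
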
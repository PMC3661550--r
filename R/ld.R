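## Pairwise linkage disequilibrium by direct haplotype counting over phased
## panels, LD stratification, and multi-locus haplotype frequencies.

.ldStats <- function(x, y) {
    pA <- mean(x)
    pB <- mean(y)
    if (pA == 0 || pA == 1 || pB == 0 || pB == 1)
        stop("monomorphic site: r-squared denominator undefined", call. = FALSE)
    pAB <- mean(x == 1L & y == 1L)
    D <- pAB - pA * pB
    r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
    if (D > 0) {
        dmax <- min(pA * (1 - pB), (1 - pA) * pB)
        dprime <- D / dmax
    } else if (D < 0) {
        dmax <- min(pA * pB, (1 - pA) * (1 - pB))
        dprime <- -D / dmax
    } else {
        dprime <- 0
    }
    list(r2 = r2, D = D, Dprime = dprime)
}

#' Two-locus LD statistics from a phased panel
#'
#' Computes r-squared, the coefficient of linkage disequilibrium D, and
#' normalized D-prime for two sites by direct counting over the 2n
#' haplotypes: with haplotype frequency \eqn{p_{AB}} and allele frequencies
#' \eqn{p_A, p_B} of the ALT alleles, \eqn{D = p_{AB} - p_A p_B},
#' \eqn{r^2 = D^2 / (p_A(1-p_A)p_B(1-p_B))}, and \eqn{D' = |D| / D_{max}}
#' where \eqn{D_{max} = \min(p_A(1-p_B), (1-p_A)p_B)} for \eqn{D>0} and
#' \eqn{\min(p_A p_B, (1-p_A)(1-p_B))} for \eqn{D<0}.
#'
#' @param panel a [HaplotypePanel-class].
#' @param a,b variant ids in the panel; both sites must be polymorphic.
#'
#' @return list with elements \code{r2}, \code{D}, \code{Dprime}.
#' @examples
#' # 8 haplotypes: AB,AB,AB,Ab,aB,ab,ab,ab -> r2 = 0.25
#' m <- rbind(c(1,1,1,1,0,0,0,0), c(1,1,1,0,1,0,0,0))
#' p <- HaplotypePanel(m, "chr1", c(10L, 20L), c("a", "b"),
#'                     ref = c("A", "A"), alt = c("G", "G"))
#' twoLocusR2(p, "a", "b")$r2
#' @export
twoLocusR2 <- function(panel, a, b) {
    .ldStats(.hapAlleles(panel, a), .hapAlleles(panel, b))
}

#' Scan all panel sites for LD with an index SNP
#'
#' One record per other polymorphic site in the panel; monomorphic sites
#' are skipped with a reported count. Records are sorted by decreasing
#' r-squared, then by absolute distance.
#'
#' @param panel a [HaplotypePanel-class].
#' @param indexRsid id of the index SNP (must be in the panel).
#'
#' @return \code{DataFrame} with columns \code{index_rsid}, \code{corr_rsid},
#'   \code{chrom}, \code{pos}, \code{r2}, \code{D}, \code{Dprime},
#'   \code{distance_bp} (signed, correlated minus index), \code{maf_index},
#'   \code{maf_corr}.
#' @export
ldScan <- function(panel, indexRsid) {
    x <- .hapAlleles(panel, indexRsid)
    ids <- setdiff(variantIds(panel), indexRsid)
    pos <- stats::setNames(start(rowRanges(panel)), variantIds(panel))
    chrom <- if (nrow(panel)) as.character(seqnames(rowRanges(panel)))[1L]
             else NA_character_
    m <- hapMatrix(panel)
    pIdx <- mean(x)
    rows <- vector("list", length(ids))
    nskip <- 0L
    for (i in seq_along(ids)) {
        y <- m[ids[i], ]
        st <- tryCatch(.ldStats(x, y), error = function(e) NULL)
        if (is.null(st)) {
            nskip <- nskip + 1L
            next
        }
        rows[[i]] <- data.frame(
            index_rsid = indexRsid, corr_rsid = ids[i], chrom = chrom,
            pos = unname(pos[ids[i]]), r2 = st$r2, D = st$D,
            Dprime = st$Dprime,
            distance_bp = unname(pos[ids[i]] - pos[indexRsid]),
            maf_index = min(pIdx, 1 - pIdx),
            maf_corr = min(mean(y), 1 - mean(y)),
            stringsAsFactors = FALSE)
    }
    if (nskip)
        message(sprintf("ldScan: skipped %d monomorphic site(s)", nskip))
    rows <- rows[!vapply(rows, is.null, logical(1))]
    out <- if (length(rows)) do.call(rbind, rows) else
        data.frame(index_rsid = character(), corr_rsid = character(),
                   chrom = character(), pos = integer(), r2 = numeric(),
                   D = numeric(), Dprime = numeric(), distance_bp = integer(),
                   maf_index = numeric(), maf_corr = numeric(),
                   stringsAsFactors = FALSE)
    out <- out[order(-out$r2, abs(out$distance_bp)), , drop = FALSE]
    rownames(out) <- NULL
    DataFrame(out)
}

#' LD bin specification
#'
#' Default strata are half-open below with a closed top bin:
#' very_low \eqn{[0, 0.1)}, low \eqn{[0.1, 0.5)}, high \eqn{[0.5, 1]}.
#'
#' @param edges strictly increasing cut points in [0,1], starting at the
#'   lower bound of the first bin.
#' @param labels one label per bin.
#' @return list with class \code{"LDBinSpec"}.
#' @export
ldBinSpec <- function(edges = c(0, 0.1, 0.5),
                      labels = c("very_low", "low", "high")) {
    if (is.unsorted(edges, strictly = TRUE) || any(edges < 0) || any(edges > 1))
        stop("edges must be strictly increasing within [0,1]", call. = FALSE)
    if (length(labels) != length(edges))
        stop("need one label per bin", call. = FALSE)
    structure(list(edges = edges, labels = labels), class = "LDBinSpec")
}

#' Stratify LD records into r-squared bins
#'
#' Bins are half-open below and the top bin is closed at 1, so with the
#' default edges an r-squared of exactly 0.1 falls in "low" and exactly 0.5
#' in "high". Per-bin counts always sum to the record count.
#'
#' @param records output of [ldScan()] (any table with an \code{r2} column).
#' @param spec an [ldBinSpec()].
#' @return list with \code{counts} (named integer) and \code{records} (the
#'   input with a \code{bin} column added).
#' @export
binLD <- function(records, spec = ldBinSpec()) {
    r2 <- records$r2
    if (length(r2) && (any(r2 < 0) || any(r2 > 1)))
        stop("all r2 must be in [0,1]", call. = FALSE)
    idx <- findInterval(r2, c(spec$edges, 1), rightmost.closed = TRUE)
    bin <- spec$labels[idx]
    records$bin <- factor(bin, levels = spec$labels)
    counts <- stats::setNames(as.integer(table(records$bin)), spec$labels)
    list(counts = counts, records = records)
}

#' Multi-locus haplotype frequencies
#'
#' Counts the observed haplotypes over an ordered set of panel sites.
#' Haplotypes are reported as allele-base strings (ref/alt bases joined by
#' "-") in descending frequency, ties broken lexicographically by the
#' haplotype string. Frequencies sum to 1.
#'
#' @param panel a [HaplotypePanel-class].
#' @param rsids ordered variant ids, no duplicates.
#' @return \code{DataFrame} with columns \code{haplotype} (bases),
#'   \code{alleles} (0/1 string), \code{count}, \code{frequency}; the rsid
#'   order is attached as \code{metadata(x)$rsids}.
#' @export
multiLocusHaplotypes <- function(panel, rsids) {
    if (anyDuplicated(rsids))
        stop("duplicate rsids in haplotype request", call. = FALSE)
    missing <- setdiff(rsids, variantIds(panel))
    if (length(missing))
        stop(sprintf("variant(s) not in panel: %s",
                     paste(missing, collapse = ", ")), call. = FALSE)
    m <- hapMatrix(panel)[rsids, , drop = FALSE]
    refs <- refAllele(panel)[rsids]
    alts <- altAllele(panel)[rsids]
    alleles <- apply(m, 2L, paste0, collapse = "")
    tab <- table(alleles)
    allele_str <- names(tab)
    base_str <- vapply(allele_str, function(s) {
        bits <- as.integer(strsplit(s, "")[[1L]])
        paste(ifelse(bits == 1L, alts, refs), collapse = "-")
    }, character(1))
    out <- DataFrame(haplotype = unname(base_str), alleles = allele_str,
                     count = as.integer(tab),
                     frequency = as.integer(tab) / ncol(m))
    out <- out[order(-out$frequency, out$haplotype), , drop = FALSE]
    rownames(out) <- NULL
    metadata(out)$rsids <- rsids
    out
}
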
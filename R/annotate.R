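## Classification of high-LD SNPs into exon / TSS-region / enhancer
## categories by coincidence with chromatin biofeature tracks.
##
## Boundary conventions: BED intervals are half-open [start, end) in 0-based
## BED coordinates, imported natively via rtracklayer; a SNP at the BED start
## coordinate overlaps, a SNP at the end coordinate does not. TSS windows are
## [tss - halfWidth, tss + halfWidth) (3 kb wide at the default), so a SNP
## exactly 1.5 kb upstream of a TSS is in the TSS window and not in the
## enhancer domain.

#' Construct an AnnotationTrack
#'
#' @param name track name (unique within a run).
#' @param trackClass functional class; see [AnnotationTrack-class].
#' @param ranges a \code{GRanges} of intervals (sorted internally).
#' @return an [AnnotationTrack-class].
#' @export
annotationTrack <- function(name, trackClass, ranges) {
    new("AnnotationTrack", name = name, trackClass = trackClass,
        ranges = sort(ranges))
}

#' @rdname AnnotationTrack-class
#' @export
setMethod("trackName", "AnnotationTrack", function(x) x@name)

#' @rdname AnnotationTrack-class
#' @export
setMethod("trackClass", "AnnotationTrack", function(x) x@trackClass)

#' @rdname AnnotationTrack-class
#' @export
setMethod("trackRanges", "AnnotationTrack", function(x) x@ranges)

setMethod("show", "AnnotationTrack", function(object) {
    cat(sprintf("AnnotationTrack '%s' (%s): %d interval(s)\n",
                object@name, object@trackClass, length(object@ranges)))
})

#' Read a BED peak track
#'
#' @param path BED3+ file.
#' @inheritParams annotationTrack
#' @return an [AnnotationTrack-class].
#' @export
readTrackBed <- function(path, name, trackClass) {
    gr <- rtracklayer::import(path, format = "bed")
    annotationTrack(name, trackClass, gr)
}

.isPromoterClass <- function(cls)
    cls %in% c("open_chromatin", "promoter_mark", "promoter_enhancer_mark")
.isEnhancerClass <- function(cls)
    cls %in% c("open_chromatin", "enhancer_mark", "promoter_enhancer_mark")

.snpGRanges <- function(snps) {
    GRanges(snps$chrom, IRanges(as.integer(snps$pos), width = 1L))
}

.tssWindow <- function(chrom, tss, halfWidth) {
    # [tss - halfWidth, tss + halfWidth) in 1-based closed coordinates
    GRanges(chrom, IRanges(start = tss - halfWidth, end = tss + halfWidth - 1L))
}

#' TSS positions of a set of transcript models
#'
#' @param models list of [TranscriptModel-class] objects.
#' @return data.frame with columns gene_id, transcript_id, chrom, tss, strand.
#' @export
tssTable <- function(models) {
    do.call(rbind, lapply(models, function(m) {
        data.frame(gene_id = m@geneId, transcript_id = m@transcriptId,
                   chrom = m@chrom, tss = transcriptTss(m),
                   strand = m@strand, stringsAsFactors = FALSE)
    }))
}

#' Build qualifying TSS regions
#'
#' A TSS region is a window of width \code{2 * halfWidth} (3 kb at the
#' default) centered on a transcript's annotated TSS (5' end: leftmost
#' coordinate on "+", rightmost on "-"). Only windows containing at least one
#' interval of an open-chromatin or promoter-mark track are retained.
#'
#' @param models list of [TranscriptModel-class] objects (strand required).
#' @param tracks list of [AnnotationTrack-class] objects.
#' @param halfWidth half window size in bp (default 1500).
#' @return \code{GRanges} of retained windows with metadata columns
#'   \code{gene_id}, \code{transcript_id}, \code{tss},
#'   \code{qualifying_tracks} (comma-separated track names).
#' @export
buildTssRegions <- function(models, tracks, halfWidth = 1500L) {
    tt <- tssTable(models)
    if (is.null(tt) || nrow(tt) == 0L)
        return(GRanges())
    win <- .tssWindow(tt$chrom, as.integer(tt$tss), as.integer(halfWidth))
    mcols(win)$gene_id <- tt$gene_id
    mcols(win)$transcript_id <- tt$transcript_id
    mcols(win)$tss <- as.integer(tt$tss)
    qual <- rep("", length(win))
    for (tr in tracks) {
        if (!.isPromoterClass(trackClass(tr))) next
        hit <- countOverlaps(win, trackRanges(tr)) > 0L
        qual[hit] <- ifelse(nzchar(qual[hit]),
                            paste(qual[hit], trackName(tr), sep = ","),
                            trackName(tr))
    }
    mcols(win)$qualifying_tracks <- qual
    win[nzchar(qual)]
}

#' Enhancer-eligible domain
#'
#' The intronic plus intergenic space more than \code{halfWidth} bp from
#' every TSS: per chromosome, the complement of the union of all exons and
#' all TSS windows over the declared chromosome extent.
#'
#' @param models list of [TranscriptModel-class] objects.
#' @param chromLengths named integer vector of chromosome lengths; every
#'   chromosome carrying a model must be present.
#' @param halfWidth TSS exclusion half-width in bp (default 1500).
#' @return \code{GRanges} of enhancer-eligible intervals.
#' @export
enhancerDomain <- function(models, chromLengths, halfWidth = 1500L) {
    chroms <- unique(c(vapply(models, function(m) m@chrom, character(1)),
                       names(chromLengths)))
    missing <- setdiff(chroms, names(chromLengths))
    if (length(missing))
        stop(sprintf("unknown chromosome extent for: %s",
                     paste(missing, collapse = ", ")), call. = FALSE)
    genome <- GRanges(names(chromLengths),
                      IRanges(1L, as.integer(chromLengths)))
    excl <- GRanges()
    if (length(models)) {
        exons <- do.call(c, lapply(unname(models), function(m) {
            g <- m@cdsExons
            strand(g) <- "*"
            g
        }))
        tt <- tssTable(models)
        tssw <- .tssWindow(tt$chrom, as.integer(tt$tss), as.integer(halfWidth))
        excl <- GenomicRanges::reduce(c(exons, tssw))
    }
    GenomicRanges::setdiff(genome, excl, ignore.strand = TRUE)
}

#' Per-SNP overlap with a single track
#'
#' Pure interval membership under the half-open BED convention: a SNP at a
#' BED interval's start coordinate overlaps, a SNP at its end coordinate
#' does not.
#'
#' @param snps data.frame with columns \code{rsid}, \code{chrom}, \code{pos}.
#' @param track an [AnnotationTrack-class].
#' @return named logical vector of overlap flags, one per SNP.
#' @export
annotateTrack <- function(snps, track) {
    flags <- countOverlaps(.snpGRanges(snps), trackRanges(track)) > 0L
    stats::setNames(flags, snps$rsid)
}

#' Classify SNPs into exon / TSS-region / enhancer categories
#'
#' Category rules (multi-category membership is allowed):
#' \itemize{
#'   \item \strong{exon}: the SNP lies inside a coding-exon interval of
#'     \code{exonTrack} (no chromatin peak required; coding exons are their
#'     own biofeature).
#'   \item \strong{tss}: the SNP lies inside a retained TSS-region window
#'     \emph{and} directly overlaps at least one open-chromatin or
#'     promoter-mark peak.
#'   \item \strong{enhancer}: the SNP lies inside the enhancer domain
#'     (intronic/intergenic, > 1.5 kb from every TSS) \emph{and} directly
#'     overlaps at least one open-chromatin or enhancer-mark peak.
#' }
#' A SNP can never be both tss and enhancer: the two spatial domains are
#' disjoint by construction.
#'
#' @param snps data.frame with columns \code{rsid}, \code{chrom}, \code{pos}.
#' @param exonTrack an [AnnotationTrack-class] of coding exons (class "exon").
#' @param tssRegions output of [buildTssRegions()].
#' @param enhDomain output of [enhancerDomain()].
#' @param tracks list of [AnnotationTrack-class] chromatin biofeatures; used
#'   both for the direct-overlap requirement and for the per-SNP biofeature
#'   overlap count (distinct tracks, not distinct peaks).
#' @param models optional list of [TranscriptModel-class] used for nearest
#'   gene / TSS distance (defaults to the genes behind \code{tssRegions}).
#' @return \code{DataFrame} with columns \code{rsid}, \code{chrom},
#'   \code{pos}, \code{in_exon}, \code{in_tss}, \code{in_enhancer},
#'   \code{category} (comma-joined), \code{overlap_count},
#'   \code{overlapping_tracks}, \code{nearest_gene}, \code{tss_distance_bp}
#'   (signed, pos minus nearest TSS).
#' @export
classifySnps <- function(snps, exonTrack, tssRegions, enhDomain, tracks,
                         models = NULL) {
    gr <- .snpGRanges(snps)
    n <- length(gr)
    in_exon <- if (!is.null(exonTrack))
        countOverlaps(gr, trackRanges(exonTrack)) > 0L else rep(FALSE, n)
    in_tss_window <- countOverlaps(gr, tssRegions) > 0L
    in_enh_domain <- countOverlaps(gr, enhDomain) > 0L
    prom_peak <- rep(FALSE, n)
    enh_peak <- rep(FALSE, n)
    ov_tracks <- vector("list", n)
    for (tr in tracks) {
        hit <- countOverlaps(gr, trackRanges(tr)) > 0L
        if (.isPromoterClass(trackClass(tr))) prom_peak <- prom_peak | hit
        if (.isEnhancerClass(trackClass(tr))) enh_peak <- enh_peak | hit
        for (i in which(hit))
            ov_tracks[[i]] <- c(ov_tracks[[i]], trackName(tr))
    }
    in_tss <- in_tss_window & prom_peak
    in_enh <- in_enh_domain & enh_peak
    # nearest gene / TSS distance
    tt <- if (!is.null(models)) tssTable(models) else if (length(tssRegions))
        data.frame(gene_id = mcols(tssRegions)$gene_id,
                   chrom = as.character(seqnames(tssRegions)),
                   tss = mcols(tssRegions)$tss, stringsAsFactors = FALSE)
    else NULL
    nearest_gene <- rep(NA_character_, n)
    tss_dist <- rep(NA_integer_, n)
    if (!is.null(tt) && nrow(tt)) {
        for (i in seq_len(n)) {
            same <- tt$chrom == snps$chrom[i]
            if (!any(same)) next
            d <- snps$pos[i] - tt$tss[same]
            j <- which.min(abs(d))
            nearest_gene[i] <- tt$gene_id[same][j]
            tss_dist[i] <- d[j]
        }
    }
    cats <- mapply(function(e, t, h) {
        paste(c("exon", "tss", "enhancer")[c(e, t, h)], collapse = ",")
    }, in_exon, in_tss, in_enh)
    DataFrame(rsid = snps$rsid, chrom = snps$chrom, pos = as.integer(snps$pos),
              in_exon = unname(in_exon), in_tss = unname(in_tss),
              in_enhancer = unname(in_enh), category = unname(cats),
              overlap_count = vapply(ov_tracks,
                                     function(x) length(unique(x)), integer(1)),
              overlapping_tracks = vapply(ov_tracks, function(x)
                  paste(unique(x), collapse = ","), character(1)),
              nearest_gene = nearest_gene, tss_distance_bp = tss_dist)
}

#' Summarize category membership
#'
#' @param annotated output of [classifySnps()].
#' @return list with \code{per_category} (named counts for exon, tss,
#'   enhancer), \code{multi_category} (SNPs in more than one category),
#'   \code{union} (distinct SNPs in at least one category),
#'   \code{genes_per_category} (distinct nearest genes per category).
#' @export
summarizeCategories <- function(annotated) {
    nmemb <- annotated$in_exon + annotated$in_tss + annotated$in_enhancer
    per <- c(exon = sum(annotated$in_exon), tss = sum(annotated$in_tss),
             enhancer = sum(annotated$in_enhancer))
    genes <- c(
        exon = length(unique(annotated$nearest_gene[annotated$in_exon])),
        tss = length(unique(annotated$nearest_gene[annotated$in_tss])),
        enhancer = length(unique(annotated$nearest_gene[annotated$in_enhancer])))
    list(per_category = per,
         multi_category = sum(nmemb > 1L),
         union = sum(nmemb >= 1L),
         genes_per_category = genes)
}

#' Category-union arithmetic
#'
#' The number of distinct SNPs in at least one category equals the sum of
#' per-category counts minus the extra memberships contributed by
#' multi-category SNPs (one extra per second category, two per third).
#'
#' @param perCategory numeric vector of per-category SNP counts.
#' @param extraMemberships total extra memberships; for \code{nMulti} SNPs
#'   each in exactly two categories this is \code{nMulti}.
#' @return the unique-SNP union count.
#' @examples
#' categoryUnion(c(21, 76, 921), 13)  # 1005
#' @export
categoryUnion <- function(perCategory, extraMemberships) {
    sum(perCategory) - sum(extraMemberships)
}
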
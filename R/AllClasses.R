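#' @import methods
#' @importFrom S4Vectors DataFrame metadata `metadata<-` mcols `mcols<-` queryHits subjectHits
#' @importFrom BiocGenerics start end width strand `strand<-`
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames findOverlaps countOverlaps
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowRanges colData
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))

#' HaplotypePanel: a phased binary haplotype matrix over biallelic SNVs
#'
#' A \code{HaplotypePanel} holds the substrate of all LD computations: a
#' matrix of 0/1 alleles with one row per biallelic SNV and one column per
#' haplotype (two per diploid sample), together with variant coordinates and
#' ref/alt alleles as a \code{GRanges}. It extends
#' \code{RangedSummarizedExperiment}; the single assay is named
#' \code{"haplotypes"}. Allele 1 is the VCF ALT allele.
#'
#' @slot ... inherited from \code{RangedSummarizedExperiment}; row ranges carry
#'   \code{ref} and \code{alt} metadata columns and rownames are variant ids.
#'
#' @seealso [HaplotypePanel()], [loadPhasedWindow()], [twoLocusR2()]
#' @export
setClass("HaplotypePanel",
         contains = "RangedSummarizedExperiment")

.validHaplotypePanel <- function(object) {
    msg <- character()
    if (!"haplotypes" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'haplotypes' is required")
    else {
        m <- SummarizedExperiment::assay(object, "haplotypes")
        if (!all(m %in% c(0L, 1L)))
            msg <- c(msg, "haplotype matrix entries must be 0/1 (handle missing data before construction)")
    }
    rr <- SummarizedExperiment::rowRanges(object)
    if (length(rr)) {
        if (length(unique(as.character(seqnames(rr)))) > 1L)
            msg <- c(msg, "a panel spans a single chromosome")
        if (any(width(rr) != 1L))
            msg <- c(msg, "all sites must be single-nucleotide (width 1)")
        if (is.unsorted(start(rr), strictly = TRUE))
            msg <- c(msg, "positions must be strictly increasing")
        if (!all(c("ref", "alt") %in% colnames(mcols(rr))))
            msg <- c(msg, "row ranges need 'ref' and 'alt' metadata columns")
        else {
            ok <- nchar(mcols(rr)$ref) == 1L & nchar(mcols(rr)$alt) == 1L
            if (!all(ok))
                msg <- c(msg, "all sites must be biallelic SNVs (single-base ref and alt)")
        }
        if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
            msg <- c(msg, "variant ids (rownames) must be present and unique")
    }
    if (length(msg)) msg else TRUE
}
setValidity("HaplotypePanel", .validHaplotypePanel)

#' MotifMatrix: a probability position weight matrix with background
#'
#' Column-normalized 4 x L probability matrix (rows A, C, G, T) plus a
#' background base distribution. Log-odds scores are reported in bits:
#' \code{sum_i log2(p(base_i, i) / q(base_i))}.
#'
#' @slot name motif (transcription factor) name.
#' @slot probs 4 x L numeric matrix, rownames A,C,G,T; every column sums to 1
#'   and every cell is strictly positive (apply a pseudocount at read time).
#' @slot background named numeric of length 4 over A,C,G,T, summing to 1.
#' @slot source one of \code{"jaspar"}, \code{"meme"}, \code{"other"}.
#'
#' @seealso [MotifMatrix()], [lodScore()], [scanAlleles()]
#' @export
setClass("MotifMatrix",
         representation(name = "character", probs = "matrix",
                        background = "numeric", source = "character"))

.validMotifMatrix <- function(object) {
    msg <- character()
    p <- object@probs
    if (!identical(rownames(p), c("A", "C", "G", "T")))
        msg <- c(msg, "probs must have rownames A,C,G,T")
    if (ncol(p) < 1L)
        msg <- c(msg, "motif length must be >= 1")
    if (any(p <= 0))
        msg <- c(msg, "all probabilities must be > 0 after pseudocounting")
    if (any(abs(colSums(p) - 1) > 1e-9))
        msg <- c(msg, "each probs column must sum to 1 (tol 1e-9)")
    b <- object@background
    if (!identical(names(b), c("A", "C", "G", "T")) || abs(sum(b) - 1) > 1e-9 ||
        any(b <= 0))
        msg <- c(msg, "background must be a positive distribution over A,C,G,T")
    if (!object@source %in% c("jaspar", "meme", "other"))
        msg <- c(msg, "source must be one of jaspar, meme, other")
    if (length(msg)) msg else TRUE
}
setValidity("MotifMatrix", .validMotifMatrix)

#' AnnotationTrack: a named chromatin biofeature interval track
#'
#' Wraps a sorted \code{GRanges} of peak intervals (e.g. DNase, FAIRE,
#' H3K4me1/2/3, H3K9ac, H3K27ac, coding exons, segmentation states) together
#' with its functional class used by the SNP classifier.
#'
#' @slot name track name, unique within a run.
#' @slot trackClass one of \code{open_chromatin}, \code{promoter_mark},
#'   \code{enhancer_mark}, \code{exon}, \code{segmentation}, \code{other}.
#'   Marks diagnostic of both promoters and enhancers (H3K4me2, H3K9ac,
#'   H3K27ac) may carry the compound class \code{promoter_enhancer_mark}.
#' @slot ranges \code{GRanges} of intervals.
#'
#' @seealso [annotationTrack()], [classifySnps()]
#' @export
setClass("AnnotationTrack",
         representation(name = "character", trackClass = "character",
                        ranges = "GRanges"))

.trackClasses <- c("open_chromatin", "promoter_mark", "enhancer_mark",
                   "promoter_enhancer_mark", "exon", "segmentation", "other")

.validAnnotationTrack <- function(object) {
    msg <- character()
    if (length(object@name) != 1L || !nzchar(object@name))
        msg <- c(msg, "track name must be a non-empty string")
    if (!object@trackClass %in% .trackClasses)
        msg <- c(msg, paste("trackClass must be one of:",
                            paste(.trackClasses, collapse = ", ")))
    if (length(msg)) msg else TRUE
}
setValidity("AnnotationTrack", .validAnnotationTrack)

#' TranscriptModel: a coding transcript with ordered CDS exons
#'
#' @slot transcriptId,geneId identifiers.
#' @slot strand "+" or "-".
#' @slot chrom chromosome name.
#' @slot txStart,txEnd 1-based transcript span (TSS is \code{txStart} on "+"
#'   and \code{txEnd} on "-").
#' @slot cdsExons \code{GRanges} of CDS exons, genomic ascending,
#'   non-overlapping, total width divisible by 3.
#'
#' @seealso [transcriptModelsFromGtf()], [codonEffect()]
#' @export
setClass("TranscriptModel",
         representation(transcriptId = "character", geneId = "character",
                        strand = "character", chrom = "character",
                        txStart = "integer", txEnd = "integer",
                        cdsExons = "GRanges"))

.validTranscriptModel <- function(object) {
    msg <- character()
    if (!object@strand %in% c("+", "-"))
        msg <- c(msg, "strand must be '+' or '-'")
    w <- sum(width(object@cdsExons))
    if (w %% 3L != 0L)
        msg <- c(msg, sprintf("total CDS length (%d) must be divisible by 3", w))
    if (length(object@cdsExons) > 1L) {
        s <- start(object@cdsExons)
        e <- end(object@cdsExons)
        if (is.unsorted(s, strictly = TRUE) ||
            any(s[-1L] <= e[-length(e)]))
            msg <- c(msg, "CDS exons must be genomic-ascending and non-overlapping")
    }
    if (object@txStart > object@txEnd)
        msg <- c(msg, "txStart must be <= txEnd")
    if (length(msg)) msg else TRUE
}
setValidity("TranscriptModel", .validTranscriptModel)

#' PlantedPairSpec: design of one two-locus pair at a target r-squared
#'
#' Describes an index/partner SNP pair to plant into a synthetic haplotype
#' panel. The implied coefficient of linkage disequilibrium is
#' \code{D = dSign * sqrt(r2Target * pIndex(1-pIndex) * pPartner(1-pPartner))}
#' and the four implied haplotype frequencies must all lie in [0, 1]
#' (Lewontin feasibility); infeasible combinations are rejected at
#' construction with the violated bound named.
#'
#' @slot indexRsid,partnerRsid variant identifiers.
#' @slot pIndex,pPartner frequency of allele "1" (the ALT allele), strictly in (0,1).
#' @slot r2Target target squared correlation in [0,1].
#' @slot dSign +1 or -1, the sign of D.
#' @slot posIndex,posPartner 1-based positions used when the pair is written
#'   into a fixture bundle.
#'
#' @seealso [plantedPairSpec()], [plantTwoLocusHaplotypes()]
#' @export
setClass("PlantedPairSpec",
         representation(indexRsid = "character", partnerRsid = "character",
                        pIndex = "numeric", pPartner = "numeric",
                        r2Target = "numeric", dSign = "numeric",
                        posIndex = "integer", posPartner = "integer"))

.validPlantedPairSpec <- function(object) {
    msg <- character()
    if (object@pIndex <= 0 || object@pIndex >= 1)
        msg <- c(msg, "pIndex must be strictly in (0,1)")
    if (object@pPartner <= 0 || object@pPartner >= 1)
        msg <- c(msg, "pPartner must be strictly in (0,1)")
    if (object@r2Target < 0 || object@r2Target > 1)
        msg <- c(msg, "r2Target must be in [0,1]")
    if (!object@dSign %in% c(-1, 1))
        msg <- c(msg, "dSign must be +1 or -1")
    if (!length(msg)) {
        h <- tryCatch(pairHaplotypeFrequencies(object@pIndex, object@pPartner,
                                               object@r2Target, object@dSign),
                      error = function(e) conditionMessage(e))
        if (is.character(h)) msg <- c(msg, h)
    }
    if (length(msg)) msg else TRUE
}

setValidity("PlantedPairSpec", .validPlantedPairSpec)

#' FixtureSpec: full design of a synthetic fixture bundle
#'
#' A complete, seeded description of a self-contained fixture bundle: a
#' phased VCF panel with planted two-locus LD, a random genome with planted
#' motif consensus sites, gene models, chromatin peak tracks placed in TSS
#' windows or enhancer space, an eQTL table and an index-SNP list. A fixed
#' seed makes [writeBundle()] byte-deterministic.
#'
#' @slot nHaplotypes even haplotype count (two per diploid sample).
#' @slot chrom,chromLength the single synthetic chromosome and its length.
#' @slot plantedPairs list of [PlantedPairSpec-class] objects; pairs sharing
#'   an index SNP must agree on \code{pIndex}.
#' @slot nBackgroundSnps count of independent background SNVs.
#' @slot geneBlueprints list; each element has \code{gene_id}, \code{strand},
#'   \code{exon_starts}, \code{exon_widths} (1-based CDS exon layout).
#' @slot trackBlueprints list; each element has \code{name}, \code{class},
#'   \code{placement} ("tss" or "enhancer"), \code{gene}, \code{offset},
#'   \code{width}, \code{jitter}.
#' @slot pwmBlueprints list; each element has \code{name}, \code{consensus},
#'   \code{snp_id}, \code{snp_offset} (0-based offset of the SNP inside the
#'   consensus site), \code{p_consensus}.
#' @slot eqtlRows data.frame with columns snp, gene, p, tissue, source.
#' @slot indexLoci data.frame with columns rsid, locus (locus labels for the
#'   index SNPs, in input order).
#' @slot seed integer RNG seed.
#'
#' @seealso [fixtureSpec()], [demoFixtureSpec()], [writeBundle()]
#' @export
setClass("FixtureSpec",
         representation(nHaplotypes = "integer", chrom = "character",
                        chromLength = "integer", plantedPairs = "list",
                        nBackgroundSnps = "integer", geneBlueprints = "list",
                        trackBlueprints = "list", pwmBlueprints = "list",
                        eqtlRows = "data.frame", indexLoci = "data.frame",
                        seed = "integer"))

.validFixtureSpec <- function(object) {
    msg <- character()
    if (object@nHaplotypes < 2L || object@nHaplotypes %% 2L != 0L)
        msg <- c(msg, "nHaplotypes must be a positive even count")
    if (object@chromLength < 1000L)
        msg <- c(msg, "chromLength must be at least 1 kb")
    for (p in object@plantedPairs)
        if (!is(p, "PlantedPairSpec"))
            msg <- c(msg, "plantedPairs must contain PlantedPairSpec objects")
    pos <- unlist(lapply(object@plantedPairs,
                         function(p) c(p@posIndex, p@posPartner)))
    ids <- unlist(lapply(object@plantedPairs,
                         function(p) c(p@indexRsid, p@partnerRsid)))
    keep <- !duplicated(ids)
    if (anyDuplicated(pos[keep]))
        msg <- c(msg, "planted SNP positions must be unique")
    # pairs sharing an index SNP must agree on its allele frequency
    idx <- vapply(object@plantedPairs, function(p) p@indexRsid, character(1))
    pidx <- vapply(object@plantedPairs, function(p) p@pIndex, numeric(1))
    for (i in unique(idx)) {
        if (length(unique(pidx[idx == i])) > 1L)
            msg <- c(msg, sprintf("pairs sharing index %s disagree on pIndex", i))
    }
    if (nrow(object@eqtlRows) &&
        !all(c("snp", "gene", "p", "tissue", "source") %in%
             colnames(object@eqtlRows)))
        msg <- c(msg, "eqtlRows needs columns snp, gene, p, tissue, source")
    if (length(msg)) msg else TRUE
}
setValidity("FixtureSpec", .validFixtureSpec)
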
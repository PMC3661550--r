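## Projection of exonic SNPs through transcript models to codon changes,
## effect classification, and haplotype protein isoforms.

#' @rdname TranscriptModel-class
#' @export
setMethod("cdsExons", "TranscriptModel", function(x) x@cdsExons)

#' @rdname TranscriptModel-class
#' @export
setMethod("transcriptTss", "TranscriptModel", function(x)
    if (x@strand == "+") x@txStart else x@txEnd)

setMethod("show", "TranscriptModel", function(object) {
    cat(sprintf("TranscriptModel %s (gene %s, %s%s): %d CDS exon(s), CDS %d bp\n",
                object@transcriptId, object@geneId, object@chrom,
                object@strand, length(object@cdsExons),
                sum(width(object@cdsExons))))
})

#' Construct a TranscriptModel
#'
#' @param transcriptId,geneId identifiers.
#' @param chrom chromosome.
#' @param strand "+" or "-".
#' @param exonStarts,exonEnds 1-based inclusive CDS exon coordinates
#'   (genomic ascending).
#' @param txStart,txEnd transcript span; defaults to the CDS span.
#' @return a [TranscriptModel-class].
#' @export
transcriptModel <- function(transcriptId, geneId, chrom, strand,
                            exonStarts, exonEnds,
                            txStart = min(exonStarts),
                            txEnd = max(exonEnds)) {
    o <- order(exonStarts)
    g <- GRanges(chrom, IRanges(as.integer(exonStarts[o]),
                                as.integer(exonEnds[o])), strand = strand)
    new("TranscriptModel", transcriptId = transcriptId, geneId = geneId,
        strand = strand, chrom = chrom, txStart = as.integer(txStart),
        txEnd = as.integer(txEnd), cdsExons = g)
}

#' Read transcript models from a GTF file
#'
#' Builds one [TranscriptModel-class] per transcript carrying CDS features;
#' the transcript span is taken from the transcript feature when present,
#' otherwise from the CDS span.
#'
#' @param path GTF file.
#' @return named list of [TranscriptModel-class] objects.
#' @export
transcriptModelsFromGtf <- function(path) {
    g <- rtracklayer::import(path, format = "gtf")
    cds <- g[g$type == "CDS"]
    tx <- g[g$type == "transcript"]
    if (!length(cds))
        stop(sprintf("no CDS features in '%s'", path), call. = FALSE)
    out <- list()
    for (tid in unique(cds$transcript_id)) {
        e <- cds[cds$transcript_id == tid]
        st <- as.character(strand(e))[1L]
        if (!st %in% c("+", "-"))
            stop(sprintf("transcript %s has no strand", tid), call. = FALSE)
        span <- tx[!is.na(tx$transcript_id) & tx$transcript_id == tid]
        ts <- if (length(span)) start(span)[1L] else min(start(e))
        te <- if (length(span)) end(span)[1L] else max(end(e))
        out[[tid]] <- transcriptModel(
            tid, e$gene_id[1L], as.character(seqnames(e))[1L], st,
            start(sort(e)), end(sort(e)), txStart = ts, txEnd = te)
    }
    out
}

#' Project a genomic position into CDS coordinates
#'
#' Strand-aware cumulative offset: 1 is the first base of the initiator
#' codon. Positions outside every CDS exon are rejected.
#'
#' @param model a [TranscriptModel-class].
#' @param genomicPos 1-based genomic position.
#' @return 1-based CDS position.
#' @export
projectToCds <- function(model, genomicPos) {
    ex <- model@cdsExons
    s <- start(ex); e <- end(ex); w <- width(ex)
    i <- which(genomicPos >= s & genomicPos <= e)
    if (!length(i))
        stop(sprintf("position %d is intronic/UTR for transcript %s",
                     genomicPos, model@transcriptId), call. = FALSE)
    if (model@strand == "+") {
        before <- if (i > 1L) sum(w[seq_len(i - 1L)]) else 0L
        before + (genomicPos - s[i] + 1L)
    } else {
        after <- if (i < length(w)) sum(w[(i + 1L):length(w)]) else 0L
        after + (e[i] - genomicPos + 1L)
    }
}

.cdsSequence <- function(model, genome) {
    ex <- model@cdsExons
    parts <- vapply(seq_along(ex), function(i)
        .genomeSlice(genome, model@chrom, start(ex)[i], end(ex)[i]),
        character(1))
    seqc <- paste(parts, collapse = "")
    if (model@strand == "-") seqc <- .revcomp(seqc)
    seqc
}

.translateCodon <- function(codon) {
    aa <- Biostrings::GENETIC_CODE[[codon]]
    if (is.null(aa)) stop(sprintf("cannot translate codon '%s'", codon),
                          call. = FALSE)
    aa
}

#' Codon change and effect class of a coding SNP
#'
#' Translates the reference and alternate codons under the standard genetic
#' code and classifies the change: \code{synonymous} (identical residues),
#' \code{missense}, \code{nonsense} (alternate codon is a stop),
#' \code{stop_loss} (reference codon is a stop, alternate is not) or
#' \code{start_loss} (codon 1 loses the initiator Met). \code{ref}/\code{alt}
#' are plus-strand bases as in a VCF; they are complemented internally for
#' minus-strand transcripts.
#'
#' @param model a [TranscriptModel-class].
#' @param genome \code{DNAStringSet} named by chromosome.
#' @param pos 1-based genomic position inside a CDS exon.
#' @param ref,alt single plus-strand bases; \code{ref} must match the genome.
#' @return \code{DataFrame} row: \code{rsid} (NA unless given),
#'   \code{transcript_id}, \code{cds_pos}, \code{codon_index},
#'   \code{ref_codon}, \code{alt_codon}, \code{ref_aa}, \code{alt_aa},
#'   \code{aa_change} ("A31T"-style), \code{effect}.
#' @param rsid optional variant id carried through.
#' @export
codonEffect <- function(model, genome, pos, ref, alt, rsid = NA_character_) {
    gbase <- .genomeSlice(genome, model@chrom, pos, pos)
    if (gbase != ref)
        stop(sprintf("ref allele mismatch at %s:%d (genome %s, snp %s)",
                     model@chrom, pos, gbase, ref), call. = FALSE)
    cds_pos <- projectToCds(model, pos)
    seqc <- .cdsSequence(model, genome)
    ci <- ceiling(cds_pos / 3)
    if (3L * ci > nchar(seqc))
        stop(sprintf("SNP at CDS position %d falls in an incomplete terminal codon of %s",
                     cds_pos, model@transcriptId), call. = FALSE)
    ref_t <- if (model@strand == "+") ref else .revcomp(ref)
    alt_t <- if (model@strand == "+") alt else .revcomp(alt)
    ref_codon <- substr(seqc, 3L * ci - 2L, 3L * ci)
    pin <- cds_pos - 3L * (ci - 1L)
    if (substr(ref_codon, pin, pin) != ref_t)
        stop(sprintf("transcript-oriented ref base mismatch at CDS %d of %s",
                     cds_pos, model@transcriptId), call. = FALSE)
    alt_codon <- ref_codon
    substr(alt_codon, pin, pin) <- alt_t
    ref_aa <- .translateCodon(ref_codon)
    alt_aa <- .translateCodon(alt_codon)
    effect <- if (ref_aa == alt_aa) "synonymous"
              else if (ci == 1L && ref_aa == "M") "start_loss"
              else if (alt_aa == "*") "nonsense"
              else if (ref_aa == "*") "stop_loss"
              else "missense"
    DataFrame(rsid = rsid, transcript_id = model@transcriptId,
              gene_id = model@geneId, cds_pos = cds_pos, codon_index = ci,
              ref_codon = ref_codon, alt_codon = alt_codon,
              ref_aa = ref_aa, alt_aa = alt_aa,
              aa_change = paste0(ref_aa, ci, alt_aa), effect = effect)
}

#' Compose multi-SNP haplotypes into protein isoforms
#'
#' Maps each observed haplotype over a set of coding SNPs (from
#' [multiLocusHaplotypes()]) to its amino-acid states: allele 0 gives the
#' reference residue, allele 1 the alternate residue of the matching
#' [codonEffect()] record. All effects must come from the same transcript.
#'
#' @param effects table of [codonEffect()] rows, one per SNP.
#' @param haplotypes output of [multiLocusHaplotypes()] over the same SNPs
#'   (same order).
#' @return \code{DataFrame} with columns \code{haplotype} (allele bases),
#'   \code{alleles}, \code{residues} (e.g. "A-L-L"), \code{frequency}.
#' @export
haplotypeIsoform <- function(effects, haplotypes) {
    rsids <- metadata(haplotypes)$rsids
    if (is.null(rsids))
        stop("haplotypes must come from multiLocusHaplotypes()", call. = FALSE)
    if (length(unique(effects$transcript_id)) != 1L)
        stop("all effects must be on the same transcript", call. = FALSE)
    missing <- setdiff(rsids, effects$rsid)
    if (length(missing))
        stop(sprintf("no coding effect for SNP(s): %s",
                     paste(missing, collapse = ", ")), call. = FALSE)
    eff <- effects[match(rsids, effects$rsid), , drop = FALSE]
    residues <- vapply(haplotypes$alleles, function(s) {
        bits <- as.integer(strsplit(s, "")[[1L]])
        paste(ifelse(bits == 1L, eff$alt_aa, eff$ref_aa), collapse = "-")
    }, character(1))
    DataFrame(haplotype = haplotypes$haplotype, alleles = haplotypes$alleles,
              residues = unname(residues), frequency = haplotypes$frequency)
}
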
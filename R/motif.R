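## Allele-specific PWM log-odds scanning, exact match p-values by dynamic
## programming over discretized column scores, affected-RE decisions and TF
## ranking.

.BASES <- c("A", "C", "G", "T")

#' Construct a MotifMatrix
#'
#' @param name motif name.
#' @param probs 4 x L matrix of column probabilities (rows A,C,G,T) or
#'   counts; columns are renormalized after adding \code{pseudocount}.
#' @param background named base distribution (default uniform).
#' @param source one of "jaspar", "meme", "other".
#' @param pseudocount value added to every cell before renormalization
#'   (default 0: \code{probs} must already be strictly positive).
#' @return a [MotifMatrix-class].
#' @export
MotifMatrix <- function(name, probs, background = c(A = 0.25, C = 0.25,
                                                    G = 0.25, T = 0.25),
                        source = "other", pseudocount = 0) {
    probs <- as.matrix(probs)
    rownames(probs) <- .BASES
    probs <- probs + pseudocount
    probs <- sweep(probs, 2L, colSums(probs), "/")
    new("MotifMatrix", name = name, probs = probs,
        background = background[.BASES], source = source)
}

#' @rdname MotifMatrix-class
#' @export
setMethod("motifName", "MotifMatrix", function(x) x@name)

#' @rdname MotifMatrix-class
#' @export
setMethod("motifLength", "MotifMatrix", function(x) ncol(x@probs))

#' @rdname MotifMatrix-class
#' @export
setMethod("motifProbs", "MotifMatrix", function(x) x@probs)

#' @rdname MotifMatrix-class
#' @export
setMethod("motifBackground", "MotifMatrix", function(x) x@background)

setMethod("show", "MotifMatrix", function(object) {
    cons <- paste(.BASES[apply(object@probs, 2L, which.max)], collapse = "")
    cat(sprintf("MotifMatrix '%s' (%s), length %d, consensus %s\n",
                object@name, object@source, ncol(object@probs), cons))
})

#' Read motifs in JASPAR count format
#'
#' Parses the JASPAR 2016 matrix format: a \code{>identifier name} header
#' followed by four lines \code{A [ n n ... ]} etc. Counts get the JASPAR
#' pseudocount (default +0.25 per cell) before column normalization.
#'
#' @param path file with one or more JASPAR matrices.
#' @param pseudocount added to every count cell (default 0.25).
#' @param background base distribution (default uniform).
#' @return list of [MotifMatrix-class] objects named by motif.
#' @export
readJasparMotifs <- function(path, pseudocount = 0.25,
                             background = c(A = 0.25, C = 0.25,
                                            G = 0.25, T = 0.25)) {
    lines <- readLines(path)
    starts <- grep("^>", lines)
    if (!length(starts))
        stop(sprintf("no JASPAR motif headers in '%s'", path), call. = FALSE)
    out <- list()
    for (s in starts) {
        hdr <- sub("^>\\s*", "", lines[s])
        nm <- utils::tail(strsplit(hdr, "\\s+")[[1L]], 1L)
        rows <- lines[s + 1:4]
        counts <- t(vapply(rows, function(l) {
            v <- gsub("^[ACGT]\\s*\\[|\\]\\s*$", "", l)
            as.numeric(strsplit(trimws(v), "\\s+")[[1L]])
        }, numeric(length(strsplit(trimws(gsub(
            "^[ACGT]\\s*\\[|\\]\\s*$", "", rows[1L])), "\\s+")[[1L]]))))
        out[[nm]] <- MotifMatrix(nm, counts, background = background,
                                 source = "jaspar", pseudocount = pseudocount)
    }
    out
}

#' Read motifs in MEME minimal format
#'
#' Parses \code{MOTIF} blocks with \code{letter-probability matrix} sections;
#' uses the file's \code{Background letter frequencies} when present.
#' Probabilities get a small pseudocount (default +0.01) and are
#' renormalized so log-odds are finite.
#'
#' @param path MEME minimal-format file.
#' @param pseudocount added to every probability cell (default 0.01).
#' @return list of [MotifMatrix-class] objects named by motif.
#' @export
readMemeMotifs <- function(path, pseudocount = 0.01) {
    lines <- readLines(path)
    bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
    bgi <- grep("^Background letter frequencies", lines)
    if (length(bgi) && bgi[1L] < length(lines)) {
        tok <- strsplit(trimws(lines[bgi[1L] + 1L]), "\\s+")[[1L]]
        if (length(tok) >= 8L) {
            v <- as.numeric(tok[seq(2L, 8L, by = 2L)])
            names(v) <- tok[seq(1L, 7L, by = 2L)]
            bg <- v[.BASES]
        }
    }
    starts <- grep("^MOTIF\\b", lines)
    if (!length(starts))
        stop(sprintf("no MOTIF blocks in '%s'", path), call. = FALSE)
    out <- list()
    for (s in starts) {
        nm <- strsplit(trimws(lines[s]), "\\s+")[[1L]][2L]
        hi <- grep("^letter-probability matrix", lines)
        hi <- hi[hi > s][1L]
        w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hi]))
        block <- lines[hi + seq_len(w)]
        probs <- t(vapply(block, function(l)
            as.numeric(strsplit(trimws(l), "\\s+")[[1L]]), numeric(4)))
        out[[nm]] <- MotifMatrix(nm, t(probs), background = bg,
                                 source = "meme", pseudocount = pseudocount)
    }
    out
}

#' Log-odds score of a sequence window
#'
#' \eqn{\sum_i \log_2(p(b_i, i) / q(b_i))} in bits. Windows containing
#' ambiguous bases are rejected (callers skip them with a logged count).
#'
#' @param pwm a [MotifMatrix-class].
#' @param window character string over A,C,G,T of length
#'   \code{motifLength(pwm)}.
#' @return score in bits.
#' @export
lodScore <- function(pwm, window) {
    b <- strsplit(toupper(window), "")[[1L]]
    if (length(b) != motifLength(pwm))
        stop("window length must equal motif length", call. = FALSE)
    if (!all(b %in% .BASES))
        stop(sprintf("ambiguous base in window '%s'", window), call. = FALSE)
    idx <- match(b, .BASES)
    sum(log2(motifProbs(pwm)[cbind(idx, seq_along(idx))] /
             motifBackground(pwm)[idx]))
}

#' Maximum attainable log-odds score of a motif
#' @param pwm a [MotifMatrix-class].
#' @return score in bits of the per-column argmax window.
#' @export
motifMaxScore <- function(pwm) {
    sum(apply(log2(sweep(motifProbs(pwm), 1L, motifBackground(pwm), "/")),
              2L, max))
}

.revcompMotif <- function(pwm) {
    p <- motifProbs(pwm)[4:1, ncol(motifProbs(pwm)):1, drop = FALSE]
    rownames(p) <- .BASES
    MotifMatrix(motifName(pwm), p, background = motifBackground(pwm),
                source = pwm@source)
}

.revcomp <- function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

.genomeSlice <- function(genome, chrom, from, to) {
    if (!chrom %in% names(genome))
        stop(sprintf("chromosome '%s' not in genome", chrom), call. = FALSE)
    as.character(Biostrings::subseq(genome[[chrom]], start = from, end = to))
}

#' Allele-specific best motif scores at a SNP
#'
#' Evaluates every length-L window covering the SNP, on both strands, for
#' the reference and alternate alleles; the per-allele best is the maximum
#' over windows and strands. The best strand/offset are recorded from the
#' alternate-allele best; \code{delta_lod = best_lod_alt - best_lod_ref}.
#' Windows containing ambiguous bases or extending past the chromosome ends
#' are skipped (counted).
#'
#' @param pwm a [MotifMatrix-class].
#' @param genome a \code{DNAStringSet} named by chromosome.
#' @param snp list or one-row data.frame with \code{rsid}, \code{chrom},
#'   \code{pos}, \code{ref}, \code{alt}; \code{ref} must match the genome.
#' @return one-row \code{DataFrame}: \code{pwm_name}, \code{rsid},
#'   \code{best_lod_ref}, \code{best_lod_alt}, \code{delta_lod},
#'   \code{best_strand}, \code{best_offset} (0-based SNP offset within the
#'   motif window), \code{p_ref}, \code{p_alt}.
#' @export
scanAlleles <- function(pwm, genome, snp) {
    L <- motifLength(pwm)
    pos <- as.integer(snp$pos)
    chrlen <- length(genome[[snp$chrom]])
    gbase <- .genomeSlice(genome, snp$chrom, pos, pos)
    if (gbase != snp$ref)
        stop(sprintf("ref allele mismatch at %s:%d (genome %s, snp %s)",
                     snp$chrom, pos, gbase, snp$ref), call. = FALSE)
    from <- max(1L, pos - L + 1L)
    to <- min(chrlen, pos + L - 1L)
    ctx <- .genomeSlice(genome, snp$chrom, from, to)
    centre <- pos - from + 1L
    score_allele <- function(allele) {
        seqc <- ctx
        substr(seqc, centre, centre) <- allele
        best <- -Inf; bstrand <- NA_character_; boff <- NA_integer_
        nskip <- 0L
        for (j in 0:(L - 1L)) {
            s <- centre - j
            if (s < 1L || s + L - 1L > nchar(seqc)) { nskip <- nskip + 1L; next }
            w <- substr(seqc, s, s + L - 1L)
            if (grepl("[^ACGT]", w)) { nskip <- nskip + 1L; next }
            sp <- lodScore(pwm, w)
            if (sp > best) { best <- sp; bstrand <- "+"; boff <- j }
            sm <- lodScore(pwm, .revcomp(w))
            if (sm > best) { best <- sm; bstrand <- "-"; boff <- L - 1L - j }
        }
        list(best = best, strand = bstrand, offset = boff, nskip = nskip)
    }
    r <- score_allele(snp$ref)
    a <- score_allele(snp$alt)
    if (!is.finite(r$best) || !is.finite(a$best))
        stop(sprintf("no scorable window covers %s:%d", snp$chrom, pos),
             call. = FALSE)
    DataFrame(pwm_name = motifName(pwm), rsid = snp$rsid,
              best_lod_ref = r$best, best_lod_alt = a$best,
              delta_lod = a$best - r$best,
              best_strand = a$strand, best_offset = a$offset,
              p_ref = scorePvalue(pwm, r$best),
              p_alt = scorePvalue(pwm, a$best))
}

.discColumnBins <- function(pwm, binWidth) {
    # per-column integer score bins, rounded UP so the DP tail mass is a
    # guaranteed upper bound on the true single-window p-value
    lod <- log2(sweep(motifProbs(pwm), 1L, motifBackground(pwm), "/"))
    matrix(as.integer(ceiling(lod / binWidth - 1e-12)), nrow = 4L,
           dimnames = list(.BASES, NULL))
}

.discDistribution <- function(pwm, binWidth) {
    bins <- .discColumnBins(pwm, binWidth)
    bg <- motifBackground(pwm)
    cur <- numeric(0)
    curlo <- 0L
    for (j in seq_len(ncol(bins))) {
        colbins <- bins[, j]
        if (j == 1L) {
            curlo <- min(colbins)
            cur <- numeric(max(colbins) - curlo + 1L)
            for (b in 1:4)
                cur[colbins[b] - curlo + 1L] <- cur[colbins[b] - curlo + 1L] + bg[b]
        } else {
            newlo <- curlo + min(colbins)
            newhi <- curlo + length(cur) - 1L + max(colbins)
            nxt <- numeric(newhi - newlo + 1L)
            for (b in 1:4) {
                sh <- colbins[b]
                idx <- (curlo + sh - newlo + 1L):(curlo + sh - newlo + length(cur))
                nxt[idx] <- nxt[idx] + bg[b] * cur
            }
            cur <- nxt
            curlo <- newlo
        }
    }
    list(mass = cur, lo = curlo)
}

#' Exact single-window motif score p-value
#'
#' The probability, under the background model, that one random window
#' scores at least \code{score}. Computed from the exact distribution of
#' the discretized score (column log-odds rounded up to \code{binWidth}
#' bins, convolved across columns by dynamic programming), so the reported
#' p is a guaranteed upper bound on the true tail probability and decreases
#' monotonically in \code{score}. Scores above the discretized maximum
#' return the smallest attainable tail mass (never 0).
#'
#' @param pwm a [MotifMatrix-class].
#' @param score query score in bits.
#' @param binWidth discretization width in bits (default 0.01).
#' @return p-value in (0, 1].
#' @export
scorePvalue <- function(pwm, score, binWidth = 0.01) {
    d <- .discDistribution(pwm, binWidth)
    t <- as.integer(ceiling(score / binWidth - 1e-12))
    hi <- d$lo + length(d$mass) - 1L
    if (t <= d$lo) return(1)
    if (t > hi) t <- hi  # smallest attainable tail mass
    tail <- sum(d$mass[(t - d$lo + 1L):length(d$mass)])
    if (tail <= 0) tail <- d$mass[length(d$mass)]
    min(1, tail)
}

#' Decide whether a motif hit marks an affected response element
#'
#' A SNP affects a motif's response element when the best score of either
#' allele clears the log-odds cutoff (default 5 bits) OR either allele's
#' match p-value clears the p-value cutoff (default 1e-4), AND the two
#' alleles actually score differently (\code{delta_lod != 0}).
#'
#' @param hit one-row result of [scanAlleles()].
#' @param lodMin log-odds cutoff in bits (default 5).
#' @param pMax p-value cutoff (default 1e-4).
#' @return list with \code{affected} (logical), \code{rule} (which cutoff
#'   was satisfied: "lod", "pvalue", "both" or ""), and \code{reason}.
#' @export
affectedRE <- function(hit, lodMin = 5, pMax = 1e-4) {
    lod_ok <- max(hit$best_lod_ref, hit$best_lod_alt) >= lodMin
    p_ok <- min(hit$p_ref, hit$p_alt) <= pMax
    if (hit$delta_lod == 0)
        return(list(affected = FALSE, rule = "",
                    reason = "delta_lod = 0: alleles score identically"))
    if (!lod_ok && !p_ok)
        return(list(affected = FALSE, rule = "",
                    reason = "both alleles below LOD and p-value cutoffs"))
    rule <- if (lod_ok && p_ok) "both" else if (lod_ok) "lod" else "pvalue"
    list(affected = TRUE, rule = rule,
         reason = sprintf("passed %s rule with delta_lod %.3f", rule,
                          hit$delta_lod))
}

#' Rank transcription factors by number of affected SNPs
#'
#' One row per motif with the count of distinct SNPs affecting its response
#' elements and the count of distinct risk loci contributing those SNPs.
#' Sorted by \code{n_snps} descending, ties broken by \code{n_loci}
#' descending then motif name ascending; ranks are contiguous from 1. For
#' report tables a minimum-SNP floor and a top-N filter can be applied.
#'
#' @param hits table of affected motif hits with columns \code{pwm_name}
#'   and \code{rsid} (e.g. rows of [scanAlleles()] results that passed
#'   [affectedRE()]).
#' @param snpLocus named character vector mapping every rsid to its risk
#'   locus.
#' @param minSnps minimum SNP count to keep a row (default 1; the report
#'   default in the field is 2).
#' @param topN keep at most this many rows after ranking (default all).
#' @return \code{DataFrame} with columns \code{motif}, \code{n_snps},
#'   \code{n_loci}, \code{rank}.
#' @export
rankTFs <- function(hits, snpLocus, minSnps = 1L, topN = Inf) {
    if (nrow(hits) == 0L)
        return(DataFrame(motif = character(), n_snps = integer(),
                         n_loci = integer(), rank = integer()))
    missing <- setdiff(unique(hits$rsid), names(snpLocus))
    if (length(missing))
        stop(sprintf("no locus mapping for SNP(s): %s",
                     paste(missing, collapse = ", ")), call. = FALSE)
    sp <- split(hits$rsid, hits$pwm_name)
    tab <- data.frame(
        motif = names(sp),
        n_snps = vapply(sp, function(r) length(unique(r)), integer(1)),
        n_loci = vapply(sp, function(r)
            length(unique(snpLocus[unique(r)])), integer(1)),
        stringsAsFactors = FALSE)
    tab <- tab[order(-tab$n_snps, -tab$n_loci, tab$motif), , drop = FALSE]
    tab <- tab[tab$n_snps >= minSnps, , drop = FALSE]
    if (is.finite(topN)) tab <- utils::head(tab, topN)
    tab$rank <- seq_len(nrow(tab))
    rownames(tab) <- NULL
    DataFrame(tab)
}
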
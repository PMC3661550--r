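## Synthetic fixture bundles: phased panels with planted two-locus LD,
## a random genome with planted motif consensus sites, gene models, peak
## tracks, eQTL tables and a ground-truth manifest. Everything downstream
## of the generator can be tested against the manifest.

.withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(),
                            inherits = FALSE))
                rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
    expr
}

.subSeed <- function(seed, k) (as.integer(seed) + 1000003L * as.integer(k)) %% 2147483647L

#' Implied two-locus haplotype frequencies
#'
#' From allele frequencies and a target r-squared,
#' \eqn{D = d \sqrt{r^2 p_A(1-p_A) p_B(1-p_B)}} and the four haplotype
#' frequencies are \eqn{h_{AB} = p_A p_B + D}, \eqn{h_{Ab} = p_A(1-p_B) - D},
#' \eqn{h_{aB} = (1-p_A)p_B - D}, \eqn{h_{ab} = (1-p_A)(1-p_B) + D}. Any
#' frequency outside [0,1] makes the combination infeasible; the violated
#' bound is named in the error.
#'
#' @param pA,pB allele-1 frequencies, strictly in (0,1).
#' @param r2 target squared correlation in [0,1].
#' @param dSign +1 or -1.
#' @return named numeric: \code{hAB}, \code{hAb}, \code{haB}, \code{hab}.
#' @examples
#' pairHaplotypeFrequencies(0.3, 0.4, 0, 1)["hAB"]  # 0.12: independence
#' @export
pairHaplotypeFrequencies <- function(pA, pB, r2, dSign = 1) {
    D <- dSign * sqrt(r2 * pA * (1 - pA) * pB * (1 - pB))
    h <- c(hAB = pA * pB + D, hAb = pA * (1 - pB) - D,
           haB = (1 - pA) * pB - D, hab = (1 - pA) * (1 - pB) + D)
    bad <- which(h < -1e-12 | h > 1 + 1e-12)
    if (length(bad))
        stop(sprintf(
            "infeasible (r2, frequency) combination: %s = %.4f outside [0,1]",
            names(h)[bad[1L]], h[bad[1L]]), call. = FALSE)
    pmin(pmax(h, 0), 1)
}

#' Construct a PlantedPairSpec
#'
#' @param indexRsid,partnerRsid variant ids.
#' @param pIndex,pPartner allele-1 (ALT) frequencies in (0,1).
#' @param r2Target target r-squared in [0,1].
#' @param dSign +1 or -1 (default +1).
#' @param posIndex,posPartner 1-based positions used in fixture bundles.
#' @return a [PlantedPairSpec-class]; infeasible combinations are rejected
#'   with the violated haplotype-frequency bound named.
#' @export
plantedPairSpec <- function(indexRsid, partnerRsid, pIndex, pPartner,
                            r2Target, dSign = 1, posIndex = 1L,
                            posPartner = 2L) {
    new("PlantedPairSpec", indexRsid = indexRsid, partnerRsid = partnerRsid,
        pIndex = pIndex, pPartner = pPartner, r2Target = r2Target,
        dSign = dSign, posIndex = as.integer(posIndex),
        posPartner = as.integer(posPartner))
}

#' Sample two-locus haplotypes at a target r-squared
#'
#' Draws \code{n} haplotypes from the four implied haplotype frequencies,
#' either multinomially (default) or by exact rounding of expected counts
#' (for deterministic tests).
#'
#' @param spec a [PlantedPairSpec-class].
#' @param n haplotype count.
#' @param seed optional RNG seed (local to the call).
#' @param exact logical; round expected counts instead of sampling.
#' @return list with \code{frequencies} (the four implied frequencies),
#'   \code{counts} (sampled counts summing to n) and \code{haplotypes}
#'   (n x 2 integer matrix of 0/1 alleles, columns index/partner).
#' @export
plantTwoLocusHaplotypes <- function(spec, n, seed = NULL, exact = FALSE) {
    h <- pairHaplotypeFrequencies(spec@pIndex, spec@pPartner,
                                  spec@r2Target, spec@dSign)
    draw <- function() {
        if (exact) {
            cnt <- round(h * n)
            # fix rounding drift on the largest class
            cnt[which.max(cnt)] <- cnt[which.max(cnt)] + (n - sum(cnt))
            cnt
        } else {
            as.vector(stats::rmultinom(1L, n, h))
        }
    }
    cnt <- if (is.null(seed)) draw() else .withSeed(seed, draw())
    names(cnt) <- names(h)
    combos <- rbind(c(1L, 1L), c(1L, 0L), c(0L, 1L), c(0L, 0L))
    haps <- combos[rep(1:4, cnt), , drop = FALSE]
    colnames(haps) <- c(spec@indexRsid, spec@partnerRsid)
    list(frequencies = h, counts = cnt, haplotypes = haps)
}

#' Blueprint helpers for fixture specs
#'
#' Plain-list blueprint constructors consumed by [fixtureSpec()]:
#' \code{geneBlueprint} lays out a coding gene (1-based CDS exon
#' coordinates; total length must be divisible by 3),
#' \code{trackBlueprint} places one peak either inside a gene's TSS window
#' (\code{placement = "tss"}) or in enhancer space (> 1.5 kb from every
#' TSS), and \code{pwmBlueprint} plants a motif consensus site in the
#' genome so that the named SNP's reference allele completes the consensus
#' and its alternate allele breaks it at \code{snp_offset}.
#'
#' @param gene_id,strand,exon_starts,exon_widths gene layout.
#' @return a named list.
#' @export
geneBlueprint <- function(gene_id, strand, exon_starts, exon_widths) {
    list(gene_id = gene_id, strand = strand,
         exon_starts = as.integer(exon_starts),
         exon_widths = as.integer(exon_widths))
}

#' @rdname geneBlueprint
#' @param name,class,placement,gene,offset,width,jitter,at peak placement:
#'   center = gene TSS + \code{offset} (or absolute position \code{at}),
#'   plus a uniform jitter of up to \code{jitter} bp.
#' @export
trackBlueprint <- function(name, class, placement = c("tss", "enhancer"),
                           gene = NULL, offset = 0L, width = 400L,
                           jitter = 0L, at = NULL) {
    placement <- match.arg(placement)
    list(name = name, class = class, placement = placement, gene = gene,
         offset = as.integer(offset), width = as.integer(width),
         jitter = as.integer(jitter),
         at = if (is.null(at)) NULL else as.integer(at))
}

#' @rdname geneBlueprint
#' @param consensus,snp_id,snp_offset,p_consensus motif planting: the
#'   consensus string written into the genome, the planted SNP, its 0-based
#'   offset inside the site, and the per-column consensus probability.
#' @export
pwmBlueprint <- function(name, consensus, snp_id, snp_offset,
                         p_consensus = 0.97) {
    stopifnot(snp_offset >= 0L, snp_offset < nchar(consensus))
    list(name = name, consensus = toupper(consensus), snp_id = snp_id,
         snp_offset = as.integer(snp_offset), p_consensus = p_consensus)
}

#' Construct a FixtureSpec
#'
#' @param plantedPairs list of [plantedPairSpec()] objects.
#' @param nHaplotypes even haplotype count (default 758, two per diploid
#'   individual of a 379-sample European-like reference panel).
#' @param chrom,chromLength the synthetic chromosome.
#' @param nBackgroundSnps independent background SNVs (no LD planted).
#' @param geneBlueprints,trackBlueprints,pwmBlueprints blueprint lists.
#' @param eqtlRows data.frame(snp, gene, p, tissue, source).
#' @param indexLoci data.frame(rsid, locus).
#' @param seed integer RNG seed; fixes the bundle byte-for-byte.
#' @return a [FixtureSpec-class].
#' @export
fixtureSpec <- function(plantedPairs, nHaplotypes = 758L, chrom = "chr1",
                        chromLength = 200000L, nBackgroundSnps = 100L,
                        geneBlueprints = list(), trackBlueprints = list(),
                        pwmBlueprints = list(),
                        eqtlRows = data.frame(snp = character(),
                                              gene = character(),
                                              p = numeric(),
                                              tissue = character(),
                                              source = character()),
                        indexLoci = NULL, seed = 1L) {
    if (is.null(indexLoci)) {
        idx <- unique(vapply(plantedPairs, function(p) p@indexRsid,
                             character(1)))
        indexLoci <- data.frame(rsid = idx,
                                locus = paste0("L", seq_along(idx)),
                                stringsAsFactors = FALSE)
    }
    new("FixtureSpec", nHaplotypes = as.integer(nHaplotypes), chrom = chrom,
        chromLength = as.integer(chromLength),
        plantedPairs = plantedPairs,
        nBackgroundSnps = as.integer(nBackgroundSnps),
        geneBlueprints = geneBlueprints, trackBlueprints = trackBlueprints,
        pwmBlueprints = pwmBlueprints, eqtlRows = eqtlRows,
        indexLoci = indexLoci, seed = as.integer(seed))
}

#' Build transcript models from a fixture spec
#'
#' One single-transcript coding gene per blueprint. Rejected if a gene's
#' CDS length is not divisible by 3 or if two genes overlap on a strand.
#'
#' @param spec a [FixtureSpec-class].
#' @return named list of [TranscriptModel-class] objects.
#' @export
makeGeneModels <- function(spec) {
    out <- list()
    spans <- list()
    for (g in spec@geneBlueprints) {
        if (sum(g$exon_widths) %% 3L != 0L)
            stop(sprintf("gene %s: CDS length %d is not a multiple of 3",
                         g$gene_id, sum(g$exon_widths)), call. = FALSE)
        ends <- g$exon_starts + g$exon_widths - 1L
        m <- transcriptModel(paste0(g$gene_id, ".t1"), g$gene_id,
                             spec@chrom, g$strand, g$exon_starts, ends)
        for (sp in spans)
            if (sp$strand == g$strand &&
                min(g$exon_starts) <= sp$end && max(ends) >= sp$start)
                stop(sprintf("gene %s overlaps %s on strand %s",
                             g$gene_id, sp$id, g$strand), call. = FALSE)
        spans[[length(spans) + 1L]] <-
            list(id = g$gene_id, strand = g$strand,
                 start = min(g$exon_starts), end = max(ends))
        out[[m@transcriptId]] <- m
    }
    out
}

.tssWindowBounds <- function(tss, halfWidth = 1500L) {
    c(tss - halfWidth, tss + halfWidth - 1L)  # 1-based closed
}

#' Place peak tracks from a fixture spec
#'
#' Peaks with \code{placement = "tss"} must lie fully inside the 3 kb TSS
#' window of their gene; peaks with \code{placement = "enhancer"} must lie
#' entirely more than 1.5 kb from every TSS. Impossible placements are
#' rejected with a named failure. Blueprints sharing a track name merge
#' into one track (their classes must agree).
#'
#' @param spec a [FixtureSpec-class].
#' @param models output of [makeGeneModels()].
#' @param seed RNG seed for jitter (local to the call).
#' @return named list of [AnnotationTrack-class] objects.
#' @export
makePeakTracks <- function(spec, models, seed = spec@seed) {
    if (!length(spec@trackBlueprints)) return(list())
    tt <- tssTable(models)
    .withSeed(seed, {
        peaks <- list()
        for (b in spec@trackBlueprints) {
            if (is.null(b$at)) {
                if (is.null(b$gene) || !b$gene %in% tt$gene_id)
                    stop(sprintf("track %s: placement references unknown gene '%s'",
                                 b$name, b$gene %||% "<missing>"), call. = FALSE)
                tss <- tt$tss[match(b$gene, tt$gene_id)]
                centre <- tss + b$offset
            } else centre <- b$at
            if (b$jitter > 0L)
                centre <- centre + sample.int(2L * b$jitter + 1L, 1L) -
                    b$jitter - 1L
            lo <- centre - b$width %/% 2L
            hi <- lo + b$width - 1L
            if (b$placement == "tss") {
                wb <- .tssWindowBounds(tt$tss[match(b$gene, tt$gene_id)])
                if (lo < wb[1L] || hi > wb[2L])
                    stop(sprintf(
                        "track %s: peak [%d,%d] does not fit inside the TSS window [%d,%d] of %s",
                        b$name, lo, hi, wb[1L], wb[2L], b$gene), call. = FALSE)
            } else {
                for (k in seq_len(nrow(tt))) {
                    wb <- .tssWindowBounds(tt$tss[k])
                    if (lo <= wb[2L] && hi >= wb[1L])
                        stop(sprintf(
                            "track %s: enhancer peak [%d,%d] is within 1.5 kb of the TSS of %s",
                            b$name, lo, hi, tt$gene_id[k]), call. = FALSE)
                }
            }
            if (lo < 1L || hi > spec@chromLength)
                stop(sprintf("track %s: peak [%d,%d] falls off the chromosome",
                             b$name, lo, hi), call. = FALSE)
            peaks[[b$name]]$class <- c(peaks[[b$name]]$class, b$class)
            peaks[[b$name]]$lo <- c(peaks[[b$name]]$lo, lo)
            peaks[[b$name]]$hi <- c(peaks[[b$name]]$hi, hi)
        }
        out <- list()
        for (nm in names(peaks)) {
            cls <- unique(peaks[[nm]]$class)
            if (length(cls) > 1L)
                stop(sprintf("track %s: conflicting classes %s", nm,
                             paste(cls, collapse = ", ")), call. = FALSE)
            out[[nm]] <- annotationTrack(
                nm, cls, GRanges(spec@chrom,
                                 IRanges(peaks[[nm]]$lo, peaks[[nm]]$hi)))
        }
        out
    })
}

#' Random genome with planted motif consensus sites
#'
#' Draws an i.i.d. uniform A/C/G/T chromosome, then writes each PWM
#' blueprint's consensus so that the planted SNP's position carries the
#' consensus base (the reference allele completes the motif) and picks a
#' minimum-probability alternate allele that breaks it. Sites falling off
#' the chromosome or overlapping another planted SNP are rejected.
#'
#' @param spec a [FixtureSpec-class].
#' @param seed RNG seed (local to the call).
#' @return list with \code{genome} (\code{DNAStringSet}), \code{motifs}
#'   (list of [MotifMatrix-class]), and \code{plantings} (data.frame of
#'   name, snp_id, site_start, ref, alt, consensus).
#' @export
makePwmSet <- function(spec, seed = spec@seed) {
    snp_pos <- c()
    for (p in spec@plantedPairs) {
        snp_pos[p@indexRsid] <- p@posIndex
        snp_pos[p@partnerRsid] <- p@posPartner
    }
    .withSeed(seed, {
        bases <- sample(c("A", "C", "G", "T"), spec@chromLength,
                        replace = TRUE)
        motifs <- list()
        plantings <- NULL
        for (b in spec@pwmBlueprints) {
            if (!b$snp_id %in% names(snp_pos))
                stop(sprintf("pwm %s: planted SNP '%s' does not exist",
                             b$name, b$snp_id), call. = FALSE)
            L <- nchar(b$consensus)
            pos <- snp_pos[[b$snp_id]]
            site_start <- pos - b$snp_offset
            site_end <- site_start + L - 1L
            if (site_start < 1L || site_end > spec@chromLength)
                stop(sprintf(
                    "pwm %s: consensus longer than available sequence at %d",
                    b$name, pos), call. = FALSE)
            other <- snp_pos[names(snp_pos) != b$snp_id]
            clash <- other[other >= site_start & other <= site_end]
            if (length(clash))
                stop(sprintf("pwm %s: consensus site overlaps planted SNP %s",
                             b$name, names(clash)[1L]), call. = FALSE)
            cons <- strsplit(b$consensus, "")[[1L]]
            bases[site_start:site_end] <- cons
            ref <- cons[b$snp_offset + 1L]
            alt <- setdiff(c("A", "C", "G", "T"), ref)[1L]
            if (is.null(motifs[[b$name]])) {
                probs <- matrix((1 - b$p_consensus) / 3, nrow = 4L,
                                ncol = L, dimnames = list(c("A", "C", "G", "T"),
                                                          NULL))
                probs[cbind(match(cons, c("A", "C", "G", "T")),
                            seq_len(L))] <- b$p_consensus
                motifs[[b$name]] <- MotifMatrix(b$name, probs,
                                                source = "other")
            }
            plantings <- rbind(plantings, data.frame(
                name = b$name, snp_id = b$snp_id,
                site_start = site_start, snp_offset = b$snp_offset,
                ref = ref, alt = alt, consensus = b$consensus,
                stringsAsFactors = FALSE))
        }
        genome <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
        names(genome) <- spec@chrom
        list(genome = genome, motifs = motifs, plantings = plantings)
    })
}

.sampleBundleHaplotypes <- function(spec, seed) {
    n <- spec@nHaplotypes
    .withSeed(seed, {
        idx_rsids <- unique(vapply(spec@plantedPairs,
                                   function(p) p@indexRsid, character(1)))
        haps <- list()
        for (ir in idx_rsids) {
            pr <- Filter(function(p) p@indexRsid == ir, spec@plantedPairs)
            pI <- pr[[1L]]@pIndex
            x <- stats::rbinom(n, 1L, pI)
            haps[[ir]] <- x
            for (p in pr) {
                h <- pairHaplotypeFrequencies(p@pIndex, p@pPartner,
                                              p@r2Target, p@dSign)
                p1 <- h["hAB"] / p@pIndex          # P(partner=1 | index=1)
                p0 <- h["haB"] / (1 - p@pIndex)    # P(partner=1 | index=0)
                haps[[p@partnerRsid]] <-
                    stats::rbinom(n, 1L, ifelse(x == 1L, p1, p0))
            }
        }
        haps
    })
}

#' Write a complete fixture bundle
#'
#' Emits, under \code{dir}: \code{genome.fa}, \code{genotypes.vcf} (phased
#' GT), \code{models.gtf}, \code{tracks/<name>.bed}, \code{motifs.jaspar},
#' \code{motifs.meme}, \code{eqtl.tsv}, \code{index_snps.tsv} and
#' \code{manifest.json} recording the seed and the planted ground truth.
#' Identical spec + seed produce byte-identical bundles.
#'
#' @param spec a [FixtureSpec-class].
#' @param dir output directory (created if needed).
#' @return the manifest, invisibly (as an R list).
#' @export
writeBundle <- function(spec, dir) {
    validObject(spec)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    dir.create(file.path(dir, "tracks"), showWarnings = FALSE)

    models <- makeGeneModels(spec)
    pw <- makePwmSet(spec, seed = .subSeed(spec@seed, 1L))
    tracks <- makePeakTracks(spec, models, seed = .subSeed(spec@seed, 2L))
    genome <- pw$genome

    ## assemble the SNP table ------------------------------------------------
    snp_pos <- c()
    for (p in spec@plantedPairs) {
        snp_pos[p@indexRsid] <- p@posIndex
        snp_pos[p@partnerRsid] <- p@posPartner
    }
    gseq <- strsplit(as.character(genome[[spec@chrom]]), "")[[1L]]
    planted <- data.frame(rsid = names(snp_pos), pos = unname(snp_pos),
                          stringsAsFactors = FALSE)
    planted$ref <- gseq[planted$pos]
    planted$alt <- NA_character_
    if (!is.null(pw$plantings)) {
        m <- match(planted$rsid, pw$plantings$snp_id)
        planted$alt <- ifelse(is.na(m), NA, pw$plantings$alt[m])
    }
    bg <- .withSeed(.subSeed(spec@seed, 3L), {
        avoid <- planted$pos
        cand <- setdiff(seq_len(spec@chromLength), avoid)
        pos <- sort(sample(cand, spec@nBackgroundSnps))
        data.frame(rsid = sprintf("rs_bg%04d", seq_along(pos)), pos = pos,
                   ref = gseq[pos],
                   alt = vapply(gseq[pos], function(r)
                       sample(setdiff(c("A", "C", "G", "T"), r), 1L),
                       character(1)),
                   freq = stats::runif(length(pos), 0.05, 0.5),
                   stringsAsFactors = FALSE)
    })
    planted$alt[is.na(planted$alt)] <- .withSeed(
        .subSeed(spec@seed, 4L),
        vapply(planted$ref[is.na(planted$alt)], function(r)
            sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1)))

    ## haplotypes ------------------------------------------------------------
    hp <- .sampleBundleHaplotypes(spec, seed = .subSeed(spec@seed, 5L))
    bg_h <- .withSeed(.subSeed(spec@seed, 6L), {
        lapply(stats::setNames(bg$freq, bg$rsid), function(f)
            stats::rbinom(spec@nHaplotypes, 1L, f))
    })
    allsnps <- rbind(planted[, c("rsid", "pos", "ref", "alt")],
                     bg[, c("rsid", "pos", "ref", "alt")])
    allsnps <- allsnps[order(allsnps$pos), , drop = FALSE]
    hapmat <- do.call(rbind, c(hp, bg_h))[allsnps$rsid, , drop = FALSE]

    ## write files -----------------------------------------------------------
    Biostrings::writeXStringSet(genome, file.path(dir, "genome.fa"))
    .writeBundleVcf(file.path(dir, "genotypes.vcf"), spec, allsnps, hapmat)
    .writeBundleGtf(file.path(dir, "models.gtf"), spec, models)
    track_files <- character()
    for (nm in names(tracks)) {
        f <- file.path(dir, "tracks", paste0(nm, ".bed"))
        .writeBundleBed(f, nm, trackRanges(tracks[[nm]]))
        track_files[nm] <- f
    }
    if (length(pw$motifs)) {
        .writeJaspar(file.path(dir, "motifs.jaspar"), pw$motifs)
        .writeMeme(file.path(dir, "motifs.meme"), pw$motifs)
    }
    eq <- spec@eqtlRows
    writeLines(c("snp\tgene\tp\ttissue\tsource",
                 if (nrow(eq)) paste(eq$snp, eq$gene,
                                     format(eq$p, scientific = TRUE,
                                            digits = 3, trim = TRUE),
                                     eq$tissue, eq$source, sep = "\t")),
               file.path(dir, "eqtl.tsv"))
    idx <- spec@indexLoci
    idx$pos <- snp_pos[idx$rsid]
    writeLines(c("rsid\tchrom\tpos\tlocus",
                 paste(idx$rsid, spec@chrom, idx$pos, idx$locus, sep = "\t")),
               file.path(dir, "index_snps.tsv"))

    manifest <- .bundleManifest(spec, models, tracks, pw, allsnps)
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(manifest)
}

.writeBundleVcf <- function(path, spec, snps, hapmat) {
    nind <- spec@nHaplotypes %/% 2L
    samples <- sprintf("S%04d", seq_len(nind))
    gts <- apply(hapmat, 1L, function(h) {
        paste(h[seq(1L, length(h), 2L)], h[seq(2L, length(h), 2L)],
              sep = "|", collapse = "\t")
    })
    header <- c("##fileformat=VCFv4.2",
                sprintf("##contig=<ID=%s,length=%d>", spec@chrom,
                        spec@chromLength),
                '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
                paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", samples), collapse = "\t"))
    body <- paste(spec@chrom, snps$pos, snps$rsid, snps$ref, snps$alt,
                  ".", "PASS", ".", "GT", gts, sep = "\t")
    writeLines(c(header, body), path)
}

.writeBundleGtf <- function(path, spec, models) {
    lines <- character()
    for (m in models) {
        attr_g <- sprintf('gene_id "%s";', m@geneId)
        attr_t <- sprintf('gene_id "%s"; transcript_id "%s";', m@geneId,
                          m@transcriptId)
        lines <- c(lines, paste(spec@chrom, "synth", "gene", m@txStart,
                                m@txEnd, ".", m@strand, ".", attr_g,
                                sep = "\t"))
        lines <- c(lines, paste(spec@chrom, "synth", "transcript", m@txStart,
                                m@txEnd, ".", m@strand, ".", attr_t,
                                sep = "\t"))
        ex <- m@cdsExons
        ord <- if (m@strand == "+") seq_along(ex) else rev(seq_along(ex))
        cum <- 0L
        for (i in ord) {
            frame <- (3L - cum %% 3L) %% 3L
            lines <- c(lines, paste(spec@chrom, "synth", "exon", start(ex)[i],
                                    end(ex)[i], ".", m@strand, ".", attr_t,
                                    sep = "\t"))
            lines <- c(lines, paste(spec@chrom, "synth", "CDS", start(ex)[i],
                                    end(ex)[i], ".", m@strand, frame, attr_t,
                                    sep = "\t"))
            cum <- cum + width(ex)[i]
        }
    }
    writeLines(lines, path)
}

.writeBundleBed <- function(path, name, gr) {
    writeLines(paste(as.character(seqnames(gr)), start(gr) - 1L, end(gr),
                     paste0(name, "_peak", seq_along(gr)), sep = "\t"),
               path)
}

.writeJaspar <- function(path, motifs) {
    lines <- character()
    for (m in motifs) {
        counts <- round(motifProbs(m) * 100)
        lines <- c(lines, sprintf(">%s %s", motifName(m), motifName(m)))
        for (b in c("A", "C", "G", "T"))
            lines <- c(lines, sprintf("%s  [ %s ]", b,
                                      paste(counts[b, ], collapse = " ")))
    }
    writeLines(lines, path)
}

.writeMeme <- function(path, motifs) {
    lines <- c("MEME version 4", "", "ALPHABET= ACGT", "",
               "Background letter frequencies", "A 0.25 C 0.25 G 0.25 T 0.25",
               "")
    for (m in motifs) {
        p <- motifProbs(m)
        lines <- c(lines, sprintf("MOTIF %s", motifName(m)),
                   sprintf("letter-probability matrix: alength= 4 w= %d nsites= 100 E= 0",
                           ncol(p)),
                   vapply(seq_len(ncol(p)), function(j)
                       paste(sprintf("%.6f", p[, j]), collapse = " "),
                       character(1)),
                   "")
    }
    writeLines(lines, path)
}

.bundleManifest <- function(spec, models, tracks, pw, allsnps) {
    tt <- if (length(models)) tssTable(models) else NULL
    exon_iv <- if (length(models))
        do.call(rbind, lapply(models, function(m)
            cbind(start(m@cdsExons), end(m@cdsExons)))) else NULL
    prom_iv <- NULL; enh_iv <- NULL
    track_iv <- list()
    for (nm in names(tracks)) {
        iv <- cbind(start(trackRanges(tracks[[nm]])),
                    end(trackRanges(tracks[[nm]])))
        track_iv[[nm]] <- list(class = trackClass(tracks[[nm]]),
                               intervals = iv)
        if (.isPromoterClass(trackClass(tracks[[nm]])))
            prom_iv <- rbind(prom_iv, iv)
        if (.isEnhancerClass(trackClass(tracks[[nm]])))
            enh_iv <- rbind(enh_iv, iv)
    }
    inIv <- function(pos, iv) !is.null(iv) &&
        any(pos >= iv[, 1L] & pos <= iv[, 2L])
    truth <- list()
    for (p in spec@plantedPairs) {
        pos <- p@posPartner
        cats <- character()
        if (inIv(pos, exon_iv)) cats <- c(cats, "exon")
        in_tss_win <- FALSE; qualifies <- FALSE
        if (!is.null(tt)) for (k in seq_len(nrow(tt))) {
            wb <- .tssWindowBounds(tt$tss[k])
            if (pos >= wb[1L] && pos <= wb[2L]) {
                in_tss_win <- TRUE
                # window retained iff a promoter-class peak intersects it
                if (!is.null(prom_iv) &&
                    any(prom_iv[, 1L] <= wb[2L] & prom_iv[, 2L] >= wb[1L]))
                    qualifies <- TRUE
            }
        }
        if (in_tss_win && qualifies && inIv(pos, prom_iv))
            cats <- c(cats, "tss")
        if (!in_tss_win && !inIv(pos, exon_iv) && inIv(pos, enh_iv))
            cats <- c(cats, "enhancer")
        truth[[p@partnerRsid]] <- list(
            r2_target = p@r2Target, high_ld = p@r2Target >= 0.5,
            categories = cats,
            pair_frequencies = as.list(pairHaplotypeFrequencies(
                p@pIndex, p@pPartner, p@r2Target, p@dSign)))
    }
    high <- names(Filter(function(x) x$high_ld, truth))
    cats_high <- lapply(truth[high], `[[`, "categories")
    per <- c(exon = sum(vapply(cats_high, function(x) "exon" %in% x, TRUE)),
             tss = sum(vapply(cats_high, function(x) "tss" %in% x, TRUE)),
             enhancer = sum(vapply(cats_high, function(x)
                 "enhancer" %in% x, TRUE)))
    eq <- spec@eqtlRows
    eq_expected <- if (nrow(eq))
        sort(unique(eq$snp[eq$p < 1e-5 & eq$snp %in% high])) else character()
    motif_truth <- list()
    if (!is.null(pw$plantings))
        for (nm in unique(pw$plantings$name))
            motif_truth[[nm]] <-
                sort(pw$plantings$snp_id[pw$plantings$name == nm])
    list(seed = spec@seed, chrom = spec@chrom, chrom_length = spec@chromLength,
         n_haplotypes = spec@nHaplotypes,
         pairs = lapply(spec@plantedPairs, function(p) list(
             index_rsid = p@indexRsid, partner_rsid = p@partnerRsid,
             p_index = p@pIndex, p_partner = p@pPartner,
             r2_target = p@r2Target, d_sign = p@dSign,
             pos_index = p@posIndex, pos_partner = p@posPartner)),
         snp_truth = truth,
         high_ld_partners = high,
         per_category = as.list(per),
         multi_category = sum(vapply(cats_high,
                                     function(x) length(x) > 1L, TRUE)),
         union = sum(vapply(cats_high, function(x) length(x) >= 1L, TRUE)),
         motif_affected_snps = motif_truth,
         eqtl_expected_retained = eq_expected,
         genes = if (is.null(tt)) list() else
             lapply(seq_len(nrow(tt)), function(k)
                 list(gene_id = tt$gene_id[k], tss = tt$tss[k],
                      strand = tt$strand[k])),
         tracks = lapply(track_iv, function(t)
             list(class = t$class,
                  intervals = lapply(seq_len(nrow(t$intervals)), function(i)
                      c(t$intervals[i, 1L], t$intervals[i, 2L])))),
         n_background_snps = spec@nBackgroundSnps)
}

#' Read a bundle manifest
#' @param dir bundle directory.
#' @return the manifest as an R list.
#' @export
readBundleManifest <- function(dir) {
    jsonlite::fromJSON(file.path(dir, "manifest.json"),
                       simplifyVector = TRUE)
}

#' A ready-made demonstration fixture spec
#'
#' A 200 kb chromosome with three coding genes, one GWAS index SNP at
#' position 100,000 and five planted partner SNPs: a dual-category
#' exon+TSS SNP (r2 0.80), a TSS SNP (0.75), two enhancer SNPs (0.70,
#' 0.65) that also break planted 16-bp motif consensus sites, and one
#' low-LD partner (0.15). Panel size follows a 379-individual
#' European-like reference panel (758 haplotypes). The planted r2 values
#' sit at least five standard errors from the 0.5 high-LD cutoff so the
#' designed strata are recovered for essentially every seed.
#'
#' @param seed integer seed (default 20130522).
#' @return a [FixtureSpec-class].
#' @export
demoFixtureSpec <- function(seed = 20130522L) {
    pairs <- list(
        plantedPairSpec("rs_idx1", "rsP1", 0.4, 0.40, 0.80,
                        posIndex = 100000L, posPartner = 40100L),
        plantedPairSpec("rs_idx1", "rsP2", 0.4, 0.35, 0.75,
                        posIndex = 100000L, posPartner = 139000L),
        plantedPairSpec("rs_idx1", "rsP3", 0.4, 0.40, 0.70,
                        posIndex = 100000L, posPartner = 120000L),
        plantedPairSpec("rs_idx1", "rsP4", 0.4, 0.45, 0.65,
                        posIndex = 100000L, posPartner = 60000L),
        plantedPairSpec("rs_idx1", "rsP5", 0.4, 0.30, 0.15,
                        posIndex = 100000L, posPartner = 70000L))
    genes <- list(
        geneBlueprint("GENE1", "+", c(40000L, 41400L), c(300L, 300L)),
        geneBlueprint("GENE2", "-", 89101L, 900L),
        geneBlueprint("GENE3", "+", 140000L, 600L))
    tracks <- list(
        trackBlueprint("DNase", "open_chromatin", "tss", gene = "GENE1",
                       offset = 100L, width = 400L),
        trackBlueprint("DNase", "open_chromatin", "enhancer", at = 120000L,
                       width = 400L),
        trackBlueprint("DNase", "open_chromatin", "enhancer", at = 60000L,
                       width = 200L),
        trackBlueprint("H3K4me3", "promoter_mark", "tss", gene = "GENE3",
                       offset = -1000L, width = 300L),
        trackBlueprint("H3K4me1", "enhancer_mark", "enhancer", at = 120000L,
                       width = 600L),
        trackBlueprint("FAIRE", "open_chromatin", "enhancer", at = 60000L,
                       width = 300L),
        trackBlueprint("H3K27ac", "promoter_enhancer_mark", "enhancer",
                       at = 70000L, width = 400L))
    pwms <- list(
        pwmBlueprint("MOTIF_GCBOX", "GGGGCGGGGGCGGGGC", "rsP3", 5L),
        pwmBlueprint("MOTIF_GCBOX", "GGGGCGGGGGCGGGGC", "rsP4", 5L),
        pwmBlueprint("MOTIF_EBOX", "CACGTGTCAGCATGCC", "rsP2", 7L))
    eqtl <- data.frame(
        snp = c("rsP1", "rsP3", "rsP4", "rsP5", "rs_bg0001"),
        gene = c("GENE1", "GENE2", "GENE2", "GENE3", "GENE1"),
        p = c(2.46e-6, 1e-5, 3e-7, 1e-9, 1e-8),
        tissue = c("ER+ breast tumor", "breast", "breast", "breast",
                   "breast"),
        source = c("studyA", "studyA", "studyB", "studyA", "studyB"),
        stringsAsFactors = FALSE)
    fixtureSpec(pairs, nHaplotypes = 758L, chrom = "chr1",
                chromLength = 200000L, nBackgroundSnps = 120L,
                geneBlueprints = genes, trackBlueprints = tracks,
                pwmBlueprints = pwms, eqtlRows = eqtl, seed = seed)
}
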
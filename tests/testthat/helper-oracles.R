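# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: LD via literal haplotype-count enumeration and
# squared Pearson correlation, intervals via per-base membership vectors,
# codons via seqinr's translator, PWM tails via exhaustive window
# enumeration.

# literal haplotype-counting LD oracle
oracle_ld <- function(x, y) {
    n <- length(x)
    cnt <- table(factor(paste0(x, y), levels = c("11", "10", "01", "00")))
    pAB <- cnt[["11"]] / n
    pA <- sum(x) / n
    pB <- sum(y) / n
    D <- pAB - pA * pB
    r2 <- unname(cor(x, y)^2)
    dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
            else min(pA * pB, (1 - pA) * (1 - pB))
    list(r2 = r2, D = D, Dprime = if (D == 0) 0 else abs(D) / dmax)
}

random_small_panel <- function(m, n2) {
    mat <- matrix(sample(0:1, m * n2, replace = TRUE), nrow = m)
    HaplotypePanel(mat, "chr1", seq_len(m) * 10L, paste0("s", seq_len(m)),
                   ref = rep("A", m), alt = rep("G", m))
}

# per-base interval membership over a small chromosome
oracle_membership <- function(chrom_len, starts, ends) {
    v <- logical(chrom_len)
    for (k in seq_along(starts)) v[starts[k]:ends[k]] <- TRUE
    v
}

# brute-force per-base classifier mirroring the published category rules
oracle_classify <- function(pos, chrom_len, exon_iv, genes, tracks,
                            half = 1500L) {
    in_iv <- function(p, iv) nrow(iv) > 0 &&
        any(p >= iv[, 1] & p <= iv[, 2])
    exon <- in_iv(pos, exon_iv)
    prom_iv <- do.call(rbind, c(list(matrix(numeric(0), ncol = 2)),
        lapply(tracks, function(t) if (t$class %in%
            c("open_chromatin", "promoter_mark", "promoter_enhancer_mark"))
            t$iv)))
    enh_iv <- do.call(rbind, c(list(matrix(numeric(0), ncol = 2)),
        lapply(tracks, function(t) if (t$class %in%
            c("open_chromatin", "enhancer_mark", "promoter_enhancer_mark"))
            t$iv)))
    in_win <- FALSE; qualifies <- FALSE
    for (g in genes) {
        wb <- c(g$tss - half, g$tss + half - 1L)
        if (pos >= wb[1] && pos <= wb[2]) {
            in_win <- TRUE
            if (nrow(prom_iv) &&
                any(prom_iv[, 1] <= wb[2] & prom_iv[, 2] >= wb[1]))
                qualifies <- TRUE
        }
    }
    tss <- in_win && qualifies && in_iv(pos, prom_iv)
    enh <- !in_win && !exon && pos >= 1 && pos <= chrom_len &&
        in_iv(pos, enh_iv)
    c(exon = exon, tss = tss, enhancer = enh)
}

# codon-effect oracle on top of seqinr's translator
oracle_codon_effect <- function(ref_codon, alt_codon, codon_index) {
    ref_aa <- seqinr::translate(strsplit(ref_codon, "")[[1]])
    alt_aa <- seqinr::translate(strsplit(alt_codon, "")[[1]])
    if (ref_aa == alt_aa) "synonymous"
    else if (codon_index == 1 && ref_aa == "M") "start_loss"
    else if (alt_aa == "*") "nonsense"
    else if (ref_aa == "*") "stop_loss"
    else "missense"
}

# exhaustive enumeration of all 4^L windows: exact discretized-score tail
oracle_pwm_tail <- function(pwm, binWidth = 0.01) {
    L <- motifLength(pwm)
    lod <- log2(sweep(motifProbs(pwm), 1, motifBackground(pwm), "/"))
    bins <- ceiling(lod / binWidth - 1e-12)
    grid <- as.matrix(expand.grid(rep(list(1:4), L)))
    disc <- integer(nrow(grid))
    raw <- numeric(nrow(grid))
    prob <- rep(1, nrow(grid))
    bg <- motifBackground(pwm)
    for (j in seq_len(L)) {
        disc <- disc + bins[cbind(grid[, j], j)]
        raw <- raw + lod[cbind(grid[, j], j)]
        prob <- prob * bg[grid[, j]]
    }
    list(disc = disc, raw = raw, prob = prob)
}

random_pwm <- function(L, name = "rnd") {
    p <- matrix(stats::rgamma(4 * L, 1) + 0.02, nrow = 4)
    rownames(p) <- c("A", "C", "G", "T")
    MotifMatrix(name, sweep(p, 2, colSums(p), "/"))
}
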
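uniform_bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)

two_col_pwm <- function() {
    p <- matrix(0.1, 4, 2, dimnames = list(c("A", "C", "G", "T"), NULL))
    p["A", 1] <- 0.7
    p["C", 2] <- 0.7
    MotifMatrix("two", p)
}

test_that("log-odds scores follow the PWM definition", {
    flat <- MotifMatrix("flat", matrix(0.25, 4, 5,
                                       dimnames = list(c("A", "C", "G", "T"),
                                                       NULL)))
    expect_equal(lodScore(flat, "ACGTA"), 0)
    pwm <- two_col_pwm()
    expect_equal(lodScore(pwm, "AC"), 2 * log2(0.7 / 0.25), tolerance = 1e-12)
    expect_error(lodScore(pwm, "AN"), "ambiguous")
    # the per-column argmax window attains the maximum over all windows
    set.seed(55)
    for (L in 2:4) {
        rp <- random_pwm(L)
        o <- oracle_pwm_tail(rp)
        expect_equal(motifMaxScore(rp), max(o$raw), tolerance = 1e-9)
    }
})

test_that("motif files round-trip through the JASPAR and MEME readers", {
    d <- demo_bundle_dir()
    jm <- readJasparMotifs(file.path(d, "motifs.jaspar"))
    mm <- readMemeMotifs(file.path(d, "motifs.meme"))
    expect_setequal(names(jm), c("MOTIF_GCBOX", "MOTIF_EBOX"))
    expect_setequal(names(mm), names(jm))
    for (nm in names(jm)) {
        expect_equal(colSums(motifProbs(jm[[nm]])),
                     rep(1, motifLength(jm[[nm]])), tolerance = 1e-9,
                     ignore_attr = TRUE)
        # same consensus through both formats
        expect_identical(unname(apply(motifProbs(jm[[nm]]), 2, which.max)),
                         unname(apply(motifProbs(mm[[nm]]), 2, which.max)))
    }
})

test_that("allele scanning finds per-allele best windows and errors on ref mismatch", {
    # genome with a planted consensus for a sharp 6-mer
    p <- matrix(0.03, 4, 6, dimnames = list(c("A", "C", "G", "T"), NULL))
    cons <- c("G", "G", "C", "G", "T", "T")
    for (j in 1:6) p[cons[j], j] <- 0.91
    pwm <- MotifMatrix("sharp", p)
    genome <- Biostrings::DNAStringSet("AAAAAAGGCGTTAAAAAA")
    names(genome) <- "chrM"
    snp <- list(rsid = "s1", chrom = "chrM", pos = 9L, ref = "C", alt = "T")
    hit <- scanAlleles(pwm, genome, snp)
    expect_equal(hit$best_lod_ref, motifMaxScore(pwm), tolerance = 1e-9)
    # alternate allele breaks exactly one column
    expect_equal(hit$delta_lod, log2(0.03 / 0.91), tolerance = 1e-9)
    expect_equal(hit$best_offset, 2L)
    # antisymmetry: swapping ref and alt negates delta
    genome2 <- Biostrings::DNAStringSet("AAAAAAGGTGTTAAAAAA")
    names(genome2) <- "chrM"
    hit2 <- scanAlleles(pwm, genome2,
                        list(rsid = "s1", chrom = "chrM", pos = 9L,
                             ref = "T", alt = "C"))
    expect_equal(hit2$delta_lod, -hit$delta_lod, tolerance = 1e-9)
    expect_error(scanAlleles(pwm, genome,
                             list(rsid = "s1", chrom = "chrM", pos = 9L,
                                  ref = "G", alt = "T")),
                 "ref allele mismatch")
})

test_that("scanning is reverse-complement invariant and strand-symmetric", {
    set.seed(66)
    pwm <- random_pwm(5, "rc")
    genome <- Biostrings::DNAStringSet(paste(
        sample(c("A", "C", "G", "T"), 40, replace = TRUE), collapse = ""))
    names(genome) <- "chrM"
    pos <- 20L
    ref <- as.character(Biostrings::subseq(genome[[1]], pos, pos))
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    hit <- scanAlleles(pwm, genome, list(rsid = "x", chrom = "chrM",
                                         pos = pos, ref = ref, alt = alt))
    # reverse-complement the genome and the PWM: identical best scores
    rcg <- Biostrings::reverseComplement(genome)
    names(rcg) <- "chrM"
    rcpwm <- LDannotate:::.revcompMotif(pwm)
    rcpos <- 40L - pos + 1L
    rchit <- scanAlleles(rcpwm, rcg,
                         list(rsid = "x", chrom = "chrM", pos = rcpos,
                              ref = LDannotate:::.revcomp(ref),
                              alt = LDannotate:::.revcomp(alt)))
    expect_equal(rchit$best_lod_ref, hit$best_lod_ref, tolerance = 1e-9)
    expect_equal(rchit$best_lod_alt, hit$best_lod_alt, tolerance = 1e-9)
    expect_equal(rchit$p_ref, hit$p_ref, tolerance = 1e-12)
    # palindromic PWM scores both strands identically
    pp <- matrix(0.1, 4, 4, dimnames = list(c("A", "C", "G", "T"), NULL))
    pp["A", 1] <- pp["C", 2] <- pp["G", 3] <- pp["T", 4] <- 0.7
    pal <- MotifMatrix("pal", pp)  # consensus ACGT is its own RC
    w <- "ACGT"
    expect_equal(lodScore(pal, w), lodScore(pal, LDannotate:::.revcomp(w)),
                 tolerance = 1e-12)
})

test_that("DP p-values equal exhaustive enumeration and are monotone", {
    set.seed(88)
    for (rep in 1:10) {
        pwm <- random_pwm(sample(2:5, 1))
        o <- oracle_pwm_tail(pwm)
        # spot-check the public function at attainable window scores
        sc <- sample(o$raw, 8)
        for (s in sc) {
            t <- ceiling(s / 0.01 - 1e-12)
            expect_equal(scorePvalue(pwm, s), sum(o$prob[o$disc >= t]),
                         tolerance = 1e-9)
        }
        # monotone: higher score never has larger p
        ss <- sort(sample(o$raw, 5))
        ps <- vapply(ss, function(s) scorePvalue(pwm, s), numeric(1))
        expect_true(all(diff(ps) <= 1e-12))
        # guaranteed upper bound on the true tail
        s0 <- stats::median(o$raw)
        expect_gte(scorePvalue(pwm, s0) + 1e-12, sum(o$prob[o$raw >= s0]))
    }
    # boundary behaviour
    pwm <- two_col_pwm()
    o <- oracle_pwm_tail(pwm)
    expect_equal(scorePvalue(pwm, min(o$raw)), 1)
    pmax_attain <- scorePvalue(pwm, max(o$raw) + 1)
    expect_gt(pmax_attain, 0)
    expect_lte(pmax_attain, sum(o$prob[o$disc == max(o$disc)]) + 1e-12)
})

test_that("affected-RE decisions apply the LOD-or-p rule with nonzero delta", {
    hit <- S4Vectors::DataFrame(best_lod_ref = 6.2, best_lod_alt = 3.1,
                                delta_lod = -3.1, p_ref = 0.01, p_alt = 0.2)
    d <- affectedRE(hit)
    expect_true(d$affected)
    expect_identical(d$rule, "lod")
    # both alleles below both thresholds
    low <- S4Vectors::DataFrame(best_lod_ref = 1, best_lod_alt = 0.5,
                                delta_lod = -0.5, p_ref = 0.3, p_alt = 0.6)
    expect_false(affectedRE(low)$affected)
    # high score but identical alleles is not a disruption
    same <- S4Vectors::DataFrame(best_lod_ref = 9, best_lod_alt = 9,
                                 delta_lod = 0, p_ref = 1e-6, p_alt = 1e-6)
    expect_false(affectedRE(same)$affected)
    # p-value rule alone suffices
    pv <- S4Vectors::DataFrame(best_lod_ref = 4, best_lod_alt = 2,
                               delta_lod = -2, p_ref = 5e-5, p_alt = 0.2)
    expect_identical(affectedRE(pv)$rule, "pvalue")
})

test_that("TF ranking tallies distinct SNPs and loci with stable tie-breaks", {
    hits <- S4Vectors::DataFrame(
        pwm_name = c(rep("SP1", 7), rep("EGR1", 3), "ZNF1"),
        rsid = c(paste0("s", 1:6), "s1", "s7", "s8", "s8", "s9"))
    loci <- setNames(c("L1", "L1", "L2", "L3", "L4", "L5", "L6", "L7", "L8"),
                     paste0("s", 1:9))
    rk <- rankTFs(hits, loci)
    # brute-force tally oracle
    expect_identical(rk$motif, c("SP1", "EGR1", "ZNF1"))
    expect_identical(rk$n_snps, c(6L, 2L, 1L))   # s1 counted once for SP1
    expect_identical(rk$n_loci, c(5L, 2L, 1L))   # 6 SNPs from 5 risk loci
    expect_identical(rk$rank, 1:3)
    expect_true(all(rk$n_loci <= rk$n_snps))
    # minimum-SNP floor for report tables
    expect_identical(rankTFs(hits, loci, minSnps = 2L)$motif,
                     c("SP1", "EGR1"))
    # no affected hits: empty ranking
    none <- rankTFs(S4Vectors::DataFrame(pwm_name = character(),
                                         rsid = character()), loci)
    expect_equal(nrow(none), 0L)
    expect_error(rankTFs(hits, loci[-1]), "no locus mapping")
})
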
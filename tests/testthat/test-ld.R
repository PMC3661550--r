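test_that("two-locus statistics match hand counts on the toy panel", {
    p <- toy_panel()  # AB,AB,AB,Ab,aB,ab,ab,ab
    st <- twoLocusR2(p, "siteA", "siteB")
    expect_equal(st$D, 0.375 - 0.25)
    expect_equal(st$r2, 0.015625 / 0.0625)
    expect_equal(st$Dprime, 0.125 / 0.25)
    # self comparison is the identity
    self <- twoLocusR2(p, "siteA", "siteA")
    expect_equal(self$r2, 1)
    expect_equal(self$Dprime, 1)
    # monomorphic sites are undefined
    mono <- HaplotypePanel(rbind(c(1, 1, 1, 1), c(1, 0, 1, 0)), "chr1",
                           c(1L, 2L), c("m", "x"), ref = c("A", "A"),
                           alt = c("G", "G"))
    expect_error(twoLocusR2(mono, "m", "x"), "monomorphic")
})

test_that("LD statistics agree with a brute-force counting oracle and obey invariants", {
    set.seed(401)
    checked <- 0L
    for (rep in 1:300) {
        panel <- random_small_panel(sample(2:6, 1), 2L * sample(2:5, 1))
        m <- hapMatrix(panel)
        ids <- variantIds(panel)
        poly <- apply(m, 1, function(r) length(unique(r)) > 1)
        if (sum(poly) < 2) next
        ab <- sample(which(poly), 2)
        st <- twoLocusR2(panel, ids[ab[1]], ids[ab[2]])
        orc <- oracle_ld(m[ab[1], ], m[ab[2], ])
        expect_equal(st$r2, orc$r2, tolerance = 1e-12)
        expect_equal(st$D, orc$D, tolerance = 1e-12)
        expect_equal(st$Dprime, orc$Dprime, tolerance = 1e-12)
        # symmetry in the pair order
        st2 <- twoLocusR2(panel, ids[ab[2]], ids[ab[1]])
        expect_equal(st$r2, st2$r2)
        expect_equal(st$D, st2$D)
        expect_equal(st$Dprime, st2$Dprime)
        # label invariance: flipping 0<->1 at one site negates D only
        flip <- m
        flip[ab[1], ] <- 1L - flip[ab[1], ]
        pf <- HaplotypePanel(flip, "chr1", start(rowRanges(panel)), ids,
                             refAllele(panel), altAllele(panel))
        sf <- twoLocusR2(pf, ids[ab[1]], ids[ab[2]])
        expect_equal(sf$r2, st$r2, tolerance = 1e-12)
        expect_equal(sf$Dprime, st$Dprime, tolerance = 1e-12)
        expect_equal(sf$D, -st$D, tolerance = 1e-12)
        # bounds: 0 <= r2 <= D' <= 1 for direct-count estimates
        expect_true(st$r2 >= 0 && st$r2 <= st$Dprime + 1e-12 &&
                    st$Dprime <= 1 + 1e-12)
        checked <- checked + 1L
    }
    expect_gt(checked, 100L)
})

test_that("ldScan reports every polymorphic site and recovers planted LD", {
    # a panel holding only the index yields an empty scan
    solo <- HaplotypePanel(matrix(c(1L, 0L), nrow = 1), "chr1", 5L, "idx",
                           ref = "A", alt = "G")
    expect_equal(nrow(ldScan(solo, "idx")), 0L)
    # demo bundle: planted partners recovered within 3 empirical SE of
    # target (SE from replicate simulation of the planting process)
    run <- demo_run()
    mf <- demo_manifest()
    ld <- run$ld
    set.seed(410)
    for (k in seq_len(nrow(mf$pairs))) {
        r2t <- mf$pairs$r2_target[k]
        s <- plantedPairSpec("i", "p", mf$pairs$p_index[k],
                             mf$pairs$p_partner[k], r2t)
        sims <- replicate(200, {
            h <- plantTwoLocusHaplotypes(s, mf$n_haplotypes)
            LDannotate:::.ldStats(h$haplotypes[, 1], h$haplotypes[, 2])$r2
        })
        got <- ld$r2[ld$corr_rsid == mf$pairs$partner_rsid[k]]
        expect_lt(abs(got - r2t), 3 * sd(sims) + 0.005)
    }
    # signed distances and descending r2 ordering
    expect_true(all(diff(ld$r2) <= 0))
    p3 <- ld[ld$corr_rsid == "rsP3", ]
    expect_equal(p3$distance_bp, 120000L - 100000L)
})

test_that("r2 strata use half-open bins with a closed top", {
    rec <- S4Vectors::DataFrame(r2 = c(0, 0.05, 0.1, 0.3, 0.5, 0.9, 1))
    b <- binLD(rec)
    expect_identical(as.character(b$records$bin),
                     c("very_low", "very_low", "low", "low", "high", "high",
                       "high"))
    expect_identical(unname(b$counts), c(2L, 2L, 3L))
    expect_equal(sum(b$counts), nrow(rec))
    # empty input gives all-zero counts
    empty <- binLD(S4Vectors::DataFrame(r2 = numeric()))
    expect_identical(unname(empty$counts), c(0L, 0L, 0L))
    expect_error(binLD(S4Vectors::DataFrame(r2 = 1.2)), "\\[0,1\\]")
})

test_that("multi-locus haplotype counting matches hand counts", {
    p <- toy_panel()
    h <- multiLocusHaplotypes(p, c("siteA", "siteB"))
    expect_equal(sum(h$frequency), 1)
    expect_identical(h$alleles[1:2], c("00", "11"))  # ties broken by string
    expect_equal(h$frequency[h$alleles == "11"], 0.375)
    expect_equal(h$frequency[h$alleles == "10"], 0.125)
    # single site reduces to the allele frequencies
    h1 <- multiLocusHaplotypes(p, "siteA")
    expect_equal(sort(h1$frequency), c(0.5, 0.5))
    expect_error(multiLocusHaplotypes(p, c("siteA", "siteA")), "duplicate")
    # planted two-locus structure recovered from the demo bundle panel
    mf <- demo_manifest()
    panel <- suppressMessages(
        loadPhasedWindow(file.path(demo_bundle_dir(), "genotypes.vcf"),
                         "rs_idx1", windowBp = 200000))
    hh <- multiLocusHaplotypes(panel, c("rs_idx1", "rsP1"))
    truth <- unlist(mf$snp_truth$rsP1$pair_frequencies)
    freq <- setNames(hh$frequency, hh$alleles)
    se <- sqrt(truth * (1 - truth) / mf$n_haplotypes)
    expect_lt(abs(freq[["11"]] - truth[["hAB"]]), 3 * se[["hAB"]] + 0.01)
    expect_lt(abs(freq[["00"]] - truth[["hab"]]), 3 * se[["hab"]] + 0.01)
})

test_that("planted-LD recovery: mean estimate within 0.02 of target", {
    set.seed(402)
    for (r2t in c(0.2, 0.8)) {
        s <- plantedPairSpec("i", "p", 0.4, 0.4, r2t)
        err <- replicate(200, {
            h <- plantTwoLocusHaplotypes(s, 1000)
            est <- LDannotate:::.ldStats(h$haplotypes[, 1],
                                         h$haplotypes[, 2])
            est$r2 - r2t
        })
        expect_lt(abs(mean(err)), 0.02)
    }
})
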
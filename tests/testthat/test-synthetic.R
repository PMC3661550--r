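test_that("implied haplotype frequencies follow the planting algebra", {
    # perfect LD forces the two coupling haplotypes
    h <- pairHaplotypeFrequencies(0.5, 0.5, 1, 1)
    expect_equal(unname(h), c(0.5, 0, 0, 0.5))
    # D = 0 means independence: product rule
    h0 <- pairHaplotypeFrequencies(0.3, 0.4, 0, 1)
    expect_identical(unname(h0[["hAB"]]), 0.3 * 0.4)
    # closing the loop: recomputing r2 from the emitted frequencies
    h2 <- pairHaplotypeFrequencies(0.3, 0.4, 0.25, 1)
    pA <- h2[["hAB"]] + h2[["hAb"]]
    pB <- h2[["hAB"]] + h2[["haB"]]
    D <- h2[["hAB"]] - pA * pB
    expect_equal(D^2 / (pA * (1 - pA) * pB * (1 - pB)), 0.25,
                 tolerance = 1e-12)
    expect_equal(D, 0.5 * sqrt(0.3 * 0.7 * 0.4 * 0.6), tolerance = 1e-12)
    # infeasible combination rejected with the violated bound named
    expect_error(pairHaplotypeFrequencies(0.05, 0.95, 0.8, 1),
                 "infeasible.*hAb")
    expect_error(plantedPairSpec("i", "p", 0.05, 0.95, 0.8),
                 "infeasible")
})

test_that("two-locus planting samples haplotypes at the target LD", {
    s <- plantedPairSpec("i", "p", 0.3, 0.4, 0.25)
    r <- plantTwoLocusHaplotypes(s, 1000, seed = 11)
    expect_equal(sum(r$counts), 1000)
    expect_equal(dim(r$haplotypes), c(1000L, 2L))
    # exact mode is deterministic rounding
    e1 <- plantTwoLocusHaplotypes(s, 200, exact = TRUE)
    e2 <- plantTwoLocusHaplotypes(s, 200, exact = TRUE)
    expect_identical(e1$counts, e2$counts)
    expect_equal(sum(e1$counts), 200)
    # perfect-LD planting yields only the two coupling haplotypes
    sp <- plantedPairSpec("i", "p", 0.5, 0.5, 1)
    rp <- plantTwoLocusHaplotypes(sp, 100, seed = 1)
    expect_true(all(rp$haplotypes[, 1] == rp$haplotypes[, 2]))
})

test_that("gene models honour strand conventions and reject bad CDS", {
    spec <- fixtureSpec(list(plantedPairSpec("i", "p", 0.4, 0.4, 0.8,
                                             posIndex = 5000L,
                                             posPartner = 6000L)),
                        chromLength = 100000L,
                        geneBlueprints = list(
                            geneBlueprint("gplus", "+", 10000L, 300L),
                            geneBlueprint("gminus", "-", 50001L, 900L)))
    models <- makeGeneModels(spec)
    expect_equal(transcriptTss(models[["gplus.t1"]]), 10000L)
    # minus strand: TSS is the rightmost transcript coordinate
    expect_equal(transcriptTss(models[["gminus.t1"]]), 50900L)
    bad <- fixtureSpec(spec@plantedPairs, chromLength = 100000L,
                       geneBlueprints = list(
                           geneBlueprint("gbad", "+", 10000L, 301L)))
    expect_error(makeGeneModels(bad), "not a multiple of 3")
})

test_that("written bundles round-trip through the pipeline's own readers", {
    d <- demo_bundle_dir()
    mf <- demo_manifest()
    # GTF round-trip: intergenic layout preserved
    models <- transcriptModelsFromGtf(file.path(d, "models.gtf"))
    expect_setequal(vapply(models, function(m) m@geneId, character(1)),
                    c("GENE1", "GENE2", "GENE3"))
    expect_equal(start(cdsExons(models[["GENE1.t1"]])), c(40000L, 41400L))
    # VCF: every GT field phased with "|"
    body <- readLines(file.path(d, "genotypes.vcf"))
    body <- body[!startsWith(body, "#")]
    gts <- unlist(lapply(strsplit(body, "\t"), function(f) f[-(1:9)]))
    expect_true(all(grepl("^[01]\\|[01]$", gts)))
    expect_equal(length(body),
                 length(mf$pairs$partner_rsid) + 1L + mf$n_background_snps)
    # BED round-trip matches the manifest intervals
    tr <- readTrackBed(file.path(d, "tracks", "H3K4me1.bed"),
                       "H3K4me1", "enhancer_mark")
    iv <- mf$tracks$H3K4me1$intervals
    if (is.list(iv)) iv <- do.call(rbind, iv)
    expect_equal(start(trackRanges(tr)), iv[, 1])
    expect_equal(end(trackRanges(tr)), iv[, 2])
    # genome FASTA carries the planted consensus at the motif site
    genome <- Biostrings::readDNAStringSet(file.path(d, "genome.fa"))
    names(genome) <- sub("\\s.*", "", names(genome))
    site <- as.character(Biostrings::subseq(genome[["chr1"]],
                                            120000L - 5L, 120000L + 10L))
    expect_identical(site, "GGGGCGGGGGCGGGGC")
    expect_identical(mf$seed, demoFixtureSpec()@seed)
})

test_that("identical spec and seed give byte-identical bundles", {
    d1 <- file.path(tempdir(), "det-a")
    d2 <- file.path(tempdir(), "det-b")
    spec <- demoFixtureSpec(seed = 424242L)
    suppressMessages(writeBundle(spec, d1))
    suppressMessages(writeBundle(spec, d2))
    for (f in list.files(d1, recursive = TRUE))
        expect_identical(readBin(file.path(d1, f), "raw", 10e6),
                         readBin(file.path(d2, f), "raw", 10e6),
                         label = f)
    unlink(c(d1, d2), recursive = TRUE)
})

test_that("peak placement rules are enforced with named failures", {
    pairs <- list(plantedPairSpec("i", "p", 0.4, 0.4, 0.8,
                                  posIndex = 50000L, posPartner = 60000L))
    genes <- list(geneBlueprint("g1", "+", 10000L, 300L))
    # enhancer peak too close to a TSS is rejected by name
    bad <- fixtureSpec(pairs, chromLength = 100000L, geneBlueprints = genes,
                       trackBlueprints = list(
                           trackBlueprint("DNase", "open_chromatin",
                                          "enhancer", at = 10500L)))
    expect_error(makePeakTracks(bad, makeGeneModels(bad)),
                 "within 1.5 kb of the TSS")
    # TSS peak falling outside the window is rejected by name
    bad2 <- fixtureSpec(pairs, chromLength = 100000L, geneBlueprints = genes,
                        trackBlueprints = list(
                            trackBlueprint("DNase", "open_chromatin", "tss",
                                           gene = "g1", offset = 2000L)))
    expect_error(makePeakTracks(bad2, makeGeneModels(bad2)),
                 "does not fit inside the TSS window")
    # a valid enhancer peak really is > 1.5 kb from every TSS in the output
    ok <- fixtureSpec(pairs, chromLength = 100000L, geneBlueprints = genes,
                      trackBlueprints = list(
                          trackBlueprint("DNase", "open_chromatin",
                                         "enhancer", at = 30000L,
                                         width = 400L, jitter = 50L)))
    tracks <- makePeakTracks(ok, makeGeneModels(ok), seed = 3L)
    gr <- trackRanges(tracks$DNase)
    expect_true(min(abs(c(start(gr), end(gr)) - 10000L)) > 1500L)
    # empty blueprint list: no tracks, no failure
    none <- fixtureSpec(pairs, chromLength = 100000L, geneBlueprints = genes)
    expect_identical(makePeakTracks(none, makeGeneModels(none)), list())
})

test_that("planted motif sites behave as designed", {
    d <- demo_bundle_dir()
    motifs <- readJasparMotifs(file.path(d, "motifs.jaspar"))
    genome <- Biostrings::readDNAStringSet(file.path(d, "genome.fa"))
    names(genome) <- sub("\\s.*", "", names(genome))
    pwm <- motifs$MOTIF_GCBOX
    site <- as.character(Biostrings::subseq(genome[["chr1"]],
                                            120000L - 5L, 120000L + 10L))
    # reference allele completes the consensus: the site is the argmax window
    expect_equal(lodScore(pwm, site), motifMaxScore(pwm), tolerance = 1e-9)
    # a PWM equal to background is inert for any allele pair
    flat <- MotifMatrix("flat", matrix(0.25, 4, 6,
                                       dimnames = list(c("A", "C", "G", "T"),
                                                       NULL)))
    expect_equal(lodScore(flat, "ACGTAC"), 0)
    # planting at a SNP that does not exist is rejected
    spec <- demoFixtureSpec()
    spec@pwmBlueprints <- list(pwmBlueprint("M", "ACGTACGT", "rs_nope", 2L))
    expect_error(makePwmSet(spec), "does not exist")
})
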
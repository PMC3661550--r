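make_track <- function(name, class, starts, ends) {
    annotationTrack(name, class, GRanges("chr1", IRanges(starts, ends)))
}

test_that("TSS regions are 3 kb windows retained only with qualifying peaks", {
    models <- list(
        transcriptModel("t1", "g1", "chr1", "+", 10000L, 10299L),
        transcriptModel("t2", "g2", "chr1", "-", 49101L, 50000L),
        transcriptModel("t3", "g3", "chr1", "+", 80000L, 80299L))
    dnase <- make_track("DNase", "open_chromatin",
                        c(10050L, 80100L), c(10250L, 80200L))
    regions <- buildTssRegions(models, list(dnase))
    # g1 and g3 qualify; g2 (TSS 50000, no peaks within 1.5 kb) is dropped
    expect_equal(length(regions), 2L)
    expect_setequal(mcols(regions)$gene_id, c("g1", "g3"))
    r1 <- regions[mcols(regions)$gene_id == "g1"]
    expect_equal(start(r1), 10000L - 1500L)
    expect_equal(end(r1), 10000L + 1499L)
    expect_equal(width(r1), 3000L)
    expect_match(mcols(r1)$qualifying_tracks, "DNase")
    # unstranded transcripts are rejected at construction
    expect_error(transcriptModel("tx", "gx", "chr1", "*", 1L, 300L),
                 "strand")
})

test_that("enhancer domain is the complement of exons and TSS neighbourhoods", {
    chromLens <- c(chr1 = 30000L)
    # zero genes: the whole chromosome is enhancer-eligible
    whole <- enhancerDomain(list(), chromLens)
    expect_equal(sum(width(whole)), 30000L)
    # two genes with overlapping TSS windows: union exclusion, no double gap
    models <- list(
        transcriptModel("t1", "g1", "chr1", "+", 10000L, 10299L),
        transcriptModel("t2", "g2", "chr1", "+", 11000L, 11299L))
    dom <- enhancerDomain(models, chromLens)
    member <- oracle_membership(30000L, start(dom), end(dom))
    excl <- oracle_membership(
        30000L,
        c(10000L, 11000L, 10000L - 1500L, 11000L - 1500L),
        c(10299L, 11299L, 10000L + 1499L, 11000L + 1499L))
    expect_identical(member, !excl)
    expect_error(enhancerDomain(models, c(chr2 = 1000L)),
                 "unknown chromosome extent")
})

test_that("SNP classification follows the exon / TSS / enhancer rules", {
    models <- list(transcriptModel("t1", "g1", "chr1", "+", 10000L, 10299L))
    exons <- make_track("coding_exon", "exon", 10000L, 10299L)
    tracks <- list(
        make_track("DNase", "open_chromatin", 10050L, 10250L),
        make_track("H3K4me1", "enhancer_mark",
                   c(10040L, 20000L), c(10260L, 20400L)),
        make_track("H3K4me2", "promoter_enhancer_mark", 10040L, 10260L),
        make_track("H3K4me3", "promoter_mark", 10030L, 10270L),
        make_track("DNase2", "open_chromatin", 20100L, 20300L))
    regions <- buildTssRegions(models, tracks)
    dom <- enhancerDomain(models, c(chr1 = 30000L))
    snps <- data.frame(rsid = c("inExon", "farEnh", "winNoPeak"),
                       chrom = "chr1", pos = c(10100L, 20150L, 9000L))
    ann <- classifySnps(snps, exons, regions, dom, tracks, models = models)
    # exonic SNP under promoter+enhancer histone signals: exon + tss, >= 3 marks
    expect_true(ann$in_exon[1] && ann$in_tss[1] && !ann$in_enhancer[1])
    expect_gte(ann$overlap_count[1], 3L)
    # SNP 10 kb from the TSS inside DNase + H3K4me1 peaks: enhancer only
    expect_identical(ann$category[2], "enhancer")
    expect_equal(ann$overlap_count[2], 2L)
    expect_gt(abs(ann$tss_distance_bp[2]), 1500L)
    # SNP inside the TSS window but outside every peak: annotated, no category
    expect_identical(ann$category[3], "")
    # classification is order-independent
    ann_rev <- classifySnps(snps[3:1, ], exons, regions, dom, tracks,
                            models = models)
    a <- as.data.frame(ann_rev)[3:1, ]
    b <- as.data.frame(ann)
    rownames(a) <- rownames(b) <- NULL
    expect_equal(a, b)
})

test_that("track overlap uses the half-open BED convention", {
    bed <- tempfile(fileext = ".bed")
    writeLines("chr1\t100\t200\tpeak1", bed)  # BED: [100, 200) 0-based
    tr <- readTrackBed(bed, "t", "other")
    snps <- data.frame(rsid = c("atStart", "inside", "atEnd", "before"),
                       chrom = "chr1", pos = c(101L, 150L, 201L, 100L))
    flags <- annotateTrack(snps, tr)
    # 1-based position 101 is BED start 100 (inclusive); 201 is end (exclusive)
    expect_identical(unname(flags), c(TRUE, TRUE, FALSE, FALSE))
    # random SNPs against random intervals match the per-base oracle
    set.seed(77)
    starts <- sort(sample(1:4500, 20)); ends <- starts + sample(10:200, 20)
    rtr <- make_track("r", "other", starts, ends)
    member <- oracle_membership(5000L, starts, ends)
    pos <- sample(1:5000, 100)
    got <- annotateTrack(data.frame(rsid = paste0("s", 1:100),
                                    chrom = "chr1", pos = pos), rtr)
    expect_identical(unname(got), member[pos])
})

test_that("category summaries are re-derivable and the union arithmetic holds", {
    expect_identical(categoryUnion(c(21, 76, 921), 13), 1005)
    run <- demo_run()
    mf <- demo_manifest()
    cs <- summarizeCategories(run$annotated)
    expect_identical(as.list(cs$per_category), mf$per_category)
    expect_identical(cs$multi_category, mf$multi_category)
    expect_identical(cs$union, mf$union)
    expect_identical(
        cs$union,
        as.integer(categoryUnion(cs$per_category,
                                 cs$multi_category)))  # demo SNPs are dual at most
    # empty input gives all zeros
    none <- summarizeCategories(classifySnps(
        data.frame(rsid = character(), chrom = character(), pos = integer()),
        NULL, GRanges(), GRanges(), list()))
    expect_identical(unname(none$per_category), c(0L, 0L, 0L))
    expect_identical(none$union, 0L)
})
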
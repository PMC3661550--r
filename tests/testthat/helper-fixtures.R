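# Shared fixtures, built once per test run and cached: the demonstration
# bundle and an end-to-end pipeline run over it.

suppressPackageStartupMessages({
    library(S4Vectors)
    library(IRanges)
    library(GenomicRanges)
    library(SummarizedExperiment)
    library(Biostrings)
})

.fixture_cache <- new.env(parent = emptyenv())

demo_bundle_dir <- function() {
    if (is.null(.fixture_cache$dir)) {
        d <- file.path(tempdir(), "LDannotate-demo-bundle")
        suppressMessages(writeBundle(demoFixtureSpec(), d))
        .fixture_cache$dir <- d
    }
    .fixture_cache$dir
}

demo_manifest <- function() readBundleManifest(demo_bundle_dir())

demo_run <- function() {
    if (is.null(.fixture_cache$run)) {
        cfg <- bundleRunConfig(demo_bundle_dir(), windowBp = 200000,
                               outDir = file.path(tempdir(),
                                                  "LDannotate-demo-run"),
                               seed = 7L)
        .fixture_cache$run <- suppressMessages(runPipeline(cfg))
    }
    .fixture_cache$run
}

# toy 8-haplotype two-site panel: AB,AB,AB,Ab,aB,ab,ab,ab
toy_panel <- function() {
    m <- rbind(c(1, 1, 1, 1, 0, 0, 0, 0),
               c(1, 1, 1, 0, 1, 0, 0, 0))
    HaplotypePanel(m, "chr1", c(100L, 200L), c("siteA", "siteB"),
                   ref = c("A", "A"), alt = c("B", "B"))
}

# genome + single-transcript model for codon tests: CDS = ATG GCC TAA
toy_cds_genome <- function(prefix = "TTTT", suffix = "TTTT") {
    seqs <- Biostrings::DNAStringSet(paste0(prefix, "ATGGCCTAA", suffix))
    names(seqs) <- "chrT"
    seqs
}

toy_cds_model <- function(prefix_len = 4L) {
    transcriptModel("toy.t1", "TOY", "chrT", "+",
                    prefix_len + 1L, prefix_len + 9L)
}
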
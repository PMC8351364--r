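gr <- function(chrom, start0, end0) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end0))
}

toy_genes <- function() {
  g <- data.frame(gene_id = "G1", chrom = "chr1", strand = "+",
                  tss = 5001L, tts = 20001L, stringsAsFactors = FALSE)
  g$exon_starts <- list(c(5000L, 19800L))
  g$exon_ends <- list(c(5200L, 20000L))
  g
}

test_that("context tracks follow the 2 kb promoter/shore/shelf definitions", {
  tracks <- build_context_tracks(toy_genes(), gr("chr1", 10000, 11000))
  # promoter covers [3000, 7000) in 0-based coordinates for a TSS at 5000
  expect_equal(BiocGenerics::start(tracks$promoter), 3001L)
  expect_equal(BiocGenerics::end(tracks$promoter), 7000L)
  # shores: [8000,10000) and [11000,13000)
  expect_equal(BiocGenerics::start(tracks$shore), c(8001L, 11001L))
  expect_equal(BiocGenerics::end(tracks$shore), c(10000L, 13000L))
  # shelves: [6000,8000) and [13000,15000)
  expect_equal(BiocGenerics::start(tracks$shelf), c(6001L, 13001L))
  expect_equal(BiocGenerics::end(tracks$shelf), c(8000L, 15000L))
  # cgi/shore/shelf are pairwise disjoint
  expect_equal(length(GenomicRanges::intersect(tracks$cgi, tracks$shore)), 0L)
  expect_equal(length(GenomicRanges::intersect(tracks$cgi, tracks$shelf)), 0L)
  expect_equal(length(GenomicRanges::intersect(tracks$shore, tracks$shelf)), 0L)
})

test_that("promoter windows are clipped at the contig start", {
  g <- toy_genes()
  g$tss <- 500L
  tracks <- build_context_tracks(g, gr("chr1", 10000, 11000))
  expect_equal(BiocGenerics::start(tracks$promoter), 1L)
})

test_that("promoter CGIs are the promoter/island intersection", {
  tracks <- build_context_tracks(toy_genes(), gr("chr1", 6500, 12000))
  expect_equal(BiocGenerics::start(tracks$promoter_cgi), 6501L)
  expect_equal(BiocGenerics::end(tracks$promoter_cgi), 7000L)
})

test_that("locus centers receive exactly one label per axis with precedence", {
  tracks <- build_context_tracks(toy_genes(), gr("chr1", 4000, 6000))
  loci <- data.frame(
    chrom = "chr1",
    start = c(4995L, 100000L, 19505L, 10500L),
    end = c(5005L, 100010L, 19515L, 10510L),
    stringsAsFactors = FALSE)
  ann <- annotate_locus_center(loci, tracks)
  # inside CGI and promoter -> promoter wins the genic axis, cgi the CpG axis
  expect_equal(ann$genic_feature[1], "promoter_tss")
  expect_equal(ann$cpg_context[1], "cgi")
  # in no track at all
  expect_equal(ann$genic_feature[2], "intergenic")
  expect_equal(ann$cpg_context[2], "open_sea")
  # inside the TTS window (exon 19800-20000 does not contain 19510)
  expect_equal(ann$genic_feature[3], "tts")
  # gene body, outside exons and windows -> intron; beyond shelves -> open sea
  expect_equal(ann$genic_feature[4], "intron")
  expect_equal(ann$cpg_context[4], "open_sea")
})

test_that("exon-in-shore centers pick exon and shore labels", {
  g <- toy_genes()
  g$exon_starts <- list(c(12000L, 19800L))
  g$exon_ends <- list(c(12500L, 20000L))
  tracks <- build_context_tracks(g, gr("chr1", 10000, 11000))
  ann <- annotate_locus_center(
    data.frame(chrom = "chr1", start = 12200L, end = 12210L), tracks)
  expect_equal(ann$genic_feature, "exon")
  expect_equal(ann$cpg_context, "shore")
})

test_that("unknown chromosomes warn and fall back to intergenic/open_sea", {
  tracks <- build_context_tracks(toy_genes(), gr("chr1", 4000, 6000))
  expect_warning(
    ann <- annotate_locus_center(
      data.frame(chrom = "chrUn", start = 100L, end = 140L), tracks),
    "absent from all tracks")
  expect_equal(ann$genic_feature, "intergenic")
  expect_equal(ann$cpg_context, "open_sea")
})

test_that("region flags mark center membership", {
  tracks <- build_context_tracks(toy_genes(), gr("chr1", 4000, 6000))
  ann <- annotate_locus_center(
    data.frame(chrom = "chr1", start = c(100L, 30000L), end = c(140L, 30040L)),
    tracks, regions = list(pmd = gr("chr1", 25000, 50000)))
  expect_equal(ann$in_pmd, c(FALSE, TRUE))
})

test_that("region overlap statistics cover identity, disjoint, half cases", {
  a <- gr("chr1", 0, 100)
  expect_equal(region_overlap_stats(a, a),
               list(base_overlap_fraction_of_A = 1, jaccard = 1))
  expect_equal(region_overlap_stats(a, gr("chr1", 200, 300)),
               list(base_overlap_fraction_of_A = 0, jaccard = 0))
  st <- region_overlap_stats(a, gr("chr1", 50, 150))
  expect_equal(st$base_overlap_fraction_of_A, 0.5)
  expect_equal(st$jaccard, 1 / 3)
  expect_error(region_overlap_stats(GenomicRanges::GRanges(), a), "empty")
})

test_that("overlap stats satisfy the symmetry identities", {
  set.seed(3)
  sa <- sort(sample(0:5000, 5)) * 10
  sb <- sort(sample(0:5000, 4)) * 10
  a <- GenomicRanges::reduce(gr("chr1", sa, sa + 800))
  b <- GenomicRanges::reduce(gr("chr1", sb, sb + 1200))
  ab <- region_overlap_stats(a, b)
  ba <- region_overlap_stats(b, a)
  expect_equal(ab$jaccard, ba$jaccard)
  expect_equal(ab$base_overlap_fraction_of_A * sum(BiocGenerics::width(a)),
               ba$base_overlap_fraction_of_A * sum(BiocGenerics::width(b)))
})

test_that("region summaries merge before computing coverage", {
  s <- region_summary(gr("chr1", 0, 100), genome_size = 1000)
  expect_equal(s, list(n = 1L, median_length = 100, genome_coverage = 0.1))
  overl <- c(gr("chr1", 0, 100), gr("chr1", 50, 150))
  s2 <- region_summary(overl, genome_size = 150)
  expect_equal(s2$genome_coverage, 1)  # merged: coverage cannot exceed 1
  s3 <- region_summary(c(gr("chr1", 0, 10), gr("chr1", 100, 120),
                         gr("chr1", 200, 230)), genome_size = 1e4)
  expect_equal(s3$median_length, 20)
  empty <- region_summary(GenomicRanges::GRanges(), 1000)
  expect_equal(empty$n, 0L)
  expect_true(is.na(empty$median_length))
  expect_equal(empty$genome_coverage, 0)
})

test_that("TSS boundary distances and quantile conventions", {
  regions <- gr("chr1", 0, 1000)
  tss <- data.frame(gene_id = c("a", "b"), chrom = "chr1",
                    tss = c(101L, 501L), stringsAsFactors = FALSE)
  d <- tss_boundary_distance(tss, regions)
  expect_equal(unname(d$distances), c(100, 500))

  tss4 <- data.frame(gene_id = letters[1:4], chrom = "chr1",
                     tss = c(2L, 3L, 4L, 101L), stringsAsFactors = FALSE)
  # distances 1, 2, 3, 100
  lin <- tss_boundary_distance(tss4, regions)
  expect_equal(unname(lin$quantile), 27.25)
  nr <- tss_boundary_distance(tss4, regions,
                              config = epishift_config(quantile_type = 1))
  expect_equal(unname(nr$quantile), 3)
})

test_that("TSS outside every region is skipped with a warning", {
  regions <- gr("chr1", 0, 1000)
  tss <- data.frame(gene_id = c("in", "out"), chrom = "chr1",
                    tss = c(500L, 5000L), stringsAsFactors = FALSE)
  expect_warning(d <- tss_boundary_distance(tss, regions), "skipped")
  expect_equal(names(d$distances), "in")
})
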
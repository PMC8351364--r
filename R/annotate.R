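# Genomic context: promoters / TTS / exon / intron / intergenic on one axis,
# CGI / shore / shelf / open sea on the other, plus membership in arbitrary
# region sets (e.g. partially methylated domains).

.expand_gr <- function(gr, w) {
  s <- pmax(1L, BiocGenerics::start(gr) - w)
  e <- BiocGenerics::end(gr) + w
  GenomicRanges::reduce(GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                                               IRanges::IRanges(s, e)))
}

#' Build genomic context tracks from gene models and CpG islands
#'
#' Promoters are TSS +/- `promoter_flank` (default 2 kb); TTS windows are
#' TTS +/- `tts_flank`; shores are the `shore_width` flanks of (merged) CpG
#' islands minus the islands; shelves the next `shelf_width` minus shores and
#' islands; promoter CGIs are the intersection of promoters and islands.
#' Windows running past the contig start are clipped at the first base.
#'
#' @param genes Gene model data.frame (see [parse_genes()]).
#' @param cgis `GRanges` of CpG islands.
#' @param config [epishift_config()].
#' @return Named list of `GRanges`: `promoter`, `tts`, `exon`, `intron`,
#'   `gene`, `cgi`, `shore`, `shelf`, `promoter_cgi`.
#' @export
build_context_tracks <- function(genes, cgis, config = epishift_config()) {
  pf <- config$promoter_flank
  promoter <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(1L, genes$tss - pf), genes$tss + pf - 1L))
  tf <- config$tts_flank
  tts <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(1L, genes$tts - tf), genes$tts + tf - 1L))
  nex <- lengths(genes$exon_starts)
  exon <- GenomicRanges::GRanges(
    rep(genes$chrom, nex),
    IRanges::IRanges(unlist(genes$exon_starts) + 1L, unlist(genes$exon_ends)))
  gene_span <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmin(genes$tss, genes$tts), pmax(genes$tss, genes$tts)))
  intron <- GenomicRanges::setdiff(GenomicRanges::reduce(gene_span),
                                   GenomicRanges::reduce(exon))
  cgi <- GenomicRanges::reduce(cgis)
  shore <- GenomicRanges::setdiff(.expand_gr(cgi, config$shore_width), cgi)
  shelf <- GenomicRanges::setdiff(
    .expand_gr(cgi, config$shore_width + config$shelf_width),
    GenomicRanges::union(cgi, shore))
  promoter_cgi <- GenomicRanges::intersect(GenomicRanges::reduce(promoter), cgi)
  list(promoter = promoter, tts = tts, exon = exon, intron = intron,
       gene = gene_span, cgi = cgi, shore = shore, shelf = shelf,
       promoter_cgi = promoter_cgi)
}

#' Annotate loci by the genomic context of their center
#'
#' The center of a locus is `floor((start + end) / 2)` over its first/last
#' CpG positions. The genic label follows the precedence
#' promoter_tss > tts > exon > intron > intergenic; the CpG label follows
#' cgi > shore > shelf > open_sea. Each locus receives exactly one label per
#' axis. Loci on chromosomes absent from every track fall back to
#' intergenic/open_sea with a warning.
#'
#' @param loci data.frame with `chrom`, `start`, `end` (and optionally
#'   `locus_id`), e.g. a pattern table or locus metrics.
#' @param tracks Track list from [build_context_tracks()].
#' @param regions Optional named list of `GRanges`; adds a logical
#'   `in_<name>` column per set (center-based membership).
#' @return data.frame: `locus_id`, `center`, `genic_feature`, `cpg_context`
#'   and any region flags.
#' @export
annotate_locus_center <- function(loci, tracks, regions = NULL) {
  center <- as.integer(floor((loci$start + loci$end) / 2))
  pts <- GenomicRanges::GRanges(loci$chrom, IRanges::IRanges(center, center))
  # cross-seqlevel overlap is expected for unknown chromosomes; the package
  # emits its own warning for those below
  hit <- function(track) suppressWarnings(IRanges::overlapsAny(pts, track))
  genic <- rep("intergenic", length(pts))
  genic[hit(tracks$intron)] <- "intron"
  genic[hit(tracks$exon)] <- "exon"
  genic[hit(tracks$tts)] <- "tts"
  genic[hit(tracks$promoter)] <- "promoter_tss"
  cpg <- rep("open_sea", length(pts))
  cpg[hit(tracks$shelf)] <- "shelf"
  cpg[hit(tracks$shore)] <- "shore"
  cpg[hit(tracks$cgi)] <- "cgi"
  known <- unique(unlist(lapply(tracks, function(g)
    as.character(unique(GenomicRanges::seqnames(g))))))
  unknown <- setdiff(unique(loci$chrom), known)
  if (length(unknown))
    warning(sprintf("chromosome(s) absent from all tracks: %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)
  out <- data.frame(
    locus_id = if (!is.null(loci$locus_id)) loci$locus_id
      else .locus_id(loci$chrom, loci$start, loci$end),
    center = center,
    genic_feature = genic,
    cpg_context = cpg,
    stringsAsFactors = FALSE)
  if (!is.null(regions)) {
    if (is.null(names(regions))) stop("regions must be a named list")
    for (nm in names(regions))
      out[[paste0("in_", nm)]] <- hit(regions[[nm]])
  }
  out
}

#' Base-pair overlap statistics between two region sets
#'
#' @param setA,setB `GRanges` region sets (merged internally).
#' @return list: `base_overlap_fraction_of_A` (`|A ∩ B| / |A|` in bases) and
#'   `jaccard` (`|A ∩ B| / |A ∪ B|`).
#' @export
region_overlap_stats <- function(setA, setB) {
  a <- GenomicRanges::reduce(setA)
  b <- GenomicRanges::reduce(setB)
  if (length(a) == 0L) stop("empty set A: overlap fraction undefined")
  inter <- sum(BiocGenerics::width(GenomicRanges::intersect(a, b)))
  wa <- sum(BiocGenerics::width(a))
  uni <- sum(BiocGenerics::width(GenomicRanges::union(a, b)))
  list(base_overlap_fraction_of_A = inter / wa,
       jaccard = if (uni > 0) inter / uni else 0)
}

#' Summary of a region set
#'
#' @param set `GRanges`.
#' @param genome_size Total genome size in bases (`> 0`).
#' @return list: `n` intervals, `median_length` (NA when empty) and
#'   `genome_coverage` (merged base count / genome size).
#' @export
region_summary <- function(set, genome_size) {
  if (!is.numeric(genome_size) || genome_size <= 0)
    stop("genome_size must be positive")
  n <- length(set)
  list(n = n,
       median_length = if (n) stats::median(BiocGenerics::width(set)) else NA_real_,
       genome_coverage =
         sum(BiocGenerics::width(GenomicRanges::reduce(set))) / genome_size)
}

#' Distance from each TSS to the nearest boundary of its containing region
#'
#' For each gene whose TSS lies inside a region, the distance is
#' `min(TSS - start, end - TSS)` in 0-based coordinates. Genes outside all
#' regions are skipped with a warning.
#'
#' @param tss data.frame with `gene_id`, `chrom`, `tss` (1-based position).
#' @param regions `GRanges` (e.g. partially methylated domains).
#' @param probs Quantile to report (default third quartile).
#' @param config [epishift_config()]; `quantile_type` selects the quantile
#'   convention (7 = linear interpolation, 1 = nearest rank).
#' @return list: `distances` (named by `gene_id`) and `quantile`.
#' @export
tss_boundary_distance <- function(tss, regions, probs = 0.75,
                                  config = epishift_config()) {
  pts <- GenomicRanges::GRanges(tss$chrom, IRanges::IRanges(tss$tss, tss$tss))
  hits <- GenomicRanges::findOverlaps(pts, regions, select = "first")
  miss <- is.na(hits)
  if (any(miss))
    warning(sprintf("%d TSS outside all regions were skipped", sum(miss)),
            call. = FALSE)
  keep <- which(!miss)
  t0 <- tss$tss[keep] - 1
  s0 <- BiocGenerics::start(regions)[hits[keep]] - 1
  e0 <- BiocGenerics::end(regions)[hits[keep]]
  d <- pmin(t0 - s0, e0 - t0)
  names(d) <- tss$gene_id[keep]
  list(distances = d,
       quantile = if (length(d))
         stats::quantile(d, probs, type = config$quantile_type, names = FALSE)
       else NA_real_)
}
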
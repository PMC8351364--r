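#' Analysis configuration
#'
#' Bundles every threshold used across the pipeline. Defaults follow the
#' methclone-style conventions for deep targeted bisulfite data: loci of 4
#' adjacent CpGs at a minimum depth of 60 reads, per-CpG coverage of at least
#' 10 reads, eloci called at an entropy shift below -70 on the \[-100, 0\]
#' entropy scale, a 25% methylation difference for hyper/hypo direction, and
#' 30%/70% minor/dominant proportions for pattern-change classification.
#'
#' @param min_locus_depth Minimum number of reads covering all 4 CpGs of a
#'   locus for the locus to be retained (reads).
#' @param min_cpg_coverage Minimum number of reads with a valid call at a CpG
#'   for that CpG to enter the locus map (reads).
#' @param elocus_delta_s_threshold Entropy-shift threshold: a shared locus is
#'   an elocus when its (signed or negated-absolute) entropy difference falls
#'   strictly below this value.
#' @param elocus_on_absolute_delta_s If `TRUE`, eloci are called on
#'   `-abs(delta_s)` so that entropy gains and losses both qualify; the
#'   default signed rule only calls entropy gains (`S2 - S1 < threshold`).
#' @param meth_diff_threshold Minimum absolute locus methylation difference
#'   for a hyper-/hypomethylated direction call (proportion).
#' @param dominant_threshold A pattern is "highly predominant" at a stage when
#'   its proportion is strictly above this value.
#' @param minor_threshold A stage has "no predominant pattern" when every
#'   pattern proportion is strictly below this value.
#' @param entropy_scale Per-locus entropy units per bit; the default 25 gives
#'   S in \[-100, 0\] for 4-CpG loci.
#' @param n_npc Number of control (normal plasma cell) samples required for
#'   the consensus elocus rule.
#' @param fpm_expressed_threshold A gene is expressed when its FPM is strictly
#'   above this value.
#' @param promoter_meth_low,promoter_meth_high Promoter mean methylation below
#'   `promoter_meth_low` is "unmethylated", above `promoter_meth_high`
#'   "methylated"; genes in between are excluded from odds-ratio tables.
#' @param promoter_flank Promoter half-width around the TSS (bp).
#' @param tts_flank Transcription-termination-site window half-width (bp).
#' @param shore_width Width of CpG shores flanking islands (bp).
#' @param shelf_width Width of CpG shelves beyond the shores (bp).
#' @param discordant_locus_fraction PDR cutoff used when reporting the
#'   fraction of loci dominated by discordant reads.
#' @param min_mean_fpm Genes with mean expression at or below this value are
#'   excluded from coefficient-of-variation summaries.
#' @param quantile_type Quantile convention (passed to [stats::quantile()]);
#'   7 = linear interpolation (default), 1 = nearest rank.
#'
#' @return A list of class `epishift_config`.
#' @export
#' @examples
#' cfg <- epishift_config()
#' cfg$min_locus_depth
epishift_config <- function(min_locus_depth = 60,
                            min_cpg_coverage = 10,
                            elocus_delta_s_threshold = -70,
                            elocus_on_absolute_delta_s = FALSE,
                            meth_diff_threshold = 0.25,
                            dominant_threshold = 0.70,
                            minor_threshold = 0.30,
                            entropy_scale = 25,
                            n_npc = 3,
                            fpm_expressed_threshold = 1,
                            promoter_meth_low = 0.25,
                            promoter_meth_high = 0.75,
                            promoter_flank = 2000,
                            tts_flank = 2000,
                            shore_width = 2000,
                            shelf_width = 2000,
                            discordant_locus_fraction = 0.50,
                            min_mean_fpm = 1,
                            quantile_type = 7) {
  if (min_locus_depth < 1) stop("min_locus_depth must be >= 1")
  if (min_cpg_coverage < 1) stop("min_cpg_coverage must be >= 1")
  if (!is.finite(elocus_delta_s_threshold) || elocus_delta_s_threshold >= 0)
    stop("elocus_delta_s_threshold must be negative")
  if (meth_diff_threshold <= 0 || meth_diff_threshold > 1)
    stop("meth_diff_threshold must be in (0, 1]")
  if (!(minor_threshold > 0 && minor_threshold < dominant_threshold &&
        dominant_threshold < 1))
    stop("need 0 < minor_threshold < dominant_threshold < 1")
  if (entropy_scale <= 0) stop("entropy_scale must be positive")
  if (n_npc < 1) stop("n_npc must be >= 1")
  if (!(promoter_meth_low >= 0 && promoter_meth_low < promoter_meth_high &&
        promoter_meth_high <= 1))
    stop("need 0 <= promoter_meth_low < promoter_meth_high <= 1")
  if (promoter_flank <= 0 || tts_flank <= 0 || shore_width <= 0 ||
      shelf_width <= 0)
    stop("flank and shore/shelf widths must be positive")
  if (discordant_locus_fraction < 0 || discordant_locus_fraction > 1)
    stop("discordant_locus_fraction must be in [0, 1]")
  if (!quantile_type %in% 1:9) stop("quantile_type must be in 1..9")
  structure(list(
    min_locus_depth = as.integer(min_locus_depth),
    min_cpg_coverage = as.integer(min_cpg_coverage),
    elocus_delta_s_threshold = elocus_delta_s_threshold,
    elocus_on_absolute_delta_s = isTRUE(elocus_on_absolute_delta_s),
    meth_diff_threshold = meth_diff_threshold,
    dominant_threshold = dominant_threshold,
    minor_threshold = minor_threshold,
    entropy_scale = entropy_scale,
    n_npc = as.integer(n_npc),
    fpm_expressed_threshold = fpm_expressed_threshold,
    promoter_meth_low = promoter_meth_low,
    promoter_meth_high = promoter_meth_high,
    promoter_flank = as.integer(promoter_flank),
    tts_flank = as.integer(tts_flank),
    shore_width = as.integer(shore_width),
    shelf_width = as.integer(shelf_width),
    discordant_locus_fraction = discordant_locus_fraction,
    min_mean_fpm = min_mean_fpm,
    quantile_type = as.integer(quantile_type)
  ), class = "epishift_config")
}

#' @export
print.epishift_config <- function(x, ...) {
  cat("epishift analysis configuration\n")
  for (nm in names(x)) cat(sprintf("  %-28s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
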
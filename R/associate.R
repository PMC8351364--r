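# Expression-methylation association: per-gene promoter state, odds ratios
# of expression vs promoter methylation stratified by promoter PDR, and
# expression variability by gene set.

#' Promoter methylation/heterogeneity state per gene
#'
#' Promoter loci are the loci whose center lies within TSS +/-
#' `promoter_flank`; promoter mean methylation and promoter PDR are
#' unweighted means over those loci. Genes without promoter loci are skipped
#' with a warning. The PDR stratum is `high` when the promoter PDR is
#' strictly above the cohort mean promoter PDR (over the returned genes).
#'
#' @param genes Gene model data.frame (see [parse_genes()]).
#' @param metrics Locus metrics data.frame (see [locus_metrics()]).
#' @param expression Expression table (see [parse_expression()]).
#' @param sample Name of the expression column to use.
#' @param config [epishift_config()].
#' @return data.frame: `gene_id`, `promoter_mean_methylation`,
#'   `promoter_pdr`, `fpm`, `expressed`, `meth_class` (`unmethylated` /
#'   `methylated` / `intermediate`; intermediate genes are excluded from
#'   odds-ratio tables) and `pdr_stratum` (`low` / `high`).
#' @export
gene_promoter_state <- function(genes, metrics, expression, sample,
                                config = epishift_config()) {
  if (!sample %in% names(expression))
    stop(sprintf("sample '%s' not found in expression table", sample))
  pf <- config$promoter_flank
  prom <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(1L, genes$tss - pf), genes$tss + pf - 1L))
  center <- as.integer(floor((metrics$start + metrics$end) / 2))
  pts <- GenomicRanges::GRanges(metrics$chrom,
                                IRanges::IRanges(center, center))
  hits <- GenomicRanges::findOverlaps(pts, prom)
  gi <- S4Vectors::subjectHits(hits)
  li <- S4Vectors::queryHits(hits)
  meth <- tapply(metrics$mean_meth[li], gi, mean)
  pdr_ <- tapply(metrics$pdr[li], gi, mean)
  idx <- as.integer(names(meth))
  skipped <- setdiff(seq_len(nrow(genes)), idx)
  if (length(skipped))
    warning(sprintf("%d gene(s) without promoter loci were skipped",
                    length(skipped)), call. = FALSE)
  fpm <- expression[[sample]][match(genes$gene_id[idx], expression$gene_id)]
  out <- data.frame(
    gene_id = genes$gene_id[idx],
    promoter_mean_methylation = as.vector(meth),
    promoter_pdr = as.vector(pdr_),
    fpm = fpm,
    stringsAsFactors = FALSE)
  out$expressed <- out$fpm > config$fpm_expressed_threshold
  out$meth_class <- ifelse(
    out$promoter_mean_methylation < config$promoter_meth_low, "unmethylated",
    ifelse(out$promoter_mean_methylation > config$promoter_meth_high,
           "methylated", "intermediate"))
  out$pdr_stratum <- ifelse(out$promoter_pdr > mean(out$promoter_pdr),
                            "high", "low")
  out
}

#' 2x2 expression-by-methylation table for a PDR stratum
#'
#' Rows are expressed / not expressed, columns methylated / unmethylated;
#' genes with intermediate promoter methylation are excluded. With this
#' orientation an odds ratio above 1 marks enrichment of expressed genes
#' among methylated promoters (i.e. decoupling from the canonical repressive
#' relationship).
#'
#' @param states Output of [gene_promoter_state()].
#' @param stratum `"all"`, `"low"` or `"high"` promoter-PDR stratum.
#' @return 2x2 integer matrix.
#' @export
promoter_or_table <- function(states, stratum = c("all", "low", "high")) {
  stratum <- match.arg(stratum)
  d <- states[states$meth_class != "intermediate", , drop = FALSE]
  if (stratum != "all") d <- d[d$pdr_stratum == stratum, , drop = FALSE]
  matrix(c(sum(d$expressed & d$meth_class == "methylated"),
           sum(d$expressed & d$meth_class == "unmethylated"),
           sum(!d$expressed & d$meth_class == "methylated"),
           sum(!d$expressed & d$meth_class == "unmethylated")),
         nrow = 2L, byrow = TRUE,
         dimnames = list(expressed = c("yes", "no"),
                         methylation = c("methylated", "unmethylated")))
}

#' Odds ratio with 95% confidence interval for a 2x2 table
#'
#' `OR = (a d) / (b c)` for the table `rbind(c(a, b), c(c, d))`. When any
#' cell is zero the Haldane-Anscombe correction adds 0.5 to every cell. The
#' 95% CI is Woolf's interval on the log scale,
#' `exp(log(OR) +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`.
#'
#' @param table 2x2 non-negative count matrix (or length-4 vector
#'   `c(a, b, c, d)` filled by row).
#' @return list: `estimate`, `ci_low`, `ci_high`, `corrected`, `table`.
#' @export
#' @examples
#' odds_ratio(matrix(c(20, 10, 10, 20), 2, byrow = TRUE))$estimate  # 4
odds_ratio <- function(table) {
  if (is.vector(table) && length(table) == 4L)
    table <- matrix(table, nrow = 2L, byrow = TRUE)
  if (!is.matrix(table) || any(dim(table) != 2L))
    stop("expected a 2x2 table")
  if (any(table < 0) || any(!is.finite(table)))
    stop("cell counts must be non-negative and finite")
  if (sum(table) == 0) stop("all-zero table: odds ratio undefined")
  corrected <- any(table == 0)
  t2 <- if (corrected) table + 0.5 else table
  or <- (t2[1L, 1L] * t2[2L, 2L]) / (t2[1L, 2L] * t2[2L, 1L])
  se <- sqrt(sum(1 / t2))
  list(estimate = or,
       ci_low = exp(log(or) - 1.96 * se),
       ci_high = exp(log(or) + 1.96 * se),
       corrected = corrected,
       table = table)
}

#' Coefficient of variation of gene expression, by gene set
#'
#' Per-gene CV = sd / mean across samples (sample standard deviation, n-1
#' denominator). Genes with mean expression at or below `min_mean_fpm`
#' (default 1) are excluded.
#'
#' @param expression Expression table (see [parse_expression()]), at least 2
#'   sample columns.
#' @param gene_sets Optional named list of gene-id vectors; when given, the
#'   return value is a named list of per-set CV vectors (empty sets produce
#'   a warning).
#' @param min_mean_fpm Mean-expression inclusion threshold.
#' @return data.frame (`gene_id`, `mean_fpm`, `cv`) or, with `gene_sets`, a
#'   named list of CV vectors.
#' @export
expression_cv <- function(expression, gene_sets = NULL, min_mean_fpm = 1) {
  if (ncol(expression) < 3L)
    stop("need at least 2 sample columns to compute a CV")
  m <- as.matrix(expression[, -1L, drop = FALSE])
  mu <- rowMeans(m)
  sdv <- apply(m, 1L, stats::sd)
  keep <- mu > min_mean_fpm
  cv <- data.frame(gene_id = expression$gene_id[keep],
                   mean_fpm = mu[keep],
                   cv = sdv[keep] / mu[keep],
                   stringsAsFactors = FALSE)
  if (is.null(gene_sets)) return(cv)
  if (is.null(names(gene_sets))) stop("gene_sets must be a named list")
  out <- lapply(names(gene_sets), function(nm) {
    v <- cv$cv[cv$gene_id %in% gene_sets[[nm]]]
    if (!length(v))
      warning(sprintf("gene set '%s' has no qualifying genes", nm),
              call. = FALSE)
    v
  })
  stats::setNames(out, names(gene_sets))
}
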
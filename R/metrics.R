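# Per-locus heterogeneity metrics.
#
# All metrics operate on the 16-pattern epiallele distribution of one locus:
#   epipolymorphism  Epi = 1 - sum p_i^2           (Gini-Simpson diversity)
#   PDR              fraction of reads neither fully methylated (pattern 15)
#                    nor fully unmethylated (pattern 0)
#   entropy          S = entropy_scale * sum p_i log2 p_i, in [-4*scale, 0]
#   mean methylation sum p_i * popcount(i) / 4

#' Epipolymorphism of a pattern distribution
#'
#' `Epi = 1 - sum(p_i^2)` over the 16 epiallele proportions. Ranges from 0
#' (a single pattern carries all reads) to 0.9375 (all 16 patterns equally
#' represented).
#'
#' @param p Numeric vector of 16 pattern proportions summing to 1.
#' @return Epipolymorphism in `[0, 0.9375]`.
#' @export
#' @examples
#' epipolymorphism(rep(1/16, 16))  # 0.9375
#' epipolymorphism(c(1, rep(0, 15)))  # 0
epipolymorphism <- function(p) {
  p <- .check_dist(p)
  1 - sum(p^2)
}

#' Proportion of discordant reads (PDR) at a locus
#'
#' The fraction of a locus's reads whose pattern is neither fully methylated
#' nor fully unmethylated. A 50/50 mixture of fully methylated and fully
#' unmethylated reads is concordant (PDR 0) even though it is maximally
#' bimodal.
#'
#' @param counts Numeric vector of 16 pattern counts with positive depth.
#' @return PDR in `[0, 1]`.
#' @export
#' @examples
#' pdr(c(30, rep(0, 14), 30))  # 0: bimodal but concordant
pdr <- function(counts) {
  counts <- .check_counts(counts)
  depth <- sum(counts)
  if (depth <= 0) stop("undefined for zero depth")
  (depth - counts[1L] - counts[16L]) / depth
}

#' Combinatorial entropy of a pattern distribution
#'
#' `S = entropy_scale * sum(p_i * log2(p_i))` with `0 * log2(0) = 0`. With
#' the default scale of 25 per bit, S ranges from -100 (uniform over the 16
#' patterns) to 0 (single pattern).
#'
#' @param p Numeric vector of 16 pattern proportions summing to 1.
#' @param entropy_scale Units per bit (default 25).
#' @return Entropy in `[-4 * entropy_scale, 0]`.
#' @export
#' @examples
#' entropy(rep(1/16, 16))  # -100
entropy <- function(p, entropy_scale = 25) {
  p <- .check_dist(p)
  nz <- p > 0
  entropy_scale * sum(p[nz] * log2(p[nz]))
}

#' Mean methylation of a locus
#'
#' Average methylated fraction over the 4 CpGs, weighted by pattern counts:
#' `sum(p_i * popcount(i)) / 4`.
#'
#' @param counts Numeric vector of 16 pattern counts (or proportions) with
#'   positive sum.
#' @return Mean methylation in `[0, 1]`.
#' @export
#' @examples
#' x <- numeric(16); x[9] <- 40  # pattern 8 = MUUU
#' mean_methylation(x)  # 0.25
mean_methylation <- function(counts) {
  counts <- .check_counts(counts)
  depth <- sum(counts)
  if (depth <= 0) stop("undefined for zero depth")
  sum(counts * .PATTERN_POPCOUNT) / (4 * depth)
}

#' Epipolymorphism envelope at a given mean methylation
#'
#' For each mean methylation level `m`, returns the maximal epipolymorphism
#' attainable by any 16-pattern distribution with that mean (`max_epi`) and
#' the epipolymorphism of the purely bimodal mixture that places mass only on
#' the fully unmethylated and fully methylated patterns
#' (`bimodal_epi = 2 m (1 - m)`). `max_epi` is computed exactly by quadratic
#' optimization over the five pattern weight classes (patterns grouped by
#' methylated-CpG count, with multiplicities 1, 4, 6, 4, 1; within a class an
#' equal split maximizes diversity).
#'
#' @param m Numeric vector of mean methylation levels in `[0, 1]`.
#' @return data.frame with columns `m`, `max_epi`, `bimodal_epi`.
#' @export
#' @examples
#' epipolymorphism_envelope(c(0, 0.5, 1))
epipolymorphism_envelope <- function(m) {
  if (!is.numeric(m) || any(!is.finite(m)) || any(m < 0) || any(m > 1))
    stop("mean methylation must be in [0, 1]")
  data.frame(m = m,
             max_epi = vapply(m, .max_epi_one, numeric(1)),
             bimodal_epi = 2 * m * (1 - m))
}

# exact maximum of 1 - sum p^2 at fixed mean methylation: minimize
# sum q_k^2 / c_k over the class-mass simplex (c = multiplicities 1,4,6,4,1,
# k = methylated CpGs) subject to sum q = 1, sum q*k/4 = m. Convex QP solved
# by enumerating KKT active sets (31 non-empty free sets).
.max_epi_one <- function(m) {
  cls <- c(1, 4, 6, 4, 1)
  kk <- 0:4
  best <- Inf
  for (mask in 1:31) {
    free <- which(bitwAnd(mask, bitwShiftL(1L, 0:4)) > 0L)
    cF <- cls[free]; kF <- kk[free]
    if (length(free) == 1L) {
      if (abs(kF / 4 - m) < 1e-9) best <- min(best, 1 / cF)
      next
    }
    A <- matrix(c(sum(cF), sum(cF * kF), sum(cF * kF), sum(cF * kF^2)), 2L)
    if (abs(det(A)) < 1e-12) next
    lm_ <- solve(A, c(1, 4 * m))
    q <- cF * (lm_[1L] + lm_[2L] * kF)
    if (any(q < -1e-9)) next
    best <- min(best, sum(q^2 / cF))
  }
  1 - best
}

#' Per-locus metrics for a pattern table
#'
#' Vectorized computation of depth, epipolymorphism, PDR, entropy and mean
#' methylation for every locus of a pattern table.
#'
#' @param patterns Pattern table (see [enumerate_loci()]).
#' @param config [epishift_config()]; `entropy_scale` is used here.
#' @return data.frame: `locus_id`, `chrom`, `start`, `end`, `positions`,
#'   `depth`, `epi`, `pdr`, `entropy`, `mean_meth`.
#' @export
locus_metrics <- function(patterns, config = epishift_config()) {
  m <- .counts_matrix(patterns)
  depth <- rowSums(m)
  if (any(depth <= 0)) stop("pattern table contains zero-depth loci")
  p <- m / depth
  plog <- p * log2(p)
  plog[p == 0] <- 0
  data.frame(
    locus_id = .locus_id(patterns$chrom, patterns$start, patterns$end),
    chrom = patterns$chrom, start = patterns$start, end = patterns$end,
    positions = patterns$positions,
    depth = as.integer(depth),
    epi = 1 - rowSums(p^2),
    pdr = (depth - m[, 1L] - m[, 16L]) / depth,
    entropy = config$entropy_scale * rowSums(plog),
    mean_meth = as.vector(p %*% .PATTERN_POPCOUNT) / 4,
    stringsAsFactors = FALSE)
}

#' Sample-level summary of locus metrics
#'
#' Unweighted (locus-weighted) means over loci, plus the fraction of loci
#' whose PDR exceeds `discordant_locus_fraction`.
#'
#' @param metrics Locus metrics data.frame (see [locus_metrics()]).
#' @param config [epishift_config()].
#' @return list: `n_loci`, `mean_epi`, `mean_pdr`,
#'   `fraction_discordant_loci`.
#' @export
sample_summary <- function(metrics, config = epishift_config()) {
  if (nrow(metrics) == 0L) stop("no loci to summarize")
  list(n_loci = nrow(metrics),
       mean_epi = mean(metrics$epi),
       mean_pdr = mean(metrics$pdr),
       fraction_discordant_loci =
         mean(metrics$pdr > config$discordant_locus_fraction))
}
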
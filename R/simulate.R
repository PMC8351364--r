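# Synthetic cohort generator.
#
# Emulates a paired-sample deep bisulfite cohort: a consensus baseline
# distribution per 4-CpG locus, three control (NPC) replicates jittered
# around it, a diagnosis sample carrying planted epiallele-shift events of
# each pattern-change category, an optional relapse sample with its own
# planted events, PMD-like region sets, gene models anchored at promoter
# loci, and an expression table whose methylation coupling depends on
# promoter PDR. Reads are drawn multinomially from each locus's true
# distribution at Poisson depth clamped at the locus depth floor.

.SIM_SAMPLES <- function(n_npc) c(paste0("npc_", seq_len(n_npc)),
                                  "diagnosis", "relapse")

.EVENT_CATEGORIES <- c("selection", "disorder", "switch",
                       "disorder_maintenance", "hyper_shift", "hypo_shift")

#' Simulation configuration
#'
#' @param seed Integer seed; every source of randomness flows from it.
#' @param n_chromosomes Number of synthetic chromosomes.
#' @param n_loci Total number of 4-CpG loci.
#' @param depth_mean Mean per-locus read depth (Poisson), clamped at
#'   `min_depth`.
#' @param min_depth Depth floor so no locus silently fails the 60-read locus
#'   filter.
#' @param archetype_weights Mixture weights over the background locus
#'   archetypes `bimodal_concordant`, `dominant_single`,
#'   `dirichlet_disordered`.
#' @param dirichlet_alpha Dirichlet concentration of the disordered
#'   background archetype.
#' @param disordered_alpha Concentration used for category-constrained
#'   disordered stages (rejection-sampled so every pattern stays at or below
#'   0.25, a 0.05 margin inside the 30% rule).
#' @param uniformish_alpha Concentration of near-uniform stages used for
#'   large entropy shifts.
#' @param npc_jitter_concentration Dirichlet concentration of the control
#'   replicates around the baseline (higher = tighter).
#' @param n_npc Number of control samples.
#' @param planted_events data.frame (`category`, `fraction`) of events
#'   planted between baseline and diagnosis; unassigned loci are null
#'   (diagnosis distribution identical to baseline).
#' @param relapse_events Same, between diagnosis and relapse; events are
#'   planted only at loci whose diagnosis distribution is compatible with the
#'   category's stage-1 requirement.
#' @param dropout_rate Per-CpG probability of a missing call in emitted
#'   reads (default 0).
#' @param pmd_genome_fraction Fraction of the synthetic genome covered by
#'   PMD-like regions.
#' @param pmd_mean_length Mean PMD segment length (bp; scaled to the small
#'   synthetic genome).
#' @param n_genes Number of genes; each gene's TSS sits at the center of a
#'   dedicated promoter locus.
#' @param expression_base_log2_fpm,expression_meth_slope Coupled genes have
#'   `log2(FPM) = base - slope * promoter_methylation + noise`.
#' @param expression_coupled_noise_sd,expression_decoupled_noise_sd Lognormal
#'   noise SDs (log2 scale) for coupled and decoupled genes.
#' @param locus_spacing Distance between consecutive locus anchors (bp).
#' @param cpg_gap_range Range of gaps between the 4 CpGs of a locus (bp).
#' @return list of class `epishift_sim_config`.
#' @export
simulation_config <- function(seed = 1,
                              n_chromosomes = 2,
                              n_loci = 200,
                              depth_mean = 80,
                              min_depth = 60,
                              archetype_weights = c(bimodal_concordant = 0.55,
                                                    dominant_single = 0.25,
                                                    dirichlet_disordered = 0.20),
                              dirichlet_alpha = 0.6,
                              disordered_alpha = 3,
                              uniformish_alpha = 12,
                              npc_jitter_concentration = 1500,
                              n_npc = 3,
                              planted_events = data.frame(
                                category = c("selection", "disorder", "switch",
                                             "disorder_maintenance",
                                             "hyper_shift", "hypo_shift"),
                                fraction = c(0.02, 0.02, 0.01, 0.02,
                                             0.015, 0.035),
                                stringsAsFactors = FALSE),
                              relapse_events = data.frame(
                                category = c("selection", "switch"),
                                fraction = c(0.03, 0.01),
                                stringsAsFactors = FALSE),
                              dropout_rate = 0,
                              pmd_genome_fraction = 0.65,
                              pmd_mean_length = 20000,
                              n_genes = 120,
                              expression_base_log2_fpm = 4,
                              expression_meth_slope = 6,
                              expression_coupled_noise_sd = 1,
                              expression_decoupled_noise_sd = 1.5,
                              locus_spacing = 5000,
                              cpg_gap_range = c(4, 20)) {
  if (depth_mean < min_depth)
    stop("depth_mean must be at least min_depth")
  if (min_depth < 1) stop("min_depth must be >= 1")
  if (n_loci < 1 || n_chromosomes < 1) stop("need n_loci and n_chromosomes >= 1")
  if (n_genes > n_loci) stop("n_genes cannot exceed n_loci")
  if (any(archetype_weights < 0) || sum(archetype_weights) <= 0)
    stop("archetype_weights must be non-negative with positive sum")
  for (ev in list(planted_events, relapse_events)) {
    if (nrow(ev)) {
      if (!all(ev$category %in% .EVENT_CATEGORIES))
        stop("unknown planted event category")
      if (any(ev$fraction < 0) || any(ev$fraction > 1))
        stop("event fractions must be in [0, 1]")
    }
  }
  if (sum(planted_events$fraction) > 1 || sum(relapse_events$fraction) > 1)
    stop("planted event fractions must sum to at most 1")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)")
  if (pmd_genome_fraction < 0 || pmd_genome_fraction > 1)
    stop("pmd_genome_fraction must be in [0, 1]")
  structure(list(
    seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
    n_loci = as.integer(n_loci), depth_mean = depth_mean,
    min_depth = as.integer(min_depth),
    archetype_weights = archetype_weights / sum(archetype_weights),
    dirichlet_alpha = dirichlet_alpha, disordered_alpha = disordered_alpha,
    uniformish_alpha = uniformish_alpha,
    npc_jitter_concentration = npc_jitter_concentration,
    n_npc = as.integer(n_npc),
    planted_events = planted_events, relapse_events = relapse_events,
    dropout_rate = dropout_rate,
    pmd_genome_fraction = pmd_genome_fraction,
    pmd_mean_length = pmd_mean_length,
    n_genes = as.integer(n_genes),
    expression_base_log2_fpm = expression_base_log2_fpm,
    expression_meth_slope = expression_meth_slope,
    expression_coupled_noise_sd = expression_coupled_noise_sd,
    expression_decoupled_noise_sd = expression_decoupled_noise_sd,
    locus_spacing = as.integer(locus_spacing),
    cpg_gap_range = as.integer(cpg_gap_range)
  ), class = "epishift_sim_config")
}

.rdirichlet <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  s <- sum(x)
  if (s <= 0) {
    p <- numeric(length(alpha))
    p[which.max(alpha)] <- 1
    return(p)
  }
  x / s
}

.dist_disordered <- function(alpha, max_p = 0.25) {
  repeat {
    p <- .rdirichlet(rep(alpha, 16L))
    if (max(p) <= max_p) return(p)
  }
}

.dist_dominant <- function(pattern = NULL, lo = 0.78, hi = 0.95) {
  if (is.null(pattern)) pattern <- sample.int(16L, 1L)
  w <- stats::runif(1L, lo, hi)
  p <- numeric(16L)
  p[-pattern] <- .rdirichlet(rep(1, 15L)) * (1 - w)
  p[pattern] <- w
  p
}

.dist_bimodal <- function() {
  m <- stats::rbeta(1L, 0.4, 0.4)
  p <- numeric(16L); p[1L] <- 1 - m; p[16L] <- m
  p
}

.dist_single <- function(pattern) {
  p <- numeric(16L); p[pattern] <- 1
  p
}

# near-uniform mass tilted toward methylated (or unmethylated) patterns;
# high entropy (about -96 on the default scale) with mean methylation near
# 0.58 (resp. 0.42)
.dist_meth_weighted <- function(high, conc = 3) {
  alpha <- if (high) conc * (1 + .PATTERN_POPCOUNT)
           else conc * (5 - .PATTERN_POPCOUNT)
  .rdirichlet(alpha)
}

# gene-promoter archetypes: methylation pinned outside the intermediate
# band with either low (concordant) or high (discordant) PDR
.dist_promoter <- function(type) {
  switch(type,
    concordant_low = ,
    concordant_high = {
      high <- type == "concordant_high"
      w <- stats::runif(1L, 0.86, 0.95)
      p <- numeric(16L)
      main <- if (high) 16L else 1L
      other <- if (high) 1L else 16L
      disc <- if (high) c(8L, 12L, 14L, 15L) else c(2L, 3L, 5L, 9L)
      p[main] <- w
      p[other] <- (1 - w) * 0.6
      p[disc] <- (1 - w) * 0.4 / 4
      p
    },
    discordant_low = {
      idx <- c(1L, 2L, 3L, 5L, 9L)  # UUUU plus single-methylated patterns
      p <- numeric(16L)
      p[idx] <- .rdirichlet(c(4, 2, 2, 2, 2))
      p
    },
    discordant_high = {
      idx <- c(16L, 8L, 12L, 14L, 15L)  # MMMM plus single-unmethylated
      p <- numeric(16L)
      p[idx] <- .rdirichlet(c(4, 2, 2, 2, 2))
      p
    },
    stop("unknown promoter archetype"))
}

# stage pair for an event planted between baseline and diagnosis
.event_stage_pair <- function(category, cfg) {
  switch(category,
    selection = list(s1 = .dist_disordered(cfg$disordered_alpha),
                     s2 = .dist_dominant()),
    disorder = list(s1 = .dist_single(sample.int(16L, 1L)),
                    s2 = .rdirichlet(rep(cfg$uniformish_alpha, 16L))),
    switch = {
      a <- sample.int(16L, 1L)
      b <- sample(setdiff(1:16, a), 1L)
      list(s1 = .dist_dominant(a), s2 = .dist_dominant(b))
    },
    disorder_maintenance = list(s1 = .dist_disordered(cfg$disordered_alpha),
                                s2 = .dist_disordered(cfg$disordered_alpha)),
    hyper_shift = list(s1 = .dist_single(1L),
                       s2 = .dist_meth_weighted(TRUE)),
    hypo_shift = list(s1 = .dist_single(16L),
                      s2 = .dist_meth_weighted(FALSE)),
    stop("unknown event category"))
}

# stage-2 distribution for an event planted on top of a fixed stage 1;
# NULL when stage 1 is incompatible with the category
.event_from_stage1 <- function(category, s1, cfg) {
  m1 <- sum(s1 * .PATTERN_POPCOUNT) / 4
  switch(category,
    selection = if (max(s1) <= 0.25) .dist_dominant() else NULL,
    disorder = if (max(s1) >= 0.75)
      .rdirichlet(rep(cfg$uniformish_alpha, 16L)) else NULL,
    switch = if (max(s1) >= 0.75)
      .dist_dominant(sample(setdiff(1:16, which.max(s1)), 1L)) else NULL,
    disorder_maintenance = if (max(s1) <= 0.25)
      .dist_disordered(cfg$disordered_alpha) else NULL,
    hyper_shift = if (m1 <= 0.3) .dist_meth_weighted(TRUE) else NULL,
    hypo_shift = if (m1 >= 0.7) .dist_meth_weighted(FALSE) else NULL,
    stop("unknown event category"))
}

.row_entropy <- function(mat, scale) {
  pl <- mat * log2(mat)
  pl[mat == 0] <- 0
  scale * rowSums(pl)
}

.row_meth <- function(mat) as.vector(mat %*% .PATTERN_POPCOUNT) / 4

.row_pdr <- function(mat) 1 - mat[, 1L] - mat[, 16L]

.simulate_pmds <- function(chrom, len, frac, mean_len) {
  if (frac <= 0)
    return(GenomicRanges::GRanges())
  gap_mean <- max(500, mean_len * (1 - frac) / max(frac, 1e-9))
  pos <- 1; starts <- integer(); ends <- integer()
  state <- stats::runif(1L) < frac
  while (pos < len) {
    l <- max(500, round(stats::rlnorm(1L,
      log(if (state) mean_len else gap_mean), 0.4)))
    if (state) {
      starts <- c(starts, pos)
      ends <- c(ends, min(len, pos + l - 1))
    }
    pos <- pos + l
    state <- !state
  }
  GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, ends))
}

.emit_reads <- function(sample_name, loci, dists, cfg) {
  n <- nrow(loci)
  depth <- pmax(cfg$min_depth, stats::rpois(n, cfg$depth_mean))
  total <- sum(depth)
  chrom <- rep(loci$chrom, depth)
  read_id <- sprintf("%s_L%05d_r%03d", sample_name,
                     rep(seq_len(n), depth),
                     unlist(lapply(depth, seq_len), use.names = FALSE))
  draws <- integer(total)
  off <- 0L
  for (l in seq_len(n)) {
    draws[(off + 1L):(off + depth[l])] <-
      sample.int(16L, depth[l], replace = TRUE, prob = dists[l, ])
    off <- off + depth[l]
  }
  calls <- .PATTERN_STRINGS[draws]
  if (cfg$dropout_rate > 0) {
    drop <- matrix(stats::runif(4L * total) < cfg$dropout_rate, ncol = 4L)
    any_drop <- which(rowSums(drop) > 0L)
    for (i in any_drop) {
      ch <- strsplit(calls[i], "", fixed = TRUE)[[1L]]
      ch[drop[i, ]] <- "."
      calls[i] <- paste(ch, collapse = "")
    }
  }
  pos_list <- rep(loci$pos_list, depth)
  out <- data.frame(chrom = chrom, read_id = read_id,
                    stringsAsFactors = FALSE)
  out$cpg_positions <- pos_list
  out$calls <- calls
  out
}

#' Simulate a complete synthetic cohort
#'
#' Deterministic given `config$seed`. Returns (and optionally writes) epiread
#' tables for each control, the diagnosis and the relapse sample, PMD-like
#' and CpG-island region sets, gene models, an expression table and a truth
#' table carrying the true per-sample distributions, entropy shifts and
#' planted event labels.
#'
#' @param config [simulation_config()].
#' @param out_dir Optional directory; when given, all outputs are written in
#'   the on-disk dialects of the package (`<sample>.epiread`, `pmd.bed`,
#'   `cgi.bed`, `genes.tsv`, `expression.tsv`, `truth.tsv`).
#' @return list: `epireads` (named list of epiread data.frames), `truth`
#'   (`$loci` data.frame, `$genes` data.frame, `$distributions` with the true
#'   per-sample pattern matrices), `regions` (`$pmd`), `cgis`, `genes`,
#'   `expression`, and `files` when `out_dir` was given.
#' @export
simulate_cohort <- function(config = simulation_config(), out_dir = NULL) {
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_loci

  # genome layout: evenly spaced locus anchors over n_chromosomes
  per_chrom <- ceiling(n / cfg$n_chromosomes)
  chrom_of <- sprintf("chrS%d", ((seq_len(n) - 1L) %/% per_chrom) + 1L)
  slot <- ((seq_len(n) - 1L) %% per_chrom)
  anchor <- slot * cfg$locus_spacing + 1000L
  gaps <- matrix(sample(seq(cfg$cpg_gap_range[1L], cfg$cpg_gap_range[2L]),
                        3L * n, replace = TRUE), ncol = 3L)
  p1 <- anchor
  p2 <- p1 + gaps[, 1L]; p3 <- p2 + gaps[, 2L]; p4 <- p3 + gaps[, 3L]
  loci <- data.frame(chrom = chrom_of, start = p1, end = p4,
                     positions = paste(p1, p2, p3, p4, sep = ","),
                     stringsAsFactors = FALSE)
  loci$pos_list <- mapply(function(a, b, c, d) c(a, b, c, d),
                          p1, p2, p3, p4, SIMPLIFY = FALSE)
  loci$center <- as.integer(floor((p1 + p4) / 2))
  loci$locus_id <- .locus_id(loci$chrom, loci$start, loci$end)
  chrom_len <- per_chrom * cfg$locus_spacing + 2000L

  # gene promoter loci and archetypes
  gene_locus <- sort(sample.int(n, cfg$n_genes))
  promoter_types <- rep(c("concordant_low", "concordant_high",
                          "discordant_low", "discordant_high"),
                        length.out = cfg$n_genes)
  archetype <- rep(NA_character_, n)
  archetype[gene_locus] <- promoter_types
  bg <- which(is.na(archetype))
  archetype[bg] <- sample(names(cfg$archetype_weights), length(bg),
                          replace = TRUE, prob = cfg$archetype_weights)

  # baseline distributions
  base <- matrix(0, n, 16L)
  for (i in seq_len(n)) {
    base[i, ] <- switch(archetype[i],
      bimodal_concordant = .dist_bimodal(),
      dominant_single = .dist_dominant(),
      dirichlet_disordered = .rdirichlet(rep(cfg$dirichlet_alpha, 16L)),
      .dist_promoter(archetype[i]))
  }

  # plant events between baseline and diagnosis (background loci only, so
  # the expression design stays anchored at stable promoter states)
  category <- rep("null", n)
  diag <- base
  avail <- setdiff(seq_len(n), gene_locus)
  if (nrow(cfg$planted_events)) {
    for (r in seq_len(nrow(cfg$planted_events))) {
      k <- round(cfg$planted_events$fraction[r] * n)
      k <- min(k, length(avail))
      if (k < 1) next
      pick <- avail[sample.int(length(avail), k)]
      avail <- setdiff(avail, pick)
      for (i in pick) {
        pair <- .event_stage_pair(cfg$planted_events$category[r], cfg)
        base[i, ] <- pair$s1
        diag[i, ] <- pair$s2
        category[i] <- cfg$planted_events$category[r]
      }
    }
  }

  # relapse events on top of the diagnosis state, where compatible
  category_relapse <- rep("null", n)
  relapse <- diag
  avail_r <- setdiff(seq_len(n), gene_locus)
  if (nrow(cfg$relapse_events)) {
    for (r in seq_len(nrow(cfg$relapse_events))) {
      cat_r <- cfg$relapse_events$category[r]
      k <- round(cfg$relapse_events$fraction[r] * n)
      cand <- avail_r[sample.int(length(avail_r))]
      picked <- 0L
      for (i in cand) {
        if (picked >= k) break
        s2 <- .event_from_stage1(cat_r, diag[i, ], cfg)
        if (is.null(s2)) next
        relapse[i, ] <- s2
        category_relapse[i] <- cat_r
        avail_r <- setdiff(avail_r, i)
        picked <- picked + 1L
      }
    }
  }

  # control replicates: Dirichlet jitter around the baseline
  npc <- lapply(seq_len(cfg$n_npc), function(j) {
    m <- matrix(0, n, 16L)
    for (i in seq_len(n))
      m[i, ] <- .rdirichlet(cfg$npc_jitter_concentration * base[i, ] + 0.05)
    m
  })

  # region sets
  chroms <- unique(loci$chrom)
  pmd <- suppressWarnings(do.call(c, lapply(chroms, function(ch)
    .simulate_pmds(ch, chrom_len, cfg$pmd_genome_fraction,
                   cfg$pmd_mean_length))))
  centers <- GenomicRanges::GRanges(loci$chrom,
                                    IRanges::IRanges(loci$center, loci$center))
  in_pmd <- IRanges::overlapsAny(centers, pmd)
  cgis <- GenomicRanges::GRanges(
    loci$chrom[gene_locus],
    IRanges::IRanges(pmax(1L, loci$start[gene_locus] - 150L),
                     loci$end[gene_locus] + 150L))

  # gene models anchored at their promoter locus center
  tss <- loci$center[gene_locus]
  tts <- tss + 5000L
  genes <- data.frame(
    gene_id = sprintf("G%04d", seq_len(cfg$n_genes)),
    chrom = loci$chrom[gene_locus], strand = "+",
    tss = tss, tts = tts, stringsAsFactors = FALSE)
  genes$exon_starts <- lapply(seq_len(cfg$n_genes), function(i)
    c(tss[i] - 1L, tts[i] - 201L))
  genes$exon_ends <- lapply(seq_len(cfg$n_genes), function(i)
    c(tss[i] + 199L, tts[i] - 1L))

  # truth table
  scale <- 25
  s_base <- .row_entropy(base, scale)
  s_diag <- .row_entropy(diag, scale)
  s_rel <- .row_entropy(relapse, scale)
  truth_loci <- data.frame(
    locus_id = loci$locus_id, chrom = loci$chrom,
    start = loci$start, end = loci$end, positions = loci$positions,
    archetype = archetype,
    gene_id = NA_character_,
    category = category, category_relapse = category_relapse,
    s_npc = s_base, s_diagnosis = s_diag, s_relapse = s_rel,
    delta_s_true = s_diag - s_base,
    delta_s_relapse_true = s_rel - s_diag,
    meth_npc = .row_meth(base), meth_diagnosis = .row_meth(diag),
    meth_relapse = .row_meth(relapse),
    pdr_diagnosis_true = .row_pdr(diag),
    in_pmd = in_pmd,
    stringsAsFactors = FALSE)
  truth_loci$gene_id[gene_locus] <- genes$gene_id

  pdr_prom <- .row_pdr(diag)[gene_locus]
  truth_genes <- data.frame(
    gene_id = genes$gene_id,
    locus_index = gene_locus,
    locus_id = loci$locus_id[gene_locus],
    promoter_pdr_true = pdr_prom,
    coupled = pdr_prom <= mean(pdr_prom),
    stringsAsFactors = FALSE)

  # emit reads
  sample_names <- .SIM_SAMPLES(cfg$n_npc)
  dist_by_sample <- c(npc, list(diag, relapse))
  names(dist_by_sample) <- sample_names
  epireads <- lapply(sample_names, function(s)
    .emit_reads(s, loci, dist_by_sample[[s]], cfg))
  names(epireads) <- sample_names

  truth <- list(loci = truth_loci, genes = truth_genes,
                distributions = list(npc_base = base, npc = npc,
                                     diagnosis = diag, relapse = relapse))

  expression <- simulate_expression(truth, cfg, seed = NULL)

  res <- list(epireads = epireads, truth = truth,
              regions = list(pmd = pmd), cgis = cgis, genes = genes,
              expression = expression, config = cfg)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- list()
    for (s in sample_names) {
      f <- file.path(out_dir, paste0(s, ".epiread"))
      write_epireads(epireads[[s]], f)
      files[[s]] <- f
    }
    files$pmd <- write_bed(pmd, file.path(out_dir, "pmd.bed"))
    files$cgi <- write_bed(cgis, file.path(out_dir, "cgi.bed"))
    files$genes <- write_genes(genes, file.path(out_dir, "genes.tsv"))
    files$expression <- write_expression(expression,
                                         file.path(out_dir, "expression.tsv"))
    tf <- file.path(out_dir, "truth.tsv")
    write.table(truth_loci, tf, sep = "\t", quote = FALSE, row.names = FALSE)
    files$truth <- tf
    res$files <- files
  }
  res
}

#' Simulate an expression table from cohort truth
#'
#' Genes with a low-PDR (coupled) promoter follow
#' `log2(FPM) = base - slope * promoter_methylation + noise` in every
#' sample; genes with a high-PDR (decoupled) promoter draw their expression
#' independently of methylation, around the mid-methylation expectation.
#'
#' @param truth Truth list from [simulate_cohort()].
#' @param config [simulation_config()].
#' @param seed Optional seed; `NULL` continues the caller's RNG stream (used
#'   internally by [simulate_cohort()]).
#' @return Expression data.frame: `gene_id` plus one FPM column per sample.
#' @export
simulate_expression <- function(truth, config = simulation_config(),
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  g <- truth$genes
  meth_by_sample <- c(
    lapply(truth$distributions$npc, function(m)
      .row_meth(m)[g$locus_index]),
    list(.row_meth(truth$distributions$diagnosis)[g$locus_index],
         .row_meth(truth$distributions$relapse)[g$locus_index]))
  names(meth_by_sample) <- .SIM_SAMPLES(cfg$n_npc)
  out <- data.frame(gene_id = g$gene_id, stringsAsFactors = FALSE)
  for (s in names(meth_by_sample)) {
    meth <- meth_by_sample[[s]]
    mu <- ifelse(g$coupled,
                 cfg$expression_base_log2_fpm -
                   cfg$expression_meth_slope * meth,
                 cfg$expression_base_log2_fpm -
                   cfg$expression_meth_slope * 0.5)
    sdv <- ifelse(g$coupled, cfg$expression_coupled_noise_sd,
                  cfg$expression_decoupled_noise_sd)
    out[[s]] <- 2^(mu + stats::rnorm(nrow(g), sd = sdv))
  }
  out
}
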
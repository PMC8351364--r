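# End-to-end patient analysis: controls vs diagnosis (consensus eloci) and
# diagnosis vs relapse, with per-stage counts, direction split, category
# fractions, annotation breakdowns and region-set membership.

.as_granges_input <- function(x) {
  if (is.null(x)) return(NULL)
  if (methods::is(x, "GRanges")) return(x)
  if (is.character(x) && length(x) == 1L) return(parse_bed(x))
  stop("expected a GRanges or a BED file path")
}

.as_genes_input <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.data.frame(x)) return(x)
  if (is.character(x) && length(x) == 1L) return(parse_genes(x))
  stop("expected a gene model data.frame or a TSV path")
}

.direction_of <- function(diff, thr) {
  ifelse(diff >= thr, "hyper", ifelse(diff <= -thr, "hypo", "none"))
}

#' Run the full paired-sample epiallele analysis for one patient
#'
#' Parses the epiread files, enumerates 4-CpG loci per sample, computes
#' per-locus metrics and sample summaries, calls consensus eloci between the
#' controls and the diagnosis sample (a locus qualifies only when it is an
#' elocus against every control), optionally compares diagnosis and relapse,
#' splits eloci by methylation direction (25% rule), classifies pattern
#' changes, annotates elocus positions when gene models and CpG islands are
#' supplied, and reports the fraction of hyper-/hypomethylated eloci inside
#' each supplied region set.
#'
#' The consensus section reports `C` as the number of loci covered in the
#' diagnosis sample and in all controls, `E` as the consensus elocus count
#' and `EPM = 1e6 * E / C`. Consensus elocus direction uses the diagnosis
#' methylation minus the mean control methylation; the pattern-change
#' category uses the pooled control counts as stage 1. The written report
#' contains no timestamps so that reruns on identical inputs are
#' byte-identical.
#'
#' @param npc_files Character vector of `config$n_npc` control epiread
#'   files.
#' @param diagnosis_file Diagnosis epiread file.
#' @param relapse_file Optional relapse epiread file; when `NULL` a
#'   diagnosis-only report is produced.
#' @param genes,cgis Optional gene models (TSV path or data.frame) and CpG
#'   islands (BED path or GRanges) for annotation.
#' @param regions Optional named list of region sets (BED paths or GRanges),
#'   e.g. `list(pmd = "pmd.bed")`.
#' @param config [epishift_config()].
#' @param out_dir Optional output directory; writes `summary.tsv`,
#'   `loci_metrics.tsv`, `comparisons.tsv`, `eloci.bed` (0-based) and
#'   `report.json`.
#' @return The report, an invisible list.
#' @export
run_patient_analysis <- function(npc_files, diagnosis_file,
                                 relapse_file = NULL,
                                 genes = NULL, cgis = NULL, regions = NULL,
                                 config = epishift_config(),
                                 out_dir = NULL) {
  if (length(npc_files) < config$n_npc)
    stop(sprintf("need %d control epiread files, got %d",
                 config$n_npc, length(npc_files)))
  if (length(npc_files) > config$n_npc) {
    warning(sprintf("using the first %d of %d control files",
                    config$n_npc, length(npc_files)), call. = FALSE)
    npc_files <- npc_files[seq_len(config$n_npc)]
  }
  genes <- .as_genes_input(genes)
  cgis <- .as_granges_input(cgis)
  if (!is.null(regions)) {
    if (is.null(names(regions))) stop("regions must be a named list")
    regions <- lapply(regions, .as_granges_input)
  }

  input_files <- c(stats::setNames(npc_files,
                                   paste0("npc_", seq_along(npc_files))),
                   diagnosis = diagnosis_file)
  if (!is.null(relapse_file))
    input_files <- c(input_files, relapse = relapse_file)

  reads <- lapply(input_files, parse_epireads)
  chrom_sets <- lapply(reads, function(r) unique(r$chrom))
  if (length(Reduce(intersect, chrom_sets)) == 0L)
    stop("no chromosome shared across all epiread inputs")

  patterns <- lapply(reads, enumerate_loci, config = config)
  metrics <- lapply(patterns, locus_metrics, config = config)
  summaries <- lapply(names(metrics), function(s) {
    sm <- sample_summary(metrics[[s]], config)
    c(list(sample = s), sm)
  })

  # controls vs diagnosis
  npc_names <- paste0("npc_", seq_len(config$n_npc))
  npc_cmp <- lapply(npc_names, function(s)
    compare_samples(patterns[[s]], patterns$diagnosis, config))
  names(npc_cmp) <- npc_names
  cons <- consensus_eloci(npc_cmp, config)
  shared_all <- Reduce(intersect, lapply(npc_cmp, function(x)
    x$comparisons$locus_id))
  C_cons <- length(shared_all)
  E_cons <- length(cons)
  epm_cons <- if (C_cons > 0) epm(E_cons, C_cons) else NA_real_

  # consensus elocus direction (diagnosis vs mean control methylation) and
  # category (pooled control counts as stage 1)
  cons_dir <- character(0)
  cons_cat <- character(0)
  if (E_cons > 0) {
    meth_npc <- vapply(cons, function(id)
      mean(vapply(npc_cmp, function(x)
        x$comparisons$meth1[match(id, x$comparisons$locus_id)], numeric(1))),
      numeric(1))
    i_d <- match(cons, patterns$diagnosis$locus_id)
    m_d <- .counts_matrix(patterns$diagnosis)[i_d, , drop = FALSE]
    meth_diag <- as.vector((m_d / rowSums(m_d)) %*% .PATTERN_POPCOUNT) / 4
    cons_dir <- .direction_of(meth_diag - meth_npc,
                              config$meth_diff_threshold)
    pooled <- Reduce(`+`, lapply(npc_names, function(s) {
      i_n <- match(cons, patterns[[s]]$locus_id)
      .counts_matrix(patterns[[s]])[i_n, , drop = FALSE]
    }))
    cons_cat <- vapply(seq_along(cons), function(i)
      classify_change(pooled[i, ] / sum(pooled[i, ]),
                      m_d[i, ] / sum(m_d[i, ]), config), character(1))
    names(cons_dir) <- names(cons_cat) <- cons
  }
  dir_counts <- table(factor(cons_dir, levels = c("hyper", "hypo", "none")))
  cons_cat_frac <- if (E_cons > 0)
    as.list(stats::setNames(as.vector(
      table(factor(cons_cat, levels = .CHANGE_CATEGORIES))) / E_cons,
      .CHANGE_CATEGORIES))
  else NULL

  # diagnosis vs relapse
  relapse_section <- NULL
  if (!is.null(relapse_file)) {
    rel_cmp <- compare_samples(patterns$diagnosis, patterns$relapse, config)
    rel_el <- rel_cmp$comparisons[rel_cmp$comparisons$is_elocus, ,
                                  drop = FALSE]
    relapse_section <- list(
      E = rel_cmp$E, C = rel_cmp$C, epm = rel_cmp$epm,
      n_hyper = sum(rel_el$direction == "hyper"),
      n_hypo = sum(rel_el$direction == "hypo"),
      n_none = sum(rel_el$direction == "none"),
      category_fractions = if (rel_cmp$E > 0)
        as.list(category_fractions(rel_cmp)) else NULL)
  }

  # annotation of consensus eloci
  annotation <- NULL
  tracks <- NULL
  if (!is.null(genes) && !is.null(cgis)) {
    tracks <- build_context_tracks(genes, cgis, config)
    if (E_cons > 0) {
      loci_df <- patterns$diagnosis[match(cons, patterns$diagnosis$locus_id),
                                    c("chrom", "start", "end", "locus_id")]
      ann <- annotate_locus_center(loci_df, tracks, regions)
      annotation <- list(
        genic = as.list(table(ann$genic_feature)),
        cpg = as.list(table(ann$cpg_context)))
    }
  }

  # fraction of directional consensus eloci inside each region set
  region_fractions <- NULL
  if (!is.null(regions) && E_cons > 0) {
    loci_df <- patterns$diagnosis[match(cons, patterns$diagnosis$locus_id), ]
    centers <- GenomicRanges::GRanges(
      loci_df$chrom,
      IRanges::IRanges(as.integer(floor((loci_df$start + loci_df$end) / 2)),
                       as.integer(floor((loci_df$start + loci_df$end) / 2))))
    region_fractions <- lapply(regions, function(gr) {
      inside <- IRanges::overlapsAny(centers, gr)
      list(
        fraction_hyper_inside = if (any(cons_dir == "hyper"))
          mean(inside[cons_dir == "hyper"]) else NA_real_,
        fraction_hypo_inside = if (any(cons_dir == "hypo"))
          mean(inside[cons_dir == "hypo"]) else NA_real_)
    })
  }

  report <- list(
    manifest = list(
      package_version = as.character(utils::packageVersion("epishift")),
      config = unclass(config),
      inputs = as.list(unname(tools::md5sum(input_files))) |>
        stats::setNames(names(input_files))),
    samples = summaries,
    stage_counts = lapply(patterns, nrow),
    npc_consensus = list(
      E = E_cons, C = C_cons, epm = epm_cons,
      epm_per_npc = lapply(npc_cmp, function(x)
        list(E = x$E, C = x$C, epm = x$epm)),
      eloci = as.list(cons),
      n_hyper = as.integer(dir_counts[["hyper"]]),
      n_hypo = as.integer(dir_counts[["hypo"]]),
      n_none = as.integer(dir_counts[["none"]]),
      category_fractions = cons_cat_frac),
    diagnosis_relapse = relapse_section,
    annotation = annotation,
    region_fractions = region_fractions)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    sm <- do.call(rbind, lapply(summaries, as.data.frame))
    write.table(sm, file.path(out_dir, "summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    lm <- do.call(rbind, lapply(names(metrics), function(s)
      cbind(sample = s, metrics[[s]])))
    write.table(lm, file.path(out_dir, "loci_metrics.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    cmp_rows <- lapply(npc_names, function(s)
      cbind(comparison = paste0(s, "_vs_diagnosis"),
            npc_cmp[[s]]$comparisons))
    if (!is.null(relapse_file))
      cmp_rows <- c(cmp_rows, list(cbind(
        comparison = "diagnosis_vs_relapse",
        compare_samples(patterns$diagnosis, patterns$relapse,
                        config)$comparisons)))
    write.table(do.call(rbind, cmp_rows),
                file.path(out_dir, "comparisons.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (E_cons > 0) {
      loci_df <- patterns$diagnosis[match(cons, patterns$diagnosis$locus_id), ]
      gr <- GenomicRanges::GRanges(loci_df$chrom,
                                   IRanges::IRanges(loci_df$start,
                                                    loci_df$end))
      S4Vectors::mcols(gr)$name <- loci_df$locus_id
      write_bed(gr, file.path(out_dir, "eloci.bed"))
    } else {
      writeLines(character(0), file.path(out_dir, "eloci.bed"))
    }
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  }
  invisible(report)
}
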
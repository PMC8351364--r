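# On-disk formats.
#
# Coordinate conventions: per-CpG positions are 1-based (position of the C on
# the + strand; G-strand calls are assumed collapsed onto the C by the
# upstream caller). Interval files (BED) are 0-based half-open on disk and
# converted to 1-based closed GRanges in memory. PHRED filtering (>= 20) is
# assumed applied upstream; an optional per-CpG quality column in epiread
# files is honored with the same threshold.

.read_data_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

#' Parse an epiread file
#'
#' The epiread dialect is a TSV with one row per sequenced read (one row per
#' read *pair* for paired-end data): chromosome, read id, comma-separated
#' 1-based CpG positions, and a call string over `M` (methylated), `U`
#' (unmethylated) and `.` (missing), in genomic order. An optional fifth
#' column of comma-separated PHRED base qualities masks calls below
#' `quality_min` as missing. A `#`-prefixed header is ignored.
#'
#' @param path Path to an epiread TSV.
#' @param strict If `TRUE` (default) malformed lines abort with an error
#'   naming the line number; otherwise they are skipped with a warning.
#' @param quality_min PHRED threshold applied to the optional quality column.
#' @return A data.frame with columns `chrom`, `read_id`, `cpg_positions`
#'   (list column of integer vectors, strictly ascending) and `calls`
#'   (character strings over `M`/`U`/`.`), in file order.
#' @export
parse_epireads <- function(path, strict = TRUE, quality_min = 20) {
  dat <- .read_data_lines(path)
  empty <- data.frame(chrom = character(), read_id = character(),
                      stringsAsFactors = FALSE)
  empty$cpg_positions <- list()
  empty$calls <- character()
  if (length(dat$lines) == 0L) return(empty)

  fields <- strsplit(dat$lines, "\t", fixed = TRUE)
  n <- length(fields)
  chrom <- character(n); read_id <- character(n)
  positions <- vector("list", n); calls <- character(n)
  ok <- logical(n)
  for (i in seq_len(n)) {
    f <- fields[[i]]
    msg <- NULL
    if (!(length(f) %in% c(4L, 5L))) {
      msg <- sprintf("wrong column count (%d)", length(f))
    } else {
      pos <- suppressWarnings(as.integer(strsplit(f[3L], ",", fixed = TRUE)[[1L]]))
      cal <- strsplit(f[4L], "", fixed = TRUE)[[1L]]
      if (length(pos) < 1L || anyNA(pos)) {
        msg <- "unparseable CpG positions"
      } else if (any(diff(pos) <= 0L)) {
        msg <- "CpG positions not strictly ascending"
      } else if (!all(cal %in% c("M", "U", "."))) {
        msg <- "invalid call character"
      } else if (length(cal) != length(pos)) {
        msg <- "length mismatch between positions and calls"
      } else if (length(f) == 5L) {
        qual <- suppressWarnings(as.integer(strsplit(f[5L], ",", fixed = TRUE)[[1L]]))
        if (length(qual) != length(pos) || anyNA(qual)) {
          msg <- "invalid quality column"
        } else {
          cal[qual < quality_min] <- "."
        }
      }
    }
    if (!is.null(msg)) {
      full <- sprintf("epiread parse error at line %d: %s", dat$lineno[i], msg)
      if (strict) stop(full) else { warning(full, call. = FALSE); next }
    }
    chrom[i] <- f[1L]; read_id[i] <- f[2L]
    positions[[i]] <- pos; calls[i] <- paste(cal, collapse = "")
    ok[i] <- TRUE
  }
  out <- data.frame(chrom = chrom[ok], read_id = read_id[ok],
                    stringsAsFactors = FALSE)
  out$cpg_positions <- positions[ok]
  out$calls <- calls[ok]
  out
}

#' Write an epiread data.frame to disk
#'
#' Inverse of [parse_epireads()] (quality columns are not emitted).
#'
#' @param reads data.frame as returned by [parse_epireads()].
#' @param path Output path.
#' @export
write_epireads <- function(reads, path) {
  header <- "#chrom\tread_id\tcpg_positions\tcalls"
  body <- if (nrow(reads)) {
    paste(reads$chrom, reads$read_id,
          vapply(reads$cpg_positions, paste, character(1), collapse = ","),
          reads$calls, sep = "\t")
  } else character()
  writeLines(c(header, body), path)
  invisible(path)
}

#' Parse a BED interval file into a GRanges
#'
#' BED3/BED6, 0-based half-open on disk; intervals are converted to 1-based
#' closed GRanges and sorted. Overlapping intervals are preserved as-is.
#'
#' @param path Path to a BED file.
#' @return A sorted `GRanges` (with `name`, `score`, `strand` when present).
#' @export
parse_bed <- function(path) {
  dat <- .read_data_lines(path)
  if (length(dat$lines) == 0L)
    return(GenomicRanges::GRanges())
  fields <- strsplit(dat$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop(sprintf("BED parse error at line %d: fewer than 3 columns",
                 dat$lineno[which(nf < 3L)[1L]]))
  chrom <- vapply(fields, `[`, character(1), 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 3L)))
  if (anyNA(start) || anyNA(end))
    stop("BED parse error: non-numeric start/end")
  bad <- which(start >= end)
  if (length(bad))
    stop(sprintf("BED parse error at line %d: start >= end", dat$lineno[bad[1L]]))
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
  if (all(nf >= 4L)) S4Vectors::mcols(gr)$name <- vapply(fields, `[`, character(1), 4L)
  if (all(nf >= 5L)) S4Vectors::mcols(gr)$score <-
      suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 5L)))
  if (all(nf >= 6L)) {
    str <- vapply(fields, `[`, character(1), 6L)
    if (all(str %in% c("+", "-", "."))) BiocGenerics::strand(gr) <- str
  }
  BiocGenerics::sort(gr)
}

#' Write a GRanges as a BED file (0-based half-open)
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @export
write_bed <- function(gr, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = BiocGenerics::start(gr) - 1L,
                   end = BiocGenerics::end(gr),
                   stringsAsFactors = FALSE)
  if (!is.null(S4Vectors::mcols(gr)$name)) df$name <- S4Vectors::mcols(gr)$name
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a locus pattern table
#'
#' Columns: `chrom`, `start`, `end` (1-based first/last CpG), `positions`
#' (comma list of the 4 CpG positions) and the 16 integer pattern counts
#' `n0`..`n15` indexed by the [encode_pattern()] bit convention.
#'
#' @param patterns Pattern table data.frame (e.g. from [enumerate_loci()]).
#' @param path Output path.
#' @export
write_pattern_table <- function(patterns, path) {
  cols <- c("chrom", "start", "end", "positions", paste0("n", 0:15))
  if (!all(cols %in% names(patterns)))
    stop("pattern table is missing required columns")
  write.table(patterns[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a locus pattern table
#'
#' Inverse of [write_pattern_table()]; validates counts and positions and
#' recomputes `depth` and `locus_id`.
#'
#' @param path Path to a pattern table TSV.
#' @return Pattern table data.frame with derived `locus_id` and `depth`.
#' @export
read_pattern_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  cols <- c("chrom", "start", "end", "positions", paste0("n", 0:15))
  if (!all(cols %in% names(df)))
    stop("pattern table is missing required columns")
  cnt <- as.matrix(df[, paste0("n", 0:15), drop = FALSE])
  if (any(cnt < 0) || any(cnt != round(cnt)))
    stop("pattern counts must be non-negative integers")
  poslist <- strsplit(df$positions, ",", fixed = TRUE)
  if (any(lengths(poslist) != 4L))
    stop("each locus must list exactly 4 CpG positions")
  p1 <- as.integer(vapply(poslist, `[`, character(1), 1L))
  p4 <- as.integer(vapply(poslist, `[`, character(1), 4L))
  if (any(p1 != df$start) || any(p4 != df$end))
    stop("start/end do not match first/last CpG positions")
  .finish_pattern_table(df)
}

.finish_pattern_table <- function(df) {
  df$depth <- as.integer(rowSums(df[, paste0("n", 0:15), drop = FALSE]))
  df$locus_id <- .locus_id(df$chrom, df$start, df$end)
  df
}

#' Parse per-CpG methylation counts
#'
#' bedGraph-like TSV: `chrom`, `pos` (1-based), `methylated_count`,
#' `total_count`.
#'
#' @param path Input path.
#' @return data.frame with the four columns, validated
#'   (`0 <= methylated_count <= total_count`, `total_count > 0`).
#' @export
parse_cpg_bedgraph <- function(path) {
  dat <- .read_data_lines(path)
  if (length(dat$lines) == 0L)
    return(data.frame(chrom = character(), pos = integer(),
                      methylated_count = integer(), total_count = integer(),
                      stringsAsFactors = FALSE))
  fields <- strsplit(dat$lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 4L))
    stop("per-CpG file must have 4 columns")
  df <- data.frame(
    chrom = vapply(fields, `[`, character(1), 1L),
    pos = as.integer(vapply(fields, `[`, character(1), 2L)),
    methylated_count = as.integer(vapply(fields, `[`, character(1), 3L)),
    total_count = as.integer(vapply(fields, `[`, character(1), 4L)),
    stringsAsFactors = FALSE)
  if (anyNA(df$pos) || anyNA(df$methylated_count) || anyNA(df$total_count))
    stop("per-CpG file contains non-integer fields")
  if (any(df$methylated_count < 0) || any(df$total_count <= 0))
    stop("counts must satisfy methylated_count >= 0 and total_count > 0")
  if (any(df$methylated_count > df$total_count))
    stop("methylated_count exceeds total_count")
  df
}

#' Write per-CpG methylation counts
#' @param cpgs data.frame as returned by [parse_cpg_bedgraph()].
#' @param path Output path.
#' @export
write_cpg_bedgraph <- function(cpgs, path) {
  writeLines(c("#chrom\tpos\tmethylated_count\ttotal_count",
               paste(cpgs$chrom, cpgs$pos, cpgs$methylated_count,
                     cpgs$total_count, sep = "\t")), path)
  invisible(path)
}

#' Parse a gene expression table
#'
#' TSV with a `gene_id` column followed by one FPM column per sample.
#'
#' @param path Input path.
#' @return data.frame: `gene_id` plus numeric sample columns (FPM >= 0).
#' @export
parse_expression <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE)
  if (names(df)[1L] != "gene_id" || ncol(df) < 2L)
    stop("expression table must have a gene_id column plus sample columns")
  if (anyDuplicated(df$gene_id))
    stop("duplicated gene_id in expression table")
  for (j in 2:ncol(df)) {
    v <- df[[j]]
    if (!is.numeric(v) || anyNA(v)) stop("non-numeric FPM values")
    if (any(v < 0)) stop("negative FPM values")
  }
  df
}

#' Write a gene expression table (FPM values to 6 decimals)
#' @param expression data.frame as returned by [parse_expression()].
#' @param path Output path.
#' @export
write_expression <- function(expression, path) {
  out <- expression
  for (j in 2:ncol(out)) out[[j]] <- sprintf("%.6f", out[[j]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Parse a gene model table
#'
#' TSV with columns `gene_id`, `chrom`, `strand`, `tss`, `tts` (1-based
#' positions) and `exon_starts`/`exon_ends` (comma lists, 0-based half-open).
#'
#' @param path Input path.
#' @return data.frame with list columns `exon_starts`, `exon_ends`.
#' @export
parse_genes <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "strand", "tss", "tts",
            "exon_starts", "exon_ends")
  if (!all(need %in% names(df)))
    stop("gene model table is missing required columns")
  if (!all(df$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  es <- lapply(strsplit(as.character(df$exon_starts), ",", fixed = TRUE), as.integer)
  ee <- lapply(strsplit(as.character(df$exon_ends), ",", fixed = TRUE), as.integer)
  if (any(lengths(es) != lengths(ee)))
    stop("exon_starts and exon_ends differ in length")
  bad <- mapply(function(s, e) any(e <= s), es, ee)
  if (any(bad)) stop("exon with end <= start")
  df$exon_starts <- es
  df$exon_ends <- ee
  df
}

#' Write a gene model table
#' @param genes data.frame as returned by [parse_genes()].
#' @param path Output path.
#' @export
write_genes <- function(genes, path) {
  out <- data.frame(
    gene_id = genes$gene_id, chrom = genes$chrom, strand = genes$strand,
    tss = genes$tss, tts = genes$tts,
    exon_starts = vapply(genes$exon_starts, paste, character(1), collapse = ","),
    exon_ends = vapply(genes$exon_ends, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
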
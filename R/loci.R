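#' Enumerate 4-CpG epiallele loci from epireads
#'
#' Builds the observed CpG map per chromosome (positions seen in the reads,
#' restricted to CpGs with at least `min_cpg_coverage` valid calls), slides a
#' stride-1 window of 4 consecutive map CpGs, and counts, per window, the
#' epiallele pattern of every read with valid (non-missing) calls at all four
#' positions. Windows with depth below `min_locus_depth` are dropped.
#'
#' @param reads Epiread data.frame (see [parse_epireads()]).
#' @param config [epishift_config()] list; `min_locus_depth` (default 60) and
#'   `min_cpg_coverage` (default 10) are used here.
#' @param cpg_map Optional data.frame (`chrom`, `pos`) restricting the CpG
#'   map to a reference set of CpGs.
#' @return Pattern table data.frame: `chrom`, `start`, `end`, `positions`,
#'   counts `n0`..`n15`, plus derived `depth` and `locus_id`. Zero rows when
#'   no window passes the filters.
#' @export
#' @examples
#' reads <- data.frame(chrom = "chr1",
#'                     read_id = paste0("r", 1:60),
#'                     stringsAsFactors = FALSE)
#' reads$cpg_positions <- rep(list(c(10L, 15L, 22L, 30L)), 60)
#' reads$calls <- rep("MMMM", 60)
#' enumerate_loci(reads)$n15
enumerate_loci <- function(reads, config = epishift_config(), cpg_map = NULL) {
  empty <- .empty_pattern_table()
  if (nrow(reads) == 0L) return(empty)
  nc <- lengths(reads$cpg_positions)
  long <- data.frame(
    chrom = rep(reads$chrom, nc),
    read = rep(seq_len(nrow(reads)), nc),
    pos = unlist(reads$cpg_positions, use.names = FALSE),
    call = unlist(strsplit(reads$calls, "", fixed = TRUE), use.names = FALSE),
    stringsAsFactors = FALSE)
  long <- long[long$call != ".", , drop = FALSE]
  if (nrow(long) == 0L) return(empty)
  long$meth <- as.integer(long$call == "M")

  out <- list()
  for (ch in unique(long$chrom)) {
    d <- long[long$chrom == ch, , drop = FALSE]
    cov <- table(d$pos)
    map <- sort(as.integer(names(cov)[cov >= config$min_cpg_coverage]))
    if (!is.null(cpg_map))
      map <- map[map %in% cpg_map$pos[cpg_map$chrom == ch]]
    if (length(map) < 4L) next
    d$idx <- match(d$pos, map)
    d <- d[!is.na(d$idx), , drop = FALSE]
    d <- d[order(d$read, d$idx), , drop = FALSE]
    n <- nrow(d)
    if (n < 4L) next
    i1 <- seq_len(n - 3L)
    ok <- d$read[i1] == d$read[i1 + 3L] &
      d$idx[i1 + 1L] == d$idx[i1] + 1L &
      d$idx[i1 + 2L] == d$idx[i1] + 2L &
      d$idx[i1 + 3L] == d$idx[i1] + 3L
    w <- i1[ok]
    if (!length(w)) next
    win <- d$idx[w]
    pat <- 8L * d$meth[w] + 4L * d$meth[w + 1L] +
      2L * d$meth[w + 2L] + d$meth[w + 3L]
    tab <- table(factor(win, levels = sort(unique(win))),
                 factor(pat, levels = 0:15))
    counts <- matrix(as.integer(tab), nrow = nrow(tab))
    depth <- rowSums(counts)
    keep <- depth >= config$min_locus_depth
    if (!any(keep)) next
    starts <- as.integer(rownames(tab))[keep]
    counts <- counts[keep, , drop = FALSE]
    block <- data.frame(chrom = ch,
                        start = map[starts],
                        end = map[starts + 3L],
                        positions = vapply(starts, function(j)
                          paste(map[j:(j + 3L)], collapse = ","), character(1)),
                        stringsAsFactors = FALSE)
    cdf <- as.data.frame(counts)
    names(cdf) <- paste0("n", 0:15)
    out[[ch]] <- cbind(block, cdf)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  .finish_pattern_table(res)
}

.empty_pattern_table <- function() {
  df <- data.frame(chrom = character(), start = integer(), end = integer(),
                   positions = character(), stringsAsFactors = FALSE)
  for (nm in paste0("n", 0:15)) df[[nm]] <- integer()
  df$depth <- integer()
  df$locus_id <- character()
  df
}
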
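# Shared fixtures and independent brute-force oracles.

# expand pattern counts into one row per read and recompute the metrics
# read-by-read, independently of the vectorized implementation
oracle_metrics <- function(counts) {
  reads <- rep(0:15, counts)  # one pattern index per read
  n <- length(reads)
  bits <- t(vapply(reads, function(i) as.integer(intToBits(i))[4:1],
                   integer(4)))
  p_hat <- as.vector(table(factor(reads, levels = 0:15))) / n
  list(
    epi = 1 - sum(p_hat^2),
    pdr = mean(reads != 0 & reads != 15),
    mean_meth = mean(rowSums(bits)) / 4
  )
}

# brute-force locus enumeration: every window of 4 consecutive CpGs of the
# coverage-filtered map, counting reads one at a time
oracle_enumerate <- function(reads, config = epishift_config()) {
  out <- list()
  for (ch in unique(reads$chrom)) {
    rr <- reads[reads$chrom == ch, , drop = FALSE]
    cov <- list()
    for (i in seq_len(nrow(rr))) {
      pos <- rr$cpg_positions[[i]]
      cal <- strsplit(rr$calls[i], "")[[1]]
      for (j in seq_along(pos)) {
        if (cal[j] != ".") {
          key <- as.character(pos[j])
          cov[[key]] <- (if (is.null(cov[[key]])) 0L else cov[[key]]) + 1L
        }
      }
    }
    map <- sort(as.integer(names(cov)[unlist(cov) >= config$min_cpg_coverage]))
    if (length(map) < 4) next
    for (w in seq_len(length(map) - 3)) {
      quad <- map[w:(w + 3)]
      counts <- integer(16)
      for (i in seq_len(nrow(rr))) {
        pos <- rr$cpg_positions[[i]]
        cal <- strsplit(rr$calls[i], "")[[1]]
        idx <- match(quad, pos)
        if (anyNA(idx)) next
        c4 <- cal[idx]
        if (any(c4 == ".")) next
        pat <- sum(as.integer(c4 == "M") * c(8, 4, 2, 1))
        counts[pat + 1] <- counts[pat + 1] + 1L
      }
      if (sum(counts) >= config$min_locus_depth) {
        out[[length(out) + 1]] <- data.frame(
          chrom = ch, start = quad[1], end = quad[4],
          positions = paste(quad, collapse = ","),
          depth = sum(counts),
          key = paste(ch, paste(quad, collapse = ",")),
          counts = I(list(counts)), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

# simple epiread builder: n reads over the same 4 CpGs with given patterns
make_reads <- function(patterns_idx, positions = c(100L, 110L, 120L, 130L),
                       chrom = "chr1", id_prefix = "r") {
  n <- length(patterns_idx)
  df <- data.frame(chrom = chrom,
                   read_id = paste0(id_prefix, seq_len(n)),
                   stringsAsFactors = FALSE)
  df$cpg_positions <- rep(list(positions), n)
  df$calls <- vapply(patterns_idx, function(i)
    paste(decode_pattern(i), collapse = ""), character(1))
  df
}

# pattern table with a single locus holding the given counts
make_patterns <- function(counts, chrom = "chr1",
                          positions = c(100L, 110L, 120L, 130L)) {
  df <- data.frame(chrom = chrom, start = positions[1], end = positions[4],
                   positions = paste(positions, collapse = ","),
                   stringsAsFactors = FALSE)
  for (i in 0:15) df[[paste0("n", i)]] <- counts[i + 1]
  df$depth <- sum(counts)
  df$locus_id <- sprintf("%s:%d-%d", chrom, positions[1], positions[4])
  df
}

# stack several make_patterns loci at spaced positions
make_patterns_multi <- function(counts_list, chrom = "chr1") {
  do.call(rbind, lapply(seq_along(counts_list), function(i)
    make_patterns(counts_list[[i]], chrom = chrom,
                  positions = c(100L, 110L, 120L, 130L) + 1000L * (i - 1L))))
}

random_counts <- function(min_depth = 1, max_depth = 200) {
  depth <- sample(min_depth:max_depth, 1)
  as.vector(rmultinom(1, depth, prob = rgamma(16, 0.4) + 1e-6))
}
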